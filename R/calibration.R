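#' Fit results
#'
#' Both calibration routines return an object of class `osteo_fit`: the point
#' estimate, the sampling chain (MCMC) or residual history (least squares),
#' the final loss, diagnostics, and the seed that reproduces the fit.
#'
#' @name osteo_fit
NULL

new_osteo_fit <- function(method, point_estimate, loss, seed, chain = NULL,
                          history = NULL, diagnostics = list()) {
  structure(list(method = method, point_estimate = point_estimate,
                 loss = loss, chain = chain, history = history,
                 diagnostics = diagnostics, seed = seed),
            class = "osteo_fit")
}

#' @export
print.osteo_fit <- function(x, ...) {
  cat("osteoscale fit (", x$method, "), loss = ", format(x$loss), "\n", sep = "")
  print(round(x$point_estimate, 5))
  invisible(x)
}

#' @export
coef.osteo_fit <- function(object, ...) object$point_estimate

#' @export
summary.osteo_fit <- function(object, ...) {
  cat("Method:", object$method, "  seed:", object$seed, "\n")
  cat("Loss:", format(object$loss), "\n")
  if (!is.null(object$chain)) {
    cat("Chains:", dim(object$chain)[3], "x", dim(object$chain)[1],
        "kept samples\n")
    cat("Acceptance rate(s):",
        paste(round(object$diagnostics$acceptance, 3), collapse = ", "), "\n")
    if (!is.null(object$diagnostics$rhat))
      cat("Split R-hat:", paste(round(object$diagnostics$rhat, 3),
                                collapse = ", "), "\n")
    q <- apply(object$chain, 2, stats::quantile, c(0.025, 0.5, 0.975))
    print(t(round(q, 5)))
  } else {
    print(round(object$point_estimate, 6))
  }
  invisible(object)
}

# log-posterior for the molecular model: Gaussian likelihood of the observed
# phospho-trajectories + log-uniform prior on the free rates
.molecular_logpost <- function(log_free, free, base, prior_lower, prior_upper,
                               net, schedule, obs, sigma) {
  th <- exp(log_free)
  if (any(th < prior_lower[free] - 1e-12) || any(th > prior_upper[free] + 1e-12))
    return(-Inf)
  params <- base
  params[free] <- th
  pred <- tryCatch(
    .predict_rppa(net, params, schedule, obs),
    error = function(e) NULL)
  if (is.null(pred) || any(!is.finite(pred))) return(-Inf)
  sum(stats::dnorm(obs$value, pred, sigma[obs$species], log = TRUE))
}

# model prediction at the observed (species, time) points; times are hours
# after the last delivery, matching the RPPA emulation
.predict_rppa <- function(net, params, schedule, obs) {
  t0 <- max(schedule$events$day) * 24
  times <- sort(unique(c(0, t0 + unique(obs$time_h))))
  traj <- simulate_signaling(net, params, schedule, times)
  idx <- match(t0 + obs$time_h, traj$time)
  vapply(seq_len(nrow(obs)),
         function(i) traj[[obs$species[i]]][idx[i]], numeric(1))
}

#' Calibrate kinetic rates against RPPA-like data by MCMC
#'
#' Random-walk Metropolis sampling of the log-rates against a Gaussian
#' likelihood of the observed phospho-protein time courses for one treatment
#' scenario (scenarios are fitted separately). The proposal scale adapts
#' during burn-in toward an acceptance rate of ~0.3; a short deterministic
#' optimization locates the mode before sampling starts. Priors are
#' log-uniform on `[1e-3, 10]` per rate unless overridden.
#'
#' Not all 37 rates are identifiable from 12 observed species; by default only
#' the documented identifiable subset is sampled and the remaining rates are
#' held at `base`.
#'
#' @param rppa RPPA table for one scenario: data.frame with columns `species`
#'   (network species id), `time_h` (hours after the last delivery), `value`.
#' @param net A `signaling_network`.
#' @param schedule The [treatment_schedule] the data were collected under.
#' @param free Names of the rates to sample; default the identifiable subset
#'   [identifiable_rates()].
#' @param base Full [kinetic_params] vector supplying fixed rates and the
#'   optimization start.
#' @param prior_lower,prior_upper Prior bounds (recycled over parameters).
#' @param sigma Observation noise sd: a single value, or a named vector per
#'   species; if `NULL`, estimated per species from replicate spread when
#'   replicates are present, else set to 5% of the mean observed signal.
#' @param n_iter Iterations per chain (first half discarded as burn-in).
#' @param n_chains Number of chains.
#' @param seed Integer seed; same seed gives identical chains.
#' @return An [osteo_fit] with the posterior-median point estimate and the
#'   kept samples (`chain`: iterations x parameters x chains).
#' @export
fit_molecular <- function(rppa, net, schedule,
                          free = identifiable_rates(schedule$scenario),
                          base = default_kinetic_params(),
                          prior_lower = 1e-3, prior_upper = 10,
                          sigma = NULL, n_iter = 1500, n_chains = 2,
                          seed = 1) {
  stopifnot(all(free %in% names(base)))
  dyn <- net$species$id[net$species$role == "dynamic"]
  if (!all(rppa$species %in% dyn))
    stop("rppa species not in network: ",
         paste(setdiff(unique(rppa$species), dyn), collapse = ", "))
  k <- length(free)
  prior_lower <- stats::setNames(rep_len(prior_lower, length(base)), names(base))
  prior_upper <- stats::setNames(rep_len(prior_upper, length(base)), names(base))
  if (any(prior_lower <= 0) || any(prior_upper <= prior_lower))
    stop("priors must satisfy 0 < lower < upper")

  if (is.null(sigma)) {
    if ("replicate" %in% names(rppa) && max(rppa$replicate) > 1) {
      sds <- tapply(rppa$value, rppa$species, stats::sd)
      sigma <- pmax(sds, 1e-3)
    } else {
      sigma <- stats::setNames(rep(0.05 * max(mean(rppa$value), 1e-6),
                                   length(unique(rppa$species))),
                               unique(rppa$species))
    }
  } else if (length(sigma) == 1) {
    sigma <- stats::setNames(rep(sigma, length(unique(rppa$species))),
                             unique(rppa$species))
  }

  lp <- function(lth) .molecular_logpost(lth, free, base, prior_lower,
                                         prior_upper, net, schedule, rppa,
                                         sigma)
  set.seed(seed)
  start <- log(base[free])
  if (!is.finite(lp(start)))
    stop("non-finite likelihood at initialization (start outside the prior ",
         "support?); consider widening the prior")
  if (k == 1) {
    opt <- stats::optimize(function(x) -lp(x), log(c(prior_lower[free],
                                                     prior_upper[free])),
                           tol = 1e-8)
    opt <- list(par = stats::setNames(opt$minimum, free),
                value = opt$objective)
  } else {
    opt <- stats::optim(start, function(x) -lp(x), method = "Nelder-Mead",
                        control = list(maxit = 300, reltol = 1e-8))
  }
  mode <- opt$par

  keep <- floor(n_iter / 2)
  chain <- array(NA_real_, c(keep, k, n_chains),
                 dimnames = list(NULL, free, NULL))
  acc_rate <- numeric(n_chains)
  for (ch in seq_len(n_chains)) {
    set.seed(seed + 1000 * ch)
    cur <- mode + stats::rnorm(k, 0, 0.05)
    cur_lp <- lp(cur)
    step <- 0.1
    n_acc <- 0
    for (it in seq_len(n_iter)) {
      prop <- cur + stats::rnorm(k, 0, step)
      prop_lp <- lp(prop)
      if (is.finite(prop_lp) && log(stats::runif(1)) < prop_lp - cur_lp) {
        cur <- prop; cur_lp <- prop_lp; n_acc <- n_acc + 1
      }
      # Robbins-Monro scale adaptation during burn-in only
      if (it <= n_iter / 2)
        step <- exp(log(step) + (n_acc / it - 0.3) / sqrt(it))
      if (it > n_iter - keep)
        chain[it - (n_iter - keep), , ch] <- exp(cur)
    }
    acc_rate[ch] <- n_acc / n_iter
  }
  flat <- apply(chain, 2, as.vector)
  est <- apply(flat, 2, stats::median)
  rhat <- .split_rhat(chain)
  diag <- list(acceptance = acc_rate, rhat = rhat,
               acceptance_flag = any(acc_rate < 0.05 | acc_rate > 0.7),
               mode_loss = opt$value, sigma = sigma)
  new_osteo_fit("mcmc", est, loss = -lp(log(est)), seed = seed,
                chain = chain, diagnostics = diag)
}

.split_rhat <- function(chain) {
  # split each chain in half; classic potential-scale-reduction statistic
  k <- dim(chain)[2]
  vapply(seq_len(k), function(j) {
    halves <- list()
    for (ch in seq_len(dim(chain)[3])) {
      x <- chain[, j, ch]
      h <- floor(length(x) / 2)
      halves <- c(halves, list(x[1:h]), list(x[(h + 1):(2 * h)]))
    }
    m <- length(halves); n <- length(halves[[1]])
    means <- vapply(halves, mean, numeric(1))
    vars <- vapply(halves, stats::var, numeric(1))
    W <- mean(vars); B <- n * stats::var(means)
    if (W < 1e-300) return(1)
    sqrt(((n - 1) / n * W + B / n) / W)
  }, numeric(1))
}

#' Documented identifiable subset of the molecular rates
#'
#' Rates whose species are directly observed in the RPPA emulation and whose
#' profile likelihood is curved under that scenario's sampling design. RPPA
#' sampling starts at the last delivery, so a scenario only informs the rates
#' of proteins whose activation transient it covers: the BMP-2 arm (p38 MAPK
#' and SMAD1/5 pairs) is identified from B1-type scenarios, and the IGF-1 arm
#' (ERK, Akt and S6 phosphorylation plus the shared MAPK-cascade
#' dephosphorylation) from scenarios whose last delivery is IGF-1; rates of
#' pools already at steady state when sampling starts are ridge-constrained
#' (only their ratio is determined) and are excluded.
#'
#' @param scenario Scenario label (e.g. `"B1"`, `"B1I4"`).
#' @return Character vector of parameter names.
#' @export
identifiable_rates <- function(scenario = "B1") {
  last <- substr(gsub("[0-9]", "", scenario), nchar(gsub("[0-9]", "", scenario)),
                 nchar(gsub("[0-9]", "", scenario)))
  if (identical(last, "B"))
    c("a_pP38", "d_pP38", "a_pSMAD15", "d_pSMAD15")
  else
    c("a_pERK", "a_pAkt", "a_pS6", "d_mapk")
}

#' Calibrate lineage rates against dsDNA/ARS data by least squares
#'
#' Minimizes the summed squared residuals of normalized total cell mass (dsDNA
#' days 1/4/8/11) and the day-28 osteoblast readout normalized to control
#' (ARS), jointly across scenarios, with bounded Levenberg-Marquardt
#' (multi-start). TF readouts enter as fixed inputs (they come from the
#' molecular scale).
#'
#' @param dsdna data.frame `scenario`, `day`, `replicate`, `mass_norm`.
#' @param ars data.frame `scenario`, `replicate`, `ars_norm`.
#' @param tf Named list (by scenario) of per-event TF readout tables.
#' @param schedules Named list (by scenario) of [treatment_schedule]s; must
#'   include `"control"` for the ARS normalization.
#' @param free Names of the lineage parameters to fit.
#' @param base [lineage_params] supplying fixed values and the start point.
#' @param lower,upper Box bounds on the free parameters (recycled).
#' @param n_starts Extra random starts beyond `base`.
#' @param oba_day Day of the osteoblast readout (default 28, the ARS assay
#'   day).
#' @param seed Seed for the random starts.
#' @return An [osteo_fit]; `point_estimate` holds the fitted free parameters,
#'   `diagnostics$params` the full [lineage_params] object.
#' @export
fit_cellular <- function(dsdna, ars, tf, schedules,
                         free = c("b_1", "i_3", "D0_MSC", "D0_OBp"),
                         base = default_lineage_params(),
                         lower = 1e-6, upper = 5, n_starts = 3,
                         oba_day = 28, seed = 1) {
  stopifnot(all(free %in% names(base)), "control" %in% names(schedules))
  scen <- intersect(names(schedules), unique(c(dsdna$scenario, ars$scenario)))
  lower <- stats::setNames(rep_len(lower, length(free)), free)
  upper <- stats::setNames(rep_len(upper, length(free)), free)
  resid_fun <- function(theta) {
    p <- base
    p[free] <- as.list(pmin(pmax(theta, lower), upper))
    class(p) <- "lineage_params"
    .cellular_resid(p, dsdna, ars, tf, schedules, oba_day)
  }

  start0 <- unlist(base[free])
  r0 <- resid_fun(start0)
  grad_norm <- sqrt(sum(vapply(seq_along(start0), function(j) {
    h <- pmax(abs(start0[j]) * 1e-4, 1e-8)
    th <- start0; th[j] <- th[j] + h
    sum((resid_fun(th) - r0) * r0 * 2 / h)^2
  }, numeric(1))))
  flat_warning <- grad_norm < 1e-12 && sum(r0^2) > 1e-12
  if (flat_warning)
    warning("loss surface is flat at the start (gradient ~ 0); ",
            "the selected parameters may be unidentifiable")

  set.seed(seed)
  starts <- list(start0)
  for (i in seq_len(n_starts))
    starts[[i + 1]] <- lower + stats::runif(length(free)) * (pmin(upper, 2) - lower)
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = st, fn = resid_fun, lower = lower,
                         upper = upper,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-14, ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    loss <- sum(fit$fvec^2)
    if (is.null(best) || loss < best$loss)
      best <- list(fit = fit, loss = loss)
  }
  if (is.null(best)) stop("all least-squares starts failed")
  est <- stats::setNames(pmin(pmax(coef(best$fit), lower), upper), free)
  full <- base
  full[free] <- as.list(est)
  class(full) <- "lineage_params"
  new_osteo_fit("least-squares", est, loss = best$loss, seed = seed,
                history = best$fit$rsstrace,
                diagnostics = list(params = full, n_iter = best$fit$niter,
                                   flat_start = flat_warning))
}

.cellular_resid <- function(params, dsdna, ars, tf, schedules, oba_day = 28) {
  scen <- intersect(names(schedules), unique(c(dsdna$scenario, ars$scenario)))
  mass_days <- sort(unique(dsdna$day))
  horizon <- max(oba_day + 1, mass_days)
  trajs <- lapply(stats::setNames(nm = unique(c(scen, "control"))),
                  function(s) simulate_lineage(params, schedules[[s]],
                                               tf[[s]],
                                               horizon_days = horizon))
  res <- numeric(0)
  for (s in scen) {
    o <- observables(trajs[[s]], mass_days = mass_days, oba_day = oba_day,
                     control = trajs[["control"]])
    ds <- dsdna[dsdna$scenario == s, ]
    pred <- o$total_mass$mass_norm[match(ds$day, mass_days)]
    res <- c(res, ds$mass_norm - pred)
    as_ <- ars[ars$scenario == s, ]
    if (nrow(as_)) res <- c(res, as_$ars_norm - o$oba_norm)
  }
  res
}

#' Cellular calibration loss at a given parameter set
#'
#' The summed squared residuals of normalized total mass and normalized
#' osteoblast readout that [fit_cellular()] minimizes, evaluated at `params`.
#'
#' @inheritParams fit_cellular
#' @param params A [lineage_params] object.
#' @return Scalar loss (>= 0).
#' @export
cellular_loss <- function(params, dsdna, ars, tf, schedules, oba_day = 28) {
  sum(.cellular_resid(params, dsdna, ars, tf, schedules, oba_day)^2)
}

#' Per-scenario dispersion of fitted rates
#'
#' Descriptive summary of how spread out fitted rate constants are in each
#' treatment scenario: the count of parameters below `lo`, above `hi`, their
#' sum ("extreme" rates, signalling substantially impeded or enhanced
#' transduction steps), and the standard deviation and IQR of the values.
#'
#' @param fits Named list (by scenario) of [osteo_fit] objects or bare named
#'   parameter vectors on a common parameter set.
#' @param lo,hi Thresholds (defaults 0.02 and 0.08).
#' @return data.frame with one row per scenario.
#' @export
parameter_dispersion <- function(fits, lo = 0.02, hi = 0.08) {
  if (length(fits) < 2) stop("need fits for at least 2 scenarios")
  vals <- lapply(fits, function(f)
    if (inherits(f, "osteo_fit")) f$point_estimate else f)
  common <- Reduce(intersect, lapply(vals, names))
  if (!length(common)) stop("fits share no common parameters")
  out <- do.call(rbind, lapply(names(vals), function(s) {
    v <- vals[[s]][common]
    data.frame(scenario = s,
               n_low = sum(v < lo), n_high = sum(v > hi),
               n_extreme = sum(v < lo | v > hi),
               sd = stats::sd(v), iqr = stats::IQR(v))
  }))
  rownames(out) <- NULL
  out
}
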