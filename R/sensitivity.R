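#' Latin hypercube sample
#'
#' One sample per stratum per parameter, scaled to the requested bounds.
#'
#' @param bounds Named list of `c(lower, upper)` per parameter, or a 2-row
#'   matrix with named columns.
#' @param n Number of samples (one per stratum).
#' @param seed Integer seed; same seed gives identical matrices.
#' @return `n` x `k` matrix with parameter names as columns.
#' @export
lhs_sample <- function(bounds, n, seed = 1) {
  if (is.matrix(bounds))
    bounds <- stats::setNames(lapply(seq_len(ncol(bounds)),
                                     function(j) bounds[, j]),
                              colnames(bounds))
  k <- length(bounds)
  lo <- vapply(bounds, `[`, numeric(1), 1)
  hi <- vapply(bounds, `[`, numeric(1), 2)
  if (any(!is.finite(lo)) || any(!is.finite(hi)) || any(hi <= lo))
    stop("bounds must be finite with lower < upper")
  set.seed(seed)
  u <- lhs::randomLHS(n, k)
  x <- sweep(sweep(u, 2, hi - lo, `*`), 2, lo, `+`)
  colnames(x) <- names(bounds)
  x
}

#' Partial rank correlation coefficients
#'
#' Spearman partial rank correlation between each sampled parameter and the
#' model output, controlling for all other parameters: every column is rank
#' transformed, the other parameters are regressed out of both the parameter
#' and the output, and the residuals are correlated.
#'
#' @param samples `n` x `k` parameter matrix (e.g. from [lhs_sample()]).
#' @param outputs Numeric vector of length `n`.
#' @return Named vector of PRCC values in `[-1, 1]`. If the output is
#'   constant the PRCC is undefined; 0 is returned for every parameter with
#'   attribute `constant_output = TRUE`.
#' @export
prcc <- function(samples, outputs) {
  stopifnot(nrow(samples) == length(outputs))
  if (nrow(samples) < ncol(samples) + 3)
    stop("need at least 3 more samples than parameters")
  if (any(!is.finite(outputs))) stop("outputs must be finite")
  k <- ncol(samples)
  if (stats::sd(outputs) < 1e-300) {
    out <- stats::setNames(rep(0, k), colnames(samples))
    attr(out, "constant_output") <- TRUE
    return(out)
  }
  R <- apply(samples, 2, rank)
  ry <- rank(outputs)
  out <- stats::setNames(numeric(k), colnames(samples))
  for (j in seq_len(k)) {
    others <- R[, -j, drop = FALSE]
    rx <- if (ncol(others)) stats::lm.fit(cbind(1, others), R[, j])$residuals
          else R[, j] - mean(R[, j])
    ryr <- if (ncol(others)) stats::lm.fit(cbind(1, others), ry)$residuals
           else ry - mean(ry)
    out[j] <- if (stats::sd(rx) < 1e-300 || stats::sd(ryr) < 1e-300) 0
              else stats::cor(rx, ryr)
  }
  attr(out, "constant_output") <- FALSE
  out
}

#' Extended Fourier Amplitude Sensitivity Test (eFAST)
#'
#' Standard eFAST variance decomposition: each parameter in turn is assigned
#' the high driving frequency while the others share low complementary
#' frequencies; the model is evaluated along `NR` random-phase search curves;
#' the first-order (main effect) index is the variance at the parameter's
#' frequency and its first `M` harmonics over the total variance, and the
#' total-order index is one minus the variance in the low-frequency complement
#' spectrum. A dummy parameter (appended automatically) provides a
#' significance floor.
#'
#' @param fn Deterministic model function taking a parameter vector (named as
#'   in `bounds`; the dummy parameter is stripped before the call).
#' @param bounds Named list of `c(lower, upper)` per parameter.
#' @param n Samples per search curve (>= 65; default 257).
#' @param M Number of harmonics (default 4).
#' @param NR Number of resampling curves (default 3).
#' @param seed Integer seed.
#' @param dummy Include a dummy parameter (default `TRUE`).
#' @return Object of class `sensitivity_result`: data.frame with columns
#'   `param`, `main_effect`, `total_effect`; attributes `n`, `M`, `NR`,
#'   `seed`.
#' @export
efast <- function(fn, bounds, n = 257, M = 4, NR = 3, seed = 1,
                  dummy = TRUE) {
  if (dummy) bounds <- c(bounds, list(.dummy = c(0, 1)))
  k <- length(bounds)
  pn <- names(bounds)
  omega_max <- floor((n - 1) / (2 * M))
  if (omega_max < 2 * M)
    stop("n too small for M = ", M, " harmonics; need n >= ", 4 * M^2 + 1)
  m_c <- max(1, floor(omega_max / (2 * M)))
  lo <- vapply(bounds, `[`, numeric(1), 1)
  hi <- vapply(bounds, `[`, numeric(1), 2)
  s <- (2 * pi / n) * (0:(n - 1))
  set.seed(seed)

  main <- total <- matrix(NA_real_, k, NR, dimnames = list(pn, NULL))
  for (i in seq_len(k)) {
    omega <- if (k > 1) {
      w <- numeric(k)
      w[i] <- omega_max
      w[-i] <- (seq_len(k - 1) - 1) %% m_c + 1
      w
    } else omega_max
    for (r in seq_len(NR)) {
      phi <- stats::runif(k, 0, 2 * pi)
      X <- vapply(seq_len(k), function(j)
        0.5 + asin(sin(omega[j] * s + phi[j])) / pi, numeric(n))
      X <- sweep(sweep(X, 2, hi - lo, `*`), 2, lo, `+`)
      colnames(X) <- pn
      y <- apply(X, 1, function(row) {
        if (dummy) row <- row[pn != ".dummy"]
        fn(row)
      })
      if (any(!is.finite(y))) stop("model returned non-finite output")
      f <- stats::fft(y - mean(y))
      nh <- floor((n - 1) / 2)
      Sp <- (Mod(f[2:(nh + 1)])^2) / n^2  # one-sided spectrum (freq 1..nh)
      V <- 2 * sum(Sp)
      Di <- 2 * sum(Sp[seq_len(M) * omega_max])
      # everything below omega_max/2 is attributed to the complementary set
      Dc <- 2 * sum(Sp[seq_len(floor(omega_max / 2))])
      main[i, r] <- if (V > 0) Di / V else 0
      total[i, r] <- if (V > 0) 1 - Dc / V else 0
    }
  }
  res <- data.frame(param = pn,
                    main_effect = rowMeans(main),
                    total_effect = rowMeans(total))
  rownames(res) <- NULL
  structure(res, class = c("sensitivity_result", "data.frame"),
            n = n, M = M, NR = NR, seed = seed)
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat("eFAST sensitivity (n =", attr(x, "n"), ", M =", attr(x, "M"),
      ", NR =", attr(x, "NR"), ")\n")
  print(data.frame(param = x$param,
                   main_effect = round(x$main_effect, 4),
                   total_effect = round(x$total_effect, 4)))
  invisible(x)
}

#' Parameters accounting for at least a given share of output variance
#'
#' Filters the eFAST first-order indices at a variance-share threshold
#' (default 2%), sorted descending -- the parameters worth illustrating.
#'
#' @param result A `sensitivity_result` from [efast()].
#' @param threshold Minimum variance share (default 0.02).
#' @return data.frame `param`, `main_effect`, `share_pct`, sorted descending;
#'   zero rows if no parameter reaches the threshold.
#' @export
variance_share_report <- function(result, threshold = 0.02) {
  df <- as.data.frame(result)
  df <- df[df$param != ".dummy" & df$main_effect >= threshold, ]
  df <- df[order(-df$main_effect), c("param", "main_effect")]
  df$share_pct <- 100 * df$main_effect
  rownames(df) <- NULL
  df
}

#' Model-output closures for sensitivity analysis
#'
#' The default output functionals the package analyzes: for the molecular
#' system, a transcription-factor readout (Runx2 by default) of a scenario
#' simulation as a function of selected kinetic rates; for the cellular
#' system, day-29 osteoblast mass as a function of selected lineage
#' parameters (TF readouts held fixed).
#'
#' @param net A `signaling_network`.
#' @param schedule A [treatment_schedule].
#' @param free Names of the parameters the closure varies.
#' @param base Full parameter object supplying the fixed values.
#' @param tf_name Which TF readout (`"Runx2"`, `"osterix"`, `"bcatenin"`,
#'   `"proliferative"`).
#' @param window_h Readout window (hours).
#' @param tf Per-event TF readout table (cellular closure).
#' @param day OBa readout day (cellular closure).
#' @return A function mapping a (named or positional) vector over `free` to a
#'   scalar model output.
#' @export
molecular_output <- function(net, schedule, free,
                             base = default_kinetic_params(),
                             tf_name = "Runx2", window_h = 72) {
  force(net); force(schedule); force(base)
  function(x) {
    p <- base
    p[free] <- as.numeric(x)
    tfr <- tf_event_readouts(net, p, schedule, window_h = window_h)
    mean(tfr[[tf_name]])
  }
}

#' @rdname molecular_output
#' @export
cellular_output <- function(schedule, tf, free,
                            base = default_lineage_params(), day = 29) {
  force(schedule); force(tf); force(base)
  function(x) {
    p <- base
    p[free] <- as.list(as.numeric(x))
    class(p) <- "lineage_params"
    traj <- simulate_lineage(p, schedule, tf, horizon_days = day)
    observables(traj, oba_day = day)$oba
  }
}
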