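#' Mass-action right-hand side of the signaling system
#'
#' Evaluates, for every dynamic species `M`, the mass-action balance
#' `d[pM]/dt = sum_j a_j [pA_j] (C_M - [pM]) - sum_j d_j [I_j] [pM]`, where the
#' `a_j` terms run over the species' activators (read from the network's
#' activation edges; unphosphorylated complements are used where the sign
#' convention demands, e.g. active GSK3beta driving beta-catenin
#' phosphorylation), the basal deactivation term has an implicit unit
#' phosphatase concentration, and inhibition edges contribute additional
#' `d_j [I_j] [pM]` terms. Ligand-receptor complexes follow the same form with
#' association/dissociation rates; unpaired activity variables use a unit
#' capacity.
#'
#' @param state List with elements `t` (time, hours) and `concentrations`
#'   (named vector covering all dynamic species; input ligands may be included
#'   and default to 0).
#' @param params A [kinetic_params] vector complete for `net`.
#' @param net A `signaling_network`.
#' @return Named vector of time derivatives for the dynamic species.
#' @export
signaling_rhs <- function(state, params, net) {
  conc <- state$concentrations
  if (any(conc < 0))
    stop("negative concentration in state: ",
         paste(names(conc)[conc < 0], collapse = ", "))
  pt <- param_table(net)
  missing <- setdiff(unique(pt$param), names(params))
  if (length(missing))
    stop("missing kinetic parameter(s): ", paste(missing, collapse = ", "))
  dyn <- net$species$id[net$species$role == "dynamic"]
  for (i in seq_len(nrow(net$pairs))) {
    ph <- net$pairs$phospho[i]
    if (ph %in% names(conc) &&
        conc[[ph]] > net$totals[[net$pairs$total_id[i]]] + 1e-9)
      stop("state violates conservation bound for ", ph)
  }
  lookup <- function(sp) {
    if (sp %in% names(conc)) return(conc[[sp]])
    j <- match(sp, net$pairs$base)
    if (!is.na(j)) {
      ph <- net$pairs$phospho[j]
      return(net$totals[[net$pairs$total_id[j]]] - conc[[ph]])
    }
    0
  }
  dy <- stats::setNames(numeric(length(dyn)), dyn)
  for (k in seq_len(nrow(pt))) {
    tgt <- pt$target[k]
    rate <- params[[pt$param[k]]]
    src <- if (is.na(pt$source[k])) 1 else lookup(pt$source[k])
    cap <- if (is.na(pt$capacity[k])) 1 else net$totals[[pt$capacity[k]]]
    dy[tgt] <- dy[tgt] + if (pt$type[k] == "a")
      rate * src * (cap - conc[[tgt]]) else -rate * src * conc[[tgt]]
  }
  dy
}

# Compiled RHS closure for the integrator: precomputes index vectors so each
# evaluation is a handful of vectorized operations. Ligand levels are computed
# from the schedule inside the closure (step inputs, optional decay).
make_rhs_fun <- function(net, params, schedule, ref_dose = 50, decay = 0) {
  pt <- param_table(net)
  missing <- setdiff(unique(pt$param), names(params))
  if (length(missing))
    stop("missing kinetic parameter(s): ", paste(missing, collapse = ", "))
  dyn <- net$species$id[net$species$role == "dynamic"]
  n <- length(dyn)
  rate <- as.numeric(params[pt$param])
  tgt <- match(pt$target, dyn)
  cap <- ifelse(is.na(pt$capacity), 1, unname(net$totals[pt$capacity]))
  # source kinds: 0 basal (constant 1), 1 dynamic, 2 algebraic complement,
  # 3 input ligand
  kind <- integer(nrow(pt)); sidx <- integer(nrow(pt)); stot <- numeric(nrow(pt))
  inputs <- net$species$id[net$species$role == "input"]
  for (k in seq_len(nrow(pt))) {
    s <- pt$source[k]
    if (is.na(s)) { kind[k] <- 0L; next }
    if (s %in% dyn) { kind[k] <- 1L; sidx[k] <- match(s, dyn); next }
    j <- match(s, net$pairs$base)
    if (!is.na(j)) {
      kind[k] <- 2L
      sidx[k] <- match(net$pairs$phospho[j], dyn)
      stot[k] <- net$totals[[net$pairs$total_id[j]]]
      next
    }
    if (s %in% inputs) { kind[k] <- 3L; sidx[k] <- match(s, c("BMP2", "IGF1")); next }
    stop("edge source '", s, "' is neither dynamic, paired-algebraic nor input")
  }
  is_a <- pt$type == "a"
  ev <- schedule$events
  ev_on <- ev$day * 24
  ev_amp <- ev$dose / ref_dose
  ev_cyt <- match(ev$cytokine, c("BMP2", "IGF1"))
  grp <- sort(unique(tgt))

  function(t, y, parms) {
    lig <- c(0, 0)
    on <- which(ev_on <= t)
    for (i in on) {
      a <- ev_amp[i]
      if (decay > 0) a <- a * exp(-decay * (t - ev_on[i]))
      lig[ev_cyt[i]] <- lig[ev_cyt[i]] + a
    }
    sv <- numeric(length(kind))
    sv[kind == 0L] <- 1
    sv[kind == 1L] <- y[sidx[kind == 1L]]
    sv[kind == 2L] <- stot[kind == 2L] - y[sidx[kind == 2L]]
    sv[kind == 3L] <- lig[sidx[kind == 3L]]
    flux <- ifelse(is_a, rate * sv * (cap - y[tgt]), -rate * sv * y[tgt])
    dy <- numeric(n)
    dy[grp] <- rowsum(flux, tgt)
    list(dy)
  }
}

#' Simulate the signaling ODE system
#'
#' Integrates the 20 dynamic species with a stiff-capable adaptive solver
#' (`deSolve::lsoda`), restarting at every delivery time so the ligand step
#' inputs are handled exactly, then fills the 16 algebraic complements from the
#' conservation relations. Delivered ligand is a step input held constant after
#' its delivery day (normalized so the standard 50 ng/ml dose is 1 unit);
#' exponential ligand decay is available but off by default. Initial condition
#' defaults to all phospho/complex/activity pools at zero.
#'
#' Negative excursions beyond -1e-9 abort with the time of failure; excursions
#' within `[-1e-9, 0)` (solver round-off) are clipped to 0.
#'
#' @param net A `signaling_network`.
#' @param params A [kinetic_params] vector.
#' @param schedule A [treatment_schedule].
#' @param t_grid Strictly increasing output times in hours.
#' @param initial Optional named vector of initial dynamic-species values.
#' @param rtol,atol Solver tolerances.
#' @param ligand_decay First-order ligand decay rate (per hour), default 0.
#' @return A data.frame of class `signaling_traj`: column `time` (hours) plus
#'   all 36 model variables; attribute `scenario`.
#' @export
simulate_signaling <- function(net, params, schedule, t_grid,
                               initial = NULL, rtol = 1e-6, atol = 1e-9,
                               ligand_decay = 0) {
  if (length(t_grid) < 2 || any(diff(t_grid) <= 0))
    stop("t_grid must be strictly increasing with at least two points")
  dyn <- net$species$id[net$species$role == "dynamic"]
  y0 <- stats::setNames(numeric(length(dyn)), dyn)
  if (!is.null(initial)) y0[names(initial)] <- initial
  rhs <- make_rhs_fun(net, params, schedule, decay = ligand_decay)

  ev_h <- sort(unique(schedule$events$day * 24))
  breaks <- ev_h[ev_h > min(t_grid) & ev_h < max(t_grid)]
  seg_bounds <- sort(unique(c(min(t_grid), breaks, max(t_grid))))

  out <- NULL
  y <- y0
  for (s in seq_len(length(seg_bounds) - 1)) {
    t0 <- seg_bounds[s]; t1 <- seg_bounds[s + 1]
    times <- sort(unique(c(t0, t_grid[t_grid > t0 & t_grid <= t1], t1)))
    sol <- tryCatch(
      deSolve::lsoda(y, times, rhs, parms = NULL, rtol = rtol, atol = atol,
                     tcrit = t1),
      error = function(e) stop("solver failure in [", t0, ", ", t1, "] h: ",
                               conditionMessage(e), call. = FALSE))
    if (attr(sol, "istate")[1] < 0)
      stop("solver failure near t = ", sol[nrow(sol), 1], " h")
    y <- sol[nrow(sol), -1]
    keep <- sol[, 1] %in% t_grid
    if (!is.null(out)) keep <- keep & !(sol[, 1] %in% out[, 1])
    out <- rbind(out, sol[keep, , drop = FALSE])
  }
  colnames(out) <- c("time", dyn)
  vals <- out[, -1, drop = FALSE]
  if (any(vals < -1e-9))
    stop("negative concentration beyond tolerance at t = ",
         out[which(apply(vals < -1e-9, 1, any))[1], 1], " h")
  vals[vals < 0] <- 0
  df <- data.frame(time = out[, 1], vals, check.names = FALSE)
  # algebraic complements from conservation
  for (i in seq_len(nrow(net$pairs))) {
    tot <- net$totals[[net$pairs$total_id[i]]]
    df[[net$pairs$base[i]]] <- tot - df[[net$pairs$phospho[i]]]
  }
  attr(df, "scenario") <- schedule$scenario
  class(df) <- c("signaling_traj", "data.frame")
  df
}

# trapezoid time-average of a trajectory column over [lo, hi] (hours)
.time_average <- function(tt, y, lo = min(tt), hi = max(tt)) {
  keep <- tt >= lo - 1e-9 & tt <= hi + 1e-9
  tt <- tt[keep]; y <- y[keep]
  if (length(tt) < 2) return(y[1])
  sum(diff(tt) * (utils::head(y, -1) + utils::tail(y, -1)) / 2) / (max(tt) - min(tt))
}

#' Transcription-factor activity readouts
#'
#' Reduces a signaling trajectory to one scalar per transcription factor in
#' `[0, 1]`: the time-average of the active pool over the readout window,
#' normalized by its capacity. Runx2, osterix and the proliferative program are
#' tracked directly as normalized activities; the beta-catenin readout uses the
#' *unphosphorylated* pool (`C - [p beta-catenin]`), implementing the
#' convention that the phosphorylated form is degradation-bound and inactive.
#' A time-average (rather than an endpoint) is used so short transients, such
#' as minute-scale ERK bursts, do not dominate the readout.
#'
#' @param traj A `signaling_traj` from [simulate_signaling()].
#' @param net The network it was simulated from.
#' @param window Optional `c(lo, hi)` readout window in hours; defaults to the
#'   whole trajectory.
#' @return Named vector `c(Runx2, osterix, bcatenin, proliferative)` in `[0,1]`.
#' @export
tf_readout <- function(traj, net, window = NULL) {
  if (!nrow(traj)) stop("empty trajectory")
  tt <- traj$time
  if (is.null(window)) window <- range(tt)
  c_bcat <- net$totals[["C_Bcat"]]
  vals <- c(
    Runx2 = .time_average(tt, traj$aRunx2, window[1], window[2]),
    osterix = .time_average(tt, traj$aOsterix, window[1], window[2]),
    bcatenin = .time_average(tt, (c_bcat - traj$pBcat) / c_bcat,
                             window[1], window[2]),
    proliferative = .time_average(tt, traj$aProlif, window[1], window[2])
  )
  pmin(pmax(vals, 0), 1)
}

#' Per-delivery transcription-factor readouts for a scenario
#'
#' Simulates the full scenario once and evaluates [tf_readout()] over a window
#' starting at each delivery event. These per-event scalars are the coupling
#' quantities handed to the cellular lineage model: each delivered cytokine
#' modulates lineage rates in proportion to the TF activities it (and any
#' co-present cytokine) generated during its readout window.
#'
#' @param net,params,schedule As in [simulate_signaling()].
#' @param window_h Readout window length in hours (default 72).
#' @param dt_h Output resolution of the underlying simulation, hours.
#' @param ... Passed to [simulate_signaling()].
#' @return data.frame with one row per delivery event: `cytokine`, `day`,
#'   `dose`, plus the four TF readout columns.
#' @export
tf_event_readouts <- function(net, params, schedule, window_h = 72,
                              dt_h = 0.5, ...) {
  ev <- schedule$events
  out <- data.frame(cytokine = character(0), day = numeric(0),
                    dose = numeric(0), Runx2 = numeric(0), osterix = numeric(0),
                    bcatenin = numeric(0), proliferative = numeric(0))
  if (!nrow(ev)) return(out)
  t_end <- max(ev$day) * 24 + window_h
  t_grid <- seq(0, t_end, by = dt_h)
  traj <- simulate_signaling(net, params, schedule, t_grid, ...)
  for (i in seq_len(nrow(ev))) {
    w <- c(ev$day[i] * 24, ev$day[i] * 24 + window_h)
    r <- tf_readout(traj, net, window = w)
    out <- rbind(out, data.frame(cytokine = ev$cytokine[i], day = ev$day[i],
                                 dose = ev$dose[i], t(r)))
  }
  rownames(out) <- NULL
  out
}

#' Export a trajectory as tidy CSV
#'
#' Long format with columns `time`, `species`, `value`, `scenario`.
#'
#' @param traj A `signaling_traj`.
#' @param path Output file path.
#' @export
export_trajectory <- function(traj, path) {
  sp <- setdiff(names(traj), "time")
  long <- data.frame(
    time = rep(traj$time, times = length(sp)),
    species = rep(sp, each = nrow(traj)),
    value = unlist(traj[sp], use.names = FALSE),
    scenario = attr(traj, "scenario") %||% NA_character_
  )
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
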