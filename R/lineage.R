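#' Parameters of the four-compartment cell-lineage model
#'
#' Basal per-day rates of the compartmental model (BMSC, quiescent/
#' non-osteoblastic MSCq, preosteoblast OBp, mature osteoblast OBa) plus the
#' cytokine effect coefficients that couple delivered BMP-2/IGF-1 -- through
#' their transcription-factor readouts -- to the rates, and the effective time
#' `t_p` a delivered cytokine keeps modulating the rates.
#'
#' Coupling (each term active only inside the delivery window
#' `[day, day + t_p]`, rates floored at 0):
#' \describe{
#'   \item{b_1}{BMP-2 promotion of BMSC->OBp differentiation, scaled by the
#'     Runx2 readout of the BMP-2 delivery.}
#'   \item{b_2}{BMP-2 promotion of OBp->OBa maturation, scaled by the osterix
#'     readout.}
#'   \item{i_1}{IGF-1 mitogenic promotion of all proliferation rates, scaled by
#'     the proliferative-program readout.}
#'   \item{i_2}{IGF-1 promotion of OBp->OBa maturation, scaled by the
#'     beta-catenin readout.}
#'   \item{i_3}{IGF-1 promotion of BMSC non-osteoblastic transformation, scaled
#'     by the *lack* of timely Runx2 activation (`1 - Runx2`): IGF-1 delivered
#'     before BMP-2 routes stem cells out of the osteogenic lineage.}
#'   \item{q_1}{promotion of OBp non-osteoblastic exit under IGF-1, scaled by
#'     `1 - osterix`.}
#' }
#'
#' @param P0_MSC,P0_OBp,P0_OBa Basal proliferation rates (per day).
#' @param D0_MSC,D0_OBp Basal differentiation rates (per day).
#' @param Q0_MSC,Q0_OBp Basal non-osteoblastic transformation rates (per day).
#' @param b_1,b_2,i_1,i_2,i_3,q_1 Cytokine effect coefficients (per day).
#' @param t_p Effective time of a delivered cytokine (days, > 0).
#' @return Object of class `lineage_params` (a named list).
#' @export
lineage_params <- function(P0_MSC, P0_OBp, P0_OBa, D0_MSC, D0_OBp,
                           Q0_MSC, Q0_OBp, b_1, b_2, i_1, i_2, i_3, q_1, t_p) {
  p <- list(P0_MSC = P0_MSC, P0_OBp = P0_OBp, P0_OBa = P0_OBa,
            D0_MSC = D0_MSC, D0_OBp = D0_OBp, Q0_MSC = Q0_MSC,
            Q0_OBp = Q0_OBp, b_1 = b_1, b_2 = b_2, i_1 = i_1, i_2 = i_2,
            i_3 = i_3, q_1 = q_1, t_p = t_p)
  basal <- unlist(p[c("P0_MSC", "P0_OBp", "P0_OBa", "D0_MSC", "D0_OBp",
                      "Q0_MSC", "Q0_OBp")])
  if (any(basal < 0)) stop("basal rates must be >= 0")
  if (p$t_p <= 0) stop("t_p must be > 0")
  structure(p, class = "lineage_params")
}

#' Ground-truth lineage parameters
#'
#' The packaged defaults under which the synthetic-data generator operates.
#' Proliferation rates are nearly compartment-independent (so early total-mass
#' curves barely separate between treatments); preosteoblasts that linger
#' without maturation cues leak slowly into the non-osteoblastic pool, so
#' earlier maturation compounds into more day-29 osteoblast mass.
#'
#' @return A `lineage_params` object.
#' @export
default_lineage_params <- function() {
  lineage_params(
    P0_MSC = 0.095, P0_OBp = 0.093, P0_OBa = 0.088,
    D0_MSC = 0.010, D0_OBp = 0.015,
    Q0_MSC = 0.010, Q0_OBp = 0.025,
    b_1 = 0.65, b_2 = 0.10, i_1 = 0.040, i_2 = 2.5, i_3 = 0.060,
    q_1 = 0.020, t_p = 3
  )
}

#' @export
print.lineage_params <- function(x, ...) {
  cat("Lineage parameters (per day; t_p in days):\n")
  print(unlist(x))
  invisible(x)
}

#' Time-dependent effective lineage rates
#'
#' Each rate is its basal value plus the sum, over delivery events whose window
#' `[day, day + t_p]` contains `t`, of coefficient x TF readout terms (see
#' [lineage_params()] for the coupling map). Results are floored at 0.
#'
#' @param t Time in days.
#' @param params A [lineage_params] object.
#' @param schedule A [treatment_schedule].
#' @param tf Per-event TF readouts as returned by [tf_event_readouts()]
#'   (columns `cytokine`, `day`, `Runx2`, `osterix`, `bcatenin`,
#'   `proliferative`).
#' @return Named vector `c(P_MSC, P_OBp, P_OBa, D_MSC, D_OBp, Q_MSC, Q_OBp)`.
#' @export
effective_rates <- function(t, params, schedule, tf) {
  r <- c(P_MSC = params$P0_MSC, P_OBp = params$P0_OBp, P_OBa = params$P0_OBa,
         D_MSC = params$D0_MSC, D_OBp = params$D0_OBp,
         Q_MSC = params$Q0_MSC, Q_OBp = params$Q0_OBp)
  ev <- schedule$events
  for (i in seq_len(nrow(ev))) {
    if (t < ev$day[i] || t > ev$day[i] + params$t_p) next
    j <- which(tf$cytokine == ev$cytokine[i] & tf$day == ev$day[i])[1]
    if (is.na(j))
      stop("no TF readout for event ", ev$cytokine[i], " at day ", ev$day[i])
    if (ev$cytokine[i] == "BMP2") {
      r["D_MSC"] <- r["D_MSC"] + params$b_1 * tf$Runx2[j]
      r["D_OBp"] <- r["D_OBp"] + params$b_2 * tf$osterix[j]
    } else {
      r["P_MSC"] <- r["P_MSC"] + params$i_1 * tf$proliferative[j]
      r["P_OBp"] <- r["P_OBp"] + params$i_1 * tf$proliferative[j]
      r["P_OBa"] <- r["P_OBa"] + params$i_1 * tf$proliferative[j]
      r["D_OBp"] <- r["D_OBp"] + params$i_2 * tf$bcatenin[j]
      r["Q_MSC"] <- r["Q_MSC"] + params$i_3 * (1 - tf$Runx2[j])
      r["Q_OBp"] <- r["Q_OBp"] + params$q_1 * (1 - tf$osterix[j])
    }
  }
  pmax(r, 0)
}

#' Right-hand side of the compartmental lineage system
#'
#' The four balance equations: BMSC proliferates and loses mass to
#' differentiation (-> OBp) and non-osteoblastic exit (-> MSCq); MSCq only
#' accumulates (no proliferation, no outflow); OBp proliferates, gains from
#' BMSC differentiation and loses to maturation (-> OBa) and exit (-> MSCq);
#' OBa proliferates and gains from OBp maturation, with no outflow.
#'
#' @param state Named vector or list with `BMSC`, `MSCq`, `OBp`, `OBa` (>= 0).
#' @param rates Named vector as returned by [effective_rates()] (all >= 0).
#' @return Named vector of derivatives.
#' @export
lineage_rhs <- function(state, rates) {
  if (any(rates < 0)) stop("negative rate passed to lineage_rhs (floor upstream)")
  s <- unlist(state[c("BMSC", "MSCq", "OBp", "OBa")])
  c(
    BMSC = unname(rates["P_MSC"] * s["BMSC"] -
                    (rates["D_MSC"] + rates["Q_MSC"]) * s["BMSC"]),
    MSCq = unname(rates["Q_MSC"] * s["BMSC"] + rates["Q_OBp"] * s["OBp"]),
    OBp = unname(rates["P_OBp"] * s["OBp"] + rates["D_MSC"] * s["BMSC"] -
                   (rates["D_OBp"] + rates["Q_OBp"]) * s["OBp"]),
    OBa = unname(rates["P_OBa"] * s["OBa"] + rates["D_OBp"] * s["OBp"])
  )
}

#' Simulate the cell-lineage system
#'
#' Integrates the four compartments over the culture horizon with rates that
#' are piecewise constant between delivery-window boundaries (the integrator is
#' restarted at each boundary). Output is daily plus all window boundaries.
#'
#' @param params A [lineage_params] object.
#' @param schedule A [treatment_schedule].
#' @param tf Per-event TF readouts ([tf_event_readouts()]); may be an empty
#'   data.frame for the control scenario.
#' @param horizon_days Simulation horizon (days, >= 1).
#' @param initial Named vector of initial masses; default 100% BMSC, mass 1.
#' @param dt_out Output resolution in days.
#' @param rtol,atol Solver tolerances.
#' @return data.frame of class `lineage_traj` with columns `day`, `BMSC`,
#'   `MSCq`, `OBp`, `OBa`; attribute `scenario`.
#' @export
simulate_lineage <- function(params, schedule, tf, horizon_days = 29,
                             initial = c(BMSC = 1, MSCq = 0, OBp = 0, OBa = 0),
                             dt_out = 0.25, rtol = 1e-8, atol = 1e-10) {
  if (horizon_days < 1) stop("horizon must be at least 1 day")
  if (initial[["BMSC"]] <= 0) stop("initial BMSC mass must be > 0")
  ev <- schedule$events
  bounds <- sort(unique(c(0, horizon_days,
                          ev$day[ev$day < horizon_days],
                          pmin(ev$day + params$t_p, horizon_days))))
  t_grid <- sort(unique(c(seq(0, horizon_days, by = dt_out), bounds)))
  y <- initial[c("BMSC", "MSCq", "OBp", "OBa")]
  out <- NULL
  for (s in seq_len(length(bounds) - 1)) {
    t0 <- bounds[s]; t1 <- bounds[s + 1]
    rates <- effective_rates((t0 + t1) / 2, params, schedule, tf)
    deriv <- function(t, y, p) list(lineage_rhs(y, rates))
    times <- sort(unique(c(t0, t_grid[t_grid > t0 & t_grid <= t1], t1)))
    sol <- tryCatch(
      deSolve::lsoda(y, times, deriv, parms = NULL, rtol = rtol, atol = atol,
                     tcrit = t1),
      error = function(e) stop("lineage solver failure in [", t0, ", ", t1,
                               "] d: ", conditionMessage(e), call. = FALSE))
    y <- sol[nrow(sol), -1]
    keep <- !duplicated(sol[, 1])
    if (!is.null(out)) keep <- keep & !(sol[, 1] %in% out[, 1])
    out <- rbind(out, sol[keep, , drop = FALSE])
  }
  colnames(out) <- c("day", "BMSC", "MSCq", "OBp", "OBa")
  vals <- out[, -1, drop = FALSE]
  if (any(vals < -1e-9))
    stop("negative compartment mass at day ",
         out[which(apply(vals < -1e-9, 1, any))[1], 1])
  vals[vals < 0] <- 0
  df <- data.frame(day = out[, 1], vals)
  attr(df, "scenario") <- schedule$scenario
  class(df) <- c("lineage_traj", "data.frame")
  df
}

#' Cellular observables of a lineage trajectory
#'
#' Total cell mass (dsDNA-equivalent, `BMSC + MSCq + OBp + OBa`) at the assay
#' days, normalized to day 1, and the osteoblast (OBa) mass at a readout day.
#' Model predictions are reported at day 29; the matching calcium-deposition
#' assay is read at day 28, so both are exported by the pipeline.
#'
#' @param traj A `lineage_traj`.
#' @param mass_days Days at which total mass is reported (default the dsDNA
#'   assay days 1, 4, 8, 11).
#' @param oba_day Day at which OBa is reported (default 29).
#' @param control Optional control-scenario `lineage_traj` used to normalize
#'   the OBa readout.
#' @return List with `total_mass` (data.frame `day`, `mass`, `mass_norm`),
#'   `oba` (raw OBa at `oba_day`) and `oba_norm` (normalized to control, `NA`
#'   if no control trajectory is supplied).
#' @export
observables <- function(traj, mass_days = c(1, 4, 8, 11), oba_day = 29,
                        control = NULL) {
  at_day <- function(tr, d, col) {
    i <- which(abs(tr$day - d) < 1e-8)[1]
    if (is.na(i)) stop("requested day ", d, " beyond simulated horizon")
    if (col == "total") tr$BMSC[i] + tr$MSCq[i] + tr$OBp[i] + tr$OBa[i]
    else tr[[col]][i]
  }
  mass <- vapply(mass_days, at_day, numeric(1), tr = traj, col = "total")
  oba <- at_day(traj, oba_day, "OBa")
  oba_norm <- if (is.null(control)) NA_real_ else
    oba / at_day(control, oba_day, "OBa")
  list(
    total_mass = data.frame(day = mass_days, mass = mass,
                            mass_norm = mass / mass[1]),
    oba = oba, oba_norm = oba_norm
  )
}

#' End-to-end multiscale simulation of one treatment scenario
#'
#' Runs the signaling system, reduces it to per-event TF readouts, and drives
#' the lineage model with them.
#'
#' @param net,kinetic A `signaling_network` and [kinetic_params].
#' @param lineage A [lineage_params] object.
#' @param schedule A [treatment_schedule].
#' @param horizon_days Lineage horizon (days).
#' @param window_h TF readout window (hours).
#' @param ... Passed to [simulate_lineage()].
#' @return List with `tf` (per-event readouts) and `lineage` (trajectory).
#' @export
simulate_scenario <- function(net, kinetic, lineage, schedule,
                              horizon_days = 29, window_h = 72, ...) {
  tf <- tf_event_readouts(net, kinetic, schedule, window_h = window_h)
  traj <- simulate_lineage(lineage, schedule, tf, horizon_days = horizon_days,
                           ...)
  list(tf = tf, lineage = traj)
}
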