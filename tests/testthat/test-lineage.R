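test_that("lineage rhs matches hand evaluation of the balance equations", {
  rates <- c(P_MSC = 0.2, P_OBp = 0, P_OBa = 0, D_MSC = 0.1, D_OBp = 0,
             Q_MSC = 0.05, Q_OBp = 0)
  d <- lineage_rhs(c(BMSC = 1, MSCq = 0, OBp = 0, OBa = 0), rates)
  expect_equal(d[["BMSC"]], 0.2 - 0.1 - 0.05)
  expect_equal(d[["OBp"]], 0.1)
  expect_equal(d[["MSCq"]], 0.05)
  expect_equal(d[["OBa"]], 0)

  # all rates zero: fixed point
  z <- lineage_rhs(c(BMSC = 2, MSCq = 1, OBp = 3, OBa = 4),
                   rates * 0)
  expect_equal(unname(z), rep(0, 4))

  expect_error(lineage_rhs(c(BMSC = 1, MSCq = 0, OBp = 0, OBa = 0),
                           c(rates[-1], P_MSC = -0.1)),
               "negative rate")
})

test_that("effective rates reduce to basal outside delivery windows", {
  lp <- default_lineage_params()
  sch <- canonical()$scen$B1I4
  tf <- data.frame(cytokine = c("BMP2", "IGF1"), day = c(1, 4),
                   Runx2 = c(0.6, 0.6), osterix = c(0, 0.5),
                   bcatenin = c(0.2, 0.4), proliferative = c(0, 0.5))
  basal <- c(P_MSC = lp$P0_MSC, P_OBp = lp$P0_OBp, P_OBa = lp$P0_OBa,
             D_MSC = lp$D0_MSC, D_OBp = lp$D0_OBp, Q_MSC = lp$Q0_MSC,
             Q_OBp = lp$Q0_OBp)
  # before any delivery and after the last window: basal
  expect_equal(effective_rates(0.5, lp, sch, tf), basal)
  expect_equal(effective_rates(4 + lp$t_p + 0.1, lp, sch, tf), basal)
  # inside the BMP-2 window: D_MSC = D0 + b_1 * Runx2 readout
  r2 <- effective_rates(2, lp, sch, tf)
  expect_equal(r2[["D_MSC"]], lp$D0_MSC + lp$b_1 * 0.6)
  # no-cytokine schedule: always basal
  expect_equal(effective_rates(3, lp, treatment_schedule(),
                               tf[0, ]), basal)
})

test_that("pure transfer dynamics conserve total mass", {
  lp <- lineage_params(P0_MSC = 0, P0_OBp = 0, P0_OBa = 0,
                       D0_MSC = 0.2, D0_OBp = 0.1, Q0_MSC = 0.05,
                       Q0_OBp = 0.05, b_1 = 0, b_2 = 0, i_1 = 0, i_2 = 0,
                       i_3 = 0, q_1 = 0, t_p = 3)
  traj <- simulate_lineage(lp, treatment_schedule(), NULL, horizon_days = 29)
  total <- traj$BMSC + traj$MSCq + traj$OBp + traj$OBa
  expect_true(all(abs(total - 1) < 1e-8))
  # MSCq and OBa absorb: never lose mass
  expect_true(all(diff(traj$MSCq) >= -1e-10))
  expect_true(all(diff(traj$OBa) >= -1e-10))
})

test_that("with zero rates the trajectory is constant; with only P it grows exponentially", {
  lp0 <- lineage_params(0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, t_p = 3)
  tr <- simulate_lineage(lp0, treatment_schedule(), NULL, horizon_days = 10)
  expect_true(all(abs(tr$BMSC - 1) < 1e-10))
  expect_true(all(tr$MSCq + tr$OBp + tr$OBa < 1e-12))

  lpP <- lineage_params(0.3, 0.2, 0.1, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, t_p = 3)
  init <- c(BMSC = 1, MSCq = 0, OBp = 0.5, OBa = 0.25)
  trP <- simulate_lineage(lpP, treatment_schedule(), NULL, horizon_days = 10,
                          initial = init)
  i10 <- which(abs(trP$day - 10) < 1e-9)
  expect_equal(trP$BMSC[i10], exp(0.3 * 10), tolerance = 1e-6)
  expect_equal(trP$OBp[i10], 0.5 * exp(0.2 * 10), tolerance = 1e-6)
  expect_equal(trP$OBa[i10], 0.25 * exp(0.1 * 10), tolerance = 1e-6)
})

test_that("adaptive lineage solution matches fixed-step RK4", {
  cc <- canonical()
  sch <- cc$scen$B1I4
  tf <- truth_runs()$B1I4$tf
  traj <- simulate_lineage(cc$lp, sch, tf, horizon_days = 12)
  # piecewise-constant rates: integrate each window with RK4 at dt = 1e-3 d
  bounds <- sort(unique(c(0, 1, 4, 1 + cc$lp$t_p, 4 + cc$lp$t_p, 12)))
  y <- c(BMSC = 1, MSCq = 0, OBp = 0, OBa = 0)
  for (s in seq_len(length(bounds) - 1)) {
    rates <- effective_rates((bounds[s] + bounds[s + 1]) / 2, cc$lp, sch, tf)
    y <- rk4_integrate(function(t, y) lineage_rhs(y, rates), y,
                       bounds[s + 1] - bounds[s], dt = 1e-3)
  }
  got <- unlist(traj[abs(traj$day - 12) < 1e-9, c("BMSC", "MSCq", "OBp", "OBa")])
  expect_equal(unname(got), unname(y), tolerance = 1e-5)
})

test_that("observables normalize mass to day 1 and OBa to control", {
  runs <- truth_runs()
  o <- observables(runs$B1I4$lineage, oba_day = 29,
                   control = runs$control$lineage)
  expect_equal(o$total_mass$mass_norm[1], 1)
  expect_equal(o$total_mass$day, c(1, 4, 8, 11))
  # control normalized to itself is 1
  oc <- observables(runs$control$lineage, oba_day = 29,
                    control = runs$control$lineage)
  expect_equal(oc$oba_norm, 1)
  expect_error(observables(runs$B1I4$lineage, oba_day = 99), "horizon")
})

test_that("increasing BMP-2 differentiation coupling does not decrease day-29 osteoblasts", {
  cc <- canonical()
  sch <- cc$scen$B1
  tf <- truth_runs()$B1$tf
  oba <- vapply(c(0.2, 0.5, 0.8, 1.2), function(b1) {
    lp <- cc$lp
    lp$b_1 <- b1
    traj <- simulate_lineage(lp, sch, tf, horizon_days = 29)
    observables(traj, oba_day = 29)$oba
  }, numeric(1))
  expect_true(all(diff(oba) >= -1e-9))
})

test_that("B1I4 outperforms I1 in day-29 osteoblast mass under ground truth", {
  runs <- truth_runs()
  oba <- function(s) observables(runs[[s]]$lineage, oba_day = 29)$oba
  expect_gt(oba("B1I4"), oba("I1"))
})
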