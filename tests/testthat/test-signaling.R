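test_that("mass-action rhs matches hand evaluation on a single pair", {
  toy <- toy_pair_network(a = 0.1, d = 0.05, C = 1)
  state <- list(t = 0, concentrations = c(pM = 0.5, BMP2 = 1))
  dy <- signaling_rhs(state, toy$params, toy$net)
  # 0.1 * 1 * (1 - 0.5) - 0.05 * 1 * 0.5
  expect_equal(unname(dy["pM"]), 0.025, tolerance = 1e-12)

  # saturated substrate: activation term vanishes
  dy_sat <- signaling_rhs(list(t = 0, concentrations = c(pM = 1, BMP2 = 5)),
                          toy$params, toy$net)
  expect_equal(unname(dy_sat["pM"]), -0.05, tolerance = 1e-12)

  # empty pool: decay term vanishes, derivative nonnegative
  dy0 <- signaling_rhs(list(t = 0, concentrations = c(pM = 0, BMP2 = 0)),
                       toy$params, toy$net)
  expect_gte(unname(dy0["pM"]), 0)
})

test_that("rhs flags missing parameters and negative concentrations", {
  toy <- toy_pair_network()
  incomplete <- kinetic_params(c(a_pM = 0.1))
  expect_error(
    signaling_rhs(list(t = 0, concentrations = c(pM = 0.2, BMP2 = 1)),
                  incomplete, toy$net),
    "d_pM")
  expect_error(
    signaling_rhs(list(t = 0, concentrations = c(pM = -0.1, BMP2 = 1)),
                  toy$params, toy$net),
    "negative")
})

test_that("with all activation rates zeroed every pool decays monotonically", {
  cc <- canonical()
  kp <- cc$kp
  kp[startsWith(names(kp), "a_")] <- 1e-12
  sch <- canonical()$scen$B1
  init <- stats::setNames(
    rep(0.5, sum(cc$net$species$role == "dynamic")),
    cc$net$species$id[cc$net$species$role == "dynamic"])
  traj <- simulate_signaling(cc$net, kp, sch, seq(24, 72, by = 4),
                             initial = init)
  for (sp in names(init)) {
    d <- diff(traj[[sp]])
    expect_true(all(d <= 1e-9), label = paste(sp, "monotone decay"))
  }
})

test_that("conservation holds along canonical trajectories", {
  cc <- canonical()
  for (scn in c("B1", "B1I4")) {
    sch <- cc$scen[[scn]]
    traj <- simulate_signaling(cc$net, cc$kp, sch, seq(0, 168, by = 2))
    for (i in seq_len(nrow(cc$net$pairs))) {
      tot <- cc$net$totals[[cc$net$pairs$total_id[i]]]
      s <- traj[[cc$net$pairs$phospho[i]]] + traj[[cc$net$pairs$base[i]]]
      expect_true(all(abs(s - tot) / tot < 1e-6),
                  label = paste(scn, cc$net$pairs$phospho[i], "conserved"))
    }
    # receptor totals (free + complexed) stay constant
    expect_true(all(abs(traj$cBMPR + traj$BMPR - 1) < 1e-6))
    expect_true(all(abs(traj$cIGFR + traj$IGFR - 1) < 1e-6))
    # nonnegativity after the clip policy
    expect_true(all(as.matrix(traj[, -1]) >= 0))
  }
})

test_that("adaptive solution matches fixed-step RK4 on the toy cascade", {
  toy <- toy_cascade_network()
  sch <- treatment_schedule("BMP2", 0)
  traj <- simulate_signaling(toy$net, toy$params, sch, c(0, 4, 8, 12))
  rhs <- osteoscale:::make_rhs_fun(toy$net, toy$params, sch)
  deriv <- function(t, y) rhs(t, y, NULL)[[1]]
  y0 <- c(pM1 = 0, pM2 = 0, pM3 = 0)
  for (tend in c(4, 8, 12)) {
    ref <- rk4_integrate(deriv, y0, tend, dt = 1e-3)
    got <- unlist(traj[traj$time == tend, c("pM1", "pM2", "pM3")])
    expect_equal(unname(got), unname(ref), tolerance = 1e-4)
  }
})

test_that("ligand step input switches on at the delivery day and persists", {
  toy <- toy_pair_network(a = 0.5, d = 0.1)
  sch <- treatment_schedule("BMP2", 1)
  traj <- simulate_signaling(toy$net, toy$params, sch, seq(0, 72, by = 1))
  expect_true(all(traj$pM[traj$time <= 24] < 1e-12))
  expect_true(all(diff(traj$pM[traj$time >= 24]) > -1e-9))
  expect_gt(traj$pM[traj$time == 72], 0.5)
  # no-event schedule relaxes from the initial state
  relax <- simulate_signaling(toy$net, toy$params,
                              treatment_schedule(), c(0, 10, 20),
                              initial = c(pM = 0.8))
  expect_true(all(diff(relax$pM) < 0))
})

test_that("tf_readout normalizes active pools into [0, 1]", {
  cc <- canonical()
  traj <- simulate_signaling(cc$net, cc$kp, cc$scen$B1I4, seq(0, 168, by = 2))
  r <- tf_readout(traj, cc$net)
  expect_named(r, c("Runx2", "osterix", "bcatenin", "proliferative"))
  expect_true(all(r >= 0 & r <= 1))

  # all-zero trajectory: direct TF activities are zero, beta-catenin readout
  # is its full unphosphorylated pool
  zero <- traj
  for (sp in setdiff(names(zero), "time")) zero[[sp]] <- 0
  r0 <- tf_readout(zero, cc$net)
  expect_equal(unname(r0[c("Runx2", "osterix", "proliferative")]), rep(0, 3))
  expect_equal(unname(r0["bcatenin"]), 1)

  # constant saturated upstream: readout = 1
  sat <- traj
  sat$aRunx2 <- 1
  expect_equal(unname(tf_readout(sat, cc$net)["Runx2"]), 1)
})

test_that("the late IGF-1 delivery in B1I4 strongly phosphorylates GSK3beta", {
  cc <- canonical()
  t_grid <- seq(0, 24 * 8, by = 2)
  tr_b1i4 <- simulate_signaling(cc$net, cc$kp, cc$scen$B1I4, t_grid)
  tr_i1 <- simulate_signaling(cc$net, cc$kp, cc$scen$I1, t_grid)
  tr_b1 <- simulate_signaling(cc$net, cc$kp, cc$scen$B1, t_grid)
  late <- t_grid > 24 * 6
  # after the day-4 IGF-1 delivery equilibrates, B1I4 matches the full
  # IGF-1-driven phosphorylation level and dwarfs the BMP-2-only baseline
  expect_true(all(tr_b1i4$pGSK3B[late] > 0.9 * tr_i1$pGSK3B[late]))
  expect_true(all(tr_b1i4$pGSK3B[late] > 10 * tr_b1$pGSK3B[late] + 1e-12))
  # before its IGF-1 arrives, B1I4 shows no GSK3beta phosphorylation
  expect_true(all(tr_b1i4$pGSK3B[t_grid < 96] < 1e-9))
  # ... and the phosphorylation de-represses beta-catenin (lower pBcat pool)
  # relative to the no-IGF baseline at matched times
  expect_lt(tail(tr_b1i4$pBcat, 1), tail(tr_b1$pBcat, 1))
})

test_that("Runx2 readout requires BMP-2: B1 exceeds I1", {
  cc <- canonical()
  tf_b1 <- tf_event_readouts(cc$net, cc$kp, cc$scen$B1)
  tf_i1 <- tf_event_readouts(cc$net, cc$kp, cc$scen$I1)
  expect_gt(tf_b1$Runx2[1], tf_i1$Runx2[1])
  expect_lt(tf_i1$Runx2[1], 0.05)
})

test_that("trajectory export produces tidy long CSV", {
  toy <- toy_pair_network()
  sch <- treatment_schedule("BMP2", 0)
  traj <- simulate_signaling(toy$net, toy$params, sch, c(0, 1, 2))
  path <- withr::local_tempfile(fileext = ".csv")
  export_trajectory(traj, path)
  got <- utils::read.csv(path)
  expect_named(got, c("time", "species", "value", "scenario"))
  expect_equal(nrow(got), 3 * 2)  # 3 times x (pM, M)
  expect_equal(got$value[got$species == "pM" & got$time == 1],
               traj$pM[traj$time == 1])
})
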