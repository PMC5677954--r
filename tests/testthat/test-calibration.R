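test_that("cellular least squares has zero loss at truth and recovers it", {
  ds0 <- zero_noise_dataset()
  scen <- canonical()$scen
  # start away from truth
  base <- default_lineage_params()
  truth <- unlist(base[c("b_1", "i_3", "D0_MSC", "D0_OBp")])
  base$b_1 <- 0.3
  base$i_3 <- 0.15
  base$D0_MSC <- 0.03
  base$D0_OBp <- 0.05
  fit <- fit_cellular(ds0$dsdna, ds0$ars, ds0$tf, scen, base = base,
                      n_starts = 0, seed = 1)
  expect_s3_class(fit, "osteo_fit")
  expect_lt(fit$loss, 1e-10)
  rel <- abs(fit$point_estimate - truth) / truth
  expect_true(all(rel < 0.15), label = paste("max rel err", max(rel)))
  # and the loss evaluated at truth itself is (numerically) zero
  fit_at_truth <- fit_cellular(ds0$dsdna, ds0$ars, ds0$tf, scen,
                               base = default_lineage_params(),
                               n_starts = 0, seed = 1)
  expect_lt(fit_at_truth$loss, 1e-12)
})

test_that("noisy-data estimate fits at least as well as truth", {
  ds <- generate_synthetic(seed = 5, noise_cv = 0.1)
  scen <- canonical()$scen
  fit <- fit_cellular(ds$dsdna, ds$ars, ds$tf, scen, n_starts = 0, seed = 1)
  loss_truth <- cellular_loss(default_lineage_params(), ds$dsdna, ds$ars,
                              ds$tf, scen)
  expect_gt(loss_truth, 0)  # the noise floor
  expect_lte(fit$loss, loss_truth + 1e-8)
})

test_that("cellular fit is invariant to row order of the input tables", {
  ds0 <- zero_noise_dataset()
  scen <- canonical()$scen
  base <- default_lineage_params()
  base$b_1 <- 0.4
  set.seed(99)
  perm_d <- sample(nrow(ds0$dsdna))
  perm_a <- sample(nrow(ds0$ars))
  f1 <- fit_cellular(ds0$dsdna, ds0$ars, ds0$tf, scen, base = base,
                     n_starts = 0, seed = 1)
  f2 <- fit_cellular(ds0$dsdna[perm_d, ], ds0$ars[perm_a, ], ds0$tf, scen,
                     base = base, n_starts = 0, seed = 1)
  expect_equal(f1$point_estimate, f2$point_estimate, tolerance = 1e-8)
})

test_that("molecular likelihood is maximal near truth for zero-noise data", {
  ds0 <- zero_noise_dataset()
  cc <- canonical()
  rp <- ds0$rppa[ds0$rppa$scenario == "B1", ]
  sigma <- stats::setNames(rep(0.05, 12), unique(rp$species))
  lp_at <- function(mult) {
    th <- cc$kp[identifiable_rates("B1")] * mult
    osteoscale:::.molecular_logpost(
      log(th), identifiable_rates("B1"), cc$kp,
      stats::setNames(rep(1e-3, 37), names(cc$kp)),
      stats::setNames(rep(10, 37), names(cc$kp)),
      cc$net, cc$scen$B1, rp, sigma)
  }
  expect_gte(lp_at(1), lp_at(2))
  expect_gte(lp_at(1), lp_at(0.5))
})

test_that("MCMC chains are seed-reproducible and diagnostics populated", {
  ds0 <- zero_noise_dataset()
  cc <- canonical()
  rp <- ds0$rppa[ds0$rppa$scenario == "B1", ]
  base <- cc$kp
  base[identifiable_rates("B1")] <- base[identifiable_rates("B1")] * 1.5
  f1 <- fit_molecular(rp, cc$net, cc$scen$B1, base = base, n_iter = 120,
                      n_chains = 1, seed = 4)
  f2 <- fit_molecular(rp, cc$net, cc$scen$B1, base = base, n_iter = 120,
                      n_chains = 1, seed = 4)
  expect_identical(f1$chain, f2$chain)
  expect_identical(f1$point_estimate, f2$point_estimate)
  expect_true(is.finite(f1$diagnostics$acceptance))
  expect_true(all(is.finite(f1$diagnostics$rhat)))
})

test_that("molecular fit rejects impossible inputs informatively", {
  ds0 <- zero_noise_dataset()
  cc <- canonical()
  rp <- ds0$rppa[ds0$rppa$scenario == "B1", ]
  bad <- rp
  bad$species[1] <- "notaspecies"
  expect_error(fit_molecular(bad, cc$net, cc$scen$B1, n_iter = 10), "notaspecies")
  # truth far outside the prior: non-finite likelihood at initialization
  expect_error(
    fit_molecular(rp, cc$net, cc$scen$B1, n_iter = 10,
                  prior_lower = 5, prior_upper = 10),
    "prior")
})

test_that("posterior spread shrinks as sampling densifies", {
  # 3-species cascade sub-network: double the timepoints, expect a tighter
  # posterior for the directly observed rate
  toy <- toy_cascade_network()
  sch <- treatment_schedule("BMP2", 0, scenario = "B0")
  make_obs <- function(times) {
    traj <- simulate_signaling(toy$net, toy$params, sch, c(0, times))
    do.call(rbind, lapply(c("pM1", "pM2", "pM3"), function(sp)
      data.frame(species = sp, time_h = times,
                 value = traj[[sp]][match(times, traj$time)])))
  }
  sparse <- make_obs(c(1, 4, 12))
  dense <- make_obs(c(0.5, 1, 2, 4, 8, 12))
  base <- toy$params
  base["a_pM2"] <- 1.2
  sd_of <- function(obs) {
    f <- fit_molecular(obs, toy$net, sch, free = c("a_pM2"), base = base,
                       sigma = 0.05, n_iter = 600, n_chains = 1, seed = 2)
    stats::sd(f$chain[, "a_pM2", 1])
  }
  expect_lt(sd_of(dense), sd_of(sparse))
})

test_that("parameter dispersion counts extremes by direct thresholding", {
  fits <- list(
    I1 = c(a = 0.05, b = 0.05, c = 0.05),
    B1I4 = c(a = 0.01, b = 0.05, c = 0.30)
  )
  disp <- parameter_dispersion(fits)
  expect_equal(disp$n_extreme[disp$scenario == "I1"], 0)
  expect_equal(disp$n_low[disp$scenario == "B1I4"], 1)
  expect_equal(disp$n_high[disp$scenario == "B1I4"], 1)
  expect_equal(disp$n_extreme[disp$scenario == "B1I4"], 2)
  # identical fits across scenarios give equal counts
  disp2 <- parameter_dispersion(list(A = fits$I1, B = fits$I1))
  expect_equal(disp2$n_extreme, c(0, 0))
  expect_error(parameter_dispersion(fits["I1"]), "2 scenarios")
})
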