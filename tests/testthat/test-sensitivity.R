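test_that("Latin hypercube puts exactly one sample in each stratum", {
  X <- lhs_sample(list(x = c(0, 1)), 4, seed = 1)
  counts <- table(cut(X[, "x"], breaks = seq(0, 1, by = 0.25)))
  expect_true(all(counts == 1))

  X2 <- lhs_sample(list(a = c(0, 1), b = c(-2, 6)), 1000, seed = 2)
  for (j in 1:2) {
    lo <- c(0, -2)[j]; hi <- c(1, 6)[j]
    counts <- table(cut(X2[, j], breaks = seq(lo, hi, length.out = 1001)))
    expect_true(all(counts == 1))
  }
  expect_identical(lhs_sample(list(a = c(0, 1)), 50, seed = 7),
                   lhs_sample(list(a = c(0, 1)), 50, seed = 7))
  expect_error(lhs_sample(list(a = c(1, 1)), 10), "bounds")
})

test_that("PRCC isolates monotone dependence and signs", {
  set.seed(10)
  X <- lhs_sample(list(x1 = c(0, 1), x2 = c(0, 1), x3 = c(0, 1)), 500,
                  seed = 10)
  y <- X[, "x1"]^3 + 0.02 * stats::rnorm(500)
  p <- prcc(X, y)
  expect_gt(p[["x1"]], 0.95)
  expect_lt(abs(p[["x2"]]), 0.1)  # non-influential parameter
  expect_lt(abs(p[["x3"]]), 0.1)
  expect_true(all(p >= -1 & p <= 1))

  y2 <- X[, "x1"] - X[, "x2"]
  p2 <- prcc(X, y2)
  expect_gt(p2[["x1"]], 0)
  expect_lt(p2[["x2"]], 0)

  pc <- prcc(X, rep(3, 500))
  expect_true(attr(pc, "constant_output"))
  expect_equal(unname(pc), rep(0, 3), ignore_attr = TRUE)
})

test_that("eFAST reproduces closed-form indices of an additive function", {
  # f = x1 + 2 x2 + 3 x3, x_j ~ U(0,1): Var_j = j^2/12, shares j^2/14
  f <- function(x) x[1] + 2 * x[2] + 3 * x[3]
  ef <- efast(f, list(x1 = c(0, 1), x2 = c(0, 1), x3 = c(0, 1)), seed = 2)
  main <- ef$main_effect[match(c("x1", "x2", "x3"), ef$param)]
  expect_equal(main, c(1, 4, 9) / 14, tolerance = 0.05)
  expect_lt(abs(sum(main) - 1), 0.05)
  # dummy parameter stays below the significance floor
  expect_lt(ef$total_effect[ef$param == ".dummy"], 0.05)
  # main <= total within estimator noise
  expect_true(all(ef$main_effect <= ef$total_effect + 0.05))
})

test_that("eFAST attributes a single-input function entirely to that input", {
  f <- function(x) sin(2 * x[1])
  ef <- efast(f, list(x1 = c(0, 1), x2 = c(0, 1)), seed = 3)
  expect_gt(ef$main_effect[ef$param == "x1"], 0.9)
  expect_gt(ef$total_effect[ef$param == "x1"], 0.9)
  expect_lt(ef$total_effect[ef$param == "x2"], 0.05)
  expect_error(efast(f, list(x1 = c(0, 1)), n = 33), "n too small")
})

test_that("variance share report filters at the 2% threshold, descending", {
  f <- function(x) x[1] + 2 * x[2] + 3 * x[3]
  ef <- efast(f, list(x1 = c(0, 1), x2 = c(0, 1), x3 = c(0, 1)), seed = 4)
  rep_ <- variance_share_report(ef)
  expect_equal(rep_$param, c("x3", "x2", "x1"))
  expect_true(all(diff(rep_$share_pct) <= 0))
  expect_true(all(rep_$share_pct >= 2))
  # threshold above everything: empty table
  expect_equal(nrow(variance_share_report(ef, threshold = 0.99)), 0)
  # single-input function: only that input is reported
  ef1 <- efast(function(x) x[1], list(x1 = c(0, 1), x2 = c(0, 1)), seed = 5)
  expect_equal(variance_share_report(ef1)$param, "x1")
})

test_that("PRCC and eFAST rank a monotone model identically", {
  f <- function(x) 0.5 * x[1] + 2 * x[2] + 5 * x[3]
  bounds <- list(a = c(0, 1), b = c(0, 1), c = c(0, 1))
  X <- lhs_sample(bounds, 400, seed = 6)
  y <- apply(X, 1, f)
  p <- abs(prcc(X, y))
  ef <- efast(f, bounds, seed = 6)
  m <- ef$main_effect[match(names(p), ef$param)]
  expect_gte(stats::cor(rank(p), rank(m), method = "spearman"), 0.8)
})

test_that("cellular output closure responds to its parameters", {
  cc <- canonical()
  tfb <- truth_runs()$B1I4$tf
  f <- cellular_output(cc$scen$B1I4, tfb, free = c("b_1", "D0_OBp"),
                       base = cc$lp)
  y1 <- f(c(0.2, 0.01))
  y2 <- f(c(1.0, 0.01))
  expect_gt(y2, y1)  # more differentiation coupling, more osteoblasts
})
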