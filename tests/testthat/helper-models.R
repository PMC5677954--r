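# Shared fixtures: tiny networks and cached expensive simulations.

# Minimal one-pair network: input ligand pA activates pM (paired with M).
toy_pair_network <- function(a = 0.1, d = 0.05, C = 1) {
  net <- signaling_network(
    species = data.frame(id = c("pM", "M", "BMP2", "IGF1"),
                         role = c("dynamic", "algebraic", "input", "input")),
    edges = data.frame(from = "BMP2", to = "pM", sign = "activate"),
    pairs = data.frame(phospho = "pM", base = "M", total_id = "C_M"),
    ligand_bindings = data.frame(ligand = character(0),
                                 receptor = character(0),
                                 complex = character(0)),
    totals = c(C_M = C)
  )
  list(net = net, params = kinetic_params(c(a_pM = a, d_pM = d)))
}

# Three-species cascade driven by BMP2: pM1 -> pM2 -> pM3, all paired.
toy_cascade_network <- function() {
  sp <- data.frame(
    id = c("pM1", "pM2", "pM3", "M1", "M2", "M3", "BMP2", "IGF1"),
    role = c(rep("dynamic", 3), rep("algebraic", 3), "input", "input"))
  edges <- data.frame(from = c("BMP2", "pM1", "pM2"),
                      to = c("pM1", "pM2", "pM3"),
                      sign = "activate")
  pairs <- data.frame(phospho = c("pM1", "pM2", "pM3"),
                      base = c("M1", "M2", "M3"),
                      total_id = c("C_M1", "C_M2", "C_M3"))
  lb <- data.frame(ligand = character(0), receptor = character(0),
                   complex = character(0))
  net <- signaling_network(sp, edges, pairs, lb,
                           c(C_M1 = 1, C_M2 = 1, C_M3 = 1))
  params <- kinetic_params(c(a_pM1 = 0.8, a_pM2 = 0.6, a_pM3 = 0.4,
                             d_pM1 = 0.3, d_pM2 = 0.2, d_pM3 = 0.1))
  list(net = net, params = params)
}

# Classical explicit fourth-order fixed-step integrator, used as the
# brute-force oracle for the adaptive solver.
rk4_integrate <- function(deriv, y0, t_end, dt) {
  y <- y0
  t <- 0
  while (t < t_end - dt / 2) {
    k1 <- deriv(t, y)
    k2 <- deriv(t + dt / 2, y + dt / 2 * k1)
    k3 <- deriv(t + dt / 2, y + dt / 2 * k2)
    k4 <- deriv(t + dt, y + dt * k3)
    y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    t <- t + dt
  }
  y
}

# Cached canonical objects (built once per test run).
canonical <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- list(net = build_canonical_network(),
                     kp = default_kinetic_params(),
                     lp = default_lineage_params(),
                     scen = scenario_table())
    cache
  }
})

# Cached zero-noise dataset (the most reused expensive fixture).
zero_noise_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_synthetic(seed = 1, noise_cv = 0)
    cache
  }
})

# Cached 7x7 schedule grid under ground truth.
grid_cache <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cc <- canonical()
      cache <<- run_grid(cc$net, cc$kp, cc$lp)
    }
    cache
  }
})

# Cached six-scenario forward runs under ground truth.
truth_runs <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cc <- canonical()
      cache <<- lapply(cc$scen, function(s)
        simulate_scenario(cc$net, cc$kp, cc$lp, s))
    }
    cache
  }
})
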