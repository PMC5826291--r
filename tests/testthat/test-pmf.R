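# Umbrella sampling and free-energy reconstruction: window layout, restrained
# sampling statistics, WHAM against a direct Boltzmann oracle, polynomial
# smoothing, barriers and Arrhenius rates.

test_that("window layout follows the stated spacing rule", {
  w <- make_windows(-52, 52, 1.3, replicates = 1)
  expect_equal(nrow(w), 81)
  expect_equal(w$z0[1], -52)
  expect_equal(diff(w$z0)[1], 1.3)
  expect_equal(unique(w$k), 10)
  w1 <- make_windows(0, 0)
  expect_equal(length(unique(w1$z0)), 1)
  expect_equal(unique(w1$replicate), c(1, 2)) # two starting configurations
  expect_error(make_windows(0, 1, spacing = -1), "positive")
})

test_that("restrained cargo samples harmonic-oscillator statistics", {
  cargo <- build_cargo("custom", radius = 7.4, charge = 0, n_hydro_sites = 0,
                       mass = 500)
  win <- make_windows(0, 0, k = 10, replicates = 1)
  cfg <- simulation_config(n_steps = 50000, timestep = 0.02, friction = 0.1,
                           stride = 50, seed = 11)
  samp <- run_umbrella(NULL, cargo, win, cfg, box = c(60, 60, 60))
  expect_equal(var(samp$z), kBT() / 10, tolerance = 0.1)
  expect_equal(mean(samp$z), 0, tolerance = 3 * sqrt(kBT() / 10 / 50))
  # stiff-spring limit: variance shrinks ~ 1/k
  win2 <- make_windows(0, 0, k = 100, replicates = 1)
  samp2 <- run_umbrella(NULL, cargo, win2, cfg, box = c(60, 60, 60))
  expect_equal(var(samp2$z) / var(samp$z), 0.1, tolerance = 0.35)
  # neighbouring-window overlap at the default 1.3 nm spacing: Gaussian
  # widths sqrt(kBT/k) ~ 0.5 nm give substantial overlap
  w3 <- make_windows(0, 1.3, k = 10, replicates = 1)
  samp3 <- run_umbrella(NULL, cargo, w3, cfg, box = c(60, 60, 60))
  z_a <- samp3$z[samp3$window == 1]
  z_b <- samp3$z[samp3$window == 2]
  overlap <- mean(z_a > quantile(z_b, 0.025)) # fraction of A in B's support
  expect_gt(overlap, 0.05)
})

test_that("WHAM reconstructs a quartic potential against a Boltzmann oracle", {
  U <- function(z) 0.05 * z^4 - 0.8 * z^2
  set.seed(42)
  wins <- make_windows(-5, 5, spacing = 1, k = 10, replicates = 1)
  wins <- wins[wins$replicate == 1, ]
  samples <- boltzmann_window_samples(U, wins, n_per_window = 5000)
  pm <- wham(samples, bin_width = 0.1)
  expect_true(pm$converged)
  # accuracy over the region the window design samples (outermost centres
  # at +/- 5 nm); beyond it the tail bins carry few counts by construction
  sel <- abs(pm$profile$z) <= 5
  ref <- U(pm$profile$z[sel]); ref <- ref - min(ref)
  est <- pm$profile$pmf[sel]; est <- est - min(est)
  off <- mean(est - ref)
  rms <- sqrt(mean((est - ref - off)^2))
  expect_lt(rms, 0.3)
  # flat potential: constant PMF within noise over the window span (the
  # sparse tails beyond the outermost windows carry no information)
  flat <- boltzmann_window_samples(function(z) 0 * z, wins, n_per_window = 5000)
  pf <- wham(flat, bin_width = 0.1)
  central <- pf$profile[abs(pf$profile$z) <= 5, ]
  expect_lt(max(central$pmf) - min(central$pmf), 0.8)
  expect_lt(pmf_barrier(central, smooth = TRUE), 0.8)
  # gauge invariance: adding a constant to the potential leaves the barrier
  # unchanged (PMF defined up to an additive constant)
  set.seed(42)
  shifted <- boltzmann_window_samples(function(z) U(z) + 7, wins,
                                      n_per_window = 5000)
  ps <- wham(shifted, bin_width = 0.1)
  expect_equal(pmf_barrier(ps), pmf_barrier(pm), tolerance = 0.05)
  # disjoint histograms are rejected
  bad <- samples[samples$window %in% c(1, 11), ]
  expect_error(wham(bad), "disjoint")
})

test_that("WHAM matches direct Boltzmann inversion for one dense window", {
  # single wide window with a weak spring: inversion of the biased histogram
  U <- function(z) 1.2 * z^2
  set.seed(7)
  wins <- tibble::tibble(window = 1:2, z0 = c(-0.5, 0.5), k = 0.5,
                         replicate = 1)
  class(wins) <- c("umbrella_windows", class(wins))
  samples <- boltzmann_window_samples(U, wins, n_per_window = 20000,
                                      z_range = c(-4, 4))
  pm <- wham(samples, bin_width = 0.1)
  sel <- abs(pm$profile$z) < 1.5
  ref <- U(pm$profile$z[sel]); ref <- ref - min(ref)
  est <- pm$profile$pmf[sel]; est <- est - min(est)
  expect_lt(sqrt(mean((est - ref - mean(est - ref))^2)), 0.3)
})

test_that("barrier: smoothing branches and closed-form checks", {
  # symmetric parabola-shaped PMF: barrier equals the analytic depth
  z <- seq(-10, 10, by = 0.1)
  depth <- 9
  curve <- tibble::tibble(z = z, pmf = depth * (1 - (z / 10)^2))
  expect_equal(pmf_barrier(curve, smooth = FALSE), depth)
  # sixth-order branches reproduce a polynomial PMF exactly
  expect_equal(pmf_barrier(curve, smooth = TRUE), depth, tolerance = 1e-6)
  # axis reversal leaves the barrier unchanged for symmetric profiles
  rev <- tibble::tibble(z = -z, pmf = curve$pmf)
  expect_equal(pmf_barrier(rev), pmf_barrier(curve), tolerance = 1e-6)
  expect_error(smooth_pmf(tibble::tibble(z = 1:3, pmf = 1:3)),
               "polynomial degrees")
})

test_that("Arrhenius rates and rate ratios", {
  rm <- rate_model(gamma0 = 16.9, temperature = 298)
  expect_equal(arrhenius_rate(rm, 0), 16.9)
  # ratio between 6 and 12 kJ/mol barriers at 298 K: exp(6/kBT) ~ 11.2,
  # an order of magnitude between receptor and inert cargo
  ratio <- arrhenius_rate(rm, 6) / arrhenius_rate(rm, 12)
  expect_equal(ratio, exp(6 / kBT(298)))
  expect_equal(ratio, 11.2, tolerance = 0.01)
  # log-linearity with slope 1/kBT
  dE <- c(0, 2, 4, 8)
  lr <- log(arrhenius_rate(rm, dE))
  expect_equal(unname(coef(lm(lr ~ dE))[2]), -1 / kBT(298))
  expect_error(arrhenius_rate(rm, -1), ">= 0")
  expect_error(rate_model(-1), ">= 0")
})

test_that("steric PMF grows with grafted-chain density (small pore)", {
  # inert cargo on the axis of a small pore: the mean restrained force and
  # the PMF barrier should increase when chains are added
  geom <- pore_geometry(17, box = c(40, 40, 60))
  # light cargo: equilibrium statistics are mass-independent and the
  # position relaxation time zeta/k stays well below the sampling window.
  # Radius 6 in a 17 nm pore: clears the token stubs but must displace a
  # dense 40-residue brush
  cargo <- build_cargo("custom", radius = 6, charge = 0, n_hydro_sites = 0,
                       mass = 50)
  # the production umbrella parameters: 1.3 nm spacing, k = 10 (thermal
  # width ~0.5 nm), stiff enough to hold the cargo inside the brush
  win <- make_windows(-9.75, 9.75, spacing = 1.3, k = 10, replicates = 1)
  cfg <- simulation_config(n_steps = 15000, timestep = 0.015, friction = 0.2,
                           stride = 200, equil_fraction = 0.4, seed = 21)
  # nearly empty pore (token 4-bead stubs at the wall)
  sys0 <- assemble_system(geom, build_anchors(geom, 12),
                          seq_segment(load_builtin("Nsp1"), 1, 4), seed = 1)
  samp0 <- run_umbrella(sys0, cargo, win, cfg)
  pm0 <- wham(samp0, bin_width = 0.25)
  expect_lt(pmf_barrier(pm0), 5)
  # densely grafted pore: higher steric barrier; if the brush is impassable
  # at this spring stiffness the windows lose overlap, which bounds the
  # barrier from below even more strongly
  sys1 <- assemble_system(geom, build_anchors(geom, 7),
                          seq_segment(load_builtin("Nsp1"), 1, 40), seed = 1)
  sys1 <- minimize_system(sys1, max_iter = 150, force_tol = 100)
  samp1 <- suppressWarnings(run_umbrella(sys1, cargo, win, cfg))
  b1 <- tryCatch(pmf_barrier(wham(samp1, bin_width = 0.25)),
                 error = function(e) Inf)
  expect_gt(b1, pmf_barrier(pm0) + 1)
})
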