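# Density-based conductance: local law, radial integration, the
# pore + access relation, fitting, sigmoids and robustness.

test_that("local conductivity law: linear decrease, clipped at rho_crit", {
  m <- conductivity_model()
  expect_equal(local_conductivity(0, m), 2.2)
  expect_equal(local_conductivity(85, m), 0)
  expect_equal(local_conductivity(170, m), 0) # clipped, not negative
  expect_equal(local_conductivity(42.5, m), 1.1)
  expect_error(conductivity_model(sigma_bare = -1), "positive")
})

test_that("region conductivity: radial integral with analytic checks", {
  m <- conductivity_model()
  # uniform rho = rho_crit/2 -> sigma_bare/2 exactly (trapezoid exact)
  expect_equal(region_conductivity(fixture_uniform_profile(42.5), m, 45),
               1.1, tolerance = 1e-12)
  expect_equal(region_conductivity(fixture_uniform_profile(0), m, 45), 2.2)
  # annular step profile: blocked for a < r < b, open elsewhere:
  # sigma = sigma_bare (1 - (b^2 - a^2)/(d/2)^2)
  a <- 8; b <- 14; half <- 20
  prof <- tibble::tibble(r = seq(0.05, half, by = 0.1))
  prof$density <- ifelse(prof$r > a & prof$r <= b, 200, 0)
  got <- region_conductivity(prof, m, 2 * half)
  expected <- 2.2 * (1 - (b^2 - a^2) / half^2)
  expect_equal(got, expected, tolerance = 0.01)
  expect_error(region_conductivity(fixture_uniform_profile(0, r_max = 5), m, 45),
               "extends to")
})

test_that("total conductance: series pore + access resistance", {
  # sigma_pore = sigma_access = sigma_bare reduces exactly to the bare law,
  # checked against a one-line evaluation
  d <- 50; l <- 20; s <- 2.2
  oracle <- s * 1 / (4 * l / (pi * d^2) + 1 / d)
  expect_equal(total_conductance(s, s, d, l), oracle)
  expect_equal(bare_conductance(d), oracle)
  # zero pore conductivity blocks the series circuit
  expect_equal(total_conductance(0, s, d, l), 0)
  # linearity: doubling both conductivities doubles G
  expect_equal(total_conductance(2 * s, 2 * s, d, l),
               2 * total_conductance(s, s, d, l))
  expect_error(total_conductance(s, s, -1), "positive")
})

test_that("relation reduces to the bare law at zero density and is monotone", {
  m <- conductivity_model()
  g0 <- gen_density(density_spec("uniform", amplitude = 0, diameter = 45))
  pc <- predict_conductance(g0, 45, m)
  expect_equal(pc$G, bare_conductance(45), tolerance = 1e-6)
  # G non-increasing under pointwise density increase
  amps <- c(0, 20, 40, 60, 84)
  gs <- vapply(amps, function(a) {
    predict_conductance(gen_density(density_spec("uniform", amplitude = a,
                                                 diameter = 45)), 45, m)$G
  }, numeric(1))
  expect_true(all(diff(gs) < 0))
  # non-decreasing in rho_crit
  g1 <- gen_density(density_spec("uniform", amplitude = 50, diameter = 45))
  gcs <- vapply(c(60, 85, 120, 200), function(rc) {
    predict_conductance(g1, 45, conductivity_model(rho_crit = rc))$G
  }, numeric(1))
  expect_true(all(diff(gcs) > 0))
})

test_that("model fitting recovers generating parameters", {
  set.seed(31)
  # sigma_bare from noisy bare-pore data generated at 2.2
  d <- c(10, 20, 30, 40, 50, 60)
  G <- bare_conductance(d, 2.2) * (1 + rnorm(6, 0, 0.02))
  fit <- fit_conductivity(tibble::tibble(diameter = d, G = G))
  expect_equal(fit$sigma_bare, 2.2, tolerance = 0.05)
  expect_lt(abs(fit$sigma_bare - 2.2), 3 * fit$sigma_bare_se + 0.05)
  # rho_crit from synthetic coated data generated at 85
  m_true <- conductivity_model(2.2, 85)
  ds <- c(25, 35, 45, 55)
  profs <- lapply(ds, function(dd) {
    g <- gen_density(density_spec("center_peaked", amplitude = 90,
                                  background = 45, diameter = dd,
                                  box = c(dd + 20, dd + 20, 100)))
    list(pore = radial_profile(g, "pore"), access = radial_profile(g, "access"))
  })
  names(profs) <- as.character(ds)
  Gc <- vapply(seq_along(ds), function(i) {
    total_conductance(
      region_conductivity(profs[[i]]$pore, m_true, ds[i]),
      region_conductivity(profs[[i]]$access, m_true, ds[i]), ds[i], 20)
  }, numeric(1))
  fit2 <- fit_conductivity(tibble::tibble(diameter = d, G = G),
                           coated_data = tibble::tibble(diameter = ds, G = Gc),
                           profiles = profs)
  expect_equal(fit2$rho_crit, 85, tolerance = 0.05)
  td <- generics::tidy(fit2)
  expect_equal(td$term, c("sigma_bare", "rho_crit"))
  expect_error(fit_conductivity(tibble::tibble(diameter = c(10, 10), G = c(1, 1))),
               "3 distinct")
})

test_that("sigmoid closed form reproduces the two-regime conductance shape", {
  # synthetic conductivities: near zero below ~35 nm, rising toward bare
  d <- seq(20, 62, by = 6)
  sp <- 2.2 / (1 + exp(-(d - 40) / 4))
  sa <- 2.2 / (1 + exp(-(d - 30) / 5))
  fits <- fit_sigmoid_conductivity(
    tibble::tibble(diameter = d, sigma_pore = sp, sigma_access = sa))
  curve <- closed_form_curve(fits, seq(20, 62, by = 0.5))
  expect_true(all(curve$G >= 0))
  expect_true(all(diff(curve$G) > -1e-9)) # monotone for monotone sigmoids
  expect_lt(curve$G[1], 4)
  expect_gt(max(curve$G), 30)
  thr <- threshold_diameter(curve, 4)
  expect_gt(thr, 20); expect_lt(thr, 50)
  # sigmoids frozen at sigma_bare coincide with the bare-pore law
  fits0 <- fits
  fits0$pore <- list(lo = 2.2, hi = 2.2, d0 = 40, s = 4)
  fits0$access <- list(lo = 2.2, hi = 2.2, d0 = 40, s = 4)
  c0 <- closed_form_curve(fits0, c(30, 45, 60))
  expect_equal(c0$G, bare_conductance(c(30, 45, 60)))
  expect_warning(closed_form_curve(fits, c(10, 30)), "extrapolation")
})

test_that("conductance is robust to shrinking the access window", {
  # on packaged synthetic profiles, shrinking the access region threefold
  # changes G by a bounded amount (the published sensitivity bound is 13%)
  m <- conductivity_model()
  g <- gen_density(density_spec("center_peaked", amplitude = 90,
                                background = 45, diameter = 45))
  sp <- region_conductivity(radial_profile(g, "pore"), m, 45)
  G_full <- total_conductance(
    sp, region_conductivity(radial_profile(g, "access"), m, 45), 45, 20)
  G_shrunk <- total_conductance(
    sp, region_conductivity(radial_profile(g, c(10, 20)), m, 45), 45, 20)
  expect_lt(abs(G_shrunk - G_full) / G_full, 0.13)
})
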