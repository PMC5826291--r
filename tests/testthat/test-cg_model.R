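# Force-field components: bead parameters, Debye screening, pair potentials
# (continuity, derivatives, symmetries), bonded terms and cargo models.

test_that("bead parameters satisfy the model's invariants", {
  bp <- bead_parameters()
  expect_equal(nrow(bp), 20)
  expect_true(all(bp$lambda >= 0 & bp$lambda <= 1))
  expect_equal(bp$charge[bp$code %in% c("D", "E")], c(-1, -1))
  expect_equal(bp$charge[bp$code %in% c("K", "R")], c(1, 1))
  expect_equal(sum(bp$charge != 0), 4) # histidine neutral at pH 7.4
  expect_equal(mean(bp$mass[match(strsplit("GSAFN", "")[[1]], bp$code)]),
               mean(c(57.0519, 87.0782, 71.0788, 147.1766, 114.1038)))
})

test_that("Debye constant reproduces physiological screening", {
  # 150 mM KCl at 298 K: kappa = 1.27 nm^-1
  expect_equal(debye_constant(0.150, 298, 80), 1.27, tolerance = 0.01)
  expect_equal(debye_constant(0, 298), 0)
  # square-root law in ionic strength
  for (I in c(0.01, 0.15, 1)) {
    expect_equal(debye_constant(4 * I) / debye_constant(I), 2)
  }
  expect_error(debye_constant(-1), ">= 0")
})

test_that("nonbonded pair potential has the stated limits and symmetries", {
  ff <- force_field()
  g <- fixture_bead("G")   # lambda > 0 but charge 0
  bp <- bead_parameters()
  inert <- as.list(dplyr::mutate(bp[bp$code == "G", ], lambda = 0))
  r <- seq(0.62, 2.4, by = 0.02)
  # lambda = 0, q = 0: repulsive only, vanishing at large r
  u0 <- nonbonded_energy(inert, inert, r, ff)
  expect_true(all(u0 >= 0))
  expect_equal(u0[r > 0.7], rep(0, sum(r > 0.7)))
  # equal charges, lambda = 0: monotonically repulsive screened-Coulomb tail
  kpos <- as.list(dplyr::mutate(bp[bp$code == "K", ], lambda = 0))
  uk <- nonbonded_energy(kpos, kpos, r, ff)
  expect_true(all(uk[r < 2] > 0))
  expect_true(all(diff(uk[r > 0.7 & r < 2.1]) < 0))
  # exchange symmetry and odd under charge flip (electrostatic part;
  # checked beyond the repulsive core where the even WCA term vanishes)
  kneg <- as.list(dplyr::mutate(bp[bp$code == "K", ], lambda = 0, charge = -1))
  expect_equal(nonbonded_energy(kpos, kneg, r, ff),
               nonbonded_energy(kneg, kpos, r, ff))
  tail_r <- r[r > 0.7]
  expect_equal(nonbonded_energy(kpos, kneg, tail_r, ff),
               -nonbonded_energy(kpos, kpos, tail_r, ff))
  # F-F at the LJ minimum: independent hand evaluation of the closed form
  f <- fixture_bead("F")
  rmin <- 2^(1 / 6) * f$diameter
  lam <- f$lambda
  hand <- (4 * ff$epsilon0 * ((f$diameter / rmin)^12 - (f$diameter / rmin)^6) +
             (1 - lam) * ff$epsilon0) # switch = 1 at rmin
  expect_equal(nonbonded_energy(f, f, rmin, ff), hand)
  expect_equal(hand, -lam * ff$epsilon0 + 0) # well depth -lambda*eps0
  expect_error(nonbonded_energy(f, f, 0.01, ff), "below the minimum")
})

test_that("analytic force matches central differences (C1 continuity)", {
  ff <- force_field()
  pairs <- list(c("F", "F"), c("F", "K"), c("K", "E"), c("G", "S"))
  r <- seq(0.45, 3.2, by = 0.037) # avoids landing exactly on cutoffs
  h <- 1e-6
  for (p in pairs) {
    bi <- fixture_bead(p[1]); bj <- fixture_bead(p[2])
    num <- (nonbonded_energy(bi, bj, r + h, ff) -
              nonbonded_energy(bi, bj, r - h, ff)) / (2 * h)
    ana <- nonbonded_energy_deriv(bi, bj, r, ff)
    expect_lt(max(abs(num - ana) / pmax(abs(ana), 1)), 1e-5)
  }
})

test_that("compiled pair kernel agrees with the reference potential", {
  ff <- force_field()
  for (codes in list(c("F", "F"), c("F", "K"), c("K", "E"))) {
    for (r in c(0.5, 0.674, 0.9, 1.3, 2.0, 2.4)) {
      sys <- fixture_pair_system(codes, r)
      eC <- nupore:::cg_energy_forces(nupore:::.pack_state(sys, ff))$energy
      eR <- nonbonded_energy(fixture_bead(codes[1]), fixture_bead(codes[2]), r, ff)
      expect_equal(eC, eR, tolerance = 1e-10)
    }
  }
})

test_that("bonded energy: harmonic bonds plus tabulated angle/torsion terms", {
  ff <- force_field()
  # straight trimer at exact bond length, no tables: zero energy
  chain0 <- rbind(c(0, 0, 0), c(0.38, 0, 0), c(0.76, 0, 0))
  expect_equal(bonded_energy(chain0, ff), 0)
  # single bond stretched to 0.40 nm: closed form
  dimer <- rbind(c(0, 0, 0), c(0.40, 0, 0))
  expect_equal(bonded_energy(dimer, ff), 0.5 * ff$bond_k * 0.02^2)
  expect_error(bonded_energy(rbind(c(0, 0, 0), c(0, 0, 0)), ff), "coincident")
  # nonuniform torsion table: matches direct evaluation at an independently
  # computed dihedral angle
  tt <- data.frame(dihedral = seq(-180, 180, by = 5))
  tt$energy <- sin(tt$dihedral * pi / 180) + 0.3 * cos(2 * tt$dihedral * pi / 180)
  fft <- force_field(torsion_table = tt)
  p <- rbind(c(0, 0, 0), c(0.38, 0, 0), c(0.38, 0.38, 0), c(0.1, 0.38, 0.3))
  # oracle: dihedral via an independent construction (projection onto the
  # plane normal to the central bond)
  b2 <- p[3, ] - p[2, ]; b2 <- b2 / sqrt(sum(b2^2))
  v1 <- (p[1, ] - p[2, ]) - sum((p[1, ] - p[2, ]) * b2) * b2
  v2 <- (p[4, ] - p[3, ]) - sum((p[4, ] - p[3, ]) * b2) * b2
  ang <- acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
  sgn <- sign(sum(cross <- c(v1[2] * v2[3] - v1[3] * v2[2],
                             v1[3] * v2[1] - v1[1] * v2[3],
                             v1[1] * v2[2] - v1[2] * v2[1]) * b2))
  expect_equal(abs(dihedral_angle(p[1, ], p[2, ], p[3, ], p[4, ])), ang,
               tolerance = 1e-8)
  phi <- sgn * ang
  bond_part <- bonded_energy(p, force_field())
  expected_torsion <- approx(tt$dihedral, tt$energy, xout = phi)$y
  expect_equal(bonded_energy(p, fft) - bond_part, expected_torsion,
               tolerance = 1e-6)
  # angle table interpolation
  at <- data.frame(angle = c(0, 90, 180), energy = c(5, 1, 0))
  ffa <- force_field(angle_table = at)
  straight <- rbind(c(0, 0, 0), c(0.38, 0, 0), c(0.76, 0, 0))
  expect_equal(bonded_energy(straight, ffa), 0)     # 180 degrees
  bent <- rbind(c(0.38, 0, 0), c(0, 0, 0), c(0, 0.38, 0))
  expect_equal(bonded_energy(bent, ffa), 1)         # 90 degrees
})

test_that("cargo models match the stated specifications", {
  k <- build_cargo("Kap95")
  expect_equal(k$radius, 8.5)
  expect_equal(k$charge, -43)
  expect_equal(k$n_hydro_sites, 10L)
  t <- build_cargo("tCherry")
  expect_equal(t$radius, 7.4)
  expect_equal(t$charge, 0)
  expect_equal(t$n_hydro_sites, 0L)
  expect_error(build_cargo("custom", radius = -1, charge = 0, n_hydro_sites = 0),
               "positive")
  # binding spots on the unit sphere, deterministic, well separated:
  # compare against an independent random-restart Thomson minimization
  s1 <- sphere_points(10)
  s2 <- sphere_points(10)
  expect_identical(s1, s2)
  expect_equal(rowSums(s1^2), rep(1, 10), tolerance = 1e-8)
  min_angle <- function(m) {
    cosim <- tcrossprod(m)
    min(acos(pmin(pmax(cosim[upper.tri(cosim)], -1), 1)))
  }
  set.seed(99)
  best <- -Inf
  for (i in 1:5) {
    m0 <- matrix(rnorm(30), 10, 3)
    m0 <- m0 / sqrt(rowSums(m0^2))
    en <- function(p) {
      m <- matrix(p, ncol = 3); m <- m / sqrt(rowSums(m^2))
      d <- as.matrix(dist(m)); sum(1 / d[upper.tri(d)])
    }
    opt <- optim(as.vector(m0), en, method = "L-BFGS-B",
                 control = list(maxit = 300))
    m <- matrix(opt$par, ncol = 3); m <- m / sqrt(rowSums(m^2))
    best <- max(best, min_angle(m))
  }
  expect_gt(min_angle(s1), 0.95 * best)
})

test_that("dielectric saturates sigmoidally to the bulk value", {
  expect_lt(dielectric_sigmoid(0.2), 20)
  expect_equal(dielectric_sigmoid(100), 80, tolerance = 1e-6)
  r <- seq(0.1, 5, by = 0.1)
  expect_true(all(diff(dielectric_sigmoid(r)) > 0))
})
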