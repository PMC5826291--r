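# Langevin integrator physics: minimization descent, Einstein diffusion,
# thermostat, bond statistics, determinism, symplectic limit and chain
# observables.

test_that("minimization is a descent that removes overlaps", {
  ff <- force_field()
  # pre-minimized dimer at the bond length: unchanged
  sq <- nup_sequence("GG", "gg")
  sys <- assemble_free_chain(sq, box = c(20, 20, 20), seed = 1)
  sys$beads$x <- c(0, 0.38); sys$beads$y <- c(0, 0); sys$beads$z <- c(0, 0)
  m <- minimize_system(sys, ff, max_iter = 50, force_tol = 1)
  expect_equal(m$beads$x, sys$beads$x, tolerance = 1e-6)
  # overlapping neutral beads separate to at least contact
  sys$beads$x <- c(0, 0.15)
  sys$bonds <- matrix(0L, 0, 2)
  st0 <- nupore:::cg_energy_forces(nupore:::.pack_state(sys, ff))$energy
  m2 <- minimize_system(sys, ff, max_iter = 400, force_tol = 5)
  sep <- abs(diff(m2$beads$x))
  expect_gt(sqrt(sum((m2$beads[2, c("x", "y", "z")] -
                        m2$beads[1, c("x", "y", "z")])^2)), 0.6 * 0.95)
  expect_lte(attr(m2, "minimization")$energy, st0)
})

test_that("free beads obey the Einstein relation and the thermostat", {
  # ideal gas of 150 independent beads
  sq <- nup_sequence("G", "g")
  beads <- do.call(rbind, lapply(1:150, function(i) {
    s <- assemble_free_chain(sq, box = c(900, 900, 900), seed = i)$beads
    s$chain <- i
    s
  }))
  set.seed(1)
  beads$x <- runif(150, -300, 300)
  beads$y <- runif(150, -300, 300)
  beads$z <- runif(150, -300, 300)
  sys <- assemble_free_chain(sq, box = c(900, 900, 900), seed = 1)
  sys$beads <- beads
  sys$bonds <- matrix(0L, 0, 2)
  gamma <- 1
  cfg <- simulation_config(n_steps = 20000, timestep = 0.01, friction = gamma,
                           stride = 50, equil_fraction = 0, ramp_fraction = 0,
                           seed = 5)
  tr <- run_dynamics(sys, cfg)
  # kinetic temperature within 3%
  expect_equal(mean(tr$temperature), 298, tolerance = 0.03)
  # MSD slope: 6 D t with D = kBT / (m gamma); lag of 100 ps >> 1/gamma so
  # the inertial correction (1 - exp(-gamma t))/gamma t is < 1%
  lag <- 200 # frames of 0.5 ps
  nf <- dim(tr$coords)[3]
  disp <- tr$coords[, , (lag + 1):nf, drop = FALSE] -
    tr$coords[, , 1:(nf - lag), drop = FALSE]
  msd <- mean(apply(disp^2, c(1, 3), sum))
  D_emp <- msd / (6 * lag * 50 * 0.01)
  D_th <- kBT(298) / (57.0519 * gamma)
  expect_equal(D_emp, D_th, tolerance = 0.05)
})

test_that("bonded dimer samples the harmonic bond distribution at 0.38 nm", {
  sq <- nup_sequence("GG", "gg")
  sys <- assemble_free_chain(sq, box = c(30, 30, 30), seed = 1)
  cfg <- simulation_config(n_steps = 60000, timestep = 0.01, friction = 1,
                           stride = 20, equil_fraction = 0.1,
                           ramp_fraction = 0, seed = 4)
  tr <- run_dynamics(sys, cfg)
  bl <- sqrt(colSums((tr$coords[1, , ] - tr$coords[2, , ])^2))
  expect_equal(mean(bl), 0.38, tolerance = 0.01)
  # fluctuation width ~ sqrt(kBT / k_bond) (radial Jacobian widens slightly)
  expect_equal(sd(bl), sqrt(kBT() / 8000), tolerance = 0.15)
})

test_that("dynamics are bit-reproducible for a fixed seed", {
  sq <- nup_sequence("FGFG", "t")
  sys <- assemble_free_chain(sq, box = c(20, 20, 20), seed = 2)
  cfg <- simulation_config(n_steps = 2000, stride = 50, seed = 11)
  t1 <- run_dynamics(sys, cfg)
  t2 <- run_dynamics(sys, cfg)
  expect_identical(t1$coords, t2$coords)
  cfg2 <- simulation_config(n_steps = 2000, stride = 50, seed = 12)
  t3 <- run_dynamics(sys, cfg2)
  expect_false(identical(t1$coords, t3$coords))
})

test_that("noise-free integration conserves energy (symplectic check)", {
  # interacting trimer, displaced from the minimum, friction/noise off
  sq <- nup_sequence("FGF", "t")
  sys <- assemble_free_chain(sq, box = c(30, 30, 30), seed = 3)
  sys <- minimize_system(sys, max_iter = 300, force_tol = 1)
  sys$beads$x[1] <- sys$beads$x[1] + 0.05 # inject potential energy
  cfg <- simulation_config(n_steps = 10000, timestep = 0.002, friction = 0,
                           stride = 5, equil_fraction = 0, ramp_fraction = 0,
                           seed = 1)
  tr <- run_dynamics(sys, cfg, noise = FALSE)
  ke <- 1.5 * 3 * 0.00831446262 * tr$temperature
  etot <- tr$potential + ke
  drift <- (max(etot) - min(etot)) / max(abs(diff(range(tr$potential))), 1e-12)
  # total-energy fluctuation small relative to the potential-energy exchange
  expect_lt(drift, 1e-2)
  # and tiny in absolute terms over 1e4 steps
  expect_lt(max(etot) - min(etot), 1e-3 * max(ke))
})

test_that("tethered anchors stay at their sites within thermal amplitude", {
  geom <- pore_geometry(16, box = c(40, 40, 60))
  an <- build_anchors(geom, 10)
  sq <- seq_segment(load_builtin("Nsp1"), 600, 637) # short C-terminal piece
  sys <- assemble_system(geom, an, sq, seed = 3)
  sys <- minimize_system(sys, max_iter = 200, force_tol = 100)
  cfg <- simulation_config(n_steps = 5000, stride = 50, seed = 6,
                           equil_fraction = 0.2, tether_k = 500)
  tr <- run_dynamics(sys, cfg)
  anchor_idx <- sys$tethers$bead
  for (i in seq_along(anchor_idx)) {
    dev <- sqrt((tr$coords[anchor_idx[i], 1, ] - sys$tethers$x[i])^2 +
                  (tr$coords[anchor_idx[i], 2, ] - sys$tethers$y[i])^2 +
                  (tr$coords[anchor_idx[i], 3, ] - sys$tethers$z[i])^2)
    expect_lt(max(dev), 6 * sqrt(3 * kBT() / 500))
  }
})

test_that("chain observables: closed forms for rods and the Kirkwood sum", {
  # rigid two-bead rod: Kirkwood Rs = 2D exactly
  fake <- list(
    coords = array(rep(c(0, 0, 0, 0, 0, 3), 60), dim = c(2, 3, 60)),
    system = list(beads = tibble::tibble(chain = c(1, 1))),
    time = 1:60, temperature = rep(298, 60)
  )
  fake$coords <- array(0, dim = c(2, 3, 60))
  fake$coords[2, 1, ] <- 3 # separation D = 3 along x
  class(fake) <- "cg_trajectory"
  ob <- chain_observables(fake)
  expect_equal(ob$Rs, 2 * 3)
  # N collinear equally spaced beads: discrete-rod Rg closed form
  N <- 9; a <- 0.38
  fake2 <- fake
  fake2$coords <- array(0, dim = c(N, 3, 60))
  fake2$coords[, 1, ] <- (0:(N - 1)) * a
  ob2 <- chain_observables(fake2)
  expect_equal(ob2$Rg, a * sqrt((N^2 - 1) / 12))
  expect_error(chain_observables(fake, selection = integer(0)), "empty")
})
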