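# shared fixtures: tiny sequences, analytic profiles, and a sampler used as
# the independent Boltzmann oracle for WHAM tests

fixture_bead <- function(code = "F") {
  bp <- bead_parameters()
  as.list(bp[bp$code == code, ])
}

# flat radial profile out to r_max (0.5 nm bins, bin centres)
fixture_uniform_profile <- function(rho, r_max = 25) {
  tibble::tibble(r = seq(0.25, r_max, by = 0.5), density = rho)
}

# direct Boltzmann sampling from U(z) + harmonic bias on a fine grid:
# the independent oracle for umbrella/WHAM reconstruction tests
boltzmann_window_samples <- function(U, windows, n_per_window = 5000,
                                     z_range = c(-8, 8), temperature = 298) {
  kT <- nupore::kBT(temperature)
  zg <- seq(z_range[1], z_range[2], by = 1e-3)
  out <- lapply(seq_len(nrow(windows)), function(i) {
    w <- exp(-(U(zg) + windows$k[i] / 2 * (zg - windows$z0[i])^2) / kT)
    z <- sample(zg, n_per_window, replace = TRUE, prob = w) +
      stats::runif(n_per_window, -5e-4, 5e-4)
    data.frame(window = windows$window[i], z0 = windows$z0[i],
               k = windows$k[i], replicate = 1, z = z)
  })
  tibble::as_tibble(do.call(rbind, out))
}

# two-bead system at separation r along x, no bonds; used to compare the
# compiled force kernel against the reference pair potential
fixture_pair_system <- function(codes = c("F", "K"), r = 1) {
  sys <- assemble_free_chain(nup_sequence(paste(codes, collapse = ""), "pair"),
                             box = c(50, 50, 50), seed = 3)
  sys$bonds <- matrix(0L, 0, 2)
  sys$beads$x <- c(0, r)
  sys$beads$y <- c(0, 0)
  sys$beads$z <- c(0, 0)
  sys
}
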