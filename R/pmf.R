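# Umbrella sampling along the pore axis, WHAM reconstruction of the
# potential of mean force, sixth-order polynomial smoothing, barrier
# extraction and Arrhenius event rates.

#' Build umbrella windows along the pore axis
#'
#' Regularly spaced harmonic restraint centres from `z_min` upward with the
#' stated spacing (default 1.3 nm) and spring constant (default
#' 10 kJ/mol/nm^2).
#'
#' @param z_min,z_max axial range, nm
#' @param spacing window spacing, nm
#' @param k restraint spring constant, kJ/mol/nm^2
#' @param replicates starting configurations per window
#' @return tibble of class `umbrella_windows`: `window`, `z0`, `k`,
#'   `replicate`
#' @export
make_windows <- function(z_min, z_max, spacing = 1.3, k = 10, replicates = 2) {
  if (spacing <= 0) abort("spacing must be positive")
  if (z_min > z_max) abort("z_min must be <= z_max")
  z0 <- seq(z_min, z_max, by = spacing)
  out <- tidyr::expand_grid(window = seq_along(z0), replicate = seq_len(replicates)) |>
    mutate(z0 = z0[.data$window], k = k) |>
    select("window", "z0", "k", "replicate")
  class(out) <- c("umbrella_windows", class(out))
  out
}

#' Run umbrella sampling for a cargo in a pore system
#'
#' For each window and replicate, places the cargo on the axis at the window
#' centre, relaxes the system briefly, runs restrained Langevin dynamics and
#' records the cargo's axial position each post-equilibration step. Replicate
#' runs use different seeds (fresh protein starting configurations).
#'
#' @param system a `pore_system` (may be `NULL` for an empty pore / free
#'   cargo)
#' @param cargo a [build_cargo()] model
#' @param windows an [make_windows()] tibble
#' @param config a [simulation_config()]; each window runs `config$n_steps`
#'   steps
#' @param ff a [force_field()]
#' @param box box for the empty-system case, nm
#' @return tibble of class `umbrella_samples`: `window`, `z0`, `k`,
#'   `replicate`, `z` (one row per sample)
#' @export
run_umbrella <- function(system, cargo, windows,
                         config = simulation_config(n_steps = 4000, stride = 50),
                         ff = force_field(), box = c(40, 40, 120)) {
  if (is.null(system)) {
    geom <- structure(list(diameter = Inf, height = 0, box = box,
                           wall_bead_diameter = 0), class = "pore_geometry")
    system <- structure(
      list(beads = tibble(chain = integer(), index = integer(),
                          residue = character(), mass = numeric(),
                          charge = numeric(), lambda = numeric(),
                          diameter = numeric(), x = numeric(), y = numeric(),
                          z = numeric()),
           bonds = matrix(0L, 0, 2),
           tethers = tibble(bead = integer(), x = numeric(), y = numeric(),
                            z = numeric()),
           wall = tibble(x = numeric(), y = numeric(), z = numeric(),
                         diameter = numeric()),
           geometry = geom, sequence = NULL, seed = config$seed),
      class = "pore_system")
  }
  runs <- purrr::pmap(
    list(windows$window, windows$z0, windows$k, windows$replicate),
    function(w, z0, k, rep) {
      cfg <- config
      cfg$seed <- config$seed + 1000L * rep + w
      cargo_w <- cargo
      cargo_w$center <- c(0, 0, z0)
      restraint <- list(z0 = z0, k = k, on = TRUE, k_lat = k)
      sys_w <- minimize_system(system, ff, cfg, max_iter = 300,
                               force_tol = 100, cargo = cargo_w,
                               restraint = restraint)
      traj <- run_dynamics(sys_w, cfg, ff, cargo = cargo_w, restraint = restraint)
      tibble(window = w, z0 = z0, k = k, replicate = rep,
             z = as.numeric(traj$cargo_z_samples))
    })
  out <- dplyr::bind_rows(runs)
  mean_dev <- out |>
    group_by(.data$window, .data$z0, .data$k) |>
    summarise(m = mean(.data$z), .groups = "drop")
  kBT_ <- kBT(config$temperature)
  bad <- abs(mean_dev$m - mean_dev$z0) > 3 * sqrt(kBT_ / mean_dev$k)
  if (any(bad)) {
    warn(sprintf("%d windows have mean positions > 3 thermal widths from their centres (poor restraint)",
                 sum(bad)))
  }
  class(out) <- c("umbrella_samples", class(out))
  out
}

#' Weighted histogram analysis (WHAM)
#'
#' Combines biased umbrella-window histograms into a single free-energy
#' profile by self-consistent iteration of the window free energies; the
#' profile is defined up to an additive constant (minimum set to zero).
#'
#' @param samples an `umbrella_samples` tibble (columns `window`, `z0`, `k`,
#'   `z`; replicates are pooled per window)
#' @param temperature K
#' @param bin_width histogram bin width, nm (default 0.1)
#' @param tolerance convergence threshold on window free-energy changes,
#'   kJ/mol
#' @param max_iter iteration cap
#' @return object of class `pmf_curve`: tibble `z`, `pmf` (kJ/mol) in
#'   `$profile`, plus convergence info
#' @export
wham <- function(samples, temperature = 298, bin_width = 0.1,
                 tolerance = 1e-6, max_iter = 5000) {
  wins <- samples |>
    group_by(.data$window, .data$z0, .data$k) |>
    summarise(n = dplyr::n(), .groups = "drop")
  if (nrow(wins) < 2L) abort("WHAM needs at least 2 windows")
  kT <- kBT(temperature)
  zlo <- min(samples$z); zhi <- max(samples$z)
  edges <- seq(floor(zlo / bin_width) * bin_width,
               ceiling(zhi / bin_width) * bin_width, by = bin_width)
  mids <- edges[-1] - bin_width / 2
  nb <- length(mids)
  nw <- nrow(wins)
  counts <- matrix(0, nw, nb)
  for (i in seq_len(nw)) {
    zi <- samples$z[samples$window == wins$window[i]]
    counts[i, ] <- tabulate(pmin(pmax(findInterval(zi, edges), 1L), nb), nb)
  }
  # check overlap connectivity
  occ <- counts > 0
  reach <- occ[1, ]
  repeat {
    newreach <- reach
    for (i in seq_len(nw)) if (any(occ[i, ] & reach)) newreach <- newreach | occ[i, ]
    if (all(newreach == reach)) break
    reach <- newreach
  }
  if (!all(apply(occ, 1, function(o) any(o & reach)))) {
    abort("disjoint window histograms: no overlap path connects all windows")
  }
  Ni <- rowSums(counts)
  bias <- matrix(0, nw, nb)
  for (i in seq_len(nw)) bias[i, ] <- wins$k[i] / 2 * (mids - wins$z0[i])^2
  expb <- exp(-bias / kT)
  f <- rep(0, nw)
  tot <- colSums(counts)
  for (iter in seq_len(max_iter)) {
    denom <- colSums(Ni * exp(f / kT) * expb)
    P <- tot / denom
    P[!is.finite(P)] <- 0
    fn <- -kT * log(pmax(expb %*% P, 1e-300))[, 1]
    fn <- fn - fn[1]
    delta <- max(abs(fn - f))
    f <- fn
    if (delta < tolerance) break
  }
  pmf <- -kT * log(pmax(P, 1e-300))
  keep <- tot > 0
  pmf <- pmf[keep] - min(pmf[keep])
  structure(
    list(profile = tibble(z = mids[keep], pmf = pmf),
         converged = delta < tolerance, iterations = iter,
         temperature = temperature, bin_width = bin_width,
         window_free_energies = tibble(window = wins$window, f = f)),
    class = "pmf_curve"
  )
}

#' @export
print.pmf_curve <- function(x, ...) {
  cat(sprintf("<pmf_curve> %d bins (%g nm), %s after %d iterations\n",
              nrow(x$profile), x$bin_width,
              if (x$converged) "converged" else "NOT converged", x$iterations))
  invisible(x)
}

#' Smooth a PMF with sixth-order polynomial branches
#'
#' Fits separate sixth-order polynomials to the z < 0 and z >= 0 branches
#' and concatenates them on a fine grid for the extremum search.
#'
#' @param curve a `pmf_curve` or tibble with `z`, `pmf`
#' @param n_grid evaluation points per branch
#' @return tibble `z`, `pmf` (smoothed)
#' @export
smooth_pmf <- function(curve, n_grid = 200) {
  df <- if (inherits(curve, "pmf_curve")) curve$profile else curve
  branches <- list(df[df$z < 0, ], df[df$z >= 0, ])
  purrr::map(branches, function(b) {
    if (nrow(b) == 0L) return(NULL)
    if (nrow(b) < 8L) {
      abort("fewer PMF points than polynomial degrees of freedom in a branch")
    }
    fit <- lm(pmf ~ poly(z, 6, raw = TRUE), data = b)
    zg <- seq(min(b$z), max(b$z), length.out = n_grid)
    tibble(z = zg, pmf = unname(predict(fit, newdata = data.frame(z = zg))))
  }) |> dplyr::bind_rows()
}

#' Energy barrier of a PMF curve
#'
#' The work required for transport through the channel: the difference
#' between the maximum and minimum of the (smoothed) PMF.
#'
#' @param curve a `pmf_curve` or tibble with `z`, `pmf`
#' @param smooth apply the sixth-order polynomial branch smoothing first
#' @return barrier height, kJ/mol (>= 0)
#' @export
pmf_barrier <- function(curve, smooth = TRUE) {
  sm <- if (smooth) smooth_pmf(curve) else {
    if (inherits(curve, "pmf_curve")) curve$profile else curve
  }
  max(sm$pmf) - min(sm$pmf)
}

#' Arrhenius rate model
#'
#' @param gamma0 attempt (bare-pore event) frequency, Hz
#' @param temperature K
#' @return object of class `rate_model`
#' @export
rate_model <- function(gamma0, temperature = 298) {
  if (gamma0 < 0) abort("gamma0 must be >= 0")
  structure(list(gamma0 = gamma0, temperature = temperature,
                 kBT = kBT(temperature)),
            class = "rate_model")
}

#' Arrhenius event rate for an energy barrier
#'
#' `Gamma = Gamma0 exp(-dE / kBT)`. The proportionality constant resembles
#' the event frequency of the bare pore; rate *ratios* between barriers
#' cancel it and are the primary validated quantity.
#'
#' @param model a [rate_model()]
#' @param barrier energy barrier dE, kJ/mol (vectorized)
#' @return event rate, Hz
#' @export
arrhenius_rate <- function(model, barrier) {
  if (any(barrier < 0)) abort("barrier must be >= 0")
  model$gamma0 * exp(-barrier / model$kBT)
}
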