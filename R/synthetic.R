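# Synthetic-data generators standing in for the wet-lab instruments:
# patch-clamp-like current traces with Poisson events, log-normal dwell
# times, Gaussian blockades and white + 1/f noise; parametric axisymmetric
# protein-density fields; random test chains with controlled composition.

#' Specification of a synthetic current trace
#'
#' Defaults emulate the bare-pore transport-receptor recordings: 1.7 Hz
#' Poisson events, log-normal dwell times with linear mean 0.29 ms and sd
#' 0.16 ms, Gaussian blockades of 0.22 +/- 0.07 nS (truncated positive), a
#' 7 nA baseline at 100 mV.
#'
#' @param duration s
#' @param sampling_rate Hz
#' @param baseline baseline current, nA
#' @param voltage mV
#' @param rate Poisson event rate, Hz
#' @param dwell_mean,dwell_sd linear-scale mean and sd of the log-normal
#'   dwell distribution, s
#' @param blockade_mean,blockade_sd Gaussian blockade parameters, nS
#'   (truncated positive)
#' @param noise_sd white-noise sd, nA (default gives a signal-to-noise
#'   ratio of about 13 for the default blockade, comparable to clearly
#'   resolvable recorded spikes)
#' @param onef_amplitude rms of the 1/f^alpha noise component, nA
#' @param onef_alpha 1/f exponent alpha
#' @return list of class `trace_spec`
#' @export
trace_spec <- function(duration = 60, sampling_rate = 50000, baseline = 7,
                       voltage = 100, rate = 1.7,
                       dwell_mean = 0.29e-3, dwell_sd = 0.16e-3,
                       blockade_mean = 0.22, blockade_sd = 0.07,
                       noise_sd = 0.0015, onef_amplitude = 0.0008,
                       onef_alpha = 1) {
  stopifnot(duration > 0, sampling_rate > 0, dwell_mean > 0, blockade_mean > 0)
  # log-normal parameters from the linear mean/sd
  cv2 <- (dwell_sd / dwell_mean)^2
  sdlog <- sqrt(log(1 + cv2))
  meanlog <- log(dwell_mean) - sdlog^2 / 2
  if (rate * dwell_mean > 0.5) {
    warn("event rate x mean dwell > 0.5: pore occupancy too high, events will overlap")
  }
  structure(
    list(duration = duration, sampling_rate = sampling_rate,
         baseline = baseline, voltage = voltage, rate = rate,
         meanlog = meanlog, sdlog = sdlog, dwell_mean = dwell_mean,
         dwell_sd = dwell_sd, blockade_mean = blockade_mean,
         blockade_sd = blockade_sd, noise_sd = noise_sd,
         onef_amplitude = onef_amplitude, onef_alpha = onef_alpha),
    class = "trace_spec"
  )
}

# 1/f^alpha noise by spectral shaping of white noise, returned with unit rms
.onef_noise <- function(n, alpha) {
  nf <- floor(n / 2)
  freqs <- seq_len(nf)
  amps <- freqs^(-alpha / 2)
  phases <- runif(nf, 0, 2 * pi)
  spec <- complex(modulus = amps, argument = phases)
  full <- complex(real = numeric(n))
  full[2:(nf + 1)] <- spec
  if (n %% 2 == 0) {
    full[nf + 1] <- complex(real = Re(spec[nf]))
    if (nf > 1) full[seq(n, nf + 2)] <- Conj(spec[1:(nf - 1)])
  } else {
    full[seq(n, nf + 1)] <- Conj(spec)
  }
  x <- Re(fft(full, inverse = TRUE))
  x / sd(x)
}

#' Generate a synthetic current trace with ground truth
#'
#' Baseline plus Poisson-placed downward dips (trapezoidal with 2-sample
#' edges), white noise and spectrally shaped 1/f noise. The ground-truth
#' event list is returned for recovery tests.
#'
#' @param spec a [trace_spec()]
#' @param seed RNG seed
#' @return list: `trace` (a [current_trace()]), `truth` (tibble `start`,
#'   `dwell`, `blockade`), `spec`
#' @export
gen_trace <- function(spec = trace_spec(), seed = 1) {
  set.seed(seed)
  n <- round(spec$duration * spec$sampling_rate)
  fs <- spec$sampling_rate
  n_events <- rpois(1, spec$rate * spec$duration)
  starts <- sort(runif(n_events, 0, spec$duration))
  dwells <- rlnorm(n_events, spec$meanlog, spec$sdlog)
  blockades <- abs(rnorm(n_events, spec$blockade_mean, spec$blockade_sd))
  # drop events that would overlap their predecessor or run off the end
  keep <- rep(TRUE, n_events)
  if (n_events > 1) {
    last_end <- -Inf
    for (i in seq_len(n_events)) {
      if (starts[i] <= last_end + 2 / fs) { keep[i] <- FALSE; next }
      if (starts[i] + dwells[i] >= spec$duration) { keep[i] <- FALSE; next }
      last_end <- starts[i] + dwells[i]
    }
  }
  starts <- starts[keep]; dwells <- dwells[keep]; blockades <- blockades[keep]
  current <- rep(spec$baseline, n)
  v_volts <- spec$voltage / 1000
  for (i in seq_along(starts)) {
    i0 <- floor(starts[i] * fs) + 1L
    i1 <- min(floor((starts[i] + dwells[i]) * fs) + 1L, n)
    if (i1 <= i0) next
    depth <- blockades[i] * v_volts  # nS * V -> nA
    idx <- i0:i1
    shape <- rep(1, length(idx))
    ne <- min(2L, length(idx))
    shape[seq_len(ne)] <- seq_len(ne) / (ne + 1)
    shape[length(idx) - seq_len(ne) + 1L] <- seq_len(ne) / (ne + 1)
    current[idx] <- current[idx] - depth * shape
  }
  if (spec$noise_sd > 0) current <- current + rnorm(n, 0, spec$noise_sd)
  if (spec$onef_amplitude > 0) {
    # 1/f noise is low-frequency by construction: synthesize on a decimated
    # grid and interpolate to full rate
    dec <- if (n > 2e5) 10L else 1L
    nd <- ceiling(n / dec)
    lf <- .onef_noise(nd, spec$onef_alpha)
    lf_full <- if (dec > 1L) {
      approx(seq(1, n, length.out = nd), lf, xout = seq_len(n))$y
    } else lf
    current <- current + spec$onef_amplitude * lf_full
  }
  trace <- current_trace(seq_len(n) / fs, current, spec$voltage)
  list(
    trace = trace,
    truth = tibble(start = starts, dwell = dwells, blockade = blockades),
    spec = spec
  )
}

#' Specification of a synthetic protein density field
#'
#' Three axisymmetric families emulating the simulated FG-domain
#' distributions: `"uniform"` (mutant-like: constant density across the
#' pore), `"center_peaked"` (wildtype-like: Gaussian maximum on the axis over
#' a uniform background) and `"ring"` (collapsed-domain-like: a dense annulus
#' near the wall with an open centre).
#'
#' @param family density family
#' @param amplitude peak density, mg/ml
#' @param background background (wing) density inside the pore, mg/ml
#' @param width Gaussian width of the central peak or the ring, nm
#' @param ring_radius centre radius of the ring family, nm (defaults to 3 nm
#'   inside the wall)
#' @param diameter,height pore geometry, nm
#' @param box grid extent, nm
#' @param access_scale densities in the access region (|z| between l/2 and
#'   l/2 + access_extent) are this fraction of the in-pore value
#' @param access_extent axial extent of protein above/below the pore, nm
#' @return list of class `density_spec`
#' @export
density_spec <- function(family = c("uniform", "center_peaked", "ring"),
                         amplitude = 50, background = NULL, width = 6,
                         ring_radius = NULL, diameter = 45, height = 20,
                         box = c(70, 70, 100), access_scale = 0.5,
                         access_extent = 20) {
  family <- match.arg(family)
  if (amplitude < 0) abort("amplitude must be >= 0")
  background <- background %||% switch(family,
    uniform = amplitude, center_peaked = amplitude * 0.7, ring = 0)
  ring_radius <- ring_radius %||% (diameter / 2 - 3)
  structure(
    list(family = family, amplitude = amplitude, background = background,
         width = width, ring_radius = ring_radius, diameter = diameter,
         height = height, box = box, access_scale = access_scale,
         access_extent = access_extent),
    class = "density_spec"
  )
}

# radial law of a density_spec, vectorized over r
.density_radial_law <- function(spec, r) {
  inside <- r < spec$diameter / 2
  rho <- switch(spec$family,
    uniform = rep(spec$amplitude, length(r)),
    center_peaked = spec$background +
      (spec$amplitude - spec$background) * exp(-r^2 / (2 * spec$width^2)),
    ring = spec$amplitude * exp(-(r - spec$ring_radius)^2 / (2 * spec$width^2))
  )
  rho * inside
}

#' Generate a synthetic density grid
#'
#' Realizes the axisymmetric family on a (0.5 nm)^3 grid: full density
#' inside the pore cylinder, `access_scale` times the radial law in the
#' access region above and below the pore, zero elsewhere.
#'
#' @param spec a [density_spec()]
#' @param cell_edge grid cell edge, nm
#' @return a `density_grid`
#' @export
gen_density <- function(spec = density_spec(), cell_edge = 0.5) {
  g <- density_grid(spec$box, cell_edge)
  cx <- g$origin[1] + (seq_len(g$dims[1]) - 0.5) * cell_edge
  cy <- g$origin[2] + (seq_len(g$dims[2]) - 0.5) * cell_edge
  cz <- g$origin[3] + (seq_len(g$dims[3]) - 0.5) * cell_edge
  rmat <- sqrt(outer(cx^2, cy^2, `+`))
  radial <- .density_radial_law(spec, as.numeric(rmat))
  hl <- spec$height / 2
  for (k in seq_along(cz)) {
    az <- abs(cz[k])
    scale <- if (az < hl) 1 else if (az < hl + spec$access_extent) spec$access_scale else 0
    if (scale > 0) g$rho[, , k] <- matrix(radial * scale, g$dims[1], g$dims[2])
  }
  g$frames <- 1L
  g
}

#' Generate a random test chain with controlled composition
#'
#' Random sequences with specified charged (half K, half E) and hydrophobic
#' (F) fractions, the remainder filled with serine and glycine; used for
#' force-field property tests. Returns the sequence and a random-walk
#' starting conformation.
#'
#' @param n number of beads (>= 2)
#' @param frac_charged,frac_hydrophobic composition fractions (sum <= 1)
#' @param seed RNG seed
#' @return list: `sequence` (a [nup_sequence()]), `coords` (n x 3 matrix, nm)
#' @export
gen_test_chain <- function(n, frac_charged = 0.2, frac_hydrophobic = 0.2,
                           seed = 1) {
  if (n < 2) abort("need at least 2 beads")
  if (frac_charged + frac_hydrophobic > 1) {
    abort("impossible composition: fractions sum to more than 1")
  }
  set.seed(seed)
  n_ch <- round(n * frac_charged)
  n_ch <- n_ch - n_ch %% 2L # equal K and E for net charge 0
  n_hp <- round(n * frac_hydrophobic)
  pool <- c(rep(c("K", "E"), n_ch / 2), rep("F", n_hp),
            sample(c("S", "G"), n - n_ch - n_hp, replace = TRUE))
  res <- paste(sample(pool), collapse = "")
  sq <- nup_sequence(res, id = sprintf("test%d", n))
  coords <- matrix(0, n, 3)
  for (i in 2:n) {
    d <- rnorm(3)
    coords[i, ] <- coords[i - 1, ] + 0.38 * d / sqrt(sum(d^2))
  }
  list(sequence = sq, coords = coords)
}
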