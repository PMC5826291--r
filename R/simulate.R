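# Langevin dynamics and energy minimization of assembled systems, plus
# single-chain observables (radius of gyration, Kirkwood Stokes radius) and
# plain-text XYZ trajectory interchange.

#' Simulation configuration
#'
#' Time is measured in picosecond-equivalent reduced units: with lengths in
#' nm, energies in kJ/mol and masses in Da, one time unit equals one
#' picosecond of inertial dynamics (the physical time mapping of the
#' overdamped coarse-grained model is faster and is discussed in the methods
#' vignette). The first `equil_fraction` of steps is discarded, mirroring a
#' production protocol that ignores the initial tenth of the run; long-range
#' (hydrophobic + electrostatic) prefactors are ramped linearly over
#' `ramp_fraction` of the steps.
#'
#' @param n_steps total integration steps
#' @param timestep integration step, ps
#' @param friction Langevin collision frequency, 1/ps
#' @param temperature K
#' @param equil_fraction fraction of steps discarded as equilibration
#' @param stride output stride (frames every `stride` steps)
#' @param ramp_fraction fraction of steps over which long-range forces are
#'   switched on
#' @param seed RNG seed
#' @param tether_k anchor tether spring constant, kJ/mol/nm^2
#' @param wall_k membrane/box confinement stiffness, kJ/mol/nm^2
#' @return an object of class `simulation_config`
#' @export
simulation_config <- function(n_steps = 20000, timestep = 0.01, friction = 1,
                              temperature = 298, equil_fraction = 0.1,
                              stride = 100, ramp_fraction = 0.05, seed = 1,
                              tether_k = 500, wall_k = 100) {
  if (equil_fraction >= 1) abort("equil_fraction must be < 1")
  structure(
    list(n_steps = as.integer(n_steps), timestep = timestep,
         friction = friction, temperature = temperature,
         equil_fraction = equil_fraction, stride = as.integer(stride),
         ramp_fraction = ramp_fraction, seed = seed,
         tether_k = tether_k, wall_k = wall_k),
    class = "simulation_config"
  )
}

# pack a pore_system (+ optional cargo/restraint) into the flat list the C++
# core consumes; chain beads first (mobile), wall beads after (fixed)
.pack_state <- function(system, ff = force_field(), config = simulation_config(),
                        cargo = NULL, restraint = NULL, coords = NULL) {
  b <- system$beads
  nw <- nrow(system$wall)
  nm <- nrow(b)
  cm <- if (is.null(coords)) cbind(b$x, b$y, b$z) else coords[seq_len(nm), , drop = FALSE]
  if (nw > 0) {
    wc <- cbind(system$wall$x, system$wall$y, system$wall$z)
    cm <- rbind(cm, wc)
  }
  cargo_list <- if (is.null(cargo)) {
    list(present = FALSE)
  } else {
    rs <- restraint %||% list(z0 = 0, k = 0, on = FALSE, k_lat = 0)
    list(
      present = TRUE,
      center = as.numeric(cargo$center %||% c(0, 0, rs$z0 %||% 0)),
      radius = cargo$radius, charge = cargo$charge, mass = cargo$mass,
      site_strength = if (cargo$n_hydro_sites > 0) cargo$site_strength else 0,
      site_lambda_threshold = cargo$site_lambda_threshold,
      site_sigma = 0.8,
      sites = if (cargo$n_hydro_sites > 0) cargo$sites else matrix(0, 0, 3),
      restraint_on = isTRUE(rs$on),
      restraint_z0 = rs$z0 %||% 0,
      restraint_k = rs$k %||% 0,
      restraint_k_lat = rs$k_lat %||% (rs$k %||% 0)
    )
  }
  list(
    coords = cm,
    n_mobile = nm,
    mass = c(b$mass, rep(1e9, nw)),
    charge = c(b$charge, rep(0, nw)),
    lambda = c(b$lambda, rep(0, nw)),
    diameter = c(b$diameter, if (nw > 0) system$wall$diameter else numeric(0)),
    bonds = if (nrow(system$bonds) > 0) system$bonds else matrix(0L, 0, 2),
    bond_r0 = ff$bond_length, bond_k = ff$bond_k,
    bend_k = ff$bend_k %||% 0,
    tether_bead = as.integer(system$tethers$bead),
    tether_site = cbind(system$tethers$x, system$tethers$y, system$tethers$z),
    tether_k = config$tether_k,
    geom = list(
      pore_radius = if (is.finite(system$geometry$diameter)) system$geometry$diameter / 2 else 1e6,
      half_height = system$geometry$height / 2,
      has_membrane = is.finite(system$geometry$diameter) && system$geometry$height > 0,
      wall_k = config$wall_k,
      box = as.numeric(system$geometry$box),
      box_k = config$wall_k
    ),
    ff = ff[c("epsilon0", "kappa", "lj_cutoff_factor", "coulomb_cutoff",
              "switch_fraction", "min_separation")] |>
      c(list(dielectric = ff$dielectric)),
    cargo = cargo_list
  )
}

#' Energy-minimize a system
#'
#' Adaptive steepest descent with displacement capping, removing bead
#' overlaps left by the random-walk initialization.
#'
#' @param system a `pore_system` from [assemble_system()] or
#'   [assemble_free_chain()]
#' @param ff a [force_field()]
#' @param config a [simulation_config()]
#' @param max_iter iteration cap
#' @param force_tol convergence threshold on the max force component,
#'   kJ/mol/nm
#' @param cargo,restraint optional [build_cargo()] model and restraint list
#'   (`z0`, `k`, `on`)
#' @return the system with updated coordinates plus attributes
#'   `minimization` (energy, iterations, converged, max_force)
#' @export
minimize_system <- function(system, ff = force_field(),
                            config = simulation_config(),
                            max_iter = 500, force_tol = 50,
                            cargo = NULL, restraint = NULL) {
  st <- .pack_state(system, ff, config, cargo, restraint)
  res <- cg_minimize(st, max_iter = max_iter, force_tol = force_tol)
  nm <- nrow(system$beads)
  system$beads$x <- res$coords[seq_len(nm), 1]
  system$beads$y <- res$coords[seq_len(nm), 2]
  system$beads$z <- res$coords[seq_len(nm), 3]
  attr(system, "minimization") <- res[c("energy", "iterations", "converged", "max_force")]
  attr(system, "cargo_center") <- res$cargo_center
  system
}

#' Run Langevin dynamics
#'
#' BAOAB-split Langevin integration at the target temperature. Wall beads are
#' fixed; tethers, membrane half-spaces and box confinement act as configured;
#' long-range force prefactors ramp on over the warm-up window. Bit-for-bit
#' reproducible for a given seed (single-threaded).
#'
#' @param system a `pore_system`
#' @param config a [simulation_config()]
#' @param ff a [force_field()]
#' @param cargo optional [build_cargo()] model
#' @param restraint optional list `(z0, k, on = TRUE, k_lat)`: harmonic
#'   restraint on the cargo centre (axial plus lateral, keeping the cargo on
#'   the pore axis; default k = 10 kJ/mol/nm^2 in [umbrella windows][make_windows])
#' @param noise set `FALSE` for deterministic (NVE) integration, used by the
#'   energy-drift checks
#' @return an object of class `cg_trajectory`: `coords` array
#'   (beads x 3 x frames), `time` (ps), `temperature`, `potential`,
#'   `cargo` frame positions, `cargo_z_samples` (every post-equilibration
#'   step), the `system` snapshot and `config`
#' @export
run_dynamics <- function(system, config = simulation_config(),
                         ff = force_field(), cargo = NULL, restraint = NULL,
                         noise = TRUE) {
  st <- .pack_state(system, ff, config, cargo, restraint)
  equil <- as.integer(floor(config$n_steps * config$equil_fraction))
  ramp <- as.integer(floor(config$n_steps * config$ramp_fraction))
  set.seed(config$seed)
  res <- cg_run(st, dt = config$timestep, gamma = config$friction,
                temperature = config$temperature, n_steps = config$n_steps,
                equil_steps = equil, stride = config$stride,
                ramp_steps = ramp, noise = noise)
  nm <- res$n_mobile
  coords <- array(res$frames, dim = c(nm, 3, res$n_frames))
  final_system <- system
  final_system$beads$x <- res$final_coords[seq_len(nm), 1]
  final_system$beads$y <- res$final_coords[seq_len(nm), 2]
  final_system$beads$z <- res$final_coords[seq_len(nm), 3]
  structure(
    list(coords = coords, time = res$time, temperature = res$temperature,
         potential = res$potential, cargo = res$cargo_frames,
         cargo_z_samples = res$cargo_z_samples,
         final_system = final_system, system = system, config = config,
         ff = ff),
    class = "cg_trajectory"
  )
}

#' @export
print.cg_trajectory <- function(x, ...) {
  cat(sprintf("<cg_trajectory> %d frames x %d beads, %.0f ps, <T> = %.0f K\n",
              dim(x$coords)[3], dim(x$coords)[1],
              if (length(x$time)) max(x$time) else 0, mean(x$temperature)))
  invisible(x)
}

#' Trajectory frames as a tidy tibble
#'
#' @param x a `cg_trajectory`
#' @param ... unused
#' @return tibble with columns `frame`, `time`, `bead`, `chain`, `residue`,
#'   `x`, `y`, `z`
#' @export
as_tibble.cg_trajectory <- function(x, ...) {
  nf <- dim(x$coords)[3]
  nb <- dim(x$coords)[1]
  purrr::map(seq_len(nf), function(f) {
    tibble(frame = f, time = x$time[f], bead = seq_len(nb),
           chain = x$system$beads$chain, residue = x$system$beads$residue,
           x = x$coords[, 1, f], y = x$coords[, 2, f], z = x$coords[, 3, f])
  }) |> dplyr::bind_rows()
}

#' Radius of gyration and Kirkwood Stokes radius
#'
#' Time-averaged radius of gyration and the hydrodynamic (Stokes) radius from
#' the Kirkwood double-sum approximation,
#' `1/Rs = <(1/N^2) sum_{i != j} 1/r_ij>` (self terms excluded), over the
#' selected beads and frames.
#'
#' @param traj a `cg_trajectory`
#' @param selection integer bead indices (default: all beads)
#' @return one-row tibble with `Rg` (nm), `Rs` (nm), `n_frames`
#' @export
chain_observables <- function(traj, selection = NULL) {
  nb <- dim(traj$coords)[1]
  sel <- selection %||% seq_len(nb)
  if (length(sel) == 0L) abort("empty bead selection")
  nf <- dim(traj$coords)[3]
  if (nf < 50L) warn("fewer than 50 frames: Rg/Rs estimates may be poorly converged")
  n <- length(sel)
  rg2 <- numeric(nf)
  inv_sum <- numeric(nf)
  for (f in seq_len(nf)) {
    m <- traj$coords[sel, , f, drop = FALSE][, , 1, drop = TRUE]
    if (is.null(dim(m))) m <- matrix(m, ncol = 3)
    com <- colMeans(m)
    rg2[f] <- mean(rowSums(sweep(m, 2, com)^2))
    if (n > 1) {
      d <- stats::dist(m)
      inv_sum[f] <- 2 * sum(1 / d) / n^2
    }
  }
  rs <- if (n > 1) 1 / mean(inv_sum) else NA_real_
  tibble(Rg = sqrt(mean(rg2)), Rs = rs, n_frames = nf)
}

#' Write coordinates or a trajectory to an XYZ file
#'
#' Plain-text XYZ interchange: atom count, comment line (time), then
#' `residue x y z` per bead, one block per frame, coordinates in nm.
#'
#' @param x a `pore_system` or `cg_trajectory`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_xyz <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (inherits(x, "pore_system")) {
    b <- x$beads
    writeLines(as.character(nrow(b)), con)
    writeLines("pore_system t=0", con)
    writeLines(sprintf("%s %.5f %.5f %.5f", b$residue, b$x, b$y, b$z), con)
  } else if (inherits(x, "cg_trajectory")) {
    nb <- dim(x$coords)[1]
    res <- x$system$beads$residue
    for (f in seq_len(dim(x$coords)[3])) {
      writeLines(as.character(nb), con)
      writeLines(sprintf("frame %d t=%.3f", f, x$time[f]), con)
      writeLines(sprintf("%s %.5f %.5f %.5f", res,
                         x$coords[, 1, f], x$coords[, 2, f], x$coords[, 3, f]), con)
    }
  } else {
    abort("write_xyz handles pore_system and cg_trajectory objects")
  }
  invisible(path)
}

#' Read an XYZ file
#'
#' @param path XYZ file written by [write_xyz()] (or any standard XYZ)
#' @return tibble with `frame`, `label`, `x`, `y`, `z`
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  out <- list()
  i <- 1L; f <- 0L
  while (i <= length(lines)) {
    n <- as.integer(lines[i])
    if (is.na(n)) abort(sprintf("malformed XYZ at line %d", i))
    f <- f + 1L
    block <- lines[(i + 2L):(i + 1L + n)]
    parts <- strsplit(trimws(block), "[[:space:]]+")
    out[[f]] <- tibble(
      frame = f,
      label = vapply(parts, `[[`, character(1), 1),
      x = as.numeric(vapply(parts, `[[`, character(1), 2)),
      y = as.numeric(vapply(parts, `[[`, character(1), 3)),
      z = as.numeric(vapply(parts, `[[`, character(1), 4))
    )
    i <- i + 2L + n
  }
  dplyr::bind_rows(out)
}
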