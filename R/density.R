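# Time-averaged mass-density fields: 3D grids on (0.5 nm)^3 cells,
# circumferentially averaged (r, z) maps, and radial profiles for the pore
# (-10 < z < 10 nm) and access (10 < |z| < 40 nm) windows.

#' Construct an empty density grid
#'
#' Cells are half-open cubes `[x, x + h)` of edge `h` centred on the origin of
#' the simulation box; densities are stored in mg/ml.
#'
#' @param box box dimensions (x, y, z), nm
#' @param cell_edge cell edge length, nm (default 0.5)
#' @return object of class `density_grid` with zeroed density array
#' @export
density_grid <- function(box, cell_edge = 0.5) {
  dims <- as.integer(round(box / cell_edge))
  structure(
    list(
      cell_edge = cell_edge,
      origin = -box / 2,
      dims = dims,
      box = box,
      rho = array(0, dim = dims),
      frames = 0L
    ),
    class = "density_grid"
  )
}

#' @export
print.density_grid <- function(x, ...) {
  cat(sprintf(
    "<density_grid> %d x %d x %d cells of (%g nm)^3, %d frames, total mass %.3g mg/ml*nm^3\n",
    x$dims[1], x$dims[2], x$dims[3], x$cell_edge, x$frames,
    sum(x$rho) * x$cell_edge^3))
  invisible(x)
}

#' Accumulate a trajectory into a time-averaged mass-density grid
#'
#' Particle-in-cell counting (no kernel smoothing): each bead's mass is
#' assigned to the cell containing its centre, counts are averaged over
#' frames and converted to mg/ml (1 Da/nm^3 = 1.66054 mg/ml).
#'
#' @param traj a `cg_trajectory`
#' @param cell_edge cell edge, nm
#' @param box grid extent; defaults to the system box
#' @param masses per-bead masses, Da; defaults to the system bead masses
#' @return a `density_grid`
#' @export
accumulate_grid <- function(traj, cell_edge = 0.5, box = NULL, masses = NULL) {
  box <- box %||% traj$system$geometry$box
  masses <- masses %||% traj$system$beads$mass
  g <- density_grid(box, cell_edge)
  nf <- dim(traj$coords)[3]
  acc <- numeric(prod(g$dims))
  for (f in seq_len(nf)) {
    ix <- floor((traj$coords[, 1, f] - g$origin[1]) / cell_edge)
    iy <- floor((traj$coords[, 2, f] - g$origin[2]) / cell_edge)
    iz <- floor((traj$coords[, 3, f] - g$origin[3]) / cell_edge)
    bad <- which(ix < 0 | ix >= g$dims[1] | iy < 0 | iy >= g$dims[2] |
                   iz < 0 | iz >= g$dims[3])
    if (length(bad) > 0) {
      abort(sprintf("bead %d outside the grid box in frame %d", bad[1], f))
    }
    lin <- 1 + ix + g$dims[1] * (iy + g$dims[2] * iz)
    s <- rowsum(masses, lin)
    idx <- as.integer(rownames(s))
    acc[idx] <- acc[idx] + s[, 1]
  }
  g$rho <- array(acc / (nf * cell_edge^3) * .const$da_nm3_to_mg_ml, dim = g$dims)
  g$frames <- nf
  g
}

#' Total mass represented by a density grid
#'
#' @param grid a `density_grid`
#' @return mass in Da (per-frame average)
#' @export
grid_total_mass <- function(grid) {
  sum(grid$rho) * grid$cell_edge^3 / .const$da_nm3_to_mg_ml
}

#' Circumferentially averaged (r, z) density map
#'
#' Azimuthal mean of the 3D density at each radius/height: cells are grouped
#' by the radius of their centre (bins of the cell edge width) and their
#' z-slice; the mean over an annulus uses the actual cell count so mass is
#' reconstructed with annulus volume = n_cells * cell volume.
#'
#' @param grid a `density_grid` centred on the pore axis
#' @return tibble of class `density_rz`: `r`, `z` (bin centres, nm),
#'   `density` (mg/ml), `n_cells`
#' @export
rz_average <- function(grid) {
  h <- grid$cell_edge
  cx <- grid$origin[1] + (seq_len(grid$dims[1]) - 0.5) * h
  cy <- grid$origin[2] + (seq_len(grid$dims[2]) - 0.5) * h
  cz <- grid$origin[3] + (seq_len(grid$dims[3]) - 0.5) * h
  if (min(cx) > h || max(cx) < -h || min(cy) > h || max(cy) < -h) {
    abort("pore axis (x = y = 0) not inside the grid")
  }
  rmat <- sqrt(outer(cx^2, cy^2, `+`))
  rbin <- floor(rmat / h) # radial bin index
  df <- purrr::map(seq_len(grid$dims[3]), function(k) {
    t1 <- rowsum(as.numeric(grid$rho[, , k]), as.numeric(rbin))
    cnt <- rowsum(rep(1, length(rbin)), as.numeric(rbin))
    tibble(
      r = (as.numeric(rownames(t1)) + 0.5) * h,
      z = cz[k],
      density = unname(t1[, 1] / cnt[, 1]),
      n_cells = unname(cnt[, 1])
    )
  }) |> dplyr::bind_rows()
  class(df) <- c("density_rz", class(df))
  attr(df, "cell_edge") <- h
  df
}

#' Mass reconstructed from an (r, z) map
#'
#' @param rz a `density_rz` tibble
#' @return mass in Da
#' @export
rz_total_mass <- function(rz) {
  h <- attr(rz, "cell_edge")
  sum(rz$density * rz$n_cells) * h^3 / .const$da_nm3_to_mg_ml
}

#' Radial density profile over an axial window
#'
#' Averages the grid azimuthally and axially inside the requested z-window.
#' The pore window (-10 nm < z < 10 nm) is divided into 1 nm slices whose
#' per-slice radial curves are returned alongside the window average; the
#' access region extends over 10 nm < |z| < 40 nm.
#'
#' @param grid a `density_grid`
#' @param z_window `"pore"`, `"access"`, or a numeric `c(zlo, zhi)` (a
#'   symmetric window `|z|` in `[zlo, zhi]` when both bounds are positive and
#'   `zlo > 0`)
#' @param slice_thickness thickness of the per-slice curves, nm
#' @return object of class `radial_profile`: list with `profile` (tibble `r`,
#'   `density`), `slices` (tibble `z`, `r`, `density`), `window`
#' @export
radial_profile <- function(grid, z_window = "pore", slice_thickness = 1) {
  h <- grid$cell_edge
  cz <- grid$origin[3] + (seq_len(grid$dims[3]) - 0.5) * h
  if (is.character(z_window)) {
    z_window <- match.arg(z_window, c("pore", "access"))
    sel <- switch(z_window,
      pore = which(cz > -10 & cz < 10),
      access = which(abs(cz) > 10 & abs(cz) < 40)
    )
    win_label <- z_window
  } else {
    if (length(z_window) != 2L || z_window[1] >= z_window[2]) {
      abort("numeric z_window must be c(zlo, zhi) with zlo < zhi")
    }
    sel <- if (z_window[1] >= 0) {
      which(abs(cz) > z_window[1] & abs(cz) < z_window[2])
    } else {
      which(cz > z_window[1] & cz < z_window[2])
    }
    win_label <- sprintf("[%g, %g]", z_window[1], z_window[2])
  }
  if (length(sel) == 0L) abort("empty z-window: no grid slices selected")
  rz <- rz_average(grid)
  rzw <- rz |> filter(.data$z %in% cz[sel])
  prof <- rzw |>
    group_by(.data$r) |>
    summarise(density = sum(.data$density * .data$n_cells) / sum(.data$n_cells),
              .groups = "drop")
  slice_id <- floor((rzw$z + 1e-9) / slice_thickness) * slice_thickness +
    slice_thickness / 2
  slices <- rzw |>
    mutate(zs = slice_id) |>
    group_by(.data$zs, .data$r) |>
    summarise(density = sum(.data$density * .data$n_cells) / sum(.data$n_cells),
              .groups = "drop") |>
    dplyr::rename(z = "zs")
  structure(
    list(profile = prof, slices = slices, window = win_label,
         cell_edge = h),
    class = "radial_profile"
  )
}

#' @export
print.radial_profile <- function(x, ...) {
  cat(sprintf(
    "<radial_profile> window '%s', %d radial bins, %d slices, peak %.1f mg/ml\n",
    x$window, nrow(x$profile), length(unique(x$slices$z)),
    max(x$profile$density)))
  invisible(x)
}

#' Mean density inside the pore cylinder
#'
#' Characteristic in-pore protein density: the mean mass density within the
#' cylinder r < d/2, -l/2 < z < l/2.
#'
#' @param grid a `density_grid`
#' @param diameter pore diameter, nm
#' @param height pore height, nm
#' @return mean density, mg/ml
#' @export
pore_mean_density <- function(grid, diameter, height = 20) {
  h <- grid$cell_edge
  cx <- grid$origin[1] + (seq_len(grid$dims[1]) - 0.5) * h
  cy <- grid$origin[2] + (seq_len(grid$dims[2]) - 0.5) * h
  cz <- grid$origin[3] + (seq_len(grid$dims[3]) - 0.5) * h
  rmat <- sqrt(outer(cx^2, cy^2, `+`))
  inside_rz <- rmat < diameter / 2
  ksel <- which(abs(cz) < height / 2)
  vals <- vapply(ksel, function(k) {
    slab <- grid$rho[, , k]
    c(sum(slab[inside_rz]), sum(inside_rz))
  }, numeric(2))
  sum(vals[1, ]) / sum(vals[2, ])
}

#' Central-region density
#'
#' Mean density within a central cylinder of radius `r_max` inside the pore
#' height; used for the wildtype-versus-mutant contrast.
#'
#' @param grid a `density_grid`
#' @param r_max radius of the central region, nm
#' @param height axial extent, nm
#' @return mean density, mg/ml
#' @export
central_density <- function(grid, r_max = 3, height = 20) {
  pore_mean_density(grid, diameter = 2 * r_max, height = height)
}
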