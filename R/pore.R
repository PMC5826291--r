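# Biomimetic pore construction: cylindrical wall of inert beads, close-packed
# triangular anchor lattice wrapped on the cylinder, grafted chains.

#' Pore geometry
#'
#' Cylindrical pore of diameter `d` and height `l` centred at the origin with
#' the axis along z (the pore spans -l/2 <= z <= l/2), inside a rectangular
#' simulation box.
#'
#' @param diameter pore diameter, nm
#' @param height pore (membrane) height, nm
#' @param wall_bead_diameter diameter of the inert wall beads, nm
#' @param box box dimensions (x, y, z), nm
#' @return an object of class `pore_geometry`
#' @export
pore_geometry <- function(diameter, height = 20, wall_bead_diameter = 3,
                          box = c(100, 100, 140)) {
  if (diameter <= 0) abort("pore diameter must be positive")
  if (diameter >= min(box[1:2])) abort("pore does not fit inside the box laterally")
  structure(
    list(diameter = diameter, height = height,
         wall_bead_diameter = wall_bead_diameter, box = box),
    class = "pore_geometry"
  )
}

#' @export
print.pore_geometry <- function(x, ...) {
  cat(sprintf("<pore_geometry> d = %g nm, l = %g nm, box %g x %g x %g nm\n",
              x$diameter, x$height, x$box[1], x$box[2], x$box[3]))
  invisible(x)
}

#' Build the cylindrical wall of inert beads
#'
#' Wall beads tile the inner cylindrical surface in a triangular arrangement:
#' rings of `round(pi d / d_bead)` beads spaced `d_bead * sqrt(3)/2` apart
#' axially, alternate rings rotated by half a step. Wall beads are immobile
#' and purely repulsive (hydrophobicity 0, charge 0). The top/bottom membrane
#' faces are modelled as repulsive half-spaces during dynamics, not as beads.
#'
#' @param geom a [pore_geometry()]
#' @return tibble of wall bead coordinates (`x`, `y`, `z`, `diameter`)
#' @export
build_wall <- function(geom) {
  d <- geom$diameter; l <- geom$height; b <- geom$wall_bead_diameter
  if (d < 2 * b) abort("pore diameter smaller than two wall-bead diameters")
  r_shell <- d / 2 + b / 2  # bead centres half a bead outside the lumen surface
  n_col <- max(3L, round(pi * (2 * r_shell) / b))
  dz <- b * sqrt(3) / 2
  n_row <- max(1L, round(l / dz))
  zs <- -l / 2 + (seq_len(n_row) - 0.5) * (l / n_row)
  rows <- purrr::map(seq_len(n_row), function(i) {
    offset <- if (i %% 2 == 0) 0.5 else 0
    th <- 2 * pi * (seq_len(n_col) - 1 + offset) / n_col
    tibble(x = r_shell * cos(th), y = r_shell * sin(th), z = zs[i])
  })
  dplyr::bind_rows(rows) |> mutate(diameter = b)
}

#' Build the triangular anchor lattice on the pore surface
#'
#' A close-packed triangular lattice of grafting sites wrapped onto the inner
#' cylinder surface. Wrapping cannot be exact for arbitrary diameter: the
#' number of circumferential columns is fixed to `round(pi d / a)` and the
#' number of rows to `round(l / (a sqrt(3)/2))`, preserving the target areal
#' density (one site per `sqrt(3)/2 a^2`); the realized spacing is reported.
#'
#' @param geom a [pore_geometry()]
#' @param spacing target grafting distance `a`, nm (default 5.7, i.e. one
#'   chain per 28 nm^2)
#' @return an object of class `anchor_lattice`: tibble of `sites` (x, y, z),
#'   `spacing` (requested), `realized_spacing`, `area_per_site`
#' @export
build_anchors <- function(geom, spacing = 5.7) {
  d <- geom$diameter; l <- geom$height
  if (spacing <= 0) abort("spacing must be positive")
  if (spacing >= pi * d) abort("spacing too large: no anchor column fits on the circumference")
  r <- d / 2
  n_col <- max(1L, round(pi * d / spacing))
  dz_t <- spacing * sqrt(3) / 2
  n_row <- max(1L, round(l / dz_t))
  zs <- -l / 2 + (seq_len(n_row) - 0.5) * (l / n_row)
  rows <- purrr::map(seq_len(n_row), function(i) {
    offset <- if (i %% 2 == 0) 0.5 else 0
    th <- 2 * pi * (seq_len(n_col) - 1 + offset) / n_col
    tibble(x = r * cos(th), y = r * sin(th), z = zs[i])
  })
  sites <- dplyr::bind_rows(rows)
  a_circ <- 2 * pi * r / n_col
  dz <- l / n_row
  realized <- min(a_circ, sqrt((a_circ / 2)^2 + dz^2))
  area <- 2 * pi * r * l / nrow(sites)
  structure(
    list(sites = sites, spacing = spacing, realized_spacing = realized,
         area_per_site = area, n_col = n_col, n_row = n_row, geometry = geom),
    class = "anchor_lattice"
  )
}

#' @export
print.anchor_lattice <- function(x, ...) {
  cat(sprintf(
    "<anchor_lattice> %d sites (%d cols x %d rows), requested a = %g nm, realized %.2f nm, %.1f nm^2/site\n",
    nrow(x$sites), x$n_col, x$n_row, x$spacing, x$realized_spacing, x$area_per_site))
  invisible(x)
}

# grow one chain from its anchor as a non-overlapping random walk biased
# inward; checks committed beads via the shared hash grid and its own beads
# locally, so a failed growth leaves no trace in the grid
.grow_chain <- function(anchor, n_beads, bond_length, min_sep, geom, grid,
                        max_retry = 150L) {
  inward <- -c(anchor$x, anchor$y, 0) / sqrt(anchor$x^2 + anchor$y^2 + 1e-12)
  coords <- matrix(NA_real_, n_beads, 3)
  coords[1, ] <- c(anchor$x, anchor$y, anchor$z)
  r_max <- geom$diameter / 2
  hl <- geom$height / 2
  i <- 2L
  while (i <= n_beads) {
    placed <- FALSE
    for (tr in seq_len(max_retry)) {
      dir <- rnorm(3) + 0.25 * inward
      dir <- dir / sqrt(sum(dir^2))
      cand <- coords[i - 1L, ] + bond_length * dir
      rxy <- sqrt(cand[1]^2 + cand[2]^2)
      if (rxy > r_max - 0.3 && abs(cand[3]) < hl) next
      if (abs(cand[3]) > geom$box[3] / 2 - 1) next
      if (rxy > min(geom$box[1:2]) / 2 - 1) next
      if (!.grid_clear(grid, cand, min_sep)) next
      if (i > 2L) {
        prev <- coords[seq_len(i - 2L), , drop = FALSE]
        dd <- sweep(prev, 2, cand)
        if (min(rowSums(dd^2)) < min_sep^2) next
      }
      coords[i, ] <- cand
      placed <- TRUE
      break
    }
    if (!placed) return(NULL)
    i <- i + 1L
  }
  coords
}

# commit a grown chain's coordinates to the shared grid
.grid_commit <- function(grid, coords) {
  for (i in seq_len(nrow(coords))) .grid_add(grid, coords[i, ])
  invisible(NULL)
}

# simple hash-grid occupancy helpers (cell size = min_sep)
.grid_new <- function(cell) {
  e <- new.env(parent = emptyenv())
  e$cell <- cell
  e$tab <- new.env(parent = emptyenv())
  e
}
.grid_key <- function(g, p) paste(floor(p / g$cell), collapse = ",")
.grid_add <- function(g, p) {
  k <- .grid_key(g, p)
  g$tab[[k]] <- rbind(g$tab[[k]], p)
  invisible(NULL)
}
.grid_clear <- function(g, p, min_sep) {
  base <- floor(p / g$cell)
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    k <- paste(base + c(dx, dy, dz), collapse = ",")
    pts <- g$tab[[k]]
    if (!is.null(pts)) {
      dd <- sweep(pts, 2, p)
      if (any(rowSums(dd^2) < min_sep^2)) return(FALSE)
    }
  }
  TRUE
}

#' Assemble a grafted-pore system
#'
#' Builds the wall, grafts one copy of `seq` per anchor site as a
#' non-overlapping random walk growing inward from its anchor, and records the
#' chain topology. For C-terminally anchored sequences (Nsp1, Nsp1-S) the
#' anchored bead is the C-terminal residue. Reproducible for a given seed.
#'
#' @param geom a [pore_geometry()]
#' @param lattice an [anchor_lattice()] from [build_anchors()]
#' @param seq a [nup_sequence()] grafted at every site
#' @param seed RNG seed
#' @param min_separation minimum inter-bead distance at initialization, nm
#' @param max_restarts per-chain rebuild budget before failing
#' @return an object of class `pore_system`: `beads` tibble (chain, index,
#'   residue, mass, charge, lambda, diameter, x, y, z), `bonds` matrix,
#'   `tethers` (bead id + site), `wall` tibble, `geometry`, `sequence`
#' @export
assemble_system <- function(geom, lattice, seq, seed = 1,
                            min_separation = 0.32, max_restarts = 60L) {
  set.seed(seed)
  wall <- build_wall(geom)
  params <- bead_parameters()
  chars <- seq_chars(seq)
  n <- length(chars)
  # chain bead order: bead 1 = anchored terminus
  chain_codes <- if (seq$anchor_terminus == "C") rev(chars) else chars
  grid <- .grid_new(max(min_separation, 0.5))
  sites <- lattice$sites
  chains <- vector("list", nrow(sites))
  for (ci in seq_len(nrow(sites))) {
    site <- sites[ci, ]
    ok <- NULL
    for (attempt in seq_len(max_restarts)) {
      ok <- .grow_chain(site, n, 0.38, min_separation, geom, grid)
      if (!is.null(ok)) break
    }
    if (is.null(ok)) {
      abort(sprintf(
        "chain initialization failed at anchor %d after %d restarts (overcrowded geometry)",
        ci, max_restarts))
    }
    .grid_commit(grid, ok)
    chains[[ci]] <- ok
  }
  idx <- params$code
  lam <- setNames(params$lambda, idx)
  chg <- setNames(params$charge, idx)
  mas <- setNames(params$mass, idx)
  dia <- setNames(params$diameter, idx)
  beads <- dplyr::bind_rows(purrr::map(seq_len(nrow(sites)), function(ci) {
    tibble(
      chain = ci, index = seq_len(n), residue = chain_codes,
      mass = unname(mas[chain_codes]), charge = unname(chg[chain_codes]),
      lambda = unname(lam[chain_codes]), diameter = unname(dia[chain_codes]),
      x = chains[[ci]][, 1], y = chains[[ci]][, 2], z = chains[[ci]][, 3]
    )
  }))
  nb <- nrow(beads)
  per <- n
  bonds <- do.call(rbind, purrr::map(seq_len(nrow(sites)), function(ci) {
    off <- (ci - 1L) * per
    cbind(off + seq_len(per - 1L), off + seq_len(per - 1L) + 1L)
  }))
  tethers <- tibble(
    bead = (seq_len(nrow(sites)) - 1L) * per + 1L,
    x = sites$x, y = sites$y, z = sites$z
  )
  structure(
    list(beads = beads, bonds = bonds, tethers = tethers, wall = wall,
         geometry = geom, lattice = lattice, sequence = seq, seed = seed),
    class = "pore_system"
  )
}

#' @export
print.pore_system <- function(x, ...) {
  cat(sprintf(
    "<pore_system> %d chains x %d beads (%d chain beads, %d wall beads), d = %g nm\n",
    max(x$beads$chain), max(x$beads$index), nrow(x$beads), nrow(x$wall),
    x$geometry$diameter))
  invisible(x)
}

#' Assemble free chains in a box (no pore)
#'
#' Utility for single-chain and small-system simulations: places `n_chains`
#' copies of `seq` as random walks in the box, untethered.
#'
#' @param seq a [nup_sequence()]
#' @param box box dimensions, nm
#' @param n_chains number of copies
#' @param seed RNG seed
#' @param min_separation minimum inter-bead distance at initialization, nm
#' @return a `pore_system` without wall beads or tethers
#' @export
assemble_free_chain <- function(seq, box = c(30, 30, 30), n_chains = 1,
                                seed = 1, min_separation = 0.38) {
  set.seed(seed)
  params <- bead_parameters()
  chars <- seq_chars(seq)
  n <- length(chars)
  grid <- .grid_new(max(min_separation, 0.5))
  geom <- structure(list(diameter = Inf, height = 0, box = box,
                         wall_bead_diameter = 0), class = "pore_geometry")
  chains <- purrr::map(seq_len(n_chains), function(ci) {
    repeat {
      start <- (runif(3) - 0.5) * box * 0.3
      fake_anchor <- list(x = start[1], y = start[2], z = start[3])
      cc <- .grow_chain(fake_anchor, n, 0.38, min_separation,
                        list(diameter = Inf, height = 0, box = box), grid)
      if (!is.null(cc)) {
        .grid_commit(grid, cc)
        return(cc)
      }
    }
  })
  lam <- setNames(params$lambda, params$code)
  chg <- setNames(params$charge, params$code)
  mas <- setNames(params$mass, params$code)
  dia <- setNames(params$diameter, params$code)
  beads <- dplyr::bind_rows(purrr::map(seq_len(n_chains), function(ci) {
    tibble(
      chain = ci, index = seq_len(n), residue = chars,
      mass = unname(mas[chars]), charge = unname(chg[chars]),
      lambda = unname(lam[chars]), diameter = unname(dia[chars]),
      x = chains[[ci]][, 1], y = chains[[ci]][, 2], z = chains[[ci]][, 3]
    )
  }))
  bonds <- do.call(rbind, purrr::map(seq_len(n_chains), function(ci) {
    off <- (ci - 1L) * n
    cbind(off + seq_len(n - 1L), off + seq_len(n - 1L) + 1L)
  }))
  structure(
    list(beads = beads, bonds = bonds,
         tethers = tibble(bead = integer(), x = numeric(), y = numeric(),
                          z = numeric()),
         wall = tibble(x = numeric(), y = numeric(), z = numeric(),
                       diameter = numeric()),
         geometry = geom, lattice = NULL, sequence = seq, seed = seed),
    class = "pore_system"
  )
}
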