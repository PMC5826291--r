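# One-bead-per-amino-acid force field: per-residue bead parameters,
# hydrophobicity-scaled nonbonded attraction, screened electrostatics with a
# distance-dependent dielectric, bonded terms, and rigid cargo models.

# Fauchere-Pliska octanol-water partition energies (kcal/mol), used as the
# experimental partition scale behind the normalized hydrophobicity lambda.
.fp_partition <- c(
  A = 0.31, R = -1.01, N = -0.60, D = -0.77, C = 1.54,
  Q = -0.22, E = -0.64, G = 0.00, H = 0.13, I = 1.80,
  L = 1.70, K = -0.99, M = 1.23, F = 1.79, P = 0.72,
  S = -0.04, T = 0.26, W = 2.25, Y = 0.96, V = 1.22
)

.aa_charge <- c(
  A = 0, R = 1, N = 0, D = -1, C = 0, Q = 0, E = -1, G = 0, H = 0, I = 0,
  L = 0, K = 1, M = 0, F = 0, P = 0, S = 0, T = 0, W = 0, Y = 0, V = 0
)

#' Per-residue bead parameters
#'
#' One bead per amino acid, centred at the C-alpha position. Charges are the
#' integer charges at pH 7.4 (D, E = -1; K, R = +1; histidine neutral).
#' Hydrophobicity `lambda` is the Fauchere-Pliska experimental partition
#' energy renormalized to the range 0 (arginine) to 1 (tryptophan); this is a
#' reconstruction of the published scale, exposed so an alternative table can
#' be substituted. Masses are average residue masses; the excluded-volume
#' diameter defaults to 0.6 nm for every bead.
#'
#' @param diameter excluded-volume diameter applied to all beads, nm
#' @return tibble with columns `code`, `mass` (Da), `charge` (e), `lambda`,
#'   `diameter` (nm)
#' @export
bead_parameters <- function(diameter = 0.6) {
  codes <- names(.fp_partition)
  lam <- (.fp_partition - min(.fp_partition)) /
    (max(.fp_partition) - min(.fp_partition))
  tibble(
    code = codes,
    mass = unname(.aa_residue_mass[codes]),
    charge = unname(.aa_charge[codes]),
    lambda = unname(lam),
    diameter = diameter
  )
}

#' Inverse Debye screening length for a 1:1 electrolyte
#'
#' kappa = sqrt(2 NA e^2 I / (eps0 eps_r kB T)). 150 mM KCl at 298 K in water
#' (eps_r = 80) gives ~1.27 nm^-1.
#'
#' @param ionic_strength molar ionic strength, mol/L
#' @param temperature K
#' @param relative_permittivity bulk relative permittivity
#' @return kappa in nm^-1
#' @export
debye_constant <- function(ionic_strength, temperature = 298,
                           relative_permittivity = 80) {
  if (ionic_strength < 0) abort("ionic_strength must be >= 0")
  if (temperature <= 0) abort("temperature must be > 0")
  num <- 2 * .const$NA_mol * .const$e_C^2 * ionic_strength * 1000
  den <- .const$eps0_SI * relative_permittivity * .const$kB_SI * temperature
  sqrt(num / den) * 1e-9
}

#' Distance-dependent dielectric (sigmoidal saturation)
#'
#' Mehler-Solmajer-type sigmoid rising from low values at contact to the bulk
#' permittivity at large separation:
#' eps(r) = A + (eps_bulk - A) / (1 + k exp(-l B r)), B = eps_bulk - A.
#'
#' @param r separation, nm
#' @param eps_bulk bulk permittivity (default 80)
#' @param A,k,l sigmoid shape parameters (defaults follow the standard
#'   Mehler-Solmajer parameterization with r converted from Angstrom)
#' @return eps(r), dimensionless
#' @export
dielectric_sigmoid <- function(r, eps_bulk = 80, A = -8.5525, k = 7.7839,
                               l = 0.003627) {
  B <- eps_bulk - A
  A + B / (1 + k * exp(-l * B * (r * 10)))
}

# derivative of dielectric_sigmoid wrt r (nm)
.dielectric_sigmoid_deriv <- function(r, eps_bulk = 80, A = -8.5525,
                                      k = 7.7839, l = 0.003627) {
  B <- eps_bulk - A
  ex <- k * exp(-l * B * (r * 10))
  B * ex * (l * B * 10) / (1 + ex)^2
}

#' Coarse-grained force-field parameter set
#'
#' Bundles the bonded and nonbonded parameters of the one-bead model. Bonds
#' are stiff harmonic springs at 0.38 nm. Chain stiffness defaults to a
#' one-parameter Kratky-Porod bending term (`bend_k`); tabulated bending and
#' torsion potentials (energy versus angle/dihedral, linearly interpolated)
#' can be supplied via `angle_table`/`torsion_table` to drop in a published
#' parameterization, and an `angle_table` replaces the Kratky-Porod default. The nonbonded interaction is an
#' Ashbaugh-Hatch-type modified Lennard-Jones: a WCA repulsive core plus an
#' attractive well whose depth scales with the combined pair hydrophobicity
#' sqrt(lambda_i lambda_j) and vanishes for lambda = 0, smoothly switched to
#' zero at the cutoff. Electrostatics are Debye-screened Coulomb with the
#' distance-dependent dielectric of [dielectric_sigmoid()].
#'
#' @param bond_length equilibrium bond length, nm
#' @param bond_k bond spring constant, kJ/mol/nm^2
#' @param bend_k Kratky-Porod bending stiffness, kJ/mol: the default chain
#'   stiffness is `U = bend_k (1 + cos theta)` per bond angle (zero when the
#'   chain is straight), a one-parameter stand-in for Ramachandran-derived
#'   bending statistics, calibrated jointly with `epsilon0` against
#'   single-chain Stokes radii; `angle_table` overrides it when supplied
#' @param epsilon0 hydrophobic interaction strength, kJ/mol (calibrated so
#'   that single-chain Stokes radii of FG-domain segments reproduce the
#'   model's stated ~20% accuracy)
#' @param kappa inverse Debye length, nm^-1 (default 1.27, 150 mM KCl)
#' @param lj_cutoff_factor Lennard-Jones cutoff as a multiple of the pair
#'   diameter sigma_ij
#' @param coulomb_cutoff electrostatic cutoff, nm
#' @param switch_fraction switching starts at `switch_fraction * cutoff`
#' @param angle_table,torsion_table data frames with columns `angle` (deg) /
#'   `dihedral` (deg) and `energy` (kJ/mol); linearly interpolated
#' @param dielectric list of [dielectric_sigmoid()] parameters
#' @param min_separation smallest pair separation at which the potential is
#'   defined, nm
#' @return an object of class `force_field` (a list)
#' @export
force_field <- function(bond_length = 0.38,
                        bond_k = 8000,
                        bend_k = 4,
                        epsilon0 = 1.25,
                        kappa = 1.27,
                        lj_cutoff_factor = 2.5,
                        coulomb_cutoff = 2.5,
                        switch_fraction = 0.85,
                        angle_table = NULL,
                        torsion_table = NULL,
                        dielectric = list(eps_bulk = 80, A = -8.5525,
                                          k = 7.7839, l = 0.003627),
                        min_separation = 0.05) {
  if (kappa < 0) abort("kappa must be >= 0")
  structure(
    list(
      bond_length = bond_length, bond_k = bond_k, bend_k = bend_k,
      epsilon0 = epsilon0,
      kappa = kappa, lj_cutoff_factor = lj_cutoff_factor,
      coulomb_cutoff = coulomb_cutoff, switch_fraction = switch_fraction,
      angle_table = angle_table, torsion_table = torsion_table,
      dielectric = dielectric, min_separation = min_separation
    ),
    class = "force_field"
  )
}

# C2 switching function: 1 below r_on, 0 above r_off (quintic smoothstep)
.switch_fn <- function(r, r_on, r_off) {
  x <- pmin(pmax((r - r_on) / (r_off - r_on), 0), 1)
  1 - (10 * x^3 - 15 * x^4 + 6 * x^5)
}

.switch_fn_deriv <- function(r, r_on, r_off) {
  x <- (r - r_on) / (r_off - r_on)
  inside <- x > 0 & x < 1
  d <- numeric(length(r))
  d[inside] <- -(30 * x[inside]^2 - 60 * x[inside]^3 + 30 * x[inside]^4) / (r_off - r_on)
  d
}

# Ashbaugh-Hatch pair potential before switching; lam is sqrt(lambda_i lambda_j)
.ah_core <- function(r, sigma, lam, eps0) {
  sr6 <- (sigma / r)^6
  ulj <- 4 * eps0 * (sr6^2 - sr6)
  rmin <- 2^(1 / 6) * sigma
  ifelse(r <= rmin, ulj + (1 - lam) * eps0, lam * ulj)
}

.ah_core_deriv <- function(r, sigma, lam, eps0) {
  sr6 <- (sigma / r)^6
  dulj <- 4 * eps0 * (-12 * sr6^2 + 6 * sr6) / r
  rmin <- 2^(1 / 6) * sigma
  ifelse(r <= rmin, dulj, lam * dulj)
}

#' Nonbonded pair energy of the coarse-grained model
#'
#' Sum of (a) the excluded-volume plus hydrophobicity-scaled attraction and
#' (b) screened Coulomb `ke q_i q_j exp(-kappa r) / (eps(r) r)`, each smoothly
#' switched to zero at its cutoff. Beads are rows of [bead_parameters()] (or
#' any list with `charge`, `lambda`, `diameter`).
#'
#' @param bead_i,bead_j bead parameter rows
#' @param r separation(s), nm
#' @param ff a [force_field()]
#' @return energy in kJ/mol (vectorized over `r`)
#' @export
nonbonded_energy <- function(bead_i, bead_j, r, ff = force_field()) {
  if (any(r < ff$min_separation)) {
    abort(sprintf(
      "separation %.3g nm below the minimum %.3g nm for pair %s-%s",
      min(r), ff$min_separation,
      bead_i$code %||% "?", bead_j$code %||% "?"
    ))
  }
  sigma <- (bead_i$diameter + bead_j$diameter) / 2
  lam <- sqrt(bead_i$lambda * bead_j$lambda)
  rc <- ff$lj_cutoff_factor * sigma
  u_hp <- .ah_core(r, sigma, lam, ff$epsilon0) *
    .switch_fn(r, ff$switch_fraction * rc, rc)
  u_hp[r >= rc] <- 0
  qq <- bead_i$charge * bead_j$charge
  u_el <- 0
  if (qq != 0) {
    d <- ff$dielectric
    eps_r <- dielectric_sigmoid(r, d$eps_bulk, d$A, d$k, d$l)
    u_el <- .const$ke * qq * exp(-ff$kappa * r) / (eps_r * r) *
      .switch_fn(r, ff$switch_fraction * ff$coulomb_cutoff, ff$coulomb_cutoff)
    u_el[r >= ff$coulomb_cutoff] <- 0
  }
  u_hp + u_el
}

#' Analytic radial derivative of [nonbonded_energy()]
#'
#' The force on bead i is `-dU/dr` along the pair vector; used by the
#' integrator and validated against central differences in the test suite.
#'
#' @inheritParams nonbonded_energy
#' @return dU/dr in kJ/mol/nm
#' @export
nonbonded_energy_deriv <- function(bead_i, bead_j, r, ff = force_field()) {
  sigma <- (bead_i$diameter + bead_j$diameter) / 2
  lam <- sqrt(bead_i$lambda * bead_j$lambda)
  rc <- ff$lj_cutoff_factor * sigma
  s_on <- ff$switch_fraction * rc
  du_hp <- .ah_core_deriv(r, sigma, lam, ff$epsilon0) * .switch_fn(r, s_on, rc) +
    .ah_core(r, sigma, lam, ff$epsilon0) * .switch_fn_deriv(r, s_on, rc)
  du_hp[r >= rc] <- 0
  qq <- bead_i$charge * bead_j$charge
  du_el <- 0
  if (qq != 0) {
    d <- ff$dielectric
    eps_r <- dielectric_sigmoid(r, d$eps_bulk, d$A, d$k, d$l)
    deps <- .dielectric_sigmoid_deriv(r, d$eps_bulk, d$A, d$k, d$l)
    base <- .const$ke * qq * exp(-ff$kappa * r) / (eps_r * r)
    dbase <- base * (-ff$kappa - 1 / r - deps / eps_r)
    c_on <- ff$switch_fraction * ff$coulomb_cutoff
    du_el <- dbase * .switch_fn(r, c_on, ff$coulomb_cutoff) +
      base * .switch_fn_deriv(r, c_on, ff$coulomb_cutoff)
    du_el[r >= ff$coulomb_cutoff] <- 0
  }
  du_hp + du_el
}

# linear interpolation of a tabulated angular potential, periodic handling
# left to the table author; outside the table range the boundary value holds
.table_energy <- function(tab, x, xcol) {
  if (is.null(tab)) return(numeric(length(x)) * 0)
  approx(tab[[xcol]], tab$energy, xout = x, rule = 2)$y
}

#' Bonded energy of an ordered bead chain
#'
#' Harmonic bond terms plus tabulated bending and torsion contributions
#' (linear interpolation in the supplied tables; zero when no table is set).
#'
#' @param coords numeric matrix, one bead per row (x, y, z in nm), chain order
#' @param ff a [force_field()]
#' @return total bonded energy, kJ/mol
#' @export
bonded_energy <- function(coords, ff = force_field()) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n < 2L) abort("need at least two beads for bonded terms")
  dvec <- coords[-1, , drop = FALSE] - coords[-n, , drop = FALSE]
  blen <- sqrt(rowSums(dvec^2))
  if (any(blen < 1e-9)) abort("coincident bonded neighbours")
  e <- sum(0.5 * ff$bond_k * (blen - ff$bond_length)^2)
  if (is.null(ff$angle_table) && (ff$bend_k %||% 0) > 0 && n >= 3L) {
    u <- dvec[-(n - 1L), , drop = FALSE]
    v <- dvec[-1L, , drop = FALSE]
    ct <- rowSums(-u * v) / (sqrt(rowSums(u^2)) * sqrt(rowSums(v^2)))
    e <- e + sum(ff$bend_k * (1 + pmin(pmax(ct, -1), 1)))
  }
  if (!is.null(ff$angle_table) && n >= 3L) {
    ang <- vapply(seq_len(n - 2L), function(i) {
      v1 <- coords[i, ] - coords[i + 1, ]
      v2 <- coords[i + 2, ] - coords[i + 1, ]
      ct <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
      acos(pmin(pmax(ct, -1), 1)) * 180 / pi
    }, numeric(1))
    e <- e + sum(.table_energy(ff$angle_table, ang, "angle"))
  }
  if (!is.null(ff$torsion_table) && n >= 4L) {
    dih <- vapply(seq_len(n - 3L), function(i) {
      dihedral_angle(coords[i, ], coords[i + 1, ], coords[i + 2, ], coords[i + 3, ])
    }, numeric(1))
    e <- e + sum(.table_energy(ff$torsion_table, dih, "dihedral"))
  }
  e
}

#' Dihedral angle of four points
#'
#' Signed dihedral in degrees (IUPAC convention, atan2 formulation).
#'
#' @param p1,p2,p3,p4 numeric length-3 coordinates
#' @return angle in degrees in (-180, 180]
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  cross12 <- c(n1[2] * n2[3] - n1[3] * n2[2],
               n1[3] * n2[1] - n1[1] * n2[3],
               n1[1] * n2[2] - n1[2] * n2[1])
  atan2(sum(cross12 * b2) / sqrt(sum(b2^2)), sum(n1 * n2)) * 180 / pi
}

#' Deterministic quasi-uniform points on the unit sphere
#'
#' Fibonacci-lattice start refined by minimizing the inverse-distance
#' (Thomson) energy with L-BFGS; deterministic for a given `n`.
#'
#' @param n number of points
#' @return n x 3 matrix of unit vectors
#' @export
sphere_points <- function(n) {
  if (n == 0L) return(matrix(numeric(0), 0, 3))
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  x <- cbind(cos(theta) * sin(phi), sin(theta) * sin(phi), cos(phi))
  if (n < 2L) return(x)
  en <- function(p) {
    m <- matrix(p, ncol = 3)
    m <- m / sqrt(rowSums(m^2))
    d <- as.matrix(stats::dist(m))
    sum(1 / d[upper.tri(d)])
  }
  opt <- stats::optim(as.vector(x), en, method = "L-BFGS-B",
                      control = list(maxit = 200))
  m <- matrix(opt$par, ncol = 3)
  m / sqrt(rowSums(m^2))
}

#' Rigid cargo-particle model
#'
#' `"Kap95"` (nuclear transport receptor): sphere of radius 8.5 nm carrying 10
#' hydrophobic binding spots homogeneously distributed on the surface and a
#' total charge of -43 e spread homogeneously. `"tCherry"` (inert control):
#' sphere of radius 7.4 nm, no charge, no binding spots. A custom cargo is
#' built by supplying `radius`, `charge` and `n_hydro_sites`.
#'
#' @param kind `"Kap95"`, `"tCherry"`, or `"custom"`
#' @param radius,charge,n_hydro_sites custom cargo fields (nm, e, count)
#' @param site_strength hydrophobic binding-spot well depth, kJ/mol
#' @param site_lambda_threshold binding spots interact only with beads whose
#'   hydrophobicity lambda exceeds this threshold
#' @param mass cargo mass, Da
#' @return an object of class `cargo_model` with unit-sphere `sites`
#' @export
build_cargo <- function(kind = c("Kap95", "tCherry", "custom"),
                        radius = NULL, charge = NULL, n_hydro_sites = NULL,
                        site_strength = 12, site_lambda_threshold = 0.6,
                        mass = 1e5) {
  kind <- match.arg(kind)
  if (kind == "Kap95") {
    radius <- 8.5; charge <- -43; n_hydro_sites <- 10L
  } else if (kind == "tCherry") {
    radius <- 7.4; charge <- 0; n_hydro_sites <- 0L
  } else if (is.null(radius) || is.null(charge) || is.null(n_hydro_sites)) {
    abort("custom cargo needs radius, charge and n_hydro_sites")
  }
  if (radius <= 0) abort("cargo radius must be positive")
  structure(
    list(
      kind = kind, radius = radius, charge = charge,
      n_hydro_sites = as.integer(n_hydro_sites),
      sites = sphere_points(as.integer(n_hydro_sites)),
      site_strength = site_strength,
      site_lambda_threshold = site_lambda_threshold,
      mass = mass
    ),
    class = "cargo_model"
  )
}

#' @export
print.cargo_model <- function(x, ...) {
  cat(sprintf("<cargo_model> %s: R = %.1f nm, q = %+d e, %d hydrophobic sites\n",
              x$kind, x$radius, as.integer(x$charge), x$n_hydro_sites))
  invisible(x)
}
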