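# Density-based ionic conductance: local conductivity falling linearly with
# protein density, radial integration to pore/access conductivities, the
# pore + access-resistance conductance relation, parameter fitting and
# sigmoidal closed-form G(d) curves.

#' Density-based conductivity model
#'
#' Local ionic conductivity decreases in proportion to the local protein
#' density, `sigma(rho) = sigma_bare * max(0, 1 - rho/rho_crit)`, vanishing
#' at and beyond the critical density.
#'
#' @param sigma_bare bare-pore conductivity, nS/nm (default 2.2, 150 mM KCl)
#' @param rho_crit critical protein density, mg/ml (default 85)
#' @param height pore height l, nm
#' @return an object of class `conductivity_model`
#' @export
conductivity_model <- function(sigma_bare = 2.2, rho_crit = 85, height = 20) {
  if (sigma_bare <= 0 || rho_crit <= 0) {
    abort("sigma_bare and rho_crit must be positive")
  }
  structure(
    list(sigma_bare = sigma_bare, rho_crit = rho_crit, height = height),
    class = "conductivity_model"
  )
}

#' @export
print.conductivity_model <- function(x, ...) {
  cat(sprintf("<conductivity_model> sigma_bare = %g nS/nm, rho_crit = %g mg/ml, l = %g nm\n",
              x$sigma_bare, x$rho_crit, x$height))
  invisible(x)
}

#' Local conductivity at a protein density
#'
#' @param rho protein density, mg/ml (vectorized)
#' @param model a [conductivity_model()]
#' @return conductivity, nS/nm (clipped at zero beyond the critical density)
#' @export
local_conductivity <- function(rho, model = conductivity_model()) {
  model$sigma_bare * pmax(0, 1 - rho / model$rho_crit)
}

#' Region conductivity by radial integration
#'
#' `sigma_region = (4 / pi d^2) * integral_0^{d/2} 2 pi r sigma(r) dr`,
#' evaluated by trapezoidal quadrature on the profile's radial grid (exact
#' for piecewise-linear profiles). The same operation serves the pore
#' (-10 < z < 10 nm) and access (10 < |z| < 40 nm) windows.
#'
#' @param profile a `radial_profile` or a data frame with columns `r`,
#'   `density`
#' @param model a [conductivity_model()]
#' @param diameter pore diameter d, nm
#' @return region conductivity, nS/nm
#' @export
region_conductivity <- function(profile, model = conductivity_model(),
                                diameter = NULL) {
  df <- if (inherits(profile, "radial_profile")) profile$profile else profile
  if (is.null(diameter)) abort("diameter must be supplied")
  half <- diameter / 2
  if (max(df$r) < half - 0.51) {
    abort(sprintf("profile extends to r = %.2f nm but d/2 = %.2f nm", max(df$r), half))
  }
  r_grid <- sort(unique(c(df$r[df$r <= half], half, 0)))
  rho <- approx(c(0, df$r), c(df$density[1], df$density), xout = r_grid, rule = 2)$y
  sig <- local_conductivity(rho, model)
  integrand <- 2 * pi * r_grid * sig
  int <- sum(diff(r_grid) * (utils::head(integrand, -1) + utils::tail(integrand, -1)) / 2)
  (4 / (pi * diameter^2)) * int
}

#' Total pore conductance from pore and access conductivities
#'
#' `G = [4 l / (pi d^2 sigma_pore) + 1 / (d sigma_access)]^-1`: the first
#' term is the pore (channel) resistance, the second the access resistance of
#' the solution flanking the pore. With `sigma_pore = sigma_access =
#' sigma_bare` this is the bare-pore relation.
#'
#' @param sigma_pore,sigma_access conductivities, nS/nm
#' @param diameter pore diameter, nm
#' @param height pore height l, nm
#' @return conductance in nS (0 when either conductivity is 0)
#' @export
total_conductance <- function(sigma_pore, sigma_access, diameter, height = 20) {
  if (any(diameter <= 0)) abort("diameter must be positive")
  if (any(sigma_pore < 0) || any(sigma_access < 0)) abort("conductivities must be >= 0")
  n <- max(length(sigma_pore), length(sigma_access), length(diameter))
  sp <- rep_len(sigma_pore, n)
  sa <- rep_len(sigma_access, n)
  d <- rep_len(diameter, n)
  out <- numeric(n)
  ok <- sp > 0 & sa > 0
  out[ok] <- 1 / (4 * height / (pi * d[ok]^2 * sp[ok]) + 1 / (d[ok] * sa[ok]))
  out
}

#' Bare-pore conductance (uniform conductivity)
#'
#' @param diameter pore diameter, nm (vectorized)
#' @param sigma_bare bulk conductivity, nS/nm
#' @param height pore height, nm
#' @return conductance, nS
#' @export
bare_conductance <- function(diameter, sigma_bare = 2.2, height = 20) {
  total_conductance(sigma_bare, sigma_bare, diameter, height)
}

#' Predict conductance from a density grid
#'
#' Convenience wrapper: radial profiles over the pore and access windows,
#' region conductivities, then the total conductance.
#'
#' @param grid a `density_grid`
#' @param diameter pore diameter, nm
#' @param model a [conductivity_model()]
#' @return one-row tibble: `diameter`, `sigma_pore`, `sigma_access`, `G`
#' @export
predict_conductance <- function(grid, diameter, model = conductivity_model()) {
  pp <- radial_profile(grid, "pore")
  pa <- radial_profile(grid, "access")
  sp <- region_conductivity(pp, model, diameter)
  sa <- region_conductivity(pa, model, diameter)
  tibble(diameter = diameter, sigma_pore = sp, sigma_access = sa,
         G = total_conductance(sp, sa, diameter, model$height))
}

#' Fit the conductivity model to conductance data
#'
#' Two-stage least squares following the experimental procedure: `sigma_bare`
#' from bare-pore G(d) data (linear in sigma, closed-form estimate with a
#' standard error), then `rho_crit` from coated-pore G(d) data plus the
#' per-diameter density profiles (1D least squares).
#'
#' @param bare_data data frame with `diameter` (nm), `G` (nS) for bare pores
#' @param coated_data optional data frame with `diameter`, `G` for coated
#'   pores
#' @param profiles optional named list: for each coated diameter (name =
#'   diameter) a list with elements `pore` and `access` radial profiles
#' @param height pore height, nm
#' @param rho_interval search interval for rho_crit, mg/ml
#' @return a `conductivity_fit` object (also a valid `conductivity_model`)
#'   with elements `sigma_bare`, `sigma_bare_se`, `rho_crit`, `rho_crit_se`,
#'   `residuals`
#' @export
fit_conductivity <- function(bare_data, coated_data = NULL, profiles = NULL,
                             height = 20, rho_interval = c(10, 500)) {
  if (length(unique(bare_data$diameter)) < 3L) {
    abort("need at least 3 distinct diameters to fit sigma_bare")
  }
  # G = sigma * a(d), a(d) = [4l/(pi d^2) + 1/d]^-1  => linear regression
  a <- 1 / (4 * height / (pi * bare_data$diameter^2) + 1 / bare_data$diameter)
  fit <- lm(G ~ 0 + a, data = data.frame(G = bare_data$G, a = a))
  sigma_bare <- unname(coef(fit)[1])
  sigma_se <- unname(sqrt(diag(stats::vcov(fit)))[1])
  rho_crit <- NA_real_; rho_se <- NA_real_; resids <- NULL
  if (!is.null(coated_data)) {
    if (is.null(profiles)) abort("profiles are required to fit rho_crit")
    ssr <- function(rc) {
      mod <- conductivity_model(sigma_bare, rc, height)
      gpred <- vapply(seq_len(nrow(coated_data)), function(i) {
        d <- coated_data$diameter[i]
        pr <- profiles[[as.character(d)]]
        sp <- region_conductivity(pr$pore, mod, d)
        sa <- region_conductivity(pr$access, mod, d)
        total_conductance(sp, sa, d, height)
      }, numeric(1))
      sum((gpred - coated_data$G)^2)
    }
    opt <- optimize(ssr, rho_interval)
    rho_crit <- opt$minimum
    # curvature-based standard error
    h <- max(1, rho_crit * 1e-3)
    d2 <- (ssr(rho_crit + h) - 2 * opt$objective + ssr(rho_crit - h)) / h^2
    n <- nrow(coated_data)
    s2 <- opt$objective / max(n - 1, 1)
    rho_se <- if (d2 > 0) sqrt(2 * s2 / d2) else NA_real_
    mod <- conductivity_model(sigma_bare, rho_crit, height)
    resids <- vapply(seq_len(nrow(coated_data)), function(i) {
      d <- coated_data$diameter[i]
      pr <- profiles[[as.character(d)]]
      total_conductance(
        region_conductivity(pr$pore, mod, d),
        region_conductivity(pr$access, mod, d), d, height) - coated_data$G[i]
    }, numeric(1))
  }
  structure(
    list(sigma_bare = sigma_bare, sigma_bare_se = sigma_se,
         rho_crit = rho_crit, rho_crit_se = rho_se, height = height,
         residuals = resids, n_bare = nrow(bare_data),
         n_coated = if (is.null(coated_data)) 0L else nrow(coated_data)),
    class = c("conductivity_fit", "conductivity_model")
  )
}

#' @export
print.conductivity_fit <- function(x, ...) {
  cat(sprintf("<conductivity_fit> sigma_bare = %.3f +/- %.3f nS/nm",
              x$sigma_bare, x$sigma_bare_se))
  if (!is.na(x$rho_crit)) {
    cat(sprintf(", rho_crit = %.1f +/- %.1f mg/ml", x$rho_crit, x$rho_crit_se))
  }
  cat("\n")
  invisible(x)
}

# 4-parameter logistic in d, bounded in [0, upper]
.sigmoid4 <- function(d, lo, hi, d0, s) lo + (hi - lo) / (1 + exp(-(d - d0) / s))

#' Fit sigmoidal conductivity-versus-diameter curves
#'
#' Fits 4-parameter logistic functions to pore and access conductivities as a
#' function of diameter, bounded to [0, sigma_bare], for use in the
#' closed-form G(d) curve.
#'
#' @param data data frame with columns `diameter`, `sigma_pore`,
#'   `sigma_access` (e.g. rows of [predict_conductance()])
#' @param sigma_bare upper bound, nS/nm
#' @return object of class `sigmoid_fit`: fitted parameter lists and
#'   residuals for both curves
#' @export
fit_sigmoid_conductivity <- function(data, sigma_bare = 2.2) {
  fit_one <- function(y) {
    d <- data$diameter
    resid_fn <- function(p) {
      .sigmoid4(d, p["lo"], p["hi"], p["d0"], p["s"]) - y
    }
    st <- c(lo = max(min(y), 1e-3), hi = max(y), d0 = mean(d),
            s = diff(range(d)) / 4)
    fit <- minpack.lm::nls.lm(
      par = st, fn = resid_fn,
      lower = c(0, 0, 0, 0.1), upper = c(sigma_bare, sigma_bare, 1000, 1000),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    )
    list(par = as.list(fit$par), residuals = -resid_fn(fit$par))
  }
  fp <- fit_one(data$sigma_pore)
  fa <- fit_one(data$sigma_access)
  structure(
    list(pore = fp$par, access = fa$par,
         residuals = tibble(diameter = data$diameter,
                            pore = as.numeric(fp$residuals),
                            access = as.numeric(fa$residuals)),
         sigma_bare = sigma_bare,
         d_range = range(data$diameter)),
    class = "sigmoid_fit"
  )
}

#' Closed-form conductance curve from sigmoid fits
#'
#' Substitutes the fitted sigmoidal conductivities into the conductance
#' relation to obtain a continuous G(d): near-zero below the threshold
#' diameter, near-linear above it.
#'
#' @param fits a `sigmoid_fit`
#' @param diameters evaluation diameters, nm
#' @param height pore height, nm
#' @return tibble of class `conductance_curve`: `diameter`, `sigma_pore`,
#'   `sigma_access`, `G`, `extrapolated`
#' @export
closed_form_curve <- function(fits, diameters, height = 20) {
  sp <- do.call(.sigmoid4, c(list(d = diameters), fits$pore))
  sa <- do.call(.sigmoid4, c(list(d = diameters), fits$access))
  extra <- diameters < fits$d_range[1] | diameters > fits$d_range[2]
  if (any(extra)) {
    warn(sprintf("%d diameters outside the fitted range [%g, %g] nm (extrapolation)",
                 sum(extra), fits$d_range[1], fits$d_range[2]))
  }
  out <- tibble(
    diameter = diameters, sigma_pore = sp, sigma_access = sa,
    G = total_conductance(sp, sa, diameters, height),
    extrapolated = extra
  )
  class(out) <- c("conductance_curve", class(out))
  out
}

#' Threshold diameter of a conductance curve
#'
#' Smallest diameter at which G(d) crosses the stated conductance level
#' (default 4 nS, the level separating the low- and high-conductance regimes).
#'
#' @param curve a `conductance_curve` (or tibble with `diameter`, `G`)
#' @param level conductance level, nS
#' @return threshold diameter, nm (linear interpolation; NA if never crossed)
#' @export
threshold_diameter <- function(curve, level = 4) {
  o <- curve[order(curve$diameter), ]
  above <- which(o$G >= level)
  if (length(above) == 0L || above[1] == 1L) {
    return(if (length(above) == 0L) NA_real_ else o$diameter[1])
  }
  i <- above[1]
  approx(o$G[c(i - 1, i)], o$diameter[c(i - 1, i)], xout = level)$y
}
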