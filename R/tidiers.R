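# broom-style tidiers for fitted objects.

#' @export
tidy.conductivity_fit <- function(x, ...) {
  out <- tibble(
    term = "sigma_bare", estimate = x$sigma_bare, std.error = x$sigma_bare_se
  )
  if (!is.na(x$rho_crit)) {
    out <- dplyr::bind_rows(out, tibble(
      term = "rho_crit", estimate = x$rho_crit, std.error = x$rho_crit_se
    ))
  }
  out
}

#' @export
glance.conductivity_fit <- function(x, ...) {
  tibble(
    n_bare = x$n_bare, n_coated = x$n_coated,
    rss_coated = if (is.null(x$residuals)) NA_real_ else sum(x$residuals^2)
  )
}

#' @export
tidy.sigmoid_fit <- function(x, ...) {
  dplyr::bind_rows(
    tibble(region = "pore", term = names(x$pore),
           estimate = unlist(x$pore)),
    tibble(region = "access", term = names(x$access),
           estimate = unlist(x$access))
  )
}

#' @export
tidy.pmf_curve <- function(x, ...) x$profile

#' @export
glance.pmf_curve <- function(x, ...) {
  tibble(
    barrier = pmf_barrier(x), n_bins = nrow(x$profile),
    converged = x$converged, iterations = x$iterations,
    temperature = x$temperature
  )
}

#' @export
tidy.event_stats <- function(x, ...) {
  tibble(
    term = c("meanlog", "sdlog", "dwell_mean", "dwell_sd",
             "blockade_mean", "blockade_sd", "rate"),
    estimate = c(x$meanlog, x$sdlog, x$dwell_mean, x$dwell_sd,
                 x$blockade_mean, x$blockade_sd, x$rate)
  )
}

#' @export
glance.grafting_estimate <- function(x, ...) as_tibble(unclass(x))
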