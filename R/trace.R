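# Nanopore current-trace analytics: two-threshold event detection on a
# moving-baseline estimate, log-normal dwell-time statistics, event rates,
# and a power-spectral-density utility for 1/f noise characterization.

#' Construct a current trace
#'
#' @param time sample times, s (uniform)
#' @param current current, nA
#' @param voltage applied voltage, mV
#' @return tibble of class `current_trace` with attributes `voltage` (mV) and
#'   `sampling_rate` (Hz)
#' @export
current_trace <- function(time, current, voltage) {
  if (length(time) != length(current)) abort("time and current lengths differ")
  if (any(!is.finite(current))) abort("non-finite current values")
  dt <- diff(time)
  if (length(dt) > 0 && (max(dt) - min(dt)) > 1e-6 * stats::median(dt)) {
    abort("sampling is not uniform")
  }
  out <- tibble(time = time, current = current)
  class(out) <- c("current_trace", class(out))
  attr(out, "voltage") <- voltage
  attr(out, "sampling_rate") <- if (length(dt) > 0) 1 / stats::median(dt) else NA_real_
  out
}

#' Read a two-column delimited current trace
#'
#' @param path file with columns time (s) and current (nA); `#` comments
#'   allowed
#' @param voltage applied voltage, mV
#' @param ... passed to [utils::read.table()]
#' @return a [current_trace()]
#' @export
read_trace <- function(path, voltage, ...) {
  df <- utils::read.table(path, col.names = c("time", "current"),
                          comment.char = "#", ...)
  current_trace(df$time, df$current, voltage)
}

#' Detect translocation events in a current trace
#'
#' Two-threshold scheme on a moving-baseline estimate: the baseline is a
#' running median, the noise scale is the MAD of the residual, an event
#' starts where the current drops below `threshold` noise units and extends
#' outward to the `exit_threshold` crossings. Each downward spike yields a
#' dwell time tau (exit-threshold crossing width) and conductance blockade
#' dG = dI / V. Events separated by less than `min_duration` merge.
#'
#' @param trace a [current_trace()]
#' @param baseline_window running-median window, s
#' @param threshold entry threshold in baseline-noise sigma units
#' @param exit_threshold exit threshold in sigma units (default half the
#'   entry threshold)
#' @param min_duration minimum event duration, s
#' @return tibble of class `event_table`: `start` (s), `dwell` (s),
#'   `blockade` (nS), `peak_amplitude` (nA); attribute `duration` (s)
#' @export
detect_events <- function(trace, baseline_window = 0.5, threshold = 5,
                          exit_threshold = threshold / 2,
                          min_duration = 5e-5) {
  v <- attr(trace, "voltage")
  if (is.null(v) || v == 0) abort("zero or missing voltage: blockade dG undefined")
  fs <- attr(trace, "sampling_rate")
  n <- nrow(trace)
  if (baseline_window * fs >= n) abort("trace shorter than the baseline window")
  # the baseline varies on the (slow) 1/f scale: estimate the running median
  # on a decimated copy and interpolate back, which is robust to the (sparse,
  # fast) events and much cheaper than a full-rate running median
  dec <- max(1L, floor(baseline_window * fs / 400))
  idx <- seq(1L, n, by = dec)
  kd <- min(2L * floor(baseline_window * fs / dec / 2) + 1L,
            2L * floor((length(idx) - 1) / 2) + 1L)
  if (kd < 3L) abort("trace shorter than the baseline window")
  base_dec <- runmed(trace$current[idx], kd, endrule = "median")
  base <- approx(idx, base_dec, xout = seq_len(n), rule = 2)$y
  resid <- trace$current - base
  sigma <- mad(resid)
  below_entry <- resid < -threshold * sigma
  below_exit <- resid < -exit_threshold * sigma
  if (!any(below_entry)) {
    out <- tibble(start = numeric(), dwell = numeric(), blockade = numeric(),
                  peak_amplitude = numeric())
    class(out) <- c("event_table", class(out))
    attr(out, "duration") <- n / fs
    return(out)
  }
  # contiguous runs below the exit threshold that contain an entry crossing
  r <- rle(below_exit)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- tibble(start = starts[r$values], end = ends[r$values])
  runs <- runs |>
    mutate(has_entry = purrr::map2_lgl(.data$start, .data$end,
                                       ~ any(below_entry[.x:.y]))) |>
    filter(.data$has_entry)
  if (nrow(runs) > 1L) {
    gap_samples <- max(1L, round(min_duration * fs))
    merged <- list()
    cur <- runs[1, ]
    for (i in seq_len(nrow(runs))[-1]) {
      if (runs$start[i] - cur$end <= gap_samples) {
        cur$end <- runs$end[i]
      } else {
        merged[[length(merged) + 1L]] <- cur
        cur <- runs[i, ]
      }
    }
    merged[[length(merged) + 1L]] <- cur
    runs <- dplyr::bind_rows(merged)
  }
  ev <- runs |>
    mutate(
      n_samp = .data$end - .data$start + 1L,
      dwell = .data$n_samp / fs,
      start_t = trace$time[.data$start],
      depth = purrr::map2_dbl(.data$start, .data$end,
                              ~ -median(resid[.x:.y])),
      peak = purrr::map2_dbl(.data$start, .data$end, ~ -min(resid[.x:.y]))
    ) |>
    filter(.data$dwell >= min_duration, .data$depth > 0)
  out <- tibble(
    start = ev$start_t,
    dwell = ev$dwell,
    blockade = ev$depth / (abs(v) / 1000),  # nA / V -> nS
    peak_amplitude = ev$peak
  )
  class(out) <- c("event_table", class(out))
  attr(out, "duration") <- n / fs
  attr(out, "noise_sigma") <- sigma
  out
}

#' Log-normal dwell-time statistics
#'
#' Maximum-likelihood log-normal fit of the dwell times (the MLE of meanlog
#' and sdlog are the mean and the sd of the log dwell times) with the
#' linear-scale mean and standard deviation derived from the fitted
#' parameters, plus blockade statistics and the event frequency.
#'
#' @param events an `event_table` from [detect_events()]
#' @param duration analyzed duration, s (defaults to the table's attribute)
#' @return one-row tibble of class `event_stats`: `n_events`, `meanlog`,
#'   `sdlog`, `dwell_mean`, `dwell_sd` (s), `blockade_mean`, `blockade_sd`
#'   (nS), `rate` (Hz), `rate_se`
#' @export
dwell_lognormal_fit <- function(events, duration = NULL) {
  duration <- duration %||% attr(events, "duration")
  if (any(events$dwell <= 0)) abort("non-positive dwell times")
  n <- nrow(events)
  if (n < 20L) warn(sprintf("only %d events: dwell fit is poorly determined", n))
  lt <- log(events$dwell)
  mu <- mean(lt)
  sig <- sqrt(mean((lt - mu)^2)) # MLE (1/n)
  out <- tibble(
    n_events = n,
    meanlog = mu,
    sdlog = sig,
    dwell_mean = exp(mu + sig^2 / 2),
    dwell_sd = exp(mu + sig^2 / 2) * sqrt(exp(sig^2) - 1),
    blockade_mean = mean(events$blockade),
    blockade_sd = sd(events$blockade),
    rate = n / duration,
    rate_se = sqrt(n) / duration
  )
  class(out) <- c("event_stats", class(out))
  out
}

#' Event frequency with Poisson standard error
#'
#' @param events an `event_table` (or anything with `nrow`)
#' @param duration analyzed duration, s
#' @return one-row tibble: `n_events`, `duration`, `rate` (Hz), `rate_se`
#' @export
event_rate <- function(events, duration = NULL) {
  duration <- duration %||% attr(events, "duration")
  if (is.null(duration) || duration <= 0) abort("duration must be positive")
  n <- nrow(events)
  tibble(n_events = n, duration = duration, rate = n / duration,
         rate_se = sqrt(n) / duration)
}

#' Power spectral density of a current trace
#'
#' Periodogram with optional log-binned averaging; the low-frequency slope of
#' log PSD vs log f characterizes 1/f noise (slope approximately -1).
#'
#' @param trace a [current_trace()]
#' @param f_range frequency range for the slope fit, Hz
#' @return list: `psd` tibble (`frequency` Hz, `power` nA^2/Hz), `slope`
#'   (log-log slope over `f_range`)
#' @export
trace_psd <- function(trace, f_range = c(1, 100)) {
  fs <- attr(trace, "sampling_rate")
  sp <- spec.pgram(stats::ts(trace$current, frequency = fs), taper = 0,
                   plot = FALSE, detrend = TRUE)
  psd <- tibble(frequency = as.numeric(sp$freq), power = as.numeric(sp$spec))
  sel <- psd$frequency >= f_range[1] & psd$frequency <= f_range[2] & psd$power > 0
  slope <- NA_real_
  if (sum(sel) > 5) {
    slope <- unname(coef(lm(log10(power) ~ log10(frequency), data = psd[sel, ]))[2])
  }
  list(psd = psd, slope = slope)
}
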