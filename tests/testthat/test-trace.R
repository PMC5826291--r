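# Current-trace analytics: event detection contracts, log-normal dwell fits,
# rates, PSD, and the grafting/Sauerbrey arithmetic.

test_that("flat noisy trace yields no events at a 6-sigma threshold", {
  set.seed(1)
  n <- 5e5
  tr <- current_trace(seq_len(n) / 5e4, 7 + rnorm(n, 0, 0.003), voltage = 100)
  ev <- detect_events(tr, baseline_window = 0.2, threshold = 6)
  expect_equal(nrow(ev), 0)
  expect_equal(attr(ev, "duration"), 10)
  expect_error(detect_events(current_trace(1:100 / 1e3, rnorm(100), 0)),
               "voltage")
})

test_that("injected events at SNR 8 are recovered with unbiased statistics", {
  # 100 fixed-size events on a white-noise baseline, depth = 8 sigma
  set.seed(5)
  fs <- 5e4
  sigma <- 0.003
  sp <- trace_spec(duration = 60, sampling_rate = fs, rate = 100 / 60,
                   dwell_mean = 0.5e-3, dwell_sd = 0.12e-3,
                   blockade_mean = 8 * sigma / 0.1, blockade_sd = 1e-6,
                   noise_sd = sigma, onef_amplitude = 0)
  res <- gen_trace(sp, seed = 5)
  n_true <- nrow(res$truth)
  expect_gt(n_true, 80)
  ev <- detect_events(res$trace, baseline_window = 0.2, threshold = 5,
                      min_duration = 1e-4)
  expect_gte(nrow(ev), 0.95 * n_true)
  expect_lte(nrow(ev), 1.02 * n_true)
  st <- dwell_lognormal_fit(ev)
  expect_equal(st$dwell_mean, mean(res$truth$dwell), tolerance = 0.1)
  expect_equal(st$blockade_mean, mean(res$truth$blockade), tolerance = 0.1)
  # detection is invariant to a baseline offset
  tr2 <- res$trace
  tr2$current <- tr2$current + 3
  attr(tr2, "voltage") <- 100; attr(tr2, "sampling_rate") <- fs
  class(tr2) <- class(res$trace)
  ev2 <- detect_events(tr2, baseline_window = 0.2, threshold = 5,
                       min_duration = 1e-4)
  expect_equal(nrow(ev2), nrow(ev))
  expect_equal(ev2$blockade, ev$blockade, tolerance = 1e-8)
  # blockade dG scales inversely with voltage for the same current dip
  tr3 <- res$trace
  attr(tr3, "voltage") <- 200
  ev3 <- detect_events(tr3, baseline_window = 0.2, threshold = 5,
                       min_duration = 1e-4)
  expect_equal(median(ev3$blockade), median(ev$blockade) / 2, tolerance = 0.02)
})

test_that("events merging closer than the minimum duration is documented behaviour", {
  # two dips separated by less than min_duration merge into one event
  fs <- 5e4
  n <- 1e5
  cur <- rep(7, n)
  cur[50000:50010] <- 6.5
  cur[50012:50022] <- 6.5  # 1-sample gap << min_duration
  set.seed(2)
  cur <- cur + rnorm(n, 0, 0.002)
  tr <- current_trace(seq_len(n) / fs, cur, 100)
  ev <- detect_events(tr, baseline_window = 0.2, threshold = 5,
                      min_duration = 2e-4)
  expect_equal(nrow(ev), 1)
  expect_gt(ev$dwell, 20 / fs)
})

test_that("log-normal dwell fit is the closed-form MLE", {
  set.seed(3)
  x <- rlnorm(500, meanlog = log(2.9e-4), sdlog = 0.5)
  ev <- tibble::tibble(start = seq_along(x), dwell = x, blockade = 0.2,
                       peak_amplitude = 0.02)
  class(ev) <- c("event_table", class(ev))
  attr(ev, "duration") <- 100
  st <- dwell_lognormal_fit(ev)
  expect_equal(st$meanlog, mean(log(x)))
  expect_equal(st$sdlog, sqrt(mean((log(x) - mean(log(x)))^2)))
  # agrees with an independent ML fitter
  fd <- fitdistrplus::fitdist(x, "lnorm")
  expect_equal(st$meanlog, unname(coef(fd)["meanlog"]), tolerance = 1e-4)
  expect_equal(st$sdlog, unname(coef(fd)["sdlog"]), tolerance = 1e-3)
  # linear-scale moments of the fitted law
  expect_equal(st$dwell_mean, exp(st$meanlog + st$sdlog^2 / 2))
  # degenerate case: identical dwell times
  ev2 <- ev; ev2$dwell <- rep(2e-4, 500)
  st2 <- dwell_lognormal_fit(ev2)
  expect_equal(st2$sdlog, 0)
  expect_equal(st2$dwell_mean, 2e-4)
  expect_equal(st2$dwell_sd, 0)
  ev3 <- ev; ev3$dwell[1] <- -1
  expect_error(dwell_lognormal_fit(ev3), "non-positive")
})

test_that("event rate: count over duration with Poisson error", {
  ev <- tibble::tibble(start = 1:170, dwell = 1e-3, blockade = 0.2,
                       peak_amplitude = 1)
  r <- event_rate(ev, duration = 100)
  expect_equal(r$rate, 1.7)
  expect_equal(r$rate_se, sqrt(170) / 100)
  expect_equal(event_rate(ev[0, ], 10)$rate, 0)
  # Poisson coverage: estimate within 2 SE in ~95% of seeds
  set.seed(9)
  lam <- 3; dur <- 50
  hits <- vapply(1:200, function(i) {
    k <- rpois(1, lam * dur)
    abs(k / dur - lam) <= 2 * sqrt(max(k, 1)) / dur
  }, logical(1))
  expect_gt(mean(hits), 0.9)
})

test_that("PSD of synthesized 1/f noise has slope near -1", {
  sp <- trace_spec(duration = 20, sampling_rate = 2e4, rate = 0,
                   noise_sd = 0, onef_amplitude = 0.01, onef_alpha = 1)
  res <- gen_trace(sp, seed = 8)
  expect_equal(nrow(res$truth), 0)
  ps <- trace_psd(res$trace, f_range = c(1, 50))
  expect_equal(ps$slope, -1, tolerance = 0.2)
})

test_that("grafting arithmetic reproduces the published estimates", {
  g <- grafting_from_conductance(70, 12, 0.54, radius = 24, height = 20,
                                 mw = 65700)
  expect_equal(g$count, 107)
  expect_equal(g$area_per_protein, 28, tolerance = 0.02)
  expect_equal(g$spacing, 5.7, tolerance = 0.02)
  expect_equal(g$density, 320, tolerance = 0.02)
  g2 <- grafting_from_conductance(70.3, 34.6, 0.34, radius = 25, height = 20,
                                  mw = 65700)
  expect_equal(g2$count, 105)
  expect_equal(g2$spacing, 5.9, tolerance = 0.02)
  expect_error(grafting_from_conductance(50, 50, 0.5), "exceed")
  expect_error(grafting_from_conductance(50, 20, 0), "positive")
})

test_that("Sauerbrey conventions and lattice geometry", {
  # zero shift -> zero mass; linear in |df|
  expect_error(sauerbrey_spacing(10), "negative frequency")
  s1 <- sauerbrey_spacing(-30)
  s2 <- sauerbrey_spacing(-60)
  expect_equal(s2$areal_mass, 2 * s1$areal_mass)
  # the published spacing (5.6 +/- 0.2 nm for df = -60 Hz) is approached
  # only by the multiply-by-overtone convention with a square lattice
  sq <- sauerbrey_spacing(-60, overtone = 3, mw = 65700, lattice = "square",
                          convention = "times_overtone")
  expect_equal(sq$spacing, 5.6, tolerance = 0.06)
  # the standard per-overtone convention gives a far larger spacing
  pv <- sauerbrey_spacing(-60, overtone = 3, mw = 65700, lattice = "square",
                          convention = "per_overtone")
  expect_gt(pv$spacing, 3 * sq$spacing)
  expect_error(sauerbrey_spacing(-60, mw = 0), "positive")
})
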