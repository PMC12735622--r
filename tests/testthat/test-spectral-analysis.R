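test_that("single-component EM equals the closed-form sample moments", {
  set.seed(2)
  x <- stats::rnorm(200, mean = 480, sd = 22)
  bg <- em_background_fit(x, k = 1)
  expect_equal(bg$means, mean(x), tolerance = 1e-12)
  expect_equal(bg$variances, mean((x - mean(x))^2), tolerance = 1e-12)
  expect_identical(bg$weights, 1)
  expect_true(bg$converged)
  expect_equal(bg$background_level, mean(x), tolerance = 1e-12)
})

test_that("EM recovers a well-separated two-component mixture within 1%", {
  set.seed(6)
  x <- c(stats::rnorm(5000, 100, 5), stats::rnorm(5000, 1000, 20))
  bg <- em_background_fit(x, k = 2)
  mu <- sort(bg$means)
  expect_lt(abs(mu[1] - 100) / 100, 0.01)
  expect_lt(abs(mu[2] - 1000) / 1000, 0.01)
  expect_equal(sum(bg$weights), 1, tolerance = 1e-9)
  expect_true(all(bg$weights > 0 & bg$weights < 1))
  expect_true(bg$converged)
  expect_equal(bg$background_level, mu[1], tolerance = 1e-9)
  # log-likelihood trace is non-decreasing at every iteration (EM guarantee)
  expect_true(all(diff(bg$loglik_trace) >= -1e-8 * abs(bg$loglik)))
})

test_that("EM agrees with an independent mixture fitter on the same data", {
  library(mclust)  # Mclust needs its namespace attached
  set.seed(14)
  x <- c(stats::rnorm(3000, 200, 10), stats::rnorm(7000, 900, 30))
  bg <- em_background_fit(x, k = 2)
  mc <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(sort(bg$means), sort(as.numeric(mc$parameters$mean)),
               tolerance = 1e-3)
  expect_equal(sort(bg$weights), sort(as.numeric(mc$parameters$pro)),
               tolerance = 0.01)
})

test_that("EM input contracts are enforced", {
  expect_error(em_background_fit(1:5), "at least 10")
  expect_error(em_background_fit(1:20, k = 0), ">= 1")
  expect_error(em_background_fit(1:20, k = 30), "exceeds")
})

test_that("background subtraction shifts counts, floors at zero, and guards its level", {
  f <- seq(2800, 2820, 1)
  s <- odmr_spectrum(f, rep(100, 21))
  expect_equal(subtract_background(s, 0)$counts, s$counts)
  expect_equal(subtract_background(s, 40)$counts, rep(60, 21))
  expect_match(subtract_background(s, 40)$metadata$processing, "em_subtract")
  expect_error(subtract_background(s, 150), "maximum count")
  s2 <- odmr_spectrum(f, c(rep(100, 20), 1000))
  expect_error(subtract_background(s2, 900), "99th percentile")
})

test_that("fitted dark-frame background recovers the generator baseline within 2%", {
  sh <- line_shape_params()
  m <- ensemble_spectrum(c(0, 0, 1.7), bulk_ensemble(), shape = sh,
                         mode = "secular")
  nm <- noise_model(background_rate = 800, shot_noise = TRUE,
                    drift_amplitude = 0, seed = 5)
  scan <- generate_scan(m, sh, nm)
  dark <- dark_frame_scan(noise_model(background_rate = 800, seed = 6))
  bg <- em_background_fit(dark$counts, k = 2)
  cleaned <- subtract_background(scan, bg)
  baseline <- stats::median(cleaned$counts[cleaned$counts >=
                                             stats::quantile(cleaned$counts, 0.75)])
  expect_equal(baseline, sh$baseline_rate, tolerance = 0.02)
})

test_that("moving-average smoothing truncates at edges and damps white noise", {
  f7 <- seq(2800, 2806, 1)
  s <- odmr_spectrum(f7, c(0, 0, 0, 3, 0, 0, 0))
  sm <- smooth_spectrum(s, 3)
  expect_equal(sm$counts, c(0, 0, 1, 1, 1, 0, 0))
  expect_match(sm$metadata$processing, "smooth\\(w=3\\)")

  const <- odmr_spectrum(seq(2800, 2850, 1), rep(7, 51))
  expect_equal(smooth_spectrum(const, 5)$counts, rep(7, 51))

  expect_error(smooth_spectrum(const, 4), "odd")
  expect_error(smooth_spectrum(const, 1), "odd")
  expect_error(smooth_spectrum(const, 51), "odd")

  set.seed(9)
  noisy <- odmr_spectrum(seq_len(2001) + 2000, 1000 + stats::rnorm(2001, 0, 10))
  sm5 <- smooth_spectrum(noisy, 5)
  inner <- 3:1999
  ratio <- stats::var(noisy$counts[inner]) / stats::var(sm5$counts[inner])
  expect_equal(ratio, 5, tolerance = 0.30)
})

test_that("natural cubic spline interpolates exactly and reproduces cubics", {
  f <- seq(2800, 2840, 2)
  y <- 1e4 + (f - 2820)^2
  s <- odmr_spectrum(f, y)
  r1 <- spline_resample(s, 1)
  expect_equal(r1$frequencies, f)
  expect_equal(r1$counts, y, tolerance = 1e-12)

  # cubic between interior knots: spline error vanishes away from the ends
  yc <- 5e4 + (f - 2820)^3 / 10 + 3 * (f - 2820)
  sc <- odmr_spectrum(f, yc - min(yc) + 1e4)
  r10 <- spline_resample(sc, 10)
  interior <- r10$frequencies > 2810 & r10$frequencies < 2830
  truth <- 5e4 + (r10$frequencies - 2820)^3 / 10 + 3 * (r10$frequencies - 2820) -
    min(yc) + 1e4
  expect_equal(r10$counts[interior], truth[interior], tolerance = 1e-6)

  # monotone Lorentzian flank stays monotone between knots on this fixture
  fl <- seq(2875, 2895, 1)
  sl <- odmr_spectrum(fl, 1e5 * (1 - 0.02 * lorentzian_dip(fl, 2870, 10)))
  rl <- spline_resample(sl, 10)
  expect_true(all(diff(rl$counts) > 0))

  expect_error(spline_resample(odmr_spectrum(f[1:3], y[1:3]), 10), "4 points")
})

test_that("detect_dips finds, refines and bounds resonance dips", {
  sh <- line_shape_params()
  one <- aligned_scan(0, sh)
  d1 <- detect_dips(one)
  expect_equal(nrow(d1), 1L)
  expect_lt(abs(d1$center - 2870), 0.5)
  expect_equal(d1$depth, sh$contrast, tolerance = 0.01)
  expect_equal(d1$width, sh$fwhm, tolerance = 0.05)

  two <- aligned_scan(1.7, sh)
  d2 <- detect_dips(two)
  expect_equal(nrow(d2), 2L)
  expect_lt(abs((d2$center[2] - d2$center[1]) - 95.2), 1)

  flat <- odmr_spectrum(seq(2800, 2900, 1), rep(1000, 101))
  expect_equal(nrow(detect_dips(flat)), 0L)
})

test_that("double-Lorentzian fit recovers exact and noisy parameters", {
  f <- sweep_config()$grid
  truth <- list(b = 1e5, c1 = 2822.4, c2 = 2917.6, a1 = 0.012, a2 = 0.010,
                w1 = 9, w2 = 11)
  y <- dlor_counts(f, truth$b, truth$c1, truth$c2, truth$a1, truth$a2,
                   truth$w1, truth$w2)
  fit <- double_lorentzian_fit(odmr_spectrum(f, y))
  expect_true(fit$converged)
  expect_false(fit$degenerate)
  expect_equal(fit$baseline, truth$b, tolerance = 1e-6)
  expect_equal(fit$centers, c(truth$c1, truth$c2), tolerance = 1e-6)
  expect_equal(fit$amplitudes, c(truth$a1, truth$a2), tolerance = 1e-4)
  expect_equal(fit$widths, c(truth$w1, truth$w2), tolerance = 1e-4)

  # with Poisson noise at baseline 1e5 the center standard error is a few
  # tenths of a MHz; assert the mean error over a fixed seed ensemble
  ctrue <- c(2822.4, 2917.6)
  errs <- vapply(1:12, function(seed) {
    lambda <- dlor_counts(f, 1e5, ctrue[1], ctrue[2], 0.02, 0.018, 10, 11)
    counts <- nvodmr:::with_seed(seed, stats::rpois(length(lambda), lambda))
    nfit <- double_lorentzian_fit(odmr_spectrum(f, counts))
    expect_true(nfit$converged)
    mean(abs(nfit$centers - ctrue))
  }, numeric(1))
  expect_lt(mean(errs), 0.5)
})

test_that("single-dip data produce a flagged degenerate double fit", {
  f <- sweep_config()$grid
  y <- dlor_counts(f, 1e5, 2870, 2870, 0.01, 0.01, 10, 10)
  s <- odmr_spectrum(f, y)
  expect_error(double_lorentzian_fit(s), "2 detected dips")
  fit <- double_lorentzian_fit(s, init = list(baseline = 1e5,
                                              centers = c(2865, 2875),
                                              amplitudes = c(0.01, 0.01),
                                              widths = c(10, 10)))
  expect_true(fit$degenerate)
})

test_that("measure_splitting reports both separation conventions", {
  d <- detect_dips(aligned_scan(1.7))
  sp <- measure_splitting(d)
  expect_equal(sp$separation, 95.2, tolerance = 0.01)
  expect_equal(sp$per_dip_shift, sp$separation / 2)
  d1 <- detect_dips(aligned_scan(0))
  expect_error(measure_splitting(d1), "found 1")
})

test_that("the analysis chain is idempotent on degenerate inputs", {
  s <- odmr_spectrum(seq(2800, 2850, 1), rep(500, 51), list(processing = ""))
  expect_equal(smooth_spectrum(s, 5)$counts, s$counts)
  expect_equal(subtract_background(s, 0)$counts, s$counts)
})

test_that("the full chain recovers the bulk fixture's dip centers within 1 MHz", {
  # shot noise off isolates the chain's own systematics (EM subtraction of a
  # Poisson dark frame, smoothing, spline, parabolic refinement); with shot
  # noise on, the center standard error alone is ~1 MHz at these count rates
  scans <- fixture_presets("field_1p7mT_bulk", seed = 19,
                           noise = noise_model(500, FALSE, 0))
  avg <- average_scans(scans)
  bg <- em_background_fit(attr(scans, "dark_frame")$counts, k = 2)
  cleaned <- subtract_background(avg, bg)
  sp <- spline_resample(smooth_spectrum(cleaned, 5), 10)
  dips <- detect_dips(sp, max_dips = 2)
  expect_equal(nrow(dips), 2L)
  truth <- 2870 + c(-1, 1) * 47.6 / sqrt(3)
  expect_lt(max(abs(dips$center - truth)), 1)
})
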