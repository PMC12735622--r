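test_that("field inversion follows each geometry convention", {
  d <- detect_dips(aligned_scan(1.7))
  est <- estimate_field(d, convention = "aligned")
  expect_equal(est$B, 1.7, tolerance = 1e-3)
  expect_gt(est$uncertainty, 0)

  db <- detect_dips(average_scans(list(
    generate_scan(ensemble_spectrum(c(0, 0, 1.7), bulk_ensemble(),
                                    mode = "secular"),
                  noise = noiseless_noise()))))
  estb <- estimate_field(db, convention = "bulk_tetrahedral")
  expect_equal(estb$B, 1.7, tolerance = 5e-3)

  zero <- detect_dips(aligned_scan(0))
  zero2 <- rbind(zero, zero)
  class(zero2) <- class(zero); attr(zero2, "step") <- 1
  expect_equal(estimate_field(zero2, convention = "aligned")$B, 0)

  expect_error(estimate_field(d, convention = "sideways"), "arg")
  expect_error(estimate_field(d, convention = "powder_edge"), "spectrum")
})

test_that("powder_edge inversion recovers the field within 15% for B >= 1 mT", {
  sh <- line_shape_params()
  for (B in c(1, 1.7, 3)) {
    m <- ensemble_spectrum(c(0, 0, B), powder_ensemble(20000, seed = 7),
                           shape = sh, mode = "secular")
    s <- generate_scan(m, sh, noiseless_noise())
    est <- estimate_field(NULL, convention = "powder_edge", spectrum = s)
    expect_lt(abs(est$B - B) / B, 0.15)
  }
})

test_that("noiseless aligned field recovery is within 1% and monotone", {
  # window widened so the B = 3 mT dip pair (2786/2954 MHz) stays in range
  sw <- sweep_config(2650, 3090, 1)
  fields <- c(0.5, 1.0, 1.7, 3.0)
  est <- vapply(fields, function(B) {
    d <- detect_dips(aligned_scan(B, sweep = sw))
    estimate_field(d, convention = "aligned")$B
  }, numeric(1))
  expect_lt(max(abs(est - fields) / fields), 0.01)
  expect_true(all(diff(est) > 0))
})

test_that("gyromagnetic calibration recovers 28 MHz/mT", {
  mk <- function(B) list(B_true = B, spectrum = aligned_scan(B))
  cal <- calibrate_gamma(lapply(c(0.5, 1.0, 1.5, 2.0), mk))
  expect_equal(cal$slope, 28, tolerance = 0.5 / 28)

  expect_error(calibrate_gamma(list(mk(1), mk(1))), "distinct")

  # noisy scans: average two replicates per field, as in the measurement
  # protocol, before extracting the shifts
  noisy <- lapply(c(0.5, 1.0, 1.5, 2.0), function(B) {
    m <- ensemble_spectrum(c(0, 0, B), single_ensemble(), mode = "secular")
    reps <- lapply(1:2, function(j)
      generate_scan(m, line_shape_params(),
                    noise_model(500, TRUE, 0.005, seed = round(1000 * B) + j)))
    list(B_true = B, spectrum = average_scans(reps))
  })
  caln <- calibrate_gamma(noisy, window = 5, spline_factor = 10)
  expect_lt(abs(caln$slope - 28), 1)
})

test_that("resolution planning scales linearly and flags infeasible steps", {
  r <- required_frequency_resolution(4e-6)
  expect_equal(r$required_resolution, 1.12e-4)  # 112 Hz for a 4 nT field
  expect_false(r$feasible)

  r2 <- required_frequency_resolution(1.7)
  expect_equal(r2$required_resolution, 47.6)
  expect_true(r2$feasible)

  expect_equal(required_frequency_resolution(2 * 0.3)$required_resolution,
               2 * required_frequency_resolution(0.3)$required_resolution)
  expect_error(required_frequency_resolution(0), "positive")
  expect_error(required_frequency_resolution(-1), "positive")
})

test_that("run_pipeline estimates the bulk preset field within 5%", {
  rep_bulk <- run_pipeline(list(preset = "field_1p7mT_bulk", branch = "bulk",
                                convention = "bulk_tetrahedral", seed = 23))
  expect_identical(rep_bulk$status, "ok")
  expect_true(rep_bulk$fit$converged)
  expect_false(rep_bulk$fit$degenerate)
  expect_lt(abs(rep_bulk$field_mT - 1.7) / 1.7, 0.05)
  expect_match(rep_bulk$processing, "em_subtract.*smooth.*spline")
})

test_that("run_pipeline reports no splitting on the zero-field powder preset", {
  rep_zf <- run_pipeline(list(preset = "zero_field_nd", branch = "nd",
                              seed = 23, prominence = 0.5))
  if (rep_zf$status == "no_splitting") {
    expect_match(rep_zf$message, "no splitting")
    expect_lte(nrow(rep_zf$dips), 1L)
    if (nrow(rep_zf$dips) == 1L)
      expect_lt(abs(rep_zf$dips$center - 2870), 2)
  } else {
    # two sub-dips of the hyperfine-broadened resonance: still centered on D
    expect_lt(abs(mean(rep_zf$dips$center) - 2870), 2)
  }
})

test_that("run_pipeline validates its configuration and writes its report", {
  expect_error(run_pipeline(list(preset = "zero_field_nd", bogus_key = 1)),
               "bogus_key")
  expect_error(run_pipeline(list()), "preset")
  expect_error(run_pipeline(list(preset = "zero_field_nd", branch = "x")),
               "branch")

  out <- withr::local_tempdir()
  rep_bulk <- run_pipeline(list(preset = "field_1p7mT_bulk", branch = "bulk",
                                convention = "bulk_tetrahedral", seed = 23,
                                out_dir = out))
  expect_true(file.exists(file.path(out, "report.json")))
  js <- jsonlite::read_json(file.path(out, "report.json"))
  expect_equal(js$field_mT, rep_bulk$field_mT, tolerance = 1e-9)
  proc <- read_spectrum(file.path(out, "processed_spectrum.tsv"))
  expect_match(proc$metadata$processing, "spline")
})

test_that("run_pipeline analyzes spectra loaded from files like presets", {
  dirp <- withr::local_tempdir()
  scans <- fixture_presets("field_1p7mT_bulk", seed = 41)
  paths <- file.path(dirp, sprintf("scan%d.tsv", seq_along(scans)))
  for (i in seq_along(scans)) write_spectrum(scans[[i]], paths[i])
  dpath <- file.path(dirp, "dark.tsv")
  write_spectrum(attr(scans, "dark_frame"), dpath)

  rep_f <- run_pipeline(list(files = paths, dark_frame = dpath,
                             branch = "bulk", convention = "bulk_tetrahedral"))
  rep_p <- run_pipeline(list(preset = "field_1p7mT_bulk", branch = "bulk",
                             convention = "bulk_tetrahedral", seed = 41))
  expect_equal(rep_f$field_mT, rep_p$field_mT, tolerance = 1e-9)
})

test_that("calibration closes the loop on the generator's gyromagnetic ratio", {
  # full parameter-recovery loop: simulate with a non-default gamma_e and
  # read it back through the analysis chain
  p <- nv_params(gamma_e = 25)
  mk <- function(B) {
    m <- ensemble_spectrum(c(0, 0, B), single_ensemble(), params = p,
                           mode = "secular")
    list(B_true = B, spectrum = generate_scan(m, noise = noiseless_noise()))
  }
  cal <- calibrate_gamma(lapply(c(0.6, 1.2, 1.8), mk), params = p)
  expect_equal(cal$slope, 25, tolerance = 0.02)
})
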