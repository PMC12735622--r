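#' ODMR spectrum container
#'
#' One frequency sweep: a strictly increasing frequency axis (MHz), the
#' photon counts recorded at each point, and free-form scalar metadata
#' (field, ensemble kind, seeds, processing history). Raw scans carry
#' integer counts; averaging and background subtraction produce reals.
#'
#' @param frequencies Strictly increasing numeric vector, MHz.
#' @param counts Nonnegative numeric vector, same length.
#' @param metadata Named list of scalar values.
#' @return An object of class `odmr_spectrum`.
#' @export
odmr_spectrum <- function(frequencies, counts, metadata = list()) {
  stopifnot(is.numeric(frequencies), is.numeric(counts))
  if (length(frequencies) != length(counts))
    stop("`frequencies` and `counts` must have equal length")
  if (length(frequencies) > 1L && any(diff(frequencies) <= 0))
    stop("`frequencies` must be strictly increasing")
  if (any(!is.finite(frequencies)) || any(!is.finite(counts)))
    stop("frequencies and counts must be finite")
  if (any(counts < 0)) stop("counts must be nonnegative")
  if (length(metadata) && (is.null(names(metadata)) || any(names(metadata) == "")))
    stop("`metadata` must be a fully named list")
  structure(list(frequencies = as.numeric(frequencies),
                 counts = as.numeric(counts),
                 metadata = metadata),
            class = "odmr_spectrum")
}

#' @export
print.odmr_spectrum <- function(x, ...) {
  n <- length(x$frequencies)
  cat(sprintf("ODMR spectrum: %d points, %g-%g MHz\n",
              n, min(x$frequencies), max(x$frequencies)))
  if (length(x$metadata)) {
    cat("metadata:\n")
    for (k in names(x$metadata))
      cat(sprintf("  %s = %s\n", k, paste(format(x$metadata[[k]]), collapse = ",")))
  }
  invisible(x)
}

append_processing <- function(s, tag) {
  prev <- s$metadata$processing
  s$metadata$processing <- if (is.null(prev) || !nzchar(prev)) tag else
    paste(prev, tag, sep = ";")
  s
}

#' Spectrometer noise model
#'
#' @param background_rate Expected additive background counts per point
#'   (spectrometer dark counts). Default 500.
#' @param shot_noise Logical; Poisson-sample the counts.
#' @param drift_amplitude Bound on the relative baseline drift per scan
#'   (laser-power fluctuation, below 1% in the emulated setup). Default 0.01.
#' @param seed RNG seed; required whenever shot noise or drift is active.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(background_rate = 500, shot_noise = TRUE,
                        drift_amplitude = 0.01, seed = NULL) {
  if (!is.numeric(background_rate) || background_rate < 0)
    stop("`background_rate` must be >= 0")
  if (!is.numeric(drift_amplitude) || drift_amplitude < 0 || drift_amplitude >= 1)
    stop("`drift_amplitude` must be in [0, 1)")
  stopifnot(is.logical(shot_noise), length(shot_noise) == 1L)
  structure(list(background_rate = background_rate, shot_noise = shot_noise,
                 drift_amplitude = drift_amplitude, seed = seed),
            class = "noise_model")
}

#' Generate one spectrometer scan from a spectrum model
#'
#' Expected counts at each frequency are
#' `baseline_rate * (1 + drift(f)) * relative_pl(f) + background_rate`,
#' where `drift` is a smooth half-sine perturbation with random amplitude
#' bounded by `drift_amplitude`, redrawn per scan. With `shot_noise` the
#' counts are Poisson samples of that expectation; the whole scan is a pure
#' function of the noise seed.
#'
#' @param model A `spectrum_model` from [model_spectrum()] or
#'   [ensemble_spectrum()].
#' @param shape [line_shape_params()] supplying `baseline_rate`.
#' @param noise [noise_model()].
#' @return An `odmr_spectrum` (integer counts when shot noise is on).
#' @export
generate_scan <- function(model, shape = line_shape_params(),
                          noise = noise_model()) {
  stopifnot(inherits(model, "spectrum_model"))
  f <- model$frequencies
  if (!length(f)) stop("model grid is empty")
  stochastic <- noise$shot_noise || noise$drift_amplitude > 0
  if (stochastic && is.null(noise$seed))
    stop("`noise$seed` is required when shot noise or drift is enabled")
  run <- function() {
    drift <- 0
    if (noise$drift_amplitude > 0) {
      amp <- stats::runif(1, -noise$drift_amplitude, noise$drift_amplitude)
      x <- (f - f[1L]) / max(f[length(f)] - f[1L], 1)
      drift <- amp * sin(pi * x)
    }
    lambda <- shape$baseline_rate * (1 + drift) * model$relative_pl +
      noise$background_rate
    if (noise$shot_noise) stats::rpois(length(lambda), lambda) else lambda
  }
  counts <- if (stochastic) with_seed(noise$seed, run()) else run()
  md <- list(
    field_mT = model$provenance$field_mT,
    ensemble = model$provenance$ensemble_kind,
    baseline_rate = shape$baseline_rate,
    background_rate = noise$background_rate,
    drift_amplitude = noise$drift_amplitude,
    shot_noise = noise$shot_noise,
    raw_counts = if (noise$shot_noise) "integer" else "real"
  )
  if (!is.null(noise$seed)) md$seed <- as.numeric(noise$seed)
  md <- md[!vapply(md, is.null, logical(1))]
  odmr_spectrum(f, counts, md)
}

#' Dark-frame scan (spectrometer background only)
#'
#' Poisson samples of the background rate on the sweep grid, emulating a
#' scan with the PL signal blocked. Used to fit the background model that
#' the subtraction step removes.
#'
#' @param noise [noise_model()] (its `background_rate` and `seed` are used).
#' @param sweep [sweep_config()].
#' @return An `odmr_spectrum` with `metadata$kind = "dark"`.
#' @export
dark_frame_scan <- function(noise = noise_model(), sweep = sweep_config()) {
  if (is.null(noise$seed)) stop("`noise$seed` is required")
  counts <- with_seed(noise$seed,
                      stats::rpois(length(sweep$grid), noise$background_rate))
  odmr_spectrum(sweep$grid, counts,
                list(kind = "dark", background_rate = noise$background_rate,
                     seed = as.numeric(noise$seed), raw_counts = "integer"))
}

#' Average replicate scans
#'
#' Pointwise arithmetic mean of scans sharing an identical frequency grid
#' (no silent interpolation). Metadata records how many scans went in and
#' their seeds.
#'
#' @param scans List of `odmr_spectrum` objects.
#' @return An `odmr_spectrum` with real-valued counts.
#' @export
average_scans <- function(scans) {
  if (!length(scans)) stop("`scans` must be a nonempty list")
  if (inherits(scans, "odmr_spectrum")) scans <- list(scans)
  stopifnot(all(vapply(scans, inherits, logical(1), "odmr_spectrum")))
  f <- scans[[1L]]$frequencies
  for (s in scans[-1L])
    if (length(s$frequencies) != length(f) || any(s$frequencies != f))
      stop("cannot average scans: frequency grids differ")
  counts <- rowMeans(vapply(scans, function(s) s$counts, numeric(length(f))))
  md <- scans[[1L]]$metadata
  md$n_averaged <- length(scans)
  seeds <- unlist(lapply(scans, function(s) s$metadata$seed))
  if (length(seeds)) md$source_seeds <- paste(format(seeds, trim = TRUE), collapse = ",")
  md$seed <- NULL
  md$raw_counts <- "real"
  out <- odmr_spectrum(f, counts, md)
  append_processing(out, sprintf("average(n=%d)", length(scans)))
}

format_meta_value <- function(v) {
  if (is.numeric(v)) sprintf("%.17g", v) else as.character(v)
}

parse_meta_value <- function(v) {
  if (v %in% c("TRUE", "FALSE")) return(as.logical(v))
  num <- suppressWarnings(as.numeric(v))
  if (!is.na(num) && grepl("^[-+0-9.eE]+$", v)) num else v
}

#' Write / read the spectra file format
#'
#' Plain-text spectra files: UTF-8, LF line endings, `# key = value` header
#' lines, a `frequency_MHz<TAB>counts` column-header row, then one row per
#' grid point with ascending frequencies. The reader also accepts
#' comma-separated data and scientific notation; a file without a metadata
#' header is accepted with a warning.
#'
#' @param s An `odmr_spectrum`.
#' @param path File path.
#' @return `read_spectrum` returns an `odmr_spectrum`; `write_spectrum`
#'   returns `path` invisibly.
#' @export
write_spectrum <- function(s, path) {
  stopifnot(inherits(s, "odmr_spectrum"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  hdr <- vapply(names(s$metadata), function(k)
    sprintf("# %s = %s", k, format_meta_value(s$metadata[[k]])), character(1))
  body <- sprintf("%.17g\t%.17g", s$frequencies, s$counts)
  writeLines(c(hdr, "frequency_MHz\tcounts", body), con, sep = "\n")
  invisible(path)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  metadata <- list()
  freqs <- counts <- numeric(0)
  seen_header <- FALSE
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) next
    if (startsWith(ln, "#")) {
      kv <- sub("^#\\s*", "", ln)
      eq <- regexpr("=", kv, fixed = TRUE)
      if (eq < 0)
        stop(sprintf("parse error at line %d: metadata line without '=': %s", i, ln))
      key <- trimws(substr(kv, 1L, eq - 1L))
      val <- trimws(substr(kv, eq + 1L, nchar(kv)))
      if (!nzchar(key))
        stop(sprintf("parse error at line %d: empty metadata key", i))
      metadata[[key]] <- parse_meta_value(val)
      next
    }
    fields <- strsplit(ln, "[\t,]")[[1L]]
    fields <- fields[nzchar(trimws(fields))]
    if (!seen_header && !length(freqs) && length(fields) >= 1L &&
        any(is.na(suppressWarnings(as.numeric(fields))))) {
      seen_header <- TRUE  # column-header row (before any data only)
      next
    }
    if (length(fields) != 2L)
      stop(sprintf("parse error at line %d: expected 2 columns, found %d",
                   i, length(fields)))
    vals <- suppressWarnings(as.numeric(fields))
    if (any(is.na(vals)))
      stop(sprintf("parse error at line %d: non-numeric value in '%s'", i, ln))
    freqs <- c(freqs, vals[1L])
    counts <- c(counts, vals[2L])
  }
  if (!length(freqs)) stop("no data rows found in ", path)
  if (length(freqs) > 1L && any(diff(freqs) <= 0))
    stop("frequencies in ", path, " are not strictly increasing")
  if (!length(metadata))
    warning("no metadata header found in ", path, "; proceeding with empty metadata")
  odmr_spectrum(freqs, counts, metadata)
}

preset_table <- function() {
  list(
    zero_field_nd = list(
      B = c(0, 0, 0), ensemble = "powder", mode = "full",
      hyperfine = TRUE, n_rep = 3L
    ),
    field_1p7mT_nd = list(
      B = c(0, 0, 1.7), ensemble = "powder", mode = "full",
      hyperfine = TRUE, n_rep = 2L
    ),
    field_1p7mT_bulk = list(
      B = c(0, 0, 1.7), ensemble = "bulk_tetrahedral", mode = "secular",
      hyperfine = TRUE, n_rep = 2L
    )
  )
}

#' Replicate-scan fixtures for the study conditions
#'
#' Generates 2-3 replicate noisy scans on the default 2800-3000 MHz, 1 MHz
#' grid for one of three named conditions: a zero-field nanodiamond powder
#' (hyperfine on), a powder in a 1.7 mT field, and a tetrahedral bulk sample
#' in a 1.7 mT field along lab Z. A matching dark frame is attached as
#' `attr(x, "dark_frame")`. The entire output is a pure function of
#' `(name, seed)`.
#'
#' @param name One of `"zero_field_nd"`, `"field_1p7mT_nd"`,
#'   `"field_1p7mT_bulk"`.
#' @param seed Master seed; per-replicate seeds are derived from it.
#' @param n_orientations Powder fidelity (number of sampled ND axes).
#' @param shape [line_shape_params()].
#' @param noise Base [noise_model()] (its seed field is ignored; per-scan
#'   seeds are derived from `seed`).
#' @return List of `odmr_spectrum` replicates with a `dark_frame` attribute.
#' @export
fixture_presets <- function(name, seed, n_orientations = 2000,
                            shape = line_shape_params(),
                            noise = noise_model()) {
  presets <- preset_table()
  if (!is.character(name) || length(name) != 1L || !name %in% names(presets))
    stop("unknown preset '", name, "'; valid presets: ",
         paste(names(presets), collapse = ", "))
  p <- presets[[name]]
  seeds <- derive_seeds(seed, p$n_rep + 2L)
  ens <- switch(p$ensemble,
                powder = powder_ensemble(n_orientations, seed = seeds[p$n_rep + 1L]),
                bulk_tetrahedral = bulk_ensemble())
  model <- ensemble_spectrum(p$B, ens, mode = p$mode, hyperfine = p$hyperfine,
                             shape = shape)
  scans <- lapply(seq_len(p$n_rep), function(i) {
    ni <- noise
    ni$seed <- seeds[i]
    s <- generate_scan(model, shape, ni)
    s$metadata$preset <- name
    s$metadata$scan_index <- i
    s
  })
  nd <- noise
  nd$seed <- seeds[p$n_rep + 2L]
  attr(scans, "dark_frame") <- dark_frame_scan(nd)
  scans
}
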