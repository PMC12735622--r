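#' Microwave sweep configuration
#'
#' Defaults reproduce the study conditions: a CW sweep from 2800 to 3000 MHz
#' in 1 MHz steps (201 points, endpoints inclusive).
#'
#' @param f_start,f_stop Sweep limits, MHz (`f_start < f_stop`).
#' @param step Step size, MHz (> 0).
#' @return An object of class `sweep_config` with the frequency grid in
#'   `$grid` (arithmetic sequence starting at `f_start`, last point
#'   `<= f_stop`).
#' @export
sweep_config <- function(f_start = 2800, f_stop = 3000, step = 1) {
  stopifnot(is.numeric(f_start), is.numeric(f_stop), is.numeric(step),
            length(f_start) == 1L, length(f_stop) == 1L, length(step) == 1L)
  if (!(f_start < f_stop)) stop("`f_start` must be < `f_stop`")
  if (step <= 0) stop("`step` must be > 0")
  structure(
    list(f_start = f_start, f_stop = f_stop, step = step,
         grid = seq(f_start, f_stop, by = step)),
    class = "sweep_config"
  )
}

#' Lineshape and baseline parameters
#'
#' The study reports spectra but not linewidths, contrasts or count rates;
#' these are therefore free effective parameters with declared defaults.
#'
#' @param fwhm Full width at half maximum of each Lorentzian dip, MHz.
#' @param contrast Fractional PL drop of a fully weighted line at its center.
#' @param baseline_rate Expected off-resonant counts per sweep point.
#' @return An object of class `line_shape_params`.
#' @export
line_shape_params <- function(fwhm = 10, contrast = 0.02, baseline_rate = 1e5) {
  if (!is.numeric(fwhm) || fwhm <= 0) stop("`fwhm` must be > 0")
  if (!is.numeric(contrast) || contrast <= 0 || contrast >= 1)
    stop("`contrast` must be in (0, 1)")
  if (!is.numeric(baseline_rate) || baseline_rate <= 0)
    stop("`baseline_rate` must be > 0")
  structure(list(fwhm = fwhm, contrast = contrast, baseline_rate = baseline_rate),
            class = "line_shape_params")
}

#' Unit-amplitude Lorentzian dip profile
#'
#' `(fwhm/2)^2 / ((f - center)^2 + (fwhm/2)^2)`: 1 at the center, 1/2 at
#' `center +/- fwhm/2`.
#'
#' @param f Frequency (vectorized), MHz.
#' @param center Line center, MHz.
#' @param fwhm Full width at half maximum, MHz (> 0).
#' @return Values in (0, 1].
#' @export
lorentzian_dip <- function(f, center, fwhm) {
  if (fwhm <= 0) stop("`fwhm` must be > 0")
  hw2 <- (fwhm / 2)^2
  hw2 / ((f - center)^2 + hw2)
}

#' Noiseless spectrum model from a set of resonance lines
#'
#' Superposes weighted Lorentzian dips on a unit baseline:
#' `relative_pl(f) = 1 - contrast * sum_i w_i * L(f; c_i, fwhm)`.
#'
#' @param lines `data.frame(center, weight)` with nonnegative weights; an
#'   empty frame yields a flat spectrum.
#' @param shape [line_shape_params()].
#' @param sweep [sweep_config()].
#' @return An object of class `spectrum_model`: `$frequencies` (MHz),
#'   `$relative_pl` (dimensionless, 1 at baseline) and `$provenance`.
#' @export
model_spectrum <- function(lines, shape = line_shape_params(),
                           sweep = sweep_config()) {
  if (is.null(lines)) lines <- data.frame(center = numeric(), weight = numeric())
  stopifnot(is.data.frame(lines), all(c("center", "weight") %in% names(lines)))
  if (any(lines$weight < 0)) stop("line weights must be nonnegative")
  total <- shape$contrast * sum(lines$weight)
  if (total >= 1)
    stop("non-physical total contrast: contrast * sum(weights) = ",
         signif(total, 4), " >= 1")
  f <- sweep$grid
  dip <- numeric(length(f))
  n <- nrow(lines)
  if (n > 0) {
    # chunked so powder ensembles with 1e5 lines stay within memory
    chunk <- 2000L
    for (i0 in seq(1L, n, by = chunk)) {
      i1 <- min(i0 + chunk - 1L, n)
      L <- outer(f, lines$center[i0:i1],
                 function(x, c0) lorentzian_dip(x, c0, shape$fwhm))
      dip <- dip + drop(L %*% lines$weight[i0:i1])
    }
  }
  structure(
    list(frequencies = f,
         relative_pl = 1 - shape$contrast * dip,
         provenance = list(shape = shape, sweep = sweep, n_lines = n)),
    class = "spectrum_model"
  )
}

#' Orientation ensembles
#'
#' A set of NV-axis unit vectors with weights: a single axis, the four
#' tetrahedral bulk families, or a random powder sample.
#'
#' @param axes Numeric matrix, one unit axis per row (rows are normalized).
#' @param weights Nonnegative, recycled/normalized to sum to 1.
#' @param kind One of `"single"`, `"bulk_tetrahedral"`, `"powder"`.
#' @return An object of class `orientation_ensemble`.
#' @export
orientation_ensemble <- function(axes, weights = NULL,
                                 kind = c("single", "bulk_tetrahedral", "powder")) {
  kind <- match.arg(kind)
  if (is.null(dim(axes))) axes <- matrix(axes, nrow = 1L)
  stopifnot(is.numeric(axes), ncol(axes) == 3L, nrow(axes) >= 1L)
  nrm <- sqrt(rowSums(axes^2))
  if (any(nrm == 0) || any(!is.finite(nrm))) stop("axes must be nonzero and finite")
  axes <- axes / nrm
  if (is.null(weights)) weights <- rep(1 / nrow(axes), nrow(axes))
  if (any(weights < 0)) stop("weights must be nonnegative")
  s <- sum(weights)
  if (s <= 0) stop("weights must not all be zero")
  structure(list(axes = axes, weights = weights / s, kind = kind),
            class = "orientation_ensemble")
}

#' @rdname orientation_ensemble
#' @param axis Single NV axis (3-vector) for a single-orientation ensemble.
#' @export
single_ensemble <- function(axis = c(0, 0, 1)) {
  orientation_ensemble(matrix(axis, nrow = 1L), kind = "single")
}

#' @rdname orientation_ensemble
#' @export
bulk_ensemble <- function() {
  orientation_ensemble(tetrahedral_axes(), kind = "bulk_tetrahedral")
}

#' Random powder ensemble of NV axes
#'
#' Draws `n_orientations` axes isotropically on the unit sphere (normalized
#' Gaussian triples), equal weights, deterministic under `seed`. Emulates
#' nanodiamonds suspended with random orientations.
#'
#' @param n_orientations Number of axes (>= 1).
#' @param seed RNG seed (required).
#' @return An `orientation_ensemble` of kind `"powder"`.
#' @export
powder_ensemble <- function(n_orientations, seed) {
  if (!is.numeric(n_orientations) || length(n_orientations) != 1L ||
      n_orientations < 1)
    stop("`n_orientations` must be >= 1")
  if (missing(seed) || is.null(seed)) stop("`seed` is required")
  n <- as.integer(n_orientations)
  axes <- with_seed(seed, {
    m <- matrix(stats::rnorm(3L * n), ncol = 3L)
    bad <- rowSums(m^2) == 0
    while (any(bad)) {
      m[bad, ] <- stats::rnorm(3L * sum(bad))
      bad <- rowSums(m^2) == 0
    }
    m
  })
  orientation_ensemble(axes, kind = "powder")
}

#' Resonance lines of an orientation ensemble
#'
#' For each axis, computes the two spin transitions (secular or full mode)
#' and optionally expands each into its hyperfine triplet. Line weights are
#' orientation weight / 2 per transition (x 1/3 per hyperfine component), so
#' they always sum to 1.
#'
#' @param B Lab-frame field 3-vector, mT.
#' @param ensemble [orientation_ensemble()].
#' @param params [nv_params()].
#' @param mode `"secular"` or `"full"`.
#' @param hyperfine Logical; expand lines into hyperfine components.
#' @return `data.frame(center, weight)`.
#' @export
ensemble_lines <- function(B, ensemble, params = nv_params(),
                           mode = c("secular", "full"), hyperfine = FALSE) {
  mode <- match.arg(mode)
  check_field_vec(B)
  trans <- if (mode == "secular") transition_frequencies_secular else
    transition_frequencies_full
  n <- nrow(ensemble$axes)
  centers <- matrix(0, n, 2L)
  for (i in seq_len(n))
    centers[i, ] <- trans(B, nv_orientation(ensemble$axes[i, ]), params)
  w <- rep(ensemble$weights / 2, each = 2L)
  lines <- data.frame(center = as.vector(t(centers)), weight = w)
  if (hyperfine && params$A_hf > 0) {
    lines <- data.frame(
      center = as.vector(outer(c(-params$A_hf, 0, params$A_hf), lines$center, `+`)),
      weight = rep(lines$weight / 3, each = 3L)
    )
  }
  lines
}

#' Noiseless CW-ODMR spectrum of an orientation ensemble
#'
#' Combines [ensemble_lines()] and [model_spectrum()]: the Zeeman splitting
#' of each orientation superposes into a composite lineshape. Randomly
#' oriented powders broaden into a band spanning `D +/- gamma_e |B|`, while
#' a [001]-field bulk sample keeps a single sharp split pair.
#'
#' @inheritParams ensemble_lines
#' @param shape [line_shape_params()].
#' @param sweep [sweep_config()].
#' @return A `spectrum_model`.
#' @export
ensemble_spectrum <- function(B, ensemble, params = nv_params(),
                              shape = line_shape_params(),
                              sweep = sweep_config(),
                              mode = c("secular", "full"), hyperfine = FALSE) {
  mode <- match.arg(mode)
  lines <- ensemble_lines(B, ensemble, params, mode, hyperfine)
  m <- model_spectrum(lines, shape, sweep)
  m$provenance$ensemble_kind <- ensemble$kind
  m$provenance$field_mT <- sqrt(sum(B^2))
  m$provenance$mode <- mode
  m$provenance$hyperfine <- hyperfine
  m
}
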