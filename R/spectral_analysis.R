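#' Gaussian-mixture background model via expectation-maximization
#'
#' Fits a one-dimensional Gaussian mixture to count values by EM and
#' extracts the spectrometer background level from it. Initialization is
#' deterministic: component means at evenly spaced quantiles (the 10th and
#' 90th percentiles for `k = 2`), equal mixing weights, pooled variance.
#' `k = 1` reduces to the closed-form sample moments.
#'
#' The background level is the mean of the heaviest-weight component among
#' those whose mean does not exceed the mixture's grand mean (for `k = 2`,
#' ordinarily the low-mean component).
#'
#' @param counts Numeric vector of count values (>= 10 samples).
#' @param k Number of mixture components (1 <= k <= length(counts)).
#' @param seed Accepted for interface stability; the initialization is
#'   deterministic so the seed is not consumed.
#' @param tol Relative log-likelihood change declaring convergence.
#' @param max_iter Iteration cap; exceeding it flags `converged = FALSE`
#'   without raising.
#' @return An object of class `background_model`: `means`, `variances`,
#'   `weights`, `background_level`, `n_iterations`, `converged`, `loglik`
#'   and the per-iteration `loglik_trace` (non-decreasing).
#' @export
em_background_fit <- function(counts, k = 2, seed = NULL, tol = 1e-8,
                              max_iter = 500) {
  x <- as.numeric(counts)
  n <- length(x)
  if (n < 10L) stop("need at least 10 samples, got ", n)
  if (any(!is.finite(x))) stop("counts must be finite")
  k <- as.integer(k)
  if (k < 1L) stop("`k` must be >= 1")
  if (k > n) stop("`k` (", k, ") exceeds the number of samples (", n, ")")

  if (k == 1L) {
    mu <- mean(x)
    v <- mean((x - mu)^2)
    ll <- sum(stats::dnorm(x, mu, sqrt(max(v, 1e-300)), log = TRUE))
    return(new_background_model(mu, v, 1, 1L, TRUE, ll, ll))
  }

  probs <- if (k == 2L) c(0.1, 0.9) else seq(0.1, 0.9, length.out = k)
  mu <- as.numeric(stats::quantile(x, probs, names = FALSE))
  v <- rep(max(stats::var(x) * (n - 1) / n, 1e-12), k)
  w <- rep(1 / k, k)
  var_floor <- max(1e-10 * stats::var(x), 1e-300)

  ll_trace <- numeric(0)
  ll_prev <- -Inf
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    # E step: responsibilities via log-sum-exp for numerical safety
    logd <- vapply(seq_len(k), function(j)
      log(w[j]) + stats::dnorm(x, mu[j], sqrt(v[j]), log = TRUE),
      numeric(n))
    m <- apply(logd, 1L, max)
    lse <- m + log(rowSums(exp(logd - m)))
    ll <- sum(lse)
    ll_trace <- c(ll_trace, ll)
    resp <- exp(logd - lse)
    # M step
    nk <- colSums(resp)
    nk <- pmax(nk, 1e-12)
    w <- nk / n
    mu <- colSums(resp * x) / nk
    v <- pmax(colSums(resp * outer(x, mu, `-`)^2) / nk, var_floor)
    if (is.finite(ll_prev) &&
        abs(ll - ll_prev) <= tol * max(abs(ll_prev), 1e-12)) {
      converged <- TRUE
      break
    }
    ll_prev <- ll
  }
  new_background_model(mu, v, w, iter, converged, ll_trace[length(ll_trace)],
                       ll_trace)
}

new_background_model <- function(means, variances, weights, n_iterations,
                                 converged, loglik, loglik_trace) {
  gm <- sum(weights * means)
  cand <- which(means <= gm)
  if (!length(cand)) cand <- which.min(means)
  bg <- means[cand[which.max(weights[cand])]]
  structure(
    list(means = means, variances = variances, weights = weights,
         background_level = bg, n_iterations = n_iterations,
         converged = converged, loglik = loglik, loglik_trace = loglik_trace),
    class = "background_model"
  )
}

#' @export
print.background_model <- function(x, ...) {
  cat(sprintf("Gaussian-mixture background model (%d components, %d EM iterations%s)\n",
              length(x$means), x$n_iterations,
              if (x$converged) ", converged" else ", NOT converged"))
  for (j in seq_along(x$means))
    cat(sprintf("  mean %.4g  sd %.4g  weight %.3f\n",
                x$means[j], sqrt(x$variances[j]), x$weights[j]))
  cat(sprintf("  background level = %.6g counts\n", x$background_level))
  invisible(x)
}

#' Subtract a fitted background level from a spectrum
#'
#' Subtracts `background_level` from every count, flooring at zero, and
#' appends to the processing history.
#'
#' @param s An `odmr_spectrum`.
#' @param bg A `background_model` or a single numeric level (counts).
#' @return The background-subtracted `odmr_spectrum`.
#' @export
subtract_background <- function(s, bg) {
  stopifnot(inherits(s, "odmr_spectrum"))
  level <- if (inherits(bg, "background_model")) bg$background_level else bg
  stopifnot(is.numeric(level), length(level) == 1L, is.finite(level))
  if (level > max(s$counts))
    stop("background level (", signif(level, 6),
         ") exceeds the maximum count; subtraction would zero the spectrum")
  if (level > stats::quantile(s$counts, 0.99))
    stop("background level (", signif(level, 6),
         ") exceeds the 99th percentile of the counts; not a plausible baseline")
  s$counts <- pmax(s$counts - level, 0)
  s$metadata$raw_counts <- "real"
  append_processing(s, sprintf("em_subtract(level=%.6g)", level))
}

#' Moving-average smoothing
#'
#' Centered moving average with the window truncated at the spectrum edges
#' (the first point is the mean of the first `(window+1)/2` points, and so
#' on). Grid unchanged.
#'
#' @param s An `odmr_spectrum`.
#' @param window Odd window length in points, `3 <= window <= n/2`.
#' @return The smoothed `odmr_spectrum`.
#' @export
smooth_spectrum <- function(s, window = 5) {
  stopifnot(inherits(s, "odmr_spectrum"))
  n <- length(s$counts)
  if (!is.numeric(window) || length(window) != 1L || window %% 2 != 1 ||
      window < 3 || window > n / 2)
    stop("`window` must be an odd integer in [3, n/2]")
  h <- (window - 1L) / 2L
  cs <- cumsum(c(0, s$counts))
  i <- seq_len(n)
  lo <- pmax(i - h, 1L)
  hi <- pmin(i + h, n)
  s$counts <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  append_processing(s, sprintf("smooth(w=%d)", as.integer(window)))
}

#' Natural cubic-spline resampling
#'
#' Interpolating natural cubic spline through the (smoothed) points,
#' evaluated on a grid refined by `factor`; passes through every input
#' point exactly.
#'
#' @param s An `odmr_spectrum` with >= 4 points.
#' @param factor Integer refinement factor >= 1 (1 reproduces the input
#'   grid).
#' @return The resampled `odmr_spectrum`.
#' @export
spline_resample <- function(s, factor = 10) {
  stopifnot(inherits(s, "odmr_spectrum"))
  f <- s$frequencies
  n <- length(f)
  if (n < 4L) stop("need at least 4 points for cubic-spline resampling")
  if (anyDuplicated(f)) stop("duplicate frequencies")
  if (!is.numeric(factor) || length(factor) != 1L || factor < 1 ||
      factor != round(factor))
    stop("`factor` must be an integer >= 1")
  factor <- as.integer(factor)
  sf <- stats::splinefun(f, s$counts, method = "natural")
  grid <- if (factor == 1L) f else
    seq(f[1L], f[n], length.out = (n - 1L) * factor + 1L)
  s$frequencies <- grid
  s$counts <- pmax(sf(grid), 0)
  append_processing(s, sprintf("spline(x%d)", factor))
}

dip_baseline <- function(counts) {
  stats::median(counts[counts >= stats::quantile(counts, 0.75)])
}

# Topographic prominence of each candidate dip: with z = baseline - counts
# ("dip height"), walk outward from the minimum until a deeper minimum is
# passed (z exceeds z[i]); the higher of the two saddles reached bounds the
# dip from below. Side wiggles on the flank of a larger dip get a small
# prominence and are rejected, however deep they sit in absolute terms.
dip_prominence <- function(z, idx) {
  n <- length(z)
  vapply(idx, function(i) {
    j <- i - 1L
    while (j >= 1L && z[j] <= z[i]) j <- j - 1L
    lmin <- min(z[max(j, 1L):i])
    j <- i + 1L
    while (j <= n && z[j] <= z[i]) j <- j + 1L
    rmin <- min(z[i:min(j, n)])
    z[i] - max(lmin, rmin)
  }, numeric(1))
}

#' Detect resonance dips
#'
#' Finds local minima, measures their depth relative to an internal baseline
#' (the median of the upper quartile of counts) and their topographic
#' prominence (depth above the higher of the two saddles separating the
#' minimum from deeper ones), keeps minima whose prominence is at least
#' `prominence` times the most prominent dip's, truncates to the `max_dips`
#' most prominent, and refines each center by parabolic interpolation
#' through the three points around the minimum. Widths are full widths at
#' half the dip depth, linearly interpolated.
#'
#' @param s An `odmr_spectrum`.
#' @param prominence Relative prominence threshold (fraction of the maximum
#'   dip prominence). Default 0.3.
#' @param max_dips Keep at most this many dips (the most prominent).
#'   Default 2.
#' @param method Provenance tag recorded on the result.
#' @return A `dip_set`: `data.frame(center, depth, width)` sorted by center,
#'   possibly empty, with attributes `method`, `baseline` and `step`.
#' @export
detect_dips <- function(s, prominence = 0.3, max_dips = 2,
                        method = "spline") {
  stopifnot(inherits(s, "odmr_spectrum"))
  f <- s$frequencies
  y <- s$counts
  n <- length(y)
  if (n < 3L) stop("need at least 3 points")
  base <- dip_baseline(y)
  if (base <= 0) stop("nonpositive baseline; cannot normalize")
  idx <- which(y[2:(n - 1L)] < y[1:(n - 2L)] & y[2:(n - 1L)] < y[3:n]) + 1L
  depth <- (base - y[idx]) / base
  keep <- depth > 0
  idx <- idx[keep]; depth <- depth[keep]
  if (length(idx)) {
    prom <- dip_prominence(base - y, idx) / base
    keep <- prom >= prominence * max(prom)
    idx <- idx[keep]; depth <- depth[keep]; prom <- prom[keep]
    ord <- order(prom, decreasing = TRUE)[seq_len(min(max_dips, length(idx)))]
    idx <- idx[ord]; depth <- depth[ord]
  }
  center <- width <- numeric(length(idx))
  for (j in seq_along(idx)) {
    i <- idx[j]
    h <- (f[i + 1L] - f[i - 1L]) / 2
    den <- y[i - 1L] - 2 * y[i] + y[i + 1L]
    center[j] <- if (den > 0) f[i] + 0.5 * h * (y[i - 1L] - y[i + 1L]) / den else f[i]
    half <- base - 0.5 * depth[j] * base
    # walk outward to the half-depth crossings
    l <- i
    while (l > 1L && y[l] < half) l <- l - 1L
    f_lo <- if (y[l] >= half && l < i)
      f[l] + (half - y[l]) / (y[l + 1L] - y[l]) * (f[l + 1L] - f[l]) else f[1L]
    r <- i
    while (r < n && y[r] < half) r <- r + 1L
    f_hi <- if (y[r] >= half && r > i)
      f[r] - (half - y[r]) / (y[r - 1L] - y[r]) * (f[r] - f[r - 1L]) else f[n]
    width[j] <- f_hi - f_lo
  }
  ord <- order(center)
  out <- data.frame(center = center[ord], depth = depth[ord], width = width[ord])
  attr(out, "method") <- method
  attr(out, "baseline") <- base
  attr(out, "step") <- stats::median(diff(f))
  class(out) <- c("dip_set", "data.frame")
  out
}

#' Double-Lorentzian least-squares fit
#'
#' Fits `baseline * (1 - a1 L(f; c1, w1) - a2 L(f; c2, w2))` to the counts
#' by Levenberg-Marquardt least squares, initialized from [detect_dips()]
#' (or explicit values). This is the standard representation of bulk-diamond
#' field-split spectra; randomly oriented powder spectra are not expressible
#' as a sum of two such terms and should go through [detect_dips()] instead.
#'
#' A fit is flagged degenerate when the two centers collapse to within one
#' grid step or one amplitude falls below 1% of the other.
#'
#' @param s An `odmr_spectrum`.
#' @param init Optional named list with `baseline`, `centers` (length 2),
#'   `amplitudes` (length 2), `widths` (length 2); derived from
#'   [detect_dips()] when `NULL` (requires two detectable dips).
#' @return An object of class `dlor_fit`: fitted `baseline`, `centers`
#'   (ascending), `amplitudes`, `widths`, `residual_norm`, `converged`,
#'   `degenerate`.
#' @export
double_lorentzian_fit <- function(s, init = NULL) {
  stopifnot(inherits(s, "odmr_spectrum"))
  f <- s$frequencies
  y <- s$counts
  step <- stats::median(diff(f))
  if (is.null(init)) {
    # initialize from dips detected on a lightly smoothed copy; the fit
    # itself always runs on the raw counts
    s_init <- if (length(f) >= 12L) smooth_spectrum(s, 5) else s
    dips <- detect_dips(s_init, max_dips = 2)
    if (nrow(dips) < 2L)
      stop("need >= 2 detected dips to initialize the fit (found ",
           nrow(dips), "); supply `init`")
    init <- list(baseline = attr(dips, "baseline"),
                 centers = dips$center,
                 amplitudes = dips$depth,
                 widths = ifelse(dips$width > 0, dips$width, 10))
  }
  start <- list(b = init$baseline,
                c1 = init$centers[1L], c2 = init$centers[2L],
                a1 = init$amplitudes[1L], a2 = init$amplitudes[2L],
                w1 = init$widths[1L], w2 = init$widths[2L])
  lower <- c(b = 0, c1 = min(f), c2 = min(f), a1 = 0, a2 = 0,
             w1 = step / 10, w2 = step / 10)
  upper <- c(b = Inf, c1 = max(f), c2 = max(f), a1 = 1, a2 = 1,
             w1 = Inf, w2 = Inf)
  start <- start[c("b", "c1", "c2", "a1", "a2", "w1", "w2")]
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ b * (1 - a1 * (w1 / 2)^2 / ((f - c1)^2 + (w1 / 2)^2)
                 - a2 * (w2 / 2)^2 / ((f - c2)^2 + (w2 / 2)^2)),
      data = data.frame(f = f, y = y),
      start = start, lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = 500)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    pars <- unlist(start)
    converged <- FALSE
    resid <- y - pars["b"] *
      (1 - pars["a1"] * lorentzian_dip(f, pars["c1"], pars["w1"])
         - pars["a2"] * lorentzian_dip(f, pars["c2"], pars["w2"]))
  } else {
    pars <- stats::coef(fit)
    converged <- isTRUE(fit$convInfo$isConv)
    resid <- stats::residuals(fit)
  }
  ord <- order(c(pars["c1"], pars["c2"]))
  centers <- unname(c(pars["c1"], pars["c2"])[ord])
  amplitudes <- unname(c(pars["a1"], pars["a2"])[ord])
  widths <- unname(c(pars["w1"], pars["w2"])[ord])
  amax <- max(amplitudes)
  degenerate <- (centers[2L] - centers[1L]) < step ||
    (amax > 0 && min(amplitudes) / amax < 0.01)
  structure(
    list(baseline = unname(pars["b"]), centers = centers,
         amplitudes = amplitudes, widths = widths,
         residual_norm = sqrt(sum(resid^2)), converged = converged,
         degenerate = degenerate, step = step),
    class = "dlor_fit"
  )
}

#' Dips implied by a double-Lorentzian fit
#'
#' @param fit A `dlor_fit`.
#' @return A `dip_set` with method tag `"lorentzian_fit"`.
#' @export
as_dip_set <- function(fit) {
  stopifnot(inherits(fit, "dlor_fit"))
  out <- data.frame(center = fit$centers, depth = fit$amplitudes,
                    width = fit$widths)
  attr(out, "method") <- "lorentzian_fit"
  attr(out, "baseline") <- fit$baseline
  attr(out, "step") <- fit$step
  class(out) <- c("dip_set", "data.frame")
  out
}

#' Zeeman splitting read from a two-dip set
#'
#' Reports both conventions in play for a split pair: the dip-to-dip
#' separation `c2 - c1` and the per-dip shift `(c2 - c1)/2`. Which one maps
#' to the field is decided downstream by [estimate_field()]'s convention.
#'
#' @param d A `dip_set` with exactly two dips.
#' @return List with `separation` and `per_dip_shift`, MHz.
#' @export
measure_splitting <- function(d) {
  stopifnot(inherits(d, "dip_set"))
  if (nrow(d) != 2L)
    stop("expected exactly 2 dips, found ", nrow(d))
  sep <- d$center[2L] - d$center[1L]
  list(separation = sep, per_dip_shift = sep / 2)
}
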