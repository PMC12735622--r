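#' NV-center model parameters
#'
#' Physical constants of the NV spin-1 ground-state model, in frequency units
#' (MHz) and magnetic-field units of millitesla, so that the gyromagnetic
#' ratio carries the field's standard value of 28 MHz/mT.
#'
#' @param D Zero-field splitting in MHz. Default 2870 (the ~2.87 GHz
#'   separation between the m = 0 and m = +/-1 sublevels).
#' @param gamma_e Gyromagnetic ratio of the NV electron spin, MHz/mT.
#'   Default 28.
#' @param A_hf Hyperfine splitting between adjacent nitrogen nuclear-spin
#'   lines, MHz. Default 2.16, the 14N literature value; set to 0 to disable
#'   hyperfine structure.
#' @param strain_E Transverse zero-field (strain) term, MHz. Default 0.
#'
#' @return An object of class `nv_params`.
#' @examples
#' p <- nv_params()
#' zeeman_shift(1.7, p) # 47.6 MHz
#' @export
nv_params <- function(D = 2870, gamma_e = 28, A_hf = 2.16, strain_E = 0) {
  if (!is.numeric(D) || length(D) != 1L || !is.finite(D) || D <= 0)
    stop("`D` must be a single positive number (MHz)")
  if (!is.numeric(gamma_e) || length(gamma_e) != 1L || !is.finite(gamma_e) || gamma_e <= 0)
    stop("`gamma_e` must be a single positive number (MHz/mT)")
  if (!is.numeric(A_hf) || length(A_hf) != 1L || !is.finite(A_hf) || A_hf < 0)
    stop("`A_hf` must be a single nonnegative number (MHz)")
  if (!is.numeric(strain_E) || length(strain_E) != 1L || !is.finite(strain_E) || strain_E < 0)
    stop("`strain_E` must be a single nonnegative number (MHz)")
  structure(
    list(D = D, gamma_e = gamma_e, A_hf = A_hf, strain_E = strain_E),
    class = "nv_params"
  )
}

#' @export
print.nv_params <- function(x, ...) {
  cat("NV model parameters:\n")
  cat(sprintf("  D        = %g MHz (zero-field splitting)\n", x$D))
  cat(sprintf("  gamma_e  = %g MHz/mT\n", x$gamma_e))
  cat(sprintf("  A_hf     = %g MHz (hyperfine)\n", x$A_hf))
  cat(sprintf("  strain_E = %g MHz\n", x$strain_E))
  invisible(x)
}

#' NV orientation (unit axis in the lab frame)
#'
#' @param axis Numeric 3-vector; normalized to unit length internally.
#' @return A unit-norm numeric 3-vector of class `nv_orientation`.
#' @export
nv_orientation <- function(axis) {
  if (!is.numeric(axis) || length(axis) != 3L || any(!is.finite(axis)))
    stop("`axis` must be a finite numeric 3-vector")
  nrm <- sqrt(sum(axis^2))
  if (nrm == 0) stop("`axis` must be nonzero")
  structure(axis / nrm, class = "nv_orientation")
}

check_field_vec <- function(B) {
  if (!is.numeric(B) || length(B) != 3L || any(!is.finite(B)))
    stop("magnetic field must be a finite numeric 3-vector (mT)")
  invisible(B)
}

#' First-order Zeeman shift of an aligned NV resonance
#'
#' The per-dip shift `gamma_e * B` of the m = +/-1 resonances for an NV whose
#' axis is parallel to the applied field. At 1.7 mT this is 47.6 MHz; a 4 nT
#' action-potential-scale field gives 1.12e-4 MHz (112 Hz).
#'
#' @param B_magnitude Field magnitude, mT (scalar or vector, `>= 0`).
#' @param params [nv_params()].
#' @return Shift(s) in MHz.
#' @export
zeeman_shift <- function(B_magnitude, params = nv_params()) {
  if (!is.numeric(B_magnitude) || any(!is.finite(B_magnitude)) || any(B_magnitude < 0))
    stop("`B_magnitude` must be nonnegative and finite (mT)")
  params$gamma_e * B_magnitude
}

# Spin-1 operators in the |+1>, |0>, |-1> basis. Sy only enters through
# Sx^2 - Sy^2, which is real, so the Hamiltonian stays real symmetric.
spin1_sz <- function() diag(c(1, 0, -1))
spin1_sx <- function() matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3, 3) / sqrt(2)
spin1_sx2_minus_sy2 <- function() matrix(c(0, 0, 1, 0, 0, 0, 1, 0, 0), 3, 3)

#' Secular-approximation transition frequencies
#'
#' Keeps only the field component along the NV axis:
#' `f_pm = D +/- gamma_e * |B . axis|`. This is the printed two-level form of
#' the spin Hamiltonian; it is exact for an aligned field and ignores
#' transverse-field mixing.
#'
#' @param B Lab-frame field 3-vector, mT.
#' @param orient [nv_orientation()] (or any 3-vector, normalized internally).
#' @param params [nv_params()].
#' @return Numeric `c(f_minus, f_plus)` in MHz, `f_minus <= f_plus`.
#' @export
transition_frequencies_secular <- function(B, orient, params = nv_params()) {
  check_field_vec(B)
  orient <- nv_orientation(unclass(orient))
  proj <- abs(sum(B * orient))
  c(params$D - params$gamma_e * proj, params$D + params$gamma_e * proj)
}

#' Full-diagonalization transition frequencies
#'
#' Diagonalizes the 3x3 spin-1 Hamiltonian
#' `D Sz^2 + strain_E (Sx^2 - Sy^2) + gamma_e (B . S)` in the NV frame and
#' returns the two transitions from the eigenstate adiabatically connected to
#' m = 0 to those connected to m = -/+1, sorted ascending. The transverse
#' field component is placed along the NV-frame x axis; with `strain_E = 0`
#' the result is independent of that choice. Valid for `gamma_e |B| << D`
#' (the m = 0-connected state is then the lowest eigenstate).
#'
#' Unlike the secular form, this captures the second-order repulsion of the
#' levels for misaligned fields -- the physics behind powder broadening when
#' the field is nearly perpendicular to an NV axis.
#'
#' @inheritParams transition_frequencies_secular
#' @return Numeric `c(f_minus, f_plus)` in MHz, sorted ascending.
#' @export
transition_frequencies_full <- function(B, orient, params = nv_params()) {
  check_field_vec(B)
  orient <- nv_orientation(unclass(orient))
  b_par <- sum(B * orient)
  b_tot2 <- sum(B^2)
  b_perp <- sqrt(max(b_tot2 - b_par^2, 0))
  H <- params$D * spin1_sz() %*% spin1_sz() +
    params$strain_E * spin1_sx2_minus_sy2() +
    params$gamma_e * (b_par * spin1_sz() + b_perp * spin1_sx())
  ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
  if (any(!is.finite(ev)))
    stop("eigensolve of the spin Hamiltonian did not converge")
  ev <- sort(ev)
  # lowest eigenvalue is the m = 0-connected level for gamma_e|B| << D
  sort(c(ev[2] - ev[1], ev[3] - ev[1]))
}

#' Hyperfine components of a resonance line
#'
#' Coupling to the 14N nuclear spin (I = 1) splits each electron-spin
#' resonance into three equally weighted lines separated by `A_hf`.
#'
#' @param f_center Line center, MHz.
#' @param params [nv_params()]; `A_hf = 0` collapses to one line of weight 1.
#' @return `data.frame(frequency, weight)`, weights summing to 1.
#' @export
hyperfine_components <- function(f_center, params = nv_params()) {
  stopifnot(is.numeric(f_center), length(f_center) == 1L, is.finite(f_center))
  if (params$A_hf == 0)
    return(data.frame(frequency = f_center, weight = 1))
  data.frame(
    frequency = f_center + c(-params$A_hf, 0, params$A_hf),
    weight = rep(1 / 3, 3)
  )
}

#' The four NV crystallographic axes of diamond
#'
#' Unit vectors along (1,1,1), (1,-1,-1), (-1,1,-1), (-1,-1,1); pairwise dot
#' products are -1/3. With the lab field along Z = (0,0,1) all four families
#' share |cos theta| = 1/sqrt(3), so a [001]-oriented bulk sample shows a
#' single well-defined split pair.
#'
#' @return A 4 x 3 numeric matrix, one unit axis per row.
#' @export
tetrahedral_axes <- function() {
  m <- rbind(
    c(1, 1, 1),
    c(1, -1, -1),
    c(-1, 1, -1),
    c(-1, -1, 1)
  ) / sqrt(3)
  rownames(m) <- c("111", "1-1-1", "-11-1", "-1-11")
  m
}
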