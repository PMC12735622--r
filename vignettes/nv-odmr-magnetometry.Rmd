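---
title: "Simulating and analyzing CW-ODMR spectra for NV magnetometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analyzing CW-ODMR spectra for NV magnetometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nvodmr)
```

## The measurement this package models

Nitrogen-vacancy (NV) centers in diamond are spin-1 defects whose
photoluminescence (PL) drops when a microwave drive is resonant with a
ground-state spin transition. Sweeping the microwave frequency while
recording PL — continuous-wave optically detected magnetic resonance
(CW-ODMR) — therefore produces a spectrum with dips at the transition
frequencies. At zero field both transitions sit at the zero-field splitting
$D \approx 2870$ MHz; an applied magnetic field splits them, to first order
by $\pm \gamma_e B_\parallel$ with $\gamma_e = 28$ MHz/mT and $B_\parallel$
the projection of the field on the NV symmetry axis. Reading the splitting
back out of a measured spectrum is magnetometry.

The package covers the full loop for three sample geometries:

* a **single NV** (one axis),
* an **oriented bulk ensemble** — the four crystallographic NV families of a
  [001]-cut diamond, which all project onto a lab-Z field at
  $|\cos\theta| = 1/\sqrt3$ and hence show one well-defined split pair,
* a **nanodiamond powder** — axes drawn isotropically on the sphere, as for
  nanodiamonds suspended in solution or taken up by cells, whose
  orientation-distributed Zeeman splittings smear the pair into a broad band
  spanning $D \pm \gamma_e |B|$.

## Spin model

The working Hamiltonian (in frequency units, MHz; fields in mT) is

$$H = D S_z^2 + E\,(S_x^2 - S_y^2) + \gamma_e\, \mathbf{B}\cdot\mathbf{S}.$$

Two evaluation modes are provided:

* `transition_frequencies_secular()` keeps only the axial field component:
  $f_\pm = D \pm \gamma_e |\mathbf{B}\cdot\hat n|$. This is exact for an
  aligned field and is the two-line form usually quoted for ODMR
  magnetometry.
* `transition_frequencies_full()` diagonalizes the $3\times3$ matrix. The
  transverse component is placed along the NV-frame $x$ axis; with the
  default $E = 0$ the spectrum does not depend on that choice. The full mode
  matters for powders, which always contain near-perpendicular geometries
  where the secular form misses the second-order level repulsion of order
  $(\gamma_e B)^2/D$ (0.79 MHz at 1.7 mT). The identification of the
  $m=0$-connected eigenstate with the lowest eigenvalue is valid for
  $\gamma_e|B| \ll D$, i.e. fields well below ~100 mT; all study conditions
  are in the single-mT range.

Defaults follow the field's standard constants: $D = 2870$ MHz,
$\gamma_e = 28$ MHz/mT. The hyperfine splitting to the $^{14}$N nuclear spin,
`A_hf = 2.16` MHz, is a literature constant (it is not printed in the study
this package emulates); it expands each electron-spin line into an equally
weighted triplet. The strain term `strain_E` defaults to zero and exists
only so strain-split zero-field spectra can be emulated if desired.

## Forward spectra and the synthetic spectrometer

`ensemble_spectrum()` superposes a unit-amplitude Lorentzian dip per
transition line,

$$\mathrm{PL}(f) = 1 - C \sum_i w_i\,
\frac{(w/2)^2}{(f-c_i)^2 + (w/2)^2},$$

with orientation weights split equally over the two transitions (and over
hyperfine components when enabled). Lorentzian lineshapes are chosen because
field-split bulk spectra are conventionally fit with a double-Lorentzian
model; linewidth and contrast are *effective* parameters — microwave power
broadening is deliberately not modeled.

The emulated study conditions, used as defaults throughout:

| parameter | default | meaning |
|---|---|---|
| sweep | 2800–3000 MHz, 1 MHz step | the printed CW sweep (201 points) |
| `fwhm` | 10 MHz | effective dip width (not printed; typical CW value) |
| `contrast` | 0.02 | fractional PL drop per fully weighted line (not printed) |
| `baseline_rate` | $10^5$ counts/point | off-resonant CCD counts (not printed) |
| `background_rate` | 500 counts/point | spectrometer dark counts |
| `drift_amplitude` | 0.01 | per-scan smooth baseline drift bound (laser stability "below 1%") |
| powder size | 2000 axes | Monte-Carlo fidelity knob |

`generate_scan()` turns a noiseless model into CCD-like data: expected
counts `baseline_rate * (1 + drift) * relative_pl + background_rate`, with a
random-amplitude half-sine drift per scan and optional Poisson shot noise,
all reproducible from a single seed. `fixture_presets()` packages the three
study conditions (zero-field powder, powder at 1.7 mT, bulk at 1.7 mT along
lab Z) as 2–3 replicate scans plus a dark frame, mirroring the protocol of
averaging two or three measurements. Orientation sampling is Monte-Carlo
rather than deterministic quadrature: it matches the physical picture of
discrete nanodiamonds and makes the orientation count an explicit fidelity
knob.

What the generator does **not** emulate: wavelength-domain CCD output,
power broadening, optical pumping dynamics, NV density variation between
nanodiamonds (orientation weights absorb multiplicity), or any
cell-generated field. Passing tests therefore validate the analysis chain
against this idealized instrument, not against raw laboratory spectra.

## The analysis chain

`run_pipeline()` executes the chain in the order the measurements are
processed:

1. **Average replicates** (`average_scans()`): pointwise mean over an
   identical grid; mismatched grids are an error, never silently
   interpolated.
2. **EM background subtraction** (`em_background_fit()` +
   `subtract_background()`): a hand-written 1-D Gaussian-mixture EM with
   deterministic initialization (means at the 10th/90th percentiles for
   $k=2$, equal weights, pooled variance; `tol = 1e-8` on the relative
   log-likelihood, `max_iter = 500`). The background level is the mean of
   the heaviest low-mean component. The mixture is fit to **dark-frame
   counts**: which data the published subtraction ran on is not stated, and
   fitting the scan itself would estimate the PL baseline rather than the
   spectrometer background — subtracting dark counts is the only reading
   under which the recovered baseline matches the known generator baseline.
   Spectra loaded without a dark frame skip the step with a processing note.
3. **Smoothing** (`smooth_spectrum()`): centered moving average, default
   window 5, truncated at the edges — the least-assumptive smoother.
4. **Spline resampling** (`spline_resample()`): interpolating natural cubic
   spline through the smoothed points, refined 10x by default (the
   "continuous line through the data" representation used for powder
   spectra).
5. **Dip extraction**: either `detect_dips()` (powder branch — a powder
   band is explicitly *not* representable as a sum of two Lorentzians) or
   `double_lorentzian_fit()` (bulk branch, Levenberg–Marquardt via
   minpack.lm, initialized from dips detected on a lightly smoothed copy
   and always fit to the unsmoothed input).
6. **Splitting and field** (`measure_splitting()`, `estimate_field()`).

### Numerical choices that matter

* **Prominence, not depth.** `detect_dips()` ranks local minima by
  topographic prominence — depth above the higher of the two saddles
  separating the minimum from deeper ones. Ranking by raw depth treats
  noise wiggles on the flank of a broad dip as separate dips and corrupts
  every downstream splitting readout.
* **Parabolic center refinement** through the three points around each
  minimum removes the grid-quantization bias (it is exact for a symmetric
  dip sampled on a uniform grid).
* **Degenerate double fits** are flagged when the two centers collapse to
  within one grid step or one amplitude falls below 1% of the other —
  single-dip data pushed through a two-dip model must not masquerade as a
  splitting.
* **Estimator precision.** At the default count rates (2% contrast,
  $10^5$ counts, 10 MHz width), the statistical standard error of a fitted
  dip center is 0.4–1.2 MHz per scan — the least-squares optimum itself
  scatters by that much over noise realizations. Tests of noisy recovery
  therefore assert ensemble means over fixed seeds rather than single
  draws, and accuracy claims below the 0.1 MHz level are only meaningful
  for noiseless inputs.

### Field conventions

A measured separation $\Delta$ maps to a field differently per geometry,
so `estimate_field()` requires an explicit convention:
aligned, $B = \Delta/2\gamma_e$; bulk tetrahedral,
$B = \sqrt3\,\Delta/2\gamma_e$; powder edge, $B$ from the outer band edges
(outermost frequencies whose depth exceeds half the maximum), which for a
powder is where the field information actually lives — the interior dip
structure of a powder band does not track $\gamma_e B$ directly.
`measure_splitting()` always reports both the dip-to-dip separation and the
per-dip shift, because a printed "splitting" can mean either; the
convention flag, not the reader's guess, picks the inversion.

The reported uncertainty on $B$ is the grid step propagated in quadrature
over the two dip centers through the inversion slope — a declared
convention for grid-limited readouts, not a full error budget.

## Calibration and sensitivity planning

`calibrate_gamma()` closes the loop: simulate aligned scans at known
fields, extract per-dip shifts, and fit shift versus field by ordinary
least squares. On noiseless scans at 0.5/1.0/1.5/2.0 mT the slope comes
back 28.02 MHz/mT against the generator's 28 — the residual 0.02 is the
dip-overlap pull of two Lorentzians at finite separation, not an error in
the chain.

`required_frequency_resolution()` converts a target field to the sweep
resolution needed to resolve its first-order shift: 47.6 MHz for the
1.7 mT coil field (trivially resolved at a 1 MHz step), but 112 Hz for the
4 nT scale of neuron action-potential fields — which is why hertz-level RF
resolution, not better optics, is the gating requirement for cellular
magnetometry with this readout.

## Problem sizes and runtime

The test suite and the analysis scripts run powder ensembles of 2000 axes
(20000 where band-edge convergence is itself the property under test),
201-point sweeps, and noisy-recovery ensembles of 6–12 seeds; the full
suite completes in well under a minute on one core. These sizes put
Monte-Carlo scatter comfortably below the tolerances being asserted and
are stated here as the package's own choices.

## Known limitations

* The secular/full pairing covers misaligned fields, but hyperfine
  structure is attached *after* the electronic transition frequencies are
  computed — nuclear-state mixing at high transverse fields is not modeled.
* The powder band model assumes isotropic orientations; partially aligned
  or surface-attached nanodiamond populations would need a custom
  `orientation_ensemble`.
* The EM background model is a two-component Gaussian mixture on count
  values; structured backgrounds (fringes, wavelength-dependent response)
  are out of scope.
* `estimate_field()` inverts a scalar magnitude only — vector magnetometry
  from multi-family spectra is deliberately not implemented.
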