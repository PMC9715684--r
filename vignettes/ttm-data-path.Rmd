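---
title: "The single-photon time-tagging data path: models, conventions, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The single-photon time-tagging data path}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ttmtools)
```

This vignette is the package's own account of the science it implements:
the measurement model of an FPGA time-tagging module (TTM) for SPAD-array
laser-scanning microscopy, the calibration theory, the two downstream
analyses (FLISM and FLFS), what the synthetic-data generator emulates, and
every numerical convention a maintainer would want stated.

## 1. The measurement model

A pulsed laser excites the sample; a detector array (default 5×5 = 25
elements) detects single photons. The module runs a free-running 16-bit
coarse counter at 240 MHz (`T_sysclk = 1/240 MHz ≈ 4.1667 ns`). Each
photon channel owns a *tapped delay line* (TDL): the asynchronous photon
edge enters the line and propagates until the next rising clock edge; the
tap it reached encodes the sub-clock interval with ~48 ps granularity (the
LSB). All channels share one STOP line for the laser SYNC. Because both
lines are asynchronous to the clock (a *sliding-scale* arrangement), code
usage is statistically uniformized, which (i) averages out differential
nonlinearity and (ii) enables self-calibration (§3).

The start–stop time of a photon — its delay to the next laser pulse, the
reverse start–stop convention — is reconstructed as

    Δt = Δt_STOP − Δt_START + Δn · T_sysclk ,   Δn = n_SYNC − n_photon ≥ 0.

**Edge convention.** The TDL physically captures `edge_time − event_time`
(event to *next* edge); the printed formula above uses times measured from
the *previous* edge, `T_sysclk − captured`. The two are algebraically
identical (`Δt = cap_START − cap_STOP + Δn·T`); the codec stores the
captured code, the calibration maps code → captured interval, and
`calibrate_tables()` evaluates the formula in that form. Coarse times are
exact integer arithmetic: `t̂_photon = n_photon·T_sysclk`, REF delays
`(n_photon − n_REF)·T_sysclk`, and the absolute SYNC time
`t_SYNC = n_SYNC·T_sysclk − cap_STOP`.

The dead time of a fine TDC is one line traversal (~4.2 ns, shorter than
SPAD hold-off); the simulator drops and counts violating events.

## 2. The wire format

Each transmitted structure is a 16-bit-word sequence: a 7-bit ID, 1-bit
valid flag, 8-bit payload per word. Five header words (IDs 123–127, in
order: REF flags + "laser data valid" bit, SYNC tap code, STEP low byte,
STEP high byte, spare byte) are followed by one word per channel hit in
ascending channel order; channels without hits transmit nothing (zero
suppression). On the 32-bit transfer link two words are packed
little-endian; on disk the `.ttm` file is a 4-byte preamble (`TTM` + the
format version byte 1) followed by the flat little-endian word sequence.

A structure is transmitted only on: a photon START; the first STOP (SYNC)
after one or more pending STARTs; a REF event (pixel/line/frame clock); or
a force-write at least once per 1/16 of the coarse-counter rollover
(2^16/240 MHz/16 ≈ 17.07 µs), which guarantees the 16-bit counter can
always be unwrapped. The decoder validates header order and ascending
channel IDs; corrupt structures are skipped and counted rather than
aborting — the software analogue of the hardware's fail-safe priority.

Two conventions the hardware description leaves open, fixed here and kept
stable: the exact header payload layout above, and "transmit the *first*
STOP after ≥1 START" (not every subsequent SYNC). When a photon and its
SYNC share one clock frame, the tap codes disambiguate the order (a larger
code means earlier in the cycle).

## 3. Calibration

**Code density.** Temporally random events populate TDL codes in
proportion to the physical tap widths, so a histogram of ≥10^5
uncorrelated events measures `width_i = (count_i/Σ)·T_sysclk` directly.
The code→time map uses the **bin-center convention**
(`Δt(k) = Σ_{i<k} w_i + w_k/2`), which minimizes quantization bias; the
convention is a package decision, documented rather than inherited.
Because the line is deliberately slightly longer than the clock period,
the final tap is only partially exercised; its *effective* width is
estimated, which is what reconstruction needs. DNL is
`w_i/LSB_ideal − 1` with `LSB_ideal = T_sysclk/n_codes`; INL is its
cumulative sum; both reported as population SDs in LSB units, invariant
to count rescaling.

**Single-shot precision (SSP)** is the Gaussian-fit σ of the start–stop
histogram of a constant true delay (least squares with Poisson weights,
sample-SD fallback, non-unimodality warning). One ideal 48 ps quantizer
over uniformly spread phases contributes 48/√12 ≈ 13.9 ps; with the
clock-commensurate test-bench SYNC the STOP side contributes only a fixed
bias, so an injected jitter σ_j yields √(σ_j² + 13.9²).

**Inter-channel alignment.** Each element/TDC adds a fixed delay. A
reference measurement of a known single-exponential dye (fluorescein,
τ = 4.1 ns) is phasor-transformed per channel; the phase excess over
`atan(ωτ_ref)` divided by ω is the channel offset, applied as a circular
Fourier shift (amplitude-free, bin-width independent). Offsets below the
counting floor (<100 counts) are zeroed with a warning.

## 4. The simulator: the stated world

Event generation is continuous-time float64 nanoseconds; quantization
happens *only* in `tdc_encode()`, so ground truth stays exact. Defaults
are chosen once as a realistic microscope and not revisited:

* Laser 40 MHz (25 ns period; 5–80 MHz supported), lifetime 4 ns, IRF
  σ = 0.1 ns, uniform background fraction as stated per experiment.
* TDL: 87 taps of 48 ps (span 4.176 ns > T_sysclk). The tap count is a
  package choice (only the LSB is fixed by the hardware description);
  non-uniform lines draw log-normal widths at 5% dispersion for
  calibration tests.
* Detector: 5×5 elements, detection volumes laterally shifted copies of a
  Gaussian. Imaging: pitch 0.09 µm in sample space, PSF FWHM 0.25 µm,
  pixels 0.05 µm. Fluctuation work: pitch 0.15 µm, ω₀ = 0.3 µm,
  eccentricity k = 4.5 (central) / 4.1 (summed volumes).
* Diffusion: Brownian steps of 10 µs (≪ τ_D = 1.5 ms at D = 15 µm²/s) in
  a periodic box, photons as an inhomogeneous Poisson process with rates
  frozen within a step; compiled with a self-contained xoshiro256+ RNG so
  streams are reproducible from an integer seed.
* SYLAP test bench: fixed-frequency clock (2.5 ns granularity), decimated
  delayed pulse train (39.0625 ps delay granularity), optional Gaussian
  jitter; off-grid values are rounded with a warning.

**What a green test does not establish.** The simulator's channels share
one brightness and one PSF shape (no per-element efficiency or cross-talk
spectra); its effective per-channel PSF is a *single* shifted Gaussian, so
pixel reassignment recovers resolution by unsmearing the open sum, not by
element-wise PSF narrowing as in a physical product-of-Gaussians system;
cross-talk and afterpulsing are stylized (neighbour echo with a fixed bump
distribution); SPAD hold-off, pile-up and laser pulse shape are not
modelled. Periodic boundaries quantize diffusive relaxation: modes slower
than ~(L/2π)²/D are absent, so correlation tails beyond ~25 ms (for the
default 4×4×6 µm box) are artificially suppressed — FCS fits therefore
restrict lags to ≤20 ms (§6). Box size 4×4×6 µm at 0.5 particles/µm³ (48
particles) balances that cutoff against simulation cost.

## 5. FLISM conventions

* Binning is left-edged on the TCSPC delay (start–stop delay modulo the
  laser period), default 48 ps bins; photons before the first pixel clock
  carry x = −1 and are excluded from images, never silently dropped from
  counts.
* Registration of channel images to the central element uses Fourier
  cross-correlation with sub-pixel refinement by matrix-multiply DFT
  upsampling (±1 px window, 20×). Full spectral whitening (classic phase
  correlation) is available (`whiten = "phase"`) but the default keeps
  spectral amplitudes: at photon-counting noise levels whitening amplifies
  empty high frequencies, and for the symmetric PSFs of this problem the
  matched-filter peak is unbiased.
* APR shifts every Δt plane of a channel by the *same* fingerprint vector
  (Fourier shift, circular), then sums channels. Sums are conserved up to
  border wrap; the reconstruction logs totals.
* Lifetime maps: per-pixel count-weighted linear regression of log counts
  on the post-peak window [argmax, argmax + 10 ns] — the same crop used by
  the FLFS filters, kept for consistency. Pixels under the count threshold
  are masked (NA). Aggregate histograms use the full nonlinear
  `A·exp(−t/τ) + B` fit instead.
* Phasors use bin-center times at ω = 2π/period; the finite bin
  attenuates the transform by sinc(ωb/2), divided out by default
  (toggleable). Referencing rotates/scales by a measured reference phasor
  against its theoretical position — full phase *and* modulation for the
  system IRF; channel *alignment* (§3) corrects phase only, because fixed
  cable/TDC delays are pure phase.
* FRC: photons are split odd/even on the raw START tap code (sliding
  scale ⇒ near-uniform code usage ⇒ balanced independent halves), images
  reconstructed separately, ring-normalized cross-correlation smoothed
  over ±2 rings, resolution at the fixed 1/7 threshold crossing (linear
  interpolation between rings; alternatives exist, the constant is
  documented and fixed).

## 6. FLFS conventions

* The absolute photon time is the `t_SYNC` of its associated SYNC event —
  exact to one laser period, which is irrelevant at FCS time scales.
* The correlator bins timestamps at 1 µs and runs a multi-tau cascade:
  lags 1–16 bins, then 9–16 after each factor-2 coarsening (8 points per
  octave), estimator `G(τ) = ⟨c_k c_{k+m}⟩/(mean_head·mean_tail) − 1`
  (0-baseline fluctuation form; add 1 for the display convention). An
  independent brute-force R implementation of the same estimator serves
  as the oracle; the two agree to float precision, with and without
  weights, and weights ≡ 1 reduce exactly to the unweighted path.
* Chunks default to 5 s; chunks whose count rate or early-lag amplitude
  deviates >3 robust σ from the median are rejected automatically — a
  reproducible replacement for visual curve inspection.
* FCS models: point `G(τ) = (1/N)(1+τ/τ_D)⁻¹(1+τ/(k²τ_D))^(−1/2)`;
  circular scanning multiplies by
  `exp(−(4R²/ω₀²)·sin²(πτ/T_scan)/(1+τ/τ_D))` (beam displacement
  `2R·sin(πτ/T)` relaxed by diffusion), which is 1 at τ = mT and reduces
  to the point model at R = 0. Because multi-tau lag bins are wide at
  large lags, the fitted model is averaged over each lag's triangular
  binning kernel with a quadrature dense enough to resolve the scan
  oscillation — without this the oscillating factor aliases and biases
  τ_D. Fits are Nelder-Mead least squares in log-parameters with inverse
  chunk-variance weights; circular-scan data must be fitted with the
  circular model (the point model on scanned data is misspecified and
  biases amplitudes). Fit range defaults to all lags; on simulated data
  lags are restricted to ≤20 ms (periodic-box cutoff, §4).
* FLCS: crop [peak, peak + 10 ns], fit `A·exp(−t/τ_fl) + B`; bins with
  counts ≤ B + 3√B are removed as almost-certainly background (Poisson
  criterion); filters come from the patterns {normalized exponential,
  uniform B/A} by the standard weighted-least-squares construction with
  the *fitted* histogram as the variance model, which makes the two
  filters sum to exactly 1 on every retained bin. If B̂ ≈ 0 the
  construction degenerates gracefully to filter ≡ 1. Per-photon weight =
  fluorescence filter at the photon's delay bin; removed bins weight 0.
  With a background fraction B/(S+B), the unfiltered amplitude is biased
  by (1 + B/S)²; filtering restores it.
* Spot variation: linear fit of τ_D against fitted ω₀² across detection
  volume classes (central / sum3×3 / sum5×5 — the latter excludes the
  four corner elements); slope 1/(4D), intercept ≈ 0 for free diffusion.
  Note the summed volumes are sums of shifted Gaussians, *approximated*
  as Gaussians by the fit — good to a few percent here, and the reason
  the law's slope-D can differ more from truth than the central-element
  D.
* Lifetime-vs-time: fixed 5 s windows, per-window decay fit and
  (optionally) the D_central/D_5×5 mobility ratio; windows under 10³
  photons are masked.

## 7. Degenerate inputs and numerical guards

Empty streams decode to empty tables; truncated final frames are dropped
with a warning; a stream with no SYNC discards all photons and counts
them; empty channel tables are legal everywhere (HDF5 skips the empty
compound datasets and the reader reconstitutes them). The decay fitter
falls back to NA on failure; the SSP fitter falls back to the sample SD;
FLCS disables itself (weights ≡ 1, warning) when its fit fails or the
crop is shorter than 8 bins. `fmod` is avoided in compiled code (glibc
symbol-version portability); periodic wrapping uses floor arithmetic.

## 8. Known limitations

Only single-frame rasters are exercised by the shipped analyses (the
binning supports frame stacks); lifetime fitting is single-exponential
(no global or multi-exponential fitting, no deconvolution-based ISM
variants); cross-correlation between channels, pair-correlation imaging
and the broader comprehensive-correlation suite are out of scope; the
simulator's cross-talk/afterpulsing are qualitative stand-ins; the
streaming path is batch, not online.
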