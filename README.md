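# ttmtools

Single-photon time-tagging data path for laser-scanning microscopy, in R.

Modern single-photon laser-scanning microscopy (SP-LSM) records every
photon from a SPAD array detector with a spatial tag (which detector
element fired) and temporal tags (delay from the last laser pulse, the
*start–stop time*; delay from pixel/line/frame clocks; absolute arrival
time). An FPGA time-tagging module (TTM) produces these tags with a
sliding-scale time-to-digital converter (TDC): per-channel tapped delay
lines give ~50 ps granularity for the start–stop time, and a free-running
16-bit counter at 240 MHz gives ~4.2 ns precision over unlimited range for
everything else. The tags are streamed to the host as a compact,
zero-suppressed 16-bit word format.

`ttmtools` implements that whole data path in software, plus the physics
needed to test it without hardware:

* **words** — bit-exact encoder/decoder for the frame-like word stream
  (5-word headers, zero suppression, the event filter's four transmission
  conditions, force-write keep-alives every 1/16 of the counter rollover).
* **simulate** — continuous-time physics simulator: pulsed-laser
  fluorescence decays (exponential ⊛ Gaussian IRF + uniform background),
  SYLAP-style test-bench signals, raster-scanned samples seen through a
  5×5 array of shifted detection volumes, Brownian diffusion for FCS
  (compiled core), and serialization of it all into `.ttm` word streams
  with exact ground truth.
* **calibrate** — statistical code-density calibration of the delay lines
  (tap widths from code occupancy of asynchronous events), DNL/INL,
  start–stop reconstruction `Δt = Δt_STOP − Δt_START + Δn·T_sysclk`,
  single-shot precision, phasor-based inter-channel alignment.
* **tables** — counter unwrapping, reverse start–stop matching, scan
  coordinate assignment, HDF5 event tables (`/main`, `/ch00`…`/ch24`).
* **flism** — 4D photon binning (ch, x, y, fr, Δt), adaptive pixel
  reassignment (APR) from a phase-correlation shift fingerprint, per-pixel
  single-exponential lifetime maps, phasor analysis
  (`g = Σc·cos(ωt)/Σc`, `s = Σc·sin(ωt)/Σc`), and Fourier ring correlation
  resolution from an odd–even photon split on the raw tap codes.
* **flfs** — multi-tau photon-timestamp correlator (compiled, with an
  independent brute-force oracle), chunking with automated outlier
  rejection, FLCS filter functions from `H(t) = A·exp(−t/τ_fl) + B`,
  single-point and circular-scanning FCS fits
  (`G(τ) = (1/N)(1+τ/τ_D)⁻¹(1+τ/(k²τ_D))^(−1/2)`, scanned variant with the
  periodic displacement factor), and the spot-variation diffusion law
  `τ_D(ω₀²)` with `D = ω₀²/(4τ_D)`.

## Worked example: single-shot precision through the full pipeline

```r
library(ttmtools)
set.seed(42)

# 1. test-bench signal: 50 MHz SYNC, pulses decimated 30x, 5 ns delay,
#    30 ps timing jitter
sy <- simulate_sylap(clock_period_ns = 20, pulse_delay_ns = 5,
                     decimation = 30, jitter_sigma_ps = 30,
                     n_pulses = 20000)

# 2. through the sliding-scale TDC and the event filter onto the wire
st <- build_stream(data.frame(t_ns = sy$pulse_ns, channel = 12L),
                   laser_period_ns = 20, tdl = tdl_model())
length(st$words)
#> [1] 220000

# 3. decode, build tables, calibrate with a code-density test
cal <- code_density_calibrate(
  tdc_encode(runif(2e5, 0, 1e6), tdl_model()$start_widths[, 13])$code,
  n_codes = 87)
res <- process_stream(st$words, laser_period_ns = 20, cal, cal)
nrow(res$photons)
#> [1] 20000

# 4. single-shot precision from the reconstructed start-stop times
ssp <- single_shot_precision(res$photons$dt_ns)
round(ssp$sigma_ps, 1)
#> [1] 33.2
sqrt(30^2 + (48/sqrt(12))^2)   # jitter + one 48 ps quantizer
#> [1] 33.04542
```

Every pulse survives the stream round trip (20 000 photons in, 20 000
reconstructed), and the measured precision (33.2 ps) matches the expected
combination of the injected 30 ps jitter with the 48 ps tapped-delay-line
quantization (33.0 ps): the sliding scale works.

## Command line

A thin CLI over the same functions ships in `inst/scripts/ttm.R`:

```sh
Rscript inst/scripts/ttm.R decode run.ttm
Rscript inst/scripts/ttm.R preprocess run.ttm -o tables.h5
Rscript inst/scripts/ttm.R simulate scenario.json -o run.ttm
```

## Documentation

The methods vignette (`vignettes/ttm-data-path.Rmd`) describes the word
format, the TDC model and its calibration, what the simulator does and
does not emulate, the numerical conventions (bin centers, fit ranges,
estimator normalizations), and known limitations.
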