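# ---------------------------------------------------------------------------
# Physics and electronics simulator: synthetic photon events, scan clocks,
# TDC codes and full word streams with known ground truth.  All event
# generation is continuous-time (float64 nanoseconds); quantization happens
# only in tdc_encode, so the ground truth stays exact.
# ---------------------------------------------------------------------------

#' Fluorescence decay model
#'
#' @param lifetime_ns Fluorescence lifetime tau_fl (ns).
#' @param irf_sigma_ns Gaussian instrument-response sigma (ns).
#' @param background_fraction Fraction of photons that are uncorrelated
#'   background, uniform over the laser period; in [0, 1).  The remaining
#'   fraction is fluorescence signal.
#' @param laser_period_ns Laser repetition period (ns); 25 ns = 40 MHz.
#' @param crosstalk_prob Probability that a detected photon spawns an
#'   additional near-simultaneous event on a 4-neighbour channel.
#' @param afterpulse_prob Probability of an exponential-tail echo event.
#' @return Object of class \code{decay_model}.
#' @export
decay_model <- function(lifetime_ns = 4, irf_sigma_ns = 0.1,
                        background_fraction = 0, laser_period_ns = 25,
                        crosstalk_prob = 0, afterpulse_prob = 0) {
  stopifnot(lifetime_ns > 0, irf_sigma_ns >= 0,
            background_fraction >= 0, background_fraction < 1,
            laser_period_ns > 0)
  structure(list(lifetime_ns = lifetime_ns, irf_sigma_ns = irf_sigma_ns,
                 background_fraction = background_fraction,
                 laser_period_ns = laser_period_ns,
                 crosstalk_prob = crosstalk_prob,
                 afterpulse_prob = afterpulse_prob),
            class = "decay_model")
}

#' Draw start-stop delays from a decay model
#'
#' Delays are exponential (tau_fl) convolved with the Gaussian IRF, modulo
#' the laser period; background photons are uniform over the period.
#'
#' @param model A \code{decay_model}.
#' @param n Number of delays.
#' @return Numeric vector of delays in [0, laser_period_ns).
#' @export
draw_delays <- function(model, n) {
  is_bg <- runif(n) < model$background_fraction
  d <- numeric(n)
  nsig <- sum(!is_bg)
  if (nsig) {
    d[!is_bg] <- (rexp(nsig, 1 / model$lifetime_ns) +
                    rnorm(nsig, 0, model$irf_sigma_ns)) %% model$laser_period_ns
  }
  if (any(is_bg)) d[is_bg] <- runif(sum(is_bg), 0, model$laser_period_ns)
  d
}

#' Simulate fluorescence decay photons under pulsed excitation
#'
#' Each laser pulse yields a photon with probability \code{rate} (single
#' photon counting regime, \code{rate << 1}); the photon's delay from its
#' pulse follows the decay model.
#'
#' @param model A \code{decay_model}.
#' @param n_pulses Number of laser pulses.
#' @param rate Photons per pulse (must be << 1).
#' @param channel Channel label(s) for the photons; a single value or a
#'   probability vector over channels 0..length-1.
#' @param seed Optional RNG seed.
#' @return Data frame with \code{t_ns} (absolute time), \code{delay_ns}
#'   (start-stop delay from the pulse) and \code{channel}, sorted by time.
#' @export
simulate_decay_photons <- function(model, n_pulses, rate, channel = 0L,
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (rate > 0.2) warning("rate per pulse is high; pile-up is not modelled")
  n <- rpois(1, n_pulses * rate)
  pulses <- sort(sample.int(n_pulses, n, replace = TRUE)) - 1L
  delays <- draw_delays(model, n)
  ch <- if (length(channel) == 1L) {
    rep(as.integer(channel), n)
  } else {
    sample.int(length(channel), n, replace = TRUE, prob = channel) - 1L
  }
  out <- data.frame(t_ns = pulses * model$laser_period_ns + delays,
                    delay_ns = delays, channel = ch)
  out[order(out$t_ns), , drop = FALSE]
}

#' Simulate the SYLAP-style test-bench signal pair
#'
#' A fixed-frequency clock plus a decimated, delayed, optionally jittered
#' pulse train: the standard fixture for code-density and single-shot
#' precision measurements.  The pulse delay is quantized to the 39.0625 ps
#' hardware granularity and the clock period to 2.5 ns (values off-grid
#' are rounded with a warning).
#'
#' @param clock_period_ns Clock period (ns); 20 ns = 50 MHz.
#' @param pulse_delay_ns Fixed delay of the pulse from its clock edge (ns).
#' @param decimation Pulses are emitted every \code{decimation}-th clock.
#' @param jitter_sigma_ps Gaussian jitter of the pulse (ps).
#' @param n_pulses Number of emitted pulses.
#' @param seed Optional RNG seed.
#' @return List with \code{sync_ns} (all clock edges) and \code{pulse_ns}.
#' @export
simulate_sylap <- function(clock_period_ns = 20, pulse_delay_ns = 5,
                           decimation = 30L, jitter_sigma_ps = 0,
                           n_pulses = 1e5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  grid_delay <- 0.0390625
  qd <- round(pulse_delay_ns / grid_delay) * grid_delay
  if (abs(qd - pulse_delay_ns) > 1e-12) {
    warning(sprintf("pulse delay rounded to the %.7g ns grid: %.7g ns",
                    grid_delay, qd))
  }
  qc <- round(clock_period_ns / 2.5) * 2.5
  if (abs(qc - clock_period_ns) > 1e-12) {
    warning(sprintf("clock period rounded to the 2.5 ns grid: %.7g ns", qc))
  }
  n_clocks <- as.numeric(n_pulses) * decimation
  sync <- (seq_len(n_clocks) - 1) * qc
  base <- (seq_len(n_pulses) - 1) * decimation * qc
  pulse <- base + qd + rnorm(n_pulses, 0, jitter_sigma_ps * 1e-3)
  list(sync_ns = sync, pulse_ns = pulse, delay_ns = qd,
       clock_period_ns = qc)
}

#' SPAD array detector geometry
#'
#' A square array of detector elements whose detection volumes are
#' laterally shifted, scaled copies of the central 3D Gaussian.  Shifts
#' are expressed in sample space (um); the central element has shift
#' (0, 0).
#'
#' @param n_side Elements per side (default 5, i.e. 25 channels).
#' @param pitch_um Projected element pitch in sample space (um).  Default
#'   0.09 um, about the pitch of a 1.4 AU-spanning 5x5 array for a green
#'   dye and a 1.4 NA objective.
#' @param psf_fwhm_um Lateral FWHM of each element's effective PSF for
#'   imaging (um).
#' @param w0_um 1/e^2 lateral waist of the central detection volume for
#'   fluctuation work (um).
#' @param k_central,k_sum Detection-volume eccentricity (axial/lateral) for
#'   the central element and for summed volumes.
#' @return Object of class \code{detector_geometry} with per-channel
#'   \code{shift_x_um}, \code{shift_y_um} (row-major element order) and the
#'   scalar optical parameters.
#' @export
detector_geometry <- function(n_side = 5L, pitch_um = 0.09,
                              psf_fwhm_um = 0.25, w0_um = 0.3,
                              k_central = 4.5, k_sum = 4.1) {
  half <- (n_side - 1) / 2
  ij <- expand.grid(ix = seq_len(n_side) - 1 - half,
                    iy = seq_len(n_side) - 1 - half)
  # row-major channel order: channel = iy * n_side + ix
  ij <- ij[order(ij$iy, ij$ix), ]
  structure(list(n_side = as.integer(n_side),
                 n_channels = as.integer(n_side^2),
                 shift_x_um = ij$ix * pitch_um,
                 shift_y_um = ij$iy * pitch_um,
                 pitch_um = pitch_um, psf_fwhm_um = psf_fwhm_um,
                 w0_um = w0_um, k_central = k_central, k_sum = k_sum),
            class = "detector_geometry")
}

#' Channel index helpers for a square array
#'
#' \code{central_channel} is the middle element; \code{channel_set}
#' returns the 0-based channels of the named detection-volume class:
#' \code{"central"}, \code{"sum3x3"} (the 9 innermost elements) or
#' \code{"sum5x5"} (all elements except the four corners).
#'
#' @param geometry A \code{detector_geometry}.
#' @param set One of "central", "sum3x3", "sum5x5".
#' @return Integer vector of 0-based channel indices.
#' @export
channel_set <- function(geometry, set = c("central", "sum3x3", "sum5x5")) {
  set <- match.arg(set)
  n <- geometry$n_side
  mid <- (n - 1L) %/% 2L
  idx <- function(ix, iy) iy * n + ix
  switch(set,
    central = idx(mid, mid),
    sum3x3 = as.integer(outer((mid - 1L):(mid + 1L),
                              (mid - 1L):(mid + 1L),
                              function(ix, iy) idx(ix, iy))),
    sum5x5 = {
      all_ch <- 0:(n^2 - 1L)
      corners <- c(idx(0L, 0L), idx(n - 1L, 0L), idx(0L, n - 1L),
                   idx(n - 1L, n - 1L))
      setdiff(all_ch, corners)
    })
}

#' @rdname channel_set
#' @export
central_channel <- function(geometry) channel_set(geometry, "central")

#' Raster/circular/point scan configuration
#'
#' @param mode "raster", "circular" or "point".
#' @param nx,ny,n_frames Raster geometry (pixels).
#' @param pixel_dwell_us Pixel dwell time (us).
#' @param pixel_size_um Raster pixel size (um).
#' @param radius_um,period_us Circular-scan radius and period.
#' @return Object of class \code{scan_config}.
#' @export
scan_config <- function(mode = c("raster", "circular", "point"),
                        nx = 64L, ny = 64L, n_frames = 1L,
                        pixel_dwell_us = 100, pixel_size_um = 0.05,
                        radius_um = 0.25, period_us = 1000) {
  mode <- match.arg(mode)
  structure(list(mode = mode, nx = as.integer(nx), ny = as.integer(ny),
                 n_frames = as.integer(n_frames),
                 pixel_dwell_us = pixel_dwell_us,
                 pixel_size_um = pixel_size_um,
                 radius_um = radius_um, period_us = period_us),
            class = "scan_config")
}

#' Simulate a raster-scanned sample with a detector array
#'
#' Each channel's expected count in a pixel follows its shifted Gaussian
#' PSF evaluated at the emitter-beam offset; counts are Poisson.  Pixel,
#' line and frame clock (REF) events are emitted at exact scan boundaries
#' in nested order: a frame event, then per row a line event, then per
#' pixel a pixel event.  Photon absolute times snap to the laser pulse
#' grid plus the decay delay.
#'
#' @param emitters Data frame with \code{x_um}, \code{y_um},
#'   \code{brightness} (expected peak counts per pixel dwell for the
#'   central channel) and optional \code{lifetime_ns}.
#' @param geometry A \code{detector_geometry}.
#' @param scan A \code{scan_config} (raster mode).
#' @param decay A \code{decay_model}; per-emitter lifetimes override
#'   \code{decay$lifetime_ns}.
#' @param dark_rate_hz Uniform dark-count rate per channel.
#' @param seed Optional RNG seed.
#' @return List with \code{photons} (data frame: t_ns, delay_ns, channel,
#'   x, y, fr -- ground truth), \code{ref_ns} (data frame: t_ns, type in
#'   pixel/line/frame) and the scan timing constants.
#' @export
simulate_scan <- function(emitters, geometry, scan,
                          decay = decay_model(), dark_rate_hz = 0,
                          seed = NULL) {
  stopifnot(scan$mode == "raster")
  if (!is.null(seed)) set.seed(seed)
  dwell_ns <- scan$pixel_dwell_us * 1e3
  px_um <- scan$pixel_size_um
  nx <- scan$nx; ny <- scan$ny; nf <- scan$n_frames
  nch <- geometry$n_channels
  sigma <- geometry$psf_fwhm_um / (2 * sqrt(2 * log(2)))
  if (is.null(emitters$lifetime_ns)) {
    emitters$lifetime_ns <- rep(decay$lifetime_ns, nrow(emitters))
  }
  # REF events: frame at frame start, line at row start, pixel at pixel
  # start (pixel event trails the line event by half a clock period so
  # ordering is unambiguous)
  eps <- ttm_clock_period() / 2
  row_dur <- nx * dwell_ns
  frame_dur <- ny * row_dur
  fr_idx <- rep(seq_len(nf) - 1L, each = ny)
  row_idx <- rep(seq_len(ny) - 1L, nf)
  line_t <- fr_idx * frame_dur + row_idx * row_dur
  frame_t <- (seq_len(nf) - 1L) * frame_dur
  pix_t <- rep(line_t, each = nx) + (seq_len(nx) - 1L) * dwell_ns + eps
  ref <- rbind(data.frame(t_ns = frame_t, type = "frame"),
               data.frame(t_ns = line_t + eps / 2, type = "line"),
               data.frame(t_ns = pix_t, type = "pixel"))
  ref <- ref[order(ref$t_ns), , drop = FALSE]
  # expected counts per (pixel, channel, emitter)
  xs <- (seq_len(nx) - 0.5) * px_um
  ys <- (seq_len(ny) - 0.5) * px_um
  photons <- vector("list", nch)
  for (ch in seq_len(nch)) {
    # detection volume of channel ch is centred at beam - shift, so the
    # channel image is the central image translated by +shift/px
    cxs <- outer(xs - geometry$shift_x_um[ch], emitters$x_um, "-")
    cys <- outer(ys - geometry$shift_y_um[ch], emitters$y_um, "-")
    gx <- exp(-cxs^2 / (2 * sigma^2))              # nx x ne
    gy <- exp(-cys^2 / (2 * sigma^2))              # ny x ne
    lam_e <- lapply(seq_len(nrow(emitters)), function(e) {
      emitters$brightness[e] * outer(gx[, e], gy[, e])
    })
    dark <- dark_rate_hz * dwell_ns * 1e-9
    for (e in seq_along(lam_e)) {
      lam <- lam_e[[e]]
      cnt <- array(rpois(length(lam) * nf, rep(lam, nf)), c(nx, ny, nf))
      tot <- sum(cnt)
      if (!tot) next
      w <- which(cnt > 0, arr.ind = TRUE)
      reps <- cnt[cnt > 0]
      xi <- rep(w[, 1], reps) - 1L
      yi <- rep(w[, 2], reps) - 1L
      fi <- rep(w[, 3], reps) - 1L
      t0 <- fi * frame_dur + yi * row_dur + xi * dwell_ns + eps
      u <- t0 + runif(tot, 0, dwell_ns - 2 * eps)
      dm <- decay
      dm$lifetime_ns <- emitters$lifetime_ns[e]
      delay <- draw_delays(dm, tot)
      t_abs <- floor(u / decay$laser_period_ns) * decay$laser_period_ns +
        delay
      photons[[ch]][[length(photons[[ch]]) + 1L]] <-
        data.frame(t_ns = t_abs, delay_ns = delay, channel = ch - 1L,
                   x = xi, y = yi, fr = fi)
    }
    if (dark > 0) {
      ndark <- rpois(1, dark * nx * ny * nf)
      if (ndark) {
        td <- runif(ndark, 0, nf * frame_dur)
        pix <- floor(td / dwell_ns)
        delay <- runif(ndark, 0, decay$laser_period_ns)
        photons[[ch]][[length(photons[[ch]]) + 1L]] <-
          data.frame(t_ns = floor(td / decay$laser_period_ns) *
                       decay$laser_period_ns + delay,
                     delay_ns = delay, channel = ch - 1L,
                     x = as.integer(pix %% nx),
                     y = as.integer((pix %/% nx) %% ny),
                     fr = as.integer(pix %/% (nx * ny)))
      }
    }
  }
  parts <- unlist(photons, recursive = FALSE)
  ph <- if (length(parts)) do.call(rbind, parts) else NULL
  if (is.null(ph)) {
    ph <- data.frame(t_ns = numeric(0), delay_ns = numeric(0),
                     channel = integer(0), x = integer(0), y = integer(0),
                     fr = integer(0))
  }
  ph <- ph[order(ph$t_ns), , drop = FALSE]
  rownames(ph) <- NULL
  list(photons = ph, ref = ref, dwell_ns = dwell_ns,
       duration_ns = nf * frame_dur,
       laser_period_ns = decay$laser_period_ns)
}

#' Simulate Brownian diffusion through shifted detection volumes
#'
#' Thin wrapper around the compiled diffusion core.  Particles perform
#' Brownian motion in a periodic box; each detector channel sees a 3D
#' Gaussian detection volume laterally shifted by the array geometry, and
#' photons are emitted as an inhomogeneous Poisson process.  Start-stop
#' delays are attached from the decay model afterwards (diffusion and
#' nanosecond decay are separable time scales).
#'
#' @param n_particles Number of particles.
#' @param d_um2_s Diffusion coefficient (um^2/s).
#' @param box_um Box side lengths c(x, y, z) in um.
#' @param geometry A \code{detector_geometry}.
#' @param duration_s Simulated duration (s).
#' @param brightness_hz Peak detected count rate per particle per channel
#'   at the focus centre (Hz).
#' @param scan A \code{scan_config} ("point" or "circular").
#' @param decay A \code{decay_model} for the start-stop delays.
#' @param dt_s Simulation step (s); must be small versus the diffusion
#'   time through the focus.
#' @param seed Integer seed for the compiled RNG (required, reproducible).
#' @return Data frame with \code{t_ns}, \code{delay_ns}, \code{channel},
#'   sorted by time.
#' @export
simulate_diffusion <- function(n_particles, d_um2_s, box_um, geometry,
                               duration_s, brightness_hz = 30e3,
                               scan = scan_config(mode = "point"),
                               decay = decay_model(), dt_s = 1e-5,
                               seed = 1) {
  stopifnot(scan$mode %in% c("point", "circular"))
  R <- if (scan$mode == "circular") scan$radius_um else 0
  Tp <- if (scan$mode == "circular") scan$period_us * 1e-6 else 0
  res <- sim_diffusion_cpp(as.integer(n_particles), d_um2_s,
                           as.numeric(box_um),
                           geometry$shift_x_um, geometry$shift_y_um,
                           geometry$w0_um, geometry$k_central,
                           brightness_hz, duration_s, dt_s, R, Tp,
                           as.numeric(seed))
  ord <- order(res$time_s)
  t_s <- res$time_s[ord]
  ch <- res$channel[ord]
  n <- length(t_s)
  delay <- draw_delays(decay, n)
  t_ns <- floor(t_s * 1e9 / decay$laser_period_ns) * decay$laser_period_ns +
    delay
  data.frame(t_ns = t_ns, delay_ns = delay, channel = as.integer(ch))
}

#' Add detector cross-talk and afterpulsing to a photon stream
#'
#' Stylized SPAD-array artifact model.  With probability
#' \code{crosstalk_prob} a detected photon spawns a near-simultaneous
#' event on a 4-neighbour element, its start-stop delay offset by a fixed
#' "bump" distribution (Gaussian, \code{bump_delay_ns} after the parent).
#' With probability \code{afterpulse_prob} a photon echoes on its own
#' channel after an exponential-tail dead-time-scale delay with a uniform
#' start-stop delay (afterpulses are uncorrelated with the laser).  The
#' artifact events are appended and the stream re-sorted.
#'
#' @param photons Data frame with \code{t_ns}, \code{delay_ns},
#'   \code{channel} (0-based, row-major square array).
#' @param geometry A \code{detector_geometry} (for the neighbour lattice).
#' @param crosstalk_prob,afterpulse_prob Per-photon probabilities.
#' @param bump_delay_ns,bump_sigma_ns Cross-talk bump location and width.
#' @param afterpulse_tau_ns Exponential tail of the afterpulse delay.
#' @param laser_period_ns Laser period for the uniform afterpulse delay.
#' @return The augmented photon data frame (extra column \code{artifact}
#'   with values "", "crosstalk", "afterpulse"), sorted by time.
#' @export
add_detector_artifacts <- function(photons, geometry = detector_geometry(),
                                   crosstalk_prob = 0.01,
                                   afterpulse_prob = 0.01,
                                   bump_delay_ns = 0.3,
                                   bump_sigma_ns = 0.1,
                                   afterpulse_tau_ns = 50,
                                   laser_period_ns = 25) {
  n <- nrow(photons)
  photons$artifact <- rep("", n)
  out <- list(photons)
  nside <- geometry$n_side
  ct <- which(runif(n) < crosstalk_prob)
  if (length(ct)) {
    ix <- photons$channel[ct] %% nside
    iy <- photons$channel[ct] %/% nside
    # pick one in-bounds 4-neighbour
    dx <- cbind(c(1, -1, 0, 0), c(0, 0, 1, -1))
    pick <- sample.int(4, length(ct), replace = TRUE)
    nx_ <- ix + dx[pick, 1]
    ny_ <- iy + dx[pick, 2]
    ok <- nx_ >= 0 & nx_ < nside & ny_ >= 0 & ny_ < nside
    if (any(ok)) {
      dly <- abs(rnorm(sum(ok), bump_delay_ns, bump_sigma_ns))
      out[[length(out) + 1L]] <- data.frame(
        t_ns = photons$t_ns[ct[ok]] + dly,
        delay_ns = (photons$delay_ns[ct[ok]] + dly) %% laser_period_ns,
        channel = as.integer(ny_[ok] * nside + nx_[ok]),
        artifact = "crosstalk")
    }
  }
  ap <- which(runif(n) < afterpulse_prob)
  if (length(ap)) {
    out[[length(out) + 1L]] <- data.frame(
      t_ns = photons$t_ns[ap] + rexp(length(ap), 1 / afterpulse_tau_ns),
      delay_ns = runif(length(ap), 0, laser_period_ns),
      channel = photons$channel[ap],
      artifact = "afterpulse")
  }
  common <- c("t_ns", "delay_ns", "channel", "artifact")
  res <- do.call(rbind, lapply(out, function(d) d[common]))
  res <- res[order(res$t_ns), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Serialize simulated events into a TTM word stream
#'
#' Runs photons, laser SYNC pulses and REF events through the sliding-scale
#' TDC model and the event filter, producing the on-the-wire word stream
#' plus the ground truth needed to verify the decoding pipeline.  Only the
#' first SYNC after one or more pending photons is transmitted
#' (stop-after-start); force-write frames keep the coarse counter
#' unwrappable.
#'
#' @param photons Data frame with \code{t_ns} and \code{channel} (0-based).
#' @param laser_period_ns Laser SYNC period (ns).
#' @param ref Optional data frame with \code{t_ns} and \code{type}
#'   ("pixel", "line", "frame").
#' @param tdl A \code{tdl_model}.
#' @param duration_ns Total stream duration (default: past the last event).
#' @param n_channels Number of photon channels in the word format.
#' @return List with \code{words} (integer vector), \code{truth} (photon
#'   ground-truth data frame with the TDC quantities and dead-time drops
#'   flagged), \code{n_dead_dropped} and the header tables used.
#' @export
build_stream <- function(photons, laser_period_ns, ref = NULL,
                         tdl = tdl_model(), duration_ns = NULL,
                         n_channels = 25L) {
  Tc <- tdl$clock_period_ns
  if (is.null(duration_ns)) {
    duration_ns <- max(c(photons$t_ns, ref$t_ns, 0)) + 2 * laser_period_ns
  }
  # --- photons through their per-channel START lines (dead time applies)
  ph <- photons[order(photons$t_ns), , drop = FALSE]
  ph$kept <- rep(TRUE, nrow(ph))
  ph$n <- rep(NA_integer_, nrow(ph))
  ph$code <- rep(NA_integer_, nrow(ph))
  for (ch in sort(unique(ph$channel))) {
    sel <- which(ph$channel == ch)
    enc <- tdc_encode(ph$t_ns[sel], tdl$start_widths[, ch + 1L], Tc)
    kept_sel <- sel[enc$kept]   # sel is already time-ordered
    ph$kept[sel[!enc$kept]] <- FALSE
    ph$n[kept_sel] <- enc$n
    ph$code[kept_sel] <- enc$code
  }
  n_dead <- sum(!ph$kept)
  phk <- ph[ph$kept, , drop = FALSE]
  # --- first SYNC pulse after each kept photon, through the STOP line
  sync_idx <- floor(phk$t_ns / laser_period_ns) + 1  # pulse k at k*T_l
  sync_t <- sync_idx * laser_period_ns
  need <- sort(unique(sync_t))
  enc_s <- tdc_encode(need, tdl$stop_widths, Tc, apply_dead_time = FALSE)
  sync_tab <- data.frame(t_ns = need, n = enc_s$n, code = enc_s$code)
  phk$sync_t <- sync_t
  # --- REF events (coarse only)
  ref_tab <- NULL
  if (!is.null(ref) && nrow(ref)) {
    ref_tab <- data.frame(n = as.integer(ceiling(ref$t_ns / Tc)),
                          type = ref$type)
  }
  # --- assemble per-frame content
  frame_n <- sort(unique(c(phk$n, sync_tab$n, ref_tab$n)))
  # force-write frames: gap between consecutive transmitted frames must
  # not exceed the force-write interval (1/16 of the rollover)
  fw_cycles <- 2^16 %/% 16L
  bounds <- c(0, frame_n, ceiling(duration_ns / Tc))
  fw <- unlist(lapply(which(diff(bounds) > fw_cycles), function(i) {
    seq(bounds[i] + fw_cycles, bounds[i + 1] - 1, by = fw_cycles)
  }))
  frame_n <- sort(unique(c(frame_n, fw)))
  headers <- data.frame(
    step = as.integer(frame_n %% 2^16),
    stop_code = 0L, sync_valid = FALSE, ref_pixel = FALSE,
    ref_line = FALSE, ref_frame = FALSE, spare = 0L)
  si <- match(sync_tab$n, frame_n)
  headers$stop_code[si] <- sync_tab$code
  headers$sync_valid[si] <- TRUE
  if (!is.null(ref_tab)) {
    headers$ref_pixel[match(ref_tab$n[ref_tab$type == "pixel"], frame_n)] <- TRUE
    headers$ref_line[match(ref_tab$n[ref_tab$type == "line"], frame_n)] <- TRUE
    headers$ref_frame[match(ref_tab$n[ref_tab$type == "frame"], frame_n)] <- TRUE
  }
  hits <- data.frame(frame = match(phk$n, frame_n),
                     channel = phk$channel, start_code = phk$code,
                     valid = rep(TRUE, nrow(phk)))
  words <- encode_words(headers, hits, n_channels = n_channels)
  truth <- ph
  list(words = words, truth = truth, headers = headers, hits = hits,
       sync = sync_tab, n_dead_dropped = n_dead,
       laser_period_ns = laser_period_ns, duration_ns = duration_ns)
}
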