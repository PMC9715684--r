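test_that("decay photon delays have the right distribution", {
  set.seed(120)
  # closed-form exponential MLE: tau_hat = mean(delays), s.e. tau/sqrt(n)
  m <- decay_model(lifetime_ns = 4, irf_sigma_ns = 0,
                   background_fraction = 0, laser_period_ns = 200)
  ph <- simulate_decay_photons(m, n_pulses = 2e7, rate = 0.05)
  n <- nrow(ph)
  expect_gt(n, 9e5)
  tau_hat <- mean(ph$delay_ns)  # truncation at 200 ns is ~ exp(-50)
  expect_lt(abs(tau_hat - 4) / 4, 0.01)
  expect_lt(abs(tau_hat - 4), 3 * 4 / sqrt(n) + 0.001)
  # pure background is uniform over the laser period
  mb <- decay_model(background_fraction = 0.999999, laser_period_ns = 25)
  phb <- simulate_decay_photons(mb, 1e6, 0.05)
  ks <- ks.test(phb$delay_ns, "punif", 0, 25)
  expect_gt(ks$p.value, 1e-3)
  # delays always inside [0, laser period)
  m40 <- decay_model(lifetime_ns = 4, irf_sigma_ns = 0.1,
                     background_fraction = 0.1, laser_period_ns = 25)
  ph40 <- simulate_decay_photons(m40, 1e6, 0.02)
  expect_true(all(ph40$delay_ns >= 0 & ph40$delay_ns < 25))
})

test_that("SYLAP generator implements decimation, delay grid and jitter", {
  set.seed(121)
  sy <- simulate_sylap(clock_period_ns = 20, pulse_delay_ns = 5,
                       decimation = 30L, jitter_sigma_ps = 0,
                       n_pulses = 2e4)
  # 50 MHz clock, decimation 30 -> pulse rate ~ 1.667 MHz
  rate_mhz <- (length(sy$pulse_ns) - 1) /
    (max(sy$pulse_ns) - min(sy$pulse_ns)) * 1e3
  expect_equal(rate_mhz, 50 / 30, tolerance = 1e-6)
  # noiseless: constant measured delay
  d <- sy$pulse_ns - sy$sync_ns[findInterval(sy$pulse_ns, sy$sync_ns)]
  expect_equal(max(d) - min(d), 0)
  expect_equal(d[1], 5)
  # off-grid delay rounded with a warning (39.0625 ps granularity)
  expect_warning(sy2 <- simulate_sylap(pulse_delay_ns = 5.01,
                                       n_pulses = 10), "grid")
  expect_equal(sy2$delay_ns %% 0.0390625, 0, tolerance = 1e-9)
  # 13 ps jitter recovered from the delay histogram
  sy3 <- simulate_sylap(pulse_delay_ns = 5, jitter_sigma_ps = 13,
                        n_pulses = 3e4)
  d3 <- sy3$pulse_ns - sy3$sync_ns[findInterval(sy3$pulse_ns, sy3$sync_ns)]
  expect_equal(sd(d3) * 1e3, 13, tolerance = 13 * 0.05)
})

test_that("raster scan produces shifted Gaussian channel images", {
  set.seed(122)
  geom <- detector_geometry(n_side = 3, pitch_um = 0.1,
                            psf_fwhm_um = 0.25)
  sc <- scan_config(nx = 32, ny = 32, pixel_dwell_us = 10,
                    pixel_size_um = 0.05)
  em <- data.frame(x_um = 0.8, y_um = 0.8, brightness = 400)
  sim <- simulate_scan(em, geom, sc, decay_model(lifetime_ns = 3),
                       seed = 123)
  ism <- bin_4d(sim$photons, 9, 32, 32, 1, 25, bin_ns = 0.4)
  imgs <- channel_images(ism)
  # central channel (index 5 of 9): Gaussian spot centred at the emitter
  ctr <- imgs[central_channel(geom) + 1L, , ]
  cx <- sum(row(ctr) * ctr) / sum(ctr)
  cy <- sum(col(ctr) * ctr) / sum(ctr)
  expect_equal(cx, 0.8 / 0.05 + 0.5, tolerance = 0.15)
  expect_equal(cy, 0.8 / 0.05 + 0.5, tolerance = 0.15)
  # a shifted channel's image is the central image translated by the
  # geometry shift (phase-correlation oracle, +-0.2 px)
  ch0 <- 1L  # element (-1,-1): shift (-0.1, -0.1) um = (-2, -2) px
  s <- ttmtools:::phase_correlate(ctr, imgs[ch0, , ])
  expect_equal(unname(s[1]), -2, tolerance = 0.2)
  expect_equal(unname(s[2]), -2, tolerance = 0.2)
  # REF events nest: 1 frame, ny lines, nx*ny pixels
  expect_identical(sum(sim$ref$type == "frame"), 1L)
  expect_identical(sum(sim$ref$type == "line"), 32L)
  expect_identical(sum(sim$ref$type == "pixel"), 32L * 32L)
})

test_that("empty sample yields only REF and force-write structures", {
  geom <- detector_geometry(n_side = 3)
  sc <- scan_config(nx = 4, ny = 3, pixel_dwell_us = 20)
  sim <- simulate_scan(data.frame(x_um = numeric(0), y_um = numeric(0),
                                  brightness = numeric(0)),
                       geom, sc, decay_model(), seed = 124)
  expect_identical(nrow(sim$photons), 0L)
  st <- build_stream(sim$photons, 25, ref = sim$ref,
                     duration_ns = sim$duration_ns, n_channels = 9L)
  dec <- decode_words(st$words, n_channels = 9L)
  expect_identical(nrow(dec$hits), 0L)
  expect_true(all(!dec$headers$sync_valid))
  has_ref <- dec$headers$ref_pixel | dec$headers$ref_line |
    dec$headers$ref_frame
  # everything else is a force-write keep-alive
  expect_true(all(has_ref | !dec$headers$sync_valid))
})

test_that("tdc code occupancy matches tap widths for a dispersed line", {
  set.seed(125)
  tdl <- tdl_model(dispersion = 0.05, n_start_lines = 1, seed = 9)
  ev <- runif(3e5, 0, 1e6)
  enc <- tdc_encode(ev, tdl$start_widths[, 1], apply_dead_time = FALSE)
  counts <- tabulate(enc$code + 1L, 87)
  # effective widths: the line is longer than the clock period, so the
  # last tap is clipped at the period
  eff <- pmin(tdl$start_widths[, 1],
              pmax(0, ttm_clock_period() * 1e3 -
                     c(0, cumsum(tdl$start_widths[-87, 1]))))
  chi <- chisq.test(counts, p = eff / sum(eff))
  expect_gt(chi$p.value, 1e-4)
})

test_that("build_stream conserves photons and emits force-writes", {
  set.seed(126)
  m <- decay_model(lifetime_ns = 4, laser_period_ns = 25)
  ph <- simulate_decay_photons(m, 4e5, 0.01, channel = 12L)
  dur <- 4e5 * 25
  st <- build_stream(ph, 25, tdl = tdl_model(), duration_ns = dur)
  dec <- decode_words(st$words)
  expect_identical(dec$n_corrupt, 0L)
  # conservation: decoded hits = input photons - dead-time drops
  expect_identical(nrow(dec$hits), nrow(ph) - st$n_dead_dropped)
  # at least one frame per force-write interval of simulated time
  fw_ns <- 2^16 / 16 * ttm_clock_period()
  expect_gte(nrow(dec$headers), floor(dur / fw_ns))
  n <- unwrap_counter(dec$headers$step)
  expect_lte(max(diff(n)), 2^16 / 16)
})

test_that("SYLAP through the stream reconstructs a constant delay", {
  set.seed(127)
  sy <- simulate_sylap(clock_period_ns = 20, pulse_delay_ns = 5,
                       decimation = 30L, n_pulses = 3000)
  ph <- data.frame(t_ns = sy$pulse_ns, channel = 12L)
  st <- build_stream(ph, laser_period_ns = 20, tdl = tdl_model(),
                     duration_ns = max(sy$sync_ns) + 40)
  res <- process_stream(st$words, 20, uniform_calibration(),
                        uniform_calibration())
  # reverse start-stop: delay to next sync = 20 - 5 = 15 ns
  expect_equal(nrow(res$photons), 3000 - st$n_dead_dropped)
  expect_equal(mean(res$photons$dt_ns), 15, tolerance = 0.05)
  expect_lt(sd(res$photons$dt_ns) * 1e3, 2 * 48 / sqrt(12) + 5)
})

test_that("diffusion degenerate cases behave", {
  geom <- detector_geometry(n_side = 3, pitch_um = 0.15, w0_um = 0.3)
  # immobile particles: G flat at small lags
  ph0 <- simulate_diffusion(50, 0, c(3, 3, 3), geom, 10,
                            brightness_hz = 2e4, seed = 31)
  expect_gt(nrow(ph0), 1000)
  cv <- correlate(ph0, chunk_s = 5, max_lag_s = 0.1, reject_sigma = Inf)
  early <- cv$G[cv$lag_s <= 1e-3]
  late <- cv$G[cv$lag_s > 1e-2]
  expect_lt(abs(mean(early) - mean(late)), 0.05)
  # circular scan with R = 0 is statistically a point measurement
  sc0 <- scan_config(mode = "circular", radius_um = 0, period_us = 1000)
  pha <- simulate_diffusion(20, 15, c(3, 3, 3), geom, 5,
                            brightness_hz = 2e4, scan = sc0, seed = 32)
  phb <- simulate_diffusion(20, 15, c(3, 3, 3), geom, 5,
                            brightness_hz = 2e4, seed = 32)
  expect_identical(nrow(pha), nrow(phb))
  expect_equal(pha$t_ns, phb$t_ns)
})

test_that("detector artifacts add a neighbour bump and afterpulse tail", {
  set.seed(128)
  geom <- detector_geometry()
  n <- 2e4
  # constant parent delay isolates the cross-talk bump shift exactly
  ph <- data.frame(t_ns = sort(runif(n, 0, 1e7)),
                   delay_ns = 2, channel = 12L)
  aug <- add_detector_artifacts(ph, geom, crosstalk_prob = 0.05,
                                afterpulse_prob = 0.03)
  ct <- aug[aug$artifact == "crosstalk", ]
  apls <- aug[aug$artifact == "afterpulse", ]
  # rates near the requested probabilities (binomial tolerance)
  expect_equal(nrow(ct), 0.05 * n, tolerance = 0.15)
  expect_equal(nrow(apls), 0.03 * n, tolerance = 0.2)
  # cross-talk lands on 4-neighbours of the central element only
  expect_true(all(ct$channel %in% c(7L, 11L, 13L, 17L)))
  # the bump sits after the parent decay: mean delay shifted by ~0.3 ns
  expect_equal(mean(ct$delay_ns) - 2, 0.3, tolerance = 0.05)
  # afterpulses echo on the same channel, uniform in the laser period
  expect_true(all(apls$channel == 12L))
  expect_gt(ks.test(apls$delay_ns, "punif", 0, 25)$p.value, 1e-4)
  # originals preserved
  expect_identical(sum(aug$artifact == ""), as.integer(n))
})
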