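test_that("channel merging implements the detection-volume classes", {
  geom <- detector_geometry()
  expect_identical(central_channel(geom), 12L)
  expect_length(channel_set(geom, "sum3x3"), 9L)
  s5 <- channel_set(geom, "sum5x5")
  expect_length(s5, 21L)  # all 25 except the four corners
  expect_false(any(c(0L, 4L, 20L, 24L) %in% s5))
  ph <- data.frame(t_ns = c(5, 1, 3, 2), channel = c(0L, 12L, 7L, 24L))
  m <- merge_channels(ph, "sum5x5", geom)
  expect_identical(nrow(m), 2L)          # corners dropped
  expect_equal(m$t_ns, c(1, 3))          # sorted
  # merging disjoint sorted lists preserves counts; empty lists are fine
  m2 <- merge_channels(ph, c(0L, 12L), geom)
  expect_identical(nrow(m2), 2L)
  m3 <- merge_channels(ph[ph$channel == 0L, ], c(0L, 3L), geom)
  expect_equal(m3$t_ns, 5)
})

test_that("compiled correlator equals the brute-force oracle", {
  set.seed(150)
  t_s <- sort(runif(1e4, 0, 2))
  w <- runif(1e4, 0.2, 2)
  for (weights in list(NULL, w)) {
    a <- ttmtools:::multitau_cpp(t_s, if (is.null(weights))
      numeric(0) else weights, 2, 1e-4, 0.4)
    b <- correlate_bruteforce(t_s, weights, 2, 1e-4, 0.4)
    expect_equal(a$lag, b$lag, tolerance = 1e-12)
    expect_equal(a$G, b$G, tolerance = 1e-9)
  }
  # weights of exactly 1 reduce to the unweighted estimator
  a1 <- ttmtools:::multitau_cpp(t_s, rep(1, length(t_s)), 2, 1e-4, 0.4)
  a0 <- ttmtools:::multitau_cpp(t_s, numeric(0), 2, 1e-4, 0.4)
  expect_identical(a1$G, a0$G)
})

test_that("homogeneous Poisson photons decorrelate to zero", {
  set.seed(151)
  tp <- sort(runif(3e5, 0, 20)) * 1e9
  cv <- correlate(data.frame(t_ns = tp), chunk_s = 5, max_lag_s = 0.5)
  expect_lt(max(abs(cv$G)), 0.05)
  expect_true(all(diff(cv$lag_s) > 0))
})

test_that("chunk averaging of identical chunks equals a single chunk", {
  set.seed(152)
  t1 <- sort(runif(2000, 0, 5))
  t_all <- c(t1, t1 + 5, t1 + 10)
  cv <- correlate(data.frame(t_ns = t_all * 1e9), chunk_s = 5,
                  max_lag_s = 0.2, reject_sigma = Inf)
  one <- ttmtools:::multitau_cpp(t1, numeric(0), 5, 1e-6, 0.2)
  expect_equal(cv$G, one$G, tolerance = 1e-9)
  expect_equal(unname(cv$G_sd), rep(0, length(one$G)), tolerance = 1e-9)
})

test_that("FLCS filters have the documented structure", {
  set.seed(153)
  bin <- 0.048
  period <- 25
  nb <- ceiling(period / bin)
  tt <- (seq_len(nb) - 0.5) * bin
  # pure decay (B = 0): fluorescence filter is 1, background filter 0
  h0 <- rpois(nb, 4e4 * exp(-tt / 4) * bin)
  f0 <- flcs_filters(h0, bin)
  expect_true(f0$ok)
  expect_true(all(abs(f0$f_fluor - 1) < 0.05))
  expect_true(all(abs(f0$f_bg) < 0.05))
  # decay + background: filters partition unity on retained bins
  h1 <- rpois(nb, (4e4 * exp(-tt / 4) + 2e3) * bin)
  f1 <- flcs_filters(h1, bin)
  expect_true(f1$ok)
  expect_equal(f1$f_fluor + f1$f_bg, rep(1, length(f1$bins)),
               tolerance = 1e-9)
  expect_equal(unname(f1$fit[["tau_ns"]]), 4, tolerance = 0.2)
  # early bins weighted above 1, late bins below; removed-tail flagged
  expect_gt(f1$f_fluor[1], 1)
  expect_lt(f1$f_fluor[length(f1$f_fluor)], 1)
  expect_lt(length(f1$bins), nb)
  # per-photon weights: removed/outside bins carry weight 0
  ph <- data.frame(delay_ns = c(tt[f1$bins[1]], 24.9))
  w <- apply_flcs_weights(ph, f1, period)$weight
  expect_gt(w[1], 1)
  expect_identical(w[2], 0)
  # unusable histogram disables filtering with a warning
  expect_warning(fbad <- flcs_filters(c(5, 0, 0, 2), bin), "disabled")
  expect_false(fbad$ok)
  expect_true(all(fbad$weight_lut == 1))
})

test_that("point FCS fit recovers a noiseless model curve exactly", {
  lag <- 10^seq(-6, 0, length.out = 60)
  curve <- structure(list(lag_s = lag,
                          G = fcs_model_point(lag, 2, 1e-3, 4.5),
                          G_sd = NULL), class = "correlation_curve")
  f <- fit_point_fcs(curve, w0_um = 0.3, k = 4.5)
  expect_equal(f$N, 2, tolerance = 1e-4)
  expect_equal(f$tauD_s, 1e-3, tolerance = 1e-4)
  # D from the printed formula: w0 = 0.3 um, tauD = 1.5 ms -> 15 um^2/s
  curve2 <- structure(list(lag_s = lag,
                           G = fcs_model_point(lag, 1, 1.5e-3, 4.5),
                           G_sd = NULL), class = "correlation_curve")
  f2 <- fit_point_fcs(curve2, w0_um = 0.3, k = 4.5)
  expect_equal(f2$D_um2_s, 15, tolerance = 0.01)
})

test_that("circular model reduces correctly and fits noiseless data", {
  lag <- 10^seq(-6, 0, length.out = 80)
  # R = 0 reduces to the point model exactly
  expect_equal(fcs_model_circular(lag, 2, 1e-3, 4.5, 0.3, 0, 1e-3),
               fcs_model_point(lag, 2, 1e-3, 4.5))
  # scanner back at start: scanning factor is 1 at tau = m T
  Tscan <- 1e-3
  m <- fcs_model_circular(c(Tscan, 3 * Tscan), 2, 1e-3, 4.5, 0.3, 0.25,
                          Tscan)
  expect_equal(m, fcs_model_point(c(Tscan, 3 * Tscan), 2, 1e-3, 4.5),
               tolerance = 1e-9)
  # noiseless circular curve: all three parameters recovered
  G <- fcs_model_circular(lag, 1.5, 1.5e-3, 4.5, 0.3, 0.25, Tscan)
  curve <- structure(list(lag_s = lag, G = G, G_sd = NULL),
                     class = "correlation_curve")
  f <- fit_circular_fcs(curve, R_um = 0.25, T_s = Tscan, k = 4.5,
                        w0_start_um = 0.4)
  expect_equal(f$N, 1.5, tolerance = 1e-3)
  expect_equal(f$tauD_s, 1.5e-3, tolerance = 1e-3)
  expect_equal(f$w0_um, 0.3, tolerance = 1e-3)
})

test_that("spot variation reports the diffusion law", {
  # three synthetic points on a line through the origin, slope 1/(4*15)
  mkfit <- function(w0, k) {
    tauD <- w0^2 / (4 * 15)
    structure(list(N = 1, tauD_s = tauD, w0_um = w0, k = k,
                   D_um2_s = w0^2 / (4 * tauD),
                   concentration_per_um3 = 1 / (pi^1.5 * w0^3 * k)),
              class = "fcs_fit")
  }
  fits <- list(central = mkfit(0.3, 4.5), sum3x3 = mkfit(0.38, 4.1),
               sum5x5 = mkfit(0.45, 4.1))
  sv <- spot_variation(fits)
  expect_equal(sv$D_um2_s, 15, tolerance = 1e-9)
  expect_equal(sv$intercept_ms, 0, tolerance = 1e-9)
  expect_equal(unname(sv$D_per_class), rep(15, 3), tolerance = 1e-9)
  expect_equal(sv$D_ratio, 1, tolerance = 1e-9)
  expect_error(spot_variation(fits[1]), "2")
})

test_that("lifetime-vs-time series tracks stationarity and steps", {
  set.seed(154)
  period <- 25
  mkph <- function(n, tau, t0, t1) {
    data.frame(t_ns = sort(runif(n, t0, t1)) * 1e9,
               delay_ns = rexp(n, 1 / tau) %% period,
               channel = 12L)
  }
  # stationary: flat series
  ph <- mkph(5e4, 4, 0, 20)
  lv <- lifetime_vs_time(ph, window_s = 5, laser_period_ns = period)
  expect_identical(nrow(lv), 4L)
  expect_true(all(abs(lv$tau_ns - 4) / 4 < 0.1))
  # lifetime step 4 -> 2 ns mid-run detected at the step window
  ph2 <- rbind(mkph(3e4, 4, 0, 10), mkph(3e4, 2, 10, 20))
  lv2 <- lifetime_vs_time(ph2, window_s = 5, laser_period_ns = period)
  expect_true(all(abs(lv2$tau_ns[1:2] - 4) / 4 < 0.1))
  expect_true(all(abs(lv2$tau_ns[3:4] - 2) / 2 < 0.1))
  # sparse window is masked
  ph3 <- rbind(mkph(2e4, 4, 0, 10), mkph(100, 4, 10, 15),
               mkph(2e4, 4, 15, 20))
  lv3 <- lifetime_vs_time(ph3, window_s = 5, laser_period_ns = period)
  expect_true(is.na(lv3$tau_ns[3]))
  expect_false(any(is.na(lv3$tau_ns[c(1, 2, 4)])))
})

test_that("FLCS filtering corrects the correlation amplitude", {
  set.seed(155)
  # diffusing fluorescent signal plus uniform (uncorrelated) background
  geom <- detector_geometry(n_side = 3, pitch_um = 0.15, w0_um = 0.3)
  sig <- simulate_diffusion(24, 15, c(3, 3, 4), geom, 25,
                            brightness_hz = 2.5e4,
                            decay = decay_model(lifetime_ns = 4,
                                                laser_period_ns = 25),
                            seed = 41)
  sig <- sig[sig$channel == 4L, c("t_ns", "delay_ns")]  # central of 3x3
  nbg <- nrow(sig)  # 50% background
  bg <- data.frame(t_ns = sort(runif(nbg, 0, 25e9)),
                   delay_ns = runif(nbg, 0, 25))
  mix <- rbind(sig, bg)
  mix <- mix[order(mix$t_ns), ]
  # reference: amplitude of the clean signal
  f_true <- fit_point_fcs(correlate(sig, chunk_s = 5, max_lag_s = 0.2),
                          0.3, 4.5)
  # unfiltered: amplitude diluted by (1 + B/S)^2 = 4
  cv_unf <- correlate(mix, chunk_s = 5, max_lag_s = 0.2)
  f_unf <- fit_point_fcs(cv_unf, 0.3, 4.5)
  expect_gt(f_unf$N / f_true$N, 2)
  expect_equal(f_unf$N / f_true$N, 4, tolerance = 0.25)
  # filtered: weights from the decay histogram restore the amplitude
  bin <- 0.048
  nb <- ceiling(25 / bin)
  h <- tabulate(pmin(floor(mix$delay_ns / bin), nb - 1L) + 1L, nbins = nb)
  fl <- flcs_filters(h, bin)
  expect_true(fl$ok)
  mixw <- apply_flcs_weights(mix, fl, 25)
  cv_f <- correlate(mixw, chunk_s = 5, max_lag_s = 0.2)
  f_fil <- fit_point_fcs(cv_f, 0.3, 4.5)
  expect_equal(f_fil$N, f_true$N, tolerance = 0.1 * f_true$N)
})
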