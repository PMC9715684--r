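# ---------------------------------------------------------------------------
# FLFS: weighted timestamp correlation, chunking, FLCS filters, FCS model
# fits and the spot-variation diffusion law.
# ---------------------------------------------------------------------------

#' Merge channel photon lists into one sorted time list
#'
#' Selects the channels of a detection-volume class ("central", "sum3x3",
#' "sum5x5" = all but the four corners, or an explicit 0-based channel
#' vector) and merges their absolute photon times into a single sorted
#' list, carrying optional weights.
#'
#' @param photons Photon list data frame (needs \code{t_ns},
#'   \code{channel}; \code{weight} honoured if present).
#' @param selection Class name or integer channel vector.
#' @param geometry A \code{detector_geometry} (for the named classes).
#' @return Data frame with \code{t_ns}, \code{channel} and \code{weight},
#'   sorted by time; attribute \code{selection} records the class.
#' @export
merge_channels <- function(photons, selection = "sum5x5",
                           geometry = detector_geometry()) {
  chans <- if (is.character(selection)) {
    channel_set(geometry, selection)
  } else {
    as.integer(selection)
  }
  sel <- photons$channel %in% chans
  out <- photons[sel, , drop = FALSE]
  if (is.null(out$weight)) out$weight <- 1
  out <- out[order(out$t_ns), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "selection") <-
    if (is.character(selection)) selection else "custom"
  out
}

#' Timestamp autocorrelation with chunking
#'
#' Splits the photon list into chunks, computes the multi-tau fluctuation
#' autocorrelation of each chunk directly from the (weighted) timestamps,
#' rejects outlier chunks automatically (mean count rate or correlation
#' amplitude deviating more than \code{reject_sigma} robust sigmas from
#' the median) and averages the remainder.  The estimator is normalized to
#' a 0 baseline: G(tau -> infinity) -> 0.
#'
#' @param photons Data frame with \code{t_ns} (and optional
#'   \code{weight}), or a bare numeric vector of times in ns.
#' @param chunk_s Chunk length in seconds (default 5).
#' @param dt0_s Base lag resolution (s, default 1e-6).
#' @param max_lag_s Largest lag (s, default 1; must be well below the
#'   chunk length).
#' @param reject_sigma Robust outlier threshold (default 3; Inf disables).
#' @return Object of class \code{correlation_curve}: list with
#'   \code{lag_s}, \code{G} (mean), \code{G_sd}, \code{G_chunks} (matrix),
#'   \code{kept}, \code{rate_hz}.
#' @export
correlate <- function(photons, chunk_s = 5, dt0_s = 1e-6, max_lag_s = 1,
                      reject_sigma = 3) {
  if (is.data.frame(photons)) {
    t_s <- photons$t_ns * 1e-9
    w <- if (is.null(photons$weight)) rep(1, length(t_s)) else photons$weight
  } else {
    t_s <- photons * 1e-9
    w <- rep(1, length(t_s))
  }
  if (!length(t_s)) stop("no photons to correlate")
  duration <- max(t_s)
  n_chunks <- max(1L, floor(duration / chunk_s))
  curves <- vector("list", n_chunks)
  rates <- numeric(n_chunks)
  for (k in seq_len(n_chunks)) {
    lo <- (k - 1) * chunk_s
    sel <- t_s >= lo & t_s < lo + chunk_s
    if (!any(sel)) { rates[k] <- 0; next }  # empty chunk skipped with log
    res <- multitau_cpp(t_s[sel] - lo, w[sel], chunk_s, dt0_s, max_lag_s)
    curves[[k]] <- res
    rates[k] <- sum(sel) / chunk_s
  }
  nonempty <- !vapply(curves, is.null, logical(1))
  if (!all(nonempty)) {
    message(sprintf("%d empty chunk(s) skipped", sum(!nonempty)))
  }
  curves <- curves[nonempty]
  rates <- rates[nonempty]
  lag <- curves[[1]]$lag
  Gm <- vapply(curves, function(cv) cv$G, numeric(length(lag)))
  Gm <- matrix(Gm, nrow = length(lag))
  kept <- rep(TRUE, ncol(Gm))
  if (is.finite(reject_sigma) && ncol(Gm) >= 3) {
    # amplitude proxy: mean over the first octave of lags
    amp <- colMeans(Gm[seq_len(min(8, nrow(Gm))), , drop = FALSE])
    for (v in list(amp, rates)) {
      med <- median(v); s <- mad(v)
      if (s > 0) kept <- kept & abs(v - med) <= reject_sigma * s
    }
    if (!any(kept)) kept <- rep(TRUE, ncol(Gm))  # never reject everything
  }
  Gk <- Gm[, kept, drop = FALSE]
  structure(list(lag_s = lag, lag_dt_s = curves[[1]]$dt,
                 G = rowMeans(Gk),
                 G_sd = apply(Gk, 1, sd), G_chunks = Gm, kept = kept,
                 rate_hz = mean(rates[kept]), chunk_s = chunk_s),
            class = "correlation_curve")
}

#' @export
print.correlation_curve <- function(x, ...) {
  cat(sprintf("<correlation_curve> %d lags (%.2g-%.2g s), %d/%d chunks, %.3g kHz\n",
              length(x$lag_s), min(x$lag_s), max(x$lag_s), sum(x$kept),
              length(x$kept), x$rate_hz / 1e3))
  invisible(x)
}

#' Brute-force reference correlator (oracle)
#'
#' Direct R implementation of the same binned multi-tau estimator used by
#' the compiled correlator, for small photon lists.  Kept deliberately
#' independent of the C++ path: dense trace via tabulate, plain vector
#' products per lag.
#'
#' @param t_s Photon times (s).
#' @param w Weights (default 1).
#' @param duration Chunk duration (s).
#' @param dt0_s Base resolution (s).
#' @param max_lag_s Maximum lag (s).
#' @return List with \code{lag} and \code{G}.
#' @export
correlate_bruteforce <- function(t_s, w = NULL, duration, dt0_s,
                                 max_lag_s) {
  if (is.null(w)) w <- rep(1, length(t_s))
  n0 <- ceiling(duration / dt0_s)
  b <- floor(t_s / dt0_s) + 1
  ok <- b >= 1 & b <= n0
  trace <- as.vector(tapply(w[ok], factor(b[ok], levels = seq_len(n0)), sum))
  trace[is.na(trace)] <- 0
  lag <- numeric(0); G <- numeric(0)
  dt <- dt0_s; level <- 0
  while (TRUE) {
    n <- length(trace)
    m_lo <- if (level == 0) 1 else 9
    if (n < 32) break
    for (m in m_lo:16) {
      if (m * dt > max_lag_s) break
      head_ <- trace[1:(n - m)]
      tail_ <- trace[(1 + m):n]
      g <- mean(head_ * tail_) / (mean(head_) * mean(tail_)) - 1
      lag <- c(lag, m * dt); G <- c(G, g)
    }
    if (16 * dt >= max_lag_s) break
    nh <- floor(n / 2)
    trace <- trace[2 * seq_len(nh) - 1] + trace[2 * seq_len(nh)]
    dt <- 2 * dt; level <- level + 1
  }
  list(lag = lag, G = G)
}

#' FLCS filter functions from a decay histogram
#'
#' Crops the TCSPC histogram to the post-peak range (peak to about 10 ns
#' later), fits \code{H(t) = A exp(-t/tau) + B}, removes bins whose counts
#' are statistically indistinguishable from the background offset
#' (\code{counts <= B + 3 sqrt(B)}: almost certainly background), and
#' builds the two standard FLCS filter functions from the patterns
#' \{normalized exponential decay\} and \{uniform B/A\} by weighted least
#' squares.  The per-photon weight is the fluorescence filter value at the
#' photon's delay bin; the background filter is returned but not used
#' further.
#'
#' @param hist Counts per delay bin (full laser period).
#' @param bin_ns Bin width (ns).
#' @param fit_window_ns Post-peak crop length (default 10 ns).
#' @return Object of class \code{flcs_filters}: list with \code{bins}
#'   (retained bin indices), \code{f_fluor}, \code{f_bg} (filter values on
#'   the retained bins), \code{fit} (A, tau_ns, B), \code{weight_lut}
#'   (per-bin photon weight over the full histogram, 0 outside retained
#'   bins) and \code{ok}.
#' @export
flcs_filters <- function(hist, bin_ns, fit_window_ns = 10) {
  nb <- length(hist)
  pk <- which.max(hist)
  hi <- min(nb, pk + ceiling(fit_window_ns / bin_ns))
  rng <- pk:hi
  tt <- (rng - pk) * bin_ns  # time from the peak
  y <- hist[rng]
  fit <- if (length(y) < 8) NULL else tryCatch({
    tau0 <- max(bin_ns, sum(y * tt) / sum(y))
    nls(y ~ A * exp(-tt / tau) + B,
        start = list(A = max(y), tau = tau0, B = max(min(y), 1)),
        lower = c(A = 0, tau = bin_ns, B = 0), algorithm = "port",
        control = nls.control(maxiter = 200, warnOnly = TRUE))
  }, error = function(e) NULL)
  if (is.null(fit) || !all(is.finite(coef(fit)))) {
    warning("decay fit failed: FLCS filters disabled, unfiltered path used")
    return(structure(list(ok = FALSE,
                          weight_lut = rep(1, nb), bins = seq_len(nb),
                          f_fluor = rep(1, nb), f_bg = rep(0, nb),
                          fit = NULL),
                     class = "flcs_filters"))
  }
  co <- coef(fit)
  A <- co[["A"]]; tau <- co[["tau"]]; B <- co[["B"]]
  # background-only bins removed entirely
  keep <- y > B + 3 * sqrt(max(B, 0))
  bins <- rng[keep]
  tk <- tt[keep]
  if (B <= 1e-9 * A) {
    # single-component degenerate case: pure decay
    f_fl <- rep(1, length(bins)); f_bg <- rep(0, length(bins))
  } else {
    p1 <- exp(-tk / tau); p1 <- p1 / sum(p1)
    p2 <- rep(1 / length(tk), length(tk))
    M <- cbind(p1, p2)
    # weights from the fitted model counts (exact partition property)
    Hm <- A * exp(-tk / tau) + B
    Dm <- M / Hm                       # diag(1/H) %*% M
    Ft <- solve(t(M) %*% Dm, t(Dm))    # 2 x nbins filter matrix
    f_fl <- Ft[1, ]; f_bg <- Ft[2, ]
  }
  lut <- rep(0, nb)
  lut[bins] <- f_fl
  structure(list(ok = TRUE, bins = bins, f_fluor = f_fl, f_bg = f_bg,
                 fit = c(A = A, tau_ns = tau, B = B), peak_bin = pk,
                 weight_lut = lut, bin_ns = bin_ns),
            class = "flcs_filters")
}

#' Attach FLCS weights to a photon list
#'
#' @param photons Photon list with \code{delay_ns}.
#' @param filters A \code{flcs_filters}.
#' @param laser_period_ns Laser period (ns).
#' @return The photon list with a \code{weight} column; photons in removed
#'   bins carry weight 0.
#' @export
apply_flcs_weights <- function(photons, filters, laser_period_ns) {
  nb <- length(filters$weight_lut)
  bin <- pmin(floor((photons$delay_ns %% laser_period_ns) /
                      filters$bin_ns), nb - 1L) + 1L
  photons$weight <- filters$weight_lut[bin]
  photons
}

#' Single-point FCS model
#'
#' 3D Gaussian detection volume, one diffusing component:
#' \code{G(tau) = 1/N * (1 + tau/tauD)^-1 * (1 + tau/(k^2 tauD))^-1/2}.
#'
#' @param tau_s Lag times (s).
#' @param N Mean particle number in the volume.
#' @param tauD_s Diffusion time (s).
#' @param k Eccentricity of the detection volume.
#' @return Model values.
#' @export
fcs_model_point <- function(tau_s, N, tauD_s, k) {
  1 / N / (1 + tau_s / tauD_s) / sqrt(1 + tau_s / (k^2 * tauD_s))
}

#' Circular-scanning FCS model
#'
#' The point model times the scanning factor
#' \code{exp(-(4 R^2 / w0^2) sin^2(pi tau / T) / (1 + tau/tauD))}: the
#' periodic beam displacement decorrelates the signal except when the
#' scanner returns to its start (tau = m T), where the factor is 1.  With
#' R and T fixed the fit determines N, tauD and w0 from one experiment.
#'
#' @param tau_s Lag times (s).
#' @param N,tauD_s,k As in \code{\link{fcs_model_point}}.
#' @param w0_um Lateral 1/e^2 waist (um).
#' @param R_um Scan radius (um).
#' @param T_s Scan period (s).
#' @param lag_dt_s Optional per-lag bin width: the multi-tau estimator
#'   correlates coarsened traces, which averages the fast scanning
#'   oscillation over a triangular window of half-width one bin; the model
#'   is averaged the same way for an unbiased fit.
#' @return Model values.
#' @export
fcs_model_circular <- function(tau_s, N, tauD_s, k, w0_um, R_um, T_s,
                               lag_dt_s = NULL) {
  eval1 <- function(tau) {
    base <- fcs_model_point(tau, N, tauD_s, k)
    sfac <- exp(-(4 * R_um^2 / w0_um^2) * sin(pi * tau / T_s)^2 /
                  (1 + tau / tauD_s))
    base * sfac
  }
  if (R_um <= 0 || T_s <= 0) return(fcs_model_point(tau_s, N, tauD_s, k))
  if (is.null(lag_dt_s)) return(eval1(tau_s))
  # triangular bin-averaging (trace binning kernel); the quadrature has to
  # resolve the scan oscillation, so its density adapts to dt/T
  out <- numeric(length(tau_s))
  for (grp in split(seq_along(tau_s), lag_dt_s)) {
    dt <- lag_dt_s[grp[1]]
    npts <- min(129L, 2L * ceiling(4 * max(1, dt / T_s)) + 7L)
    u <- seq(-1, 1, length.out = npts)
    wq <- 1 - abs(u)
    wq <- wq / sum(wq)
    acc <- numeric(length(grp))
    for (j in seq_along(u)) {
      acc <- acc + wq[j] * eval1(pmax(tau_s[grp] + u[j] * dt, 0))
    }
    out[grp] <- acc
  }
  out
}

fcs_weights <- function(curve) {
  w <- rep(1, length(curve$lag_s))
  if (!is.null(curve$G_sd) && all(is.finite(curve$G_sd)) &&
      any(curve$G_sd > 0)) {
    w <- 1 / pmax(curve$G_sd, max(curve$G_sd) * 1e-3)^2
  }
  w
}

#' Fit the single-point FCS model
#'
#' The focal spot size is kept fixed (from a circular-scanning
#' calibration); amplitude and diffusion time are fitted.  The diffusion
#' coefficient follows as \code{D = w0^2 / (4 tauD)}.
#'
#' @param curve A \code{correlation_curve}.
#' @param w0_um Fixed lateral waist (um).
#' @param k Fixed eccentricity (4.5 central element, 4.1 summed volumes).
#' @param fit_range_s Optional c(min, max) lag range.
#' @return Object of class \code{fcs_fit}: list with \code{N},
#'   \code{tauD_s}, \code{w0_um}, \code{k}, \code{D_um2_s},
#'   \code{concentration_per_um3} (N / Veff, Veff = pi^{3/2} w0^3 k)
#'   and the fitted curve.
#' @export
fit_point_fcs <- function(curve, w0_um, k = 4.5, fit_range_s = NULL) {
  sel <- is.finite(curve$G)
  if (!is.null(fit_range_s)) {
    sel <- sel & curve$lag_s >= fit_range_s[1] & curve$lag_s <= fit_range_s[2]
  }
  tau <- curve$lag_s[sel]; G <- curve$G[sel]; w <- fcs_weights(curve)[sel]
  G0 <- max(mean(G[seq_len(min(4, length(G)))]), 1e-6)
  tD0 <- tau[which.min(abs(G - G0 / 2))]
  obj <- function(p) {
    m <- fcs_model_point(tau, exp(p[1]), exp(p[2]), k)
    sum(w * (m - G)^2)
  }
  fit <- optim(c(log(1 / G0), log(tD0)), obj, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-12))
  N <- exp(fit$par[1]); tauD <- exp(fit$par[2])
  structure(list(N = N, tauD_s = tauD, w0_um = w0_um, k = k,
                 D_um2_s = w0_um^2 / (4 * tauD) * 1e-0,
                 concentration_per_um3 = N / (pi^1.5 * w0_um^3 * k),
                 model = fcs_model_point(curve$lag_s, N, tauD, k),
                 convergence = fit$convergence, mode = "point"),
            class = "fcs_fit")
}

#' Fit the circular-scanning FCS model
#'
#' Scan radius and period are kept fixed; amplitude, diffusion time and
#' focal spot size are fitted simultaneously.
#'
#' @param curve A \code{correlation_curve}.
#' @param R_um Scan radius (um).
#' @param T_s Scan period (s).
#' @param k Eccentricity.
#' @param w0_start_um Starting value for the waist.
#' @param fit_range_s Optional lag range.
#' @return An \code{fcs_fit} with fitted \code{w0_um}.
#' @export
fit_circular_fcs <- function(curve, R_um, T_s, k = 4.5, w0_start_um = 0.3,
                             fit_range_s = NULL) {
  sel <- is.finite(curve$G)
  if (!is.null(fit_range_s)) {
    sel <- sel & curve$lag_s >= fit_range_s[1] & curve$lag_s <= fit_range_s[2]
  }
  tau <- curve$lag_s[sel]; G <- curve$G[sel]; w <- fcs_weights(curve)[sel]
  dts <- if (!is.null(curve$lag_dt_s)) curve$lag_dt_s[sel] else NULL
  G0 <- max(mean(G[seq_len(min(4, length(G)))]), 1e-6)
  tD0 <- tau[which.min(abs(G - G0 / 2))]
  obj <- function(p) {
    m <- fcs_model_circular(tau, exp(p[1]), exp(p[2]), k, exp(p[3]),
                            R_um, T_s, lag_dt_s = dts)
    sum(w * (m - G)^2)
  }
  fit <- optim(c(log(1 / G0), log(tD0), log(w0_start_um)), obj,
               method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-12))
  N <- exp(fit$par[1]); tauD <- exp(fit$par[2]); w0 <- exp(fit$par[3])
  structure(list(N = N, tauD_s = tauD, w0_um = w0, k = k,
                 R_um = R_um, T_s = T_s,
                 D_um2_s = w0^2 / (4 * tauD),
                 concentration_per_um3 = N / (pi^1.5 * w0^3 * k),
                 model = fcs_model_circular(curve$lag_s, N, tauD, k, w0,
                                            R_um, T_s),
                 convergence = fit$convergence, mode = "circular"),
            class = "fcs_fit")
}

#' @export
print.fcs_fit <- function(x, ...) {
  cat(sprintf("<fcs_fit %s> N=%.3g tauD=%.3g ms w0=%.3g um D=%.3g um2/s\n",
              x$mode, x$N, x$tauD_s * 1e3, x$w0_um, x$D_um2_s))
  invisible(x)
}

#' Spot-variation diffusion-law summary
#'
#' Linear fit of the diffusion time versus the squared focal spot size
#' over the detection-volume classes.  Free diffusion gives a line through
#' the origin with slope 1/(4D); a positive intercept indicates domain
#' confinement, a negative one meshwork hindrance.  Also reports the
#' per-class D, the ratio D_central / D_5x5 and the fitted concentrations.
#'
#' @param fits Named list of \code{fcs_fit} objects (e.g. central, sum3x3,
#'   sum5x5), at least 2.
#' @return List with \code{slope}, \code{intercept_ms} (and its standard
#'   error), \code{D_um2_s} (slope-based), \code{D_per_class},
#'   \code{D_ratio}, \code{concentrations}.
#' @export
spot_variation <- function(fits) {
  stopifnot(length(fits) >= 2)
  w02 <- vapply(fits, function(f) f$w0_um^2, numeric(1))
  tauD <- vapply(fits, function(f) f$tauD_s, numeric(1))
  lmfit <- stats::lm(tauD ~ w02)
  co <- suppressWarnings(summary(lmfit))$coefficients
  slope <- co["w02", "Estimate"]
  Dcls <- vapply(fits, function(f) f$D_um2_s, numeric(1))
  ratio <- if (!is.null(fits$central) && !is.null(fits$sum5x5)) {
    fits$central$D_um2_s / fits$sum5x5$D_um2_s
  } else {
    Dcls[[1]] / Dcls[[length(Dcls)]]
  }
  list(slope_s_per_um2 = slope,
       intercept_ms = co["(Intercept)", "Estimate"] * 1e3,
       intercept_se_ms = co["(Intercept)", "Std. Error"] * 1e3,
       D_um2_s = 1 / (4 * slope),
       D_per_class = Dcls, D_ratio = ratio,
       concentrations = vapply(fits, function(f) f$concentration_per_um3,
                               numeric(1)),
       lm = lmfit)
}

#' Lifetime and mobility versus measurement time
#'
#' Splits the measurement into fixed-length windows; per window fits the
#' pooled start-stop histogram with a single exponential (plus offset) and
#' optionally computes the spot-variation D ratio from per-window
#' correlations.  Windows with too few photons are masked.
#'
#' @param photons Calibrated photon list (t_ns, delay_ns, channel).
#' @param window_s Window length (s, default 5).
#' @param laser_period_ns Laser period (ns).
#' @param bin_ns Histogram bin width (ns).
#' @param min_photons Mask threshold per window (default 1000).
#' @param geometry Detector geometry (for the D-ratio classes).
#' @param mobility Also compute D_central/D_5x5 per window (slower;
#'   default FALSE).
#' @param w0_central_um,w0_sum_um Fixed waists for the mobility fits.
#' @param fit_window_ns Post-peak fit range (ns).
#' @return Data frame with one row per window: \code{t_mid_s},
#'   \code{n_photons}, \code{tau_ns} (NA when masked) and, if requested,
#'   \code{D_ratio}.
#' @export
lifetime_vs_time <- function(photons, window_s = 5, laser_period_ns,
                             bin_ns = 0.048, min_photons = 1000,
                             geometry = detector_geometry(),
                             mobility = FALSE, w0_central_um = 0.3,
                             w0_sum_um = 0.4, fit_window_ns = 10) {
  t_s <- photons$t_ns * 1e-9
  nw <- max(1L, ceiling(max(t_s) / window_s - 1e-9))
  out <- data.frame(t_mid_s = (seq_len(nw) - 0.5) * window_s,
                    n_photons = NA_integer_, tau_ns = NA_real_)
  if (mobility) out$D_ratio <- NA_real_
  nb <- ceiling(laser_period_ns / bin_ns)
  for (k in seq_len(nw)) {
    sel <- t_s >= (k - 1) * window_s & t_s < k * window_s
    out$n_photons[k] <- sum(sel)
    if (sum(sel) < min_photons) next
    d <- photons$delay_ns[sel] %% laser_period_ns
    h <- tabulate(pmin(floor(d / bin_ns), nb - 1L) + 1L, nbins = nb)
    ft <- fit_decay(h, bin_ns, fit_window_ns = fit_window_ns)
    out$tau_ns[k] <- ft[["tau_ns"]]
    if (mobility) {
      pc <- merge_channels(photons[sel, ], "central", geometry)
      p5 <- merge_channels(photons[sel, ], "sum5x5", geometry)
      cc <- correlate(pc, chunk_s = window_s / 2, max_lag_s = 0.2,
                      reject_sigma = Inf)
      c5 <- correlate(p5, chunk_s = window_s / 2, max_lag_s = 0.2,
                      reject_sigma = Inf)
      fc <- fit_point_fcs(cc, w0_central_um, k = geometry$k_central)
      f5 <- fit_point_fcs(c5, w0_sum_um, k = geometry$k_sum)
      out$D_ratio[k] <- fc$D_um2_s / f5$D_um2_s
    }
  }
  out
}

#' Single-exponential + offset fit of a decay histogram
#'
#' Fits \code{A exp(-t/tau) + B} on the post-peak range of a TCSPC
#' histogram (nonlinear least squares, port algorithm).
#'
#' @param hist Counts per bin.
#' @param bin_ns Bin width (ns).
#' @param fit_window_ns Post-peak range length (default 10 ns).
#' @return Named vector c(A, tau_ns, B).
#' @export
fit_decay <- function(hist, bin_ns, fit_window_ns = 10) {
  nb <- length(hist)
  pk <- which.max(hist)
  hi <- min(nb, pk + ceiling(fit_window_ns / bin_ns))
  rng <- pk:hi
  tt <- (rng - pk) * bin_ns
  y <- hist[rng]
  tau0 <- max(bin_ns, sum(y * tt) / sum(y))
  fit <- tryCatch(
    nls(y ~ A * exp(-tt / tau) + B,
        start = list(A = max(y), tau = tau0, B = max(min(y), 0.5)),
        lower = c(A = 0, tau = bin_ns / 10, B = 0), algorithm = "port",
        control = nls.control(maxiter = 200, warnOnly = TRUE)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(c(A = NA_real_, tau_ns = NA_real_, B = NA_real_))
  }
  co <- coef(fit)
  c(A = co[["A"]], tau_ns = co[["tau"]], B = co[["B"]])
}
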