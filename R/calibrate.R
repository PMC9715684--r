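# ---------------------------------------------------------------------------
# Code-density calibration and time reconstruction.
#
# Because the START/STOP delay lines are asynchronous to the free-running
# clock, temporally random events populate the tap codes in proportion to
# the physical tap widths.  A code-density test (many uncorrelated events)
# therefore measures the code -> time mapping directly, and the same
# statistics yield the DNL/INL linearity figures.
# ---------------------------------------------------------------------------

#' Code-density calibration of one delay line
#'
#' Estimates per-code tap widths from the code histogram of temporally
#' uncorrelated events and builds the code -> time map.  The width of code
#' i is its occupancy fraction times the clock period; the mapped time of
#' code k is the cumulative width below it plus half its own width
#' (bin-center convention).
#'
#' @param codes Integer vector of observed tap codes (0-based), from
#'   temporally uncorrelated events.
#' @param n_codes Number of codes of the line (default \code{max(codes)+1}).
#' @param clock_period_ns Clock period (ns).
#' @param min_events Minimum number of events required (default 1e5; the
#'   statistical error of the widths scales as 1/sqrt(counts)).
#' @return Object of class \code{tdl_calibration}: list with
#'   \code{widths_ns}, \code{time_ns} (bin-center map, ns), \code{counts},
#'   \code{n_codes}, \code{clock_period_ns}.
#' @export
code_density_calibrate <- function(codes, n_codes = NULL,
                                   clock_period_ns = ttm_clock_period(),
                                   min_events = 1e5) {
  if (length(codes) < min_events) {
    stop(sprintf("code-density test needs >= %g events, got %d",
                 min_events, length(codes)))
  }
  if (is.null(n_codes)) n_codes <- max(codes) + 1L
  counts <- tabulate(codes + 1L, nbins = n_codes)
  if (any(counts == 0L)) {
    warning(sprintf("%d empty code bins assigned zero width",
                    sum(counts == 0L)))
  }
  widths <- counts / sum(counts) * clock_period_ns
  time_ns <- cumsum(widths) - widths / 2
  structure(list(widths_ns = widths, time_ns = time_ns, counts = counts,
                 n_codes = as.integer(n_codes),
                 clock_period_ns = clock_period_ns),
            class = "tdl_calibration")
}

#' @export
print.tdl_calibration <- function(x, ...) {
  cat(sprintf("<tdl_calibration> %d codes, mean width %.2f ps (%d events)\n",
              x$n_codes, mean(x$widths_ns) * 1e3, sum(x$counts)))
  invisible(x)
}

#' Map tap codes to times through a calibration
#' @param cal A \code{tdl_calibration}.
#' @param codes Integer codes (0-based).
#' @return Times in ns (bin centers).
#' @export
codes_to_time <- function(cal, codes) cal$time_ns[codes + 1L]

#' Differential and integral nonlinearity of a delay line
#'
#' DNL of code i is its width relative to the ideal LSB minus one
#' (\code{LSB_ideal = clock_period / n_codes}); INL is the running sum of
#' the DNL.  Reported sigmas are population standard deviations in LSB
#' units.  The report is invariant to rescaling the counts.
#'
#' @param counts Per-code event counts from a code-density test.
#' @param clock_period_ns Clock period (ns).
#' @return List with \code{dnl}, \code{inl} (LSB units), \code{sigma_dnl},
#'   \code{sigma_inl}, \code{lsb_ideal_ps}.
#' @export
nonlinearity <- function(counts, clock_period_ns = ttm_clock_period()) {
  n_codes <- length(counts)
  widths <- counts / sum(counts) * clock_period_ns
  lsb_ideal <- clock_period_ns / n_codes
  dnl <- widths / lsb_ideal - 1
  inl <- cumsum(dnl)
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  list(dnl = dnl, inl = inl,
       sigma_dnl = pop_sd(dnl), sigma_inl = pop_sd(inl),
       lsb_ideal_ps = lsb_ideal * 1e3)
}

#' Start-stop time from fine and coarse TDC values
#'
#' Implements the reconstruction formula
#' \code{dt = dt_stop - dt_start + dn * T_sysclk}, with
#' \code{dn = n_SYNC - n_photon} the elapsed clock cycles between the
#' photon (START) and its following laser SYNC (STOP).  The caller applies
#' the modulo with the laser period downstream.
#'
#' @param dt_start,dt_stop Fine TDC times (ns), measured from the clock
#'   edge preceding the event.
#' @param dn Integer clock-cycle difference, must be >= 0.
#' @param clock_period_ns Clock period (ns).
#' @return Start-stop times (ns).  Negative values with \code{dn == 0} are
#'   flagged with a warning (mis-association).
#' @export
start_stop <- function(dt_start, dt_stop, dn,
                       clock_period_ns = ttm_clock_period()) {
  if (any(dn < 0)) stop("dn must be >= 0 (SYNC must follow the photon)")
  dt <- dt_stop - dt_start + dn * clock_period_ns
  if (any(dt < 0)) {
    warning(sprintf("%d negative start-stop times flagged (mis-association)",
                    sum(dt < 0)))
  }
  dt
}

#' Coarse absolute and relative times from counter values
#'
#' The coarse counter gives nanosecond-precision times by integer
#' arithmetic: the photon's coarse absolute time is
#' \code{n_photon * T_sysclk} and its delay from a REF event is
#' \code{(n_photon - n_ref) * T_sysclk}.  With the SYNC fine time the
#' absolute SYNC time is \code{n_sync * T_sysclk + dt_sync}.
#'
#' @param n_photon,n_sync,n_ref Monotonic (unwrapped) counter values.
#' @param dt_sync Fine SYNC times (ns), optional.
#' @param clock_period_ns Clock period (ns).
#' @return List with \code{t_photon_ns}, and where inputs are given
#'   \code{dt_ref_ns} and \code{t_sync_ns}.
#' @export
coarse_times <- function(n_photon, n_sync = NULL, n_ref = NULL,
                         dt_sync = NULL,
                         clock_period_ns = ttm_clock_period()) {
  out <- list(t_photon_ns = n_photon * clock_period_ns)
  if (!is.null(n_ref)) {
    out$dt_ref_ns <- (n_photon - n_ref) * clock_period_ns
  }
  if (!is.null(n_sync)) {
    ts <- n_sync * clock_period_ns
    if (!is.null(dt_sync)) ts <- ts + dt_sync
    out$t_sync_ns <- ts
  }
  out
}

#' Single-shot precision from repeated constant-delay measurements
#'
#' Histograms the measured start-stop times and fits a Gaussian by least
#' squares with Poisson weights; falls back to the sample standard
#' deviation if the fit fails.  Used both for the single-channel SSP and
#' for the dual-channel variant (histogram of pairwise channel
#' differences).
#'
#' @param dt_ns Measured delays (ns) of a constant true delay; >= 1e4
#'   samples recommended.
#' @param bin_ps Histogram bin width (ps, default 48 = one LSB).
#' @return List with \code{sigma_ps}, \code{center_ns}, \code{method}
#'   ("gaussian_fit" or "sample_sd") and \code{fit_warning} (TRUE when the
#'   histogram looks non-unimodal).
#' @export
single_shot_precision <- function(dt_ns, bin_ps = 48) {
  bw <- bin_ps * 1e-3
  br <- range(dt_ns)
  breaks <- seq(floor(br[1] / bw) * bw, ceiling(br[2] / bw) * bw + bw, by = bw)
  h <- graphics::hist(dt_ns, breaks = breaks, plot = FALSE)
  x <- h$mids
  y <- h$counts
  keep <- y > 0
  fit_warning <- FALSE
  # crude unimodality check: more than one well-separated local max above
  # half peak height
  pk <- which(y > max(y) / 2)
  if (length(pk) && any(diff(pk) > 3)) fit_warning <- TRUE
  mu0 <- sum(x * y) / sum(y)
  s0 <- sqrt(sum(y * (x - mu0)^2) / sum(y))
  fit <- tryCatch({
    nls(y ~ a * exp(-(x - mu)^2 / (2 * s^2)),
        start = list(a = max(y), mu = mu0, s = max(s0, bw / 2)),
        weights = 1 / pmax(y, 1),  # Poisson weights
        subset = keep,
        control = nls.control(maxiter = 200, warnOnly = TRUE))
  }, error = function(e) NULL)
  if (!is.null(fit) && is.finite(coef(fit)[["s"]])) {
    co <- coef(fit)
    list(sigma_ps = abs(co[["s"]]) * 1e3, center_ns = co[["mu"]],
         method = "gaussian_fit", fit_warning = fit_warning)
  } else {
    list(sigma_ps = s0 * 1e3, center_ns = mu0,
         method = "sample_sd", fit_warning = fit_warning)
  }
}

#' Phasor-based inter-channel time alignment
#'
#' Each detector element and TDC introduces a fixed delay, so the decay
#' histograms of the channels are mutually shifted.  Using a reference
#' measurement of a known single-exponential emitter (fluorescein,
#' lifetime 4.1 ns), each channel's histogram phase at the laser harmonic
#' is compared with the phase expected from the reference lifetime
#' (\code{atan(w * tau)}); the phase excess divided by \code{w} is the
#' channel's time offset.  Offsets are amplitude-free (phase only), so they
#' are invariant to histogram rescaling; applying them is a circular shift
#' in time.
#'
#' @param histograms Matrix (bins x channels) of reference TCSPC counts.
#' @param bin_ns Histogram bin width (ns).
#' @param laser_period_ns Laser repetition period (ns).
#' @param reference_lifetime_ns Known lifetime of the reference dye
#'   (default 4.1, fluorescein in water).
#' @param min_counts Channels with fewer counts get offset 0 with a warning.
#' @return Numeric vector of per-channel time offsets (ns): the measured
#'   delay each channel adds, to be subtracted to align histograms.
#' @export
align_channels <- function(histograms, bin_ns, laser_period_ns,
                           reference_lifetime_ns = 4.1, min_counts = 100) {
  histograms <- as.matrix(histograms)
  w <- 2 * pi / laser_period_ns
  centers <- (seq_len(nrow(histograms)) - 0.5) * bin_ns
  phi_expected <- atan(w * reference_lifetime_ns)
  low <- colSums(histograms) < min_counts
  if (any(low)) {
    warning(sprintf("%d channels below %g counts: offset set to 0",
                    sum(low), min_counts))
  }
  offs <- vapply(seq_len(ncol(histograms)), function(ch) {
    if (low[ch]) return(0)
    cnt <- histograms[, ch]
    g <- sum(cnt * cos(w * centers)) / sum(cnt)
    s <- sum(cnt * sin(w * centers)) / sum(cnt)
    phi <- atan2(s, g)
    d <- (phi - phi_expected) / w
    # wrap into (-period/2, period/2]
    d - round(d / laser_period_ns) * laser_period_ns
  }, numeric(1))
  offs
}

#' Apply per-channel offsets as a circular time shift
#'
#' Shifts each channel's histogram back by its measured offset using the
#' Fourier shift theorem (circular, bin-width independent).
#'
#' @param histograms Matrix (bins x channels).
#' @param offsets_ns Per-channel offsets as returned by
#'   \code{\link{align_channels}}.
#' @param bin_ns Bin width (ns).
#' @return Shifted histogram matrix (real-valued).
#' @export
shift_histograms <- function(histograms, offsets_ns, bin_ns) {
  histograms <- as.matrix(histograms)
  nb <- nrow(histograms)
  freq <- c(0:(nb %/% 2), -((nb - nb %/% 2 - 1):1)) / (nb * bin_ns)
  if (nb %% 2 == 0) freq[nb %/% 2 + 1] <- abs(freq[nb %/% 2 + 1])
  out <- vapply(seq_len(ncol(histograms)), function(ch) {
    ph <- exp(2i * pi * freq * offsets_ns[ch])
    Re(fft(fft(histograms[, ch]) * ph, inverse = TRUE)) / nb
  }, numeric(nb))
  out
}
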