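# ---------------------------------------------------------------------------
# Sliding-scale interpolating TDC model.
#
# Each photon channel owns a START tapped-delay line (TDL); all channels
# share one STOP line for the laser SYNC.  An asynchronous event enters the
# line and propagates until the next rising edge of the free-running
# 240 MHz clock; the tap it has reached encodes the sub-clock interval
# (edge_time - event_time).  Because events are asynchronous to the clock,
# the code occupancy of random events is proportional to the tap widths --
# the premise of the statistical code-density self-calibration.
# ---------------------------------------------------------------------------

#' Tapped-delay-line model
#'
#' Builds the ground-truth TDL tap widths for the simulator.  The default
#' is 87 uniform taps of 48 ps (the nominal LSB), which spans 4.176 ns,
#' slightly longer than the 4.1667 ns clock period as the hardware
#' requires.  Non-uniform lines draw tap widths log-normally around the
#' nominal width (controlled dispersion) and are used to exercise the
#' code-density calibration.
#'
#' @param n_taps Number of taps per line (default 87).
#' @param lsb_ps Nominal tap width in ps (default 48).
#' @param dispersion Relative log-normal dispersion of tap widths
#'   (default 0 = ideal uniform line).
#' @param n_start_lines Number of START lines (one per photon channel).
#' @param clock_period_ns System clock period (ns).
#' @param seed Optional seed for reproducible tap widths.
#' @return Object of class \code{tdl_model}: list with \code{start_widths}
#'   (matrix n_taps x n_start_lines, ps), \code{stop_widths} (vector, ps)
#'   and \code{clock_period_ns}.
#' @export
tdl_model <- function(n_taps = 87L, lsb_ps = 48, dispersion = 0,
                      n_start_lines = 25L,
                      clock_period_ns = ttm_clock_period(), seed = NULL) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  draw <- function(n) {
    if (dispersion > 0) {
      lsb_ps * exp(rnorm(n, -dispersion^2 / 2, dispersion))
    } else {
      rep(lsb_ps, n)
    }
  }
  rescale <- function(w) {
    # keep the line "slightly longer than the clock period"
    span <- n_taps * lsb_ps
    w * (span / sum(w))
  }
  sw <- vapply(seq_len(n_start_lines),
               function(i) rescale(draw(n_taps)), numeric(n_taps))
  stw <- rescale(draw(n_taps))
  if (n_taps * lsb_ps < clock_period_ns * 1e3) {
    stop("TDL span shorter than the clock period; increase n_taps or lsb_ps")
  }
  structure(list(start_widths = sw, stop_widths = stw,
                 n_taps = as.integer(n_taps), lsb_ps = lsb_ps,
                 clock_period_ns = clock_period_ns),
            class = "tdl_model")
}

#' @export
print.tdl_model <- function(x, ...) {
  cat(sprintf("<tdl_model> %d taps x %d START lines + 1 STOP line, LSB %.1f ps\n",
              x$n_taps, ncol(x$start_widths), x$lsb_ps))
  invisible(x)
}

#' Quantize event times through a tapped delay line
#'
#' Converts continuous event times to (coarse count, tap code) pairs.  The
#' coarse count \code{n} is the number of clock cycles from t = 0 to the
#' next rising edge after the event; the code is the index of the tap
#' interval containing (edge_time - event_time).  Events arriving within
#' one full line traversal (the TDC dead time, about 4.2 ns) of a previous
#' accepted event on the same line are dropped and counted.
#'
#' @param times_ns Event times (ns), need not be sorted; dead time is
#'   applied in time order.
#' @param widths_ps Tap widths of the line (ps).
#' @param clock_period_ns Clock period (ns).
#' @param apply_dead_time Drop events within one line traversal of the
#'   previous accepted event on this line (default TRUE).
#' @return List with \code{n} (integer coarse counts), \code{code}
#'   (integer tap indices, 0-based), \code{kept} (logical index into the
#'   time-sorted input) and \code{n_dead_dropped}.
#' @export
tdc_encode <- function(times_ns, widths_ps,
                       clock_period_ns = ttm_clock_period(),
                       apply_dead_time = TRUE) {
  ord <- order(times_ns)
  t <- times_ns[ord]
  kept <- rep(TRUE, length(t))
  dead_ns <- sum(widths_ps) * 1e-3
  if (apply_dead_time && length(t) > 1L && any(diff(t) < dead_ns)) {
    # sequential dead time: an event is dropped if within dead_ns of the
    # last *accepted* event
    last <- -Inf
    for (i in seq_along(t)) {
      if (t[i] - last < dead_ns) kept[i] <- FALSE else last <- t[i]
    }
  }
  tk <- t[kept]
  n <- as.integer(ceiling(tk / clock_period_ns))
  on_edge <- tk == n * clock_period_ns  # measure to *next* edge: open at 0
  n[on_edge] <- n[on_edge] + 1L
  delta_ns <- n * clock_period_ns - tk
  edges <- cumsum(widths_ps) * 1e-3
  code <- findInterval(delta_ns, edges, left.open = TRUE)
  code[code >= length(widths_ps)] <- length(widths_ps) - 1L
  list(n = n, code = as.integer(code), kept = kept, order = ord,
       n_dead_dropped = sum(!kept))
}
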