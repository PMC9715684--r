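# ---------------------------------------------------------------------------
# Pre-processing: decoded frames -> joinable event tables.
#
# The main table has one row per transmitted SYNC event (monotonic counter
# n_SYNC, stop code, scan coordinates, unique row index idx); each of the
# 25 channel tables has one row per photon (start code, elapsed cycles
# dn = n_SYNC - n_photon, join key idx).  Calibration adds t_SYNC to the
# main table and the start-stop time dt to the channel tables.
# ---------------------------------------------------------------------------

#' Unwrap the 16-bit coarse counter into a monotonic counter
#'
#' Whenever the raw counter value decreases, one rollover (2^16) is added
#' to it and to all following values.  Force-write frames guarantee at
#' least one structure per sixteenth of the rollover period, so consecutive
#' frames can never legitimately be more than one rollover apart.
#'
#' @param step Raw 16-bit counter values per frame, in stream order.
#' @param warn_gap_cycles Warn when consecutive unwrapped values differ by
#'   more than this many cycles (default one rollover: possible fail-safe
#'   data loss upstream).
#' @return Numeric vector of monotonic counter values, congruent to
#'   \code{step} modulo 2^16.
#' @export
unwrap_counter <- function(step, warn_gap_cycles = 2^16) {
  if (!length(step)) return(numeric(0))
  wraps <- cumsum(c(0, diff(step) < 0))
  n <- step + wraps * 2^16
  if (any(diff(n) > warn_gap_cycles)) {
    warning("counter gap exceeding one rollover period: possible data loss")
  }
  n
}

#' Build main and channel tables from decoded frames
#'
#' Implements the reverse start-stop strategy: each photon (START) is
#' associated with the first subsequent SYNC (STOP) event, whether it sits
#' in the same data structure or a later one.  When photon and SYNC share a
#' frame, the tap codes disambiguate the order within the clock cycle
#' (larger code = earlier in the cycle).  Photons with no SYNC within the
#' orphan window are discarded and counted.
#'
#' @param decoded Columnar decode as returned by \code{\link{decode_words}}.
#' @param laser_period_ns Laser period, used for the orphan window.
#' @param orphan_window_periods Photons whose matched SYNC lies more than
#'   this many laser periods ahead are discarded (default 2).
#' @param n_channels Number of photon channels.
#' @param clock_period_ns Clock period (ns).
#' @return Object of class \code{ttm_tables}: list with \code{main} (data
#'   frame: idx, n_sync, stop_code, x, y, fr), \code{channels} (list of
#'   data frames: start_code, dn, idx), \code{n_orphans} and the constants.
#' @export
match_start_stop <- function(decoded, laser_period_ns,
                             orphan_window_periods = 2, n_channels = 25L,
                             clock_period_ns = ttm_clock_period()) {
  h <- decoded$headers
  hits <- decoded$hits
  n_mono <- unwrap_counter(h$step)
  coords <- assign_coordinates(h)
  # SYNC events -> main table
  sy <- which(h$sync_valid)
  main <- data.frame(idx = seq_along(sy), n_sync = n_mono[sy],
                     stop_code = h$stop_code[sy],
                     x = coords$x[sy], y = coords$y[sy], fr = coords$fr[sy])
  # photons -> first sync with n_sync >= n_photon
  ph_n <- n_mono[hits$frame]
  ph_code <- hits$start_code
  keep <- rep(TRUE, nrow(hits))
  if (nrow(main)) {
    pos <- findInterval(ph_n - 1, main$n_sync) + 1L
    same <- pos <= nrow(main) & main$n_sync[pmin(pos, nrow(main))] == ph_n
    # same-frame order: the TDL code measures event -> next clock edge, so
    # a larger code means the event happened earlier in the cycle; the
    # SYNC is the photon's stop only if it comes later (smaller code)
    adv <- same & main$stop_code[pmin(pos, nrow(main))] > ph_code
    pos[adv] <- pos[adv] + 1L
    ok <- pos <= nrow(main)
    win <- orphan_window_periods * laser_period_ns / clock_period_ns
    ok[ok] <- (main$n_sync[pos[ok]] - ph_n[ok]) <= win
    keep <- ok
    dn <- rep(NA_real_, nrow(hits))
    dn[keep] <- main$n_sync[pos[keep]] - ph_n[keep]
    idx <- rep(NA_integer_, nrow(hits))
    idx[keep] <- main$idx[pos[keep]]
  } else {
    keep[] <- FALSE
    dn <- rep(NA_real_, nrow(hits))
    idx <- rep(NA_integer_, nrow(hits))
  }
  channels <- lapply(seq_len(n_channels) - 1L, function(ch) {
    sel <- which(hits$channel == ch & keep & hits$valid)
    data.frame(start_code = hits$start_code[sel], dn = dn[sel],
               idx = idx[sel])
  })
  names(channels) <- sprintf("ch%02d", seq_len(n_channels) - 1L)
  structure(list(main = main, channels = channels,
                 n_orphans = sum(!keep | !hits$valid),
                 n_channels = as.integer(n_channels),
                 clock_period_ns = clock_period_ns,
                 laser_period_ns = laser_period_ns,
                 calibrated = FALSE),
            class = "ttm_tables")
}

#' @export
print.ttm_tables <- function(x, ...) {
  cat(sprintf("<ttm_tables> %d SYNC rows, %d photons in %d channels%s\n",
              nrow(x$main), sum(vapply(x$channels, nrow, 1L)),
              x$n_channels, if (x$calibrated) " (calibrated)" else ""))
  invisible(x)
}

#' Scan-coordinate assignment from REF flags
#'
#' Pixel, line and frame clocks update the coordinate counters: a pixel
#' event increments x; a line event resets x and increments y; a frame
#' event resets x and y and increments fr.  All counters start at -1 so
#' the first clock of each kind addresses index 0; photons arriving before
#' the first pixel event carry x = -1 and are excluded from images.  When
#' several flags share one frame they apply in nested order (frame, line,
#' pixel).
#'
#' @param headers Header data frame from \code{\link{decode_words}}.
#' @return Data frame with \code{x}, \code{y}, \code{fr} per input frame:
#'   the counter state at (after) that frame.
#' @export
assign_coordinates <- function(headers) {
  nf <- nrow(headers)
  # event-driven state machine over the (sparse) flagged frames
  x <- y <- fr <- rep(-1L, nf)
  flagged <- which(headers$ref_pixel | headers$ref_line | headers$ref_frame)
  cx <- cy <- cf <- -1L
  xs <- ys <- frs <- integer(length(flagged))
  for (k in seq_along(flagged)) {
    i <- flagged[k]
    if (headers$ref_frame[i]) { cx <- -1L; cy <- -1L; cf <- cf + 1L }
    if (headers$ref_line[i]) { cx <- -1L; cy <- cy + 1L }
    if (headers$ref_pixel[i]) cx <- cx + 1L
    xs[k] <- cx; ys[k] <- cy; frs[k] <- cf
  }
  if (length(flagged)) {
    seg <- findInterval(seq_len(nf), flagged)
    has <- seg >= 1L
    x[has] <- xs[seg[has]]
    y[has] <- ys[seg[has]]
    fr[has] <- frs[seg[has]]
  }
  data.frame(x = x, y = y, fr = fr)
}

#' Apply a TDC calibration to event tables
#'
#' Converts tap codes to times and evaluates the start-stop formula
#' \code{dt = dt_STOP - dt_START + dn * T_sysclk} for every photon, plus
#' the absolute SYNC time for every main-table row.  The calibration maps
#' a code to the captured interval (event to next clock edge); the
#' previous-edge times entering the formula are the clock period minus
#' that interval.
#'
#' @param tables A \code{ttm_tables}.
#' @param start_cals List of \code{tdl_calibration}, one per channel (or a
#'   single calibration recycled).
#' @param stop_cal \code{tdl_calibration} of the shared STOP line.
#' @param offsets_ns Optional per-channel time offsets (from
#'   \code{\link{align_channels}}), subtracted from the channel's dt.
#' @return The tables with \code{t_sync_ns} added to main and
#'   \code{dt_ns} to each channel table; \code{calibrated} set.
#' @export
calibrate_tables <- function(tables, start_cals, stop_cal,
                             offsets_ns = NULL) {
  stopifnot(inherits(tables, "ttm_tables"))
  Tc <- tables$clock_period_ns
  nch <- tables$n_channels
  if (inherits(start_cals, "tdl_calibration")) {
    start_cals <- rep(list(start_cals), nch)
  }
  if (is.null(offsets_ns)) offsets_ns <- numeric(nch)
  cap_s <- codes_to_time(stop_cal, tables$main$stop_code)
  tables$main$t_sync_ns <- tables$main$n_sync * Tc - cap_s
  for (ch in seq_len(nch)) {
    tb <- tables$channels[[ch]]
    if (!nrow(tb)) { tables$channels[[ch]]$dt_ns <- numeric(0); next }
    cap_p <- codes_to_time(start_cals[[ch]], tb$start_code)
    # dt = (T - cap_s) - (T - cap_p) + dn*T  =  cap_p - cap_s + dn*T
    dt <- cap_p - cap_s[tb$idx] + tb$dn * Tc - offsets_ns[ch]
    tables$channels[[ch]]$dt_ns <- dt
  }
  tables$calibrated <- TRUE
  tables
}

#' Flat calibrated photon list from tables
#'
#' Joins every channel table to the main table and returns one row per
#' photon with its absolute time (the t_SYNC of its SYNC event, the
#' standard shortcut for fluctuation work), start-stop time, TCSPC delay
#' (delay from the previous laser pulse), raw tap code, channel and scan
#' coordinates.
#'
#' @param tables Calibrated \code{ttm_tables}.
#' @return Data frame sorted by absolute time.
#' @export
photon_list <- function(tables) {
  stopifnot(isTRUE(tables$calibrated))
  Tl <- tables$laser_period_ns
  out <- do.call(rbind, lapply(seq_len(tables$n_channels), function(ch) {
    tb <- tables$channels[[ch]]
    if (!nrow(tb)) return(NULL)
    m <- tables$main[tb$idx, ]
    data.frame(t_ns = m$t_sync_ns, dt_ns = tb$dt_ns,
               delay_ns = (Tl - tb$dt_ns) %% Tl,
               start_code = tb$start_code,
               channel = ch - 1L, x = m$x, y = m$y, fr = m$fr)
  }))
  if (is.null(out)) {
    out <- data.frame(t_ns = numeric(0), dt_ns = numeric(0),
                      delay_ns = numeric(0), start_code = integer(0),
                      channel = integer(0), x = integer(0), y = integer(0),
                      fr = integer(0))
  }
  out <- out[order(out$t_ns), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write / read event tables to HDF5
#'
#' One file holds the main table at \code{/main}, the channel tables at
#' \code{/ch00} ... \code{/ch24} and the constants as attributes of the
#' root group (\code{T_sysclk_ns}, \code{laser_period_ns}, schema version).
#' The round trip is lossless.
#'
#' @param tables A \code{ttm_tables}.
#' @param path HDF5 file path.
#' @param level Deflate compression level 0-9 (default 4; 0 and 4 read
#'   back identically).
#' @return \code{write_tables}: invisibly the path; \code{read_tables}:
#'   the \code{ttm_tables}.
#' @export
write_tables <- function(tables, path, level = 4) {
  stopifnot(inherits(tables, "ttm_tables"))
  if (file.exists(path)) file.remove(path)
  rhdf5::h5createFile(path)
  fid <- rhdf5::H5Fopen(path)
  on.exit(rhdf5::H5Fclose(fid), add = TRUE)
  rhdf5::h5writeDataset(tables$main, fid, "main", level = level)
  for (ch in seq_len(tables$n_channels)) {
    tb <- tables$channels[[ch]]
    # HDF5 compound datasets cannot be empty: skip and reconstitute on read
    if (nrow(tb) > 0L) {
      rhdf5::h5writeDataset(tb, fid, names(tables$channels)[ch],
                            level = level)
    }
  }
  meta <- c(schema_version = 1, n_channels = tables$n_channels,
            T_sysclk_ns = tables$clock_period_ns,
            laser_period_ns = tables$laser_period_ns,
            n_orphans = tables$n_orphans,
            calibrated = as.numeric(tables$calibrated))
  rhdf5::h5writeDataset(meta, fid, "meta")
  rhdf5::h5writeDataset(names(meta), fid, "meta_names")
  invisible(path)
}

#' @rdname write_tables
#' @export
read_tables <- function(path) {
  meta_v <- rhdf5::h5read(path, "meta")
  names(meta_v) <- rhdf5::h5read(path, "meta_names")
  if (meta_v[["schema_version"]] != 1) {
    stop(sprintf("unsupported table schema version %g",
                 meta_v[["schema_version"]]))
  }
  nch <- as.integer(meta_v[["n_channels"]])
  undim <- function(df) {
    as.data.frame(lapply(df, function(col) { dim(col) <- NULL; col }))
  }
  main <- undim(rhdf5::h5read(path, "main"))
  present <- rhdf5::h5ls(path)$name
  calibrated <- meta_v[["calibrated"]] == 1
  empty_channel <- if (calibrated) {
    data.frame(start_code = integer(0), dn = numeric(0), idx = integer(0),
               dt_ns = numeric(0))
  } else {
    data.frame(start_code = integer(0), dn = numeric(0), idx = integer(0))
  }
  chn <- sprintf("ch%02d", seq_len(nch) - 1L)
  channels <- lapply(chn, function(nm) {
    if (nm %in% present) undim(rhdf5::h5read(path, nm)) else empty_channel
  })
  names(channels) <- chn
  structure(list(main = main, channels = channels,
                 n_orphans = as.integer(meta_v[["n_orphans"]]),
                 n_channels = nch,
                 clock_period_ns = meta_v[["T_sysclk_ns"]],
                 laser_period_ns = meta_v[["laser_period_ns"]],
                 calibrated = meta_v[["calibrated"]] == 1),
            class = "ttm_tables")
}

#' Full pipeline: word stream to calibrated photon list
#'
#' Convenience wrapper chaining decode, table building and calibration.
#'
#' @param words Integer word vector (or a path to a \code{.ttm} file).
#' @param laser_period_ns Laser period (ns).
#' @param start_cals,stop_cal Calibrations (see
#'   \code{\link{calibrate_tables}}).
#' @param n_channels Number of photon channels.
#' @return List with \code{tables} (calibrated) and \code{photons}
#'   (flat photon list).
#' @export
process_stream <- function(words, laser_period_ns, start_cals, stop_cal,
                           n_channels = 25L) {
  if (is.character(words)) words <- read_ttm(words)
  dec <- decode_words(words, n_channels)
  tb <- match_start_stop(dec, laser_period_ns, n_channels = n_channels)
  tb <- calibrate_tables(tb, start_cals, stop_cal)
  list(tables = tb, photons = photon_list(tb))
}
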