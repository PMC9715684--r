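#' @useDynLib ttmtools, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif rexp rpois sd coef nls optim median
#'   fft mad quantile approx nls.control
#' @importFrom graphics hist
#' @importFrom utils head tail
NULL

# ---------------------------------------------------------------------------
# On-the-wire word format.
#
# Every word is 16 bits: a 7-bit identifier (ID, bits 15..9), a 1-bit valid
# flag (bit 8) and an 8-bit payload (bits 7..0).  A frame-like data
# structure -- one slot of the free-running 240 MHz system clock that the
# event filter decided to transmit -- serializes to exactly 5 header words
# (IDs 123..127, in that order) followed by one word per channel hit
# (ID = channel index), in ascending channel order; channels without a hit
# produce no words (zero suppression).
#
# Header payloads:
#   ID 123  bits 0..2 = pixel/line/frame REF flags, bit 3 = VL
#           ("laser data valid"), bits 4..7 = 0
#   ID 124  SYNC tapped-delay-line value (stop code)
#   ID 125  STEP low byte   (free-running 16-bit coarse counter)
#   ID 126  STEP high byte
#   ID 127  spare / debug byte
# ---------------------------------------------------------------------------

TTM_HEADER_IDS <- 123:127
TTM_SYSCLK_HZ <- 240e6

#' System clock period of the time-tagging module
#'
#' The module's whole architecture runs at a 240 MHz system clock; the
#' coarse counter increments once per period.
#'
#' @return Clock period in nanoseconds (about 4.1667 ns).
#' @export
ttm_clock_period <- function() 1e9 / TTM_SYSCLK_HZ

#' Coarse-counter rollover and force-write periods
#'
#' The coarse counter is stored on 16 bits, so it rolls over every
#' \code{2^16} clock cycles (about 273 us).  To keep counter unwrapping
#' possible even with no photons, a force-write event transmits a frame at
#' least once per one-sixteenth of the rollover period (about 17 us).
#'
#' @return Named numeric vector with \code{rollover_us} and
#'   \code{force_write_us}.
#' @export
ttm_counter_periods <- function() {
  roll <- 2^16 / TTM_SYSCLK_HZ * 1e6
  c(rollover_us = roll, force_write_us = roll / 16)
}

#' Construct one frame-like data structure
#'
#' @param step Coarse-counter value, integer in [0, 65535].
#' @param stop_code SYNC tapped-delay-line value, integer in [0, 255].
#' @param sync_valid Logical; TRUE if a SYNC (laser) event occurred in this
#'   clock frame ("laser data valid", VL).
#' @param ref_pixel,ref_line,ref_frame Logical REF event flags.
#' @param spare Debug byte, integer in [0, 255].
#' @param hits Data frame with columns \code{channel} (integer, 0-based),
#'   \code{start_code} (integer in [0, 255]) and \code{valid} (logical); at
#'   most one row per channel.
#' @return An object of class \code{ttm_frame}.
#' @export
ttm_frame <- function(step = 0L, stop_code = 0L, sync_valid = FALSE,
                      ref_pixel = FALSE, ref_line = FALSE, ref_frame = FALSE,
                      spare = 0L, hits = NULL) {
  if (is.null(hits)) {
    hits <- data.frame(channel = integer(0), start_code = integer(0),
                       valid = logical(0))
  }
  hits <- hits[order(hits$channel), , drop = FALSE]
  rownames(hits) <- NULL
  structure(list(step = as.integer(step), stop_code = as.integer(stop_code),
                 sync_valid = isTRUE(sync_valid),
                 ref_pixel = isTRUE(ref_pixel), ref_line = isTRUE(ref_line),
                 ref_frame = isTRUE(ref_frame),
                 spare = as.integer(spare), hits = hits),
            class = "ttm_frame")
}

#' @export
print.ttm_frame <- function(x, ...) {
  cat(sprintf("<ttm_frame> step=%d VL=%s refs=[%s%s%s] hits=%d\n",
              x$step, x$sync_valid,
              if (x$ref_pixel) "P" else "-", if (x$ref_line) "L" else "-",
              if (x$ref_frame) "F" else "-", nrow(x$hits)))
  invisible(x)
}

#' @export
format.ttm_frame <- function(x, ...) {
  sprintf("ttm_frame(step=%d, hits=%d)", x$step, nrow(x$hits))
}

#' Compare two frames for equality
#' @param a,b \code{ttm_frame} objects.
#' @return Logical scalar.
#' @export
frames_equal <- function(a, b) {
  isTRUE(a$step == b$step) && isTRUE(a$stop_code == b$stop_code) &&
    a$sync_valid == b$sync_valid && a$ref_pixel == b$ref_pixel &&
    a$ref_line == b$ref_line && a$ref_frame == b$ref_frame &&
    a$spare == b$spare && nrow(a$hits) == nrow(b$hits) &&
    all(a$hits$channel == b$hits$channel) &&
    all(a$hits$start_code == b$hits$start_code) &&
    all(a$hits$valid == b$hits$valid)
}

pack_word <- function(id, valid, payload) {
  as.integer(id) * 512L + as.integer(valid) * 256L + as.integer(payload)
}

check_range <- function(x, lo, hi, field) {
  if (any(x < lo | x > hi | x != floor(x))) {
    stop(sprintf("encoding error: field '%s' out of range [%d, %d]",
                 field, lo, hi), call. = FALSE)
  }
}

#' Encode one frame to 16-bit words
#'
#' Serializes a frame to its on-the-wire representation: 5 header words
#' followed by one word per channel hit in ascending channel order.
#' Channels without hits are zero-suppressed.
#'
#' @param frame A \code{ttm_frame}.
#' @param n_channels Number of photon channels the format admits (default
#'   25; the architecture is 49-ready).
#' @return Integer vector of 16-bit word values (each in [0, 65535]).
#' @export
encode_frame <- function(frame, n_channels = 25L) {
  stopifnot(inherits(frame, "ttm_frame"))
  check_range(frame$step, 0L, 65535L, "step")
  check_range(frame$stop_code, 0L, 255L, "stop_code")
  check_range(frame$spare, 0L, 255L, "spare")
  h <- frame$hits
  if (nrow(h)) {
    check_range(h$channel, 0L, n_channels - 1L, "channel")
    check_range(h$start_code, 0L, 255L, "start_code")
    if (anyDuplicated(h$channel)) {
      stop("encoding error: field 'channel' has duplicate hits",
           call. = FALSE)
    }
  }
  flags <- as.integer(frame$ref_pixel) + 2L * as.integer(frame$ref_line) +
    4L * as.integer(frame$ref_frame) + 8L * as.integer(frame$sync_valid)
  header <- pack_word(TTM_HEADER_IDS, TRUE,
                      c(flags, frame$stop_code,
                        frame$step %% 256L, frame$step %/% 256L, frame$spare))
  if (nrow(h)) {
    ord <- order(h$channel)
    c(header, pack_word(h$channel[ord], h$valid[ord], h$start_code[ord]))
  } else {
    header
  }
}

unpack_words <- function(words) {
  words <- as.integer(words)
  data.frame(id = words %/% 512L,
             valid = (words %/% 256L) %% 2L == 1L,
             payload = words %% 256L)
}

frame_from_parts <- function(hdr_payload, ch) {
  flags <- hdr_payload[1L]
  ttm_frame(step = hdr_payload[3L] + 256L * hdr_payload[4L],
            stop_code = hdr_payload[2L],
            sync_valid = flags %/% 8L %% 2L == 1L,
            ref_pixel = flags %% 2L == 1L,
            ref_line = flags %/% 2L %% 2L == 1L,
            ref_frame = flags %/% 4L %% 2L == 1L,
            spare = hdr_payload[5L],
            hits = ch)
}

#' Decode a word stream into columnar frame tables
#'
#' Vectorized core decoder.  Splits the stream at header-start IDs,
#' validates each structure (the 5 header IDs must appear in order, channel
#' words must carry in-range IDs in strictly ascending channel order) and
#' drops corrupt structures with a count of discarded words, mirroring the
#' integrity check of the data receiver.  A truncated final structure is
#' dropped with a warning.
#'
#' @param words Integer vector of 16-bit word values.
#' @param n_channels Number of photon channels (default 25).
#' @return List with \code{headers} (data frame: step, stop_code,
#'   sync_valid, ref_pixel, ref_line, ref_frame, spare -- one row per good
#'   frame, in stream order), \code{hits} (data frame: frame -- row index
#'   into headers, channel, start_code, valid), \code{n_corrupt},
#'   \code{n_discarded_words}.
#' @export
decode_words <- function(words, n_channels = 25L) {
  w <- unpack_words(words)
  n <- nrow(w)
  empty <- list(
    headers = data.frame(step = integer(0), stop_code = integer(0),
                         sync_valid = logical(0), ref_pixel = logical(0),
                         ref_line = logical(0), ref_frame = logical(0),
                         spare = integer(0)),
    hits = data.frame(frame = integer(0), channel = integer(0),
                      start_code = integer(0), valid = logical(0)),
    n_corrupt = 0L, n_discarded_words = 0L)
  if (n == 0L) return(empty)
  first_id <- TTM_HEADER_IDS[1L]
  starts <- which(w$id == first_id)
  if (!length(starts)) {
    empty$n_corrupt <- 1L
    empty$n_discarded_words <- n
    return(empty)
  }
  n_corrupt <- 0L
  n_discard <- 0L
  if (starts[1L] > 1L) {  # garbage before the first header start
    n_discard <- starts[1L] - 1L
    n_corrupt <- 1L
  }
  seg_start <- starts
  seg_end <- c(starts[-1L] - 1L, n)
  seg_len <- seg_end - seg_start + 1L
  ns <- length(seg_start)
  # header validity (guard out-of-bounds via length check first)
  hdr_ok <- seg_len >= 5L
  idx <- which(hdr_ok)
  for (k in 1:4) {
    hdr_ok[idx] <- hdr_ok[idx] & w$id[seg_start[idx] + k] == first_id + k
  }
  truncated <- seg_len < 5L
  if (any(truncated)) warning("truncated final frame dropped")
  # per-word segment membership and offset
  pos <- seq_len(n)
  seg_of <- findInterval(pos, seg_start)
  off <- pos - seg_start[pmax(seg_of, 1L)]
  in_seg <- seg_of >= 1L
  is_ch <- in_seg & off > 4L
  # channel-word validity: in-range id, strictly ascending within segment
  bad_word <- is_ch & w$id >= n_channels
  # word p violates ascending order if p-1 is a channel word of the same
  # segment (off > 5 implies that) and ids do not strictly increase
  asc_bad <- is_ch & off > 5L & c(FALSE, diff(w$id) <= 0L)
  seg_bad_words <- tabulate(seg_of[bad_word | asc_bad], nbins = ns) > 0L
  good <- hdr_ok & !seg_bad_words
  if (any(!good)) {
    n_corrupt <- n_corrupt + sum(!good)
    n_discard <- n_discard + sum(seg_len[!good])
  }
  gidx <- which(good)
  if (!length(gidx)) {
    empty$n_corrupt <- n_corrupt
    empty$n_discarded_words <- n_discard
    return(empty)
  }
  s <- seg_start[gidx]
  flags <- w$payload[s]
  headers <- data.frame(
    step = w$payload[s + 2L] + 256L * w$payload[s + 3L],
    stop_code = w$payload[s + 1L],
    sync_valid = flags %/% 8L %% 2L == 1L,
    ref_pixel = flags %% 2L == 1L,
    ref_line = flags %/% 2L %% 2L == 1L,
    ref_frame = flags %/% 4L %% 2L == 1L,
    spare = w$payload[s + 4L])
  frame_row <- integer(ns)
  frame_row[gidx] <- seq_along(gidx)
  keep_ch <- is_ch & good[pmax(seg_of, 1L)]
  hits <- data.frame(frame = frame_row[seg_of[keep_ch]],
                     channel = w$id[keep_ch],
                     start_code = w$payload[keep_ch],
                     valid = w$valid[keep_ch])
  list(headers = headers, hits = hits, n_corrupt = n_corrupt,
       n_discarded_words = n_discard)
}

#' Decode a word stream into a list of frames
#'
#' Convenience wrapper around \code{\link{decode_words}} returning
#' \code{ttm_frame} objects in stream order.
#'
#' @param words Integer vector of 16-bit word values.
#' @param n_channels Number of photon channels (default 25).
#' @return List with \code{frames} (list of \code{ttm_frame}),
#'   \code{n_corrupt} and \code{n_discarded_words}.
#' @export
decode_stream <- function(words, n_channels = 25L) {
  d <- decode_words(words, n_channels)
  h <- d$headers
  hit_split <- split(d$hits[c("channel", "start_code", "valid")],
                     factor(d$hits$frame, levels = seq_len(nrow(h))))
  frames <- lapply(seq_len(nrow(h)), function(i) {
    hh <- hit_split[[i]]
    rownames(hh) <- NULL
    ttm_frame(step = h$step[i], stop_code = h$stop_code[i],
              sync_valid = h$sync_valid[i], ref_pixel = h$ref_pixel[i],
              ref_line = h$ref_line[i], ref_frame = h$ref_frame[i],
              spare = h$spare[i], hits = hh)
  })
  list(frames = frames, n_corrupt = d$n_corrupt,
       n_discarded_words = d$n_discarded_words)
}

#' Encode columnar frame tables into a word stream
#'
#' Vectorized bulk counterpart of \code{\link{encode_frame}} used by the
#' simulator to serialize large streams.
#'
#' @param headers Data frame as in \code{\link{decode_words}}.
#' @param hits Data frame (frame, channel, start_code, valid); rows are
#'   emitted in ascending channel order within each frame.
#' @param n_channels Number of photon channels.
#' @return Integer vector of 16-bit word values.
#' @export
encode_words <- function(headers, hits = NULL, n_channels = 25L) {
  nh <- nrow(headers)
  if (nh == 0L) return(integer(0))
  check_range(headers$step, 0L, 65535L, "step")
  check_range(headers$stop_code, 0L, 255L, "stop_code")
  check_range(headers$spare, 0L, 255L, "spare")
  if (!is.null(hits) && nrow(hits)) {
    check_range(hits$channel, 0L, n_channels - 1L, "channel")
    check_range(hits$start_code, 0L, 255L, "start_code")
    hits <- hits[order(hits$frame, hits$channel), , drop = FALSE]
    if (anyDuplicated(hits[c("frame", "channel")])) {
      stop("encoding error: field 'channel' has duplicate hits",
           call. = FALSE)
    }
  } else {
    hits <- data.frame(frame = integer(0), channel = integer(0),
                       start_code = integer(0), valid = logical(0))
  }
  flags <- as.integer(headers$ref_pixel) + 2L * as.integer(headers$ref_line) +
    4L * as.integer(headers$ref_frame) + 8L * as.integer(headers$sync_valid)
  hdr_words <- rbind(pack_word(123L, TRUE, flags),
                     pack_word(124L, TRUE, headers$stop_code),
                     pack_word(125L, TRUE, headers$step %% 256L),
                     pack_word(126L, TRUE, headers$step %/% 256L),
                     pack_word(127L, TRUE, headers$spare))
  ch_words <- pack_word(hits$channel, hits$valid, hits$start_code)
  nhit <- tabulate(hits$frame, nbins = nh)
  # interleave: emit 5 header words then the frame's channel words
  total <- 5L * nh + length(ch_words)
  out <- integer(total)
  frame_base <- cumsum(c(0L, (5L + nhit)[-nh]))
  hdr_pos <- rep(frame_base, each = 5L) + rep(1:5, nh)
  out[hdr_pos] <- as.integer(hdr_words)
  if (length(ch_words)) {
    ch_pos <- frame_base[hits$frame] + 5L +
      sequence(nhit[nhit > 0L])
    out[ch_pos] <- ch_words
  }
  out
}

#' Event-filter transmission decision
#'
#' A frame is transmitted only if one of four conditions holds: a START
#' event in a photon channel; a STOP (SYNC) event following a pending START
#' (reverse start-stop association); a REF event (pixel/line/frame clock);
#' or a force-write when too much time elapsed since the last transmission.
#' Otherwise the frame is suppressed.
#'
#' @param frame A \code{ttm_frame}.
#' @param elapsed_ns Time since the last transmitted structure (ns).
#' @param photon_pending Logical; TRUE if a photon START awaits its SYNC.
#' @param force_write_ns Force-write interval in ns (default one-sixteenth
#'   of the coarse-counter rollover period, about 17.07 us).
#' @return One of \code{"photon_start"}, \code{"stop_after_start"},
#'   \code{"ref_event"}, \code{"force_write"}, or \code{NA_character_} if
#'   the frame is suppressed.
#' @export
transmit_decision <- function(frame, elapsed_ns = 0,
                              photon_pending = FALSE,
                              force_write_ns = 2^16 / 16 * ttm_clock_period()) {
  if (nrow(frame$hits) > 0L && any(frame$hits$valid)) return("photon_start")
  if (frame$sync_valid && photon_pending) return("stop_after_start")
  if (frame$ref_pixel || frame$ref_line || frame$ref_frame) {
    return("ref_event")
  }
  if (elapsed_ns >= force_write_ns) return("force_write")
  NA_character_
}

#' Write / read a binary word-stream file
#'
#' The stream file starts with a 4-byte preamble ("TTM" + format version
#' byte, currently 1) followed by the 16-bit words, little-endian.  On the
#' transfer link two 16-bit words are packed per 32-bit transfer word; the
#' byte sequence on disk is identical, so the file is simply the flat
#' little-endian word sequence.
#'
#' @param words Integer vector of 16-bit word values.
#' @param path Output file path.
#' @return \code{write_ttm}: invisibly, the path. \code{read_ttm}: the
#'   integer word vector.
#' @export
write_ttm <- function(words, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(charToRaw("TTM"), as.raw(1L)), con)
  # writeBin size=2 is signed; map [32768, 65535] to negative two's complement
  v <- as.integer(words)
  v[v > 32767L] <- v[v > 32767L] - 65536L
  writeBin(v, con, size = 2L, endian = "little")
  invisible(path)
}

#' @rdname write_ttm
#' @export
read_ttm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  pre <- readBin(con, "raw", 4L)
  if (!identical(pre[1:3], charToRaw("TTM"))) {
    stop("not a TTM stream file (bad preamble)")
  }
  sz <- file.info(path)$size - 4L
  v <- readBin(con, "integer", n = sz %/% 2L, size = 2L, signed = FALSE,
               endian = "little")
  v
}

#' Encode many frames into one stream
#' @param frames List of \code{ttm_frame} objects.
#' @param n_channels Number of photon channels.
#' @return Integer vector of words.
#' @export
encode_stream <- function(frames, n_channels = 25L) {
  if (!length(frames)) return(integer(0))
  unlist(lapply(frames, encode_frame, n_channels = n_channels),
         use.names = FALSE)
}

#' Generate a random valid frame (testing / property checks)
#' @param n_channels Number of photon channels.
#' @param p_hit Per-channel hit probability.
#' @return A \code{ttm_frame}.
#' @export
random_frame <- function(n_channels = 25L, p_hit = 0.15) {
  chans <- which(runif(n_channels) < p_hit) - 1L
  hits <- if (length(chans)) {
    data.frame(channel = chans,
               start_code = sample.int(256L, length(chans),
                                       replace = TRUE) - 1L,
               valid = runif(length(chans)) < 0.95)
  } else NULL
  ttm_frame(step = sample.int(65536L, 1L) - 1L,
            stop_code = sample.int(256L, 1L) - 1L,
            sync_valid = runif(1) < 0.5,
            ref_pixel = runif(1) < 0.1, ref_line = runif(1) < 0.05,
            ref_frame = runif(1) < 0.02,
            spare = sample.int(256L, 1L) - 1L, hits = hits)
}
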