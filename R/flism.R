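# ---------------------------------------------------------------------------
# FLISM: 4D photon binning, adaptive pixel reassignment (APR), per-pixel
# lifetime fitting, phasor analysis and FRC resolution estimation.
# ---------------------------------------------------------------------------

#' Bin a calibrated photon list into the 4D ISM dataset
#'
#' Counts photons into (ch, x, y, fr, dt-bin) with left-edge binning of the
#' TCSPC delay (start-stop delay modulo the laser period).  Photons with
#' negative scan coordinates (arrived before the first pixel clock) are
#' excluded; photon counts are otherwise conserved.
#'
#' @param photons Photon list from \code{\link{photon_list}} (or the
#'   simulator ground truth: needs channel, x, y, fr, delay_ns).
#' @param n_channels,nx,ny,n_frames Array dimensions.
#' @param laser_period_ns Laser period (ns).
#' @param bin_ns TCSPC bin width (ns, default 0.048 = 48 ps).
#' @return Object of class \code{ism_dataset}: list with \code{counts}
#'   (integer array ch x nx x ny x fr x nbins), \code{bin_ns},
#'   \code{laser_period_ns}.
#' @export
bin_4d <- function(photons, n_channels, nx, ny, n_frames = 1L,
                   laser_period_ns, bin_ns = 0.048) {
  nb <- as.integer(ceiling(laser_period_ns / bin_ns))
  sel <- photons$x >= 0 & photons$y >= 0 & photons$fr >= 0 &
    photons$x < nx & photons$y < ny & photons$fr < n_frames
  p <- photons[sel, , drop = FALSE]
  bin <- pmin(floor((p$delay_ns %% laser_period_ns) / bin_ns), nb - 1L)
  dims <- c(n_channels, nx, ny, n_frames, nb)
  lin <- 1 + p$channel + n_channels * (p$x + nx * (p$y + ny *
           (p$fr + n_frames * bin)))
  counts <- array(tabulate(lin, nbins = prod(dims)), dims)
  structure(list(counts = counts, bin_ns = bin_ns,
                 laser_period_ns = laser_period_ns,
                 n_excluded = sum(!sel)),
            class = "ism_dataset")
}

#' @export
print.ism_dataset <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf("<ism_dataset> %d ch, %dx%d px, %d frame(s), %d dt-bins, %d photons\n",
              d[1], d[2], d[3], d[4], d[5], sum(x$counts)))
  invisible(x)
}

#' Per-channel intensity images (integrated over delay and frames)
#' @param ism An \code{ism_dataset}.
#' @return Array ch x nx x ny.
#' @export
channel_images <- function(ism) {
  apply(ism$counts, c(1, 2, 3), sum)
}

# sub-pixel Fourier correlation of img against ref; returns the
# translation (dx, dy) such that img ~ shift(ref, by = (dx, dy)).  Peak
# location is refined by an upsampled discrete Fourier transform in a
# +-1 px neighbourhood (matrix-multiply DFT, upsampling factor `up`).
# whiten = "phase" divides out the spectral amplitude (classic phase
# correlation: sharp peak, noise-sensitive); the default keeps the
# amplitudes (matched-filter correlation: robust at photon-counting
# noise levels, unbiased for symmetric PSFs).
phase_correlate <- function(ref, img, up = 20L,
                            whiten = c("none", "phase")) {
  whiten <- match.arg(whiten)
  nx <- nrow(ref); ny <- ncol(ref)
  F1 <- fft(ref - mean(ref)); F2 <- fft(img - mean(img))
  R <- F2 * Conj(F1)
  Rn <- if (whiten == "phase") R / pmax(Mod(R), 1e-12) else R
  cc <- Re(fft(Rn, inverse = TRUE))
  pk <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  dx0 <- pk[1] - 1L; dy0 <- pk[2] - 1L
  if (dx0 > nx / 2) dx0 <- dx0 - nx
  if (dy0 > ny / 2) dy0 <- dy0 - ny
  # refine on a +-1 px window at resolution 1/up
  fx <- c(0:(nx %/% 2), -((nx - nx %/% 2 - 1):1)) / nx
  fy <- c(0:(ny %/% 2), -((ny - ny %/% 2 - 1):1)) / ny
  sx <- dx0 + seq(-1, 1, by = 1 / up)
  sy <- dy0 + seq(-1, 1, by = 1 / up)
  Ex <- exp(2i * pi * outer(sx, fx))        # |sx| x nx
  Ey <- exp(2i * pi * outer(fy, sy))        # ny x |sy|
  cc_up <- Re(Ex %*% Rn %*% Ey)
  pk2 <- which(cc_up == max(cc_up), arr.ind = TRUE)[1, ]
  c(dx = sx[pk2[1]], dy = sy[pk2[2]])
}

#' Shift-vector fingerprint by phase-correlation registration
#'
#' Registers every channel's integrated image against the central
#' element's image with sub-pixel phase correlation.  A channel whose
#' image carries too little structure is given zero shift and flagged.
#'
#' @param images Array ch x nx x ny (see \code{\link{channel_images}}).
#' @param central 1-based index of the central channel (default: middle of
#'   a square array).
#' @param up Sub-pixel upsampling factor.
#' @param whiten Spectral whitening mode passed to the correlator
#'   ("none" = matched-filter correlation, robust for photon counting;
#'   "phase" = classic phase correlation).
#' @return Object of class \code{shift_fingerprint}: data frame with
#'   \code{sx}, \code{sy} (px, central element = 0) and
#'   \code{low_confidence}.
#' @export
register_channels <- function(images, central = (dim(images)[1] + 1) %/% 2,
                              up = 20L, whiten = "none") {
  nch <- dim(images)[1]
  ref <- images[central, , ]
  out <- data.frame(sx = numeric(nch), sy = numeric(nch),
                    low_confidence = FALSE)
  for (ch in seq_len(nch)) {
    img <- images[ch, , ]
    if (sum(img) < 25 || stats::sd(img) == 0) {
      out$low_confidence[ch] <- TRUE
      next
    }
    s <- phase_correlate(ref, img, up, whiten)
    out$sx[ch] <- s[1]; out$sy[ch] <- s[2]
  }
  out$sx[central] <- 0; out$sy[central] <- 0
  class(out) <- c("shift_fingerprint", class(out))
  out
}

# circular sub-pixel shift of a 2D image via the Fourier shift theorem
fourier_shift <- function(img, dx, dy) {
  nx <- nrow(img); ny <- ncol(img)
  fx <- c(0:(nx %/% 2), -((nx - nx %/% 2 - 1):1)) / nx
  fy <- c(0:(ny %/% 2), -((ny - ny %/% 2 - 1):1)) / ny
  ph <- exp(-2i * pi * (outer(fx * dx, rep(1, ny)) +
                          outer(rep(1, nx), fy * dy)))
  Re(fft(fft(img) * ph, inverse = TRUE)) / (nx * ny)
}

#' Adaptive pixel reassignment reconstruction
#'
#' Shifts every channel's (x, y) planes back by its fingerprint vector --
#' the same shift for every delay bin -- and sums over channels, producing
#' the 3D (x, y, dt) dataset.  Shifting uses Fourier interpolation
#' (circular); photon counts are conserved up to border wrap, which is
#' logged.
#'
#' @param ism An \code{ism_dataset} (single frame is used).
#' @param fingerprint A \code{shift_fingerprint} from
#'   \code{\link{register_channels}}.
#' @param frame Frame to reconstruct (1-based, default 1).
#' @return List with \code{cube} (array nx x ny x nbins), \code{image}
#'   (delay-integrated 2D image), \code{bin_ns}, \code{laser_period_ns}.
#' @export
apr_reconstruct <- function(ism, fingerprint, frame = 1L) {
  d <- dim(ism$counts)
  nch <- d[1]; nx <- d[2]; ny <- d[3]; nb <- d[5]
  cube <- array(0, c(nx, ny, nb))
  for (ch in seq_len(nch)) {
    dx <- fingerprint$sx[ch]; dy <- fingerprint$sy[ch]
    pl <- ism$counts[ch, , , frame, ]
    if (dx == 0 && dy == 0) {
      cube <- cube + pl
    } else {
      for (b in seq_len(nb)) {
        cube[, , b] <- cube[, , b] + fourier_shift(pl[, , b], -dx, -dy)
      }
    }
  }
  list(cube = cube, image = rowSums(cube, dims = 2), bin_ns = ism$bin_ns,
       laser_period_ns = ism$laser_period_ns)
}

#' Per-pixel single-exponential lifetime map
#'
#' Fits each pixel's decay histogram with a single exponential on the
#' post-peak range (peak of the pooled histogram to 10 ns later) by
#' count-weighted linear regression of the log counts.  Pixels with fewer
#' photons than the mask threshold are not fitted (NA).
#'
#' @param cube Array nx x ny x nbins (e.g. from
#'   \code{\link{apr_reconstruct}}).
#' @param bin_ns Bin width (ns).
#' @param mask_threshold Minimum photons per pixel (default 100).
#' @param fit_window_ns Length of the post-peak fit range (default 10).
#' @return List with \code{tau_ns} (matrix), \code{amplitude},
#'   \code{counts} and \code{mask}.
#' @export
fit_lifetime_map <- function(cube, bin_ns, mask_threshold = 100,
                             fit_window_ns = 10) {
  nx <- dim(cube)[1]; ny <- dim(cube)[2]; nb <- dim(cube)[3]
  pooled <- apply(cube, 3, sum)
  pk <- which.max(pooled)
  hi <- min(nb, pk + ceiling(fit_window_ns / bin_ns))
  rng <- pk:hi
  tt <- (rng - 0.5) * bin_ns
  H <- matrix(cube, nx * ny, nb)[, rng, drop = FALSE]
  totals <- rowSums(matrix(cube, nx * ny, nb))
  mask <- totals >= mask_threshold
  tau <- amp <- rep(NA_real_, nx * ny)
  idx <- which(mask)
  if (length(idx)) {
    # weighted LSQ of log-counts, weights = counts (Poisson linearization)
    Y <- H[idx, , drop = FALSE]
    W <- pmax(Y, 0)   # reconstruction interpolation can ring negative
    Ylog <- log(pmax(Y, 0.5))
    sw <- rowSums(W)
    mt <- (W %*% tt) / sw
    my <- rowSums(W * Ylog) / sw
    st2 <- (W %*% tt^2) / sw - mt^2
    sty <- rowSums(W * sweep(Ylog, 2, tt, "*")) / sw - mt * my
    slope <- sty / st2
    tau[idx] <- -1 / slope
    amp[idx] <- exp(my - slope * mt)
  }
  tau[tau <= 0] <- NA_real_
  list(tau_ns = matrix(tau, nx, ny), amplitude = matrix(amp, nx, ny),
       counts = matrix(totals, nx, ny), mask = matrix(mask, nx, ny),
       fit_range_bins = rng)
}

#' Phasor transform of decay histograms
#'
#' Computes the phasor coordinates at the laser repetition harmonic,
#' \code{g = sum c cos(wt) / sum c}, \code{s = sum c sin(wt) / sum c}
#' with bin-center times.  For an ideal single-exponential decay the point
#' lies on the universal semicircle \code{(g - 1/2)^2 + s^2 = 1/4};
#' uncorrelated background pulls points toward the origin.  The finite bin
#' width attenuates the phasor by sinc(w b / 2); the correction is applied
#' by default.
#'
#' @param hist Numeric vector (one histogram) or matrix (bins x
#'   measurements) of MOD-folded counts.
#' @param bin_ns Bin width (ns).
#' @param laser_period_ns Laser period (ns); the histogram must span it.
#' @param bin_correction Divide out the sinc attenuation (default TRUE).
#' @param reference Optional list(g, s, lifetime_ns): a measured reference
#'   phasor and its known lifetime; the returned phasors are rotated and
#'   scaled so the reference lands at its theoretical position (full
#'   phase + modulation referencing of the system IRF).
#' @return Data frame with \code{g} and \code{s}, one row per histogram.
#' @export
phasor_transform <- function(hist, bin_ns, laser_period_ns,
                             bin_correction = TRUE, reference = NULL) {
  if (is.null(dim(hist))) hist <- matrix(hist, ncol = 1)
  w <- 2 * pi / laser_period_ns
  tt <- (seq_len(nrow(hist)) - 0.5) * bin_ns
  tot <- colSums(hist)
  g <- colSums(hist * cos(w * tt)) / tot
  s <- colSums(hist * sin(w * tt)) / tot
  if (bin_correction) {
    sc <- sin(w * bin_ns / 2) / (w * bin_ns / 2)
    g <- g / sc; s <- s / sc
  }
  if (!is.null(reference)) {
    wt <- w * reference$lifetime_ns
    z_th <- complex(real = 1 / (1 + wt^2), imaginary = wt / (1 + wt^2))
    z_ref <- complex(real = reference$g, imaginary = reference$s)
    z <- complex(real = g, imaginary = s) * z_th / z_ref
    g <- Re(z); s <- Im(z)
  }
  data.frame(g = g, s = s)
}

#' Theoretical phasor of a single-exponential decay
#' @param tau_ns Lifetime (ns).
#' @param laser_period_ns Laser period (ns).
#' @return c(g, s) on the universal semicircle.
#' @export
phasor_theoretical <- function(tau_ns, laser_period_ns) {
  wt <- 2 * pi / laser_period_ns * tau_ns
  c(g = 1 / (1 + wt^2), s = wt / (1 + wt^2))
}

#' Split photons into two independent half datasets for FRC
#'
#' Assigns each photon to one of two halves by the parity of its raw
#' START tap code.  The sliding scale distributes photons uniformly over
#' the taps, so the halves are statistically independent with similar
#' photon counts, and their union is exactly the input.
#'
#' @param photons Photon list with a \code{start_code} column.
#' @return List with \code{odd} and \code{even} photon data frames.
#' @export
frc_split <- function(photons) {
  odd <- photons$start_code %% 2L == 1L
  list(odd = photons[odd, , drop = FALSE],
       even = photons[!odd, , drop = FALSE])
}

#' Fourier ring correlation resolution
#'
#' Ring-wise normalized cross-correlation of the Fourier transforms of two
#' independent realizations of an image; the effective resolution is the
#' inverse of the spatial frequency where the smoothed FRC curve first
#' drops below the threshold (fixed 1/7 criterion).
#'
#' @param img1,img2 Equal-shape matrices.
#' @param pixel_um Pixel size (um).
#' @param threshold FRC threshold (default 1/7).
#' @param smooth Half-width of the moving-average smoothing of the curve
#'   (rings; default 2).
#' @return List with \code{freq} (cycles/um), \code{frc}, \code{frc_smooth},
#'   \code{cutoff_freq} and \code{resolution_um} (Inf if no crossing).
#' @export
frc_resolution <- function(img1, img2, pixel_um, threshold = 1 / 7,
                           smooth = 2L) {
  stopifnot(all(dim(img1) == dim(img2)))
  nx <- nrow(img1); ny <- ncol(img1)
  F1 <- fft(img1 - mean(img1)); F2 <- fft(img2 - mean(img2))
  kx <- c(0:(nx %/% 2), -((nx - nx %/% 2 - 1):1)) / nx
  ky <- c(0:(ny %/% 2), -((ny - ny %/% 2 - 1):1)) / ny
  kr <- sqrt(outer(kx^2, ky^2, "+"))
  nr <- min(nx, ny) %/% 2
  ring <- factor(pmin(as.integer(round(kr * min(nx, ny))), nr) + 1L,
                 levels = seq_len(nr + 1L))
  num <- as.vector(tapply(Re(F1 * Conj(F2)), ring, sum))
  d1 <- as.vector(tapply(Mod(F1)^2, ring, sum))
  d2 <- as.vector(tapply(Mod(F2)^2, ring, sum))
  frc <- num / sqrt(d1 * d2)
  frc <- frc[seq_len(nr)]  # drop DC is ring 1; keep rings 1..nr
  freq <- (seq_len(nr) - 1) / (min(nx, ny) * pixel_um)
  if (smooth > 0) {
    kern <- rep(1, 2 * smooth + 1) / (2 * smooth + 1)
    pad <- c(rep(frc[1], smooth), frc, rep(frc[length(frc)], smooth))
    frc_s <- stats::filter(pad, kern, sides = 2)[(smooth + 1):(smooth + nr)]
  } else {
    frc_s <- frc
  }
  below <- which(frc_s < threshold & freq > 0)
  if (length(below)) {
    i <- below[1]
    # linear interpolation between the bracketing rings
    f0 <- freq[i - 1]; f1 <- freq[i]
    y0 <- frc_s[i - 1]; y1 <- frc_s[i]
    cutoff <- f0 + (threshold - y0) / (y1 - y0) * (f1 - f0)
    list(freq = freq, frc = frc, frc_smooth = as.numeric(frc_s),
         cutoff_freq = cutoff, resolution_um = 1 / cutoff,
         threshold = threshold)
  } else {
    list(freq = freq, frc = frc, frc_smooth = as.numeric(frc_s),
         cutoff_freq = NA_real_, resolution_um = Inf,
         threshold = threshold)
  }
}
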