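#' Radius-time curve of one ultra-high-speed recording
#'
#' Holds uniformly sampled radius-versus-time data from one recording of a
#' single microbubble, together with the transmit frequency and peak
#' negative pressure of the ultrasound burst (both `NA` for the baseline
#' recording made without ultrasound).
#'
#' @param t Sample times (s), uniformly spaced, at least 2 samples.
#' @param r Radius samples (m), strictly positive.
#' @param fT Transmit frequency (Hz), or `NA` for a baseline recording.
#' @param pnp Peak negative pressure (Pa), or `NA`.
#' @param bubble_id Optional identifier.
#'
#' @return An object of class `rt_curve` with fields `t`, `r`, `fT`, `pnp`,
#'   `frame_rate` (derived), `bubble_id`.
#' @export
rt_curve <- function(t, r, fT = NA_real_, pnp = NA_real_, bubble_id = NULL) {
  if (length(t) < 2L || length(t) != length(r)) {
    stop("rt_curve needs >= 2 samples with matching t and r lengths")
  }
  dt <- diff(t)
  if (any(dt <= 0) || (max(dt) - min(dt)) > 1e-9 * mean(dt) * length(t)) {
    stop("rt_curve requires uniform, increasing sample times")
  }
  if (any(!is.finite(r)) || any(r <= 0)) {
    stop("radius samples must be positive and finite")
  }
  structure(list(t = as.numeric(t), r = as.numeric(r),
                 fT = fT, pnp = pnp,
                 frame_rate = 1 / mean(dt), bubble_id = bubble_id),
            class = "rt_curve")
}

#' @export
print.rt_curve <- function(x, ...) {
  cat(sprintf("R-t curve: %d frames at %.3g Mfps, R0 ~ %.3g um",
              length(x$r), x$frame_rate / 1e6, mean(x$r[1:5]) * 1e6))
  if (!is.na(x$fT)) cat(sprintf(", fT = %.2f MHz", x$fT / 1e6))
  if (!is.na(x$pnp)) cat(sprintf(", PNP = %.0f kPa", x$pnp / 1e3))
  cat("\n")
  invisible(x)
}

#' Resting radius of a recording
#'
#' The resting radius is defined as the mean of the first five radius
#' samples of the recording.
#'
#' @param curve An [rt_curve()].
#' @return Resting radius (m).
#' @export
resting_radius <- function(curve) {
  stopifnot(inherits(curve, "rt_curve"))
  if (length(curve$r) < 5L) {
    stop("resting_radius needs at least 5 samples")
  }
  mean(curve$r[1:5])
}

#' Band-pass filter a radius-time curve around a centre frequency
#'
#' Applies a third-order Butterworth band-pass filter centred at `center`
#' with a fixed (default 300 kHz) bandwidth to the radius excursion. The
#' filter is run zero-phase (forward-backward) so the location and value of
#' the excursion maximum are not phase-shifted; the quoted -3 dB bandwidth
#' refers to the single-pass design. The short record is extended by odd
#' reflection at both ends before filtering to suppress edge transients,
#' and the padding is discarded afterwards.
#'
#' @param curve An [rt_curve()].
#' @param center Centre frequency (Hz).
#' @param bandwidth Full filter bandwidth (Hz), default 300 kHz.
#' @param order Butterworth order of the single-pass design, default 3.
#'
#' @return Zero-mean filtered radius-excursion signal (m), same length as
#'   the input record.
#' @export
bandpass_filter <- function(curve, center, bandwidth = 300e3, order = 3L) {
  stopifnot(inherits(curve, "rt_curve"))
  if (!is.finite(center) || center <= 0) stop("center frequency must be positive")
  fs <- curve$frame_rate
  hi <- center + bandwidth / 2
  lo <- center - bandwidth / 2
  if (lo <= 0) stop("filter band extends below 0 Hz")
  if (fs <= 2 * hi) {
    stop(sprintf("sampling rate %.3g Hz violates Nyquist for band edge %.3g Hz",
                 fs, hi))
  }
  bf <- signal::butter(order, c(lo, hi) / (fs / 2), type = "pass")
  x <- curve$r - mean(curve$r)
  n <- length(x)
  npad <- n - 1L
  # odd (point-symmetric) reflection about the end samples
  pre <- 2 * x[1L] - x[(npad + 1L):2L]
  post <- 2 * x[n] - x[(n - 1L):(n - npad)]
  y <- signal::filtfilt(bf, c(pre, x, post))
  y[(npad + 1L):(npad + n)]
}

#' Relative oscillation amplitude x0 of one recording
#'
#' The relative oscillation amplitude is the maximum absolute value of the
#' band-pass-filtered radius excursion (filter centred at the transmit
#' frequency), divided by the resting radius.
#'
#' @param curve An [rt_curve()] with `fT` set (or `center` supplied).
#' @param R0 Resting radius (m); defaults to [resting_radius()] of the curve.
#' @param center Filter centre frequency (Hz); defaults to `curve$fT`.
#' @param bandwidth Filter bandwidth (Hz), default 300 kHz.
#'
#' @return x0, the dimensionless relative oscillation amplitude (>= 0).
#' @export
relative_amplitude <- function(curve, R0 = resting_radius(curve),
                               center = curve$fT, bandwidth = 300e3) {
  if (!is.finite(R0) || R0 <= 0) stop("R0 must be positive")
  if (is.na(center)) stop("no transmit frequency: supply center explicitly")
  y <- bandpass_filter(curve, center, bandwidth)
  max(abs(y)) / R0
}

#' Deflation (acoustic stability) across a spectroscopy session
#'
#' Quantifies the relative diameter decrease over an insonification
#' session as `(D0 - Dend) / D0`, with `D0` the mean diameter over all
#' frames of the first (no-ultrasound) recording and `Dend` the mean
#' diameter over the last ten frames of the last recording. A growing
#' bubble yields a negative deflation; this is reported as-is with a
#' warning so the sign convention stays visible.
#'
#' @param baseline The first recording, made without ultrasound.
#' @param last The last recording of the session (>= 10 samples).
#'
#' @return An object of class `stability_result` with fields `D0`, `Dend`
#'   (m) and `deflation` (dimensionless).
#' @export
deflation <- function(baseline, last) {
  stopifnot(inherits(baseline, "rt_curve"), inherits(last, "rt_curve"))
  if (length(last$r) < 10L) {
    stop("deflation needs >= 10 samples in the last recording")
  }
  D0 <- mean(2 * baseline$r)
  Dend <- mean(2 * utils::tail(last$r, 10L))
  defl <- (D0 - Dend) / D0
  if (defl < 0) {
    warning(sprintf("negative deflation (%.3g): bubble grew during session", defl))
  }
  structure(list(D0 = D0, Dend = Dend, deflation = defl),
            class = "stability_result")
}

#' @export
print.stability_result <- function(x, ...) {
  cat(sprintf("Deflation: D0 = %.3g um, Dend = %.3g um, (D0-Dend)/D0 = %.1f%%\n",
              x$D0 * 1e6, x$Dend * 1e6, 100 * x$deflation))
  invisible(x)
}

#' Track the bubble radius through a bright-disk image stack
#'
#' Per frame, the image is thresholded (Otsu), the largest connected
#' component taken as the bubble, and the radius reported as the
#' equivalent-area radius of that component. This is a deliberately simple
#' contour-free tracker for synthetic and well-contrasted recordings; it
#' does no sub-pixel refinement.
#'
#' @param frames 3D array (x, y, frame) of image intensities, one bright
#'   disk per frame on a dark background.
#' @param pixel_size Pixel pitch (m/pixel).
#' @param frame_rate Frame rate (frames/s).
#' @param fT,pnp Metadata forwarded to the returned [rt_curve()].
#'
#' @return An [rt_curve()].
#' @export
track_radius <- function(frames, pixel_size, frame_rate,
                         fT = NA_real_, pnp = NA_real_) {
  stopifnot(is.array(frames), length(dim(frames)) == 3L)
  nf <- dim(frames)[3]
  r <- numeric(nf)
  for (k in seq_len(nf)) {
    img <- frames[, , k]
    thr <- otsu_threshold(as.numeric(img))
    mask <- img > thr
    if (!any(mask)) stop(sprintf("no object found in frame %d", k))
    lab <- label_components(mask)
    sizes <- tabulate(lab[lab > 0L])
    if (length(sizes) == 0L) stop(sprintf("no object found in frame %d", k))
    area <- max(sizes)
    r[k] <- sqrt(area / pi) * pixel_size
  }
  rt_curve(t = (seq_len(nf) - 1) / frame_rate, r = r, fT = fT, pnp = pnp)
}
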