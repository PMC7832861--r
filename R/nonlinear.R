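#' Amplitude FFT of a radius-time curve
#'
#' Magnitude spectrum of the mean-removed radius excursion in dB
#' (20 log10 of the amplitude in metres). No window is applied (the records
#' are short transients); the spectrum is zero-padded (default 4x) so peaks
#' can be located within the narrow analysis bands. With the `2/N`
#' normalization used here a sinusoid of amplitude `a` metres whose
#' frequency lies on the original bin grid peaks at exactly
#' `20*log10(a)` dB.
#'
#' @param curve An [rt_curve()] with >= 16 uniformly spaced samples.
#' @param zero_pad Zero-padding factor (>= 1), default 4.
#'
#' @return An object of class `amplitude_fft`: `freqs` (Hz, 0..Nyquist),
#'   `amp_db`, and `frame_rate`.
#' @export
fft_amplitude <- function(curve, zero_pad = 4L) {
  stopifnot(inherits(curve, "rt_curve"))
  n <- length(curve$r)
  if (n < 16L) stop("fft_amplitude needs >= 16 samples")
  x <- curve$r - mean(curve$r)
  nfft <- as.integer(round(zero_pad)) * n
  X <- stats::fft(c(x, rep(0, nfft - n)))
  half <- seq_len(nfft %/% 2 + 1L)
  mag <- 2 * Mod(X[half]) / n
  freqs <- (half - 1L) * curve$frame_rate / nfft
  structure(list(freqs = freqs,
                 amp_db = 20 * log10(pmax(mag, 1e-300)),
                 frame_rate = curve$frame_rate),
            class = "amplitude_fft")
}

# indices of the analysis band [center - bw/2, center + bw/2]; errors when
# the band leaves (0, Nyquist]
.band_idx <- function(fftamp, center, bandwidth) {
  nyq <- max(fftamp$freqs)
  if (center - bandwidth / 2 < 0 || center + bandwidth / 2 > nyq) {
    stop(sprintf("band %.3g +/- %.3g Hz outside (0, Nyquist = %.3g Hz)",
                 center, bandwidth / 2, nyq))
  }
  which(fftamp$freqs >= center - bandwidth / 2 &
          fftamp$freqs <= center + bandwidth / 2)
}

# local maxima (strict against the previous bin, >= the next, so plateau
# peaks take the lowest-frequency bin), as bin indices
.local_maxima <- function(y) {
  n <- length(y)
  if (n < 3L) return(integer(0))
  i <- 2:(n - 1L)
  i[y[i] > y[i - 1L] & y[i] >= y[i + 1L]]
}

#' Noise floor of a microbubble from its baseline recording
#'
#' The noise level of a bubble in a given analysis band is the median
#' FFT amplitude (dB) of the first, no-ultrasound recording within the
#' band (300 kHz wide by default) centred at `band_center`. The median (the
#' statistic is a package choice) is robust to isolated baseline spikes.
#'
#' @param baseline The no-ultrasound [rt_curve()] (`fT` must be `NA`).
#' @param band_center Band centre (Hz).
#' @param bandwidth Band width (Hz), default 300 kHz.
#' @param zero_pad Zero-padding factor forwarded to [fft_amplitude()].
#'
#' @return Noise floor in dB.
#' @export
noise_level <- function(baseline, band_center, bandwidth = 300e3,
                        zero_pad = 4L) {
  stopifnot(inherits(baseline, "rt_curve"))
  if (!is.na(baseline$fT)) {
    stop("noise_level expects the no-ultrasound baseline recording (fT = NA)")
  }
  fa <- fft_amplitude(baseline, zero_pad)
  stats::median(fa$amp_db[.band_idx(fa, band_center, bandwidth)])
}

#' Detect a sub- or second-harmonic response in one recording
#'
#' A harmonic response is detected when the FFT of the recording has a
#' local maximum inside the 300 kHz band centred at `fT/2` (subharmonic) or
#' `2 fT` (second harmonic) whose amplitude is at least `threshold_db`
#' (default 6 dB) above the bubble's noise floor in that band. The harmonic
#' amplitude is the maximum FFT amplitude in the band, normalized to the
#' fundamental (the maximum FFT amplitude in an equally wide band around
#' `fT`), reported as a dB difference so any absolute calibration cancels.
#'
#' @param recording An [rt_curve()] with `fT` set.
#' @param baseline The bubble's no-ultrasound recording.
#' @param kind `"subharmonic"` or `"second_harmonic"`.
#' @param bandwidth Analysis band width (Hz), default 300 kHz.
#' @param threshold_db Detection threshold above the noise floor, default 6.
#' @param zero_pad Zero-padding factor for the FFTs.
#'
#' @return List: `detected`, `amplitude_db` (harmonic re fundamental),
#'   `peak_db`, `noise_db`, `band_center`.
#' @export
detect_harmonic <- function(recording, baseline,
                            kind = c("subharmonic", "second_harmonic"),
                            bandwidth = 300e3, threshold_db = 6,
                            zero_pad = 4L) {
  kind <- match.arg(kind)
  stopifnot(inherits(recording, "rt_curve"))
  if (is.na(recording$fT)) stop("recording has no transmit frequency")
  center <- if (kind == "subharmonic") recording$fT / 2 else 2 * recording$fT
  fa <- fft_amplitude(recording, zero_pad)
  band <- .band_idx(fa, center, bandwidth)
  noise_db <- noise_level(baseline, center, bandwidth, zero_pad)
  locmax <- intersect(.local_maxima(fa$amp_db), band)
  peak_db <- if (length(locmax)) max(fa$amp_db[locmax]) else -Inf
  detected <- length(locmax) > 0 && peak_db >= noise_db + threshold_db
  fund_band <- .band_idx(fa, recording$fT, bandwidth)
  fund_db <- max(fa$amp_db[fund_band])
  list(detected = detected,
       amplitude_db = max(fa$amp_db[band]) - fund_db,
       peak_db = peak_db,
       noise_db = noise_db,
       band_center = center)
}

#' Classify a spectroscopy session as sub-/second-harmonic responsive
#'
#' A bubble is classified as exhibiting nonlinear behaviour of a given kind
#' when the harmonic is detected in at least two recordings of the session.
#' The per-recording normalized amplitudes of the detected recordings are
#' reported, summarized by their maximum.
#'
#' @param session A [spectroscopy_session()].
#' @param kind `"subharmonic"` or `"second_harmonic"`.
#' @param ... Passed to [detect_harmonic()].
#'
#' @return An object of class `harmonic_call`: `kind`, `detected`
#'   (per-recording logical), `n_detected`, `classified`, `amplitude_db`
#'   (per detected recording), `max_amp_db` (NA when none detected).
#' @export
classify_session <- function(session, kind = c("subharmonic", "second_harmonic"),
                             ...) {
  kind <- match.arg(kind)
  stopifnot(inherits(session, "spectroscopy_session"))
  recs <- session$recordings
  det <- logical(length(recs))
  amp <- rep(NA_real_, length(recs))
  for (k in seq_along(recs)) {
    h <- detect_harmonic(recs[[k]], session$baseline, kind, ...)
    det[k] <- h$detected
    if (h$detected) amp[k] <- h$amplitude_db
  }
  structure(list(kind = kind,
                 detected = det,
                 n_detected = sum(det),
                 classified = sum(det) >= 2L,
                 amplitude_db = amp[det],
                 max_amp_db = if (any(det)) max(amp[det]) else NA_real_),
            class = "harmonic_call")
}

#' @export
print.harmonic_call <- function(x, ...) {
  cat(sprintf("%s: %d/%d recordings detected -> %sclassified",
              x$kind, x$n_detected, length(x$detected),
              if (x$classified) "" else "not "))
  if (!is.na(x$max_amp_db)) {
    cat(sprintf(" (max amplitude %.1f dB re fundamental)", x$max_amp_db))
  }
  cat("\n")
  invisible(x)
}
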