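#' Spectroscopy session of one microbubble
#'
#' One baseline recording made without ultrasound plus one recording per
#' transmit frequency (sorted by frequency) at a single session pressure.
#'
#' @param baseline Baseline [rt_curve()] (`fT` must be `NA`).
#' @param recordings List of [rt_curve()]s with `fT` set, sorted ascending.
#' @param pnp Session peak negative pressure (Pa).
#' @param bubble_id Identifier.
#' @param truth Optional `synthetic_truth` sidecar for generated sessions.
#'
#' @return An object of class `spectroscopy_session`.
#' @export
spectroscopy_session <- function(baseline, recordings, pnp = NA_real_,
                                 bubble_id = NULL, truth = NULL) {
  stopifnot(inherits(baseline, "rt_curve"))
  if (!is.na(baseline$fT)) stop("baseline recording must have fT = NA")
  if (!length(recordings)) stop("session needs >= 1 ultrasound recording")
  fTs <- vapply(recordings, function(x) x$fT, numeric(1))
  if (any(is.na(fTs))) stop("every ultrasound recording needs an fT")
  if (any(diff(fTs) <= 0)) stop("recordings must be sorted by increasing fT")
  structure(list(baseline = baseline, recordings = recordings,
                 pnp = pnp, bubble_id = bubble_id, truth = truth),
            class = "spectroscopy_session")
}

#' @export
print.spectroscopy_session <- function(x, ...) {
  fTs <- vapply(x$recordings, function(r) r$fT, numeric(1))
  cat(sprintf("Spectroscopy session%s: baseline + %d recordings, fT %.1f-%.1f MHz",
              if (is.null(x$bubble_id)) "" else paste0(" [", x$bubble_id, "]"),
              length(fTs), min(fTs) / 1e6, max(fTs) / 1e6))
  if (!is.na(x$pnp)) cat(sprintf(", PNP %.0f kPa", x$pnp / 1e3))
  cat("\n")
  invisible(x)
}

#' Measure the amplitude spectrum of a session
#'
#' Applies the per-recording pipeline (resting radius, band-pass filter at
#' the transmit frequency, relative amplitude) to every recording of a
#' session and assembles the bubble's amplitude spectrum. The resting
#' radius attached to the spectrum is taken from the baseline recording.
#'
#' @param session A [spectroscopy_session()].
#' @param bandwidth Filter bandwidth (Hz), default 300 kHz.
#'
#' @return An [amplitude_spectrum()].
#' @export
session_spectrum <- function(session, bandwidth = 300e3) {
  stopifnot(inherits(session, "spectroscopy_session"))
  fTs <- vapply(session$recordings, function(r) r$fT, numeric(1))
  x0 <- vapply(session$recordings, function(r)
    relative_amplitude(r, bandwidth = bandwidth), numeric(1))
  amplitude_spectrum(fTs, x0, R0 = resting_radius(session$baseline),
                     P = session$pnp, bubble_id = session$bubble_id)
}

#' Deflation of a session
#'
#' Convenience wrapper around [deflation()] using the session's baseline
#' and its last ultrasound recording.
#'
#' @param session A [spectroscopy_session()].
#' @return A `stability_result`.
#' @export
session_deflation <- function(session) {
  deflation(session$baseline,
            session$recordings[[length(session$recordings)]])
}
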