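#' Amplitude spectrum of a single microbubble
#'
#' The per-frequency relative oscillation amplitudes x0(fT) of one bubble at
#' one drive pressure, the input to the oscillator-model fit.
#'
#' @param fT Transmit frequencies (Hz), strictly increasing, >= 3 points.
#' @param x0 Relative oscillation amplitudes (dimensionless, >= 0).
#' @param R0 Resting radius (m).
#' @param P Drive pressure (Pa).
#' @param bubble_id Optional identifier.
#'
#' @return An object of class `amplitude_spectrum`.
#' @export
amplitude_spectrum <- function(fT, x0, R0, P, bubble_id = NULL) {
  if (length(fT) < 3L || length(fT) != length(x0)) {
    stop("amplitude_spectrum needs >= 3 matching (fT, x0) points")
  }
  if (any(diff(fT) <= 0)) stop("fT must be strictly increasing")
  if (any(x0 < 0)) stop("x0 must be non-negative")
  if (!is.finite(R0) || R0 <= 0) stop("R0 must be positive")
  if (!is.finite(P) || P < 0) stop("P must be non-negative")
  structure(list(fT = as.numeric(fT), x0 = as.numeric(x0),
                 R0 = R0, P = P, bubble_id = bubble_id),
            class = "amplitude_spectrum")
}

#' Default spectroscopy transmit-frequency grid
#'
#' 1 to 4 MHz in 0.2 MHz steps: 16 transmit frequencies.
#'
#' @return Numeric vector of 16 frequencies (Hz).
#' @export
default_ft_grid <- function() {
  seq(1e6, 4e6, by = 0.2e6)
}

#' Predict an amplitude spectrum from shell parameters
#'
#' Forward-evaluates the steady-state oscillator amplitude on a transmit
#' frequency grid for a bubble with the given coating parameters.
#'
#' @param shell A [shell_params()] object (or a list with `chi`, `kappa_s`).
#' @param R0 Resting radius (m); defaults to `shell$R0`.
#' @param P Drive pressure (Pa).
#' @param grid Transmit frequencies (Hz), default [default_ft_grid()].
#' @param consts A [physical_constants()] object.
#'
#' @return An [amplitude_spectrum()].
#' @export
#' @examples
#' sp <- predict_spectrum(shell_params(0.14, 0.43e-8, 2.5e-6), P = 50e3)
predict_spectrum <- function(shell, R0 = shell$R0, P = 50e3,
                             grid = default_ft_grid(),
                             consts = physical_constants()) {
  f0 <- eigenfrequency(R0, shell$chi, consts)
  delta <- damping_coefficient(R0, f0, shell$kappa_s, consts)
  x0 <- oscillator_amplitude(grid, P, R0, f0, delta, consts)
  amplitude_spectrum(grid, x0, R0, P)
}

# Model x0 on the spectrum grid for parameters (chi [N/m], ks8 [1e-8 kg/s]).
.osc_model <- function(par, spectrum, consts) {
  chi <- max(par[1], 0)
  ks <- max(par[2], 0) * 1e-8
  f0 <- eigenfrequency(spectrum$R0, chi, consts)
  delta <- damping_coefficient(spectrum$R0, f0, ks, consts)
  oscillator_amplitude(spectrum$fT, spectrum$P, spectrum$R0, f0, delta, consts)
}

# Initial (chi, ks8) guesses from the spectrum peak: chi by inverting the
# eigenfrequency at the peak location, ks by matching the peak amplitude.
.fit_init <- function(spectrum, consts) {
  ipk <- which.max(spectrum$x0)
  fpk <- spectrum$fT[ipk]
  R0 <- spectrum$R0
  chi0 <- (consts$rho * R0^2 * (2 * pi * fpk)^2 -
             3 * consts$gamma * consts$P0 -
             2 * (3 * consts$gamma - 1) * consts$sigma_w / R0) * R0 / 4
  chi0 <- min(max(chi0, 1e-3), 5)
  # peak amplitude ~ P / (4 pi^2 rho R0^2 delta f0^2) -> delta -> kappa_s
  f0g <- eigenfrequency(R0, chi0, consts)
  xpk <- max(spectrum$x0[ipk], 1e-6)
  dguess <- spectrum$P / (4 * pi^2 * consts$rho * R0^2 * xpk * f0g^2)
  w0 <- 2 * pi * f0g
  drad <- w0 * R0 / consts$c
  dvis <- 4 * consts$mu / (consts$rho * w0 * R0^2)
  ks0 <- (dguess - drad - dvis) * consts$rho * w0 * R0^3 / 4
  ks0 <- min(max(ks0, 1e-11), 1e-6)
  c(chi0, ks0 * 1e8)
}

#' Fit the harmonic-oscillator model to an amplitude spectrum
#'
#' Estimates shell elasticity `chi` and shell viscosity `kappa_s` of one
#' microbubble by unweighted least squares between the measured x0(fT) and
#' the steady-state oscillator amplitude, with the eigenfrequency and
#' damping tied to (`chi`, `kappa_s`) through the resting radius. Bounds are
#' physical (`chi` in \[0, 5\] N/m, `kappa_s` in \[0, 1e-6\] kg/s). A small
#' multi-start (3 deterministic starts around a peak-based initialization)
#' protects against flat off-resonance minima. The resonance frequency is
#' computed from the fitted pair.
#'
#' @param spectrum An [amplitude_spectrum()].
#' @param consts A [physical_constants()] object.
#' @param chi_bounds,kappa_bounds Parameter bounds (N/m, kg/s).
#' @param n_starts Number of starts (default 3).
#'
#' @return An object of class `fit_result`: fields `shell`
#'   ([shell_params()]), `residual` (RMS misfit in x0 units), `n_points`,
#'   `converged`, and `peak_outside_grid` (TRUE when the measured spectrum
#'   peaks at a grid end point, so the resonance is poorly constrained).
#' @export
#' @examples
#' sp <- predict_spectrum(shell_params(0.14, 0.43e-8, 2.5e-6), P = 50e3)
#' fit_oscillator(sp)
fit_oscillator <- function(spectrum, consts = physical_constants(),
                           chi_bounds = c(0, 5),
                           kappa_bounds = c(0, 1e-6),
                           n_starts = 3L) {
  stopifnot(inherits(spectrum, "amplitude_spectrum"))
  lower <- c(chi_bounds[1], kappa_bounds[1] * 1e8)
  upper <- c(chi_bounds[2], kappa_bounds[2] * 1e8)

  degenerate <- max(spectrum$x0) == 0
  best <- NULL
  if (!degenerate) {
    init <- .fit_init(spectrum, consts)
    starts <- list(init,
                   pmin(pmax(init * c(0.5, 2.0), lower + 1e-6), upper),
                   pmin(pmax(init * c(2.0, 0.5), lower + 1e-6), upper))
    starts <- starts[seq_len(min(n_starts, 3L))]
    for (st in starts) {
      fit <- try(minpack.lm::nls.lm(
        par = st,
        lower = lower, upper = upper,
        fn = function(p) .osc_model(p, spectrum, consts) - spectrum$x0,
        control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14,
                                             ptol = 1e-14)), silent = TRUE)
      if (inherits(fit, "try-error")) next
      if (is.null(best) || fit$deviance < best$deviance) best <- fit
    }
  }

  if (is.null(best)) {
    # degenerate or failed: report bounds with converged = FALSE
    par <- c(lower[1], upper[2])
    conv <- FALSE
    dev <- sum((.osc_model(par, spectrum, consts) - spectrum$x0)^2)
  } else {
    par <- best$par
    conv <- best$info %in% 1:4
    dev <- best$deviance
  }
  shell <- shell_params(max(par[1], 0), max(par[2], 0) * 1e-8,
                        spectrum$R0, consts)
  ipk <- which.max(spectrum$x0)
  structure(list(
    shell = shell,
    residual = sqrt(dev / length(spectrum$x0)),
    n_points = length(spectrum$x0),
    converged = conv,
    peak_outside_grid = ipk %in% c(1L, length(spectrum$x0)),
    bubble_id = spectrum$bubble_id
  ), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Oscillator fit (%d points, %s):\n", x$n_points,
              if (x$converged) "converged" else "NOT converged"))
  print(x$shell)
  cat(sprintf("  RMS residual = %.3g\n", x$residual))
  if (x$peak_outside_grid) {
    cat("  warning: spectrum peaks at a grid end point; resonance poorly constrained\n")
  }
  invisible(x)
}

#' Cohort summary of fitted shell parameters
#'
#' Median and interquartile range of shell elasticity and viscosity over the
#' converged fits of a cohort, the form in which spectroscopy results are
#' reported per microbubble type. Non-converged fits are excluded. Quartiles
#' use linearly interpolated order statistics (R's default type 7).
#'
#' @param fits List of [fit_oscillator()] results.
#' @return A one-row data frame: `n`, `chi_median`, `chi_q1`, `chi_q3`,
#'   `kappa_s_median`, `kappa_s_q1`, `kappa_s_q3` (SI units).
#' @export
cohort_summary <- function(fits) {
  if (length(fits) == 0L) stop("empty fit list")
  ok <- vapply(fits, function(f) isTRUE(f$converged), logical(1))
  if (!any(ok)) stop("no converged fits to summarize")
  chi <- vapply(fits[ok], function(f) f$shell$chi, numeric(1))
  ks <- vapply(fits[ok], function(f) f$shell$kappa_s, numeric(1))
  q <- function(v) stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  qc <- q(chi); qk <- q(ks)
  data.frame(n = sum(ok),
             chi_median = qc[2], chi_q1 = qc[1], chi_q3 = qc[3],
             kappa_s_median = qk[2], kappa_s_q1 = qk[1], kappa_s_q3 = qk[3])
}
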