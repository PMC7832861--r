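#' Physical constants for coated-microbubble linear dynamics
#'
#' Container for the medium and gas-core constants entering the linearized
#' oscillator model of a coated microbubble. Defaults are the values for a
#' C4F10-filled phospholipid-coated bubble in water at room temperature.
#'
#' @param gamma Ratio of specific heats of the core gas (dimensionless).
#' @param P0 Ambient pressure (Pa).
#' @param sigma_w Surface tension of water (N/m).
#' @param rho Liquid density (kg/m^3).
#' @param c Speed of sound in the liquid (m/s).
#' @param mu Liquid dynamic viscosity (Pa s).
#'
#' @return An object of class `physical_constants` (named list).
#' @export
#' @examples
#' physical_constants()
physical_constants <- function(gamma = 1.07, P0 = 1e5, sigma_w = 0.072,
                               rho = 1000, c = 1500, mu = 1e-3) {
  vals <- list(gamma = gamma, P0 = P0, sigma_w = sigma_w,
               rho = rho, c = c, mu = mu)
  bad <- vapply(vals, function(v) !is.numeric(v) || length(v) != 1L ||
                  !is.finite(v) || v <= 0, logical(1))
  # sigma_w and mu may be set to 0 in limiting cases used for verification
  bad[c("sigma_w", "mu")] <- vapply(vals[c("sigma_w", "mu")], function(v)
    !is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0, logical(1))
  if (any(bad)) {
    stop("physical constants must be positive finite scalars (sigma_w, mu >= 0): ",
         paste(names(vals)[bad], collapse = ", "))
  }
  structure(vals, class = "physical_constants")
}

#' @export
print.physical_constants <- function(x, ...) {
  cat("Physical constants:\n")
  cat(sprintf("  gamma = %.3f  P0 = %.3g Pa  sigma_w = %.3g N/m\n",
              x$gamma, x$P0, x$sigma_w))
  cat(sprintf("  rho = %.3g kg/m^3  c = %.4g m/s  mu = %.3g Pa s\n",
              x$rho, x$c, x$mu))
  invisible(x)
}

#' Eigenfrequency of a coated microbubble
#'
#' Undamped natural frequency of the linearized coated-bubble oscillator,
#' \deqn{f_0 = \frac{1}{2\pi}\sqrt{\frac{1}{\rho R_0^2}\left[3\gamma P_0 +
#'   2(3\gamma - 1)\frac{\sigma_w}{R_0} + \frac{4\chi}{R_0}\right]}}
#' with resting radius \eqn{R_0} and shell elasticity \eqn{\chi}. It is
#' monotonically increasing in `chi` and decreasing in `R0`.
#'
#' @param R0 Resting radius (m), positive. Vectorized.
#' @param chi Shell elasticity (N/m), non-negative. Vectorized.
#' @param consts A [physical_constants()] object.
#'
#' @return Eigenfrequency in Hz.
#' @export
#' @examples
#' eigenfrequency(2.5e-6, chi = 0.14)  # about 1.65 MHz
eigenfrequency <- function(R0, chi, consts = physical_constants()) {
  if (any(!is.finite(R0)) || any(R0 <= 0)) {
    stop("R0 must be positive and finite")
  }
  if (any(!is.finite(chi)) || any(chi < 0)) {
    stop("chi must be non-negative and finite")
  }
  g <- consts$gamma
  stiff <- 3 * g * consts$P0 + 2 * (3 * g - 1) * consts$sigma_w / R0 +
    4 * chi / R0
  sqrt(stiff / (consts$rho * R0^2)) / (2 * pi)
}

#' Damping coefficient of a coated microbubble
#'
#' Dimensionless damping of the linearized oscillator, the sum of the
#' radiation, liquid-viscous and shell-viscous contributions evaluated at the
#' eigenfrequency \eqn{\omega_0 = 2\pi f_0}:
#' \deqn{\delta = \frac{\omega_0 R_0}{c} + \frac{4\mu}{\rho\omega_0 R_0^2} +
#'   \frac{4\kappa_s}{\rho\omega_0 R_0^3}}
#' The damping is treated as frequency-independent per bubble (evaluated at
#' \eqn{\omega_0}); it is strictly increasing (linear) in `kappa_s`.
#'
#' @param R0 Resting radius (m), positive.
#' @param f0 Eigenfrequency (Hz), positive.
#' @param kappa_s Shell viscosity (kg/s), non-negative.
#' @param consts A [physical_constants()] object.
#'
#' @return Damping coefficient (dimensionless).
#' @export
#' @examples
#' f0 <- eigenfrequency(2.5e-6, 0.14)
#' damping_coefficient(2.5e-6, f0, 0.43e-8)  # about 0.185
damping_coefficient <- function(R0, f0, kappa_s, consts = physical_constants()) {
  if (any(!is.finite(R0)) || any(R0 <= 0)) stop("R0 must be positive")
  if (any(!is.finite(f0)) || any(f0 <= 0)) stop("f0 must be positive")
  if (any(!is.finite(kappa_s)) || any(kappa_s < 0)) {
    stop("kappa_s must be non-negative")
  }
  w0 <- 2 * pi * f0
  w0 * R0 / consts$c +
    4 * consts$mu / (consts$rho * w0 * R0^2) +
    4 * kappa_s / (consts$rho * w0 * R0^3)
}

#' Resonance frequency from eigenfrequency and damping
#'
#' \deqn{f_{res} = f_0\sqrt{1 - \delta^2/2}} which is real only for
#' \eqn{\delta^2 < 2} (below that bound the damped oscillator has no
#' amplitude-response maximum).
#'
#' @param f0 Eigenfrequency (Hz).
#' @param delta Damping coefficient (dimensionless).
#'
#' @return Resonance frequency (Hz), always `<= f0`.
#' @export
resonance_frequency <- function(f0, delta) {
  if (any(!is.finite(f0)) || any(f0 <= 0)) stop("f0 must be positive")
  if (any(delta < 0)) stop("delta must be non-negative")
  if (any(delta^2 >= 2)) {
    stop("overdamped: delta^2 >= 2, no real resonance frequency")
  }
  f0 * sqrt(1 - delta^2 / 2)
}

#' Steady-state relative oscillation amplitude of the driven oscillator
#'
#' Analytic steady-state amplitude of the linear coated-bubble oscillator
#' driven at transmit frequency `fT` with acoustic pressure `P`:
#' \deqn{x_0 = \frac{|P|/(4\pi^2\rho R_0^2)}
#'   {\sqrt{(f_0^2 - f_T^2)^2 + (\delta f_T f_0)^2}}}
#' `x0` is the radial excursion amplitude relative to the resting radius.
#'
#' @param fT Transmit frequency (Hz), positive. Vectorized.
#' @param P Acoustic pressure amplitude (Pa), non-negative.
#' @param R0 Resting radius (m).
#' @param f0 Eigenfrequency (Hz).
#' @param delta Damping coefficient.
#' @param consts A [physical_constants()] object (supplies `rho`).
#'
#' @return Relative oscillation amplitude (dimensionless).
#' @export
#' @examples
#' f0 <- eigenfrequency(2.5e-6, 0.14)
#' d <- damping_coefficient(2.5e-6, f0, 0.43e-8)
#' oscillator_amplitude(f0, 50e3, 2.5e-6, f0, d)  # about 0.40 at resonance
oscillator_amplitude <- function(fT, P, R0, f0, delta,
                                 consts = physical_constants()) {
  if (any(!is.finite(fT)) || any(fT <= 0)) stop("fT must be positive")
  if (any(P < 0)) stop("P must be non-negative")
  if (any(R0 <= 0)) stop("R0 must be positive")
  denom <- sqrt((f0^2 - fT^2)^2 + (delta * fT * f0)^2)
  if (any(denom == 0)) {
    stop("singular response: fT equals f0 with zero damping")
  }
  (abs(P) / (4 * pi^2 * consts$rho * R0^2)) / denom
}

#' Shell parameter set of one microbubble
#'
#' Bundles the coating parameters with the derived linear-oscillator
#' quantities: eigenfrequency `f0`, damping `delta` and resonance frequency
#' `f_res` (NA when overdamped, `delta^2 >= 2`).
#'
#' @param chi Shell elasticity (N/m), non-negative.
#' @param kappa_s Shell viscosity (kg/s), non-negative.
#' @param R0 Resting radius (m).
#' @param consts A [physical_constants()] object.
#'
#' @return An object of class `shell_params` with fields `chi`, `kappa_s`,
#'   `R0`, `f0`, `delta`, `f_res`.
#' @export
#' @examples
#' shell_params(0.14, 0.43e-8, 2.5e-6)
shell_params <- function(chi, kappa_s, R0, consts = physical_constants()) {
  f0 <- eigenfrequency(R0, chi, consts)
  delta <- damping_coefficient(R0, f0, kappa_s, consts)
  f_res <- if (delta^2 < 2) f0 * sqrt(1 - delta^2 / 2) else NA_real_
  structure(list(chi = chi, kappa_s = kappa_s, R0 = R0,
                 f0 = f0, delta = delta, f_res = f_res,
                 consts = consts),
            class = "shell_params")
}

#' @export
print.shell_params <- function(x, ...) {
  cat("Microbubble shell parameters:\n")
  cat(sprintf("  chi     = %.4g N/m\n", x$chi))
  cat(sprintf("  kappa_s = %.4g kg/s (%.3g x 1e-8)\n", x$kappa_s, x$kappa_s * 1e8))
  cat(sprintf("  R0      = %.3g um\n", x$R0 * 1e6))
  cat(sprintf("  f0      = %.4g MHz   delta = %.4g   f_res = %.4g MHz\n",
              x$f0 / 1e6, x$delta,
              if (is.na(x$f_res)) NA else x$f_res / 1e6))
  invisible(x)
}
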