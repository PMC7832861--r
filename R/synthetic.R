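#' Ultrasound driving pulse
#'
#' Description of the transmitted burst: an `n_cycles`-cycle sine at the
#' transmit frequency, either Gaussian-tapered (default, emulating the
#' bursts used for single-bubble spectroscopy) or flat (rectangular,
#' useful for steady-state verification). For the Gaussian taper the
#' envelope width is set so that the -6 dB (half-amplitude) duration of
#' the envelope spans the `n_cycles` cycles.
#'
#' @param fT Transmit frequency (Hz).
#' @param pnp Peak negative pressure (Pa), >= 0.
#' @param n_cycles Number of cycles (default 8).
#' @param envelope `"gaussian"` or `"flat"`.
#'
#' @return An object of class `driving_pulse`.
#' @export
driving_pulse <- function(fT, pnp, n_cycles = 8, envelope = c("gaussian", "flat")) {
  envelope <- match.arg(envelope)
  if (!is.finite(fT) || fT <= 0) stop("fT must be positive")
  if (!is.finite(pnp) || pnp < 0) stop("pnp must be non-negative")
  if (n_cycles < 1) stop("n_cycles must be >= 1")
  structure(list(fT = fT, pnp = pnp, n_cycles = n_cycles, envelope = envelope),
            class = "driving_pulse")
}

# instantaneous drive pressure of a pulse centred at t_center
pulse_pressure <- function(pulse, t, t_center) {
  dt <- t - t_center
  env <- if (pulse$envelope == "gaussian") {
    # half-amplitude full width = n_cycles / fT
    tau <- (pulse$n_cycles / (2 * pulse$fT)) / sqrt(2 * log(2))
    exp(-dt^2 / (2 * tau^2))
  } else {
    as.numeric(abs(dt) <= pulse$n_cycles / (2 * pulse$fT))
  }
  pulse$pnp * sin(2 * pi * pulse$fT * dt) * env
}

#' Ground truth of a synthetic microbubble
#'
#' Everything the generators need to produce data with known truth: the
#' coating parameters, injected harmonic components, measurement noise,
#' inter-recording deflation, and the seed that fixes all randomness. The
#' sidecar travels with every generated object so validation code consumes
#' ground truth only through it.
#'
#' @param chi Shell elasticity (N/m).
#' @param kappa_s Shell viscosity (kg/s).
#' @param R0 Resting radius (m).
#' @param harmonics List of injected components, each a list with `kind`
#'   (`"subharmonic"` or `"second_harmonic"`) and `level_db` (dB relative
#'   to the peak fundamental excursion).
#' @param noise_sigma Gaussian radius noise, standard deviation relative
#'   to `R0` (dimensionless).
#' @param deflation_rate Total relative radius decrease across a session
#'   (applied linearly per recording).
#' @param seed Integer seed, or `NULL` for unseeded.
#'
#' @return An object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(chi, kappa_s, R0, harmonics = list(),
                            noise_sigma = 0, deflation_rate = 0, seed = NULL) {
  if (R0 <= 0) stop("R0 must be positive")
  if (chi < 0 || kappa_s < 0) stop("chi and kappa_s must be non-negative")
  if (noise_sigma < 0) stop("noise_sigma must be non-negative")
  for (h in harmonics) {
    if (!h$kind %in% c("subharmonic", "second_harmonic")) {
      stop("harmonic kind must be 'subharmonic' or 'second_harmonic'")
    }
  }
  structure(list(chi = chi, kappa_s = kappa_s, R0 = R0,
                 harmonics = harmonics, noise_sigma = noise_sigma,
                 deflation_rate = deflation_rate, seed = seed),
            class = "synthetic_truth")
}

# run code under a local seed, restoring the RNG state afterwards
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Simulate the radius-time response of a coated microbubble
#'
#' Integrates the linearized coated-bubble oscillator
#' \deqn{\ddot x + \delta\omega_0\dot x + \omega_0^2 x = -P(t)/(\rho R_0^2)}
#' for the relative excursion \eqn{x = (R - R_0)/R_0} driven by the
#' enveloped burst, samples it at the camera frame times, and adds the
#' optional injected harmonic components (at `fT/2` and/or `2 fT`, scaled
#' relative to the peak fundamental excursion and sharing its envelope)
#' and Gaussian radius noise. The drive scaling is fixed by the steady
#' state: a long flat drive reproduces [oscillator_amplitude()] within 1%.
#'
#' @param truth A [synthetic_truth()].
#' @param pulse A [driving_pulse()]; `pnp = 0` gives a baseline recording.
#' @param frame_rate Camera frame rate (frames/s), default 17e6.
#' @param n_frames Number of frames, default 128.
#' @param consts A [physical_constants()] object.
#' @param t_center Burst centre (s), default mid-record.
#' @param x_init,v_init Initial relative excursion and its velocity.
#' @param R0 Resting radius override (m), used by the session generator to
#'   apply inter-recording deflation; defaults to `truth$R0`.
#' @param seed Seed for the noise (default `truth$seed`); the RNG state of
#'   the caller is restored afterwards.
#'
#' @return An [rt_curve()]; `fT` is `NA` when `pulse$pnp == 0`.
#' @export
simulate_rt <- function(truth, pulse, frame_rate = 17e6, n_frames = 128L,
                        consts = physical_constants(), t_center = NULL,
                        x_init = 0, v_init = 0, R0 = truth$R0,
                        seed = truth$seed) {
  stopifnot(inherits(truth, "synthetic_truth"), inherits(pulse, "driving_pulse"))
  if (frame_rate <= 4 * pulse$fT) {
    stop("frame rate violates Nyquist for the second harmonic (need > 4 fT)")
  }
  times <- (seq_len(n_frames) - 1) / frame_rate
  tc <- t_center %||% (max(times) / 2)

  x <- rep(0, n_frames)
  if (pulse$pnp > 0 || x_init != 0 || v_init != 0) {
    f0 <- eigenfrequency(R0, truth$chi, consts)
    delta <- damping_coefficient(R0, f0, truth$kappa_s, consts)
    w0 <- 2 * pi * f0
    drive <- -1 / (consts$rho * R0^2)
    deriv <- function(t, y, parms) {
      list(c(y[2],
             drive * pulse_pressure(pulse, t, tc) -
               delta * w0 * y[2] - w0^2 * y[1]))
    }
    sol <- deSolve::ode(y = c(x_init, v_init), times = times, func = deriv,
                        parms = NULL, method = "lsoda",
                        rtol = 1e-9, atol = 1e-12,
                        hmax = 1 / (40 * max(pulse$fT, f0)))
    x <- sol[, 2]
  }

  if (length(truth$harmonics) && pulse$pnp > 0) {
    xpk <- max(abs(x))
    dt <- times - tc
    env <- if (pulse$envelope == "gaussian") {
      tau <- (pulse$n_cycles / (2 * pulse$fT)) / sqrt(2 * log(2))
      exp(-dt^2 / (2 * tau^2))
    } else {
      as.numeric(abs(dt) <= pulse$n_cycles / (2 * pulse$fT))
    }
    for (h in truth$harmonics) {
      fh <- if (h$kind == "subharmonic") pulse$fT / 2 else 2 * pulse$fT
      x <- x + 10^(h$level_db / 20) * xpk * env * sin(2 * pi * fh * dt)
    }
  }

  r <- R0 * (1 + x)
  if (truth$noise_sigma > 0) {
    r <- r + with_local_seed(seed, stats::rnorm(n_frames, 0, truth$noise_sigma * R0))
  }
  rt_curve(t = times, r = r,
           fT = if (pulse$pnp > 0) pulse$fT else NA_real_,
           pnp = if (pulse$pnp > 0) pulse$pnp else NA_real_)
}

#' Simulate a full spectroscopy session
#'
#' Generates one baseline recording (no drive, noise only) followed by one
#' recording per transmit frequency of the grid, all with the session
#' pressure and per-recording bursts. Deflation is applied as a linear
#' decrease of the resting radius across recordings, reaching
#' `truth$deflation_rate` (relative) at the last recording. Randomness is
#' fixed by `truth$seed`: recording `k` uses seed `truth$seed + k`
#' (baseline `k = 0`).
#'
#' @param truth A [synthetic_truth()].
#' @param grid Transmit frequencies (Hz), default [default_ft_grid()].
#' @param pnp Session peak negative pressure (Pa), default 50 kPa.
#' @param frame_rate,n_frames Camera sampling, defaults 17e6 and 128.
#' @param n_cycles,envelope Burst shape, defaults 8 cycles, Gaussian.
#' @param consts A [physical_constants()] object.
#' @param bubble_id Identifier stored on the session.
#'
#' @return A [spectroscopy_session()] carrying `truth` as its sidecar.
#' @export
simulate_session <- function(truth, grid = default_ft_grid(), pnp = 50e3,
                             frame_rate = 17e6, n_frames = 128L,
                             n_cycles = 8, envelope = "gaussian",
                             consts = physical_constants(),
                             bubble_id = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (!length(grid)) stop("empty transmit grid")
  K <- length(grid)
  seed0 <- truth$seed
  baseline <- simulate_rt(truth, driving_pulse(grid[1], 0, n_cycles, envelope),
                          frame_rate, n_frames, consts,
                          seed = if (is.null(seed0)) NULL else seed0)
  recs <- vector("list", K)
  for (k in seq_len(K)) {
    R0k <- truth$R0 * (1 - truth$deflation_rate * k / K)
    recs[[k]] <- simulate_rt(truth,
                             driving_pulse(grid[k], pnp, n_cycles, envelope),
                             frame_rate, n_frames, consts, R0 = R0k,
                             seed = if (is.null(seed0)) NULL else seed0 + k)
  }
  spectroscopy_session(baseline, recs, pnp = pnp, bubble_id = bubble_id,
                       truth = truth)
}

#' Synthetic number-weighted size distribution
#'
#' Draws a lognormal diameter sample and histograms it on Coulter-counter
#' style bins (1-30 um by default), returning both the binned distribution
#' and the raw draws (as the `draws` attribute) so percentile computations
#' can be cross-checked against the sample.
#'
#' @param meanlog,sdlog Lognormal parameters of the diameter (um).
#' @param n Number of particles.
#' @param breaks Bin edges (um), default `seq(1, 30, by = 0.1)`.
#' @param seed Integer seed or `NULL`.
#'
#' @return A [size_distribution()] with attribute `draws` (the raw sample,
#'   truncated to the bin range).
#' @export
synth_size_distribution <- function(meanlog = log(3), sdlog = 0.35, n = 5000,
                                    breaks = seq(1, 30, by = 0.1),
                                    seed = NULL) {
  if (n < 1) stop("n must be >= 1")
  d <- with_local_seed(seed, stats::rlnorm(n, meanlog, sdlog))
  d <- d[d >= min(breaks) & d <= max(breaks)]
  h <- graphics::hist(d, breaks = breaks, plot = FALSE)
  out <- size_distribution(h$mids, h$counts)
  attr(out, "draws") <- d
  out
}
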