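# FFT-based sub-/second-harmonic classification. Test tones are placed on
# the pre-padding bin grid (fs = 12.8 MHz, 128 frames -> 100 kHz bins) so
# peak amplitudes are exact.

fs_nl <- 12.8e6
n_nl <- 128L

test_that("fft_amplitude resolves on-grid tones at their exact level", {
  cu <- tone_curve(fs_nl, n_nl, 2.5e-6, list(list(a = 50e-9, f = 2e6)))
  fa <- fft_amplitude(cu)
  ipk <- which.max(fa$amp_db)
  expect_equal(fa$freqs[ipk], 2e6)
  expect_equal(fa$amp_db[ipk], 20 * log10(50e-9), tolerance = 1e-9)

  # doubling the amplitude raises the peak by 6.02 dB
  cu2 <- tone_curve(fs_nl, n_nl, 2.5e-6, list(list(a = 100e-9, f = 2e6)))
  fa2 <- fft_amplitude(cu2)
  expect_equal(max(fa2$amp_db) - max(fa$amp_db), 20 * log10(2),
               tolerance = 1e-9)

  # seeded white noise has no towering outlier bins
  wn <- tone_curve(fs_nl, 512L, 2.5e-6, list(), noise_sd = 1e-9, seed = 5)
  fawn <- fft_amplitude(wn)
  expect_lt(max(fawn$amp_db), median(fawn$amp_db) + 20)

  expect_error(fft_amplitude(tone_curve(fs_nl, 8L, 2.5e-6, list())), ">= 16")
})

test_that("noise floor is deterministic, median-based, and scales linearly", {
  bl <- tone_curve(fs_nl, n_nl, 2.5e-6, list(), noise_sd = 1e-9, seed = 1)
  expect_identical(noise_level(bl, 4e6), noise_level(bl, 4e6))

  # near-silent baseline -> very low floor (dB re 1 m)
  quiet <- tone_curve(fs_nl, n_nl, 2.5e-6, list(), noise_sd = 1e-13, seed = 2)
  expect_lt(noise_level(quiet, 4e6), -100)

  # doubling the baseline noise raises the floor by ~6 dB (same seed)
  bl2 <- tone_curve(fs_nl, n_nl, 2.5e-6, list(), noise_sd = 2e-9, seed = 1)
  expect_equal(noise_level(bl2, 4e6) - noise_level(bl, 4e6), 20 * log10(2),
               tolerance = 1e-9)

  expect_error(noise_level(bl, 6.3e6), "Nyquist")
  rec <- tone_curve(fs_nl, n_nl, 2.5e-6, list(), fT = 2e6)
  expect_error(noise_level(rec, 4e6), "baseline")
})

test_that("harmonic detection flips exactly at the 6 dB threshold", {
  bl <- tone_curve(fs_nl, n_nl, 2.5e-6, list(), noise_sd = 3e-9, seed = 11)
  nf <- noise_level(bl, 4e6)
  t <- (seq_len(n_nl) - 1) / fs_nl
  mk <- function(over_db) {
    ah <- 10^((nf + over_db) / 20)
    rt_curve(t, 2.5e-6 + 5e-9 * sin(2 * pi * 2e6 * t) +
               ah * sin(2 * pi * 4e6 * t), fT = 2e6, pnp = 50e3)
  }
  below <- detect_harmonic(mk(5.9), bl, "second_harmonic")
  above <- detect_harmonic(mk(6.1), bl, "second_harmonic")
  expect_false(below$detected)
  expect_true(above$detected)
  expect_equal(above$peak_db - above$noise_db, 6.1, tolerance = 1e-6)
})

test_that("harmonic amplitude is recovered within 1 dB and is scale-invariant", {
  bl <- tone_curve(fs_nl, n_nl, 2.5e-6, list(), noise_sd = 1e-10, seed = 3)
  t <- (seq_len(n_nl) - 1) / fs_nl
  for (level_db in c(-30, -20, -10)) {
    af <- 50e-9
    r <- 2.5e-6 + af * sin(2 * pi * 2e6 * t) +
      af * 10^(level_db / 20) * sin(2 * pi * 4e6 * t)
    rec <- rt_curve(t, r, fT = 2e6, pnp = 50e3)
    h <- detect_harmonic(rec, bl, "second_harmonic")
    expect_true(h$detected)
    expect_equal(h$amplitude_db, level_db, tolerance = 1)

    # multiplying the whole radius signal by a constant cancels in the ratio
    rec2 <- rt_curve(t, 2.5e-6 + 3 * (r - 2.5e-6), fT = 2e6, pnp = 50e3)
    h2 <- detect_harmonic(rec2, bl, "second_harmonic")
    expect_equal(h2$amplitude_db, h$amplitude_db, tolerance = 1e-9)
  }
})

test_that("detection is monotone in the injected harmonic level", {
  # floor set above the fundamental's leakage sidelobes so detection is
  # governed by the injected level alone
  bl <- tone_curve(fs_nl, n_nl, 2.5e-6, list(), noise_sd = 2e-8, seed = 6)
  t <- (seq_len(n_nl) - 1) / fs_nl
  det <- vapply(seq(-60, -6, by = 6), function(level_db) {
    r <- 2.5e-6 + 50e-9 * sin(2 * pi * 2e6 * t) +
      50e-9 * 10^(level_db / 20) * sin(2 * pi * 1e6 * t)
    detect_harmonic(rt_curve(t, r, fT = 2e6, pnp = 50e3), bl,
                    "subharmonic")$detected
  }, logical(1))
  expect_true(all(diff(as.integer(det)) >= 0))
})

test_that("sessions are classified only with detections in >= 2 recordings", {
  t <- (seq_len(n_nl) - 1) / fs_nl
  bl <- tone_curve(fs_nl, n_nl, 2.5e-6, list(), noise_sd = 1e-8, seed = 9)
  clean <- function(fT) {
    tone_curve(fs_nl, n_nl, 2.5e-6, list(list(a = 50e-9, f = fT)),
               fT = fT, pnp = 50e3)
  }
  harm <- function(fT) {
    tone_curve(fs_nl, n_nl, 2.5e-6,
               list(list(a = 50e-9, f = fT), list(a = 10e-9, f = 2 * fT)),
               fT = fT, pnp = 50e3)
  }
  grid <- c(1e6, 1.5e6, 2e6)

  s1 <- spectroscopy_session(bl, list(harm(1e6), clean(1.5e6), clean(2e6)),
                             pnp = 50e3)
  c1 <- classify_session(s1, "second_harmonic")
  expect_equal(c1$n_detected, 1L)
  expect_false(c1$classified)

  s2 <- spectroscopy_session(bl, list(harm(1e6), harm(1.5e6), clean(2e6)),
                             pnp = 50e3)
  c2 <- classify_session(s2, "second_harmonic")
  expect_equal(c2$n_detected, 2L)
  expect_true(c2$classified)
  expect_equal(c2$max_amp_db, 20 * log10(10e-9 / 50e-9), tolerance = 1)

  s0 <- spectroscopy_session(bl, lapply(grid, clean), pnp = 50e3)
  c0 <- classify_session(s0, "second_harmonic")
  expect_false(c0$classified)
  expect_true(is.na(c0$max_amp_db))
})

test_that("generator-injected harmonics are recovered end to end", {
  tr <- synthetic_truth(0.14, 0.43e-8, 2.5e-6,
                        harmonics = list(list(kind = "second_harmonic",
                                              level_db = -20)),
                        noise_sigma = 1e-5, seed = 7)
  bl <- simulate_rt(tr, driving_pulse(2e6, 0), frame_rate = fs_nl)
  rec <- simulate_rt(tr, driving_pulse(2e6, 50e3), frame_rate = fs_nl)
  h <- detect_harmonic(rec, bl, "second_harmonic")
  expect_true(h$detected)
  expect_equal(h$amplitude_db, -20, tolerance = 1)
})
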