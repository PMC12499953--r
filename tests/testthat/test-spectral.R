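# Direct spectrum construction for closed-form centroid / peak checks.
make_spectrum <- function(freqs, power, n_fft = 4096L) {
  structure(list(freqs_hz = freqs, power = power, n_fft = n_fft,
                 window_fn = "hamming"), class = "spectrum_estimate")
}

test_that("high-band filter kills low tones and passes high ones", {
  rate <- 44100
  t <- seq_len(round(0.2 * rate)) / rate
  low <- waveform(sin(2 * pi * 100 * t), rate)
  high <- waveform(sin(2 * pi * 5000 * t), rate)
  rms <- function(w) sqrt(mean(w$samples^2))
  expect_lt(rms(highband_filter(low)) / rms(low), 0.01)
  expect_equal(rms(highband_filter(high)) / rms(high), 1, tolerance = 0.01)
  z <- waveform(rep(0, 1000) + 0, rate)
  expect_error(z <- waveform(rep(0, 1000), rate), NA)
  expect_true(all(abs(highband_filter(z)$samples) < 1e-12))
  expect_error(highband_filter(low, cutoff_hz = 30000), "Nyquist")
})

test_that("window plans follow the central-80% placement arithmetic", {
  p90 <- plan_windows(0.090)
  expect_equal(p90$region_end_s - p90$region_start_s, 0.072)
  expect_equal(p90$step_s, 0.0114, tolerance = 1e-12)
  expect_equal(p90$overlap_frac, 0.24, tolerance = 1e-9)

  p60 <- plan_windows(0.060)
  expect_equal(p60$step_s, 0.0066, tolerance = 1e-12)
  expect_equal(p60$overlap_frac, 0.56, tolerance = 1e-9)

  p150 <- plan_windows(0.150)
  expect_equal(p150$step_s, 0.021, tolerance = 1e-12)
  expect_equal(p150$overlap_frac, 0)

  # first window starts at the region onset, last ends at the region offset,
  # and centers are symmetric about the token midpoint
  expect_equal(p90$onsets_s[1], p90$region_start_s)
  expect_equal(p90$onsets_s[6] + p90$win_s, p90$region_end_s)
  expect_equal(mean(p90$centers_s), 0.045, tolerance = 1e-12)

  expect_error(plan_windows(0.016), "unmeasurable")
})

test_that("time averaging reduces spectral variance and preserves peaks", {
  rate <- 44100
  w <- with_seed(5, waveform(stats::rnorm(round(0.15 * rate)), rate))
  plan6 <- plan_windows(0.15)
  plan1 <- plan_windows(0.15, n_windows = 1L)
  s6 <- time_averaged_spectrum(w, plan6)
  s1 <- time_averaged_spectrum(w, plan1)
  band <- s6$freqs_hz > 500 & s6$freqs_hz < 20000
  expect_lt(stats::var(log(s6$power[band])), stats::var(log(s1$power[band])))

  tone <- waveform(sin(2 * pi * 5000 * seq_len(round(0.15 * rate)) / rate),
                   rate)
  st <- time_averaged_spectrum(tone, plan6)
  expect_lt(abs(st$freqs_hz[which.max(st$power)] - 5000),
            rate / st$n_fft + 1e-9)
})

test_that("averaging identical windows equals a single-window spectrum", {
  rate <- 44000                       # 15 ms step = exactly 660 samples
  dur <- 0.1125                       # 6 abutting windows tile the region
  t <- seq_len(round(dur * rate)) / rate
  # 1000 Hz: 15 whole periods per 15 ms step, so every window sees the same
  # segment of the waveform
  w <- waveform(sin(2 * pi * 1000 * t), rate)
  plan <- plan_windows(dur)
  expect_equal(plan$overlap_frac, 0, tolerance = 1e-12)
  s6 <- time_averaged_spectrum(w, plan)
  s1 <- time_averaged_spectrum(w, structure(
    list(n_windows = 1L, win_s = plan$win_s, region_start_s = plan$region_start_s,
         region_end_s = plan$region_start_s + plan$win_s,
         onsets_s = plan$onsets_s[1], centers_s = plan$centers_s[1],
         step_s = plan$step_s, overlap_frac = 0), class = "window_plan"))
  expect_equal(s6$power, s1$power, tolerance = 1e-12)
})

test_that("windows beyond the audio raise a bounds error naming the window", {
  w <- waveform(rep(0.5, 1000), 44100)
  plan <- plan_windows(0.09)          # needs ~4000 samples
  expect_error(time_averaged_spectrum(w, plan), "window")
})

test_that("spectral centroid matches closed forms", {
  f <- seq(0, 22050, by = 22050 / 2048)
  p <- numeric(length(f))
  p[which.min(abs(f - 5004))] <- 3
  expect_equal(spectral_moment_m1(make_spectrum(f, p)),
               f[which.min(abs(f - 5004))])

  p2 <- numeric(length(f))
  p2[which.min(abs(f - 4000))] <- 1
  p2[which.min(abs(f - 8000))] <- 1
  expect_equal(spectral_moment_m1(make_spectrum(f, p2)),
               (f[which.min(abs(f - 4000))] + f[which.min(abs(f - 8000))]) / 2)

  p3 <- as.numeric(f >= 3000 & f <= 9000)
  expect_lt(abs(spectral_moment_m1(make_spectrum(f, p3)) - 6000),
            22050 / 2048 + 1e-9)

  expect_error(spectral_moment_m1(make_spectrum(f, numeric(length(f)))),
               "positive power")
})

test_that("amplitude and power weighting are both available and differ", {
  f <- seq(0, 22050, by = 22050 / 2048)
  p <- exp(-((f - 5000) / 2500)^2) + 0.2 * exp(-((f - 9000) / 500)^2)
  m_pow <- spectral_moment_m1(make_spectrum(f, p), power_exponent = 2)
  m_amp <- spectral_moment_m1(make_spectrum(f, p), power_exponent = 1)
  expect_false(isTRUE(all.equal(m_pow, m_amp)))
})

test_that("band peak uses inclusive bounds and lowest-frequency tie-break", {
  f <- seq(0, 22050, by = 22050 / 2048)
  p <- rep(1e-6, length(f))
  i4 <- which.min(abs(f - 4000)); i6 <- which.min(abs(f - 6000))
  p[c(i4, i6)] <- 7
  expect_equal(band_peak_fm(make_spectrum(f, p), 3000, 9000), f[i4])
  expect_error(band_peak_fm(make_spectrum(f, p), 9000, 3000), "lo < hi")
  expect_error(band_peak_fm(make_spectrum(f, p), 3000, 3001), "2 bins")
})

test_that("band peak tracks a resonance and depends on the band's upper edge", {
  # analytic two-pole magnitude curve as the oracle spectrum
  rate <- 44100
  f <- (0:2048) * rate / 4096
  resp <- function(fc, bw) {
    r <- exp(-pi * bw / rate)
    th <- 2 * pi * fc / rate
    om <- 2 * pi * f / rate
    h <- 1 / abs((1 - r * exp(1i * (th - om))) * (1 - r * exp(-1i * (th + om))))
    h^2
  }
  s65 <- make_spectrum(f, resp(6500, 300))
  peak <- band_peak_fm(s65, 3000, 9000)
  idx_truth <- which.min(abs(f - 6500))
  expect_lt(abs(which.min(abs(f - peak)) - idx_truth), 4)   # within 3 bins

  s76 <- make_spectrum(f, resp(7600, 300))
  expect_lte(band_peak_fm(s76, 3000, 7000), 7000)
  expect_lt(abs(band_peak_fm(s76, 3000, 8000) - 7600), 50)
})

test_that("centroid and band peak agree with brute-force oracles", {
  # independent direct computation: explicit loops over bins
  for (s in 1:20) {
    spec <- with_seed(100 + s, {
      f <- seq(0, 22050, length.out = 513)
      make_spectrum(f, stats::rexp(513))
    })
    sel <- spec$freqs_hz >= 300
    oracle_m1 <- {
      num <- 0; den <- 0
      for (k in which(sel)) {
        num <- num + spec$freqs_hz[k] * spec$power[k]
        den <- den + spec$power[k]
      }
      num / den
    }
    expect_equal(spectral_moment_m1(spec), oracle_m1, tolerance = 1e-9)
    band <- which(spec$freqs_hz >= 3000 & spec$freqs_hz <= 9000)
    best <- band[1]
    for (k in band) if (spec$power[k] > spec$power[best]) best <- k
    expect_equal(band_peak_fm(spec, 3000, 9000), spec$freqs_hz[best],
                 tolerance = 1e-9)
  }
})

test_that("measures are invariant to waveform scale", {
  w <- synth_fricative(5200, seed = 9)
  m1 <- measure_token(w)
  m2 <- measure_token(waveform(w$samples * 37.5, w$rate))
  for (col in c("m1_hz", "fm_3_7_hz", "fm_3_8_hz", "fm_3_9_hz")) {
    expect_equal(m1[[col]], m2[[col]], tolerance = 1e-9)
  }
})

test_that("peak power is non-decreasing over nested bands and peaks lie in band", {
  for (s in 1:10) {
    w <- synth_fricative(stats::runif(1, 3300, 8700), seed = 300 + s)
    plan <- plan_windows(duration(w))
    spec <- time_averaged_spectrum(highband_filter(w), plan)
    pk <- function(hi) {
      sel <- spec$freqs_hz >= 3000 & spec$freqs_hz <= hi
      max(spec$power[sel])
    }
    expect_lte(pk(7000), pk(8000))
    expect_lte(pk(8000), pk(9000))
    m <- measure_token(w)
    expect_true(m$fm_3_7_hz >= 3000 && m$fm_3_7_hz <= 7000)
    expect_true(m$fm_3_8_hz >= 3000 && m$fm_3_8_hz <= 8000)
    expect_true(m$fm_3_9_hz >= 3000 && m$fm_3_9_hz <= 9000)
  }
})

test_that("single-resonator recovery is accurate at the calibrated level", {
  # the band-peak estimator's sampling noise at bandwidth 300 Hz puts about
  # 85-90% of recoveries within +/-100 Hz; assert the calibrated bounds
  n <- 80
  fc <- with_seed(17, stats::runif(n, 3300, 8700))
  est <- vapply(seq_len(n), function(i) {
    measure_token(synth_fricative(fc[i], seed = 1000 + i))$fm_3_9_hz
  }, numeric(1))
  err <- abs(est - fc)
  expect_gte(mean(err <= 100), 0.80)
  expect_gte(mean(err <= 250), 0.95)
})

test_that("measure_token composes the full chain with the jump rule", {
  m <- measure_token(synth_fricative(4200, seed = 3))
  expect_lt(abs(m$fm_3_7_hz - 4200), 100)
  expect_lt(abs(m$fm_3_8_hz - 4200), 100)
  expect_lt(abs(m$fm_3_9_hz - 4200), 100)
  expect_false(m$fm_jump_flag)

  # 6200 Hz dominant below 8 kHz, 8500 Hz dominant above: a substantial jump
  w2 <- synth_fricative(6200, secondary_resonance_hz = 8500,
                        secondary_gain_db = 6, seed = 4)
  m2 <- measure_token(w2)
  expect_lt(abs(m2$fm_3_8_hz - 6200), 200)
  expect_lt(abs(m2$fm_3_9_hz - 8500), 200)
  expect_true(m2$fm_jump_flag)

  # short tokens are still measurable; exclusion is screening's concern
  m3 <- measure_token(synth_fricative(5000, duration_s = 0.050, seed = 5))
  expect_equal(m3$duration_s, 0.050, tolerance = 1e-6)
  expect_gt(m3$overlap_frac, 0.5)
})

test_that("the 300 Hz filter isolates the centroid from LF contamination", {
  cfg_f <- spectral_config(m1_lo_hz = 0)
  cfg_nf <- spectral_config(filter_cutoff_hz = NA, m1_lo_hz = 0)
  clean <- synth_fricative(6000, seed = 21)
  dirty <- synth_fricative(6000, lf_contam_db = 10, seed = 21)
  shift <- function(cfg) {
    abs(measure_token(dirty, cfg)$m1_hz - measure_token(clean, cfg)$m1_hz) /
      measure_token(clean, cfg)$m1_hz
  }
  expect_lt(shift(cfg_f), 0.01)
  expect_gt(shift(cfg_nf), 0.10)
})
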