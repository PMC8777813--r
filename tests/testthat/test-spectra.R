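# direct power_spectrum construction for band arithmetic checks
flat_spectrum <- function(freq, power) {
  structure(list(frequency = freq, power = power, sampling_rate = NA,
                 n_replicates = 1L, role = "sample"),
            class = "power_spectrum")
}

test_that("averaged power spectrum localizes a pure tone and is idempotent", {
  fs <- 50e6
  t <- (0:511) / fs
  tone <- sin(2 * pi * 5e6 * t)
  set1 <- waveform_set(cbind(tone), fs)
  sp <- averaged_power_spectrum(set1)
  expect_equal(sp$frequency[which.max(sp$power)], 5e6,
               tolerance = fs / 512 / 5e6)
  # mean of two identical replicates equals either
  sp2 <- averaged_power_spectrum(waveform_set(cbind(tone, tone), fs))
  expect_equal(sp2$power, sp$power, tolerance = 1e-12)
  expect_error(waveform_set(list(tone, tone[-1]), fs), "mixed lengths")
})

test_that("white-noise periodogram averages to a flat spectrum", {
  set.seed(42)
  fs <- 10e6
  waves <- matrix(rnorm(256 * 400), nrow = 256)
  sp <- averaged_power_spectrum(waveform_set(waves, fs))
  db <- 10 * log10(sp$power / mean(sp$power))
  expect_lt(max(abs(db)), 1)
})

test_that("attenuation spectrum recovers a uniform power deficit", {
  fs <- 50e6
  t <- (0:511) / fs
  # broadband click with ~2 MHz spectral sigma around 4 MHz
  base <- exp(-0.5 * ((t - 2e-6) * 2 * pi * 2e6)^2) * sin(2 * pi * 4e6 * t)
  baseline <- waveform_set(cbind(base), fs, role = "baseline")
  # identical sets: zero attenuation
  a0 <- attenuation_spectrum(baseline, waveform_set(cbind(base), fs))
  expect_lt(max(abs(a0$attenuation)), 1e-9)
  # sample amplitude scaled by 10^(-16/20): 16 dB power deficit over 8 cm
  sample <- waveform_set(cbind(base * 10^(-16 / 20)), fs)
  a <- attenuation_spectrum(baseline, sample, path_cm = 8)
  excited <- a$frequency >= 0.5e6 & a$frequency <= 10e6  # click bandwidth
  expect_equal(range(a$attenuation[excited]), c(2, 2), tolerance = 1e-6)
  # antisymmetric under role swap
  rev <- attenuation_spectrum(sample, baseline, path_cm = 8)
  expect_equal(rev$attenuation, -a$attenuation, tolerance = 1e-12)
})

test_that("resonance peak obeys band limits and tie rules", {
  f <- seq(1e6, 10e6, by = 0.1e6)
  flat <- structure(list(frequency = f, attenuation = rep(1, length(f)),
                         path_cm = 8), class = "attenuation_spectrum")
  # flat spectrum: tie resolves to the lowest band frequency
  expect_equal(resonance_peak(flat, c(2e6, 5e6))$f_peak, 2e6)
  # peak on the band edge returned without extrapolation
  ramp <- structure(list(frequency = f, attenuation = f / 1e6, path_cm = 8),
                    class = "attenuation_spectrum")
  expect_equal(resonance_peak(ramp, c(2e6, 5e6))$f_peak, 5e6)
  expect_error(resonance_peak(flat, c(20e6, 30e6)), "band")
})

test_that("generated attenuation profiles round-trip through the analysis", {
  # flat 2 dB/cm, noiseless
  ws <- gen_waveform_set(function(f) rep(2, length(f)), noise_db = 0,
                         n_replicates = 3, seed = 5)
  sp <- attenuation_spectrum(ws$baseline, ws$sample)
  sel <- sp$frequency >= 1e6 & sp$frequency <= 10e6
  expect_equal(mean(sp$attenuation[sel]), 2, tolerance = 0.005)
  expect_lt(max(abs(sp$attenuation[sel] - 2)), 0.05)

  # Gaussian resonance profile (2.78 MHz, 4 dB/cm) with 0.2 dB noise:
  # peak recovered within one frequency bin
  prof <- function(f) 4 * exp(-0.5 * ((f - 2.78e6) / 0.6e6)^2)
  ws2 <- gen_waveform_set(prof, noise_db = 0.2, n_replicates = 15, seed = 6)
  sp2 <- attenuation_spectrum(ws2$baseline, ws2$sample)
  pk <- resonance_peak(sp2, c(1e6, 8e6))
  bin <- sp2$frequency[2] - sp2$frequency[1]
  expect_lt(abs(pk$f_peak - 2.78e6), bin)
  expect_equal(pk$a_peak, 4, tolerance = 0.1)
})

test_that("band metrics isolate the subharmonic and integral bands", {
  f <- seq(0.1e6, 12e6, by = 0.05e6)
  bg <- flat_spectrum(f, rep(1, length(f)))
  # identical spectra sit at the floor
  m0 <- band_metrics(bg, bg)
  expect_equal(m0$subharmonic_db, 0)
  expect_equal(m0$spectral_integral_db, 0)
  # injected tone at 500 kHz, +20 dB over background
  p <- rep(1, length(f))
  p[which.min(abs(f - 500e3))] <- 100
  m <- band_metrics(flat_spectrum(f, p), bg)
  expect_equal(m$subharmonic_db, 20, tolerance = 1e-9)
  expect_gt(m$spectral_integral_db, 0)
  # tone at 3 MHz only: subharmonic at floor, integral above it
  p3 <- rep(1, length(f))
  p3[which.min(abs(f - 3e6))] <- 100
  m3 <- band_metrics(flat_spectrum(f, p3), bg)
  expect_equal(m3$subharmonic_db, 0, tolerance = 1e-9)
  expect_gt(m3$spectral_integral_db, 0)
  # content outside both bands changes nothing
  p_out <- p
  p_out[f > 11e6] <- 500
  m_out <- band_metrics(flat_spectrum(f, p_out), bg)
  expect_equal(m_out$subharmonic_db, m$subharmonic_db)
  expect_equal(m_out$spectral_integral_db, m$spectral_integral_db)
  expect_error(band_metrics(bg, bg, integral_band = c(200e3, 20e6)), "band")
})
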