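# Spectrogram, induced spectral power, band profiles, gamma peak.

gamma_band_amp_z <- function(isp, lo = 35, hi = 55) {
  fsel <- isp$freq_hz >= lo & isp$freq_hz <= hi
  tsel <- isp$time_ms >= 200 & isp$time_ms <= 500
  mean(isp$z_amp[fsel, tsel])
}

test_that("spectrogram localizes tones and satisfies a Parseval check", {
  fs <- 1000
  t <- seq(-500, 499)
  x <- sin(2 * pi * 40 * t / 1000)
  sp <- spectrogram(x, fs, time_ms = t)
  peak_bins <- apply(sp$power[, , 1], 2, which.max)
  expect_true(all(abs(sp$freq_hz[peak_bins] - 40) <= fs / sp$nfft))

  # zero trace -> zero power; shorter than a window -> failure
  expect_equal(max(spectrogram(rep(0, 500), fs)$power), 0)
  expect_error(spectrogram(rnorm(50), fs), "shorter")

  # Parseval: total power of one window equals N x tapered-segment energy
  set.seed(1)
  y <- rnorm(200)
  spy <- spectrogram(y, fs, step_ms = 1000)
  seg <- y[1:100]
  taper <- 0.5 * (1 - cos(2 * pi * (0:99) / 99))
  tapered <- (seg - mean(seg)) * taper
  # reassemble the two-sided spectrum from the stored half
  p_half <- spy$power[, 1, 1]
  total <- p_half[1] + p_half[513] + 2 * sum(p_half[2:512])
  expect_equal(total, 1024 * sum(tapered^2), tolerance = 1e-6)
})

test_that("white-noise spectra are flat and trial order does not matter", {
  set.seed(7)
  x <- matrix(rnorm(200 * 600), 200)
  sp <- spectrogram(x, 1000)
  mean_pow <- apply(sp$power, 1, mean)
  # flat above the demeaning roll-off (per-window mean removal attenuates
  # frequencies below the ~10 Hz window resolution)
  sel <- sp$freq_hz >= 15 & sp$freq_hz <= 100
  expect_lt(max(abs(mean_pow[sel] / mean(mean_pow[sel]) - 1)), 0.1)

  # band power is invariant under trial permutation
  t <- seq(-500, 499)
  xt <- matrix(rnorm(20 * 1000), 20)
  z1 <- induced_power_z(spectrogram(xt, 1000, time_ms = t))
  z2 <- induced_power_z(spectrogram(xt[sample(20), ], 1000, time_ms = t))
  expect_equal(gamma_band_amp_z(z1), gamma_band_amp_z(z2), tolerance = 1e-9)
})

test_that("iSP detects planted post-stimulus oscillations and only those", {
  t <- seq(-500, 499)
  set.seed(11)
  gamma40 <- function(amp) {
    x <- matrix(rnorm(40 * 1000), 40)
    osc <- amp * sin(2 * pi * 40 * t / 1000) * (t >= 100)
    sweep(x, 2, osc, `+`)
  }
  sp <- spectrogram(gamma40(1), 1000, time_ms = t)
  isp <- induced_power_z(sp)
  tsel <- isp$time_ms >= 200 & isp$time_ms <= 500
  band_z <- function(lo, hi, slot = "z") {
    mean(isp[[slot]][isp$freq_hz >= lo & isp$freq_hz <= hi, tsel])
  }
  expect_gt(band_z(35, 55), 3)
  # amplitude z is band-specific: nothing was planted in theta
  expect_gt(band_z(35, 55, "z_amp"), 3)
  expect_lt(abs(band_z(4, 8, "z_amp")), 1)

  # doubling the planted amplitude strictly increases the amplitude z
  isp2 <- induced_power_z(spectrogram(gamma40(2), 1000, time_ms = t))
  expect_gt(gamma_band_amp_z(isp2), gamma_band_amp_z(isp))

  # a band beyond the frequency grid fails loudly
  expect_error(band_power_profile(
    tibble::tibble(channel = 1, diameter_deg = 0.5, isp = list(isp)),
    bands = list(bad = c(600, 700))), "no frequency bins")
})

test_that("iSP of baseline-identical data is near-calibrated", {
  set.seed(5)
  frac <- c()
  for (rep in 1:6) {
    x <- matrix(rnorm(60 * 1000), 60)
    sp <- spectrogram(x, 1000, time_ms = seq(-500, 499))
    isp <- induced_power_z(sp)
    fsel <- which(isp$freq_hz >= 4 & isp$freq_hz <= 100)
    fsel <- fsel[seq(1, length(fsel), by = 10)]
    tsel <- which(isp$time_ms >= 0)
    tsel <- tsel[seq(1, length(tsel), by = 10)]
    frac <- c(frac, as.vector(abs(isp$z[fsel, tsel]) > 1.96))
  }
  expect_gt(mean(frac), 0.01)
  expect_lt(mean(frac), 0.10)
})

test_that("gamma peak frequency tracks a planted narrowband oscillation", {
  t <- seq(-500, 499)
  set.seed(13)
  mk_isp <- function(freq) {
    x <- matrix(rnorm(40 * 1000), 40)
    x <- sweep(x, 2, 3 * sin(2 * pi * freq * t / 1000) * (t >= 100), `+`)
    induced_power_z(spectrogram(x, 1000, time_ms = t))
  }
  expect_lt(abs(gamma_peak_frequency(mk_isp(42)) - 42), 2)

  # planted frequency decreasing with diameter: recovered decreasing
  freqs <- c(48, 42, 36)
  rec <- vapply(freqs, function(f) gamma_peak_frequency(mk_isp(f)), numeric(1))
  expect_true(all(diff(rec) < 0))

  # spectrum with no positive excursion in range: undefined
  null_isp <- induced_power_z(spectrogram(matrix(rnorm(10 * 1000), 10), 1000,
                                          time_ms = t))
  null_isp$z_amp[, ] <- -abs(null_isp$z_amp)
  expect_true(is.na(gamma_peak_frequency(null_isp)))
})
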