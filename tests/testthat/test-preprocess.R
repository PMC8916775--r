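# LFP/MUAe conditioning, epoching, bipolar referencing, baseline z-scoring.

raw_of <- function(x, fs = 8000) {
  session_recording(matrix(x, nrow = 1), fs,
                    tibble::tibble(onset_s = 1, diameter_deg = 1, trial_id = 1))
}

test_that("LFP extraction is zero-phase and band-limited", {
  fs <- 8000
  t <- (0:79999) / fs
  # 40 Hz in the pass band: amplitude within 1%, phase within 1 degree
  lfp <- extract_lfp(raw_of(sin(2 * pi * 40 * t)))
  mid <- 3000:7000
  tt <- (mid - 1) / 1000
  ref <- sin(2 * pi * 40 * tt)
  amp <- sd(lfp$samples[1, mid]) * sqrt(2)
  expect_lt(abs(amp - 1), 0.01)
  phase_err <- acos(min(1, cor(lfp$samples[1, mid], ref))) * 180 / pi
  expect_lt(phase_err, 1)

  # 5 kHz at 32 kHz raw: crushed by the 300 Hz corner
  t32 <- (0:159999) / 32000
  hf <- extract_lfp(raw_of(sin(2 * pi * 5000 * t32), fs = 32000))
  expect_lt(sd(hf$samples[1, 1000:4000]) / (1 / sqrt(2)), 0.01)

  # zero in, zero out; exact linearity
  expect_equal(max(abs(extract_lfp(raw_of(rep(0, 16000)))$samples)), 0)
  x <- rnorm(16000); y <- rnorm(16000)
  lx <- extract_lfp(raw_of(x))$samples
  ly <- extract_lfp(raw_of(y))$samples
  lxy <- extract_lfp(raw_of(2 * x - 0.5 * y))$samples
  # the 0.75 Hz high-pass poles sit near the unit circle, which amplifies
  # floating-point rounding; linearity holds to ~1e-7 relative
  expect_equal(lxy, 2 * lx - 0.5 * ly, tolerance = 1e-6)

  # non-integer decimation factor is refused with a suggestion
  expect_error(extract_lfp(raw_of(rnorm(16000)), fs_target_hz = 900),
               "integer divisor")
})

test_that("MUAe is a rectified band-limited envelope tracking amplitude", {
  fs <- 8000
  expect_equal(max(abs(extract_muae(raw_of(rep(0, 16000)))$samples)), 0)

  # amplitude step x2: envelope means scale by ~2 (1 s segments)
  set.seed(1)
  noise <- rnorm(fs * 3)
  noise <- c(noise[1:(2 * fs)], 2 * noise[(2 * fs + 1):(3 * fs)])
  mu <- extract_muae(raw_of(noise))$samples[1, ]
  before <- mean(mu[500:1900]); after <- mean(mu[2100:2900])
  expect_lt(abs(after / before - 2), 0.2)
  expect_true(all(mu >= 0))

  # content below the multi-unit band is rejected
  t <- (0:23999) / fs
  lowf <- extract_muae(raw_of(sin(2 * pi * 10 * t)))$samples[1, 500:2500]
  expect_lt(sqrt(mean(lowf^2)) / sqrt(mean(abs(sin(2 * pi * 10 * t))^2)), 0.02)

  # raw rate must support the band
  expect_error(extract_muae(raw_of(rnorm(4000), fs = 1000)),
               "does not support")
})

test_that("epoching follows the half-open window convention and drops edge trials", {
  fs <- 1000
  cont <- list(samples = matrix(rnorm(2 * 10000), 2), fs_hz = fs)
  ev <- tibble::tibble(onset_s = c(1, 3, 5), diameter_deg = c(0.5, 15, 0.5),
                       trial_id = 1:3)
  ep <- epoch_trials(cont, ev, c(-500, 500))
  expect_equal(dim(ep$data), c(3, 2, 1000))
  expect_equal(ep$time_ms[1], -500)
  expect_equal(ep$time_ms[1000], 499)
  expect_equal(ep$condition, c(0.5, 15, 0.5))

  # epoch content equals the corresponding continuous slice
  expect_equal(ep$data[2, 1, ], cont$samples[1, 2501:3500])

  # event 10 ms from the end: dropped with a warning, count decremented
  ev2 <- tibble::tibble(onset_s = c(1, 9.99), diameter_deg = c(1, 2),
                        trial_id = 1:2)
  expect_warning(ep2 <- epoch_trials(cont, ev2), "dropping 1")
  expect_equal(dim(ep2$data)[1], 1)
})

test_that("bipolar referencing is the centered difference and rejects common mode", {
  t_ms <- seq(-500, 499)
  # identical signal on all channels vanishes
  common <- make_epoched(function(tr, ch, t) sin(2 * pi * 10 * t / 1000),
                         n_channels = 5, kind = "LFP")
  bp <- bipolar_reference(common)
  expect_equal(max(abs(bp$data)), 0)
  expect_equal(bp$kind, "LFPbp")
  expect_equal(bp$usable, c(FALSE, TRUE, TRUE, TRUE, FALSE))

  # potential linear in depth with slope s per contact -> constant -2s
  s <- 3.5
  lin <- make_epoched(function(tr, ch, t) s * ch, n_channels = 6, kind = "LFP")
  bpl <- bipolar_reference(lin)
  expect_true(all(abs(bpl$data[, 2:5, ] + 2 * s) < 1e-12))

  # single-channel deflection appears only at the flanking contacts
  single <- make_epoched(function(tr, ch, t) if (ch == 3) dnorm(t, 0, 50) else 0,
                         n_channels = 5, kind = "LFP")
  bps <- bipolar_reference(single)
  expect_equal(max(abs(bps$data[, c(3), ])), 0)
  expect_equal(bps$data[1, 2, ], -bps$data[1, 4, ])
  expect_gt(max(abs(bps$data[1, 2, ])), 0)

  # invariance to adding any channel-independent signal
  set.seed(2)
  base <- make_epoched(function(tr, ch, t) rnorm(length(t)), n_channels = 4,
                       kind = "LFP")
  shared <- rnorm(1000)
  shifted <- base
  for (ch in 1:4) shifted$data[1, ch, ] <- shifted$data[1, ch, ] + shared
  expect_equal(bipolar_reference(base)$data, bipolar_reference(shifted)$data,
               tolerance = 1e-12)

  # successive-pair variant and the channel-count guard
  bps2 <- bipolar_reference(lin, method = "successive")
  expect_true(all(abs(bps2$data[, 1:5, ] + s) < 1e-12))
  two <- make_epoched(function(tr, ch, t) 0, n_channels = 2, kind = "LFP")
  expect_error(bipolar_reference(two), "at least 3")
})

test_that("baseline z-scoring matches its definition and flags degenerate input", {
  t_ms <- seq(-500, 499)
  set.seed(3)
  ep <- make_epoched(function(tr, ch, t) rnorm(length(t), mean = 2, sd = 1),
                     n_trials = 50, n_channels = 2, kind = "MUAe")
  z <- zscore_to_baseline(ep)
  sel <- z$time_ms >= -300 & z$time_ms < 0
  expect_lt(abs(mean(z$data[, 1, sel])), 1e-10)
  expect_equal(sd(as.vector(z$data[, 1, sel])), 1, tolerance = 1e-10)
  expect_equal(z$units, "z")

  # a sample 3 baseline SDs above the baseline mean scores z = 3
  bl <- ep$data[, 2, sel]
  target <- mean(bl) + 3 * sd(as.vector(bl))
  ep2 <- ep; ep2$data[1, 2, 900] <- target
  z2 <- zscore_to_baseline(ep2)
  expect_equal(z2$data[1, 2, 900], 3, tolerance = 1e-6)

  # trace equal to its baseline mean everywhere -> z identically 0 elsewhere
  flat <- ep
  flat$data[, 1, ] <- mean(ep$data[, 1, sel])
  # channel 1 now has zero baseline variance: explicit failure naming it
  expect_error(zscore_to_baseline(flat), "channel 1")
})
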