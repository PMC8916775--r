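# Synthetic session generator and its ground truth.

test_that("configuration invariants are enforced", {
  expect_error(synth_config(sink_channel = 0), "sink_channel")
  expect_error(synth_config(sink_peak_ms = 80), "35, 55")
  expect_error(synth_config(fs_raw_hz = 1000), "MUA band")
  # the multi-unit band scales with the raw rate
  expect_equal(synth_config(fs_raw_hz = 2000)$mua_band, c(600, 900))
  expect_equal(synth_config(fs_raw_hz = 32000)$mua_band, c(600, 9000))
  expect_error(synth_config(fs_target_hz = 900), "integer divisor")
  expect_error(synth_config(coupling_spec = list(
    list(source = 3, target = 5, band = c(35, 55), strength = .5, lag_ms = -2))),
    "positive")
  expect_error(synth_config(coupling_spec = list(
    list(source = 3, target = 5, band = c(35, 55), strength = .5, lag_ms = 2),
    list(source = 5, target = 3, band = c(35, 55), strength = .5, lag_ms = 2))),
    "cycle")
  expect_error(synth_config(coupling_spec = list(
    list(source = 3, target = 5, band = c(400, 600), strength = .5, lag_ms = 2))),
    "fs_target")
})

test_that("generation is deterministic and lays out the stimulus protocol", {
  cfg <- synth_config(n_trials_per_condition = 1, seed = 99)
  g1 <- generate_session(cfg)
  g2 <- generate_session(cfg)
  expect_identical(g1$session$samples, g2$session$samples)
  expect_identical(g1$session$events, g2$session$events)

  ev <- g1$session$events
  expect_equal(nrow(ev), 6)          # 1 trial x 6 diameters
  expect_setequal(ev$diameter_deg, c(0.5, 0.75, 1.5, 3, 7, 15))
  expect_true(all(diff(ev$onset_s) > 0))
  expect_equal(unique(diff(ev$onset_s)), 1)  # 500 ms blank + 500 ms stimulus

  cfg3 <- synth_config(n_trials_per_condition = 3, seed = 99)
  expect_equal(nrow(generate_session(cfg3)$session$events), 18)
})

test_that("planted coupling shows as a lagged cross-correlation of the latents", {
  cfg <- synth_config(seed = 5)
  osc <- simulate_coupled_oscillations(cfg, n_samples = 32000)
  fs <- cfg$fs_raw_hz
  lag_n <- round(5 * fs / 1000)
  src <- osc$latents["11@35-55", ]
  tgt <- osc$latents["13@35-55", ]
  cc <- ccf(tgt, src, lag.max = 2 * lag_n, plot = FALSE)
  best <- cc$lag[which.max(abs(cc$acf))]
  expect_lte(abs(best - lag_n), 1)  # target trails source by the planted lag
})

test_that("common-noise mixing is instantaneous and symmetric in time", {
  cfg <- synth_config(seed = 6, coupling_spec = list(),
                      gamma_by_diameter = NULL, common_noise_gain = 1)
  osc <- simulate_coupled_oscillations(cfg, n_samples = 16000)
  x <- osc$channel_contribution[2, ]
  y <- osc$channel_contribution[9, ]
  expect_gt(cor(x, y), 0.5)
  cc <- ccf(x, y, lag.max = 80, plot = FALSE)
  best <- cc$lag[which.max(abs(cc$acf))]
  expect_lte(abs(best), 1)          # no lagged asymmetry
  expect_length(osc$mixing_weights, 16)
})

test_that("uncoupled channels stay incoherent in the analysis bands", {
  ss <- small_session()
  # channels 2 and 15 carry no planted oscillation source
  seg <- function(ch) gc_segment(ss$lfp_ep, ch, start_ms = 200, n_bins = 256)
  X <- t(apply(seg(2), 1, function(v) fft((v - mean(v)) * hanning_win(256))))
  Y <- t(apply(seg(15), 1, function(v) fft((v - mean(v)) * hanning_win(256))))
  f <- (0:255) * 1000 / 256
  sel <- f >= 4 & f <= 55
  coh <- abs(colMeans(X * Conj(Y)))^2 /
    (colMeans(abs(X)^2) * colMeans(abs(Y)^2))
  expect_lt(mean(coh[sel]), 0.1)
})

test_that("the MUA carrier is silent without rate modulation and tracks R(t) with it", {
  zero_rate <- list(peak_z = 0, mu1_ms = 50, sigma1_ms = 10,
                    suppression = 0, latency_shift_ms = 0)
  cfg <- synth_config(n_trials_per_condition = 1,
                      latency_params_by_layer = list(
                        supragranular = zero_rate, granular = zero_rate,
                        infragranular = zero_rate),
                      seed = 7)
  ev <- tibble::tibble(onset_s = c(1, 2.5), diameter_deg = c(0.5, 15),
                       trial_id = 1:2)
  mua <- simulate_mua_carrier(cfg, ev, n_samples = 4 * cfg$fs_raw_hz)
  expect_true(all(is.na(mua$true_latency$latency_ms)))
  raw <- session_recording(mua$samples, cfg$fs_raw_hz, ev)
  ep <- epoch_trials(extract_muae(raw), ev, kind = "MUAe")
  z <- zscore_to_baseline(ep)
  post <- z$time_ms >= 0
  expect_lt(abs(mean(z$data[, 8, post])), 0.5)
})

test_that("ground-truth latency is the dense-grid crossing of the noiseless profile", {
  cfg <- synth_config(seed = 1)
  par <- synth_rate_params(cfg, 8, 0.5)
  tg <- seq(0, 200, by = 0.1)
  manual <- tg[which(transient_model(tg, par) > 3)[1]]
  expect_identical(true_latency_from_params(par), manual)
  # latency grows with stimulus size as configured
  lat <- vapply(cfg$diameters_deg, function(d)
    true_latency_from_params(synth_rate_params(cfg, 8, d)), numeric(1))
  expect_true(all(diff(lat) > 0))
})

test_that("the default session passes QC with the sink where it was planted", {
  ss <- small_session()
  csd <- compute_icsd(trial_average(ss$lfp_ep), time_ms = ss$lfp_ep$time_ms)
  qc <- qc_session(csd)
  expect_true(qc$pass)
  expect_equal(qc$alignment$channel, ss$gen$ground_truth$sink_channel)
  expect_gte(qc$alignment$peak_ms, 35)
  expect_lte(qc$alignment$peak_ms, 50)
})

test_that("clean bipolar representatives avoid other oscillation carriers", {
  ss <- small_session()
  pairs <- planted_gc_pairs(ss$gen$ground_truth)
  expect_equal(nrow(pairs), 2)
  carriers <- c(ss$gen$ground_truth$osc_channels,
                ss$gen$ground_truth$sink_channel)
  for (k in seq_len(nrow(pairs))) {
    for (bpch in c(pairs$source_bp[k], pairs$target_bp[k])) {
      touched <- c(bpch - 1L, bpch + 1L)
      own <- c(pairs$source[k], pairs$target[k])
      expect_length(setdiff(intersect(touched, carriers), own), 0)
    }
  }
})
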