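# Synthetic laminar sessions with full ground truth.

#' Construct a raw session recording
#'
#' @param samples channels x time matrix, microvolts, channels ordered top to
#'   bottom.
#' @param fs_hz raw sampling rate.
#' @param events tibble with `onset_s`, `diameter_deg`, `trial_id` (onsets
#'   strictly increasing).
#' @param spacing_um contact spacing.
#' @return object of class `session_recording`.
#' @export
session_recording <- function(samples, fs_hz, events, spacing_um = 150) {
  if (is.unsorted(events$onset_s, strictly = TRUE)) {
    abort("event onsets must be strictly increasing")
  }
  structure(list(samples = samples, fs_hz = fs_hz,
                 events = as_tibble(events), spacing_um = spacing_um,
                 channel_order = "top-to-bottom"),
            class = "session_recording")
}

#' @export
print.session_recording <- function(x, ...) {
  cat(sprintf("<session_recording> %d channels x %d samples @ %g Hz (%.1f s), %d events, %g um spacing\n",
              nrow(x$samples), ncol(x$samples), x$fs_hz,
              ncol(x$samples) / x$fs_hz, nrow(x$events), x$spacing_um))
  invisible(x)
}

# AR(2) resonator innovations-to-signal recursion: poles at r exp(+-i w0).
ar2_oscillation <- function(n, f0_hz, bw_hz, fs_hz) {
  r <- exp(-pi * bw_hz / fs_hz)
  w0 <- 2 * pi * f0_hz / fs_hz
  a <- c(2 * r * cos(w0), -r^2)
  x <- as.numeric(stats::filter(rnorm(n + 200L), a, method = "recursive"))
  x <- x[-(1:200)]
  x / sd(x)
}

#' Simulate the coupled band-limited oscillation network
#'
#' Latent sources are stable AR(2) resonators (band-shaped spectra); each
#' directed edge adds a lagged, scaled copy of the source latent to the
#' target latent (a lagged-oscillator network, acyclic within each band, so
#' stability follows from the resonators' poles). Each latent is injected
#' into its channel; an optional shared broadband source is mixed into all
#' channels with channel-specific weights (the common-noise scenario that
#' the reversal test must reject).
#'
#' @param config a [synth_config()].
#' @param n_samples samples to generate at `fs_raw_hz`.
#' @param seed seed (defaults to the config seed).
#' @return list: `latents` (node x time, unit variance before coupling),
#'   `nodes` tibble (channel, band_lo, band_hi), `channel_contribution`
#'   (channels x time, microvolts, oscillations only), `common_source`
#'   (time vector or NULL), `mixing_weights` (per channel),
#'   `adjacency` tibble (source, target, band, strength, lag_ms).
#' @export
simulate_coupled_oscillations <- function(config, n_samples,
                                          seed = config$seed) {
  stopifnot(inherits(config, "synth_config"))
  fs <- config$fs_raw_hz
  node_id <- function(ch, band) sprintf("%d@%g-%g", ch, band[1], band[2])
  order <- coupling_topo_order(config$coupling_spec)
  contribution <- matrix(0, config$n_channels, n_samples)
  latents <- NULL
  nodes <- NULL
  if (length(order)) {
    parse_node <- function(id) {
      m <- regmatches(id, regexec("^(\\d+)@([0-9.]+)-([0-9.]+)$", id))[[1]]
      list(channel = as.integer(m[2]), band = c(as.numeric(m[3]), as.numeric(m[4])))
    }
    lat <- matrix(0, length(order), n_samples,
                  dimnames = list(order, NULL))
    with_stream(seed, "oscillations", {
      for (id in order) {
        nd <- parse_node(id)
        x <- ar2_oscillation(n_samples, mean(nd$band), diff(nd$band), fs)
        for (e in config$coupling_spec) {
          if (node_id(e$target, e$band) != id) next
          lagn <- round(e$lag_ms * fs / 1000)
          src <- lat[node_id(e$source, e$band), ]
          x <- x + e$strength * c(rep(0, lagn), src[seq_len(n_samples - lagn)])
        }
        lat[id, ] <- x
      }
      # band-limit each latent with a zero-phase pass of its own band: the
      # filter is linear and time-invariant, so the planted lag structure is
      # preserved exactly while the resonator skirts outside the band vanish
      for (id in order) {
        nd <- parse_node(id)
        f <- butter_zerophase(lat[id, ], fs, low = nd$band[1],
                              high = nd$band[2], pad_s = 0.25)
        lat[id, ] <- f / sd(f)
      }
    })
    latents <- lat
    nodes <- purrr::map_dfr(order, function(id) {
      nd <- parse_node(id)
      tibble(node = id, channel = nd$channel,
             band_lo = nd$band[1], band_hi = nd$band[2])
    })
    for (k in seq_len(nrow(nodes))) {
      contribution[nodes$channel[k], ] <-
        contribution[nodes$channel[k], ] + config$osc_amplitude_uv * lat[k, ]
    }
  }
  common_source <- NULL
  mixing <- rep(0, config$n_channels)
  if (config$common_noise_gain > 0) {
    cn <- with_stream(seed, "common-noise", {
      src <- butter_zerophase(rnorm(n_samples), fs, high = 150)
      # fixed, channel-dependent weights so bipolar referencing does not
      # cancel the shared source exactly
      list(source = src / sd(src),
           mixing = 0.6 + 0.8 * runif(config$n_channels))
    })
    common_source <- cn$source
    mixing <- cn$mixing
    contribution <- contribution + config$common_noise_gain *
      config$osc_amplitude_uv * (mixing %o% common_source)
  }
  adjacency <- purrr::map_dfr(config$coupling_spec, function(e) {
    tibble(source = e$source, target = e$target,
           band_lo = e$band[1], band_hi = e$band[2],
           strength = e$strength, lag_ms = e$lag_ms)
  })
  list(latents = latents, nodes = nodes, channel_contribution = contribution,
       common_source = common_source, mixing_weights = mixing,
       adjacency = adjacency)
}

#' Simulate the amplitude-modulated multi-unit carrier
#'
#' Broadband noise in the multi-unit band whose amplitude envelope follows
#' the planted per-channel, per-condition rate profile R(t). The envelope is
#' calibrated empirically so that the MUAe extracted by the package's own
#' filter chain, z-scored against the pre-stimulus baseline, has expectation
#' ~R(t) in z units: a baseline-only carrier stretch is run through
#' [extract_muae()] once to measure the baseline mean and single-sample SD,
#' and the modulation gain is their ratio.
#'
#' @param config a [synth_config()].
#' @param events event table (from [generate_session()]'s schedule).
#' @param n_samples total samples at `fs_raw_hz`.
#' @param seed seed (defaults to the config seed).
#' @return list: `samples` (channels x time, microvolts),
#'   `true_latency` tibble (channel, diameter_deg, latency_ms from the
#'   noiseless profile on a 0.1 ms grid), `calibration` (baseline mean/SD).
#' @export
simulate_mua_carrier <- function(config, events, n_samples,
                                 seed = config$seed) {
  stopifnot(inherits(config, "synth_config"))
  fs <- config$fs_raw_hz
  calib <- muae_calibration(config, seed)
  rho <- calib$sd / calib$mean   # modulation per z unit

  # per-channel x condition rate profiles over the stimulus epoch
  prof_t <- seq(0, 500 - 1000 / fs, by = 1000 / fs)
  envelope <- matrix(1, config$n_channels, n_samples)
  for (cond in config$diameters_deg) {
    onsets <- events$onset_s[events$diameter_deg == cond]
    for (ch in seq_len(config$n_channels)) {
      r <- transient_model(prof_t, synth_rate_params(config, ch, cond))
      gain <- pmax(1 + rho * r, 0.05)
      for (on in onsets) {
        i0 <- round(on * fs) + 1L
        idx <- i0:(i0 + length(gain) - 1L)
        envelope[ch, idx] <- gain
      }
    }
  }
  samples <- with_stream(seed, "mua-carrier", {
    out <- matrix(0, config$n_channels, n_samples)
    for (ch in seq_len(config$n_channels)) {
      carrier <- butter_zerophase(rnorm(n_samples), fs,
                                  low = config$mua_band[1],
                                  high = config$mua_band[2], pad_s = 0.1)
      out[ch, ] <- config$mua_amplitude_uv * carrier * envelope[ch, ]
    }
    out
  })
  true_latency <- tidyr::expand_grid(channel = seq_len(config$n_channels),
                                     diameter_deg = config$diameters_deg) |>
    dplyr::mutate(latency_ms = purrr::map2_dbl(
      .data$channel, .data$diameter_deg,
      function(ch, d) true_latency_from_params(synth_rate_params(config, ch, d))))
  list(samples = samples, true_latency = true_latency, calibration = calib)
}

# Baseline statistics of the processed MUAe for an unmodulated carrier:
# one channel-equivalent calibration stretch through the package's own
# MUAe chain. Deterministic given the seed.
muae_calibration <- function(config, seed = config$seed) {
  fs <- config$fs_raw_hz
  n <- round(20 * fs)  # 20 s calibration stretch
  x <- with_stream(seed, "mua-calibration", {
    config$mua_amplitude_uv *
      butter_zerophase(rnorm(n), fs, low = config$mua_band[1],
                       high = config$mua_band[2], pad_s = 0.1)
  })
  raw <- session_recording(matrix(x, nrow = 1L), fs,
                           tibble(onset_s = 1, diameter_deg = NA_real_,
                                  trial_id = 1L),
                           config$spacing_um)
  mu <- extract_muae(raw, config$fs_target_hz, config$mua_band)
  v <- mu$samples[1L, -seq_len(config$fs_target_hz)]  # drop first second
  list(mean = mean(v), sd = sd(v))
}

# Sink-positive, charge-balanced CSD template and the matching potentials.
# Spatial profile: depth Gaussian centered on the sink channel, mean-removed
# per column so current is conserved; temporal profile: Gaussian at the sink
# peak time. Scaled so the evoked potential peaks at vep_peak_uv.
synth_csd_template <- function(config) {
  t_ms <- seq(0, 150, by = 1000 / config$fs_raw_hz)
  w <- dnorm(seq_len(config$n_channels), config$sink_channel, 0.8)
  w <- w - mean(w)
  w <- w / max(w)
  g <- dnorm(t_ms, config$sink_peak_ms, 8)
  g <- g / max(g)
  csd <- w %o% g
  phi <- forward_potentials_from_csd(csd, spacing_um = config$spacing_um)
  scale <- config$vep_peak_uv / max(abs(phi))
  list(csd = csd * scale, phi = phi * scale, time_ms = t_ms)
}

#' Generate a complete synthetic session with ground truth
#'
#' Composes the evoked-potential forward model, the coupled-oscillation
#' network, the modulated multi-unit carrier and background LFP-band noise
#' into one continuous raw recording: trials of 500 ms blank + 500 ms
#' stimulus at six diameters in randomized order, padded by 1 s at both
#' ends. Deterministic for a fixed config seed.
#'
#' @param config a [synth_config()].
#' @return list with `session` (a [session_recording()]) and `ground_truth`
#'   (class `ground_truth`): `true_csd` (channels x time template and
#'   per-diameter scale), `true_latency_ms`, `coupling_adjacency`,
#'   `true_phase_lag_ms`, `mixing_weights`, `sink_channel`, `sink_peak_ms`,
#'   `osc_channels`, `gamma_by_diameter`, `seed`.
#' @export
generate_session <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  fs <- config$fs_raw_hz
  n_trials <- config$n_trials_per_condition * length(config$diameters_deg)
  trial_s <- 1.0        # 500 ms blank + 500 ms stimulus
  pad_s <- 1.0
  total_s <- 2 * pad_s + n_trials * trial_s
  n_samples <- round(total_s * fs)

  conds <- with_stream(config$seed, "schedule", {
    sample(rep(config$diameters_deg, config$n_trials_per_condition))
  })
  events <- tibble(
    onset_s = pad_s + (seq_len(n_trials) - 1L) * trial_s + 0.5,
    diameter_deg = conds,
    trial_id = seq_len(n_trials))

  # background LFP-band noise (independent per channel, < 300 Hz)
  samples <- with_stream(config$seed, "background", {
    out <- matrix(0, config$n_channels, n_samples)
    for (ch in seq_len(config$n_channels)) {
      out[ch, ] <- config$noise_uv *
        butter_zerophase(rnorm(n_samples), fs, high = 300, pad_s = 0.1)
    }
    out
  })

  # evoked potentials from the planted CSD, attenuated with stimulus size
  tmpl <- synth_csd_template(config)
  nk <- max(length(config$diameters_deg) - 1L, 1L)
  csd_scale <- 1 - 0.25 * (seq_along(config$diameters_deg) - 1L) / nk
  names(csd_scale) <- as.character(config$diameters_deg)
  for (k in seq_len(n_trials)) {
    i0 <- round(events$onset_s[k] * fs) + 1L
    idx <- i0:(i0 + ncol(tmpl$phi) - 1L)
    sc <- csd_scale[[as.character(events$diameter_deg[k])]]
    samples[, idx] <- samples[, idx] + sc * tmpl$phi
  }

  # sustained-period gating envelope for oscillatory components
  env <- numeric(n_samples)
  t_rel <- seq(0, trial_s * 1000 - 1000 / fs, by = 1000 / fs) - 500  # ms from onset
  ramp <- pmin(pmax((t_rel - 100) / 100, 0), 1) * (t_rel <= 500) *
    pmin(pmax((520 - t_rel) / 20, 0), 1)
  for (k in seq_len(n_trials)) {
    i0 <- round((events$onset_s[k] - 0.5) * fs) + 1L
    env[i0:(i0 + length(ramp) - 1L)] <- ramp
  }

  osc <- simulate_coupled_oscillations(config, n_samples)
  samples <- samples + sweep(osc$channel_contribution, 2L, env, `*`)

  # size-dependent narrowband gamma at the sink channel
  if (!is.null(config$gamma_by_diameter)) {
    with_stream(config$seed, "gamma-peak", {
      for (ci in seq_along(config$diameters_deg)) {
        cond <- config$diameters_deg[ci]
        x <- config$osc_amplitude_uv *
          config$gamma_by_diameter$rel_amplitude[ci] *
          ar2_oscillation(n_samples, config$gamma_by_diameter$freq_hz[ci],
                          10, fs)
        gate <- numeric(n_samples)
        for (on in events$onset_s[events$diameter_deg == cond]) {
          i0 <- round((on - 0.5) * fs) + 1L
          gate[i0:(i0 + length(ramp) - 1L)] <- ramp
        }
        samples[config$sink_channel, ] <- samples[config$sink_channel, ] +
          x * gate
      }
    })
  }

  mua <- simulate_mua_carrier(config, events, n_samples)
  samples <- samples + mua$samples

  session <- session_recording(samples, fs, events, config$spacing_um)
  ground_truth <- structure(list(
    true_csd = list(template = tmpl$csd, time_ms = tmpl$time_ms,
                    scale_by_diameter = csd_scale),
    true_latency_ms = mua$true_latency,
    coupling_adjacency = osc$adjacency,
    true_phase_lag_ms = if (nrow(osc$adjacency)) {
      dplyr::mutate(osc$adjacency, phase_lag_ms = .data$lag_ms)
    } else {
      osc$adjacency
    },
    mixing_weights = osc$mixing_weights,
    sink_channel = config$sink_channel,
    sink_peak_ms = config$sink_peak_ms,
    osc_channels = if (is.null(osc$nodes)) integer() else unique(osc$nodes$channel),
    gamma_by_diameter = config$gamma_by_diameter,
    muae_calibration = mua$calibration,
    seed = config$seed), class = "ground_truth")
  list(session = session, ground_truth = ground_truth)
}

#' Bipolar channel pairs for evaluating planted directed coupling
#'
#' A latent oscillation injected on LFP channel `c` appears on bipolar
#' contacts `c - 1` and `c + 1` (with opposite signs); evaluating the
#' recovered Granger direction of a planted edge therefore needs one
#' bipolar representative per endpoint. For each edge this helper picks the
#' flanking bipolar contact whose stencil does not touch any *other*
#' oscillation-carrying channel, so the representative carries the
#' endpoint's latent and nothing else that is phase-structured.
#'
#' @param ground_truth a `ground_truth` from [generate_session()].
#' @param n_channels probe size (default 16).
#' @return tibble: source, target, source_bp, target_bp, band_lo, band_hi,
#'   strength, lag_ms.
#' @export
planted_gc_pairs <- function(ground_truth, n_channels = 16) {
  adj <- ground_truth$coupling_adjacency
  if (!nrow(adj)) return(adj)
  carriers <- unique(c(ground_truth$osc_channels,
                       if (!is.null(ground_truth$gamma_by_diameter))
                         ground_truth$sink_channel))
  pick_bp <- function(ch) {
    others <- setdiff(carriers, ch)
    for (cand in c(ch - 1L, ch + 1L)) {
      if (cand <= 1L || cand >= n_channels) next  # bipolar end contacts unusable
      if (!any(c(cand - 1L, cand + 1L) %in% others)) return(cand)
    }
    NA_integer_
  }
  adj$source_bp <- vapply(adj$source, pick_bp, integer(1))
  adj$target_bp <- vapply(adj$target, pick_bp, integer(1))
  adj
}

#' Evaluate recovery of the planted directed coupling from a session
#'
#' Validation utility: extracts the LFP of the channels flanking each
#' planted edge's bipolar representatives (see [planted_gc_pairs()]), forms
#' the bipolar series, and runs the band-integrated Granger analysis with
#' the time-reversal control on each planted edge. An edge is recovered
#' when the net GC in the planted band is positive from source to target.
#'
#' @param gen a list from [generate_session()].
#' @param condition stimulus diameter to analyze (default: the largest).
#' @param order,n_bins,n_boot Granger settings (see [fit_var_pair()],
#'   [reverse_granger_test()]).
#' @param seed seed for the reversal-test null.
#' @return [planted_gc_pairs()] tibble with `net`, `rgt_pass`, `correct`.
#' @export
evaluate_gc_direction_recovery <- function(gen, condition = NULL, order = 50,
                                           n_bins = 256, n_boot = 9,
                                           seed = 1) {
  gt <- gen$ground_truth
  n_ch <- nrow(gen$session$samples)
  pairs <- planted_gc_pairs(gt, n_channels = n_ch)
  if (!nrow(pairs)) abort("session has no planted coupling to recover")
  need <- sort(unique(c(pairs$source_bp - 1L, pairs$source_bp + 1L,
                        pairs$target_bp - 1L, pairs$target_bp + 1L)))
  sub <- gen$session
  sub$samples <- gen$session$samples[need, , drop = FALSE]
  lfp <- extract_lfp(sub)
  ep <- epoch_trials(lfp, gen$session$events, kind = "LFP")
  condition <- condition %||% max(gen$session$events$diameter_deg)
  bp_series <- function(bp_ch) {
    up <- match(bp_ch - 1L, need)
    dn <- match(bp_ch + 1L, need)
    gc_segment(ep, up, condition = condition, n_bins = n_bins) -
      gc_segment(ep, dn, condition = condition, n_bins = n_bins)
  }
  pairs$net <- NA_real_
  pairs$rgt_pass <- NA
  for (k in seq_len(nrow(pairs))) {
    band <- c(pairs$band_lo[k], pairs$band_hi[k])
    rgt <- reverse_granger_test(bp_series(pairs$source_bp[k]),
                                bp_series(pairs$target_bp[k]),
                                band, order = order, fs_hz = ep$fs_hz,
                                n_boot = n_boot, seed = seed + k)
    pairs$net[k] <- rgt$net
    pairs$rgt_pass[k] <- rgt$pass
  }
  pairs$correct <- pairs$net > 0
  pairs
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> sink ch %d @ %g ms, %d coupling edge(s), seed %d\n",
              x$sink_channel, x$sink_peak_ms, nrow(x$coupling_adjacency),
              x$seed))
  invisible(x)
}
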