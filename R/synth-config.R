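# Configuration and validation for the synthetic laminar-session generator.

#' Configuration for the synthetic laminar-session generator
#'
#' Defines the study conditions the generator emulates: a 16-contact probe
#' at 150 um spacing, trials of 500 ms blank followed by 500 ms of a grating
#' at one of six diameters, an early layer-4c current sink, per-layer MUAe
#' latencies with surround suppression, band-limited oscillations with
#' directed cross-layer coupling, and an optional instantaneously mixed
#' common-noise source for reversal testing. The default raw rate is 8 kHz
#' (the acquisition-equivalent 32 kHz is available by configuration; the
#' multi-unit band scales with the raw rate, see [extract_muae()]).
#'
#' @param n_channels contacts, top to bottom (default 16).
#' @param spacing_um inter-contact spacing (default 150).
#' @param fs_raw_hz raw sampling rate, Hz (default 8000, up to 32000).
#' @param fs_target_hz analysis rate after decimation (default 1000).
#' @param n_trials_per_condition trials per grating diameter (default 20).
#' @param diameters_deg grating diameters, degrees.
#' @param sink_channel channel carrying the early current sink (1-based from
#'   the top, default 8).
#' @param sink_peak_ms sink peak time, ms in `[35, 55]` (default 45).
#' @param vep_peak_uv peak amplitude of the evoked potential (default 150).
#' @param coupling_spec list of directed edges, each a list with `source`,
#'   `target` (channel indices), `band` (Hz pair), `strength` (relative to a
#'   unit-variance latent) and `lag_ms` (> 0). Default: gamma-band routing
#'   layer 5 (ch 11, -450 um) -> layer 6 (ch 13, -750 um) -> supragranular
#'   (ch 5, +450 um), 5 ms lags.
#'   Must be acyclic within each band.
#' @param osc_amplitude_uv oscillation amplitude on the mixed channels
#'   (default 30).
#' @param gamma_by_diameter optional planted narrowband oscillator at the
#'   sink channel whose peak frequency falls and amplitude grows with
#'   stimulus size: list with `freq_hz` and `rel_amplitude` per diameter, or
#'   `NULL` to disable.
#' @param common_noise_gain gain of the instantaneously mixed shared noise
#'   source, in units of `osc_amplitude_uv` (default 0).
#' @param noise_uv per-channel background LFP-band noise SD (default 15).
#' @param mua_amplitude_uv baseline multi-unit carrier SD (default 20).
#' @param latency_params_by_layer list with entries `supragranular`,
#'   `granular`, `infragranular`, each a list with `peak_z`, `mu1_ms`,
#'   `sigma1_ms`, `suppression` (fractional amplitude loss at the largest
#'   size) and `latency_shift_ms` (latency increase from smallest to largest
#'   size).
#' @param seed master seed; every internal stream derives from it.
#' @return validated list of class `synth_config`.
#' @export
synth_config <- function(n_channels = 16,
                         spacing_um = 150,
                         fs_raw_hz = 8000,
                         fs_target_hz = 1000,
                         n_trials_per_condition = 20,
                         diameters_deg = c(0.5, 0.75, 1.5, 3.0, 7.0, 15.0),
                         sink_channel = 8,
                         sink_peak_ms = 45,
                         vep_peak_uv = 150,
                         coupling_spec = default_coupling_spec(),
                         osc_amplitude_uv = 30,
                         gamma_by_diameter = default_gamma_by_diameter(diameters_deg),
                         common_noise_gain = 0,
                         noise_uv = 15,
                         mua_amplitude_uv = 20,
                         latency_params_by_layer = default_latency_params(),
                         seed = 1) {
  cfg <- list(
    n_channels = as.integer(n_channels), spacing_um = spacing_um,
    fs_raw_hz = fs_raw_hz, fs_target_hz = fs_target_hz,
    n_trials_per_condition = as.integer(n_trials_per_condition),
    diameters_deg = diameters_deg, sink_channel = as.integer(sink_channel),
    sink_peak_ms = sink_peak_ms, vep_peak_uv = vep_peak_uv,
    coupling_spec = coupling_spec, osc_amplitude_uv = osc_amplitude_uv,
    gamma_by_diameter = gamma_by_diameter,
    common_noise_gain = common_noise_gain, noise_uv = noise_uv,
    mua_amplitude_uv = mua_amplitude_uv,
    latency_params_by_layer = latency_params_by_layer,
    mua_band = c(600, min(9000, 0.45 * fs_raw_hz)),
    seed = as.integer(seed))
  class(cfg) <- "synth_config"
  validate_synth_config(cfg)
}

default_coupling_spec <- function() {
  list(
    list(source = 11L, target = 13L, band = c(35, 55), strength = 0.8, lag_ms = 5),
    list(source = 13L, target = 5L, band = c(35, 55), strength = 0.8, lag_ms = 5))
}

default_gamma_by_diameter <- function(diameters_deg) {
  k <- seq_along(diameters_deg) - 1L
  nk <- max(length(diameters_deg) - 1L, 1L)
  list(freq_hz = 45 - 7 * k / nk,           # 45 Hz smallest -> 38 Hz largest
       rel_amplitude = 0.6 + 0.5 * k / nk)  # gamma grows with size
}

default_latency_params <- function() {
  list(
    supragranular = list(peak_z = 8, mu1_ms = 60, sigma1_ms = 10,
                         suppression = 0.35, latency_shift_ms = 5),
    granular = list(peak_z = 10, mu1_ms = 45, sigma1_ms = 10,
                    suppression = 0.25, latency_shift_ms = 4),
    infragranular = list(peak_z = 9, mu1_ms = 52, sigma1_ms = 10,
                         suppression = 0.12, latency_shift_ms = 3))
}

validate_synth_config <- function(cfg) {
  assert_scalar_num(cfg$fs_raw_hz, "fs_raw_hz", lower = 1000)
  assert_scalar_num(cfg$fs_target_hz, "fs_target_hz", lower = 100)
  check_decimation(cfg$fs_raw_hz, cfg$fs_target_hz)
  if (cfg$mua_band[2] <= cfg$mua_band[1] ||
      cfg$fs_raw_hz < 2 * cfg$mua_band[2]) {
    abort("fs_raw_hz cannot support the MUA band (needs at least twice its upper edge)")
  }
  if (cfg$n_channels < 3L) abort("need at least 3 channels")
  if (cfg$sink_channel < 1L || cfg$sink_channel > cfg$n_channels) {
    abort("sink_channel outside [1, n_channels]")
  }
  if (cfg$sink_peak_ms < 35 || cfg$sink_peak_ms > 55) {
    abort("sink_peak_ms must lie in [35, 55]")
  }
  for (e in cfg$coupling_spec) {
    if (e$lag_ms <= 0) abort("coupling lags must be positive")
    if (e$band[1] <= 0 || e$band[2] >= cfg$fs_target_hz / 2) {
      abort("coupling band outside (0, fs_target_hz / 2)")
    }
    if (e$source < 1 || e$source > cfg$n_channels ||
        e$target < 1 || e$target > cfg$n_channels) {
      abort("coupling channels outside the probe")
    }
  }
  coupling_topo_order(cfg$coupling_spec)  # errors when cyclic
  needed <- c("supragranular", "granular", "infragranular")
  if (!all(needed %in% names(cfg$latency_params_by_layer))) {
    abort("latency_params_by_layer must define all three compartments")
  }
  cfg
}

# Topological order of the (channel, band) latent nodes; errors on cycles.
coupling_topo_order <- function(coupling_spec) {
  if (!length(coupling_spec)) return(character())
  node_id <- function(ch, band) sprintf("%d@%g-%g", ch, band[1], band[2])
  nodes <- unique(unlist(lapply(coupling_spec, function(e) {
    c(node_id(e$source, e$band), node_id(e$target, e$band))
  })))
  edges <- lapply(coupling_spec, function(e) {
    c(node_id(e$source, e$band), node_id(e$target, e$band))
  })
  order <- character()
  remaining <- nodes
  while (length(remaining)) {
    has_pending_parent <- vapply(remaining, function(nd) {
      any(vapply(edges, function(ed) ed[2] == nd && ed[1] %in% remaining,
                 logical(1)))
    }, logical(1))
    if (all(has_pending_parent)) {
      abort("coupling_spec contains a cycle within a band")
    }
    ready <- remaining[!has_pending_parent]
    order <- c(order, ready)
    remaining <- setdiff(remaining, ready)
  }
  order
}

#' @export
print.synth_config <- function(x, ...) {
  cat(sprintf("<synth_config> %d ch @ %g um, fs %g -> %g Hz, %d trials x %d diameters, sink ch %d @ %g ms, %d coupling edge(s), common noise %g, seed %d\n",
              x$n_channels, x$spacing_um, x$fs_raw_hz, x$fs_target_hz,
              x$n_trials_per_condition, length(x$diameters_deg),
              x$sink_channel, x$sink_peak_ms, length(x$coupling_spec),
              x$common_noise_gain, x$seed))
  invisible(x)
}

#' Transient-model parameters planted for one channel and stimulus size
#'
#' Builds the ground-truth rate-profile parameters for [transient_model()]
#' from the per-layer configuration: Gaussian amplitudes are scaled so the
#' stated `peak_z` is (approximately) the first transient's peak height,
#' surround suppression reduces amplitudes with stimulus size (more
#' superficially than infragranularly), and latency grows linearly with the
#' size rank.
#'
#' @param config a [synth_config()].
#' @param channel channel index.
#' @param diameter_deg stimulus diameter (must be one of the configured
#'   diameters).
#' @return named list of R(t) parameters (G1..G3, mu1..mu3, sigma1..sigma3).
#' @export
synth_rate_params <- function(config, channel, diameter_deg) {
  stopifnot(inherits(config, "synth_config"))
  idx <- match(diameter_deg, config$diameters_deg)
  if (is.na(idx)) abort("diameter_deg is not one of the configured diameters")
  frac <- (idx - 1) / max(length(config$diameters_deg) - 1, 1)
  comp <- if (channel < config$sink_channel - 1L) "supragranular"
          else if (channel > config$sink_channel + 1L) "infragranular"
          else "granular"
  p <- config$latency_params_by_layer[[comp]]
  amp <- p$peak_z * (1 - p$suppression * frac)
  mu1 <- p$mu1_ms + p$latency_shift_ms * frac
  list(G1 = amp * sqrt(2 * pi) * p$sigma1_ms,
       G2 = 0.25 * amp * sqrt(2 * pi) * 25,
       G3 = 0.3 * amp,
       mu1 = mu1, mu2 = mu1 + 60, mu3 = mu1 + 5,
       sigma1 = p$sigma1_ms, sigma2 = 25, sigma3 = 10)
}

#' Ground-truth threshold-crossing latency of a noiseless rate profile
#'
#' Evaluates the planted R(t) on a dense 0.1 ms grid and returns the first
#' time it exceeds the z threshold, independent of any estimator.
#'
#' @param par parameter list for [transient_model()].
#' @param threshold z threshold (default 3).
#' @param window_ms evaluation window, default `c(0, 200)`.
#' @param grid_ms grid step, default 0.1.
#' @return latency ms, or `NA` when never exceeded.
#' @export
true_latency_from_params <- function(par, threshold = 3,
                                     window_ms = c(0, 200), grid_ms = 0.1) {
  tg <- seq(window_ms[1], window_ms[2], by = grid_ms)
  r <- transient_model(tg, par)
  i <- which(r > threshold)[1]
  if (is.na(i)) NA_real_ else tg[i]
}
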