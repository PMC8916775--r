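# Phase-triggered averaging: broadband LFPbp aligned to band-filtered troughs.

#' Detect oscillation-trough triggers on a reference trace
#'
#' Band-pass filters the reference trace (zero-phase 3rd-order Butterworth)
#' to obtain the phase-providing signal, then takes every strict local
#' minimum (trough) inside the analysis window as a trigger. No amplitude
#' threshold is applied; spurious noise troughs average out. Triggers whose
#' averaging window of `half_width_ms` would extend past the epoch are
#' discarded.
#'
#' @param trace numeric vector, one trial of the reference channel.
#' @param time_ms time axis, ms.
#' @param fs_hz sampling rate, Hz.
#' @param band band corners in Hz (e.g. `pta_bands()$gamma$band`).
#' @param window_ms analysis window, default `c(200, 500)` (sustained
#'   response).
#' @param half_width_ms averaging half-width used downstream; needed for the
#'   edge rule.
#' @return numeric vector of trigger times, ms (possibly empty).
#' @export
detect_phase_triggers <- function(trace, time_ms, fs_hz, band,
                                  window_ms = c(200, 500), half_width_ms = 25) {
  s_phase <- butter_zerophase(as.numeric(trace), fs_hz,
                              low = band[1], high = band[2], pad_s = 0.25)
  n <- length(s_phase)
  # a numerically-zero filtered signal (e.g. a constant input) has no phase;
  # 1e-4 sits far above filter round-off yet far below any real band content
  if (max(abs(s_phase)) < 1e-4 * max(abs(trace), 1)) return(numeric())
  i <- 2:(n - 1L)
  is_trough <- s_phase[i] < s_phase[i - 1L] & s_phase[i] < s_phase[i + 1L]
  t_tr <- time_ms[i][is_trough]
  t_tr <- t_tr[t_tr >= window_ms[1] & t_tr <= window_ms[2]]
  t_tr[t_tr - half_width_ms >= time_ms[1] & t_tr + half_width_ms <= time_ms[n]]
}

#' Phase-triggered average of broadband signals across channels
#'
#' For one frequency band: on each trial, detects the troughs of the
#' band-filtered reference channel, then averages the broadband
#' (amplitude-providing) signal of every channel in a symmetric lag window
#' around each trigger, pooling triggers across all trials (of one stimulus
#' condition when `condition` is given).
#'
#' @param targets an [epoched_signal()] of kind `"LFPbp"` (broadband).
#' @param reference_channel channel whose band-limited phase supplies the
#'   triggers.
#' @param band band corners, Hz.
#' @param half_width_ms lag half-width, ms (band-specific: theta 120,
#'   alpha 80, beta 80, gamma 25; see [pta_bands()]).
#' @param window_ms trigger analysis window, default `c(200, 500)`.
#' @param condition optional stimulus diameter; only those trials are used.
#' @return object of class `pta_profile`: `averages` (channel x lag),
#'   `lag_ms`, `n_triggers`, `reference_channel`, `band`.
#' @export
phase_triggered_average <- function(targets, reference_channel, band,
                                    half_width_ms, window_ms = c(200, 500),
                                    condition = NULL) {
  stopifnot(inherits(targets, "epoched_signal"))
  fs <- targets$fs_hz
  trials <- if (is.null(condition)) seq_len(dim(targets$data)[1L]) else
    which(targets$condition == condition)
  nch <- dim(targets$data)[2L]
  hw <- round(half_width_ms * fs / 1000)
  lag_ms <- (-hw:hw) * 1000 / fs
  acc <- matrix(0, nch, 2L * hw + 1L)
  n_trig <- 0L
  for (tr in trials) {
    trig_t <- detect_phase_triggers(targets$data[tr, reference_channel, ],
                                    targets$time_ms, fs, band,
                                    window_ms, half_width_ms)
    if (!length(trig_t)) next
    trig_i <- vapply(trig_t, function(tt) which.min(abs(targets$time_ms - tt)),
                     integer(1))
    for (ti in trig_i) {
      acc <- acc + targets$data[tr, , (ti - hw):(ti + hw)]
      n_trig <- n_trig + 1L
    }
  }
  averages <- if (n_trig > 0L) acc / n_trig else acc * NA_real_
  structure(list(averages = averages, lag_ms = lag_ms, n_triggers = n_trig,
                 reference_channel = reference_channel, band = band,
                 half_width_ms = half_width_ms, usable = targets$usable),
            class = "pta_profile")
}

#' @export
print.pta_profile <- function(x, ...) {
  cat(sprintf("<pta_profile> %d channels x %d lags (+-%g ms), ref channel %d, band %g-%g Hz, %d triggers\n",
              nrow(x$averages), length(x$lag_ms), x$half_width_ms,
              x$reference_channel, x$band[1], x$band[2], x$n_triggers))
  invisible(x)
}

#' Tidy a PTA profile into a long tibble
#' @param x a `pta_profile`.
#' @param ... unused.
#' @export
tidy.pta_profile <- function(x, ...) {
  tibble(
    channel = rep(seq_len(nrow(x$averages)), times = length(x$lag_ms)),
    lag_ms = rep(x$lag_ms, each = nrow(x$averages)),
    value = as.vector(x$averages),
    n_triggers = x$n_triggers)
}

#' Per-channel phase lag from a PTA profile
#'
#' Since averaging is trough-triggered, a channel phase-coupled to the
#' reference shows a trough near lag 0. The lag is the time of the strict
#' local trough nearest lag 0 in that channel's average; negative lags mean
#' the target leads the reference. Channels with no local trough (flat or
#' unusable profiles) get `NA`.
#'
#' @param profile a `pta_profile`.
#' @return tibble with channel, lag_ms, extremum value.
#' @export
pta_lag <- function(profile) {
  stopifnot(inherits(profile, "pta_profile"))
  purrr::map_dfr(seq_len(nrow(profile$averages)), function(ch) {
    v <- profile$averages[ch, ]
    n <- length(v)
    if (n < 3L || profile$n_triggers == 0L || any(!is.finite(v))) {
      return(tibble(channel = ch, lag_ms = NA_real_, value = NA_real_))
    }
    i <- 2:(n - 1L)
    trough <- i[v[i] < v[i - 1L] & v[i] < v[i + 1L]]
    if (!length(trough)) {
      return(tibble(channel = ch, lag_ms = NA_real_, value = NA_real_))
    }
    best <- trough[which.min(abs(profile$lag_ms[trough]))]
    tibble(channel = ch, lag_ms = profile$lag_ms[best], value = v[best])
  })
}
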