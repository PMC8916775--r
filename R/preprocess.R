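# Signal conditioning: raw samples -> LFP / MUAe -> epochs -> LFPbp -> z-scores.

#' Extract the local field potential from a raw session
#'
#' Band-pass filters the raw broadband signal between 0.75 and 300 Hz
#' (3rd-order Butterworth, applied forward-backward so the result is
#' zero-phase) and decimates to the target rate. The raw rate must be an
#' integer multiple of the target rate; decimation is plain subsampling,
#' which is alias-free because the 300 Hz low-pass sits below the target
#' Nyquist frequency.
#'
#' @param raw a [session_recording()].
#' @param fs_target_hz output rate, Hz (default 1000; the acquisition system
#'   equivalent is ~1 kHz).
#' @param band LFP corners in Hz, default `c(0.75, 300)`.
#' @return list with `samples` (channels x time matrix at `fs_target_hz`) and
#'   `fs_hz`.
#' @export
extract_lfp <- function(raw, fs_target_hz = 1000, band = c(0.75, 300)) {
  stopifnot(inherits(raw, "session_recording"))
  check_decimation(raw$fs_hz, fs_target_hz)
  if (raw$fs_hz < 2 * band[2]) abort("raw sampling rate below twice the upper LFP corner")
  filtered <- butter_zerophase(t(raw$samples), raw$fs_hz,
                               low = band[1], high = band[2])
  decim <- decimate_cols(filtered, raw$fs_hz, fs_target_hz)
  list(samples = t(decim), fs_hz = fs_target_hz)
}

#' Extract the multi-unit activity envelope (MUAe) from a raw session
#'
#' High-pass/band-pass filters the raw signal into the multi-unit band
#' (3rd-order Butterworth), full-wave rectifies, low-passes the rectified
#' signal at 200 Hz, and decimates to the target rate. The reference band is
#' 0.6-9 kHz at a 32 kHz acquisition rate; at lower simulation rates the
#' upper corner is capped at 0.45 x the raw rate.
#'
#' @param raw a [session_recording()].
#' @param fs_target_hz output rate, Hz.
#' @param mua_band multi-unit band corners in Hz; `NULL` (default) uses
#'   `c(600, min(9000, 0.45 * fs_raw))`.
#' @param envelope_lp_hz low-pass corner applied to the rectified signal
#'   (default 200 Hz).
#' @return list with `samples` (channels x time, non-negative) and `fs_hz`.
#' @export
extract_muae <- function(raw, fs_target_hz = 1000, mua_band = NULL,
                         envelope_lp_hz = 200) {
  stopifnot(inherits(raw, "session_recording"))
  check_decimation(raw$fs_hz, fs_target_hz)
  mua_band <- mua_band %||% c(600, min(9000, 0.45 * raw$fs_hz))
  if (raw$fs_hz < 2 * mua_band[2] || mua_band[2] <= mua_band[1]) {
    abort("raw sampling rate does not support the configured MUA band")
  }
  x <- t(raw$samples)
  x <- butter_zerophase(x, raw$fs_hz, low = mua_band[1], high = mua_band[2])
  x <- abs(x)
  x <- butter_zerophase(x, raw$fs_hz, high = envelope_lp_hz)
  x[x < 0] <- 0  # zero-phase low-pass can undershoot slightly near transients
  decim <- decimate_cols(x, raw$fs_hz, fs_target_hz)
  list(samples = t(decim), fs_hz = fs_target_hz)
}

check_decimation <- function(fs_raw, fs_target) {
  assert_scalar_num(fs_target, "fs_target_hz", lower = 1)
  factor <- fs_raw / fs_target
  if (abs(factor - round(factor)) > 1e-9) {
    abort(sprintf(
      "fs_target_hz = %g is not an integer divisor of the raw rate %g; use e.g. %g Hz",
      fs_target, fs_raw, fs_raw / ceiling(factor)))
  }
  invisible(as.integer(round(factor)))
}

decimate_cols <- function(x, fs_raw, fs_target) {
  f <- check_decimation(fs_raw, fs_target)
  x[seq(1L, nrow(x), by = f), , drop = FALSE]
}

#' Cut a continuous recording into stimulus-locked trials
#'
#' Slices a continuous multichannel signal into one epoch per stimulus event
#' using the half-open window `[window_ms[1], window_ms[2])` in ms relative
#' to onset (0-based sample indexing, so a `[-500, 500)` window at 1 kHz
#' yields exactly 1000 samples). Events whose window would extend past either
#' end of the recording are dropped with a warning.
#'
#' @param continuous list with `samples` (channels x time) and `fs_hz`, as
#'   returned by [extract_lfp()] / [extract_muae()].
#' @param events data frame with columns `onset_s` and `diameter_deg`.
#' @param window_ms epoch window, default `c(-500, 500)`.
#' @param kind signal kind tag carried into the result.
#' @return an [epoched_signal()].
#' @export
epoch_trials <- function(continuous, events, window_ms = c(-500, 500),
                         kind = "LFP") {
  fs <- continuous$fs_hz
  nsmp <- ncol(continuous$samples)
  nch <- nrow(continuous$samples)
  i0 <- round(window_ms[1] * fs / 1000)
  i1 <- round(window_ms[2] * fs / 1000)  # exclusive
  nt <- i1 - i0
  onset_idx <- round(events$onset_s * fs)  # 0-based sample of stimulus onset
  lo <- onset_idx + i0
  hi <- onset_idx + i1 - 1L
  ok <- lo >= 0L & hi <= nsmp - 1L
  if (any(!ok)) {
    warn(sprintf("dropping %d trial(s) too close to the recording edge", sum(!ok)))
  }
  keep <- which(ok)
  if (!length(keep)) abort("no complete trials inside the recording")
  data <- array(NA_real_, dim = c(length(keep), nch, nt))
  for (j in seq_along(keep)) {
    idx <- (lo[keep[j]] + 1L):(hi[keep[j]] + 1L)
    data[j, , ] <- continuous$samples[, idx]
  }
  epoched_signal(
    data,
    time_ms = (i0 + seq_len(nt) - 1L) * 1000 / fs,
    fs_hz = fs, kind = kind,
    condition = events$diameter_deg[keep]
  )
}

#' Bipolar-reference an epoched LFP
#'
#' Suppresses volume-conducted common signals by taking, at each contact, the
#' difference between the potentials at its two flanking contacts:
#' `LFPbp(i) = LFP(i-1) - LFP(i+1)` with contacts ordered top to bottom
#' (the default, centered stencil). `method = "successive"` instead differences
#' successive pairs, `LFP(i) - LFP(i+1)`, assigned to the upper contact.
#' End contacts without both neighbours are zeroed and marked unusable.
#'
#' @param lfp an [epoched_signal()] of kind `"LFP"`.
#' @param method `"centered"` (default) or `"successive"`.
#' @return an [epoched_signal()] of kind `"LFPbp"`.
#' @export
bipolar_reference <- function(lfp, method = c("centered", "successive")) {
  stopifnot(inherits(lfp, "epoched_signal"))
  method <- match.arg(method)
  if (lfp$kind != "LFP") abort("bipolar referencing expects kind = 'LFP'")
  nch <- dim(lfp$data)[2L]
  if (nch < 3L) abort("bipolar referencing needs at least 3 channels")
  out <- array(0, dim = dim(lfp$data))
  usable <- rep(FALSE, nch)
  if (method == "centered") {
    idx <- 2L:(nch - 1L)
    out[, idx, ] <- lfp$data[, idx - 1L, , drop = FALSE] -
      lfp$data[, idx + 1L, , drop = FALSE]
    usable[idx] <- TRUE
  } else {
    idx <- 1L:(nch - 1L)
    out[, idx, ] <- lfp$data[, idx, , drop = FALSE] -
      lfp$data[, idx + 1L, , drop = FALSE]
    usable[idx] <- TRUE
  }
  epoched_signal(out, lfp$time_ms, lfp$fs_hz, kind = "LFPbp",
                 condition = lfp$condition, usable = usable, units = lfp$units)
}

#' Z-score an epoched signal against its pre-stimulus baseline
#'
#' Per channel: subtract the baseline mean and divide by the baseline
#' standard deviation, both pooled over all trials and all samples in the
#' baseline window (spontaneous activity in the 300 ms before onset by
#' default).
#'
#' @param epoched an [epoched_signal()].
#' @param baseline_ms half-open baseline window, default `c(-300, 0)`.
#' @return an [epoched_signal()] in z units.
#' @export
zscore_to_baseline <- function(epoched, baseline_ms = c(-300, 0)) {
  stopifnot(inherits(epoched, "epoched_signal"))
  sel <- epoched$time_ms >= baseline_ms[1] & epoched$time_ms < baseline_ms[2]
  if (!any(sel)) abort("baseline window lies outside the epoch")
  d <- epoched$data
  out <- d
  for (ch in seq_len(dim(d)[2L])) {
    bl <- d[, ch, sel]
    m <- mean(bl)
    s <- sd(as.vector(bl))
    if (!is.finite(s) || s == 0) {
      abort(sprintf("channel %d has zero baseline variance; cannot z-score", ch))
    }
    out[, ch, ] <- (d[, ch, ] - m) / s
  }
  epoched_signal(out, epoched$time_ms, epoched$fs_hz, kind = epoched$kind,
                 condition = epoched$condition, usable = epoched$usable,
                 units = "z")
}
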