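# Time-frequency decomposition and induced spectral power (iSP).

#' Moving-window Hanning spectrogram
#'
#' Short-time Fourier power with a 100 ms moving window stepped by 10 ms.
#' Each window is demeaned, Hanning-tapered, zero-padded to `nfft = 1024`
#' points and squared-magnitude transformed. Window centers define the
#' spectrogram timestamps, so the frequency resolution of the grid is
#' `fs / 1024` (~1 Hz at 1 kHz) while the true spectral resolution is set by
#' the 100 ms window.
#'
#' @param x single trace (numeric vector) or trials x time matrix.
#' @param fs_hz sampling rate, Hz.
#' @param time_ms optional time axis (defaults to 0-based sample times).
#' @param window_ms taper window length, ms (default 100).
#' @param step_ms window step, ms (default 10).
#' @param nfft FFT length (default 1024).
#' @return object of class `spectrogram`: `power` (freq x time x trial),
#'   `freq_hz`, `time_ms` (window centers), and the parameters.
#' @export
spectrogram <- function(x, fs_hz, time_ms = NULL, window_ms = 100,
                        step_ms = 10, nfft = 1024) {
  if (is.vector(x)) x <- matrix(x, nrow = 1L)
  n <- ncol(x)
  L <- round(window_ms * fs_hz / 1000)
  if (n < L) abort("trace shorter than one spectrogram window")
  step <- max(1L, round(step_ms * fs_hz / 1000))
  time_ms <- time_ms %||% ((seq_len(n) - 1L) * 1000 / fs_hz)
  starts <- seq(1L, n - L + 1L, by = step)
  centers <- (time_ms[starts] + time_ms[starts + L - 1L]) / 2
  taper <- 0.5 * (1 - cos(2 * pi * (seq_len(L) - 1L) / (L - 1L)))
  nfreq <- nfft %/% 2L + 1L
  ntr <- nrow(x)
  power <- array(0, dim = c(nfreq, length(starts), ntr))
  seg <- matrix(0, nfft, length(starts))
  for (tr in seq_len(ntr)) {
    for (w in seq_along(starts)) {
      s <- x[tr, starts[w]:(starts[w] + L - 1L)]
      seg[, w] <- c((s - mean(s)) * taper, rep(0, nfft - L))
    }
    X <- stats::mvfft(seg)
    power[, , tr] <- abs(X[seq_len(nfreq), , drop = FALSE])^2
  }
  structure(
    list(power = power, freq_hz = (seq_len(nfreq) - 1L) * fs_hz / nfft,
         time_ms = centers, fs_hz = fs_hz, window_ms = window_ms,
         step_ms = step_ms, nfft = nfft, taper = "hanning"),
    class = "spectrogram")
}

#' @export
print.spectrogram <- function(x, ...) {
  d <- dim(x$power)
  cat(sprintf("<spectrogram> %d freqs x %d windows x %d trials (%g ms Hanning, %g ms step, nfft %d)\n",
              d[1], d[2], d[3], x$window_ms, x$step_ms, x$nfft))
  invisible(x)
}

#' Induced spectral power as a baseline z-score (iSP)
#'
#' Expresses stimulus-period spectral power relative to the spontaneous
#' activity in the pre-stimulus baseline, in two complementary
#' normalizations computed together:
#'
#' * `z_amp` ("amplitude" z, the display form): trial-mean power minus the
#'   mean of the per-trial baseline means, divided by the SD of the
#'   per-trial baseline means. Faithful to the *magnitude* of the power
#'   change (it grows with oscillation amplitude), so band-power size
#'   tuning and peak-frequency readouts use it; its null spread is wider
#'   than N(0,1) because the numerator carries single-window variance.
#' * `z` ("paired" z, the detection form): each trial's power at a bin is
#'   paired with that trial's own mean baseline power and the differences
#'   reduced to `mean(d) / (sd(d) / sqrt(n))`, a one-sample statistic whose
#'   null is standard normal at these trial counts. Calibrated (5% of null
#'   bins beyond |1.96|), but it saturates for strong effects and so
#'   carries no spectral-shape information.
#'
#' Bins with zero baseline variability are flagged and excluded from
#' downstream summaries.
#'
#' @param spec a multi-trial [spectrogram()].
#' @param baseline_ms baseline period, default `c(-300, 0)` ms.
#' @return object of class `isp`: `z` (paired detection z, freq x time),
#'   `z_amp` (amplitude z), `freq_hz`, `time_ms`, `n_trials`, `flagged`.
#' @export
induced_power_z <- function(spec, baseline_ms = c(-300, 0)) {
  stopifnot(inherits(spec, "spectrogram"))
  ntr <- dim(spec$power)[3L]
  if (ntr < 2L) abort("iSP needs at least 2 trials")
  half <- spec$window_ms / 2
  bl <- which(spec$time_ms - half >= baseline_ms[1] &
                spec$time_ms + half <= baseline_ms[2])
  if (length(bl) < 1L) abort("no spectrogram windows fully inside the baseline")
  # per-trial baseline mean power, freq x trial
  B <- apply(spec$power[, bl, , drop = FALSE], c(1L, 3L), mean)
  B_mean <- rowMeans(B)
  B_sd <- apply(B, 1L, sd)
  nfreq <- dim(spec$power)[1L]
  nt <- dim(spec$power)[2L]
  z <- matrix(NA_real_, nfreq, nt)
  z_amp <- matrix(NA_real_, nfreq, nt)
  flagged <- matrix(FALSE, nfreq, nt)
  for (ti in seq_len(nt)) {
    d <- spec$power[, ti, ] - B            # freq x trial paired differences
    m <- rowMeans(d)
    s <- apply(d, 1L, sd)
    bad <- !is.finite(s) | s == 0 | !is.finite(B_sd) | B_sd == 0
    flagged[bad, ti] <- TRUE
    z[!bad, ti] <- m[!bad] / (s[!bad] / sqrt(ntr))
    z_amp[!bad, ti] <- (rowMeans(spec$power[, ti, ])[!bad] - B_mean[!bad]) /
      B_sd[!bad]
  }
  structure(list(z = z, z_amp = z_amp, freq_hz = spec$freq_hz,
                 time_ms = spec$time_ms, n_trials = ntr, flagged = flagged,
                 baseline_ms = baseline_ms),
            class = "isp")
}

#' @export
print.isp <- function(x, ...) {
  cat(sprintf("<isp> %d freqs x %d windows, %d trials, baseline [%g, %g] ms\n",
              nrow(x$z), ncol(x$z), x$n_trials, x$baseline_ms[1], x$baseline_ms[2]))
  invisible(x)
}

#' Mean iSP in a frequency band over a time window
#' @keywords internal
#' @noRd
isp_band_mean <- function(isp, band, window_ms, slot = "z_amp") {
  fsel <- which(isp$freq_hz >= band[1] & isp$freq_hz <= band[2])
  if (!length(fsel)) abort(sprintf("band %g-%g Hz contains no frequency bins",
                                   band[1], band[2]))
  tsel <- which(isp$time_ms >= window_ms[1] & isp$time_ms <= window_ms[2])
  if (!length(tsel)) abort("analysis window contains no spectrogram bins")
  vals <- isp[[slot]][fsel, tsel, drop = FALSE]
  vals[isp$flagged[fsel, tsel, drop = FALSE]] <- NA
  mean(vals, na.rm = TRUE)
}

#' Band-integrated iSP by depth and stimulus size
#'
#' Averages the amplitude iSP z-score (`z_amp`, see [induced_power_z()])
#' over each band's frequency bins and the sustained analysis window
#' (200-500 ms after onset) for every channel and stimulus diameter.
#'
#' @param isp_table tibble with columns `channel`, `diameter_deg` and a
#'   list-column `isp` of [induced_power_z()] results (one per channel x
#'   condition), e.g. from [isp_by_channel()].
#' @param bands named list of band edges, default [classic_bands()].
#' @param window_ms sustained window, default `c(200, 500)`.
#' @param depths optional depth map from [assign_depths()].
#' @return tibble: band, channel, depth_um (if depths given), diameter_deg, z.
#' @export
band_power_profile <- function(isp_table, bands = classic_bands(),
                               window_ms = c(200, 500), depths = NULL) {
  out <- purrr::imap_dfr(bands, function(band_edges, bname) {
    isp_table |>
      dplyr::mutate(
        band = bname,
        z = purrr::map_dbl(.data$isp, isp_band_mean, band = !!band_edges,
                           window_ms = !!window_ms)) |>
      dplyr::select(dplyr::all_of(c("band", "channel", "diameter_deg", "z")))
  })
  if (!is.null(depths)) out <- dplyr::left_join(out, depths, by = "channel")
  out
}

#' Compute iSP for every usable channel and condition of an epoched signal
#'
#' @param epoched an [epoched_signal()] (normally kind `"LFPbp"`).
#' @param channels channels to include (default: usable ones).
#' @param baseline_ms baseline period for [induced_power_z()].
#' @param ... passed to [spectrogram()].
#' @return tibble with channel, diameter_deg and an `isp` list-column.
#' @export
isp_by_channel <- function(epoched, channels = NULL, baseline_ms = c(-300, 0),
                           ...) {
  stopifnot(inherits(epoched, "epoched_signal"))
  channels <- channels %||% which(epoched$usable)
  grid <- tidyr::expand_grid(channel = channels,
                             diameter_deg = sort(unique(epoched$condition)))
  grid$isp <- purrr::map2(grid$channel, grid$diameter_deg, function(ch, cond) {
    tr <- which(epoched$condition == cond)
    spec <- spectrogram(epoched$data[tr, ch, ], epoched$fs_hz,
                        time_ms = epoched$time_ms, ...)
    induced_power_z(spec, baseline_ms)
  })
  grid
}

#' Gamma peak frequency of an iSP map
#'
#' Frequency bin of maximal mean amplitude-normalized iSP (`z_amp`) within
#' the search range over the sustained window. Undefined (`NA`) when no bin
#' in range has positive mean z (no evoked narrowband oscillation).
#'
#' @param isp an [induced_power_z()] result.
#' @param search_hz search range, default `c(25, 65)`.
#' @param window_ms sustained window, default `c(200, 500)`.
#' @return peak frequency in Hz, or `NA`.
#' @export
gamma_peak_frequency <- function(isp, search_hz = c(25, 65),
                                 window_ms = c(200, 500)) {
  stopifnot(inherits(isp, "isp"))
  fsel <- which(isp$freq_hz >= search_hz[1] & isp$freq_hz <= search_hz[2])
  tsel <- which(isp$time_ms >= window_ms[1] & isp$time_ms <= window_ms[2])
  if (!length(fsel) || !length(tsel)) abort("search range outside the iSP grid")
  vals <- isp$z_amp[fsel, tsel, drop = FALSE]
  vals[isp$flagged[fsel, tsel, drop = FALSE]] <- NA
  prof <- rowMeans(vals, na.rm = TRUE)
  if (all(!is.finite(prof)) || max(prof, na.rm = TRUE) <= 0) return(NA_real_)
  isp$freq_hz[fsel[which.max(prof)]]
}
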