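# Internal helpers: zero-phase filtering, seed streams, small validators.

#' Zero-phase Butterworth filtering with reflection padding
#'
#' Designs a 3rd-order Butterworth filter and applies it forward and
#' backward, so the net phase response is zero. Bands whose lower corner
#' sits very close to DC (normalized frequency < 0.01, e.g. the 0.75-300 Hz
#' LFP band at 8 kHz) are realized as a high-pass/low-pass cascade because
#' the single band-pass polynomial is numerically fragile there. The signal
#' is extended at both ends by odd reflection before filtering to suppress
#' edge transients.
#'
#' @param x numeric vector or matrix (filtered along columns).
#' @param fs sampling rate, Hz.
#' @param low,high band corners in Hz; `NA` low gives a low-pass, `NA` high a
#'   high-pass.
#' @param order filter order per section (default 3, as used throughout).
#' @param pad_s reflection pad length in seconds.
#' @return filtered object of the same shape as `x`.
#' @keywords internal
#' @noRd
butter_zerophase <- function(x, fs, low = NA, high = NA, order = 3,
                             pad_s = 1) {
  if (is.na(low) && is.na(high)) abort("at least one band corner is required")
  nyq <- fs / 2
  for (corner in c(low, high)) {
    if (!is.na(corner) && (corner <= 0 || corner >= nyq)) {
      abort(sprintf("filter corner %g Hz outside (0, %g) at fs = %g Hz",
                    corner, nyq, fs))
    }
  }
  filts <- list()
  if (!is.na(low) && !is.na(high) && low / nyq >= 0.01) {
    # single band-pass polynomial is numerically safe away from DC
    filts <- list(signal::butter(order, c(low, high) / nyq, type = "pass"))
  } else {
    if (!is.na(low)) filts <- c(filts, list(signal::butter(order, low / nyq, type = "high")))
    if (!is.na(high)) filts <- c(filts, list(signal::butter(order, high / nyq, type = "low")))
  }

  apply_one <- function(v) {
    n <- length(v)
    npad <- min(n - 1L, max(16L, round(pad_s * fs)))
    # odd reflection: mirrors the signal about its endpoints
    pre <- 2 * v[1L] - v[seq(npad + 1L, 2L)]
    post <- 2 * v[n] - v[seq(n - 1L, n - npad)]
    ext <- c(pre, v, post)
    for (f in filts) {
      ext <- signal::filtfilt(f, ext)
    }
    ext[seq(npad + 1L, npad + n)]
  }
  if (is.matrix(x)) {
    out <- apply(x, 2L, apply_one)
    dim(out) <- dim(x)
    dimnames(out) <- dimnames(x)
    out
  } else {
    apply_one(as.numeric(x))
  }
}

#' Derive a per-stage seed from one master seed
#'
#' Every stochastic stage draws its own named stream so that stages are
#' reproducible independently of each other.
#' @keywords internal
#' @noRd
stream_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 10007 + h) %% 2147483647)
}

with_stream <- function(seed, stage, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(stream_seed(seed, stage))
  force(code)
}

assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a finite number in [%g, %g]", name, lower, upper))
  }
  invisible(x)
}

#' Classic electrophysiology frequency bands
#'
#' Band edges used by the spectral-power analyses: theta 4-8, alpha 8-13,
#' beta 14-25, gamma 35-55 Hz. The phase-triggered averaging stage uses its
#' own slightly wider gamma band (30-55 Hz); see [pta_bands()].
#'
#' @return named list of `c(low, high)` Hz pairs.
#' @export
#' @examples
#' classic_bands()$gamma
classic_bands <- function() {
  list(theta = c(4, 8), alpha = c(8, 13), beta = c(14, 25), gamma = c(35, 55))
}

#' Frequency bands and averaging half-widths for phase-triggered averaging
#'
#' The trigger filter bands (gamma here is 30-55 Hz) together with the
#' band-specific half-widths of the averaging window: theta 120, alpha 80,
#' beta 80, gamma 25 ms.
#'
#' @return named list with elements `band` (Hz pair) and `half_width_ms`.
#' @export
pta_bands <- function() {
  list(
    theta = list(band = c(4, 8), half_width_ms = 120),
    alpha = list(band = c(8, 13), half_width_ms = 80),
    beta  = list(band = c(14, 25), half_width_ms = 80),
    gamma = list(band = c(30, 55), half_width_ms = 25)
  )
}
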