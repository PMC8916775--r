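# The epoched-signal container shared by every analysis stage.

#' Construct an epoched multichannel signal
#'
#' Light container for trials x channels x time data with a uniform time axis
#' relative to stimulus onset. `kind` tracks which conditioning chain produced
#' the data: broadband LFP, MUA envelope, bipolar-referenced LFP, or CSD.
#'
#' @param data numeric array, trials x channels x time.
#' @param time_ms numeric vector of sample times in ms relative to stimulus
#'   onset; must be uniform and strictly increasing.
#' @param fs_hz sampling rate in Hz.
#' @param kind one of `"LFP"`, `"MUAe"`, `"LFPbp"`, `"CSD"`.
#' @param condition per-trial condition label (grating diameter in degrees).
#' @param usable logical per channel; bipolar referencing marks end contacts
#'   unusable.
#' @param units unit string, `"uV"` or `"z"`.
#' @return object of class `epoched_signal`.
#' @export
epoched_signal <- function(data, time_ms, fs_hz,
                           kind = c("LFP", "MUAe", "LFPbp", "CSD"),
                           condition = NULL, usable = NULL, units = "uV") {
  kind <- match.arg(kind)
  if (length(dim(data)) != 3L) abort("`data` must be trials x channels x time")
  if (length(time_ms) != dim(data)[3L]) {
    abort("`time_ms` length must match the time dimension of `data`")
  }
  dt <- diff(time_ms)
  if (length(dt) && (any(dt <= 0) || diff(range(dt)) > 1e-6 * mean(dt))) {
    abort("`time_ms` must be strictly increasing and uniform")
  }
  condition <- condition %||% rep(NA_real_, dim(data)[1L])
  if (length(condition) != dim(data)[1L]) {
    abort("`condition` must have one entry per trial")
  }
  usable <- usable %||% rep(TRUE, dim(data)[2L])
  structure(
    list(data = data, time_ms = as.numeric(time_ms), fs_hz = fs_hz,
         kind = kind, condition = condition, usable = usable, units = units),
    class = "epoched_signal"
  )
}

#' @export
print.epoched_signal <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<epoched_signal: %s> %d trials x %d channels x %d samples @ %g Hz [%g, %g] ms (%s)\n",
    x$kind, d[1], d[2], d[3], x$fs_hz, min(x$time_ms), max(x$time_ms), x$units))
  invisible(x)
}

#' @export
dim.epoched_signal <- function(x) dim(x$data)

#' Average trials of an epoched signal
#'
#' @param x an [epoched_signal()].
#' @param condition optional condition value; only matching trials are
#'   averaged.
#' @return channels x time matrix.
#' @export
trial_average <- function(x, condition = NULL) {
  stopifnot(inherits(x, "epoched_signal"))
  keep <- if (is.null(condition)) seq_len(dim(x$data)[1L]) else which(x$condition == condition)
  if (!length(keep)) abort("no trials match the requested condition")
  out <- apply(x$data[keep, , , drop = FALSE], c(2L, 3L), mean)
  dimnames(out) <- NULL
  out
}

#' Tidy an epoched signal into a long tibble
#'
#' @param x an [epoched_signal()].
#' @param ... unused.
#' @return tibble with columns trial, channel, time_ms, condition, value.
#' @export
tidy.epoched_signal <- function(x, ...) {
  d <- dim(x$data)
  tibble(
    trial = rep(seq_len(d[1]), times = d[2] * d[3]),
    channel = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
    time_ms = rep(x$time_ms, each = d[1] * d[2]),
    condition = rep(x$condition, times = d[2] * d[3]),
    value = as.vector(x$data)
  )
}
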