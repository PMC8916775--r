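# Inverse current-source density, layer-4c alignment, depth maps, session QC.

# Vaknin-extended second-difference operator M (n x n) such that
# CSD = -(sigma / h^2) * M %*% phi. Boundary potentials are duplicated
# (Vaknin), so all n channels survive. M is symmetric, singular (constants in
# its null space) and its range is the zero-sum subspace: any CSD it produces
# conserves current across depth.
csd_operator <- function(n) {
  if (n < 3L) abort("CSD needs at least 3 channels")
  M <- matrix(0, n, n)
  for (i in 2:(n - 1L)) M[i, (i - 1L):(i + 1L)] <- c(1, -2, 1)
  M[1L, 1:2] <- c(-1, 1)
  M[n, (n - 1L):n] <- c(1, -1)
  M
}

#' Compute the inverse-CSD depth profile of a potential map
#'
#' Standard finite-difference inverse CSD:
#' `CSD(z) = -sigma * (phi(z+h) - 2 phi(z) + phi(z-h)) / h^2`,
#' with the top and bottom channels regained by duplicating the boundary
#' potentials (the Vaknin method). The sign convention is sink-positive:
#' a current sink (net inward transmembrane current) appears as a positive
#' value.
#'
#' @param vep trial-averaged potentials, channels (superficial to deep) x
#'   time, in microvolts (converted to volts internally so the output is in
#'   SI units).
#' @param sigma_s_per_m extracellular conductivity, S/m (default 0.3).
#' @param spacing_um inter-contact spacing, micrometers (default 150).
#' @param time_ms optional time axis for the columns.
#' @param units_in `"uV"` (default) or `"V"`.
#' @return a `csd_profile` object; values in A/m^3, sink-positive.
#' @export
#' @examples
#' phi <- matrix(c(0, 1000, 0), ncol = 1)  # 1 mV bump on the middle contact
#' compute_icsd(phi)$values[2, 1]          # ~ +2.667e4 A/m^3
compute_icsd <- function(vep, sigma_s_per_m = 0.3, spacing_um = 150,
                         time_ms = NULL, units_in = c("uV", "V")) {
  units_in <- match.arg(units_in)
  vep <- as.matrix(vep)
  if (!all(is.finite(vep))) abort("potentials must be finite")
  assert_scalar_num(sigma_s_per_m, "sigma_s_per_m", lower = 1e-12)
  assert_scalar_num(spacing_um, "spacing_um", lower = 1e-9)
  n <- nrow(vep)
  phi_v <- if (units_in == "uV") vep * 1e-6 else vep
  h_m <- spacing_um * 1e-6
  values <- -(sigma_s_per_m / h_m^2) * (csd_operator(n) %*% phi_v)
  new_csd_profile(values,
                  time_ms = time_ms %||% seq_len(ncol(vep)) - 1,
                  sigma = sigma_s_per_m, spacing_um = spacing_um)
}

new_csd_profile <- function(values, time_ms, sigma, spacing_um,
                            depth_um = NULL, normalization = "raw") {
  structure(
    list(values = unname(as.matrix(values)), time_ms = as.numeric(time_ms),
         depth_um = depth_um, sigma = sigma, spacing_um = spacing_um,
         normalization = normalization),
    class = "csd_profile")
}

#' @export
print.csd_profile <- function(x, ...) {
  cat(sprintf("<csd_profile> %d depths x %d times, sigma = %g S/m, spacing = %g um (%s)\n",
              nrow(x$values), ncol(x$values), x$sigma, x$spacing_um,
              x$normalization))
  invisible(x)
}

#' Tidy a CSD profile into a long tibble
#' @param x a `csd_profile`.
#' @param ... unused.
#' @return tibble with channel, depth_um (if assigned), time_ms, csd.
#' @export
tidy.csd_profile <- function(x, ...) {
  n <- nrow(x$values)
  out <- tibble(
    channel = rep(seq_len(n), times = ncol(x$values)),
    time_ms = rep(x$time_ms, each = n),
    csd = as.vector(x$values)
  )
  if (!is.null(x$depth_um)) out$depth_um <- rep(x$depth_um, times = ncol(x$values))
  out
}

#' Forward volume-conduction model: potentials from a planted CSD map
#'
#' Inverts the discrete Vaknin-extended CSD operator so that running
#' [compute_icsd()] on the returned potentials reproduces the input map to
#' machine precision. Because current is conserved across the probe, the
#' operator's range is the zero-depth-sum subspace: a CSD column that does
#' not sum to zero is first projected onto that subspace (with a warning).
#' The gauge freedom (a depth-constant potential offset is invisible to the
#' CSD) is fixed by making each output column zero-mean.
#'
#' @param csd_map channels x time CSD, A/m^3, sink-positive.
#' @param sigma_s_per_m conductivity, S/m.
#' @param spacing_um contact spacing, micrometers.
#' @param units_out `"uV"` (default) or `"V"`.
#' @return channels x time matrix of potentials.
#' @export
forward_potentials_from_csd <- function(csd_map, sigma_s_per_m = 0.3,
                                        spacing_um = 150,
                                        units_out = c("uV", "V")) {
  units_out <- match.arg(units_out)
  csd_map <- as.matrix(csd_map)
  if (!all(is.finite(csd_map))) abort("CSD map must be finite")
  assert_scalar_num(spacing_um, "spacing_um", lower = 1e-9)
  n <- nrow(csd_map)
  h_m <- spacing_um * 1e-6
  M <- csd_operator(n)
  colsum <- colSums(csd_map)
  scale <- max(abs(csd_map), 1e-300)
  if (any(abs(colsum) > 1e-9 * n * scale)) {
    warn(paste("CSD columns do not sum to zero (current not conserved);",
               "projecting onto the charge-balanced subspace"))
    csd_map <- sweep(csd_map, 2L, colsum / n)
  }
  # gauge-fixed solve: append a zero-mean constraint row to the singular M
  A <- rbind(M, rep(1, n))
  rhs <- rbind(-(h_m^2 / sigma_s_per_m) * csd_map,
               rep(0, ncol(csd_map)))
  qrA <- qr(A)
  if (qrA$rank < n) abort("singular CSD operator: degenerate geometry")
  phi_v <- qr.coef(qrA, rhs)
  phi_v <- unname(as.matrix(phi_v))
  if (units_out == "uV") phi_v * 1e6 else phi_v
}

#' Locate the early layer-4c current sink
#'
#' Returns the channel whose maximum sink-positive CSD within the search
#' window (35-55 ms after stimulus onset by default) is largest, together
#' with the time of that peak. Ties go to the more superficial channel with
#' a warning.
#'
#' @param csd a `csd_profile` with a time axis covering the window.
#' @param window_ms sink search window, default `c(35, 55)`.
#' @return list with `channel` (1-based from the top) and `peak_ms`.
#' @export
find_alignment_channel <- function(csd, window_ms = c(35, 55)) {
  stopifnot(inherits(csd, "csd_profile"))
  sel <- which(csd$time_ms >= window_ms[1] & csd$time_ms <= window_ms[2])
  if (!length(sel)) abort("CSD time axis does not cover the sink search window")
  win <- csd$values[, sel, drop = FALSE]
  peaks <- apply(win, 1L, max)
  if (max(peaks) <= 0) {
    abort(sprintf("no identifiable sink: no positive CSD in %g-%g ms",
                  window_ms[1], window_ms[2]))
  }
  best <- which(peaks == max(peaks))
  if (length(best) > 1L) {
    warn(sprintf("tied sink peaks on channels %s; taking the most superficial",
                 paste(best, collapse = ", ")))
  }
  ch <- best[1L]
  list(channel = ch, peak_ms = csd$time_ms[sel[which.max(win[ch, ])]])
}

#' Assign cortical depths relative to the alignment channel
#'
#' Depth 0 um is the alignment channel (putative layer 4c); channels above
#' it get positive depths: `depth(ch) = (alignment - ch) * spacing`.
#' Three contacts above the alignment channel at 150 um spacing is +450 um
#' (supragranular), three below is -450 um (infragranular).
#'
#' @param alignment_channel 1-based channel index from the top.
#' @param n_channels number of contacts.
#' @param spacing_um contact spacing, micrometers.
#' @return tibble with channel, depth_um, and compartment
#'   (supragranular / granular / infragranular).
#' @export
assign_depths <- function(alignment_channel, n_channels, spacing_um = 150) {
  if (alignment_channel < 1 || alignment_channel > n_channels) {
    abort("alignment channel outside the probe")
  }
  ch <- seq_len(n_channels)
  depth <- (alignment_channel - ch) * spacing_um
  tibble(
    channel = ch,
    depth_um = depth,
    compartment = dplyr::case_when(
      depth > 0 ~ "supragranular",
      depth == 0 ~ "granular",
      TRUE ~ "infragranular"
    )
  )
}

#' Quality-control a session from its CSD profile
#'
#' Automates the session inclusion rules: (1) an identifiable early sink
#' whose peak occurs no later than 50 ms after stimulus onset; (2) the
#' alignment channel lies between the seventh and twelfth contact from the
#' top (minimum coverage of layers 2-6); (3) a CSD pattern consistent with
#' the majority of sessions - inherently a manual judgement, recorded as
#' supplied and never auto-decided.
#'
#' @param csd a `csd_profile` averaged across all stimulus presentations.
#' @param manual_pattern_ok `NA` (unreviewed, default), `TRUE` or `FALSE`.
#' @param sink_window_ms search window passed to [find_alignment_channel()].
#' @param max_peak_ms latest admissible sink peak (default 50 ms).
#' @param channel_range admissible alignment-channel range, default `c(7, 12)`.
#' @return list of class `qc_report`: `pass`, `criteria` tibble,
#'   `alignment` (or NULL), `notes`.
#' @export
qc_session <- function(csd, manual_pattern_ok = NA,
                       sink_window_ms = c(35, 55), max_peak_ms = 50,
                       channel_range = c(7, 12)) {
  alignment <- tryCatch(find_alignment_channel(csd, sink_window_ms),
                        error = function(e) NULL)
  notes <- character()
  c1 <- !is.null(alignment) && alignment$peak_ms <= max_peak_ms
  if (is.null(alignment)) notes <- c(notes, "no identifiable early sink")
  c2 <- !is.null(alignment) &&
    alignment$channel >= channel_range[1] && alignment$channel <= channel_range[2]
  criteria <- tibble(
    criterion = c("early_sink_by_50ms", "alignment_channel_7_to_12",
                  "csd_pattern_consistent"),
    status = c(ifelse(c1, "pass", "fail"),
               ifelse(c2, "pass", "fail"),
               dplyr::case_when(is.na(manual_pattern_ok) ~ "manual",
                                manual_pattern_ok ~ "pass",
                                TRUE ~ "fail"))
  )
  pass <- c1 && c2 && !isFALSE(manual_pattern_ok)
  structure(list(pass = pass, criteria = criteria, alignment = alignment,
                 notes = notes),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> %s\n", if (x$pass) "PASS" else "FAIL"))
  for (i in seq_len(nrow(x$criteria))) {
    cat(sprintf("  %-28s %s\n", x$criteria$criterion[i], x$criteria$status[i]))
  }
  if (!is.null(x$alignment)) {
    cat(sprintf("  alignment channel %d, sink peak %.1f ms\n",
                x$alignment$channel, x$alignment$peak_ms))
  }
  invisible(x)
}

#' Normalize a CSD profile to its early sink peak
#'
#' Divides the whole map by the maximum sink-positive value on the alignment
#' channel inside the normalization window (40-70 ms by default), so the
#' early sink has amplitude 1.
#'
#' @param csd a `csd_profile`.
#' @param alignment_channel channel carrying the early sink.
#' @param window_ms normalization window, default `c(40, 70)`.
#' @return the rescaled `csd_profile` (`normalization = "sink-peak"`).
#' @export
normalize_to_sink <- function(csd, alignment_channel, window_ms = c(40, 70)) {
  stopifnot(inherits(csd, "csd_profile"))
  sel <- csd$time_ms >= window_ms[1] & csd$time_ms <= window_ms[2]
  peak <- max(csd$values[alignment_channel, sel])
  if (peak <= 0) abort("no positive sink peak to normalize to")
  csd$values <- csd$values / peak
  csd$normalization <- "sink-peak"
  csd
}
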