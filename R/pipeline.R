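# End-to-end orchestration of one or many sessions.

#' Analysis configuration for the full pipeline
#'
#' Collects every numeric constant used by the stages in one validated
#' place; the configuration is echoed into each results bundle so a bundle
#' is fully reproducible from (session, config, seed).
#'
#' @param bands spectral bands, default [classic_bands()].
#' @param pta phase-triggered-averaging bands/half-widths, default
#'   [pta_bands()].
#' @param epoch_window_ms,baseline_ms,sustained_ms analysis windows.
#' @param fs_target_hz analysis rate after decimation.
#' @param lfp_band LFP filter corners, Hz.
#' @param latency_window_ms,latency_threshold transient-fit window and z
#'   threshold.
#' @param gc_order,gc_start_ms,gc_n_bins,gc_n_null Granger-causality
#'   settings ([fit_var_pair()], [gc_segment()], [reverse_granger_test()]).
#' @param gc_conditions diameters to run GC on; `NULL` means the smallest
#'   and largest configured stimulus.
#' @param gc_channels channel subset for the GC graph (`NULL`: all usable).
#' @param pta_reference_depth_um depth of the PTA reference contact
#'   (default -150, one contact below the alignment channel).
#' @param enforce_qc skip downstream stages when QC fails (default TRUE).
#' @param seed master seed for permutation/null streams.
#' @return list of class `analysis_config`.
#' @export
analysis_config <- function(bands = classic_bands(), pta = pta_bands(),
                            epoch_window_ms = c(-500, 500),
                            baseline_ms = c(-300, 0),
                            sustained_ms = c(200, 500),
                            fs_target_hz = 1000,
                            lfp_band = c(0.75, 300),
                            latency_window_ms = c(0, 200),
                            latency_threshold = 3,
                            gc_order = 50, gc_start_ms = 200,
                            gc_n_bins = 256, gc_n_null = 9,
                            gc_conditions = NULL, gc_channels = NULL,
                            pta_reference_depth_um = -150,
                            enforce_qc = TRUE, seed = 1) {
  if (baseline_ms[1] < epoch_window_ms[1] || sustained_ms[2] > epoch_window_ms[2]) {
    abort("analysis windows must lie inside the epoch window")
  }
  if (!length(bands)) abort("at least one spectral band is required")
  structure(as.list(environment()), class = "analysis_config")
}

#' Run the full laminar analysis pipeline on one session
#'
#' Stages, in order: LFP/MUAe conditioning and epoching; inverse CSD,
#' layer-4c sink alignment and session QC (when QC fails and `force` is
#' FALSE, downstream stages are skipped); MUAe baseline z-scoring and
#' latency depth profiles; bipolar referencing; induced spectral power and
#' band-power profiles with gamma peak frequencies; phase-triggered
#' averages per band and stimulus size; the Granger-causality graph with
#' reversal control per selected stimulus size.
#'
#' @param session a [session_recording()] or a container directory path.
#' @param config an [analysis_config()].
#' @param force run all stages even when QC fails.
#' @return list of class `lamflow_bundle`.
#' @export
run_pipeline <- function(session, config = analysis_config(), force = FALSE) {
  if (is.character(session)) session <- read_session(session)$session
  stopifnot(inherits(session, "session_recording"),
            inherits(config, "analysis_config"))
  log <- list(started = Sys.time(), config = config)

  lfp <- extract_lfp(session, config$fs_target_hz, config$lfp_band)
  muae <- extract_muae(session, config$fs_target_hz)
  lfp_ep <- epoch_trials(lfp, session$events, config$epoch_window_ms, kind = "LFP")
  muae_ep <- epoch_trials(muae, session$events, config$epoch_window_ms, kind = "MUAe")

  vep <- trial_average(lfp_ep)
  csd <- compute_icsd(vep, spacing_um = session$spacing_um,
                      time_ms = lfp_ep$time_ms)
  qc <- qc_session(csd)
  bundle <- list(qc = qc, csd = csd, config = config, log = log)
  class(bundle) <- "lamflow_bundle"
  if (!qc$pass && config$enforce_qc && !force) {
    inform("session failed QC; downstream stages skipped (use force = TRUE to override)")
    return(bundle)
  }
  alignment <- qc$alignment %||% find_alignment_channel(csd)
  depths <- assign_depths(alignment$channel, nrow(session$samples),
                          session$spacing_um)
  bundle$depths <- depths
  bundle$csd_normalized <- normalize_to_sink(csd, alignment$channel)

  muae_z <- zscore_to_baseline(muae_ep, config$baseline_ms)
  bundle$latency <- latency_profile(muae_z, depths, config$latency_window_ms,
                                    config$latency_threshold)

  sus <- muae_z$time_ms >= config$sustained_ms[1] &
    muae_z$time_ms < config$sustained_ms[2]
  bundle$muae_sustained <- purrr::map_dfr(
    sort(unique(muae_z$condition)), function(cond) {
      avg <- trial_average(muae_z, cond)
      tibble(channel = seq_len(nrow(avg)), diameter_deg = cond,
             z = rowMeans(avg[, sus, drop = FALSE]))
    }) |>
    dplyr::left_join(depths, by = "channel")

  lfpbp <- bipolar_reference(lfp_ep)
  isp_table <- isp_by_channel(lfpbp, baseline_ms = config$baseline_ms)
  bundle$band_power <- band_power_profile(isp_table, config$bands,
                                          config$sustained_ms, depths)
  bundle$gamma_peak <- isp_table |>
    dplyr::mutate(peak_hz = purrr::map_dbl(.data$isp, gamma_peak_frequency,
                                           window_ms = config$sustained_ms)) |>
    dplyr::select(dplyr::all_of(c("channel", "diameter_deg", "peak_hz")))

  ref_ch <- depths$channel[depths$depth_um == config$pta_reference_depth_um]
  if (length(ref_ch) == 1L && lfpbp$usable[ref_ch]) {
    bundle$pta <- purrr::imap(config$pta, function(spec, bname) {
      purrr::map(stats::setNames(nm = sort(unique(lfpbp$condition))),
                 function(cond) {
        phase_triggered_average(lfpbp, ref_ch, spec$band, spec$half_width_ms,
                                config$sustained_ms, condition = cond)
      })
    })
  }

  gc_conds <- config$gc_conditions %||%
    range(unique(session$events$diameter_deg))
  bundle$gc <- purrr::map(stats::setNames(nm = gc_conds), function(cond) {
    build_gc_graph(lfpbp, config$bands, depths,
                   channels = config$gc_channels, condition = cond,
                   order = config$gc_order, start_ms = config$gc_start_ms,
                   n_bins = config$gc_n_bins, n_null = config$gc_n_null,
                   seed = config$seed)
  })
  bundle$log$finished <- Sys.time()
  bundle
}

#' @export
print.lamflow_bundle <- function(x, ...) {
  cat("<lamflow_bundle>\n")
  cat(sprintf("  QC: %s\n", if (x$qc$pass) "pass" else "fail"))
  for (nm in c("depths", "latency", "muae_sustained", "band_power",
               "gamma_peak", "pta", "gc")) {
    if (!is.null(x[[nm]])) cat(sprintf("  %s: computed\n", nm))
  }
  invisible(x)
}

# two-adjacent-channel compartments used for size-tuning summaries
compartment_channels <- function(depths) {
  list(supragranular = depths$channel[depths$depth_um %in% c(450, 600)],
       granular = depths$channel[depths$depth_um == 0],
       infragranular = depths$channel[depths$depth_um %in% c(-450, -600)])
}

#' Size-tuning summaries across sessions
#'
#' Per laminar compartment (supragranular centered +450 um, granular 0 um,
#' infragranular centered -450 um; the off-granular compartments average two
#' adjacent channels) and stimulus diameter: mean and s.e.m. across sessions
#' of the sustained MUAe z-score, the band-integrated iSP, and the response
#' latency.
#'
#' @param bundles a single `lamflow_bundle` or a list of them.
#' @return tibble: response, band (NA except for band power), compartment,
#'   diameter_deg, mean, sem (NA with a single session), n_sessions.
#' @export
summarize_size_tuning <- function(bundles) {
  if (inherits(bundles, "lamflow_bundle")) bundles <- list(bundles)
  if (!length(bundles)) abort("no bundles supplied")
  per_session <- purrr::imap_dfr(bundles, function(b, si) {
    if (is.null(b$depths)) return(tibble())
    comps <- compartment_channels(b$depths)
    purrr::imap_dfr(comps, function(chs, comp) {
      if (!length(chs)) return(tibble())
      mu <- b$muae_sustained |>
        dplyr::filter(.data$channel %in% chs) |>
        dplyr::group_by(.data$diameter_deg) |>
        dplyr::summarise(value = mean(.data$z), .groups = "drop") |>
        dplyr::mutate(response = "muae_z", band = NA_character_)
      lat <- b$latency$by_channel |>
        dplyr::filter(.data$channel %in% chs) |>
        dplyr::group_by(.data$diameter_deg) |>
        dplyr::summarise(value = mean(.data$latency_ms, na.rm = TRUE),
                         .groups = "drop") |>
        dplyr::mutate(response = "latency_ms", band = NA_character_)
      bp <- b$band_power |>
        dplyr::filter(.data$channel %in% chs) |>
        dplyr::group_by(.data$band, .data$diameter_deg) |>
        dplyr::summarise(value = mean(.data$z), .groups = "drop") |>
        dplyr::mutate(response = "band_power_z")
      dplyr::bind_rows(mu, lat, bp) |>
        dplyr::mutate(compartment = comp, session = si)
    })
  })
  if (!nrow(per_session)) abort("no summarizable bundles (all skipped by QC?)")
  single <- length(unique(per_session$session)) == 1L
  if (single) inform("single session: s.e.m. undefined")
  per_session |>
    dplyr::group_by(.data$response, .data$band, .data$compartment,
                    .data$diameter_deg) |>
    dplyr::summarise(
      mean = mean(.data$value, na.rm = TRUE),
      sem = if (dplyr::n() > 1L) sd(.data$value, na.rm = TRUE) / sqrt(dplyr::n())
            else NA_real_,
      n_sessions = dplyr::n(), .groups = "drop")
}
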