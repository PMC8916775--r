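# Versioned on-disk session container: a directory with a JSON header,
# an Arrow/Feather sample table, an events CSV sidecar, and (optionally)
# the generator's ground truth.

CONTAINER_SCHEMA_VERSION <- "1.0"

#' Write a session recording to a directory container
#'
#' Layout: `meta.json` (schema version, rate, geometry), `samples.feather`
#' (one column per channel, top to bottom), `events.csv`, and when ground
#' truth is supplied `ground_truth.json` + `true_csd.tsv`.
#'
#' @param session a [session_recording()].
#' @param dir output directory (created if missing).
#' @param ground_truth optional `ground_truth` object from
#'   [generate_session()].
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir, ground_truth = NULL) {
  stopifnot(inherits(session, "session_recording"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) abort(sprintf("cannot create container directory %s", dir))
  meta <- list(schema_version = CONTAINER_SCHEMA_VERSION,
               fs_hz = session$fs_hz,
               spacing_um = session$spacing_um,
               n_channels = nrow(session$samples),
               n_samples = ncol(session$samples),
               channel_order = session$channel_order,
               units = "uV")
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE)
  df <- as.data.frame(t(session$samples))
  names(df) <- sprintf("ch%02d", seq_len(nrow(session$samples)))
  arrow::write_feather(df, file.path(dir, "samples.feather"))
  utils::write.csv(session$events, file.path(dir, "events.csv"),
                   row.names = FALSE)
  if (!is.null(ground_truth)) {
    gt <- ground_truth
    jsonlite::write_json(
      list(true_latency_ms = gt$true_latency_ms,
           coupling_adjacency = gt$coupling_adjacency,
           true_phase_lag_ms = gt$true_phase_lag_ms,
           mixing_weights = gt$mixing_weights,
           sink_channel = gt$sink_channel,
           sink_peak_ms = gt$sink_peak_ms,
           osc_channels = gt$osc_channels,
           gamma_by_diameter = gt$gamma_by_diameter,
           muae_calibration = gt$muae_calibration,
           csd_time_ms = gt$true_csd$time_ms,
           csd_scale_by_diameter = gt$true_csd$scale_by_diameter,
           seed = gt$seed),
      file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
    utils::write.table(gt$true_csd$template, file.path(dir, "true_csd.tsv"),
                       sep = "\t", row.names = FALSE, col.names = FALSE)
  }
  invisible(dir)
}

#' Read a session recording from a directory container
#'
#' @param dir container directory written by [write_session()].
#' @return list with `session` (a [session_recording()]) and `ground_truth`
#'   (list, or `NULL` when the container has none).
#' @export
read_session <- function(dir) {
  meta_path <- file.path(dir, "meta.json")
  if (!file.exists(meta_path)) abort(sprintf("%s is not a session container", dir))
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (!identical(meta$schema_version, CONTAINER_SCHEMA_VERSION)) {
    abort(sprintf("unsupported container schema version %s", meta$schema_version))
  }
  df <- arrow::read_feather(file.path(dir, "samples.feather"))
  events <- utils::read.csv(file.path(dir, "events.csv"))
  samples <- unname(t(as.matrix(df)))
  session <- session_recording(samples, meta$fs_hz,
                               as_tibble(events), meta$spacing_um)
  gt <- NULL
  gt_path <- file.path(dir, "ground_truth.json")
  if (file.exists(gt_path)) {
    gt <- jsonlite::read_json(gt_path, simplifyVector = TRUE)
    gt$true_latency_ms <- as_tibble(gt$true_latency_ms)
    gt$coupling_adjacency <- as_tibble(gt$coupling_adjacency)
    csd_path <- file.path(dir, "true_csd.tsv")
    if (file.exists(csd_path)) {
      gt$true_csd <- list(
        template = as.matrix(utils::read.table(csd_path, sep = "\t")),
        time_ms = gt$csd_time_ms,
        scale_by_diameter = gt$csd_scale_by_diameter)
    }
  }
  list(session = session, ground_truth = gt)
}
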