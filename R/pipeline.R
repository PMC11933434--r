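#' Long-format synchrony profile table for a cohort
#'
#' Converts recordings to acceleration-norm series at the analysis rate and
#' computes, per performance, the performer-audience (or audience-audience)
#' per-scale coherence profiles, stacked into one long table.
#'
#' @param recordings named list of \code{\link{accel_recording}} (one per
#'   subject x performance, as produced by \code{\link{gen_cohort}}).
#' @param design performance design table.
#' @param channel \code{"pa"} (performer-audience) or \code{"aa"}
#'   (audience-audience).
#' @param cfg a \code{\link{wtc_config}}.
#' @param analysis_fs analysis rate; recordings are anti-alias resampled to
#'   this rate first (no-op when already there).
#' @return Data frame with columns \code{subject_id, piece, mode, period_s,
#'   mean_r2, sd_r2, n_times_used}.
#' @export
profiles_table <- function(recordings, design, channel = c("pa", "aa"),
                           cfg = wtc_config(), analysis_fs = 50) {
  channel <- match.arg(channel)
  perf <- unique(design[, c("piece", "mode")])
  out <- list()
  for (k in seq_len(nrow(perf))) {
    piece <- perf$piece[k]; mode <- perf$mode[k]
    keys <- names(recordings)[vapply(recordings, function(r) {
      identical(as.character(r$piece), as.character(piece)) &&
        identical(as.character(r$mode), as.character(mode))
    }, logical(1))]
    recs <- recordings[keys]
    roles <- vapply(recs, function(r) r$role, character(1))
    to_series <- function(r) resample_to(accel_norm(r), analysis_fs)
    aud <- lapply(recs[roles == "audience"], to_series)
    prof <- if (channel == "pa") {
      per <- lapply(recs[roles == "performer"], to_series)
      pa_profiles(per, aud, cfg)
    } else {
      aa_profiles(aud, cfg)
    }
    for (sid in names(prof)) {
      p <- prof[[sid]]
      p$subject_id <- sid
      p$piece <- piece
      p$mode <- mode
      out[[length(out) + 1L]] <- p
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[, c("subject_id", "piece", "mode", "period_s", "mean_r2", "sd_r2",
          "n_times_used")]
}

#' Full band analysis of a profile table
#'
#' Runs the scale-wise mode contrasts on the time-mean and temporal-SD
#' coherence, extracts the beat-sync / music-sync / variability bands at the
#' given FDR, and computes the band-averaged measures per subject and
#' performance.
#'
#' @param profiles output of \code{\link{profiles_table}}.
#' @param design performance design table.
#' @param q false-discovery rate.
#' @param method contrast engine passed to \code{\link{per_scale_contrast}}.
#' @param channel label stored in the band definition.
#' @param mode_levels the two mode labels (contrast: second minus first).
#' @return List: \code{stats_mean}, \code{stats_sd}, \code{bands},
#'   \code{measures}.
#' @export
band_analysis <- function(profiles, design, q = 0.05, method = "auto",
                          channel = "P-A",
                          mode_levels = c("Strict", "Let-go")) {
  stats_mean <- per_scale_contrast(profiles, design, dv = "mean", q = q,
                                   method = method, mode_levels = mode_levels)
  stats_sd <- per_scale_contrast(profiles, design, dv = "sd", q = q,
                                 method = method, mode_levels = mode_levels)
  bands <- extract_bands(stats_mean, stats_sd, q = q, channel = channel)
  measures <- suppressWarnings(band_measures(profiles, bands))
  list(stats_mean = stats_mean, stats_sd = stats_sd, bands = bands,
       measures = measures)
}

#' Breathing summaries for every performance of a cohort
#'
#' @param recordings named list of recordings.
#' @param design performance design table.
#' @param ... passed to \code{\link{breath_summary}}.
#' @return Stacked data frame \code{subject_id, piece, mode, mean_plv,
#'   entropy_rate} over all performances (audience members only).
#' @export
cohort_breath_summary <- function(recordings, design, ...) {
  perf <- unique(design[, c("piece", "mode")])
  out <- list()
  for (k in seq_len(nrow(perf))) {
    recs <- recordings[vapply(recordings, function(r) {
      r$role == "audience" &&
        identical(as.character(r$piece), as.character(perf$piece[k])) &&
        identical(as.character(r$mode), as.character(perf$mode[k]))
    }, logical(1))]
    out[[k]] <- breath_summary(recs, ...)
  }
  do.call(rbind, out)
}
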