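# Apply the notch filter to every recording, collapsing the repeated
# Nyquist-degeneracy warning (one per recording otherwise) to one.
filter_session <- function(session, notch_hz, q = 30) {
  msgs <- character(0)
  out <- withCallingHandlers(
    lapply(session, function(rec) {
      rec$samples <- notch_filter(rec$samples, rec$fs_hz, notch_hz, q = q)
      rec
    }),
    warning = function(w) {
      msgs <<- unique(c(msgs, conditionMessage(w)))
      invokeRestart("muffleWarning")
    })
  for (m in msgs) warning(m, call. = FALSE)
  out
}

#' Run the full pipeline on a session of recordings
#'
#' Optionally contaminates the raw recordings with white Gaussian noise,
#' notch-filters each recording, concatenates repetitions per class,
#' segments into sliding windows, extracts features and cross-validates a
#' classifier. This is the single-call counterpart of the composed
#' module functions.
#'
#' @param session List of `rsc_recording` objects.
#' @param ids Feature ids to use (default RMS + WL, the compact optimal
#'   set for KNN).
#' @param spec Classifier specification (default KNN, K = 3).
#' @param window_ms,increment_ms Sliding-window parameters (default
#'   300 / 100 ms).
#' @param notch_hz Power-line notch frequency; `NA` disables filtering.
#' @param n_folds CV folds (default 4).
#' @param straddle Allow windows to straddle repetition boundaries.
#' @param noise_ratio_pct White-noise contamination of the raw signals,
#'   in percent of per-channel RMS (0 = clean).
#' @param noise_seed Seed for the contamination draw. The noise amplitude
#'   is `noise_ratio_pct`% of each channel's RMS over the whole session
#'   (one fixed noise floor, as circuit noise has), not per recording.
#' @return An `rsc_eval` report.
#' @export
#' @examples
#' session <- simulate_session(session_config(n_repetitions = 4, seed = 1))
#' report <- suppressWarnings(
#'   evaluate_session(session, ids = c("RMS", "WL")))
evaluate_session <- function(session, ids = c("RMS", "WL"),
                             spec = classifier_spec("KNN"),
                             window_ms = 300, increment_ms = 100,
                             notch_hz = 50, n_folds = 4, straddle = TRUE,
                             noise_ratio_pct = 0, noise_seed = 1) {
  if (noise_ratio_pct > 0)
    session <- contaminate_session(session, noise_ratio_pct, noise_seed)
  if (!is.na(notch_hz)) session <- filter_session(session, notch_hz)
  concat <- concatenate_recordings(session)
  ds <- segment_windows(concat, window_ms, increment_ms,
                        straddle = straddle)
  cross_validate(ds, ids, spec, n_folds)
}

# Sensor/circuit noise has one fixed amplitude across the whole session,
# so the ratio references the per-channel RMS over all recordings stacked;
# a per-recording RMS reference would give each motion class its own noise
# floor and leak class identity into otherwise silent windows.
contaminate_session <- function(session, ratio_pct, seed) {
  lens <- vapply(session, function(r) nrow(r$samples), integer(1))
  stacked <- do.call(rbind, lapply(session, function(r) r$samples))
  noisy <- add_white_noise(stacked, ratio_pct, seed = seed)
  offsets <- cumsum(c(0L, lens[-length(lens)]))
  lapply(seq_along(session), function(i) {
    rec <- session[[i]]
    rec$samples <- noisy[offsets[i] + seq_len(lens[i]), , drop = FALSE]
    rec
  })
}

#' Window-length sweep
#'
#' Re-runs segmentation and cross-validation for each analysis window
#' length at a fixed increment, to map the accuracy/latency trade-off
#' (accuracy typically rises steeply from 100 to 300 ms windows).
#'
#' @param session List of `rsc_recording` objects.
#' @param lengths_ms Window lengths to evaluate (duplicates are dropped
#'   with a warning).
#' @param spec Classifier specification.
#' @param ids Feature ids.
#' @param increment_ms Fixed window increment (default 100 ms).
#' @param notch_hz,n_folds,straddle As in [evaluate_session()].
#' @return `data.frame` with columns `window_ms`, `ca_pct`, `ca_sd_pct`.
#' @export
window_sweep <- function(session, lengths_ms, spec = classifier_spec("KNN"),
                         ids = c("RMS", "WL"), increment_ms = 100,
                         notch_hz = 50, n_folds = 4, straddle = TRUE) {
  if (anyDuplicated(lengths_ms)) {
    warning("duplicated window lengths dropped", call. = FALSE)
    lengths_ms <- unique(lengths_ms)
  }
  if (!is.na(notch_hz)) {
    session <- filter_session(session, notch_hz)
    notch_hz <- NA
  }
  rows <- lapply(lengths_ms, function(w) {
    rep <- evaluate_session(session, ids = ids, spec = spec, window_ms = w,
                            increment_ms = min(increment_ms, w),
                            notch_hz = notch_hz, n_folds = n_folds,
                            straddle = straddle)
    data.frame(window_ms = w, ca_pct = rep$ca_pct,
               ca_sd_pct = rep$ca_sd_pct)
  })
  do.call(rbind, rows)
}

#' White-noise robustness sweep
#'
#' Adds white Gaussian noise to the raw recordings (before filtering and
#' segmentation) at each ratio and re-runs the full pipeline, repeating
#' over noise seeds; reports mean and sd of accuracy per ratio. The
#' ratio-0 rows reproduce the clean-pipeline accuracy exactly.
#'
#' @param session List of `rsc_recording` objects.
#' @param ratios_pct Noise ratios in percent of per-channel signal RMS.
#' @param spec Classifier specification.
#' @param ids Feature ids.
#' @param seeds Integer noise seeds (one pipeline run per seed per ratio).
#' @param window_ms,increment_ms,notch_hz,n_folds,straddle As in
#'   [evaluate_session()].
#' @return `data.frame` with columns `ratio_pct`, `ca_mean_pct`,
#'   `ca_sd_pct` (sd across seeds).
#' @export
noise_sweep <- function(session, ratios_pct = c(0, 20, 40, 60, 80, 100),
                        spec = classifier_spec("KNN"),
                        ids = c("RMS", "WL"), seeds = 1:5,
                        window_ms = 300, increment_ms = 100, notch_hz = 50,
                        n_folds = 4, straddle = TRUE) {
  if (any(ratios_pct < 0)) stop("`ratios_pct` must be >= 0", call. = FALSE)
  rows <- lapply(ratios_pct, function(r) {
    cas <- vapply(seeds, function(s) {
      evaluate_session(session, ids = ids, spec = spec,
                       window_ms = window_ms, increment_ms = increment_ms,
                       notch_hz = notch_hz, n_folds = n_folds,
                       straddle = straddle, noise_ratio_pct = r,
                       noise_seed = s)$ca_pct
    }, numeric(1))
    data.frame(ratio_pct = r, ca_mean_pct = mean(cas),
               ca_sd_pct = if (length(cas) > 1) sd(cas) else 0)
  })
  do.call(rbind, rows)
}
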