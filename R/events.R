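#' Event-related response of one event, per channel
#'
#' The hemodynamic response to a sequence event is the mean over
#' `[onset + 10 s, offset)` (10 s lets the response reach its peak) minus
#' the mean over the 5-s baseline `[onset - 5 s, onset)`, computed per
#' channel separately for HbO and HbR.
#'
#' @param hb an `hb_series` (with `fs`).
#' @param onset,duration event timing (s).
#' @return List with numeric vectors `hbo_mean` and `hbr_mean` (µM, one
#'   entry per channel).
#' @export
epoch_response <- function(hb, onset, duration) {
  fs <- hb$fs
  if (duration <= 10)
    stop("event shorter than 10 s cannot be epoched (decoy?)")
  n <- nrow(hb$hbo)
  win <- (round((onset + 10) * fs) + 1L):round((onset + duration) * fs)
  base <- (round((onset - 5) * fs) + 1L):round(onset * fs)
  if (base[1] < 1L || max(win) > n)
    stop("event window extends outside the recording")
  list(hbo_mean = colMeans(hb$hbo[win, , drop = FALSE]) -
         colMeans(hb$hbo[base, , drop = FALSE]),
       hbr_mean = colMeans(hb$hbr[win, , drop = FALSE]) -
         colMeans(hb$hbr[base, , drop = FALSE]))
}

#' Cerebral oxygen exchange
#'
#' `HbDiff = HbO - HbR`, the study's primary outcome: oxygenated blood
#' entering minus deoxygenated blood leaving a region.
#'
#' @param hbo_mean,hbr_mean window-mean concentration changes (µM).
#' @return `hbo_mean - hbr_mean`.
#' @export
hbdiff <- function(hbo_mean, hbr_mean) {
  stopifnot(all(is.finite(hbo_mean)), all(is.finite(hbr_mean)))
  hbo_mean - hbr_mean
}

#' Epoch all analysable events of a recording
#'
#' Applies [epoch_response()] to every low-context, non-practice event;
#' decoys (high-context, shorter than the 10-s response window) and
#' practice events are excluded and logged in the `excluded` attribute.
#'
#' @param hb an `hb_series` from [run_pipeline()].
#' @param events an [event_list()].
#' @return Data frame, one row per event x channel, with `event`,
#'   `condition`, `channel`, `hbo_mean`, `hbr_mean`, `hbdiff`.
#' @export
epoch_events <- function(hb, events) {
  test <- events[!events$practice, , drop = FALSE]
  keep <- test$context == "low" & test$duration > 10
  excluded <- which(!keep)
  rows <- lapply(which(keep), function(i) {
    r <- epoch_response(hb, test$onset[i], test$duration[i])
    data.frame(event = i, condition = test$condition[i],
               channel = seq_along(r$hbo_mean),
               hbo_mean = r$hbo_mean, hbr_mean = r$hbr_mean,
               hbdiff = hbdiff(r$hbo_mean, r$hbr_mean))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}

#' Aggregate channel responses into prefrontal subregions
#'
#' Each subregion (left lateral, lower medial, right lateral) is the mean
#' of its two channels; if one channel was rejected by QC the surviving
#' channel stands alone, and if both were rejected the row is retained
#' with a missing value (the multilevel models tolerate missingness).
#'
#' @param responses output of [epoch_events()].
#' @param montage a [probe_montage()].
#' @param qc a `qc_report` from [reject_channels()] (or `NULL` for no
#'   rejection).
#' @return Data frame, one row per event x subregion: `event`, `condition`,
#'   `subregion`, `hbo_mean`, `hbr_mean`, `hbdiff`, `n_valid_channels`.
#' @export
aggregate_subregions <- function(responses, montage, qc = NULL) {
  ch <- montage$channels
  rejected <- if (is.null(qc)) rep(FALSE, nrow(ch)) else qc$rejected
  rows <- list()
  for (ev in unique(responses$event)) {
    sub <- responses[responses$event == ev, , drop = FALSE]
    for (s in SUBREGIONS) {
      members <- ch$channel[ch$subregion == s]
      ok <- members[!rejected[match(members, ch$channel)]]
      vals <- sub[match(ok, sub$channel), , drop = FALSE]
      rows[[length(rows) + 1L]] <- data.frame(
        event = ev, condition = sub$condition[1], subregion = s,
        hbo_mean = if (length(ok)) mean(vals$hbo_mean) else NA_real_,
        hbr_mean = if (length(ok)) mean(vals$hbr_mean) else NA_real_,
        hbdiff = if (length(ok)) mean(vals$hbdiff) else NA_real_,
        n_valid_channels = length(ok))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Participant-level condition averages
#'
#' Mean HbDiff per condition x subregion across all low-context trials.
#'
#' @param trials subregion-level trial data (from [aggregate_subregions()]
#'   or [build_trial_table()]), with columns `condition`, `subregion`,
#'   `hbdiff` and optionally `participant`.
#' @return Data frame of means (NA rows dropped).
#' @export
condition_average <- function(trials) {
  by_cols <- intersect(c("participant", "condition", "subregion"),
                       names(trials))
  ok <- !is.na(trials$hbdiff)
  agg <- aggregate(trials$hbdiff[ok],
                   by = trials[ok, by_cols, drop = FALSE],
                   FUN = mean)
  names(agg)[ncol(agg)] <- "hbdiff"
  agg
}

#' Assemble the long-format analysis table for one session
#'
#' Runs epoching and subregion aggregation on pipeline output and joins
#' the behavioural record of each low-context event, yielding the
#' trial x subregion table the multilevel models consume.
#'
#' @param hb,qc output of [run_pipeline()].
#' @param rec the [raw_recording()] (events + metadata).
#' @param behaviour output of [simulate_behaviour()] or a behavioural table
#'   with columns `event`, `correct`, `effort` aligned to non-practice
#'   events.
#' @return Data frame with columns `participant`, `condition`, `subregion`,
#'   `event`, `hbdiff`, `effort`, `correct`, `handedness`.
#' @export
build_trial_table <- function(hb, qc, rec, behaviour = NULL) {
  resp <- epoch_events(hb, rec$events)
  agg <- aggregate_subregions(resp, rec$montage, qc)
  out <- data.frame(participant = rec$meta$participant,
                    condition = agg$condition,
                    subregion = agg$subregion,
                    event = agg$event,
                    hbdiff = agg$hbdiff,
                    n_valid_channels = agg$n_valid_channels,
                    handedness = rec$meta$handedness,
                    stringsAsFactors = FALSE)
  if (!is.null(behaviour)) {
    i <- match(out$event, behaviour$event)
    out$effort <- behaviour$effort[i]
    out$correct <- behaviour$correct[i]
  }
  out
}

#' Normalized subregion time series for plotting
#'
#' Z-scores each channel's HbDiff series and averages within subregion;
#' display-only companion to the statistics (which always use the raw
#' window measures).
#'
#' @param hb an `hb_series` from [run_pipeline()].
#' @param montage a [probe_montage()].
#' @return Matrix time x subregion.
#' @export
normalized_timeseries <- function(hb, montage) {
  d <- hb$hbo - hb$hbr
  z <- scale(d)
  ch <- montage$channels
  out <- sapply(SUBREGIONS, function(s)
    rowMeans(z[, ch$subregion == s & !ch$is_short, drop = FALSE]))
  colnames(out) <- SUBREGIONS
  out
}
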