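#' Construct an event list
#'
#' One row per sequence event. Times are seconds from recording start;
#' events occupy the half-open interval `[onset, onset + duration)`.
#'
#' @param onset,duration numeric vectors (s).
#' @param condition `"standard"` or `"dnn"` hearing-aid program per event.
#' @param context `"low"` (analysed sequences) or `"high"` (decoys).
#' @param n_sentences integer 1..5, sentences in the sequence.
#' @param block integer block label (0 = practice).
#' @param practice logical, practice-block flag.
#' @return A data frame of class `event_list`, time-ordered.
#' @export
event_list <- function(onset, duration, condition, context, n_sentences,
                       block, practice) {
  ev <- data.frame(onset = as.numeric(onset),
                   duration = as.numeric(duration),
                   condition = as.character(condition),
                   context = as.character(context),
                   n_sentences = as.integer(n_sentences),
                   block = as.integer(block),
                   practice = as.logical(practice),
                   stringsAsFactors = FALSE)
  ev <- ev[order(ev$onset), , drop = FALSE]
  rownames(ev) <- NULL
  class(ev) <- c("event_list", "data.frame")
  validate_events(ev)
  ev
}

validate_events <- function(ev, baseline_s = 30, baseline_tol = 1) {
  if (nrow(ev) == 0L) return(invisible(ev))
  if (!all(ev$condition %in% CONDITIONS))
    stop("event condition must be one of: ", paste(CONDITIONS, collapse = ", "))
  if (!all(ev$context %in% c("low", "high")))
    stop("event context must be 'low' or 'high'")
  if (!all(ev$n_sentences %in% 1:5))
    stop("n_sentences must lie in 1..5")
  low <- ev$context == "low"
  if (any(ev$n_sentences[low] < 3))
    stop("low-context sequences must contain at least 3 sentences")
  if (any(ev$duration[low] < 18))
    stop("low-context sequences must last at least 18 s")
  off <- ev$onset + ev$duration
  if (nrow(ev) > 1L) {
    gap <- ev$onset[-1L] - off[-nrow(ev)]
    if (any(gap < 0)) stop("events overlap")
    if (any(gap < baseline_s - baseline_tol))
      stop("inter-event baseline gaps must be at least ",
           baseline_s - baseline_tol, " s")
  }
  invisible(ev)
}

#' Construct a raw dual-wavelength recording
#'
#' @param intensity numeric array, time x channel x wavelength, strictly
#'   positive device units. The wavelength dimension follows
#'   `montage$wavelengths` order (760 then 850 nm).
#' @param fs sampling rate in Hz (the device samples at 10 Hz).
#' @param events an [event_list()].
#' @param montage a [probe_montage()].
#' @param meta list with at least `participant` (character id) and
#'   `handedness` (`"left"` or `"right"`).
#' @return An object of class `raw_recording`.
#' @export
raw_recording <- function(intensity, fs, events, montage = default_montage(),
                          meta = list(participant = "sim01",
                                      handedness = "right")) {
  intensity <- as.array(intensity)
  stopifnot(length(dim(intensity)) == 3L)
  rec <- structure(
    list(intensity = intensity, fs = as.numeric(fs),
         events = events, montage = montage, meta = meta),
    class = "raw_recording")
  validate_recording(rec)
  rec
}

validate_recording <- function(rec) {
  if (rec$fs <= 0) stop("sampling rate must be positive")
  d <- dim(rec$intensity)
  n_ch <- nrow(rec$montage$channels)
  if (d[2] != n_ch)
    stop("intensity has ", d[2], " channels but montage defines ", n_ch)
  if (d[3] != 2L) stop("intensity must carry both wavelengths")
  if (!all(is.finite(rec$intensity)))
    stop("intensity contains non-finite samples")
  if (any(rec$intensity <= 0))
    stop("intensity must be strictly positive everywhere")
  if (nrow(rec$events) > 0L) {
    t_end <- d[1] / rec$fs
    if (any(rec$events$onset - 5 < 0) ||
        any(rec$events$onset + rec$events$duration > t_end))
      stop("all event windows (including the 5-s baseline) must lie within ",
           "the recording")
  }
  if (!rec$meta$handedness %in% c("left", "right"))
    stop("meta$handedness must be 'left' or 'right'")
  invisible(rec)
}

#' @export
print.raw_recording <- function(x, ...) {
  d <- dim(x$intensity)
  cat(sprintf(
    "Raw fNIRS recording '%s': %d samples (%.1f s at %g Hz), %d channels x 2 wavelengths, %d events\n",
    x$meta$participant, d[1], d[1] / x$fs, x$fs, d[2], nrow(x$events)))
  invisible(x)
}

# ---- SNIRF-style HDF5 container -------------------------------------------

#' Write a recording to a SNIRF-style HDF5 file
#'
#' Layout follows the SNIRF convention with one data block per wavelength
#' (`/nirs/data1` = 760 nm, `/nirs/data2` = 850 nm), a probe group with 2-D
#' optode positions, a stimulus table and metadata tags. Stimulus rows carry
#' the full event annotation (condition, context, n_sentences, block,
#' practice) beyond the canonical onset/duration columns.
#'
#' @param rec a [raw_recording()].
#' @param path output file path (overwritten if present).
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  validate_recording(rec)
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("directory does not exist: ", dir)
  if (file.exists(path)) file.remove(path)
  rhdf5::h5createFile(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  rhdf5::h5write("1.0", path, "formatVersion")
  rhdf5::h5createGroup(path, "nirs")
  n <- dim(rec$intensity)[1]
  tvec <- (seq_len(n) - 1L) / rec$fs
  for (w in 1:2) {
    g <- sprintf("nirs/data%d", w)
    rhdf5::h5createGroup(path, g)
    rhdf5::h5write(rec$intensity[, , w], path, file.path(g, "dataTimeSeries"))
    rhdf5::h5write(tvec, path, file.path(g, "time"))
    rhdf5::h5write(as.numeric(w), path, file.path(g, "wavelengthIndex"))
  }
  rhdf5::h5createGroup(path, "nirs/probe")
  rhdf5::h5write(rec$montage$emitters, path, "nirs/probe/sourcePos2D")
  rhdf5::h5write(rec$montage$detectors, path, "nirs/probe/detectorPos2D")
  rhdf5::h5write(rec$montage$wavelengths, path, "nirs/probe/wavelengths")
  ch <- rec$montage$channels
  ch$is_short <- as.integer(ch$is_short)
  rhdf5::h5write(ch, path, "nirs/probe/measurementList")
  ev <- as.data.frame(rec$events)
  ev$practice <- as.integer(ev$practice)
  if (nrow(ev) > 0L) {
    rhdf5::h5write(ev, path, "nirs/stim1")
  } else {
    rhdf5::h5write(0L, path, "nirs/stim1Empty")  # HDF5 compound needs >= 1 row
  }
  rhdf5::h5createGroup(path, "nirs/metaDataTags")
  rhdf5::h5write(rec$meta$participant, path, "nirs/metaDataTags/SubjectID")
  rhdf5::h5write(rec$meta$handedness, path, "nirs/metaDataTags/Handedness")
  rhdf5::h5write(rec$fs, path, "nirs/metaDataTags/SamplingRate")
  invisible(path)
}

#' Read a recording from a SNIRF-style HDF5 file
#'
#' Inverse of [write_recording()]. Channels are returned in the canonical
#' order stored in the probe measurement list (left to right, long before
#' short).
#'
#' @param path file written by [write_recording()].
#' @return A validated [raw_recording()].
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  contents <- rhdf5::h5ls(path)
  full <- sub("^//", "/", paste(contents$group, contents$name, sep = "/"))
  need <- c("/nirs/data1/dataTimeSeries", "/nirs/data2/dataTimeSeries")
  for (grp in need)
    if (!grp %in% full)
      stop("malformed container: missing wavelength data block '", grp, "'")
  has_stim <- "/nirs/stim1" %in% full
  if (!has_stim && !"/nirs/stim1Empty" %in% full)
    stop("malformed container: missing stimulus table '/nirs/stim1'")
  i1 <- as.matrix(rhdf5::h5read(path, "nirs/data1/dataTimeSeries"))
  i2 <- as.matrix(rhdf5::h5read(path, "nirs/data2/dataTimeSeries"))
  if (!all(dim(i1) == dim(i2)))
    stop("malformed container: wavelength blocks disagree in shape")
  intensity <- array(c(i1, i2), dim = c(dim(i1), 2))
  if (any(intensity <= 0))
    stop("malformed container: non-positive intensity samples in ",
         "'/nirs/data'")
  em <- as.matrix(rhdf5::h5read(path, "nirs/probe/sourcePos2D"))
  de <- as.matrix(rhdf5::h5read(path, "nirs/probe/detectorPos2D"))
  wl <- as.numeric(rhdf5::h5read(path, "nirs/probe/wavelengths"))
  chd <- as.data.frame(rhdf5::h5read(path, "nirs/probe/measurementList"))
  chd[] <- lapply(chd, as.vector)
  chd$is_short <- as.logical(chd$is_short)
  montage <- probe_montage(em, de, chd, wl)
  if (has_stim) {
    evd <- as.data.frame(rhdf5::h5read(path, "nirs/stim1"))
    evd[] <- lapply(evd, as.vector)
    ev <- event_list(evd$onset, evd$duration, evd$condition, evd$context,
                     evd$n_sentences, evd$block, as.logical(evd$practice))
  } else {
    ev <- event_list(numeric(0), numeric(0), character(0), character(0),
                     integer(0), integer(0), logical(0))
  }
  meta <- list(
    participant = as.character(rhdf5::h5read(path, "nirs/metaDataTags/SubjectID")),
    handedness = as.character(rhdf5::h5read(path, "nirs/metaDataTags/Handedness")))
  fs <- as.numeric(rhdf5::h5read(path, "nirs/metaDataTags/SamplingRate"))
  raw_recording(intensity, fs, ev, montage, meta)
}
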