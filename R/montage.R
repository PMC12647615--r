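#' Construct a prefrontal probe montage
#'
#' A montage describes the optode geometry of the 8-emitter / 2-detector
#' prefrontal headband: six long measurement channels (two per subregion:
#' left lateral, lower medial, right lateral) and two short-separation
#' channels that sample extracerebral tissue only. Every channel is measured
#' at both wavelengths (760 and 850 nm).
#'
#' @param emitters numeric matrix (8 x 2), emitter positions in cm on the
#'   scalp plane.
#' @param detectors numeric matrix (2 x 2), detector positions in cm.
#' @param channels data frame with columns `channel`, `emitter`, `detector`,
#'   `is_short` (logical) and `subregion` (one of `"left_lateral"`,
#'   `"lower_medial"`, `"right_lateral"`, `"short"`).
#' @param wavelengths numeric length-2 vector of wavelengths in nm.
#'
#' @return An object of class `probe_montage`.
#' @seealso [default_montage()], [nearest_short_channel()]
#' @export
probe_montage <- function(emitters, detectors, channels,
                          wavelengths = WAVELENGTHS) {
  emitters <- as.matrix(emitters)
  detectors <- as.matrix(detectors)
  stopifnot(is.data.frame(channels),
            all(c("channel", "emitter", "detector", "is_short", "subregion")
                %in% names(channels)))
  m <- structure(
    list(emitters = emitters, detectors = detectors,
         channels = channels, wavelengths = as.numeric(wavelengths)),
    class = "probe_montage")
  validate_montage(m)
  m
}

validate_montage <- function(m) {
  ch <- m$channels
  n_long <- sum(!ch$is_short)
  n_short <- sum(ch$is_short)
  if (n_long != 6L)
    stop("montage must contain exactly 6 long measurement channels, found ",
         n_long)
  if (n_short != 2L)
    stop("montage must contain exactly 2 short-separation channels, found ",
         n_short)
  for (s in SUBREGIONS) {
    n <- sum(ch$subregion == s & !ch$is_short)
    if (n != 2L)
      stop("subregion '", s, "' must contain exactly 2 channels, found ", n)
  }
  if (any(ch$subregion[ch$is_short] != "short"))
    stop("short channels must be assigned subregion 'short'")
  if (length(m$wavelengths) != 2L || any(is.na(m$wavelengths)))
    stop("montage needs exactly two wavelengths")
  sep <- channel_separation(m)
  if (any(sep[ch$is_short] >= min(sep[!ch$is_short])))
    stop("short-channel separation must be strictly smaller than every ",
         "long-channel separation")
  invisible(m)
}

#' Emitter-detector separation per channel (cm)
#' @param montage a `probe_montage`.
#' @return numeric vector, one separation per channel row.
#' @export
channel_separation <- function(montage) {
  ch <- montage$channels
  e <- montage$emitters[ch$emitter, , drop = FALSE]
  d <- montage$detectors[ch$detector, , drop = FALSE]
  sqrt(rowSums((e - d)^2))
}

#' Channel position: midpoint of emitter and detector (cm)
#' @inheritParams channel_separation
#' @return numeric matrix, one row per channel.
#' @export
channel_position <- function(montage) {
  ch <- montage$channels
  (montage$emitters[ch$emitter, , drop = FALSE] +
     montage$detectors[ch$detector, , drop = FALSE]) / 2
}

#' Default OctaMon-like prefrontal montage
#'
#' A 2-D scalp-plane layout consistent with the headband geometry: two
#' detectors left and right of the midline, six long channels at ~3.5 cm
#' separation (two per subregion) and one short-separation channel next to
#' each detector. Coordinates are package-invented approximations that
#' satisfy the geometric invariants; the device vendor publishes no
#' coordinate set.
#'
#' @param long_sep long-channel emitter-detector separation in cm.
#' @param short_sep short-channel separation in cm (must be < `long_sep`).
#' @return A `probe_montage`.
#' @export
default_montage <- function(long_sep = 3.5, short_sep = 1.0) {
  stopifnot(short_sep < long_sep)
  dL <- c(-3, 0); dR <- c(3, 0)
  ang <- pi * c(150, 210) / 180
  emitters <- rbind(
    dL + long_sep * c(cos(ang[1]), sin(ang[1])),  # E1 left lateral upper
    dL + long_sep * c(cos(ang[2]), sin(ang[2])),  # E2 left lateral lower
    dL + c(long_sep, 0),                          # E3 left medial
    dL + c(0, short_sep),                         # E4 left short
    dR + long_sep * c(cos(pi - ang[1]), sin(ang[1])),  # E5 right lateral upper
    dR + long_sep * c(cos(pi - ang[2]), sin(ang[2])),  # E6 right lateral lower
    dR + c(-long_sep, 0),                         # E7 right medial
    dR + c(0, short_sep)                          # E8 right short
  )
  detectors <- rbind(dL, dR)
  rownames(emitters) <- paste0("E", 1:8)
  rownames(detectors) <- c("D1", "D2")
  channels <- data.frame(
    channel = 1:8,
    emitter = c(1, 2, 3, 7, 5, 6, 4, 8),
    detector = c(1, 1, 1, 2, 2, 2, 1, 2),
    is_short = c(rep(FALSE, 6), TRUE, TRUE),
    subregion = c("left_lateral", "left_lateral",
                  "lower_medial", "lower_medial",
                  "right_lateral", "right_lateral",
                  "short", "short"),
    stringsAsFactors = FALSE
  )
  probe_montage(emitters, detectors, channels)
}

#' Nearest short-separation channel for a long channel
#'
#' Selects the short channel minimizing the Euclidean distance between
#' channel midpoints; ties break towards the lowest channel index. Used to
#' pair each long channel with its superficial-noise regressor.
#'
#' @param montage a `probe_montage`.
#' @param channel_id index (row of `montage$channels`) of a long channel.
#' @return The channel id of the nearest short channel.
#' @export
nearest_short_channel <- function(montage, channel_id) {
  ch <- montage$channels
  if (!channel_id %in% ch$channel)
    stop("unknown channel id: ", channel_id)
  row <- match(channel_id, ch$channel)
  if (ch$is_short[row])
    stop("channel ", channel_id, " is a short channel")
  shorts <- which(ch$is_short)
  if (length(shorts) == 0L) stop("montage contains no short channels")
  pos <- channel_position(montage)
  d <- sqrt(rowSums((pos[shorts, , drop = FALSE] -
                       matrix(pos[row, ], length(shorts), ncol(pos),
                              byrow = TRUE))^2))
  ch$channel[shorts[which.min(d)]]  # which.min takes the first (lowest) tie
}

#' @export
print.probe_montage <- function(x, ...) {
  sep <- channel_separation(x)
  cat("Prefrontal probe montage:",
      sum(!x$channels$is_short), "long +",
      sum(x$channels$is_short), "short channels,",
      paste(x$wavelengths, collapse = "/"), "nm\n")
  df <- cbind(x$channels, separation_cm = round(sep, 2))
  print(df, row.names = FALSE)
  invisible(x)
}
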