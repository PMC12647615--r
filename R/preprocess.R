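#' Remove step-like contact-loss artifacts
#'
#' Brief losses of contact between headband and skin produce abrupt steps
#' in the raw intensity. Per series the first difference is taken, samples
#' whose absolute derivative exceeds `mean(d) + k_sd * sd(d)` are zeroed,
#' and the series is rebuilt as the first sample plus the cumulative sum of
#' the modified derivative. A linear ramp (constant derivative) passes
#' unchanged; an isolated step is levelled so the post-step signal rejoins
#' the pre-step baseline.
#'
#' @param x numeric vector, matrix (time x channel) or array
#'   (time x channel x wavelength) of intensities.
#' @param k_sd threshold in derivative standard deviations (default 2).
#' @return Same shape as `x`.
#' @export
remove_step_noise <- function(x, k_sd = 2) {
  apply_columns(x, function(v) {
    if (length(v) < 3L) stop("series too short for step-noise removal")
    d <- diff(v)
    thr <- mean(d) + k_sd * sd(d)
    d[abs(d) > thr] <- 0
    c(v[1L], v[1L] + cumsum(d))
  })
}

#' Scalp coupling index of one channel
#'
#' Band-pass filters both wavelengths of a channel to the cardiac band and
#' correlates them. Good optode-skin contact lets the heartbeat register
#' identically at both wavelengths (correlation near 1); poor contact
#' decorrelates them.
#'
#' @param i760,i850 intensity vectors of the two wavelengths.
#' @param fs sampling rate (Hz).
#' @param band cardiac band in Hz.
#' @return Pearson correlation in `[-1, 1]`; 0 with a warning when either
#'   filtered series has zero variance.
#' @export
scalp_coupling_index <- function(i760, i850, fs, band = c(0.5, 1.5)) {
  stopifnot(length(i760) == length(i850))
  if (length(i760) < 10 * fs)
    stop("need at least 10 s of data for the scalp coupling index")
  f1 <- bandpass(i760, band[1], band[2], fs)
  f2 <- bandpass(i850, band[1], band[2], fs)
  if (sd(f1) == 0 || sd(f2) == 0) {
    warning("zero variance in cardiac band; SCI set to 0")
    return(0)
  }
  cor(f1, f2)
}

#' Reject channels with poor scalp coupling
#'
#' Scores every channel (short channels included) with the scalp coupling
#' index over the whole recording and flags channels with SCI below the
#' threshold as rejected.
#'
#' @param rec a [raw_recording()] (step-artifact removal is expected to
#'   have been applied to `rec$intensity` by the pipeline; the index is
#'   computed on whatever is passed).
#' @param threshold rejection threshold (default 0.75; rejection is
#'   `sci < threshold`).
#' @return A data frame of class `qc_report` with columns `channel`,
#'   `sci`, `rejected`, plus attributes `threshold` and `fraction_rejected`
#'   (over measurement channels).
#' @export
reject_channels <- function(rec, threshold = 0.75) {
  n_ch <- dim(rec$intensity)[2]
  sci <- vapply(seq_len(n_ch), function(j)
    scalp_coupling_index(rec$intensity[, j, 1], rec$intensity[, j, 2], rec$fs),
    numeric(1))
  rep_df <- data.frame(channel = rec$montage$channels$channel,
                       is_short = rec$montage$channels$is_short,
                       sci = sci,
                       rejected = sci < threshold)
  attr(rep_df, "threshold") <- threshold
  long <- !rep_df$is_short
  attr(rep_df, "fraction_rejected") <- mean(rep_df$rejected[long])
  class(rep_df) <- c("qc_report", "data.frame")
  rep_df
}

#' Convert intensity to optical density change
#'
#' `OD(t) = -ln(I(t) / mean(I))` per channel and wavelength, so the OD of
#' the reference (mean) intensity is 0 and scaling the intensity by any
#' positive constant leaves the result unchanged.
#'
#' @param intensity strictly positive vector/matrix/array.
#' @return Same shape, dimensionless optical density.
#' @export
intensity_to_od <- function(intensity) {
  if (any(intensity <= 0)) {
    if (is.null(dim(intensity))) stop("non-positive intensity samples")
    bad <- which(apply(intensity <= 0, 2, any))
    stop("non-positive intensity in channel(s): ",
         paste(unique(bad), collapse = ", "))
  }
  apply_columns(intensity, function(v) -log(v / mean(v)))
}

#' Convert optical density to hemoglobin concentration change
#'
#' Inverts the modified Beer-Lambert law per channel: the OD change at each
#' wavelength is the sum of HbO and HbR contributions weighted by their
#' extinction coefficients, the emitter-detector separation and the
#' differential pathlength factor. The 2x2 linear system across the two
#' wavelengths is solved for each sample.
#'
#' @param od array time x channel x wavelength (natural-log OD).
#' @param montage a [probe_montage()] supplying per-channel separations.
#' @param dpf differential pathlength factor (applied at both wavelengths).
#' @return An `hb_series`: list with `hbo`, `hbr` (time x channel matrices,
#'   concentration change in µM), `fs` absent (attach downstream), and the
#'   channel table.
#' @export
od_to_hemoglobin <- function(od, montage, dpf = DEFAULT_DPF) {
  stopifnot(length(dim(od)) == 3L)
  sep <- channel_separation(montage)
  E <- EXTINCTION * log(10)   # natural-log OD against decadic coefficients
  if (abs(det(E)) < 1e-8) stop("singular extinction matrix")
  Einv <- solve(E)
  n_ch <- dim(od)[2]
  hbo <- matrix(0, dim(od)[1], n_ch)
  hbr <- matrix(0, dim(od)[1], n_ch)
  for (j in seq_len(n_ch)) {
    # OD = E %*% c(hbo_mM, hbr_mM) * sep * dpf  (per wavelength)
    conc <- cbind(od[, j, 1], od[, j, 2]) %*% t(Einv) / (sep[j] * dpf)
    hbo[, j] <- conc[, 1] * 1000  # mM -> µM
    hbr[, j] <- conc[, 2] * 1000
  }
  structure(list(hbo = hbo, hbr = hbr, channels = montage$channels),
            class = "hb_series")
}

#' Zero-phase Butterworth band-pass filter
#'
#' 3rd-order Butterworth applied forward and backward (`filtfilt`), the
#' conventional zero-phase choice for CW-NIRS. DC is fully removed; gain at
#' the band centre stays within a few percent of unity.
#'
#' @param x vector/matrix/array over time.
#' @param lo_hz,hi_hz band edges, `0 < lo < hi < fs/2`.
#' @param fs sampling rate (Hz).
#' @param order filter order.
#' @return Filtered object, same shape.
#' @export
bandpass <- function(x, lo_hz, hi_hz, fs, order = 3) {
  if (!(lo_hz > 0 && hi_hz > lo_hz && hi_hz < fs / 2))
    stop("invalid band: need 0 < lo < hi < fs/2")
  bf <- signal::butter(order, c(lo_hz, hi_hz) / (fs / 2), type = "pass")
  apply_columns(x, function(v) {
    # demean and odd-reflect the ends before filtfilt: suppresses the
    # start-up transient the filter would otherwise ring off the DC level
    # and the edge discontinuity
    n <- length(v)
    m <- mean(v)
    v <- v - m
    pad <- min(n - 1L, ceiling(3 * fs / lo_hz))
    left <- 2 * v[1L] - v[seq(pad + 1L, 2L)]
    right <- 2 * v[n] - v[seq(n - 1L, n - pad)]
    f <- signal::filtfilt(bf, c(left, v, right))
    f[pad + seq_len(n)]
  })
}

#' Regress superficial signal out of a long channel
#'
#' Fits `long ~ short` by ordinary least squares and returns the residual
#' (intercept removed), leaving a series orthogonal to the short-separation
#' regressor. Applied separately to HbO and HbR by the pipeline.
#'
#' @param long_hb,short_hb numeric vectors of equal length.
#' @return Residual vector.
#' @export
short_separation_regress <- function(long_hb, short_hb) {
  stopifnot(length(long_hb) == length(short_hb))
  if (var(short_hb) == 0) return(long_hb - mean(long_hb))
  beta <- cov(long_hb, short_hb) / var(short_hb)
  res <- long_hb - beta * short_hb
  res - mean(res)
}

#' Default preprocessing parameters
#'
#' Every default is the analysis value used throughout: derivative
#' threshold 2 SD, SCI threshold 0.75, wavelet IQR factor 0.1, band-pass
#' 0.01-1.5 Hz before and 0.01-0.09 Hz after short-separation regression,
#' DPF 6.0.
#'
#' @param k_sd,sci_threshold,iqr_k,band1,band2,dpf stage parameters.
#' @param stages character vector naming the stage order; the order is part
#'   of the method and [run_pipeline()] refuses any permutation.
#' @return A list of class `pipeline_params`.
#' @export
pipeline_params <- function(k_sd = 2, sci_threshold = 0.75, iqr_k = 0.1,
                            band1 = c(0.01, 1.5), band2 = c(0.01, 0.09),
                            dpf = DEFAULT_DPF,
                            stages = PIPELINE_STAGES) {
  structure(list(k_sd = k_sd, sci_threshold = sci_threshold, iqr_k = iqr_k,
                 band1 = band1, band2 = band2, dpf = dpf, stages = stages),
            class = "pipeline_params")
}

PIPELINE_STAGES <- c("step_removal", "sci_rejection", "optical_density",
                     "wavelet_correction", "beer_lambert", "bandpass_wide",
                     "short_separation", "bandpass_narrow")

#' Run the full preprocessing pipeline
#'
#' Applies, in fixed order: step-artifact removal, SCI channel rejection,
#' optical-density conversion, wavelet motion correction, modified
#' Beer-Lambert conversion, 0.01-1.5 Hz band-pass, short-separation
#' regression (each long channel against its nearest surviving short
#' channel), and a final 0.01-0.09 Hz band-pass.
#'
#' @param rec a [raw_recording()].
#' @param params a [pipeline_params()].
#' @return List with `hb` (an `hb_series` with `hbo`/`hbr` time x channel
#'   matrices in µM, `fs`, and rejection mask) and `qc` (a `qc_report`
#'   augmented with a per-stage log).
#' @export
run_pipeline <- function(rec, params = pipeline_params()) {
  validate_recording(rec)
  if (!identical(params$stages, PIPELINE_STAGES))
    stop("the preprocessing stage order is fixed; refusing permuted stages")
  log <- character(0)
  note <- function(...) log <<- c(log, sprintf(...))

  intensity <- remove_step_noise(rec$intensity, params$k_sd)
  note("step_removal: k_sd = %g", params$k_sd)

  rec_clean <- rec; rec_clean$intensity <- pmax(intensity, .Machine$double.eps)
  qc <- reject_channels(rec_clean, params$sci_threshold)
  long_idx <- which(!qc$is_short)
  if (all(qc$rejected[long_idx]))
    stop("all measurement channels rejected (SCI < ", params$sci_threshold, ")")
  note("sci_rejection: %d of %d measurement channels rejected",
       sum(qc$rejected[long_idx]), length(long_idx))

  od <- intensity_to_od(rec_clean$intensity)
  note("optical_density")
  od <- wavelet_motion_correct(od, params$iqr_k)
  note("wavelet_correction: iqr_k = %g", params$iqr_k)
  hb <- od_to_hemoglobin(od, rec$montage, params$dpf)
  note("beer_lambert: dpf = %g", params$dpf)
  hb$hbo <- bandpass(hb$hbo, params$band1[1], params$band1[2], rec$fs)
  hb$hbr <- bandpass(hb$hbr, params$band1[1], params$band1[2], rec$fs)
  note("bandpass_wide: %g-%g Hz", params$band1[1], params$band1[2])

  shorts <- qc$channel[qc$is_short]
  shorts_ok <- qc$channel[qc$is_short & !qc$rejected]
  for (j in long_idx) {
    if (qc$rejected[j]) next
    ch_id <- qc$channel[j]
    s <- nearest_short_channel(rec$montage, ch_id)
    if (!(s %in% shorts_ok)) {
      alt <- setdiff(shorts_ok, s)
      if (length(alt) == 0L) {
        note("short_separation: channel %d left uncorrected (no surviving short channel)",
             ch_id)
        next
      }
      note("short_separation: channel %d fell back from rejected short %d to %d",
           ch_id, s, alt[1])
      s <- alt[1]
    }
    si <- match(s, qc$channel)
    hb$hbo[, j] <- short_separation_regress(hb$hbo[, j], hb$hbo[, si])
    hb$hbr[, j] <- short_separation_regress(hb$hbr[, j], hb$hbr[, si])
  }
  note("short_separation: nearest-short GLM regression applied")

  hb$hbo <- bandpass(hb$hbo, params$band2[1], params$band2[2], rec$fs)
  hb$hbr <- bandpass(hb$hbr, params$band2[1], params$band2[2], rec$fs)
  note("bandpass_narrow: %g-%g Hz", params$band2[1], params$band2[2])

  hb$fs <- rec$fs
  hb$rejected <- qc$rejected
  attr(qc, "stage_log") <- log
  list(hb = hb, qc = qc)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("Channel QC (SCI threshold %.2f): %.1f%% of measurement channels rejected\n",
              attr(x, "threshold"), 100 * attr(x, "fraction_rejected")))
  print(as.data.frame(x), row.names = FALSE)
  invisible(x)
}
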