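# Synthetic session generator: known-ground-truth raw recordings and
# behavioural records emulating the study's session structure (blocks of 8
# sequence events, 30-s baselines, practice + alternating test blocks) and
# the physiological noise the preprocessing pipeline is built to remove.

#' Evaluate code under a temporary RNG seed
#'
#' Sets the seed, runs the expression, and restores the caller's RNG state,
#' so generators are deterministic without clobbering the session RNG.
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  code
}

derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(k) * 104729) %% 2147483629L)
}

#' Hemodynamic ground truth for the generator
#'
#' @param hbdiff_amp 3 x 2 matrix of programmed event-related HbDiff
#'   amplitudes (µM) per subregion (rows: left lateral, lower medial,
#'   right lateral) and condition (columns: standard, dnn). The default
#'   places the whole condition contrast (+19 µM, standard minus dnn) in
#'   the left lateral subregion, at the absolute levels reported for that
#'   region (+4.2 / -14.8 µM).
#' @param hrf_peak,hrf_undershoot gamma shape parameters (s) of the
#'   canonical double-gamma hemodynamic response.
#' @param hrf_ratio undershoot-to-peak amplitude ratio.
#' @param hbr_scale,hbr_lag HbR response as a scaled (default -1/3),
#'   lagged (default 2 s) copy of the HbO shape.
#' @param superficial_gain per-long-channel weight of the shared
#'   superficial (scalp/systemic) component leaking into long channels.
#' @return A list of class `ground_truth`.
#' @export
ground_truth <- function(hbdiff_amp = default_hbdiff_amp(),
                         hrf_peak = 6, hrf_undershoot = 16, hrf_ratio = 1 / 6,
                         hbr_scale = -1 / 3, hbr_lag = 2,
                         superficial_gain = rep(0.5, 6)) {
  stopifnot(nrow(hbdiff_amp) == 3, ncol(hbdiff_amp) == 2,
            length(superficial_gain) == 6)
  structure(list(hbdiff_amp = hbdiff_amp,
                 hrf_peak = hrf_peak, hrf_undershoot = hrf_undershoot,
                 hrf_ratio = hrf_ratio, hbr_scale = hbr_scale,
                 hbr_lag = hbr_lag, superficial_gain = superficial_gain),
            class = "ground_truth")
}

#' @rdname ground_truth
#' @export
default_hbdiff_amp <- function() {
  matrix(c(4.2, -14.8,
           0, 0,
           0, 0),
         nrow = 3, byrow = TRUE,
         dimnames = list(SUBREGIONS, CONDITIONS))
}

#' Physiological and instrumental noise parameters
#'
#' Amplitudes are hemoglobin-equivalent (µM) for the oscillatory and drift
#' components, optical density units for instrument noise and artifacts.
#'
#' @param cardiac_hz,cardiac_amp heartbeat frequency (within the 0.5-1.5 Hz
#'   coupling-index band) and HbO amplitude.
#' @param cardiac_scale per-channel multiplier on the cardiac component
#'   (set an entry to 0 to emulate a decoupled optode).
#' @param resp_hz,resp_amp respiration component.
#' @param mayer_hz,mayer_amp Mayer-wave component.
#' @param drift_rw_sd random-walk drift increment SD (µM per sample).
#' @param drift_lin_amp peak linear drift over the session (µM).
#' @param white_od_sd white instrument noise SD (OD units).
#' @param n_steps,step_od_sd scheduled contact-loss step artifacts: count
#'   per session and magnitude SD (OD).
#' @param n_spikes,spike_od motion-spike artifacts: count and magnitude (OD).
#' @return A list of class `noise_params`.
#' @export
noise_params <- function(cardiac_hz = 1.1, cardiac_amp = 3.0,
                         cardiac_scale = rep(1, 8),
                         resp_hz = 0.25, resp_amp = 0.5,
                         mayer_hz = 0.1, mayer_amp = 1.5,
                         drift_rw_sd = 0.03, drift_lin_amp = 3,
                         white_od_sd = 1e-3,
                         n_steps = 2, step_od_sd = 0.05,
                         n_spikes = 3, spike_od = 0.15) {
  stopifnot(cardiac_hz >= 0.5, cardiac_hz <= 1.5,
            all(c(cardiac_amp, resp_amp, mayer_amp, drift_rw_sd,
                  white_od_sd, spike_od) >= 0))
  structure(as.list(environment()), class = "noise_params")
}

#' Zero-noise parameter set
#' @return `noise_params` with every amplitude and artifact count at zero.
#' @export
noise_off <- function() {
  noise_params(cardiac_amp = 0, resp_amp = 0, mayer_amp = 0,
               drift_rw_sd = 0, drift_lin_amp = 0, white_od_sd = 0,
               n_steps = 0, n_spikes = 0, spike_od = 0)
}

#' Generate a session event design
#'
#' One practice block (standard program) followed by `n_blocks` test blocks
#' split evenly between conditions in randomized order. Each block holds 8
#' sequence events in randomized order: 6 low-context sequences of 3-5
#' sentences (18-30 s) and 2 short high-context decoys of 1-2 sentences,
#' separated by 30-s silent baselines.
#'
#' @param n_blocks number of test blocks (the study used 4).
#' @param seed integer seed; the same seed reproduces the design exactly.
#' @param baseline_s inter-event baseline duration (s).
#' @param lead_in_s quiet time before the first event (s).
#' @return An [event_list()].
#' @export
make_session_design <- function(n_blocks = 4, seed = 1, baseline_s = 30,
                                lead_in_s = 40) {
  stopifnot(n_blocks >= 1)
  with_seed(derive_seed(seed, 1), {
    conds <- rep(CONDITIONS, length.out = n_blocks)
    conds <- sample(conds)
    blocks <- c("practice", conds)
    onset <- lead_in_s
    rows <- list()
    for (b in seq_along(blocks)) {
      practice <- blocks[b] == "practice"
      cond <- if (practice) "standard" else blocks[b]
      n_sent <- sample(c(sample(3:5, 6, replace = TRUE),
                         sample(1:2, 2, replace = TRUE)))
      for (ns in n_sent) {
        dur <- ns * SENTENCE_DURATION_S
        rows[[length(rows) + 1L]] <- data.frame(
          onset = onset, duration = dur,
          condition = cond, context = if (ns >= 3) "low" else "high",
          n_sentences = ns, block = b - 1L, practice = practice)
        onset <- onset + dur + baseline_s
      }
    }
    ev <- do.call(rbind, rows)
    event_list(ev$onset, ev$duration, ev$condition, ev$context,
               ev$n_sentences, ev$block, ev$practice)
  })
}

#' Canonical double-gamma hemodynamic response function
#'
#' Difference of two gamma densities (peak ~`peak` s, undershoot
#' ~`undershoot` s), sampled at `fs` over `len_s` seconds. Returned
#' unnormalized; the generator calibrates its scale against the
#' event-window measure.
#'
#' @param fs sampling rate (Hz).
#' @param peak,undershoot,ratio shape parameters.
#' @param len_s kernel length (s).
#' @return numeric vector of kernel samples.
#' @export
canonical_hrf <- function(fs = 10, peak = 6, undershoot = 16,
                          ratio = 1 / 6, len_s = 40) {
  t <- seq(0, len_s, by = 1 / fs)
  dgamma(t, shape = peak, rate = 1) -
    ratio * dgamma(t, shape = undershoot, rate = 1)
}

conv_causal <- function(x, h) {
  n <- length(x)
  convolve(c(x, numeric(length(h))), rev(h), type = "open")[seq_len(n)]
}

# Scale factor such that a reference 24-s sequence of unit boxcar amplitude
# yields an event-window measure (mean over [onset+10, offset) minus the
# 5-s pre-onset baseline) of exactly 1.
hrf_calibration <- function(h, fs, ref_dur = 24) {
  n <- round((ref_dur + 60) * fs)
  stim <- numeric(n)
  i0 <- round(10 * fs) + 1L  # event onset at t = 10 s, baseline settled at 0
  stim[i0:(i0 + round(ref_dur * fs) - 1L)] <- 1
  y <- conv_causal(stim, h) / fs
  win <- (i0 + round(10 * fs)):(i0 + round(ref_dur * fs) - 1L)
  base <- (i0 - round(5 * fs)):(i0 - 1L)
  mean(y[win]) - mean(y[base])
}

#' Simulate noiseless hemodynamic ground truth
#'
#' Convolves per-sentence boxcars with the canonical double-gamma response,
#' exploiting the temporal superposition of successive sentence responses
#' within a sequence. Boxcar amplitude is set per event condition and
#' channel subregion so that the HbDiff event-window measure of a
#' reference-length sequence equals the programmed amplitude; HbR is a
#' scaled, lagged copy of the HbO shape. Short channels carry no neural
#' signal.
#'
#' @param design an [event_list()].
#' @param truth a [ground_truth()].
#' @param montage a [probe_montage()].
#' @param fs sampling rate (Hz).
#' @param tail_s recording time appended after the last event (s).
#' @return An `hb_series` with `hbo`, `hbr` (time x channel, µM), `fs`.
#' @export
simulate_hemodynamics <- function(design, truth, montage = default_montage(),
                                  fs = 10, tail_s = 40) {
  t_end <- max(design$onset + design$duration) + tail_s
  n <- round(t_end * fs)
  h <- canonical_hrf(fs, truth$hrf_peak, truth$hrf_undershoot, truth$hrf_ratio)
  cal <- hrf_calibration(h, fs)
  h_o <- h / cal
  lag_n <- round(truth$hbr_lag * fs)
  h_r <- truth$hbr_scale * c(numeric(lag_n), h_o)

  # HbDiff measure of a unit-amplitude reference event (HbO minus HbR
  # contribution); divides the programmed amplitude into a boxcar height.
  unit_diff <- 1 - truth$hbr_scale * hrf_calibration(h_r / truth$hbr_scale, fs)

  stim <- matrix(0, n, length(CONDITIONS), dimnames = list(NULL, CONDITIONS))
  for (i in seq_len(nrow(design))) {
    ns <- design$n_sentences[i]
    sent_dur <- design$duration[i] / ns
    for (s in seq_len(ns)) {
      a <- round((design$onset[i] + (s - 1) * sent_dur) * fs) + 1L
      b <- min(round((design$onset[i] + s * sent_dur) * fs), n)
      stim[a:b, design$condition[i]] <- 1
    }
  }
  resp_o <- apply(stim, 2, conv_causal, h = h_o) / fs
  resp_r <- apply(stim, 2, conv_causal, h = h_r) / fs

  ch <- montage$channels
  n_ch <- nrow(ch)
  hbo <- matrix(0, n, n_ch)
  hbr <- matrix(0, n, n_ch)
  for (j in seq_len(n_ch)) {
    if (ch$is_short[j]) next
    amps <- truth$hbdiff_amp[ch$subregion[j], ] / unit_diff
    hbo[, j] <- resp_o %*% amps
    hbr[, j] <- resp_r %*% amps
  }
  structure(list(hbo = hbo, hbr = hbr, fs = fs, channels = ch),
            class = "hb_series")
}

#' Forward-model raw intensities from hemoglobin ground truth
#'
#' Adds shared superficial physiology (respiration, Mayer wave, drift) and
#' per-channel cardiac pulsation to the neural traces, maps hemoglobin to
#' optical density through the modified Beer-Lambert law at both
#' wavelengths, injects scheduled step and spike artifacts plus white
#' instrument noise, and exponentiates to strictly positive intensities.
#' Short channels receive the superficial and systemic components at unit
#' gain and no event-locked neural signal; long channels receive neural
#' signal plus a channel-specific fraction of the same superficial
#' component.
#'
#' @param true_hb output of [simulate_hemodynamics()].
#' @param noise a [noise_params()].
#' @param truth the [ground_truth()] supplying superficial gains.
#' @param montage a [probe_montage()].
#' @param seed integer seed.
#' @param dpf differential pathlength factor for the forward model.
#' @param i0 reference intensity (device units).
#' @param events the [event_list()] to attach to the recording.
#' @param meta participant metadata list.
#' @return A [raw_recording()].
#' @export
simulate_raw_intensity <- function(true_hb, noise = noise_params(),
                                   truth = ground_truth(),
                                   montage = default_montage(), seed = 1,
                                   dpf = DEFAULT_DPF, i0 = 1000,
                                   events = NULL, meta = NULL) {
  n <- nrow(true_hb$hbo)
  fs <- true_hb$fs
  tt <- (seq_len(n) - 1) / fs
  ch <- montage$channels
  n_ch <- nrow(ch)
  with_seed(derive_seed(seed, 2), {
    sup <- noise$resp_amp * sin(2 * pi * noise$resp_hz * tt + runif(1, 0, 2 * pi)) +
      noise$mayer_amp * sin(2 * pi * noise$mayer_hz * tt + runif(1, 0, 2 * pi)) +
      cumsum(rnorm(n, 0, noise$drift_rw_sd)) +
      noise$drift_lin_amp * sample(c(-1, 1), 1) * tt / max(tt)
    gain <- numeric(n_ch)
    gain[ch$is_short] <- 1
    gain[!ch$is_short] <- truth$superficial_gain
    sep <- channel_separation(montage)
    E <- EXTINCTION * log(10)
    od <- array(0, dim = c(n, n_ch, 2))
    for (j in seq_len(n_ch)) {
      cardiac <- noise$cardiac_scale[j] * noise$cardiac_amp *
        sin(2 * pi * noise$cardiac_hz * tt + runif(1, 0, 2 * pi))
      hbo <- (true_hb$hbo[, j] + gain[j] * sup + cardiac) / 1000      # µM -> mM
      hbr <- (true_hb$hbr[, j] - 0.25 * gain[j] * sup + 0.2 * cardiac) / 1000
      for (w in 1:2)
        od[, j, w] <- (E[w, 1] * hbo + E[w, 2] * hbr) * sep[j] * dpf
    }
    # artifacts are drawn per channel x wavelength: the two LED chips of an
    # optode couple to the skin independently, so a contact change need not
    # be common-mode across wavelengths
    if (noise$n_steps > 0)
      for (k in seq_len(noise$n_steps)) {
        j <- sample(n_ch, 1); w <- sample(2, 1)
        t0 <- sample(seq(round(n * 0.1), round(n * 0.9)), 1)
        od[t0:n, j, w] <- od[t0:n, j, w] + rnorm(1, 0, noise$step_od_sd)
      }
    if (noise$n_spikes > 0)
      for (k in seq_len(noise$n_spikes)) {
        j <- sample(n_ch, 1); w <- sample(2, 1)
        t0 <- sample(seq(round(n * 0.1), round(n * 0.9)), 1)
        shape <- noise$spike_od * sample(c(-1, 1), 1) * c(1, 0.6, 0.3)
        idx <- t0:min(t0 + 2, n)
        od[idx, j, w] <- od[idx, j, w] + shape[seq_along(idx)]
      }
    if (noise$white_od_sd > 0)
      od <- od + rnorm(length(od), 0, noise$white_od_sd)
    intensity <- i0 * exp(-od)
    if (any(!is.finite(intensity)) || any(intensity <= 0))
      stop("simulated amplitudes too large: non-positive intensity")
    if (is.null(events))
      events <- event_list(numeric(0), numeric(0), character(0), character(0),
                           integer(0), integer(0), logical(0))
    if (is.null(meta))
      meta <- list(participant = sprintf("sim%04d", seed), handedness = "right")
    raw_recording(intensity, fs, events, montage, meta)
  })
}

#' Behavioural response-model parameters
#'
#' Condition means and variance components for the 7-point effort rating
#' (participant offset shared across conditions, condition-specific offset,
#' trial noise) and per-condition word-repetition probabilities.
#'
#' @param effort_mean named condition means of the effort rating.
#' @param effort_sd_between between-participant SD of the shared offset.
#' @param effort_sd_cond SD of the condition-specific participant offset.
#' @param effort_sd_trial trial-to-trial rating SD.
#' @param p_correct named per-condition probability of a correct repeat.
#' @return List of class `behaviour_params`.
#' @export
behaviour_params <- function(effort_mean = c(standard = 4.02, dnn = 3.08),
                             effort_sd_between = 0.85,
                             effort_sd_cond = 0.25,
                             effort_sd_trial = 0.8,
                             p_correct = c(standard = 0.63, dnn = 0.768)) {
  structure(as.list(environment()), class = "behaviour_params")
}

#' Simulate trial-level behavioural records for one session
#'
#' One record per non-practice event: a 1-7 effort rating (rounded,
#' clipped normal around the participant's condition mean) and a Bernoulli
#' correctness flag.
#'
#' @param design an [event_list()].
#' @param params a [behaviour_params()].
#' @param seed integer seed.
#' @return Data frame with columns `event`, `block`, `condition`,
#'   `context`, `n_sentences`, `correct`, `effort`.
#' @export
simulate_behaviour <- function(design, params = behaviour_params(), seed = 1) {
  test <- design[!design$practice, , drop = FALSE]
  with_seed(derive_seed(seed, 3), {
    u <- rnorm(1, 0, params$effort_sd_between)
    uc <- setNames(rnorm(2, 0, params$effort_sd_cond), CONDITIONS)
    mu <- params$effort_mean[test$condition] + u + uc[test$condition]
    rating <- round(mu + rnorm(nrow(test), 0, params$effort_sd_trial))
    rating <- pmin(pmax(rating, 1), 7)
    data.frame(event = seq_len(nrow(test)),
               block = test$block,
               condition = test$condition,
               context = test$context,
               n_sentences = test$n_sentences,
               correct = rbinom(nrow(test), 1, params$p_correct[test$condition]),
               effort = as.integer(rating),
               stringsAsFactors = FALSE)
  })
}

#' Simulate a complete session
#'
#' Design, ground-truth hemodynamics, raw dual-wavelength intensities and
#' behavioural records for one participant, all derived from one seed.
#'
#' @param seed integer seed.
#' @param n_blocks number of test blocks.
#' @param truth,noise,behav generator parameter sets.
#' @param montage a [probe_montage()].
#' @param fs sampling rate (Hz).
#' @param handedness `"left"`, `"right"`, or `NULL` to draw with the study
#'   proportion (22 right : 4 left).
#' @param participant_amp_sd SD (µM) of the participant-level offset added
#'   to every subregion's event-response amplitude (the random intercept of
#'   the multilevel hierarchy, expressed at the signal level).
#' @param handedness_effect µM added to every amplitude for right-handed
#'   participants (overall oxygenation runs higher in right-handers).
#' @return List with `recording`, `behaviour`, `truth_hb`, `design`,
#'   `truth` (the session's realized truth, offsets included).
#' @export
simulate_session <- function(seed = 1, n_blocks = 4,
                             truth = ground_truth(), noise = noise_params(),
                             behav = behaviour_params(),
                             montage = default_montage(), fs = 10,
                             handedness = NULL,
                             participant_amp_sd = 3,
                             handedness_effect = 13.46) {
  design <- make_session_design(n_blocks, seed)
  if (is.null(handedness))
    handedness <- with_seed(derive_seed(seed, 4),
                            sample(c("right", "left"), 1,
                                   prob = c(22, 4) / 26))
  truth_p <- truth
  truth_p$hbdiff_amp <- truth$hbdiff_amp +
    with_seed(derive_seed(seed, 7), rnorm(1, 0, participant_amp_sd)) +
    handedness_effect * (handedness == "right")
  truth_hb <- simulate_hemodynamics(design, truth_p, montage, fs)
  rec <- simulate_raw_intensity(
    truth_hb, noise, truth_p, montage, seed, events = design,
    meta = list(participant = sprintf("sim%04d", seed),
                handedness = handedness))
  behaviour <- simulate_behaviour(design, behav, seed)
  list(recording = rec, behaviour = behaviour, truth_hb = truth_hb,
       design = design, truth = truth_p)
}
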