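test_that("step removal matches the hand-computed diff/zero/cumsum oracle", {
  # flat signal with one +100 step plus small deterministic jitter
  x <- rep(1000, 200) + sin(seq_len(200))
  x[101:200] <- x[101:200] + 100
  # oracle, written out longhand
  d <- diff(x)
  thr <- mean(d) + 2 * sd(d)
  d0 <- d; d0[abs(d0) > thr] <- 0
  expected <- c(x[1], x[1] + cumsum(d0))
  got <- remove_step_noise(x)
  expect_equal(got, expected)
  # the step is gone: post-step level rejoins the pre-step baseline
  expect_lt(abs(mean(got[150:200]) - mean(got[1:50])), 1)
  expect_equal(length(got), length(x))
})

test_that("a linear ramp passes step removal unchanged", {
  x <- seq(0, 100, length.out = 500)
  expect_equal(remove_step_noise(x), x)
})

test_that("step removal is idempotent on the cleaned signal", {
  x <- rep(1000, 200) + sin(seq_len(200))
  x[101:200] <- x[101:200] + 100
  once <- remove_step_noise(x)
  expect_equal(remove_step_noise(once), once)
  expect_error(remove_step_noise(c(1, 2)), "too short")
})

test_that("scalp coupling index separates coupled from uncoupled channels", {
  fs <- 10
  t <- seq(0, 60, by = 1 / fs)
  cardiac <- sin(2 * pi * 1.1 * t)
  expect_gt(scalp_coupling_index(1000 + cardiac, 900 + 2 * cardiac, fs), 0.99)
  expect_lt(scalp_coupling_index(1000 + cardiac, 900 - 2 * cardiac, fs), -0.99)
  # amplitude scaling of either wavelength leaves the index unchanged
  expect_equal(scalp_coupling_index(1000 + cardiac, 900 + 2 * cardiac, fs),
               scalp_coupling_index(5 * (1000 + cardiac),
                                    0.1 * (900 + 2 * cardiac), fs))
})

test_that("independent white noise gives near-zero coupling", {
  fs <- 10
  n <- 60 * fs
  scis <- vapply(1:200, function(k) {
    set.seed(k)
    scalp_coupling_index(1000 + rnorm(n), 900 + rnorm(n), fs)
  }, numeric(1))
  expect_lt(mean(abs(scis) >= 0.3), 0.02)
  expect_lt(abs(mean(scis)), 0.05)
})

test_that("zero cardiac-band variance yields SCI 0 with a warning", {
  fs <- 10
  x <- rep(1000, 600)
  expect_warning(s <- scalp_coupling_index(x, x, fs), "zero variance")
  expect_equal(s, 0)
})

test_that("channel rejection applies the 0.75 threshold as a strict cut", {
  s <- clean_session()
  qc <- reject_channels(s$recording)
  expect_true(all(!qc$rejected))
  expect_equal(attr(qc, "fraction_rejected"), 0)
  # threshold semantics: sci < threshold rejects, sci >= threshold keeps
  qc2 <- reject_channels(s$recording, threshold = min(qc$sci) + 1e-6)
  expect_true(qc2$rejected[which.min(qc2$sci)])
  qc3 <- reject_channels(s$recording, threshold = min(qc$sci))
  expect_false(qc3$rejected[which.min(qc3$sci)])
})

test_that("a cardiac-free channel is the one rejected", {
  s <- clean_session()
  noise <- noise_params()
  noise$cardiac_scale[4] <- 0
  rec <- simulate_raw_intensity(s$truth_hb, noise, s$truth, seed = 21,
                                events = s$design)
  qc <- reject_channels(rec)
  expect_identical(which(qc$rejected), 4L)
})

test_that("optical density conversion has the closed-form properties", {
  x <- rep(8, 100)
  expect_equal(intensity_to_od(x), rep(0, 100))
  # halving the intensity raises OD by ln 2 over the pre-jump level
  y <- c(rep(10, 100), rep(5, 100))
  od <- intensity_to_od(y)
  expect_equal(od[150] - od[50], log(2))
  # scale invariance
  z <- 10 + runif(100)
  expect_equal(intensity_to_od(z * 37.5), intensity_to_od(z))
  # mean OD is zero to first order (exactly 0 only for constant intensity)
  expect_lt(abs(mean(intensity_to_od(z))), 1e-3)
  expect_error(intensity_to_od(c(1, -1, 2)), "non-positive")
})

test_that("wavelet correction removes spikes but spares smooth signal", {
  t <- seq(0, 100, by = 0.1)
  smooth <- 3 + 0.01 * t + 1e-4 * t^2
  out <- wavelet_motion_correct(smooth)
  expect_lt(max(abs(out - smooth)) / diff(range(smooth)), 0.01)
  # 50-SD single-sample spike attenuated by >= 90%
  x <- sin(2 * pi * 0.05 * t) * 0.1
  spike_at <- 500
  xs <- x; xs[spike_at] <- xs[spike_at] + 50 * sd(x)
  corrected <- wavelet_motion_correct(xs)
  residual_spike <- abs(corrected[spike_at] - x[spike_at])
  original_spike <- abs(xs[spike_at] - x[spike_at])
  expect_lt(residual_spike / original_spike, 0.10)
  # infinite IQR factor reduces to perfect reconstruction
  expect_lt(max(abs(wavelet_motion_correct(xs, iqr_k = Inf) - xs)), 1e-8)
})

test_that("short series pass through wavelet correction with a warning", {
  expect_warning(out <- wavelet_motion_correct(rnorm(20)), "too short")
  expect_equal(length(out), 20)
})

test_that("Beer-Lambert inversion is exact and linear", {
  m <- default_montage()
  expect_equal(od_to_hemoglobin(array(0, c(50, 8, 2)), m)$hbo,
               matrix(0, 50, 8))
  # forward-model OD from known concentrations, then invert
  set.seed(42)
  hbo_true <- matrix(rnorm(50 * 8), 50, 8)
  hbr_true <- matrix(rnorm(50 * 8), 50, 8)
  E <- matrix(c(0.5860, 1.5485, 1.0580, 0.6913), 2, byrow = TRUE) * log(10)
  sep <- channel_separation(m)
  dpf <- 1.0
  od <- array(0, c(50, 8, 2))
  for (j in 1:8) for (w in 1:2)
    od[, j, w] <- (E[w, 1] * hbo_true[, j] / 1000 +
                     E[w, 2] * hbr_true[, j] / 1000) * sep[j] * dpf
  hb <- od_to_hemoglobin(od, m, dpf = dpf)
  expect_lt(max(abs(hb$hbo - hbo_true)) / max(abs(hbo_true)), 1e-6)
  expect_lt(max(abs(hb$hbr - hbr_true)) / max(abs(hbr_true)), 1e-6)
  # doubling the DPF halves the recovered concentrations
  hb2 <- od_to_hemoglobin(od, m, dpf = 2 * dpf)
  expect_equal(hb2$hbo, hb$hbo / 2)
  # linearity in OD
  hb3 <- od_to_hemoglobin(od * 3, m, dpf = dpf)
  expect_equal(hb3$hbo, hb$hbo * 3, tolerance = 1e-10)
})

test_that("band-pass gains verified by FFT at the narrow band", {
  fs <- 10
  t <- seq(0, 600, by = 1 / fs)
  x <- 5 + sin(2 * pi * 0.05 * t) + sin(2 * pi * 1.1 * t)
  y <- bandpass(x, 0.01, 0.09, fs)
  amp <- function(sig, f) {
    n <- length(sig)
    i <- which.min(abs((0:(n - 1)) / n * fs - f))
    2 * Mod(fft(sig)[i]) / n
  }
  expect_gte(amp(y, 0.05) / amp(x, 0.05), 0.9)
  expect_lte(amp(y, 1.1) / amp(x, 1.1), 0.05)
  expect_lt(abs(mean(y)), 1e-3)           # DC fully removed
  # wide band keeps both components
  yw <- bandpass(x, 0.01, 1.5, fs)
  expect_gte(amp(yw, 1.1) / amp(x, 1.1), 0.8)
  expect_error(bandpass(x, 0.09, 0.01, fs), "invalid band")
  expect_error(bandpass(x, 0.01, 6, fs), "invalid band")
})

test_that("short-separation regression leaves residual orthogonal to regressor", {
  set.seed(7)
  n <- 2000
  short <- sin(2 * pi * 0.08 * (1:n) / 10) + rnorm(n, 0, 0.2)
  neural <- sin(2 * pi * 0.03 * (1:n) / 10)
  long <- neural + 0.8 * short
  out <- short_separation_regress(long, short)
  expect_lt(abs(cor(out, short)), 1e-8)
  expect_lt(sqrt(mean((out - (neural - mean(neural)))^2)) / sd(neural), 0.05)
  # perfect proportionality yields an identically zero residual
  expect_lt(max(abs(short_separation_regress(2 * short, short))), 1e-10)
  # orthogonal regressor leaves the signal essentially untouched
  ortho <- rnorm(n)
  ortho <- residuals(lm(ortho ~ neural))
  kept <- short_separation_regress(neural, ortho)
  expect_gt(cor(kept, neural), 0.999)
})

test_that("the pipeline refuses permuted stage orders", {
  s <- clean_session()
  p <- pipeline_params()
  p$stages <- rev(p$stages)
  expect_error(run_pipeline(s$recording, p), "fixed")
})

test_that("an impossible SCI threshold aborts cleanly", {
  s <- clean_session()
  expect_error(run_pipeline(s$recording,
                            pipeline_params(sci_threshold = 1.01)),
               "all measurement channels rejected")
})

test_that("every stage preserves sample count and sampling rate", {
  s <- noisy_session()
  pp <- noisy_pipeline()
  expect_equal(nrow(pp$hb$hbo), dim(s$recording$intensity)[1])
  expect_equal(nrow(pp$hb$hbr), dim(s$recording$intensity)[1])
  expect_equal(pp$hb$fs, s$recording$fs)
  expect_true(all(is.finite(pp$hb$hbo)))
  expect_gte(length(attr(pp$qc, "stage_log")), 8)
})

test_that("the full pipeline recovers programmed effects on noisy sessions", {
  contrasts <- vapply(1:3, function(seed) {
    s <- simulate_session(seed = seed, n_blocks = 4,
                          participant_amp_sd = 0, handedness = "right")
    pp <- run_pipeline(s$recording)
    agg <- aggregate_subregions(epoch_events(pp$hb, s$recording$events),
                                s$recording$montage, pp$qc)
    ca <- condition_average(agg)
    ll <- ca[ca$subregion == "left_lateral", ]
    ll$hbdiff[ll$condition == "standard"] - ll$hbdiff[ll$condition == "dnn"]
  }, numeric(1))
  expect_true(all(contrasts > 0))
  expect_lt(abs(mean(contrasts) - 19) / 19, 0.25)
})
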