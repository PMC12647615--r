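test_that("session design reproduces the block structure", {
  d <- make_session_design(n_blocks = 4, seed = 11)
  test <- d[!d$practice, ]
  expect_equal(nrow(test), 32)                       # 4 blocks x 8 events
  low <- test[test$context == "low", ]
  expect_equal(nrow(low), 24)                        # 6 per block
  expect_equal(sum(low$condition == "standard"), 12) # 12 analysed per cond
  expect_equal(sum(low$condition == "dnn"), 12)
  expect_true(all(low$duration >= 18))
  expect_true(all(low$n_sentences >= 3 & low$n_sentences <= 5))
  decoys <- test[test$context == "high", ]
  expect_true(all(decoys$n_sentences <= 2))
  practice <- d[d$practice, ]
  expect_equal(nrow(practice), 8)
  expect_true(all(practice$condition == "standard"))
  # 30-s baselines between events
  gaps <- d$onset[-1] - (d$onset + d$duration)[-nrow(d)]
  expect_true(all(abs(gaps - 30) < 1e-9))
})

test_that("the design is a deterministic function of its seed", {
  expect_identical(make_session_design(4, seed = 5),
                   make_session_design(4, seed = 5))
  expect_false(identical(make_session_design(4, seed = 5),
                         make_session_design(4, seed = 6)))
})

test_that("zero programmed amplitude yields flat hemodynamics", {
  d <- make_session_design(1, seed = 2)
  th <- ground_truth(hbdiff_amp = matrix(0, 3, 2,
                                         dimnames = dimnames(default_hbdiff_amp())))
  hb <- simulate_hemodynamics(d, th)
  expect_true(all(hb$hbo == 0))
  expect_true(all(hb$hbr == 0))
})

test_that("a single sequence recovers its programmed amplitude within 10%", {
  ev <- event_list(60, 18, "standard", "low", 3, 1, FALSE)
  amp <- matrix(c(10, 10, 0, 0, 0, 0), 3, 2, byrow = TRUE,
                dimnames = dimnames(default_hbdiff_amp()))
  hb <- simulate_hemodynamics(ev, ground_truth(hbdiff_amp = amp))
  d <- hb$hbo[, 1] - hb$hbr[, 1]
  measured <- oracle_epoch(d, hb$fs, 60, 18)
  expect_lt(abs(measured - 10) / 10, 0.10)
  # a reference-length (24 s) sequence is calibrated almost exactly
  ev2 <- event_list(60, 24, "standard", "low", 4, 1, FALSE)
  hb2 <- simulate_hemodynamics(ev2, ground_truth(hbdiff_amp = amp))
  d2 <- hb2$hbo[, 1] - hb2$hbr[, 1]
  expect_lt(abs(oracle_epoch(d2, hb2$fs, 60, 24) - 10) / 10, 0.01)
})

test_that("generated traces match an independent convolution oracle", {
  # rebuild the expected HbO trace for one event by direct summation,
  # bypassing the generator's FFT convolution
  ev <- event_list(60, 24, "standard", "low", 4, 1, FALSE)
  amp <- matrix(c(8, 8, 0, 0, 0, 0), 3, 2, byrow = TRUE,
                dimnames = dimnames(default_hbdiff_amp()))
  th <- ground_truth(hbdiff_amp = amp)
  hb <- simulate_hemodynamics(ev, th, fs = 10)
  fs <- 10
  h <- canonical_hrf(fs)
  stim <- numeric(nrow(hb$hbo))
  stim[(60 * fs + 1):(84 * fs)] <- 1
  direct <- numeric(length(stim))
  for (i in seq_along(stim)) if (stim[i] > 0) {
    idx <- i:min(i + length(h) - 1L, length(stim))
    direct[idx] <- direct[idx] + h[seq_along(idx)] / fs
  }
  # the generator scales the same shape; compare up to one global factor
  k <- sum(direct * hb$hbo[, 1]) / sum(direct^2)
  expect_lt(max(abs(hb$hbo[, 1] - k * direct)), 1e-6 * max(abs(hb$hbo[, 1])))
})

test_that("left-lateral HbDiff contrast equals the programmed +19", {
  d <- make_session_design(4, seed = 9)
  hb <- simulate_hemodynamics(d, ground_truth())
  hb_for_epoch <- hb
  resp <- epoch_events(hb_for_epoch, d)
  agg <- aggregate_subregions(resp, default_montage())
  ca <- condition_average(agg)
  ll <- ca[ca$subregion == "left_lateral", ]
  contrast <- ll$hbdiff[ll$condition == "standard"] -
    ll$hbdiff[ll$condition == "dnn"]
  expect_lt(abs(contrast - 19) / 19, 0.05)
  other <- ca[ca$subregion != "left_lateral", ]
  expect_true(all(abs(other$hbdiff) < 1e-9))
})

test_that("noiseless forward model inverts exactly through OD and MBLL", {
  s <- clean_session()
  d <- s$design
  th <- s$truth
  hbt <- simulate_hemodynamics(d, th)
  rec <- simulate_raw_intensity(hbt, noise_off(), th, seed = 5, events = d)
  hb2 <- od_to_hemoglobin(intensity_to_od(rec$intensity), rec$montage)
  for (j in c(1, 3, 5)) {
    a <- hbt$hbo[, j] - mean(hbt$hbo[, j])
    b <- hb2$hbo[, j] - mean(hb2$hbo[, j])
    expect_lt(max(abs(a - b)), 0.01 * max(abs(a)))
  }
})

test_that("noise and truth off give constant intensities", {
  d <- make_session_design(1, seed = 2)
  th <- ground_truth(hbdiff_amp = matrix(0, 3, 2,
                                         dimnames = dimnames(default_hbdiff_amp())))
  hb <- simulate_hemodynamics(d, th)
  rec <- simulate_raw_intensity(hb, noise_off(), th, seed = 1, events = d)
  expect_equal(max(rec$intensity) - min(rec$intensity), 0)
})

test_that("short channels never carry event-locked signal", {
  s <- noisy_session()
  expect_true(all(s$truth_hb$hbo[, 7:8] == 0))
  expect_true(all(s$truth_hb$hbr[, 7:8] == 0))
})

test_that("overdriven amplitudes are refused rather than clipped", {
  d <- make_session_design(1, seed = 2)
  amp <- matrix(3e5, 3, 2, dimnames = dimnames(default_hbdiff_amp()))
  hb <- simulate_hemodynamics(d, ground_truth(hbdiff_amp = amp))
  expect_error(simulate_raw_intensity(hb, noise_off(), ground_truth(),
                                      seed = 1, events = d),
               "non-positive intensity")
})

test_that("behaviour simulation is deterministic and respects p_correct", {
  d <- make_session_design(4, seed = 3)
  expect_identical(simulate_behaviour(d, seed = 8),
                   simulate_behaviour(d, seed = 8))
  b <- simulate_behaviour(d, behaviour_params(p_correct = c(standard = 1,
                                                            dnn = 1)),
                          seed = 8)
  expect_true(all(b$correct == 1))
  expect_true(all(b$effort %in% 1:7))
  expect_equal(nrow(b), 32)  # one record per non-practice event
})

test_that("cohort effort means approach the programmed condition means", {
  ratings <- do.call(rbind, lapply(1:26, function(i) {
    d <- make_session_design(4, seed = i)
    b <- simulate_behaviour(d, seed = i)
    b <- b[b$context == "low", ]
    data.frame(std = mean(b$effort[b$condition == "standard"]),
               dnn = mean(b$effort[b$condition == "dnn"]))
  }))
  expect_lt(abs(mean(ratings$std) - 4.02), 0.2)
  expect_lt(abs(mean(ratings$dnn) - 3.08), 0.2)
})
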