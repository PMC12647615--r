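# Shared fixtures, built once per test run and memoized.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixtures)) assign(key, builder(), envir = .fixtures)
  get(key, envir = .fixtures)
}

# one-block noiseless-physiology session (cardiac only, needed for QC)
clean_session <- function() memo("clean", function() {
  noise <- noise_off()
  noise$cardiac_amp <- 3
  simulate_session(seed = 3, n_blocks = 1, noise = noise,
                   participant_amp_sd = 0, handedness = "right")
})

# one-block session at default noise
noisy_session <- function() memo("noisy", function() {
  simulate_session(seed = 4, n_blocks = 1, handedness = "right")
})

noisy_pipeline <- function() memo("noisy_pp", function() {
  run_pipeline(noisy_session()$recording)
})

# independent epoch-measure oracle: plain index arithmetic on a vector
oracle_epoch <- function(x, fs, onset, duration) {
  win <- (round((onset + 10) * fs) + 1):round((onset + duration) * fs)
  base <- (round((onset - 5) * fs) + 1):round(onset * fs)
  mean(x[win]) - mean(x[base])
}
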