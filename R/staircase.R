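# Adaptive SNR-50 search: 20-trial one-down/one-up staircase with 4-dB
# steps over the first five trials and 2-dB steps thereafter, start 8 dB.

#' Initialize a staircase
#'
#' @param start_snr starting SNR in dB (the protocol uses 8).
#' @param n_trials number of sentences per run.
#' @param big_step,small_step step sizes (dB) for trials 1-5 and 6 onward.
#' @param switch_after last trial index adjusted with the big step.
#' @return A list of class `staircase_state`.
#' @export
staircase_init <- function(start_snr = 8, n_trials = 20,
                           big_step = 4, small_step = 2, switch_after = 5) {
  structure(list(trial = 1L, snr = start_snr,
                 history = data.frame(trial = integer(0), snr = numeric(0),
                                      correct = logical(0)),
                 n_trials = n_trials, big_step = big_step,
                 small_step = small_step, switch_after = switch_after),
            class = "staircase_state")
}

#' Advance the staircase after a response
#'
#' The SNR decreases after a correct response and increases after an
#' incorrect one. The step size is determined by the index of the trial
#' just answered: trials 1-5 move 4 dB, trials 6-20 move 2 dB.
#'
#' @param state a `staircase_state`.
#' @param correct logical, response to the current trial.
#' @return Updated state, with `snr` holding the next presentation level.
#' @export
next_snr <- function(state, correct) {
  if (state$trial > state$n_trials)
    stop("staircase already completed ", state$n_trials, " trials")
  step <- if (state$trial <= state$switch_after) state$big_step
          else state$small_step
  state$history <- rbind(state$history,
                         data.frame(trial = state$trial, snr = state$snr,
                                    correct = correct))
  state$snr <- state$snr + if (correct) -step else step
  state$trial <- state$trial + 1L
  state
}

#' Simulated logistic listener
#'
#' `P(correct | snr) = logistic((snr - snr50) * slope)`; at `snr = snr50`
#' the listener scores exactly 50%.
#'
#' @param snr50 true 50%-intelligibility SNR (dB).
#' @param slope psychometric slope (dB^-1).
#' @return A list of class `listener`.
#' @export
listener <- function(snr50 = 0, slope = 1) {
  stopifnot(slope > 0)
  structure(list(snr50 = snr50, slope = slope), class = "listener")
}

p_correct <- function(lst, snr) plogis((snr - lst$snr50) * lst$slope)

#' Run one 20-trial SNR-50 staircase
#'
#' The SNR-50 estimate is the mean of the ten values: the SNRs presented
#' at trials 12 through 20 plus the SNR that would have been presented at
#' trial 21.
#'
#' @param lst a [listener()] (or a function `snr -> logical`, for
#'   deterministic response rules).
#' @param seed integer seed for the Bernoulli responses.
#' @param ... passed to [staircase_init()].
#' @return List of class `snr50_run`: `estimate` (dB), `trace` (presented
#'   SNRs including the virtual trial 21), `responses`.
#' @export
run_staircase <- function(lst, seed = 1, ...) {
  state <- staircase_init(...)
  respond <- if (is.function(lst)) {
    function(snr) lst(snr)
  } else {
    function(snr) runif(1) < p_correct(lst, snr)
  }
  with_seed(derive_seed(seed, 5), {
    while (state$trial <= state$n_trials)
      state <- next_snr(state, respond(state$snr))
  })
  trace <- c(state$history$snr, state$snr)  # trial 21 = would-be next SNR
  est <- mean(trace[12:21])
  structure(list(estimate = est, trace = trace,
                 responses = state$history$correct),
            class = "snr50_run")
}

#' Three-run SNR-50 protocol
#'
#' Three staircase runs; the test SNR is the mean SNR-50 of the last two
#' runs plus 2 dB (added to lift performance above chance and hold
#' listening effort near its peak).
#'
#' @param lst a [listener()].
#' @param seed integer seed (each run uses a derived sub-seed).
#' @param offset_db dB added to the mean of runs 2 and 3.
#' @return List: `test_snr`, `runs` (the three per-run estimates).
#' @export
snr50_protocol <- function(lst, seed = 1, offset_db = 2) {
  runs <- vapply(1:3, function(k)
    run_staircase(lst, seed = derive_seed(seed, 100 + k))$estimate,
    numeric(1))
  list(test_snr = mean(runs[2:3]) + offset_db, runs = runs)
}

#' @export
print.snr50_run <- function(x, ...) {
  cat(sprintf("SNR-50 staircase run: estimate %.2f dB (%d trials)\n",
              x$estimate, length(x$responses)))
  invisible(x)
}
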