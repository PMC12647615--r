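#' Rationalized arcsine transform of a proportion-correct score
#'
#' Studebaker's count-based transform, used to decompress intelligibility
#' scores clustered near ceiling:
#' `t = asin(sqrt(x/(n+1))) + asin(sqrt((x+1)/(n+1)))`,
#' `RAU = (146/pi) * t - 23`. Maps 0..n correct onto roughly (-23, 123)
#' with 50% near 50 RAU.
#'
#' @param x_correct number of correct items (0..n), vectorized.
#' @param n_items number of items.
#' @return RAU score(s).
#' @export
rau_transform <- function(x_correct, n_items) {
  if (any(x_correct < 0 | x_correct > n_items))
    stop("x_correct must lie in 0..n_items")
  t <- asin(sqrt(x_correct / (n_items + 1))) +
    asin(sqrt((x_correct + 1) / (n_items + 1)))
  (146 / pi) * t - 23
}

#' Paired-samples t-test with effect size
#'
#' Two-sided paired t-test of `a` against `b` with 95% confidence interval
#' on the mean difference and Cohen's d for paired designs (`|t|/sqrt(n)`).
#'
#' @param a,b paired numeric vectors (e.g., per-participant condition
#'   means), equal length >= 2.
#' @return Object of class `paired_test` with fields `mean_a`, `mean_b`,
#'   `sd_a`, `sd_b`, `diff`, `ci95`, `df`, `t`, `p`, `d`, `n`.
#' @export
paired_t <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  if (sd(a - b) == 0 && !all(a == b))
    stop("zero variance of paired differences")
  n <- length(a)
  if (all(a == b)) {
    res <- list(statistic = c(t = 0), p.value = 1, conf.int = c(0, 0),
                parameter = c(df = n - 1))
  } else {
    res <- t.test(a, b, paired = TRUE)
  }
  structure(list(mean_a = mean(a), mean_b = mean(b),
                 sd_a = sd(a), sd_b = sd(b),
                 diff = mean(a) - mean(b),
                 ci95 = as.numeric(res$conf.int),
                 df = as.numeric(res$parameter),
                 t = as.numeric(res$statistic),
                 p = res$p.value,
                 d = cohens_d_paired(as.numeric(res$statistic), n),
                 n = n),
            class = "paired_test")
}

#' Cohen's d for a paired design
#'
#' `d = |t| / sqrt(n)`; invariant to the sign of `t`.
#'
#' @param t paired t statistic.
#' @param n number of pairs.
#' @return Effect size d.
#' @export
cohens_d_paired <- function(t, n) {
  stopifnot(n >= 2)
  abs(t) / sqrt(n)
}

#' Reconstruct the 95% CI of a paired mean difference from its t statistic
#'
#' `SE = diff / t`; `CI = diff +/- t_{0.975, n-1} * SE`. Useful for
#' auditing reported results from summary statistics alone.
#'
#' @param diff mean difference.
#' @param t paired t statistic.
#' @param n number of pairs.
#' @return Length-2 vector (lower, upper).
#' @export
paired_ci <- function(diff, t, n) {
  se <- diff / t
  diff + c(-1, 1) * qt(0.975, n - 1) * abs(se)
}

#' Behavioural summary across a simulated cohort
#'
#' Averages effort ratings over low-context trials per participant and
#' condition, converts per-participant correct counts to RAU, and runs the
#' two paired tests (effort; RAU accuracy), mirroring the standard
#' results-table layout.
#'
#' @param behaviour_list list of per-session behaviour tables (one per
#'   participant) as produced by [simulate_behaviour()].
#' @return List with `effort` and `accuracy` (`paired_test` objects) and
#'   the per-participant summary table.
#' @export
behaviour_summary <- function(behaviour_list) {
  per <- lapply(seq_along(behaviour_list), function(i) {
    b <- behaviour_list[[i]]
    b <- b[b$context == "low", , drop = FALSE]
    do.call(rbind, lapply(CONDITIONS, function(cond) {
      sub <- b[b$condition == cond, , drop = FALSE]
      data.frame(participant = i, condition = cond,
                 effort = mean(sub$effort),
                 n_trials = nrow(sub), n_correct = sum(sub$correct),
                 rau = rau_transform(sum(sub$correct), nrow(sub)))
    }))
  })
  per <- do.call(rbind, per)
  eff_std <- per$effort[per$condition == "standard"]
  eff_dnn <- per$effort[per$condition == "dnn"]
  rau_std <- per$rau[per$condition == "standard"]
  rau_dnn <- per$rau[per$condition == "dnn"]
  list(effort = paired_t(eff_std, eff_dnn),
       accuracy = paired_t(rau_std, rau_dnn),
       table = per)
}

#' @export
print.paired_test <- function(x, ...) {
  cat(sprintf(
    "Paired t-test: M_a = %.2f (SD %.2f), M_b = %.2f (SD %.2f)\n  diff = %.2f, 95%% CI [%.2f, %.2f], t(%d) = %.2f, p = %.3g, d = %.2f\n",
    x$mean_a, x$sd_a, x$mean_b, x$sd_b, x$diff, x$ci95[1], x$ci95[2],
    x$df, x$t, x$p, x$d))
  invisible(x)
}
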