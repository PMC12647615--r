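# Nested multilevel models for trial-level HbDiff: participant random
# intercept, full-information maximum likelihood, Satterthwaite degrees of
# freedom, likelihood-ratio model comparison and simple-slopes probing.

MLM_TERMS <- c("condition", "subregion", "condition:subregion",
               "handedness", "effort")

#' Specify a multilevel model for HbDiff
#'
#' Fixed terms are drawn from `condition` (hearing-aid program),
#' `subregion`, their interaction, `handedness` and `effort`. Dummy coding
#' uses the study's reference levels: standard program, left-lateral
#' subregion, left-handedness. The random part is a participant intercept;
#' estimation is full maximum likelihood so that nested models are
#' comparable by likelihood ratio.
#'
#' @param fixed character vector of fixed terms (`character(0)` gives the
#'   unconditional model).
#' @param subregion_ref reference subregion for dummy coding.
#' @return A list of class `mlm_spec`.
#' @export
mlm_spec <- function(fixed = c("condition", "subregion",
                               "condition:subregion", "handedness"),
                     subregion_ref = "left_lateral") {
  bad <- setdiff(fixed, MLM_TERMS)
  if (length(bad))
    stop("unknown fixed term(s): ", paste(bad, collapse = ", "),
         " (allowed: ", paste(MLM_TERMS, collapse = ", "), ")")
  if ("condition:subregion" %in% fixed &&
      !all(c("condition", "subregion") %in% fixed))
    stop("the interaction requires both main effects")
  stopifnot(subregion_ref %in% SUBREGIONS)
  structure(list(fixed = fixed, subregion_ref = subregion_ref),
            class = "mlm_spec")
}

prepare_trial_data <- function(data, subregion_ref = "left_lateral") {
  data$condition <- factor(data$condition, levels = CONDITIONS)
  data$subregion <- factor(data$subregion, levels = SUBREGIONS)
  data$subregion <- relevel(data$subregion, ref = subregion_ref)
  if ("handedness" %in% names(data))
    data$handedness <- factor(data$handedness, levels = c("left", "right"))
  data$participant <- factor(data$participant)
  data[!is.na(data$hbdiff), , drop = FALSE]
}

mlm_formula <- function(spec) {
  rhs <- if (length(spec$fixed)) paste(spec$fixed, collapse = " + ") else "1"
  as.formula(paste("hbdiff ~", rhs, "+ (1 | participant)"))
}

#' Fit a multilevel model for HbDiff
#'
#' @param data long trial table, one row per participant x event x
#'   subregion, columns `participant`, `condition`, `subregion`, `hbdiff`
#'   and any covariates the spec names; missing `hbdiff` rows are dropped
#'   (observation-level full-information likelihood).
#' @param spec an [mlm_spec()].
#' @return Object of class `mlm_fit`: fixed-effect table (estimate, SE,
#'   Satterthwaite df, t, p), log-likelihood, AIC, variance components,
#'   and the underlying fit.
#' @export
fit_mlm <- function(data, spec = mlm_spec()) {
  d <- prepare_trial_data(data, spec$subregion_ref)
  # a categorical term with a single observed level is inestimable (e.g. an
  # all-right-handed cohort): drop it rather than fail in the optimizer
  observed <- vapply(c("condition", "subregion", "handedness"), function(v)
    v %in% names(d) && length(unique(as.character(d[[v]]))) >= 2, logical(1))
  degenerate <- names(observed)[!observed]
  dropped <- spec$fixed[vapply(spec$fixed, function(tm)
    any(vapply(degenerate, function(v) grepl(v, tm, fixed = TRUE),
               logical(1))), logical(1))]
  if (length(dropped)) {
    spec <- mlm_spec(setdiff(spec$fixed, dropped), spec$subregion_ref)
  }
  fml <- mlm_formula(spec)
  if (var(d$hbdiff) == 0) {
    # degenerate outcome: every slope is exactly 0 and no stochastic model
    # is identifiable; return the trivial fit rather than a failed optimizer
    X <- stats::model.matrix(stats::as.formula(
      paste("~", if (length(spec$fixed)) paste(spec$fixed, collapse = " + ")
            else "1")), d)
    co <- matrix(NA_real_, ncol(X), 5,
                 dimnames = list(colnames(X),
                                 c("estimate", "se", "df", "t", "p")))
    co[, "estimate"] <- c(d$hbdiff[1], numeric(ncol(X) - 1L))
    return(structure(list(model = NULL, spec = spec, coefficients = co,
                          loglik = NA_real_, df_model = ncol(X) + 2L,
                          aic = NA_real_, n_obs = nrow(d),
                          varcomp = data.frame(grp = c("participant",
                                                       "Residual"),
                                               sdcor = c(0, 0)),
                          data = d, formula = fml),
                     class = "mlm_fit"))
  }
  fit <- lmerTest::lmer(fml, data = d, REML = FALSE)
  msgs <- fit@optinfo$conv$lme4$messages
  if (any(grepl("failed to converge", msgs)))
    stop("multilevel model failed to converge: ",
         paste(msgs, collapse = "; "))
  co <- summary(fit)$coefficients  # Estimate, SE, df, t, p (Satterthwaite)
  colnames(co) <- c("estimate", "se", "df", "t", "p")
  ll <- logLik(fit)
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(list(model = fit, spec = spec, coefficients = co,
                 loglik = as.numeric(ll), df_model = attr(ll, "df"),
                 aic = AIC(fit), n_obs = nrow(d),
                 varcomp = vc[, c("grp", "sdcor")], data = d,
                 formula = fml, dropped_terms = dropped),
            class = "mlm_fit")
}

#' @export
print.mlm_fit <- function(x, ...) {
  cat("Multilevel model (ML):",
      deparse(x$formula), "\n")
  cat(sprintf("  n = %d, logLik = %.1f, AIC = %.1f\n",
              x$n_obs, x$loglik, x$aic))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
summary.mlm_fit <- function(object, ...) {
  cat("Fixed effects (Satterthwaite df):\n")
  print(round(object$coefficients, 4))
  cat("\nVariance components (SD scale):\n")
  print(object$varcomp, row.names = FALSE)
  cat(sprintf("\nlogLik %.2f  AIC %.2f  n_obs %d\n",
              object$loglik, object$aic, object$n_obs))
  invisible(object)
}

#' @export
coef.mlm_fit <- function(object, ...) lme4::fixef(object$model)

#' @export
logLik.mlm_fit <- function(object, ...) logLik(object$model)

#' @export
predict.mlm_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) predict(object$model, ...)
  else predict(object$model, newdata = newdata, ...)
}

#' @export
residuals.mlm_fit <- function(object, ...) residuals(object$model, ...)

#' Likelihood-ratio comparison of nested multilevel models
#'
#' @param m_small,m_big `mlm_fit` objects fitted by maximum likelihood on
#'   the same rows, the smaller model's fixed terms a subset of the
#'   larger's.
#' @return List of class `mlm_comparison`: `chi2` (`= 2 * delta logLik`),
#'   `df` (parameter-count difference), `p`, `aic_small`, `aic_big`,
#'   `delta_aic` (big minus small).
#' @export
compare_nested <- function(m_small, m_big) {
  if (!all(m_small$spec$fixed %in% m_big$spec$fixed))
    stop("models are not nested: smaller model has terms absent from ",
         "the larger model")
  if (m_small$n_obs != m_big$n_obs)
    stop("models were fitted to different numbers of observations")
  chi2 <- 2 * (m_big$loglik - m_small$loglik)
  if (chi2 < -1e-6)
    stop("larger model has lower likelihood; models are not nested as fit")
  chi2 <- max(chi2, 0)
  df <- m_big$df_model - m_small$df_model
  p <- if (df > 0) pchisq(chi2, df, lower.tail = FALSE) else 1
  structure(list(chi2 = chi2, df = df, p = p,
                 aic_small = m_small$aic, aic_big = m_big$aic,
                 delta_aic = m_big$aic - m_small$aic),
            class = "mlm_comparison")
}

#' @export
print.mlm_comparison <- function(x, ...) {
  cat(sprintf("LRT: chi2(%d) = %.2f, p = %.4g; delta AIC = %.1f\n",
              x$df, x$chi2, x$p, x$delta_aic))
  invisible(x)
}

#' Simple slopes of the program effect per subregion
#'
#' Probes the program x subregion interaction: the conditional effect of
#' the hearing-aid program within each subregion, with Satterthwaite df and
#' 95% Wald confidence intervals. `method = "refit"` re-parameterizes by
#' refitting with each subregion as the dummy-coding reference;
#' `method = "contrast"` takes the equivalent linear combination of the
#' fitted coefficients. The two agree algebraically.
#'
#' @param fit an `mlm_fit` containing `condition:subregion`.
#' @param method `"refit"` or `"contrast"`.
#' @return Data frame: `subregion`, `estimate`, `se`, `df`, `t`, `p`,
#'   `ci_lo`, `ci_hi`.
#' @export
simple_slopes <- function(fit, method = c("refit", "contrast")) {
  method <- match.arg(method)
  if (!"condition:subregion" %in% fit$spec$fixed)
    stop("simple slopes require the condition:subregion interaction")
  rows <- lapply(SUBREGIONS, function(s) {
    if (method == "refit") {
      spec_s <- fit$spec
      spec_s$subregion_ref <- s
      f <- fit_mlm(fit$data, spec_s)
      co <- f$coefficients["conditiondnn", ]
    } else {
      fe <- lme4::fixef(fit$model)
      cvec <- setNames(numeric(length(fe)), names(fe))
      cvec["conditiondnn"] <- 1
      inter <- paste0("conditiondnn:subregion", s)
      if (inter %in% names(fe)) cvec[inter] <- 1
      ct <- lmerTest::contest1D(fit$model, cvec)
      co <- c(ct$Estimate, ct$`Std. Error`, ct$df, ct$`t value`,
              ct$`Pr(>|t|)`)
      names(co) <- c("estimate", "se", "df", "t", "p")
    }
    data.frame(subregion = s, estimate = co["estimate"], se = co["se"],
               df = co["df"], t = co["t"], p = co["p"],
               ci_lo = co["estimate"] - qt(0.975, co["df"]) * co["se"],
               ci_hi = co["estimate"] + qt(0.975, co["df"]) * co["se"],
               row.names = NULL)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("simple_slopes", "data.frame")
  out
}

#' Brain-behaviour model in the left lateral subregion
#'
#' Relates trial-level HbDiff in the left lateral prefrontal subregion to
#' the trial's effort rating (participant random intercept, ML), optionally
#' on correct trials only - incorrect trials may reflect attentional lapses
#' rather than listening effort. Returns the effort slope and a
#' likelihood-ratio test against the unconditional model on the same rows.
#'
#' @param trial_table long trial table with `subregion`, `hbdiff`,
#'   `effort`, `correct`, `participant`.
#' @param correct_only restrict to correct trials (default TRUE).
#' @return List of class `brain_behaviour`: `slope`, `se`, `df`, `t`, `p`,
#'   `lrt`, `n_obs`, `fit`.
#' @export
brain_behaviour_model <- function(trial_table, correct_only = TRUE) {
  d <- trial_table[trial_table$subregion == "left_lateral" &
                     !is.na(trial_table$hbdiff) &
                     !is.na(trial_table$effort), , drop = FALSE]
  if (correct_only) d <- d[d$correct == 1, , drop = FALSE]
  if (nrow(d) == 0L)
    stop(if (correct_only) "no correct trials available"
         else "no trials available")
  m0 <- fit_mlm(d, mlm_spec(fixed = character(0)))
  m1 <- fit_mlm(d, mlm_spec(fixed = "effort"))
  co <- m1$coefficients["effort", ]
  structure(list(slope = unname(co["estimate"]), se = unname(co["se"]),
                 df = unname(co["df"]), t = unname(co["t"]),
                 p = unname(co["p"]),
                 lrt = compare_nested(m0, m1),
                 n_obs = m1$n_obs, fit = m1),
            class = "brain_behaviour")
}

#' @export
print.brain_behaviour <- function(x, ...) {
  cat(sprintf(
    "Brain-behaviour model (left lateral): HbDiff rises %.2f µM per effort unit\n  t(%.0f) = %.2f, p = %.3g; LRT vs unconditional: chi2(%d) = %.2f, p = %.3g (n = %d)\n",
    x$slope, x$df, x$t, x$p, x$lrt$df, x$lrt$chi2, x$lrt$p, x$n_obs))
  invisible(x)
}
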