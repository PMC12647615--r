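# End-to-end orchestration: simulate -> preprocess -> epoch -> statistics,
# reproducible from one seed and one configuration object.

#' Build a run configuration
#'
#' Every default equals the analysis value used throughout the package:
#' 2-SD derivative threshold, SCI 0.75, wavelet IQR factor 0.1, band-passes
#' 0.01-1.5 and 0.01-0.09 Hz, 10-s response / 5-s baseline windows, DPF 6,
#' staircase start 8 dB with 4/2-dB steps and the +2-dB test offset.
#'
#' @param seed master seed; every stochastic stage derives its own
#'   sub-seed from it.
#' @param n_participants cohort size for simulated studies.
#' @param n_blocks test blocks per session.
#' @param preprocessing a [pipeline_params()].
#' @param truth,noise,behav generator parameter sets.
#' @return List of class `run_config`.
#' @export
run_config <- function(seed = 1, n_participants = 26, n_blocks = 4,
                       preprocessing = pipeline_params(),
                       truth = ground_truth(), noise = noise_params(),
                       behav = behaviour_params()) {
  structure(list(seed = seed, n_participants = n_participants,
                 n_blocks = n_blocks, preprocessing = preprocessing,
                 truth = truth, noise = noise, behav = behav),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Scalar fields override the defaults of [run_config()],
#' [pipeline_params()], [ground_truth()], [noise_params()] and
#' [behaviour_params()]; anything omitted keeps its default.
#'
#' @param path YAML file with optional sections `preprocessing`, `truth`,
#'   `noise`, `behav` and top-level `seed`, `n_participants`, `n_blocks`.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  take <- function(ctor, section) {
    args <- y[[section]]
    if (is.null(args)) return(ctor())
    do.call(ctor, args)
  }
  run_config(
    seed = if (is.null(y$seed)) 1 else y$seed,
    n_participants = if (is.null(y$n_participants)) 26 else y$n_participants,
    n_blocks = if (is.null(y$n_blocks)) 4 else y$n_blocks,
    preprocessing = take(pipeline_params, "preprocessing"),
    truth = take(ground_truth, "truth"),
    noise = take(noise_params, "noise"),
    behav = take(behaviour_params, "behav"))
}

#' Process one session end to end
#'
#' Preprocess a recording, epoch its events and assemble the trial table.
#'
#' @param session output of [simulate_session()] (or a list with
#'   `recording` and optionally `behaviour`).
#' @param params a [pipeline_params()].
#' @return List with `trial_table`, `qc`, `hb`.
#' @export
process_session <- function(session, params = pipeline_params()) {
  pp <- run_pipeline(session$recording, params)
  tt <- build_trial_table(pp$hb, pp$qc, session$recording,
                          session$behaviour)
  list(trial_table = tt, qc = pp$qc, hb = pp$hb)
}

#' Run a full simulated study
#'
#' Simulates `n_participants` sessions, preprocesses each, assembles the
#' pooled trial table, and runs the statistics: behavioural paired tests,
#' the nested model hierarchy (unconditional, main effect, interaction)
#' with likelihood-ratio comparisons, and the simple-slopes analysis.
#' Deterministic given the config seed.
#'
#' @param config a [run_config()].
#' @param out_dir optional directory; when given, writes `trials.csv`,
#'   `qc.json` and `summary.json` artifacts.
#' @return List of class `study_report`: `trial_table`, `qc_fraction`,
#'   `behaviour` (paired tests), `models` (the three `mlm_fit`s),
#'   `comparisons`, `slopes`.
#' @export
run_all <- function(config = run_config(), out_dir = NULL) {
  sessions <- lapply(seq_len(config$n_participants), function(i)
    simulate_session(seed = derive_seed(config$seed, 1000 + i),
                     n_blocks = config$n_blocks, truth = config$truth,
                     noise = config$noise, behav = config$behav))
  processed <- lapply(sessions, function(s) {
    out <- process_session(s, config$preprocessing)
    out$trial_table$participant <- s$recording$meta$participant
    out
  })
  trials <- do.call(rbind, lapply(processed, `[[`, "trial_table"))
  qc_fraction <- mean(vapply(processed, function(p)
    attr(p$qc, "fraction_rejected"), numeric(1)))
  behaviour <- behaviour_summary(lapply(sessions, `[[`, "behaviour"))

  m0 <- fit_mlm(trials, mlm_spec(fixed = character(0)))
  m1 <- fit_mlm(trials, mlm_spec(fixed = c("condition", "handedness")))
  m2 <- fit_mlm(trials, mlm_spec())
  comparisons <- list(main_vs_null = compare_nested(m0, m1),
                      interaction_vs_main = compare_nested(m1, m2),
                      interaction_vs_null = compare_nested(m0, m2))
  slopes <- simple_slopes(m2)

  report <- structure(
    list(trial_table = trials, qc_fraction = qc_fraction,
         behaviour = behaviour,
         models = list(unconditional = m0, main_effect = m1,
                       interaction = m2),
         comparisons = comparisons, slopes = slopes,
         config = config),
    class = "study_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(trials, file.path(out_dir, "trials.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(qc_fraction = qc_fraction,
           effort = unclass(behaviour$effort)[c("diff", "t", "p", "d")],
           accuracy = unclass(behaviour$accuracy)[c("diff", "t", "p", "d")],
           slopes = slopes),
      file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  }
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("Simulated study: %d participants, %.1f%% channels rejected\n",
              x$config$n_participants, 100 * x$qc_fraction))
  cat("\nEffort: "); print(x$behaviour$effort)
  cat("Accuracy (RAU): "); print(x$behaviour$accuracy)
  cat("\nModel comparison (main effect vs interaction): ")
  print(x$comparisons$interaction_vs_main)
  cat("\nSimple slopes of the program effect:\n")
  print(as.data.frame(lapply(x$slopes, function(c)
    if (is.numeric(c)) round(c, 3) else c)), row.names = FALSE)
  invisible(x)
}

OSF_EXPORT_COLUMNS <- c("participant", "condition", "subregion", "event",
                        "hbdiff", "effort", "correct", "handedness")

#' Load a deposited trial-table export
#'
#' Maps a locally supplied CSV export of an archived trial-level dataset
#' onto the package's long-table contract. The loader is best-effort: it
#' requires the canonical columns (case-insensitive, with `program`
#' accepted for `condition` and `region` for `subregion`) and refuses
#' anything else, listing what is expected.
#'
#' @param path CSV file.
#' @return Trial table suitable for [fit_mlm()].
#' @export
load_osf_export <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  nm <- tolower(names(raw))
  nm[nm == "program"] <- "condition"
  nm[nm == "region"] <- "subregion"
  names(raw) <- nm
  missing <- setdiff(OSF_EXPORT_COLUMNS, nm)
  if (length(missing))
    stop("export is missing column(s): ", paste(missing, collapse = ", "),
         "; expected columns: ", paste(OSF_EXPORT_COLUMNS, collapse = ", "))
  raw[, OSF_EXPORT_COLUMNS]
}
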