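#' Configure an end-to-end pipeline run
#'
#' Strict constructor for [run_pipeline()]'s configuration: unknown keys
#' are errors so the `stated` (correlation cutoff 0.7) and `paper`
#' (cutoff 0.6, expert keep-list) profiles cannot drift silently.
#'
#' @param profile selection profile, `"paper"` or `"stated"`
#'   (see [stated_profile()]).
#' @param seed master seed for cohort simulation.
#' @param n_training,n_test simulated cohort sizes (ignored when cohorts
#'   are supplied to [run_pipeline()] directly).
#' @param target_crossing_rate 3-month crossing-rate target for the
#'   simulator.
#' @param timepoint triage timepoint (default `"M3"`).
#' @param out_dir optional directory; when set, [run_pipeline()] writes its
#'   artifact files there.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(profile = c("paper", "stated"), seed = 1L,
                            n_training = 746, n_test = 482,
                            target_crossing_rate = 0.29, timepoint = "M3",
                            out_dir = NULL) {
  structure(list(profile = match.arg(profile), seed = as.integer(seed),
                 n_training = n_training, n_test = n_test,
                 target_crossing_rate = target_crossing_rate,
                 timepoint = timepoint, out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the whole triage pipeline
#'
#' Simulate (or accept) a training and a test cohort, run the six-stage
#' item selection on the training cohort, triage both cohorts with the
#' selected rule, and compare the allocation rates. When
#' `config$out_dir` is set, writes the selection report, the final rule
#' JSON, per-patient allocations and a run manifest there; every file is
#' re-readable by the package's own readers.
#'
#' @param config a [pipeline_config()].
#' @param training,test optional [pro_cohort()]s; simulated via
#'   [make_paperlike_fixture()] when omitted.
#' @param rule candidate rule (default [candidate_rule()]).
#' @return list of class `promtriage_run`: `manifest` (seed, profile,
#'   config, per-stage timings, decision log lines), `selection`,
#'   `triage_training`, `triage_test`, `comparison`.
#' @export
run_pipeline <- function(config = pipeline_config(), training = NULL, test = NULL,
                         rule = candidate_rule()) {
  stopifnot(inherits(config, "pipeline_config"))
  timings <- c()
  tick <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e)
      pt_stop(paste0("pipeline stage '", stage, "' failed: ", conditionMessage(e))))
    timings[[stage]] <<- proc.time()[["elapsed"]] - t0
    out
  }
  shift <- NA_real_
  if (is.null(training) || is.null(test)) {
    fix <- tick("simulate", make_paperlike_fixture(config$seed,
                                                   config$target_crossing_rate))
    training <- training %||% fix$training
    test <- test %||% fix$test
    shift <- fix$shift
  }
  cfg_sel <- if (config$profile == "paper") paper_profile() else stated_profile()
  sel <- tick("selection", run_selection(training, rule, cfg_sel))
  tr_a <- tick("triage_training", triage_cohort(training, sel$final_rule, config$timepoint))
  tr_b <- tick("triage_test", triage_cohort(test, sel$final_rule, config$timepoint))
  cmp <- tick("compare", compare_rates(tr_a$summary, tr_b$summary))
  dec <- sel$decisions
  log_lines <- sprintf("decision key=%s status=%s reason=%s", dec$key, dec$status,
                       ifelse(is.na(dec$reason), "-", dec$reason))
  manifest <- list(
    package_version = as.character(utils::packageVersion("promtriage")),
    profile = config$profile, seed = config$seed, m3_shift = shift,
    timepoint = config$timepoint,
    n_training = nrow(training$patients), n_test = nrow(test$patients),
    stage_timings_s = as.list(timings), decisions = log_lines)
  out <- structure(list(manifest = manifest, selection = sel,
                        triage_training = tr_a, triage_test = tr_b,
                        comparison = cmp),
                   class = "promtriage_run")
  if (!is.null(config$out_dir)) write_run_artifacts(out, config$out_dir)
  out
}

write_run_artifacts <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(run$selection$decisions, file.path(dir, "selection_decisions.csv"),
                   row.names = FALSE)
  write_triage_rule(run$selection$final_rule, file.path(dir, "final_rule.json"))
  utils::write.csv(run$triage_training$outcomes, file.path(dir, "allocations_training.csv"),
                   row.names = FALSE)
  utils::write.csv(run$triage_test$outcomes, file.path(dir, "allocations_test.csv"),
                   row.names = FALSE)
  jsonlite::write_json(run$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(run)
}

#' @export
print.promtriage_run <- function(x, ...) {
  cat(sprintf("<promtriage_run> profile=%s seed=%d\n",
              x$manifest$profile, x$manifest$seed))
  print(x$selection)
  a <- x$triage_training$summary; b <- x$triage_test$summary
  cat(sprintf("  training hospital: %s | test hospital: %s\n",
              fmt_pct(a$n_hospital, a$n_allocated), fmt_pct(b$n_hospital, b$n_allocated)))
  if (x$comparison$method == "CHI_SQUARE")
    cat(sprintf("  chi-square %.3f (p=%.3f uncorrected; p=%.3f Yates-corrected)\n",
                x$comparison$statistic, x$comparison$p_uncorrected,
                x$comparison$p_corrected))
  else cat(sprintf("  Fisher exact p=%.3f\n", x$comparison$p_value))
  invisible(x)
}
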