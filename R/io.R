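# Trial-table I/O, external-data adaptation, configuration, and the
# end-to-end pipeline.

trial_schema <- function(experiment) {
  common <- c("subject_id", "experiment", "block", "trial_index",
              "modality", "response", "rt_ms")
  if (experiment == 1) {
    c(common, "rate_hz", "noise_level", "ipi_sequence", "pulses_presented")
  } else {
    c(common, "gap_ms", "dp_first", "sp_duration_ms", "correct")
  }
}

validate_trials <- function(trials, experiment) {
  required <- trial_schema(experiment)
  missing <- setdiff(required, names(trials))
  if (length(missing)) {
    stop("trial table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  allowed_mod <- if (experiment == 1) MODALITIES_EXP1 else MODALITIES_EXP2
  bad <- which(!trials$modality %in% allowed_mod)
  if (length(bad)) {
    stop(sprintf("invalid modality code '%s' at row %d",
                 trials$modality[bad[1]], bad[1]), call. = FALSE)
  }
  allowed_resp <- if (experiment == 1) {
    c("slow", "fast", "none")
  } else {
    c("first", "second", "none")
  }
  bad <- which(!trials$response %in% allowed_resp)
  if (length(bad)) {
    stop(sprintf("invalid response '%s' at row %d",
                 trials$response[bad[1]], bad[1]), call. = FALSE)
  }
  dur_col <- if (experiment == 1) "rt_ms" else "gap_ms"
  bad <- which(!is.na(trials[[dur_col]]) & trials[[dur_col]] < 0)
  if (length(bad)) {
    stop(sprintf("negative %s at row %d", dur_col, bad[1]), call. = FALSE)
  }
  invisible(trials)
}

#' Read / write a trial table
#'
#' Trial tables are plain CSV, one row per trial, with a fixed documented
#' schema per experiment (see [simulate_dataset()] for the columns).
#' Reading validates the schema and fails with an error naming the first
#' offending column or row; the write/read round trip is lossless.
#'
#' @param path File path.
#' @param experiment 1 or 2; inferred from the file's `experiment` column
#'   when omitted.
#' @return `read_trials()` returns a validated tibble; `write_trials()`
#'   returns `path` invisibly.
#' @export
read_trials <- function(path, experiment = NULL) {
  trials <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (is.null(experiment)) {
    if (!"experiment" %in% names(trials)) {
      stop("trial table is missing required column(s): experiment",
           call. = FALSE)
    }
    experiment <- unique(trials$experiment)
  }
  if (length(experiment) != 1 || !experiment %in% c(1, 2)) {
    stop("`experiment` must be 1 or 2", call. = FALSE)
  }
  validate_trials(trials, experiment)
  trials
}

#' @param trials A trial table.
#' @rdname read_trials
#' @export
write_trials <- function(trials, path) {
  validate_trials(trials, unique(trials$experiment))
  readr::write_csv(trials, path, progress = FALSE)
  invisible(path)
}

#' Adapt an externally exported trial table to the package schema
#'
#' External deposits use their own column names and codings.  This adapter
#' renames columns via a user-supplied mapping (`c(ours = "theirs")`),
#' optionally recodes modality and response values, fills in constant
#' columns that the source lacks, and validates the result.
#'
#' @param data A data frame as read from the external source.
#' @param experiment 1 or 2.
#' @param mapping Named character vector: names are package schema columns,
#'   values are the source's column names.
#' @param recode Optional named list of named vectors, e.g.
#'   `list(modality = c(visual = "V"))`, applied to the renamed columns.
#' @param constants Optional named list of scalar columns to add (e.g.
#'   `list(experiment = 1)`).
#' @return A validated trial-table tibble.
#' @export
adapt_trials <- function(data, experiment, mapping, recode = list(),
                         constants = list()) {
  missing_src <- setdiff(unname(mapping), names(data))
  if (length(missing_src)) {
    stop("source data lacks mapped column(s): ",
         paste(missing_src, collapse = ", "), call. = FALSE)
  }
  out <- tibble::as_tibble(data)
  out <- dplyr::rename(out, !!!rlang::set_names(mapping, names(mapping)))
  for (col in names(recode)) {
    codes <- recode[[col]]
    out[[col]] <- dplyr::recode(as.character(out[[col]]), !!!codes)
  }
  for (col in names(constants)) {
    out[[col]] <- constants[[col]]
  }
  validate_trials(out, experiment)
  out[, trial_schema(experiment), drop = FALSE]
}

#' Default pipeline configuration
#'
#' All design constants default to the studied experiments: 28 subjects x
#' 800 rate-categorization trials, 14 subjects x 450 gap-detection trials,
#' thresholds at 76% correct (d' = 1), 5000 bootstrap resamples.
#'
#' @param seed Integer seed driving every stochastic stage.
#' @param experiments Which experiments to run (subset of `c(1, 2)`).
#' @param n_subjects_exp1,n_subjects_exp2 Synthetic sample sizes.
#' @param bootstrap_B Bootstrap resamples for threshold SEs (0 to skip).
#' @param target_pc Threshold criterion.
#' @param rate_observer,gap_observer Observer parameter objects.
#' @return A `pipeline_config` list.
#' @export
default_config <- function(seed = 1L,
                           experiments = c(1L, 2L),
                           n_subjects_exp1 = 28L,
                           n_subjects_exp2 = 14L,
                           bootstrap_B = 5000L,
                           target_pc = 0.76,
                           rate_observer = rate_observer_params(),
                           gap_observer = gap_observer_params()) {
  stopifnot(length(seed) == 1, is.finite(seed),
            all(experiments %in% c(1L, 2L)))
  structure(
    list(
      seed = as.integer(seed),
      experiments = as.integer(experiments),
      n_subjects_exp1 = n_subjects_exp1,
      n_subjects_exp2 = n_subjects_exp2,
      bootstrap_B = bootstrap_B,
      target_pc = target_pc,
      rate_observer = rate_observer,
      gap_observer = gap_observer
    ),
    class = "pipeline_config"
  )
}

#' Run the full simulation-and-analysis pipeline
#'
#' Executes, per configured experiment: schedule construction, synthetic
#' data generation, exclusions, and the corresponding analyses
#' (sensitivity/criterion estimation plus criterion and simple-effect
#' tests for the rate task; psychometric fits, thresholds with bootstrap
#' SEs, subject fits and the unimodal-bimodal relations for the gap
#' task).  Every stochastic stage is seeded from `config$seed`, so the
#' bundle is reproducible bit-for-bit.
#'
#' @param config A [default_config()] list.
#' @param out_dir Optional directory; when given, trial tables and result
#'   tables are written there as CSV.
#' @return A `pipeline_result` list with elements `config_hash`, `seed`,
#'   and (per experiment) `exp1` / `exp2` result bundles.
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  result <- list(
    config_hash = rlang::hash(config),
    seed = config$seed
  )
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  if (1L %in% config$experiments) {
    schedule <- build_exp1_schedule(seed = config$seed)
    trials <- simulate_dataset(schedule, config$rate_observer,
                               config$n_subjects_exp1,
                               seed = config$seed + 101L)
    excl <- apply_exclusions(trials, experiment = 1)
    estimates <- estimate_sdt(excl$trials)
    result$exp1 <- list(
      trials = trials,
      exclusions = excl$summary,
      estimates = estimates,
      bias_tests = test_bias_neutral(estimates),
      simple_effects_A = simple_effect_modality(estimates, "A"),
      simple_effects_b = simple_effect_modality(estimates, "b")
    )
    if (!is.null(out_dir)) {
      write_trials(trials, file.path(out_dir, "exp1_trials.csv"))
      readr::write_csv(estimates, file.path(out_dir, "exp1_estimates.csv"),
                       progress = FALSE)
      readr::write_csv(result$exp1$bias_tests,
                       file.path(out_dir, "exp1_bias_tests.csv"),
                       progress = FALSE)
    }
  }
  if (2L %in% config$experiments) {
    schedule <- build_exp2_schedule(seed = config$seed + 200L)
    trials <- simulate_dataset(schedule, config$gap_observer,
                               config$n_subjects_exp2,
                               seed = config$seed + 201L)
    thresholds <- fit_gap_thresholds(trials, target_pc = config$target_pc,
                                     B = config$bootstrap_B,
                                     seed = config$seed + 202L)
    subjects <- fit_subject_pfs(trials, target_pc = config$target_pc)
    acc <- tidyr::pivot_wider(subjects$accuracy, names_from = "modality",
                              values_from = "accuracy")
    result$exp2 <- list(
      trials = trials,
      thresholds = thresholds,
      subject_fits = subjects$fits,
      accuracy = subjects$accuracy,
      relation_T_VT = unimodal_bimodal_relation(acc$T, acc$VT),
      relation_V_VT = unimodal_bimodal_relation(acc$V, acc$VT)
    )
    if (!is.null(out_dir)) {
      write_trials(trials, file.path(out_dir, "exp2_trials.csv"))
      readr::write_csv(thresholds, file.path(out_dir, "exp2_thresholds.csv"),
                       progress = FALSE)
      readr::write_csv(subjects$accuracy,
                       file.path(out_dir, "exp2_accuracy.csv"),
                       progress = FALSE)
    }
  }
  structure(result, class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> seed %d, config %s\n", x$seed,
              x$config_hash))
  if (!is.null(x$exp1)) {
    cat(sprintf("  exp1: %d trials, %d subject-level estimates\n",
                nrow(x$exp1$trials), nrow(x$exp1$estimates)))
  }
  if (!is.null(x$exp2)) {
    thr <- x$exp2$thresholds
    cat(sprintf("  exp2: thresholds (ms) %s\n",
                paste(sprintf("%s=%.1f", thr$modality, thr$threshold_ms),
                      collapse = ", ")))
  }
  invisible(x)
}
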