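#' Write cohort tables as delimited text
#'
#' Writes `subjects.csv`, `press_log.csv` (one row per press),
#' `recall.csv`, `anxiety.csv`, `agreement.csv`, `norms.csv` and
#' `truth.json` (generating parameters and latent boundary times, for
#' recovery tests) into `dir`.
#'
#' @param cohort A `cohort` from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) utils::write.csv(df, file.path(dir, name), row.names = FALSE)
  w(cohort$subjects, "subjects.csv")
  w(cohort$press_log, "press_log.csv")
  w(cohort$recall, "recall.csv")
  w(cohort$anxiety, "anxiety.csv")
  w(cohort$agreement, "agreement.csv")
  w(cohort$norms, "norms.csv")
  truth <- list(
    config = unclass(cohort$config),
    videos = purrr::map(cohort$truth$videos, function(v) {
      list(video_id = v$video_id, duration_s = v$duration_s,
           boundary_times = v$boundary_times, salience = v$salience)
    }),
    ability = setNames(as.list(cohort$subjects$ability), cohort$subjects$subject_id)
  )
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read cohort tables from a directory of delimited text files
#'
#' Expects the schema written by [write_cohort()] (at minimum
#' `subjects.csv`, `press_log.csv`, `recall.csv`, `anxiety.csv`).
#'
#' @param dir Directory containing the CSV files.
#' @return A list with `subjects`, `press_log`, `recall`, `anxiety` tibbles.
#' @export
read_cohort_tables <- function(dir) {
  rd <- function(name, cols) {
    path <- file.path(dir, name)
    if (!file.exists(path)) {
      abort(sprintf("Missing input table: %s", path),
            class = "eventmem_input_error")
    }
    df <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
    assert_columns(df, cols, name)
    df
  }
  list(
    subjects = rd("subjects.csv", c("subject_id", "group", "pcl_total")),
    press_log = rd("press_log.csv", c("subject_id", "video_id", "condition", "press_time_s")),
    recall = rd("recall.csv", c("subject_id", "video_id", "condition",
                                "n_units_total", "n_recalled")),
    anxiety = rd("anxiety.csv", c("subject_id", "condition", "trial_index", "rating"))
  )
}

#' Run the full analysis pipeline
#'
#' One call that generates (or ingests) a cohort, scores segmentation
#' agreement and recall, fits the six crossed mixed models (group and
#' severity variants for anxiety, agreement, recall), runs both mediation
#' analyses, and returns a structured report. With `out_dir` set, all
#' intermediate tables plus `report.json` and a human-readable
#' `report.md` are written; the run is deterministic under a fixed config
#' seed.
#'
#' @param config A [cohort_config()] (synthetic mode), or a path to a
#'   YAML/JSON config file.
#' @param out_dir Optional output directory for artifacts.
#' @param input_dir Optional directory of observed tables in the
#'   [write_cohort()] schema; when given, generation is skipped and
#'   `config$videos` supplies the durations.
#' @param n_draws Monte-Carlo draws for each mediation.
#' @return A list of class `report_bundle`: `config`, `descriptives`,
#'   `models` (six `mem_fit`s), `mediation` (two `mediation_result`s),
#'   `exclusions`, and `truth` when synthetic.
#' @export
#' @examples
#' rep <- run_pipeline(cohort_config(n_ptsd = 10, n_control = 10, seed = 2),
#'                     n_draws = 200)
#' rep$descriptives$boundaries_per_video
run_pipeline <- function(config = cohort_config(), out_dir = NULL,
                         input_dir = NULL, n_draws = 1000) {
  if (is.character(config)) config <- read_config(config)
  config <- validate_config(config)

  exclusions <- list()
  if (is.null(input_dir)) {
    cohort <- generate_cohort(config)
    truth <- cohort$truth
  } else {
    tabs <- read_cohort_tables(input_dir)
    durations <- setNames(config$videos$duration_s, config$videos$video_id)
    frame <- dplyr::distinct(tabs$recall, .data$subject_id, .data$video_id,
                             .data$condition)
    seg <- segmentation_agreement(tabs$press_log, durations, conditions = frame)
    cohort <- c(tabs, seg)
    cohort$config <- config
    truth <- NULL
  }
  n_degenerate <- sum(is.na(cohort$agreement$scaled))
  exclusions$degenerate_agreement <- n_degenerate

  if (!is.null(out_dir)) {
    if (inherits(cohort, "cohort")) {
      write_cohort(cohort, out_dir)
    } else {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    }
  }

  presses_per <- dplyr::left_join(
    dplyr::select(cohort$agreement, "subject_id", "video_id"),
    dplyr::count(cohort$press_log, .data$subject_id, .data$video_id),
    by = c("subject_id", "video_id"))
  presses_per$n[is.na(presses_per$n)] <- 0L
  recall_scored <- score_recall(cohort$recall)
  subj <- cohort$subjects

  grp_mean <- function(df, value, key) {
    tab <- df
    if (!key %in% names(tab) || key == "group") {
      tab <- dplyr::left_join(
        dplyr::select(df, -dplyr::any_of("group")),
        dplyr::select(subj, "subject_id", "group"), by = "subject_id")
    }
    as.list(tapply(tab[[value]], tab[[key]], mean, na.rm = TRUE))
  }
  descriptives <- list(
    n_subjects = nrow(subj),
    boundaries_per_video = list(
      mean = mean(presses_per$n),
      sd = sd(presses_per$n),
      range = range(presses_per$n)
    ),
    anxiety_by_group = grp_mean(cohort$anxiety, "rating", "group"),
    anxiety_by_condition = grp_mean(cohort$anxiety, "rating", "condition"),
    agreement_by_group = grp_mean(cohort$agreement, "scaled", "group"),
    agreement_by_condition = grp_mean(cohort$agreement, "scaled", "condition"),
    recall_by_group = grp_mean(recall_scored, "proportion", "group"),
    recall_by_condition = grp_mean(recall_scored, "proportion", "condition")
  )

  models <- list()
  for (oc in c("anxiety", "agreement", "recall")) {
    models[[paste0("group_", oc)]] <- run_group_model(cohort, oc)
    models[[paste0("severity_", oc)]] <- run_severity_model(cohort, oc)
  }

  summaries <- aggregate_per_subject(cohort$agreement, recall_scored, subj)
  med_seed <- config$seed + 101L
  mediation <- list(
    group = estimate_mediation(summaries, "group", n_draws = n_draws,
                               seed = med_seed),
    severity = estimate_mediation(summaries, "severity", n_draws = n_draws,
                                  seed = med_seed + 1L)
  )

  report <- structure(
    list(config = config, descriptives = descriptives, models = models,
         mediation = mediation, exclusions = exclusions,
         truth = truth),
    class = "report_bundle"
  )

  if (!is.null(out_dir)) {
    utils::write.csv(recall_scored, file.path(out_dir, "recall_scores.csv"),
                     row.names = FALSE)
    utils::write.csv(summaries, file.path(out_dir, "subject_summaries.csv"),
                     row.names = FALSE)
    jsonlite::write_json(report_as_list(report), file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
    writeLines(report_markdown(report), file.path(out_dir, "report.md"))
  }
  report
}

report_as_list <- function(report) {
  list(
    seed = report$config$seed,
    n_ptsd = report$config$n_ptsd,
    n_control = report$config$n_control,
    descriptives = report$descriptives,
    exclusions = report$exclusions,
    models = purrr::map(report$models, function(m) {
      list(outcome = m$outcome, converged = m$converged,
           fit_method = m$fit_method,
           fixed_effects = as.data.frame(m$fixed_effects),
           variance_components = as.list(m$variance_components),
           n_obs = m$n_obs)
    }),
    mediation = purrr::map(report$mediation, function(x) {
      list(predictor = x$predictor, n_subjects = x$n_subjects,
           n_draws = x$n_draws, paths = as.list(x$paths),
           acme = x$acme, acme_ci = x$acme_ci, acme_p = x$acme_p,
           ade = x$ade, ade_ci = x$ade_ci, ade_p = x$ade_p,
           total = x$total, total_ci = x$total_ci, total_p = x$total_p,
           prop_mediated = x$prop_mediated,
           prop_mediated_untruncated = x$prop_mediated_untruncated,
           r_squared_outcome = x$r_squared_outcome)
    })
  )
}

report_markdown <- function(report) {
  d <- report$descriptives
  lines <- c(
    "# Event segmentation & memory pipeline report", "",
    sprintf("Subjects: %d (seed %s)", d$n_subjects, report$config$seed),
    sprintf("Mean boundaries per video: %.2f (SD %.2f, range %d-%d)",
            d$boundaries_per_video$mean, d$boundaries_per_video$sd,
            d$boundaries_per_video$range[1], d$boundaries_per_video$range[2]),
    "", "## Group means",
    sprintf("- Anxiety: PTSD %.2f / control %.2f; traumatic %.2f / positive %.2f",
            d$anxiety_by_group$PTSD, d$anxiety_by_group$CONTROL,
            d$anxiety_by_condition$TRAUMATIC, d$anxiety_by_condition$POSITIVE),
    sprintf("- Agreement: PTSD %.3f / control %.3f",
            d$agreement_by_group$PTSD, d$agreement_by_group$CONTROL),
    sprintf("- Recall: PTSD %.3f / control %.3f",
            d$recall_by_group$PTSD, d$recall_by_group$CONTROL),
    "", "## Fixed effects (estimate, p)")
  for (nm in names(report$models)) {
    fe <- report$models[[nm]]$fixed_effects
    fe <- fe[fe$term != "(Intercept)", ]
    lines <- c(lines, sprintf("- %s: %s", nm,
      paste(sprintf("%s = %.4f (p = %.3g)", fe$term, fe$estimate, fe$p_value),
            collapse = ", ")))
  }
  lines <- c(lines, "", "## Mediation")
  for (nm in names(report$mediation)) {
    x <- report$mediation[[nm]]
    lines <- c(lines, sprintf(
      "- %s: ACME %.4f, ADE %.4f, total %.4f, proportion mediated %.1f%%, outcome R2 %.2f",
      nm, x$acme, x$ade, x$total, 100 * x$prop_mediated, x$r_squared_outcome))
  }
  lines
}

#' @export
print.report_bundle <- function(x, ...) {
  cat(report_markdown(x), sep = "\n")
  invisible(x)
}
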