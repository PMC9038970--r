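#' Fit a linear mixed model with crossed random intercepts
#'
#' Fits `outcome ~ fixed terms + (1 | f) ...` by REML with an independent
#' random intercept for each grouping factor, treatment coding (first
#' factor level is the reference), and Wald z tests for the fixed effects.
#' Non-convergence never fails silently: the returned fit carries a
#' `converged` flag and the fitting messages.
#'
#' @param data Data frame containing the outcome, fixed-effect columns and
#'   grouping factors.
#' @param outcome Name of the numeric outcome column.
#' @param fixed Character vector of fixed-effect terms (may include `:`
#'   interactions), or a one-sided formula.
#' @param random Character vector of grouping-factor column names, each
#'   receiving an independent random intercept.
#' @return An object of class `mem_fit`: list with `fixed_effects` (tibble
#'   of term, estimate, std_error, statistic, p_value), `variance_components`,
#'   `n_obs`, `converged`, `fit_method`, `reference_levels`, `outcome`, and
#'   the underlying `lme4` fit in `$fit`.
#' @export
#' @examples
#' d <- tidyr::expand_grid(s = factor(1:6), v = factor(1:4))
#' d$x <- rep(c(0, 1), length.out = nrow(d))
#' d$y <- 2 + 1 * d$x + rnorm(nrow(d), 0, 0.1)
#' fit <- fit_crossed_mixed(d, "y", "x", c("s", "v"))
#' tidy(fit)
fit_crossed_mixed <- function(data, outcome, fixed, random) {
  if (inherits(fixed, "formula")) fixed <- attr(stats::terms(fixed), "term.labels")
  assert_columns(data, c(outcome, all.vars(stats::reformulate(fixed)), random),
                 "model `data`")
  if (!is.numeric(data[[outcome]])) {
    abort(sprintf("Outcome `%s` must be numeric.", outcome),
          class = "eventmem_input_error")
  }
  for (g in random) {
    data[[g]] <- factor(data[[g]])
    if (nlevels(data[[g]]) < 2L) {
      abort(sprintf("Random factor `%s` needs >= 2 levels.", g),
            class = "eventmem_input_error")
    }
  }
  rhs <- paste(c(fixed, sprintf("(1 | %s)", random)), collapse = " + ")
  form <- stats::as.formula(paste(outcome, "~", rhs))

  msgs <- character(0)
  fit <- withCallingHandlers(
    lme4::lmer(form, data = data, REML = TRUE,
               control = lme4::lmerControl(check.conv.singular = "ignore")),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    },
    message = function(m) {
      msgs <<- c(msgs, conditionMessage(m))
      invokeRestart("muffleMessage")
    }
  )
  conv <- length(fit@optinfo$conv$lme4$messages %||% character(0)) == 0L
  if (!conv) {
    warn(sprintf("Mixed model for `%s` did not converge cleanly; fit flagged.",
                 outcome))
  }

  sm <- summary(fit)$coefficients
  fe <- tibble::tibble(
    term = rownames(sm),
    estimate = unname(sm[, "Estimate"]),
    std_error = unname(sm[, "Std. Error"]),
    statistic = unname(sm[, "t value"]),
    p_value = unname(2 * pnorm(-abs(sm[, "t value"])))
  )
  vc <- as.data.frame(lme4::VarCorr(fit))
  vcs <- setNames(vc$vcov, vc$grp)

  refs <- vapply(names(data)[vapply(data, is.factor, logical(1))],
                 function(nm) levels(data[[nm]])[1], character(1))
  structure(
    list(
      outcome = outcome,
      fixed_effects = fe,
      variance_components = vcs,
      n_obs = stats::nobs(fit),
      converged = conv,
      fit_method = "REML, treatment coding, Wald z",
      reference_levels = refs,
      messages = msgs,
      fit = fit
    ),
    class = "mem_fit"
  )
}

# Build the merged analysis table for one outcome from a cohort's tables.
build_analysis_table <- function(cohort, outcome) {
  subjects <- dplyr::select(cohort$subjects, "subject_id", "group", "pcl_total")
  if (outcome == "anxiety") {
    tab <- dplyr::left_join(cohort$anxiety,
                            dplyr::select(subjects, "subject_id", "pcl_total"),
                            by = "subject_id") |>
      dplyr::rename(y = "rating") |>
      dplyr::mutate(trial = factor(.data$trial_index))
  } else if (outcome == "agreement") {
    tab <- dplyr::left_join(cohort$agreement, subjects, by = "subject_id") |>
      dplyr::rename(y = "scaled")
    n_drop <- sum(is.na(tab$y))
    if (n_drop > 0) {
      inform(sprintf("Dropping %d subject-video(s) with missing scaled agreement.",
                     n_drop))
      tab <- tab[!is.na(tab$y), ]
    }
  } else if (outcome == "recall") {
    tab <- score_recall(cohort$recall) |>
      dplyr::left_join(subjects, by = "subject_id") |>
      dplyr::rename(y = "proportion")
  } else {
    abort(sprintf("Unknown outcome `%s`.", outcome),
          class = "eventmem_input_error")
  }
  tab$group <- factor(tab$group, levels = c("CONTROL", "PTSD"))
  tab$condition <- factor(tab$condition, levels = c("POSITIVE", "TRAUMATIC"))
  tab
}

model_random_factors <- function(outcome) {
  if (outcome == "anxiety") c("subject_id", "trial") else c("subject_id", "video_id")
}

#' Group-by-condition mixed model for one outcome
#'
#' Fits the diagnosis analysis: fixed effects of Group (PTSD vs. control
#' reference), narrative Condition (traumatic vs. positive reference) and
#' their interaction, with crossed random intercepts for subject and trial
#' (anxiety) or subject and video (agreement, recall).
#'
#' @param cohort A `cohort` from [generate_cohort()] or a list with the
#'   same named tables (`subjects`, `agreement`, `recall`, `anxiety`).
#' @param outcome One of `"anxiety"`, `"agreement"`, `"recall"`.
#' @param session_average For anxiety only: average the trial-level ratings
#'   per subject-session first (the random structure then reduces to a
#'   subject intercept).
#' @return A `mem_fit`.
#' @export
run_group_model <- function(cohort, outcome = c("anxiety", "agreement", "recall"),
                            session_average = FALSE) {
  outcome <- match.arg(outcome)
  tab <- build_analysis_table(cohort, outcome)
  rand <- model_random_factors(outcome)
  if (outcome == "anxiety" && session_average) {
    tab <- dplyr::summarise(tab, y = mean(.data$y),
                            .by = c("subject_id", "group", "condition"))
    rand <- "subject_id"
  }
  fit_crossed_mixed(tab, "y", c("group", "condition", "group:condition"), rand)
}

#' Symptom-severity mixed model for one outcome
#'
#' Same structure as [run_group_model()] but with the mean-centered PCL
#' total (`severity`) replacing Group; centering uses the mean over the
#' distinct subjects of the analysis sample, before the interaction is
#' formed.
#'
#' @inheritParams run_group_model
#' @return A `mem_fit`.
#' @export
run_severity_model <- function(cohort, outcome = c("anxiety", "agreement", "recall"),
                               session_average = FALSE) {
  outcome <- match.arg(outcome)
  tab <- build_analysis_table(cohort, outcome)
  if (anyNA(tab$pcl_total)) {
    abort("PCL totals missing for some subjects.", class = "eventmem_input_error")
  }
  subj_pcl <- dplyr::distinct(tab, .data$subject_id, .data$pcl_total)
  if (sd(subj_pcl$pcl_total) == 0) {
    abort("Symptom severity has zero variance.", class = "eventmem_input_error")
  }
  tab$severity <- tab$pcl_total - mean(subj_pcl$pcl_total)
  rand <- model_random_factors(outcome)
  if (outcome == "anxiety" && session_average) {
    tab <- dplyr::summarise(tab, y = mean(.data$y),
                            .by = c("subject_id", "severity", "condition"))
    rand <- "subject_id"
  }
  fit_crossed_mixed(tab, "y", c("severity", "condition", "severity:condition"), rand)
}

#' @export
print.mem_fit <- function(x, ...) {
  cat("Crossed random-intercept model (", x$fit_method, ")\n", sep = "")
  cat("Outcome:", x$outcome, " n =", x$n_obs,
      if (!x$converged) " [NOT CONVERGED]" else "", "\n")
  print(as.data.frame(x$fixed_effects), digits = 3)
  cat("Variance components:\n")
  print(round(x$variance_components, 5))
  invisible(x)
}

#' Tidy a crossed mixed-model fit
#'
#' @param x A `mem_fit`.
#' @param ... Unused.
#' @return Tibble of fixed effects: `term`, `estimate`, `std_error`,
#'   `statistic`, `p_value`.
#' @method tidy mem_fit
#' @export
tidy.mem_fit <- function(x, ...) x$fixed_effects

#' One-row summary of a crossed mixed-model fit
#'
#' @param x A `mem_fit`.
#' @param ... Unused.
#' @return One-row tibble: `n_obs`, `converged`, `sigma2_residual`, one
#'   `var_*` column per grouping factor.
#' @method glance mem_fit
#' @export
glance.mem_fit <- function(x, ...) {
  vcs <- x$variance_components
  out <- tibble::tibble(n_obs = x$n_obs, converged = x$converged)
  for (nm in names(vcs)) {
    col <- if (nm == "Residual") "sigma2_residual" else paste0("var_", nm)
    out[[col]] <- unname(vcs[[nm]])
  }
  out
}
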