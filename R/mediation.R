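#' Aggregate agreement and recall to one row per subject
#'
#' The mediation analysis uses one segmentation score and one memory score
#' per subject: the unweighted mean of scaled agreement and of recall
#' proportion over all non-missing videos, pooled across both narrative
#' conditions. Subjects with no scoreable video are excluded with a
#' warning.
#'
#' @param agreement Agreement table from [score_agreement()].
#' @param recall Recall table (raw counts or already scored with
#'   [score_recall()]).
#' @param subjects Subject table with `subject_id`, `group`, `pcl_total`.
#' @return Tibble with one row per subject: `subject_id`, `group`,
#'   `pcl_total`, `mean_agreement`, `mean_recall`.
#' @export
aggregate_per_subject <- function(agreement, recall, subjects) {
  assert_columns(agreement, c("subject_id", "scaled"), "`agreement`")
  assert_columns(subjects, c("subject_id", "group", "pcl_total"), "`subjects`")
  if (!"proportion" %in% names(recall)) recall <- score_recall(recall)

  ag <- dplyr::summarise(agreement,
                         mean_agreement = mean(.data$scaled, na.rm = TRUE),
                         n_valid = sum(!is.na(.data$scaled)),
                         .by = "subject_id")
  rc <- dplyr::summarise(recall, mean_recall = mean(.data$proportion),
                         .by = "subject_id")
  out <- dplyr::select(subjects, "subject_id", "group", "pcl_total") |>
    dplyr::inner_join(ag, by = "subject_id") |>
    dplyr::inner_join(rc, by = "subject_id")
  n_excluded <- sum(out$n_valid == 0) + (nrow(subjects) - nrow(out))
  if (n_excluded > 0) {
    warn(sprintf("%d subject(s) excluded: no valid agreement or recall scores.",
                 n_excluded))
    out <- out[out$n_valid > 0, ]
  }
  dplyr::select(out, -"n_valid")
}

#' Quasi-Bayesian causal mediation of the group or severity effect on recall
#'
#' Estimates how much of the predictor's total effect on memory travels
#' through segmentation agreement. Fits the mediator regression
#' `M ~ X` and the outcome regression `Y ~ X + M` by least squares, draws
#' `n_draws` coefficient vectors from each fit's asymptotic normal
#' approximation, and per draw computes the average causal mediation effect
#' `ACME = a * b`, the average direct effect `ADE = c'`, and the total
#' effect `a * b + c'` (so the decomposition is exact in every draw).
#' Point estimates are draw means; intervals are percentile; p-values are
#' two-sided Monte-Carlo sign probabilities. The headline proportion
#' mediated is the ratio of the ACME point estimate to the total-effect
#' point estimate, truncated to `[0, 1]` (the ratio of draw means is much
#' less biased than the mean of per-draw ratios, which is kept in the
#' result as `prop_mediated_draw_mean`); its interval comes from the
#' per-draw truncated ratios, and it is flagged unstable when the total
#' effect is not distinguishable from zero.
#'
#' @param summaries Per-subject table from [aggregate_per_subject()].
#' @param predictor `"group"` (PTSD vs. control, control = 0) or
#'   `"severity"` (mean-centered PCL total).
#' @param n_draws Number of Monte-Carlo parameter draws (default 1000).
#' @param seed Seed for the draws (required for reproducibility).
#' @param method `"quasi-bayes"` (parameter draws, default) or `"boot"`
#'   (nonparametric subject resampling).
#' @return An object of class `mediation_result`; see [tidy.mediation_result()].
#' @export
#' @examples
#' coh <- generate_cohort(cohort_config(n_ptsd = 15, n_control = 15, seed = 3))
#' s <- aggregate_per_subject(coh$agreement, coh$recall, coh$subjects)
#' med <- estimate_mediation(s, "group", n_draws = 200, seed = 1)
#' med
estimate_mediation <- function(summaries, predictor = c("group", "severity"),
                               n_draws = 1000, seed,
                               method = c("quasi-bayes", "boot")) {
  predictor <- match.arg(predictor)
  method <- match.arg(method)
  if (missing(seed)) {
    abort("`seed` is required for the Monte-Carlo draws.",
          class = "eventmem_config_error")
  }
  assert_columns(summaries, c("group", "pcl_total", "mean_agreement", "mean_recall"),
                 "`summaries`")
  if (nrow(summaries) < 20L) {
    abort("Mediation needs at least 20 subjects.", class = "eventmem_input_error")
  }
  d <- tibble::tibble(
    x = if (predictor == "group") as.numeric(summaries$group == "PTSD")
        else summaries$pcl_total - mean(summaries$pcl_total),
    m = summaries$mean_agreement,
    y = summaries$mean_recall
  )
  d <- d[complete.cases(d), ]
  if (sd(d$x) == 0) {
    abort("Predictor is constant.", class = "eventmem_input_error")
  }

  fit_m <- lm(m ~ x, data = d)
  fit_y <- lm(y ~ x + m, data = d)

  draws <- with_seed(seed, {
    if (method == "quasi-bayes") {
      a <- mvn_draws(n_draws, coef(fit_m), vcov(fit_m))[, "x"]
      by_mat <- mvn_draws(n_draws, coef(fit_y), vcov(fit_y))
      tibble::tibble(a = a, b = by_mat[, "m"], cprime = by_mat[, "x"])
    } else {
      n <- nrow(d)
      purrr::map_dfr(seq_len(n_draws), function(i) {
        idx <- sample.int(n, n, replace = TRUE)
        db <- d[idx, ]
        if (sd(db$x) == 0 || sd(db$m) == 0) {
          return(tibble::tibble(a = NA_real_, b = NA_real_, cprime = NA_real_))
        }
        cm <- coef(lm(m ~ x, data = db))
        cy <- coef(lm(y ~ x + m, data = db))
        tibble::tibble(a = cm[["x"]], b = cy[["m"]], cprime = cy[["x"]])
      }) |> stats::na.omit()
    }
  })

  acme_d <- draws$a * draws$b
  ade_d <- draws$cprime
  total_d <- acme_d + ade_d
  ratio_d <- acme_d / total_d

  pct <- function(v) unname(quantile(v, c(0.025, 0.975)))
  pval <- function(v) min(1, 2 * min(mean(v > 0), mean(v < 0)) + 1 / length(v))

  total_p <- pval(total_d)
  unstable <- total_p > 0.10
  if (unstable) {
    warn("Total effect indistinguishable from 0; proportion mediated flagged unstable.")
  }

  structure(
    list(
      predictor = toupper(predictor),
      n_subjects = nrow(d),
      n_draws = nrow(draws),
      seed = seed,
      method = method,
      paths = c(a = unname(coef(fit_m)[["x"]]),
                b = unname(coef(fit_y)[["m"]]),
                cprime = unname(coef(fit_y)[["x"]])),
      acme = mean(acme_d), acme_ci = pct(acme_d), acme_p = pval(acme_d),
      ade = mean(ade_d), ade_ci = pct(ade_d), ade_p = pval(ade_d),
      total = mean(total_d), total_ci = pct(total_d), total_p = total_p,
      prop_mediated = clamp(mean(acme_d) / mean(total_d), 0, 1),
      prop_mediated_ci = pct(clamp(ratio_d, 0, 1)),
      prop_mediated_untruncated = mean(acme_d) / mean(total_d),
      prop_mediated_draw_mean = mean(clamp(ratio_d, 0, 1)),
      prop_unstable = unstable,
      r_squared_outcome = summary(fit_y)$r.squared,
      fits = list(mediator = fit_m, outcome = fit_y)
    ),
    class = "mediation_result"
  )
}

mvn_draws <- function(n, mu, sigma) {
  L <- chol(sigma)
  z <- matrix(rnorm(n * length(mu)), nrow = n)
  sweep(z %*% L, 2, mu, `+`)
}

#' Proportion of the total effect carried by the mediator, in percent
#'
#' @param result A `mediation_result`.
#' @return The headline proportion mediated as a percentage of the total
#'   effect (per-draw ratio truncated to `[0, 1]`, averaged). A warning is
#'   re-issued when the total effect was unstable.
#' @export
proportion_mediated <- function(result) {
  stopifnot(inherits(result, "mediation_result"))
  if (result$prop_unstable) {
    warn("Proportion mediated is unstable (total effect near 0).")
  }
  100 * result$prop_mediated
}

#' @export
print.mediation_result <- function(x, ...) {
  cat("Causal mediation (", x$method, ", ", x$n_draws, " draws)\n", sep = "")
  cat("Predictor:", x$predictor, "| mediator: segmentation agreement | outcome: recall\n")
  fmt <- function(est, ci, p) sprintf("%8.4f  [%7.4f, %7.4f]  p = %.3f", est, ci[1], ci[2], p)
  cat("  ACME  (indirect):", fmt(x$acme, x$acme_ci, x$acme_p), "\n")
  cat("  ADE   (direct):  ", fmt(x$ade, x$ade_ci, x$ade_p), "\n")
  cat("  Total effect:    ", fmt(x$total, x$total_ci, x$total_p), "\n")
  cat(sprintf("  Proportion mediated: %.1f%%%s\n", 100 * x$prop_mediated,
              if (x$prop_unstable) " (unstable)" else ""))
  cat(sprintf("  Outcome R-squared: %.3f | n = %d subjects\n",
              x$r_squared_outcome, x$n_subjects))
  invisible(x)
}

#' Tidy a mediation result
#'
#' @param x A `mediation_result`.
#' @param ... Unused.
#' @return Tibble with one row per effect (`acme`, `ade`, `total`,
#'   `prop_mediated`): `estimate`, `conf_low`, `conf_high`, `p_value`.
#' @method tidy mediation_result
#' @export
tidy.mediation_result <- function(x, ...) {
  tibble::tibble(
    term = c("acme", "ade", "total", "prop_mediated"),
    estimate = c(x$acme, x$ade, x$total, x$prop_mediated),
    conf_low = c(x$acme_ci[1], x$ade_ci[1], x$total_ci[1], x$prop_mediated_ci[1]),
    conf_high = c(x$acme_ci[2], x$ade_ci[2], x$total_ci[2], x$prop_mediated_ci[2]),
    p_value = c(x$acme_p, x$ade_p, x$total_p, NA_real_)
  )
}

#' One-row summary of a mediation result
#'
#' @param x A `mediation_result`.
#' @param ... Unused.
#' @return One-row tibble: predictor, n_subjects, n_draws,
#'   r_squared_outcome, prop_mediated, prop_unstable.
#' @method glance mediation_result
#' @export
glance.mediation_result <- function(x, ...) {
  tibble::tibble(
    predictor = x$predictor,
    n_subjects = x$n_subjects,
    n_draws = x$n_draws,
    r_squared_outcome = x$r_squared_outcome,
    prop_mediated = x$prop_mediated,
    prop_unstable = x$prop_unstable
  )
}
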