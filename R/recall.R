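#' Score recall as the proportion of A1 units recalled
#'
#' Adds `proportion = n_recalled / n_units_total` per subject-video row,
#' the study's memory measure.
#'
#' @param recall Data frame with `subject_id`, `video_id`, `condition`,
#'   `n_units_total` (>= 1), `n_recalled`.
#' @return The input tibble with a `proportion` column appended.
#' @export
#' @examples
#' score_recall(tibble::tibble(subject_id = "S1", video_id = "v",
#'   condition = "POSITIVE", n_units_total = 40, n_recalled = 10))
score_recall <- function(recall) {
  assert_columns(recall, c("subject_id", "video_id", "condition",
                           "n_units_total", "n_recalled"), "`recall`")
  if (any(recall$n_units_total < 1)) {
    abort("`n_units_total` must be >= 1 for every row.",
          class = "eventmem_input_error")
  }
  bad <- which(recall$n_recalled > recall$n_units_total | recall$n_recalled < 0)
  if (length(bad)) {
    abort(sprintf("`n_recalled` outside [0, n_units_total] in row(s): %s",
                  paste(head(bad, 5L), collapse = ", ")),
          class = "eventmem_input_error")
  }
  dplyr::mutate(tibble::as_tibble(recall),
                proportion = .data$n_recalled / .data$n_units_total)
}

#' Cohen's kappa for two binary coders
#'
#' Chance-corrected interrater agreement
#' `kappa = (p_o - p_e) / (1 - p_e)` with observed agreement `p_o` and
#' chance agreement `p_e` from the coders' marginal rates; used to validate
#' unit-level recall coding.
#'
#' @param coder_a,coder_b Equal-length binary (0/1 or logical) vectors of
#'   per-unit decisions, length >= 2.
#' @return Kappa in `[-1, 1]`.
#' @export
#' @examples
#' cohens_kappa(c(1, 1, 0, 0, 1), c(1, 1, 0, 1, 1))
cohens_kappa <- function(coder_a, coder_b) {
  a <- as.integer(coder_a)
  b <- as.integer(coder_b)
  if (length(a) != length(b) || length(a) < 2L) {
    abort("Coders must supply equal-length vectors of length >= 2.",
          class = "eventmem_input_error")
  }
  if (!all(a %in% c(0L, 1L)) || !all(b %in% c(0L, 1L))) {
    abort("Coder decisions must be binary (0/1).",
          class = "eventmem_input_error")
  }
  n <- length(a)
  p_o <- mean(a == b)
  pa <- mean(a)
  pb <- mean(b)
  p_e <- pa * pb + (1 - pa) * (1 - pb)
  if (1 - p_e < .Machine$double.eps) {
    abort("Kappa is undefined: chance agreement is 1 (both coders constant with identical marginals).",
          class = "eventmem_undefined_error")
  }
  (p_o - p_e) / (1 - p_e)
}
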