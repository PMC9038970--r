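#' Bin press times into one-second indicator vectors
#'
#' Divides each video into `bin_width`-second bins (half-open intervals
#' `[b*w, (b+1)*w)`, 0-based bin indices) and marks a bin when at least one
#' press falls in it. A press at exactly the video duration is assigned to
#' the final bin. Subject-videos with no presses yield all-zero vectors
#' when they are listed in `conditions`; otherwise only subject-videos
#' present in the press log appear.
#'
#' @param press_log Data frame with `subject_id`, `video_id`, `condition`,
#'   `press_time_s` (one row per press).
#' @param durations Named numeric vector (`video_id -> duration_s`) or a
#'   data frame with columns `video_id`, `duration_s`.
#' @param bin_width Bin width in seconds (default 1).
#' @param subjects Optional character vector of all subject ids (used with
#'   `conditions` to retain press-free subject-videos).
#' @param conditions Optional data frame `subject_id`, `video_id`,
#'   `condition` enumerating every subject-video pairing to score.
#' @return Tibble with one row per subject-video: `subject_id`, `video_id`,
#'   `condition`, `k` (number of marked bins), `n_bins`, and a list-column
#'   `indicator` of 0/1 integer vectors.
#' @export
#' @examples
#' log <- tibble::tibble(subject_id = "S1", video_id = "v", condition = "POSITIVE",
#'                       press_time_s = c(3.2, 3.7, 10.0))
#' bin_presses(log, c(v = 12))[, c("k", "n_bins")]
bin_presses <- function(press_log, durations, bin_width = 1,
                        subjects = NULL, conditions = NULL) {
  assert_columns(press_log, c("subject_id", "video_id", "condition", "press_time_s"),
                 "`press_log`")
  if (is.data.frame(durations)) {
    durations <- setNames(durations$duration_s, durations$video_id)
  }
  unknown <- setdiff(unique(press_log$video_id), names(durations))
  if (length(unknown)) {
    abort(sprintf("No duration given for video(s): %s",
                  paste(unknown, collapse = ", ")),
          class = "eventmem_input_error")
  }
  dur <- unname(durations[press_log$video_id])
  bad <- which(press_log$press_time_s < 0 | press_log$press_time_s > dur)
  if (length(bad)) {
    abort(sprintf(
      "Press time outside [0, duration] in press_log row(s): %s",
      paste(head(bad, 5L), collapse = ", ")),
      class = "eventmem_input_error")
  }

  frame <- if (!is.null(conditions)) {
    tibble::as_tibble(conditions)
  } else {
    dplyr::distinct(press_log, .data$subject_id, .data$video_id, .data$condition)
  }
  assert_columns(frame, c("subject_id", "video_id", "condition"), "`conditions`")

  split_key <- paste(press_log$subject_id, press_log$video_id, sep = "\r")
  press_split <- split(press_log$press_time_s, split_key)

  n_bins_of <- ceiling(unname(durations[frame$video_id]) / bin_width)
  frame_key <- paste(frame$subject_id, frame$video_id, sep = "\r")
  indicator <- purrr::map(seq_len(nrow(frame)), function(r) {
    nb <- n_bins_of[r]
    t <- press_split[[frame_key[r]]]
    ind <- integer(nb)
    if (!is.null(t) && length(t)) {
      idx <- pmin(floor(t / bin_width), nb - 1L)  # clamp press at exact end
      ind[idx + 1L] <- 1L
    }
    ind
  })

  tibble::tibble(
    subject_id = frame$subject_id,
    video_id = frame$video_id,
    condition = frame$condition,
    k = vapply(indicator, sum, numeric(1)),
    n_bins = as.integer(n_bins_of),
    indicator = indicator
  )
}

#' Compute per-bin segmentation norms
#'
#' For each video, the norm profile is the proportion of participants who
#' marked each one-second bin. By default every participant who segmented
#' the video contributes, across both narrative conditions (each video is
#' seen once per participant).
#'
#' @param binned Output of [bin_presses()].
#' @return Tibble `video_id`, `bin_index` (0-based), `proportion`, `n_ref`.
#' @export
compute_norms <- function(binned) {
  assert_columns(binned, c("video_id", "indicator"), "`binned`")
  purrr::map_dfr(split(binned, binned$video_id), function(b) {
    lens <- lengths(b$indicator)
    if (length(unique(lens)) != 1L) {
      abort(sprintf("Indicator length mismatch for video %s.", b$video_id[1]),
            class = "eventmem_input_error")
    }
    if (nrow(b) < 2L) {
      abort(sprintf("Video %s has fewer than 2 participants.", b$video_id[1]),
            class = "eventmem_input_error")
    }
    mat <- do.call(rbind, b$indicator)
    tibble::tibble(
      video_id = b$video_id[1],
      bin_index = seq_len(ncol(mat)) - 1L,
      proportion = colMeans(mat),
      n_ref = nrow(mat)
    )
  })
}

# Pearson correlation between a k-ones binary vector with marked-norm sum S
# and the norm vector y; depends on the marked bins only through S.
binary_norm_cor <- function(S, k, y) {
  n <- length(y)
  ssy <- sum((y - mean(y))^2)
  ssx <- k * (1 - k / n)
  if (ssx <= 0 || ssy <= .Machine$double.eps^0.5) return(NA_real_)
  (S - k * mean(y)) / sqrt(ssx * ssy)
}

#' Score segmentation agreement against the sample norms
#'
#' Correlates each participant's binned indicator with the norm profile
#' (Pearson), then rescales the correlation to `[0, 1]` against the best
#' and worst correlations achievable with the same number of marked bins
#' `k`: `scaled = (r - r_min) / (r_max - r_min)`, where `r_max` places the
#' k marks in the k highest-norm bins and `r_min` in the k lowest-norm bins
#' (ties broken by lowest bin index). This controls for individual
#' differences in how many boundaries a participant marks. Degenerate cases
#' — `k = 0`, `k = n_bins`, or a constant norm profile — get a missing
#' scaled score and are counted in a warning.
#'
#' @param binned Output of [bin_presses()].
#' @param norms Output of [compute_norms()]; must cover every video in
#'   `binned`.
#' @param leave_one_out If `TRUE`, each participant is scored against norms
#'   recomputed without that participant.
#' @return Tibble `subject_id`, `video_id`, `condition`, `k`, `raw_r`,
#'   `scaled`.
#' @export
#' @examples
#' log <- tibble::tibble(
#'   subject_id = rep(c("a", "b", "c"), times = c(2, 1, 1)),
#'   video_id = "v", condition = "POSITIVE",
#'   press_time_s = c(0.5, 3.5, 0.2, 3.1))
#' b <- bin_presses(log, c(v = 5))
#' score_agreement(b, compute_norms(b))
score_agreement <- function(binned, norms, leave_one_out = FALSE) {
  assert_columns(norms, c("video_id", "bin_index", "proportion", "n_ref"), "`norms`")
  norm_split <- split(norms, norms$video_id)
  missing_videos <- setdiff(unique(binned$video_id), names(norm_split))
  if (length(missing_videos)) {
    abort(sprintf("No norms for video(s): %s",
                  paste(missing_videos, collapse = ", ")),
          class = "eventmem_input_error")
  }

  res <- purrr::map_dfr(split(binned, binned$video_id), function(b) {
    nv <- norm_split[[b$video_id[1]]]
    nv <- nv[order(nv$bin_index), ]
    y_all <- nv$proportion
    n_ref <- nv$n_ref[1]
    if (length(y_all) != length(b$indicator[[1]])) {
      abort(sprintf("Norm length does not match indicators for video %s.",
                    b$video_id[1]),
            class = "eventmem_input_error")
    }
    one <- function(r) {
      x <- b$indicator[[r]]
      y <- y_all
      if (leave_one_out) {
        y <- (y * n_ref - x) / (n_ref - 1L)
      }
      k <- sum(x)
      n <- length(x)
      S_obs <- sum(y[x == 1L])
      raw_r <- binary_norm_cor(S_obs, k, y)
      scaled <- NA_real_
      if (!is.na(raw_r) && k > 0 && k < n) {
        ord_hi <- order(-y, seq_along(y))
        ord_lo <- order(y, seq_along(y))
        r_max <- binary_norm_cor(sum(y[ord_hi[seq_len(k)]]), k, y)
        r_min <- binary_norm_cor(sum(y[ord_lo[seq_len(k)]]), k, y)
        if (!is.na(r_max) && !is.na(r_min) &&
            (r_max - r_min) > .Machine$double.eps^0.5) {
          scaled <- clamp((raw_r - r_min) / (r_max - r_min), 0, 1)
        }
      }
      c(raw_r = raw_r, scaled = scaled)
    }
    sc <- vapply(seq_len(nrow(b)), one, c(raw_r = 0, scaled = 0))
    tibble::tibble(
      subject_id = b$subject_id,
      video_id = b$video_id,
      condition = b$condition,
      k = b$k,
      raw_r = unname(sc["raw_r", ]),
      scaled = unname(sc["scaled", ])
    )
  })
  res <- res[order(match(paste(res$subject_id, res$video_id),
                         paste(binned$subject_id, binned$video_id))), ]
  n_degen <- sum(is.na(res$scaled))
  if (n_degen > 0) {
    warn(sprintf(
      "%d subject-video(s) received a missing scaled agreement (degenerate k or constant norms).",
      n_degen))
  }
  tibble::as_tibble(res)
}

#' Full segmentation-agreement chain on a press log
#'
#' Convenience wrapper: bins presses, computes norms, scores agreement.
#'
#' @inheritParams bin_presses
#' @inheritParams score_agreement
#' @return List with `binned`, `norms`, `agreement`.
#' @export
segmentation_agreement <- function(press_log, durations, bin_width = 1,
                                   conditions = NULL, leave_one_out = FALSE) {
  binned <- bin_presses(press_log, durations, bin_width, conditions = conditions)
  norms <- compute_norms(binned)
  list(binned = binned, norms = norms,
       agreement = score_agreement(binned, norms, leave_one_out = leave_one_out))
}
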