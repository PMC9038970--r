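#' Generate the subject table of a synthetic cohort
#'
#' Draws PCL symptom-checklist totals from group-specific censored normals:
#' a normal draw rounded to an integer and clipped to the instrument's
#' 17-85 range, which puts a realistic point mass at the floor for
#' low-symptom controls (a purely truncated normal cannot reach the
#' published control moments, whose SD exceeds the mean-to-floor gap).
#' Also assigns a latent segmentation-fidelity score `ability` in (0,1)
#' that decreases with symptom severity and with a PTSD diagnosis. Session
#' order (which narrative comes first) is counterbalanced deterministically
#' by alternating assignment within each group.
#'
#' @param config A [cohort_config()].
#' @return Tibble with one row per subject: `subject_id`, `group`
#'   (`"PTSD"`/`"CONTROL"`), `pcl_total`, `ability`, `session_order`
#'   (`"trauma_first"`/`"positive_first"`).
#' @export
#' @examples
#' subj <- generate_subjects(cohort_config(n_ptsd = 5, n_control = 5, seed = 1))
#' subj
generate_subjects <- function(config) {
  config <- validate_config(config)
  n <- config$n_ptsd + config$n_control
  group <- c(rep("PTSD", config$n_ptsd), rep("CONTROL", config$n_control))
  seeds <- make_seed_stream(config$seed, n + 1L)

  pcl_par <- config$pcl
  ab <- config$ability
  pcl_total <- integer(n)
  ability <- numeric(n)
  for (i in seq_len(n)) {
    g <- if (group[i] == "PTSD") pcl_par$ptsd else pcl_par$control
    vals <- with_seed(seeds[i], {
      p <- round(rnorm(1, g$mean, g$sd))  # censored below at the item floor
      u <- rnorm(1, 0, ab$re_sd)
      c(p, u)
    })
    pcl_total[i] <- clamp(vals[1], pcl_par$min, pcl_par$max)
    z <- (pcl_total[i] - pcl_par$center) / pcl_par$scale
    eta <- ab$intercept + ab$pcl_slope * pcl_par$scale * z +
      ab$group_offset * (group[i] == "PTSD") + vals[2]
    ability[i] <- plogis(eta)
  }
  # alternate within group so both orders are near-balanced in each group
  order_within <- stats::ave(seq_len(n), group, FUN = seq_along)
  session_order <- ifelse(order_within %% 2L == 1L, "trauma_first", "positive_first")

  tibble::tibble(
    subject_id = sprintf("S%03d", seq_len(n)),
    group = group,
    pcl_total = as.integer(pcl_total),
    ability = ability,
    session_order = session_order
  )
}

#' Generate the latent boundary structure of one video
#'
#' Places event boundaries by a renewal process with exponential gaps
#' (mean `press$boundary_gap_mean` seconds) and draws a per-boundary
#' salience in (0,1] from a Beta distribution. These latent boundaries are
#' what the sample norms estimate; they are never observed directly.
#'
#' @param video_id Label for the video.
#' @param duration_s Positive duration in seconds.
#' @param config A [cohort_config()].
#' @param seed Integer seed for this video's sub-stream.
#' @return A list of class `video_truth`: `video_id`, `duration_s`,
#'   `boundary_times` (strictly increasing, in `[0, duration_s)`), and
#'   `salience` (same length). The boundary list may be empty when the mean
#'   gap is large relative to the duration; this is reported via a message.
#' @export
generate_video_truth <- function(video_id, duration_s, config, seed) {
  config <- validate_config(config)
  if (duration_s <= 0) {
    abort("`duration_s` must be positive.", class = "eventmem_config_error")
  }
  pp <- config$press
  times <- with_seed(seed, {
    # exponential renewal; draw enough gaps to cover the duration
    n_max <- max(10L, ceiling(4 * duration_s / pp$boundary_gap_mean))
    gaps <- rexp(n_max, rate = 1 / pp$boundary_gap_mean)
    t <- cumsum(gaps)
    while (sum(gaps) < duration_s) {
      gaps <- c(gaps, rexp(n_max, rate = 1 / pp$boundary_gap_mean))
      t <- cumsum(gaps)
    }
    t[t < duration_s]
  })
  sal <- with_seed(seed + 1, {
    s <- rbeta(length(times), pp$salience_shape1, pp$salience_shape2)
    pmax(s, .Machine$double.eps)  # salience strictly positive
  })
  if (length(times) == 0L) {
    inform(sprintf("Video %s: no latent boundaries (gap mean %.1f s >= duration %s s).",
                   video_id, pp$boundary_gap_mean, duration_s))
  }
  structure(
    list(video_id = video_id, duration_s = duration_s,
         boundary_times = times, salience = sal),
    class = "video_truth"
  )
}

#' Generate one subject's press log for one video
#'
#' Realises the button-press model: each latent boundary is marked with
#' probability `clamp01(base_hit + hit_slope * ability)^(1/salience)` —
#' increasing in both subject ability and boundary salience — and the
#' emitted press time is the boundary time plus Gaussian jitter truncated
#' to the video. False alarms arrive as a homogeneous Poisson process with
#' rate `fa_rate * (1 - ability)` per second. In the noiseless limit
#' (ability 1, zero jitter, zero false-alarm rate) presses sit exactly on
#' the boundary times.
#'
#' @param subject One row of the subject table (list or one-row data frame).
#' @param truth A `video_truth` from [generate_video_truth()].
#' @param condition `"TRAUMATIC"` or `"POSITIVE"`.
#' @param config A [cohort_config()].
#' @param seed Integer seed for this subject-video sub-stream.
#' @return Tibble with `subject_id`, `video_id`, `condition`,
#'   `press_time_s`, sorted by press time; zero rows when no press occurred.
#' @export
generate_press_log <- function(subject, truth, condition, config, seed) {
  pp <- config$press
  ability <- subject$ability
  cond_shift <- pp$condition_effect * (condition == "TRAUMATIC")
  q <- clamp(pp$base_hit + pp$hit_slope * ability + cond_shift, 0, 1)
  times <- with_seed(seed, {
    hit_p <- if (length(truth$boundary_times)) q^(1 / truth$salience) else numeric(0)
    hits <- truth$boundary_times[runif(length(hit_p)) < hit_p]
    if (length(hits) && pp$jitter_sd > 0) {
      hits <- clamp(hits + rnorm(length(hits), 0, pp$jitter_sd), 0, truth$duration_s)
    }
    n_fa <- rpois(1, pp$fa_rate * (1 - ability) * truth$duration_s)
    fa <- runif(n_fa, 0, truth$duration_s)
    sort(c(hits, fa))
  })
  tibble::tibble(
    subject_id = rep(subject$subject_id, length(times)),
    video_id = rep(truth$video_id, length(times)),
    condition = rep(condition, length(times)),
    press_time_s = times
  )
}

#' Generate recall records given segmentation agreement
#'
#' Encodes the mediation structure of the design: each of `n_units` A1
#' action units is recalled independently with probability
#' `plogis(intercept + agreement_slope * scaled_agreement +
#' group_effect * 1[PTSD] + severity_effect * (pcl - center) +
#' condition_effect * 1[TRAUMATIC] + noise)`, where `noise` is a
#' subject-level logit offset shared across videos. Group and symptom
#' severity affect recall only through these explicit direct terms;
#' everything else flows through agreement, so switching
#' `agreement_slope` off zeroes the true indirect effect.
#'
#' @param subjects Subject table from [generate_subjects()].
#' @param agreement Agreement table from [score_agreement()] with columns
#'   `subject_id`, `video_id`, `condition`, `scaled`. Missing (degenerate)
#'   scaled scores fall back to the subject's mean scaled agreement, or 0.5
#'   if the subject has none.
#' @param config A [cohort_config()].
#' @return Tibble: `subject_id`, `video_id`, `condition`, `n_units_total`,
#'   `n_recalled`.
#' @export
generate_recall <- function(subjects, agreement, config) {
  config <- validate_config(config)
  rc <- config$recall
  if (rc$n_units <= 0) {
    abort("`recall$n_units` must be positive.", class = "eventmem_config_error")
  }
  assert_columns(agreement, c("subject_id", "video_id", "condition", "scaled"),
                 "`agreement`")
  n <- nrow(subjects)
  seeds <- make_seed_stream(config$seed + 11L, n + nrow(agreement))

  subj_noise <- vapply(seq_len(n), function(i) {
    with_seed(seeds[i], rnorm(1, 0, rc$noise_sd))
  }, numeric(1))
  names(subj_noise) <- subjects$subject_id

  ag <- dplyr::left_join(
    agreement,
    dplyr::select(subjects, "subject_id", "group", "pcl_total"),
    by = "subject_id"
  )
  subj_mean <- tapply(ag$scaled, ag$subject_id, mean, na.rm = TRUE)
  m <- ag$scaled
  fallback <- subj_mean[ag$subject_id]
  m[is.na(m)] <- fallback[is.na(m)]
  m[is.na(m)] <- 0.5

  eta <- rc$intercept + rc$agreement_slope * m +
    rc$group_effect * (ag$group == "PTSD") +
    (rc$severity_effect %||% 0) * (ag$pcl_total - config$pcl$center) +
    rc$condition_effect * (ag$condition == "TRAUMATIC") +
    subj_noise[ag$subject_id]
  p <- plogis(eta)
  n_rec <- vapply(seq_len(nrow(ag)), function(r) {
    with_seed(seeds[n + r], rbinom(1, rc$n_units, p[r]))
  }, integer(1))

  tibble::tibble(
    subject_id = ag$subject_id,
    video_id = ag$video_id,
    condition = ag$condition,
    n_units_total = as.integer(rc$n_units),
    n_recalled = n_rec
  )
}

#' Generate trial-level anxiety ratings
#'
#' Ratings on the 1-10 scale follow
#' `mu + group * 1[PTSD] + condition * 1[TRAUMATIC] + interaction *
#' 1[PTSD & TRAUMATIC] + subject intercept + trial effect + residual`,
#' clipped to the scale bounds. Each subject contributes `n_trials` ratings
#' per narrative condition.
#'
#' @param subjects Subject table from [generate_subjects()].
#' @param config A [cohort_config()].
#' @return Tibble: `subject_id`, `group`, `condition`, `trial_index`,
#'   `rating`.
#' @export
generate_anxiety <- function(subjects, config) {
  config <- validate_config(config)
  ax <- config$anxiety
  n <- nrow(subjects)
  seeds <- make_seed_stream(config$seed + 23L, n + ax$n_trials + 1L)

  trial_eff <- with_seed(seeds[n + 1L], rnorm(ax$n_trials, 0, ax$trial_sd))

  rows <- purrr::map(seq_len(n), function(i) {
    s <- subjects[i, ]
    draws <- with_seed(seeds[i], {
      list(u = rnorm(1, 0, ax$subject_sd),
           eps = rnorm(2 * ax$n_trials, 0, ax$residual_sd))
    })
    grid <- tidyr::expand_grid(
      condition = c("TRAUMATIC", "POSITIVE"),
      trial_index = seq_len(ax$n_trials)
    )
    is_ptsd <- s$group == "PTSD"
    is_trauma <- grid$condition == "TRAUMATIC"
    latent <- ax$mu + ax$group * is_ptsd + ax$condition * is_trauma +
      ax$interaction * (is_ptsd & is_trauma) +
      draws$u + trial_eff[grid$trial_index] + draws$eps
    tibble::tibble(
      subject_id = s$subject_id,
      group = s$group,
      condition = grid$condition,
      trial_index = grid$trial_index,
      rating = clamp(latent, ax$scale_min, ax$scale_max)
    )
  })
  dplyr::bind_rows(rows)
}

#' Generate a complete synthetic cohort
#'
#' Runs the full generative chain: subjects, latent video boundary
#' structure, press logs, binned segmentation and agreement scores (via the
#' segmentation module), recall records conditional on agreement, and
#' trial-level anxiety ratings. The returned `truth` element records every
#' generating parameter and latent quantity needed for parameter-recovery
#' checks.
#'
#' @param config A [cohort_config()].
#' @return A list of class `cohort` with elements `subjects`, `press_log`,
#'   `binned`, `norms`, `agreement`, `recall`, `anxiety`, `truth`, `config`.
#' @export
#' @examples
#' coh <- generate_cohort(cohort_config(n_ptsd = 4, n_control = 4, seed = 7))
#' names(coh)
#' head(coh$agreement)
generate_cohort <- function(config = cohort_config()) {
  config <- validate_config(config)
  subjects <- generate_subjects(config)
  videos <- config$videos
  vseeds <- make_seed_stream(config$seed + 5L, 2L * nrow(videos))
  truth_list <- purrr::map(seq_len(nrow(videos)), function(v) {
    generate_video_truth(videos$video_id[v], videos$duration_s[v],
                         config, vseeds[2L * v - 1L])
  })
  names(truth_list) <- videos$video_id

  # condition of each video for a subject follows the session split and the
  # subject's counterbalanced narrative order
  cond_for <- function(session_order, session) {
    first <- if (session_order == "trauma_first") "TRAUMATIC" else "POSITIVE"
    second <- setdiff(c("TRAUMATIC", "POSITIVE"), first)
    ifelse(session == 1L, first, second)
  }

  pseeds <- make_seed_stream(config$seed + 7L, nrow(subjects) * nrow(videos))
  k <- 0L
  press_rows <- vector("list", nrow(subjects) * nrow(videos))
  for (i in seq_len(nrow(subjects))) {
    s <- subjects[i, ]
    conds <- cond_for(s$session_order, videos$session)
    for (v in seq_len(nrow(videos))) {
      k <- k + 1L
      press_rows[[k]] <- generate_press_log(s, truth_list[[v]], conds[v],
                                            config, pseeds[k])
    }
  }
  press_log <- dplyr::bind_rows(press_rows)

  durations <- setNames(videos$duration_s, videos$video_id)
  binned <- bin_presses(press_log, durations,
                        subjects = subjects$subject_id,
                        conditions = condition_map(subjects, videos))
  norms <- compute_norms(binned)
  agreement <- score_agreement(binned, norms)
  recall <- generate_recall(subjects, agreement, config)
  anxiety <- generate_anxiety(subjects, config)

  structure(
    list(
      subjects = subjects,
      press_log = press_log,
      binned = binned,
      norms = norms,
      agreement = agreement,
      recall = recall,
      anxiety = anxiety,
      truth = list(videos = truth_list, config = config),
      config = config
    ),
    class = "cohort"
  )
}

# Long table of (subject_id, video_id, condition) for every pairing,
# including subject-videos with zero presses.
condition_map <- function(subjects, videos) {
  tidyr::expand_grid(subject_id = subjects$subject_id,
                     video_id = videos$video_id) |>
    dplyr::left_join(dplyr::select(subjects, "subject_id", "session_order"),
                     by = "subject_id") |>
    dplyr::left_join(dplyr::select(videos, "video_id", "session"),
                     by = "video_id") |>
    dplyr::mutate(
      condition = dplyr::case_when(
        (.data$session_order == "trauma_first") == (.data$session == 1L) ~ "TRAUMATIC",
        TRUE ~ "POSITIVE"
      )
    ) |>
    dplyr::select("subject_id", "video_id", "condition")
}

#' @export
print.cohort <- function(x, ...) {
  cat("Synthetic cohort:", nrow(x$subjects), "subjects (",
      sum(x$subjects$group == "PTSD"), "PTSD /",
      sum(x$subjects$group == "CONTROL"), "control ),",
      nrow(x$config$videos), "videos\n")
  cat("  presses:", nrow(x$press_log),
      "| mean presses per subject-video:",
      round(nrow(x$press_log) / nrow(x$agreement), 2), "\n")
  cat("  mean scaled agreement:",
      round(mean(x$agreement$scaled, na.rm = TRUE), 3),
      "| mean recall proportion:",
      round(mean(x$recall$n_recalled / x$recall$n_units_total), 3), "\n")
  invisible(x)
}
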