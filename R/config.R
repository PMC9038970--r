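#' Configuration for the synthetic cohort generator
#'
#' Builds the full parameter list that drives [generate_cohort()]. The
#' defaults encode the study conditions of the motivating design: 63 PTSD
#' and 64 control participants, six everyday-activity videos with the
#' standard durations, PCL symptom-checklist distributions per group, and
#' press/recall/anxiety model coefficients solved numerically (one-time
#' calibration, see the methods vignette) so that large-sample expectations
#' of the generated cohorts reproduce the published sample descriptives:
#' group mean scaled agreement near 0.63/0.59, group mean recall proportion
#' near 0.23/0.20, an indirect (through-agreement) share of the group
#' effect on recall near 45%, and roughly 28.7 presses per subject-video.
#'
#' @param n_ptsd,n_control Number of subjects per group.
#' @param seed Root seed; all generator randomness derives from it through
#'   per-record sub-streams, so subsets of a cohort are reproducible.
#' @param videos Data frame with columns `video_id`, `duration_s` (seconds)
#'   and `session` (1 or 2); videos in session 1 are seen after the first
#'   narrative, session 2 after the second, with session order
#'   counterbalanced across subjects (alternating assignment).
#' @param pcl List: per-group latent `mean` and `sd` of the normal draw
#'   behind the 17-item PCL total (rounded and clipped to the `min`/`max`
#'   instrument bounds, 17 and 85), plus fixed standardisation constants
#'   `center`/`scale` used inside the ability model. The latent defaults
#'   are solved so the clipped sample moments reproduce the published
#'   group means and SDs, 54.60 (13.66) and 20.81 (6.21).
#' @param ability List defining latent segmentation fidelity
#'   `plogis(intercept + pcl_slope * (pcl - center) + group_offset * 1[PTSD]
#'   + u)`, `u ~ N(0, re_sd^2)` (`pcl_slope` is per PCL point). `pcl_slope`
#'   and `group_offset` are negative by default: higher severity and a PTSD
#'   diagnosis both lower fidelity; the diagnosis term carries the part of
#'   the group difference not explained by the checklist total.
#' @param press List: `boundary_gap_mean` (mean seconds between latent
#'   boundaries of the renewal process), `salience_shape1`/`salience_shape2`
#'   (Beta parameters for per-boundary salience in (0,1]), `base_hit` and
#'   `hit_slope` (boundary-hit probability is
#'   `clamp01(base_hit + hit_slope * ability) ^ (1/salience)`, increasing in
#'   both ability and salience), `jitter_sd` (Gaussian jitter of press times
#'   around the boundary, seconds), `fa_rate` (false-alarm Poisson rate per
#'   second at ability 0; the realised rate is `fa_rate * (1 - ability)`),
#'   and `condition_effect` (additive shift of the hit probability after the
#'   traumatic narrative; 0 by default).
#' @param recall List: `n_units` (A1 action units per video), logistic
#'   coefficients `intercept`, `agreement_slope`, `group_effect`,
#'   `severity_effect` (per PCL point above `pcl$center`; the part of the
#'   direct memory deficit tied to symptom load rather than diagnosis),
#'   `condition_effect`, and `noise_sd` (subject-level logit noise shared
#'   across that subject's videos).
#' @param anxiety List: latent mean `mu` and effects `group`, `condition`,
#'   `interaction` on the 1-10 rating scale, `subject_sd`, `trial_sd`,
#'   `residual_sd`, `n_trials` per session, and the clipping bounds
#'   `scale_min`/`scale_max`.
#'
#' @return A list of class `cohort_config`.
#' @seealso [generate_cohort()]
#' @export
#' @examples
#' cfg <- cohort_config(n_ptsd = 8, n_control = 8, seed = 42)
#' cfg$pcl$ptsd
cohort_config <- function(n_ptsd = 63,
                          n_control = 64,
                          seed = 1L,
                          videos = default_videos(),
                          pcl = list(),
                          ability = list(),
                          press = list(),
                          recall = list(),
                          anxiety = list()) {
  cfg <- list(
    n_ptsd = n_ptsd,
    n_control = n_control,
    seed = seed,
    videos = tibble::as_tibble(videos),
    pcl = utils::modifyList(list(
      ptsd = list(mean = 54.6563, sd = 13.8776),
      control = list(mean = 15.1619, sd = 11.7136),
      min = 17, max = 85,
      center = 37.7, scale = 20
    ), pcl),
    ability = utils::modifyList(list(
      intercept = 2.0655,
      pcl_slope = -0.00183,
      group_offset = -0.5415,
      re_sd = 1.05
    ), ability),
    press = utils::modifyList(list(
      boundary_gap_mean = 11,
      salience_shape1 = 5,
      salience_shape2 = 2,
      base_hit = 0,
      hit_slope = 1,
      jitter_sd = 1.5,
      fa_rate = 0.1196,
      condition_effect = 0
    ), press),
    recall = utils::modifyList(list(
      n_units = 40,
      intercept = -2.4944,
      agreement_slope = 2.0574,
      group_effect = -0.0973,
      severity_effect = -0.00018,
      condition_effect = -0.07,
      noise_sd = 0.2470
    ), recall),
    anxiety = utils::modifyList(list(
      mu = 1.3837,
      group = 1.2842,
      condition = 1.0467,
      interaction = 0.8203,
      subject_sd = 0.80,
      trial_sd = 0.10,
      residual_sd = 0.70,
      n_trials = 11,
      scale_min = 1, scale_max = 10
    ), anxiety)
  )
  class(cfg) <- "cohort_config"
  validate_config(cfg)
}

#' Default video set
#'
#' Six everyday-activity videos with the standard durations in seconds,
#' split three per narrative session.
#'
#' @return Tibble with `video_id`, `duration_s`, `session`.
#' @export
default_videos <- function() {
  tibble::tibble(
    video_id = c("breakfast", "party", "plants", "library", "sweeping", "dishes"),
    duration_s = c(329L, 376L, 354L, 249L, 263L, 327L),
    session = c(1L, 1L, 1L, 2L, 2L, 2L)
  )
}

validate_config <- function(cfg) {
  fail <- function(msg) abort(msg, class = "eventmem_config_error")
  if (!is.numeric(cfg$n_ptsd) || !is.numeric(cfg$n_control) ||
      cfg$n_ptsd < 1 || cfg$n_control < 1) {
    fail("`n_ptsd` and `n_control` must both be positive integers.")
  }
  v <- cfg$videos
  assert_columns(v, c("video_id", "duration_s", "session"), "`videos`")
  if (any(v$duration_s <= 0)) fail("Video durations must be positive.")
  if (anyDuplicated(v$video_id)) fail("Video ids must be unique.")
  with(cfg$pcl, {
    if (min >= max) fail("PCL truncation bounds are inverted.")
    if (ptsd$sd < 0 || control$sd < 0) fail("PCL sds must be nonnegative.")
    if (scale <= 0) fail("PCL standardisation scale must be positive.")
  })
  if (cfg$ability$re_sd < 0) fail("Ability random-effect sd must be nonnegative.")
  with(cfg$press, {
    if (boundary_gap_mean <= 0) fail("Boundary gap mean must be positive.")
    if (salience_shape1 <= 0 || salience_shape2 <= 0)
      fail("Salience Beta shapes must be positive.")
    if (jitter_sd < 0 || fa_rate < 0)
      fail("Press jitter sd and false-alarm rate must be nonnegative.")
  })
  if (cfg$recall$n_units < 1) fail("`recall$n_units` must be a positive integer.")
  if (cfg$recall$noise_sd < 0) fail("Recall noise sd must be nonnegative.")
  with(cfg$anxiety, {
    if (subject_sd < 0 || trial_sd < 0 || residual_sd < 0)
      fail("Anxiety sds must be nonnegative.")
    if (n_trials < 1) fail("`anxiety$n_trials` must be positive.")
    if (scale_min >= scale_max) fail("Anxiety scale bounds are inverted.")
  })
  cfg
}

#' Read a generator configuration from a YAML or JSON file
#'
#' The file may override any subset of [cohort_config()] fields; unspecified
#' fields keep their calibrated defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `cohort_config` list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Config file not found: %s", path),
          class = "eventmem_config_error")
  }
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  args <- raw[intersect(names(raw), names(formals(cohort_config)))]
  do.call(cohort_config, args)
}
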