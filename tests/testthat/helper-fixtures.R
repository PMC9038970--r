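# Shared fixture builders; everything is generated in code at test time.

tiny_videos <- function() {
  tibble::tibble(video_id = c("v1", "v2"),
                 duration_s = c(40L, 30L),
                 session = c(1L, 2L))
}

tiny_config <- function(seed = 1, ...) {
  cohort_config(n_ptsd = 4, n_control = 4, seed = seed,
                videos = tiny_videos(), ...)
}

tiny_cohort <- function(seed = 1, ...) {
  suppressWarnings(generate_cohort(tiny_config(seed = seed, ...)))
}

press_tbl <- function(times, subject = "S1", video = "v", cond = "POSITIVE") {
  tibble::tibble(subject_id = subject, video_id = video,
                 condition = cond, press_time_s = times)
}

norms_tbl <- function(props, video = "v") {
  tibble::tibble(video_id = video, bin_index = seq_along(props) - 1L,
                 proportion = props, n_ref = 10L)
}

binned_row <- function(indicator, subject = "S1", video = "v",
                       cond = "POSITIVE") {
  tibble::tibble(subject_id = subject, video_id = video, condition = cond,
                 k = sum(indicator), n_bins = length(indicator),
                 indicator = list(as.integer(indicator)))
}

# linear-Gaussian mediation cohort with known paths a, b, cprime
linear_mediation_data <- function(n, a, b, cprime, seed,
                                  sd_m = 0.5, sd_y = 0.5) {
  withr::with_seed(seed, {
    x <- rnorm(n)
    m <- a * x + rnorm(n, 0, sd_m)
    y <- cprime * x + b * m + rnorm(n, 0, sd_y)
    tibble::tibble(subject_id = sprintf("S%04d", seq_len(n)),
                   group = "CONTROL", pcl_total = x,
                   mean_agreement = m, mean_recall = y)
  })
}

# default-calibration cohorts shared across acceptance blocks (built once)
.acceptance_env <- new.env(parent = emptyenv())
acceptance_cohorts <- function(n_seeds = 16) {
  key <- paste0("coh", n_seeds)
  if (is.null(.acceptance_env[[key]])) {
    .acceptance_env[[key]] <- lapply(seq_len(n_seeds), function(s) {
      suppressWarnings(generate_cohort(cohort_config(seed = 1000 + s)))
    })
  }
  .acceptance_env[[key]]
}
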