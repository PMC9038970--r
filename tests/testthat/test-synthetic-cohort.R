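test_that("generation is deterministic under a fixed seed", {
  a <- tiny_cohort(seed = 99)
  b <- tiny_cohort(seed = 99)
  expect_identical(a$subjects, b$subjects)
  expect_identical(a$press_log, b$press_log)
  expect_identical(a$recall, b$recall)
  expect_identical(a$anxiety, b$anxiety)
  expect_identical(a$agreement, b$agreement)
  c <- tiny_cohort(seed = 100)
  expect_false(identical(a$press_log, c$press_log))
})

test_that("PCL totals respect instrument bounds and degenerate variance collapses groups", {
  subj <- generate_subjects(tiny_config(seed = 2))
  expect_true(all(subj$pcl_total >= 17 & subj$pcl_total <= 85))
  expect_true(all(subj$pcl_total == round(subj$pcl_total)))
  expect_true(all(subj$ability > 0 & subj$ability < 1))
  expect_equal(sum(subj$group == "PTSD"), 4)
  expect_equal(sum(subj$group == "CONTROL"), 4)
  # alternating counterbalancing within group
  expect_equal(subj$session_order[subj$group == "PTSD"],
               rep(c("trauma_first", "positive_first"), 2))

  degen <- generate_subjects(tiny_config(
    seed = 3,
    pcl = list(ptsd = list(mean = 60, sd = 0), control = list(mean = 20, sd = 0))))
  expect_equal(unique(degen$pcl_total[degen$group == "PTSD"]), 60)
  expect_equal(unique(degen$pcl_total[degen$group == "CONTROL"]), 20)
})

test_that("latent boundaries follow the renewal expectation and salience stays in (0, 1]", {
  cfg <- cohort_config()
  counts <- vapply(1:30, function(s) {
    length(generate_video_truth("v", 329, cfg, seed = s)$boundary_times)
  }, numeric(1))
  expect_equal(mean(counts), 329 / cfg$press$boundary_gap_mean, tolerance = 0.12)

  tr <- generate_video_truth("v", 329, cfg, seed = 5)
  expect_identical(tr$boundary_times,
                   generate_video_truth("v", 329, cfg, seed = 5)$boundary_times)
  expect_true(all(diff(tr$boundary_times) > 0))
  expect_equal(length(tr$salience), length(tr$boundary_times))

  # brute-force draw check on ~1e4 salience values
  big <- generate_video_truth("long", 5000, cohort_config(
    press = list(boundary_gap_mean = 0.5)), seed = 8)
  expect_gt(length(big$salience), 9000)
  expect_true(all(big$salience > 0 & big$salience <= 1))
})

test_that("press model has the documented noiseless and ability-zero limits", {
  cfg <- cohort_config(press = list(jitter_sd = 0, fa_rate = 0))
  truth <- generate_video_truth("v", 300, cfg, seed = 4)
  perfect <- list(subject_id = "S1", ability = 1)
  log1 <- generate_press_log(perfect, truth, "POSITIVE", cfg, seed = 21)
  expect_equal(log1$press_time_s, truth$boundary_times)

  # ability 0: false alarms only, Poisson mean fa_rate * duration
  cfg2 <- cohort_config(press = list(fa_rate = 0.1))
  none <- list(subject_id = "S1", ability = 0)
  counts <- vapply(1:30, function(s) {
    nrow(generate_press_log(none, truth, "POSITIVE", cfg2, seed = s))
  }, numeric(1))
  expect_equal(mean(counts), 0.1 * 300, tolerance = 0.12)

  # higher ability -> binned overlap with truth bins is higher (same seed)
  cfg3 <- cohort_config(press = list(jitter_sd = 0, fa_rate = 0))
  hi <- generate_press_log(list(subject_id = "H", ability = 0.9), truth,
                           "POSITIVE", cfg3, seed = 77)
  lo <- generate_press_log(list(subject_id = "L", ability = 0.1), truth,
                           "POSITIVE", cfg3, seed = 77)
  truth_bins <- unique(floor(truth$boundary_times))
  overlap <- function(log) length(intersect(unique(floor(log$press_time_s)), truth_bins))
  expect_gt(overlap(hi), overlap(lo))
})

test_that("expected scaled agreement is nondecreasing in ability", {
  cfg <- cohort_config()
  truth_videos <- cfg$videos[1, ]
  abilities <- c(0.25, 0.55, 0.85)
  subjects <- tibble::tibble(
    subject_id = sprintf("S%03d", seq_len(50 * length(abilities))),
    ability = rep(abilities, each = 50))
  truth <- generate_video_truth("breakfast", 329, cfg, seed = 1)
  logs <- dplyr::bind_rows(lapply(seq_len(nrow(subjects)), function(i) {
    generate_press_log(subjects[i, ], truth, "POSITIVE", cfg, seed = 300 + i)
  }))
  frame <- tibble::tibble(subject_id = subjects$subject_id,
                          video_id = "breakfast", condition = "POSITIVE")
  seg <- suppressWarnings(
    segmentation_agreement(logs, c(breakfast = 329), conditions = frame))
  means <- tapply(seg$agreement$scaled,
                  rep(abilities, each = 50), mean, na.rm = TRUE)
  expect_true(all(diff(means) > 0))
})

test_that("recall generator hits its logistic limits and mediation nulls", {
  # all coefficients zero -> expected proportion 0.5
  cfg0 <- tiny_config(seed = 6, recall = list(
    intercept = 0, agreement_slope = 0, group_effect = 0,
    severity_effect = 0, condition_effect = 0, noise_sd = 0))
  coh0 <- suppressWarnings(generate_cohort(cfg0))
  expect_lt(abs(mean(coh0$recall$n_recalled / coh0$recall$n_units_total) - 0.5), 0.06)

  # strongly negative group effect -> PTSD mean below control on every seed
  for (s in 1:20) {
    cfgG <- cohort_config(n_ptsd = 6, n_control = 6, seed = s,
                          videos = tiny_videos(),
                          recall = list(group_effect = -3))
    cohG <- suppressWarnings(generate_cohort(cfgG))
    rec <- score_recall(cohG$recall) |>
      dplyr::left_join(dplyr::select(cohG$subjects, "subject_id", "group"),
                       by = "subject_id")
    means <- tapply(rec$proportion, rec$group, mean)
    expect_lt(means[["PTSD"]], means[["CONTROL"]])
  }

  expect_error(generate_cohort(tiny_config(recall = list(n_units = 0))),
               class = "eventmem_config_error")
})

test_that("anxiety generator is exact in the noise-free limit and respects the scale", {
  cfg <- tiny_config(seed = 8, anxiety = list(
    mu = 2, group = 0, condition = 0, interaction = 0,
    subject_sd = 0, trial_sd = 0, residual_sd = 0))
  subj <- generate_subjects(cfg)
  anx <- generate_anxiety(subj, cfg)
  expect_true(all(anx$rating == 2))
  expect_equal(nrow(anx), nrow(subj) * 2 * cfg$anxiety$n_trials)

  anx2 <- generate_anxiety(subj, tiny_config(seed = 9))
  expect_true(all(anx2$rating >= 1 & anx2$rating <= 10))
  counts <- dplyr::count(anx2, .data$subject_id, .data$condition)
  expect_true(all(counts$n == 11))
})

test_that("outputs satisfy their type invariants under randomized configs", {
  withr::with_seed(2024, {
    for (i in 1:1000) {
      cfg <- cohort_config(
        n_ptsd = sample(1:3, 1), n_control = sample(1:3, 1),
        seed = sample.int(1e6, 1),
        videos = tibble::tibble(
          video_id = c("a", "b"),
          duration_s = sample(10:50, 2, replace = TRUE),
          session = c(1L, 2L)),
        pcl = list(ptsd = list(mean = runif(1, 30, 80), sd = runif(1, 0, 20)),
                   control = list(mean = runif(1, 5, 40), sd = runif(1, 0, 15))),
        ability = list(re_sd = runif(1, 0, 2)),
        press = list(boundary_gap_mean = runif(1, 2, 20),
                     jitter_sd = runif(1, 0, 3),
                     fa_rate = runif(1, 0, 0.2)),
        recall = list(n_units = sample(5:50, 1), noise_sd = runif(1, 0, 1)),
        anxiety = list(n_trials = sample(2:5, 1),
                       subject_sd = runif(1, 0, 2),
                       residual_sd = runif(1, 0, 2)))

      subj <- generate_subjects(cfg)
      expect_true(all(subj$pcl_total >= 17 & subj$pcl_total <= 85))
      expect_true(all(subj$ability > 0 & subj$ability < 1))
      expect_equal(nrow(subj), cfg$n_ptsd + cfg$n_control)

      if (i %% 4 == 0) {
        coh <- suppressWarnings(suppressMessages(generate_cohort(cfg)))
        dur <- setNames(cfg$videos$duration_s, cfg$videos$video_id)
        expect_true(all(coh$press_log$press_time_s >= 0 &
                          coh$press_log$press_time_s <= dur[coh$press_log$video_id]))
        expect_true(all(coh$recall$n_recalled >= 0 &
                          coh$recall$n_recalled <= coh$recall$n_units_total))
        expect_true(all(coh$anxiety$rating >= 1 & coh$anxiety$rating <= 10))
        sc <- coh$agreement$scaled
        expect_true(all(is.na(sc) | (sc >= 0 & sc <= 1)))
        expect_true(all(coh$norms$proportion >= 0 & coh$norms$proportion <= 1))
      }
    }
  })
})

test_that("invalid configurations are rejected before any computation", {
  expect_error(cohort_config(n_ptsd = 0), class = "eventmem_config_error")
  expect_error(cohort_config(press = list(boundary_gap_mean = -1)),
               class = "eventmem_config_error")
  expect_error(cohort_config(pcl = list(min = 90)), class = "eventmem_config_error")
  expect_error(cohort_config(anxiety = list(scale_min = 11)),
               class = "eventmem_config_error")
  expect_error(generate_video_truth("v", -5, cohort_config(), 1),
               class = "eventmem_config_error")
})
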