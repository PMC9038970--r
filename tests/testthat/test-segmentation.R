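test_that("presses are binned into half-open one-second bins with end clamping", {
  b <- bin_presses(press_tbl(c(3.2, 3.7, 10.0)), c(v = 12))
  expect_equal(b$k, 2)
  expect_equal(which(b$indicator[[1]] == 1L) - 1L, c(3L, 10L))
  expect_equal(b$n_bins, 12L)

  # a press at exactly the video end lands in the final bin
  b_end <- bin_presses(press_tbl(329), c(v = 329))
  expect_equal(which(b_end$indicator[[1]] == 1L) - 1L, 328L)

  # empty press list yields an all-zero vector only when the pairing is listed
  frame <- tibble::tibble(subject_id = "S1", video_id = "v", condition = "POSITIVE")
  b0 <- bin_presses(press_tbl(numeric(0)), c(v = 10), conditions = frame)
  expect_equal(b0$k, 0)
  expect_equal(sum(b0$indicator[[1]]), 0L)

  expect_error(bin_presses(press_tbl(12.5), c(v = 12)),
               class = "eventmem_input_error")
  expect_error(bin_presses(press_tbl(-0.1), c(v = 12)),
               class = "eventmem_input_error")
})

test_that("norms are per-bin proportions of the reference group", {
  b <- dplyr::bind_rows(
    binned_row(c(1, 0, 0, 1, 0), subject = "a"),
    binned_row(c(1, 0, 0, 0, 0), subject = "b"),
    binned_row(c(0, 0, 0, 1, 0), subject = "c"))
  n <- compute_norms(b)
  expect_equal(n$proportion, c(2 / 3, 0, 0, 2 / 3, 0))
  expect_equal(n$n_ref, rep(3L, 5))

  # all participants identical -> norms equal the shared indicator
  b2 <- dplyr::bind_rows(binned_row(c(1, 0, 1), subject = "a", video = "w"),
                         binned_row(c(1, 0, 1), subject = "b", video = "w"))
  expect_equal(compute_norms(b2)$proportion, c(1, 0, 1))

  expect_error(compute_norms(binned_row(c(1, 0))),
               class = "eventmem_input_error")  # < 2 participants
  b3 <- dplyr::bind_rows(binned_row(c(1, 0)), binned_row(c(1, 0, 1), subject = "b"))
  expect_error(compute_norms(b3), class = "eventmem_input_error")
})

test_that("agreement equals hand-computed Pearson and min-max rescaling", {
  norms <- norms_tbl(c(0.8, 0.6, 0.2, 0.1, 0.1))
  best <- score_agreement(binned_row(c(1, 1, 0, 0, 0)), norms)
  expect_equal(best$raw_r,
               cor(c(1, 1, 0, 0, 0), norms$proportion))
  expect_equal(best$raw_r, 0.967, tolerance = 1e-3)
  expect_equal(best$scaled, 1.0, tolerance = 1e-3)

  worst <- score_agreement(binned_row(c(0, 0, 0, 1, 1)), norms)
  expect_equal(worst$scaled, 0)

  # scores depend only on (indicator, norms): identical vectors, same score
  twin <- score_agreement(
    dplyr::bind_rows(binned_row(c(1, 1, 0, 0, 0), subject = "a"),
                     binned_row(c(1, 1, 0, 0, 0), subject = "b")), norms)
  expect_equal(twin$scaled[1], twin$scaled[2])
  expect_equal(twin$raw_r[1], twin$raw_r[2])
})

test_that("degenerate vectors and constant norms give missing scaled scores", {
  norms <- norms_tbl(c(0.8, 0.6, 0.2, 0.1, 0.1))
  expect_warning(out <- score_agreement(binned_row(c(0, 0, 0, 0, 0)), norms),
                 "missing scaled")
  expect_true(is.na(out$scaled))
  expect_warning(out2 <- score_agreement(binned_row(c(1, 1, 1, 1, 1)), norms))
  expect_true(is.na(out2$scaled))
  expect_warning(out3 <- score_agreement(binned_row(c(1, 0, 1, 0, 0)),
                                         norms_tbl(rep(0.4, 5))))
  expect_true(is.na(out3$scaled))
})

test_that("scaled is 1 exactly for subsets maximising Pearson correlation (exhaustive oracle)", {
  withr::with_seed(42, {
    for (case in 1:25) {
      n <- sample(5:12, 1)
      y <- runif(n)
      k <- sample(seq_len(n - 1), 1)
      marked <- sort(sample(n, k))
      x <- integer(n); x[marked] <- 1L
      out <- score_agreement(binned_row(x), norms_tbl(y))

      subsets <- utils::combn(n, k)
      rs <- apply(subsets, 2, function(idx) {
        xx <- integer(n); xx[idx] <- 1L
        suppressWarnings(cor(xx, y))
      })
      expect_equal(out$raw_r, cor(x, y), tolerance = 1e-12)
      expect_gte(out$raw_r, min(rs) - 1e-12)
      expect_lte(out$raw_r, max(rs) + 1e-12)
      expect_equal(out$scaled,
                   (cor(x, y) - min(rs)) / (max(rs) - min(rs)),
                   tolerance = 1e-10)
      is_best <- abs(cor(x, y) - max(rs)) < 1e-12
      expect_equal(out$scaled > 1 - 1e-9, is_best)
    }
  })
})

test_that("agreement is equivariant to bin permutation and invariant to duplicating the reference group", {
  withr::with_seed(7, {
    n <- 9
    y <- runif(n)
    x <- as.integer(runif(n) < 0.4); x[1] <- 1L; x[2] <- 0L
    base <- score_agreement(binned_row(x), norms_tbl(y))
    p <- sample(n)
    perm <- score_agreement(binned_row(x[p]), norms_tbl(y[p]))
    expect_equal(perm$raw_r, base$raw_r, tolerance = 1e-12)
    expect_equal(perm$scaled, base$scaled, tolerance = 1e-12)
  })

  coh <- tiny_cohort(seed = 3)
  doubled <- dplyr::bind_rows(
    coh$binned,
    dplyr::mutate(coh$binned, subject_id = paste0(.data$subject_id, "_dup")))
  norms2 <- compute_norms(doubled)
  expect_equal(norms2$proportion, coh$norms$proportion)
  resc <- suppressWarnings(score_agreement(coh$binned, norms2))
  expect_equal(resc$scaled, coh$agreement$scaled)
})

test_that("scores are bounded on random cohorts and leave-one-out changes the reference", {
  for (s in 1:4) {
    coh <- tiny_cohort(seed = 10 + s)
    ok <- !is.na(coh$agreement$scaled)
    expect_true(all(coh$agreement$scaled[ok] >= 0 & coh$agreement$scaled[ok] <= 1))
    expect_true(all(abs(coh$agreement$raw_r[ok]) <= 1 + 1e-12))
  }
  coh <- tiny_cohort(seed = 31)
  loo <- suppressWarnings(score_agreement(coh$binned, coh$norms,
                                          leave_one_out = TRUE))
  ok <- !is.na(loo$scaled) & !is.na(coh$agreement$scaled)
  expect_true(all(loo$scaled[ok] >= 0 & loo$scaled[ok] <= 1))
  expect_false(isTRUE(all.equal(loo$raw_r[ok], coh$agreement$raw_r[ok])))
})
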