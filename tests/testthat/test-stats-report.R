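test_that("stance peaks are located in the two configured windows", {
  force <- numeric(101)
  force[13] <- 100 # 12% cycle
  force[49] <- 80 # 48% cycle
  cv <- make_toy_curve(force)
  pk <- detect_stance_peaks(cv, stance_fraction = 0.6, split = 0.3)
  expect_true(pk$valid)
  expect_equal(pk$first_peak, 100)
  expect_equal(pk$first_peak_time, 0.12)
  expect_equal(pk$second_peak, 80)
  expect_equal(pk$second_peak_time, 0.48)
  expect_lt(pk$first_peak_time, pk$second_peak_time)
})

test_that("slack curves and degenerate stance shapes are handled", {
  pk0 <- detect_stance_peaks(make_toy_curve(numeric(101)))
  expect_false(pk0$valid)
  expect_true(is.na(pk0$first_peak))

  # monotone-decreasing stance force: first peak at cycle start
  force <- c(seq(100, 0, length.out = 61), numeric(40))
  pk <- detect_stance_peaks(make_toy_curve(force))
  expect_equal(pk$first_peak_time, 0)
  expect_equal(pk$first_peak, 100)

  expect_error(
    detect_stance_peaks(make_toy_curve(force), stance_fraction = 0.2, split = 0.3),
    "stance_fraction"
  )
})

test_that("correlation against the center curve matches the textbook formula", {
  x <- make_toy_curve(withr::with_seed(0, stats::runif(101, 0, 100)))
  y <- make_toy_curve(withr::with_seed(1, stats::runif(101, 0, 100)))
  res <- correlate_with_center(x, y)
  ora <- oracle_pearson(x$force, y$force)
  expect_lt(abs(res$r - ora$r), 1e-12)
  expect_lt(abs(res$p_value - ora$p), 1e-12)
  expect_equal(res$n_points, 101)

  expect_equal(correlate_with_center(x, x)$r, 1)
  neg <- make_toy_curve(-x$force + 200)
  expect_equal(correlate_with_center(x, neg)$r, -1)
})

test_that("constant or slack curves give an N/A correlation, not a number", {
  x <- make_toy_curve(withr::with_seed(2, stats::runif(101)))
  flat <- make_toy_curve(numeric(101))
  expect_true(correlate_with_center(x, flat)$na)
  expect_true(correlate_with_center(flat, x)$na)
  expect_true(is.na(correlate_with_center(flat, x)$r))
  expect_error(correlate_with_center(x$force, x$force[1:50]), "equal length")
})

test_that("paired t-test matches the formula-and-CDF oracle on a fixed 7-pair set", {
  center <- c(71.4, 65.2, 90.1, 55.9, 80.3, 62.8, 77.5)
  offset <- c(139.7, 120.2, 160.8, 131.5, 150.0, 118.9, 145.2)
  res <- paired_ttest_vs_center(center, offset)
  ora <- oracle_paired_t(center, offset)
  expect_lt(abs(res$t - ora$t), 1e-10)
  expect_lt(abs(res$p_value - ora$p), 1e-10)
  expect_equal(res$n_pairs, 7)
  expect_equal(res$mean_center, mean(center))
  expect_equal(res$sd_offset, stats::sd(offset))
})

test_that("degenerate paired samples are flagged rather than mis-reported", {
  x <- c(1, 2, 3)
  same <- paired_ttest_vs_center(x, x)
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)

  shifted <- paired_ttest_vs_center(x, x + 1)
  expect_true(shifted$zero_variance)
  expect_equal(shifted$p_value, 0)

  # pairwise exclusion of slack peaks; < 2 remaining pairs -> N/A
  res <- paired_ttest_vs_center(c(NA, NA, 3), c(1, 2, NA))
  expect_true(res$na)
  expect_equal(res$n_pairs, 0)
  one <- paired_ttest_vs_center(c(1, NA, 3), c(2, 5, NA))
  expect_true(one$na)
  expect_equal(one$n_pairs, 1)
})

make_report_fixture <- function(n_subjects = 3) {
  cfg <- default_config()
  cfg$cohort$n_subjects <- as.integer(n_subjects)
  sweep <- run_sweep(cohort_from_config(cfg), config = cfg)
  list(cfg = cfg, sweep = sweep, report = build_report(sweep, cfg))
}

test_that("the report renders slack conditions as N/A and never as zeros", {
  fx <- make_report_fixture(3)
  rep <- fx$report
  post5 <- rep$correlations[
    rep$correlations$direction == "posterior" & rep$correlations$magnitude_mm >= 5,
  ]
  expect_true(all(post5$na))
  expect_true(all(is.na(post5$r)))
  pk5 <- rep$peak_table[
    rep$peak_table$direction == "posterior" & rep$peak_table$magnitude_mm >= 5,
  ]
  expect_true(all(is.na(pk5$first_mean)))
  expect_true(any(grepl("N/A", rep$report_md)))
})

test_that("report means equal independently recomputed means of non-N/A rows", {
  fx <- make_report_fixture(3)
  rep <- fx$report
  for (i in seq_len(nrow(rep$correlation_means))) {
    row <- rep$correlation_means[i, ]
    subj <- rep$correlations[
      rep$correlations$direction == row$direction &
        rep$correlations$magnitude_mm == row$magnitude_mm,
    ]
    if (all(subj$na)) {
      expect_true(is.na(row$mean_r))
    } else {
      expect_equal(row$mean_r, sum(subj$r[!subj$na]) / sum(!subj$na),
        tolerance = 1e-12
      )
    }
  }
})

test_that("significance stars reproduce exactly from the stored p-values", {
  fx <- make_report_fixture(3)
  rep <- fx$report
  lv <- sort(fx$cfg$significance_levels)
  expected <- ifelse(!is.finite(rep$correlations$p_value), "",
    ifelse(rep$correlations$p_value < lv[1], "**",
      ifelse(rep$correlations$p_value < lv[2], "*", "")
    )
  )
  expect_identical(rep$correlations$stars, expected)
})

test_that("a single-subject sweep yields correlations but all-N/A t-tests", {
  fx <- make_report_fixture(1)
  rep <- fx$report
  expect_true(any(!rep$correlations$na))
  off <- rep$peak_table[rep$peak_table$direction != "center", ]
  expect_true(all(is.na(off$first_p)))
  expect_true(all(is.na(off$second_p)))
})

test_that("an incomplete sweep is rejected with the missing cells listed", {
  fx <- make_report_fixture(2)
  sweep <- fx$sweep
  drop <- vapply(sweep$curves, function(cv) {
    cv$subject_id == "S02" && cv$direction == "medial" && cv$magnitude_mm == 5
  }, logical(1))
  sweep$curves <- sweep$curves[!drop]
  expect_error(build_report(sweep, fx$cfg), "S02 medial 5")
})
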