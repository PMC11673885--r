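# stratum summaries, rank-sum tests, weighted pooling, labels

test_that("stratum summaries match hand-computed t intervals", {
  tab <- make_counts(c(2L, 4L, 6L, 8L))
  s <- stratum_summary(tab, "d1", "moderate", "MA")
  expect_equal(s$mean, 5)
  hw <- qt(0.975, 3) * sd(c(2, 4, 6, 8)) / 2
  expect_equal(s$ci_low, 5 - hw)
  expect_equal(s$ci_high, 5 + hw)
  expect_equal(round(c(s$ci_low, s$ci_high), 2), c(0.89, 9.11))

  z <- stratum_summary(make_counts(rep(0L, 6)), "d1", "moderate", "MA")
  expect_equal(c(z$mean, z$ci_low, z$ci_high), c(0, 0, 0))

  one <- stratum_summary(make_counts(5L), "d1", "moderate", "MA")
  expect_equal(c(one$ci_low, one$ci_high), c(5, 5))

  empty <- stratum_summary(make_counts(5L), "d1", "severe", "MA")
  expect_equal(empty$n, 0)
  expect_true(is.na(empty$mean))
})

test_that("rank-sum p-values match the full-enumeration oracle", {
  tab <- rbind(make_counts(c(1L, 2L, 3L), grade = "moderate"),
               make_counts(c(4L, 5L, 6L), grade = "severe"))
  tab$image_id <- sprintf("i%d", 1:6)
  r <- wilcoxon_pairwise(count_table(tab), "d1", "MA", "moderate",
                         "severe")
  expect_equal(r$p_value, 0.1)
  expect_equal(r$statistic, 0)

  set.seed(51)
  for (i in 1:20) {
    n1 <- sample(3:6, 1); n2 <- sample(3:6, 1)
    v <- sample(1000L, n1 + n2)  # distinct values: no ties
    tab <- rbind(make_counts(v[seq_len(n1)], grade = "mild"),
                 make_counts(v[n1 + seq_len(n2)], grade = "severe"))
    tab$image_id <- sprintf("i%d", seq_len(n1 + n2))
    r <- wilcoxon_pairwise(count_table(tab), "d1", "MA", "mild",
                           "severe")
    expect_equal(r$p_value, enum_ranksum_p(v[seq_len(n1)],
                                           v[n1 + seq_len(n2)]),
                 tolerance = 1e-12)
  }
})

test_that("identical all-zero strata give p = 1, NS", {
  tab <- rbind(make_counts(rep(0L, 8), grade = "no_DR"),
               make_counts(rep(0L, 9), grade = "mild"))
  tab$image_id <- sprintf("i%d", 1:17)
  r <- wilcoxon_pairwise(count_table(tab), "d1", "Hma", "no_DR", "mild")
  expect_equal(r$p_value, 1)
  expect_equal(r$label, "NS")
})

test_that("significance labels follow the alpha thresholds", {
  expect_equal(significance_label(c(5e-4, 5e-3, 0.03, 0.2, 0.05)),
               c("***", "**", "*", "NS", "NS"))
  expect_error(significance_label(1.2), "outside")
  expect_error(significance_label(-0.1), "outside")
})

test_that("weighted pooling reproduces arithmetic and edge cases", {
  s <- data.frame(dataset_id = c("a", "b"), grade = "severe",
                  lesion = "MA", n = c(30L, 10L), mean = c(10, 20),
                  sd = c(2, 2), ci_low = NA, ci_high = NA)
  w <- weighted_mean_across_datasets(s, "severe", "MA")
  expect_equal(w$pooled_mean, 12.5)
  expect_equal(unname(attr(w, "weights")), c(0.75, 0.25))

  # single contributing dataset: pooled equals that dataset
  w1 <- weighted_mean_across_datasets(s[1, ], "severe", "MA")
  expect_equal(w1$pooled_mean, 10)
  expect_equal(w1$total_n, 30)

  # equal n: pooled mean is the unweighted mean of dataset means
  s$n <- c(20L, 20L)
  expect_equal(weighted_mean_across_datasets(s, "severe",
                                             "MA")$pooled_mean, 15)

  expect_null(weighted_mean_across_datasets(s, "mild", "MA"))
})

test_that("pooled CI equals the CI of the pooled records", {
  set.seed(52)
  tab <- rbind(make_counts(rnbinom(40, mu = 12, size = 3),
                           dataset_id = "d1"),
               make_counts(rnbinom(25, mu = 18, size = 3),
                           dataset_id = "d2"))
  tab$image_id <- sprintf("i%d", seq_len(nrow(tab)))
  tab <- count_table(tab)
  sums <- summarize_strata(tab, lesions = "MA")
  w <- weighted_mean_across_datasets(sums, "moderate", "MA")
  direct <- stratum_summary(tab, NULL, "moderate", "MA")
  expect_equal(w$pooled_mean, direct$mean)
  expect_equal(w$ci_low, direct$ci_low, tolerance = 1e-12)
  expect_equal(w$ci_high, direct$ci_high, tolerance = 1e-12)
})

test_that("pooled means recover the calibrated monotone trend", {
  gen <- generate_count_table(cohort = cohort_spec(seed = 53))
  res <- filter_outliers(gen$table)
  sums <- summarize_strata(res$filtered)
  w <- weighted_summaries(sums)
  for (lesion in c("MA", "RL")) {
    m <- w$pooled_mean[w$lesion == lesion][order(match(
      w$grade[w$lesion == lesion], severity_grades()))]
    expect_true(all(diff(m) > 0))
  }
  hma <- w[w$lesion == "Hma", ]
  hma <- hma[order(match(hma$grade, severity_grades())), ]
  expect_true(all(diff(hma$pooled_mean[-1]) > 0))  # strict from mild up
  # no-DR and mild share the trace Hma profile: means nearly equal
  expect_lt(abs(hma$pooled_mean[1] - hma$pooled_mean[2]), 0.2)
})
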