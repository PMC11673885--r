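# severity profiles, count cohorts, planted masks, on-disk datasets

test_that("default profiles carry the published calibration constants", {
  p <- default_severity_profiles()
  get <- function(g, l) p$target_mean[p$grade == g & p$lesion == l]
  expect_equal(get("mild", "MA"), 4.3)
  expect_equal(get("moderate", "MA"), 14.2)
  expect_equal(get("severe", "MA"), 53.1)
  expect_equal(get("moderate", "Hma"), 8.7)
  expect_equal(get("severe", "Hma"), 51.1)
  expect_equal(get("moderate", "HE"), 30)
  expect_equal(get("severe", "HE"), 58.2)
  # HE is absent below moderate; no-DR/mild carry only negligible,
  # identically distributed red-lesion noise
  expect_equal(get("mild", "HE"), 0)
  expect_equal(get("no_DR", "HE"), 0)
  expect_lt(get("no_DR", "MA"), 1)
  expect_lt(get("mild", "Hma"), 1)
  expect_equal(p[p$grade == "no_DR" & p$lesion == "Hma", -1],
               p[p$grade == "mild" & p$lesion == "Hma", -1],
               ignore_attr = TRUE)
  # monotone calibration for the red lesions
  for (l in c("MA", "Hma")) {
    m <- vapply(severity_grades(), get, numeric(1), l = l)
    expect_true(all(diff(m) >= 0))
  }
  expect_error(severity_profiles(transform(p, dispersion = NA)),
               "dispersion required")
})

test_that("sampled counts recover the profile means (law of large numbers)", {
  co <- cohort_spec(sizes = c(d1 = 10000),
                    grade_mix = matrix(c(0, 0, 1, 0), 1),
                    outlier_rate = 0, seed = 71)
  gen <- generate_count_table(cohort = co)
  expect_equal(mean(gen$table$ma_count), 14.2, tolerance = 0.02)
  expect_equal(mean(gen$table$hma_count), 8.7, tolerance = 0.02)
  expect_equal(mean(gen$table$he_count), 30, tolerance = 0.03)
  # by-definition zeros hold exactly in mild strata
  co2 <- cohort_spec(sizes = c(d1 = 2000),
                     grade_mix = matrix(c(0, 1, 0, 0), 1),
                     outlier_rate = 0, seed = 72)
  t2 <- generate_count_table(cohort = co2)$table
  expect_true(all(t2$he_count == 0))
  expect_lt(mean(t2$hma_count), 0.5)  # trace hemorrhage noise only
  expect_true(all(t2$rl_count == t2$ma_count + t2$hma_count))
})

test_that("cohort generation is reproducible and structurally sound", {
  g1 <- generate_count_table(cohort = cohort_spec(seed = 73))
  g2 <- generate_count_table(cohort = cohort_spec(seed = 73))
  expect_identical(g1$table, g2$table)
  expect_identical(g1$outliers, g2$outliers)
  expect_equal(nrow(g1$table), 2175)
  expect_equal(as.vector(table(g1$table$dataset_id)[
    c("dataset1", "dataset2", "dataset3", "dataset4")]),
    c(144, 586, 1395, 50))
  # dataset4 is moderate/severe only under the default mixtures
  d4 <- g1$table$grade[g1$table$dataset_id == "dataset4"]
  expect_true(all(d4 %in% c("moderate", "severe")))
})

test_that("empty cohorts produce empty tables", {
  co <- cohort_spec(sizes = c(d1 = 0), seed = 1)
  expect_equal(nrow(generate_count_table(cohort = co)$table), 0)
})

test_that("planted masks honour count, overlap and XML ground truth", {
  e0 <- generate_mask(mask_spec(0, seed = 81))
  expect_equal(sum(e0$mask$pixels), 0)
  expect_equal(nrow(e0$mapping$entries), 0)

  g <- generate_mask(mask_spec(12, overlap_fraction = 0, seed = 82))
  expect_equal(count_lesions(g$mask), 12)
  expect_equal(count_components(g$mask)$n_instances, 12)

  go <- generate_mask(mask_spec(12, overlap_fraction = 0.5,
                                lesion_class = "Hma", seed = 83))
  expect_lt(count_components(go$mask)$n_instances, 12)
  expect_equal(count_lesions(go$mask), 12)

  # XML round-trip preserves planted centroids to well under half a pixel
  d <- withr::local_tempdir()
  write_lesion_xml(go$mapping, file.path(d, "m.xml"))
  back <- read_lesion_xml(file.path(d, "m.xml"))
  expect_equal(nrow(back$entries), 12)
  expect_lt(max(abs(back$entries$x - go$mapping$entries$x),
                abs(back$entries$y - go$mapping$entries$y)), 0.5)

  expect_error(generate_mask(mask_spec(50, height = 32, width = 32,
                                       lesion_class = "HE")),
               "infeasible packing")
})

test_that("on-disk datasets run the pipeline and are byte-reproducible", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  co <- cohort_spec(sizes = c(demo = 4),
                    grade_mix = matrix(c(0, 1, 0, 0), 1),
                    image_dim = c(128, 128), outlier_rate = 0, seed = 85)
  p1 <- generate_dataset(co, d1)
  man <- read_manifest(p1)
  expect_equal(nrow(man), 4)
  expect_true(all(file.exists(file.path(d1, man$ma_mask))))
  counts <- count_dataset(man)
  expect_equal(nrow(counts), 4)
  # the counter recovers the planted per-image counts exactly
  tab <- generate_count_table(cohort = co)$table
  expect_equal(counts$ma_count[order(counts$image_id)],
               tab$ma_count[order(tab$image_id)])
  expect_equal(counts$hma_count[order(counts$image_id)],
               tab$hma_count[order(tab$image_id)])

  p2 <- generate_dataset(co, d2)
  expect_identical(readLines(p1), readLines(p2))
  h1 <- tools::md5sum(file.path(d1, sort(man$ma_mask)))
  h2 <- tools::md5sum(file.path(d2, sort(man$ma_mask)))
  expect_identical(unname(h1), unname(h2))
})
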