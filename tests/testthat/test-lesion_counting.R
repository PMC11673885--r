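# connected components, watershed splitting, HE area, RL combination

test_that("count_components matches examples and the flood-fill oracle", {
  expect_equal(count_components(lesion_mask(matrix(FALSE, 16, 16)))$n_instances,
               0)

  # 5 disjoint 3x3 squares
  px <- matrix(FALSE, 30, 30)
  for (o in list(c(2, 2), c(2, 20), c(14, 10), c(25, 3), c(25, 25)))
    px[o[1] + 0:2, o[2] + 0:2] <- TRUE
  expect_equal(count_components(lesion_mask(px),
                                counting_params(min_size = 3))$n_instances, 5)

  # size filter: a 3x3 square plus a lone pixel
  px <- matrix(FALSE, 12, 12)
  px[2:4, 2:4] <- TRUE
  px[10, 10] <- TRUE
  expect_equal(count_components(lesion_mask(px),
                                counting_params(min_size = 3))$n_instances, 1)

  set.seed(21)
  for (i in 1:150) {
    m <- matrix(runif(24 * 24) < 0.3, 24, 24)
    conn <- if (i %% 2) 8 else 4
    got <- count_components(lesion_mask(m),
                            counting_params(connectivity = conn,
                                            min_size = 1))$n_instances
    expect_equal(got, bfs_count(m, conn, 1))
  }
})

test_that("labels are consecutive and restricted to foreground", {
  set.seed(22)
  m <- matrix(runif(40 * 40) < 0.35, 40, 40)
  lab <- count_components(lesion_mask(m), counting_params(min_size = 2))
  ids <- sort(unique(as.vector(lab$labels[lab$labels > 0])))
  expect_equal(ids, seq_len(lab$n_instances))
  expect_true(all(m[lab$labels > 0]))
})

test_that("watershed splits touching disks and conserves pixels", {
  # a single disk stays one instance
  one <- lesion_mask(disk(matrix(FALSE, 40, 40), 20, 20, 8))
  expect_equal(count_lesions(one), 1)

  # two radius-6 disks, centers 9 px apart, merge under CC but split
  px <- disk(disk(matrix(FALSE, 40, 40), 20, 14, 6), 20, 23, 6)
  m <- lesion_mask(px)
  cc <- count_components(m)
  expect_equal(cc$n_instances, 1)
  sp <- split_touching(cc)
  expect_equal(sp$n_instances, 2)
  expect_equal(sum(sp$labels > 0), sum(px))

  # 10 planted disks with 3 overlapping pairs
  g <- generate_mask(mask_spec(10, height = 200, width = 200,
                               lesion_class = "Hma",
                               overlap_fraction = 0.3, seed = 31))
  cc <- count_components(g$mask)
  expect_lt(cc$n_instances, 10)
  sp <- split_touching(cc)
  expect_equal(sp$n_instances, 10)
  expect_equal(sum(sp$labels > 0), sum(g$mask$pixels))
})

test_that("splitting never reduces counts; equality without overlap", {
  set.seed(23)
  for (i in 1:10) {
    over <- if (i %% 2) 0 else 0.3
    g <- generate_mask(mask_spec(8, height = 160, width = 160,
                                 lesion_class = "Hma",
                                 overlap_fraction = over))
    cc <- count_components(g$mask)
    sp <- split_touching(cc)
    expect_gte(sp$n_instances, cc$n_instances)
    if (over == 0) {
      expect_equal(cc$n_instances, 8)
      expect_equal(sp$n_instances, 8)
    }
  }
})

test_that("counting is equivariant under rotations and shifts", {
  g <- generate_mask(mask_spec(9, height = 120, width = 120,
                               overlap_fraction = 0.25, seed = 33))
  px <- g$mask$pixels
  k0 <- count_lesions(g$mask)
  rot90 <- function(m) t(m)[, nrow(m):1, drop = FALSE]
  m <- px
  for (r in 1:3) {
    m <- rot90(m)
    expect_equal(count_lesions(lesion_mask(m)), k0)
  }
  shifted <- matrix(FALSE, 130, 135)
  shifted[7 + seq_len(120), 11 + seq_len(120)] <- px
  expect_equal(count_lesions(lesion_mask(shifted)), k0)
})

test_that("count_lesions handles empty and well-separated masks", {
  expect_equal(count_lesions(lesion_mask(matrix(FALSE, 8, 8))), 0)
  g <- generate_mask(mask_spec(14, height = 256, width = 256, seed = 35))
  expect_equal(count_lesions(g$mask), 14)
  # split disabled: CC count alone
  expect_equal(count_lesions(g$mask,
                             counting_params(split_enabled = FALSE)), 14)
})

test_that("HE area measurement is exact and matches planted analytic area", {
  expect_equal(measure_he_area(lesion_mask(matrix(FALSE, 10, 10),
                                           lesion_class = "HE")),
               list(area_px = 0L, area_fraction = 0))

  px <- matrix(FALSE, 100, 100)
  px[1:10, 1:25] <- TRUE
  a <- measure_he_area(lesion_mask(px, lesion_class = "HE"))
  expect_equal(a$area_px, 250L)
  expect_equal(a$area_fraction, 0.025)

  g <- generate_mask(mask_spec(12, height = 320, width = 320,
                               lesion_class = "HE",
                               radius_range = c(8, 15),
                               overlap_fraction = 0, seed = 37))
  planted <- sum(pi * g$radii^2)
  got <- measure_he_area(g$mask)$area_px
  expect_lt(abs(got - planted) / planted, 0.02)
})

test_that("red-lesion combination adds counts and propagates missingness", {
  expect_equal(combine_red_lesions(0L, 0L), 0L)
  expect_equal(combine_red_lesions(4L, 9L), 13L)
  expect_equal(combine_red_lesions(3L, NA_integer_), NA_integer_)
  expect_equal(combine_red_lesions(c(1L, NA, 5L), c(2L, 3L, NA)),
               c(3L, NA, NA))
})
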