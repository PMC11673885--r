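# feature building, MLP training, evaluation

make_separable <- function(n_per = 60) {
  # one informative feature with disjoint class ranges
  ma <- c(sample(0:5, n_per, TRUE), sample(20:30, n_per, TRUE),
          sample(60:80, n_per, TRUE), sample(150:200, n_per, TRUE))
  make_counts(as.integer(ma), hma = 0L, he = 0L,
              grade = rep(severity_grades(), each = n_per))
}

test_that("build_features drops incomplete rows and validates classes", {
  tab <- make_counts(1:10, hma = 1L, he = 2L,
                     grade = rep(c("mild", "moderate"), 5))
  tab$he_count[c(2, 5, 9)] <- NA_integer_
  expect_message(f <- build_features(count_table(tab)), "3 row")
  expect_equal(nrow(f$x), 7)
  expect_equal(f$n_dropped, 3)

  uni <- make_counts(1:30, hma = 0L, he = 0L, grade = "moderate")
  expect_error(build_features(count_table(uni)), "2 severity classes")
  expect_error(build_features(count_table(tab), "nope"), "unknown feature")
})

test_that("a separable problem is learned perfectly", {
  tab <- count_table(make_separable())
  tab$image_id <- sprintf("i%d", seq_len(nrow(tab)))
  f <- build_features(tab)
  res <- train_classifier(f, classifier_config(seed = 7))
  expect_equal(res$report$accuracy, 1.0)
  # evaluating on the full data (includes the training set): still perfect
  full <- evaluate_classifier(res$model, f)
  expect_equal(full$accuracy, 1.0)
  expect_equal(unname(full$sensitivity), rep(1, 4))
})

test_that("confusion-matrix arithmetic matches a hand-built model", {
  # one feature, hand-chosen weights implementing 'mild iff x > 0'
  model <- structure(list(
    params = list(W1 = matrix(10), b1 = 0,
                  W2 = matrix(c(-20, 20), 1, 2), b2 = c(10, -10)),
    classes = c("no_DR", "mild"), center = 0, spread = 1,
    features = "ma_count", converged = TRUE), class = "dr_model")
  x <- matrix(c(-1, -1, -1, 1), ncol = 1,
              dimnames = list(NULL, "ma_count"))
  f <- structure(list(x = x,
                      y = factor(c("no_DR", "no_DR", "mild", "mild"),
                                 levels = severity_grades()),
                      features = "ma_count", n_dropped = 0L),
                 class = "feature_matrix")
  rep <- evaluate_classifier(model, f)
  expect_equal(rep$confusion["no_DR", "no_DR"], 2)
  expect_equal(rep$confusion["mild", "no_DR"], 1)
  expect_equal(rep$confusion["mild", "mild"], 1)
  expect_equal(rep$accuracy, 0.75)
  expect_equal(unname(rep$sensitivity[c("no_DR", "mild")]), c(1, 0.5))
  expect_true(all(is.na(rep$sensitivity[c("moderate", "severe")])))
  expect_equal(sum(rep$confusion), rep$n_test)
})

test_that("training is deterministic under a fixed seed", {
  gen <- generate_count_table(cohort = cohort_spec(sizes = c(d1 = 400),
                                                   seed = 61))
  f <- build_features(gen$table)
  r1 <- train_classifier(f, classifier_config(seed = 5,
                                              max_iterations = 200))
  r2 <- train_classifier(f, classifier_config(seed = 5,
                                              max_iterations = 200))
  expect_identical(r1$report$confusion, r2$report$confusion)
  expect_identical(r1$model$params, r2$model$params)
})

test_that("test rows never influence scaling (no leakage)", {
  gen <- generate_count_table(cohort = cohort_spec(sizes = c(d1 = 300),
                                                   seed = 62))
  f <- build_features(gen$table)
  res <- train_classifier(f, classifier_config(seed = 3,
                                               max_iterations = 200))
  # predictions are row-wise: subsetting cannot change them
  p_all <- predict(res$model, f$x)
  p_sub <- predict(res$model, f$x[11:20, , drop = FALSE])
  expect_equal(p_all[11:20], p_sub)
  # scaling parameters come from the training split alone
  expect_false(isTRUE(all.equal(unname(res$model$center),
                                unname(colMeans(f$x)))))
})

test_that("permuted labels collapse accuracy to the majority share", {
  gen <- generate_count_table(cohort = cohort_spec(sizes = c(d1 = 400),
                                                   seed = 63))
  f <- build_features(gen$table)
  maj <- max(table(f$y)) / length(f$y)
  accs <- vapply(1:20, function(s) {
    set.seed(1000 + s)
    fp <- f
    fp$y <- sample(f$y)
    train_classifier(fp, classifier_config(seed = s,
                                           max_iterations = 150))$report$accuracy
  }, numeric(1))
  expect_lt(abs(mean(accs) - maj), 0.1)
})

test_that("feature-set mismatch is rejected at prediction time", {
  tab <- count_table(make_separable(30))
  tab$image_id <- sprintf("i%d", seq_len(nrow(tab)))
  res <- train_classifier(build_features(tab),
                          classifier_config(seed = 2,
                                            max_iterations = 100))
  bad <- tab[, c("ma_count", "hma_count")]
  expect_error(predict(res$model, as.matrix(bad)), "feature set mismatch")
})
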