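# Severity classification from lesion counts: a single-hidden-layer
# feed-forward network (sigmoid hidden units, softmax output,
# cross-entropy loss with an L2 weight-decay penalty), trained by BFGS.
# Defaults mirror the canonical small count-feature classifier: 7 hidden
# units, weight decay 0.001, stratified 80/20 train/test split.

#' Classifier configuration
#'
#' @param hidden_units Hidden-layer size; default 7.
#' @param weight_decay L2 penalty on all weights and biases; default
#'   0.001.
#' @param train_fraction Share of samples used for training; default
#'   0.8.
#' @param seed Integer seed controlling the split and the weight
#'   initialization.
#' @param max_iterations BFGS iteration cap; default 500.
#' @param features Count-table columns used as features.  Default MA,
#'   Hma and HE counts; RL is excluded by default because it is an exact
#'   linear combination of MA and Hma.
#' @return An object of class `classifier_config`.
#' @export
classifier_config <- function(hidden_units = 7, weight_decay = 0.001,
                              train_fraction = 0.8, seed = 1,
                              max_iterations = 500,
                              features = c("ma_count", "hma_count",
                                           "he_count")) {
  stopifnot(hidden_units >= 1, weight_decay >= 0,
            train_fraction > 0, train_fraction < 1, max_iterations >= 1,
            length(features) >= 1)
  structure(list(hidden_units = as.integer(hidden_units),
                 weight_decay = weight_decay,
                 train_fraction = train_fraction, seed = as.integer(seed),
                 max_iterations = as.integer(max_iterations),
                 features = features),
            class = "classifier_config")
}

#' Build a feature matrix from a count table
#'
#' Rows missing any selected feature (or the grade) are dropped; the
#' number dropped is reported via [message()].  Feature scaling happens
#' later, on the training split only.
#'
#' @param table A [count_table()].
#' @param features Count-table columns to use as features.
#' @return Object of class `feature_matrix`: list with `x` (numeric
#'   matrix), `y` (grade factor over all four levels), `features` and
#'   `n_dropped`.
#' @export
build_features <- function(table, features = c("ma_count", "hma_count",
                                               "he_count")) {
  table <- count_table(table)
  miss <- setdiff(features, names(table))
  if (length(miss)) stop("unknown feature column(s): ",
                         paste(miss, collapse = ", "))
  x <- as.matrix(table[, features, drop = FALSE])
  storage.mode(x) <- "double"
  keep <- complete.cases(x) & !is.na(table$grade)
  n_dropped <- sum(!keep)
  if (n_dropped > 0)
    message(n_dropped, " row(s) dropped for missing feature values")
  x <- x[keep, , drop = FALSE]
  y <- factor(as.character(table$grade[keep]), levels = GRADE_LEVELS)
  if (length(unique(y)) < 2)
    stop("fewer than 2 severity classes remain; cannot train")
  structure(list(x = x, y = y, features = features, n_dropped = n_dropped),
            class = "feature_matrix")
}

# internal MLP engine -------------------------------------------------

unpack_params <- function(theta, p, h, k) {
  i <- 0
  W1 <- matrix(theta[i + seq_len(p * h)], p, h); i <- i + p * h
  b1 <- theta[i + seq_len(h)]; i <- i + h
  W2 <- matrix(theta[i + seq_len(h * k)], h, k); i <- i + h * k
  b2 <- theta[i + seq_len(k)]
  list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
}

mlp_forward <- function(pr, x) {
  z <- sweep(x %*% pr$W1, 2, pr$b1, "+")
  a <- 1 / (1 + exp(-z))
  s <- sweep(a %*% pr$W2, 2, pr$b2, "+")
  s <- s - apply(s, 1, max)  # numerical stability
  es <- exp(s)
  list(hidden = a, probs = es / rowSums(es))
}

fit_mlp <- function(x, y, size, decay, maxit) {
  p <- ncol(x); k <- nlevels(y)
  ymat <- diag(k)[as.integer(y), , drop = FALSE]
  npar <- p * size + size + size * k + k
  theta0 <- runif(npar, -0.5, 0.5)
  obj <- function(theta) {
    pr <- unpack_params(theta, p, size, k)
    fw <- mlp_forward(pr, x)
    -sum(ymat * log(pmax(fw$probs, 1e-12))) + decay * sum(theta^2)
  }
  grad <- function(theta) {
    pr <- unpack_params(theta, p, size, k)
    fw <- mlp_forward(pr, x)
    d2 <- fw$probs - ymat                      # n x k
    gW2 <- t(fw$hidden) %*% d2
    gb2 <- colSums(d2)
    d1 <- (d2 %*% t(pr$W2)) * fw$hidden * (1 - fw$hidden)
    gW1 <- t(x) %*% d1
    gb1 <- colSums(d1)
    c(gW1, gb1, gW2, gb2) + 2 * decay * theta
  }
  fit <- optim(theta0, obj, grad, method = "BFGS",
               control = list(maxit = maxit))
  list(params = unpack_params(fit$par, p, size, k),
       converged = fit$convergence == 0, value = fit$value)
}

# training / evaluation ----------------------------------------------

stratified_split <- function(y, train_fraction) {
  train <- integer(0)
  for (lev in levels(y)) {
    idx <- which(y == lev)
    n_tr <- round(length(idx) * train_fraction)
    if (length(idx) > 0)
      train <- c(train, sample(idx, min(length(idx), max(1, n_tr))))
  }
  sort(train)
}

#' Train the severity classifier
#'
#' Stratified 80/20 split (seeded), z-score scaling with parameters
#' estimated on the training split only, then a single-hidden-layer
#' network trained by BFGS on cross-entropy with L2 weight decay.  The
#' report is computed on the held-out test split.
#'
#' @param features A [build_features()] result.
#' @param config A [classifier_config()].
#' @return List with `model` (class `dr_model`: parameters, scaling,
#'   feature list) and `report` (a `classifier_report`, see
#'   [evaluate_classifier()]).  Non-convergence is flagged in the
#'   report, not raised.
#' @export
train_classifier <- function(features, config = classifier_config()) {
  stopifnot(inherits(features, "feature_matrix"),
            inherits(config, "classifier_config"))
  if (nrow(features$x) < 20) stop("need at least 20 samples to train")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)
  tr <- stratified_split(features$y, config$train_fraction)
  te <- setdiff(seq_len(nrow(features$x)), tr)
  xtr <- features$x[tr, , drop = FALSE]
  center <- colMeans(xtr)
  spread <- apply(xtr, 2, sd)
  spread[spread == 0] <- 1
  scale_x <- function(x) sweep(sweep(x, 2, center), 2, spread, "/")
  fit <- fit_mlp(scale_x(xtr), droplevels(features$y[tr]),
                 config$hidden_units, config$weight_decay,
                 config$max_iterations)
  model <- structure(list(params = fit$params,
                          classes = levels(droplevels(features$y[tr])),
                          center = center, spread = spread,
                          features = features$features,
                          converged = fit$converged, config = config),
                     class = "dr_model")
  test_features <- structure(list(x = features$x[te, , drop = FALSE],
                                  y = features$y[te],
                                  features = features$features,
                                  n_dropped = 0L),
                             class = "feature_matrix")
  report <- evaluate_classifier(model, test_features)
  report$n_train <- length(tr)
  if (!fit$converged)
    report$warning <- "optimizer did not converge within max_iterations"
  list(model = model, report = report)
}

#' Predict severity grades for new feature rows
#'
#' @param object A trained `dr_model`.
#' @param newdata A `feature_matrix` or numeric matrix with the model's
#'   feature columns.
#' @param type `"class"` (default) or `"prob"`.
#' @param ... Unused.
#' @return Factor of predicted grades, or a probability matrix.
#' @export
predict.dr_model <- function(object, newdata, type = c("class", "prob"),
                             ...) {
  type <- match.arg(type)
  x <- if (inherits(newdata, "feature_matrix")) newdata$x else newdata
  if (!identical(colnames(x), object$features))
    stop("feature set mismatch: model expects ",
         paste(object$features, collapse = ", "))
  xs <- sweep(sweep(x, 2, object$center), 2, object$spread, "/")
  probs <- mlp_forward(object$params, xs)$probs
  colnames(probs) <- object$classes
  if (type == "prob") return(probs)
  factor(object$classes[max.col(probs, ties.method = "first")],
         levels = GRADE_LEVELS)
}

#' Evaluate a trained classifier
#'
#' @param model A trained `dr_model`.
#' @param features A [build_features()] result (the evaluation set; its
#'   rows never influence the model's scaling parameters).
#' @return Object of class `classifier_report`: `confusion` (4x4
#'   integer matrix, rows = true grade, columns = predicted),
#'   `accuracy` (trace over total), `sensitivity` (per-class true
#'   positive rate; `NA` for absent classes) and `n_test`.
#' @export
evaluate_classifier <- function(model, features) {
  stopifnot(inherits(model, "dr_model"),
            inherits(features, "feature_matrix"))
  pred <- predict(model, features)
  truth <- factor(as.character(features$y), levels = GRADE_LEVELS)
  confusion <- table(truth = truth, predicted = pred)
  confusion <- unclass(confusion)
  rs <- rowSums(confusion)
  sens <- ifelse(rs > 0, diag(confusion) / rs, NA_real_)
  structure(list(confusion = confusion,
                 accuracy = sum(diag(confusion)) / sum(confusion),
                 sensitivity = sens, n_test = sum(confusion)),
            class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat("<classifier_report>\n")
  print(x$confusion)
  cat(sprintf("accuracy: %.3f on %d held-out samples\n", x$accuracy,
              x$n_test))
  cat("per-class sensitivity:\n")
  print(round(x$sensitivity, 3))
  if (!is.null(x$warning)) cat("warning:", x$warning, "\n")
  invisible(x)
}

#' Serialize a classifier report to CSV
#'
#' @param report A `classifier_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_classifier_report <- function(report, path) {
  stopifnot(inherits(report, "classifier_report"))
  df <- as.data.frame(report$confusion)
  df <- data.frame(truth = rownames(report$confusion),
                   report$confusion, check.names = FALSE)
  df$sensitivity <- report$sensitivity
  df$accuracy <- report$accuracy
  write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}
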