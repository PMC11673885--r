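# Per-stratum summaries (mean with 95% CI), pairwise rank-sum tests
# across ICDR severity grades, and sample-size-weighted pooling of
# per-dataset summaries.

LESION_COLUMNS <- c(MA = "ma_count", Hma = "hma_count", RL = "rl_count",
                    HE = "he_count", HE_area = "he_area_px")

lesion_values <- function(table, dataset_id, grade, lesion) {
  lesion <- match.arg(lesion, names(LESION_COLUMNS))
  sel <- table$grade == grade
  if (!is.null(dataset_id)) sel <- sel & table$dataset_id == dataset_id
  v <- table[[LESION_COLUMNS[[lesion]]]][sel]
  v[!is.na(v)]
}

#' Mean and 95% confidence interval for one stratum
#'
#' The CI is Student-t on the mean: `mean +/- t(0.975, n-1) * sd /
#' sqrt(n)`.  A stratum with a single value yields a degenerate CI equal
#' to the mean; an empty stratum yields an all-`NA` sentinel row.
#'
#' @param table A [count_table()].
#' @param dataset_id Dataset identifier, or `NULL` to pool all datasets.
#' @param grade Severity grade label.
#' @param lesion One of `"MA"`, `"Hma"`, `"RL"`, `"HE"`, `"HE_area"`.
#' @param ci_method `"t"` (default) or `"bootstrap"` (percentile, 2000
#'   resamples; seed with [set.seed()] for reproducibility).
#' @return One-row data frame: `dataset_id, grade, lesion, n, mean, sd,
#'   ci_low, ci_high`.
#' @export
stratum_summary <- function(table, dataset_id = NULL, grade, lesion,
                            ci_method = c("t", "bootstrap")) {
  ci_method <- match.arg(ci_method)
  v <- lesion_values(table, dataset_id, grade, lesion)
  n <- length(v)
  out <- data.frame(dataset_id = dataset_id %||% "all",
                    grade = grade, lesion = lesion, n = n,
                    mean = NA_real_, sd = NA_real_, ci_low = NA_real_,
                    ci_high = NA_real_, stringsAsFactors = FALSE)
  if (n == 0) return(out)
  out$mean <- mean(v)
  out$sd <- if (n > 1) sd(v) else 0
  if (n == 1) {
    out$ci_low <- out$ci_high <- out$mean
  } else if (ci_method == "t") {
    hw <- qt(0.975, n - 1) * out$sd / sqrt(n)
    out$ci_low <- out$mean - hw
    out$ci_high <- out$mean + hw
  } else {
    bm <- vapply(seq_len(2000),
                 function(i) mean(v[sample.int(n, n, replace = TRUE)]),
                 numeric(1))
    q <- quantile(bm, c(0.025, 0.975), names = FALSE)
    out$ci_low <- q[1]
    out$ci_high <- q[2]
  }
  out
}

#' Summaries for every (dataset, grade, lesion) stratum
#'
#' @param table A [count_table()].
#' @param lesions Lesion metrics to summarize.
#' @param by_dataset Summarize per dataset (`TRUE`, default) or pooled.
#' @inheritParams stratum_summary
#' @return Data frame with one [stratum_summary()] row per non-empty
#'   stratum.
#' @export
summarize_strata <- function(table, lesions = c("MA", "Hma", "RL", "HE"),
                             by_dataset = TRUE, ci_method = "t") {
  datasets <- if (by_dataset) unique(table$dataset_id) else list(NULL)
  rows <- list()
  for (ds in datasets) {
    for (g in GRADE_LEVELS) {
      for (le in lesions) {
        s <- stratum_summary(table, ds, g, le, ci_method)
        if (s$n > 0) rows[[length(rows) + 1L]] <- s
      }
    }
  }
  do.call(rbind, rows)
}

#' Two-sided unpaired Wilcoxon rank-sum test between two grades
#'
#' Exact null distribution when both groups have at most 25 observations
#' and no ties; normal approximation with tie and continuity correction
#' otherwise.  When every value in both groups is identical the test is
#' undefined under the normal approximation; that case is reported as
#' `p = 1` (no evidence of a shift), matching two all-zero strata.
#'
#' @param table A [count_table()].
#' @param dataset_id Dataset identifier, or `NULL` to pool datasets.
#' @param lesion Lesion metric, see [stratum_summary()].
#' @param grade_a,grade_b The two severity grades compared.
#' @return One-row data frame: `dataset_id, lesion, grade_a, grade_b,
#'   n_a, n_b, statistic` (Mann-Whitney U of group a), `p_value,
#'   label`.  Empty strata yield an `NA` sentinel row.
#' @export
wilcoxon_pairwise <- function(table, dataset_id = NULL, lesion, grade_a,
                              grade_b) {
  x <- lesion_values(table, dataset_id, grade_a, lesion)
  y <- lesion_values(table, dataset_id, grade_b, lesion)
  out <- data.frame(dataset_id = dataset_id %||% "all", lesion = lesion,
                    grade_a = grade_a, grade_b = grade_b,
                    n_a = length(x), n_b = length(y),
                    statistic = NA_real_, p_value = NA_real_,
                    label = NA_character_, stringsAsFactors = FALSE)
  if (length(x) == 0 || length(y) == 0) return(out)
  if (length(unique(c(x, y))) == 1L) {
    out$statistic <- length(x) * length(y) / 2
    out$p_value <- 1
  } else {
    use_exact <- length(x) <= 25 && length(y) <= 25 &&
      !anyDuplicated(c(x, y))
    wt <- suppressWarnings(wilcox.test(x, y, alternative = "two.sided",
                                       exact = use_exact, correct = TRUE))
    out$statistic <- unname(wt$statistic)
    out$p_value <- min(1, wt$p.value)
  }
  out$label <- significance_label(out$p_value)
  out
}

#' Pairwise rank-sum tests across severity grades
#'
#' @param table A [count_table()].
#' @param lesions Lesion metrics to test.
#' @param pairs `"adjacent"` (default: no_DR-mild, mild-moderate,
#'   moderate-severe) or `"all"` grade pairs.
#' @param by_dataset Test within each dataset (`TRUE`, default, the
#'   per-dataset analysis) or on the pooled table.
#' @return Data frame of [wilcoxon_pairwise()] rows for every pair whose
#'   two strata are non-empty.
#' @export
pairwise_tests <- function(table, lesions = c("MA", "Hma", "RL", "HE"),
                           pairs = c("adjacent", "all"),
                           by_dataset = TRUE) {
  pairs <- match.arg(pairs)
  gp <- if (pairs == "adjacent") {
    cbind(GRADE_LEVELS[-4], GRADE_LEVELS[-1])
  } else {
    t(combn(GRADE_LEVELS, 2))
  }
  datasets <- if (by_dataset) unique(table$dataset_id) else list(NULL)
  rows <- list()
  for (ds in datasets) {
    for (le in lesions) {
      for (i in seq_len(nrow(gp))) {
        r <- wilcoxon_pairwise(table, ds, le, gp[i, 1], gp[i, 2])
        if (r$n_a > 0 && r$n_b > 0) rows[[length(rows) + 1L]] <- r
      }
    }
  }
  do.call(rbind, rows)
}

#' Significance label for a p-value
#'
#' `***` below 0.001, `**` below 0.01, `*` below 0.05 (the working
#' alpha), `NS` otherwise.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Character vector of labels.
#' @export
significance_label <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1)))
    stop("p-value(s) outside [0, 1]")
  ifelse(is.na(p), NA_character_,
         ifelse(p < 0.001, "***",
                ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "NS"))))
}

#' Sample-size-weighted pooling of per-dataset stratum summaries
#'
#' Pooled mean with weights proportional to per-dataset stratum sizes —
#' algebraically the mean of the pooled records.  The pooled 95% CI is
#' computed on the pooled sample, with the pooled variance recovered
#' exactly from the per-dataset `n`, `mean` and `sd` (within plus
#' between components).
#'
#' @param summaries A [summarize_strata()] data frame (per dataset).
#' @param grade Severity grade to pool.
#' @param lesion Lesion metric to pool.
#' @return One-row data frame: `grade, lesion, total_n, pooled_mean,
#'   ci_low, ci_high`, with a `weights` attribute (named, summing to 1),
#'   or `NULL` when no dataset contributes the stratum.
#' @export
weighted_mean_across_datasets <- function(summaries, grade, lesion) {
  s <- summaries[summaries$grade == grade & summaries$lesion == lesion &
                   summaries$n > 0, , drop = FALSE]
  if (nrow(s) == 0) return(NULL)
  ntot <- sum(s$n)
  w <- s$n / ntot
  m <- sum(w * s$mean)
  # exact pooled variance from group moments
  ss_within <- sum((s$n - 1) * s$sd^2)
  ss_between <- sum(s$n * (s$mean - m)^2)
  pooled_var <- if (ntot > 1) (ss_within + ss_between) / (ntot - 1) else 0
  hw <- if (ntot > 1) qt(0.975, ntot - 1) * sqrt(pooled_var / ntot) else 0
  out <- data.frame(grade = grade, lesion = lesion, total_n = ntot,
                    pooled_mean = m, ci_low = m - hw, ci_high = m + hw,
                    stringsAsFactors = FALSE)
  attr(out, "weights") <- setNames(w, s$dataset_id)
  out
}

#' Weighted pooled summaries for every (grade, lesion)
#'
#' @param summaries A [summarize_strata()] data frame (per dataset).
#' @return Data frame of [weighted_mean_across_datasets()] rows.
#' @export
weighted_summaries <- function(summaries) {
  rows <- list()
  for (g in GRADE_LEVELS) {
    for (le in unique(summaries$lesion)) {
      r <- weighted_mean_across_datasets(summaries, g, le)
      if (!is.null(r)) rows[[length(rows) + 1L]] <- r
    }
  }
  do.call(rbind, rows)
}

#' @importFrom utils combn
NULL
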