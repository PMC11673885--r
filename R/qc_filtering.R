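# Outlier exclusion on per-image lesion counts: records whose MA or Hma
# count falls outside [Q1 - 1.5 IQR, Q3 + 1.5 IQR] of their stratum are
# considered unreliable and removed, once, in a single pass.

FILTER_LESIONS <- c(MA = "ma_count", Hma = "hma_count")

quantile_cr <- function(x, p, qtype) {
  switch(qtype,
         linear = unname(quantile(x, p, type = 7, names = FALSE)),
         lower = sort(x)[pmax(1L, floor((length(x) - 1) * p + 1))],
         higher = sort(x)[pmin(length(x), ceiling((length(x) - 1) * p + 1))],
         stop("unknown quantile type: ", qtype))
}

#' Interquartile-range exclusion bounds
#'
#' Quartiles by linear interpolation between closest ranks (the common
#' "type 7" default; `lower`/`higher` pick the bracketing order
#' statistics instead), then `lower = q1 - 1.5 * iqr`,
#' `upper = q3 + 1.5 * iqr`.
#'
#' @param values Numeric vector of counts; `NA`s are dropped.
#' @param qtype Quantile convention: `"linear"` (default), `"lower"` or
#'   `"higher"`.
#' @return List with `q1`, `q3`, `lower`, `upper`, `n` and `degenerate`.
#'   With fewer than 4 non-missing values the bounds are degenerate: a
#'   no-filter sentinel (`lower = -Inf`, `upper = Inf`) is returned with
#'   a warning and the stratum passes unfiltered.
#' @export
compute_iqr_bounds <- function(values, qtype = c("linear", "lower",
                                                 "higher")) {
  qtype <- match.arg(qtype)
  v <- values[!is.na(values)]
  if (length(v) < 4) {
    warning("fewer than 4 values (", length(v),
            "); IQR bounds degenerate, stratum passes unfiltered")
    return(list(q1 = NA_real_, q3 = NA_real_, lower = -Inf, upper = Inf,
                n = length(v), degenerate = TRUE))
  }
  q1 <- quantile_cr(v, 0.25, qtype)
  q3 <- quantile_cr(v, 0.75, qtype)
  iqr <- q3 - q1
  list(q1 = q1, q3 = q3, lower = q1 - 1.5 * iqr, upper = q3 + 1.5 * iqr,
       n = length(v), degenerate = FALSE)
}

#' Exclude records with outlying MA or Hma counts
#'
#' Within each stratum, IQR bounds are computed separately for MA and
#' Hma counts; a record is removed when either count violates its
#' bounds.  HE values never trigger exclusion.  Filtering is single
#' pass: bounds are computed once on the input and never recomputed on
#' the filtered table (re-filtering a filtered table is deliberately not
#' idempotent and is not done).
#'
#' @param table A [count_table()].
#' @param stratify Grouping for the bounds: `"dataset_grade"` (default;
#'   pooling grades would systematically delete legitimate severe
#'   cases), `"dataset"`, or `"global"`.
#' @param qtype Quantile convention, see [compute_iqr_bounds()].
#' @return List of class `filter_report_result` with elements
#'   `filtered` (the retained [count_table()]) and `report`, itself a
#'   list with `strata` (per dataset x grade x lesion: bounds and
#'   before/after sizes) and `excluded` (one row per excluded record and
#'   violated lesion).
#' @export
filter_outliers <- function(table, stratify = c("dataset_grade", "dataset",
                                                "global"),
                            qtype = "linear") {
  table <- count_table(table)
  stratify <- match.arg(stratify)
  key <- switch(stratify,
                dataset_grade = paste(table$dataset_id, table$grade,
                                      sep = "\r"),
                dataset = table$dataset_id,
                global = rep("all", nrow(table)))
  drop <- rep(FALSE, nrow(table))
  strata <- list()
  excl <- list()
  for (k in unique(key)) {
    idx <- which(key == k)
    for (lesion in names(FILTER_LESIONS)) {
      v <- table[[FILTER_LESIONS[[lesion]]]][idx]
      b <- withCallingHandlers(
        compute_iqr_bounds(v, qtype),
        warning = function(w) invokeRestart("muffleWarning"))
      if (b$degenerate && b$n > 0)
        message("stratum ", sub("\r", "/", k), " ", lesion, ": only ",
                b$n, " value(s); passes unfiltered")
      bad <- !is.na(v) & (v < b$lower | v > b$upper)
      strata[[length(strata) + 1L]] <- data.frame(
        stratum = sub("\r", "/", k),
        dataset_id = if (stratify == "global") NA_character_ else
          table$dataset_id[idx[1]],
        grade = if (stratify == "dataset_grade")
          as.character(table$grade[idx[1]]) else NA_character_,
        lesion = lesion, q1 = b$q1, q3 = b$q3, lower = b$lower,
        upper = b$upper, n_before = b$n, n_excluded = sum(bad),
        n_after = b$n - sum(bad), degenerate = b$degenerate,
        stringsAsFactors = FALSE)
      if (any(bad)) {
        excl[[length(excl) + 1L]] <- data.frame(
          dataset_id = table$dataset_id[idx[bad]],
          image_id = table$image_id[idx[bad]], lesion = lesion,
          value = v[bad], stringsAsFactors = FALSE)
        drop[idx[bad]] <- TRUE
      }
    }
  }
  excluded <- if (length(excl)) do.call(rbind, excl) else
    data.frame(dataset_id = character(), image_id = character(),
               lesion = character(), value = numeric())
  filtered <- table[!drop, , drop = FALSE]
  rownames(filtered) <- NULL
  report <- structure(list(strata = do.call(rbind, strata),
                           excluded = excluded,
                           n_before = nrow(table), n_after = sum(!drop),
                           stratify = stratify, qtype = qtype),
                      class = "filter_report")
  structure(list(filtered = count_table(filtered), report = report),
            class = "filter_report_result")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("<filter_report> 1.5 x IQR rule on MA/Hma, stratified by %s\n",
              x$stratify))
  cat(sprintf("  records: %d -> %d (%.1f%% excluded)\n", x$n_before,
              x$n_after, 100 * (x$n_before - x$n_after) /
                max(1, x$n_before)))
  invisible(x)
}

#' Serialize a filter report to CSV files
#'
#' @param report The `report` element of a [filter_outliers()] result.
#' @param strata_path,excluded_path Output CSV paths.
#' @return Invisibly, the two paths.
#' @export
write_filter_report <- function(report, strata_path, excluded_path) {
  stopifnot(inherits(report, "filter_report"))
  write.csv(report$strata, strata_path, row.names = FALSE, na = "")
  write.csv(report$excluded, excluded_path, row.names = FALSE, na = "")
  invisible(c(strata_path, excluded_path))
}
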