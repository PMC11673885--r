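# Pipeline orchestration: count -> filter -> stats -> classify, with a
# JSON config file, structured stderr logging and a run manifest.  Also
# the command-line entry point (subcommands simulate, count, filter,
# stats, classify, run-all).

#' Pipeline configuration
#'
#' @param manifest Path to a dataset manifest CSV, or `NULL` to simulate
#'   a cohort first (see `cohort`).
#' @param out_dir Output directory.
#' @param params A [counting_params()].
#' @param filter Apply the IQR outlier filter?  Default `TRUE`.
#' @param stratify IQR stratification mode, see [filter_outliers()].
#' @param qtype Quantile convention, see [compute_iqr_bounds()].
#' @param ci_method CI method for summaries, see [stratum_summary()].
#' @param pairs Grade comparisons: `"adjacent"` or `"all"`.
#' @param classifier A [classifier_config()].
#' @param cohort A [cohort_spec()] used when `manifest` is `NULL`.
#' @param seed Global seed; propagates to simulation and to the
#'   classifier split/initialization.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(manifest = NULL, out_dir = "drquant_out",
                            params = counting_params(), filter = TRUE,
                            stratify = "dataset_grade", qtype = "linear",
                            ci_method = "t", pairs = "adjacent",
                            classifier = classifier_config(),
                            cohort = cohort_spec(), seed = 1) {
  structure(list(manifest = manifest, out_dir = out_dir, params = params,
                 filter = isTRUE(filter), stratify = stratify,
                 qtype = qtype, ci_method = ci_method, pairs = pairs,
                 classifier = classifier, cohort = cohort,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a JSON file
#'
#' Recognized top-level keys mirror the [pipeline_config()] arguments;
#' `params`, `classifier` and `cohort` are nested objects whose fields
#' are passed to the respective constructors.
#'
#' @param path Path to a JSON file.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  args <- cfg[intersect(names(cfg),
                        c("manifest", "out_dir", "filter", "stratify",
                          "qtype", "ci_method", "pairs", "seed"))]
  if (!is.null(cfg$params))
    args$params <- do.call(counting_params, as.list(cfg$params))
  if (!is.null(cfg$classifier))
    args$classifier <- do.call(classifier_config, as.list(cfg$classifier))
  if (!is.null(cfg$cohort)) {
    co <- as.list(cfg$cohort)
    if (!is.null(co$sizes)) co$sizes <- unlist(co$sizes)
    if (!is.null(co$grade_mix)) co$grade_mix <- as.matrix(co$grade_mix)
    args$cohort <- do.call(cohort_spec, co)
  }
  do.call(pipeline_config, args)
}

log_msg <- function(...) {
  message(format(Sys.time(), "%H:%M:%S"), " [drquant] ", ...)
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(config, f)
  unname(tools::md5sum(f))
}

#' Run the full analysis pipeline
#'
#' Stages run in order: (simulate) -> count -> filter -> stats ->
#' classify.  Every stage writes a CSV under `out_dir`; a run manifest
#' JSON records the seed, the config hash and per-stage row counts.
#' Outputs are pure functions of (inputs, config, seed).
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the principal results (`counts`,
#'   `filter`, `summaries`, `tests`, `weighted`, `classifier`) and
#'   `out_dir`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  stage <- "simulate"
  res <- tryCatch({
    if (is.null(config$manifest)) {
      log_msg("simulating cohort (seed ", config$seed, ")")
      sim_dir <- file.path(config$out_dir, "simulated")
      manifest_path <- generate_dataset(config$cohort, sim_dir)
    } else manifest_path <- config$manifest

    stage <- "count"
    manifest <- read_manifest(manifest_path)
    log_msg("counting lesions in ", nrow(manifest), " images")
    counts <- count_dataset(manifest, config$params)
    write_counts(counts, file.path(config$out_dir, "counts.csv"))

    stage <- "filter"
    if (config$filter) {
      fr <- filter_outliers(counts, stratify = config$stratify,
                            qtype = config$qtype)
      log_msg("filtered ", fr$report$n_before, " -> ",
              fr$report$n_after, " records")
      write_filter_report(fr$report,
                          file.path(config$out_dir, "filter_strata.csv"),
                          file.path(config$out_dir,
                                    "filter_excluded.csv"))
      analysis <- fr$filtered
    } else {
      fr <- NULL
      analysis <- counts
      log_msg("outlier filtering disabled")
    }
    write_counts(analysis, file.path(config$out_dir,
                                     "counts_filtered.csv"))

    stage <- "stats"
    summaries <- summarize_strata(analysis, ci_method = config$ci_method)
    write.csv(summaries, file.path(config$out_dir, "summaries.csv"),
              row.names = FALSE, na = "")
    tests <- pairwise_tests(analysis, pairs = config$pairs)
    write.csv(tests, file.path(config$out_dir, "pairwise_tests.csv"),
              row.names = FALSE, na = "")
    weighted <- weighted_summaries(summaries)
    write.csv(weighted, file.path(config$out_dir,
                                  "weighted_summaries.csv"),
              row.names = FALSE, na = "")
    plot_severity_summaries(weighted,
                            file.path(config$out_dir,
                                      "weighted_summaries.png"))
    log_msg("stats: ", nrow(summaries), " strata, ", nrow(tests),
            " pairwise tests")

    stage <- "classify"
    cls_cfg <- config$classifier
    cls_cfg$seed <- config$seed
    feats <- build_features(analysis, cls_cfg$features)
    trained <- train_classifier(feats, cls_cfg)
    write_classifier_report(trained$report,
                            file.path(config$out_dir,
                                      "classifier_report.csv"))
    plot_confusion(trained$report,
                   file.path(config$out_dir, "confusion.png"))
    log_msg(sprintf("classifier: held-out accuracy %.3f",
                    trained$report$accuracy))

    list(counts = counts, filter = fr, summaries = summaries,
         tests = tests, weighted = weighted, classifier = trained,
         out_dir = config$out_dir)
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })

  manifest_json <- list(
    package = "drquant",
    version = as.character(utils::packageVersion("drquant")),
    seed = config$seed, config_hash = config_hash(config),
    n_images = nrow(res$counts),
    n_after_filter = if (!is.null(res$filter))
      res$filter$report$n_after else nrow(res$counts),
    n_strata = nrow(res$summaries), n_tests = nrow(res$tests),
    accuracy = res$classifier$report$accuracy)
  jsonlite::write_json(manifest_json,
                       file.path(config$out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(res)
}

# plots ---------------------------------------------------------------

#' Plot pooled lesion means with CI whiskers against severity grade
#'
#' @param weighted A [weighted_summaries()] data frame.
#' @param path Optional PNG path; when given, the plot is written there.
#' @return Invisibly, `path` (or `NULL` when plotting to the active
#'   device).
#' @export
plot_severity_summaries <- function(weighted, path = NULL) {
  if (!is.null(path)) {
    grDevices::png(path, width = 900, height = 600)
    on.exit(grDevices::dev.off())
  }
  lesions <- unique(weighted$lesion)
  cols <- setNames(grDevices::hcl.colors(length(lesions), "Dark 3"),
                   lesions)
  gx <- setNames(seq_along(GRADE_LEVELS), GRADE_LEVELS)
  off <- seq(-0.18, 0.18, length.out = length(lesions))
  ylim <- c(0, max(weighted$ci_high, na.rm = TRUE) * 1.05)
  graphics::plot(NA, xlim = c(0.5, 4.5), ylim = ylim, xaxt = "n",
                 xlab = "ICDR severity grade",
                 ylab = "lesions per image (mean, 95% CI)")
  graphics::axis(1, at = gx, labels = names(gx))
  for (i in seq_along(lesions)) {
    s <- weighted[weighted$lesion == lesions[i], ]
    x <- gx[as.character(s$grade)] + off[i]
    graphics::points(x, s$pooled_mean, pch = 19, col = cols[i])
    has_ci <- !is.na(s$ci_low) & s$ci_high - s$ci_low > 1e-9
    if (any(has_ci))
      graphics::arrows(x[has_ci], s$ci_low[has_ci], x[has_ci],
                       s$ci_high[has_ci], angle = 90, code = 3,
                       length = 0.04, col = cols[i])
  }
  graphics::legend("topleft", legend = lesions, col = cols, pch = 19,
                   bty = "n")
  invisible(path)
}

#' Render a confusion matrix with per-class sensitivity
#'
#' @param report A `classifier_report`.
#' @param path Optional PNG path.
#' @return Invisibly, `path`.
#' @export
plot_confusion <- function(report, path = NULL) {
  if (!is.null(path)) {
    grDevices::png(path, width = 700, height = 600)
    on.exit(grDevices::dev.off())
  }
  cm <- report$confusion
  k <- nrow(cm)
  graphics::image(seq_len(k + 1), seq_len(k),
                  rbind(t(cm[k:1, ]), NA_real_),
                  col = grDevices::hcl.colors(64, "Blues 3", rev = TRUE),
                  xlab = "predicted", ylab = "true", axes = FALSE,
                  main = sprintf("accuracy %.1f%%", 100 * report$accuracy))
  graphics::axis(1, at = seq_len(k), labels = colnames(cm))
  graphics::axis(4, at = (k + 1), labels = "sens.", tick = FALSE)
  graphics::axis(2, at = seq_len(k), labels = rev(rownames(cm)))
  for (i in seq_len(k)) for (j in seq_len(k))
    graphics::text(j, k + 1 - i, cm[i, j])
  for (i in seq_len(k))
    graphics::text(k + 1, k + 1 - i,
                   ifelse(is.na(report$sensitivity[i]), "-",
                          sprintf("%.2f", report$sensitivity[i])))
  invisible(path)
}

# CLI -----------------------------------------------------------------

cli_options <- function() {
  list(
    optparse::make_option("--config", type = "character", default = NULL,
                          help = "JSON pipeline config file"),
    optparse::make_option("--manifest", type = "character",
                          default = NULL, help = "dataset manifest CSV"),
    optparse::make_option("--out", type = "character",
                          default = "drquant_out",
                          help = "output directory [default %default]"),
    optparse::make_option("--seed", type = "integer", default = 1,
                          help = "global seed [default %default]"),
    optparse::make_option("--no-filter", action = "store_true",
                          default = FALSE, dest = "no_filter",
                          help = "skip IQR outlier filtering"),
    optparse::make_option("--pairs", type = "character",
                          default = "adjacent",
                          help = "grade comparisons: adjacent|all"),
    optparse::make_option("--features", type = "character",
                          default = "ma_count,hma_count,he_count",
                          help = "classifier feature columns"),
    optparse::make_option("--quantile-type", type = "character",
                          default = "linear", dest = "quantile_type",
                          help = "IQR quantiles: linear|lower|higher"))
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (write a synthetic dataset), `count`,
#' `filter`, `stats`, `classify` (single stages on CSV inputs) and
#' `run-all` (the full pipeline).  Invoke as e.g.
#' `Rscript -e 'drquant::cli_main()' run-all --out results --seed 7`.
#'
#' @param args Character vector of command-line arguments; defaults to
#'   the process arguments.
#' @return Exit status 0, invisibly.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  cmds <- c("simulate", "count", "filter", "stats", "classify",
            "run-all")
  if (length(args) == 0 || !(args[1] %in% cmds)) {
    message("usage: drquant <", paste(cmds, collapse = "|"),
            "> [options]")
    return(invisible(1L))
  }
  cmd <- args[1]
  parser <- optparse::OptionParser(option_list = cli_options(),
                                   prog = paste("drquant", cmd))
  opt <- optparse::parse_args(parser, args = args[-1])

  config <- if (!is.null(opt$config)) read_pipeline_config(opt$config)
            else pipeline_config()
  if (!is.null(opt$manifest)) config$manifest <- opt$manifest
  config$out_dir <- opt$out
  config$seed <- opt$seed
  config$filter <- !opt$no_filter
  config$pairs <- opt$pairs
  config$qtype <- opt$quantile_type
  config$classifier$features <- strsplit(opt$features, ",")[[1]]

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  switch(cmd,
    "simulate" = {
      p <- generate_dataset(config$cohort, config$out_dir)
      log_msg("wrote ", p)
    },
    "count" = {
      counts <- count_dataset(read_manifest(config$manifest),
                              config$params)
      write_counts(counts, file.path(config$out_dir, "counts.csv"))
    },
    "filter" = {
      counts <- read_counts(file.path(config$out_dir, "counts.csv"))
      fr <- filter_outliers(counts, stratify = config$stratify,
                            qtype = config$qtype)
      write_counts(fr$filtered,
                   file.path(config$out_dir, "counts_filtered.csv"))
      write_filter_report(fr$report,
                          file.path(config$out_dir, "filter_strata.csv"),
                          file.path(config$out_dir,
                                    "filter_excluded.csv"))
    },
    "stats" = {
      counts <- read_counts(file.path(config$out_dir,
                                      "counts_filtered.csv"))
      summaries <- summarize_strata(counts, ci_method = config$ci_method)
      write.csv(summaries, file.path(config$out_dir, "summaries.csv"),
                row.names = FALSE, na = "")
      write.csv(pairwise_tests(counts, pairs = config$pairs),
                file.path(config$out_dir, "pairwise_tests.csv"),
                row.names = FALSE, na = "")
      weighted <- weighted_summaries(summaries)
      write.csv(weighted,
                file.path(config$out_dir, "weighted_summaries.csv"),
                row.names = FALSE, na = "")
      plot_severity_summaries(weighted,
                              file.path(config$out_dir,
                                        "weighted_summaries.png"))
    },
    "classify" = {
      counts <- read_counts(file.path(config$out_dir,
                                      "counts_filtered.csv"))
      cls_cfg <- config$classifier
      cls_cfg$seed <- config$seed
      trained <- train_classifier(build_features(counts,
                                                 cls_cfg$features),
                                  cls_cfg)
      write_classifier_report(trained$report,
                              file.path(config$out_dir,
                                        "classifier_report.csv"))
      plot_confusion(trained$report,
                     file.path(config$out_dir, "confusion.png"))
      print(trained$report)
    },
    "run-all" = run_pipeline(config))
  invisible(0L)
}
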