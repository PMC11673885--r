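# Instance counting on binary lesion masks: connected components with a
# minimum-size filter, refined by a marker-controlled watershed that
# separates touching lesions, plus hard-exudate area measurement.

#' Counting parameters
#'
#' @param connectivity Pixel neighbourhood, 4 or 8.  Default 8: round
#'   lesions that touch diagonally belong together.
#' @param min_size Minimum component area in pixels; smaller components
#'   are discarded as annotation noise.  Default 3.
#' @param marker_min_distance Minimum separation (pixels, Euclidean)
#'   between watershed markers within one component.  Default 5; two
#'   merged lesions are split when their cores are at least this far
#'   apart.
#' @param marker_min_prominence Minimum height (pixels of distance) a
#'   marker must rise above the saddle joining it to a neighbouring
#'   region; shallower regions are merged back.  Default 0.5, enough to
#'   absorb spurious maxima created by grid discretization while
#'   keeping genuine lesion cores.
#' @param split_enabled Run the watershed refinement?  Default `TRUE`.
#' @return An object of class `counting_params`.
#' @export
counting_params <- function(connectivity = 8, min_size = 3,
                            marker_min_distance = 5,
                            marker_min_prominence = 0.5,
                            split_enabled = TRUE) {
  if (!connectivity %in% c(4, 8)) stop("connectivity must be 4 or 8")
  if (min_size < 1) stop("min_size must be >= 1")
  if (marker_min_distance < 1) stop("marker_min_distance must be >= 1")
  if (marker_min_prominence < 0) stop("marker_min_prominence must be >= 0")
  structure(list(connectivity = as.integer(connectivity),
                 min_size = as.integer(min_size),
                 marker_min_distance = as.numeric(marker_min_distance),
                 marker_min_prominence = as.numeric(marker_min_prominence),
                 split_enabled = isTRUE(split_enabled)),
            class = "counting_params")
}

new_labeled_mask <- function(labels, mask) {
  structure(list(image_id = mask$image_id, lesion_class = mask$lesion_class,
                 labels = labels,
                 n_instances = attr(labels, "n_instances")),
            class = "labeled_mask")
}

#' @export
print.labeled_mask <- function(x, ...) {
  cat(sprintf("<labeled_mask> image %s, class %s, %d instance(s)\n",
              x$image_id, x$lesion_class, x$n_instances))
  invisible(x)
}

#' Label connected foreground components of a lesion mask
#'
#' Maximal connected foreground regions under the chosen connectivity;
#' components smaller than `min_size` pixels are removed and the rest
#' relabeled consecutively (1..k, deterministic scan order).
#'
#' @param mask A [lesion_mask()].
#' @param params A [counting_params()].
#' @return An object of class `labeled_mask` with fields `labels`
#'   (integer matrix, 0 = background) and `n_instances`.
#' @export
count_components <- function(mask, params = counting_params()) {
  stopifnot(inherits(mask, "lesion_mask"), inherits(params, "counting_params"))
  labels <- cc_label(mask$pixels, params$connectivity, params$min_size)
  new_labeled_mask(labels, mask)
}

#' Split touching lesions with a marker-controlled watershed
#'
#' For each labeled component, the Euclidean distance transform is
#' computed and markers are placed at its local maxima (plateaus
#' collapse to a single marker; markers closer than
#' `marker_min_distance` are merged greedily, highest first).
#' Components holding two or more markers are flooded from those
#' markers; regions whose marker rises less than
#' `marker_min_prominence` above the saddle to a neighbouring region
#' are then merged back (maxima dynamics), which suppresses spurious
#' peaks created by grid discretization.  Components with a single
#' marker are left unchanged, so isolated lesions are never over-split.
#' Total foreground is exactly conserved.
#'
#' @param labeled A `labeled_mask` from [count_components()].
#' @param params A [counting_params()].
#' @return A `labeled_mask` with `n_instances >=` the input's.
#' @export
split_touching <- function(labeled, params = counting_params()) {
  stopifnot(inherits(labeled, "labeled_mask"))
  d <- sqrt(edt_squared(labeled$labels > 0L))
  labels <- ws_split(labeled$labels, d, params$marker_min_distance,
                     params$marker_min_prominence)
  structure(list(image_id = labeled$image_id,
                 lesion_class = labeled$lesion_class, labels = labels,
                 n_instances = attr(labels, "n_instances")),
            class = "labeled_mask")
}

#' Count lesion instances in a binary mask
#'
#' Connected-components analysis followed (when `split_enabled`) by the
#' watershed split of touching lesions.
#'
#' @param mask A [lesion_mask()].
#' @param params A [counting_params()].
#' @return Non-negative integer lesion count.
#' @export
count_lesions <- function(mask, params = counting_params()) {
  lab <- count_components(mask, params)
  if (params$split_enabled) lab <- split_touching(lab, params)
  lab$n_instances
}

#' Measure hard-exudate area
#'
#' HEs aggregate into clusters, which makes their area a more robust
#' severity metric than their count in severe disease.
#'
#' @param mask A [lesion_mask()] of class HE.
#' @return List with `area_px` (foreground pixel count) and
#'   `area_fraction` (share of the image area, in `[0, 1]`).
#' @export
measure_he_area <- function(mask) {
  stopifnot(inherits(mask, "lesion_mask"))
  px <- sum(mask$pixels)
  list(area_px = as.integer(px), area_fraction = px / length(mask$pixels))
}

#' Combine microaneurysm and hemorrhage counts into red-lesion counts
#'
#' Red lesions (RLs) are MAs and Hmas considered jointly.  The combined
#' count is the sum of the two class counts (not a count of the union
#' mask); missingness in either operand propagates.
#'
#' @param ma_count,hma_count Non-negative integer vectors, `NA` allowed.
#' @return Integer vector of RL counts.
#' @export
combine_red_lesions <- function(ma_count, hma_count) {
  as.integer(ma_count) + as.integer(hma_count)
}

#' Count lesions for every image of a dataset manifest
#'
#' Reads each annotated mask, counts MA/Hma/HE instances, derives RL
#' counts and measures HE area.  Lesion classes without a mask path stay
#' missing (`NA`), never zero.
#'
#' @param manifest A [read_manifest()] result.
#' @param params A [counting_params()].
#' @param base_dir Directory against which relative mask paths resolve;
#'   default the manifest's own directory.
#' @return A [count_table()].
#' @export
count_dataset <- function(manifest, params = counting_params(),
                          base_dir = NULL) {
  stopifnot(inherits(manifest, "dataset_manifest"))
  base_dir <- base_dir %||% attr(manifest, "base_dir") %||% "."
  n <- nrow(manifest)
  ma <- hma <- he <- area <- rep(NA_integer_, n)
  frac <- rep(NA_real_, n)
  cols <- c(MA = "ma_mask", Hma = "hma_mask", HE = "he_mask")
  for (i in seq_len(n)) {
    for (cls in names(cols)) {
      p <- manifest[[cols[[cls]]]][i]
      if (is.na(p)) next
      full <- if (grepl("^(/|[A-Za-z]:)", p)) p else file.path(base_dir, p)
      m <- read_mask(full, lesion_class = cls,
                     image_id = manifest$image_id[i])
      k <- count_lesions(m, params)
      if (cls == "MA") ma[i] <- k
      else if (cls == "Hma") hma[i] <- k
      else {
        he[i] <- k
        a <- measure_he_area(m)
        area[i] <- a$area_px
        frac[i] <- a$area_fraction
      }
    }
  }
  count_table(data.frame(
    dataset_id = manifest$dataset_id, image_id = manifest$image_id,
    grade = manifest$grade, ma_count = ma, hma_count = hma,
    rl_count = combine_red_lesions(ma, hma), he_count = he,
    he_area_px = area, he_area_fraction = frac,
    stringsAsFactors = FALSE))
}
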