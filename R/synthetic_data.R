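# Synthetic stand-ins for the study data: (a) binary masks with planted,
# optionally overlapping disk lesions plus XML ground truth, for
# validating the counting kernel; (b) multi-dataset count cohorts drawn
# from severity profiles calibrated to published per-grade means.

#' Default per-grade lesion-count severity profiles
#'
#' Target means are the published post-filter per-grade means: MA
#' 4.3 / 14.2 / 53.1 (mild / moderate / severe), Hma 8.7 / 51.1 and HE
#' 30 / 58.2 (moderate / severe).  The no-DR MA mean is negligible but
#' not zero (0.8): graded real-world no-DR images carry stray MA
#' annotations, which is what makes the published no-DR classifier
#' sensitivity imperfect.  For the same reason no-DR and mild carry an
#' identical trace Hma profile (Poisson, mean 0.35) — identical, so the
#' no-DR vs mild Hma comparison stays non-significant, yet enough that
#' mild red lesions exceed mild MAs by the published margin (4.6 vs
#' 4.3).  HE means are zero below moderate (absent by ICDR definition).
#' Counts are zero-inflated negative binomial; dispersion (NB size) is
#' 3 for MA (punctate, well segmented), 1.5 for Hma (confluence) and 0.6
#' with 20% zero inflation for HE (cluster aggregation — deliberately
#' the widest spread).  See the methods vignette for the calibration
#' rationale.
#'
#' @return Data frame with columns `grade, lesion, target_mean,
#'   dispersion, zero_inflation`, classed `severity_profiles`.
#' @export
default_severity_profiles <- function() {
  severity_profiles(data.frame(
    grade = rep(GRADE_LEVELS, each = 3),
    lesion = rep(c("MA", "Hma", "HE"), times = 4),
    target_mean = c(0.8, 0.35, 0,
                    4.3, 0.35, 0,
                    14.2, 8.7, 30,
                    53.1, 51.1, 58.2),
    dispersion = c(1, 1e6, NA,
                   3, 1e6, NA,
                   3, 1.5, 0.6,
                   3, 1.5, 0.6),
    zero_inflation = c(0, 0, 0,
                       0, 0, 0,
                       0, 0, 0.2,
                       0, 0, 0.2),
    stringsAsFactors = FALSE))
}

#' Validate a severity-profile table
#'
#' @param df Data frame with columns `grade, lesion, target_mean,
#'   dispersion` (NB size; `NA` allowed where the mean is 0) and
#'   `zero_inflation`.
#' @return `df`, classed `severity_profiles`.
#' @export
severity_profiles <- function(df) {
  need <- c("grade", "lesion", "target_mean", "dispersion",
            "zero_inflation")
  stopifnot(all(need %in% names(df)))
  stopifnot(all(df$grade %in% GRADE_LEVELS),
            all(df$lesion %in% LESION_CLASSES),
            all(df$target_mean >= 0),
            all(is.na(df$dispersion) | df$dispersion > 0),
            all(df$zero_inflation >= 0 & df$zero_inflation < 1))
  if (any(df$target_mean > 0 & is.na(df$dispersion)))
    stop("dispersion required wherever target_mean > 0")
  for (le in c("MA", "Hma")) {
    m <- df$target_mean[match(paste(GRADE_LEVELS, le),
                              paste(df$grade, df$lesion))]
    if (any(diff(m[!is.na(m)]) < 0))
      stop("profile means for ", le, " must be non-decreasing in grade")
  }
  structure(df, class = c("severity_profiles", "data.frame"))
}

profile_lookup <- function(profiles, grade, lesion) {
  i <- which(profiles$grade == grade & profiles$lesion == lesion)
  if (length(i) != 1) stop("no unique profile for (", grade, ", ",
                           lesion, ")")
  profiles[i, ]
}

draw_counts <- function(profiles, grade, lesion, n) {
  pr <- profile_lookup(profiles, grade, lesion)
  if (pr$target_mean == 0) return(rep(0L, n))
  mu_pos <- pr$target_mean / (1 - pr$zero_inflation)
  x <- rnbinom(n, mu = mu_pos, size = pr$dispersion)
  if (pr$zero_inflation > 0) x[runif(n) < pr$zero_inflation] <- 0L
  as.integer(x)
}

#' Cohort specification for the synthetic multi-dataset generator
#'
#' Defaults emulate the four-dataset study structure: sizes 144, 586,
#' 1395 and 50; grade mixtures that concentrate mass on moderate NPDR,
#' with the smallest dataset restricted to moderate/severe; an 11%
#' planted-outlier rate (matching the published 2445 -> 2175 shrink on
#' filtering).
#'
#' @param sizes Named integer vector of images per dataset.
#' @param grade_mix Matrix (datasets x 4 grades) of grade proportions,
#'   rows summing to 1.
#' @param annotated Named list: lesion classes annotated per dataset.
#' @param outlier_rate Fraction of records planted as extreme
#'   (unreliable) images; their MA/Hma counts are redrawn at 5-8 times
#'   the stratum mean.
#' @param image_dim `c(height, width)` of the nominal raster, pixels.
#' @param he_lesion_area Mean area (pixels) of one hard exudate, used to
#'   synthesize HE area from HE counts.
#' @param overlap_fraction Share of planted lesions that touch a
#'   neighbour when masks are written ([generate_dataset()]).
#' @param seed Optional integer seed; `NULL` uses the current RNG state.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(sizes = c(dataset1 = 144, dataset2 = 586,
                                  dataset3 = 1395, dataset4 = 50),
                        grade_mix = NULL, annotated = NULL,
                        outlier_rate = 0.11,
                        image_dim = c(512, 512), he_lesion_area = 300,
                        overlap_fraction = 0.15, seed = NULL) {
  stopifnot(all(sizes >= 0), outlier_rate >= 0, outlier_rate < 1,
            length(image_dim) == 2, all(image_dim >= 16))
  if (is.null(names(sizes))) names(sizes) <- paste0("dataset",
                                                    seq_along(sizes))
  if (is.null(grade_mix)) {
    grade_mix <- rbind(c(0.25, 0.25, 0.35, 0.15),
                       c(0.00, 0.20, 0.60, 0.20),
                       c(0.10, 0.25, 0.50, 0.15),
                       c(0.00, 0.00, 0.60, 0.40))
    grade_mix <- grade_mix[rep_len(seq_len(4), length(sizes)), ,
                           drop = FALSE]
  }
  grade_mix <- as.matrix(grade_mix)
  colnames(grade_mix) <- GRADE_LEVELS
  rownames(grade_mix) <- names(sizes)
  if (any(abs(rowSums(grade_mix) - 1) > 1e-8))
    stop("grade mixtures must sum to 1 per dataset")
  if (is.null(annotated))
    annotated <- setNames(rep(list(LESION_CLASSES), length(sizes)),
                          names(sizes))
  structure(list(sizes = sizes, grade_mix = grade_mix,
                 annotated = annotated, outlier_rate = outlier_rate,
                 image_dim = as.integer(image_dim),
                 he_lesion_area = he_lesion_area,
                 overlap_fraction = overlap_fraction, seed = seed),
            class = "cohort_spec")
}

#' Generate a multi-dataset count table with planted outliers
#'
#' Counts are drawn independently per lesion class from the stratum's
#' profile; RL = MA + Hma; HE area is synthesized from the HE count via
#' a gamma model of per-lesion area.  A fraction `outlier_rate` of
#' records (in strata where MA or Hma has a mean of at least 2) is
#' replanted with MA/Hma counts at 5-8 times the stratum mean,
#' emulating unreliable images that the IQR filter is meant to remove.
#'
#' @param profiles A [severity_profiles()] table.
#' @param cohort A [cohort_spec()].
#' @return List with `table` (a [count_table()]) and `outliers` (data
#'   frame of the planted outlier record ids — the filtering ground
#'   truth).
#' @export
generate_count_table <- function(profiles = default_severity_profiles(),
                                 cohort = cohort_spec()) {
  if (!is.null(cohort$seed)) set.seed(cohort$seed)
  rows <- list()
  outliers <- list()
  for (d in names(cohort$sizes)) {
    n <- cohort$sizes[[d]]
    if (n == 0) next
    grades <- sample(GRADE_LEVELS, n, replace = TRUE,
                     prob = cohort$grade_mix[d, ])
    ann <- cohort$annotated[[d]]
    df <- data.frame(dataset_id = d,
                     image_id = sprintf("%s_img%05d", d, seq_len(n)),
                     grade = grades,
                     ma_count = NA_integer_, hma_count = NA_integer_,
                     rl_count = NA_integer_, he_count = NA_integer_,
                     he_area_px = NA_integer_,
                     he_area_fraction = NA_real_,
                     stringsAsFactors = FALSE)
    for (g in unique(grades)) {
      sel <- which(grades == g)
      if ("MA" %in% ann) df$ma_count[sel] <-
          draw_counts(profiles, g, "MA", length(sel))
      if ("Hma" %in% ann) df$hma_count[sel] <-
          draw_counts(profiles, g, "Hma", length(sel))
      if ("HE" %in% ann) df$he_count[sel] <-
          draw_counts(profiles, g, "HE", length(sel))
      # plant unreliable records: extreme MA/Hma counts.  Only strata
      # with a mean of at least 2 are eligible — five- to eight-fold a
      # near-zero mean is not a "heavy" count and would be
      # indistinguishable from ordinary annotation noise.
      mu_ma <- profile_lookup(profiles, g, "MA")$target_mean
      mu_hma <- profile_lookup(profiles, g, "Hma")$target_mean
      if (cohort$outlier_rate > 0 && (mu_ma >= 2 || mu_hma >= 2)) {
        out_sel <- sel[runif(length(sel)) < cohort$outlier_rate]
        if (length(out_sel) > 0) {
          if ("MA" %in% ann && mu_ma >= 2)
            df$ma_count[out_sel] <-
              as.integer(round(runif(length(out_sel), 5, 8) * mu_ma))
          if ("Hma" %in% ann && mu_hma >= 2)
            df$hma_count[out_sel] <-
              as.integer(round(runif(length(out_sel), 5, 8) * mu_hma))
          outliers[[length(outliers) + 1L]] <- data.frame(
            dataset_id = d, image_id = df$image_id[out_sel],
            grade = g, stringsAsFactors = FALSE)
        }
      }
    }
    df$rl_count <- combine_red_lesions(df$ma_count, df$hma_count)
    he <- df$he_count
    pos <- !is.na(he) & he > 0
    area <- ifelse(is.na(he), NA_real_, 0)
    if (any(pos))
      area[pos] <- round(rgamma(sum(pos), shape = 4 * he[pos],
                                scale = cohort$he_lesion_area / 4))
    df$he_area_px <- as.integer(area)
    df$he_area_fraction <- area / prod(cohort$image_dim)
    rows[[length(rows) + 1L]] <- df
  }
  if (length(rows) == 0) {
    rows <- list(data.frame(
      dataset_id = character(), image_id = character(),
      grade = character(), ma_count = integer(), hma_count = integer(),
      rl_count = integer(), he_count = integer(),
      he_area_px = integer(), he_area_fraction = numeric()))
  }
  table <- count_table(do.call(rbind, rows))
  outliers <- if (length(outliers)) do.call(rbind, outliers) else
    data.frame(dataset_id = character(), image_id = character(),
               grade = character())
  list(table = table, outliers = outliers)
}

# mask generation -----------------------------------------------------

CLASS_RADII <- list(MA = c(2, 5), Hma = c(4, 12), HE = c(5, 15))

#' Specification of one planted-lesion mask
#'
#' @param n_lesions Number of lesions to plant.
#' @param height,width Raster dimensions, pixels.
#' @param lesion_class Lesion class; sets the default radius range (MA
#'   2-5 px, Hma 4-12 px, HE 5-15 px — plausible relative scales).
#' @param radius_range `c(min, max)` disk radius in pixels.
#' @param overlap_fraction Share of lesions planted to intersect a
#'   neighbour, in `[0, 1]`; `ceiling(overlap_fraction * n_lesions)`
#'   lesions are attached to an already-placed anchor.
#' @param min_center_separation Minimum distance between the centers of
#'   an overlapping pair, pixels.  Default 8: comfortably above the
#'   watershed's default `marker_min_distance = 5`, because the discrete
#'   distance-transform maxima can sit up to a pixel inside the true
#'   centers and markers closer than the minimum distance are merged.
#' @param seed Optional integer seed.
#' @return An object of class `mask_spec`.
#' @export
mask_spec <- function(n_lesions, height = 256, width = 256,
                      lesion_class = "MA", radius_range = NULL,
                      overlap_fraction = 0,
                      min_center_separation = 8, seed = NULL) {
  lesion_class <- match.arg(lesion_class, LESION_CLASSES)
  radius_range <- radius_range %||% CLASS_RADII[[lesion_class]]
  stopifnot(n_lesions >= 0, height > 0, width > 0,
            length(radius_range) == 2, radius_range[1] >= 1,
            radius_range[2] >= radius_range[1],
            overlap_fraction >= 0, overlap_fraction <= 1,
            min_center_separation >= 1)
  structure(list(n_lesions = as.integer(n_lesions),
                 height = as.integer(height), width = as.integer(width),
                 lesion_class = lesion_class, radius_range = radius_range,
                 overlap_fraction = overlap_fraction,
                 min_center_separation = min_center_separation,
                 seed = seed),
            class = "mask_spec")
}

paint_disk <- function(px, cy, cx, r) {
  # cy, cx are 0-based centers; matrix indices are 1-based
  rr <- max(0, floor(cy - r)):min(nrow(px) - 1, ceiling(cy + r))
  cc <- max(0, floor(cx - r)):min(ncol(px) - 1, ceiling(cx + r))
  d2 <- outer((rr - cy)^2, (cc - cx)^2, "+")
  px[rr + 1, cc + 1][d2 <= r^2] <- TRUE
  px
}

#' Generate a binary mask with planted disk lesions and ground truth
#'
#' Lesions are filled disks at uniform-random in-bounds centers.
#' Non-overlapping lesions are kept strictly separated (no shared or
#' 8-adjacent pixels); each overlapping lesion is placed to intersect a
#' previously placed anchor, with center separation between
#' `min_center_separation` and the sum of radii minus one, both centers
#' outside the partner disk, and each distance-transform peak at least
#' 2 px above the valley joining the pair — i.e. planted overlaps are
#' resolvable by construction, emulating discernible touching lesions
#' rather than indistinguishable confluence.
#'
#' @param spec A [mask_spec()].
#' @return List with `mask` (a [lesion_mask()]), `mapping` (a
#'   [lesion_mapping()] listing every planted lesion's class and center;
#'   x = column, y = row, 0-based) and `radii` (the planted disk radii,
#'   pixels, in planting order).
#' @export
generate_mask <- function(spec) {
  stopifnot(inherits(spec, "mask_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  H <- spec$height; W <- spec$width
  n <- spec$n_lesions
  rmax <- spec$radius_range[2]
  if (n * pi * rmax^2 > 0.5 * H * W)
    stop("infeasible packing: ", n, " lesions of radius up to ", rmax,
         " cannot fit a ", H, "x", W, " raster")
  # with overlap_fraction 1 the first lesion is still placed freely and
  # becomes part of a pair when its neighbour attaches to it
  n_over <- min(ceiling(spec$overlap_fraction * n), max(0L, n - 1L))
  n_free <- n - n_over
  # Overlapping pairs must be resolvable: each lesion's distance peak
  # (its radius) must rise >= 2 px above the connecting valley, whose
  # depth is the common half-chord v; v = m at center distance
  # d = sqrt(ra^2 - m^2) + sqrt(rb^2 - m^2), padded by a further 0.5 px
  # against discretization.  With equal radii this is feasible only for
  # r >= 4.49, so when overlaps are requested all radii are drawn above
  # that floor.
  r_floor <- if (n_over > 0) max(spec$radius_range[1], 4.49) else
    spec$radius_range[1]
  if (r_floor > spec$radius_range[2])
    stop("infeasible packing: radius_range max ",
         spec$radius_range[2], " is too small for resolvable ",
         "overlapping lesions (needs >= 3.92)")
  for (attempt in seq_len(20)) {
    cy <- cx <- rad <- numeric(0)
    anchor_used <- logical(0)
    ok <- TRUE
    draw_center <- function(r) c(runif(1, r + 1, H - r - 2),
                                 runif(1, r + 1, W - r - 2))
    for (i in seq_len(n_free)) {
      r <- runif(1, r_floor, spec$radius_range[2])
      placed <- FALSE
      for (try in seq_len(500)) {
        p <- draw_center(r)
        if (all((p[1] - cy)^2 + (p[2] - cx)^2 >= (r + rad + 2)^2)) {
          cy <- c(cy, p[1]); cx <- c(cx, p[2]); rad <- c(rad, r)
          anchor_used <- c(anchor_used, FALSE)
          placed <- TRUE
          break
        }
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (ok) for (i in seq_len(n_over)) {
      placed <- FALSE
      for (try in seq_len(500)) {
        cand <- if (any(!anchor_used)) which(!anchor_used) else
          seq_along(rad)
        a <- if (length(cand) == 1) cand else sample(cand, 1)
        ra <- rad[a]
        r_lo <- max(r_floor, spec$min_center_separation + 1 - ra)
        if (r_lo > spec$radius_range[2]) next
        r <- runif(1, r_lo, spec$radius_range[2])
        m <- min(ra, r) - 2   # deepest admissible valley
        d_lo <- max(spec$min_center_separation, max(ra, r) + 1,
                    sqrt(ra^2 - m^2) + sqrt(r^2 - m^2) + 0.5)
        d_hi <- ra + r - 1
        if (d_lo > d_hi) next
        d <- runif(1, d_lo, d_hi)
        th <- runif(1, 0, 2 * pi)
        p <- c(cy[a] + d * sin(th), cx[a] + d * cos(th))
        if (p[1] < r + 1 || p[1] > H - r - 2 ||
            p[2] < r + 1 || p[2] > W - r - 2) next
        others <- setdiff(seq_along(rad), a)
        if (length(others) > 0 &&
            any((p[1] - cy[others])^2 + (p[2] - cx[others])^2 <
                (r + rad[others] + 2)^2)) next
        cy <- c(cy, p[1]); cx <- c(cx, p[2]); rad <- c(rad, r)
        anchor_used[a] <- TRUE
        anchor_used <- c(anchor_used, TRUE)
        placed <- TRUE
        break
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (ok) {
      px <- matrix(FALSE, H, W)
      for (i in seq_along(rad)) px <- paint_disk(px, cy[i], cx[i], rad[i])
      mask <- lesion_mask(px, image_id = "synthetic",
                          lesion_class = spec$lesion_class)
      mapping <- lesion_mapping(
        "synthetic",
        data.frame(lesion_class = rep(spec$lesion_class, length(rad)),
                   x = cx, y = cy), width = W, height = H)
      return(list(mask = mask, mapping = mapping, radii = rad))
    }
  }
  stop("infeasible packing: could not place ", n, " lesions (radii ",
       spec$radius_range[1], "-", spec$radius_range[2], ", overlap ",
       spec$overlap_fraction, ") in a ", H, "x", W, " raster")
}

#' Write a complete synthetic dataset to disk
#'
#' Draws a count cohort from the profiles, plants the drawn number of
#' lesions per image and class as disk masks, writes PNG masks, one XML
#' ground-truth mapping per image, and a manifest CSV — a complete
#' runnable input for the full pipeline.  Lesion counts are capped at
#' the raster's packing capacity (with a message) so extreme planted
#' outliers stay placeable.
#'
#' @param cohort A [cohort_spec()] (use small sizes; every image writes
#'   up to three PNG files).
#' @param out_dir Output directory (created if absent).
#' @param profiles A [severity_profiles()] table.
#' @return Path of the written manifest CSV, invisibly.
#' @export
generate_dataset <- function(cohort, out_dir,
                             profiles = default_severity_profiles()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  gen <- generate_count_table(profiles, cohort)
  tab <- gen$table
  H <- cohort$image_dim[1]; W <- cohort$image_dim[2]
  cols <- c(MA = "ma_count", Hma = "hma_count", HE = "he_count")
  man <- data.frame(dataset_id = tab$dataset_id, image_id = tab$image_id,
                    grade = as.character(tab$grade),
                    ma_mask = NA_character_, hma_mask = NA_character_,
                    he_mask = NA_character_, stringsAsFactors = FALSE)
  mcols <- c(MA = "ma_mask", Hma = "hma_mask", HE = "he_mask")
  for (i in seq_len(nrow(tab))) {
    entries <- list()
    for (cls in LESION_CLASSES) {
      k <- tab[[cols[[cls]]]][i]
      if (is.na(k)) next
      cap <- floor(0.3 * H * W / (pi * CLASS_RADII[[cls]][2]^2))
      if (k > cap) {
        message("capping ", cls, " count ", k, " at packing capacity ",
                cap, " for image ", tab$image_id[i])
        k <- cap
      }
      g <- generate_mask(mask_spec(k, height = H, width = W,
                                   lesion_class = cls,
                                   overlap_fraction =
                                     cohort$overlap_fraction))
      fn <- sprintf("%s_%s.png", tab$image_id[i], cls)
      write_mask(g$mask, file.path(out_dir, fn))
      man[[mcols[[cls]]]][i] <- fn
      entries[[cls]] <- g$mapping$entries
    }
    mapping <- lesion_mapping(tab$image_id[i], do.call(rbind, entries),
                              width = W, height = H)
    write_lesion_xml(mapping,
                     file.path(out_dir,
                               sprintf("%s.xml", tab$image_id[i])))
  }
  path <- file.path(out_dir, "manifest.csv")
  write_manifest(man, path)
  invisible(path)
}
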