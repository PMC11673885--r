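# Reading and writing lesion masks, lesion-mapping XML, dataset
# manifests and count tables.
#
# File conventions:
#   * masks: PNG, one raster per lesion class per image, filename
#     <image_id>_<MA|Hma|HE>.png, foreground = nonzero;
#   * manifest CSV header: dataset_id,image_id,grade,ma_mask,hma_mask,
#     he_mask (empty cell = lesion class not annotated for that image);
#   * counts CSV header: dataset_id,image_id,grade,ma_count,hma_count,
#     rl_count,he_count,he_area_px,he_area_fraction.

#' Construct a lesion mask
#'
#' A lesion mask is one binary raster holding every annotated lesion of
#' one class (MA, Hma or HE) for one fundus image.
#'
#' @param pixels Logical matrix; `TRUE` marks lesion pixels.
#' @param image_id Image identifier.
#' @param lesion_class One of `"MA"`, `"Hma"`, `"HE"`.  `"RL"` is a
#'   derived class (MA + Hma) and is never stored as a mask.
#' @return An object of class `lesion_mask`.
#' @export
lesion_mask <- function(pixels, image_id = "img", lesion_class = "MA") {
  if (is.numeric(pixels)) {
    storage.mode(pixels) <- "double"
    pixels <- pixels != 0
  }
  if (!is.matrix(pixels) || !is.logical(pixels))
    stop("pixels must be a logical (or 0/1 numeric) matrix")
  if (length(pixels) == 0L) stop("zero-area mask raster")
  lesion_class <- match.arg(lesion_class, LESION_CLASSES)
  structure(list(image_id = as.character(image_id),
                 lesion_class = lesion_class, pixels = pixels),
            class = "lesion_mask")
}

#' @export
print.lesion_mask <- function(x, ...) {
  cat(sprintf("<lesion_mask> image %s, class %s, %d x %d, %d foreground px\n",
              x$image_id, x$lesion_class, nrow(x$pixels), ncol(x$pixels),
              sum(x$pixels)))
  invisible(x)
}

#' @export
dim.lesion_mask <- function(x) dim(x$pixels)

#' Read a binary lesion mask from a PNG file
#'
#' Grayscale rasters are binarized at intensity > 127 (of 255); RGB(A)
#' rasters are collapsed by any-color-channel-nonzero.  Masks are
#' nominally binary already; the threshold only guards against
#' antialiased exports.
#'
#' @param path Path to a PNG file.
#' @param lesion_class Lesion class stored in the mask.
#' @param image_id Image identifier; default is the file name stripped
#'   of its `_<class>.png` suffix.
#' @return A [lesion_mask()].
#' @export
read_mask <- function(path, lesion_class = "MA", image_id = NULL) {
  if (!file.exists(path)) stop("cannot read mask file: ", path)
  img <- tryCatch(png::readPNG(path),
                  error = function(e) stop("cannot decode PNG '", path,
                                           "': ", conditionMessage(e)))
  if (is.null(image_id)) {
    image_id <- sub("_(MA|Hma|HE)$", "",
                    tools::file_path_sans_ext(basename(path)))
  }
  if (length(dim(img)) == 3L) {
    nch <- min(dim(img)[3], 3L)  # ignore alpha
    px <- apply(img[, , seq_len(nch), drop = FALSE], c(1, 2),
                function(v) any(v > 0))
  } else {
    px <- img > 127 / 255
  }
  lesion_mask(px, image_id = image_id, lesion_class = lesion_class)
}

#' Write a lesion mask as a grayscale PNG (0 background, 255 foreground)
#'
#' @param mask A [lesion_mask()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "lesion_mask"))
  png::writePNG(ifelse(mask$pixels, 1, 0), target = path)
  invisible(path)
}

# lesion-mapping XML --------------------------------------------------

#' Construct a lesion mapping (per-lesion ground truth)
#'
#' @param image_id Image identifier.
#' @param entries Data frame with columns `lesion_class`, `x` (column
#'   coordinate, pixels) and `y` (row coordinate, pixels); 0-based,
#'   origin at the top-left corner.  May have zero rows.
#' @param width,height Image dimensions in pixels (used for bounds
#'   validation); may be `NA` when unknown.
#' @return An object of class `lesion_mapping`.
#' @export
lesion_mapping <- function(image_id, entries = NULL, width = NA_integer_,
                           height = NA_integer_) {
  if (is.null(entries))
    entries <- data.frame(lesion_class = character(), x = numeric(),
                          y = numeric())
  stopifnot(all(c("lesion_class", "x", "y") %in% names(entries)))
  bad <- !(entries$lesion_class %in% LESION_CLASSES)
  if (any(bad))
    stop("unknown lesion class in mapping: ",
         paste(unique(entries$lesion_class[bad]), collapse = ", "))
  if (!is.na(width) && !is.na(height) && nrow(entries) > 0) {
    out <- entries$x < 0 | entries$x > width - 1 |
      entries$y < 0 | entries$y > height - 1
    if (any(out))
      stop("lesion centroid(s) outside image bounds at entry ",
           paste(which(out), collapse = ", "))
  }
  structure(list(image_id = as.character(image_id), entries = entries,
                 width = width, height = height),
            class = "lesion_mapping")
}

#' Read per-lesion ground-truth annotations from XML
#'
#' Expected schema (this package's own; centroids 0-based, x = column,
#' y = row):
#' `<image id="..." width="512" height="512">`
#' `<lesion class="MA" x="12.0" y="30.5"/>...</image>`
#'
#' @param path Path to an XML file.
#' @return A [lesion_mapping()].  The per-class entry counts are the
#'   ground-truth lesion counts used to validate automated counting.
#' @export
read_lesion_xml <- function(path) {
  if (!file.exists(path)) stop("cannot read XML file: ", path)
  doc <- xml2::read_xml(path)
  root <- xml2::xml_name(doc)
  if (root != "image") stop("expected <image> root element, found <",
                            root, "> in ", path)
  id <- xml2::xml_attr(doc, "id")
  w <- suppressWarnings(as.integer(xml2::xml_attr(doc, "width")))
  h <- suppressWarnings(as.integer(xml2::xml_attr(doc, "height")))
  nodes <- xml2::xml_find_all(doc, "./lesion")
  entries <- data.frame(
    lesion_class = xml2::xml_attr(nodes, "class"),
    x = as.numeric(xml2::xml_attr(nodes, "x")),
    y = as.numeric(xml2::xml_attr(nodes, "y")))
  lesion_mapping(id, entries, width = w, height = h)
}

#' Write a lesion mapping as XML
#'
#' @param mapping A [lesion_mapping()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lesion_xml <- function(mapping, path) {
  stopifnot(inherits(mapping, "lesion_mapping"))
  doc <- xml2::xml_new_root("image", id = mapping$image_id)
  if (!is.na(mapping$width)) {
    xml2::xml_set_attr(doc, "width", mapping$width)
    xml2::xml_set_attr(doc, "height", mapping$height)
  }
  e <- mapping$entries
  for (i in seq_len(nrow(e))) {
    xml2::xml_add_child(doc, "lesion", class = e$lesion_class[i],
                        x = format(e$x[i]), y = format(e$y[i]))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

# manifests -----------------------------------------------------------

#' Read a dataset manifest CSV
#'
#' The manifest maps each image to its dataset, ICDR grade and
#' per-lesion-class mask files.  An empty mask cell means the class is
#' not annotated for that image (a missing count downstream, never 0).
#'
#' @param path Path to a CSV with header
#'   `dataset_id,image_id,grade,ma_mask,hma_mask,he_mask`.
#' @return Data frame of class `dataset_manifest`; mask paths are kept
#'   as written (resolve them against `dirname(path)`, recorded in the
#'   `base_dir` attribute).
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("cannot read manifest: ", path)
  df <- read.csv(path, colClasses = "character")
  if (!identical(names(df), MANIFEST_COLUMNS))
    stop("manifest header must be exactly: ",
         paste(MANIFEST_COLUMNS, collapse = ","))
  bad <- !(df$grade %in% GRADE_LEVELS)
  if (any(bad)) {
    i <- which(bad)[1]
    stop("unknown grade label '", df$grade[i], "' in manifest row ", i,
         " (PDR and other labels outside the four ICDR NPDR levels are",
         " not supported)")
  }
  key <- paste(df$dataset_id, df$image_id, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (dataset_id, image_id): ",
         paste(unique(sub("\r", "/", key[duplicated(key)])), collapse = ", "))
  for (col in c("ma_mask", "hma_mask", "he_mask"))
    df[[col]][!nzchar(df[[col]])] <- NA_character_
  nomask <- is.na(df$ma_mask) & is.na(df$hma_mask) & is.na(df$he_mask)
  if (any(nomask))
    stop("manifest row(s) without any mask path: ",
         paste(which(nomask), collapse = ", "))
  df$grade <- as_severity_grade(df$grade)
  structure(df, class = c("dataset_manifest", "data.frame"),
            base_dir = dirname(path))
}

#' Write a dataset manifest CSV
#'
#' @param manifest Data frame with the manifest columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  df <- as.data.frame(manifest)[, MANIFEST_COLUMNS]
  df$grade <- as.character(df$grade)
  write.csv(df, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

# count tables --------------------------------------------------------

#' Validate and classify a per-image lesion-count table
#'
#' The central row type of the pipeline: one row per image with MA, Hma,
#' RL and HE counts, HE area, ICDR grade and dataset provenance.
#' Missing values mean "not annotated", never zero.
#'
#' @param df Data frame with columns `dataset_id, image_id, grade,
#'   ma_count, hma_count, rl_count, he_count, he_area_px,
#'   he_area_fraction`.
#' @return `df` with grade as an ordered factor, classed `count_table`.
#' @export
count_table <- function(df) {
  miss <- setdiff(COUNT_COLUMNS, names(df))
  if (length(miss) > 0)
    stop("count table lacks column(s): ", paste(miss, collapse = ", "))
  df <- as.data.frame(df)[, COUNT_COLUMNS]
  df$grade <- as_severity_grade(df$grade)
  for (col in c("ma_count", "hma_count", "rl_count", "he_count",
                "he_area_px")) {
    v <- df[[col]]
    if (any(!is.na(v) & v < 0)) stop("negative values in ", col)
  }
  both <- !is.na(df$ma_count) & !is.na(df$hma_count) & !is.na(df$rl_count)
  if (any(df$rl_count[both] != df$ma_count[both] + df$hma_count[both]))
    stop("integrity error: rl_count != ma_count + hma_count in row(s) ",
         paste(which(both)[df$rl_count[both] !=
                           df$ma_count[both] + df$hma_count[both]],
               collapse = ", "))
  class(df) <- c("count_table", "data.frame")
  df
}

#' Write a count table to CSV
#'
#' Rows are written in deterministic `(dataset_id, image_id)` order;
#' missing values as empty cells.  Refuses tables violating the
#' red-lesion identity `rl = ma + hma`.
#'
#' @param table A [count_table()] (or coercible data frame).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(table, path) {
  df <- count_table(table)  # re-validate: enforces the RL identity
  df <- df[order(df$dataset_id, df$image_id), ]
  df$grade <- as.character(df$grade)
  ok <- tryCatch({
    write.csv(df, path, row.names = FALSE, na = "", quote = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write counts CSV to ", path)
  invisible(path)
}

#' Read a count table from CSV
#'
#' @param path Path to a CSV written by [write_counts()].
#' @return A [count_table()].
#' @export
read_counts <- function(path) {
  if (!file.exists(path)) stop("cannot read counts CSV: ", path)
  df <- read.csv(path, colClasses = c(dataset_id = "character",
                                      image_id = "character",
                                      grade = "character"))
  for (col in c("ma_count", "hma_count", "rl_count", "he_count",
                "he_area_px"))
    df[[col]] <- as.integer(df[[col]])
  df$he_area_fraction <- as.numeric(df$he_area_fraction)
  count_table(df)
}
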