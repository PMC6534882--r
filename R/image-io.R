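# Image and label containers, standard-format I/O, ROI handling and
# intensity normalization.
#
# Conventions used throughout the package: images are numeric matrices
# indexed [row, col] with the origin at the top-left; public bounding boxes
# are 0-based and half-open. Point coordinates inside contours are
# (row, col) with 1-based continuous pixel-center positions.

#' Grayscale image
#'
#' Thin S3 wrapper around a numeric matrix of intensities. Intensities are
#' arbitrary finite values on load and are mapped to \[0, 1\] by
#' [normalize_intensity()]; every routine downstream of normalization assumes
#' the \[0, 1\] working range.
#'
#' @param pixels numeric matrix (rows x cols) of finite intensities.
#' @param spacing physical size of a pixel (isotropic), default 1.
#' @return a `gray_image` object (a matrix with class and `spacing` attribute).
#' @export
gray_image <- function(pixels, spacing = 1) {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "double"
  if (length(pixels) < 4L) stop("gray_image needs at least 4 pixels")
  if (!all(is.finite(pixels))) stop("gray_image: all intensities must be finite")
  structure(pixels, spacing = spacing, class = c("gray_image", "matrix", "array"))
}

#' Label image
#'
#' Integer-valued matrix of region labels; 0 is background.
#'
#' @param labels matrix of nonnegative integers.
#' @return a `label_image` object.
#' @export
label_image <- function(labels) {
  labels <- as.matrix(labels)
  if (any(labels < 0) || any(labels != round(labels)))
    stop("label_image: labels must be nonnegative integers")
  storage.mode(labels) <- "integer"
  structure(labels, class = c("label_image", "matrix", "array"))
}

#' Atlas: a paired intensity image and reference label
#'
#' @param intensity a [gray_image()].
#' @param label a [label_image()] of the same shape.
#' @param id identifier string.
#' @return an `atlas` object (list with `intensity`, `label`, `id`).
#' @export
atlas <- function(intensity, label, id = "atlas") {
  if (!identical(dim(intensity), dim(label)))
    stop("atlas: intensity and label shapes differ")
  structure(list(intensity = intensity, label = label, id = as.character(id)),
            class = "atlas")
}

#' Rectangular region of interest
#'
#' Bounds are 0-based and half-open: rows `[row_min, row_max)`, columns
#' `[col_min, col_max)`, matching the smallest rectangle that contains all
#' tissue of interest.
#'
#' @param row_min,row_max,col_min,col_max integer bounds, 0-based half-open.
#' @return a `roi_box` object.
#' @export
roi_box <- function(row_min, row_max, col_min, col_max) {
  stopifnot(row_min >= 0, col_min >= 0, row_min < row_max, col_min < col_max)
  structure(list(row_min = as.integer(row_min), row_max = as.integer(row_max),
                 col_min = as.integer(col_min), col_max = as.integer(col_max)),
            class = "roi_box")
}

#' 1-based R index vectors for a ROI box
#' @param box a [roi_box()].
#' @return list with integer vectors `rows` and `cols`.
#' @export
roi_indices <- function(box) {
  list(rows = (box$row_min + 1L):box$row_max,
       cols = (box$col_min + 1L):box$col_max)
}

# ---------------------------------------------------------------------------
# Fixture raster format: a plain-text PGM-style file.  Intensity rasters use
# magic "F2" with full-precision floats (so write -> read round trips are
# bit-exact); label rasters are standard ASCII PGM ("P2").

#' Write a grayscale image in the text fixture format
#' @param img a [gray_image()] or numeric matrix.
#' @param path output file path.
#' @export
write_fixture_image <- function(img, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("F2", paste(ncol(img), nrow(img))), con)
  writeLines(apply(unclass(img), 1L, function(r)
    paste(sprintf("%.17g", r), collapse = " ")), con)
  invisible(path)
}

#' Read a grayscale image from the text fixture format
#' @param path file path.
#' @return a [gray_image()].
#' @export
read_fixture_image <- function(path) {
  lines <- readLines(path)
  if (lines[1L] != "F2") stop("not a fixture intensity raster (missing F2 magic): ", path)
  dims <- as.integer(strsplit(trimws(lines[2L]), "\\s+")[[1L]])
  vals <- as.numeric(unlist(strsplit(trimws(lines[-(1:2)]), "\\s+")))
  if (length(vals) != dims[1L] * dims[2L]) stop("corrupt fixture raster: ", path)
  gray_image(matrix(vals, nrow = dims[2L], ncol = dims[1L], byrow = TRUE))
}

#' Write a label image as ASCII PGM (P2)
#' @param label a [label_image()].
#' @param path output file path.
#' @export
write_fixture_label <- function(label, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(label), nrow(label)), as.character(max(1L, max(label)))), con)
  writeLines(apply(unclass(label), 1L, paste, collapse = " "), con)
  invisible(path)
}

#' Read a label image from ASCII PGM (P2)
#' @param path file path.
#' @return a [label_image()].
#' @export
read_fixture_label <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  if (lines[1L] != "P2") stop("not an ASCII PGM label raster: ", path)
  dims <- as.integer(strsplit(trimws(lines[2L]), "\\s+")[[1L]])
  vals <- as.integer(unlist(strsplit(trimws(lines[-(1:3)]), "\\s+")))
  label_image(matrix(vals, nrow = dims[2L], ncol = dims[1L], byrow = TRUE))
}

# ---------------------------------------------------------------------------

#' Load a volume or slice as grayscale images
#'
#' Reads NIfTI volumes (`.nii`, `.nii.gz`) slice-wise along the third axis in
#' axial order, or a single fixture-format raster. Optionally pairs each slice
#' with the matching slice of a label volume. Intensities are returned as
#' stored — not yet normalized.
#'
#' @param path file path (NIfTI or `F2` fixture raster).
#' @param slice_index integer slice number (1-based) or `"all"`.
#' @param label_path optional path to a label volume/raster of the same shape.
#' @return list of `list(image = gray_image, label = label_image or NULL)`.
#' @export
load_volume <- function(path, slice_index = "all", label_path = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  read_gray <- function(p) {
    if (grepl("\\.nii(\\.gz)?$", p)) {
      arr <- as.array(RNifti::readNifti(p))
      if (length(dim(arr)) == 2L) dim(arr) <- c(dim(arr), 1L)
      lapply(seq_len(dim(arr)[3L]), function(k) arr[, , k])
    } else {
      list(unclass(read_fixture_image(p)))
    }
  }
  read_lab <- function(p) {
    if (grepl("\\.nii(\\.gz)?$", p)) {
      arr <- as.array(RNifti::readNifti(p))
      if (length(dim(arr)) == 2L) dim(arr) <- c(dim(arr), 1L)
      lapply(seq_len(dim(arr)[3L]), function(k) round(arr[, , k]))
    } else {
      list(unclass(read_fixture_label(p)))
    }
  }
  slices <- read_gray(path)
  labels <- if (!is.null(label_path)) read_lab(label_path) else NULL
  n <- length(slices)
  idx <- if (identical(slice_index, "all")) seq_len(n) else as.integer(slice_index)
  if (any(idx < 1L | idx > n))
    stop("slice_index out of range: volume has ", n, " slice(s)")
  lapply(idx, function(k) {
    list(image = gray_image(slices[[k]]),
         label = if (is.null(labels)) NULL else label_image(labels[[k]]))
  })
}

#' Write a volume (stack of slices) to NIfTI
#' @param slices list of matrices/gray_images of equal shape.
#' @param path output `.nii` or `.nii.gz` path.
#' @export
write_volume <- function(slices, path) {
  arr <- array(0, c(dim(slices[[1L]]), length(slices)))
  for (k in seq_along(slices)) arr[, , k] <- unclass(slices[[k]])
  RNifti::writeNifti(RNifti::asNifti(arr), path)
  invisible(path)
}

#' Min-max intensity normalization
#'
#' Rescales intensities linearly to \[0, 1\]. When a ROI is given the scale
#' is taken from the ROI pixels only (so background does not dominate the
#' range) and the rescaled image is clipped to \[0, 1\] outside. A constant
#' image maps to all zeros and is flagged with attribute `constant = TRUE`.
#' The operation is idempotent.
#'
#' @param img a [gray_image()] or matrix.
#' @param roi optional [roi_box()] providing the normalization support.
#' @return a normalized [gray_image()].
#' @export
normalize_intensity <- function(img, roi = NULL) {
  m <- unclass(as.matrix(img))
  support <- if (is.null(roi)) m else {
    ix <- roi_indices(roi); m[ix$rows, ix$cols]
  }
  rng <- range(support)
  if (rng[2] - rng[1] < .EPS) {
    out <- gray_image(matrix(0, nrow(m), ncol(m)))
    attr(out, "constant") <- TRUE
    return(out)
  }
  gray_image(clamp((m - rng[1]) / (rng[2] - rng[1]), 0, 1),
             spacing = attr(img, "spacing") %||% 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Tight bounding box of the nonzero pixels
#'
#' @param label_or_mask a [label_image()], logical or numeric matrix; any
#'   nonzero entry counts as tissue.
#' @return a [roi_box()] (0-based, half-open).
#' @export
compute_roi <- function(label_or_mask) {
  m <- unclass(as.matrix(label_or_mask)) != 0
  if (!any(m)) stop("compute_roi: mask is empty")
  rows <- which(rowSums(m) > 0)
  cols <- which(colSums(m) > 0)
  roi_box(min(rows) - 1L, max(rows), min(cols) - 1L, max(cols))
}
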