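#' Construct a binary vessel mask
#'
#' A `binary_mask` is the universal container of the package: a 2-D logical
#' grid in which `TRUE` marks vessel foreground. Row 1 is the top of the
#' image and indexing is (row, column) with a 0-based coordinate convention
#' in all ROI specifications.
#'
#' @param pixels Logical matrix (or coercible 0/1 matrix); `TRUE` = vessel.
#' @param name Free-text identifier carried through the pipeline.
#' @return An object of class `binary_mask` with elements `pixels` and `name`.
#' @examples
#' m <- binary_mask(matrix(c(TRUE, FALSE, TRUE, TRUE), 2, 2), "toy")
#' mask_dim(m)
#' @export
binary_mask <- function(pixels, name = "mask") {
  if (is.numeric(pixels)) {
    storage.mode(pixels) <- "logical"
  }
  if (!is.matrix(pixels) || !is.logical(pixels)) {
    stop("`pixels` must be a logical matrix", call. = FALSE)
  }
  if (anyNA(pixels)) stop("mask pixels must be strictly binary (no NA)", call. = FALSE)
  if (nrow(pixels) < 1L || ncol(pixels) < 1L) {
    stop("mask must have height >= 1 and width >= 1", call. = FALSE)
  }
  structure(list(pixels = pixels, name = as.character(name)[1]),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<%s> '%s': %d x %d px, %d foreground (%.2f%%)\n",
              class(x)[1], x$name, d[1], d[2], sum(x$pixels),
              100 * mean(x$pixels)))
  invisible(x)
}

#' @rdname binary_mask
#' @param mask A `binary_mask`.
#' @return `mask_dim()`: integer vector `c(height, width)` in pixels.
#' @export
mask_dim <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  dim(mask$pixels)
}

#' Read a binary mask from a PNG or TIFF raster
#'
#' Multi-channel rasters are collapsed to luminance (Rec. 601 weights) before
#' thresholding; pixels strictly brighter than `threshold` become foreground.
#' HRF-style gold-standard segmentations (white vessels on black) therefore
#' load with the defaults.
#'
#' @param path Path to a PNG or TIFF file.
#' @param threshold Intensity threshold on the 0--255 scale (default 127).
#' @param name Identifier; defaults to the file name without extension.
#' @return A [binary_mask] with the raster's dimensions.
#' @export
read_mask <- function(path, threshold = 127, name = NULL) {
  if (!file.exists(path)) stop("cannot read mask: no such file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported raster format '", ext, "' (PNG or TIFF expected)", call. = FALSE)
  )
  if (length(img) == 0L || is.null(dim(img)) || any(dim(img)[1:2] == 0L)) {
    stop("zero-area image: ", path, call. = FALSE)
  }
  if (length(dim(img)) == 3L) {
    nch <- dim(img)[3]
    img <- if (nch >= 3L) {
      0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
    } else {
      img[, , 1]
    }
  }
  if (is.null(name)) name <- tools::file_path_sans_ext(basename(path))
  binary_mask(img * 255 > threshold, name = name)
}

#' Write a binary mask as an 8-bit grayscale PNG
#'
#' Foreground is written as 255, background as 0, so [read_mask()] round-trips
#' any mask bit-exactly.
#'
#' @param mask A [binary_mask].
#' @param path Output path (`.png`).
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "binary_mask"))
  png::writePNG(mask$pixels * 1.0, target = path)
  invisible(path)
}

#' Specify a region of interest
#'
#' ROIs address a `size` x `size` window of a mask, centred on a pixel.
#' Coordinates are 0-based, `(x, y)` = (column, row), top-left origin; the
#' window spans `[centre - size/2, centre + size/2)` (half-open) along each
#' axis. Circular ROIs occupy the inscribed circle of diameter `size`: a pixel
#' belongs to the circle iff its centre lies within `(size - 1)/2` of the
#' window centre.
#'
#' @param centre_x,centre_y Centre pixel (0-based column, row).
#' @param shape `"square"` or `"circle"`.
#' @param size Side length (square) or diameter (circle) in px; default 1000,
#'   the window size used for optic-disc and macular regions in
#'   high-resolution fundus work.
#' @param label One of `"optic_disc"`, `"macula"`, `"whole"`, `"custom"`.
#' @return An object of class `roi_spec`.
#' @export
roi_spec <- function(centre_x, centre_y, shape = c("square", "circle"),
                     size = 1000, label = c("custom", "optic_disc", "macula", "whole")) {
  shape <- match.arg(shape)
  label <- match.arg(label)
  size <- as.integer(size)
  if (size < 2L) stop("ROI size must be >= 2 px", call. = FALSE)
  structure(list(label = label, centre_x = as.numeric(centre_x),
                 centre_y = as.numeric(centre_y), shape = shape, size = size),
            class = "roi_spec")
}

# half-open window [start, start + size) of an ROI, 0-based
roi_window <- function(roi) {
  half <- roi$size / 2
  r0 <- floor(roi$centre_y - half)
  c0 <- floor(roi$centre_x - half)
  list(r0 = r0, c0 = c0, r1 = r0 + roi$size, c1 = c0 + roi$size)
}

#' Crop a region of interest out of a mask
#'
#' Extracts the square window addressed by `roi`; for `shape = "circle"` the
#' pixels outside the inscribed circle are forced to background, so the
#' output is still a `size` x `size` square (the corner background then
#' counts in density denominators, as it does when circular crops are padded
#' to squares for box counting).
#'
#' @param mask A [binary_mask].
#' @param roi An [roi_spec]. Its centre must lie inside the mask.
#' @param clamp If `TRUE`, a window that overruns the image edge is shifted
#'   back inside bounds (with a message); if `FALSE` (default) this is an
#'   error, because silently truncated windows are not comparable across
#'   images.
#' @return A [binary_mask] of dimensions `size` x `size`.
#' @export
crop_roi <- function(mask, roi, clamp = FALSE) {
  stopifnot(inherits(mask, "binary_mask"), inherits(roi, "roi_spec"))
  d <- dim(mask$pixels)
  if (roi$centre_y < 0 || roi$centre_y > d[1] - 1 ||
      roi$centre_x < 0 || roi$centre_x > d[2] - 1) {
    stop("ROI centre (", roi$centre_x, ", ", roi$centre_y,
         ") lies outside the image", call. = FALSE)
  }
  w <- roi_window(roi)
  if (w$r0 < 0 || w$c0 < 0 || w$r1 > d[1] || w$c1 > d[2]) {
    if (!clamp) {
      stop("ROI window [", w$c0, ",", w$c1, ") x [", w$r0, ",", w$r1,
           ") exceeds image bounds ", d[2], " x ", d[1],
           "; set clamp = TRUE to shift it inside", call. = FALSE)
    }
    if (roi$size > d[1] || roi$size > d[2]) {
      stop("ROI size ", roi$size, " exceeds image dimensions", call. = FALSE)
    }
    w$r0 <- min(max(w$r0, 0L), d[1] - roi$size)
    w$c0 <- min(max(w$c0, 0L), d[2] - roi$size)
    w$r1 <- w$r0 + roi$size
    w$c1 <- w$c0 + roi$size
    message("ROI window clamped to [", w$c0, ",", w$c1, ") x [", w$r0, ",", w$r1, ")")
  }
  sub <- mask$pixels[(w$r0 + 1):w$r1, (w$c0 + 1):w$c1, drop = FALSE]
  if (roi$shape == "circle") {
    sub <- sub & circle_membership(roi$size)
  }
  binary_mask(sub, name = paste0(mask$name, ":", roi$label, "_", roi$shape))
}

# logical size x size matrix: pixel centres within (size-1)/2 of window centre
circle_membership <- function(size) {
  ctr <- (size - 1) / 2
  idx <- seq_len(size) - 1
  dr2 <- outer((idx - ctr)^2, (idx - ctr)^2, "+")
  dr2 <= ((size - 1) / 2)^2
}

#' Read a dataset manifest
#'
#' The manifest is a plain CSV with header
#' `image,mask,group,od_x,od_y,mac_x,mac_y`: one row per eye, carrying the
#' raw-image and mask paths, the diagnostic group, and the 0-based pixel
#' coordinates of the optic-disc and macula centres (expert-annotated
#' inputs, as in the HRF database; this package does not localize them).
#'
#' @param path CSV file path.
#' @param groups Allowed group labels; defaults to the three study groups
#'   `H` (healthy), `G` (glaucoma), `DR` (diabetic retinopathy).
#' @param roi_size,roi_shape Defaults used to build the per-record
#'   [roi_spec]s (1000-px squares).
#' @return A data frame of class `dataset_manifest` with one row per record.
#' @export
read_manifest <- function(path, groups = c("H", "G", "DR"),
                          roi_size = 1000, roi_shape = "square") {
  if (!file.exists(path)) stop("manifest not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("image", "mask", "group", "od_x", "od_y", "mac_x", "mac_y")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stop("manifest is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!(df$group %in% groups))
  if (length(bad)) {
    stop("unknown group label(s) in manifest row(s) ",
         paste(bad, collapse = ", "), ": ",
         paste(unique(df$group[bad]), collapse = ", "), call. = FALSE)
  }
  if (nrow(df) > 0 && anyDuplicated(df$mask)) {
    stop("duplicate mask paths in manifest", call. = FALSE)
  }
  attr(df, "roi_size") <- as.integer(roi_size)
  attr(df, "roi_shape") <- roi_shape
  class(df) <- c("dataset_manifest", "data.frame")
  df
}

#' @rdname read_manifest
#' @param manifest A `dataset_manifest`.
#' @param row Record number.
#' @param which `"optic_disc"` or `"macula"`.
#' @return `manifest_roi()`: the [roi_spec] for one record and region.
#' @export
manifest_roi <- function(manifest, row, which = c("optic_disc", "macula")) {
  which <- match.arg(which)
  rec <- manifest[row, ]
  if (which == "optic_disc") {
    roi_spec(rec$od_x, rec$od_y, shape = attr(manifest, "roi_shape") %||% "square",
             size = attr(manifest, "roi_size") %||% 1000, label = "optic_disc")
  } else {
    roi_spec(rec$mac_x, rec$mac_y, shape = attr(manifest, "roi_shape") %||% "square",
             size = attr(manifest, "roi_size") %||% 1000, label = "macula")
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
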