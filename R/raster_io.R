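#' In-memory raster types and readers/writers
#'
#' Images are stored as plain numeric arrays in `[row, col, channel]` order
#' (row-major, 0-based coordinate convention for all point-like quantities),
#' with 8-bit channel values in `[0, 255]` and channel order R, G, B. Binary
#' masks are logical `H x W` matrices; tissue label masks are integer `H x W`
#' matrices with 0 reserved for background.
#'
#' @name raster_io
NULL

#' Construct an RGB image object
#'
#' @param pixels numeric `H x W x 3` array with values in `[0, 255]`.
#' @return An object of class `rgb_image` (the validated array).
#' @export
rgb_image <- function(pixels) {
  d <- dim(pixels)
  if (length(d) != 3 || d[3] != 3)
    stop_wm("pixels must be an H x W x 3 array", class = "input_error")
  if (d[1] < 1 || d[2] < 1)
    stop_wm("image must be at least 1 x 1", class = "input_error")
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255)
    stop_wm("channel values must lie in [0, 255]", class = "input_error")
  structure(pixels, class = "rgb_image")
}

#' @export
print.rgb_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<rgb_image %d x %d px, mean intensity %.1f>\n", d[1], d[2], mean(x)))
  invisible(x)
}

image_dims <- function(image) dim(image)[1:2]

#' Construct a binary mask
#'
#' @param pixels logical (or 0/1) `H x W` matrix.
#' @return Object of class `binary_mask`.
#' @export
binary_mask <- function(pixels) {
  if (!is.matrix(pixels)) stop_wm("mask must be a matrix", class = "input_error")
  m <- matrix(as.logical(pixels), nrow(pixels), ncol(pixels))
  if (anyNA(m)) stop_wm("mask contains NA", class = "input_error")
  structure(m, class = "binary_mask")
}

#' Number of foreground pixels in a mask
#'
#' Always recomputed from the raster, never cached.
#' @param mask a `binary_mask` (or logical matrix).
#' @return integer pixel count.
#' @export
mask_area_px <- function(mask) sum(mask)

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask %d x %d, %d foreground px>\n",
              nrow(x), ncol(x), mask_area_px(x)))
  invisible(x)
}

#' Default tissue legend
#'
#' Label 0 is background / non-wound; 1 = necrotic, 2 = slough, 3 = granulated.
#' @return named integer vector mapping tissue name to label.
#' @export
tissue_legend <- function() c(necrotic = 1L, slough = 2L, granulated = 3L)

#' Construct a tissue label mask
#'
#' @param pixels integer `H x W` matrix of small non-negative labels.
#' @param legend named integer vector mapping tissue name to label.
#' @return Object of class `label_mask` with a `legend` attribute.
#' @export
label_mask <- function(pixels, legend = tissue_legend()) {
  if (!is.matrix(pixels)) stop_wm("labels must be a matrix", class = "input_error")
  m <- matrix(as.integer(pixels), nrow(pixels), ncol(pixels))
  if (anyNA(m) || min(m) < 0)
    stop_wm("labels must be non-negative integers", class = "input_error")
  structure(m, legend = legend, class = "label_mask")
}

#' Construct a scribble (user-drawn polyline inside the wound)
#'
#' @param points `n x 2` matrix of (row, col) pixel coordinates, 0-based.
#' @return Object of class `scribble`.
#' @export
scribble <- function(points) {
  points <- matrix(as.numeric(points), ncol = 2)
  if (nrow(points) < 1) stop_wm("scribble needs at least 1 point", class = "input_error")
  structure(list(points = points), class = "scribble")
}

#' Rasterise a scribble as a 1-pixel-wide stroke
#'
#' Consecutive points are joined by interpolated line segments.
#'
#' @param scr a `scribble`.
#' @param h,w frame dimensions in pixels.
#' @return a `binary_mask`.
#' @export
scribble_as_mask <- function(scr, h, w) {
  pts <- scr$points
  if (any(pts[, 1] < 0 | pts[, 1] > h - 1 | pts[, 2] < 0 | pts[, 2] > w - 1))
    stop_wm("scribble point outside image bounds", class = "input_error")
  m <- matrix(FALSE, h, w)
  mark <- function(r, c) m[round(r) + 1, round(c) + 1] <<- TRUE
  n <- nrow(pts)
  for (i in seq_len(n)) {
    mark(pts[i, 1], pts[i, 2])
    if (i < n) {
      steps <- max(abs(pts[i + 1, ] - pts[i, ]))
      if (steps >= 1) {
        t <- seq(0, 1, length.out = ceiling(steps) + 1)
        for (tt in t) mark(pts[i, 1] + tt * (pts[i + 1, 1] - pts[i, 1]),
                           pts[i, 2] + tt * (pts[i + 1, 2] - pts[i, 2]))
      }
    }
  }
  binary_mask(m)
}

#' Read a PNG or JPEG photograph as an 8-bit RGB image
#'
#' Grayscale inputs are replicated across the three channels; an alpha channel
#' is dropped.
#'
#' @param path file path to a PNG or JPEG image.
#' @return an `rgb_image`.
#' @export
read_image <- function(path) {
  if (!file.exists(path))
    stop_wm("cannot read image: no such file: ", path, class = "format_error")
  img <- tryCatch(EBImage::readImage(path),
                  error = function(e) stop_wm("cannot decode image '", path, "': ",
                                              conditionMessage(e), class = "format_error"))
  dat <- EBImage::imageData(img)  # [x, y(, channel)] in [0, 1]
  if (length(dim(dat)) == 2) {
    px <- array(rep(t(dat), 3), c(dim(dat)[2], dim(dat)[1], 3))
  } else {
    nc <- dim(dat)[3]
    if (nc == 2) dat <- dat[, , 1, drop = FALSE]          # gray + alpha
    if (nc >= 4) dat <- dat[, , 1:3, drop = FALSE]        # drop alpha
    if (dim(dat)[3] == 1) {
      px <- array(rep(t(dat[, , 1]), 3), c(dim(dat)[2], dim(dat)[1], 3))
    } else {
      px <- aperm(dat, c(2, 1, 3))
    }
  }
  rgb_image(round(px * 255))
}

#' Write an RGB image to PNG or JPEG (by file extension)
#'
#' @param image an `rgb_image`.
#' @param path destination path ending in .png, .jpg or .jpeg.
#' @export
write_image <- function(image, path) {
  EBImage::writeImage(EBImage::Image(aperm(image / 255, c(2, 1, 3)),
                                     colormode = "Color"), path)
  invisible(NULL)
}

#' Read an 8-bit single-channel PNG as a binary mask
#'
#' @param path mask file path.
#' @param positive_labels integer values mapped to foreground.
#' @return a `binary_mask`.
#' @export
read_mask <- function(path, positive_labels = 1L) {
  if (!file.exists(path))
    stop_wm("cannot read mask: no such file: ", path, class = "format_error")
  img <- tryCatch(EBImage::readImage(path),
                  error = function(e) stop_wm("cannot decode mask '", path, "': ",
                                              conditionMessage(e), class = "format_error"))
  dat <- EBImage::imageData(img)
  if (length(dim(dat)) != 2)
    stop_wm("mask must be single-channel: ", path, class = "format_error")
  vals <- round(t(dat) * 255)
  binary_mask(matrix(vals %in% positive_labels, nrow(vals), ncol(vals)))
}

#' Read an 8-bit single-channel PNG as a tissue label mask
#'
#' @inheritParams read_mask
#' @param legend named label legend, see [tissue_legend()].
#' @return a `label_mask`.
#' @export
read_label_mask <- function(path, legend = tissue_legend()) {
  if (!file.exists(path))
    stop_wm("cannot read mask: no such file: ", path, class = "format_error")
  dat <- EBImage::imageData(EBImage::readImage(path))
  if (length(dim(dat)) != 2)
    stop_wm("label mask must be single-channel: ", path, class = "format_error")
  label_mask(round(t(dat) * 255), legend = legend)
}

#' Write a binary or label mask as an 8-bit PNG
#'
#' Binary masks are stored with values 0/1; label masks keep their labels.
#' @param mask a `binary_mask` or `label_mask`.
#' @param path destination .png path.
#' @export
write_mask <- function(mask, path) {
  EBImage::writeImage(EBImage::Image(t(unclass(mask)) / 255), path, bits.per.sample = 8L)
  invisible(NULL)
}

#' Assemble an assessment report
#'
#' The top-level result of the pipeline: physical area, calibration scale,
#' marker validation summary and tissue fractions.
#'
#' @param area_cm2 physical wound area in cm^2, or `NA` when the marker failed
#'   validation.
#' @param scale_cm2_per_px calibration factor, or `NA`.
#' @param marker a `marker_result` (see [find_marker()]).
#' @param tissue_fractions named numeric vector over tissue classes summing to
#'   1, or `NULL` when classification was not run.
#' @param provenance named list of parameters recorded for reproducibility.
#' @return object of class `assessment_report`.
#' @export
assessment_report <- function(area_cm2, scale_cm2_per_px, marker,
                              tissue_fractions = NULL, provenance = list()) {
  if (!is.null(tissue_fractions)) {
    if (any(tissue_fractions < 0) || abs(sum(tissue_fractions) - 1) > 1e-6)
      stop_wm("tissue fractions must be >= 0 and sum to 1", class = "input_error")
  }
  if (!is.na(area_cm2) && area_cm2 < 0)
    stop_wm("area_cm2 must be >= 0", class = "input_error")
  structure(list(area_cm2 = area_cm2, scale_cm2_per_px = scale_cm2_per_px,
                 marker = marker, tissue_fractions = tissue_fractions,
                 provenance = provenance),
            class = "assessment_report")
}

report_to_list <- function(report) {
  mk <- report$marker
  list(
    area_cm2 = if (is.na(report$area_cm2)) NULL else report$area_cm2,
    scale_cm2_per_px = if (is.na(report$scale_cm2_per_px)) NULL else report$scale_cm2_per_px,
    marker = list(
      valid = mk$valid,
      proportionality = if (is.null(mk$proportionality)) NULL else mk$proportionality,
      asymmetry = if (is.null(mk$asymmetry)) NULL else mk$asymmetry,
      quad_area_px = if (is.null(mk$quad_area_px)) NULL else mk$quad_area_px,
      reject_reason = mk$reject_reason
    ),
    tissue_fractions = if (is.null(report$tissue_fractions)) NULL
                       else as.list(report$tissue_fractions),
    provenance = report$provenance
  )
}

#' Write an assessment report as JSON
#'
#' Keys are written in a stable order; numeric fields round-trip through
#' [read_report()] to better than 1e-9.
#'
#' @param report an `assessment_report`.
#' @param path destination .json path.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report_to_list(report), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(NULL)
}

#' Read an assessment report written by [write_report()]
#'
#' @param path .json path.
#' @return an `assessment_report`.
#' @export
read_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  marker <- x$marker
  assessment_report(
    area_cm2 = if (is.null(x$area_cm2)) NA_real_ else x$area_cm2,
    scale_cm2_per_px = if (is.null(x$scale_cm2_per_px)) NA_real_ else x$scale_cm2_per_px,
    marker = marker,
    tissue_fractions = if (is.null(x$tissue_fractions)) NULL else unlist(x$tissue_fractions),
    provenance = if (is.null(x$provenance)) list() else x$provenance
  )
}

#' @export
print.assessment_report <- function(x, ...) {
  cat("Wound assessment report\n")
  if (is.na(x$area_cm2)) {
    cat(sprintf("  area: unavailable (marker rejected: %s)\n",
                x$marker$reject_reason))
  } else {
    cat(sprintf("  area: %.2f cm^2  (scale %.3g cm^2/px)\n",
                x$area_cm2, x$scale_cm2_per_px))
  }
  if (!is.null(x$tissue_fractions)) {
    cat("  tissue fractions:",
        paste(sprintf("%s %.1f%%", names(x$tissue_fractions),
                      100 * x$tissue_fractions), collapse = ", "), "\n")
  }
  invisible(x)
}
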