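#' Fiducial-marker detection and pixel-to-cm^2 calibration
#'
#' The physical scale of a photograph is recovered from a blue square marker
#' of known size (2 cm x 2 cm = 4 cm^2) placed in the wound plane.  The image
#' is converted to HSV, thresholded to a blue mask, and each connected blue
#' component's contour is simplified to a quadrilateral.  The candidate whose
#' quadrilateral area best matches its raw mask area is selected, then
#' validated geometrically: a marker is accepted only when its
#' proportionality (shortest/longest side) is high and its asymmetry
#' (opposite-side disparity, which grows with perspective foreshortening) is
#' low, reflecting the capture protocol's demand that an inclined or occluded
#' marker triggers a recapture rather than a miscalibrated measurement.
#'
#' @name marker_calibration
NULL

#' Convert an RGB image to HSV
#'
#' Standard hexcone HSV with hue in degrees `[0, 360)` and saturation/value
#' in `[0, 1]`.
#'
#' @param image an [rgb_image()].
#' @return `H x W x 3` array `(hue_deg, sat, val)`.
#' @export
to_hsv <- function(image) {
  h <- dim(image)[1]; w <- dim(image)[2]
  hsv <- grDevices::rgb2hsv(r = as.vector(image[, , 1]),
                            g = as.vector(image[, , 2]),
                            b = as.vector(image[, , 3]), maxColorValue = 255)
  out <- array(0, c(h, w, 3))
  out[, , 1] <- matrix(hsv[1, ] * 360, h, w)
  out[, , 2] <- matrix(hsv[2, ], h, w)
  out[, , 3] <- matrix(hsv[3, ], h, w)
  out
}

#' HSV threshold range
#'
#' @param hue_deg `(low, high)` hue interval in degrees (no wraparound; the
#'   blue default does not need it).
#' @param sat,val `(low, high)` saturation and value intervals in `[0, 1]`.
#' @return object of class `hsv_range`.
#' @export
hsv_range <- function(hue_deg = c(200, 260), sat = c(0.35, 1), val = c(0.20, 1)) {
  if (hue_deg[1] > hue_deg[2] || sat[1] > sat[2] || val[1] > val[2])
    stop_wm("range lower bounds must not exceed upper bounds", class = "input_error")
  structure(list(hue_deg = hue_deg, sat = sat, val = val), class = "hsv_range")
}

#' Threshold an HSV raster to the marker-colour mask
#'
#' A pixel is foreground iff all three channels fall inside their intervals.
#'
#' @param hsv array from [to_hsv()].
#' @param range an [hsv_range()]; the default covers the shades of blue the
#'   marker is printed in.
#' @return a [binary_mask()].
#' @export
blue_mask <- function(hsv, range = hsv_range()) {
  m <- hsv[, , 1] >= range$hue_deg[1] & hsv[, , 1] <= range$hue_deg[2] &
    hsv[, , 2] >= range$sat[1] & hsv[, , 2] <= range$sat[2] &
    hsv[, , 3] >= range$val[1] & hsv[, , 3] <= range$val[2]
  binary_mask(m)
}

#' Marker quality-control thresholds
#'
#' @param min_proportionality minimum allowed shortest/longest side ratio.
#' @param max_asymmetry maximum allowed opposite-side disparity.
#' @param min_area_px minimum blue-component size considered a candidate.
#' @return object of class `marker_qc`.
#' @export
marker_qc <- function(min_proportionality = 0.8, max_asymmetry = 0.2,
                      min_area_px = 400) {
  structure(list(min_proportionality = min_proportionality,
                 max_asymmetry = max_asymmetry, min_area_px = min_area_px),
            class = "marker_qc")
}

quad_side_lengths <- function(corners) {
  # corners clockwise from top-left: sides top, right, bottom, left
  d <- corners[c(2, 3, 4, 1), , drop = FALSE] - corners
  sqrt(rowSums(d^2))
}

#' Opposite-side disparity of a quadrilateral
#'
#' Zero for any parallelogram (so also for every in-plane rotation of the
#' square marker); grows with perspective foreshortening as opposite sides
#' become unequal.  Defined as the larger of the top/bottom and left/right
#' relative length differences.
#'
#' @param corners 4 x 2 matrix of (row, col) corners, clockwise from top-left.
#' @return non-negative disparity ratio.
#' @export
asymmetry_score <- function(corners) {
  s <- quad_side_lengths(corners)
  if (any(s == 0)) stop_wm("degenerate quadrilateral side", class = "geometry_error")
  max(abs(s[1] - s[3]) / max(s[1], s[3]),
      abs(s[2] - s[4]) / max(s[2], s[4]))
}

proportionality_score <- function(corners) {
  s <- quad_side_lengths(corners)
  min(s) / max(s)
}

# A contour traced through pixel centres underestimates the *covered* extent
# of the component by half a pixel on every side; push each corner outward by
# 0.5 px along both adjacent edge directions so side lengths and the shoelace
# area refer to covered pixels (a traced 99 x 39 centre-to-centre rectangle
# becomes the 100 x 40 covered one).
expand_quad_corners <- function(corners) {
  out <- corners
  for (i in 1:4) {
    prev <- corners[(i - 2) %% 4 + 1, ]
    nxt <- corners[i %% 4 + 1, ]
    u1 <- corners[i, ] - prev; u1 <- u1 / sqrt(sum(u1^2))
    u2 <- corners[i, ] - nxt; u2 <- u2 / sqrt(sum(u2^2))
    out[i, ] <- corners[i, ] + 0.5 * (u1 + u2)
  }
  out
}

quad_pixel_area <- function(corners) polygon_area(corners)

#' Detect and validate the calibration marker
#'
#' Pipeline: HSV blue mask, connected components, per-component contour
#' extraction and polygon simplification to 4 vertices (tolerance 2% of the
#' perimeter, relaxed stepwise to 5%); components that cannot be reduced to a
#' quadrilateral or are smaller than `qc$min_area_px` are rejected.  Among the
#' survivors the candidate minimising the relative mismatch
#' `|quad_area_px - mask_area_px| / mask_area_px` is selected.  The selected
#' quadrilateral is validated by proportionality and asymmetry; when valid the
#' scale is `4 / quad_area_px` cm^2 per pixel.
#'
#' @param image an [rgb_image()].
#' @param range an [hsv_range()] for the marker colour.
#' @param qc a [marker_qc()].
#' @return object of class `marker_result`: `corners`, `quad_area_px`,
#'   `mask_area_px`, `proportionality`, `asymmetry`, `valid`,
#'   `scale_cm2_per_px` (iff valid), `reject_reason` (iff invalid).
#' @export
find_marker <- function(image, range = hsv_range(), qc = marker_qc()) {
  bm <- blue_mask(to_hsv(image), range)
  reject <- function(reason) structure(
    list(corners = NULL, quad_area_px = NULL, mask_area_px = NULL,
         proportionality = NULL, asymmetry = NULL, valid = FALSE,
         scale_cm2_per_px = NULL, reject_reason = reason),
    class = "marker_result")
  if (!any(bm)) return(reject("no marker found"))
  cc <- from_ebimage_mask(EBImage::bwlabel(as_ebimage_mask(unclass(bm))))
  ncc <- max(cc)
  cand <- list()
  for (id in seq_len(ncc)) {
    comp_area <- sum(cc == id)
    if (comp_area < qc$min_area_px) next
    oc <- EBImage::ocontour(EBImage::Image(t(cc == id) * 1))[[1]]
    pts <- cbind(oc[, 2], oc[, 1])           # (row, col), 0-based
    quad <- simplify_closed_to_ngon(pts, target = 4L)
    if (is.null(quad)) next
    quad <- expand_quad_corners(order_quad_corners(quad))
    qa <- quad_pixel_area(quad)
    cand[[length(cand) + 1]] <- list(
      corners = quad, quad_area_px = qa, mask_area_px = comp_area,
      mismatch = abs(qa - comp_area) / comp_area)
  }
  if (!length(cand)) return(reject("no marker found"))
  best <- cand[[which.min(vapply(cand, `[[`, numeric(1), "mismatch"))]]
  prop <- proportionality_score(best$corners)
  asym <- asymmetry_score(best$corners)
  valid <- prop >= qc$min_proportionality && asym <= qc$max_asymmetry
  structure(list(
    corners = best$corners, quad_area_px = best$quad_area_px,
    mask_area_px = best$mask_area_px, proportionality = prop,
    asymmetry = asym, valid = valid,
    scale_cm2_per_px = if (valid) 4 / best$quad_area_px else NULL,
    reject_reason = if (valid) NULL else
      sprintf("marker QC failed (proportionality %.3f, asymmetry %.3f)", prop, asym)),
    class = "marker_result")
}

#' @export
print.marker_result <- function(x, ...) {
  if (x$valid) {
    cat(sprintf("<marker_result: valid, %.0f px^2, prop %.3f, asym %.3f, scale %.3g cm^2/px>\n",
                x$quad_area_px, x$proportionality, x$asymmetry, x$scale_cm2_per_px))
  } else {
    cat(sprintf("<marker_result: INVALID (%s)>\n", x$reject_reason))
  }
  invisible(x)
}

#' Physical wound area from an ROI and a validated marker
#'
#' @param roi a `roi_result` (or any object with a `wound_mask`).
#' @param marker a valid `marker_result`.
#' @return wound area in cm^2.
#' @export
measure_area <- function(roi, marker) {
  if (!isTRUE(marker$valid))
    stop_wm("cannot measure area: ", marker$reject_reason %||% "marker invalid",
            class = "measurement_error")
  mask_area_px(roi$wound_mask) * marker$scale_cm2_per_px
}

`%||%` <- function(a, b) if (is.null(a)) b else a
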