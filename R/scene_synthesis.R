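#' Synthetic wound scenes with full ground truth
#'
#' Renders a wound photograph the way the capture protocol produces them: an
#' irregular wound blob with concentric tissue zones (dark necrotic core,
#' yellow slough ring, red granulation rim) on a skin-toned background, plus a
#' blue square fiducial marker of known physical size (2 cm x 2 cm) rendered
#' under a configurable in-plane rotation and perspective map, global
#' illumination gain and additive Gaussian sensor noise.  Every render carries
#' its complete ground truth, so segmentation, calibration and classification
#' can all be scored against it.
#'
#' @name scene_synthesis
NULL

#' Default scene palette
#'
#' Mean RGB colours for the tissue classes, the skin background and the marker
#' saturation/value used when rendering.  Chosen to be separable under the
#' default HSV marker gate and the default colour-distance merge threshold.
#'
#' @return named list of RGB triplets (0-255) and marker HSV settings.
#' @export
scene_palette <- function() {
  list(necrotic = c(40, 30, 30), slough = c(200, 180, 90),
       granulated = c(180, 60, 60), skin = c(220, 180, 160),
       marker_sat = 0.80, marker_val = 0.80)
}

#' Specify a synthetic scene
#'
#' @param image_size `(H, W)` frame size in pixels.
#' @param wound_center `(row, col)` of the wound centre.
#' @param wound_radii `(r_row, r_col)` elliptical base radii in pixels.
#' @param boundary_roughness amplitude of the radial boundary perturbation,
#'   dimensionless in `[0, 1]`.
#' @param tissue_mix fractions `(necrotic, slough, granulated)` of the wound
#'   area, summing to 1.
#' @param marker_side_px marker side length in pixels (the physical side is
#'   always 2 cm).
#' @param marker_center `(row, col)` of the marker centre.
#' @param marker_tilt_deg in-plane rotation of the marker in degrees.
#' @param marker_perspective 3x3 homography applied to the marker in its own
#'   normalised coordinates; identity means fronto-parallel.  See
#'   [perspective_skew()].
#' @param marker_hue_deg marker hue in degrees `[0, 360)`.
#' @param illumination_gain global multiplicative illumination factor.
#' @param noise_sd additive Gaussian sensor noise, in 8-bit intensity units.
#' @param seed random seed for the sensor noise.
#' @param shape_seed seed for the wound-boundary harmonics; kept separate from
#'   `seed` so that re-rendering with a different `seed` changes only the pixel
#'   noise, never the geometry or the ground-truth masks.
#' @return object of class `scene_spec`.
#' @export
scene_spec <- function(image_size = c(300, 400),
                       wound_center = c(150, 130),
                       wound_radii = c(80, 60),
                       boundary_roughness = 0.15,
                       tissue_mix = c(0.2, 0.3, 0.5),
                       marker_side_px = 60,
                       marker_center = c(150, 330),
                       marker_tilt_deg = 0,
                       marker_perspective = diag(3),
                       marker_hue_deg = 225,
                       illumination_gain = 1,
                       noise_sd = 5,
                       seed = 1L,
                       shape_seed = 42L) {
  if (abs(sum(tissue_mix) - 1) > 1e-9)
    stop_wm("tissue_mix must sum to 1", class = "input_error")
  if (any(tissue_mix < 0)) stop_wm("tissue_mix fractions must be >= 0", class = "input_error")
  if (boundary_roughness < 0 || boundary_roughness > 1)
    stop_wm("boundary_roughness must lie in [0, 1]", class = "input_error")
  structure(list(image_size = image_size, wound_center = wound_center,
                 wound_radii = wound_radii, boundary_roughness = boundary_roughness,
                 tissue_mix = tissue_mix, marker_side_px = marker_side_px,
                 marker_center = marker_center, marker_tilt_deg = marker_tilt_deg,
                 marker_perspective = marker_perspective,
                 marker_hue_deg = marker_hue_deg,
                 illumination_gain = illumination_gain, noise_sd = noise_sd,
                 seed = seed, shape_seed = shape_seed),
            class = "scene_spec")
}

#' One-parameter perspective skew for the marker
#'
#' Returns a homography that foreshortens the marker top-to-bottom, emulating a
#' marker plane tipped away from the camera.  `skew = 0` is the identity;
#' increasing `skew` increases the disparity between the top and bottom edge
#' lengths, so the marker's asymmetry score grows with it.
#'
#' @param skew non-negative foreshortening parameter (useful range 0-0.8).
#' @return 3x3 homography matrix in normalised marker coordinates.
#' @export
perspective_skew <- function(skew) {
  matrix(c(1, 0, 0,
           0, 1, 0,
           0, skew, 1), 3, 3, byrow = TRUE)
}

# Marker corner coordinates (row, col) for a spec, before rasterisation.
marker_quad <- function(spec) {
  u <- matrix(c(-0.5, -0.5,   # (v=row-like, u=col-like) unit square corners
                -0.5,  0.5,
                 0.5,  0.5,
                 0.5, -0.5), 4, 2, byrow = TRUE)
  H <- spec$marker_perspective
  hom <- cbind(u[, 2], u[, 1], 1) %*% t(H)     # (x=u, y=v, w)
  x <- hom[, 1] / hom[, 3]; y <- hom[, 2] / hom[, 3]
  s <- spec$marker_side_px
  th <- spec$marker_tilt_deg * pi / 180
  r <- s * (y * cos(th) - x * sin(th)) + spec$marker_center[1]
  c <- s * (y * sin(th) + x * cos(th)) + spec$marker_center[2]
  cbind(row = r, col = c)
}

#' Render a synthetic wound scene
#'
#' Deterministic for a fixed spec: the wound geometry depends only on the
#' spec's shape parameters and `shape_seed`, while `seed` drives the sensor
#' noise alone.
#'
#' @param spec a [scene_spec()].
#' @return object of class `wound_scene` with fields `image` ([rgb_image]),
#'   `wound_mask` ([binary_mask]), `tissue_labels` ([label_mask]),
#'   `marker_corners` (4 x 2, (row, col), clockwise from top-left),
#'   `true_scale_cm2_per_px` and `spec`.
#' @export
render_scene <- function(spec) {
  h <- spec$image_size[1]; w <- spec$image_size[2]
  pal <- scene_palette()

  # wound blob: radial perturbation of an ellipse; label zones by the squared
  # normalised radius so zone areas match tissue_mix exactly in the continuum
  harm <- with_seed(spec$shape_seed, {
    k <- 2:5
    list(amp = runif(length(k), 0.3, 1) / k, phase = runif(length(k), 0, 2 * pi), k = k)
  })
  amp <- harm$amp / sum(harm$amp)        # max perturbation <= roughness
  rr <- outer(0:(h - 1) - spec$wound_center[1], rep(1, w)) / spec$wound_radii[1]
  cc <- outer(rep(1, h), 0:(w - 1) - spec$wound_center[2]) / spec$wound_radii[2]
  theta <- atan2(rr, cc)
  pert <- matrix(0, h, w)
  for (i in seq_along(harm$k))
    pert <- pert + amp[i] * cos(harm$k[i] * theta + harm$phase[i])
  bound <- 1 + spec$boundary_roughness * pert
  u2 <- (rr^2 + cc^2) / bound^2          # squared normalised radius
  cum <- cumsum(spec$tissue_mix)
  labels <- matrix(0L, h, w)
  labels[u2 < cum[3]] <- 3L
  labels[u2 < cum[2]] <- 2L
  labels[u2 < cum[1]] <- 1L
  wound <- labels > 0L

  # marker quadrilateral
  quad <- marker_quad(spec)
  if (min(quad[, 1]) < 0 || max(quad[, 1]) > h - 1 ||
      min(quad[, 2]) < 0 || max(quad[, 2]) > w - 1)
    stop_wm("marker placed outside the frame", class = "geometry_error")
  mmask <- rasterize_polygon(quad, h, w)
  if (any(mmask & wound))
    stop_wm("marker overlaps the wound", class = "geometry_error")

  # compose image
  mcol <- grDevices::hsv(spec$marker_hue_deg / 360, pal$marker_sat, pal$marker_val)
  mcol <- as.numeric(grDevices::col2rgb(mcol))
  px <- array(0, c(h, w, 3))
  zones <- list(pal$skin, pal$necrotic, pal$slough, pal$granulated)
  for (ch in 1:3) {
    plane <- matrix(pal$skin[ch], h, w)
    for (lab in 1:3) plane[labels == lab] <- zones[[lab + 1]][ch]
    plane[mmask] <- mcol[ch]
    px[, , ch] <- plane
  }
  px <- px * spec$illumination_gain
  if (spec$noise_sd > 0)
    px <- px + with_seed(spec$seed, array(rnorm(h * w * 3, 0, spec$noise_sd), c(h, w, 3)))
  px <- round(pmin(pmax(px, 0), 255))

  structure(list(image = rgb_image(px),
                 wound_mask = binary_mask(wound),
                 tissue_labels = label_mask(labels),
                 marker_corners = order_quad_corners(quad),
                 marker_mask_px = sum(mmask),
                 true_scale_cm2_per_px = 4 / sum(mmask),
                 spec = spec),
            class = "wound_scene")
}

#' @export
print.wound_scene <- function(x, ...) {
  cat(sprintf("<wound_scene %d x %d px, wound %d px, marker %d px, scale %.3g cm^2/px>\n",
              dim(x$image)[1], dim(x$image)[2], mask_area_px(x$wound_mask),
              x$marker_mask_px, x$true_scale_cm2_per_px))
  invisible(x)
}

#' Default scribble across a rendered wound
#'
#' Emulates the clinician's stroke: a horizontal polyline through the wound
#' centre spanning most of the wound's width, so that every concentric tissue
#' zone is touched.
#'
#' @param scene a `wound_scene`.
#' @param span fraction of the wound half-width covered on each side.
#' @return a [scribble()].
#' @export
default_scribble <- function(scene, span = 0.75) {
  ctr <- scene$spec$wound_center
  r <- round(ctr[1])
  inside <- which(scene$wound_mask[r + 1, ])
  if (!length(inside))
    stop_wm("wound mask empty on the centre row", class = "geometry_error")
  lo <- min(inside) - 1; hi <- max(inside) - 1   # 0-based
  half <- (hi - lo) / 2 * span
  cols <- seq(ctr[2] - half, ctr[2] + half, by = 2)
  scribble(cbind(rep(r, length(cols)), cols))
}

#' Generate a reference/test tracing pair with a known relationship
#'
#' The reference is the scene's ground-truth wound mask; the test tracing is
#' the reference dilated by `dilate_px` (disc structuring element) and then
#' translated `shift_px` pixels to the right.  Used to manufacture tracing
#' pairs with known FNR/FPR behaviour.
#'
#' @param scene a `wound_scene`.
#' @param dilate_px dilation radius in pixels (0 = none).
#' @param shift_px rightward translation in pixels (0 = none).
#' @return list `(reference, test)` of [binary_mask()]s.
#' @export
render_tracing_pair <- function(scene, dilate_px = 0, shift_px = 0) {
  if (dilate_px < 0 || shift_px < 0)
    stop_wm("dilate_px and shift_px must be >= 0", class = "input_error")
  ref <- scene$wound_mask
  test <- unclass(ref)
  if (dilate_px > 0) {
    brush <- EBImage::makeBrush(2 * as.integer(dilate_px) + 1, shape = "disc")
    test <- from_ebimage_mask(EBImage::dilate(as_ebimage_mask(test), brush)) > 0
  }
  if (shift_px > 0) {
    w <- ncol(test)
    if (shift_px >= w || any(test[, (w - shift_px + 1):w]))
      stop_wm("shift pushes the tracing outside the frame", class = "geometry_error")
    shifted <- matrix(FALSE, nrow(test), w)
    shifted[, (shift_px + 1):w] <- test[, 1:(w - shift_px)]
    test <- shifted
  }
  list(reference = ref, test = binary_mask(test))
}
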