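# Shared fixtures: small, fast synthetic scenes for module tests.  The
# acceptance tests use the full default scene size; module tests use this
# reduced frame so the suite stays quick.

small_scene_spec <- function(...) {
  args <- utils::modifyList(
    list(image_size = c(150, 220), wound_center = c(75, 60),
         wound_radii = c(42, 32), marker_side_px = 40,
         marker_center = c(75, 170)),
    list(...))
  do.call(scene_spec, args)
}

small_params <- function(...) superpixel_params(n_segments = 60, sigma = 2, ...)

solid_image <- function(h, w, rgb) {
  px <- array(0, c(h, w, 3))
  for (c in 1:3) px[, , c] <- rgb[c]
  rgb_image(px)
}

# brute-force per-pixel set-operation oracle for tracing metrics
oracle_metrics <- function(ref, tst) {
  ri <- which(as.logical(ref)); ti <- which(as.logical(tst))
  R <- length(ri); T <- length(ti); O <- length(intersect(ri, ti))
  list(R = R, T = T, O = O,
       fnr = 100 * (R - O) / R, fpr = 100 * (T - O) / R,
       rv = 100 * (T - R) / R, arv = abs(100 * (T - R) / R),
       jac = O / length(union(ri, ti)), dice = 2 * O / (R + T))
}

random_mask_pair <- function(h = 40, w = 40) {
  a <- matrix(runif(h * w) < runif(1, 0.2, 0.6), h, w)
  b <- matrix(runif(h * w) < runif(1, 0.2, 0.6), h, w)
  # correlate them somewhat so overlap varies
  flip <- matrix(runif(h * w) < 0.3, h, w)
  b[!flip] <- a[!flip]
  if (!any(a)) a[1, 1] <- TRUE
  if (!any(b)) b[2, 2] <- TRUE
  list(ref = binary_mask(a), test = binary_mask(b))
}

# variance-components rater table with a chosen true ICC (row effect variance
# icc, residual 1 - icc)
simulate_rater_table <- function(n_rows, n_raters, icc, seed) {
  withr::with_seed(seed, {
    row_eff <- rnorm(n_rows, 0, sqrt(icc))
    row_eff + matrix(rnorm(n_rows * n_raters, 0, sqrt(1 - icc)), n_rows, n_raters)
  })
}
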