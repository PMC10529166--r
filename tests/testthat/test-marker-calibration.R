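test_that("HSV conversion matches the hexcone closed forms", {
  img <- rgb_image(array(c(255, 0, 128,   0, 0, 128,   0, 255, 128),
                         c(3, 1, 3)))
  hsv <- to_hsv(img)
  expect_equal(hsv[1, 1, ], c(0, 1, 1))                 # pure red
  expect_equal(hsv[2, 1, ], c(240, 1, 1))               # pure blue
  expect_equal(hsv[3, 1, ], c(0, 0, 128 / 255))         # gray
})

test_that("blue thresholding isolates the marker pixels", {
  expect_true(all(blue_mask(to_hsv(solid_image(5, 5, c(30, 60, 230))))))
  expect_false(any(blue_mask(to_hsv(solid_image(5, 5, c(230, 30, 30))))))

  sc <- render_scene(small_scene_spec(seed = 4))
  bm <- blue_mask(to_hsv(sc$image))
  cc <- EBImage::bwlabel(EBImage::Image(t(unclass(bm)) * 1))
  comp_area <- max(tabulate(as.vector(cc)[as.vector(cc) > 0]))
  expect_equal(comp_area, sc$marker_mask_px, tolerance = 0.03)
})

test_that("asymmetry is zero for parallelograms and exact for trapezoids", {
  sq <- rbind(c(0, 0), c(0, 10), c(10, 10), c(10, 0))
  expect_equal(asymmetry_score(sq), 0)
  for (tilt in c(15, 40, 85)) {
    th <- tilt * pi / 180
    R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)
    rot <- t(R %*% t(sq))
    expect_equal(asymmetry_score(rot), 0, tolerance = 1e-12)
  }
  trap <- rbind(c(0, 10), c(0, 90), c(30, 100), c(30, 0))  # top 80, bottom 100
  expect_equal(asymmetry_score(trap), 0.2)
  expect_error(asymmetry_score(rbind(c(0, 0), c(0, 0), c(1, 1), c(1, 0))),
               class = "geometry_error")
})

test_that("a rendered fronto-parallel marker calibrates to 4 cm^2 exactly", {
  sc <- render_scene(scene_spec(marker_side_px = 100, marker_center = c(150, 320)))
  mk <- find_marker(sc$image)
  expect_true(mk$valid)
  expect_equal(mk$scale_cm2_per_px, 4e-4, tolerance = 0.02)
})

test_that("an elongated blue rectangle is rejected with proportionality 0.4", {
  px <- array(200, c(200, 300, 3))
  px[60:159, 100:139, 1] <- 30; px[60:159, 100:139, 2] <- 60
  px[60:159, 100:139, 3] <- 255
  mk <- find_marker(rgb_image(px))
  expect_equal(mk$proportionality, 0.4, tolerance = 1e-9)
  expect_false(mk$valid)
  expect_match(mk$reject_reason, "QC failed")
})

test_that("candidate selection minimises the quad/mask area mismatch", {
  px <- array(210, c(240, 320, 3))
  blue <- function(rs, cs) {
    px[rs, cs, 1] <<- 30; px[rs, cs, 2] <<- 60; px[rs, cs, 3] <<- 255
  }
  blue(40:99, 40:99)                      # clean 60 x 60 square
  blue(140:199, 200:259)                  # second component ...
  px[140:169, 200:229, ] <- 210           # ... with a quadrant removed: L-shape
  img <- rgb_image(px)
  mk <- find_marker(img)
  expect_true(mk$valid)
  # detected centre sits in the clean square, not the blob
  ctr <- colMeans(mk$corners)
  expect_lt(abs(ctr[1] - 69.5), 5)
  expect_lt(abs(ctr[2] - 69.5), 5)

  # brute-force oracle over both candidates' mismatch agrees with selection
  bm <- blue_mask(to_hsv(img))
  cc <- t(EBImage::imageData(EBImage::bwlabel(EBImage::Image(t(unclass(bm)) * 1))))
  mism <- sapply(1:max(cc), function(id) {
    oc <- EBImage::ocontour(EBImage::Image(t(cc == id) * 1))[[1]]
    quad <- woundmetric:::simplify_closed_to_ngon(cbind(oc[, 2], oc[, 1]), 4L)
    if (is.null(quad)) return(Inf)
    quad <- woundmetric:::expand_quad_corners(woundmetric:::order_quad_corners(quad))
    abs(woundmetric:::quad_pixel_area(quad) - sum(cc == id)) / sum(cc == id)
  })
  expect_equal(which.min(mism), cc[70, 70])
})

test_that("a frame with no blue at all reports a missing marker", {
  mk <- find_marker(solid_image(50, 50, c(220, 180, 160)))
  expect_false(mk$valid)
  expect_equal(mk$reject_reason, "no marker found")
})

test_that("physical area measurement follows the 4 cm^2 scale ratio", {
  roi <- list(wound_mask = binary_mask(matrix(TRUE, 250, 100)))  # 25000 px
  mk <- list(valid = TRUE, scale_cm2_per_px = 4e-4)
  expect_equal(measure_area(roi, mk), 10.0)
  roi0 <- list(wound_mask = binary_mask(matrix(FALSE, 10, 10)))
  expect_equal(measure_area(roi0, mk), 0)
  bad <- list(valid = FALSE, reject_reason = "no marker found")
  expect_error(measure_area(roi, bad), class = "measurement_error")
})

test_that("the calibrated area is invariant to render scale and marker rotation", {
  base <- scene_spec(image_size = c(300, 400), wound_radii = c(60, 45),
                     marker_side_px = 60, marker_center = c(150, 330))
  twox <- scene_spec(image_size = c(600, 800), wound_center = c(300, 260),
                     wound_radii = c(120, 90), marker_side_px = 120,
                     marker_center = c(300, 660))
  s1 <- render_scene(base); s2 <- render_scene(twox)
  m1 <- find_marker(s1$image); m2 <- find_marker(s2$image)
  expect_true(m1$valid && m2$valid)
  expect_equal(m2$quad_area_px / m1$quad_area_px, 4, tolerance = 0.05)
  a1 <- mask_area_px(s1$wound_mask) * m1$scale_cm2_per_px
  a2 <- mask_area_px(s2$wound_mask) * m2$scale_cm2_per_px
  expect_equal(a2 / a1, 1, tolerance = 0.02)

  for (tilt in c(25, 60)) {
    st <- render_scene(scene_spec(marker_tilt_deg = tilt))
    mt <- find_marker(st$image)
    expect_true(mt$valid)
    expect_lt(mt$asymmetry, 0.05)
    expect_equal(mt$scale_cm2_per_px, st$true_scale_cm2_per_px, tolerance = 0.03)
  }
})
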