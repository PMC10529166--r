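# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

stop_wm <- function(..., class) {
  stop(errorCondition(paste0(...), class = c(class, "woundmetric_error")))
}

# row/col arrays are 0-based throughout; matrices in R are 1-based, so
# converters live here rather than scattered +1/-1 arithmetic.
as_ebimage_mask <- function(mask) EBImage::Image(t(mask) * 1)
from_ebimage_mask <- function(img) t(EBImage::imageData(img))

# Separable Gaussian blur of an H x W matrix; replicate-padded borders.
gaussian_blur_matrix <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  h <- nrow(m); w <- ncol(m)
  # rows (vertical) pass
  idx <- pmin(pmax(seq_len(h + 2 * r) - r, 1L), h)
  mp <- m[idx, , drop = FALSE]
  out <- matrix(0, h, w)
  for (j in seq_along(k)) out <- out + k[j] * mp[seq_len(h) + (j - 1L), , drop = FALSE]
  # cols (horizontal) pass
  idx <- pmin(pmax(seq_len(w + 2 * r) - r, 1L), w)
  mp <- out[, idx, drop = FALSE]
  out2 <- matrix(0, h, w)
  for (j in seq_along(k)) out2 <- out2 + k[j] * mp[, seq_len(w) + (j - 1L), drop = FALSE]
  out2
}

blur_image_array <- function(px, sigma) {
  if (sigma <= 0) return(px)
  for (c in 1:3) px[, , c] <- gaussian_blur_matrix(px[, , c], sigma)
  px
}

# sRGB (0-255) N x 3 matrix -> CIELAB N x 3.
srgb_to_lab <- function(rgb) {
  grDevices::convertColor(rgb / 255, from = "sRGB", to = "Lab")
}

# Bilinear resample of an H x W (matrix) or H x W x C (array) raster to
# out_h x out_w.  `method` "bilinear" or "nearest".  Pixel centres are mapped
# so the corners of the input and output grids coincide (align-corners
# convention is not used; this is the usual area-based mapping).
resize_raster <- function(x, out_h, out_w, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  dims <- dim(x)
  h <- dims[1]; w <- dims[2]
  sy <- h / out_h; sx <- w / out_w
  yc <- (seq_len(out_h) - 0.5) * sy - 0.5  # 0-based source coords
  xc <- (seq_len(out_w) - 0.5) * sx - 0.5
  one_plane <- function(m) {
    if (method == "nearest") {
      yi <- pmin(pmax(round(yc) + 1, 1), h)
      xi <- pmin(pmax(round(xc) + 1, 1), w)
      return(m[yi, xi, drop = FALSE])
    }
    y0 <- pmin(pmax(floor(yc), 0), h - 1); y1 <- pmin(y0 + 1, h - 1)
    x0 <- pmin(pmax(floor(xc), 0), w - 1); x1 <- pmin(x0 + 1, w - 1)
    fy <- pmin(pmax(yc - y0, 0), 1); fx <- pmin(pmax(xc - x0, 0), 1)
    a <- m[y0 + 1, x0 + 1, drop = FALSE]; b <- m[y0 + 1, x1 + 1, drop = FALSE]
    c_ <- m[y1 + 1, x0 + 1, drop = FALSE]; d <- m[y1 + 1, x1 + 1, drop = FALSE]
    top <- a * outer(rep(1, out_h), 1 - fx) + b * outer(rep(1, out_h), fx)
    bot <- c_ * outer(rep(1, out_h), 1 - fx) + d * outer(rep(1, out_h), fx)
    top * outer(1 - fy, rep(1, out_w)) + bot * outer(fy, rep(1, out_w))
  }
  if (length(dims) == 2) return(one_plane(x))
  out <- array(0, c(out_h, out_w, dims[3]))
  for (c in seq_len(dims[3])) out[, , c] <- one_plane(x[, , c])
  out
}

# Shoelace area of a polygon given as an n x 2 matrix of (row, col) vertices.
polygon_area <- function(pts) {
  n <- nrow(pts)
  i2 <- c(2:n, 1)
  abs(sum(pts[, 2] * pts[i2, 1] - pts[i2, 2] * pts[, 1])) / 2
}

polygon_perimeter <- function(pts) {
  n <- nrow(pts)
  i2 <- c(2:n, 1)
  sum(sqrt(rowSums((pts[i2, , drop = FALSE] - pts)^2)))
}

# Rasterise a filled simple polygon ((row, col) vertices, 0-based pixel-centre
# coordinates) into an H x W logical mask by even-odd scanline crossing tests.
# Half-open fill convention in both axes, so a lattice-aligned square with
# side s covers exactly s x s pixels.
rasterize_polygon <- function(pts, h, w) {
  mask <- matrix(FALSE, h, w)
  ymin <- max(0L, floor(min(pts[, 1]))); ymax <- min(h - 1L, ceiling(max(pts[, 1])))
  if (ymax < ymin) return(mask)
  n <- nrow(pts)
  y1 <- pts[, 1]; x1 <- pts[, 2]
  y2 <- pts[c(2:n, 1), 1]; x2 <- pts[c(2:n, 1), 2]
  for (y in ymin:ymax) {
    crosses <- ((y1 <= y) & (y2 > y)) | ((y2 <= y) & (y1 > y))
    if (!any(crosses)) next
    xs <- x1[crosses] + (y - y1[crosses]) / (y2[crosses] - y1[crosses]) *
      (x2[crosses] - x1[crosses])
    xs <- sort(xs)
    for (k in seq(1, length(xs) - 1, by = 2)) {
      lo <- max(0L, ceiling(xs[k])); hi <- min(w - 1L, ceiling(xs[k + 1]) - 1L)
      if (hi >= lo) mask[y + 1L, (lo:hi) + 1L] <- TRUE
    }
  }
  mask
}

# Ramer-Douglas-Peucker simplification of an open polyline (n x 2 matrix).
rdp_simplify <- function(pts, eps) {
  n <- nrow(pts)
  if (n <= 2) return(pts)
  keep <- rep(FALSE, n)
  keep[c(1, n)] <- TRUE
  stack <- list(c(1L, n))
  while (length(stack)) {
    seg <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- seg[1]; j <- seg[2]
    if (j - i < 2) next
    a <- pts[i, ]; b <- pts[j, ]
    ab <- b - a
    len2 <- sum(ab^2)
    mid <- pts[(i + 1):(j - 1), , drop = FALSE]
    if (len2 == 0) {
      d <- sqrt(rowSums((mid - matrix(a, nrow(mid), 2, byrow = TRUE))^2))
    } else {
      rel <- sweep(mid, 2, a)
      d <- abs(rel[, 1] * ab[2] - rel[, 2] * ab[1]) / sqrt(len2)
    }
    kmax <- which.max(d)
    if (d[kmax] > eps) {
      k <- i + kmax
      keep[k] <- TRUE
      stack[[length(stack) + 1]] <- c(i, k)
      stack[[length(stack) + 1]] <- c(k, j)
    }
  }
  pts[keep, , drop = FALSE]
}

# Simplify a closed contour to exactly `target` vertices if possible: split at
# the two mutually farthest points, RDP both halves, re-join.  Returns NULL if
# no tolerance in [eps_lo, eps_hi] (fractions of the perimeter) achieves it.
simplify_closed_to_ngon <- function(pts, target = 4L, eps_lo = 0.02, eps_hi = 0.05) {
  n <- nrow(pts)
  if (n < target) return(NULL)
  per <- polygon_perimeter(pts)
  # farthest pair: approximate by farthest from centroid, then farthest from it
  ctr <- colMeans(pts)
  i1 <- which.max(rowSums(sweep(pts, 2, ctr)^2))
  i2 <- which.max(rowSums(sweep(pts, 2, pts[i1, ])^2))
  lo <- min(i1, i2); hi <- max(i1, i2)
  half1 <- pts[lo:hi, , drop = FALSE]
  half2 <- pts[c(hi:n, 1:lo), , drop = FALSE]
  for (frac in seq(eps_lo, eps_hi, by = 0.005)) {
    eps <- frac * per
    s1 <- rdp_simplify(half1, eps)
    s2 <- rdp_simplify(half2, eps)
    poly <- rbind(s1, s2[-c(1, nrow(s2)), , drop = FALSE])
    if (nrow(poly) == target) return(poly)
  }
  NULL
}

# Order 4 quadrilateral vertices clockwise starting from the top-left
# (smallest row+col sum) in (row, col) image coordinates.
order_quad_corners <- function(pts) {
  ctr <- colMeans(pts)
  # angle measured in (col, -row) so that increasing angle is counter-clockwise
  # on screen; sort decreasing for clockwise in image coordinates
  ang <- atan2(pts[, 1] - ctr[1], pts[, 2] - ctr[2])
  pts <- pts[order(ang), , drop = FALSE]
  start <- which.min(pts[, 1] + pts[, 2])
  pts[((seq_len(4) + start - 2) %% 4) + 1, , drop = FALSE]
}
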