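#' Wound region-of-interest segmentation
#'
#' The wound contour is found in two stages: a SLIC-style superpixel
#' over-segmentation (localised k-means in a joint CIELAB colour + position
#' space), followed by scribble-seeded merging of superpixels into the wound
#' region over the superpixel adjacency graph.
#'
#' @name roi_segmentation
NULL

#' Superpixel operating parameters
#'
#' @param n_segments requested number of superpixels (the realised count may
#'   differ slightly). Default 100, the best-performing setting of the
#'   parameter study together with `sigma = 3`.
#' @param compactness weight of spatial proximity against colour similarity in
#'   the clustering distance; larger values give squarer superpixels.
#' @param max_iter cap on the localised k-means iterations.
#' @param sigma width (pixels) of the Gaussian pre-blur applied before
#'   clustering.
#' @param enforce_connectivity if `TRUE`, orphan fragments of a superpixel are
#'   relabelled to their largest adjacent superpixel so each id is one
#'   4-connected component.
#' @return object of class `superpixel_params`.
#' @export
superpixel_params <- function(n_segments = 100L, compactness = 10,
                              max_iter = 10L, sigma = 3,
                              enforce_connectivity = TRUE) {
  if (n_segments < 2) stop_wm("n_segments must be >= 2", class = "parameter_error")
  if (sigma < 0) stop_wm("sigma must be >= 0", class = "parameter_error")
  if (max_iter < 1) stop_wm("max_iter must be >= 1", class = "parameter_error")
  structure(list(n_segments = as.integer(n_segments), compactness = compactness,
                 max_iter = as.integer(max_iter), sigma = sigma,
                 enforce_connectivity = isTRUE(enforce_connectivity)),
            class = "superpixel_params")
}

# Mean CIELAB colour of every superpixel; rows indexed by label id.
superpixel_mean_lab <- function(labels, lab_flat) {
  k <- max(labels)
  out <- matrix(0, k, 3)
  for (ch in 1:3)
    out[, ch] <- as.numeric(rowsum(lab_flat[, ch], as.vector(labels))) /
      as.numeric(table(as.vector(labels)))
  out
}

# Undirected adjacency pairs (i < j) between superpixel labels.
superpixel_adjacency <- function(labels) {
  h <- nrow(labels); w <- ncol(labels)
  pairs <- rbind(
    cbind(as.vector(labels[-h, ]), as.vector(labels[-1, ])),
    cbind(as.vector(labels[, -w]), as.vector(labels[, -1]))
  )
  pairs <- pairs[pairs[, 1] != pairs[, 2], , drop = FALSE]
  pairs <- cbind(pmin(pairs[, 1], pairs[, 2]), pmax(pairs[, 1], pairs[, 2]))
  unique(pairs)
}

#' Compute SLIC-style superpixels
#'
#' Localised k-means clustering in the 5-dimensional (L, a, b, row, col) space
#' after a Gaussian pre-blur.  Cluster centres start on a regular grid (one
#' per requested segment) and pixels are only contested by nearby centres, so
#' the result is deterministic; on exact distance ties the lowest centre id
#' wins.
#'
#' @param image an [rgb_image()].
#' @param params a [superpixel_params()].
#' @return integer `H x W` matrix of superpixel ids (1-based, a partition of
#'   the frame).
#' @export
compute_superpixels <- function(image, params = superpixel_params()) {
  h <- dim(image)[1]; w <- dim(image)[2]
  n <- params$n_segments
  if (n > h * w)
    stop_wm("n_segments exceeds the pixel count", class = "parameter_error")
  S <- sqrt(h * w / n)
  if (S > min(h, w))
    stop_wm("image is smaller than the superpixel seed grid spacing",
            class = "parameter_error")
  px <- blur_image_array(unclass(image), params$sigma)
  lab_flat <- srgb_to_lab(cbind(as.vector(px[, , 1]), as.vector(px[, , 2]),
                                as.vector(px[, , 3])))
  L <- matrix(lab_flat[, 1], h, w); A <- matrix(lab_flat[, 2], h, w)
  B <- matrix(lab_flat[, 3], h, w)

  nr <- max(1L, round(h / S)); nc <- max(1L, round(w / S))
  cr <- (seq_len(nr) - 0.5) * h / nr
  cc <- (seq_len(nc) - 0.5) * w / nc
  centers <- cbind(rep(cr, times = nc), rep(cc, each = nr))
  k <- nrow(centers)
  ci <- pmin(pmax(round(centers[, 1] + 0.5), 1), h)
  cj <- pmin(pmax(round(centers[, 2] + 0.5), 1), w)
  cfeat <- cbind(L[cbind(ci, cj)], A[cbind(ci, cj)], B[cbind(ci, cj)],
                 centers[, 1], centers[, 2])

  m2 <- (params$compactness / S)^2
  labels <- matrix(0L, h, w)
  for (iter in seq_len(params$max_iter)) {
    dist <- matrix(Inf, h, w)
    labels[] <- 0L
    win <- ceiling(1.5 * S)
    for (id in seq_len(k)) {
      r0 <- max(1, floor(cfeat[id, 4] - win)); r1 <- min(h, ceiling(cfeat[id, 4] + win))
      c0 <- max(1, floor(cfeat[id, 5] - win)); c1 <- min(w, ceiling(cfeat[id, 5] + win))
      rs <- r0:r1; cs <- c0:c1
      dc2 <- (L[rs, cs] - cfeat[id, 1])^2 + (A[rs, cs] - cfeat[id, 2])^2 +
        (B[rs, cs] - cfeat[id, 3])^2
      ds2 <- outer((rs - 0.5 - cfeat[id, 4])^2, rep(1, length(cs))) +
        outer(rep(1, length(rs)), (cs - 0.5 - cfeat[id, 5])^2)
      d <- dc2 + ds2 * m2
      upd <- d < dist[rs, cs]
      if (any(upd)) {
        dsub <- dist[rs, cs]; lsub <- labels[rs, cs]
        dsub[upd] <- d[upd]; lsub[upd] <- id
        dist[rs, cs] <- dsub; labels[rs, cs] <- lsub
      }
    }
    # pixels missed by every window (possible after large centre moves)
    if (any(labels == 0L)) {
      miss <- which(labels == 0L)
      mr <- (miss - 1L) %% h + 1L; mc <- (miss - 1L) %/% h + 1L
      for (t in seq_along(miss)) {
        d <- (cfeat[, 4] - mr[t] + 0.5)^2 + (cfeat[, 5] - mc[t] + 0.5)^2
        labels[miss[t]] <- which.min(d)
      }
    }
    # recompute centres as the mean of their members
    sz <- tabulate(as.vector(labels), nbins = k)
    keep <- sz > 0
    flat <- as.vector(labels)
    rows <- matrix(rep(seq_len(h) - 0.5, w), h, w)
    cols <- matrix(rep(seq_len(w) - 0.5, each = h), h, w)
    newf <- cbind(rowsum(as.vector(L), flat), rowsum(as.vector(A), flat),
                  rowsum(as.vector(B), flat), rowsum(as.vector(rows), flat),
                  rowsum(as.vector(cols), flat)) / sz[sort(unique(flat))]
    cfeat[sort(unique(flat)), ] <- newf
  }
  if (params$enforce_connectivity) labels <- enforce_label_connectivity(labels)
  compact_labels(labels)
}

# Renumber labels to 1..k with no gaps.
compact_labels <- function(labels) {
  ids <- sort(unique(as.vector(labels)))
  map <- integer(max(ids)); map[ids] <- seq_along(ids)
  matrix(map[labels], nrow(labels), ncol(labels))
}

# Relabel orphan fragments (label pieces that are not the label's largest
# 4-connected component) to their largest adjacent superpixel.
enforce_label_connectivity <- function(labels, max_pass = 5L) {
  h <- nrow(labels); w <- ncol(labels)
  for (pass in seq_len(max_pass)) {
    changed <- FALSE
    sizes <- tabulate(as.vector(labels), nbins = max(labels))
    for (id in sort(unique(as.vector(labels)))) {
      cc <- from_ebimage_mask(EBImage::bwlabel(as_ebimage_mask(labels == id)))
      ncc <- max(cc)
      if (ncc <= 1) next
      comp_sz <- tabulate(as.vector(cc)[as.vector(cc) > 0], nbins = ncc)
      main <- which.max(comp_sz)
      for (frag in setdiff(seq_len(ncc), main)) {
        fpix <- which(cc == frag)
        fr <- (fpix - 1L) %% h + 1L; fc <- (fpix - 1L) %/% h + 1L
        nb <- integer(0)
        for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
          rr <- fr + d[1]; cc2 <- fc + d[2]
          ok <- rr >= 1 & rr <= h & cc2 >= 1 & cc2 <= w
          nb <- c(nb, labels[cbind(rr[ok], cc2[ok])])
        }
        nb <- setdiff(unique(nb), id)
        if (length(nb)) {
          labels[fpix] <- nb[which.max(sizes[nb])]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  labels
}

#' Merge superpixels into a wound region from a user scribble
#'
#' The superpixels touched by the scribble seed a region that grows over the
#' superpixel adjacency graph: a candidate superpixel is admitted when the
#' Euclidean CIELAB distance between its mean colour and the mean colour of an
#' already-admitted neighbour is below `merge_threshold`.  The admitted set is
#' therefore the graph reachability set over colour-similar adjacency edges,
#' which makes the result deterministic and monotone in the threshold.
#'
#' @param labels superpixel id matrix from [compute_superpixels()].
#' @param image the [rgb_image()] the labels were computed from.
#' @param scr a [scribble()] lying inside the wound.
#' @param merge_threshold CIELAB colour-distance admission threshold
#'   (default 20, calibrated so typical tissue-to-skin contrast is excluded
#'   while within-tissue variation is admitted).
#' @param params the [superpixel_params()] used (recorded in the result).
#' @return object of class `roi_result` with fields `labels`, `wound_mask`,
#'   `contour` (0-based (row, col) polygon of the largest component's
#'   boundary), `params` and `merge_threshold`.
#' @export
merge_from_scribble <- function(labels, image, scr, merge_threshold = 20,
                                params = NULL) {
  h <- nrow(labels); w <- ncol(labels)
  smask <- scribble_as_mask(scr, h, w)
  seeds <- sort(unique(labels[unclass(smask)]))
  if (!length(seeds))
    stop_wm("scribble does not intersect any superpixel", class = "input_error")
  lab_flat <- srgb_to_lab(cbind(as.vector(image[, , 1]), as.vector(image[, , 2]),
                                as.vector(image[, , 3])))
  means <- superpixel_mean_lab(labels, lab_flat)
  adj <- superpixel_adjacency(labels)
  k <- max(labels)
  nbrs <- vector("list", k)
  for (i in seq_len(nrow(adj))) {
    nbrs[[adj[i, 1]]] <- c(nbrs[[adj[i, 1]]], adj[i, 2])
    nbrs[[adj[i, 2]]] <- c(nbrs[[adj[i, 2]]], adj[i, 1])
  }
  admitted <- rep(FALSE, k)
  admitted[seeds] <- TRUE
  frontier <- seeds
  while (length(frontier)) {
    nxt <- integer(0)
    for (u in frontier) {
      for (v in nbrs[[u]]) {
        if (!admitted[v] &&
            sqrt(sum((means[v, ] - means[u, ])^2)) < merge_threshold) {
          admitted[v] <- TRUE
          nxt <- c(nxt, v)
        }
      }
    }
    frontier <- sort(unique(nxt))
  }
  wound <- matrix(admitted[labels], h, w)
  contour <- largest_component_contour(wound)
  structure(list(labels = labels, wound_mask = binary_mask(wound),
                 contour = contour, params = params,
                 merge_threshold = merge_threshold),
            class = "roi_result")
}

# Boundary polygon ((row, col), 0-based) of the largest 4-connected component.
largest_component_contour <- function(mask) {
  if (!any(mask)) return(matrix(numeric(0), 0, 2))
  cc <- from_ebimage_mask(EBImage::bwlabel(as_ebimage_mask(mask)))
  sizes <- tabulate(as.vector(cc)[as.vector(cc) > 0], nbins = max(cc))
  main <- cc == which.max(sizes)
  oc <- EBImage::ocontour(EBImage::Image(t(main) * 1))[[1]]  # (x, y) 0-based
  cbind(row = oc[, 2], col = oc[, 1])
}

#' @export
print.roi_result <- function(x, ...) {
  cat(sprintf("<roi_result: %d superpixels, wound %d px, threshold %.1f>\n",
              max(x$labels), mask_area_px(x$wound_mask), x$merge_threshold))
  invisible(x)
}

#' Resolution-to-parameters regression model
#'
#' A polynomial map from image resolution (megapixels) to the superpixel
#' parameters `(n_segments, sigma)`.  An empty (default) model always returns
#' the best fixed combination from the parameter study, `n_segments = 100`,
#' `sigma = 3`.  Predictions are clipped to the explored ranges
#' `n_segments` in `[50, 300]` and `sigma` in `[1, 5]`.
#'
#' @param coef_n,coef_sigma polynomial coefficients (intercept first) for the
#'   two targets, or `NULL` for the fixed default.
#' @param degree polynomial degree.
#' @return object of class `param_model`.
#' @export
param_model <- function(coef_n = NULL, coef_sigma = NULL, degree = 1L) {
  structure(list(coef_n = coef_n, coef_sigma = coef_sigma,
                 degree = as.integer(degree)), class = "param_model")
}

#' Fit the resolution-to-parameters polynomial
#'
#' Ordinary least squares on observed `(megapixels, n_segments, sigma)`
#' triples, e.g. collected from the manual parameter study.
#'
#' @param megapixels numeric vector of image resolutions.
#' @param n_segments,sigma numeric vectors of the parameters judged best at
#'   each resolution.
#' @param degree polynomial degree (default 1).
#' @return a fitted [param_model()].
#' @export
fit_param_model <- function(megapixels, n_segments, sigma, degree = 1L) {
  X <- outer(megapixels, 0:degree, `^`)
  cn <- qr.solve(X, n_segments)
  cs <- qr.solve(X, sigma)
  param_model(coef_n = cn, coef_sigma = cs, degree = degree)
}

#' Suggest superpixel parameters for an image
#'
#' @param image an [rgb_image()].
#' @param model a [param_model()]; the default (empty) model returns
#'   `n_segments = 100`, `sigma = 3`.
#' @return a [superpixel_params()].
#' @export
suggest_params <- function(image, model = param_model()) {
  if (is.null(model$coef_n)) return(superpixel_params(100L, sigma = 3))
  mp <- prod(dim(image)[1:2]) / 1e6
  basis <- mp^(0:model$degree)
  n <- sum(model$coef_n * basis)
  s <- sum(model$coef_sigma * basis)
  superpixel_params(n_segments = round(min(max(n, 50), 300)),
                    sigma = min(max(s, 1), 5))
}
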