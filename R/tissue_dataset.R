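#' Tissue patch datasets
#'
#' Preprocessing mirrors the capture-to-classifier path: the region of
#' interest is black-masked (everything outside the wound set to (0,0,0)),
#' cropped to its bounding box, resized to 200 x 200 pixels, scaled to
#' `[0, 1]`, and cut into a non-overlapping 40 x 40 grid of 5 x 5-pixel
#' patches.  Each patch becomes one labelled example (majority tissue label);
#' patches that are more than half background are dropped.  Augmentation adds
#' horizontally flipped and zoom-resampled copies of training patches, and the
#' train/test split is stratified by tissue class and assigned at the
#' source-scene level so that no scene contributes to both splits.
#'
#' @name tissue_dataset
NULL

#' Black-mask, crop and resize a region of interest
#'
#' @param image an [rgb_image()].
#' @param roi a [binary_mask()] of the same frame.
#' @param size output side length in pixels (default 200).
#' @return `size x size x 3` numeric array with intensities in `[0, 1]`.
#' @export
preprocess_roi <- function(image, roi, size = 200L) {
  if (!any(roi)) stop_wm("ROI is empty", class = "input_error")
  if (!all(dim(image)[1:2] == dim(roi)))
    stop_wm("image and ROI dimensions differ", class = "input_error")
  px <- unclass(image)
  m <- unclass(roi)
  for (c in 1:3) px[, , c][!m] <- 0
  rows <- range(which(rowSums(m) > 0)); cols <- range(which(colSums(m) > 0))
  px <- px[rows[1]:rows[2], cols[1]:cols[2], , drop = FALSE]
  resize_raster(px, size, size, method = "bilinear") / 255
}

# Align a label mask through the same crop+resize, nearest-neighbour.
preprocess_labels <- function(labels, roi, size = 200L) {
  m <- unclass(roi)
  lab <- unclass(labels)
  lab[!m] <- 0L
  rows <- range(which(rowSums(m) > 0)); cols <- range(which(colSums(m) > 0))
  lab <- lab[rows[1]:rows[2], cols[1]:cols[2], drop = FALSE]
  matrix(as.integer(resize_raster(lab, size, size, method = "nearest")), size, size)
}

#' Cut a preprocessed ROI into labelled 5 x 5 patches
#'
#' @param processed `200 x 200 x 3` array from [preprocess_roi()].
#' @param labels `200 x 200` integer matrix aligned to `processed`
#'   (crop/resize with nearest-neighbour; see the module description).
#' @param source_scene identifier of the originating scene (used by
#'   [split_dataset()] to prevent leakage).
#' @param patch patch side length (default 5).
#' @return object of class `tissue_dataset`: list with `x` (n x 75 matrix of
#'   flattened patches), `y` (integer class labels 1..3), `scene` (character),
#'   `split` (factor, initially all `"train"`).
#' @export
extract_patches <- function(processed, labels, source_scene = "scene", patch = 5L) {
  d <- dim(processed)
  if (!all(dim(labels) == d[1:2]))
    stop_wm("labels not aligned with processed raster", class = "input_error")
  ng <- d[1] %/% patch
  xs <- list(); ys <- integer(0)
  for (gi in seq_len(ng)) for (gj in seq_len(ng)) {
    rs <- ((gi - 1) * patch + 1):(gi * patch)
    cs <- ((gj - 1) * patch + 1):(gj * patch)
    cell <- labels[rs, cs]
    nbg <- sum(cell == 0L)
    if (nbg > length(cell) / 2) next
    tab <- tabulate(cell[cell > 0L], nbins = 3L)
    ys <- c(ys, which.max(tab))
    xs[[length(xs) + 1]] <- as.vector(processed[rs, cs, ])
  }
  x <- if (length(xs)) do.call(rbind, xs) else matrix(numeric(0), 0, patch * patch * 3)
  structure(list(x = x, y = ys,
                 scene = rep(as.character(source_scene), length(ys)),
                 split = rep("train", length(ys)), patch = patch),
            class = "tissue_dataset")
}

#' Concatenate tissue datasets
#'
#' @param ... `tissue_dataset` objects.
#' @return a combined `tissue_dataset`.
#' @export
bind_datasets <- function(...) {
  ds <- list(...)
  if (length(ds) == 1 && is.list(ds[[1]]) && !inherits(ds[[1]], "tissue_dataset"))
    ds <- ds[[1]]
  structure(list(x = do.call(rbind, lapply(ds, `[[`, "x")),
                 y = unlist(lapply(ds, `[[`, "y")),
                 scene = unlist(lapply(ds, `[[`, "scene")),
                 split = unlist(lapply(ds, `[[`, "split")),
                 patch = ds[[1]]$patch),
            class = "tissue_dataset")
}

#' @export
print.tissue_dataset <- function(x, ...) {
  cat(sprintf("<tissue_dataset: %d patches (%s), %d scenes>\n", length(x$y),
              paste(sprintf("%s %d", names(tissue_legend()),
                            tabulate(x$y, 3)), collapse = ", "),
              length(unique(x$scene))))
  invisible(x)
}

# zoom-resample a flat 5x5x3 patch about its centre by factor z, re-crop to 5x5
zoom_patch <- function(flat, patch, z) {
  arr <- array(flat, c(patch, patch, 3))
  big <- max(patch, round(patch * z))
  up <- resize_raster(arr, big, big, method = "bilinear")
  off <- (big - patch) %/% 2
  out <- up[(off + 1):(off + patch), (off + 1):(off + patch), , drop = FALSE]
  as.vector(pmin(pmax(out, 0), 1))
}

#' Augment training patches
#'
#' Adds a horizontally flipped copy and a zoom-resampled copy (zoom factor
#' uniform in `[0.9, 1.1]`, re-cropped to the patch size) of every example;
#' `n` inputs give `3n` outputs.  Only training-split examples may be
#' augmented.
#'
#' @param dataset a `tissue_dataset` whose examples are all in the train
#'   split.
#' @param seed RNG seed for the zoom factors.
#' @return enlarged `tissue_dataset`.
#' @export
augment_patches <- function(dataset, seed = 1L) {
  if (any(dataset$split != "train"))
    stop_wm("only training examples may be augmented", class = "usage_error")
  p <- dataset$patch
  n <- length(dataset$y)
  idx_flip <- as.vector(aperm(array(seq_len(3 * p * p), c(p, p, 3))[, p:1, ,
                                                                    drop = FALSE],
                              c(1, 2, 3)))
  flipped <- dataset$x[, idx_flip, drop = FALSE]
  zooms <- with_seed(seed, runif(n, 0.9, 1.1))
  zoomed <- t(vapply(seq_len(n),
                     function(i) zoom_patch(dataset$x[i, ], p, zooms[i]),
                     numeric(3 * p * p)))
  structure(list(x = rbind(dataset$x, flipped, zoomed),
                 y = rep(dataset$y, 3),
                 scene = rep(dataset$scene, 3),
                 split = rep("train", 3 * n), patch = p),
            class = "tissue_dataset")
}

#' Stratified 80/20 train/test split, grouped by source scene
#'
#' Scenes (not individual patches) are assigned to the two splits so no scene
#' leaks across them; the greedy assignment balances every tissue class as
#' close to the target fraction as the scene granularity allows (exact to
#' within one example when every scene holds one example).
#'
#' @param dataset a `tissue_dataset`.
#' @param fraction training fraction (default 0.8).
#' @param seed RNG seed (scene processing order).
#' @return the dataset with its `split` field set to `"train"`/`"test"`.
#' @export
split_dataset <- function(dataset, fraction = 0.8, seed = 1L) {
  counts <- tabulate(dataset$y, nbins = 3L)
  if (any(counts > 0 & counts < 10))
    stop_wm("every represented class needs at least 10 examples",
            class = "input_error")
  scenes <- unique(dataset$scene)
  per_scene <- lapply(scenes, function(s)
    tabulate(dataset$y[dataset$scene == s], nbins = 3L))
  target <- fraction * counts
  got <- c(0, 0, 0)
  ord <- with_seed(seed, sample(seq_along(scenes)))
  train_scenes <- character(0)
  for (i in ord) {
    add <- per_scene[[i]]
    # assign to train while it moves class counts toward (not past) the target
    if (sum(pmin(got + add, target) - pmin(got, target)) >= sum(add) / 2) {
      train_scenes <- c(train_scenes, scenes[i])
      got <- got + add
    }
  }
  dataset$split <- ifelse(dataset$scene %in% train_scenes, "train", "test")
  # degenerate guard: both splits must be populated
  if (!any(dataset$split == "test")) {
    drop <- scenes[ord[1]]
    dataset$split[dataset$scene == drop] <- "test"
  }
  if (!any(dataset$split == "train")) {
    add <- scenes[ord[1]]
    dataset$split[dataset$scene == add] <- "train"
  }
  dataset
}

#' Subset a dataset by split
#'
#' @param dataset a `tissue_dataset`.
#' @param split `"train"` or `"test"`.
#' @return a `tissue_dataset` restricted to the split.
#' @export
dataset_split <- function(dataset, split = c("train", "test")) {
  split <- match.arg(split)
  i <- dataset$split == split
  structure(list(x = dataset$x[i, , drop = FALSE], y = dataset$y[i],
                 scene = dataset$scene[i], split = dataset$split[i],
                 patch = dataset$patch),
            class = "tissue_dataset")
}

#' Build a labelled patch dataset from a rendered scene
#'
#' Convenience wrapper: preprocesses the scene's image with its ground-truth
#' wound mask, aligns the tissue labels, and extracts patches.
#'
#' @param scene a `wound_scene`.
#' @param id scene identifier.
#' @param max_patches optional cap on the number of patches kept (deterministic
#'   subsample under `seed`), to bound training-set sizes.
#' @param seed RNG seed for the subsample.
#' @return a `tissue_dataset`.
#' @export
scene_patches <- function(scene, id = "scene", max_patches = Inf, seed = 1L) {
  proc <- preprocess_roi(scene$image, scene$wound_mask)
  lab <- preprocess_labels(scene$tissue_labels, scene$wound_mask)
  ds <- extract_patches(proc, lab, source_scene = id)
  if (is.finite(max_patches) && length(ds$y) > max_patches) {
    keep <- with_seed(seed, sort(sample(length(ds$y), max_patches)))
    ds$x <- ds$x[keep, , drop = FALSE]
    ds$y <- ds$y[keep]; ds$scene <- ds$scene[keep]; ds$split <- ds$split[keep]
  }
  ds
}
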