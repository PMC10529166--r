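make_colour_dataset <- function(n_per_class, noise = 0.02, seed = 1,
                                scenes_per_class = n_per_class) {
  # linearly separable colour patches: three well-separated class colours
  cols <- list(c(0.1, 0.1, 0.1), c(0.8, 0.7, 0.3), c(0.7, 0.2, 0.2))
  withr::with_seed(seed, {
    x <- do.call(rbind, lapply(1:3, function(k) {
      base <- matrix(rep(rep(cols[[k]], each = 25), n_per_class),
                     n_per_class, 75, byrow = TRUE)
      pmin(pmax(base + matrix(rnorm(n_per_class * 75, 0, noise),
                              n_per_class, 75), 0), 1)
    }))
    y <- rep(1:3, each = n_per_class)
    scene <- paste0("s", rep(seq_len(scenes_per_class), length.out = 3 * n_per_class))
    structure(list(x = x, y = y,
                   scene = paste0(scene, "_c", y),
                   split = rep("train", length(y)), patch = 5L),
              class = "tissue_dataset")
  })
}

test_that("ROI preprocessing black-masks, crops and resizes to 200 x 200", {
  sc <- render_scene(small_scene_spec(seed = 6))
  out <- preprocess_roi(sc$image, sc$wound_mask)
  expect_equal(dim(out), c(200, 200, 3))
  expect_true(all(out >= 0 & out <= 1))

  # identity geometry: all-true ROI on an already-200x200 image
  img <- rgb_image(array(withr::with_seed(1, sample(0:255, 200 * 200 * 3, TRUE)),
                         c(200, 200, 3)))
  roi <- binary_mask(matrix(TRUE, 200, 200))
  expect_equal(preprocess_roi(img, roi), unclass(img) / 255, tolerance = 1e-9)

  # a diagonal ROI keeps black outside the wound after crop+resize
  tri <- binary_mask(outer(1:200, 1:200, function(r, c) r >= c))
  ptri <- preprocess_roi(img, tri)
  expect_equal(sum(ptri[30, 150:200, ]), 0)  # upper-right corner masked

  # 400 x 400 input resizes to exactly 200 x 200
  big <- rgb_image(array(120, c(400, 400, 3)))
  expect_equal(dim(preprocess_roi(big, binary_mask(matrix(TRUE, 400, 400)))),
               c(200, 200, 3))

  expect_error(preprocess_roi(img, binary_mask(matrix(FALSE, 200, 200))),
               class = "input_error")
})

test_that("patch extraction follows the 5 x 5 grid and majority-label rule", {
  proc <- array(0.5, c(200, 200, 3))
  full <- matrix(3L, 200, 200)
  ds <- extract_patches(proc, full)
  expect_equal(length(ds$y), 1600)
  expect_true(all(ds$y == 3L))
  expect_equal(ncol(ds$x), 75)

  half <- matrix(0L, 200, 200); half[, 1:100] <- 1L
  dh <- extract_patches(proc, half)
  expect_lt(abs(length(dh$y) - 800), 40)

  # a cell with 13/25 background pixels is dropped; 12/25 is kept
  lab <- matrix(0L, 200, 200)
  cell <- matrix(0L, 5, 5); cell[1:12] <- 2L
  lab[1:5, 1:5] <- cell                       # 13 background -> dropped
  cell2 <- matrix(2L, 5, 5); cell2[1:12] <- 0L
  lab[6:10, 1:5] <- cell2                     # 12 background -> kept
  dd <- extract_patches(proc, lab)
  expect_equal(length(dd$y), 1)
  expect_equal(dd$y, 2L)

  expect_error(extract_patches(proc, matrix(1L, 100, 100)),
               class = "input_error")
})

test_that("augmentation triples the set, flips are involutions, test set untouched", {
  ds <- make_colour_dataset(10, seed = 2)
  aug <- augment_patches(ds, seed = 3)
  expect_equal(length(aug$y), 3 * length(ds$y))
  expect_equal(aug$y, rep(ds$y, 3))

  # flipping the flipped block recovers the originals
  n <- length(ds$y)
  flipped <- aug$x[(n + 1):(2 * n), , drop = FALSE]
  idx <- as.vector(array(seq_len(75), c(5, 5, 3))[, 5:1, ])
  expect_equal(flipped[, idx], ds$x, tolerance = 1e-12)

  # a zoom factor of exactly 1 is the identity resample
  expect_equal(woundmetric:::zoom_patch(ds$x[1, ], 5L, 1), ds$x[1, ],
               tolerance = 1e-12)

  ds$split[1] <- "test"
  expect_error(augment_patches(ds), class = "usage_error")
})

test_that("the 80/20 split is stratified and never leaks a scene", {
  ds <- make_colour_dataset(100, seed = 4)   # every example its own scene
  sp <- split_dataset(ds, 0.8, seed = 5)
  for (k in 1:3) {
    n_train <- sum(sp$y == k & sp$split == "train")
    expect_lte(abs(n_train - 80), 1)
  }
  sp2 <- split_dataset(ds, 0.8, seed = 5)
  expect_identical(sp$split, sp2$split)

  # heterogeneous scene sizes: no scene id in both splits
  scenes <- lapply(0:5, function(s)
    scene_patches(render_scene(small_scene_spec(seed = s)),
                  id = paste0("sc", s), max_patches = 60, seed = s + 1))
  big <- bind_datasets(scenes)
  spl <- split_dataset(big, 0.8, seed = 6)
  tr <- unique(spl$scene[spl$split == "train"])
  te <- unique(spl$scene[spl$split == "test"])
  expect_length(intersect(tr, te), 0)
  expect_gt(length(te), 0)

  tiny <- make_colour_dataset(3)
  expect_error(split_dataset(tiny), class = "input_error")
})

test_that("cross-entropy and the combined objective match closed forms", {
  expect_equal(cross_entropy_loss(c(1, 0, 0), c(1, 0, 0)), 0)
  expect_equal(cross_entropy_loss(c(0, 1, 0), rep(1 / 3, 3)), log(3))
  expect_equal(cross_entropy_loss(c(0, 1, 0), c(0.2, 0.5, 0.3)), -log(0.5))
  expect_error(cross_entropy_loss(c(1, 0), c(0.5, 0.2, 0.3)),
               class = "input_error")
  expect_error(cross_entropy_loss(c(1, 0, 0), c(0.9, 0.3, 0.3)),
               class = "input_error")

  expect_equal(combined_objective(c(0, 0), c(0, 0))$total, 0)
  expect_equal(combined_objective(c(1, 2), c(3, 4))$total, 10)
  ls <- withr::with_seed(1, runif(20)); lt <- withr::with_seed(2, runif(20))
  expect_equal(combined_objective(ls, lt)$total,
               sum(ls) + sum(lt), tolerance = 1e-12)
  expect_error(combined_objective(1:3, 1:2), class = "input_error")
})

test_that("training separates well-separated colour classes and is deterministic", {
  ds <- make_colour_dataset(60, seed = 7)
  cfg <- training_config(epochs = 30, patience = 5, seed = 11)
  m0 <- tissue_model(seed = 11)

  # softmax normalisation on every forward pass
  p0 <- predict(m0, ds)
  expect_true(all(abs(rowSums(p0) - 1) < 1e-6))

  m <- train_tissue_model(m0, ds, cfg)
  acc <- mean(max.col(predict(m, ds)) == ds$y)
  expect_gte(acc, 0.99)
  # loss decreased from its pre-training value
  expect_lt(tail(m$loss_trajectory, 1), m$loss_trajectory[1])

  m2 <- train_tissue_model(tissue_model(seed = 11), ds, cfg)
  expect_equal(m$loss_trajectory, m2$loss_trajectory, tolerance = 1e-6)
  expect_equal(m$weights$W4, m2$weights$W4, tolerance = 1e-9)

  mz <- train_tissue_model(tissue_model(seed = 11), ds,
                           training_config(epochs = 0, seed = 11))
  expect_identical(mz$weights, m0$weights)
  expect_length(mz$loss_trajectory, 1)
})

test_that("evaluation reproduces hand-computed confusion arithmetic", {
  conf <- matrix(c(8, 1, 1,
                   2, 7, 1,
                   0, 2, 8), 3, 3, byrow = TRUE,
                 dimnames = list(true = names(tissue_legend()),
                                 predicted = names(tissue_legend())))
  rep <- woundmetric:::eval_report_from_confusion(conf)
  expect_equal(rep$per_class$recall[1], 0.8)
  expect_equal(rep$per_class$precision[1], 8 / 10)
  expect_equal(rep$per_class$recall[2], 0.7)
  expect_equal(rep$per_class$precision[3], 8 / 10)
  f1_1 <- 2 * 0.8 * 0.8 / 1.6
  expect_equal(rep$per_class$f1[1], f1_1)
  expect_equal(unname(rep$macro_avg["f1"]), mean(rep$per_class$f1),
               tolerance = 1e-9)
  expect_equal(rep$overall_accuracy, 23 / 30)
  expect_equal(rowSums(rep$confusion), setNames(rep$per_class$support,
                                                rownames(conf)))

  # random predictions over balanced classes hover at chance accuracy
  chance <- withr::with_seed(13, {
    y <- rep(1:3, each = 1000)
    pred <- sample(1:3, 3000, replace = TRUE)
    conf2 <- table(factor(y, 1:3), factor(pred, 1:3))
    sum(diag(conf2)) / 3000
  })
  expect_lt(abs(chance - 1 / 3), 0.03)
})

test_that("a perfectly predicted test set scores 1 everywhere", {
  ds <- make_colour_dataset(40, seed = 8)
  m <- train_tissue_model(tissue_model(seed = 2), ds,
                          training_config(epochs = 25, patience = 5, seed = 2))
  rep <- evaluate_model(m, ds)
  if (rep$overall_accuracy == 1) {
    expect_true(all(rep$per_class$precision == 1))
    expect_true(all(rep$per_class$f1 == 1))
  }
  expect_equal(sum(rep$per_class$support), length(ds$y))
})

test_that("size categories use left-closed thresholds", {
  expect_equal(as.character(size_category(2.0, c(5, 20))), "small")
  expect_equal(as.character(size_category(5.0, c(5, 20))), "medium")
  expect_equal(as.character(size_category(100, c(5, 20))), "large")
  expect_error(size_category(-1), class = "input_error")
  expect_error(size_category(1, c(20, 5)), class = "input_error")
})

test_that("models round-trip through their JSON serialisation", {
  ds <- make_colour_dataset(20, seed = 9)
  m <- train_tissue_model(tissue_model(seed = 3), ds,
                          training_config(epochs = 5, seed = 3))
  tmp <- withr::local_tempdir()
  p <- file.path(tmp, "model.json")
  save_tissue_model(m, p)
  m2 <- load_tissue_model(p)
  expect_equal(predict(m2, ds), predict(m, ds), tolerance = 1e-12)
  expect_equal(m2$loss_trajectory, m$loss_trajectory, tolerance = 1e-12)
})

test_that("predicted tissue fractions track the scene's true mix", {
  mixes <- list(c(0.5, 0.25, 0.25), c(0.2, 0.5, 0.3), c(0.15, 0.25, 0.6))
  scenes <- lapply(seq_along(mixes), function(i)
    render_scene(small_scene_spec(seed = i, tissue_mix = mixes[[i]])))
  train <- bind_datasets(lapply(seq_along(scenes), function(i)
    scene_patches(scenes[[i]], id = paste0("s", i), max_patches = 150,
                  seed = i)))
  m <- train_tissue_model(tissue_model(seed = 5), train,
                          training_config(epochs = 25, patience = 5, seed = 5))
  for (i in seq_along(scenes)) {
    fr <- classify_tissue_fractions(m, scenes[[i]]$image, scenes[[i]]$wound_mask)
    expect_equal(sum(fr), 1, tolerance = 1e-9)
    expect_true(all(abs(fr - mixes[[i]]) < 0.15))
  }
})
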