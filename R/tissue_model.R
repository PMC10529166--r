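#' Compact convolutional tissue classifier
#'
#' A small network trained from scratch on 5 x 5 RGB patches: two 3 x 3
#' convolution layers (valid padding, ReLU) reduce the patch to a feature
#' vector, followed by the classification head — flatten, dense with ReLU,
#' dropout at rate 0.3 (training only), and a dense softmax over the tissue
#' classes.  Training minimises the mean tissue cross-entropy by mini-batch
#' stochastic gradient descent with a fixed seed (fixed initialisation, fixed
#' shuffle), early-stopping on a held-out 10% of the training set.
#'
#' @name tissue_model
NULL

#' Training configuration
#'
#' @param epochs maximum number of epochs.
#' @param batch_size mini-batch size.
#' @param learning_rate SGD learning rate.
#' @param patience early-stopping patience (epochs without validation
#'   improvement).
#' @param val_fraction fraction of the training set held out for early
#'   stopping.
#' @param seed RNG seed for initialisation, shuffling and dropout.
#' @return list of class `training_config`.
#' @export
training_config <- function(epochs = 60L, batch_size = 64L, learning_rate = 0.05,
                            patience = 10L, val_fraction = 0.1, seed = 1L) {
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, patience = as.integer(patience),
                 val_fraction = val_fraction, seed = as.integer(seed)),
            class = "training_config")
}

# conv layer geometry for 5x5 patches: conv1 3x3x3 -> 8 maps over 9 positions,
# conv2 3x3x8 -> 16 maps over the single remaining position.
conv1_index <- function(patch = 5L) {
  # idx[p, ] = the 27 flat indices of the 3x3x3 window at position p (1..9)
  pos <- expand.grid(r = 0:2, c = 0:2)  # window origins (0-based)
  idx <- matrix(0L, nrow(pos), 27L)
  for (p in seq_len(nrow(pos))) {
    a <- array(seq_len(patch * patch * 3), c(patch, patch, 3))
    win <- a[pos$r[p] + 1:3, pos$c[p] + 1:3, , drop = FALSE]
    idx[p, ] <- as.vector(win)
  }
  idx
}

#' Initialise a tissue model
#'
#' @param n_classes number of tissue classes (default 3:
#'   necrotic / slough / granulated).
#' @param n_filters1,n_filters2 filters in the two convolution layers.
#' @param n_hidden width of the dense ReLU layer in the head.
#' @param dropout dropout rate in the head (default 0.3).
#' @param seed RNG seed for the (He-scaled) weight initialisation.
#' @return object of class `tissue_model`.
#' @export
tissue_model <- function(n_classes = 3L, n_filters1 = 8L, n_filters2 = 16L,
                         n_hidden = 32L, dropout = 0.3, seed = 1L) {
  he <- function(nin, nout) matrix(rnorm(nin * nout, 0, sqrt(2 / nin)), nin, nout)
  W <- with_seed(seed, list(
    W1 = he(27, n_filters1), b1 = rep(0, n_filters1),
    W2 = he(9 * n_filters1, n_filters2), b2 = rep(0, n_filters2),
    W3 = he(n_filters2, n_hidden), b3 = rep(0, n_hidden),
    W4 = he(n_hidden, n_classes), b4 = rep(0, n_classes)))
  structure(list(weights = W, n_classes = as.integer(n_classes),
                 n_filters1 = as.integer(n_filters1),
                 n_filters2 = as.integer(n_filters2),
                 n_hidden = as.integer(n_hidden), dropout = dropout,
                 idx1 = conv1_index(), trained = FALSE,
                 loss_trajectory = numeric(0), training_config = NULL),
            class = "tissue_model")
}

# Forward pass on a batch (n x 75 matrix).  Returns activations for backprop.
# drop_mask: NULL for inference (no dropout; weights are not rescaled because
# inverted dropout is applied at train time).
forward_pass <- function(model, X, drop_mask = NULL) {
  W <- model$weights
  n <- nrow(X)
  f1 <- model$n_filters1
  Z1 <- matrix(0, n, 9 * f1)
  for (p in 1:9) {
    Z1[, ((p - 1) * f1 + 1):(p * f1)] <-
      X[, model$idx1[p, ], drop = FALSE] %*% W$W1 +
      matrix(W$b1, n, f1, byrow = TRUE)
  }
  A1 <- pmax(Z1, 0)
  Z2 <- A1 %*% W$W2 + matrix(W$b2, n, model$n_filters2, byrow = TRUE)
  A2 <- pmax(Z2, 0)
  Z3 <- A2 %*% W$W3 + matrix(W$b3, n, model$n_hidden, byrow = TRUE)
  A3 <- pmax(Z3, 0)
  if (!is.null(drop_mask)) A3 <- A3 * drop_mask / (1 - model$dropout)
  logits <- A3 %*% W$W4 + matrix(W$b4, n, model$n_classes, byrow = TRUE)
  m <- apply(logits, 1, max)
  e <- exp(logits - m)
  probs <- e / rowSums(e)
  list(Z1 = Z1, A1 = A1, Z2 = Z2, A2 = A2, Z3 = Z3, A3 = A3, probs = probs)
}

#' Predict class probabilities for patches
#'
#' @param object a `tissue_model`.
#' @param newdata `n x 75` matrix of flattened patches (or a
#'   `tissue_dataset`).
#' @param ... unused.
#' @return `n x n_classes` matrix of softmax probabilities (rows sum to 1).
#' @export
predict.tissue_model <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "tissue_dataset")) newdata$x else newdata
  forward_pass(object, X)$probs
}

#' Multi-class cross-entropy loss
#'
#' `-sum_k z_k log p_k` with the natural logarithm; probabilities are clamped
#' at `1e-12` before the log.  Used both for the tissue term and the size term
#' of the combined objective.
#'
#' @param true_onehot one-hot vector (or `n x k` matrix) of true classes.
#' @param predicted_probs probability vector (or `n x k` matrix) summing to 1
#'   per example.
#' @return loss value (or vector of per-example losses).
#' @export
cross_entropy_loss <- function(true_onehot, predicted_probs) {
  z <- rbind(true_onehot); p <- rbind(predicted_probs)
  if (!all(dim(z) == dim(p)))
    stop_wm("one-hot and probability shapes differ", class = "input_error")
  if (any(abs(rowSums(p) - 1) > 1e-6))
    stop_wm("probabilities must sum to 1", class = "input_error")
  out <- -rowSums(z * log(pmax(p, 1e-12)))
  if (is.vector(true_onehot) && is.vector(predicted_probs)) out[[1]] else out
}

#' Combined size + tissue training objective
#'
#' `J = sum_i (Ls_i + Lt_i)` over the examples, the sum of the per-example
#' size-classification and tissue-classification cross-entropies.
#'
#' @param size_losses,tissue_losses equal-length numeric vectors of
#'   per-example losses.
#' @return list with `total` (J) and `mean` (J / n).
#' @export
combined_objective <- function(size_losses, tissue_losses) {
  if (length(size_losses) != length(tissue_losses))
    stop_wm("loss vectors must have equal length", class = "input_error")
  tot <- sum(size_losses + tissue_losses)
  list(total = tot, mean = tot / length(size_losses))
}

onehot <- function(y, k) {
  m <- matrix(0, length(y), k)
  m[cbind(seq_along(y), y)] <- 1
  m
}

mean_ce <- function(model, X, y) {
  p <- forward_pass(model, X)$probs
  mean(cross_entropy_loss(onehot(y, model$n_classes), p))
}

#' Train the tissue classifier
#'
#' Mini-batch SGD on the mean tissue cross-entropy, deterministic under the
#' configuration seed.  A 10% tail of the (shuffled) training set is held out
#' for early stopping; training stops when the validation loss has not
#' improved for `patience` epochs, and the best-validation weights are kept.
#' With `epochs = 0` the model is returned unchanged (apart from the recorded
#' initial loss).
#'
#' @param model a [tissue_model()].
#' @param train a `tissue_dataset` (training split).
#' @param config a [training_config()].
#' @return the trained `tissue_model` with `loss_trajectory` (training loss
#'   per epoch, starting with the pre-training loss) and `training_config`
#'   recorded.
#' @export
train_tissue_model <- function(model, train, config = training_config()) {
  X <- train$x; y <- train$y
  if (!length(y)) stop_wm("empty training set", class = "input_error")
  nc <- model$n_classes
  perm <- with_seed(config$seed, sample(length(y)))
  nval <- max(0L, min(length(y) - 1L, floor(config$val_fraction * length(y))))
  val_idx <- if (nval > 0) perm[seq_len(nval)] else integer(0)
  tr_idx <- setdiff(perm, val_idx)
  Xt <- X[tr_idx, , drop = FALSE]; yt <- y[tr_idx]
  Xv <- X[val_idx, , drop = FALSE]; yv <- y[val_idx]

  traj <- mean_ce(model, Xt, yt)
  model$loss_trajectory <- traj
  model$training_config <- config
  if (config$epochs == 0) return(model)

  W <- model$weights
  f1 <- model$n_filters1
  best <- list(W = W, val = if (nval) mean_ce(model, Xv, yv) else Inf, epoch = 0L)
  stall <- 0L
  rng_stream <- config$seed + 1000L
  for (epoch in seq_len(config$epochs)) {
    ord <- with_seed(rng_stream + epoch, sample(length(yt)))
    nb <- ceiling(length(yt) / config$batch_size)
    for (b in seq_len(nb)) {
      idx <- ord[((b - 1) * config$batch_size + 1):min(b * config$batch_size, length(yt))]
      Xb <- Xt[idx, , drop = FALSE]; yb <- yt[idx]
      n <- nrow(Xb)
      dm <- with_seed(rng_stream + 10000L + epoch * 1000L + b,
                      matrix(runif(n * model$n_hidden) >= model$dropout,
                             n, model$n_hidden))
      model$weights <- W
      fw <- forward_pass(model, Xb, drop_mask = dm)
      # backprop
      dlogits <- (fw$probs - onehot(yb, nc)) / n
      gW4 <- t(fw$A3) %*% dlogits; gb4 <- colSums(dlogits)
      dA3 <- dlogits %*% t(W$W4)
      dA3 <- dA3 * dm / (1 - model$dropout)
      dZ3 <- dA3 * (fw$Z3 > 0)
      gW3 <- t(fw$A2) %*% dZ3; gb3 <- colSums(dZ3)
      dA2 <- dZ3 %*% t(W$W3)
      dZ2 <- dA2 * (fw$Z2 > 0)
      gW2 <- t(fw$A1) %*% dZ2; gb2 <- colSums(dZ2)
      dA1 <- dZ2 %*% t(W$W2)
      dZ1 <- dA1 * (fw$Z1 > 0)
      gW1 <- matrix(0, 27, f1); gb1 <- rep(0, f1)
      for (p in 1:9) {
        dzp <- dZ1[, ((p - 1) * f1 + 1):(p * f1), drop = FALSE]
        gW1 <- gW1 + t(Xb[, model$idx1[p, ], drop = FALSE]) %*% dzp
        gb1 <- gb1 + colSums(dzp)
      }
      lr <- config$learning_rate
      W$W1 <- W$W1 - lr * gW1; W$b1 <- W$b1 - lr * gb1
      W$W2 <- W$W2 - lr * gW2; W$b2 <- W$b2 - lr * gb2
      W$W3 <- W$W3 - lr * gW3; W$b3 <- W$b3 - lr * gb3
      W$W4 <- W$W4 - lr * gW4; W$b4 <- W$b4 - lr * gb4
    }
    model$weights <- W
    tr_loss <- mean_ce(model, Xt, yt)
    if (!is.finite(tr_loss))
      stop_wm("training diverged at epoch ", epoch, " (loss not finite)",
              class = "training_error")
    traj <- c(traj, tr_loss)
    if (nval) {
      val_loss <- mean_ce(model, Xv, yv)
      if (val_loss < best$val - 1e-6) {
        best <- list(W = W, val = val_loss, epoch = epoch)
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= config$patience) break
      }
    }
  }
  if (nval) model$weights <- best$W
  model$loss_trajectory <- traj
  model$trained <- TRUE
  model
}

#' @export
print.tissue_model <- function(x, ...) {
  cat(sprintf("<tissue_model: conv(%d)-conv(%d)-dense(%d)-dropout(%.1f)-softmax(%d); %s>\n",
              x$n_filters1, x$n_filters2, x$n_hidden, x$dropout, x$n_classes,
              if (x$trained) sprintf("trained, final loss %.4f",
                                     tail(x$loss_trajectory, 1))
              else "untrained"))
  invisible(x)
}

#' Evaluate a classifier on a test set
#'
#' Argmax predictions are scored against the labels: per-class precision,
#' recall and F1 from the confusion matrix, their unweighted macro averages,
#' and overall accuracy.  A class absent from the test set has undefined
#' recall, reported as `NaN` with a warning.
#'
#' @param model a trained `tissue_model`.
#' @param test a `tissue_dataset`.
#' @return object of class `eval_report`: `confusion` (true x predicted),
#'   `per_class` data frame (class, precision, recall, f1, support),
#'   `macro_avg`, `overall_accuracy`.
#' @export
evaluate_model <- function(model, test) {
  if (!length(test$y)) stop_wm("empty test set", class = "input_error")
  probs <- predict(model, test)
  pred <- max.col(probs, ties.method = "first")
  k <- model$n_classes
  confusion <- matrix(0L, k, k,
                      dimnames = list(true = names(tissue_legend())[1:k],
                                      predicted = names(tissue_legend())[1:k]))
  for (i in seq_along(test$y))
    confusion[test$y[i], pred[i]] <- confusion[test$y[i], pred[i]] + 1L
  eval_report_from_confusion(confusion)
}

# Precision/recall/F1 arithmetic, separated from prediction so a confusion
# matrix from any source can be scored.
eval_report_from_confusion <- function(confusion) {
  support <- rowSums(confusion)
  tp <- diag(confusion)
  prec <- ifelse(colSums(confusion) > 0, tp / colSums(confusion), NaN)
  rec <- ifelse(support > 0, tp / support, NaN)
  if (any(support == 0))
    warning("class absent from the test set: recall undefined (NaN)")
  f1 <- ifelse(is.nan(prec) | is.nan(rec) | (prec + rec) == 0,
               ifelse(is.nan(prec) | is.nan(rec), NaN, 0),
               2 * prec * rec / (prec + rec))
  structure(list(
    confusion = confusion,
    per_class = data.frame(class = rownames(confusion), precision = prec,
                           recall = rec, f1 = f1, support = as.integer(support),
                           row.names = NULL),
    macro_avg = c(precision = mean(prec), recall = mean(rec), f1 = mean(f1)),
    overall_accuracy = sum(tp) / sum(confusion)),
    class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("Tissue classification report\n")
  print(x$per_class, digits = 3)
  cat(sprintf("macro F1 %.3f, overall accuracy %.3f\n",
              x$macro_avg["f1"], x$overall_accuracy))
  invisible(x)
}

#' Size category from measured area
#'
#' Left-closed bins: small for `area < small_max`, medium for
#' `small_max <= area < medium_max`, large otherwise.
#'
#' @param area_cm2 measured wound area, cm^2.
#' @param thresholds `(small_max, medium_max)` in cm^2, increasing.
#' @return `"small"`, `"medium"` or `"large"`.
#' @export
size_category <- function(area_cm2, thresholds = c(5, 20)) {
  if (any(area_cm2 < 0)) stop_wm("area must be >= 0", class = "input_error")
  if (thresholds[1] >= thresholds[2] || any(thresholds <= 0))
    stop_wm("thresholds must be positive and increasing", class = "input_error")
  cut(area_cm2, c(-Inf, thresholds, Inf), labels = c("small", "medium", "large"),
      right = FALSE)
}

#' Tissue fractions of a wound region
#'
#' Classifies every 5 x 5 patch of the preprocessed region and returns the
#' fraction of patches assigned to each tissue class (sums to 1).
#'
#' @param model a trained `tissue_model`.
#' @param image an [rgb_image()].
#' @param roi the wound [binary_mask()].
#' @return named numeric vector of tissue fractions.
#' @export
classify_tissue_fractions <- function(model, image, roi) {
  proc <- preprocess_roi(image, roi)
  lab <- preprocess_labels(label_mask(matrix(1L, dim(image)[1], dim(image)[2])),
                           roi)
  ds <- extract_patches(proc, lab)
  if (!length(ds$y)) stop_wm("no patches inside the ROI", class = "input_error")
  pred <- max.col(predict(model, ds), ties.method = "first")
  counts <- tabulate(pred, nbins = model$n_classes)
  setNames(counts / sum(counts), names(tissue_legend())[1:model$n_classes])
}

#' Serialise a tissue model to portable JSON
#'
#' Architecture, weights and training configuration in one text file;
#' [load_tissue_model()] restores it.
#'
#' @param model a `tissue_model`.
#' @param path destination .json path.
#' @export
save_tissue_model <- function(model, path) {
  obj <- list(n_classes = model$n_classes, n_filters1 = model$n_filters1,
              n_filters2 = model$n_filters2, n_hidden = model$n_hidden,
              dropout = model$dropout, trained = model$trained,
              loss_trajectory = model$loss_trajectory,
              training_config = unclass(model$training_config),
              weights = lapply(model$weights, function(w)
                if (is.matrix(w)) list(dim = dim(w), data = as.vector(w))
                else list(dim = NULL, data = as.vector(w))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}

#' Load a tissue model saved by [save_tissue_model()]
#'
#' @param path .json path.
#' @return a `tissue_model`.
#' @export
load_tissue_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  model <- tissue_model(n_classes = obj$n_classes, n_filters1 = obj$n_filters1,
                        n_filters2 = obj$n_filters2, n_hidden = obj$n_hidden,
                        dropout = obj$dropout)
  model$weights <- lapply(obj$weights, function(w) {
    if (!is.null(w$dim) && length(w$dim)) matrix(w$data, w$dim[1], w$dim[2])
    else as.numeric(w$data)
  })
  model$trained <- obj$trained
  model$loss_trajectory <- as.numeric(obj$loss_trajectory)
  if (!is.null(obj$training_config) && length(obj$training_config))
    model$training_config <- structure(as.list(obj$training_config),
                                       class = "training_config")
  model
}
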