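#' Tracing-agreement metrics
#'
#' Agreement between a reference wound tracing and a test tracing, expressed
#' with the planimetry error metrics used to validate digital wound
#' measurement: with `R` the reference area, `T` the test area and `O` their
#' overlap,
#'
#' \deqn{FNR = 100 (R - O) / R} (reference area the test tracing missed),
#' \deqn{FPR = 100 (T - O) / R} (extra test area, normalised by the reference),
#' \deqn{RV  = 100 (T - R) / R} (signed relative area variance; ARV = |RV|),
#'
#' plus Jaccard `O / (R + T - O)` and Dice `2O / (R + T)`.  When both tracings
#' are empty ("full epithelialisation" on both) no comparison is meaningful
#' and the pair is flagged non-comparable.  Note ARV can be zero for disjoint
#' tracings of equal area: it ignores boundary location by design.
#'
#' @name area_metrics
NULL

#' Compare two tracings
#'
#' @param reference,test [binary_mask()]s (or logical matrices) of identical
#'   dimensions.
#' @return object of class `tracing_comparison` with fields `R`, `T`, `O`,
#'   `fnr_pct`, `fpr_pct`, `rv_pct`, `arv_pct`, `jaccard`, `dice`,
#'   `comparable`, `degenerate`.  When `R = 0` but `T > 0` (only the reference
#'   saw full epithelialisation) the reference-normalised metrics are
#'   undefined; the pair is flagged `degenerate` and FPR is reported
#'   normalised by `T` instead.
#' @export
compare_tracings <- function(reference, test) {
  if (!all(dim(reference) == dim(test)))
    stop_wm("tracings must share dimensions", class = "input_error")
  ref <- as.logical(reference); tst <- as.logical(test)
  R <- sum(ref); T <- sum(tst); O <- sum(ref & tst)
  out <- list(R = R, T = T, O = O, comparable = TRUE, degenerate = FALSE,
              fnr_pct = NA_real_, fpr_pct = NA_real_, rv_pct = NA_real_,
              arv_pct = NA_real_, jaccard = NA_real_, dice = NA_real_)
  if (R == 0 && T == 0) {
    out$comparable <- FALSE
    return(structure(out, class = "tracing_comparison"))
  }
  if (R == 0) {
    out$degenerate <- TRUE
    out$fpr_pct <- 100 * (T - O) / T
    out$jaccard <- O / (R + T - O)
    out$dice <- 2 * O / (R + T)
    return(structure(out, class = "tracing_comparison"))
  }
  out$fnr_pct <- 100 * (R - O) / R
  out$fpr_pct <- 100 * (T - O) / R
  out$rv_pct <- 100 * (T - R) / R
  out$arv_pct <- abs(out$rv_pct)
  out$jaccard <- O / (R + T - O)
  out$dice <- 2 * O / (R + T)
  structure(out, class = "tracing_comparison")
}

#' @export
print.tracing_comparison <- function(x, ...) {
  if (!x$comparable) {
    cat("<tracing_comparison: non-comparable (both tracings empty)>\n")
  } else {
    cat(sprintf("<tracing_comparison: R=%d T=%d O=%d | FNR %.2f%% FPR %.2f%% RV %+.2f%% Dice %.3f>\n",
                x$R, x$T, x$O, x$fnr_pct, x$fpr_pct,
                if (is.na(x$rv_pct)) NA else x$rv_pct, x$dice))
  }
  invisible(x)
}

#' Intraclass correlation, two-way random effects, absolute agreement
#'
#' ICC(2,1) for single measurements: wounds (rows) and raters/methods
#' (columns) are both treated as random, and systematic offsets between
#' raters count against agreement.  Computed from the two-way mean squares:
#' \deqn{ICC = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E + \frac{k}{n}(MS_C - MS_E)}}
#' with `n` wounds and `k` raters.
#'
#' @param table numeric matrix, rows = wounds, columns = raters/methods, no
#'   missing cells, at least 2 x 2.
#' @return ICC estimate in `(-1, 1]`; `NaN` (with a warning) when the table
#'   has no between-row variance to support the decomposition.
#' @export
icc_absolute_agreement <- function(table) {
  table <- as.matrix(table)
  if (nrow(table) < 2 || ncol(table) < 2)
    stop_wm("rater table must be at least 2 x 2", class = "input_error")
  if (anyNA(table))
    stop_wm("rater table must have no missing cells", class = "input_error")
  n <- nrow(table); k <- ncol(table)
  row_m <- rowMeans(table); col_m <- colMeans(table); grand <- mean(table)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sse <- sum((table - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + k * (msc - mse) / n
  if (denom <= 0 || (msr == 0 && mse == 0)) {
    warning("ICC undefined: no variance to decompose")
    return(NaN)
  }
  (msr - mse) / denom
}

#' Score a batch of predicted wound masks against rendered ground truth
#'
#' Applies [compare_tracings()] per scene, excludes non-comparable pairs (both
#' masks empty) and summarises each metric by its mean and median.
#'
#' @param scenes list of `wound_scene` objects (the ground truth).
#' @param predictions index-aligned list of predicted [binary_mask()]s.
#' @return object of class `pipeline_summary`: `per_scene` data frame,
#'   `summary` data frame (metric, mean, median), `n_excluded`.
#' @export
pipeline_vs_truth <- function(scenes, predictions) {
  if (length(scenes) != length(predictions))
    stop_wm("scenes and predictions must have equal length", class = "input_error")
  comps <- lapply(seq_along(scenes), function(i)
    compare_tracings(scenes[[i]]$wound_mask, predictions[[i]]))
  keep <- vapply(comps, `[[`, logical(1), "comparable")
  metrics <- c("fnr_pct", "fpr_pct", "rv_pct", "arv_pct", "jaccard", "dice")
  per_scene <- data.frame(scene = seq_along(scenes), comparable = keep)
  for (m in metrics)
    per_scene[[m]] <- vapply(comps, function(x) x[[m]] %||% NA_real_, numeric(1))
  kept <- per_scene[keep, , drop = FALSE]
  summary <- data.frame(
    metric = metrics,
    mean = vapply(metrics, function(m) mean(kept[[m]], na.rm = TRUE), numeric(1)),
    median = vapply(metrics, function(m) median(kept[[m]], na.rm = TRUE), numeric(1)),
    row.names = NULL)
  structure(list(per_scene = per_scene, summary = summary,
                 n_excluded = sum(!keep)),
            class = "pipeline_summary")
}

#' @export
print.pipeline_summary <- function(x, ...) {
  cat(sprintf("<pipeline_summary: %d scenes, %d non-comparable excluded>\n",
              nrow(x$per_scene), x$n_excluded))
  print(x$summary)
  invisible(x)
}
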