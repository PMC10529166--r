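test_that("tracing metrics reproduce the planimetry definitions exactly", {
  # R = 100, O = 80, T = 90 by construction on a 10 x 30 grid
  ref <- matrix(FALSE, 10, 30); ref[, 1:10] <- TRUE          # 100 px
  tst <- matrix(FALSE, 10, 30); tst[, 3:11] <- TRUE          # 90 px, O = 80
  cmp <- compare_tracings(binary_mask(ref), binary_mask(tst))
  expect_equal(cmp$R, 100); expect_equal(cmp$T, 90); expect_equal(cmp$O, 80)
  expect_equal(cmp$fnr_pct, 20.0)
  expect_equal(cmp$fpr_pct, 10.0)
  expect_equal(cmp$rv_pct, -10.0)
  expect_equal(cmp$arv_pct, 10.0)

  idc <- compare_tracings(binary_mask(ref), binary_mask(ref))
  expect_equal(idc$fnr_pct, 0); expect_equal(idc$fpr_pct, 0)
  expect_equal(idc$rv_pct, 0); expect_equal(idc$jaccard, 1)
  expect_equal(idc$dice, 1)
})

test_that("metrics agree with a brute-force set-operation oracle on random pairs", {
  withr::with_seed(99, {
    for (i in 1:15) {
      p <- random_mask_pair()
      got <- compare_tracings(p$ref, p$test)
      o <- oracle_metrics(p$ref, p$test)
      expect_equal(got$fnr_pct, o$fnr, tolerance = 1e-12)
      expect_equal(got$fpr_pct, o$fpr, tolerance = 1e-12)
      expect_equal(got$rv_pct, o$rv, tolerance = 1e-12)
      expect_equal(got$jaccard, o$jac, tolerance = 1e-12)
      expect_equal(got$dice, o$dice, tolerance = 1e-12)
      # invariants
      expect_equal(got$fnr_pct + 100 * got$O / got$R, 100)
      expect_lte(got$jaccard, got$dice)
      expect_equal(got$dice,
                   compare_tracings(p$test, p$ref)$dice)  # symmetry
      # FNR/FPR swap roles under argument exchange, scaled by the area ratio
      rev <- compare_tracings(p$test, p$ref)
      expect_equal(rev$fpr_pct * rev$R / got$R, got$fnr_pct, tolerance = 1e-9)
    }
  })
})

test_that("ARV ignores boundary location: disjoint equal-area tracings give 0", {
  a <- matrix(FALSE, 20, 40); a[5:10, 2:11] <- TRUE
  b <- matrix(FALSE, 20, 40); b[5:10, 25:34] <- TRUE
  cmp <- compare_tracings(binary_mask(a), binary_mask(b))
  expect_equal(cmp$arv_pct, 0)
  expect_equal(cmp$fnr_pct, 100)
  expect_equal(cmp$dice, 0)
})

test_that("full epithelialisation on both tracings is non-comparable", {
  e <- binary_mask(matrix(FALSE, 5, 5))
  cmp <- compare_tracings(e, e)
  expect_false(cmp$comparable)
  expect_true(is.na(cmp$fnr_pct) && is.na(cmp$dice))

  # only the reference empty: degenerate, FPR normalised by T instead
  t1 <- binary_mask(matrix(c(rep(TRUE, 5), rep(FALSE, 20)), 5, 5))
  dg <- compare_tracings(e, t1)
  expect_true(dg$comparable)
  expect_true(dg$degenerate)
  expect_equal(dg$fpr_pct, 100)
  expect_true(is.na(dg$fnr_pct))

  expect_error(compare_tracings(e, binary_mask(matrix(FALSE, 4, 4))),
               class = "input_error")
})

test_that("ICC(2,1) matches the two-way ANOVA mean-squares oracle", {
  tab <- matrix(c(9, 2, 5, 8,
                  6, 1, 3, 2,
                  8, 4, 6, 8,
                  7, 1, 2, 6,
                  10, 5, 6, 9,
                  6, 2, 4, 7), 6, 4, byrow = TRUE)
  got <- icc_absolute_agreement(tab)
  # independent oracle: mean squares from stats::aov on the long layout
  long <- data.frame(y = as.vector(tab),
                     row = factor(rep(1:6, 4)), col = factor(rep(1:4, each = 6)))
  ms <- summary(stats::aov(y ~ row + col, data = long))[[1]][["Mean Sq"]]
  n <- 6; k <- 4
  oracle <- (ms[1] - ms[3]) / (ms[1] + (k - 1) * ms[3] + k * (ms[2] - ms[3]) / n)
  expect_equal(got, oracle, tolerance = 1e-12)
})

test_that("ICC reaches 1 for identical raters and ~0 for pure noise", {
  x <- c(1.2, 3.4, 2.2, 5.1, 4.4, 0.7)
  expect_equal(icc_absolute_agreement(cbind(x, x, x)), 1.0)

  noisy <- withr::with_seed(7, {
    rows <- rnorm(100, 0, 0.05)
    rows + matrix(rnorm(300, 0, 10), 100, 3)
  })
  expect_lt(abs(icc_absolute_agreement(noisy)), 0.2)

  expect_warning(out <- icc_absolute_agreement(matrix(2, 5, 3)))
  expect_true(is.nan(out))
  expect_error(icc_absolute_agreement(matrix(1:2, 1, 2)), class = "input_error")
})

test_that("batch scoring aggregates per-scene metrics and excludes empty pairs", {
  scenes <- lapply(0:2, function(s) render_scene(small_scene_spec(seed = s)))
  preds <- lapply(scenes, `[[`, "wound_mask")
  out <- pipeline_vs_truth(scenes, preds)
  expect_equal(out$summary$median[out$summary$metric == "fnr_pct"], 0)
  expect_equal(out$summary$median[out$summary$metric == "dice"], 1)
  expect_equal(out$n_excluded, 0)

  # an empty/empty pair is excluded and counted
  fake <- scenes
  fake[[2]]$wound_mask <- binary_mask(matrix(FALSE, 150, 220))
  preds2 <- preds
  preds2[[2]] <- binary_mask(matrix(FALSE, 150, 220))
  out2 <- pipeline_vs_truth(fake, preds2)
  expect_equal(out2$n_excluded, 1)

  # summary medians equal recomputation from the per-pair oracle
  preds3 <- lapply(scenes, function(s) {
    m <- unclass(s$wound_mask)
    m[1:40, ] <- FALSE
    binary_mask(m)
  })
  out3 <- pipeline_vs_truth(scenes, preds3)
  oracle_fnr <- median(vapply(seq_along(scenes), function(i)
    oracle_metrics(scenes[[i]]$wound_mask, preds3[[i]])$fnr, numeric(1)))
  expect_equal(out3$summary$median[out3$summary$metric == "fnr_pct"], oracle_fnr)

  expect_error(pipeline_vs_truth(scenes, preds[1:2]), class = "input_error")
})
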