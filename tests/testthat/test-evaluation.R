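test_that("stratified folds reproduce the study-dimension allocation", {
  y <- c(rep(1, 63), rep(0, 99))
  folds <- stratified_folds(y, 5, seed = 2)
  expect_equal(sort(lengths(folds), decreasing = TRUE), c(33, 33, 32, 32, 32))
  expect_equal(sort(vapply(folds, function(i) sum(y[i]), numeric(1)),
                    decreasing = TRUE), c(13, 13, 13, 12, 12))
  all_idx <- sort(unlist(folds))
  expect_equal(all_idx, seq_along(y))  # disjoint partition
  expect_identical(stratified_folds(y, 5, seed = 2),
                   stratified_folds(y, 5, seed = 2))
})

test_that("k = n yields leave-one-out; small classes error", {
  y <- c(0, 1, 0, 1)
  folds <- stratified_folds(y, 4, seed = 1)
  expect_true(all(lengths(folds) == 1L))
  expect_error(stratified_folds(c(0, 0, 0, 1), 2), "stratification error")
})

test_that("SMOTE balances classes with convex-combination synthetic rows", {
  X <- matrix(withr::with_seed(3, rnorm(15 * 4)), 15)
  y <- c(rep(1, 5), rep(0, 10))
  expect_warning(sm <- smote_oversample(X, y, k_neighbors = 5, seed = 7),
                 "shrunk")
  expect_equal(as.vector(table(sm$y)), c(10, 10))
  expect_equal(sm$X[1:15, ], X)  # originals unchanged
  minority <- X[y == 1, , drop = FALSE]
  synth <- sm$X[sm$synthetic, , drop = FALSE]
  for (r in seq_len(nrow(synth))) {
    # componentwise betweenness of some minority pair
    ok <- any(apply(minority, 1, function(a) {
      any(apply(minority, 1, function(b) {
        all(synth[r, ] >= pmin(a, b) - 1e-12 & synth[r, ] <= pmax(a, b) + 1e-12)
      }))
    }))
    expect_true(ok)
  }
})

test_that("SMOTE no-ops on balanced input and errors on singleton minority", {
  X <- matrix(1:8, 4)
  sm <- smote_oversample(X, c(0, 1, 0, 1))
  expect_equal(sm$X, X)
  expect_false(any(sm$synthetic))
  expect_error(smote_oversample(X, c(0, 0, 0, 1)), "single member")
  # 1-D minority {0, 1}: convexity keeps synthetics inside [0, 1]
  X1 <- matrix(c(0, 1, 5, 6, 7, 8), ncol = 1)
  sm1 <- smote_oversample(X1, c(1, 1, 0, 0, 0, 0), k_neighbors = 1, seed = 4)
  expect_true(all(sm1$X[sm1$synthetic, ] >= 0 & sm1$X[sm1$synthetic, ] <= 1))
})

test_that("confusion metrics follow the closed forms with explicit NA reasons", {
  m <- metrics_from_counts(confusion_counts(1, 1, 1, 1))
  expect_equal(unlist(m[c("accuracy", "sensitivity", "precision", "f1")]),
               c(accuracy = 0.5, sensitivity = 0.5, precision = 0.5, f1 = 0.5))
  m <- metrics_from_counts(confusion_counts(tp = 0, tn = 10, fp = 0, fn = 0))
  expect_equal(m$accuracy, 1)
  expect_true(is.na(m$precision))
  expect_match(m$reasons[["precision"]], "no positive predictions")
  expect_error(metrics_from_counts(confusion_counts(0, 0, 0, 0)),
               "no evaluated instances")
})

test_that("count metrics agree with an independent direct implementation", {
  withr::with_seed(11, {
    for (i in 1:200) {
      cts <- rmultinom(1, sample(10:500, 1), prob = runif(4, 0.05, 1))
      tp <- cts[1]; tn <- cts[2]; fp <- cts[3]; fn <- cts[4]
      m <- metrics_from_counts(confusion_counts(tp, tn, fp, fn))
      expect_equal(m$accuracy, (tp + tn) / sum(cts))
      if (tp + fn > 0) expect_equal(m$sensitivity, tp / (tp + fn))
      if (tp + fp > 0) expect_equal(m$precision, tp / (tp + fp))
      if (tp + fn > 0 && tp + fp > 0 && (m$sensitivity + m$precision) > 0) {
        expect_equal(m$f1, 2 * m$sensitivity * m$precision /
                       (m$sensitivity + m$precision))
      }
    }
  })
})

test_that("probability metrics match closed forms and a pair-counting oracle", {
  y <- c(1, 0, 1, 0)
  expect_equal(probability_metrics(y, y)$brier, 0)
  expect_equal(probability_metrics(y, y)$roc_auc, 1)
  expect_equal(probability_metrics(rep(0.5, 10), rep(0:1, 5))$brier, 0.25)

  pm <- probability_metrics(c(0.9, 0.8, 0.3, 0.1), y)
  # concordant pairs / total pairs over all 4 positive-negative pairs
  pos <- c(0.9, 0.3); neg <- c(0.8, 0.1)
  conc <- sum(outer(pos, neg, ">")) + 0.5 * sum(outer(pos, neg, "=="))
  expect_equal(pm$roc_auc, conc / 4)
  expect_equal(pm$roc_auc, 0.75)

  pm1 <- probability_metrics(rep(0.7, 4), rep(1, 4))
  expect_true(is.na(pm1$roc_auc))
  expect_match(pm1$reasons[["roc_auc"]], "single-class")
})

test_that("trapezoidal ROC-AUC agrees with pROC on random data including ties", {
  skip_if_not_installed("pROC")
  withr::with_seed(13, {
    for (i in 1:20) {
      n <- sample(20:80, 1)
      y <- rbinom(n, 1, 0.4)
      if (length(unique(y)) < 2) next
      p <- round(runif(n), 1)  # coarse grid forces ties
      ours <- probability_metrics(p, y)$roc_auc
      ref <- as.numeric(pROC::auc(pROC::roc(y, p, quiet = TRUE,
                                            direction = "<",
                                            levels = c(0, 1))))
      expect_equal(ours, ref, tolerance = 1e-10)
    }
  })
})

test_that("calibration bins partition all predictions", {
  withr::with_seed(17, {
    p <- runif(500); y <- rbinom(500, 1, p)
    cal <- probability_metrics(p, y)$calibration
    expect_equal(sum(cal$count), 500)
    expect_true(all(cal$observed_frequency >= 0 & cal$observed_frequency <= 1,
                    na.rm = TRUE))
  })
})

test_that("paired fold test matches the closed form and reports exact ties", {
  a <- c(2, 4, 6, 8, 10); b <- c(1, 2, 3, 4, 5)  # differences 1..5
  r <- paired_fold_test(a, b)
  expect_equal(r$mean_difference, 3)
  expect_equal(r$t, 3 / (sd(1:5) / sqrt(5)))
  expect_equal(r$t, 3 * sqrt(5) / sqrt(2.5))
  expect_equal(mean(r$conf_int), r$mean_difference)  # CI symmetric
  ref <- t.test(a, b, paired = TRUE)
  expect_equal(r$t, unname(ref$statistic))
  expect_equal(r$p_value, ref$p.value)
  tie <- paired_fold_test(a, a)
  expect_true(tie$tie)
  expect_equal(tie$mean_difference, 0)
})

test_that("cross_validate is leakage-audited, pooled-exact and deterministic", {
  co <- fixture_cohort(n = 150, seed = 61)
  spec <- model_spec("simple", "cart", seed = 3)
  cv <- cv_config(seed = 19)
  r1 <- cross_validate(spec, co, cv)
  expect_equal(r1$audit$contaminated_test_rows, 0L)
  expect_true(r1$audit$folds_partition_n)
  expect_equal(r1$pooled_counts$total, nrow(co))
  expect_equal(nrow(r1$fold_metrics), 5L)
  r2 <- cross_validate(spec, co, cv)
  expect_identical(r1$fold_metrics, r2$fold_metrics)
  expect_identical(r1$predictions, r2$predictions)
})

test_that("ablation fold-score differences are rerun-stable", {
  co <- fixture_cohort(n = 120, seed = 67)
  cv <- cv_config(seed = 23)
  s2 <- model_spec("lr_hybrid", "cart", seed = 4)
  s3 <- model_spec("abc_lr_hybrid", "cart", abc = abc_config(6, 5, seed = 4),
                   seed = 4)
  d1 <- cross_validate(s3, co, cv)$fold_metrics$f1 -
    cross_validate(s2, co, cv)$fold_metrics$f1
  d2 <- cross_validate(s3, co, cv)$fold_metrics$f1 -
    cross_validate(s2, co, cv)$fold_metrics$f1
  expect_identical(d1, d2)
})

test_that("comparison_table formats percentages and isolates failures", {
  expect_equal(format_percent(0.913580), "91.36")
  co <- fixture_cohort(n = 100, seed = 71)
  tab <- comparison_table(co, model_grid(bases = "cart", stages = "simple",
                                         seed = 2),
                          cv_config(seed = 3), quiet = TRUE)
  expect_equal(nrow(tab), 1L)
  expect_false(tab$failed)
  expect_true(tab$best)
  expect_equal(tab$accuracy, round(attr(tab, "reports")[["CART"]]$
                                     mean_metrics$accuracy * 100, 2))
})
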