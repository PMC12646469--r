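test_that("l1_select returns the lasso support and honours the penalty limit", {
  co <- fixture_cohort(n = 500, seed = 17,
                       beta = c(omega3 = 2, folic_acid = 2, coq10 = 2))
  X <- cohort_matrix(co); y <- cohort_outcome(co)
  m <- l1_select(X, y, strength = 0.05)
  expect_s3_class(m, "feature_mask")
  expect_true(all(m[c("omega3", "folic_acid", "coq10")] == 1))
  # extreme penalty: empty mask, flagged infeasible, not an error
  m0 <- l1_select(X, y, strength = 10)
  expect_true(attr(m0, "infeasible"))
  expect_error(l1_select(X, rep(1, nrow(X))), "single-class")
})

test_that("the documented reference mask selects the 11 reported features", {
  m <- lr_reference_mask()
  expect_equal(sum(m), 11L)
  expect_true(all(m[c("omega3", "folic_acid", "coq10", "vit_b12", "vit_c",
                      "vit_b6", "vit_d", "phytoalexin", "selenium", "zinc",
                      "dietician_support")] == 1))
  expect_equal(attr(m, "provenance"), "l1_selection")
})

test_that("all 12 grid specifications are constructible and labelled", {
  grid <- model_grid()
  expect_length(grid, 12L)
  expect_setequal(
    names(grid),
    c("RF", "KNN", "SVM", "CART",
      "LR - RF", "LR - KNN", "LR - SVM", "LR - CART",
      "ABC-LR-RF", "ABC-LR-KNN", "ABC-LR-SVM", "ABC-LR-CART"))
  expect_error(model_spec("simple", "boost"), "arg")
})

test_that("stage masks compose as specified", {
  co <- fixture_cohort(n = 200, seed = 23)
  X <- cohort_matrix(co); y <- cohort_outcome(co)
  f1 <- fit_model(model_spec("simple", "rf", seed = 1), X, y)
  expect_true(all(f1$mask == 1L))
  f2 <- fit_model(model_spec("lr_hybrid", "knn", l1_strength = 0.03,
                             seed = 1), X, y)
  expect_equal(as.integer(f2$mask),
               as.integer(l1_select(X, y, strength = 0.03)))
})

test_that("fit/predict honours the probability contract on each learner", {
  # linearly separable toy cohort
  d <- as.data.frame(fixture_cohort(n = 80, seed = 31))
  d$transfer_state <- as.numeric(d$oocyte_count > median(d$oocyte_count))
  co <- cohort_table(d)
  X <- cohort_matrix(co); y <- cohort_outcome(co)
  for (bl in c("rf", "cart")) {
    f <- fit_model(model_spec("simple", bl, seed = 2), X, y)
    expect_equal(mean(predict(f, X, type = "class") == y), 1.0)
  }
  for (bl in c("knn", "svm")) {
    f <- fit_model(model_spec("simple", bl, seed = 2), X, y)
    p <- predict(f, X, type = "prob")
    expect_true(all(p >= 0 & p <= 1))
    expect_equal(as.numeric(p >= 0.5), predict(f, X, type = "class"))
  }
  f <- fit_model(model_spec("simple", "rf", seed = 2), X, y)
  expect_error(predict(f, X[, -3]), "column mismatch")
})

test_that("masked-out features are inert: permuting them leaves predictions unchanged", {
  co <- fixture_cohort(n = 150, seed = 37,
                       beta = c(omega3 = 2.5, folic_acid = 2.5))
  X <- cohort_matrix(co); y <- cohort_outcome(co)
  f <- fit_model(model_spec("lr_hybrid", "cart", l1_strength = 0.08,
                            seed = 3), X, y)
  off <- names(which(f$mask == 0))
  skip_if(length(off) == 0, "mask selected every feature")
  Xp <- X
  Xp[, off[1]] <- withr::with_seed(5, sample(Xp[, off[1]]))
  expect_identical(predict(f, X, type = "prob"),
                   predict(f, Xp, type = "prob"))
})

test_that("ABC search matches exhaustive enumeration of a small mask space", {
  co <- fixture_cohort(n = 120, seed = 41,
                       beta = c(omega3 = 2, folic_acid = 2))
  feats <- table2_features()[1:6]
  X <- cohort_matrix(co)[, feats]
  y <- cohort_outcome(co)
  seed <- 11L

  # independent re-derivation of the wrapper objective (same seeds/folds)
  folds <- stratified_folds(y, 3, seed = derive_seed(seed, "inner_cv"))
  objective <- function(mask) {
    key <- paste(mask, collapse = "")
    scores <- vapply(seq_along(folds), function(f) {
      test <- folds[[f]]; train <- setdiff(seq_along(y), test)
      sm <- smote_oversample(X[train, mask == 1, drop = FALSE], y[train],
                             seed = derive_seed(seed, paste0("smote", f)))
      bf <- ivfabc:::fit_base("cart", sm$X, sm$y, list())
      probs <- ivfabc:::predict_prob_base(bf, X[test, mask == 1, drop = FALSE])
      ivfabc:::fitness_score(probs, y[test], "f1")
    }, numeric(1))
    1 - mean(scores)
  }
  masks <- as.matrix(expand.grid(rep(list(0:1), 6)))[-1, ]
  oracle <- min(apply(masks, 1, objective))

  res <- abc_feature_search(X, y, "cart", abc = abc_config(15, 30, seed = seed),
                            seed = seed)
  expect_equal(res$objective, oracle, tolerance = 1e-12)
  expect_true(all(diff(res$trace$best_objective) <= 0))
})

test_that("identical columns make any single-feature mask optimal", {
  co <- fixture_cohort(n = 90, seed = 47, beta = c(dha = 2))
  x <- cohort_matrix(co)[, "dha"]
  X <- matrix(rep(x, 4), ncol = 4,
              dimnames = list(NULL, paste0("f", 1:4)))
  y <- cohort_outcome(co)
  seed <- 5L
  res <- abc_feature_search(X, y, "cart", abc = abc_config(8, 10, seed = seed),
                            seed = seed)
  folds <- stratified_folds(y, 3, seed = derive_seed(seed, "inner_cv"))
  single <- vapply(seq_along(folds), function(f) {
    test <- folds[[f]]; train <- setdiff(seq_along(y), test)
    sm <- smote_oversample(X[train, 1, drop = FALSE], y[train],
                           seed = derive_seed(seed, paste0("smote", f)))
    bf <- ivfabc:::fit_base("cart", sm$X, sm$y, list())
    probs <- ivfabc:::predict_prob_base(bf, X[test, 1, drop = FALSE])
    ivfabc:::fitness_score(probs, y[test], "f1")
  }, numeric(1))
  expect_equal(res$objective, 1 - mean(single), tolerance = 1e-12)
})

test_that("stage-3 fitting is reproducible and records its search trace", {
  co <- fixture_cohort(n = 120, seed = 53)
  X <- cohort_matrix(co)[, 1:8]; y <- cohort_outcome(co)
  spec <- model_spec("abc_lr_hybrid", "knn", abc = abc_config(6, 6, seed = 9),
                     seed = 9)
  fa <- fit_model(spec, X, y)
  fb <- fit_model(spec, X, y)
  expect_identical(as.integer(fa$mask), as.integer(fb$mask))
  expect_identical(fa$trace, fb$trace)
  expect_gte(sum(fa$mask), 1L)
  expect_equal(attr(fa$mask, "provenance"), "abc_search")
})
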