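# The three model stages behind one fit/predict contract: baseline
# classifiers, L1-logistic feature selection feeding classifiers, and
# ABC-driven feature-subset search with cross-validated classifier
# performance as fitness.

#' Construct a feature mask
#'
#' A binary inclusion vector aligned to the cohort's canonical feature
#' order. A mask used for fitting must select at least one feature; an
#' all-zero mask carries an `infeasible` attribute.
#'
#' @param bits 0/1 vector (or logical).
#' @param features optional feature names (attached as names).
#' @param provenance one of `"l1_selection"`, `"abc_search"`, `"manual"`.
#' @return integer vector of class `feature_mask`.
#' @export
feature_mask <- function(bits, features = NULL,
                         provenance = c("manual", "l1_selection", "abc_search")) {
  provenance <- match.arg(provenance)
  m <- as.integer(bits)
  stopifnot(all(m %in% c(0L, 1L)))
  if (!is.null(features)) {
    stopifnot(length(features) == length(m))
    names(m) <- features
  }
  structure(m, class = "feature_mask", provenance = provenance,
            infeasible = all(m == 0L))
}

#' The documented L1-logistic reference feature set
#'
#' The 11-predictor subset reported as the output of L1-regularised
#' logistic feature selection on the original study cohort: omega-3, folic
#' acid, coenzyme Q10, vitamins B12, C, B6 and D, phytoalexin, selenium,
#' zinc, and dietician support. Shipped as a named fixture mask for
#' downstream tests and warm starts; it is not recomputable without the
#' private data.
#'
#' @param features feature order, default [table2_features()].
#' @return a [feature_mask()].
#' @export
lr_reference_mask <- function(features = table2_features()) {
  sel <- c("omega3", "folic_acid", "coq10", "vit_b12", "vit_c", "vit_b6",
           "vit_d", "phytoalexin", "selenium", "zinc", "dietician_support")
  feature_mask(as.integer(features %in% sel), features, "l1_selection")
}

#' L1-regularised logistic feature selection
#'
#' Fits an L1-penalised (lasso) logistic regression at a fixed penalty and
#' returns the indicator of non-zero coefficients. Predictors are
#' standardized internally by glmnet, so the penalty acts comparably
#' across binary and count features.
#'
#' @param X numeric predictor matrix (n x p).
#' @param y 0/1 outcome with both classes present.
#' @param strength lasso penalty (glmnet `lambda`). Larger values select
#'   fewer features; an extreme penalty yields an empty (infeasible) mask,
#'   returned as such for the caller to decide a fallback.
#' @return a [feature_mask()] with provenance `"l1_selection"`.
#' @export
l1_select <- function(X, y, strength = 0.05) {
  X <- as.matrix(X)
  if (length(unique(y)) < 2L) stop("l1_select: single-class outcome", call. = FALSE)
  fit <- glmnet::glmnet(X, y, family = "binomial", alpha = 1,
                        lambda = strength, standardize = TRUE)
  beta <- as.numeric(fit$beta[, 1])
  feature_mask(as.integer(beta != 0), colnames(X), "l1_selection")
}

# ---- base learners ------------------------------------------------------
# One internal contract: fit_base() returns an opaque state;
# predict_prob_base() returns P(class = 1). Standardization (where the
# learner is scale-sensitive) uses training moments only.

default_base_params <- function(learner) {
  switch(learner,
         knn = list(k = 5L),
         cart = list(cp = 0.01, minsplit = 20L),
         svm = list(kernel = "radial", cost = 1),
         rf = list(ntree = 100L),
         stop("unknown base learner '", learner, "'", call. = FALSE))
}

scale_train <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl == 0] <- 1
  list(X = sweep(sweep(X, 2, ctr), 2, scl, "/"), center = ctr, scale = scl)
}

scale_apply <- function(X, sc) sweep(sweep(X, 2, sc$center), 2, sc$scale, "/")

fit_base <- function(learner, X, y, params = list()) {
  X <- as.matrix(X)
  p <- utils::modifyList(default_base_params(learner), params)
  yf <- factor(y, levels = c(0, 1))
  state <- switch(
    learner,
    knn = {
      sc <- scale_train(X)
      list(sc = sc, X = sc$X, y = yf, k = p$k)
    },
    cart = {
      d <- data.frame(X, check.names = FALSE)
      d$.y <- yf
      rpart::rpart(.y ~ ., data = d, method = "class",
                   control = rpart::rpart.control(cp = p$cp,
                                                  minsplit = p$minsplit,
                                                  xval = 0L))
    },
    svm = {
      sc <- scale_train(X)
      m <- e1071::svm(sc$X, yf, kernel = p$kernel, cost = p$cost,
                      scale = FALSE)
      # logistic link on training decision values, so probability-based
      # metrics (Brier, calibration, AUCs) are computable for the SVM too
      dv <- as.numeric(attr(stats::predict(m, sc$X, decision.values = TRUE),
                            "decision.values"))
      sign1 <- if (colnames(attr(stats::predict(m, sc$X[1, , drop = FALSE],
                                                decision.values = TRUE),
                                 "decision.values")) == "0/1") -1 else 1
      dv <- sign1 * dv
      platt <- suppressWarnings(
        stats::glm(y ~ dv, family = stats::binomial(),
                   data = data.frame(y = y, dv = dv)))
      list(sc = sc, svm = m, platt = platt, sign1 = sign1)
    },
    rf = randomForest::randomForest(X, yf, ntree = p$ntree)
  )
  structure(list(learner = learner, state = state, params = p,
                 features = colnames(X)), class = "base_fit")
}

predict_prob_base <- function(fit, X) {
  X <- as.matrix(X)[, fit$features, drop = FALSE]
  switch(
    fit$learner,
    knn = {
      Xs <- scale_apply(X, fit$state$sc)
      pred <- class::knn(fit$state$X, Xs, fit$state$y, k = fit$state$k,
                         prob = TRUE)
      win <- attr(pred, "prob")
      ifelse(pred == "1", win, 1 - win)
    },
    cart = {
      d <- data.frame(X, check.names = FALSE)
      as.numeric(stats::predict(fit$state, d, type = "prob")[, "1"])
    },
    svm = {
      Xs <- scale_apply(X, fit$state$sc)
      dv <- fit$state$sign1 *
        as.numeric(attr(stats::predict(fit$state$svm, Xs,
                                       decision.values = TRUE),
                        "decision.values"))
      as.numeric(stats::predict(fit$state$platt,
                                newdata = data.frame(dv = dv),
                                type = "response"))
    },
    rf = as.numeric(stats::predict(fit$state, X, type = "prob")[, "1"])
  )
}

# ---- model specification ------------------------------------------------

#' Specify a model from the stage x base-learner grid
#'
#' Three stages: `"simple"` fits the base learner on all features;
#' `"lr_hybrid"` applies L1-logistic feature selection and fits the base
#' learner on the selected subset; `"abc_lr_hybrid"` searches feature
#' subsets with the ABC optimizer, using inner cross-validated classifier
#' performance (SMOTE inside inner training folds) as fitness. All 12
#' combinations of 3 stages x 4 learners are constructible.
#'
#' @param stage one of `"simple"`, `"lr_hybrid"`, `"abc_lr_hybrid"`.
#' @param base_learner one of `"knn"`, `"cart"`, `"svm"`, `"rf"`.
#' @param base_params named list overriding learner hyperparameters
#'   (defaults: knn k = 5; cart cp = 0.01; svm radial, cost = 1; rf
#'   ntree = 100).
#' @param l1_strength lasso penalty for stage 2 (and the stage-3 warm
#'   start).
#' @param abc an [abc_config()] (stage 3 only).
#' @param inner_cv inner fold count for stage-3 fitness (default 3).
#' @param metric fitness metric id: `"f1"` (default), `"accuracy"`,
#'   `"recall"` or `"precision"`.
#' @param warm_start seed one initial ABC food source with the L1-selected
#'   mask (default `TRUE`).
#' @param seed seed for the fitting pipeline.
#' @return list of class `model_spec`.
#' @export
model_spec <- function(stage = c("simple", "lr_hybrid", "abc_lr_hybrid"),
                       base_learner = c("rf", "knn", "svm", "cart"),
                       base_params = list(), l1_strength = 0.05,
                       abc = abc_config(), inner_cv = 3L, metric = "f1",
                       warm_start = TRUE, seed = 1L) {
  stage <- match.arg(stage)
  base_learner <- match.arg(base_learner)
  stopifnot(metric %in% c("f1", "accuracy", "recall", "precision"),
            inner_cv >= 2L)
  if (stage == "abc_lr_hybrid" && is.null(abc)) {
    stop("stage 'abc_lr_hybrid' requires an abc_config", call. = FALSE)
  }
  structure(list(stage = stage, base_learner = base_learner,
                 base_params = base_params, l1_strength = l1_strength,
                 abc = abc, inner_cv = as.integer(inner_cv), metric = metric,
                 warm_start = isTRUE(warm_start), seed = seed),
            class = "model_spec")
}

#' Human-readable model label
#'
#' @param spec a [model_spec()].
#' @return e.g. `"RF"`, `"LR - RF"`, `"ABC-LR-RF"`.
#' @export
model_label <- function(spec) {
  base <- toupper(spec$base_learner)
  switch(spec$stage,
         simple = base,
         lr_hybrid = paste0("LR - ", base),
         abc_lr_hybrid = paste0("ABC-LR-", base))
}

#' Build an unfitted model from a specification
#'
#' @param spec a [model_spec()].
#' @return object of class `ivf_model` honouring the fit/predict contract.
#' @export
build_model <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  structure(list(spec = spec), class = "ivf_model")
}

#' Fit a model (applying its stage's feature selection)
#'
#' Runs the stage's feature-selection step on the supplied training data
#' only, then fits the base learner on the masked feature set. The fitted
#' object applies the mask internally: `predict()` always takes the full
#' original feature set.
#'
#' @param model an `ivf_model` from [build_model()], or a [model_spec()].
#' @param X numeric predictor matrix (n x p) with column names.
#' @param y 0/1 outcome vector with both classes present.
#' @return object of class `ivf_fitted` with the applied [feature_mask()],
#'   the opaque learner state and, for stage 3, the ABC fitness trace.
#' @export
fit_model <- function(model, X, y) {
  if (inherits(model, "model_spec")) model <- build_model(model)
  stopifnot(inherits(model, "ivf_model"))
  spec <- model$spec
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (length(unique(y)) < 2L) stop("fit_model: single-class outcome", call. = FALSE)
  trace <- NULL
  mask <- switch(
    spec$stage,
    simple = feature_mask(rep(1L, ncol(X)), colnames(X), "manual"),
    lr_hybrid = {
      m <- l1_select(X, y, spec$l1_strength)
      if (attr(m, "infeasible")) {
        warning("l1_select returned an empty mask; falling back to all features",
                call. = FALSE)
        m <- feature_mask(rep(1L, ncol(X)), colnames(X), "manual")
      }
      m
    },
    abc_lr_hybrid = {
      warm <- NULL
      if (spec$warm_start) {
        wm <- l1_select(X, y, spec$l1_strength)
        if (!attr(wm, "infeasible")) warm <- wm
      }
      sr <- abc_feature_search(X, y, spec$base_learner, abc = spec$abc,
                               inner_cv = spec$inner_cv, metric = spec$metric,
                               seed = spec$seed,
                               base_params = spec$base_params,
                               warm_mask = warm)
      trace <- sr$trace
      sr$mask
    }
  )
  base <- with_seed(derive_seed(spec$seed, "base_fit"),
                    fit_base(spec$base_learner,
                             X[, mask == 1L, drop = FALSE], y,
                             spec$base_params))
  structure(list(spec = spec, mask = mask, base = base,
                 features = colnames(X), trace = trace,
                 seed = spec$seed),
            class = "ivf_fitted")
}

#' Predict from a fitted model
#'
#' @param object an `ivf_fitted` from [fit_model()].
#' @param newdata matrix/data frame with exactly the training feature
#'   columns (order-checked); the fitted mask is applied internally.
#' @param type `"prob"` for P(outcome = 1), `"class"` for 0/1 labels at
#'   the 0.5 threshold.
#' @param ... unused.
#' @return numeric vector of probabilities or 0/1 labels.
#' @export
predict.ivf_fitted <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  X <- as.matrix(newdata)
  if (is.null(colnames(X)) && ncol(X) == length(object$features)) {
    colnames(X) <- object$features
  }
  if (!identical(colnames(X), object$features)) {
    stop("predict: column mismatch; expected columns (in order): ",
         paste(object$features, collapse = ", "), call. = FALSE)
  }
  p <- predict_prob_base(object$base, X[, object$mask == 1L, drop = FALSE])
  if (type == "prob") p else as.numeric(p >= 0.5)
}

#' @export
print.ivf_fitted <- function(x, ...) {
  cat(sprintf("ivf_fitted: %s, %d/%d features (%s)\n", model_label(x$spec),
              sum(x$mask), length(x$mask), attr(x$mask, "provenance")))
  invisible(x)
}

# fold-level score for the wrapper fitness; undefined metrics (e.g.
# precision with no positive predictions) score 0, the worst value
fitness_score <- function(probs, y, metric) {
  lab <- as.numeric(probs >= 0.5)
  cm <- confusion_counts(tp = sum(lab == 1 & y == 1),
                         tn = sum(lab == 0 & y == 0),
                         fp = sum(lab == 1 & y == 0),
                         fn = sum(lab == 0 & y == 1))
  mt <- metrics_from_counts(cm)
  v <- switch(metric, f1 = mt$f1, accuracy = mt$accuracy,
              recall = mt$sensitivity, precision = mt$precision)
  if (is.na(v)) 0 else v
}

#' ABC feature-subset search with cross-validated fitness
#'
#' Wrapper feature selection: the ABC optimizer searches binary feature
#' masks, scoring each candidate mask by `1 - mean` inner stratified
#' cross-validated performance of the base learner on the masked features,
#' with SMOTE applied inside the inner training folds only. Inner folds
#' are fixed once per search so all masks are compared on identical
#' splits, and mask objectives are memoized (neighborhood moves often
#' leave the decoded mask unchanged).
#'
#' @param X,y training data (both classes present).
#' @param base_learner `"knn"`, `"cart"`, `"svm"` or `"rf"`.
#' @param abc an [abc_config()].
#' @param inner_cv inner fold count (>= 2).
#' @param metric fitness metric id (see [model_spec()]).
#' @param seed seed for folds, SMOTE and learner fits.
#' @param base_params learner hyperparameter overrides.
#' @param warm_mask optional [feature_mask()] seeding one initial food
#'   source.
#' @param resampling `"smote_within_fold"` (default) or `"none"`.
#' @param smote_neighbors SMOTE neighbor count.
#' @return list with `mask` (provenance `"abc_search"`), `objective`,
#'   `trace` (per-iteration best objective, monotone non-increasing),
#'   `n_evaluations`, `n_fits` (model fits actually run) and
#'   `cache_hits`.
#' @export
abc_feature_search <- function(X, y, base_learner, abc = abc_config(),
                               inner_cv = 3L, metric = "f1", seed = 1L,
                               base_params = list(), warm_mask = NULL,
                               resampling = c("smote_within_fold", "none"),
                               smote_neighbors = 5L) {
  resampling <- match.arg(resampling)
  X <- as.matrix(X)
  if (length(unique(y)) < 2L) stop("single-class outcome", call. = FALSE)
  stopifnot(inner_cv >= 2L)
  folds <- stratified_folds(y, inner_cv, seed = derive_seed(seed, "inner_cv"))
  cache <- new.env(parent = emptyenv())
  n_fits <- 0L
  cache_hits <- 0L

  objective <- function(mask) {
    key <- paste(mask, collapse = "")
    if (!is.null(cache[[key]])) {
      cache_hits <<- cache_hits + 1L
      return(cache[[key]])
    }
    scores <- vapply(seq_along(folds), function(f) {
      test <- folds[[f]]
      train <- setdiff(seq_along(y), test)
      Xtr <- X[train, mask == 1L, drop = FALSE]
      ytr <- y[train]
      if (resampling == "smote_within_fold") {
        sm <- smote_oversample(Xtr, ytr, k_neighbors = smote_neighbors,
                               seed = derive_seed(seed, paste0("smote", f)))
        Xtr <- sm$X; ytr <- sm$y
      }
      bf <- with_seed(derive_seed(seed, paste0("fit", f, key)),
                      fit_base(base_learner, Xtr, ytr, base_params))
      probs <- predict_prob_base(bf, X[test, mask == 1L, drop = FALSE])
      fitness_score(probs, y[test], metric)
    }, numeric(1))
    n_fits <<- n_fits + length(folds)
    val <- 1 - mean(scores)
    cache[[key]] <- val
    val
  }

  space <- search_space(ncol(X), "binary_mask")
  init <- NULL
  if (!is.null(warm_mask)) {
    stopifnot(length(warm_mask) == ncol(X))
    init <- matrix(ifelse(as.integer(warm_mask) == 1L, 0.75, 0.25), nrow = 1)
  }
  res <- abc_optimize(objective, space, abc, init_positions = init)
  if (is.null(res$best_mask) || attr(res$best_mask, "infeasible")) {
    stop("abc_feature_search: no feasible mask found within the budget",
         call. = FALSE)
  }
  mask <- feature_mask(res$best_mask, colnames(X), "abc_search")
  list(mask = mask, objective = res$best_objective, trace = res$history,
       n_evaluations = res$n_evaluations, n_fits = n_fits,
       cache_hits = cache_hits)
}
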