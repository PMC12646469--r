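# Leakage-safe stratified k-fold cross-validation with SMOTE confined to
# training folds, the confusion-matrix metric suite, calibration and
# discrimination curves, paired-fold significance testing, and the
# stage x learner comparison report.

#' Cross-validation configuration
#'
#' @param k fold count (default 5).
#' @param stratified preserve class proportions per fold (default `TRUE`).
#' @param resampling `"smote_within_fold"` (default) or `"none"`. SMOTE is
#'   applied to the training portion of each fold only, after splitting,
#'   so synthetic rows can never reach a test fold.
#' @param smote_neighbors SMOTE neighbor count (default 5; auto-shrunk
#'   with a warning when the minority class is tiny).
#' @param seed RNG seed; fixed seed gives identical folds and reports.
#' @return list of class `cv_config`.
#' @export
cv_config <- function(k = 5L, stratified = TRUE,
                      resampling = c("smote_within_fold", "none"),
                      smote_neighbors = 5L, seed = 1L) {
  resampling <- match.arg(resampling)
  stopifnot(k >= 2L, smote_neighbors >= 1L)
  structure(list(k = as.integer(k), stratified = isTRUE(stratified),
                 resampling = resampling,
                 smote_neighbors = as.integer(smote_neighbors), seed = seed),
            class = "cv_config")
}

#' Stratified k-fold partition
#'
#' Splits indices into k disjoint folds preserving class proportions:
#' within each class, members are shuffled and dealt so per-fold class
#' counts differ by at most one from proportionality; class remainders are
#' assigned to the folds with the smallest running totals so overall fold
#' sizes are also balanced (for 162 cases with 63 positives and k = 5 this
#' yields fold sizes 33/33/32/32/32 with 13/13/13/12/12 positives).
#'
#' @param y 0/1 (or factor) labels; every class must have at least k
#'   members.
#' @param k fold count.
#' @param seed RNG seed.
#' @return list of k integer index vectors partitioning `seq_along(y)`.
#' @export
stratified_folds <- function(y, k, seed = 1L) {
  k <- as.integer(k)
  # k = n is the leave-one-out boundary: singleton folds, stratification vacuous
  if (k == length(y)) {
    return(with_seed(seed, as.list(sample(seq_along(y)))))
  }
  classes <- sort(unique(y))
  for (cl in classes) {
    if (sum(y == cl) < k) {
      stop(sprintf("stratification error: class '%s' has %d members < k = %d",
                   format(cl), sum(y == cl), k), call. = FALSE)
    }
  }
  with_seed(seed, {
    folds <- vector("list", k)
    totals <- integer(k)
    for (cl in classes) {
      idx <- sample(which(y == cl))
      n_cl <- length(idx)
      counts <- rep(n_cl %/% k, k)
      extras <- n_cl %% k
      if (extras > 0L) {
        recv <- order(totals, seq_len(k))[seq_len(extras)]
        counts[recv] <- counts[recv] + 1L
      }
      at <- 1L
      for (f in seq_len(k)) {
        if (counts[f] > 0L) {
          folds[[f]] <- c(folds[[f]], idx[at:(at + counts[f] - 1L)])
          at <- at + counts[f]
        }
      }
      totals <- totals + counts
    }
    lapply(folds, sort)
  })
}

#' SMOTE oversampling
#'
#' Synthetic minority over-sampling: new minority rows are convex
#' combinations `s = x_i + u (x_j - x_i)`, `u ~ Uniform(0, 1)`, of a
#' minority point and one of its `k_neighbors` minority-class nearest
#' neighbors (Euclidean distance), until the classes are exactly balanced.
#' Original rows are returned unchanged; already-balanced input is a
#' no-op.
#'
#' @param X numeric matrix / data frame of predictors.
#' @param y 0/1 labels; the minority class must have at least 2 members.
#' @param k_neighbors neighbor count (default 5), shrunk to
#'   `minority - 1` with a warning when necessary.
#' @param seed RNG seed.
#' @return list with `X` (original rows first, synthetic rows appended),
#'   `y`, and logical `synthetic` marking the appended rows.
#' @export
smote_oversample <- function(X, y, k_neighbors = 5L, seed = 1L) {
  X <- as.matrix(X)
  stopifnot(length(y) == nrow(X))
  tab <- table(factor(y, levels = c(0, 1)))
  if (tab["0"] == tab["1"]) {
    return(list(X = X, y = y, synthetic = rep(FALSE, nrow(X))))
  }
  minority <- if (tab["0"] < tab["1"]) 0 else 1
  m_idx <- which(y == minority)
  m <- length(m_idx)
  if (m < 2L) stop("smote_oversample: minority class has a single member",
                   call. = FALSE)
  k <- min(k_neighbors, m - 1L)
  if (k < k_neighbors) {
    warning(sprintf("smote_oversample: k_neighbors shrunk from %d to %d (minority size %d)",
                    k_neighbors, k, m), call. = FALSE)
  }
  need <- abs(tab["0"] - tab["1"])
  Xm <- X[m_idx, , drop = FALSE]
  D <- as.matrix(stats::dist(Xm))
  diag(D) <- Inf
  nn <- matrix(apply(D, 1, function(r) order(r)[seq_len(k)]),
               nrow = m, byrow = TRUE)
  with_seed(seed, {
    base <- sample.int(m, need, replace = TRUE)
    pick <- nn[cbind(base, sample.int(k, need, replace = TRUE))]
    u <- stats::runif(need)
    synth <- Xm[base, , drop = FALSE] +
      u * (Xm[pick, , drop = FALSE] - Xm[base, , drop = FALSE])
    list(X = rbind(X, synth),
         y = c(y, rep(minority, need)),
         synthetic = c(rep(FALSE, nrow(X)), rep(TRUE, need)))
  })
}

#' Confusion counts
#'
#' @param tp,tn,fp,fn non-negative integer counts.
#' @return list of class `confusion_counts`.
#' @export
confusion_counts <- function(tp, tn, fp, fn) {
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0)
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn,
                 total = tp + tn + fp + fn),
            class = "confusion_counts")
}

#' Classification metrics from confusion counts
#'
#' Accuracy `(TP+TN)/(TP+TN+FP+FN)`, sensitivity (recall) `TP/(TP+FN)`,
#' precision `TP/(TP+FP)` and F1 `2PR/(P+R)`. Ratios with a zero
#' denominator are reported as `NA` with a reason code in the `reasons`
#' element — never silently coerced to 0.
#'
#' @param counts a [confusion_counts()].
#' @return list of class `classification_metrics` with elements
#'   `accuracy`, `sensitivity`, `precision`, `f1`, `reasons` (named
#'   character) and the input `counts`.
#' @export
metrics_from_counts <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  if (counts$total == 0) stop("metrics_from_counts: no evaluated instances",
                              call. = FALSE)
  reasons <- character(0)
  accuracy <- (counts$tp + counts$tn) / counts$total
  sensitivity <- if (counts$tp + counts$fn > 0) {
    counts$tp / (counts$tp + counts$fn)
  } else {
    reasons["sensitivity"] <- "no positive cases"
    NA_real_
  }
  precision <- if (counts$tp + counts$fp > 0) {
    counts$tp / (counts$tp + counts$fp)
  } else {
    reasons["precision"] <- "no positive predictions"
    NA_real_
  }
  f1 <- if (is.na(sensitivity) || is.na(precision)) {
    reasons["f1"] <- "undefined precision or sensitivity"
    NA_real_
  } else if (sensitivity + precision == 0) {
    reasons["f1"] <- "precision + sensitivity = 0"
    NA_real_
  } else {
    2 * sensitivity * precision / (sensitivity + precision)
  }
  structure(list(accuracy = accuracy, sensitivity = sensitivity,
                 precision = precision, f1 = f1, reasons = reasons,
                 counts = counts),
            class = "classification_metrics")
}

#' Probability-based metrics: Brier score, calibration, ROC-AUC, PR-AUC
#'
#' Brier score is `mean((p_i - y_i)^2)` (0 = perfect; 0.25 = the
#' uninformative constant 0.5). ROC-AUC integrates the full threshold
#' sweep by the trapezoidal rule; PR-AUC uses step interpolation
#' (average-precision form). The calibration curve bins predictions into
#' `n_bins` equal-width bins on [0, 1].
#'
#' @param probs predicted probabilities in [0, 1].
#' @param y 0/1 outcomes; both classes must be present for the AUCs
#'   (otherwise they are `NA` with a reason).
#' @param n_bins calibration bin count (default 10).
#' @return list with `brier`, `roc_auc`, `pr_auc`, `calibration` (data
#'   frame: `bin_lo`, `bin_hi`, `mean_predicted`, `observed_frequency`,
#'   `count`) and `reasons`.
#' @export
probability_metrics <- function(probs, y, n_bins = 10L) {
  stopifnot(all(probs >= 0 & probs <= 1), length(probs) == length(y))
  brier <- mean((probs - y)^2)
  reasons <- character(0)
  if (length(unique(y)) < 2L) {
    roc_auc <- pr_auc <- NA_real_
    reasons["roc_auc"] <- reasons["pr_auc"] <- "single-class outcome"
  } else {
    ord <- order(probs, decreasing = TRUE)
    ys <- y[ord]; ps <- probs[ord]
    # collapse threshold ties so the sweep visits each distinct cutoff once
    grp <- cumsum(!duplicated(ps))
    tp <- cumsum(ys); fp <- cumsum(1 - ys)
    last <- which(!duplicated(grp, fromLast = TRUE))
    tp <- tp[last]; fp <- fp[last]
    P <- sum(y); N <- sum(1 - y)
    tpr <- c(0, tp / P); fpr <- c(0, fp / N)
    roc_auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
    recall <- tp / P
    precision <- tp / (tp + fp)
    pr_auc <- sum(diff(c(0, recall)) * precision)
  }
  edges <- seq(0, 1, length.out = n_bins + 1L)
  bin <- pmin(findInterval(probs, edges, rightmost.closed = TRUE), n_bins)
  calibration <- data.frame(
    bin_lo = edges[seq_len(n_bins)],
    bin_hi = edges[-1],
    mean_predicted = vapply(seq_len(n_bins), function(b) {
      if (any(bin == b)) mean(probs[bin == b]) else NA_real_
    }, numeric(1)),
    observed_frequency = vapply(seq_len(n_bins), function(b) {
      if (any(bin == b)) mean(y[bin == b]) else NA_real_
    }, numeric(1)),
    count = vapply(seq_len(n_bins), function(b) sum(bin == b), numeric(1))
  )
  list(brier = brier, roc_auc = roc_auc, pr_auc = pr_auc,
       calibration = calibration, reasons = reasons)
}

#' Paired t-test on fold scores
#'
#' Classical two-sided paired t-test with df = k - 1 and a 95% confidence
#' interval from the t quantile, for comparing two models evaluated on
#' identical fold partitions. Zero-variance differences yield an
#' exact-tie report instead of a t statistic.
#'
#' @param scores_a,scores_b equal-length (>= 2) fold score vectors from
#'   the same fold partition.
#' @param conf_level confidence level (default 0.95).
#' @return list of class `paired_fold_test`: `mean_difference`, `t`, `df`,
#'   `p_value`, `conf_int`, `tie`.
#' @export
paired_fold_test <- function(scores_a, scores_b, conf_level = 0.95) {
  stopifnot(length(scores_a) == length(scores_b), length(scores_a) >= 2L)
  d <- scores_a - scores_b
  k <- length(d)
  md <- mean(d)
  if (stats::sd(d) == 0) {
    return(structure(list(mean_difference = md, t = NA_real_,
                          df = k - 1L, p_value = NA_real_,
                          conf_int = c(md, md), tie = TRUE),
                     class = "paired_fold_test"))
  }
  se <- stats::sd(d) / sqrt(k)
  tstat <- md / se
  df <- k - 1L
  p <- 2 * stats::pt(-abs(tstat), df)
  q <- stats::qt(1 - (1 - conf_level) / 2, df)
  structure(list(mean_difference = md, t = tstat, df = df, p_value = p,
                 conf_int = c(md - q * se, md + q * se), tie = FALSE),
            class = "paired_fold_test")
}

#' @export
print.paired_fold_test <- function(x, ...) {
  if (x$tie) {
    cat(sprintf("paired fold test: exact tie (mean difference %.4g)\n",
                x$mean_difference))
  } else {
    cat(sprintf("paired fold test: mean diff %.4g, t(%d) = %.3f, p = %.4g, 95%% CI [%.4g, %.4g]\n",
                x$mean_difference, x$df, x$t, x$p_value,
                x$conf_int[1], x$conf_int[2]))
  }
  invisible(x)
}

#' Leakage-safe cross-validation of a model specification
#'
#' For each fold: the training portion is (optionally) SMOTE-resampled,
#' the full model pipeline — including any L1 or ABC feature selection —
#' is fitted on that fold's training data only, and the untouched test
#' fold is predicted. Synthetic rows are appended after the split, so by
#' construction none can reach a test fold; the report carries an audit
#' field asserting this.
#'
#' Headline metrics are fold-averaged (undefined fold values are excluded
#' from averages, with an exclusion count); pooled-count metrics over the
#' aggregated out-of-fold confusion matrix are also reported, since the
#' two conventions can disagree.
#'
#' @param spec a [model_spec()].
#' @param cohort a [cohort_table()] (or list with `X`, `y`).
#' @param cv a [cv_config()].
#' @return list of class `metrics_report`: `fold_metrics` (data frame),
#'   `mean_metrics`, `n_excluded`, `pooled_counts`, `pooled_metrics`,
#'   `probability` (Brier/AUCs/calibration over pooled out-of-fold
#'   predictions), `predictions`, `audit`, `spec`, `cv`.
#' @export
cross_validate <- function(spec, cohort, cv = cv_config()) {
  if (inherits(cohort, "cohort_table")) {
    X <- cohort_matrix(cohort)
    y <- cohort_outcome(cohort)
  } else {
    X <- as.matrix(cohort$X); y <- cohort$y
  }
  folds <- stratified_folds(y, cv$k, seed = derive_seed(cv$seed, "folds"))
  n <- length(y)
  preds <- data.frame(row = integer(), fold = integer(), prob = numeric(),
                      label = numeric(), truth = numeric())
  fold_rows <- list()
  synthetic_in_test <- 0L
  for (f in seq_along(folds)) {
    test <- folds[[f]]
    train <- setdiff(seq_len(n), test)
    if (length(unique(y[test])) < 2L || length(unique(y[train])) < 2L) {
      stop(sprintf("cross_validate: fold %d has a single class", f),
           call. = FALSE)
    }
    Xtr <- X[train, , drop = FALSE]; ytr <- y[train]
    row_ids <- train  # identity audit: original row indices, no synthetic ids
    if (cv$resampling == "smote_within_fold") {
      sm <- smote_oversample(Xtr, ytr, k_neighbors = cv$smote_neighbors,
                             seed = derive_seed(cv$seed, paste0("smote", f)))
      Xtr <- sm$X; ytr <- sm$y
      row_ids <- c(row_ids, rep(NA_integer_, sum(sm$synthetic)))
    }
    # row-identity audit: synthetic rows carry no original index (NA id)
    # and exist only in the training design; any test index found among
    # the training row ids would be train/test contamination
    synthetic_in_test <- synthetic_in_test + sum(test %in% row_ids)
    fspec <- spec
    fspec$seed <- derive_seed(cv$seed, paste0("fold", f, spec$seed))
    fitted <- fit_model(build_model(fspec), Xtr, ytr)
    prob <- predict(fitted, X[test, , drop = FALSE], type = "prob")
    lab <- as.numeric(prob >= 0.5)
    preds <- rbind(preds, data.frame(row = test, fold = f, prob = prob,
                                     label = lab, truth = y[test]))
    cm <- confusion_counts(tp = sum(lab == 1 & y[test] == 1),
                           tn = sum(lab == 0 & y[test] == 0),
                           fp = sum(lab == 1 & y[test] == 0),
                           fn = sum(lab == 0 & y[test] == 1))
    mt <- metrics_from_counts(cm)
    pm <- probability_metrics(prob, y[test])
    fold_rows[[f]] <- data.frame(
      fold = f, n_test = length(test), accuracy = mt$accuracy,
      sensitivity = mt$sensitivity, precision = mt$precision, f1 = mt$f1,
      brier = pm$brier, roc_auc = pm$roc_auc, pr_auc = pm$pr_auc,
      tp = cm$tp, tn = cm$tn, fp = cm$fp, fn = cm$fn)
  }
  fold_metrics <- do.call(rbind, fold_rows)
  metric_cols <- c("accuracy", "sensitivity", "precision", "f1", "brier",
                   "roc_auc", "pr_auc")
  mean_metrics <- vapply(fold_metrics[metric_cols],
                         function(v) mean(v, na.rm = TRUE), numeric(1))
  n_excluded <- vapply(fold_metrics[metric_cols],
                       function(v) sum(is.na(v)), numeric(1))
  pooled_counts <- confusion_counts(tp = sum(fold_metrics$tp),
                                    tn = sum(fold_metrics$tn),
                                    fp = sum(fold_metrics$fp),
                                    fn = sum(fold_metrics$fn))
  stopifnot(pooled_counts$total == n)  # pooled counts sum to n
  structure(list(
    fold_metrics = fold_metrics,
    mean_metrics = as.list(mean_metrics),
    n_excluded = as.list(n_excluded),
    pooled_counts = pooled_counts,
    pooled_metrics = metrics_from_counts(pooled_counts),
    probability = probability_metrics(preds$prob, preds$truth),
    predictions = preds,
    audit = list(contaminated_test_rows = synthetic_in_test,
                 folds_partition_n = sum(lengths(folds)) == n),
    spec = spec, cv = cv
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("metrics_report: %s, %d-fold CV (%s)\n", model_label(x$spec),
              x$cv$k, x$cv$resampling))
  m <- x$mean_metrics
  cat(sprintf("  fold-mean: acc %.4f  sens %.4f  prec %.4f  f1 %.4f  brier %.4f  roc_auc %.4f  pr_auc %.4f\n",
              m$accuracy, m$sensitivity, m$precision, m$f1, m$brier,
              m$roc_auc, m$pr_auc))
  p <- x$pooled_metrics
  cat(sprintf("  pooled:    acc %.4f  sens %.4f  prec %.4f  f1 %.4f\n",
              p$accuracy, p$sensitivity, p$precision, p$f1))
  invisible(x)
}

#' The full stage x base-learner model grid
#'
#' @param bases base learners (default the four of the comparison grid).
#' @param stages stage names to include.
#' @param ... passed to every [model_spec()] (e.g. `abc`, `inner_cv`,
#'   `base_params`).
#' @return named list of 12 (by default) [model_spec()]s, grouped by
#'   stage.
#' @export
model_grid <- function(bases = c("rf", "knn", "svm", "cart"),
                       stages = c("simple", "lr_hybrid", "abc_lr_hybrid"),
                       ...) {
  specs <- list()
  for (st in stages) {
    for (b in bases) {
      sp <- model_spec(stage = st, base_learner = b, ...)
      specs[[model_label(sp)]] <- sp
    }
  }
  specs
}

#' Percent formatting to two decimals
#'
#' @param x proportion in [0, 1].
#' @return character, e.g. `0.913580 -> "91.36"`.
#' @export
format_percent <- function(x) {
  ifelse(is.na(x), NA_character_, sprintf("%.2f", round(x * 100, 2)))
}

#' Cross-validated comparison of a model grid
#'
#' Runs [cross_validate()] for every specification in the grid and
#' assembles the comparison report: one row per (stage, base learner)
#' with accuracy, F-score, recall and precision as percentages to two
#' decimals (fold-averaged), grouped by stage, with the best accuracy row
#' flagged. A failed model run is marked failed (with the error class)
#' and the remaining rows still complete.
#'
#' @param cohort a [cohort_table()].
#' @param grid named list of [model_spec()]s, e.g. [model_grid()].
#' @param cv a [cv_config()].
#' @param quiet suppress per-model progress messages.
#' @return data frame of class `comparison_table` with columns `no`,
#'   `stage`, `model`, `accuracy`, `f_score`, `recall`, `precision`,
#'   `model_type`, `best`, `failed`, `error`; the per-model
#'   [cross_validate()] reports are attached as attribute `reports`.
#' @export
comparison_table <- function(cohort, grid = model_grid(), cv = cv_config(),
                             quiet = FALSE) {
  rows <- list()
  reports <- list()
  stage_no <- c(simple = 1L, lr_hybrid = 2L, abc_lr_hybrid = 3L)
  for (i in seq_along(grid)) {
    spec <- grid[[i]]
    label <- names(grid)[i]
    if (!quiet) message("comparison_table: evaluating ", label)
    res <- tryCatch(cross_validate(spec, cohort, cv), error = identity)
    if (inherits(res, "error")) {
      rows[[i]] <- data.frame(
        no = i, stage = stage_no[[spec$stage]], model = label,
        accuracy = NA_real_, f_score = NA_real_, recall = NA_real_,
        precision = NA_real_,
        model_type = if (spec$stage == "simple") "Simple" else "Hybrid",
        best = FALSE, failed = TRUE, error = class(res)[1])
    } else {
      reports[[label]] <- res
      m <- res$mean_metrics
      rows[[i]] <- data.frame(
        no = i, stage = stage_no[[spec$stage]], model = label,
        accuracy = round(m$accuracy * 100, 2),
        f_score = round(m$f1 * 100, 2),
        recall = round(m$sensitivity * 100, 2),
        precision = round(m$precision * 100, 2),
        model_type = if (spec$stage == "simple") "Simple" else "Hybrid",
        best = FALSE, failed = FALSE, error = NA_character_)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$stage, out$no), ]
  out$no <- seq_len(nrow(out))
  rownames(out) <- NULL
  if (any(!out$failed)) {
    out$best[which.max(ifelse(out$failed, -Inf, out$accuracy))] <- TRUE
  }
  structure(out, class = c("comparison_table", "data.frame"),
            reports = reports)
}
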