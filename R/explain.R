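# LIME-style local surrogate explanations: perturb an instance, weight
# neighbors by proximity, fit a sparse weighted linear surrogate to the
# model's probabilities, report signed feature contributions.

#' Configuration for local surrogate explanations
#'
#' @param n_perturbations number of perturbed samples (>= 10; default
#'   1000).
#' @param kernel_width proximity kernel width on the standardized distance
#'   scale; `NULL` (default) uses the common heuristic `0.75 * sqrt(p)`.
#' @param max_features maximum number of reported features (default 10).
#' @param binary_sampling `"uniform"` (default; binary features resampled
#'   from {0, 1} with probability 1/2, i.e. flipped with probability 0.5
#'   relative to the instance, giving symmetric coverage) or
#'   `"prevalence"` (resampled from the cohort prevalence).
#' @param seed RNG seed; fixed seed gives a byte-identical explanation.
#' @return list of class `explain_config`.
#' @export
explain_config <- function(n_perturbations = 1000L, kernel_width = NULL,
                           max_features = 10L,
                           binary_sampling = c("uniform", "prevalence"),
                           seed = 1L) {
  binary_sampling <- match.arg(binary_sampling)
  stopifnot(n_perturbations >= 10L, is.null(kernel_width) || kernel_width > 0)
  structure(list(n_perturbations = as.integer(n_perturbations),
                 kernel_width = kernel_width,
                 max_features = as.integer(max_features),
                 binary_sampling = binary_sampling, seed = seed),
            class = "explain_config")
}

# Per-feature sampling statistics taken from a cohort: mean, sd, and
# whether the column is binary.
cohort_stats <- function(cohort) {
  X <- cohort_matrix(cohort)
  list(mean = colMeans(X), sd = apply(X, 2, stats::sd),
       binary = vapply(as.data.frame(X), function(v) all(v %in% c(0, 1)),
                       logical(1)),
       features = colnames(X))
}

#' Perturb an instance and compute proximity weights
#'
#' Binary features are resampled independently (uniform from {0, 1} by
#' default); continuous features are jittered with Gaussian noise scaled
#' by the cohort SD. Proximity weight is `exp(-d^2 / width^2)` where `d`
#' is a normalized Euclidean distance: binary features contribute one unit
#' per flip and continuous features are SD-standardized. Zero-SD features
#' are left unperturbed and excluded from the distance. The unperturbed
#' instance itself has weight exactly 1.
#'
#' @param instance named numeric vector (or 1-row matrix/data frame)
#'   conforming to the cohort schema.
#' @param stats sampling statistics (means/SDs/binary flags), typically
#'   from a cohort via the internal helper; pass the training
#'   [cohort_table()] to [explain_instance()] instead of calling this
#'   directly.
#' @param config an [explain_config()].
#' @return list with `X` (perturbed design, instance's features as
#'   columns) and `weights`.
#' @export
perturb_samples <- function(instance, stats, config = explain_config()) {
  x0 <- as.numeric(instance)[seq_along(stats$features)]
  names(x0) <- stats$features
  p <- length(x0)
  width <- config$kernel_width %||% (0.75 * sqrt(p))
  with_seed(config$seed, {
    n <- config$n_perturbations
    Z <- matrix(rep(x0, each = n), nrow = n,
                dimnames = list(NULL, stats$features))
    for (j in seq_len(p)) {
      if (stats$sd[j] == 0) next  # degenerate feature: left unperturbed
      if (stats$binary[j]) {
        pr <- if (config$binary_sampling == "uniform") 0.5 else stats$mean[j]
        Z[, j] <- stats::rbinom(n, 1L, pr)
      } else {
        Z[, j] <- x0[j] + stats::rnorm(n, 0, stats$sd[j])
      }
    }
    # distance scale: binary features contribute 1 per flip; continuous
    # features are SD-standardized (bounding rare-feature contributions)
    live <- stats$sd > 0
    scl <- ifelse(stats$binary, 1, stats$sd)
    D2 <- rowSums(sweep(sweep(Z[, live, drop = FALSE], 2, x0[live]), 2,
                        scl[live], "/")^2)
    list(X = Z, weights = exp(-D2 / width^2))
  })
}

#' Fit a sparse weighted linear surrogate
#'
#' Screens the `max_features` columns with the largest absolute weighted
#' covariance with the model's probabilities, then solves a
#' ridge-stabilized weighted least squares on the screened columns.
#' Fidelity is the weighted R-squared of the surrogate against the model
#' probabilities; a constant model short-circuits to all-zero weights
#' with fidelity 1.
#'
#' @param X perturbed design matrix.
#' @param probs model probabilities for the rows of `X`.
#' @param weights proximity weights.
#' @param config an [explain_config()].
#' @param keep optional logical vector marking columns eligible for
#'   selection (e.g. the fitted model's feature mask); others get weight
#'   exactly 0.
#' @return list with `coefficients` (named, zeros for unselected
#'   features), `intercept`, `fidelity`, `selected`.
#' @export
fit_surrogate <- function(X, probs, weights, config = explain_config(),
                          keep = NULL) {
  X <- as.matrix(X)
  p <- ncol(X)
  if (is.null(keep)) keep <- rep(TRUE, p)
  coefs <- stats::setNames(numeric(p), colnames(X))
  if (length(unique(probs)) < 2L) {
    return(list(coefficients = coefs,
                intercept = probs[1], fidelity = 1, selected = character(0)))
  }
  w <- weights / sum(weights)
  mx <- colSums(X * w)
  my <- sum(probs * w)
  cov_xy <- colSums((X - rep(mx, each = nrow(X))) * (probs - my) * w)
  sdx <- sqrt(pmax(colSums(sweep(X, 2, mx)^2 * w), 0))
  # screen on the SD-standardized scale so high-variance noise columns
  # cannot crowd out genuine low-variance predictors
  score <- abs(cov_xy) / ifelse(sdx > 0, sdx, Inf)
  score[!keep | sdx == 0] <- -Inf
  k <- min(config$max_features, sum(is.finite(score) & score > -Inf))
  sel <- order(score, decreasing = TRUE)[seq_len(k)]
  Xs <- cbind(`(Intercept)` = 1, X[, sel, drop = FALSE])
  W <- weights
  XtWX <- crossprod(Xs, Xs * W)
  lambda <- 1e-10 * mean(diag(XtWX))
  A <- XtWX + diag(lambda, ncol(Xs))
  b <- crossprod(Xs, probs * W)
  kappa <- tryCatch(kappa(A, exact = FALSE), error = function(e) Inf)
  beta <- solve(A, b)
  fittedv <- drop(Xs %*% beta)
  ss_res <- sum(W * (probs - fittedv)^2)
  ss_tot <- sum(W * (probs - my)^2)
  coefs[sel] <- beta[-1]
  list(coefficients = coefs, intercept = beta[1],
       fidelity = 1 - ss_res / ss_tot,
       selected = colnames(X)[sel],
       condition_extreme = is.finite(kappa) && kappa > 1e12)
}

#' Explain a single prediction with a local linear surrogate
#'
#' Composes [perturb_samples()], the fitted model's probability calls and
#' [fit_surrogate()]. Features masked out by the fitted model are
#' excluded from the surrogate and reported with weight exactly 0.
#' Features are ranked by absolute weight (ties broken by feature order).
#'
#' @param fitted an `ivf_fitted` from [fit_model()].
#' @param instance named numeric vector (or 1-row data frame) with the
#'   model's training features.
#' @param cohort the training [cohort_table()] (source of perturbation
#'   statistics).
#' @param config an [explain_config()].
#' @return object of class `explanation`: `instance`, `predicted_class`,
#'   `predicted_probability`, `contributions` (data frame `feature`,
#'   `weight`, ranked), `intercept`, `fidelity`.
#' @export
explain_instance <- function(fitted, instance, cohort,
                             config = explain_config()) {
  stopifnot(inherits(fitted, "ivf_fitted"))
  st <- cohort_stats(cohort)
  if (is.data.frame(instance) || is.matrix(instance)) {
    instance <- as.numeric(as.data.frame(instance)[1, fitted$features])
  }
  names(instance) <- fitted$features
  pert <- perturb_samples(instance, st, config)
  probs <- predict(fitted, pert$X, type = "prob")
  sur <- fit_surrogate(pert$X, probs, pert$weights, config,
                       keep = fitted$mask == 1L)
  ord <- order(abs(sur$coefficients), decreasing = TRUE,
               seq_along(sur$coefficients))
  top <- ord[seq_len(min(config$max_features, length(ord)))]
  contributions <- data.frame(feature = names(sur$coefficients)[top],
                              weight = unname(sur$coefficients[top]))
  prob0 <- predict(fitted, matrix(instance, nrow = 1,
                                  dimnames = list(NULL, fitted$features)),
                   type = "prob")
  structure(list(instance = instance,
                 predicted_class = as.numeric(prob0 >= 0.5),
                 predicted_probability = prob0,
                 contributions = contributions,
                 intercept = sur$intercept, fidelity = sur$fidelity,
                 config = config),
            class = "explanation")
}

#' @export
print.explanation <- function(x, ...) {
  cat(sprintf("explanation: predicted class %d with probability %.3f (local fidelity R^2 = %.3f)\n",
              x$predicted_class, x$predicted_probability, x$fidelity))
  for (i in seq_len(nrow(x$contributions))) {
    cat(sprintf("  %-20s %+0.4f\n", x$contributions$feature[i],
                x$contributions$weight[i]))
  }
  invisible(x)
}

#' Serialize an explanation to JSON
#'
#' @param x an `explanation`.
#' @param path optional output file; when `NULL` the JSON string is
#'   returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
explanation_to_json <- function(x, path = NULL) {
  obj <- list(predicted_class = x$predicted_class,
              predicted_probability = x$predicted_probability,
              fidelity = x$fidelity, intercept = x$intercept,
              contributions = x$contributions)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
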