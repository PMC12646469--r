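# Synthetic cohort generator: marginal fidelity to the published summary
# table plus a configurable planted logistic outcome signal, so the whole
# pipeline is testable without the private patient data.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards. `seed = NULL` uses the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

#' Derive a component seed from a global seed
#'
#' Deterministic fan-out of one global seed into per-component seeds, so
#' each pipeline stage is independently reproducible. Kept below 2^31 - 1.
#'
#' @param seed integer global seed.
#' @param salt character label of the component.
#' @return integer seed.
#' @export
derive_seed <- function(seed, salt) {
  h <- sum(utf8ToInt(salt) * seq_along(utf8ToInt(salt)))
  as.integer((as.double(seed) * 48271 + h) %% 2147483647)
}

#' Default marginal specification of the study cohort
#'
#' Per-feature marginal distributions matching the published descriptive
#' table of the modified dataset: Bernoulli prevalences for the 20 binary
#' indicators, a truncated-and-rounded normal for age (mean 34.36, SD 4.58,
#' range 24-43), and a truncated negative binomial for oocyte count whose
#' post-truncation moments are calibrated to mean 7.58 and SD 9.81 on
#' [0, 58]. The outcome (transfer success) prevalence is 0.38.
#'
#' @return An object of class `marginal_spec`: a list with elements
#'   `binary` (named prevalences), `age`, `oocyte` and `outcome_prevalence`.
#' @export
default_table2_spec <- function() {
  structure(list(
    binary = c(working_status = 0.72, diagnosed_illness = 0.35, dha = 0.72,
               omega3 = 0.39, folic_acid = 0.10, coq10 = 0.30,
               vit_b12 = 0.03, ferritin = 0.04, vit_c = 0.03, vit_b6 = 0.03,
               vit_b5 = 0.006, vit_d = 0.09, phytoalexin = 0.02,
               magnesium = 0.04, selenium = 0.03, zinc = 0.02,
               melatonin = 0.006, exercise = 0.24, embryo_quality = 0.44,
               dietician_support = 0.25),
    age = list(mean = 34.36, sd = 4.58, lo = 24, hi = 43),
    oocyte = list(mean = 7.58, sd = 9.81, hi = 58),
    outcome_prevalence = 0.38
  ), class = "marginal_spec")
}

# Post-truncation mean and SD of a negative binomial (mu, size) truncated
# to {0, ..., hi}, by direct summation over the support.
truncated_nb_moments <- function(mu, size, hi) {
  k <- 0:hi
  p <- stats::dnbinom(k, mu = mu, size = size)
  w <- p / sum(p)
  m <- sum(k * w)
  v <- sum(k^2 * w) - m^2
  c(mean = m, sd = sqrt(v))
}

#' Calibrate a truncated negative binomial to target moments
#'
#' Finds (mu, size) of a negative binomial such that, after truncation to
#' `{0, ..., hi}`, the distribution has the requested mean and SD. The
#' variance far exceeds the mean in the study's oocyte counts, which rules
#' out a Poisson model. Solved by nested one-dimensional root searches:
#' for each dispersion `size`, `mu` is matched to the mean, and the outer
#' search matches the SD.
#'
#' @param mean,sd target post-truncation moments.
#' @param hi truncation bound (inclusive).
#' @return list with `mu`, `size`, and the achieved `moments`.
#' @export
calibrate_truncated_nb <- function(mean = 7.58, sd = 9.81, hi = 58) {
  if (sd^2 <= mean) stop("requires variance > mean (negative binomial)", call. = FALSE)
  mu_for <- function(size) {
    stats::uniroot(function(mu) truncated_nb_moments(mu, size, hi)["mean"] - mean,
                   interval = c(mean / 10, 1e4), tol = 1e-10)$root
  }
  # post-truncation SD decreases in size; sizes below ~0.2 cannot reach the
  # target mean under truncation, so the bracket starts above that
  sd_gap <- function(size) {
    truncated_nb_moments(mu_for(size), size, hi)["sd"] - sd
  }
  size <- stats::uniroot(sd_gap, interval = c(0.25, 5), tol = 1e-9)$root
  mu <- mu_for(size)
  list(mu = mu, size = size, moments = truncated_nb_moments(mu, size, hi))
}

# Reference moments (mean, sd) per predictor under the marginal spec; used
# to standardize predictors before applying planted coefficients.
spec_moments <- function(marginals) {
  feats <- table2_features()
  m <- s <- numeric(length(feats))
  names(m) <- names(s) <- feats
  for (f in names(marginals$binary)) {
    p <- marginals$binary[[f]]
    m[f] <- p
    s[f] <- sqrt(p * (1 - p))
  }
  m["age"] <- marginals$age$mean
  s["age"] <- marginals$age$sd
  m["oocyte_count"] <- marginals$oocyte$mean
  s["oocyte_count"] <- marginals$oocyte$sd
  list(mean = m, sd = s)
}

#' Configuration for synthetic cohort generation
#'
#' @param n cohort size (n >= 0).
#' @param seed integer RNG seed; a fixed seed yields a byte-identical cohort.
#' @param marginals a `marginal_spec`, default [default_table2_spec()].
#' @param beta named numeric vector of planted logistic coefficients on
#'   standardized predictors (names must be predictor names); unnamed
#'   predictors get coefficient 0. Effect sizes are therefore comparable
#'   across binary and count features.
#' @param beta0 logistic intercept; `NULL` (default) calibrates it so the
#'   marginal outcome prevalence matches `target_prevalence`.
#' @param target_prevalence outcome prevalence used when `beta0 = NULL`;
#'   defaults to the spec's `outcome_prevalence`.
#' @param correlation optional positive-definite correlation matrix
#'   (p x p, predictor order) for a Gaussian-copula dependence hook;
#'   `NULL` (default) draws features independently.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(n, seed = 1L, marginals = default_table2_spec(),
                             beta = numeric(0), beta0 = NULL,
                             target_prevalence = marginals$outcome_prevalence,
                             correlation = NULL) {
  if (n < 0) stop("n must be >= 0", call. = FALSE)
  feats <- table2_features()
  b <- stats::setNames(numeric(length(feats)), feats)
  if (length(beta) > 0L) {
    if (is.null(names(beta)) || !all(names(beta) %in% feats)) {
      stop("beta must be named with predictor names", call. = FALSE)
    }
    b[names(beta)] <- beta
  }
  stopifnot(all(is.finite(b)))
  structure(list(n = as.integer(n), seed = seed, marginals = marginals,
                 beta = b, beta0 = beta0,
                 target_prevalence = target_prevalence,
                 correlation = correlation),
            class = "synthetic_config")
}

# Draw the predictor matrix only (no outcome); used by both the generator
# and Monte-Carlo intercept calibration. Consumes the current RNG stream.
draw_features <- function(n, marginals, correlation = NULL) {
  feats <- table2_features()
  X <- matrix(0, nrow = n, ncol = length(feats), dimnames = list(NULL, feats))
  if (n == 0L) return(X)
  nb <- calibrate_truncated_nb(marginals$oocyte$mean, marginals$oocyte$sd,
                               marginals$oocyte$hi)
  k <- 0:marginals$oocyte$hi
  nbp <- stats::dnbinom(k, mu = nb$mu, size = nb$size)
  nbp <- nbp / sum(nbp)
  # uniforms per feature: independent by default, Gaussian copula otherwise
  U <- if (is.null(correlation)) {
    matrix(stats::runif(n * length(feats)), nrow = n)
  } else {
    L <- chol(correlation)
    Z <- matrix(stats::rnorm(n * length(feats)), nrow = n) %*% L
    stats::pnorm(Z)
  }
  colnames(U) <- feats
  for (f in names(marginals$binary)) {
    X[, f] <- as.numeric(U[, f] < marginals$binary[[f]])
  }
  a <- marginals$age
  plo <- stats::pnorm(a$lo, a$mean, a$sd)
  phi <- stats::pnorm(a$hi, a$mean, a$sd)
  X[, "age"] <- round(stats::qnorm(plo + U[, "age"] * (phi - plo), a$mean, a$sd))
  X[, "oocyte_count"] <- k[findInterval(U[, "oocyte_count"], cumsum(nbp)) + 1L]
  X
}

#' Calibrate the logistic intercept to a target outcome prevalence
#'
#' Finds the intercept `beta0` such that the marginal outcome prevalence
#' `E[logistic(beta0 + X beta)]` matches `target`. With a null coefficient
#' vector the closed form `qlogis(target)` is returned; otherwise the
#' expectation is estimated over `mc_n` Monte-Carlo feature draws and the
#' intercept found by bracketed root search, deterministic for fixed seed.
#'
#' @param config a [synthetic_config()] (its `beta`, `marginals` and
#'   `correlation` are used).
#' @param target target prevalence in (0, 1).
#' @param mc_n number of Monte-Carlo draws.
#' @param seed RNG seed for the draws.
#' @param tol tolerance of the root search.
#' @return intercept value (numeric scalar).
#' @export
calibrate_intercept <- function(config, target = config$target_prevalence,
                                mc_n = 100000L, seed = config$seed, tol = 1e-10) {
  stopifnot(target > 0, target < 1)
  if (all(config$beta == 0)) return(stats::qlogis(target))
  eta <- with_seed(seed, {
    Xs <- standardize_features(draw_features(mc_n, config$marginals,
                                             config$correlation),
                               config$marginals)
    drop(Xs %*% config$beta)
  })
  f <- function(b0) mean(stats::plogis(b0 + eta)) - target
  lo <- -30; hi <- 30
  if (f(lo) > 0 || f(hi) < 0) {
    stop(sprintf("intercept calibration failed: f(%g) = %g, f(%g) = %g",
                 lo, f(lo), hi, f(hi)), call. = FALSE)
  }
  stats::uniroot(f, c(lo, hi), tol = tol)$root
}

# Standardize a predictor matrix by the spec's reference moments.
standardize_features <- function(X, marginals) {
  mom <- spec_moments(marginals)
  sweep(sweep(X, 2, mom$mean[colnames(X)]), 2, mom$sd[colnames(X)], "/")
}

#' Generate a synthetic cohort
#'
#' Draws predictors from the marginal specification (independently unless a
#' copula correlation is supplied) and the binary outcome from
#' `Bernoulli(logistic(beta0 + Xs beta))`, where `Xs` is the predictor
#' matrix standardized by the spec's reference moments. A fixed seed yields
#' a byte-identical cohort; the result passes [validate_cohort()] by
#' construction whenever both outcome classes are drawn.
#'
#' @param config a [synthetic_config()].
#' @return A [cohort_table()] with `config$n` rows.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  beta0 <- config$beta0
  if (is.null(beta0)) {
    beta0 <- calibrate_intercept(config,
                                 seed = derive_seed(config$seed, "intercept"))
  }
  d <- with_seed(config$seed, {
    X <- draw_features(config$n, config$marginals, config$correlation)
    eta <- if (config$n > 0L) {
      beta0 + drop(standardize_features(X, config$marginals) %*% config$beta)
    } else numeric(0)
    y <- stats::rbinom(config$n, 1L, stats::plogis(eta))
    cbind(as.data.frame(X), transfer_state = as.numeric(y))
  })
  cohort_table(d, provenance = sprintf("synthetic cohort (n = %d, seed = %s)",
                                       config$n, format(config$seed)),
               validate = FALSE)
}

#' Construct intake records that binarize to a requested flag matrix
#'
#' Builds raw intake records whose active-ingredient binarization (under the
#' default sum-across-products policy) reproduces a requested 0/1 flag
#' matrix exactly: flagged ingredients get a total daily amount in
#' [100%, 300%] of the requirement (possibly split over two products),
#' unflagged ones get either no record or a sub-threshold amount in
#' [0%, 99%].
#'
#' @param flags 0/1 matrix or data frame, patients x ingredients; column
#'   names must appear in `rdi$ingredient`. Row names (or
#'   `paste0("P", row)` by default) become patient ids.
#' @param rdi daily-requirement table (see [read_rdi()]).
#' @param seed RNG seed.
#' @return data frame of intake records (see [read_intakes()]).
#' @export
generate_intake_fixture <- function(flags, rdi, seed = 1L) {
  flags <- as.matrix(flags)
  stopifnot(all(flags %in% c(0, 1)), all(colnames(flags) %in% rdi$ingredient))
  ids <- rownames(flags)
  if (is.null(ids)) ids <- paste0("P", seq_len(nrow(flags)))
  with_seed(seed, {
    rows <- list()
    for (i in seq_len(nrow(flags))) {
      for (ing in colnames(flags)) {
        req <- rdi$daily_requirement[rdi$ingredient == ing]
        unit <- rdi$unit[rdi$ingredient == ing]
        if (flags[i, ing] == 1) {
          total <- stats::runif(1, 1.0, 3.0) * req
          split <- stats::runif(1) < 0.5
          if (split) {
            a <- stats::runif(1, 0.2, 0.8) * total
            rows[[length(rows) + 1L]] <- data.frame(
              patient_id = ids[i], product = paste0("prod_", ing, "_a"),
              ingredient = ing, amount = a, unit = unit)
            rows[[length(rows) + 1L]] <- data.frame(
              patient_id = ids[i], product = paste0("prod_", ing, "_b"),
              ingredient = ing, amount = total - a, unit = unit)
          } else {
            rows[[length(rows) + 1L]] <- data.frame(
              patient_id = ids[i], product = paste0("prod_", ing),
              ingredient = ing, amount = total, unit = unit)
          }
        } else if (stats::runif(1) < 0.5) {
          rows[[length(rows) + 1L]] <- data.frame(
            patient_id = ids[i], product = paste0("prod_", ing),
            ingredient = ing, amount = stats::runif(1, 0, 0.99) * req,
            unit = unit)
        }
      }
    }
    if (length(rows) == 0L) {
      return(data.frame(patient_id = character(), product = character(),
                        ingredient = character(), amount = numeric(),
                        unit = character()))
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
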