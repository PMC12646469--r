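# Artificial bee colony (ABC) metaheuristic: employed, onlooker and scout
# phases with greedy selection, fitness-proportional recruitment and an
# abandonment limit, over continuous boxes or thresholded binary masks.

#' ABC optimizer configuration
#'
#' @param n_sources number of food sources (candidate solutions); one
#'   employed bee per source and equally many onlooker selections per
#'   iteration. Default 15.
#' @param max_iterations number of colony iterations. Default 30.
#' @param abandonment abandonment parameter expressed as a fraction of the
#'   total evaluation budget: the trial limit is
#'   `max(1, round(abandonment * n_sources * max_iterations))` (half-up
#'   rounding), i.e. 5 unimproved trials at the defaults. A raw fractional
#'   trial count would be meaningless for an integer counter.
#' @param limit explicit integer trial limit overriding `abandonment`.
#' @param seed RNG seed; fixed seed gives an identical trajectory.
#' @param elitism track and return the global best over the whole
#'   trajectory (default `TRUE`), guaranteeing a monotone non-increasing
#'   best-so-far history.
#' @return list of class `abc_config`.
#' @export
abc_config <- function(n_sources = 15L, max_iterations = 30L,
                       abandonment = 0.01, limit = NULL, seed = 1L,
                       elitism = TRUE) {
  stopifnot(n_sources >= 2L, max_iterations >= 1L)
  if (is.null(limit)) {
    limit <- max(1L, as.integer(floor(abandonment * n_sources * max_iterations + 0.5)))
  }
  structure(list(n_sources = as.integer(n_sources),
                 max_iterations = as.integer(max_iterations),
                 abandonment = abandonment, limit = as.integer(limit),
                 seed = seed, elitism = isTRUE(elitism)),
            class = "abc_config")
}

#' Search space for the ABC optimizer
#'
#' Positions always live in a continuous box. With `encoding =
#' "binary_mask"` a position is decoded to a feature-inclusion mask by
#' thresholding (see [decode_mask()]) before the objective is evaluated.
#'
#' @param dimension number of coordinates (>= 1).
#' @param encoding `"continuous"` or `"binary_mask"`.
#' @param lower,upper per-dimension bounds (recycled to `dimension`).
#' @param threshold decode threshold in (0, 1) for binary masks.
#' @return list of class `search_space`.
#' @export
search_space <- function(dimension, encoding = c("continuous", "binary_mask"),
                         lower = 0, upper = 1, threshold = 0.5) {
  encoding <- match.arg(encoding)
  stopifnot(dimension >= 1L, threshold > 0, threshold < 1)
  lower <- rep_len(lower, dimension)
  upper <- rep_len(upper, dimension)
  stopifnot(all(lower <= upper))
  structure(list(dimension = as.integer(dimension), encoding = encoding,
                 lower = lower, upper = upper, threshold = threshold),
            class = "search_space")
}

#' Fitness transform of an objective value
#'
#' Canonical ABC transform mapping a minimized objective to a positive
#' fitness: `1 / (1 + f)` for `f >= 0` and `1 + |f|` otherwise.
#'
#' @param f numeric objective value(s).
#' @return positive fitness value(s).
#' @export
abc_fitness <- function(f) ifelse(f >= 0, 1 / (1 + f), 1 + abs(f))

#' Onlooker selection probabilities
#'
#' Fitness-proportional recruitment: `p_i = fitness_i / sum(fitness)`. An
#' all-zero fitness vector falls back to uniform probabilities.
#'
#' @param fitness vector of non-negative finite fitness values.
#' @return probability vector summing to 1.
#' @export
selection_probabilities <- function(fitness) {
  stopifnot(all(is.finite(fitness)), all(fitness >= 0))
  s <- sum(fitness)
  if (s == 0) return(rep(1 / length(fitness), length(fitness)))
  fitness / s
}

#' Decode a continuous position into a feature mask
#'
#' `mask_j = 1` iff `position_j >= threshold` (closed lower boundary: a
#' coordinate exactly at the threshold is included). An all-zero mask is
#' infeasible for model fitting and is flagged.
#'
#' @param position numeric vector.
#' @param space a [search_space()] with `encoding = "binary_mask"`.
#' @return integer 0/1 vector with attribute `infeasible` (logical).
#' @export
decode_mask <- function(position, space) {
  stopifnot(space$encoding == "binary_mask")
  m <- as.integer(position >= space$threshold)
  attr(m, "infeasible") <- all(m == 0L)
  m
}

#' Single-coordinate neighborhood move
#'
#' The canonical ABC perturbation `v_j = x_j + phi * (x_j - x_kj)` with
#' `phi ~ Uniform(-1, 1)`, applied to one coordinate and clipped to the
#' box. The candidate differs from the source in at most that coordinate
#' (exactly, unless source and partner coincide there).
#'
#' @param position source position.
#' @param partner partner position (another food source).
#' @param dim coordinate index to perturb.
#' @param space a [search_space()].
#' @param phi perturbation multiplier; drawn `Uniform(-1, 1)` when `NULL`.
#' @return candidate position vector.
#' @export
neighbor_move <- function(position, partner, dim, space, phi = NULL) {
  if (is.null(phi)) phi <- stats::runif(1, -1, 1)
  v <- position
  v[dim] <- position[dim] + phi * (position[dim] - partner[dim])
  v[dim] <- min(max(v[dim], space$lower[dim]), space$upper[dim])
  v
}

# Largest finite sentinel for infeasible decodings: never selected over a
# real objective value and quickly abandoned.
infeasible_sentinel <- function() .Machine$double.xmax

# Evaluate a position: binary spaces decode first and short-circuit
# infeasible all-zero masks with the sentinel.
evaluate_position <- function(objective, position, space) {
  if (space$encoding == "binary_mask") {
    m <- decode_mask(position, space)
    if (attr(m, "infeasible")) return(infeasible_sentinel())
    f <- objective(m)
  } else {
    f <- objective(position)
  }
  if (!is.finite(f)) {
    stop("non-finite objective at position (",
         paste(signif(position, 4), collapse = ", "), ")", call. = FALSE)
  }
  f
}

#' Initialize the food-source population
#'
#' Draws `n_sources` positions uniformly within the box and evaluates each
#' once. Trial counters start at 0.
#'
#' @param objective objective function (minimized). For binary-mask spaces
#'   it receives the decoded integer mask, otherwise the position vector.
#' @param space a [search_space()].
#' @param config an [abc_config()]. The caller controls the RNG stream.
#' @param init_positions optional matrix of positions (rows) used verbatim
#'   for the first food sources (clipped to the box), e.g. a warm start.
#' @return list with `positions` (n_sources x d matrix), `objectives`,
#'   `trials`.
#' @export
init_sources <- function(objective, space, config, init_positions = NULL) {
  d <- space$dimension
  pos <- matrix(stats::runif(config$n_sources * d), ncol = d)
  pos <- sweep(sweep(pos, 2, space$upper - space$lower, "*"), 2, space$lower, "+")
  if (!is.null(init_positions)) {
    init_positions <- matrix(init_positions, ncol = d)
    k <- min(nrow(init_positions), config$n_sources)
    for (r in seq_len(k)) {
      pos[r, ] <- pmin(pmax(init_positions[r, ], space$lower), space$upper)
    }
  }
  obj <- apply(pos, 1, function(x) evaluate_position(objective, x, space))
  list(positions = pos, objectives = obj,
       trials = integer(config$n_sources))
}

#' Run the artificial bee colony optimizer
#'
#' Each iteration runs (1) the employed phase: every source proposes a
#' single-coordinate neighborhood move against a random partner and keeps
#' the better of the pair (greedy selection, trial counter reset on
#' improvement); (2) the onlooker phase: `n_sources` selections drawn with
#' fitness-proportional probabilities, each triggering another
#' neighborhood move on the selected source; (3) the scout phase: at most
#' one source per iteration whose trial counter exceeds the abandonment
#' limit (the worst offender) is replaced by a fresh uniform draw.
#'
#' @param objective function to minimize. For binary-mask spaces it is
#'   called with the decoded integer mask (infeasible all-zero masks are
#'   short-circuited with a largest-finite sentinel and never reach it);
#'   for continuous spaces with the position vector.
#' @param space a [search_space()].
#' @param config an [abc_config()].
#' @param init_positions optional warm-start positions (see
#'   [init_sources()]).
#' @return list of class `abc_result`: `best_position`, `best_objective`,
#'   `best_mask` (binary spaces), `history` (data frame with `iteration`,
#'   `best_objective`, `mean_objective`), `n_evaluations`, `n_scouts`.
#' @export
abc_optimize <- function(objective, space, config = abc_config(),
                         init_positions = NULL) {
  n_eval <- 0L
  counting <- function(x) { n_eval <<- n_eval + 1L; objective(x) }
  with_seed(config$seed, {
    st <- init_sources(counting, space, config, init_positions)
    pos <- st$positions; obj <- st$objectives; trials <- st$trials
    ns <- config$n_sources
    best_i <- which.min(obj)
    best_pos <- pos[best_i, ]; best_obj <- obj[best_i]
    history <- data.frame(iteration = integer(), best_objective = numeric(),
                          mean_objective = numeric())
    n_scouts <- 0L

    try_move <- function(i) {
      k <- sample(setdiff(seq_len(ns), i), 1L)
      j <- sample(space$dimension, 1L)
      cand <- neighbor_move(pos[i, ], pos[k, ], j, space)
      f <- evaluate_position(counting, cand, space)
      if (f < obj[i]) {
        pos[i, ] <<- cand; obj[i] <<- f; trials[i] <<- 0L
        if (f < best_obj) { best_obj <<- f; best_pos <<- cand }
      } else {
        trials[i] <<- trials[i] + 1L
      }
    }

    for (iter in seq_len(config$max_iterations)) {
      for (i in seq_len(ns)) try_move(i)                      # employed
      p <- selection_probabilities(abc_fitness(obj))
      picks <- sample.int(ns, ns, replace = TRUE, prob = p)   # onlookers
      for (i in picks) try_move(i)
      over <- which(trials > config$limit)                    # scout
      if (length(over) > 0L) {
        i <- over[which.max(trials[over])]
        fresh <- space$lower + stats::runif(space$dimension) *
          (space$upper - space$lower)
        pos[i, ] <- fresh
        obj[i] <- evaluate_position(counting, fresh, space)
        trials[i] <- 0L
        n_scouts <- n_scouts + 1L
        if (obj[i] < best_obj) { best_obj <- obj[i]; best_pos <- fresh }
      }
      if (!config$elitism) {
        bi <- which.min(obj)
        best_obj <- obj[bi]; best_pos <- pos[bi, ]
      }
      history <- rbind(history, data.frame(
        iteration = iter, best_objective = best_obj,
        mean_objective = mean(obj[obj < infeasible_sentinel()])))
    }

    res <- list(best_position = best_pos, best_objective = best_obj,
                history = history, n_evaluations = n_eval,
                n_scouts = n_scouts, config = config, space = space)
    if (space$encoding == "binary_mask") {
      res$best_mask <- decode_mask(best_pos, space)
    }
    structure(res, class = "abc_result")
  })
}

#' @export
print.abc_result <- function(x, ...) {
  cat(sprintf("abc_result: best objective %.6g after %d evaluations (%d scouts)\n",
              x$best_objective, x$n_evaluations, x$n_scouts))
  if (!is.null(x$best_mask)) {
    cat("best mask:", paste(x$best_mask, collapse = ""), "\n")
  }
  invisible(x)
}

#' Parameter sensitivity grid for the ABC optimizer
#'
#' Runs the optimizer across a grid of (n_sources, max_iterations,
#' abandonment) settings and several seeds, reporting the mean and SD of
#' the best objective per setting — the protocol used for metaheuristic
#' parameter sensitivity analyses.
#'
#' @param objective,space as in [abc_optimize()].
#' @param n_sources,max_iterations,abandonment vectors of settings; the
#'   full cross product is evaluated.
#' @param seeds integer vector of seeds per setting.
#' @return data frame with one row per setting: the parameters,
#'   `mean_best`, `sd_best`, `n_seeds`.
#' @export
abc_sensitivity_grid <- function(objective, space, n_sources = c(10L, 15L, 20L),
                                 max_iterations = c(15L, 30L, 60L),
                                 abandonment = c(0.005, 0.01, 0.02),
                                 seeds = 1:5) {
  grid <- expand.grid(n_sources = n_sources, max_iterations = max_iterations,
                      abandonment = abandonment)
  res <- lapply(seq_len(nrow(grid)), function(g) {
    best <- vapply(seeds, function(s) {
      cfg <- abc_config(grid$n_sources[g], grid$max_iterations[g],
                        grid$abandonment[g], seed = s)
      abc_optimize(objective, space, cfg)$best_objective
    }, numeric(1))
    cbind(grid[g, , drop = FALSE],
          data.frame(mean_best = mean(best), sd_best = stats::sd(best),
                     n_seeds = length(seeds)))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
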