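#' Parameter grid for detector tuning
#'
#' A named collection of candidate values whose cartesian product is
#' enumerated in declaration order: the first declared parameter varies
#' slowest, the last fastest, so grid point 1 pairs every parameter with
#' its first candidate.
#'
#' @param ... named vectors of candidate values (at least one).
#' @return an object of class `param_grid`: a list of named parameter
#'   lists, one per grid point.
#' @examples
#' g <- param_grid(k = c(2, 5, 10), cutoff = c(0.7, 0.9))
#' length(g)
#' g[[1]]
#' @export
param_grid <- function(...) {
  params <- list(...)
  if (length(params) == 0L || is.null(names(params)) ||
      any(names(params) == "")) {
    stop("param_grid() needs at least one named parameter")
  }
  if (any(lengths(params) == 0L)) stop("parameters need at least one value")
  # expand.grid varies the first factor fastest; reverse to get
  # declaration-order iteration (first parameter slowest)
  df <- expand.grid(rev(params), KEEP.OUT.ATTRS = FALSE,
                    stringsAsFactors = FALSE)[, names(params), drop = FALSE]
  points <- lapply(seq_len(nrow(df)), function(i) as.list(df[i, , drop = FALSE]))
  structure(points, class = "param_grid")
}

#' @export
print.param_grid <- function(x, ...) {
  cat(sprintf("param_grid: %d points over {%s}\n", length(x),
              paste(names(x[[1L]]), collapse = ", ")))
  invisible(x)
}

#' Grid-search training of a module detector
#'
#' Runs a detector at every grid point, scores each resulting module set
#' against the known modules with the permutation-normalized composite
#' ([normalized_scores()]), and records the best parameters. A detector is
#' any function `f(expr, params)` (or `f(expr, params, seed)` for seeded
#' methods) returning a [module_set]; a failing grid point scores 0 with a
#' warning rather than aborting the search. Observed modules are passed
#' through [restrict_observed()] before scoring. Ties in the best score go
#' to the earliest grid point.
#'
#' @param detector detector function (see above).
#' @param grid a [param_grid()].
#' @param expr numeric genes x samples expression matrix.
#' @param known non-empty [module_set] of known modules.
#' @param universe scoring/permutation universe; defaults to the union of
#'   known-module genes.
#' @param n_perm permutations for score normalization.
#' @param seed integer seed (scoring and seeded detectors).
#' @param min_size minimum observed-module size kept before scoring.
#' @param dataset optional dataset identifier carried into the result.
#' @param definition optional module-definition identifier.
#' @param real optional logical realness tag (`TRUE` = real data); used by
#'   [transfer_test()] to refuse synthetic-to-real parameter transfer.
#' @return an object of class `tune_result`: list with `scores` (one per
#'   grid point), `best_index`, `best_params`, `training_score`, `grid`,
#'   `dataset`, `definition`, `real`, `seed`.
#' @export
grid_search <- function(detector, grid, expr, known, universe = NULL,
                        n_perm = 100L, seed = 1L, min_size = 5L,
                        dataset = NULL, definition = NULL, real = NA) {
  stopifnot(is.function(detector), inherits(grid, "param_grid"))
  stopifnot(inherits(known, "module_set"), length(known) > 0L)
  if (is.null(universe)) universe <- module_genes(known)
  scores <- vapply(seq_along(grid), function(i) {
    score_grid_point(detector, grid[[i]], expr, known, universe,
                     n_perm, seed, min_size)
  }, numeric(1L))
  best <- which.max(scores)  # first maximizer on ties
  structure(list(scores = scores,
                 best_index = best,
                 best_params = grid[[best]],
                 training_score = scores[best],
                 grid = grid,
                 dataset = dataset, definition = definition, real = real,
                 seed = as.integer(seed)),
            class = "tune_result")
}

score_grid_point <- function(detector, params, expr, known, universe,
                             n_perm, seed, min_size) {
  observed <- tryCatch({
    if (length(formals(detector)) >= 3L) detector(expr, params, seed)
    else detector(expr, params)
  }, error = function(e) {
    warning("detector failed (", conditionMessage(e), "); scoring 0",
            call. = FALSE)
    NULL
  })
  if (is.null(observed) || length(observed) == 0L) return(0)
  observed <- restrict_observed(observed, universe, min_size = min_size)
  if (length(observed) == 0L) return(0)
  normalized_scores(known, observed, universe = universe,
                    n_perm = n_perm, seed = seed)$composite
}

#' @export
print.tune_result <- function(x, ...) {
  cat(sprintf("tune_result: %d grid points, training score %.4f at point %d\n",
              length(x$scores), x$training_score, x$best_index))
  cat("  best params:",
      paste(names(x$best_params), unlist(x$best_params), sep = "=",
            collapse = ", "), "\n")
  invisible(x)
}

#' Cross-dataset parameter transfer (test score)
#'
#' Scores a detector on a target dataset using the best parameters learned
#' on a source dataset — the cross-validation-style test score that
#' penalizes parameter overfitting. Parameters tuned on synthetic data do
#' not generalize to real data, so the transfer refuses to move parameters
#' from a synthetic source to a real target when both carry realness tags.
#'
#' @param source a `tune_result` from [grid_search()].
#' @param detector the detector function.
#' @param target_expr target expression matrix.
#' @param target_known target known [module_set].
#' @param universe scoring universe (default: target known genes).
#' @param n_perm,seed,min_size as in [grid_search()].
#' @param target_real optional logical realness tag of the target dataset.
#' @return the test score (normalized composite, a single number).
#' @export
transfer_test <- function(source, detector, target_expr, target_known,
                          universe = NULL, n_perm = 100L, seed = 1L,
                          min_size = 5L, target_real = NA) {
  stopifnot(inherits(source, "tune_result"))
  if (isFALSE(source$real) && isTRUE(target_real)) {
    stop("refusing to transfer parameters tuned on synthetic data to a ",
         "real dataset")
  }
  if (is.null(universe)) universe <- module_genes(target_known)
  score_grid_point(detector, source$best_params, target_expr, target_known,
                   universe, n_perm, seed, min_size)
}

#' Aggregate scores with equal influence per organism and definition
#'
#' Final benchmark aggregation: a weighted mean over (dataset, module
#' definition) scores where each organism and each module definition
#' exerts equal total influence regardless of how many datasets an
#' organism contributes. Row weights are
#' `1 / (n_organisms * n_datasets_in_that_organism * n_definitions)`.
#'
#' @param scores data.frame with columns `dataset`, `organism`,
#'   `definition`, `score` (no missing labels).
#' @return the aggregate score (single number).
#' @examples
#' df <- data.frame(dataset = c("d1", "d2", "d3", "d4"),
#'                  organism = c("A", "B", "B", "B"),
#'                  definition = "minimal",
#'                  score = c(1, 0, 0, 0))
#' aggregate_scores(df)  # organism A carries half the weight -> 0.5
#' @export
aggregate_scores <- function(scores) {
  req <- c("dataset", "organism", "definition", "score")
  if (!is.data.frame(scores) || !all(req %in% names(scores))) {
    stop("`scores` needs columns dataset, organism, definition, score")
  }
  if (nrow(scores) == 0L) stop("`scores` must be non-empty")
  lab <- scores[, c("dataset", "organism", "definition")]
  if (anyNA(lab) || any(as.matrix(lab) == "")) {
    stop("missing dataset/organism/definition label")
  }
  n_org <- length(unique(scores$organism))
  n_def <- length(unique(scores$definition))
  datasets_per_org <- tapply(scores$dataset, scores$organism,
                             function(d) length(unique(d)))
  w <- 1 / (n_org * datasets_per_org[scores$organism] * n_def)
  sum(w * scores$score) / sum(w)
}

#' Subsample and noise a dataset
#'
#' Dataset perturbation for robustness analysis: keeps a uniform random
#' subset of `round(sample_fraction * n)` samples (without replacement,
#' original column order preserved) and adds i.i.d. Gaussian noise with
#' standard deviation `noise_sd` to every value.
#'
#' @param expr numeric genes x samples matrix.
#' @param sample_fraction fraction of samples kept, in (0, 1\].
#' @param noise_sd non-negative noise standard deviation.
#' @param seed integer seed.
#' @return the perturbed matrix; an error if fewer than 2 samples remain.
#' @export
perturb_dataset <- function(expr, sample_fraction = 1, noise_sd = 0,
                            seed = 1L) {
  check_expression(expr, min_samples = 2L)
  stopifnot(sample_fraction > 0, sample_fraction <= 1, noise_sd >= 0)
  n <- ncol(expr)
  keep_n <- round(sample_fraction * n)
  if (keep_n < 2L) stop("perturbation would leave fewer than 2 samples")
  withr::with_seed(seed, {
    keep <- sort(sample.int(n, keep_n))
    out <- expr[, keep, drop = FALSE]
    if (noise_sd > 0) {
      out <- out + matrix(stats::rnorm(length(out), sd = noise_sd),
                          nrow = nrow(out))
    }
    out
  })
}
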