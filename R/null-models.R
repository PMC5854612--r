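#' Permute a module set by random gene relabeling
#'
#' Draws one uniform random bijection of the universe onto itself and
#' replaces every gene occurrence in every module by its image. Module
#' count, sizes, and all pairwise intersection sizes are preserved exactly
#' — only the assignment of genes to the structure changes, making this
#' the null model for "how well would a method score against modules with
#' the same structure but random content".
#'
#' @param ms a [module_set]
#' @param universe character vector containing all genes of `ms` (typically
#'   all genes of the expression dataset).
#' @param seed integer seed; the same seed yields the same permutation.
#' @return a [module_set] with the same structure and permuted genes.
#' @export
permute_modules <- function(ms, universe, seed) {
  stopifnot(inherits(ms, "module_set"))
  universe <- unique(as.character(universe))
  miss <- setdiff(module_genes(ms), universe)
  if (length(miss) > 0L) {
    stop("universe lacks module gene(s): ",
         paste(utils::head(miss, 5L), collapse = ", "))
  }
  withr::with_seed(seed, permute_modules_impl(ms, universe))
}

# uses the current RNG state (callers manage seeding)
permute_modules_impl <- function(ms, universe) {
  image <- sample(universe)
  names(image) <- universe
  mods <- lapply(ms$modules, function(g) unname(image[g]))
  module_set(mods, universe = universe)
}

#' Permutation-normalized module comparison scores
#'
#' Computes the four raw comparison scores (recovery, relevance and the
#' overlap-aware recall and precision) between known and observed modules,
#' then normalizes each by its mean over `n_perm` random gene-relabeling
#' permutations of the *known* set ([permute_modules()]); the observed set
#' stays fixed. A normalized score of x reads as "x-fold improvement over
#' structurally identical random modules", which stops easy module
#' structures (few, small, non-overlapping modules) from inflating
#' comparisons across datasets and module definitions. The composite is
#' the harmonic mean of the four normalized scores.
#'
#' @param known,observed non-empty [module_set]s (restrict the observed set
#'   with [restrict_observed()] first).
#' @param universe permutation universe; defaults to the union of
#'   known-module genes, but pass all genes of the expression dataset when
#'   available.
#' @param n_perm number of permutations (500 gives stable null means;
#'   smaller values trade precision for speed).
#' @param seed integer seed controlling the permutation stream.
#' @return an object of class `score_report`: a list with elements `raw`,
#'   `null_means`, `null_sds`, `normalized` (named numeric vectors over
#'   recovery / relevance / recall / precision), `null_values` (the
#'   `n_perm` x 4 matrix of per-permutation raw scores), `composite`,
#'   `n_permutations`, `seed`.
#' @examples
#' known <- module_set(list(a = c("g1", "g2", "g3"), b = c("g3", "g4", "g5")))
#' r <- normalized_scores(known, known, n_perm = 50, seed = 1)
#' r$composite > 1
#' @export
normalized_scores <- function(known, observed, universe = NULL,
                              n_perm = 500L, seed = 1L) {
  stopifnot(inherits(known, "module_set"), inherits(observed, "module_set"))
  stopifnot(n_perm >= 1L)
  if (is.null(universe)) universe <- module_genes(known)
  universe <- unique(as.character(universe))
  miss <- setdiff(module_genes(known), universe)
  if (length(miss) > 0L) {
    stop("permutation universe lacks known-module gene(s): ",
         paste(utils::head(miss, 5L), collapse = ", "))
  }
  raw <- raw_scores(known, observed)
  null_values <- matrix(NA_real_, n_perm, length(raw),
                        dimnames = list(NULL, names(raw)))
  withr::with_seed(seed, {
    for (i in seq_len(n_perm)) {
      perm <- permute_modules_impl(known, universe)
      null_values[i, ] <- raw_scores(perm, observed)
    }
  })
  null_means <- colMeans(null_values)
  if (any(null_means == 0)) {
    stop("permutation null mean is 0 for: ",
         paste(names(raw)[null_means == 0], collapse = ", "),
         "; use a larger universe or more permutations")
  }
  normalized <- raw / null_means
  structure(list(raw = raw,
                 null_means = null_means,
                 null_sds = apply(null_values, 2L, stats::sd),
                 null_values = null_values,
                 normalized = normalized,
                 composite = harmonic_mean(normalized),
                 n_permutations = as.integer(n_perm),
                 seed = as.integer(seed)),
            class = "score_report")
}

# the four raw scores in fixed order
raw_scores <- function(known, observed) {
  m <- match_scores(known, observed)
  p <- cice_scores(known, observed)
  c(recovery = unname(m["recovery"]), relevance = unname(m["relevance"]),
    recall = unname(p["recall"]), precision = unname(p["precision"]))
}

#' @export
print.score_report <- function(x, ...) {
  cat("module comparison (", x$n_permutations, " permutations, seed ",
      x$seed, ")\n", sep = "")
  tab <- rbind(raw = x$raw, `null mean` = x$null_means,
               normalized = x$normalized)
  print(round(tab, 4))
  cat(sprintf("composite (harmonic mean of normalized): %.4f\n", x$composite))
  invisible(x)
}

#' Degree-preserving random rewiring of a network (sticky model)
#'
#' Generates a random directed network whose expected in- and out-degree
#' sequences match the input. Each node gets an outgoing stickiness
#' `s_out = outdeg / sqrt(|E|)` and incoming stickiness
#' `s_in = indeg / sqrt(|E|)`; every potential edge (r, t) over the
#' network's nodes is then included independently with probability
#' `min(1, s_out(r) * s_in(t))`. Useful as a structure-aware null model
#' for network-derived module definitions.
#'
#' @param net a [regulatory_network]
#' @param seed integer seed.
#' @return an unweighted [regulatory_network] (possibly empty; an attribute
#'   is not kept for empty draws, which return a 0-row network).
#' @export
sticky_rewire <- function(net, seed) {
  stopifnot(inherits(net, "regulatory_network"))
  nodes <- network_nodes(net)
  n_edges <- nrow(net)
  if (n_edges == 0L) return(regulatory_network(character(0), character(0)))
  outdeg <- table(factor(net$regulator, levels = nodes))
  indeg <- table(factor(net$target, levels = nodes))
  s_out <- as.numeric(outdeg) / sqrt(n_edges)
  s_in <- as.numeric(indeg) / sqrt(n_edges)
  p <- pmin(1, outer(s_out, s_in))
  draw <- withr::with_seed(seed, {
    matrix(stats::runif(length(p)) < p, nrow = length(nodes))
  })
  idx <- which(draw, arr.ind = TRUE)
  regulatory_network(nodes[idx[, 1L]], nodes[idx[, 2L]])
}
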