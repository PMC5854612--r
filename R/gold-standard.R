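#' Known modules by minimal co-regulation
#'
#' Under the minimal co-regulation definition, genes sharing at least one
#' regulator form a module: every regulator with at least one target yields
#' one module (its regulon), named after the regulator. Modules may overlap
#' since a gene can have several regulators.
#'
#' @param net a [regulatory_network]
#' @return a [module_set], one module per regulator, in first-appearance
#'   order of the regulators.
#' @seealso [strict_coregulation()], [interconnected_modules()],
#'   [filter_modules()]
#' @export
minimal_coregulation <- function(net) {
  stopifnot(inherits(net, "regulatory_network"))
  if (nrow(net) == 0L) stop("network has no edges")
  regs <- unique(net$regulator)
  modules <- lapply(regs, function(r) unique(net$target[net$regulator == r]))
  names(modules) <- regs
  module_set(modules)
}

#' Known modules by strict co-regulation
#'
#' Genes regulated by exactly the same set of regulators form a module.
#' The result is a partition of the regulated genes (pairwise disjoint,
#' covering every gene with at least one incoming edge); unregulated genes
#' are excluded. Modules are named by their sorted regulator set joined
#' with `+`.
#'
#' @param net a [regulatory_network]
#' @return a [module_set] partitioning the regulated genes.
#' @export
strict_coregulation <- function(net) {
  stopifnot(inherits(net, "regulatory_network"))
  if (nrow(net) == 0L) stop("network has no edges")
  regsets <- split(net$regulator, net$target)
  key <- vapply(regsets, function(r) paste(sort(unique(r)), collapse = "+"),
                character(1L))
  groups <- split(names(regsets), key)
  # deterministic order: by first target gene's appearance in the edge list
  first_pos <- vapply(groups, function(g) min(match(g, net$target)), numeric(1L))
  groups <- groups[order(first_pos)]
  module_set(groups)
}

#' Known modules from graph interconnectivity (Markov clustering)
#'
#' Clusters the regulatory network into strongly interconnected gene groups
#' using the Markov Cluster algorithm (MCL) on the symmetrized adjacency
#' matrix. The inflation parameter controls granularity: larger values give
#' smaller, tighter clusters (typical settings: 2, 10, 50).
#'
#' MCL details: the adjacency matrix is symmetrized by `max(A, t(A))`, unit
#' self-loops are added, and columns are normalized to a stochastic matrix.
#' Expansion (matrix square) alternates with inflation (elementwise power
#' and column renormalization); entries below `1e-8` are pruned each
#' iteration. Convergence is declared when the largest absolute change
#' falls below `1e-6`. Clusters are read from the attractor rows of the
#' limit matrix; attractor rows spanning the same node set are deduplicated
#' but genuinely overlapping clusters are kept.
#'
#' @param net a [regulatory_network]; edge weights are used as adjacency
#'   values when present.
#' @param inflation inflation exponent, must be > 1.
#' @param max_iter iteration cap; non-convergence is an error reporting the
#'   residual change.
#' @return a [module_set] over the network's nodes, modules named
#'   `mcl_1`, `mcl_2`, ... ordered by decreasing size.
#' @export
interconnected_modules <- function(net, inflation = 2, max_iter = 200L) {
  stopifnot(inherits(net, "regulatory_network"))
  if (nrow(net) == 0L) stop("network has no edges")
  stopifnot(is.numeric(inflation), length(inflation) == 1L, inflation > 1)
  nodes <- network_nodes(net)
  n <- length(nodes)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  w <- if (is_weighted(net)) net$weight else rep(1, nrow(net))
  A[cbind(match(net$regulator, nodes), match(net$target, nodes))] <- w
  A <- pmax(A, t(A))          # symmetrize
  diag(A) <- diag(A) + 1      # self-loops stabilize odd-length walks
  M <- mcl_iterate(A, inflation = inflation, max_iter = max_iter)
  clusters <- mcl_clusters(M, nodes)
  ord <- order(-lengths(clusters),
               vapply(clusters, function(cl) min(match(cl, nodes)), numeric(1L)))
  clusters <- clusters[ord]
  names(clusters) <- paste0("mcl_", seq_along(clusters))
  module_set(clusters, universe = nodes)
}

# core MCL loop on a non-negative adjacency matrix with self-loops
mcl_iterate <- function(A, inflation, expansion = 2L, prune = 1e-8,
                        tol = 1e-6, max_iter = 200L) {
  normalize <- function(M) sweep(M, 2L, pmax(colSums(M), .Machine$double.eps), "/")
  M <- normalize(A)
  for (iter in seq_len(max_iter)) {
    M_old <- M
    M2 <- M
    for (k in seq_len(expansion - 1L)) M2 <- M2 %*% M
    # scale each column by its maximum before exponentiating so large
    # inflation values cannot underflow, then renormalize and prune
    M2 <- sweep(M2, 2L, pmax(apply(M2, 2L, max), .Machine$double.eps), "/")
    M2 <- normalize(M2^inflation)
    M2[M2 < prune] <- 0
    M <- normalize(M2)
    resid <- max(abs(M - M_old))
    if (resid < tol) return(M)
  }
  stop(sprintf("MCL did not converge in %d iterations (residual %.3g)",
               max_iter, resid))
}

# read clusters from attractor rows of the converged MCL matrix
mcl_clusters <- function(M, nodes, thresh = 1e-7) {
  attractors <- which(diag(M) > thresh)
  if (length(attractors) == 0L) attractors <- which(rowSums(M) > thresh)
  clusters <- lapply(attractors, function(i) nodes[M[i, ] > thresh])
  clusters <- clusters[lengths(clusters) > 0L]
  unique(clusters)
}

#' Threshold a weighted network
#'
#' Converts a weighted network (e.g. direct network inference output) to an
#' unweighted one by keeping edges with weight at or above `cutoff`. The
#' usual post-processing step before applying a module definition to a
#' weighed regulatory network.
#'
#' @param net a weighted [regulatory_network]
#' @param cutoff edge weight cutoff (edges with `weight >= cutoff` kept).
#' @return an unweighted [regulatory_network] (possibly with zero edges).
#' @export
threshold_weighted_network <- function(net, cutoff) {
  stopifnot(inherits(net, "regulatory_network"))
  if (!is_weighted(net)) stop("network is unweighted; nothing to threshold")
  stopifnot(is.numeric(cutoff), length(cutoff) == 1L, is.finite(cutoff))
  keep <- net$weight >= cutoff
  df <- net[keep, , drop = FALSE]
  structure(data.frame(regulator = df$regulator, target = df$target,
                       stringsAsFactors = FALSE),
            class = c("regulatory_network", "data.frame"), weighted = FALSE)
}

#' Filter a module set: merge strong overlaps, drop small modules
#'
#' Post-processing applied to known (and observed) module sets:
#' (1) optionally intersect every module with a gene universe,
#' (2) repeatedly merge the module pair with the highest Jaccard overlap
#' while any pair exceeds `merge_jaccard` (strict inequality),
#' (3) drop modules smaller than `min_size` genes.
#'
#' Merging is deterministic: the currently highest-Jaccard qualifying pair
#' is merged into its union (ties broken by the lexicographically smallest
#' name pair); the merged module keeps the larger member's name
#' (lexicographically first on equal size).
#'
#' @param ms a [module_set]
#' @param merge_jaccard Jaccard threshold above which two modules are
#'   considered redundant and merged; in (0, 1].
#' @param min_size minimum module size retained.
#' @param universe optional gene set to intersect modules with first.
#' @return a [module_set], ordered by decreasing size then name; may be
#'   empty.
#' @export
filter_modules <- function(ms, merge_jaccard = 0.8, min_size = 5L,
                           universe = NULL) {
  stopifnot(inherits(ms, "module_set"))
  stopifnot(merge_jaccard > 0, merge_jaccard <= 1, min_size >= 1L)
  mods <- ms$modules
  if (!is.null(universe)) {
    universe <- unique(as.character(universe))
    mods <- lapply(mods, intersect, y = universe)
    mods <- mods[lengths(mods) > 0L]
  }
  mods <- merge_overlapping(mods, merge_jaccard)
  mods <- mods[lengths(mods) >= min_size]
  ord <- order(-lengths(mods), names(mods))
  module_set(mods[ord], universe = ms$universe)
}

# repeatedly merge the highest-Jaccard pair above the threshold
merge_overlapping <- function(mods, threshold) {
  while (length(mods) >= 2L) {
    k <- length(mods)
    best <- NULL
    best_j <- -Inf
    best_nm <- ""
    for (i in seq_len(k - 1L)) {
      for (j in (i + 1L):k) {
        jac <- jaccard(mods[[i]], mods[[j]])
        if (jac <= threshold) next
        nm_pair <- paste(sort(names(mods)[c(i, j)]), collapse = "\r")
        if (is.null(best) || jac > best_j ||
            (jac == best_j && nm_pair < best_nm)) {
          best <- c(i, j)
          best_j <- jac
          best_nm <- nm_pair
        }
      }
    }
    if (is.null(best)) break
    i <- best[1L]; j <- best[2L]
    merged <- union(mods[[i]], mods[[j]])
    nm <- names(mods)[c(i, j)]
    keep_name <- if (length(mods[[i]]) != length(mods[[j]])) {
      nm[which.max(c(length(mods[[i]]), length(mods[[j]])))]
    } else min(nm)
    mods[[i]] <- merged
    names(mods)[i] <- keep_name
    mods <- mods[-j]
  }
  mods
}
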