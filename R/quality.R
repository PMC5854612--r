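#' Correlation distance matrix between gene expression profiles
#'
#' Distance `1 - |r|` (default) between all gene pairs, where r is the
#' Pearson correlation of the two expression profiles; strongly correlated
#' *and* strongly anti-correlated genes are both "close", matching how
#' co-regulation manifests in expression. With `absolute = FALSE` the
#' signed form `(1 - r) / 2` is used so anti-correlated genes are maximally
#' distant; both forms lie in \[0, 1\] with a zero diagonal.
#'
#' @param expr numeric genes x samples matrix (>= 3 samples); genes with
#'   zero variance are an error (their correlation is undefined).
#' @param absolute use `|r|` (default) or signed r.
#' @return symmetric distance matrix with gene dimnames and zero diagonal.
#' @export
correlation_distance <- function(expr, absolute = TRUE) {
  check_expression(expr, min_genes = 2L, min_samples = 3L)
  sds <- apply(expr, 1L, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance gene(s): ",
         paste(utils::head(rownames(expr)[sds == 0], 5L), collapse = ", "))
  }
  r <- stats::cor(t(expr))
  d <- if (absolute) 1 - abs(r) else (1 - r) / 2
  d[d < 0] <- 0  # guard tiny negative rounding
  diag(d) <- 0
  d
}

#' Assign unassigned genes to their best-correlated module
#'
#' Non-exhaustive module detection methods leave genes unassigned, which
#' cluster validity indices cannot handle. Every gene of the expression
#' matrix absent from all modules is added to the module with the highest
#' mean Pearson correlation between the gene and the module's (original)
#' members; exact ties go to the earliest module. Already-assigned genes
#' are never moved.
#'
#' @param ms non-empty [module_set].
#' @param expr numeric genes x samples matrix covering all module genes.
#' @return an exhaustive [module_set] over the genes of `expr`.
#' @export
complete_assignment <- function(ms, expr) {
  stopifnot(inherits(ms, "module_set"), length(ms) > 0L)
  check_expression(expr, min_samples = 2L)
  genes <- rownames(expr)
  miss <- setdiff(module_genes(ms), genes)
  if (length(miss) > 0L) {
    stop("module gene(s) missing from expression matrix: ",
         paste(utils::head(miss, 5L), collapse = ", "))
  }
  unassigned <- setdiff(genes, module_genes(ms))
  if (length(unassigned) == 0L) {
    return(module_set(ms$modules, universe = genes))
  }
  r <- suppressWarnings(stats::cor(t(expr)))
  mods <- ms$modules
  members <- lapply(mods, identity)  # original membership only
  for (g in unassigned) {
    mean_cor <- vapply(members, function(m) {
      mean(r[g, m], na.rm = TRUE)
    }, numeric(1L))
    mods[[which.max(mean_cor)]] <- c(mods[[which.max(mean_cor)]], g)
  }
  module_set(mods, universe = genes)
}

#' Resolve overlapping modules to a hard partition
#'
#' Cluster validity indices require a partition. Each gene belonging to
#' several modules is kept only in the module with which it has the
#' highest mean Pearson correlation (computed against the module's full
#' member list); ties go to the earliest module.
#'
#' @param ms non-empty [module_set].
#' @param expr numeric genes x samples matrix covering all module genes.
#' @return a [module_set] with pairwise disjoint modules.
#' @export
disambiguate_modules <- function(ms, expr) {
  stopifnot(inherits(ms, "module_set"), length(ms) > 0L)
  check_expression(expr, min_samples = 2L)
  counts <- table(unlist(ms$modules, use.names = FALSE))
  multi <- names(counts)[counts > 1L]
  if (length(multi) == 0L) return(ms)
  r <- suppressWarnings(stats::cor(t(expr)))
  mods <- ms$modules
  for (g in multi) {
    holders <- which(vapply(mods, function(m) g %in% m, logical(1L)))
    mean_cor <- vapply(holders, function(i) {
      others <- setdiff(mods[[i]], g)
      if (length(others) == 0L) return(-Inf)
      mean(r[g, others], na.rm = TRUE)
    }, numeric(1L))
    keep <- holders[which.max(mean_cor)]
    for (i in setdiff(holders, keep)) mods[[i]] <- setdiff(mods[[i]], g)
  }
  mods <- mods[lengths(mods) > 0L]
  module_set(mods, universe = ms$universe)
}

#' Internal cluster validity indices on a distance matrix
#'
#' Quality of a hard, exhaustive clustering without external truth, used
#' for automatic parameter estimation. Three indices are available:
#' * `silhouette` — mean silhouette width (higher is better, in \[-1, 1\]);
#' * `davies_bouldin` — mean over clusters of the worst
#'   `(scatter_i + scatter_j) / separation_ij` ratio, in a centroid-free
#'   medoid formulation on the distance matrix (lower is better, >= 0);
#' * `kim_ramakrishna` — sum of an under-partition term (mean
#'   within-cluster distance to the medoid) and an over-partition term
#'   (cluster count over minimal medoid separation); lower is better.
#'
#' @param ms an exhaustive, non-overlapping [module_set] over the items of
#'   `dist` with at least 2 modules (use [complete_assignment()] and
#'   [disambiguate_modules()] first).
#' @param dist symmetric distance matrix with item dimnames (e.g. from
#'   [correlation_distance()]).
#' @param index which index to compute.
#' @return a list with `value`, `index` and `higher_better`.
#' @export
cluster_validity <- function(ms, dist,
                             index = c("silhouette", "davies_bouldin",
                                       "kim_ramakrishna")) {
  index <- match.arg(index)
  stopifnot(inherits(ms, "module_set"))
  if (length(ms) < 2L) stop("cluster validity needs at least 2 modules")
  items <- rownames(dist)
  all_genes <- unlist(ms$modules, use.names = FALSE)
  if (anyDuplicated(all_genes)) stop("modules overlap; disambiguate first")
  if (!setequal(all_genes, items)) {
    stop("modules must partition exactly the items of the distance matrix")
  }
  labels <- integer(length(items))
  names(labels) <- items
  for (j in seq_along(ms$modules)) labels[ms$modules[[j]]] <- j
  labels <- labels[items]
  value <- switch(index,
    silhouette = mean_silhouette(dist, labels),
    davies_bouldin = davies_bouldin(dist, labels),
    kim_ramakrishna = kim_ramakrishna(dist, labels))
  list(value = value, index = index,
       higher_better = index == "silhouette")
}

mean_silhouette <- function(dist, labels) {
  k <- max(labels)
  n <- length(labels)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i])
    if (length(own) == 1L) { s[i] <- 0; next }  # singleton convention
    a <- mean(dist[i, setdiff(own, i)])
    b <- min(vapply(setdiff(seq_len(k), labels[i]), function(cl) {
      mean(dist[i, labels == cl])
    }, numeric(1L)))
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  mean(s)
}

cluster_medoids <- function(dist, labels) {
  vapply(seq_len(max(labels)), function(cl) {
    idx <- which(labels == cl)
    idx[which.min(rowSums(dist[idx, idx, drop = FALSE]))]
  }, integer(1L))
}

davies_bouldin <- function(dist, labels) {
  k <- max(labels)
  med <- cluster_medoids(dist, labels)
  scatter <- vapply(seq_len(k), function(cl) {
    mean(dist[med[cl], labels == cl])
  }, numeric(1L))
  ratios <- vapply(seq_len(k), function(i) {
    max(vapply(setdiff(seq_len(k), i), function(j) {
      sep <- dist[med[i], med[j]]
      if (sep == 0) {
        if (scatter[i] + scatter[j] == 0) 0 else Inf
      } else (scatter[i] + scatter[j]) / sep
    }, numeric(1L)))
  }, numeric(1L))
  mean(ratios)
}

kim_ramakrishna <- function(dist, labels) {
  k <- max(labels)
  med <- cluster_medoids(dist, labels)
  under <- mean(vapply(seq_len(k), function(cl) {
    mean(dist[med[cl], labels == cl])
  }, numeric(1L)))
  seps <- dist[med, med][upper.tri(matrix(0, k, k))]
  over <- if (min(seps) == 0) Inf else k / min(seps)
  under + over
}

#' Co-expression metrics for one module
#'
#' Three complementary views of how co-expressed a gene module is:
#' * `avg_correlation` — mean pairwise Pearson correlation of the member
#'   profiles (global co-expression);
#' * `extreme_z` — per gene, the mean of its top 5% of z-scores across
#'   samples, averaged over genes (extreme-expression behaviour: high when
#'   the module switches on strongly in a few samples);
#' * `rmsd` — root mean squared deviation of gene-standardized values
#'   around the per-sample module mean (pattern tightness; 0 for
#'   identical standardized profiles).
#'
#' @param module character vector of >= 2 genes, all present in `expr`.
#' @param expr numeric genes x samples matrix.
#' @param top_fraction fraction of samples counted as "extreme" per gene.
#' @return a list with `avg_correlation`, `extreme_z` and `rmsd`.
#' @export
coexpression_metrics <- function(module, expr, top_fraction = 0.05) {
  check_expression(expr, min_samples = 2L)
  module <- unique(as.character(module))
  if (length(module) < 2L) stop("module must contain at least 2 genes")
  miss <- setdiff(module, rownames(expr))
  if (length(miss) > 0L) {
    stop("module gene(s) missing from expression matrix: ",
         paste(utils::head(miss, 5L), collapse = ", "))
  }
  x <- expr[module, , drop = FALSE]
  r <- suppressWarnings(stats::cor(t(x)))
  avg_cor <- mean(r[upper.tri(r)], na.rm = TRUE)
  z <- t(scale(t(x)))  # per-gene standardization
  z[is.nan(z)] <- 0    # constant genes carry no signal
  n_top <- max(1L, ceiling(top_fraction * ncol(x)))
  extreme <- mean(apply(z, 1L, function(v) {
    mean(sort(v, decreasing = TRUE)[seq_len(n_top)])
  }))
  mu <- colMeans(z)
  rmsd <- sqrt(mean(sweep(z, 2L, mu)^2))
  list(avg_correlation = avg_cor, extreme_z = extreme, rmsd = rmsd)
}

#' Do real modules out-score permuted modules on a co-expression metric?
#'
#' Compares the per-module distribution of a co-expression metric between
#' a module set and gene-relabeled permutations of it, reporting the
#' median difference (real minus permuted) and a two-sided Wilcoxon
#' rank-sum p-value. A positive median difference on `avg_correlation` or
#' `extreme_z` (or a negative one on `rmsd`, where smaller is tighter)
#' supports that the modules capture genuine co-expression.
#'
#' @param ms non-empty [module_set] with all genes in `expr`.
#' @param expr numeric genes x samples matrix.
#' @param metric which component of [coexpression_metrics()] to compare.
#' @param n_perm number of permutations (>= 10).
#' @param seed integer seed.
#' @return a list with `median_diff`, `p_value`, `real` and `permuted`
#'   metric values.
#' @export
permuted_metric_test <- function(ms, expr,
                                 metric = c("avg_correlation", "extreme_z",
                                            "rmsd"),
                                 n_perm = 100L, seed = 1L) {
  metric <- match.arg(metric)
  stopifnot(inherits(ms, "module_set"), length(ms) > 0L)
  if (n_perm < 10L) stop("`n_perm` must be at least 10")
  check_expression(expr, min_samples = 2L)
  metric_values <- function(set) {
    vapply(set$modules, function(m) {
      coexpression_metrics(m, expr)[[metric]]
    }, numeric(1L))
  }
  real <- metric_values(ms)
  universe <- rownames(expr)
  permuted <- withr::with_seed(seed, {
    unlist(lapply(seq_len(n_perm), function(i) {
      metric_values(permute_modules_impl(ms, universe))
    }))
  })
  p <- suppressWarnings(
    stats::wilcox.test(real, permuted, exact = length(real) <= 10L &&
                         length(permuted) <= 10L)$p.value)
  list(median_diff = stats::median(real) - stats::median(permuted),
       p_value = p, real = real, permuted = permuted)
}
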