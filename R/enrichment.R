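#' Right-tailed Fisher enrichment of a module in a gene set
#'
#' Hypergeometric upper-tail p-value `P(X >= overlap)` for the 2x2 table of
#' module membership against gene-set membership within a universe, plus
#' the odds ratio `(a*d)/(b*c)` quantifying enrichment strength. When any
#' table cell is 0, the Haldane correction (+0.5 to every cell) is applied
#' to the odds ratio only — the p-value is always exact.
#'
#' @param module,geneset character vectors, both subsets of `universe`.
#' @param universe character vector, the gene background (>= 2 genes).
#' @return a list with `p_value`, `odds_ratio` and `table` (2x2 integer
#'   matrix: module membership in rows, gene-set membership in columns).
#' @export
fisher_enrichment <- function(module, geneset, universe) {
  universe <- unique(as.character(universe))
  if (length(universe) < 2L) stop("universe must contain at least 2 genes")
  module <- unique(as.character(module))
  geneset <- unique(as.character(geneset))
  if (length(setdiff(module, universe)) > 0L) {
    stop("module contains genes outside the universe")
  }
  if (length(setdiff(geneset, universe)) > 0L) {
    stop("geneset contains genes outside the universe")
  }
  a <- length(intersect(module, geneset))
  b <- length(module) - a
  cc <- length(geneset) - a
  d <- length(universe) - a - b - cc
  p <- stats::phyper(a - 1L, length(geneset),
                     length(universe) - length(geneset),
                     length(module), lower.tail = FALSE)
  cells <- c(a, b, cc, d)
  if (any(cells == 0L)) cells <- cells + 0.5
  or <- (cells[1L] * cells[4L]) / (cells[2L] * cells[3L])
  tab <- matrix(as.integer(c(a, b, cc, d)), 2L, 2L, byrow = TRUE,
                dimnames = list(module = c("in", "out"),
                                geneset = c("in", "out")))
  list(p_value = p, odds_ratio = or, table = tab)
}

#' Holm-Sidak step-down multiple-testing correction
#'
#' Sorts the p-values ascending, applies the Sidak adjustment
#' `1 - (1 - p_(i))^(m - i + 1)` to the i-th smallest of m values, enforces
#' step-down monotonicity (each adjusted value at least as large as the
#' previous), and returns the adjusted values in input order.
#'
#' @param pvalues numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values in input order, all in \[0, 1\] and
#'   elementwise no smaller than the input.
#' @export
holm_sidak <- function(pvalues) {
  stopifnot(is.numeric(pvalues))
  if (any(!is.finite(pvalues)) || any(pvalues < 0) || any(pvalues > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  m <- length(pvalues)
  if (m == 0L) return(numeric(0))
  ord <- order(pvalues)
  adj <- 1 - (1 - pvalues[ord])^(m - seq_len(m) + 1L)
  adj <- cummax(adj)
  out <- numeric(m)
  out[ord] <- pmin(adj, 1)
  out
}

#' Area under the odds-ratio coverage curve (aucodds)
#'
#' Summarizes a collection of best-enrichment odds ratios as the area under
#' the curve of "fraction of items with OR at or above the cutoff", with
#' the cutoff swept over `log10` enrichment between `lo` and `hi`
#' (default 1- to 1000-fold), normalized by the interval width. Odds
#' ratios are clamped into \[lo, hi\], so the score is 1 when every item
#' reaches `hi` and 0 when none exceeds `lo`.
#'
#' @param odds_ratios non-empty vector of non-negative odds ratios
#'   (`Inf` allowed; clamped to `hi`).
#' @param lo,hi integration bounds on the odds-ratio scale, `0 < lo < hi`.
#' @return a score in \[0, 1\].
#' @export
aucodds <- function(odds_ratios, lo = 1, hi = 1000) {
  if (length(odds_ratios) == 0L) stop("`odds_ratios` must be non-empty")
  stopifnot(is.numeric(odds_ratios), all(!is.na(odds_ratios)),
            all(odds_ratios >= 0), lo > 0, lo < hi)
  x <- log10(pmin(pmax(odds_ratios, lo), hi))
  mean(x - log10(lo)) / (log10(hi) - log10(lo))
}

#' Read a weighted regulon collection
#'
#' Per-context regulator-to-target weights (e.g. tissue- and cell-type
#' resolved regulatory circuits) from a TSV with columns
#' `context<TAB>regulator<TAB>target<TAB>weight`. Lines starting with `#`
#' are skipped.
#'
#' @param path file path.
#' @return a data.frame with class `regulon_collection` and columns
#'   `context`, `regulator`, `target`, `weight` (finite, > 0).
#' @export
read_regulons <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, header = FALSE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE,
                          col.names = c("context", "regulator", "target",
                                        "weight"))
  regulon_collection(df$context, df$regulator, df$target, df$weight)
}

#' @rdname read_regulons
#' @param context,regulator,target character vectors.
#' @param weight numeric vector of positive finite weights.
#' @export
regulon_collection <- function(context, regulator, target, weight) {
  weight <- as.numeric(weight)
  if (any(!is.finite(weight)) || any(weight <= 0)) {
    stop("regulon weights must be finite and positive")
  }
  df <- data.frame(context = as.character(context),
                   regulator = as.character(regulator),
                   target = as.character(target),
                   weight = weight, stringsAsFactors = FALSE)
  structure(df, class = c("regulon_collection", "data.frame"))
}

#' Regulator-coverage score from weighted regulons
#'
#' Scores an observed module set by how well it covers the regulators of a
#' weighted, per-context regulon collection — the evaluation of choice when
#' regulator-target weights across many tissue/cell-type contexts are
#' available but a hard gold standard is not. For each weight cutoff:
#' regulon targets are thresholded; each (regulator, context) is tested
#' against every module with [fisher_enrichment()] and Holm-Sidak corrected
#' across modules; per regulator and module the minimal corrected p across
#' contexts is retained with its matching odds ratio (the relevant cellular
#' context being unknown a priori); the regulator's score is its maximal
#' odds ratio among modules with corrected p below `p_cutoff`, or 1 if none
#' is significant. [aucodds()] is computed over the regulators' odds
#' ratios, and the final score is the mean over all weight cutoffs.
#'
#' @param observed non-empty [module_set].
#' @param regulons a `regulon_collection` (see [regulon_collection()]).
#' @param universe the gene background for the enrichment tests.
#' @param p_cutoff corrected-p significance threshold (default 0.1).
#' @param weight_cutoffs numeric vector of weight cutoffs; defaults to the
#'   deciles (0%, 10%, ..., 90%) of the positive weight distribution so the
#'   score is averaged over regulon stringencies.
#' @return a score in \[0, 1\].
#' @export
regulator_coverage_score <- function(observed, regulons, universe,
                                     p_cutoff = 0.1, weight_cutoffs = NULL) {
  stopifnot(inherits(observed, "module_set"), length(observed) > 0L)
  stopifnot(inherits(regulons, "regulon_collection"))
  universe <- unique(as.character(universe))
  if (is.null(weight_cutoffs)) {
    weight_cutoffs <- unname(stats::quantile(regulons$weight,
                                             probs = seq(0, 0.9, by = 0.1)))
  }
  mods <- lapply(observed$modules, intersect, y = universe)
  per_cutoff <- vapply(weight_cutoffs, function(cut) {
    kept <- regulons[regulons$weight >= cut, , drop = FALSE]
    regulator_aucodds(mods, kept, universe, p_cutoff)
  }, numeric(1L))
  mean(per_cutoff)
}

# aucodds over regulators for one thresholded regulon collection
regulator_aucodds <- function(mods, kept, universe, p_cutoff) {
  regs <- unique(kept$regulator)
  key <- paste(kept$regulator, kept$context, sep = "\r")
  fam <- split(seq_len(nrow(kept)), key)
  n_mod <- length(mods)
  # per regulator: running min corrected p and matched OR, per module
  best_p <- lapply(regs, function(r) rep(Inf, n_mod))
  best_or <- lapply(regs, function(r) rep(1, n_mod))
  names(best_p) <- names(best_or) <- regs
  any_target <- FALSE
  for (f in fam) {
    r <- kept$regulator[f[1L]]
    targets <- intersect(unique(kept$target[f]), universe)
    if (length(targets) == 0L) next
    any_target <- TRUE
    res <- lapply(mods, fisher_enrichment, geneset = targets,
                  universe = universe)
    p_adj <- holm_sidak(vapply(res, `[[`, numeric(1L), "p_value"))
    ors <- vapply(res, `[[`, numeric(1L), "odds_ratio")
    better <- p_adj < best_p[[r]]
    best_p[[r]][better] <- p_adj[better]
    best_or[[r]][better] <- ors[better]
  }
  if (!any_target) {
    stop("no regulator has any target inside the universe at this cutoff")
  }
  reg_or <- vapply(regs, function(r) {
    sig <- best_p[[r]] < p_cutoff
    if (any(sig)) max(best_or[[r]][sig]) else 1
  }, numeric(1L))
  aucodds(reg_or)
}

#' Drop redundant gene sets from a functional collection
#'
#' Iterates the gene sets in decreasing size order and removes a set when
#' its Jaccard overlap with any larger retained set exceeds `max_jaccard`.
#' Applied to GO/KEGG-like collections before functional-coherence scoring
#' so near-duplicate terms do not dominate.
#'
#' @param gs named list of character vectors (a gene-set collection).
#' @param max_jaccard redundancy threshold in (0, 1\].
#' @return the retained sub-collection, in the original order.
#' @export
filter_redundant_genesets <- function(gs, max_jaccard = 0.7) {
  stopifnot(is.list(gs), !is.null(names(gs)))
  stopifnot(max_jaccard > 0, max_jaccard <= 1)
  ord <- order(-lengths(gs))
  kept <- integer(0)
  for (i in ord) {
    redundant <- any(vapply(kept, function(j) {
      jaccard(gs[[i]], gs[[j]]) > max_jaccard
    }, logical(1L)))
    if (!redundant) kept <- c(kept, i)
  }
  gs[sort(kept)]
}

#' Two-way functional enrichment score (F-aucodds)
#'
#' Functional-coherence score used for parameter estimation without a gold
#' standard: [aucodds()] is computed in the gene-set dimension (each gene
#' set's best odds ratio among modules where it is significantly enriched
#' — how well the modules cover the functional space) and in the module
#' dimension (each module's best odds ratio among significantly enriched
#' gene sets — how functionally coherent each module is), and the two are
#' combined by their harmonic mean. Holm-Sidak correction runs across
#' modules within each gene set for the first dimension and across gene
#' sets within each module for the second. Non-significant items floor at
#' an odds ratio of 1.
#'
#' @param observed non-empty [module_set].
#' @param gs named list of gene sets (pre-filter with
#'   [filter_redundant_genesets()]).
#' @param universe gene background for the enrichment tests.
#' @param p_cutoff corrected-p significance threshold.
#' @return a score in \[0, 1\].
#' @export
faucodds <- function(observed, gs, universe, p_cutoff = 0.1) {
  stopifnot(inherits(observed, "module_set"), length(observed) > 0L)
  if (length(gs) == 0L) stop("empty gene-set collection")
  universe <- unique(as.character(universe))
  mods <- lapply(observed$modules, intersect, y = universe)
  sets <- lapply(gs, intersect, y = universe)
  P <- matrix(1, length(sets), length(mods))
  OR <- matrix(0, length(sets), length(mods))
  for (i in seq_along(sets)) {
    for (j in seq_along(mods)) {
      res <- fisher_enrichment(mods[[j]], sets[[i]], universe)
      P[i, j] <- res$p_value
      OR[i, j] <- res$odds_ratio
    }
  }
  best_or <- function(p_adj, ors) {
    sig <- p_adj < p_cutoff
    if (any(sig)) max(ors[sig]) else 1
  }
  set_or <- vapply(seq_along(sets), function(i) {
    best_or(holm_sidak(P[i, ]), OR[i, ])
  }, numeric(1L))
  mod_or <- vapply(seq_along(mods), function(j) {
    best_or(holm_sidak(P[, j]), OR[, j])
  }, numeric(1L))
  harmonic_mean(c(aucodds(set_or), aucodds(mod_or)))
}

#' Biological homogeneity index (BHI)
#'
#' The proportion of intra-module gene pairs that share at least one
#' functional annotation, computed over pairs where both genes are
#' annotated, averaged per module and then across modules. Modules with
#' fewer than two annotated genes do not contribute; it is an error if no
#' module has an annotated pair.
#'
#' @param observed non-empty [module_set].
#' @param gs named list of gene sets (the annotation).
#' @return a score in \[0, 1\].
#' @export
bhi <- function(observed, gs) {
  stopifnot(inherits(observed, "module_set"), length(observed) > 0L)
  stopifnot(is.list(gs))
  ann_genes <- unique(unlist(gs, use.names = FALSE))
  per_module <- vapply(observed$modules, function(m) {
    ann <- intersect(m, ann_genes)
    if (length(ann) < 2L) return(NA_real_)
    inc <- vapply(gs, function(s) ann %in% s, logical(length(ann)))
    co <- tcrossprod(inc * 1)  # shared-annotation counts per pair
    pairs <- co[upper.tri(co)]
    mean(pairs > 0)
  }, numeric(1L))
  if (all(is.na(per_module))) {
    stop("no module contains a pair of annotated genes")
  }
  mean(per_module, na.rm = TRUE)
}
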