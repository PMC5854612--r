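#' Jaccard index of two gene sets
#'
#' @param a,b character vectors (treated as sets).
#' @return `|a n b| / |a u b|`, defined as 0 when both sets are empty.
#' @export
jaccard <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0L) return(0)
  length(intersect(a, b)) / u
}

#' Restrict observed modules to the gold-standard universe
#'
#' Genes absent from every known module are removed from the observed
#' modules before scoring — most such genes likely belong to co-regulated
#' modules that are simply not yet known, so counting them as false
#' positives would be misleading. Modules falling below `min_size` genes
#' after restriction are dropped.
#'
#' @param observed a [module_set] of detected modules.
#' @param universe character vector: the scoring universe (typically the
#'   union of known-module genes).
#' @param min_size minimum module size kept after restriction.
#' @return a restricted [module_set] (possibly empty).
#' @export
restrict_observed <- function(observed, universe, min_size = 5L) {
  stopifnot(inherits(observed, "module_set"))
  universe <- unique(as.character(universe))
  if (length(universe) == 0L) stop("`universe` must be non-empty")
  mods <- lapply(observed$modules, intersect, y = universe)
  mods <- mods[lengths(mods) >= min_size]
  module_set(mods, universe = universe)
}

#' Overlap-aware precision and recall (CICE-BCubed)
#'
#' Gene-pair-centric precision and recall between a known and an observed
#' module set, valid for overlapping and non-exhaustive module sets. For
#' each gene pair sharing at least one observed module, the number of
#' shared observed modules is compared with the number of shared known
#' modules, weighted by a module-matching term Phi (the mean, over
#' observed modules containing both genes, of the best Jaccard match among
#' known modules containing both). Both scores reach 1 exactly when the
#' two overlapping module sets are equal.
#'
#' Precision averages over genes covered by at least one observed module;
#' recall is the same construction with the roles of known and observed
#' swapped (so it averages over genes covered by a known module).
#'
#' @param known,observed [module_set]s; both must be non-empty. Pass the
#'   observed set through [restrict_observed()] first so both sets live on
#'   the gold-standard universe.
#' @return named numeric vector `c(precision = , recall = )`, both in
#'   \[0, 1\].
#' @references Rosales-Mendez & Ramirez-Cruz (2013), CICE-BCubed; Amigo et
#'   al. (2009), Extended BCubed.
#' @seealso [match_scores()] for the best-match recovery/relevance pair.
#' @export
cice_scores <- function(known, observed) {
  stopifnot(inherits(known, "module_set"), inherits(observed, "module_set"))
  if (length(known) == 0L || length(observed) == 0L) {
    stop("both module sets must be non-empty")
  }
  c(precision = cice_directional(known, observed),
    recall = cice_directional(observed, known))
}

# One direction of the CICE-BCubed score: `eval` plays the observed role
# (outer average over genes covered by `eval`), `ref` the known role.
# Dense-matrix formulation over the union gene universe.
cice_directional <- function(ref, eval_ms, subset = NULL) {
  genes <- union(module_genes(ref), module_genes(eval_ms))
  A <- incidence(ref, genes)      # genes x |ref|
  B <- incidence(eval_ms, genes)  # genes x |eval|
  N <- tcrossprod(A)              # shared ref-module counts per gene pair
  Np <- tcrossprod(B)             # shared eval-module counts per gene pair
  J <- module_jaccard(B, A)       # |eval| x |ref| Jaccard between modules
  Phi <- phi_matrix(A, B, J)
  term <- matrix(0, length(genes), length(genes))
  pos <- Np > 0
  term[pos] <- pmin(Np[pos], N[pos]) * Phi[pos] / Np[pos]
  covered <- diag(Np) > 0
  per_gene <- rowSums(term) / pmax(rowSums(pos), 1L)
  if (is.null(subset)) {
    mean(per_gene[covered])
  } else {
    sel <- covered & genes %in% subset
    if (!any(sel)) stop("no subset gene is covered by the evaluated modules")
    mean(per_gene[sel])
  }
}

# 0/1 incidence matrix genes x modules
incidence <- function(ms, genes) {
  M <- matrix(0, length(genes), length(ms$modules),
              dimnames = list(genes, names(ms$modules)))
  for (j in seq_along(ms$modules)) {
    M[match(ms$modules[[j]], genes), j] <- 1
  }
  M
}

# Jaccard between all module pairs of two incidence matrices (cols)
module_jaccard <- function(B, A) {
  inter <- crossprod(B, A)
  sizes_b <- colSums(B)
  sizes_a <- colSums(A)
  inter / (outer(sizes_b, sizes_a, "+") - inter)
}

# Phi[g, g'] = mean over eval modules m' containing both genes of the best
# Jaccard J[m', m] over ref modules m containing both genes (0 if none).
phi_matrix <- function(A, B, J) {
  n <- nrow(A)
  phi_sum <- matrix(0, n, n)
  phi_cnt <- matrix(0, n, n)
  for (mp in seq_len(ncol(B))) {
    mem <- which(B[, mp] > 0)
    if (length(mem) == 0L) next
    v <- J[mp, ]
    best <- matrix(0, length(mem), length(mem))
    assigned <- matrix(FALSE, length(mem), length(mem))
    for (m in order(v, decreasing = TRUE)) {
      if (v[m] <= 0) break
      inmod <- A[mem, m] > 0
      if (!any(inmod)) next
      co <- outer(inmod, inmod, "&") & !assigned
      best[co] <- v[m]
      assigned <- assigned | co
    }
    phi_sum[mem, mem] <- phi_sum[mem, mem] + best
    phi_cnt[mem, mem] <- phi_cnt[mem, mem] + 1
  }
  out <- matrix(0, n, n)
  pos <- phi_cnt > 0
  out[pos] <- phi_sum[pos] / phi_cnt[pos]
  out
}

#' Subset-restricted precision* and recall*
#'
#' The CICE-BCubed scores with the outer average restricted to a gene
#' subset (e.g. genes belonging to exactly one known module versus genes in
#' several), quantifying how well a method handles overlap. Inner sums
#' still run over the full co-membership neighbourhoods, so the subset
#' scores are comparable with the global ones; with `subset` equal to all
#' genes they reproduce [cice_scores()] exactly.
#'
#' @inheritParams cice_scores
#' @param subset non-empty character vector of genes to average over.
#' @return named numeric vector `c(precision = , recall = )`.
#' @export
cice_scores_subset <- function(known, observed, subset) {
  stopifnot(inherits(known, "module_set"), inherits(observed, "module_set"))
  subset <- unique(as.character(subset))
  if (length(subset) == 0L) stop("`subset` must be non-empty")
  if (length(known) == 0L || length(observed) == 0L) {
    stop("both module sets must be non-empty")
  }
  c(precision = cice_directional(known, observed, subset = subset),
    recall = cice_directional(observed, known, subset = subset))
}

#' Best-match recovery and relevance
#'
#' Module-level comparison scores from the biclustering evaluation
#' literature: relevance is the mean, over observed modules, of the best
#' Jaccard overlap with any known module (are the detected modules real?);
#' recovery is the mean, over known modules, of the best Jaccard overlap
#' with any observed module (are the real modules detected?).
#'
#' @inheritParams cice_scores
#' @return named numeric vector `c(recovery = , relevance = )`, both in
#'   \[0, 1\].
#' @export
match_scores <- function(known, observed) {
  stopifnot(inherits(known, "module_set"), inherits(observed, "module_set"))
  if (length(known) == 0L || length(observed) == 0L) {
    stop("both module sets must be non-empty")
  }
  genes <- union(module_genes(known), module_genes(observed))
  J <- module_jaccard(incidence(observed, genes), incidence(known, genes))
  c(recovery = mean(apply(J, 2L, max)),
    relevance = mean(apply(J, 1L, max)))
}

#' Harmonic mean with a zero rule
#'
#' The composite used to combine the four normalized comparison scores:
#' `n / sum(1 / v)`, defined as 0 whenever any component is 0 (a method
#' failing completely on one aspect scores 0 overall). Always between the
#' minimum and maximum of its inputs.
#'
#' @param values numeric vector of non-negative values.
#' @return the harmonic mean.
#' @export
harmonic_mean <- function(values) {
  if (length(values) == 0L) stop("`values` must be non-empty")
  stopifnot(is.numeric(values), all(is.finite(values)), all(values >= 0))
  if (any(values == 0)) return(0)
  length(values) / sum(1 / values)
}
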