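# Independent reference implementations used as oracles. These evaluate
# the defining formulas literally (triple loops, explicit enumeration)
# and stay deliberately separate from the package's optimized code paths.

oracle_jaccard <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0L) return(0)
  length(intersect(a, b)) / u
}

# literal gene-pair evaluation of the overlap-aware precision formula;
# `Mp` plays the observed role (outer average over genes it covers)
oracle_cice_dir <- function(M, Mp) {
  genes <- union(unlist(M), unlist(Mp))
  mods_of <- function(set, g) {
    which(vapply(set, function(m) g %in% m, logical(1L)))
  }
  covered <- genes[vapply(genes, function(g) length(mods_of(Mp, g)) > 0L,
                          logical(1L))]
  per_gene <- vapply(covered, function(g) {
    Eg <- genes[vapply(genes, function(gp) {
      length(intersect(mods_of(Mp, g), mods_of(Mp, gp))) > 0L
    }, logical(1L))]
    inner <- vapply(Eg, function(gp) {
      shared_obs <- intersect(mods_of(Mp, g), mods_of(Mp, gp))
      shared_known <- intersect(mods_of(M, g), mods_of(M, gp))
      phi_terms <- vapply(shared_obs, function(i) {
        if (length(shared_known) == 0L) return(0)
        max(vapply(shared_known, function(j) {
          oracle_jaccard(Mp[[i]], M[[j]])
        }, numeric(1L)))
      }, numeric(1L))
      phi <- mean(phi_terms)
      min(length(shared_obs), length(shared_known)) * phi /
        length(shared_obs)
    }, numeric(1L))
    sum(inner) / length(Eg)
  }, numeric(1L))
  mean(per_gene)
}

oracle_cice <- function(known, observed) {
  c(precision = oracle_cice_dir(known$modules, observed$modules),
    recall = oracle_cice_dir(observed$modules, known$modules))
}

oracle_match <- function(known, observed) {
  best <- function(from, against) {
    vapply(from, function(m) {
      max(vapply(against, function(m2) oracle_jaccard(m, m2), numeric(1L)))
    }, numeric(1L))
  }
  c(recovery = mean(best(known$modules, observed$modules)),
    relevance = mean(best(observed$modules, known$modules)))
}

# hypergeometric upper tail by explicit choose() enumeration
oracle_fisher_p <- function(n_universe, n_geneset, n_module, overlap) {
  ks <- overlap:min(n_module, n_geneset)
  ks <- ks[ks >= max(0L, n_module + n_geneset - n_universe)]
  sum(choose(n_geneset, ks) * choose(n_universe - n_geneset, n_module - ks)) /
    choose(n_universe, n_module)
}

# aucodds by explicit piecewise-constant step integration
oracle_aucodds <- function(ors, lo = 1, hi = 1000) {
  x <- log10(pmin(pmax(ors, lo), hi))
  lo_l <- log10(lo); hi_l <- log10(hi)
  breaks <- sort(unique(c(lo_l, x, hi_l)))
  area <- 0
  for (i in seq_len(length(breaks) - 1L)) {
    mid <- (breaks[i] + breaks[i + 1L]) / 2
    frac <- mean(x >= mid)
    area <- area + frac * (breaks[i + 1L] - breaks[i])
  }
  area / (hi_l - lo_l)
}
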