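#' Configuration for the synthetic benchmark generator
#'
#' Bundles and validates the parameters of the planted-module generator:
#' a regulator-target network with `n_regulators` regulons of
#' `targets_per_regulator` genes, a fraction `overlap_fraction` of each
#' regulon borrowed from other regulons (creating multi-module genes),
#' `n_background_genes` unregulated genes, and an expression matrix of
#' `n_samples` samples where each module drives a shared activity signal.
#' A fraction `local_fraction` of the modules is only active in a random
#' subset of `round(active_sample_fraction * n_samples)` samples (local
#' co-expression); `noise_sd` is the measurement noise standard deviation
#' in units of the unit-variance module activity.
#'
#' Defaults describe a mid-sized, moderately hard benchmark: 10 regulons
#' of 20 genes with 20% borrowed genes, background genes at half the
#' module-gene count, 200 samples, a quarter of the modules local with 30%
#' active samples, and noise at half the signal scale.
#'
#' @param n_regulators number of regulators (= planted modules).
#' @param targets_per_regulator regulon size.
#' @param overlap_fraction fraction of each regulon drawn from other
#'   regulons' genes, in \[0, 1).
#' @param n_background_genes unregulated pure-noise genes; default half of
#'   the distinct module genes.
#' @param n_samples number of expression samples.
#' @param local_fraction fraction of modules active only in a sample
#'   subset, in \[0, 1\].
#' @param active_sample_fraction fraction of samples where a local module
#'   is active, in (0, 1\].
#' @param noise_sd measurement noise standard deviation (>= 0).
#' @param seed integer seed; all generator output is reproducible per seed.
#' @return an object of class `synthetic_config` (a validated list).
#' @export
synthetic_config <- function(n_regulators = 10L, targets_per_regulator = 20L,
                             overlap_fraction = 0.2,
                             n_background_genes = NULL, n_samples = 200L,
                             local_fraction = 0.25,
                             active_sample_fraction = 0.3, noise_sd = 0.5,
                             seed = 1L) {
  stopifnot(n_regulators >= 1L, targets_per_regulator >= 1L,
            overlap_fraction >= 0, overlap_fraction < 1,
            n_samples >= 2L,
            local_fraction >= 0, local_fraction <= 1,
            active_sample_fraction > 0, active_sample_fraction <= 1,
            noise_sd >= 0)
  if (!is.null(n_background_genes)) stopifnot(n_background_genes >= 0L)
  structure(list(n_regulators = as.integer(n_regulators),
                 targets_per_regulator = as.integer(targets_per_regulator),
                 overlap_fraction = overlap_fraction,
                 n_background_genes = n_background_genes,
                 n_samples = as.integer(n_samples),
                 local_fraction = local_fraction,
                 active_sample_fraction = active_sample_fraction,
                 noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate a synthetic gold standard
#'
#' Builds a regulator-target network with planted regulons and derives the
#' known modules from it by [minimal_coregulation()]. Each regulator
#' receives `targets_per_regulator` targets of which
#' `round(overlap_fraction * targets_per_regulator)` are sampled from the
#' other regulators' own genes, so overlapping module structure arises by
#' construction. Deterministic per `cfg$seed`.
#'
#' @param cfg a [synthetic_config()].
#' @return a list with `network` (a [regulatory_network]) and `modules`
#'   (the known [module_set]).
#' @export
generate_gold_standard <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  k <- cfg$n_regulators
  tpr <- cfg$targets_per_regulator
  n_shared <- round(cfg$overlap_fraction * tpr)
  n_own <- tpr - n_shared
  if (n_own < 1L) stop("overlap_fraction too high: no own genes per regulon")
  if (k > 1L && n_shared > (k - 1L) * n_own) {
    stop("infeasible overlap: not enough genes in other regulons")
  }
  if (k == 1L && n_shared > 0L) {
    stop("cannot borrow overlap genes with a single regulator")
  }
  regs <- sprintf("R%02d", seq_len(k))
  own <- split(sprintf("g%04d", seq_len(k * n_own)),
               rep(seq_len(k), each = n_own))
  withr::with_seed(cfg$seed, {
    regulons <- lapply(seq_len(k), function(i) {
      pool <- unlist(own[-i], use.names = FALSE)
      c(own[[i]], if (n_shared > 0L) sample(pool, n_shared))
    })
    net <- regulatory_network(rep(regs, times = lengths(regulons)),
                              unlist(regulons, use.names = FALSE))
    list(network = net, modules = minimal_coregulation(net))
  })
}

#' Simulate expression with planted module activities
#'
#' A linear module-activity model: every module m gets an activity
#' `a(m, s) ~ N(0, 1)` per sample s; local modules have their activity
#' zeroed outside a random active-sample subset. A gene's expression is
#' the sum of the activities of the modules containing it plus
#' `N(0, noise_sd)` measurement noise. Background (unregulated) genes get
#' independent unit-variance baseline noise plus the same measurement
#' noise, so they are non-degenerate even at `noise_sd = 0`. Deterministic
#' per `cfg$seed`.
#'
#' @param modules the planted [module_set].
#' @param cfg a [synthetic_config()].
#' @return numeric genes x samples matrix (module genes first, then
#'   background genes `bg0001`, ...). The attribute `active_samples` (a
#'   named list per local module) records the ground-truth active-sample
#'   subsets.
#' @export
simulate_expression <- function(modules, cfg) {
  stopifnot(inherits(modules, "module_set"), length(modules) > 0L)
  stopifnot(inherits(cfg, "synthetic_config"))
  genes <- module_genes(modules)
  n_bg <- if (is.null(cfg$n_background_genes)) {
    round(0.5 * length(genes))
  } else cfg$n_background_genes
  bg <- if (n_bg > 0L) sprintf("bg%04d", seq_len(n_bg)) else character(0)
  k <- length(modules)
  S <- cfg$n_samples
  withr::with_seed(cfg$seed + 1L, {
    activity <- matrix(stats::rnorm(k * S), k, S)
    n_local <- round(cfg$local_fraction * k)
    active_samples <- list()
    if (n_local > 0L) {
      local_mods <- sample.int(k, n_local)
      n_active <- max(1L, round(cfg$active_sample_fraction * S))
      for (m in local_mods) {
        active <- sort(sample.int(S, n_active))
        activity[m, -active] <- 0
        active_samples[[names(modules$modules)[m]]] <- active
      }
    }
    inc <- incidence(modules, genes)  # genes x modules
    signal <- inc %*% activity
    bg_signal <- if (n_bg > 0L) matrix(stats::rnorm(n_bg * S), n_bg, S)
                 else matrix(0, 0L, S)
    out <- rbind(signal, bg_signal)
    if (cfg$noise_sd > 0) {
      out <- out + matrix(stats::rnorm(length(out), sd = cfg$noise_sd),
                          nrow = nrow(out))
    }
    rownames(out) <- c(genes, bg)
    colnames(out) <- sprintf("s%04d", seq_len(S))
    # ground truth for local co-expression, for downstream analyses
    attr(out, "active_samples") <- active_samples
    out
  })
}

#' Controlled corruption of a module set
#'
#' Test instrument for score monotonicity: each module independently has
#' `round(swap_fraction * size)` of its members replaced by uniformly
#' drawn non-member genes from the universe. Module count and sizes are
#' preserved exactly; overlap with the original decays with
#' `swap_fraction`.
#'
#' @param ms non-empty [module_set].
#' @param universe gene pool to draw replacements from (must contain all
#'   module genes).
#' @param swap_fraction fraction of each module replaced, in \[0, 1\].
#' @param seed integer seed.
#' @return a [module_set] with the same structure.
#' @export
degrade_modules <- function(ms, universe, swap_fraction, seed = 1L) {
  stopifnot(inherits(ms, "module_set"), length(ms) > 0L)
  stopifnot(swap_fraction >= 0, swap_fraction <= 1)
  universe <- unique(as.character(universe))
  miss <- setdiff(module_genes(ms), universe)
  if (length(miss) > 0L) {
    stop("universe lacks module gene(s): ",
         paste(utils::head(miss, 5L), collapse = ", "))
  }
  withr::with_seed(seed, {
    mods <- lapply(ms$modules, function(m) {
      n_swap <- round(swap_fraction * length(m))
      if (n_swap == 0L) return(m)
      outside <- setdiff(universe, m)
      if (length(outside) < n_swap) {
        stop("universe too small to swap ", n_swap, " genes")
      }
      drop_idx <- sample.int(length(m), n_swap)
      c(m[-drop_idx], sample(outside, n_swap))
    })
    module_set(mods, universe = universe)
  })
}

#' Correlation-graph + Markov-cluster module detector
#'
#' A deliberately simple reference detector used to exercise the tuning
#' harness and the synthetic benchmark: build a gene-gene graph connecting
#' pairs with `|Pearson r| >= cutoff` (after dropping zero-variance
#' genes), then cluster it with [interconnected_modules()] (MCL). With
#' noise-free planted data and `cutoff` below 1 it recovers disjoint
#' planted modules exactly.
#'
#' @param expr numeric genes x samples matrix.
#' @param params list with elements `cutoff` (default 0.9) and `inflation`
#'   (default 2) — the [grid_search()] detector contract.
#' @return a [module_set] (possibly empty if the graph has no edges).
#' @export
cor_graph_detector <- function(expr, params = list()) {
  cutoff <- if (is.null(params$cutoff)) 0.9 else params$cutoff
  inflation <- if (is.null(params$inflation)) 2 else params$inflation
  sds <- apply(expr, 1L, stats::sd)
  x <- expr[sds > 0, , drop = FALSE]
  if (nrow(x) < 2L) return(module_set(list()))
  r <- stats::cor(t(x))
  diag(r) <- 0
  idx <- which(abs(r) >= cutoff & upper.tri(r), arr.ind = TRUE)
  if (nrow(idx) == 0L) return(module_set(list()))
  net <- regulatory_network(rownames(x)[idx[, 1L]], rownames(x)[idx[, 2L]])
  interconnected_modules(net, inflation = inflation)
}
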