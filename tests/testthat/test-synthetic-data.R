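test_that("gold-standard generation plants the requested regulon structure", {
  cfg <- synthetic_config(n_regulators = 5L, targets_per_regulator = 20L,
                          overlap_fraction = 0, seed = 1)
  gs <- generate_gold_standard(cfg)
  expect_length(gs$modules, 5L)
  expect_true(all(lengths(gs$modules$modules) == 20L))
  expect_equal(anyDuplicated(unlist(gs$modules$modules)), 0L)  # disjoint

  # determinism per seed
  gs2 <- generate_gold_standard(cfg)
  expect_identical(gs$network, gs2$network)
  expect_identical(gs$modules$modules, gs2$modules$modules)

  # overlap planting creates multi-module genes
  shared_per_seed <- vapply(1:20, function(s) {
    cfg_o <- synthetic_config(n_regulators = 5L, targets_per_regulator = 10L,
                              overlap_fraction = 0.5, seed = s)
    mods <- generate_gold_standard(cfg_o)$modules$modules
    counts <- table(unlist(mods))
    mean(counts[counts > 1])
  }, numeric(1L))
  expect_true(all(shared_per_seed > 1))

  expect_error(generate_gold_standard(
    synthetic_config(n_regulators = 2L, targets_per_regulator = 10L,
                     overlap_fraction = 0.8, seed = 1)), "infeasible")
})

test_that("simulated expression realizes global and local co-expression", {
  cfg <- synthetic_config(n_regulators = 4L, targets_per_regulator = 10L,
                          overlap_fraction = 0, n_background_genes = 20L,
                          n_samples = 50L, local_fraction = 0, noise_sd = 0,
                          seed = 2)
  gs <- generate_gold_standard(cfg)
  expr <- simulate_expression(gs$modules, cfg)
  expect_equal(dim(expr), c(40L + 20L, 50L))
  # noise-free global module: perfect within-module correlation
  r <- cor(t(expr[gs$modules$modules[[1]], ]))
  expect_true(all(abs(r) > 0.999))

  # local module: correlation concentrated in the active samples
  cfg_loc <- synthetic_config(n_regulators = 6L, targets_per_regulator = 10L,
                              overlap_fraction = 0, n_background_genes = 0L,
                              n_samples = 100L, local_fraction = 1,
                              active_sample_fraction = 0.3, noise_sd = 0.2,
                              seed = 5)
  gs_loc <- generate_gold_standard(cfg_loc)
  expr_loc <- simulate_expression(gs_loc$modules, cfg_loc)
  mod1_name <- names(gs_loc$modules$modules)[1]
  mod1 <- gs_loc$modules$modules[[1]]
  active <- attr(expr_loc, "active_samples")[[mod1_name]]
  mean_cor <- function(cols) {
    r <- cor(t(expr_loc[mod1, cols]))
    mean(r[upper.tri(r)])
  }
  expect_gt(mean_cor(active), mean_cor(setdiff(seq_len(100L), active)))

  # reproducible per seed
  expect_identical(simulate_expression(gs$modules, cfg), expr)
})

test_that("module degradation preserves structure and decays overlap", {
  set <- ms(A = paste0("g", 1:10), B = paste0("g", 11:20))
  uni <- paste0("g", 1:60)
  expect_identical(degrade_modules(set, uni, 0, seed = 1)$modules,
                   set$modules)
  half <- degrade_modules(set, uni, 0.5, seed = 1)
  expect_equal(lengths(half$modules), lengths(set$modules))
  expect_equal(length(intersect(half$modules$A, set$modules$A)), 5L)

  # full swap: Jaccard with the original matches the hypergeometric
  # expectation of drawing 10 replacements from the 50 outside genes
  jacc <- vapply(1:200, function(s) {
    d <- degrade_modules(set, uni, 1, seed = s)
    jaccard(d$modules$A, set$modules$A)
  }, numeric(1L))
  # overlap k ~ Hypergeom(50, 10 old genes excluded -> replacements cannot
  # hit the original module), so expected Jaccard is 0
  expect_equal(mean(jacc), 0)

  single <- ms(A = paste0("g", 1:10))
  expect_error(degrade_modules(single, paste0("g", 1:12), 0.5, seed = 1),
               "too small")
})

test_that("the reference detector recovers planted modules exactly at zero noise", {
  cfg <- synthetic_config(n_regulators = 5L, targets_per_regulator = 20L,
                          overlap_fraction = 0, n_background_genes = 0L,
                          n_samples = 100L, local_fraction = 0, noise_sd = 0,
                          seed = 1)
  gs <- generate_gold_standard(cfg)
  expr <- simulate_expression(gs$modules, cfg)
  found <- cor_graph_detector(expr, list(cutoff = 0.9, inflation = 2))
  expect_setequal(unname(lapply(found$modules, sort)),
                  unname(lapply(gs$modules$modules, sort)))
})

test_that("planted modules stay above the permutation null under moderate noise", {
  for (s in 0:2) {
    cfg <- synthetic_config(n_regulators = 5L, targets_per_regulator = 10L,
                            overlap_fraction = 0, n_background_genes = 20L,
                            n_samples = 40L, local_fraction = 0,
                            noise_sd = 0.5, seed = s)
    gs <- generate_gold_standard(cfg)
    r <- normalized_scores(gs$modules, gs$modules, n_perm = 25, seed = s)
    expect_gt(r$composite, 1)
  }
})
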