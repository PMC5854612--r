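# a detector whose quality is controlled by a single parameter: it returns
# the planted modules degraded by `corruption`
make_planted_detector <- function(known, universe) {
  function(expr, params, seed = 1L) {
    if (params$corruption == 0) return(known)
    degrade_modules(known, universe, swap_fraction = params$corruption,
                    seed = seed)
  }
}

test_that("parameter grids enumerate the cartesian product in declaration order", {
  g <- param_grid(k = c(2, 5, 10), cutoff = c(0.7, 0.9))
  expect_length(g, 6L)
  expect_equal(g[[1]], list(k = 2, cutoff = 0.7))
  expect_equal(g[[2]], list(k = 2, cutoff = 0.9))  # last parameter fastest
  expect_equal(g[[6]], list(k = 10, cutoff = 0.9))
  expect_error(param_grid(), "named")
  expect_error(param_grid(c(1, 2)), "named")
})

test_that("grid search picks the parameters that reproduce the known modules", {
  cfg <- synthetic_config(n_regulators = 6L, targets_per_regulator = 10L,
                          overlap_fraction = 0, n_background_genes = 20L,
                          n_samples = 30L, local_fraction = 0,
                          noise_sd = 0.2, seed = 3)
  gs <- generate_gold_standard(cfg)
  expr <- simulate_expression(gs$modules, cfg)
  uni <- module_genes(gs$modules)
  det <- make_planted_detector(gs$modules, uni)
  grid <- param_grid(corruption = c(0.6, 0, 0.3))
  tuned <- grid_search(det, grid, expr, gs$modules, uni,
                       n_perm = 20, seed = 1)
  expect_equal(tuned$best_params$corruption, 0)
  expect_equal(tuned$training_score, max(tuned$scores))
  # determinism
  tuned2 <- grid_search(det, grid, expr, gs$modules, uni,
                        n_perm = 20, seed = 1)
  expect_identical(tuned$scores, tuned2$scores)

  # a parameter-blind detector scores identically everywhere; first point wins
  flat <- function(expr, params) gs$modules
  flat_tuned <- grid_search(flat, grid, expr, gs$modules, uni,
                            n_perm = 20, seed = 1)
  expect_equal(length(unique(flat_tuned$scores)), 1L)
  expect_equal(flat_tuned$best_index, 1L)
})

test_that("failing grid points score 0 with a warning instead of aborting", {
  known <- ms(A = paste0("g", 1:6), B = paste0("g", 7:12))
  x <- block_expression(6, 10, seed = 1)
  bad <- function(expr, params) {
    if (params$p == 1) stop("boom")
    known
  }
  expect_warning(
    tuned <- grid_search(bad, param_grid(p = c(1, 2)), x, known,
                         module_genes(known), n_perm = 10, seed = 1,
                         min_size = 2L),
    "detector failed")
  expect_equal(tuned$scores[1], 0)
  expect_gt(tuned$scores[2], 0)
})

test_that("same-dataset transfer reproduces the training score exactly", {
  cfg <- synthetic_config(n_regulators = 5L, targets_per_regulator = 8L,
                          overlap_fraction = 0, n_background_genes = 10L,
                          n_samples = 20L, noise_sd = 0.2, seed = 11)
  gs <- generate_gold_standard(cfg)
  expr <- simulate_expression(gs$modules, cfg)
  uni <- module_genes(gs$modules)
  det <- make_planted_detector(gs$modules, uni)
  grid <- param_grid(corruption = c(0, 0.5))
  tuned <- grid_search(det, grid, expr, gs$modules, uni, n_perm = 15, seed = 2)
  test_score <- transfer_test(tuned, det, expr, gs$modules, uni,
                              n_perm = 15, seed = 2)
  expect_identical(test_score, tuned$training_score)
})

test_that("synthetic-to-real parameter transfer is refused when tagged", {
  known <- ms(A = paste0("g", 1:6), B = paste0("g", 7:12))
  x <- block_expression(6, 10, seed = 2)
  det <- function(expr, params) known
  tuned <- grid_search(det, param_grid(p = 1), x, known, module_genes(known),
                       n_perm = 10, seed = 1, min_size = 2L, real = FALSE)
  expect_error(transfer_test(tuned, det, x, known, target_real = TRUE),
               "synthetic")
  # untagged transfers remain allowed
  expect_silent(transfer_test(tuned, det, x, known, module_genes(known),
                              n_perm = 10, seed = 1, min_size = 2L))
})

test_that("aggregation weights organisms and definitions equally", {
  df <- data.frame(dataset = c("d1", "d2", "d3", "d4"),
                   organism = c("A", "B", "B", "B"),
                   definition = "minimal",
                   score = c(1, 0, 0, 0))
  expect_equal(aggregate_scores(df), 0.5)
  # constant scores aggregate to the constant
  df2 <- transform(df, score = 0.7)
  expect_equal(aggregate_scores(df2), 0.7)
  # invariant to row order
  expect_equal(aggregate_scores(df[c(3, 1, 4, 2), ]), 0.5)
  df_bad <- df; df_bad$organism[2] <- NA
  expect_error(aggregate_scores(df_bad), "missing")
})

test_that("dataset perturbation subsamples and injects noise as configured", {
  x <- block_expression(5, 100, seed = 6)
  expect_identical(perturb_dataset(x, 1, 0, seed = 1), x)
  half <- perturb_dataset(x, 0.5, 0, seed = 1)
  expect_equal(ncol(half), 50L)
  expect_true(all(colnames(half) %in% colnames(x)))
  expect_error(perturb_dataset(x, 0.01, 0, seed = 1), "fewer than 2")

  # strong noise destroys planted co-expression
  clean_cor <- coexpression_metrics(paste0("a", 1:5), x)$avg_correlation
  noisy <- perturb_dataset(x, 1, 10, seed = 0)
  noisy_cor <- coexpression_metrics(paste0("a", 1:5), noisy)$avg_correlation
  expect_equal(clean_cor, 1)
  expect_lt(noisy_cor, 0.2)
})

test_that("training beats test on average across synthetic dataset pairs", {
  cfgs <- lapply(1:5, function(s) {
    synthetic_config(n_regulators = 5L, targets_per_regulator = 8L,
                     overlap_fraction = 0, n_background_genes = 10L,
                     n_samples = 20L, noise_sd = 0.6, seed = 100 + s)
  })
  data <- lapply(cfgs, function(cfg) {
    gs <- generate_gold_standard(cfg)
    list(known = gs$modules, expr = simulate_expression(gs$modules, cfg),
         uni = module_genes(gs$modules))
  })
  # parameter-sensitive detector whose best variant differs per dataset:
  # each variant is a different random degradation of the planted truth
  make_variant_detector <- function(known, uni) {
    function(expr, params, seed = 1L) {
      degrade_modules(known, uni, swap_fraction = 0.3,
                      seed = params$variant * 1000L + seed)
    }
  }
  grid <- param_grid(variant = 1:3)
  tuned <- lapply(seq_along(data), function(i) {
    det <- make_variant_detector(data[[i]]$known, data[[i]]$uni)
    grid_search(det, grid, data[[i]]$expr, data[[i]]$known, data[[i]]$uni,
                n_perm = 10, seed = 7)
  })
  train <- c(); test <- c()
  for (i in seq_along(data)) {
    for (j in seq_along(data)) {
      if (i == j) next
      det_j <- make_variant_detector(data[[j]]$known, data[[j]]$uni)
      test <- c(test, transfer_test(tuned[[i]], det_j, data[[j]]$expr,
                                    data[[j]]$known, data[[j]]$uni,
                                    n_perm = 10, seed = 7))
      train <- c(train, tuned[[j]]$training_score)
    }
  }
  expect_length(test, 20L)
  expect_gte(mean(train), mean(test))
})
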