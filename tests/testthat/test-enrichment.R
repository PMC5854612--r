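test_that("Fisher enrichment p-values are exact hypergeometric upper tails", {
  u20 <- paste0("g", 1:20)
  res <- fisher_enrichment(u20[1:5], u20[c(1:4, 6)], u20)
  expect_equal(res$p_value, 76 / 15504)
  expect_equal(res$odds_ratio, 56)
  expect_equal(unname(res$table[1, 1]), 4L)

  # zero overlap gives p = 1
  res0 <- fisher_enrichment(u20[1:5], u20[6:10], u20)
  expect_equal(res0$p_value, 1)

  # module = geneset of size 2 in universe of 4: p = 1/C(4,2)
  u4 <- letters[1:4]
  expect_equal(fisher_enrichment(u4[1:2], u4[1:2], u4)$p_value, 1 / 6)

  expect_error(fisher_enrichment(c("a", "zz"), "a", u4), "outside")
})

test_that("Fisher p matches choose()-based enumeration over many tables", {
  # sweep all margins for a range of universe sizes
  for (n in c(2L, 5L, 11L, 18L, 25L, 30L)) {
    uni <- paste0("u", seq_len(n))
    for (k_gs in seq(0L, n, by = max(1L, n %/% 5L))) {
      for (k_mod in seq(1L, n, by = max(1L, n %/% 4L))) {
        lo <- max(0L, k_mod + k_gs - n)
        hi <- min(k_mod, k_gs)
        for (a in lo:hi) {
          module <- c(uni[seq_len(a)],
                      setdiff(uni, uni[seq_len(k_gs)])[seq_len(k_mod - a)])
          geneset <- uni[seq_len(k_gs)]
          expect_equal(fisher_enrichment(module, geneset, uni)$p_value,
                       oracle_fisher_p(n, k_gs, k_mod, a),
                       tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("Holm-Sidak adjustment matches hand computation and is monotone", {
  expect_equal(holm_sidak(0.3), 0.3)
  expect_equal(holm_sidak(c(0.01, 0.04)), c(1 - 0.99^2, 0.04))
  expect_equal(holm_sidak(c(1, 1, 1)), c(1, 1, 1))
  expect_error(holm_sidak(c(0.1, 1.2)), "0, 1")

  withr::with_seed(5, {
    for (i in 1:10) {
      p <- runif(sample(2:12, 1))
      adj <- holm_sidak(p)
      expect_true(all(adj >= p))
      expect_true(all(adj <= 1))
      # order-preserving on the sorted scale
      expect_false(is.unsorted(adj[order(p)]))
    }
  })
})

test_that("aucodds hits its limits, midpoint and the step-integration oracle", {
  expect_equal(aucodds(c(1000, 5000, Inf)), 1)
  expect_equal(aucodds(c(0, 0.5, 1)), 0)
  expect_equal(aucodds(c(10, 1000)), 2 / 3)

  withr::with_seed(9, {
    for (i in 1:15) {
      ors <- 10^runif(sample(1:8, 1), -1, 4)
      expect_equal(aucodds(ors), oracle_aucodds(ors), tolerance = 1e-10)
      # monotone: raising any OR never decreases the score
      bumped <- ors
      j <- sample(length(ors), 1)
      bumped[j] <- bumped[j] * 10
      expect_gte(aucodds(bumped), aucodds(ors))
    }
  })
  expect_error(aucodds(numeric(0)), "non-empty")
})

test_that("regulator coverage scores self-matching regulons highly, misses at 0", {
  withr::with_seed(0, {
    uni <- paste0("g", 1:500)
    regulons <- lapply(1:10, function(i) uni[((i - 1) * 20 + 1):(i * 20)])
    names(regulons) <- paste0("R", 1:10)
    rc <- regulon_collection(
      context = rep("ctx1", 200),
      regulator = rep(names(regulons), each = 20),
      target = unlist(regulons),
      weight = runif(200, 0.5, 1))
    obs <- module_set(regulons)
    score <- regulator_coverage_score(obs, rc, uni)
    expect_gte(score, 0.8)

    # modules disjoint from every regulon floor all odds ratios at 1
    far <- module_set(list(f1 = uni[301:320], f2 = uni[321:340]))
    rc_small <- regulon_collection(rep("c", 40),
                                   rep(c("R1", "R2"), each = 20),
                                   uni[1:40], rep(1, 40))
    expect_equal(regulator_coverage_score(far, rc_small, uni), 0)

    # duplicating a context changes nothing (min over equal values)
    rc_dup <- regulon_collection(
      context = rep(c("c1", "c2"), each = 40),
      regulator = rep(rep(c("R1", "R2"), each = 20), 2),
      target = rep(uni[1:40], 2),
      weight = rep(1, 80))
    rc_one <- regulon_collection(rep("c1", 40),
                                 rep(c("R1", "R2"), each = 20),
                                 uni[1:40], rep(1, 40))
    obs2 <- module_set(list(a = uni[1:20], b = uni[21:40]))
    expect_equal(regulator_coverage_score(obs2, rc_dup, uni),
                 regulator_coverage_score(obs2, rc_one, uni))
  })
})

test_that("redundant gene sets are removed largest-first", {
  gs <- list(big = letters[1:8], dup = letters[1:8], half = letters[1:4],
             nested6 = letters[1:6])
  kept <- filter_redundant_genesets(gs, max_jaccard = 0.7)
  expect_true("big" %in% names(kept))
  expect_false("dup" %in% names(kept))
  expect_false("nested6" %in% names(kept))  # Jaccard 6/8 = 0.75 > 0.7
  expect_true("half" %in% names(kept))      # Jaccard 4/8 = 0.5
})

test_that("two-way functional aucodds behaves at its fixed points", {
  uni <- paste0("g", 1:200)
  mods <- lapply(1:5, function(i) uni[((i - 1) * 10 + 1):(i * 10)])
  names(mods) <- paste0("m", 1:5)
  obs <- module_set(mods)
  # gene sets identical to the modules: every odds ratio saturates
  expect_equal(faucodds(obs, mods, uni), 1)
  # no enrichment anywhere
  shifted <- list(s1 = uni[101:150], s2 = uni[151:200])
  none <- faucodds(module_set(list(a = uni[1:10], b = uni[11:20])),
                   shifted, uni)
  expect_equal(none, 0)
})

test_that("biological homogeneity index counts co-annotated pairs", {
  gs <- list(s1 = c("a", "b", "c"), s2 = c("c", "d"))
  all_shared <- bhi(ms(m = c("a", "b", "c")), gs)
  expect_equal(all_shared, 1)
  none_shared <- bhi(ms(m = c("a", "d")), gs)
  expect_equal(none_shared, 0)
  # 4 annotated genes, exactly 3 of 6 pairs share an annotation
  gs2 <- list(s1 = c("a", "b", "c"), s2 = "d")
  expect_equal(bhi(ms(m = c("a", "b", "c", "d")), gs2), 0.5)
  expect_error(bhi(ms(m = c("x", "y")), gs), "annotated")
})
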