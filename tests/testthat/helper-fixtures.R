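# quick module_set construction from unnamed vectors
ms <- function(...) {
  mods <- list(...)
  if (is.null(names(mods)) || any(names(mods) == "")) {
    names(mods) <- paste0("m", seq_along(mods))
  }
  module_set(mods)
}

# random overlapping module-set instance for property tests
random_moduleset <- function(seed, max_genes = 12L, max_modules = 5L,
                             prefix = "g") {
  withr::with_seed(seed, {
    n_genes <- sample(4:max_genes, 1L)
    genes <- paste0(prefix, seq_len(n_genes))
    k <- sample(2:max_modules, 1L)
    mods <- lapply(seq_len(k), function(i) {
      sample(genes, sample(2:max(2L, n_genes %/% 2L), 1L))
    })
    names(mods) <- paste0("m", seq_len(k))
    module_set(mods)
  })
}

# random directed network
random_network <- function(seed, n_reg = 4L, n_tgt = 12L, p = 0.3) {
  withr::with_seed(seed, {
    regs <- paste0("R", seq_len(n_reg))
    tgts <- paste0("t", seq_len(n_tgt))
    pairs <- expand.grid(r = regs, t = tgts, stringsAsFactors = FALSE)
    pairs <- pairs[stats::runif(nrow(pairs)) < p, , drop = FALSE]
    if (nrow(pairs) == 0L) pairs <- data.frame(r = regs[1L], t = tgts[1L])
    regulatory_network(pairs$r, pairs$t)
  })
}

# small expression matrix with two perfectly co-expressed blocks
block_expression <- function(n_per_block = 4L, n_samples = 10L, seed = 1L) {
  withr::with_seed(seed, {
    base1 <- stats::rnorm(n_samples)
    base2 <- stats::rnorm(n_samples)
    x <- rbind(matrix(rep(base1, n_per_block), nrow = n_per_block,
                      byrow = TRUE),
               matrix(rep(base2, n_per_block), nrow = n_per_block,
                      byrow = TRUE))
    rownames(x) <- c(paste0("a", seq_len(n_per_block)),
                     paste0("b", seq_len(n_per_block)))
    colnames(x) <- paste0("s", seq_len(n_samples))
    x
  })
}
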