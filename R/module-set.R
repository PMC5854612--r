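#' Construct a module set
#'
#' A module set is an ordered, named collection of gene sets ("modules").
#' Modules may overlap and need not cover every gene (non-exhaustive module
#' detection methods leave genes unassigned). An optional universe records
#' the full gene background the modules were drawn from.
#'
#' @param modules a named list of character vectors of gene identifiers.
#'   Duplicate genes within a module are removed; empty modules are not
#'   allowed. Names must be unique.
#' @param universe optional character vector of gene identifiers. When given
#'   it must contain every gene appearing in `modules`.
#' @return an object of class `module_set`: a list with elements `modules`
#'   (named list of character vectors) and `universe` (character or `NULL`).
#' @examples
#' ms <- module_set(list(m1 = c("a", "b"), m2 = c("b", "c")))
#' length(ms)
#' module_genes(ms)
#' @export
module_set <- function(modules, universe = NULL) {
  if (!is.list(modules)) stop("`modules` must be a list of character vectors")
  nm <- names(modules)
  if (length(modules) > 0L && (is.null(nm) || anyNA(nm) || any(nm == ""))) {
    stop("every module must be named")
  }
  if (anyDuplicated(nm)) {
    stop("duplicate module name: ", nm[duplicated(nm)][1L])
  }
  modules <- lapply(modules, function(g) {
    g <- as.character(g)
    check_gene_ids(g)
    unique(g)
  })
  if (any(lengths(modules) == 0L)) stop("modules must be non-empty gene sets")
  if (!is.null(universe)) {
    universe <- unique(as.character(universe))
    check_gene_ids(universe)
    missing <- setdiff(unlist(modules, use.names = FALSE), universe)
    if (length(missing) > 0L) {
      stop("universe does not contain module gene(s): ",
           paste(utils::head(missing, 5L), collapse = ", "))
    }
  }
  structure(list(modules = modules, universe = universe),
            class = "module_set")
}

# gene identifiers: non-empty, no tabs or newlines (would break GMT/TSV)
check_gene_ids <- function(g) {
  if (length(g) == 0L) return(invisible(g))
  if (anyNA(g) || any(g == "")) stop("gene identifiers must be non-empty")
  if (any(grepl("[\t\n\r]", g))) {
    stop("gene identifiers must not contain tab or newline characters")
  }
  invisible(g)
}

#' @export
length.module_set <- function(x) length(x$modules)

#' @export
print.module_set <- function(x, ...) {
  sz <- lengths(x$modules)
  cat(sprintf("module_set: %d modules, %d distinct genes\n",
              length(sz), length(module_genes(x))))
  if (length(sz) > 0L) {
    cat(sprintf("  sizes: min %d / median %s / max %d\n",
                min(sz), format(stats::median(sz)), max(sz)))
  }
  if (!is.null(x$universe)) {
    cat(sprintf("  universe: %d genes\n", length(x$universe)))
  }
  invisible(x)
}

#' @export
as.list.module_set <- function(x, ...) x$modules

#' Genes covered by a module set
#'
#' @param ms a [module_set]
#' @return character vector: the union of all module gene sets, in order of
#'   first appearance.
#' @export
module_genes <- function(ms) {
  stopifnot(inherits(ms, "module_set"))
  unique(unlist(ms$modules, use.names = FALSE))
}

#' Construct a regulatory network
#'
#' A directed network of regulator to target-gene edges, optionally weighted
#' (e.g. confidence scores from a network inference method). Duplicate
#' (regulator, target) pairs are collapsed keeping the maximum weight.
#' Self-edges are allowed but counted and reported by `print()`.
#'
#' @param regulator,target character vectors of equal length.
#' @param weight optional numeric vector of finite edge weights.
#' @return an object of class `regulatory_network`: a data.frame with
#'   columns `regulator`, `target` and (if weighted) `weight`.
#' @examples
#' net <- regulatory_network(c("R1", "R1", "R2"), c("a", "b", "b"))
#' net
#' @export
regulatory_network <- function(regulator, target, weight = NULL) {
  regulator <- as.character(regulator)
  target <- as.character(target)
  if (length(regulator) != length(target)) {
    stop("`regulator` and `target` must have equal length")
  }
  check_gene_ids(regulator)
  check_gene_ids(target)
  weighted <- !is.null(weight)
  if (weighted) {
    weight <- as.numeric(weight)
    if (length(weight) != length(regulator)) {
      stop("`weight` must match the number of edges")
    }
    if (any(!is.finite(weight))) stop("edge weights must be finite")
  } else {
    weight <- rep(NA_real_, length(regulator))
  }
  df <- data.frame(regulator = regulator, target = target, weight = weight,
                   stringsAsFactors = FALSE)
  # collapse duplicate edges, keeping the maximum weight
  key <- paste(df$regulator, df$target, sep = "\t")
  if (anyDuplicated(key)) {
    ord <- order(key, -df$weight, na.last = TRUE)
    df <- df[ord, , drop = FALSE]
    df <- df[!duplicated(key[ord]), , drop = FALSE]
    df <- df[order(as.integer(rownames(df))), , drop = FALSE]
  }
  rownames(df) <- NULL
  if (!weighted) df$weight <- NULL
  structure(df, class = c("regulatory_network", "data.frame"),
            weighted = weighted)
}

#' @export
print.regulatory_network <- function(x, ...) {
  n_self <- sum(x$regulator == x$target)
  cat(sprintf("regulatory_network: %d edges, %d regulators, %d targets%s%s\n",
              nrow(x), length(unique(x$regulator)),
              length(unique(x$target)),
              if (isTRUE(attr(x, "weighted"))) ", weighted" else "",
              if (n_self > 0L) sprintf(" (%d self-edges)", n_self) else ""))
  invisible(x)
}

#' @rdname regulatory_network
#' @param net a `regulatory_network`
#' @export
is_weighted <- function(net) {
  stopifnot(inherits(net, "regulatory_network"))
  isTRUE(attr(net, "weighted"))
}

network_nodes <- function(net) {
  unique(c(net$regulator, net$target))
}

# validate a genes x samples expression matrix
check_expression <- function(expr, min_genes = 1L, min_samples = 1L) {
  if (!is.matrix(expr) || !is.numeric(expr)) {
    stop("expression data must be a numeric matrix (genes x samples)")
  }
  if (is.null(rownames(expr)) || is.null(colnames(expr))) {
    stop("expression matrix needs gene row names and sample column names")
  }
  if (anyDuplicated(rownames(expr))) stop("duplicate gene identifiers")
  if (anyDuplicated(colnames(expr))) stop("duplicate sample identifiers")
  if (any(!is.finite(expr))) stop("expression values must be finite")
  if (nrow(expr) < min_genes || ncol(expr) < min_samples) {
    stop(sprintf("expression matrix must have at least %d genes and %d samples",
                 min_genes, min_samples))
  }
  invisible(expr)
}
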