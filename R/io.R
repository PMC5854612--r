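#' Read and write gene sets in GMT format
#'
#' GMT is the de-facto gene-set interchange format: one set per line,
#' tab-separated fields `name<TAB>description<TAB>gene1<TAB>gene2...`.
#' `read_gmt()` deduplicates genes within a line; the description field is
#' ignored on input and written as `"na"` on output, so a write/read round
#' trip reproduces the module set exactly.
#'
#' @param path file path.
#' @return `read_gmt()` returns a [module_set]; `write_gmt()` returns `path`
#'   invisibly.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty GMT file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short) > 0L) {
    stop(sprintf("GMT line %d has fewer than 3 tab-separated fields", short[1L]))
  }
  nm <- vapply(fields, `[[`, character(1L), 1L)
  if (anyDuplicated(nm)) {
    stop("duplicate module name in GMT: ", nm[duplicated(nm)][1L])
  }
  modules <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(modules) <- nm
  module_set(modules)
}

#' @rdname read_gmt
#' @param ms a [module_set]
#' @export
write_gmt <- function(ms, path) {
  stopifnot(inherits(ms, "module_set"))
  lines <- vapply(seq_along(ms$modules), function(i) {
    paste(c(names(ms$modules)[i], "na", ms$modules[[i]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path, sep = "\n")
  invisible(path)
}

#' Read and write regulatory networks as TSV edge lists
#'
#' The edge list has two or three tab-separated columns: regulator, target
#' and an optional finite weight. Lines starting with `#` are treated as
#' comments/headers and skipped. Duplicate (regulator, target) edges are
#' collapsed keeping the maximum weight.
#'
#' @param path file path.
#' @return `read_network()` returns a [regulatory_network].
#' @export
read_network <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) stop("no edges in network file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 2L | nf > 3L)) {
    stop(sprintf("network line %d: expected 2 or 3 tab-separated columns",
                 which(nf < 2L | nf > 3L)[1L]))
  }
  if (length(unique(nf)) > 1L) {
    stop("network file mixes weighted and unweighted lines")
  }
  reg <- vapply(fields, `[[`, character(1L), 1L)
  tgt <- vapply(fields, `[[`, character(1L), 2L)
  if (nf[1L] == 3L) {
    w <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1L), 3L)))
    if (any(!is.finite(w))) {
      stop(sprintf("network line %d: non-finite or non-numeric weight",
                   which(!is.finite(w))[1L]))
    }
    regulatory_network(reg, tgt, w)
  } else {
    regulatory_network(reg, tgt)
  }
}

#' @rdname read_network
#' @param net a [regulatory_network]
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "regulatory_network"))
  if (is_weighted(net)) {
    lines <- paste(net$regulator, net$target,
                   formatC(net$weight, format = "g", digits = 15), sep = "\t")
    header <- "#regulator\ttarget\tweight"
  } else {
    lines <- paste(net$regulator, net$target, sep = "\t")
    header <- "#regulator\ttarget"
  }
  writeLines(c(header, lines), path, sep = "\n")
  invisible(path)
}

#' Read and write expression matrices as TSV
#'
#' Tab-separated text with sample identifiers in the first row and gene
#' identifiers in the first column; `.` decimal separator; `#`-prefixed
#' lines are ignored.
#'
#' @param path file path.
#' @return `read_expression()` returns a numeric genes x samples matrix with
#'   gene row names and sample column names.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", row.names = NULL,
                          comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE, colClasses = "character")
  if (ncol(df) < 2L) stop("expression TSV needs a gene column and >=1 sample")
  genes <- df[[1L]]
  if (anyDuplicated(genes)) {
    stop("duplicate gene identifier: ", genes[duplicated(genes)][1L])
  }
  vals <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  if (any(is.na(num))) {
    bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric expression value at gene '%s', sample '%s'",
                 genes[bad[1L]], colnames(vals)[bad[2L]]))
  }
  rownames(num) <- genes
  colnames(num) <- colnames(vals)
  check_expression(num)
  num
}

#' @rdname read_expression
#' @param expr numeric genes x samples matrix with dimnames.
#' @export
write_expression <- function(expr, path) {
  check_expression(expr)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(c("gene", colnames(expr)), collapse = "\t"), con, sep = "\n")
  body <- apply(expr, 1L, function(v) {
    paste(formatC(v, format = "g", digits = 15), collapse = "\t")
  })
  writeLines(paste(rownames(expr), body, sep = "\t"), con, sep = "\n")
  invisible(path)
}

#' Drop genes with low expression variance
#'
#' Standard pre-filter applied to expression compendia before module
#' detection: genes whose sample standard deviation (n - 1 denominator)
#' falls below `min_sd` are removed. A threshold of 0.5 is conventional for
#' microbial compendia and 1 for human data.
#'
#' @param expr numeric genes x samples matrix.
#' @param min_sd non-negative standard deviation threshold; genes with
#'   `sd >= min_sd` are retained.
#' @return the filtered matrix (samples unchanged).
#' @export
filter_low_variance <- function(expr, min_sd = 0.5) {
  check_expression(expr, min_samples = 2L)
  stopifnot(is.numeric(min_sd), length(min_sd) == 1L, min_sd >= 0)
  sds <- apply(expr, 1L, stats::sd)
  keep <- sds >= min_sd
  if (!any(keep)) {
    stop("no genes pass the variance filter; lower `min_sd` (currently ",
         min_sd, ")")
  }
  expr[keep, , drop = FALSE]
}

#' Crisp modules from fuzzy membership values
#'
#' Converts a genes x modules matrix of membership strengths (fuzzy
#' clustering or decomposition output) into a crisp but possibly
#' overlapping [module_set]: gene g belongs to module j iff
#' `mm[g, j] >= cutoff`. Empty modules are dropped.
#'
#' @param mm numeric genes x modules matrix with gene row names and module
#'   column names; values finite.
#' @param cutoff finite membership cutoff.
#' @return a [module_set] (possibly with zero modules).
#' @export
threshold_memberships <- function(mm, cutoff) {
  if (!is.matrix(mm) || !is.numeric(mm)) stop("`mm` must be a numeric matrix")
  if (is.null(rownames(mm)) || is.null(colnames(mm))) {
    stop("membership matrix needs gene row names and module column names")
  }
  if (any(!is.finite(mm))) stop("membership values must be finite")
  stopifnot(is.numeric(cutoff), length(cutoff) == 1L, is.finite(cutoff))
  modules <- lapply(seq_len(ncol(mm)), function(j) {
    rownames(mm)[mm[, j] >= cutoff]
  })
  names(modules) <- colnames(mm)
  modules <- modules[lengths(modules) > 0L]
  module_set(modules, universe = rownames(mm))
}
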