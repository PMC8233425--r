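#' Construct a two-condition count matrix
#'
#' @param counts Non-negative integer matrix, genes in rows (unique
#'   rownames), samples in columns.
#' @param condition Named character vector mapping every column to
#'   `"ref"` or `"test"` (reference vs test condition).
#' @return A `count_matrix` object.
#' @export
count_matrix <- function(counts, condition) {
  stopifnot(is.matrix(counts))
  if (is.null(rownames(counts)) || anyDuplicated(rownames(counts))) {
    stop("counts must have unique gene symbols as rownames", call. = FALSE)
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (is.null(colnames(counts))) {
    stop("counts must have sample labels as colnames", call. = FALSE)
  }
  miss <- setdiff(colnames(counts), names(condition))
  if (length(miss)) {
    stop("no condition assignment for sample(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  condition <- condition[colnames(counts)]
  if (!all(condition %in% c("ref", "test"))) {
    stop("conditions must be 'ref' or 'test'", call. = FALSE)
  }
  if (!all(c("ref", "test") %in% condition)) {
    stop("both conditions must have at least one sample", call. = FALSE)
  }
  if (any(colSums(counts) == 0)) {
    stop("every sample must have a positive library size", call. = FALSE)
  }
  structure(list(counts = counts, condition = condition),
            class = "count_matrix")
}

#' Read a gene x sample count matrix from TSV
#'
#' First column = gene symbols, remaining columns = samples (header row
#' carries the sample labels).
#'
#' @param path Counts TSV.
#' @param condition Named ref/test assignment for the samples.
#' @return A `count_matrix`.
#' @export
read_count_matrix <- function(path, condition) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  genes <- trimws(tab[[1L]])
  m <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(m) <- genes
  count_matrix(m, condition)
}

#' Counts per million
#'
#' `cpm(g, s) = counts(g, s) / library_size(s) * 1e6`; every column of the
#' result sums to one million.
#'
#' @param x A `count_matrix` or plain counts matrix.
#' @return Matrix of CPM values, same dimensions as the counts.
#' @export
cpm <- function(x) {
  counts <- if (inherits(x, "count_matrix")) x$counts else x
  totals <- colSums(counts)
  if (any(totals == 0)) {
    stop("zero library size: CPM undefined", call. = FALSE)
  }
  sweep(counts, 2L, totals, "/") * 1e6
}

#' Per-gene log2 fold change and root-square deviation
#'
#' The contrast is defined on per-condition mean CPM: for each gene,
#' `logfc = log2(mean_cpm_test + pseudocount) - log2(mean_cpm_ref +
#' pseudocount)`, so `logfc > 0` means higher CPM in the test condition.
#' The root-square deviation (RSD) -- the square root of the squared
#' difference -- equals `|logfc|` and is carried as the magnitude-of-change
#' metric.
#'
#' @param x A `count_matrix`.
#' @param pseudocount Positive value added to CPM before the log
#'   (default 0.5, bounding the fold change for zero counts).
#' @return data.frame with `gene`, `log2cpm_ref`, `log2cpm_test`, `logfc`,
#'   `rsd`, in input gene order.
#' @export
log_fold_change <- function(x, pseudocount = 0.5) {
  stopifnot(inherits(x, "count_matrix"))
  if (!is.numeric(pseudocount) || length(pseudocount) != 1L ||
      pseudocount <= 0) {
    stop("pseudocount must be a single positive number", call. = FALSE)
  }
  cp <- cpm(x)
  mean_ref <- rowMeans(cp[, x$condition == "ref", drop = FALSE])
  mean_test <- rowMeans(cp[, x$condition == "test", drop = FALSE])
  l_ref <- log2(mean_ref + pseudocount)
  l_test <- log2(mean_test + pseudocount)
  logfc <- l_test - l_ref
  data.frame(gene = rownames(cp), log2cpm_ref = l_ref, log2cpm_test = l_test,
             logfc = logfc, rsd = sqrt(logfc^2),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Top-ranked genes of a contrast
#'
#' Stable sort by `logfc` (descending for `"up"`, ascending for `"down"`)
#' or by `rsd` descending for `"deviation"`; ties break lexicographically by
#' gene symbol. `n` larger than the gene count returns all genes.
#'
#' @param records Output of [log_fold_change()].
#' @param n Number of genes to return.
#' @param direction `"up"`, `"down"` or `"deviation"`.
#' @return Character vector of gene symbols.
#' @export
rank_top <- function(records, n, direction = c("up", "down", "deviation")) {
  direction <- match.arg(direction)
  stopifnot(n >= 1L)
  ord <- switch(direction,
    up = order(-records$logfc, records$gene),
    down = order(records$logfc, records$gene),
    deviation = order(-records$rsd, records$gene)
  )
  utils::head(records$gene[ord], n)
}

#' Build a pathway catalog
#'
#' @param sets Named list of character vectors (pathway id -> member gene
#'   symbols); empty sets are rejected. Symbols are whitespace-stripped and
#'   matched case-sensitively throughout.
#' @param universe Gene universe for enrichment; defaults to the union of
#'   all catalogued symbols (the set of genes that exist in any pathway).
#' @return A `pathway_catalog` object.
#' @export
pathway_catalog <- function(sets, universe = NULL) {
  stopifnot(is.list(sets), length(sets) > 0L, !is.null(names(sets)))
  sets <- lapply(sets, function(s) unique(trimws(s)))
  if (any(lengths(sets) == 0L)) {
    stop("pathway catalog contains an empty pathway", call. = FALSE)
  }
  if (is.null(universe)) {
    universe <- sort(unique(unlist(sets, use.names = FALSE)))
  } else {
    universe <- unique(trimws(universe))
    outside <- setdiff(unlist(sets, use.names = FALSE), universe)
    if (length(outside)) {
      stop("pathway member(s) outside the universe: ",
           paste(utils::head(outside, 5L), collapse = ", "), call. = FALSE)
    }
  }
  structure(list(pathways = sets, universe = universe),
            class = "pathway_catalog")
}

#' Read pathway gene sets in GMT format
#'
#' @param path GMT file (set name, description, member symbols per line).
#' @return A `pathway_catalog`.
#' @export
read_gmt <- function(path) {
  pathway_catalog(fgsea::gmtPathways(path))
}

#' Fisher-exact pathway over-representation
#'
#' For each pathway, a one-sided (over-representation) Fisher exact test on
#' the 2x2 table of membership in the query set versus the pathway, over the
#' catalog universe. Query symbols outside the universe are dropped with a
#' message. No multiple-testing correction is applied; significance is a
#' predefined level `alpha` on the raw p-values.
#'
#' @param query Character vector of gene symbols.
#' @param catalog A [pathway_catalog()].
#' @param alpha Significance level (default 0.01).
#' @return data.frame with `pathway`, overlap `k`, pathway size `K`, query
#'   size `n`, universe size `N`, `p` and `significant`.
#' @export
fisher_enrichment <- function(query, catalog, alpha = 0.01) {
  stopifnot(inherits(catalog, "pathway_catalog"))
  query <- unique(trimws(query))
  dropped <- setdiff(query, catalog$universe)
  if (length(dropped)) {
    message(length(dropped), " query symbol(s) not in the universe dropped")
  }
  query <- intersect(query, catalog$universe)
  if (!length(query)) {
    warning("empty query after intersection with the universe")
    return(data.frame(pathway = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0), p = numeric(0),
                      significant = logical(0)))
  }
  N <- length(catalog$universe)
  n <- length(query)
  rows <- lapply(names(catalog$pathways), function(id) {
    members <- intersect(catalog$pathways[[id]], catalog$universe)
    K <- length(members)
    k <- length(intersect(query, members))
    tab <- matrix(c(k, K - k, n - k, N - K - (n - k)), nrow = 2L)
    p <- stats::fisher.test(tab, alternative = "greater")$p.value
    data.frame(pathway = id, k = k, K = K, n = n, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$significant <- out$p < alpha
  out[order(out$p, out$pathway), , drop = FALSE]
}

#' Mean log2 fold change per pathway
#'
#' Arithmetic mean of the contrast `logfc` over the pathway members present
#' among the expression records; pathways without any matching symbol are
#' reported with `NA` mean and zero matches rather than dropped.
#'
#' @param records Output of [log_fold_change()].
#' @param catalog A [pathway_catalog()].
#' @return data.frame with `pathway`, `n_matched`, `mean_logfc`.
#' @export
pathway_mean_logfc <- function(records, catalog) {
  stopifnot(inherits(catalog, "pathway_catalog"))
  lfc <- stats::setNames(records$logfc, records$gene)
  rows <- lapply(names(catalog$pathways), function(id) {
    hit <- intersect(catalog$pathways[[id]], names(lfc))
    data.frame(pathway = id, n_matched = length(hit),
               mean_logfc = if (length(hit)) mean(lfc[hit]) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
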