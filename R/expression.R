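# Per-gene expression: median-of-ratios (RLE) normalization, log2(x+1)
# transformation and expression-profile clustering.

#' Construct a count matrix with replicate grouping
#'
#' @param counts Non-negative integer matrix, genes in rows, samples in
#'   columns. IR-duplicated genes are separate rows (`_1`/`_2` suffixes);
#'   trans-spliced parts are separate rows (`_2`/`_3` suffixes).
#' @param groups Optional character vector mapping each sample to its group
#'   (e.g. morphotype); defaults to one group.
#' @return A `count_matrix` object.
#' @export
count_matrix <- function(counts, groups = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != floor(counts)))
    stop("counts must be non-negative integers", call. = FALSE)
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("sample", seq_len(ncol(counts)))
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("gene", seq_len(nrow(counts)))
  if (is.null(groups)) groups <- rep("all", ncol(counts))
  stopifnot(length(groups) == ncol(counts))
  structure(list(counts = counts, groups = setNames(as.character(groups),
                                                    colnames(counts)),
                 size_factors = NULL, normalized = NULL),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("<count_matrix> ", nrow(x$counts), " genes x ", ncol(x$counts),
      " samples (", length(unique(x$groups)), " groups)",
      if (!is.null(x$size_factors)) "; normalized", "\n", sep = "")
  invisible(x)
}

#' Read a counts TSV
#'
#' @param path TSV with gene identifiers in the first column and one column
#'   per sample.
#' @param groups Optional sample-to-group vector.
#' @return A [count_matrix()].
#' @export
read_counts <- function(path, groups = NULL) {
  df <- utils::read.delim(path, row.names = 1L, check.names = FALSE)
  count_matrix(as.matrix(df), groups)
}

#' Relative log expression (median-of-ratios) normalization
#'
#' The per-gene reference is the geometric mean of counts across samples,
#' over the genes with all-positive counts; each sample's size factor is
#' the median of its count/reference ratios over those genes; normalized
#' counts are raw counts divided by the size factor.
#'
#' @param x A [count_matrix()] (needs >= 2 samples and >= 1 gene with
#'   positive counts in every sample).
#' @return The input with `size_factors` and `normalized` filled in.
#' @export
rle_normalize <- function(x) {
  stopifnot(inherits(x, "count_matrix"))
  counts <- x$counts
  if (ncol(counts) < 2L) stop("need >= 2 samples", call. = FALSE)
  ref_genes <- rowSums(counts > 0) == ncol(counts)
  if (!any(ref_genes))
    stop("cannot compute size factors: no gene has positive counts in all ",
         "samples", call. = FALSE)
  log_geo <- rowMeans(log(counts[ref_genes, , drop = FALSE]))
  sf <- apply(counts[ref_genes, , drop = FALSE], 2L, function(cnt)
    exp(median(log(cnt) - log_geo)))
  x$size_factors <- sf
  x$normalized <- sweep(counts, 2L, sf, "/")
  x
}

#' log2(x + 1) transformation
#'
#' @param x A non-negative numeric matrix (e.g. the `normalized` element of
#'   a normalized [count_matrix()]).
#' @return `log2(x + 1)`, elementwise.
#' @export
log_transform <- function(x) {
  if (any(x < 0)) stop("negative values in input", call. = FALSE)
  log2(x + 1)
}

#' Cluster expression profiles
#'
#' Hierarchical clustering of samples on `1 - Pearson correlation` between
#' expression profiles, with average linkage by default. The dendrogram is
#' deterministic; hclust breaks ties by input order.
#'
#' @param mat Numeric matrix, genes in rows, samples in columns (typically
#'   log-transformed normalized counts); needs >= 2 samples and >= 2 genes
#'   with variance.
#' @param linkage Linkage method for [stats::hclust()] (default
#'   `"average"`).
#' @return A list with `hclust` (the tree), `order` (leaf names for heat-map
#'   reproduction), `dist` (the distance object) and `newick` (the tree as a
#'   Newick string, via ape).
#' @export
cluster_profiles <- function(mat, linkage = "average") {
  mat <- as.matrix(mat)
  if (ncol(mat) < 2L) stop("need >= 2 samples", call. = FALSE)
  if (nrow(mat) < 2L) stop("need >= 2 genes", call. = FALSE)
  sds <- apply(mat, 2L, stats::sd)
  if (any(sds == 0))
    stop("zero-variance sample(s): ",
         paste(colnames(mat)[sds == 0], collapse = ", "), call. = FALSE)
  d <- as.dist(1 - cor(mat, method = "pearson"))
  hc <- hclust(d, method = linkage)
  phy <- ape::as.phylo(hc)
  list(hclust = hc, order = hc$labels[hc$order], dist = d,
       newick = ape::write.tree(phy))
}
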