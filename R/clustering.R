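#' Z-score the rows of a matrix
#'
#' Centers and scales each row to mean 0 and population standard deviation
#' 1 (divisor `n`, not `n - 1`); constant rows map to all-zeros.
#'
#' @param m numeric matrix with at least two columns.
#' @return matrix of the same shape.
#' @export
zscore_rows <- function(m) {
  m <- as.matrix(m)
  if (ncol(m) < 2) stop2("zscore_rows needs at least two columns")
  mu <- rowMeans(m)
  sd_pop <- sqrt(rowMeans((m - mu)^2))
  z <- (m - mu) / ifelse(sd_pop == 0, 1, sd_pop)
  z[sd_pop == 0, ] <- 0
  z
}

# deterministic relabeling: cluster ids ordered by size (descending),
# ties broken by first appearance
relabel_by_size <- function(labels) {
  tab <- table(labels)
  first <- vapply(names(tab), function(l) match(l, labels), integer(1))
  ord <- names(tab)[order(-as.integer(tab), first)]
  out <- match(as.character(labels), ord)
  names(out) <- names(labels)
  out
}

#' Hierarchical bi-clustering of a gene-by-tumor-type matrix
#'
#' Agglomerative clustering with Euclidean distance and Ward linkage
#' (`ward.D2`, i.e. Ward's criterion on squared Euclidean distances),
#' applied independently to rows (genes) and columns (tumor types) of a
#' row-Z-scored matrix; each tree is cut to the requested number of
#' clusters. Labels are renumbered by cluster size (largest = 1) so the
#' partition is deterministic up to the linkage itself.
#'
#' @param m numeric matrix, typically [zscore_rows()] of the selected-gene
#'   by tumor-type mean-expression matrix.
#' @param n_gene_clusters,n_tumor_groups number of clusters to cut the
#'   row/column trees into (default 5 and 3).
#' @return a `gc_biclust`: `gene_clusters`, `tumor_groups` (named integer
#'   vectors), `gene_tree`, `tumor_tree` (`hclust` objects).
#' @export
bicluster <- function(m, n_gene_clusters = 5, n_tumor_groups = 3) {
  m <- as.matrix(m)
  if (n_gene_clusters < 1 || n_gene_clusters > nrow(m)) {
    stop2("n_gene_clusters must be between 1 and nrow(m)")
  }
  if (n_tumor_groups < 1 || n_tumor_groups > ncol(m)) {
    stop2("n_tumor_groups must be between 1 and ncol(m)")
  }
  gene_tree <- stats::hclust(stats::dist(m), method = "ward.D2")
  tumor_tree <- stats::hclust(stats::dist(t(m)), method = "ward.D2")
  gene_clusters <- relabel_by_size(stats::cutree(gene_tree, k = n_gene_clusters))
  tumor_groups <- relabel_by_size(stats::cutree(tumor_tree, k = n_tumor_groups))
  structure(
    list(gene_clusters = gene_clusters, tumor_groups = tumor_groups,
         gene_tree = gene_tree, tumor_tree = tumor_tree),
    class = "gc_biclust"
  )
}

#' @export
print.gc_biclust <- function(x, ...) {
  gs <- table(x$gene_clusters); ts <- table(x$tumor_groups)
  cat(sprintf("<gc_biclust> %d genes in %d clusters (%s); %d tumor types in %d groups (%s)\n",
              length(x$gene_clusters), length(gs),
              paste(as.integer(gs), collapse = "/"),
              length(x$tumor_groups), length(ts),
              paste(as.integer(ts), collapse = "/")))
  invisible(x)
}

#' Heat-map display of a bi-clustering
#'
#' Rows and columns ordered by their dendrograms; Z-score color scale.
#' @param x a [bicluster()] result.
#' @param m the matrix that was clustered.
#' @param ... passed to [stats::heatmap()].
#' @export
plot.gc_biclust <- function(x, m, ...) {
  stats::heatmap(as.matrix(m),
                 Rowv = stats::as.dendrogram(x$gene_tree),
                 Colv = stats::as.dendrogram(x$tumor_tree),
                 scale = "none", ...)
  invisible(x)
}

#' Write the two linkage trees in Newick format
#'
#' @param x a [bicluster()] result.
#' @param gene_path,tumor_path output files.
#' @export
write_trees <- function(x, gene_path, tumor_path) {
  stopifnot(inherits(x, "gc_biclust"))
  ape::write.tree(ape::as.phylo(x$gene_tree), gene_path)
  ape::write.tree(ape::as.phylo(x$tumor_tree), tumor_path)
  invisible(c(gene_path, tumor_path))
}
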