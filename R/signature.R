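#' Single-sample rank-percentile signature score
#'
#' Within each sample, all `N` universe genes are ranked by expression
#' (ascending, average ranks for ties); a gene's percentile is
#' `rank / N * 100` and the score is the mean percentile of the geneset
#' genes present in the universe. The score lies in (0, 100] and is
#' invariant under any strictly monotone transform of the sample's
#' expression values, which makes it comparable across differently
#' normalized samples.
#'
#' @param expression gene-by-sample numeric matrix (or a named vector for
#'   a single sample) over the gene universe.
#' @param geneset character vector of gene symbols; members missing from
#'   the universe are dropped and counted in `geneset_size_used`.
#' @return data.frame `sample`, `score`, `geneset_size_used`.
#' @export
signature_score <- function(expression, geneset) {
  if (is.null(dim(expression))) {
    expression <- matrix(expression, ncol = 1,
                         dimnames = list(names(expression), "sample_1"))
  }
  expression <- as.matrix(expression)
  if (is.null(rownames(expression))) stop2("expression needs gene rownames")
  used <- intersect(unique(geneset), rownames(expression))
  if (length(used) == 0) stop2("empty effective geneset: no geneset gene in the universe")
  n <- nrow(expression)
  idx <- match(used, rownames(expression))
  scores <- vapply(seq_len(ncol(expression)), function(j) {
    x <- expression[, j]
    if (max(x) == min(x)) {
      warning("all-constant expression vector in sample '",
              colnames(expression)[j], "': ranking is undefined", call. = FALSE)
    }
    pct <- rank(x, ties.method = "average") / n * 100
    mean(pct[idx])
  }, numeric(1))
  data.frame(
    sample = colnames(expression),
    score = scores,
    geneset_size_used = length(used),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Screen genes for correlation with a signature score
#'
#' Pearson correlation of each gene's expression with the per-sample score,
#' with a two-sided p-value from the t distribution on `n - 2` degrees of
#' freedom. Genes pass into the positive list when `r > r_threshold` and
#' `p < p_threshold`, into the negative list when `r < -r_threshold` and
#' `p < p_threshold`. Constant-expression genes cannot be correlated and
#' are reported in `skipped`.
#'
#' @param expression gene-by-sample matrix over the scored samples.
#' @param scores named numeric vector or [signature_score()] data.frame.
#' @param r_threshold,p_threshold screening thresholds (defaults 0.5, 0.05).
#' @return list with data.frames `positive` and `negative` (`gene`, `r`,
#'   `p`, `direction`), `all` (every testable gene), and `skipped`.
#' @export
correlate_with_score <- function(expression, scores,
                                 r_threshold = 0.5, p_threshold = 0.05) {
  scores <- as_score_vector(scores)
  expression <- as.matrix(expression)
  if (!all(names(scores) %in% colnames(expression))) {
    stop2("score samples missing from the expression matrix")
  }
  expression <- expression[, names(scores), drop = FALSE]
  n <- length(scores)
  if (n < 3) stop2("need at least 3 samples to correlate")
  sds <- apply(expression, 1, stats::sd)
  skipped <- rownames(expression)[sds == 0]
  keep <- sds > 0
  r <- as.vector(stats::cor(t(expression[keep, , drop = FALSE]), scores))
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  p[abs(r) >= 1] <- 0
  all_df <- data.frame(
    gene = rownames(expression)[keep], r = r, p = p,
    direction = ifelse(r > 0, "positive", "negative"),
    row.names = NULL, stringsAsFactors = FALSE
  )
  list(
    positive = all_df[all_df$r > r_threshold & all_df$p < p_threshold, ,
                      drop = FALSE],
    negative = all_df[all_df$r < -r_threshold & all_df$p < p_threshold, ,
                      drop = FALSE],
    all = all_df,
    skipped = skipped
  )
}
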