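#' Dataset kinds recognized by the pipeline
#'
#' The eight roles an expression matrix can play: embryonic germ cells
#' profiled in vivo (`hpgc`) and in vitro (`pgclc`), embryonic stem cells
#' (`esc`), the gonadal somatic tissue that surrounds germ cells in situ
#' (`soma`), adult male germ cells (`adult_germ`), a healthy-tissue
#' compendium (`normal_compendium`), a tumor compendium
#' (`tumor_compendium`) and an optional cell-line panel (`cell_lines`).
#' @export
dataset_kinds <- function() {
  c("hpgc", "pgclc", "esc", "soma", "adult_germ",
    "normal_compendium", "tumor_compendium", "cell_lines")
}

#' Construct an expression dataset
#'
#' The common currency of the pipeline: a gene-by-sample numeric matrix with
#' a scale flag and per-sample annotations. Values on the `linear` scale are
#' normalized expression estimates (e.g. TPM-like); `log2` means
#' `log2(x + 1)` of those.
#'
#' @param values numeric matrix, genes as rows (unique rownames), samples as
#'   columns (colnames = sample ids).
#' @param scale `"linear"` or `"log2"`.
#' @param samples data.frame with at least `sample_id` and `group`; optional
#'   `sex` (`"female"`/`"male"`) and `stage_weeks` for germ-cell datasets.
#' @param kind one of [dataset_kinds()].
#' @return an object of class `expression_dataset`.
#' @export
expression_dataset <- function(values, scale = c("linear", "log2"), samples, kind) {
  scale <- match.arg(scale)
  kind <- match.arg(kind, dataset_kinds())
  values <- as.matrix(values)
  if (!is.numeric(values)) stop2("expression values must be numeric")
  if (is.null(rownames(values)) || anyNA(rownames(values))) {
    stop2("values must carry gene identifiers as rownames")
  }
  if (anyDuplicated(rownames(values))) {
    stop2("duplicate gene identifiers in expression matrix")
  }
  if (is.null(colnames(values))) stop2("values must carry sample ids as colnames")
  if (scale == "linear" && any(values < 0, na.rm = TRUE)) {
    stop2("negative values are not allowed on the linear scale")
  }
  samples <- as.data.frame(samples)
  if (!all(c("sample_id", "group") %in% names(samples))) {
    stop2("samples must have columns 'sample_id' and 'group'")
  }
  if (!all(colnames(values) %in% samples$sample_id)) {
    stop2("every matrix column needs a row in the sample annotation")
  }
  if (anyNA(samples$group)) stop2("every sample needs a group label")
  samples <- samples[match(colnames(values), samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL
  structure(
    list(values = values, scale = scale, samples = samples, kind = kind),
    class = "expression_dataset"
  )
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf(
    "<expression_dataset: %s> %d genes x %d samples (%s scale), %d groups\n",
    x$kind, nrow(x$values), ncol(x$values), x$scale,
    length(unique(x$samples$group))
  ))
  invisible(x)
}

#' @export
dim.expression_dataset <- function(x) dim(x$values)

#' Gene-length correction of linear-scale expression
#'
#' Rescales a linear-scale expression estimate by transcript length:
#' `expression / length * 1000`. Used for the embryonic germ-cell datasets
#' whose upstream normalization is not length-aware.
#'
#' @param expression non-negative linear-scale value(s).
#' @param length_bp transcript length(s) in bp, positive; recycled.
#' @return corrected value(s).
#' @examples
#' length_correct(10, 2000)  # 5
#' @export
length_correct <- function(expression, length_bp) {
  if (any(length_bp <= 0)) stop2("transcript length must be positive")
  if (any(expression < 0)) stop2("expression must be non-negative (linear scale)")
  expression / length_bp * 1000
}

#' Apply gene-length correction to a whole dataset
#'
#' @param dataset a linear-scale [expression_dataset()].
#' @param gene_lengths named numeric vector (or data.frame with `gene`,
#'   `length_bp`) covering every gene of the dataset.
#' @return the corrected dataset, still linear scale.
#' @export
apply_length_correction <- function(dataset, gene_lengths) {
  stopifnot(inherits(dataset, "expression_dataset"))
  if (dataset$scale != "linear") {
    stop2("length correction applies to linear-scale data only")
  }
  if (is.data.frame(gene_lengths)) {
    gene_lengths <- stats::setNames(gene_lengths$length_bp, gene_lengths$gene)
  }
  genes <- rownames(dataset$values)
  if (!all(genes %in% names(gene_lengths))) {
    stop2("gene_lengths missing for some genes in the dataset")
  }
  len <- gene_lengths[genes]
  dataset$values <- dataset$values / len * 1000
  dataset
}

#' Convert a dataset to the log2 scale
#'
#' Maps every linear value `x` to `log2(x + 1)`; the +1 pseudocount keeps
#' zeros at zero. A no-op on data already flagged `log2`.
#'
#' @param dataset an [expression_dataset()].
#' @return the dataset with `scale = "log2"`.
#' @export
to_log2 <- function(dataset) {
  stopifnot(inherits(dataset, "expression_dataset"))
  if (dataset$scale == "log2") return(dataset)
  if (any(dataset$values < 0, na.rm = TRUE)) {
    stop2("negative values cannot be log-transformed")
  }
  dataset$values <- log2(dataset$values + 1)
  dataset$scale <- "log2"
  dataset
}

#' Build the shared gene universe
#'
#' A gene enters the universe iff it has an expression row in every required
#' dataset; genes missing from one carry the first missing dataset's kind as
#' their exclusion reason. Mirrors the practice of dropping genes absent
#' from either of the two large compendia before thresholding.
#'
#' @param datasets named list of [expression_dataset()] objects.
#' @param required_kinds kinds a gene must be measured in (default: the
#'   normal and tumor compendia).
#' @return `gene_universe`: list with `included` (character vector) and
#'   `excluded` (data.frame `gene`, `reason`).
#' @export
build_universe <- function(datasets,
                           required_kinds = c("normal_compendium", "tumor_compendium")) {
  kinds <- vapply(datasets, function(d) d$kind, character(1))
  if (!all(required_kinds %in% kinds)) {
    stop2("required dataset kinds missing: ",
          paste(setdiff(required_kinds, kinds), collapse = ", "))
  }
  all_genes <- unique(unlist(lapply(datasets, function(d) rownames(d$values))))
  reason <- rep(NA_character_, length(all_genes))
  names(reason) <- all_genes
  for (k in required_kinds) {
    ds <- datasets[[which(kinds == k)[1]]]
    missing <- setdiff(all_genes, rownames(ds$values))
    newly <- missing[is.na(reason[missing])]
    reason[newly] <- k
  }
  included <- all_genes[is.na(reason)]
  excluded <- data.frame(
    gene = all_genes[!is.na(reason)],
    reason = reason[!is.na(reason)],
    row.names = NULL, stringsAsFactors = FALSE
  )
  if (length(included) == 0) {
    stop2("empty gene universe: no gene is present in all required datasets")
  }
  structure(list(included = included, excluded = excluded), class = "gene_universe")
}

#' @export
print.gene_universe <- function(x, ...) {
  cat(sprintf("<gene_universe> %d genes included, %d excluded\n",
              length(x$included), nrow(x$excluded)))
  invisible(x)
}

#' Summarize a dataset per sample group
#'
#' Collapses samples to one column per group label (tissue or tumor type)
#' using `mean` or `max`, after dropping any groups in `exclude_groups`
#' (e.g. testis, ovary and transformed cell lines for the normal
#' compendium, so genes shared with the adult germline are not filtered
#' away).
#'
#' @param dataset a log2-scale [expression_dataset()].
#' @param statistic `"mean"` or `"max"` across the samples of a group.
#' @param exclude_groups group labels to drop; must all be observed.
#' @return `tissue_summary`: list with `values` (gene x group matrix),
#'   `statistic`, `source_kind`.
#' @export
summarize_groups <- function(dataset, statistic = c("mean", "max"),
                             exclude_groups = character()) {
  stopifnot(inherits(dataset, "expression_dataset"))
  statistic <- match.arg(statistic)
  if (dataset$scale != "log2") stop2("summarize_groups expects log2-scale data")
  observed <- unique(dataset$samples$group)
  if (!all(exclude_groups %in% observed)) {
    stop2("exclude_groups not observed in dataset: ",
          paste(setdiff(exclude_groups, observed), collapse = ", "))
  }
  keep <- setdiff(observed, exclude_groups)
  if (length(keep) == 0) stop2("all groups excluded")
  fun <- if (statistic == "mean") {
    function(m) rowMeans(m, na.rm = TRUE)
  } else {
    function(m) apply(m, 1, max, na.rm = TRUE)
  }
  cols <- lapply(keep, function(g) {
    ids <- dataset$samples$sample_id[dataset$samples$group == g]
    if (length(ids) == 0) stop2("group with zero samples: ", g)
    fun(dataset$values[, ids, drop = FALSE])
  })
  values <- do.call(cbind, cols)
  colnames(values) <- keep
  structure(
    list(values = values, statistic = statistic, source_kind = dataset$kind),
    class = "tissue_summary"
  )
}

#' @export
print.tissue_summary <- function(x, ...) {
  cat(sprintf("<tissue_summary: %s of %s> %d genes x %d groups\n",
              x$statistic, x$source_kind, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
as.matrix.tissue_summary <- function(x, ...) x$values

# accept a tissue_summary, matrix, or named vector and return a per-gene
# vector: the rowwise max for matrix-like inputs
summary_to_vector <- function(x) {
  if (inherits(x, "tissue_summary")) x <- x$values
  if (is.matrix(x)) {
    apply(x, 1, max)
  } else if (is.numeric(x) && !is.null(names(x))) {
    x
  } else {
    stop2("expected a tissue_summary, matrix, or named numeric vector")
  }
}
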