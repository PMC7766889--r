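#' Write an expression matrix as TSV
#'
#' Genes as rows; first column `gene`, remaining columns one per sample.
#' @param values gene x sample matrix with dimnames.
#' @param path output file.
#' @export
write_expression_tsv <- function(values, path) {
  df <- data.frame(gene = rownames(values), values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an expression matrix from TSV
#'
#' Expects the layout of [write_expression_tsv()].
#' @param path TSV file, first column = gene symbol.
#' @return numeric matrix with gene rownames.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- df[[1]]
  m
}

#' Read a newline-delimited gene list
#'
#' One symbol per line; blank lines and surrounding whitespace dropped.
#' @param path text file.
#' @return character vector of symbols.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x[nzchar(x)]
}

#' Write a synthetic cohort to a directory of plain-text files
#'
#' Each expression dataset becomes `<name>.tsv` (matrix) plus
#' `<name>.samples.tsv` (annotations); gene lengths, truth labels, protein
#' tables and the survival table are TSV; the generating configuration is
#' echoed as JSON.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, file) {
    utils::write.table(df, file.path(dir, file), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  for (nm in names(cohort$datasets)) {
    ds <- cohort$datasets[[nm]]
    write_expression_tsv(ds$values, file.path(dir, paste0(nm, ".tsv")))
    wt(ds$samples, paste0(nm, ".samples.tsv"))
  }
  wt(cohort$gene_lengths, "gene_lengths.tsv")
  wt(cohort$truth, "truth.tsv")
  wt(cohort$protein$hpa_tissue, "hpa_tissue.tsv")
  wt(cohort$protein$hpa_tumor, "hpa_tumor.tsv")
  wt(cohort$protein$cptac, "cptac.tsv")
  wt(cohort$protein$truth, "protein_truth.tsv")
  wt(cohort$survival, "survival.tsv")
  cfg <- cohort$config
  cfg$selection <- unclass(cfg$selection)
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory produced by [write_cohort()].
#' @return a `synthetic_cohort` object (datasets on their original linear
#'   scale, ready for harmonization).
#' @export
read_cohort <- function(dir) {
  rt <- function(file) {
    utils::read.delim(file.path(dir, file), check.names = FALSE,
                      stringsAsFactors = FALSE)
  }
  cfg <- jsonlite::read_json(file.path(dir, "config.json"), simplifyVector = TRUE)
  sel <- do.call(selection_config, cfg$selection)
  cfg$selection <- NULL
  config <- do.call(simulation_config, c(cfg, list(selection = sel)))
  datasets <- list()
  for (nm in dataset_kinds()) {
    f <- file.path(dir, paste0(nm, ".tsv"))
    if (!file.exists(f)) next
    samples <- rt(paste0(nm, ".samples.tsv"))
    samples$sample_id <- as.character(samples$sample_id)
    datasets[[nm]] <- expression_dataset(
      read_expression_tsv(f), scale = "linear", samples = samples, kind = nm
    )
  }
  surv <- rt("survival.tsv")
  surv$sample <- as.character(surv$sample)
  structure(list(
    datasets = datasets,
    gene_lengths = rt("gene_lengths.tsv"),
    truth = rt("truth.tsv"),
    protein = list(
      hpa_tissue = rt("hpa_tissue.tsv"),
      hpa_tumor = rt("hpa_tumor.tsv"),
      cptac = rt("cptac.tsv"),
      truth = rt("protein_truth.tsv")
    ),
    survival = surv,
    config = config
  ), class = "synthetic_cohort")
}
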