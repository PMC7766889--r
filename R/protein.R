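protein_levels <- c("not_detected", "low", "medium", "high")

#' Categorical (immunohistochemistry-style) protein validation for one gene
#'
#' Two flags: `somatic_clear` — every healthy tissue other than the exempt
#' gonadal ones is `not_detected`; `tumor_positive` — at least one tumor
#' type where the protein was detected in at least 50% of the investigated
#' samples (inclusive; panels hold at most ~12 samples).
#'
#' @param tissue_levels named character vector, healthy tissue ->
#'   detection category (`not_detected`/`low`/`medium`/`high`).
#' @param tumor_detection data.frame `tumor_type`, `n_detected`,
#'   `n_investigated` (optional; `tumor_positive` is `NA` if omitted).
#' @param exempt_tissues tissues ignored by the somatic rule.
#' @return list `somatic_clear`, `tumor_positive`.
#' @export
hpa_validate <- function(tissue_levels, tumor_detection = NULL,
                         exempt_tissues = c("seminiferous_tubules", "ovary")) {
  if (length(tissue_levels) == 0) stop2("tissue_levels must be non-empty")
  if (!all(tissue_levels %in% protein_levels)) {
    stop2("unknown detection category: ",
          paste(setdiff(tissue_levels, protein_levels), collapse = ", "))
  }
  somatic <- tissue_levels[!(names(tissue_levels) %in% exempt_tissues)]
  somatic_clear <- all(somatic == "not_detected")
  tumor_positive <- if (is.null(tumor_detection) || nrow(tumor_detection) == 0) {
    NA
  } else {
    if (any(tumor_detection$n_detected > tumor_detection$n_investigated)) {
      stop2("n_detected exceeds n_investigated")
    }
    any(tumor_detection$n_detected / tumor_detection$n_investigated >= 0.5)
  }
  list(somatic_clear = somatic_clear, tumor_positive = tumor_positive)
}

#' Quantitative (mass-spectrometry-style) protein validation for one gene
#'
#' A dataset is positive when the median tumor abundance strictly exceeds
#' the median abundance in matched normal tissue; equal medians do not
#' count. Datasets with an empty tumor or normal list are skipped with a
#' warning.
#'
#' @param records data.frame for one gene with columns `dataset`,
#'   `tissue_class` (`"tumor"`/`"normal"`), `abundance`.
#' @return character vector of positive dataset labels.
#' @export
cptac_validate <- function(records) {
  if (nrow(records) == 0) return(character(0))
  out <- character(0)
  for (ds in unique(records$dataset)) {
    r <- records[records$dataset == ds, , drop = FALSE]
    tu <- r$abundance[r$tissue_class == "tumor"]
    no <- r$abundance[r$tissue_class == "normal"]
    if (length(tu) == 0 || length(no) == 0) {
      warning("dataset '", ds, "' skipped: empty abundance list", call. = FALSE)
      next
    }
    if (stats::median(tu) > stats::median(no)) out <- c(out, ds)
  }
  out
}

#' Protein-level validation verdicts over a gene table
#'
#' Combines both evidence types: a gene is validated when the categorical
#' rule fires (somatic clear AND a tumor type with >= 50% detection) or
#' when at least one quantitative dataset is positive. Genes with only one
#' evidence type are evaluated on the available side.
#'
#' @param hpa_tissue data.frame `gene`, `tissue`, `level`.
#' @param hpa_tumor data.frame `gene`, `tumor_type`, `n_detected`,
#'   `n_investigated`.
#' @param cptac data.frame `gene`, `dataset`, `sample`, `abundance`,
#'   `tissue_class`.
#' @param exempt_tissues passed to [hpa_validate()].
#' @return data.frame `gene`, `hpa_somatic_clear`, `hpa_tumor_positive`,
#'   `cptac_positive_datasets` (comma-separated), `validated`, `basis`.
#' @export
protein_validate <- function(hpa_tissue = NULL, hpa_tumor = NULL,
                             cptac = NULL,
                             exempt_tissues = c("seminiferous_tubules", "ovary")) {
  genes <- unique(c(
    if (!is.null(hpa_tissue)) hpa_tissue$gene,
    if (!is.null(cptac)) cptac$gene
  ))
  rows <- lapply(genes, function(g) {
    hc <- ht <- NA
    if (!is.null(hpa_tissue) && g %in% hpa_tissue$gene) {
      lv <- hpa_tissue[hpa_tissue$gene == g, , drop = FALSE]
      td <- if (!is.null(hpa_tumor)) {
        hpa_tumor[hpa_tumor$gene == g, , drop = FALSE]
      } else NULL
      v <- hpa_validate(stats::setNames(lv$level, lv$tissue), td, exempt_tissues)
      hc <- v$somatic_clear; ht <- v$tumor_positive
    }
    pos <- if (!is.null(cptac) && g %in% cptac$gene) {
      cptac_validate(cptac[cptac$gene == g, , drop = FALSE])
    } else character(0)
    hpa_fired <- isTRUE(hc) && isTRUE(ht)
    cptac_fired <- length(pos) > 0
    basis <- c(if (hpa_fired) "hpa", if (cptac_fired) "cptac")
    data.frame(
      gene = g, hpa_somatic_clear = hc, hpa_tumor_positive = ht,
      cptac_positive_datasets = paste(pos, collapse = ","),
      validated = hpa_fired || cptac_fired,
      basis = if (length(basis)) paste(basis, collapse = "+") else "none",
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
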