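#' Tumor-breadth classification of selected genes
#'
#' Breadth = number of tumor types whose mean expression exceeds the tumor
#' threshold (the `qualifying` sets of the selection). Flags: `pan_tumor`
#' for genes qualifying in at least `k` types (default 17, half of the 33
#' standard types), `single_tumor` for breadth 1, and `tgct_only` when the
#' sole qualifying type is the testicular germ cell tumor.
#'
#' @param result a [select_gc_genes()] result.
#' @param k minimum breadth for the `pan_tumor` flag (>= 1).
#' @param tgct_label label of the germ-cell tumor type.
#' @param genes genes to classify; defaults to the selected set.
#' @return data.frame `gene`, `breadth`, `single_tumor`, `pan_tumor`,
#'   `tgct_only`.
#' @export
tumor_breadth <- function(result, k = 17, tgct_label = "TGCT",
                          genes = result$selected) {
  stopifnot(inherits(result, "gc_selection"))
  if (k < 1) stop2("k must be at least 1")
  if (!all(genes %in% names(result$qualifying))) {
    stop2("some genes lack an evidence record")
  }
  q <- result$qualifying[genes]
  breadth <- vapply(q, length, integer(1))
  data.frame(
    gene = genes,
    breadth = unname(breadth),
    single_tumor = unname(breadth == 1L),
    pan_tumor = unname(breadth >= k),
    tgct_only = vapply(q, function(s) identical(s, tgct_label), logical(1),
                       USE.NAMES = FALSE),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Embryonic-germline-specific subset of the selected genes
#'
#' Keeps selected genes with no adult-germline trace: adult-germ-cell
#' expression below `adult_floor`, gonadal (testis/ovary) expression below
#' `gonad_floor`, and gonadal-soma expression strictly below the gene's
#' germ-cell statistic. Matrix-like summaries are reduced per gene by their
#' maximum over groups; all comparisons are strict.
#'
#' @param result a [select_gc_genes()] result.
#' @param adult_germ_summary,gonad_summary,soma_summary per-gene summaries
#'   over the selected genes ([summarize_groups()] result, matrix, or named
#'   vector); `gonad_summary` is the normal compendium restricted to its
#'   testis/ovary columns.
#' @param pgc_stat named per-gene germ-cell statistic ([hpgc_statistic()]).
#' @param adult_floor,gonad_floor log2 floors below which expression counts
#'   as absent; default to the somatic ceiling of the selection cascade.
#' @return character vector, a subset of `result$selected`.
#' @export
embryonic_specific <- function(result, adult_germ_summary, gonad_summary,
                               soma_summary, pgc_stat,
                               adult_floor = 3.0, gonad_floor = 3.0) {
  stopifnot(inherits(result, "gc_selection"))
  if (!all(is.finite(c(adult_floor, gonad_floor)))) stop2("floors must be finite")
  adult <- summary_to_vector(adult_germ_summary)
  gonad <- summary_to_vector(gonad_summary)
  soma <- summary_to_vector(soma_summary)
  sel <- result$selected
  for (v in list(adult = adult, gonad = gonad, soma = soma, pgc = pgc_stat)) {
    if (!all(sel %in% names(v))) {
      stop2("missing summary row for a selected gene")
    }
  }
  keep <- adult[sel] < adult_floor &
    gonad[sel] < gonad_floor &
    soma[sel] < pgc_stat[sel]
  sel[keep]
}
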