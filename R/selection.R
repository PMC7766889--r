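#' Threshold configuration for the GC-gene inclusion cascade
#'
#' A gene is called an embryonic germline/cancer (GC) gene when it is
#' expressed in the embryonic germline (hPGC or PGCLC statistic above its
#' threshold), silent in every healthy somatic tissue (normal-compendium
#' maximum below `theta_normal`), and expressed in at least one tumor type
#' (tumor-compendium maximum above `theta_tumor`). All comparisons are
#' strict. Thresholds are fixed constants on the log2 scale; the defaults
#' are the per-dataset cutoffs used in the original compendium analysis
#' (0.72 and 0.50 sit at the 33rd expression percentile of the respective
#' germline datasets there).
#'
#' @param theta_hpgc log2 threshold for the hPGC min/max statistic.
#' @param theta_pgclc log2 threshold for the PGCLC mean.
#' @param theta_normal log2 ceiling for healthy-tissue expression.
#' @param theta_tumor log2 floor a tumor type must exceed.
#' @param excluded_normal_groups normal-compendium groups excluded from the
#'   somatic ceiling (gonadal tissues and transformed cell lines).
#' @return a `selection_config` object.
#' @export
selection_config <- function(theta_hpgc = 0.72,
                             theta_pgclc = 0.50,
                             theta_normal = 3.0,
                             theta_tumor = 2.3,
                             excluded_normal_groups = c(
                               "testis", "ovary",
                               "cells_cultured_fibroblasts",
                               "cells_ebv_lymphocytes"
                             )) {
  thetas <- c(theta_hpgc, theta_pgclc, theta_normal, theta_tumor)
  if (!all(is.finite(thetas))) stop2("all thresholds must be finite")
  structure(
    list(theta_hpgc = theta_hpgc, theta_pgclc = theta_pgclc,
         theta_normal = theta_normal, theta_tumor = theta_tumor,
         excluded_normal_groups = excluded_normal_groups),
    class = "selection_config"
  )
}

#' @export
print.selection_config <- function(x, ...) {
  cat(sprintf(
    "<selection_config> hPGC > %.2f | PGCLC > %.2f; normal < %.2f; tumor > %.2f\n",
    x$theta_hpgc, x$theta_pgclc, x$theta_normal, x$theta_tumor))
  cat("  excluded normal groups:", paste(x$excluded_normal_groups, collapse = ", "), "\n")
  invisible(x)
}

#' Per-gene hPGC expression statistic
#'
#' For each sex, replicate samples of the same developmental stage are
#' averaged, the minimum over stages is taken (a gene must be expressed
#' throughout the sampled window to count), and the statistic is the
#' maximum of the female and male minima (expression in either sex
#' suffices).
#'
#' @param hpgc a log2-scale [expression_dataset()] whose samples carry
#'   `sex` (`"female"`/`"male"`) and `stage_weeks` annotations.
#' @return named numeric vector, one value per gene.
#' @export
hpgc_statistic <- function(hpgc) {
  stopifnot(inherits(hpgc, "expression_dataset"))
  if (hpgc$scale != "log2") stop2("hpgc_statistic expects log2-scale data")
  ann <- hpgc$samples
  if (!all(c("sex", "stage_weeks") %in% names(ann))) {
    stop2("hPGC samples need 'sex' and 'stage_weeks' annotations")
  }
  if (!all(ann$sex %in% c("female", "male"))) {
    stop2("unknown sex label; expected 'female' or 'male'")
  }
  sex_min <- lapply(c("female", "male"), function(s) {
    ids <- ann$sample_id[ann$sex == s]
    if (length(ids) == 0) stop2("no samples for sex: ", s)
    stages <- ann$stage_weeks[match(ids, ann$sample_id)]
    stage_means <- vapply(unique(stages), function(st) {
      rowMeans(hpgc$values[, ids[stages == st], drop = FALSE])
    }, numeric(nrow(hpgc$values)))
    # genes x stages, even when either dimension is 1
    stage_means <- matrix(stage_means, nrow = nrow(hpgc$values))
    apply(stage_means, 1, min)
  })
  out <- pmax(sex_min[[1]], sex_min[[2]])
  names(out) <- rownames(hpgc$values)
  out
}

#' Per-gene PGCLC expression statistic
#'
#' The arithmetic mean across PGCLC replicates.
#'
#' @param pgclc a log2-scale [expression_dataset()] with at least one sample.
#' @return named numeric vector, one value per gene.
#' @export
pgclc_statistic <- function(pgclc) {
  stopifnot(inherits(pgclc, "expression_dataset"))
  if (pgclc$scale != "log2") stop2("pgclc_statistic expects log2-scale data")
  if (ncol(pgclc$values) == 0) stop2("PGCLC dataset has no samples")
  rowMeans(pgclc$values)
}

#' Run the GC-gene inclusion cascade
#'
#' Applies the four criteria over the shared gene universe: germline
#' expression (`hpgc_stat > theta_hpgc` OR `pgclc_stat > theta_pgclc`),
#' somatic silence (max over normal-tissue groups `< theta_normal`), and
#' tumor expression (max over tumor types `> theta_tumor`). Every gene gets
#' an evidence record; `qualifying` lists, per gene, the tumor types whose
#' mean exceeds `theta_tumor`.
#'
#' @param hpgc_stat,pgclc_stat named per-gene vectors from
#'   [hpgc_statistic()] / [pgclc_statistic()].
#' @param normal_summary [summarize_groups()] result (statistic `max`) with
#'   the excluded groups already absent.
#' @param tumor_summary [summarize_groups()] result (statistic `mean`), one
#'   column per tumor type.
#' @param config a [selection_config()].
#' @return a `gc_selection`: `selected` (character), `evidence`
#'   (data.frame), `qualifying` (named list), `config`.
#' @export
select_gc_genes <- function(hpgc_stat, pgclc_stat, normal_summary,
                            tumor_summary, config = selection_config()) {
  stopifnot(inherits(config, "selection_config"))
  nm <- if (inherits(normal_summary, "tissue_summary")) normal_summary$values else as.matrix(normal_summary)
  tm <- if (inherits(tumor_summary, "tissue_summary")) tumor_summary$values else as.matrix(tumor_summary)
  genes <- rownames(nm)
  same <- function(x) length(x) == length(genes) && setequal(x, genes)
  if (!same(names(hpgc_stat)) || !same(names(pgclc_stat)) || !same(rownames(tm))) {
    stop2("gene universe mismatch between selection inputs")
  }
  hpgc_stat <- hpgc_stat[genes]
  pgclc_stat <- pgclc_stat[genes]
  tm <- tm[genes, , drop = FALSE]

  normal_max <- apply(nm, 1, max)
  tumor_max <- apply(tm, 1, max)
  pass_germ <- hpgc_stat > config$theta_hpgc | pgclc_stat > config$theta_pgclc
  pass_normal <- normal_max < config$theta_normal
  pass_tumor <- tumor_max > config$theta_tumor
  selected <- pass_germ & pass_normal & pass_tumor

  qualifying <- lapply(genes, function(g) {
    colnames(tm)[tm[g, ] > config$theta_tumor]
  })
  names(qualifying) <- genes

  evidence <- data.frame(
    gene = genes,
    hpgc_stat = unname(hpgc_stat),
    pgclc_stat = unname(pgclc_stat),
    normal_max = unname(normal_max),
    tumor_max = unname(tumor_max),
    n_qualifying_tumor_types = vapply(qualifying, length, integer(1)),
    pass_germline = unname(pass_germ),
    pass_normal = unname(pass_normal),
    pass_tumor = unname(pass_tumor),
    selected = unname(selected),
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(
    list(selected = genes[selected], evidence = evidence,
         qualifying = qualifying, config = config),
    class = "gc_selection"
  )
}

#' @export
print.gc_selection <- function(x, ...) {
  cat(sprintf("<gc_selection> %d of %d universe genes selected\n",
              length(x$selected), nrow(x$evidence)))
  invisible(x)
}

#' @export
summary.gc_selection <- function(object, ...) {
  ev <- object$evidence
  out <- list(
    n_universe = nrow(ev),
    n_selected = length(object$selected),
    frac_pass_germline = mean(ev$pass_germline),
    frac_pass_normal = mean(ev$pass_normal),
    frac_pass_tumor = mean(ev$pass_tumor),
    config = object$config
  )
  class(out) <- "summary.gc_selection"
  out
}

#' @export
print.summary.gc_selection <- function(x, ...) {
  cat(sprintf("GC-gene selection: %d / %d genes\n", x$n_selected, x$n_universe))
  cat(sprintf("  germline criterion passed by %.1f%% of universe\n",
              100 * x$frac_pass_germline))
  cat(sprintf("  somatic-silence criterion passed by %.1f%%\n",
              100 * x$frac_pass_normal))
  cat(sprintf("  tumor-expression criterion passed by %.1f%%\n",
              100 * x$frac_pass_tumor))
  print(x$config)
  invisible(x)
}

#' Three-set Venn partition against prior gene lists
#'
#' Region sizes for all seven regions of the Venn diagram of the newly
#' selected set against prior cancer/testis (CT) and prior adult
#' germline/cancer (GC) lists, plus the split of the selected set into
#' previously known vs new genes.
#'
#' @param selected,prior_ct,prior_gc character vectors of gene symbols
#'   (empty sets allowed).
#' @return a `venn_partition`: named `regions` vector, `n_known`, `n_new`,
#'   and the three input sizes.
#' @export
venn_overlap <- function(selected, prior_ct, prior_gc) {
  selected <- unique(selected); prior_ct <- unique(prior_ct); prior_gc <- unique(prior_gc)
  u <- unique(c(selected, prior_ct, prior_gc))
  a <- u %in% selected; b <- u %in% prior_ct; c_ <- u %in% prior_gc
  regions <- c(
    selected_only = sum(a & !b & !c_),
    ct_only = sum(!a & b & !c_),
    gc_only = sum(!a & !b & c_),
    selected_ct = sum(a & b & !c_),
    selected_gc = sum(a & !b & c_),
    ct_gc = sum(!a & b & c_),
    selected_ct_gc = sum(a & b & c_)
  )
  structure(
    list(
      regions = regions,
      n_known = sum(a & (b | c_)),
      n_new = sum(a & !b & !c_),
      sizes = c(selected = sum(a), prior_ct = sum(b), prior_gc = sum(c_))
    ),
    class = "venn_partition"
  )
}

#' @export
print.venn_partition <- function(x, ...) {
  cat("<venn_partition>\n")
  for (nm in names(x$regions)) cat(sprintf("  %-16s %d\n", nm, x$regions[[nm]]))
  cat(sprintf("  selected & previously known: %d; new: %d\n", x$n_known, x$n_new))
  invisible(x)
}
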