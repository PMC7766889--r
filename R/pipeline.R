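# kinds whose upstream normalization is not length-aware
length_corrected_kinds <- c("hpgc", "pgclc", "soma", "esc")

#' Harmonize a cohort's datasets onto the shared log2 gene universe
#'
#' Applies gene-length correction to the embryonic germ-cell datasets
#' (linear scale, before the log transform), converts every dataset to
#' `log2(x + 1)`, builds the shared gene universe from the required
#' compendia, and subsets all matrices to it in a common row order.
#'
#' @param cohort a `synthetic_cohort` (or any list with `datasets` and
#'   `gene_lengths` of the same shape).
#' @return list `datasets` (log2-scale, universe rows), `universe`.
#' @export
harmonize_cohort <- function(cohort) {
  datasets <- cohort$datasets
  for (nm in names(datasets)) {
    ds <- datasets[[nm]]
    if (ds$scale == "linear" && ds$kind %in% length_corrected_kinds) {
      ds <- apply_length_correction(ds, cohort$gene_lengths)
    }
    datasets[[nm]] <- to_log2(ds)
  }
  universe <- build_universe(datasets)
  for (nm in names(datasets)) {
    datasets[[nm]]$values <-
      datasets[[nm]]$values[universe$included, , drop = FALSE]
  }
  list(datasets = datasets, universe = universe)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop2("pipeline stage '", name, "' failed: ", conditionMessage(e))
  })
}

#' Run the full GC-gene discovery pipeline on a cohort
#'
#' Executes harmonization, the selection cascade, breadth subgroups and the
#' embryonic-specific filter, bi-clustering of the selected-gene by
#' tumor-type matrix, signature scoring of the tumor samples with the
#' selected set, the correlation screen, signature-stratified survival, and
#' protein validation. Each stage is a pure function of its inputs, so the
#' whole run is deterministic for a given cohort; a stage failure aborts
#' with the stage name and cause.
#'
#' @param cohort a [simulate_cohort()] result (or [read_cohort()] output).
#' @param config a [selection_config()].
#' @param k_pan breadth cutoff for the pan-tumor flag.
#' @param tgct_label tumor-type label of the germ-cell tumor.
#' @param adult_floor,gonad_floor floors of the embryonic-specific filter.
#' @param n_gene_clusters,n_tumor_groups bi-clustering cuts.
#' @param survival_method `"median"` or `"scan"` dichotomization.
#' @param r_threshold,p_threshold correlation-screen thresholds.
#' @return a `gc_run`: all stage outputs plus a `report` of headline counts.
#' @export
run_gc_pipeline <- function(cohort,
                            config = selection_config(),
                            k_pan = 17,
                            tgct_label = "TGCT",
                            adult_floor = config$theta_normal,
                            gonad_floor = config$theta_normal,
                            n_gene_clusters = 5,
                            n_tumor_groups = 3,
                            survival_method = c("median", "scan"),
                            r_threshold = 0.5,
                            p_threshold = 0.05) {
  survival_method <- match.arg(survival_method)
  harmonized <- stage("harmonize", harmonize_cohort(cohort))
  ds <- harmonized$datasets

  summaries <- stage("summarize", {
    normal_all <- summarize_groups(ds$normal_compendium, "max")
    list(
      normal = summarize_groups(ds$normal_compendium, "max",
                                exclude_groups = intersect(
                                  config$excluded_normal_groups,
                                  unique(ds$normal_compendium$samples$group))),
      gonad = {
        g <- intersect(c("testis", "ovary"),
                       colnames(normal_all$values))
        normal_all$values[, g, drop = FALSE]
      },
      tumor = summarize_groups(ds$tumor_compendium, "mean"),
      adult_germ = summarize_groups(ds$adult_germ, "max"),
      soma = summarize_groups(ds$soma, "max")
    )
  })

  selection <- stage("select", {
    select_gc_genes(
      hpgc_statistic(ds$hpgc), pgclc_statistic(ds$pgclc),
      summaries$normal, summaries$tumor, config
    )
  })

  breadth <- stage("subgroups", tumor_breadth(selection, k = k_pan,
                                              tgct_label = tgct_label))
  embryonic <- stage("subgroups", embryonic_specific(
    selection, summaries$adult_germ, summaries$gonad, summaries$soma,
    hpgc_statistic(ds$hpgc),
    adult_floor = adult_floor, gonad_floor = gonad_floor
  ))

  clustering <- stage("cluster", {
    if (length(selection$selected) >= max(2, n_gene_clusters)) {
      m <- zscore_rows(summaries$tumor$values[selection$selected, , drop = FALSE])
      bicluster(m, n_gene_clusters, n_tumor_groups)
    } else NULL
  })

  scores <- stage("score", signature_score(ds$tumor_compendium$values,
                                           selection$selected))
  correlation <- stage("score", correlate_with_score(
    ds$tumor_compendium$values, scores,
    r_threshold = r_threshold, p_threshold = p_threshold
  ))

  surv <- stage("survival", {
    if (is.null(cohort$survival)) NULL else {
      st <- cohort$survival[match(scores$sample, cohort$survival$sample), ]
      di <- dichotomize(scores, method = survival_method,
                        time = st$time, event = st$event)
      lr <- logrank_test(st$time, st$event, di$group[st$sample])
      km <- km_estimate(st$time, st$event, di$group[st$sample])
      list(dichotomy = di, logrank = lr, km = km)
    }
  })

  protein <- stage("protein-validate", {
    if (is.null(cohort$protein)) NULL else {
      verdicts <- protein_validate(cohort$protein$hpa_tissue,
                                   cohort$protein$hpa_tumor,
                                   cohort$protein$cptac)
      verdicts[verdicts$gene %in% selection$selected, , drop = FALSE]
    }
  })

  report <- list(
    n_universe = length(harmonized$universe$included),
    n_excluded = nrow(harmonized$universe$excluded),
    n_selected = length(selection$selected),
    breadth_histogram = as.integer(table(factor(
      breadth$breadth, levels = seq_len(ncol(summaries$tumor$values))))),
    n_pan_tumor = sum(breadth$pan_tumor),
    n_single_tumor = sum(breadth$single_tumor),
    n_tgct_only = sum(breadth$tgct_only),
    n_embryonic_specific = length(embryonic),
    gene_cluster_sizes = if (is.null(clustering)) integer(0) else
      as.integer(table(clustering$gene_clusters)),
    tumor_group_sizes = if (is.null(clustering)) integer(0) else
      as.integer(table(clustering$tumor_groups)),
    score_summary = unname(stats::quantile(scores$score)),
    n_correlated_positive = nrow(correlation$positive),
    n_correlated_negative = nrow(correlation$negative),
    survival_p = if (is.null(surv)) NA_real_ else surv$logrank$p_value,
    n_protein_validated = if (is.null(protein)) NA_integer_ else
      sum(protein$validated),
    config = config
  )

  structure(
    list(harmonized = harmonized, summaries = summaries,
         selection = selection, breadth = breadth, embryonic = embryonic,
         clustering = clustering, scores = scores,
         correlation = correlation, survival = surv, protein = protein,
         report = report),
    class = "gc_run"
  )
}

#' @export
print.gc_run <- function(x, ...) {
  r <- x$report
  cat("<gc_run>\n")
  cat(sprintf("  universe: %d genes (%d excluded)\n", r$n_universe, r$n_excluded))
  cat(sprintf("  selected GC genes: %d\n", r$n_selected))
  cat(sprintf("  pan-tumor (breadth >= k): %d; single-tumor: %d; TGCT-only: %d\n",
              r$n_pan_tumor, r$n_single_tumor, r$n_tgct_only))
  cat(sprintf("  embryonic-germline-specific: %d\n", r$n_embryonic_specific))
  if (length(r$gene_cluster_sizes)) {
    cat(sprintf("  gene clusters: %s; tumor groups: %s\n",
                paste(r$gene_cluster_sizes, collapse = "/"),
                paste(r$tumor_group_sizes, collapse = "/")))
  }
  cat(sprintf("  correlated genes: %d positive / %d negative\n",
              r$n_correlated_positive, r$n_correlated_negative))
  if (!is.na(r$survival_p)) {
    cat(sprintf("  survival log-rank p: %.4g\n", r$survival_p))
  }
  if (!is.na(r$n_protein_validated)) {
    cat(sprintf("  protein-validated among selected: %d\n", r$n_protein_validated))
  }
  invisible(x)
}
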