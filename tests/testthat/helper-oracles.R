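# Independent oracles and small fixture builders used across the suite.
# Everything here recomputes quantities by explicit enumeration / loops,
# deliberately avoiding the package's own code paths.

# quick expression_dataset builder: one column per entry of `groups`
make_ds <- function(values, kind, groups, scale = "log2",
                    sex = NULL, stage = NULL) {
  values <- as.matrix(values)
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("%s_s%02d", kind, seq_len(ncol(values)))
  }
  samples <- data.frame(sample_id = colnames(values), group = groups,
                        stringsAsFactors = FALSE)
  if (!is.null(sex)) samples$sex <- sex
  if (!is.null(stage)) samples$stage_weeks <- stage
  expression_dataset(values, scale = scale, samples = samples, kind = kind)
}

# brute-force evaluation of the four selection criteria straight from the
# raw (linear-scale) cohort files, gene by gene
bf_selected <- function(cohort, cfg = cohort$config$selection) {
  len <- stats::setNames(cohort$gene_lengths$length_bp, cohort$gene_lengths$gene)
  l2 <- function(ds, corrected) {
    v <- ds$values
    if (corrected) v <- v / len[rownames(v)] * 1000
    log2(v + 1)
  }
  hv <- l2(cohort$datasets$hpgc, TRUE)
  pv <- l2(cohort$datasets$pgclc, TRUE)
  nv <- l2(cohort$datasets$normal_compendium, FALSE)
  tv <- l2(cohort$datasets$tumor_compendium, FALSE)
  ann <- cohort$datasets$hpgc$samples
  nsam <- cohort$datasets$normal_compendium$samples
  tsam <- cohort$datasets$tumor_compendium$samples
  keep_norm <- nsam$sample_id[!(nsam$group %in% cfg$excluded_normal_groups)]
  type_ids <- split(tsam$sample_id, tsam$group)
  genes <- rownames(hv)
  sel <- logical(length(genes))
  for (i in seq_along(genes)) {
    sexmin <- vapply(c("female", "male"), function(s) {
      ids <- ann$sample_id[ann$sex == s]
      st <- ann$stage_weeks[ann$sex == s]
      min(vapply(unique(st), function(w) mean(hv[i, ids[st == w]]), 0))
    }, 0)
    hstat <- max(sexmin)
    pstat <- mean(pv[i, ])
    nmax <- max(nv[i, keep_norm])
    tpass <- any(vapply(type_ids, function(ids) mean(tv[i, ids]), 0) > cfg$theta_tumor)
    sel[i] <- (hstat > cfg$theta_hpgc || pstat > cfg$theta_pgclc) &&
      nmax < cfg$theta_normal && tpass
  }
  genes[sel]
}

# adjusted Rand index from the contingency table
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  sa <- sum(choose(rowSums(tab), 2))
  sb <- sum(choose(colSums(tab), 2))
  expected <- sa * sb / choose(n, 2)
  (sij - expected) / ((sa + sb) / 2 - expected)
}

# product-limit estimate by explicit risk-set bookkeeping (one group);
# events precede censoring at tied times
naive_km <- function(time, event) {
  ord <- order(time, -event)
  time <- time[ord]; event <- as.integer(event[ord])
  s <- 1
  out <- data.frame(time = numeric(0), n_risk = numeric(0),
                    n_event = numeric(0), survival = numeric(0))
  for (t in unique(time)) {
    at_risk <- sum(time >= t)
    d <- sum(event[time == t])
    if (d > 0) {
      s <- s * (1 - d / at_risk)
      out <- rbind(out, data.frame(time = t, n_risk = at_risk,
                                   n_event = d, survival = s))
    }
  }
  out
}

# mean-percentile signature score by explicit sort-and-average
naive_score <- function(x, geneset) {
  n <- length(x)
  pct <- rank(x, ties.method = "average") / n * 100
  mean(pct[names(x) %in% geneset])
}

# block-structured matrix with known row/column groups
planted_blocks <- function(n_per = 10, p_per = 4, noise = 0, seed = 1) {
  set.seed(seed)
  centers <- matrix(c(5, 0, 0,
                      0, 5, 0,
                      0, 0, 5), 3, 3, byrow = TRUE)
  rows <- rep(1:3, each = n_per)
  cols <- rep(1:3, each = p_per)
  m <- centers[rows, cols] + matrix(rnorm(length(rows) * length(cols), 0, noise),
                                    length(rows), length(cols))
  # small deterministic jitter keeps within-block rows distinct
  m <- m + outer(seq_along(rows), seq_along(cols), function(i, j) (i * 7 + j) %% 5) / 100
  dimnames(m) <- list(sprintf("g%02d", seq_along(rows)),
                      sprintf("t%02d", seq_along(cols)))
  list(m = m, rows = rows, cols = cols)
}

# small default cohort used by several files (shared to amortize cost)
tiny_config <- function(...) {
  simulation_config(n_genes = 300, n_planted_gc = 30,
                    n_planted_embryonic_only = 10, samples_per_group = 2,
                    n_cell_lines = 0, ...)
}
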