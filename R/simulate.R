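#' Default tissue labels for the synthetic normal compendium
#'
#' 54 healthy-tissue labels in the style of the large public normal-tissue
#' compendium, including the gonadal tissues and the two transformed cell
#' lines that the selection cascade excludes from the somatic ceiling.
#' @param n number of labels; the first 54 are named, extras are generic.
#' @export
normal_tissue_names <- function(n = 54) {
  base <- c(
    "adipose_subcutaneous", "adipose_visceral", "adrenal_gland",
    "artery_aorta", "artery_coronary", "artery_tibial", "bladder",
    "brain_amygdala", "brain_anterior_cingulate", "brain_caudate",
    "brain_cerebellar_hemisphere", "brain_cerebellum", "brain_cortex",
    "brain_frontal_cortex", "brain_hippocampus", "brain_hypothalamus",
    "brain_nucleus_accumbens", "brain_putamen", "brain_spinal_cord",
    "brain_substantia_nigra", "breast_mammary",
    "cells_cultured_fibroblasts", "cells_ebv_lymphocytes",
    "cervix_ectocervix", "cervix_endocervix", "colon_sigmoid",
    "colon_transverse", "esophagus_gastroesophageal_junction",
    "esophagus_mucosa", "esophagus_muscularis", "fallopian_tube",
    "heart_atrial_appendage", "heart_left_ventricle", "kidney_cortex",
    "kidney_medulla", "liver", "lung", "minor_salivary_gland",
    "muscle_skeletal", "nerve_tibial", "ovary", "pancreas", "pituitary",
    "prostate", "skin_not_sun_exposed", "skin_sun_exposed",
    "small_intestine", "spleen", "stomach", "testis", "thyroid", "uterus",
    "vagina", "whole_blood"
  )
  if (n <= length(base)) base[seq_len(n)] else {
    c(base, sprintf("tissue_%02d", seq_len(n - length(base))))
  }
}

#' Default tumor-type labels for the synthetic tumor compendium
#'
#' The 33 tumor-type abbreviations of the large public tumor compendium
#' (TGCT = testicular germ cell tumor, the type most directly derived from
#' the germline; LUAD = lung adenocarcinoma, used for survival analysis).
#' @param n number of labels; the first 33 are the standard codes.
#' @export
tumor_type_names <- function(n = 33) {
  base <- c(
    "ACC", "BLCA", "BRCA", "CESC", "CHOL", "COAD", "DLBC", "ESCA", "GBM",
    "HNSC", "KICH", "KIRC", "KIRP", "LAML", "LGG", "LIHC", "LUAD", "LUSC",
    "MESO", "OV", "PAAD", "PCPG", "PRAD", "READ", "SARC", "SKCM", "STAD",
    "TGCT", "THCA", "THYM", "UCEC", "UCS", "UVM"
  )
  if (n <= length(base)) base[seq_len(n)] else {
    c(base, sprintf("TT%02d", seq_len(n - length(base))))
  }
}

#' Configuration of the synthetic cohort generator
#'
#' The defaults state the simulated world: a 2,000-gene universe with 100
#' planted germline/cancer (GC) genes of which 25 are restricted to the
#' embryonic germline, 54 normal tissues and 33 tumor types as in the real
#' compendia, planted genes separated from every selection threshold by
#' 1 log2 unit, and Gaussian noise of 0.25 log2 units on top.
#'
#' @param n_genes size of the gene universe.
#' @param n_planted_gc number of planted GC genes.
#' @param n_planted_embryonic_only planted GC genes additionally silent in
#'   adult germ cells, testis and ovary, with gonadal-soma expression below
#'   their germ-cell expression (subset of the planted GC genes).
#' @param n_normal_tissues,n_tumor_types compendium group counts.
#' @param samples_per_group replicates per tissue/tumor group and per
#'   hPGC sex-stage cell (the PGCLC dataset always has two replicates).
#' @param n_cell_lines size of the optional cell-line panel.
#' @param hpgc_stages developmental stages (weeks) sampled for hPGCs.
#' @param expression_margin log2 separation between planted structure and
#'   every threshold, before noise.
#' @param noise_sd per-sample Gaussian noise, log2 units.
#' @param gene_length_range transcript length interval (bp).
#' @param hazard_ratio hazard ratio between high- and low-signature groups
#'   in the simulated survival table.
#' @param baseline_hazard exponential baseline hazard (default: median
#'   survival of 50 time units in the low group).
#' @param censoring_rate expected fraction of censored samples (uniform,
#'   independent censoring).
#' @param seed integer seed; the cohort is a pure function of it.
#' @param selection the [selection_config()] whose thresholds the planted
#'   structure is built around.
#' @return a `simulation_config` object.
#' @export
simulation_config <- function(n_genes = 2000,
                              n_planted_gc = 100,
                              n_planted_embryonic_only = 25,
                              n_normal_tissues = 54,
                              n_tumor_types = 33,
                              samples_per_group = 4,
                              n_cell_lines = 30,
                              hpgc_stages = c(5.5, 6.5, 7.5, 8.5),
                              expression_margin = 1.0,
                              noise_sd = 0.25,
                              gene_length_range = c(500, 10000),
                              hazard_ratio = 2,
                              baseline_hazard = log(2) / 50,
                              censoring_rate = 0.3,
                              seed = 1,
                              selection = selection_config()) {
  if (n_planted_gc > n_genes) stop2("n_planted_gc must not exceed n_genes")
  if (n_planted_embryonic_only > n_planted_gc) {
    stop2("n_planted_embryonic_only must not exceed n_planted_gc")
  }
  if (noise_sd < 0) stop2("noise_sd must be non-negative")
  if (hazard_ratio <= 0) stop2("hazard_ratio must be positive")
  if (baseline_hazard <= 0) stop2("baseline_hazard must be positive")
  if (censoring_rate < 0 || censoring_rate >= 1) {
    stop2("censoring_rate must be in [0, 1)")
  }
  if (expression_margin <= 0) stop2("expression_margin must be positive")
  if (n_normal_tissues < 3) stop2("need at least 3 normal tissues (incl. testis, ovary)")
  if (n_tumor_types < 2) stop2("need at least 2 tumor types")
  if (samples_per_group < 1) stop2("samples_per_group must be at least 1")
  if (length(hpgc_stages) < 1) stop2("need at least one hPGC stage")
  if (length(gene_length_range) != 2 || gene_length_range[1] <= 0 ||
      diff(gene_length_range) < 0) {
    stop2("gene_length_range must be a positive increasing interval")
  }
  # the planted structure must be representable with non-negative log2 values
  if (selection$theta_normal - expression_margin <= 0) {
    stop2("inconsistent config: theta_normal - expression_margin <= 0, ",
          "planted genes cannot sit below the somatic ceiling by the margin")
  }
  if (selection$theta_tumor - expression_margin < 0) {
    stop2("inconsistent config: theta_tumor - expression_margin < 0, ",
          "background genes cannot sit below the tumor floor by the margin")
  }
  structure(
    list(n_genes = as.integer(n_genes),
         n_planted_gc = as.integer(n_planted_gc),
         n_planted_embryonic_only = as.integer(n_planted_embryonic_only),
         n_normal_tissues = as.integer(n_normal_tissues),
         n_tumor_types = as.integer(n_tumor_types),
         samples_per_group = as.integer(samples_per_group),
         n_cell_lines = as.integer(n_cell_lines),
         hpgc_stages = as.numeric(hpgc_stages),
         expression_margin = as.numeric(expression_margin),
         noise_sd = as.numeric(noise_sd),
         gene_length_range = as.numeric(gene_length_range),
         hazard_ratio = as.numeric(hazard_ratio),
         baseline_hazard = as.numeric(baseline_hazard),
         censoring_rate = as.numeric(censoring_rate),
         seed = as.integer(seed), selection = selection),
    class = "simulation_config"
  )
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf(
    "<simulation_config> %d genes (%d planted GC, %d embryonic-only), %d tissues, %d tumor types, seed %d\n",
    x$n_genes, x$n_planted_gc, x$n_planted_embryonic_only,
    x$n_normal_tissues, x$n_tumor_types, x$seed))
  invisible(x)
}

#' Generate a synthetic cohort with planted ground truth
#'
#' Builds the full set of expression datasets the pipeline ingests, on the
#' linear scale they would arrive in (the germ-cell datasets additionally
#' carry the inverse of the gene-length correction, so harmonization is
#' exercised end to end). Planted GC genes exceed the germline and tumor
#' thresholds by at least `expression_margin` and sit below the somatic
#' ceiling by at least the margin, before noise; background genes violate
#' at least one criterion by the margin, with the failing criterion
#' randomized so each filter is independently exercised. Embryonic-only
#' planted genes are additionally silent in adult germ cells and gonadal
#' tissue and weaker in gonadal soma than in germ cells. Protein evidence
#' (categorical and quantitative) is constructed noise-free and consistent
#' with a planted protein-validation label; a survival table links an
#' exponential proportional-hazards model to the planted-gene signature
#' score. The cohort is a pure function of `config` (including its seed).
#'
#' @param config a [simulation_config()].
#' @return a `synthetic_cohort`: `datasets` (named list of
#'   [expression_dataset()]), `gene_lengths`, `truth`, `protein` (tables +
#'   planted verdicts), `survival`, `config`.
#' @export
simulate_cohort <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(config) {
  sel <- config$selection
  n <- config$n_genes
  m <- config$expression_margin
  spg <- config$samples_per_group
  genes <- sprintf("G%05d", seq_len(n))
  tissues <- normal_tissue_names(config$n_normal_tissues)
  tumors <- tumor_type_names(config$n_tumor_types)

  planted <- sort(sample.int(n, config$n_planted_gc))
  emb_only <- sort(sample(planted, config$n_planted_embryonic_only))
  shared <- setdiff(planted, emb_only)
  label <- rep("background", n)
  label[planted] <- "gc"
  label[emb_only] <- "embryonic_only"
  truth <- data.frame(gene = genes, label = label, stringsAsFactors = FALSE)

  lengths_bp <- round(stats::runif(n, config$gene_length_range[1],
                                   config$gene_length_range[2]))
  gene_lengths <- data.frame(gene = genes, length_bp = lengths_bp,
                             stringsAsFactors = FALSE)

  is_bg <- label == "background"
  n_bg <- sum(is_bg)
  # which criteria each background gene fails (at least one)
  fails <- matrix(stats::runif(n_bg * 3) < 0.45, n_bg, 3,
                  dimnames = list(NULL, c("germ", "normal", "tumor")))
  none <- rowSums(fails) == 0
  if (any(none)) fails[cbind(which(none), sample.int(3, sum(none), TRUE))] <- TRUE

  uplift <- stats::runif(n, 0, 1)  # per-gene headroom above thresholds

  # ---- germline datasets (per-gene flat level across cells) ----
  lvl_hpgc <- lvl_pgclc <- numeric(n)
  lvl_hpgc[planted] <- sel$theta_hpgc + m + uplift[planted]
  lvl_pgclc[planted] <- sel$theta_pgclc + m + uplift[planted]
  bg_idx <- which(is_bg)
  germ_fail <- bg_idx[fails[, "germ"]]
  germ_pass <- setdiff(bg_idx, germ_fail)
  lvl_hpgc[germ_pass] <- sel$theta_hpgc + m + stats::runif(length(germ_pass), 0, 1.5)
  lvl_pgclc[germ_pass] <- sel$theta_pgclc + m + stats::runif(length(germ_pass), 0, 1.5)
  lvl_hpgc[germ_fail] <- stats::runif(length(germ_fail), 0, max(0, sel$theta_hpgc - m))
  lvl_pgclc[germ_fail] <- stats::runif(length(germ_fail), 0, max(0, sel$theta_pgclc - m))

  # ---- normal compendium: per-gene x tissue means ----
  cap_n <- sel$theta_normal - m
  M_norm <- matrix(stats::runif(n * length(tissues), 0, cap_n),
                   n, length(tissues), dimnames = list(genes, tissues))
  gonad <- intersect(c("testis", "ovary"), tissues)
  M_norm[shared, gonad] <- 5 + stats::runif(length(shared) * length(gonad), 0, 2)
  norm_fail <- bg_idx[fails[, "normal"]]
  eligible <- setdiff(seq_along(tissues),
                      which(tissues %in% sel$excluded_normal_groups))
  for (g in norm_fail) {
    hot <- sample(eligible, size = sample.int(max(1, length(eligible) %/% 4), 1))
    M_norm[g, hot] <- sel$theta_normal + m + stats::runif(length(hot), 0, 2)
  }

  # ---- tumor compendium: per-gene x type means ----
  off_cap <- max(0, sel$theta_tumor - m)
  M_tum <- matrix(stats::runif(n * length(tumors), 0, off_cap),
                  n, length(tumors), dimnames = list(genes, tumors))
  tgct <- if ("TGCT" %in% tumors) "TGCT" else tumors[length(tumors)]
  breadth_of <- function(k) {
    u <- stats::runif(k)
    b <- integer(k)
    pan_lo <- min(max(2, ceiling(length(tumors) / 2)), length(tumors))
    b[u < 0.3] <- sample(seq(pan_lo, length(tumors)), sum(u < 0.3), TRUE)
    b[u >= 0.3 & u < 0.6] <- 1L
    mid <- which(u >= 0.6)
    if (length(mid)) b[mid] <- sample(seq(2, max(2, pan_lo - 1)), length(mid), TRUE)
    b
  }
  expressed_in <- vector("list", n)
  pb <- breadth_of(length(planted))
  for (i in seq_along(planted)) {
    g <- planted[i]
    q <- if (pb[i] == 1 && stats::runif(1) < 0.5) tgct else
      sample(tumors, pb[i])
    expressed_in[[g]] <- q
  }
  tum_fail <- bg_idx[fails[, "tumor"]]
  tum_pass <- setdiff(bg_idx, tum_fail)
  for (g in tum_pass) expressed_in[[g]] <- sample(tumors, sample.int(length(tumors), 1))
  for (g in c(planted, tum_pass)) {
    q <- expressed_in[[g]]
    M_tum[g, q] <- sel$theta_tumor + m + stats::runif(length(q), 0, 2)
  }

  # ---- small germline-context datasets ----
  lvl_adult <- stats::runif(n, 0, 5)
  lvl_adult[shared] <- 5 + stats::runif(length(shared), 0, 2)
  lvl_adult[emb_only] <- stats::runif(length(emb_only), 0, sel$theta_normal - m)
  lvl_soma <- stats::runif(n, 0, 4)
  lvl_soma[emb_only] <- pmax(0, lvl_hpgc[emb_only] - m -
                               stats::runif(length(emb_only), 0, 0.3))
  lvl_esc <- stats::runif(n, 0, 6)
  lvl_esc[planted] <- stats::runif(length(planted), 2, 6)

  # ---- assemble expression datasets (noise, back-transform to linear) ----
  noise <- function(nr, nc) {
    if (config$noise_sd == 0) 0 else
      matrix(stats::rnorm(nr * nc, 0, config$noise_sd), nr, nc)
  }
  materialize <- function(log2_means, samples, kind, length_corrected) {
    v <- pmax(log2_means + noise(nrow(log2_means), ncol(log2_means)), 0)
    lin <- 2^v - 1
    if (length_corrected) lin <- lin * lengths_bp / 1000
    rownames(lin) <- genes
    expression_dataset(lin, scale = "linear", samples = samples, kind = kind)
  }
  expand <- function(level_or_matrix, reps) {
    mm <- if (is.matrix(level_or_matrix)) level_or_matrix else
      matrix(level_or_matrix, n, 1)
    mm[, rep(seq_len(ncol(mm)), each = reps), drop = FALSE]
  }

  # hPGC: sex x stage x replicate
  hp_grid <- expand.grid(rep = seq_len(spg), stage = config$hpgc_stages,
                         sex = c("female", "male"), stringsAsFactors = FALSE)
  hp_samples <- data.frame(
    sample_id = sprintf("hpgc_%s_w%s_r%d", substr(hp_grid$sex, 1, 1),
                        hp_grid$stage, hp_grid$rep),
    group = "hpgc", sex = hp_grid$sex, stage_weeks = hp_grid$stage,
    stringsAsFactors = FALSE
  )
  hp_m <- matrix(lvl_hpgc, n, nrow(hp_samples),
                 dimnames = list(genes, hp_samples$sample_id))
  datasets <- list()
  datasets$hpgc <- materialize(hp_m, hp_samples, "hpgc", TRUE)

  pg_samples <- data.frame(sample_id = c("pgclc_r1", "pgclc_r2"),
                           group = "pgclc", stringsAsFactors = FALSE)
  pg_m <- matrix(lvl_pgclc, n, 2, dimnames = list(genes, pg_samples$sample_id))
  datasets$pgclc <- materialize(pg_m, pg_samples, "pgclc", TRUE)

  esc_samples <- data.frame(sample_id = sprintf("esc_r%d", seq_len(spg)),
                            group = "esc", stringsAsFactors = FALSE)
  datasets$esc <- materialize(
    matrix(lvl_esc, n, spg, dimnames = list(genes, esc_samples$sample_id)),
    esc_samples, "esc", TRUE)

  soma_samples <- data.frame(sample_id = sprintf("soma_r%d", seq_len(spg)),
                             group = "gonadal_soma", stringsAsFactors = FALSE)
  datasets$soma <- materialize(
    matrix(lvl_soma, n, spg, dimnames = list(genes, soma_samples$sample_id)),
    soma_samples, "soma", TRUE)

  ag_samples <- data.frame(sample_id = sprintf("adult_germ_r%d", seq_len(spg)),
                           group = "adult_germ", stringsAsFactors = FALSE)
  datasets$adult_germ <- materialize(
    matrix(lvl_adult, n, spg, dimnames = list(genes, ag_samples$sample_id)),
    ag_samples, "adult_germ", FALSE)

  nc_samples <- data.frame(
    sample_id = sprintf("%s_s%d", rep(tissues, each = spg), seq_len(spg)),
    group = rep(tissues, each = spg), stringsAsFactors = FALSE
  )
  nc_m <- expand(M_norm, spg)
  colnames(nc_m) <- nc_samples$sample_id
  datasets$normal_compendium <- materialize(nc_m, nc_samples,
                                            "normal_compendium", FALSE)

  tc_samples <- data.frame(
    sample_id = sprintf("%s_s%d", rep(tumors, each = spg), seq_len(spg)),
    group = rep(tumors, each = spg), stringsAsFactors = FALSE
  )
  tc_m <- expand(M_tum, spg)
  colnames(tc_m) <- tc_samples$sample_id
  datasets$tumor_compendium <- materialize(tc_m, tc_samples,
                                           "tumor_compendium", FALSE)

  if (config$n_cell_lines > 0) {
    resemblance <- stats::runif(config$n_cell_lines)
    cl_samples <- data.frame(
      sample_id = sprintf("CL%03d", seq_len(config$n_cell_lines)),
      group = sprintf("CL%03d", seq_len(config$n_cell_lines)),
      stringsAsFactors = FALSE
    )
    cl_m <- matrix(stats::runif(n * config$n_cell_lines, 0, 5),
                   n, config$n_cell_lines,
                   dimnames = list(genes, cl_samples$sample_id))
    cl_m[planted, ] <- rep(1 + 5 * resemblance, each = length(planted))
    datasets$cell_lines <- materialize(cl_m, cl_samples, "cell_lines", FALSE)
  }

  # ---- protein evidence, noise-free and consistent with planted labels ----
  protein <- simulate_protein_evidence(genes, planted, tumors, config)

  # ---- survival linked to the planted-gene signature ----
  tum_log2 <- log2(datasets$tumor_compendium$values + 1)
  scores <- signature_score(tum_log2, genes[planted])
  survival <- simulate_survival(
    scores, hazard_ratio = config$hazard_ratio,
    baseline_hazard = config$baseline_hazard,
    censoring_rate = config$censoring_rate, seed = NULL
  )

  structure(
    list(datasets = datasets, gene_lengths = gene_lengths, truth = truth,
         protein = protein, survival = survival, config = config),
    class = "synthetic_cohort"
  )
}

# categorical + quantitative protein tables with a planted verdict per
# covered gene; construction is noise-free so the verdict is exact
simulate_protein_evidence <- function(genes, planted, tumors, config) {
  somatic <- c("cerebral_cortex", "liver", "lung", "colon", "kidney",
               "heart_muscle", "skin", "pancreas", "spleen", "prostate",
               "breast", "adipose_tissue")
  exempt <- c("seminiferous_tubules", "ovary")
  hpa_tumors <- tumors[seq_len(min(20, length(tumors)))]
  cptac_sets <- c("LUAD", "COAD", "UCEC")
  levels_all <- c("not_detected", "low", "medium", "high")

  n <- length(genes)
  bg <- setdiff(seq_len(n), planted)
  covered_bg <- bg[stats::runif(length(bg)) < 0.1]
  covered <- c(planted, covered_bg)

  tissue_rows <- list(); tumor_rows <- list(); cptac_rows <- list()
  truth_rows <- list()

  for (g in covered) {
    gene <- genes[g]
    is_planted <- g %in% planted
    has_hpa <- stats::runif(1) < 0.7
    has_cptac <- stats::runif(1) < 0.6
    if (!has_hpa && !has_cptac) {
      if (stats::runif(1) < 0.5) has_hpa <- TRUE else has_cptac <- TRUE
    }
    want_valid <- is_planted && stats::runif(1) < 0.5
    route <- if (!want_valid) "none" else if (has_hpa && has_cptac) {
      sample(c("hpa", "cptac", "both"), 1)
    } else if (has_hpa) "hpa" else "cptac"

    if (has_hpa) {
      hpa_ok <- route %in% c("hpa", "both")
      if (hpa_ok) {
        lev <- stats::setNames(rep("not_detected", length(somatic)), somatic)
        pos_tumor <- sample(hpa_tumors, 1)
      } else {
        mode <- sample(c("somatic", "tumor", "both_fail"), 1)
        lev <- stats::setNames(rep("not_detected", length(somatic)), somatic)
        if (mode != "tumor") {
          hit <- sample(somatic, sample.int(3, 1))
          lev[hit] <- sample(c("low", "medium", "high"), length(hit), TRUE)
        }
        pos_tumor <- NA_character_
      }
      lev_exempt <- stats::setNames(sample(levels_all, length(exempt), TRUE), exempt)
      tissue_rows[[length(tissue_rows) + 1]] <- data.frame(
        gene = gene, tissue = c(somatic, exempt),
        level = c(unname(lev), unname(lev_exempt)), stringsAsFactors = FALSE
      )
      n_inv <- sample(3:12, length(hpa_tumors), replace = TRUE)
      n_det <- integer(length(hpa_tumors))
      for (j in seq_along(hpa_tumors)) {
        tt <- hpa_tumors[j]
        if (!is.na(pos_tumor) && tt == pos_tumor) {
          n_det[j] <- sample(ceiling(n_inv[j] / 2):n_inv[j], 1)
        } else if (hpa_ok) {
          n_det[j] <- sample(0:n_inv[j], 1)  # extra positives allowed
        } else {
          n_det[j] <- sample(0:floor((n_inv[j] - 1) / 2), 1)  # all < 50%
        }
      }
      tumor_rows[[length(tumor_rows) + 1]] <- data.frame(
        gene = gene, tumor_type = hpa_tumors,
        n_detected = n_det, n_investigated = n_inv, stringsAsFactors = FALSE
      )
    } else hpa_ok <- FALSE

    if (has_cptac) {
      cptac_ok <- route %in% c("cptac", "both")
      present <- cptac_sets[stats::runif(3) < 0.8]
      if (length(present) == 0) present <- sample(cptac_sets, 1)
      pos_sets <- if (cptac_ok) {
        present[c(TRUE, stats::runif(length(present) - 1) < 0.4)]
      } else character(0)
      for (ds in present) {
        nt <- 8; nn <- 8
        tu <- stats::rnorm(nt, 10, 1); no <- stats::rnorm(nn, 10, 1)
        if (ds %in% pos_sets) {
          tu <- tu - stats::median(tu) + stats::median(no) + 1
        } else if (stats::runif(1) < 0.5) {
          tu <- tu - stats::median(tu) + stats::median(no) - 1
        } else {
          tu <- sample(no)  # identical multiset: medians exactly equal
        }
        cptac_rows[[length(cptac_rows) + 1]] <- data.frame(
          gene = gene, dataset = ds,
          sample = c(sprintf("%s_T%02d", ds, seq_len(nt)),
                     sprintf("%s_N%02d", ds, seq_len(nn))),
          abundance = c(tu, no),
          tissue_class = rep(c("tumor", "normal"), c(nt, nn)),
          stringsAsFactors = FALSE
        )
      }
    } else cptac_ok <- FALSE

    basis <- c(if (hpa_ok) "hpa", if (cptac_ok) "cptac")
    truth_rows[[length(truth_rows) + 1]] <- data.frame(
      gene = gene, hpa_available = has_hpa, cptac_available = has_cptac,
      validated = hpa_ok || cptac_ok,
      basis = if (length(basis)) paste(basis, collapse = "+") else "none",
      stringsAsFactors = FALSE
    )
  }
  list(
    hpa_tissue = do.call(rbind, tissue_rows),
    hpa_tumor = do.call(rbind, tumor_rows),
    cptac = do.call(rbind, cptac_rows),
    truth = do.call(rbind, truth_rows)
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "<synthetic_cohort> %d genes (%d planted GC, %d embryonic-only), %d datasets, seed %d\n",
    x$config$n_genes, x$config$n_planted_gc,
    x$config$n_planted_embryonic_only, length(x$datasets), x$config$seed))
  invisible(x)
}

#' Simulate survival times linked to a signature score
#'
#' Exponential proportional-hazards model: samples with a score above the
#' median have hazard `hazard_ratio` times the baseline. Censoring is
#' independent uniform on `[0, cmax]`, with `cmax` solved so the expected
#' censoring fraction equals `censoring_rate`.
#'
#' @param scores named numeric vector of per-sample scores, or a
#'   [signature_score()] data.frame.
#' @param hazard_ratio hazard ratio of the high-score group (> 0).
#' @param baseline_hazard exponential hazard of the low-score group.
#' @param censoring_rate expected censored fraction in `[0, 1)`.
#' @param seed optional integer seed (RNG state is restored afterwards).
#' @return data.frame `sample`, `time`, `event` (1 = death observed),
#'   `group` (`"high"`/`"low"`).
#' @export
simulate_survival <- function(scores, hazard_ratio = 2,
                              baseline_hazard = log(2) / 50,
                              censoring_rate = 0.3, seed = NULL) {
  scores <- as_score_vector(scores)
  if (length(scores) == 0 || all(is.na(scores))) {
    stop2("empty score list: no samples to simulate survival for")
  }
  if (hazard_ratio <= 0) stop2("hazard_ratio must be positive")
  if (censoring_rate < 0 || censoring_rate >= 1) {
    stop2("censoring_rate must be in [0, 1)")
  }
  run <- function() {
    high <- scores > stats::median(scores)
    lambda <- ifelse(high, hazard_ratio * baseline_hazard, baseline_hazard)
    t_event <- stats::rexp(length(scores), rate = lambda)
    if (censoring_rate > 0) {
      p_cens <- function(cmax) {
        mean((1 - exp(-lambda * cmax)) / (lambda * cmax)) - censoring_rate
      }
      cmax <- stats::uniroot(p_cens, lower = 1e-9 / baseline_hazard,
                             upper = 1e6 / baseline_hazard)$root
      t_cens <- stats::runif(length(scores), 0, cmax)
    } else {
      t_cens <- rep(Inf, length(scores))
    }
    data.frame(
      sample = names(scores),
      time = pmin(t_event, t_cens),
      event = as.integer(t_event <= t_cens),
      group = ifelse(high, "high", "low"),
      stringsAsFactors = FALSE
    )
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}
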