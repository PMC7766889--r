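# helper: hPGC dataset from a sex x stage table of per-cell means
hpgc_from_table <- function(values_by_cell, reps = 1, noise = 0) {
  cells <- expand.grid(rep = seq_len(reps),
                       stage = unique(values_by_cell$stage),
                       sex = c("female", "male"), stringsAsFactors = FALSE)
  ids <- sprintf("h_%s_%s_%d", cells$sex, cells$stage, cells$rep)
  genes <- unique(values_by_cell$gene)
  m <- matrix(0, length(genes), nrow(cells), dimnames = list(genes, ids))
  for (k in seq_len(nrow(cells))) {
    v <- values_by_cell$value[values_by_cell$sex == cells$sex[k] &
                                values_by_cell$stage == cells$stage[k]]
    m[, k] <- v + if (noise > 0) rnorm(length(v), 0, noise) else 0
  }
  make_ds(m, "hpgc", groups = "hpgc", sex = cells$sex, stage = cells$stage)
}

test_that("hPGC statistic is max over sexes of the min over stage means", {
  tab <- expand.grid(gene = "g1", stage = 1:3, sex = c("female", "male"),
                     stringsAsFactors = FALSE)
  tab$value <- c(1, 2, 3, 0.5, 4, 4)   # female min 1, male min 0.5
  expect_equal(unname(hpgc_statistic(hpgc_from_table(tab))["g1"]), 1)

  # single stage, both sexes: the statistic is the larger measurement
  tab1 <- data.frame(gene = "g1", stage = 5.5, sex = c("female", "male"),
                     value = c(2.2, 1.1))
  expect_equal(unname(hpgc_statistic(hpgc_from_table(tab1))["g1"]), 2.2)

  # replicates of a stage are averaged before the minimum
  tab2 <- expand.grid(gene = "g1", stage = 1:2, sex = c("female", "male"),
                      stringsAsFactors = FALSE)
  tab2$value <- c(3, 1, 0, 0)
  ds2 <- hpgc_from_table(tab2, reps = 3, noise = 0)
  expect_equal(unname(hpgc_statistic(ds2)["g1"]), 1)

  # missing sex / unknown label are errors
  bad <- hpgc_from_table(tab1)
  bad$samples$sex <- "female"
  expect_error(hpgc_statistic(bad), "no samples for sex")
  bad$samples$sex <- c("female", "unknown")
  expect_error(hpgc_statistic(bad), "unknown sex")
})

test_that("hPGC statistic equals exhaustive enumeration on random tables", {
  set.seed(21)
  for (rep in 1:5) {
    genes <- sprintf("g%02d", 1:12)
    tab <- expand.grid(gene = genes, stage = c(5.5, 7, 8.5),
                       sex = c("female", "male"), stringsAsFactors = FALSE)
    tab$value <- runif(nrow(tab), 0, 5)
    ds <- hpgc_from_table(tab)
    got <- hpgc_statistic(ds)
    for (g in genes) {
      want <- max(vapply(c("female", "male"), function(s) {
        min(tab$value[tab$gene == g & tab$sex == s])
      }, 0))
      expect_equal(unname(got[g]), want)
    }
  }
})

test_that("PGCLC statistic is the plain mean across replicates", {
  m <- matrix(c(1, 2), 1, 2, dimnames = list("g1", c("r1", "r2")))
  ds <- make_ds(m, "pgclc", groups = c("pgclc", "pgclc"))
  expect_equal(unname(pgclc_statistic(ds)["g1"]), 1.5)
  one <- make_ds(m[, 1, drop = FALSE], "pgclc", groups = "pgclc")
  expect_equal(unname(pgclc_statistic(one)["g1"]), 1)
  set.seed(5)
  m5 <- matrix(runif(3 * 5), 3, 5, dimnames = list(paste0("g", 1:3), paste0("r", 1:5)))
  ds5 <- make_ds(m5, "pgclc", groups = rep("pgclc", 5))
  expect_equal(unname(pgclc_statistic(ds5)), unname(apply(m5, 1, sum) / 5))
})

test_that("selection cascade applies strict inequalities at the default thresholds", {
  genes <- c("gPass", "gBoundary", "gNoTumor")
  hs <- setNames(c(0.73, 0.73, 0.73), genes)
  ps <- setNames(c(0, 0, 0), genes)
  nm <- matrix(c(2.9, 3.0, 1.0), 3, 1, dimnames = list(genes, "liver"))
  tm <- matrix(c(2.4, 2.4, 2.3), 3, 1, dimnames = list(genes, "LUAD"))
  res <- select_gc_genes(hs, ps, nm, tm, selection_config())
  expect_identical(res$selected, "gPass")
  ev <- res$evidence
  expect_false(ev$selected[ev$gene == "gBoundary"])   # normal_max == 3.0
  expect_false(ev$selected[ev$gene == "gNoTumor"])    # tumor_max == 2.3
  expect_equal(res$qualifying$gPass, "LUAD")
  # universe mismatch is an error
  expect_error(select_gc_genes(hs[-1], ps, nm, tm), "universe mismatch")
})

test_that("selection equals an independent per-gene re-evaluation", {
  set.seed(31)
  n <- 200
  genes <- sprintf("g%03d", 1:n)
  hs <- setNames(runif(n, 0, 2), genes)
  ps <- setNames(runif(n, 0, 2), genes)
  nm <- matrix(runif(n * 6, 0, 5), n, 6,
               dimnames = list(genes, paste0("tis", 1:6)))
  tm <- matrix(runif(n * 5, 0, 5), n, 5,
               dimnames = list(genes, paste0("tum", 1:5)))
  cfg <- selection_config()
  res <- select_gc_genes(hs, ps, nm, tm, cfg)
  want <- genes[vapply(genes, function(g) {
    (hs[g] > cfg$theta_hpgc || ps[g] > cfg$theta_pgclc) &&
      max(nm[g, ]) < cfg$theta_normal && max(tm[g, ]) > cfg$theta_tumor
  }, logical(1))]
  expect_setequal(res$selected, want)
  # evidence records reproduce the verdict
  ev <- res$evidence
  redo <- (ev$hpgc_stat > cfg$theta_hpgc | ev$pgclc_stat > cfg$theta_pgclc) &
    ev$normal_max < cfg$theta_normal & ev$tumor_max > cfg$theta_tumor
  expect_identical(redo, ev$selected)
})

test_that("selection is monotone in the somatic and tumor thresholds", {
  set.seed(41)
  n <- 150
  genes <- sprintf("g%03d", 1:n)
  hs <- setNames(runif(n, 0, 2), genes)
  ps <- setNames(runif(n, 0, 2), genes)
  nm <- matrix(runif(n * 4, 0, 5), n, 4, dimnames = list(genes, paste0("t", 1:4)))
  tm <- matrix(runif(n * 4, 0, 5), n, 4, dimnames = list(genes, paste0("u", 1:4)))
  sizes_n <- sapply(seq(1, 5, length.out = 5), function(th) {
    length(select_gc_genes(hs, ps, nm, tm,
                           selection_config(theta_normal = th))$selected)
  })
  expect_true(all(diff(sizes_n) >= 0))       # weaker somatic filter never shrinks
  sizes_t <- sapply(seq(0.5, 4.5, length.out = 5), function(th) {
    length(select_gc_genes(hs, ps, nm, tm,
                           selection_config(theta_tumor = th))$selected)
  })
  expect_true(all(diff(sizes_t) <= 0))       # higher tumor bar never grows
  sizes_g <- sapply(seq(0.1, 1.9, length.out = 5), function(th) {
    length(select_gc_genes(hs, ps, nm, tm,
                           selection_config(theta_hpgc = th,
                                            theta_pgclc = th))$selected)
  })
  expect_true(all(diff(sizes_g) <= 0))       # higher germline bar never grows
})

test_that("Venn partition sizes come from exact set algebra", {
  v <- venn_overlap(c("a", "b"), c("c", "d", "e"), c("f", "g", "h", "i"))
  expect_equal(unname(v$regions[c("selected_only", "ct_only", "gc_only")]),
               c(2, 3, 4))
  expect_equal(sum(v$regions[4:7]), 0)
  sub <- venn_overlap(c("a", "b"), character(0), c("a", "b", "c"))
  expect_equal(unname(sub$regions["selected_only"]), 0)   # fully known
  expect_equal(sub$n_new, 0)
  expect_equal(sub$n_known, 2)
})
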