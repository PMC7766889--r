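test_that("categorical validation applies the somatic-silence and 50% tumor rules", {
  tissues <- setNames(rep("not_detected", 5),
                      c("liver", "lung", "colon", "seminiferous_tubules", "ovary"))
  tumors <- data.frame(tumor_type = "LUAD", n_detected = 6, n_investigated = 12)
  v <- hpa_validate(tissues, tumors)
  expect_true(v$somatic_clear)
  expect_true(v$tumor_positive)          # 6/12 = 50% is inclusive
  # detection in one non-exempt tissue breaks somatic silence
  t2 <- tissues; t2["lung"] <- "low"
  expect_false(hpa_validate(t2, tumors)$somatic_clear)
  # detection only in exempt gonadal tissue does not
  t3 <- tissues; t3["seminiferous_tubules"] <- "high"; t3["ovary"] <- "medium"
  expect_true(hpa_validate(t3, tumors)$somatic_clear)
  # 5/12 is below half
  v5 <- hpa_validate(tissues, data.frame(tumor_type = "LUAD",
                                         n_detected = 5, n_investigated = 12))
  expect_false(v5$tumor_positive)
  expect_error(hpa_validate(c(liver = "weak")), "unknown detection category")
  expect_error(hpa_validate(tissues, data.frame(tumor_type = "X",
                                                n_detected = 13,
                                                n_investigated = 12)),
               "exceeds")
})

test_that("growing the exempt list never breaks somatic clearance", {
  set.seed(4)
  all_t <- c("liver", "lung", "colon", "kidney", "skin")
  for (i in 1:20) {
    # mostly-clear profiles so both branches of the implication occur
    lev <- setNames(sample(c(rep("not_detected", 6), "low", "medium", "high"),
                           5, TRUE), all_t)
    base <- hpa_validate(lev, exempt_tissues = character(0))$somatic_clear
    wider <- hpa_validate(lev, exempt_tissues = sample(all_t, 2))$somatic_clear
    expect_true(!base || wider)   # adding exempt tissues never flips TRUE -> FALSE
  }
})

test_that("quantitative validation requires the tumor median to strictly exceed normal", {
  rec <- function(tu, no, ds = "LUAD") {
    data.frame(dataset = ds, tissue_class = rep(c("tumor", "normal"),
                                                c(length(tu), length(no))),
               abundance = c(tu, no))
  }
  expect_equal(cptac_validate(rec(c(2, 2, 3), c(1, 1, 2))), "LUAD")
  expect_equal(cptac_validate(rec(c(1, 2, 3), c(3, 2, 1))), character(0)) # equal
  expect_warning(out <- cptac_validate(rec(numeric(0), c(1, 2))), "skipped")
  expect_equal(out, character(0))
  # verdict matches an independent sort-based median on random lists
  set.seed(14)
  for (i in 1:20) {
    tu <- runif(20); no <- runif(20)
    med <- function(x) { s <- sort(x); (s[10] + s[11]) / 2 }
    want <- if (med(tu) > med(no)) "D" else character(0)
    expect_equal(cptac_validate(rec(tu, no, "D")), want)
  }
})

test_that("combined verdicts honor either route and reordering of evidence", {
  hpa_tissue <- data.frame(
    gene = rep(c("gHpa", "gCptac", "gNeither"), each = 2),
    tissue = rep(c("liver", "lung"), 3),
    level = c("not_detected", "not_detected",   # gHpa: clear
              "low", "not_detected",            # gCptac: somatic fails
              "medium", "high"),                # gNeither
    stringsAsFactors = FALSE
  )
  hpa_tumor <- data.frame(
    gene = c("gHpa", "gCptac", "gNeither"),
    tumor_type = "LUAD", n_detected = c(7, 2, 1), n_investigated = 12
  )
  cptac <- rbind(
    data.frame(gene = "gCptac", dataset = "UCEC", sample = paste0("t", 1:4),
               abundance = c(5, 6, 2, 2.5),
               tissue_class = c("tumor", "tumor", "normal", "normal")),
    data.frame(gene = "gNeither", dataset = "UCEC", sample = paste0("u", 1:4),
               abundance = c(2, 2.5, 5, 6),
               tissue_class = c("tumor", "tumor", "normal", "normal"))
  )
  v <- protein_validate(hpa_tissue, hpa_tumor, cptac)
  rownames(v) <- v$gene
  expect_true(v["gHpa", "validated"]);    expect_equal(v["gHpa", "basis"], "hpa")
  expect_true(v["gCptac", "validated"]);  expect_equal(v["gCptac", "basis"], "cptac")
  expect_false(v["gNeither", "validated"])
  # gHpa has no quantitative data: evaluated on the categorical side only
  expect_equal(v["gHpa", "cptac_positive_datasets"], "")
  # shuffling evidence rows changes nothing
  set.seed(8)
  v2 <- protein_validate(hpa_tissue[sample(nrow(hpa_tissue)), ],
                         hpa_tumor[sample(nrow(hpa_tumor)), ],
                         cptac[sample(nrow(cptac)), ])
  v2 <- v2[match(v$gene, v2$gene), ]
  expect_equal(v2$validated, v$validated)
  expect_equal(v2$basis, v$basis)
})
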