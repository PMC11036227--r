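test_that("qualifying allele counting follows P/LP-only, hom-counts-twice rules", {
  hom_lp <- data.frame(gene = "MMAA", variant_id = "c.365T>C",
                       acmg_class = "LP", zygosity = "hom")
  expect_identical(qualifying_allele_count(hom_lp), 2L)

  lp_plus_vus <- data.frame(gene = "ACADS",
                            variant_id = c("c.322G>A", "c.779G>T"),
                            acmg_class = c("LP", "VUS"),
                            zygosity = c("het", "het"))
  expect_identical(qualifying_allele_count(lp_plus_vus), 1L)

  expect_identical(qualifying_allele_count(lp_plus_vus[0, ]), 0L)

  mixed <- data.frame(gene = c("A", "B"), variant_id = c("v1", "v2"),
                      acmg_class = "P", zygosity = "het")
  expect_error(qualifying_allele_count(mixed), class = "nbs_contract_error")

  dup <- data.frame(gene = "A", variant_id = c("v1", "v1"),
                    acmg_class = "P", zygosity = "het")
  expect_error(qualifying_allele_count(dup), class = "nbs_validation_error")
})

test_that("single-subject classification handles VUS, off-panel and inheritance rules", {
  panel <- default_panel()
  # P het + VUS het in an AR gene is not biallelic
  p18 <- data.frame(gene = "DBT",
                    variant_id = c("c.75_76delAT", "c.1359_1360delAG"),
                    acmg_class = c("P", "VUS"), zygosity = "het")
  expect_identical(classify_genetic(p18, "M", panel)$call, "negative")

  # two P hets in an off-panel gene never trigger
  p23 <- data.frame(gene = "ETFA", variant_id = c("c.369G>A", "c.659delC"),
                    acmg_class = "P", zygosity = "het")
  expect_identical(classify_genetic(p23, "M", panel)$call, "negative")

  # homozygous P is positive with two qualifying alleles
  p6 <- data.frame(gene = "MMACHC", variant_id = "c.658_660delAAG",
                   acmg_class = "P", zygosity = "hom")
  res <- classify_genetic(p6, "M", panel)
  expect_identical(res$call, "positive")
  expect_identical(res$triggering_gene, "MMACHC")
  expect_identical(res$qualifying_alleles, 2L)

  # variant-free record
  expect_identical(classify_genetic(p6[0, ], "F", panel)$call, "negative")
})

test_that("X-linked rules: male single-allele positivity, female homozygote requirement", {
  panel <- test_panel()
  hemi <- data.frame(gene = "XLG1", variant_id = "v1", acmg_class = "P",
                     zygosity = "hemi")
  expect_identical(classify_genetic(hemi, "M", panel)$call, "positive")
  expect_error(classify_genetic(hemi, "F", panel),
               class = "nbs_validation_error")

  het <- data.frame(gene = "XLG1", variant_id = "v1", acmg_class = "LP",
                    zygosity = "het")
  expect_identical(classify_genetic(het, "M", panel)$call, "positive")
  expect_identical(classify_genetic(het, "F", panel)$call, "negative")
  hom <- data.frame(gene = "XLG1", variant_id = "v1", acmg_class = "LP",
                    zygosity = "hom")
  expect_identical(classify_genetic(hom, "F", panel)$call, "positive")

  # policy override: carrier females reportable if a program opts in
  panel_override <- as_nbs_panel(as.data.frame(panel),
                                 xl_female_het_positive = TRUE)
  expect_identical(classify_genetic(het, "F", panel_override)$call,
                   "positive")
})

test_that("cohort classification reproduces the 23 diagnosed subjects' calls", {
  t3 <- fixture_table3()
  res <- classify_cohort_genetic(t3$variants, default_panel(),
                                 t3$subjects[, c("subject_id", "sex")])
  expect_identical(attr(res, "n_positive"), 17L)
  expect_identical(res$call, t3$subjects$ngs_call)
  # positives are exactly P1-P17
  expect_identical(res$subject_id[res$call == "positive"], paste0("P", 1:17))
})

test_that("cohort classification validates ids and handles empty cohorts", {
  dup <- data.frame(subject_id = c("a", "a"), sex = "M")
  expect_error(
    classify_cohort_genetic(data.frame(subject_id = character(),
                                       gene = character(),
                                       variant_id = character(),
                                       acmg_class = character(),
                                       zygosity = character()),
                            test_panel(), dup),
    class = "nbs_validation_error")
  empty <- classify_cohort_genetic(
    data.frame(subject_id = character(), gene = character(),
               variant_id = character(), acmg_class = character(),
               zygosity = character()),
    test_panel(), data.frame(subject_id = character(), sex = character()))
  expect_identical(nrow(empty), 0L)
  expect_identical(attr(empty, "n_positive"), 0L)
})

test_that("classifier agrees with a brute-force enumeration oracle", {
  panel <- test_panel()
  # AR gene: all genotypes of <= 3 variants over {P, LP, VUS} x {het, hom}
  for (sex in c("M", "F")) {
    for (g in enumerate_genotypes("ARG1")) {
      got <- classify_genetic(g, sex, panel)$call == "positive"
      expect_identical(got, oracle_genetic_positive(g, sex, panel),
                       info = paste(sex, paste(g$acmg_class, g$zygosity,
                                               collapse = "|")))
    }
  }
  # XL gene in males over {het, hemi}; in females over {het, hom}
  for (g in enumerate_genotypes("XLG1", zygosities = c("het", "hemi"))) {
    got <- classify_genetic(g, "M", panel)$call == "positive"
    expect_identical(got, oracle_genetic_positive(g, "M", panel))
  }
  for (g in enumerate_genotypes("XLG1", zygosities = c("het", "hom"))) {
    got <- classify_genetic(g, "F", panel)$call == "positive"
    expect_identical(got, oracle_genetic_positive(g, "F", panel))
  }
  # off-panel gene: never positive
  for (g in enumerate_genotypes("OFFP")) {
    expect_identical(classify_genetic(g, "M", panel)$call, "negative")
  }
})

test_that("pathogenicity upgrades and variant removal are monotone", {
  panel <- test_panel()
  ladder <- c("B", "LB", "VUS", "LP", "P")
  set.seed(202)
  for (rep in 1:60) {
    n <- sample(1:3, 1)
    g <- data.frame(gene = "ARG1", variant_id = paste0("v", seq_len(n)),
                    acmg_class = sample(ladder, n, replace = TRUE),
                    zygosity = sample(c("het", "hom"), n, replace = TRUE),
                    stringsAsFactors = FALSE)
    base_pos <- classify_genetic(g, "F", panel)$call == "positive"
    # upgrading any single variant never flips positive -> negative
    for (i in seq_len(n)) {
      pos <- match(g$acmg_class[i], ladder)
      if (pos < length(ladder)) {
        up <- g
        up$acmg_class[i] <- ladder[pos + 1L]
        up_pos <- classify_genetic(up, "F", panel)$call == "positive"
        if (base_pos) expect_true(up_pos)
      }
    }
    # removing a variant never flips negative -> positive
    for (i in seq_len(n)) {
      sub <- g[-i, , drop = FALSE]
      sub_pos <- classify_genetic(sub, "F", panel)$call == "positive"
      if (!base_pos) expect_false(sub_pos)
    }
  }
})
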