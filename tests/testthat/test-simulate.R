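test_that("cohort configuration validates probabilities, weights and frequencies", {
  expect_s3_class(cohort_config(100), "cohort_config")
  expect_error(cohort_config(100, msms_fp_rate = 1.2),
               class = "nbs_validation_error")
  bad_centers <- data.frame(center_id = "A", weight = 0.5, recall_prob = 1)
  expect_error(cohort_config(100, centers = bad_centers),
               class = "nbs_validation_error")
  g <- default_gene_params()
  g$carrier_freq[1] <- 0.999 # no real Hardy-Weinberg solution
  expect_error(cohort_config(100, genes = g, hw_mode = "exact"),
               class = "nbs_validation_error")
  g$carrier_freq[1] <- 1.2 # not a frequency
  expect_error(cohort_config(100, genes = g),
               class = "nbs_validation_error")
})

test_that("simulation is deterministic under a seed and empty at n = 0", {
  cfg <- cohort_config(2000, seed = 31)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a, b)
  # and leaves the caller's RNG stream untouched
  set.seed(1); before <- stats::runif(3)
  set.seed(1); invisible(simulate_cohort(cfg)); after <- stats::runif(3)
  expect_identical(before, after)

  empty <- simulate_cohort(cohort_config(0, seed = 1))
  expect_identical(nrow(empty$subjects), 0L)
  expect_identical(nrow(empty$variants), 0L)
})

test_that("zero allele frequencies produce a variant-free cohort", {
  g <- default_gene_params()
  g$carrier_freq <- 0
  g$vus_freq <- 0
  co <- simulate_cohort(cohort_config(500, seed = 2, genes = g,
                                      msms_fp_rate = 0))
  expect_identical(nrow(co$variants), 0L)
  expect_false(any(co$subjects$diseased))
  # and with no background false-positive rate, nobody screens positive
  m <- classify_cohort_msms(co$analytes, co$cutoffs)
  expect_identical(attr(m, "n_positive"), 0L)
})

test_that("genotype draws recover configured carrier and affected frequencies", {
  g <- default_gene_params()[1, ] # PAH alone, carrier frequency 1/42
  cfg <- cohort_config(100000, seed = 11, genes = g)
  set.seed(cfg$seed)
  geno <- simulate_genotypes(cfg)
  q <- cfg$genes$q
  # carriers (>= 1 P/LP allele, not biallelic): expected 2q(1-q)
  ce <- carrier_frequency(geno$variants, "PAH", cfg$n_newborns,
                          config_panel(cfg))
  c_true <- 2 * q * (1 - q)
  se <- sqrt(c_true * (1 - c_true) / cfg$n_newborns)
  expect_lt(abs(ce$frequency - c_true), 3 * se)
  # affected genotypes: Poisson bounds around n q^2
  lambda <- cfg$n_newborns * q^2
  n_aff <- nrow(geno$truth)
  expect_gte(n_aff, stats::qpois(0.005, lambda))
  expect_lte(n_aff, stats::qpois(0.995, lambda))
})

test_that("distinct seeds give homogeneous carrier frequencies", {
  g <- default_gene_params()[1, ]
  counts <- vapply(1:10, function(s) {
    co <- simulate_cohort(cohort_config(5000, seed = 100 + s, genes = g))
    carrier_frequency(co$variants, "PAH", 5000, config_panel(co$config))$n_carriers
  }, integer(1))
  ht <- stats::chisq.test(counts)
  expect_gt(ht$p.value, 0.01)
})

test_that("analyte generation honours penetrance, attenuation and background rates", {
  g <- default_gene_params()
  g$carrier_freq[g$gene == "PAH"] <- 0.2 # inflate cases for a small cohort
  # full penetrance, no attenuation, no background noise:
  # every affected subject is MS/MS positive and no healthy subject is
  cfg <- cohort_config(3000, seed = 8, genes = g,
                       penetrance_biochemical = 1, attenuation_prob = 0,
                       msms_fp_rate = 0)
  co <- simulate_cohort(cfg)
  expect_gt(sum(co$subjects$diseased), 0)
  m <- classify_cohort_msms(co$analytes, co$cutoffs)
  pos <- m$subject_id[m$call == "positive"]
  expect_setequal(pos, co$subjects$subject_id[co$subjects$diseased])
  # attenuation 1: every diseased subject stays within cutoffs
  cfg2 <- cohort_config(3000, seed = 8, genes = g,
                        penetrance_biochemical = 1, attenuation_prob = 1,
                        msms_fp_rate = 0)
  co2 <- simulate_cohort(cfg2)
  m2 <- classify_cohort_msms(co2$analytes, co2$cutoffs)
  expect_identical(attr(m2, "n_positive"), 0L)
})

test_that("default calibration lands near the observed MS/MS positive rate", {
  cfg <- cohort_config(29601, seed = 13)
  co <- simulate_cohort(cfg)
  m <- classify_cohort_msms(co$analytes, co$cutoffs)
  rate <- 100 * attr(m, "n_positive") / cfg$n_newborns
  # 1.71% +/- 3 binomial SD (~0.23 percentage points)
  se3 <- 3 * 100 * sqrt(0.0171 * (1 - 0.0171) / 29601)
  expect_lt(abs(rate - 1.71), se3)
})

test_that("X-linked genes produce hemizygous male calls that screen positive", {
  g <- default_gene_params()
  g <- g[g$gene == "OTC", ]
  g$carrier_freq <- 0.02
  cfg <- cohort_config(5000, seed = 21, genes = g)
  co <- simulate_cohort(cfg)
  v <- co$variants
  males <- co$subjects$subject_id[co$subjects$sex == "M"]
  expect_true(all(v$zygosity[v$subject_id %in% males] == "hemi"))
  expect_false(any(v$zygosity[!v$subject_id %in% males] == "hemi"))
  aff_m <- co$truth$subject_id[co$truth$subject_id %in% males]
  if (length(aff_m)) {
    res <- classify_cohort_genetic(v, config_panel(cfg), co$subjects)
    expect_true(all(res$call[res$subject_id %in% aff_m] == "positive"))
  }
})

test_that("an end-to-end simulated cohort shows the dual-platform structure", {
  co <- simulate_cohort(cohort_config(100000, seed = 42))
  fit <- nbs_screen(co)
  cf <- coef(fit)
  # genetic screening trades sensitivity for a far higher PPV
  expect_gt(cf["ngs_ppv"], cf["msms_ppv"])
  expect_gt(cf["msms_sensitivity"], cf["ngs_sensitivity"])
  # VUS-masked and off-panel cases are invisible to the genetic rule
  masked <- co$truth$subject_id[co$truth$vus_masked |
                                  co$truth$gene == "ETFA"]
  out <- fit$outcomes
  expect_true(all(out$ngs_call[out$subject_id %in% masked] == "negative"))
})
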