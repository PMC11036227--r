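test_that("headline metrics reproduce printed percentages with half-up rounding", {
  expect_identical(ppv(21, 397), 5.29)
  expect_identical(ppv(17, 24), 70.83)
  expect_identical(ppv(0, 10), 0)
  expect_error(ppv(0, 0), class = "nbs_metric_error")

  expect_identical(sensitivity(21, 2, digits = 1), 91.3)
  expect_identical(sensitivity(17, 6), 73.91)
  expect_identical(sensitivity(5, 0), 100)
  expect_error(sensitivity(0, 0), class = "nbs_metric_error")

  expect_identical(recall_rate(397, 507), 78.3)
  expect_identical(recall_rate(36, 113, digits = 2), 31.86)
  expect_identical(recall_rate(0, 5), 0)
  expect_error(recall_rate(0, 0), class = "nbs_metric_error")

  expect_identical(positive_rate(507, 29601), 1.71)
  expect_identical(positive_rate(24, 29601), 0.08)

  # half-up at the margin, where round-half-even would disagree
  expect_identical(round_half_up(2.445, 2), 2.45)
  expect_identical(round_half_up(0.5), 1)
})

test_that("incidence reciprocals match the printed 1-in-N figures", {
  expect_identical(incidence(23, 29601)$reciprocal, 1287)
  expect_identical(incidence(3, 29601)$reciprocal, 9867)
  expect_identical(incidence(2, 29601)$reciprocal, 14801)
  expect_identical(incidence(29601, 29601)$reciprocal, 1)
  # zero cases: no estimate, not an error, for batch tables
  expect_true(is.na(incidence(0, 100)$reciprocal))
  t1 <- load_fixtures("table1")
  inc <- incidence(t1$n_cases, 29601, t1$disease)
  expect_equal(inc$reciprocal, t1$incidence_n, ignore_attr = TRUE)
})

test_that("per-center performance tables reproduce every printed cell", {
  t2 <- load_fixtures("table2")
  perf <- performance_from_counts(t2, "msms")
  expect_identical(perf$ppv[match(c("SH", "GZ", "JN", "SJZ", "CQ", "YN",
                                    "NMG", "HN"), perf$center_id)],
                   c(2.44, 8.51, 4.35, 3.08, 9.09, 5.00, 5.56, 25))
  tot <- perf[perf$center_id == "Total", ]
  expect_identical(tot$n_screened, 29601L)
  expect_identical(tot$n_positive, 507L)
  expect_identical(tot$n_recalled, 397L)
  expect_identical(tot$recall_rate, 78.3)
  expect_identical(tot$n_confirmed, 21L)
  expect_identical(tot$ppv, 5.29)
  expect_identical(tot$n_false_negative, 2L)
  expect_identical(sensitivity(tot$n_confirmed, tot$n_false_negative,
                               digits = 1), 91.3)

  perf_g <- performance_from_counts(t2, "ngs")
  tot_g <- perf_g[perf_g$center_id == "Total", ]
  expect_identical(tot_g$n_positive, 24L)
  expect_identical(tot_g$n_recalled, 24L)
  expect_identical(tot_g$recall_rate, 100)
  expect_identical(tot_g$n_confirmed, 17L)
  expect_identical(tot_g$ppv, 70.83)
  expect_identical(tot_g$n_false_negative, 6L)
  expect_identical(tot_g$sensitivity, 73.91)

  # NMG recall rate printed at two decimals
  expect_identical(performance_from_counts(t2, "msms",
                                           digits_recall = 2)$recall_rate[7],
                   31.86)

  # single-center input equals its own totals row
  one <- performance_from_counts(t2[3, ], "msms")
  expect_identical(unname(unlist(one[1, -1])), unname(unlist(one[2, -1])))
})

test_that("pooled PPV is a weighted mean: always between per-center extremes", {
  set.seed(404)
  for (rep in 1:25) {
    k <- sample(2:6, 1)
    rec <- sample(5:200, k, replace = TRUE)
    conf <- vapply(rec, function(r) sample(0:r, 1), integer(1))
    counts <- data.frame(center = paste0("c", seq_len(k)),
                         n_screened = rec * 10, msms_positive = rec,
                         msms_recalled = rec, msms_confirmed = conf,
                         msms_false_negative = 0)
    perf <- performance_from_counts(counts, "msms", digits_ppv = 6)
    per <- perf$ppv[perf$center_id != "Total"]
    tot <- perf$ppv[perf$center_id == "Total"]
    expect_gte(tot, min(per) - 1e-9)
    expect_lte(tot, max(per) + 1e-9)
  }
})

test_that("performance tables built from labelled outcomes match count-based tables", {
  set.seed(77)
  n <- 400
  out <- data.frame(
    subject_id = paste0("s", 1:n),
    center_id = sample(c("A", "B"), n, replace = TRUE),
    ngs_call = sample(c("positive", "negative"), n, TRUE, c(.05, .95)),
    msms_call = sample(c("positive", "negative"), n, TRUE, c(.1, .9)))
  out <- apply_recall(out, recall_prob = 0.8, seed = 1)
  out$confirmed <- out$recalled & stats::runif(n) < 0.2
  out <- label_outcomes(out)
  perf <- build_performance_table(out, "msms")
  tot <- perf[perf$center_id == "Total", ]
  pos <- out$msms_call == "positive"
  expect_identical(tot$n_positive, sum(pos))
  expect_identical(tot$n_recalled, sum(pos & out$recalled))
  expect_identical(tot$n_confirmed, sum(out$msms_label == "TP"))
  expect_identical(tot$n_false_negative, sum(out$msms_label == "FN"))
  expect_identical(tot$ppv, ppv(tot$n_confirmed, tot$n_recalled))
  # per-center counts add up to the pooled row
  per <- perf[perf$center_id != "Total", ]
  expect_identical(sum(per$n_positive), tot$n_positive)
  expect_identical(sum(per$n_confirmed), tot$n_confirmed)
})
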