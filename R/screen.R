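#' Evaluate dual-platform newborn screening on a cohort
#'
#' The central evaluator. It runs the genotype-based classifier and the
#' analyte-cutoff classifier on every subject, combines the calls into
#' referrals, applies recall attrition (genetic positives are always
#' recalled), attaches confirmed diagnoses, labels per-modality outcomes and
#' derives per-center and pooled performance tables. Returns a fitted-object
#' style result with \code{print}, \code{summary}, \code{coef},
#' \code{predict} and \code{plot} methods.
#'
#' @param x for the default method, a variant-call data.frame
#'   (\code{subject_id}, \code{gene}, \code{variant_id}, \code{acmg_class},
#'   \code{zygosity}); alternatively a simulated \code{"nbs_cohort"}.
#' @param ... passed between methods.
#' @return object of class \code{"nbs_screen"}.
#' @seealso \code{\link{simulate_cohort}}, \code{\link{load_fixtures}}
#' @export
nbs_screen <- function(x, ...) UseMethod("nbs_screen")

.nbs_screen_core <- function(subjects, genetic, msms, truth, recall_prob,
                             seed, panel, cutoffs, call) {
  out <- data.frame(subject_id = subjects$subject_id,
                    center_id = subjects$center_id,
                    sex = subjects$sex,
                    stringsAsFactors = FALSE)
  out$ngs_call <- genetic$call[match(out$subject_id, genetic$subject_id)]
  out$msms_call <- msms$call[match(out$subject_id, msms$subject_id)]
  out$msms_call[is.na(out$msms_call)] <- "negative"
  out$ngs_call[is.na(out$ngs_call)] <- "negative"
  out <- apply_recall(out, recall_prob = recall_prob, seed = seed)
  if (!is.null(truth)) {
    idx <- match(out$subject_id, truth$subject_id)
    out$disease <- truth$disease[idx]
    if ("confirmed" %in% names(truth)) {
      out$confirmed <- !is.na(idx) & truth$confirmed[pmax(idx, 1L)]
    } else {
      diseased <- !is.na(idx) & truth$diseased[pmax(idx, 1L)]
      out$confirmed <- diseased & out$recalled
    }
    out$confirmed[is.na(idx)] <- FALSE
  } else {
    out$disease <- NA_character_
    out$confirmed <- FALSE
  }
  out <- label_outcomes(out)
  perf <- list(msms = build_performance_table(out, "msms"),
               ngs = build_performance_table(out, "ngs"))
  n <- nrow(out)
  conf <- out[out$confirmed, , drop = FALSE]
  inc <- if (nrow(conf)) {
    by_dis <- table(conf$disease)
    rbind(incidence(sum(out$confirmed), n, "all IEMs"),
          incidence(as.integer(by_dis), n, names(by_dis)))
  } else incidence(0, n, "all IEMs")
  structure(list(outcomes = out, performance = perf, incidence = inc,
                 n_screened = n, panel = panel, cutoffs = cutoffs,
                 call = call),
            class = "nbs_screen")
}

#' @rdname nbs_screen
#' @param analytes long analyte table (\code{subject_id}, \code{marker},
#'   \code{value}, optional per-row \code{cutoff}) or a subjects-by-markers
#'   matrix.
#' @param panel gene panel (see \code{\link{as_nbs_panel}}).
#' @param cutoffs cutoff set; may be \code{NULL} when \code{analytes}
#'   carries per-row cutoffs.
#' @param subjects data.frame \code{subject_id}, \code{sex} and optionally
#'   \code{center_id} defining the cohort (defaults to subjects seen in the
#'   inputs).
#' @param diagnoses data.frame \code{subject_id}, \code{disease} plus either
#'   \code{confirmed} (resolved diagnosis labels) or \code{diseased} (ground
#'   truth; confirmation then requires recall).
#' @param recall_prob scalar or per-center named vector of MS/MS recall
#'   probabilities; genetic positives are exempt from attrition.
#' @param seed optional integer making recall thinning reproducible.
#' @export
nbs_screen.default <- function(x, analytes, panel, cutoffs = NULL,
                               subjects = NULL, diagnoses = NULL,
                               recall_prob = 1, seed = NULL, ...) {
  variants <- x
  if (!inherits(panel, "nbs_panel")) panel <- as_nbs_panel(panel)
  if (is.null(subjects)) {
    ids <- unique(c(variants$subject_id,
                    if (is.matrix(analytes)) rownames(analytes)
                    else analytes$subject_id))
    sx <- variants$sex[match(ids, variants$subject_id)] %||%
      rep(NA_character_, length(ids))
    sx[is.na(sx)] <- "F"
    subjects <- data.frame(subject_id = ids, sex = sx,
                           stringsAsFactors = FALSE)
  }
  if (!"center_id" %in% names(subjects)) subjects$center_id <- "ALL"
  g <- classify_cohort_genetic(variants, panel, subjects)
  m <- classify_cohort_msms(analytes, cutoffs)
  .nbs_screen_core(subjects, g, m, diagnoses, recall_prob, seed, panel,
                   cutoffs, match.call())
}

#' @rdname nbs_screen
#' @export
nbs_screen.nbs_cohort <- function(x, recall_prob = NULL, seed = NULL, ...) {
  panel <- config_panel(x$config)
  if (is.null(recall_prob)) {
    recall_prob <- stats::setNames(x$config$centers$recall_prob,
                                   x$config$centers$center_id)
  }
  if (is.null(seed)) seed <- x$config$seed + 1L
  g <- classify_cohort_genetic(x$variants, panel, x$subjects)
  m <- classify_cohort_msms(x$analytes, x$cutoffs)
  truth <- x$subjects[x$subjects$genotype_affected,
                      c("subject_id", "disease", "diseased"), drop = FALSE]
  .nbs_screen_core(x$subjects, g, m, truth, recall_prob, seed, panel,
                   x$cutoffs, match.call())
}

#' @export
print.nbs_screen <- function(x, ...) {
  cf <- stats::coef(x)
  cat("Dual-platform newborn screening evaluation\n")
  cat("  newborns screened:", x$n_screened, "\n")
  tot_m <- x$performance$msms[nrow(x$performance$msms), ]
  tot_g <- x$performance$ngs[nrow(x$performance$ngs), ]
  cat(sprintf("  MS/MS: %d positive, %d recalled, %d confirmed, %d missed\n",
              tot_m$n_positive, tot_m$n_recalled, tot_m$n_confirmed,
              tot_m$n_false_negative))
  cat(sprintf("  NGS:   %d positive, %d recalled, %d confirmed, %d missed\n",
              tot_g$n_positive, tot_g$n_recalled, tot_g$n_confirmed,
              tot_g$n_false_negative))
  cat(sprintf("  PPV:         MS/MS %s%%, NGS %s%%\n",
              format(cf["msms_ppv"]), format(cf["ngs_ppv"])))
  cat(sprintf("  sensitivity: MS/MS %s%%, NGS %s%%\n",
              format(cf["msms_sensitivity"]), format(cf["ngs_sensitivity"])))
  if (!is.na(cf["incidence_one_in"])) {
    cat(sprintf("  incidence: 1 in %d\n", as.integer(cf["incidence_one_in"])))
  }
  invisible(x)
}

#' Headline performance coefficients
#'
#' Positive rate, recall rate, PPV and sensitivity per modality (percent,
#' rounded half-up at reporting precision) plus the overall "1 in N"
#' incidence reciprocal.
#'
#' @param object an \code{\link{nbs_screen}} object.
#' @param ... unused.
#' @return named numeric vector.
#' @export
coef.nbs_screen <- function(object, ...) {
  tot <- function(m) object$performance[[m]][nrow(object$performance[[m]]), ]
  tm <- tot("msms"); tg <- tot("ngs")
  pr <- function(t) positive_rate(t$n_positive, t$n_screened)
  c(msms_positive_rate = pr(tm), msms_recall_rate = tm$recall_rate,
    msms_ppv = tm$ppv, msms_sensitivity = tm$sensitivity,
    ngs_positive_rate = pr(tg), ngs_recall_rate = tg$recall_rate,
    ngs_ppv = tg$ppv, ngs_sensitivity = tg$sensitivity,
    incidence_one_in = object$incidence$reciprocal[1])
}

#' @export
summary.nbs_screen <- function(object, ...) {
  structure(list(performance = object$performance,
                 incidence = object$incidence,
                 n_screened = object$n_screened,
                 coef = stats::coef(object)),
            class = "summary.nbs_screen")
}

#' @export
print.summary.nbs_screen <- function(x, ...) {
  cat("MS/MS screening performance (per center, pooled Total):\n")
  print(x$performance$msms, row.names = FALSE)
  cat("\nGenetic screening performance (per center, pooled Total):\n")
  print(x$performance$ngs, row.names = FALSE)
  cat("\nIncidence:\n")
  print(x$incidence, row.names = FALSE)
  invisible(x)
}

#' Screen new subjects with a fitted evaluator's panel and cutoffs
#'
#' @param object an \code{\link{nbs_screen}} object.
#' @param variants,analytes new subjects' inputs (same formats as
#'   \code{\link{nbs_screen}}).
#' @param subjects optional cohort frame (\code{subject_id}, \code{sex}).
#' @param ... unused.
#' @return data.frame \code{subject_id}, \code{ngs_call}, \code{msms_call},
#'   \code{referral}.
#' @export
predict.nbs_screen <- function(object, variants, analytes, subjects = NULL,
                               ...) {
  g <- classify_cohort_genetic(variants, object$panel, subjects)
  m <- classify_cohort_msms(analytes, object$cutoffs)
  ids <- if (!is.null(subjects)) subjects$subject_id else
    unique(c(g$subject_id, m$subject_id))
  ngs <- g$call[match(ids, g$subject_id)]
  msms <- m$call[match(ids, m$subject_id)]
  ngs[is.na(ngs)] <- "negative"
  msms[is.na(msms)] <- "negative"
  data.frame(subject_id = ids, ngs_call = ngs, msms_call = msms,
             referral = combine_calls(ngs, msms), stringsAsFactors = FALSE)
}

#' @export
plot.nbs_screen <- function(x, ...) {
  cf <- stats::coef(x)
  m <- rbind(`PPV` = c(cf["msms_ppv"], cf["ngs_ppv"]),
             `Sensitivity` = c(cf["msms_sensitivity"],
                               cf["ngs_sensitivity"]))
  colnames(m) <- c("MS/MS", "NGS")
  graphics::barplot(t(m), beside = TRUE, ylim = c(0, 100),
                    ylab = "percent", legend.text = colnames(m),
                    main = "Screening performance by platform", ...)
  invisible(x)
}
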