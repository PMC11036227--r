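#' Screening performance metrics
#'
#' Positive predictive value, sensitivity, recall rate and positive rate, as
#' percentages rounded half-up at a configurable precision. The PPV
#' denominator is the number of \emph{recalled} positives, not all screen
#' positives: positives lost to recall have unknown outcomes and are excluded.
#'
#' @param n_confirmed,n_recalled,n_true_positive,n_false_negative,n_positive,n_screened
#'   non-negative counts.
#' @param digits decimal places for the reported percentage (half-up).
#' @return percentage in \[0, 100\].
#' @examples
#' ppv(21, 397)        # 5.29
#' ppv(17, 24)         # 70.83
#' sensitivity(21, 2)  # 91.3 at 1 digit
#' @name performance-metrics
NULL

#' @rdname performance-metrics
#' @export
ppv <- function(n_confirmed, n_recalled, digits = 2) {
  if (any(n_recalled < 1)) {
    nbs_stop("PPV undefined with no recalled positives", "nbs_metric_error")
  }
  round_half_up(100 * n_confirmed / n_recalled, digits)
}

#' @rdname performance-metrics
#' @export
sensitivity <- function(n_true_positive, n_false_negative, digits = 2) {
  denom <- n_true_positive + n_false_negative
  if (any(denom < 1)) {
    nbs_stop("sensitivity undefined with no detectable cases",
             "nbs_metric_error")
  }
  round_half_up(100 * n_true_positive / denom, digits)
}

#' @rdname performance-metrics
#' @export
recall_rate <- function(n_recalled, n_positive, digits = 1) {
  if (any(n_positive < 1)) {
    nbs_stop("recall rate undefined with no positives", "nbs_metric_error")
  }
  round_half_up(100 * n_recalled / n_positive, digits)
}

#' @rdname performance-metrics
#' @export
positive_rate <- function(n_positive, n_screened, digits = 2) {
  if (any(n_screened < 1)) {
    nbs_stop("positive rate undefined with no screened subjects",
             "nbs_metric_error")
  }
  round_half_up(100 * n_positive / n_screened, digits)
}

#' Birth incidence as "1 in N"
#'
#' @param n_cases confirmed cases (vectorised); zero cases yields an
#'   \code{NA} reciprocal rather than an error, for batch tables.
#' @param n_screened cohort size.
#' @param disease optional disease label(s).
#' @return data.frame \code{disease}, \code{n_cases}, \code{n_screened},
#'   \code{reciprocal} where \code{reciprocal} is the half-up-rounded N of
#'   "1 in N".
#' @examples
#' incidence(23, 29601) # 1 in 1287
#' @export
incidence <- function(n_cases, n_screened, disease = NA_character_) {
  if (any(n_cases < 0) || any(n_screened < 1)) {
    nbs_stop("invalid incidence inputs", "nbs_validation_error")
  }
  data.frame(disease = disease, n_cases = n_cases, n_screened = n_screened,
             reciprocal = ifelse(n_cases >= 1,
                                 round_half_up(n_screened / n_cases), NA),
             stringsAsFactors = FALSE)
}

# shared derivation of a performance row from raw counts
.perf_rows <- function(center, n_screened, n_pos, n_rec, n_conf, n_fn,
                       digits_ppv, digits_recall, digits_sens) {
  data.frame(
    center_id = center,
    n_screened = as.integer(n_screened),
    n_positive = as.integer(n_pos),
    n_recalled = as.integer(n_rec),
    recall_rate = ifelse(n_pos >= 1,
                         round_half_up(100 * n_rec / n_pos, digits_recall),
                         NA),
    n_confirmed = as.integer(n_conf),
    ppv = ifelse(n_rec >= 1, round_half_up(100 * n_conf / n_rec, digits_ppv),
                 NA),
    n_false_negative = as.integer(n_fn),
    sensitivity = ifelse(n_conf + n_fn >= 1,
                         round_half_up(100 * n_conf / (n_conf + n_fn),
                                       digits_sens), NA),
    stringsAsFactors = FALSE
  )
}

#' Per-center performance table from count data
#'
#' Derives recall rate, PPV and sensitivity for every center plus a pooled
#' \code{Total} row. Totals are computed from pooled counts, never by
#' averaging per-center percentages.
#'
#' @param counts data.frame with columns \code{center}, \code{n_screened}
#'   and, per modality \code{<m>_positive}, \code{<m>_recalled},
#'   \code{<m>_confirmed}, \code{<m>_false_negative} where \code{<m>} is
#'   \code{msms} or \code{ngs}.
#' @param modality \code{"msms"} or \code{"ngs"}.
#' @param digits_ppv,digits_recall,digits_sens printed precision (half-up).
#' @return data.frame of performance rows; the last row is \code{Total}.
#' @export
performance_from_counts <- function(counts, modality = c("msms", "ngs"),
                                    digits_ppv = 2, digits_recall = 1,
                                    digits_sens = 2) {
  modality <- match.arg(modality)
  cols <- paste0(modality, c("_positive", "_recalled", "_confirmed",
                             "_false_negative"))
  assert_columns(counts, c("center", "n_screened", cols), "counts")
  per <- .perf_rows(counts$center, counts$n_screened, counts[[cols[1]]],
                    counts[[cols[2]]], counts[[cols[3]]], counts[[cols[4]]],
                    digits_ppv, digits_recall, digits_sens)
  tot <- .perf_rows("Total", sum(counts$n_screened), sum(counts[[cols[1]]]),
                    sum(counts[[cols[2]]]), sum(counts[[cols[3]]]),
                    sum(counts[[cols[4]]]), digits_ppv, digits_recall,
                    digits_sens)
  rbind(per, tot)
}

#' Per-center performance table from labelled subject outcomes
#'
#' Aggregates \code{\link{label_outcomes}} output into the same row shape as
#' \code{\link{performance_from_counts}}. Recalled positives form the PPV
#' denominator; screen positives lost to recall count toward the positive
#' tally but not toward PPV.
#'
#' @param outcomes labelled outcome data.frame (needs \code{center_id},
#'   \code{recalled} and the modality's call/label columns).
#' @param modality \code{"msms"} or \code{"ngs"}.
#' @param digits_ppv,digits_recall,digits_sens printed precision (half-up).
#' @return data.frame of performance rows; the last row is \code{Total}.
#' @export
build_performance_table <- function(outcomes, modality = c("msms", "ngs"),
                                    digits_ppv = 2, digits_recall = 1,
                                    digits_sens = 2) {
  modality <- match.arg(modality)
  call_col <- paste0(modality, "_call")
  lab_col <- paste0(modality, "_label")
  assert_columns(outcomes, c("center_id", "recalled", call_col, lab_col),
                 "outcomes")
  agg <- function(sub) {
    pos <- sub[[call_col]] == "positive"
    c(n_screened = nrow(sub),
      n_pos = sum(pos),
      n_rec = sum(pos & sub$recalled),
      n_conf = sum(sub[[lab_col]] == "TP"),
      n_fn = sum(sub[[lab_col]] == "FN"))
  }
  centers <- sort(unique(outcomes$center_id))
  mat <- vapply(centers, function(cc)
    agg(outcomes[outcomes$center_id == cc, , drop = FALSE]), numeric(5))
  per <- .perf_rows(centers, mat["n_screened", ], mat["n_pos", ],
                    mat["n_rec", ], mat["n_conf", ], mat["n_fn", ],
                    digits_ppv, digits_recall, digits_sens)
  tot_counts <- agg(outcomes)
  tot <- .perf_rows("Total", tot_counts["n_screened"], tot_counts["n_pos"],
                    tot_counts["n_rec"], tot_counts["n_conf"],
                    tot_counts["n_fn"], digits_ppv, digits_recall,
                    digits_sens)
  out <- rbind(per, tot)
  rownames(out) <- NULL
  out
}
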