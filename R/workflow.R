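#' Combine the two first-tier screen calls into a referral decision
#'
#' A newborn positive on either platform is referred for confirmatory
#' testing; the decision is symmetric in the two calls.
#'
#' @param ngs_call,msms_call character vectors of \code{"positive"} /
#'   \code{"negative"} calls, or the result data.frames from
#'   \code{\link{classify_cohort_genetic}} / \code{\link{classify_cohort_msms}}
#'   (matched on \code{subject_id}).
#' @return character vector of \code{"refer"} / \code{"no_refer"}.
#' @examples
#' combine_calls("positive", "negative") # refer
#' @export
combine_calls <- function(ngs_call, msms_call) {
  if (is.data.frame(ngs_call) && is.data.frame(msms_call)) {
    if (!identical(sort(ngs_call$subject_id), sort(msms_call$subject_id))) {
      nbs_stop("subject_id mismatch between the two screen results",
               "nbs_validation_error")
    }
    msms_call <- msms_call[match(ngs_call$subject_id, msms_call$subject_id), ]
    ngs_call <- ngs_call$call
    msms_call <- msms_call$call
  }
  ok <- c("positive", "negative")
  if (!all(ngs_call %in% ok) || !all(msms_call %in% ok)) {
    nbs_stop("calls must be 'positive' or 'negative'", "nbs_validation_error")
  }
  ifelse(ngs_call == "positive" | msms_call == "positive",
         "refer", "no_refer")
}

#' Apply recall attrition to referred newborns
#'
#' Genetic-screen positives are always recalled. MS/MS-only referrals are
#' recalled with a per-center probability, modelling the attrition observed
#' between screen positivity and recall review.
#'
#' @param outcomes data.frame with columns \code{subject_id},
#'   \code{ngs_call}, \code{msms_call} and (when \code{recall_prob} is a
#'   named vector) \code{center_id}.
#' @param recall_prob single probability in \[0, 1\], or a named vector of
#'   per-center probabilities.
#' @param seed optional integer for reproducible thinning.
#' @return \code{outcomes} with logical columns \code{referred} and
#'   \code{recalled} added.
#' @export
apply_recall <- function(outcomes, recall_prob = 1, seed = NULL) {
  assert_columns(outcomes, c("subject_id", "ngs_call", "msms_call"),
                 "outcomes")
  if (any(recall_prob < 0 | recall_prob > 1)) {
    nbs_stop("recall probabilities must lie in [0, 1]",
             "nbs_validation_error")
  }
  if (!is.null(seed)) set.seed(seed)
  p <- if (length(recall_prob) > 1L || !is.null(names(recall_prob))) {
    assert_columns(outcomes, "center_id", "outcomes")
    unknown <- setdiff(unique(outcomes$center_id), names(recall_prob))
    if (length(unknown)) {
      nbs_stop(paste("no recall probability for center(s):",
                     paste(unknown, collapse = ", ")),
               "nbs_validation_error")
    }
    unname(recall_prob[outcomes$center_id])
  } else rep(recall_prob, nrow(outcomes))
  outcomes$referred <- combine_calls(outcomes$ngs_call,
                                     outcomes$msms_call) == "refer"
  ngs_pos <- outcomes$ngs_call == "positive"
  drawn <- stats::runif(nrow(outcomes)) < p
  outcomes$recalled <- outcomes$referred & (ngs_pos | drawn)
  outcomes
}

#' Label per-modality screening outcomes
#'
#' For each modality (genetic and MS/MS) a subject is a true positive when
#' screen-positive and confirmed; a false positive when screen-positive,
#' recalled, and not confirmed; a false negative when screen-negative but
#' confirmed (necessarily through the other modality's referral); an unknown
#' when screen-positive but never recalled (excluded from PPV denominators);
#' and a true negative otherwise.
#'
#' @param outcomes data.frame with columns \code{ngs_call}, \code{msms_call},
#'   \code{recalled} (logical) and \code{confirmed} (logical).
#' @return \code{outcomes} with character columns \code{ngs_label} and
#'   \code{msms_label} (\code{TP}, \code{FP}, \code{FN}, \code{TN},
#'   \code{unknown}).
#' @export
label_outcomes <- function(outcomes) {
  assert_columns(outcomes, c("ngs_call", "msms_call", "recalled", "confirmed"),
                 "outcomes")
  bad <- outcomes$confirmed & !outcomes$recalled
  if (any(bad)) {
    warning(sum(bad), " confirmed but unrecalled subject(s): ",
            "inconsistent records", call. = FALSE)
  }
  lab <- function(pos) {
    ifelse(pos & outcomes$confirmed, "TP",
    ifelse(pos & outcomes$recalled, "FP",
    ifelse(pos, "unknown",
    ifelse(outcomes$confirmed, "FN", "TN"))))
  }
  outcomes$ngs_label <- lab(outcomes$ngs_call == "positive")
  outcomes$msms_label <- lab(outcomes$msms_call == "positive")
  outcomes
}
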