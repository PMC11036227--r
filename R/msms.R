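#' The tandem-mass-spectrometry marker registry
#'
#' Eleven amino acids, thirty acylcarnitines, free carnitine (C0),
#' succinylacetone (SA), and the ratio markers used as secondary screening
#' indicators. Only registered markers may be classified.
#'
#' @return character vector of marker names.
#' @export
marker_registry <- function() {
  amino <- c("Ala", "Arg", "Cit", "Gly", "Leu", "Met", "Orn", "Phe", "Pro",
             "Tyr", "Val")
  acyl <- c("C2", "C3", "C3DC", "C4", "C5", "C5:1", "C5DC", "C5OH", "C6",
            "C6DC", "C8", "C8:1", "C10", "C10:1", "C10:2", "C12", "C12:1",
            "C14", "C14:1", "C14:2", "C14OH", "C16", "C16:1", "C16OH",
            "C16:1OH", "C18", "C18:1", "C18:2", "C18OH", "C18:1OH")
  ratios <- c("C3/C2", "Phe/Tyr", "C4/C3", "C8/C10", "C0/(C16+C18)",
              "Cit/Arg", "Met/Phe", "Leu/Phe", "C14:1/C2", "C5/C3", "C8/C2")
  c(amino, acyl, "C0", "SA", ratios)
}

# canonical flagging direction per marker: deficiency markers (free carnitine,
# methionine) flag low, accumulation markers and all ratios flag high
marker_directions <- function() {
  reg <- marker_registry()
  dir <- rep("high", length(reg))
  names(dir) <- reg
  dir[c("C0", "Met")] <- "low"
  dir
}

#' Build a cutoff set
#'
#' @param cutoffs data.frame with columns \code{marker}, \code{threshold},
#'   \code{direction} (\code{"high"}/\code{"low"}) and optionally \code{unit}
#'   and \code{center_id}.
#' @param center_id screening-center label (cutoffs are center-specific).
#' @return validated data.frame of class \code{"cutoff_set"}.
#' @export
as_cutoff_set <- function(cutoffs, center_id = NULL) {
  assert_columns(cutoffs, c("marker", "threshold", "direction"), "cutoffs")
  if (!is.null(center_id)) cutoffs <- cutoffs[cutoffs$center_id == center_id, ]
  if (anyDuplicated(cutoffs$marker)) {
    nbs_stop("one cutoff per marker per center", "nbs_validation_error")
  }
  unknown <- setdiff(cutoffs$marker, marker_registry())
  if (length(unknown)) {
    nbs_stop(paste("unknown marker(s):", paste(unknown, collapse = ", ")),
             "nbs_registry_error")
  }
  if (any(!is.finite(cutoffs$threshold)) || any(cutoffs$threshold <= 0)) {
    nbs_stop("cutoff thresholds must be positive", "nbs_validation_error")
  }
  if (!all(cutoffs$direction %in% c("high", "low"))) {
    nbs_stop("cutoff direction must be 'high' or 'low'",
             "nbs_validation_error")
  }
  class(cutoffs) <- c("cutoff_set", "data.frame")
  cutoffs
}

#' Reference cutoff set
#'
#' A single-center reference cutoff table assembled from the per-case cutoffs
#' printed for the diagnosed subjects, used as the simulator default. Real
#' screening centers each calibrate their own values.
#'
#' @return a \code{\link{as_cutoff_set}} object.
#' @export
reference_cutoffs <- function() {
  path <- system.file("extdata", "reference_cutoffs.tsv", package = "nbsdual",
                      mustWork = TRUE)
  as_cutoff_set(utils::read.delim(path, check.names = FALSE,
                                  stringsAsFactors = FALSE))
}

#' Is a marker value abnormal?
#'
#' Strict-inequality convention: a value exactly at its threshold is normal.
#' High-direction markers flag above the threshold, low-direction markers
#' below it.
#'
#' @param value non-negative numeric vector of marker values.
#' @param threshold positive cutoff(s).
#' @param direction \code{"high"} or \code{"low"} (recycled).
#' @return logical vector.
#' @examples
#' marker_abnormal(0.356, 0.2, "high") # TRUE
#' marker_abnormal(4.4, 4.5, "high")   # FALSE
#' @export
marker_abnormal <- function(value, threshold, direction) {
  if (any(value < 0, na.rm = TRUE)) {
    nbs_stop("marker values must be non-negative", "nbs_validation_error")
  }
  if (!all(direction %in% c("high", "low"))) {
    nbs_stop("direction must be 'high' or 'low'", "nbs_validation_error")
  }
  n <- max(length(value), length(threshold), length(direction))
  ifelse(rep_len(direction, n) == "high",
         rep_len(value, n) > rep_len(threshold, n),
         rep_len(value, n) < rep_len(threshold, n))
}

#' MS/MS screen positivity for one newborn
#'
#' Positive when at least one marker is abnormal against the center's
#' direction-aware cutoffs. Markers without a configured cutoff are skipped
#' with a warning.
#'
#' @param profile named numeric vector of marker values, or a data.frame with
#'   columns \code{marker} and \code{value}.
#' @param cutoffs a \code{\link{as_cutoff_set}} (or coercible data.frame).
#' @return list with \code{call} (\code{"positive"}/\code{"negative"}) and
#'   \code{flagged}, a data.frame of abnormal markers (marker, value,
#'   threshold, direction) sorted by marker name.
#' @examples
#' classify_msms(c(C0 = 6.78), as_cutoff_set(
#'   data.frame(marker = "C0", threshold = 10, direction = "low")))
#' @export
classify_msms <- function(profile, cutoffs) {
  if (is.data.frame(profile)) {
    assert_columns(profile, c("marker", "value"), "profile")
    profile <- stats::setNames(profile$value, profile$marker)
  }
  if (length(profile) == 0L) {
    nbs_stop("empty analyte profile", "nbs_validation_error")
  }
  unknown <- setdiff(names(profile), marker_registry())
  if (length(unknown)) {
    nbs_stop(paste("unknown marker(s):", paste(unknown, collapse = ", ")),
             "nbs_registry_error")
  }
  if (!inherits(cutoffs, "cutoff_set")) cutoffs <- as_cutoff_set(cutoffs)
  idx <- match(names(profile), cutoffs$marker)
  if (anyNA(idx)) {
    warning("no cutoff for marker(s): ",
            paste(names(profile)[is.na(idx)], collapse = ", "),
            "; skipped", call. = FALSE)
  }
  keep <- !is.na(idx)
  abn <- marker_abnormal(unname(profile[keep]),
                         cutoffs$threshold[idx[keep]],
                         cutoffs$direction[idx[keep]])
  flagged <- data.frame(marker = names(profile)[keep][abn],
                        value = unname(profile[keep][abn]),
                        threshold = cutoffs$threshold[idx[keep]][abn],
                        direction = cutoffs$direction[idx[keep]][abn],
                        stringsAsFactors = FALSE)
  flagged <- flagged[order(flagged$marker), , drop = FALSE]
  rownames(flagged) <- NULL
  list(call = if (nrow(flagged)) "positive" else "negative", flagged = flagged)
}

#' MS/MS screen positivity for a cohort
#'
#' Two input forms are supported: a long analyte table with a per-row
#' \code{cutoff} column (as printed in per-case screening reports, where each
#' subject's center supplies the threshold), or a plain value table classified
#' against a single \code{\link{as_cutoff_set}}. In the per-row form the
#' flagging direction is taken from the package's canonical per-marker
#' direction (see \code{marker_registry}).
#'
#' @param analytes long data.frame \code{subject_id}, \code{marker},
#'   \code{value} and optionally \code{cutoff}; or a numeric matrix with
#'   subjects as rows and markers as columns.
#' @param cutoffs optional \code{\link{as_cutoff_set}}; required unless
#'   \code{analytes} carries a \code{cutoff} column.
#' @return data.frame \code{subject_id}, \code{call}, \code{n_flagged},
#'   \code{flagged_markers} (comma-separated, sorted); positives counted in
#'   \code{attr(., "n_positive")}.
#' @export
classify_cohort_msms <- function(analytes, cutoffs = NULL) {
  if (is.matrix(analytes)) {
    if (is.null(cutoffs)) {
      nbs_stop("matrix input requires a cutoff set", "nbs_validation_error")
    }
    if (!inherits(cutoffs, "cutoff_set")) cutoffs <- as_cutoff_set(cutoffs)
    markers <- intersect(colnames(analytes), cutoffs$marker)
    idx <- match(markers, cutoffs$marker)
    flag <- vapply(seq_along(markers), function(j) {
      marker_abnormal(analytes[, markers[j]], cutoffs$threshold[idx[j]],
                      cutoffs$direction[idx[j]])
    }, logical(nrow(analytes)))
    flag <- matrix(flag, nrow = nrow(analytes),
                   dimnames = list(NULL, markers))
    n_flagged <- rowSums(flag)
    flagged_markers <- apply(flag, 1L, function(f)
      paste(sort(markers[f]), collapse = ","))
    out <- data.frame(subject_id = rownames(analytes),
                      call = ifelse(n_flagged > 0, "positive", "negative"),
                      n_flagged = as.integer(n_flagged),
                      flagged_markers = flagged_markers,
                      stringsAsFactors = FALSE)
    attr(out, "n_positive") <- sum(n_flagged > 0)
    return(out)
  }

  assert_columns(analytes, c("subject_id", "marker", "value"), "analytes")
  dirs <- marker_directions()
  per_row <- "cutoff" %in% names(analytes) && is.null(cutoffs)
  if (!per_row && is.null(cutoffs)) {
    nbs_stop("supply a cutoff set or a per-row cutoff column",
             "nbs_validation_error")
  }
  if (!per_row && !inherits(cutoffs, "cutoff_set")) {
    cutoffs <- as_cutoff_set(cutoffs)
  }
  ids <- unique(analytes$subject_id)
  rows <- lapply(ids, function(id) {
    a <- analytes[analytes$subject_id == id, , drop = FALSE]
    if (per_row) {
      keep <- !is.na(a$cutoff)
      cs <- as_cutoff_set(data.frame(marker = a$marker[keep],
                                     threshold = a$cutoff[keep],
                                     direction = unname(dirs[a$marker[keep]]),
                                     stringsAsFactors = FALSE))
      res <- classify_msms(stats::setNames(a$value[keep], a$marker[keep]), cs)
    } else {
      res <- classify_msms(stats::setNames(a$value, a$marker), cutoffs)
    }
    data.frame(subject_id = id, call = res$call,
               n_flagged = nrow(res$flagged),
               flagged_markers = paste(res$flagged$marker, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n_positive") <- sum(out$call == "positive")
  out
}
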