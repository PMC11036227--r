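#' Carrier frequency of a gene in a screened cohort
#'
#' A carrier is an unaffected subject with at least one qualifying
#' heterozygous allele in the gene. By default only P/LP alleles qualify
#' (\code{rule = "any_PLP_het"}); \code{rule = "any_variant"} also counts VUS
#' carriers. Subjects whose genotype in the gene is itself disease-causing
#' (homozygous or compound-heterozygous P/LP, hemizygous P/LP) are affected,
#' not carriers, and are excluded from the numerator unless
#' \code{include_affected = TRUE}.
#'
#' @param variants cohort variant table (\code{subject_id}, \code{gene},
#'   \code{variant_id}, \code{acmg_class}, \code{zygosity}).
#' @param gene gene symbol, which must be in \code{panel}.
#' @param n_screened cohort size (the denominator; the variant table is
#'   sparse and lists only subjects carrying something).
#' @param panel gene panel (see \code{\link{as_nbs_panel}}).
#' @param rule carrier counting rule.
#' @param include_affected count biallelic subjects in the numerator too.
#' @return one-row data.frame of class \code{"carrier_estimate"}:
#'   \code{gene}, \code{n_carriers}, \code{n_screened}, \code{frequency} and
#'   \code{one_in} (the half-up-rounded N of "1 in N").
#' @export
carrier_frequency <- function(variants, gene, n_screened, panel,
                              rule = c("any_PLP_het", "any_variant"),
                              include_affected = FALSE) {
  rule <- match.arg(rule)
  if (!inherits(panel, "nbs_panel")) panel <- as_nbs_panel(panel)
  if (!gene %in% panel$gene) {
    nbs_stop(paste("gene not in panel:", gene), "nbs_validation_error")
  }
  if (n_screened < 1) {
    nbs_stop("empty cohort", "nbs_validation_error")
  }
  v <- variants[variants$gene == gene, , drop = FALSE]
  n_carriers <- 0L
  if (nrow(v)) {
    per <- split(v, v$subject_id)
    status <- vapply(per, function(sv) {
      qual <- sv[sv$acmg_class %in% c("P", "LP"), , drop = FALSE]
      affected <- any(qual$zygosity %in% c("hom", "hemi")) ||
        length(unique(qual$variant_id[qual$zygosity == "het"])) >= 2L
      has_het <- if (rule == "any_PLP_het") {
        any(qual$zygosity == "het")
      } else {
        any(sv$zygosity == "het" & sv$acmg_class != "B")
      }
      if (affected) {
        if (include_affected) 1L else 0L
      } else if (has_het) 1L else 0L
    }, integer(1))
    n_carriers <- sum(status)
  }
  out <- data.frame(gene = gene, n_carriers = n_carriers,
                    n_screened = n_screened,
                    frequency = n_carriers / n_screened,
                    one_in = if (n_carriers >= 1)
                      round_half_up(n_screened / n_carriers) else NA,
                    stringsAsFactors = FALSE)
  class(out) <- c("carrier_estimate", "data.frame")
  out
}

#' Project disease incidence from a carrier frequency (Hardy-Weinberg)
#'
#' Under random mating the disease-allele frequency \eqn{q} relates to the
#' carrier frequency \eqn{c} through \eqn{c = 2q(1-q)}, and the expected
#' birth incidence of the recessive disease is \eqn{q^2}. The rare-disease
#' approximation takes \eqn{q = c/2}; the exact mode inverts the quadratic,
#' \eqn{q = (1 - \sqrt{1 - 2c})/2}, which requires \eqn{c \le 0.5}.
#'
#' @param c carrier frequency in (0, 1), e.g. \code{1/42}.
#' @param mode \code{"rare"} (default) or \code{"exact"}.
#' @return one-row data.frame: \code{carrier_frequency},
#'   \code{allele_frequency}, \code{incidence} and \code{one_in}
#'   (half-up-rounded reciprocal incidence).
#' @examples
#' hw_project_incidence(1 / 42)                  # 1 in 7056
#' hw_project_incidence(1 / 42, mode = "exact")  # 1 in 6887
#' @export
hw_project_incidence <- function(c, mode = c("rare", "exact")) {
  mode <- match.arg(mode)
  if (any(c <= 0 | c >= 1)) {
    nbs_stop("carrier frequency must lie in (0, 1)", "nbs_validation_error")
  }
  q <- if (mode == "rare") {
    c / 2
  } else {
    if (any(c > 0.5)) {
      nbs_stop("exact Hardy-Weinberg inversion needs c <= 0.5",
               "nbs_validation_error")
    }
    (1 - sqrt(1 - 2 * c)) / 2
  }
  inc <- q^2
  data.frame(carrier_frequency = c, allele_frequency = q, incidence = inc,
             one_in = round_half_up(1 / inc), mode = mode,
             stringsAsFactors = FALSE)
}

#' Variant spectrum (hotspot tally) for a gene
#'
#' Counts observed alleles per variant (homozygotes contribute two), sorted
#' by descending allele count with lexicographic tie-break, with an optional
#' per-center breakdown.
#'
#' @param variants cohort variant table; a \code{center_id} column enables
#'   the geographic breakdown.
#' @param gene gene symbol.
#' @param top_n number of top variants to keep (all if fewer observed).
#' @return data.frame \code{gene}, \code{variant_id}, \code{n_alleles}; when
#'   centers are available, the per-center allele-count matrix is attached as
#'   \code{attr(., "by_center")}.
#' @export
variant_spectrum <- function(variants, gene, top_n = 10) {
  if (top_n < 1) nbs_stop("top_n must be >= 1", "nbs_validation_error")
  v <- variants[variants$gene == gene, , drop = FALSE]
  if (nrow(v) == 0L) {
    return(data.frame(gene = character(), variant_id = character(),
                      n_alleles = integer(), stringsAsFactors = FALSE))
  }
  w <- ifelse(v$zygosity == "hom", 2L, 1L)
  counts <- tapply(w, v$variant_id, sum)
  ord <- order(-counts, names(counts))
  counts <- counts[ord]
  keep <- utils::head(seq_along(counts), top_n)
  out <- data.frame(gene = gene, variant_id = names(counts)[keep],
                    n_alleles = as.integer(counts[keep]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  if ("center_id" %in% names(v)) {
    bc <- tapply(w, list(v$variant_id, v$center_id), sum, default = 0L)
    attr(out, "by_center") <- bc[out$variant_id, , drop = FALSE]
  }
  out
}
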