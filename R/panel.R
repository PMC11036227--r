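#' Validate a gene panel specification
#'
#' A panel describes, for each screened gene, its inheritance mode (autosomal
#' recessive \code{"AR"} or X-linked \code{"XL"}), whether it is covered by the
#' sequencing assay (\code{in_panel}), the disease it causes and a coarse
#' disease group (amino acid / organic acid / fatty acid oxidation disorder).
#' Genes with \code{in_panel = FALSE} can appear in variant tables (e.g. found
#' later by exome sequencing) but never trigger a genetic screen-positive call.
#'
#' @param panel data.frame with columns \code{gene}, \code{inheritance},
#'   \code{in_panel}, \code{disease}, \code{group}.
#' @param xl_female_het_positive logical; treat heterozygous females as
#'   positive for XL genes. The default \code{FALSE} reflects the usual
#'   recessive interpretation of X-linked screening findings.
#' @return the validated panel with class \code{"nbs_panel"} and the
#'   \code{xl_female_het_positive} policy stored as an attribute.
#' @examples
#' as_nbs_panel(data.frame(gene = "PAH", inheritance = "AR",
#'                         in_panel = TRUE, disease = "PKU", group = "AA"))
#' @export
as_nbs_panel <- function(panel, xl_female_het_positive = FALSE) {
  assert_columns(panel, c("gene", "inheritance", "in_panel", "disease"),
                 "panel")
  if (!"group" %in% names(panel)) panel$group <- "other"
  if (anyDuplicated(panel$gene)) {
    nbs_stop("duplicated gene symbol in panel", "nbs_validation_error")
  }
  if (any(!nzchar(panel$gene)) || anyNA(panel$gene)) {
    nbs_stop("empty gene symbol in panel", "nbs_validation_error")
  }
  if (!all(panel$inheritance %in% c("AR", "XL"))) {
    nbs_stop("panel inheritance must be 'AR' or 'XL'", "nbs_validation_error")
  }
  panel$in_panel <- as.logical(panel$in_panel)
  if (anyNA(panel$in_panel)) {
    nbs_stop("panel in_panel must be TRUE/FALSE", "nbs_validation_error")
  }
  structure(panel,
            class = c("nbs_panel", "data.frame"),
            xl_female_het_positive = isTRUE(xl_female_het_positive))
}

#' Default gene panel used by the fixtures and the simulator
#'
#' Covers the eleven genes seen among the diagnosed subjects (ETFA off-panel,
#' as it was absent from the sequencing assay) plus PRODH, ACADSB and the
#' X-linked OTC, which occur among genotype-positive but biochemically normal
#' newborns.
#'
#' @return an \code{\link{as_nbs_panel}}-validated panel.
#' @export
default_panel <- function() {
  path <- system.file("extdata", "panel.tsv", package = "nbsdual",
                      mustWork = TRUE)
  as_nbs_panel(utils::read.delim(path, stringsAsFactors = FALSE))
}
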