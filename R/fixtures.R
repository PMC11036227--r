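#' Load packaged study fixtures
#'
#' Small plain-text tables shipped with the package: per-disease incidence
#' and carrier frequencies (\code{"table1"}), per-center screening counts for
#' both platforms (\code{"table2"}), and the 23 diagnosed subjects'
#' genotypes, analyte values with their printed cutoffs, screen calls and
#' diagnoses (\code{"table3"}). \code{"panel"} and \code{"cutoffs"} return
#' the default gene panel and reference cutoff set.
#'
#' Fixtures are schema-validated on load: table3 must hold exactly 23
#' subjects and table2 center sizes must sum to 29,601.
#'
#' @param name one of \code{"table1"}, \code{"table2"}, \code{"table3"},
#'   \code{"panel"}, \code{"cutoffs"}.
#' @return a data.frame, or for \code{"table3"} a list with \code{subjects},
#'   \code{variants} and \code{analytes}.
#' @examples
#' t3 <- load_fixtures("table3")
#' nrow(t3$subjects) # 23
#' @export
load_fixtures <- function(name = c("table1", "table2", "table3", "panel",
                                   "cutoffs")) {
  name <- match.arg(name)
  rd <- function(f) {
    utils::read.delim(system.file("extdata", f, package = "nbsdual",
                                  mustWork = TRUE),
                      check.names = FALSE, stringsAsFactors = FALSE)
  }
  switch(name,
    table1 = {
      t1 <- rd("table1_incidence.tsv")
      assert_columns(t1, c("disease", "gene", "n_cases", "incidence_n",
                           "carrier_n"), "table1")
      if (sum(t1$n_cases) != 23L) {
        nbs_stop("table1 fixture must total 23 cases", "nbs_fixture_error")
      }
      t1
    },
    table2 = {
      t2 <- rd("table2_performance.tsv")
      assert_columns(t2, c("center", "n_screened", "msms_positive",
                           "msms_recalled", "msms_confirmed",
                           "msms_false_negative", "ngs_positive",
                           "ngs_recalled", "ngs_confirmed",
                           "ngs_false_negative"), "table2")
      if (sum(t2$n_screened) != 29601L) {
        nbs_stop("table2 center totals must sum to 29,601",
                 "nbs_fixture_error")
      }
      t2
    },
    table3 = {
      subjects <- rd("table3_subjects.tsv")
      variants <- rd("table3_variants.tsv")
      analytes <- rd("table3_analytes.tsv")
      assert_columns(subjects, c("subject_id", "sex", "ngs_call",
                                 "msms_call", "disorder", "confirmed"),
                     "table3 subjects")
      assert_columns(variants, c("subject_id", "gene", "variant_id",
                                 "acmg_class", "zygosity"),
                     "table3 variants")
      assert_columns(analytes, c("subject_id", "phase", "marker", "value",
                                 "cutoff", "unit"), "table3 analytes")
      if (nrow(subjects) != 23L) {
        nbs_stop("table3 fixture must hold exactly 23 subjects",
                 "nbs_fixture_error")
      }
      if (!all(variants$subject_id %in% subjects$subject_id) ||
          !all(analytes$subject_id %in% subjects$subject_id)) {
        nbs_stop("table3 cross-references broken", "nbs_fixture_error")
      }
      list(subjects = subjects, variants = variants, analytes = analytes)
    },
    panel = default_panel(),
    cutoffs = reference_cutoffs()
  )
}
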