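# Tabular readers/writers: UTF-8 TSV with declared headers, decimal point.

#' Read and write the package's TSV formats
#'
#' Thin wrappers over [utils::read.delim()] / [utils::write.table()] that fix
#' the dialect (tab-separated, header, no quoting, no row names) so that a
#' write followed by a read is the identity on records.
#'
#' @param path file path.
#' @param x data.frame to write.
#' @param required character vector of columns that must be present.
#' @return \code{read_tsv}: a data.frame. \code{write_tsv}: \code{path},
#'   invisibly.
#' @export
read_tsv <- function(path, required = NULL) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8")
  if (!is.null(required)) assert_columns(df, required, path)
  df
}

#' @rdname read_tsv
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname read_tsv
#' @export
read_variant_table <- function(path) {
  read_tsv(path, c("subject_id", "gene", "variant_id", "acmg_class",
                   "zygosity"))
}

#' @rdname read_tsv
#' @export
read_analyte_table <- function(path) {
  read_tsv(path, c("subject_id", "marker", "value"))
}

#' @rdname read_tsv
#' @export
read_cutoff_table <- function(path) {
  as_cutoff_set(read_tsv(path, c("marker", "threshold", "direction")))
}

#' @rdname read_tsv
#' @export
read_panel_table <- function(path) {
  as_nbs_panel(read_tsv(path, c("gene", "inheritance", "in_panel",
                                "disease")))
}
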