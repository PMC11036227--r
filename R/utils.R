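#' Round half away from zero
#'
#' Screening reports conventionally round 5 upward (2.445 -> 2.45), whereas
#' [base::round()] rounds half to even. Used for every printed percentage and
#' for "1 in N" reciprocals.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up.
#' @examples
#' round_half_up(2.445, 2) # 2.45
#' round_half_up(14800.5)  # 14801
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  # tolerance absorbs binary representation error (2.445 * 100 is stored as
  # 244.4999...), so printed halves round up as intended
  sign(x) * floor(abs(x) * scale + 0.5 + sqrt(.Machine$double.eps)) / scale
}

# stop() with a consistent condition class so callers can test errors precisely
nbs_stop <- function(msg, class) {
  stop(structure(
    class = c(class, "nbs_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

assert_columns <- function(df, cols, what) {
  if (!is.data.frame(df)) {
    nbs_stop(sprintf("%s must be a data.frame", what), "nbs_validation_error")
  }
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    nbs_stop(sprintf("%s is missing column(s): %s", what,
                     paste(missing, collapse = ", ")),
             "nbs_validation_error")
  }
  invisible(df)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
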