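#' Count qualifying alleles in one gene
#'
#' A qualifying allele is a pathogenic (P) or likely pathogenic (LP) allele.
#' Homozygous calls contribute two alleles; heterozygous and hemizygous calls
#' one. Variants of uncertain significance (VUS) and (likely) benign variants
#' never contribute, no matter what they are paired with.
#'
#' @param variants data.frame of variant calls for a single subject and a
#'   single gene, with columns \code{gene}, \code{variant_id},
#'   \code{acmg_class} (\code{P}, \code{LP}, \code{VUS}, \code{LB}, \code{B})
#'   and \code{zygosity} (\code{het}, \code{hom}, \code{hemi}).
#' @return integer number of qualifying alleles.
#' @examples
#' qualifying_allele_count(data.frame(gene = "MMAA", variant_id = "c.365T>C",
#'                                    acmg_class = "LP", zygosity = "hom"))
#' @export
qualifying_allele_count <- function(variants) {
  if (nrow(variants) == 0L) return(0L)
  assert_columns(variants, c("gene", "variant_id", "acmg_class", "zygosity"),
                 "variants")
  if (length(unique(variants$gene)) > 1L) {
    nbs_stop("qualifying_allele_count expects variants from a single gene",
             "nbs_contract_error")
  }
  if (anyDuplicated(variants$variant_id)) {
    nbs_stop("duplicated variant_id within a subject-gene pair",
             "nbs_validation_error")
  }
  qual <- variants$acmg_class %in% c("P", "LP")
  sum(ifelse(qual, ifelse(variants$zygosity == "hom", 2L, 1L), 0L))
}

# per-gene positivity rule given inheritance, sex and the gene's variant rows
.gene_triggers <- function(variants, inheritance, sex,
                           xl_female_het_positive = FALSE) {
  n_qual <- qualifying_allele_count(variants)
  qual <- variants[variants$acmg_class %in% c("P", "LP"), , drop = FALSE]
  if (inheritance == "AR") {
    # biallelic: a homozygote, or two distinct het P/LP alleles assumed in trans
    hit <- any(qual$zygosity == "hom") ||
      length(unique(qual$variant_id[qual$zygosity == "het"])) >= 2L
  } else { # XL
    if (identical(sex, "M")) {
      hit <- n_qual >= 1L
    } else {
      hit <- any(qual$zygosity == "hom") ||
        (xl_female_het_positive && n_qual >= 1L)
    }
  }
  list(hit = hit, n_qual = n_qual)
}

#' Genotype-based screen positivity for one newborn
#'
#' A subject is screen-positive when some in-panel gene carries pathogenic or
#' likely pathogenic (P/LP) variation matching that gene's inheritance
#' pattern: for autosomal recessive genes a homozygous P/LP variant or two
#' distinct heterozygous P/LP variants (assumed in trans, phase being
#' unobserved); for X-linked genes a single qualifying allele in males and a
#' homozygous genotype in females. VUS alleles never qualify, and off-panel
#' genes never trigger.
#'
#' @param variants data.frame of this subject's variant calls (columns
#'   \code{gene}, \code{variant_id}, \code{acmg_class}, \code{zygosity}); may
#'   have zero rows.
#' @param sex \code{"M"} or \code{"F"}.
#' @param panel an \code{\link{as_nbs_panel}} object (or coercible
#'   data.frame).
#' @return a one-row data.frame: \code{call} (\code{"positive"} /
#'   \code{"negative"}), \code{triggering_gene} (first triggering gene in
#'   lexicographic order, \code{NA} if negative), \code{qualifying_alleles}
#'   for that gene, and a human-readable \code{reason} listing every
#'   triggering gene.
#' @examples
#' panel <- default_panel()
#' v <- data.frame(gene = "MMACHC", variant_id = "c.658_660delAAG",
#'                 acmg_class = "P", zygosity = "hom")
#' classify_genetic(v, sex = "M", panel = panel)
#' @export
classify_genetic <- function(variants, sex, panel) {
  if (!inherits(panel, "nbs_panel")) panel <- as_nbs_panel(panel)
  xl_pol <- isTRUE(attr(panel, "xl_female_het_positive"))
  if (!sex %in% c("M", "F")) {
    nbs_stop("sex must be 'M' or 'F'", "nbs_validation_error")
  }
  if (nrow(variants)) {
    assert_columns(variants, c("gene", "variant_id", "acmg_class", "zygosity"),
                   "variants")
    inh <- panel$inheritance[match(variants$gene, panel$gene)]
    bad_hemi <- variants$zygosity == "hemi" &
      (sex == "F" | is.na(inh) | inh != "XL")
    if (any(bad_hemi)) {
      nbs_stop("hemizygous call outside an XL gene in a male subject",
               "nbs_validation_error")
    }
  }
  neg <- data.frame(call = "negative", triggering_gene = NA_character_,
                    qualifying_alleles = 0L, reason = "no qualifying genotype",
                    stringsAsFactors = FALSE)
  if (nrow(variants) == 0L) return(neg)

  genes <- sort(intersect(unique(variants$gene),
                          panel$gene[panel$in_panel]))
  hits <- list()
  for (g in genes) {
    res <- .gene_triggers(variants[variants$gene == g, , drop = FALSE],
                          panel$inheritance[panel$gene == g], sex, xl_pol)
    if (res$hit) hits[[g]] <- res$n_qual
  }
  if (!length(hits)) return(neg)
  first <- names(hits)[1L] # genes already lexicographically sorted
  data.frame(call = "positive", triggering_gene = first,
             qualifying_alleles = as.integer(hits[[first]]),
             reason = paste0("qualifying genotype in: ",
                             paste(names(hits), collapse = ", ")),
             stringsAsFactors = FALSE)
}

#' Genotype-based screen positivity for a cohort
#'
#' Applies \code{\link{classify_genetic}} to every subject, preserving subject
#' order. Subjects listed in \code{subjects} but absent from \code{variants}
#' are variant-free and therefore negative.
#'
#' @param variants data.frame of variant calls with columns
#'   \code{subject_id}, \code{gene}, \code{variant_id}, \code{acmg_class},
#'   \code{zygosity} and, unless \code{subjects} supplies it, \code{sex}.
#' @param panel gene panel (see \code{\link{as_nbs_panel}}).
#' @param subjects optional data.frame \code{subject_id}, \code{sex} defining
#'   the cohort; defaults to the subjects present in \code{variants}.
#' @return data.frame with one row per subject (\code{subject_id},
#'   \code{call}, \code{triggering_gene}, \code{qualifying_alleles},
#'   \code{reason}); the number of positives is available as
#'   \code{attr(., "n_positive")}.
#' @export
classify_cohort_genetic <- function(variants, panel, subjects = NULL) {
  if (!inherits(panel, "nbs_panel")) panel <- as_nbs_panel(panel)
  if (is.null(subjects)) {
    assert_columns(variants, c("subject_id", "sex"), "variants")
    subjects <- unique(variants[, c("subject_id", "sex")])
  }
  assert_columns(subjects, c("subject_id", "sex"), "subjects")
  if (anyDuplicated(subjects$subject_id)) {
    nbs_stop("duplicate subject_id in cohort", "nbs_validation_error")
  }
  if (nrow(subjects) == 0L) {
    out <- data.frame(subject_id = character(), call = character(),
                      triggering_gene = character(),
                      qualifying_alleles = integer(), reason = character(),
                      stringsAsFactors = FALSE)
    attr(out, "n_positive") <- 0L
    return(out)
  }
  # variant-free subjects are negative by construction; classify only the
  # (sparse) subset actually carrying variant calls
  out <- data.frame(subject_id = subjects$subject_id, call = "negative",
                    triggering_gene = NA_character_,
                    qualifying_alleles = 0L,
                    reason = "no qualifying genotype",
                    stringsAsFactors = FALSE)
  with_var <- intersect(subjects$subject_id, variants$subject_id)
  if (length(with_var)) {
    v <- variants[variants$subject_id %in% with_var, , drop = FALSE]
    vsplit <- split(v, factor(v$subject_id, levels = with_var))
    sex <- subjects$sex[match(with_var, subjects$subject_id)]
    rows <- lapply(seq_along(with_var), function(i)
      classify_genetic(vsplit[[i]], sex[i], panel))
    res <- do.call(rbind, rows)
    idx <- match(with_var, out$subject_id)
    out[idx, c("call", "triggering_gene", "qualifying_alleles", "reason")] <-
      res
  }
  rownames(out) <- NULL
  attr(out, "n_positive") <- sum(out$call == "positive")
  out
}
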