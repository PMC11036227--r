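# Independent brute-force oracle for genotype-based screen positivity:
# enumerates disease-causing allele configurations directly (single
# homozygote, or an explicit pair scan over distinct heterozygous P/LP
# variants) instead of counting qualifying alleles.
oracle_genetic_positive <- function(variants, sex, panel) {
  genes <- unique(variants$gene)
  for (g in genes) {
    sp <- panel[panel$gene == g, ]
    if (nrow(sp) == 0L || !sp$in_panel) next
    v <- variants[variants$gene == g &
                    variants$acmg_class %in% c("P", "LP"), , drop = FALSE]
    if (nrow(v) == 0L) next
    if (sp$inheritance == "XL" && sex == "M") {
      return(TRUE) # any qualifying allele suffices in a hemizygous male
    }
    if (any(v$zygosity == "hom")) return(TRUE)
    if (sp$inheritance == "AR") {
      hets <- v$variant_id[v$zygosity == "het"]
      if (length(hets) >= 2L) {
        for (i in seq_along(hets)) {
          for (j in seq_along(hets)) {
            if (i < j && hets[i] != hets[j]) return(TRUE)
          }
        }
      }
    }
  }
  FALSE
}

# every genotype of <= 3 variants in one gene over the given class/zygosity
# alphabet, as a list of variant-call data.frames
enumerate_genotypes <- function(gene, classes = c("P", "LP", "VUS"),
                                zygosities = c("het", "hom")) {
  slot_opts <- c(list(NULL), as.list(as.data.frame(t(
    expand.grid(acmg_class = classes, zygosity = zygosities,
                stringsAsFactors = FALSE)), stringsAsFactors = FALSE)))
  combos <- expand.grid(s1 = seq_along(slot_opts), s2 = seq_along(slot_opts),
                        s3 = seq_along(slot_opts))
  lapply(seq_len(nrow(combos)), function(k) {
    rows <- list()
    for (slot in 1:3) {
      opt <- slot_opts[[combos[k, slot]]]
      if (!is.null(opt)) {
        rows[[length(rows) + 1L]] <- data.frame(
          gene = gene, variant_id = paste0("c.", slot, "00A>G"),
          acmg_class = opt[1], zygosity = opt[2], stringsAsFactors = FALSE)
      }
    }
    if (length(rows)) do.call(rbind, rows) else
      data.frame(gene = character(), variant_id = character(),
                 acmg_class = character(), zygosity = character(),
                 stringsAsFactors = FALSE)
  })
}

# small panels used across tests
test_panel <- function() {
  as_nbs_panel(data.frame(
    gene = c("ARG1", "XLG1", "OFFP"),
    inheritance = c("AR", "XL", "AR"),
    in_panel = c(TRUE, TRUE, FALSE),
    disease = c("d1", "d2", "d3"),
    group = "other", stringsAsFactors = FALSE))
}

fixture_table3 <- function() load_fixtures("table3")

# primary-screen analytes for the 23 diagnosed subjects
fixture_primary <- function() {
  a <- fixture_table3()$analytes
  a[a$phase == "primary", , drop = FALSE]
}
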