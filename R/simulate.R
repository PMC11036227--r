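#' Default per-gene simulation parameters
#'
#' Carrier frequencies follow the headline estimates for the most frequently
#' carried screening genes (PAH 1/42, PRODH 1/51, MMACHC 1/52, SLC25A13 1/55,
#' SLC22A5 1/63) and the per-disease "1 in N" carrier figures for the rarer
#' genes; ETFA is off-panel and OTC is X-linked. \code{markers} names the
#' disease's primary MS/MS indicators. VUS allele frequencies are a few per
#' mille, reflecting that panels report uncertain variants far more often
#' than P/LP ones.
#'
#' @return data.frame \code{gene}, \code{inheritance}, \code{in_panel},
#'   \code{disease}, \code{carrier_freq}, \code{vus_freq}, \code{markers}.
#' @export
default_gene_params <- function() {
  data.frame(
    gene = c("PAH", "PRODH", "MMACHC", "SLC25A13", "SLC22A5", "ACADS",
             "ACAD8", "ACADM", "CPT2", "MMAA", "DBT", "ETFA", "OTC"),
    inheritance = c(rep("AR", 12), "XL"),
    in_panel = c(rep(TRUE, 11), FALSE, TRUE),
    disease = c("PKU", "HPRO", "cblC-MMA", "NICCD", "PCD", "SCADD", "IBD",
                "MCAD", "CPTII", "cblA-MMA", "MSUD", "MADD", "OTCD"),
    carrier_freq = c(1 / 42, 1 / 51, 1 / 52, 1 / 55, 1 / 63, 1 / 127,
                     1 / 211, 1 / 251, 1 / 580, 1 / 1139, 1 / 1480,
                     1 / 1000, 2e-4),
    vus_freq = c(0.004, 0.003, 0.003, 0.003, 0.003, 0.002, 0.002, 0.001,
                 0.001, 0.001, 0.001, 0.001, 0.0005),
    markers = c("Phe,Phe/Tyr", "Pro", "C3,C3/C2", "Cit", "C0", "C4,C4/C3",
                "C4,C4/C3", "C8,C8/C10", "C16,C18:1", "C3,C3/C2", "Leu,Val",
                "C5,C8", "Cit"),
    stringsAsFactors = FALSE
  )
}

#' Default hotspot variant catalogue for the simulator
#'
#' Relative frequencies of P/LP alleles per gene, seeded with the hotspot
#' variants reported for the healthy population (e.g. MMACHC c.609G>A,
#' c.658_660delAAG, c.482G>A; SLC22A5 c.1400C>G, c.51C>G).
#'
#' @return data.frame \code{gene}, \code{variant_id}, \code{acmg_class},
#'   \code{rel_freq}.
#' @export
default_variant_catalogue <- function() {
  spec1 <- c(
    "PAH c.728G>A P .35", "PAH c.721C>T P .20", "PAH c.611A>G P .15",
    "PAH c.331C>T P .10", "PAH c.1197A>T P .10", "PAH c.1238G>C P .10",
    "PRODH c.1322T>C LP .6", "PRODH c.273+1G>C P .4",
    "MMACHC c.609G>A LP .45", "MMACHC c.658_660delAAG P .20",
    "MMACHC c.482G>A LP .15", "MMACHC c.80A>G LP .20",
    "SLC25A13 c.852_855delTATG P .5", "SLC25A13 c.790G>A P .3",
    "SLC25A13 c.1638_1660dup P .2",
    "SLC22A5 c.1400C>G P .5", "SLC22A5 c.51C>G LP .25",
    "SLC22A5 c.760C>T P .15", "SLC22A5 c.428C>T P .10",
    "ACADS c.1031A>G P .6", "ACADS c.322G>A LP .4",
    "ACAD8 c.413delA P .5", "ACAD8 c.289G>A LP .5",
    "ACADM c.946-1G>C LP .5", "ACADM c.1085G>A LP .5",
    "CPT2 c.338C>T P .6", "CPT2 c.886C>T P .4",
    "MMAA c.365T>C LP 1",
    "DBT c.75_76delAT P 1",
    "ETFA c.369G>A P .5", "ETFA c.659delC P .5",
    "OTC c.830G>A P 1"
  )
  m <- do.call(rbind, strsplit(spec1, " "))
  data.frame(gene = m[, 1], variant_id = m[, 2], acmg_class = m[, 3],
             rel_freq = as.numeric(m[, 4]), stringsAsFactors = FALSE)
}

#' Configure a synthetic newborn cohort
#'
#' The defaults emulate the study conditions of a multicenter dual-platform
#' screening cohort: eight centers with their observed sizes and MS/MS recall
#' rates, per-gene P/LP allele frequencies derived from the printed carrier
#' frequencies (rare approximation \eqn{q = c/2} by default), incomplete
#' biochemical penetrance (17/24: genotype-positive but biochemically normal
#' newborns become genetic-screen false positives), an attenuation
#' probability (2/23: diseased newborns whose primary markers stay within
#' cutoffs and are missed by MS/MS), a VUS-second-allele share among affected
#' genotypes (5/23: true cases invisible to the genetic rule because one
#' allele is uncertain), one off-panel disease gene, and a background
#' per-subject MS/MS false-positive rate of 1.64% chosen so the overall
#' positive rate lands near 1.71%.
#'
#' @param n_newborns cohort size.
#' @param seed integer seed governing all randomness.
#' @param centers data.frame \code{center_id}, \code{weight},
#'   \code{recall_prob}; weights must sum to 1.
#' @param genes per-gene parameters (see \code{\link{default_gene_params}}).
#' @param catalogue P/LP variant catalogue
#'   (see \code{\link{default_variant_catalogue}}).
#' @param sex_ratio probability a newborn is male.
#' @param penetrance_biochemical probability an affected genotype shows
#'   shifted analytes (and true disease).
#' @param attenuation_prob probability a diseased newborn's primary markers
#'   stay within cutoffs at first screening.
#' @param vus_case_share share of affected genotypes whose second allele is
#'   reported as VUS, making them genetic-screen negative by construction.
#' @param msms_fp_rate per-subject probability that a healthy profile crosses
#'   at least one cutoff.
#' @param hw_mode how allele frequencies are derived from carrier
#'   frequencies: \code{"rare"} (\eqn{q = c/2}) or \code{"exact"}.
#' @return validated list of class \code{"cohort_config"}.
#' @export
cohort_config <- function(n_newborns, seed = 1L,
                          centers = NULL,
                          genes = default_gene_params(),
                          catalogue = default_variant_catalogue(),
                          sex_ratio = 0.5,
                          penetrance_biochemical = 17 / 24,
                          attenuation_prob = 2 / 23,
                          vus_case_share = 5 / 23,
                          msms_fp_rate = 0.0164,
                          hw_mode = c("rare", "exact")) {
  hw_mode <- match.arg(hw_mode)
  if (is.null(centers)) {
    n <- c(SH = 4888, GZ = 4813, JN = 4797, SJZ = 4899, CQ = 2988,
           YN = 3006, NMG = 3233, HN = 977)
    rp <- c(SH = .872, GZ = .94, JN = .926, SJZ = .97, CQ = .733, YN = .93,
            NMG = .3186, HN = 1)
    centers <- data.frame(center_id = names(n), weight = unname(n) / sum(n),
                          recall_prob = unname(rp), stringsAsFactors = FALSE)
  }
  assert_columns(centers, c("center_id", "weight", "recall_prob"), "centers")
  if (abs(sum(centers$weight) - 1) > 1e-8) {
    nbs_stop("center weights must sum to 1", "nbs_validation_error")
  }
  probs <- c(sex_ratio, penetrance_biochemical, attenuation_prob,
             vus_case_share, msms_fp_rate, centers$recall_prob)
  if (any(probs < 0 | probs > 1)) {
    nbs_stop("all probabilities must lie in [0, 1]", "nbs_validation_error")
  }
  assert_columns(genes, c("gene", "inheritance", "in_panel", "disease",
                          "carrier_freq", "vus_freq", "markers"), "genes")
  if (any(genes$carrier_freq < 0 | genes$carrier_freq >= 1)) {
    nbs_stop("carrier frequencies must lie in [0, 1)", "nbs_validation_error")
  }
  genes$q <- if (hw_mode == "rare") {
    genes$carrier_freq / 2
  } else {
    if (any(genes$carrier_freq > 0.5)) {
      nbs_stop("exact Hardy-Weinberg inversion needs carrier frequency <= 0.5",
               "nbs_validation_error")
    }
    (1 - sqrt(1 - 2 * genes$carrier_freq)) / 2
  }
  if (any(genes$q > 0.5)) {
    nbs_stop("P/LP allele frequency q must be <= 0.5", "nbs_validation_error")
  }
  if (any(genes$q + genes$vus_freq > 1)) {
    nbs_stop("allele frequencies exceed 1", "nbs_validation_error")
  }
  structure(list(n_newborns = as.integer(n_newborns), seed = as.integer(seed),
                 centers = centers, genes = genes, catalogue = catalogue,
                 sex_ratio = sex_ratio,
                 penetrance_biochemical = penetrance_biochemical,
                 attenuation_prob = attenuation_prob,
                 vus_case_share = vus_case_share,
                 msms_fp_rate = msms_fp_rate, hw_mode = hw_mode),
            class = "cohort_config")
}

#' Panel implied by a cohort configuration
#' @param config a \code{\link{cohort_config}}.
#' @return an \code{\link{as_nbs_panel}} object.
#' @export
config_panel <- function(config) {
  as_nbs_panel(data.frame(gene = config$genes$gene,
                          inheritance = config$genes$inheritance,
                          in_panel = config$genes$in_panel,
                          disease = config$genes$disease,
                          group = "other", stringsAsFactors = FALSE))
}

# sample allele classes for n alleles: 0 ref, 1 P/LP, 2 VUS
.draw_alleles <- function(n, q, v) {
  u <- stats::runif(n)
  ifelse(u < q, 1L, ifelse(u < q + v, 2L, 0L))
}

# sample variant ids for a vector of allele classes (1 P/LP from the
# catalogue, 2 VUS from a fixed generated trio)
.draw_ids <- function(class, gene, catalogue) {
  ids <- character(length(class))
  n_plp <- sum(class == 1L)
  if (n_plp) {
    cat_g <- catalogue[catalogue$gene == gene, , drop = FALSE]
    if (nrow(cat_g) == 0L) {
      nbs_stop(paste("no catalogue variants for gene", gene),
               "nbs_config_error")
    }
    ids[class == 1L] <- sample(cat_g$variant_id, n_plp, replace = TRUE,
                               prob = cat_g$rel_freq)
  }
  n_vus <- sum(class == 2L)
  if (n_vus) {
    ids[class == 2L] <- sample(paste0("c.", c(1501, 1502, 1503), "G>A"),
                               n_vus, replace = TRUE)
  }
  ids
}

#' Simulate cohort genotypes
#'
#' Per autosomal-recessive gene, two alleles are drawn independently per
#' subject with P/LP probability \eqn{q} and VUS probability \eqn{v}; per
#' X-linked gene, one allele for males (hemizygous) and two for females.
#' Variant identities are drawn from the hotspot catalogue. A subject is
#' genotype-affected when carrying a biallelic (or male hemizygous) P/LP
#' genotype; a configured share of affected genotypes has its second allele
#' downgraded to VUS, leaving true disease in place but hiding it from the
#' genetic rule.
#'
#' @param config a \code{\link{cohort_config}}. Randomness comes from the
#'   current RNG state (\code{\link{simulate_cohort}} seeds it).
#' @return list with \code{subjects} (subject_id, sex, center_id),
#'   \code{variants} (sparse variant-call table) and \code{truth}
#'   (subject_id, gene, disease, genotype_affected, vus_masked).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_newborns
  subjects <- data.frame(
    subject_id = sprintf("S%06d", seq_len(n)),
    sex = ifelse(stats::runif(n) < config$sex_ratio, "M", "F"),
    center_id = if (n) sample(config$centers$center_id, n, replace = TRUE,
                              prob = config$centers$weight) else character(),
    stringsAsFactors = FALSE
  )
  var_list <- list()
  truth_list <- list()
  for (i in seq_len(nrow(config$genes))) {
    g <- config$genes[i, ]
    male <- subjects$sex == "M"
    a1 <- .draw_alleles(n, g$q, g$vus_freq)
    a2 <- .draw_alleles(n, g$q, g$vus_freq)
    if (g$inheritance == "XL") a2[male] <- 0L
    carrier_idx <- which(a1 > 0L | a2 > 0L)
    if (!length(carrier_idx)) next
    affected <- if (g$inheritance == "AR") {
      a1 == 1L & a2 == 1L
    } else {
      (male & a1 == 1L) | (!male & a1 == 1L & a2 == 1L)
    }
    vus_masked <- affected & g$inheritance == "AR" &
      stats::runif(n) < config$vus_case_share
    a2[vus_masked] <- 2L

    cat_g <- config$catalogue[config$catalogue$gene == g$gene, , drop = FALSE]
    cls_of <- function(class, id) ifelse(class == 1L,
      cat_g$acmg_class[match(id, cat_g$variant_id)], "VUS")
    # allele-level draws for the (sparse) carrier subset, then collapse
    # matching allele pairs into homozygous rows
    id1 <- id2 <- rep(NA_character_, n)
    id1[a1 > 0L] <- .draw_ids(a1[a1 > 0L], g$gene, config$catalogue)
    id2[a2 > 0L] <- .draw_ids(a2[a2 > 0L], g$gene, config$catalogue)
    hom <- a1 > 0L & a1 == a2 & !is.na(id1) & id1 == id2
    hemi <- g$inheritance == "XL" & male
    mk <- function(idx, id, class, zyg) {
      if (!length(idx)) return(NULL)
      data.frame(subject_id = subjects$subject_id[idx], gene = g$gene,
                 variant_id = id[idx], acmg_class = cls_of(class[idx],
                                                           id[idx]),
                 zygosity = zyg, stringsAsFactors = FALSE)
    }
    var_list[[g$gene]] <- rbind(
      mk(which(hom), id1, a1, "hom"),
      mk(which(a1 > 0L & !hom & hemi), id1, a1, "hemi"),
      mk(which(a1 > 0L & !hom & !hemi), id1, a1, "het"),
      mk(which(a2 > 0L & !hom), id2, a2, "het"))
    aff_idx <- which(affected)
    if (length(aff_idx)) {
      truth_list[[g$gene]] <- data.frame(
        subject_id = subjects$subject_id[aff_idx], gene = g$gene,
        disease = g$disease, genotype_affected = TRUE,
        vus_masked = vus_masked[aff_idx], stringsAsFactors = FALSE)
    }
  }
  variants <- if (length(var_list)) do.call(rbind, var_list) else
    data.frame(subject_id = character(), gene = character(),
               variant_id = character(), acmg_class = character(),
               zygosity = character(), stringsAsFactors = FALSE)
  truth <- if (length(truth_list)) do.call(rbind, truth_list) else
    data.frame(subject_id = character(), gene = character(),
               disease = character(), genotype_affected = logical(),
               vus_masked = logical(), stringsAsFactors = FALSE)
  rownames(variants) <- rownames(truth) <- NULL
  variants <- merge(variants, subjects, by = "subject_id", sort = FALSE)
  list(subjects = subjects, variants = variants, truth = truth)
}

#' Simulate cohort analyte profiles
#'
#' Healthy newborns draw every registered marker from a baseline log-normal
#' distribution whose tail mass beyond the cutoff is calibrated so that the
#' per-subject probability of crossing at least one cutoff equals
#' \code{msms_fp_rate}. Diseased, non-attenuated newborns draw their
#' disease's primary markers beyond the cutoff; attenuated (and
#' non-penetrant genotype-positive) newborns keep in-range primary markers
#' and are detectable only by genotype.
#'
#' @param genotypes result of \code{\link{simulate_genotypes}}.
#' @param config a \code{\link{cohort_config}}.
#' @param cutoffs cutoff set defining which markers are simulated.
#' @return list with \code{analytes} (numeric matrix, subjects x markers,
#'   rownames = subject ids) and \code{truth} (per-subject disease status:
#'   subject_id, gene, disease, genotype_affected, vus_masked, diseased,
#'   attenuated).
#' @export
simulate_analytes <- function(genotypes, config,
                              cutoffs = reference_cutoffs()) {
  stopifnot(inherits(config, "cohort_config"))
  if (!inherits(cutoffs, "cutoff_set")) cutoffs <- as_cutoff_set(cutoffs)
  subjects <- genotypes$subjects
  n <- nrow(subjects)
  markers <- cutoffs$marker
  K <- length(markers)
  # per-marker tail probability giving the configured per-subject rate
  t <- 1 - (1 - config$msms_fp_rate)^(1 / K)
  sigma <- 0.25
  analytes <- matrix(0, nrow = n, ncol = K,
                     dimnames = list(subjects$subject_id, markers))
  for (j in seq_len(K)) {
    thr <- cutoffs$threshold[j]
    mu <- if (cutoffs$direction[j] == "high") {
      log(thr) - sigma * stats::qnorm(1 - t)
    } else {
      log(thr) + sigma * stats::qnorm(1 - t)
    }
    analytes[, j] <- stats::rlnorm(n, mu, sigma)
  }

  # resolve disease status per genotype-affected subject
  truth <- genotypes$truth
  if (nrow(truth)) {
    gene_par <- config$genes[match(truth$gene, config$genes$gene), ]
    missing_map <- !vapply(strsplit(gene_par$markers, ","), function(m)
      all(m %in% markers), logical(1))
    if (any(missing_map)) {
      nbs_stop(paste("disease gene lacks simulated marker(s):",
                     paste(unique(truth$gene[missing_map]), collapse = ", ")),
               "nbs_config_error")
    }
    truth$diseased <- stats::runif(nrow(truth)) <
      config$penetrance_biochemical
    truth$attenuated <- truth$diseased &
      stats::runif(nrow(truth)) < config$attenuation_prob
    for (k in seq_len(nrow(truth))) {
      mk <- strsplit(gene_par$markers[k], ",")[[1]]
      row <- match(truth$subject_id[k], subjects$subject_id)
      for (m in mk) {
        j <- match(m, markers)
        thr <- cutoffs$threshold[j]
        shift <- 0.05 + abs(stats::rnorm(1, 0, 0.5))
        inside <- 0.01 + abs(stats::rnorm(1, 0, 0.3))
        hi <- cutoffs$direction[j] == "high"
        analytes[row, j] <-
          if (truth$diseased[k] && !truth$attenuated[k]) {
            if (hi) thr * exp(shift) else thr * exp(-shift)
          } else {
            if (hi) thr * exp(-inside) else thr * exp(inside)
          }
      }
    }
  } else {
    truth$diseased <- logical(0)
    truth$attenuated <- logical(0)
  }
  list(analytes = analytes, truth = truth)
}

#' Simulate a full newborn cohort
#'
#' Composes the genotype and analyte generators under a single seed and
#' attaches ground truth. Identical configurations (including seed) produce
#' identical cohorts; the caller's RNG state is restored afterwards.
#'
#' @param config a \code{\link{cohort_config}}.
#' @param cutoffs cutoff set used for analyte calibration.
#' @return object of class \code{"nbs_cohort"}: list with \code{subjects}
#'   (per-subject sex, center, disease status), \code{variants},
#'   \code{analytes} (matrix), \code{truth} (per affected genotype),
#'   \code{config} and \code{cutoffs}.
#' @examples
#' cohort <- simulate_cohort(cohort_config(500, seed = 7))
#' table(cohort$subjects$diseased)
#' @export
simulate_cohort <- function(config, cutoffs = reference_cutoffs()) {
  stopifnot(inherits(config, "cohort_config"))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(config$seed)
  geno <- simulate_genotypes(config)
  ana <- simulate_analytes(geno, config, cutoffs)
  subjects <- geno$subjects
  truth <- ana$truth
  idx <- match(subjects$subject_id, truth$subject_id)
  subjects$genotype_affected <- !is.na(idx)
  subjects$gene <- truth$gene[idx]
  subjects$disease <- truth$disease[idx]
  subjects$diseased <- !is.na(idx) & truth$diseased[pmax(idx, 1L)]
  subjects$diseased[is.na(idx)] <- FALSE
  subjects$attenuated <- !is.na(idx) & truth$attenuated[pmax(idx, 1L)]
  subjects$attenuated[is.na(idx)] <- FALSE
  structure(list(subjects = subjects, variants = geno$variants,
                 analytes = ana$analytes, truth = truth, config = config,
                 cutoffs = cutoffs),
            class = "nbs_cohort")
}

#' @export
print.nbs_cohort <- function(x, ...) {
  cat("Simulated newborn cohort\n")
  cat("  newborns:         ", nrow(x$subjects), "\n")
  cat("  centers:          ", nrow(x$config$centers), "\n")
  cat("  variant calls:    ", nrow(x$variants), "\n")
  cat("  affected genotypes:", nrow(x$truth), "\n")
  cat("  diseased:         ", sum(x$subjects$diseased), "\n")
  invisible(x)
}
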