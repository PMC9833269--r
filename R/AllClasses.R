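#' @import methods
NULL

GROUPS <- c("CONTROL", "FH_M_NEG", "FH_M_POS")
DIPLOTYPES <- c("E2E2", "E2E3", "E2E4", "E3E3", "E3E4", "E4E4")
NUCS <- c("A", "C", "G", "T")

#' ScorePanel: the 12-SNP / 6-SNP LDL-C score definition
#'
#' An S4 container for the score reference: ten weighted non-APOE variants,
#' the two APOE SNPs (rs429358, rs7412, unweighted), the APOE
#' epsilon-diplotype weight table, and per-group minor-allele and diplotype
#' frequencies for three cohorts (`CONTROL`, `FH_M_NEG`, `FH_M_POS`).
#'
#' @slot variants data.frame with columns `rsid`, `gene`, `risk_allele`,
#'   `other_allele`, `weight` (score units per risk allele; `NA` for the two
#'   APOE SNPs), `in_6snp`, `risk_is_minor` (`NA` for APOE), and minor-allele
#'   frequency columns `maf_control`, `maf_fh_neg`, `maf_fh_pos`.
#' @slot apoeWeights named numeric of length 6, diplotype -> score units;
#'   unordered diplotypes named `E2E2` ... `E4E4`.
#' @slot apoeFreq 6 x 3 numeric matrix of diplotype frequencies, rows the
#'   diplotypes, columns the groups. Stored exactly as published
#'   (unnormalized); consumers renormalize where probabilistic validity
#'   matters (simulation, variance).
#' @slot version character scalar identifying the panel file format/version.
#'
#' @seealso [loadPanel()], [defaultPanel()], [riskAlleleFrequency()]
#' @exportClass ScorePanel
setClass("ScorePanel", representation(
  variants = "data.frame",
  apoeWeights = "numeric",
  apoeFreq = "matrix",
  version = "character"
))

setValidity("ScorePanel", function(object) {
  v <- object@variants
  need <- c("rsid", "gene", "risk_allele", "other_allele", "weight",
            "in_6snp", "risk_is_minor", "maf_control", "maf_fh_neg",
            "maf_fh_pos")
  miss <- setdiff(need, names(v))
  if (length(miss) > 0)
    return(sprintf("panel schema error: missing field(s) %s",
                   paste(miss, collapse = ", ")))
  if (nrow(v) != 12L)
    return(sprintf("panel must define exactly 12 variants, found %d", nrow(v)))
  if (anyDuplicated(v$rsid))
    return("duplicate rsid in panel")
  apoe_rs <- c("rs429358", "rs7412")
  if (!all(apoe_rs %in% v$rsid))
    return("panel must include the APOE SNPs rs429358 and rs7412")
  is_apoe <- v$rsid %in% apoe_rs
  if (sum(v$in_6snp) != 6L)
    return(sprintf("exactly 6 variants must be flagged in_6snp, found %d",
                   sum(v$in_6snp)))
  if (!all(is.na(v$weight[is_apoe])))
    return("APOE SNPs must not carry a per-allele weight")
  if (anyNA(v$weight[!is_apoe]))
    return(sprintf("missing weight for %s",
                   paste(v$rsid[!is_apoe][is.na(v$weight[!is_apoe])],
                         collapse = ", ")))
  if (any(v$weight[!is_apoe] < 0))
    return(sprintf("negative weight for %s",
                   paste(v$rsid[!is_apoe][v$weight[!is_apoe] < 0],
                         collapse = ", ")))
  bad_alleles <- !(v$risk_allele %in% NUCS) | !(v$other_allele %in% NUCS)
  if (any(bad_alleles))
    return(sprintf("invalid allele for %s",
                   paste(v$rsid[bad_alleles], collapse = ", ")))
  same <- v$risk_allele == v$other_allele
  if (any(same))
    return(sprintf("risk and other allele identical for %s",
                   paste(v$rsid[same], collapse = ", ")))
  fcols <- c("maf_control", "maf_fh_neg", "maf_fh_pos")
  for (fc in fcols) {
    f <- v[[fc]]
    if (anyNA(f) || any(f < 0) || any(f > 0.5 + 1e-3))
      return(sprintf("%s out of [0, 0.5] for %s", fc,
                     paste(v$rsid[is.na(f) | f < 0 | f > 0.5 + 1e-3],
                           collapse = ", ")))
  }
  if (!identical(sort(names(object@apoeWeights)), DIPLOTYPES))
    return("apoeWeights must be named by the six diplotypes E2E2..E4E4")
  w <- object@apoeWeights
  if (w[["E3E3"]] != 0)
    return("E3E3 diplotype weight must be 0 (reference haplotype pair)")
  if (!isTRUE(all.equal(w[["E2E2"]], -34.75)) ||
      !isTRUE(all.equal(w[["E4E4"]], 7.72)))
    return("E2E2/E4E4 diplotype weights disagree with the published table")
  fq <- object@apoeFreq
  if (!identical(rownames(fq), DIPLOTYPES) ||
      !identical(colnames(fq), GROUPS))
    return("apoeFreq must be a 6 x 3 matrix, diplotypes x groups")
  if (anyNA(fq) || any(fq < 0) || any(fq > 1))
    return("apoeFreq entries must lie in [0, 1]")
  TRUE
})

#' CohortGenotypes: subject x variant risk-allele dosages
#'
#' An S4 container holding, for each subject, the risk-allele dosage (0, 1, 2
#' or `NA` for missing) at each of the ten weighted panel SNPs, plus the raw
#' unphased genotypes at the two APOE SNPs as sorted two-letter strings
#' (e.g. `"CT"`; `NA` when missing).
#'
#' @slot subjectIds character vector, unique subject identifiers.
#' @slot dosage integer matrix, subjects x non-APOE panel variants; entries
#'   in `{0, 1, 2, NA}` count risk alleles. Column order matches the panel.
#' @slot apoeGeno character matrix, subjects x 2 with columns `rs429358` and
#'   `rs7412`.
#'
#' @seealso [readVcfGenotypes()], [readDosageTable()], [simulateGenotypes()]
#' @exportClass CohortGenotypes
setClass("CohortGenotypes", representation(
  subjectIds = "character",
  dosage = "matrix",
  apoeGeno = "matrix"
))

setValidity("CohortGenotypes", function(object) {
  n <- length(object@subjectIds)
  if (anyDuplicated(object@subjectIds))
    return("duplicate subject ids")
  if (nrow(object@dosage) != n || nrow(object@apoeGeno) != n)
    return("dosage/apoeGeno row count must equal number of subjects")
  d <- object@dosage
  if (n > 0 && !all(d %in% c(0L, 1L, 2L, NA_integer_)))
    return("dosage entries must be 0, 1, 2 or NA")
  if (ncol(object@apoeGeno) != 2L ||
      !identical(colnames(object@apoeGeno), c("rs429358", "rs7412")))
    return("apoeGeno must have columns rs429358 and rs7412")
  TRUE
})

#' @describeIn ScorePanel-class compact display of the panel
#' @param object a `ScorePanel`
#' @export
setMethod("show", "ScorePanel", function(object) {
  v <- object@variants
  apoe <- v$gene == "APOE"
  cat(sprintf("ScorePanel (%s): %d variants (%d weighted + %d APOE), %d in 6-SNP subset\n",
              object@version, nrow(v), sum(!apoe), sum(apoe), sum(v$in_6snp)))
  cat(sprintf("  weighted-sum range per subject: [%.2f, %.2f] score units\n",
              min(object@apoeWeights),
              2 * sum(v$weight[!apoe]) + max(object@apoeWeights)))
  cat(sprintf("  frequency columns: %s\n", paste(GROUPS, collapse = ", ")))
})

#' @describeIn CohortGenotypes-class compact display of the genotype matrix
#' @param object a `CohortGenotypes`
#' @export
setMethod("show", "CohortGenotypes", function(object) {
  n <- length(object@subjectIds)
  cat(sprintf("CohortGenotypes: %d subjects x %d weighted SNPs (+ APOE pair)\n",
              n, ncol(object@dosage)))
  if (n > 0) {
    miss <- sum(is.na(object@dosage)) + sum(is.na(object@apoeGeno))
    cat(sprintf("  missing calls: %d\n", miss))
  }
})

#' @rdname subjectIds
#' @export
setGeneric("subjectIds", function(x) standardGeneric("subjectIds"))

#' Subject identifiers of a genotype container
#'
#' @param x a [CohortGenotypes-class] object
#' @return character vector of subject ids
#' @export
setMethod("subjectIds", "CohortGenotypes", function(x) x@subjectIds)

#' @rdname dosages
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))

#' Risk-allele dosage matrix
#'
#' @param x a [CohortGenotypes-class] object
#' @return integer matrix (subjects x weighted SNPs), entries 0/1/2/NA
#' @export
setMethod("dosages", "CohortGenotypes", function(x) x@dosage)

#' @rdname apoeGenotypes
#' @export
setGeneric("apoeGenotypes", function(x) standardGeneric("apoeGenotypes"))

#' Raw APOE SNP genotypes
#'
#' @param x a [CohortGenotypes-class] object
#' @return character matrix with columns `rs429358`, `rs7412`; entries are
#'   sorted two-letter genotype strings or `NA`
#' @export
setMethod("apoeGenotypes", "CohortGenotypes", function(x) x@apoeGeno)

#' @rdname panelVariants
#' @export
setGeneric("panelVariants", function(x) standardGeneric("panelVariants"))

#' Variant table of a score panel
#'
#' @param x a [ScorePanel-class] object
#' @return data.frame of the 12 panel variants
#' @export
setMethod("panelVariants", "ScorePanel", function(x) x@variants)

#' @rdname apoeWeights
#' @export
setGeneric("apoeWeights", function(x) standardGeneric("apoeWeights"))

#' APOE diplotype weight table
#'
#' @param x a [ScorePanel-class] object
#' @return named numeric, diplotype (E2E2..E4E4) -> score units
#' @export
setMethod("apoeWeights", "ScorePanel", function(x) x@apoeWeights)

#' @rdname apoeFrequencies
#' @export
setGeneric("apoeFrequencies", function(x) standardGeneric("apoeFrequencies"))

#' APOE diplotype frequencies per group (as published, unnormalized)
#'
#' @param x a [ScorePanel-class] object
#' @return 6 x 3 numeric matrix, diplotypes x groups
#' @export
setMethod("apoeFrequencies", "ScorePanel", function(x) x@apoeFreq)

#' @rdname panelVersion
#' @export
setGeneric("panelVersion", function(x) standardGeneric("panelVersion"))

#' Panel version string
#'
#' @param x a [ScorePanel-class] object
#' @return character scalar
#' @export
setMethod("panelVersion", "ScorePanel", function(x) x@version)

# internal helpers shared across modules ------------------------------------

matchGroup <- function(group) {
  if (length(group) != 1L || !(group %in% GROUPS))
    stop(sprintf("unknown group '%s'; expected one of %s",
                 paste(group, collapse = ","), paste(GROUPS, collapse = ", ")),
         call. = FALSE)
  group
}

mafColumn <- function(group) {
  c(CONTROL = "maf_control", FH_M_NEG = "maf_fh_neg",
    FH_M_POS = "maf_fh_pos")[[matchGroup(group)]]
}

freqColumn <- function(group) matchGroup(group)

nonApoeVariants <- function(panel) {
  v <- panel@variants
  v[v$gene != "APOE", , drop = FALSE]
}

apoeVariantRows <- function(panel) {
  v <- panel@variants
  v[v$gene == "APOE", , drop = FALSE]
}
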