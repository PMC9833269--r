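#' Compute the 12-SNP and/or 6-SNP weighted LDL-C scores
#'
#' The score is the weighted sum of risk-allele dosages over the panel's
#' weighted SNPs plus the APOE diplotype weight for the subject's epsilon
#' diplotype (called from the raw rs429358/rs7412 genotypes). The 6-SNP
#' score restricts the sum to the four weighted SNPs flagged in the short
#' panel plus APOE.
#'
#' Missingness policies:
#' \describe{
#'   \item{fail}{(default) any missing dosage or unknown diplotype is an
#'     error listing the subjects and variants affected.}
#'   \item{omit}{missing terms contribute 0; `n_missing` reports how many of
#'     the 12 panel entries (10 dosages + the APOE diplotype) were
#'     unavailable.}
#'   \item{expected_impute}{a missing dosage is replaced by twice the
#'     risk-allele frequency of `imputeGroup`; an unknown diplotype by the
#'     frequency-weighted mean diplotype weight of that group (renormalized
#'     frequencies).}
#' }
#'
#' @param genotypes a [CohortGenotypes-class]
#' @param panel a [ScorePanel-class]
#' @param panelSize `"both"` (default), `"12"` or `"6"`
#' @param missingPolicy `"fail"`, `"omit"` or `"expected_impute"`
#' @param imputeGroup group label, required for `expected_impute`
#' @return data.frame with columns `subject_id`, `prs12` and/or `prs6`,
#'   `apoe_diplotype`, `n_missing`, `missing_policy_applied`
#' @examples
#' p <- defaultPanel()
#' g <- simulateGenotypes(cohortSimConfig("CONTROL", n = 5, seed = 1), p)
#' computePrs(g, p)
#' @export
computePrs <- function(genotypes, panel,
                       panelSize = c("both", "12", "6"),
                       missingPolicy = c("fail", "omit", "expected_impute"),
                       imputeGroup = NULL) {
  stopifnot(is(genotypes, "CohortGenotypes"), is(panel, "ScorePanel"))
  panelSize <- match.arg(as.character(panelSize[1]), c("both", "12", "6"))
  missingPolicy <- match.arg(missingPolicy)
  v <- nonApoeVariants(panel)
  d <- genotypes@dosage
  if (!identical(colnames(d), v$rsid)) {
    j <- match(v$rsid, colnames(d))
    if (anyNA(j))
      stop(sprintf("genotypes lack panel variant column(s): %s",
                   paste(v$rsid[is.na(j)], collapse = ", ")), call. = FALSE)
    d <- d[, j, drop = FALSE]
  }
  dip <- callApoeDiplotype(genotypes@apoeGeno[, "rs429358"],
                           genotypes@apoeGeno[, "rs7412"])
  n_missing <- rowSums(is.na(d)) + (dip == "UNKNOWN")

  if (missingPolicy == "fail" && any(n_missing > 0)) {
    bad <- which(n_missing > 0)
    detail <- vapply(utils::head(bad, 5L), function(i) {
      miss <- colnames(d)[is.na(d[i, ])]
      if (dip[i] == "UNKNOWN") miss <- c(miss, "APOE")
      sprintf("%s (%s)", genotypes@subjectIds[i], paste(miss, collapse = ","))
    }, character(1))
    stop(sprintf("missing genotypes under policy 'fail' for %d subject(s): %s%s",
                 length(bad), paste(detail, collapse = "; "),
                 if (length(bad) > 5) " ..." else ""), call. = FALSE)
  }

  dn <- d
  dipw <- unname(panel@apoeWeights[dip])   # NA for UNKNOWN
  if (missingPolicy == "expected_impute") {
    if (is.null(imputeGroup))
      stop("missingPolicy 'expected_impute' requires imputeGroup",
           call. = FALSE)
    ef <- 2 * riskAlleleFrequencies(panel, imputeGroup)
    for (j in seq_len(ncol(dn))) {
      nas <- is.na(dn[, j])
      if (any(nas)) dn[nas, j] <- ef[[colnames(dn)[j]]]
    }
    fdip <- apoeFreqNormalized(panel, imputeGroup)
    dipw[is.na(dipw)] <- sum(fdip * panel@apoeWeights[names(fdip)])
  } else {
    dn[is.na(dn)] <- 0
    dipw[is.na(dipw)] <- 0
  }

  out <- data.frame(subject_id = genotypes@subjectIds,
                    stringsAsFactors = FALSE)
  if (panelSize %in% c("both", "12"))
    out$prs12 <- as.numeric(dn %*% v$weight + dipw)
  if (panelSize %in% c("both", "6")) {
    w6 <- ifelse(v$in_6snp, v$weight, 0)
    out$prs6 <- as.numeric(dn %*% w6 + dipw)
  }
  out$apoe_diplotype <- dip
  out$n_missing <- as.integer(n_missing)
  out$missing_policy_applied <- rep(missingPolicy, nrow(out))
  out
}

#' Analytic expected score for a group from the panel frequency tables
#'
#' Under an additive model the population mean of the score is
#' `sum_j w_j * 2 * f_j` over the included weighted SNPs (`f_j` the group's
#' risk-allele frequency) plus `sum_d freq_d * w_d` over the six APOE
#' diplotypes. Diplotype frequencies are used exactly as published
#' (unnormalized), reproducing the arithmetic context of the source table;
#' see [scoreVarianceHwe()] for the renormalized variance oracle.
#'
#' @param panel a [ScorePanel-class]
#' @param group group label
#' @param panelSize 12 or 6
#' @return expected score, in score units
#' @examples
#' expectedScore(defaultPanel(), "CONTROL", 12)   # ~33.1
#' expectedScore(defaultPanel(), "FH_M_NEG", 6)   # ~27.7
#' @export
expectedScore <- function(panel, group, panelSize = 12) {
  stopifnot(is(panel, "ScorePanel"))
  panelSize <- match.arg(as.character(panelSize), c("12", "6"))
  v <- nonApoeVariants(panel)
  f <- riskAlleleFrequencies(panel, group)
  w <- if (panelSize == "6") ifelse(v$in_6snp, v$weight, 0) else v$weight
  fq <- panel@apoeFreq[, matchGroup(group)]
  sum(w * 2 * f) + sum(fq * panel@apoeWeights[names(fq)])
}

#' Analytic score variance under Hardy-Weinberg and linkage equilibrium
#'
#' `sum_j w_j^2 * 2 f_j (1 - f_j)` over included weighted SNPs plus the
#' variance of the APOE diplotype weight under the group's *renormalized*
#' diplotype frequencies. This is the calibration oracle for the synthetic
#' cohort generator; published real-cohort score SDs additionally reflect
#' linkage disequilibrium and are not a reproduction target.
#'
#' @inheritParams expectedScore
#' @return score variance, in squared score units
#' @export
scoreVarianceHwe <- function(panel, group, panelSize = 12) {
  stopifnot(is(panel, "ScorePanel"))
  panelSize <- match.arg(as.character(panelSize), c("12", "6"))
  v <- nonApoeVariants(panel)
  f <- riskAlleleFrequencies(panel, group)
  w <- if (panelSize == "6") ifelse(v$in_6snp, v$weight, 0) else v$weight
  fq <- apoeFreqNormalized(panel, group)
  wd <- panel@apoeWeights[names(fq)]
  apoe_var <- sum(fq * wd^2) - sum(fq * wd)^2
  sum(w^2 * 2 * f * (1 - f)) + apoe_var
}

#' Write a score table
#'
#' Tab-separated output of [computePrs()] results; scores rounded to two
#' decimals (internal arithmetic is full precision).
#'
#' @param scores data.frame from [computePrs()]
#' @param path output file
#' @return `path`, invisibly
#' @export
writeScoreTable <- function(scores, path) {
  out <- scores
  for (col in intersect(c("prs12", "prs6"), names(out)))
    out[[col]] <- round(out[[col]], 2)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-group score summary
#'
#' Means and SDs of the computed scores by a grouping vector, as printed in
#' cohort descriptions.
#'
#' @param scores data.frame from [computePrs()]
#' @param group character/factor vector aligned with `scores` rows
#' @return data.frame with group, n, mean/sd for each score column present
#' @export
summarizeScores <- function(scores, group) {
  stopifnot(nrow(scores) == length(group))
  cols <- intersect(c("prs12", "prs6"), names(scores))
  do.call(rbind, lapply(split(seq_len(nrow(scores)), group), function(i) {
    row <- data.frame(group = as.character(group[i[1]]), n = length(i))
    for (col in cols) {
      row[[paste0("mean_", col)]] <- mean(scores[[col]][i])
      row[[paste0("sd_", col)]] <- stats::sd(scores[[col]][i])
    }
    row
  }))
}
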