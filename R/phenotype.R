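#' Estimate untreated LDL-C from an on-treatment measurement
#'
#' For subjects on statins and/or ezetimibe with no recorded pre-treatment
#' value, the untreated LDL-C concentration is estimated by multiplying the
#' observed value by the correction coefficient 1.43 (the standard
#' adjustment for average statin/ezetimibe response). Untreated subjects are
#' returned unchanged. When a measured baseline is available it should be
#' preferred over this correction (see [preparePhenotypes()]).
#'
#' @param ldlObserved observed LDL-C, mg/dL (vectorized)
#' @param onLipidTherapy logical, on lipid-lowering therapy
#' @return corrected LDL-C, mg/dL
#' @examples
#' adjustLdlForTreatment(140, TRUE)   # 200.2
#' adjustLdlForTreatment(140, FALSE)  # 140
#' @export
adjustLdlForTreatment <- function(ldlObserved, onLipidTherapy) {
  if (any(ldlObserved < 0, na.rm = TRUE))
    stop("ldlObserved must be nonnegative", call. = FALSE)
  ifelse(rep_len(as.logical(onLipidTherapy), length(ldlObserved)),
         ldlObserved * 1.43, ldlObserved)
}

#' Percent LDL-C reduction under pharmacological treatment
#'
#' `100 * (baseline - on-treatment) / baseline`; negative when LDL-C rose.
#'
#' @param ldlBaseline pre-treatment LDL-C, mg/dL (> 0)
#' @param ldlOnTreatment on-treatment LDL-C, mg/dL
#' @return percent reduction (vectorized)
#' @examples
#' percentLdlReduction(250, 125)  # 50
#' percentLdlReduction(277, 145)  # 47.65 (2 dp)
#' @export
percentLdlReduction <- function(ldlBaseline, ldlOnTreatment) {
  if (any(ldlBaseline <= 0, na.rm = TRUE))
    stop("ldlBaseline must be positive", call. = FALSE)
  100 * (ldlBaseline - ldlOnTreatment) / ldlBaseline
}

#' Categorize a coronary artery calcium (Agatston) score
#'
#' Four conventional categories: `ZERO` (0), `LOW` (1-99), `MODERATE`
#' (100-400), `SEVERE` (> 400), plus the binary high-burden flag
#' `cac >= 100` used as the logistic-model outcome. Boundaries at 100 and
#' 400 are closed on the `MODERATE` side, so the flagged categories are
#' exactly `MODERATE` and `SEVERE`.
#'
#' @param cac Agatston score, `>= 0` (vectorized; `NA` passes through)
#' @return data.frame with columns `cac`, `category` (ordered factor),
#'   `binary_high` (logical)
#' @examples
#' categorizeCac(c(0, 50, 250, 401))
#' @export
categorizeCac <- function(cac) {
  if (any(cac < 0, na.rm = TRUE))
    stop("cac must be nonnegative", call. = FALSE)
  category <- factor(
    ifelse(cac == 0, "ZERO",
           ifelse(cac < 100, "LOW",
                  ifelse(cac <= 400, "MODERATE", "SEVERE"))),
    levels = c("ZERO", "LOW", "MODERATE", "SEVERE"), ordered = TRUE)
  data.frame(cac = cac, category = category, binary_high = cac >= 100)
}

#' Read a phenotype table
#'
#' Tab-separated with header `subject_id, group, age, sex, ldl_mgdl,
#' on_therapy, ldl_baseline_mgdl, cac, mi, stroke, revasc, hypertension,
#' smoking`; `NA` marks missing values. Only the first six columns are
#' required.
#'
#' @param path tab-separated phenotype file
#' @return data.frame, one row per subject
#' @export
readPhenotypeTable <- function(path) {
  if (!file.exists(path))
    stop(sprintf("phenotype file not found: %s", path), call. = FALSE)
  # sex must be read as character: bare "F" would otherwise parse as FALSE
  ph <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = c(subject_id = "character",
                                         group = "character",
                                         sex = "character"))
  need <- c("subject_id", "group", "age", "sex", "ldl_mgdl", "on_therapy")
  miss <- setdiff(need, names(ph))
  if (length(miss) > 0)
    stop(sprintf("phenotype table missing column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  validatePhenotypes(ph)
  ph
}

validatePhenotypes <- function(ph) {
  if (nrow(ph) == 0) return(invisible(ph))
  if (any(ph$age <= 0, na.rm = TRUE))
    stop("age must be positive", call. = FALSE)
  if (any(ph$ldl_mgdl <= 0, na.rm = TRUE))
    stop("ldl_mgdl must be positive", call. = FALSE)
  if (!is.null(ph$cac) && any(ph$cac < 0, na.rm = TRUE))
    stop("cac must be nonnegative", call. = FALSE)
  bad <- !(ph$group %in% GROUPS)
  if (any(bad))
    stop(sprintf("unknown group label(s): %s",
                 paste(unique(ph$group[bad]), collapse = ", ")),
         call. = FALSE)
  if (!all(ph$sex %in% c("F", "M", NA)))
    stop("sex must be F or M", call. = FALSE)
  invisible(ph)
}

#' Write a phenotype table
#'
#' @param phenotypes data.frame as produced by [simulatePhenotypes()] or
#'   read by [readPhenotypeTable()]
#' @param path output file
#' @return `path`, invisibly
#' @export
writePhenotypeTable <- function(phenotypes, path) {
  utils::write.table(phenotypes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Analysis-ready LDL-C: baseline when measured, else treatment-corrected
#'
#' Returns the LDL-C column used by the association analyses: the measured
#' pre-treatment baseline when present, otherwise the observed value
#' corrected by 1.43 for treated subjects (`ldlAdjust = "factor"`), or the
#' raw observed value (`ldlAdjust = "none"`).
#'
#' @param phenotypes phenotype data.frame
#' @param ldlAdjust `"factor"` (default) or `"none"`
#' @return numeric vector of analysis LDL-C values, mg/dL
#' @export
preparePhenotypes <- function(phenotypes, ldlAdjust = c("factor", "none")) {
  ldlAdjust <- match.arg(ldlAdjust)
  validatePhenotypes(phenotypes)
  obs <- phenotypes$ldl_mgdl
  adj <- if (ldlAdjust == "factor")
    adjustLdlForTreatment(obs, phenotypes$on_therapy) else obs
  base <- phenotypes$ldl_baseline_mgdl
  if (is.null(base)) adj else ifelse(!is.na(base), base, adj)
}
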