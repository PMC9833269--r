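#' Configuration for a synthetic cohort
#'
#' Bundles the generative parameters for one study group. Defaults encode
#' the published cohort structure: group sizes 1605 / 491 / 193, baseline
#' LDL-C centers at the published group medians (127 control, 239
#' mutation-negative, 277 mutation-positive, mg/dL), an additive per-allele
#' LDL effect equal to the score weights times `effect_scale`, a residual SD
#' of 40 mg/dL (chosen so the control-group score explains ~4.5% of LDL-C
#' variance), therapy probabilities and mean percent reductions from the
#' cohort table, and an FH ascertainment floor of baseline LDL >= 210 mg/dL
#' applied by rejection sampling.
#'
#' @param group `"CONTROL"`, `"FH_M_NEG"` or `"FH_M_POS"`
#' @param n number of subjects (default: the published group size)
#' @param seed integer seed; all randomness derives from it (the phenotype
#'   stage uses `seed + 500000` so genotype draws are unchanged when only
#'   phenotypes are regenerated)
#' @param effect_scale mg/dL of baseline LDL-C per score unit (default 1)
#' @param ldl_intercept baseline LDL-C, mg/dL, at the group-average score
#' @param residual_sd residual SD of baseline LDL-C, mg/dL
#' @param therapy_prob probability of lipid-lowering therapy at enrolment
#' @param reduction_mean,reduction_sd percent LDL-C reduction under therapy
#'   (normal, truncated to `[0, 100)`)
#' @param age_mean,age_sd age distribution, years (truncated to `[18, 95]`)
#' @param female_prob probability of female sex
#' @param cac_params list: `zero_intercept`, `zero_age`, `zero_male` (logit
#'   of P(CAC = 0)); `high_intercept`, `high_age`, `high_male`,
#'   `high_q4_logodds` (logit of P(CAC >= 100 | CAC > 0), quartile-4 tilt
#'   `ln 1.7 ~ 0.55`); `log_mu_low`, `log_sd_low`, `log_sd_high` for the
#'   positive Agatston magnitudes
#' @param fh_ldl_floor inclusion threshold on baseline LDL-C, mg/dL
#'   (default 210 for FH groups, `NA` = none for controls)
#' @param max_reject_iter cap on rejection-sampling rounds for the floor
#' @return a list of class `CohortSimConfig`
#' @export
cohortSimConfig <- function(group, n = NULL, seed = 1L,
                            effect_scale = 1.0,
                            ldl_intercept = NULL,
                            residual_sd = 40,
                            therapy_prob = NULL,
                            reduction_mean = NULL, reduction_sd = 15,
                            age_mean = NULL, age_sd = NULL,
                            female_prob = NULL,
                            cac_params = NULL,
                            fh_ldl_floor = NULL,
                            max_reject_iter = 1000L) {
  group <- matchGroup(group)
  defaults <- list(
    CONTROL  = list(n = 1605L, ldl = 127, ther = 0.05, red = 30,
                    age_mean = 50, age_sd = 9, female = 0.541, floor = NA),
    FH_M_NEG = list(n = 491L, ldl = 239, ther = 0.7145, red = 49,
                    age_mean = 55, age_sd = 12.6, female = 0.684,
                    floor = 210),
    FH_M_POS = list(n = 193L, ldl = 277, ther = 0.8229, red = 48,
                    age_mean = 47, age_sd = 16.3, female = 0.601,
                    floor = 210))[[group]]
  if (is.null(cac_params))
    cac_params <- list(zero_intercept = 1.3, zero_age = -0.07,
                       zero_male = -0.7,
                       high_intercept = -1.0, high_age = 0.09,
                       high_male = 0.9, high_q4_logodds = log(1.7),
                       log_mu_low = 3.0, log_sd_low = 1.0,
                       log_sd_high = 1.2)
  cfg <- list(group = group,
              n = as.integer(if (is.null(n)) defaults$n else n),
              seed = as.integer(seed),
              effect_scale = effect_scale,
              ldl_intercept = if (is.null(ldl_intercept)) defaults$ldl
                              else ldl_intercept,
              residual_sd = residual_sd,
              therapy_prob = if (is.null(therapy_prob)) defaults$ther
                             else therapy_prob,
              reduction_mean = if (is.null(reduction_mean)) defaults$red
                               else reduction_mean,
              reduction_sd = reduction_sd,
              age_mean = if (is.null(age_mean)) defaults$age_mean else age_mean,
              age_sd = if (is.null(age_sd)) defaults$age_sd else age_sd,
              female_prob = if (is.null(female_prob)) defaults$female
                            else female_prob,
              cac_params = cac_params,
              fh_ldl_floor = if (is.null(fh_ldl_floor)) defaults$floor
                             else fh_ldl_floor,
              max_reject_iter = as.integer(max_reject_iter))
  if (cfg$n < 0) stop("n must be nonnegative", call. = FALSE)
  if (cfg$residual_sd <= 0) stop("residual_sd must be positive", call. = FALSE)
  if (cfg$therapy_prob < 0 || cfg$therapy_prob > 1)
    stop("therapy_prob must lie in [0, 1]", call. = FALSE)
  class(cfg) <- "CohortSimConfig"
  cfg
}

# diplotype -> sorted genotype strings at (rs429358, rs7412)
DIPLOTYPE_TO_GENO <- list(
  E2E2 = c("TT", "TT"), E2E3 = c("TT", "CT"), E2E4 = c("CT", "CT"),
  E3E3 = c("TT", "CC"), E3E4 = c("CT", "CC"), E4E4 = c("CC", "CC"))

#' Simulate panel genotypes for one group
#'
#' Each weighted-SNP dosage is drawn `Binomial(2, f)` at the group's
#' risk-allele frequency (Hardy-Weinberg, linkage equilibrium across loci).
#' The APOE diplotype is drawn from the group's renormalized diplotype
#' frequency vector and back-converted to the two SNP genotypes (`E2E4`
#' becomes the doubly heterozygous pair `("CT", "CT")`). Fully reproducible
#' from `config$seed`.
#'
#' @param config a [cohortSimConfig()]
#' @param panel a [ScorePanel-class]
#' @return a [CohortGenotypes-class]
#' @export
simulateGenotypes <- function(config, panel) {
  stopifnot(inherits(config, "CohortSimConfig"), is(panel, "ScorePanel"))
  n <- config$n
  v <- nonApoeVariants(panel)
  f <- riskAlleleFrequencies(panel, config$group)
  ids <- if (n > 0) sprintf("%s_%05d", config$group, seq_len(n)) else character(0)
  withr::with_seed(config$seed, {
    dos <- matrix(NA_integer_, nrow = n, ncol = nrow(v),
                  dimnames = list(ids, v$rsid))
    for (j in seq_len(nrow(v)))
      dos[, j] <- stats::rbinom(n, 2L, f[[v$rsid[j]]])
    fdip <- apoeFreqNormalized(panel, config$group)
    dip <- sample(names(fdip), n, replace = TRUE, prob = fdip)
    apoe <- matrix(NA_character_, nrow = n, ncol = 2L,
                   dimnames = list(ids, c("rs429358", "rs7412")))
    if (n > 0) {
      conv <- do.call(rbind, DIPLOTYPE_TO_GENO[dip])
      apoe[, "rs429358"] <- conv[, 1]
      apoe[, "rs7412"] <- conv[, 2]
    }
    new("CohortGenotypes", subjectIds = ids, dosage = dos, apoeGeno = apoe)
  })
}

truncNorm <- function(n, mean, sd, lo, hi) {
  # inverse-CDF truncation: exact, vectorized, no rejection loop
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
}

#' Simulate phenotypes consistent with a genotype matrix
#'
#' Baseline LDL-C is `ldl_intercept + effect_scale * (prs12 - E[prs12]) +
#' Normal(0, residual_sd)`; for FH groups rejection sampling enforces the
#' ascertainment floor `fh_ldl_floor` (default 210 mg/dL), the mechanism
#' that attenuates within-FH score-LDL association. Therapy is Bernoulli;
#' the observed LDL of treated subjects is the baseline reduced by a
#' truncated-normal percent reduction. Age and sex follow the group's
#' published distributions. CAC is zero-inflated (calibrated so >= 70% of
#' controls are zero), with the positive part log-normal and a quartile-4
#' log-odds tilt of `ln 1.7` on the probability of CAC >= 100.
#'
#' @param genotypes a [CohortGenotypes-class] (complete, no missing calls)
#' @param config a [cohortSimConfig()]
#' @param panel a [ScorePanel-class]
#' @return phenotype data.frame (see [readPhenotypeTable()] for columns)
#' @export
simulatePhenotypes <- function(genotypes, config, panel) {
  stopifnot(is(genotypes, "CohortGenotypes"),
            inherits(config, "CohortSimConfig"), is(panel, "ScorePanel"))
  n <- length(genotypes@subjectIds)
  prs <- computePrs(genotypes, panel, panelSize = "12",
                    missingPolicy = "fail")$prs12
  mu <- expectedScore(panel, config$group, 12)
  cp <- config$cac_params
  withr::with_seed(config$seed + 500000L, {
    center <- config$ldl_intercept +
      config$effect_scale * (prs - mu)
    ldl_base <- center + stats::rnorm(n, 0, config$residual_sd)
    floor <- config$fh_ldl_floor
    if (!is.na(floor)) {
      it <- 0L
      repeat {
        low <- which(ldl_base < floor)
        if (length(low) == 0) break
        it <- it + 1L
        if (it > config$max_reject_iter)
          stop(sprintf(
            "rejection sampling for LDL floor %.0f exceeded %d rounds; lower fh_ldl_floor or raise ldl_intercept",
            floor, config$max_reject_iter), call. = FALSE)
        ldl_base[low] <- center[low] +
          stats::rnorm(length(low), 0, config$residual_sd)
      }
    }
    ldl_base <- pmax(ldl_base, 1)
    on_therapy <- stats::runif(n) < config$therapy_prob
    reduction <- truncNorm(n, config$reduction_mean, config$reduction_sd,
                           0, 100 - 1e-9)
    ldl_obs <- ifelse(on_therapy, ldl_base * (1 - reduction / 100), ldl_base)
    age <- truncNorm(n, config$age_mean, config$age_sd, 18, 95)
    sex <- ifelse(stats::runif(n) < config$female_prob, "F", "M")
    male <- as.integer(sex == "M")
    q <- if (n >= 4 && length(unique(prs)) >= 4) assignQuantiles(prs, 4)
         else rep(1L, n)
    p_zero <- stats::plogis(cp$zero_intercept + cp$zero_age * (age - 50) +
                              cp$zero_male * male)
    is_zero <- stats::runif(n) < p_zero
    p_high <- stats::plogis(cp$high_intercept + cp$high_age * (age - 50) +
                              cp$high_male * male +
                              cp$high_q4_logodds * (q == 4L))
    is_high <- stats::runif(n) < p_high
    log100 <- log(100)
    # positive part: log-normal below 100 (inverse-CDF truncated) or a
    # folded-normal excess above 100 for the high-burden stratum
    u <- stats::runif(n)
    cac_low <- exp(stats::qnorm(
      u * stats::pnorm(log100, cp$log_mu_low, cp$log_sd_low),
      cp$log_mu_low, cp$log_sd_low))
    cac_high <- 100 * exp(abs(stats::rnorm(n, 0, cp$log_sd_high)))
    cac <- ifelse(is_zero, 0, ifelse(is_high, cac_high, cac_low))
    # clinical-event placeholders: modest age/sex/burden-linked frequencies
    p_mi <- stats::plogis(-4 + 0.05 * (age - 50) + 0.6 * male +
                            0.8 * (cac >= 100))
    mi <- stats::runif(n) < p_mi
    stroke <- stats::runif(n) < stats::plogis(-4.5 + 0.04 * (age - 50))
    revasc <- stats::runif(n) < stats::plogis(-4.2 + 0.04 * (age - 50) +
                                                0.5 * male)
    hypertension <- stats::runif(n) <
      stats::plogis(-1.2 + 0.05 * (age - 50) + 0.2 * male)
    smoking <- sample(c("never", "former", "current"), n, replace = TRUE,
                      prob = c(0.55, 0.28, 0.17))
    data.frame(subject_id = genotypes@subjectIds,
               group = rep(config$group, n),
               age = round(age, 1), sex = sex,
               ldl_mgdl = round(ldl_obs, 1),
               on_therapy = on_therapy,
               ldl_baseline_mgdl = round(ldl_base, 1),
               cac = round(cac, 1), mi = mi, stroke = stroke,
               revasc = revasc, hypertension = hypertension,
               smoking = smoking, stringsAsFactors = FALSE)
  })
}

#' Simulate a complete cohort (genotypes + phenotypes)
#'
#' @param config a [cohortSimConfig()]
#' @param panel a [ScorePanel-class]
#' @return list with elements `genotypes` and `phenotypes`
#' @export
simulateCohort <- function(config, panel = defaultPanel()) {
  g <- simulateGenotypes(config, panel)
  list(genotypes = g, phenotypes = simulatePhenotypes(g, config, panel))
}

#' Write a simulated cohort to disk
#'
#' Emits `genotypes.vcf` (or `dosages.tsv` when `format = "dosage"`),
#' `phenotypes.tsv` and a `manifest.txt` echoing the configuration, seed and
#' file checksums. Outputs are byte-stable for a fixed seed and round-trip
#' losslessly through the package readers.
#'
#' @param genotypes a [CohortGenotypes-class]
#' @param phenotypes phenotype data.frame
#' @param outDir output directory (created if absent)
#' @param panel a [ScorePanel-class] (for VCF REF/ALT orientation)
#' @param format `"vcf"` (default) or `"dosage"`
#' @param config optional [cohortSimConfig()] echoed into the manifest
#' @return named character vector of written file paths, invisibly
#' @export
writeCohort <- function(genotypes, phenotypes, outDir, panel = defaultPanel(),
                        format = c("vcf", "dosage"), config = NULL) {
  stopifnot(is(genotypes, "CohortGenotypes"))
  format <- match.arg(format)
  if (!identical(genotypes@subjectIds, phenotypes$subject_id))
    stop("genotype and phenotype subject ids disagree", call. = FALSE)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  gpath <- if (format == "vcf") {
    p <- file.path(outDir, "genotypes.vcf")
    writeCohortVcf(genotypes, p, panel)
    p
  } else {
    writeDosageTable(genotypes, file.path(outDir, "dosages.tsv"))
    file.path(outDir, "dosages.tsv")
  }
  ppath <- file.path(outDir, "phenotypes.tsv")
  writePhenotypeTable(phenotypes, ppath)
  mpath <- file.path(outDir, "manifest.txt")
  lines <- c("ldlprs cohort manifest",
             sprintf("n_subjects: %d", length(genotypes@subjectIds)),
             sprintf("genotype_format: %s", format),
             sprintf("panel_version: %s", panel@version))
  if (!is.null(config))
    lines <- c(lines, sprintf("config_%s: %s", names(config),
                              vapply(config, function(x)
                                paste(format(unlist(x)), collapse = ","),
                                character(1))))
  lines <- c(lines,
             sprintf("md5_%s: %s", basename(c(gpath, ppath)),
                     tools::md5sum(c(gpath, ppath))))
  writeLines(lines, mpath)
  invisible(c(genotypes = gpath, phenotypes = ppath, manifest = mpath))
}

# minimal fixed-format VCF writer: biallelic SNVs, REF = other allele,
# ALT = risk allele, synthetic coordinates (matching is by rsID only)
writeCohortVcf <- function(genotypes, path, panel) {
  v <- panel@variants
  ids <- genotypes@subjectIds
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=ldlprs-simulated-cohort",
               "##contig=<ID=1>",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", ids), collapse = "\t")), con)
  dos <- genotypes@dosage
  apoe <- genotypes@apoeGeno
  gtString <- function(cnt) {
    ifelse(is.na(cnt), "./.", c("0/0", "0/1", "1/1")[cnt + 1L])
  }
  for (j in seq_len(nrow(v))) {
    rs <- v$rsid[j]
    if (v$gene[j] == "APOE") {
      # REF = common allele (other_allele column), ALT = minor
      ref <- v$other_allele[j]; alt <- v$risk_allele[j]
      cnt <- vapply(apoe[, rs], function(g) {
        if (is.na(g)) NA_integer_
        else sum(strsplit(g, "")[[1]] == alt)
      }, integer(1), USE.NAMES = FALSE)
    } else {
      ref <- v$other_allele[j]; alt <- v$risk_allele[j]
      cnt <- dos[, rs]
    }
    row <- paste(c("1", as.character(1000L * j), rs, ref, alt, ".", "PASS",
                   ".", "GT", gtString(cnt)), collapse = "\t")
    writeLines(row, con)
  }
  invisible(path)
}
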