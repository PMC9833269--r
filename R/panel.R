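#' Load a score panel definition from file
#'
#' Parses the two-block tab-separated panel format: a `[variants]` block with
#' the 12 SNPs (rsid, gene, risk/other allele, per-allele weight, 6-SNP flag,
#' risk-is-minor flag, three per-group minor-allele frequency columns) and an
#' `[apoe_diplotypes]` block with the six diplotype weights and per-group
#' diplotype frequency vectors. Lines starting with `#` are comments.
#'
#' Frequencies are kept exactly as printed in the source table (three
#' decimals, no renormalization). The published APOE diplotype frequency
#' vectors sum to approximately but not exactly 1; [simulateGenotypes()] and
#' [scoreVarianceHwe()] renormalize them, [expectedScore()] does not.
#'
#' @param path path to a panel file; defaults to the packaged reference panel
#' @return a validated [ScorePanel-class] object
#' @examples
#' panel <- loadPanel()
#' panel
#' @export
loadPanel <- function(path = defaultPanelPath()) {
  if (!file.exists(path))
    stop(sprintf("panel file not found: %s", path), call. = FALSE)
  raw <- readLines(path, warn = FALSE)
  lines <- raw[!grepl("^\\s*#", raw) & nzchar(trimws(raw))]
  iv <- which(trimws(lines) == "[variants]")
  ia <- which(trimws(lines) == "[apoe_diplotypes]")
  if (length(iv) != 1L || length(ia) != 1L || iv >= ia)
    stop("panel schema error: expected a [variants] block followed by an [apoe_diplotypes] block",
         call. = FALSE)
  vtab <- utils::read.table(text = lines[(iv + 1L):(ia - 1L)], header = TRUE,
                            sep = "\t", stringsAsFactors = FALSE,
                            colClasses = c(rsid = "character",
                                           gene = "character",
                                           risk_allele = "character",
                                           other_allele = "character"))
  need <- c("rsid", "gene", "risk_allele", "other_allele", "weight",
            "in_6snp", "risk_is_minor", "maf_control", "maf_fh_neg",
            "maf_fh_pos")
  miss <- setdiff(need, names(vtab))
  if (length(miss) > 0)
    stop(sprintf("panel schema error: missing field(s) %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  atab <- utils::read.table(text = lines[(ia + 1L):length(lines)],
                            header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  aneed <- c("diplotype", "weight", "freq_control", "freq_fh_neg",
             "freq_fh_pos")
  amiss <- setdiff(aneed, names(atab))
  if (length(amiss) > 0)
    stop(sprintf("panel schema error: missing field(s) %s",
                 paste(amiss, collapse = ", ")), call. = FALSE)
  if (!identical(sort(atab$diplotype), DIPLOTYPES))
    stop("panel schema error: apoe_diplotypes block must list E2E2..E4E4",
         call. = FALSE)
  o <- match(DIPLOTYPES, atab$diplotype)
  w <- stats::setNames(atab$weight[o], DIPLOTYPES)
  fq <- as.matrix(atab[o, c("freq_control", "freq_fh_neg", "freq_fh_pos")])
  dimnames(fq) <- list(DIPLOTYPES, GROUPS)
  new("ScorePanel", variants = vtab, apoeWeights = w, apoeFreq = fq,
      version = panelFormatVersion(raw))
}

panelFormatVersion <- function(raw) {
  m <- grep("^#\\s*format:", raw, value = TRUE)
  if (length(m) > 0) trimws(sub("^#\\s*format:", "", m[1])) else "unversioned"
}

#' Path to the packaged reference panel file
#'
#' @return file path of the tab-separated panel shipped with the package
#' @export
defaultPanelPath <- function() {
  system.file("extdata", "ldl_prs12_panel.tsv", package = "ldlprs",
              mustWork = TRUE)
}

#' The packaged reference score panel
#'
#' Convenience wrapper: `loadPanel(defaultPanelPath())`.
#'
#' @return a [ScorePanel-class]
#' @export
defaultPanel <- function() loadPanel(defaultPanelPath())

#' Write a score panel back to the two-block file format
#'
#' Round-trips with [loadPanel()]: `loadPanel(writePanel(p, f))` is
#' field-by-field identical to `p`.
#'
#' @param panel a [ScorePanel-class]
#' @param path output file path
#' @return `path`, invisibly
#' @export
writePanel <- function(panel, path) {
  stopifnot(is(panel, "ScorePanel"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# LDL-C polygenic score panel (written by ldlprs)",
               sprintf("# format: %s", panel@version), "[variants]"), con)
  v <- panel@variants
  utils::write.table(v, con, sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines("[apoe_diplotypes]", con)
  atab <- data.frame(diplotype = DIPLOTYPES,
                     weight = unname(panel@apoeWeights[DIPLOTYPES]),
                     freq_control = panel@apoeFreq[, "CONTROL"],
                     freq_fh_neg = panel@apoeFreq[, "FH_M_NEG"],
                     freq_fh_pos = panel@apoeFreq[, "FH_M_POS"])
  utils::write.table(atab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Risk-allele frequency of a weighted panel SNP in a group
#'
#' The panel stores minor-allele frequencies as published; the risk allele
#' (the allele associated with higher LDL-C) is the minor allele for some
#' SNPs and the common allele for others. Returns the published MAF when the
#' risk allele is minor, else `1 - MAF`.
#'
#' @param panel a [ScorePanel-class]
#' @param rsid a non-APOE panel variant identifier
#' @param group one of `"CONTROL"`, `"FH_M_NEG"`, `"FH_M_POS"`
#' @return risk-allele frequency in `[0, 1]`
#' @examples
#' p <- defaultPanel()
#' riskAlleleFrequency(p, "rs2479409", "CONTROL")  # risk allele is minor
#' riskAlleleFrequency(p, "rs6511720", "CONTROL")  # risk allele is common
#' @export
riskAlleleFrequency <- function(panel, rsid, group) {
  stopifnot(is(panel, "ScorePanel"))
  v <- nonApoeVariants(panel)
  i <- match(rsid, v$rsid)
  if (is.na(i))
    stop(sprintf("unknown or unweighted (APOE) rsid '%s'", rsid),
         call. = FALSE)
  maf <- v[[mafColumn(group)]][i]
  if (v$risk_is_minor[i]) maf else 1 - maf
}

# risk-allele frequencies for all weighted SNPs at once (internal)
riskAlleleFrequencies <- function(panel, group) {
  v <- nonApoeVariants(panel)
  maf <- v[[mafColumn(group)]]
  stats::setNames(ifelse(v$risk_is_minor, maf, 1 - maf), v$rsid)
}

# renormalized diplotype frequency vector for a group (internal)
apoeFreqNormalized <- function(panel, group) {
  f <- panel@apoeFreq[, matchGroup(group)]
  s <- sum(f)
  if (s <= 0) stop(sprintf("group %s has no APOE diplotype frequencies", group),
                   call. = FALSE)
  f / s
}
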