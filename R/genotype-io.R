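#' Call the APOE epsilon diplotype from the two defining SNP genotypes
#'
#' The epsilon haplotypes are defined over rs429358 and rs7412:
#' e2 = (T, T), e3 = (T, C), e4 = (C, C). Given the unphased genotype pair at
#' each SNP the unique consistent unordered haplotype pair is returned. The
#' doubly heterozygous case (`"CT"`, `"CT"`) is phase-ambiguous between
#' e2/e4 and e1/e3; it is resolved to `E2E4` because e1 (C, T) is vanishingly
#' rare and absent from the published diplotype table. Any combination that
#' *requires* an e1 haplotype returns `UNKNOWN`, as does any missing input.
#'
#' @param g429358 unphased genotype at rs429358 as a two-letter string over
#'   `{T, C}` in any order (e.g. `"TC"`), or `NA`
#' @param g7412 unphased genotype at rs7412 over `{C, T}`, or `NA`
#' @return one of `"E2E2"`, `"E2E3"`, `"E2E4"`, `"E3E3"`, `"E3E4"`,
#'   `"E4E4"`, `"UNKNOWN"` (vectorized over inputs)
#' @examples
#' callApoeDiplotype("TT", "CC")  # E3E3
#' callApoeDiplotype("CT", "CT")  # E2E4 (ambiguity rule)
#' @export
callApoeDiplotype <- function(g429358, g7412) {
  n <- max(length(g429358), length(g7412))
  g1 <- rep_len(as.character(g429358), n)
  g2 <- rep_len(as.character(g7412), n)
  vapply(seq_len(n), function(i) apoeCallOne(g1[i], g2[i]), character(1))
}

sortGeno <- function(g) {
  paste(sort(strsplit(g, "")[[1]]), collapse = "")
}

apoeCallOne <- function(g1, g2) {
  if (is.na(g1) || is.na(g2)) return("UNKNOWN")
  if (nchar(g1) != 2L || nchar(g2) != 2L)
    stop(sprintf("malformed APOE genotype '%s'/'%s'", g1, g2), call. = FALSE)
  a1 <- strsplit(toupper(g1), "")[[1]]
  a2 <- strsplit(toupper(g2), "")[[1]]
  if (!all(a1 %in% c("T", "C")))
    stop(sprintf("rs429358 genotype '%s' outside allele set {T,C}", g1),
         call. = FALSE)
  if (!all(a2 %in% c("C", "T")))
    stop(sprintf("rs7412 genotype '%s' outside allele set {C,T}", g2),
         call. = FALSE)
  nC1 <- sum(a1 == "C")          # rs429358 C count (e4-defining allele)
  nT2 <- sum(a2 == "T")          # rs7412 T count (e2-defining allele)
  key <- paste0(nC1, nT2)
  switch(key,
         "00" = "E3E3",
         "01" = "E2E3",
         "02" = "E2E2",
         "10" = "E3E4",
         "11" = "E2E4",          # ambiguity rule: e2/e4 preferred over e1/e3
         "20" = "E4E4",
         # any remaining combination needs an e1 = (C, T) haplotype
         "UNKNOWN")
}

#' Read panel genotypes from a VCF file
#'
#' Matches biallelic SNV records to panel variants by the VCF `ID` field
#' (rsID; coordinates and genome build are ignored), orients GT allele counts
#' to the panel's risk allele, and extracts the raw APOE SNP genotypes.
#' If a record's REF/ALT equals (other, risk) the ALT count is the dosage;
#' if (risk, other) the count is flipped to `2 - ALT count`. A record whose
#' alleles match neither orientation raises an error naming the rsid: no
#' silent strand complementing is ever attempted. Panel variants absent from
#' the file give `NA` for every subject; `./.` and half-calls give `NA` for
#' that subject.
#'
#' @param path a VCF 4.x file with GT fields
#' @param panel a [ScorePanel-class]
#' @return a [CohortGenotypes-class]
#' @export
readVcfGenotypes <- function(path, panel) {
  stopifnot(is(panel, "ScorePanel"))
  if (!file.exists(path))
    stop(sprintf("VCF not found: %s", path), call. = FALSE)
  vcf <- VariantAnnotation::readVcf(path)
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt))
    stop("VCF has no GT field", call. = FALSE)
  ids <- rownames(vcf)
  ref <- as.character(VariantAnnotation::ref(vcf))
  altl <- VariantAnnotation::alt(vcf)
  alt <- vapply(seq_along(altl), function(i) {
    a <- as.character(altl[[i]])
    if (length(a) != 1L)
      stop(sprintf("record %s is not biallelic", ids[i]), call. = FALSE)
    a
  }, character(1))
  subjects <- colnames(gt)
  if (is.null(subjects) || length(subjects) == 0)
    stop("VCF has no sample columns", call. = FALSE)

  altCount <- function(g) {
    # diploid GT string -> ALT allele count; NA on any missing allele
    al <- strsplit(sub("\\|", "/", g), "/", fixed = TRUE)
    vapply(al, function(a) {
      if (length(a) != 2L || any(a == ".") || any(is.na(a)))
        return(NA_integer_)
      sum(as.integer(a) > 0L)
    }, integer(1))
  }

  v <- nonApoeVariants(panel)
  dos <- matrix(NA_integer_, nrow = length(subjects), ncol = nrow(v),
                dimnames = list(subjects, v$rsid))
  matched <- character(0)
  for (j in seq_len(nrow(v))) {
    i <- match(v$rsid[j], ids)
    if (is.na(i)) next
    ac <- altCount(gt[i, ])
    if (ref[i] == v$other_allele[j] && alt[i] == v$risk_allele[j]) {
      dos[, j] <- ac
    } else if (ref[i] == v$risk_allele[j] && alt[i] == v$other_allele[j]) {
      dos[, j] <- 2L - ac
    } else {
      stop(sprintf(
        "allele mismatch for %s: VCF REF/ALT %s/%s vs panel %s/%s (no strand flipping attempted)",
        v$rsid[j], ref[i], alt[i], v$risk_allele[j], v$other_allele[j]),
        call. = FALSE)
    }
    matched <- c(matched, v$rsid[j])
  }

  av <- apoeVariantRows(panel)
  apoe <- matrix(NA_character_, nrow = length(subjects), ncol = 2L,
                 dimnames = list(subjects, c("rs429358", "rs7412")))
  for (rs in c("rs429358", "rs7412")) {
    k <- match(rs, av$rsid)
    i <- match(rs, ids)
    if (is.na(i)) next
    pan_alleles <- sort(c(av$risk_allele[k], av$other_allele[k]))
    if (!identical(sort(c(ref[i], alt[i])), pan_alleles))
      stop(sprintf(
        "allele mismatch for %s: VCF REF/ALT %s/%s vs panel alleles %s",
        rs, ref[i], alt[i], paste(pan_alleles, collapse = "/")),
        call. = FALSE)
    ac <- altCount(gt[i, ])
    gstr <- ifelse(is.na(ac), NA_character_, vapply(ac, function(k2) {
      paste(sort(c(rep(ref[i], 2L - k2), rep(alt[i], k2))), collapse = "")
    }, character(1)))
    apoe[, rs] <- gstr
    matched <- c(matched, rs)
  }
  message(sprintf("matched %d/12 panel variants in %s (%d missing)",
                  length(matched), basename(path), 12L - length(matched)))
  new("CohortGenotypes", subjectIds = subjects, dosage = dos,
      apoeGeno = apoe)
}

#' Read panel genotypes from a tab-separated dosage table
#'
#' Rows are subjects (first column `subject_id`), columns are panel rsIDs.
#' Weighted-SNP columns hold risk-allele dosages in `{0, 1, 2, NA}`; the two
#' APOE columns hold genotype strings such as `"TC"`. Columns not in the
#' panel are ignored with a warning; panel variants without a column are
#' `NA` for every subject.
#'
#' @param path tab-separated file
#' @param panel a [ScorePanel-class]
#' @return a [CohortGenotypes-class]
#' @export
readDosageTable <- function(path, panel) {
  stopifnot(is(panel, "ScorePanel"))
  if (!file.exists(path))
    stop(sprintf("dosage table not found: %s", path), call. = FALSE)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  if (!("subject_id" %in% names(tab)))
    stop("dosage table must have a subject_id column", call. = FALSE)
  subjects <- tab$subject_id
  v <- nonApoeVariants(panel)
  known <- c("subject_id", v$rsid, "rs429358", "rs7412")
  extra <- setdiff(names(tab), known)
  if (length(extra) > 0)
    warning(sprintf("ignoring %d non-panel column(s): %s", length(extra),
                    paste(extra, collapse = ", ")), call. = FALSE)
  dos <- matrix(NA_integer_, nrow = length(subjects), ncol = nrow(v),
                dimnames = list(subjects, v$rsid))
  for (rs in intersect(v$rsid, names(tab))) {
    x <- tab[[rs]]
    x[x %in% c("NA", "")] <- NA
    bad <- !is.na(x) & !(x %in% c("0", "1", "2"))
    if (any(bad))
      stop(sprintf("non-dosage entry '%s' for %s (allowed: 0, 1, 2, NA)",
                   x[bad][1], rs), call. = FALSE)
    dos[, rs] <- as.integer(x)
  }
  apoe <- matrix(NA_character_, nrow = length(subjects), ncol = 2L,
                 dimnames = list(subjects, c("rs429358", "rs7412")))
  for (rs in intersect(c("rs429358", "rs7412"), names(tab))) {
    x <- toupper(tab[[rs]])
    x[x %in% c("NA", "")] <- NA
    ok <- is.na(x) | grepl("^[ACGT]{2}$", x)
    if (!all(ok))
      stop(sprintf("malformed APOE genotype '%s' for %s", x[!ok][1], rs),
           call. = FALSE)
    apoe[, rs] <- ifelse(is.na(x), NA,
                         vapply(ifelse(is.na(x), "NN", x), sortGeno,
                                character(1), USE.NAMES = FALSE))
  }
  if (length(subjects) > 0)
    message(sprintf("read %d subjects x %d panel columns from %s",
                    length(subjects),
                    length(intersect(names(tab), known)) - 1L,
                    basename(path)))
  new("CohortGenotypes", subjectIds = subjects, dosage = dos,
      apoeGeno = apoe)
}

#' Write genotypes as a dosage table
#'
#' Inverse of [readDosageTable()]; round-trips losslessly.
#'
#' @param genotypes a [CohortGenotypes-class]
#' @param path output file
#' @return `path`, invisibly
#' @export
writeDosageTable <- function(genotypes, path) {
  stopifnot(is(genotypes, "CohortGenotypes"))
  d <- genotypes@dosage
  out <- data.frame(subject_id = genotypes@subjectIds,
                    as.data.frame(d, optional = TRUE),
                    rs429358 = genotypes@apoeGeno[, "rs429358"],
                    rs7412 = genotypes@apoeGeno[, "rs7412"],
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
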