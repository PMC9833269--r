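# shared fixtures: all built in code at test time

PANEL <- defaultPanel()
NON_APOE <- panelVariants(PANEL)[panelVariants(PANEL)$gene != "APOE", ]

# CohortGenotypes from a dosage matrix (rows = subjects) and APOE genotype
# strings; dosage columns default to panel order
makeGenotypes <- function(dosage, apoe429358, apoe7412,
                          ids = paste0("s", seq_len(nrow(dosage)))) {
  dimnames(dosage) <- list(ids, NON_APOE$rsid)
  apoe <- cbind(rs429358 = apoe429358, rs7412 = apoe7412)
  rownames(apoe) <- ids
  new("CohortGenotypes", subjectIds = ids,
      dosage = matrix(as.integer(dosage), nrow(dosage), ncol(dosage),
                      dimnames = dimnames(dosage)),
      apoeGeno = apoe)
}

oneSubject <- function(dosages, g429358, g7412) {
  makeGenotypes(matrix(dosages, nrow = 1), g429358, g7412)
}

# independent brute-force APOE caller: enumerate haplotype pairs consistent
# with the two unphased genotypes against the epsilon definitions
bruteApoe <- function(g1, g2) {
  if (is.na(g1) || is.na(g2)) return("UNKNOWN")
  eps <- list(E1 = c("C", "T"), E2 = c("T", "T"), E3 = c("T", "C"),
              E4 = c("C", "C"))
  a1 <- strsplit(g1, "")[[1]]; a2 <- strsplit(g2, "")[[1]]
  hits <- character(0)
  for (i in names(eps)) for (j in names(eps)) {
    h1 <- eps[[i]]; h2 <- eps[[j]]
    if (setequal_pair(c(h1[1], h2[1]), a1) &&
        setequal_pair(c(h1[2], h2[2]), a2))
      hits <- c(hits, paste(sort(c(i, j)), collapse = ""))
  }
  hits <- unique(hits)
  no_e1 <- hits[!grepl("E1", hits)]
  if (length(no_e1) == 0) return("UNKNOWN")
  if (length(no_e1) == 1) return(sub("E(\\d)E(\\d)", "E\\1E\\2", no_e1))
  # only ambiguity without E1 is {E2E4, E3E3}? no: (CT, CT) -> E2E4 vs E1E3;
  # after dropping E1 forms the documented tie-break keeps E2E4
  if ("E2E4" %in% no_e1) return("E2E4")
  no_e1[1]
}

setequal_pair <- function(x, y) identical(sort(x), sort(y))

# write a minimal VCF for given records; gts is a list of per-record
# genotype string vectors over the sample names
writeTestVcf <- function(path, ids, ref, alt, gts,
                         samples = paste0("s", seq_along(gts[[1]]))) {
  lines <- c("##fileformat=VCFv4.2", "##contig=<ID=1>",
             '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", samples), collapse = "\t"))
  for (i in seq_along(ids))
    lines <- c(lines, paste(c("1", 1000 * i, ids[i], ref[i], alt[i], ".",
                              "PASS", ".", "GT", gts[[i]]), collapse = "\t"))
  writeLines(lines, path)
  path
}

suppressReaderChatter <- function(expr) suppressMessages(expr)
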