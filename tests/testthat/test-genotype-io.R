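test_that("APOE diplotype calling agrees with haplotype-pair enumeration", {
  genos1 <- c("TT", "CT", "CC")
  genos2 <- c("CC", "CT", "TT")
  for (g1 in genos1) for (g2 in genos2)
    expect_identical(callApoeDiplotype(g1, g2), bruteApoe(g1, g2),
                     label = sprintf("(%s, %s)", g1, g2))
  # worked cases from the epsilon definitions
  expect_identical(callApoeDiplotype("TT", "CC"), "E3E3")
  expect_identical(callApoeDiplotype("CC", "CC"), "E4E4")
  expect_identical(callApoeDiplotype("CT", "CT"), "E2E4")
  expect_identical(callApoeDiplotype("CC", "TT"), "UNKNOWN")  # needs e1 twice
  expect_identical(callApoeDiplotype("TT", NA), "UNKNOWN")
  expect_identical(callApoeDiplotype(NA, "CC"), "UNKNOWN")
  # genotype order never matters
  expect_identical(callApoeDiplotype("TC", "CT"), callApoeDiplotype("CT", "TC"))
  expect_error(callApoeDiplotype("AA", "CC"), "allele set")
  expect_error(callApoeDiplotype("TT", "GG"), "allele set")
})

test_that("VCF dosages are oriented to the risk allele", {
  f <- withr::local_tempfile(fileext = ".vcf")
  # rs6511720 panel risk/other = G/T: REF=G means risk is REF, so 0/0 -> 2
  # rs1367117 panel risk/other = A/G: REF=G ALT=A, heterozygote -> 1
  writeTestVcf(f, c("rs6511720", "rs1367117"), ref = c("G", "G"),
               alt = c("T", "A"),
               gts = list(c("0/0", "1/1", "0/1", "./."),
                          c("0/1", "0/0", "1/1", "0/.")))
  g <- suppressReaderChatter(readVcfGenotypes(f, PANEL))
  d <- dosages(g)
  expect_equal(unname(d[, "rs6511720"]), c(2L, 0L, 1L, NA))
  expect_equal(unname(d[, "rs1367117"]), c(1L, 0L, 2L, NA))
  # variants absent from the file are missing for everyone
  expect_true(all(is.na(d[, "rs2479409"])))
  expect_true(all(is.na(apoeGenotypes(g))))
})

test_that("orientation involution: flipping REF/ALT leaves dosages fixed", {
  set.seed(11)
  gtpool <- c("0/0", "0/1", "1/1")
  n <- 6L
  rs <- NON_APOE$rsid
  gts <- lapply(rs, function(x) sample(gtpool, n, replace = TRUE))
  flip <- function(g) chartr("01", "10", g)
  f1 <- withr::local_tempfile(fileext = ".vcf")
  f2 <- withr::local_tempfile(fileext = ".vcf")
  writeTestVcf(f1, rs, ref = NON_APOE$other_allele,
               alt = NON_APOE$risk_allele, gts = gts)
  writeTestVcf(f2, rs, ref = NON_APOE$risk_allele,
               alt = NON_APOE$other_allele, gts = lapply(gts, flip))
  g1 <- suppressReaderChatter(readVcfGenotypes(f1, PANEL))
  g2 <- suppressReaderChatter(readVcfGenotypes(f2, PANEL))
  expect_identical(dosages(g1), dosages(g2))
  # per-genotype brute force: ALT count under (other, risk) orientation IS
  # the risk-allele count of the diploid genotype
  counts <- vapply(gts[[1]], function(g)
    sum(strsplit(g, "/")[[1]] == "1"), integer(1), USE.NAMES = FALSE)
  expect_equal(unname(dosages(g1)[, rs[1]]), counts)
})

test_that("allele mismatches are errors, never silently flipped", {
  f <- withr::local_tempfile(fileext = ".vcf")
  writeTestVcf(f, "rs629301", ref = "G", alt = "C", gts = list("0/1"))
  expect_error(suppressReaderChatter(readVcfGenotypes(f, PANEL)),
               "rs629301.*mismatch|mismatch.*rs629301")
  # strand-complement of the true alleles must also fail
  f2 <- withr::local_tempfile(fileext = ".vcf")
  writeTestVcf(f2, "rs1367117", ref = "C", alt = "T", gts = list("0/0"))
  expect_error(suppressReaderChatter(readVcfGenotypes(f2, PANEL)), "rs1367117")
})

test_that("dosage tables validate entries and round-trip", {
  f <- withr::local_tempfile(fileext = ".tsv")
  g <- makeGenotypes(matrix(c(0:2, rep(1, 27)), 3, 10),
                     c("TT", "CT", "CC"), c("CC", "CC", "CT"))
  writeDosageTable(g, f)
  g2 <- suppressReaderChatter(readDosageTable(f, PANEL))
  expect_identical(dosages(g2), dosages(g))
  expect_identical(apoeGenotypes(g2), apoeGenotypes(g))
  expect_identical(subjectIds(g2), subjectIds(g))
  # entry outside {0,1,2,NA} is a parse error
  tab <- read.table(f, header = TRUE, sep = "\t", check.names = FALSE)
  tab$rs629301[1] <- 3
  write.table(tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(suppressReaderChatter(readDosageTable(f, PANEL)),
               "rs629301")
  # unknown columns are ignored with a warning
  tab$rs629301[1] <- 1
  tab$not_a_snp <- 5
  write.table(tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_warning(suppressReaderChatter(readDosageTable(f, PANEL)),
                 "not_a_snp")
})

test_that("duplicate subject ids are rejected", {
  expect_error(makeGenotypes(matrix(1, 2, 10), c("TT", "TT"),
                             c("CC", "CC"), ids = c("a", "a")),
               "duplicate")
})
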