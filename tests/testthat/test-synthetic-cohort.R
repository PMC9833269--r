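test_that("genotype simulation is seeded, frequency-faithful and HWE", {
  cfg <- cohortSimConfig("CONTROL", n = 20000, seed = 17)
  g1 <- simulateGenotypes(cfg, PANEL)
  g2 <- simulateGenotypes(cfg, PANEL)
  expect_identical(dosages(g1), dosages(g2))
  expect_identical(apoeGenotypes(g1), apoeGenotypes(g2))
  # per-locus empirical risk-allele frequency within binomial error
  d <- dosages(g1)
  for (rs in c("rs629301", "rs6511720", "rs1800562")) {
    f <- riskAlleleFrequency(PANEL, rs, "CONTROL")
    fhat <- mean(d[, rs]) / 2
    expect_lt(abs(fhat - f), 3 * sqrt(f * (1 - f) / (2 * cfg$n)))
  }
  # a zero-frequency locus yields all-zero dosages
  p2 <- PANEL
  v <- panelVariants(p2)
  v$maf_control[v$rsid == "rs1800562"] <- 0
  v$risk_is_minor[v$rsid == "rs1800562"] <- TRUE
  p2@variants <- v
  g0 <- simulateGenotypes(cohortSimConfig("CONTROL", n = 500, seed = 1), p2)
  expect_true(all(dosages(g0)[, "rs1800562"] == 0))
})

test_that("simulated APOE diplotypes follow the renormalized table", {
  cfg <- cohortSimConfig("FH_M_NEG", n = 20000, seed = 23)
  g <- simulateGenotypes(cfg, PANEL)
  dip <- callApoeDiplotype(apoeGenotypes(g)[, "rs429358"],
                           apoeGenotypes(g)[, "rs7412"])
  fq <- apoeFrequencies(PANEL)[, "FH_M_NEG"]
  fq <- fq / sum(fq)
  # E2E4 subjects come back as E2E4 via the double-heterozygote rule, so
  # the full diplotype distribution is recoverable from the genotypes
  for (dpl in names(fq)[fq > 0]) {
    se <- sqrt(fq[dpl] * (1 - fq[dpl]) / cfg$n)
    expect_lt(abs(mean(dip == dpl) - fq[dpl]), 4 * se + 1e-4)
  }
  expect_identical(sort(unique(dip[dip != "UNKNOWN"])),
                   sort(names(fq)[fq > 0]))
})

test_that("phenotype generation encodes the stated effect structure", {
  cfg <- cohortSimConfig("CONTROL", n = 1605, seed = 29)
  sim <- simulateCohort(cfg, PANEL)
  ph <- sim$phenotypes
  sc <- computePrs(sim$genotypes, PANEL)
  expect_identical(ph$subject_id, subjectIds(sim$genotypes))
  # null effect: correlation vanishes when effect_scale = 0
  cfg0 <- cohortSimConfig("CONTROL", n = 4000, seed = 29, effect_scale = 0)
  sim0 <- simulateCohort(cfg0, PANEL)
  sc0 <- computePrs(sim0$genotypes, PANEL)
  r0 <- cor(sc0$prs12, sim0$phenotypes$ldl_baseline_mgdl)
  expect_lt(abs(r0), 3 / sqrt(cfg0$n))
  # treated subjects sit below their own baseline; untreated match it
  expect_true(all(ph$ldl_mgdl[ph$on_therapy] <
                    ph$ldl_baseline_mgdl[ph$on_therapy]))
  expect_true(all(ph$ldl_mgdl[!ph$on_therapy] ==
                    ph$ldl_baseline_mgdl[!ph$on_therapy]))
  # control CAC zero-inflation stays above the published 70%
  expect_gte(mean(ph$cac == 0), 0.70 - 3 * sqrt(0.7 * 0.3 / nrow(ph)))
  expect_true(all(ph$age >= 18 & ph$age <= 95))
  expect_true(all(ph$cac >= 0))
})

test_that("FH ascertainment floor truncates baseline LDL-C", {
  cfg <- cohortSimConfig("FH_M_NEG", n = 491, seed = 31)
  sim <- simulateCohort(cfg, PANEL)
  expect_true(all(sim$phenotypes$ldl_baseline_mgdl >= 210))
  # an unreachable floor trips the documented iteration cap
  bad <- cohortSimConfig("FH_M_NEG", n = 50, seed = 31, fh_ldl_floor = 900,
                         max_reject_iter = 5L)
  g <- simulateGenotypes(bad, PANEL)
  expect_error(simulatePhenotypes(g, bad, PANEL), "rejection|rounds")
})

test_that("written cohorts are byte-stable and round-trip through scoring", {
  cfg <- cohortSimConfig("FH_M_POS", n = 3, seed = 37)
  sim <- simulateCohort(cfg, PANEL)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  f1 <- writeCohort(sim$genotypes, sim$phenotypes, d1, PANEL, config = cfg)
  sim_b <- simulateCohort(cfg, PANEL)
  f2 <- writeCohort(sim_b$genotypes, sim_b$phenotypes, d2, PANEL,
                    config = cfg)
  expect_identical(readLines(f1["genotypes"]), readLines(f2["genotypes"]))
  expect_identical(readLines(f1["phenotypes"]), readLines(f2["phenotypes"]))
  expect_true(file.exists(f1["manifest"]))
  # write -> read -> score equals in-memory scores
  g2 <- suppressReaderChatter(readVcfGenotypes(f1["genotypes"], PANEL))
  s_mem <- computePrs(sim$genotypes, PANEL)
  s_rt <- computePrs(g2, PANEL)
  expect_equal(s_rt$prs12, s_mem$prs12)
  expect_equal(s_rt$prs6, s_mem$prs6)
  # dosage-table dialect round-trips too
  d3 <- withr::local_tempdir()
  f3 <- writeCohort(sim$genotypes, sim$phenotypes, d3, PANEL,
                    format = "dosage")
  g3 <- suppressReaderChatter(readDosageTable(f3["genotypes"], PANEL))
  expect_identical(dosages(g3), dosages(sim$genotypes))
})

test_that("empty cohorts produce valid empty files", {
  cfg <- cohortSimConfig("CONTROL", n = 0, seed = 1)
  sim <- simulateCohort(cfg, PANEL)
  expect_equal(nrow(sim$phenotypes), 0L)
  d <- withr::local_tempdir()
  f <- writeCohort(sim$genotypes, sim$phenotypes, d, PANEL)
  expect_true(all(file.exists(f)))
  ph <- readPhenotypeTable(f["phenotypes"])
  expect_equal(nrow(ph), 0L)
})

test_that("simulated variance tracks the HWE oracle", {
  cfg <- cohortSimConfig("CONTROL", n = 30000, seed = 41)
  sc <- computePrs(simulateGenotypes(cfg, PANEL), PANEL)
  v_oracle <- scoreVarianceHwe(PANEL, "CONTROL", 12)
  se_var <- v_oracle * sqrt(2 / (cfg$n - 1))
  expect_lt(abs(var(sc$prs12) - v_oracle), 3 * se_var)
})
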