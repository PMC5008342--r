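test_that("study design validates its metastatic ordering", {
  d <- studyDesign()
  expect_equal(cellLines(d), c("Hep3B", "MHCC97L", "MHCC97H", "HCCLM3"))
  expect_equal(unname(metastaticRanks(d)), 0:3)
  expect_equal(nReplicates(d), 3L)
  expect_equal(nFractions(d), 12L)
  expect_error(studyDesign(ranks = c(0, 1, 1, 3)), "permutation")
  expect_error(studyDesign(nReplicates = 0), ">= 1")
  expect_output(show(d), "Hep3B < MHCC97L < MHCC97H < HCCLM3")
})

test_that("an empty proteome request yields empty outputs", {
  out <- generateProteome(0)
  expect_equal(length(out$proteome), 0L)
  expect_equal(nrow(out$truth), 0L)
  expect_error(generateProteome(5, lengthRange = c(400, 100)), "lengthRange")
  expect_error(generateProteome(5, lengthRange = c(3, 100)), "lengthRange")
})

test_that("generation is deterministic in the seed", {
  a <- generateProteome(20, seed = 5)
  b <- generateProteome(20, seed = 5)
  expect_identical(as.character(a$proteome), as.character(b$proteome))
  expect_identical(a$truth$trend, b$truth$trend)
  c <- generateProteome(20, seed = 6)
  expect_false(identical(as.character(a$proteome), as.character(c$proteome)))
})

test_that("truth sequon counts equal an independent regex scan, and planted sites sit on sequons", {
  sim <- tinyStudy(seed = 13, nProteins = 25)
  seqs <- as.character(sim$proteome)
  for (i in seq_len(nrow(sim$truth))) {
    positions <- oracleSequons(seqs[[sim$truth$accession[i]]])
    expect_equal(sim$truth$n_sequons[i], length(positions))
    expect_true(all(sim$truth$glycosites[[i]] %in% positions))
  }
})

test_that("every emitted peptide is a substring of its source protein and fractions partition runs", {
  design <- studyDesign()
  sim <- tinyStudy(seed = 14, nProteins = 15)
  psms <- simulatePsmTables(sim$proteome, sim$truth, design, depth = 1, seed = 15)
  targets <- psms[!psms$is_decoy, ]
  seqs <- as.character(sim$proteome)
  hit <- mapply(function(p, a) grepl(p, seqs[[a]], fixed = TRUE),
                targets$peptide, targets$accessions)
  expect_true(all(hit))
  expect_true(all(psms$fraction %in% seq_len(nFractions(design))))
  # per-fraction counts sum to the per-run draw
  perRun <- table(psms$run_id)
  perFrac <- table(psms$run_id, psms$fraction)
  expect_equal(as.numeric(rowSums(perFrac)[names(perRun)]), as.numeric(perRun))
  # determinism
  psms2 <- simulatePsmTables(sim$proteome, sim$truth, design, depth = 1, seed = 15)
  expect_identical(psms, psms2)
})

test_that("a zero-abundance protein never yields PSMs", {
  design <- studyDesign(nReplicates = 2)
  sim <- tinyStudy(seed = 16, nProteins = 8)
  sim$truth$base_abundance[1] <- 0
  psms <- simulatePsmTables(sim$proteome, sim$truth, design, depth = 3, seed = 17)
  expect_false(sim$truth$accession[1] %in% psms$accessions)
})

test_that("mean PSM counts match abundance x theoretical peptides x depth", {
  # one protein observed over many simulated runs: Monte-Carlo check of the
  # Poisson mean against the closed form, within 3 standard errors
  design <- studyDesign(cellLines = c("Hep3B", "MHCC97L", "MHCC97H", "HCCLM3"),
                        nReplicates = 1, nFractions = 2)
  sim <- tinyStudy(seed = 18, nProteins = 3)
  sim$truth$trend <- "flat"
  depth <- 2
  theo <- theoreticalTrypticPeptides(as.character(sim$proteome))
  acc <- sim$truth$accession[which(theo > 0)[1]]
  expectMean <- sim$truth$base_abundance[sim$truth$accession == acc] *
    theo[[acc]] * depth
  counts <- vapply(1:200, function(s) {
    p <- simulatePsmTables(sim$proteome, sim$truth, design, depth = depth,
                           decoyFraction = 0, seed = 1000 + s)
    sum(p$accessions == acc & p$cell_line == "Hep3B")
  }, numeric(1))
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - expectMean), 3 * se + 1e-9)
})

test_that("glyco simulation is deterministic and clean at contaminant fraction 0", {
  design <- studyDesign(nReplicates = 2, nFractions = 1)
  sim <- tinyStudy(seed = 19, nProteins = 20)
  g1 <- simulateGlycoPsms(sim$proteome, sim$truth, design, seed = 20)
  g2 <- simulateGlycoPsms(sim$proteome, sim$truth, design, seed = 20)
  expect_identical(g1, g2)
  val <- validateGlycoPsm(g1, sim$proteome)
  expect_equal(nrow(val$rejected), 0L)   # everything passes sequon validation
  expect_gt(nrow(val$accepted), 0L)
})

test_that("contaminant glyco-PSMs are rejected at close to the planted rate", {
  design <- studyDesign(nReplicates = 2, nFractions = 1)
  sim <- generateProteome(60, lengthRange = c(150, 300), seed = 21)
  g <- simulateGlycoPsms(sim$proteome, sim$truth, design, seed = 22,
                         contaminantFraction = 0.2)
  val <- validateGlycoPsm(g, sim$proteome)
  n <- nrow(g)
  frac <- nrow(val$rejected) / n
  se <- sqrt(0.2 * 0.8 / n)
  expect_lt(abs(frac - 0.2), 3 * se)
})

test_that("clinical cohorts have the requested size and are deterministic", {
  co <- simulateClinicalCohort(2, seed = 1)
  expect_equal(nrow(co), 2L)
  a <- simulateClinicalCohort(80, positiveRate = 0.4, association = 3, seed = 9)
  b <- simulateClinicalCohort(80, positiveRate = 0.4, association = 3, seed = 9)
  expect_identical(a, b)
  expect_error(simulateClinicalCohort(1), ">= 2")
  # a strong association shifts the covariate distribution for positives
  big <- simulateClinicalCohort(4000, positiveRate = 0.5, association = 6, seed = 10)
  tab <- cohortContingency(big, "sex")
  p <- pearsonChi2(tab)$p.value
  expect_lt(p, 1e-6)
})
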