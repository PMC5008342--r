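test_that("tryptic cleavage respects the KP rule and the length floor", {
  expect_equal(theoreticalTrypticPeptides("AAAAAAA"), 1L)   # one 7-mer
  expect_equal(theoreticalTrypticPeptides("AAAKAAA"), 0L)   # segments 4 + 3
  expect_equal(theoreticalTrypticPeptides("AAAKPAAAA"), 1L) # K before P: no cut
  expect_equal(theoreticalTrypticPeptides(""), 0L)
  expect_equal(theoreticalTrypticPeptides("AAAAAAAKAAAAAAAA"), 2L)
})

test_that("tryptic counting matches an independent regex oracle on random sequences", {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  set.seed(11)
  for (i in 1:30) {
    s <- paste(sample(aa, 200, replace = TRUE), collapse = "")
    expect_equal(theoreticalTrypticPeptides(s), oracleTrypticCount(s))
    # digested peptides reassemble to the full sequence
    expect_equal(paste(digestTryptic(s, minLength = 1)[[1]], collapse = ""), s)
  }
})

test_that("SAF1 is the 10x PSM/theoretical ratio, linear in counts", {
  expect_equal(computeSaf1(10, 10), 10)
  expect_equal(computeSaf1(0, 5), 0)
  expect_equal(computeSaf1(8, 4), 2 * computeSaf1(4, 4))
  expect_warning(out <- computeSaf1(3, 0), "zero theoretical")
  expect_true(is.na(out))
})

test_that("NSAF5 normalizes each run to 1e5 and is scale invariant", {
  expect_equal(computeNsaf5(7), 1e5)                       # single GP
  expect_equal(computeNsaf5(c(3, 3)), c(5e4, 5e4))        # symmetry
  set.seed(3)
  for (i in 1:20) {
    v <- rexp(sample(2:50, 1))
    out <- computeNsaf5(v)
    expect_equal(sum(out), 1e5, tolerance = 1e-9)
    expect_equal(computeNsaf5(v * 17), out, tolerance = 1e-12)
  }
  expect_error(computeNsaf5(c(0, 0)), "no quantifiable")
})

# a small pipeline slice shared by the matrix-level tests
makeTinySe <- function(seed = 5, nProteins = 25, replicateSigma = 0.2) {
  design <- studyDesign()
  sim <- tinyStudy(seed = seed, nProteins = nProteins)
  psms <- simulatePsmTables(sim$proteome, sim$truth, design, depth = 2,
                            decoyFraction = 0.1,
                            replicateSigma = replicateSigma, seed = seed + 1)
  filtered <- stepwiseQcFilter(computePeptideFdr(psms))
  map <- buildPeptideProteinMap(filtered, sim$proteome)
  groups <- parsimonyGroup(map, proteome = sim$proteome)
  gps <- collapseToGp(groups, sim$geneMap, proteome = sim$proteome)
  list(se = buildAbundanceMatrix(filtered, gps, sim$proteome, design),
       sim = sim, filtered = filtered, design = design, gps = gps)
}

test_that("abundance matrix columns sum to 1e5 and PSMs are conserved per run", {
  fx <- makeTinySe()
  nsaf5 <- SummarizedExperiment::assay(fx$se, "nsaf5")
  expect_true(all(abs(colSums(nsaf5) - 1e5) < 1e5 * 1e-9))
  psm <- SummarizedExperiment::assay(fx$se, "psm")
  perRun <- table(paste(fx$filtered$cell_line, fx$filtered$replicate, sep = "_R"))
  expect_equal(colSums(psm)[names(perRun)], as.numeric(perRun),
               ignore_attr = TRUE)
})

test_that("NSAF5 is invariant to fraction splitting and to uniform count scaling", {
  fx <- makeTinySe()
  # pre-pooled: collapse all fractions to fraction 1
  pooled <- fx$filtered
  pooled$fraction <- 1L
  se2 <- buildAbundanceMatrix(pooled, fx$gps, fx$sim$proteome, fx$design)
  expect_equal(SummarizedExperiment::assay(se2, "nsaf5"),
               SummarizedExperiment::assay(fx$se, "nsaf5"))
  # uniform scaling: duplicate every PSM (x2 counts) leaves NSAF5 unchanged
  doubled <- rbind(fx$filtered, fx$filtered)
  se3 <- buildAbundanceMatrix(doubled, fx$gps, fx$sim$proteome, fx$design)
  expect_equal(SummarizedExperiment::assay(se3, "nsaf5"),
               SummarizedExperiment::assay(fx$se, "nsaf5"), tolerance = 1e-12)
})

test_that("replicate correlation handles self, negation and matches the formula", {
  m <- cbind(a = c(1, 2, 3, 4), b = c(2, 4, 5, 9))
  out <- replicateCorrelation(m, minShared = 3)
  expect_equal(diag(out), c(a = 1, b = 1))
  x <- m[, 1]; y <- m[, 2]
  manual <- sum((x - mean(x)) * (y - mean(y))) / ((length(x) - 1) * sd(x) * sd(y))
  expect_equal(out["a", "b"], manual)
  # too few shared nonzero entries -> undefined
  m2 <- cbind(a = c(1, 2, 0, 0), b = c(2, 0, 3, 0))
  expect_true(is.na(replicateCorrelation(m2, minShared = 3)["a", "b"]))
})

test_that("replicates of the same line correlate tightly on synthetic data", {
  fx <- makeTinySe(nProteins = 40, replicateSigma = 0.1)
  corr <- replicateCorrelation(fx$se)
  cd <- SummarizedExperiment::colData(fx$se)
  same <- outer(cd$cell_line, cd$cell_line, "==") & upper.tri(corr)
  diffPair <- !outer(cd$cell_line, cd$cell_line, "==") & upper.tri(corr)
  expect_gt(min(corr[same], na.rm = TRUE), 0.5)
  expect_gt(mean(corr[same], na.rm = TRUE), mean(corr[diffPair], na.rm = TRUE))
})

test_that("ANOVA returns F = 0, p = 1 for identical group means and matches hand formula", {
  design <- studyDesign()
  vals <- matrix(rep(c(1, 2, 3), 4), nrow = 1)  # same triplet in every line
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(nsaf5 = vals),
    colData = S4Vectors::DataFrame(
      cell_line = rep(cellLines(design), each = 3), replicate = rep(1:3, 4))
  )
  rownames(se) <- "gp1"
  out <- anovaScreen(se, design)
  expect_equal(out$F, 0)
  expect_equal(out$p, 1)

  set.seed(9)
  vals2 <- matrix(rnorm(12, mean = rep(c(1, 1, 2, 3), each = 3)), nrow = 1)
  se2 <- SummarizedExperiment::SummarizedExperiment(
    assays = list(nsaf5 = vals2), colData = SummarizedExperiment::colData(se))
  rownames(se2) <- "gp1"
  out2 <- anovaScreen(se2, design)
  g <- rep(1:4, each = 3)
  gm <- tapply(vals2[1, ], g, mean)
  ssb <- sum(3 * (gm - mean(vals2))^2)
  ssw <- sum((vals2[1, ] - gm[g])^2)
  expect_equal(out2$F, (ssb / 3) / (ssw / 8), tolerance = 1e-10)
})

test_that("zero-variance GPs are flagged degenerate and never significant", {
  design <- studyDesign()
  vals <- rbind(gpA = rep(5, 12), gpB = c(rep(1, 6), rep(9, 6)))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(nsaf5 = vals),
    colData = S4Vectors::DataFrame(
      cell_line = rep(cellLines(design), each = 3), replicate = rep(1:3, 4))
  )
  out <- anovaScreen(se, design)
  expect_true(out$degenerate[out$gp_id == "gpA"])
  expect_false(out$significant[out$gp_id == "gpA"])
  expect_true(out$significant[out$gp_id == "gpB"])
})
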