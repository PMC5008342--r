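test_that("sequon finder honors the proline veto and overlaps", {
  expect_equal(nrow(findSequons("NPS")), 0L)
  ngs <- findSequons("NGS")
  expect_equal(ngs$position, 1L)
  expect_equal(ngs$sequon, "NGS")
  nnst <- findSequons("NNST")
  expect_equal(nnst$position, c(1L, 2L))
  expect_equal(nnst$sequon, c("NNS", "NST"))
  expect_equal(nrow(findSequons("NG")), 0L)
})

test_that("sequon finder matches a sliding-window oracle on random sequences", {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  set.seed(21)
  for (i in 1:30) {
    s <- paste(sample(aa, 150, replace = TRUE, prob = c(rep(1, 11), 4, 1, 1, 1, 4, 4, 1, 1, 1)),
               collapse = "")
    got <- findSequons(s)
    expect_equal(got$position, oracleSequons(s))
    # the stored 3-mer re-extracts from the sequence at the coordinate
    expect_equal(got$sequon, substring(s, got$position, got$position + 2))
  }
})

glycoFixture <- function() {
  #            1234567890123456789
  prot <- c(P1 = "MKAAANGSAAKWWNPSWWK", P2 = "MKAAANGSAAKWWNPSWWK")
  # peptide AAANGSAAK starts at 3 in P1; its N at peptide pos 4 -> protein pos 6
  base <- data.frame(
    peptide = "AAANGSAAK", accessions = "P1", mod_flags = "4:deam18O",
    delta_mass = 2.9848, precursor_area = 10,
    run_id = "Hep3B_R1", cell_line = "Hep3B", replicate = 1L,
    stringsAsFactors = FALSE
  )
  list(prot = Biostrings::AAStringSet(prot), base = base)
}

test_that("a flagged N on a sequon with the exact shift is accepted at the right coordinate", {
  fx <- glycoFixture()
  out <- validateGlycoPsm(fx$base, fx$prot)
  expect_equal(nrow(out$accepted), 1L)
  expect_equal(out$accepted$site_position, 6L)
  expect_equal(out$accepted$sequon, "NGS")
  expect_false(out$accepted$ambiguous)
  expect_equal(nrow(out$rejected), 0L)
})

test_that("non-motif deamidation and mass mismatches are rejected with reasons", {
  fx <- glycoFixture()
  # N at protein position 14 sits in an NPS context: proline veto
  bad <- fx$base
  bad$peptide <- "WWNPSWWK"; bad$mod_flags <- "3:deam18O"
  out <- validateGlycoPsm(bad, fx$prot)
  expect_equal(out$rejected$reason, "non-motif deamidation")

  off <- fx$base
  off$delta_mass <- 2.9848 + 1
  out2 <- validateGlycoPsm(off, fx$prot)
  expect_equal(out2$rejected$reason, "mass mismatch")
})

test_that("multiple flagged sites need the additive shift and yield one record each", {
  prot <- Biostrings::AAStringSet(c(P1 = "MKNGSANGTAAAK"))
  two <- data.frame(
    peptide = "NGSANGTAAAK", accessions = "P1", mod_flags = "1:deam18O;5:deam18O",
    delta_mass = 2 * 2.9848 + 0.015,   # inside 2 x tol
    precursor_area = 4, run_id = "r", cell_line = "Hep3B", replicate = 1L,
    stringsAsFactors = FALSE
  )
  out <- validateGlycoPsm(two, prot)
  expect_equal(nrow(out$accepted), 2L)
  expect_equal(sort(out$accepted$site_position), c(3L, 7L))
  two$delta_mass <- 2 * 2.9848 + 0.05  # outside 2 x tol
  expect_equal(validateGlycoPsm(two, prot)$rejected$reason, "mass mismatch")
})

test_that("a flagged non-N position is a malformed-input error", {
  fx <- glycoFixture()
  bad <- fx$base
  bad$mod_flags <- "1:deam18O"
  expect_error(validateGlycoPsm(bad, fx$prot), "not an asparagine")
})

test_that("peptides shared by two proteins give one ambiguous record per protein", {
  fx <- glycoFixture()
  shared <- fx$base
  shared$accessions <- "P1;P2"
  out <- validateGlycoPsm(shared, fx$prot)
  expect_equal(nrow(out$accepted), 2L)
  expect_true(all(out$accepted$ambiguous))
  expect_equal(sort(out$accepted$accession), c("P1", "P2"))
})

test_that("area normalization is a direct ratio and scale invariant", {
  fx <- glycoFixture()
  design <- studyDesign(nReplicates = 1, nFractions = 1)
  acc <- validateGlycoPsm(fx$base, fx$prot)$accepted
  acc <- acc[rep(1, 4), ]
  acc$run_id <- .runIds <- paste(cellLines(design), 1, sep = "_R")
  acc$cell_line <- cellLines(design)
  acc$precursor_area <- 5
  totals <- setNames(rep(10, 4), .runIds)
  gqt <- normalizeGlycoAreas(acc, totals, design)
  expect_equal(unname(SummarizedExperiment::assay(gqt, "norm")[1, ]), rep(0.5, 4))
  # reference-line mean ratio is 1
  expect_equal(unname(SummarizedExperiment::assay(gqt, "ratio")[1, "Hep3B_R1"]), 1)
  # scaling areas and totals together changes nothing
  acc2 <- acc; acc2$precursor_area <- 50
  gqt2 <- normalizeGlycoAreas(acc2, totals * 10, design)
  expect_equal(SummarizedExperiment::assay(gqt2, "norm"),
               SummarizedExperiment::assay(gqt, "norm"))
  expect_error(normalizeGlycoAreas(acc, totals * 0, design), "positive total")
})

test_that("planted fold steps survive normalization and ratios at zero noise", {
  design <- studyDesign(nReplicates = 2, nFractions = 1)
  sim <- tinyStudy(seed = 8, nProteins = 30)
  g <- simulateGlycoPsms(sim$proteome, sim$truth, design, seed = 9,
                         massNoiseSd = 0, areaSigma = 0, replicateSigma = 0,
                         siteSigma = 0)
  val <- validateGlycoPsm(g, sim$proteome)
  expect_equal(nrow(val$rejected), 0L)
  # fixed run total isolates the planted per-site fold structure
  totals <- setNames(rep(1, 8), unique(g$run_id))
  gqt <- normalizeGlycoAreas(val$accepted, totals, design)
  rd <- SummarizedExperiment::rowData(gqt)
  ratio <- SummarizedExperiment::assay(gqt, "ratio")
  up <- sim$truth$accession[sim$truth$trend == "increased"]
  for (site in rownames(rd)[rd$accession %in% up]) {
    expect_equal(unname(ratio[site, "HCCLM3_R1"]), 2^3, tolerance = 1e-9)
  }
})

test_that("glyco trend clustering separates mirrored up and down sites", {
  design <- studyDesign(nReplicates = 2, nFractions = 1)
  runs <- paste(rep(cellLines(design), each = 2), 1:2, sep = "_R")
  up <- t(replicate(10, rep(2^(0:3), each = 2)))
  dn <- t(replicate(10, rep(2^(3:0), each = 2)))
  m <- rbind(up, dn) * runif(20, 0.5, 2)
  rownames(m) <- paste0("P", 1:20, "@", 1:20)
  colnames(m) <- runs
  gqt <- SummarizedExperiment::SummarizedExperiment(
    assays = list(norm = m),
    rowData = S4Vectors::DataFrame(
      accession = sub("@.*", "", rownames(m)),
      site_position = 1:20, row.names = rownames(m)),
    colData = S4Vectors::DataFrame(
      run_id = runs, cell_line = rep(cellLines(design), each = 2),
      replicate = rep(1:2, 4), row.names = runs)
  )
  gt <- glycoTrend(gqt, design, k = 2, seed = 4)
  expect_setequal(unname(gt$labels), c("increased", "decreased"))
  expect_setequal(gt$increased$sites, rownames(m)[1:10])
  expect_setequal(gt$increased$accessions, paste0("P", 1:10))
})
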