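#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end run with its documented
#' default. All randomness downstream flows from the single \code{seed}.
#'
#' @param seed master integer seed.
#' @param nProteins synthetic proteome size (default 300).
#' @param trendProps planted trend proportions (default 10\% increased,
#'   10\% decreased, 80\% flat).
#' @param foldStep planted fold change per metastatic rank (default 2).
#' @param depth expected PSMs per abundance unit per theoretical peptide.
#' @param decoyFraction expected decoy PSM proportion.
#' @param replicateSigma log-scale replicate noise sd (default 0.2).
#' @param tiers QC tier table (see \code{\link{qcTiers}}).
#' @param minPeptideLength identification length floor (default 7).
#' @param alpha ANOVA significance level (default 0.05).
#' @param kSecretome secretome trend clusters (default 3).
#' @param kGlyco glyco trend clusters (default 2).
#' @param massShift,massTol 18O deamidation shift and tolerance in Da.
#' @param contaminantFraction non-motif glyco contaminant proportion.
#' @param glycoReplicates biological replicates in the glyco arm (default 2).
#' @param referenceLine reference cell line for glyco ratios (default the
#'   non-metastatic control).
#' @param outDir output directory for stage TSVs, or NULL to skip writing.
#' @return a named list of class \code{pipelineConfig}.
#' @export
pipelineConfig <- function(seed = 1, nProteins = 300,
                           trendProps = c(increased = 0.1, decreased = 0.1, flat = 0.8),
                           foldStep = 2, depth = 1, decoyFraction = 0.1,
                           replicateSigma = 0.2,
                           tiers = qcTiers(), minPeptideLength = 7,
                           alpha = 0.05, kSecretome = 3, kGlyco = 2,
                           massShift = 2.9848, massTol = 0.01,
                           contaminantFraction = 0.1, glycoReplicates = 2,
                           referenceLine = "Hep3B", outDir = NULL) {
  structure(list(
    seed = as.integer(seed), nProteins = nProteins, trendProps = trendProps,
    foldStep = foldStep, depth = depth, decoyFraction = decoyFraction,
    replicateSigma = replicateSigma, tiers = tiers,
    minPeptideLength = minPeptideLength, alpha = alpha,
    kSecretome = kSecretome, kGlyco = kGlyco,
    massShift = massShift, massTol = massTol,
    contaminantFraction = contaminantFraction,
    glycoReplicates = glycoReplicates,
    referenceLine = referenceLine, outDir = outDir
  ), class = "pipelineConfig")
}

#' SecretomeRun: the end-to-end pipeline report
#'
#' Holds the per-stage tallies and result sets of one pipeline run:
#' identification and QC counts, group/GP counts, the significant set,
#' trend clusters, glycosite acceptance, secretion-category composition
#' and the candidate list, together with the stage objects needed for
#' further analysis.
#'
#' @slot counts named list of per-stage tallies.
#' @slot candidates character vector of candidate GP ids.
#' @slot results named list of stage objects (truth, abundance matrix,
#'   ANOVA table, cluster assignments, glyco table, category summary).
#' @slot config the echoed \code{pipelineConfig}.
#' @aliases SecretomeRun-class
#' @exportClass SecretomeRun
setClass("SecretomeRun",
  representation(counts = "list", candidates = "character",
                 results = "list", config = "list")
)

setValidity("SecretomeRun", function(object) {
  cn <- object@counts
  if (!is.null(cn$significant_gps) && !is.null(cn$quantifiable_gps) &&
      cn$significant_gps > cn$quantifiable_gps)
    return("significant GPs cannot exceed quantifiable GPs")
  TRUE
})

#' @describeIn runPipeline candidate GP ids of a finished run.
#' @param object a \code{SecretomeRun}.
#' @export
setGeneric("candidates", function(object) standardGeneric("candidates"))

#' @rdname runPipeline
#' @export
setMethod("candidates", "SecretomeRun", function(object) object@candidates)

#' @describeIn runPipeline per-stage tallies of a finished run.
#' @export
setGeneric("stageCounts", function(object) standardGeneric("stageCounts"))

#' @rdname runPipeline
#' @export
setMethod("stageCounts", "SecretomeRun", function(object) object@counts)

#' @describeIn runPipeline stage result objects of a finished run.
#' @export
setGeneric("stageResults", function(object) standardGeneric("stageResults"))

#' @rdname runPipeline
#' @export
setMethod("stageResults", "SecretomeRun", function(object) object@results)

setMethod("show", "SecretomeRun", function(object) {
  cn <- object@counts
  cat("SecretomeRun (seed ", object@config$seed, ")\n", sep = "")
  cat("  PSMs:", cn$psms_in, "->", cn$psms_qc, "after QC\n")
  cat("  groups:", cn$protein_groups, "| GPs:", cn$gps,
      "| quantifiable:", cn$quantifiable_gps, "\n")
  cat("  ANOVA significant:", cn$significant_gps,
      "| secretome increased:", cn$secretome_increased, "\n")
  cat("  glycosites accepted:", cn$glycosites_accepted,
      "rejected:", cn$glycosites_rejected,
      "| glyco increased GPs:", cn$glyco_increased, "\n")
  cat("  candidates:", length(object@candidates), "\n")
})

#' Run the full secretome / N-glycosecretome pipeline on synthetic data
#'
#' Executes simulate -> QC -> inference -> quantification -> ANOVA ->
#' trend clustering -> glycosite validation and quantification ->
#' secretion classification -> candidate intersection, with every stage
#' seeded from the single configured seed. Rerunning with an identical
#' configuration reproduces the report exactly.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @return a \linkS4class{SecretomeRun}.
#' @examples
#' \donttest{
#' run <- runPipeline(pipelineConfig(seed = 7, nProteins = 60, depth = 2))
#' run
#' candidates(run)
#' }
#' @export
runPipeline <- function(config = pipelineConfig()) {
  stopifnot(inherits(config, "pipelineConfig"))
  seed <- config$seed
  design <- studyDesign()
  glycoDesign <- studyDesign(nReplicates = config$glycoReplicates, nFractions = 1)

  ## stage 1: synthetic inputs with planted truth
  sim <- generateProteome(config$nProteins, seed = .deriveSeed(seed, 1),
                          trendProps = config$trendProps,
                          foldStep = config$foldStep)
  psms <- simulatePsmTables(sim$proteome, sim$truth, design,
                            depth = config$depth,
                            decoyFraction = config$decoyFraction,
                            replicateSigma = config$replicateSigma,
                            seed = .deriveSeed(seed, 2))
  glycoPsms <- simulateGlycoPsms(sim$proteome, sim$truth, glycoDesign,
                                 seed = .deriveSeed(seed, 3),
                                 contaminantFraction = config$contaminantFraction,
                                 massShift = config$massShift,
                                 replicateSigma = config$replicateSigma)
  predictors <- simulatePredictorScores(sim$truth, seed = .deriveSeed(seed, 4))

  ## stage 2: PSM quality control
  psms <- computePeptideFdr(psms)
  filtered <- stepwiseQcFilter(psms, config$tiers, config$minPeptideLength)

  ## stage 3: inference
  map <- buildPeptideProteinMap(filtered, sim$proteome)
  pepCounts <- table(filtered$peptide)
  pepCounts <- stats::setNames(as.numeric(pepCounts), names(pepCounts))
  groups <- parsimonyGroup(map, psmCounts = pepCounts, proteome = sim$proteome)
  gps <- collapseToGp(groups, sim$geneMap, proteome = sim$proteome)
  quantifiable <- selectQuantifiable(gps)

  ## stage 4: quantification + differential screen
  se <- buildAbundanceMatrix(filtered, gps, sim$proteome, design,
                             minLength = config$minPeptideLength)
  corr <- replicateCorrelation(se)
  screen <- anovaScreen(se, design, alpha = config$alpha)

  ## stage 5: secretome trend clustering
  sig <- screen$gp_id[screen$significant]
  m <- SummarizedExperiment::assay(se, "nsaf5")[sig, , drop = FALSE]
  fit <- kmeansProfiles(m, SummarizedExperiment::colData(se)$cell_line,
                        design, k = config$kSecretome,
                        seed = .deriveSeed(seed, 5))
  labels <- labelTrendClusters(fit, design)
  secUp <- names(fit$cluster)[fit$cluster %in% which(labels == "increased")]

  ## stage 6: glyco arm
  val <- validateGlycoPsm(glycoPsms, sim$proteome,
                          shift = config$massShift, tol = config$massTol)
  runTotals <- tapply(glycoPsms$precursor_area, glycoPsms$run_id, sum)
  gqt <- normalizeGlycoAreas(val$accepted, runTotals, glycoDesign,
                             referenceLine = config$referenceLine)
  # trend-cluster the differential glycosites only, as in the secretome arm;
  # with two replicates per line the linear-trend screen is the powerful choice
  glycoScreen <- trendScreen(gqt, glycoDesign, alpha = config$alpha)
  sigSites <- glycoScreen$gp_id[glycoScreen$significant]
  gt <- glycoTrend(gqt[sigSites, ], glycoDesign, k = config$kGlyco,
                   seed = .deriveSeed(seed, 6))
  geneOf <- stats::setNames(sim$geneMap$gene_id, sim$geneMap$accession)
  glycoUpGps <- sort(unique(unname(geneOf[gt$increased$accessions])))

  ## stage 7: secretion categorization of the significant set
  cls <- classifySecretion(predictors)
  sigAcc <- quantifiable$representative[match(sig, quantifiable$gp_id)]
  catSummary <- summarizeCategories(cls[stats::na.omit(sigAcc)])

  ## stage 8: candidates
  cand <- intersectCandidates(secUp, glycoUpGps)

  counts <- list(
    proteins = config$nProteins,
    psms_in = nrow(psms), psms_qc = nrow(filtered),
    protein_groups = nrow(groups), gps = nrow(gps),
    quantifiable_gps = nrow(quantifiable),
    significant_gps = length(sig),
    cluster_sizes = as.list(table(fit$cluster)),
    secretome_increased = length(secUp),
    glycosites_accepted = nrow(val$accepted),
    glycosites_rejected = nrow(val$rejected),
    glyco_increased = length(glycoUpGps),
    category_fractions = stats::setNames(as.list(catSummary$fraction),
                                         catSummary$category),
    candidates = length(cand)
  )
  run <- methods::new("SecretomeRun",
    counts = counts, candidates = cand,
    results = list(truth = sim$truth, geneMap = sim$geneMap,
                   abundance = se, correlation = corr, anova = screen,
                   secretomeClusters = list(assignment = fit, labels = labels),
                   glyco = list(table = gqt, trend = gt, rejected = val$rejected),
                   categories = catSummary),
    config = unclass(config)
  )
  if (!is.null(config$outDir)) .writeRunArtifacts(run, sim, filtered, config$outDir)
  run
}

# stage TSV/JSON artifacts, one file per spec'd output
.writeRunArtifacts <- function(run, sim, filtered, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  Biostrings::writeXStringSet(sim$proteome, file.path(outDir, "proteome.fasta"))
  writeTsv(filtered, file.path(outDir, "psms_filtered.tsv"))
  res <- run@results
  se <- res$abundance
  ab <- data.frame(gp_id = rownames(se),
                   SummarizedExperiment::assay(se, "nsaf5"), check.names = FALSE)
  writeTsv(ab, file.path(outDir, "abundance_nsaf5.tsv"))
  writeTsv(res$anova, file.path(outDir, "anova.tsv"))
  cl <- res$secretomeClusters
  writeTsv(data.frame(gp_id = names(cl$assignment$cluster),
                      cluster = unname(cl$assignment$cluster),
                      trend = cl$labels[cl$assignment$cluster]),
           file.path(outDir, "clusters.tsv"))
  gq <- res$glyco$table
  writeTsv(data.frame(as.data.frame(SummarizedExperiment::rowData(gq)),
                      SummarizedExperiment::assay(gq, "norm"), check.names = FALSE),
           file.path(outDir, "glycosites.tsv"))
  writeTsv(res$categories, file.path(outDir, "secretion_classes.tsv"))
  writeTsv(data.frame(gp_id = run@candidates), file.path(outDir, "candidates.tsv"))
  jsonlite::write_json(run@counts, file.path(outDir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(NULL)
}
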