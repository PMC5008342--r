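#' In silico tryptic digestion
#'
#' Cleaves an amino-acid sequence after every K or R that is not followed by
#' P (trypsin's canonical specificity), with zero missed cleavages, and
#' returns the resulting peptides of at least \code{minLength} residues.
#'
#' @param sequence character vector of protein sequences.
#' @param minLength minimum peptide length retained (default 7, the search
#'   engine's identification floor).
#' @return list (one element per sequence) of peptide character vectors.
#' @examples
#' digestTryptic("MKWVTFISLLLLFSSAYSRGVFRR")
#' @export
digestTryptic <- function(sequence, minLength = 7) {
  chars <- as.character(sequence)
  out <- lapply(chars, function(s) {
    if (is.na(s) || nchar(s) == 0L) return(character(0))
    segs <- strsplit(s, "(?<=[KR])(?!P)", perl = TRUE)[[1]]
    segs[nchar(segs) >= minLength]
  })
  names(out) <- names(sequence)
  out
}

#' Theoretical number of full tryptic peptides
#'
#' Counts the peptides a protein can yield under complete tryptic digestion
#' (cleavage after K/R not before P, zero missed cleavages) that reach the
#' minimum identifiable length. This count is the per-protein normalization
#' denominator of the spectral abundance factor: longer proteins yield more
#' peptides and therefore more spectra at equal molar abundance.
#'
#' Positional segments are counted, so two identical peptide sequences at
#' different positions both count.
#'
#' @inheritParams digestTryptic
#' @return integer vector of counts (0 for empty sequences).
#' @examples
#' theoreticalTrypticPeptides(c("AAAAAAA", "AAAKAAA", "AAAKPAAAA"))
#' @export
theoreticalTrypticPeptides <- function(sequence, minLength = 7) {
  vapply(digestTryptic(sequence, minLength = minLength), length, integer(1))
}

#' Spectral abundance factor (SAF1)
#'
#' SAF1 = 10 x (PSM count) / (theoretical full tryptic peptide count). The
#' factor 10 is a display convention only. Entries with a zero theoretical
#' count cannot be normalized and are returned as NA with a warning; they
#' are excluded from downstream quantification.
#'
#' @param psmCount numeric vector of observed PSM counts.
#' @param theoCount parallel vector of theoretical peptide counts.
#' @return numeric vector of SAF1 values.
#' @export
computeSaf1 <- function(psmCount, theoCount) {
  stopifnot(length(psmCount) == length(theoCount))
  bad <- theoCount < 1
  if (any(bad)) {
    warning(sum(bad), " entries with zero theoretical peptides excluded from SAF1")
  }
  out <- ifelse(bad, NA_real_, 10 * psmCount / theoCount)
  out
}

#' Run-normalized spectral abundance (NSAF5)
#'
#' NSAF5_i = 1e5 x SAF1_i / sum_j SAF1_j within one run, so each run's
#' quantifiable entries sum to 1e5. Scaling every PSM count in a run by a
#' common factor leaves NSAF5 unchanged.
#'
#' @param saf1 numeric vector of SAF1 values for one run (NA entries are
#'   excluded from the normalizing sum and returned as NA).
#' @return numeric vector of NSAF5 values.
#' @export
computeNsaf5 <- function(saf1) {
  tot <- sum(saf1, na.rm = TRUE)
  if (!is.finite(tot) || tot <= 0) {
    stop("no quantifiable evidence in run (total SAF1 is zero)")
  }
  1e5 * saf1 / tot
}

#' Assemble the gene-product abundance matrix
#'
#' Pools the fractions of every (cell line, replicate) run, assigns each
#' quality-controlled PSM to its covering gene-product group, and computes
#' SAF1/NSAF5 per quantifiable GP per run. The SAF1 denominator uses the
#' group's representative accession (its longest member).
#'
#' @param psms filtered PSM table (see \code{\link{stepwiseQcFilter}}).
#' @param gpGroups GP-level groups from \code{\link{collapseToGp}}; only
#'   quantifiable groups (>= 1 unique peptide) enter the matrix.
#' @param proteome named \code{AAStringSet} (or character vector) of protein
#'   sequences, used for the theoretical peptide counts.
#' @param design a \linkS4class{StudyDesign}.
#' @param minLength minimum peptide length for the theoretical digest.
#' @return a \code{SummarizedExperiment} with assays \code{nsaf5} and
#'   \code{psm}, one row per quantifiable GP and one column per run.
#' @export
buildAbundanceMatrix <- function(psms, gpGroups, proteome, design, minLength = 7) {
  gpGroups <- selectQuantifiable(gpGroups)
  if (nrow(gpGroups) == 0L) stop("no quantifiable gene products")
  seqs <- stats::setNames(as.character(proteome), names(proteome))
  theo <- theoreticalTrypticPeptides(seqs[gpGroups$representative],
                                     minLength = minLength)
  if (any(theo < 1)) {
    drop <- theo < 1
    warning("dropping ", sum(drop), " GP(s) whose representative has no theoretical peptides")
    gpGroups <- gpGroups[!drop, , drop = FALSE]
    theo <- theo[!drop]
  }

  # peptide -> owning GP (the group whose cover claimed it); shared-peptide
  # PSMs follow their peptide's assignment so per-run counts are conserved
  pep2gp <- unlist(mapply(function(gp, peps) stats::setNames(rep(gp, length(peps)), peps),
                          gpGroups$gp_id, gpGroups$assigned_peptides,
                          SIMPLIFY = FALSE, USE.NAMES = FALSE))

  runs <- .runTable(design)
  psms$run_id <- paste(psms$cell_line, psms$replicate, sep = "_R")
  psms <- psms[psms$peptide %in% names(pep2gp), , drop = FALSE]
  gp <- pep2gp[psms$peptide]

  counts <- matrix(0, nrow = nrow(gpGroups), ncol = nrow(runs),
                   dimnames = list(gpGroups$gp_id, runs$run_id))
  if (nrow(psms) > 0L) {
    tab <- table(factor(gp, levels = gpGroups$gp_id),
                 factor(psms$run_id, levels = runs$run_id))
    counts[] <- as.numeric(tab)
  }

  saf1 <- sweep(counts, 1, theo, "/") * 10
  nsaf5 <- apply(saf1, 2, computeNsaf5)

  SummarizedExperiment::SummarizedExperiment(
    assays = list(nsaf5 = nsaf5, psm = counts),
    rowData = S4Vectors::DataFrame(
      gp_id = gpGroups$gp_id,
      representative = gpGroups$representative,
      n_peptides = lengths(gpGroups$peptides),
      n_unique_peptides = lengths(gpGroups$unique_peptides),
      theo_peptides = theo
    ),
    colData = S4Vectors::DataFrame(runs, row.names = runs$run_id)
  )
}

#' Pearson correlation between run columns
#'
#' Computes the Pearson correlation between every pair of runs over the GPs
#' quantified (nonzero) in both. Pairs sharing fewer than \code{minShared}
#' nonzero GPs, or with a constant column, are flagged undefined (NA).
#'
#' @param x abundance \code{SummarizedExperiment} (assay \code{nsaf5}) or a
#'   numeric matrix with runs in columns.
#' @param minShared minimum shared nonzero GPs per pair (default 3).
#' @return symmetric correlation matrix with unit diagonal.
#' @export
replicateCorrelation <- function(x, minShared = 3) {
  m <- if (methods::is(x, "SummarizedExperiment"))
    SummarizedExperiment::assay(x, "nsaf5") else as.matrix(x)
  if (ncol(m) < 2L) stop("need at least two runs")
  p <- ncol(m)
  out <- diag(1, p)
  dimnames(out) <- list(colnames(m), colnames(m))
  for (i in seq_len(p - 1L)) {
    for (j in (i + 1L):p) {
      keep <- m[, i] > 0 & m[, j] > 0
      if (sum(keep) < minShared ||
          stats::sd(m[keep, i]) == 0 || stats::sd(m[keep, j]) == 0) {
        out[i, j] <- out[j, i] <- NA_real_
      } else {
        out[i, j] <- out[j, i] <- stats::cor(m[keep, i], m[keep, j])
      }
    }
  }
  out
}

#' One-way ANOVA differential screen
#'
#' Tests each GP for a difference in mean NSAF5 across cell lines with a
#' standard one-way fixed-effects ANOVA (equal-variance F test) on the raw
#' NSAF5 values. The significant set is \{p < alpha\} with no
#' multiple-testing correction. GPs with zero variance across all runs are
#' flagged degenerate and excluded from the significant set.
#'
#' @param x abundance \code{SummarizedExperiment} (assay \code{nsaf5}).
#' @param design a \linkS4class{StudyDesign}.
#' @param alpha significance level (default 0.05).
#' @param assay assay to test (default \code{nsaf5}; the glyco arm screens
#'   its \code{norm} assay the same way).
#' @param logTransform test on the natural-log scale (off by default for
#'   the secretome's raw NSAF5 convention; the glyco arm turns it on
#'   because precursor areas are log-normal). Zeros are offset by half the
#'   smallest positive value before the log.
#' @return data frame with one row per GP: F, p, per-line means, and flags.
#'   The reported group means are always on the original scale.
#' @export
anovaScreen <- function(x, design, alpha = 0.05, assay = "nsaf5",
                        logTransform = FALSE) {
  m <- SummarizedExperiment::assay(x, assay)
  mTest <- if (logTransform) {
    off <- min(m[m > 0]) / 2
    log(m + off)
  } else m
  line <- factor(SummarizedExperiment::colData(x)$cell_line,
                 levels = cellLines(design))
  if (nlevels(line) < 2L) stop("need at least two cell lines")
  if (min(table(line)) < 2L) stop("need at least two replicates per cell line")

  res <- t(vapply(seq_len(nrow(m)), function(i) {
    v <- mTest[i, ]
    mns <- tapply(m[i, ], line, mean)
    if (stats::sd(v) == 0) return(c(NA_real_, NA_real_, mns))
    fit <- stats::oneway.test(v ~ line, var.equal = TRUE)
    c(unname(fit$statistic), fit$p.value, mns)
  }, numeric(2L + nlevels(line))))
  out <- data.frame(gp_id = rownames(m), F = res[, 1], p = res[, 2],
                    res[, -(1:2), drop = FALSE],
                    row.names = NULL, check.names = FALSE)
  names(out)[4:(3 + nlevels(line))] <- paste0("mean_", levels(line))
  out$degenerate <- is.na(out$p)
  out$significant <- !out$degenerate & out$p < alpha
  out
}

#' Linear-trend screen across the metastatic ordering
#'
#' Tests each feature for a linear trend of (log) abundance over the
#' metastatic ranks — the natural screen when the alternative of interest
#' is monotone change along an ordered gradient, and considerably more
#' powerful than the omnibus ANOVA when replication is thin (the glyco arm
#' has two replicates per line). The statistic is the t test of the slope
#' in a least-squares fit of the values on the integer ranks.
#'
#' @inheritParams anovaScreen
#' @param logTransform test on the natural-log scale (default TRUE, the
#'   appropriate scale for log-normal precursor areas).
#' @return data frame per feature: slope, t, p, significance flag.
#' @export
trendScreen <- function(x, design, alpha = 0.05, assay = "norm",
                        logTransform = TRUE) {
  m <- SummarizedExperiment::assay(x, assay)
  if (logTransform) {
    off <- min(m[m > 0]) / 2
    m <- log(m + off)
  }
  ranks <- metastaticRanks(design)
  r <- as.numeric(ranks[SummarizedExperiment::colData(x)$cell_line])
  sxx <- sum((r - mean(r))^2)
  if (sxx == 0) stop("design has a single cell line; no trend to test")
  df <- ncol(m) - 2L
  res <- t(apply(m, 1, function(v) {
    if (stats::sd(v) == 0) return(c(NA_real_, NA_real_, NA_real_))
    b <- sum((r - mean(r)) * (v - mean(v))) / sxx
    fitted <- mean(v) + b * (r - mean(r))
    s2 <- sum((v - fitted)^2) / df
    tstat <- b / sqrt(s2 / sxx)
    c(b, tstat, 2 * stats::pt(-abs(tstat), df))
  }))
  out <- data.frame(gp_id = rownames(m), slope = res[, 1], t = res[, 2],
                    p = res[, 3], row.names = NULL)
  out$degenerate <- is.na(out$p)
  out$significant <- !out$degenerate & out$p < alpha
  out
}
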