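#' Find N-glycosylation sequons in a protein sequence
#'
#' Reports every 1-based position i with residue(i) = N, residue(i+1) != P
#' and residue(i+2) in \{S, T\} (the canonical N-X-S/T motif with the
#' proline veto). Overlapping sequons are all reported.
#'
#' @param sequence a single amino-acid string.
#' @return data frame with columns \code{position} and \code{sequon}
#'   (the 3-residue motif); zero rows when none are present.
#' @examples
#' findSequons("MNGSANPTKNNST")
#' @export
findSequons <- function(sequence) {
  sequence <- as.character(sequence)
  stopifnot(length(sequence) == 1L)
  if (is.na(sequence) || nchar(sequence) < 3L) {
    return(data.frame(position = integer(0), sequon = character(0)))
  }
  m <- gregexpr("N(?=[^P][ST])", sequence, perl = TRUE)[[1]]
  if (m[1] == -1L) {
    return(data.frame(position = integer(0), sequon = character(0)))
  }
  pos <- as.integer(m)
  data.frame(position = pos,
             sequon = substring(sequence, pos, pos + 2L),
             stringsAsFactors = FALSE)
}

#' Validate deamidated glyco-PSMs against sequon context and the 18O mass shift
#'
#' PNGase F deglycosylation in heavy-oxygen water converts each glycosylated
#' asparagine to an 18O-labelled aspartate, adding a characteristic mass
#' shift per site. A glyco-PSM is accepted only if (a) every flagged
#' peptide position is an N residue, (b) the corresponding protein
#' coordinate falls on a sequon, and (c) the reported mass delta equals
#' (number of flagged sites) x \code{shift} within (number of sites) x
#' \code{tol}. Peptides mapping to several proteins yield one record per
#' protein, marked ambiguous.
#'
#' @param psms glyco-PSM table with columns \code{peptide},
#'   \code{accessions} (semicolon-joined), \code{mod_flags}
#'   (semicolon-joined \code{pos:deam18O} entries), \code{delta_mass},
#'   \code{precursor_area} and run coordinates
#'   (\code{run_id}, \code{cell_line}, \code{replicate}).
#' @param proteome named \code{AAStringSet} or character vector.
#' @param shift expected mass increase per deglycosylated site in Da
#'   (default 2.9848).
#' @param tol mass tolerance per site in Da (default 0.01).
#' @return list with \code{accepted} (one row per flagged site per protein:
#'   accession, 1-based \code{site_position}, \code{sequon}, peptide, run
#'   coordinates, area, \code{ambiguous} flag) and \code{rejected}
#'   (input row index and reason).
#' @export
validateGlycoPsm <- function(psms, proteome, shift = 2.9848, tol = 0.01) {
  seqs <- stats::setNames(as.character(proteome), names(proteome))
  accepted <- list()
  rejected <- list()
  sequonCache <- new.env(parent = emptyenv())
  sequonsOf <- function(acc) {
    if (is.null(sequonCache[[acc]])) sequonCache[[acc]] <- findSequons(seqs[[acc]])
    sequonCache[[acc]]
  }

  for (i in seq_len(nrow(psms))) {
    row <- psms[i, ]
    flags <- .splitField(row$mod_flags)[[1]]
    flags <- flags[nzchar(flags)]
    if (length(flags) == 0L) next
    pepPos <- as.integer(sub(":.*", "", flags))
    nf <- length(pepPos)
    if (any(is.na(pepPos)) || any(pepPos < 1L) || any(pepPos > nchar(row$peptide))) {
      stop("malformed mod_flags in glyco-PSM row ", i)
    }
    if (any(substring(row$peptide, pepPos, pepPos) != "N")) {
      stop("flagged position is not an asparagine in glyco-PSM row ", i)
    }
    if (abs(row$delta_mass - nf * shift) > nf * tol) {
      rejected[[length(rejected) + 1L]] <-
        data.frame(row = i, reason = "mass mismatch", stringsAsFactors = FALSE)
      next
    }
    accs <- .splitField(row$accessions)[[1]]
    accs <- accs[accs %in% names(seqs)]
    if (length(accs) == 0L) {
      rejected[[length(rejected) + 1L]] <-
        data.frame(row = i, reason = "unmapped peptide", stringsAsFactors = FALSE)
      next
    }
    ambiguous <- length(accs) > 1L
    for (acc in accs) {
      start <- regexpr(row$peptide, seqs[[acc]], fixed = TRUE)
      if (start == -1L) {
        rejected[[length(rejected) + 1L]] <-
          data.frame(row = i, reason = "peptide not in protein", stringsAsFactors = FALSE)
        next
      }
      sitePos <- as.integer(start) + pepPos - 1L
      sq <- sequonsOf(acc)
      onSequon <- sitePos %in% sq$position
      if (!all(onSequon)) {
        rejected[[length(rejected) + 1L]] <-
          data.frame(row = i, reason = "non-motif deamidation", stringsAsFactors = FALSE)
        next
      }
      accepted[[length(accepted) + 1L]] <- data.frame(
        accession = acc, site_position = sitePos,
        sequon = sq$sequon[match(sitePos, sq$position)],
        peptide = row$peptide, run_id = row$run_id,
        cell_line = row$cell_line, replicate = row$replicate,
        precursor_area = row$precursor_area,
        ambiguous = ambiguous, psm_row = i, stringsAsFactors = FALSE
      )
    }
  }
  emptyAcc <- data.frame(accession = character(0), site_position = integer(0),
                         sequon = character(0), peptide = character(0),
                         run_id = character(0), cell_line = character(0),
                         replicate = integer(0), precursor_area = numeric(0),
                         ambiguous = logical(0), psm_row = integer(0))
  list(
    accepted = if (length(accepted)) do.call(rbind, accepted) else emptyAcc,
    rejected = if (length(rejected)) do.call(rbind, rejected)
               else data.frame(row = integer(0), reason = character(0))
  )
}

#' Normalize glycosite precursor areas within runs
#'
#' For each accepted site and run, the quantitative value is the sum of its
#' supporting-peptide precursor areas divided by the run's total
#' identified-peptide area, making values comparable across runs of
#' different depth. Per-site ratios are then computed against the mean of
#' the reference cell line; sites with zero reference signal keep their
#' normalized values with the ratio flagged unavailable (NA). Ambiguous
#' (multi-protein) records are excluded by default.
#'
#' @param accepted accepted site records from \code{\link{validateGlycoPsm}}.
#' @param runTotals named numeric vector: total identified-peptide area per
#'   run id (all > 0).
#' @param design a \linkS4class{StudyDesign} for the glyco arm.
#' @param referenceLine reference cell line for ratios (default the
#'   design's rank-0 line).
#' @param includeAmbiguous keep multi-protein records (default FALSE).
#' @return \code{SummarizedExperiment} with assays \code{norm} and
#'   \code{ratio}; rows are (accession, site) pairs.
#' @export
normalizeGlycoAreas <- function(accepted, runTotals, design,
                                referenceLine = NULL, includeAmbiguous = FALSE) {
  if (is.null(referenceLine)) {
    referenceLine <- cellLines(design)[metastaticRanks(design)[cellLines(design)] == 0L]
  }
  if (!includeAmbiguous) accepted <- accepted[!accepted$ambiguous, , drop = FALSE]
  if (nrow(accepted) == 0L) stop("no accepted glycosites to quantify")
  runs <- .runTable(design)
  if (any(is.na(runTotals[runs$run_id])) || any(runTotals[runs$run_id] <= 0)) {
    stop("every run needs a positive total identified-peptide area")
  }

  site <- paste(accepted$accession, accepted$site_position, sep = "@")
  siteLevels <- sort(unique(site))
  m <- matrix(0, nrow = length(siteLevels), ncol = nrow(runs),
              dimnames = list(siteLevels, runs$run_id))
  agg <- tapply(accepted$precursor_area,
                list(factor(site, siteLevels), factor(accepted$run_id, runs$run_id)),
                sum)
  agg[is.na(agg)] <- 0
  m[] <- agg
  norm <- sweep(m, 2, runTotals[runs$run_id], "/")

  refCols <- runs$run_id[runs$cell_line == referenceLine]
  refMean <- rowMeans(norm[, refCols, drop = FALSE])
  ratio <- norm / ifelse(refMean > 0, refMean, NA_real_)

  first <- match(siteLevels, site)
  SummarizedExperiment::SummarizedExperiment(
    assays = list(norm = norm, ratio = ratio),
    rowData = S4Vectors::DataFrame(
      accession = accepted$accession[first],
      site_position = accepted$site_position[first],
      sequon = accepted$sequon[first],
      n_peptides = as.integer(tapply(accepted$peptide, factor(site, siteLevels),
                                     function(p) length(unique(p)))),
      row.names = siteLevels
    ),
    colData = S4Vectors::DataFrame(runs, row.names = runs$run_id)
  )
}

#' Trend clustering of glycosites across the metastatic ordering
#'
#' Applies the same k-means trend partition used for the secretome to the
#' normalized glycosite table, with k = 2 (increased vs decreased).
#'
#' @param gqt \code{SummarizedExperiment} from
#'   \code{\link{normalizeGlycoAreas}} (assay \code{norm}).
#' @param design glyco-arm \linkS4class{StudyDesign}.
#' @param k number of clusters (default 2).
#' @param seed integer seed for the k-means restarts.
#' @param nRestarts random restarts (default 20).
#' @return list: the cluster assignment (see \code{\link{kmeansProfiles}}),
#'   per-cluster trend labels, and \code{increased} — accessions and sites
#'   of the increased cluster(s).
#' @export
glycoTrend <- function(gqt, design, k = 2, seed = 1, nRestarts = 20) {
  m <- SummarizedExperiment::assay(gqt, "norm")
  fit <- kmeansProfiles(m, SummarizedExperiment::colData(gqt)$cell_line,
                        design, k = k, seed = seed, nRestarts = nRestarts)
  labels <- labelTrendClusters(fit, design)
  upClusters <- which(labels == "increased")
  upSites <- names(fit$cluster)[fit$cluster %in% upClusters]
  rd <- SummarizedExperiment::rowData(gqt)
  list(assignment = fit, labels = labels,
       increased = list(
         sites = upSites,
         accessions = sort(unique(rd$accession[rownames(rd) %in% upSites]))
       ))
}
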