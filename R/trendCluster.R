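#' K-means clustering of expression profiles over the metastatic ordering
#'
#' Averages replicate columns per cell line (in metastatic rank order),
#' z-score standardizes each row, and partitions the standardized 4-point
#' profiles by Euclidean k-means, keeping the best of \code{nRestarts}
#' random starts by total within-cluster sum of squares. Rows with zero
#' variance across lines standardize to all-zeros and are assigned
#' normally. Deterministic for a fixed seed; the partition is invariant to
#' row order up to cluster relabeling.
#'
#' @param m numeric matrix, rows = features (GPs or glycosites), columns =
#'   runs.
#' @param colLines cell line of each column.
#' @param design a \linkS4class{StudyDesign} giving the metastatic order.
#' @param k number of clusters (3 for the secretome arm, 2 for the glyco
#'   arm).
#' @param seed integer seed.
#' @param nRestarts number of k-means restarts (default 20).
#' @return list: \code{cluster} (named assignment), \code{centers}
#'   (k x n-lines centroid matrix in metastatic order), \code{k},
#'   \code{tot.withinss}, and \code{profiles} (the standardized matrix).
#' @export
kmeansProfiles <- function(m, colLines, design, k, seed = 1, nRestarts = 20) {
  m <- as.matrix(m)
  if (k > nrow(m)) stop("k exceeds the number of rows to cluster")
  ranks <- metastaticRanks(design)
  lines <- names(sort(ranks))
  prof <- sapply(lines, function(l) rowMeans(m[, colLines == l, drop = FALSE]))
  if (is.null(dim(prof))) prof <- matrix(prof, nrow = 1, dimnames = list(rownames(m), lines))

  z <- t(apply(prof, 1, function(v) {
    s <- stats::sd(v)
    if (s == 0) rep(0, length(v)) else (v - mean(v)) / s
  }))
  dimnames(z) <- dimnames(prof)

  if (k == nrow(z)) {
    # degenerate case: every row its own cluster
    fit <- list(cluster = seq_len(nrow(z)), centers = z,
                size = rep(1L, nrow(z)), tot.withinss = 0)
  } else {
    fit <- NULL
    for (attempt in 0:9) {
      fit <- try(.withSeed(.deriveSeed(seed, attempt),
                           stats::kmeans(z, centers = k, nstart = nRestarts)),
                 silent = TRUE)
      if (!inherits(fit, "try-error") && all(fit$size > 0)) break
    }
    if (inherits(fit, "try-error")) {
      # duplicated rows can starve the random starts; seed from distinct rows
      uniq <- unique(z)
      if (k > nrow(uniq)) stop("k exceeds the number of distinct profiles")
      fit <- stats::kmeans(z, centers = uniq[seq_len(k), , drop = FALSE])
    }
  }

  list(cluster = stats::setNames(fit$cluster, rownames(z)),
       centers = fit$centers, k = k,
       tot.withinss = fit$tot.withinss, profiles = z)
}

#' Label trend clusters by centroid monotonicity
#'
#' A cluster is labeled \code{increased} when its centroid is strictly
#' monotone increasing over the metastatic ranks (Spearman rho = +1),
#' \code{decreased} when strictly monotone decreasing, and \code{mixed}
#' otherwise (ties count as non-strict).
#'
#' @param assignment result of \code{\link{kmeansProfiles}}.
#' @param design a \linkS4class{StudyDesign}.
#' @return character vector of labels, one per cluster.
#' @export
labelTrendClusters <- function(assignment, design) {
  centers <- assignment$centers
  ranks <- metastaticRanks(design)
  ord <- order(ranks[colnames(centers)])
  apply(centers[, ord, drop = FALSE], 1, function(v) {
    d <- diff(v)
    if (all(d > 0)) "increased" else if (all(d < 0)) "decreased" else "mixed"
  })
}

#' Intersect the increased secretome and N-glycosecretome sets
#'
#' The validation candidates are the gene products assigned to an increased
#' trend cluster in both the secretome and the glyco arm.
#'
#' @param secretomeIncreased GP ids of the secretome's increased cluster.
#' @param glycoIncreased GP ids of the glyco arm's increased cluster.
#' @return sorted character vector of candidate GP ids (possibly empty,
#'   with a message).
#' @export
intersectCandidates <- function(secretomeIncreased, glycoIncreased) {
  out <- sort(intersect(secretomeIncreased, glycoIncreased))
  if (length(out) == 0L) message("no candidates: the increased sets are disjoint")
  out
}
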