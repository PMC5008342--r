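#' Target-decoy peptide q-values
#'
#' Estimates a q-value for every PSM from the decoy score distribution.
#' Records are ranked by descending ion score (decoys counted before
#' targets at equal score, the conservative convention); at each score
#' threshold t the running FDR is
#' (decoys with score >= t) / max(1, targets with score >= t), and the
#' q-value of a record is the minimum FDR over all thresholds at or below
#' its score (the standard monotonized target-decoy estimate). Decoy
#' records receive q-values too but are removed by the downstream filter.
#'
#' @param psms PSM table with numeric \code{ion_score} and logical
#'   \code{is_decoy} columns.
#' @return the same table with a \code{q_value} column (input order
#'   preserved). Empty input passes through.
#' @export
computePeptideFdr <- function(psms) {
  if (nrow(psms) == 0L) {
    psms$q_value <- numeric(0)
    return(psms)
  }
  stopifnot(is.numeric(psms$ion_score), is.logical(psms$is_decoy))
  ord <- order(-psms$ion_score, -psms$is_decoy)
  decoy <- psms$is_decoy[ord]
  cumD <- cumsum(decoy)
  cumT <- cumsum(!decoy)
  fdr <- cumD / pmax(1, cumT)
  q <- rev(cummin(rev(fdr)))
  psms$q_value <- q[order(ord)]
  psms
}

#' Quality-control tier table
#'
#' A tier is an (ion score, q-value) acceptance pair; a PSM passes a tier
#' when its score is strictly above the tier's minimum and its q-value
#' strictly below the tier's maximum. The default two tiers — score > 30
#' with q < 1\%, or score > 40 with q < 5\% — trade score stringency
#' against FDR stringency.
#'
#' @param min_ion_score numeric vector of score floors.
#' @param max_q parallel vector of q-value ceilings, each in (0, 1].
#' @return data frame of tiers.
#' @export
qcTiers <- function(min_ion_score = c(30, 40), max_q = c(0.01, 0.05)) {
  stopifnot(length(min_ion_score) == length(max_q))
  if (length(max_q) == 0L) stop("at least one QC tier is required")
  if (any(max_q <= 0 | max_q > 1)) stop("max_q must lie in (0, 1]")
  data.frame(min_ion_score = min_ion_score, max_q = max_q)
}

#' Stepwise stringent quality-control filter
#'
#' Retains a target PSM if it satisfies at least one tier (union of the
#' tiers' acceptance regions), drops all decoys, and removes peptides
#' shorter than the identification length floor.
#'
#' @param psms PSM table with \code{q_value} set (see
#'   \code{\link{computePeptideFdr}}).
#' @param tiers tier table from \code{\link{qcTiers}}.
#' @param minLength minimum peptide length (default 7).
#' @return the filtered table of target PSMs. Filtering is idempotent and
#'   monotone: tightening any tier never enlarges the result.
#' @export
stepwiseQcFilter <- function(psms, tiers = qcTiers(), minLength = 7) {
  if (is.null(tiers) || nrow(tiers) == 0L) stop("at least one QC tier is required")
  if (nrow(psms) == 0L) return(psms)
  if (is.null(psms$q_value) || anyNA(psms$q_value)) {
    stop("q_value must be set before filtering; run computePeptideFdr()")
  }
  passAny <- Reduce(`|`, lapply(seq_len(nrow(tiers)), function(i) {
    psms$ion_score > tiers$min_ion_score[i] & psms$q_value < tiers$max_q[i]
  }))
  psms[!psms$is_decoy & nchar(psms$peptide) >= minLength & passAny, , drop = FALSE]
}
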