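#' Secretion-pathway categorization from predictor scores
#'
#' Assigns each protein to one of four secretion categories from the three
#' sequence-predictor outputs (classical signal peptide, non-classical
#' secretion score, predicted transmembrane helices):
#' \describe{
#'   \item{Part4}{classical secretome: signal peptide present and no
#'     transmembrane helix.}
#'   \item{Part3}{extracellular membrane protein: at least one
#'     transmembrane helix (and no Part4 call).}
#'   \item{Part1}{non-classical secretome: no signal peptide, no helix,
#'     SecretomeP score strictly above 0.5.}
#'   \item{Part2}{other: none of the above (SecretomeP <= 0.5).}
#' }
#' The SecretomeP cutoff is strict (> 0.5); the transmembrane cutoff is
#' exact zero. Each branch threshold is an argument.
#'
#' @param scores data frame with columns \code{accession},
#'   \code{signal_peptide} (logical), \code{secretomep_score} (in [0,1])
#'   and \code{tm_count} (integer >= 0).
#' @param secretomepCutoff non-classical secretion cutoff (default 0.5).
#' @param tmCutoff transmembrane-helix count treated as "none" (default 0).
#' @return factor of categories (levels Part1..Part4), named by accession.
#' @examples
#' classifySecretion(data.frame(accession = "P1", signal_peptide = TRUE,
#'                              secretomep_score = 0.2, tm_count = 0))
#' @export
classifySecretion <- function(scores, secretomepCutoff = 0.5, tmCutoff = 0) {
  need <- c("accession", "signal_peptide", "secretomep_score", "tm_count")
  if (!all(need %in% names(scores))) {
    stop("predictor table must have columns: ", paste(need, collapse = ", "))
  }
  with(scores, {
    if (any(is.na(signal_peptide) | is.na(secretomep_score) | is.na(tm_count))) {
      stop("predictor scores contain missing values")
    }
    if (any(secretomep_score < 0 | secretomep_score > 1)) {
      stop("secretomep_score must lie in [0, 1]")
    }
    if (any(tm_count < 0)) stop("tm_count must be >= 0")
    cls <- ifelse(signal_peptide & tm_count <= tmCutoff, "Part4",
           ifelse(tm_count > tmCutoff, "Part3",
           ifelse(secretomep_score > secretomepCutoff, "Part1", "Part2")))
    factor(stats::setNames(cls, accession), levels = paste0("Part", 1:4))
  })
}

#' Summarize secretion-category composition
#'
#' @param categories factor (or character) of Part1..Part4 assignments.
#' @return data frame with per-category counts and fractions (summing to 1).
#' @export
summarizeCategories <- function(categories) {
  if (length(categories) == 0L) stop("empty category set")
  categories <- factor(categories, levels = paste0("Part", 1:4))
  n <- table(categories)
  data.frame(category = names(n), count = as.integer(n),
             fraction = as.numeric(n) / length(categories),
             stringsAsFactors = FALSE)
}
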