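#' StudyDesign: cell lines, metastatic ordering and replication structure
#'
#' Describes the factorial layout of a secretome profiling study: the cell
#' lines with their metastatic rank (0 = non-metastatic control, increasing
#' with metastatic potential), the number of biological replicates, and the
#' number of peptide-level isoelectric-focusing fractions per run.
#'
#' The default layout is four hepatocellular carcinoma lines in the order
#' Hep3B (no metastatic potential) < MHCC97L (low) < MHCC97H (high) <
#' HCCLM3 (highest), three biological replicates and twelve fractions.
#'
#' @slot cellLines character vector of cell-line labels.
#' @slot ranks integer metastatic ranks, a permutation of 0..(n-1) parallel
#'   to \code{cellLines}.
#' @slot nReplicates integer, biological replicates per cell line.
#' @slot nFractions integer, fractions per (cell line, replicate) run.
#'
#' @aliases StudyDesign-class
#' @exportClass StudyDesign
setClass("StudyDesign",
  representation(
    cellLines   = "character",
    ranks       = "integer",
    nReplicates = "integer",
    nFractions  = "integer"
  )
)

setValidity("StudyDesign", function(object) {
  n <- length(object@cellLines)
  if (n < 1L) return("at least one cell line is required")
  if (length(object@ranks) != n)
    return("ranks must be parallel to cellLines")
  if (!identical(sort(object@ranks), 0:(n - 1L)))
    return("ranks must be a permutation of 0..(n-1)")
  if (anyDuplicated(object@cellLines))
    return("cell-line labels must be unique")
  if (object@nReplicates < 1L || object@nFractions < 1L)
    return("replicate and fraction counts must be >= 1")
  TRUE
})

#' Construct a StudyDesign
#'
#' @param cellLines cell-line labels, given in metastatic order unless
#'   \code{ranks} says otherwise.
#' @param ranks integer metastatic ranks (permutation of 0..(n-1)).
#' @param nReplicates biological replicates per line.
#' @param nFractions fractions per run.
#' @return a \linkS4class{StudyDesign} object.
#' @examples
#' studyDesign()                     # the default 4-line HCC panel
#' studyDesign(nReplicates = 2)      # glyco arm layout
#' @export
studyDesign <- function(cellLines = c("Hep3B", "MHCC97L", "MHCC97H", "HCCLM3"),
                        ranks = seq_along(cellLines) - 1L,
                        nReplicates = 3,
                        nFractions = 12) {
  methods::new("StudyDesign",
    cellLines = as.character(cellLines),
    ranks = as.integer(ranks),
    nReplicates = as.integer(nReplicates),
    nFractions = as.integer(nFractions)
  )
}

#' @describeIn studyDesign cell-line labels.
#' @param object,design a \code{StudyDesign}.
#' @export
setGeneric("cellLines", function(object) standardGeneric("cellLines"))

#' @rdname studyDesign
#' @export
setMethod("cellLines", "StudyDesign", function(object) object@cellLines)

#' @describeIn studyDesign integer metastatic ranks, named by cell line.
#' @export
setGeneric("metastaticRanks", function(object) standardGeneric("metastaticRanks"))

#' @rdname studyDesign
#' @export
setMethod("metastaticRanks", "StudyDesign", function(object)
  stats::setNames(object@ranks, object@cellLines))

#' @describeIn studyDesign number of biological replicates.
#' @export
setGeneric("nReplicates", function(object) standardGeneric("nReplicates"))

#' @rdname studyDesign
#' @export
setMethod("nReplicates", "StudyDesign", function(object) object@nReplicates)

#' @describeIn studyDesign number of fractions per run.
#' @export
setGeneric("nFractions", function(object) standardGeneric("nFractions"))

#' @rdname studyDesign
#' @export
setMethod("nFractions", "StudyDesign", function(object) object@nFractions)

setMethod("show", "StudyDesign", function(object) {
  ord <- order(object@ranks)
  cat("StudyDesign:", length(object@cellLines), "cell lines,",
      object@nReplicates, "replicates x", object@nFractions, "fractions\n")
  cat("  metastatic order:", paste(object@cellLines[ord], collapse = " < "), "\n")
})

# run labels in a fixed, reproducible order (line-major, then replicate)
.runTable <- function(design) {
  lines <- cellLines(design)
  reps <- seq_len(nReplicates(design))
  out <- expand.grid(replicate = reps, cell_line = lines,
                     stringsAsFactors = FALSE)[, c("cell_line", "replicate")]
  out$run_id <- paste(out$cell_line, out$replicate, sep = "_R")
  out
}
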