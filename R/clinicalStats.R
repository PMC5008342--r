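#' Pearson chi-square test for a 2 x k contingency table
#'
#' Classical chi-square test of independence with expected counts
#' E_ij = row_i x col_j / N and, optionally, the Yates continuity
#' correction (|O - E| reduced by 0.5, applied to 2 x 2 tables only).
#' Degenerate margins (a zero row or column total) are an error.
#'
#' @param table integer matrix of non-negative counts, 2 rows (marker
#'   positive/negative) by k >= 2 covariate levels.
#' @param correct apply the continuity correction (2 x 2 tables only).
#' @return list with \code{statistic}, \code{df}, \code{p.value} and the
#'   \code{expected} counts.
#' @examples
#' # liver cirrhosis vs tumor DKK3 expression in a 75-patient HCC cohort
#' pearsonChi2(matrix(c(12, 10, 33, 20), nrow = 2))$p.value   # 0.534
#' @export
pearsonChi2 <- function(table, correct = FALSE) {
  table <- as.matrix(table)
  if (nrow(table) < 2L || ncol(table) < 2L) stop("need at least a 2 x 2 table")
  if (any(table < 0) || sum(table) < 1) stop("counts must be non-negative with a positive total")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("degenerate margin: a zero row or column total")
  }
  if (correct && !all(dim(table) == 2L)) {
    stop("the continuity correction applies to 2 x 2 tables only")
  }
  fit <- suppressWarnings(stats::chisq.test(table, correct = correct))
  list(statistic = unname(fit$statistic), df = unname(fit$parameter),
       p.value = fit$p.value, expected = fit$expected)
}

#' Fisher's exact test for a 2 x 2 table
#'
#' Two-sided exact test by hypergeometric enumeration over all tables with
#' the observed margins; the p-value sums the probabilities of tables no
#' more probable than the observed one.
#'
#' @param table 2 x 2 matrix of non-negative counts.
#' @return two-sided p-value.
#' @export
fisherExact2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == 2L)) stop("Fisher's exact test here requires a 2 x 2 table")
  if (sum(table) < 1) stop("grand total must be positive")
  stats::fisher.test(table)$p.value
}

#' Clinicopathological contingency tables for tumor DKK3 expression
#'
#' A packaged set of 2 x k contingency tables relating DKK3
#' immunohistochemistry status (positive/negative) to clinicopathological
#' variables in a 75-patient hepatocellular carcinoma cohort, together with
#' the published p-value for each variable and the test variant that
#' reproduces it (\code{pearson} = uncorrected chi-square, \code{yates} =
#' continuity-corrected chi-square).
#'
#' @return named list; each element holds \code{counts} (2 x k matrix, rows
#'   positive/negative), \code{variant} and \code{published_p}.
#' @examples
#' tabs <- dkk3ClinicalTables()
#' pearsonChi2(tabs$liver_cirrhosis$counts)$p.value
#' @export
dkk3ClinicalTables <- function() {
  path <- system.file("extdata", "dkk3_clinical_tables.csv",
                      package = "glycoSecretome", mustWork = TRUE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- lapply(split(raw, raw$variable), function(d) {
    d <- d[order(d$level_order), ]
    counts <- t(as.matrix(d[, c("positive", "negative")]))
    dimnames(counts) <- list(c("positive", "negative"), d$level)
    list(counts = counts, variant = d$variant[1], published_p = d$published_p[1])
  })
  out[unique(raw$variable)]
}

#' Run the pinned test variant on each clinical table
#'
#' Applies to every table the chi-square variant recorded with it
#' (\code{pearson}, \code{yates} or \code{fisher}) and returns the
#' recomputed p-values alongside the published ones.
#'
#' @param tables list as returned by \code{\link{dkk3ClinicalTables}}.
#' @return data frame: variable, variant, recomputed \code{p}, published p.
#' @export
clinicalAssociation <- function(tables = dkk3ClinicalTables()) {
  rows <- lapply(names(tables), function(v) {
    tb <- tables[[v]]
    p <- switch(tb$variant,
      pearson = pearsonChi2(tb$counts, correct = FALSE)$p.value,
      yates   = pearsonChi2(tb$counts, correct = TRUE)$p.value,
      fisher  = fisherExact2x2(tb$counts),
      stop("unknown test variant: ", tb$variant)
    )
    data.frame(variable = v, variant = tb$variant, p = p,
               published_p = tb$published_p, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Build a 2 x k marker-by-covariate contingency table from a cohort
#'
#' @param cohort patient table from \code{\link{simulateClinicalCohort}}.
#' @param variable name of a categorical covariate column.
#' @return 2 x k integer matrix (rows: marker positive/negative).
#' @export
cohortContingency <- function(cohort, variable) {
  if (!variable %in% names(cohort)) stop("no such covariate: ", variable)
  t(table(factor(cohort[[variable]]),
          factor(cohort$marker, levels = c("positive", "negative"))))
}
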