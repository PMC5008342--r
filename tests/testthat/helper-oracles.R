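# Independent brute-force oracles used across the suite. Each one is a
# deliberately naive re-derivation of a quantity the package computes by a
# different route.

# q-values by explicit enumeration over all score thresholds
oracleQValues <- function(score, decoy) {
  thr <- sort(unique(score), decreasing = TRUE)
  fdrAt <- vapply(thr, function(t) {
    sum(decoy & score >= t) / max(1, sum(!decoy & score >= t))
  }, numeric(1))
  vapply(score, function(s) min(fdrAt[thr <= s]), numeric(1))
}

# tryptic peptide count through a different mechanism: insert break marks
# after K/R not followed by P, then split
oracleTrypticCount <- function(seq, minLength = 7) {
  marked <- gsub("([KR])(?!P)", "\\1|", seq, perl = TRUE)
  segs <- strsplit(marked, "|", fixed = TRUE)[[1]]
  sum(nchar(segs) >= minLength)
}

# sequon positions by an explicit sliding window
oracleSequons <- function(seq) {
  n <- nchar(seq)
  if (n < 3) return(integer(0))
  hits <- integer(0)
  for (i in 1:(n - 2)) {
    a <- substring(seq, i, i)
    b <- substring(seq, i + 1, i + 1)
    c3 <- substring(seq, i + 2, i + 2)
    if (a == "N" && b != "P" && (c3 == "S" || c3 == "T")) hits <- c(hits, i)
  }
  hits
}

# all-pairs substring scan for the peptide-protein map
oracleSubstringMap <- function(peptides, seqs) {
  out <- lapply(peptides, function(p) {
    hit <- character(0)
    for (a in names(seqs)) {
      if (length(Biostrings::matchPattern(p, Biostrings::AAString(seqs[[a]]))) > 0) {
        hit <- c(hit, a)
      }
    }
    hit
  })
  names(out) <- peptides
  out
}

# exhaustive minimum set cover size over protein subsets
oracleMinCoverSize <- function(map) {
  accs <- sort(unique(unlist(map)))
  peps <- names(map)
  for (k in seq_along(accs)) {
    combs <- utils::combn(accs, k, simplify = FALSE)
    for (cc in combs) {
      covered <- vapply(map, function(h) any(h %in% cc), logical(1))
      if (all(covered)) return(k)
    }
  }
  length(accs)
}

# chi-square by direct O/E summation (standard clamped Yates form)
oracleChi2 <- function(tab, correct = FALSE) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  cc <- if (correct && all(dim(tab) == 2L)) 0.5 else 0
  stat <- sum(pmax(0, abs(tab - E) - cc)^2 / E)
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  list(statistic = stat, df = df, p.value = stats::pchisq(stat, df, lower.tail = FALSE))
}

# Fisher two-sided p by hypergeometric enumeration over the margin support
oracleFisher <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  lo <- max(0, r1 + c1 - n); hi <- min(r1, c1)
  k <- lo:hi
  pr <- stats::dhyper(k, c1, n - c1, r1)
  obs <- stats::dhyper(tab[1, 1], c1, n - c1, r1)
  sum(pr[pr <= obs * (1 + 1e-7)])
}

# adjusted Rand index between two partitions
oracleARI <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sumij <- sum(comb2(tab))
  ai <- sum(comb2(rowSums(tab))); bj <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  exp_ij <- ai * bj / n
  (sumij - exp_ij) / ((ai + bj) / 2 - exp_ij)
}

# small ready-made synthetic study shared by several files
tinyStudy <- function(seed = 42, nProteins = 40, ...) {
  generateProteome(nProteins, lengthRange = c(80, 200), seed = seed, ...)
}
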