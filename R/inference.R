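#' Map peptides to the proteins that contain them
#'
#' Exact substring search of each distinct peptide against every protein
#' sequence (I and L are treated as distinct residues). Peptides matching
#' no protein are dropped with a warning.
#'
#' @param peptides character vector of peptide sequences (or a PSM table
#'   with a \code{peptide} column).
#' @param proteome named \code{AAStringSet} or named character vector of
#'   protein sequences.
#' @return named list: peptide -> character vector of accessions.
#' @export
buildPeptideProteinMap <- function(peptides, proteome) {
  if (is.data.frame(peptides)) peptides <- peptides$peptide
  peptides <- unique(as.character(peptides))
  seqs <- as.character(proteome)
  acc <- names(seqs)
  if (is.null(acc) || length(seqs) == 0L) stop("proteome must be non-empty and named")
  hits <- lapply(peptides, function(p) acc[grepl(p, seqs, fixed = TRUE)])
  names(hits) <- peptides
  miss <- lengths(hits) == 0L
  if (any(miss)) {
    warning(sum(miss), " peptide(s) matched no protein and were dropped")
    hits <- hits[!miss]
  }
  hits
}

# internal group record builder
.groupDf <- function(group_id, representative, members, peptides,
                     unique_peptides, assigned_peptides, n_psms) {
  data.frame(
    group_id = group_id, representative = representative,
    members = I(members), peptides = I(peptides),
    unique_peptides = I(unique_peptides),
    assigned_peptides = I(assigned_peptides),
    n_psms = n_psms, stringsAsFactors = FALSE
  )
}

#' Parsimony grouping of proteins from shared peptide evidence
#'
#' Applies the parsimony principle: report the smallest set of protein
#' groups that explains every observed peptide. Three passes:
#' \enumerate{
#'   \item proteins with identical peptide sets are merged into one group;
#'   \item proteins whose peptide set is a strict subset of another's are
#'     subsumed (removed as independent groups);
#'   \item remaining ambiguity is resolved by greedy set cover: the group
#'     covering the most still-uncovered peptides is selected repeatedly
#'     until every peptide is covered.
#' }
#' Greedy ties break by larger total PSM count, then lexicographically by
#' representative accession, so the output is order-independent.
#'
#' @param map peptide -> accessions list from
#'   \code{\link{buildPeptideProteinMap}}.
#' @param psmCounts optional named numeric vector of PSM counts per peptide
#'   (defaults to 1 per peptide) used for tie-breaking and evidence totals.
#' @param proteome optional named sequences; when given, each group's
#'   representative is its longest member (otherwise the lexicographic first).
#' @return data frame of groups with list columns \code{members},
#'   \code{peptides}, \code{unique_peptides} (peptides hitting no other
#'   retained group) and \code{assigned_peptides} (the peptides this group
#'   claimed during the cover, a partition of all peptides).
#' @export
parsimonyGroup <- function(map, psmCounts = NULL, proteome = NULL) {
  if (length(map) == 0L) stop("peptide-protein map is empty")
  peps <- names(map)
  if (is.null(psmCounts)) psmCounts <- stats::setNames(rep(1, length(peps)), peps)

  # invert to accession -> peptide set
  accs <- sort(unique(unlist(map, use.names = FALSE)))
  acc2pep <- lapply(accs, function(a) sort(peps[vapply(map, function(h) a %in% h, logical(1))]))
  names(acc2pep) <- accs

  # (1) merge identical peptide sets
  key <- vapply(acc2pep, paste, character(1), collapse = "\r")
  mergedMembers <- split(accs, key)
  mergedPeps <- acc2pep[!duplicated(key)]
  names(mergedPeps) <- key[!duplicated(key)]
  groups <- lapply(names(mergedPeps), function(k)
    list(members = sort(mergedMembers[[k]]), peptides = mergedPeps[[k]]))

  # (2) strict-subset subsumption
  sizes <- vapply(groups, function(g) length(g$peptides), integer(1))
  subsumed <- vapply(seq_along(groups), function(i) {
    any(vapply(seq_along(groups), function(j) {
      j != i && sizes[j] > sizes[i] && all(groups[[i]]$peptides %in% groups[[j]]$peptides)
    }, logical(1)))
  }, logical(1))
  groups <- groups[!subsumed]

  pickRep <- function(members) {
    if (!is.null(proteome)) {
      lens <- nchar(as.character(proteome)[members])
      members[order(-lens, members)][1]
    } else sort(members)[1]
  }
  reps <- vapply(groups, function(g) pickRep(g$members), character(1))

  # (3) greedy set cover with deterministic tie-breaks
  uncovered <- peps
  selected <- integer(0)
  assigned <- vector("list", length(groups))
  while (length(uncovered) > 0L) {
    gain <- vapply(groups, function(g) sum(g$peptides %in% uncovered), numeric(1))
    gain[selected] <- -1
    totals <- vapply(groups, function(g) sum(psmCounts[g$peptides]), numeric(1))
    best <- order(-gain, -totals, reps)[1]
    if (gain[best] <= 0) break  # cannot happen: every peptide is in some group
    selected <- c(selected, best)
    assigned[[best]] <- intersect(groups[[best]]$peptides, uncovered)
    uncovered <- setdiff(uncovered, groups[[best]]$peptides)
  }
  keep <- sort(selected)
  groups <- groups[keep]
  reps <- reps[keep]
  assigned <- assigned[keep]

  # unique = peptides present in exactly one retained group
  retainedSets <- lapply(groups, `[[`, "peptides")
  hitCount <- table(unlist(retainedSets))
  uniq <- lapply(retainedSets, function(p) p[hitCount[p] == 1L])

  ord <- order(reps)
  .groupDf(
    group_id = reps[ord], representative = reps[ord],
    members = lapply(groups, `[[`, "members")[ord],
    peptides = retainedSets[ord], unique_peptides = uniq[ord],
    assigned_peptides = assigned[ord],
    n_psms = vapply(assigned, function(p) sum(psmCounts[p]), numeric(1))[ord]
  )
}

#' Collapse protein groups to gene products
#'
#' Groups whose representative maps to the same gene identifier are merged
#' into one gene product (GP): member and peptide sets are unioned, claimed
#' peptides concatenated, and PSM evidence summed. Accessions missing from
#' the map trigger a warning and stand as their own GP. Peptide uniqueness
#' is re-evaluated at GP level: a peptide shared only between accessions of
#' the same gene counts as unique.
#'
#' @param groups output of \code{\link{parsimonyGroup}}.
#' @param geneMap named character vector or two-column data frame
#'   (\code{accession}, \code{gene_id}).
#' @param proteome optional named sequences for representative re-selection
#'   (longest member).
#' @return data frame of GP-level groups with a \code{gp_id} column.
#' @export
collapseToGp <- function(groups, geneMap, proteome = NULL) {
  if (is.data.frame(geneMap)) {
    geneMap <- stats::setNames(as.character(geneMap$gene_id), geneMap$accession)
  }
  gene <- geneMap[groups$representative]
  miss <- is.na(gene)
  if (any(miss)) {
    warning(sum(miss), " accession(s) missing from the gene map; used as their own GP")
    gene[miss] <- groups$representative[miss]
  }

  idx <- split(seq_len(nrow(groups)), gene)
  merged <- lapply(names(idx), function(g) {
    i <- idx[[g]]
    members <- sort(unique(unlist(groups$members[i])))
    rep <- if (!is.null(proteome)) {
      lens <- nchar(as.character(proteome)[members])
      members[order(-lens, members)][1]
    } else groups$representative[i][1]
    list(gp_id = g, representative = rep,
         members = members,
         peptides = sort(unique(unlist(groups$peptides[i]))),
         assigned = sort(unique(unlist(groups$assigned_peptides[i]))),
         n_psms = sum(groups$n_psms[i]))
  })

  sets <- lapply(merged, `[[`, "peptides")
  hitCount <- table(unlist(sets))
  uniq <- lapply(sets, function(p) p[hitCount[p] == 1L])

  out <- .groupDf(
    group_id = vapply(merged, `[[`, character(1), "gp_id"),
    representative = vapply(merged, `[[`, character(1), "representative"),
    members = lapply(merged, `[[`, "members"),
    peptides = sets, unique_peptides = uniq,
    assigned_peptides = lapply(merged, `[[`, "assigned"),
    n_psms = vapply(merged, `[[`, numeric(1), "n_psms")
  )
  names(out)[names(out) == "group_id"] <- "gp_id"
  out[order(out$gp_id), , drop = FALSE]
}

#' Restrict GP groups to those quantifiable by unique peptides
#'
#' GPs whose entire evidence consists of peptides shared with other GPs are
#' excluded from quantification (they remain in identification lists).
#'
#' @param gpGroups GP-level groups from \code{\link{collapseToGp}}.
#' @return the subset with at least one unique peptide.
#' @export
selectQuantifiable <- function(gpGroups) {
  gpGroups[lengths(gpGroups$unique_peptides) > 0L, , drop = FALSE]
}
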