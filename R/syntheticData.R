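#' Generate a synthetic proteome with planted ground truth
#'
#' Draws random protein sequences over the 20 standard residues, enriches
#' them with N-glycosylation sequons to a target density, and plants, per
#' protein: an abundance trend over the metastatic ordering (increased,
#' decreased or flat), a base abundance, a fold step per metastatic rank, a
#' secretion category, and a set of true glycosites chosen among the
#' sequence's sequons. Every generator in this package is a pure function
#' of its arguments including the seed.
#'
#' The planted abundance model is
#' abundance(line) = base x fold^rank for increased proteins,
#' base x fold^(-rank) for decreased, and base for flat — the simplest
#' monotone model consistent with trend clusters over a metastatic
#' gradient.
#'
#' @param nProteins number of proteins (0 gives an empty proteome).
#' @param lengthRange integer c(min, max) sequence length, min >= 7.
#' @param sequonRate expected sequons per 100 residues (default 1).
#' @param seed integer seed.
#' @param trendProps named proportions for \code{increased},
#'   \code{decreased}, \code{flat} (default 0.1 / 0.1 / 0.8).
#' @param foldStep fold change per metastatic rank for non-flat proteins
#'   (> 1, default 2).
#' @param classProbs category probabilities for Part1..Part4 (defaults
#'   0.52 / 0.13 / 0.14 / 0.21, the composition typical of a secretome's
#'   differentially expressed set).
#' @param glycositeRate probability that a sequon carries a planted
#'   glycosite (default 0.5).
#' @return list with \code{proteome} (named \code{AAStringSet}),
#'   \code{truth} (one row per protein: accession, gene_id, trend,
#'   base_abundance, fold_step, secretion_class, n_sequons, list column
#'   \code{glycosites}), and \code{geneMap} (accession -> gene_id).
#' @export
generateProteome <- function(nProteins, lengthRange = c(150, 400),
                             sequonRate = 1, seed = 1,
                             trendProps = c(increased = 0.1, decreased = 0.1, flat = 0.8),
                             foldStep = 2,
                             classProbs = c(Part1 = 0.52, Part2 = 0.13,
                                            Part3 = 0.14, Part4 = 0.21),
                             glycositeRate = 0.5) {
  if (nProteins < 0) stop("nProteins must be >= 0")
  if (length(lengthRange) != 2L || lengthRange[1] > lengthRange[2] || lengthRange[1] < 7) {
    stop("lengthRange must be c(min, max) with 7 <= min <= max")
  }
  if (foldStep <= 1) stop("foldStep must be > 1 for non-flat trends")
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  emptyTruth <- data.frame(
    accession = character(0), gene_id = character(0), length = integer(0),
    trend = character(0), base_abundance = numeric(0), fold_step = numeric(0),
    secretion_class = character(0), n_sequons = integer(0),
    glycosites = I(list()), stringsAsFactors = FALSE
  )
  if (nProteins == 0L) {
    return(list(proteome = Biostrings::AAStringSet(), truth = emptyTruth,
                geneMap = data.frame(accession = character(0), gene_id = character(0))))
  }

  .withSeed(seed, {
    lens <- sample(lengthRange[1]:lengthRange[2], nProteins, replace = TRUE)
    seqs <- vapply(lens, function(L) paste(sample(aa, L, replace = TRUE), collapse = ""),
                   character(1))
    # enrich to the target sequon density by overwriting random triplets
    seqs <- vapply(seq_along(seqs), function(i) {
      s <- seqs[i]
      L <- lens[i]
      want <- stats::rpois(1, L * sequonRate / 100)
      have <- nrow(findSequons(s))
      extra <- want - have
      tries <- 0L
      while (extra > 0L && tries < 50L) {
        pos <- sample(seq_len(L - 2L), 1)
        x <- sample(setdiff(aa, "P"), 1)
        st <- sample(c("S", "T"), 1)
        cand <- paste0(substring(s, 1, pos - 1L), "N", x, st,
                       substring(s, pos + 3L, L))
        if (nrow(findSequons(cand)) > nrow(findSequons(s))) {
          s <- cand
          extra <- extra - 1L
        }
        tries <- tries + 1L
      }
      s
    }, character(1))

    acc <- sprintf("NP_%06d", seq_len(nProteins))
    gene <- sprintf("GENE%05d", seq_len(nProteins))
    trend <- sample(names(trendProps), nProteins, replace = TRUE, prob = trendProps)
    base <- stats::rlnorm(nProteins, meanlog = 0, sdlog = 0.5)
    cls <- sample(names(classProbs), nProteins, replace = TRUE, prob = classProbs)

    sequons <- lapply(seqs, findSequons)
    sites <- lapply(sequons, function(sq) {
      if (nrow(sq) == 0L) return(integer(0))
      sq$position[stats::runif(nrow(sq)) < glycositeRate]
    })

    truth <- data.frame(
      accession = acc, gene_id = gene, length = nchar(seqs),
      trend = trend, base_abundance = base,
      fold_step = ifelse(trend == "flat", 1, foldStep),
      secretion_class = cls,
      n_sequons = vapply(sequons, nrow, integer(1)),
      glycosites = I(sites), stringsAsFactors = FALSE
    )
    proteome <- Biostrings::AAStringSet(stats::setNames(seqs, acc))
    list(proteome = proteome, truth = truth,
         geneMap = data.frame(accession = acc, gene_id = gene,
                              stringsAsFactors = FALSE))
  })
}

# planted abundance of each protein in a given cell line
.plantedAbundance <- function(truth, rank) {
  ifelse(truth$trend == "increased", truth$base_abundance * truth$fold_step^rank,
  ifelse(truth$trend == "decreased", truth$base_abundance * truth$fold_step^(-rank),
         truth$base_abundance))
}

#' Simulate PSM tables for the secretome arm
#'
#' For every (cell line, replicate) run, each protein's PSM count is drawn
#' Poisson with mean abundance(line) x theoretical-peptide-count x depth
#' (times a mean-one log-normal replicate effect); peptides are sampled
#' uniformly from the protein's full tryptic peptides of length >= 7, and
#' PSMs are spread over fractions by a uniform multinomial. Target ion
#' scores are drawn from a high Normal, decoy scores from a lower null,
#' both truncated at zero; decoys carry reversed peptides. Proteins with
#' zero theoretical peptides yield zero PSMs. q-values are left unset.
#'
#' @param proteome,truth from \code{\link{generateProteome}}.
#' @param design a \linkS4class{StudyDesign}.
#' @param depth expected PSMs per abundance unit per theoretical peptide
#'   (default 1).
#' @param decoyFraction expected proportion of decoy PSMs (default 0.1).
#' @param scoreParams list with \code{target} and \code{decoy} c(mean, sd)
#'   for the ion-score distributions.
#' @param areaSigma log-normal sd of precursor areas (natural-log scale).
#' @param replicateSigma log-normal sd of the per-(protein, run) abundance
#'   multiplier (mean one; 0 disables replicate noise).
#' @param seed integer seed.
#' @return PSM data frame in the package's TSV dialect: run_id, cell_line,
#'   replicate, fraction, spectrum_id, peptide, accessions, ion_score,
#'   is_decoy, precursor_area, mod_flags.
#' @export
simulatePsmTables <- function(proteome, truth, design, depth = 1,
                              decoyFraction = 0.1,
                              scoreParams = list(target = c(45, 8), decoy = c(20, 8)),
                              areaSigma = 0.25, replicateSigma = 0.2, seed = 1) {
  if (depth <= 0) stop("depth must be > 0")
  if (decoyFraction < 0 || decoyFraction >= 1) stop("decoyFraction must be in [0, 1)")
  peps <- digestTryptic(as.character(proteome), minLength = 7)
  names(peps) <- names(proteome)
  theo <- lengths(peps)
  runs <- .runTable(design)
  ranks <- metastaticRanks(design)

  .withSeed(seed, {
    out <- vector("list", nrow(runs))
    for (r in seq_len(nrow(runs))) {
      run <- runs[r, ]
      ab <- .plantedAbundance(truth, ranks[[run$cell_line]])
      mult <- if (replicateSigma > 0) {
        stats::rlnorm(nrow(truth), meanlog = -replicateSigma^2 / 2, sdlog = replicateSigma)
      } else rep(1, nrow(truth))
      lambda <- ab * theo[truth$accession] * depth * mult
      n <- stats::rpois(nrow(truth), lambda)
      n[theo[truth$accession] == 0L] <- 0L
      tot <- sum(n)

      pep <- unlist(lapply(which(n > 0L), function(i) {
        sample(peps[[truth$accession[i]]], n[i], replace = TRUE)
      }), use.names = FALSE)
      accv <- rep(truth$accession, n)
      abv <- rep(ab, n)

      nDecoy <- if (decoyFraction > 0 && tot > 0) {
        stats::rpois(1, tot * decoyFraction / (1 - decoyFraction))
      } else 0L
      if (nDecoy > 0L) {
        src <- sample(length(pep), nDecoy, replace = TRUE)
        dpep <- vapply(pep[src], function(p)
          paste(rev(strsplit(p, "")[[1]]), collapse = ""), character(1))
        pep <- c(pep, unname(dpep))
        accv <- c(accv, paste0("DECOY_", accv[src]))
        abv <- c(abv, abv[src])
      }
      total <- tot + nDecoy
      if (total == 0L) next
      isDecoy <- c(rep(FALSE, tot), rep(TRUE, nDecoy))
      mu <- ifelse(isDecoy, scoreParams$decoy[1], scoreParams$target[1])
      sdv <- ifelse(isDecoy, scoreParams$decoy[2], scoreParams$target[2])
      out[[r]] <- data.frame(
        run_id = run$run_id, cell_line = run$cell_line, replicate = run$replicate,
        fraction = sample(nFractions(design), total, replace = TRUE),
        spectrum_id = sprintf("%s_S%06d", run$run_id, seq_len(total)),
        peptide = pep, accessions = accv,
        ion_score = pmax(0, stats::rnorm(total, mu, sdv)),
        is_decoy = isDecoy,
        precursor_area = stats::rlnorm(total, meanlog = log(abv * 1e6), sdlog = areaSigma),
        mod_flags = "", stringsAsFactors = FALSE
      )
    }
    out <- out[!vapply(out, is.null, logical(1))]
    if (length(out) == 0L) {
      return(data.frame(run_id = character(0), cell_line = character(0),
                        replicate = integer(0), fraction = integer(0),
                        spectrum_id = character(0), peptide = character(0),
                        accessions = character(0), ion_score = numeric(0),
                        is_decoy = logical(0), precursor_area = numeric(0),
                        mod_flags = character(0)))
    }
    do.call(rbind, out)
  })
}

#' Simulate glyco-PSM tables with precursor areas
#'
#' Emits one deamidated glyco-PSM per planted glycosite per (cell line,
#' replicate) run of the glyco arm, provided the site lies on a tryptic
#' peptide of length >= 7. Each PSM carries the covering peptide, the
#' flagged peptide position, a reported mass delta equal to the 18O
#' deamidation shift plus Gaussian mass noise, and a log-normal precursor
#' area around the planted line abundance. A configurable fraction of
#' contaminant PSMs carries deamidation at non-sequon asparagines so the
#' downstream sequon validation has something to reject.
#'
#' @inheritParams simulatePsmTables
#' @param contaminantFraction expected proportion of non-motif contaminant
#'   PSMs (default 0).
#' @param massShift reported shift per site in Da (default 2.9848).
#' @param massNoiseSd Gaussian sd of the mass-delta noise in Da (default
#'   0.002, well inside the 0.01 Da acceptance tolerance).
#' @param siteSigma log-normal sd of the fixed per-site area factor.
#' @return glyco-PSM data frame (PSM dialect plus \code{delta_mass}).
#' @export
simulateGlycoPsms <- function(proteome, truth, design, seed = 1,
                              contaminantFraction = 0, massShift = 2.9848,
                              massNoiseSd = 0.002, areaSigma = 0.25,
                              replicateSigma = 0.2, siteSigma = 0.3) {
  if (contaminantFraction < 0 || contaminantFraction >= 1) {
    stop("contaminantFraction must be in [0, 1)")
  }
  if (sum(lengths(truth$glycosites)) == 0L) {
    warning("no planted glycosites in the truth table")
  }
  seqs <- stats::setNames(as.character(proteome), names(proteome))
  runs <- .runTable(design)
  ranks <- metastaticRanks(design)

  # site -> covering tryptic peptide (>= 7 residues), dropped when uncovered
  siteTable <- do.call(rbind, lapply(seq_len(nrow(truth)), function(i) {
    sites <- truth$glycosites[[i]]
    if (length(sites) == 0L) return(NULL)
    acc <- truth$accession[i]
    segs <- digestTryptic(seqs[[acc]], minLength = 1)[[1]]
    starts <- cumsum(c(1L, nchar(segs)))[seq_along(segs)]
    covering <- vapply(sites, function(s) {
      k <- findInterval(s, starts)
      if (nchar(segs[k]) >= 7L) k else NA_integer_
    }, integer(1))
    keep <- !is.na(covering)
    if (!any(keep)) return(NULL)
    data.frame(accession = acc, site = sites[keep],
               peptide = segs[covering[keep]],
               pep_start = starts[covering[keep]],
               row = i, stringsAsFactors = FALSE)
  }))
  if (is.null(siteTable) || nrow(siteTable) == 0L) {
    stop("no planted glycosite is covered by an identifiable tryptic peptide")
  }

  # contaminant pool: tryptic peptides >= 7 with a non-sequon N
  contamPool <- do.call(rbind, lapply(seq_len(nrow(truth)), function(i) {
    acc <- truth$accession[i]
    sq <- findSequons(seqs[[acc]])$position
    segs <- digestTryptic(seqs[[acc]], minLength = 7)[[1]]
    all1 <- digestTryptic(seqs[[acc]], minLength = 1)[[1]]
    starts <- cumsum(c(1L, nchar(all1)))[seq_along(all1)]
    starts <- starts[nchar(all1) >= 7L]
    res <- lapply(seq_along(segs), function(k) {
      npos <- gregexpr("N", segs[k], fixed = TRUE)[[1]]
      if (npos[1] == -1L) return(NULL)
      prot <- starts[k] + as.integer(npos) - 1L
      ok <- !(prot %in% sq)
      if (!any(ok)) return(NULL)
      data.frame(accession = acc, peptide = segs[k], pep_start = starts[k],
                 pep_pos = as.integer(npos)[ok], stringsAsFactors = FALSE)
    })
    do.call(rbind, res)
  }))

  .withSeed(seed, {
    siteFactor <- stats::rlnorm(nrow(siteTable), meanlog = 0, sdlog = siteSigma)
    out <- vector("list", nrow(runs))
    for (r in seq_len(nrow(runs))) {
      run <- runs[r, ]
      ab <- .plantedAbundance(truth, ranks[[run$cell_line]])[siteTable$row]
      mult <- if (replicateSigma > 0) {
        stats::rlnorm(nrow(siteTable), meanlog = -replicateSigma^2 / 2,
                      sdlog = replicateSigma)
      } else rep(1, nrow(siteTable))
      nG <- nrow(siteTable)
      true <- data.frame(
        run_id = run$run_id, cell_line = run$cell_line, replicate = run$replicate,
        fraction = 1L,
        spectrum_id = sprintf("%s_G%06d", run$run_id, seq_len(nG)),
        peptide = siteTable$peptide, accessions = siteTable$accession,
        ion_score = pmax(0, stats::rnorm(nG, 60, 8)), is_decoy = FALSE,
        precursor_area = stats::rlnorm(nG,
          meanlog = log(ab * siteFactor * mult * 1e5), sdlog = areaSigma),
        mod_flags = sprintf("%d:deam18O", siteTable$site - siteTable$pep_start + 1L),
        delta_mass = massShift + stats::rnorm(nG, 0, massNoiseSd),
        stringsAsFactors = FALSE
      )
      nC <- if (contaminantFraction > 0 && !is.null(contamPool)) {
        stats::rpois(1, nG * contaminantFraction / (1 - contaminantFraction))
      } else 0L
      if (nC > 0L) {
        pick <- sample(nrow(contamPool), nC, replace = TRUE)
        cp <- contamPool[pick, ]
        contam <- data.frame(
          run_id = run$run_id, cell_line = run$cell_line, replicate = run$replicate,
          fraction = 1L,
          spectrum_id = sprintf("%s_C%06d", run$run_id, seq_len(nC)),
          peptide = cp$peptide, accessions = cp$accession,
          ion_score = pmax(0, stats::rnorm(nC, 60, 8)), is_decoy = FALSE,
          precursor_area = stats::rlnorm(nC, meanlog = log(1e5), sdlog = areaSigma),
          mod_flags = sprintf("%d:deam18O", cp$pep_pos),
          delta_mass = massShift + stats::rnorm(nC, 0, massNoiseSd),
          stringsAsFactors = FALSE
        )
        true <- rbind(true, contam)
      }
      out[[r]] <- true
    }
    do.call(rbind, out)
  })
}

#' Simulate predictor scores consistent with planted secretion classes
#'
#' Draws SignalP flags, SecretomeP scores and transmembrane-helix counts so
#' that the \code{\link{classifySecretion}} decision tree maps every
#' protein back to its planted category.
#'
#' @param truth truth table from \code{\link{generateProteome}}.
#' @param seed integer seed.
#' @return predictor data frame: accession, signal_peptide,
#'   secretomep_score, tm_count.
#' @export
simulatePredictorScores <- function(truth, seed = 1) {
  stopifnot(all(truth$secretion_class %in% paste0("Part", 1:4)))
  n <- nrow(truth)
  .withSeed(seed, {
    cls <- truth$secretion_class
    signal <- cls == "Part4"
    tm <- ifelse(cls == "Part3", sample(1:7, n, replace = TRUE), 0L)
    sp <- stats::runif(n)                       # free where the tree ignores it
    sp[cls == "Part1"] <- stats::runif(sum(cls == "Part1"), 0.51, 1)
    sp[cls == "Part2"] <- stats::runif(sum(cls == "Part2"), 0, 0.5)
    data.frame(accession = truth$accession, signal_peptide = signal,
               secretomep_score = sp, tm_count = as.integer(tm),
               stringsAsFactors = FALSE)
  })
}

#' Simulate a clinical cohort with a binary tumor marker
#'
#' Patients receive a Bernoulli marker status and categorical covariates;
#' for marker-positive patients the odds of each covariate's first level
#' are multiplied by the per-covariate association (1 = null, no
#' association). The default covariates mirror a typical HCC
#' clinicopathological panel.
#'
#' @param nPatients number of patients (>= 2).
#' @param positiveRate marker prevalence (default 0.3).
#' @param association odds multiplier, a single number applied to every
#'   covariate or a named vector per covariate (default 1, the null).
#' @param covariates named list: covariate -> list(levels, p = baseline
#'   probability of the first level).
#' @param seed integer seed.
#' @return data frame: patient_id, marker (positive/negative), covariates.
#' @export
simulateClinicalCohort <- function(nPatients, positiveRate = 0.3, association = 1,
                                   covariates = list(
                                     sex = list(levels = c("Male", "Female"), p = 0.85),
                                     age = list(levels = c("<=50", ">50"), p = 0.35),
                                     liver_cirrhosis = list(levels = c("Absent", "Present"), p = 0.6),
                                     venous_invasion = list(levels = c("Absent", "Present"), p = 0.85)
                                   ),
                                   seed = 1) {
  if (nPatients < 2) stop("nPatients must be >= 2")
  if (length(association) == 1L && is.null(names(association))) {
    association <- stats::setNames(rep(association, length(covariates)), names(covariates))
  }
  .withSeed(seed, {
    marker <- ifelse(stats::runif(nPatients) < positiveRate, "positive", "negative")
    out <- data.frame(patient_id = sprintf("PT%04d", seq_len(nPatients)),
                      marker = marker, stringsAsFactors = FALSE)
    for (v in names(covariates)) {
      p0 <- covariates[[v]]$p
      orv <- association[[v]]
      odds <- p0 / (1 - p0) * ifelse(marker == "positive", orv, 1)
      p <- odds / (1 + odds)
      lvl <- covariates[[v]]$levels
      out[[v]] <- ifelse(stats::runif(nPatients) < p, lvl[1], lvl[2])
    }
    out
  })
}
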