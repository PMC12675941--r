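## profile standardization, z-scoring and gene-set partitioning

AAProfileSetFromMatrices <- function(rawFreq, standardized, zscored,
                                     totalCounted, totalSkipped, geneSet) {
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(rawFreq = rawFreq, standardized = standardized,
                  zscored = zscored),
    colData = S4Vectors::DataFrame(totalCounted = totalCounted,
                                   totalSkipped = totalSkipped,
                                   row.names = colnames(rawFreq)),
    metadata = list(geneSet = geneSet))
  new("AAProfileSet", se)
}

#' Standardize and z-score amino-acid profiles across species
#'
#' Converts pooled residue counts into relative frequencies
#' (\code{count / total_counted} per species), divides each frequency by the
#' codon-redundancy count of its amino acid, then centres and scales each
#' amino acid across species (sample standard deviation, matching
#' \code{scale()} defaults). The z-score is invariant to the constant
#' redundancy divisor; the divisor matters for the reported standardized
#' values.
#'
#' @param countsBySpecies named list of \code{ResidueCounts}, one per species
#'   (>= 2 species).
#' @param redundancy codon-redundancy table, as from
#'   \code{\link{codonRedundancyTable}}.
#' @param geneSet provenance label: \code{"all"}, \code{"ortholog"} or
#'   \code{"non_ortholog"}.
#' @return an \linkS4class{AAProfileSet} (20 amino acids x species).
#' @export
standardizeProfiles <- function(countsBySpecies,
                                redundancy = codonRedundancyTable(),
                                geneSet = "all") {
  if (length(countsBySpecies) < 2L)
    ppglsStop("at least two species are required for cross-species scaling",
              "ppglsValidationError")
  sp <- names(countsBySpecies)
  if (is.null(sp) || any(!nzchar(sp)))
    ppglsStop("countsBySpecies must be a named list", "ppglsValidationError")
  totals <- vapply(countsBySpecies, function(x) x$total_counted, 0)
  if (any(totals == 0))
    ppglsStop(sprintf("species with zero counted residues: %s",
                      paste(sp[totals == 0], collapse = ", ")),
              "ppglsValidationError")
  raw <- vapply(countsBySpecies,
                function(x) x$counts[AA_LETTERS] / x$total_counted,
                numeric(20L))
  rownames(raw) <- AA_LETTERS
  std <- raw / redundancy[AA_LETTERS]
  sds <- apply(std, 1L, sd)
  if (any(sds == 0))
    ppglsStop(sprintf("cannot z-score zero-variance amino acid column(s): %s",
                      paste(AA_LETTERS[sds == 0], collapse = ", ")),
              "ppglsValidationError")
  z <- t(scale(t(std)))            # per amino acid across species, (n-1) sd
  dimnames(z) <- dimnames(std)
  AAProfileSetFromMatrices(
    raw, std, z,
    totalCounted = vapply(countsBySpecies, function(x) x$total_counted, 0L),
    totalSkipped = vapply(countsBySpecies, function(x) x$total_skipped, 0L),
    geneSet = geneSet)
}

#' Whole-proteome amino-acid profiles from protein records
#'
#' Convenience wrapper: counts residues per species and standardizes across
#' species.
#'
#' @param recordsBySpecies named list of \code{AAStringSet}, one per species.
#' @inheritParams standardizeProfiles
#' @return an \linkS4class{AAProfileSet}.
#' @export
aaProfiles <- function(recordsBySpecies,
                       redundancy = codonRedundancyTable(),
                       geneSet = "all") {
  counts <- lapply(recordsBySpecies, countResidues)
  standardizeProfiles(counts, redundancy, geneSet)
}

#' Partition profiles into orthologous and non-orthologous gene sets
#'
#' Splits each species' proteins into those assigned to any orthogroup
#' (orthologous) and the complement (non-orthologous), pools residue counts
#' within species within each partition, and standardizes/z-scores the two
#' partitions independently.
#'
#' @param recordsBySpecies named list of \code{AAStringSet}, one per species.
#' @param assignment orthogroup membership, as from
#'   \code{\link{readOrthogroups}}.
#' @param redundancy codon-redundancy table.
#' @param orthologDef \code{"any_group"} (default: membership in any
#'   orthogroup, including species-specific groups, counts as orthologous)
#'   or \code{"multi_species"} (only groups spanning >= 2 species count).
#' @return named list with \code{ortholog} and \code{non_ortholog}
#'   \linkS4class{AAProfileSet} objects.
#' @export
partitionProfiles <- function(recordsBySpecies, assignment,
                              redundancy = codonRedundancyTable(),
                              orthologDef = c("any_group", "multi_species")) {
  orthologDef <- match.arg(orthologDef)
  asg <- assignment
  if (orthologDef == "multi_species") {
    span <- tapply(asg$species, asg$orthogroup,
                   function(s) length(unique(s)))
    keep <- names(span)[span >= 2L]
    asg <- asg[asg$orthogroup %in% keep, , drop = FALSE]
  }
  sp <- names(recordsBySpecies)
  orthoCounts <- list()
  nonCounts <- list()
  for (s in sp) {
    recs <- recordsBySpecies[[s]]
    ids <- names(recs)
    assigned <- unique(asg$protein[asg$species == canonicalLabel(s)])
    unknown <- setdiff(assigned, ids)
    if (length(unknown))
      ppglsStop(sprintf(
        "orthogroup assignment references unknown protein id(s) for %s: %s",
        s, paste(utils::head(unknown, 3L), collapse = ", ")),
        "ppglsValidationError")
    inOrtho <- ids %in% assigned
    for (part in c("ortholog", "non_ortholog")) {
      sel <- if (part == "ortholog") inOrtho else !inOrtho
      if (!any(sel))
        ppglsStop(sprintf("species %s has no proteins in the %s partition",
                          s, part), "ppglsValidationError")
    }
    orthoCounts[[s]] <- countResidues(recs[inOrtho])
    nonCounts[[s]] <- countResidues(recs[!inOrtho])
  }
  list(ortholog = standardizeProfiles(orthoCounts, redundancy, "ortholog"),
       non_ortholog = standardizeProfiles(nonCounts, redundancy,
                                          "non_ortholog"))
}

#' Write an AAProfileSet as a tidy table
#'
#' Long-format tab-separated output with columns \code{species},
#' \code{gene_set}, \code{amino_acid}, \code{raw_freq}, \code{standardized},
#' \code{zscored}.
#'
#' @param x an \linkS4class{AAProfileSet}.
#' @param path output file path.
#' @return the tidy data.frame, invisibly.
#' @export
writeProfileTable <- function(x, path) {
  sp <- speciesNames(x)
  df <- data.frame(
    species = rep(sp, each = 20L),
    gene_set = geneSet(x),
    amino_acid = rep(AA_LETTERS, times = length(sp)),
    raw_freq = as.vector(rawFreq(x)),
    standardized = as.vector(standardizedFreq(x)),
    zscored = as.vector(zscores(x)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
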