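## S4 classes for the central containers.

#' AAProfileSet: standardized amino-acid profiles for a set of species
#'
#' A \linkS4class{SummarizedExperiment} with one row per canonical amino acid
#' (fixed order \code{\link{AA_LETTERS}}) and one column per species, holding
#' three assays:
#' \describe{
#'   \item{\code{rawFreq}}{relative residue frequency per species (columns sum
#'     to 1).}
#'   \item{\code{standardized}}{\code{rawFreq} divided by the codon-redundancy
#'     count of each amino acid.}
#'   \item{\code{zscored}}{\code{standardized} centred and scaled per amino
#'     acid across species (sample standard deviation).}
#' }
#' Column metadata records \code{totalCounted} and \code{totalSkipped}
#' residues per species; \code{metadata(x)$geneSet} labels the provenance
#' (\code{"all"}, \code{"ortholog"} or \code{"non_ortholog"}).
#'
#' @aliases AAProfileSet-class
#' @export
setClass("AAProfileSet", contains = "SummarizedExperiment")

setValidity("AAProfileSet", function(object) {
  msgs <- character()
  a <- SummarizedExperiment::assays(object)
  need <- c("rawFreq", "standardized", "zscored")
  if (!all(need %in% names(a)))
    return(sprintf("assays must include %s", paste(need, collapse = ", ")))
  if (nrow(object) != 20L || !identical(rownames(object), AA_LETTERS))
    msgs <- c(msgs, "rows must be the 20 canonical amino acids in fixed order")
  gs <- S4Vectors::metadata(object)$geneSet
  if (is.null(gs) || !gs %in% c("all", "ortholog", "non_ortholog"))
    msgs <- c(msgs, "metadata geneSet must be all/ortholog/non_ortholog")
  rf <- a$rawFreq
  if (ncol(rf) > 0L) {
    cs <- colSums(rf)
    if (any(abs(cs - 1) > 1e-9))
      msgs <- c(msgs, "rawFreq columns must sum to 1")
  }
  z <- a$zscored
  if (ncol(z) >= 2L) {
    rm0 <- rowMeans(z)
    rs <- apply(z, 1L, sd)
    if (any(abs(rm0) > 1e-9) || any(abs(rs - 1) > 1e-9))
      msgs <- c(msgs, "zscored rows must have mean 0 and sample sd 1")
  }
  if (length(msgs)) msgs else TRUE
})

#' PGLSFit: one phylogenetic generalized least squares fit
#'
#' Result of regressing one amino acid's z-scored profile on the ecological
#' predictors under Brownian-motion covariance.
#'
#' @slot aminoAcid single letter, or \code{NA}.
#' @slot geneSet gene-set label, or \code{NA}.
#' @slot coefficients,stdErrors,tValues,pValues named numeric vectors, one
#'   entry per design column.
#' @slot sigma2 residual rate estimate (whitened residual sum of squares over
#'   residual degrees of freedom).
#' @slot r2 GLS coefficient of determination against the GLS intercept-only
#'   fit under the same covariance.
#' @slot n number of taxa.
#' @slot dfResid residual degrees of freedom.
#'
#' @aliases PGLSFit-class
#' @export
setClass("PGLSFit", representation(
  aminoAcid = "character", geneSet = "character",
  coefficients = "numeric", stdErrors = "numeric",
  tValues = "numeric", pValues = "numeric",
  sigma2 = "numeric", r2 = "numeric",
  n = "integer", dfResid = "integer"))

setValidity("PGLSFit", function(object) {
  msgs <- character()
  p <- length(object@coefficients)
  if (length(object@stdErrors) != p || length(object@tValues) != p ||
      length(object@pValues) != p)
    msgs <- c(msgs, "coefficient vectors must have equal length")
  if (object@dfResid < 1L) msgs <- c(msgs, "dfResid must be >= 1")
  tt <- object@coefficients / object@stdErrors
  if (any(abs(tt - object@tValues) > 1e-9 * pmax(1, abs(tt))))
    msgs <- c(msgs, "tValues must equal coefficients/stdErrors")
  if (!is.na(object@r2) && (object@r2 < -1e-12 || object@r2 > 1 + 1e-12))
    msgs <- c(msgs, "r2 must lie in [0, 1]")
  if (length(msgs)) msgs else TRUE
})

#' EnsembleSummary: PGLS results aggregated over a topology ensemble
#'
#' Long-format summary of per-amino-acid PGLS fits repeated over the trees of
#' an ensemble and over gene sets. Each row holds, for one
#' (gene set, amino acid, term, metric) combination, the point value (median
#' across trees by default) and the min-max interval across trees.
#'
#' @slot results data.frame with columns \code{gene_set}, \code{amino_acid},
#'   \code{term}, \code{metric}, \code{point}, \code{low}, \code{high}.
#' @slot nTreesUsed number of trees successfully analysed.
#' @slot droppedTrees character vector of logged reasons for dropped trees.
#' @slot pointStat \code{"median"} or \code{"mean"}.
#' @slot bhFamily \code{"per_predictor"} or \code{"pooled"}.
#'
#' @aliases EnsembleSummary-class
#' @export
setClass("EnsembleSummary", representation(
  results = "data.frame", nTreesUsed = "integer",
  droppedTrees = "character", pointStat = "character",
  bhFamily = "character"))

setValidity("EnsembleSummary", function(object) {
  need <- c("gene_set", "amino_acid", "term", "metric", "point", "low", "high")
  if (!all(need %in% names(object@results)))
    return("results must have gene_set/amino_acid/term/metric/point/low/high")
  r <- object@results
  bad <- r$low > r$point + 1e-12 | r$point > r$high + 1e-12
  if (any(bad)) return("interval must satisfy low <= point <= high")
  TRUE
})

#' ClimateGrid: a bio5-style gridded temperature layer
#'
#' Plain rectangular grid of maximum-temperature-of-warmest-month values
#' (degrees Celsius) with a north-west origin and square cells. Cells are
#' half-open: closed on their west and north edges, so a point exactly on the
#' east or south outer boundary is off-grid.
#'
#' @slot west,north longitude/latitude of the outer north-west corner.
#' @slot cellSize cell edge length in degrees (> 0).
#' @slot values rows x cols matrix, rows running north to south; \code{NA}
#'   marks missing cells.
#'
#' @aliases ClimateGrid-class
#' @export
setClass("ClimateGrid", representation(
  west = "numeric", north = "numeric", cellSize = "numeric",
  values = "matrix"))

setValidity("ClimateGrid", function(object) {
  msgs <- character()
  if (length(object@cellSize) != 1L || !is.finite(object@cellSize) ||
      object@cellSize <= 0)
    msgs <- c(msgs, "cellSize must be a single positive number")
  if (nrow(object@values) < 1L || ncol(object@values) < 1L)
    msgs <- c(msgs, "grid must have at least one row and column")
  if (length(msgs)) msgs else TRUE
})

#' SyntheticScenario: ground-truth parameterization of a simulated study
#'
#' Holds every parameter of the synthetic-data generator: tree model,
#' per-amino-acid regression coefficients and residual rates, Brownian-motion
#' parameters of the (log) ecological traits, proteome emission settings, and
#' the master seed. Identical seeds reproduce bit-identical outputs.
#'
#' @slot nSpecies number of species (>= 3).
#' @slot birthRate Yule speciation rate (events per unit branch-length time).
#' @slot nTrees ensemble size.
#' @slot beta 3 x 20 matrix of true coefficients (rows intercept,
#'   log_diet_breadth, log_max_temp; columns \code{\link{AA_LETTERS}}).
#' @slot sigma2Resid length-20 Brownian residual rate per amino acid.
#' @slot traitRoot,traitRate named length-2 vectors (\code{logDiet},
#'   \code{logTemp}): root value and Brownian rate of each log trait.
#' @slot proteinsPerSpecies,meanProteinLength proteome emission sizes.
#' @slot orthologFraction fraction of proteins assigned to orthogroups.
#' @slot gridCellSize climate-grid cell size in degrees.
#' @slot injectInFrequencies if \code{TRUE}, the trait effects are also
#'   injected into the emitted residue frequencies (exercises the
#'   standardization chain); by default effects live on the z-scored response.
#' @slot seed master seed; per-component streams are derived from it.
#'
#' @aliases SyntheticScenario-class
#' @export
setClass("SyntheticScenario", representation(
  nSpecies = "integer", birthRate = "numeric", nTrees = "integer",
  beta = "matrix", sigma2Resid = "numeric",
  traitRoot = "numeric", traitRate = "numeric",
  proteinsPerSpecies = "integer", meanProteinLength = "numeric",
  orthologFraction = "numeric", gridCellSize = "numeric",
  injectInFrequencies = "logical", seed = "integer"))

setValidity("SyntheticScenario", function(object) {
  msgs <- character()
  if (object@nSpecies < 3L) msgs <- c(msgs, "nSpecies must be >= 3")
  if (object@birthRate <= 0) msgs <- c(msgs, "birthRate must be > 0")
  if (object@nTrees < 1L) msgs <- c(msgs, "nTrees must be >= 1")
  if (!identical(dim(object@beta), c(3L, 20L)))
    msgs <- c(msgs, "beta must be a 3 x 20 matrix")
  if (length(object@sigma2Resid) != 20L || any(object@sigma2Resid <= 0))
    msgs <- c(msgs, "sigma2Resid must be 20 positive rates")
  if (any(object@traitRate <= 0)) msgs <- c(msgs, "trait rates must be > 0")
  if (object@orthologFraction < 0 || object@orthologFraction > 1)
    msgs <- c(msgs, "orthologFraction must lie in [0, 1]")
  if (length(msgs)) msgs else TRUE
})
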