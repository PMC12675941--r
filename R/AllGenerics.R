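## generics, accessors and show methods

#' @rdname AAProfileSet-class
#' @param x,object an object.
#' @export
setGeneric("rawFreq", function(x) standardGeneric("rawFreq"))
#' @rdname AAProfileSet-class
#' @export
setGeneric("standardizedFreq", function(x) standardGeneric("standardizedFreq"))
#' @rdname AAProfileSet-class
#' @export
setGeneric("zscores", function(x) standardGeneric("zscores"))
#' @rdname AAProfileSet-class
#' @export
setGeneric("geneSet", function(x) standardGeneric("geneSet"))
#' @rdname AAProfileSet-class
#' @export
setGeneric("speciesNames", function(x) standardGeneric("speciesNames"))

#' @rdname AAProfileSet-class
setMethod("rawFreq", "AAProfileSet", function(x)
  SummarizedExperiment::assay(x, "rawFreq"))
#' @rdname AAProfileSet-class
setMethod("standardizedFreq", "AAProfileSet", function(x)
  SummarizedExperiment::assay(x, "standardized"))
#' @rdname AAProfileSet-class
setMethod("zscores", "AAProfileSet", function(x)
  SummarizedExperiment::assay(x, "zscored"))
#' @rdname AAProfileSet-class
setMethod("geneSet", "AAProfileSet", function(x)
  S4Vectors::metadata(x)$geneSet)
#' @rdname AAProfileSet-class
setMethod("speciesNames", "AAProfileSet", function(x) colnames(x))

#' @rdname AAProfileSet-class
setMethod("show", "AAProfileSet", function(object) {
  cat(sprintf("AAProfileSet: %d species, gene set '%s'\n",
              ncol(object), geneSet(object)))
  cat(sprintf("  residues counted: %s\n",
              paste(range(colData(object)$totalCounted), collapse = " - ")))
  invisible(NULL)
})

#' @rdname PGLSFit-class
#' @param object a \code{PGLSFit}.
#' @export
setGeneric("coefTable", function(object) standardGeneric("coefTable"))

#' @rdname PGLSFit-class
setMethod("coefTable", "PGLSFit", function(object) {
  data.frame(term = names(object@coefficients),
             estimate = unname(object@coefficients),
             std_error = unname(object@stdErrors),
             t_value = unname(object@tValues),
             p_value = unname(object@pValues),
             row.names = NULL)
})

#' @rdname PGLSFit-class
setMethod("show", "PGLSFit", function(object) {
  cat(sprintf("PGLSFit (amino acid %s, gene set %s): n = %d, df = %d, R2 = %.3f\n",
              object@aminoAcid, object@geneSet, object@n, object@dfResid,
              object@r2))
  print(coefTable(object), digits = 4)
  invisible(NULL)
})

#' @rdname EnsembleSummary-class
#' @param object an \code{EnsembleSummary}.
#' @export
setGeneric("ensembleResults", function(object) standardGeneric("ensembleResults"))

#' @rdname EnsembleSummary-class
setMethod("ensembleResults", "EnsembleSummary", function(object) object@results)

#' @rdname EnsembleSummary-class
setMethod("show", "EnsembleSummary", function(object) {
  cat(sprintf(
    "EnsembleSummary: %d gene set(s) x %d amino acids over %d tree(s)\n",
    length(unique(object@results$gene_set)),
    length(unique(object@results$amino_acid)), object@nTreesUsed))
  if (length(object@droppedTrees))
    cat(sprintf("  %d tree(s) dropped\n", length(object@droppedTrees)))
  cat(sprintf("  point statistic: %s; BH family: %s\n",
              object@pointStat, object@bhFamily))
  invisible(NULL)
})

#' @rdname ClimateGrid-class
#' @param object a \code{ClimateGrid}.
setMethod("show", "ClimateGrid", function(object) {
  v <- object@values
  cat(sprintf("ClimateGrid: %d x %d cells of %g deg, NW corner (%g, %g)\n",
              nrow(v), ncol(v), object@cellSize, object@west, object@north))
  cat(sprintf("  values: %g to %g degC, %d missing\n",
              suppressWarnings(min(v, na.rm = TRUE)),
              suppressWarnings(max(v, na.rm = TRUE)), sum(is.na(v))))
  invisible(NULL)
})

#' @rdname SyntheticScenario-class
#' @param object a \code{SyntheticScenario}.
setMethod("show", "SyntheticScenario", function(object) {
  cat(sprintf(
    "SyntheticScenario: %d species, %d tree(s), seed %d\n",
    object@nSpecies, object@nTrees, object@seed))
  nz <- colnames(object@beta)[colSums(abs(object@beta[-1, , drop = FALSE])) > 0]
  cat(sprintf("  amino acids with non-zero trait effects: %s\n",
              if (length(nz)) paste(nz, collapse = ", ") else "none (null)"))
  invisible(NULL)
})
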