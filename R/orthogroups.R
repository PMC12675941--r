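## orthogroup membership table (OrthoFinder Orthogroups.tsv dialect)

#' Read an orthogroup membership table
#'
#' Parses the tab-separated orthogroup layout produced by orthology-inference
#' tools: a header row of species column labels (first column: group id),
#' then one row per orthogroup with comma-separated protein ids per species
#' cell. Empty cells yield no assignments. Orthology inference itself is out
#' of scope; this consumes its output.
#'
#' @param path path to the tab-separated table.
#' @param species optional character vector of expected species labels;
#'   unknown columns trigger a warning (and are still parsed).
#' @return data.frame with columns \code{orthogroup}, \code{species}
#'   (canonicalised), \code{protein}; zero rows if the file is header-only.
#' @export
readOrthogroups <- function(path, species = NULL) {
  if (!file.exists(path))
    ppglsStop(sprintf("orthogroup table not found: %s", path),
              "ppglsValidationError")
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           quote = "", comment.char = "")
  if (ncol(tab) < 2L)
    ppglsStop("orthogroup table needs a group-id column plus species columns",
              "ppglsValidationError")
  spCols <- canonicalLabel(colnames(tab)[-1])
  if (!is.null(species)) {
    unknown <- setdiff(spCols, canonicalLabel(species))
    if (length(unknown))
      warning(sprintf("orthogroup table has unknown species column(s): %s",
                      paste(unknown, collapse = ", ")), call. = FALSE)
  }
  if (nrow(tab) == 0L) {
    warning("no orthogroups in table", call. = FALSE)
    return(data.frame(orthogroup = character(), species = character(),
                      protein = character()))
  }
  parts <- lapply(seq_along(spCols), function(j) {
    cells <- tab[[j + 1L]]
    ids <- strsplit(cells, ",[[:space:]]*")
    n <- lengths(ids)
    out <- data.frame(orthogroup = rep(tab[[1L]], n),
                      species = spCols[j],
                      protein = trimws(unlist(ids, use.names = FALSE)))
    out[nzchar(out$protein), , drop = FALSE]
  })
  res <- do.call(rbind, parts)
  rownames(res) <- NULL
  key <- paste(res$species, res$protein, sep = "\r")
  dupGroups <- tapply(res$orthogroup, key, function(g) length(unique(g)))
  if (any(dupGroups > 1L)) {
    bad <- strsplit(names(dupGroups)[dupGroups > 1L][1], "\r")[[1]]
    ppglsStop(sprintf(
      "protein '%s' of species %s appears in more than one orthogroup",
      bad[2], bad[1]), "ppglsValidationError")
  }
  unique(res)
}
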