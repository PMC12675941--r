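## proteome reading and residue counting

#' Codon-redundancy table of the standard genetic code
#'
#' Number of synonymous sense codons per amino acid, derived from the
#' standard genetic code (64 codons, 3 stops). Met and Trp have 1 codon;
#' Leu, Ser and Arg have 6; the values sum to 61.
#'
#' @return named integer vector over \code{\link{AA_LETTERS}}.
#' @examples
#' tab <- codonRedundancyTable()
#' tab["L"]  # 6
#' sum(tab)  # 61
#' @export
codonRedundancyTable <- function() {
  code <- Biostrings::GENETIC_CODE
  tab <- table(code[code != "*"])
  out <- as.integer(tab[AA_LETTERS])
  names(out) <- AA_LETTERS
  stopifnot(sum(out) == 61L)
  out
}

#' Read a protein FASTA file for one species
#'
#' Reads a (possibly gzip-compressed) protein FASTA file, upper-cases the
#' sequences and returns them as an \code{AAStringSet} named by the first
#' whitespace-delimited token of each header. Record order is preserved.
#'
#' @param path path to the FASTA file.
#' @param species optional species label stored in the result's metadata.
#' @return \code{AAStringSet} with unique non-empty names.
#' @export
readProteomeFasta <- function(path, species = NULL) {
  if (!file.exists(path))
    ppglsStop(sprintf("proteome FASTA file not found: %s", path),
              "ppglsValidationError")
  ln <- readLines(path, warn = FALSE)   # transparent gzip decompression
  nonblank <- which(nzchar(trimws(ln)))
  if (length(nonblank) == 0L)
    ppglsStop(sprintf("no sequences in FASTA file %s", path),
              "ppglsValidationError")
  if (!startsWith(trimws(ln[nonblank[1]]), ">"))
    ppglsStop(sprintf(
      "malformed FASTA %s: sequence data before first header at line %d",
      path, nonblank[1]), "ppglsValidationError")
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) == 0L)
    ppglsStop(sprintf("no sequences in FASTA file %s", path),
              "ppglsValidationError")
  ids <- sub("\\s.*$", "", names(seqs))
  if (any(!nzchar(ids)))
    ppglsStop(sprintf("empty record id in %s", path), "ppglsValidationError")
  if (anyDuplicated(ids))
    ppglsStop(sprintf("duplicate record id '%s' in %s",
                      ids[duplicated(ids)][1], path), "ppglsValidationError")
  out <- Biostrings::AAStringSet(toupper(as.character(seqs)))
  names(out) <- ids
  S4Vectors::metadata(out)$species <- species
  out
}

#' Count amino-acid residues over a set of protein records
#'
#' Pools residue counts over all sequences. The twenty canonical letters are
#' counted; the skip-set (\code{X B Z J U O * -}: ambiguity codes,
#' selenocysteine/pyrrolysine, stop marks, gaps) increments the skipped total
#' only. Any other character is an error naming the character and the
#' offending record.
#'
#' @param records \code{AAStringSet} (as from \code{\link{readProteomeFasta}})
#'   or character vector of upper-case sequences.
#' @return list with class \code{ResidueCounts}: \code{counts} (named integer
#'   over \code{\link{AA_LETTERS}}), \code{total_counted},
#'   \code{total_skipped}.
#' @export
countResidues <- function(records) {
  if (is(records, "AAStringSet")) {
    chr <- as.character(records)
  } else {
    ## as.character/toupper drop names; keep them for error reporting
    chr <- setNames(toupper(as.character(records)), names(records))
  }
  if (length(chr) == 0L)
    ppglsStop("no records to count", "ppglsValidationError")
  ids <- names(chr) %||% as.character(seq_along(chr))
  allowed <- c(AA_LETTERS, AA_SKIP)
  pat <- "[^ACDEFGHIKLMNPQRSTVWYXBZJUO*-]"
  bad <- grepl(pat, chr)
  if (any(bad)) {
    i <- which(bad)[1]
    ch <- regmatches(chr[i], regexpr(pat, chr[i]))
    ppglsStop(sprintf("invalid residue '%s' in record %s", ch, ids[i]),
              "ppglsValidationError")
  }
  af <- Biostrings::alphabetFrequency(Biostrings::AAStringSet(chr))
  tot <- colSums(af)
  counts <- as.integer(tot[AA_LETTERS])
  names(counts) <- AA_LETTERS
  skipped <- sum(tot[intersect(AA_SKIP, names(tot))])
  structure(list(counts = counts,
                 total_counted = sum(counts),
                 total_skipped = as.integer(skipped)),
            class = "ResidueCounts")
}

#' @export
print.ResidueCounts <- function(x, ...) {
  cat(sprintf("ResidueCounts: %d counted, %d skipped\n",
              x$total_counted, x$total_skipped))
  print(x$counts)
  invisible(x)
}
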