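## internal helpers: label canonicalisation, seeds, key-value files, logging

#' Canonicalise species labels
#'
#' Trims surrounding whitespace and collapses runs of spaces/underscores to a
#' single underscore, so that tip labels written in Newick convention
#' (\code{"Pieris_rapae"}) match labels from tabular files
#' (\code{"Pieris rapae"}).
#'
#' @param x character vector of labels.
#' @return character vector of canonical labels.
#' @export
canonicalLabel <- function(x) {
  gsub("[ _]+", "_", trimws(as.character(x)))
}

## deterministic per-component sub-seed derived from a master seed, so that
## changing one generator component does not perturb the streams of the others
subSeed <- function(seed, component) {
  offsets <- c(tree = 1L, traits = 2L, residuals = 3L, frequencies = 4L,
               proteomes = 5L, orthogroups = 6L, ecology = 7L, misc = 8L)
  off <- offsets[[component]]
  as.integer((as.numeric(seed) %% 1000003) * 2099 + off * 7919) %% 2147483629L
}

## classed error helper; class maps the spec'd failure modes onto R conditions
ppglsStop <- function(msg, class = "ppglsError", call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "ppglsError")))
}

#' Read a flat key-value configuration file
#'
#' Lines of the form \code{key = value} (or \code{key: value}); blank lines
#' and lines starting with \code{#} are ignored.
#'
#' @param path file path.
#' @return named character vector.
#' @export
readKeyValue <- function(path) {
  if (!file.exists(path))
    ppglsStop(sprintf("configuration file not found: %s", path),
              "ppglsValidationError")
  ln <- trimws(readLines(path, warn = FALSE))
  ln <- ln[nzchar(ln) & !startsWith(ln, "#")]
  m <- regmatches(ln, regexec("^([^=:]+)[=:](.*)$", ln))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad))
    ppglsStop(sprintf("malformed configuration line: '%s'", ln[bad][1]),
              "ppglsValidationError")
  vals <- trimws(vapply(m, `[`, "", 3L))
  names(vals) <- trimws(vapply(m, `[`, "", 2L))
  vals
}

writeKeyValue <- function(x, path) {
  writeLines(paste(names(x), unlist(x), sep = " = "), path)
}

## log to stderr and (optionally) append to a run log file
ppglsLog <- function(msg, logfile = NULL) {
  message(msg)
  if (!is.null(logfile)) cat(msg, "\n", sep = "", file = logfile, append = TRUE)
  invisible(msg)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L) b else a
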