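## ecological predictors: diet breadth and realised thermal maximum

detectSep <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (grepl("\t", first)) "\t" else ","
}

#' Read a host-plant record table
#'
#' Tab- or comma-separated file with header columns \code{species} and
#' \code{host}. Species labels are canonicalised; host names must be
#' non-empty after trimming.
#'
#' @param path file path.
#' @return data.frame with columns \code{species}, \code{host}.
#' @export
readHostRecords <- function(path) {
  if (!file.exists(path))
    ppglsStop(sprintf("host record file not found: %s", path),
              "ppglsValidationError")
  df <- utils::read.table(path, header = TRUE, sep = detectSep(path),
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "")
  if (!all(c("species", "host") %in% names(df)))
    ppglsStop("host records need 'species' and 'host' columns",
              "ppglsValidationError")
  df$species <- canonicalLabel(df$species)
  df$host <- trimws(df$host)
  if (any(!nzchar(df$host)))
    ppglsStop("empty host plant name in host records", "ppglsValidationError")
  df[c("species", "host")]
}

#' Read an occurrence table
#'
#' Tab- or comma-separated file with header columns \code{species},
#' \code{lon}, \code{lat}. Coordinates must be finite and within
#' [-180, 180] x [-90, 90].
#'
#' @param path file path.
#' @return data.frame with columns \code{species}, \code{lon}, \code{lat}.
#' @export
readOccurrences <- function(path) {
  if (!file.exists(path))
    ppglsStop(sprintf("occurrence file not found: %s", path),
              "ppglsValidationError")
  df <- utils::read.table(path, header = TRUE, sep = detectSep(path),
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "")
  if (!all(c("species", "lon", "lat") %in% names(df)))
    ppglsStop("occurrences need 'species', 'lon' and 'lat' columns",
              "ppglsValidationError")
  df$species <- canonicalLabel(df$species)
  ok <- is.finite(df$lon) & is.finite(df$lat) &
    df$lon >= -180 & df$lon <= 180 & df$lat >= -90 & df$lat <= 90
  if (!all(ok))
    ppglsStop(sprintf("%d occurrence record(s) with invalid coordinates",
                      sum(!ok)), "ppglsValidationError")
  df[c("species", "lon", "lat")]
}

#' Read an ESRI ASCII grid of bio5-style temperatures
#'
#' Plain-text raster: six header lines (\code{ncols}, \code{nrows},
#' \code{xllcorner}, \code{yllcorner}, \code{cellsize},
#' \code{NODATA_value}), then rows of cell values running north to south.
#'
#' @param path file path.
#' @return a \linkS4class{ClimateGrid} (missing cells as \code{NA}).
#' @export
readAsciiGrid <- function(path) {
  if (!file.exists(path))
    ppglsStop(sprintf("climate grid not found: %s", path),
              "ppglsValidationError")
  hdr <- readLines(path, n = 6L, warn = FALSE)
  kv <- do.call(rbind, strsplit(trimws(hdr), "[[:space:]]+"))
  keys <- tolower(kv[, 1])
  vals <- as.numeric(kv[, 2])
  names(vals) <- keys
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
            "nodata_value")
  if (!all(need %in% keys))
    ppglsStop("ASCII grid header must define ncols/nrows/xllcorner/yllcorner/cellsize/NODATA_value",
              "ppglsValidationError")
  nc <- as.integer(vals["ncols"]); nr <- as.integer(vals["nrows"])
  body <- scan(path, skip = 6L, quiet = TRUE)
  if (length(body) != nc * nr)
    ppglsStop(sprintf("grid body has %d values, expected %d",
                      length(body), nc * nr), "ppglsValidationError")
  m <- matrix(body, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == vals["nodata_value"]] <- NA_real_
  new("ClimateGrid",
      west = unname(vals["xllcorner"]),
      north = unname(vals["yllcorner"] + nr * vals["cellsize"]),
      cellSize = unname(vals["cellsize"]),
      values = m)
}

#' Write a ClimateGrid as an ESRI ASCII grid
#'
#' @param grid a \linkS4class{ClimateGrid}.
#' @param path output path.
#' @param nodata sentinel written for missing cells.
#' @return \code{path}, invisibly.
#' @export
writeAsciiGrid <- function(grid, path, nodata = -9999) {
  v <- grid@values
  v[is.na(v)] <- nodata
  hdr <- c(sprintf("ncols %d", ncol(v)),
           sprintf("nrows %d", nrow(v)),
           sprintf("xllcorner %.6f", grid@west),
           sprintf("yllcorner %.6f", grid@north - nrow(v) * grid@cellSize),
           sprintf("cellsize %.6f", grid@cellSize),
           sprintf("NODATA_value %d", as.integer(nodata)))
  rows <- apply(v, 1L, function(r) paste(sprintf("%.2f", r), collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Genus-level diet breadth of one species
#'
#' Number of distinct host-plant genera recorded for the species, where the
#' genus is the first whitespace-delimited token of the host name,
#' case-folded to initial-capital form. Duplicated records and record order
#' do not affect the count.
#'
#' @param hosts host record table (\code{\link{readHostRecords}} layout).
#' @param species species label (canonicalised for matching).
#' @return positive integer count of genera.
#' @export
dietBreadth <- function(hosts, species) {
  rec <- hosts$host[hosts$species == canonicalLabel(species)]
  if (length(rec) == 0L)
    ppglsStop(sprintf("no host data for species %s", species),
              "ppglsDataError")
  genus <- sub("\\s.*$", "", trimws(rec))
  genus <- paste0(toupper(substr(genus, 1L, 1L)),
                  tolower(substring(genus, 2L)))
  length(unique(genus))
}

#' Realised thermal maximum of one species over a climate grid
#'
#' Looks up the grid cell under each occurrence point (half-open cells,
#' closed on their west/north edges) and returns the maximum cell value.
#' Points falling off-grid or on missing cells are skipped and counted in
#' the \code{"skipped"} attribute.
#'
#' @param occ occurrence table (\code{\link{readOccurrences}} layout).
#' @param grid a \linkS4class{ClimateGrid}.
#' @param species species label.
#' @return maximum temperature (degrees C) with attribute \code{skipped}.
#' @export
extractBio5Max <- function(occ, grid, species) {
  pts <- occ[occ$species == canonicalLabel(species), , drop = FALSE]
  if (nrow(pts) == 0L)
    ppglsStop(sprintf("no climate coverage for species %s (no occurrences)",
                      species), "ppglsDataError")
  cs <- grid@cellSize
  col <- floor((pts$lon - grid@west) / cs)
  row <- floor((grid@north - pts$lat) / cs)
  v <- grid@values
  on <- col >= 0 & col < ncol(v) & row >= 0 & row < nrow(v)
  vals <- rep(NA_real_, nrow(pts))
  vals[on] <- v[cbind(row[on] + 1L, col[on] + 1L)]
  usable <- !is.na(vals)
  if (!any(usable))
    ppglsStop(sprintf("no climate coverage for species %s", species),
              "ppglsDataError")
  structure(max(vals[usable]), skipped = sum(!usable))
}

#' Assemble the ecological trait table
#'
#' Retains exactly the species for which both a diet breadth and a thermal
#' maximum can be derived; every exclusion is recorded with its reason in
#' the \code{"exclusions"} attribute. Data missing from any source excludes
#' the species from the analysis.
#'
#' @param hosts host record table.
#' @param occ occurrence table.
#' @param grid a \linkS4class{ClimateGrid}.
#' @param species candidate species labels.
#' @return data.frame with columns \code{species}, \code{diet_breadth},
#'   \code{max_temp} and attributes \code{exclusions} (data.frame
#'   species/reason) and \code{skipped_points} (named integer).
#' @export
assembleTraitTable <- function(hosts, occ, grid, species) {
  species <- canonicalLabel(species)
  rows <- list()
  excl <- list()
  skipped <- integer()
  for (s in species) {
    db <- tryCatch(dietBreadth(hosts, s), error = function(e) e)
    mt <- tryCatch(extractBio5Max(occ, grid, s), error = function(e) e)
    if (inherits(db, "error")) {
      excl[[s]] <- conditionMessage(db)
    } else if (inherits(mt, "error")) {
      excl[[s]] <- conditionMessage(mt)
    } else {
      rows[[s]] <- data.frame(species = s, diet_breadth = db,
                              max_temp = as.numeric(mt))
      skipped[s] <- attr(mt, "skipped")
    }
  }
  if (length(rows) < 3L)
    ppglsStop(sprintf(
      "only %d species with complete trait data; at least 3 required",
      length(rows)), "ppglsDataError")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "exclusions") <- data.frame(
    species = as.character(names(excl) %||% character()),
    reason = as.character(unlist(excl, use.names = FALSE) %||% character()))
  attr(out, "skipped_points") <- skipped
  out
}
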