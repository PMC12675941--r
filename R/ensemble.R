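## repeating the per-amino-acid PGLS across a topology ensemble

fitsToLong <- function(fits, bhFamily) {
  ## one gene set, one tree: 20 fits -> long data.frame with adjusted p
  tab <- do.call(rbind, lapply(names(fits), function(a) {
    ct <- coefTable(fits[[a]])
    ct$amino_acid <- a
    ct
  }))
  tab$p_adj <- NA_real_
  if (bhFamily == "per_predictor") {
    for (tm in unique(tab$term)) {
      sel <- tab$term == tm
      tab$p_adj[sel] <- bhAdjust(tab$p_value[sel])
    }
  } else {
    tab$p_adj <- bhAdjust(tab$p_value)
  }
  r2 <- data.frame(term = "model", estimate = NA_real_, std_error = NA_real_,
                   t_value = NA_real_, p_value = NA_real_,
                   amino_acid = names(fits), p_adj = NA_real_,
                   r_squared = vapply(fits, function(f) f@r2, 0))
  tab$r_squared <- NA_real_
  rbind(tab, r2)
}

#' Run the PGLS analysis over a tree ensemble and gene sets
#'
#' For every tree and every gene-set profile matrix, fits the 20
#' per-amino-acid PGLS models, applies Benjamini-Hochberg adjustment within
#' each (tree, gene set, predictor) family of 20 p-values (or pooled within
#' tree and gene set), and aggregates each quantity across trees into a
#' point value (median by default) and a min-max topology interval. Trees
#' whose fits fail are dropped with a logged reason; more than
#' \code{maxFailFrac} failures is fatal.
#'
#' @param profilesList named list of \linkS4class{AAProfileSet} objects
#'   (e.g. \code{all}, \code{ortholog}, \code{non_ortholog}).
#' @param traits trait table covering the profile species.
#' @param ensemble \code{multiPhylo} (or list) of trees sharing the analysis
#'   tip set.
#' @param includeInteraction passed to \code{\link{buildDesign}}.
#' @param bhFamily \code{"per_predictor"} (default) or \code{"pooled"}.
#' @param pointStat \code{"median"} (default; even tree counts average the
#'   two central order statistics) or \code{"mean"}.
#' @param maxFailFrac maximum tolerated fraction of dropped trees.
#' @return an \linkS4class{EnsembleSummary}.
#' @export
runEnsemble <- function(profilesList, traits, ensemble,
                        includeInteraction = FALSE,
                        bhFamily = c("per_predictor", "pooled"),
                        pointStat = c("median", "mean"),
                        maxFailFrac = 0.1) {
  bhFamily <- match.arg(bhFamily)
  pointStat <- match.arg(pointStat)
  if (length(ensemble) < 1L)
    ppglsStop("ensemble must contain at least one tree",
              "ppglsValidationError")
  if (is.null(names(profilesList)))
    names(profilesList) <- vapply(profilesList, geneSet, "")
  perTree <- list()
  dropped <- character()
  for (i in seq_along(ensemble)) {
    res <- tryCatch({
      do.call(rbind, lapply(names(profilesList), function(gs) {
        fits <- fitAllAminoAcids(profilesList[[gs]], traits, ensemble[[i]],
                                 includeInteraction)
        long <- fitsToLong(fits, bhFamily)
        long$gene_set <- gs
        long
      }))
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) {
      dropped <- c(dropped, sprintf("tree %d: %s", i, res))
    } else {
      res$tree <- i
      perTree[[length(perTree) + 1L]] <- res
    }
  }
  nUsed <- length(perTree)
  if (nUsed == 0L || length(dropped) > maxFailFrac * length(ensemble))
    ppglsStop(sprintf("ensemble failure rate too high: %d of %d trees dropped",
                      length(dropped), length(ensemble)), "ppglsEnsembleError")
  all <- do.call(rbind, perTree)
  ## long metric layout: one row per (gene_set, aa, term, metric, tree)
  metrics <- c(estimate = "estimate", std_error = "std_error",
               t_value = "t_value", p_value = "p_value", p_adj = "p_adj",
               r_squared = "r_squared")
  pieces <- lapply(names(metrics), function(m) {
    v <- all[[metrics[[m]]]]
    keep <- !is.na(v)
    data.frame(gene_set = all$gene_set[keep], amino_acid = all$amino_acid[keep],
               term = all$term[keep], metric = m, value = v[keep],
               tree = all$tree[keep])
  })
  longm <- do.call(rbind, pieces)
  pointFun <- if (pointStat == "median") median else mean
  key <- interaction(longm$gene_set, longm$amino_acid, longm$term,
                     longm$metric, drop = TRUE)
  agg <- function(f) vapply(split(longm$value, key), f, 0)
  pts <- agg(pointFun); lo <- agg(min); hi <- agg(max)
  first <- !duplicated(key)
  out <- data.frame(gene_set = longm$gene_set[first],
                    amino_acid = longm$amino_acid[first],
                    term = longm$term[first],
                    metric = longm$metric[first],
                    point = unname(pts[as.character(key[first])]),
                    low = unname(lo[as.character(key[first])]),
                    high = unname(hi[as.character(key[first])]))
  out <- out[order(out$gene_set, out$amino_acid, out$term, out$metric), ]
  rownames(out) <- NULL
  new("EnsembleSummary", results = out, nTreesUsed = as.integer(nUsed),
      droppedTrees = dropped, pointStat = pointStat, bhFamily = bhFamily)
}

fmtInterval <- function(point, low, high, digits = 4) {
  s <- function(x) formatC(signif(x, digits), format = "fg", flag = "#")
  sprintf("%s (%s to %s)", trimws(s(point)), trimws(s(low)), trimws(s(high)))
}

#' Format an ensemble summary as a publication-style table
#'
#' One row per (gene set, amino acid); for each model term the estimate,
#' standard error, t-value and adjusted p are rendered as
#' \code{"point (low to high)"}, the interval spanning the topology
#' ensemble, plus an \code{r_squared} column.
#'
#' @param es an \linkS4class{EnsembleSummary}.
#' @return data.frame of formatted strings.
#' @export
formatSummaryTable <- function(es) {
  r <- es@results
  terms <- setdiff(unique(r$term), "model")
  combos <- unique(r[c("gene_set", "amino_acid")])
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    gs <- combos$gene_set[i]; aa <- combos$amino_acid[i]
    sub <- r[r$gene_set == gs & r$amino_acid == aa, ]
    row <- list(gene_set = gs, amino_acid = aa)
    for (tm in terms) {
      for (m in c("estimate", "std_error", "t_value", "p_adj")) {
        x <- sub[sub$term == tm & sub$metric == m, ]
        base <- gsub("^_+|_+$", "", gsub("[^[:alnum:]]+", "_", tolower(tm)))
        nm <- paste(base, m, sep = "_")
        row[[nm]] <- fmtInterval(x$point, x$low, x$high)
      }
    }
    x <- sub[sub$term == "model" & sub$metric == "r_squared", ]
    row$r_squared <- fmtInterval(x$point, x$low, x$high)
    as.data.frame(row, check.names = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write ensemble results, long-format companion and run manifest
#'
#' @param es an \linkS4class{EnsembleSummary}.
#' @param dir output directory (created if needed).
#' @param runInfo named list/vector echoed into the manifest (seed, input
#'   checksums, ...).
#' @return named character vector of written paths, invisibly.
#' @export
writeEnsembleResults <- function(es, dir, runInfo = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tab <- formatSummaryTable(es)
  p1 <- file.path(dir, "summary_table.tsv")
  write.table(tab, p1, sep = "\t", quote = FALSE, row.names = FALSE)
  p2 <- file.path(dir, "results_long.tsv")
  write.table(es@results, p2, sep = "\t", quote = FALSE, row.names = FALSE)
  p3 <- file.path(dir, "run_manifest.txt")
  info <- c(list(point_statistic = es@pointStat, bh_family = es@bhFamily,
                 trees_used = es@nTreesUsed,
                 trees_dropped = length(es@droppedTrees)),
            runInfo)
  writeKeyValue(info, p3)
  invisible(c(summary = p1, long = p2, manifest = p3))
}
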