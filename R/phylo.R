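## tree parsing, validation, pruning and Brownian covariance

#' Parse a Newick string into a validated phylogeny
#'
#' Thin validated front end over \code{ape}'s Newick reader. The string must
#' be terminated by \code{';'} and have balanced parentheses; after parsing,
#' tip labels must be unique and branch lengths non-negative and finite.
#'
#' @param text a single Newick string.
#' @return an \code{ape} \code{phylo} object.
#' @export
parseNewick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  txt <- trimws(text)
  if (!endsWith(txt, ";"))
    ppglsStop("Newick string must be terminated by ';'", "ppglsParseError")
  depth <- 0L
  chars <- strsplit(txt, "")[[1]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        ppglsStop(sprintf(
          "unbalanced parentheses: unmatched ')' at character %d", i),
          "ppglsParseError")
    }
  }
  if (depth != 0L)
    ppglsStop(sprintf("unbalanced parentheses: %d '(' left open", depth),
              "ppglsParseError")
  phy <- tryCatch(ape::read.tree(text = txt),
                  error = function(e) NULL, warning = function(w) NULL)
  if (is.null(phy) || !inherits(phy, "phylo"))
    ppglsStop("could not parse Newick string", "ppglsParseError")
  validatePhylogeny(phy)
  phy
}

validatePhylogeny <- function(phy) {
  if (anyDuplicated(phy$tip.label))
    ppglsStop(sprintf("duplicate tip label '%s'",
                      phy$tip.label[duplicated(phy$tip.label)][1]),
              "ppglsParseError")
  if (is.null(phy$edge.length))
    ppglsStop("tree has no branch lengths", "ppglsParseError")
  if (any(!is.finite(phy$edge.length)))
    ppglsStop("tree has missing or non-finite branch lengths",
              "ppglsParseError")
  if (any(phy$edge.length < 0))
    ppglsStop("tree has negative branch length(s)", "ppglsParseError")
  invisible(phy)
}

#' Prune a phylogeny to a set of taxa
#'
#' Induced subtree on the requested taxa. Suppressed degree-2 nodes merge
#' their branch lengths additively, so root-to-tip distances of retained
#' taxa are preserved.
#'
#' @param tree a \code{phylo} object.
#' @param taxa labels to retain (must be a subset of the tree's tips).
#' @return pruned \code{phylo} object.
#' @export
pruneToTaxa <- function(tree, taxa) {
  taxa <- unique(as.character(taxa))
  missing <- setdiff(taxa, tree$tip.label)
  if (length(missing))
    ppglsStop(sprintf("taxa not in tree: %s", paste(missing, collapse = ", ")),
              "ppglsValidationError")
  if (setequal(taxa, tree$tip.label)) return(tree)
  pr <- ape::drop.tip(tree, setdiff(tree$tip.label, taxa))
  pr$root.edge <- NULL
  ## if pruning re-rooted at the retained MRCA, keep the removed stem as a
  ## root edge so root-to-tip distances survive pruning
  ref <- taxa[1]
  oldDepth <- ape::node.depth.edgelength(tree)[match(ref, tree$tip.label)] +
    (tree$root.edge %||% 0)
  newDepth <- ape::node.depth.edgelength(pr)[match(ref, pr$tip.label)]
  shift <- oldDepth - newDepth
  if (shift > 0) pr$root.edge <- shift
  pr
}

#' Load a multi-tree Newick ensemble
#'
#' Reads one-Newick-per-line (or concatenated) tree files, canonicalises tip
#' labels, prunes every tree to the analysis taxa and drops trees that fail
#' validation or lack required taxa, recording the reason.
#'
#' @param path path to the multi-tree Newick file.
#' @param taxa required tip set (canonical labels); each usable tree is
#'   pruned to exactly this set.
#' @return a \code{multiPhylo} list of pruned trees with attribute
#'   \code{"dropped"}: character vector of reasons for rejected trees.
#' @export
loadTreeEnsemble <- function(path, taxa) {
  if (!file.exists(path))
    ppglsStop(sprintf("tree file not found: %s", path),
              "ppglsValidationError")
  trees <- tryCatch(suppressWarnings(ape::read.tree(path)),
                    error = function(e) NULL)
  if (is.null(trees))
    ppglsStop(sprintf("no trees could be read from %s", path),
              "ppglsValidationError")
  if (inherits(trees, "phylo")) trees <- c(trees)  # promote to multiPhylo
  taxa <- canonicalLabel(taxa)
  kept <- list()
  dropped <- character()
  for (i in seq_along(trees)) {
    phy <- trees[[i]]
    phy$tip.label <- canonicalLabel(phy$tip.label)
    res <- tryCatch({
      validatePhylogeny(phy)
      pruneToTaxa(phy, taxa)
    }, error = function(e) conditionMessage(e))
    if (inherits(res, "phylo")) kept[[length(kept) + 1L]] <- res
    else dropped <- c(dropped, sprintf("tree %d: %s", i, res))
  }
  if (length(kept) == 0L)
    ppglsStop(sprintf("no usable trees in %s (%d rejected)",
                      path, length(dropped)), "ppglsValidationError")
  out <- do.call(c, kept)
  if (inherits(out, "phylo")) out <- c(out)
  attr(out, "dropped") <- dropped
  out
}

#' Brownian-motion tip covariance matrix
#'
#' Under Brownian trait evolution the covariance of two tips equals the
#' branch-length distance from the root to their most recent common
#' ancestor; the diagonal holds root-to-tip distances. Polytomies are
#' allowed; branch lengths are required.
#'
#' @param tree rooted \code{phylo} object with branch lengths.
#' @return symmetric positive semi-definite matrix with dimnames equal to
#'   the tip labels, in tip order.
#' @export
brownianCovariance <- function(tree) {
  validatePhylogeny(tree)
  ntip <- length(tree$tip.label)
  rootEdge <- tree$root.edge %||% 0   # shared stem retained by pruning
  depths <- ape::node.depth.edgelength(tree) + rootEdge
  m <- ape::mrca(tree)
  C <- matrix(depths[m], ntip, ntip,
              dimnames = list(tree$tip.label, tree$tip.label))
  diag(C) <- depths[seq_len(ntip)]
  C
}

#' Test whether a tree is (approximately) ultrametric
#'
#' True iff the maximum and minimum root-to-tip distances differ by at most
#' \code{relTol} times the maximum. Calibrated trees should be
#' near-ultrametric; this is used as a validation warning, not a hard gate.
#'
#' @param tree a \code{phylo} object with branch lengths.
#' @param relTol relative tolerance (fraction of the maximum depth).
#' @return logical scalar.
#' @export
isUltrametric <- function(tree, relTol = 0.01) {
  depths <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  (max(depths) - min(depths)) <= relTol * max(depths)
}
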