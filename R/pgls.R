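## phylogenetic generalized least squares, fitted from the closed form

#' Build the PGLS design matrix
#'
#' Columns \code{(Intercept)}, \code{log_diet_breadth}, \code{log_max_temp}
#' (natural logarithms), ordered to match the requested taxa; optionally
#' their interaction. Inference is invariant to the log base (a base change
#' rescales coefficients, not t or p).
#'
#' @param traits trait table (\code{\link{assembleTraitTable}} layout).
#' @param taxa taxon labels giving the required row order.
#' @param includeInteraction add a \code{log_diet_breadth:log_max_temp}
#'   column (off by default; main effects are the reported model).
#' @return numeric matrix with rownames \code{taxa}, full column rank.
#' @export
buildDesign <- function(traits, taxa, includeInteraction = FALSE) {
  taxa <- canonicalLabel(taxa)
  idx <- match(taxa, canonicalLabel(traits$species))
  if (anyNA(idx))
    ppglsStop(sprintf("taxa missing from trait table: %s",
                      paste(taxa[is.na(idx)], collapse = ", ")),
              "ppglsValidationError")
  db <- traits$diet_breadth[idx]
  mt <- traits$max_temp[idx]
  if (any(db < 1))
    ppglsStop("diet_breadth must be >= 1 for the log transform",
              "ppglsValidationError")
  if (any(mt <= 0))
    ppglsStop("max_temp must be > 0 for the log transform (degC scale)",
              "ppglsValidationError")
  X <- cbind(`(Intercept)` = 1, log_diet_breadth = log(db),
             log_max_temp = log(mt))
  if (includeInteraction)
    X <- cbind(X, `log_diet_breadth:log_max_temp` = log(db) * log(mt))
  rownames(X) <- taxa
  if (qr(X)$rank < ncol(X)) {
    sds <- apply(X[, -1L, drop = FALSE], 2L, sd)
    culprit <- if (any(sds == 0)) names(sds)[sds == 0][1] else "design"
    ppglsStop(sprintf("design matrix is rank deficient (%s)", culprit),
              "ppglsValidationError")
  }
  X
}

## Cholesky factor of C, with a single diagonal jitter retry (total added
## mass <= 1e-10 * trace) for matrices that are PSD up to rounding
cholCov <- function(C) {
  R <- tryCatch(chol(C), error = function(e) NULL)
  if (is.null(R)) {
    eps <- 1e-10 * mean(diag(C))
    R <- tryCatch(chol(C + diag(eps, nrow(C))), error = function(e) NULL)
    if (is.null(R))
      ppglsStop("phylogenetic covariance matrix is singular", "ppglsFitError")
  }
  R
}

#' Fit one generalized least squares regression under Brownian covariance
#'
#' Closed-form GLS via a triangular (Cholesky) factorization of the
#' covariance, never forming an explicit inverse:
#' \deqn{\hat\beta = (X^T C^{-1} X)^{-1} X^T C^{-1} y,}
#' with \eqn{\hat\sigma^2 = RSS_{gls} / (n - p)} and standard errors from
#' \eqn{\hat\sigma^2 (X^T C^{-1} X)^{-1}}. Two-sided p-values come from the
#' t distribution on \code{n - p} degrees of freedom; \eqn{R^2} compares the
#' fit against the GLS intercept-only model under the same covariance.
#' Scaling \code{C} by any positive constant leaves estimates, t and p
#' unchanged.
#'
#' @param y response vector (z-scored amino-acid values), optionally named.
#' @param X design matrix (see \code{\link{buildDesign}}).
#' @param C phylogenetic covariance matrix in the same taxon order.
#' @param aminoAcid,geneSet labels stored in the result.
#' @return a \linkS4class{PGLSFit}.
#' @export
glsFit <- function(y, X, C, aminoAcid = NA_character_,
                   geneSet = NA_character_) {
  y <- as.numeric(y)
  n <- length(y)
  if (nrow(X) != n || nrow(C) != n || ncol(C) != n)
    ppglsStop("dimensions of y, X and C disagree", "ppglsValidationError")
  p <- ncol(X)
  df <- n - p
  if (df < 1L)
    ppglsStop(sprintf("no residual degrees of freedom (n = %d, p = %d)",
                      n, p), "ppglsFitError")
  R <- cholCov(C)                      # C = R'R, R upper triangular
  ## whitening: multiply by inv(R') via a triangular solve
  Xw <- backsolve(R, X, transpose = TRUE)
  yw <- backsolve(R, y, transpose = TRUE)
  XtX <- crossprod(Xw)
  beta <- drop(solve(XtX, crossprod(Xw, yw)))
  res <- yw - Xw %*% beta
  rss <- sum(res^2)
  sigma2 <- rss / df
  covb <- sigma2 * solve(XtX)
  se <- sqrt(diag(covb))
  tv <- beta / se
  pv <- 2 * pt(-abs(tv), df)
  ## GLS intercept-only baseline under the same covariance
  w0 <- backsolve(R, rep(1, n), transpose = TRUE)
  b0 <- sum(w0 * yw) / sum(w0^2)
  rss0 <- sum((yw - w0 * b0)^2)
  r2 <- if (rss0 > 0) min(1, max(0, 1 - rss / rss0)) else NA_real_
  nm <- colnames(X) %||% paste0("b", seq_len(p))
  names(beta) <- names(se) <- names(tv) <- names(pv) <- nm
  new("PGLSFit", aminoAcid = aminoAcid, geneSet = geneSet,
      coefficients = beta, stdErrors = se, tValues = tv, pValues = pv,
      sigma2 = sigma2, r2 = r2, n = as.integer(n), dfResid = as.integer(df))
}

#' Fit the PGLS model for every amino acid
#'
#' One regression of the z-scored profile on log diet breadth and log
#' thermal maximum per amino acid, all sharing the same taxa, design and
#' covariance. Rows are aligned by species label, never by position.
#'
#' @param profiles an \linkS4class{AAProfileSet}.
#' @param traits trait table covering the same species.
#' @param tree \code{phylo} object whose tip set equals the profile/trait
#'   species.
#' @param includeInteraction passed to \code{\link{buildDesign}}.
#' @return named list of 20 \linkS4class{PGLSFit} objects.
#' @export
fitAllAminoAcids <- function(profiles, traits, tree,
                             includeInteraction = FALSE) {
  taxaP <- canonicalLabel(speciesNames(profiles))
  taxaT <- canonicalLabel(traits$species)
  taxaTree <- canonicalLabel(tree$tip.label)
  for (pair in list(c("profiles", "traits"), c("profiles", "tree"))) {
    a <- if (pair[1] == "profiles") taxaP else taxaT
    b <- if (pair[2] == "traits") taxaT else taxaTree
    if (!setequal(a, b)) {
      diff <- union(setdiff(a, b), setdiff(b, a))
      ppglsStop(sprintf("taxa mismatch between %s and %s: %s",
                        pair[1], pair[2], paste(diff, collapse = ", ")),
                "ppglsValidationError")
    }
  }
  ord <- taxaTree
  C <- brownianCovariance(tree)
  X <- buildDesign(traits, ord, includeInteraction)
  z <- zscores(profiles)
  colnames(z) <- taxaP
  fits <- lapply(AA_LETTERS, function(a)
    glsFit(z[a, ord], X, C, aminoAcid = a, geneSet = geneSet(profiles)))
  names(fits) <- AA_LETTERS
  fits
}

#' Benjamini-Hochberg adjustment of p-values
#'
#' Step-up false-discovery-rate adjustment (sorted ascending,
#' \eqn{\tilde p_{(i)} = \min_{j \ge i} \min(1, p_{(j)} m / j)}, mapped back
#' to input order), delegated to \code{stats::p.adjust}. Inputs outside
#' [0, 1] are an error.
#'
#' @param p numeric vector of p-values.
#' @return adjusted p-values in input order.
#' @export
bhAdjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    ppglsStop("p-values must lie in [0, 1]", "ppglsValidationError")
  p.adjust(p, method = "BH")
}
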