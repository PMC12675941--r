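## independent oracles used across the suite; each deliberately avoids the
## code path it checks

## character-histogram residue counter: per record, then summed
histCountOracle <- function(seqs) {
  chars <- unlist(strsplit(toupper(as.character(seqs)), ""), use.names = FALSE)
  counts <- vapply(AA_LETTERS, function(a) sum(chars == a), 0L)
  skip <- c("X", "B", "Z", "J", "U", "O", "*", "-")
  list(counts = counts, total_counted = sum(counts),
       total_skipped = sum(chars %in% skip))
}

## closed-form ordinary least squares with explicit inverses
olsOracle <- function(y, X) {
  XtXi <- solve(t(X) %*% X)
  beta <- drop(XtXi %*% t(X) %*% y)
  res <- y - X %*% beta
  df <- length(y) - ncol(X)
  s2 <- sum(res^2) / df
  se <- sqrt(diag(s2 * XtXi))
  tv <- beta / se
  list(beta = beta, se = se, t = tv, p = 2 * pt(-abs(tv), df),
       sigma2 = s2)
}

## dense GLS with explicit matrix inverses (brute force)
denseGLSOracle <- function(y, X, C) {
  Ci <- solve(C)
  A <- solve(t(X) %*% Ci %*% X)
  beta <- drop(A %*% t(X) %*% Ci %*% y)
  res <- y - X %*% beta
  df <- length(y) - ncol(X)
  s2 <- drop(t(res) %*% Ci %*% res) / df
  list(beta = beta, se = sqrt(diag(s2 * A)), sigma2 = s2)
}

## definitional Benjamini-Hochberg step-up: for each i, min over j >= i
bhBruteOracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m))
    adj[i] <- min(vapply(i:m, function(j) min(1, ps[j] * m / j), 0))
  out <- numeric(m)
  out[o] <- adj
  out
}

## Brownian covariance from patristic distances:
## C[i,j] = (d(root,i) + d(root,j) - d(i,j)) / 2
patristicCovOracle <- function(tree) {
  depths <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  d <- stats::cophenetic(tree)
  d <- d[tree$tip.label, tree$tip.label]
  C <- (outer(depths, depths, "+") - d) / 2
  dimnames(C) <- list(tree$tip.label, tree$tip.label)
  C
}

writeFasta <- function(lines, path = tempfile(fileext = ".fasta")) {
  writeLines(lines, path)
  path
}

## ResidueCounts built directly from a named count vector
makeCounts <- function(...) {
  v <- c(...)
  counts <- setNames(integer(20L), AA_LETTERS)
  counts[names(v)] <- as.integer(v)
  structure(list(counts = counts, total_counted = sum(counts),
                 total_skipped = 0L), class = "ResidueCounts")
}

## small random profile set + matching trait table for regression tests
randomProfileTraits <- function(nSpecies, seed = 1L) {
  set.seed(seed)
  sp <- sprintf("sp%04d", seq_len(nSpecies))
  counts <- lapply(sp, function(s) {
    k <- as.vector(stats::rmultinom(1, 5000,
                                    prob = runif(20, 0.5, 1.5) / 20))
    names(k) <- AA_LETTERS
    structure(list(counts = k, total_counted = sum(k), total_skipped = 0L),
              class = "ResidueCounts")
  })
  names(counts) <- sp
  profiles <- standardizeProfiles(counts)
  traits <- data.frame(species = sp,
                       diet_breadth = sample(1:9, nSpecies, replace = TRUE),
                       max_temp = round(runif(nSpecies, 22, 36), 1))
  list(profiles = profiles, traits = traits, species = sp)
}
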