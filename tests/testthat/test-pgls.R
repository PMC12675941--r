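test_that("the design matrix log-transforms predictors in taxon order", {
  traits <- data.frame(species = c("a", "b", "c", "d"),
                       diet_breadth = c(1, 2, 4, 8),
                       max_temp = c(exp(1), 25, 30, 35))
  X <- buildDesign(traits, c("d", "a", "b", "c"))
  expect_identical(colnames(X),
                   c("(Intercept)", "log_diet_breadth", "log_max_temp"))
  expect_identical(rownames(X), c("d", "a", "b", "c"))
  expect_equal(X["a", "log_diet_breadth"], 0)
  expect_equal(X["a", "log_max_temp"], 1)

  const <- transform(traits, max_temp = 30)
  expect_error(buildDesign(const, traits$species), "log_max_temp")
  neg <- transform(traits, max_temp = c(-1, 25, 30, 35))
  expect_error(buildDesign(neg, traits$species), "max_temp")
})

test_that("a noiseless fit under identity covariance is exact", {
  set.seed(2)
  n <- 12
  X <- cbind(`(Intercept)` = 1, x1 = rnorm(n), x2 = rnorm(n))
  beta <- c(0.5, -1.2, 2)
  y <- drop(X %*% beta)
  fit <- glsFit(y, X, diag(n))
  expect_equal(unname(fit@coefficients), beta, tolerance = 1e-10)
  expect_equal(fit@r2, 1, tolerance = 1e-10)
})

test_that("PGLS on a star phylogeny reproduces ordinary least squares", {
  set.seed(31)
  for (i in 1:5) {
    n <- sample(10:40, 1)
    X <- cbind(1, rnorm(n), rnorm(n))
    colnames(X) <- c("(Intercept)", "x1", "x2")
    y <- rnorm(n)
    v <- runif(1, 0.1, 5)
    fit <- glsFit(y, X, v * diag(n))
    ols <- olsOracle(y, X)
    expect_equal(unname(fit@coefficients), unname(ols$beta),
                 tolerance = 1e-8)
    expect_equal(unname(fit@stdErrors), unname(ols$se), tolerance = 1e-8)
    expect_equal(unname(fit@tValues), unname(ols$t), tolerance = 1e-8)
    expect_equal(unname(fit@pValues), unname(ols$p), tolerance = 1e-8)
  }
})

test_that("a three-taxon fit matches brute-force dense arithmetic", {
  phy <- parseNewick("((A:1,B:1):1,C:2);")
  C <- brownianCovariance(phy)
  X <- cbind(`(Intercept)` = c(1, 1, 1), x = c(0.2, 1.4, 2.7))
  y <- c(0.31, -0.42, 1.05)
  fit <- glsFit(y, X, C)
  oracle <- denseGLSOracle(y, X, C)
  expect_equal(unname(fit@coefficients), unname(oracle$beta),
               tolerance = 1e-10)
  expect_equal(unname(fit@stdErrors), unname(oracle$se), tolerance = 1e-10)
})

test_that("estimates, t and p are invariant to covariance scale", {
  set.seed(7)
  phy <- ape::rcoal(15)
  C <- brownianCovariance(phy)
  X <- cbind(1, rnorm(15), rnorm(15))
  y <- rnorm(15)
  f1 <- glsFit(y, X, C)
  f2 <- glsFit(y, X, 17.3 * C)
  expect_equal(f1@coefficients, f2@coefficients, tolerance = 1e-10)
  expect_equal(f1@tValues, f2@tValues, tolerance = 1e-10)
  expect_equal(f1@pValues, f2@pValues, tolerance = 1e-10)
  expect_equal(f1@r2, f2@r2, tolerance = 1e-10)
  expect_equal(f2@sigma2, f1@sigma2 / 17.3, tolerance = 1e-10)
})

test_that("the fit agrees with an established GLS implementation", {
  set.seed(19)
  phy <- ape::rcoal(12)
  sp <- phy$tip.label
  df <- data.frame(sp = sp, y = rnorm(12), x1 = rnorm(12), x2 = rnorm(12))
  X <- cbind(`(Intercept)` = 1, x1 = df$x1, x2 = df$x2)
  fit <- glsFit(df$y, X, brownianCovariance(phy))
  ref <- nlme::gls(y ~ x1 + x2, data = df,
                   correlation = ape::corBrownian(1, phy, form = ~sp))
  expect_equal(unname(fit@coefficients), unname(coef(ref)),
               tolerance = 1e-6)
  refSE <- sqrt(diag(ref$varBeta))
  expect_equal(unname(fit@stdErrors), unname(refSE), tolerance = 1e-6)
})

test_that("degenerate fits are rejected", {
  X <- cbind(1, c(0, 1, 2))
  expect_error(glsFit(c(1, 2, 4), X, diag(3)[, 1:2]), "dimensions")
  expect_error(glsFit(c(1, 2), cbind(1, c(0, 1)), diag(2)),
               "degrees of freedom")
  ## indefinite "covariance" that no jitter-scale fix can repair
  sing <- diag(4)
  sing[1, 2] <- sing[2, 1] <- 2
  expect_error(glsFit(rnorm(4), cbind(1, rnorm(4)), sing), "singular")
})

test_that("one model is fitted per amino acid, aligned by species label", {
  pt <- randomProfileTraits(10, seed = 4)
  phy <- simulateTree(10, seed = 4)   # tips sp0001..sp0010
  fits <- fitAllAminoAcids(pt$profiles, pt$traits, phy)
  expect_identical(names(fits), AA_LETTERS)
  expect_true(all(vapply(fits, function(f) f@n, 0L) == 10L))

  ## permuting the species columns of the profile matrix changes nothing
  perm <- sample(10)
  shuffled <- pt$profiles[, perm]
  fits2 <- fitAllAminoAcids(shuffled, pt$traits, phy)
  expect_equal(fits2$M@coefficients, fits$M@coefficients, tolerance = 1e-12)

  ## a species present in the tree but absent from the profiles is named
  smaller <- randomProfileTraits(9, seed = 4)$profiles
  err <- expect_error(fitAllAminoAcids(smaller, pt$traits, phy))
  expect_match(conditionMessage(err), "sp0010")
})

test_that("BH adjustment matches its definition and dominates raw p", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhAdjust(0.5), 0.5)
  expect_equal(bhAdjust(c(1, 1, 1)), c(1, 1, 1))
  expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(77)
  for (i in 1:20) {
    p <- runif(20)
    adj <- bhAdjust(p)
    expect_equal(adj, bhBruteOracle(p), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-15))
    expect_true(all(diff(adj[order(p)]) >= -1e-15))   # monotone in p order
  }
})
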