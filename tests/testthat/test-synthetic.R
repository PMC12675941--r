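test_that("Yule simulation produces valid ultrametric trees,
           deterministically", {
  phy <- simulateTree(3, seed = 1)
  expect_s3_class(phy, "phylo")
  expect_identical(length(phy$tip.label), 3L)
  expect_identical(phy$Nnode, 2L)
  expect_true(isUltrametric(phy, relTol = 1e-8))

  expect_identical(ape::write.tree(simulateTree(40, seed = 9)),
                   ape::write.tree(simulateTree(40, seed = 9)))
  expect_false(identical(ape::write.tree(simulateTree(40, seed = 9)),
                         ape::write.tree(simulateTree(40, seed = 10))))
  expect_error(simulateTree(2), "at least 3")
})

test_that("mean Yule tree height matches the analytic expectation", {
  ## E[height] at rate 1 for n tips is sum_{k=2..n} 1/k
  n <- 200
  expected <- sum(1 / (2:n))
  set.seed(123)
  heights <- replicate(200, {
    phy <- simulateTree(n, birthRate = 1)
    max(ape::node.depth.edgelength(phy))
  })
  mcse <- sd(heights) / sqrt(length(heights))
  expect_lt(abs(mean(heights) - expected), 3 * mcse)
})

test_that("Brownian simulation has the covariance the tree implies", {
  phy <- parseNewick("(A:1,B:1,C:1);")
  expect_equal(unname(simulateBM(phy, rootValue = 2.5, sigma2 = 1e-12,
                                 seed = 5)),
               rep(2.5, 3), tolerance = 1e-4)

  ## star tree: tips i.i.d. around the root
  set.seed(55)
  draws <- t(replicate(2000, simulateBM(phy, 0, 1)))
  S <- cov(draws)
  expect_equal(unname(diag(S)), rep(1, 3), tolerance = 0.15)
  expect_lt(max(abs(S[upper.tri(S)])), 0.1)

  ## 2-tip tree with branch length 2: Var = 2 sigma2, Cov = 0
  phy2 <- ape::read.tree(text = "(A:2,B:2);")
  set.seed(56)
  draws2 <- t(replicate(2000, simulateBM(phy2, 0, 1)))
  S2 <- cov(draws2)
  expect_equal(unname(diag(S2)), c(2, 2), tolerance = 0.25)
  expect_lt(abs(S2[1, 2]), 0.15)
})

test_that("the noiseless generative limit is recovered exactly by PGLS", {
  beta <- matrix(0, 3, 20)
  beta[, 1] <- c(0.7, -0.3, 0.5)    # amino acid A
  sc <- syntheticScenario(nSpecies = 20L, nTrees = 1L, beta = beta,
                          sigma2Resid = 1e-16, seed = 99L)
  sim <- simulateTraitsAndProfiles(sc)
  X <- buildDesign(sim$traits, sim$tree$tip.label)
  C <- brownianCovariance(sim$tree)
  fit <- glsFit(sim$zTruth[sim$tree$tip.label, "A"], X, C)
  expect_equal(unname(fit@coefficients), c(0.7, -0.3, 0.5),
               tolerance = 1e-6)
})

test_that("emitted proteomes realise their target frequencies", {
  sc <- syntheticScenario(nSpecies = 3L, nTrees = 1L,
                          proteinsPerSpecies = 1000L,
                          meanProteinLength = 400, seed = 17L)
  sim <- simulateTraitsAndProfiles(sc)
  freqs <- proteoPGLS:::targetFrequencies(sc, sim$zTruth)
  dir <- file.path(tempfile(), "prot")
  out <- emitProteomes(freqs[1:2, ], sc, dir)
  for (s in rownames(freqs)[1:2]) {
    recs <- readProteomeFasta(out$fasta[[s]])
    rc <- countResidues(recs)
    realized <- rc$counts / rc$total_counted
    expect_lt(max(abs(realized - freqs[s, ])), 0.005)
  }
})

test_that("the ortholog fraction extremes exercise the partition error
           paths", {
  sc0 <- syntheticScenario(nSpecies = 3L, nTrees = 1L,
                           proteinsPerSpecies = 10L,
                           meanProteinLength = 50,
                           orthologFraction = 0, seed = 3L)
  sim <- simulateTraitsAndProfiles(sc0)
  freqs <- proteoPGLS:::targetFrequencies(sc0, sim$zTruth)
  d0 <- file.path(tempfile(), "f0")
  out0 <- emitProteomes(freqs, sc0, d0)
  asg0 <- suppressWarnings(readOrthogroups(out0$orthogroups))
  expect_identical(nrow(asg0), 0L)
  recs <- lapply(out0$fasta, readProteomeFasta)
  expect_error(partitionProfiles(recs, asg0), "ortholog partition")

  sc1 <- syntheticScenario(nSpecies = 3L, nTrees = 1L,
                           proteinsPerSpecies = 10L,
                           meanProteinLength = 50,
                           orthologFraction = 1, seed = 3L)
  d1 <- file.path(tempfile(), "f1")
  out1 <- emitProteomes(freqs, sc1, d1)
  asg1 <- readOrthogroups(out1$orthogroups)
  recs1 <- lapply(out1$fasta, readProteomeFasta)
  expect_error(partitionProfiles(recs1, asg1), "non_ortholog partition")
})

test_that("emitted ecology files reproduce the ground truth exactly", {
  sc <- syntheticScenario(nSpecies = 8L, nTrees = 1L,
                          proteinsPerSpecies = 10L, meanProteinLength = 30,
                          seed = 23L)
  sim <- simulateTraitsAndProfiles(sc)
  dir <- tempfile()
  eco <- emitEcology(sim$traits, sc, dir)
  hosts <- readHostRecords(eco$hosts)
  occ <- readOccurrences(eco$occurrences)
  grid <- readAsciiGrid(eco$grid)
  for (i in seq_len(nrow(sim$traits))) {
    s <- sim$traits$species[i]
    expect_identical(dietBreadth(hosts, s), sim$traits$diet_breadth[i])
    expect_identical(as.numeric(extractBio5Max(occ, grid, s)),
                     sim$traits$max_temp[i])
  }
  ## assembly retains every generated species with zero exclusions
  tab <- assembleTraitTable(hosts, occ, grid, sim$traits$species)
  expect_identical(nrow(tab), 8L)
  expect_identical(nrow(attr(tab, "exclusions")), 0L)
})

test_that("scenario generation is byte-identical under the same seed", {
  sc <- syntheticScenario(nSpecies = 5L, nTrees = 3L,
                          proteinsPerSpecies = 20L, meanProteinLength = 60,
                          seed = 31L)
  d1 <- file.path(tempfile(), "a")
  d2 <- file.path(tempfile(), "b")
  writeScenario(sc, d1)
  writeScenario(sc, d2)
  f1 <- list.files(d1, recursive = TRUE)
  f2 <- list.files(d2, recursive = TRUE)
  expect_identical(f1, f2)
  m1 <- tools::md5sum(file.path(d1, f1))
  m2 <- tools::md5sum(file.path(d2, f2))
  expect_identical(unname(m1), unname(m2))
})
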