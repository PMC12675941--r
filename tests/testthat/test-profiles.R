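## two species with 100 residues each, differing in every column (the
## z-score needs cross-species variance in all 20 amino acids)
twoSpeciesCounts <- function() {
  s1 <- setNames(c(10L, 2L, 4L, 6L, 2L, 6L, 2L, 4L, 6L, 12L,
                   2L, 4L, 4L, 4L, 6L, 8L, 6L, 6L, 2L, 4L), AA_LETTERS)
  s2 <- s1 + rep(c(1L, -1L), 10L)
  list(s1 = makeCounts(s1), s2 = makeCounts(s2))
}

test_that("standardization divides relative frequency by codon redundancy", {
  counts <- twoSpeciesCounts()
  prof <- standardizeProfiles(counts)
  expect_s4_class(prof, "AAProfileSet")
  expect_equal(rawFreq(prof)["L", "s1"], 0.12)
  expect_equal(standardizedFreq(prof)["L", "s1"], 0.02)   # 0.12 / 6
  expect_equal(standardizedFreq(prof)["M", "s1"], 0.02)   # redundancy 1
  expect_equal(colSums(rawFreq(prof)), c(s1 = 1, s2 = 1))
})

test_that("z-scoring uses the sample standard deviation across species", {
  ## M has redundancy 1, so standardized == raw frequency: {0.01, 0.03}
  s1 <- setNames(c(15L, 2L, 4L, 6L, 3L, 6L, 2L, 5L, 6L, 10L,
                   1L, 4L, 4L, 4L, 6L, 8L, 6L, 6L, 1L, 1L), AA_LETTERS)
  s2 <- setNames(c(13L, 3L, 3L, 7L, 2L, 7L, 1L, 6L, 5L, 11L,
                   3L, 3L, 5L, 3L, 7L, 7L, 7L, 5L, 2L, 0L), AA_LETTERS)
  stopifnot(sum(s1) == 100L, sum(s2) == 100L)
  prof <- standardizeProfiles(list(s1 = makeCounts(s1), s2 = makeCounts(s2)))
  expect_equal(standardizedFreq(prof)["M", ], c(s1 = 0.01, s2 = 0.03))
  ## {0.01, 0.03}: mean 0.02, sample sd sqrt(2e-4) -> z = -/+ 0.7071
  expect_equal(unname(zscores(prof)["M", ]), c(-0.7071068, 0.7071068),
               tolerance = 1e-6)
})

test_that("z-score round trip reproduces standardized values", {
  pt <- randomProfileTraits(12, seed = 3)
  std <- standardizedFreq(pt$profiles)
  z <- zscores(pt$profiles)
  mu <- rowMeans(std)
  sds <- apply(std, 1, sd)
  expect_true(max(abs(z * sds + mu - std)) < 1e-12)
})

test_that("degenerate inputs are rejected with informative errors", {
  counts <- list(s1 = makeCounts(M = 1L, A = 9L),
                 s2 = makeCounts(M = 1L, A = 9L))
  expect_error(standardizeProfiles(counts), "zero-variance")
  expect_error(standardizeProfiles(counts["s1"]), "two species")
  zero <- structure(list(counts = setNames(integer(20), AA_LETTERS),
                         total_counted = 0L, total_skipped = 3L),
                    class = "ResidueCounts")
  expect_error(standardizeProfiles(list(s1 = zero, s2 = makeCounts(M = 2L))),
               "zero counted")
})

test_that("profiles are invariant to record order, species order and
           sequence duplication", {
  set.seed(11)
  recs <- lapply(1:3, function(i) {
    s <- vapply(1:15, function(j)
      paste(sample(AA_LETTERS, 50, replace = TRUE), collapse = ""), "")
    names(s) <- paste0("p", 1:15)
    s
  })
  names(recs) <- c("a", "b", "c")
  base <- aaProfiles(recs)
  shuffled <- lapply(recs, function(x) x[sample(length(x))])[c("c", "a", "b")]
  expect_equal(rawFreq(aaProfiles(shuffled))[, c("a", "b", "c")],
               rawFreq(base)[, c("a", "b", "c")])
  doubled <- recs
  doubled$a <- c(doubled$a, setNames(doubled$a, paste0("q", 1:15)))
  expect_equal(rawFreq(aaProfiles(doubled)), rawFreq(base))
})

test_that("orthogroup table parsing handles the tab-separated dialect", {
  p <- tempfile()
  writeLines(c("Orthogroup\tA\tB",
               "OG0000001\tp1, p2\tq9",
               "OG0000002\tp3\t"), p)
  asg <- readOrthogroups(p, species = c("A", "B"))
  expect_identical(nrow(asg), 4L)
  expect_setequal(asg$protein[asg$orthogroup == "OG0000001"],
                  c("p1", "p2", "q9"))
  expect_identical(asg$species[asg$protein == "q9"], "B")
  expect_false("B" %in% asg$species[asg$orthogroup == "OG0000002"])

  headerOnly <- tempfile()
  writeLines("Orthogroup\tA\tB", headerOnly)
  expect_warning(empty <- readOrthogroups(headerOnly), "no orthogroups")
  expect_identical(nrow(empty), 0L)

  dup <- tempfile()
  writeLines(c("Orthogroup\tA", "OG1\tp1", "OG2\tp1"), dup)
  expect_error(readOrthogroups(dup), "more than one orthogroup")

  expect_warning(readOrthogroups(p, species = "A"), "unknown species")
})

mkseq <- function(n) paste(sample(AA_LETTERS, n, replace = TRUE),
                           collapse = "")

test_that("partitioning splits counts and conserves totals", {
  set.seed(33)
  ## prime pool sizes: partition totals share no ratio, so no amino acid
  ## can tie exactly across species (the z-score gate rejects ties)
  recs <- list(
    A = c(p1 = mkseq(263), p2 = mkseq(199), p3 = mkseq(149)),
    B = c(q1 = mkseq(241), q2 = mkseq(211), q3 = mkseq(139)))
  asg <- data.frame(orthogroup = c("OG1", "OG2", "OG1", "OG2"),
                    species = c("A", "A", "B", "B"),
                    protein = c("p1", "p2", "q1", "q2"))
  parts <- partitionProfiles(recs, asg)
  expect_identical(names(parts), c("ortholog", "non_ortholog"))
  expect_identical(geneSet(parts$ortholog), "ortholog")
  ## ortholog profile of A is built from the assigned records only
  cA <- countResidues(recs$A[c("p1", "p2")])
  expect_equal(unname(rawFreq(parts$ortholog)[, "A"]),
               unname(cA$counts / cA$total_counted))
  cAnon <- countResidues(recs$A["p3"])
  expect_equal(unname(rawFreq(parts$non_ortholog)[, "A"]),
               unname(cAnon$counts / cAnon$total_counted))
  ## conservation: partition totals sum to whole-proteome totals
  whole <- aaProfiles(recs)
  expect_identical(
    colData(parts$ortholog)$totalCounted +
      colData(parts$non_ortholog)$totalCounted,
    colData(whole)$totalCounted)
})

test_that("partitioning rejects empty partitions and unknown proteins", {
  recs <- list(A = c(p1 = "MMM", p2 = "KKK"),
               B = c(q1 = "MMM", q2 = "KKK"))
  allAssigned <- data.frame(orthogroup = "OG1",
                            species = c("A", "A", "B", "B"),
                            protein = c("p1", "p2", "q1", "q2"))
  expect_error(partitionProfiles(recs, allAssigned),
               "no proteins in the non_ortholog partition")
  unknown <- data.frame(orthogroup = "OG1", species = "A", protein = "zz")
  expect_error(partitionProfiles(recs, unknown), "unknown protein")
})

test_that("species-specific orthogroups can be excluded from orthology", {
  set.seed(34)
  recs <- list(A = c(p1 = mkseq(251), p2 = mkseq(163), p3 = mkseq(157)),
               B = c(q1 = mkseq(241), q2 = mkseq(151)))
  asg <- data.frame(orthogroup = c("OG1", "OG1", "OGprivate"),
                    species = c("A", "B", "A"),
                    protein = c("p1", "q1", "p2"))
  anyGroup <- partitionProfiles(recs, asg, orthologDef = "any_group")
  expect_equal(colData(anyGroup$ortholog)$totalCounted[["A"]], 414L)
  multi <- partitionProfiles(recs, asg, orthologDef = "multi_species")
  expect_equal(colData(multi$ortholog)$totalCounted[["A"]], 251L)
})

test_that("tidy profile output has the documented layout", {
  pt <- randomProfileTraits(4, seed = 9)
  path <- tempfile(fileext = ".tsv")
  df <- writeProfileTable(pt$profiles, path)
  back <- read.delim(path)
  expect_identical(names(back),
                   c("species", "gene_set", "amino_acid", "raw_freq",
                     "standardized", "zscored"))
  expect_identical(nrow(back), 80L)
  expect_equal(sum(back$raw_freq), 4)
})
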