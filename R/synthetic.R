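## ground-truth data generation for every pipeline input

## baseline residue frequencies loosely shaped like an average eukaryote
## proteome (sums to 1); the generator targets statistical structure, not
## the codon usage of any real taxon
.BASE_AA_FREQ <- c(
  A = 0.074, C = 0.020, D = 0.053, E = 0.063, F = 0.040, G = 0.062,
  H = 0.026, I = 0.053, K = 0.062, L = 0.092, M = 0.023, N = 0.044,
  P = 0.051, Q = 0.041, R = 0.052, S = 0.082, T = 0.055, V = 0.062,
  W = 0.013, Y = 0.032)
.BASE_AA_FREQ <- .BASE_AA_FREQ / sum(.BASE_AA_FREQ)

#' Construct a synthetic study scenario
#'
#' Bundles every ground-truth parameter of the generator. Defaults mirror
#' the study design the pipeline targets: 35 species, an ensemble of 1000
#' topology replicates, and null trait effects (all betas zero) so the
#' generated data match the no-association regime; effects are injected by
#' passing a non-zero \code{beta} matrix.
#'
#' @param nSpecies number of species (>= 3).
#' @param nTrees ensemble size.
#' @param birthRate Yule speciation rate.
#' @param beta 3 x 20 coefficient matrix (intercept, log_diet_breadth,
#'   log_max_temp rows; \code{\link{AA_LETTERS}} columns). Default all zero.
#' @param sigma2Resid Brownian residual rate per amino acid (length 20 or
#'   scalar).
#' @param traitRoot,traitRate named (\code{logDiet}, \code{logTemp}) root
#'   values and Brownian rates of the log-scale traits.
#' @param proteinsPerSpecies,meanProteinLength proteome emission sizes.
#' @param orthologFraction fraction of each species' proteins assigned to
#'   shared orthogroups.
#' @param gridCellSize climate-grid cell size (degrees).
#' @param injectInFrequencies also perturb emitted residue frequencies with
#'   the trait effects (exercises the standardization chain).
#' @param seed master seed; per-component random streams are derived from it.
#' @return a \linkS4class{SyntheticScenario}.
#' @export
syntheticScenario <- function(nSpecies = 35L, nTrees = 1000L, birthRate = 1,
                              beta = NULL, sigma2Resid = 0.3,
                              traitRoot = c(logDiet = log(5),
                                            logTemp = log(30)),
                              traitRate = c(logDiet = 0.1,
                                            logTemp = 0.002),
                              proteinsPerSpecies = 300L,
                              meanProteinLength = 300,
                              orthologFraction = 0.6,
                              gridCellSize = 0.5,
                              injectInFrequencies = FALSE,
                              seed = 20240101L) {
  if (is.null(beta)) beta <- matrix(0, 3L, 20L)
  dimnames(beta) <- list(c("(Intercept)", "log_diet_breadth", "log_max_temp"),
                         AA_LETTERS)
  if (length(sigma2Resid) == 1L) sigma2Resid <- rep(sigma2Resid, 20L)
  names(sigma2Resid) <- AA_LETTERS
  new("SyntheticScenario", nSpecies = as.integer(nSpecies),
      birthRate = birthRate, nTrees = as.integer(nTrees), beta = beta,
      sigma2Resid = sigma2Resid,
      traitRoot = traitRoot[c("logDiet", "logTemp")],
      traitRate = traitRate[c("logDiet", "logTemp")],
      proteinsPerSpecies = as.integer(proteinsPerSpecies),
      meanProteinLength = meanProteinLength,
      orthologFraction = orthologFraction, gridCellSize = gridCellSize,
      injectInFrequencies = injectInFrequencies, seed = as.integer(seed))
}

#' Simulate an ultrametric Yule tree
#'
#' Forward pure-birth simulation: starting from the root's two lineages,
#' the wait before the split from k to k+1 lineages is exponential with
#' rate \code{k * birthRate}; after the n-th lineage appears one further
#' exponential stretch is added, so the expected tree height at rate 1 is
#' \eqn{\sum_{k=2}^{n} 1/k}. Tips are labelled \code{sp0001, sp0002, ...}.
#'
#' @param n number of tips (>= 3).
#' @param birthRate speciation rate (> 0).
#' @param seed optional seed for reproducibility; \code{NULL} uses the
#'   current random stream.
#' @return ultrametric \code{phylo} object.
#' @export
simulateTree <- function(n, birthRate = 1, seed = NULL) {
  if (n < 3L) ppglsStop("a tree needs at least 3 tips",
                        "ppglsValidationError")
  if (birthRate <= 0) ppglsStop("birthRate must be > 0",
                                "ppglsValidationError")
  if (!is.null(seed)) set.seed(seed)
  waits <- rexp(n - 1L, rate = birthRate * (2:n))
  eventTimes <- cumsum(waits)            # splits at eventTimes[1..n-2]
  height <- eventTimes[n - 1L]
  ## lineage bookkeeping: each active lineage is an open edge
  rootId <- 1L
  nextNode <- 2L
  edges <- list()                         # parent, childNode/tip, start
  active <- list(list(parent = rootId, start = 0),
                 list(parent = rootId, start = 0))
  if (n > 2L) {
    for (j in seq_len(n - 2L)) {
      t <- eventTimes[j]
      pick <- sample.int(length(active), 1L)
      lin <- active[[pick]]
      node <- nextNode; nextNode <- nextNode + 1L
      edges[[length(edges) + 1L]] <-
        list(parent = lin$parent, child = node, len = t - lin$start,
             tip = FALSE)
      active[[pick]] <- list(parent = node, start = t)
      active[[length(active) + 1L]] <- list(parent = node, start = t)
    }
  }
  nint <- nextNode - 1L                  # internal node count == n - 1
  tipEdges <- lapply(active, function(lin)
    list(parent = lin$parent, child = NA, len = height - lin$start,
         tip = TRUE))
  allEdges <- c(edges, tipEdges)
  ## ape numbering: tips 1..n, internals n+1 .. n+nint (root first)
  tipCounter <- 0L
  edgeMat <- matrix(0L, length(allEdges), 2L)
  lens <- numeric(length(allEdges))
  for (i in seq_along(allEdges)) {
    e <- allEdges[[i]]
    edgeMat[i, 1L] <- n + e$parent
    if (e$tip) {
      tipCounter <- tipCounter + 1L
      edgeMat[i, 2L] <- tipCounter
    } else {
      edgeMat[i, 2L] <- n + e$child
    }
    lens[i] <- e$len
  }
  phy <- structure(list(edge = edgeMat, edge.length = lens,
                        Nnode = nint,
                        tip.label = sprintf("sp%04d", seq_len(n))),
                   class = "phylo", order = "cladewise")
  ape::reorder.phylo(phy)
}

#' Simulate Brownian motion along a tree
#'
#' Recursive root-to-tip simulation: every branch adds an independent
#' normal increment with variance \code{sigma2 * branch length}, so tip
#' values have covariance \code{sigma2} times the Brownian covariance of
#' the tree.
#'
#' @param tree \code{phylo} object with branch lengths.
#' @param rootValue trait value at the root.
#' @param sigma2 Brownian rate (> 0).
#' @param seed optional seed; \code{NULL} uses the current stream.
#' @return named numeric vector of tip values.
#' @export
simulateBM <- function(tree, rootValue = 0, sigma2 = 1, seed = NULL) {
  if (sigma2 <= 0) ppglsStop("sigma2 must be > 0", "ppglsValidationError")
  if (!is.null(seed)) set.seed(seed)
  phy <- ape::reorder.phylo(tree)        # parents precede children
  ntip <- length(phy$tip.label)
  vals <- numeric(ntip + phy$Nnode)
  vals[ntip + 1L] <- rootValue
  inc <- rnorm(nrow(phy$edge), 0, sqrt(sigma2 * phy$edge.length))
  for (i in seq_len(nrow(phy$edge)))
    vals[phy$edge[i, 2L]] <- vals[phy$edge[i, 1L]] + inc[i]
  setNames(vals[seq_len(ntip)], phy$tip.label)
}

#' Simulate ecological traits and ground-truth responses
#'
#' Log diet breadth and log thermal maximum evolve as Brownian motion on
#' the tree, then are discretized (diet: ceiling of the exponential,
#' forced >= 1; temperature: exponential rounded to 0.01 degC so the file
#' round trip is exact). For each amino acid the response is
#' \code{y = b0 + b_d log(diet) + b_t log(temp) + eps} with \code{eps}
#' Brownian on the same tree — exactly the generative model the PGLS
#' inverts.
#'
#' @param scenario a \linkS4class{SyntheticScenario}.
#' @param tree data-generating tree (defaults to a fresh Yule tree from the
#'   scenario's tree stream).
#' @return list with \code{traits} (data.frame), \code{zTruth}
#'   (species x 20 response matrix) and \code{tree}.
#' @export
simulateTraitsAndProfiles <- function(scenario, tree = NULL) {
  if (is.null(tree))
    tree <- simulateTree(scenario@nSpecies, scenario@birthRate,
                         seed = subSeed(scenario@seed, "tree"))
  set.seed(subSeed(scenario@seed, "traits"))
  ld <- simulateBM(tree, scenario@traitRoot["logDiet"],
                   scenario@traitRate["logDiet"])
  lt <- simulateBM(tree, scenario@traitRoot["logTemp"],
                   scenario@traitRate["logTemp"])
  traits <- data.frame(species = tree$tip.label,
                       diet_breadth = pmax(1L, as.integer(ceiling(exp(ld)))),
                       max_temp = round(exp(lt), 2))
  X <- cbind(1, log(traits$diet_breadth), log(traits$max_temp))
  set.seed(subSeed(scenario@seed, "residuals"))
  z <- vapply(AA_LETTERS, function(a) {
    drop(X %*% scenario@beta[, a]) +
      unname(simulateBM(tree, 0, scenario@sigma2Resid[a]))
  }, numeric(length(tree$tip.label)))
  rownames(z) <- tree$tip.label
  list(traits = traits, zTruth = z, tree = tree)
}

## per-species target residue frequencies: baseline times species-level
## lognormal variation (so cross-species z-scoring has non-trivial spread),
## optionally tilted by the ground-truth responses
targetFrequencies <- function(scenario, zTruth) {
  set.seed(subSeed(scenario@seed, "frequencies"))
  n <- nrow(zTruth)
  noise <- matrix(rnorm(n * 20L, 0, 0.05), n, 20L)
  tilt <- if (scenario@injectInFrequencies) 0.05 * zTruth else 0
  f <- matrix(rep(.BASE_AA_FREQ, each = n), n, 20L) * exp(noise + tilt)
  f <- f / rowSums(f)
  dimnames(f) <- list(rownames(zTruth), AA_LETTERS)
  f
}

#' Emit proteome FASTA files and an orthogroup table
#'
#' Each species receives \code{proteinsPerSpecies} sequences with lengths
#' Poisson-distributed around \code{meanProteinLength} and residues drawn
#' i.i.d. from that species' target frequency vector. A random
#' \code{orthologFraction} of each species' protein ids is written into a
#' shared orthogroup table (OrthoFinder-style TSV); a fraction of 0 yields
#' a header-only table.
#'
#' @param freqs species x 20 matrix of target frequencies (rows sum to 1).
#' @param scenario a \linkS4class{SyntheticScenario}.
#' @param dir output directory.
#' @return list: \code{fasta} (named paths), \code{orthogroups} (path),
#'   \code{assignment} (ground-truth data.frame), invisibly.
#' @export
emitProteomes <- function(freqs, scenario, dir) {
  stopifnot(all(abs(rowSums(freqs) - 1) < 1e-8))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(subSeed(scenario@seed, "proteomes"))
  sp <- rownames(freqs)
  nprot <- scenario@proteinsPerSpecies
  fastaPaths <- character(0)
  idsBySpecies <- list()
  for (s in sp) {
    lens <- pmax(1L, rpois(nprot, scenario@meanProteinLength))
    residues <- sample(AA_LETTERS, sum(lens), replace = TRUE,
                       prob = freqs[s, ])
    joined <- paste(residues, collapse = "")
    ends <- cumsum(lens)
    starts <- c(1L, utils::head(ends, -1L) + 1L)
    seqs <- substring(joined, starts, ends)
    ids <- sprintf("%s_p%05d", s, seq_len(nprot))
    idsBySpecies[[s]] <- ids
    path <- file.path(dir, paste0(s, ".fasta"))
    Biostrings::writeXStringSet(Biostrings::AAStringSet(setNames(seqs, ids)),
                                path)
    fastaPaths[s] <- path
  }
  set.seed(subSeed(scenario@seed, "orthogroups"))
  nAssign <- round(scenario@orthologFraction * nprot)
  ogPath <- file.path(dir, "Orthogroups.tsv")
  if (nAssign == 0L) {
    writeLines(paste(c("Orthogroup", sp), collapse = "\t"), ogPath)
    assignment <- data.frame(orthogroup = character(),
                             species = character(), protein = character())
  } else {
    nGroups <- max(1L, nAssign %/% 2L)
    rows <- lapply(sp, function(s) {
      chosen <- sort(sample(idsBySpecies[[s]], nAssign))
      data.frame(orthogroup = sprintf("OG%07d",
                                      rep_len(seq_len(nGroups), nAssign)),
                 species = s, protein = chosen)
    })
    assignment <- do.call(rbind, rows)
    cells <- matrix("", nGroups, length(sp), dimnames = list(NULL, sp))
    for (s in sp) {
      byG <- split(assignment$protein[assignment$species == s],
                   assignment$orthogroup[assignment$species == s])
      cells[match(names(byG), sprintf("OG%07d", seq_len(nGroups))), s] <-
        vapply(byG, paste, "", collapse = ", ")
    }
    lines <- c(paste(c("Orthogroup", sp), collapse = "\t"),
               vapply(seq_len(nGroups), function(g)
                 paste(c(sprintf("OG%07d", g), cells[g, ]), collapse = "\t"),
                 ""))
    writeLines(lines, ogPath)
  }
  invisible(list(fasta = fastaPaths, orthogroups = ogPath,
                 assignment = assignment))
}

#' Emit host records, occurrences and a climate grid
#'
#' Constructs files whose pipeline-derived traits equal the ground truth
#' exactly: each species gets \code{diet_breadth} distinct synthetic plant
#' genera (with a duplicated record to exercise deduplication), one
#' occurrence on a dedicated grid cell valued at its true thermal maximum,
#' plus cooler background points, a duplicate point, one off-grid point and
#' one point on a missing cell (both skipped by extraction).
#'
#' @param traits ground-truth trait table (species, diet_breadth, max_temp).
#' @param scenario a \linkS4class{SyntheticScenario}.
#' @param dir output directory.
#' @return list of written paths plus the \linkS4class{ClimateGrid},
#'   invisibly.
#' @export
emitEcology <- function(traits, scenario, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(subSeed(scenario@seed, "ecology"))
  sp <- traits$species
  n <- length(sp)
  cs <- scenario@gridCellSize
  west <- 0; north <- 60
  ## grid: row 1 dedicated cells (one per species), row 2 cool background,
  ## row 3 missing
  bg <- min(traits$max_temp) - 5
  vals <- rbind(traits$max_temp, rep(bg, n), rep(NA_real_, n))
  grid <- new("ClimateGrid", west = west, north = north, cellSize = cs,
              values = vals)
  gridPath <- file.path(dir, "bio5_grid.asc")
  writeAsciiGrid(grid, gridPath)
  ## hosts: diet_breadth distinct genera + one duplicated record
  pool <- sprintf("Syngenus%03d", seq_len(max(traits$diet_breadth) + 5L))
  hostRows <- lapply(seq_len(n), function(i) {
    genera <- sample(pool, traits$diet_breadth[i])
    data.frame(species = sp[i],
               host = paste(c(genera, genera[1]), "plantus"))
  })
  hosts <- do.call(rbind, hostRows)
  hostsPath <- file.path(dir, "hosts.csv")
  write.csv(hosts, hostsPath, row.names = FALSE, quote = FALSE)
  ## occurrences: dedicated cell centre, background cell (plus duplicate),
  ## an off-grid point and a point on the missing row
  occRows <- lapply(seq_len(n), function(i) {
    lonOwn <- west + (i - 0.5) * cs
    latTop <- north - 0.5 * cs
    latBg <- north - 1.5 * cs
    latNa <- north - 2.5 * cs
    data.frame(species = sp[i],
               lon = c(lonOwn, lonOwn, lonOwn, west - 2 * cs, lonOwn),
               lat = c(latTop, latBg, latBg, latBg, latNa))
  })
  occ <- do.call(rbind, occRows)
  occPath <- file.path(dir, "occurrences.csv")
  write.csv(occ, occPath, row.names = FALSE, quote = FALSE)
  invisible(list(hosts = hostsPath, occurrences = occPath,
                 grid = gridPath, climateGrid = grid))
}

#' Write a complete synthetic scenario to disk
#'
#' Generates the data-generating tree plus ensemble replicates (independent
#' Yule topologies on the same tip set), the ground-truth traits and
#' responses, proteome FASTA files, the orthogroup table, ecology files and
#' a manifest of every ground-truth parameter, laid out exactly as the
#' pipeline readers expect. A ready-to-run \code{config.txt} pointing at
#' the generated files is included.
#'
#' @param scenario a \linkS4class{SyntheticScenario}.
#' @param dir output directory (created).
#' @return list with element \code{paths} (named character) and
#'   \code{truth} (tree, traits, zTruth, assignment), invisibly.
#' @export
writeScenario <- function(scenario, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(subSeed(scenario@seed, "tree"))
  trees <- vector("list", scenario@nTrees)
  for (i in seq_len(scenario@nTrees))
    trees[[i]] <- simulateTree(scenario@nSpecies, scenario@birthRate)
  class(trees) <- "multiPhylo"
  treePath <- file.path(dir, "trees.nwk")
  ape::write.tree(trees, treePath)
  sim <- simulateTraitsAndProfiles(scenario, tree = trees[[1]])
  freqs <- targetFrequencies(scenario, sim$zTruth)
  prot <- emitProteomes(freqs, scenario, file.path(dir, "proteomes"))
  eco <- emitEcology(sim$traits, scenario, dir)
  truthPath <- file.path(dir, "ground_truth_traits.tsv")
  write.table(sim$traits, truthPath, sep = "\t", quote = FALSE,
              row.names = FALSE)
  manifest <- c(
    list(n_species = scenario@nSpecies, n_trees = scenario@nTrees,
         birth_rate = scenario@birthRate, seed = scenario@seed,
         trait_root_log_diet = scenario@traitRoot["logDiet"],
         trait_root_log_temp = scenario@traitRoot["logTemp"],
         trait_rate_log_diet = scenario@traitRate["logDiet"],
         trait_rate_log_temp = scenario@traitRate["logTemp"],
         proteins_per_species = scenario@proteinsPerSpecies,
         mean_protein_length = scenario@meanProteinLength,
         ortholog_fraction = scenario@orthologFraction,
         inject_in_frequencies = scenario@injectInFrequencies),
    setNames(as.list(scenario@beta["log_diet_breadth", ]),
             paste0("beta_diet_", AA_LETTERS)),
    setNames(as.list(scenario@beta["log_max_temp", ]),
             paste0("beta_temp_", AA_LETTERS)),
    setNames(as.list(scenario@sigma2Resid),
             paste0("sigma2_", AA_LETTERS)))
  writeKeyValue(manifest, file.path(dir, "scenario_manifest.txt"))
  config <- c(proteome_dir = "proteomes", orthogroups = "proteomes/Orthogroups.tsv",
              hosts = "hosts.csv", occurrences = "occurrences.csv",
              grid = "bio5_grid.asc", trees = "trees.nwk",
              gene_sets = "all,ortholog,non_ortholog",
              interaction = "false", bh_family = "per_predictor",
              point_stat = "median", seed = scenario@seed)
  writeKeyValue(as.list(config), file.path(dir, "config.txt"))
  invisible(list(
    paths = c(trees = treePath, config = file.path(dir, "config.txt"),
              manifest = file.path(dir, "scenario_manifest.txt"),
              ground_truth = truthPath, orthogroups = prot$orthogroups,
              hosts = eco$hosts, occurrences = eco$occurrences,
              grid = eco$grid),
    truth = list(tree = sim$tree, traits = sim$traits, zTruth = sim$zTruth,
                 assignment = prot$assignment)))
}
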