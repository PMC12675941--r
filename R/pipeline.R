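## configuration-driven pipeline: profiles -> traits -> ensemble PGLS

resolveConfig <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config))
      ppglsStop(sprintf("configuration file not found: %s", config),
                "ppglsValidationError")
    base <- dirname(normalizePath(config))
    cfg <- as.list(readKeyValue(config))
    pathKeys <- c("proteome_dir", "orthogroups", "hosts", "occurrences",
                  "grid", "trees")
    for (k in intersect(pathKeys, names(cfg))) {
      p <- cfg[[k]]
      if (!grepl("^(/|[A-Za-z]:)", p)) cfg[[k]] <- file.path(base, p)
    }
    cfg
  } else if (is.list(config)) {
    config
  } else {
    ppglsStop("config must be a key-value file path or a named list",
              "ppglsValidationError")
  }
}

configFlag <- function(cfg, key, default = FALSE) {
  v <- cfg[[key]]
  if (is.null(v)) return(default)
  tolower(as.character(v)) %in% c("true", "1", "yes")
}

validateRunConfig <- function(cfg) {
  geneSets <- cfg$gene_sets %||% "all,ortholog,non_ortholog"
  if (length(geneSets) == 1L)
    geneSets <- strsplit(geneSets, ",[[:space:]]*")[[1]]
  bad <- setdiff(geneSets, c("all", "ortholog", "non_ortholog"))
  if (length(bad))
    ppglsStop(sprintf("unknown gene set(s): %s", paste(bad, collapse = ", ")),
              "ppglsValidationError")
  need <- c("proteome_dir", "hosts", "occurrences", "grid", "trees")
  if (any(c("ortholog", "non_ortholog") %in% geneSets))
    need <- c(need, "orthogroups")
  missingKeys <- setdiff(need, names(cfg))
  if (length(missingKeys))
    ppglsStop(sprintf("config is missing required key(s): %s",
                      paste(missingKeys, collapse = ", ")),
              "ppglsValidationError")
  missingPaths <- need[!file.exists(unlist(cfg[need]))]
  if (length(missingPaths))
    ppglsStop(sprintf("config path(s) do not exist: %s",
                      paste(unlist(cfg[missingPaths]), collapse = ", ")),
              "ppglsValidationError")
  cfg$gene_sets <- geneSets
  cfg
}

listProteomeFiles <- function(dir) {
  files <- list.files(dir, pattern = "\\.(fa|faa|fasta)(\\.gz)?$",
                      full.names = TRUE)
  if (length(files) == 0L)
    ppglsStop(sprintf("no FASTA files in proteome directory %s", dir),
              "ppglsValidationError")
  sp <- canonicalLabel(sub("\\.(fa|faa|fasta)(\\.gz)?$", "", basename(files)))
  setNames(files, sp)
}

#' Run the profile stage
#'
#' Reads every proteome FASTA in the configured directory (optionally
#' restricted to given species), computes whole-proteome profiles and, if
#' requested, the orthologous/non-orthologous partitions, and writes one
#' tidy profile table per gene set.
#'
#' @param config config file path or named list (keys \code{proteome_dir},
#'   \code{orthogroups}, \code{gene_sets}, ...).
#' @param outDir output directory.
#' @param species optional species subset (canonical labels).
#' @return named list of \linkS4class{AAProfileSet} objects, invisibly.
#' @export
runProfileStage <- function(config, outDir, species = NULL) {
  cfg <- validateRunConfig(resolveConfig(config))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(outDir, "run.log")
  files <- listProteomeFiles(cfg$proteome_dir)
  if (!is.null(species)) files <- files[intersect(names(files), species)]
  records <- lapply(names(files), function(s)
    readProteomeFasta(files[[s]], species = s))
  names(records) <- names(files)
  redundancy <- codonRedundancyTable()
  profiles <- list(all = aaProfiles(records, redundancy, "all"))
  if (any(c("ortholog", "non_ortholog") %in% cfg$gene_sets)) {
    assignment <- readOrthogroups(cfg$orthogroups, species = names(records))
    parts <- partitionProfiles(records, assignment, redundancy)
    profiles <- c(profiles, parts)
  }
  profiles <- profiles[intersect(c("all", "ortholog", "non_ortholog"),
                                 cfg$gene_sets)]
  for (gs in names(profiles)) {
    writeProfileTable(profiles[[gs]],
                      file.path(outDir, sprintf("profiles_%s.tsv", gs)))
    ppglsLog(sprintf("profile stage: wrote %s profiles for %d species",
                     gs, length(files)), logf)
  }
  invisible(profiles)
}

#' Run the trait stage
#'
#' Derives diet breadth and the realised thermal maximum for the candidate
#' species, logging every exclusion with its reason, and writes the trait
#' table.
#'
#' @param config config file path or named list (keys \code{hosts},
#'   \code{occurrences}, \code{grid}).
#' @param outDir output directory.
#' @param species candidate species labels (defaults to the proteome
#'   directory contents).
#' @return trait table data.frame, invisibly.
#' @export
runTraitStage <- function(config, outDir, species = NULL) {
  cfg <- validateRunConfig(resolveConfig(config))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(outDir, "run.log")
  if (is.null(species)) species <- names(listProteomeFiles(cfg$proteome_dir))
  hosts <- readHostRecords(cfg$hosts)
  occ <- readOccurrences(cfg$occurrences)
  grid <- readAsciiGrid(cfg$grid)
  unknownHosts <- setdiff(unique(hosts$species), canonicalLabel(species))
  if (length(unknownHosts))
    ppglsLog(sprintf("trait stage: ignoring host records for unknown species: %s",
                     paste(unknownHosts, collapse = ", ")), logf)
  traits <- assembleTraitTable(hosts, occ, grid, species)
  excl <- attr(traits, "exclusions")
  for (i in seq_len(nrow(excl)))
    ppglsLog(sprintf("trait stage: excluded %s (%s)",
                     excl$species[i], excl$reason[i]), logf)
  sk <- attr(traits, "skipped_points")
  for (s in names(sk)[sk > 0])
    ppglsLog(sprintf("trait stage: %s had %d occurrence point(s) off-grid or on missing cells",
                     s, sk[s]), logf)
  write.table(traits, file.path(outDir, "traits.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(traits)
}

#' Run the PGLS stage
#'
#' Loads the tree ensemble pruned to the retained species, repeats the
#' per-amino-acid PGLS over trees and gene sets, and writes the
#' publication-style summary, the machine-readable long format and a run
#' manifest (seed, tree counts, dropped trees, BH family, input checksums).
#'
#' @param config config file path or named list.
#' @param outDir output directory.
#' @param profiles named list of \linkS4class{AAProfileSet} (from
#'   \code{\link{runProfileStage}}).
#' @param traits trait table (from \code{\link{runTraitStage}}).
#' @return an \linkS4class{EnsembleSummary}, invisibly.
#' @export
runPGLSStage <- function(config, outDir, profiles, traits) {
  cfg <- validateRunConfig(resolveConfig(config))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(outDir, "run.log")
  ensemble <- loadTreeEnsemble(cfg$trees, traits$species)
  for (msg in attr(ensemble, "dropped"))
    ppglsLog(sprintf("pgls stage: rejected %s", msg), logf)
  if (!all(vapply(ensemble, isUltrametric, TRUE, relTol = 0.01)))
    ppglsLog("pgls stage: some trees are not ultrametric within 1% (proceeding)",
             logf)
  es <- runEnsemble(profiles, traits, ensemble,
                    includeInteraction = configFlag(cfg, "interaction"),
                    bhFamily = cfg$bh_family %||% "per_predictor",
                    pointStat = cfg$point_stat %||% "median")
  for (msg in es@droppedTrees)
    ppglsLog(sprintf("pgls stage: dropped %s", msg), logf)
  inputs <- unlist(cfg[intersect(c("orthogroups", "hosts", "occurrences",
                                   "grid", "trees"), names(cfg))])
  sums <- tools::md5sum(inputs)
  runInfo <- c(list(seed = cfg$seed %||% "NA",
                    gene_sets = paste(names(profiles), collapse = ","),
                    n_species = nrow(traits),
                    interaction = configFlag(cfg, "interaction")),
               setNames(as.list(unname(sums)),
                        paste0("md5_", basename(names(sums)))))
  writeEnsembleResults(es, outDir, runInfo)
  ppglsLog(sprintf("pgls stage: %d gene set(s) x 20 amino acids over %d tree(s)",
                   length(profiles), es@nTreesUsed), logf)
  invisible(es)
}

#' Run the full pipeline
#'
#' Chains the profile, trait and PGLS stages: species retained for analysis
#' are exactly those with proteome, host and occurrence coverage
#' (profiles are computed, and z-scored, on the retained set only).
#'
#' @param config config file path (e.g. the \code{config.txt} written by
#'   \code{\link{writeScenario}}) or named list.
#' @param outDir output directory for all stage outputs and the run log.
#' @return list with \code{profiles}, \code{traits}, \code{summary}
#'   (an \linkS4class{EnsembleSummary}) and \code{outputs} (paths),
#'   invisibly.
#' @export
runAll <- function(config, outDir) {
  cfg <- validateRunConfig(resolveConfig(config))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(outDir, "run.log")
  cat("", file = logf)  # truncate log for a fresh run
  candidates <- names(listProteomeFiles(cfg$proteome_dir))
  traits <- runTraitStage(cfg, outDir, species = candidates)
  profiles <- runProfileStage(cfg, outDir, species = traits$species)
  es <- runPGLSStage(cfg, outDir, profiles, traits)
  outputs <- c(summary = file.path(outDir, "summary_table.tsv"),
               long = file.path(outDir, "results_long.tsv"),
               manifest = file.path(outDir, "run_manifest.txt"),
               traits = file.path(outDir, "traits.tsv"),
               log = logf)
  invisible(list(profiles = profiles, traits = traits, summary = es,
                 outputs = outputs))
}
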