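# Pipeline entry points behind the command-line front-end
# (inst/scripts/secomm). Each reads inputs, runs the corresponding
# analysis, writes deterministic result tables plus a run manifest, and
# returns its main result invisibly.

# Run manifest: config snapshot, input digests, seed, package version and
# per-stage row counts, so identical manifests imply identical outputs.
.writeManifest <- function(outDir, command, inputs, config, seed, counts) {
  digests <- if (length(inputs) > 0L) {
    as.list(tools::md5sum(normalizePath(inputs)))
  } else {
    list()
  }
  manifest <- list(
    command = command,
    package_version = as.character(utils::packageVersion("SEcomm")),
    rng_seed = seed,
    inputs = digests,
    config = config[setdiff(names(config), "columnMap")],
    column_map = as.list(config$columnMap),
    row_counts = counts)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  invisible(manifest)
}

.ensureDir <- function(outDir) {
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  outDir
}

#' Two-phase comparison pipeline
#'
#' Reads a reference and a comparator LR inference table, applies the
#' double p-value filter per state, computes SE scores and the
#' consensus/gain/potential-loss classification for every communication
#' type, aggregates the organ-level SE, and runs the consensus-shift
#' tests. Writes `se_table.csv`, `classification.csv`,
#' `consensus_shift.csv`, `organ_summary.json` and `manifest.json` into
#' `outDir`.
#'
#' @param refPath,cmpPath Paths to the reference and comparator tables.
#' @param refLabel,cmpLabel State labels.
#' @param outDir Output directory (created if needed).
#' @param config An [analysisConfig()].
#' @return Invisibly, the [CCCComparison].
#' @export
runCompare <- function(refPath, cmpPath, outDir,
                       refLabel = "state1", cmpLabel = "state2",
                       config = analysisConfig()) {
  .ensureDir(outDir)
  ref <- readInteractionTable(refPath, refLabel, config$columnMap, config$sep)
  cmp <- readInteractionTable(cmpPath, cmpLabel, config$columnMap, config$sep)
  res <- compareTables(ref, cmp, config)
  organ <- suppressWarnings(
    aggregateOrgan(res, includeEmergent = config$includeEmergent))
  shifts <- consensusShiftAll(res, config$pThreshold)
  writeResults(seTable(res), file.path(outDir, "se_table.csv"))
  writeResults(classificationTable(res),
               file.path(outDir, "classification.csv"))
  writeResults(shifts, file.path(outDir, "consensus_shift.csv"))
  writeResults(organ, file.path(outDir, "organ_summary.json"))
  .writeManifest(outDir, "compare", c(refPath, cmpPath), config,
                 config$rngSeed,
                 list(ref_rows = nrow(interactionData(ref)),
                      ref_rows_filtered = sum(
                        interactionData(ref)$pval_method_a < config$pThreshold &
                        interactionData(ref)$pval_method_b < config$pThreshold),
                      cmp_rows = nrow(interactionData(cmp)),
                      cmp_rows_filtered = sum(
                        interactionData(cmp)$pval_method_a < config$pThreshold &
                        interactionData(cmp)$pval_method_b < config$pThreshold),
                      comm_types = nrow(seTable(res)),
                      units = nrow(classificationTable(res))))
  invisible(res)
}

#' Lifespan-series pipeline
#'
#' Runs the two-phase comparison over every consecutive interval of an
#' ordered list of state tables (the two-phase design: adjacent states,
#' not a single early-vs-late contrast) and writes, per interval,
#' `se_table.csv` / `classification.csv` / `consensus_shift.csv` /
#' `organ_summary.json` under `interval_<i>_<ref>-<cmp>/`, plus an
#' organ-SE trajectory table (`organ_trajectory.csv`), the binary
#' significance matrix across intervals (`significance_matrix.csv`) and
#' a manifest.
#'
#' @param paths Character vector of >= 2 table paths, ordered by state.
#' @param labels State labels, same length as `paths`.
#' @param outDir Output directory.
#' @param config An [analysisConfig()].
#' @return Invisibly, a list of [CCCComparison], one per interval.
#' @export
runSeries <- function(paths, labels = NULL, outDir,
                      config = analysisConfig()) {
  if (length(paths) < 2L) {
    stop("usage error: a series needs at least two state tables",
         call. = FALSE)
  }
  if (is.null(labels)) labels <- sprintf("state%d", seq_along(paths))
  stopifnot(length(labels) == length(paths))
  .ensureDir(outDir)
  tables <- mapply(readInteractionTable, paths, labels,
                   MoreArgs = list(columnMap = config$columnMap,
                                   sep = config$sep),
                   SIMPLIFY = FALSE)
  nInt <- length(paths) - 1L
  comparisons <- vector("list", nInt)
  shiftTables <- vector("list", nInt)
  trajRows <- vector("list", nInt)
  intervalLabels <- paste(labels[-length(labels)], labels[-1L], sep = "->")
  names(shiftTables) <- intervalLabels
  for (i in seq_len(nInt)) {
    res <- compareTables(tables[[i]], tables[[i + 1L]], config)
    comparisons[[i]] <- res
    sub <- file.path(outDir, sprintf("interval_%02d_%s-%s", i, labels[i],
                                     labels[i + 1L]))
    .ensureDir(sub)
    organ <- suppressWarnings(
      aggregateOrgan(res, includeEmergent = config$includeEmergent))
    shiftTables[[i]] <- consensusShiftAll(res, config$pThreshold)
    writeResults(seTable(res), file.path(sub, "se_table.csv"))
    writeResults(classificationTable(res), file.path(sub, "classification.csv"))
    writeResults(shiftTables[[i]], file.path(sub, "consensus_shift.csv"))
    writeResults(organ, file.path(sub, "organ_summary.json"))
    trajRows[[i]] <- data.frame(interval = intervalLabels[i],
                                n_expand = organ$n_expand,
                                n_shrink = organ$n_shrink,
                                n_stable = organ$n_stable,
                                n_total = organ$n_total,
                                se_organ = organ$se_organ,
                                stringsAsFactors = FALSE)
  }
  writeResults(do.call(rbind, trajRows),
               file.path(outDir, "organ_trajectory.csv"))
  writeResults(significanceMatrix(shiftTables),
               file.path(outDir, "significance_matrix.csv"))
  counts <- as.list(stats::setNames(
    vapply(tables, function(t) nrow(interactionData(t)), integer(1)),
    labels))
  .writeManifest(outDir, "series", paths, config, config$rngSeed, counts)
  names(comparisons) <- intervalLabels
  invisible(comparisons)
}

#' Shortlisting pipeline
#'
#' Compares two state tables, shortlists gain and potential-loss units
#' by interaction magnitude and consensus units by absolute rank change,
#' counts per-pair directional-change frequencies, selects the top-k
#' records per category, and decomposes the top pairs into single
#' molecules. Writes `shortlist.csv`, `frequencies.csv`,
#' `top_pairs.csv`, `molecules.csv` and a manifest.
#'
#' @inheritParams runCompare
#' @return Invisibly, a list with `shortlist`, `frequencies`,
#'   `top_pairs`, `molecules`.
#' @export
runShortlist <- function(refPath, cmpPath, outDir,
                         refLabel = "state1", cmpLabel = "state2",
                         config = analysisConfig()) {
  .ensureDir(outDir)
  ref <- readInteractionTable(refPath, refLabel, config$columnMap, config$sep)
  cmp <- readInteractionTable(cmpPath, cmpLabel, config$columnMap, config$sep)
  res <- compareTables(ref, cmp, config)
  shortlist <- rbind(shortlistGainPL(res, "gain"),
                     shortlistGainPL(res, "potential_loss"),
                     shortlistConsensus(res))
  interval <- paste(refLabel, cmpLabel, sep = "->")
  freqs <- pairFrequencies(classificationTable(res), interval)
  top <- do.call(rbind, lapply(
    sort(unique(freqs$category), method = "radix"),
    function(cat) topKPairs(freqs[freqs$category == cat, , drop = FALSE],
                            config$topK)))
  if (is.null(top)) top <- freqs
  molecules <- decomposeMolecules(top, config$splitComplexes)
  writeResults(shortlist, file.path(outDir, "shortlist.csv"))
  writeResults(freqs, file.path(outDir, "frequencies.csv"))
  writeResults(top, file.path(outDir, "top_pairs.csv"))
  writeResults(molecules, file.path(outDir, "molecules.csv"))
  .writeManifest(outDir, "shortlist", c(refPath, cmpPath), config,
                 config$rngSeed,
                 list(shortlist = nrow(shortlist), frequencies = nrow(freqs),
                      top_pairs = nrow(top), molecules = nrow(molecules)))
  invisible(list(shortlist = shortlist, frequencies = freqs,
                 top_pairs = top, molecules = molecules))
}

#' Permutation-test pipeline
#'
#' Compares two state tables, takes the top-k most frequent LR pairs
#' across all categorical changes, and tests whether the number of pairs
#' with multiple category labels is lower than expected under random
#' label assignment ([permutationOverlapTest()]). Writes
#' `permutation_report.json` (including the full null distribution) and
#' a manifest.
#'
#' @inheritParams runCompare
#' @param seed Integer seed for the permutation stream; defaults to the
#'   config's `rngSeed` (or 1 when unset), fanned out via
#'   [deriveSeed()].
#' @return Invisibly, the [permutationOverlapTest()] result.
#' @export
runPermTest <- function(refPath, cmpPath, outDir,
                        refLabel = "state1", cmpLabel = "state2",
                        config = analysisConfig(), seed = NULL) {
  .ensureDir(outDir)
  if (is.null(seed)) seed <- if (is.null(config$rngSeed)) 1L else config$rngSeed
  ref <- readInteractionTable(refPath, refLabel, config$columnMap, config$sep)
  cmp <- readInteractionTable(cmpPath, cmpLabel, config$columnMap, config$sep)
  res <- compareTables(ref, cmp, config)
  cl <- classificationTable(res)
  interval <- paste(refLabel, cmpLabel, sep = "->")
  observed <- topPairsAcrossCategories(cl, config$topK, interval)
  k <- min(config$topK, length(unique(pairKey(cl$ligand, cl$receptor))))
  report <- permutationOverlapTest(observed, cl, k = k,
                                   nPermutations = config$nPermutations,
                                   seed = deriveSeed(seed, "permtest"))
  report$stage_label <- interval
  writeResults(report, file.path(outDir, "permutation_report.json"))
  .writeManifest(outDir, "permtest", c(refPath, cmpPath), config, seed,
                 list(units = nrow(cl), observed_pairs = k))
  invisible(report)
}

#' Simulation pipeline
#'
#' Generates a synthetic scenario — two states by default, or a lifespan
#' series when `nStates > 2` — and writes one CSV per state in LIANA
#' consensus column naming (readable back with the default column map),
#' the planted truth as `truth.json`, and a manifest.
#'
#' @param outDir Output directory.
#' @param nStates Number of states. Default 2.
#' @param nCommTypes Communication types per state. Default 12.
#' @param seed Integer seed (required).
#' @param config An [analysisConfig()] (threshold and column naming).
#' @param ... Passed to [generateTwoState()] or
#'   [generateLifespanSeries()].
#' @return Invisibly, the generator's result list.
#' @export
runSimulate <- function(outDir, nStates = 2L, nCommTypes = 12L, seed,
                        config = analysisConfig(), ...) {
  stopifnot(!missing(seed))
  .ensureDir(outDir)
  if (nStates == 2L) {
    syn <- generateTwoState(nCommTypes = nCommTypes,
                            pThreshold = config$pThreshold, seed = seed, ...)
    tables <- list(syn$ref, syn$cmp)
    truth <- syn$truth
  } else {
    syn <- generateLifespanSeries(nStates = nStates, nCommTypes = nCommTypes,
                                  pThreshold = config$pThreshold,
                                  seed = seed, ...)
    tables <- unname(syn$tables)
    truth <- syn$truth
  }
  paths <- character(length(tables))
  for (i in seq_along(tables)) {
    paths[i] <- file.path(outDir, sprintf("state_%02d_%s.csv", i,
                                          stateLabel(tables[[i]])))
    writeInteractionTable(tables[[i]], paths[i], config$columnMap, config$sep)
  }
  writeResults(truth, file.path(outDir, "truth.json"))
  .writeManifest(outDir, "simulate", character(0), config, as.integer(seed),
                 as.list(stats::setNames(
                   vapply(tables, function(t) nrow(interactionData(t)),
                          integer(1)),
                   vapply(tables, stateLabel, character(1)))))
  invisible(syn)
}
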