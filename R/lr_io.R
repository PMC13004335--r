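# Reading, validating, filtering and writing LR inference tables.

#' Default column map for LIANA-style consensus tables
#'
#' Maps the canonical schema roles to the column names of LIANA v0.1.x
#' `rank_aggregate` consensus output. Every role is remappable, either by
#' passing a modified map to [readInteractionTable()] or via the
#' `column_map` entry of a YAML config (see [analysisConfig()]).
#'
#' @return Named character vector: role -> input column name.
#' @examples
#' defaultColumnMap()
#' @export
defaultColumnMap <- function() {
  c(source = "source",
    target = "target",
    ligand = "ligand_complex",
    receptor = "receptor_complex",
    lr_mean = "lr_means",
    pval_method_a = "cellphone_pvals",
    pval_method_b = "cellchat_pvals")
}

#' Analysis configuration
#'
#' Bundles the tunable parameters of the two-phase comparison workflow.
#' Defaults follow the analysis conventions the framework was designed
#' around: interactions are retained only when both method p-values fall
#' strictly below 0.05; molecule shortlisting uses a two-cluster split
#' (`nClusters = 2`, the only supported value); frequency ranking keeps the
#' top 20 pairs; the permutation null uses 200 replicates.
#'
#' @param pThreshold Significance threshold for the double p-value filter,
#'   in (0, 1). Default 0.05.
#' @param nClusters Number of clusters for shortlisting. Must be 2: the
#'   shortlisting rule is defined as a high/low split.
#' @param topK Number of top-frequency pairs retained. Default 20.
#' @param nPermutations Permutation replicates for the null distribution.
#'   Default 200.
#' @param rngSeed Integer seed, or `NULL` to leave the RNG untouched.
#' @param seSignConvention `"semantic"` (default; expansion positive) or
#'   `"literal"` (the printed difference of intersection ratios, opposite
#'   sign). See [seScore()].
#' @param columnMap Named character vector mapping schema roles to input
#'   column names; see [defaultColumnMap()].
#' @param sep Input field separator. Default `","`.
#' @param splitComplexes Whether single-molecule decomposition splits
#'   multi-subunit complex names on `"_"`. Default `TRUE`.
#' @param includeEmergent Whether communication types present in only one
#'   state (emergent/vanished) enter organ aggregation. Default `TRUE`.
#' @return A list of class `"AnalysisConfig"`.
#' @examples
#' analysisConfig(pThreshold = 0.01, topK = 10)
#' @export
analysisConfig <- function(pThreshold = 0.05,
                           nClusters = 2L,
                           topK = 20L,
                           nPermutations = 200L,
                           rngSeed = NULL,
                           seSignConvention = c("semantic", "literal"),
                           columnMap = defaultColumnMap(),
                           sep = ",",
                           splitComplexes = TRUE,
                           includeEmergent = TRUE) {
  seSignConvention <- match.arg(seSignConvention)
  stopifnot(is.numeric(pThreshold), length(pThreshold) == 1L,
            pThreshold > 0, pThreshold < 1)
  if (as.integer(nClusters) != 2L) {
    stop("nClusters must be 2: shortlisting is a two-cluster split",
         call. = FALSE)
  }
  stopifnot(topK >= 1L, nPermutations >= 1L)
  missingRoles <- setdiff(.RECORD_COLS, names(columnMap))
  if (length(missingRoles) > 0L) {
    stop("columnMap lacks roles: ", paste(missingRoles, collapse = ", "),
         call. = FALSE)
  }
  structure(list(pThreshold = pThreshold,
                 nClusters = 2L,
                 topK = as.integer(topK),
                 nPermutations = as.integer(nPermutations),
                 rngSeed = if (is.null(rngSeed)) NULL else as.integer(rngSeed),
                 seSignConvention = seSignConvention,
                 columnMap = columnMap,
                 sep = sep,
                 splitComplexes = isTRUE(splitComplexes),
                 includeEmergent = isTRUE(includeEmergent)),
            class = "AnalysisConfig")
}

#' Read an analysis configuration from YAML
#'
#' Fields absent from the file keep their [analysisConfig()] defaults; the
#' YAML `column_map` entry (a role -> column mapping) overrides individual
#' roles of [defaultColumnMap()].
#'
#' @param path Path to a YAML file.
#' @return An `"AnalysisConfig"` list.
#' @export
readAnalysisConfig <- function(path) {
  y <- yaml::read_yaml(path)
  cm <- defaultColumnMap()
  if (!is.null(y$column_map)) {
    over <- unlist(y$column_map)
    cm[names(over)] <- over
  }
  pick <- function(field, default) if (is.null(y[[field]])) default else y[[field]]
  analysisConfig(
    pThreshold = pick("p_threshold", 0.05),
    nClusters = pick("n_clusters", 2L),
    topK = pick("top_k", 20L),
    nPermutations = pick("n_permutations", 200L),
    rngSeed = y$rng_seed,
    seSignConvention = pick("se_sign_convention", "semantic"),
    columnMap = cm,
    sep = pick("sep", ","),
    splitComplexes = pick("split_complexes", TRUE),
    includeEmergent = pick("include_emergent", TRUE)
  )
}

#' Construct an InteractionTable from a data.frame
#'
#' Low-level constructor used by [readInteractionTable()] and the
#' synthetic-data generator; the input must already use the canonical
#' column names. Duplicate (source, target, ligand, receptor) keys are
#' collapsed deterministically: smallest `pval_method_a`, then smallest
#' `pval_method_b`, then first occurrence; collapses are reported via
#' `message()`.
#'
#' @param df `data.frame` with columns `source`, `target`, `ligand`,
#'   `receptor`, `lr_mean`, `pval_method_a`, `pval_method_b`.
#' @param stateLabel Character scalar naming the state.
#' @return An [InteractionTable].
#' @export
interactionTable <- function(df, stateLabel) {
  missing <- setdiff(.RECORD_COLS, names(df))
  if (length(missing) > 0L) {
    stop("schema error: missing role(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df <- df[, .RECORD_COLS, drop = FALSE]
  for (col in c("source", "target", "ligand", "receptor")) {
    df[[col]] <- as.character(df[[col]])
  }
  assertNoSep(df$ligand, .PAIR_SEP, "ligand")
  assertNoSep(df$receptor, .PAIR_SEP, "receptor")
  assertNoSep(df$source, .COMM_SEP, "source cell type")
  assertNoSep(df$target, .COMM_SEP, "target cell type")
  for (col in c("lr_mean", "pval_method_a", "pval_method_b")) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))[1]
      stop(sprintf("unparseable numeric in column '%s' (row %d)", col,
                   if (is.na(bad)) NA_integer_ else bad), call. = FALSE)
    }
  }
  key <- paste(df$source, df$target, df$ligand, df$receptor, sep = "\r")
  if (anyDuplicated(key)) {
    ord <- radixOrder(key, df$pval_method_a, df$pval_method_b,
                      seq_len(nrow(df)))
    df <- df[ord, , drop = FALSE]
    keep <- !duplicated(key[ord])
    message(sprintf("collapsed %d duplicate LR key(s) in state '%s' (kept min pval_method_a)",
                    sum(!keep), stateLabel))
    df <- df[keep, , drop = FALSE]
  }
  rownames(df) <- NULL
  new("InteractionTable", data = df, stateLabel = as.character(stateLabel))
}

#' Read a ligand-receptor inference table
#'
#' Parses a delimited text file of per-interaction inference results (one
#' row per source/target/ligand/receptor combination) into an
#' [InteractionTable], mapping input columns onto the canonical schema
#' roles. A missing mapped column raises a schema error naming the role; a
#' non-numeric value in a numeric role raises a row-level error with the
#' row number. Duplicate keys are collapsed (see [interactionTable()]).
#'
#' @param path Path to a delimited text file with one header row (UTF-8).
#' @param stateLabel State label to attach (e.g. `"18m"`).
#' @param columnMap Role -> column-name mapping; see [defaultColumnMap()].
#' @param sep Field separator. Default `","`.
#' @return An [InteractionTable].
#' @examples
#' tmp <- tempfile(fileext = ".csv")
#' df <- data.frame(source = "EC", target = "EC",
#'                  ligand_complex = "APP", receptor_complex = "CD74",
#'                  lr_means = 1.2, cellphone_pvals = 0.01,
#'                  cellchat_pvals = 0.02)
#' write.csv(df, tmp, row.names = FALSE)
#' readInteractionTable(tmp, stateLabel = "1m")
#' @export
readInteractionTable <- function(path, stateLabel,
                                 columnMap = defaultColumnMap(),
                                 sep = ",") {
  if (!file.exists(path)) {
    stop(sprintf("input file not found: %s", path), call. = FALSE)
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           quote = "\"", comment.char = "",
                           colClasses = "character", encoding = "UTF-8")
  missingRoles <- names(columnMap)[!columnMap %in% names(raw)]
  if (length(missingRoles) > 0L) {
    stop(sprintf("schema error: input lacks column(s) for role(s): %s (expected column(s): %s)",
                 paste(missingRoles, collapse = ", "),
                 paste(columnMap[missingRoles], collapse = ", ")),
         call. = FALSE)
  }
  df <- data.frame(raw[, columnMap[.RECORD_COLS], drop = FALSE],
                   stringsAsFactors = FALSE)
  names(df) <- .RECORD_COLS
  for (col in c("lr_mean", "pval_method_a", "pval_method_b")) {
    num <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(num) & !is.na(df[[col]]) & nzchar(df[[col]]))
    if (length(bad) > 0L) {
      stop(sprintf("unparseable numeric '%s' in column '%s' (file row %d)",
                   df[[col]][bad[1]], columnMap[[col]], bad[1] + 1L),
           call. = FALSE)
    }
    df[[col]] <- num
  }
  interactionTable(df, stateLabel)
}

#' Write an InteractionTable as a delimited file
#'
#' Inverse of [readInteractionTable()]: canonical roles are renamed to the
#' external column names of `columnMap`, so the default writes tables in
#' LIANA consensus naming that [readInteractionTable()] re-reads with the
#' default map.
#'
#' @param x An [InteractionTable].
#' @param path Output path.
#' @param columnMap Role -> column-name mapping used for the header.
#' @param sep Field separator.
#' @return Invisibly, `path`.
#' @export
writeInteractionTable <- function(x, path, columnMap = defaultColumnMap(),
                                  sep = ",") {
  stopifnot(is(x, "InteractionTable"))
  df <- x@data
  names(df) <- unname(columnMap[names(df)])
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Double p-value filter
#'
#' Retains only interactions supported by both inference methods:
#' `pval_method_a < threshold` AND `pval_method_b < threshold`, with strict
#' inequality, so boundary values are dropped. The filter is idempotent
#' and its output is a subset of its input; it is applied independently
#' per state table.
#'
#' @param x An [InteractionTable].
#' @param threshold Significance threshold in (0, 1). Default 0.05.
#' @return A filtered [InteractionTable] (possibly with zero rows).
#' @examples
#' df <- data.frame(source = "A", target = "B", ligand = "L1",
#'                  receptor = "R1", lr_mean = 1,
#'                  pval_method_a = c(0.01), pval_method_b = c(0.04))
#' doublePvalueFilter(interactionTable(df, "1m"), 0.05)
#' @export
doublePvalueFilter <- function(x, threshold = 0.05) {
  stopifnot(is(x, "InteractionTable"),
            is.numeric(threshold), length(threshold) == 1L,
            threshold > 0, threshold < 1)
  df <- x@data
  keep <- df$pval_method_a < threshold & df$pval_method_b < threshold
  out <- df[keep, , drop = FALSE]
  rownames(out) <- NULL
  initialize(x, data = out)
}

#' Write a result table to CSV or JSON
#'
#' CSV output is plain (no quoting of numerics, no row names) and
#' round-trip stable: reading it back reproduces the table field for
#' field. JSON output is an array of row objects.
#'
#' @param x A `data.frame` (any result table) or a list (e.g. an organ
#'   summary), written as a single JSON object in the latter case.
#' @param path Output path.
#' @param format `"csv"` or `"json"`. Defaults from the file extension.
#' @return Invisibly, `path`.
#' @export
writeResults <- function(x, path, format = c("csv", "json")) {
  if (missing(format)) {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
  } else {
    if (!is.data.frame(x)) {
      stop("CSV output requires a data.frame", call. = FALSE)
    }
    utils::write.table(x, path, sep = ",", row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
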