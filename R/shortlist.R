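# Molecule shortlisting: exact 1-D two-cluster partitioning, category
# shortlists, frequency ranking, top-k selection, molecule decomposition.

#' Exact two-cluster partition of 1-D values
#'
#' Splits a numeric vector into two groups minimising the within-group
#' sum of squared deviations — the exact optimum of k-means with k = 2 on
#' a line, computed by scanning all split points of the sorted values
#' rather than by iterative refinement. The group with the larger mean is
#' returned as `high`. With a single value, or all values identical,
#' every index is returned as `high` with `degenerate = TRUE`.
#'
#' @param values Non-empty numeric vector (finite).
#' @return List with integer index vectors `high` and `low` (indices into
#'   `values`) and a logical `degenerate` flag.
#' @examples
#' twoClusterPartition(c(1, 2, 10, 11))$high  # indices of 10 and 11
#' @export
twoClusterPartition <- function(values) {
  n <- length(values)
  if (n == 0L) stop("cannot partition an empty vector", call. = FALSE)
  stopifnot(is.numeric(values), all(is.finite(values)))
  if (n == 1L || length(unique(values)) == 1L) {
    return(list(high = seq_len(n), low = integer(0), degenerate = TRUE))
  }
  ord <- order(values, method = "radix")
  x <- values[ord]
  cs <- cumsum(x)
  cs2 <- cumsum(x^2)
  total <- cs[n]
  total2 <- cs2[n]
  # within-SS of {x[1..i]} + {x[(i+1)..n]} for every split i
  i <- seq_len(n - 1L)
  ssLow <- cs2[i] - cs[i]^2 / i
  ssHigh <- (total2 - cs2[i]) - (total - cs[i])^2 / (n - i)
  ss <- ssLow + ssHigh
  best <- which.min(ss)  # first minimal split on ties: deterministic
  low <- ord[seq_len(best)]
  high <- ord[seq.int(best + 1L, n)]
  # sorted ascending, so the upper group always has the larger mean
  list(high = sort(high), low = sort(low), degenerate = FALSE)
}

#' Shortlist gain or potential-loss units by interaction magnitude
#'
#' For the gain and potential-loss categories, shortlisting is based on
#' the interaction magnitude `lr_mean`, taken from the state in which the
#' pair is present (gain: comparator; potential loss: reference). Within
#' each communication type (default; `perCommType = FALSE` pools the
#' whole category), [twoClusterPartition()] splits the magnitudes and the
#' higher-mean cluster is selected.
#'
#' @param comparison A magnitude-annotated [CCCComparison] (from
#'   [compareTables()]).
#' @param category `"gain"` or `"potential_loss"`.
#' @param perCommType Partition within each communication type (default)
#'   or pooled across the category.
#' @return `data.frame` with `source`, `target`, `ligand`, `receptor`,
#'   `category`, `score` (the magnitude used), `selected`, `degenerate`.
#'   Empty category gives zero rows.
#' @export
shortlistGainPL <- function(comparison, category = c("gain", "potential_loss"),
                            perCommType = TRUE) {
  category <- match.arg(category)
  stopifnot(is(comparison, "CCCComparison"))
  cl <- comparison@classification
  if (!all(c("lr_mean_ref", "lr_mean_cmp") %in% names(cl))) {
    stop("classification lacks lr_mean annotation; build via compareTables()",
         call. = FALSE)
  }
  sub <- cl[cl$category == category, , drop = FALSE]
  scoreCol <- if (category == "gain") "lr_mean_cmp" else "lr_mean_ref"
  sub$score <- sub[[scoreCol]]
  .runPartition(sub, perCommType)
}

#' Shortlist consensus units by rank change
#'
#' Consensus pairs persist in both states, so they are prioritised by
#' rank dynamics rather than magnitude: within each communication type
#' the consensus pairs are ranked by `lr_mean` separately in each state
#' (rank 1 = largest; ties receive average ranks), the score is the
#' absolute rank change, and selection takes the high-score cluster of
#' [twoClusterPartition()].
#'
#' @inheritParams shortlistGainPL
#' @param perCommType Partition scores within each communication type
#'   (default) or pooled (ranks are always computed within type).
#' @return `data.frame` as in [shortlistGainPL()] with `score` = absolute
#'   rank change.
#' @export
shortlistConsensus <- function(comparison, perCommType = TRUE) {
  stopifnot(is(comparison, "CCCComparison"))
  cl <- comparison@classification
  if (!all(c("lr_mean_ref", "lr_mean_cmp") %in% names(cl))) {
    stop("classification lacks lr_mean annotation; build via compareTables()",
         call. = FALSE)
  }
  sub <- cl[cl$category == "consensus", , drop = FALSE]
  if (nrow(sub) > 0L) {
    key <- commKey(sub$source, sub$target)
    sub$score <- unsplit(lapply(split(seq_len(nrow(sub)), key), function(idx) {
      rRef <- rank(-sub$lr_mean_ref[idx], ties.method = "average")
      rCmp <- rank(-sub$lr_mean_cmp[idx], ties.method = "average")
      abs(rRef - rCmp)
    }), key)
  } else {
    sub$score <- numeric(0)
  }
  .runPartition(sub, perCommType)
}

# Shared partition-and-flag step for the shortlist operations.
.runPartition <- function(sub, perCommType) {
  out <- sub[, c("source", "target", "ligand", "receptor", "category"),
             drop = FALSE]
  out$score <- sub$score
  out$selected <- logical(nrow(sub))
  out$degenerate <- logical(nrow(sub))
  if (nrow(sub) > 0L) {
    groups <- if (perCommType) {
      split(seq_len(nrow(sub)), commKey(sub$source, sub$target))
    } else {
      list(seq_len(nrow(sub)))
    }
    for (idx in groups) {
      part <- twoClusterPartition(out$score[idx])
      out$selected[idx[part$high]] <- TRUE
      out$degenerate[idx] <- part$degenerate
    }
  }
  ord <- radixOrder(out$source, out$target, out$category, out$ligand,
                    out$receptor)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Frequency of directional changes per LR pair
#'
#' For one organ and one stage interval, counts for every (LR pair,
#' category) combination the number of distinct communication types in
#' which that pair exhibits that categorical change. A pair gaining in
#' two communication types has frequency 2 in the gain category for that
#' interval; the same pair holding different categories in different
#' types yields separate records.
#'
#' @param classification Classification long table (`source`, `target`,
#'   `ligand`, `receptor`, `category`) for one stage interval, e.g.
#'   [classificationTable()] output.
#' @param intervalLabel Label for the interval (e.g. `"1m->3m"`).
#' @return `data.frame` with `ligand`, `receptor`, `stage_interval`,
#'   `category`, `frequency`, deterministically sorted.
#' @export
pairFrequencies <- function(classification, intervalLabel = "") {
  stopifnot(all(c("source", "target", "ligand", "receptor", "category")
                %in% names(classification)))
  if (nrow(classification) == 0L) {
    return(data.frame(ligand = character(0), receptor = character(0),
                      stage_interval = character(0), category = character(0),
                      frequency = integer(0), stringsAsFactors = FALSE))
  }
  agg <- stats::aggregate(
    list(frequency = commKey(classification$source, classification$target)),
    by = list(ligand = classification$ligand,
              receptor = classification$receptor,
              category = classification$category),
    FUN = function(v) length(unique(v)))
  out <- data.frame(ligand = agg$ligand, receptor = agg$receptor,
                    stage_interval = intervalLabel, category = agg$category,
                    frequency = as.integer(agg$frequency),
                    stringsAsFactors = FALSE)
  ord <- radixOrder(-out$frequency, out$category, out$ligand, out$receptor)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Top-k frequency records
#'
#' Deterministic top-k selection: records are sorted by frequency
#' (descending), then category, ligand and receptor (ascending, C
#' locale), and the first `k` are kept; with fewer than `k` records all
#' are returned. Idempotent and invariant to input row order.
#'
#' @param freqs A [pairFrequencies()] table (or any `data.frame` with
#'   `frequency`, `category`, `ligand`, `receptor`).
#' @param k Number of records to keep. Default 20.
#' @return The selected rows, in sorted order.
#' @export
topKPairs <- function(freqs, k = 20L) {
  stopifnot(k >= 1L,
            all(c("frequency", "category", "ligand", "receptor")
                %in% names(freqs)))
  ord <- radixOrder(-freqs$frequency, freqs$category, freqs$ligand,
                    freqs$receptor)
  out <- freqs[ord, , drop = FALSE]
  out <- utils::head(out, k)
  rownames(out) <- NULL
  out
}

#' Most frequent pairs across all categories, with their labels
#'
#' Identifies the `k` most frequent distinct LR pairs of a stage interval
#' across all categorical changes (total frequency summed over
#' categories; ties broken by ligand then receptor) and returns their
#' per-category label records — the observed input of
#' [permutationOverlapTest()].
#'
#' @inheritParams pairFrequencies
#' @param k Number of distinct pairs. Default 20.
#' @return `data.frame` with `ligand`, `receptor`, `category`,
#'   `frequency` (one row per retained pair-category assignment).
#' @export
topPairsAcrossCategories <- function(classification, k = 20L,
                                     intervalLabel = "") {
  freqs <- pairFrequencies(classification, intervalLabel)
  if (nrow(freqs) == 0L) return(freqs[, c("ligand", "receptor", "category",
                                          "frequency")])
  key <- pairKey(freqs$ligand, freqs$receptor)
  tot <- tapply(freqs$frequency, key, sum)
  keys <- names(tot)
  ord <- radixOrder(-as.integer(tot), keys)
  keep <- keys[utils::head(ord, k)]
  out <- freqs[key %in% keep, c("ligand", "receptor", "category",
                                "frequency"), drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Decompose top LR pairs into single molecules
#'
#' Transforms the base unit from LR pairs to individual molecules: every
#' pair contributes its ligand and its receptor symbol, with
#' multi-subunit complex names optionally split on the `"_"` subunit
#' separator (LIANA convention), and occurrences are accumulated per
#' (molecule, stage interval, category), with a ligand/receptor role
#' breakdown. Without complexes and without splitting, total occurrence
#' mass is exactly twice the number of input pairs.
#'
#' @param topPairs `data.frame` with columns `ligand`, `receptor`,
#'   `category` and optionally `stage_interval`.
#' @param splitComplexes Split complex names on `"_"`. Default `TRUE`.
#' @return `data.frame` with `molecule`, `stage_interval`, `category`,
#'   `n_as_ligand`, `n_as_receptor`, `occurrence_count`.
#' @export
decomposeMolecules <- function(topPairs, splitComplexes = TRUE) {
  stopifnot(all(c("ligand", "receptor", "category") %in% names(topPairs)))
  empty <- data.frame(molecule = character(0), stage_interval = character(0),
                      category = character(0), n_as_ligand = integer(0),
                      n_as_receptor = integer(0), occurrence_count = integer(0),
                      stringsAsFactors = FALSE)
  if (nrow(topPairs) == 0L) return(empty)
  interval <- if ("stage_interval" %in% names(topPairs)) {
    topPairs$stage_interval
  } else {
    rep("", nrow(topPairs))
  }
  expand <- function(symbols) {
    if (splitComplexes) strsplit(symbols, .COMPLEX_SEP, fixed = TRUE)
    else as.list(symbols)
  }
  rows <- list()
  for (role in c("ligand", "receptor")) {
    mols <- expand(topPairs[[role]])
    nmol <- lengths(mols)
    rows[[role]] <- data.frame(
      molecule = unlist(mols),
      stage_interval = rep(interval, nmol),
      category = rep(topPairs$category, nmol),
      role = role, stringsAsFactors = FALSE)
  }
  long <- rbind(rows$ligand, rows$receptor)
  agg <- stats::aggregate(
    list(n = rep(1L, nrow(long))),
    by = long[, c("molecule", "stage_interval", "category", "role")],
    FUN = sum)
  wide <- stats::reshape(agg, idvar = c("molecule", "stage_interval",
                                        "category"),
                         timevar = "role", direction = "wide")
  names(wide)[names(wide) == "n.ligand"] <- "n_as_ligand"
  names(wide)[names(wide) == "n.receptor"] <- "n_as_receptor"
  for (col in c("n_as_ligand", "n_as_receptor")) {
    if (!col %in% names(wide)) wide[[col]] <- NA_integer_
    wide[[col]][is.na(wide[[col]])] <- 0L
  }
  wide$occurrence_count <- wide$n_as_ligand + wide$n_as_receptor
  wide <- wide[, c("molecule", "stage_interval", "category", "n_as_ligand",
                   "n_as_receptor", "occurrence_count")]
  ord <- radixOrder(-wide$occurrence_count, wide$molecule, wide$category)
  wide <- wide[ord, , drop = FALSE]
  rownames(wide) <- NULL
  wide
}
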