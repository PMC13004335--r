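# Consensus-shift testing and the permutation null for non-stochastic
# categorical change.

#' Consensus-shift test for one communication type
#'
#' Tests whether the interaction magnitudes (`lr_mean`) of the consensus
#' LR pairs of one communication type shift between states, using the
#' two-sided Wilcoxon signed-rank test on the paired differences
#' (comparator minus reference). Zero differences are dropped before
#' ranking (classic signed-rank handling); the exact null distribution is
#' used for up to `exactMax` nonzero differences (falling back to the
#' normal approximation when ties make the exact distribution
#' unavailable), and the normal approximation with continuity correction
#' otherwise. With no nonzero difference the test is flagged untestable
#' and no p-value is produced.
#'
#' @param refValues,cmpValues Numeric vectors of per-pair magnitudes,
#'   matched by pair identity (same length, same order).
#' @param threshold Significance threshold. Default 0.05.
#' @param exactMax Largest number of nonzero differences for which the
#'   exact distribution is used. Default 25.
#' @return List with `n_pairs` (nonzero differences ranked), `statistic`
#'   (signed-rank V), `p_value`, `significant` (`p_value < threshold`),
#'   `testable`.
#' @examples
#' consensusShiftTest(c(1, 2, 3, 4, 5, 6), c(2, 4, 6, 8, 10, 12))
#' @export
consensusShiftTest <- function(refValues, cmpValues, threshold = 0.05,
                               exactMax = 25L) {
  stopifnot(length(refValues) == length(cmpValues))
  d <- cmpValues - refValues
  d <- d[d != 0]
  n <- length(d)
  if (n < 1L) {
    return(list(n_pairs = 0L, statistic = NA_real_, p_value = NA_real_,
                significant = NA, testable = FALSE))
  }
  ht <- suppressWarnings(
    stats::wilcox.test(d, mu = 0, alternative = "two.sided",
                       exact = n <= exactMax, correct = TRUE)
  )
  list(n_pairs = n, statistic = unname(ht$statistic),
       p_value = ht$p.value, significant = ht$p.value < threshold,
       testable = TRUE)
}

#' Consensus-shift tests across all communication types
#'
#' Applies [consensusShiftTest()] to the consensus pairs of every
#' communication type of a magnitude-annotated [CCCComparison] (from
#' [compareTables()]). Multiple testing across communication types is not
#' corrected by default, mirroring conventional single-threshold use with
#' contextual interpretation; `adjust = "BH"` adds a Benjamini-Hochberg
#' adjusted p-value column and bases `significant` on it.
#'
#' @param comparison A [CCCComparison] with `lr_mean_ref`/`lr_mean_cmp`
#'   columns in its classification table.
#' @param threshold Significance threshold. Default 0.05.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return `data.frame` with one row per communication type holding
#'   consensus pairs: `source`, `target`, `n_pairs`, `statistic`,
#'   `p_value`, `significant`, `testable` (plus `p_adjusted` for BH).
#' @export
consensusShiftAll <- function(comparison, threshold = 0.05,
                              adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  stopifnot(is(comparison, "CCCComparison"))
  cl <- comparison@classification
  if (!all(c("lr_mean_ref", "lr_mean_cmp") %in% names(cl))) {
    stop("classification lacks lr_mean annotation; build via compareTables()",
         call. = FALSE)
  }
  cons <- cl[cl$category == "consensus", , drop = FALSE]
  keys <- unique(commKey(cons$source, cons$target))
  keys <- sort(keys, method = "radix")
  rows <- lapply(keys, function(k) {
    st <- splitCommKey(k)
    sub <- cons[cons$source == st$source & cons$target == st$target, ,
                drop = FALSE]
    r <- consensusShiftTest(sub$lr_mean_ref, sub$lr_mean_cmp, threshold)
    data.frame(source = st$source, target = st$target, n_pairs = r$n_pairs,
               statistic = r$statistic, p_value = r$p_value,
               significant = r$significant, testable = r$testable,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(source = character(0), target = character(0),
                      n_pairs = integer(0), statistic = numeric(0),
                      p_value = numeric(0), significant = logical(0),
                      testable = logical(0), stringsAsFactors = FALSE)
  }
  if (adjust == "BH" && nrow(out) > 0L) {
    out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
    out$significant <- ifelse(is.na(out$p_adjusted), NA,
                              out$p_adjusted < threshold)
  }
  rownames(out) <- NULL
  out
}

#' Binary significance matrix across intervals
#'
#' Assembles per-interval consensus-shift results into a wide 0/1 matrix
#' (communication types in rows, stage intervals in columns; 1 =
#' significant shift, NA = untestable), the tabular form of the classic
#' black/white significance grid.
#'
#' @param shiftTables Named list of [consensusShiftAll()] results; names
#'   are interval labels (e.g. `"1m->3m"`).
#' @return `data.frame` with `source`, `target` and one 0/1 column per
#'   interval.
#' @export
significanceMatrix <- function(shiftTables) {
  stopifnot(is.list(shiftTables), length(shiftTables) > 0L,
            !is.null(names(shiftTables)))
  keys <- sort(unique(unlist(lapply(shiftTables, function(df) {
    commKey(df$source, df$target)
  }))), method = "radix")
  out <- splitCommKey(keys)
  for (nm in names(shiftTables)) {
    df <- shiftTables[[nm]]
    v <- rep(NA_integer_, length(keys))
    idx <- match(commKey(df$source, df$target), keys)
    v[idx] <- ifelse(is.na(df$significant), NA_integer_,
                     as.integer(df$significant))
    out[[nm]] <- v
  }
  out
}

#' Permutation test for non-stochastic categorical change
#'
#' Tests whether the categorical changes (gain / consensus / potential
#' loss) of the most frequent LR pairs are distributed non-randomly
#' across categories. Under a stochastic model the three labels would be
#' spread over each pair's occurrences, so many top pairs would carry
#' multiple labels; the observed statistic is the number of distinct
#' top-k pairs carrying two or more distinct category labels
#' (`statistic = "pairs"`, default; `"occurrences"` counts the total
#' number of extra distinct labels beyond the first instead).
#'
#' Each permutation draws `k` distinct pairs uniformly without
#' replacement from the universe of pairs, assigns every occurrence of a
#' drawn pair (its rows in `universe`) a label uniformly at random from
#' the three categories, and recomputes the statistic over the 200 (or
#' `nPermutations`) replicates. The p-value uses the add-one estimator
#' \eqn{(1 + \#\{null \le obs\}) / (n + 1)} on the lower tail by default
#' (non-stochastic change means the observed overlap is LOW), so it is
#' never exactly zero.
#'
#' @param observedTop `data.frame` with columns `ligand`, `receptor`,
#'   `category`: the category labels of the observed top-k pairs (one
#'   row per pair-category assignment, e.g. the classification rows of
#'   those pairs).
#' @param universe `data.frame` with columns `ligand`, `receptor`,
#'   `category`: all pair-category assignments of the stage (one row per
#'   communication-type occurrence).
#' @param k Number of pairs drawn per permutation; must not exceed the
#'   number of distinct pairs in `universe`. Default 20.
#' @param nPermutations Number of replicates. Default 200.
#' @param seed Integer seed; the null distribution is bit-reproducible
#'   given the seed.
#' @param tail `"lower"` (default) or `"upper"`.
#' @param statistic `"pairs"` or `"occurrences"`.
#' @return List with `observed_overlap`, `null_distribution` (integer
#'   vector of length `nPermutations`), `cutoff_05` (the 5% tail cutoff
#'   of the null on the configured tail), `p_value`, `n_permutations`,
#'   `rng_seed`, `tail`, `statistic`.
#' @export
permutationOverlapTest <- function(observedTop, universe, k = 20L,
                                   nPermutations = 200L, seed = 1L,
                                   tail = c("lower", "upper"),
                                   statistic = c("pairs", "occurrences")) {
  tail <- match.arg(tail)
  statistic <- match.arg(statistic)
  stopifnot(all(c("ligand", "receptor", "category") %in% names(observedTop)),
            all(c("ligand", "receptor", "category") %in% names(universe)),
            nPermutations >= 1L)
  categories <- c("consensus", "gain", "potential_loss")

  overlapStat <- function(pairs, labels) {
    nlab <- tapply(labels, pairs, function(v) length(unique(v)))
    if (statistic == "pairs") sum(nlab >= 2L) else sum(nlab - 1L)
  }

  obsPairs <- pairKey(observedTop$ligand, observedTop$receptor)
  observed <- if (length(obsPairs) == 0L) 0L else
    as.integer(overlapStat(obsPairs, observedTop$category))

  uniPairs <- pairKey(universe$ligand, universe$receptor)
  # occurrence multiplicities per distinct pair, in stable (C-locale) order
  # so the null is invariant to the row ordering of `universe`
  occ <- table(uniPairs)
  occ <- occ[sort(names(occ), method = "radix")]
  nDistinct <- length(occ)
  if (k > nDistinct) {
    stop(sprintf("k (%d) exceeds the number of distinct pairs in the universe (%d)",
                 k, nDistinct), call. = FALSE)
  }
  nullDist <- withSeed(as.integer(seed), {
    vapply(seq_len(nPermutations), function(i) {
      drawn <- sample.int(nDistinct, k, replace = FALSE)
      m <- as.integer(occ[drawn])
      labs <- sample(categories, sum(m), replace = TRUE)
      as.integer(overlapStat(rep(seq_len(k), m), labs))
    }, integer(1))
  })
  pval <- if (tail == "lower") {
    (1 + sum(nullDist <= observed)) / (nPermutations + 1)
  } else {
    (1 + sum(nullDist >= observed)) / (nPermutations + 1)
  }
  cutoff <- unname(stats::quantile(nullDist,
                                   if (tail == "lower") 0.05 else 0.95,
                                   type = 1))
  list(observed_overlap = observed, null_distribution = nullDist,
       cutoff_05 = cutoff, p_value = pval,
       n_permutations = as.integer(nPermutations),
       rng_seed = as.integer(seed), tail = tail, statistic = statistic)
}
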