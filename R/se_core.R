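# SE scoring: per-type LR sets, intersection ratios, SE scores,
# consensus/gain/potential-loss classification, organ aggregation.

#' Build per-communication-type LR sets for one state
#'
#' Materialises \eqn{L_t(s)}: for every communication type
#' \eqn{t(A \to B)} in the (already filtered) table, the set of LR pairs
#' inferred in this state. Communication types are directed source ->
#' target; autocrine types (source equal to target) are ordinary members.
#'
#' @param x A filtered [InteractionTable].
#' @param stateIndex `1L` (reference) or `2L` (comparator).
#' @return A [StateSet].
#' @examples
#' df <- data.frame(source = c("EC", "EC"), target = c("EC", "FB"),
#'                  ligand = c("APP", "FBLN1"),
#'                  receptor = c("CD74", "ITGB1"), lr_mean = c(1, 2),
#'                  pval_method_a = 0.01, pval_method_b = 0.01)
#' buildStateSet(interactionTable(df, "1m"), 1L)
#' @export
buildStateSet <- function(x, stateIndex) {
  stopifnot(is(x, "InteractionTable"))
  stateIndex <- as.integer(stateIndex)
  df <- x@data
  if (nrow(df) == 0L) {
    return(new("StateSet", stateLabel = x@stateLabel,
               stateIndex = stateIndex, sets = list()))
  }
  ck <- commKey(df$source, df$target)
  pk <- pairKey(df$ligand, df$receptor)
  sets <- split(pk, ck)
  # unique() is a no-op given InteractionTable key uniqueness, kept as a
  # guard for the class invariant
  sets <- lapply(sets, function(v) sort(unique(v), method = "radix"))
  sets <- sets[radixOrder(names(sets))]
  new("StateSet", stateLabel = x@stateLabel, stateIndex = stateIndex,
      sets = sets)
}

#' Intersection ratios between two non-empty LR sets
#'
#' For reference set \eqn{L(1)} and comparator set \eqn{L(2)} with
#' intersection \eqn{I}, the ratios \eqn{r(1) = |I| / |L(1)|} (proportion
#' of reference interactions retained) and \eqn{r(2) = |I| / |L(2)|}
#' (proportion of comparator interactions already present) are each the
#' proportion of conserved interactions relative to one state.
#'
#' @param lRef,lCmp Character vectors of LR pair keys (duplicate-free),
#'   both non-empty; an empty set is a precondition error (callers route
#'   single-state types to emergent/vanished handling in [seScore()]).
#' @return List with `r_ref`, `r_cmp`, `n_intersection`.
#' @examples
#' intersectionRatios(c("a", "b"), c("a", "b", "c", "d"))
#' @export
intersectionRatios <- function(lRef, lCmp) {
  if (length(lRef) == 0L || length(lCmp) == 0L) {
    stop("intersection ratios are undefined for an empty LR set",
         call. = FALSE)
  }
  nI <- length(intersect(lRef, lCmp))
  list(r_ref = nI / length(lRef), r_cmp = nI / length(lCmp),
       n_intersection = nI)
}

#' SE score for one communication type
#'
#' The Shrink/Expand (SE) score is a bounded directional set-similarity
#' metric comparing the LR sets of two states. Under the default
#' `"semantic"` convention
#' \deqn{SE = |I| (1/|L(1)| - 1/|L(2)|) = r(1) - r(2),}
#' so a comparator that strictly gains pairs scores positive (net
#' expansion) and one that strictly loses pairs scores negative (net
#' shrinkage); `"literal"` returns \eqn{r(2) - r(1)}, the same quantity
#' with opposite sign, retained for audit. \eqn{|SE| \le 1} always, and
#' SE = 0 reflects a net balance of gains and losses — which does not
#' imply the network is unchanged (complete turnover between equal-sized
#' sets also balances).
#'
#' A communication type present in only one state has no defined ratio on
#' the empty side; it is reported as `emergent` (reference empty,
#' se = +1) or `vanished` (comparator empty, se = -1) under the semantic
#' convention (signs negated under literal, preserving antisymmetry).
#' Both sets empty is an error.
#'
#' @inheritParams intersectionRatios
#' @param convention `"semantic"` (default) or `"literal"`.
#' @return List with `n_ref`, `n_cmp`, `n_intersection`, `r_ref`,
#'   `r_cmp` (NA on an empty side), `se`, `direction` (one of
#'   `"expanding"`, `"shrinking"`, `"stable"`, `"emergent"`,
#'   `"vanished"`).
#' @examples
#' seScore(c("a", "b"), c("a", "b", "c", "d"))          # se = +0.5
#' seScore(c("a", "b", "c", "d"), c("a", "b"))          # se = -0.5
#' seScore(c("a", "b"), c("a", "b"))                    # se = 0
#' @export
seScore <- function(lRef, lCmp, convention = c("semantic", "literal")) {
  convention <- match.arg(convention)
  nRef <- length(lRef)
  nCmp <- length(lCmp)
  if (nRef == 0L && nCmp == 0L) {
    stop("SE score is undefined when both LR sets are empty", call. = FALSE)
  }
  sgn <- if (convention == "semantic") 1 else -1
  if (nRef == 0L || nCmp == 0L) {
    emergent <- nRef == 0L
    return(list(n_ref = nRef, n_cmp = nCmp, n_intersection = 0L,
                r_ref = if (emergent) NA_real_ else 0,
                r_cmp = if (emergent) 0 else NA_real_,
                se = sgn * (if (emergent) 1 else -1),
                direction = if (emergent) "emergent" else "vanished"))
  }
  ir <- intersectionRatios(lRef, lCmp)
  se <- sgn * (ir$r_ref - ir$r_cmp)
  direction <- if (se > 0) "expanding" else if (se < 0) "shrinking" else "stable"
  list(n_ref = nRef, n_cmp = nCmp, n_intersection = ir$n_intersection,
       r_ref = ir$r_ref, r_cmp = ir$r_cmp, se = se, direction = direction)
}

#' Classify CCC inference units of one communication type
#'
#' Partitions the union of the two states' LR sets into Consensus
#' (\eqn{C = L(1) \cap L(2)}, present in both states), Gain
#' (\eqn{G = L(2) \setminus L(1)}, newly appearing in the comparator) and
#' Potential Loss (\eqn{PL = L(1) \setminus L(2)}, putatively lost), and
#' computes the gain ratio \eqn{GR = |G| / |L(2)|} and potential-loss
#' ratio \eqn{PLR = |PL| / |L(1)|}. GR = 1 means the comparator's
#' communication content is completely new; PLR = 0 means all reference
#' communication was preserved. A ratio with an empty denominator state is
#' reported as `NA`.
#'
#' @inheritParams intersectionRatios
#' @return List with character vectors `consensus`, `gain`,
#'   `potential_loss` (sorted, C locale) and numerics `gain_ratio`,
#'   `potential_loss_ratio`.
#' @examples
#' classifyUnits(c("a", "b"), c("b", "c"))
#' @export
classifyUnits <- function(lRef, lCmp) {
  if (length(lRef) == 0L && length(lCmp) == 0L) {
    stop("classification is undefined when both LR sets are empty",
         call. = FALSE)
  }
  cons <- sort(intersect(lRef, lCmp), method = "radix")
  gain <- sort(setdiff(lCmp, lRef), method = "radix")
  pl <- sort(setdiff(lRef, lCmp), method = "radix")
  list(consensus = cons, gain = gain, potential_loss = pl,
       gain_ratio = if (length(lCmp) == 0L) NA_real_ else
         length(gain) / length(lCmp),
       potential_loss_ratio = if (length(lRef) == 0L) NA_real_ else
         length(pl) / length(lRef))
}

#' Compare two communication states
#'
#' Runs SE scoring and consensus/gain/potential-loss classification for
#' every communication type present in either state (types absent from
#' both never appear). The reference must carry state index 1 and the
#' comparator state index 2.
#'
#' @param ref,cmp [StateSet] objects for the reference and comparator.
#' @param convention SE sign convention, `"semantic"` or `"literal"`.
#' @return A [CCCComparison]. Its SE table carries one row per
#'   communication type with `gain_ratio`/`potential_loss_ratio`
#'   appended; its classification table one row per CCC inference unit.
#' @seealso [compareTables()] for the file-level convenience wrapper.
#' @export
compareStates <- function(ref, cmp, convention = c("semantic", "literal")) {
  convention <- match.arg(convention)
  stopifnot(is(ref, "StateSet"), is(cmp, "StateSet"))
  if (ref@stateIndex != 1L || cmp@stateIndex != 2L) {
    stop("compareStates() expects ref with stateIndex 1 and cmp with stateIndex 2",
         call. = FALSE)
  }
  keys <- sort(union(names(ref@sets), names(cmp@sets)), method = "radix")
  seRows <- vector("list", length(keys))
  clRows <- vector("list", length(keys))
  for (i in seq_along(keys)) {
    k <- keys[i]
    lRef <- ref@sets[[k]]
    lCmp <- cmp@sets[[k]]
    if (is.null(lRef)) lRef <- character(0)
    if (is.null(lCmp)) lCmp <- character(0)
    st <- splitCommKey(k)
    sc <- seScore(lRef, lCmp, convention)
    cu <- classifyUnits(lRef, lCmp)
    seRows[[i]] <- data.frame(
      source = st$source, target = st$target,
      n_ref = sc$n_ref, n_cmp = sc$n_cmp,
      n_intersection = sc$n_intersection,
      r_ref = sc$r_ref, r_cmp = sc$r_cmp, se = sc$se,
      direction = sc$direction,
      gain_ratio = cu$gain_ratio,
      potential_loss_ratio = cu$potential_loss_ratio,
      stringsAsFactors = FALSE)
    pairs <- c(cu$consensus, cu$gain, cu$potential_loss)
    if (length(pairs) > 0L) {
      lr <- splitPairKey(pairs)
      clRows[[i]] <- data.frame(
        source = st$source, target = st$target,
        ligand = lr$ligand, receptor = lr$receptor,
        category = rep(c("consensus", "gain", "potential_loss"),
                       c(length(cu$consensus), length(cu$gain),
                         length(cu$potential_loss))),
        stringsAsFactors = FALSE)
    }
  }
  se <- do.call(rbind, seRows)
  if (is.null(se)) {
    se <- data.frame(source = character(0), target = character(0),
                     n_ref = integer(0), n_cmp = integer(0),
                     n_intersection = integer(0), r_ref = numeric(0),
                     r_cmp = numeric(0), se = numeric(0),
                     direction = character(0), gain_ratio = numeric(0),
                     potential_loss_ratio = numeric(0),
                     stringsAsFactors = FALSE)
  }
  cl <- do.call(rbind, clRows[!vapply(clRows, is.null, logical(1))])
  if (is.null(cl)) {
    cl <- data.frame(source = character(0), target = character(0),
                     ligand = character(0), receptor = character(0),
                     category = character(0), stringsAsFactors = FALSE)
  }
  rownames(se) <- rownames(cl) <- NULL
  new("CCCComparison", refLabel = ref@stateLabel, cmpLabel = cmp@stateLabel,
      convention = convention, se = se, classification = cl)
}

#' Filter, build and compare two interaction tables
#'
#' Convenience wrapper for the standard two-phase workflow: applies the
#' double p-value filter to each state independently, builds the state
#' sets, compares them, and annotates the classification with per-state
#' interaction magnitudes (`lr_mean_ref`, `lr_mean_cmp`; `NA` on the side
#' where a pair is absent) for downstream shortlisting and consensus-shift
#' testing.
#'
#' @param ref,cmp [InteractionTable] objects (unfiltered) for the
#'   reference and comparator states.
#' @param config An [analysisConfig()].
#' @return A [CCCComparison].
#' @examples
#' syn <- generateTwoState(nCommTypes = 3, seed = 1)
#' compareTables(syn$ref, syn$cmp)
#' @export
compareTables <- function(ref, cmp, config = analysisConfig()) {
  stopifnot(is(ref, "InteractionTable"), is(cmp, "InteractionTable"))
  refF <- doublePvalueFilter(ref, config$pThreshold)
  cmpF <- doublePvalueFilter(cmp, config$pThreshold)
  res <- compareStates(buildStateSet(refF, 1L), buildStateSet(cmpF, 2L),
                       config$seSignConvention)
  cl <- res@classification
  if (nrow(cl) > 0L) {
    lookup <- function(tbl) {
      df <- tbl@data
      stats::setNames(df$lr_mean,
                      paste(df$source, df$target, df$ligand, df$receptor,
                            sep = "\r"))
    }
    key <- paste(cl$source, cl$target, cl$ligand, cl$receptor, sep = "\r")
    cl$lr_mean_ref <- unname(lookup(refF)[key])
    cl$lr_mean_cmp <- unname(lookup(cmpF)[key])
  } else {
    cl$lr_mean_ref <- numeric(0)
    cl$lr_mean_cmp <- numeric(0)
  }
  initialize(res, classification = cl)
}

#' @describeIn aggregateOrgan Aggregate a per-type SE `data.frame` (needs
#'   columns `se` and `direction`). Communication types with a net
#'   directional change (non-zero SE) are counted as expanding or
#'   shrinking; stable types (SE = 0) are counted but excluded from the
#'   total, and the organ score is
#'   \eqn{SE_{organ} = (N_{expand} - N_{shrink}) / N_{total}} with
#'   \eqn{N_{total} = N_{expand} + N_{shrink}}. When no type changes,
#'   `se_organ` is `NA` with a warning rather than 0.
#' @param includeEmergent Whether emergent/vanished types (se = +1/-1)
#'   are counted; default `TRUE`.
#' @return A list with `n_expand`, `n_shrink`, `n_stable`, `n_total`,
#'   `se_organ`.
#' @examples
#' se <- data.frame(se = c(0.5, 0.2, -0.1, 0, 0, 0),
#'                  direction = c("expanding", "expanding", "shrinking",
#'                                "stable", "stable", "stable"))
#' aggregateOrgan(se)
#' @export
setMethod("aggregateOrgan", "data.frame", function(x, includeEmergent = TRUE) {
  stopifnot(all(c("se", "direction") %in% names(x)))
  if (!includeEmergent) {
    x <- x[!x$direction %in% c("emergent", "vanished"), , drop = FALSE]
  }
  nExpand <- sum(x$se > 0)
  nShrink <- sum(x$se < 0)
  nStable <- sum(x$se == 0)
  nTotal <- nExpand + nShrink
  seOrgan <- if (nTotal == 0L) {
    warning("no communication type with non-zero SE; organ SE is undefined",
            call. = FALSE)
    NA_real_
  } else {
    (nExpand - nShrink) / nTotal
  }
  list(n_expand = nExpand, n_shrink = nShrink, n_stable = nStable,
       n_total = nTotal, se_organ = seOrgan)
})

#' @describeIn aggregateOrgan Aggregate the SE table of a
#'   [CCCComparison].
#' @export
setMethod("aggregateOrgan", "CCCComparison",
          function(x, includeEmergent = TRUE) {
  aggregateOrgan(x@se, includeEmergent = includeEmergent)
})
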