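# Synthetic LR inference tables with planted ground truth. Emulates the
# downstream table contract of LIANA-style consensus output: per-state
# presence/absence of significant LR pairs per communication type,
# log-normal interaction magnitudes, and p-values straddling the
# significance threshold. It does not simulate counts, cells, or any
# upstream scoring.

# Synthetic vocabularies: cell types CT01..., pairs LIG001|REC001... drawn
# from a shared pool so the same pair can recur across communication types
# (as real LR resources do).
.synthCellTypes <- function(n) sprintf("CT%02d", seq_len(n))

.synthPairPool <- function(n) {
  pairKey(sprintf("LIG%03d", seq_len(n)), sprintf("REC%03d", seq_len(n)))
}

# p-value regimes: significant rows draw both p-values in (0, threshold/2],
# decoys draw the failing p-value(s) in [threshold, 1]. The strict-inequality
# boundary is thus never hit by chance; it is exercised by dedicated tests.
.pSig <- function(n, threshold) stats::runif(n, 0, threshold / 2)
.pBad <- function(n, threshold) stats::runif(n, threshold, 1)

# One state's rows for one communication type: significant planted pairs
# plus decoy rows failing the double filter in one of three patterns.
.synthStateRows <- function(src, tgt, sigPairs, decoyPairs, threshold,
                            meanlog, sdlog) {
  nS <- length(sigPairs)
  nD <- length(decoyPairs)
  pa <- pb <- numeric(0)
  if (nD > 0L) {
    pattern <- sample(c("a", "b", "both"), nD, replace = TRUE)
    pa <- ifelse(pattern %in% c("a", "both"),
                 .pBad(nD, threshold), .pSig(nD, threshold))
    pb <- ifelse(pattern %in% c("b", "both"),
                 .pBad(nD, threshold), .pSig(nD, threshold))
  }
  pairs <- c(sigPairs, decoyPairs)
  lr <- splitPairKey(pairs)
  data.frame(source = src, target = tgt, ligand = lr$ligand,
             receptor = lr$receptor,
             lr_mean = stats::rlnorm(nS + nD, meanlog, sdlog),
             pval_method_a = c(.pSig(nS, threshold), pa),
             pval_method_b = c(.pSig(nS, threshold), pb),
             stringsAsFactors = FALSE)
}

# Planted SE arithmetic, inlined (not routed through seScore) so the truth
# is an independent statement of what the pipeline must recover.
.plantedSE <- function(nC, nG, nPL) {
  nRef <- nC + nPL
  nCmp <- nC + nG
  if (nRef == 0L && nCmp == 0L) {
    stop("a planted communication type must be non-empty in at least one state",
         call. = FALSE)
  }
  if (nRef == 0L) {
    return(list(se = 1, direction = "emergent", gr = 1, plr = NA_real_))
  }
  if (nCmp == 0L) {
    return(list(se = -1, direction = "vanished", gr = NA_real_, plr = 1))
  }
  se <- nC * (1 / nRef - 1 / nCmp)
  list(se = se,
       direction = if (se > 0) "expanding" else if (se < 0) "shrinking"
                   else "stable",
       gr = nG / nCmp, plr = nPL / nRef)
}

# Organ-level counts over a list of planted per-type results.
.plantedOrgan <- function(perType) {
  ses <- vapply(perType, function(t) t$se, numeric(1))
  nExpand <- sum(ses > 0)
  nShrink <- sum(ses < 0)
  nTotal <- nExpand + nShrink
  list(n_expand = nExpand, n_shrink = nShrink, n_stable = sum(ses == 0),
       n_total = nTotal,
       se_organ = if (nTotal == 0L) NA_real_ else (nExpand - nShrink) / nTotal)
}

#' Generate a two-state LR inference scenario with planted truth
#'
#' Builds reference and comparator [InteractionTable] objects in which
#' every communication type has planted consensus, gain and
#' potential-loss sets, so that after the double p-value filter the
#' recovered sets equal the planted sets exactly. Decoy rows whose
#' p-values fail the filter in one or both methods are interleaved to
#' exercise filtering; interaction magnitudes are log-normal (positive,
#' right-skewed, resembling mean-expression magnitudes). Generation is
#' fully deterministic given `seed`.
#'
#' Defaults emulate a desk-scale organ: 12 directed communication types
#' over a small cell-type vocabulary, 4-12 consensus and 0-6 gain/loss
#' pairs per type, magnitudes from lognormal(0, 1), threshold 0.05.
#'
#' @param nCommTypes Number of communication types. Default 12.
#' @param sizes Optional integer matrix/data.frame with columns
#'   `consensus`, `gain`, `loss` (one row per type) fixing the planted
#'   cardinalities; sampled when `NULL`.
#' @param sets Optional named list (names `"SRC->TGT"`) of lists with
#'   character pair-key vectors `consensus`, `gain`, `potential_loss`,
#'   overriding both `nCommTypes` and `sizes` for full manual planting.
#' @param nDecoys Decoy rows per communication type per state. Default 3.
#' @param lrMeanParams Length-2 numeric, lognormal `(meanlog, sdlog)` of
#'   `lr_mean`. Default `c(0, 1)`.
#' @param pThreshold Significance threshold the p-value regimes straddle.
#'   Default 0.05.
#' @param refLabel,cmpLabel State labels. Defaults `"1m"`, `"3m"`.
#' @param poolSize Size of the shared LR pair pool. Default 150.
#' @param allowEmergent Permit planted types empty in one state.
#'   Default `FALSE`.
#' @param seed Integer seed (required).
#' @return List with `ref` and `cmp` ([InteractionTable]s) and `truth`, a
#'   list holding per-type planted sets, SE scores, directions, ratios,
#'   and the planted organ-level counts.
#' @examples
#' syn <- generateTwoState(nCommTypes = 4, seed = 7)
#' syn$truth$organ
#' @export
generateTwoState <- function(nCommTypes = 12L, sizes = NULL, sets = NULL,
                             nDecoys = 3L, lrMeanParams = c(0, 1),
                             pThreshold = 0.05, refLabel = "1m",
                             cmpLabel = "3m", poolSize = 150L,
                             allowEmergent = FALSE, seed) {
  stopifnot(!missing(seed), length(lrMeanParams) == 2L,
            pThreshold > 0, pThreshold < 1)
  withSeed(as.integer(seed), {
    pool <- .synthPairPool(poolSize)
    if (is.null(sets)) {
      nCommTypes <- as.integer(nCommTypes)
      stopifnot(nCommTypes >= 1L)
      nct <- max(2L, ceiling(sqrt(nCommTypes)) + 1L)
      ct <- .synthCellTypes(nct)
      combos <- expand.grid(source = ct, target = ct,
                            stringsAsFactors = FALSE)
      pick <- sample.int(nrow(combos), nCommTypes)
      commKeys <- commKey(combos$source[pick], combos$target[pick])
      if (is.null(sizes)) {
        sizes <- data.frame(consensus = sample(4:12, nCommTypes, TRUE),
                            gain = sample(0:6, nCommTypes, TRUE),
                            loss = sample(0:6, nCommTypes, TRUE))
      } else {
        sizes <- as.data.frame(sizes)
        stopifnot(nrow(sizes) == nCommTypes,
                  all(c("consensus", "gain", "loss") %in% names(sizes)))
      }
      if (!allowEmergent &&
          any(sizes$consensus + sizes$gain < 1 |
              sizes$consensus + sizes$loss < 1)) {
        stop("planted sizes would leave a state empty; set allowEmergent = TRUE",
             call. = FALSE)
      }
      sets <- vector("list", nCommTypes)
      names(sets) <- commKeys
      for (i in seq_len(nCommTypes)) {
        tot <- sizes$consensus[i] + sizes$gain[i] + sizes$loss[i]
        stopifnot(tot <= length(pool))
        drawn <- sample(pool, tot)
        sets[[i]] <- list(
          consensus = drawn[seq_len(sizes$consensus[i])],
          gain = drawn[seq_len(sizes$gain[i]) + sizes$consensus[i]],
          potential_loss = drawn[seq_len(sizes$loss[i]) +
                                   sizes$consensus[i] + sizes$gain[i]])
      }
    }
    perType <- list()
    refRows <- list()
    cmpRows <- list()
    for (k in names(sets)) {
      st <- splitCommKey(k)
      s <- sets[[k]]
      refSig <- c(s$consensus, s$potential_loss)
      cmpSig <- c(s$consensus, s$gain)
      refDecoy <- sample(setdiff(pool, refSig), min(nDecoys,
                         length(setdiff(pool, refSig))))
      cmpDecoy <- sample(setdiff(pool, cmpSig), min(nDecoys,
                         length(setdiff(pool, cmpSig))))
      refRows[[k]] <- .synthStateRows(st$source, st$target, refSig, refDecoy,
                                      pThreshold, lrMeanParams[1],
                                      lrMeanParams[2])
      cmpRows[[k]] <- .synthStateRows(st$source, st$target, cmpSig, cmpDecoy,
                                      pThreshold, lrMeanParams[1],
                                      lrMeanParams[2])
      pl <- .plantedSE(length(s$consensus), length(s$gain),
                       length(s$potential_loss))
      perType[[k]] <- list(
        consensus = sort(s$consensus, method = "radix"),
        gain = sort(s$gain, method = "radix"),
        potential_loss = sort(s$potential_loss, method = "radix"),
        n_ref = length(refSig), n_cmp = length(cmpSig),
        se = pl$se, direction = pl$direction,
        gain_ratio = pl$gr, potential_loss_ratio = pl$plr)
    }
    truth <- list(ref_label = refLabel, cmp_label = cmpLabel,
                  p_threshold = pThreshold, rng_seed = as.integer(seed),
                  lr_mean_params = lrMeanParams,
                  types = perType, organ = .plantedOrgan(perType))
    list(ref = interactionTable(do.call(rbind, refRows), refLabel),
         cmp = interactionTable(do.call(rbind, cmpRows), cmpLabel),
         truth = truth)
  })
}

#' Generate a multi-state lifespan series with planted drift
#'
#' Emulates a consecutive-interval lifespan design (e.g. ages 1, 3, 18,
#' 21, 30 months): each communication type starts from an initial LR set
#' and every transition applies a planted number of gains (new pairs from
#' the pool) and losses (dropped pairs), so transition-wise truths are
#' mutually consistent — state s+1's reference set is exactly state s's
#' comparator set. Each state's table carries fresh log-normal magnitudes
#' and decoy rows.
#'
#' @param nStates Number of states (>= 2). Default 5.
#' @param driftSpec Optional `data.frame` with integer columns `nGain`,
#'   `nLoss` (one row per transition) fixing the per-transition drift;
#'   sampled in 0-4 when `NULL`. Losses are capped so a set never
#'   empties.
#' @param stateLabels Character vector of state labels; defaults
#'   `"1m", "3m", "18m", "21m", "30m"` (extended numerically beyond 5).
#' @param nCommTypes Number of communication types. Default 8.
#' @param initSize Initial LR pairs per type. Default 8.
#' @inheritParams generateTwoState
#' @return List with `tables` (named list of [InteractionTable]s, one per
#'   state) and `truth` (per-transition planted sets, SE and organ
#'   summaries under `transitions`).
#' @examples
#' ser <- generateLifespanSeries(nStates = 3, seed = 11)
#' names(ser$tables)
#' @export
generateLifespanSeries <- function(nStates = 5L, driftSpec = NULL,
                                   stateLabels = NULL, nCommTypes = 8L,
                                   initSize = 8L, nDecoys = 3L,
                                   lrMeanParams = c(0, 1), pThreshold = 0.05,
                                   poolSize = 150L, seed) {
  stopifnot(!missing(seed), nStates >= 2L)
  nStates <- as.integer(nStates)
  if (is.null(stateLabels)) {
    base <- c("1m", "3m", "18m", "21m", "30m")
    stateLabels <- if (nStates <= 5L) base[seq_len(nStates)] else
      c(base, sprintf("%dm", 30L + 6L * seq_len(nStates - 5L)))
  }
  stopifnot(length(stateLabels) == nStates)
  withSeed(as.integer(seed), {
    pool <- .synthPairPool(poolSize)
    nct <- max(2L, ceiling(sqrt(nCommTypes)) + 1L)
    ct <- .synthCellTypes(nct)
    combos <- expand.grid(source = ct, target = ct, stringsAsFactors = FALSE)
    pick <- sample.int(nrow(combos), nCommTypes)
    commKeys <- commKey(combos$source[pick], combos$target[pick])
    if (is.null(driftSpec)) {
      driftSpec <- data.frame(nGain = sample(0:4, nStates - 1L, TRUE),
                              nLoss = sample(0:4, nStates - 1L, TRUE))
    }
    stopifnot(nrow(driftSpec) == nStates - 1L,
              all(c("nGain", "nLoss") %in% names(driftSpec)))
    current <- lapply(commKeys, function(k) sample(pool, initSize))
    names(current) <- commKeys
    stateSets <- vector("list", nStates)
    stateSets[[1L]] <- current
    transitions <- vector("list", nStates - 1L)
    names(transitions) <- paste(stateLabels[-nStates], stateLabels[-1L],
                                sep = "->")
    for (s in seq_len(nStates - 1L)) {
      perType <- list()
      nxt <- current
      for (k in commKeys) {
        cur <- current[[k]]
        nLoss <- min(driftSpec$nLoss[s], length(cur) - 1L)
        nLoss <- max(nLoss, 0L)
        lost <- if (nLoss > 0L) sample(cur, nLoss) else character(0)
        avail <- setdiff(pool, cur)
        nGain <- min(driftSpec$nGain[s], length(avail))
        gained <- if (nGain > 0L) sample(avail, nGain) else character(0)
        nxt[[k]] <- c(setdiff(cur, lost), gained)
        cons <- setdiff(cur, lost)
        pl <- .plantedSE(length(cons), length(gained), length(lost))
        perType[[k]] <- list(
          consensus = sort(cons, method = "radix"),
          gain = sort(gained, method = "radix"),
          potential_loss = sort(lost, method = "radix"),
          n_ref = length(cur), n_cmp = length(nxt[[k]]),
          se = pl$se, direction = pl$direction,
          gain_ratio = pl$gr, potential_loss_ratio = pl$plr)
      }
      transitions[[s]] <- list(ref_label = stateLabels[s],
                               cmp_label = stateLabels[s + 1L],
                               types = perType,
                               organ = .plantedOrgan(perType))
      current <- nxt
      stateSets[[s + 1L]] <- current
    }
    tables <- vector("list", nStates)
    names(tables) <- stateLabels
    for (s in seq_len(nStates)) {
      rows <- list()
      for (k in commKeys) {
        st <- splitCommKey(k)
        sig <- stateSets[[s]][[k]]
        decoy <- sample(setdiff(pool, sig),
                        min(nDecoys, length(setdiff(pool, sig))))
        rows[[k]] <- .synthStateRows(st$source, st$target, sig, decoy,
                                     pThreshold, lrMeanParams[1],
                                     lrMeanParams[2])
      }
      tables[[s]] <- interactionTable(do.call(rbind, rows), stateLabels[s])
    }
    list(tables = tables,
         truth = list(state_labels = stateLabels, rng_seed = as.integer(seed),
                      p_threshold = pThreshold, transitions = transitions))
  })
}
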