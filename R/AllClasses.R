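#' @import methods
NULL

# Canonical column set for interaction records after ingest. External
# tables (e.g. LIANA consensus output) are mapped onto these roles by a
# column map at read time.
.RECORD_COLS <- c("source", "target", "ligand", "receptor",
                  "lr_mean", "pval_method_a", "pval_method_b")

#' InteractionTable: ligand-receptor inference rows for one state
#'
#' An `InteractionTable` holds one biological state's ligand-receptor (LR)
#' inference results, one row per (source cell type, target cell type,
#' ligand, receptor) with an interaction-magnitude column `lr_mean` and two
#' per-method p-values (`pval_method_a`, CellPhoneDB-style permutation p;
#' `pval_method_b`, CellChat-style p). This matches the consensus output
#' schema of LIANA-style aggregation after column mapping.
#'
#' Validity requires: all canonical columns present; `lr_mean >= 0`; both
#' p-values in `[0, 1]`; the (source, target, ligand, receptor) key unique;
#' no reserved separator characters in labels.
#'
#' @slot data A `data.frame` with columns `source`, `target`, `ligand`,
#'   `receptor`, `lr_mean`, `pval_method_a`, `pval_method_b`.
#' @slot stateLabel Character scalar naming the state (e.g. `"3m"`).
#'
#' @seealso [readInteractionTable()], [doublePvalueFilter()],
#'   [buildStateSet()]
#' @export
setClass("InteractionTable",
         slots = c(data = "data.frame", stateLabel = "character"))

setValidity("InteractionTable", function(object) {
  df <- object@data
  missing <- setdiff(.RECORD_COLS, names(df))
  if (length(missing) > 0L) {
    return(sprintf("missing columns: %s", paste(missing, collapse = ", ")))
  }
  if (length(object@stateLabel) != 1L || is.na(object@stateLabel)) {
    return("stateLabel must be a single non-NA string")
  }
  if (nrow(df) == 0L) return(TRUE)
  if (any(!is.finite(df$lr_mean)) || any(df$lr_mean < 0)) {
    return("lr_mean must be finite and non-negative")
  }
  for (pc in c("pval_method_a", "pval_method_b")) {
    if (any(!is.finite(df[[pc]])) || any(df[[pc]] < 0 | df[[pc]] > 1)) {
      return(sprintf("%s must lie in [0, 1]", pc))
    }
  }
  key <- paste(df$source, df$target, df$ligand, df$receptor, sep = "\r")
  if (anyDuplicated(key)) {
    return("duplicate (source, target, ligand, receptor) keys")
  }
  TRUE
})

#' StateSet: per-communication-type LR pair sets for one state
#'
#' A `StateSet` materialises, for one state \eqn{s \in \{1, 2\}}, the map
#' from each communication type \eqn{t(A \to B)} (an ordered source/target
#' cell-type pair; A may equal B) to its set \eqn{L_t(s)} of LR pairs. It
#' is the input to SE scoring and Consensus/Gain/Potential-Loss
#' classification.
#'
#' @slot stateLabel Character scalar naming the state.
#' @slot stateIndex Integer, `1L` (reference) or `2L` (comparator).
#' @slot sets Named list; names are communication-type keys
#'   (`"source->target"`), elements are character vectors of LR pair keys
#'   (`"ligand|receptor"`), duplicate-free.
#'
#' @seealso [buildStateSet()], [compareStates()]
#' @export
setClass("StateSet",
         slots = c(stateLabel = "character", stateIndex = "integer",
                   sets = "list"))

setValidity("StateSet", function(object) {
  if (!object@stateIndex %in% c(1L, 2L)) {
    return("stateIndex must be 1 (reference) or 2 (comparator)")
  }
  if (length(object@sets) > 0L && is.null(names(object@sets))) {
    return("sets must be a named list keyed by communication type")
  }
  for (nm in names(object@sets)) {
    v <- object@sets[[nm]]
    if (!is.character(v)) return("each set must be a character vector")
    if (anyDuplicated(v)) {
      return(sprintf("duplicate LR pairs in communication type '%s'", nm))
    }
  }
  TRUE
})

#' CCCComparison: two-phase comparison of communication states
#'
#' Holds the full result of comparing a reference and a comparator
#' [StateSet]: the per-communication-type SE table (set sizes,
#' intersection ratios, SE score and direction) and the long
#' classification table assigning every CCC inference unit — one
#' (communication type, LR pair) combination — to consensus, gain or
#' potential loss. When built via [compareTables()] the classification
#' also carries the per-state interaction magnitudes used downstream for
#' shortlisting and consensus-shift testing.
#'
#' @slot refLabel,cmpLabel State labels of the reference and comparator.
#' @slot convention `"semantic"` or `"literal"` SE sign convention.
#' @slot se `data.frame` with columns `source`, `target`, `n_ref`,
#'   `n_cmp`, `n_intersection`, `r_ref`, `r_cmp`, `se`, `direction`.
#' @slot classification `data.frame` with columns `source`, `target`,
#'   `ligand`, `receptor`, `category` (consensus/gain/potential_loss) and,
#'   when annotated, `lr_mean_ref` and `lr_mean_cmp`.
#'
#' @seealso [compareStates()], [compareTables()], [aggregateOrgan()]
#' @export
setClass("CCCComparison",
         slots = c(refLabel = "character", cmpLabel = "character",
                   convention = "character", se = "data.frame",
                   classification = "data.frame"))

setValidity("CCCComparison", function(object) {
  if (!object@convention %in% c("semantic", "literal")) {
    return("convention must be 'semantic' or 'literal'")
  }
  need <- c("source", "target", "n_ref", "n_cmp", "n_intersection",
            "r_ref", "r_cmp", "se", "direction")
  if (!all(need %in% names(object@se))) {
    return("se table lacks required columns")
  }
  needc <- c("source", "target", "ligand", "receptor", "category")
  if (!all(needc %in% names(object@classification))) {
    return("classification table lacks required columns")
  }
  ok <- object@classification$category %in%
    c("consensus", "gain", "potential_loss")
  if (!all(ok)) return("unknown classification category")
  TRUE
})
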