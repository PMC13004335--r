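# Accessors and show() methods for the core S4 containers.

#' @rdname InteractionTable-class
#' @export
setMethod("interactionData", "InteractionTable", function(x) x@data)

#' @rdname InteractionTable-class
#' @export
setMethod("stateLabel", "InteractionTable", function(x) x@stateLabel)

#' @rdname StateSet-class
#' @export
setMethod("stateLabel", "StateSet", function(x) x@stateLabel)

#' @rdname StateSet-class
#' @export
setMethod("stateIndex", "StateSet", function(x) x@stateIndex)

#' @rdname StateSet-class
#' @export
setMethod("lrSets", "StateSet", function(x) x@sets)

#' @rdname StateSet-class
#' @export
setMethod("commTypes", "StateSet", function(x) {
  if (length(x@sets) == 0L) {
    return(data.frame(source = character(0), target = character(0),
                      stringsAsFactors = FALSE))
  }
  splitCommKey(names(x@sets))
})

#' @rdname CCCComparison-class
#' @export
setMethod("seTable", "CCCComparison", function(x) x@se)

#' @rdname CCCComparison-class
#' @export
setMethod("classificationTable", "CCCComparison", function(x) x@classification)

#' @rdname CCCComparison-class
#' @export
setMethod("stateLabel", "CCCComparison",
          function(x) c(reference = x@refLabel, comparator = x@cmpLabel))

setMethod("show", "InteractionTable", function(object) {
  df <- object@data
  cat(sprintf("InteractionTable: %d LR interactions, state '%s'\n",
              nrow(df), object@stateLabel))
  if (nrow(df) > 0L) {
    cat(sprintf("  %d communication types, %d distinct LR pairs\n",
                length(unique(commKey(df$source, df$target))),
                length(unique(pairKey(df$ligand, df$receptor)))))
    cat(sprintf("  lr_mean range: [%.3g, %.3g]\n",
                min(df$lr_mean), max(df$lr_mean)))
  }
  invisible(object)
})

setMethod("show", "StateSet", function(object) {
  sizes <- lengths(object@sets)
  cat(sprintf("StateSet: state '%s' (index %d), %d communication types\n",
              object@stateLabel, object@stateIndex, length(sizes)))
  if (length(sizes) > 0L) {
    cat(sprintf("  LR pairs per type: min %d, median %g, max %d\n",
                min(sizes), stats::median(sizes), max(sizes)))
  }
  invisible(object)
})

setMethod("show", "CCCComparison", function(object) {
  se <- object@se
  cat(sprintf("CCCComparison: '%s' (reference) vs '%s' (comparator), %s convention\n",
              object@refLabel, object@cmpLabel, object@convention))
  cat(sprintf("  %d communication types: %d expanding, %d shrinking, %d stable",
              nrow(se), sum(se$direction == "expanding"),
              sum(se$direction == "shrinking"),
              sum(se$direction == "stable")))
  ne <- sum(se$direction %in% c("emergent", "vanished"))
  if (ne > 0L) cat(sprintf(", %d emergent/vanished", ne))
  cat("\n")
  cl <- object@classification
  cat(sprintf("  CCC inference units: %d consensus, %d gain, %d potential loss\n",
              sum(cl$category == "consensus"), sum(cl$category == "gain"),
              sum(cl$category == "potential_loss")))
  invisible(object)
})
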