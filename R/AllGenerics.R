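#' Accessors for HubScreen classes
#'
#' Small accessor generics so user code never touches slots directly:
#' `networkName()`, `nodeSet()`, `edgeTable()` for graphs and maps;
#' `mapMode()` for an [ActionMap-class]; `commonHubs()`, `specificHubs()`,
#' `overlapPercent()` for a [HubOverlap-class]; `centralNode()`,
#' `criticalSet()`, `excludedNodes()`, `roleTable()`, `regulatorEvidence()`
#' for a [ScreeningResult-class]; `plantedCore()`, `plantedRegulators()`
#' for a [SyntheticTruth-class].
#'
#' @param x an object of the matching class.
#' @param which for `specificHubs()`, `"a"` or `"b"`.
#' @return The requested component (character vector, data.frame, list or
#'   scalar as documented per slot).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("networkName", function(x) standardGeneric("networkName"))
#' @rdname accessors
#' @export
setGeneric("nodeSet", function(x) standardGeneric("nodeSet"))
#' @rdname accessors
#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))
#' @rdname accessors
#' @export
setGeneric("mapMode", function(x) standardGeneric("mapMode"))
#' @rdname accessors
#' @export
setGeneric("commonHubs", function(x) standardGeneric("commonHubs"))
#' @rdname accessors
#' @export
setGeneric("specificHubs", function(x, which = c("a", "b"))
  standardGeneric("specificHubs"))
#' @rdname accessors
#' @export
setGeneric("overlapPercent", function(x) standardGeneric("overlapPercent"))
#' @rdname accessors
#' @export
setGeneric("centralNode", function(x) standardGeneric("centralNode"))
#' @rdname accessors
#' @export
setGeneric("criticalSet", function(x) standardGeneric("criticalSet"))
#' @rdname accessors
#' @export
setGeneric("excludedNodes", function(x) standardGeneric("excludedNodes"))
#' @rdname accessors
#' @export
setGeneric("roleTable", function(x) standardGeneric("roleTable"))
#' @rdname accessors
#' @export
setGeneric("regulatorEvidence", function(x) standardGeneric("regulatorEvidence"))
#' @rdname accessors
#' @export
setGeneric("plantedCore", function(x) standardGeneric("plantedCore"))
#' @rdname accessors
#' @export
setGeneric("plantedRegulators", function(x) standardGeneric("plantedRegulators"))

#' @rdname accessors
#' @export
setMethod("networkName", "InteractionNetwork", function(x) x@name)
#' @rdname accessors
#' @export
setMethod("nodeSet", "InteractionNetwork", function(x) x@nodes)
#' @rdname accessors
#' @export
setMethod("edgeTable", "InteractionNetwork", function(x) x@edges)
#' @rdname accessors
#' @export
setMethod("nodeSet", "ActionMap", function(x) x@nodes)
#' @rdname accessors
#' @export
setMethod("edgeTable", "ActionMap", function(x) x@edges)
#' @rdname accessors
#' @export
setMethod("mapMode", "ActionMap", function(x) x@mode)
#' @rdname accessors
#' @export
setMethod("commonHubs", "HubOverlap", function(x) x@common)
#' @rdname accessors
#' @export
setMethod("specificHubs", "HubOverlap", function(x, which = c("a", "b")) {
  if (identical(match.arg(which), "a")) x@specificA else x@specificB
})
#' @rdname accessors
#' @export
setMethod("overlapPercent", "HubOverlap", function(x) x@overlapPercent)
#' @rdname accessors
#' @export
setMethod("centralNode", "ScreeningResult", function(x) x@centralNode)
#' @rdname accessors
#' @export
setMethod("criticalSet", "ScreeningResult", function(x) x@critical)
#' @rdname accessors
#' @export
setMethod("excludedNodes", "ScreeningResult", function(x) x@excluded)
#' @rdname accessors
#' @export
setMethod("roleTable", "ScreeningResult", function(x) x@roles)
#' @rdname accessors
#' @export
setMethod("regulatorEvidence", "ScreeningResult", function(x) x@evidence)
#' @rdname accessors
#' @export
setMethod("plantedCore", "SyntheticTruth", function(x) x@plantedCore)
#' @rdname accessors
#' @export
setMethod("plantedRegulators", "SyntheticTruth", function(x) x@regulators)
#' @rdname accessors
#' @export
setMethod("centralNode", "SyntheticTruth", function(x) x@central)

setMethod("show", "InteractionNetwork", function(object) {
  cat(sprintf("InteractionNetwork '%s': %d nodes, %d edges\n",
              object@name, length(object@nodes), nrow(object@edges)))
})

setMethod("show", "ActionMap", function(object) {
  cat(sprintf("ActionMap mode=%s: universe of %d nodes, %d directed edges\n",
              object@mode, length(object@nodes), nrow(object@edges)))
})

setMethod("show", "HubOverlap", function(object) {
  cat(sprintf("HubOverlap (k = %d): %d common hubs (%.1f%%)\n",
              object@k, length(object@common), object@overlapPercent))
  cat("  specific to A:", paste(object@specificA, collapse = ", "), "\n")
  cat("  specific to B:", paste(object@specificB, collapse = ", "), "\n")
})

setMethod("show", "ScreeningResult", function(object) {
  cat(sprintf("ScreeningResult: central node %s, %d excluded, critical core of %d\n",
              object@centralNode, length(object@excluded),
              length(object@critical)))
  cat("  critical:", paste(object@critical, collapse = ", "), "\n")
})

setMethod("show", "SyntheticTruth", function(object) {
  cat(sprintf(
    "SyntheticTruth (seed %d): core %d, specific %d+%d, central %s, %d regulators\n",
    object@seed, length(object@plantedCore), length(object@plantedSpecificA),
    length(object@plantedSpecificB), object@central,
    length(object@regulators)))
})
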