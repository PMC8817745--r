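#' @import methods
NULL

ACTION_MODES <- c("expression", "activation", "inhibition")
ACTION_SIGNS <- c("positive", "negative", "unspecified")
NODE_ROLES   <- c("regulator", "regulated_only", "isolated")
EXCLUSION_REASONS <- c("isolated_all_maps", "regulated_only", "generic_central")

#' InteractionNetwork: an undirected simple scored protein graph
#'
#' One disease's protein-protein interaction network. Edges are unordered
#' symbol pairs stored canonically (`from` < `to` lexicographically), each
#' with a single retained confidence score; the graph is simple (no
#' self-loops, no parallel edges) and every edge endpoint belongs to the
#' node set.
#'
#' @slot name disease label, e.g. `"liver"`.
#' @slot nodes character vector of gene symbols (sorted, unique).
#' @slot edges data.frame with columns `from`, `to` (character) and
#'   `score` (integer, 0-1000 STRING scale), one row per undirected edge.
#'
#' @seealso [buildNetwork()], [degreeTable()]
#' @export
setClass("InteractionNetwork",
  representation(name = "character", nodes = "character", edges = "data.frame"))

setValidity("InteractionNetwork", function(object) {
  msg <- character()
  ed <- object@edges
  if (!all(c("from", "to", "score") %in% names(ed)))
    msg <- c(msg, "edges must have columns 'from', 'to', 'score'")
  else {
    if (any(ed$from == ed$to)) msg <- c(msg, "self-loops are not allowed")
    if (any(ed$from > ed$to))
      msg <- c(msg, "edges must be stored canonically with from < to")
    if (anyDuplicated(paste(ed$from, ed$to)))
      msg <- c(msg, "parallel edges are not allowed")
    if (!all(c(ed$from, ed$to) %in% object@nodes))
      msg <- c(msg, "every edge endpoint must be a network node")
    if (nrow(ed) && (any(ed$score < 0) || any(ed$score > 1000)))
      msg <- c(msg, "scores must lie in [0, 1000]")
  }
  if (anyDuplicated(object@nodes)) msg <- c(msg, "nodes must be unique")
  if (length(msg)) msg else TRUE
})

#' ActionMap: a directed typed regulatory subgraph
#'
#' The restriction of one regulatory relation mode (expression, activation
#' or inhibition) to a fixed node universe. The node slot always equals the
#' supplied universe so that isolated nodes are representable; edges are
#' ordered `(source, target, sign)` triples.
#'
#' @slot mode one of `"expression"`, `"activation"`, `"inhibition"`.
#' @slot nodes character vector: the restriction universe.
#' @slot edges data.frame with columns `source`, `target`, `sign`.
#'
#' @seealso [buildActionMap()], [classifyRoles()]
#' @export
setClass("ActionMap",
  representation(mode = "character", nodes = "character", edges = "data.frame"))

setValidity("ActionMap", function(object) {
  msg <- character()
  if (length(object@mode) != 1L || !object@mode %in% ACTION_MODES)
    msg <- c(msg, sprintf("mode must be one of %s",
                          paste(ACTION_MODES, collapse = ", ")))
  ed <- object@edges
  if (!all(c("source", "target", "sign") %in% names(ed)))
    msg <- c(msg, "edges must have columns 'source', 'target', 'sign'")
  else {
    if (!all(c(ed$source, ed$target) %in% object@nodes))
      msg <- c(msg, "every edge endpoint must lie in the node universe")
    if (anyDuplicated(paste(ed$source, ed$target, ed$sign)))
      msg <- c(msg, "duplicate (source, target, sign) triples are not allowed")
    if (nrow(ed) && !all(ed$sign %in% ACTION_SIGNS))
      msg <- c(msg, "edge signs must be positive/negative/unspecified")
  }
  if (anyDuplicated(object@nodes)) msg <- c(msg, "universe must be unique")
  if (length(msg)) msg else TRUE
})

#' HubOverlap: comparison of two equally sized hub lists
#'
#' @slot k hub list size (the top-k cut, default 20 upstream).
#' @slot common symbols present in both lists.
#' @slot specificA,specificB symbols unique to the first/second list.
#' @slot overlapPercent `100 * |common| / k`.
#'
#' @seealso [compareHubs()]
#' @export
setClass("HubOverlap",
  representation(k = "integer", common = "character",
                 specificA = "character", specificB = "character",
                 overlapPercent = "numeric"))

setValidity("HubOverlap", function(object) {
  msg <- character()
  if (length(object@common) + length(object@specificA) != object@k)
    msg <- c(msg, "|common| + |specificA| must equal k")
  if (length(object@common) + length(object@specificB) != object@k)
    msg <- c(msg, "|common| + |specificB| must equal k")
  expect <- 100 * length(object@common) / object@k
  if (abs(object@overlapPercent - expect) > 1e-8)
    msg <- c(msg, "overlapPercent must equal 100 * |common| / k")
  if (length(msg)) msg else TRUE
})

#' ScreeningResult: outcome of the critical-hub screening
#'
#' Produced by [screenCriticalHubs()]. Records the generic central node,
#' every excluded hub with its exclusion reason, the per-node regulatory
#' roles, and the surviving critical regulator set with the `(map, sign)`
#' evidence tying each critical protein to the central node.
#'
#' @slot centralNode the generic central node (excluded from the core).
#' @slot roles data.frame from [classifyRoles()]: one row per hub with
#'   per-map and overall roles.
#' @slot excluded named character vector, symbol -> reason, reasons in
#'   `isolated_all_maps`, `regulated_only`, `generic_central`.
#' @slot critical sorted character vector: the critical regulator core.
#' @slot evidence named list, one entry per critical symbol, each a
#'   data.frame with columns `map`, `sign` describing its directed
#'   relations onto the central node.
#'
#' @export
setClass("ScreeningResult",
  representation(centralNode = "character", roles = "data.frame",
                 excluded = "character", critical = "character",
                 evidence = "list"))

setValidity("ScreeningResult", function(object) {
  msg <- character()
  if (length(intersect(object@critical, names(object@excluded))))
    msg <- c(msg, "critical set and excluded set must be disjoint")
  if (object@centralNode %in% object@critical)
    msg <- c(msg, "central node cannot be critical")
  if (!setequal(object@critical, names(object@evidence)))
    msg <- c(msg, "evidence must cover exactly the critical set")
  if (length(object@excluded) &&
      !all(object@excluded %in% EXCLUSION_REASONS))
    msg <- c(msg, "unknown exclusion reason")
  if (length(msg)) msg else TRUE
})

#' SyntheticTruth: planted ground truth of a generated network pair
#'
#' @slot plantedCore symbols planted at high degree in both networks.
#' @slot plantedSpecificA,plantedSpecificB symbols forced into only one
#'   network's top-k.
#' @slot central the planted central node.
#' @slot regulators planted regulator set (a subset of the core minus the
#'   central node).
#' @slot seed integer seed the pair was generated from.
#'
#' @seealso [generatePair()]
#' @export
setClass("SyntheticTruth",
  representation(plantedCore = "character", plantedSpecificA = "character",
                 plantedSpecificB = "character", central = "character",
                 regulators = "character", seed = "integer"))

setValidity("SyntheticTruth", function(object) {
  msg <- character()
  if (length(intersect(object@plantedCore, object@plantedSpecificA)))
    msg <- c(msg, "core and network-A-specific sets must be disjoint")
  if (length(intersect(object@plantedCore, object@plantedSpecificB)))
    msg <- c(msg, "core and network-B-specific sets must be disjoint")
  if (!all(object@regulators %in% setdiff(object@plantedCore, object@central)))
    msg <- c(msg, "regulators must lie in the planted core minus the central node")
  if (length(msg)) msg else TRUE
})
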