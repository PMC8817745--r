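#' Degree table of an interaction network
#'
#' Unweighted degree centrality: per node, the number of distinct
#' neighbors (confidence scores play no role after thresholding). The
#' full table is returned, sorted by degree descending with alphabetical
#' tie-break, and 1-based consecutive ranks.
#'
#' @param network an [InteractionNetwork-class].
#' @return data.frame with columns `rank`, `symbol`, `degree`.
#' @examples
#' net <- buildNetwork(data.frame(proteinA = c("X", "X", "X"),
#'                                proteinB = c("A", "B", "C"),
#'                                combinedScore = 900L), "star")
#' degreeTable(net)
#' @export
degreeTable <- function(network) {
  stopifnot(is(network, "InteractionNetwork"))
  if (!length(network@nodes))
    return(data.frame(rank = integer(), symbol = character(),
                      degree = integer(), stringsAsFactors = FALSE))
  deg <- igraph::degree(asIgraph(network))
  ord <- order(-deg, names(deg))
  data.frame(rank = seq_along(deg), symbol = names(deg)[ord],
             degree = as.integer(deg[ord]), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Select the top-k hubs of a degree table
#'
#' Hub selection as performed with a network analyzer's degree ranking:
#' the `k` highest-degree nodes. Ties at the k-th degree are resolved
#' alphabetically under `"strict_k"` (deterministic, exactly
#' `min(k, nrow(table))` symbols); `"include_ties"` additionally returns
#' every symbol tied with the k-th degree, acknowledging that degree
#' rankings are ambiguous at the cut.
#'
#' @param table data.frame from [degreeTable()] (columns `symbol`,
#'   `degree`).
#' @param k number of hubs, default 20.
#' @param tiePolicy `"strict_k"` or `"include_ties"`.
#' @return character vector of hub symbols in (degree desc, symbol asc)
#'   order.
#' @export
selectTopHubs <- function(table, k = 20L, tiePolicy = c("strict_k", "include_ties")) {
  tiePolicy <- match.arg(tiePolicy)
  if (length(k) != 1L || is.na(k) || k < 1) stop("k must be a positive integer")
  stopifnot(all(c("symbol", "degree") %in% names(table)))
  if (!nrow(table)) stop("degree table is empty")
  ord <- order(-table$degree, table$symbol)
  sym <- table$symbol[ord]
  deg <- table$degree[ord]
  kk <- min(k, length(sym))
  if (tiePolicy == "strict_k") sym[seq_len(kk)]
  else sym[deg >= deg[kk]]
}

#' Compare two equally sized hub lists
#'
#' Set comparison of the top-k hubs of two disease networks: the common
#' hubs, the disease-specific hubs of each, and the overlap percentage
#' `100 * |common| / k` (rounded only when displayed).
#'
#' @param hubsA,hubsB character vectors of equal length `k`, no
#'   duplicates.
#' @return a [HubOverlap-class].
#' @examples
#' fx <- loadCuratedHubData()
#' compareHubs(fx$liverHubs, fx$pancreasHubs)
#' @export
compareHubs <- function(hubsA, hubsB) {
  if (length(hubsA) != length(hubsB))
    stop("hub lists must have equal length (symmetric k design)")
  if (anyDuplicated(hubsA) || anyDuplicated(hubsB))
    stop("hub lists must not contain duplicates")
  k <- length(hubsA)
  if (k < 1) stop("hub lists must be nonempty")
  common <- sort(intersect(hubsA, hubsB))
  new("HubOverlap", k = as.integer(k), common = common,
      specificA = sort(setdiff(hubsA, hubsB)),
      specificB = sort(setdiff(hubsB, hubsA)),
      overlapPercent = 100 * length(common) / k)
}

#' Write a hub table as TSV
#'
#' Mirrors the published degree-table layout: columns `rank`, `symbol`,
#' `degree`.
#'
#' @param table data.frame from [degreeTable()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeHubTable <- function(table, path) {
  stopifnot(all(c("rank", "symbol", "degree") %in% names(table)))
  write.table(table[, c("rank", "symbol", "degree")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}
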