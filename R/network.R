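#' Build an undirected simple interaction network
#'
#' Turns score-filtered interaction records into a simple undirected
#' graph: self-pairs are dropped, duplicate rows and reversed duplicates
#' (`(A,B)` and `(B,A)`) collapse into one edge retaining the maximum
#' score (deterministic and monotone under score thresholding), and the
#' node set is the set of endpoints of surviving edges.
#'
#' @param records data.frame as returned by [readInteractions()].
#' @param name disease label stored on the network.
#' @return an [InteractionNetwork-class].
#' @examples
#' buildNetwork(data.frame(proteinA = c("A", "B", "C"),
#'                         proteinB = c("B", "A", "C"),
#'                         combinedScore = c(900L, 700L, 999L)), "demo")
#' @export
buildNetwork <- function(records, name = "network") {
  stopifnot(all(c("proteinA", "proteinB", "combinedScore") %in% names(records)))
  if (!nrow(records)) {
    warning("no interaction records: building an empty network")
    return(new("InteractionNetwork", name = name, nodes = character(),
               edges = data.frame(from = character(), to = character(),
                                  score = integer(),
                                  stringsAsFactors = FALSE)))
  }
  a <- normSymbol(records$proteinA)
  b <- normSymbol(records$proteinB)
  score <- as.integer(records$combinedScore)
  keep <- a != b
  from <- pmin(a[keep], b[keep])
  to <- pmax(a[keep], b[keep])
  score <- score[keep]
  if (!length(from)) {
    warning("all records were self-pairs: building an empty network")
    return(new("InteractionNetwork", name = name, nodes = character(),
               edges = data.frame(from = character(), to = character(),
                                  score = integer(),
                                  stringsAsFactors = FALSE)))
  }
  key <- paste(from, to, sep = "\t")
  best <- tapply(score, key, max)
  parts <- strsplit(names(best), "\t", fixed = TRUE)
  edges <- data.frame(from = vapply(parts, `[`, "", 1L),
                      to = vapply(parts, `[`, "", 2L),
                      score = as.integer(best),
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  new("InteractionNetwork", name = name,
      nodes = sort(unique(c(edges$from, edges$to))), edges = edges)
}

#' Build one directed typed action map over a node universe
#'
#' Restricts typed action records to a single relation mode and a node
#' universe (typically the common-hub set): only directed records of the
#' requested mode with both endpoints in the universe survive; self-edges
#' are dropped; duplicate `(source, target, sign)` triples collapse. The
#' map's node set is always the full universe, so nodes left without edges
#' remain representable as isolated.
#'
#' @param actions data.frame as returned by [readActions()].
#' @param mode one of `"expression"`, `"activation"`, `"inhibition"`.
#' @param universe character vector of gene symbols.
#' @return an [ActionMap-class].
#' @export
buildActionMap <- function(actions, mode = ACTION_MODES, universe) {
  mode <- match.arg(mode)
  if (!length(universe)) stop("universe must be nonempty")
  universe <- sort(unique(normSymbol(universe)))
  stopifnot(all(c("source", "target", "mode", "sign", "directed") %in%
                names(actions)))
  keep <- actions$directed & actions$mode == mode &
    actions$source %in% universe & actions$target %in% universe &
    actions$source != actions$target
  ed <- actions[keep, c("source", "target", "sign"), drop = FALSE]
  ed <- unique(ed)
  ed <- ed[order(ed$source, ed$target, ed$sign), , drop = FALSE]
  rownames(ed) <- NULL
  new("ActionMap", mode = mode, nodes = universe, edges = ed)
}

#' Convert a HubScreen graph to an igraph object
#'
#' @param x an [InteractionNetwork-class] (undirected) or
#'   [ActionMap-class] (directed).
#' @return an igraph graph including isolated vertices.
#' @export
asIgraph <- function(x) {
  if (is(x, "InteractionNetwork"))
    igraph::graph_from_data_frame(x@edges, directed = FALSE,
                                  vertices = x@nodes)
  else if (is(x, "ActionMap"))
    igraph::graph_from_data_frame(
      x@edges[, c("source", "target", "sign")], directed = TRUE,
      vertices = x@nodes)
  else stop("cannot convert class ", class(x), " to igraph")
}

#' Export a graph as SIF or plain edge-list TSV
#'
#' `exportSIF()` writes the Cytoscape simple-interaction format
#' (`source<TAB>relation<TAB>target`); interaction networks use the
#' relation `pp`, action maps use their mode. `exportEdgeList()` writes
#' the edge data.frame as a headered TSV.
#'
#' @param x an [InteractionNetwork-class] or [ActionMap-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
exportSIF <- function(x, path) {
  if (is(x, "InteractionNetwork"))
    out <- data.frame(source = x@edges$from, relation = "pp",
                      target = x@edges$to)
  else if (is(x, "ActionMap"))
    out <- data.frame(source = x@edges$source, relation = x@mode,
                      target = x@edges$target)
  else stop("cannot export class ", class(x))
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname exportSIF
#' @export
exportEdgeList <- function(x, path) {
  if (is(x, "InteractionNetwork") || is(x, "ActionMap"))
    write.table(x@edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  else stop("cannot export class ", class(x))
  invisible(path)
}
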