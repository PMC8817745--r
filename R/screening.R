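#' Classify the regulatory role of every node, per map and overall
#'
#' In a single action map a node is a `regulator` when it has at least one
#' outgoing edge, `regulated_only` when it has incoming but no outgoing
#' edges, and `isolated` when it touches no edge. The overall role
#' aggregates across the three maps: a node that regulates anything in any
#' map is an overall regulator; otherwise a node regulated anywhere is
#' overall regulated-only; otherwise it is isolated everywhere. Activity
#' in a single map never rescues a node that regulates nothing anywhere.
#'
#' @param maps named list of [ActionMap-class] objects (names
#'   `expression`, `activation`, `inhibition`), all sharing one universe.
#' @return data.frame with one row per universe symbol and columns
#'   `symbol`, one role column per map, and `overall`.
#' @export
classifyRoles <- function(maps) {
  maps <- checkMaps(maps)
  universe <- maps[[1L]]@nodes
  roles <- data.frame(symbol = universe, stringsAsFactors = FALSE)
  for (m in names(maps)) {
    ed <- maps[[m]]@edges
    out <- universe %in% ed$source
    inn <- universe %in% ed$target
    roles[[m]] <- ifelse(out, "regulator",
                  ifelse(inn, "regulated_only", "isolated"))
  }
  per <- as.matrix(roles[, names(maps), drop = FALSE])
  roles$overall <- apply(per, 1L, function(r) {
    if (any(r == "regulator")) "regulator"
    else if (any(r == "regulated_only")) "regulated_only"
    else "isolated"
  })
  roles
}

checkMaps <- function(maps) {
  if (!is.list(maps) || !length(maps) || is.null(names(maps)))
    stop("maps must be a named list of ActionMap objects")
  if (!setequal(names(maps), ACTION_MODES))
    stop("maps must be named expression, activation, inhibition")
  maps <- maps[ACTION_MODES]
  ok <- vapply(maps, is, TRUE, "ActionMap")
  if (!all(ok)) stop("all maps must be ActionMap objects")
  u <- maps[[1L]]@nodes
  same <- vapply(maps, function(m) setequal(m@nodes, u), TRUE)
  if (!all(same)) stop("all maps must share one node universe")
  maps
}

#' Pick the generic central node of the common-hub set
#'
#' The central node is the common hub with the greatest summed degree
#' across the two disease networks, with alphabetical tie-break. It is
#' the node too generically connected to discriminate between the
#' diseases; screening replaces it by its regulators. An explicit
#' `override` short-circuits the formula, since prominence arguments may
#' designate a central node directly.
#'
#' @param degrees data.frame with a `symbol` column and two per-network
#'   degree columns (any further columns are ignored; the second and
#'   third columns are taken as the two degrees when `kLiver` /
#'   `kPancreas` are absent).
#' @param common character vector of common-hub symbols (default: all
#'   symbols in `degrees`).
#' @param override optional symbol to use instead of the formula.
#' @return a single gene symbol.
#' @examples
#' fx <- loadCuratedHubData()
#' pickCentralNode(fx$hubDegrees)  # "TP53"
#' @export
pickCentralNode <- function(degrees, common = degrees$symbol, override = NULL) {
  if (!length(common)) stop("common hub set must be nonempty")
  if (!is.null(override)) {
    override <- normSymbol(override)
    if (!override %in% common) stop("central-node override not in common set")
    return(override)
  }
  stopifnot("symbol" %in% names(degrees))
  cols <- if (all(c("kLiver", "kPancreas") %in% names(degrees)))
    c("kLiver", "kPancreas") else setdiff(names(degrees), "symbol")[1:2]
  idx <- match(common, degrees$symbol)
  if (anyNA(idx))
    stop("degree missing for symbol(s): ",
         paste(common[is.na(idx)], collapse = ", "))
  total <- rowSums(as.matrix(degrees[idx, cols, drop = FALSE]))
  common[order(-total, common)][1L]
}

#' Find all regulators of a target node across the action maps
#'
#' The union, over the three maps, of sources of directed edges into the
#' target, each annotated with its `(map, sign)` evidence. Contradictory
#' relations (e.g. a protein that both up- and downregulates the target)
#' are all retained; no sign reconciliation is attempted.
#'
#' @param maps named list of [ActionMap-class] objects sharing one
#'   universe.
#' @param target gene symbol, must be in the universe.
#' @return named list, one entry per regulator symbol, each a data.frame
#'   with columns `map` and `sign`.
#' @export
findRegulators <- function(maps, target) {
  maps <- checkMaps(maps)
  target <- normSymbol(target)
  if (!target %in% maps[[1L]]@nodes)
    stop("target ", target, " is not in the map universe")
  ev <- do.call(rbind, lapply(names(maps), function(m) {
    ed <- maps[[m]]@edges
    hit <- ed[ed$target == target, , drop = FALSE]
    if (!nrow(hit)) return(NULL)
    data.frame(source = hit$source, map = m, sign = hit$sign,
               stringsAsFactors = FALSE)
  }))
  if (is.null(ev)) return(structure(list(), names = character()))
  out <- lapply(split(ev[, c("map", "sign")], ev$source),
                function(d) { rownames(d) <- NULL; d })
  out[sort(names(out))]
}

#' Screen the common hubs down to the critical regulator core
#'
#' The four-step exclusion pipeline applied to the shared hub set and its
#' typed action maps:
#' \enumerate{
#'   \item drop hubs isolated in all three maps (no regulatory context at
#'     all);
#'   \item drop hubs that are regulated somewhere but regulate nothing in
#'     any map (`regulated_only` overall);
#'   \item pick the generic central node (greatest summed degree across
#'     the two networks, or an explicit override) and drop it as too
#'     ubiquitous to discriminate;
#'   \item the critical core is the set of surviving hubs holding at
#'     least one directed action edge onto the central node, each with
#'     its `(map, sign)` evidence.
#' }
#' The step order is fixed; every removal is recorded with its reason.
#'
#' @param common character vector: the common-hub set (the maps'
#'   universe).
#' @param maps named list of [ActionMap-class] objects over `common`.
#' @param degrees data.frame of per-network degrees as in
#'   [pickCentralNode()].
#' @param central optional central-node override.
#' @return a [ScreeningResult-class].
#' @examples
#' fx <- loadCuratedHubData()
#' common <- sort(intersect(fx$liverHubs, fx$pancreasHubs))
#' maps <- sapply(c("expression", "activation", "inhibition"),
#'                function(m) buildActionMap(fx$actions, m, common),
#'                simplify = FALSE)
#' screenCriticalHubs(common, maps, fx$hubDegrees)
#' @export
screenCriticalHubs <- function(common, maps, degrees, central = NULL) {
  if (!length(common)) stop("common hub set must be nonempty")
  common <- sort(unique(normSymbol(common)))
  maps <- checkMaps(maps)
  if (!setequal(maps[[1L]]@nodes, common))
    stop("maps' universe must equal the common hub set")
  roles <- classifyRoles(maps)
  excluded <- character()
  iso <- roles$symbol[roles$overall == "isolated"]
  excluded[iso] <- "isolated_all_maps"
  reg <- roles$symbol[roles$overall == "regulated_only"]
  excluded[reg] <- "regulated_only"
  centralNode <- pickCentralNode(degrees, common, override = central)
  excluded[centralNode] <- "generic_central"
  survivors <- setdiff(common, names(excluded))
  evidence <- findRegulators(maps, centralNode)
  evidence <- evidence[intersect(names(evidence), survivors)]
  new("ScreeningResult", centralNode = centralNode, roles = roles,
      excluded = excluded, critical = sort(names(evidence)),
      evidence = evidence)
}
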