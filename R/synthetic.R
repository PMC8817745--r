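#' Configuration for the paired-network generator
#'
#' Defaults mirror the study design the package models: two
#' preferential-attachment networks of 300 proteins each (attachment
#' parameter m = 2), a planted shared hub core of 18, top-k hub lists of
#' k = 20 (so each network carries 2 disease-specific planted hubs), a
#' planted central node with 4 planted regulators, and a sparse typed
#' action overlay (density 0.08 per ordered core pair) mixing expression,
#' activation and inhibition. Scores are drawn uniformly from 400-999,
#' i.e. at or above the medium-confidence threshold.
#'
#' @param nNodes nodes per network.
#' @param m preferential-attachment parameter (edges per new vertex).
#' @param coreSize planted shared core size `c` (`c <= k <= nNodes`).
#' @param k hub-list size.
#' @param separation `"separated"` plants core and specific hubs at
#'   degrees strictly above the background maximum, making top-k recovery
#'   exact; `"overlapping"` plants them at background degrees to exercise
#'   tie handling.
#' @param actionDensity probability of a typed action edge per ordered
#'   core pair, in \[0, 1\].
#' @param modeMixture named nonnegative weights over the three modes.
#' @param nRegulators size of the planted regulator set.
#' @param scoreRange integer range edge scores are drawn from.
#' @param seed integer seed; equal seeds give identical output.
#' @return a validated config list of class `GeneratorConfig`.
#' @export
syntheticConfig <- function(nNodes = 300L, m = 2L, coreSize = 18L, k = 20L,
                            separation = c("separated", "overlapping"),
                            actionDensity = 0.08,
                            modeMixture = c(expression = 0.4,
                                            activation = 0.3,
                                            inhibition = 0.3),
                            nRegulators = 4L,
                            scoreRange = c(400L, 999L),
                            seed = 1L) {
  separation <- match.arg(separation)
  if (coreSize > k) stop("infeasible config: coreSize must not exceed k")
  if (k > nNodes) stop("infeasible config: k must not exceed nNodes")
  if (actionDensity < 0 || actionDensity > 1)
    stop("actionDensity must lie in [0, 1]")
  if (!setequal(names(modeMixture), ACTION_MODES) || any(modeMixture < 0) ||
      sum(modeMixture) <= 0)
    stop("modeMixture must be nonnegative weights over the three modes")
  if (nRegulators > coreSize - 1L)
    stop("infeasible config: nRegulators must leave room for the central node")
  if (m < 1L) stop("m must be at least 1")
  structure(list(nNodes = as.integer(nNodes), m = as.integer(m),
                 coreSize = as.integer(coreSize), k = as.integer(k),
                 separation = separation, actionDensity = actionDensity,
                 modeMixture = modeMixture[ACTION_MODES],
                 nRegulators = as.integer(nRegulators),
                 scoreRange = as.integer(scoreRange),
                 seed = as.integer(seed)),
            class = "GeneratorConfig")
}

# One scale-free network over the given symbol sets. In separated mode the
# planted symbols are mapped onto the lowest-degree vertices and then
# augmented with background edges to exact target degrees strictly above
# anything the background can reach (background gains at most one edge per
# planted node, hence the +planted+1 margin).
synthesizeNetwork <- function(planted, background, central, m, separation,
                              scoreRange, name) {
  nv <- length(planted) + length(background)
  g <- igraph::sample_pa(nv, power = 1, m = m, directed = FALSE)
  deg <- igraph::degree(g)
  labels <- character(nv)
  if (separation == "separated") {
    plantedIdx <- order(deg, seq_len(nv))[seq_along(planted)]
  } else {
    plantedIdx <- sample(nv, length(planted))
  }
  bgIdx <- setdiff(seq_len(nv), plantedIdx)
  labels[plantedIdx] <- planted
  labels[bgIdx] <- sample(background)
  if (separation == "separated") {
    base <- max(deg[bgIdx]) + length(planted) + 1L
    target <- ifelse(planted == central, base + 2L, base)
    if (max(target) > length(bgIdx))
      stop("infeasible config: not enough background nodes to separate hub degrees")
    for (i in seq_along(plantedIdx)) {
      v <- plantedIdx[i]
      need <- target[i] - igraph::degree(g, v)
      if (need < 0)
        stop("infeasible config: planted vertex exceeds its target degree")
      if (need > 0) {
        free <- setdiff(bgIdx, c(v, as.integer(igraph::neighbors(g, v))))
        if (length(free) < need)
          stop("infeasible config: not enough free background neighbors")
        nb <- sample(free, need)
        g <- igraph::add_edges(g, rbind(v, nb))
      }
    }
  }
  el <- igraph::as_edgelist(g, names = FALSE)
  records <- data.frame(
    proteinA = labels[el[, 1L]],
    proteinB = labels[el[, 2L]],
    combinedScore = sample(scoreRange[1L]:scoreRange[2L], nrow(el),
                           replace = TRUE),
    stringsAsFactors = FALSE)
  buildNetwork(records, name)
}

#' Generate a paired benchmark with planted ground truth
#'
#' Builds two scale-free (preferential-attachment) interaction networks
#' over partially shared synthetic symbol vocabularies (`S0001`,
#' `S0002`, ...; never real gene names), with a planted common hub core
#' shared by both, one planted disease-specific hub set per network, and
#' a directed typed action overlay among the core carrying a planted
#' central node and regulator set. In `"separated"` mode every planted
#' hub's degree strictly exceeds the background maximum and the central
#' node sits strictly above the other planted hubs in both networks, so
#' top-k selection, hub comparison, central-node choice and screening all
#' have exact known answers. Random action edges never point at the
#' central node — only the forced regulator edges do — so the critical
#' regulator set is recoverable exactly.
#'
#' @param config a `GeneratorConfig` from [syntheticConfig()].
#' @return list with components `networkA`, `networkB`
#'   ([InteractionNetwork-class]), `actions` (action-record data.frame)
#'   and `truth` ([SyntheticTruth-class]).
#' @examples
#' pair <- generatePair(syntheticConfig(nNodes = 150, seed = 42))
#' overlapPercent(compareHubs(
#'   selectTopHubs(degreeTable(pair$networkA), 20),
#'   selectTopHubs(degreeTable(pair$networkB), 20)))  # 90
#' @export
generatePair <- function(config) {
  stopifnot(inherits(config, "GeneratorConfig"))
  set.seed(config$seed)
  nSpec <- config$k - config$coreSize
  nBg <- config$nNodes - config$k
  nShared <- nBg %/% 2L
  nOwn <- nBg - nShared
  total <- config$coreSize + 2L * nSpec + nShared + 2L * nOwn
  vocab <- sprintf("S%05d", seq_len(total))
  take <- function(n) {
    out <- vocab[seq_len(n)]
    vocab <<- vocab[-seq_len(n)]
    out
  }
  core <- take(config$coreSize)
  specA <- take(nSpec)
  specB <- take(nSpec)
  sharedBg <- take(nShared)
  ownA <- take(nOwn)
  ownB <- take(nOwn)
  central <- sample(core, 1L)
  regulators <- sort(sample(setdiff(core, central), config$nRegulators))

  netA <- synthesizeNetwork(c(core, specA), c(sharedBg, ownA), central,
                            config$m, config$separation, config$scoreRange,
                            "synthetic_A")
  netB <- synthesizeNetwork(c(core, specB), c(sharedBg, ownB), central,
                            config$m, config$separation, config$scoreRange,
                            "synthetic_B")

  # random typed overlay among the core, central node never a target
  pairs <- expand.grid(source = core, target = setdiff(core, central),
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$source != pairs$target, , drop = FALSE]
  hit <- stats::runif(nrow(pairs)) < config$actionDensity
  drawModes <- function(n)
    sample(ACTION_MODES, n, replace = TRUE,
           prob = config$modeMixture / sum(config$modeMixture))
  rand <- pairs[hit, , drop = FALSE]
  randMode <- drawModes(nrow(rand))
  forcedMode <- drawModes(length(regulators))
  actions <- data.frame(
    source = c(rand$source, regulators),
    target = c(rand$target, rep(central, length(regulators))),
    mode = c(randMode, forcedMode),
    stringsAsFactors = FALSE)
  actions$sign <- ifelse(actions$mode == "activation", "positive",
                  ifelse(actions$mode == "inhibition", "negative",
                         sample(c("positive", "negative"), nrow(actions),
                                replace = TRUE)))
  actions$directed <- TRUE
  actions <- unique(actions)
  rownames(actions) <- NULL

  truth <- new("SyntheticTruth", plantedCore = core,
               plantedSpecificA = specA, plantedSpecificB = specB,
               central = central, regulators = regulators,
               seed = config$seed)
  list(networkA = netA, networkB = netB, actions = actions, truth = truth)
}

#' Write a generated pair in the formats the readers consume
#'
#' Emits `links_a.tsv` / `links_b.tsv` (interaction dialect),
#' `actions.tsv` (protein-actions dialect) and `truth.json` into a
#' directory.
#'
#' @param pair list from [generatePair()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeSyntheticData <- function(pair, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  edgeRecords <- function(net) {
    ed <- edgeTable(net)
    data.frame(proteinA = ed$from, proteinB = ed$to,
               combinedScore = ed$score, stringsAsFactors = FALSE)
  }
  writeInteractions(edgeRecords(pair$networkA), file.path(dir, "links_a.tsv"))
  writeInteractions(edgeRecords(pair$networkB), file.path(dir, "links_b.tsv"))
  writeActions(pair$actions, file.path(dir, "actions.tsv"))
  tr <- pair$truth
  jsonlite::write_json(
    list(planted_core = tr@plantedCore,
         planted_specific_a = tr@plantedSpecificA,
         planted_specific_b = tr@plantedSpecificB,
         central = tr@central, regulators = tr@regulators, seed = tr@seed),
    file.path(dir, "truth.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Power-law tail check of a degree distribution
#'
#' Fits a straight line to the log-log degree survival function
#' `S(d) = P(degree >= d)` over the distinct positive degrees and returns
#' its slope, with the fit's R-squared attached as attribute
#' `"r.squared"`. The slope alone does not separate heavy tails from
#' fast-decaying ones — a Poisson (random-graph) survival curve fits with
#' an even steeper slope — so the soft scale-free property used on
#' generator output combines both: slope below -1 and an approximately
#' linear log-log fit (see [passesTailCheck()]). This is a sanity
#' statistic, not a formal power-law test. A degenerate degree sequence
#' (fewer than three distinct positive degrees, as in a star graph)
#' yields `NA` with a warning.
#'
#' @param network an [InteractionNetwork-class] with at least 100 nodes.
#' @return the fitted slope (numeric scalar, attribute `r.squared`), or
#'   `NA` when degenerate.
#' @export
degreeDistributionCheck <- function(network) {
  stopifnot(is(network, "InteractionNetwork"))
  if (length(network@nodes) < 100L)
    stop("degree-distribution check needs at least 100 nodes")
  d <- igraph::degree(asIgraph(network))
  u <- sort(unique(d[d > 0]))
  if (length(u) < 3L) {
    warning("degenerate degree sequence: tail exponent undefined")
    return(NA_real_)
  }
  surv <- vapply(u, function(k) mean(d >= k), 0)
  fit <- stats::lm(log(surv) ~ log(u))
  structure(unname(stats::coef(fit)[2L]),
            r.squared = summary(fit)$r.squared)
}

#' @rdname degreeDistributionCheck
#' @param slopeMax the slope must fall below this value (default -1).
#' @param minLinearity minimum R-squared of the log-log fit (default 0.9).
#' @return `passesTailCheck()`: `TRUE` when the degree distribution is
#'   consistent with a heavy power-law tail, `FALSE` otherwise (including
#'   degenerate sequences).
#' @export
passesTailCheck <- function(network, slopeMax = -1, minLinearity = 0.9) {
  slope <- suppressWarnings(degreeDistributionCheck(network))
  if (is.na(slope)) return(FALSE)
  slope < slopeMax && attr(slope, "r.squared") >= minLinearity
}
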