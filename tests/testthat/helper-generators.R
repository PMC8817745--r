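# Random record builders used across test files. All take an explicit
# seed so property loops are reproducible.

randomInteractionRecords <- function(n, nSymbols = 30, seed = 1,
                                     allowSelf = FALSE) {
  set.seed(seed)
  syms <- sprintf("P%03d", seq_len(nSymbols))
  a <- sample(syms, n, replace = TRUE)
  b <- sample(syms, n, replace = TRUE)
  if (!allowSelf) {
    while (any(a == b)) {
      i <- a == b
      b[i] <- sample(syms, sum(i), replace = TRUE)
    }
  }
  data.frame(proteinA = a, proteinB = b,
             combinedScore = sample(0:1000, n, replace = TRUE),
             stringsAsFactors = FALSE)
}

randomActionRecords <- function(n, symbols = sprintf("P%03d", 1:15), seed = 1) {
  set.seed(seed)
  src <- sample(symbols, n, replace = TRUE)
  tgt <- sample(symbols, n, replace = TRUE)
  mode <- sample(c("expression", "activation", "inhibition"), n, replace = TRUE)
  sign <- ifelse(mode == "activation", "positive",
          ifelse(mode == "inhibition", "negative",
                 sample(c("positive", "negative"), n, replace = TRUE)))
  data.frame(source = src, target = tgt, mode = mode, sign = sign,
             directed = sample(c(TRUE, TRUE, TRUE, FALSE), n, replace = TRUE),
             stringsAsFactors = FALSE)
}

# The curated dataset and its derived action maps, loaded once per run.
curated <- loadCuratedHubData()
curatedCommon <- sort(intersect(curated$liverHubs, curated$pancreasHubs))
curatedMaps <- sapply(c("expression", "activation", "inhibition"),
                      function(m) buildActionMap(curated$actions, m,
                                                 curatedCommon),
                      simplify = FALSE)

# Three-map bundle over a universe from a bare edge table; maps not named
# in `edges` stay empty.
mapsFromEdges <- function(universe, edges = list()) {
  sapply(c("expression", "activation", "inhibition"), function(m) {
    ed <- edges[[m]]
    rec <- if (is.null(ed))
      data.frame(source = character(), target = character(),
                 mode = character(), sign = character(),
                 directed = logical(), stringsAsFactors = FALSE)
    else
      data.frame(source = ed$source, target = ed$target, mode = m,
                 sign = if (m == "activation") "positive"
                        else if (m == "inhibition") "negative"
                        else "positive",
                 directed = TRUE, stringsAsFactors = FALSE)
    buildActionMap(rec, m, universe)
  }, simplify = FALSE)
}

# Interaction network wrapping an igraph graph (for distribution checks).
networkFromIgraph <- function(g, name = "g") {
  el <- igraph::as_edgelist(g, names = FALSE)
  buildNetwork(data.frame(proteinA = sprintf("N%04d", el[, 1]),
                          proteinB = sprintf("N%04d", el[, 2]),
                          combinedScore = 500L), name)
}
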