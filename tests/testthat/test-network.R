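test_that("network construction drops self-loops and merges duplicates at max score", {
  net <- buildNetwork(data.frame(proteinA = c("A", "B", "C"),
                                 proteinB = c("B", "A", "C"),
                                 combinedScore = c(900L, 700L, 999L)), "toy")
  expect_setequal(nodeSet(net), c("A", "B"))
  ed <- edgeTable(net)
  expect_equal(nrow(ed), 1L)
  expect_equal(ed$score, 900L)
  expect_warning(empty <- buildNetwork(
    data.frame(proteinA = character(), proteinB = character(),
               combinedScore = integer()), "none"), "empty")
  expect_length(nodeSet(empty), 0L)
  expect_equal(nrow(edgeTable(empty)), 0L)
})

test_that("edge count equals a brute-force count of distinct unordered pairs", {
  rec <- randomInteractionRecords(200, nSymbols = 25, seed = 11,
                                 allowSelf = TRUE)
  net <- buildNetwork(rec, "random")
  keep <- rec$proteinA != rec$proteinB
  pairKeys <- unique(paste(pmin(rec$proteinA, rec$proteinB)[keep],
                           pmax(rec$proteinA, rec$proteinB)[keep]))
  expect_equal(nrow(edgeTable(net)), length(pairKeys))
  # per-pair retained score is the max over duplicate rows
  ed <- edgeTable(net)
  for (i in seq_len(nrow(ed))) {
    dup <- keep & pmin(rec$proteinA, rec$proteinB) == ed$from[i] &
      pmax(rec$proteinA, rec$proteinB) == ed$to[i]
    expect_equal(ed$score[i], max(rec$combinedScore[dup]))
  }
})

test_that("network construction is idempotent under record duplication", {
  rec <- randomInteractionRecords(80, seed = 3)
  once <- buildNetwork(rec, "x")
  twice <- buildNetwork(rbind(rec, rec), "x")
  expect_equal(edgeTable(once), edgeTable(twice))
  expect_equal(nodeSet(once), nodeSet(twice))
})

test_that("degree summed over nodes equals twice the edge count", {
  for (seed in 1:5) {
    net <- buildNetwork(randomInteractionRecords(120, seed = seed), "p")
    tab <- degreeTable(net)
    expect_equal(sum(tab$degree), 2L * nrow(edgeTable(net)))
  }
})

test_that("action maps keep the full universe and filter edges correctly", {
  act <- randomActionRecords(50, seed = 21)
  universe <- sprintf("P%03d", 1:8)
  for (m in c("expression", "activation", "inhibition")) {
    amap <- buildActionMap(act, m, universe)
    expect_setequal(nodeSet(amap), universe)
    expect_equal(mapMode(amap), m)
    # brute-force filter: directed, right mode, both endpoints in universe
    want <- act[act$directed & act$mode == m &
                act$source %in% universe & act$target %in% universe &
                act$source != act$target,
                c("source", "target", "sign")]
    want <- unique(want)
    got <- edgeTable(amap)
    expect_setequal(paste(got$source, got$target, got$sign),
                    paste(want$source, want$target, want$sign))
  }
  # universe disjoint from all endpoints: no edges, universe intact
  far <- c("Q1", "Q2", "Q3")
  amap <- buildActionMap(act, "activation", far)
  expect_equal(nrow(edgeTable(amap)), 0L)
  expect_length(nodeSet(amap), 3L)
})

test_that("curated inhibition map carries the published central-node inhibitions", {
  ed <- edgeTable(curatedMaps$inhibition)
  expect_true(any(ed$source == "AKT1" & ed$target == "TP53" &
                  ed$sign == "negative"))
  expect_true(any(ed$source == "CDKN2A" & ed$target == "TP53" &
                  ed$sign == "negative"))
})

test_that("graphs export to SIF and edge-list TSV", {
  net <- buildNetwork(data.frame(proteinA = c("A", "B"),
                                 proteinB = c("B", "C"),
                                 combinedScore = c(500L, 600L)), "toy")
  f <- withr::local_tempfile(fileext = ".sif")
  exportSIF(net, f)
  sif <- read.delim(f, header = FALSE)
  expect_equal(sif$V2, c("pp", "pp"))
  expect_equal(sort(sif$V1), c("A", "B"))
  amap <- buildActionMap(
    data.frame(source = "A", target = "B", mode = "inhibition",
               sign = "negative", directed = TRUE),
    "inhibition", c("A", "B"))
  exportSIF(amap, f)
  sif <- read.delim(f, header = FALSE)
  expect_equal(unlist(sif), c(V1 = "A", V2 = "inhibition", V3 = "B"))
  g <- withr::local_tempfile(fileext = ".tsv")
  exportEdgeList(net, g)
  expect_equal(read.delim(g), edgeTable(net), ignore_attr = TRUE)
})
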