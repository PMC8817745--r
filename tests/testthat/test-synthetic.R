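test_that("generator output is fully reproducible from the seed", {
  p1 <- generatePair(syntheticConfig(seed = 123L))
  p2 <- generatePair(syntheticConfig(seed = 123L))
  expect_identical(edgeTable(p1$networkA), edgeTable(p2$networkA))
  expect_identical(edgeTable(p1$networkB), edgeTable(p2$networkB))
  expect_identical(p1$actions, p2$actions)
  expect_identical(plantedCore(p1$truth), plantedCore(p2$truth))
  expect_identical(plantedRegulators(p1$truth),
                   plantedRegulators(p2$truth))
  p3 <- generatePair(syntheticConfig(seed = 124L))
  expect_false(identical(edgeTable(p1$networkA), edgeTable(p3$networkA)))
})

test_that("infeasible generator configs are rejected", {
  expect_error(syntheticConfig(coreSize = 25, k = 20), "coreSize")
  expect_error(syntheticConfig(k = 50, nNodes = 40), "nNodes")
  expect_error(syntheticConfig(nRegulators = 18, coreSize = 18), "central")
  expect_error(syntheticConfig(actionDensity = 1.5), "actionDensity")
})

test_that("with density 0 the critical set is exactly the forced regulators", {
  cfg <- syntheticConfig(actionDensity = 0, seed = 55L)
  pair <- generatePair(cfg)
  common <- plantedCore(pair$truth)
  ta <- degreeTable(pair$networkA)
  tb <- degreeTable(pair$networkB)
  deg <- data.frame(symbol = common,
                    kLiver = ta$degree[match(common, ta$symbol)],
                    kPancreas = tb$degree[match(common, tb$symbol)])
  maps <- sapply(c("expression", "activation", "inhibition"),
                 function(m) buildActionMap(pair$actions, m, common),
                 simplify = FALSE)
  sc <- screenCriticalHubs(common, maps, deg)
  expect_equal(criticalSet(sc), plantedRegulators(pair$truth))
  expect_equal(centralNode(sc), centralNode(pair$truth))
})

test_that("separated mode plants every top hub above the background", {
  pair <- generatePair(syntheticConfig(seed = 8L))
  tr <- pair$truth
  ta <- degreeTable(pair$networkA)
  plantedA <- c(plantedCore(tr), tr@plantedSpecificA)
  bgMax <- max(ta$degree[!ta$symbol %in% plantedA])
  expect_true(min(ta$degree[ta$symbol %in% plantedA]) > bgMax)
  expect_setequal(selectTopHubs(ta, 20), plantedA)
})

test_that("overlapping mode yields valid networks without degree separation", {
  pair <- generatePair(syntheticConfig(separation = "overlapping", seed = 5L))
  expect_s4_class(pair$networkA, "InteractionNetwork")
  tab <- degreeTable(pair$networkA)
  expect_equal(sum(tab$degree), 2L * nrow(edgeTable(pair$networkA)))
})

test_that("generated TSVs round-trip through the readers", {
  pair <- generatePair(syntheticConfig(nNodes = 120L, seed = 31L))
  dir <- withr::local_tempdir()
  writeSyntheticData(pair, dir)
  net <- buildNetwork(readInteractions(file.path(dir, "links_a.tsv"), 0),
                      "synthetic_A")
  expect_equal(edgeTable(net), edgeTable(pair$networkA))
  act <- readActions(file.path(dir, "actions.tsv"))
  expect_equal(act, pair$actions, ignore_attr = TRUE)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$regulators, plantedRegulators(pair$truth))
})

test_that("tail-exponent check separates heavy-tailed from degenerate graphs", {
  star <- buildNetwork(data.frame(proteinA = "HUB",
                                  proteinB = sprintf("L%03d", 1:150),
                                  combinedScore = 500L), "star")
  expect_warning(slope <- degreeDistributionCheck(star), "degenerate")
  expect_true(is.na(slope))
  tiny <- buildNetwork(randomInteractionRecords(30, nSymbols = 20, seed = 2),
                       "tiny")
  expect_error(degreeDistributionCheck(tiny), "100")
  set.seed(17)
  pa <- networkFromIgraph(
    igraph::sample_pa(1000, power = 1, m = 2, directed = FALSE), "pa")
  expect_lt(as.numeric(degreeDistributionCheck(pa)), -1)
  expect_true(passesTailCheck(pa))
  expect_false(passesTailCheck(star))
})

test_that("preferential attachment passes the tail check more often than random graphs", {
  paPass <- erPass <- logical(20)
  for (s in 1:20) {
    set.seed(1000 + s)
    gpa <- igraph::sample_pa(400, power = 1, m = 2, directed = FALSE)
    ger <- igraph::sample_gnm(400, igraph::ecount(gpa))
    paPass[s] <- passesTailCheck(networkFromIgraph(gpa))
    erPass[s] <- passesTailCheck(networkFromIgraph(ger))
  }
  expect_gt(sum(paPass), sum(erPass))
})
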