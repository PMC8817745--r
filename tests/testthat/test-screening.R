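test_that("role classification follows the out/in-degree definitions", {
  maps <- mapsFromEdges(c("X", "Y", "Z"),
                        list(activation = data.frame(source = "X",
                                                     target = "Y")))
  roles <- classifyRoles(maps)
  expect_equal(roles$activation[roles$symbol == "X"], "regulator")
  expect_equal(roles$activation[roles$symbol == "Y"], "regulated_only")
  expect_equal(roles$activation[roles$symbol == "Z"], "isolated")
  expect_equal(roles$overall, c("regulator", "regulated_only", "isolated"))
  # maps over different universes are rejected
  bad <- maps
  bad$expression <- buildActionMap(
    data.frame(source = character(), target = character(),
               mode = character(), sign = character(), directed = logical()),
    "expression", c("X", "Y"))
  expect_error(classifyRoles(bad), "universe")
})

test_that("curated maps classify the published roles", {
  roles <- classifyRoles(curatedMaps)
  expect_equal(roles$overall[roles$symbol == "VEGFA"], "isolated")
  expect_equal(roles$overall[roles$symbol == "MYC"], "isolated")
  expect_equal(roles$activation[roles$symbol == "PTEN"], "regulated_only")
  expect_equal(roles$overall[roles$symbol == "ALB"], "regulated_only")
  expect_equal(roles$overall[roles$symbol == "GAPDH"], "regulated_only")
  expect_equal(roles$overall[roles$symbol == "TP53"], "regulator")
})

test_that("central node maximizes summed degree with alphabetical ties", {
  expect_equal(pickCentralNode(curated$hubDegrees), "TP53")
  one <- data.frame(symbol = "AKT1", kLiver = 1L, kPancreas = 1L)
  expect_equal(pickCentralNode(one), "AKT1")
  tie <- data.frame(symbol = c("ZZZ", "AAA"), kLiver = c(5L, 5L),
                    kPancreas = c(5L, 5L))
  expect_equal(pickCentralNode(tie), "AAA")
  expect_equal(pickCentralNode(tie, override = "ZZZ"), "ZZZ")
  expect_error(pickCentralNode(tie, common = c("AAA", "MISSING")), "MISSING")
})

test_that("regulator lookup collects per-map signed evidence", {
  regs <- findRegulators(curatedMaps, "TP53")
  expect_setequal(names(regs), c("AKT1", "CDKN2A", "ERBB2", "IL6"))
  cdk <- regs$CDKN2A
  expect_true(any(cdk$map == "inhibition" & cdk$sign == "negative"))
  expect_true(any(cdk$map == "activation" & cdk$sign == "positive"))
  akt <- regs$AKT1  # contradictory relations all retained
  expect_true(all(c("positive", "negative") %in%
                  akt$sign[akt$map == "expression"]))
  expect_length(findRegulators(curatedMaps, "CCND1"), 0L)
  expect_error(findRegulators(curatedMaps, "NOTCH1"), "universe")
})

test_that("screening the curated hubs yields the published critical core", {
  sc <- screenCriticalHubs(curatedCommon, curatedMaps, curated$hubDegrees)
  expect_equal(criticalSet(sc), c("AKT1", "CDKN2A", "ERBB2", "IL6"))
  expect_equal(centralNode(sc), "TP53")
  ex <- excludedNodes(sc)
  expect_equal(unname(ex["VEGFA"]), "isolated_all_maps")
  expect_equal(unname(ex["MYC"]), "isolated_all_maps")
  expect_equal(unname(ex["ALB"]), "regulated_only")
  expect_equal(unname(ex["GAPDH"]), "regulated_only")
  expect_equal(unname(ex["TP53"]), "generic_central")
  expect_length(intersect(criticalSet(sc), names(ex)), 0L)
})

test_that("screening with edgeless maps isolates every non-central node", {
  universe <- c("A", "B", "C", "D")
  deg <- data.frame(symbol = universe, kLiver = c(4L, 3L, 2L, 1L),
                    kPancreas = c(4L, 3L, 2L, 1L))
  sc <- screenCriticalHubs(universe, mapsFromEdges(universe), deg)
  expect_length(criticalSet(sc), 0L)
  ex <- excludedNodes(sc)
  expect_equal(unname(ex["A"]), "generic_central")
  expect_true(all(ex[c("B", "C", "D")] == "isolated_all_maps"))
})

test_that("adding a survivor-to-central edge can only grow the critical set", {
  universe <- curatedCommon
  base <- screenCriticalHubs(universe, curatedMaps, curated$hubDegrees)
  # ESR1 survives screening (it regulates GAPDH) but is not critical
  expect_false("ESR1" %in% criticalSet(base))
  aug <- curated$actions
  aug <- rbind(aug, data.frame(source = "ESR1", target = "TP53",
                               mode = "inhibition", sign = "negative",
                               directed = TRUE))
  maps2 <- sapply(c("expression", "activation", "inhibition"),
                  function(m) buildActionMap(aug, m, universe),
                  simplify = FALSE)
  grown <- screenCriticalHubs(universe, maps2, curated$hubDegrees)
  expect_true(all(criticalSet(base) %in% criticalSet(grown)))
  expect_true("ESR1" %in% criticalSet(grown))
})

test_that("screening is invariant to edge order and symbol relabeling", {
  set.seed(99)
  shuffled <- curated$actions[sample(nrow(curated$actions)), ]
  mapsShuf <- sapply(c("expression", "activation", "inhibition"),
                     function(m) buildActionMap(shuffled, m, curatedCommon),
                     simplify = FALSE)
  base <- screenCriticalHubs(curatedCommon, curatedMaps, curated$hubDegrees)
  shuf <- screenCriticalHubs(curatedCommon, mapsShuf, curated$hubDegrees)
  expect_equal(criticalSet(shuf), criticalSet(base))
  expect_equal(excludedNodes(shuf)[order(names(excludedNodes(shuf)))],
               excludedNodes(base)[order(names(excludedNodes(base)))])

  # structure-preserving relabeling: G0xx aliases, order-preserving so the
  # alphabetical tie-breaks map through the bijection
  relab <- setNames(sprintf("G%03d", seq_along(curatedCommon)),
                    sort(curatedCommon))
  act2 <- curated$actions
  act2$source <- unname(relab[act2$source])
  act2$target <- unname(relab[act2$target])
  deg2 <- curated$hubDegrees
  deg2$symbol <- unname(relab[deg2$symbol])
  uni2 <- unname(relab[curatedCommon])
  maps3 <- sapply(c("expression", "activation", "inhibition"),
                  function(m) buildActionMap(act2, m, uni2),
                  simplify = FALSE)
  rel <- screenCriticalHubs(uni2, maps3, deg2)
  expect_equal(criticalSet(rel), sort(unname(relab[criticalSet(base)])))
  expect_equal(centralNode(rel), unname(relab[centralNode(base)]))
})
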