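test_that("validation reports nothing on a well-formed model and names offenders otherwise", {
  expect_length(validateModel(toyChain3()), 0)

  ## consumer diet column summing to 0.9
  g <- groupTable(toyChain3())
  d <- dietMatrix(toyChain3())
  d[1, 2] <- 0.9
  broken <- FoodWebModel(g, d, validate = FALSE)
  v <- validateModel(broken)
  expect_true(any(grepl("diet column of consumer 2", v)))

  ## production exceeding assimilated consumption
  g2 <- g
  g2$pb[3] <- 10                       # ae*qb = 0.8*2 = 1.6 < 10
  broken2 <- FoodWebModel(g2, dietMatrix(toyChain3()), validate = FALSE)
  v2 <- validateModel(broken2)
  expect_true(any(grepl("group 3 .*pb .*exceeds ae\\*qb", v2)))

  ## non-square diet is a structural error
  expect_error(FoodWebModel(g, d[, 1:2]), "square")
})

test_that("ecotrophic efficiency follows the mass-balance arithmetic", {
  ## demand 1*5*1 = 5 against production 10*1 = 10
  ee <- eeVector(computeEE(toyProducerHerbivore(qbHerb = 5)))
  expect_equal(unname(ee["1"]), 0.5)
  expect_equal(unname(ee["2"]), 0)     # nothing consumes the herbivore
  expect_true(isBalanced(toyProducerHerbivore(qbHerb = 5)))

  ## demand 25 against production 10: unbalanced but still reported
  m <- toyProducerHerbivore(qbHerb = 25)
  expect_equal(unname(eeVector(m)["1"]), 2.5)
  expect_false(isBalanced(m))

  ## zero production under positive demand is a hard error naming the group
  g <- groupTable(toyProducerHerbivore())
  g$pb[1] <- 0
  broken <- FoodWebModel(g, dietMatrix(toyProducerHerbivore()))
  expect_error(computeEE(broken), "group 1.*zero production")
})

test_that("consumption fluxes are B*QB*DC with landings on fleet edges", {
  ## B_j = 2, qb_j = 10, DC[i,j] = 0.25 -> q = 5
  groups <- data.frame(
    id = 1:3, name = c("preyA", "preyB", "cons"),
    type = rep("living", 3),
    biomass = c(50, 50, 2), pb = c(5, 5, 1), qb = c(0, 0, 10),
    ae = c(0.9, 0.9, 0.8))
  d <- matrix(0, 3, 3)
  d[1, 3] <- 0.25
  d[2, 3] <- 0.75
  m <- FoodWebModel(groups, d)
  q <- fluxMatrix(consumptionFlux(m))
  expect_equal(q["1", "3"], 5)
  expect_equal(q["2", "3"], 15)
  expect_equal(q["3", "1"], 0)         # DC = 0 -> no edge
  ## inflow of a consumer with a unit diet column is its total consumption
  expect_equal(sum(q[, "3"]), 2 * 10)

  ## fleet edges carry the landings rates
  m2 <- generateWeb(syntheticWebSpec(nLiving = 8, seed = 11))
  q2 <- fluxMatrix(consumptionFlux(m2))
  fl <- as.character(groupIdsOfType(m2, "fleet"))
  expect_equal(q2[, fl], landingsMatrix(m2)[, fl])
})

test_that("production fate splits consumption exactly as egestion/metabolism/predation/senescence", {
  f <- buildProductionFate(fateToy())
  fm <- fateMatrix(f)
  focal <- "3"
  ## hand arithmetic: Q = 10, ae = 0.8, pb/qb = 0.3, ee = 0.8
  expect_equal(sum(f@egestion[focal, ]), 0.2, tolerance = 1e-12)
  expect_equal(sum(f@metabolism[focal, ]), 0.5, tolerance = 1e-12)
  expect_equal(sum(f@predation[focal, ]), 0.24, tolerance = 1e-12)
  expect_equal(sum(f@senescence[focal, ]), 0.06, tolerance = 1e-12)
  expect_equal(unname(rowSums(fm)), rep(1, nrow(fm)))

  ## ee = 1 kills senescence: crank the predator up to consume all production
  m <- fateToy()
  g <- groupTable(m)
  g$qb[5] <- 5                        # flux on focal = 0.6*5 = 3 = production
  m2 <- FoodWebModel(g, dietMatrix(m))
  f2 <- buildProductionFate(m2)
  expect_equal(sum(f2@senescence["3", ]), 0, tolerance = 1e-12)

  ## ae = 1 with pb/qb = 1: everything is consumed production
  g3 <- g
  g3$ae[3] <- 1; g3$pb[3] <- 10; g3$qb[5] <- 4
  f3 <- buildProductionFate(FoodWebModel(g3, dietMatrix(m)))
  expect_equal(sum(f3@egestion["3", ]), 0)
  expect_equal(sum(f3@metabolism["3", ]), 0)
  expect_equal(sum(f3@predation["3", ]) + sum(f3@senescence["3", ]), 1)

  ## ae below pb/qb (negative metabolism) is caught by validation
  g4 <- groupTable(fateToy())
  g4$ae[3] <- 0.2                     # below pb/qb = 0.3
  broken <- FoodWebModel(g4, dietMatrix(fateToy()), validate = FALSE)
  expect_error(buildProductionFate(broken), "exceeds ae\\*qb")
})

test_that("aggregation merges by biomass-weighted diets and conserves totals", {
  ## two consumers B = 2 and B = 8 with diets (1,0) and (0.5,0.5)
  groups <- data.frame(
    id = 1:4, name = c("preyA", "preyB", "consSmall", "consBig"),
    type = rep("living", 4),
    biomass = c(100, 100, 2, 8), pb = c(5, 5, 1, 2), qb = c(0, 0, 4, 6),
    ae = c(0.9, 0.9, 0.8, 0.8))
  d <- matrix(0, 4, 4)
  d[1, 3] <- 1
  d[1, 4] <- 0.5
  d[2, 4] <- 0.5
  m <- FoodWebModel(groups, d)
  merged <- aggregateGroups(m, data.frame(old_id = 1:4, new_id = c(1, 2, 3, 3)))
  dm <- dietMatrix(merged)
  expect_equal(unname(dm[c("1", "2"), "3"]), c(0.6, 0.4))
  expect_equal(groupTable(merged)$biomass[3], 10)

  ## total system consumption is invariant
  expect_equal(sum(fluxMatrix(consumptionFlux(merged))[, c("1", "2", "3")]),
               sum(fluxMatrix(consumptionFlux(m))), tolerance = 1e-9)

  ## identity mapping leaves the model unchanged
  idm <- aggregateGroups(m, data.frame(old_id = 1:4, new_id = 1:4))
  expect_equal(groupTable(idm)$biomass, groupTable(m)$biomass)
  expect_equal(unname(dietMatrix(idm)), unname(dietMatrix(m)))

  ## merging across types is refused
  g2 <- groups; g2$type[2] <- "detritus"; d2 <- d; d2[2, 4] <- 0; d2[1, 4] <- 1
  m2 <- FoodWebModel(g2, d2)
  expect_error(aggregateGroups(m2, data.frame(old_id = 1:4, new_id = c(1, 1, 3, 4))),
               "across group types")
})

test_that("trace-group insertion adds a tiny node and respects conservation", {
  m <- toyChain3()
  m2 <- addTraceGroup(m, "pyrosome", biomass = 1e-5, pb = 10, qb = 30,
                      ae = 0.7, diet = c("1" = 1))
  expect_equal(nGroups(m2), 4)
  expect_equal(groupTable(m2)$biomass[4], 1e-5)
  expect_length(validateModel(m2), 0)
  expect_error(addTraceGroup(m2, "pyrosome", diet = c("1" = 1)),
               "already present")
  expect_error(addTraceGroup(m, "ghost", biomass = 0, diet = c("1" = 1)),
               "biomass > 0")

  ## aggregate it back into the herbivore: biomass conserved
  merged <- aggregateGroups(m2, data.frame(old_id = 1:4, new_id = c(1, 2, 3, 2)))
  expect_equal(sum(groupTable(merged)$biomass), sum(groupTable(m2)$biomass))
})

test_that("diet columns stay unit-sum through every diet-editing operation", {
  m <- generateWeb(syntheticWebSpec(nLiving = 15, seed = 21))
  checkCols <- function(model) {
    g <- groupTable(model)
    cs <- colSums(dietMatrix(model))[g$type == "living" & g$qb > 0]
    expect_true(all(abs(cs - 1) <= 1e-9))
  }
  checkCols(m)
  checkCols(addTraceGroup(m, "invader", diet = c("1" = 0.3, "2" = 0.7),
                          predators = c("10" = 0.01)))
  mapping <- data.frame(old_id = groupIds(m), new_id = groupIds(m))
  mapping$new_id[mapping$old_id == 4] <- 3
  checkCols(aggregateGroups(m, mapping))
  d <- dietMatrix(m)
  pos <- which(d > 0, arr.ind = TRUE)
  keep <- pos[-1, , drop = FALSE]      # drop one evidenced link
  ev <- data.frame(prey = as.integer(rownames(d)[keep[, 1]]),
                   predator = as.integer(colnames(d)[keep[, 2]]))
  checkCols(pruneCarryoverLinks(m, ev)$model)
})
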