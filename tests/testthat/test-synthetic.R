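test_that("generated webs validate, balance, and reproduce bitwise under a seed", {
  for (seed in c(2, 7, 19)) {
    m <- generateWeb(syntheticWebSpec(nLiving = 20, seed = seed))
    expect_length(validateModel(m), 0)
    ee <- eeVector(m)
    expect_true(all(ee <= 1 + 1e-9))
    g <- groupTable(m)
    cs <- colSums(dietMatrix(m))[g$type == "living" & g$qb > 0]
    expect_true(all(abs(cs - 1) <= 1e-9))
  }
  s <- syntheticWebSpec(nLiving = 15, seed = 4)
  expect_identical(dietMatrix(generateWeb(s)), dietMatrix(generateWeb(s)))
  expect_identical(groupTable(generateWeb(s)), groupTable(generateWeb(s)))
})

test_that("the default-size web mirrors the study structure and balances", {
  m <- generateWeb(syntheticWebSpec(seed = 1))
  g <- groupTable(m)
  expect_equal(sum(g$type == "living"), 80)
  expect_equal(sum(g$type == "nutrient"), 3)
  expect_equal(sum(g$type == "detritus"), 5)
  expect_equal(sum(g$type == "fleet"), 2)
  expect_true(all(eeVector(m) <= 1 + 1e-9))
  expect_true(all(pedigreeCVs(m)$diet %in% c(0, 0.1, 0.5, 0.8)))
})

test_that("chain topology yields the staircase of trophic levels", {
  m <- generateWeb(syntheticWebSpec(nLiving = 4, topology = "chain", seed = 2))
  g <- groupTable(m)
  living <- as.character(g$id[g$type == "living"])
  tl <- trophicLevels(m)[living]
  expect_equal(unname(tl), c(1, 2, 3, 4), tolerance = 1e-9)
})

test_that("infeasible guild structures are rejected", {
  expect_error(syntheticWebSpec(nNutrient = 0), "nutrient")
  expect_error(
    generateWeb(syntheticWebSpec(
      nLiving = 4,
      guildProportions = c(producer = 0.5, herbivore = 0, omnivore = 0,
                           carnivore = 0.5), seed = 1)),
    "infeasible")
})

test_that("model pairs carry a recoverable ground truth", {
  sp <- syntheticWebSpec(nLiving = 12, seed = 9)
  base <- generateWeb(sp)
  d <- dietMatrix(base)
  pos <- which(d > 0, arr.ind = TRUE)
  ## pick a removable link whose predator keeps some diet
  k <- which(vapply(seq_len(nrow(pos)),
                    function(i) sum(d[, pos[i, 2]] > 0) > 1, TRUE))[1]
  rl <- data.frame(prey = as.integer(rownames(d)[pos[k, 1]]),
                   predator = as.integer(colnames(d)[pos[k, 2]]))
  pert <- list(
    biomassFactors = setNames(3, groupIds(base)[1]),
    removeLinks = rl,
    invader = list(name = "invader", biomass = 1,
                   pb = 10, qb = 30, ae = 0.7,
                   diet = setNames(1, groupIds(base)[1])))
  pair <- generateModelPair(sp, pert, seed = 9)
  expect_length(validateModel(pair$after), 0)
  expect_true(all(eeVector(pair$after) <= 1 + 1e-9))

  ## injected biomass factors recovered exactly by the difference network
  h <- harmonizeModels(pair$before, pair$after)
  nd <- diffNodes(differenceNetwork(h$A, h$B))
  expect_equal(nd$factor[nd$id == groupIds(base)[1]], 3, tolerance = 1e-12)
  expect_equal(nd$factor[nd$name == "invader"], 1 / 1e-5, tolerance = 1e-9)
  untouched <- setdiff(nd$id[nd$type == "living"],
                       c(groupIds(base)[1],
                         nd$id[nd$name == "invader"]))
  expect_true(all(nd$factor[nd$id %in% untouched] == 1))

  ## injected link removal recovered exactly by the pruning report
  dm <- dietMatrix(pair$after)
  posAfter <- which(dm > 0, arr.ind = TRUE)
  ev <- data.frame(prey = as.integer(rownames(dm)[posAfter[, 1]]),
                   predator = as.integer(colnames(dm)[posAfter[, 2]]))
  idsBefore <- groupIds(pair$before)
  ev <- ev[ev$prey %in% idsBefore & ev$predator %in% idsBefore, ]
  rep <- pruneCarryoverLinks(pair$before, ev)$report
  expect_true(any(rep$prey == rl$prey & rep$predator == rl$predator))

  ## an empty perturbation gives the identity difference
  pair0 <- generateModelPair(sp, list(), seed = 9)
  dn0 <- differenceNetwork(pair0$before, pair0$after)
  expect_true(all(diffNodes(dn0)$factor == 1))
  expect_true(all(deltaMatrix(dn0) == 0))
})

test_that("halving a consumer's biomass reduces its footprint", {
  drops <- 0; total <- 0
  for (seed in 1:20) {
    sp <- syntheticWebSpec(nLiving = 8, seed = seed)
    base <- generateWeb(sp)
    g <- groupTable(base)
    cand <- g$id[g$type == "living" & g$qb > 0 &
                 grepl("herbivore|omnivore|carnivore", g$name)]
    if (!length(cand)) next
    f <- as.character(cand[1])
    fpBefore <- footprint(base, f)
    if (fpBefore <= 0) next
    pair <- generateModelPair(
      sp, list(biomassFactors = setNames(0.5, f)), seed = seed)
    fpAfter <- footprint(pair$after, f)
    total <- total + 1
    if (fpAfter < fpBefore + 1e-12) drops <- drops + 1
  }
  expect_gt(total, 10)
  expect_equal(drops, total)
})

test_that("ensemble footprint converges to the base value as CVs shrink", {
  m <- generateWeb(syntheticWebSpec(nLiving = 8, seed = 3))
  focal <- groupTable(m)$name[grep("carnivore|omnivore",
                                   groupTable(m)$name)][1]
  base <- footprint(m, focal)
  shrink <- function(f) {
    ped <- pedigreeCVs(m)
    ped$params <- ped$params * f
    ped$diet <- ped$diet * f
    mm <- FoodWebModel(groupTable(m), dietMatrix(m),
                       landings = landingsMatrix(m), pedigree = ped)
    ens <- drawEnsemble(mm, n = 150, seed = 5)
    mean(ensembleMetrics(ens, focals = list(f = focal))$f.footprint)
  }
  err1 <- abs(shrink(0.2) - base)
  err0 <- abs(shrink(0.02) - base)
  expect_lt(err0, 0.01 * max(base, 0.01))
  expect_lte(err0, err1 + 1e-9)
})
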