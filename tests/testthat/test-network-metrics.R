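test_that("trophic levels solve the diet-weighted linear system, cycles included", {
  ## producer at 1; chain with a 50/50 top consumer at 1 + 0.5*2 + 0.5*1 = 2.5
  tl <- trophicLevels(toyChain3())
  expect_equal(unname(tl[c("1", "2", "3")]), c(1, 2, 2.5))

  ## mutual predation: two consumers each eating 50% of the other and 50%
  ## producer; the fixed point of TL = 1.5 + 0.5 TL is 3
  d <- matrix(0, 3, 3, dimnames = list(1:3, 1:3))
  d[1, 2] <- 0.5; d[3, 2] <- 0.5
  d[1, 3] <- 0.5; d[2, 3] <- 0.5
  tl2 <- trophicLevels(d)
  expect_equal(unname(tl2), c(1, 3, 3))

  ## a closed consumer loop with no basal path is singular and named
  d3 <- matrix(0, 2, 2, dimnames = list(1:2, 1:2))
  d3[1, 2] <- 1; d3[2, 1] <- 1
  expect_error(trophicLevels(d3), "singular")
})

test_that("trophic-level solver matches the path-series oracle on acyclic webs", {
  for (seed in 1:25) {
    m <- randomSmallWeb(seed)
    nodes <- analyzedNodes(m)
    ids <- as.character(nodes)
    d <- dietMatrix(m)[ids, ids]
    fl <- as.character(groupIdsOfType(m, "fleet"))
    for (f in intersect(ids, fl)) {
      y <- landingsMatrix(m)[ids, f]
      if (sum(y) > 0) d[, f] <- y / sum(y)
    }
    expect_equal(trophicLevels(m, nodes), oracleTrophicLevels(d),
                 tolerance = 1e-9)
  }
})

test_that("mean and biomass-weighted trophic levels are the stated averages", {
  expect_equal(meanTrophicLevel(c(1, 2, 3)), 2)
  expect_equal(biomassWeightedTL(c(1, 3), c(3, 1)), 1.5)    # (3*1 + 1*3)/4
  tl <- c(a = 1.2, b = 2.8, c = 3.1)
  expect_equal(biomassWeightedTL(tl, rep(4, 3)), meanTrophicLevel(tl))
  expect_error(biomassWeightedTL(tl, rep(0, 3)), "all-zero biomass")
})

test_that("connectance uses the N^2 denominator and link density is connectance * N", {
  ## 3 nodes, 4 links
  a <- matrix(0, 3, 3)
  a[1, 2] <- a[1, 3] <- a[2, 3] <- a[3, 3] <- 1
  expect_equal(connectance(a), 4 / 9)
  expect_equal(linkDensity(a), 4 / 3)

  ## fully connected: connectance 1, density N (self-links possible)
  full <- matrix(1, 86, 86)
  expect_equal(connectance(full), 1)
  expect_equal(linkDensity(full), 86)
  expect_equal(sum(full > 0), 7396)

  ## identity link_density = connectance * N on random matrices
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(3:40, 1)
    a <- matrix(rbinom(n^2, 1, runif(1, 0.05, 0.9)), n, n)
    expect_equal(linkDensity(a), connectance(a) * n)
  }
  expect_error(connectance(matrix(numeric(0), 0, 0)), "empty")
})

test_that("trophic adjacency counts diet and landings support, on the nutrient-free node set", {
  m <- generateWeb(syntheticWebSpec(nLiving = 10, seed = 31))
  nodes <- analyzedNodes(m)
  expect_false(any(groupIdsOfType(m, "nutrient") %in% nodes))
  a <- trophicAdjacency(m)
  ids <- as.character(nodes)
  d <- dietMatrix(m)[ids, ids]
  fl <- as.character(groupIdsOfType(m, "fleet"))
  nonFleet <- setdiff(ids, fl)
  expect_equal(unname(a[, nonFleet]), unname(((d > 0) * 1)[, nonFleet]))
  expect_equal(unname(a[, fl]),
               unname((landingsMatrix(m)[ids, fl] > 0) * 1))
})

test_that("node bootstrap is reproducible and degenerate cases are exact", {
  full <- matrix(1, 12, 12)
  b <- bootstrapMetrics(full, nBoot = 20, seed = 4)
  expect_true(all(b$replicates$connectance == 1))
  expect_equal(b$summary$sd, c(0, 0))

  empty <- matrix(0, 12, 12)
  b0 <- bootstrapMetrics(empty, nBoot = 20, seed = 4)
  expect_true(all(b0$replicates$connectance == 0))
  expect_true(all(b0$replicates$link_density == 0))

  a <- matrix(rbinom(400, 1, 0.3), 20, 20)
  expect_identical(bootstrapMetrics(a, nBoot = 50, seed = 7)$replicates,
                   bootstrapMetrics(a, nBoot = 50, seed = 7)$replicates)
})

test_that("bootstrap mean connectance converges to the true connectance", {
  ## adjacency built so diagonal density equals overall density exactly
  ## (160 of 400 cells, 8 of 20 diagonal): the resampling expectation is
  ## then exactly the true connectance
  set.seed(99)
  n <- 20
  a <- matrix(0, n, n)
  diagCells <- cbind(1:n, 1:n)
  offCells <- which(row(a) != col(a), arr.ind = TRUE)
  a[diagCells[sample(n, 8), ]] <- 1
  a[offCells[sample(nrow(offCells), 152), ]] <- 1
  expect_equal(sum(a > 0), 160)
  trueConn <- connectance(a)
  b <- bootstrapMetrics(a, nBoot = 1e4, seed = 12)
  se <- b$summary$sd[1] / sqrt(1e4)
  expect_lt(abs(b$summary$mean[1] - trueConn), 3 * se)
})
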