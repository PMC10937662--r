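test_that("an all-zero-CV ensemble reproduces the base model exactly", {
  m <- toyChain3()                     # pedigree defaults to all zeros
  ens <- drawEnsemble(m, n = 5, seed = 3)
  for (d in ensembleDraws(ens)) {
    expect_identical(groupTable(d)$biomass, groupTable(m)$biomass)
    expect_identical(dietMatrix(d), dietMatrix(m))
  }
})

test_that("truncated-normal sampling reproduces the censored-normal mean", {
  ## one parameter with cv = 0.5: E[max(0, N(mu, 0.5 mu))] =
  ## mu*pnorm(2) + 0.5*mu*dnorm(2)
  m <- toyChain3()
  ped <- pedigreeCVs(m)
  ped$params["1", "biomass"] <- 0.5
  m2 <- FoodWebModel(groupTable(m), dietMatrix(m), pedigree = ped)
  n <- 4000
  ens <- drawEnsemble(m2, n = n, seed = 17)
  draws <- vapply(ensembleDraws(ens), function(d) groupTable(d)$biomass[1], 0)
  mu <- groupTable(m)$biomass[1]       # 100
  expected <- mu * pnorm(2) + 0.5 * mu * dnorm(2)
  se <- sd(draws) / sqrt(n)
  expect_lt(abs(mean(draws) - expected), 3 * se)

  ## lognormal alternative: mean matched to the base value
  ensL <- drawEnsemble(m2, n = n, seed = 18, sampling = "lognormal")
  drawsL <- vapply(ensembleDraws(ensL), function(d) groupTable(d)$biomass[1], 0)
  expect_lt(abs(mean(drawsL) - mu), 3 * sd(drawsL) / sqrt(n))
  expect_true(all(drawsL > 0))
})

test_that("ensembles are seed-reproducible and draws stay valid", {
  m <- generateWeb(syntheticWebSpec(nLiving = 10, seed = 5))
  e1 <- drawEnsemble(m, n = 10, seed = 42)
  e2 <- drawEnsemble(m, n = 10, seed = 42)
  for (k in 1:10) {
    expect_identical(dietMatrix(ensembleDraws(e1)[[k]]),
                     dietMatrix(ensembleDraws(e2)[[k]]))
    expect_length(validateModel(ensembleDraws(e1)[[k]]), 0)
  }
})

test_that("Welch t-test matches the closed-form arithmetic", {
  r <- welchTTest(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$t, -3.674235, tolerance = 1e-6)
  expect_equal(r$df, 4)
  expect_equal(r$p, 0.02131164, tolerance = 1e-6)

  same <- welchTTest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  zv <- welchTTest(c(2, 2, 2), c(2, 2, 2))
  expect_equal(zv$t, 0)
  expect_equal(zv$p, 1)
  expect_error(welchTTest(c(2, 2), c(3, 3)), "zero variance")
})

test_that("summary-statistic Welch form reproduces a published comparison row", {
  ## connectance 0.229 +- 0.022 vs 0.251 +- 0.023, n = 100 each:
  ## |t| between 6.7 and 6.9 with df near 198 (inputs rounded to 3 decimals)
  r <- welchTTestStats(0.229, 0.022, 100, 0.251, 0.023, 100)
  expect_gte(abs(r$t), 6.6)
  expect_lte(abs(r$t), 7.0)
  expect_equal(r$df, 197.8, tolerance = 0.005)
  expect_lt(r$p, 1e-9)
})

test_that("Bonferroni correction is min(1, m*p) and order preserving", {
  expect_equal(bonferroni(0.01, m = 5), 0.05)
  expect_equal(bonferroni(0.6, m = 2), 1)
  expect_equal(bonferroni(c(0.2, 0.01, 0.04)), c(0.6, 0.03, 0.12))
  expect_equal(bonferroni(0.2, m = 1), 0.2)
  p <- c(0.001, 0.01, 0.02, 0.4)
  expect_equal(order(bonferroni(p, m = 8)), order(p))
  expect_error(bonferroni(1.2), "0, 1")
  expect_error(bonferroni(c(0.1, 0.2), m = 1), "family size")
})

test_that("ensemble comparison flags a 10-sigma shift and nothing on identical input", {
  set.seed(1)
  a <- data.frame(draw = 1:1000, g.footprint = rnorm(1000, 0.30, 0.01))
  b <- data.frame(draw = 1:1000, g.footprint = rnorm(1000, 0.40, 0.01))
  res <- compareEnsembles(a, b)
  expect_true(res$significant)
  expect_equal(res$p_adjusted, min(1, res$p))

  resSame <- compareEnsembles(a, a)
  expect_false(any(resSame$significant))
  expect_error(compareEnsembles(a, data.frame(draw = 1:3, other = 1:3)),
               "metric sets differ")

  ## doubling the family size doubles adjusted p until the cap
  res2 <- compareEnsembles(a, b, m = 2)
  expect_equal(res2$p_adjusted, pmin(1, 2 * res$p_adjusted))
})

test_that("ensemble metric spread scales linearly with a global CV multiplier", {
  m <- generateWeb(syntheticWebSpec(nLiving = 8, seed = 13))
  scaleCV <- function(model, f) {
    ped <- pedigreeCVs(model)
    ped$params <- ped$params * f
    ped$diet <- ped$diet * f
    FoodWebModel(groupTable(model), dietMatrix(model),
                 landings = landingsMatrix(model), pedigree = ped)
  }
  focal <- groupTable(m)$name[grep("carnivore|omnivore", groupTable(m)$name)][1]
  sdAt <- function(f) {
    ens <- drawEnsemble(scaleCV(m, f), n = 400, seed = 7)
    sd(ensembleMetrics(ens, focals = list(f = focal))$f.footprint)
  }
  s1 <- sdAt(0.0625)
  s2 <- sdAt(0.125)
  expect_equal(s2 / s1, 2, tolerance = 0.35)
})

test_that("family-wise type-I error under the null stays near nominal", {
  m <- generateWeb(syntheticWebSpec(nLiving = 6, seed = 23))
  focal <- groupTable(m)$name[grep("herbivore|omnivore|carnivore",
                                   groupTable(m)$name)][1]
  hits <- 0
  reps <- 60
  for (r in seq_len(reps)) {
    eA <- drawEnsemble(m, n = 25, seed = 1000 + 2 * r)
    eB <- drawEnsemble(m, n = 25, seed = 1001 + 2 * r)
    res <- compareEnsembles(ensembleMetrics(eA, focals = list(f = focal)),
                            ensembleMetrics(eB, focals = list(f = focal)))
    if (any(res$significant)) hits <- hits + 1
  }
  ## binomial 3-sigma envelope around 0.05 with 60 replications
  expect_lte(hits / reps, 0.05 + 3 * sqrt(0.05 * 0.95 / reps))
})
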