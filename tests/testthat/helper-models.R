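## Small hand-built fixture models and independent oracles, constructed in
## code so every expected value can be traced to arithmetic on this page.

## producer (no consumption) + herbivore eating it; optional landings
toyProducerHerbivore <- function(qbHerb = 5) {
  groups <- data.frame(
    id = 1:2, name = c("producer", "herbivore"),
    type = c("living", "living"),
    biomass = c(10, 1), pb = c(1, 1), qb = c(0, qbHerb), ae = c(0.9, 0.8))
  diet <- matrix(0, 2, 2)
  diet[1, 2] <- 1
  FoodWebModel(groups, diet)
}

## chain producer -> herbivore -> carnivore; carnivore splits 50/50 over
## herbivore and producer, giving the hand-solved TL of 2.5
toyChain3 <- function() {
  groups <- data.frame(
    id = 1:3, name = c("producer", "herbivore", "carnivore"),
    type = rep("living", 3),
    biomass = c(100, 10, 1), pb = c(2, 1, 0.5), qb = c(0, 5, 2),
    ae = c(0.9, 0.8, 0.8))
  diet <- matrix(0, 3, 3)
  diet[1, 2] <- 1
  diet[1, 3] <- 0.5
  diet[2, 3] <- 0.5
  FoodWebModel(groups, diet)
}

## branched web P -> {H1, H2} -> C with production fractions
## phi[P->H1] = phi[P->H2] = 0.4, phi[H1->C] = phi[H2->C] = 0.5.
## `herbPb`/`carnPb` let the production vector be re-weighted without
## touching the fluxes that define phi.
branchedWeb <- function(herbPb = 1, carnPb = 1) {
  ## P: B = 10, pb = 1 -> prod 10; H consumption 4 each (qb 2, B 2) so
  ## phi[P->H] = 4/10; C consumption 2 (qb 4, B 0.5) split 50/50 so each
  ## phi[H->C] = 1 / prod(H)
  stopifnot(herbPb * 2 >= 1)     # keep ee(H) <= 1
  groups <- data.frame(
    id = 1:4, name = c("P", "H1", "H2", "C"),
    type = rep("living", 4),
    biomass = c(10, 2, 2, 0.5),
    pb = c(1, herbPb, herbPb, carnPb),
    qb = c(0, 2, 2, 4),
    ae = c(0.9, 0.9, 0.9, 0.9))
  diet <- matrix(0, 4, 4)
  diet[1, 2] <- 1
  diet[1, 3] <- 1
  diet[2, 4] <- 0.5
  diet[3, 4] <- 0.5
  FoodWebModel(groups, diet)
}

## group 3 has Q = 10, ae = 0.8, pb/qb = 0.3 and is consumed at rate 2.4
## (ee = 0.8): fate fractions 0.2 / 0.5 / 0.24 / 0.06 by hand
fateToy <- function() {
  groups <- data.frame(
    id = 1:5,
    name = c("nutrient", "detritus", "focal", "producer", "predator"),
    type = c("nutrient", "detritus", "living", "living", "living"),
    biomass = c(1, 1, 1, 100, 0.6),
    pb = c(0, 0, 3, 1, 1), qb = c(0, 0, 10, 0, 4),
    ae = c(1, 1, 0.8, 0.9, 0.8))
  diet <- matrix(0, 5, 5)
  diet[4, 3] <- 1            # focal eats the producer
  diet[3, 5] <- 1            # predator eats the focal: flux 0.6*4 = 2.4
  FoodWebModel(groups, diet)
}

## ---- independent oracles ----------------------------------------------------

## trophic levels by the explicit path series sum_k (DC^T)^k 1 on an
## acyclic web (columns renormalized the same way as the solver input)
oracleTrophicLevels <- function(diet) {
  cs <- colSums(diet)
  cons <- cs > 0
  diet[, cons] <- sweep(diet[, cons, drop = FALSE], 2, cs[cons], `/`)
  n <- nrow(diet)
  tl <- rep(1, n)
  term <- rep(1, n)
  M <- t(diet)
  for (k in seq_len(n + 1)) {
    term <- as.numeric(M %*% term)
    tl <- tl + term
    if (all(abs(term) < 1e-15)) break
  }
  setNames(tl, colnames(diet))
}

## destined fractions by depth-first enumeration of every directed path from
## g to the focal set through living, non-focal intermediates (valid on DAGs)
oracleDestined <- function(phi, focal, living) {
  rec <- setdiff(living, focal)
  walk <- function(g) {
    tot <- sum(phi[g, focal])
    for (k in rec)
      if (phi[g, k] > 0) tot <- tot + phi[g, k] * walk(k)
    tot
  }
  out <- setNames(numeric(length(living)), living)
  for (g in rec) out[g] <- walk(g)
  out[focal] <- 1
  out
}

## pass-through fractions by enumeration of every path from focal to c
oraclePassThrough <- function(psi, focal, living) {
  rec <- setdiff(living, focal)
  walk <- function(c) {
    tot <- sum(psi[focal, c])
    for (k in rec)
      if (psi[k, c] > 0) tot <- tot + psi[k, c] * walk(k)
    tot
  }
  out <- setNames(numeric(length(living)), living)
  for (c in rec) out[c] <- walk(c)
  out[focal] <- 1
  out
}

## the phi matrix (fraction of prey production consumed by each consumer)
## for feeding oracles; shares only trivial arithmetic with the package
phiMatrix <- function(model) {
  g <- groupTable(model)
  q <- fluxMatrix(consumptionFlux(model))
  prod <- ifelse(g$type == "living", g$biomass * g$pb, 0)
  phi <- q / ifelse(prod > 0, prod, Inf)
  dimnames(phi) <- dimnames(dietMatrix(model))
  phi
}

## small random balanced acyclic web (the generator feeds guilds strictly
## downward, so its webs are acyclic by construction)
randomSmallWeb <- function(seed, nLiving = NULL) {
  set.seed(seed * 7 + 1)
  if (is.null(nLiving)) nLiving <- sample(4:8, 1)
  generateWeb(syntheticWebSpec(
    nLiving = nLiving, nNutrient = 1, nDetritus = 1, nFleets = 1,
    guildProportions = c(producer = 0.3, herbivore = 0.3,
                         omnivore = 0.2, carnivore = 0.2),
    dietSparsity = 0.6, seed = seed), seed = seed)
}
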