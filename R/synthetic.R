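#' Specification for a synthetic balanced food web
#'
#' Describes the structure of a generated ecosystem model: group counts
#' mirroring the study system (80 living groups, 3 nutrient pools, 5 detritus
#' pools, 2 fleets by default), trophic-guild proportions, log-spread
#' biomasses declining up the web, guild-specific turnover ranges, diet
#' sparsity, and the pedigree CV classes (0.1 / 0.5 / 0.8) expressing diet
#' data quality.
#'
#' @param nLiving,nNutrient,nDetritus,nFleets group counts.
#' @param guildProportions proportions of living groups that are producers,
#'   herbivores, omnivores, carnivores; must sum to 1.
#' @param topology \code{"random"} guild-structured web or \code{"chain"}
#'   (each living group eats only the previous one; trophic levels 1, 2, ...,
#'   n).
#' @param biomassLogMean,biomassLogSD,biomassTrophicDecay parameters of the
#'   log-normal biomass draw: \code{log B ~ N(logMean - decay * (guild - 1),
#'   logSD)}.
#' @param pbRanges named list of c(min, max) P/B draw ranges per guild (per
#'   year).
#' @param aeRange assimilation-efficiency draw range.
#' @param ggeRange gross-growth-efficiency (P/Q) draw range for consumers;
#'   producers use a high-efficiency range internally.
#' @param dietSparsity probability that an available prey enters a consumer's
#'   diet, in (0, 1].
#' @param detritusDietFraction upper bound on the detrital share of herbivore
#'   and omnivore diets.
#' @param cvClasses,cvClassProbs pedigree CV classes assigned to whole diet
#'   columns and their sampling probabilities.
#' @param paramCV pedigree CV attached to biomass, P/B, Q/B and AE.
#' @param eeCap target upper bound on generated ecotrophic efficiencies; the
#'   generator caps consumer Q/B against available prey production so that
#'   every EE is below this value (hence below 1: balanced by construction).
#' @param seed default RNG seed used by \code{\link{generateWeb}}.
#' @return a list of class \code{"SyntheticWebSpec"}.
#' @export
syntheticWebSpec <- function(nLiving = 80, nNutrient = 3, nDetritus = 5,
                             nFleets = 2,
                             guildProportions = c(producer = 0.15,
                                                  herbivore = 0.30,
                                                  omnivore = 0.30,
                                                  carnivore = 0.25),
                             topology = c("random", "chain"),
                             biomassLogMean = 2, biomassLogSD = 1,
                             biomassTrophicDecay = 1.5,
                             pbRanges = list(producer = c(50, 150),
                                             herbivore = c(5, 25),
                                             omnivore = c(1, 8),
                                             carnivore = c(0.2, 2)),
                             aeRange = c(0.7, 0.9),
                             ggeRange = c(0.1, 0.3),
                             dietSparsity = 0.4,
                             detritusDietFraction = 0.2,
                             cvClasses = c(0.1, 0.5, 0.8),
                             cvClassProbs = c(1, 1, 1) / 3,
                             paramCV = 0.1,
                             eeCap = 0.9, seed = 1) {
  topology <- match.arg(topology)
  stopifnot(nLiving >= 1, nNutrient >= 0, nDetritus >= 0, nFleets >= 0,
            dietSparsity > 0, dietSparsity <= 1,
            eeCap > 0, eeCap < 1, all(cvClasses >= 0))
  if (abs(sum(guildProportions) - 1) > NORM_TOL)
    stop("guild proportions must sum to 1")
  if (nNutrient < 1)
    stop("producers consume nutrient pools; at least one is required")
  structure(as.list(environment()), class = "SyntheticWebSpec")
}

#' Generate a balanced synthetic food-web model
#'
#' Builds a model with the structure of \code{\link{syntheticWebSpec}} that is
#' guaranteed to validate and to be mass-balanced (all ecotrophic efficiencies
#' below the spec's \code{eeCap}). Guilds feed strictly downward (producers on
#' nutrient pools only), so trophic levels are finite; balance is achieved
#' constructively, guild by guild from the bottom up, by scaling each
#' consumer's Q/B against the production its prey still have available.
#' Fully reproducible: the same spec and seed give a bitwise-identical model.
#'
#' @param spec a \code{"SyntheticWebSpec"}.
#' @param seed RNG seed; defaults to the spec's.
#' @return a balanced \linkS4class{FoodWebModel} with EE filled in.
#' @export
generateWeb <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "SyntheticWebSpec"))
  set.seed(seed)
  nl <- spec$nLiving

  ## guild levels: 1 producer, 2 herbivore, 3 omnivore, 4 carnivore
  if (spec$topology == "chain") {
    levels <- seq_len(nl)
    guild <- pmin(levels, 4L)
  } else {
    counts <- .guildCounts(nl, spec$guildProportions)
    guild <- rep(1:4, counts)
    levels <- guild
  }

  nN <- spec$nNutrient; nD <- spec$nDetritus; nF <- spec$nFleets
  n <- nl + nN + nD + nF
  ids <- seq_len(n)
  type <- c(rep("living", nl), rep("nutrient", nN), rep("detritus", nD),
            rep("fleet", nF))
  name <- c(sprintf("%s_%02d", c("producer", "herbivore", "omnivore",
                                 "carnivore")[guild], seq_len(nl)),
            sprintf("nutrient_%d", seq_len(nN)),
            sprintf("detritus_%d", seq_len(nD)),
            sprintf("fleet_%d", seq_len(nF)))

  biomass <- numeric(n)
  biomass[1:nl] <- exp(rnorm(nl, spec$biomassLogMean -
                               spec$biomassTrophicDecay * (guild - 1),
                             spec$biomassLogSD))
  biomass[type == "nutrient"] <- exp(rnorm(nN, spec$biomassLogMean + 1, 0.5))
  biomass[type == "detritus"] <- exp(rnorm(nD, spec$biomassLogMean, 0.5))

  ae <- numeric(n)
  ae[1:nl] <- runif(nl, spec$aeRange[1], spec$aeRange[2])
  pb <- qb <- numeric(n)
  gnames <- c("producer", "herbivore", "omnivore", "carnivore")
  for (i in seq_len(nl)) {
    r <- spec$pbRanges[[gnames[guild[i]]]]
    pb[i] <- runif(1, r[1], r[2])
    gge <- if (guild[i] == 1) runif(1, 0.5, 0.95) * ae[i]
           else runif(1, spec$ggeRange[1], min(spec$ggeRange[2], ae[i]))
    qb[i] <- pb[i] / gge
  }

  diet <- matrix(0, n, n, dimnames = list(ids, ids))
  nutIdx <- which(type == "nutrient")
  detIdx <- which(type == "detritus")
  for (i in seq_len(nl)) {
    if (levels[i] == 1) {
      w <- runif(length(nutIdx))
      diet[nutIdx, i] <- w / sum(w)
      next
    }
    if (spec$topology == "chain") {
      diet[i - 1L, i] <- 1           # single-prey staircase
      next
    }
    preyPool <- which(levels < levels[i] & levels >= levels[i] - 2)
    if (!length(preyPool))
      stop("infeasible spec: guild ", gnames[guild[i]],
           " has no prey guild below it")
    sel <- preyPool[runif(length(preyPool)) < spec$dietSparsity]
    if (!length(sel)) sel <- preyPool[sample.int(length(preyPool), 1)]
    w <- runif(length(sel))
    w <- w / sum(w)
    detShare <- 0
    if (guild[i] %in% 2:3 && length(detIdx) &&
        spec$detritusDietFraction > 0 && runif(1) < 0.5) {
      detShare <- runif(1, 0, spec$detritusDietFraction)
      dw <- runif(length(detIdx))
      diet[detIdx, i] <- detShare * dw / sum(dw)
    }
    diet[sel, i] <- (1 - detShare) * w
  }

  ## ---- bottom-up balance: cap consumer Q/B against available production ----
  prod <- biomass * pb
  committed <- numeric(n)            # predation demand already booked per prey
  for (lv in sort(unique(levels[levels > 1]))) {
    js <- which(levels == lv)
    newDemand <- as.numeric(diet[, js, drop = FALSE] %*% (biomass[js] * qb[js]))
    livingPrey <- which(newDemand > 0 & type == "living")
    s <- rep(1, n)
    if (length(livingPrey)) {
      avail <- pmax(spec$eeCap * prod[livingPrey] - committed[livingPrey], 0)
      s[livingPrey] <- pmin(1, avail / newDemand[livingPrey])
    }
    for (j in js) {
      pr <- which(diet[, j] > 0 & type == "living")
      if (length(pr)) qb[j] <- qb[j] * min(s[pr])
      pb[j] <- min(pb[j], ae[j] * qb[j])
    }
    prod <- biomass * pb
    committed <- committed +
      as.numeric(diet[, js, drop = FALSE] %*% (biomass[js] * qb[js]))
  }

  ## ---- landings on the top two guild levels, inside remaining headroom ----
  fleetIdx <- which(type == "fleet")
  landings <- matrix(0, n, nF, dimnames = list(ids, ids[fleetIdx]))
  if (nF > 0) {
    topLv <- sort(unique(levels), decreasing = TRUE)
    targetPool <- which(levels %in% topLv[seq_len(min(2, length(topLv)))])
    for (f in seq_len(nF)) {
      tg <- if (length(targetPool) > 6) sample(targetPool, 6) else targetPool
      head <- pmax(0.98 * prod[tg] - committed[tg], 0)
      landings[tg, f] <- runif(length(tg), 0.1, 0.5) * head / nF
    }
    committed <- committed + rowSums(landings)
  }

  ## ---- pedigree: one CV class per consumer diet column, fixed param CV ----
  pedDiet <- matrix(0, n, n, dimnames = list(ids, ids))
  classes <- sample(spec$cvClasses, nl, replace = TRUE, prob = spec$cvClassProbs)
  for (i in seq_len(nl))
    pedDiet[diet[, i] > 0, i] <- classes[i]
  pedPar <- matrix(0, n, 4, dimnames = list(ids, c("biomass", "pb", "qb", "ae")))
  pedPar[1:nl, c("biomass", "pb", "qb")] <- spec$paramCV
  pedPar[1:nl, "ae"] <- min(spec$paramCV, 0.05)

  groups <- data.frame(id = ids, name = name, type = type, biomass = biomass,
                       pb = pb, qb = qb, ae = ae)
  m <- FoodWebModel(groups, diet, landings = landings,
                    pedigree = list(params = pedPar, diet = pedDiet),
                    provenance = sprintf("synthetic web (seed %d)", seed))
  computeEE(m)
}

.guildCounts <- function(nl, props) {
  counts <- floor(nl * props)
  rem <- nl - sum(counts)
  if (rem > 0) {
    frac <- nl * props - counts
    add <- order(frac, decreasing = TRUE)[seq_len(rem)]
    counts[add] <- counts[add] + 1
  }
  if (counts[1] < 1) {
    k <- which.max(counts[-1]) + 1
    counts[k] <- counts[k] - 1
    counts[1] <- counts[1] + 1
  }
  if (counts[4] > 0 && counts[2] + counts[3] == 0)
    stop("infeasible spec: carnivores but no herbivore or omnivore prey")
  if ((counts[2] > 0 || counts[3] > 0) && counts[1] == 0)
    stop("infeasible spec: consumers but no producers")
  counts
}

#' Generate a before/after model pair with known injected changes
#'
#' Produces two models differing by a fully recorded perturbation, enabling
#' parameter-recovery checks of the whole comparison pipeline: biomass
#' multipliers must be recovered exactly by the difference network's node
#' factors, and removed diet links by the pruning report.
#'
#' @param spec a \code{"SyntheticWebSpec"} for the base (before) model.
#' @param perturbation list with any of: \code{biomassFactors} (named numeric,
#'   names = group ids, multiplicative), \code{removeLinks} (data.frame
#'   \code{prey}, \code{predator}), \code{addLinks} (data.frame \code{prey},
#'   \code{predator}, \code{fraction}), \code{invader} (list \code{name},
#'   \code{biomass}, \code{pb}, \code{qb}, \code{ae}, \code{diet} named
#'   vector).
#' @param seed RNG seed for the base model.
#' @return list with \code{before}, \code{after} (both balanced), and
#'   \code{truth}: the applied edits, including any Q/B re-capping needed to
#'   restore balance.
#' @export
generateModelPair <- function(spec, perturbation = list(), seed = spec$seed) {
  before <- generateWeb(spec, seed)
  after <- before
  truth <- perturbation

  if (!is.null(perturbation$biomassFactors)) {
    f <- perturbation$biomassFactors
    idx <- match(as.integer(names(f)), after@groups$id)
    if (anyNA(idx)) stop("biomassFactors name unknown group ids")
    after@groups$biomass[idx] <- after@groups$biomass[idx] * as.numeric(f)
  }
  if (!is.null(perturbation$removeLinks)) {
    rl <- perturbation$removeLinks
    d <- after@diet
    for (k in seq_len(nrow(rl))) {
      i <- as.character(rl$prey[k]); j <- as.character(rl$predator[k])
      if (d[i, j] <= 0) stop("removeLinks names an absent link ", i, "->", j)
      d[i, j] <- 0
      if (sum(d[, j]) <= 0)
        stop("perturbation empties the diet of consumer ", j)
      d[, j] <- d[, j] / sum(d[, j])
    }
    after@diet <- d
  }
  if (!is.null(perturbation$addLinks)) {
    al <- perturbation$addLinks
    d <- after@diet
    for (k in seq_len(nrow(al))) {
      i <- as.character(al$prey[k]); j <- as.character(al$predator[k])
      fr <- al$fraction[k]
      stopifnot(fr > 0, fr < 1)
      d[, j] <- d[, j] * (1 - fr)
      d[i, j] <- d[i, j] + fr
    }
    after@diet <- d
  }
  if (!is.null(perturbation$invader)) {
    iv <- perturbation$invader
    after <- do.call(addTraceGroup,
                     c(list(model = after, name = iv$name,
                            biomass = iv$biomass),
                       iv[setdiff(names(iv), c("name", "biomass"))]))
  }
  after@groups$ee <- NA_real_

  ## restore balance by re-capping over-stressed consumers' Q/B
  recap <- .recapBalance(after)
  truth$recappedGroups <- recap$recapped
  list(before = before, after = computeEE(recap$model), truth = truth)
}

## iterative Q/B capping until all EE <= cap; errors if it cannot converge
.recapBalance <- function(model, cap = 0.98, maxIter = 50) {
  recapped <- integer(0)
  for (it in seq_len(maxIter)) {
    model <- computeEE(model)
    ee <- eeVector(model)
    if (all(ee <= cap)) return(list(model = model, recapped = sort(unique(recapped))))
    g <- model@groups
    over <- as.integer(names(ee)[ee > cap])
    s <- setNames(rep(1, nrow(g)), g$id)
    s[as.character(over)] <- cap / ee[as.character(over)]
    for (j in which(g$type == "living" & g$qb > 0)) {
      pr <- as.character(g$id[model@diet[, j] > 0 & g$type == "living"])
      if (!length(pr)) next
      f <- min(s[pr])
      if (f < 1) {
        model@groups$qb[j] <- g$qb[j] * f
        model@groups$pb[j] <- min(g$pb[j],
                                  model@groups$ae[j] * model@groups$qb[j])
        recapped <- c(recapped, g$id[j])
      }
    }
    model@groups$ee <- NA_real_
  }
  stop("perturbation breaks mass balance beyond repair: EE cannot be capped")
}
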