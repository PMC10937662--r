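#' Production-fate matrix of all consumption
#'
#' Splits each living group's total consumption Q = B * Q/B into its four
#' fates: non-assimilated egestion (fraction 1 - AE, to detritus pools),
#' metabolic costs (AE - (P/B)/(Q/B), to nutrient pools), production consumed
#' by each predator or fleet (q[g -> j] / Q), and senescence of unconsumed
#' production ((P/B)/(Q/B) * (1 - EE), to detritus pools). The four components
#' sum to 1 for every group: consumption is conserved.
#'
#' @param model a validated, balanced \linkS4class{FoodWebModel} (EE is
#'   computed internally if absent).
#' @param detritusRouting optional matrix (living groups x detritus pools) of
#'   routing weights for egestion and senescence, rows summing to 1; default
#'   uniform across detritus pools.
#' @param nutrientRouting optional matrix (living groups x nutrient pools) for
#'   metabolism; default uniform across nutrient pools.
#' @return a \linkS4class{ProductionFateMatrix}.
#' @details Errors: negative implied metabolism (AE < (P/B)/(Q/B)) and
#'   ecotrophic efficiency above 1 (unbalanced model) are both rejected rather
#'   than clipped. Senescence is computed as the residual P/B / Q/B minus the
#'   realized predation fractions, so row sums are exactly 1 by construction.
#' @export
buildProductionFate <- function(model, detritusRouting = NULL,
                                nutrientRouting = NULL) {
  model <- computeEE(model)
  assertValid(model)
  g <- model@groups
  livIdx <- which(g$type == "living" & g$qb > 0)
  if (!length(livIdx)) stop("model has no living consumers")
  detIds <- as.character(g$id[g$type == "detritus"])
  nutIds <- as.character(g$id[g$type == "nutrient"])
  consIds <- as.character(g$id[(g$type == "living" & g$qb > 0) |
                               g$type == "fleet"])
  nl <- length(livIdx)

  detritusRouting <- .routingWeights(detritusRouting, nl, detIds, "detritus")
  nutrientRouting <- .routingWeights(nutrientRouting, nl, nutIds, "nutrient")

  q <- fluxMatrix(consumptionFlux(model))
  Q <- g$biomass[livIdx] * g$qb[livIdx]
  pq <- g$pb[livIdx] / g$qb[livIdx]
  ae <- g$ae[livIdx]
  ee <- g$ee[livIdx]

  neg <- ae < pq - NORM_TOL
  if (any(neg))
    stop(sprintf(
      "group %d (%s): assimilation efficiency %.4g below production efficiency %.4g implies negative metabolism",
      g$id[livIdx][neg], g$name[livIdx][neg], ae[neg], pq[neg]))
  if (any(ee > 1 + NORM_TOL))
    stop(sprintf("group %d (%s): ecotrophic efficiency %.4g > 1; balance the model first",
                 g$id[livIdx][ee > 1 + NORM_TOL],
                 g$name[livIdx][ee > 1 + NORM_TOL], ee[ee > 1 + NORM_TOL]))

  ids <- as.character(g$id[livIdx])
  pred <- q[ids, consIds, drop = FALSE] / Q   # predation + fleet fractions
  sen <- pq - rowSums(pred)                   # = pq * (1 - ee), residual form
  sen[abs(sen) < NORM_TOL] <- 0
  if (any(sen < 0))
    stop("negative senescence fraction; predation exceeds production for group(s) ",
         paste(ids[sen < 0], collapse = ", "))

  egestion <- (1 - ae) * detritusRouting
  senescence <- sen * detritusRouting
  metabolism <- (ae - pmax(pq, 0)) * nutrientRouting
  rownames(pred) <- rownames(egestion) <- rownames(senescence) <-
    rownames(metabolism) <- ids

  new("ProductionFateMatrix", groupIds = g$id[livIdx],
      egestion = egestion, metabolism = metabolism,
      predation = pred, senescence = senescence)
}

## default: uniform routing across the pools of a class; zero-column matrix
## when the model has no pool of that class (the corresponding fate fraction
## must then be zero, which validity will enforce).
.routingWeights <- function(w, nl, poolIds, what) {
  np <- length(poolIds)
  if (is.null(w)) {
    w <- matrix(if (np) 1 / np else 0, nl, np,
                dimnames = list(NULL, poolIds))
  } else {
    w <- as.matrix(w)
    if (nrow(w) != nl || ncol(w) != np)
      stop(what, " routing must be living-groups x ", what, "-pools")
    if (np && any(abs(rowSums(w) - 1) > NORM_TOL))
      stop(what, " routing rows must sum to 1")
  }
  w
}
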