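#' Ecotrophic efficiency and mass balance
#'
#' Computes the ecotrophic efficiency of every living group from the Ecopath
#' master equation at steady state with no import/export or biomass
#' accumulation:
#' \deqn{B_i (P/B)_i EE_i = \sum_j B_j (Q/B)_j DC_{ij} + \sum_f Y_{if}}
#' i.e. \code{EE = (predation demand + landings) / production}. A model is
#' balanced when every EE is at most 1: no group's production is over-consumed.
#'
#' @param model a validated \linkS4class{FoodWebModel}.
#' @return the model with the \code{ee} column of the group table filled in for
#'   living groups (use \code{eeVector} for the bare vector).
#' @details A living group with zero production (B * P/B = 0) gets EE = 0 when
#'   nothing consumes it; positive demand on such a group is a mass-balance
#'   impossibility and raises an error naming the group.
#' @seealso \code{\link{isBalanced}}, \code{\link{eeVector}}
#' @export
computeEE <- function(model) {
  assertValid(model)
  g <- model@groups
  liv <- which(g$type == "living")
  demand <- .predationDemand(model) + rowSums(model@landings)
  prod <- g$biomass * g$pb
  ee <- rep(NA_real_, nrow(g))
  for (i in liv) {
    if (prod[i] > 0) {
      ee[i] <- demand[i] / prod[i]
    } else if (demand[i] <= NORM_TOL) {
      ee[i] <- 0
    } else {
      stop(sprintf(
        "mass-balance impossibility: group %d (%s) has zero production but positive demand %.4g",
        g$id[i], g$name[i], demand[i]))
    }
  }
  model@groups$ee <- ee
  model
}

## total predation demand on each group: sum over living consumers of B*qb*DC
.predationDemand <- function(model) {
  g <- model@groups
  cons <- g$type == "living" & g$qb > 0
  w <- ifelse(cons, g$biomass * g$qb, 0)
  as.numeric(model@diet %*% w)
}

#' @describeIn computeEE the EE vector for living groups, named by group id
#'   (computing it first if absent).
#' @export
eeVector <- function(model) {
  if (anyNA(model@groups$ee[model@groups$type == "living"]))
    model <- computeEE(model)
  g <- model@groups
  setNames(g$ee[g$type == "living"], g$id[g$type == "living"])
}

#' Is the model mass-balanced?
#'
#' @param model a \linkS4class{FoodWebModel}.
#' @param tol tolerance on the EE <= 1 test.
#' @return \code{TRUE} iff every living group's ecotrophic efficiency is at
#'   most 1.
#' @export
isBalanced <- function(model, tol = NORM_TOL) {
  all(eeVector(model) <= 1 + tol)
}
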