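#' Destined fractions of production (footprint trace)
#'
#' For a focal consumer group (or set of groups treated as one), computes for
#' every living group g the fraction D[g] of g's production that ends up
#' supporting the focal group through all direct and indirect living pathways.
#' Detritus and nutrient pools are excluded from the pathways entirely: energy
#' entering a detrital pool is treated as leaving the traced web. With
#' \eqn{\phi[g,k]} the fraction of g's production (B g * P/B g) consumed by k
#' (predation plus landings), D solves
#' \deqn{D[g] = \phi[g, focal] + \sum_{k \notin excl, k \neq focal} \phi[g, k] D[k]}
#' with D[focal] = 1, as a linear system; leakage to detritus, metabolism and
#' senescence keeps the spectral radius below 1 so cycles are handled.
#'
#' @param model a validated, balanced \linkS4class{FoodWebModel}.
#' @param focal group id, group name, or vector thereof (a focal set is merged
#'   at the recursion boundary).
#' @param exclude ids of additional living groups to cut out of the pathway
#'   recursion (nutrient and detritus pools are always excluded).
#' @return named numeric vector D over living groups (1 for focal members).
#' @export
destinedFractions <- function(model, focal, exclude = integer(0)) {
  tr <- .traceSetup(model, focal, exclude)
  ## phi[g, k]: fraction of g's production consumed by k (incl. fleets)
  phi <- tr$q / ifelse(tr$prod > 0, tr$prod, Inf)  # rows: all groups
  R <- tr$recursion
  b <- rowSums(phi[R, tr$focalIds, drop = FALSE])
  A <- diag(length(R)) - phi[R, R, drop = FALSE]
  d <- .traceSolve(A, b, R)
  out <- setNames(numeric(length(tr$living)), tr$living)
  out[R] <- d
  out[tr$focalIds[tr$focalIds %in% tr$living]] <- 1
  out
}

#' Pass-through fractions of consumption (reach trace)
#'
#' The dual of \code{\link{destinedFractions}}: for every living consumer c,
#' the fraction P[c] of c's production that originated with, or passed
#' through, the focal group. With \eqn{\psi[k, c] = DC[k, c]} the fraction of
#' c's consumption taken from k,
#' \deqn{P[c] = \psi[focal, c] + \sum_{k \notin excl, k \neq focal} \psi[k, c] P[k]}
#' with P[focal] = 1, again excluding detritus and nutrient pools from the
#' pathways.
#'
#' @inheritParams destinedFractions
#' @return named numeric vector P over living groups (1 for focal members).
#' @export
passThroughFractions <- function(model, focal, exclude = integer(0)) {
  tr <- .traceSetup(model, focal, exclude)
  psi <- model@diet
  R <- tr$recursion
  b <- colSums(psi[tr$focalIds, R, drop = FALSE])
  A <- diag(length(R)) - t(psi[R, R, drop = FALSE])
  p <- .traceSolve(A, b, R)
  out <- setNames(numeric(length(tr$living)), tr$living)
  out[R] <- p
  out[tr$focalIds[tr$focalIds %in% tr$living]] <- 1
  out
}

#' Footprint and reach of a focal group
#'
#' Two non-dimensional measures of a group's whole-system role.
#' \strong{Footprint}: the proportion of total system production (over living
#' groups other than the focal) consumed by the focal group via all direct and
#' indirect living pathways — its trophic impact on lower trophic levels.
#' \strong{Reach}: the proportion of total consumer production that originated
#' with or passed through the focal group (the focal's own production counts)
#' — its importance to higher trophic levels. Both are production-weighted
#' aggregates of the trace vectors, with production \eqn{Prod_g = B_g (P/B)_g}.
#'
#' @inheritParams destinedFractions
#' @return a single number in [0, 1] (\code{footprint}, \code{reach}), or for
#'   \code{footprintReach} a one-row data.frame with both.
#' @export
footprint <- function(model, focal, exclude = integer(0)) {
  tr <- .traceSetup(model, focal, exclude)
  D <- destinedFractions(model, focal, exclude)
  others <- setdiff(tr$living, tr$focalIds)
  prod <- tr$prodNamed[others]
  if (sum(prod) <= 0) stop("zero total production outside the focal set")
  sum(D[others] * prod) / sum(prod)
}

#' @rdname footprint
#' @export
reach <- function(model, focal, exclude = integer(0)) {
  tr <- .traceSetup(model, focal, exclude)
  P <- passThroughFractions(model, focal, exclude)
  ## consumers: living groups with at least some living or detrital prey
  cons <- tr$consumers
  if (!length(cons)) stop("model has no living consumer groups")
  prod <- tr$prodNamed[cons]
  if (sum(prod) <= 0) stop("zero total consumer production")
  P[intersect(tr$focalIds, cons)] <- 1
  sum(P[cons] * prod) / sum(prod)
}

#' @rdname footprint
#' @export
footprintReach <- function(model, focal, exclude = integer(0)) {
  data.frame(focal = paste(focal, collapse = "+"),
             footprint = footprint(model, focal, exclude),
             reach = reach(model, focal, exclude))
}

## shared setup: resolve focal names, build flux and production, pick the
## recursion set (living groups minus focal minus user exclusions)
.traceSetup <- function(model, focal, exclude) {
  model <- computeEE(model)
  assertValid(model)
  g <- model@groups
  focalIds <- .resolveIds(model, focal)
  living <- as.character(g$id[g$type == "living"])
  if (!all(focalIds %in% c(living, as.character(g$id[g$type == "fleet"]))))
    stop("focal groups must be living groups or fleets")
  q <- fluxMatrix(consumptionFlux(model))
  prod <- setNames(ifelse(g$type == "living", g$biomass * g$pb, 0),
                   as.character(g$id))
  ## consumers = living groups taking living or detrital prey (true
  ## producers feed only on nutrient pools)
  dn <- as.character(g$id[g$type %in% c("living", "detritus")])
  cs <- colSums(model@diet[dn, living, drop = FALSE])
  consumers <- living[cs > 0]
  recursion <- setdiff(living, c(focalIds, as.character(exclude)))
  list(q = q[as.character(g$id), as.character(g$id)],
       prod = as.numeric(prod), prodNamed = prod, living = living,
       consumers = consumers, focalIds = focalIds, recursion = recursion)
}

.traceSolve <- function(A, b, R) {
  sol <- tryCatch(solve(A, b), error = function(e)
    stop("trace system is singular (no energetic leakage anywhere); ",
         "groups: ", paste(R, collapse = ", "), call. = FALSE))
  ## clip tiny negative round-off
  pmin(pmax(sol, 0), 1)
}

.resolveIds <- function(model, x) {
  g <- model@groups
  if (is.character(x) && !all(x %in% as.character(g$id))) {
    hit <- match(x, g$name)
    if (anyNA(hit)) stop("unknown group name(s): ",
                         paste(x[is.na(hit)], collapse = ", "))
    return(as.character(g$id[hit]))
  }
  x <- as.character(as.integer(as.numeric(x)))
  if (!all(x %in% as.character(g$id)))
    stop("unknown group id(s): ", paste(setdiff(x, g$id), collapse = ", "))
  x
}
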