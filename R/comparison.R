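#' Harmonize two models onto a common group set
#'
#' Two models of the same ecosystem built at different times rarely resolve
#' taxa identically; before any comparison they must share one group list.
#' Each model's groups are first aggregated under an explicit mapping
#' (\code{\link{aggregateGroups}}); any harmonized group present in only one
#' model is then inserted into the other at trace biomass
#' (\code{\link{addTraceGroup}}, default 1e-5), with the diet column copied
#' from the model that has the group. Both outputs have identical group ids in
#' identical order and validate.
#'
#' @param modelA,modelB validated \linkS4class{FoodWebModel}s.
#' @param mapping data.frame with columns \code{model} ("A" or "B"),
#'   \code{old_id}, \code{new_id}, optional \code{new_name}; must cover every
#'   group of both models. \code{NULL} when the ids already correspond.
#' @param traceBiomass biomass for inserted missing groups.
#' @return list with elements \code{A} and \code{B}, the harmonized models.
#' @export
harmonizeModels <- function(modelA, modelB, mapping = NULL,
                            traceBiomass = TRACE_BIOMASS) {
  if (!is.null(mapping)) {
    mapping <- as.data.frame(mapping)
    stopifnot(all(c("model", "old_id", "new_id") %in% names(mapping)))
    modelA <- aggregateGroups(modelA, mapping[mapping$model == "A", ])
    modelB <- aggregateGroups(modelB, mapping[mapping$model == "B", ])
  }
  modelA <- .insertMissing(modelA, modelB, traceBiomass)
  modelB <- .insertMissing(modelB, modelA, traceBiomass)
  idsA <- sort(groupIds(modelA))
  idsB <- sort(groupIds(modelB))
  if (!identical(idsA, idsB))
    stop("unmappable groups: id sets still differ after harmonization (",
         paste(union(setdiff(idsA, idsB), setdiff(idsB, idsA)), collapse = ", "), ")")
  list(A = .reorderGroups(modelA, idsA), B = .reorderGroups(modelB, idsA))
}

## insert, at trace biomass, every group of `donor` that `target` lacks
.insertMissing <- function(target, donor, traceBiomass) {
  missing <- setdiff(groupIds(donor), groupIds(target))
  for (mid in missing) {
    gd <- donor@groups[donor@groups$id == mid, ]
    dietCol <- donor@diet[, as.character(mid)]
    keep <- dietCol[names(dietCol) %in% as.character(groupIds(target))]
    keep <- keep[keep > 0]
    target <- addTraceGroup(target, name = gd$name, type = gd$type,
                            biomass = traceBiomass, pb = gd$pb, qb = gd$qb,
                            ae = gd$ae,
                            diet = if (length(keep)) keep else NULL)
    ## addTraceGroup assigns max(id)+1; force the donor's id for alignment
    target@groups$id[nrow(target@groups)] <- as.integer(mid)
    ids <- as.character(target@groups$id)
    dimnames(target@diet) <- list(ids, ids)
    rownames(target@landings) <- ids
    rownames(target@pedigree$params) <- ids
    dimnames(target@pedigree$diet) <- list(ids, ids)
    colnames(target@landings) <- ids[target@groups$type == "fleet"]
  }
  target
}

.reorderGroups <- function(model, ids) {
  ord <- match(ids, model@groups$id)
  cid <- as.character(ids)
  g <- model@groups[ord, ]
  rownames(g) <- NULL
  FoodWebModel(g, model@diet[cid, cid],
               landings = model@landings[cid, as.character(g$id[g$type == "fleet"]), drop = FALSE],
               pedigree = list(params = model@pedigree$params[cid, , drop = FALSE],
                               diet = model@pedigree$diet[cid, cid]),
               currency = model@currency, timeUnit = model@timeUnit,
               provenance = model@provenance)
}

#' Prune diet links carried over without period evidence
#'
#' When a later model inherits the trophic connections of an earlier one, its
#' connectance is inflated by links never observed in the later period's diet
#' data. This operation zeroes every positive diet cell that is not in the
#' evidence set, renormalizes the affected consumer columns to 1, and reports
#' what was removed.
#'
#' @param model a validated \linkS4class{FoodWebModel}.
#' @param evidence data.frame with columns \code{prey}, \code{predator}
#'   (group ids): the prey-predator pairs actually observed.
#' @return list with \code{model} (pruned) and \code{report} (data.frame
#'   \code{prey}, \code{predator}, \code{removed_fraction}).
#' @details A consumer whose entire diet would be pruned away is an error (the
#'   evidence then contradicts the group's existence as a consumer).
#' @export
pruneCarryoverLinks <- function(model, evidence) {
  assertValid(model)
  evidence <- as.data.frame(evidence)
  stopifnot(all(c("prey", "predator") %in% names(evidence)))
  ids <- as.character(groupIds(model))
  if (!all(as.character(evidence$prey) %in% ids) ||
      !all(as.character(evidence$predator) %in% ids))
    stop("evidence pairs reference unknown group ids")
  d <- model@diet
  keep <- matrix(FALSE, nrow(d), ncol(d), dimnames = dimnames(d))
  keep[cbind(as.character(evidence$prey), as.character(evidence$predator))] <- TRUE

  g <- model@groups
  consCols <- which(g$type == "living" & g$qb > 0)
  rep_prey <- integer(0); rep_pred <- integer(0); rep_frac <- numeric(0)
  for (j in consCols) {
    drop <- d[, j] > 0 & !keep[, j]
    if (!any(drop)) next
    rep_prey <- c(rep_prey, g$id[drop])
    rep_pred <- c(rep_pred, rep(g$id[j], sum(drop)))
    rep_frac <- c(rep_frac, d[drop, j])
    d[drop, j] <- 0
    s <- sum(d[, j])
    if (s <= 0)
      stop(sprintf("pruning removes the entire diet of consumer %d (%s)",
                   g$id[j], g$name[j]))
    d[, j] <- d[, j] / s
  }
  model@diet <- d
  model@groups$ee <- NA_real_
  assertValid(model)
  list(model = model,
       report = data.frame(prey = rep_prey, predator = rep_pred,
                           removed_fraction = rep_frac))
}

#' Difference network between two harmonized models
#'
#' Per-node biomass multiplication factors (second state over first: a factor
#' above 1 is an increase) with their logs, and per-edge signed
#' consumption-flux deltas (second minus first), on the shared node ordering
#' of two harmonized models. A trace-biomass floor keeps the ratio finite for
#' groups absent (inserted at trace) in one model.
#'
#' @param before,after \linkS4class{FoodWebModel}s or
#'   \linkS4class{FluxNetwork}s with identical node sets in identical order.
#' @param traceFloor biomass floor for the ratio denominator/numerator.
#' @return a \linkS4class{DifferenceNetwork}.
#' @export
differenceNetwork <- function(before, after, traceFloor = TRACE_BIOMASS) {
  fa <- if (is(before, "FoodWebModel")) consumptionFlux(before) else before
  fb <- if (is(after, "FoodWebModel")) consumptionFlux(after) else after
  na <- nodeTable(fa); nb <- nodeTable(fb)
  if (!identical(na$id, nb$id))
    stop("node sets differ or are ordered differently; harmonize first")
  bA <- pmax(na$biomass, traceFloor)
  bB <- pmax(nb$biomass, traceFloor)
  factor <- bB / bA
  nodes <- data.frame(id = na$id, name = na$name, type = na$type,
                      biomassBefore = na$biomass, biomassAfter = nb$biomass,
                      factor = factor, logFactor = log(factor))
  delta <- fluxMatrix(fb) - fluxMatrix(fa)
  new("DifferenceNetwork", nodes = nodes, delta = delta)
}

#' @rdname differenceNetwork
#' @param object a \linkS4class{DifferenceNetwork}.
#' @return \code{diffNodes}: the node table; \code{diffEdges}: long-format
#'   data.frame (\code{src}, \code{dst}, \code{delta}) of non-zero edge
#'   deltas; \code{deltaMatrix}: the full signed delta matrix.
#' @export
diffNodes <- function(object) object@nodes

#' @rdname differenceNetwork
#' @export
deltaMatrix <- function(object) object@delta

#' @rdname differenceNetwork
#' @export
diffEdges <- function(object) {
  idx <- which(object@delta != 0, arr.ind = TRUE)
  data.frame(src = as.integer(rownames(object@delta)[idx[, 1]]),
             dst = as.integer(colnames(object@delta)[idx[, 2]]),
             delta = object@delta[idx])
}
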