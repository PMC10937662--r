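#' Aggregate functional groups
#'
#' Merges groups according to an explicit old-id to new-id mapping, the way
#' two differently resolved models are brought onto a common group set: member
#' biomasses are summed; diet columns are combined as the biomass-weighted mean
#' of the member predators' columns; prey rows are summed within each predator
#' column; P/B, Q/B and AE are biomass-weighted means; landings are summed.
#' Total system consumption is conserved (sum of B * Q/B is invariant under
#' biomass-weighted averaging of Q/B).
#'
#' @param model a validated \linkS4class{FoodWebModel}.
#' @param mapping data.frame with columns \code{old_id}, \code{new_id} and
#'   optionally \code{new_name}; every group id of the model must appear
#'   exactly once in \code{old_id}. Alternatively a named numeric vector
#'   (names = old ids, values = new ids).
#' @return the aggregated \linkS4class{FoodWebModel}, groups ordered by new id.
#' @details Groups may only merge within a group type, and a merged set of two
#'   or more members must have positive total biomass (the weights are
#'   otherwise undefined). Diet CVs of merged cells are combined
#'   conservatively as the maximum member CV; parameter CVs as
#'   biomass-weighted means.
#' @export
aggregateGroups <- function(model, mapping) {
  assertValid(model)
  g <- model@groups
  if (is.numeric(mapping) && !is.null(names(mapping)))
    mapping <- data.frame(old_id = as.integer(names(mapping)),
                          new_id = as.integer(mapping))
  mapping <- as.data.frame(mapping)
  stopifnot(all(c("old_id", "new_id") %in% names(mapping)))
  if (!setequal(mapping$old_id, g$id) || anyDuplicated(mapping$old_id))
    stop("mapping must cover every group id exactly once")
  key <- mapping$new_id[match(g$id, mapping$old_id)]

  newIds <- sort(unique(key))
  members <- split(seq_len(nrow(g)), factor(key, levels = newIds))
  for (m in members) {
    if (length(unique(g$type[m])) > 1)
      stop("cannot merge across group types: ",
           paste(g$name[m], collapse = ", "))
    if (length(m) > 1 && sum(g$biomass[m]) <= 0)
      stop("cannot merge groups with all-zero biomass: ",
           paste(g$name[m], collapse = ", "))
  }

  nn <- length(newIds)
  d <- model@diet
  ped <- model@pedigree

  newGroups <- data.frame(
    id = newIds,
    name = vapply(members, function(m) paste(unique(g$name[m]), collapse = "+"), ""),
    type = vapply(members, function(m) g$type[m][1], ""),
    biomass = vapply(members, function(m) sum(g$biomass[m]), 0),
    pb = NA_real_, qb = NA_real_, ae = NA_real_, ee = NA_real_,
    stringsAsFactors = FALSE)
  if (!is.null(mapping$new_name)) {
    nm <- mapping$new_name[match(newIds, mapping$new_id)]
    newGroups$name <- ifelse(is.na(nm) | !nzchar(nm), newGroups$name, nm)
  }

  wts <- lapply(members, function(m) {
    b <- g$biomass[m]
    if (sum(b) > 0) b / sum(b) else rep(1 / length(m), length(m))
  })
  for (p in c("pb", "qb", "ae"))
    newGroups[[p]] <- vapply(seq_len(nn),
      function(k) sum(wts[[k]] * g[[p]][members[[k]]]), 0)

  ## diet: biomass-weighted mean over member predator columns, then sum rows
  newDiet <- matrix(0, nn, nn, dimnames = list(newIds, newIds))
  newDietCV <- matrix(0, nn, nn, dimnames = list(newIds, newIds))
  for (k in seq_len(nn)) {
    ## weight diet columns by biomass among members that are consumers (a
    ## zero-qb member has no diet and must not dilute the merged column)
    m <- members[[k]]
    w <- wts[[k]]
    isCons <- g$qb[m] > 0 & colSums(d[, m, drop = FALSE]) > 0
    if (any(isCons)) {
      w <- ifelse(isCons, w, 0)
      w <- w / sum(w)
    }
    colw <- as.numeric(d[, m, drop = FALSE] %*% w)
    newDiet[, k] <- vapply(members, function(mm) sum(colw[mm]), 0)
    cvcol <- ped$diet[, members[[k]], drop = FALSE]
    newDietCV[, k] <- vapply(members,
      function(m) max(cvcol[m, , drop = FALSE], 0), 0)
  }
  ## drift from floating-point averaging: renormalize consumer columns
  newDiet <- .renormalizeColumns(newDiet,
    which(newGroups$type == "living" & newGroups$qb > 0))

  fleetsNew <- as.character(newIds[newGroups$type == "fleet"])
  oldFleetCols <- colnames(model@landings)
  newLand <- matrix(0, nn, length(fleetsNew),
                    dimnames = list(newIds, fleetsNew))
  if (length(oldFleetCols)) {
    fleetKey <- as.character(key[match(as.integer(oldFleetCols), g$id)])
    for (k in seq_len(nn)) {
      rows <- colSums(model@landings[members[[k]], , drop = FALSE])
      for (fc in seq_along(oldFleetCols))
        newLand[k, fleetKey[fc]] <- newLand[k, fleetKey[fc]] + rows[fc]
    }
  }

  newPedPar <- matrix(0, nn, 4,
    dimnames = list(newIds, c("biomass", "pb", "qb", "ae")))
  for (k in seq_len(nn))
    newPedPar[k, ] <- as.numeric(wts[[k]] %*%
      ped$params[members[[k]], , drop = FALSE])

  FoodWebModel(newGroups, newDiet, landings = newLand,
               pedigree = list(params = newPedPar, diet = newDietCV),
               currency = model@currency, timeUnit = model@timeUnit,
               provenance = model@provenance)
}

#' Insert a group at trace biomass
#'
#' Appends a functional group that is absent from one of two compared models so
#' that both share a node set, at a vanishingly small biomass (default 1e-5 in
#' the model's currency) that leaves mass balance essentially untouched. The
#' supplied diet column is renormalized to 1; existing consumers can optionally
#' be given a small trace fraction of the new group in their diets.
#'
#' @param model a validated \linkS4class{FoodWebModel}.
#' @param name new group name (must not already exist).
#' @param type group type, default \code{"living"}.
#' @param biomass insertion biomass, must be > 0; default \code{1e-5}.
#' @param pb,qb,ae rate parameters of the new group.
#' @param diet named numeric vector of prey shares (names = existing group
#'   ids); renormalized to sum to 1. Required when \code{qb > 0}.
#' @param predators optional named numeric vector (names = consumer group ids)
#'   of small fractions epsilon: each named consumer's column is rescaled by
#'   (1 - epsilon) and given epsilon on the new group, registering trace
#'   predation.
#' @param cv pedigree CV attached to the new group's parameters and diet cells.
#' @return the extended \linkS4class{FoodWebModel}.
#' @export
addTraceGroup <- function(model, name, type = "living",
                          biomass = TRACE_BIOMASS,
                          pb = 1, qb = 5, ae = 0.8,
                          diet = NULL, predators = NULL, cv = 0) {
  assertValid(model)
  if (name %in% model@groups$name)
    stop("group name already present: ", name)
  if (!isTRUE(biomass > 0))
    stop("trace insertion requires biomass > 0")
  g <- model@groups
  n <- nrow(g)
  newId <- max(g$id) + 1L
  ids <- as.character(g$id)

  col <- setNames(numeric(n), ids)
  if (qb > 0 && type == "living") {
    if (is.null(diet) || sum(diet) <= 0)
      stop("a living consumer needs a diet column with positive total")
    if (!all(names(diet) %in% ids))
      stop("diet names must be existing group ids")
    col[names(diet)] <- diet / sum(diet)
  }

  newGroups <- rbind(g, data.frame(id = newId, name = name, type = type,
                                   biomass = biomass, pb = pb, qb = qb,
                                   ae = ae, ee = NA_real_))
  d <- rbind(cbind(model@diet, col), c(setNames(numeric(n), ids), 0))
  dimnames(d) <- list(c(ids, newId), c(ids, newId))
  if (!is.null(predators)) {
    if (any(predators < 0 | predators >= 1))
      stop("predator trace fractions must lie in [0, 1)")
    for (j in names(predators)) {
      eps <- predators[[j]]
      d[, j] <- d[, j] * (1 - eps)
      d[as.character(newId), j] <- eps
    }
  }

  land <- rbind(model@landings, setNames(numeric(ncol(model@landings)),
                                         colnames(model@landings)))
  rownames(land) <- c(ids, newId)
  if (type == "fleet") {
    land <- cbind(land, setNames(numeric(n + 1), newId))
    colnames(land)[ncol(land)] <- newId
  }

  ped <- model@pedigree
  pedPar <- rbind(ped$params, rep(cv, 4))
  pedDiet <- rbind(cbind(ped$diet, ifelse(col > 0, cv, 0)), numeric(n + 1))
  rownames(pedPar) <- c(ids, newId)
  dimnames(pedDiet) <- dimnames(d)

  FoodWebModel(newGroups, d, landings = land,
               pedigree = list(params = pedPar, diet = pedDiet),
               currency = model@currency, timeUnit = model@timeUnit,
               provenance = model@provenance)
}

## renormalize the given columns to sum to 1. Drift <= NORM_TOL is silent,
## drift <= errorAbove warns, larger drift errors (unless errorAbove = Inf,
## used by operations whose whole point is a large renormalization).
.renormalizeColumns <- function(m, cols, errorAbove = NORM_WARN) {
  for (j in cols) {
    s <- sum(m[, j])
    if (s <= 0) next
    drift <- abs(s - 1)
    if (drift > errorAbove)
      stop(sprintf("diet column %s sums to %.8f; drift too large to renormalize silently",
                   colnames(m)[j], s))
    if (drift > NORM_TOL)
      warning(sprintf("diet column %s renormalized from %.10f",
                      colnames(m)[j], s))
    m[, j] <- m[, j] / s
  }
  m
}
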