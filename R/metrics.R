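#' Analyzed node set
#'
#' The node set over which network metrics are computed. Following the
#' convention that nutrient pools are not functional groups for network
#' purposes, the default includes living groups, detritus pools and fleets and
#' excludes nutrients; the rule is overridable.
#'
#' @param model a \linkS4class{FoodWebModel}.
#' @param include group types to include.
#' @return integer vector of group ids, in model order.
#' @export
analyzedNodes <- function(model, include = c("living", "detritus", "fleet")) {
  groupIdsOfType(model, include)
}

#' Diet-weighted trophic levels
#'
#' Computes the standard diet-weighted trophic level
#' \eqn{TL_j = 1 + \sum_i DC_{ij} TL_i}
#' over an analyzed node set (nutrients excluded by default). Nodes with no
#' prey inside the node set (producers, detritus) sit at TL = 1; consumers are
#' solved jointly as the linear system \eqn{(I - DC^T) TL = 1}, which handles
#' cycles (cannibalism, mutual predation) exactly. Fleet nodes, which have no
#' diet column, are assigned the landings-share-weighted mean prey TL plus 1.
#'
#' @param model a \linkS4class{FoodWebModel}, or a square diet matrix (then
#'   \code{nodes} must be its ids and every node with a zero column is basal).
#' @param nodes ids of the analyzed node set; default
#'   \code{analyzedNodes(model)}.
#' @return named numeric vector of trophic levels (names = node ids).
#' @details Diet columns are renormalized over the analyzed node set, so a
#'   consumer feeding partly on excluded nutrient pools has its remaining diet
#'   rescaled to 1. A consumer loop with no path to a basal node makes the
#'   system singular; the offending groups are named in the error.
#' @export
trophicLevels <- function(model, nodes = NULL) {
  if (is(model, "FoodWebModel")) {
    if (is.null(nodes)) nodes <- analyzedNodes(model)
    ids <- as.character(nodes)
    d <- model@diet[ids, ids, drop = FALSE]
    g <- model@groups
    ## fleet "diet" = normalized landings composition over analyzed nodes
    fl <- intersect(ids, as.character(g$id[g$type == "fleet"]))
    for (f in fl) {
      y <- model@landings[ids, f]
      if (sum(y) > 0) d[, f] <- y / sum(y)
    }
  } else {
    d <- as.matrix(model)
    if (is.null(nodes)) nodes <- colnames(d)
    ids <- as.character(nodes)
    d <- d[ids, ids, drop = FALSE]
  }
  cs <- colSums(d)
  cons <- cs > 0
  d[, cons] <- sweep(d[, cons, drop = FALSE], 2, cs[cons], `/`)

  tl <- setNames(rep(1, length(ids)), ids)
  if (any(cons)) {
    C <- ids[cons]
    B <- ids[!cons]
    A <- diag(length(C)) - t(d[C, C, drop = FALSE])
    rhs <- 1 + as.numeric(colSums(d[B, C, drop = FALSE]))
    sol <- tryCatch(solve(A, rhs), error = function(e) {
      stop("trophic-level system is singular: consumer loop with no path ",
           "to a basal node among groups ", paste(C, collapse = ", "),
           call. = FALSE)
    })
    tl[C] <- sol
  }
  tl
}

#' Mean and biomass-weighted trophic level
#'
#' @param tl named trophic-level vector (from \code{\link{trophicLevels}}).
#' @return arithmetic mean of the trophic levels.
#' @export
meanTrophicLevel <- function(tl) mean(tl)

#' @rdname meanTrophicLevel
#' @param biomass biomass vector aligned with \code{tl} (same order or same
#'   names).
#' @return \code{biomassWeightedTL}: the biomass-weighted mean
#'   \eqn{\sum B_i TL_i / \sum B_i}.
#' @export
biomassWeightedTL <- function(tl, biomass) {
  if (!is.null(names(biomass)) && !is.null(names(tl)))
    biomass <- biomass[names(tl)]
  if (length(biomass) != length(tl))
    stop("tl and biomass must align")
  if (sum(biomass) <= 0) stop("all-zero biomass: weighted mean undefined")
  sum(biomass * tl) / sum(biomass)
}

#' Connectance and link density
#'
#' A link is any strictly positive directed edge of the adjacency (diet or
#' landings support, or a flux matrix); self-links count, so an N-node network
#' has N^2 possible links. Connectance = links / N^2; link density = links / N
#' (identically connectance times N).
#'
#' @param adjacency square numeric or logical matrix over the analyzed node
#'   set.
#' @return a single number.
#' @export
connectance <- function(adjacency) {
  n <- .checkAdjacency(adjacency)
  sum(adjacency > 0) / n^2
}

#' @rdname connectance
#' @export
linkDensity <- function(adjacency) {
  n <- .checkAdjacency(adjacency)
  sum(adjacency > 0) / n
}

.checkAdjacency <- function(a) {
  if (!is.matrix(a) || nrow(a) != ncol(a))
    stop("adjacency must be a square matrix")
  if (nrow(a) == 0) stop("empty node set")
  nrow(a)
}

#' Trophic adjacency of a model
#'
#' Binary support of trophic links over a node set: \code{A[i, j]} is 1 when
#' predator j takes prey i in its diet (\code{DC > 0}) or fleet j lands group
#' i (\code{Y > 0}). Realized links are counted on this support, not on a
#' thresholded flux.
#'
#' @param model a \linkS4class{FoodWebModel}.
#' @param nodes analyzed node ids; default \code{analyzedNodes(model)}.
#' @return square 0/1 matrix.
#' @export
trophicAdjacency <- function(model, nodes = NULL) {
  if (is.null(nodes)) nodes <- analyzedNodes(model)
  ids <- as.character(nodes)
  a <- (model@diet[ids, ids, drop = FALSE] > 0) * 1
  fl <- intersect(ids, as.character(groupIdsOfType(model, "fleet")))
  if (length(fl))
    a[, fl] <- (model@landings[ids, fl, drop = FALSE] > 0) * 1
  a
}

#' One-row network metric summary
#'
#' Computes the comparison statistics for one model over its analyzed node
#' set: node and link counts, mean and biomass-weighted trophic level,
#' connectance, and link density.
#'
#' @param model a \linkS4class{FoodWebModel}.
#' @param nodes analyzed node ids; default \code{analyzedNodes(model)}.
#' @return one-row data.frame with columns \code{n_nodes}, \code{n_links},
#'   \code{mean_tl}, \code{biomass_weighted_tl}, \code{connectance},
#'   \code{link_density}.
#' @export
networkMetrics <- function(model, nodes = NULL) {
  if (is.null(nodes)) nodes <- analyzedNodes(model)
  ids <- as.character(nodes)
  a <- trophicAdjacency(model, nodes)
  tl <- trophicLevels(model, nodes)
  b <- setNames(model@groups$biomass, model@groups$id)[ids]
  data.frame(
    n_nodes = length(ids),
    n_links = sum(a > 0),
    mean_tl = meanTrophicLevel(tl),
    biomass_weighted_tl = biomassWeightedTL(tl, b),
    connectance = connectance(a),
    link_density = linkDensity(a))
}

#' Node-bootstrap of connectance and link density
#'
#' Generates bootstrap replicates of the structural metrics by resampling
#' which nodes to use: each replicate draws N node indices with replacement,
#' forms the induced N x N matrix \code{A[s, s]} (duplicate rows and columns
#' retained), and recomputes connectance and link density.
#'
#' @param adjacency square adjacency matrix (see
#'   \code{\link{trophicAdjacency}}).
#' @param nBoot number of bootstrap replicates (the comparison analyses use
#'   100).
#' @param seed RNG seed for reproducibility.
#' @return list with \code{replicates} (data.frame: replicate, connectance,
#'   link_density) and \code{summary} (mean and SD per metric).
#' @export
bootstrapMetrics <- function(adjacency, nBoot = 100, seed = 1) {
  n <- .checkAdjacency(adjacency)
  stopifnot(nBoot >= 1)
  set.seed(seed)
  reps <- vapply(seq_len(nBoot), function(r) {
    s <- sample.int(n, n, replace = TRUE)
    ab <- adjacency[s, s, drop = FALSE]
    c(connectance(ab), linkDensity(ab))
  }, numeric(2))
  replicates <- data.frame(replicate = seq_len(nBoot),
                           connectance = reps[1, ],
                           link_density = reps[2, ])
  summary <- data.frame(
    metric = c("connectance", "link_density"),
    mean = c(mean(replicates$connectance), mean(replicates$link_density)),
    sd = c(sd(replicates$connectance), sd(replicates$link_density)))
  list(replicates = replicates, summary = summary)
}
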