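#' @import methods
#' @importFrom stats rnorm rlnorm runif setNames t.test pt sd quantile
#' @importFrom utils read.csv write.csv
NULL

GROUP_TYPES <- c("living", "nutrient", "detritus", "fleet")
NORM_TOL <- 1e-9      # hard tolerance on every normalisation invariant
NORM_WARN <- 1e-6     # drift below this is silently renormalised with a warning
TRACE_BIOMASS <- 1e-5 # trace-insertion default, mt km^-2

#' Mass-balanced food-web model
#'
#' An S4 container for one parameterized ecosystem state: an ordered table of
#' functional groups (living groups, nutrient pools, detritus pools, fishing
#' fleets), a square diet-composition matrix, a landings matrix, and pedigree
#' coefficients of variation expressing data-quality-based uncertainty on every
#' parameter and diet cell.
#'
#' @slot groups data.frame with columns \code{id}, \code{name}, \code{type}
#'   (one of living/nutrient/detritus/fleet), \code{biomass}, \code{pb}
#'   (production/biomass), \code{qb} (consumption/biomass), \code{ae}
#'   (assimilation efficiency), \code{ee} (ecotrophic efficiency, \code{NA}
#'   until computed).
#' @slot diet square numeric matrix \code{DC[prey, predator]}; each living
#'   consumer's column sums to 1.
#' @slot landings numeric matrix \code{[group, fleet]} of catch rates.
#' @slot pedigree list with elements \code{params} (groups x biomass/pb/qb/ae
#'   CV matrix) and \code{diet} (CV per diet cell).
#' @slot currency biomass-density currency tag, e.g. \code{"mt km^-2"}.
#' @slot timeUnit rate time-unit tag, e.g. \code{"yr^-1"}.
#' @slot provenance free-text description of the model's origin.
#' @export
setClass("FoodWebModel",
  slots = c(
    groups = "data.frame",
    diet = "matrix",
    landings = "matrix",
    pedigree = "list",
    currency = "character",
    timeUnit = "character",
    provenance = "character"
  )
)

setValidity("FoodWebModel", function(object) {
  v <- validateModel(object, structural = TRUE)
  if (length(v) == 0) TRUE else v
})

#' Directed consumption-flux network
#'
#' Node biomasses plus directed edge weights \code{q[i, j]}: the rate at which
#' consumer (or fleet) \code{j} removes biomass from prey \code{i}, in the
#' model's biomass-density per time.
#'
#' @slot nodes data.frame with \code{id}, \code{name}, \code{type},
#'   \code{biomass}.
#' @slot flux square numeric matrix of consumption rates, prey in rows.
#' @slot currency,timeUnit unit tags inherited from the source model.
#' @export
setClass("FluxNetwork",
  slots = c(nodes = "data.frame", flux = "matrix",
            currency = "character", timeUnit = "character")
)

setValidity("FluxNetwork", function(object) {
  if (nrow(object@flux) != ncol(object@flux))
    return("flux matrix must be square")
  if (nrow(object@nodes) != nrow(object@flux))
    return("node table and flux matrix dimensions disagree")
  if (any(object@flux < 0)) return("flux rates must be non-negative")
  TRUE
})

#' Production-fate matrix
#'
#' For every living group, the split of its total consumption Q = B * Q/B into
#' non-assimilated egestion (to detritus pools), metabolic costs (to nutrient
#' pools), production consumed by each predator or fleet, and senescence (to
#' detritus pools). Each group's fractions sum to 1: all consumption is
#' accounted for.
#'
#' @slot groupIds integer ids of the living groups (rows).
#' @slot egestion matrix living x detritus-pool fate fractions.
#' @slot metabolism matrix living x nutrient-pool fate fractions.
#' @slot predation matrix living x (consumer + fleet) fate fractions.
#' @slot senescence matrix living x detritus-pool fate fractions.
#' @export
setClass("ProductionFateMatrix",
  slots = c(groupIds = "integer", egestion = "matrix", metabolism = "matrix",
            predation = "matrix", senescence = "matrix")
)

setValidity("ProductionFateMatrix", function(object) {
  tot <- rowSums(object@egestion) + rowSums(object@metabolism) +
    rowSums(object@predation) + rowSums(object@senescence)
  if (any(abs(tot - 1) > NORM_TOL))
    return(sprintf("fate fractions of group(s) %s do not sum to 1",
                   paste(object@groupIds[abs(tot - 1) > NORM_TOL],
                         collapse = ", ")))
  allv <- c(object@egestion, object@metabolism, object@predation,
            object@senescence)
  if (any(allv < -NORM_TOL) || any(allv > 1 + NORM_TOL))
    return("fate fractions must lie in [0, 1]")
  TRUE
})

#' Difference network between two harmonized models
#'
#' Node-wise biomass multiplication factors (second state over first; a factor
#' of 1 means no change) and edge-wise signed consumption-flux deltas
#' (second minus first), on a shared node ordering.
#'
#' @slot nodes data.frame with \code{id}, \code{name}, \code{type},
#'   \code{biomassBefore}, \code{biomassAfter}, \code{factor},
#'   \code{logFactor}.
#' @slot delta square matrix of signed flux differences (after - before).
#' @export
setClass("DifferenceNetwork",
  slots = c(nodes = "data.frame", delta = "matrix")
)

#' Monte Carlo ensemble of perturbed food-web models
#'
#' Holds the base model plus \code{n} seeded draws in which every CV-flagged
#' parameter and diet cell was resampled; used to propagate pedigree
#' uncertainty into downstream metrics.
#'
#' @slot base the unperturbed \linkS4class{FoodWebModel}.
#' @slot draws list of perturbed models.
#' @slot n number of draws.
#' @slot seed RNG seed used.
#' @slot sampling "normal" (truncated at 0) or "lognormal".
#' @export
setClass("MonteCarloEnsemble",
  slots = c(base = "FoodWebModel", draws = "list", n = "integer",
            seed = "integer", sampling = "character")
)

## ---- constructors -----------------------------------------------------------

#' Construct a food-web model
#'
#' @param groups data.frame with columns \code{id,name,type,biomass,pb,qb,ae}
#'   (and optionally \code{ee}).
#' @param diet square matrix \code{[prey, predator]} in group order (dimnames
#'   are set to the group ids).
#' @param landings matrix \code{[group, fleet]} of catch rates, columns named
#'   by fleet group id; \code{NULL} for all-zero.
#' @param pedigree list with \code{params} and \code{diet} CV matrices;
#'   \code{NULL} for all-zero (all parameters fixed).
#' @param currency,timeUnit unit tags; the analysis is unit-covariant and no
#'   conversion is ever applied.
#' @param provenance free text recorded with the model.
#' @param validate run full invariant validation (set \code{FALSE} to build a
#'   deliberately broken model for inspection).
#' @return a \linkS4class{FoodWebModel}.
#' @export
FoodWebModel <- function(groups, diet, landings = NULL, pedigree = NULL,
                         currency = "mt km^-2", timeUnit = "yr^-1",
                         provenance = "", validate = TRUE) {
  groups <- as.data.frame(groups, stringsAsFactors = FALSE)
  need <- c("id", "name", "type", "biomass", "pb", "qb", "ae")
  miss <- setdiff(need, names(groups))
  if (length(miss))
    stop("groups table lacks column(s): ", paste(miss, collapse = ", "))
  groups$id <- as.integer(groups$id)
  if (is.null(groups$ee)) groups$ee <- NA_real_
  groups <- groups[, c(need, "ee")]
  rownames(groups) <- NULL
  n <- nrow(groups)
  ids <- as.character(groups$id)

  diet <- as.matrix(diet)
  if (nrow(diet) != n || ncol(diet) != n)
    stop("diet matrix must be square with one row/column per group (",
         n, " groups, got ", nrow(diet), " x ", ncol(diet), ")")
  dimnames(diet) <- list(ids, ids)

  fleets <- ids[groups$type == "fleet"]
  if (is.null(landings)) {
    landings <- matrix(0, n, length(fleets), dimnames = list(ids, fleets))
  } else {
    landings <- as.matrix(landings)
    if (nrow(landings) != n || ncol(landings) != length(fleets))
      stop("landings matrix must be n_groups x n_fleets")
    dimnames(landings) <- list(ids, fleets)
  }

  if (is.null(pedigree)) {
    pedigree <- list(
      params = matrix(0, n, 4, dimnames = list(ids, c("biomass", "pb", "qb", "ae"))),
      diet = matrix(0, n, n, dimnames = list(ids, ids))
    )
  } else {
    stopifnot(is.list(pedigree), all(c("params", "diet") %in% names(pedigree)))
    dimnames(pedigree$params) <- list(ids, c("biomass", "pb", "qb", "ae"))
    dimnames(pedigree$diet) <- list(ids, ids)
  }

  m <- new("FoodWebModel", groups = groups, diet = diet, landings = landings,
           pedigree = pedigree, currency = currency, timeUnit = timeUnit,
           provenance = provenance)
  if (validate) {
    v <- validateModel(m)
    if (length(v)) stop("invalid food-web model:\n  ",
                        paste(v, collapse = "\n  "))
  }
  m
}

## ---- accessors --------------------------------------------------------------

#' @rdname FoodWebModel-accessors
#' @name FoodWebModel-accessors
#' @title Accessors for food-web model components
#' @param object a \linkS4class{FoodWebModel} (or \linkS4class{FluxNetwork}
#'   where noted).
#' @details Slot access from user code is discouraged; these accessors are the
#'   supported surface.
NULL

#' @describeIn FoodWebModel-accessors the group parameter table.
#' @export
groupTable <- function(object) object@groups

#' @describeIn FoodWebModel-accessors the square diet-composition matrix
#'   \code{DC[prey, predator]}.
#' @export
dietMatrix <- function(object) object@diet

#' @describeIn FoodWebModel-accessors the landings (catch-rate) matrix
#'   \code{[group, fleet]}.
#' @export
landingsMatrix <- function(object) object@landings

#' @describeIn FoodWebModel-accessors pedigree CV list (\code{params},
#'   \code{diet}).
#' @export
pedigreeCVs <- function(object) object@pedigree

#' @describeIn FoodWebModel-accessors number of groups.
#' @export
nGroups <- function(object) nrow(object@groups)

#' @describeIn FoodWebModel-accessors integer group ids, in model order.
#' @export
groupIds <- function(object) object@groups$id

#' @describeIn FoodWebModel-accessors ids of a given group type.
#' @param type one of \code{"living"}, \code{"nutrient"}, \code{"detritus"},
#'   \code{"fleet"}.
#' @export
groupIdsOfType <- function(object, type) {
  object@groups$id[object@groups$type %in% type]
}

#' @describeIn FoodWebModel-accessors node table of a flux network.
#' @export
nodeTable <- function(object) object@nodes

#' @describeIn FoodWebModel-accessors consumption-rate matrix of a flux
#'   network, prey in rows.
#' @export
fluxMatrix <- function(object) object@flux

#' Combined production-fate matrix
#'
#' Collapses the four fate components of a \linkS4class{ProductionFateMatrix}
#' into one living-groups x destinations matrix (egestion and senescence both
#' land in the detritus-pool columns). Rows sum to 1.
#'
#' @param object a \linkS4class{ProductionFateMatrix}.
#' @return numeric matrix, one row per living group.
#' @export
fateMatrix <- function(object) {
  det <- object@egestion + object@senescence
  cbind(det, object@metabolism, object@predation)
}

#' @rdname MonteCarloEnsemble-accessors
#' @name MonteCarloEnsemble-accessors
#' @title Accessors for Monte Carlo ensembles
#' @param object a \linkS4class{MonteCarloEnsemble}.
NULL

#' @describeIn MonteCarloEnsemble-accessors list of perturbed draw models.
#' @export
ensembleDraws <- function(object) object@draws

#' @describeIn MonteCarloEnsemble-accessors number of draws.
#' @export
ensembleSize <- function(object) object@n

## ---- show -------------------------------------------------------------------

setMethod("show", "FoodWebModel", function(object) {
  tab <- table(factor(object@groups$type, levels = GROUP_TYPES))
  cat("FoodWebModel:", nrow(object@groups), "groups (",
      paste(sprintf("%d %s", as.integer(tab), names(tab)), collapse = ", "),
      ")\n")
  cat("  currency:", object@currency, " time unit:", object@timeUnit, "\n")
  nl <- sum(object@diet > 0)
  cat("  diet links:", nl, " landings entries:", sum(object@landings > 0), "\n")
  if (!all(is.na(object@groups$ee))) {
    ee <- object@groups$ee[object@groups$type == "living"]
    cat(sprintf("  ecotrophic efficiency: max %.3f (%s)\n", max(ee, na.rm = TRUE),
                if (isTRUE(all(ee <= 1 + NORM_TOL))) "balanced" else "UNBALANCED"))
  }
  if (nzchar(object@provenance)) cat("  provenance:", object@provenance, "\n")
  invisible(NULL)
})

setMethod("show", "FluxNetwork", function(object) {
  cat("FluxNetwork:", nrow(object@nodes), "nodes,",
      sum(object@flux > 0), "positive edges\n")
  cat(sprintf("  total flux: %.4g %s %s\n", sum(object@flux),
              object@currency, object@timeUnit))
  invisible(NULL)
})

setMethod("show", "DifferenceNetwork", function(object) {
  ch <- sum(abs(object@nodes$factor - 1) > NORM_TOL)
  cat("DifferenceNetwork:", nrow(object@nodes), "nodes (", ch, "changed ),",
      sum(abs(object@delta) > 0), "non-zero edge deltas\n")
  invisible(NULL)
})

setMethod("show", "MonteCarloEnsemble", function(object) {
  cat("MonteCarloEnsemble:", object@n, "draws (", object@sampling,
      "sampling, seed", object@seed, ") of a",
      nrow(object@base@groups), "group model\n")
  invisible(NULL)
})
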