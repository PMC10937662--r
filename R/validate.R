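#' Validate a food-web model
#'
#' Checks every structural and mass-balance-precondition invariant of a model
#' and returns a character vector of human-readable violations (empty when the
#' model is well formed). Checked rules:
#' \itemize{
#'   \item unique positive integer ids; known group types; index sets of the
#'     diet, landings and pedigree matrices agree with the group table;
#'   \item biomass, P/B, Q/B, landings and pedigree CVs non-negative;
#'     assimilation efficiency in [0, 1];
#'   \item for living groups with Q/B > 0: P/B <= AE * Q/B (production cannot
#'     exceed assimilated consumption);
#'   \item each living consumer's diet column sums to 1 (absolute tolerance
#'     1e-9); diet cells in [0, 1];
#'   \item nutrient, detritus and fleet columns of the diet matrix are all
#'     zero (fleets take catch through landings, not diet), and nutrient or
#'     detritus pools never act as predators on living prey.
#' }
#'
#' @param model a \linkS4class{FoodWebModel}.
#' @param structural only run the cheap structural checks (used by the class
#'   validity method).
#' @return character vector of violations; \code{character(0)} if valid.
#' @export
validateModel <- function(model, structural = FALSE) {
  g <- model@groups
  d <- model@diet
  v <- character(0)

  if (anyDuplicated(g$id)) v <- c(v, "group ids are not unique")
  if (any(g$id < 1)) v <- c(v, "group ids must be >= 1")
  bad <- setdiff(unique(g$type), GROUP_TYPES)
  if (length(bad))
    v <- c(v, paste0("unknown group type(s): ", paste(bad, collapse = ", ")))
  n <- nrow(g)
  if (nrow(d) != n || ncol(d) != n)
    v <- c(v, "diet matrix is not square on the group set")
  nf <- sum(g$type == "fleet")
  if (nrow(model@landings) != n || ncol(model@landings) != nf)
    v <- c(v, "landings matrix dimensions disagree with the group table")
  if (length(v) || structural) return(v)

  ids <- as.character(g$id)
  if (any(g$biomass < 0)) {
    w <- which(g$biomass < 0)
    v <- c(v, sprintf("group %d (%s): negative biomass", g$id[w], g$name[w]))
  }
  if (any(g$pb < 0)) v <- c(v, sprintf("group %d: negative pb", g$id[g$pb < 0]))
  if (any(g$qb < 0)) v <- c(v, sprintf("group %d: negative qb", g$id[g$qb < 0]))
  if (any(g$ae < 0 | g$ae > 1))
    v <- c(v, sprintf("group %d: ae outside [0, 1]", g$id[g$ae < 0 | g$ae > 1]))
  if (any(model@landings < 0)) v <- c(v, "negative landings rate")
  if (any(model@pedigree$params < 0) || any(model@pedigree$diet < 0))
    v <- c(v, "negative pedigree CV")

  liv <- g$type == "living"
  over <- liv & g$qb > 0 & g$pb > g$ae * g$qb + NORM_TOL
  if (any(over))
    v <- c(v, sprintf(
      "group %d (%s): pb (%.4g) exceeds ae*qb (%.4g); production cannot exceed assimilated consumption",
      g$id[over], g$name[over], g$pb[over], (g$ae * g$qb)[over]))

  if (any(d < -NORM_TOL) || any(d > 1 + NORM_TOL))
    v <- c(v, "diet fractions outside [0, 1]")

  ## living consumers: columns sum to 1
  cons <- liv & g$qb > 0
  cs <- colSums(d)
  offc <- cons & abs(cs - 1) > NORM_TOL
  if (any(offc))
    v <- c(v, sprintf(
      "diet column of consumer %d (%s) sums to %.10g, expected 1",
      g$id[offc], g$name[offc], cs[offc]))

  ## non-consumer columns all zero
  nonliv <- g$type %in% c("nutrient", "detritus", "fleet")
  offz <- nonliv & cs > NORM_TOL
  if (any(offz))
    v <- c(v, sprintf(
      "diet column of %s group %d (%s) must be all zero",
      g$type[offz], g$id[offz], g$name[offz]))
  v
}

#' Assert a model is valid, stopping otherwise
#' @param model a \linkS4class{FoodWebModel}.
#' @return the model, invisibly.
#' @keywords internal
assertValid <- function(model) {
  v <- validateModel(model)
  if (length(v)) stop("invalid food-web model:\n  ", paste(v, collapse = "\n  "))
  invisible(model)
}
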