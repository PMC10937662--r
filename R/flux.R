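#' Consumption-flux network
#'
#' Turns a model into the directed network of biomass-exchange rates: for every
#' living consumer j, \code{q[i, j] = B_j * (Q/B)_j * DC[i, j]}; for every
#' fleet f, \code{q[i, f] = Y[i, f]} (catch). Node biomasses are copied from
#' the model. When a consumer's diet column sums to 1, its total inflow equals
#' its total consumption B * Q/B.
#'
#' @param model a validated \linkS4class{FoodWebModel}.
#' @return a \linkS4class{FluxNetwork}.
#' @export
consumptionFlux <- function(model) {
  assertValid(model)
  g <- model@groups
  cons <- g$type == "living" & g$qb > 0
  w <- ifelse(cons, g$biomass * g$qb, 0)
  q <- sweep(model@diet, 2, w, `*`)
  fl <- as.character(g$id[g$type == "fleet"])
  if (length(fl)) q[, fl] <- model@landings[, fl, drop = FALSE]
  new("FluxNetwork",
      nodes = g[, c("id", "name", "type", "biomass")],
      flux = q, currency = model@currency, timeUnit = model@timeUnit)
}
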