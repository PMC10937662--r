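#' Draw a Monte Carlo ensemble from pedigree uncertainty
#'
#' Propagates the pedigree CVs of a model into an ensemble of plausible
#' parameterizations: in each draw, every CV-flagged group parameter (biomass,
#' P/B, Q/B, AE) and every CV-flagged diet cell is resampled from a normal
#' distribution with mean equal to the base value and standard deviation
#' CV * |base value|, truncated at zero; diet columns are then renormalized to
#' sum to 1 and all derived quantities (ecotrophic efficiency, fluxes,
#' metrics) are recomputed per draw. A parameter with CV = 0 is held fixed, so
#' with all CVs zero every draw equals the base model exactly.
#'
#' @param model a validated \linkS4class{FoodWebModel} with pedigree CVs.
#' @param n number of draws (the footprint/reach analyses use 1000; the
#'   network-metric comparisons use 100).
#' @param seed RNG seed; the ensemble is bit-reproducible given the seed.
#' @param sampling \code{"normal"} (truncated at 0, the default) or
#'   \code{"lognormal"} (meanlog/sdlog matched to the same mean and CV, never
#'   negative).
#' @param maxRetries bound on redraws of a diet column that truncates to all
#'   zero.
#' @return a \linkS4class{MonteCarloEnsemble}.
#' @details Assimilation efficiency is additionally clipped to [0, 1], and
#'   P/B is capped at AE * Q/B where a joint draw would violate the
#'   thermodynamic constraint; both adjustments are rare for the conservative
#'   CV classes (0.1 / 0.5 / 0.8) used in practice.
#' @export
drawEnsemble <- function(model, n = 1000, seed = 1,
                         sampling = c("normal", "lognormal"),
                         maxRetries = 10) {
  assertValid(model)
  sampling <- match.arg(sampling)
  stopifnot(n >= 1)
  set.seed(seed)
  draws <- vector("list", n)
  for (k in seq_len(n))
    draws[[k]] <- .perturbModel(model, sampling, maxRetries)
  new("MonteCarloEnsemble", base = model, draws = draws, n = as.integer(n),
      seed = as.integer(seed), sampling = sampling)
}

.sampleParam <- function(base, cv, sampling) {
  idx <- which(cv > 0 & base != 0)
  if (!length(idx)) return(base)
  out <- base
  if (sampling == "normal") {
    out[idx] <- pmax(0, rnorm(length(idx), base[idx], cv[idx] * abs(base[idx])))
  } else {
    sdlog <- sqrt(log1p(cv[idx]^2))
    meanlog <- log(base[idx]) - sdlog^2 / 2
    out[idx] <- rlnorm(length(idx), meanlog, sdlog)
  }
  out
}

.perturbModel <- function(model, sampling, maxRetries) {
  g <- model@groups
  ped <- model@pedigree
  for (p in c("biomass", "pb", "qb", "ae"))
    g[[p]] <- .sampleParam(g[[p]], ped$params[, p], sampling)
  g$ae <- pmin(g$ae, 1)
  liv <- g$type == "living" & g$qb > 0
  g$pb[liv] <- pmin(g$pb[liv], (g$ae * g$qb)[liv])
  g$ee <- NA_real_

  d <- model@diet
  consCols <- which(liv)
  for (j in consCols) {
    if (all(ped$diet[, j] == 0)) next
    for (try in seq_len(maxRetries)) {
      col <- .sampleParam(d[, j], ped$diet[, j], sampling)
      if (sum(col) > 0) break
      col <- NULL
    }
    if (is.null(col))
      stop("diet column of group ", g$id[j],
           " truncated to zero in every retry")
    d[, j] <- col / sum(col)
  }
  new("FoodWebModel", groups = g, diet = d, landings = model@landings,
      pedigree = ped, currency = model@currency, timeUnit = model@timeUnit,
      provenance = model@provenance)
}

#' Per-draw metrics of an ensemble
#'
#' Evaluates footprint/reach for a set of focal groups, and optionally the
#' network metrics, on every draw of a Monte Carlo ensemble.
#'
#' @param ensemble a \linkS4class{MonteCarloEnsemble}.
#' @param focals named list of focal id/name vectors (names label the
#'   metrics), or \code{NULL} for none.
#' @param network also compute mean/biomass-weighted trophic level,
#'   connectance and link density per draw.
#' @return data.frame, one row per draw, one column per metric
#'   (\code{<focal>.footprint}, \code{<focal>.reach}, network metric names).
#' @export
ensembleMetrics <- function(ensemble, focals = NULL, network = FALSE) {
  rows <- lapply(ensembleDraws(ensemble), function(m) {
    out <- list()
    if (!is.null(focals)) {
      for (nm in names(focals)) {
        out[[paste0(nm, ".footprint")]] <- footprint(m, focals[[nm]])
        out[[paste0(nm, ".reach")]] <- reach(m, focals[[nm]])
      }
    }
    if (network) {
      nm <- networkMetrics(m)
      out$mean_tl <- nm$mean_tl
      out$biomass_weighted_tl <- nm$biomass_weighted_tl
      out$connectance <- nm$connectance
      out$link_density <- nm$link_density
    }
    as.data.frame(out)
  })
  res <- do.call(rbind, rows)
  res <- cbind(draw = seq_len(nrow(res)), res)
  rownames(res) <- NULL
  res
}

#' Welch's two-sample t-test
#'
#' Unequal-variance (Welch) two-tailed t-test, the form whose fractional
#' Satterthwaite degrees of freedom appear in the model-comparison tables.
#' Thin wrapper around \code{stats::t.test(var.equal = FALSE)} returning the
#' three reported numbers.
#'
#' @param x,y numeric samples (each of length >= 2).
#' @return list with \code{t}, \code{df} and two-tailed \code{p}.
#' @details Two degenerate-variance samples with equal means give t = 0,
#'   p = 1; unequal means with zero variance are undefined and raise an error.
#' @export
welchTTest <- function(x, y) {
  stopifnot(length(x) >= 2, length(y) >= 2)
  if (sd(x) == 0 && sd(y) == 0) {
    if (mean(x) == mean(y)) return(list(t = 0, df = length(x) + length(y) - 2, p = 1))
    stop("both samples have zero variance with unequal means; t undefined")
  }
  ht <- t.test(x, y, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' @rdname welchTTest
#' @param mean1,sd1,n1,mean2,sd2,n2 summary statistics of the two samples, for
#'   recomputing published table rows from their printed mean/SD/N.
#' @export
welchTTestStats <- function(mean1, sd1, n1, mean2, sd2, n2) {
  v1 <- sd1^2 / n1
  v2 <- sd2^2 / n2
  t <- (mean1 - mean2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

#' Bonferroni correction
#'
#' Conservative family-wise correction: adjusted p = min(1, m * p),
#' order-preserving. \code{m} defaults to the number of p-values (matching
#' \code{p.adjust(method = "bonferroni")}) but may be larger when the family
#' of comparisons extends beyond the vector at hand.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @param m family size; must be at least \code{length(p)}.
#' @return adjusted p-values.
#' @export
bonferroni <- function(p, m = length(p)) {
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  if (m < length(p)) stop("family size m must be >= number of p-values")
  pmin(1, m * p)
}

#' Compare two Monte Carlo ensembles metric by metric
#'
#' Runs one Welch t-test per shared metric column of two per-draw metric
#' tables (see \code{\link{ensembleMetrics}}) and applies a Bonferroni
#' correction over the whole family of comparisons, producing the
#' significance table used to flag which group-level footprint/reach or
#' network-metric differences between two ecosystem states are credible.
#'
#' @param metricsA,metricsB data.frames of per-draw metrics with identical
#'   metric columns (a \code{draw} column is ignored).
#' @param m family size for the Bonferroni correction; default the number of
#'   metrics compared.
#' @param alpha family-wise significance level for the flag.
#' @return data.frame with one row per metric: \code{metric}, \code{meanA},
#'   \code{sdA}, \code{meanB}, \code{sdB}, \code{t}, \code{df}, \code{p},
#'   \code{p_adjusted}, \code{significant}.
#' @export
compareEnsembles <- function(metricsA, metricsB, m = NULL, alpha = 0.05) {
  ca <- setdiff(names(metricsA), "draw")
  cb <- setdiff(names(metricsB), "draw")
  if (!identical(sort(ca), sort(cb)))
    stop("metric sets differ between the two ensembles")
  if (is.null(m)) m <- length(ca)
  rows <- lapply(ca, function(col) {
    x <- metricsA[[col]]
    y <- metricsB[[col]]
    ht <- if (sd(x) == 0 && sd(y) == 0 && mean(x) == mean(y))
      list(t = 0, df = length(x) + length(y) - 2, p = 1)
    else welchTTest(x, y)
    data.frame(metric = col, meanA = mean(x), sdA = sd(x),
               meanB = mean(y), sdB = sd(y),
               t = ht$t, df = ht$df, p = ht$p)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- bonferroni(out$p, m)
  out$significant <- out$p_adjusted < alpha
  rownames(out) <- NULL
  out
}
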