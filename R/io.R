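#' Read and write food-web models as CSV directories
#'
#' The exchange format is a directory of plain CSV files:
#' \describe{
#'   \item{groups.csv}{columns \code{id,name,type,biomass,pb,qb,ae} (header
#'     required, UTF-8, '.' decimal).}
#'   \item{diet.csv}{square matrix with an \code{id} header column and one
#'     column per group id; cell [i, j] = fraction of predator j's consumption
#'     taken from prey i.}
#'   \item{landings.csv}{long format \code{group_id,fleet_id,rate}; optional,
#'     absent means no catch.}
#'   \item{pedigree.csv}{\code{target,cv} where target is
#'     \code{param:<group_id>:<biomass|pb|qb|ae>} or
#'     \code{diet:<prey_id>:<predator_id>}; optional, absent means all CVs 0
#'     (a warning notes the defaulting).}
#' }
#' Values are written at full precision so \code{readFoodWebModel(
#' writeFoodWebModel(m, d))} reproduces \code{m} exactly.
#'
#' @param path model directory.
#' @param validate run full validation on read (disable to inspect a broken
#'   model).
#' @return \code{readFoodWebModel}: a \linkS4class{FoodWebModel}.
#' @export
readFoodWebModel <- function(path, validate = TRUE) {
  gf <- file.path(path, "groups.csv")
  df <- file.path(path, "diet.csv")
  if (!file.exists(gf)) stop("missing groups.csv in ", path)
  if (!file.exists(df)) stop("missing diet.csv in ", path)
  groups <- read.csv(gf, stringsAsFactors = FALSE, encoding = "UTF-8")
  if (anyDuplicated(groups$id))
    stop("duplicated group id(s) in groups.csv: ",
         paste(unique(groups$id[duplicated(groups$id)]), collapse = ", "))
  ids <- as.character(groups$id)

  dietRaw <- read.csv(df, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(dietRaw)[1] != "id")
    stop("diet.csv must have an 'id' first column")
  rn <- as.character(dietRaw$id)
  diet <- as.matrix(dietRaw[, -1, drop = FALSE])
  rownames(diet) <- rn
  missCol <- setdiff(ids, colnames(diet))
  missRow <- setdiff(ids, rn)
  if (length(missCol) || length(missRow))
    stop("diet.csv shape mismatch; missing row/column for id(s): ",
         paste(unique(c(missRow, missCol)), collapse = ", "))
  diet <- diet[ids, ids]

  fleets <- ids[groups$type == "fleet"]
  landings <- matrix(0, nrow(groups), length(fleets),
                     dimnames = list(ids, fleets))
  lf <- file.path(path, "landings.csv")
  if (file.exists(lf)) {
    ll <- read.csv(lf, stringsAsFactors = FALSE)
    stopifnot(all(c("group_id", "fleet_id", "rate") %in% names(ll)))
    if (!all(as.character(ll$fleet_id) %in% fleets))
      stop("landings.csv references non-fleet id(s)")
    landings[cbind(as.character(ll$group_id), as.character(ll$fleet_id))] <-
      ll$rate
  }

  ped <- list(params = matrix(0, nrow(groups), 4,
                              dimnames = list(ids, c("biomass", "pb", "qb", "ae"))),
              diet = matrix(0, nrow(groups), nrow(groups),
                            dimnames = list(ids, ids)))
  pf <- file.path(path, "pedigree.csv")
  if (file.exists(pf)) {
    pp <- read.csv(pf, stringsAsFactors = FALSE)
    stopifnot(all(c("target", "cv") %in% names(pp)))
    parts <- strsplit(pp$target, ":", fixed = TRUE)
    for (k in seq_along(parts)) {
      p <- parts[[k]]
      if (p[1] == "param") ped$params[p[2], p[3]] <- pp$cv[k]
      else if (p[1] == "diet") ped$diet[p[2], p[3]] <- pp$cv[k]
      else stop("unknown pedigree target kind: ", p[1])
    }
  } else {
    warning("pedigree.csv absent in ", path, "; all CVs default to 0")
  }

  meta <- file.path(path, "meta.csv")
  currency <- "mt km^-2"; timeUnit <- "yr^-1"; prov <- ""
  if (file.exists(meta)) {
    mm <- read.csv(meta, stringsAsFactors = FALSE)
    kv <- setNames(mm$value, mm$key)
    if (!is.na(kv["currency"])) currency <- kv[["currency"]]
    if (!is.na(kv["timeUnit"])) timeUnit <- kv[["timeUnit"]]
    if (!is.na(kv["provenance"])) prov <- kv[["provenance"]]
  }
  FoodWebModel(groups, diet, landings = landings, pedigree = ped,
               currency = currency, timeUnit = timeUnit, provenance = prov,
               validate = validate)
}

#' @rdname readFoodWebModel
#' @param model a \linkS4class{FoodWebModel} to write.
#' @return \code{writeFoodWebModel}: the directory path, invisibly.
#' @export
writeFoodWebModel <- function(model, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  g <- model@groups
  ids <- as.character(g$id)
  gout <- data.frame(id = g$id, name = g$name, type = g$type,
                     biomass = .num(g$biomass), pb = .num(g$pb),
                     qb = .num(g$qb), ae = .num(g$ae))
  if (any(!is.na(g$ee)))
    gout$ee <- ifelse(is.na(g$ee), "", .num(g$ee))
  .writeCSV(gout, file.path(path, "groups.csv"))
  dd <- as.data.frame(apply(model@diet, 2, .num))
  names(dd) <- ids
  .writeCSV(cbind(id = ids, dd), file.path(path, "diet.csv"))
  idx <- which(model@landings > 0, arr.ind = TRUE)
  fleets <- ids[g$type == "fleet"]
  .writeCSV(data.frame(group_id = as.character(rownames(model@landings)[idx[, 1]]),
                       fleet_id = as.character(fleets[idx[, 2]]),
                       rate = .num(model@landings[idx]),
                       stringsAsFactors = FALSE),
            file.path(path, "landings.csv"))
  ped <- model@pedigree
  pi <- which(ped$params > 0, arr.ind = TRUE)
  di <- which(ped$diet > 0, arr.ind = TRUE)
  .writeCSV(data.frame(
    target = c(sprintf("param:%s:%s", rownames(ped$params)[pi[, 1]],
                       colnames(ped$params)[pi[, 2]]),
               sprintf("diet:%s:%s", rownames(ped$diet)[di[, 1]],
                       colnames(ped$diet)[di[, 2]])),
    cv = .num(c(ped$params[pi], ped$diet[di]))),
    file.path(path, "pedigree.csv"))
  .writeCSV(data.frame(key = c("currency", "timeUnit", "provenance"),
                       value = c(model@currency, model@timeUnit,
                                 model@provenance)),
            file.path(path, "meta.csv"))
  invisible(path)
}

## full-precision numeric formatting: round-trips doubles exactly
.num <- function(x) sprintf("%.17g", as.numeric(x))

.writeCSV <- function(d, f) {
  write.csv(d, f, row.names = FALSE, quote = TRUE, fileEncoding = "UTF-8")
}

#' Read an analysis configuration
#'
#' Configuration for \code{\link{runPipeline}}, as YAML or JSON. Recognized
#' fields (all optional unless noted): \code{modelA}, \code{modelB} (model
#' directory paths; required unless synthetic generation is configured),
#' \code{synthetic} (list: \code{nLiving}, \code{perturbation}, ... passed to
#' the generator), \code{nodeSet} (types to analyze; default living +
#' detritus + fleet), \code{focals} (named list of focal group name vectors),
#' \code{monteCarloN} (default 1000), \code{bootstrapN} (default 100),
#' \code{seed} (default 1), \code{temperature} (list \code{tBefore},
#' \code{tAfter}, \code{q10}), \code{outDir}.
#'
#' @param path config file (.yaml/.yml/.json).
#' @return a validated config list.
#' @export
readAnalysisConfig <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  .normalizeConfig(cfg)
}

.normalizeConfig <- function(cfg) {
  defaults <- list(nodeSet = c("living", "detritus", "fleet"),
                   focals = NULL, monteCarloN = 1000, bootstrapN = 100,
                   seed = 1, temperature = NULL, outDir = NULL,
                   modelA = NULL, modelB = NULL, synthetic = NULL,
                   mapping = NULL)
  for (k in names(defaults))
    if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  stopifnot(cfg$seed >= 1, cfg$monteCarloN >= 1, cfg$bootstrapN >= 1)
  cfg
}
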