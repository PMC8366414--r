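## shared delimited-text reader with per-line validation
.readTable <- function(path, needCols = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(needCols)) {
    miss <- setdiff(needCols, names(df))
    if (length(miss))
      stop(sprintf("%s: missing column(s): %s", path,
                   paste(miss, collapse = ", ")))
  }
  df
}

#' Read an omics block from delimited text
#'
#' Tab-delimited matrix: first column `sample_id`, remaining header =
#' feature identifiers. Non-numeric cells and duplicate feature names are
#' errors (with the offending line/column named).
#'
#' @param path file path.
#' @param blockId `"expression"`, `"genotype"` or `"methylation"`.
#' @return an [OmicsBlock-class].
#' @export
readBlock <- function(path, blockId) {
  df <- .readTable(path)
  if (names(df)[1] != "sample_id")
    stop(sprintf("%s: first column must be 'sample_id'", path))
  feats <- names(df)[-1]
  if (anyDuplicated(feats))
    stop(sprintf("%s: duplicate feature name(s): %s", path,
                 paste(unique(feats[duplicated(feats)]), collapse = ", ")))
  vals <- as.matrix(df[, -1, drop = FALSE])
  suppressWarnings(storage.mode(vals) <- "double")
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1, ]
    stop(sprintf("%s: non-numeric or missing cell at data line %d, column '%s'",
                 path, bad[1], feats[bad[2]]))
  }
  OmicsBlock(vals, blockId, sampleIds = as.character(df$sample_id),
             featureIds = feats)
}

#' @rdname readBlock
#' @param block an [OmicsBlock-class] to write.
#' @export
writeBlock <- function(block, path) {
  df <- data.frame(sample_id = block@sampleIds, check.names = FALSE)
  df <- cbind(df, as.data.frame(block@values, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read survival outcomes from delimited text
#'
#' Tab-delimited with header `sample_id`, `time`, `event`; `event` must
#' be 0 or 1, `time` positive.
#'
#' @param path file path.
#' @return a [SurvivalData-class].
#' @export
readSurvival <- function(path) {
  df <- .readTable(path, c("sample_id", "time", "event"))
  time <- suppressWarnings(as.numeric(df$time))
  event <- suppressWarnings(as.numeric(df$event))
  if (anyNA(time))
    stop(sprintf("%s: non-numeric time at data line %d", path, which(is.na(time))[1]))
  if (anyNA(event) || !all(event %in% c(0, 1)))
    stop(sprintf("%s: event must be 0 or 1", path))
  SurvivalData(as.character(df$sample_id), time, event)
}

#' @rdname readSurvival
#' @param data a [SurvivalData-class]; reweighted data additionally write
#'   `ipc_weight` and `reweighted_time` columns.
#' @export
writeSurvival <- function(data, path) {
  df <- data.frame(sample_id = data@sampleIds, time = data@time,
                   event = data@event)
  if (data@reweighted) {
    df$ipc_weight <- data@ipcWeight
    df$reweighted_time <- data@reweightedTime
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a QTL pair table from delimited text
#'
#' Tab-delimited with header `target_feature`, `partner_feature`,
#' `adjusted_p`; p-values must be numeric in `[0, 1]`. An empty file
#' (header only) gives an empty map.
#'
#' @param path file path.
#' @param mapType `"eQTL"`, `"meQTL"` or `"eQTM"`.
#' @return a [QTLMap-class].
#' @export
readQTLMap <- function(path, mapType) {
  df <- .readTable(path, c("target_feature", "partner_feature", "adjusted_p"))
  p <- suppressWarnings(as.numeric(df$adjusted_p))
  if (nrow(df) && (anyNA(p) || any(p < 0 | p > 1)))
    stop(sprintf("%s: malformed adjusted_p at data line %d", path,
                 which(is.na(p) | p < 0 | p > 1)[1]))
  df$adjusted_p <- p
  QTLMap(df, mapType)
}

#' @rdname readQTLMap
#' @param map a [QTLMap-class] to write.
#' @export
writeQTLMap <- function(map, path) {
  utils::write.table(map@pairs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Serialize / restore a fitted model
#'
#' The model is written as a single JSON document (metadata plus dense
#' arrays at full double precision) keyed by feature identifiers, so
#' reloaded models give bitwise-identical predictions on ID-aligned data.
#'
#' @param model a fitted [SMBPLSModel-class].
#' @param path output path (conventionally `.cxm.json`).
#' @export
writeModel <- function(model, path) {
  ser <- list(
    format = "coxsmbpls-model",
    version = 1L,
    blockIds = model@blockIds,
    featureIds = model@featureIds,
    directions = lapply(model@directions, function(m) as.data.frame(m)),
    omega = as.data.frame(model@omega),
    omegaRaw = as.data.frame(model@omegaRaw),
    projection = lapply(model@projection, function(m) as.data.frame(m)),
    activeSets = model@activeSets,
    plsBeta = model@plsBeta,
    components = as.data.frame(model@components),
    coxCoef = model@coxCoef,
    coxSe = model@coxSe,
    coxPvalues = model@coxPvalues,
    lambda = model@lambda,
    k = model@k,
    preprocess = model@preprocess,
    config = model@config
  )
  jsonlite::write_json(ser, path, digits = I(17), auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname writeModel
#' @return `readModel` returns the restored [SMBPLSModel-class].
#' @export
readModel <- function(path) {
  ser <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(ser$format, "coxsmbpls-model"))
    stop(sprintf("%s is not a coxsmbpls model file", path))
  asMat <- function(df) as.matrix(as.data.frame(df))
  pre <- ser$preprocess
  ## restore residual fit coefficient vectors as plain numerics
  if (length(pre$residualFits)) {
    pre$residualFits <- lapply(pre$residualFits, function(byFeat)
      lapply(byFeat, function(f) {
        f$coefficients <- as.numeric(unlist(f$coefficients))
        f$partner_features <- as.character(unlist(f$partner_features))
        f
      }))
  }
  pre$center <- lapply(pre$center, as.numeric)
  pre$scale <- lapply(pre$scale, as.numeric)
  new("SMBPLSModel",
      blockIds = as.character(ser$blockIds),
      featureIds = lapply(ser$featureIds, as.character),
      directions = setNames(lapply(ser$directions, asMat), names(ser$directions)),
      omega = asMat(ser$omega),
      omegaRaw = asMat(ser$omegaRaw),
      projection = setNames(lapply(ser$projection, asMat), names(ser$projection)),
      activeSets = lapply(ser$activeSets, as.character),
      plsBeta = lapply(ser$plsBeta, as.numeric),
      components = asMat(ser$components),
      coxCoef = as.numeric(ser$coxCoef),
      coxSe = as.numeric(ser$coxSe),
      coxPvalues = as.numeric(ser$coxPvalues),
      lambda = as.numeric(ser$lambda),
      k = as.numeric(ser$k),
      preprocess = pre,
      config = ser$config)
}

#' Read and validate a YAML/JSON run configuration
#'
#' Known sections: `paths` (expression, genotype, methylation, survival,
#' eqtl, meqtl, eqtm, out), `qtl` (alpha, residual_mode), `core` (k,
#' lambda, eta, deflation, component_source), `cv` (folds, seed, k_grid,
#' eta_grid, metric), `sim` (scenario fields), `logging` (level). Unknown
#' keys are rejected; referenced input paths must exist.
#'
#' @param path YAML (or JSON) configuration file.
#' @return validated named list.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- list(
    paths = c("expression", "genotype", "methylation", "survival",
              "eqtl", "meqtl", "eqtm", "out", "model"),
    qtl = c("alpha", "residual_mode"),
    core = c("k", "lambda", "eta", "deflation", "component_source"),
    cv = c("folds", "seed", "k_grid", "eta_grid", "metric"),
    sim = c("n", "p_per_block", "censoring", "k", "n_true_per_block",
            "effect_size", "qtl_pair_fraction", "within_block_correlation",
            "seed"),
    logging = c("level")
  )
  badTop <- setdiff(names(cfg), names(known))
  if (length(badTop))
    stop(sprintf("unknown config section(s): %s", paste(badTop, collapse = ", ")))
  for (sec in names(cfg)) {
    bad <- setdiff(names(cfg[[sec]]), known[[sec]])
    if (length(bad))
      stop(sprintf("unknown key(s) in section '%s': %s", sec,
                   paste(bad, collapse = ", ")))
  }
  inPaths <- setdiff(names(cfg$paths), c("out", "model"))
  for (nm in inPaths) {
    if (!file.exists(cfg$paths[[nm]]))
      stop(sprintf("config path '%s' does not exist: %s", nm, cfg$paths[[nm]]))
  }
  if (!is.null(cfg$qtl$alpha) &&
      (cfg$qtl$alpha <= 0 || cfg$qtl$alpha > 1))
    stop("qtl.alpha must be in (0, 1]")
  if (!is.null(cfg$core$eta) && (cfg$core$eta < 0 || cfg$core$eta >= 1))
    stop("core.eta must be in [0, 1)")
  cfg
}

#' Write a reproducibility manifest
#'
#' Records the configuration (content hash), seed and package versions
#' used by a run, sufficient to reproduce its outputs.
#'
#' @param path output JSON path.
#' @param configPath optional configuration file to hash.
#' @param seed integer seed of the run.
#' @param extra optional named list of extra fields.
#' @export
writeManifest <- function(path, configPath = NULL, seed = NULL, extra = list()) {
  man <- c(list(
    package = "coxsmbpls",
    packageVersion = as.character(utils::packageVersion("coxsmbpls")),
    rVersion = as.character(getRversion()),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    configHash = if (!is.null(configPath)) unname(tools::md5sum(configPath)) else NULL
  ), extra)
  jsonlite::write_json(man[!vapply(man, is.null, logical(1))], path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
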