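#' @import methods
#' @importFrom stats approx coef cor lm.fit na.omit pchisq plogis pnorm qlogis
#'   quantile rbinom rexp rnorm runif sd setNames uniroot var predict
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

.BLOCK_IDS <- c("expression", "genotype", "methylation")
.MAP_TYPES <- c("eQTL", "meQTL", "eQTM")

## map type -> block holding the residualized targets / the regression partners
.MAP_TARGET_BLOCK  <- c(eQTL = "expression", meQTL = "genotype", eQTM = "methylation")
.MAP_PARTNER_BLOCK <- c(eQTL = "genotype",   meQTL = "methylation", eQTM = "expression")

#' OmicsBlock: one samples x features omics matrix
#'
#' Container for a single omics compartment (gene expression, genotype minor
#' allele counts, or DNA methylation beta values) measured on the same set of
#' samples as its sibling blocks.
#'
#' @slot blockId one of `"expression"`, `"genotype"`, `"methylation"`.
#' @slot sampleIds character vector of sample identifiers (row names).
#' @slot featureIds character vector of feature identifiers (column names),
#'   no duplicates.
#' @slot values numeric matrix, samples x features.
#' @slot standardized logical flag; `TRUE` after [scaleBlocks()].
#' @slot center,scale numeric vectors (length = number of features) holding
#'   the centering/scaling constants once standardized; length zero before.
#'
#' @export
setClass("OmicsBlock",
  representation(
    blockId = "character",
    sampleIds = "character",
    featureIds = "character",
    values = "matrix",
    standardized = "logical",
    center = "numeric",
    scale = "numeric"
  ),
  prototype(standardized = FALSE, center = numeric(0), scale = numeric(0))
)

setValidity("OmicsBlock", function(object) {
  msg <- character(0)
  if (length(object@blockId) != 1L || !object@blockId %in% .BLOCK_IDS)
    msg <- c(msg, sprintf("blockId must be one of: %s",
                          paste(.BLOCK_IDS, collapse = ", ")))
  if (!is.numeric(object@values))
    msg <- c(msg, "values must be a numeric matrix")
  if (nrow(object@values) != length(object@sampleIds))
    msg <- c(msg, "nrow(values) must equal length(sampleIds)")
  if (ncol(object@values) != length(object@featureIds))
    msg <- c(msg, "ncol(values) must equal length(featureIds)")
  if (anyDuplicated(object@featureIds))
    msg <- c(msg, "duplicate featureIds are not allowed")
  if (anyDuplicated(object@sampleIds))
    msg <- c(msg, "duplicate sampleIds are not allowed")
  if (length(object@center) && length(object@center) != length(object@featureIds))
    msg <- c(msg, "center must have one entry per feature")
  if (length(object@scale) && length(object@scale) != length(object@featureIds))
    msg <- c(msg, "scale must have one entry per feature")
  if (length(msg)) msg else TRUE
})

#' Construct an OmicsBlock
#'
#' @param values numeric matrix (samples x features). Row/column names are
#'   used as sample/feature identifiers when `sampleIds`/`featureIds` are
#'   not given.
#' @param blockId `"expression"`, `"genotype"` or `"methylation"`.
#' @param sampleIds,featureIds optional identifier vectors.
#' @return an [OmicsBlock-class] object.
#' @examples
#' m <- matrix(rnorm(12), 4, 3,
#'             dimnames = list(paste0("s", 1:4), paste0("g", 1:3)))
#' OmicsBlock(m, "expression")
#' @export
OmicsBlock <- function(values, blockId,
                       sampleIds = rownames(values),
                       featureIds = colnames(values)) {
  values <- as.matrix(values)
  if (is.null(sampleIds)) sampleIds <- paste0("sample", seq_len(nrow(values)))
  if (is.null(featureIds)) featureIds <- paste0("feature", seq_len(ncol(values)))
  dimnames(values) <- list(sampleIds, featureIds)
  new("OmicsBlock", blockId = blockId, sampleIds = as.character(sampleIds),
      featureIds = as.character(featureIds), values = values)
}

#' QTLMap: typed cross-block cis-regulatory pair table
#'
#' Holds eQTL (SNP -> gene), meQTL (CpG -> SNP residual target) or eQTM
#' (gene -> CpG) pairs with provider-adjusted p-values. The `target` of a
#' pair is the feature that gets replaced by a regression residual; the
#' `partner` is the feature in the other block it is regressed on.
#'
#' @slot mapType `"eQTL"`, `"meQTL"` or `"eQTM"`.
#' @slot pairs data.frame with columns `target_feature`, `partner_feature`,
#'   `adjusted_p` (in `[0, 1]`).
#' @export
setClass("QTLMap",
  representation(mapType = "character", pairs = "data.frame")
)

setValidity("QTLMap", function(object) {
  msg <- character(0)
  if (length(object@mapType) != 1L || !object@mapType %in% .MAP_TYPES)
    msg <- c(msg, sprintf("mapType must be one of: %s",
                          paste(.MAP_TYPES, collapse = ", ")))
  need <- c("target_feature", "partner_feature", "adjusted_p")
  if (!all(need %in% names(object@pairs)))
    msg <- c(msg, sprintf("pairs must have columns: %s",
                          paste(need, collapse = ", ")))
  else {
    p <- object@pairs$adjusted_p
    if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1))
      msg <- c(msg, "adjusted_p must be numeric in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a QTLMap
#'
#' @param pairs data.frame with columns `target_feature`, `partner_feature`,
#'   `adjusted_p`; zero rows give an empty map.
#' @param mapType `"eQTL"`, `"meQTL"` or `"eQTM"`.
#' @return a [QTLMap-class] object.
#' @export
QTLMap <- function(pairs, mapType) {
  if (nrow(pairs) == 0L) {
    pairs <- data.frame(target_feature = character(0),
                        partner_feature = character(0),
                        adjusted_p = numeric(0))
  }
  pairs$target_feature <- as.character(pairs$target_feature)
  pairs$partner_feature <- as.character(pairs$partner_feature)
  pairs$adjusted_p <- as.numeric(pairs$adjusted_p)
  new("QTLMap", mapType = mapType, pairs = pairs)
}

#' Block targeted / used as partner by a QTL map type
#' @param mapType `"eQTL"`, `"meQTL"` or `"eQTM"`.
#' @return block identifier string.
#' @export
qtlTargetBlock <- function(mapType) unname(.MAP_TARGET_BLOCK[[mapType]])

#' @rdname qtlTargetBlock
#' @export
qtlPartnerBlock <- function(mapType) unname(.MAP_PARTNER_BLOCK[[mapType]])

#' SurvivalData: right-censored survival outcomes with IPC weights
#'
#' Observed times `y_i`, event indicators `delta_i`, and -- once
#' [reweightTimes()] has been applied -- the inverse-probability-of-censoring
#' weights `w_i = delta_i / S_C(y_i-)` and the reweighted times
#' `y*_i = w_i * y_i` used as the sMBPLS response.
#'
#' @slot sampleIds character sample identifiers.
#' @slot time positive observed times.
#' @slot event 0/1 event indicators (1 = event observed).
#' @slot ipcWeight derived IPC weights (length zero before reweighting).
#' @slot reweightedTime derived reweighted times (length zero before
#'   reweighting).
#' @slot reweighted logical flag guarding against double reweighting.
#' @export
setClass("SurvivalData",
  representation(
    sampleIds = "character",
    time = "numeric",
    event = "numeric",
    ipcWeight = "numeric",
    reweightedTime = "numeric",
    reweighted = "logical"
  ),
  prototype(ipcWeight = numeric(0), reweightedTime = numeric(0),
            reweighted = FALSE)
)

setValidity("SurvivalData", function(object) {
  msg <- character(0)
  n <- length(object@sampleIds)
  if (length(object@time) != n || length(object@event) != n)
    msg <- c(msg, "sampleIds, time and event must have equal length")
  bad <- !is.finite(object@time) | object@time <= 0
  if (any(bad))
    msg <- c(msg, sprintf("nonpositive or nonfinite time for sample(s): %s",
                          paste(object@sampleIds[bad], collapse = ", ")))
  if (!all(object@event %in% c(0, 1)))
    msg <- c(msg, "event must be 0 or 1")
  if (object@reweighted) {
    if (length(object@ipcWeight) != n || length(object@reweightedTime) != n)
      msg <- c(msg, "reweighted data must carry ipcWeight and reweightedTime")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a SurvivalData object
#'
#' @param sampleIds character sample identifiers.
#' @param time positive observed survival/censoring times.
#' @param event 0/1 event indicators (1 = event).
#' @return a [SurvivalData-class] object.
#' @examples
#' SurvivalData(paste0("s", 1:4), c(1, 2, 3, 4), c(1, 0, 1, 1))
#' @export
SurvivalData <- function(sampleIds, time, event) {
  new("SurvivalData", sampleIds = as.character(sampleIds),
      time = as.numeric(time), event = as.numeric(event))
}

#' CensoringCurve: Kaplan-Meier estimate of the censoring distribution
#'
#' Product-limit estimate of `S_C(t) = P(C > t)` obtained by treating the
#' censoring indicator `1 - delta` as the event. Right-continuous step
#' function; left limits available via [evalCensoringCurve()].
#'
#' @slot jumpTimes strictly increasing times at which the curve drops.
#' @slot survValues curve values just after each jump, nonincreasing, in
#'   `(0, 1]` except possibly a final 0.
#' @slot nAtRisk number at risk at each jump.
#' @export
setClass("CensoringCurve",
  representation(jumpTimes = "numeric", survValues = "numeric",
                 nAtRisk = "integer")
)

setValidity("CensoringCurve", function(object) {
  msg <- character(0)
  if (length(object@jumpTimes) != length(object@survValues))
    msg <- c(msg, "jumpTimes and survValues must have equal length")
  if (is.unsorted(object@jumpTimes, strictly = TRUE))
    msg <- c(msg, "jumpTimes must be strictly increasing")
  if (length(object@survValues) &&
      any(diff(object@survValues) > 1e-12))
    msg <- c(msg, "survValues must be nonincreasing")
  if (length(msg)) msg else TRUE
})

#' SMBPLSModel: fitted supervised Cox-sMBPLS model
#'
#' Returned by [coxSMBPLS()]. Bundles the sparse block direction vectors,
#' block weights, active sets, PLS coefficients, retained latent components,
#' the final Cox fit on those components, and the training preprocessing
#' (residualization fits and scaling constants) needed to project new
#' samples with [predictRisk()].
#'
#' @slot blockIds block identifiers in fitting order.
#' @slot featureIds list (per block) of feature identifiers.
#' @slot directions list (per block) of p_b x K sparse direction matrices.
#' @slot omega B x K matrix of unit-norm block weights per component.
#' @slot omegaRaw B x K matrix of block weights before normalization.
#' @slot projection list (per block) of p_b x K PLS projection matrices
#'   (`W (P'W)^{-1}` mapped back to full feature space) used to rebuild
#'   component scores.
#' @slot activeSets list (per block) of selected feature identifiers.
#' @slot plsBeta list (per block) of final PLS regression coefficients
#'   (length p_b, zero off the active set).
#' @slot components n x K matrix of retained training latent components.
#' @slot coxCoef,coxSe,coxPvalues per-component Cox coefficient, standard
#'   error and Wald p-value.
#' @slot lambda sparsity parameter actually used.
#' @slot k number of retained components.
#' @slot preprocess list with residualization fits and scaling constants.
#' @slot config list snapshot of fitting options.
#' @export
setClass("SMBPLSModel",
  representation(
    blockIds = "character",
    featureIds = "list",
    directions = "list",
    omega = "matrix",
    omegaRaw = "matrix",
    projection = "list",
    activeSets = "list",
    plsBeta = "list",
    components = "matrix",
    coxCoef = "numeric",
    coxSe = "numeric",
    coxPvalues = "numeric",
    lambda = "numeric",
    k = "numeric",
    preprocess = "list",
    config = "list"
  )
)

setValidity("SMBPLSModel", function(object) {
  msg <- character(0)
  K <- object@k
  if (length(object@coxCoef) != K || length(object@coxPvalues) != K)
    msg <- c(msg, "coxCoef/coxPvalues length must equal k")
  if (any(!is.finite(object@coxCoef)))
    msg <- c(msg, "coxCoef must be finite")
  if (length(object@coxPvalues) &&
      any(object@coxPvalues < 0 | object@coxPvalues > 1, na.rm = TRUE))
    msg <- c(msg, "component p-values must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

## ------------------------------------------------------------------
## Accessors and show methods
## ------------------------------------------------------------------

#' @rdname OmicsBlock
#' @param object,x an object.
#' @export
setGeneric("blockValues", function(x) standardGeneric("blockValues"))

#' @rdname OmicsBlock
#' @export
setMethod("blockValues", "OmicsBlock", function(x) x@values)

#' @rdname OmicsBlock
#' @export
setGeneric("blockId", function(x) standardGeneric("blockId"))

#' @rdname OmicsBlock
#' @export
setMethod("blockId", "OmicsBlock", function(x) x@blockId)

#' @rdname OmicsBlock
#' @export
setGeneric("featureIds", function(x) standardGeneric("featureIds"))

#' @rdname OmicsBlock
#' @export
setMethod("featureIds", "OmicsBlock", function(x) x@featureIds)

#' @rdname OmicsBlock
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname OmicsBlock
#' @export
setMethod("sampleIds", "OmicsBlock", function(x) x@sampleIds)

#' @rdname SurvivalData
#' @param x a `SurvivalData` object.
#' @export
setMethod("sampleIds", "SurvivalData", function(x) x@sampleIds)

#' Survival accessors
#'
#' @param x a [SurvivalData-class] object.
#' @return numeric vectors: observed times, 0/1 event indicators, IPC
#'   weights and reweighted times (the latter two error before
#'   [reweightTimes()] has been applied).
#' @export
survTime <- function(x) x@time

#' @rdname survTime
#' @export
survEvent <- function(x) x@event

#' @rdname survTime
#' @export
ipcWeights <- function(x) {
  if (!x@reweighted) stop("survival data have not been reweighted yet")
  x@ipcWeight
}

#' @rdname survTime
#' @export
reweightedTimes <- function(x) {
  if (!x@reweighted) stop("survival data have not been reweighted yet")
  x@reweightedTime
}

#' @rdname SMBPLSModel
#' @param x a fitted `SMBPLSModel`.
#' @export
setGeneric("components", function(x) standardGeneric("components"))

#' @rdname SMBPLSModel
#' @export
setMethod("components", "SMBPLSModel", function(x) x@components)

#' @rdname SMBPLSModel
#' @export
setGeneric("activeSets", function(x) standardGeneric("activeSets"))

#' @rdname SMBPLSModel
#' @export
setMethod("activeSets", "SMBPLSModel", function(x) x@activeSets)

#' @rdname SMBPLSModel
#' @export
setGeneric("blockWeights", function(x) standardGeneric("blockWeights"))

#' @rdname SMBPLSModel
#' @export
setMethod("blockWeights", "SMBPLSModel", function(x) x@omega)

#' @rdname SMBPLSModel
#' @export
setGeneric("directionVectors", function(x) standardGeneric("directionVectors"))

#' @rdname SMBPLSModel
#' @export
setMethod("directionVectors", "SMBPLSModel", function(x) x@directions)

#' @rdname SMBPLSModel
#' @export
setGeneric("coxCoefficients", function(x) standardGeneric("coxCoefficients"))

#' @rdname SMBPLSModel
#' @export
setMethod("coxCoefficients", "SMBPLSModel", function(x) x@coxCoef)

setMethod("show", "OmicsBlock", function(object) {
  cat(sprintf("OmicsBlock '%s': %d samples x %d features%s\n",
              object@blockId, length(object@sampleIds),
              length(object@featureIds),
              if (object@standardized) " (standardized)" else ""))
})

setMethod("show", "QTLMap", function(object) {
  cat(sprintf("QTLMap '%s': %d pairs (%s -> %s targets)\n",
              object@mapType, nrow(object@pairs),
              qtlPartnerBlock(object@mapType),
              qtlTargetBlock(object@mapType)))
})

setMethod("show", "SurvivalData", function(object) {
  cat(sprintf("SurvivalData: %d samples, %d events (%.0f%% censored)%s\n",
              length(object@time), sum(object@event),
              100 * mean(object@event == 0),
              if (object@reweighted) ", reweighted" else ""))
})

setMethod("show", "CensoringCurve", function(object) {
  cat(sprintf("CensoringCurve: %d censoring jump(s)", length(object@jumpTimes)))
  if (length(object@jumpTimes))
    cat(sprintf(", final value %.4f", min(object@survValues)))
  cat("\n")
})

setMethod("show", "SMBPLSModel", function(object) {
  cat(sprintf("SMBPLSModel: %d component(s), lambda = %.4g\n",
              object@k, object@lambda))
  for (b in seq_along(object@blockIds)) {
    cat(sprintf("  %s: %d/%d active features\n", object@blockIds[b],
                length(object@activeSets[[b]]),
                length(object@featureIds[[b]])))
  }
  cat("  component p-values:",
      paste(signif(object@coxPvalues, 3), collapse = ", "), "\n")
})
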