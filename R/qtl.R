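#' Split an omics block into QT and non-QT features
#'
#' A feature is a QT (quantitative-trait) feature when it appears as the
#' target of at least one map pair with `adjusted_p < alpha` whose partner
#' feature is actually present in the partner block. All other features are
#' non-QT and pass through residualization unchanged.
#'
#' @param block an [OmicsBlock-class].
#' @param map a [QTLMap-class] whose `mapType` targets `block`'s `blockId`.
#' @param alpha adjusted p-value cutoff in `(0, 1]` (default 0.05).
#' @param partnerFeatures character vector of features available in the
#'   partner block; `NULL` skips the partner-existence check.
#' @return list with character vectors `qt` and `nonQt` (disjoint, union =
#'   all block features).
#' @export
splitBlock <- function(block, map, alpha = 0.05, partnerFeatures = NULL) {
  stopifnot(is(block, "OmicsBlock"), is(map, "QTLMap"))
  if (qtlTargetBlock(map@mapType) != block@blockId)
    stop(sprintf("map '%s' targets block '%s', not '%s'",
                 map@mapType, qtlTargetBlock(map@mapType), block@blockId))
  if (!(alpha > 0 && alpha <= 1)) stop("alpha must be in (0, 1]")
  pairs <- map@pairs[map@pairs$adjusted_p < alpha, , drop = FALSE]
  if (!is.null(partnerFeatures))
    pairs <- pairs[pairs$partner_feature %in% partnerFeatures, , drop = FALSE]
  qt <- intersect(block@featureIds, unique(pairs$target_feature))
  list(qt = qt, nonQt = setdiff(block@featureIds, qt))
}

#' Residualize one target feature on its cross-block partners
#'
#' Ordinary least squares of the target on its partner columns plus an
#' intercept; the residual vector replaces the target column in the
#' updated block. With `mode = "joint"` (default) one multiple regression
#' on all partners is fit, so the residual is orthogonal to every partner
#' column and to the constant. `mode = "sum_univariate"` instead fits one
#' univariate regression per partner and subtracts the sum of the centered
#' fits.
#'
#' When the partner matrix is rank deficient, or when the number of
#' partners reaches `n - 2`, a ridge-regularized fit with a tiny penalty
#' (`1e-6` times the mean diagonal of the cross-product) is used and a
#' warning is emitted.
#'
#' @param target numeric vector of length n.
#' @param partners numeric matrix n x m (m >= 1).
#' @param mode `"joint"` or `"sum_univariate"`.
#' @return list with `coefficients` (per partner), `intercept`,
#'   `residuals`, `mode` and `ridge` (logical).
#' @export
residualizeFeature <- function(target, partners,
                               mode = c("joint", "sum_univariate")) {
  mode <- match.arg(mode)
  partners <- as.matrix(partners)
  n <- length(target)
  m <- ncol(partners)
  if (m < 1L) stop("need at least one partner feature")
  if (nrow(partners) != n) stop("target and partners must have equal length")

  cp <- colMeans(partners)
  Zc <- sweep(partners, 2, cp)
  tm <- mean(target)
  yc <- target - tm

  if (mode == "sum_univariate") {
    beta <- vapply(seq_len(m), function(j) {
      ss <- sum(Zc[, j]^2)
      if (ss < 1e-12) 0 else sum(Zc[, j] * yc) / ss
    }, numeric(1))
    resid <- yc - drop(Zc %*% beta)
    intercept <- tm - sum(cp * beta)
    return(list(coefficients = beta, intercept = intercept,
                residuals = resid, mode = mode, ridge = FALSE))
  }

  ridge <- FALSE
  if (m >= n - 2L) {
    ridge <- TRUE
  } else {
    qrz <- qr(Zc)
    if (qrz$rank < m) ridge <- TRUE
  }
  if (ridge) {
    A <- crossprod(Zc)
    pen <- 1e-6 * mean(diag(A))
    if (pen <= 0) pen <- 1e-6
    beta <- drop(solve(A + diag(pen, m), crossprod(Zc, yc)))
    warning("rank-deficient or oversized partner set; using ridge-regularized residualization")
  } else {
    beta <- qr.coef(qrz, yc)
    beta[is.na(beta)] <- 0
  }
  resid <- yc - drop(Zc %*% beta)
  intercept <- tm - sum(cp * beta)
  list(coefficients = beta, intercept = intercept, residuals = resid,
       mode = mode, ridge = ridge)
}

## partner sets per target feature, after the alpha filter and the
## partner-existence check; warns once about skipped pairs
.partnerSets <- function(map, targetFeatures, partnerFeatures, alpha) {
  pairs <- map@pairs[map@pairs$adjusted_p < alpha, , drop = FALSE]
  missing <- !(pairs$partner_feature %in% partnerFeatures)
  if (any(missing)) {
    warning(sprintf(
      "%s map: skipping %d pair(s) whose partner feature is absent from the '%s' block",
      map@mapType, sum(missing), qtlPartnerBlock(map@mapType)))
    pairs <- pairs[!missing, , drop = FALSE]
  }
  pairs <- pairs[pairs$target_feature %in% targetFeatures, , drop = FALSE]
  if (!nrow(pairs)) return(list())
  ## sort partners so the result is independent of pair-list order
  split(pairs$partner_feature, pairs$target_feature) |>
    lapply(function(p) sort(unique(p)))
}

#' Replace QT features with cis-regulatory residuals in all blocks
#'
#' Applies the three QTL updates: expression genes in eQTL pairs are
#' replaced by residuals of their regression on eQTL-SNP partners,
#' genotype SNPs in meQTL pairs by residuals on meQTL-CpG partners, and
#' methylation CpGs in eQTM pairs by residuals on eQTM-gene partners. All
#' three updates draw partner columns from the ORIGINAL (pre-update)
#' blocks, so the result does not depend on the order of the maps or of
#' the pairs within a map. Non-QT features pass through unchanged; updated
#' blocks keep exactly the shape and feature identifiers of the inputs.
#'
#' @param blocks named list of the three [OmicsBlock-class] objects
#'   (`expression`, `genotype`, `methylation`) sharing sample order.
#' @param maps list of [QTLMap-class] objects, at most one per map type.
#' @param alpha adjusted p-value cutoff (default 0.05).
#' @param mode residualization mode, see [residualizeFeature()].
#' @return list with `blocks` (updated blocks), `fits` (per map type, per
#'   target feature: partner ids, coefficients, intercept) and `splits`
#'   (per map type: the QT / non-QT partition).
#' @export
updateBlocks <- function(blocks, maps = list(), alpha = 0.05,
                         mode = c("joint", "sum_univariate")) {
  mode <- match.arg(mode)
  blocks <- .namedBlocks(blocks)
  if (!length(maps))
    return(list(blocks = blocks, fits = list(), splits = list()))
  types <- vapply(maps, function(m) m@mapType, character(1))
  if (anyDuplicated(types)) stop("at most one map per map type")

  updated <- blocks
  fits <- list()
  splits <- list()
  for (map in maps) {
    tb <- qtlTargetBlock(map@mapType)
    pb <- qtlPartnerBlock(map@mapType)
    target <- blocks[[tb]]
    partner <- blocks[[pb]]
    psets <- .partnerSets(map, target@featureIds, partner@featureIds, alpha)
    splits[[map@mapType]] <- list(qt = names(psets),
                                  nonQt = setdiff(target@featureIds, names(psets)))
    mapFits <- list()
    vals <- updated[[tb]]@values
    for (feat in names(psets)) {
      fit <- residualizeFeature(blocks[[tb]]@values[, feat],
                                blocks[[pb]]@values[, psets[[feat]], drop = FALSE],
                                mode = mode)
      fit$partner_features <- psets[[feat]]
      fit$residuals <- unname(fit$residuals)
      mapFits[[feat]] <- fit[c("partner_features", "coefficients",
                               "intercept", "mode", "ridge", "residuals")]
      vals[, feat] <- fit$residuals
    }
    updated[[tb]]@values <- vals
    fits[[map@mapType]] <- lapply(mapFits, function(f) {
      f$residuals <- NULL; f
    })
  }
  list(blocks = updated, fits = fits, splits = splits)
}

## apply stored residualization fits to new blocks (prediction path)
.applyResidualFits <- function(blocks, fits) {
  if (!length(fits)) return(blocks)
  out <- blocks
  for (type in names(fits)) {
    tb <- qtlTargetBlock(type)
    pb <- qtlPartnerBlock(type)
    vals <- out[[tb]]@values
    for (feat in names(fits[[type]])) {
      f <- fits[[type]][[feat]]
      Z <- blocks[[pb]]@values[, f$partner_features, drop = FALSE]
      vals[, feat] <- blocks[[tb]]@values[, feat] -
        (f$intercept + drop(Z %*% f$coefficients))
    }
    out[[tb]]@values <- vals
  }
  out
}

#' Center and scale all block columns
#'
#' Each column is centered to mean 0 and scaled to unit standard
#' deviation. Genotype columns are treated as quantitative minor-allele
#' counts and scaled like any other column. Zero-variance columns are
#' centered, left at 0 (scale constant 1) and flagged with a warning.
#'
#' When `reference` is supplied (a list of blocks already standardized,
#' e.g. the training blocks stored in a fitted model), its centering and
#' scaling constants are applied instead of recomputing them -- this is
#' how test samples must be standardized.
#'
#' @param blocks named list of [OmicsBlock-class] objects.
#' @param reference optional named list of standardized blocks providing
#'   the constants.
#' @return named list of standardized blocks with `center`/`scale` slots
#'   filled and `standardized = TRUE`.
#' @export
scaleBlocks <- function(blocks, reference = NULL) {
  blocks <- .namedBlocks(blocks)
  out <- blocks
  for (nm in names(blocks)) {
    b <- blocks[[nm]]
    if (is.null(reference)) {
      ctr <- colMeans(b@values)
      scl <- apply(b@values, 2, sd)
      zero <- !is.finite(scl) | scl < 1e-12
      if (any(zero)) {
        warning(sprintf("block '%s': %d zero-variance column(s) centered only",
                        nm, sum(zero)))
        scl[zero] <- 1
      }
    } else {
      ref <- reference[[nm]]
      if (!identical(ref@featureIds, b@featureIds))
        stop(sprintf("block '%s': feature ids do not match the reference", nm))
      ctr <- ref@center
      scl <- ref@scale
    }
    b@values <- sweep(sweep(b@values, 2, ctr), 2, scl, "/")
    b@center <- ctr
    b@scale <- scl
    b@standardized <- TRUE
    out[[nm]] <- b
  }
  out
}

## normalize a block list to a named list in canonical order, checking
## shared sample order
.namedBlocks <- function(blocks) {
  if (is(blocks, "OmicsBlock")) blocks <- list(blocks)
  ids <- vapply(blocks, function(b) b@blockId, character(1))
  if (anyDuplicated(ids)) stop("duplicate block ids")
  names(blocks) <- ids
  ord <- intersect(.BLOCK_IDS, ids)
  blocks <- blocks[ord]
  ref <- blocks[[1]]@sampleIds
  for (b in blocks) {
    if (!identical(b@sampleIds, ref))
      stop("all blocks must share the same sample order; align by ID first")
  }
  blocks
}
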