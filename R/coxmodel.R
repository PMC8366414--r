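#' Final Cox proportional-hazards fit on latent components
#'
#' Maximizes the Cox partial likelihood (Breslow tie handling) of the
#' ORIGINAL `(time, event)` outcome -- not the reweighted times -- on the
#' retained latent component scores. Rank-deficient component matrices
#' (e.g. duplicated columns) have their redundant columns dropped with a
#' warning; dropped columns get coefficient 0 and p-value 1.
#'
#' @param components numeric matrix n x K of component scores.
#' @param data a [SurvivalData-class] object (original times/events).
#' @return list with `coef`, `se`, `pvalues` (length K) and the
#'   underlying `survival::coxph` fit.
#' @export
fitFinalCox <- function(components, data) {
  stopifnot(is(data, "SurvivalData"))
  components <- as.matrix(components)
  K <- ncol(components)
  if (K < 1L) stop("need at least one component")
  if (sum(data@event) < 1) stop("no events in the survival data")

  keep <- seq_len(K)
  qrc <- qr(sweep(components, 2, colMeans(components)))
  if (qrc$rank < K) {
    keep <- sort(qrc$pivot[seq_len(qrc$rank)])
    warning(sprintf("component matrix is rank deficient; dropping %d redundant column(s)",
                    K - qrc$rank))
  }
  X <- components[, keep, drop = FALSE]
  colnames(X) <- paste0("T", keep)
  fit <- survival::coxph(
    survival::Surv(data@time, data@event) ~ X,
    ties = "breslow",
    control = survival::coxph.control(iter.max = 50)
  )
  if (any(!is.finite(coef(fit))))
    stop("Cox fit did not converge to finite coefficients")
  cf <- rep(0, K); se <- rep(0, K); pv <- rep(1, K)
  cf[keep] <- unname(coef(fit))
  se[keep] <- unname(sqrt(diag(fit$var)))
  z <- ifelse(se > 0, cf / se, 0)
  pv[keep] <- 2 * pnorm(-abs(z[keep]))
  list(coef = cf, se = se, pvalues = pv, fit = fit)
}

#' Align multi-omics blocks and survival data by sample identifier
#'
#' Harmonizes sample order across blocks (and optional survival data) by
#' an inner join on sample ids -- never by row order. Any loss of samples
#' is an error listing the differences unless `allowSubset = TRUE`.
#'
#' @param blocks list of [OmicsBlock-class] objects.
#' @param survival optional [SurvivalData-class].
#' @param allowSubset allow dropping samples missing from some input.
#' @return list with `blocks` (named, canonical order) and `survival`
#'   (reordered or `NULL`).
#' @export
alignSamples <- function(blocks, survival = NULL, allowSubset = FALSE) {
  if (is(blocks, "OmicsBlock")) blocks <- list(blocks)
  ids <- vapply(blocks, function(b) b@blockId, character(1))
  names(blocks) <- ids
  blocks <- blocks[intersect(.BLOCK_IDS, ids)]
  idSets <- lapply(blocks, function(b) b@sampleIds)
  if (!is.null(survival)) idSets$survival <- survival@sampleIds
  common <- Reduce(intersect, idSets)
  if (!length(common)) stop("no samples shared by all inputs")
  lost <- unique(unlist(lapply(idSets, function(s) setdiff(s, common))))
  if (length(lost) && !allowSubset)
    stop(sprintf("sample id sets differ across inputs (%d sample(s) not shared): %s",
                 length(lost), paste(utils::head(lost, 10), collapse = ", ")))
  blocks <- lapply(blocks, function(b) {
    b@values <- b@values[match(common, b@sampleIds), , drop = FALSE]
    b@sampleIds <- common
    b
  })
  if (!is.null(survival)) {
    ord <- match(common, survival@sampleIds)
    survival <- SurvivalData(common, survival@time[ord], survival@event[ord])
  }
  list(blocks = blocks, survival = survival)
}

#' Fit a supervised Cox-sMBPLS model
#'
#' End-to-end fit: (1) align samples by id; (2) reweight survival times by
#' inverse censoring probability; (3) replace QT features with
#' cis-regulatory residuals; (4) center and scale every column; (5) run
#' the sparse multi-block PLS engine on the reweighted times; (6) fit a
#' Cox proportional-hazards model (Breslow ties) of the original
#' `(time, event)` outcome on the retained latent components.
#'
#' @param blocks list of [OmicsBlock-class] objects (expression, genotype,
#'   methylation; fewer blocks are accepted).
#' @param survival a [SurvivalData-class] object.
#' @param maps list of [QTLMap-class] objects (possibly empty).
#' @param k number of latent components.
#' @param lambda sparsity parameter; alternatively give `eta`, the
#'   scale-free fraction of the full-shrinkage threshold (see
#'   [fitSMBPLS()]).
#' @param eta sparsity fraction in `[0, 1)`.
#' @param alpha adjusted p-value cutoff for QTL pairs.
#' @param residualMode `"joint"` or `"sum_univariate"`, see
#'   [residualizeFeature()].
#' @param control engine options from [smbplsControl()].
#' @param allowSubset allow sample sets to differ across inputs.
#' @return a fitted [SMBPLSModel-class].
#' @examples
#' set.seed(1)
#' ds <- simulateDataset(scenarioConfig(n = 60, pPerBlock = 20, seed = 1))
#' fit <- coxSMBPLS(ds$blocks, ds$survival, ds$maps, k = 2, eta = 0.5)
#' fit
#' @export
coxSMBPLS <- function(blocks, survival, maps = list(), k = 2,
                      lambda = NULL, eta = NULL, alpha = 0.05,
                      residualMode = c("joint", "sum_univariate"),
                      control = smbplsControl(), allowSubset = FALSE) {
  residualMode <- match.arg(residualMode)
  al <- alignSamples(blocks, survival, allowSubset = allowSubset)
  blocks <- al$blocks
  survival <- al$survival

  curve <- estimateCensoringSurvival(survival)
  rw <- reweightTimes(survival, curve)
  yStar <- reweightedTimes(rw)

  upd <- updateBlocks(blocks, maps, alpha = alpha, mode = residualMode)
  scaled <- scaleBlocks(upd$blocks)

  core <- fitSMBPLS(scaled, yStar, k = k, lambda = lambda, eta = eta,
                    control = control)
  cox <- fitFinalCox(core$components, survival)

  new("SMBPLSModel",
      blockIds = core$blockIds,
      featureIds = setNames(core$featureIds, core$blockIds),
      directions = core$directions,
      omega = core$omega,
      omegaRaw = core$omegaRaw,
      projection = core$projection,
      activeSets = core$activeSets,
      plsBeta = core$plsBeta,
      components = core$components,
      coxCoef = cox$coef,
      coxSe = cox$se,
      coxPvalues = cox$pvalues,
      lambda = core$lambda,
      k = core$k,
      preprocess = list(
        residualFits = upd$fits,
        splits = upd$splits,
        center = lapply(scaled, function(b) b@center),
        scale = lapply(scaled, function(b) b@scale),
        alpha = alpha,
        residualMode = residualMode
      ),
      config = list(k = k, lambda = core$lambda, eta = eta,
                    deflation = control$deflation,
                    componentSource = core$componentSource))
}

## rebuild component scores for (already raw) blocks using the stored
## preprocessing + projections; returns m x K matrix
.componentScores <- function(model, blocks) {
  al <- alignSamples(blocks, NULL, allowSubset = TRUE)
  blocks <- al$blocks
  for (b in model@blockIds) {
    if (is.null(blocks[[b]]))
      stop(sprintf("missing block '%s'", b))
    miss <- setdiff(model@featureIds[[b]], blocks[[b]]@featureIds)
    if (length(miss))
      stop(sprintf("block '%s' is missing model feature(s): %s", b,
                   paste(utils::head(miss, 10), collapse = ", ")))
    ## restrict and order to the model's features
    idx <- match(model@featureIds[[b]], blocks[[b]]@featureIds)
    blocks[[b]]@values <- blocks[[b]]@values[, idx, drop = FALSE]
    blocks[[b]]@featureIds <- model@featureIds[[b]]
  }
  blocks <- .applyResidualFits(blocks, model@preprocess$residualFits)
  for (b in model@blockIds) {
    blocks[[b]]@values <- sweep(
      sweep(blocks[[b]]@values, 2, model@preprocess$center[[b]]),
      2, model@preprocess$scale[[b]], "/")
  }
  K <- model@k
  n <- nrow(blocks[[1]]@values)
  scores <- matrix(0, n, K)
  src <- model@config$componentSource
  if (length(src) == 1L) src <- rep(src, K)
  for (kk in seq_len(K)) {
    Tk <- rep(0, n)
    for (bi in seq_along(model@blockIds)) {
      b <- model@blockIds[bi]
      loading <- if (identical(src[kk], "post_refit")) model@projection[[b]][, kk]
                 else model@directions[[b]][, kk]
      Tk <- Tk + model@omega[bi, kk] *
        drop(blocks[[b]]@values %*% loading)
    }
    scores[, kk] <- Tk
  }
  rownames(scores) <- blocks[[1]]@sampleIds
  scores
}

#' Predict linear risk scores for new samples
#'
#' Projects new samples through the training pipeline -- residualization
#' with the TRAINING regression fits, centering/scaling with the TRAINING
#' constants, component reconstruction from the stored loadings and block
#' weights -- and returns the Cox linear predictor
#' `sum_k coef_k * T_k(new)`. Higher values mean higher hazard. A sample
#' at the training feature means has risk exactly 0.
#'
#' @param model a fitted [SMBPLSModel-class].
#' @param newBlocks list of [OmicsBlock-class] objects containing at least
#'   the model's features (raw, unscaled values).
#' @return named numeric vector of risk scores, one per sample.
#' @export
predictRisk <- function(model, newBlocks) {
  stopifnot(is(model, "SMBPLSModel"))
  scores <- .componentScores(model, newBlocks)
  drop(scores %*% model@coxCoef)
}

#' Extract multi-omics modules from a fitted model
#'
#' One module per retained latent component: its members are the features
#' with nonzero direction weight in each block (the sparsity penalty
#' already enforces "large" weights), together with the component's Cox
#' p-value and a significance flag (`p < threshold`, default 0.1). A
#' feature may belong to several modules. Optionally keep only the top
#' fraction of members by absolute weight.
#'
#' @param model a fitted [SMBPLSModel-class].
#' @param threshold significance cutoff on the component Cox p-value.
#' @param topFraction optional fraction in `(0, 1]`; keep only the
#'   highest-|weight| fraction of members per block.
#' @return list of modules; each has `component`, `coxPvalue`,
#'   `significant`, `members` (per-block feature id lists), `weights`
#'   (matching weights) and `counts`.
#' @export
extractModules <- function(model, threshold = 0.1, topFraction = NULL) {
  stopifnot(is(model, "SMBPLSModel"))
  lapply(seq_len(model@k), function(kk) {
    members <- list(); weights <- list()
    for (b in model@blockIds) {
      w <- model@directions[[b]][, kk]
      sel <- which(abs(w) > 1e-12)
      if (!is.null(topFraction) && length(sel)) {
        keepN <- max(1L, ceiling(topFraction * length(sel)))
        sel <- sel[order(abs(w[sel]), decreasing = TRUE)][seq_len(keepN)]
      }
      members[[b]] <- model@featureIds[[b]][sel]
      weights[[b]] <- w[sel]
    }
    list(component = kk,
         coxPvalue = model@coxPvalues[kk],
         significant = model@coxPvalues[kk] < threshold,
         members = members,
         weights = weights,
         counts = vapply(members, length, integer(1)))
  })
}

#' Tabulate modules as a data.frame
#'
#' @param modules result of [extractModules()].
#' @return data.frame with columns `component`, `block`, `feature_id`,
#'   `weight`, `cox_pvalue`, `significant`.
#' @export
modulesTable <- function(modules) {
  rows <- lapply(modules, function(m) {
    do.call(rbind, lapply(names(m$members), function(b) {
      if (!length(m$members[[b]])) return(NULL)
      data.frame(component = m$component, block = b,
                 feature_id = m$members[[b]],
                 weight = unname(m$weights[[b]]),
                 cox_pvalue = m$coxPvalue,
                 significant = m$significant)
    }))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(component = integer(0), block = character(0),
                      feature_id = character(0), weight = numeric(0),
                      cox_pvalue = numeric(0), significant = logical(0))
  rownames(out) <- NULL
  out
}
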