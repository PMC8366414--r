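#' Upper bound on the number of latent components under k-fold CV
#'
#' `min(p, ceiling(((folds - 1) / folds) * n))`: a training fold has about
#' `((folds - 1)/folds) * n` samples, which caps the extractable
#' components; rounding is upward (e.g. `n = 91`, 5 folds: `72.8 -> 73`).
#'
#' @param n sample size.
#' @param p total number of covariates across blocks.
#' @param folds number of CV folds.
#' @return integer upper bound for `k`.
#' @examples
#' kUpperBound(91, 618774, 5)   # 73
#' @export
kUpperBound <- function(n, p, folds) {
  min(p, ceiling((folds - 1) / folds * n))
}

## stratified fold assignment: events and censored samples are spread
## evenly; redraws (up to maxTries) until every fold contains an event
.makeFolds <- function(event, folds, seed, maxTries = 100L) {
  n <- length(event)
  rng <- .seededRNG(seed)
  for (try in seq_len(maxTries)) {
    assign <- integer(n)
    for (grp in list(which(event == 1), which(event == 0))) {
      if (!length(grp)) next
      ord <- grp[rng$sampleIdx(length(grp))]
      assign[ord] <- rep_len(seq_len(folds), length(ord))
    }
    ok <- all(vapply(seq_len(folds), function(f)
      sum(event[assign != f]) > 0 && sum(assign == f) > 0, logical(1)))
    if (ok) return(assign)
  }
  stop("could not build folds with events in every training split")
}

## small self-contained RNG wrapper so fold draws are reproducible
## without touching the caller's global RNG stream
.seededRNG <- function(seed) {
  env <- new.env()
  env$state <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    s <- get(".Random.seed", globalenv())
    if (!is.null(old)) assign(".Random.seed", old, globalenv()) else rm(".Random.seed", envir = globalenv())
    s
  })
  list(
    sampleIdx = function(n) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      assign(".Random.seed", env$state, globalenv())
      out <- sample.int(n)
      env$state <- get(".Random.seed", globalenv())
      if (!is.null(old)) assign(".Random.seed", old, globalenv())
      out
    }
  )
}

#' Cross-validated tuning of (k, lambda) for Cox-sMBPLS
#'
#' Seeded, event-stratified k-fold cross-validation over a grid of
#' component counts and sparsity values. For every grid cell the full
#' pipeline (reweighting, QTL residualization, scaling, sMBPLS, final Cox
#' fit) is re-fit on each training split -- so no test-fold information
#' leaks into the transforms -- and the held-out Harrell C-index is
#' averaged across folds. The best cell maximizes the mean C-index; a
#' one-standard-error summary is reported alongside.
#'
#' @param blocks list of [OmicsBlock-class] objects (raw values).
#' @param survival a [SurvivalData-class] object.
#' @param maps list of [QTLMap-class] objects.
#' @param kGrid integer vector of component counts; values above
#'   [kUpperBound()] are an error.
#' @param etaGrid numeric vector of sparsity fractions in `[0, 1)`
#'   (scale-free parameterization; see [fitSMBPLS()]). Give `lambdaGrid`
#'   instead to search absolute penalties.
#' @param lambdaGrid optional numeric vector of absolute penalties.
#' @param folds number of folds (>= 2).
#' @param seed integer seed for the fold assignment.
#' @param alpha QTL adjusted-p cutoff.
#' @param control engine options, see [smbplsControl()].
#' @return list with `grid` (data.frame: k, eta/lambda, cvMetric, se,
#'   nFoldsUsed), `bestK`, `bestEta`/`bestLambda`, `bestMetric`,
#'   `oneSeThreshold` and `foldAssignments`.
#' @export
crossValidate <- function(blocks, survival, maps = list(),
                          kGrid = 2, etaGrid = seq(0.1, 0.9, by = 0.1),
                          lambdaGrid = NULL, folds = 5, seed = 1,
                          alpha = 0.05, control = smbplsControl()) {
  if (folds < 2) stop("folds must be >= 2")
  useEta <- is.null(lambdaGrid)
  sGrid <- if (useEta) etaGrid else lambdaGrid
  if (!length(kGrid) || !length(sGrid)) stop("empty tuning grid")
  al <- alignSamples(blocks, survival)
  blocks <- al$blocks; survival <- al$survival
  n <- length(survival@time)
  p <- sum(vapply(blocks, function(b) length(b@featureIds), integer(1)))
  kMax <- kUpperBound(n, p, folds)
  if (any(kGrid > kMax))
    stop(sprintf("kGrid exceeds the component upper bound min{p, ((folds-1)/folds) n} = %d", kMax))

  assign <- .makeFolds(survival@event, folds, seed)
  grid <- expand.grid(k = kGrid, s = sGrid)
  res <- lapply(seq_len(nrow(grid)), function(g) {
    kk <- grid$k[g]; ss <- grid$s[g]
    cs <- vapply(seq_len(folds), function(f) {
      tr <- assign != f
      trBlocks <- lapply(blocks, function(b) {
        b@values <- b@values[tr, , drop = FALSE]
        b@sampleIds <- b@sampleIds[tr]
        b
      })
      trSurv <- SurvivalData(survival@sampleIds[tr], survival@time[tr],
                             survival@event[tr])
      teBlocks <- lapply(blocks, function(b) {
        b@values <- b@values[!tr, , drop = FALSE]
        b@sampleIds <- b@sampleIds[!tr]
        b
      })
      teSurv <- SurvivalData(survival@sampleIds[!tr], survival@time[!tr],
                             survival@event[!tr])
      out <- tryCatch({
        fit <- if (useEta)
          coxSMBPLS(trBlocks, trSurv, maps, k = kk, eta = ss,
                    alpha = alpha, control = control)
        else
          coxSMBPLS(trBlocks, trSurv, maps, k = kk, lambda = ss,
                    alpha = alpha, control = control)
        harrellC(predictRisk(fit, teBlocks), teSurv)
      }, error = function(e) NA_real_)
      out
    }, numeric(1))
    c(mean = mean(cs, na.rm = TRUE),
      se = sd(cs, na.rm = TRUE) / sqrt(sum(!is.na(cs))),
      nUsed = sum(!is.na(cs)))
  })
  res <- do.call(rbind, res)
  grid$cvMetric <- res[, "mean"]
  grid$se <- res[, "se"]
  grid$nFoldsUsed <- res[, "nUsed"]
  names(grid)[names(grid) == "s"] <- if (useEta) "eta" else "lambda"
  best <- which.max(grid$cvMetric)
  oneSe <- grid$cvMetric[best] - grid$se[best]
  out <- list(grid = grid, bestK = grid$k[best],
              bestMetric = grid$cvMetric[best],
              oneSeThreshold = oneSe,
              foldAssignments = assign, seed = seed, folds = folds)
  if (useEta) out$bestEta <- grid$eta[best] else out$bestLambda <- grid$lambda[best]
  out
}
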