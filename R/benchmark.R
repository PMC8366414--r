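## 80/20 split stratified by event status
.trainTestSplit <- function(event, fraction = 0.8) {
  idx <- integer(0)
  for (grp in list(which(event == 1), which(event == 0))) {
    if (!length(grp)) next
    nTr <- round(fraction * length(grp))
    idx <- c(idx, sample(grp, nTr))
  }
  sort(idx)
}

.subsetBlocks <- function(blocks, keep) {
  lapply(blocks, function(b) {
    b@values <- b@values[keep, , drop = FALSE]
    b@sampleIds <- b@sampleIds[keep]
    b
  })
}

.subsetSurvival <- function(surv, keep) {
  SurvivalData(surv@sampleIds[keep], surv@time[keep], surv@event[keep])
}

#' Elastic-net Cox baseline on concatenated raw blocks
#'
#' Comparator model: penalized Cox regression (elastic-net penalty,
#' `glmnet`) on the column-concatenated raw feature blocks, with the
#' penalty weight tuned by k-fold cross-validation on the training split.
#'
#' @param blocks named list of [OmicsBlock-class] objects (training).
#' @param survival training [SurvivalData-class].
#' @param alpha elastic-net mixing parameter (default 0.95, a
#'   near-lasso mixture).
#' @param folds CV folds for the penalty weight.
#' @return list with the fitted `cv.glmnet` object and a
#'   `predict(newBlocks)` closure returning linear risk scores.
#' @export
elasticNetCox <- function(blocks, survival, alpha = 0.95, folds = 5) {
  X <- do.call(cbind, lapply(blocks, function(b) b@values))
  colnames(X) <- unlist(lapply(blocks, function(b) b@featureIds))
  y <- survival::Surv(survival@time, survival@event)
  cvfit <- glmnet::cv.glmnet(X, y, family = "cox", alpha = alpha,
                             nfolds = folds)
  list(
    fit = cvfit,
    predict = function(newBlocks) {
      Xn <- do.call(cbind, lapply(newBlocks, function(b) b@values))
      drop(predict(cvfit, newx = Xn, s = "lambda.min", type = "link"))
    }
  )
}

#' Benchmark Cox-sMBPLS against an elastic-net Cox baseline
#'
#' For every scenario and replicate: simulate a dataset, split 80/20
#' stratified by event status, tune and fit each method on the training
#' split, and score the held-out split with Harrell's C-index (and Uno's
#' cumulative/dynamic AUC at the median event time). Replicate `r` of a
#' scenario uses seed `config$seed + r - 1`. A method failure on a
#' replicate is recorded as `NA`, not fatal.
#'
#' @param scenarios list of [scenarioConfig()] objects (or a single one).
#' @param replicates replicates per scenario (the study design used 20
#'   seeds).
#' @param methods subset of `c("cox_smbpls", "elastic_net_cox")`.
#' @param etaGrid sparsity grid for the Cox-sMBPLS CV tuning.
#' @param folds CV folds for both methods.
#' @param alphaQtl QTL adjusted-p cutoff passed to the pipeline.
#' @param enetAlpha elastic-net mixing parameter (near-lasso default).
#' @return list with `results` (one row per scenario x replicate x
#'   method: cIndex, unoAuc) and `summary` (mean and SD per scenario x
#'   method).
#' @export
runBenchmark <- function(scenarios, replicates = 20,
                         methods = c("cox_smbpls", "elastic_net_cox"),
                         etaGrid = seq(0.1, 0.9, by = 0.2), folds = 5,
                         alphaQtl = 0.05, enetAlpha = 0.95) {
  if (inherits(scenarios, "ScenarioConfig")) scenarios <- list(scenarios)
  methods <- match.arg(methods, several.ok = TRUE)
  rows <- list()
  for (si in seq_along(scenarios)) {
    base <- scenarios[[si]]
    for (r in seq_len(replicates)) {
      cfg <- base
      cfg$seed <- base$seed + r - 1L
      ds <- simulateDataset(cfg)
      set.seed(cfg$seed + 10000L)
      tr <- .trainTestSplit(ds$survival@event)
      te <- setdiff(seq_len(cfg$n), tr)
      trB <- .subsetBlocks(ds$blocks, tr); teB <- .subsetBlocks(ds$blocks, te)
      trS <- .subsetSurvival(ds$survival, tr)
      teS <- .subsetSurvival(ds$survival, te)
      tMed <- stats::median(teS@time[teS@event == 1])

      for (m in methods) {
        val <- tryCatch({
          if (m == "cox_smbpls") {
            cv <- crossValidate(trB, trS, ds$maps, kGrid = cfg$k,
                                etaGrid = etaGrid, folds = folds,
                                seed = cfg$seed, alpha = alphaQtl)
            fit <- coxSMBPLS(trB, trS, ds$maps, k = cfg$k,
                             eta = cv$bestEta, alpha = alphaQtl)
            risk <- predictRisk(fit, teB)
          } else {
            en <- elasticNetCox(trB, trS, alpha = enetAlpha, folds = folds)
            risk <- en$predict(teB)
          }
          c(harrellC(risk, teS),
            as.numeric(cdAucUno(risk, teS, tMed)))
        }, error = function(e) c(NA_real_, NA_real_))
        rows[[length(rows) + 1L]] <- data.frame(
          scenario = si, replicate = r, seed = cfg$seed, method = m,
          censoring = cfg$censoringTarget, pPerBlock = cfg$pPerBlock,
          k = cfg$k, cIndex = val[1], unoAuc = val[2])
      }
    }
  }
  results <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(split(
    results, interaction(results$scenario, results$method, drop = TRUE)),
    function(d) data.frame(
      scenario = d$scenario[1], method = d$method[1],
      censoring = d$censoring[1], k = d$k[1],
      meanCIndex = mean(d$cIndex, na.rm = TRUE),
      sdCIndex = sd(d$cIndex, na.rm = TRUE),
      meanUnoAuc = mean(d$unoAuc, na.rm = TRUE),
      nOk = sum(!is.na(d$cIndex)))))
  rownames(summary) <- NULL
  list(results = results, summary = summary)
}
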