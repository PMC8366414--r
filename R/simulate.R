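#' Simulation scenario configuration
#'
#' Design point of the synthetic multi-omics survival benchmark: three
#' correlated omics blocks with known cross-block QTL pairs, sparse true
#' direction vectors, and right-censored survival times at a controlled
#' censoring rate. Defaults reproduce the low-dimensionality study
#' condition: `n = 91` samples, `p_b = 100` features per block, 10%
#' censoring, `k = 2` components.
#'
#' @param n sample size (default 91).
#' @param pPerBlock features per block; study grid uses 100 / 1000 / 10000.
#' @param censoringTarget target censoring fraction in `[0, 1)`; study
#'   grid uses 0.10 / 0.40 / 0.60.
#' @param k number of true (and fitted) latent components (2, 5 or 10 in
#'   the study grid).
#' @param nTruePerBlock size of the true sparse support per block.
#' @param effectSize scale of the standardized linear predictor (log
#'   hazard-ratio per SD of the true component score).
#' @param qtlPairFraction fraction of each block's features receiving
#'   injected cross-block QTL partners.
#' @param qtlPartners number of partner features per QT target (cis
#'   effects commonly involve several partners, e.g. multiple eQTL SNPs
#'   per gene).
#' @param withinBlockCorrelation AR-1 correlation between neighbouring
#'   features within a block.
#' @param qtlSlope,qtlNoiseSd slope on the standardized partner and
#'   residual noise SD of injected QTL effects.
#' @param seed integer seed; the whole dataset is deterministic given the
#'   config.
#' @return a `ScenarioConfig` list.
#' @export
scenarioConfig <- function(n = 91, pPerBlock = 100, censoringTarget = 0.10,
                           k = 2, nTruePerBlock = 50, effectSize = 3,
                           qtlPairFraction = 0.6, qtlPartners = 3,
                           withinBlockCorrelation = 0.5,
                           qtlSlope = 3, qtlNoiseSd = 0.5, seed = 1) {
  stopifnot(censoringTarget >= 0, censoringTarget < 1,
            nTruePerBlock <= pPerBlock, n >= 10,
            withinBlockCorrelation >= 0, withinBlockCorrelation < 1)
  structure(list(n = n, pPerBlock = pPerBlock,
                 censoringTarget = censoringTarget, k = k,
                 nTruePerBlock = nTruePerBlock, effectSize = effectSize,
                 qtlPairFraction = qtlPairFraction,
                 qtlPartners = qtlPartners,
                 withinBlockCorrelation = withinBlockCorrelation,
                 qtlSlope = qtlSlope, qtlNoiseSd = qtlNoiseSd,
                 seed = as.integer(seed)),
            class = "ScenarioConfig")
}

## AR-1 latent Gaussian matrix: cor(x_j, x_{j+1}) = rho
.ar1Matrix <- function(n, p, rho) {
  Z <- matrix(rnorm(n * p), n, p)
  if (rho > 0 && p > 1) {
    for (j in 2:p) Z[, j] <- rho * Z[, j - 1] + sqrt(1 - rho^2) * Z[, j]
  }
  Z
}

#' Generate the three correlated omics blocks and their QTL maps
#'
#' Expression: correlated Gaussian (AR-1 within-block). Genotype: binomial
#' minor-allele counts with MAFs drawn uniformly in (0.05, 0.5).
#' Methylation: logit-normal beta values in (0, 1). For a
#' `qtlPairFraction` of features per map type, a cross-block partner
#' linearly influences the target (on the logit scale for bounded or
#' discrete targets) and the pair is recorded in the corresponding QTL
#' map with `adjusted_p = 0.001`. All injections use the base
#' (pre-injection) partner values so the three maps act in parallel.
#'
#' @param config a [scenarioConfig()].
#' @return list with `blocks` (named list of [OmicsBlock-class]) and
#'   `maps` (list of [QTLMap-class], empty when `qtlPairFraction = 0`).
#' @export
generateBlocks <- function(config) {
  set.seed(config$seed)
  .generateBlocksNoSeed(config)
}

.generateBlocksNoSeed <- function(config) {
  n <- config$n; p <- config$pPerBlock
  rho <- config$withinBlockCorrelation
  sampleIds <- sprintf("s%03d", seq_len(n))
  geneIds <- sprintf("gene%04d", seq_len(p))
  snpIds <- sprintf("snp%04d", seq_len(p))
  cpgIds <- sprintf("cpg%04d", seq_len(p))

  ## base (pre-injection) layers
  exprBase <- .ar1Matrix(n, p, rho)
  maf <- runif(p, 0.05, 0.5)
  genoBase <- vapply(seq_len(p), function(j) rbinom(n, 2, maf[j]), numeric(n))
  methLatent <- .ar1Matrix(n, p, rho)

  nQtl <- round(config$qtlPairFraction * p)
  m <- max(1L, as.integer(config$qtlPartners %||% 1L))
  maps <- list()
  expr <- exprBase; geno <- genoBase
  if (nQtl > 0) {
    slope <- config$qtlSlope; noiseSd <- config$qtlNoiseSd
    gamma <- slope / max(noiseSd, 1e-8)  # logit-scale strength

    ## combined standardized partner score over a partner set
    partnerScore <- function(M, idx) {
      Z <- M[, idx, drop = FALSE]
      Z <- apply(Z, 2, function(z) if (sd(z) > 0) (z - mean(z)) / sd(z) else z * 0)
      rowSums(Z) / sqrt(length(idx))
    }

    ## eQTL: SNP partners -> gene target
    tg <- sample.int(p, nQtl)
    pt <- lapply(seq_len(nQtl), function(i) sample.int(p, m))
    for (i in seq_len(nQtl)) {
      zs <- partnerScore(genoBase, pt[[i]])
      expr[, tg[i]] <- slope * zs + noiseSd * exprBase[, tg[i]]
    }
    maps$eQTL <- QTLMap(data.frame(
      target_feature = rep(geneIds[tg], each = m),
      partner_feature = snpIds[unlist(pt)],
      adjusted_p = 0.001), "eQTL")

    ## meQTL: CpG partners -> SNP target (logit shift of the allele prob.)
    tg <- sample.int(p, nQtl)
    pt <- lapply(seq_len(nQtl), function(i) sample.int(p, m))
    for (i in seq_len(nQtl)) {
      zs <- partnerScore(methLatent, pt[[i]])
      pr <- plogis(qlogis(maf[tg[i]]) + gamma * zs)
      geno[, tg[i]] <- rbinom(n, 2, pr)
    }
    maps$meQTL <- QTLMap(data.frame(
      target_feature = rep(snpIds[tg], each = m),
      partner_feature = cpgIds[unlist(pt)],
      adjusted_p = 0.001), "meQTL")

    ## eQTM: gene partners -> CpG target (latent logit scale)
    tg <- sample.int(p, nQtl)
    pt <- lapply(seq_len(nQtl), function(i) sample.int(p, m))
    for (i in seq_len(nQtl)) {
      zs <- partnerScore(exprBase, pt[[i]])
      methLatent[, tg[i]] <- gamma * zs + methLatent[, tg[i]]
    }
    maps$eQTM <- QTLMap(data.frame(
      target_feature = rep(cpgIds[tg], each = m),
      partner_feature = geneIds[unlist(pt)],
      adjusted_p = 0.001), "eQTM")
  }
  meth <- plogis(methLatent)

  blocks <- list(
    expression = OmicsBlock(expr, "expression", sampleIds, geneIds),
    genotype = OmicsBlock(geno, "genotype", sampleIds, snpIds),
    methylation = OmicsBlock(meth, "methylation", sampleIds, cpgIds)
  )
  list(blocks = blocks, maps = unname(maps))
}

#' Sample sparse true direction vectors
#'
#' Per block, `nTruePerBlock` features are chosen uniformly at random and
#' given weights drawn from a Laplace (double-exponential) distribution
#' -- a heavy-tailed stand-in for the empirical distribution of sparse-PLS
#' weights -- then scaled to unit L2 norm per block; all other weights
#' are exactly 0.
#'
#' @param config a [scenarioConfig()].
#' @return named list (per block) with `support` (feature indices) and
#'   `weights` (length `pPerBlock`, unit L2 norm).
#' @export
sampleTrueDirections <- function(config) {
  set.seed(config$seed + 1L)
  .sampleTrueDirectionsNoSeed(config)
}

.sampleTrueDirectionsNoSeed <- function(config) {
  p <- config$pPerBlock
  nt <- config$nTruePerBlock
  out <- lapply(.BLOCK_IDS, function(b) {
    supp <- sort(sample.int(p, nt))
    w <- rep(0, p)
    raw <- rexp(nt) * sample(c(-1, 1), nt, replace = TRUE)
    w[supp] <- raw / sqrt(sum(raw^2))
    list(support = supp, weights = w)
  })
  names(out) <- .BLOCK_IDS
  out
}

#' Simulate right-censored survival times from a flexible-hazard model
#'
#' The baseline log-hazard is a piecewise-linear interpolation through 5
#' equally spaced knots on `[0, 10]` with i.i.d. Uniform(-1, 1) heights
#' (constant beyond the last knot), giving a non-trivial non-monotone
#' baseline. Subject hazards are `h0(t) * exp(eta)`; event times are
#' drawn by numerically inverting the cumulative hazard. Censoring times
#' are i.i.d. exponential with the rate solved so the expected censoring
#' fraction matches `censoringTarget`.
#'
#' @param eta numeric linear predictor of length n (standardized and
#'   scaled by the caller).
#' @param config a [scenarioConfig()].
#' @param sampleIds optional sample identifiers.
#' @return a [SurvivalData-class] object with attribute
#'   `"achievedCensoring"`.
#' @export
simulateSurvival <- function(eta, config, sampleIds = NULL) {
  n <- length(eta)
  if (any(!is.finite(eta))) stop("non-finite linear predictor")
  if (is.null(sampleIds)) sampleIds <- sprintf("s%03d", seq_len(n))

  tmax <- 10
  grid <- seq(0, 60, by = 0.01)
  trueT <- NULL
  shape <- 4  # time-power of the rising baseline (hazard ~ t^(shape-1))
  for (try in seq_len(10)) {
    knots <- seq(0, tmax, length.out = 5)
    heights <- runif(5, -1, 1)
    ## accelerating baseline: Weibull-type time power modulated by the
    ## random piecewise-linear log-hazard; hazards rising with follow-up
    ## are typical of chronic-disease cohorts and keep event times from
    ## being exponentially skewed in the linear predictor
    logh <- (shape - 1) * log(pmax(grid, 1e-8) / tmax) +
      approx(knots, heights, xout = pmin(grid, tmax), rule = 2)$y
    h <- exp(logh)
    H <- c(0, cumsum((h[-1] + h[-length(h)]) / 2 * diff(grid)))
    u <- rexp(n)
    target <- u / exp(eta - mean(eta))
    tt <- approx(H, grid, xout = pmin(target, max(H) * 0.999999))$y
    if (all(is.finite(tt)) && all(tt > 0)) { trueT <- tt; break }
  }
  if (is.null(trueT)) stop("event-time inversion failed after 10 knot resamples")

  if (config$censoringTarget <= 0) {
    out <- SurvivalData(sampleIds, trueT, rep(1, n))
    attr(out, "achievedCensoring") <- 0
    return(out)
  }
  ## solve the exponential censoring rate: mean P(C < T_i) = target
  f <- function(logRate) mean(1 - exp(-exp(logRate) * trueT)) - config$censoringTarget
  logRate <- uniroot(f, c(-15, 15))$root
  cens <- rexp(n, exp(logRate))
  time <- pmin(trueT, cens)
  event <- as.numeric(trueT <= cens)
  out <- SurvivalData(sampleIds, time, event)
  attr(out, "achievedCensoring") <- mean(event == 0)
  attr(out, "trueTime") <- trueT
  out
}

#' Simulate a complete multi-omics survival dataset
#'
#' Generates the three blocks and QTL maps, samples sparse true direction
#' vectors, builds the true combined component
#' `eta = effectSize * standardize(sum_b X^(b) w_T^(b))` from the
#' column-standardized blocks, and simulates right-censored survival
#' times. Fully deterministic given `config` (including its seed).
#'
#' @param config a [scenarioConfig()].
#' @return list of class `SimulatedDataset` with `blocks`, `maps`,
#'   `survival`, `truth`, `eta`, `achievedCensoring` and `config`.
#' @export
simulateDataset <- function(config) {
  set.seed(config$seed)
  gen <- .generateBlocksNoSeed(config)
  truth <- .sampleTrueDirectionsNoSeed(config)
  ## the true score lives in the model's covariate space: direction
  ## weights act on the QTL-residualized, standardized columns
  upd <- suppressWarnings(updateBlocks(gen$blocks, gen$maps))
  scl <- suppressWarnings(scaleBlocks(upd$blocks))
  lp <- rep(0, config$n)
  for (b in names(scl)) {
    X <- scl[[b]]@values
    X[!is.finite(X)] <- 0
    lp <- lp + drop(X %*% truth[[b]]$weights)
  }
  s <- sd(lp)
  eta <- if (s > 0) config$effectSize * (lp - mean(lp)) / s else lp * 0
  surv <- simulateSurvival(eta, config,
                           sampleIds = gen$blocks[[1]]@sampleIds)
  structure(list(blocks = gen$blocks, maps = gen$maps, survival = surv,
                 truth = truth, eta = eta,
                 achievedCensoring = attr(surv, "achievedCensoring"),
                 config = config),
            class = "SimulatedDataset")
}

#' Feature-selection AUC of a fitted model against the simulation truth
#'
#' Ranks all features by their largest absolute direction weight across
#' components and computes the Mann-Whitney AUC of that ranking against
#' the true support indicators, pooled over blocks.
#'
#' @param model a fitted [SMBPLSModel-class].
#' @param truth truth component of a [simulateDataset()] result.
#' @return AUC in `[0, 1]`; 0.5 means no selection signal.
#' @export
featureSelectionAuc <- function(model, truth) {
  score <- c(); label <- c()
  for (b in model@blockIds) {
    W <- model@directions[[b]]
    score <- c(score, apply(abs(W), 1, max))
    lab <- rep(0, length(model@featureIds[[b]]))
    lab[truth[[b]]$support] <- 1
    label <- c(label, lab)
  }
  pos <- score[label == 1]; neg <- score[label == 0]
  (sum(outer(pos, neg, ">")) + 0.5 * sum(outer(pos, neg, "=="))) /
    (length(pos) * length(neg))
}
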