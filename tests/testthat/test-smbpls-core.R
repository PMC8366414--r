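# independent 1-D grid minimizer of the penalized direction objective
# c^2 - 2 c phi + lambda |c| (separable across coordinates)
gridSoftThreshold <- function(phi, lambda, step = 1e-3) {
  grid <- seq(-1.5, 1.5, by = step)
  vapply(phi, function(ph) {
    obj <- grid^2 - 2 * grid * ph + lambda * abs(grid)
    grid[which.min(obj)]
  }, numeric(1))
}

test_that("soft-thresholding matches the closed form and the grid oracle", {
  expect_equal(softThreshold(c(0.8, -0.3, 0.1), 0.4), c(0.6, -0.1, 0))
  v <- c(-1.2, 0.4, 0, 2.5)
  expect_equal(softThreshold(v, 0), v)                       # identity
  expect_equal(softThreshold(v, 2 * max(abs(v))), rep(0, 4)) # full shrinkage
  expect_error(softThreshold(v, -1), "nonnegative")

  set.seed(21)
  for (rep in 1:20) {
    p <- sample(2:4, 1)
    phi <- runif(p, -1, 1)
    lambda <- runif(1, 0, 2)
    expect_lt(max(abs(softThreshold(phi, lambda) -
                      gridSoftThreshold(phi, lambda))), 6e-4)
  }
})

test_that("support shrinks monotonically in lambda", {
  set.seed(22)
  for (rep in 1:10) {
    v <- rnorm(30)
    l1 <- runif(1, 0, 1); l2 <- l1 + runif(1, 0, 1)
    s1 <- which(softThreshold(v, l1) != 0)
    s2 <- which(softThreshold(v, l2) != 0)
    expect_true(all(s2 %in% s1))
  }
})

test_that("computeDirection is the thresholded normalized covariance", {
  set.seed(23)
  X <- scale(matrix(rnorm(100), 20, 5))
  y <- rnorm(20)
  phi <- drop(crossprod(X, y)); phi <- phi / sqrt(sum(phi^2))
  expect_equal(computeDirection(X, y, 0), phi)               # classical PLS
  expect_equal(computeDirection(X, y, 0.3), softThreshold(phi, 0.3))
  # single column equal to y
  expect_equal(unname(computeDirection(cbind(y), y, 0.4)),
               softThreshold(1, 0.4))
  # response orthogonal to all columns -> zero direction
  expect_equal(computeDirection(X, rep(0, 20), 0.1), rep(0, 5))
})

test_that("combineComponents normalizes block weights as specified", {
  set.seed(24)
  y <- rnorm(10)
  # construct tau with tau'y = (3, 4)
  t1 <- y * 3 / sum(y^2)
  t2 <- y * 4 / sum(y^2)
  lc <- combineComponents(cbind(t1, t2), y)
  expect_equal(unname(lc$omega), c(0.6, 0.8))
  expect_equal(unname(lc$omegaRaw), c(3, 4))
  expect_equal(lc$combined, drop(cbind(t1, t2) %*% c(0.6, 0.8)))
  # B = 1: omega = 1
  expect_equal(unname(combineComponents(cbind(t1), y)$omega), 1)
  # a block orthogonal to y gets weight 0
  orth <- residuals(lm(rnorm(10) ~ y))
  expect_equal(unname(combineComponents(cbind(t1, orth), y)$omega[2]), 0,
               tolerance = 1e-12)
  expect_error(combineComponents(matrix(0, 10, 2), y), "no informative block")
})

test_that("active sets grow by support unions", {
  w <- c(a = 0.5, b = -0.2, c = 0)
  expect_equal(updateActiveSet(character(0), w), c("a", "b"))
  beta <- c(a = 0, b = 0.1, c = 0.3)
  expect_equal(updateActiveSet(character(0), w, beta), c("a", "b", "c"))
  # zero direction with nonzero beta keeps the incoming set
  expect_equal(updateActiveSet(c("a", "b"), w * 0, beta * 0), c("a", "b"))
  expect_equal(updateActiveSet(c("a"), c(a = 0, b = 1, c = 0),
                               c(a = 0, b = 1, c = 1)), c("a", "b", "c"))
})

test_that("the dense PLS refit matches an independent NIPALS oracle", {
  library(mixOmics)
  set.seed(25)
  X <- scale(matrix(rnorm(10 * 4), 10, 4))
  colnames(X) <- paste0("v", 1:4)
  y <- rnorm(10)
  fit <- plsRefit(X, y, 2)
  mo <- mixOmics::pls(X, y, ncomp = 2, mode = "regression", scale = FALSE)
  pred <- predict(mo, X)$predict[, 1, 2]
  expect_equal(fit$intercept + drop(X %*% fit$beta), unname(pred),
               tolerance = 1e-8)
  # scores agree up to sign
  for (k in 1:2)
    expect_gt(abs(cor(fit$scores[, k], mo$variates$X[, k])), 1 - 1e-8)
})

test_that("a saturated PLS refit equals least squares", {
  set.seed(26)
  X <- scale(matrix(rnorm(15 * 3), 15, 3))
  y <- rnorm(15)
  fit <- plsRefit(X, y, 3)
  expect_equal(unname(fit$beta), unname(coef(lm(y ~ X))[-1]),
               tolerance = 1e-8)
  # single active column: beta = <x, y> / <x, x> on centered data
  x1 <- X[, 1, drop = FALSE]
  f1 <- plsRefit(x1, y, 1)
  xc <- x1 - mean(x1); yc <- y - mean(y)
  expect_equal(unname(f1$beta), sum(xc * yc) / sum(xc^2), tolerance = 1e-10)
  # k above the rank is reduced with a warning
  Xdup <- cbind(X, X[, 1])
  expect_warning(fr <- plsRefit(Xdup, y, 4), "rank")
  expect_equal(fr$ncomp, 3L)
  expect_error(plsRefit(X[, 0], y, 1), "empty active set")
})

test_that("deflation subtracts the summed fitted block contributions", {
  set.seed(27)
  mats <- list(scale(matrix(rnorm(40), 10, 4)), scale(matrix(rnorm(30), 10, 3)))
  betas <- list(rnorm(4), rnorm(3))
  y <- rnorm(10)
  expect_equal(deflateResponse(y, mats, betas),
               y - mats[[1]] %*% betas[[1]] - mats[[2]] %*% betas[[2]],
               ignore_attr = TRUE)
  expect_equal(deflateResponse(y, mats, list(rep(0, 4), rep(0, 3))), y)
})

test_that("with one block and no penalty the engine reduces to classical PLS", {
  library(mixOmics)
  set.seed(28)
  X <- scale(matrix(rnorm(30 * 8), 30, 8))
  colnames(X) <- paste0("f", 1:8)
  y <- rnorm(30)
  core <- fitSMBPLS(list(expression = X), y, k = 3, lambda = 0)
  mo <- mixOmics::pls(X, y, ncomp = 3, mode = "regression", scale = FALSE)
  for (k in 1:3)
    expect_gt(abs(cor(core$components[, k], mo$variates$X[, k])), 1 - 1e-8)
})

test_that("a block containing the response dominates the first component", {
  set.seed(29)
  n <- 300
  y <- rnorm(n)
  X1 <- cbind(y, matrix(rnorm(n * 4), n, 4))
  colnames(X1) <- paste0("f", 1:5)
  core <- fitSMBPLS(list(expression = scale(X1)), scale(y)[, 1],
                    k = 1, lambda = 0)
  w <- core$directions[[1]][, 1]
  expect_equal(unname(which.max(abs(w))), 1L)
  expect_gt(abs(cor(core$components[, 1], y)), 0.99)
})

test_that("the engine is deterministic, scale-equivariant and sparsity-aware", {
  blocks <- scaleBlocks(makeToyBlocks(n = 30, p = 6, seed = 30))
  set.seed(31)
  y <- rnorm(30)
  a <- fitSMBPLS(blocks, y, k = 2, eta = 0.3)
  b <- fitSMBPLS(blocks, y, k = 2, eta = 0.3)
  expect_identical(a$components, b$components)       # bitwise determinism
  # rescaling the response leaves directions unchanged
  c2 <- fitSMBPLS(blocks, 7.3 * y, k = 2, eta = 0.3)
  expect_equal(a$directions, c2$directions, tolerance = 1e-10)
  # lambda too large: nothing selected at iteration 1
  expect_error(fitSMBPLS(blocks, y, k = 1, lambda = 10),
               "decrease lambda")
})

test_that("successive retained components are nearly conjugate", {
  ds <- simulateDataset(scenarioConfig(seed = 4))
  rw <- reweightTimes(ds$survival, estimateCensoringSurvival(ds$survival))
  upd <- updateBlocks(ds$blocks, ds$maps)
  core <- fitSMBPLS(scaleBlocks(upd$blocks), reweightedTimes(rw),
                    k = 3, eta = 0.5)
  cc <- cor(core$components)
  expect_true(all(abs(cc[upper.tri(cc)]) < 0.2))
})
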