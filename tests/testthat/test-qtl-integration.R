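test_that("splitBlock partitions by the adjusted-p filter and partner presence", {
  b <- OmicsBlock(matrix(rnorm(20), 4, 5,
                         dimnames = list(paste0("s", 1:4), paste0("g", 1:5))),
                  "expression")
  map <- QTLMap(data.frame(
    target_feature = c("g1", "g3", "g5"),
    partner_feature = c("snpA", "snpB", "snpC"),
    adjusted_p = c(0.01, 0.01, 0.2)), "eQTL")
  sp <- splitBlock(b, map, alpha = 0.05,
                   partnerFeatures = c("snpA", "snpB", "snpC"))
  expect_setequal(sp$qt, c("g1", "g3"))
  expect_setequal(sp$nonQt, c("g2", "g4", "g5"))

  # empty map -> everything non-QT; p = 0 everywhere -> everything QT
  empty <- QTLMap(data.frame(target_feature = character(0),
                             partner_feature = character(0),
                             adjusted_p = numeric(0)), "eQTL")
  expect_length(splitBlock(b, empty)$qt, 0)
  full <- QTLMap(data.frame(target_feature = paste0("g", 1:5),
                            partner_feature = "snpA",
                            adjusted_p = 0), "eQTL")
  expect_setequal(splitBlock(b, full)$qt, paste0("g", 1:5))

  # partner absent from the partner block removes the pair
  expect_length(splitBlock(b, map, partnerFeatures = "snpZ")$qt, 0)
  # wrong target block
  expect_error(splitBlock(b, QTLMap(map@pairs, "meQTL")), "targets block")
})

test_that("residualization agrees with an lm() normal-equations oracle", {
  set.seed(5)
  n <- 30
  Z <- matrix(rnorm(n * 3), n, 3)
  y <- 2 + Z %*% c(1, -0.5, 0.2) + rnorm(n)
  fit <- residualizeFeature(drop(y), Z)
  oracle <- lm(y ~ Z)
  expect_equal(fit$residuals, unname(resid(oracle)), tolerance = 1e-10)
  expect_equal(unname(fit$coefficients), unname(coef(oracle)[-1]),
               tolerance = 1e-10)
  expect_equal(fit$intercept, unname(coef(oracle)[1]), tolerance = 1e-10)

  # the tiny hand case: single partner, closed-form slope 2, intercept -0.5
  f2 <- residualizeFeature(c(1, 2, 3, 4), cbind(c(1, 1, 2, 2)))
  expect_equal(unname(f2$coefficients), 2)
  expect_equal(f2$intercept, -0.5)
  expect_equal(f2$residuals, c(-0.5, 0.5, -0.5, 0.5))
})

test_that("residualization handles degenerate partner sets", {
  set.seed(6)
  y <- rnorm(20)
  # target a perfect linear combination -> zero residual
  Z <- matrix(rnorm(40), 20, 2)
  lin <- drop(Z %*% c(2, -1)) + 3
  expect_equal(residualizeFeature(lin, Z)$residuals, rep(0, 20),
               tolerance = 1e-10)
  # partners orthogonal (constant) -> centered target via the ridge path
  expect_warning(f <- residualizeFeature(y, cbind(rep(1, 20))),
                 "ridge")
  expect_equal(f$residuals, y - mean(y), tolerance = 1e-6)
  # duplicated partner columns -> rank deficient, ridge fallback
  Zdup <- cbind(Z[, 1], Z[, 1])
  expect_warning(fd <- residualizeFeature(y, Zdup), "ridge")
  expect_length(fd$coefficients, 2)
  # oversized partner set (m >= n - 2)
  expect_warning(residualizeFeature(rnorm(6), matrix(rnorm(24), 6, 4)),
                 "ridge")
  # constant target -> ~zero residuals
  expect_equal(residualizeFeature(rep(2, 20), Z)$residuals, rep(0, 20),
               tolerance = 1e-10)
})

test_that("sum_univariate mode subtracts the summed per-partner fits", {
  set.seed(8)
  Z <- matrix(rnorm(60), 20, 3)
  y <- rnorm(20)
  f <- residualizeFeature(y, Z, mode = "sum_univariate")
  beta <- sapply(1:3, function(j) coef(lm(y ~ Z[, j]))[2])
  Zc <- scale(Z, scale = FALSE)
  expect_equal(f$residuals, drop(y - mean(y) - Zc %*% beta),
               tolerance = 1e-10)
})

test_that("updateBlocks conserves shape, passes non-QT through, and is order-invariant", {
  blocks <- makeToyBlocks(n = 20, p = 6, seed = 9)
  maps <- list(
    QTLMap(data.frame(target_feature = c("gene1", "gene3", "gene3"),
                      partner_feature = c("snp2", "snp4", "snp5"),
                      adjusted_p = 0.01), "eQTL"),
    QTLMap(data.frame(target_feature = "snp1",
                      partner_feature = "cpg2",
                      adjusted_p = 0.001), "meQTL"),
    QTLMap(data.frame(target_feature = "cpg6",
                      partner_feature = "gene2",
                      adjusted_p = 0.02), "eQTM")
  )
  upd <- updateBlocks(blocks, maps)
  for (b in names(blocks)) {
    expect_identical(featureIds(upd$blocks[[b]]), featureIds(blocks[[b]]))
    expect_identical(dim(blockValues(upd$blocks[[b]])),
                     dim(blockValues(blocks[[b]])))
  }
  # non-QT columns untouched
  expect_identical(blockValues(upd$blocks$expression)[, "gene2"],
                   blockValues(blocks$expression)[, "gene2"])
  # residualized columns orthogonal to each ORIGINAL partner column
  expect_lt(abs(cor(blockValues(upd$blocks$expression)[, "gene3"],
                    blockValues(blocks$genotype)[, "snp4"])), 1e-8)
  expect_lt(abs(cor(blockValues(upd$blocks$expression)[, "gene3"],
                    blockValues(blocks$genotype)[, "snp5"])), 1e-8)
  expect_lt(abs(cor(blockValues(upd$blocks$genotype)[, "snp1"],
                    blockValues(blocks$methylation)[, "cpg2"])), 1e-8)

  # permuting pair rows and map order leaves the result unchanged
  mapsPerm <- list(maps[[3]], maps[[2]],
                   QTLMap(maps[[1]]@pairs[c(3, 1, 2), ], "eQTL"))
  updPerm <- updateBlocks(blocks, mapsPerm)
  for (b in names(blocks))
    expect_equal(blockValues(upd$blocks[[b]]),
                 blockValues(updPerm$blocks[[b]]))

  # no maps -> unchanged; missing partner -> warning, pair skipped
  expect_identical(blockValues(updateBlocks(blocks)$blocks$expression),
                   blockValues(blocks$expression))
  badMap <- QTLMap(data.frame(target_feature = "gene1",
                              partner_feature = "snp99",
                              adjusted_p = 0.01), "eQTL")
  expect_warning(u2 <- updateBlocks(blocks, list(badMap)), "absent")
  expect_identical(blockValues(u2$blocks$expression),
                   blockValues(blocks$expression))
  expect_error(updateBlocks(blocks, list(maps[[1]], maps[[1]])),
               "at most one map")
})

test_that("a target with a zero-variance partner is only centered", {
  blocks <- makeToyBlocks(n = 15, p = 3, seed = 10)
  blocks$genotype@values[, "snp1"] <- 1  # monomorphic
  map <- QTLMap(data.frame(target_feature = "gene1",
                           partner_feature = "snp1",
                           adjusted_p = 0.01), "eQTL")
  expect_warning(upd <- updateBlocks(blocks, list(map)), "ridge")
  g1 <- blockValues(blocks$expression)[, "gene1"]
  expect_equal(blockValues(upd$blocks$expression)[, "gene1"],
               g1 - mean(g1), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("scaleBlocks standardizes columns and respects a reference", {
  blocks <- makeToyBlocks(n = 25, p = 5, seed = 11)
  sc <- scaleBlocks(blocks)
  for (b in names(sc)) {
    expect_equal(unname(colMeans(blockValues(sc[[b]]))), rep(0, 5),
                 tolerance = 1e-12)
    expect_equal(unname(apply(blockValues(sc[[b]]), 2, sd)), rep(1, 5),
                 tolerance = 1e-12)
    expect_true(sc[[b]]@standardized)
  }
  # scaling preserves Pearson correlations
  expect_equal(cor(blockValues(sc$expression)),
               cor(blockValues(blocks$expression)), tolerance = 1e-12)
  # reference constants are applied verbatim (test-sample pathway)
  sc2 <- scaleBlocks(blocks, reference = sc)
  expect_equal(blockValues(sc2$expression), blockValues(sc$expression))
  # zero-variance column flagged and left centered at 0
  blocks$expression@values[, 1] <- 5
  expect_warning(sc3 <- scaleBlocks(blocks), "zero-variance")
  expect_equal(unname(blockValues(sc3$expression)[, 1]), rep(0, 25))
})
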