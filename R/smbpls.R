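#' Soft-thresholding operator
#'
#' Elementwise shrink-and-select `(|v_j| - lambda/2)_+ * sign(v_j)` -- the
#' closed-form minimizer of `c^2 - 2 c v_j + lambda |c|` per coordinate,
#' i.e. the univariate soft-thresholding solution of the L1-penalized
#' direction problem in the limit of an infinite L2 penalty.
#'
#' @param v numeric vector.
#' @param lambda nonnegative sparsity parameter; `0` is the identity and
#'   `lambda >= 2 max|v|` gives the zero vector.
#' @return numeric vector of the same length.
#' @examples
#' softThreshold(c(0.8, -0.3, 0.1), 0.4)   # 0.6 -0.1 0.0
#' @export
softThreshold <- function(v, lambda) {
  if (lambda < 0) stop("lambda must be nonnegative")
  sign(v) * pmax(abs(v) - lambda / 2, 0)
}

#' Sparse block direction vector
#'
#' Computes the first-direction surrogate
#' `w = softThreshold(X'y / ||X'y||_2, lambda)` for one block. With
#' `lambda = 0` this is the classical first PLS direction.
#'
#' @param X numeric matrix (n x p), columns centered/scaled.
#' @param y numeric response vector of length n.
#' @param lambda nonnegative sparsity parameter.
#' @return numeric vector of length p; the zero vector when `X'y = 0`
#'   (response orthogonal to every column), leaving termination to the
#'   caller.
#' @export
computeDirection <- function(X, y, lambda) {
  phi <- drop(crossprod(X, y))
  nrm <- sqrt(sum(phi^2))
  if (nrm < 1e-300) return(rep(0, ncol(X)))
  softThreshold(phi / nrm, lambda)
}

#' Combine block components into one latent component
#'
#' Given per-block score columns `tau^(b) = X^(b) w^(b)`, computes the raw
#' block weights `omega_raw = tau' y`, normalizes them to unit L2 norm
#' (the stated constraint `||omega||_2 = 1`; the rescaling is absorbed by
#' the final Cox fit), and returns the combined component
#' `T = tau %*% omega`.
#'
#' @param tauBlock numeric matrix n x B of block components (zero columns
#'   allowed for blocks with empty directions).
#' @param y numeric response vector.
#' @return list with `omega` (unit norm), `omegaRaw` and `combined`
#'   (length-n component).
#' @export
combineComponents <- function(tauBlock, y) {
  tauBlock <- as.matrix(tauBlock)
  if (any(!is.finite(tauBlock))) stop("non-finite block components")
  omegaRaw <- drop(crossprod(tauBlock, y))
  nrm <- sqrt(sum(omegaRaw^2))
  if (nrm < 1e-300) stop("no informative block: all block components are orthogonal to the response")
  omega <- omegaRaw / nrm
  list(omega = omega, omegaRaw = omegaRaw,
       combined = drop(tauBlock %*% omega))
}

#' Update the active feature set of one block
#'
#' Union of the incoming set with the supports of the direction vector and
#' of the PLS coefficient vector (a value is nonzero iff `|.| > 1e-12`).
#' Active sets are nondecreasing across iterations.
#'
#' @param active integer or character vector of currently active features.
#' @param w direction vector (named or positional).
#' @param beta PLS coefficient vector of the same length.
#' @return sorted union of the three supports (same id type as `active`).
#' @export
updateActiveSet <- function(active, w, beta = rep(0, length(w))) {
  sel <- which(abs(w) > 1e-12 | abs(beta) > 1e-12)
  ids <- if (!is.null(names(w))) names(w)[sel] else sel
  sort(union(active, ids))
}

#' Dense univariate-response PLS regression (NIPALS)
#'
#' Classical (unpenalized) PLS regression of `y` on the active columns of
#' a block, used for the per-block refit of the sparse multi-block loop.
#' Direction vectors form a Krylov sequence of `(X'X, X'y)` on the active
#' subspace. With `k` equal to the rank of the active columns the
#' coefficients coincide with ordinary least squares.
#'
#' @param X numeric matrix n x p (the active columns; at least one).
#' @param y numeric response of length n.
#' @param k number of latent components; reduced to the effective rank
#'   with a warning if larger.
#' @return list with `beta` (length p coefficients), `intercept`,
#'   `scores` (n x k orthogonal score matrix), `projection` (p x k matrix
#'   `R = W (P'W)^{-1}` with `scores = Xc %*% R`), `xMeans`, `yMean` and
#'   `ncomp` actually used.
#' @export
plsRefit <- function(X, y, k) {
  X <- as.matrix(X)
  if (ncol(X) < 1L) stop("empty active set: lambda is too large, no features selected")
  if (k < 1L) stop("k must be >= 1")
  n <- nrow(X); p <- ncol(X)
  xm <- colMeans(X)
  ym <- mean(y)
  Xc <- sweep(X, 2, xm)
  yc <- y - ym
  W <- matrix(0, p, 0); P <- matrix(0, p, 0); Q <- numeric(0)
  Tm <- matrix(0, n, 0)
  Xk <- Xc; yk <- yc
  for (a in seq_len(k)) {
    w <- drop(crossprod(Xk, yk))
    wn <- sqrt(sum(w^2))
    if (wn < 1e-12) break
    w <- w / wn
    tvec <- drop(Xk %*% w)
    tt <- sum(tvec^2)
    if (tt < 1e-12) break
    pvec <- drop(crossprod(Xk, tvec)) / tt
    qval <- sum(yk * tvec) / tt
    Xk <- Xk - tcrossprod(tvec, pvec)
    yk <- yk - tvec * qval
    W <- cbind(W, w); P <- cbind(P, pvec); Q <- c(Q, qval)
    Tm <- cbind(Tm, tvec)
  }
  ncomp <- ncol(W)
  if (ncomp == 0L)
    return(list(beta = rep(0, p), intercept = ym, scores = Tm,
                projection = matrix(0, p, 0), xMeans = xm, yMean = ym,
                ncomp = 0L))
  if (ncomp < k)
    warning(sprintf("k = %d exceeds the rank of the active columns; using %d component(s)",
                    k, ncomp))
  R <- W %*% solve(crossprod(P, W))
  beta <- drop(R %*% Q)
  list(beta = beta, intercept = ym - sum(xm * beta), scores = Tm,
       projection = R, xMeans = xm, yMean = ym, ncomp = ncomp)
}

#' Deflate the response by the fitted block contributions
#'
#' Returns `yStar - sum_b X^(b) beta^(b)`; with centered block columns the
#' fitted contributions are mean zero, so the response mean is preserved.
#'
#' @param yStar numeric response vector.
#' @param blockMatrices list of numeric matrices (one per block).
#' @param betaList list of coefficient vectors matching the matrices.
#' @return deflated numeric vector.
#' @export
deflateResponse <- function(yStar, blockMatrices, betaList) {
  fitted <- Reduce(`+`, Map(function(X, b) drop(X %*% b),
                            blockMatrices, betaList))
  yStar - fitted
}

#' Control options for the sparse multi-block PLS engine
#'
#' @param deflation `"parallel"` (each block's refit targets the original
#'   response, the residual is the response minus the summed block fits)
#'   or `"sequential"` (blocks are fit and deflated in order within each
#'   iteration).
#' @param componentSource `"post_refit"` (default: the retained combined
#'   component of iteration k is built from the k-th orthogonal score of
#'   each block's PLS refit) or `"pre_refit"` (the step-3.6 combined
#'   component built directly from the thresholded directions).
#' @param zeroTol threshold below which a weight/coefficient counts as
#'   zero.
#' @param deflateTol stop early when the deflated response norm falls
#'   below `deflateTol * ||y*||`.
#' @return list of options for [fitSMBPLS()].
#' @export
smbplsControl <- function(deflation = c("parallel", "sequential"),
                          componentSource = c("post_refit", "pre_refit"),
                          zeroTol = 1e-12, deflateTol = 1e-10) {
  list(deflation = match.arg(deflation),
       componentSource = match.arg(componentSource),
       zeroTol = zeroTol, deflateTol = deflateTol)
}

#' Fit the sparse multi-block PLS engine
#'
#' Runs the supervised sMBPLS loop for `k` components on scaled blocks and
#' the reweighted response `y*`: per iteration, sparse block directions by
#' soft-thresholding the normalized block covariances with the current
#' residual, block components and unit-norm block weights, active-set
#' growth, a dense per-block PLS refit on the active columns (targeting
#' the original `y*`), and response deflation by the fitted block
#' contributions. Deterministic given its inputs.
#'
#' `lambda` may be given directly or through `eta`, the scale-free
#' fraction of `2 * max_j |Phi_j|` (with `Phi` the normalized block
#' covariances at iteration 1) at which all directions would vanish.
#'
#' @param blocks named list of standardized [OmicsBlock-class] objects (or
#'   plain matrices with column names).
#' @param yStar numeric response (reweighted survival times).
#' @param k number of latent components.
#' @param lambda nonnegative sparsity parameter (overrides `eta`).
#' @param eta sparsity fraction in `[0, 1)`; `lambda = eta * 2 * max|Phi|`.
#' @param control see [smbplsControl()].
#' @return list with `directions` (per block p_b x K matrices), `omega`
#'   and `omegaRaw` (B x K), `components` (n x K retained combined
#'   components), `projection` (per block p_b x K), `activeSets`,
#'   `plsBeta`, `lambda`, `k` (components retained) and `blockIds`.
#' @export
fitSMBPLS <- function(blocks, yStar, k, lambda = NULL, eta = NULL,
                      control = smbplsControl()) {
  mats <- lapply(blocks, function(b) if (is(b, "OmicsBlock")) b@values else as.matrix(b))
  B <- length(mats)
  n <- nrow(mats[[1]])
  p <- vapply(mats, ncol, integer(1))
  blockIds <- if (!is.null(names(mats))) names(mats) else paste0("block", seq_len(B))
  featIds <- lapply(mats, colnames)
  if (length(yStar) != n) stop("response length must match the number of samples")
  if (k < 1L) stop("k must be >= 1")

  ## resolve lambda from eta at iteration 1
  phiMax <- max(vapply(mats, function(X) {
    phi <- drop(crossprod(X, yStar))
    nrm <- sqrt(sum(phi^2))
    if (nrm < 1e-300) 0 else max(abs(phi / nrm))
  }, numeric(1)))
  if (is.null(lambda)) {
    if (is.null(eta)) stop("supply lambda or eta")
    if (eta < 0 || eta >= 1) stop("eta must be in [0, 1)")
    lambda <- eta * 2 * phiMax
  }

  y0 <- yStar
  ycur <- yStar
  beta <- lapply(p, function(pb) rep(0, pb))
  active <- lapply(seq_len(B), function(b) character(0))
  dirs <- lapply(p, function(pb) matrix(0, pb, 0))
  omega <- matrix(0, B, 0)
  omegaRaw <- matrix(0, B, 0)
  comps <- matrix(0, n, 0)
  proj <- vector("list", B)
  srcUsed <- character(0)

  y0nrm <- sqrt(sum(y0^2))
  for (comp in seq_len(k)) {
    if (sqrt(sum(ycur^2)) < control$deflateTol * y0nrm) {
      warning(sprintf("response fully deflated after %d component(s); stopping early",
                      comp - 1L))
      break
    }
    W <- lapply(seq_len(B), function(b)
      computeDirection(mats[[b]], ycur, lambda))
    supp <- vapply(W, function(w) sum(abs(w) > control$zeroTol), integer(1))
    if (all(supp == 0)) {
      if (comp == 1L)
        stop("no features selected; decrease lambda")
      warning(sprintf("all directions vanished at component %d; stopping early",
                      comp))
      break
    }
    tau <- vapply(seq_len(B), function(b) drop(mats[[b]] %*% W[[b]]),
                  numeric(n))
    lc <- combineComponents(tau, ycur)

    for (b in seq_len(B)) {
      wb <- W[[b]]
      names(wb) <- featIds[[b]]
      active[[b]] <- updateActiveSet(active[[b]], wb,
                                     setNames(beta[[b]], featIds[[b]]))
      dirs[[b]] <- cbind(dirs[[b]], W[[b]])
    }
    omega <- cbind(omega, lc$omega)
    omegaRaw <- cbind(omegaRaw, lc$omegaRaw)

    ## per-block dense PLS refit on the active columns; the comp-th
    ## orthogonal score (and its projection column) belongs to this
    ## iteration's retained component
    refitTarget <- y0
    tauPost <- matrix(0, n, B)
    for (b in seq_len(B)) {
      idx <- match(active[[b]], featIds[[b]])
      if (is.null(proj[[b]])) proj[[b]] <- matrix(0, p[b], 0)
      projCol <- rep(0, p[b])
      if (!length(idx)) {
        beta[[b]] <- rep(0, p[b])
        proj[[b]] <- cbind(proj[[b]], projCol)
        next
      }
      fit <- suppressWarnings(plsRefit(mats[[b]][, idx, drop = FALSE],
                                       refitTarget, comp))
      bfull <- rep(0, p[b]); bfull[idx] <- fit$beta
      beta[[b]] <- bfull
      if (fit$ncomp >= comp) {
        tauPost[, b] <- fit$scores[, comp]
        projCol[idx] <- fit$projection[, comp]
      }
      proj[[b]] <- cbind(proj[[b]], projCol)
      if (control$deflation == "sequential")
        refitTarget <- refitTarget - (fit$intercept +
          drop(mats[[b]][, idx, drop = FALSE] %*% fit$beta))
    }

    lcPost <- NULL
    if (control$componentSource == "post_refit" &&
        any(colSums(abs(tauPost)) > 0)) {
      lcPost <- tryCatch(combineComponents(tauPost, ycur), error = function(e) NULL)
    }
    if (!is.null(lcPost)) {
      comps <- cbind(comps, lcPost$combined)
      omega[, comp] <- lcPost$omega
      omegaRaw[, comp] <- lcPost$omegaRaw
      srcUsed <- c(srcUsed, "post_refit")
    } else {
      comps <- cbind(comps, lc$combined)
      srcUsed <- c(srcUsed, "pre_refit")
    }

    ycur <- if (control$deflation == "sequential") refitTarget
            else deflateResponse(y0, mats, beta)
  }

  K <- ncol(comps)
  if (K == 0L) stop("no components could be extracted")
  proj <- lapply(seq_len(B), function(b) {
    R <- proj[[b]]
    if (is.null(R)) R <- matrix(0, p[b], 0)
    if (ncol(R) < K) R <- cbind(R, matrix(0, p[b], K - ncol(R)))
    R[, seq_len(K), drop = FALSE]
  })
  dirs <- lapply(dirs, function(D) D[, seq_len(K), drop = FALSE])
  names(dirs) <- names(proj) <- names(beta) <- names(active) <- blockIds
  list(directions = dirs, omega = omega[, seq_len(K), drop = FALSE],
       omegaRaw = omegaRaw[, seq_len(K), drop = FALSE],
       components = comps, projection = proj, activeSets = active,
       plsBeta = beta, lambda = lambda, k = K, blockIds = blockIds,
       featureIds = featIds, componentSource = srcUsed, control = control)
}
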