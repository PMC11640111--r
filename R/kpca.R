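#' KernelModel: fitted kernel PCA state
#'
#' Radial-basis-function kernel PCA: the kernel matrix
#' `K_ij = exp(-gamma * ||x_i - x_j||^2)` is double-centered and
#' eigendecomposed; retained components span the leading positive
#' eigenvalues. The stored column means and grand mean of the training kernel
#' centre out-of-sample points consistently. Component signs are fixed by
#' making each component's largest-magnitude dual coefficient positive.
#'
#' @slot gamma Kernel width hyperparameter (> 0).
#' @slot X Training matrix (flattened sequences, one row per sample).
#' @slot dualCoef `n x k` dual coefficients (eigenvectors scaled by
#'   `1/sqrt(lambda)`).
#' @slot lambda Retained eigenvalues, descending.
#' @slot kColMeans,kGrandMean Centering statistics of the training kernel.
#' @slot trainProj Stored training projections (`n x k`).
#' @export
setClass("KernelModel", representation(
  gamma = "numeric", X = "matrix", dualCoef = "matrix", lambda = "numeric",
  kColMeans = "numeric", kGrandMean = "numeric", trainProj = "matrix"))

setMethod("show", "KernelModel", function(object) {
  cat(sprintf("KernelModel: gamma = %g, %d training points, %d components\n",
              object@gamma, nrow(object@X), ncol(object@dualCoef)))
})

rbfKernel <- function(A, B, gamma) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  exp(-gamma * pmax(d2, 0))
}

#' Fit kernel PCA
#'
#' @param X Numeric matrix, one flattened sample per row (`n >= 2`).
#' @param gamma RBF width, > 0.
#' @param nComponents Maximum components to retain; default
#'   `min(n - 1, 256)`.
#' @param tol Relative eigenvalue tolerance below which components are
#'   dropped (default 1e-10).
#' @return A [KernelModel-class].
#' @examples
#' X <- matrix(rnorm(40), 20, 2)
#' km <- fitKPCA(X, gamma = 0.5)
#' colMeans(projectKPCA(km, X))   # ~0 by centering
#' @export
fitKPCA <- function(X, gamma, nComponents = NULL, tol = 1e-10) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopIfNot(n >= 2L, "need at least 2 samples")
  stopIfNot(is.numeric(gamma) && length(gamma) == 1L && gamma > 0,
            "gamma must be a single positive number")
  if (is.null(nComponents)) nComponents <- min(n - 1L, 256L)
  K <- rbfKernel(X, X, gamma)
  cm <- colMeans(K)
  g <- mean(K)
  Kc <- K - matrix(rowMeans(K), n, n) - matrix(cm, n, n, byrow = TRUE) + g
  eig <- eigen(Kc, symmetric = TRUE)
  lambda <- eig$values
  keep <- which(lambda > tol * max(lambda[1], .Machine$double.eps))
  if (length(keep) == 0L)
    stop("degenerate kernel: no positive eigenvalues (all points identical?)",
         call. = FALSE)
  keep <- keep[seq_len(min(length(keep), nComponents))]
  lam <- lambda[keep]
  V <- eig$vectors[, keep, drop = FALSE]
  dual <- sweep(V, 2, sqrt(lam), "/")
  for (j in seq_len(ncol(dual))) {              # sign convention
    i <- which.max(abs(dual[, j]))
    if (dual[i, j] < 0) dual[, j] <- -dual[, j]
  }
  new("KernelModel", gamma = gamma, X = X, dualCoef = dual, lambda = lam,
      kColMeans = cm, kGrandMean = g, trainProj = Kc %*% dual)
}

#' Project points into the kernel PCA component space
#'
#' Out-of-sample points are centred with the stored training-kernel means;
#' projecting the training set reproduces the stored training components.
#'
#' @param model A [KernelModel-class].
#' @param X Matrix with the training dimensionality.
#' @return `nrow(X) x k` component matrix.
#' @export
projectKPCA <- function(model, X) {
  X <- as.matrix(X)
  stopIfNot(ncol(X) == ncol(model@X),
            sprintf("X has %d columns; model was trained on %d",
                    ncol(X), ncol(model@X)))
  Kt <- rbfKernel(X, model@X, model@gamma)
  Ktc <- Kt - matrix(rowMeans(Kt), nrow(Kt), ncol(Kt)) -
    matrix(model@kColMeans, nrow(Kt), ncol(Kt), byrow = TRUE) + model@kGrandMean
  Ktc %*% model@dualCoef
}

#' RidgeModel: one-vs-rest ridge-penalised linear classifier
#'
#' Closed-form ridge-penalised least squares on +/-1 one-vs-rest targets over
#' kernel PCA components; the penalty shrinks the weights of less useful
#' components (the intercept is unpenalised).
#'
#' @slot W Weight matrix, components x classes.
#' @slot intercept Per-class intercepts.
#' @slot alpha Penalty strength.
#' @slot classes Class labels, in column order of `W`.
#' @export
setClass("RidgeModel", representation(
  W = "matrix", intercept = "numeric", alpha = "numeric",
  classes = "character"))

setMethod("show", "RidgeModel", function(object) {
  cat(sprintf("RidgeModel: %d components -> %d classes, alpha = %g\n",
              nrow(object@W), length(object@classes), object@alpha))
})

#' Fit the ridge classifier on component scores
#'
#' @param Z Component matrix (rows = samples).
#' @param labels Class labels, one per row of `Z`.
#' @param alpha Ridge penalty, >= 0 (default 1).
#' @return A [RidgeModel-class].
#' @export
fitRidge <- function(Z, labels, alpha = 1) {
  Z <- as.matrix(Z)
  stopIfNot(nrow(Z) == length(labels), "rows(Z) must equal length(labels)")
  stopIfNot(alpha >= 0, "alpha must be >= 0")
  classes <- sort(unique(as.character(labels)))
  stopIfNot(length(classes) >= 2L, "need at least 2 classes")
  Y <- outer(as.character(labels), classes, function(a, b) ifelse(a == b, 1, -1))
  zbar <- colMeans(Z); ybar <- colMeans(Y)
  Zc <- sweep(Z, 2, zbar); Yc <- sweep(Y, 2, ybar)
  p <- ncol(Z)
  W <- solve(crossprod(Zc) + alpha * diag(p), crossprod(Zc, Yc))
  new("RidgeModel", W = W, intercept = as.numeric(ybar - zbar %*% W),
      alpha = alpha, classes = classes)
}

ridgeScores <- function(model, Z) {
  sweep(as.matrix(Z) %*% model@W, 2, model@intercept, "+")
}

#' Predict labels with a fitted KPCA + ridge pipeline
#'
#' @param kmodel A [KernelModel-class].
#' @param rmodel A [RidgeModel-class] fitted on `kmodel`'s components.
#' @param X Matrix in the training input dimensionality.
#' @return Character vector of predicted labels; per-class linear scores are
#'   attached as attribute `"scores"`.
#' @export
predictKpcaRidge <- function(kmodel, rmodel, X) {
  Z <- projectKPCA(kmodel, X)
  stopIfNot(ncol(Z) == nrow(rmodel@W),
            "ridge model dimensionality does not match kernel model")
  S <- ridgeScores(rmodel, Z)
  out <- rmodel@classes[max.col(S, ties.method = "first")]
  attr(out, "scores") <- S
  out
}

#' Stratified reduction of a training set
#'
#' Subsamples a training set to a fraction of its size, stratified by class
#' (each class keeps `round(n_c * factor)` samples), reproducibly given a
#' seed. Intended factors are 1, 1/4 and 1/16, mirroring the downsampling
#' needed to keep the kernel eigendecomposition tractable on the large
#' subsample variants.
#'
#' @param X Sample matrix (rows = samples) or `n x T x C` array.
#' @param labels Class labels.
#' @param factor Fraction to keep, in (0, 1].
#' @param seed Seed.
#' @return List with `X` and `labels` reduced; a class that ends up empty
#'   triggers a warning.
#' @export
reduceTrainingSet <- function(X, labels, factor = 1, seed = 1) {
  stopIfNot(factor > 0 && factor <= 1, "factor must lie in (0, 1]")
  n <- if (is.matrix(X)) nrow(X) else dim(X)[1]
  stopIfNot(n == length(labels), "X rows must equal length(labels)")
  if (factor == 1) return(list(X = X, labels = labels))
  # largest-remainder allocation: per-class floors, then distribute the
  # remainder so the total is exactly round(n * factor)
  classes <- sort(unique(as.character(labels)))
  nc <- vapply(classes, function(cl) sum(labels == cl), numeric(1))
  want <- nc * factor
  k <- floor(want)
  total <- round(n * factor)
  extra <- total - sum(k)
  if (extra > 0) {
    ord <- order(-(want - k))
    k[ord[seq_len(min(extra, length(k)))]] <-
      k[ord[seq_len(min(extra, length(k)))]] + 1
  }
  keep <- withSeed(seed, {
    idx <- integer()
    for (j in seq_along(classes)) {
      if (k[j] == 0) warning("class '", classes[j], "' emptied by reduction",
                             call. = FALSE)
      if (k[j] > 0) idx <- c(idx, sample(which(labels == classes[j]), k[j]))
    }
    sort(idx)
  })
  if (is.matrix(X)) list(X = X[keep, , drop = FALSE], labels = labels[keep])
  else list(X = X[keep, , , drop = FALSE], labels = labels[keep])
}

#' Validation-based gamma selection for kernel PCA
#'
#' Fits the KPCA + ridge pipeline for each candidate gamma on an internal
#' stratified split of the training data and returns the gamma with the best
#' validation accuracy.
#'
#' @param X Training matrix.
#' @param labels Training labels.
#' @param gammas Candidate gammas (typically a log grid).
#' @param alpha Ridge penalty.
#' @param ratio Internal train fraction (default 0.8).
#' @param seed Seed for the internal split.
#' @param nComponents Passed to [fitKPCA()].
#' @return List with `gamma` (best) and `accuracy` (named vector over the
#'   grid).
#' @export
selectGamma <- function(X, labels, gammas, alpha = 1, ratio = 0.8, seed = 1,
                        nComponents = NULL) {
  stopIfNot(length(gammas) >= 1L && all(gammas > 0), "gammas must be positive")
  idx <- withSeed(seed, {
    tr <- integer()
    for (cl in sort(unique(as.character(labels)))) {
      i <- which(labels == cl)
      tr <- c(tr, sample(i)[seq_len(max(1L, round(ratio * length(i))))])
    }
    sort(tr)
  })
  va <- setdiff(seq_len(nrow(X)), idx)
  acc <- vapply(gammas, function(g) {
    km <- fitKPCA(X[idx, , drop = FALSE], g, nComponents = nComponents)
    rm_ <- fitRidge(km@trainProj, labels[idx], alpha)
    mean(predictKpcaRidge(km, rm_, X[va, , drop = FALSE]) == labels[va])
  }, numeric(1))
  names(acc) <- signif(gammas, 4)
  list(gamma = gammas[which.max(acc)], accuracy = acc)
}
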