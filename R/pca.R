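# Five-stage principal component analysis with strict train/test
# asymmetry: (A) training mean, (B) unnormalized scatter matrix,
# (C) eigendecomposition, (D) component selection by cumulative-variance
# precision, (E) projection of centred data. Test batches are always
# centred with the TRAINING mean.

#' Fit a principal-component model on training vectors
#'
#' Computes the training mean, the unnormalized scatter matrix
#' \code{A = sum_i (X_i - Xbar)^T (X_i - Xbar)} (the constant 1/(n-1)
#' factor does not affect eigenvectors or variance ratios), its
#' eigendecomposition, and retains the smallest leading set of
#' components whose cumulative variance ratio reaches \code{precision}.
#' Eigenvector signs are fixed so each column's largest-magnitude entry
#' is positive, making the model fully deterministic.
#'
#' @param x numeric matrix, one training vector per row.
#' @param precision cumulative-variance threshold in (0, 1].
#' @param mode \code{"standard"}: project on the retained eigenvectors;
#'   \code{"eigenscaled"}: additionally scale each component by its eigenvalue
#'   (a per-component positive rescaling kept for audit; it changes no
#'   component ordering or selection).
#' @return a \linkS4class{PCAModel}.
#' @export
fitPCA <- function(x, precision = 0.95, mode = c("standard", "eigenscaled")) {
  mode <- match.arg(mode)
  if (nrow(x) < 2L) .stopf("need at least 2 training vectors")
  if (precision <= 0 || precision > 1) .stopf("precision must be in (0, 1]")
  center <- colMeans(x)
  xc <- sweep(x, 2L, center)
  A <- crossprod(xc)          # unnormalized scatter
  eg <- eigen(A, symmetric = TRUE)
  vals <- pmax(eg$values, 0)
  if (sum(vals) < 1e-24)
    .stopf("all training vectors identical: zero covariance")
  vecs <- eg$vectors
  for (k in seq_len(ncol(vecs))) {
    i <- which.max(abs(vecs[, k]))
    if (vecs[i, k] < 0) vecs[, k] <- -vecs[, k]
  }
  ratio <- cumsum(vals) / sum(vals)
  k <- which(ratio >= precision - 1e-12)[1L]
  if (mode == "standard") {
    red <- vecs[, seq_len(k), drop = FALSE]
  } else {
    red <- vecs[, seq_len(k), drop = FALSE] %*%
      diag(vals[seq_len(k)], nrow = k)
  }
  new("PCAModel", center = center, eigvals = vals, eigvecs = vecs,
      selected = seq_len(k), reduction = red, precision = precision,
      mode = mode)
}

#' Project vectors with a fitted model
#'
#' Subtracts the training mean (never the batch mean) and projects onto
#' the retained components.
#'
#' @param model a \linkS4class{PCAModel}.
#' @param x numeric matrix (or single vector) in the original feature
#'   space.
#' @return matrix with \code{length(model@selected)} columns.
#' @export
pcaTransform <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (ncol(x) != length(model@center))
    .stopf("vector dimension %d does not match model dimension %d",
           ncol(x), length(model@center))
  sweep(x, 2L, model@center) %*% model@reduction
}

#' Reconstruct from the reduced space
#'
#' Inverse of the standard-mode projection: lossless when all nonzero
#' components are retained (precision 1).
#'
#' @param model a \linkS4class{PCAModel} fitted with
#'   \code{mode = "standard"}.
#' @param z reduced matrix.
#' @return matrix in the original feature space.
#' @export
pcaReconstruct <- function(model, z) {
  if (model@mode != "standard")
    .stopf("reconstruction is defined for mode 'standard'")
  if (is.null(dim(z))) z <- matrix(z, nrow = 1L)
  sweep(z %*% t(model@reduction), 2L, model@center, `+`)
}

#' Explained variance ratio of the retained components
#'
#' @param model a \linkS4class{PCAModel}.
#' @return scalar in (0, 1].
#' @export
explainedVariance <- function(model) {
  sum(model@eigvals[model@selected]) / sum(model@eigvals)
}

setMethod("show", "PCAModel", function(object) {
  cat(sprintf(
    "PCAModel: %d -> %d components (precision %.3g, mode %s), explained %.4f\n",
    length(object@center), length(object@selected), object@precision,
    object@mode, explainedVariance(object)))
})
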