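#' Fit a PCA basis for channel-axis feature reduction
#'
#' In the default `"channel"` mode each 630-dimensional feature row is
#' reshaped to its 14 x 45 (feature-type x channel) block, all
#' `segments * 14` channel-profile rows are pooled, centred, and the
#' covariance of the 45-channel axis is eigendecomposed.  Projecting each
#' block onto the leading `n_keep` eigenvectors turns 14 x 45 into
#' 14 x `n_keep` -- 630 into 42 for the default `n_keep = 3`.  The
#' alternative `"full"` mode runs one PCA on the complete feature vectors
#' and keeps `14 * n_keep` components.
#'
#' @param features Numeric matrix, one segment per row, `14 * n_channels`
#'   columns in feature-major order (>= 2 rows).
#' @param n_keep Number of principal components kept per feature type
#'   (default 3).
#' @param mode `"channel"` (default) or `"full"`.
#' @return An object of class `pca_basis` with `eigenvalues` (sorted
#'   descending), orthonormal `eigenvectors` (columns), `contributions`
#'   (proportions summing to 1), `center`, `n_keep` and `mode`.
#' @export
fit_pca <- function(features, n_keep = 3L, mode = c("channel", "full")) {
  mode <- match.arg(mode)
  features <- as.matrix(features)
  if (nrow(features) < 2L)
    stop("need at least 2 feature rows to fit a basis", call. = FALSE)
  n_feat <- length(feature_names())
  if (ncol(features) %% n_feat != 0L)
    stop("feature width is not a multiple of 14", call. = FALSE)
  n_ch <- ncol(features) %/% n_feat
  if (mode == "channel") {
    stopifnot(n_keep >= 1L, n_keep <= n_ch)
    # pool the 14 channel-profiles of every segment into one matrix
    pooled <- do.call(rbind, lapply(seq_len(nrow(features)), function(i)
      matrix(features[i, ], nrow = n_feat, ncol = n_ch, byrow = TRUE)))
  } else {
    stopifnot(n_keep >= 1L, n_feat * n_keep <= ncol(features))
    pooled <- features
  }
  center <- colMeans(pooled)
  centred <- sweep(pooled, 2L, center)
  covm <- crossprod(centred) / (nrow(pooled) - 1L)
  eig <- eigen(covm, symmetric = TRUE)
  vals <- pmax(eig$values, 0)
  vecs <- eig$vectors
  # deterministic sign: largest-magnitude loading of each component > 0
  for (j in seq_len(ncol(vecs))) {
    piv <- which.max(abs(vecs[, j]))
    if (vecs[piv, j] < 0) vecs[, j] <- -vecs[, j]
  }
  structure(list(eigenvalues = vals, eigenvectors = vecs,
                 contributions = contribution_rates(vals)$proportions,
                 center = center, n_keep = as.integer(n_keep),
                 mode = mode, n_channels = n_ch, n_features = n_feat),
            class = "pca_basis")
}

#' Contribution rates of eigenvalues
#'
#' Each eigenvalue's share of the covariance trace,
#' \eqn{\lambda_i / \sum_j \lambda_j}, plus the cumulative sums used to
#' decide how many components to retain.
#'
#' @param eigenvalues Non-negative numeric vector.
#' @return List with `proportions` and `cumulative`.
#' @export
contribution_rates <- function(eigenvalues) {
  stopifnot(is.numeric(eigenvalues), all(eigenvalues >= 0))
  tot <- sum(eigenvalues)
  if (tot == 0) stop("all eigenvalues are zero", call. = FALSE)
  p <- eigenvalues / tot
  list(proportions = p, cumulative = cumsum(p))
}

#' Project features onto a fitted PCA basis
#'
#' In `"channel"` mode each 14 x 45 block is centred and projected onto
#' the top `n_keep` eigenvectors, yielding 14 x `n_keep` values per
#' segment flattened feature-major (42 for the default); `"full"` mode
#' projects whole rows onto `14 * n_keep` components.
#'
#' @param features Numeric matrix as in [fit_pca()].
#' @param basis A fitted `pca_basis`.
#' @return Numeric matrix, one row per segment.
#' @export
project <- function(features, basis) {
  stopifnot(inherits(basis, "pca_basis"))
  features <- as.matrix(features)
  nf <- basis$n_features
  if (basis$mode == "channel") {
    if (ncol(features) != nf * basis$n_channels)
      stop("feature width does not match the basis", call. = FALSE)
    V <- basis$eigenvectors[, seq_len(basis$n_keep), drop = FALSE]
    out <- t(vapply(seq_len(nrow(features)), function(i) {
      blk <- matrix(features[i, ], nrow = nf, ncol = basis$n_channels,
                    byrow = TRUE)
      as.numeric(t(sweep(blk, 2L, basis$center) %*% V))
    }, numeric(nf * basis$n_keep)))
    if (nrow(features) == 1L) out <- matrix(out, nrow = 1L)
  } else {
    ncomp <- nf * basis$n_keep
    V <- basis$eigenvectors[, seq_len(ncomp), drop = FALSE]
    out <- sweep(features, 2L, basis$center) %*% V
  }
  rownames(out) <- NULL
  out
}

#' Back-project reduced features to the original space
#'
#' Inverse of [project()]; exact when all components are kept.
#'
#' @param reduced Output of [project()].
#' @param basis The `pca_basis` used to produce it.
#' @return Numeric matrix in the original feature space.
#' @export
pca_reconstruct <- function(reduced, basis) {
  stopifnot(inherits(basis, "pca_basis"))
  reduced <- as.matrix(reduced)
  nf <- basis$n_features
  if (basis$mode == "channel") {
    V <- basis$eigenvectors[, seq_len(basis$n_keep), drop = FALSE]
    out <- t(vapply(seq_len(nrow(reduced)), function(i) {
      blk <- matrix(reduced[i, ], nrow = nf, ncol = basis$n_keep,
                    byrow = TRUE)
      as.numeric(t(sweep(blk %*% t(V), 2L, basis$center, `+`)))
    }, numeric(nf * basis$n_channels)))
    if (nrow(reduced) == 1L) out <- matrix(out, nrow = 1L)
  } else {
    ncomp <- nf * basis$n_keep
    V <- basis$eigenvectors[, seq_len(ncomp), drop = FALSE]
    out <- sweep(reduced %*% t(V), 2L, basis$center, `+`)
  }
  out
}
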