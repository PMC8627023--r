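# Transfer Component Analysis: kernel MMD between two feature domains, the
# joint kernel system (K, L, H), the regularized transfer eigenproblem, and
# projection of both domains (plus out-of-sample rows) into m latent
# components.  A PCA projection of the stacked data serves as the baseline
# the latent space is compared against.

#' Kernel specification
#'
#' @param kernel `"linear"` (default) or `"rbf"`.
#' @param sigma RBF bandwidth.  `NULL` (default) means "resolve from the
#'   data by the median pairwise Euclidean distance heuristic" at the point
#'   of use; [fitTCA()] freezes the resolved value into the projection so
#'   out-of-sample rows use the fit-time bandwidth.
#' @return a list with class `"kernelSpec"`.
#' @export
kernelSpec <- function(kernel = c("linear", "rbf"), sigma = NULL) {
  kernel <- match.arg(kernel)
  if (!is.null(sigma) && (!is.numeric(sigma) || sigma <= 0))
    .stopf("'sigma' must be a positive number")
  structure(list(kernel = kernel, sigma = sigma), class = "kernelSpec")
}

.medianHeuristic <- function(x) {
  # median pairwise distance on at most 500 rows (deterministic subsample:
  # evenly spaced indices) to keep the heuristic O(1) in memory
  n <- nrow(x)
  if (n > 500L) x <- x[round(seq(1L, n, length.out = 500L)), , drop = FALSE]
  d <- stats::dist(x)
  s <- stats::median(d)
  if (!is.finite(s) || s <= 0) 1 else s
}

.resolveKernel <- function(spec, stacked) {
  if (spec$kernel == "rbf" && is.null(spec$sigma))
    spec$sigma <- .medianHeuristic(stacked)
  spec
}

.kernelCross <- function(spec, A, B) {
  if (spec$kernel == "linear") return(A %*% t(B))
  # RBF: exp(-||a-b||^2 / (2 sigma^2))
  sq <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  sq[sq < 0] <- 0
  exp(-sq / (2 * spec$sigma^2))
}

.asMatrixInput <- function(x) {
  if (is(x, "DomainDataset")) x <- featureMatrix(x)
  .assertMatrix(x)
}

#' Squared maximum mean discrepancy between two samples
#'
#' The squared RKHS distance between the empirical kernel mean embeddings
#' of the two samples,
#' `mean(K_AA) - 2 mean(K_AB) + mean(K_BB)`, clipped at zero against
#' negative round-off.  With the linear kernel this is exactly
#' `||colMeans(A) - colMeans(B)||^2`.
#'
#' @param A,B numeric matrices (or [DomainDataset-class]s) sharing a feature
#'   dimension.
#' @param kernel a [kernelSpec()]; an unresolved RBF bandwidth is taken as
#'   the median heuristic on the stacked rows of `A` and `B`.
#' @return a non-negative scalar.
#' @examples
#' A <- matrix(rnorm(50), 10); mmdDistance(A, A)  # 0
#' @export
mmdDistance <- function(A, B, kernel = kernelSpec("linear")) {
  A <- .asMatrixInput(A); B <- .asMatrixInput(B)
  if (nrow(A) == 0L || nrow(B) == 0L) .stopf("empty sample matrix")
  if (ncol(A) != ncol(B)) .stopf("feature dimensions differ")
  .assertFinite(A, "A"); .assertFinite(B, "B")
  kernel <- .resolveKernel(kernel, rbind(A, B))
  d <- mean(.kernelCross(kernel, A, A)) -
    2 * mean(.kernelCross(kernel, A, B)) +
    mean(.kernelCross(kernel, B, B))
  max(d, 0)
}

#' Joint kernel system of the transfer eigenproblem
#'
#' Stacks source over target and returns the three matrices the transfer
#' objective is built from: the joint Gram matrix `K` (blocks K_SS, K_ST,
#' K_TS, K_TT in source-then-target order), the MMD coefficient matrix `L`
#' (`1/n1^2` within source, `1/n2^2` within target, `-1/(n1 n2)` across,
#' so that `tr(KL)` equals the squared MMD), and the centering matrix
#' `H = I - 11'/(n1+n2)`.
#'
#' @param source,target feature matrices or [DomainDataset-class]s.
#' @inheritParams mmdDistance
#' @return list with elements `K`, `L`, `H`, `n1`, `n2` and the resolved
#'   `kernel`.
#' @export
buildKernelSystem <- function(source, target, kernel = kernelSpec("linear")) {
  Xs <- .asMatrixInput(source); Xt <- .asMatrixInput(target)
  if (ncol(Xs) != ncol(Xt)) .stopf("feature dimensions differ")
  stacked <- rbind(Xs, Xt)
  .assertFinite(stacked, "features")
  kernel <- .resolveKernel(kernel, stacked)
  n1 <- nrow(Xs); n2 <- nrow(Xt); n <- n1 + n2
  K <- .kernelCross(kernel, stacked, stacked)
  K <- (K + t(K)) / 2
  L <- matrix(-1 / (n1 * n2), n, n)
  L[seq_len(n1), seq_len(n1)] <- 1 / n1^2
  L[n1 + seq_len(n2), n1 + seq_len(n2)] <- 1 / n2^2
  H <- diag(n) - matrix(1 / n, n, n)
  list(K = K, L = L, H = H, n1 = n1, n2 = n2, kernel = kernel)
}

#' Fit a Transfer Component Analysis projection
#'
#' Solves the regularized transfer eigenproblem: the leading eigenvectors
#' of `(K L K + mu I)^{-1} K H K`, equivalently the generalized symmetric
#' problem `K H K w = nu (K L K + mu I) w`.  Eigenvectors are normalized to
#' `w' (K L K + mu I) w = 1`, sorted by non-increasing eigenvalue, trimmed
#' of numerically zero eigenvalues (`|nu| <= zeroTol * max |nu|`), and the
#' first `m` are retained; each is sign-fixed so its largest-magnitude
#' entry is positive.  The fit-time embedding of the stacked domains is
#' `K %*% W`.
#'
#' @param source labeled microindel-domain dataset (matrix or
#'   [DomainDataset-class]); stacked first.
#' @param target unlabeled microexon-domain dataset; stacked second.
#' @inheritParams mmdDistance
#' @param m number of latent components to retain (default 8).
#' @param mu ridge regularizer making the system invertible (default 0.1).
#' @param zeroTol relative eigenvalue cutoff defining "nonzero".
#' @return a [TCAProjection-class].
#' @seealso [tcaTransform()], [sourceEmbedding()], [targetEmbedding()]
#' @export
fitTCA <- function(source, target, kernel = kernelSpec("linear"), m = 8L,
                   mu = 0.1, zeroTol = 1e-10) {
  if (m < 1L) .stopf("'m' must be >= 1")
  if (mu <= 0) .stopf("'mu' must be > 0")
  sys <- buildKernelSystem(source, target, kernel)
  K <- sys$K
  A <- K %*% sys$L %*% K + mu * diag(nrow(K))
  B <- K %*% sys$H %*% K
  B <- (B + t(B)) / 2
  A <- (A + t(A)) / 2

  # whiten with the Cholesky factor of A, solve the symmetric problem
  R <- tryCatch(chol(A), error = function(e)
    .stopf("transfer system is numerically singular (condition estimate %.3g); increase mu",
           kappa(A)))
  Msym <- forwardsolve(t(R), t(forwardsolve(t(R), B)))
  Msym <- (Msym + t(Msym)) / 2
  eig <- eigen(Msym, symmetric = TRUE)
  W <- backsolve(R, eig$vectors)                 # generalized eigenvectors
  vals <- eig$values

  keep <- abs(vals) > zeroTol * max(abs(vals))
  if (!any(keep)) .stopf("no nonzero eigenvalues in the transfer system")
  W <- W[, keep, drop = FALSE]; vals <- vals[keep]
  if (m > ncol(W)) {
    .warnf("only %d nonzero eigenvalues available; retaining all of them",
           ncol(W))
    m <- ncol(W)
  }
  W <- W[, seq_len(m), drop = FALSE]
  vals <- vals[seq_len(m)]
  # reproducible sign: largest-magnitude entry of each eigenvector positive
  for (j in seq_len(ncol(W))) {
    i <- which.max(abs(W[, j]))
    if (W[i, j] < 0) W[, j] <- -W[, j]
  }

  stacked <- rbind(.asMatrixInput(source), .asMatrixInput(target))
  new("TCAProjection", kernel = unclass(sys$kernel), trainMatrix = stacked,
      eigvecs = W, eigvals = vals, m = as.integer(m), mu = mu,
      nSource = sys$n1, nTarget = sys$n2, embedding = K %*% W)
}

#' @rdname tcaTransform
#' @export
setMethod("tcaTransform", "TCAProjection", function(x, data) {
  data <- .asMatrixInput(data)
  if (ncol(data) != ncol(x@trainMatrix))
    .stopf("feature dimension %d does not match the projection (%d)",
           ncol(data), ncol(x@trainMatrix))
  .assertFinite(data, "data")
  spec <- structure(x@kernel, class = "kernelSpec")
  .kernelCross(spec, data, x@trainMatrix) %*% x@eigvecs
})

#' Post-projection MMD of a fitted TCA mapping
#'
#' Linear-kernel MMD between the source and target rows of the fit-time
#' embedding — the quantity the transfer components were chosen to shrink.
#'
#' @param x a [TCAProjection-class].
#' @return non-negative scalar.
#' @export
projectedMMD <- function(x) {
  stopifnot(is(x, "TCAProjection"))
  mmdDistance(sourceEmbedding(x), targetEmbedding(x), kernelSpec("linear"))
}

#' PCA baseline projection of the stacked domains
#'
#' Projects the stacked source+target data onto the top-m principal
#' components and reports the post-projection linear-kernel MMD, for
#' comparison with the TCA latent space.  PCA maximizes retained variance
#' with no cross-domain term, so it leaves the domain shift largely in
#' place; the contrast quantifies what the transfer objective buys.
#'
#' @inheritParams fitTCA
#' @param m number of principal components (must not exceed the feature
#'   count).
#' @return list with `source` and `target` component matrices, the fitted
#'   `prcomp` object (`pca`), and `mmd`, the post-projection MMD.
#' @export
pcaBaseline <- function(source, target, m = 8L) {
  Xs <- .asMatrixInput(source); Xt <- .asMatrixInput(target)
  if (ncol(Xs) != ncol(Xt)) .stopf("feature dimensions differ")
  if (m > ncol(Xs)) .stopf("'m' exceeds the feature count")
  stacked <- rbind(Xs, Xt)
  .assertFinite(stacked, "features")
  pca <- stats::prcomp(stacked, center = TRUE, scale. = FALSE)
  comp <- pca$x[, seq_len(m), drop = FALSE]
  Es <- comp[seq_len(nrow(Xs)), , drop = FALSE]
  Et <- comp[nrow(Xs) + seq_len(nrow(Xt)), , drop = FALSE]
  list(source = Es, target = Et, pca = pca,
       mmd = mmdDistance(Es, Et, kernelSpec("linear")))
}
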