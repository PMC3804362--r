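#' Fit a 3-D thin-plate-spline warp through point pairs
#'
#' Solves the regularized TPS system with radial kernel `phi(r) = r`:
#' \deqn{[K + \lambda I, P; P^T, 0] [W; A] = [Y; 0]}
#' where `P = [1, X]`. As `lambda -> 0` the warp interpolates the pairs
#' exactly; larger `lambda` trades fit for smoothness. The side condition
#' `P^T W = 0` is enforced by the block system.
#'
#' @param control n x 3 matrix of source (control) points.
#' @param targets n x 3 matrix of target points.
#' @param lambda non-negative smoothness weight.
#' @return a [TPSWarp-class].
#' @export
fitTPS <- function(control, targets, lambda = 0) {
  control <- as.matrix(control)
  targets <- as.matrix(targets)
  n <- nrow(control)
  stopifnot(nrow(targets) == n, ncol(control) == 3, ncol(targets) == 3)
  K <- tpsKernelMatrix(control, control)
  P <- cbind(1, control)
  A <- rbind(cbind(K + lambda * diag(n), P),
             cbind(t(P), matrix(0, 4, 4)))
  rhs <- rbind(targets, matrix(0, 4, 3))
  sol <- solve(A, rhs)
  new("TPSWarp", affine = sol[(n + 1):(n + 4), , drop = FALSE],
      kernelWeights = sol[seq_len(n), , drop = FALSE],
      controlPoints = control, lambda = as.numeric(lambda))
}

#' Apply a thin-plate-spline warp to points
#'
#' Each point maps through the affine part plus the radial-kernel
#' superposition over the control points; with zero kernel weights the map
#' is exactly affine.
#'
#' @param warp a [TPSWarp-class].
#' @param points m x 3 matrix.
#' @return m x 3 matrix of warped points.
#' @export
tpsWarpPoints <- function(warp, points) {
  points <- as.matrix(points)
  stopifnot(is(warp, "TPSWarp"), ncol(points) == 3)
  out <- cbind(1, points) %*% warp@affine
  if (nrow(warp@controlPoints) > 0)
    out <- out + tpsKernelMatrix(points, warp@controlPoints) %*% warp@kernelWeights
  out
}

#' Bending energy of a fitted TPS warp
#'
#' `trace(W^T K W)` over the warp's control points; the quantity the
#' smoothness weight penalizes.
#'
#' @param warp a [TPSWarp-class].
#' @return non-negative scalar.
#' @export
tpsBendingEnergy <- function(warp) {
  K <- tpsKernelMatrix(warp@controlPoints, warp@controlPoints)
  abs(sum(diag(crossprod(warp@kernelWeights, K %*% warp@kernelWeights))))
}

# |a_i - b_j| kernel matrix, phi(r) = r (3-D TPS radial basis)
tpsKernelMatrix <- function(a, b) {
  sqrt(crossDist2(a, b))  # crossDist2 already clamps at 0
}

# squared Euclidean cross-distance matrix
crossDist2 <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  pmax(d2, 0)
}
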