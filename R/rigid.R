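#' Rigid registration of a moving surface onto a reference
#'
#' Iterative closest point on vertex sets under a symmetric cost (forward
#' plus backward mean squared nearest-neighbour distance), initialized by
#' centroid alignment in the given orientation; a principal-axes
#' orientation search is available behind `searchAxes`. Only rotation and
#' translation are estimated - no scaling - so organ size, which carries
#' diagnostic signal, is untouched. Per-iteration pose updates use the
#' Kabsch SVD solution on the symmetric correspondence set; the iteration
#' stops when the cost stops improving.
#'
#' Label volumes are accepted and converted via [extractSurface()] first.
#'
#' @param moving,reference [Surface-class] or [LabelVolume-class] objects
#'   with the same organ tag.
#' @param maxIter maximum ICP iterations per initialization.
#' @param tol relative cost-improvement threshold for convergence.
#' @param searchAxes also try principal-axes initializations (all four
#'   proper-rotation sign combinations) and keep the lowest-cost result.
#'   Off by default: medical volumes arrive in a common patient
#'   orientation with only moderate pose differences, and a global
#'   orientation search can prefer an anatomically flipped pose when
#'   disease makes the organ near-symmetric (severe left-lobe
#'   hypertrophy mirrors the lobe balance). Enable for meshes with
#'   unknown orientation.
#' @return a [RigidTransform-class] mapping `moving` onto `reference`.
#' @examples
#' sph <- icosphere(1)
#' rot <- rotationMatrix(c(0, 0, 1), 15 * pi / 180)
#' mov <- applyTransform(sph, RigidTransform(rot, c(5, -3, 2)))
#' tf <- registerRigid(mov, sph)
#' @export
registerRigid <- function(moving, reference, maxIter = 100L, tol = 1e-12,
                          searchAxes = FALSE) {
  moving <- asSurface(moving)
  reference <- asSurface(reference)
  if (!identical(moving@organ, reference@organ))
    stop("moving and reference must carry the same organ tag")
  X <- moving@vertices
  Y <- reference@vertices
  if (nrow(X) < 3 || nrow(Y) < 3) stop("need at least 3 points per surface")
  cx <- colMeans(X)
  cy <- colMeans(Y)
  Xc <- sweep(X, 2, cx)
  Yc <- sweep(Y, 2, cy)
  if (svd(Xc)$d[2] < 1e-9 * max(1, svd(Xc)$d[1]))
    stop("degenerate input: moving points are (nearly) collinear")

  inits <- list(diag(3))
  if (searchAxes) {
    # principal-axes initializations (proper rotations only)
    ex <- svd(crossprod(Xc) / nrow(Xc))$u
    ey <- svd(crossprod(Yc) / nrow(Yc))$u
    if (det(ex) < 0) ex[, 3] <- -ex[, 3]
    if (det(ey) < 0) ey[, 3] <- -ey[, 3]
    signs <- list(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
    inits <- c(inits, lapply(signs, function(s) ey %*% diag(s) %*% t(ex)))
  }

  # symmetric surface-distance cost: forward plus backward mean squared
  # nearest-neighbour distance. A one-directional cost can rate a flipped
  # pose of a nearly-symmetric organ as good; the backward term exposes it.
  icpCost <- function(P) {
    mean(cpp_nn_index(P, Y)$distance^2) + mean(cpp_nn_index(Y, P)$distance^2)
  }
  best <- NULL
  for (R0 in inits) {
    R <- R0
    t0 <- cy - R %*% cx
    P <- X %*% t(R) + matrix(t0, nrow(X), 3, byrow = TRUE)
    iter <- list(R = R, t = t0, cost = icpCost(P))  # best iterate so far
    cost <- iter$cost
    for (it in seq_len(maxIter)) {
      # symmetric correspondence set: moving->reference pairs plus the
      # reversed reference->moving pairs
      nnF <- cpp_nn_index(P, Y)$index
      nnB <- cpp_nn_index(Y, P)$index
      Xp <- rbind(X, X[nnB, , drop = FALSE])
      Q <- rbind(Y[nnF, , drop = FALSE], Y)
      # Kabsch: rigid transform of original X onto current targets Q
      cp <- colMeans(Xp)
      cq <- colMeans(Q)
      H <- crossprod(sweep(Xp, 2, cp), sweep(Q, 2, cq)) / nrow(Xp)
      sv <- svd(H)
      d <- sign(det(sv$v %*% t(sv$u)))
      R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
      t0 <- cq - R %*% cp
      P <- X %*% t(R) + matrix(t0, nrow(X), 3, byrow = TRUE)
      newCost <- icpCost(P)
      if (newCost < iter$cost) iter <- list(R = R, t = t0, cost = newCost)
      if (cost - newCost <= tol * max(1, cost)) break
      cost <- newCost
    }
    if (is.null(best) || iter$cost < best$cost) best <- iter
  }
  # never worse than the untransformed input
  if (icpCost(X) < best$cost)
    return(RigidTransform(diag(3), c(0, 0, 0)))
  RigidTransform(best$R, as.numeric(best$t))
}

#' Apply a rigid transform to a surface
#'
#' Vertices map as `R v + t`; faces are untouched, so pairwise distances
#' and topology are preserved.
#'
#' @param surface a [Surface-class].
#' @param transform a [RigidTransform-class].
#' @return the transformed [Surface-class].
#' @export
applyTransform <- function(surface, transform) {
  stopifnot(is(surface, "Surface"), is(transform, "RigidTransform"))
  v <- surface@vertices %*% t(transform@rotation) +
    matrix(transform@translation, nrow(surface@vertices), 3, byrow = TRUE)
  Surface(v, surface@faces, organ = surface@organ)
}

#' Invert a rigid transform
#'
#' @param transform a [RigidTransform-class].
#' @return the inverse [RigidTransform-class].
#' @export
invertTransform <- function(transform) {
  Rt <- t(transform@rotation)
  RigidTransform(Rt, as.numeric(-Rt %*% transform@translation))
}

#' Compose two rigid transforms (`a` after `b`)
#'
#' @param a,b [RigidTransform-class] objects.
#' @return the composition applying `b` first, then `a`.
#' @export
composeTransforms <- function(a, b) {
  RigidTransform(a@rotation %*% b@rotation,
                 as.numeric(a@rotation %*% b@translation + a@translation))
}

#' Rotation matrix about an axis
#'
#' Rodrigues formula.
#'
#' @param axis numeric(3), need not be normalized.
#' @param angle radians.
#' @return 3 x 3 rotation matrix.
#' @export
rotationMatrix <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# coerce LabelVolume input to Surface for registration
asSurface <- function(x) {
  if (is(x, "LabelVolume")) extractSurface(x) else x
}
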