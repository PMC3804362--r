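#' Non-rigid point matching by TPS-RPM
#'
#' Robust point matching under deterministic annealing: alternates
#' soft-assign correspondence updates (Gaussian affinities, Sinkhorn
#' row/column normalization) with regularized thin-plate-spline refits of
#' the reference onto its virtual (softly matched) targets, while the
#' temperature is lowered geometrically. The TPS smoothness weight is
#' annealed proportionally to the temperature. The final hard
#' correspondence is the greedy conflict-free row argmax of the last
#' soft-assign matrix, with ties broken towards the smaller subject index.
#'
#' The matching is fully deterministic given inputs and schedule. With
#' equal, standardized vertex counts the outlier row/column is disabled by
#' default; enable it for partially overlapping point sets.
#'
#' @param subject,reference [Surface-class] objects standardized to the
#'   same vertex count.
#' @param tempInit initial temperature; default is the squared largest
#'   reference-to-subject distance.
#' @param tempFinal final temperature; default is the squared mean
#'   nearest-neighbour spacing of the reference divided by 25, cold
#'   enough that the soft assignments sharpen to their nearest neighbour
#'   before the hard correspondence is read off.
#' @param annealRate geometric temperature decay per outer iteration.
#' @param innerIter soft-assign/TPS alternations per temperature.
#' @param lambda0 TPS smoothness per unit temperature.
#' @param affineAnchor weight (relative to `lambda0`) anchoring the
#'   affine part of the warp to the identity, annealed with temperature.
#'   Without it the unpenalized affine fit collapses or rotates the
#'   template at high temperature before the assignments commit.
#' @param sinkhornIter row/column normalization sweeps.
#' @param outlier enable an outlier row/column with this mass (0 = off).
#' @param maxOuter hard cap on outer iterations; exceeding it returns the
#'   best iterate with `converged = FALSE`.
#' @return a list with elements `correspondence` ([Correspondence-class]),
#'   `warp` ([TPSWarp-class]) and `energyTrace` (list of per-temperature
#'   energy vectors, one value per inner iteration).
#' @examples
#' ref <- icosphere(1, radius = 10)
#' out <- matchTpsRpm(ref, ref)
#' all(mapping(out$correspondence) == seq_len(42))
#' @export
matchTpsRpm <- function(subject, reference, tempInit = NULL,
                        tempFinal = NULL, annealRate = 0.93,
                        innerIter = 5L, lambda0 = 1, affineAnchor = 1,
                        sinkhornIter = 5L, outlier = 0, maxOuter = 500L) {
  stopifnot(is(subject, "Surface"), is(reference, "Surface"))
  X <- reference@vertices
  Y <- subject@vertices
  n <- nrow(X)
  if (nrow(Y) != n)
    stop("subject and reference must be standardized to the same vertex count")

  D0 <- crossDist2(X, Y)
  if (is.null(tempInit)) tempInit <- max(D0)
  if (is.null(tempFinal)) {
    dXX <- crossDist2(X, X)
    diag(dXX) <- Inf
    tempFinal <- mean(sqrt(apply(dXX, 1, min)))^2 / 25
  }
  if (tempFinal >= tempInit) tempFinal <- tempInit / 2

  # precompute the regularized-TPS machinery: K over the fixed control
  # points, the null-space basis Q2 of the affine design (so the side
  # condition P'W = 0 holds by construction), and the products reused at
  # every refit
  K <- tpsKernelMatrix(X, X)
  P <- cbind(1, X)
  qrP <- qr(P)
  Q2 <- qr.Q(qrP, complete = TRUE)[, -(1:4), drop = FALSE]
  U <- K %*% Q2
  UtU <- crossprod(U)
  # bending-energy quadratic: for the 3-D kernel phi(r) = r the
  # conditionally positive definite form on the side-condition subspace is
  # -Q2' K Q2 (phi = -r is the CPD polyharmonic kernel; the sign flip makes
  # the smoothness term a true penalty)
  bendQ <- -crossprod(Q2, U)
  PtU <- crossprod(P, U)
  PtP <- crossprod(P)
  affId <- rbind(0, diag(3))           # identity map in affine coordinates

  ng <- ncol(Q2)
  lhsIdx <- seq_len(ng)

  temp <- tempInit
  fit <- list(A = affId, W = matrix(0, n, 3))  # start at the identity map
  fX <- X
  M <- NULL
  energyTrace <- list()
  outer <- 0L
  converged <- TRUE
  sizeScale <- max(1, mean(rowSums(sweep(X, 2, colMeans(X))^2)))
  repeat {
    outer <- outer + 1L
    if (outer > maxOuter) { converged <- FALSE; break }
    l1 <- lambda0 * temp
    l2 <- affineAnchor * lambda0 * temp  # anchor keeping the affine part near identity
    # the warp refit minimizes |Yv - K W - P A|^2 + l1 tr(W' (-K) W)
    # + l2 |A - id|^2 with W = Q2 g; the system matrix is fixed within a
    # temperature, so factor it once
    lhs <- rbind(cbind(UtU + l1 * bendQ, t(PtU)),
                 cbind(PtU, PtP + l2 * diag(4)))
    lhsChol <- chol(lhs)
    energies <- numeric(0)
    for (it in seq_len(innerIter)) {
      D <- crossDist2(fX, Y)
      # per-row shift keeps exp() in range; Sinkhorn removes row factors
      M <- exp(-(D - apply(D, 1, min)) / temp)
      for (s in seq_len(sinkhornIter)) {
        M <- M / .rowSums(M, n, n)
        cs <- .colSums(M, n, n)
        if (outlier > 0) cs <- pmax(cs, 1 + outlier)
        M <- M * rep(1 / cs, each = n)
        if (outlier > 0) M <- pmin(M, 1)
      }
      Yv <- (M %*% Y) / .rowSums(M, n, n)
      rhs <- rbind(crossprod(U, Yv), crossprod(P, Yv) + l2 * affId)
      sol <- backsolve(lhsChol, forwardsolve(t(lhsChol), rhs))
      fit <- list(A = sol[ng + 1:4, , drop = FALSE],
                  W = Q2 %*% sol[lhsIdx, , drop = FALSE])
      fXnew <- P %*% fit$A + K %*% fit$W
      moved <- mean(rowSums((fXnew - fX)^2))
      fX <- fXnew
      D <- crossDist2(fX, Y)
      bend <- max(0, -sum(fit$W * (K %*% fit$W)))
      energies[it] <- sum(M * D) + temp * sum(M * log(pmax(M, 1e-300))) +
        l1 * bend + l2 * sum((fit$A - affId)^2)
      if (moved < 1e-8 * sizeScale) break  # alternation converged at this T
    }
    energyTrace[[length(energyTrace) + 1L]] <- energies
    if (temp <= tempFinal) break
    temp <- max(temp * annealRate, tempFinal * 0.999999)
  }
  warp <- new("TPSWarp", affine = fit$A, kernelWeights = fit$W,
              controlPoints = X, lambda = lambda0 * temp)

  map <- greedyAssign(M)
  fX <- tpsWarpPoints(warp, X)
  residual <- mean(rowSums((fX - Y[map, , drop = FALSE])^2))
  corr <- new("Correspondence", mapping = map,
              outlierMask = rep(FALSE, n), finalTemperature = temp,
              residual = residual, converged = converged)
  list(correspondence = corr, warp = warp, energyTrace = energyTrace)
}

# greedy conflict-free row argmax of a soft-assign matrix; processes
# candidate pairs by decreasing affinity, ties towards smaller subject
# (column) index, then smaller reference (row) index
greedyAssign <- function(M) {
  n <- nrow(M)
  iIdx <- rep(seq_len(n), times = ncol(M))
  jIdx <- rep(seq_len(ncol(M)), each = n)
  ord <- order(-as.vector(M), jIdx, iIdx)
  map <- integer(n)
  rowFree <- rep(TRUE, n)
  colFree <- rep(TRUE, ncol(M))
  assigned <- 0L
  for (k in ord) {
    i <- iIdx[k]; j <- jIdx[k]
    if (rowFree[i] && colFree[j]) {
      map[i] <- j
      rowFree[i] <- FALSE
      colFree[j] <- FALSE
      assigned <- assigned + 1L
      if (assigned == n) break
    }
  }
  map
}

#' Reorder subject vertices to match the reference ordering
#'
#' After matching, vertex `i` of the returned surface is the subject
#' vertex matched to reference vertex `i`; faces are re-indexed
#' consistently, so the mesh itself is unchanged up to vertex relabelling.
#'
#' @param subject a [Surface-class].
#' @param corr a [Correspondence-class] with no outliers.
#' @return the relabelled [Surface-class].
#' @export
reorderByCorrespondence <- function(subject, corr) {
  stopifnot(is(subject, "Surface"), is(corr, "Correspondence"))
  if (any(corr@outlierMask))
    stop("correspondence contains outliers; imputation is not enabled")
  map <- corr@mapping
  if (length(map) != nrow(subject@vertices))
    stop("correspondence length does not match the subject vertex count")
  inv <- integer(length(map))
  inv[map] <- seq_along(map)
  Surface(subject@vertices[map, , drop = FALSE],
          matrix(inv[subject@faces], ncol = 3),
          organ = subject@organ)
}

#' Propagate the reference mesh onto a subject via the converged warp
#'
#' Template propagation: evaluates the converged TPS warp at every
#' reference vertex and projects the result onto the subject surface
#' (closest point on its triangles). The returned surface carries the
#' reference topology with vertex i at the subject-surface location
#' corresponding to reference vertex i. Compared with hard vertex-to-
#' vertex reordering this avoids quantizing the correspondence to the
#' subject's vertex grid, which matters when the deformations of interest
#' are smaller than the vertex spacing.
#'
#' @param subject the subject [Surface-class] (same frame as the match).
#' @param reference the reference [Surface-class].
#' @param warp the converged [TPSWarp-class] from [matchTpsRpm()].
#' @return a [Surface-class] with the reference topology sampled on the
#'   subject surface.
#' @export
propagateCorrespondence <- function(subject, reference, warp) {
  stopifnot(is(subject, "Surface"), is(reference, "Surface"),
            is(warp, "TPSWarp"))
  fX <- tpsWarpPoints(warp, reference@vertices)
  proj <- cpp_closest_point_on_mesh(fX, subject@vertices, subject@faces)
  Surface(proj, reference@faces, organ = subject@organ)
}
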