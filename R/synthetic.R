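#' Subdivided icosahedron sphere mesh
#'
#' Closed genus-0 triangle mesh with 12, 42, 162, 642, ... vertices at
#' subdivision levels 0, 1, 2, 3, ...
#'
#' @param subdiv number of 4-to-1 subdivision passes.
#' @param radius sphere radius (mm).
#' @param organ organ tag for the result.
#' @return a [Surface-class].
#' @examples
#' nrow(vertices(icosphere(2)))  # 162
#' @export
icosphere <- function(subdiv = 2L, radius = 1, organ = "generic") {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  # icosahedron faces = triples of mutually adjacent vertices (pairwise at
  # the minimal distance), each wound so its normal points outward; for a
  # convex solid centred at the origin this is globally consistent
  d2 <- crossDist2(v, v)
  edge2 <- min(d2[d2 > 1e-9])
  adj <- d2 < edge2 * 1.01 & d2 > 1e-9
  f <- NULL
  for (a in 1:10) for (b in (a + 1):11) for (c_ in (b + 1):12)
    if (adj[a, b] && adj[b, c_] && adj[a, c_]) f <- rbind(f, c(a, b, c_))
  for (t in seq_len(nrow(f))) {
    tri <- v[f[t, ], ]
    n <- crossProd3(tri[2, ] - tri[1, ], tri[3, ] - tri[1, ])
    if (sum(n * colMeans(tri)) < 0) f[t, ] <- f[t, c(1, 3, 2)]
  }
  for (s in seq_len(subdiv)) {
    mid <- new.env()
    nv <- nrow(v)
    newV <- list()
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      got <- mid[[key]]
      if (!is.null(got)) return(got)
      p <- (v[i, ] + v[j, ]) / 2
      p <- p / sqrt(sum(p^2))
      newV[[length(newV) + 1L]] <<- p
      id <- nv + length(newV)
      mid[[key]] <- id
      id
    }
    newF <- matrix(0L, 4 * nrow(f), 3)
    for (t in seq_len(nrow(f))) {
      a <- f[t, 1]; b <- f[t, 2]; c_ <- f[t, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c_); ca <- midpoint(c_, a)
      newF[4 * t - 3, ] <- c(a, ab, ca)
      newF[4 * t - 2, ] <- c(b, bc, ab)
      newF[4 * t - 1, ] <- c(c_, ca, bc)
      newF[4 * t, ] <- c(ab, bc, ca)
    }
    v <- rbind(v, do.call(rbind, newV))
    f <- newF
  }
  Surface(v * radius, f, organ = organ)
}

# real low-order spherical-harmonic-style basis evaluated at unit
# directions; each column is normalized to unit RMS over the given
# vertices so coefficient magnitudes are comparable across orders
shBasis <- function(u, lmax = 3L) {
  x <- u[, 1]; y <- u[, 2]; z <- u[, 3]
  cols <- list()
  ord <- integer()
  if (lmax >= 1) { cols <- c(cols, list(x, y, z)); ord <- c(ord, 1L, 1L, 1L) }
  if (lmax >= 2) {
    cols <- c(cols, list(x * y, y * z, x * z, x^2 - y^2, 3 * z^2 - 1))
    ord <- c(ord, rep(2L, 5))
  }
  if (lmax >= 3) {
    cols <- c(cols, list(y * (3 * x^2 - y^2), x * y * z, y * (5 * z^2 - 1),
                         z * (5 * z^2 - 3), x * (5 * z^2 - 1),
                         z * (x^2 - y^2), x * (x^2 - 3 * y^2)))
    ord <- c(ord, rep(3L, 7))
  }
  B <- do.call(cbind, cols)
  rms <- sqrt(colMeans(B^2))
  B <- sweep(B, 2, pmax(rms, 1e-12), "/")
  attr(B, "order") <- ord
  B
}

# exit distance of the ray t*u (t > 0) from an ellipsoid |((p - c)/s)| = 1,
# optionally with a rotated principal frame (columns of rot = axes)
rayEllipsoidExit <- function(u, centre, semi, rot = NULL) {
  if (!is.null(rot)) {
    u <- u %*% rot           # express the ray in the ellipsoid frame
    centre <- as.numeric(centre %*% rot)
  }
  A <- rowSums(sweep(u^2, 2, semi^2, "/"))
  B <- -2 * rowSums(sweep(u, 2, centre / semi^2, "*"))
  C <- sum(centre^2 / semi^2) - 1
  disc <- B^2 - 4 * A * C
  out <- rep(-Inf, length(A))
  ok <- disc >= 0
  out[ok] <- (-B[ok] + sqrt(disc[ok])) / (2 * A[ok])
  out
}

# two fused ellipsoidal lobes, star-shaped about the origin: radius in
# direction u is the larger of the two ray-ellipsoid exit distances.
# The lobe centres are deliberately offset off every symmetry plane:
# real organs are chiral, and an (even approximately) mirror-symmetric
# fixture would make rigid registration and correspondence ambiguous up
# to a 180-degree flip.
liverRadius <- function(u, leftScale = 1, rightScale = 1, size = 80) {
  # left lobe: flat, wedge-like, tilted and displaced upward; right lobe:
  # rounder and lower. Distinct forms and orientations keep the pose
  # unambiguous even when the stage-linked scaling swaps which lobe is the
  # larger one (real livers stay chiral throughout disease progression).
  tiltL <- rotationMatrix(c(0, 1, 0.3), -35 * pi / 180)
  rl <- rayEllipsoidExit(u, centre = c(-0.35, 0.10, 0.22) * size,
                         semi = c(0.72, 0.46, 0.26) * size * leftScale,
                         rot = tiltL)
  rr <- rayEllipsoidExit(u, centre = c(0.32, -0.06, -0.08) * size,
                         semi = c(0.85, 0.70, 0.55) * size * rightScale)
  r <- pmax(rl, rr)
  # fixed chiral modulation (changes sign under every 180-degree rotation):
  # anchors rigid registration the way real anatomical landmarks do
  r * (1 + 0.14 * u[, 1] * u[, 2] + 0.10 * u[, 2] * u[, 3])
}

# bean-like spleen: a main ellipsoid fused with a smaller offset lobe,
# asymmetric for the same reason as the liver
spleenRadius <- function(u, volScale = 1, size = 40) {
  s <- volScale^(1 / 3)
  r1 <- rayEllipsoidExit(u, centre = c(0, 0, 0),
                         semi = c(1.10, 0.72, 0.50) * size * s)
  r2 <- rayEllipsoidExit(u, centre = c(0.45, 0.25, 0.20) * size * s,
                         semi = c(0.60, 0.55, 0.45) * size * s)
  pmax(r1, r2)
}

#' Generate a synthetic staged liver/spleen cohort
#'
#' Emulates the qualitative morphology of cirrhosis progression: the base
#' liver is two fused ellipsoidal lobes; per stage step the left lobe is
#' scaled by `(1 + stageEffect)` (hypertrophy), the right lobe by
#' `(1 - stageEffect)` (atrophy), and the spleen volume by
#' `(1 + stageEffect)` (splenomegaly). On top of the stage-linked
#' deformation each subject gets a smooth random radial deformation
#' (low-order spherical-harmonic displacement with per-coefficient
#' variance decaying with order), isotropic per-vertex jitter, a random
#' rigid misalignment common to both organs, and (optionally) a random
#' vertex relabelling that emulates the arbitrary vertex order of real
#' meshing, which is what makes correspondence recovery a genuine task.
#'
#' Cohorts are fully reproducible from the spec's seed; the caller's RNG
#' state is left untouched.
#'
#' @param spec a [CohortSpec-class].
#' @return a [SyntheticCohort-class].
#' @examples
#' coh <- generateCohort(CohortSpec(nPerStage = c(3, 2, 2), seed = 1))
#' cohortToLabelTable(coh)
#' @export
generateCohort <- function(spec) {
  stopifnot(is(spec, "CohortSpec"))
  oldSeed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(oldSeed)) assign(".Random.seed", oldSeed, envir = globalenv())
  })
  set.seed(spec@seed)

  base <- icosphereForCount(spec@vertices)
  u <- base@vertices / sqrt(rowSums(base@vertices^2))
  B <- shBasis(u)
  shOrd <- attr(B, "order")
  liverSize <- 80
  spleenSize <- 40
  spleenOffset <- c(120, 30, 0)

  stages <- rep(0:2, times = spec@nPerStage)
  nTotal <- length(stages)
  ids <- sprintf("S%03d", seq_len(nTotal))
  subjectList <- vector("list", nTotal)

  for (i in seq_len(nTotal)) {
    s <- stages[i]
    leftScale <- (1 + spec@stageEffect)^s
    rightScale <- (1 - spec@stageEffect)^s
    spleenVolScale <- (1 + spec@stageEffect)^s

    cL <- rnorm(ncol(B), sd = spec@deformSd / shOrd)
    cS <- rnorm(ncol(B), sd = spec@deformSd / shOrd)
    defL <- pmax(0.2, 1 + as.numeric(B %*% cL))
    defS <- pmax(0.2, 1 + as.numeric(B %*% cS))

    rLiv <- liverRadius(u, leftScale, rightScale, size = liverSize) * defL
    liverV <- u * rLiv
    rSpl <- spleenRadius(u, spleenVolScale, size = spleenSize) * defS
    spleenV <- sweep(u * rSpl, 2, spleenOffset, "+")

    if (spec@noiseSd > 0) {
      liverV <- liverV + matrix(rnorm(length(liverV),
                                      sd = spec@noiseSd * 2 * liverSize),
                                ncol = 3)
      spleenV <- spleenV + matrix(rnorm(length(spleenV),
                                        sd = spec@noiseSd * 2 * spleenSize),
                                  ncol = 3)
    }

    if (spec@maxRotation > 0 || spec@maxTranslation > 0) {
      ax <- rnorm(3)
      ang <- runif(1, 0, spec@maxRotation) * pi / 180
      R <- rotationMatrix(ax, ang)
      tr <- runif(3, -1, 1) * spec@maxTranslation * 2 * liverSize
      mis <- RigidTransform(R, tr)
    } else {
      mis <- RigidTransform()
    }
    liver <- applyTransform(Surface(liverV, base@faces, "liver"), mis)
    spleen <- applyTransform(Surface(spleenV, base@faces, "spleen"), mis)

    permL <- seq_len(nrow(liverV))
    permS <- seq_len(nrow(spleenV))
    if (spec@permuteVertices) {
      permL <- sample(nrow(liverV))
      permS <- sample(nrow(spleenV))
      liver <- permuteSurface(liver, permL)
      spleen <- permuteSurface(spleen, permS)
    }

    subjectList[[i]] <- new("SyntheticSubject", id = ids[i],
      liver = liver, spleen = spleen, stage = as.integer(s),
      groundTruth = list(leftScale = leftScale, rightScale = rightScale,
                         spleenVolScale = spleenVolScale,
                         shLiver = cL, shSpleen = cS,
                         misalignment = mis,
                         permLiver = permL, permSpleen = permS))
  }
  new("SyntheticCohort", subjects = subjectList, spec = spec)
}

# relabel vertices: new vertex k is old vertex perm[k]
permuteSurface <- function(surface, perm) {
  inv <- integer(length(perm))
  inv[perm] <- seq_along(perm)
  Surface(surface@vertices[perm, , drop = FALSE],
          matrix(inv[surface@faces], ncol = 3),
          organ = surface@organ)
}

# smallest icosphere at or above the requested count, decimated to exact
icosphereForCount <- function(n) {
  counts <- c(12L, 42L, 162L, 642L, 2562L, 10242L)
  lvl <- which(counts >= n)[1]
  if (is.na(lvl)) stop("requested vertex count too large")
  sph <- icosphere(lvl - 1L)
  if (counts[lvl] == n) sph else standardizeVertexCount(sph, n)
}

#' Label table for a cohort
#'
#' One row per subject with the binary diagnosis label (normal = 0,
#' abnormal = 1; every staged subject is abnormal) and the stage label
#' (0 = normal, 1 = early, 2 = middle/late).
#'
#' @param cohort a [SyntheticCohort-class] (or list of
#'   [SyntheticSubject-class]).
#' @return data.frame with columns `subjectId`, `binaryLabel`,
#'   `stageLabel`.
#' @export
cohortToLabelTable <- function(cohort) {
  subj <- if (is(cohort, "SyntheticCohort")) cohort@subjects else cohort
  if (!length(subj))
    return(data.frame(subjectId = character(), binaryLabel = integer(),
                      stageLabel = integer(), stringsAsFactors = FALSE))
  st <- vapply(subj, function(s) s@stage, integer(1))
  data.frame(subjectId = vapply(subj, function(s) s@id, character(1)),
             binaryLabel = as.integer(st > 0), stageLabel = st,
             stringsAsFactors = FALSE)
}
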