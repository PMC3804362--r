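#' @import methods
NULL

#' Segmented organ label volume
#'
#' A 3-D binary occupancy grid for one segmented organ, together with the
#' voxel spacing and the physical coordinate of grid index (1,1,1)
#' (0-based index (0,0,0)). Coordinates are physical millimetres,
#' right-handed, with half-open voxel extents.
#'
#' @slot grid 3-D array containing only 0 and 1.
#' @slot spacing numeric(3), per-axis voxel size in mm, strictly positive.
#' @slot origin numeric(3), physical position of the first voxel centre.
#' @slot organ single string tag, e.g. `"liver"` or `"spleen"`.
#'
#' @seealso [LabelVolume()], [extractSurface()]
#' @export
setClass("LabelVolume",
  representation(grid = "array", spacing = "numeric", origin = "numeric",
                 organ = "character"))

setValidity("LabelVolume", function(object) {
  msg <- character()
  if (length(dim(object@grid)) != 3L)
    msg <- c(msg, "grid must be a 3-D array")
  if (!all(object@grid %in% c(0, 1)))
    msg <- c(msg, "grid must contain only 0 and 1")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    msg <- c(msg, "spacing must be three strictly positive values")
  if (length(object@origin) != 3L)
    msg <- c(msg, "origin must have length 3")
  if (length(object@organ) != 1L || is.na(object@organ) || !nzchar(object@organ))
    msg <- c(msg, "organ must be a single non-empty string")
  if (length(msg)) msg else TRUE
})

#' Triangulated organ surface
#'
#' A closed, consistently oriented triangle mesh for one organ of one
#' subject, in physical coordinates (mm). Validity requires every directed
#' edge to appear exactly once (i.e. the mesh is closed, manifold and
#' orientable).
#'
#' @slot vertices numeric matrix, one 3-D point per row.
#' @slot faces integer matrix, one triple of 1-based vertex indices per row.
#' @slot organ single string tag, e.g. `"liver"` or `"spleen"`.
#'
#' @seealso [Surface()], [meshArea()], [meshVolume()], [eulerCharacteristic()]
#' @export
setClass("Surface",
  representation(vertices = "matrix", faces = "matrix", organ = "character"))

setValidity("Surface", function(object) {
  msg <- character()
  v <- object@vertices; f <- object@faces
  if (!is.numeric(v) || ncol(v) != 3L) msg <- c(msg, "vertices must be an n x 3 numeric matrix")
  if (!is.numeric(f) || ncol(f) != 3L) msg <- c(msg, "faces must be an m x 3 index matrix")
  if (length(object@organ) != 1L || !nzchar(object@organ))
    msg <- c(msg, "organ must be a single non-empty string")
  if (!length(msg)) {
    if (nrow(f) > 0 && (min(f) < 1 || max(f) > nrow(v)))
      msg <- c(msg, "face indices out of range")
    else if (nrow(f) > 0) {
      # closed orientable manifold: each directed edge used exactly once
      he <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
      key <- (he[, 1] - 1) * as.double(nrow(v)) + he[, 2]
      if (anyDuplicated(key))
        msg <- c(msg, "mesh is not consistently oriented (repeated directed edge)")
      rkey <- (he[, 2] - 1) * as.double(nrow(v)) + he[, 1]
      if (!all(key %in% rkey))
        msg <- c(msg, "mesh is not closed (unpaired edge)")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Rigid-body transform
#'
#' A rotation (proper orthonormal, det = +1) plus a translation in mm,
#' acting on points as `R v + t`. Reflections are excluded by the validity
#' check.
#'
#' @slot rotation 3 x 3 rotation matrix.
#' @slot translation numeric(3) in mm.
#'
#' @seealso [registerRigid()], [applyTransform()]
#' @export
setClass("RigidTransform",
  representation(rotation = "matrix", translation = "numeric"))

setValidity("RigidTransform", function(object) {
  R <- object@rotation
  msg <- character()
  if (!all(dim(R) == c(3L, 3L))) msg <- c(msg, "rotation must be 3 x 3")
  else {
    if (max(abs(crossprod(R) - diag(3))) > 1e-8)
      msg <- c(msg, "rotation is not orthonormal within 1e-8")
    if (abs(det(R) - 1) > 1e-6)
      msg <- c(msg, "rotation must have det = +1 (no reflection)")
  }
  if (length(object@translation) != 3L) msg <- c(msg, "translation must have length 3")
  if (length(msg)) msg else TRUE
})

#' Thin-plate-spline warp
#'
#' A 3-D TPS map `f(p) = [1, p] A + sum_i w_i phi(|p - c_i|)` with radial
#' kernel `phi(r) = r` and control points `c_i`. The kernel weights satisfy
#' the TPS side conditions (orthogonality to the affine basis).
#'
#' @slot affine 4 x 3 matrix; first row the translation, rows 2-4 the linear
#'   part (points map as `c(1, p) %*% affine`).
#' @slot kernelWeights n x 3 matrix of per-control-point weights.
#' @slot controlPoints n x 3 matrix.
#' @slot lambda non-negative smoothness weight used at fit time.
#'
#' @seealso [fitTPS()], [tpsWarpPoints()], [matchTpsRpm()]
#' @export
setClass("TPSWarp",
  representation(affine = "matrix", kernelWeights = "matrix",
                 controlPoints = "matrix", lambda = "numeric"))

setValidity("TPSWarp", function(object) {
  msg <- character()
  if (!all(dim(object@affine) == c(4L, 3L))) msg <- c(msg, "affine must be 4 x 3")
  if (ncol(object@kernelWeights) != 3L) msg <- c(msg, "kernelWeights must be n x 3")
  if (ncol(object@controlPoints) != 3L) msg <- c(msg, "controlPoints must be n x 3")
  if (nrow(object@kernelWeights) != nrow(object@controlPoints))
    msg <- c(msg, "kernelWeights and controlPoints must have matching rows")
  if (length(object@lambda) != 1L || object@lambda < 0)
    msg <- c(msg, "lambda must be a single non-negative value")
  if (!length(msg) && nrow(object@controlPoints) > 0) {
    P <- cbind(1, object@controlPoints)
    side <- crossprod(P, object@kernelWeights)
    scale <- max(1, max(abs(object@kernelWeights)) * max(abs(P)) *
                   nrow(object@controlPoints))
    if (max(abs(side)) > 1e-6 * scale)
      msg <- c(msg, "kernel weights violate the TPS side conditions")
  }
  if (length(msg)) msg else TRUE
})

#' Vertex correspondence between a subject surface and the reference
#'
#' `mapping[i]` is the subject vertex index matched to reference vertex i;
#' non-outlier entries form a partial permutation (no subject vertex used
#' twice).
#'
#' @slot mapping integer vector, one subject index per reference vertex.
#' @slot outlierMask logical vector flagging unmatched reference vertices.
#' @slot finalTemperature annealing temperature at convergence.
#' @slot residual mean squared distance between warped reference points and
#'   their matched subject points.
#' @slot converged logical; `FALSE` when the annealing loop hit its
#'   iteration cap and returned the best iterate.
#'
#' @seealso [matchTpsRpm()], [reorderByCorrespondence()]
#' @export
setClass("Correspondence",
  representation(mapping = "integer", outlierMask = "logical",
                 finalTemperature = "numeric", residual = "numeric",
                 converged = "logical"))

setValidity("Correspondence", function(object) {
  msg <- character()
  if (length(object@outlierMask) != length(object@mapping))
    msg <- c(msg, "outlierMask length must match mapping length")
  inl <- object@mapping[!object@outlierMask]
  if (anyDuplicated(inl))
    msg <- c(msg, "a subject vertex is matched to two reference vertices")
  if (length(msg)) msg else TRUE
})

#' Flattened corresponded shape vector
#'
#' The coordinates of the corresponded vertices flattened as
#' `[x1, y1, z1, x2, y2, z2, ...]` (mm). The joint layout concatenates the
#' liver block before the spleen block, giving twice the single-organ
#' length (3000 vs 6000 at the default 1000 vertices).
#'
#' @slot values numeric coordinate vector.
#' @slot layout `"liver"`, `"spleen"`, or `"joint"`.
#' @slot subjectId subject identifier.
#'
#' @seealso [assembleShapeVector()], [fitSSM()]
#' @export
setClass("ShapeVector",
  representation(values = "numeric", layout = "character",
                 subjectId = "character"))

setValidity("ShapeVector", function(object) {
  msg <- character()
  if (!object@layout %in% c("liver", "spleen", "joint"))
    msg <- c(msg, "layout must be 'liver', 'spleen' or 'joint'")
  mult <- if (identical(object@layout, "joint")) 6L else 3L
  if (length(object@values) %% mult != 0)
    msg <- c(msg, sprintf("values length must be a multiple of %d for layout '%s'",
                          mult, object@layout))
  if (length(msg)) msg else TRUE
})

#' Statistical shape model
#'
#' A point distribution model: mean shape plus orthonormal eigenshapes of
#' the training-shape covariance (1/N normalization), with non-increasing
#' eigenvalues. At most N - 1 modes are retained; modes below 1e-10 of the
#' leading eigenvalue are discarded as numerical noise. Eigenshape signs
#' are fixed so each mode's largest-magnitude entry is positive.
#'
#' @slot mean numeric mean shape vector.
#' @slot eigenshapes D x k matrix of orthonormal variation vectors.
#' @slot eigenvalues numeric(k), non-negative, non-increasing.
#' @slot nTrain number of training shapes.
#' @slot layout shape-vector layout, `"liver"`, `"spleen"` or `"joint"`.
#' @slot referenceId id of the reference subject used for normalization.
#' @slot vertexCount standardized vertex count per organ.
#'
#' @seealso [fitSSM()], [projectShape()], [reconstructShape()], [avcr()]
#' @export
setClass("SSMModel",
  representation(mean = "numeric", eigenshapes = "matrix",
                 eigenvalues = "numeric", nTrain = "integer",
                 layout = "character", referenceId = "character",
                 vertexCount = "integer"))

setValidity("SSMModel", function(object) {
  msg <- character()
  V <- object@eigenshapes
  ev <- object@eigenvalues
  if (nrow(V) != length(object@mean))
    msg <- c(msg, "eigenshapes rows must match mean length")
  if (ncol(V) != length(ev))
    msg <- c(msg, "one eigenvalue per eigenshape required")
  if (length(ev)) {
    if (any(ev < 0)) msg <- c(msg, "eigenvalues must be non-negative")
    if (is.unsorted(rev(ev))) msg <- c(msg, "eigenvalues must be non-increasing")
    if (length(ev) > object@nTrain - 1L)
      msg <- c(msg, "at most N - 1 modes may be retained")
    gram <- crossprod(V)
    if (max(abs(gram - diag(ncol(V)))) > 1e-8)
      msg <- c(msg, "eigenshapes are not orthonormal within 1e-8")
  }
  if (length(msg)) msg else TRUE
})

#' Per-subject mode coefficients
#'
#' The projection `b_j = v_j' (x - m)` of a centered shape vector onto the
#' leading eigenshapes: the morphometric feature vector used for diagnosis.
#'
#' @slot values numeric per-mode weights.
#' @slot modelId identifier of the shape model they refer to.
#' @slot subjectId subject identifier.
#'
#' @seealso [projectShape()], [reconstructShape()]
#' @export
setClass("ModeCoefficients",
  representation(values = "numeric", modelId = "character",
                 subjectId = "character"))

#' Result of combined mode selection
#'
#' Modes picked by accumulated variance contribution (`avcrSet`), by
#' label correlation (`corrSet`), and their product set (`selected`,
#' ordered by correlation, largest first). `fallback` records whether the
#' empty-intersection fallback (best-correlated mode within the AVCR set)
#' was taken.
#'
#' @slot avcrSet integer mode indices from the variance criterion.
#' @slot corrSet integer mode indices from the correlation criterion.
#' @slot selected integer product set, ordered by correlation descending.
#' @slot correlations numeric per-mode uncentered label correlations.
#' @slot fallback logical.
#'
#' @seealso [combineSelections()], [selectByAvcr()], [selectByCorrelation()]
#' @export
setClass("ModeSelection",
  representation(avcrSet = "integer", corrSet = "integer",
                 selected = "integer", correlations = "numeric",
                 fallback = "logical"))

setValidity("ModeSelection", function(object) {
  msg <- character()
  if (any(object@correlations < -1e-12 | object@correlations > 1 + 1e-12))
    msg <- c(msg, "correlations must lie in [0, 1]")
  if (!object@fallback && !all(object@selected %in%
        intersect(object@avcrSet, object@corrSet)))
    msg <- c(msg, "selected must be a subset of the intersection")
  if (length(msg)) msg else TRUE
})

#' Trained epsilon-SVR stage-mapping model
#'
#' A Gaussian-kernel support vector regression machine in dual form:
#' `f(b) = sum_i beta_i k(b_i, b) + a` with `beta_i = alpha_i - alpha_i*`,
#' `sum_i beta_i = 0` and `|beta_i| <= C`. Feature standardization
#' parameters learned on the training fold are stored for test-time reuse.
#'
#' @slot dualCoeffs numeric(N) values `alpha_i - alpha_i*`.
#' @slot bias intercept `a`.
#' @slot gamma Gaussian kernel width, `k(u, v) = exp(-gamma |u - v|^2)`.
#' @slot cost box constraint C.
#' @slot epsilon tube half-width.
#' @slot supportInputs N x d matrix of (standardized) training features.
#' @slot trainTargets numeric(N) stage labels of the training samples.
#' @slot featureCenter,featureScale standardization parameters.
#'
#' @seealso [trainSVR()], [predictStage()]
#' @export
setClass("SVRModel",
  representation(dualCoeffs = "numeric", bias = "numeric", gamma = "numeric",
                 cost = "numeric", epsilon = "numeric",
                 supportInputs = "matrix", trainTargets = "numeric",
                 featureCenter = "numeric", featureScale = "numeric"))

setValidity("SVRModel", function(object) {
  msg <- character()
  n <- nrow(object@supportInputs)
  if (length(object@dualCoeffs) != n)
    msg <- c(msg, "one dual coefficient per training sample required")
  if (length(object@trainTargets) != n)
    msg <- c(msg, "one target per training sample required")
  if (abs(sum(object@dualCoeffs)) > 1e-6 * max(1, sum(abs(object@dualCoeffs))))
    msg <- c(msg, "dual coefficients must sum to 0 (equality constraint)")
  if (any(abs(object@dualCoeffs) > object@cost + 1e-8))
    msg <- c(msg, "dual coefficients must lie in [-C, C]")
  if (length(msg)) msg else TRUE
})

#' Synthetic cohort specification
#'
#' Study conditions for the synthetic liver/spleen cohort generator:
#' per-stage subject counts, the magnitude of the stage-linked deformation
#' (left-lobe hypertrophy, right-lobe atrophy, spleen enlargement), smooth
#' per-subject shape variation, vertex jitter, and rigid misalignment.
#'
#' @slot nPerStage integer(3) subject counts for stages 0, 1, 2.
#' @slot stageEffect per-stage-step deformation magnitude (dimensionless).
#' @slot deformSd magnitude of smooth per-subject spherical-harmonic
#'   deformation (fraction of radius, per harmonic order).
#' @slot noiseSd per-vertex isotropic jitter, fraction of organ size.
#' @slot maxRotation max random misalignment rotation, degrees.
#' @slot maxTranslation max random misalignment translation, fraction of
#'   organ size.
#' @slot vertices standardized vertex count per organ surface.
#' @slot permuteVertices randomly relabel vertices per subject (emulates
#'   arbitrary meshing order; forces genuine correspondence recovery).
#' @slot seed integer RNG seed.
#'
#' @seealso [CohortSpec()], [generateCohort()]
#' @export
setClass("CohortSpec",
  representation(nPerStage = "integer", stageEffect = "numeric",
                 deformSd = "numeric", noiseSd = "numeric",
                 maxRotation = "numeric", maxTranslation = "numeric",
                 vertices = "integer", permuteVertices = "logical",
                 seed = "integer"))

setValidity("CohortSpec", function(object) {
  msg <- character()
  if (length(object@nPerStage) != 3L || any(object@nPerStage < 0))
    msg <- c(msg, "nPerStage must be three non-negative counts")
  if (sum(object@nPerStage) < 4L)
    msg <- c(msg, "total cohort size must be at least 4")
  for (s in c("stageEffect", "deformSd", "noiseSd", "maxRotation", "maxTranslation"))
    if (slot(object, s) < 0) msg <- c(msg, paste(s, "must be non-negative"))
  if (object@vertices < 12L) msg <- c(msg, "vertices must be at least 12")
  if (length(msg)) msg else TRUE
})

#' One synthetic subject: paired liver and spleen surfaces plus ground truth
#'
#' @slot id subject identifier.
#' @slot liver,spleen [Surface-class] objects.
#' @slot stage integer stage label in 0:2.
#' @slot groundTruth list of the latent parameters used (lobe scales,
#'   harmonic coefficients, misalignment transform, vertex permutations).
#'
#' @seealso [generateCohort()]
#' @export
setClass("SyntheticSubject",
  representation(id = "character", liver = "Surface", spleen = "Surface",
                 stage = "integer", groundTruth = "list"))

#' A generated cohort: subjects plus the specification that produced them
#'
#' @slot subjects list of [SyntheticSubject-class] objects.
#' @slot spec the [CohortSpec-class] used.
#'
#' @seealso [generateCohort()], [cohortToLabelTable()]
#' @export
setClass("SyntheticCohort",
  representation(subjects = "list", spec = "CohortSpec"))

#' Leave-one-out evaluation report
#'
#' @slot perClassAccuracy named numeric: NN accuracy among truly normal and
#'   truly abnormal subjects.
#' @slot perSubject data.frame with one row per subject: truth, NN label,
#'   SVR score, hard stage.
#' @slot perStageStats data.frame of mean and variance of LOO SVR scores
#'   per true stage.
#' @slot config the pipeline configuration list used.
#' @slot configHash hash of the configuration.
#' @slot seed cohort seed, if known.
#'
#' @seealso [runLOO()], [compareMethods()]
#' @export
setClass("EvaluationReport",
  representation(perClassAccuracy = "numeric", perSubject = "data.frame",
                 perStageStats = "data.frame", config = "list",
                 configHash = "character", seed = "integer"))

setValidity("EvaluationReport", function(object) {
  msg <- character()
  acc <- object@perClassAccuracy
  if (length(acc) && (any(acc < 0) || any(acc > 1)))
    msg <- c(msg, "accuracies must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})
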