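#' Construct a LabelVolume
#'
#' @param grid 3-D array of 0/1 occupancy (logical arrays are coerced).
#' @param spacing numeric(3) voxel size in mm.
#' @param origin numeric(3) physical position of the first voxel centre.
#' @param organ organ tag.
#' @return A [LabelVolume-class].
#' @examples
#' g <- array(0L, c(8, 8, 8)); g[3:6, 3:6, 3:6] <- 1L
#' LabelVolume(g, organ = "liver")
#' @export
LabelVolume <- function(grid, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                        organ = "liver") {
  if (is.logical(grid)) grid <- array(as.integer(grid), dim(grid))
  new("LabelVolume", grid = grid, spacing = as.numeric(spacing),
      origin = as.numeric(origin), organ = organ)
}

#' Construct a Surface
#'
#' @param vertices n x 3 numeric matrix of points (mm).
#' @param faces m x 3 matrix of 1-based vertex index triples.
#' @param organ organ tag.
#' @return A [Surface-class].
#' @export
Surface <- function(vertices, faces, organ = "generic") {
  storage.mode(vertices) <- "double"
  storage.mode(faces) <- "integer"
  dimnames(vertices) <- NULL
  dimnames(faces) <- NULL
  new("Surface", vertices = vertices, faces = faces, organ = organ)
}

#' Construct a RigidTransform
#'
#' @param rotation 3 x 3 rotation matrix (det +1).
#' @param translation numeric(3) in mm.
#' @return A [RigidTransform-class].
#' @export
RigidTransform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  new("RigidTransform", rotation = rotation,
      translation = as.numeric(translation))
}

#' Construct a ShapeVector
#'
#' @param values flat coordinate vector `[x1, y1, z1, ...]` (mm).
#' @param layout `"liver"`, `"spleen"` or `"joint"`.
#' @param subjectId subject identifier.
#' @return A [ShapeVector-class].
#' @export
ShapeVector <- function(values, layout, subjectId = NA_character_) {
  new("ShapeVector", values = as.numeric(values), layout = layout,
      subjectId = subjectId)
}

#' Construct a CohortSpec
#'
#' Defaults mirror the study conditions of the staged clinical cohort the
#' generator emulates: 25 normal, 8 early-stage and 2 middle/late-stage
#' subjects, stage-linked deformation of 0.15 per stage step, 2% vertex
#' jitter, and rigid misalignment up to 20 degrees and 10% of organ size.
#'
#' @param nPerStage integer(3) subject counts for stages 0, 1, 2.
#' @param stageEffect per-step deformation magnitude.
#' @param deformSd smooth per-subject deformation magnitude.
#' @param noiseSd per-vertex jitter as a fraction of organ size.
#' @param maxRotation,maxTranslation rigid misalignment bounds
#'   (degrees; fraction of organ size).
#' @param vertices standardized vertex count per organ.
#' @param permuteVertices randomly relabel vertices per subject.
#' @param seed RNG seed.
#' @return A [CohortSpec-class].
#' @examples
#' CohortSpec(seed = 1)
#' @export
CohortSpec <- function(nPerStage = c(25L, 8L, 2L), stageEffect = 0.15,
                       deformSd = 0.05, noiseSd = 0.02, maxRotation = 20,
                       maxTranslation = 0.10, vertices = 162L,
                       permuteVertices = TRUE, seed = 0L) {
  new("CohortSpec", nPerStage = as.integer(nPerStage),
      stageEffect = stageEffect, deformSd = deformSd, noiseSd = noiseSd,
      maxRotation = maxRotation, maxTranslation = maxTranslation,
      vertices = as.integer(vertices), permuteVertices = permuteVertices,
      seed = as.integer(seed))
}

setMethod("show", "LabelVolume", function(object) {
  d <- dim(object@grid)
  cat(sprintf("LabelVolume (%s): %d x %d x %d voxels, spacing %s mm, %d foreground\n",
              object@organ, d[1], d[2], d[3],
              paste(signif(object@spacing, 3), collapse = " x "),
              sum(object@grid)))
})

setMethod("show", "Surface", function(object) {
  cat(sprintf("Surface (%s): %d vertices, %d faces\n",
              object@organ, nrow(object@vertices), nrow(object@faces)))
})

setMethod("show", "RigidTransform", function(object) {
  ang <- rotationAngle(object@rotation)
  cat(sprintf("RigidTransform: rotation %.2f deg, translation (%s) mm\n",
              ang * 180 / pi,
              paste(sprintf("%.2f", object@translation), collapse = ", ")))
})

setMethod("show", "Correspondence", function(object) {
  cat(sprintf("Correspondence: %d vertices, %d outliers, residual %.4g, T_final %.4g%s\n",
              length(object@mapping), sum(object@outlierMask),
              object@residual, object@finalTemperature,
              if (isTRUE(object@converged)) "" else " (not converged)"))
})

setMethod("show", "ShapeVector", function(object) {
  cat(sprintf("ShapeVector [%s] length %d (subject %s)\n",
              object@layout, length(object@values), object@subjectId))
})

setMethod("show", "SSMModel", function(object) {
  k <- length(object@eigenvalues)
  cat(sprintf("SSMModel [%s]: D = %d, N = %d, %d modes (reference %s)\n",
              object@layout, length(object@mean), object@nTrain, k,
              object@referenceId))
  if (k) {
    kk <- min(k, 5L)
    cat("  leading eigenvalues:",
        paste(signif(object@eigenvalues[seq_len(kk)], 4), collapse = ", "),
        if (k > kk) "..." else "", "\n")
  }
})

setMethod("show", "ModeSelection", function(object) {
  cat(sprintf("ModeSelection: AVCR set {%s}, correlation set {%s} -> selected {%s}%s\n",
              paste(object@avcrSet, collapse = ","),
              paste(object@corrSet, collapse = ","),
              paste(object@selected, collapse = ","),
              if (object@fallback) " [fallback]" else ""))
})

setMethod("show", "SVRModel", function(object) {
  cat(sprintf("SVRModel: %d training samples, %d support vectors, C = %g, epsilon = %g, gamma = %g\n",
              nrow(object@supportInputs), sum(object@dualCoeffs != 0),
              object@cost, object@epsilon, object@gamma))
})

setMethod("show", "CohortSpec", function(object) {
  cat(sprintf("CohortSpec: %s subjects per stage, effect %g, deform %g, noise %g, seed %d\n",
              paste(object@nPerStage, collapse = "/"), object@stageEffect,
              object@deformSd, object@noiseSd, object@seed))
})

setMethod("show", "SyntheticSubject", function(object) {
  cat(sprintf("SyntheticSubject %s (stage %d): liver %d vertices, spleen %d vertices\n",
              object@id, object@stage, nrow(object@liver@vertices),
              nrow(object@spleen@vertices)))
})

setMethod("show", "SyntheticCohort", function(object) {
  st <- vapply(object@subjects, function(s) s@stage, integer(1))
  cat(sprintf("SyntheticCohort: %d subjects (stages: %s)\n",
              length(object@subjects),
              paste(table(factor(st, levels = 0:2)), collapse = "/")))
})

setMethod("show", "EvaluationReport", function(object) {
  cat("EvaluationReport\n")
  cat(sprintf("  NN accuracy: normal %.1f%%, abnormal %.1f%%\n",
              100 * object@perClassAccuracy[["normal"]],
              100 * object@perClassAccuracy[["abnormal"]]))
  if (nrow(object@perStageStats)) {
    cat("  SVR scores by stage:\n")
    print(object@perStageStats, row.names = FALSE)
  }
})

#' Accessors for the core model objects
#'
#' Small read-only accessors so user code never touches slots directly.
#'
#' @param object the object to query.
#' @return the requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
vertices <- function(object) object@vertices

#' @rdname accessors
#' @export
faces <- function(object) object@faces

#' @rdname accessors
#' @export
organ <- function(object) object@organ

#' @rdname accessors
#' @export
eigenvalues <- function(object) object@eigenvalues

#' @rdname accessors
#' @export
eigenshapes <- function(object) object@eigenshapes

#' @rdname accessors
#' @export
meanShape <- function(object) object@mean

#' @rdname accessors
#' @export
nModes <- function(object) length(object@eigenvalues)

#' @rdname accessors
#' @export
coefValues <- function(object) object@values

#' @rdname accessors
#' @export
selectedModes <- function(object) object@selected

#' @rdname accessors
#' @export
mapping <- function(object) object@mapping

#' @rdname accessors
#' @export
subjects <- function(object) object@subjects

#' @rdname accessors
#' @export
perClassAccuracy <- function(object) object@perClassAccuracy

#' @rdname accessors
#' @export
perSubject <- function(object) object@perSubject

#' @rdname accessors
#' @export
perStageStats <- function(object) object@perStageStats
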