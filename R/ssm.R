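#' Assemble a flat shape vector from corresponded surfaces
#'
#' Flattens the corresponded vertex coordinates as
#' `[x1, y1, z1, x2, y2, z2, ...]`. With both a liver and a spleen surface
#' the joint layout concatenates the liver block before the spleen block,
#' doubling the length (3000 vs 6000 at 1000 vertices).
#'
#' @param liver a corresponded [Surface-class] with organ `"liver"` (or a
#'   single surface of any organ for a single-organ vector).
#' @param spleen optionally, the corresponded spleen [Surface-class]; when
#'   given, a joint vector is produced.
#' @param subjectId subject identifier carried on the result.
#' @return a [ShapeVector-class].
#' @export
assembleShapeVector <- function(liver, spleen = NULL,
                                subjectId = NA_character_) {
  stopifnot(is(liver, "Surface"))
  if (is.null(spleen)) {
    layout <- if (liver@organ %in% c("liver", "spleen")) liver@organ else "liver"
    return(ShapeVector(as.vector(t(liver@vertices)), layout, subjectId))
  }
  stopifnot(is(spleen, "Surface"))
  if (!identical(liver@organ, "liver") || !identical(spleen@organ, "spleen"))
    stop("joint layout requires exactly one liver and one spleen surface")
  if (nrow(liver@vertices) != nrow(spleen@vertices))
    stop("liver and spleen must share the standardized vertex count")
  ShapeVector(c(as.vector(t(liver@vertices)), as.vector(t(spleen@vertices))),
              "joint", subjectId)
}

#' Rebuild surface vertex matrices from a shape vector
#'
#' Inverse of [assembleShapeVector()] at the coordinate level.
#'
#' @param x a [ShapeVector-class].
#' @return a list of one (`liver` or `spleen`) or two vertex matrices.
#' @export
shapeVectorToVertices <- function(x) {
  stopifnot(is(x, "ShapeVector"))
  if (identical(x@layout, "joint")) {
    half <- length(x@values) / 2
    list(liver = matrix(x@values[seq_len(half)], ncol = 3, byrow = TRUE),
         spleen = matrix(x@values[-seq_len(half)], ncol = 3, byrow = TRUE))
  } else {
    setNames(list(matrix(x@values, ncol = 3, byrow = TRUE)), x@layout)
  }
}

#' Fit a statistical shape model
#'
#' Point distribution model over corresponded shape vectors: mean
#' `m = (1/N) sum x_i` and eigen-decomposition of the covariance
#' `S = (1/N) sum (x_i - m)(x_i - m)^T`, computed through the thin SVD of
#' the centered data matrix so the D x D covariance is never materialized.
#' At most N - 1 modes are kept; modes with eigenvalue below 1e-10 of the
#' leading one are discarded as numerical noise. Each eigenshape's
#' largest-magnitude entry is made positive, so repeated fits are
#' bit-identical.
#'
#' Note the 1/N (not 1/(N-1)) covariance normalization; it affects the
#' eigenvalue scale only.
#'
#' @param training list of [ShapeVector-class] objects (same layout and
#'   length), or a D x N numeric matrix with one shape per column.
#' @param layout required when `training` is a plain matrix.
#' @param referenceId id of the normalization reference, recorded in the
#'   model for reproducibility.
#' @return an [SSMModel-class].
#' @export
fitSSM <- function(training, layout = NULL, referenceId = NA_character_) {
  if (is.list(training)) {
    stopifnot(all(vapply(training, is, logical(1), "ShapeVector")))
    layouts <- unique(vapply(training, function(s) s@layout, character(1)))
    if (length(layouts) != 1) stop("all shape vectors must share one layout")
    layout <- layouts
    lens <- vapply(training, function(s) length(s@values), integer(1))
    if (length(unique(lens)) != 1) stop("inconsistent shape-vector lengths")
    X <- vapply(training, function(s) s@values, numeric(lens[1]))
  } else {
    X <- as.matrix(training)
    if (is.null(layout)) stop("layout must be given for matrix input")
  }
  N <- ncol(X)
  if (N < 2) stop("at least two training shapes are required")
  m <- rowMeans(X)
  Xc <- X - m
  sv <- svd(Xc, nu = min(N, nrow(Xc)), nv = 0)
  ev <- sv$d^2 / N
  keep <- which(ev > 1e-10 * max(ev[1], .Machine$double.xmin))
  keep <- head(keep, N - 1L)
  V <- sv$u[, keep, drop = FALSE]
  ev <- ev[keep]
  # deterministic sign: largest-magnitude entry of each mode positive
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  vc <- nrow(Xc) / if (identical(layout, "joint")) 6L else 3L
  new("SSMModel", mean = m, eigenshapes = V, eigenvalues = ev,
      nTrain = as.integer(N), layout = layout,
      referenceId = as.character(referenceId), vertexCount = as.integer(vc))
}

#' Project a shape onto the model's leading modes
#'
#' `b_j = v_j^T (x - m)` for `j = 1..nModes`: the mode coefficients used
#' as morphometric features.
#'
#' @param model an [SSMModel-class].
#' @param x a [ShapeVector-class] (layout must match) or a bare numeric
#'   vector of matching length.
#' @param nModes number of leading modes; defaults to all stored modes.
#' @return a [ModeCoefficients-class].
#' @export
projectShape <- function(model, x, nModes = NULL) {
  stopifnot(is(model, "SSMModel"))
  subjectId <- NA_character_
  if (is(x, "ShapeVector")) {
    if (!identical(x@layout, model@layout))
      stop(sprintf("layout mismatch: shape is '%s', model is '%s'",
                   x@layout, model@layout))
    subjectId <- x@subjectId
    x <- x@values
  }
  if (length(x) != length(model@mean))
    stop("shape-vector length does not match the model")
  k <- if (is.null(nModes)) nModes(model) else as.integer(nModes)
  if (k < 1 || k > nModes(model))
    stop("nModes must lie between 1 and the number of stored modes")
  b <- as.numeric(crossprod(model@eigenshapes[, seq_len(k), drop = FALSE],
                            x - model@mean))
  new("ModeCoefficients", values = b, modelId = model@layout,
      subjectId = subjectId)
}

#' Reconstruct a shape from mode coefficients
#'
#' `x = m + sum_j b_j v_j`.
#'
#' @param model an [SSMModel-class].
#' @param b a [ModeCoefficients-class] or bare numeric coefficient vector
#'   (length at most the number of stored modes).
#' @return a [ShapeVector-class].
#' @export
reconstructShape <- function(model, b) {
  stopifnot(is(model, "SSMModel"))
  if (is(b, "ModeCoefficients")) b <- b@values
  k <- length(b)
  if (k > nModes(model))
    stop("more coefficients than stored modes")
  x <- model@mean
  if (k > 0)
    x <- x + as.numeric(model@eigenshapes[, seq_len(k), drop = FALSE] %*% b)
  ShapeVector(x, model@layout)
}

#' Accumulated variance contribution rate
#'
#' Fraction of total shape variance explained by the first `k` modes:
#' `sum_{j<=k} lambda_j / sum_j lambda_j`.
#'
#' @param model an [SSMModel-class].
#' @param k number of leading modes, `1 <= k <=` stored modes.
#' @return a fraction in (0, 1].
#' @export
avcr <- function(model, k) {
  stopifnot(is(model, "SSMModel"))
  ev <- model@eigenvalues
  if (!length(ev) || sum(ev) <= 0)
    stop("model has no variance (all eigenvalues zero)")
  k <- as.integer(k)
  if (k < 1 || k > length(ev))
    stop("k must lie between 1 and the number of stored modes")
  sum(ev[seq_len(k)]) / sum(ev)
}

#' Project every training/test shape onto a model
#'
#' Convenience wrapper returning the subjects x modes coefficient matrix
#' used by mode selection and the classifiers.
#'
#' @param model an [SSMModel-class].
#' @param shapes list of [ShapeVector-class] objects.
#' @param nModes number of leading modes (default all).
#' @return numeric matrix, one row per shape, one column per mode.
#' @export
coefficientMatrix <- function(model, shapes, nModes = NULL) {
  k <- if (is.null(nModes)) nModes(model) else as.integer(nModes)
  t(vapply(shapes, function(s) projectShape(model, s, k)@values, numeric(k)))
}
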