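#' Uncentered correlation between a mode's coefficients and the labels
#'
#' The absolute uncentered cosine
#' `|r^T b| / sqrt((r^T r)(b^T b))` between the per-subject coefficient
#' vector of one mode and the label vector. Deliberately NOT the Pearson
#' correlation: no mean-centering is applied. A centered variant is
#' available behind the `centered` flag but is off by default.
#'
#' @param coeffs per-subject coefficients of one mode (numeric).
#' @param labels per-subject labels, same length and subject order.
#' @param centered subtract means first (Pearson-style) if `TRUE`.
#' @return value in `[0, 1]`.
#' @examples
#' modeLabelCorrelation(c(1, 2, 3, 4), c(0, 0, 1, 1))  # 7 / sqrt(60)
#' @export
modeLabelCorrelation <- function(coeffs, labels, centered = FALSE) {
  if (length(coeffs) != length(labels))
    stop("coeffs and labels must have equal length")
  if (centered) {
    coeffs <- coeffs - mean(coeffs)
    labels <- labels - mean(labels)
  }
  nb <- sum(coeffs^2)
  nr <- sum(labels^2)
  if (nb == 0 || nr == 0)
    stop("undefined correlation: zero-norm vector")
  abs(sum(labels * coeffs)) / sqrt(nr * nb)
}

#' Select modes with the strongest label correlation
#'
#' Ranks modes by their uncentered label correlation and keeps the top
#' `topK` (default 4). Ties are broken towards the smaller mode index.
#'
#' @param coeffMatrix subjects x modes coefficient matrix (e.g. from
#'   [coefficientMatrix()]).
#' @param labels per-subject label vector, same row order.
#' @param topK number of modes to keep; clipped (with a warning) to the
#'   number of modes available.
#' @param centered passed to [modeLabelCorrelation()].
#' @return integer vector of selected mode indices, ordered by decreasing
#'   correlation, with the per-mode correlations as the `correlations`
#'   attribute.
#' @export
selectByCorrelation <- function(coeffMatrix, labels, topK = 4L,
                                centered = FALSE) {
  coeffMatrix <- as.matrix(coeffMatrix)
  if (nrow(coeffMatrix) != length(labels))
    stop("labels must have one entry per coefficient-matrix row")
  topK <- as.integer(topK)
  if (topK < 1) stop("topK must be at least 1")
  nm <- ncol(coeffMatrix)
  if (topK > nm) {
    warning(sprintf("topK (%d) exceeds the number of modes (%d); clipping",
                    topK, nm))
    topK <- nm
  }
  corr <- vapply(seq_len(nm), function(j)
    modeLabelCorrelation(coeffMatrix[, j], labels, centered = centered),
    numeric(1))
  sel <- order(-corr, seq_len(nm))[seq_len(topK)]
  structure(as.integer(sel), correlations = corr)
}

#' Select modes by accumulated variance contribution
#'
#' Keeps the smallest prefix of modes whose accumulated variance
#' contribution rate reaches `threshold` (default 0.90); alternatively a
#' fixed `topK` count of leading modes.
#'
#' @param model an [SSMModel-class].
#' @param threshold AVCR cut-off in (0, 1].
#' @param topK if given, ignore `threshold` and return the first `topK`
#'   modes.
#' @return integer vector of mode indices (always a prefix `1..k`).
#' @export
selectByAvcr <- function(model, threshold = 0.90, topK = NULL) {
  stopifnot(is(model, "SSMModel"))
  if (!is.null(topK)) {
    topK <- min(as.integer(topK), nModes(model))
    return(seq_len(topK))
  }
  if (threshold <= 0 || threshold > 1)
    stop("threshold must lie in (0, 1]")
  ev <- model@eigenvalues
  if (!length(ev) || sum(ev) <= 0)
    stop("model has no variance (all eigenvalues zero)")
  rate <- cumsum(ev) / sum(ev)
  k <- which(rate >= threshold - 1e-12)[1]
  if (is.na(k)) k <- length(ev)
  seq_len(k)
}

#' Combine variance-based and correlation-based mode selections
#'
#' Takes the product set (intersection) of the AVCR-selected and the
#' correlation-selected modes, ordered by correlation descending, and
#' optionally keeps the best `finalCount` members (default 1 per model).
#' If the intersection is empty the best-correlated mode within the AVCR
#' set is used as a fallback, with a warning.
#'
#' @param avcrSet integer modes from [selectByAvcr()].
#' @param corrSet integer modes from [selectByCorrelation()].
#' @param correlations per-mode correlation values (e.g. the
#'   `correlations` attribute of [selectByCorrelation()]).
#' @param finalCount how many modes to keep from the product set; `NULL`
#'   keeps all of it.
#' @return a [ModeSelection-class].
#' @export
combineSelections <- function(avcrSet, corrSet, correlations,
                              finalCount = 1L) {
  avcrSet <- as.integer(avcrSet)
  corrSet <- as.integer(corrSet)
  if (!length(avcrSet) || !length(corrSet))
    stop("both mode sets must be non-empty")
  inter <- intersect(avcrSet, corrSet)
  fallback <- FALSE
  if (!length(inter)) {
    warning("empty product set; falling back to the best-correlated mode within the AVCR set")
    fallback <- TRUE
    inter <- avcrSet[order(-correlations[avcrSet], avcrSet)][1]
  }
  inter <- inter[order(-correlations[inter], inter)]
  sel <- if (is.null(finalCount)) inter else head(inter, as.integer(finalCount))
  new("ModeSelection", avcrSet = sort(avcrSet), corrSet = corrSet,
      selected = as.integer(sel), correlations = as.numeric(correlations),
      fallback = fallback)
}

#' One-call combined mode selection against binary labels
#'
#' Convenience wrapper running [selectByAvcr()], [selectByCorrelation()]
#' and [combineSelections()] for one fitted model. Binary (normal = 0,
#' abnormal = 1) labels are used for selection even when stage labels
#' exist.
#'
#' @param model an [SSMModel-class].
#' @param shapes list of training [ShapeVector-class] objects.
#' @param labels binary per-subject labels (same order as `shapes`).
#' @param avcrThreshold AVCR cut-off.
#' @param corrTopK number of correlation-ranked modes.
#' @param finalCount modes kept from the product set.
#' @return a [ModeSelection-class].
#' @export
selectModes <- function(model, shapes, labels, avcrThreshold = 0.90,
                        corrTopK = 4L, finalCount = 1L) {
  B <- coefficientMatrix(model, shapes)
  corrSel <- selectByCorrelation(B, labels, topK = corrTopK)
  avcrSel <- selectByAvcr(model, threshold = avcrThreshold)
  combineSelections(avcrSel, corrSel, attr(corrSel, "correlations"),
                    finalCount = finalCount)
}
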