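#' Train the epsilon-SVR stage-mapping function
#'
#' Solves the standard epsilon-insensitive support vector regression dual
#' with a Gaussian kernel `k(u, v) = exp(-gamma |u - v|^2)`: maximize
#' \deqn{-\tfrac12 \sum_{ij} \beta_i \beta_j k(b_i, b_j)
#'       - \varepsilon \sum_i |\beta_i| + \sum_i r_i \beta_i}
#' over `beta_i = alpha_i - alpha_i*` with `sum_i beta_i = 0` and
#' `alpha_i, alpha_i* in [0, C]`. The solver is libsvm's SMO (via e1071)
#' run at a tight termination tolerance; the fitted machine is stored in
#' explicit dual form so the prediction
#' `f(b) = sum_i beta_i k(b_i, b) + a`, the KKT/tube conditions and the
#' dual objective can all be evaluated by package code.
#'
#' Features are standardized to zero mean and unit variance on the
#' training fold (constant features left unscaled); the parameters are
#' stored in the model for test-time reuse.
#'
#' @param features subjects x modes numeric matrix of selected-mode
#'   coefficients.
#' @param targets numeric stage labels.
#' @param cost box constraint C.
#' @param epsilon tube half-width.
#' @param gamma Gaussian kernel width; default `1 / ncol(features)` on the
#'   standardized features (i.e. 1 over the feature count times the unit
#'   feature variance).
#' @param standardize standardize features on the training fold.
#' @param tolerance SMO termination tolerance.
#' @return an [SVRModel-class].
#' @export
trainSVR <- function(features, targets, cost = 10, epsilon = 0.1,
                     gamma = NULL, standardize = TRUE, tolerance = 1e-8) {
  features <- as.matrix(features)
  targets <- as.numeric(targets)
  n <- nrow(features)
  if (n < 2) stop("at least two training subjects are required")
  if (length(targets) != n) stop("one target per training row required")
  if (cost <= 0 || epsilon < 0) stop("require C > 0 and epsilon >= 0")

  if (standardize) {
    center <- colMeans(features)
    scale <- apply(features, 2, sd)
    scale[!is.finite(scale) | scale < 1e-12] <- 1
  } else {
    center <- rep(0, ncol(features))
    scale <- rep(1, ncol(features))
  }
  Xs <- sweep(sweep(features, 2, center), 2, scale, "/")
  if (is.null(gamma)) gamma <- 1 / ncol(Xs)
  if (gamma <= 0) stop("gamma must be positive")

  if (max(targets) - min(targets) < .Machine$double.eps) {
    # zero-variation optimum: f identically the constant target
    return(new("SVRModel", dualCoeffs = rep(0, n), bias = targets[1],
               gamma = gamma, cost = cost, epsilon = epsilon,
               supportInputs = Xs, trainTargets = targets,
               featureCenter = center, featureScale = scale))
  }

  fit <- e1071::svm(x = Xs, y = targets, type = "eps-regression",
                    kernel = "radial", gamma = gamma, cost = cost,
                    epsilon = epsilon, scale = FALSE, tolerance = tolerance)
  beta <- rep(0, n)
  beta[fit$index] <- fit$coefs
  new("SVRModel", dualCoeffs = beta, bias = -fit$rho, gamma = gamma,
      cost = cost, epsilon = epsilon, supportInputs = Xs,
      trainTargets = targets, featureCenter = center, featureScale = scale)
}

#' Gaussian kernel matrix
#'
#' `K_ij = exp(-gamma |a_i - b_j|^2)`.
#'
#' @param a,b point matrices (rows are points).
#' @param gamma kernel width.
#' @return nrow(a) x nrow(b) matrix.
#' @export
gaussianKernelMatrix <- function(a, b, gamma) {
  exp(-gamma * crossDist2(as.matrix(a), as.matrix(b)))
}

#' Predict the disease stage of new subjects
#'
#' Evaluates the dual-form mapping
#' `f(b) = sum_i (alpha_i - alpha_i*) k(b_i, b) + a` on each row of `b`
#' and assigns the hard stage as the nearest label in `labelSet` (ties go
#' to the smaller label).
#'
#' @param model an [SVRModel-class].
#' @param b numeric coefficient vector, or a matrix with one subject per
#'   row (raw scale; the model's stored standardization is applied).
#' @param labelSet candidate hard labels.
#' @param subjectIds optional ids for the output.
#' @return data.frame with columns `subjectId`, `score`, `hardStage`.
#' @export
predictStage <- function(model, b, labelSet = 0:2, subjectIds = NULL) {
  stopifnot(is(model, "SVRModel"))
  if (is.null(dim(b))) b <- matrix(b, nrow = 1)
  b <- as.matrix(b)
  if (ncol(b) != ncol(model@supportInputs))
    stop(sprintf("feature length (%d) does not match training (%d)",
                 ncol(b), ncol(model@supportInputs)))
  Bs <- sweep(sweep(b, 2, model@featureCenter), 2, model@featureScale, "/")
  K <- gaussianKernelMatrix(Bs, model@supportInputs, model@gamma)
  score <- as.numeric(K %*% model@dualCoeffs + model@bias)
  hard <- vapply(score, function(s) labelSet[which.min(abs(s - labelSet))],
                 labelSet[1])
  if (is.null(subjectIds)) subjectIds <- as.character(seq_along(score))
  data.frame(subjectId = subjectIds, score = score, hardStage = hard,
             stringsAsFactors = FALSE)
}

#' Dual objective of a fitted (or candidate) epsilon-SVR solution
#'
#' Evaluates the dual objective
#' `-(1/2) beta' K beta - epsilon sum|beta| + r' beta` for dual
#' coefficients `beta = alpha - alpha*` (at the optimum at most one of
#' `alpha_i`, `alpha_i*` is nonzero, so `|beta|` recovers `alpha + alpha*`).
#'
#' @param beta dual coefficient vector.
#' @param K kernel matrix of the training inputs.
#' @param targets training targets.
#' @param epsilon tube half-width.
#' @return the dual objective value (to be maximized).
#' @export
svrDualObjective <- function(beta, K, targets, epsilon) {
  as.numeric(-0.5 * crossprod(beta, K %*% beta) - epsilon * sum(abs(beta)) +
             sum(targets * beta))
}

#' KKT/tube diagnostics for a fitted SVR model
#'
#' For every unbounded support vector (`0 < |beta_i| < C`) the prediction
#' must sit on the tube boundary: `|r_i - f(b_i)| = epsilon` up to
#' tolerance. Returns the worst violation together with the dual equality
#' residual.
#'
#' @param model an [SVRModel-class].
#' @return list with `maxFreeSVViolation`, `equalityResidual`,
#'   `dualObjective`.
#' @export
svrKKTCheck <- function(model) {
  stopifnot(is(model, "SVRModel"))
  K <- gaussianKernelMatrix(model@supportInputs, model@supportInputs,
                            model@gamma)
  f <- as.numeric(K %*% model@dualCoeffs + model@bias)
  resid <- model@trainTargets - f
  beta <- model@dualCoeffs
  tolC <- 1e-6 * model@cost
  free <- abs(beta) > tolC & abs(beta) < model@cost - tolC
  viol <- if (any(free)) max(abs(abs(resid[free]) - model@epsilon)) else 0
  list(maxFreeSVViolation = viol,
       equalityResidual = abs(sum(beta)),
       dualObjective = svrDualObjective(beta, K, model@trainTargets,
                                        model@epsilon))
}

#' Nearest-neighbour two-class classification
#'
#' Label of the Euclidean-nearest training feature; distance ties go to
#' the smallest training (subject) index.
#'
#' @param trainFeatures training matrix, one subject per row.
#' @param trainLabels per-row labels.
#' @param testFeature a single feature vector, or a matrix of them.
#' @return the predicted label(s).
#' @export
classifyNN <- function(trainFeatures, trainLabels, testFeature) {
  trainFeatures <- as.matrix(trainFeatures)
  if (nrow(trainFeatures) < 1) stop("empty training set")
  if (length(trainLabels) != nrow(trainFeatures))
    stop("one label per training row required")
  if (is.null(dim(testFeature))) testFeature <- matrix(testFeature, nrow = 1)
  testFeature <- as.matrix(testFeature)
  d2 <- crossDist2(testFeature, trainFeatures)
  idx <- apply(d2, 1, which.min)  # which.min takes the first (smallest index) on ties
  out <- trainLabels[idx]
  if (length(out) == 1) out[[1]] else out
}
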