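#' Default pipeline configuration
#'
#' All tunable parameters of the evaluation pipeline in one list: rigid
#' registration and correspondence settings, mode-selection thresholds,
#' SVR hyperparameters and the approach to evaluate.
#'
#' @param approach `"multi"` (three SSMs + combined selection, the
#'   proposed method), `"liver-combined"` (liver SSM + combined
#'   selection), or `"liver-avcr"` (liver SSM + variance-only selection,
#'   the baseline).
#' @param correspondence `"tpsrpm"` to recover vertex correspondence by
#'   robust point matching, or `"index"` when meshes are already
#'   corresponded vertex-by-vertex.
#' @param avcrThreshold AVCR cut-off for variance-based selection.
#' @param corrTopK modes kept by correlation ranking.
#' @param finalPerModel modes kept per SSM from the product set.
#' @param svrCost,svrEpsilon,svrGamma epsilon-SVR hyperparameters
#'   (`NULL` gamma = 1 / feature count on standardized features).
#' @param standardizeFeatures standardize NN/SVR features on the training
#'   fold.
#' @return named list.
#' @export
pipelineConfig <- function(approach = "multi", correspondence = "tpsrpm",
                           avcrThreshold = 0.90, corrTopK = 4L,
                           finalPerModel = 1L, svrCost = 10,
                           svrEpsilon = 0.1, svrGamma = NULL,
                           standardizeFeatures = TRUE) {
  stopifnot(approach %in% c("multi", "liver-combined", "liver-avcr"),
            correspondence %in% c("tpsrpm", "index"))
  list(approach = approach, correspondence = correspondence,
       avcrThreshold = avcrThreshold, corrTopK = as.integer(corrTopK),
       finalPerModel = as.integer(finalPerModel), svrCost = svrCost,
       svrEpsilon = svrEpsilon, svrGamma = svrGamma,
       standardizeFeatures = standardizeFeatures)
}

#' Precompute the per-reference preprocessing cache for leave-one-out runs
#'
#' Normalizes every subject against each registration reference that any
#' fold will use (at most two: the first and the second subject in
#' lexicographic id order). All computations are pairwise
#' subject-vs-reference, so the cache is identical whether built on the
#' full cohort or fold by fold - no information crosses folds through it.
#'
#' @param cohort a [SyntheticCohort-class].
#' @param config a [pipelineConfig()] list (only the correspondence
#'   settings matter).
#' @param verbose log progress.
#' @return named list: per reference id, the per-subject shape vectors.
#' @export
preprocessCache <- function(cohort, config = pipelineConfig(),
                            verbose = FALSE) {
  labels <- cohortToLabelTable(cohort)
  ids <- labels$subjectId
  orderIds <- sort(ids)
  refNeeded <- unique(vapply(seq_along(ids), function(i) {
    setdiff(orderIds, ids[i])[1]
  }, character(1)))
  cache <- list()
  for (r in refNeeded) {
    if (verbose) message("preprocessing against reference ", r)
    cache[[r]] <- preprocessToReference(cohort, r, config)
  }
  cache
}

# normalize every subject against one reference subject: rigid
# registration per organ, correspondence recovery, vertex reordering,
# shape-vector assembly. Purely pairwise subject-vs-reference, so results
# for subject A never depend on subject B (no information leak across
# leave-one-out folds).
preprocessToReference <- function(cohort, refId, config) {
  subj <- subjects(cohort)
  ids <- vapply(subj, function(s) s@id, character(1))
  ref <- subj[[match(refId, ids)]]
  out <- vector("list", length(subj))
  names(out) <- ids
  for (i in seq_along(subj)) {
    s <- subj[[i]]
    organs <- list(liver = s@liver, spleen = s@spleen)
    refOrgans <- list(liver = ref@liver, spleen = ref@spleen)
    aligned <- list()
    for (org in names(organs)) {
      if (identical(s@id, refId)) {
        aligned[[org]] <- refOrgans[[org]]
        next
      }
      tf <- registerRigid(organs[[org]], refOrgans[[org]])
      moved <- applyTransform(organs[[org]], tf)
      if (identical(config$correspondence, "tpsrpm")) {
        m <- matchTpsRpm(moved, refOrgans[[org]])
        # template propagation: reference topology sampled on the subject
        # surface via the converged warp, avoiding the vertex-grid
        # quantization of a hard reorder
        aligned[[org]] <- propagateCorrespondence(moved, refOrgans[[org]],
                                                  m$warp)
      } else {
        aligned[[org]] <- moved
      }
    }
    out[[i]] <- list(
      liver = assembleShapeVector(aligned$liver, subjectId = s@id),
      spleen = assembleShapeVector(aligned$spleen, subjectId = s@id),
      joint = assembleShapeVector(aligned$liver, aligned$spleen,
                                  subjectId = s@id))
  }
  out
}

# train one leave-one-out fold: SSM fit(s), mode selection, feature
# extraction, NN + SVR training. shapeVecs is the per-subject list from
# preprocessToReference restricted to the TRAINING subjects.
trainFold <- function(shapeVecs, binaryLabels, stageLabels, refId, config) {
  layouts <- if (identical(config$approach, "multi"))
    c("liver", "spleen", "joint") else "liver"
  models <- list()
  selections <- list()
  featList <- list()
  for (lay in layouts) {
    shapes <- lapply(shapeVecs, `[[`, lay)
    model <- fitSSM(shapes, referenceId = refId)
    if (identical(config$approach, "liver-avcr")) {
      # variance-only baseline: the AVCR prefix is the feature set
      sel <- selectByAvcr(model, threshold = config$avcrThreshold)
      selection <- new("ModeSelection", avcrSet = as.integer(sel),
                       corrSet = as.integer(sel), selected = as.integer(sel),
                       correlations = numeric(), fallback = FALSE)
    } else {
      selection <- selectModes(model, shapes, binaryLabels,
                               avcrThreshold = config$avcrThreshold,
                               corrTopK = config$corrTopK,
                               finalCount = config$finalPerModel)
    }
    B <- coefficientMatrix(model, shapes)
    featList[[lay]] <- B[, selection@selected, drop = FALSE]
    models[[lay]] <- model
    selections[[lay]] <- selection
  }
  features <- do.call(cbind, featList)
  if (config$standardizeFeatures) {
    center <- colMeans(features)
    scale <- apply(features, 2, sd)
    scale[!is.finite(scale) | scale < 1e-12] <- 1
  } else {
    center <- rep(0, ncol(features))
    scale <- rep(1, ncol(features))
  }
  featStd <- sweep(sweep(features, 2, center), 2, scale, "/")
  svr <- trainSVR(featStd, stageLabels, cost = config$svrCost,
                  epsilon = config$svrEpsilon, gamma = config$svrGamma,
                  standardize = FALSE)
  list(models = models, selections = selections, features = featStd,
       featureCenter = center, featureScale = scale,
       binaryLabels = binaryLabels, stageLabels = stageLabels, svr = svr)
}

# project a held-out subject onto the fold-trained models and standardize
# with the fold's feature statistics
foldTestFeature <- function(fold, shapeVec) {
  feats <- numeric()
  for (lay in names(fold$models)) {
    b <- projectShape(fold$models[[lay]], shapeVec[[lay]])@values
    feats <- c(feats, b[fold$selections[[lay]]@selected])
  }
  (feats - fold$featureCenter) / fold$featureScale
}

#' Leave-one-out evaluation of the staging pipeline
#'
#' For each fold the held-out subject is excluded from the choice of the
#' registration reference, the SSM fits, the mode selection and the
#' NN/SVR training; the held-out shape is then projected onto the
#' fold-trained models and evaluated. The registration reference inside
#' each fold is the first training subject in lexicographic id order, so
#' at most two references occur across all folds and subject-vs-reference
#' preprocessing (pairwise, leak-free) is cached per reference.
#'
#' @param cohort a [SyntheticCohort-class] (or any list of subjects with
#'   `liver`/`spleen` surfaces, ids and stages).
#' @param config a [pipelineConfig()] list.
#' @param verbose log per-fold progress to stderr.
#' @param preprocCache optionally, a precomputed preprocessing cache from
#'   [preprocessCache()]; registration/correspondence are by far the most
#'   expensive steps and depend only on the correspondence settings, so
#'   method comparisons share one cache.
#' @return an [EvaluationReport-class].
#' @export
runLOO <- function(cohort, config = pipelineConfig(), verbose = FALSE,
                   preprocCache = NULL) {
  subj <- subjects(cohort)
  n <- length(subj)
  if (n < 3) stop("need at least 3 subjects for leave-one-out")
  labels <- cohortToLabelTable(cohort)
  if (length(unique(labels$binaryLabel)) < 2)
    stop("need both classes present")
  ids <- labels$subjectId
  orderIds <- sort(ids)

  cache <- if (is.null(preprocCache)) {
    preprocessCache(cohort, config, verbose = verbose)
  } else preprocCache

  pred <- data.frame(subjectId = ids, truthBinary = labels$binaryLabel,
                     truthStage = labels$stageLabel,
                     nnLabel = NA_integer_, score = NA_real_,
                     hardStage = NA_integer_, stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    t0 <- Sys.time()
    trainIdx <- setdiff(seq_len(n), i)
    if (length(unique(labels$binaryLabel[trainIdx])) < 2) {
      warning("fold ", ids[i], " skipped: single-class training set")
      next
    }
    ref <- setdiff(orderIds, ids[i])[1]
    sv <- cache[[ref]]
    fold <- trainFold(sv[trainIdx], labels$binaryLabel[trainIdx],
                      labels$stageLabel[trainIdx], ref, config)
    feat <- foldTestFeature(fold, sv[[i]])
    pred$nnLabel[i] <- classifyNN(fold$features, fold$binaryLabels, feat)
    sc <- predictStage(fold$svr, feat)
    pred$score[i] <- sc$score
    pred$hardStage[i] <- sc$hardStage
    if (verbose)
      message(sprintf("fold %s: NN %d (truth %d), score %.3f [%.2fs]",
                      ids[i], pred$nnLabel[i], pred$truthBinary[i],
                      pred$score[i],
                      as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  }

  done <- !is.na(pred$nnLabel)
  acc <- c(
    normal = mean(pred$nnLabel[done & pred$truthBinary == 0] == 0),
    abnormal = mean(pred$nnLabel[done & pred$truthBinary == 1] == 1))
  stageStats <- do.call(rbind, lapply(sort(unique(pred$truthStage)), function(s) {
    sc <- pred$score[done & pred$truthStage == s]
    data.frame(stage = s, n = length(sc), meanScore = mean(sc),
               varScore = if (length(sc) > 1) var(sc) else 0)
  }))
  seed <- if (is(cohort, "SyntheticCohort")) cohort@spec@seed else NA_integer_
  new("EvaluationReport", perClassAccuracy = acc, perSubject = pred,
      perStageStats = stageStats, config = config,
      configHash = rlang::hash(config), seed = as.integer(seed))
}

#' Trained artifacts of a single leave-one-out fold
#'
#' Exposes what [runLOO()] trains for one fold (models, selections, SVR)
#' so the no-leakage property - the fold's artifacts must not depend on
#' the held-out subject's data - can be verified directly.
#'
#' @param cohort a [SyntheticCohort-class].
#' @param heldOutId id of the held-out subject.
#' @param config a [pipelineConfig()] list.
#' @return list as produced by the internal fold trainer.
#' @export
looFoldArtifacts <- function(cohort, heldOutId, config = pipelineConfig()) {
  labels <- cohortToLabelTable(cohort)
  ids <- labels$subjectId
  i <- match(heldOutId, ids)
  if (is.na(i)) stop("unknown subject id")
  ref <- setdiff(sort(ids), heldOutId)[1]
  sv <- preprocessToReference(cohort, ref, config)
  trainIdx <- setdiff(seq_along(ids), i)
  trainFold(sv[trainIdx], labels$binaryLabel[trainIdx],
            labels$stageLabel[trainIdx], ref, config)
}

#' Compare the three evaluation approaches
#'
#' Runs the leave-one-out evaluation with (a) the liver SSM and
#' variance-only (AVCR) mode selection - the baseline, (b) the liver SSM
#' with the combined selection, and (c) all three SSMs with the combined
#' selection - the proposed method. All other configuration fields are
#' held identical.
#'
#' @param cohort a [SyntheticCohort-class].
#' @param config a [pipelineConfig()] list (its `approach` is overridden).
#' @param verbose log progress.
#' @param preprocCache optional precomputed [preprocessCache()] result.
#' @return data.frame with one row per approach and the per-class
#'   accuracies; the full [EvaluationReport-class] objects are attached as
#'   the `reports` attribute.
#' @export
compareMethods <- function(cohort, config = pipelineConfig(),
                           verbose = FALSE, preprocCache = NULL) {
  approaches <- c("liver-avcr", "liver-combined", "multi")
  cache <- if (is.null(preprocCache)) {
    preprocessCache(cohort, config, verbose = verbose)
  } else preprocCache
  reports <- list()
  rows <- list()
  for (ap in approaches) {
    cfg <- config
    cfg$approach <- ap
    rep <- runLOO(cohort, cfg, verbose = verbose, preprocCache = cache)
    reports[[ap]] <- rep
    rows[[ap]] <- data.frame(approach = ap,
                             accNormal = perClassAccuracy(rep)[["normal"]],
                             accAbnormal = perClassAccuracy(rep)[["abnormal"]],
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "reports") <- reports
  out
}

#' Serialize an evaluation report to JSON
#'
#' @param report an [EvaluationReport-class].
#' @param path output path.
#' @return `path` invisibly; `readEvaluationReport` restores the object.
#' @export
writeEvaluationReport <- function(report, path) {
  stopifnot(is(report, "EvaluationReport"))
  obj <- list(perClassAccuracy = as.list(report@perClassAccuracy),
              perSubject = report@perSubject,
              perStageStats = report@perStageStats,
              config = report@config, configHash = report@configHash,
              seed = report@seed)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeEvaluationReport
#' @export
readEvaluationReport <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- obj$config
  if (!is.null(cfg$svrGamma) && length(cfg$svrGamma) == 0) cfg$svrGamma <- NULL
  new("EvaluationReport",
      perClassAccuracy = unlist(obj$perClassAccuracy),
      perSubject = as.data.frame(obj$perSubject),
      perStageStats = as.data.frame(obj$perStageStats),
      config = cfg, configHash = obj$configHash,
      seed = as.integer(obj$seed))
}
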