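# End-to-end benchmark: generate -> (render + assemble) -> normalize ->
# Procrustes-calibrate -> polynomial features -> PCA -> SVM -> metrics.
# All train-dependent statistics (Procrustes model pose, PCA mean and
# components, feature standardization, the SVM itself) are estimated on
# the training split only.

#' Default benchmark configuration
#'
#' The simulated study conditions: three activity classes (running,
#' aerobics, table tennis), 60 sequences per class of 40 frames at
#' 20 fps, rendered on a 64 x 64 grid with sigma 3 px, limb half-width
#' 2 px and 1 px coordinate noise; degree-5 segment fits, PCA precision
#' 0.95, RBF SVM with C = 1, stratified 70/30 split.
#'
#' @param ... overrides for individual fields.
#' @return named list of settings.
#' @export
benchmarkConfig <- function(...) {
  cfg <- list(
    classes = c("running", "aerobics", "table_tennis"),
    nPerClass = 60L, nFrames = 40L, fps = 20,
    gridW = 64L, gridH = 64L, sigma = 3, limbWidth = 2, noiseSd = 1,
    assemble = TRUE, peakThreshold = 0.1, nmsRadius = NULL,
    eMin = 0.5, nSamples = 10L,
    degree = 5L, pcaPrecision = 0.95, pcaMode = "standard",
    trainFraction = 0.7, stratified = TRUE,
    svmKernel = "radial", svmCost = 1, svmGamma = NULL,
    classesFile = NULL)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) .stopf("unknown config field(s): %s", paste(bad, collapse = ", "))
  utils::modifyList(cfg, over)
}

#' Run the full movement-classification benchmark
#'
#' Simulates labelled motions for each configured activity class, pushes
#' them through the complete pipeline, and reports per-class and macro
#' precision/sensitivity/specificity on the held-out split, a per-
#' activity accuracy table, and a model-comparison table (the SVM plus
#' any extra estimators supplied).
#'
#' @param config settings from \code{\link{benchmarkConfig}}.
#' @param seed master seed; every random stage (sequence noise, split,
#'   classifier) derives from it, so reruns are bit-identical.
#' @param permuteLabels randomly permute all labels before the split --
#'   the leakage control; accuracy must then collapse to chance.
#' @param extraModels named list of functions \code{function(x, y, seed)}
#'   returning a model with a \code{predict} method, added to the
#'   comparison table.
#' @param verbose print one line per stage.
#' @return list with elements \code{report}
#'   (\linkS4class{ClassifierReport}), \code{perActivity} (data frame of
#'   per-class accuracy percent), \code{comparison} (data frame of
#'   macro metrics per algorithm), \code{pca}, \code{svm}, \code{split},
#'   \code{features} and \code{labels}.
#' @export
benchmarkSuite <- function(config = benchmarkConfig(), seed = 1L,
                           permuteLabels = FALSE, extraModels = list(),
                           verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  classes <- if (is.null(config$classesFile)) activityClasses() else
    activityClasses(config$classesFile)
  params <- SceneParams(config$gridW, config$gridH, config$sigma,
                        config$limbWidth, 1L, config$noiseSd, seed)
  nTot <- length(config$classes) * config$nPerClass
  seqSeeds <- .withSeed(seed, sample.int(.Machine$integer.max - 1L, nTot))

  say("simulate: %d sequences x %d frames", nTot, config$nFrames)
  motions <- vector("list", nTot)
  labels <- character(nTot)
  k <- 0L
  for (cl in config$classes) for (i in seq_len(config$nPerClass)) {
    k <- k + 1L
    motions[[k]] <- makeMotion(cl, config$nFrames, seed = seqSeeds[k],
                               params = params, classes = classes,
                               fps = config$fps)
    labels[k] <- cl
  }

  if (isTRUE(config$assemble)) {
    say("assemble: rendering and re-detecting %d scenes",
        nTot * config$nFrames)
    motions <- lapply(motions, assembleMotion, params = params,
                      threshold = config$peakThreshold,
                      nmsRadius = config$nmsRadius, eMin = config$eMin,
                      nSamples = config$nSamples)
  }

  if (permuteLabels)
    labels <- .withSeed(seed + 777L, sample(labels))

  split <- splitData(labels, config$trainFraction, seed = seed + 1L,
                     stratified = config$stratified)

  say("calibrate: range normalization + Procrustes")
  normed <- lapply(motions, normalizeSequence)
  modelPose <- meanFrame(normed[split$train])
  calibrated <- lapply(normed, function(m)
    procrustesCalibrate(m, modelPose)$motion)

  say("features: degree-%d segment fits", config$degree)
  fv <- lapply(calibrated, extractFeatures, degree = config$degree)
  ft <- featureTable(fv)
  ft$labels <- labels   # honor a permutation applied after generation

  say("reduce: PCA at precision %.3g", config$pcaPrecision)
  pca <- fitPCA(ft$x[split$train, , drop = FALSE],
                precision = config$pcaPrecision, mode = config$pcaMode)
  zTrain <- pcaTransform(pca, ft$x[split$train, , drop = FALSE])
  zTest <- pcaTransform(pca, ft$x[split$test, , drop = FALSE])

  say("train: one-vs-rest %s SVM", config$svmKernel)
  svm <- trainSVM(zTrain, labels[split$train], kernel = config$svmKernel,
                  cost = config$svmCost, gamma = config$svmGamma,
                  seed = seed + 2L)
  report <- evaluateClassifier(svm, zTest, labels[split$test])

  conf <- report@confusion
  perActivity <- data.frame(
    class = rownames(conf),
    accuracy = ifelse(rowSums(conf) > 0, 100 * diag(conf) / rowSums(conf),
                      NA_real_))
  rownames(perActivity) <- NULL

  comparison <- data.frame(algorithm = "SVM",
                           precision = report@macro["precision"],
                           sensitivity = report@macro["sensitivity"],
                           specificity = report@macro["specificity"])
  for (nm in names(extraModels)) {
    mdl <- extraModels[[nm]](zTrain, labels[split$train], seed + 3L)
    rep2 <- evaluateClassifier(mdl, zTest, labels[split$test])
    comparison <- rbind(comparison,
                        data.frame(algorithm = nm,
                                   precision = rep2@macro["precision"],
                                   sensitivity = rep2@macro["sensitivity"],
                                   specificity = rep2@macro["specificity"]))
  }
  rownames(comparison) <- NULL

  list(report = report, perActivity = perActivity, comparison = comparison,
       pca = pca, svm = svm, split = split, features = ft, labels = labels)
}
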