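#' Configure a two-stage pipeline run
#'
#' Collects every knob of the two-step procedure: segmentation first
#' (crop, patch sampling, Dice-loss training, sliding-window inference),
#' then regression on the segmented ROIs (per-family minimum bounding
#' cubes feeding the volumetric CNN). Data can come from a cohort manifest
#' on disk or from in-memory volumes.
#'
#' @param manifest path to a cohort manifest CSV (subject_id, image_path,
#'   label_path, score), or NULL when \code{vols}/\code{scores} are given.
#' @param vols optional list of labeled \linkS4class{LabeledVolume}s.
#' @param scores optional numeric scores aligned with \code{vols}.
#' @param scheme an \linkS4class{AtlasScheme}; its merge mode decides the
#'   class count (6 classes for symmetric merging, 15 per-ROI).
#' @param cropEdge optional centered-crop edge applied on load (224 on the
#'   240 acquisition grid; NULL skips cropping).
#' @param patchEdge training patch edge (112 at full scale).
#' @param batchSize patches per optimization step (10 at full scale).
#' @param iterations optimization steps per training run (200 per epoch at
#'   full scale).
#' @param segnet a \linkS4class{SegNetConfig}; \code{nClasses} and
#'   \code{inChannels} are overridden to match the scheme and data.
#' @param lr Adam learning rate (scalar or per-iteration schedule) for the
#'   segmentation stage.
#' @param requireForeground redraw training patches until they contain a
#'   foreground voxel (default FALSE: plain uniform patch sampling).
#' @param segRestartOnCollapse retrain once from a fresh initialization if
#'   a foreground class is never predicted after training (see
#'   \code{\link{trainSegNet}}).
#' @param inferOverlap sliding-window overlap fraction used for
#'   whole-volume inference (default 0.5).
#' @param mbcTargetEdge cube edge of the extracted MBCs (64 at full scale).
#' @param mbcContent MBC content mode (see \code{\link{extractMBC}}).
#' @param mbcMethod \code{"mbc"} (two interpolations) or \code{"direct"}
#'   (single-interpolation baseline).
#' @param regressor a \linkS4class{RegressorConfig}; input edge/channels
#'   are overridden to match the cubes.
#' @param regEpochs,regBatchSize,regLr,regPatience,regWeightDecay regressor
#'   training hyperparameters (see \code{\link{trainRegressor}}).
#' @param useGroundTruthLabels feed ground-truth label maps (not
#'   predictions) to the regression stage.
#' @param trainFrac fraction of subjects used for training in each stage.
#' @param nResamples resamples for \code{\link{resampledEval}} harness runs.
#' @param seed base seed.
#' @param outputDir optional directory for logs/artifacts.
#' @return A list of class \code{"runConfig"}.
#' @export
runConfig <- function(manifest = NULL, vols = NULL, scores = NULL,
                      scheme = defaultAtlas(), cropEdge = NULL,
                      patchEdge = 32L, batchSize = 2L, iterations = 80L,
                      segnet = segNetConfig(stemChannels = 4L,
                                            channelSchedule = c(8L, 16L,
                                                                24L, 32L),
                                            expansion = 2L),
                      lr = 1e-3, mbcTargetEdge = 16L,
                      mbcContent = "masked_intensity",
                      mbcMethod = c("mbc", "direct"),
                      regressor = regressorConfig(
                        inputEdge = 16L, inChannels = 5L,
                        convChannels = c(6L, 12L, 1L),
                        fcDims = c(4096L, 256L, 32L), dropout = 0.2),
                      regEpochs = 100L, regBatchSize = 6L, regLr = 1e-3,
                      regPatience = 15L, regWeightDecay = 0,
                      regAugmentFlips = FALSE, regValFrac = 0.2,
                      useGroundTruthLabels = FALSE, trainFrac = 0.75,
                      nResamples = 5L, seed = 1L, outputDir = NULL,
                      requireForeground = FALSE,
                      segRestartOnCollapse = FALSE, inferOverlap = 0.5) {
  cfg <- list(manifest = manifest, vols = vols, scores = scores,
              scheme = scheme, cropEdge = cropEdge,
              patchEdge = as.integer(patchEdge),
              batchSize = as.integer(batchSize),
              iterations = as.integer(iterations), segnet = segnet,
              lr = lr, mbcTargetEdge = as.integer(mbcTargetEdge),
              mbcContent = mbcContent, mbcMethod = match.arg(mbcMethod),
              regressor = regressor, regEpochs = as.integer(regEpochs),
              regBatchSize = as.integer(regBatchSize), regLr = regLr,
              regPatience = as.integer(regPatience),
              regWeightDecay = regWeightDecay,
              regAugmentFlips = regAugmentFlips, regValFrac = regValFrac,
              useGroundTruthLabels = useGroundTruthLabels,
              trainFrac = trainFrac, nResamples = as.integer(nResamples),
              seed = as.integer(seed), outputDir = outputDir,
              requireForeground = requireForeground,
              segRestartOnCollapse = segRestartOnCollapse,
              inferOverlap = inferOverlap)
  class(cfg) <- "runConfig"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Maps the YAML keys onto \code{\link{runConfig}} arguments; the
#' \code{segnet} and \code{regressor} sub-maps are passed to
#' \code{\link{segNetConfig}} / \code{\link{regressorConfig}}, and
#' \code{merge_mode} selects the atlas scheme.
#'
#' @param path YAML file path.
#' @return A list of class \code{"runConfig"}.
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  for (nm in c("manifest", "cropEdge", "patchEdge", "batchSize",
               "iterations", "lr", "mbcTargetEdge", "mbcContent",
               "mbcMethod", "regEpochs", "regBatchSize", "regLr",
               "regPatience", "regWeightDecay", "regAugmentFlips",
               "regValFrac",
               "useGroundTruthLabels", "trainFrac", "nResamples", "seed",
               "outputDir", "requireForeground", "segRestartOnCollapse",
               "inferOverlap"))
    if (!is.null(y[[nm]])) args[[nm]] <- y[[nm]]
  if (!is.null(y$merge_mode)) args$scheme <- defaultAtlas(y$merge_mode)
  if (!is.null(y$atlas)) args$scheme <- readAtlas(y$atlas,
                                                  y$merge_mode %||%
                                                    "symmetric_5")
  if (!is.null(y$segnet)) args$segnet <- do.call(segNetConfig, y$segnet)
  if (!is.null(y$regressor))
    args$regressor <- do.call(regressorConfig, y$regressor)
  do.call(runConfig, args)
}

.loadCohort <- function(cfg) {
  if (!is.null(cfg$vols)) {
    vols <- cfg$vols
    scores <- cfg$scores
  } else {
    if (is.null(cfg$manifest)) stop("runConfig needs a manifest or vols")
    man <- read.csv(cfg$manifest, stringsAsFactors = FALSE)
    vols <- lapply(seq_len(nrow(man)), function(i)
      readVolume(man$image_path[i], man$label_path[i],
                 subjectId = man$subject_id[i]))
    scores <- man$score
  }
  if (!is.null(cfg$cropEdge))
    vols <- lapply(vols, centerCrop, outEdge = cfg$cropEdge)
  list(vols = vols, scores = scores)
}

.splitSubjects <- function(n, trainFrac, seed) {
  set.seed(seed)
  idx <- sample.int(n)
  nTrain <- max(1L, min(n - 1L, round(trainFrac * n)))
  list(train = sort(idx[seq_len(nTrain)]), test = sort(idx[-seq_len(nTrain)]))
}

#' Run the segmentation stage
#'
#' Loads (and optionally crops) the cohort, z-score normalizes the
#' intensities, maps the atlas-coded labels to classes under the scheme's
#' merge mode, trains the segmentation network on random patches with the
#' Dice loss, and evaluates Dice and directed surface distance per class on
#' held-out subjects via overlap-averaged sliding-window inference.
#'
#' @param cfg a \code{\link{runConfig}}.
#' @return list with \code{net}, \code{report} (an
#'   \linkS4class{EvalReport} over the held-out subjects), \code{split},
#'   and the prepared \code{vols}/\code{scores}.
#' @export
runSegmentationStage <- function(cfg) {
  data <- .loadCohort(cfg)
  K <- classCount(cfg$scheme) + 1L
  if (cfg$patchEdge > min(vapply(data$vols, function(v)
    min(dim(intensities(v))), numeric(1))))
    stop("patchEdge exceeds a cohort volume dimension")
  prep <- lapply(data$vols, function(v) {
    lab <- labelMap(v)
    if (is.null(lab)) stop("segmentation stage needs labeled volumes")
    nv <- normalizeIntensity(v)
    labeledVolume(intensities(nv), mapToClasses(lab, cfg$scheme),
                  spacing(v), subjectId(v))
  })
  split <- .splitSubjects(length(prep), cfg$trainFrac, cfg$seed)
  scfg <- cfg$segnet
  scfg@nClasses <- K
  scfg@inChannels <- 1L
  scfg@seed <- cfg$seed
  net <- buildSegNet(scfg)
  net <- trainSegNet(net, prep[split$train], iterations = cfg$iterations,
                     batchSize = cfg$batchSize, patchEdge = cfg$patchEdge,
                     lr = cfg$lr, seed = cfg$seed + 1L,
                     requireForeground = cfg$requireForeground %||% FALSE,
                     restartOnCollapse = cfg$segRestartOnCollapse %||%
                       FALSE)
  perClass <- matrix(NA_real_, length(split$test), K - 1L)
  perClassAsd <- matrix(NA_real_, length(split$test), K - 1L)
  for (i in seq_along(split$test)) {
    v <- prep[[split$test[i]]]
    predMap <- predictSegmentation(net, v, patchEdge = cfg$patchEdge,
                                   overlap = cfg$inferOverlap %||% 0.5)
    ev <- evaluateSegmentation(predMap, labelMap(v), K, spacing(v))
    perClass[i, ] <- ev$dice
    perClassAsd[i, ] <- ev$asd
  }
  meanDice <- colMeans(perClass, na.rm = TRUE)
  meanAsd <- colMeans(perClassAsd, na.rm = TRUE)
  subjDice <- rowMeans(perClass, na.rm = TRUE)
  subjAsd <- rowMeans(perClassAsd, na.rm = TRUE)
  summ <- rbind(
    data.frame(metric = "dice", mean = mean(subjDice), sd = sd(subjDice),
               lo = NA_real_, hi = NA_real_),
    data.frame(metric = "asd", mean = mean(subjAsd, na.rm = TRUE),
               sd = sd(subjAsd), lo = NA_real_, hi = NA_real_))
  report <- new("EvalReport",
                records = list(list(dice = subjDice, asd = subjAsd)),
                summary = summ,
                perClassDice = stats::setNames(meanDice,
                                               seq_len(K - 1L)),
                perClassAsd = stats::setNames(meanAsd, seq_len(K - 1L)),
                nResamples = 1L, asdVariant = "directed")
  res <- list(net = net, report = report, split = split, vols = prep,
              rawVols = data$vols, scores = data$scores)
  if (!is.null(cfg$outputDir)) .writeSegArtifacts(cfg, res)
  res
}

.writeSegArtifacts <- function(cfg, res) {
  dir.create(cfg$outputDir, recursive = TRUE, showWarnings = FALSE)
  write.csv(data.frame(iteration = seq_along(res$net$history),
                       dice_loss = res$net$history),
            file.path(cfg$outputDir, "seg_training_history.csv"),
            row.names = FALSE)
  writeEvalReport(res$report, file.path(cfg$outputDir, "seg_report.json"))
}

#' Run the regression stage
#'
#' Predicts label maps for every subject with the trained segmentation
#' network (or uses ground-truth labels when configured), extracts the five
#' per-family cubes, trains the volumetric CNN on the training subjects'
#' scores and evaluates MSE on the held-out subjects. Subjects missing a
#' family after segmentation are excluded and counted.
#'
#' @param cfg a \code{\link{runConfig}}.
#' @param seg output of \code{\link{runSegmentationStage}}; may be NULL
#'   when \code{useGroundTruthLabels} is set (the cohort is then loaded
#'   directly).
#' @return list with \code{model}, \code{report}, \code{predictions}
#'   data.frame (subject_id, true_score, predicted_score), \code{mse},
#'   \code{baselineMse} (mean-predictor), and \code{nExcluded}.
#' @export
runRegressionStage <- function(cfg, seg = NULL) {
  if (is.null(seg)) {
    if (!cfg$useGroundTruthLabels)
      stop("regression without a segmentation stage requires ",
           "useGroundTruthLabels = TRUE")
    data <- .loadCohort(cfg)
    vols <- lapply(data$vols, function(v) {
      nv <- normalizeIntensity(v)
      labeledVolume(intensities(nv),
                    mergeSymmetric(labelMap(v), cfg$scheme), spacing(v),
                    subjectId(v))
    })
    scores <- data$scores
    split <- .splitSubjects(length(vols), cfg$trainFrac, cfg$seed)
  } else {
    scores <- seg$scores
    split <- seg$split
    vols <- vector("list", length(seg$vols))
    for (i in seq_along(seg$vols)) {
      v <- seg$vols[[i]]
      lab <- if (cfg$useGroundTruthLabels) .asSymmetricClasses(cfg, v)
             else predictSegmentation(seg$net, v,
                                      patchEdge = cfg$patchEdge,
                                      overlap = cfg$inferOverlap %||% 0.5)
      vols[[i]] <- labeledVolume(intensities(v), lab, spacing(v),
                                 subjectId(v))
    }
  }
  nFam <- classCount(defaultAtlas())
  cubes <- vector("list", length(vols))
  keep <- logical(length(vols))
  for (i in seq_along(vols)) {
    present <- all(seq_len(nFam) %in% unique(as.vector(labelMap(
      vols[[i]]))))
    if (!present) next
    fc <- familyMBCs(vols[[i]], targetEdge = cfg$mbcTargetEdge,
                     content = cfg$mbcContent, method = cfg$mbcMethod,
                     preMapped = TRUE)
    cubes[[i]] <- stackCubes(fc)
    keep[i] <- TRUE
  }
  nExcluded <- sum(!keep)
  if (nExcluded)
    message(nExcluded, " subject(s) excluded: missing family after ",
            "segmentation")
  trainIdx <- intersect(split$train, which(keep))
  testIdx <- intersect(split$test, which(keep))
  if (!length(trainIdx) || !length(testIdx))
    stop("train or test set empty after exclusions")
  rcfg <- cfg$regressor
  rcfg@inputEdge <- cfg$mbcTargetEdge
  rcfg@inChannels <- as.integer(nFam)
  rcfg@fcDims[1] <- as.integer(rcfg@inputEdge^3 * rcfg@convChannels[3])
  rcfg@seed <- cfg$seed
  model <- buildRegressor(rcfg)
  model <- trainRegressor(model, cubes[trainIdx], scores[trainIdx],
                          epochs = cfg$regEpochs,
                          batchSize = cfg$regBatchSize, lr = cfg$regLr,
                          patience = cfg$regPatience %||% 15L,
                          weightDecay = cfg$regWeightDecay %||% 0,
                          augmentFlips = cfg$regAugmentFlips %||% FALSE,
                          valFrac = cfg$regValFrac %||% 0.2,
                          seed = cfg$seed + 2L)
  preds <- predictScores(model, cubes[testIdx],
                         flipAverage = cfg$regAugmentFlips %||% FALSE)
  mse <- meanSquaredError(scores[testIdx], preds)
  baseline <- meanSquaredError(scores[testIdx],
                               rep(mean(scores[trainIdx]),
                                   length(testIdx)))
  predictions <- data.frame(
    subject_id = vapply(vols[testIdx], subjectId, character(1)),
    true_score = scores[testIdx], predicted_score = preds)
  summ <- data.frame(metric = "mse", mean = mse, sd = NA_real_,
                     lo = NA_real_, hi = NA_real_)
  report <- new("EvalReport", records = list(list(mse = mse)),
                summary = summ, perClassDice = numeric(0),
                perClassAsd = numeric(0), nResamples = 1L,
                asdVariant = "directed")
  res <- list(model = model, report = report, predictions = predictions,
              mse = mse, baselineMse = baseline, nExcluded = nExcluded,
              split = list(train = trainIdx, test = testIdx))
  if (!is.null(cfg$outputDir)) {
    dir.create(cfg$outputDir, recursive = TRUE, showWarnings = FALSE)
    write.csv(predictions,
              file.path(cfg$outputDir, "reg_predictions.csv"),
              row.names = FALSE)
    write.csv(model$history,
              file.path(cfg$outputDir, "reg_training_history.csv"),
              row.names = FALSE)
  }
  res
}

# ground-truth class labels for the regression stage: the prepared volumes
# already hold class indices under the configured scheme; remap per-ROI
# classes onto families when needed so the five family cubes always exist
.asSymmetricClasses <- function(cfg, v) {
  lab <- labelMap(v)
  if (mergeMode(cfg$scheme) == "symmetric_5") return(lab)
  tb <- roiTable(cfg$scheme)
  perRoi <- .classLookup(cfg$scheme, "per_roi_14")
  fam <- .classLookup(cfg$scheme, "symmetric_5")
  out <- array(0L, dim(lab))
  for (code in names(perRoi))
    out[lab == perRoi[[code]]] <- fam[[code]]
  out
}

#' Run the full two-stage pipeline
#'
#' Segmentation first, then regression on the segmented ROIs.
#'
#' @param cfg a \code{\link{runConfig}}.
#' @return list with \code{segmentation} and \code{regression} stage
#'   results.
#' @export
runPipeline <- function(cfg) {
  seg <- runSegmentationStage(cfg)
  reg <- runRegressionStage(cfg, seg)
  list(segmentation = seg, regression = reg)
}

#' Save / load a segmentation model with its configuration
#'
#' @param net a model from \code{\link{buildSegNet}}.
#' @param path file path (.rds).
#' @return \code{loadSegNet} returns the restored model.
#' @export
saveSegNet <- function(net, path) {
  obj <- list(cfg = net$cfg, params = mget(ls(net$P), envir = net$P),
              bn = lapply(stats::setNames(ls(net$S), ls(net$S)),
                          function(nm) list(mean = net$S[[nm]]$mean,
                                            var = net$S[[nm]]$var)),
              encIn = net$encIn, history = net$history)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname saveSegNet
#' @export
loadSegNet <- function(path) {
  obj <- readRDS(path)
  net <- buildSegNet(obj$cfg)
  for (nm in names(obj$params)) net$P[[nm]] <- obj$params[[nm]]
  for (nm in names(obj$bn)) {
    net$S[[nm]]$mean <- obj$bn[[nm]]$mean
    net$S[[nm]]$var <- obj$bn[[nm]]$var
  }
  net$history <- obj$history
  net
}
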