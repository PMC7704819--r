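#' Pipeline configuration
#'
#' Single nested configuration driving [runPipeline()]: phantom cohort
#' sizes and noise, preprocessing parameters, network architecture and
#' training schedule, postprocessing connectivity, and stage toggles.
#' Every source of randomness flows from \code{seed}; a config fully
#' determines the outputs.
#'
#' @param seed master integer seed.
#' @param out output directory for artifacts (NULL = keep in memory only).
#' @param phantom list: \code{nTrainSubjects}, \code{nTestSubjects},
#'   \code{testRepeats}, \code{gridShape}, \code{spacing},
#'   \code{noiseSigma}, \code{dist} (a [cohortDistribution()]).
#' @param preprocess a [preprocessConfig()].
#' @param unet list of [unetConfig()] overrides plus \code{split}
#'   (train:validation volume proportions).
#' @param postprocess list with \code{connectivity}.
#' @param stages list of logical toggles; currently \code{train} — when
#'   FALSE, the model checkpoint from a previous run in \code{out} is
#'   loaded instead of retraining and downstream stages consume it
#'   unchanged.
#' @return nested configuration list.
#' @export
pipelineConfig <- function(seed = 1L, out = NULL,
                           phantom = list(),
                           preprocess = preprocessConfig(),
                           unet = list(),
                           postprocess = list(connectivity = 26L),
                           stages = list(train = TRUE)) {
  ph <- utils::modifyList(
    list(nTrainSubjects = 20L, nTestSubjects = 5L, testRepeats = 1L,
         gridShape = c(64L, 128L, 6L), spacing = c(1, 1, 6),
         noiseSigma = 0.03, dist = cohortDistribution(),
         baseSpec = NULL),
    phantom)
  un <- utils::modifyList(
    list(depth = 3L, baseFilters = 16L, head = "softmax",
         batchSize = 6L, epochs = 40L, learningRate = 1e-3,
         earlyStoppingPatience = Inf, split = c(3, 1)),
    unet)
  list(seed = as.integer(seed), out = out, phantom = ph,
       preprocess = preprocess, unet = un, postprocess = postprocess,
       stages = stages)
}

.stageLog <- function(name, detail = "") {
  message(sprintf("[muscleseg] stage=%s %s", name, detail))
}

# split a bilateral scan record and preprocess each thigh half:
# mask from water, mask both channels, normalize for the network.
.prepareThighs <- function(rec, pcfg) {
  halves <- splitThighs(rec$volume, pcfg)
  labHalves <- splitLabels(rec$labels, pcfg)
  lapply(c("left", "right"), function(side) {
    raw <- halves[[side]]
    mask <- muscleMaskFromWater(waterImage(raw), pcfg)
    masked <- applyMask(raw, mask)
    list(volume = normalizeChannels(masked),
         labels = labHalves[[side]],
         raw = raw, mask = mask,
         volumeId = sprintf("%s_%s", rec$subjectId, side),
         subjectId = sprintf("%s_%s", rec$subjectId, side),
         repeatId = rec$repeatId,
         trueFF = rec$trueFF)
  })
}

#' Run the full phantom-to-report pipeline
#'
#' Executes the stages in order: synthetic cohort generation, bilateral
#' splitting and subcutaneous-fat/skin removal, channel normalization,
#' slice dataset construction with a volume-level split, U-net training,
#' slice-wise prediction with largest-component postprocessing,
#' fat-fraction quantification on original intensities, and evaluation of
#' automated against ground-truth masks (Dice, volume and meanFF
#' differences; ICC across repeats when the test cohort has >= 2 repeated
#' scans of >= 2 thighs). Each stage logs what it did; artifacts (model
#' checkpoint, report CSVs, JSON summary, resolved config) are written
#' when \code{config$out} is set.
#'
#' @param config a [pipelineConfig()].
#' @param verbose print per-epoch training losses.
#' @return list with \code{model} ([UnetModel-class]), \code{report}
#'   (see [evaluateTestset()]), \code{icc} (per-ROI [IccResult-class]
#'   list or NULL), \code{quant} (per-thigh ROI statistics), and
#'   \code{config}.
#' @export
runPipeline <- function(config = pipelineConfig(), verbose = FALSE) {
  ph <- config$phantom
  pcfg <- config$preprocess
  baseSpec <- if (!is.null(ph$baseSpec)) ph$baseSpec
              else phantomSpec(gridShape = ph$gridShape,
                               spacing = ph$spacing,
                               noiseSigma = ph$noiseSigma)

  .stageLog("phantom", sprintf("train=%d test=%dx%d grid=%s",
                               ph$nTrainSubjects, ph$nTestSubjects,
                               ph$testRepeats,
                               paste(ph$gridShape, collapse = "x")))
  trainCohort <- generateCohort(ph$nTrainSubjects, 1L, dist = ph$dist,
                                baseSpec = baseSpec,
                                seed = config$seed)
  testCohort <- generateCohort(ph$nTestSubjects, ph$testRepeats,
                               dist = ph$dist, baseSpec = baseSpec,
                               seed = config$seed + 1L)

  .stageLog("preprocess", sprintf("%d bilateral scans",
                                  length(trainCohort) + length(testCohort)))
  trainThighs <- do.call(c, lapply(trainCohort, .prepareThighs, pcfg = pcfg))
  testThighs <- do.call(c, lapply(testCohort, .prepareThighs, pcfg = pcfg))

  un <- config$unet
  ucfg <- unetConfig(depth = un$depth, baseFilters = un$baseFilters,
                     head = un$head, batchSize = un$batchSize,
                     epochs = un$epochs, learningRate = un$learningRate,
                     earlyStoppingPatience = un$earlyStoppingPatience,
                     seed = config$seed + 2L)
  ds <- makeSliceDataset(trainThighs, split = un$split,
                         seed = config$seed + 3L)
  .stageLog("dataset", sprintf("%d train / %d val slices",
                               length(ds$train), length(ds$val)))

  doTrain <- isTRUE(config$stages$train) || is.null(config$stages$train)
  ckpt <- if (!is.null(config$out)) file.path(config$out, "model.json")
  if (!doTrain) {
    if (is.null(ckpt) || !file.exists(ckpt)) {
      stop("stage 'train' is off but no checkpoint found",
           if (!is.null(ckpt)) paste0(" at ", ckpt))
    }
    .stageLog("train", "skipped; loading checkpoint")
    model <- loadUnet(ckpt)
  } else {
    .stageLog("train", sprintf("depth=%d base=%d epochs=%d lr=%g head=%s",
                               ucfg$depth, ucfg$baseFilters, ucfg$epochs,
                               ucfg$learningRate, ucfg$head))
    model <- buildUnet(ucfg)
    model <- trainUnet(model, ds$train, ds$val, verbose = verbose)
  }

  conn <- config$postprocess$connectivity
  .stageLog("predict", sprintf("%d test thighs, connectivity %d",
                               length(testThighs), conn))
  pairs <- lapply(testThighs, function(th) {
    pred <- finalizeLabels(predictVolume(model, th$volume), conn)
    list(manual = th$labels, auto = pred, volume = th$raw,
         subjectId = th$subjectId, repeatId = th$repeatId,
         trueFF = th$trueFF)
  })

  .stageLog("evaluate", "")
  report <- evaluateTestset(pairs)

  icc <- NULL
  if (ph$testRepeats >= 2L && ph$nTestSubjects >= 2L) {
    icc <- lapply(1:4, function(roi) {
      sub <- report$per_scan[report$per_scan$roi == roi, ]
      tab <- stats::reshape(sub[c("subject_id", "repeat_id", "auto_meanff")],
                            idvar = "subject_id", timevar = "repeat_id",
                            direction = "wide")
      m <- as.matrix(tab[, -1])
      # thighs where a repeat produced an empty ROI carry no meanFF;
      # they cannot enter the variance decomposition
      complete <- stats::complete.cases(m)
      if (sum(complete) < 2L) {
        .stageLog("evaluate", sprintf(
          "ICC for ROI%d skipped: <2 thighs with meanFF in all repeats", roi))
        return(new("IccResult", estimate = NA_real_,
                   ci = c(NA_real_, NA_real_), model = "ICC(2,1)",
                   nSubjects = sum(complete), nRepeats = ncol(m),
                   degenerate = TRUE))
      }
      iccMeanFF(m[complete, , drop = FALSE])
    })
    names(icc) <- paste0("ROI", 1:4)
  }

  quant <- do.call(rbind, lapply(pairs, function(p) {
    q <- quantifyVolume(p$volume, p$auto)
    q$subject_id <- p$subjectId
    q$repeat_id <- p$repeatId
    q
  }))

  if (!is.null(config$out)) {
    dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
    if (doTrain) saveUnet(model, file.path(config$out, "model.json"))
    utils::write.csv(report$per_scan,
                     file.path(config$out, "report_per_scan.csv"),
                     row.names = FALSE)
    utils::write.csv(report$per_thigh,
                     file.path(config$out, "report_per_thigh.csv"),
                     row.names = FALSE)
    utils::write.csv(quant, file.path(config$out, "roi_stats.csv"),
                     row.names = FALSE)
    jsonlite::write_json(report$summary,
                         file.path(config$out, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    cfgOut <- config
    cfgOut$out <- NULL
    if (is(cfgOut$phantom$baseSpec, "PhantomSpec")) {
      # S4 spec is not YAML-serializable; record its defining fields
      bs <- cfgOut$phantom$baseSpec
      cfgOut$phantom$baseSpec <- list(
        gridShape = bs@gridShape, spacing = bs@spacing,
        thighRadius = bs@thighRadius, skinThickness = bs@skinThickness,
        subcutFatThickness = bs@subcutFatThickness,
        boneRadius = bs@boneRadius, noiseSigma = bs@noiseSigma,
        roiFatFraction = bs@roiFatFraction, seed = bs@seed)
    }
    yaml::write_yaml(cfgOut, file.path(config$out, "config_resolved.yaml"))
    .stageLog("write", config$out)
  }

  list(model = model, report = report, icc = icc, quant = quant,
       config = config)
}
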