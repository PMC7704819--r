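#' U-net configuration
#'
#' Settings of the two-channel slice-wise U-net that maps preprocessed
#' water+fat slices to the four muscle ROI masks. Training defaults follow
#' standard practice for this task: batch size 6, Adam with learning rate
#' 1e-6 over 1000 epochs, outputs squashed to (0,1) and binarized at 0.5.
#' Desk-scale runs override \code{epochs} and \code{learningRate}.
#'
#' The loss/output head is selectable: \code{"softmax"} (default) trains a
#' 5-class (background + 4 ROIs) softmax with categorical cross-entropy;
#' \code{"sigmoid"} trains 4 independent per-ROI sigmoid maps with
#' multi-label cross-entropy. Prediction is identical for both: per-ROI
#' probability maps thresholded at \code{binarizeThreshold} (strictly
#' greater; a score of exactly 0.5 counts as background), with multi-ROI
#' pixels resolved to the highest-scoring ROI.
#'
#' @param depth number of encoder levels (pooling steps), >= 2.
#' @param baseFilters channels at the first level; doubled per level.
#' @param inChannels input channels (water, fat).
#' @param nRoi number of ROI classes.
#' @param head \code{"softmax"} or \code{"sigmoid"}.
#' @param batchSize slices per optimizer step.
#' @param epochs training epochs.
#' @param learningRate Adam learning rate.
#' @param binarizeThreshold probability threshold in (0,1).
#' @param earlyStoppingPatience epochs without validation improvement
#'   before stopping; \code{Inf} disables early stopping (default).
#' @param seed RNG seed for weight initialisation and slice shuffling.
#' @return named list of validated settings.
#' @export
unetConfig <- function(depth = 3L, baseFilters = 16L, inChannels = 2L,
                       nRoi = 4L, head = c("softmax", "sigmoid"),
                       batchSize = 6L, epochs = 1000L,
                       learningRate = 1e-6, binarizeThreshold = 0.5,
                       earlyStoppingPatience = Inf, seed = 1L) {
  head <- match.arg(head)
  stopifnot(depth >= 2, baseFilters >= 1, batchSize >= 1, epochs >= 0,
            binarizeThreshold > 0, binarizeThreshold < 1,
            learningRate > 0)
  list(depth = as.integer(depth), baseFilters = as.integer(baseFilters),
       inChannels = as.integer(inChannels), nRoi = as.integer(nRoi),
       head = head,
       nOut = as.integer(if (head == "softmax") nRoi + 1L else nRoi),
       batchSize = as.integer(batchSize), epochs = as.integer(epochs),
       learningRate = learningRate,
       binarizeThreshold = binarizeThreshold,
       earlyStoppingPatience = earlyStoppingPatience,
       seed = as.integer(seed))
}

# layer inventory in the fixed parameter order shared with the C++ core:
# encoder levels (convA, convB), bottleneck (convA, convB), decoder levels
# deepest-first (up conv, convA, convB), final 1x1 conv.
.unetLayerSpec <- function(cfg) {
  d <- cfg$depth; f <- cfg$baseFilters
  ch <- function(i) f * 2^i  # channels at 0-based level i
  spec <- list()
  add <- function(name, cin, cout, k) {
    spec[[length(spec) + 1L]] <<- list(name = name, cin = cin,
                                       cout = cout, k = k)
  }
  for (i in seq_len(d)) {
    cin <- if (i == 1) cfg$inChannels else ch(i - 2)
    add(sprintf("enc%d_convA", i), cin, ch(i - 1), 3L)
    add(sprintf("enc%d_convB", i), ch(i - 1), ch(i - 1), 3L)
  }
  add("bottleneck_convA", ch(d - 1), ch(d), 3L)
  add("bottleneck_convB", ch(d), ch(d), 3L)
  for (i in d:1) {
    cAbove <- if (i == d) ch(d) else ch(i)
    add(sprintf("dec%d_up", i), cAbove, ch(i - 1), 3L)
    add(sprintf("dec%d_convA", i), 2L * ch(i - 1), ch(i - 1), 3L)
    add(sprintf("dec%d_convB", i), ch(i - 1), ch(i - 1), 3L)
  }
  add("out", f, cfg$nOut, 1L)
  spec
}

.archVector <- function(cfg) {
  c(cfg$depth, cfg$baseFilters, cfg$inChannels, cfg$nOut)
}

.headCode <- function(cfg) if (cfg$head == "softmax") 0L else 1L

#' Build an untrained U-net
#'
#' Constructs the encoder-decoder network described by \code{cfg}: each
#' encoder level applies two 3x3 ReLU convolutions and a 2x2 max-pool with
#' channel doubling per level; the decoder mirrors it with nearest-neighbour
#' upsampling, a 3x3 up-convolution and skip-connection concatenation; a
#' final 1x1 convolution produces one score map per output class. Weights
#' are He-initialised from the configured seed.
#'
#' @param cfg a [unetConfig()] list.
#' @return An untrained [UnetModel-class].
#' @examples
#' m <- buildUnet(unetConfig(depth = 2, baseFilters = 4))
#' m
#' @export
buildUnet <- function(cfg = unetConfig()) {
  spec <- .unetLayerSpec(cfg)
  params <- .withSeed(cfg$seed, {
    out <- list()
    for (ly in spec) {
      fanIn <- ly$cin * ly$k^2
      W <- matrix(stats::rnorm(ly$cout * fanIn, 0, sqrt(2 / fanIn)),
                  nrow = ly$cout, ncol = fanIn)
      out[[paste0(ly$name, "_W")]] <- W
      out[[paste0(ly$name, "_b")]] <- numeric(ly$cout)
    }
    out
  })
  new("UnetModel", config = cfg, params = params,
      log = data.frame(epoch = integer(), train_loss = numeric(),
                       val_loss = numeric()),
      trained = FALSE)
}

#' Number of trainable parameters of a U-net
#'
#' @param model a [UnetModel-class].
#' @return integer parameter count.
#' @export
nParameters <- function(model) {
  sum(vapply(model@params, length, integer(1)))
}

.checkSpatial <- function(H, W, depth) {
  f <- 2^depth
  if (H %% f != 0 || W %% f != 0) {
    stop(sprintf(paste("in-plane size %dx%d is not divisible by 2^depth",
                       "= %d; pad the slices to a multiple of %d"),
                 H, W, f, f))
  }
}

#' Normalize water and fat channels to [0, 1]
#'
#' Each channel is independently and linearly mapped so that its
#' volume-wide minimum becomes 0 and maximum becomes 1 (the network input
#' contract). A constant channel maps to all zeros. Fat-fraction maps must
#' be computed from the original intensities, never from normalized ones;
#' the pipeline driver enforces this ordering.
#'
#' @param vol a [FatWaterVolume-class].
#' @param per \code{"volume"} (default) or \code{"slice"}: the extent over
#'   which min/max are taken.
#' @return A normalized [FatWaterVolume-class].
#' @export
normalizeChannels <- function(vol, per = c("volume", "slice")) {
  per <- match.arg(per)
  norm1 <- function(a) {
    rng <- range(a)
    if (rng[2] == rng[1]) array(0, dim(a))
    else (a - rng[1]) / (rng[2] - rng[1])
  }
  if (per == "volume") {
    w <- norm1(vol@water); f <- norm1(vol@fat)
  } else {
    w <- .perSlice(vol@water, norm1)
    f <- .perSlice(vol@fat, norm1)
  }
  fatWaterVolume(w, f, vol@spacing, side = vol@side)
}

#' Build a slice dataset with a volume-level train/validation split
#'
#' Converts preprocessed, normalized thigh volumes with ground-truth labels
#' into 2D slice samples and splits them at the volume level — all slices
#' of a volume land in the same split, so validation volumes are never seen
#' during training (mirroring a roughly 3:1 scan-level split).
#'
#' @param volumes list of records, each with elements \code{volume}
#'   ([FatWaterVolume-class]) and \code{labels} ([MuscleLabelVolume-class]).
#' @param split length-2 numeric: train/validation proportions (e.g.
#'   \code{c(3, 1)}) or exact volume counts summing to
#'   \code{length(volumes)}.
#' @param seed RNG seed for the volume permutation.
#' @return list with \code{train} and \code{val}, each a list of samples
#'   \code{list(x, y, volumeId, sliceIndex)} where \code{x} is a
#'   (2 x H*W) matrix and \code{y} an integer label vector.
#' @export
makeSliceDataset <- function(volumes, split = c(3, 1), seed = 1L) {
  nVol <- length(volumes)
  if (nVol < 2L) stop("need at least 2 volumes to split")
  if (sum(split) == nVol && all(split == round(split))) {
    nVal <- as.integer(split[2])
  } else {
    nVal <- round(nVol * split[2] / sum(split))
  }
  nVal <- max(1L, min(nVol - 1L, nVal))
  perm <- .withSeed(seed, sample.int(nVol))
  valIdx <- perm[seq_len(nVal)]

  sliceSamples <- function(i) {
    rec <- volumes[[i]]
    vol <- rec$volume; lab <- rec$labels
    stopifnot(identical(dim(vol), dim(lab)))
    d <- dim(vol)
    w <- waterImage(vol); f <- fatImage(vol); L <- labelArray(lab)
    lapply(seq_len(d[3]), function(z) {
      list(x = rbind(as.vector(w[, , z]), as.vector(f[, , z])),
           y = as.integer(L[, , z]),
           volumeId = if (!is.null(rec$volumeId)) rec$volumeId else i,
           sliceIndex = z,
           H = d[1], W = d[2])
    })
  }
  trainIdx <- setdiff(seq_len(nVol), valIdx)
  list(train = do.call(c, lapply(trainIdx, sliceSamples)),
       val = do.call(c, lapply(valIdx, sliceSamples)))
}

.datasetLoss <- function(params, arch, head, samples) {
  cpp_unet_batch_loss(params, arch,
                      lapply(samples, `[[`, "x"),
                      lapply(samples, `[[`, "y"),
                      samples[[1]]$H, samples[[1]]$W, head)
}

#' Train a U-net on slice samples
#'
#' Minimises the configured cross-entropy loss with Adam, shuffling slices
#' each epoch and accumulating gradients over \code{batchSize} slices per
#' update. Training and validation loss are logged per epoch and the
#' parameters with the best validation loss are retained. All randomness
#' derives from \code{cfg$seed}, so a repeated run reproduces the loss
#' trajectory exactly.
#'
#' @param model an (untrained) [UnetModel-class] from [buildUnet()].
#' @param trainSet,valSet slice-sample lists from [makeSliceDataset()].
#' @param cfg a [unetConfig()]; defaults to the model's own config.
#' @param verbose print per-epoch losses.
#' @return The trained [UnetModel-class] with its log filled in.
#' @export
trainUnet <- function(model, trainSet, valSet, cfg = model@config,
                      verbose = FALSE) {
  if (cfg$epochs == 0L) return(model)
  if (!length(trainSet) || !length(valSet)) {
    stop("training and validation sets must be nonempty")
  }
  arch <- .archVector(cfg)
  head <- .headCode(cfg)
  params <- model@params
  mState <- lapply(params, function(p) p * 0)
  vState <- lapply(params, function(p) p * 0)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  step <- 0L
  n <- length(trainSet)
  log <- data.frame(epoch = integer(), train_loss = numeric(),
                    val_loss = numeric())
  bestVal <- Inf
  bestParams <- params
  sinceBest <- 0L

  .withSeed(cfg$seed, {
    for (epoch in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      starts <- seq(1L, n, by = cfg$batchSize)
      epochLoss <- 0
      for (s0 in starts) {
        idx <- ord[s0:min(s0 + cfg$batchSize - 1L, n)]
        nb <- length(idx)
        batch <- trainSet[idx]
        r <- cpp_unet_batch_grad(params, arch,
                                 lapply(batch, `[[`, "x"),
                                 lapply(batch, `[[`, "y"),
                                 batch[[1]]$H, batch[[1]]$W, head)
        acc <- r$grads
        bloss <- r$loss
        if (!is.finite(bloss)) {
          stop(sprintf(paste("non-finite training loss at epoch %d;",
                             "check learning rate (%.3g) and that inputs",
                             "are normalized to [0,1] (input range",
                             "%.3g..%.3g)"),
                       epoch, cfg$learningRate,
                       min(vapply(trainSet, function(s) min(s$x),
                                  numeric(1))),
                       max(vapply(trainSet, function(s) max(s$x),
                                  numeric(1)))))
        }
        epochLoss <- epochLoss + bloss * nb
        step <- step + 1L
        lrT <- cfg$learningRate * sqrt(1 - b2^step) / (1 - b1^step)
        for (j in seq_along(params)) {
          g <- acc[[j]] / nb
          mState[[j]] <- b1 * mState[[j]] + (1 - b1) * g
          vState[[j]] <- b2 * vState[[j]] + (1 - b2) * g^2
          params[[j]] <- params[[j]] -
            lrT * mState[[j]] / (sqrt(vState[[j]]) + eps)
        }
      }
      trLoss <- epochLoss / n
      vaLoss <- .datasetLoss(params, arch, head, valSet)
      log <- rbind(log, data.frame(epoch = epoch, train_loss = trLoss,
                                   val_loss = vaLoss))
      if (verbose) {
        message(sprintf("epoch %3d | train %.5f | val %.5f",
                        epoch, trLoss, vaLoss))
      }
      if (vaLoss < bestVal) {
        bestVal <- vaLoss
        bestParams <- params
        sinceBest <- 0L
      } else {
        sinceBest <- sinceBest + 1L
        if (sinceBest >= cfg$earlyStoppingPatience) break
      }
    }
  })

  new("UnetModel", config = cfg, params = bestParams, log = log,
      trained = TRUE)
}

#' Predict ROI labels for a whole volume
#'
#' Runs the network slice by slice on a preprocessed, normalized volume.
#' Per-ROI probability maps are thresholded at
#' \code{cfg$binarizeThreshold} (strict inequality: exactly 0.5 is
#' background); pixels exceeding the threshold in several ROI maps go to
#' the highest-scoring ROI. Slices are restacked in acquisition order.
#'
#' @param model a trained [UnetModel-class].
#' @param vol a [FatWaterVolume-class] (preprocessed and normalized).
#' @param cfg a [unetConfig()]; defaults to the model's config.
#' @return A [MuscleLabelVolume-class] with labels in 0..4.
#' @export
predictVolume <- function(model, vol, cfg = model@config) {
  d <- dim(vol)
  .checkSpatial(d[1], d[2], cfg$depth)
  arch <- .archVector(cfg)
  head <- .headCode(cfg)
  w <- waterImage(vol); f <- fatImage(vol)
  labels <- array(0L, d)
  for (z in seq_len(d[3])) {
    x <- rbind(as.vector(w[, , z]), as.vector(f[, , z]))
    P <- cpp_unet_predict(model@params, arch, x, d[1], d[2], head)
    roiP <- if (cfg$head == "softmax") P[-1, , drop = FALSE] else P
    best <- max.col(t(roiP), ties.method = "first")
    bestP <- roiP[cbind(best, seq_len(ncol(roiP)))]
    lab <- ifelse(bestP > cfg$binarizeThreshold, best, 0L)
    labels[, , z] <- as.integer(lab)
  }
  muscleLabelVolume(labels, voxelSpacing(vol))
}

#' Save / load a U-net model as plain text
#'
#' The checkpoint is a JSON file carrying the architecture and training
#' configuration, the training log, and every parameter matrix at full
#' double precision; reloading reproduces predictions bit for bit.
#'
#' @param model a [UnetModel-class].
#' @param path file path for the checkpoint (JSON).
#' @return \code{saveUnet}: the path, invisibly. \code{loadUnet}: the
#'   restored [UnetModel-class].
#' @export
saveUnet <- function(model, path) {
  obj <- list(
    config = model@config,
    trained = model@trained,
    log = model@log,
    params = lapply(model@params, function(p) {
      if (is.matrix(p)) list(dim = dim(p), data = as.vector(p))
      else list(dim = NULL, data = as.vector(p))
    })
  )
  writeLines(jsonlite::serializeJSON(obj, digits = I(17)), path)
  invisible(path)
}

#' @rdname saveUnet
#' @export
loadUnet <- function(path) {
  obj <- jsonlite::unserializeJSON(paste(readLines(path), collapse = "\n"))
  params <- lapply(obj$params, function(p) {
    if (!is.null(p$dim)) matrix(p$data, p$dim[1], p$dim[2]) else p$data
  })
  cfg <- obj$config
  new("UnetModel", config = cfg, params = params,
      log = as.data.frame(obj$log), trained = obj$trained)
}
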