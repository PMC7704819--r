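test_that("channel normalization maps min/max to [0,1] with declared degenerate rules", {
  a <- array(c(0, 5, 10, 10, 5, 0, 0, 10), c(2, 2, 2))
  v <- fatWaterVolume(a, array(7, c(2, 2, 2)))
  nv <- normalizeChannels(v)
  expect_equal(sort(unique(as.vector(waterImage(nv)))), c(0, 0.5, 1))
  expect_true(all(fatImage(nv) == 0))  # constant channel -> zeros
  # idempotence and scale invariance
  expect_equal(waterImage(normalizeChannels(nv)), waterImage(nv))
  v2 <- fatWaterVolume(3 * a + 2, 5 * array(7, c(2, 2, 2)))
  expect_equal(waterImage(normalizeChannels(v2)), waterImage(nv))
})

test_that("slice datasets split at the volume level and reproduce exactly", {
  mkvol <- function(seed) {
    set.seed(seed)
    list(volume = fatWaterVolume(array(runif(4 * 4 * 10), c(4, 4, 10)),
                                 array(runif(4 * 4 * 10), c(4, 4, 10))),
         labels = muscleLabelVolume(array(0L, c(4, 4, 10))))
  }
  vols <- lapply(1:4, mkvol)
  ds <- makeSliceDataset(vols, split = c(3, 1), seed = 1)
  expect_length(ds$train, 30L)
  expect_length(ds$val, 10L)
  trainVols <- unique(vapply(ds$train, `[[`, numeric(1), "volumeId"))
  valVols <- unique(vapply(ds$val, `[[`, numeric(1), "volumeId"))
  expect_length(intersect(trainVols, valVols), 0L)
  ds2 <- makeSliceDataset(vols, split = c(3, 1), seed = 1)
  expect_identical(ds, ds2)
  expect_error(makeSliceDataset(vols[1], split = c(3, 1)), "at least 2")
})

test_that("a 46-volume cohort splits into 36 training and 10 validation volumes", {
  vols <- lapply(1:46, function(i) {
    list(volume = fatWaterVolume(array(i, c(2, 2, 1)),
                                 array(1, c(2, 2, 1))),
         labels = muscleLabelVolume(array(0L, c(2, 2, 1))))
  })
  ds <- makeSliceDataset(vols, split = c(36, 10), seed = 3)
  expect_length(ds$train, 36L)
  expect_length(ds$val, 10L)
})

test_that("slicing is inverted by restacking the per-slice targets", {
  ph <- generatePhantom(tinySpec(noiseSigma = 0, side = "left",
                                 gridShape = c(32L, 32L, 4L)))
  ds <- makeSliceDataset(list(
    list(volume = ph$volume, labels = ph$labels),
    list(volume = ph$volume, labels = ph$labels)), split = c(1, 1))
  rec <- ds$train
  d <- dim(ph$labels)
  stacked <- array(0L, d)
  for (s in rec) stacked[, , s$sliceIndex] <- matrix(s$y, d[1], d[2])
  expect_identical(stacked, labelArray(ph$labels))
})

test_that("the network has the declared encoder-decoder structure", {
  m <- buildUnet(unetConfig(depth = 2, baseFilters = 4))
  # channel doubling per level and skip concatenation are visible in the
  # weight shapes: decoder convA consumes 2x the level's channels
  expect_identical(dim(m@params$enc1_convA_W), c(4L, 2L * 9L))
  expect_identical(dim(m@params$enc2_convA_W), c(8L, 4L * 9L))
  expect_identical(dim(m@params$bottleneck_convA_W), c(16L, 8L * 9L))
  expect_identical(dim(m@params$dec1_convA_W), c(4L, 8L * 9L))
  expect_identical(dim(m@params$out_W), c(5L, 4L))
  # parameter count strictly increases with base filters
  expect_gt(nParameters(buildUnet(unetConfig(depth = 2, baseFilters = 8))),
            nParameters(m))
})

test_that("prediction preserves the grid and demands divisible spatial size", {
  m <- buildUnet(unetConfig(depth = 2, baseFilters = 2))
  v <- fatWaterVolume(array(runif(16 * 16 * 3), c(16, 16, 3)),
                      array(runif(16 * 16 * 3), c(16, 16, 3)))
  pred <- predictVolume(m, normalizeChannels(v))
  expect_identical(dim(pred), c(16L, 16L, 3L))
  expect_true(all(labelArray(pred) %in% 0:4))
  bad <- fatWaterVolume(array(runif(18 * 18), c(18, 18, 1)),
                        array(runif(18 * 18), c(18, 18, 1)))
  expect_error(predictVolume(m, bad), "pad")
})

test_that("a background-biased model predicts empty ROI masks", {
  m <- buildUnet(unetConfig(depth = 2, baseFilters = 2))
  m@params$out_b <- c(10, -10, -10, -10, -10)
  v <- fatWaterVolume(array(0, c(8, 8, 2)), array(0, c(8, 8, 2)))
  pred <- predictVolume(m, v)
  expect_true(all(labelArray(pred) == 0L))
})

test_that("forward pass matches an independent R reference implementation", {
  cfg <- unetConfig(depth = 2, baseFilters = 3, seed = 21)
  m <- jitterBiases(buildUnet(cfg))
  set.seed(5)
  H <- 8; W <- 8
  x <- matrix(runif(2 * H * W), 2, H * W)
  z <- refUnetForward(m@params, cfg, x, H, W)
  pRef <- apply(z, 2, function(col) exp(col - max(col)) /
                                     sum(exp(col - max(col))))
  pCpp <- muscleseg:::cpp_unet_predict(m@params,
                                       muscleseg:::.archVector(cfg),
                                       x, H, W, 0L)
  expect_equal(pCpp, pRef, tolerance = 1e-5)
})

test_that("analytic gradients agree with central differences for both heads", {
  for (headName in c("softmax", "sigmoid")) {
    cfg <- unetConfig(depth = 2, baseFilters = 2, head = headName, seed = 9)
    m <- jitterBiases(buildUnet(cfg))
    arch <- muscleseg:::.archVector(cfg)
    head <- muscleseg:::.headCode(cfg)
    set.seed(1)
    H <- 8; W <- 8
    x <- matrix(runif(2 * H * W), 2, H * W)
    y <- sample(0:4, H * W, replace = TRUE)
    r <- muscleseg:::cpp_unet_batch_grad(m@params, arch, list(x), list(y),
                                         H, W, head)
    eps <- 1e-3
    set.seed(2)
    for (j in seq_along(m@params)) {
      for (i in sample(length(m@params[[j]]), min(4, length(m@params[[j]])))) {
        pp <- m@params
        pp[[j]][i] <- pp[[j]][i] + eps
        lp <- muscleseg:::cpp_unet_batch_loss(pp, arch, list(x), list(y),
                                              H, W, head)
        pp[[j]][i] <- pp[[j]][i] - 2 * eps
        lm <- muscleseg:::cpp_unet_batch_loss(pp, arch, list(x), list(y),
                                              H, W, head)
        num <- (lp - lm) / (2 * eps)
        ana <- r$grads[[j]][i]
        # tolerance reflects single-precision forward evaluations
        expect_lt(abs(num - ana), 5e-3 + 0.02 * (abs(num) + abs(ana)))
      }
    }
  }
})

test_that("training overfits one slice, is a no-op at zero epochs, and reproduces", {
  ph <- generatePhantom(tinySpec(noiseSigma = 0.02, side = "left",
                                 gridShape = c(16L, 16L, 1L),
                                 thighRadius = 7, skinThickness = 1,
                                 subcutFatThickness = 1.5, boneRadius = 1))
  sample1 <- list(x = rbind(as.vector(waterImage(ph$volume)) / 100,
                            as.vector(fatImage(ph$volume)) / 100),
                  y = as.integer(labelArray(ph$labels)),
                  volumeId = 1, sliceIndex = 1, H = 16L, W = 16L)
  cfg <- unetConfig(depth = 2, baseFilters = 4, epochs = 50,
                    learningRate = 3e-3, seed = 7)
  m0 <- buildUnet(cfg)
  expect_identical(trainUnet(m0, list(sample1), list(sample1),
                             unetConfig(epochs = 0)), m0)
  m1 <- trainUnet(m0, list(sample1), list(sample1))
  expect_lt(m1@log$train_loss[50], 0.3 * m1@log$train_loss[1])
  m2 <- trainUnet(m0, list(sample1), list(sample1))
  expect_identical(m1@log, m2@log)
  expect_identical(m1@params, m2@params)
  expect_error(trainUnet(m0, list(), list(sample1)), "nonempty")
})

test_that("checkpoints round-trip with bit-identical predictions", {
  cfg <- unetConfig(depth = 2, baseFilters = 2, seed = 4)
  m <- jitterBiases(buildUnet(cfg))
  path <- tempfile(fileext = ".json")
  saveUnet(m, path)
  m2 <- loadUnet(path)
  expect_identical(m2@params, m@params)
  v <- fatWaterVolume(array(runif(64), c(8, 8, 1)),
                      array(runif(64), c(8, 8, 1)))
  expect_identical(labelArray(predictVolume(m, v)),
                   labelArray(predictVolume(m2, v)))
})
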