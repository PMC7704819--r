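# Independent oracles used across the suite. These deliberately re-derive
# results by brute force or via a different library route than the
# implementation under test.

# small phantom spec that fits a 32x32 half grid
tinySpec <- function(...) {
  args <- list(gridShape = c(32L, 64L, 2L), spacing = c(1, 1, 6),
               thighRadius = 13, skinThickness = 1.2,
               subcutFatThickness = 3, boneRadius = 2)
  do.call(phantomSpec, utils::modifyList(args, list(...)))
}

tinyDist <- function() {
  cohortDistribution(thighRadiusRange = c(12, 13), subcutRange = c(2.5, 3.5),
                     maxShift = 1, maxRotation = 5)
}

tinyPipelineConfig <- function(seed = 1L, out = NULL, epochs = 2L,
                               nTrain = 3L, nTest = 2L, repeats = 1L) {
  pipelineConfig(
    seed = seed, out = out,
    phantom = list(nTrainSubjects = nTrain, nTestSubjects = nTest,
                   testRepeats = repeats, baseSpec = tinySpec(),
                   dist = tinyDist()),
    unet = list(depth = 2L, baseFilters = 4L, epochs = epochs,
                learningRate = 1e-3))
}

# brute-force Dice by explicit voxel loops
diceOracle <- function(a, b, roi) {
  A <- labelArray(a); B <- labelArray(b)
  inter <- 0L; nA <- 0L; nB <- 0L
  for (i in seq_along(A)) {
    ia <- A[i] == roi; ib <- B[i] == roi
    nA <- nA + ia; nB <- nB + ib; inter <- inter + (ia && ib)
  }
  if (nA + nB == 0) return(1)
  2 * inter / (nA + nB)
}

# queue-based flood fill, independent of the C++ labelling
floodFillOracle <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- offs[rowSums(abs(offs)) > 0, ]
  if (connectivity == 6) offs <- offs[rowSums(abs(offs)) == 1, ]
  if (connectivity == 18) offs <- offs[rowSums(abs(offs)) <= 2, ]
  lab <- array(0L, d)
  nlab <- 0L
  sizes <- integer()
  idx <- which(mask)
  for (start in idx) {
    if (lab[start] != 0L) next
    nlab <- nlab + 1L
    queue <- start
    lab[start] <- nlab
    sz <- 0L
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      sz <- sz + 1L
      z <- (v - 1) %/% (d[1] * d[2])
      r <- (v - 1) %% (d[1] * d[2])
      y <- r %/% d[1]; x <- r %% d[1]
      for (k in seq_len(nrow(offs))) {
        xx <- x + offs$dx[k]; yy <- y + offs$dy[k]; zz <- z + offs$dz[k]
        if (xx < 0 || xx >= d[1] || yy < 0 || yy >= d[2] ||
            zz < 0 || zz >= d[3]) next
        u <- xx + d[1] * (yy + d[2] * zz) + 1
        if (mask[u] && lab[u] == 0L) {
          lab[u] <- nlab
          queue <- c(queue, u)
        }
      }
    }
    sizes <- c(sizes, sz)
  }
  list(labels = lab, sizes = sizes)
}

# ICC oracle: mean squares via stats::aov, then the textbook formulas
iccOracle <- function(tab, model = "ICC(2,1)") {
  n <- nrow(tab); k <- ncol(tab)
  df <- data.frame(y = as.vector(tab),
                   subj = factor(rep(seq_len(n), k)),
                   rater = factor(rep(seq_len(k), each = n)))
  av <- summary(stats::aov(y ~ subj + rater, data = df))[[1]]
  msr <- av["subj", "Mean Sq"]
  msc <- av["rater", "Mean Sq"]
  mse <- av["Residuals", "Mean Sq"]
  if (model == "ICC(2,1)") {
    (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  } else {
    (msr - mse) / (msr + (k - 1) * mse)
  }
}

# Welch t-test from first principles (formula + t CDF)
welchOracle <- function(a, b) {
  va <- stats::var(a) / length(a); vb <- stats::var(b) / length(b)
  t <- (mean(b) - mean(a)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = stats::pt(t, df, lower.tail = FALSE))
}

# reference U-net forward in plain R (double precision), mirroring the
# declared architecture and the q*C + c kernel-column layout
refUnetForward <- function(params, cfg, x, H, W) {
  im2col3 <- function(X, H, W) {
    C <- nrow(X)
    K <- matrix(0, C * 9, H * W)
    for (dy in -1:1) for (dx in -1:1) {
      q <- (dy + 1) * 3 + (dx + 1)
      for (y in 0:(W - 1)) {
        ys <- y + dy
        if (ys < 0 || ys >= W) next
        for (x0 in 0:(H - 1)) {
          xs <- x0 + dx
          if (xs < 0 || xs >= H) next
          K[q * C + seq_len(C), x0 + H * y + 1] <- X[, xs + H * ys + 1]
        }
      }
    }
    K
  }
  conv3 <- function(X, H, W, Wm, b) {
    Y <- Wm %*% im2col3(X, H, W) + b
    Y[Y < 0] <- 0
    Y
  }
  pool2 <- function(X, H, W) {
    Ho <- H / 2; Wo <- W / 2
    Y <- matrix(0, nrow(X), Ho * Wo)
    for (y in 0:(Wo - 1)) for (x0 in 0:(Ho - 1)) {
      p00 <- 2 * x0 + H * (2 * y)
      cand <- c(p00, p00 + 1, p00 + H, p00 + H + 1) + 1
      Y[, x0 + Ho * y + 1] <- apply(X[, cand, drop = FALSE], 1, max)
    }
    Y
  }
  up2 <- function(X, H, W) {
    Ho <- 2 * H; Wo <- 2 * W
    Y <- matrix(0, nrow(X), Ho * Wo)
    for (y in 0:(Wo - 1)) for (x0 in 0:(Ho - 1))
      Y[, x0 + Ho * y + 1] <- X[, (x0 %/% 2) + H * (y %/% 2) + 1]
    Y
  }
  d <- cfg$depth
  cur <- x; h <- H; w <- W
  skips <- list()
  for (i in 1:d) {
    cur <- conv3(cur, h, w, params[[sprintf("enc%d_convA_W", i)]],
                 params[[sprintf("enc%d_convA_b", i)]])
    cur <- conv3(cur, h, w, params[[sprintf("enc%d_convB_W", i)]],
                 params[[sprintf("enc%d_convB_b", i)]])
    skips[[i]] <- cur
    cur <- pool2(cur, h, w); h <- h / 2; w <- w / 2
  }
  cur <- conv3(cur, h, w, params$bottleneck_convA_W,
               params$bottleneck_convA_b)
  cur <- conv3(cur, h, w, params$bottleneck_convB_W,
               params$bottleneck_convB_b)
  for (i in d:1) {
    cur <- up2(cur, h, w); h <- h * 2; w <- w * 2
    cur <- conv3(cur, h, w, params[[sprintf("dec%d_up_W", i)]],
                 params[[sprintf("dec%d_up_b", i)]])
    cur <- rbind(skips[[i]], cur)
    cur <- conv3(cur, h, w, params[[sprintf("dec%d_convA_W", i)]],
                 params[[sprintf("dec%d_convA_b", i)]])
    cur <- conv3(cur, h, w, params[[sprintf("dec%d_convB_W", i)]],
                 params[[sprintf("dec%d_convB_b", i)]])
  }
  params$out_W %*% cur + params$out_b
}

# random label volume with speckle
randomSpeckle <- function(dim = c(10L, 10L, 4L), p = 0.2) {
  arr <- array(0L, dim)
  n <- prod(dim)
  lab <- sample(0:4, n, replace = TRUE, prob = c(1 - p, rep(p / 4, 4)))
  array(as.integer(lab), dim)
}

# inject small nonzero biases so pre-activations sit away from the ReLU
# kink (zero-init biases put dead windows exactly at the kink, where
# central differences and subgradients legitimately disagree)
jitterBiases <- function(model, sd = 0.1, seed = 42) {
  withr::with_seed(seed, {
    for (j in grep("_b$", names(model@params))) {
      model@params[[j]] <- stats::rnorm(length(model@params[[j]]), 0, sd)
    }
  })
  model
}
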