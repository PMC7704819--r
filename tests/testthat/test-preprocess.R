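test_that("bilateral volumes split at the midline with the documented convention", {
  ph <- generatePhantom(phantomSpec(noiseSigma = 0))
  halves <- splitThighs(ph$volume)
  expect_identical(dim(halves$left), c(64L, 64L, 12L))
  expect_identical(dim(halves$right), c(64L, 64L, 12L))
  expect_identical(sideLabel(halves$left), "left")
  expect_identical(sideLabel(halves$right), "right")

  # odd extent: the extra column goes to the right half
  w <- array(runif(8 * 129 * 2), c(8, 129, 2))
  v <- fatWaterVolume(w, w, side = "bilateral")
  h2 <- splitThighs(v)
  expect_identical(dim(h2$left)[2], 64L)
  expect_identical(dim(h2$right)[2], 65L)

  # non-bilateral input is a no-op with a warning
  expect_warning(out <- splitThighs(halves$left), "not bilateral")
  expect_identical(out, halves$left)
})

test_that("split halves of a noise-free phantom are reflections of each other", {
  ph <- generatePhantom(phantomSpec(noiseSigma = 0))
  halves <- splitThighs(ph$volume)
  wl <- waterImage(halves$left)
  wr <- waterImage(halves$right)
  expect_identical(wl, wr[, rev(seq_len(dim(wr)[2])), ])
})

test_that("two-intensity disc: mask equals the brute-force morphology oracle", {
  # inner disc (muscle analogue, 100) surrounded by a ring (fat analogue, 10)
  n <- 48L
  cx <- 24.5
  dist <- sqrt(outer((1:n - cx)^2, (1:n - cx)^2, "+"))
  sl <- matrix(0, n, n)
  sl[dist <= 20] <- 10
  sl[dist <= 14] <- 100
  vol <- array(sl, c(n, n, 2))
  cfg <- preprocessConfig()
  m <- maskArray(muscleMaskFromWater(vol, cfg))[, , 1]

  # oracle: rank filter by explicit neighbourhood counting, then fill
  # (disc has no holes), then dilation by explicit distance check
  disc <- sl == 100
  cnt <- matrix(0L, n, n)
  for (i in 1:n) for (j in 1:n) {
    xs <- max(1, i - 2):min(n, i + 2)
    ys <- max(1, j - 2):min(n, j + 2)
    win <- sum(disc[xs, ys])  # zero-padded border: missing cells count 0
    cnt[i, j] <- win
  }
  eroded <- cnt >= (25 - cfg$ostatRank + 1)
  expected <- matrix(FALSE, n, n)
  er <- which(eroded, arr.ind = TRUE)
  for (i in 1:n) for (j in 1:n) {
    d2 <- (er[, 1] - i)^2 + (er[, 2] - j)^2
    expected[i, j] <- any(d2 <= cfg$dilationRadius^2)
  }
  expect_identical(m, expected)
})

test_that("phantom muscle is retained and subcutaneous fat removed", {
  ph <- generatePhantom(phantomSpec(noiseSigma = 0, side = "left",
                                    gridShape = c(64L, 64L, 4L)))
  m <- maskArray(muscleMaskFromWater(ph$volume))
  expect_gte(mean(m[ph$tissues == 3]), 0.99)
  # margin-excluded subcutaneous voxels (beyond the dilation reach)
  t1 <- ph$tissues[, , 1]; m1 <- m[, , 1]
  mus <- which(t1 == 3, arr.ind = TRUE)
  sub <- which(t1 == 2, arr.ind = TRUE)
  d2 <- outer(sub[, 1], mus[, 1], "-")^2 + outer(sub[, 2], mus[, 2], "-")^2
  far <- sqrt(apply(d2, 1, min)) > preprocessConfig()$dilationRadius + 1
  expect_gte(1 - mean(m1[sub[far, , drop = FALSE]]), 0.95)
})

test_that("masking obeys identity, annihilation, subset and idempotence", {
  set.seed(8)
  v <- fatWaterVolume(array(runif(64), c(4, 4, 4)),
                      array(runif(64), c(4, 4, 4)))
  ones <- new("MuscleRegionMask", mask = array(TRUE, c(4, 4, 4)),
              provenance = "all")
  zeros <- new("MuscleRegionMask", mask = array(FALSE, c(4, 4, 4)),
               provenance = "none")
  expect_identical(waterImage(applyMask(v, ones)), waterImage(v))
  expect_true(all(waterImage(applyMask(v, zeros)) == 0))
  rnd <- array(runif(64) > 0.5, c(4, 4, 4))
  masked <- applyMask(v, rnd)
  expect_true(all(waterImage(masked)[!rnd] == 0))
  expect_true(all(fatImage(masked)[!rnd] == 0))
  expect_identical(applyMask(masked, rnd), masked)
  expect_error(applyMask(v, array(TRUE, c(2, 2, 2))), "grid")
})

test_that("mask extraction is invariant to positive affine rescaling of water", {
  ph <- generatePhantom(tinySpec(noiseSigma = 0.02, seed = 3))
  w <- waterImage(splitThighs(ph$volume)$left)
  m1 <- maskArray(muscleMaskFromWater(w))
  m2 <- maskArray(muscleMaskFromWater(3.7 * w + 11))
  expect_identical(m1, m2)
})

test_that("dilation radius is monotone: smaller radius gives a subset mask", {
  ph <- generatePhantom(tinySpec(noiseSigma = 0.02, seed = 4))
  w <- waterImage(splitThighs(ph$volume)$left)
  m1 <- maskArray(muscleMaskFromWater(w, preprocessConfig(dilationRadius = 1)))
  m3 <- maskArray(muscleMaskFromWater(w, preprocessConfig(dilationRadius = 3)))
  expect_true(all(m3[m1]))
})

test_that("degenerate water fields are rejected", {
  expect_error(muscleMaskFromWater(array(5, c(4, 4, 2))), "constant")
  expect_error(muscleMaskFromWater(array(0, c(4, 4, 2))), "constant")
  two <- array(rep(c(0, 7), 16), c(4, 4, 2))
  expect_error(muscleMaskFromWater(two, preprocessConfig(kmeansClusters = 3)),
               "degenerate")
})
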