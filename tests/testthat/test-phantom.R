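test_that("noise-free phantom realises the prescribed fat fractions exactly", {
  spec <- phantomSpec(noiseSigma = 0, roiFatFraction = c(0.30, 0.1, 0.2, 0.4))
  ph <- generatePhantom(spec)
  w <- waterImage(ph$volume); f <- fatImage(ph$volume)
  L <- labelArray(ph$labels)
  ff <- f / (w + f)
  expect_equal(mean(ff[L == 1]), 0.30, tolerance = 1e-12)
  for (r in 2:4) {
    expect_equal(mean(ff[L == r]), spec@roiFatFraction[r], tolerance = 1e-12)
  }
  # subcutaneous ring fat-dominant, skin low in both channels
  sub <- ph$tissues == 2; skin <- ph$tissues == 1
  expect_gt(mean(ff[sub]), 0.5)
  expect_lt(max(w[skin]), max(w[L > 0]) / 2)
  expect_lt(max(f[skin]), max(f[sub]) / 2)
})

test_that("zero fat fraction everywhere gives an exactly zero fat channel in muscle", {
  ph <- generatePhantom(phantomSpec(noiseSigma = 0,
                                    roiFatFraction = rep(0, 4)))
  fat <- fatImage(ph$volume)
  expect_true(all(fat[ph$tissues == 3] == 0))
})

test_that("phantom generation is bit-identical under a fixed seed", {
  spec <- phantomSpec(noiseSigma = 0.05, seed = 123L)
  a <- generatePhantom(spec)
  b <- generatePhantom(spec)
  expect_identical(waterImage(a$volume), waterImage(b$volume))
  expect_identical(fatImage(a$volume), fatImage(b$volume))
  expect_identical(labelArray(a$labels), labelArray(b$labels))
})

test_that("bilateral thighs are mirror images before noise", {
  ph <- generatePhantom(phantomSpec(noiseSigma = 0))
  for (a in list(waterImage(ph$volume), fatImage(ph$volume),
                 labelArray(ph$labels))) {
    expect_identical(a, a[, rev(seq_len(dim(a)[2])), ])
  }
})

test_that("ground-truth meanFF increases strictly with the prescribed FF", {
  ffs <- c(0.05, 0.2, 0.5, 0.8)
  means <- vapply(ffs, function(v) {
    ph <- generatePhantom(phantomSpec(noiseSigma = 0,
                                      roiFatFraction = c(v, 0.1, 0.1, 0.1)))
    ffm <- fatFractionMap(ph$volume)
    roiStats(ffm, ph$labels, 1)$mean_ff_percent
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("inconsistent geometry is rejected with the offending pair named", {
  expect_error(phantomSpec(boneRadius = 25), "boneRadius")
  expect_error(phantomSpec(skinThickness = 20, subcutFatThickness = 10),
               "thighRadius")
  expect_error(phantomSpec(roiFatFraction = c(0.2, 0.2, 0.2, 1.5)),
               "roiFatFraction")
  bad <- defaultRoiGeometry()
  bad[[2]]$theta <- c(100, 180)  # overlaps ROI1's sector
  expect_error(phantomSpec(roiGeometry = bad), "ROI1 vs ROI2")
})

test_that("cohort generation yields the requested layout and shares anatomy within subject", {
  coh <- generateCohort(3, 3, dist = tinyDist(), baseSpec = tinySpec(),
                        seed = 5)
  expect_length(coh, 9L)
  ids <- vapply(coh, `[[`, character(1), "subjectId")
  expect_length(unique(ids), 3L)
  reps <- split(coh, ids)
  for (rs in reps) {
    ffs <- t(vapply(rs, `[[`, numeric(4), "trueFF"))
    expect_true(all(apply(ffs, 2, function(x) length(unique(x)) == 1)))
  }
})

test_that("repeats with zero repositioning and zero noise have identical ground truth", {
  dist0 <- cohortDistribution(thighRadiusRange = c(13, 13),
                              subcutRange = c(3, 3),
                              maxShift = 0, maxRotation = 0)
  base <- tinySpec(noiseSigma = 0)
  coh <- generateCohort(1, 3, dist = dist0, baseSpec = base, seed = 2)
  mff <- lapply(coh, function(rec) {
    ffm <- fatFractionMap(rec$volume)
    vapply(1:4, function(r) roiStats(ffm, rec$labels, r)$mean_ff_percent,
           numeric(1))
  })
  expect_equal(mff[[1]], mff[[2]])
  expect_equal(mff[[2]], mff[[3]])
})

test_that("cohort draws replay exactly under a fixed seed", {
  a <- generateCohort(5, 2, dist = tinyDist(), baseSpec = tinySpec(),
                      seed = 77)
  b <- generateCohort(5, 2, dist = tinyDist(), baseSpec = tinySpec(),
                      seed = 77)
  expect_identical(lapply(a, `[[`, "trueFF"), lapply(b, `[[`, "trueFF"))
  expect_identical(waterImage(a[[7]]$volume), waterImage(b[[7]]$volume))
})
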