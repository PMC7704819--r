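test_that("Dice matches the brute-force counting oracle on random masks", {
  set.seed(41)
  for (rep in 1:10) {
    a <- muscleLabelVolume(randomSpeckle(c(6L, 6L, 3L), 0.3))
    b <- muscleLabelVolume(randomSpeckle(c(6L, 6L, 3L), 0.3))
    for (roi in 1:4) {
      expect_identical(dice(a, b, roi), diceOracle(a, b, roi))
      expect_identical(dice(a, b, roi), dice(b, a, roi))  # symmetry
    }
    expect_identical(dice(a, a, 1), 1)
  }
})

test_that("Dice handles identity, disjoint and empty masks per convention", {
  L1 <- array(0L, c(4, 4, 2)); L1[1:2, 1, 1] <- 1L
  L2 <- array(0L, c(4, 4, 2)); L2[3:4, 4, 2] <- 1L
  a <- muscleLabelVolume(L1); b <- muscleLabelVolume(L2)
  expect_identical(dice(a, a, 1), 1)
  expect_identical(dice(a, b, 1), 0)
  expect_message(d0 <- dice(a, b, 2), "both")  # ROI2 empty in both
  expect_identical(d0, 1.0)
  expect_error(dice(a, muscleLabelVolume(array(0L, c(2, 2, 2))), 1), "grids")
  # known overlap: |A| = 6, |B| = 4, intersection 3
  A <- array(0L, c(4, 4, 2)); A[1:6] <- 3L
  B <- array(0L, c(4, 4, 2)); B[4:7] <- 3L
  expect_equal(dice(muscleLabelVolume(A), muscleLabelVolume(B), 3), 0.6)
})

test_that("percent volume difference is signed and flags a zero reference", {
  expect_equal(percentVolumeDiff(100, 100), 0)
  expect_equal(percentVolumeDiff(100, 110), 10)
  expect_equal(percentVolumeDiff(200, 150), -25)
  expect_warning(na <- percentVolumeDiff(0, 5), "zero")
  expect_true(is.na(na))
})

test_that("ICC matches the ANOVA mean-squares oracle on random tables", {
  set.seed(53)
  for (rep in 1:10) {
    n <- sample(4:10, 1); k <- sample(2:4, 1)
    tab <- matrix(rnorm(n * k, 10, 3), n, k) +
      rnorm(n, 0, 2)  # subject effect
    for (model in c("ICC(2,1)", "ICC(3,1)")) {
      r <- iccMeanFF(tab, model = model)
      expect_equal(r@estimate, iccOracle(tab, model), tolerance = 1e-10)
      expect_lte(r@estimate, 1)
      expect_gte(r@ci[2], r@estimate)
      expect_lte(r@ci[1], r@estimate)
      # shift invariance
      expect_equal(iccMeanFF(tab + 100, model = model)@estimate,
                   r@estimate, tolerance = 1e-8)
    }
  }
})

test_that("ICC degenerate and perfect-repeatability cases follow the declared rules", {
  perfect <- cbind(c(1, 2, 3, 4), c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(iccMeanFF(perfect)@estimate, 1.0)
  expect_equal(iccMeanFF(perfect, model = "ICC(3,1)")@estimate, 1.0)
  flat <- matrix(7, 4, 3)
  r <- iccMeanFF(flat)
  expect_true(r@degenerate)
  expect_true(is.na(r@estimate))
  expect_error(iccMeanFF(matrix(1:4, 2, 2) * NA), "complete")
  expect_error(iccMeanFF(matrix(1:3, 3, 1)), "at least 2")
})

test_that("Welch test matches the first-principles computation", {
  set.seed(67)
  for (rep in 1:10) {
    a <- rnorm(sample(3:8, 1), 10, 2)
    b <- rnorm(sample(3:8, 1), 12, 4)
    got <- welchTOneTailed(a, b, "greater")
    want <- welchOracle(a, b)
    expect_equal(got$t, want$t, tolerance = 1e-10)
    expect_equal(got$df, want$df, tolerance = 1e-10)
    expect_equal(got$p, want$p, tolerance = 1e-10)
    # swapping groups with the reversed direction gives the same p
    expect_equal(welchTOneTailed(b, a, "less")$p, got$p, tolerance = 1e-12)
  }
})

test_that("Welch p-value behaves at the null and decreases with separation", {
  g <- c(3, 4, 5, 6)
  expect_equal(welchTOneTailed(g, g, "greater")$p, 0.5)
  shifts <- c(0.5, 1, 2, 4, 8)
  ps <- vapply(shifts, function(s)
    welchTOneTailed(g, g + s, "greater")$p, numeric(1))
  expect_true(all(diff(ps) < 0))
  expect_warning(r <- welchTOneTailed(c(2, 2), c(2, 2)), "undefined")
  expect_true(is.na(r$p))
})

test_that("test-set evaluation aggregates repeats before cohort means", {
  # one thigh, three identical repeats: aggregated row equals any single row
  ph <- generatePhantom(tinySpec(noiseSigma = 0, side = "left",
                                 gridShape = c(32L, 32L, 2L)))
  rec <- list(manual = ph$labels, auto = ph$labels, volume = ph$volume,
              subjectId = "T1", repeatId = 1L)
  reps <- lapply(1:3, function(r) { rec$repeatId <- r; rec })
  rep1 <- evaluateTestset(reps)
  expect_identical(nrow(rep1$per_thigh), 4L)
  expect_equal(rep1$per_thigh$dice, rep(1, 4))
  expect_equal(rep1$summary$mean_abs_pct_volume_diff, 0)
  expect_equal(rep1$summary$mean_abs_meanff_diff_pp, 0)

  # unequal repeat counts: cohort mean weights thighs, not scans
  L <- array(0L, c(4, 4, 2)); L[1:2, 1:2, ] <- 1L
  Lsmall <- array(0L, c(4, 4, 2)); Lsmall[1:2, 1, ] <- 1L
  v <- fatWaterVolume(array(1, c(4, 4, 2)), array(1, c(4, 4, 2)))
  mk <- function(id, rep, auto) list(manual = muscleLabelVolume(L),
                                     auto = muscleLabelVolume(auto),
                                     volume = v, subjectId = id,
                                     repeatId = rep)
  pairs <- list(mk("A", 1, L), mk("A", 2, L), mk("A", 3, L),
                mk("B", 1, Lsmall))
  # ROIs 2-4 are empty in this fixture: zero-volume warnings are expected
  out <- suppressWarnings(suppressMessages(evaluateTestset(pairs)))
  thighA <- out$per_thigh[out$per_thigh$subject_id == "A" &
                          out$per_thigh$roi == 1, ]
  thighB <- out$per_thigh[out$per_thigh$subject_id == "B" &
                          out$per_thigh$roi == 1, ]
  expect_equal(thighA$dice, 1)
  expect_equal(thighB$dice, 2 * 4 / (8 + 4))
  roi1 <- out$per_thigh[out$per_thigh$roi == 1, ]
  expect_equal(mean(abs(roi1$pct_volume_diff)),
               mean(c(0, abs(percentVolumeDiff(8, 4)))))
})

test_that("eroded predictions reproduce a hand-computed report on a small fixture", {
  # ROI1: 3x3x2 block; auto = manual eroded by one voxel ring -> 1x1x2
  L <- array(0L, c(8, 8, 2)); L[2:4, 2:4, ] <- 1L
  Le <- array(0L, c(8, 8, 2)); Le[3, 3, ] <- 1L
  w <- array(3, c(8, 8, 2)); f <- array(1, c(8, 8, 2))  # uniform ff 0.25
  # only ROI1 is populated; the other ROIs trigger expected empty warnings
  out <- suppressWarnings(suppressMessages(
    evaluateTestset(list(list(manual = muscleLabelVolume(L),
                              auto = muscleLabelVolume(Le),
                              volume = fatWaterVolume(w, f),
                              subjectId = "S", repeatId = 1L)))))
  r1 <- out$per_scan[out$per_scan$roi == 1, ]
  expect_equal(r1$dice, 2 * 2 / (18 + 2))
  expect_equal(r1$pct_volume_diff, (2 - 18) / 18 * 100)
  expect_equal(r1$manual_meanff, 25)
  expect_equal(r1$auto_meanff, 25)
  expect_equal(r1$meanff_diff_pp, 0)
})
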