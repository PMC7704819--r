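#' Volumetric Dice coefficient of one ROI
#'
#' \code{2 |A intersect B| / (|A| + |B|)} over the 3D voxel sets of
#' \code{roi} in the two label volumes. When both masks are empty the
#' overlap is vacuously perfect and 1.0 is returned (with a message);
#' empty-versus-nonempty still yields 0.
#'
#' @param a,b [MuscleLabelVolume-class] objects on the same grid.
#' @param roi ROI id in 1..4.
#' @return Dice coefficient in [0, 1].
#' @examples
#' L <- array(0L, c(4, 4, 1)); L[1:2, 1, 1] <- 1L
#' dice(muscleLabelVolume(L), muscleLabelVolume(L), 1)  # 1
#' @export
dice <- function(a, b, roi) {
  if (!identical(dim(a), dim(b))) stop("label grids differ")
  A <- labelArray(a) == roi
  B <- labelArray(b) == roi
  nA <- sum(A); nB <- sum(B)
  if (nA + nB == 0L) {
    message("ROI ", roi, " empty in both volumes; Dice defined as 1")
    return(1.0)
  }
  2 * sum(A & B) / (nA + nB)
}

#' Signed percent difference in volume
#'
#' \code{(auto - manual) / manual * 100}; absolute values are taken only
#' when aggregating across a cohort.
#'
#' @param manual_mm3 reference (manual) volume, > 0.
#' @param auto_mm3 automated volume.
#' @return signed percent difference (NA with a warning when the reference
#'   volume is zero).
#' @export
percentVolumeDiff <- function(manual_mm3, auto_mm3) {
  if (manual_mm3 == 0) {
    warning("manual volume is zero; percent difference undefined")
    return(NA_real_)
  }
  (auto_mm3 - manual_mm3) / manual_mm3 * 100
}

# two-way ANOVA mean squares of a complete subjects x repeats table
.iccMeanSquares <- function(tab) {
  n <- nrow(tab); k <- ncol(tab)
  grand <- mean(tab)
  rowM <- rowMeans(tab); colM <- colMeans(tab)
  ssRow <- k * sum((rowM - grand)^2)
  ssCol <- n * sum((colM - grand)^2)
  ssTot <- sum((tab - grand)^2)
  ssErr <- ssTot - ssRow - ssCol
  list(msr = ssRow / (n - 1), msc = ssCol / (k - 1),
       mse = ssErr / ((n - 1) * (k - 1)), n = n, k = k)
}

#' Intraclass correlation of repeated meanFF measurements
#'
#' Single-measure ICC of a complete subjects-by-repeats table from the
#' classical two-way ANOVA decomposition, quantifying scan-rescan
#' reproducibility. The default model is ICC(2,1) — two-way random
#' effects, absolute agreement, single measure — appropriate when repeated
#' scans with repositioning are a random factor and absolute agreement is
#' what reproducibility means. ICC(3,1) (consistency) is selectable.
#' 95\% confidence bounds follow the standard F-distribution construction
#' (McGraw & Wong).
#'
#' @param table numeric matrix or data.frame, rows = subjects, columns =
#'   repeated measurements; must be complete with >= 2 rows and columns.
#' @param model \code{"ICC(2,1)"} (default) or \code{"ICC(3,1)"}.
#' @param conf confidence level (default 0.95).
#' @return An [IccResult-class]. With zero between-subject variance the
#'   decomposition is degenerate and the result is flagged (estimate NA).
#' @examples
#' tab <- cbind(c(1, 2, 3, 4), c(1, 2, 3, 4))  # perfect repeatability
#' iccMeanFF(tab)
#' @export
iccMeanFF <- function(table, model = c("ICC(2,1)", "ICC(3,1)"),
                      conf = 0.95) {
  model <- match.arg(model)
  tab <- as.matrix(table)
  if (anyNA(tab)) stop("ICC table must be complete (no missing cells)")
  if (nrow(tab) < 2 || ncol(tab) < 2) {
    stop("need at least 2 subjects and 2 repeats")
  }
  ms <- .iccMeanSquares(tab)
  n <- ms$n; k <- ms$k
  alpha <- 1 - conf

  totVar <- ms$msr + ms$msc + ms$mse
  if (totVar == 0 || (ms$msr == 0 && stats::var(as.vector(tab)) == 0)) {
    return(new("IccResult", estimate = NA_real_, ci = c(NA_real_, NA_real_),
               model = model, nSubjects = as.integer(n),
               nRepeats = as.integer(k), degenerate = TRUE))
  }

  if (model == "ICC(2,1)") {
    den <- ms$msr + (k - 1) * ms$mse + k * (ms$msc - ms$mse) / n
    est <- (ms$msr - ms$mse) / den
    # McGraw & Wong F-based bounds for ICC(A,1)
    a <- k * est / (n * (1 - est))
    b <- 1 + k * est * (n - 1) / (n * (1 - est))
    v <- (a * ms$msc + b * ms$mse)^2 /
      ((a * ms$msc)^2 / (k - 1) + (b * ms$mse)^2 / ((n - 1) * (k - 1)))
    fL <- stats::qf(1 - alpha / 2, n - 1, v)
    fU <- stats::qf(1 - alpha / 2, v, n - 1)
    lo <- n * (ms$msr - fL * ms$mse) /
      (fL * (k * ms$msc + (k * n - k - n) * ms$mse) + n * ms$msr)
    hi <- n * (fU * ms$msr - ms$mse) /
      (k * ms$msc + (k * n - k - n) * ms$mse + n * fU * ms$msr)
    if (ms$mse == 0 && ms$msc == 0) { est <- 1; lo <- 1; hi <- 1 }
  } else {
    est <- (ms$msr - ms$mse) / (ms$msr + (k - 1) * ms$mse)
    if (ms$mse == 0) {
      est <- 1; lo <- 1; hi <- 1
    } else {
      f0 <- ms$msr / ms$mse
      df2 <- (n - 1) * (k - 1)
      fL <- f0 / stats::qf(1 - alpha / 2, n - 1, df2)
      fU <- f0 * stats::qf(1 - alpha / 2, df2, n - 1)
      lo <- (fL - 1) / (fL + k - 1)
      hi <- (fU - 1) / (fU + k - 1)
    }
  }
  new("IccResult", estimate = est, ci = c(min(lo, est), max(hi, est)),
      model = model, nSubjects = as.integer(n), nRepeats = as.integer(k),
      degenerate = FALSE)
}

#' One-tailed two-sample Welch t-test
#'
#' Welch's t statistic with Welch-Satterthwaite degrees of freedom (unequal
#' variances assumed), one-tailed: \code{direction = "greater"} tests
#' whether group B (e.g. thighs with fat infiltration) has larger mean
#' than group A (e.g. normal thighs). Significance is conventionally read
#' at p < 0.05.
#'
#' @param group_a,group_b numeric vectors of meanFF values, each n >= 2.
#' @param direction \code{"greater"} (mean B > mean A) or \code{"less"}.
#' @return list with \code{t}, \code{df}, \code{p}.
#' @examples
#' welchTOneTailed(c(3, 4, 5), c(8, 9, 10))$p
#' @export
welchTOneTailed <- function(group_a, group_b,
                            direction = c("greater", "less")) {
  direction <- match.arg(direction)
  stopifnot(length(group_a) >= 2, length(group_b) >= 2)
  if (stats::var(group_a) == 0 && stats::var(group_b) == 0 &&
      mean(group_a) == mean(group_b)) {
    warning("both groups constant and equal; p undefined")
    return(list(t = NA_real_, df = NA_real_, p = NA_real_))
  }
  tt <- stats::t.test(group_b, group_a, alternative = direction,
                      var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}

#' Evaluate automated against manual segmentation over a test set
#'
#' Computes, for every (thigh volume, ROI) pair: the volumetric Dice
#' coefficient, manual and automated volume with their signed percent
#' difference, and manual and automated meanFF with their difference in
#' percentage points. Rows of repeated scans of one thigh are averaged
#' per thigh before any cohort mean, so subjects scanned several times do
#' not dominate, and the cohort summary reports means of the aggregated
#' absolute differences.
#'
#' @param pairs list of records with elements \code{manual} and \code{auto}
#'   ([MuscleLabelVolume-class]), \code{volume} ([FatWaterVolume-class],
#'   original intensities), \code{subjectId} and \code{repeatId}.
#' @return list with \code{per_scan} (one row per scan x ROI),
#'   \code{per_thigh} (repeated scans averaged), and \code{summary}
#'   (cohort means: Dice, mean absolute percent volume difference, mean
#'   absolute meanFF difference in percentage points).
#' @export
evaluateTestset <- function(pairs) {
  stopifnot(length(pairs) >= 1)
  rows <- list()
  for (rec in pairs) {
    ffmap <- fatFractionMap(rec$volume)
    for (roi in 1:4) {
      sM <- roiStats(ffmap, rec$manual, roi)
      sA <- roiStats(ffmap, rec$auto, roi)
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = rec$subjectId, repeat_id = rec$repeatId, roi = roi,
        dice = dice(rec$manual, rec$auto, roi),
        manual_volume_mm3 = sM$volume_mm3,
        auto_volume_mm3 = sA$volume_mm3,
        pct_volume_diff = percentVolumeDiff(sM$volume_mm3, sA$volume_mm3),
        manual_meanff = sM$mean_ff_percent,
        auto_meanff = sA$mean_ff_percent,
        meanff_diff_pp = sA$mean_ff_percent - sM$mean_ff_percent)
    }
  }
  perScan <- do.call(rbind, rows)

  num <- c("dice", "manual_volume_mm3", "auto_volume_mm3",
           "pct_volume_diff", "manual_meanff", "auto_meanff",
           "meanff_diff_pp")
  perThigh <- stats::aggregate(perScan[num],
                               by = perScan[c("subject_id", "roi")],
                               FUN = mean)
  perThigh <- perThigh[order(perThigh$subject_id, perThigh$roi), ]
  rownames(perThigh) <- NULL

  summary <- list(
    mean_dice = mean(perThigh$dice),
    mean_abs_pct_volume_diff = mean(abs(perThigh$pct_volume_diff)),
    mean_abs_meanff_diff_pp = mean(abs(perThigh$meanff_diff_pp)),
    n_thighs = nrow(unique(perThigh["subject_id"])),
    n_scans = length(pairs))

  list(per_scan = perScan, per_thigh = perThigh, summary = summary)
}
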