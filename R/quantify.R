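#' Compute a fat-fraction map
#'
#' Per-voxel fat fraction \code{fat / (water + fat)} wherever the
#' denominator is positive; voxels with zero total signal carry no fat
#' fraction and are marked undefined (they are excluded, not counted as
#' zero, in every downstream mean). Inputs are signal magnitudes and must
#' be non-negative. Fat fractions are always computed from original
#' intensities — never from channels normalized for the network.
#'
#' @param vol a [FatWaterVolume-class].
#' @return A [FatFractionMap-class].
#' @examples
#' v <- fatWaterVolume(array(3, c(2, 2, 1)), array(1, c(2, 2, 1)))
#' ffArray(fatFractionMap(v))[1, 1, 1]  # 0.25
#' @export
fatFractionMap <- function(vol) {
  w <- waterImage(vol); f <- fatImage(vol)
  if (min(w) < 0 || min(f) < 0) {
    stop("negative intensities: water and fat inputs must be magnitudes")
  }
  denom <- w + f
  defined <- denom > 0
  ff <- array(0, dim(vol))
  ff[defined] <- f[defined] / denom[defined]
  new("FatFractionMap", ff = ff, defined = defined,
      spacing = voxelSpacing(vol))
}

#' Per-ROI fat-fraction and volume statistics
#'
#' Mean fat fraction (in percent) over the defined voxels of one ROI, the
#' ROI volume from voxel count times voxel volume, and the number of
#' undefined voxels excluded from the mean. An empty ROI yields
#' \code{n_voxels = 0} and \code{NA} meanFF, with a message.
#'
#' @param ffmap a [FatFractionMap-class].
#' @param labels a [MuscleLabelVolume-class] on the same grid.
#' @param roi ROI id in 1..4.
#' @return one-row \code{data.frame} with columns \code{roi},
#'   \code{n_voxels}, \code{n_undefined}, \code{volume_mm3},
#'   \code{mean_ff_percent}.
#' @export
roiStats <- function(ffmap, labels, roi) {
  stopifnot(roi %in% 1:4)
  if (!identical(dim(ffmap), dim(labels))) {
    stop("fat-fraction map and label grids differ")
  }
  sel <- labelArray(labels) == roi
  n <- sum(sel)
  if (n == 0L) {
    message("ROI ", roi, " is empty; meanFF undefined")
    return(data.frame(roi = roi, n_voxels = 0L, n_undefined = 0L,
                      volume_mm3 = 0, mean_ff_percent = NA_real_))
  }
  def <- sel & definedMask(ffmap)
  nUndef <- n - sum(def)
  meanFF <- if (any(def)) mean(ffArray(ffmap)[def]) * 100 else NA_real_
  data.frame(roi = roi, n_voxels = n, n_undefined = nUndef,
             volume_mm3 = n * voxelVolume(labels),
             mean_ff_percent = meanFF)
}

#' Per-ROI statistics for all four ROIs
#'
#' @param vol a [FatWaterVolume-class] (original intensities).
#' @param labels a [MuscleLabelVolume-class] on the same grid.
#' @return \code{data.frame} with one row per ROI (see [roiStats()]).
#' @export
quantifyVolume <- function(vol, labels) {
  ffmap <- fatFractionMap(vol)
  do.call(rbind, lapply(1:4, function(r) roiStats(ffmap, labels, r)))
}
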