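#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib muscleseg, .registration = TRUE
NULL

setClassUnion("characterOrNULL", c("character", "NULL"))

#' FatWaterVolume: co-registered water and fat magnitude volumes
#'
#' Container for a pair of co-registered 3D scalar fields as produced by
#' multipoint Dixon fat-water decomposition: a water magnitude volume and a
#' fat magnitude volume on the same voxel grid, plus the physical voxel
#' spacing. The in-plane axes come first; the slice (acquisition) axis is
#' last.
#'
#' @slot water 3D numeric array of water signal magnitudes (non-negative).
#' @slot fat 3D numeric array of fat signal magnitudes, same dimensions.
#' @slot spacing numeric(3), voxel spacing in mm per axis.
#' @slot side one of \code{"bilateral"}, \code{"left"}, \code{"right"}, or
#'   \code{NULL} when unknown. A bilateral volume holds both thighs side by
#'   side along the second in-plane axis.
#'
#' @seealso [fatWaterVolume()], [splitThighs()], [fatFractionMap()]
#' @exportClass FatWaterVolume
setClass("FatWaterVolume",
  representation(
    water = "array",
    fat = "array",
    spacing = "numeric",
    side = "characterOrNULL"
  )
)

setValidity("FatWaterVolume", function(object) {
  msg <- character()
  if (length(dim(object@water)) != 3L) {
    msg <- c(msg, "'water' must be a 3D array")
  }
  if (!identical(dim(object@water), dim(object@fat))) {
    msg <- c(msg, "'water' and 'fat' must have identical dimensions")
  }
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0)) {
    msg <- c(msg, "'spacing' must be 3 positive finite values (mm)")
  }
  if (anyNA(object@water) || anyNA(object@fat)) {
    msg <- c(msg, "volumes must not contain NA")
  }
  if (min(object@water) < 0 || min(object@fat) < 0) {
    msg <- c(msg, "signal magnitudes must be non-negative")
  }
  if (!is.null(object@side) &&
      !object@side %in% c("bilateral", "left", "right")) {
    msg <- c(msg, "'side' must be 'bilateral', 'left' or 'right'")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a FatWaterVolume
#'
#' @param water,fat 3D numeric arrays on the same grid.
#' @param spacing voxel spacing in mm per axis, length 3.
#' @param side optional side label (\code{"bilateral"}, \code{"left"},
#'   \code{"right"}).
#' @return A [FatWaterVolume-class] object.
#' @examples
#' v <- fatWaterVolume(array(1, c(4, 4, 2)), array(0.5, c(4, 4, 2)))
#' dim(v)
#' @export
fatWaterVolume <- function(water, fat, spacing = c(1, 1, 1), side = NULL) {
  new("FatWaterVolume",
      water = water, fat = fat,
      spacing = as.numeric(spacing), side = side)
}

#' MuscleLabelVolume: integer ROI label field
#'
#' 3D integer label field on the same grid as its companion
#' [FatWaterVolume-class]. Label semantics are fixed throughout the
#' package: 0 background, 1 quadriceps femoris (ROI1), 2 sartorius (ROI2),
#' 3 gracilis (ROI3), 4 hamstrings (ROI4).
#'
#' @slot labels 3D integer array with values in 0..4.
#' @slot spacing numeric(3), voxel spacing in mm per axis.
#'
#' @seealso [muscleLabelVolume()], [finalizeLabels()], [dice()]
#' @exportClass MuscleLabelVolume
setClass("MuscleLabelVolume",
  representation(labels = "array", spacing = "numeric")
)

setValidity("MuscleLabelVolume", function(object) {
  msg <- character()
  if (length(dim(object@labels)) != 3L) {
    msg <- c(msg, "'labels' must be a 3D array")
  }
  if (!is.integer(object@labels)) {
    msg <- c(msg, "'labels' must be integer storage mode")
  } else {
    bad <- setdiff(unique(as.vector(object@labels)), 0:4)
    if (length(bad)) {
      msg <- c(msg, sprintf("invalid label value(s): %s",
                            paste(bad, collapse = ", ")))
    }
  }
  if (length(object@spacing) != 3L || any(object@spacing <= 0)) {
    msg <- c(msg, "'spacing' must be 3 positive values (mm)")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a MuscleLabelVolume
#'
#' @param labels 3D array of labels in 0..4 (coerced to integer).
#' @param spacing voxel spacing in mm per axis, length 3.
#' @return A [MuscleLabelVolume-class] object.
#' @export
muscleLabelVolume <- function(labels, spacing = c(1, 1, 1)) {
  storage.mode(labels) <- "integer"
  new("MuscleLabelVolume", labels = labels, spacing = as.numeric(spacing))
}

#' FatFractionMap: per-voxel fat fraction with a defined-voxel mask
#'
#' Per-voxel fat fraction fat/(water+fat) in [0,1]. Voxels with zero total
#' signal (water + fat == 0) carry no fat-fraction value: they are marked
#' undefined and excluded from every summary statistic.
#'
#' @slot ff 3D numeric array of fat fractions (0 where undefined).
#' @slot defined 3D logical array, TRUE where water + fat > 0.
#' @slot spacing numeric(3), voxel spacing in mm per axis.
#'
#' @seealso [fatFractionMap()], [roiStats()]
#' @exportClass FatFractionMap
setClass("FatFractionMap",
  representation(ff = "array", defined = "array", spacing = "numeric")
)

setValidity("FatFractionMap", function(object) {
  msg <- character()
  if (!identical(dim(object@ff), dim(object@defined))) {
    msg <- c(msg, "'ff' and 'defined' must have identical dimensions")
  }
  if (!is.logical(object@defined)) {
    msg <- c(msg, "'defined' must be logical")
  }
  d <- object@ff[object@defined]
  if (length(d) && (min(d) < 0 || max(d) > 1)) {
    msg <- c(msg, "'ff' must lie in [0,1] on defined voxels")
  }
  if (length(msg)) msg else TRUE
})

#' PhantomSpec: geometry and signal model of a synthetic thigh phantom
#'
#' Describes a synthetic bilateral-thigh cross-section used to exercise the
#' full pipeline with known ground truth: concentric skin and subcutaneous
#' fat rings around a muscle compartment with four angular-sector muscle
#' ROIs and a central bone. The water/fat signal model is
#' \code{water = I * (1 - FF)}, \code{fat = I * FF} per tissue class with
#' additive Gaussian noise clipped at zero, so the noise-free voxel fat
#' fraction equals the specified FF exactly.
#'
#' @slot gridShape integer(3), voxels per axis (x, y, z); for a bilateral
#'   phantom the second axis holds the two thighs side by side.
#' @slot spacing numeric(3), mm per voxel.
#' @slot thighRadius outer thigh radius in mm.
#' @slot skinThickness skin ring thickness in mm.
#' @slot subcutFatThickness subcutaneous fat ring thickness in mm.
#' @slot boneRadius bone radius in mm.
#' @slot roiGeometry list of 4 lists, each with \code{theta = c(start, end)}
#'   (degrees, counter-clockwise from +x) and \code{radial = c(inner, outer)}
#'   (fractions of the muscle-compartment radius) defining disjoint sectors.
#' @slot roiFatFraction numeric(4), true fat fraction per ROI in [0,1].
#' @slot tissueIntensity named numeric: nominal signal amplitude for
#'   \code{muscle}, \code{subcut_fat}, \code{skin}, \code{bone}.
#' @slot tissueFatFraction named numeric: FF of non-ROI tissue classes
#'   (\code{muscle} baseline, \code{subcut_fat}, \code{skin}, \code{bone}).
#' @slot noiseSigma additive Gaussian noise sd as a fraction of the muscle
#'   amplitude.
#' @slot side \code{"bilateral"} (two mirrored thighs) or a single thigh.
#' @slot centerOffset numeric(2), in-plane thigh-center shift in voxels
#'   (models repositioning translation).
#' @slot rotation in-plane rotation of the ROI sectors in degrees (models
#'   repositioning rotation).
#' @slot seed integer RNG seed; a fixed seed makes output bit-identical.
#'
#' @seealso [phantomSpec()], [generatePhantom()], [generateCohort()]
#' @exportClass PhantomSpec
setClass("PhantomSpec",
  representation(
    gridShape = "integer",
    spacing = "numeric",
    thighRadius = "numeric",
    skinThickness = "numeric",
    subcutFatThickness = "numeric",
    boneRadius = "numeric",
    roiGeometry = "list",
    roiFatFraction = "numeric",
    tissueIntensity = "numeric",
    tissueFatFraction = "numeric",
    noiseSigma = "numeric",
    side = "character",
    centerOffset = "numeric",
    rotation = "numeric",
    seed = "integer"
  )
)

setValidity("PhantomSpec", function(object) {
  msg <- character()
  if (length(object@gridShape) != 3L || any(object@gridShape[1:2] < 4L) ||
      object@gridShape[3] < 1L) {
    msg <- c(msg, "'gridShape' must be 3 integers (in-plane >= 4, >= 1 slice)")
  }
  rad <- c(boneRadius = object@boneRadius,
           thighRadius = object@thighRadius,
           skinThickness = object@skinThickness,
           subcutFatThickness = object@subcutFatThickness)
  if (any(rad <= 0)) {
    msg <- c(msg, sprintf("non-positive geometry: %s",
                          paste(names(rad)[rad <= 0], collapse = ", ")))
  }
  muscleR <- object@thighRadius - object@skinThickness -
    object@subcutFatThickness
  if (muscleR <= 0) {
    msg <- c(msg, paste("skinThickness + subcutFatThickness must be <",
                        "thighRadius (no room left for muscle)"))
  } else if (object@boneRadius >= muscleR) {
    msg <- c(msg, sprintf(
      "boneRadius (%.3g mm) must be < muscle compartment radius (%.3g mm)",
      object@boneRadius, muscleR))
  }
  if (length(object@roiFatFraction) != 4L ||
      any(object@roiFatFraction < 0) || any(object@roiFatFraction > 1)) {
    msg <- c(msg, "'roiFatFraction' must be 4 values in [0,1]")
  }
  if (length(object@roiGeometry) != 4L) {
    msg <- c(msg, "'roiGeometry' must describe exactly 4 ROIs")
  } else {
    ov <- .roiSectorOverlaps(object@roiGeometry)
    if (length(ov)) {
      msg <- c(msg, sprintf("ROI sectors overlap: %s",
                            paste(ov, collapse = "; ")))
    }
  }
  need <- c("muscle", "subcut_fat", "skin", "bone")
  if (!all(need %in% names(object@tissueIntensity))) {
    msg <- c(msg, "'tissueIntensity' must name muscle, subcut_fat, skin, bone")
  }
  if (!all(need %in% names(object@tissueFatFraction))) {
    msg <- c(msg, "'tissueFatFraction' must name muscle, subcut_fat, skin, bone")
  }
  if (object@noiseSigma < 0) msg <- c(msg, "'noiseSigma' must be >= 0")
  if (!object@side %in% c("bilateral", "left", "right")) {
    msg <- c(msg, "'side' must be 'bilateral', 'left' or 'right'")
  }
  if (length(msg)) msg else TRUE
})

# pairwise angular+radial overlap check; returns human-readable clashes
.roiSectorOverlaps <- function(geom) {
  clashes <- character()
  for (i in 1:3) for (j in (i + 1):4) {
    gi <- geom[[i]]; gj <- geom[[j]]
    angOverlap <- .arcOverlap(gi$theta, gj$theta)
    radOverlap <- max(gi$radial[1], gj$radial[1]) <
      min(gi$radial[2], gj$radial[2])
    if (angOverlap && radOverlap) {
      clashes <- c(clashes, sprintf("ROI%d vs ROI%d", i, j))
    }
  }
  clashes
}

# do two angular arcs (degrees, start<end, arbitrary offset) intersect?
.arcOverlap <- function(a, b) {
  norm <- function(x) x %% 360
  lenA <- a[2] - a[1]; lenB <- b[2] - b[1]
  # sample-free test: b's start inside a, or a's start inside b
  inArc <- function(x, start, len) (norm(x - start)) < len
  inArc(b[1], a[1], lenA) || inArc(a[1], b[1], lenB) ||
    (norm(a[1]) == norm(b[1]) && lenA > 0 && lenB > 0)
}

#' UnetModel: a slice-wise two-channel U-net
#'
#' Bundles a U-net configuration, its parameter state (a named list of
#' weight matrices and bias vectors in a fixed layer order) and the
#' per-epoch training log. Re-loading the parameter list and predicting
#' yields bit-identical output.
#'
#' @slot config list, see [unetConfig()].
#' @slot params named list of numeric matrices/vectors.
#' @slot log data.frame with one row per epoch (train/validation loss).
#' @slot trained logical.
#'
#' @seealso [buildUnet()], [trainUnet()], [predictVolume()]
#' @exportClass UnetModel
setClass("UnetModel",
  representation(config = "list", params = "list",
                 log = "data.frame", trained = "logical")
)

#' IccResult: intraclass correlation with 95\% confidence interval
#'
#' Single-measure intraclass correlation of a complete subjects-by-repeats
#' table, with the F-distribution 95\% confidence bounds of the selected
#' two-way model.
#'
#' @slot estimate ICC point estimate.
#' @slot ci numeric(2), lower and upper 95\% confidence bounds.
#' @slot model \code{"ICC(2,1)"} (two-way random, absolute agreement) or
#'   \code{"ICC(3,1)"} (two-way mixed, consistency).
#' @slot nSubjects,nRepeats table dimensions.
#' @slot degenerate TRUE when the variance decomposition is degenerate
#'   (e.g. all cells equal); the estimate is then NA.
#'
#' @seealso [iccMeanFF()]
#' @exportClass IccResult
setClass("IccResult",
  representation(estimate = "numeric", ci = "numeric", model = "character",
                 nSubjects = "integer", nRepeats = "integer",
                 degenerate = "logical")
)
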