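#' Construct a synthetic thigh phantom specification
#'
#' Builds a [PhantomSpec-class] describing a bilateral thigh cross-section:
#' a skin ring, a subcutaneous fat ring, a muscle compartment carrying four
#' disjoint angular-sector muscle ROIs (quadriceps, sartorius, gracilis,
#' hamstrings) and a central bone. The signal model ties the two channels
#' to the prescribed fat fraction exactly: \code{water = I (1 - FF)},
#' \code{fat = I FF}, so noise-free phantoms have known ground truth for
#' every downstream statistic.
#'
#' Default ROI fat fractions (0.05, 0.10, 0.20, 0.30) span the range from
#' normal muscle to clearly visible fat infiltration while keeping the
#' water image muscle-dominant, which is the regime the intensity-based
#' preprocessing (and clinical Dixon water images) operate in.
#'
#' @param gridShape voxels per axis (x, y, z); the second axis holds both
#'   thighs when \code{side = "bilateral"}.
#' @param spacing mm per voxel.
#' @param thighRadius,skinThickness,subcutFatThickness,boneRadius geometry
#'   in mm; must nest (bone < muscle compartment < fat ring < skin).
#' @param roiGeometry list of 4 sectors, each \code{list(theta = c(start,
#'   end), radial = c(inner, outer))}; angles in degrees counter-clockwise
#'   from +x, radial extents as fractions of the muscle-compartment radius.
#' @param roiFatFraction true fat fraction per ROI, length 4, in [0,1].
#' @param tissueIntensity named nominal amplitudes for muscle, subcut_fat,
#'   skin, bone.
#' @param tissueFatFraction named FF of the non-ROI tissue classes.
#' @param noiseSigma additive Gaussian noise sd as a fraction of the muscle
#'   amplitude (both channels, clipped at 0).
#' @param side \code{"bilateral"}, \code{"left"} or \code{"right"}.
#' @param centerOffset in-plane thigh-center shift in voxels (length 2).
#' @param rotation in-plane ROI-sector rotation in degrees.
#' @param seed integer RNG seed.
#' @return A validated [PhantomSpec-class].
#' @examples
#' spec <- phantomSpec(noiseSigma = 0)
#' spec
#' @export
phantomSpec <- function(gridShape = c(64L, 128L, 12L),
                        spacing = c(1, 1, 6),
                        thighRadius = 28,
                        skinThickness = 2,
                        subcutFatThickness = 6,
                        boneRadius = 5,
                        roiGeometry = defaultRoiGeometry(),
                        roiFatFraction = c(0.05, 0.10, 0.20, 0.30),
                        tissueIntensity = c(muscle = 100, subcut_fat = 100,
                                            skin = 15, bone = 40),
                        tissueFatFraction = c(muscle = 0, subcut_fat = 0.9,
                                              skin = 0.3, bone = 0.5),
                        noiseSigma = 0.03,
                        side = "bilateral",
                        centerOffset = c(0, 0),
                        rotation = 0,
                        seed = 1L) {
  new("PhantomSpec",
      gridShape = as.integer(gridShape), spacing = as.numeric(spacing),
      thighRadius = thighRadius, skinThickness = skinThickness,
      subcutFatThickness = subcutFatThickness, boneRadius = boneRadius,
      roiGeometry = roiGeometry, roiFatFraction = roiFatFraction,
      tissueIntensity = tissueIntensity,
      tissueFatFraction = tissueFatFraction,
      noiseSigma = noiseSigma, side = side,
      centerOffset = as.numeric(centerOffset), rotation = rotation,
      seed = as.integer(seed))
}

#' Default angular-sector geometry of the four muscle ROIs
#'
#' Anterior quadriceps and posterior hamstrings as large sectors, medial
#' sartorius and gracilis as small ones, separated by thin unlabelled
#' muscle gaps (fascia analogue).
#'
#' @return list of 4 sector descriptions (see [phantomSpec()]).
#' @export
defaultRoiGeometry <- function() {
  list(
    list(theta = c(15, 160),  radial = c(0.30, 0.97)),  # ROI1 quadriceps
    list(theta = c(168, 196), radial = c(0.55, 0.97)),  # ROI2 sartorius
    list(theta = c(204, 232), radial = c(0.55, 0.97)),  # ROI3 gracilis
    list(theta = c(240, 360), radial = c(0.30, 0.97))   # ROI4 hamstrings
  )
}

# tissue class codes used by the phantom ground truth
TISSUE_CODES <- c(background = 0L, skin = 1L, subcut_fat = 2L,
                  muscle = 3L, bone = 4L)

# evaluate expr with a temporary RNG seed, restoring the caller's stream
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# single-thigh noise-free fields on an nx x ny grid (one slice template).
# Returns list(tissue, roi, ff, intensity) matrices.
.thighSliceTemplate <- function(nx, ny, spacing, spec) {
  cx <- (nx + 1) / 2 + spec@centerOffset[1]
  cy <- (ny + 1) / 2 + spec@centerOffset[2]
  dx <- (seq_len(nx) - cx) * spacing[1]
  dy <- (seq_len(ny) - cy) * spacing[2]
  X <- matrix(dx, nx, ny)
  Y <- matrix(dy, nx, ny, byrow = TRUE)
  r <- sqrt(X^2 + Y^2)
  theta <- (atan2(Y, X) * 180 / pi - spec@rotation) %% 360

  muscleR <- spec@thighRadius - spec@skinThickness - spec@subcutFatThickness
  tissue <- matrix(TISSUE_CODES[["background"]], nx, ny)
  tissue[r <= spec@thighRadius] <- TISSUE_CODES[["skin"]]
  tissue[r <= spec@thighRadius - spec@skinThickness] <-
    TISSUE_CODES[["subcut_fat"]]
  tissue[r <= muscleR] <- TISSUE_CODES[["muscle"]]
  tissue[r <= spec@boneRadius] <- TISSUE_CODES[["bone"]]

  roi <- matrix(0L, nx, ny)
  inMuscle <- tissue == TISSUE_CODES[["muscle"]]
  for (k in 1:4) {
    g <- spec@roiGeometry[[k]]
    span <- g$theta[2] - g$theta[1]
    inSector <- ((theta - g$theta[1]) %% 360) < span
    rf <- r / muscleR
    inRad <- rf >= g$radial[1] & rf <= g$radial[2]
    roi[inMuscle & inSector & inRad] <- k
  }

  ff <- matrix(0, nx, ny)
  inten <- matrix(0, nx, ny)
  for (tn in c("skin", "subcut_fat", "muscle", "bone")) {
    sel <- tissue == TISSUE_CODES[[tn]]
    ff[sel] <- spec@tissueFatFraction[[tn]]
    inten[sel] <- spec@tissueIntensity[[tn]]
  }
  for (k in 1:4) ff[roi == k] <- spec@roiFatFraction[k]

  list(tissue = tissue, roi = roi, ff = ff, intensity = inten)
}

#' Generate a synthetic fat-water thigh phantom
#'
#' Realises a [PhantomSpec-class] into a co-registered water/fat volume with
#' its ground-truth muscle ROI labels and tissue-class field. A bilateral
#' spec produces two thighs that are exact mirror images about the midline
#' before noise. Noise-free, the per-voxel fat fraction
#' \code{fat/(water+fat)} of every tissue voxel equals its prescribed FF
#' exactly, so ground-truth meanFF per ROI equals
#' \code{roiFatFraction} by construction.
#'
#' @param spec a [PhantomSpec-class].
#' @return list with elements \code{volume} ([FatWaterVolume-class]),
#'   \code{labels} ([MuscleLabelVolume-class]), \code{tissues} (3D integer
#'   array of tissue classes: 0 background, 1 skin, 2 subcutaneous fat,
#'   3 muscle, 4 bone) and \code{spec}.
#' @examples
#' ph <- generatePhantom(phantomSpec(noiseSigma = 0))
#' ph$volume
#' ph$labels
#' @export
generatePhantom <- function(spec) {
  validObject(spec)
  gs <- spec@gridShape
  nx <- gs[1]; ny <- gs[2]; nz <- gs[3]

  if (spec@side == "bilateral") {
    nyh <- ny %/% 2L
    if (nyh * 2L != ny) {
      stop("bilateral phantom needs an even second axis, got ", ny)
    }
    tmplL <- .thighSliceTemplate(nx, nyh, spec@spacing, spec)
    mirror <- function(m) m[, rev(seq_len(ncol(m))), drop = FALSE]
    tissueSl <- cbind(tmplL$tissue, mirror(tmplL$tissue))
    roiSl <- cbind(tmplL$roi, mirror(tmplL$roi))
    ffSl <- cbind(tmplL$ff, mirror(tmplL$ff))
    intenSl <- cbind(tmplL$intensity, mirror(tmplL$intensity))
  } else {
    tmpl <- .thighSliceTemplate(nx, ny, spec@spacing, spec)
    if (spec@side == "right") {
      flip <- function(m) m[, rev(seq_len(ncol(m))), drop = FALSE]
      tmpl <- lapply(tmpl, flip)
    }
    tissueSl <- tmpl$tissue; roiSl <- tmpl$roi
    ffSl <- tmpl$ff; intenSl <- tmpl$intensity
  }

  rep3 <- function(m) array(m, dim = c(nx, ny, nz))
  tissues <- rep3(tissueSl)
  labels <- rep3(roiSl)
  water <- rep3(intenSl * (1 - ffSl))
  fat <- rep3(intenSl * ffSl)

  if (spec@noiseSigma > 0) {
    sd <- spec@noiseSigma * spec@tissueIntensity[["muscle"]]
    .withSeed(spec@seed, {
      water <- water + array(stats::rnorm(length(water), 0, sd), dim(water))
      fat <- fat + array(stats::rnorm(length(fat), 0, sd), dim(fat))
    })
    water[water < 0] <- 0
    fat[fat < 0] <- 0
  }

  list(
    volume = fatWaterVolume(water, fat, spec@spacing,
                            side = if (spec@side == "bilateral")
                              "bilateral" else spec@side),
    labels = muscleLabelVolume(labels, spec@spacing),
    tissues = tissues,
    spec = spec
  )
}

#' Distribution of phantom parameters across a synthetic cohort
#'
#' Ranges from which per-subject anatomy and per-repeat repositioning are
#' drawn by [generateCohort()]. Repositioning is an in-plane rigid
#' transform (default at most 3 voxels translation, 5 degrees rotation)
#' with fresh acquisition noise, emulating repeated scans of one subject.
#'
#' @param ffRange range of the uniform per-ROI true fat fraction draw.
#' @param thighRadiusRange range of the per-subject thigh radius (mm).
#' @param subcutRange range of the subcutaneous fat ring thickness (mm).
#' @param maxShift maximum repositioning translation per axis (voxels).
#' @param maxRotation maximum repositioning rotation (degrees).
#' @return named list consumed by [generateCohort()].
#' @export
cohortDistribution <- function(ffRange = c(0.05, 0.4),
                               thighRadiusRange = c(26, 30),
                               subcutRange = c(5, 7),
                               maxShift = 3,
                               maxRotation = 5) {
  list(ffRange = ffRange, thighRadiusRange = thighRadiusRange,
       subcutRange = subcutRange, maxShift = maxShift,
       maxRotation = maxRotation)
}

#' Generate a cohort of phantom scans with repeated acquisitions
#'
#' Draws per-subject anatomy (thigh radius, fat-ring thickness, per-ROI
#' true fat fractions) from \code{dist} and realises \code{repeats}
#' acquisitions per subject. Repeats of one subject share anatomy and true
#' FF but differ by a small random in-plane rigid shift/rotation and fresh
#' noise, emulating scan-rescan with repositioning. All randomness flows
#' from \code{seed}; the same call reproduces the same cohort bit for bit.
#'
#' @param nSubjects number of subjects (>= 1).
#' @param repeats acquisitions per subject (>= 1).
#' @param dist a [cohortDistribution()] list.
#' @param baseSpec template [PhantomSpec-class]; per-subject and per-repeat
#'   fields are overridden on top of it.
#' @param seed integer RNG seed for the whole cohort.
#' @return list of scan records, each with \code{volume}, \code{labels},
#'   \code{tissues}, \code{spec}, \code{subjectId} (e.g. "S01"),
#'   \code{repeatId} (1-based) and \code{trueFF} (numeric(4)).
#' @examples
#' coh <- generateCohort(2, 2, seed = 7,
#'                       baseSpec = phantomSpec(gridShape = c(32, 64, 2)))
#' length(coh)
#' @export
generateCohort <- function(nSubjects, repeats,
                           dist = cohortDistribution(),
                           baseSpec = phantomSpec(),
                           seed = 1L) {
  stopifnot(nSubjects >= 1, repeats >= 1)
  draws <- .withSeed(seed, {
    lapply(seq_len(nSubjects), function(s) {
      ff <- stats::runif(4, dist$ffRange[1], dist$ffRange[2])
      tr <- stats::runif(1, dist$thighRadiusRange[1],
                         dist$thighRadiusRange[2])
      sc <- stats::runif(1, dist$subcutRange[1], dist$subcutRange[2])
      reps <- lapply(seq_len(repeats), function(r) {
        list(shift = stats::runif(2, -dist$maxShift, dist$maxShift),
             rot = stats::runif(1, -dist$maxRotation, dist$maxRotation),
             noiseSeed = sample.int(.Machine$integer.max - 1L, 1L))
      })
      list(ff = ff, thighRadius = tr, subcut = sc, reps = reps)
    })
  })

  out <- list()
  for (s in seq_len(nSubjects)) {
    d <- draws[[s]]
    for (r in seq_len(repeats)) {
      rp <- d$reps[[r]]
      spec <- baseSpec
      spec@roiFatFraction <- d$ff
      spec@thighRadius <- d$thighRadius
      spec@subcutFatThickness <- d$subcut
      spec@centerOffset <- rp$shift
      spec@rotation <- rp$rot
      spec@seed <- rp$noiseSeed
      validObject(spec)
      ph <- generatePhantom(spec)
      ph$subjectId <- sprintf("S%02d", s)
      ph$repeatId <- r
      ph$trueFF <- d$ff
      out[[length(out) + 1L]] <- ph
    }
  }
  out
}
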