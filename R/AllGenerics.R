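#' Accessors for volume classes
#'
#' @param x a [FatWaterVolume-class], [MuscleLabelVolume-class] or
#'   [FatFractionMap-class] object.
#' @return \code{waterImage}/\code{fatImage}: 3D numeric arrays;
#'   \code{labelArray}: 3D integer array; \code{ffArray}: 3D numeric array;
#'   \code{definedMask}: 3D logical array; \code{voxelSpacing}: numeric(3)
#'   in mm; \code{sideLabel}: character or NULL; \code{voxelVolume}: scalar
#'   voxel volume in mm^3.
#' @name volume-accessors
NULL

#' @rdname volume-accessors
#' @export
setGeneric("waterImage", function(x) standardGeneric("waterImage"))
#' @rdname volume-accessors
#' @export
setGeneric("fatImage", function(x) standardGeneric("fatImage"))
#' @rdname volume-accessors
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))
#' @rdname volume-accessors
#' @export
setGeneric("sideLabel", function(x) standardGeneric("sideLabel"))
#' @rdname volume-accessors
#' @export
setGeneric("labelArray", function(x) standardGeneric("labelArray"))
#' @rdname volume-accessors
#' @export
setGeneric("ffArray", function(x) standardGeneric("ffArray"))
#' @rdname volume-accessors
#' @export
setGeneric("definedMask", function(x) standardGeneric("definedMask"))
#' @rdname volume-accessors
#' @export
setGeneric("voxelVolume", function(x) standardGeneric("voxelVolume"))

#' @rdname volume-accessors
setMethod("waterImage", "FatWaterVolume", function(x) x@water)
#' @rdname volume-accessors
setMethod("fatImage", "FatWaterVolume", function(x) x@fat)
#' @rdname volume-accessors
setMethod("voxelSpacing", "FatWaterVolume", function(x) x@spacing)
#' @rdname volume-accessors
setMethod("voxelSpacing", "MuscleLabelVolume", function(x) x@spacing)
#' @rdname volume-accessors
setMethod("voxelSpacing", "FatFractionMap", function(x) x@spacing)
#' @rdname volume-accessors
setMethod("sideLabel", "FatWaterVolume", function(x) x@side)
#' @rdname volume-accessors
setMethod("labelArray", "MuscleLabelVolume", function(x) x@labels)
#' @rdname volume-accessors
setMethod("ffArray", "FatFractionMap", function(x) x@ff)
#' @rdname volume-accessors
setMethod("definedMask", "FatFractionMap", function(x) x@defined)
#' @rdname volume-accessors
setMethod("voxelVolume", "FatWaterVolume", function(x) prod(x@spacing))
#' @rdname volume-accessors
setMethod("voxelVolume", "MuscleLabelVolume", function(x) prod(x@spacing))
#' @rdname volume-accessors
setMethod("voxelVolume", "FatFractionMap", function(x) prod(x@spacing))

#' @describeIn volume-accessors grid dimensions of the water channel
#' @export
setMethod("dim", "FatWaterVolume", function(x) dim(x@water))
#' @describeIn volume-accessors grid dimensions of the label field
#' @export
setMethod("dim", "MuscleLabelVolume", function(x) dim(x@labels))
#' @describeIn volume-accessors grid dimensions of the fat-fraction field
#' @export
setMethod("dim", "FatFractionMap", function(x) dim(x@ff))

setMethod("show", "FatWaterVolume", function(object) {
  d <- dim(object)
  cat(sprintf("FatWaterVolume %d x %d x %d voxels @ %s mm%s\n",
              d[1], d[2], d[3],
              paste(format(object@spacing, trim = TRUE), collapse = " x "),
              if (is.null(object@side)) "" else paste0(" [", object@side, "]")))
  cat(sprintf("  water range [%.3g, %.3g], fat range [%.3g, %.3g]\n",
              min(object@water), max(object@water),
              min(object@fat), max(object@fat)))
})

setMethod("show", "MuscleLabelVolume", function(object) {
  d <- dim(object)
  tab <- tabulate(object@labels + 1L, nbins = 5L)
  cat(sprintf("MuscleLabelVolume %d x %d x %d voxels @ %s mm\n",
              d[1], d[2], d[3],
              paste(format(object@spacing, trim = TRUE), collapse = " x ")))
  cat(sprintf("  voxels: bg %d | ROI1 %d | ROI2 %d | ROI3 %d | ROI4 %d\n",
              tab[1], tab[2], tab[3], tab[4], tab[5]))
})

setMethod("show", "FatFractionMap", function(object) {
  d <- dim(object)
  nd <- sum(object@defined)
  cat(sprintf("FatFractionMap %d x %d x %d voxels (%d defined)\n",
              d[1], d[2], d[3], nd))
  if (nd > 0) {
    cat(sprintf("  FF on defined voxels: mean %.4f, range [%.4f, %.4f]\n",
                mean(object@ff[object@defined]),
                min(object@ff[object@defined]),
                max(object@ff[object@defined])))
  }
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf("PhantomSpec [%s] grid %s @ %s mm\n", object@side,
              paste(object@gridShape, collapse = " x "),
              paste(format(object@spacing, trim = TRUE), collapse = " x ")))
  cat(sprintf("  thigh %.3g mm (skin %.3g, subcut fat %.3g, bone %.3g)\n",
              object@thighRadius, object@skinThickness,
              object@subcutFatThickness, object@boneRadius))
  cat(sprintf("  ROI fat fractions: %s; noise sigma %.3g; seed %d\n",
              paste(format(object@roiFatFraction, trim = TRUE),
                    collapse = ", "),
              object@noiseSigma, object@seed))
})

setMethod("show", "UnetModel", function(object) {
  cfg <- object@config
  np <- sum(vapply(object@params, length, integer(1)))
  cat(sprintf("UnetModel depth %d, base %d filters, %s head (%d parameters)%s\n",
              cfg$depth, cfg$baseFilters, cfg$head, np,
              if (object@trained) " [trained]" else " [untrained]"))
  if (nrow(object@log)) {
    last <- object@log[nrow(object@log), ]
    cat(sprintf("  %d epochs logged; last train loss %.5f, val loss %.5f\n",
                nrow(object@log), last$train_loss, last$val_loss))
  }
})

setMethod("show", "IccResult", function(object) {
  if (object@degenerate) {
    cat(sprintf("IccResult %s: degenerate (no between-subject variance)\n",
                object@model))
  } else {
    cat(sprintf("IccResult %s = %.4f [%.4f, %.4f] (n = %d subjects x %d repeats)\n",
                object@model, object@estimate, object@ci[1], object@ci[2],
                object@nSubjects, object@nRepeats))
  }
})
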