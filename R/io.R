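#' Read and write volumes as NIfTI-1
#'
#' Thin wrappers over RNifti keeping the package's conventions: arrays are
#' (x, y, z) with the slice axis last, voxel spacing is carried in the
#' header pixdim, and label volumes are validated to the 0..4 label set on
#' read.
#'
#' @param path NIfTI file (.nii or .nii.gz).
#' @param arr 3D array to write.
#' @param spacing voxel spacing in mm per axis.
#' @return \code{readNiftiArray}: list(data, spacing);
#'   \code{writeNiftiArray}: the path, invisibly.
#' @name nifti-io
NULL

#' @rdname nifti-io
#' @export
readNiftiArray <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  sp <- attr(img, "pixdim")
  if (is.null(sp)) sp <- RNifti::pixdim(img)
  sp <- as.numeric(sp)[seq_len(3)]
  if (length(sp) < 3 || anyNA(sp) || any(sp <= 0)) {
    stop("voxel spacing missing or invalid in NIfTI header of ", path)
  }
  a <- array(as.numeric(img), dim(img))
  if (length(dim(a)) == 2L) dim(a) <- c(dim(a), 1L)
  list(data = a, spacing = sp)
}

#' @rdname nifti-io
#' @export
writeNiftiArray <- function(arr, path, spacing = c(1, 1, 1)) {
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- as.numeric(spacing)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a fat-water volume pair from NIfTI files
#'
#' @param waterPath,fatPath co-registered water and fat magnitude volumes.
#' @param side optional side label.
#' @return A [FatWaterVolume-class].
#' @export
readFatWater <- function(waterPath, fatPath, side = NULL) {
  w <- readNiftiArray(waterPath)
  f <- readNiftiArray(fatPath)
  if (!identical(dim(w$data), dim(f$data))) {
    stop("water and fat grids differ: ",
         paste(dim(w$data), collapse = "x"), " vs ",
         paste(dim(f$data), collapse = "x"))
  }
  if (max(abs(w$spacing - f$spacing)) > 1e-6) {
    stop("water and fat voxel spacings differ")
  }
  fatWaterVolume(w$data, f$data, w$spacing, side = side)
}

#' Write a fat-water volume pair
#'
#' @param vol a [FatWaterVolume-class].
#' @param prefix output path prefix; \code{<prefix>_water.nii.gz} and
#'   \code{<prefix>_fat.nii.gz} are written.
#' @return character(2) of written paths, invisibly.
#' @export
writeFatWater <- function(vol, prefix) {
  pw <- paste0(prefix, "_water.nii.gz")
  pf <- paste0(prefix, "_fat.nii.gz")
  writeNiftiArray(waterImage(vol), pw, voxelSpacing(vol))
  writeNiftiArray(fatImage(vol), pf, voxelSpacing(vol))
  invisible(c(pw, pf))
}

#' Read a muscle label volume, validating the label set
#'
#' @param path NIfTI label file; values must be integers in 0..4.
#' @return A [MuscleLabelVolume-class].
#' @export
readLabelVolume <- function(path) {
  r <- readNiftiArray(path)
  v <- r$data
  if (max(abs(v - round(v))) > 0) {
    stop("label file contains non-integer values: ", path)
  }
  bad <- setdiff(unique(as.vector(v)), 0:4)
  if (length(bad)) {
    stop("invalid label value(s) ", paste(bad, collapse = ", "),
         " in ", path, " (expected 0..4)")
  }
  muscleLabelVolume(round(v), r$spacing)
}

#' Write a muscle label volume
#'
#' @param labels a [MuscleLabelVolume-class].
#' @param path output NIfTI file.
#' @return the path, invisibly.
#' @export
writeLabelVolume <- function(labels, path) {
  writeNiftiArray(labelArray(labels), path, voxelSpacing(labels))
}

#' Write a phantom cohort to disk with a manifest
#'
#' Writes water/fat/label NIfTI volumes per scan plus a
#' \code{manifest.csv} (file paths, subject_id, repeat_id, true per-ROI
#' fat fractions).
#'
#' @param cohort list of scan records from [generateCohort()].
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(cohort, function(rec) {
    stem <- sprintf("%s_rep%d", rec$subjectId, rec$repeatId)
    prefix <- file.path(dir, stem)
    writeFatWater(rec$volume, prefix)
    labPath <- paste0(prefix, "_labels.nii.gz")
    writeLabelVolume(rec$labels, labPath)
    data.frame(subject_id = rec$subjectId, repeat_id = rec$repeatId,
               water = paste0(prefix, "_water.nii.gz"),
               fat = paste0(prefix, "_fat.nii.gz"),
               labels = labPath,
               ff_roi1 = rec$trueFF[1], ff_roi2 = rec$trueFF[2],
               ff_roi3 = rec$trueFF[3], ff_roi4 = rec$trueFF[4])
  })
  manifest <- do.call(rbind, rows)
  mpath <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mpath, row.names = FALSE)
  invisible(mpath)
}
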