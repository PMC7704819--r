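#' Label the 3D connected components of a binary mask
#'
#' Components are found under voxel-topology connectivity (6 = faces,
#' 18 = faces+edges, 26 = faces+edges+corners; anisotropic spacing is
#' ignored) and numbered in scan order, so component 1 contains the
#' foreground voxel with the smallest linear array index.
#'
#' @param mask 3D logical array.
#' @param connectivity 6, 18 or 26.
#' @return list with \code{labels} (3D integer array, 0 = background) and
#'   \code{sizes} (voxel count per component).
#' @export
labelComponents <- function(mask, connectivity = 26L) {
  stopifnot(length(dim(mask)) == 3L)
  cpp_label_components(as.logical(mask), as.integer(dim(mask)),
                       as.integer(connectivity))
}

#' Keep only the largest 3D connected component of one ROI
#'
#' Stray islands of a predicted ROI are removed: voxels of \code{roi}
#' outside its largest 3D connected component are reset to background;
#' every other ROI is untouched. Ties on component size are broken
#' deterministically in favour of the component whose seed voxel comes
#' first in scan order (smallest linear index, x varying fastest).
#' An empty ROI is returned unchanged.
#'
#' @param labels a [MuscleLabelVolume-class].
#' @param roi ROI id in 1..4.
#' @param connectivity 6, 18 or 26 (default 26, the most permissive, so
#'   thin oblique muscles are not split across coarse slices).
#' @return A [MuscleLabelVolume-class].
#' @export
keepLargestComponent <- function(labels, roi, connectivity = 26L) {
  stopifnot(roi %in% 1:4)
  L <- labelArray(labels)
  mask <- L == roi
  if (!any(mask)) return(labels)
  comp <- labelComponents(mask, connectivity)
  best <- which.max(comp$sizes)  # first maximum = smallest seed voxel
  drop <- mask & comp$labels != best
  L[drop] <- 0L
  muscleLabelVolume(L, voxelSpacing(labels))
}

#' Largest-component postprocessing of all four ROIs
#'
#' Applies [keepLargestComponent()] to each of ROI1..ROI4, so every
#' nonempty ROI of the result is a single 3D connected region. The
#' operation is idempotent and never increases any ROI's voxel count.
#'
#' @param labels a [MuscleLabelVolume-class].
#' @param connectivity 6, 18 or 26.
#' @return A [MuscleLabelVolume-class].
#' @examples
#' L <- array(0L, c(8, 8, 2)); L[2:3, 2:3, 1] <- 1L; L[7, 7, 2] <- 1L
#' v <- finalizeLabels(muscleLabelVolume(L))
#' sum(labelArray(v) == 1)  # only the larger island survives
#' @export
finalizeLabels <- function(labels, connectivity = 26L) {
  for (roi in 1:4) {
    labels <- keepLargestComponent(labels, roi, connectivity)
  }
  labels
}
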