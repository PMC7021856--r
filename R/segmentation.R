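#' Reconstructed count volume
#'
#' A 3-D array of non-negative reconstructed counts together with the
#' acquisition metadata needed to turn summed counts into a rate.
#' Reconstructed counts are projection-number-scaled, so the primary rate is
#' the voxel sum divided by `n_projections * t_projection`.
#'
#' @param voxels 3-D numeric array of counts (>= 0).
#' @param voxel_size Voxel edge lengths in mm (length 1 or 3).
#' @param n_projections Number of projections acquired (> 0).
#' @param t_projection Time per projection in seconds (> 0).
#' @return An object of class `count_volume`.
#' @export
count_volume <- function(voxels, voxel_size, n_projections, t_projection) {
  if (length(dim(voxels)) != 3)
    stop("voxels must be a 3-D array", call. = FALSE)
  if (any(voxels < 0)) stop("voxel counts must be >= 0", call. = FALSE)
  if (length(voxel_size) == 1) voxel_size <- rep(voxel_size, 3)
  if (length(voxel_size) != 3 || any(voxel_size <= 0))
    stop("voxel_size must be 3 positive lengths in mm", call. = FALSE)
  if (n_projections <= 0 || t_projection <= 0)
    stop("n_projections and t_projection must be > 0", call. = FALSE)
  structure(list(voxels = voxels, voxel_size = voxel_size,
                 n_projections = n_projections, t_projection = t_projection),
            class = "count_volume")
}

#' @export
print.count_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf(
    "<count_volume> %d x %d x %d voxels (%.3g x %.3g x %.3g mm), %d proj x %g s, %.5g counts\n",
    d[1], d[2], d[3], x$voxel_size[1], x$voxel_size[2], x$voxel_size[3],
    x$n_projections, x$t_projection, sum(x$voxels)))
  invisible(x)
}

#' Primary count rate of a reconstructed volume
#'
#' Sum of (optionally masked) voxel counts divided by the product of the
#' number of projections and the time per projection.
#'
#' @param v A [count_volume()].
#' @param mask Optional logical array of the same dimensions selecting the
#'   voxels to sum.
#' @return Rate in cps.
#' @export
volume_primary_rate <- function(v, mask = NULL) {
  stopifnot(inherits(v, "count_volume"))
  if (is.null(mask)) {
    total <- sum(v$voxels)
  } else {
    if (!identical(dim(mask), dim(v$voxels)))
      stop("mask dimensions do not match the volume", call. = FALSE)
    total <- sum(v$voxels[mask])
  }
  total / (v$n_projections * v$t_projection)
}

#' Threshold segmentation mask
#'
#' Keeps voxels at or above a fraction of the maximum voxel value (default
#' 1%), suppressing diffuse spurious background while retaining the sources.
#' The comparison is inclusive, so the maximum voxel is always kept, and the
#' operation is idempotent: re-thresholding the masked volume at the same
#' fraction changes nothing.
#'
#' @param v A [count_volume()].
#' @param fraction Threshold as a fraction of the maximum voxel (default
#'   0.01).
#' @return Logical array of the volume's dimensions.
#' @export
threshold_mask <- function(v, fraction = 0.01) {
  stopifnot(inherits(v, "count_volume"))
  m <- max(v$voxels)
  if (m <= 0) stop("cannot threshold an all-zero volume", call. = FALSE)
  v$voxels >= fraction * m
}

#' Circular per-slice region of interest
#'
#' @param centre Disc centre `(x, y)` in mm measured from the volume corner.
#' @param diameter Disc diameter in mm (> 0).
#' @param slices Inclusive range of slice indices (1-based) the disc spans.
#' @return An object of class `roi_spec`.
#' @export
roi_spec <- function(centre, diameter, slices) {
  if (length(centre) != 2) stop("centre must be (x, y) in mm", call. = FALSE)
  if (diameter <= 0) stop("diameter must be > 0", call. = FALSE)
  slices <- as.integer(slices)
  structure(list(centre = centre, diameter = diameter,
                 slices = range(slices)),
            class = "roi_spec")
}

#' Region-of-interest segmentation mask
#'
#' Union of per-slice discs.  A voxel belongs to a disc if its centre (at
#' `(i - 0.5) * voxel_size` mm from the volume corner) lies within the disc
#' radius — voxel-centre inclusion, not area weighting, matching clinical
#' ROI tools.
#'
#' @param v A [count_volume()].
#' @param rois A single [roi_spec()] or a list of them.
#' @return Logical array of the volume's dimensions.
#' @export
roi_mask <- function(v, rois) {
  stopifnot(inherits(v, "count_volume"))
  if (inherits(rois, "roi_spec")) rois <- list(rois)
  d <- dim(v$voxels)
  vs <- v$voxel_size
  xc <- (seq_len(d[1]) - 0.5) * vs[1]
  yc <- (seq_len(d[2]) - 0.5) * vs[2]
  mask <- array(FALSE, dim = d)
  for (roi in rois) {
    r <- roi$diameter / 2
    if (roi$slices[1] < 1 || roi$slices[2] > d[3])
      stop("ROI slice range [", roi$slices[1], ", ", roi$slices[2],
           "] outside volume (", d[3], " slices)", call. = FALSE)
    if (roi$centre[1] - r < 0 || roi$centre[1] + r > d[1] * vs[1] ||
        roi$centre[2] - r < 0 || roi$centre[2] + r > d[2] * vs[2])
      stop("ROI disc extends outside the volume bounds", call. = FALSE)
    disc <- outer((xc - roi$centre[1])^2, (yc - roi$centre[2])^2, `+`) <= r^2
    for (z in seq.int(roi$slices[1], roi$slices[2]))
      mask[, , z] <- mask[, , z] | disc
  }
  mask
}

#' Read / write a count volume as NIfTI with a JSON sidecar
#'
#' The voxel array and voxel size travel in the NIfTI file; the acquisition
#' metadata (`n_projections`, `t_projection_s`) travels in a JSON sidecar
#' named `<path>.json`.  Masks can be written the same way as 0/1 volumes.
#'
#' @param v A [count_volume()].
#' @param path NIfTI file path (`.nii` or `.nii.gz`).
#' @return `read_count_volume()` returns a [count_volume()];
#'   `write_count_volume()` returns `path` invisibly.
#' @export
write_count_volume <- function(v, path) {
  stopifnot(inherits(v, "count_volume"))
  img <- RNifti::asNifti(v$voxels)
  RNifti::pixdim(img) <- v$voxel_size
  RNifti::writeNifti(img, path)
  jsonlite::write_json(
    list(n_projections = v$n_projections, t_projection_s = v$t_projection),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_count_volume
#' @export
read_count_volume <- function(path) {
  img <- RNifti::readNifti(path)
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar))
    stop("missing sidecar ", sidecar, call. = FALSE)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  count_volume(array(as.numeric(img), dim = dim(img)),
               voxel_size = RNifti::pixdim(img)[1:3],
               n_projections = meta$n_projections,
               t_projection = meta$t_projection_s)
}
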