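#' @useDynLib ablamargin, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Annotated binary volume
#'
#' The basic data carrier: a 3D boolean occupancy grid together with the
#' physical voxel spacing (mm per axis) and the physical position of the
#' center of voxel `[1, 1, 1]`. Grid axes are assumed to follow the canonical
#' anatomical convention (RAS: x runs left to right, y posterior to anterior,
#' z caudal to cranial); [load_mask()] reorients arbitrary NIfTI input into
#' this convention so that downstream octant localization can address
#' anatomical sides directly.
#'
#' Physical coordinates refer to voxel centers: the center of the voxel with
#' (1-based) index `i` lies at `origin + (i - 1) * spacing`. All distances in
#' the package are Euclidean distances between voxel centers, in mm.
#'
#' @param grid logical (or coercible) 3D array; `TRUE` marks occupied voxels.
#' @param spacing numeric length-3, mm per axis; all components must be > 0.
#' @param origin numeric length-3, physical position (mm) of the first voxel
#'   center. Defaults to the coordinate origin.
#' @return An object of class `annotated_volume`.
#' @examples
#' g <- array(FALSE, c(8, 8, 8)); g[4:5, 4:5, 4:5] <- TRUE
#' v <- annotated_volume(g, spacing = c(0.7, 0.7, 3.0))
#' volume_mm3(v)
#' @export
annotated_volume <- function(grid, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (is.null(dim(grid)) || length(dim(grid)) != 3L)
    stop("`grid` must be a 3D array", call. = FALSE)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive finite values (mm)", call. = FALSE)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite values (mm)", call. = FALSE)
  storage.mode(grid) <- "logical"
  grid[is.na(grid)] <- FALSE
  structure(list(grid = grid, spacing = spacing, origin = origin),
            class = "annotated_volume")
}

#' @export
print.annotated_volume <- function(x, ...) {
  cat(sprintf("<annotated_volume> %s voxels @ %s mm, %d occupied (%.1f mm^3)\n",
              paste(dim(x$grid), collapse = "x"),
              paste(format(x$spacing, trim = TRUE), collapse = "x"),
              sum(x$grid), volume_mm3(x)))
  invisible(x)
}

#' Scalar field on a volume grid
#'
#' Real-valued companion to [annotated_volume()]: same grid geometry, one
#' value (mm) per voxel. Produced by [distance_map()].
#'
#' @param values numeric 3D array.
#' @param spacing,origin grid geometry, as in [annotated_volume()].
#' @return An object of class `scalar_field`.
#' @export
scalar_field <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (is.null(dim(values)) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array", call. = FALSE)
  structure(list(values = values, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "scalar_field")
}

same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$grid), dim(b$grid)) &&
    max(abs(a$spacing - b$spacing)) < tol &&
    max(abs(a$origin - b$origin)) < tol
}

stop_if_grid_mismatch <- function(a, b) {
  if (!same_grid(a, b))
    stop("masks are not on the same grid (dimensions, spacing or origin differ); ",
         "resample with apply_transform() first", call. = FALSE)
  invisible(TRUE)
}

#' Physical coordinates of voxel centers
#'
#' @param vol an [annotated_volume()].
#' @param idx integer matrix of 1-based voxel indices (n x 3); defaults to
#'   the occupied voxels.
#' @return n x 3 matrix of mm coordinates.
#' @export
voxel_centers <- function(vol, idx = NULL) {
  if (is.null(idx)) idx <- which(vol$grid, arr.ind = TRUE)
  idx <- matrix(as.numeric(idx), ncol = 3L)
  sweep(sweep(idx - 1, 2L, vol$spacing, `*`), 2L, vol$origin, `+`)
}

#' Load a binary mask from a NIfTI file
#'
#' Reads a 3D NIfTI volume, reorients it to the canonical RAS anatomical
#' convention using its affine, and binarizes voxel values at > 0.5 (so
#' fuzzy-edged exports binarize deterministically). Spacing is taken from the
#' affine and preserved in mm.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return An [annotated_volume()]. An all-zero mask is returned with a
#'   warning, not an error.
#' @seealso [write_mask()]
#' @export
load_mask <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L)
    stop("expected a 3D volume, got ", length(dim(img)), " dimensions: ",
         path, call. = FALSE)
  aff <- RNifti::xform(img)
  rot <- aff[1:3, 1:3]
  if (!all(is.finite(rot)) || abs(det(rot)) < 1e-12)
    stop("degenerate or missing affine in ", path,
         ": cannot establish physical spacing/orientation", call. = FALSE)
  RNifti::orientation(img) <- "RAS"
  aff <- RNifti::xform(img)
  grid <- as.array(img) > 0.5
  # pixdim is stored as float32; snap to its decimal precision so that a
  # spacing written as 0.7 mm reads back as 0.7 mm
  spacing <- signif(RNifti::pixdim(img)[1:3], 7)
  vol <- annotated_volume(grid, spacing = spacing, origin = aff[1:3, 4])
  if (!any(vol$grid)) warning("mask is empty: ", path, call. = FALSE)
  vol
}

#' Write a binary mask to a NIfTI file
#'
#' @param vol an [annotated_volume()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_mask <- function(vol, path) {
  img <- RNifti::asNifti(array(as.integer(vol$grid), dim(vol$grid)))
  RNifti::pixdim(img) <- vol$spacing
  aff <- diag(4)
  diag(aff)[1:3] <- vol$spacing
  aff[1:3, 4] <- vol$origin
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Exact Euclidean distance map in millimeters
#'
#' Computes, for every voxel, the exact Euclidean distance (between voxel
#' centers, using the per-axis physical spacing) to the nearest voxel of the
#' selected region: `side = "outside"` measures distance to the nearest
#' occupied voxel (zero inside the mask; the field thresholded at `r` gives
#' the r-mm metric dilation), `side = "inside"` measures distance to the
#' nearest unoccupied voxel (depth inside the mask). Uses a separable
#' lower-envelope algorithm, so the result is the exact metric, not a
#' chamfer approximation.
#'
#' If the target region is empty (all-true or all-false grid), distances to
#' it are `+Inf`.
#'
#' @param vol an [annotated_volume()].
#' @param side `"outside"` (distance to the mask) or `"inside"` (distance to
#'   the background).
#' @return A [scalar_field()] of distances in mm.
#' @export
distance_map <- function(vol, side = c("outside", "inside")) {
  side <- match.arg(side)
  stopifnot(inherits(vol, "annotated_volume"))
  target <- if (side == "outside") vol$grid else !vol$grid
  d2 <- .edt_sq(as.logical(target), as.integer(dim(vol$grid)), vol$spacing)
  scalar_field(array(sqrt(d2), dim(vol$grid)),
               spacing = vol$spacing, origin = vol$origin)
}

#' Metric dilation by a physical radius
#'
#' Returns the set of voxels whose center lies within `r` mm of the mask
#' (Euclidean, anisotropic-aware): the r-mm safety envelope of a tumor mask.
#'
#' @param vol an [annotated_volume()].
#' @param r dilation radius in mm, `>= 0`; `r = 0` returns the input.
#' @return An [annotated_volume()] containing the dilated mask.
#' @export
dilate_mm <- function(vol, r) {
  stopifnot(inherits(vol, "annotated_volume"))
  if (!is.numeric(r) || length(r) != 1L || is.na(r) || r < 0)
    stop("`r` must be a single non-negative radius in mm", call. = FALSE)
  if (r == 0) return(vol)
  d <- distance_map(vol, "outside")
  annotated_volume(d$values <= r + 1e-9, spacing = vol$spacing,
                   origin = vol$origin)
}

#' Physical volume of a mask
#'
#' @param vol an [annotated_volume()].
#' @return Occupied-voxel count times voxel volume, in mm^3.
#' @export
volume_mm3 <- function(vol) {
  stopifnot(inherits(vol, "annotated_volume"))
  sum(vol$grid) * prod(vol$spacing)
}
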