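#' Construct a 3D volume
#'
#' A volume is a 3D scalar grid together with its voxel spacing (mm per
#' voxel along each axis) and physical origin (mm). Axis order is (x, y, z)
#' with z the slice direction; the physical coordinate of voxel index
#' (i, j, k), counted from 0, is `origin + (i*sx, j*sy, k*sz)`. All spatial
#' computation in the package happens in physical millimetres, so volumes
#' with anisotropic or mismatched voxel sizes are handled uniformly.
#'
#' @param data numeric 3D array of intensities.
#' @param spacing numeric length-3, mm per voxel; all components > 0.
#' @param origin numeric length-3, physical position (mm) of voxel (0,0,0).
#' @return An object of class `hep_volume`.
#' @export
volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("input error: `data` must be a 3D array, got ",
         paste(dim(data), collapse = "x"), call. = FALSE)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("input error: spacing must be 3 positive finite values", call. = FALSE)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("input error: origin must be 3 finite values", call. = FALSE)
  storage.mode(data) <- "double"
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "hep_volume")
}

#' Construct a binary mask
#'
#' A mask is a volume whose voxels are exactly 0 or 1. An all-zero mask is
#' rejected: an empty liver mask is an error state for every consumer in
#' the pipeline (registration, metrics, intensity masking).
#'
#' @inheritParams volume
#' @param allow_empty keep an all-zero mask instead of erroring (used only
#'   by internal resampling paths that validate emptiness themselves).
#' @return An object of class `c("hep_mask", "hep_volume")`.
#' @export
binary_mask <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                        allow_empty = FALSE) {
  v <- volume(data, spacing, origin)
  if (!all(v$data %in% c(0, 1)))
    stop("input error: mask voxels must be exactly 0 or 1", call. = FALSE)
  if (!allow_empty && sum(v$data) == 0)
    stop("input error: mask is empty (no voxel equals 1)", call. = FALSE)
  class(v) <- c("hep_mask", "hep_volume")
  v
}

is_mask <- function(x) inherits(x, "hep_mask")

#' @export
print.hep_volume <- function(x, ...) {
  kind <- if (is_mask(x)) "binary mask" else "volume"
  cat(sprintf("<hep_volume> %s %s voxels, spacing (%s) mm, origin (%s) mm\n",
              kind, paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing, trim = TRUE), collapse = ", "),
              paste(format(x$origin, trim = TRUE), collapse = ", ")))
  if (is_mask(x)) cat(sprintf("  foreground voxels: %d\n", sum(x$data)))
  invisible(x)
}

#' @export
dim.hep_volume <- function(x) dim(x$data)

# physical extent helpers ----------------------------------------------------

#' Physical coordinates of all voxel centres along one axis (mm)
#' @noRd
axis_coords <- function(v, axis) {
  v$origin[axis] + (seq_len(dim(v$data)[axis]) - 1) * v$spacing[axis]
}

#' Physical centre of the volume's field of view (mm)
#' @noRd
volume_center <- function(v) {
  v$origin + (dim(v$data) - 1) * v$spacing / 2
}

#' Mask centroid in physical coordinates
#'
#' @param mask a `hep_mask`.
#' @return numeric length-3, the intensity-weighted centre of the mask's
#'   foreground voxels in mm.
#' @export
mask_centroid <- function(mask) {
  stopifnot(is_mask(mask))
  idx <- which(mask$data == 1, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("input error: mask is empty", call. = FALSE)
  mask$origin + (colMeans(idx) - 1) * mask$spacing
}

#' Foreground volume of a mask in millilitres
#' @param mask a `hep_mask`.
#' @return scalar, mL (1 mL = 1000 mm^3).
#' @export
mask_volume_ml <- function(mask) {
  stopifnot(is_mask(mask))
  sum(mask$data) * prod(mask$spacing) / 1000
}

#' Check that two volumes live on the same grid
#' @noRd
same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$data), dim(b$data)) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

assert_same_grid <- function(a, b, what = "inputs") {
  if (!same_grid(a, b))
    stop("input error: ", what, " must share one grid (dims, spacing, origin)",
         call. = FALSE)
  invisible(TRUE)
}

# landmarks -------------------------------------------------------------------

#' Construct a landmark set
#'
#' Landmarks are labelled 3D points in the physical (mm) space of their
#' parent volume — here, centres of focal liver observations.
#'
#' @param label character vector of unique identifiers.
#' @param x,y,z numeric physical coordinates in mm.
#' @return A `data.frame` with columns `label`, `x`, `y`, `z` and class
#'   `hep_landmarks`.
#' @export
landmarks <- function(label, x, y, z) {
  label <- as.character(label)
  if (anyDuplicated(label))
    stop("input error: landmark labels must be unique within a set",
         call. = FALSE)
  n <- length(label)
  if (length(x) != n || length(y) != n || length(z) != n)
    stop("input error: label/x/y/z lengths differ", call. = FALSE)
  structure(data.frame(label = label, x = as.numeric(x), y = as.numeric(y),
                       z = as.numeric(z), stringsAsFactors = FALSE),
            class = c("hep_landmarks", "data.frame"))
}

landmark_matrix <- function(lms) as.matrix(lms[, c("x", "y", "z")])
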