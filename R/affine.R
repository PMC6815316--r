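#' Construct a 12-parameter affine parameter set
#'
#' The registration model has 12 degrees of freedom: 3 translations (mm),
#' 3 rotations (rad, applied as Rz Ry Rx), 3 strictly positive axis
#' scales (dimensionless) and 3 shears (dimensionless, upper-triangular
#' unit-diagonal entries hxy, hxz, hyz). The identity element is t = 0,
#' r = 0, s = 1, h = 0.
#'
#' @param translation numeric length-3, mm.
#' @param rotation numeric length-3, radians.
#' @param scale numeric length-3, all > 0.
#' @param shear numeric length-3.
#' @return An object of class `affine_params`.
#' @export
affine_params <- function(translation = c(0, 0, 0), rotation = c(0, 0, 0),
                          scale = c(1, 1, 1), shear = c(0, 0, 0)) {
  p <- list(translation = as.numeric(translation),
            rotation = as.numeric(rotation),
            scale = as.numeric(scale),
            shear = as.numeric(shear))
  if (any(lengths(p) != 3L))
    stop("parameter-domain error: each parameter group must have length 3",
         call. = FALSE)
  if (any(!is.finite(unlist(p))))
    stop("parameter-domain error: non-finite affine parameter", call. = FALSE)
  if (any(p$scale <= 0))
    stop("parameter-domain error: scale components must be > 0", call. = FALSE)
  structure(p, class = "affine_params")
}

#' @export
print.affine_params <- function(x, ...) {
  cat("<affine_params>\n")
  cat("  translation (mm): ", paste(signif(x$translation, 5), collapse = ", "), "\n")
  cat("  rotation   (rad): ", paste(signif(x$rotation, 5), collapse = ", "), "\n")
  cat("  scale           : ", paste(signif(x$scale, 5), collapse = ", "), "\n")
  cat("  shear           : ", paste(signif(x$shear, 5), collapse = ", "), "\n")
  invisible(x)
}

# flat vector form used by the optimizer: (tx,ty,tz, rx,ry,rz, sx,sy,sz, hxy,hxz,hyz)
params_to_vec <- function(p) {
  c(p$translation, p$rotation, p$scale, p$shear)
}

vec_to_params <- function(v) {
  affine_params(v[1:3], v[4:6], v[7:9], v[10:12])
}

param_group <- rep(c("translation", "rotation", "scale", "shear"), each = 3)

#' Build the homogeneous matrix of a parameter set
#'
#' Composition is fixed as `M x = T(t) + c + Rz Ry Rx H S (x - c)` with
#' rotation centre `c`: rotation, shear and scale act about the centre
#' (normally the static liver-mask centroid), then the translation is
#' applied. Centring on the organ decouples rotation/scale from
#' translation and stabilizes optimization. The returned matrix maps
#' static-space physical points (mm) into moving space — the pull-back
#' convention consumed directly by [resample()].
#'
#' @param params an [affine_params()] object.
#' @param center numeric length-3, rotation centre in mm.
#' @return An object of class `affine_matrix`: a 4x4 homogeneous matrix with
#'   its centre, direction tag (`"static_to_moving"`) and originating
#'   parameters attached.
#' @export
params_to_matrix <- function(params, center = c(0, 0, 0)) {
  stopifnot(inherits(params, "affine_params"))
  if (any(params$scale <= 0))
    stop("parameter-domain error: scale components must be > 0", call. = FALSE)
  center <- as.numeric(center)
  r <- params$rotation
  cx <- cos(r[1]); sx <- sin(r[1])
  cy <- cos(r[2]); sy <- sin(r[2])
  cz <- cos(r[3]); sz <- sin(r[3])
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  H <- rbind(c(1, params$shear[1], params$shear[2]),
             c(0, 1, params$shear[3]),
             c(0, 0, 1))
  A <- Rz %*% Ry %*% Rx %*% H %*% diag(params$scale)
  t_full <- params$translation + center - A %*% center
  M <- diag(4)
  M[1:3, 1:3] <- A
  M[1:3, 4] <- t_full
  new_affine_matrix(M, center, "static_to_moving", params)
}

new_affine_matrix <- function(mat, center, direction, params = NULL) {
  if (abs(det(mat[1:3, 1:3])) < 1e-12)
    stop("numerical error: affine matrix is singular", call. = FALSE)
  structure(list(mat = mat, center = as.numeric(center), direction = direction,
                 params = params),
            class = "affine_matrix")
}

#' The identity transform
#' @param center rotation centre recorded on the matrix (mm).
#' @return An `affine_matrix` equal to the identity.
#' @export
identity_matrix <- function(center = c(0, 0, 0)) {
  params_to_matrix(affine_params(), center)
}

#' @export
print.affine_matrix <- function(x, ...) {
  cat(sprintf("<affine_matrix> direction %s, centre (%s) mm\n", x$direction,
              paste(signif(x$center, 5), collapse = ", ")))
  print(signif(x$mat, 6))
  invisible(x)
}

#' Invert an affine transform
#'
#' @param m an `affine_matrix`.
#' @return The inverse transform, with the direction tag flipped. The
#'   originating parameter set does not survive inversion and is dropped.
#' @export
invert <- function(m) {
  stopifnot(inherits(m, "affine_matrix"))
  if (abs(det(m$mat[1:3, 1:3])) < 1e-12)
    stop("numerical error: matrix is singular, cannot invert", call. = FALSE)
  inv <- solve(m$mat)
  dir <- if (m$direction == "static_to_moving") "moving_to_static"
         else "static_to_moving"
  new_affine_matrix(inv, m$center, dir)
}

#' Map physical points through an affine transform
#'
#' @param m an `affine_matrix`.
#' @param points numeric length-3 vector or an n x 3 matrix of mm
#'   coordinates.
#' @return An n x 3 matrix of transformed coordinates; row order preserved.
#' @export
transform_points <- function(m, points) {
  stopifnot(inherits(m, "affine_matrix"))
  if (is.null(dim(points))) points <- matrix(points, ncol = 3, byrow = TRUE)
  points <- as.matrix(points)
  if (ncol(points) != 3)
    stop("input error: points must have 3 columns (x, y, z in mm)",
         call. = FALSE)
  out <- points %*% t(m$mat[1:3, 1:3])
  out <- sweep(out, 2, m$mat[1:3, 4], "+")
  dimnames(out) <- dimnames(points)
  out
}

#' Resample a volume onto a reference grid through an affine transform
#'
#' The transform must map the reference (static) physical space into the
#' moving physical space (pull-back). Each output voxel takes the moving
#' image's value at `M x` where `x` is the voxel's physical centre;
#' samples falling outside the moving field of view take `fill_value`.
#' Masks resampled with nearest-neighbour interpolation stay binary and
#' keep their mask class (possibly empty, when pushed out of view —
#' consumers validate emptiness).
#'
#' @param moving the volume being sampled.
#' @param m an `affine_matrix` with direction `static_to_moving`.
#' @param reference volume supplying the output grid (data unused).
#' @param interpolation `"linear"` (intensities) or `"nearest"` (masks).
#' @param fill_value value for out-of-field samples; 0 is background in
#'   both masks and magnitude images.
#' @return A volume on the reference grid.
#' @export
resample <- function(moving, m, reference,
                     interpolation = c("linear", "nearest"), fill_value = 0) {
  stopifnot(inherits(moving, "hep_volume"), inherits(m, "affine_matrix"),
            inherits(reference, "hep_volume"))
  interpolation <- match.arg(interpolation)
  interp_code <- switch(interpolation, nearest = 0L, linear = 1L)
  out <- cpp_resample(as.numeric(moving$data), dim(moving$data),
                      moving$spacing, moving$origin,
                      dim(reference$data), reference$spacing, reference$origin,
                      as.numeric(m$mat), interp_code, fill_value)
  arr <- array(out, dim = dim(reference$data))
  if (is_mask(moving) && interpolation == "nearest" &&
      fill_value %in% c(0, 1)) {
    binary_mask(arr, reference$spacing, reference$origin, allow_empty = TRUE)
  } else {
    volume(arr, reference$spacing, reference$origin)
  }
}

# transform JSON serialization ------------------------------------------------

transform_schema_version <- "hepalign-transform-1"

transform_to_list <- function(m) {
  list(format_version = transform_schema_version,
       matrix = as.numeric(t(m$mat)),  # row-major
       params = if (!is.null(m$params))
         list(translation = m$params$translation, rotation = m$params$rotation,
              scale = m$params$scale, shear = m$params$shear),
       center = m$center,
       direction = m$direction)
}

#' Write / read an affine transform as JSON
#'
#' The document carries the 16 matrix entries row-major, the 12 named
#' parameters when known, the rotation centre, the direction tag and a
#' format-version string.
#'
#' @param m an `affine_matrix`.
#' @param path file path.
#' @return `write_transform` returns `path` invisibly; `read_transform`
#'   returns the `affine_matrix`.
#' @export
write_transform <- function(m, path) {
  stopifnot(inherits(m, "affine_matrix"))
  jsonlite::write_json(transform_to_list(m), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  doc <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e)
                    stop("format error: not valid JSON: ", path,
                         call. = FALSE))
  if (is.null(doc$format_version) ||
      !identical(doc$format_version, transform_schema_version))
    stop("format error: not a recognised transform document: ", path,
         call. = FALSE)
  mat <- matrix(as.numeric(doc$matrix), 4, 4, byrow = TRUE)
  params <- if (!is.null(doc$params) && length(doc$params))
    affine_params(doc$params$translation, doc$params$rotation,
                  doc$params$scale, doc$params$shear)
  new_affine_matrix(mat, doc$center, doc$direction, params)
}
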