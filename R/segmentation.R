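#' Describe a mask source
#'
#' Registration consumes liver masks, not a particular segmenter; this spec
#' object makes the mask source pluggable. `kind = "threshold"` runs a
#' classical intensity threshold (numeric, or `"auto"` for a maximal
#' between-class-variance threshold on a 256-bin histogram) followed by
#' the standard mask post-processing; `kind = "file"` loads a precomputed
#' mask (e.g. from a segmentation CNN) and passes it through untouched.
#'
#' @param kind `"threshold"` or `"file"`.
#' @param threshold numeric intensity cut, or `"auto"`.
#' @param min_component_ml reject segmentations whose largest connected
#'   component is smaller than this volume (mL).
#' @param closing_radius morphological closing radius in voxels (0 skips).
#' @param mask_path NIfTI path, required when `kind = "file"`.
#' @return An object of class `segmenter_spec`.
#' @export
segmenter_spec <- function(kind = c("threshold", "file"), threshold = "auto",
                           min_component_ml = 1, closing_radius = 1,
                           mask_path = NULL) {
  kind <- match.arg(kind)
  if (kind == "file" && is.null(mask_path))
    stop("configuration error: kind = 'file' requires `mask_path`",
         call. = FALSE)
  if (kind == "threshold" &&
      !(identical(threshold, "auto") || is.numeric(threshold)))
    stop("configuration error: threshold must be numeric or 'auto'",
         call. = FALSE)
  structure(list(kind = kind, threshold = threshold,
                 min_component_ml = min_component_ml,
                 closing_radius = as.integer(closing_radius),
                 mask_path = mask_path),
            class = "segmenter_spec")
}

# maximal between-class variance threshold on a 256-bin histogram
otsu_threshold <- function(x, bins = 256L) {
  rng <- range(x)
  if (diff(rng) == 0)
    stop("segmentation-failure error: constant volume cannot be thresholded",
         call. = FALSE)
  h <- tabulate(pmin(floor((x - rng[1]) / diff(rng) * bins) + 1L, bins), bins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(bins))
  mu_t <- mu[bins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  k <- which.max(sigma_b)
  rng[1] + k / bins * diff(rng)
}

#' Segment the liver on a volume
#'
#' Produces the binary liver mask that drives registration. Thresholding
#' is the classical fallback standing behind the pluggable interface; a
#' trained segmentation model plugs in through `kind = "file"` masks and
#' the rest of the pipeline is unchanged.
#'
#' @param vol a [volume()].
#' @param spec a [segmenter_spec()].
#' @return A non-empty [binary_mask()] on the volume's grid, post-processed
#'   (largest component, hole fill, closing) for threshold masks; file
#'   masks are returned exactly as stored.
#' @export
segment <- function(vol, spec = segmenter_spec()) {
  stopifnot(inherits(vol, "hep_volume"), inherits(spec, "segmenter_spec"))
  if (spec$kind == "file") {
    m <- read_mask(spec$mask_path)
    assert_same_grid(vol, m, "volume and file mask")
    return(m)
  }
  x <- as.numeric(vol$data)
  if (diff(range(x)) == 0)
    stop("segmentation-failure error: volume is constant, nothing to segment",
         call. = FALSE)
  thr <- if (identical(spec$threshold, "auto")) otsu_threshold(x)
         else spec$threshold
  raw <- binary_mask(array(as.numeric(vol$data > thr), dim(vol$data)),
                     vol$spacing, vol$origin, allow_empty = TRUE)
  if (sum(raw$data) == 0)
    stop("segmentation-failure error: threshold ", signif(thr, 4),
         " selects no voxels", call. = FALSE)
  postprocess_mask(raw, spec)
}

ball_offsets <- function(radius) {
  r <- as.integer(radius)
  g <- expand.grid(i = -r:r, j = -r:r, k = -r:r)
  g <- g[g$i^2 + g$j^2 + g$k^2 <= radius^2, ]
  as.matrix(g)
}

dilate_mask <- function(m, radius) {
  if (radius < 1) return(m)
  out <- cpp_dilate(as.integer(m$data), dim(m$data), ball_offsets(radius))
  binary_mask(array(as.numeric(out), dim(m$data)), m$spacing, m$origin,
              allow_empty = TRUE)
}

# iterated unit-cross dilation/erosion: cheap approximation to a ball of
# radius k voxels, used where k can be large (phantom construction)
dilate_iter <- function(m, k) {
  off <- rbind(c(0, 0, 0), c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
               c(0, 0, 1), c(0, 0, -1))
  d <- as.integer(m$data)
  for (i in seq_len(k)) d <- cpp_dilate(d, dim(m$data), off)
  binary_mask(array(as.numeric(d), dim(m$data)), m$spacing, m$origin,
              allow_empty = TRUE)
}

erode_iter <- function(m, k) {
  inv <- binary_mask(array(1 - m$data, dim(m$data)), m$spacing, m$origin,
                     allow_empty = TRUE)
  d <- dilate_iter(inv, k)
  binary_mask(array(1 - d$data, dim(m$data)), m$spacing, m$origin,
              allow_empty = TRUE)
}

erode_mask <- function(m, radius) {
  if (radius < 1) return(m)
  inv <- binary_mask(array(1 - m$data, dim(m$data)), m$spacing, m$origin,
                     allow_empty = TRUE)
  d <- dilate_mask(inv, radius)
  binary_mask(array(1 - d$data, dim(m$data)), m$spacing, m$origin,
              allow_empty = TRUE)
}

#' Post-process a raw segmentation mask
#'
#' The standard morphology for organ masks: keep the largest 3D connected
#' component (26-connectivity), fill internal cavities, then apply a
#' morphological closing of the configured radius. The output lives on the
#' input grid.
#'
#' @param raw a [binary_mask()] (may contain islands/holes).
#' @param spec a [segmenter_spec()]; uses `closing_radius` and
#'   `min_component_ml`.
#' @return The cleaned [binary_mask()].
#' @export
postprocess_mask <- function(raw, spec = segmenter_spec()) {
  stopifnot(is_mask(raw))
  lab <- cpp_label3d(as.integer(raw$data), dim(raw$data), 26L)
  if (max(lab) == 0)
    stop("segmentation-failure error: mask empty after component filtering",
         call. = FALSE)
  counts <- tabulate(lab[lab > 0])
  keep <- which.max(counts)
  kept <- array(as.numeric(lab == keep), dim(raw$data))
  if (sum(kept) * prod(raw$spacing) / 1000 < spec$min_component_ml)
    stop("segmentation-failure error: largest component smaller than ",
         spec$min_component_ml, " mL", call. = FALSE)
  m <- binary_mask(kept, raw$spacing, raw$origin)
  filled <- cpp_fill_holes(as.integer(m$data), dim(m$data))
  m <- binary_mask(array(as.numeric(filled), dim(m$data)), m$spacing, m$origin)
  if (spec$closing_radius >= 1) {
    m <- erode_mask(dilate_mask(m, spec$closing_radius), spec$closing_radius)
  }
  m
}

#' Multiply a volume by its binary mask
#'
#' Builds the "intensity mask" registration input: original intensities
#' inside the liver, zero outside.
#'
#' @param vol a [volume()].
#' @param mask a non-empty [binary_mask()] on the same grid.
#' @return A [volume()] equal to the voxelwise product.
#' @export
make_intensity_mask <- function(vol, mask) {
  stopifnot(inherits(vol, "hep_volume"), is_mask(mask))
  assert_same_grid(vol, mask, "volume and mask")
  if (sum(mask$data) == 0)
    stop("input error: mask is empty", call. = FALSE)
  volume(vol$data * mask$data, vol$spacing, vol$origin)
}
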