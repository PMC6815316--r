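#' Slice-landmark z-alignment
#'
#' Emulates the first step of the radiologists' manual protocol: aligning
#' the slices depicting an internal landmark (in the clinic, the right
#' portal vein bifurcation) in both series. With landmark slice indices
#' supplied, the shift is pure slice arithmetic in physical mm:
#' `z_static(k_static) - z_moving(k_moving)`. Without them, an
#' exhaustive integer-slice search maximizing summed per-slice mask
#' overlap stands in (requires matching in-plane grids and equal slice
#' spacing).
#'
#' @param static_mask,moving_mask [binary_mask()] objects.
#' @param landmark_slice_static,landmark_slice_moving 1-based slice
#'   indices of the landmark; both or neither.
#' @return z-shift in mm: the static-space z of the landmark minus the
#'   moving-space z. (In the pull-back parameterization this enters the
#'   transform as `tz = -z_shift`.)
#' @export
z_align <- function(static_mask, moving_mask, landmark_slice_static = NULL,
                    landmark_slice_moving = NULL) {
  stopifnot(is_mask(static_mask), is_mask(moving_mask))
  nzs <- dim(static_mask$data)[3]
  nzm <- dim(moving_mask$data)[3]
  if (!is.null(landmark_slice_static) || !is.null(landmark_slice_moving)) {
    ks <- landmark_slice_static
    km <- landmark_slice_moving
    if (is.null(ks) || is.null(km))
      stop("input error: supply both landmark slices or neither",
           call. = FALSE)
    if (ks < 1 || ks > nzs || km < 1 || km > nzm)
      stop("input error: landmark slice index out of range", call. = FALSE)
    zs <- static_mask$origin[3] + (ks - 1) * static_mask$spacing[3]
    zm <- moving_mask$origin[3] + (km - 1) * moving_mask$spacing[3]
    return(zs - zm)
  }
  # fallback: exhaustive slice-shift search
  if (!identical(dim(static_mask$data)[1:2], dim(moving_mask$data)[1:2]) ||
      any(abs(static_mask$spacing - moving_mask$spacing) > 1e-6))
    stop("input error: overlap-search fallback needs matching grids; ",
         "supply landmark slices instead", call. = FALSE)
  sz <- static_mask$spacing[3]
  best_s <- 0L
  best_score <- -1
  for (s in -(nzm - 1):(nzs - 1)) {
    ks <- seq_len(nzs)
    km <- ks - s
    ok <- km >= 1 & km <= nzm
    if (!any(ok)) next
    score <- sum(static_mask$data[, , ks[ok]] * moving_mask$data[, , km[ok]])
    if (score > best_score) {
      best_score <- score
      best_s <- s
    }
  }
  best_s * sz + (static_mask$origin[3] - moving_mask$origin[3])
}

#' Rigid correction after z-alignment
#'
#' The second step of the manual-registration emulation: the moving mask
#' is scaled (isotropically), rotated and translated — never sheared — to
#' correct residual field-of-view and positioning differences. Runs the
#' standard optimizer with shear frozen, the three scales tied to one
#' isotropic factor, and the z-translation initialized at the slice
#' landmark shift; this is the most favorable realizable reading of a
#' human rigid correction, so comparisons against full-affine
#' registration are conservative.
#'
#' @param static_mask,moving_mask [binary_mask()] objects.
#' @param z_shift output of [z_align()], mm.
#' @param config base [registration_config()]; its `enabled_params`,
#'   `tie_scale` and mode are overridden to the rigid mask protocol.
#' @return An object of class `hep_baseline`: `z_shift`, `result` (the
#'   underlying `hep_registration`), `params`, `matrix`.
#' @export
rigid_correct <- function(static_mask, moving_mask, z_shift,
                          config = registration_config(mode = "binary_mask")) {
  stopifnot(is_mask(static_mask), is_mask(moving_mask))
  config$mode <- "binary_mask"
  config$loss <- "neg_soft_dice"
  config$enabled_params <- c(rep(TRUE, 6), TRUE, FALSE, FALSE, rep(FALSE, 3))
  config$tie_scale <- TRUE
  init <- affine_params(translation = c(0, 0, -z_shift))
  res <- register(static_mask, moving_mask, config, init = init)
  structure(list(z_shift = z_shift, result = res, params = res$params,
                 matrix = res$matrix, mode = "baseline"),
            class = "hep_baseline")
}

#' Full manual-registration emulation for one pair
#'
#' [z_align()] followed by [rigid_correct()].
#'
#' @inheritParams rigid_correct
#' @inheritParams z_align
#' @return A `hep_baseline` object.
#' @export
baseline_register <- function(static_mask, moving_mask,
                              landmark_slice_static = NULL,
                              landmark_slice_moving = NULL,
                              config = registration_config(mode = "binary_mask")) {
  zs <- z_align(static_mask, moving_mask, landmark_slice_static,
                landmark_slice_moving)
  rigid_correct(static_mask, moving_mask, zs, config)
}
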