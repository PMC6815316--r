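#' Registration configuration
#'
#' All knobs of the affine optimizer. The three input modes mirror the
#' three ways a pair can be presented: `binary_mask` (segmentation-derived
#' {0,1} masks — the primary method), `intensity_mask` (mask times
#' original intensities) and `whole_image` (no segmentation). Per-mode
#' default losses: negative soft Dice for binary masks (the natural
#' differentiable surrogate of the Jaccard score used for evaluation),
#' mean squared error on min-max-normalized intensities otherwise; a
#' negative normalized-cross-correlation loss is also selectable.
#'
#' Optimization runs over a multi-resolution pyramid (Gaussian smoothing
#' before each downsampling) on a common isotropic working grid, so the
#' capture range covers respiratory-scale displacements while the final
#' matrix is expressed in physical mm and applies exactly on native grids.
#'
#' @param mode `"binary_mask"`, `"intensity_mask"` or `"whole_image"`.
#' @param loss `"neg_soft_dice"`, `"mse"` or `"neg_ncc"`; `NULL` picks the
#'   per-mode default.
#' @param pyramid_factors strictly decreasing integer downsampling
#'   factors, last must be 1.
#' @param max_iters iterations per pyramid level (recycled).
#' @param learning_rates named list of Adam step sizes per parameter
#'   group: translation (mm), rotation (rad), scale, shear.
#' @param tolerance relative loss-change stopping threshold, evaluated
#'   over `tol_window` iterations.
#' @param tol_window window (iterations) for the stopping rule.
#' @param enabled_params logical length-12
#'   (tx,ty,tz,rx,ry,rz,sx,sy,sz,hxy,hxz,hyz); disabled parameters stay
#'   frozen at their initial values. This single mechanism implements
#'   rigid, z-only and full-affine variants.
#' @param tie_scale optimize a single isotropic scale applied to all three
#'   axes (used by the manual-registration emulator).
#' @param working_spacing isotropic working-grid spacing, mm.
#' @param crop_margin mm of context kept around the foreground bounding
#'   box on the static working grid (ignored in whole-image mode).
#' @param mi_bins histogram bins used when metrics are derived from a
#'   result.
#' @param seed integer; the default path is fully deterministic, but the
#'   seed is threaded through for optional stochastic extensions and
#'   recorded for provenance.
#' @return An object of class `registration_config`.
#' @export
registration_config <- function(mode = c("binary_mask", "intensity_mask",
                                         "whole_image"),
                                loss = NULL,
                                pyramid_factors = c(4L, 2L, 1L),
                                max_iters = c(100L, 120L, 25L),
                                learning_rates = list(translation = 1.0,
                                                      rotation = 0.01,
                                                      scale = 0.005,
                                                      shear = 0.005),
                                tolerance = 1e-5, tol_window = 10L,
                                enabled_params = rep(TRUE, 12L),
                                tie_scale = FALSE,
                                working_spacing = 1.5, crop_margin = 18,
                                mi_bins = 64L, seed = 0L) {
  mode <- match.arg(mode)
  if (is.null(loss))
    loss <- if (mode == "binary_mask") "neg_soft_dice" else "mse"
  loss <- match.arg(loss, c("neg_soft_dice", "mse", "neg_ncc"))
  pyramid_factors <- as.integer(pyramid_factors)
  if (any(diff(pyramid_factors) >= 0) ||
      pyramid_factors[length(pyramid_factors)] != 1L)
    stop("configuration error: pyramid_factors must be strictly decreasing ",
         "and end at 1", call. = FALSE)
  max_iters <- as.integer(rep_len(max_iters, length(pyramid_factors)))
  if (any(max_iters < 1L))
    stop("configuration error: max_iters must be >= 1", call. = FALSE)
  if (tolerance < 0)
    stop("configuration error: tolerance must be >= 0", call. = FALSE)
  if (length(enabled_params) != 12L || !is.logical(enabled_params))
    stop("configuration error: enabled_params must be 12 logicals",
         call. = FALSE)
  structure(list(mode = mode, loss = loss, pyramid_factors = pyramid_factors,
                 max_iters = max_iters, learning_rates = learning_rates,
                 tolerance = tolerance, tol_window = as.integer(tol_window),
                 enabled_params = enabled_params, tie_scale = tie_scale,
                 working_spacing = working_spacing, crop_margin = crop_margin,
                 mi_bins = as.integer(mi_bins), seed = as.integer(seed)),
            class = "registration_config")
}

#' Centroid-difference initialization
#'
#' Identity parameters except the translation, set to the difference of
#' the mask centroids (moving minus static, mm) so the pull-back matrix
#' maps the static liver centre onto the moving liver centre.
#'
#' @param static_mask,moving_mask non-empty [binary_mask()] objects.
#' @return An [affine_params()] object.
#' @export
initialize_params <- function(static_mask, moving_mask) {
  stopifnot(is_mask(static_mask), is_mask(moving_mask))
  if (sum(static_mask$data) == 0 || sum(moving_mask$data) == 0)
    stop("input error: mask is empty", call. = FALSE)
  affine_params(translation = mask_centroid(moving_mask) -
                  mask_centroid(static_mask))
}

#' Similarity loss between two images on one grid
#'
#' All losses are 0 at perfect agreement (for `neg_ncc`, perfect linear
#' agreement) and differentiable in the resampled values:
#' `mse` is the mean squared difference after min-max normalization of
#' each input; `neg_soft_dice` is `1 - 2*sum(ab) / (sum(a^2) + sum(b^2) +
#' 1e-7)`; `neg_ncc` is one minus the Pearson correlation.
#'
#' @param static,resampled_moving volumes on the same grid.
#' @param loss `"mse"`, `"neg_soft_dice"` or `"neg_ncc"`.
#' @return scalar loss.
#' @export
similarity_loss <- function(static, resampled_moving,
                            loss = c("mse", "neg_soft_dice", "neg_ncc")) {
  stopifnot(inherits(static, "hep_volume"),
            inherits(resampled_moving, "hep_volume"))
  loss <- match.arg(loss)
  assert_same_grid(static, resampled_moving, "loss inputs")
  a <- as.numeric(static$data)
  b <- as.numeric(resampled_moving$data)
  loss_fun(loss)(minmax(a), minmax(b))
}

minmax <- function(x) {
  rng <- range(x)
  if (diff(rng) == 0) return(x * 0)
  (x - rng[1]) / diff(rng)
}

loss_fun <- function(loss) {
  switch(loss,
    mse = function(a, b) mean((a - b)^2),
    neg_soft_dice = function(a, b) 1 - 2 * sum(a * b) /
      (sum(a * a) + sum(b * b) + 1e-7),
    neg_ncc = function(a, b) {
      if (stats::sd(a) == 0 || stats::sd(b) == 0) return(1)
      1 - stats::cor(a, b)
    })
}

# build an isotropic working copy of a volume; optionally crop to the
# bounding box of its nonzero voxels plus a margin
working_volume <- function(v, spacing, margin = NULL) {
  lo <- v$origin
  hi <- v$origin + (dim(v$data) - 1) * v$spacing
  if (!is.null(margin)) {
    idx <- which(v$data != 0, arr.ind = TRUE)
    if (nrow(idx) > 0) {
      blo <- v$origin + (apply(idx, 2, min) - 1) * v$spacing - margin
      bhi <- v$origin + (apply(idx, 2, max) - 1) * v$spacing + margin
      lo <- pmax(lo, blo)
      hi <- pmin(hi, bhi)
    }
  }
  dims <- pmax(2L, as.integer(floor((hi - lo) / spacing)) + 1L)
  ref <- volume(array(0, dims), rep(spacing, 3), lo)
  resample(v, identity_matrix(), ref, "linear")
}

# smooth + downsample a working volume by an integer factor
pyramid_level <- function(v, factor) {
  if (factor <= 1L) return(v)
  sm <- cpp_gauss_smooth(as.numeric(v$data), dim(v$data), rep(factor / 2, 3))
  smv <- volume(array(sm, dim(v$data)), v$spacing, v$origin)
  dims <- pmax(2L, as.integer(ceiling(dim(v$data) / factor)))
  ref <- volume(array(0, dims), v$spacing * factor, v$origin)
  resample(smv, identity_matrix(), ref, "linear")
}

#' Register a moving series onto a static series
#'
#' Estimates the 12 affine parameters that minimize the configured
#' similarity loss between the static input and the resampled moving
#' input, by Adam gradient descent with central-finite-difference
#' gradients over a coarse-to-fine pyramid. Deterministic given identical
#' inputs, config and seed. The result's matrix is in physical mm with
#' the pull-back (static-to-moving) direction, directly consumable by
#' [resample()] to map the entire moving series into static space.
#'
#' Disabled parameters ([registration_config()] `enabled_params`) stay at
#' their initial values; masked modes initialize the translation from the
#' mask centroids, whole-image mode starts at identity.
#'
#' @param static_input,moving_input both [binary_mask()] objects
#'   (`binary_mask` mode) or both [volume()] objects (intensity-mask /
#'   whole-image modes).
#' @param config a [registration_config()].
#' @param init optional [affine_params()] overriding the default
#'   initialization.
#' @return An object of class `hep_registration`: `params`, `matrix`,
#'   `loss_trajectory`, `converged`, `elapsed` (s), `mode`, `config`,
#'   `init_params`.
#' @export
register <- function(static_input, moving_input, config = registration_config(),
                     init = NULL) {
  t0 <- proc.time()[["elapsed"]]
  stopifnot(inherits(static_input, "hep_volume"),
            inherits(moving_input, "hep_volume"),
            inherits(config, "registration_config"))
  if (config$mode == "binary_mask") {
    if (!is_mask(static_input) || !is_mask(moving_input))
      stop("input error: binary_mask mode requires two binary masks",
           call. = FALSE)
  }
  if (is_mask(static_input) &&
      (sum(static_input$data) == 0 || sum(moving_input$data) == 0))
    stop("input error: mask is empty", call. = FALSE)

  center <- if (is_mask(static_input)) mask_centroid(static_input)
            else volume_center(static_input)
  if (is.null(init)) {
    init <- if (is_mask(static_input) && is_mask(moving_input))
      initialize_params(static_input, moving_input)
    else affine_params()
  }

  w <- config$working_spacing
  margin <- if (config$mode == "whole_image") NULL else config$crop_margin
  stat_w <- working_volume(static_input, w, margin)
  mov_w <- working_volume(moving_input, w, NULL)
  lfun <- loss_fun(config$loss)

  p <- params_to_vec(init)
  enabled <- config$enabled_params
  if (config$tie_scale) {
    # one isotropic scale lives in slot 7; slots 8-9 mirror it
    enabled[8:9] <- FALSE
    p[8:9] <- p[7]
  }
  expand_vec <- function(v) {
    if (config$tie_scale) v[8:9] <- v[7]
    v
  }
  lr <- unlist(config$learning_rates[param_group])
  fd_delta <- rep(c(0.5, 0.005, 0.002, 0.002), each = 3)

  trajectory <- numeric(0)
  converged <- FALSE
  best_p <- p
  p0 <- p  # initialization, re-checked at the finest level
  for (lev in seq_along(config$pyramid_factors)) {
    f <- config$pyramid_factors[lev]
    stat_l <- pyramid_level(stat_w, f)
    mov_l <- pyramid_level(mov_w, f)
    a <- as.numeric(stat_l$data)
    b_arr <- as.numeric(mov_l$data)
    if (config$loss == "mse") {
      a <- minmax(a)
      b_arr <- minmax(b_arr)
    }
    eval_loss <- function(v) {
      v <- expand_vec(v)
      if (any(v[7:9] <= 0)) return(Inf)
      m <- params_to_matrix(vec_to_params(v), center)
      warped <- cpp_resample(b_arr, dim(mov_l$data), mov_l$spacing,
                             mov_l$origin, dim(stat_l$data), stat_l$spacing,
                             stat_l$origin, as.numeric(m$mat), 1L, 0)
      lfun(a, warped)
    }
    if (!is.finite(eval_loss(p)))
      stop("numerical error: loss non-finite at initialization (level ",
           f, "); check input intensities", call. = FALSE)
    # coarse-to-fine parameter schedule: heavily smoothed masks are close
    # to ellipsoids, whose affine self-maps make shear nearly degenerate
    # with rotation/scale — so coarse levels keep shear frozen
    active <- enabled
    if (f > 2L) active[10:12] <- FALSE
    adam_m <- numeric(12)
    adam_v <- numeric(12)
    best_loss <- Inf
    hist <- numeric(0)
    stopped <- FALSE
    for (iter in seq_len(config$max_iters[lev])) {
      cur <- eval_loss(p)
      hist <- c(hist, cur)
      trajectory <- c(trajectory, cur)
      if (cur < best_loss) {
        best_loss <- cur
        best_p <- p
      }
      g <- numeric(12)
      for (i in which(active)) {
        d <- fd_delta[i]
        ph <- p; ph[i] <- ph[i] + d
        pl <- p; pl[i] <- pl[i] - d
        g[i] <- (eval_loss(ph) - eval_loss(pl)) / (2 * d)
      }
      adam_m <- 0.9 * adam_m + 0.1 * g
      adam_v <- 0.999 * adam_v + 0.001 * g^2
      mh <- adam_m / (1 - 0.9^iter)
      vh <- adam_v / (1 - 0.999^iter)
      step <- lr * mh / (sqrt(vh) + 1e-8)
      step[!active] <- 0
      p <- p - step
      p[7:9] <- pmax(p[7:9], 0.05)
      if (length(hist) > config$tol_window) {
        prev <- hist[length(hist) - config$tol_window]
        if (abs(prev - cur) / max(abs(prev), 1e-12) < config$tolerance) {
          stopped <- TRUE
          break
        }
      }
    }
    # carry the best parameters of this level into the next
    final <- eval_loss(p)
    if (final < best_loss) {
      best_loss <- final
      best_p <- p
    }
    if (lev == length(config$pyramid_factors)) {
      # guard against coarse-level drift: the initialization must never
      # beat the optimized result on the finest level
      init_loss <- eval_loss(p0)
      if (init_loss < best_loss) {
        best_loss <- init_loss
        best_p <- p0
      }
    }
    p <- best_p
    trajectory <- c(trajectory, best_loss)
    if (isTRUE(getOption("hepalign.verbose", FALSE)))
      message(sprintf("[hepalign] level %d/%d (factor %d): loss %.6g -> %.6g (%d iterations%s)",
                      lev, length(config$pyramid_factors), f, hist[1],
                      best_loss, length(hist),
                      if (stopped) ", tolerance reached" else ""))
    if (lev == length(config$pyramid_factors)) converged <- stopped
  }

  best_params <- vec_to_params(expand_vec(best_p))
  structure(list(params = best_params,
                 matrix = params_to_matrix(best_params, center),
                 loss_trajectory = trajectory,
                 converged = converged,
                 elapsed = proc.time()[["elapsed"]] - t0,
                 mode = config$mode,
                 config = config,
                 init_params = init),
            class = "hep_registration")
}

#' @export
print.hep_registration <- function(x, ...) {
  cat(sprintf("<hep_registration> mode %s, %d loss evaluations recorded\n",
              x$mode, length(x$loss_trajectory)))
  cat(sprintf("  loss %.6g -> %.6g, converged: %s, %.2f s\n",
              x$loss_trajectory[1], x$loss_trajectory[length(x$loss_trajectory)],
              x$converged, x$elapsed))
  print(x$params)
  invisible(x)
}
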