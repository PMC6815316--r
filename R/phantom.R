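#' Specification of a synthetic liver phantom
#'
#' The phantom emulates a hepatobiliary-phase series: a bright liver-like
#' blob (union of overlapping ellipsoids), a dark tubular vessel whose
#' central slice serves as the internal landmark slice, dark round
#' nodules standing in for focal liver observations (their centres are
#' the observation landmarks), Gaussian noise and an optional low-order
#' polynomial bias field. The uptake-scale factor multiplies liver
#' parenchyma intensity globally, emulating suboptimal contrast uptake.
#'
#' Default geometry: an 80 x 80 x 56 grid at 1.5 mm isotropic spacing
#' (120 x 120 x 84 mm field of view), which keeps a realistic liver
#' entirely in view under respiratory-scale perturbations while staying
#' cheap enough for seeded cohort studies. Nodule radii default to
#' 2-10 mm (4-20 mm diameters), within the range of reportable focal
#' observations.
#'
#' @param dim integer length-3 grid size (voxels).
#' @param spacing mm per voxel (default 1.5 isotropic; override per
#'   volume to emulate voxel-volume mismatch).
#' @param origin physical origin, mm.
#' @param liver_mean,liver_sd parenchyma intensity mean / texture SD.
#' @param background_mean,background_sd background intensity mean / SD.
#' @param vessel_intensity,vessel_radius dark vessel intensity and tube
#'   radius (mm).
#' @param n_nodules number of hypointense nodules (observation centres).
#' @param nodule_radius length-2 range of nodule radii, mm.
#' @param nodule_intensity nodule intensity.
#' @param noise_sd additive Gaussian noise SD (re-drawn independently for
#'   each series of a pair).
#' @param bias_amplitude amplitude of the low-order polynomial bias field
#'   (0 disables).
#' @param uptake_scale global liver intensity multiplier.
#' @param seed integer controlling every random choice in the phantom.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(dim = c(80L, 80L, 56L), spacing = c(1.5, 1.5, 1.5),
                         origin = c(0, 0, 0), liver_mean = 100, liver_sd = 5,
                         background_mean = 10, background_sd = 3,
                         vessel_intensity = 30, vessel_radius = 3,
                         n_nodules = 3L, nodule_radius = c(2, 10),
                         nodule_intensity = 40, noise_sd = 5,
                         bias_amplitude = 0, uptake_scale = 1, seed = 1L) {
  if (any(c(liver_mean, background_mean, vessel_intensity,
            nodule_intensity) < 0))
    stop("configuration error: intensities must be >= 0", call. = FALSE)
  if (any(nodule_radius <= 0))
    stop("configuration error: nodule radii must be > 0", call. = FALSE)
  structure(list(dim = as.integer(dim), spacing = as.numeric(spacing),
                 origin = as.numeric(origin), liver_mean = liver_mean,
                 liver_sd = liver_sd, background_mean = background_mean,
                 background_sd = background_sd,
                 vessel_intensity = vessel_intensity,
                 vessel_radius = vessel_radius, n_nodules = as.integer(n_nodules),
                 nodule_radius = nodule_radius,
                 nodule_intensity = nodule_intensity, noise_sd = noise_sd,
                 bias_amplitude = bias_amplitude, uptake_scale = uptake_scale,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

coord_arrays <- function(dim, spacing, origin) {
  xs <- origin[1] + (seq_len(dim[1]) - 1) * spacing[1]
  ys <- origin[2] + (seq_len(dim[2]) - 1) * spacing[2]
  zs <- origin[3] + (seq_len(dim[3]) - 1) * spacing[3]
  list(X = array(xs, dim),
       Y = array(rep(ys, each = dim[1]), dim),
       Z = array(rep(zs, each = dim[1] * dim[2]), dim),
       xs = xs, ys = ys, zs = zs)
}

# low-order (quadratic) polynomial field scaled to max |value| = amplitude
bias_field <- function(co, dim, amplitude) {
  nrm <- function(v) {
    r <- range(v)
    if (diff(r) == 0) return(v * 0)
    2 * (v - r[1]) / diff(r) - 1
  }
  Xn <- nrm(co$X); Yn <- nrm(co$Y); Zn <- nrm(co$Z)
  cf <- stats::runif(9, -1, 1)
  b <- cf[1] * Xn + cf[2] * Yn + cf[3] * Zn + cf[4] * Xn * Yn +
    cf[5] * Xn * Zn + cf[6] * Yn * Zn + cf[7] * Xn^2 + cf[8] * Yn^2 +
    cf[9] * Zn^2
  b / max(abs(b)) * amplitude
}

#' Generate a synthetic liver phantom
#'
#' Builds one static-series phantom from a [phantom_spec()]: the
#' intensity volume, its ground-truth liver mask, the observation
#' landmarks (nodule centres, mm) and the landmark slice index (central
#' slice of the embedded vessel). Bit-reproducible per seed.
#'
#' @param spec a [phantom_spec()].
#' @return An object of class `hep_phantom`: `volume`, `mask`, `clean`
#'   (noise- and bias-free intensities; the anatomy that a perturbed
#'   moving series is resampled from), `landmarks`, `landmark_slice`,
#'   `vessel_center`, `ellipsoids`, `spec`.
#' @export
make_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  dm <- spec$dim
  co <- coord_arrays(dm, spec$spacing, spec$origin)
  fov <- (dm - 1) * spec$spacing
  c0 <- spec$origin + fov / 2

  n_ell <- sample(2:4, 1)
  semi1 <- c(stats::runif(1, 0.22, 0.28) * fov[1],
             stats::runif(1, 0.20, 0.26) * fov[2],
             stats::runif(1, 0.22, 0.28) * fov[3])
  cen1 <- c0 + stats::runif(3, -3, 3)
  ellipsoids <- list(list(center = cen1, semi = semi1))
  for (e in seq_len(n_ell - 1)) {
    ellipsoids[[e + 1]] <- list(center = cen1 + stats::runif(3, -0.4, 0.4) * semi1,
                                semi = semi1 * stats::runif(3, 0.4, 0.7))
  }
  inside <- array(FALSE, dm)
  for (el in ellipsoids) {
    inside <- inside |
      (((co$X - el$center[1]) / el$semi[1])^2 +
       ((co$Y - el$center[2]) / el$semi[2])^2 +
       ((co$Z - el$center[3]) / el$semi[3])^2) <= 1
  }
  sm <- cpp_gauss_smooth(as.numeric(inside), dm, rep(1.5, 3))
  mask_arr <- array(as.numeric(sm >= 0.5), dm)
  mask <- binary_mask(mask_arr, spec$spacing, spec$origin)

  cen_m <- mask_centroid(mask)
  vessel <- mask_arr == 1 &
    ((co$Y - cen_m[2])^2 + (co$Z - cen_m[3])^2) <= spec$vessel_radius^2
  landmark_slice <- which.min(abs(co$zs - cen_m[3]))

  # nodules: dark spheres fully inside the liver
  lm_lab <- character(0)
  lm_pos <- matrix(numeric(0), ncol = 3)
  nodule_vox <- array(FALSE, dm)
  for (nd in seq_len(spec$n_nodules)) {
    placed <- FALSE
    for (try in 1:100) {
      r <- stats::runif(1, spec$nodule_radius[1], spec$nodule_radius[2])
      er <- erode_iter(mask, ceiling((r + 1) / min(spec$spacing)))
      cand <- which(er$data == 1)
      if (length(cand) == 0) next
      v <- cand[sample.int(length(cand), 1)]
      idx <- arrayInd(v, dm)
      ctr <- spec$origin + (idx - 1) * spec$spacing
      sph <- ((co$X - ctr[1])^2 + (co$Y - ctr[2])^2 + (co$Z - ctr[3])^2) <= r^2
      if (any(sph & mask_arr == 0)) next
      nodule_vox <- nodule_vox | sph
      lm_lab <- c(lm_lab, sprintf("nodule_%d", nd))
      lm_pos <- rbind(lm_pos, as.numeric(ctr))
      placed <- TRUE
      break
    }
    if (!placed)
      stop("generation error: could not place nodule ", nd,
           " inside the liver after bounded retries", call. = FALSE)
  }
  lms <- landmarks(lm_lab, lm_pos[, 1], lm_pos[, 2], lm_pos[, 3])

  clean <- array(spec$background_mean, dm) +
    array(stats::rnorm(prod(dm), 0, spec$background_sd), dm)
  liver_tex <- spec$liver_mean * spec$uptake_scale +
    stats::rnorm(sum(mask_arr), 0, spec$liver_sd)
  clean[mask_arr == 1] <- liver_tex
  clean[vessel] <- spec$vessel_intensity
  clean[nodule_vox] <- spec$nodule_intensity
  clean <- pmax(clean, 0)
  clean <- array(clean, dm)

  vol_arr <- clean + array(stats::rnorm(prod(dm), 0, spec$noise_sd), dm)
  if (spec$bias_amplitude > 0)
    vol_arr <- vol_arr + bias_field(co, dm, spec$bias_amplitude)

  structure(list(volume = volume(vol_arr, spec$spacing, spec$origin),
                 mask = mask,
                 clean = volume(clean, spec$spacing, spec$origin),
                 landmarks = lms, landmark_slice = landmark_slice,
                 vessel_center = cen_m, ellipsoids = ellipsoids, spec = spec),
            class = "hep_phantom")
}

#' Stamp a bright distractor structure into the background
#'
#' Adds a bright ellipsoid well away from the liver — an intensity
#' confound (e.g. stomach or subcutaneous fat analogue) that is placed
#' independently in the two series of a pair, so registration driven by
#' whole-image intensities can be misled while mask-driven registration
#' is untouched.
#'
#' @param vol the intensity [volume()] to modify.
#' @param mask the liver [binary_mask()] to stay clear of.
#' @param intensity distractor intensity.
#' @param seed placement seed.
#' @return The modified volume.
#' @export
stamp_distractor <- function(vol, mask, intensity = 110, seed = 1L) {
  stopifnot(inherits(vol, "hep_volume"), is_mask(mask))
  set.seed(seed)
  dm <- dim(vol$data)
  co <- coord_arrays(dm, vol$spacing, vol$origin)
  # keep clear of the liver by ~8 mm
  clear <- dilate_iter(mask, ceiling(8 / min(mask$spacing)))
  for (try in 1:200) {
    v <- sample.int(prod(dm), 1)
    idx <- arrayInd(v, dm)
    ctr <- vol$origin + (idx - 1) * vol$spacing
    semi <- stats::runif(3, 8, 16)
    sph <- (((co$X - ctr[1]) / semi[1])^2 + ((co$Y - ctr[2]) / semi[2])^2 +
            ((co$Z - ctr[3]) / semi[3])^2) <= 1
    if (any(sph & clear$data == 1)) next
    out <- vol$data
    out[sph] <- intensity
    return(volume(out, vol$spacing, vol$origin))
  }
  stop("generation error: no background room for a distractor", call. = FALSE)
}

#' Create a ground-truth pair from a phantom and known affine parameters
#'
#' The moving series is the phantom's noise-free anatomy resampled
#' through the inverse of the ground-truth matrix (so that registering
#' moving onto static should recover exactly these parameters), with
#' noise re-drawn independently — registration must not exploit shared
#' noise. Landmarks are mapped analytically through the matrix, never
#' through image resampling, so metric ground truth is exact to machine
#' precision.
#'
#' @param base a [make_phantom()] result.
#' @param params ground-truth [affine_params()]; the rotation centre is
#'   the static liver-mask centroid.
#' @param noise_seed seed for the moving series' independent noise.
#' @param moving_spacing optional length-3 spacing (mm) for the moving
#'   grid, emulating voxel-volume mismatch.
#' @param uptake_scale liver intensity multiplier applied to the moving
#'   series only.
#' @return An object of class `hep_pair`: `static` and `moving`
#'   (each `volume`, `mask`, `landmarks`, `landmark_slice`),
#'   `true_matrix`, `true_params`, `center`, `spec`.
#' @export
perturb_pair <- function(base, params, noise_seed = 1L, moving_spacing = NULL,
                         uptake_scale = 1) {
  stopifnot(inherits(base, "hep_phantom"), inherits(params, "affine_params"))
  center <- mask_centroid(base$mask)
  M <- params_to_matrix(params, center)
  Minv <- invert(M)

  ref <- if (is.null(moving_spacing)) {
    base$volume
  } else {
    ext <- (dim(base$volume$data) - 1) * base$volume$spacing
    dims <- as.integer(floor(ext / moving_spacing)) + 1L
    volume(array(0, dims), moving_spacing, base$volume$origin)
  }
  mov_clean <- resample(base$clean, Minv, ref, "linear")
  mov_mask <- resample(base$mask, Minv, ref, "nearest")
  kept <- sum(mov_mask$data) * prod(mov_mask$spacing)
  # the transform itself rescales volume by det(A); only true clipping counts
  expected <- sum(base$mask$data) * prod(base$mask$spacing) *
    det(M$mat[1:3, 1:3])
  if (kept < 0.8 * expected)
    stop("generation error: perturbation pushes > 20% of the liver outside ",
         "the field of view", call. = FALSE)
  if (uptake_scale != 1) {
    d <- mov_clean$data
    d[mov_mask$data == 1] <- d[mov_mask$data == 1] * uptake_scale
    mov_clean <- volume(d, mov_clean$spacing, mov_clean$origin)
  }
  set.seed(noise_seed)
  mv <- mov_clean$data
  if (base$spec$noise_sd > 0)
    mv <- mv + array(stats::rnorm(prod(dim(mv)), 0, base$spec$noise_sd),
                     dim(mv))
  if (base$spec$bias_amplitude > 0) {
    co <- coord_arrays(dim(mv), mov_clean$spacing, mov_clean$origin)
    mv <- mv + bias_field(co, dim(mv), base$spec$bias_amplitude)
  }
  mov_vol <- volume(mv, mov_clean$spacing, mov_clean$origin)

  mov_lm_pos <- transform_points(M, landmark_matrix(base$landmarks))
  mov_lms <- landmarks(base$landmarks$label, mov_lm_pos[, 1], mov_lm_pos[, 2],
                       mov_lm_pos[, 3])
  vessel_m <- transform_points(M, base$vessel_center)
  k_m <- round((vessel_m[3] - mov_vol$origin[3]) / mov_vol$spacing[3]) + 1
  k_m <- min(max(k_m, 1L), dim(mov_vol$data)[3])

  structure(list(static = list(volume = base$volume, mask = base$mask,
                               landmarks = base$landmarks,
                               landmark_slice = base$landmark_slice),
                 moving = list(volume = mov_vol, mask = mov_mask,
                               landmarks = mov_lms, landmark_slice = k_m),
                 true_matrix = M, true_params = params, center = center,
                 spec = base$spec),
            class = "hep_pair")
}

difficulty_ranges <- function(difficulty) {
  switch(difficulty,
    easy = list(t = 5, r = 3 * pi / 180, s = 0, h = 0,
                moving_spacing = NULL, uptake = 1),
    moderate = list(t = 15, r = 10 * pi / 180, s = 0.1, h = 0.1,
                    moving_spacing = NULL, uptake = 1),
    hard = list(t = 15, r = 10 * pi / 180, s = 0.1, h = 0.1,
                moving_spacing = c(2, 2, 3), uptake = 0.5),
    stop("configuration error: unknown difficulty ", difficulty,
         call. = FALSE))
}

#' Generate a seeded cohort of ground-truth pairs
#'
#' The synthetic analogue of a within-patient series-pair substudy: `n`
#' pairs with known affine ground truth, drawn from difficulty-dependent
#' perturbation ranges (easy: |t| <= 5 mm, |r| <= 3 deg; moderate:
#' |t| <= 15 mm, |r| <= 10 deg, scale 0.9-1.1, |shear| <= 0.1 — matching
#' respiratory-scale liver displacement; hard adds voxel-spacing mismatch
#' and uptake scale 0.5). With `confound = TRUE` each series additionally
#' receives an independently placed bright background distractor and the
#' moving series a strong bias field — intensity confounds that leave
#' masks untouched.
#'
#' @param n_pairs number of pairs (>= 1).
#' @param difficulty `"easy"`, `"moderate"` or `"hard"`.
#' @param seed cohort seed; every pair seed and perturbation derives from
#'   it.
#' @param out_dir optional directory: when given, volumes/masks are
#'   written as NIfTI, landmarks as tab-delimited tables, ground truth and
#'   a checksummed manifest as JSON.
#' @param confound add inconsistent intensity confounds (see above).
#' @param base_spec [phantom_spec()] shared by all pairs (per-pair seeds
#'   override its seed).
#' @return A list of [perturb_pair()] objects (class `hep_cohort`), with
#'   a `manifest` attribute; when `out_dir` is given the manifest is also
#'   written there as `manifest.json`.
#' @export
generate_cohort <- function(n_pairs, difficulty = c("moderate", "easy", "hard"),
                            seed = 1L, out_dir = NULL, confound = FALSE,
                            base_spec = phantom_spec()) {
  difficulty <- match.arg(difficulty)
  stopifnot(n_pairs >= 1)
  rg <- difficulty_ranges(difficulty)
  set.seed(seed)
  pair_seeds <- sample.int(1e6, n_pairs)
  noise_seeds <- sample.int(1e6, n_pairs)
  distractor_seeds <- matrix(sample.int(1e6, 2 * n_pairs), ncol = 2)
  draws <- lapply(seq_len(n_pairs), function(i) {
    affine_params(translation = stats::runif(3, -rg$t, rg$t),
                  rotation = stats::runif(3, -rg$r, rg$r),
                  scale = 1 + stats::runif(3, -rg$s, rg$s),
                  shear = stats::runif(3, -rg$h, rg$h))
  })
  pairs <- vector("list", n_pairs)
  for (i in seq_len(n_pairs)) {
    sp <- base_spec
    sp$seed <- pair_seeds[i]
    base <- make_phantom(sp)
    pr <- draws[[i]]
    pair <- tryCatch(
      perturb_pair(base, pr, noise_seed = noise_seeds[i],
                   moving_spacing = rg$moving_spacing,
                   uptake_scale = rg$uptake),
      error = function(e) {
        # deterministic fallback: damp the translation and retry once
        pr2 <- affine_params(pr$translation * 0.5, pr$rotation, pr$scale,
                             pr$shear)
        perturb_pair(base, pr2, noise_seed = noise_seeds[i],
                     moving_spacing = rg$moving_spacing,
                     uptake_scale = rg$uptake)
      })
    if (confound) {
      pair$static$volume <- stamp_distractor(pair$static$volume,
                                             pair$static$mask,
                                             intensity = base_spec$liver_mean,
                                             seed = distractor_seeds[i, 1])
      mv <- stamp_distractor(pair$moving$volume, pair$moving$mask,
                             intensity = base_spec$liver_mean,
                             seed = distractor_seeds[i, 2])
      set.seed(distractor_seeds[i, 2] + 1L)
      co <- coord_arrays(dim(mv$data), mv$spacing, mv$origin)
      mv <- volume(mv$data + bias_field(co, dim(mv$data),
                                        0.3 * base_spec$liver_mean),
                   mv$spacing, mv$origin)
      pair$moving$volume <- mv
    }
    pair$pair_id <- sprintf("pair_%03d", i)
    pairs[[i]] <- pair
  }
  class(pairs) <- "hep_cohort"
  manifest <- list(schema_version = "hepalign-cohort-1",
                   n_pairs = n_pairs, difficulty = difficulty, seed = seed,
                   confound = confound,
                   pair_ids = vapply(pairs, function(p) p$pair_id, ""))
  attr(pairs, "manifest") <- manifest
  if (!is.null(out_dir)) write_cohort(pairs, out_dir)
  pairs
}

write_cohort <- function(pairs, out_dir) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("io error: cannot create directory ", out_dir, call. = FALSE)
  manifest <- attr(pairs, "manifest")
  files <- character(0)
  for (p in pairs) {
    id <- p$pair_id
    f <- c(static_volume = file.path(out_dir, paste0(id, "_static.nii.gz")),
           static_mask = file.path(out_dir, paste0(id, "_static_mask.nii.gz")),
           moving_volume = file.path(out_dir, paste0(id, "_moving.nii.gz")),
           moving_mask = file.path(out_dir, paste0(id, "_moving_mask.nii.gz")),
           static_lms = file.path(out_dir, paste0(id, "_static_landmarks.tsv")),
           moving_lms = file.path(out_dir, paste0(id, "_moving_landmarks.tsv")),
           truth = file.path(out_dir, paste0(id, "_truth.json")))
    write_volume(p$static$volume, f[["static_volume"]])
    write_mask(p$static$mask, f[["static_mask"]])
    write_volume(p$moving$volume, f[["moving_volume"]])
    write_mask(p$moving$mask, f[["moving_mask"]])
    write_landmarks(p$static$landmarks, f[["static_lms"]])
    write_landmarks(p$moving$landmarks, f[["moving_lms"]])
    truth <- transform_to_list(p$true_matrix)
    truth$landmark_slice_static <- p$static$landmark_slice
    truth$landmark_slice_moving <- p$moving$landmark_slice
    jsonlite::write_json(truth, f[["truth"]], auto_unbox = TRUE, digits = NA)
    files <- c(files, f)
  }
  manifest$files <- as.list(stats::setNames(as.character(files), names(files)))
  manifest$checksums <- as.list(tools::md5sum(as.character(files)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
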