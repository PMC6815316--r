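test_that("phantom generation is bit-reproducible per seed", {
  p1 <- make_phantom(small_spec(seed = 12))
  p2 <- make_phantom(small_spec(seed = 12))
  expect_identical(p1$volume$data, p2$volume$data)
  expect_identical(p1$mask$data, p2$mask$data)
  expect_identical(as.data.frame(p1$landmarks), as.data.frame(p2$landmarks))
  p3 <- make_phantom(small_spec(seed = 13))
  expect_false(identical(p1$volume$data, p3$volume$data))
})

test_that("nodule landmarks sit inside the liver mask", {
  sp <- small_spec(seed = 14)
  sp$n_nodules <- 3L
  ph <- make_phantom(sp)
  expect_equal(nrow(ph$landmarks), 3L)
  for (i in seq_len(3)) {
    idx <- round((as.numeric(ph$landmarks[i, c("x", "y", "z")]) -
                    ph$mask$origin) / ph$mask$spacing) + 1
    expect_equal(ph$mask$data[idx[1], idx[2], idx[3]], 1)
  }
})

test_that("liver mask volume tracks the generating ellipsoid union", {
  ph <- make_phantom(phantom_spec(seed = 15))
  # Monte-Carlo volume of the analytic ellipsoid union
  set.seed(99)
  dm <- dim(ph$volume$data)
  fov_lo <- ph$volume$origin
  fov_hi <- ph$volume$origin + (dm - 1) * ph$volume$spacing
  n <- 2e5
  pts <- cbind(stats::runif(n, fov_lo[1], fov_hi[1]),
               stats::runif(n, fov_lo[2], fov_hi[2]),
               stats::runif(n, fov_lo[3], fov_hi[3]))
  inside <- rep(FALSE, n)
  for (el in ph$ellipsoids) {
    inside <- inside |
      (((pts[, 1] - el$center[1]) / el$semi[1])^2 +
       ((pts[, 2] - el$center[2]) / el$semi[2])^2 +
       ((pts[, 3] - el$center[3]) / el$semi[3])^2) <= 1
  }
  analytic_ml <- mean(inside) * prod(fov_hi - fov_lo) / 1000
  expect_lt(abs(mask_volume_ml(ph$mask) - analytic_ml) / analytic_ml, 0.3)
})

test_that("perturbed pairs carry exact, mutually consistent ground truth", {
  sp <- small_spec(seed = 16, noise_sd = 0)
  ph <- make_phantom(sp)
  idp <- perturb_pair(ph, affine_params(), noise_seed = 1)
  expect_identical(idp$moving$volume$data, idp$static$volume$data)
  expect_identical(idp$moving$mask$data, idp$static$mask$data)

  pr <- affine_params(translation = c(6, -4, 3), rotation = c(0.08, 0, 0.1),
                      scale = c(1.05, 0.95, 1), shear = c(0.05, 0, -0.05))
  pair <- perturb_pair(ph, pr, noise_seed = 2)
  expect_identical(pair$true_matrix$mat,
                   params_to_matrix(pr, mask_centroid(ph$mask))$mat)
  d <- landmark_distance(pair$static$landmarks, pair$moving$landmarks,
                         pair$true_matrix)
  expect_lt(max(d), 1e-6)
  expect_true(all(pair$moving$mask$data %in% c(0, 1)))
})

test_that("extreme perturbations that clip the liver are refused", {
  ph <- make_phantom(small_spec(seed = 17))
  expect_error(perturb_pair(ph, affine_params(translation = c(60, 0, 0))),
               "field of view")
})

test_that("difficulty widens perturbations: easy overlaps beat hard", {
  pre_j <- function(difficulty) {
    coh <- generate_cohort(3, difficulty, seed = 18,
                           base_spec = small_spec())
    vapply(coh, function(p)
      jaccard(p$static$mask,
              resample(p$moving$mask, identity_matrix(), p$static$mask,
                       "nearest")), 0)
  }
  expect_gt(mean(pre_j("easy")), mean(pre_j("hard")))
})

test_that("written cohorts are reproducible file-for-file", {
  d1 <- file.path(tempdir(), "coh1")
  d2 <- file.path(tempdir(), "coh2")
  unlink(c(d1, d2), recursive = TRUE)
  generate_cohort(2, "easy", seed = 19, out_dir = d1,
                  base_spec = small_spec())
  generate_cohort(2, "easy", seed = 19, out_dir = d2,
                  base_spec = small_spec())
  f1 <- sort(list.files(d1))
  f2 <- sort(list.files(d2))
  expect_identical(f1, f2)
  for (f in setdiff(f1, "manifest.json")) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     info = f)
  }
  # the round trip reproduces the in-memory cohort
  coh <- read_cohort(d1)
  expect_length(coh, 2)
  expect_s3_class(coh[[1]]$static$mask, "hep_mask")
  expect_equal(length(attr(coh, "manifest")$pair_ids), 2)
})
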