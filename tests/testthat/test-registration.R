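test_that("similarity losses match hand-counted values", {
  a <- array(0, c(4, 4, 1)); a[1:2, 1:2, 1] <- 1
  ma <- binary_mask(a)
  expect_lt(similarity_loss(ma, ma, "neg_soft_dice"), 1e-6)

  b <- array(0, c(4, 4, 1)); b[3:4, 3:4, 1] <- 1
  expect_equal(similarity_loss(ma, binary_mask(b), "neg_soft_dice"), 1,
               tolerance = 1e-6)

  # |A| = |B| = 4, overlap 2: 1 - 2*2/(4+4) = 0.5
  c_ <- array(0, c(4, 4, 1)); c_[2:3, 1, 1] <- 1; c_[1:2, 3, 1] <- 1
  a2 <- array(0, c(4, 4, 1)); a2[1:4, 1, 1] <- 1
  ov <- sum(a2 * c_)
  expect_equal(ov, 2)
  expect_equal(similarity_loss(binary_mask(a2), binary_mask(c_),
                               "neg_soft_dice"), 0.5, tolerance = 1e-6)

  v <- random_volume(c(5, 5, 5))
  expect_equal(similarity_loss(v, v, "mse"), 0)
  expect_equal(similarity_loss(v, v, "neg_ncc"), 0, tolerance = 1e-12)
  expect_error(similarity_loss(v, random_volume(c(4, 4, 4)), "mse"), "grid")
})

test_that("centroid initialization reduces to slice arithmetic", {
  ph <- make_phantom(small_spec(seed = 5))
  init <- initialize_params(ph$mask, ph$mask)
  expect_equal(init$translation, c(0, 0, 0))
  expect_equal(init$rotation, c(0, 0, 0))

  # shift the mask one voxel along z: centroid moves by exactly sz
  a <- ph$mask$data
  shifted <- array(0, dim(a))
  shifted[, , 2:dim(a)[3]] <- a[, , 1:(dim(a)[3] - 1)]
  stopifnot(sum(shifted) == sum(a))  # nothing clipped for this phantom
  ms <- binary_mask(shifted, ph$mask$spacing, ph$mask$origin)
  init <- initialize_params(ph$mask, ms)
  expect_equal(init$translation, c(0, 0, ph$mask$spacing[3]),
               tolerance = 1e-9)
})

test_that("self-registration stays at identity and never worsens the loss", {
  ph <- make_phantom(small_spec(seed = 6))
  reg <- register(ph$mask, ph$mask, cheap_config())
  expect_lt(max(abs(reg$params$translation)), 0.5)
  expect_lt(max(abs(reg$params$rotation)), 0.01)
  j <- jaccard(ph$mask, resample(ph$mask, reg$matrix, ph$mask, "nearest"))
  expect_gte(j, 0.99)
  tr <- reg$loss_trajectory
  expect_gt(length(tr), 0)
  expect_lte(tr[length(tr)], tr[1])
})

test_that("a known translation is recovered to within a voxel", {
  ph <- make_phantom(phantom_spec(seed = 7))
  pair <- perturb_pair(ph, affine_params(translation = c(8, -5, 4)),
                       noise_seed = 11)
  reg <- register(pair$static$mask, pair$moving$mask,
                  registration_config(mode = "binary_mask"))
  expect_lt(max(abs(reg$params$translation - c(8, -5, 4))), 1)
  j <- jaccard(pair$static$mask,
               resample(pair$moving$mask, reg$matrix, pair$static$mask,
                        "nearest"))
  expect_gte(j, 0.98)
})

test_that("registration is bit-deterministic for a fixed config and seed", {
  ph <- make_phantom(small_spec(seed = 8))
  pair <- perturb_pair(ph, affine_params(translation = c(5, 3, -4),
                                         rotation = c(0.05, 0, -0.04)),
                       noise_seed = 9)
  cfg <- cheap_config(max_iters = c(30L, 20L, 8L))
  r1 <- register(pair$static$mask, pair$moving$mask, cfg)
  r2 <- register(pair$static$mask, pair$moving$mask, cfg)
  expect_identical(unclass(r1$params), unclass(r2$params))
  expect_identical(r1$matrix$mat, r2$matrix$mat)
  expect_identical(r1$loss_trajectory, r2$loss_trajectory)
})

test_that("invalid registration inputs are rejected", {
  ph <- make_phantom(small_spec(seed = 9))
  expect_error(register(ph$volume, ph$volume,
                        registration_config(mode = "binary_mask")),
               "binary_mask mode")
  expect_error(registration_config(pyramid_factors = c(2, 4, 1)),
               "pyramid")
  expect_error(registration_config(tolerance = -1), "tolerance")
})
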