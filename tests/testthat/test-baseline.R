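test_that("z-alignment reduces to slice arithmetic and search agrees", {
  ph <- make_phantom(small_spec(seed = 21))
  m <- ph$mask
  expect_equal(z_align(m, m, 10, 10), 0)

  # moving = static shifted +2 slices; sz = 3 mm
  a <- m$data
  nz <- dim(a)[3]
  shifted <- array(0, dim(a))
  shifted[, , 3:nz] <- a[, , 1:(nz - 2)]
  stopifnot(sum(shifted) == sum(a))
  sm <- binary_mask(m$data, c(2, 2, 3), m$origin)
  mm <- binary_mask(shifted, c(2, 2, 3), m$origin)
  # landmark on slice 10 in static appears on slice 12 in moving
  zshift <- z_align(sm, mm, 10, 12)
  expect_equal(zshift, -6)
  expect_equal(abs(zshift), 6)
  # the overlap-search fallback lands on the same shift
  expect_equal(z_align(sm, mm), -6)

  expect_error(z_align(sm, mm, 10, 999), "out of range")
  expect_error(z_align(sm, mm, 10, NULL), "both")
})

test_that("rigid correction recovers pure z-shifts and stays rigid", {
  sp <- small_spec(seed = 22)
  ph <- make_phantom(sp)
  pair <- perturb_pair(ph, affine_params(translation = c(0, 0, 6)),
                       noise_seed = 3)
  b <- baseline_register(pair$static$mask, pair$moving$mask,
                         pair$static$landmark_slice,
                         pair$moving$landmark_slice,
                         cheap_config())
  # transform is (almost) a pure z translation
  expect_lt(max(abs(b$params$translation[1:2])), 1)
  expect_lt(abs(b$params$translation[3] - 6), 1)
  j <- jaccard(pair$static$mask,
               resample(pair$moving$mask, b$matrix, pair$static$mask,
                        "nearest"))
  expect_gte(j, 0.99)

  # the manual emulation can never shear, and its scale is isotropic
  expect_identical(b$params$shear, c(0, 0, 0))
  expect_equal(b$params$scale[1], b$params$scale[2])
  expect_equal(b$params$scale[1], b$params$scale[3])
  # rotation block is unit-determinant times the isotropic scale cubed
  expect_equal(det(b$matrix$mat[1:3, 1:3]), b$params$scale[1]^3,
               tolerance = 1e-9)
})

test_that("self-pair baseline settles at identity", {
  ph <- make_phantom(small_spec(seed = 23))
  b <- baseline_register(ph$mask, ph$mask, ph$landmark_slice,
                         ph$landmark_slice, cheap_config())
  expect_lt(max(abs(b$params$translation)), 0.5)
  expect_lt(max(abs(b$params$rotation)), 0.01)
})

test_that("on pure translations baseline matches full affine within 1 mm", {
  ph <- make_phantom(small_spec(seed = 24))
  pair <- perturb_pair(ph, affine_params(translation = c(6, -4, 6)),
                       noise_seed = 5)
  b <- baseline_register(pair$static$mask, pair$moving$mask,
                         pair$static$landmark_slice,
                         pair$moving$landmark_slice, cheap_config())
  full <- register(pair$static$mask, pair$moving$mask, cheap_config())
  expect_lt(max(abs(b$params$translation - full$params$translation)), 1)
})

test_that("shear in the truth favours the full affine model", {
  ph <- make_phantom(small_spec(seed = 25))
  pair <- perturb_pair(ph, affine_params(translation = c(4, 2, -3),
                                         shear = c(0.12, -0.1, 0.1)),
                       noise_seed = 6)
  b <- baseline_register(pair$static$mask, pair$moving$mask,
                         pair$static$landmark_slice,
                         pair$moving$landmark_slice, cheap_config())
  full <- register(pair$static$mask, pair$moving$mask, cheap_config())
  jb <- jaccard(pair$static$mask,
                resample(pair$moving$mask, b$matrix, pair$static$mask,
                         "nearest"))
  jf <- jaccard(pair$static$mask,
                resample(pair$moving$mask, full$matrix, pair$static$mask,
                         "nearest"))
  expect_gt(jf, jb)
})
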