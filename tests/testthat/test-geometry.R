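test_that("parameter-to-matrix construction matches closed forms", {
  # identity parameters give the exact identity matrix, any centre
  m <- params_to_matrix(affine_params(), center = c(12.3, -4, 7))
  expect_identical(m$mat, diag(4))
  expect_identical(m$direction, "static_to_moving")

  # pure translation fills only the translation column
  mt <- params_to_matrix(affine_params(translation = c(5, 0, 0)))
  expected <- diag(4)
  expected[1, 4] <- 5
  expect_equal(mt$mat, expected)

  # quarter-turn about z: closed-form z-rotation sends (1,0,0) to (0,1,0)
  mr <- params_to_matrix(affine_params(rotation = c(0, 0, pi / 2)),
                         center = c(0, 0, 0))
  p <- transform_points(mr, c(1, 0, 0))
  expect_equal(as.numeric(p), c(0, 1, 0), tolerance = 1e-9)

  expect_error(affine_params(scale = c(1, -1, 1)), "scale")
})

test_that("determinant equals the product of scales for random parameters", {
  set.seed(11)
  for (i in 1:20) {
    pr <- random_params()
    m <- params_to_matrix(pr, center = stats::runif(3, -20, 20))
    expect_equal(det(m$mat[1:3, 1:3]), prod(pr$scale), tolerance = 1e-9)
  }
})

test_that("inversion is exact and round-trips points", {
  expect_identical(invert(identity_matrix())$mat, diag(4))

  mt <- params_to_matrix(affine_params(translation = c(5, 0, 0)))
  expect_equal(invert(mt)$mat[1:3, 4], c(-5, 0, 0))
  expect_identical(invert(mt)$direction, "moving_to_static")

  set.seed(21)
  for (i in 1:20) {
    m <- params_to_matrix(random_params(), center = stats::runif(3, -20, 20))
    expect_lt(max(abs(invert(m)$mat %*% m$mat - diag(4))), 1e-9)
    pts <- matrix(stats::runif(300, -50, 50), ncol = 3)
    back <- transform_points(invert(m), transform_points(m, pts))
    expect_lt(max(abs(back - pts)), 1e-6)
  }
})

test_that("point mapping follows hand-evaluated cases", {
  pts <- matrix(stats::runif(30, -10, 10), ncol = 3)
  expect_equal(transform_points(identity_matrix(), pts), pts)

  mt <- params_to_matrix(affine_params(translation = c(3, 4, 0)))
  expect_equal(as.numeric(transform_points(mt, c(0, 0, 0))), c(3, 4, 0))

  # scaling by 2 about centre (1,1,1): C S C^-1 maps (2,1,1) -> (3,1,1)
  ms <- params_to_matrix(affine_params(scale = c(2, 2, 2)),
                         center = c(1, 1, 1))
  expect_equal(as.numeric(transform_points(ms, c(2, 1, 1))), c(3, 1, 1))
})

test_that("identity resampling onto the source grid is lossless", {
  set.seed(31)
  v <- random_volume(c(9, 8, 7), spacing = c(1.5, 2, 2.5))
  for (interp in c("nearest", "linear")) {
    out <- resample(v, identity_matrix(), v, interp)
    expect_identical(out$data, v$data)
  }
  m <- random_mask(c(9, 8, 7))
  out <- resample(m, identity_matrix(), m, "nearest")
  expect_identical(out$data, m$data)
  expect_s3_class(out, "hep_mask")
})

test_that("one-voxel translation matches the index-shift oracle", {
  set.seed(32)
  v <- random_volume(c(10, 7, 6), spacing = c(2, 1, 1))
  mt <- params_to_matrix(affine_params(translation = c(2, 0, 0)))
  out <- resample(v, mt, v, "nearest", fill_value = -99)
  expected <- array(-99, dim(v$data))
  expected[1:9, , ] <- v$data[2:10, , ]
  expect_identical(out$data, expected)
})

test_that("half-voxel linear interpolation averages a step interface", {
  a <- array(0, c(8, 4, 4))
  a[5:8, , ] <- 1
  v <- volume(a, spacing = c(1, 1, 1))
  mt <- params_to_matrix(affine_params(translation = c(0.5, 0, 0)))
  out <- resample(v, mt, v, "linear")
  # at the step the two neighbours 0|1 blend to exactly 0.5
  expect_equal(out$data[4, 2, 2], 0.5)
  expect_equal(out$data[2, 2, 2], 0)
  expect_equal(out$data[6, 2, 2], 1)
})

test_that("transform JSON round-trips matrix, parameters and metadata", {
  pr <- random_params()
  m <- params_to_matrix(pr, center = c(1, 2, 3))
  f <- tempfile(fileext = ".json")
  write_transform(m, f)
  back <- read_transform(f)
  expect_equal(back$mat, m$mat)
  expect_equal(back$center, m$center)
  expect_identical(back$direction, m$direction)
  expect_equal(unclass(back$params), unclass(pr))
  expect_error(read_transform(write_landmarks(landmarks("a", 1, 2, 3),
                                              tempfile(fileext = ".json"))),
               "format")
})
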