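test_that("jaccard matches analytic identities and a counted fixture", {
  m <- random_mask(c(6, 6, 6), p = 0.5)
  expect_equal(jaccard(m, m), 1)

  a <- array(0, c(4, 4, 1)); a[1:2, 1, 1] <- 1
  b <- array(0, c(4, 4, 1)); b[3:4, 1, 1] <- 1
  expect_equal(jaccard(binary_mask(a), binary_mask(b)), 0)

  # |A| = 4, |B| = 4, |A n B| = 2 -> |A u B| = 6 -> 1/3
  a <- array(0, c(4, 4, 1)); a[1:4, 1, 1] <- 1
  b <- array(0, c(4, 4, 1)); b[3:4, 1, 1] <- 1; b[1:2, 2, 1] <- 1
  expect_equal(jaccard(binary_mask(a), binary_mask(b)), 1 / 3,
               tolerance = 1e-6)

  expect_error(jaccard(binary_mask(a),
                       binary_mask(array(1, c(3, 3, 3)))), "grid")
})

test_that("jaccard and mutual information match brute-force oracles", {
  set.seed(7)
  for (i in 1:20) {
    dm <- sample(4:16, 3, replace = TRUE)
    a <- random_mask(dm, p = stats::runif(1, 0.2, 0.7))
    b <- random_mask(dm, p = stats::runif(1, 0.2, 0.7))
    if (sum(a$data) == 0 || sum(b$data) == 0) next
    expect_equal(jaccard(a, b), oracle_jaccard(a, b), tolerance = 1e-9)

    va <- random_volume(dm)
    vb <- volume(va$data + array(stats::rnorm(prod(dm), 0, 0.5), dm))
    bins <- sample(4:16, 1)
    expect_equal(mutual_information(va, vb, bins = bins),
                 oracle_mi(va, vb, bins), tolerance = 1e-9)
  }
})

test_that("mutual information obeys its analytic identities", {
  # fair two-level image against itself carries exactly ln 2 nats
  a <- array(0, c(8, 8, 8))
  a[1:4, , ] <- 1
  v <- volume(a)
  expect_equal(mutual_information(v, v, bins = 2), log(2), tolerance = 1e-9)
  expect_equal(mutual_information(v, v, bins = 2, unit = "bits"), 1,
               tolerance = 1e-9)

  # a constant image has zero marginal entropy
  k <- volume(array(3.7, c(8, 8, 8)))
  r <- random_volume(c(8, 8, 8))
  expect_equal(mutual_information(r, k, bins = 16), 0)

  # self-MI equals the histogram entropy (independent entropy routine)
  set.seed(8)
  x <- random_volume(c(12, 12, 12))
  expect_equal(mutual_information(x, x, bins = 16),
               oracle_entropy(x, 16), tolerance = 1e-9)

  # symmetry to numerical precision
  y <- random_volume(c(12, 12, 12))
  expect_equal(mutual_information(x, y, bins = 16),
               mutual_information(y, x, bins = 16), tolerance = 1e-12)

  # independently seeded noise shares (almost) no information
  set.seed(91)
  n1 <- volume(array(stats::runif(64^3), c(64, 64, 64)))
  set.seed(92)
  n2 <- volume(array(stats::runif(64^3), c(64, 64, 64)))
  expect_lt(mutual_information(n1, n2, bins = 32), 0.05)
})

test_that("landmark distances follow the pull-back convention", {
  lms <- landmarks(c("a", "b"), c(0, 10), c(0, -5), c(0, 2))
  d <- landmark_distance(lms, lms, identity_matrix())
  expect_equal(as.numeric(d), c(0, 0))

  moved <- landmarks(c("a", "b"), lms$x + 3, lms$y + 4, lms$z)
  d <- landmark_distance(lms, moved, identity_matrix())
  expect_equal(as.numeric(d), c(5, 5))  # 3-4-5 triangles

  # landmarks generated by the ground-truth map cancel exactly
  set.seed(13)
  m <- params_to_matrix(random_params(), center = c(5, 5, 5))
  p_m <- transform_points(m, cbind(lms$x, lms$y, lms$z))
  gen <- landmarks(lms$label, p_m[, 1], p_m[, 2], p_m[, 3])
  expect_lt(max(landmark_distance(lms, gen, m)), 1e-6)

  # matching is by label: order must not matter, extras are reported
  rev_gen <- gen[2:1, ]
  class(rev_gen) <- class(gen)
  d1 <- landmark_distance(lms, gen, m)
  d2 <- landmark_distance(lms, rev_gen, m)
  expect_equal(d1[sort(names(d1))], d2[sort(names(d2))])

  extra <- landmarks(c("a", "zzz"), c(0, 1), c(0, 1), c(0, 1))
  d3 <- landmark_distance(lms, extra, identity_matrix())
  expect_setequal(attr(d3, "unmatched"), c("b", "zzz"))
  only_b <- landmarks("q", 1, 1, 1)
  expect_error(landmark_distance(lms, only_b, identity_matrix()),
               "no shared")
})

test_that("paired comparison reproduces the textbook t statistic", {
  eq <- paired_compare(c(1, 2, 3), c(1, 2, 3))
  expect_true(eq$exactly_equal)
  expect_equal(eq$mean_diff, 0)

  # differences 1..5: mean 3, t = 3 / (sqrt(2.5)/sqrt(5)), df = 4
  a <- c(11, 12, 13, 14, 15)
  b <- c(10, 10, 10, 10, 10)
  r <- paired_compare(a, b)
  expect_equal(r$mean_diff, 3)
  expect_equal(r$t, 3 / (sqrt(2.5) / sqrt(5)), tolerance = 1e-3)
  expect_equal(r$df, 4)

  r4 <- paired_compare(a, b, bonferroni = 4)
  expect_equal(r4$p_adjusted, min(1, r4$p_value * 4))
  huge <- paired_compare(c(1, 2, 3, 2.5), c(1.1, 1.9, 3.2, 2.4),
                         bonferroni = 50)
  expect_lte(huge$p_adjusted, 1)

  expect_error(paired_compare(1:3, 1:4), "equal length")
})
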