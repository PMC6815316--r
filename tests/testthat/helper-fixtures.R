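# Shared fixtures: tiny hand-made grids, a small fast phantom, random
# well-conditioned affines, and brute-force metric oracles that stay
# independent of the package's own implementations.

# small, fast phantom used where geometric detail doesn't matter
small_spec <- function(seed = 1L, ...) {
  phantom_spec(dim = c(48L, 48L, 40L), spacing = c(2, 2, 2),
               n_nodules = 2L, nodule_radius = c(2, 5), seed = seed, ...)
}

# cheap optimizer settings for unit tests on the small phantom
cheap_config <- function(mode = "binary_mask", max_iters = c(60L, 40L, 15L),
                         ...) {
  registration_config(mode = mode, max_iters = max_iters,
                      working_spacing = 2, crop_margin = 14, ...)
}

# random binary mask volume on a unit grid
random_mask <- function(dim, p = 0.4, spacing = c(1, 1, 1)) {
  binary_mask(array(as.numeric(stats::runif(prod(dim)) < p), dim),
              spacing = spacing, allow_empty = TRUE)
}

random_volume <- function(dim, spacing = c(1, 1, 1)) {
  volume(array(stats::rnorm(prod(dim)), dim), spacing = spacing)
}

# a random well-conditioned affine parameter set
random_params <- function() {
  affine_params(translation = stats::runif(3, -10, 10),
                rotation = stats::runif(3, -0.3, 0.3),
                scale = stats::runif(3, 0.8, 1.2),
                shear = stats::runif(3, -0.15, 0.15))
}

# --- independent oracles -----------------------------------------------------

# Jaccard by literal voxel-set counting
oracle_jaccard <- function(a, b) {
  sa <- which(a$data == 1)
  sb <- which(b$data == 1)
  length(intersect(sa, sb)) / length(union(sa, sb))
}

# mutual information by an explicit double loop over the joint histogram
oracle_mi <- function(a, b, bins) {
  cut_idx <- function(x) {
    r <- range(x)
    if (diff(r) == 0) return(rep(1L, length(x)))
    pmin(floor((x - r[1]) / diff(r) * bins) + 1L, bins)
  }
  ia <- cut_idx(as.numeric(a$data))
  ib <- cut_idx(as.numeric(b$data))
  n <- length(ia)
  joint <- matrix(0, bins, bins)
  for (v in seq_len(n)) joint[ia[v], ib[v]] <- joint[ia[v], ib[v]] + 1
  joint <- joint / n
  pi_ <- rowSums(joint)
  pj_ <- colSums(joint)
  mi <- 0
  for (i in seq_len(bins)) {
    for (j in seq_len(bins)) {
      if (joint[i, j] > 0)
        mi <- mi + joint[i, j] * log(joint[i, j] / (pi_[i] * pj_[j]))
    }
  }
  mi
}

# histogram (marginal) entropy of one image, nats
oracle_entropy <- function(a, bins) {
  r <- range(a$data)
  x <- as.numeric(a$data)
  idx <- if (diff(r) == 0) rep(1L, length(x))
         else pmin(floor((x - r[1]) / diff(r) * bins) + 1L, bins)
  p <- tabulate(idx, bins) / length(x)
  p <- p[p > 0]
  -sum(p * log(p))
}
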