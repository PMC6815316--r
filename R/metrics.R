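#' Jaccard overlap of two masks
#'
#' Intersection over union of the foreground voxels; 1 means perfect liver
#' overlap, 0 means disjoint masks. Symmetric.
#'
#' @param a,b [binary_mask()] objects on the same grid.
#' @return scalar in `[0, 1]`.
#' @export
jaccard <- function(a, b) {
  stopifnot(is_mask(a), is_mask(b))
  assert_same_grid(a, b, "masks")
  inter <- sum(a$data * b$data)
  uni <- sum(pmax(a$data, b$data))
  if (uni == 0)
    stop("undefined-metric error: both masks are empty", call. = FALSE)
  inter / uni
}

bin_index <- function(x, bins) {
  rng <- range(x)
  if (diff(rng) == 0) return(rep.int(1L, length(x)))
  pmin(floor((x - rng[1]) / diff(rng) * bins) + 1L, bins)
}

#' Mutual information between two images
#'
#' Shannon mutual information of the joint intensity histogram, with
#' `bins` equal-width bins per image spanning each image's own range,
#' computed over all voxels of the common grid. A larger value indicates
#' better correspondence; because it depends on each pair's intensity
#' distribution, it is meaningful for paired comparisons only. A constant
#' image has zero marginal entropy and yields 0 (not an error).
#'
#' @param a,b volumes on the same grid.
#' @param bins histogram bins per image (>= 2).
#' @param unit `"nats"` (natural log) or `"bits"`.
#' @return scalar >= 0.
#' @export
mutual_information <- function(a, b, bins = 64L, unit = c("nats", "bits")) {
  stopifnot(inherits(a, "hep_volume"), inherits(b, "hep_volume"))
  unit <- match.arg(unit)
  assert_same_grid(a, b, "images")
  bins <- as.integer(bins)
  if (bins < 2L)
    stop("configuration error: bins must be >= 2", call. = FALSE)
  ia <- bin_index(as.numeric(a$data), bins)
  ib <- bin_index(as.numeric(b$data), bins)
  joint <- tabulate(ia + (ib - 1L) * bins, bins * bins)
  pij <- joint / sum(joint)
  pi_ <- rowSums(matrix(pij, bins, bins))
  pj_ <- colSums(matrix(pij, bins, bins))
  nz <- which(pij > 0)
  i_idx <- ((nz - 1L) %% bins) + 1L
  j_idx <- ((nz - 1L) %/% bins) + 1L
  mi <- sum(pij[nz] * log(pij[nz] / (pi_[i_idx] * pj_[j_idx])))
  mi <- max(mi, 0)
  if (unit == "bits") mi / log(2) else mi
}

#' Intra-observation distances between matched landmarks
#'
#' For each label shared between the static and moving sets, the Euclidean
#' distance (mm) between the static landmark and the moving landmark
#' mapped back into static space. With the pull-back convention
#' (`direction = "static_to_moving"`), a feature at `p_m` in the moving
#' series appears at `M^-1 p_m` after registration, so the reported value
#' is `|| p_static - M^-1 p_moving ||`. 0 mm means perfect observation
#' co-localization.
#'
#' @param static_lms,moving_lms [landmarks()] sets; matching is by label,
#'   never by proximity.
#' @param m an `affine_matrix` with direction `static_to_moving`.
#' @return Named numeric vector of distances (mm), one per shared label;
#'   unmatched labels are reported in the `"unmatched"` attribute, not
#'   scored.
#' @export
landmark_distance <- function(static_lms, moving_lms, m) {
  stopifnot(inherits(static_lms, "hep_landmarks"),
            inherits(moving_lms, "hep_landmarks"),
            inherits(m, "affine_matrix"))
  if (m$direction != "static_to_moving")
    stop("input error: matrix direction must be static_to_moving",
         call. = FALSE)
  shared <- intersect(static_lms$label, moving_lms$label)
  if (length(shared) == 0)
    stop("undefined-metric error: no shared landmark labels", call. = FALSE)
  ps <- landmark_matrix(static_lms[match(shared, static_lms$label), ])
  pm <- landmark_matrix(moving_lms[match(shared, moving_lms$label), ])
  back <- transform_points(invert(m), pm)
  d <- sqrt(rowSums((ps - back)^2))
  names(d) <- shared
  attr(d, "unmatched") <- setdiff(union(static_lms$label, moving_lms$label),
                                  shared)
  d
}

#' Paired comparison of a metric across two registration arms
#'
#' Two-sided paired t-test on the per-pair differences `a - b`, with an
#' analytic 95% confidence interval of the mean difference and an optional
#' Bonferroni multiplier (adjusted p capped at 1). Zero-variance
#' differences are flagged as exactly equal instead of producing NaN.
#'
#' @param values_a,values_b numeric cohort vectors, paired by index,
#'   length >= 2.
#' @param bonferroni multiplier (number of comparisons in the family).
#' @return list with `mean_diff`, `ci` (length 2), `t`, `df`, `p_value`,
#'   `p_adjusted`, `exactly_equal`.
#' @export
paired_compare <- function(values_a, values_b, bonferroni = 1) {
  if (length(values_a) != length(values_b))
    stop("input error: paired vectors must have equal length", call. = FALSE)
  if (length(values_a) < 2)
    stop("input error: need at least 2 pairs", call. = FALSE)
  d <- values_a - values_b
  if (stats::sd(d) == 0) {
    return(list(mean_diff = mean(d), ci = c(mean(d), mean(d)),
                t = NA_real_, df = length(d) - 1L, p_value = NA_real_,
                p_adjusted = NA_real_, exactly_equal = TRUE))
  }
  tt <- stats::t.test(values_a, values_b, paired = TRUE)
  p_adj <- min(1, unname(tt$p.value) * bonferroni)
  list(mean_diff = unname(tt$estimate), ci = as.numeric(tt$conf.int),
       t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = unname(tt$p.value), p_adjusted = p_adj,
       exactly_equal = FALSE)
}

#' All three registration metrics for one pair
#'
#' Convenience wrapper computing the liver overlap score (Jaccard), the
#' image correlation (mutual information of the two intensity masks,
#' nats), and the per-landmark intra-observation distances for one
#' static/moving pair under an estimated transform.
#'
#' @param static_mask,moving_mask native-grid liver masks.
#' @param static_int,moving_int intensity-mask volumes (optional; MI is
#'   `NA` when absent).
#' @param static_lms,moving_lms landmark sets (optional; distances `NA`
#'   when absent).
#' @param m estimated `affine_matrix` (static_to_moving).
#' @param mi_bins histogram bins for mutual information.
#' @return list with `jaccard`, `mutual_information`,
#'   `landmark_distances`, `mean_landmark_distance`.
#' @export
pair_metrics <- function(static_mask, moving_mask, m,
                         static_int = NULL, moving_int = NULL,
                         static_lms = NULL, moving_lms = NULL,
                         mi_bins = 64L) {
  warped_mask <- resample(moving_mask, m, static_mask, "nearest")
  j <- jaccard(static_mask, warped_mask)
  mi <- NA_real_
  if (!is.null(static_int) && !is.null(moving_int)) {
    warped_int <- resample(moving_int, m, static_int, "linear")
    mi <- mutual_information(static_int, warped_int, bins = mi_bins)
  }
  ld <- NULL
  mld <- NA_real_
  if (!is.null(static_lms) && !is.null(moving_lms)) {
    ld <- landmark_distance(static_lms, moving_lms, m)
    mld <- mean(ld)
  }
  list(jaccard = j, mutual_information = mi, landmark_distances = ld,
       mean_landmark_distance = mld)
}
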