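#' Parameters for a synthetic tumor phantom
#'
#' Describes one phantom: a square image with an elliptical tumor ROI whose
#' in-ROI intensities follow a two-component Gaussian mixture per sequence.
#' `clustering` controls where the high-intensity pixels sit: 0 scatters
#' them uniformly over the ROI, 1 concentrates all of them in `blob_count`
#' compact blobs. Pixel spacing is 1 mm isotropic.
#'
#' @param image_size Pixels per side of the square image.
#' @param roi_axes Ellipse semi-axes in pixels, (row, col).
#' @param mixture_means List with `t1` and `t2`, each `c(low, high)`
#'   intensity means on an arbitrary scanner scale.
#' @param mixture_sds List with `t1` and `t2`, each `c(low, high)`
#'   standard deviations.
#' @param high_fraction Proportion of ROI pixels in the high component,
#'   scalar or `c(t1 =, t2 =)`.
#' @param clustering Scalar in \[0, 1\], spatial concentration of the high
#'   component.
#' @param blob_count Number of compact high-intensity blobs.
#' @param seed Integer RNG seed.
#' @return Object of class `phantom_params`.
#' @export
phantom_params <- function(image_size = 96,
                           roi_axes = c(34, 26),
                           mixture_means = list(t1 = c(200, 500),
                                                t2 = c(300, 650)),
                           mixture_sds = list(t1 = c(35, 35),
                                              t2 = c(40, 40)),
                           high_fraction = 0.4,
                           clustering = 0,
                           blob_count = 3,
                           seed = 1L) {
  if (length(high_fraction) == 1) {
    high_fraction <- c(t1 = unname(high_fraction), t2 = unname(high_fraction))
  }
  hg_assert(image_size >= 16, "image_size too small")
  hg_assert(length(roi_axes) == 2 && all(roi_axes >= 4),
            "roi_axes must be two semi-axes >= 4 pixels")
  hg_assert(all(roi_axes < image_size / 2),
            "ROI ellipse must fit inside the image bounds")
  for (s in c("t1", "t2")) {
    hg_assert(mixture_means[[s]][1] < mixture_means[[s]][2],
              sprintf("[%s] mixture means must satisfy low < high", s))
    hg_assert(all(mixture_sds[[s]] > 0),
              sprintf("[%s] mixture sds must be positive", s))
  }
  hg_assert(all(high_fraction > 0 & high_fraction < 1),
            "high_fraction must lie in (0, 1)")
  hg_assert(clustering >= 0 && clustering <= 1,
            "clustering must lie in [0, 1]")
  hg_assert(blob_count >= 1, "blob_count must be >= 1")
  structure(list(image_size = as.integer(image_size),
                 roi_axes = as.numeric(roi_axes),
                 mixture_means = mixture_means,
                 mixture_sds = mixture_sds,
                 high_fraction = high_fraction,
                 clustering = clustering,
                 blob_count = as.integer(blob_count),
                 seed = as.integer(seed)),
            class = "phantom_params")
}

# Rejection-sample blob centers inside the ROI with pairwise separation of
# at least one blob radius; falls back to the best attempt if the ROI is
# too tight to separate them.
sample_blob_centers <- function(roi_idx, coords, n_blobs, radius) {
  best <- NULL
  best_sep <- -Inf
  for (attempt in 1:200) {
    pick <- coords[sample(length(roi_idx), n_blobs), , drop = FALSE]
    sep <- if (n_blobs == 1) Inf else min(stats::dist(pick))
    if (sep >= radius) return(pick)
    if (sep > best_sep) { best_sep <- sep; best <- pick }
  }
  best
}

# Choose which ROI pixels carry the high component for one sequence.
# A fraction `clustering` of them are the pixels nearest to the blob
# centers; the rest are drawn uniformly from the remaining ROI pixels.
place_high_component <- function(coords, n_high, clustering, blob_count) {
  n_roi <- nrow(coords)
  high <- logical(n_roi)
  n_clustered <- round(clustering * n_high)
  if (n_clustered > 0) {
    radius <- sqrt(n_high / (pi * blob_count))
    centers <- sample_blob_centers(seq_len(n_roi), coords, blob_count, radius)
    d2 <- vapply(seq_len(blob_count), function(b) {
      (coords[, 1] - centers[b, 1])^2 + (coords[, 2] - centers[b, 2])^2
    }, numeric(n_roi))
    nearest <- if (blob_count == 1) d2[, 1] else apply(d2, 1, min)
    high[order(nearest)[seq_len(n_clustered)]] <- TRUE
  }
  n_uniform <- n_high - n_clustered
  if (n_uniform > 0) {
    free <- which(!high)
    high[free[sample(length(free), n_uniform)]] <- TRUE
  }
  high
}

#' Generate one synthetic tumor phantom
#'
#' Draws the paired T1/FLAIR slices described by `params`: an elliptical
#' ROI mask shared by both sequences, in-ROI intensities from the
#' two-component mixture with the high component placed according to
#' `clustering`, and Gaussian background noise (mean 10% of the low
#' component's mean) outside the ROI. Deterministic given the seed.
#'
#' @param params A [phantom_params()] object.
#' @return A [slice_pair()] carrying two extra fields, `truth_t1` and
#'   `truth_t2`: the ground-truth binary masks of the pixels drawn from
#'   the high mixture component per sequence.
#' @export
generate_phantom <- function(params) {
  hg_assert(inherits(params, "phantom_params"),
            "params must be phantom_params")
  withr::with_seed(params$seed, {
    n <- params$image_size
    ctr <- (n - 1) / 2
    rows <- matrix(0:(n - 1), n, n)
    cols <- t(rows)
    roi <- ((rows - ctr) / params$roi_axes[1])^2 +
      ((cols - ctr) / params$roi_axes[2])^2 <= 1
    roi_idx <- which(roi)
    coords <- cbind(rows[roi_idx], cols[roi_idx])

    images <- list()
    truths <- list()
    for (s in c("t1", "t2")) {
      mu <- params$mixture_means[[s]]
      sd <- params$mixture_sds[[s]]
      n_high <- round(params$high_fraction[[s]] * length(roi_idx))
      high <- place_high_component(coords, n_high, params$clustering,
                                   params$blob_count)
      vals <- rnorm(length(roi_idx), mu[1], sd[1])
      vals[high] <- rnorm(sum(high), mu[2], sd[2])
      img <- matrix(pmax(rnorm(n * n, 0.1 * mu[1], 0.02 * mu[1]), 0), n, n)
      img[roi_idx] <- vals
      truth <- matrix(FALSE, n, n)
      truth[roi_idx[high]] <- TRUE
      images[[s]] <- img
      truths[[s]] <- truth
    }
    sp <- slice_pair(images$t1, images$t2, roi, roi,
                     spacing_mm = c(1, 1),
                     subject_id = sprintf("phantom_seed%d", params$seed))
    sp$truth_t1 <- truths$t1
    sp$truth_t2 <- truths$t2
    sp
  })
}

#' Specification of a synthetic two-class cohort
#'
#' Class 0 phantoms use `base_params` unchanged; class 1 phantoms use
#' `base_params` with `clustering` (and optionally `high_fraction`)
#' shifted by `class_effect`. `class_effect = 0` yields exchangeable
#' classes.
#'
#' @param n_per_class Subjects per outcome class (>= 2).
#' @param class_effect List with `clustering` and optional `high_fraction`
#'   shifts applied to class 1.
#' @param base_params A [phantom_params()] template.
#' @param seed Integer seed for per-subject seed derivation.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_class = 30,
                        class_effect = list(clustering = 0.8),
                        base_params = phantom_params(),
                        seed = 1L) {
  hg_assert(n_per_class >= 2, "n_per_class must be >= 2")
  hg_assert(inherits(base_params, "phantom_params"),
            "base_params must be phantom_params")
  eff <- list(clustering = 0, high_fraction = 0)
  eff[names(class_effect)] <- class_effect
  hg_assert(base_params$clustering + eff$clustering >= 0 &&
              base_params$clustering + eff$clustering <= 1,
            "shifted clustering must stay in [0, 1]")
  structure(list(n_per_class = as.integer(n_per_class),
                 class_effect = eff,
                 base_params = base_params,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic cohort with a planted class effect
#'
#' @param spec A [cohort_spec()].
#' @return List of `2 * n_per_class` elements, each
#'   `list(slices = slice_pair, label = 0 or 1)`; class 0 first.
#' @export
generate_cohort <- function(spec) {
  hg_assert(inherits(spec, "cohort_spec"), "spec must be a cohort_spec")
  n <- spec$n_per_class
  seeds <- withr::with_seed(spec$seed,
                            sample.int(.Machine$integer.max - 1L, 2 * n))
  lapply(seq_len(2 * n), function(k) {
    label <- as.integer(k > n)
    p <- spec$base_params
    if (label == 1) {
      p$clustering <- min(1, max(0, p$clustering + spec$class_effect$clustering))
      p$high_fraction <- stats::setNames(
        pmin(0.95, pmax(0.05, p$high_fraction + spec$class_effect$high_fraction)),
        names(p$high_fraction))
    }
    p$seed <- seeds[k]
    subj <- generate_phantom(p)
    subj$subject_id <- sprintf("s%03d", k)
    list(slices = subj, label = label)
  })
}
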