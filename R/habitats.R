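#' Habitat labels
#'
#' The four radiologically defined habitats, in their stable order:
#' T1 high, T1 low, T2 high, T2 low. Integer encoding is the position in
#' this vector minus one (0--3).
#'
#' @return Character vector of the four habitat labels.
#' @export
habitat_labels <- function() c("t1high", "t1low", "t2high", "t2low")

#' Construct a paired-slice object
#'
#' Bundles one subject's 2D post-contrast T1 and T2-FLAIR slices with their
#' per-sequence binary tumor ROI masks and pixel spacing.
#'
#' @param t1c 2D numeric matrix, T1 post-contrast intensities
#'   (arbitrary scanner units).
#' @param flair 2D numeric matrix, T2-FLAIR intensities.
#' @param roi_t1 Binary/logical matrix of the same shape as `t1c`.
#' @param roi_flair Binary/logical matrix of the same shape as `flair`.
#' @param spacing_mm Numeric length-2, (row, col) pixel size in mm.
#' @param subject_id Opaque identifier string.
#' @return An object of class `slice_pair`.
#' @export
slice_pair <- function(t1c, flair, roi_t1, roi_flair,
                       spacing_mm = c(1, 1), subject_id = "subject") {
  hg_assert(is.matrix(t1c) && is.matrix(flair), "t1c and flair must be 2D matrices")
  hg_assert(all(dim(t1c) == dim(roi_t1)), "t1c and roi_t1 shapes differ")
  hg_assert(all(dim(flair) == dim(roi_flair)), "flair and roi_flair shapes differ")
  roi_t1 <- roi_t1 > 0
  roi_flair <- roi_flair > 0
  hg_assert(any(roi_t1), "T1 ROI mask is empty", "habitatgraph_empty_mask")
  hg_assert(any(roi_flair), "FLAIR ROI mask is empty", "habitatgraph_empty_mask")
  hg_assert(length(spacing_mm) == 2 && all(spacing_mm > 0),
            "spacing_mm must be two positive values")
  structure(list(t1c = t1c, flair = flair,
                 roi_t1 = roi_t1, roi_flair = roi_flair,
                 spacing_mm = as.numeric(spacing_mm),
                 subject_id = as.character(subject_id)),
            class = "slice_pair")
}

#' Linearly scale intensities to the unit interval
#'
#' Maps a vector of ROI intensities onto \[0, 1\] by
#' `(v - min) / (max - min)`, the normalization applied within each tumor
#' ROI before mixture fitting.
#'
#' @param values Numeric vector of at least 2 ROI intensities.
#' @return Numeric vector in \[0, 1\] with min 0 and max 1.
#' @export
scale_intensities <- function(values) {
  hg_assert(is.numeric(values) && length(values) >= 2,
            "need at least 2 intensity values")
  hg_assert(all(is.finite(values)), "intensities must be finite")
  rng <- range(values)
  if (rng[2] == rng[1]) {
    hg_error("constant ROI intensities: habitat split undefined",
             "habitatgraph_degenerate_roi")
  }
  (values - rng[1]) / (rng[2] - rng[1])
}

#' Fit a two-component Gaussian mixture and its habitat threshold
#'
#' Fits a univariate two-component GMM by EM to scaled ROI intensities and
#' returns the habitat threshold, defined as the average of the two fitted
#' component means.
#'
#' @param scaled Numeric vector in \[0, 1\] (output of
#'   [scale_intensities()]), length at least `min_points`.
#' @param seed Integer seed (fitting is deterministic; the seed guards any
#'   backend randomness).
#' @param min_points Minimum sample size accepted for a stable fit.
#' @param equal_variance If `TRUE`, constrain the two components to a
#'   common variance.
#' @param collapse_tol Minimum separation of fitted means (in scaled
#'   units) below which the ROI is declared unimodal; the default 0.02 is
#'   2% of the intensity range, well below any radiologically meaningful
#'   habitat separation.
#' @return List with `threshold`, `mean_low`, `mean_high`.
#' @export
fit_gmm_threshold <- function(scaled, seed = 1L, min_points = 20,
                              equal_variance = FALSE, collapse_tol = 0.02) {
  hg_assert(length(scaled) >= min_points,
            sprintf("need at least %d values for the mixture fit", min_points),
            "habitatgraph_degenerate_roi")
  hg_assert(all(scaled >= 0 & scaled <= 1), "scaled values must lie in [0, 1]")
  model <- if (equal_variance) "E" else "V"
  fit <- withr::with_seed(as.integer(seed), suppressWarnings(
    mclust::Mclust(scaled, G = 2, modelNames = model, verbose = FALSE)
  ))
  if (is.null(fit)) {
    hg_error("two-component mixture fit failed (unimodal ROI?)",
             "habitatgraph_unimodal_roi")
  }
  mu <- sort(as.numeric(fit$parameters$mean))
  if (diff(mu) < collapse_tol) {
    hg_error("mixture components collapsed: ROI is effectively unimodal",
             "habitatgraph_unimodal_roi")
  }
  list(threshold = mean(mu), mean_low = mu[1], mean_high = mu[2])
}

#' Split each sequence's ROI into low/high intensity habitats
#'
#' Per sequence, scales the in-ROI intensities to \[0, 1\], fits the
#' two-component GMM threshold, and assigns scaled values strictly above
#' the threshold to the HIGH habitat and values at or below it to LOW.
#' The four resulting binary masks partition each sequence's ROI.
#'
#' @param slices A [slice_pair()].
#' @param seed Integer seed passed to [fit_gmm_threshold()].
#' @param ... Further arguments to [fit_gmm_threshold()].
#' @return An object of class `habitat_masks`: binary masks named
#'   `t1high`, `t1low`, `t2high`, `t2low`, plus fitted `thresholds` and
#'   component `means` per sequence, the pixel `spacing_mm` and
#'   `subject_id`.
#' @export
make_habitat_masks <- function(slices, seed = 1L, ...) {
  hg_assert(inherits(slices, "slice_pair"), "slices must be a slice_pair")
  split_one <- function(image, roi, sequence) {
    vals <- image[roi]
    res <- tryCatch({
      scaled <- scale_intensities(vals)
      fit <- fit_gmm_threshold(scaled, seed = seed, ...)
      list(scaled = scaled, fit = fit)
    }, habitatgraph_error = function(e) {
      hg_error(sprintf("[%s] %s", sequence, conditionMessage(e)),
               class(e)[1])
    })
    high <- matrix(FALSE, nrow(image), ncol(image))
    low <- high
    high[roi] <- res$scaled > res$fit$threshold
    low[roi] <- res$scaled <= res$fit$threshold
    list(high = high, low = low, fit = res$fit)
  }
  t1 <- split_one(slices$t1c, slices$roi_t1, "t1")
  t2 <- split_one(slices$flair, slices$roi_flair, "t2")
  structure(list(
    masks = list(t1high = t1$high, t1low = t1$low,
                 t2high = t2$high, t2low = t2$low),
    thresholds = c(t1 = t1$fit$threshold, t2 = t2$fit$threshold),
    means = list(t1 = c(low = t1$fit$mean_low, high = t1$fit$mean_high),
                 t2 = c(low = t2$fit$mean_low, high = t2$fit$mean_high)),
    spacing_mm = slices$spacing_mm,
    subject_id = slices$subject_id
  ), class = "habitat_masks")
}
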