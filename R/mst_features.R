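#' Names of the seven branch-length statistics
#' @return Character vector in the fixed feature order.
#' @export
mst_stat_names <- function() {
  c("mean", "median", "sd", "skewness", "kurtosis", "ratio", "disorder")
}

#' Branch-length statistics of a spanning tree
#'
#' Computes the seven descriptors of the MST edge-weight distribution W:
#' mean, median (average of the middle two for even counts), population
#' standard deviation (1/n), skewness and kurtosis (population moments,
#' non-excess: a normal sample has kurtosis near 3), the max(W)/min(W)
#' ratio, and disorder = sd/mean. When the weights are constant (sd = 0),
#' skewness and kurtosis are defined as 0.
#'
#' @param tree A `spanning_tree` from [build_mst()], or a numeric vector
#'   of branch lengths.
#' @return Named numeric vector of the 7 statistics.
#' @export
mst_feature_vector <- function(tree) {
  w <- if (inherits(tree, "spanning_tree")) tree$edges$weight else as.numeric(tree)
  if (length(w) < 1) {
    hg_error("spanning tree has no edges", "habitatgraph_insufficient_edges")
  }
  if (min(w) == 0) {
    hg_error("zero-length branch (coincident centroids): max/min ratio undefined",
             "habitatgraph_zero_branch")
  }
  n <- length(w)
  mu <- mean(w)
  sigma <- sqrt(sum((w - mu)^2) / n)
  if (sigma > 0) {
    skew <- sum((w - mu)^3) / (n * sigma^3)
    kurt <- sum((w - mu)^4) / (n * sigma^4)
  } else {
    skew <- 0
    kurt <- 0
  }
  c(mean = mu, median = stats::median(w), sd = sigma,
    skewness = skew, kurtosis = kurt,
    ratio = max(w) / min(w), disorder = sigma / mu)
}

#' All 28 MST features for one subject
#'
#' For each of the four habitats: grid centroids, Euclidean MST, seven
#' branch-length statistics. A habitat with fewer than 2 centroids yields
#' 7 missing values; the other habitats are unaffected.
#'
#' @param masks A `habitat_masks` object.
#' @param grid_spacing Grid cell edge in pixels (default 8).
#' @return Named numeric vector of length 28, names `{habitat}_{stat}` in
#'   habitat-major order.
#' @export
subject_mst_features <- function(masks, grid_spacing = 8) {
  hg_assert(inherits(masks, "habitat_masks"), "masks must be habitat_masks")
  out <- unlist(lapply(habitat_labels(), function(h) {
    pts <- grid_centroids(masks$masks[[h]], masks$spacing_mm, grid_spacing, h)
    stats7 <- if (nrow(pts) < 2) {
      stats::setNames(rep(NA_real_, 7), mst_stat_names())
    } else {
      mst_feature_vector(build_mst(pts, habitat = h))
    }
    stats::setNames(stats7, paste0(h, "_", mst_stat_names()))
  }))
  out
}
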