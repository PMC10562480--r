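#' Graph run-length matrix of a habitat-typed triangulated graph
#'
#' Counts, for every node and every edge type incident to it, one run
#' whose length is the largest number of consecutive same-type edges along
#' any simple path starting at that node. The run always includes at least
#' the incident edge; any node visited beyond the first step must lie
#' strictly within a circular window of radius `window_radius_mm` centered
#' at the initial node. Path lengths are counted in edges and capped at
#' `L_max`. The matrices of all nodes are accumulated into `G[t, l]`.
#'
#' @param graph A `triangulated_graph` from [build_delaunay()].
#' @param window_radius_mm Circular window radius in mm; `Inf` (default)
#'   means the whole map.
#' @param L_max Path-length cap (default 10).
#' @return Object of class `grlm`: integer matrix `G` (10 edge types x
#'   `L_max` lengths), total run count `n_r`, per-type totals `n_r_t`, and
#'   the settings used.
#' @export
compute_grlm <- function(graph, window_radius_mm = Inf, L_max = 10) {
  hg_assert(inherits(graph, "triangulated_graph"),
            "graph must be a triangulated_graph")
  hg_assert(L_max >= 1, "L_max must be >= 1")
  hg_assert(window_radius_mm > 0, "window_radius_mm must be positive")
  n <- nrow(graph$vertices)
  xs <- graph$vertices$x_mm
  ys <- graph$vertices$y_mm
  # adjacency lists split by edge type
  adj <- lapply(1:10, function(t) vector("list", n))
  e <- graph$edges
  for (k in seq_len(nrow(e))) {
    t <- e$edge_type[k] + 1L
    i <- e$i[k]; j <- e$j[k]
    adj[[t]][[i]] <- c(adj[[t]][[i]], j)
    adj[[t]][[j]] <- c(adj[[t]][[j]], i)
  }
  G <- matrix(0L, nrow = 10, ncol = L_max,
              dimnames = list(paste0("t", 0:9), NULL))
  for (t in 1:10) {
    adjt <- adj[[t]]
    for (v in seq_len(n)) {
      if (length(adjt[[v]]) == 0) next
      within <- if (is.finite(window_radius_mm)) {
        (xs - xs[v])^2 + (ys - ys[v])^2 < window_radius_mm^2
      } else rep(TRUE, n)
      best <- 0L
      visited <- rep(FALSE, n)
      visited[v] <- TRUE
      rec <- function(u, depth) {
        if (depth > best) best <<- depth
        if (depth == L_max) return(invisible())
        for (w in adjt[[u]]) {
          # the first edge of a run is always taken; only nodes reached
          # beyond it must fall inside the window
          if (!visited[w] && (depth == 0L || within[w])) {
            visited[w] <<- TRUE
            rec(w, depth + 1L)
            visited[w] <<- FALSE
          }
        }
      }
      rec(v, 0L)
      G[t, best] <- G[t, best] + 1L
    }
  }
  structure(list(G = G, n_r = sum(G), n_r_t = rowSums(G),
                 window_radius_mm = window_radius_mm, L_max = L_max),
            class = "grlm")
}

#' Names of the 24 graph run-length features
#' @return Character vector: spe, lpe, etn, pln, spe_t0..spe_t9,
#'   lpe_t0..lpe_t9.
#' @export
grlm_feature_names <- function() {
  c("spe", "lpe", "etn", "pln",
    paste0("spe_t", 0:9), paste0("lpe_t", 0:9))
}

#' Texture features of a graph run-length matrix
#'
#' Global short-path emphasis `SPE = (1/n_r) sum G(t,l)/l^2`, long-path
#' emphasis `LPE = (1/n_r) sum G(t,l) l^2`, edge-type nonuniformity
#' `ETN = (1/n_r) sum_t (sum_l G(t,l))^2`, path-length nonuniformity
#' `PLN = (1/n_r) sum_l (sum_t G(t,l))^2`, plus per-type `SPE(t)` and
#' `LPE(t)` normalized by that type's run count `n_r(t)` with the sums
#' restricted to type t. Types with no runs get missing per-type values.
#'
#' @param M A `grlm` object from [compute_grlm()].
#' @return Named numeric vector of 24 features.
#' @export
grlm_features <- function(M) {
  hg_assert(inherits(M, "grlm"), "M must be a grlm")
  if (M$n_r == 0) {
    hg_error("empty run-length matrix", "habitatgraph_empty_matrix")
  }
  l <- seq_len(M$L_max)
  inv_l2 <- 1 / l^2
  l2 <- l^2
  spe <- sum(M$G %*% inv_l2) / M$n_r
  lpe <- sum(M$G %*% l2) / M$n_r
  etn <- sum(rowSums(M$G)^2) / M$n_r
  pln <- sum(colSums(M$G)^2) / M$n_r
  spe_t <- as.numeric(M$G %*% inv_l2) / M$n_r_t
  lpe_t <- as.numeric(M$G %*% l2) / M$n_r_t
  spe_t[M$n_r_t == 0] <- NA_real_
  lpe_t[M$n_r_t == 0] <- NA_real_
  stats::setNames(c(spe, lpe, etn, pln, spe_t, lpe_t), grlm_feature_names())
}

#' All 24 graph run-length features for one subject
#'
#' Combines the centroids of all four habitats into one labeled map,
#' triangulates it, computes the run-length matrix and its features.
#'
#' @param masks A `habitat_masks` object.
#' @param grid_spacing Grid cell edge in pixels (default 8).
#' @param window_radius_mm Circular window radius in mm (default `Inf`).
#' @param L_max Path-length cap (default 10).
#' @return Named numeric vector of 24 features (per-type entries are `NA`
#'   for edge types absent from the map).
#' @export
subject_grlm_features <- function(masks, grid_spacing = 8,
                                  window_radius_mm = Inf, L_max = 10) {
  pts <- subject_centroids(masks, grid_spacing)
  g <- build_delaunay(pts)
  grlm_features(compute_grlm(g, window_radius_mm, L_max))
}
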