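# Independent oracles and fixture builders shared across the test files.
# Every oracle deliberately takes a different route than the implementation
# it checks (Prufer enumeration vs Prim, igraph path enumeration vs the
# package's DFS, pairwise Mann-Whitney vs the trapezoid sweep).

# ---- spanning trees ---------------------------------------------------

# Decode a Prufer sequence into the edge list of the labeled tree.
prufer_decode <- function(pr, n) {
  deg <- rep(1L, n)
  for (v in pr) deg[v] <- deg[v] + 1L
  edges <- matrix(0L, n - 1L, 2L)
  for (k in seq_along(pr)) {
    leaf <- min(which(deg == 1L))
    edges[k, ] <- c(leaf, pr[k])
    deg[leaf] <- 0L
    deg[pr[k]] <- deg[pr[k]] - 1L
  }
  edges[n - 1L, ] <- which(deg == 1L)
  edges
}

tree_weight <- function(edges, d) sum(d[edges])

# Minimum spanning tree weight by exhaustive enumeration of all n^(n-2)
# labeled trees (Cayley / Prufer); tractable for n <= 7.
oracle_mst_weight <- function(pts) {
  n <- nrow(pts)
  d <- as.matrix(stats::dist(pts))
  if (n == 2) return(d[1, 2])
  seqs <- as.matrix(expand.grid(rep(list(seq_len(n)), n - 2L)))
  best <- Inf
  for (r in seq_len(nrow(seqs))) {
    w <- tree_weight(prufer_decode(as.integer(seqs[r, ]), n), d)
    if (w < best) best <- w
  }
  best
}

random_spanning_tree_weight <- function(pts) {
  n <- nrow(pts)
  d <- as.matrix(stats::dist(pts))
  pr <- sample.int(n, n - 2L, replace = TRUE)
  tree_weight(prufer_decode(pr, n), d)
}

# ---- graph run-length matrices ----------------------------------------

# Build a triangulated_graph object directly from coordinates, habitat
# labels and an explicit edge list (rows of i, j vertex indices).
manual_graph <- function(x, y, habitats, edges_ij) {
  pts <- data.frame(x_mm = x, y_mm = y, habitat = habitats,
                    stringsAsFactors = FALSE)
  i <- pmin(edges_ij[, 1], edges_ij[, 2])
  j <- pmax(edges_ij[, 1], edges_ij[, 2])
  structure(list(
    vertices = pts,
    edges = data.frame(i = i, j = j,
                       edge_type = edge_type(pts$habitat[i], pts$habitat[j]),
                       length_mm = sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2))),
    class = "triangulated_graph")
}

random_labeled_graph <- function(n, seed, p_edge = 0.35) {
  withr::with_seed(seed, {
    x <- runif(n, 0, 20)
    y <- runif(n, 0, 20)
    habitats <- sample(habitat_labels(), n, replace = TRUE)
    pairs <- which(upper.tri(diag(n)), arr.ind = TRUE)
    keep <- runif(nrow(pairs)) < p_edge
    if (!any(keep)) keep[sample(length(keep), 1)] <- TRUE
    manual_graph(x, y, habitats, pairs[keep, , drop = FALSE])
  })
}

# Exhaustive reference for compute_grlm: enumerate every simple path in
# each edge-type subgraph with igraph, truncate it at the first node
# beyond the initial edge that leaves the window, and keep the maximum.
oracle_grlm <- function(graph, window_radius_mm = Inf, L_max = 10) {
  n <- nrow(graph$vertices)
  xs <- graph$vertices$x_mm
  ys <- graph$vertices$y_mm
  G <- matrix(0L, 10, L_max, dimnames = list(paste0("t", 0:9), NULL))
  for (t in 0:9) {
    et <- graph$edges[graph$edges$edge_type == t, , drop = FALSE]
    if (nrow(et) == 0) next
    g <- igraph::add_edges(igraph::make_empty_graph(n, directed = FALSE),
                           rbind(et$i, et$j))
    touched <- unique(c(et$i, et$j))
    for (v in touched) {
      within <- if (is.finite(window_radius_mm)) {
        (xs - xs[v])^2 + (ys - ys[v])^2 < window_radius_mm^2
      } else rep(TRUE, n)
      paths <- igraph::all_simple_paths(g, from = v)
      best <- 1L
      for (p in paths) {
        vp <- as.integer(p)
        len <- 1L  # first edge of the run is always allowed
        k <- 3L
        while (k <= length(vp) && within[vp[k]]) {
          len <- k - 1L
          k <- k + 1L
        }
        best <- max(best, len)
      }
      best <- min(best, L_max)
      G[t + 1L, best] <- G[t + 1L, best] + 1L
    }
  }
  G
}

# ---- ROC --------------------------------------------------------------

# AUC as the Mann-Whitney pairwise statistic (ties count one half).
oracle_auc <- function(prob, labels) {
  p1 <- prob[labels == 1]
  p0 <- prob[labels == 0]
  cmp <- outer(p1, p0, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# ---- shared fixtures --------------------------------------------------

.hg_cache <- new.env(parent = emptyenv())

hg_cached <- function(key, expr) {
  if (!exists(key, envir = .hg_cache, inherits = FALSE)) {
    assign(key, force(expr), envir = .hg_cache)
  }
  get(key, envir = .hg_cache, inherits = FALSE)
}

# The study-condition cohorts used by the planted-effect checks: 30 + 30
# phantoms, clustering 0 vs 0.8 (and a null twin), with their features.
hg_effect_cohort <- function() hg_cached("effect_cohort", {
  co <- generate_cohort(cohort_spec(n_per_class = 30,
                                    class_effect = list(clustering = 0.8),
                                    base_params = phantom_params(),
                                    seed = 20260919L))
  c(cohort_features(co), list(cohort = co))
})

hg_null_cohort <- function() hg_cached("null_cohort", {
  co <- generate_cohort(cohort_spec(n_per_class = 30,
                                    class_effect = list(clustering = 0),
                                    base_params = phantom_params(),
                                    seed = 20260920L))
  c(cohort_features(co), list(cohort = co))
})

# A single default phantom with its habitat masks, reused by many files.
hg_phantom <- function() hg_cached("phantom", {
  p <- generate_phantom(phantom_params(seed = 7L))
  list(slices = p, masks = make_habitat_masks(p, seed = 1L))
})

# Manually assembled habitat_masks (for degenerate-geometry fixtures).
fake_masks <- function(t1high, t1low, t2high, t2low, spacing = c(1, 1)) {
  structure(list(masks = list(t1high = t1high, t1low = t1low,
                              t2high = t2high, t2low = t2low),
                 thresholds = c(t1 = 0.5, t2 = 0.5),
                 means = list(t1 = c(low = 0.25, high = 0.75),
                              t2 = c(low = 0.25, high = 0.75)),
                 spacing_mm = spacing, subject_id = "fixture"),
            class = "habitat_masks")
}
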