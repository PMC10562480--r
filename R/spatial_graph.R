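#' Grid-cell centroids of a habitat mask
#'
#' Overlays a square grid on the mask's bounding box (anchored at the
#' bounding-box top-left corner) and, for every grid cell containing at
#' least one mask pixel, emits the center of mass of those pixels in
#' physical (mm) coordinates. Pixel indices are 0-based; the physical
#' coordinate of a pixel is index times spacing, and centroids are not
#' snapped to the pixel lattice.
#'
#' @param mask Binary/logical 2D matrix.
#' @param spacing_mm Numeric length-2, (row, col) pixel size in mm.
#' @param grid_spacing Cell edge length in pixels (default 8, i.e.
#'   8 mm x 8 mm at 1 mm spacing).
#' @param label Habitat label attached to every centroid.
#' @return data.frame with columns `x_mm` (row direction), `y_mm`
#'   (column direction), `habitat`. Empty mask gives zero rows.
#' @export
grid_centroids <- function(mask, spacing_mm = c(1, 1), grid_spacing = 8,
                           label = "t1high") {
  hg_assert(grid_spacing >= 1, "grid_spacing must be >= 1")
  px <- which(mask > 0, arr.ind = TRUE)
  if (nrow(px) == 0) {
    return(data.frame(x_mm = numeric(0), y_mm = numeric(0),
                      habitat = character(0), stringsAsFactors = FALSE))
  }
  r <- px[, 1] - 1L
  c <- px[, 2] - 1L
  cell <- paste(floor((r - min(r)) / grid_spacing),
                floor((c - min(c)) / grid_spacing))
  xs <- tapply(r, cell, mean) * spacing_mm[1]
  ys <- tapply(c, cell, mean) * spacing_mm[2]
  keys <- sort(unique(cell))  # fixed order: row-major over occupied cells
  data.frame(x_mm = as.numeric(xs[keys]), y_mm = as.numeric(ys[keys]),
             habitat = label, stringsAsFactors = FALSE)
}

#' Centroid map for all four habitats of a subject
#'
#' @param masks A `habitat_masks` object from [make_habitat_masks()].
#' @param grid_spacing Cell edge length in pixels.
#' @return data.frame of labeled centroids (`x_mm`, `y_mm`, `habitat`)
#'   with attribute `grid_spacing`.
#' @export
subject_centroids <- function(masks, grid_spacing = 8) {
  hg_assert(inherits(masks, "habitat_masks"), "masks must be habitat_masks")
  pts <- do.call(rbind, lapply(habitat_labels(), function(h) {
    grid_centroids(masks$masks[[h]], masks$spacing_mm, grid_spacing, h)
  }))
  attr(pts, "grid_spacing") <- grid_spacing
  pts
}

#' Euclidean minimum spanning tree of a 2D point set
#'
#' Builds the MST of the complete graph on the points with Euclidean edge
#' weights (mm). Construction is deterministic for a fixed input, so the
#' branch-length multiset feeding the features is reproducible.
#'
#' @param points data.frame or matrix with columns `x_mm`, `y_mm` (or two
#'   unnamed columns), at least 2 rows.
#' @param habitat Optional habitat label stored on the tree.
#' @return Object of class `spanning_tree`: `vertices` (n x 2 matrix, mm)
#'   and `edges` (data.frame `i`, `j`, `weight`).
#' @export
build_mst <- function(points, habitat = NA_character_) {
  pts <- as.matrix(as.data.frame(points)[, 1:2])
  storage.mode(pts) <- "double"
  if (nrow(pts) < 2) {
    hg_error("need at least 2 points for a spanning tree",
             "habitatgraph_insufficient_points")
  }
  d <- as.matrix(stats::dist(pts))
  g <- igraph::graph_from_adjacency_matrix(d, mode = "undirected",
                                           weighted = TRUE)
  t <- igraph::mst(g, algorithm = "prim")
  el <- igraph::as_edgelist(t, names = FALSE)
  edges <- data.frame(i = pmin(el[, 1], el[, 2]),
                      j = pmax(el[, 1], el[, 2]),
                      weight = igraph::E(t)$weight)
  edges <- edges[order(edges$i, edges$j), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(vertices = pts, edges = edges, habitat = habitat),
            class = "spanning_tree")
}

#' Edge type index of a habitat label pair
#'
#' Maps the unordered pair of endpoint habitat labels to a stable index
#' 0--9: the four same-label types first in habitat order
#' (t1high, t1low, t2high, t2low), then the six mixed pairs in
#' lexicographic label order. Symmetric in its arguments; vectorized.
#'
#' @param a,b Habitat labels (names from [habitat_labels()]) or their
#'   0-based integer codes.
#' @return Integer vector of edge type indices in 0--9.
#' @export
edge_type <- function(a, b) {
  labs <- habitat_labels()
  to_code <- function(v) {
    if (is.numeric(v)) {
      hg_assert(all(v %in% 0:3), "integer habitat codes must be 0-3")
      as.integer(v)
    } else {
      m <- match(as.character(v), labs)
      hg_assert(!anyNA(m), "unknown habitat label")
      m - 1L
    }
  }
  a <- to_code(a); b <- to_code(b)
  lo <- pmin(a, b); hi <- pmax(a, b)
  ifelse(lo == hi, lo,
         # mixed pairs (lo,hi), lo<hi, ranked lexicographically after the 4
         # same-label types: (0,1)=4 (0,2)=5 (0,3)=6 (1,2)=7 (1,3)=8 (2,3)=9
         as.integer(4L + lo * 3L - (lo * (lo - 1L)) %/% 2L + (hi - lo - 1L)))
}

#' Number of distinct edge types
#' @return 10L
#' @export
n_edge_types <- function() 10L

#' Delaunay triangulation of a labeled centroid map
#'
#' Triangulates all habitat centroids jointly (labels are ignored for the
#' geometry and kept on the vertices) and types every triangulation edge
#' by its endpoint habitat pair. Coordinates duplicated across habitats
#' are perturbed deterministically by multiples of 1e-6 mm before
#' triangulation so that a fixed input always yields the same edge set;
#' edge lengths are computed on the original coordinates.
#'
#' @param points data.frame with columns `x_mm`, `y_mm`, `habitat`,
#'   at least 3 non-collinear rows.
#' @return Object of class `triangulated_graph`: `vertices` (the input
#'   points) and `edges` (data.frame `i`, `j`, `edge_type`, `length_mm`),
#'   plus the triangle list in attribute `triangles`.
#' @export
build_delaunay <- function(points) {
  pts <- as.data.frame(points)
  hg_assert(all(c("x_mm", "y_mm", "habitat") %in% names(pts)),
            "points needs x_mm, y_mm, habitat columns")
  if (nrow(pts) < 3) {
    hg_error("need at least 3 points for a triangulation",
             "habitatgraph_degenerate_geometry")
  }
  x <- pts$x_mm
  y <- pts$y_mm
  dup <- duplicated(paste(x, y))
  if (any(dup)) {
    k <- seq_len(sum(dup))
    x[dup] <- x[dup] + k * 1e-6
  }
  dd <- tryCatch(deldir::deldir(x, y, round = FALSE),
                 error = function(e) {
                   hg_error(paste0("degenerate geometry (collinear points?): ",
                                   conditionMessage(e)),
                            "habitatgraph_degenerate_geometry")
                 })
  if (nrow(dd$delsgs) == 0) {
    hg_error("triangulation produced no edges",
             "habitatgraph_degenerate_geometry")
  }
  i <- pmin(dd$delsgs$ind1, dd$delsgs$ind2)
  j <- pmax(dd$delsgs$ind1, dd$delsgs$ind2)
  keep <- !duplicated(paste(i, j))
  i <- i[keep]; j <- j[keep]
  o <- order(i, j)
  i <- i[o]; j <- j[o]
  len <- sqrt((pts$x_mm[i] - pts$x_mm[j])^2 + (pts$y_mm[i] - pts$y_mm[j])^2)
  edges <- data.frame(i = i, j = j,
                      edge_type = edge_type(pts$habitat[i], pts$habitat[j]),
                      length_mm = len)
  tri <- lapply(deldir::triang.list(dd), function(t) t$ptNum)
  structure(list(vertices = pts, edges = edges),
            class = "triangulated_graph", triangles = tri)
}
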