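test_that("grid centroids are cell-wise centers of mass in mm", {
  m <- matrix(FALSE, 12, 12)
  m[4, 5] <- TRUE  # 0-based (3, 4)
  pts <- grid_centroids(m, c(1, 1), 8, "t1high")
  expect_equal(nrow(pts), 1)
  expect_equal(c(pts$x_mm, pts$y_mm), c(3, 4))

  m <- matrix(FALSE, 12, 12)
  m[1, 1] <- TRUE; m[1, 3] <- TRUE  # 0-based (0,0) and (0,2), same cell
  pts <- grid_centroids(m, c(1, 1), 8, "t1low")
  expect_equal(nrow(pts), 1)
  expect_equal(c(pts$x_mm, pts$y_mm), c(0, 1))

  m <- matrix(FALSE, 12, 12)
  m[1, 1] <- TRUE; m[10, 1] <- TRUE  # rows 0 and 9 fall in different cells
  pts <- grid_centroids(m, c(1, 1), 8, "t2high")
  expect_equal(nrow(pts), 2)

  expect_equal(nrow(grid_centroids(matrix(FALSE, 5, 5))), 0)
})

test_that("grid centroids translate with the mask by grid-multiple offsets", {
  for (seed in 1:10) {
    m <- matrix(FALSE, 60, 60)
    px <- withr::with_seed(seed, cbind(sample(5:20, 30, TRUE),
                                       sample(5:20, 30, TRUE)))
    m[px] <- TRUE
    m2 <- matrix(FALSE, 60, 60)
    m2[px + matrix(rep(c(16, 24), each = 30), ncol = 2)] <- TRUE
    a <- grid_centroids(m, c(1, 1), 8, "t1high")
    b <- grid_centroids(m2, c(1, 1), 8, "t1high")
    expect_equal(b$x_mm, a$x_mm + 16)
    expect_equal(b$y_mm, a$y_mm + 24)
  }
})

test_that("the minimum spanning tree is minimal and well-formed", {
  t2 <- build_mst(data.frame(x_mm = c(0, 5), y_mm = c(0, 0)))
  expect_equal(nrow(t2$edges), 1)
  expect_equal(t2$edges$weight, 5)

  eq <- build_mst(data.frame(x_mm = c(0, 1, 0.5), y_mm = c(0, 0, sqrt(3) / 2)))
  expect_equal(sum(eq$edges$weight), 2)

  expect_error(build_mst(data.frame(x_mm = 1, y_mm = 1)),
               class = "habitatgraph_insufficient_points")

  for (seed in 1:25) {
    n <- withr::with_seed(seed, sample(3:7, 1))
    pts <- withr::with_seed(seed + 100, matrix(runif(2 * n, 0, 10), ncol = 2))
    tr <- build_mst(pts)
    expect_equal(nrow(tr$edges), n - 1)
    expect_equal(sum(tr$edges$weight), oracle_mst_weight(pts), tolerance = 1e-12)
  }
})

test_that("no random spanning tree beats the MST", {
  pts <- withr::with_seed(17, matrix(runif(24, 0, 10), ncol = 2))
  w_mst <- sum(build_mst(pts)$edges$weight)
  withr::with_seed(18, {
    for (r in 1:1000) {
      expect_lte(w_mst, random_spanning_tree_weight(pts) + 1e-12)
    }
  })
})

test_that("edge types enumerate the 10 unordered habitat pairs stably", {
  expect_identical(edge_type("t1high", "t1high"), 0L)
  expect_identical(edge_type("t1low", "t1low"), 1L)
  expect_identical(edge_type("t2low", "t2low"), 3L)
  labs <- habitat_labels()
  all_types <- outer(labs, labs, edge_type)
  expect_identical(all_types, t(all_types))  # symmetric
  expect_setequal(as.vector(all_types), 0:9)
  expect_identical(edge_type("t1high", "t2low"), edge_type("t2low", "t1high"))
  expect_identical(edge_type(0, 1), 4L)
  expect_identical(edge_type(2, 3), 9L)
  expect_equal(n_edge_types(), 10L)
})

circumcircle_empty <- function(pts, tri, tol = 1e-9) {
  p <- as.matrix(pts[, c("x_mm", "y_mm")])
  a <- p[tri[1], ]; b <- p[tri[2], ]; c <- p[tri[3], ]
  d <- 2 * (a[1] * (b[2] - c[2]) + b[1] * (c[2] - a[2]) + c[1] * (a[2] - b[2]))
  ux <- ((sum(a^2)) * (b[2] - c[2]) + (sum(b^2)) * (c[2] - a[2]) +
           (sum(c^2)) * (a[2] - b[2])) / d
  uy <- ((sum(a^2)) * (c[1] - b[1]) + (sum(b^2)) * (a[1] - c[1]) +
           (sum(c^2)) * (b[1] - a[1])) / d
  r2 <- sum((a - c(ux, uy))^2)
  others <- setdiff(seq_len(nrow(p)), tri)
  all((p[others, 1] - ux)^2 + (p[others, 2] - uy)^2 >= r2 * (1 - tol))
}

test_that("the Delaunay triangulation is correct and degenerate-safe", {
  tri <- build_delaunay(data.frame(x_mm = c(0, 1, 0), y_mm = c(0, 0, 1),
                                   habitat = c("t1high", "t1low", "t2high")))
  expect_equal(nrow(tri$edges), 3)

  quad <- data.frame(x_mm = c(0, 3, 2, 0), y_mm = c(0, 0, 2, 1),
                     habitat = c("t1high", "t1low", "t2high", "t2low"))
  g <- build_delaunay(quad)
  expect_equal(nrow(g$edges), 5)
  for (tri_pts in attr(g, "triangles")) {
    expect_true(circumcircle_empty(quad, tri_pts))
  }

  expect_error(build_delaunay(data.frame(x_mm = c(0, 1, 2), y_mm = c(0, 0, 0),
                                         habitat = rep("t1high", 3))),
               class = "habitatgraph_degenerate_geometry")
  expect_error(build_delaunay(data.frame(x_mm = 0:1, y_mm = 0:1,
                                         habitat = rep("t1low", 2))),
               class = "habitatgraph_degenerate_geometry")
})

test_that("every triangle of random triangulations has an empty circumcircle", {
  for (seed in 1:10) {
    n <- withr::with_seed(seed, sample(10:50, 1))
    pts <- withr::with_seed(seed + 40, data.frame(
      x_mm = runif(n, 0, 30), y_mm = runif(n, 0, 30),
      habitat = sample(habitat_labels(), n, replace = TRUE)))
    g <- build_delaunay(pts)
    expect_gt(nrow(g$edges), 0)
    for (tri_pts in attr(g, "triangles")) {
      expect_true(circumcircle_empty(pts, tri_pts))
    }
    # deterministic for a fixed input
    expect_identical(g$edges, build_delaunay(pts)$edges)
  }
})

test_that("duplicate centroid coordinates across habitats survive triangulation", {
  pts <- data.frame(x_mm = c(0, 4, 2, 2), y_mm = c(0, 0, 3, 3),
                    habitat = c("t1high", "t1low", "t2high", "t2low"))
  g <- build_delaunay(pts)
  expect_equal(nrow(g$vertices), 4)
  expect_true(all(c(3, 4) %in% c(g$edges$i, g$edges$j)))
})
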