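test_that("run accumulation matches the single-edge and path fixtures", {
  # one edge: one run of length 1 from each endpoint
  g1 <- manual_graph(c(0, 1), c(0, 0), c("t1high", "t1high"),
                     matrix(c(1, 2), 1))
  M1 <- compute_grlm(g1)
  expect_equal(M1$n_r, 2)
  expect_equal(unname(M1$G["t0", 1]), 2L)

  # path A-B-C, both edges the same type, unbounded window
  g2 <- manual_graph(c(0, 1, 2), c(0, 0, 0), rep("t1high", 3),
                     rbind(c(1, 2), c(2, 3)))
  M2 <- compute_grlm(g2)
  expect_equal(unname(M2$G["t0", 2]), 2L)  # from A and from C
  expect_equal(unname(M2$G["t0", 1]), 1L)  # from B
  expect_equal(M2$n_r, 3)

  # window smaller than |A -> C|: every run truncates to the first edge
  M3 <- compute_grlm(g2, window_radius_mm = 1.5)
  expect_equal(unname(M3$G["t0", 1]), 3L)
  expect_equal(M3$n_r, 3)
})

test_that("run-length features match hand evaluation", {
  mk <- function(entries, L_max = 10) {
    G <- matrix(0L, 10, L_max, dimnames = list(paste0("t", 0:9), NULL))
    for (e in entries) G[e[1] + 1, e[2]] <- e[3]
    structure(list(G = G, n_r = sum(G), n_r_t = rowSums(G),
                   window_radius_mm = Inf, L_max = L_max), class = "grlm")
  }
  f <- grlm_features(mk(list(c(0, 1, 1))))
  expect_equal(unname(f[c("spe", "lpe", "etn", "pln")]), c(1, 1, 1, 1))

  f2 <- grlm_features(mk(list(c(0, 2, 1))))
  expect_equal(unname(f2[c("spe", "lpe", "etn", "pln")]), c(0.25, 4, 1, 1))

  # G(t,1) = 1, G(t,2) = 2 (the path example): hand-computed values
  f3 <- grlm_features(mk(list(c(0, 1, 1), c(0, 2, 2))))
  expect_equal(unname(f3[c("spe", "lpe", "etn", "pln")]),
               c(0.5, 3, 3, 5 / 3), tolerance = 1e-12)
  expect_equal(f3[["spe_t0"]], 0.5, tolerance = 1e-12)
  expect_equal(f3[["lpe_t0"]], 3, tolerance = 1e-12)
  expect_true(all(is.na(f3[paste0("spe_t", 1:9)])))

  expect_error(grlm_features(mk(list())), class = "habitatgraph_empty_matrix")
})

test_that("compute_grlm matches the exhaustive path enumerator on random graphs", {
  for (seed in 1:12) {
    n <- withr::with_seed(seed, sample(4:12, 1))
    g <- random_labeled_graph(n, seed + 300)
    expect_identical(compute_grlm(g)$G, oracle_grlm(g))
    # and with a binding window and a low path cap
    w <- withr::with_seed(seed + 600, runif(1, 3, 15))
    expect_identical(compute_grlm(g, window_radius_mm = w, L_max = 4)$G,
                     oracle_grlm(g, window_radius_mm = w, L_max = 4))
  }
})

test_that("total runs equal the number of node-incident edge-type pairs", {
  for (seed in 1:8) {
    g <- random_labeled_graph(10, seed + 900)
    M <- compute_grlm(g)
    pairs <- unique(rbind(cbind(g$edges$i, g$edges$edge_type),
                          cbind(g$edges$j, g$edges$edge_type)))
    expect_equal(M$n_r, nrow(pairs))
    expect_equal(unname(M$n_r_t), vapply(0:9, function(t) {
      sum(pairs[, 2] == t)
    }, 0))
  }
})

test_that("short- and long-path emphasis bracket 1 and shrink with the window", {
  g <- random_labeled_graph(12, 123, p_edge = 0.5)
  f <- grlm_features(compute_grlm(g))
  expect_lte(f[["spe"]], 1)
  expect_gte(f[["lpe"]], 1)

  radii <- c(Inf, 20, 10, 5, 2, 0.5)
  lpes <- vapply(radii, function(r) {
    grlm_features(compute_grlm(g, window_radius_mm = r))[["lpe"]]
  }, 0)
  expect_true(all(diff(lpes) <= 1e-12))
  expect_equal(lpes[length(lpes)], 1)  # all runs collapse to single edges
  f0 <- grlm_features(compute_grlm(g, window_radius_mm = 0.5))
  expect_equal(f0[["spe"]], 1)
})

test_that("relabeling habitats permutes per-type features and fixes global ones", {
  g <- random_labeled_graph(12, 77, p_edge = 0.5)
  perm <- c(t1high = "t2low", t1low = "t2high", t2high = "t1low",
            t2low = "t1high")
  g2 <- g
  g2$vertices$habitat <- unname(perm[g$vertices$habitat])
  g2$edges$edge_type <- edge_type(g2$vertices$habitat[g2$edges$i],
                                  g2$vertices$habitat[g2$edges$j])
  f1 <- grlm_features(compute_grlm(g))
  f2 <- grlm_features(compute_grlm(g2))
  expect_equal(f1[c("spe", "lpe", "etn", "pln")],
               f2[c("spe", "lpe", "etn", "pln")])
  # each original type's per-type values reappear under the mapped type
  labs <- habitat_labels()
  pair_of <- function(t) {
    idx <- which(outer(labs, labs, edge_type) == t, arr.ind = TRUE)[1, ]
    c(labs[idx[1]], labs[idx[2]])
  }
  for (t in 0:9) {
    p <- pair_of(t)
    t_new <- edge_type(perm[[p[1]]], perm[[p[2]]])
    expect_equal(f1[[paste0("spe_t", t)]], f2[[paste0("spe_t", t_new)]])
    expect_equal(f1[[paste0("lpe_t", t)]], f2[[paste0("lpe_t", t_new)]])
  }
})

test_that("a subject yields 24 named features; absent habitats go missing", {
  f <- subject_grlm_features(hg_phantom()$masks)
  expect_length(f, 24)
  expect_identical(names(f), grlm_feature_names())
  expect_true(all(is.finite(f)))

  # t2low habitat empty: every edge type touching it must be missing
  empty <- matrix(FALSE, 40, 40)
  blob <- matrix(FALSE, 40, 40); blob[10:30, 10:30] <- TRUE
  blob2 <- matrix(FALSE, 40, 40); blob2[12:28, 12:28] <- TRUE
  f2 <- subject_grlm_features(fake_masks(blob, blob2, blob, empty))
  t2low_types <- vapply(habitat_labels(), edge_type, 0L, b = "t2low")
  expect_true(all(is.na(f2[paste0("spe_t", t2low_types)])))
  expect_true(all(is.na(f2[paste0("lpe_t", t2low_types)])))
})
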