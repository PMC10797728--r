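# Cluster extraction, geometric graphs, spectral and MST features, and
# the 20-feature pair vector.

test_that("clusters are 4-connected components with centroid means", {
  m <- matrix(0L, 4, 4)
  m[1, 1] <- 7L; m[1, 2] <- 7L; m[4, 4] <- 7L
  cl <- extract_clusters(m, 7L)
  expect_length(cl, 2)
  sizes <- vapply(cl, function(x) nrow(x$members), 0L)
  expect_setequal(sizes, c(2L, 1L))
  big <- cl[[which(sizes == 2L)]]
  expect_equal(unname(big$centroid), c(mean(c(1, 2)) - 0.5, 1 - 0.5))
  expect_length(extract_clusters(m, 99L), 0)
  uni <- extract_clusters(matrix(3L, 2, 2), 3L)
  expect_length(uni, 1)
  expect_equal(nrow(uni[[1]]$members), 4)
})

test_that("cluster extraction matches the flood-fill oracle", {
  set.seed(17)
  for (rep in 1:10) {
    m <- matrix(sample(0:2, 12 * 15, replace = TRUE), 12, 15)
    for (cls in 0:2) {
      got <- extract_clusters(m, cls)
      want <- oracle_components(m, cls)
      expect_equal(length(got), length(want))
      key <- function(mm) paste(sort(paste(mm[, 1], mm[, 2])), collapse = ";")
      expect_setequal(vapply(got, function(x) key(x$members), ""),
                      vapply(want, key, ""))
    }
  }
})

mk_clusters <- function(xy, class_id) {
  lapply(seq_len(nrow(xy)), function(i)
    list(class_id = class_id, members = cbind(row = 1, col = 1),
         cells = 1L, centroid = c(x = xy[i, 1], y = xy[i, 2])))
}

test_that("geometric graph edges follow the radius rule exactly", {
  a <- mk_clusters(cbind(c(0, 1), c(0, 0)), 1L)
  b <- mk_clusters(cbind(3, 0), 2L)
  g <- build_geometric_graph(a, b, radius = 1.5)
  expect_equal(nrow(g$edges), 1)
  expect_setequal(as.vector(g$edges), c(1, 2))
  g0 <- build_geometric_graph(a, b, radius = 0.5)
  expect_equal(nrow(g0$edges), 0)
  gc <- build_geometric_graph(a, b, radius = 10)
  expect_equal(nrow(gc$edges), 3 * 2 / 2)
  gx <- build_geometric_graph(a, b, radius = 10, cross_only = TRUE)
  expect_equal(nrow(gx$edges), 2)
  expect_true(all(g$class[gx$edges[, 1]] != g$class[gx$edges[, 2]]))
})

test_that("spectral features match closed forms on K3, P3 and null graphs", {
  tri <- mk_clusters(cbind(c(0, 1, 0), c(0, 0, 1)), 1L)
  g3 <- build_geometric_graph(tri[1:2], tri[3], radius = 2)
  expect_equal(nrow(g3$edges), 3)
  s <- spectral_node_features(g3)
  expect_equal(s[["mean_degree"]], 2)
  expect_equal(s[["mean_clustering"]], 1)
  expect_equal(s[["spectral_radius"]], 2, tolerance = 1e-9)
  expect_equal(s[["algebraic_connectivity"]], 3, tolerance = 1e-9)
  # path P3 on a line
  line <- mk_clusters(cbind(c(0, 1, 2), 0), 1L)
  gp <- build_geometric_graph(line[1:2], line[3], radius = 1.1)
  expect_equal(nrow(gp$edges), 2)
  sp <- spectral_node_features(gp)
  expect_equal(sp[["algebraic_connectivity"]], 1, tolerance = 1e-9)
  expect_equal(sp[["spectral_radius"]], sqrt(2), tolerance = 1e-9)
  # edgeless
  far <- mk_clusters(cbind(c(0, 100), 0), 1L)
  ge <- build_geometric_graph(far[1], far[2], radius = 1)
  se <- spectral_node_features(ge)
  expect_equal(se[["mean_degree"]], 0)
  expect_equal(se[["mean_clustering"]], 0)
  expect_equal(se[["algebraic_connectivity"]], 0)
})

test_that("MST features match exhaustive spanning-tree enumeration", {
  tri <- mk_clusters(cbind(c(0, 3, 0), c(0, 0, 4)), 1L)
  g <- build_geometric_graph(tri[1:2], tri[3], radius = 100)
  f <- mst_features(g, map_diagonal = 1)
  expect_equal(f[["mst_total_norm"]], 7)
  expect_equal(f[["mst_mean_edge"]], 3.5)
  expect_equal(f[["mst_max_edge"]], 4)
  # unit square corners: MST total 3
  sq <- mk_clusters(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)), 1L)
  gs <- build_geometric_graph(sq[1:2], sq[3:4], radius = 100)
  expect_equal(mst_features(gs, 1)[["mst_total_norm"]], 3)
  # random node sets against the brute-force oracle
  set.seed(23)
  for (n in 3:6) {
    xy <- matrix(runif(2 * n, 0, 10), n, 2)
    cl <- mk_clusters(xy, 1L)
    gg <- build_geometric_graph(cl[1], cl[-1], radius = 100)
    expect_equal(mst_features(gg, 1)[["mst_total_norm"]],
                 oracle_mst_total(xy), tolerance = 1e-9)
  }
  # single node: all zeros
  g1 <- build_geometric_graph(mk_clusters(cbind(1, 1), 1L), list(), 5)
  expect_true(all(mst_features(g1, 10) == 0))
})

test_that("MST length is invariant to rigid motions and relabeling", {
  set.seed(29)
  xy <- matrix(runif(12, 0, 10), 6, 2)
  base <- mst_features(build_geometric_graph(mk_clusters(xy, 1L), list(),
                                             5), 1)[["mst_total_norm"]]
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  xy2 <- sweep(xy %*% R, 2, c(3, -2), "+")
  rot <- mst_features(build_geometric_graph(mk_clusters(xy2, 1L), list(),
                                            5), 1)[["mst_total_norm"]]
  expect_equal(rot, base, tolerance = 1e-9)
  perm <- xy[sample(6), ]
  expect_equal(mst_features(build_geometric_graph(mk_clusters(perm, 1L),
                                                  list(), 5),
                            1)[["mst_total_norm"]], base, tolerance = 1e-9)
})

test_that("pair vectors have 20 slots, argument symmetry and zero fill", {
  m <- generate_label_map(c(`1` = 1, `2` = 1), c(20, 20), seed = 5)
  f1 <- pair_features(m, NULL, 1L, 2L)
  expect_length(f1, 20)
  expect_identical(names(f1), pair_feature_names())
  expect_true(attr(f1, "valid"))
  f2 <- pair_features(m, NULL, 2L, 1L)
  expect_equal(unclass(f1), unclass(f2))
  expect_identical(f1, pair_features(m, NULL, 1L, 2L))
  # absent class: zero vector flagged invalid
  f0 <- pair_features(m, NULL, 1L, 9L)
  expect_true(all(f0 == 0))
  expect_false(attr(f0, "valid"))
})

test_that("texture averages pool the member-cell features per class", {
  m <- matrix(c(1L, 1L, 2L, 2L), 2, 2)
  tf <- matrix(seq_len(4 * 80) / 10, 4, 80,
               dimnames = list(NULL, feature_catalog()$name))
  f <- pair_features(m, tf, 1L, 2L, radius = 5)
  cells_a <- which(as.vector(m) == 1L)
  expect_equal(f[["texA_hist_entropy"]],
               mean(tf[cells_a, "hist_entropy"]))
  expect_equal(f[["node_count_ratio"]], 0.5)
})

test_that("all 16 histology classes give C(16,2) = 120 pair vectors", {
  set.seed(41)
  m <- matrix(sample(0:15, 24 * 24, replace = TRUE), 24, 24)
  pats <- list(list(patient_id = "P1", outcome = "pCR", label_map = m,
                    tile_features = NULL),
               list(patient_id = "P2", outcome = "RD", label_map = m,
                    tile_features = NULL))
  X <- cohort_pair_features(pats, 0:15)
  expect_equal(ncol(X), 120 * 20)
  expect_equal(nrow(X), 2)
  # background sentinel never becomes a node class
  Xb <- cohort_pair_features(pats, c(0:15, background_sentinel()))
  expect_equal(ncol(Xb), 120 * 20)
})
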