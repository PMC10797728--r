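# Tiling against polygon annotations, OD transform, stain estimation,
# normalization and deconvolution.

square <- function(x0, y0, side) {
  cbind(c(x0, x0 + side, x0 + side, x0),
        c(y0, y0, y0 + side, y0 + side))
}

test_that("tile retention follows the exact overlap rule", {
  # a 448x448 square anchored at the origin covers exactly 4 tiles fully
  r <- list(list(polygon = square(0, 0, 448), class_id = 1L))
  t4 <- tile_partition(r, c(1000, 1000))
  expect_equal(nrow(t4), 4)
  expect_setequal(paste(t4$grid_row, t4$grid_col),
                  c("0 0", "0 1", "1 0", "1 1"))
  expect_true(all(t4$class == 1L))
  # a 100x100 region can never reach 90% of a 224^2 tile
  r <- list(list(polygon = square(10, 10, 100), class_id = 1L))
  expect_equal(nrow(tile_partition(r, c(1000, 1000))), 0)
  # a region covering the whole extent retains every grid tile
  r <- list(list(polygon = square(0, 0, 896), class_id = 2L))
  expect_equal(nrow(tile_partition(r, c(896, 896))), 16)
})

test_that("tile partition is invariant to vertex order and grid shifts", {
  poly <- cbind(c(30, 500, 520, 40), c(20, 10, 480, 510))
  r1 <- tile_partition(list(list(polygon = poly, class_id = 3L)),
                       c(1200, 1200))
  rev_poly <- poly[nrow(poly):1, ]
  r2 <- tile_partition(list(list(polygon = rev_poly, class_id = 3L)),
                       c(1200, 1200))
  expect_equal(r1, r2)
  shifted <- sweep(poly, 2, c(224, 448), "+")
  r3 <- tile_partition(list(list(polygon = shifted, class_id = 3L)),
                       c(1600, 1600))
  expect_equal(r3$grid_col, r1$grid_col + 1)
  expect_equal(r3$grid_row, r1$grid_row + 2)
})

test_that("retention matches a rasterized-mask oracle on random polygons", {
  set.seed(21)
  for (rep in 1:5) {
    # random convex-ish polygon: points on a noisy circle
    ang <- sort(runif(7, 0, 2 * pi))
    rad <- runif(7, 150, 400)
    poly <- cbind(500 + rad * cos(ang), 500 + rad * sin(ang))
    got <- tile_partition(list(list(polygon = poly, class_id = 1L)),
                          c(1000, 1000), tile_size = 112, min_overlap = 0.9)
    want <- oracle_tile_retention(poly, c(1000, 1000), 112, 0.9)
    # pixel-center rasterization can disagree on boundary-grazing tiles
    expect_lte(abs(nrow(got) - nrow(want)), 1)
    common <- intersect(paste(got$grid_row, got$grid_col),
                        paste(want[, 1], want[, 2]))
    expect_gte(length(common), max(nrow(got), nrow(want)) - 1)
  }
})

test_that("ties and multi-region overlap resolve deterministically", {
  # two regions each covering half of tile (0,0) exactly: lower id wins
  left <- cbind(c(0, 112, 112, 0), c(0, 0, 224, 224))
  right <- cbind(c(112, 224, 224, 112), c(0, 0, 224, 224))
  r <- tile_partition(list(list(polygon = right, class_id = 7L),
                           list(polygon = left, class_id = 2L)),
                      c(224, 224), min_overlap = 0.4)
  expect_equal(r$class, 2L)
  expect_error(tile_partition(list(), c(224, 224)), "empty")
  bow <- cbind(c(0, 300, 0, 300), c(0, 300, 300, 0))
  expect_error(tile_partition(list(list(polygon = bow, class_id = 1L)),
                              c(448, 448)), "self-intersecting")
})

test_that("optical density transform matches its closed form", {
  expect_equal(rgb_to_od(255), 0, tolerance = 1e-6)
  expect_equal(rgb_to_od(25.5), 1, tolerance = 1e-6)
  ints <- seq(0, 255, by = 5)
  expect_true(all(diff(rgb_to_od(ints)) < 0))
  expect_equal(od_to_rgb(rgb_to_od(ints)), ints, tolerance = 1e-9)
})

test_that("stain vectors are recovered from planted mixtures", {
  set.seed(31)
  M <- default_stain_matrix()
  cH <- matrix(runif(64 * 64, 0.05, 1.2), 64, 64)
  cE <- matrix(runif(64 * 64, 0.05, 0.9), 64, 64)
  tile <- render_from_concentrations(cH, cE, M)
  fit <- estimate_stain_vectors(tile)
  angle <- function(a, b) acos(pmin(1, sum(a * b))) * 180 / pi
  expect_lt(angle(fit$stain_matrix[, 1], M[, 1]), 5)
  expect_lt(angle(fit$stain_matrix[, 2], M[, 2]), 5)
  # single pure stain plus white background
  cH1 <- matrix(0, 64, 64); cH1[20:40, 20:40] <- runif(21 * 21, 0.4, 1.2)
  tile1 <- render_from_concentrations(cH1, matrix(0, 64, 64), M)
  fit1 <- estimate_stain_vectors(tile1)
  expect_lt(angle(fit1$stain_matrix[, 1], M[, 1]), 2)
  # near-white tile: insufficient tissue
  white <- array(254, dim = c(32, 32, 3))
  expect_error(estimate_stain_vectors(white), "insufficient tissue")
})

test_that("stain normalization is identity-safe and removes stain shifts", {
  set.seed(32)
  M <- default_stain_matrix()
  cH <- matrix(runif(48 * 48, 0.1, 1), 48, 48)
  cE <- matrix(runif(48 * 48, 0.1, 0.8), 48, 48)
  tile <- render_from_concentrations(cH, cE, M)
  model <- structure(list(stain_matrix = M,
                          max_concentrations = c(1.2, 0.9)),
                     class = "stain_model")
  same <- normalize_stains(tile, model, model)
  expect_lt(max(abs(same - tile)), 1 + 1e-6)
  # same scene under a perturbed stain matrix
  M2 <- M + matrix(c(0.12, -0.08, 0.1, -0.05, 0.06, 0.1), 3, 2)
  M2 <- sweep(abs(M2), 2, sqrt(colSums(M2^2)), "/")
  tile2 <- render_from_concentrations(cH, cE, M2)
  before <- mean(abs(tile - tile2))
  m1 <- estimate_stain_vectors(tile)
  m2 <- estimate_stain_vectors(tile2)
  ref <- estimate_stain_vectors(tile)
  n1 <- normalize_stains(tile, m1, ref)
  n2 <- normalize_stains(tile2, m2, ref)
  expect_lt(mean(abs(n1 - n2)) * 10, before)
  expect_true(all(n2 >= 0 & n2 <= 255))
})

test_that("color deconvolution recovers the hematoxylin channel", {
  set.seed(33)
  M <- default_stain_matrix()
  model <- structure(list(stain_matrix = M, max_concentrations = c(1, 1)),
                     class = "stain_model")
  cH <- matrix(runif(32 * 32, 0, 1.5), 32, 32)
  cE <- matrix(runif(32 * 32, 0, 1.0), 32, 32)
  od <- cbind(as.vector(cH), as.vector(cE)) %*% t(M)
  conc <- tmegraph:::stain_concentrations(od, M)
  expect_lt(max(abs(matrix(conc[, 1], 32, 32) - cH)), 1e-6)
  # pure eosin: H channel near zero
  eosin <- render_from_concentrations(matrix(0, 32, 32),
                                      matrix(0.6, 32, 32), M)
  expect_lt(mean(hematoxylin_channel(eosin, model)), 0.01)
  # nuclei disks carry more hematoxylin than their surroundings
  cHn <- matrix(0.2, 64, 64)
  mask <- matrix(FALSE, 64, 64)
  for (ctr in list(c(16, 16), c(40, 48))) {
    d <- sqrt(outer((1:64 - ctr[1])^2, (1:64 - ctr[2])^2, "+"))
    mask <- mask | d <= 5
  }
  cHn[mask] <- 1.0
  nuc <- render_from_concentrations(cHn, matrix(0.3, 64, 64), M)
  h <- hematoxylin_channel(nuc, model)
  expect_gt(mean(h[mask]), mean(h[!mask]))
})

test_that("background tiles are flagged by mean optical density", {
  expect_true(is_background_tile(array(250, dim = c(8, 8, 3))))
  expect_false(is_background_tile(array(120, dim = c(8, 8, 3))))
})

test_that("QuPath-style GeoJSON annotations round-trip", {
  gj <- list(type = "FeatureCollection", features = list(
    list(type = "Feature",
         geometry = list(type = "Polygon",
                         coordinates = list(list(list(0, 0), list(300, 0),
                                                 list(300, 300), list(0, 300),
                                                 list(0, 0)))),
         properties = list(classification = list(name = "tumor")))))
  path <- tempfile(fileext = ".geojson")
  jsonlite::write_json(gj, path, auto_unbox = TRUE)
  regions <- read_annotations(path)
  expect_length(regions, 1)
  expect_equal(regions[[1]]$class_id, 1L)
  expect_equal(nrow(regions[[1]]$polygon), 4)  # closing vertex dropped
})
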