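# Texture feature families against brute-force oracles and closed forms.

test_that("GLCM matches hand-countable cases", {
  # constant tile: single co-occurrence entry
  v <- glcm_features(matrix(5, 16, 16))
  for (a in c(0, 45, 90, 135)) {
    expect_equal(v[[sprintf("glcm_contrast_a%d", a)]], 0)
    expect_equal(v[[sprintf("glcm_energy_a%d", a)]], 1)
    expect_equal(v[[sprintf("glcm_homogeneity_a%d", a)]], 1)
    expect_true(is.na(v[[sprintf("glcm_correlation_a%d", a)]]))
  }
  # 2x2 image [[0,1],[2,3]] at 4 levels, angle 0, d = 1:
  # symmetric pairs {0,1} and {2,3}, each probability 0.25 per direction
  img <- matrix(c(0, 2, 1, 3), 2, 2)  # rows: (0,1) / (2,3)
  v <- glcm_features(img, levels = 4)
  expect_equal(v[["glcm_contrast_a0"]], 1)
})

test_that("GLCM equals the counting oracle on random images", {
  offs <- list(`0` = c(0, 1), `45` = c(-1, 1), `90` = c(-1, 0),
               `135` = c(-1, -1))
  set.seed(42)
  for (rep in 1:100) {
    img <- matrix(sample(0:7, 64, replace = TRUE), 8, 8)
    for (d in 1:2) {
      v <- glcm_features(img, levels = 8, distance = d)
      q <- quantize_gray(img, 8)
      for (a in names(offs)) {
        o <- oracle_glcm(q, 8, offs[[a]][1] * d, offs[[a]][2] * d)
        for (s in c("contrast", "correlation", "energy", "homogeneity",
                    "entropy")) {
          got <- v[[sprintf("glcm_%s_a%s", s, a)]]
          if (is.na(o[[s]])) expect_true(is.na(got))
          else expect_equal(got, o[[s]], tolerance = 1e-10)
        }
      }
    }
  }
})

test_that("Gabor features respond to matched gratings and rotations", {
  expect_equal(unname(gabor_features(matrix(0, 32, 32))), rep(0, 32))
  # horizontal grating at catalog frequency 2 (0.1 cycles/px), varying
  # along x: strongest mean magnitude at (f2, orientation 0)
  x <- matrix(rep(1:64, each = 64), 64, 64)  # value = column index
  grating <- cos(2 * pi * 0.1 * x)
  v <- gabor_features(grating)
  means <- v[grep("_mean$", names(v))]
  expect_equal(names(which.max(means)), "gabor_f2_o1_mean")
  # rotating 90 degrees permutes the orientation index (o1 <-> o3)
  vr <- gabor_features(t(grating)[, 64:1])
  expect_equal(unname(vr[["gabor_f2_o3_mean"]]),
               unname(v[["gabor_f2_o1_mean"]]), tolerance = 0.05)
})

test_that("LBP histogram is a distribution and matches enumeration", {
  h <- lbp_features(matrix(3, 9, 9))
  expect_equal(sum(h), 1, tolerance = 1e-9)
  expect_equal(unname(h[["lbp_u16"]]), 1)  # all-ones pattern via >=
  set.seed(7)
  img <- matrix(runif(49), 7, 7)
  img[4, 4] <- 10  # bright center
  expect_equal(unname(lbp_features(img)), oracle_lbp(img), tolerance = 1e-12)
  img2 <- matrix(runif(144), 12, 12)
  h2 <- lbp_features(img2)
  expect_equal(sum(h2), 1, tolerance = 1e-9)
  expect_true(all(h2 >= 0))
  expect_equal(unname(h2), oracle_lbp(img2), tolerance = 1e-12)
})

test_that("Tamura features order coarseness and directionality correctly", {
  v <- tamura_features(matrix(1, 32, 32))
  expect_equal(v[["tamura_contrast"]], 0)
  expect_equal(v[["tamura_directionality"]], 0)
  checker <- function(block, n = 64)
    outer(seq_len(n), seq_len(n),
          function(r, c) (floor((r - 1) / block) + floor((c - 1) / block)) %% 2)
  expect_gt(tamura_features(checker(16))[["tamura_coarseness"]],
            tamura_features(checker(2))[["tamura_coarseness"]])
  stripes <- matrix(rep(c(0, 0, 1, 1), length.out = 48), 48, 48, byrow = FALSE)
  set.seed(1)
  noise <- matrix(runif(48 * 48), 48, 48)
  expect_gt(tamura_features(stripes)[["tamura_directionality"]],
            tamura_features(noise)[["tamura_directionality"]])
})

test_that("histogram features match closed forms", {
  v <- histogram_features(matrix(7, 5, 5))
  expect_equal(v[["hist_mean"]], 7)
  expect_equal(v[["hist_variance"]], 0)
  expect_equal(v[["hist_median"]], 7)
  expect_equal(v[["hist_mode"]], 7)
  expect_true(is.na(v[["hist_skewness"]]))
  expect_true(is.na(v[["hist_kurtosis"]]))
  expect_equal(histogram_features(c(0, 0, 0, 255))[["hist_mean"]], 63.75)
  # symmetric distribution: zero skewness
  sym <- c(1, 2, 3, 4, 5, 5, 4, 3, 2, 1)
  expect_equal(histogram_features(sym)[["hist_skewness"]], 0,
               tolerance = 1e-9)
})

test_that("extract_all is an 80-vector aligned with the catalog", {
  cat80 <- feature_catalog()
  expect_equal(nrow(cat80), 80)
  expect_equal(as.vector(table(cat80$family)[c("GLCM", "Gabor", "LBP",
                                               "Tamura", "HistLow",
                                               "HistHigh")]),
               c(20, 32, 18, 3, 4, 3))
  set.seed(3)
  g <- matrix(runif(48 * 48), 48, 48)
  v1 <- extract_all(g)
  expect_length(v1, 80)
  expect_identical(names(v1), cat80$name)
  expect_identical(v1, extract_all(g))
})

test_that("feature exclusion drops zero, NA and duplicate columns once", {
  set.seed(11)
  m <- matrix(rnorm(40), 10, 4)
  m <- cbind(m, m[, 2], 0, m[, 1])      # duplicates of 2 and 1, a zero col
  m <- cbind(m, c(NA, rnorm(9)))
  r <- exclude_features(m)
  expect_equal(r$retained, 1:4)
  expect_setequal(r$dropped$index, 5:8)
  expect_equal(r$dropped$reason[r$dropped$index == 5], "duplicate-of:2")
  expect_equal(r$dropped$reason[r$dropped$index == 6], "all-zero")
  expect_equal(r$dropped$reason[r$dropped$index == 7], "duplicate-of:1")
  expect_equal(r$dropped$reason[r$dropped$index == 8], "NA")
  # full-rank continuous matrix: everything retained
  big <- matrix(rnorm(200 * 80), 200, 80)
  expect_equal(exclude_features(big)$retained, 1:80)
  # idempotence on the retained submatrix
  r2 <- exclude_features(m[, r$retained, drop = FALSE])
  expect_equal(r2$retained, seq_along(r$retained))
  expect_equal(nrow(r2$dropped), 0)
})

test_that("family outputs tolerate a constant background border", {
  set.seed(5)
  core <- matrix(runif(32 * 32), 32, 32)
  pad <- matrix(0, 48, 48)
  pad[9:40, 9:40] <- core
  # GLCM statistics shift only moderately under padding; LBP remains a
  # distribution; the documented exception is the histogram family
  expect_equal(sum(lbp_features(pad)), 1, tolerance = 1e-9)
  expect_false(isTRUE(all.equal(histogram_features(pad)[["hist_mean"]],
                                histogram_features(core)[["hist_mean"]])))
})
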