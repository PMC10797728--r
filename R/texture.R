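# Tile-level texture features: GLCM, Gabor, LBP, Tamura, histogram.
# All operate on a single-channel image (matrix), by default the
# deconvolved hematoxylin concentration channel.

#' Quantize a gray image to discrete levels
#'
#' Linear binning of the observed intensity range into `levels` bins.
#' A constant image maps to level 0 everywhere.
#'
#' @param gray numeric matrix.
#' @param levels integer >= 2.
#' @return integer matrix with values in `0:(levels-1)`.
#' @export
quantize_gray <- function(gray, levels = 32L) {
  if (levels < 2) stop("levels must be >= 2")
  rng <- range(gray)
  if (rng[1] == rng[2]) return(matrix(0L, nrow(gray), ncol(gray)))
  q <- floor((gray - rng[1]) / (rng[2] - rng[1]) * levels)
  q[q > levels - 1] <- levels - 1L
  matrix(as.integer(q), nrow(gray), ncol(gray))
}

glcm_offsets <- function(distance = 1L) {
  # angle -> (drow, dcol) in image coordinates (row down, col right)
  list(`0` = c(0L, distance), `45` = c(-distance, distance),
       `90` = c(-distance, 0L), `135` = c(-distance, -distance))
}

# Symmetric normalized co-occurrence matrix for one offset.
glcm_matrix <- function(q, levels, offset) {
  nr <- nrow(q); nc <- ncol(q)
  dr <- offset[1]; dc <- offset[2]
  r0 <- max(1, 1 - dr):min(nr, nr - dr)
  c0 <- max(1, 1 - dc):min(nc, nc - dc)
  if (length(r0) < 1 || length(c0) < 1) stop("tile smaller than the GLCM offset")
  i <- q[r0, c0, drop = FALSE]
  j <- q[r0 + dr, c0 + dc, drop = FALSE]
  idx <- as.vector(i) * levels + as.vector(j) + 1L
  counts <- tabulate(idx, nbins = levels * levels)
  m <- matrix(counts, levels, levels, byrow = TRUE)
  m <- m + t(m)                       # symmetric pairs
  m / sum(m)
}

glcm_stats_from_matrix <- function(p) {
  levels <- nrow(p)
  ij <- 0:(levels - 1)
  I <- matrix(ij, levels, levels)
  J <- t(I)
  contrast <- sum(p * (I - J)^2)
  energy <- sum(p^2)
  homogeneity <- sum(p / (1 + (I - J)^2))
  pos <- p > 0
  entropy <- -sum(p[pos] * log2(p[pos]))
  pi_ <- rowSums(p); pj <- colSums(p)
  mu_i <- sum(ij * pi_); mu_j <- sum(ij * pj)
  var_i <- sum((ij - mu_i)^2 * pi_); var_j <- sum((ij - mu_j)^2 * pj)
  correlation <- if (var_i <= 0 || var_j <= 0) NA_real_ else
    sum(p * (I - mu_i) * (J - mu_j)) / sqrt(var_i * var_j)
  c(contrast = contrast, correlation = correlation, energy = energy,
    homogeneity = homogeneity, entropy = entropy)
}

#' Gray-level co-occurrence matrix features
#'
#' Five Haralick-style statistics (contrast, correlation, energy,
#' homogeneity, entropy) of the symmetric normalized co-occurrence
#' matrix at four offsets (0, 45, 90, 135 degrees). Correlation is NA
#' when either marginal variance is zero (e.g. a constant tile).
#'
#' @param gray numeric matrix (any range; quantized internally).
#' @param levels number of gray levels (default 32).
#' @param distance offset distance in pixels (default 1).
#' @return named numeric vector of length 20 (5 statistics x 4 angles).
#' @export
glcm_features <- function(gray, levels = 32L, distance = 1L) {
  q <- quantize_gray(gray, levels)
  out <- numeric(0)
  for (ang in names(glcm_offsets(distance))) {
    p <- glcm_matrix(q, levels, glcm_offsets(distance)[[ang]])
    s <- glcm_stats_from_matrix(p)
    names(s) <- sprintf("glcm_%s_a%s", names(s), ang)
    out <- c(out, s)
  }
  out
}

gabor_kernel <- function(frequency, theta, sigma = 0.56 / frequency,
                         gamma = 1) {
  half <- max(2L, ceiling(3 * sigma))
  xs <- -half:half
  X <- matrix(xs, 2 * half + 1, 2 * half + 1, byrow = TRUE)
  Y <- matrix(xs, 2 * half + 1, 2 * half + 1)
  xp <- X * cos(theta) + Y * sin(theta)
  yp <- -X * sin(theta) + Y * cos(theta)
  env <- exp(-(xp^2 + gamma^2 * yp^2) / (2 * sigma^2))
  env * exp(2i * pi * frequency * xp)
}

# "same"-size FFT convolution of a real image with a complex kernel.
conv2_fft <- function(img, kern) {
  nr <- nrow(img) + nrow(kern) - 1L
  nc <- ncol(img) + ncol(kern) - 1L
  A <- matrix(0, nr, nc); A[seq_len(nrow(img)), seq_len(ncol(img))] <- img
  B <- matrix(0 + 0i, nr, nc); B[seq_len(nrow(kern)), seq_len(ncol(kern))] <- kern
  full <- stats::fft(stats::fft(A) * stats::fft(B), inverse = TRUE) / (nr * nc)
  r0 <- (nrow(kern) - 1L) %/% 2L
  c0 <- (ncol(kern) - 1L) %/% 2L
  full[r0 + seq_len(nrow(img)), c0 + seq_len(ncol(img))]
}

#' Gabor filter-bank features
#'
#' Mean and standard deviation of the complex response magnitude for each
#' (frequency, orientation) filter pair.
#'
#' @param gray numeric matrix.
#' @param frequencies spatial frequencies in cycles/pixel.
#' @param orientations orientations in radians.
#' @return named numeric vector of length
#'   `2 * length(frequencies) * length(orientations)` (32 by default).
#' @export
gabor_features <- function(gray, frequencies = c(0.05, 0.1, 0.2, 0.4),
                           orientations = c(0, 45, 90, 135) * pi / 180) {
  out <- numeric(0)
  for (fi in seq_along(frequencies)) {
    for (oi in seq_along(orientations)) {
      k <- gabor_kernel(frequencies[fi], orientations[oi])
      mag <- Mod(conv2_fft(gray, k))
      v <- c(mean(mag), stats::sd(as.vector(mag)))
      names(v) <- sprintf("gabor_f%d_o%d_%s", fi, oi, c("mean", "sd"))
      out <- c(out, v)
    }
  }
  out
}

# Bilinear sample of img at fractional offsets (dr, dc) applied to the
# sub-grid rows r, cols c (vectors of valid center positions).
bilinear_shift <- function(img, r, c, dr, dc) {
  rf <- r + dr; cf <- c + dc
  r0 <- pmin(floor(rf), nrow(img) - 1L)
  c0 <- pmin(floor(cf), ncol(img) - 1L)
  fr <- rf - r0; fc <- cf - c0
  w00 <- outer(1 - fr, 1 - fc); w01 <- outer(1 - fr, fc)
  w10 <- outer(fr, 1 - fc);     w11 <- outer(fr, fc)
  img[r0, c0, drop = FALSE] * w00 + img[r0, c0 + 1L, drop = FALSE] * w01 +
    img[r0 + 1L, c0, drop = FALSE] * w10 + img[r0 + 1L, c0 + 1L, drop = FALSE] * w11
}

#' Uniform local binary pattern features
#'
#' Normalized histogram over the P + 2 uniform-pattern bins: bins
#' `0..P` hold uniform patterns (at most two 0/1 transitions around the
#' circle) keyed by their number of ones; bin `P + 1` collects all
#' non-uniform patterns. Neighbors are sampled on a circle of radius `R`
#' with bilinear interpolation and compared to the center with `>=`.
#'
#' @param gray numeric matrix larger than `2R + 1` in both dimensions.
#' @param P number of circular neighbors (default 16).
#' @param R circle radius in pixels (default 2).
#' @return named numeric vector of length `P + 2` summing to 1.
#' @export
lbp_features <- function(gray, P = 16L, R = 2) {
  nr <- nrow(gray); nc <- ncol(gray)
  m <- ceiling(R)
  if (nr <= 2 * m + 1 || nc <= 2 * m + 1) stop("tile smaller than 2R+1")
  r <- (m + 1L):(nr - m); c <- (m + 1L):(nc - m)
  center <- gray[r, c, drop = FALSE]
  bits <- array(0L, dim = c(length(r), length(c), P))
  for (p in seq_len(P)) {
    ang <- 2 * pi * (p - 1) / P
    dr <- -R * sin(ang); dc <- R * cos(ang)
    if (abs(dr) < 1e-9) dr <- 0
    if (abs(dc) < 1e-9) dc <- 0
    # >= comparison with a small slack so exact ties survive the
    # interpolation round-off (the documented tie convention)
    bits[, , p] <- (bilinear_shift(gray, r, c, dr, dc) >= center - 1e-9) * 1L
  }
  trans <- matrix(0L, length(r), length(c))
  for (p in seq_len(P)) {
    pn <- if (p == P) 1L else p + 1L
    trans <- trans + (bits[, , p] != bits[, , pn])
  }
  ones <- apply(bits, c(1, 2), sum)
  bin <- ifelse(trans <= 2L, ones, P + 1L)
  h <- tabulate(as.vector(bin) + 1L, nbins = P + 2L)
  h <- h / sum(h)
  names(h) <- sprintf("lbp_u%02d", 0:(P + 1L))
  h
}

# Box mean of side 2^k at every pixel (edge-padded), via integral image.
box_mean <- function(img, k) {
  s <- 2L^k
  half <- s %/% 2L
  nr <- nrow(img); nc <- ncol(img)
  # pad by replication so windows near edges stay defined
  pad <- img[pmin(pmax(seq_len(nr + s) - half, 1L), nr),
             pmin(pmax(seq_len(nc + s) - half, 1L), nc), drop = FALSE]
  ii <- apply(apply(pad, 2, cumsum), 1, cumsum)  # transposed integral image
  ii <- t(ii)
  Z <- matrix(0, nrow(ii) + 1L, ncol(ii) + 1L)
  Z[-1, -1] <- ii
  r1 <- seq_len(nr); c1 <- seq_len(nc)
  (Z[r1 + s, c1 + s] - Z[r1, c1 + s] - Z[r1 + s, c1] + Z[r1, c1]) / (s * s)
}

#' Tamura texture features: coarseness, contrast, directionality
#'
#' Coarseness follows Tamura's best-scale construction: for scales
#' `k = 1..kmax`, neighborhood averages over `2^k` windows are differenced
#' across `2^(k-1)`-pixel horizontal and vertical displacements, and each
#' pixel votes for the scale with the largest difference; coarseness is
#' the mean of `2^k_best`. Contrast is `sd / kurtosis^(1/4)` (0 for a
#' constant image). Directionality is the resultant length of the
#' gradient-magnitude-weighted doubled-angle distribution of Prewitt
#' gradient orientations, in [0, 1]; 0 when there is no gradient.
#'
#' @param gray numeric matrix.
#' @return named numeric vector of length 3.
#' @export
tamura_features <- function(gray) {
  nr <- nrow(gray); nc <- ncol(gray)
  # --- coarseness ---
  kmax <- max(1L, min(5L, floor(log2(min(nr, nc))) - 1L))
  best_diff <- matrix(-Inf, nr, nc)
  best_k <- matrix(1L, nr, nc)
  for (k in seq_len(kmax)) {
    A <- box_mean(gray, k)
    d <- 2L^(k - 1L)
    half <- 2L^(k - 1L)
    ridx_f <- pmin(seq_len(nr) + d, nr); ridx_b <- pmax(seq_len(nr) - d, 1L)
    cidx_f <- pmin(seq_len(nc) + d, nc); cidx_b <- pmax(seq_len(nc) - d, 1L)
    Eh <- abs(A[, cidx_f, drop = FALSE] - A[, cidx_b, drop = FALSE])
    Ev <- abs(A[ridx_f, , drop = FALSE] - A[ridx_b, , drop = FALSE])
    # only pixels whose displaced windows lie fully inside the image may
    # vote for this scale (padding would otherwise fake large-scale
    # structure on fine textures)
    rv <- seq_len(nr) >= 1L + d + half & seq_len(nr) <= nr - d - half + 1L
    cv <- seq_len(nc) >= 1L + d + half & seq_len(nc) <= nc - d - half + 1L
    Eh[, !cv] <- -Inf
    Ev[!rv, ] <- -Inf
    E <- pmax(Eh, Ev)
    upd <- E > best_diff
    best_diff[upd] <- E[upd]
    best_k[upd] <- k
  }
  coarseness <- mean(2^best_k)
  # --- contrast ---
  mu <- mean(gray)
  m2 <- mean((gray - mu)^2)
  contrast <- if (m2 <= 0) 0 else {
    m4 <- mean((gray - mu)^4)
    kurt <- m4 / m2^2
    sqrt(m2) / kurt^0.25
  }
  # --- directionality ---
  if (nr >= 3 && nc >= 3) {
    ph <- matrix(c(-1, -1, -1, 0, 0, 0, 1, 1, 1), 3, 3)  # d/dcol
    pv <- t(ph)                                          # d/drow
    gh <- Re(conv2_fft(gray, ph))[2:(nr - 1), 2:(nc - 1)]
    gv <- Re(conv2_fft(gray, pv))[2:(nr - 1), 2:(nc - 1)]
    mag <- sqrt(gh^2 + gv^2)
    # suppress FFT round-off gradients on (near-)constant images
    mag[mag < 1e-9 * max(1, max(abs(gray)))] <- 0
    tot <- sum(mag)
    directionality <- if (tot <= 0) 0 else {
      theta <- atan2(gv, gh)
      Mod(sum(mag * exp(2i * theta))) / tot
    }
  } else directionality <- 0
  c(tamura_coarseness = coarseness, tamura_contrast = contrast,
    tamura_directionality = directionality)
}

#' First-order histogram features
#'
#' Lower-order block: mean, variance, median, mode (mode taken as the
#' midpoint of the fullest of 64 equal-width bins over the observed
#' range; the constant value for a constant image). Higher-order block:
#' skewness and excess kurtosis (NA when the variance is 0) and Shannon
#' entropy (bits) of the 64-bin histogram.
#'
#' @param gray numeric matrix or vector of intensities.
#' @param nbins histogram bins for mode and entropy.
#' @return named numeric vector of length 7.
#' @export
histogram_features <- function(gray, nbins = 64L) {
  x <- as.vector(gray)
  mu <- mean(x)
  v <- stats::var(x)
  med <- stats::median(x)
  rng <- range(x)
  if (rng[1] == rng[2]) {
    mode_val <- rng[1]
    entropy <- 0
  } else {
    br <- seq(rng[1], rng[2], length.out = nbins + 1L)
    cnt <- tabulate(findInterval(x, br, rightmost.closed = TRUE), nbins)
    mode_val <- (br[which.max(cnt)] + br[which.max(cnt) + 1L]) / 2
    p <- cnt[cnt > 0] / length(x)
    entropy <- -sum(p * log2(p))
  }
  if (is.na(v) || v <= 0) {
    skew <- NA_real_; kurt <- NA_real_
  } else {
    m2 <- mean((x - mu)^2)
    skew <- mean((x - mu)^3) / m2^1.5
    kurt <- mean((x - mu)^4) / m2^2 - 3
  }
  c(hist_mean = mu, hist_variance = if (is.na(v)) 0 else v,
    hist_median = med, hist_mode = mode_val,
    hist_skewness = skew, hist_kurtosis = kurt, hist_entropy = entropy)
}

#' Extract the full 80-dimensional tile feature vector
#'
#' Concatenates the six texture families in catalog order:
#' GLCM (20), Gabor (32), LBP (18), Tamura (3), lower-order histogram (4),
#' higher-order histogram (3).
#'
#' @param gray single-channel tile (numeric matrix), typically the
#'   hematoxylin concentration channel.
#' @return named numeric vector of length 80 (NA allowed where a
#'   statistic is undefined).
#' @export
extract_all <- function(gray) {
  h <- histogram_features(gray)
  v <- c(glcm_features(gray), gabor_features(gray), lbp_features(gray),
         tamura_features(gray),
         h[c("hist_mean", "hist_variance", "hist_median", "hist_mode")],
         h[c("hist_skewness", "hist_kurtosis", "hist_entropy")])
  stopifnot(length(v) == 80L)
  v
}

#' Feature exclusion rule
#'
#' Drops features that are all-zero across tiles, contain any NA, or
#' exactly duplicate an earlier-indexed retained feature's value vector
#' (keep-first ordering).
#'
#' @param mat numeric matrix, tiles x features (>= 2 rows).
#' @param collinear if TRUE also drop features with |Pearson r| = 1
#'   against an earlier retained feature.
#' @return list with `retained` (integer indices) and `dropped`
#'   (data.frame: index, reason).
#' @export
exclude_features <- function(mat, collinear = FALSE) {
  if (is.null(dim(mat)) || nrow(mat) < 2) stop("need a matrix with >= 2 rows")
  nf <- ncol(mat)
  retained <- integer(0)
  dropped_idx <- integer(0); dropped_reason <- character(0)
  for (j in seq_len(nf)) {
    col <- mat[, j]
    reason <- NULL
    if (anyNA(col)) reason <- "NA"
    else if (all(col == 0)) reason <- "all-zero"
    else {
      for (r in retained) {
        if (identical(all.equal(col, mat[, r], tolerance = 0), TRUE) ||
            all(col == mat[, r])) {
          reason <- sprintf("duplicate-of:%d", r); break
        }
        if (collinear && stats::sd(col) > 0 && stats::sd(mat[, r]) > 0 &&
            isTRUE(abs(suppressWarnings(stats::cor(col, mat[, r]))) == 1)) {
          reason <- sprintf("duplicate-of:%d", r); break
        }
      }
    }
    if (is.null(reason)) retained <- c(retained, j)
    else { dropped_idx <- c(dropped_idx, j); dropped_reason <- c(dropped_reason, reason) }
  }
  list(retained = retained,
       dropped = data.frame(index = dropped_idx, reason = dropped_reason,
                            stringsAsFactors = FALSE))
}
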