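# ReliefF feature importance weighting and top-n selection.

#' ReliefF importance weights
#'
#' Features are min-max normalized to [0, 1]. For every instance, the k
#' nearest same-class neighbors (hits) and k nearest opposite-class
#' neighbors (misses) are found under Manhattan distance on the
#' normalized features; each feature's weight accumulates
#' (mean miss difference - mean hit difference), averaged over
#' instances, so weights lie in [-1, 1]. With binary labels the
#' prior-weighted multi-class miss term reduces to the plain miss mean.
#' All instances are used (no subsampling), so the default is
#' deterministic; `seed` only matters when `sample_size` is set.
#'
#' @param X numeric matrix, instances x features (no NA).
#' @param y binary labels (two levels, any coding).
#' @param k_neighbors neighbors per class (default 10, capped at class
#'   size - 1).
#' @param sample_size optional number of instances to iterate over
#'   (default all).
#' @param seed seed for the optional subsample.
#' @return object of class `relieff_weights`: list(weights = named
#'   numeric, k_neighbors, n_iterations, seed).
#' @export
relieff_weights <- function(X, y, k_neighbors = 10L, sample_size = NULL,
                            seed = 1L) {
  X <- as.matrix(X)
  if (anyNA(X)) stop("NA values in the feature matrix")
  y <- as.character(y)
  lev <- unique(y)
  if (length(lev) != 2) stop("ReliefF here requires exactly two classes")
  if (min(table(y)) < 2) stop("each class needs >= 2 instances")
  m <- nrow(X); d <- ncol(X)
  rng <- apply(X, 2, range)
  span <- rng[2, ] - rng[1, ]
  span[span == 0] <- 1          # constant features contribute 0 everywhere
  Z <- sweep(sweep(X, 2, rng[1, ], "-"), 2, span, "/")
  iter <- seq_len(m)
  if (!is.null(sample_size) && sample_size < m)
    iter <- with_seed(seed, sort(sample.int(m, sample_size)))
  D <- as.matrix(stats::dist(Z, method = "manhattan"))
  w <- numeric(d)
  for (i in iter) {
    same <- which(y == y[i]); same <- setdiff(same, i)
    diff <- which(y != y[i])
    kh <- min(k_neighbors, length(same))
    km <- min(k_neighbors, length(diff))
    hits <- same[order(D[i, same], same)][seq_len(kh)]
    misses <- diff[order(D[i, diff], diff)][seq_len(km)]
    hit_diff <- colMeans(abs(Z[hits, , drop = FALSE] -
                               matrix(Z[i, ], kh, d, byrow = TRUE)))
    miss_diff <- colMeans(abs(Z[misses, , drop = FALSE] -
                                matrix(Z[i, ], km, d, byrow = TRUE)))
    w <- w + (miss_diff - hit_diff)
  }
  w <- w / length(iter)
  names(w) <- colnames(X)
  structure(list(weights = w, k_neighbors = k_neighbors,
                 n_iterations = length(iter), seed = seed),
            class = "relieff_weights")
}

#' @export
print.relieff_weights <- function(x, n = 10, ...) {
  cat("ReliefF weights over", length(x$weights), "features (k =",
      x$k_neighbors, ",", x$n_iterations, "iterations)\n")
  ord <- order(x$weights, decreasing = TRUE)
  print(utils::head(x$weights[ord], n))
  invisible(x)
}

#' Select the top-n features by importance weight
#'
#' @param weights `relieff_weights` or a plain numeric vector.
#' @param n_top how many to keep (default 8).
#' @return integer indices of the `n_top` largest weights, in descending
#'   weight order; ties break to the lower index.
#' @export
rank_and_select <- function(weights, n_top = 8L) {
  w <- if (inherits(weights, "relieff_weights")) weights$weights else weights
  if (n_top <= 0) stop("n_top must be positive")
  if (n_top > length(w)) stop("n_top exceeds the feature count")
  ord <- order(-w, seq_along(w))
  ord[seq_len(n_top)]
}

#' Per-pair maximum ReliefF weight
#'
#' Aggregates per-feature weights over named pair-feature columns
#' (`pairA_B.feature`) to one weight per histology class pair — the
#' granularity ranked in the selection figure of the source study.
#'
#' @param weights `relieff_weights` over [cohort_pair_features()] columns.
#' @return data.frame: pair, weight, sorted descending.
#' @export
pair_weight_table <- function(weights) {
  w <- weights$weights
  pair <- sub("\\..*$", "", names(w))
  agg <- tapply(w, pair, max)
  out <- data.frame(pair = names(agg), weight = as.numeric(agg),
                    stringsAsFactors = FALSE)
  out[order(-out$weight), , drop = FALSE]
}
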