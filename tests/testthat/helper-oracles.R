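# Independent reference implementations used to cross-check the package.
# These are deliberately naive (nested loops, exhaustive enumeration) and
# share no code with the implementations they verify.

# Brute-force symmetric GLCM statistics by explicit pair counting.
oracle_glcm <- function(q, levels, drow, dcol) {
  counts <- matrix(0, levels, levels)
  nr <- nrow(q); nc <- ncol(q)
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      r2 <- r + drow; c2 <- c + dcol
      if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc) {
        i <- q[r, c] + 1; j <- q[r2, c2] + 1
        counts[i, j] <- counts[i, j] + 1
        counts[j, i] <- counts[j, i] + 1
      }
    }
  }
  p <- counts / sum(counts)
  lv <- 0:(levels - 1)
  contrast <- 0; energy <- 0; homog <- 0; entropy <- 0
  for (i in seq_len(levels)) for (j in seq_len(levels)) {
    pij <- p[i, j]
    contrast <- contrast + pij * (lv[i] - lv[j])^2
    energy <- energy + pij^2
    homog <- homog + pij / (1 + (lv[i] - lv[j])^2)
    if (pij > 0) entropy <- entropy - pij * log2(pij)
  }
  mi <- sum(lv * rowSums(p)); mj <- sum(lv * colSums(p))
  vi <- sum((lv - mi)^2 * rowSums(p)); vj <- sum((lv - mj)^2 * colSums(p))
  corr <- if (vi <= 0 || vj <= 0) NA_real_ else {
    s <- 0
    for (i in seq_len(levels)) for (j in seq_len(levels))
      s <- s + p[i, j] * (lv[i] - mi) * (lv[j] - mj)
    s / sqrt(vi * vj)
  }
  c(contrast = contrast, correlation = corr, energy = energy,
    homogeneity = homog, entropy = entropy)
}

# Exhaustive minimum spanning tree: try every subset of n-1 edges of the
# complete graph and keep the cheapest connected one.
oracle_mst_total <- function(xy) {
  n <- nrow(xy)
  if (n < 2) return(0)
  edges <- t(utils::combn(n, 2))
  lens <- sqrt((xy[edges[, 1], 1] - xy[edges[, 2], 1])^2 +
                 (xy[edges[, 1], 2] - xy[edges[, 2], 2])^2)
  best <- Inf
  for (sel in utils::combn(nrow(edges), n - 1, simplify = FALSE)) {
    # union-find connectivity check
    parent <- seq_len(n)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    ok <- TRUE
    for (e in sel) {
      a <- find(edges[e, 1]); b <- find(edges[e, 2])
      if (a == b) { ok <- FALSE; break }
      parent[a] <- b
    }
    if (ok) best <- min(best, sum(lens[sel]))
  }
  best
}

# Naive ReliefF: explicit loops over instances and neighbor searches.
oracle_relieff <- function(X, y, k) {
  X <- as.matrix(X); y <- as.character(y)
  m <- nrow(X); d <- ncol(X)
  rng_lo <- apply(X, 2, min); rng_hi <- apply(X, 2, max)
  span <- rng_hi - rng_lo; span[span == 0] <- 1
  Z <- X
  for (j in seq_len(d)) Z[, j] <- (X[, j] - rng_lo[j]) / span[j]
  w <- numeric(d)
  for (i in seq_len(m)) {
    dist_i <- numeric(m)
    for (l in seq_len(m)) dist_i[l] <- sum(abs(Z[i, ] - Z[l, ]))
    same <- setdiff(which(y == y[i]), i)
    diff <- which(y != y[i])
    hits <- same[order(dist_i[same], same)][seq_len(min(k, length(same)))]
    misses <- diff[order(dist_i[diff], diff)][seq_len(min(k, length(diff)))]
    for (j in seq_len(d)) {
      w[j] <- w[j] + mean(abs(Z[misses, j] - Z[i, j])) -
        mean(abs(Z[hits, j] - Z[i, j]))
    }
  }
  w / m
}

# Breadth-first flood fill for connected components of one class.
oracle_components <- function(map, class_id) {
  nr <- nrow(map); nc <- ncol(map)
  seen <- matrix(FALSE, nr, nc)
  comps <- list()
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (map[r, c] == class_id && !seen[r, c]) {
      queue <- list(c(r, c)); seen[r, c] <- TRUE
      members <- matrix(numeric(0), ncol = 2)
      while (length(queue)) {
        cur <- queue[[1]]; queue <- queue[-1]
        members <- rbind(members, cur)
        for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
          rr <- cur[1] + d[1]; cc <- cur[2] + d[2]
          if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc &&
              map[rr, cc] == class_id && !seen[rr, cc]) {
            seen[rr, cc] <- TRUE
            queue[[length(queue) + 1]] <- c(rr, cc)
          }
        }
      }
      comps[[length(comps) + 1]] <- members
    }
  }
  comps
}

# All-pairs AUC with half-credit for ties.
oracle_auc <- function(scores, positive) {
  pos <- scores[positive]; neg <- scores[!positive]
  s <- 0
  for (p in pos) for (q in neg)
    s <- s + if (p > q) 1 else if (p == q) 0.5 else 0
  s / (length(pos) * length(neg))
}

# Naive uniform LBP histogram by per-pixel enumeration.
oracle_lbp <- function(gray, P = 16, R = 2) {
  nr <- nrow(gray); nc <- ncol(gray)
  m <- ceiling(R)
  bins <- integer(P + 2)
  bil <- function(rf, cf) {
    r0 <- min(floor(rf), nr - 1); c0 <- min(floor(cf), nc - 1)
    fr <- rf - r0; fc <- cf - c0
    gray[r0, c0] * (1 - fr) * (1 - fc) + gray[r0, c0 + 1] * (1 - fr) * fc +
      gray[r0 + 1, c0] * fr * (1 - fc) + gray[r0 + 1, c0 + 1] * fr * fc
  }
  for (r in (m + 1):(nr - m)) for (c in (m + 1):(nc - m)) {
    bits <- integer(P)
    for (p in seq_len(P)) {
      ang <- 2 * pi * (p - 1) / P
      dr <- -R * sin(ang); dc <- R * cos(ang)
      if (abs(dr) < 1e-9) dr <- 0
      if (abs(dc) < 1e-9) dc <- 0
      bits[p] <- as.integer(bil(r + dr, c + dc) >= gray[r, c] - 1e-9)
    }
    trans <- sum(bits != bits[c(2:P, 1)])
    b <- if (trans <= 2) sum(bits) else P + 1
    bins[b + 1] <- bins[b + 1] + 1
  }
  bins / sum(bins)
}

# Rasterized polygon-overlap tile retention: pixel-center sampling.
oracle_tile_retention <- function(polygon, image_extent, tile_size,
                                  min_overlap) {
  inside <- function(px, py) {
    n <- nrow(polygon); cnt <- FALSE
    j <- n
    for (i in seq_len(n)) {
      xi <- polygon[i, 1]; yi <- polygon[i, 2]
      xj <- polygon[j, 1]; yj <- polygon[j, 2]
      if ((yi > py) != (yj > py) &&
          px < (xj - xi) * (py - yi) / (yj - yi) + xi) cnt <- !cnt
      j <- i
    }
    cnt
  }
  ncols <- floor(image_extent[1] / tile_size)
  nrows <- floor(image_extent[2] / tile_size)
  kept <- matrix(numeric(0), ncol = 2)
  for (gr in seq_len(nrows) - 1) for (gc in seq_len(ncols) - 1) {
    hit <- 0
    for (py in gr * tile_size + seq_len(tile_size) - 0.5)
      for (px in gc * tile_size + seq_len(tile_size) - 0.5)
        if (inside(px, py)) hit <- hit + 1
    if (hit / tile_size^2 >= min_overlap) kept <- rbind(kept, c(gr, gc))
  }
  kept
}
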