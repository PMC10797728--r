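# Tumor-microenvironment graphs: connected tile clusters per histology
# class, geometric graphs over cluster centroids, spectral and
# minimum-spanning-tree features, and the 20-feature class-pair vector.

#' Connected tile clusters of one histology class
#'
#' 4-connected components (optionally 8-connected) of map cells carrying
#' `class_id`; each cluster's centroid is the mean of its member cell
#' centers, in tile units (x = column, y = row, 0-based cell origin so a
#' cell center is at (col - 0.5, row - 0.5) in 1-based matrix indexing).
#'
#' @param map integer label matrix.
#' @param class_id class to extract.
#' @param connectivity 4 (default) or 8.
#' @return list of clusters: `list(class_id, members = <m x 2 matrix of
#'   (row, col), 1-based>, centroid = c(x, y))`.
#' @export
extract_clusters <- function(map, class_id, connectivity = 4L) {
  stopifnot(connectivity %in% c(4L, 8L))
  nr <- nrow(map); nc <- ncol(map)
  lab <- matrix(0L, nr, nc)
  nextlab <- 0L
  offs <- if (connectivity == 4L)
    cbind(c(-1L, 1L, 0L, 0L), c(0L, 0L, -1L, 1L))
  else
    cbind(rep(c(-1L, 0L, 1L), each = 3)[-5], rep(c(-1L, 0L, 1L), 3)[-5])
  target <- map == class_id
  clusters <- list()
  for (start in which(target & lab == 0L)) {
    if (lab[start] != 0L) next
    nextlab <- nextlab + 1L
    stack <- start
    members <- integer(0)
    lab[start] <- nextlab
    while (length(stack)) {
      cur <- stack[length(stack)]; stack <- stack[-length(stack)]
      members <- c(members, cur)
      r <- (cur - 1L) %% nr + 1L; c <- (cur - 1L) %/% nr + 1L
      for (k in seq_len(nrow(offs))) {
        rr <- r + offs[k, 1]; cc <- c + offs[k, 2]
        if (rr >= 1L && rr <= nr && cc >= 1L && cc <= nc &&
            target[rr, cc] && lab[rr, cc] == 0L) {
          lab[rr, cc] <- nextlab
          stack <- c(stack, (cc - 1L) * nr + rr)
        }
      }
    }
    rows <- (members - 1L) %% nr + 1L
    cols <- (members - 1L) %/% nr + 1L
    clusters[[nextlab]] <- list(
      class_id = class_id,
      members = cbind(row = rows, col = cols),
      cells = members,
      centroid = c(x = mean(cols) - 0.5, y = mean(rows) - 0.5))
  }
  clusters
}

#' Build the geometric TME graph for a class pair
#'
#' Nodes are cluster centroids of both classes; an undirected, unweighted
#' edge joins two nodes iff their Euclidean distance is at most `radius`
#' (tile units). `cross_only = TRUE` restricts edges to cross-class
#' pairs.
#'
#' @param clusters_A,clusters_B cluster lists from [extract_clusters()].
#' @param radius edge radius (> 0).
#' @param cross_only logical (default FALSE: all pairs within radius).
#' @return object of class `tme_graph`: list(xy = n x 2 coords,
#'   class = per-node class id, edges = m x 2 index matrix, radius).
#' @export
build_geometric_graph <- function(clusters_A, clusters_B, radius,
                                  cross_only = FALSE) {
  stopifnot(radius > 0)
  cents <- rbind(
    do.call(rbind, lapply(clusters_A, function(cl) cl$centroid)),
    do.call(rbind, lapply(clusters_B, function(cl) cl$centroid)))
  cls <- c(vapply(clusters_A, function(cl) cl$class_id, 0L),
           vapply(clusters_B, function(cl) cl$class_id, 0L))
  n <- length(cls)
  edges <- matrix(integer(0), ncol = 2)
  if (n >= 2) {
    d <- as.matrix(stats::dist(cents))
    adj <- d <= radius
    adj[lower.tri(adj, diag = TRUE)] <- FALSE
    if (cross_only) {
      same <- outer(cls, cls, "==")
      adj[same] <- FALSE
    }
    idx <- which(adj, arr.ind = TRUE)
    edges <- unname(idx)
  }
  structure(list(xy = cents, class = cls, edges = edges, radius = radius),
            class = "tme_graph")
}

tme_to_igraph <- function(g) {
  ig <- igraph::make_empty_graph(n = nrow(g$xy), directed = FALSE)
  if (nrow(g$edges) > 0) ig <- igraph::add_edges(ig, t(g$edges))
  ig
}

#' Spectral / local node features of a TME graph
#'
#' Seven statistics: mean degree, degree variance, mean local clustering
#' coefficient (isolated or degree-1 nodes count 0), adjacency spectral
#' radius, algebraic connectivity (second-smallest Laplacian eigenvalue;
#' 0 for disconnected or trivial graphs), normalized Laplacian energy
#' (mean squared deviation of the normalized-Laplacian spectrum from 1),
#' and the fraction of edges joining the two classes.
#'
#' @param g `tme_graph`.
#' @return named numeric vector of length 7 (all 0 for an empty node set).
#' @export
spectral_node_features <- function(g) {
  nm <- c("mean_degree", "degree_variance", "mean_clustering",
          "spectral_radius", "algebraic_connectivity",
          "norm_laplacian_energy", "cross_class_edge_fraction")
  n <- nrow(g$xy)
  out <- stats::setNames(numeric(7), nm)
  if (is.null(n) || n == 0) return(out)
  A <- matrix(0, n, n)
  if (nrow(g$edges) > 0) {
    A[g$edges] <- 1
    A[g$edges[, c(2, 1), drop = FALSE]] <- 1
  }
  deg <- rowSums(A)
  out["mean_degree"] <- mean(deg)
  out["degree_variance"] <- mean((deg - mean(deg))^2)
  # local clustering: triangles / possible neighbor pairs
  cc <- numeric(n)
  for (i in which(deg >= 2)) {
    nb <- which(A[i, ] > 0)
    cc[i] <- sum(A[nb, nb]) / (length(nb) * (length(nb) - 1))
  }
  out["mean_clustering"] <- mean(cc)
  if (n >= 2) {
    evA <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
    out["spectral_radius"] <- max(abs(evA))
    L <- diag(deg) - A
    evL <- sort(eigen(L, symmetric = TRUE, only.values = TRUE)$values)
    out["algebraic_connectivity"] <- max(0, evL[2])
    dh <- ifelse(deg > 0, 1 / sqrt(deg), 0)
    Ln <- diag(ifelse(deg > 0, 1, 0)) - (dh %o% dh) * A
    evN <- eigen(Ln, symmetric = TRUE, only.values = TRUE)$values
    out["norm_laplacian_energy"] <- mean((evN - 1)^2)
  }
  if (nrow(g$edges) > 0) {
    cross <- g$class[g$edges[, 1]] != g$class[g$edges[, 2]]
    out["cross_class_edge_fraction"] <- mean(cross)
  }
  out
}

# Euclidean MST edge lengths over a coordinate matrix (Prim's algorithm).
mst_edge_lengths <- function(xy) {
  n <- nrow(xy)
  if (n < 2) return(numeric(0))
  d <- as.matrix(stats::dist(xy))
  intree <- c(TRUE, rep(FALSE, n - 1))
  best <- d[1, ]
  lens <- numeric(0)
  for (step in seq_len(n - 1)) {
    cand <- which(!intree)
    j <- cand[which.min(best[cand])]
    lens <- c(lens, best[j])
    intree[j] <- TRUE
    best <- pmin(best, d[j, ])
  }
  lens
}

#' Global / MST features of a class-pair node set
#'
#' Six statistics from the Euclidean minimum spanning tree over all
#' nodes and the geometric graph's component structure: MST total length
#' normalized by the map diagonal, mean, sd, and max MST edge length,
#' the geometric graph's connected-component count as a fraction of the
#' node count, and the mean cross-class nearest-neighbor distance
#' (averaged over both directions). A single node yields zeros.
#'
#' @param g `tme_graph` (supplies nodes, classes and components).
#' @param map_diagonal diagonal of the map in tile units.
#' @return named numeric vector of length 6.
#' @export
mst_features <- function(g, map_diagonal) {
  nm <- c("mst_total_norm", "mst_mean_edge", "mst_sd_edge", "mst_max_edge",
          "component_fraction", "cross_class_nn_dist")
  out <- stats::setNames(numeric(6), nm)
  n <- nrow(g$xy)
  if (is.null(n) || n < 2) return(out)
  lens <- mst_edge_lengths(g$xy)
  out["mst_total_norm"] <- sum(lens) / map_diagonal
  out["mst_mean_edge"] <- mean(lens)
  out["mst_sd_edge"] <- if (length(lens) > 1) stats::sd(lens) else 0
  out["mst_max_edge"] <- max(lens)
  comp <- igraph::components(tme_to_igraph(g))$no
  out["component_fraction"] <- comp / n
  ia <- g$class == g$class[1]
  if (any(ia) && any(!ia)) {
    d <- as.matrix(stats::dist(g$xy))
    dab <- d[ia, !ia, drop = FALSE]
    out["cross_class_nn_dist"] <- mean(c(apply(dab, 1, min),
                                         apply(dab, 2, min)))
  }
  out
}

#' The 20 spatial features of one histology class pair
#'
#' Texture block (7): mean GLCM contrast, mean GLCM homogeneity (each
#' averaged over the four offsets), and mean histogram entropy over
#' member tiles of class-A clusters and class-B clusters (6), plus the
#' node count ratio |A| / (|A| + |B|). Spectral block (7) and global MST
#' block (6) as in [spectral_node_features()] and [mst_features()].
#' Class slots are keyed by the lower class id first, so the vector is
#' invariant to argument order.
#'
#' @param map integer label matrix.
#' @param tile_features per-cell feature matrix (rows in the map's
#'   column-major cell order, catalog-named columns), or NULL to zero
#'   the texture averages.
#' @param class_A,class_B class ids.
#' @param radius geometric-graph edge radius (default 8 tile widths).
#' @param connectivity cluster connectivity (default 4).
#' @param cross_only edge mode (default FALSE).
#' @return named numeric vector of length 20 with attribute `valid`
#'   (FALSE and all-zero when either class is absent from the map).
#' @export
pair_features <- function(map, tile_features, class_A, class_B,
                          radius = 8, connectivity = 4L,
                          cross_only = FALSE) {
  if (class_A > class_B) { tmp <- class_A; class_A <- class_B; class_B <- tmp }
  nm <- pair_feature_names()
  cl_A <- extract_clusters(map, class_A, connectivity)
  cl_B <- extract_clusters(map, class_B, connectivity)
  if (length(cl_A) == 0 || length(cl_B) == 0) {
    out <- stats::setNames(numeric(20), nm)
    attr(out, "valid") <- FALSE
    return(out)
  }
  tex <- function(clusters) {
    if (is.null(tile_features)) return(c(0, 0, 0))
    cells <- unlist(lapply(clusters, `[[`, "cells"))
    f <- tile_features[cells, , drop = FALSE]
    contrast_cols <- grep("^glcm_contrast_", colnames(f))
    homog_cols <- grep("^glcm_homogeneity_", colnames(f))
    c(mean(f[, contrast_cols]), mean(f[, homog_cols]),
      mean(f[, "hist_entropy"]))
  }
  g <- build_geometric_graph(cl_A, cl_B, radius, cross_only)
  diagd <- sqrt(nrow(map)^2 + ncol(map)^2)
  nA <- length(cl_A); nB <- length(cl_B)
  out <- c(tex(cl_A), tex(cl_B), nA / (nA + nB),
           spectral_node_features(g), mst_features(g, diagd))
  names(out) <- nm
  attr(out, "valid") <- TRUE
  out
}

#' Pair-feature matrix for a set of patients
#'
#' Computes the 20 features for every unordered pair of the given
#' classes for each patient, concatenated into one row per patient with
#' `pairA_B.feature` column names.
#'
#' @param patients list of patients (`label_map`, `tile_features`).
#' @param classes class ids to pair (background never included).
#' @param radius,connectivity,cross_only passed to [pair_features()].
#' @return numeric matrix, patients x (n_pairs * 20), with an
#'   `outcome` attribute when patients carry outcomes.
#' @export
cohort_pair_features <- function(patients, classes, radius = 8,
                                 connectivity = 4L, cross_only = FALSE) {
  classes <- sort(setdiff(as.integer(classes), background_sentinel()))
  prs <- utils::combn(classes, 2)
  fn <- pair_feature_names()
  cn <- as.vector(apply(prs, 2, function(p)
    sprintf("pair%d_%d.%s", p[1], p[2], fn)))
  X <- matrix(0, length(patients), length(cn),
              dimnames = list(vapply(patients, `[[`, "", "patient_id"), cn))
  for (i in seq_along(patients)) {
    p <- patients[[i]]
    row <- numeric(0)
    for (j in seq_len(ncol(prs))) {
      row <- c(row, pair_features(p$label_map, p$tile_features,
                                  prs[1, j], prs[2, j], radius,
                                  connectivity, cross_only))
    }
    X[i, ] <- row
  }
  if (!is.null(patients[[1]]$outcome))
    attr(X, "outcome") <- vapply(patients, `[[`, "", "outcome")
  X
}
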