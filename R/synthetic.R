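# Synthetic data: class-conditional tile textures, spatially coherent
# label maps, and outcome-linked cohorts with a planted spatial signal.

# Evaluate expr under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Class-conditional texture parameters
#'
#' Parameters of the generative texture model for one histology class:
#' a Gaussian random field (spectral filtering of white noise) with the
#' given correlation length and anisotropy, nucleus disks, and two-stain
#' optical-density mixing.
#'
#' @param class_id integer class id.
#' @param correlation_length field correlation length in pixels (> 0).
#' @param anisotropy_angle radians; direction in which the field is
#'   stretched.
#' @param anisotropy_ratio >= 1; 1 = isotropic.
#' @param nucleus_density nuclei per tile (>= 0).
#' @param nucleus_radius_mean,nucleus_radius_sd nucleus radius (pixels).
#' @param hematoxylin_level,eosin_level mean stain OD levels (>= 0).
#' @return object of class `class_texture_params`.
#' @export
class_texture_params <- function(class_id, correlation_length = 4,
                                 anisotropy_angle = 0, anisotropy_ratio = 1,
                                 nucleus_density = 100,
                                 nucleus_radius_mean = 3,
                                 nucleus_radius_sd = 0.5,
                                 hematoxylin_level = 0.6,
                                 eosin_level = 0.3) {
  stopifnot(correlation_length > 0, nucleus_density >= 0,
            hematoxylin_level >= 0, eosin_level >= 0, anisotropy_ratio >= 1)
  structure(list(class_id = as.integer(class_id),
                 correlation_length = correlation_length,
                 anisotropy_angle = anisotropy_angle,
                 anisotropy_ratio = anisotropy_ratio,
                 nucleus_density = nucleus_density,
                 nucleus_radius_mean = nucleus_radius_mean,
                 nucleus_radius_sd = nucleus_radius_sd,
                 hematoxylin_level = hematoxylin_level,
                 eosin_level = eosin_level),
            class = "class_texture_params")
}

#' Default synthetic class parameter sets
#'
#' Four classes with distinct second-order statistics, keyed to ids of
#' the histology catalog: stroma (0; long-range anisotropic fibers, few
#' nuclei), tumor (1; mid-scale, dense nuclei), PGCC (5; coarse field,
#' sparse very large nuclei), tTIL (10; fine-scale, very dense small
#' nuclei).
#'
#' @return named list of `class_texture_params` (names = class ids).
#' @export
default_texture_params <- function() {
  p <- list(
    class_texture_params(0L, correlation_length = 16, anisotropy_angle = pi / 4,
                         anisotropy_ratio = 3, nucleus_density = 30,
                         nucleus_radius_mean = 2.5, hematoxylin_level = 0.35,
                         eosin_level = 0.55),
    class_texture_params(1L, correlation_length = 6, nucleus_density = 150,
                         nucleus_radius_mean = 4, nucleus_radius_sd = 0.8,
                         hematoxylin_level = 0.75, eosin_level = 0.30),
    class_texture_params(5L, correlation_length = 10, nucleus_density = 12,
                         nucleus_radius_mean = 9, nucleus_radius_sd = 1.5,
                         hematoxylin_level = 0.55, eosin_level = 0.40),
    class_texture_params(10L, correlation_length = 2, nucleus_density = 350,
                         nucleus_radius_mean = 2, nucleus_radius_sd = 0.3,
                         hematoxylin_level = 0.90, eosin_level = 0.15))
  names(p) <- vapply(p, function(x) as.character(x$class_id), "")
  p
}

# Gaussian random field on an nr x nc grid: white noise filtered in the
# frequency domain with an (anisotropic) Gaussian spectrum, standardized
# to zero mean / unit sd.
gaussian_random_field <- function(nr, nc, corr_len, angle = 0, ratio = 1) {
  wn <- matrix(stats::rnorm(nr * nc), nr, nc)
  fr <- c(0:(nr %/% 2), -((ceiling(nr / 2) - 1):1)) / nr
  fc <- c(0:(nc %/% 2), -((ceiling(nc / 2) - 1):1)) / nc
  KR <- matrix(fr, nr, nc)        # frequency along rows (y)
  KC <- matrix(fc, nr, nc, byrow = TRUE)  # along cols (x)
  ka <- KC * cos(angle) + KR * sin(angle)
  kb <- -KC * sin(angle) + KR * cos(angle)
  la <- corr_len * ratio; lb <- corr_len
  spec <- exp(-2 * pi^2 * ((ka * la)^2 + (kb * lb)^2))
  f <- Re(stats::fft(stats::fft(wn) * spec, inverse = TRUE)) / (nr * nc)
  s <- stats::sd(as.vector(f))
  if (s > 0) f <- (f - mean(f)) / s
  f
}

#' Generate one synthetic H&E tile for a class
#'
#' Renders a stain mixture: per-pixel OD = H-vector * c_H + E-vector *
#' c_E, exponentiated to RGB intensities. The hematoxylin concentration
#' is a Gaussian random field at the class correlation length plus
#' anti-aliased nucleus disks; eosin is an independent field.
#' Deterministic for a given (params, seed).
#'
#' @param params `class_texture_params`.
#' @param seed integer seed.
#' @param size tile side in pixels (default 224).
#' @return RGB array `size x size x 3`, intensities in 0..255.
#' @export
generate_class_tile <- function(params, seed, size = 224L) {
  stopifnot(inherits(params, "class_texture_params"))
  with_seed(seed, {
    fH <- gaussian_random_field(size, size, params$correlation_length,
                                params$anisotropy_angle, params$anisotropy_ratio)
    fE <- gaussian_random_field(size, size, params$correlation_length,
                                params$anisotropy_angle, params$anisotropy_ratio)
    cH <- params$hematoxylin_level * pmax(0.5 + 0.25 * fH, 0)
    cE <- params$eosin_level * pmax(0.5 + 0.25 * fE, 0)
    n_nuc <- as.integer(params$nucleus_density)
    if (n_nuc > 0) {
      cx <- stats::runif(n_nuc, 1, size)
      cy <- stats::runif(n_nuc, 1, size)
      rad <- pmax(1, stats::rnorm(n_nuc, params$nucleus_radius_mean,
                                  params$nucleus_radius_sd))
      add <- max(params$hematoxylin_level, 0.2) * 1.2
      for (i in seq_len(n_nuc)) {
        r0 <- max(1L, floor(cy[i] - rad[i] - 1)); r1 <- min(size, ceiling(cy[i] + rad[i] + 1))
        c0 <- max(1L, floor(cx[i] - rad[i] - 1)); c1 <- min(size, ceiling(cx[i] + rad[i] + 1))
        rr <- r0:r1; cc <- c0:c1
        d <- sqrt(outer((rr - cy[i])^2, (cc - cx[i])^2, "+"))
        cover <- pmin(pmax(rad[i] - d + 0.5, 0), 1)  # anti-aliased disk
        cH[rr, cc] <- cH[rr, cc] + add * cover
      }
    }
    M <- default_stain_matrix()
    od <- cbind(as.vector(cH), as.vector(cE)) %*% t(M)
    array(od_to_rgb(od), dim = c(size, size, 3))
  })
}

#' Generate a spatially coherent multi-class label map
#'
#' Each cell gets the argmax over per-class smoothed Gaussian noise
#' fields scaled by the class weights. Optionally, the cells with the
#' lowest values of an extra tissue field become background sentinel.
#'
#' @param class_mixing named nonnegative weights (names = class ids).
#' @param map_shape `c(rows, cols)`.
#' @param smoothness field correlation length in cells (default 4).
#' @param seed integer seed.
#' @param background_frac fraction of cells turned into background
#'   sentinel (default 0).
#' @return integer matrix of class ids (background = [background_sentinel()]).
#' @export
generate_label_map <- function(class_mixing, map_shape, smoothness = 4,
                               seed = 1L, background_frac = 0) {
  if (any(map_shape < 1)) stop("degenerate map shape")
  w <- unlist(class_mixing)
  if (any(w < 0) || all(w == 0)) stop("weights must be nonnegative, not all zero")
  ids <- as.integer(names(w))
  if (anyNA(ids)) stop("class_mixing must be named by integer class ids")
  keep <- w > 0
  ids <- ids[keep]; w <- w[keep]
  nr <- map_shape[1]; nc <- map_shape[2]
  with_seed(seed, {
    if (length(ids) == 1L) {
      m <- matrix(ids, nr, nc)
    } else {
      scores <- array(NA_real_, c(nr, nc, length(ids)))
      for (k in seq_along(ids))
        scores[, , k] <- w[k] * gaussian_random_field(nr, nc, smoothness)
      m <- matrix(ids[apply(scores, c(1, 2), which.max)], nr, nc)
    }
    if (background_frac > 0) {
      tf <- gaussian_random_field(nr, nc, smoothness)
      thr <- stats::quantile(tf, background_frac, names = FALSE)
      m[tf <= thr] <- background_sentinel()
    }
    m
  })
}

#' Interface statistic of a class pair
#'
#' Count of 4-adjacent cell pairs with one cell of each planted class,
#' normalized by map area (cells).
#'
#' @param map integer label matrix.
#' @param pair length-2 vector of class ids.
#' @return numeric scalar.
#' @export
interface_statistic <- function(map, pair) {
  a <- pair[1]; b <- pair[2]
  nr <- nrow(map); nc <- ncol(map)
  h <- 0; v <- 0
  if (nc > 1) {
    L <- map[, -nc, drop = FALSE]; R <- map[, -1, drop = FALSE]
    h <- sum((L == a & R == b) | (L == b & R == a))
  }
  if (nr > 1) {
    U <- map[-nr, , drop = FALSE]; D <- map[-1, , drop = FALSE]
    v <- sum((U == a & D == b) | (U == b & D == a))
  }
  (h + v) / (nr * nc)
}

#' Cohort configuration
#'
#' @param n_patients cohort size (default 60).
#' @param prevalence_pCR fraction of pCR outcomes (default 0.5).
#' @param map_shape label-map grid `c(rows, cols)` (default 80 x 80).
#' @param class_mixing named weights over class ids. The default gives
#'   the tTIL class (id 10) weight 0: tumor-infiltrating lymphocytes do
#'   not form independent tissue regions, they appear only as the
#'   planted infiltrates inside tumor areas, so the planted interface
#'   statistic is built exactly from zero baseline.
#' @param planted_pair two distinct class ids whose interface density is
#'   outcome-linked (default tumor/tTIL, ids 1 and 10).
#' @param effect_size standardized group difference of the planted
#'   interface statistic (default 2).
#' @param smoothness label-map field correlation length (default 4 cells).
#' @param interface_sigma within-group sd of the planted statistic, in
#'   interface pairs per cell (default 0.01).
#' @param background_frac background fraction of map cells (default 0).
#' @param seed integer seed.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 60L, prevalence_pCR = 0.5,
                          map_shape = c(80L, 80L),
                          class_mixing = c(`0` = 1, `1` = 1.3, `5` = 0.8,
                                           `10` = 0),
                          planted_pair = c(1L, 10L), effect_size = 2,
                          smoothness = 4, interface_sigma = 0.01,
                          background_frac = 0, seed = 1L) {
  stopifnot(prevalence_pCR >= 0, prevalence_pCR <= 1, effect_size >= 0,
            planted_pair[1] != planted_pair[2])
  structure(list(n_patients = as.integer(n_patients),
                 prevalence_pCR = prevalence_pCR, map_shape = map_shape,
                 class_mixing = class_mixing,
                 planted_pair = as.integer(planted_pair),
                 effect_size = effect_size, smoothness = smoothness,
                 interface_sigma = interface_sigma,
                 background_frac = background_frac, seed = as.integer(seed)),
            class = "cohort_config")
}

# Cache of per-class tile feature statistics (mean, sd of the 80
# features over a small sample of generated tiles).
.tmegraph_cache <- new.env(parent = emptyenv())

#' Class-conditional tile feature statistics
#'
#' Mean and sd of the 80 texture features per class, estimated from
#' `n_ref` actually generated tiles per class (features computed on the
#' deconvolved hematoxylin channel). Memoized per (params, n_ref, size).
#'
#' @param params_list named list of `class_texture_params`.
#' @param n_ref tiles per class (default 6).
#' @param size tile side (default 224).
#' @return list with `mean` and `sd` matrices (classes x 80; rownames =
#'   class ids).
#' @export
class_feature_stats <- function(params_list = default_texture_params(),
                                n_ref = 6L, size = 224L) {
  key <- paste0("stats_", digest_params(params_list), "_", n_ref, "_", size)
  if (!is.null(.tmegraph_cache[[key]])) return(.tmegraph_cache[[key]])
  mu <- matrix(NA_real_, length(params_list), 80,
               dimnames = list(names(params_list), feature_catalog()$name))
  sdev <- mu
  for (k in seq_along(params_list)) {
    p <- params_list[[k]]
    feats <- t(vapply(seq_len(n_ref), function(i) {
      tile <- generate_class_tile(p, seed = 10000L * p$class_id + i, size = size)
      extract_all(hematoxylin_channel(tile))
    }, numeric(80)))
    mu[k, ] <- colMeans(feats)
    sdev[k, ] <- apply(feats, 2, stats::sd)
  }
  sdev[is.na(sdev)] <- 0
  sdev <- pmax(sdev, abs(mu) * 0.01 + 1e-6)
  out <- list(mean = mu, sd = sdev)
  .tmegraph_cache[[key]] <- out
  out
}

digest_params <- function(params_list) {
  v <- unlist(lapply(params_list, function(p) unlist(p)))
  paste(format(sum(v * seq_along(v)), digits = 12), length(v), sep = "_")
}

# Convert interior cells of class `from` into class `to` one at a time;
# each accepted flip has all four neighbors of class `from`, so it adds
# exactly 4 interface pairs. Returns the modified map (or errors if the
# map runs out of eligible cells).
plant_interface <- function(map, from, to, k_flips) {
  if (k_flips <= 0) return(map)
  nr <- nrow(map); nc <- ncol(map)
  done <- 0L
  cand <- which(map == from)
  cand <- cand[sample.int(length(cand))]
  for (idx in cand) {
    r <- (idx - 1L) %% nr + 1L; c <- (idx - 1L) %/% nr + 1L
    if (r == 1L || r == nr || c == 1L || c == nc) next
    if (map[r - 1L, c] == from && map[r + 1L, c] == from &&
        map[r, c - 1L] == from && map[r, c + 1L] == from) {
      map[r, c] <- to
      done <- done + 1L
      if (done >= k_flips) break
    }
  }
  if (done < k_flips)
    warning("planted only ", done, " of ", k_flips, " interface flips")
  map
}

#' Generate a synthetic patient cohort with a planted spatial signal
#'
#' Outcomes are drawn at `prevalence_pCR`. Each patient gets a spatially
#' coherent label map; the planted pair's interface statistic is then
#' raised by converting isolated interior cells of the first planted
#' class into the second until it reaches a per-patient target drawn
#' from N(mu_group, interface_sigma), with group means separated by
#' `effect_size * interface_sigma`. Per-cell tile features are drawn from
#' class-conditional Gaussians whose moments come from actually generated
#' tiles ([class_feature_stats()]).
#'
#' @param config `cohort_config`.
#' @param tile_features logical; draw the per-cell 80-feature matrices
#'   (default TRUE).
#' @param params_list texture parameter sets (default
#'   [default_texture_params()]).
#' @return list of patients, each
#'   `list(patient_id, outcome, label_map, tile_features)`; the feature
#'   matrix rows follow the label map's column-major cell order.
#' @export
generate_cohort <- function(config = cohort_config(), tile_features = TRUE,
                            params_list = default_texture_params()) {
  n <- config$n_patients
  if (n == 0) return(list())
  with_seed(config$seed, {
    outcome <- ifelse(stats::runif(n) < config$prevalence_pCR, "pCR", "RD")
    if (config$effect_size > 0 &&
        (sum(outcome == "pCR") < 2 || sum(outcome == "RD") < 2))
      stop("need >= 2 patients per outcome group when effect_size > 0")
    maps <- vector("list", n)
    i0 <- numeric(n)
    seeds <- sample.int(.Machine$integer.max, n)
    for (i in seq_len(n)) {
      maps[[i]] <- generate_label_map(config$class_mixing, config$map_shape,
                                      config$smoothness, seed = seeds[i],
                                      background_frac = config$background_frac)
      i0[i] <- interface_statistic(maps[[i]], config$planted_pair)
    }
    area <- prod(config$map_shape)
    sg <- config$interface_sigma
    base <- max(i0) + 3 * sg
    eta <- pmin(pmax(stats::rnorm(n, 0, sg), -3 * sg), 3 * sg)
    target <- base + eta + ifelse(outcome == "pCR",
                                  config$effect_size * sg, 0)
    stats_cache <- if (tile_features) class_feature_stats(params_list) else NULL
    patients <- vector("list", n)
    for (i in seq_len(n)) {
      k <- round((target[i] - i0[i]) * area / 4)
      m <- plant_interface(maps[[i]], config$planted_pair[1],
                           config$planted_pair[2], k)
      feats <- NULL
      if (tile_features) {
        cls <- as.character(as.vector(m))
        ridx <- match(cls, rownames(stats_cache$mean))
        nf <- ncol(stats_cache$mean)
        feats <- matrix(0, length(cls), nf,
                        dimnames = list(NULL, colnames(stats_cache$mean)))
        ok <- !is.na(ridx)
        noise <- matrix(stats::rnorm(sum(ok) * nf), sum(ok), nf)
        feats[ok, ] <- stats_cache$mean[ridx[ok], , drop = FALSE] +
          stats_cache$sd[ridx[ok], , drop = FALSE] * noise
      }
      patients[[i]] <- list(patient_id = sprintf("P%03d", i),
                            outcome = outcome[i], label_map = m,
                            tile_features = feats)
    }
    patients
  })
}

#' Write a synthetic cohort to disk
#'
#' Per-patient paletted label-map PNG (class ids mapped to gray levels),
#' a tile-feature CSV per patient (when present), and a cohort manifest
#' JSON (ids, outcomes, config echo).
#'
#' @param patients list from [generate_cohort()].
#' @param dir output directory (created).
#' @param config the `cohort_config` used (echoed in the manifest).
#' @return invisibly, the manifest path.
#' @export
write_cohort <- function(patients, dir, config = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (p in patients) {
    m <- p$label_map
    img <- (m - min(m)) / max(1, max(m) - min(m))
    png::writePNG(img, file.path(dir, paste0(p$patient_id, "_map.png")))
    if (!is.null(p$tile_features))
      utils::write.csv(p$tile_features,
                       file.path(dir, paste0(p$patient_id, "_features.csv")),
                       row.names = FALSE)
  }
  manifest <- list(
    patients = data.frame(
      patient_id = vapply(patients, `[[`, "", "patient_id"),
      outcome = vapply(patients, `[[`, "", "outcome"),
      stringsAsFactors = FALSE),
    config = if (is.null(config)) NULL else unclass(config))
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
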