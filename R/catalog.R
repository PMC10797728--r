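# Feature and class catalogs shared across the pipeline.

#' Tile texture feature catalog
#'
#' The tile-level feature vector has 80 entries drawn from six texture
#' families computed on the (single-channel) hematoxylin image:
#' \itemize{
#'   \item GLCM (20): contrast, correlation, energy, homogeneity, entropy
#'     at each of four offsets (0, 45, 90, 135 degrees, distance 1);
#'   \item Gabor (32): mean and standard deviation of the response
#'     magnitude of 4 frequencies x 4 orientations;
#'   \item LBP (18): normalized histogram over the P + 2 = 18 uniform
#'     rotation-invariant pattern bins (P = 16, R = 2);
#'   \item Tamura (3): coarseness, contrast, directionality;
#'   \item lower-order histogram (4): mean, variance, median, mode;
#'   \item higher-order histogram (3): skewness, kurtosis, entropy.
#' }
#'
#' @param gabor_frequencies numeric vector of spatial frequencies
#'   (cycles/pixel) for the Gabor bank.
#' @param gabor_orientations numeric vector of orientations in radians.
#' @return A data.frame with columns `name` and `family`, 80 rows.
#' @export
feature_catalog <- function(gabor_frequencies = c(0.05, 0.1, 0.2, 0.4),
                            gabor_orientations = c(0, 45, 90, 135) * pi / 180) {
  glcm_angles <- c(0, 45, 90, 135)
  glcm_stats <- c("contrast", "correlation", "energy", "homogeneity", "entropy")
  glcm <- as.vector(t(outer(glcm_angles, glcm_stats,
                            function(a, s) sprintf("glcm_%s_a%d", s, a))))
  gab <- character(0)
  for (f in seq_along(gabor_frequencies))
    for (o in seq_along(gabor_orientations))
      gab <- c(gab, sprintf("gabor_f%d_o%d_mean", f, o),
               sprintf("gabor_f%d_o%d_sd", f, o))
  lbp <- sprintf("lbp_u%02d", 0:17)
  tam <- c("tamura_coarseness", "tamura_contrast", "tamura_directionality")
  lo <- c("hist_mean", "hist_variance", "hist_median", "hist_mode")
  hi <- c("hist_skewness", "hist_kurtosis", "hist_entropy")
  data.frame(
    name = c(glcm, gab, lbp, tam, lo, hi),
    family = rep(c("GLCM", "Gabor", "LBP", "Tamura", "HistLow", "HistHigh"),
                 times = c(length(glcm), length(gab), length(lbp),
                           length(tam), length(lo), length(hi))),
    stringsAsFactors = FALSE
  )
}

#' Histology class catalog
#'
#' The 16 histology classes of interest plus a separately labeled
#' background class (id 16). Background tiles are classified when enabled
#' but never become tumor-microenvironment graph nodes.
#'
#' @return A data.frame with columns `class_id` (0-based) and `name`.
#' @export
histology_classes <- function() {
  data.frame(
    class_id = 0:16,
    name = c("stroma", "tumor", "teTIL", "sTIL", "normal", "PGCC",
             "blood_vessel", "necrosis", "microvessel", "benign_tumor",
             "tTIL", "in_situ_carcinoma", "hemorrhage", "adipocytes",
             "apocrine_change", "mucinous_change", "background"),
    stringsAsFactors = FALSE
  )
}

#' Background sentinel class id
#'
#' Map cells with no retained tile, and tiles whose mean optical density
#' falls below the tissue threshold, carry this class id.
#' @return integer sentinel (-1L)
#' @export
background_sentinel <- function() -1L

#' Names of the 20 per-class-pair spatial features
#'
#' Three blocks: texture averages over cluster-member tiles of each class
#' (GLCM contrast, GLCM homogeneity, histogram entropy; 6) plus the node
#' count ratio (1); spectral node statistics of the geometric graph (7);
#' minimum-spanning-tree / global connectivity statistics (6).
#'
#' @return character vector of length 20.
#' @export
pair_feature_names <- function() {
  c("texA_glcm_contrast", "texA_glcm_homogeneity", "texA_hist_entropy",
    "texB_glcm_contrast", "texB_glcm_homogeneity", "texB_hist_entropy",
    "node_count_ratio",
    "mean_degree", "degree_variance", "mean_clustering",
    "spectral_radius", "algebraic_connectivity",
    "norm_laplacian_energy", "cross_class_edge_fraction",
    "mst_total_norm", "mst_mean_edge", "mst_sd_edge", "mst_max_edge",
    "component_fraction", "cross_class_nn_dist")
}
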