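# Serialization helpers: graphs, maps, feature and weight tables.

#' Export a TME graph as node and edge CSV files
#'
#' @param g `tme_graph`.
#' @param prefix path prefix; writes `<prefix>_nodes.csv`
#'   (id, class, x, y) and `<prefix>_edges.csv` (from, to).
#' @return invisibly, the two paths.
#' @export
write_tme_graph <- function(g, prefix) {
  nodes <- data.frame(id = seq_len(nrow(g$xy)), class = g$class,
                      x = g$xy[, 1], y = g$xy[, 2])
  edges <- data.frame(from = g$edges[, 1], to = g$edges[, 2])
  pn <- paste0(prefix, "_nodes.csv"); pe <- paste0(prefix, "_edges.csv")
  utils::write.csv(nodes, pn, row.names = FALSE)
  utils::write.csv(edges, pe, row.names = FALSE)
  invisible(c(pn, pe))
}

#' Serialize a histology map as a paletted PNG plus a JSON legend
#'
#' Class ids are mapped to distinct colors; the legend records
#' id, name (when in the catalog) and RGB per class. Background
#' sentinel renders white.
#'
#' @param map integer label matrix.
#' @param path PNG output path; the legend goes to `<path>.legend.json`.
#' @param catalog class catalog (default [histology_classes()]).
#' @return invisibly, the PNG path.
#' @export
write_map_png <- function(map, path, catalog = histology_classes()) {
  ids <- sort(setdiff(unique(as.vector(map)), background_sentinel()))
  hues <- grDevices::hcl(h = seq(15, 375, length.out = length(ids) + 1)[
    seq_along(ids)], c = 80, l = 60)
  rgbm <- grDevices::col2rgb(hues) / 255
  img <- array(1, dim = c(nrow(map), ncol(map), 3))
  for (k in seq_along(ids)) {
    cells <- map == ids[k]
    for (ch in 1:3) {
      plane <- img[, , ch]; plane[cells] <- rgbm[ch, k]; img[, , ch] <- plane
    }
  }
  png::writePNG(img, path)
  legend <- data.frame(class_id = ids,
                       name = catalog$name[match(ids, catalog$class_id)],
                       color = hues)
  jsonlite::write_json(legend, paste0(path, ".legend.json"),
                       auto_unbox = TRUE)
  invisible(path)
}

#' Write a tile feature table with its catalog and retention sidecar
#'
#' CSV of the feature matrix (NA as empty fields) plus a JSON sidecar
#' carrying the feature catalog and, when given, the retention mask.
#'
#' @param mat tiles x features matrix.
#' @param path CSV output path; sidecar goes to `<path>.meta.json`.
#' @param retention optional result of [exclude_features()].
#' @return invisibly, the CSV path.
#' @export
write_feature_table <- function(mat, path, retention = NULL) {
  utils::write.csv(mat, path, row.names = FALSE, na = "")
  meta <- list(catalog = feature_catalog())
  if (!is.null(retention)) meta$retention <- retention
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE)
  invisible(path)
}

#' Write a ReliefF weight table
#'
#' One row per feature with its class pair (parsed from
#' `pairA_B.feature` names when present), weight and rank — the
#' selection-figure artifact.
#'
#' @param weights `relieff_weights`.
#' @param path CSV output path.
#' @return invisibly, the table.
#' @export
write_weight_table <- function(weights, path) {
  w <- weights$weights
  ord <- order(-w, seq_along(w))
  tab <- data.frame(feature = names(w)[ord],
                    pair = sub("\\..*$", "", names(w)[ord]),
                    weight = unname(w[ord]),
                    rank = seq_along(w))
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(tab)
}
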