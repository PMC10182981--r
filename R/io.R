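#' Write detected cells as GeoJSON
#'
#' One Feature per cell: the nucleus polygon as the geometry, the expanded cell
#' polygon (if present) and all scalar measurements in `properties`.
#' Coordinates are microns in the tile frame; full double precision is kept so
#' a write/read round trip reproduces polygons exactly.
#'
#' @param cs a [cell_set].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_detections_geojson <- function(cs, path) {
  tb <- cs$cells
  scalar_cols <- names(tb)[vapply(tb, function(x)
    is.numeric(x) || is.character(x) || is.logical(x) || is.factor(x), TRUE)]
  features <- lapply(seq_len(nrow(tb)), function(i) {
    props <- lapply(tb[i, scalar_cols], function(v)
      if (is.factor(v)) as.character(v) else v)
    geom <- list(type = "Polygon",
                 coordinates = list(close_ring(tb$nucleus_poly[[i]])))
    if ("cell_poly" %in% names(tb)) {
      props$cell_polygon <- close_ring(tb$cell_poly[[i]])
    }
    list(type = "Feature", geometry = geom, properties = props)
  })
  gj <- list(type = "FeatureCollection",
             microns_per_pixel = cs$microns_per_pixel,
             origin = cs$origin,
             features = features)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

close_ring <- function(poly) {
  m <- unname(rbind(poly, poly[1, , drop = FALSE]))
  lapply(seq_len(nrow(m)), function(i) m[i, ])
}

open_ring <- function(coords) {
  m <- do.call(rbind, lapply(coords, as.numeric))
  if (nrow(m) > 1 && all(m[1, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
  colnames(m) <- c("x", "y")
  m
}

#' Read detections back from GeoJSON
#'
#' Inverse of [write_detections_geojson()]; the label masks are not stored in
#' GeoJSON, so the returned [cell_set] carries tables and polygons only.
#'
#' @param path a GeoJSON file written by [write_detections_geojson()].
#' @return A [cell_set] (without label masks).
#' @export
read_detections_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  feats <- gj$features
  if (length(feats) == 0) {
    return(cell_set(empty_cells_tbl(), matrix(0L, 0, 0), NULL,
                    gj$microns_per_pixel, unlist(gj$origin)))
  }
  rows <- lapply(feats, function(f) {
    props <- f$properties
    cellp <- props$cell_polygon
    props$cell_polygon <- NULL
    tb <- tibble::as_tibble(lapply(props, function(v)
      if (is.null(v)) NA else v))
    tb$nucleus_poly <- list(open_ring(f$geometry$coordinates[[1]]))
    if (!is.null(cellp)) tb$cell_poly <- list(open_ring(cellp))
    tb
  })
  cells <- dplyr::bind_rows(rows)
  if ("class" %in% names(cells)) {
    cells$class <- factor(cells$class, levels = cell_classes())
  }
  cell_set(cells, matrix(0L, 0, 0), NULL, gj$microns_per_pixel,
           unlist(gj$origin))
}

#' Write / read an H&E tile as PNG with a JSON calibration sidecar
#'
#' The PNG holds the 8-bit RGB pixels; `<path>.json` records the
#' microns-per-pixel calibration and origin.
#'
#' @param tile an [he_tile].
#' @param path PNG file path.
#' @return `write_tile_png` returns `path` invisibly; `read_tile_png` an
#'   [he_tile].
#' @export
write_tile_png <- function(tile, path) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stop("the 'png' package is required to write PNG tiles", call. = FALSE)
  }
  png::writePNG(tile$rgb / 255, path)
  jsonlite::write_json(
    list(microns_per_pixel = tile$microns_per_pixel, origin = tile$origin),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_tile_png
#' @export
read_tile_png <- function(path) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stop("the 'png' package is required to read PNG tiles", call. = FALSE)
  }
  rgb <- png::readPNG(path) * 255
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  he_tile(round(rgb), meta$microns_per_pixel, meta$origin)
}

#' Write tile ground truth as GeoJSON + CSV area table
#'
#' @param truth a `tile_truth` from [generate_tile()].
#' @param geojson_path,csv_path output paths (either may be `NULL` to skip).
#' @return Invisibly, the paths written.
#' @export
write_truth <- function(truth, geojson_path = NULL, csv_path = NULL) {
  if (!is.null(geojson_path)) {
    features <- lapply(seq_len(nrow(truth$cells)), function(i) {
      r <- truth$cells[i, ]
      list(type = "Feature",
           geometry = list(type = "Polygon",
                           coordinates = list(close_ring(r$polygon[[1]]))),
           properties = list(cell = r$cell, class = as.character(r$class),
                             x_um = r$x_um, y_um = r$y_um,
                             nucleus_area_um2 = r$nucleus_area_um2))
    })
    jsonlite::write_json(
      list(type = "FeatureCollection", eastils_true = truth$eastils_true,
           features = features),
      geojson_path, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(csv_path)) {
    utils::write.csv(truth$class_areas, csv_path, row.names = FALSE)
  }
  invisible(c(geojson_path, csv_path))
}
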