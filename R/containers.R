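#' Create an H&E image tile
#'
#' The basic unit of image processing: an RGB raster with a physical pixel
#' calibration in microns. Pixel `(i, j)` (row, column) has its centre at
#' `x = origin[1] + (j - 0.5) * microns_per_pixel`,
#' `y = origin[2] + (i - 0.5) * microns_per_pixel`; all geometry downstream is
#' expressed in microns in this frame.
#'
#' @param rgb numeric array `H x W x 3` of 8-bit intensities in `[0, 255]`.
#' @param microns_per_pixel physical pixel size in microns (scalar, > 0).
#' @param origin length-2 numeric, slide-frame offset of the tile's top-left
#'   corner in microns (`x`, `y`).
#' @return An object of class `he_tile`.
#' @export
he_tile <- function(rgb, microns_per_pixel, origin = c(0, 0)) {
  stopifnot(is.array(rgb), length(dim(rgb)) == 3L, dim(rgb)[3] == 3L)
  if (!is.numeric(microns_per_pixel) || length(microns_per_pixel) != 1L ||
      microns_per_pixel <= 0) {
    stop("`microns_per_pixel` must be a single positive number", call. = FALSE)
  }
  if (min(rgb) < 0 || max(rgb) > 255) {
    stop("RGB intensities must lie in [0, 255]", call. = FALSE)
  }
  structure(
    list(rgb = rgb, microns_per_pixel = microns_per_pixel,
         origin = as.numeric(origin)),
    class = "he_tile"
  )
}

#' @export
print.he_tile <- function(x, ...) {
  d <- dim(x$rgb)
  cat(sprintf("<he_tile> %d x %d px (%.1f x %.1f um) @ %.4f um/px\n",
              d[1], d[2], d[2] * x$microns_per_pixel,
              d[1] * x$microns_per_pixel, x$microns_per_pixel))
  invisible(x)
}

#' @export
dim.he_tile <- function(x) dim(x$rgb)

#' Optical-density image
#'
#' A calibrated raster of optical densities, either raw per-RGB-channel OD or
#' deconvolved per-stain channels. Single-channel images store a matrix.
#'
#' @param data numeric matrix (`H x W`) or array (`H x W x C`), values >= 0
#'   after clamping and finite.
#' @param channels character vector naming the channels, length matching the
#'   third dimension (or 1 for a matrix).
#' @param microns_per_pixel physical pixel size in microns.
#' @param origin length-2 numeric offset in microns.
#' @return An object of class `od_image`.
#' @export
od_image <- function(data, channels, microns_per_pixel, origin = c(0, 0)) {
  nchan <- if (length(dim(data)) == 3L) dim(data)[3] else 1L
  stopifnot(length(channels) == nchan, microns_per_pixel > 0)
  if (any(!is.finite(data))) stop("OD values must be finite", call. = FALSE)
  structure(
    list(data = data, channels = channels,
         microns_per_pixel = microns_per_pixel, origin = as.numeric(origin)),
    class = "od_image"
  )
}

#' @export
print.od_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<od_image> %d x %d px, channels: %s @ %.4f um/px\n",
              d[1], d[2], paste(x$channels, collapse = ", "),
              x$microns_per_pixel))
  invisible(x)
}

#' Extract one channel of an od_image as a single-channel od_image
#'
#' @param od an [od_image].
#' @param channel channel name.
#' @return A single-channel `od_image`.
#' @export
od_channel <- function(od, channel) {
  idx <- match(channel, od$channels)
  if (is.na(idx)) {
    stop("channel '", channel, "' not present (have: ",
         paste(od$channels, collapse = ", "), ")", call. = FALSE)
  }
  dat <- if (length(dim(od$data)) == 3L) od$data[, , idx] else od$data
  od_image(dat, channel, od$microns_per_pixel, od$origin)
}

#' A set of detected cells with their label masks
#'
#' Couples the tidy per-cell table with the integer label rasters that carry the
#' exact pixel-level geometry (nucleus and expanded cell). The table and the
#' masks share cell ids; `microns_per_pixel` refers to the detection grid.
#'
#' @param cells tibble, one row per cell.
#' @param nucleus_labels integer matrix, 0 = background, `i` = cell id `i`.
#' @param cell_labels integer matrix of expanded cells, or `NULL` before
#'   expansion.
#' @param microns_per_pixel detection-grid pixel size (microns).
#' @param origin tile origin in microns.
#' @return An object of class `cell_set`.
#' @export
cell_set <- function(cells, nucleus_labels, cell_labels = NULL,
                     microns_per_pixel = NULL, origin = c(0, 0)) {
  structure(
    list(cells = tibble::as_tibble(cells), nucleus_labels = nucleus_labels,
         cell_labels = cell_labels, microns_per_pixel = microns_per_pixel,
         origin = as.numeric(origin)),
    class = "cell_set"
  )
}

#' @export
print.cell_set <- function(x, ...) {
  cat(sprintf("<cell_set> %d cells on a %s grid @ %.4f um/px%s\n",
              nrow(x$cells), paste(dim(x$nucleus_labels), collapse = " x "),
              x$microns_per_pixel,
              if (is.null(x$cell_labels)) " (nuclei only)" else ""))
  print(x$cells)
  invisible(x)
}

#' @export
as_tibble.cell_set <- function(x, ...) x$cells

#' Tidy a cell set into its per-cell table
#' @param x a [cell_set].
#' @param ... unused.
#' @return The per-cell tibble.
#' @export
tidy.cell_set <- function(x, ...) x$cells

# Run code with a temporary RNG state seeded from `seed`; restores the
# caller's .Random.seed afterwards so generators do not perturb user RNG.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# x/y coordinates (um) of pixel centres for a grid
pixel_centers <- function(nrow, ncol, mpp, origin = c(0, 0)) {
  list(x = origin[1] + (seq_len(ncol) - 0.5) * mpp,
       y = origin[2] + (seq_len(nrow) - 0.5) * mpp)
}
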