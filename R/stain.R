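#' H&E stain profile
#'
#' Unit optical-density vectors for hematoxylin and eosin plus an orthogonal
#' residual completing the basis, and the per-channel background intensity I0.
#'
#' @param hematoxylin,eosin unit OD 3-vectors (RGB order).
#' @param residual optional unit 3-vector; defaults to the normalized cross
#'   product of the two stain vectors.
#' @param I0 background (white) intensity per RGB channel.
#' @return An object of class `stain_profile`.
#' @export
stain_profile <- function(hematoxylin, eosin, residual = NULL,
                          I0 = c(255, 255, 255)) {
  unitize <- function(v) v / sqrt(sum(v^2))
  hematoxylin <- unitize(hematoxylin)
  eosin <- unitize(eosin)
  ang <- vector_angle_deg(hematoxylin, eosin)
  if (ang < 1) {
    stop("hematoxylin and eosin vectors are nearly collinear (", round(ang, 2),
         " degrees)", call. = FALSE)
  }
  if (is.null(residual)) {
    residual <- c(hematoxylin[2] * eosin[3] - hematoxylin[3] * eosin[2],
                  hematoxylin[3] * eosin[1] - hematoxylin[1] * eosin[3],
                  hematoxylin[1] * eosin[2] - hematoxylin[2] * eosin[1])
  }
  residual <- unitize(residual)
  if (any(I0 <= 0)) stop("I0 must be positive", call. = FALSE)
  structure(list(hematoxylin = hematoxylin, eosin = eosin,
                 residual = residual, I0 = as.numeric(I0)),
            class = "stain_profile")
}

#' @export
print.stain_profile <- function(x, ...) {
  cat("<stain_profile>\n")
  cat(sprintf("  hematoxylin: (%.3f, %.3f, %.3f)\n", x$hematoxylin[1],
              x$hematoxylin[2], x$hematoxylin[3]))
  cat(sprintf("  eosin:       (%.3f, %.3f, %.3f)\n", x$eosin[1], x$eosin[2],
              x$eosin[3]))
  cat(sprintf("  residual:    (%.3f, %.3f, %.3f)\n", x$residual[1],
              x$residual[2], x$residual[3]))
  cat(sprintf("  I0: %s\n", paste(x$I0, collapse = ", ")))
  invisible(x)
}

#' Default H&E stain vectors
#'
#' The conventional hematoxylin and eosin absorbance directions used when no
#' per-slide recalibration is available.
#' @return A [stain_profile].
#' @export
default_he_profile <- function() {
  stain_profile(hematoxylin = c(0.65, 0.70, 0.29),
                eosin = c(0.07, 0.99, 0.11))
}

vector_angle_deg <- function(a, b) {
  ct <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  acos(pmin(pmax(ct, -1), 1)) * 180 / pi
}

#' Convert an RGB tile to optical density
#'
#' `OD = -log10(max(I, 1) / I0)` per channel; intensities are floored at one
#' intensity unit so fully absorbed pixels stay finite, and OD is clamped at 0.
#'
#' @param tile an [he_tile].
#' @param I0 per-channel background intensity (> 0), default 255.
#' @return An [od_image] with channels `R`, `G`, `B`.
#' @export
rgb_to_od <- function(tile, I0 = c(255, 255, 255)) {
  stopifnot(inherits(tile, "he_tile"))
  if (length(I0) == 1) I0 <- rep(I0, 3)
  if (any(I0 <= 0)) stop("I0 must be positive", call. = FALSE)
  od <- array(0, dim = dim(tile$rgb))
  for (ch in 1:3) {
    od[, , ch] <- pmax(-log10(pmax(tile$rgb[, , ch], 1) / I0[ch]), 0)
  }
  od_image(od, c("R", "G", "B"), tile$microns_per_pixel, tile$origin)
}

#' Recalibrate H&E stain vectors from a tile
#'
#' Plane-fit estimator of the per-slide stain vectors (the "estimate stain
#' vectors" recalibration step). Pixels with OD magnitude below `min_od` or
#' with any channel within `near_white` intensity units of I0 are excluded;
#' the remaining OD cloud is projected onto its top-2 principal directions and
#' the robust extreme angles within that plane (the `alpha` / `1 - alpha`
#' percentiles) are taken as the two stain vectors. The vector with the larger
#' blue-channel OD component is labelled hematoxylin.
#'
#' A tile whose OD cloud collapses onto a single direction (angular spread
#' below `min_spread_deg`) is treated as single-stain: that direction is
#' assigned to the stain it resembles and the other stain falls back to the
#' default profile. A tile with fewer than `min_pixels` informative pixels
#' signals estimation failure (condition class `eastils_stain_error`), and the
#' caller is expected to fall back to [default_he_profile()].
#'
#' @param tile an [he_tile].
#' @param I0 per-channel background intensity.
#' @param min_od minimum OD magnitude for a pixel to enter the fit.
#' @param near_white intensity margin (units) below I0 regarded as background.
#' @param alpha robust percentile for the extreme angles.
#' @param min_pixels minimum number of informative pixels.
#' @param min_spread_deg angular spread below which the tile is treated as
#'   single-stain.
#' @return A [stain_profile]. Deterministic given the tile (the estimator is a
#'   pixel-population method and is invariant to pixel order).
#' @export
estimate_stain_vectors <- function(tile, I0 = c(255, 255, 255), min_od = 0.15,
                                   near_white = 2, alpha = 0.01,
                                   min_pixels = 100, min_spread_deg = 2) {
  stopifnot(inherits(tile, "he_tile"))
  if (length(I0) == 1) I0 <- rep(I0, 3)
  od <- rgb_to_od(tile, I0)$data
  n <- prod(dim(od)[1:2])
  odm <- matrix(od, n, 3)
  rgbm <- matrix(tile$rgb, n, 3)
  keep <- sqrt(rowSums(odm^2)) >= min_od &
    rgbm[, 1] < I0[1] - near_white &
    rgbm[, 2] < I0[2] - near_white &
    rgbm[, 3] < I0[3] - near_white
  odk <- odm[keep, , drop = FALSE]
  if (nrow(odk) < min_pixels) {
    abort(paste0("stain estimation failed: only ", nrow(odk),
                 " informative pixels (need ", min_pixels, ")"),
          class = "eastils_stain_error")
  }

  # top-2 principal directions of the (uncentered) OD cloud
  sv <- svd(odk, nu = 0, nv = 2)
  e1 <- sv$v[, 1]; e2 <- sv$v[, 2]
  if (sum(e1) < 0) e1 <- -e1
  # angles of pixels within the stain plane
  p1 <- odk %*% e1; p2 <- odk %*% e2
  phi <- atan2(p2, p1)
  qs <- quantile(phi, c(alpha, 1 - alpha), names = FALSE)
  mk <- function(a) {
    v <- cos(a) * e1 + sin(a) * e2
    if (sum(v) < 0) v <- -v
    v / sqrt(sum(v^2))
  }
  v1 <- mk(qs[1]); v2 <- mk(qs[2])

  if (vector_angle_deg(v1, v2) < min_spread_deg) {
    # single-stain tile: one real direction, counterpart from the defaults
    v <- mk(mean(qs))
    def <- default_he_profile()
    if (vector_angle_deg(v, def$hematoxylin) <= vector_angle_deg(v, def$eosin)) {
      return(stain_profile(hematoxylin = v, eosin = def$eosin, I0 = I0))
    }
    return(stain_profile(hematoxylin = def$hematoxylin, eosin = v, I0 = I0))
  }

  # hematoxylin = the more blue-absorbing vector (larger blue OD component);
  # exact tie broken toward v1 so assignment is deterministic
  if (v1[3] >= v2[3]) {
    stain_profile(hematoxylin = v1, eosin = v2, I0 = I0)
  } else {
    stain_profile(hematoxylin = v2, eosin = v1, I0 = I0)
  }
}

#' Colour deconvolution of an OD image
#'
#' Solves the 3x3 Beer-Lambert mixing system per pixel, mapping raw RGB optical
#' densities to per-stain concentrations (hematoxylin, eosin, residual).
#'
#' @param od an [od_image] with channels `R`, `G`, `B`.
#' @param profile a [stain_profile].
#' @param clamp clamp negative concentrations to zero (default `TRUE`; disable
#'   to verify the exact round trip).
#' @return An [od_image] with channels `hematoxylin`, `eosin`, `residual`.
#' @export
deconvolve <- function(od, profile, clamp = TRUE) {
  stopifnot(inherits(od, "od_image"), inherits(profile, "stain_profile"))
  if (!identical(od$channels, c("R", "G", "B"))) {
    stop("deconvolve expects a raw RGB od_image", call. = FALSE)
  }
  M <- rbind(profile$hematoxylin, profile$eosin, profile$residual)
  if (abs(det(M)) < 1e-8) stop("singular stain matrix", call. = FALSE)
  d <- dim(od$data)
  odm <- matrix(od$data, d[1] * d[2], 3)
  conc <- odm %*% solve(M)
  if (clamp) conc <- pmax(conc, 0)
  out <- array(conc, dim = c(d[1], d[2], 3))
  od_image(out, c("hematoxylin", "eosin", "residual"),
           od$microns_per_pixel, od$origin)
}

#' Recompose raw OD from deconvolved stain concentrations
#'
#' Inverse of [deconvolve()]; used to verify the round trip.
#'
#' @param conc an [od_image] with stain channels.
#' @param profile the [stain_profile] used for deconvolution.
#' @return An [od_image] with channels `R`, `G`, `B`.
#' @export
recompose <- function(conc, profile) {
  stopifnot(identical(conc$channels, c("hematoxylin", "eosin", "residual")))
  M <- rbind(profile$hematoxylin, profile$eosin, profile$residual)
  d <- dim(conc$data)
  cm <- matrix(conc$data, d[1] * d[2], 3)
  odm <- cm %*% M
  od_image(array(pmax(odm, 0), dim = d), c("R", "G", "B"),
           conc$microns_per_pixel, conc$origin)
}

#' Write / read a stain profile as JSON
#'
#' @param profile a [stain_profile].
#' @param path file path.
#' @return `write_stain_profile` returns `path` invisibly;
#'   `read_stain_profile` returns a [stain_profile].
#' @export
write_stain_profile <- function(profile, path) {
  jsonlite::write_json(
    list(hematoxylin = profile$hematoxylin, eosin = profile$eosin,
         residual = profile$residual, I0 = profile$I0),
    path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_stain_profile
#' @export
read_stain_profile <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  stain_profile(x$hematoxylin, x$eosin, x$residual, x$I0)
}
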