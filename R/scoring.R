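#' Invasive-tumor region annotation
#'
#' One or more simple polygons (micron coordinates) delineating the invasive
#' tumor region, optionally with excluded sub-polygons (holes) such as
#' noninvasive lesions or normal breast structures whose infiltrates must not
#' enter the score. The region area is the sum of all polygon areas minus the
#' holes.
#'
#' @param polygons list of `n x 2` matrices (columns x, y, microns), each a
#'   simple polygon with at least 3 vertices.
#' @param holes optional list of excluded sub-polygons.
#' @return An object of class `region_annotation`.
#' @export
region_annotation <- function(polygons, holes = list()) {
  if (is.matrix(polygons)) polygons <- list(polygons)
  if (is.matrix(holes)) holes <- list(holes)
  if (length(polygons) == 0) stop("empty region", call. = FALSE)
  chk <- function(p) {
    if (!is.matrix(p) || ncol(p) != 2 || nrow(p) < 3) {
      stop("each polygon must be an n x 2 matrix with n >= 3", call. = FALSE)
    }
    if (abs(shoelace_area(p)) <= 0) stop("degenerate polygon", call. = FALSE)
    p
  }
  polygons <- lapply(polygons, chk)
  holes <- lapply(holes, chk)
  area <- sum(vapply(polygons, function(p) abs(shoelace_area(p)), 0)) -
    sum(vapply(holes, function(p) abs(shoelace_area(p)), 0))
  if (area <= 0) stop("region has non-positive total area", call. = FALSE)
  structure(list(polygons = polygons, holes = holes, area_um2 = area),
            class = "region_annotation")
}

#' @export
print.region_annotation <- function(x, ...) {
  cat(sprintf("<region_annotation> %d polygon(s), %d hole(s), %.4f mm^2\n",
              length(x$polygons), length(x$holes), x$area_um2 / 1e6))
  invisible(x)
}

shoelace_area <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  0.5 * sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)
}

# closed-boundary point-in-polygon: interior via mgcv::in.out, points on an
# edge (within eps) count as inside
points_in_polygon <- function(px, py, poly, eps = 1e-9) {
  bnd <- rbind(poly, poly[1, , drop = FALSE])
  inside <- mgcv::in.out(bnd, cbind(px, py))
  onb <- points_on_boundary(px, py, poly, eps)
  inside | onb
}

points_on_boundary <- function(px, py, poly, eps = 1e-9) {
  on <- rep(FALSE, length(px))
  n <- nrow(poly)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    ax <- poly[i, 1]; ay <- poly[i, 2]
    bx <- poly[j, 1]; by <- poly[j, 2]
    vx <- bx - ax; vy <- by - ay
    L2 <- vx * vx + vy * vy
    t <- if (L2 == 0) rep(0, length(px)) else
      pmin(pmax(((px - ax) * vx + (py - ay) * vy) / L2, 0), 1)
    d2 <- (ax + t * vx - px)^2 + (ay + t * vy - py)^2
    on <- on | d2 <= eps^2
  }
  on
}

# membership in region (any polygon, closed) minus holes (closed: a point on a
# hole boundary still belongs to the region)
in_region <- function(px, py, region, eps = 1e-9) {
  inside <- rep(FALSE, length(px))
  for (p in region$polygons) inside <- inside | points_in_polygon(px, py, p, eps)
  for (h in region$holes) {
    in_h <- points_in_polygon(px, py, h, eps) &
      !points_on_boundary(px, py, h, eps)
    inside <- inside & !in_h
  }
  inside
}

#' Restrict cells to an annotated region
#'
#' A cell belongs to the region iff its nucleus centroid lies within the region
#' (boundaries are closed: a centroid exactly on the boundary is inside) and
#' outside every exclusion hole. Dropped cells are removed from the table and
#' zeroed out of the label masks so that later area accounting only sees
#' region cells; retained cell areas are additionally clipped to the region
#' boundary by [summarize_areas()].
#'
#' @param cs a [cell_set].
#' @param region a [region_annotation] in the same micron frame.
#' @return The filtered cell set, with the region attached.
#' @export
assign_cells_to_region <- function(cs, region) {
  stopifnot(inherits(cs, "cell_set"), inherits(region, "region_annotation"))
  keep <- in_region(cs$cells$x_um, cs$cells$y_um, region)
  dropped <- cs$cells$cell[!keep]
  if (length(dropped)) {
    cs$nucleus_labels[cs$nucleus_labels %in% dropped] <- 0L
    if (!is.null(cs$cell_labels)) {
      cs$cell_labels[cs$cell_labels %in% dropped] <- 0L
    }
  }
  cs$cells <- cs$cells[keep, , drop = FALSE]
  cs$region <- region
  cs
}

# logical raster of pixel centres lying in the region (minus holes)
region_mask <- function(region, dims, mpp, origin = c(0, 0)) {
  ctr <- pixel_centers(dims[1], dims[2], mpp, origin)
  px <- rep(ctr$x, each = dims[1])
  py <- rep(ctr$y, times = dims[2])
  matrix(in_region(px, py, region), dims[1], dims[2])
}

#' Per-class area accounting within a region
#'
#' Sums the region-clipped cell areas per class (in mm^2), the region area, and
#' the stromal area defined as region area minus the summed tumor-cell area.
#' All cells must be classified. The area basis is the expanded cell by
#' default; `area_basis = "nucleus"` sums nucleus areas instead.
#'
#' @param cs a classified [cell_set], typically after
#'   [assign_cells_to_region()].
#' @param region a [region_annotation]; defaults to the one attached by
#'   [assign_cells_to_region()].
#' @param area_basis `"cell"` (expanded-cell areas) or `"nucleus"`.
#' @return One-row tibble: `region_area_mm2`, `tumor_area_mm2`,
#'   `lymphocyte_area_mm2`, `stromal_cell_area_mm2`, `other_area_mm2`,
#'   `stromal_area_mm2`, `n_cells`.
#' @export
summarize_areas <- function(cs, region = NULL,
                            area_basis = c("cell", "nucleus")) {
  stopifnot(inherits(cs, "cell_set"))
  area_basis <- match.arg(area_basis)
  if (is.null(region)) region <- cs$region
  if (is.null(region)) stop("no region supplied or attached", call. = FALSE)
  if (nrow(cs$cells) > 0 &&
      (!"class" %in% names(cs$cells) || anyNA(cs$cells$class))) {
    stop("unclassified cells present: classify before scoring", call. = FALSE)
  }
  labels <- if (area_basis == "cell") {
    if (is.null(cs$cell_labels)) {
      stop("no expanded cells; run expand_cells() or use area_basis = 'nucleus'",
           call. = FALSE)
    }
    cs$cell_labels
  } else cs$nucleus_labels

  px_area <- cs$microns_per_pixel^2
  n <- max(c(0L, cs$cells$cell))
  if (n > 0 && any(labels > 0L)) {
    rm_ <- region_mask(region, dim(labels), cs$microns_per_pixel, cs$origin)
    lab_in <- labels
    lab_in[!rm_] <- 0L
    areas_px <- tabulate(lab_in[lab_in > 0L], nbins = n)
  } else {
    areas_px <- rep(0L, max(n, 0L))
  }

  per_class <- vapply(cell_classes(), function(cl) {
    ids <- cs$cells$cell[cs$cells$class == cl]
    sum(areas_px[ids]) * px_area / 1e6
  }, 0)

  region_mm2 <- region$area_um2 / 1e6
  tibble::tibble(
    region_area_mm2 = region_mm2,
    tumor_area_mm2 = per_class[["tumor"]],
    lymphocyte_area_mm2 = per_class[["lymphocyte"]],
    stromal_cell_area_mm2 = per_class[["stromal"]],
    other_area_mm2 = per_class[["other"]],
    stromal_area_mm2 = region_mm2 - per_class[["tumor"]],
    n_cells = nrow(cs$cells)
  )
}

#' Compute the easTILs% score
#'
#' `easTILs% = 100 * lymphocyte area (mm^2) / stromal area (mm^2)`, where the
#' stromal area is the invasive-tumor region area minus the summed tumor-cell
#' area. All lymphocytes inside the region are counted, so intratumoral
#' lymphocytes are included by construction. Undefined (an error) when the
#' stromal area is not positive, i.e. tumor cells fill the region.
#'
#' @param summary an area summary from [summarize_areas()] (or any data frame
#'   with `lymphocyte_area_mm2` and `stromal_area_mm2`); vectorized over rows.
#' @return Numeric vector of easTILs% values in `[0, 100]` for non-overlapping
#'   cells.
#' @export
compute_eastils <- function(summary) {
  if (any(summary$stromal_area_mm2 <= 0)) {
    stop("stromal area <= 0: easTILs% undefined (tumor fills the region)",
         call. = FALSE)
  }
  100 * summary$lymphocyte_area_mm2 / summary$stromal_area_mm2
}

#' Dichotomize a TILs score into high / low
#'
#' `high` iff the score strictly exceeds the cutoff; a score equal to the
#' cutoff is `low`. The published cutoffs are 19.9% for easTILs% and 20% for
#' pathologist sTILs%.
#'
#' @param score numeric vector of scores (>= 0).
#' @param cutoff dichotomization cutoff (default 19.9, the easTILs% cut
#'   point).
#' @return Factor with levels `low`, `high`, carrying the cutoff as an
#'   attribute.
#' @export
dichotomize_tils <- function(score, cutoff = 19.9) {
  stopifnot(all(score >= 0 | is.na(score)))
  out <- factor(ifelse(score > cutoff, "high", "low"),
                levels = c("low", "high"))
  attr(out, "cutoff") <- cutoff
  out
}
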