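#' Watershed cell-detection parameters
#'
#' The standard parameter set for nucleus detection on the hematoxylin OD
#' channel of a 20x H&E scan: work at a requested pixel size of 0.5 um,
#' estimate background by a morphological opening of radius 8 um, skip the
#' median filter, smooth with a Gaussian of sigma 1.5 um, threshold the
#' background-subtracted OD at 0.1, keep nuclei of 10-400 um^2, reject
#' detections whose local background OD exceeds 2, and expand each nucleus by
#' 5 um to approximate the full cell.
#'
#' @param requested_pixel_size_um working pixel size for detection.
#' @param background_radius_um radius of the opening structuring disk.
#' @param median_filter_radius_um median prefilter radius (0 = skipped).
#' @param sigma_um Gaussian smoothing sigma.
#' @param min_cell_area_um2,max_cell_area_um2 nucleus area window.
#' @param threshold_od OD threshold after background subtraction.
#' @param max_background_od reject detections where the local background OD
#'   exceeds this (suppresses dense artifact regions).
#' @param cell_expansion_um constrained nucleus-to-cell expansion distance.
#' @param watershed_tolerance_od minimum OD drop between two intensity peaks
#'   for them to be kept as separate nuclei; shallower peaks are merged.
#' @return An object of class `detection_params`.
#' @export
detection_params <- function(requested_pixel_size_um = 0.5,
                             background_radius_um = 8,
                             median_filter_radius_um = 0,
                             sigma_um = 1.5,
                             min_cell_area_um2 = 10,
                             max_cell_area_um2 = 400,
                             threshold_od = 0.1,
                             max_background_od = 2,
                             cell_expansion_um = 5,
                             watershed_tolerance_od = 0.05) {
  p <- structure(
    list(requested_pixel_size_um = requested_pixel_size_um,
         background_radius_um = background_radius_um,
         median_filter_radius_um = median_filter_radius_um,
         sigma_um = sigma_um,
         min_cell_area_um2 = min_cell_area_um2,
         max_cell_area_um2 = max_cell_area_um2,
         threshold_od = threshold_od,
         max_background_od = max_background_od,
         cell_expansion_um = cell_expansion_um,
         watershed_tolerance_od = watershed_tolerance_od),
    class = "detection_params"
  )
  stopifnot(p$requested_pixel_size_um > 0, p$background_radius_um >= 0,
            p$median_filter_radius_um >= 0, p$sigma_um >= 0,
            p$min_cell_area_um2 >= 0,
            p$min_cell_area_um2 < p$max_cell_area_um2,
            p$threshold_od > 0, p$cell_expansion_um >= 0,
            p$watershed_tolerance_od >= 0)
  p
}

# polygons (um) of labelled objects 1..n; list of matrices with x/y columns
label_polygons <- function(labels, mpp, origin = c(0, 0)) {
  n <- max(labels)
  if (n == 0) return(list())
  oc <- EBImage::ocontour(labels)
  lapply(seq_len(n), function(i) {
    ct <- oc[[i]]
    cbind(x = origin[1] + (ct[, 2] + 0.5) * mpp,
          y = origin[2] + (ct[, 1] + 0.5) * mpp)
  })
}

empty_cells_tbl <- function() {
  tibble::tibble(cell = integer(), x_um = numeric(), y_um = numeric(),
                 nucleus_area_um2 = numeric(),
                 nucleus_poly = list())
}

#' Detect nuclei on the hematoxylin OD channel
#'
#' Watershed cell detection: resample to the requested pixel size (bilinear),
#' optional median filter, Gaussian smoothing, background estimation by
#' morphological opening (subtracted), thresholding, and a distance-transform
#' watershed that splits touching nuclei. Each watershed object's boundary is
#' then refined on the background-subtracted *unsmoothed* image at the same
#' threshold so measured areas are not inflated by the smoothing kernel.
#' Objects with refined area outside the `[min, max]` um^2 window, or whose
#' local background OD at the centroid exceeds `max_background_od`, are
#' discarded.
#'
#' @param hema single-channel [od_image] (hematoxylin OD) with a pixel
#'   calibration.
#' @param params a [detection_params].
#' @return A [cell_set] of nucleus-only objects on the detection grid, with
#'   polygons and centroids in microns of the tile frame. An empty image gives
#'   an empty cell set (not an error).
#' @export
detect_nuclei <- function(hema, params = detection_params()) {
  stopifnot(inherits(hema, "od_image"))
  if (length(dim(hema$data)) != 2L) {
    stop("detect_nuclei expects a single-channel OD image", call. = FALSE)
  }
  if (is.null(hema$microns_per_pixel) || hema$microns_per_pixel <= 0) {
    stop("missing microns-per-pixel calibration", call. = FALSE)
  }
  mpp0 <- hema$microns_per_pixel
  mpp <- params$requested_pixel_size_um
  img0 <- hema$data
  new_nrow <- max(1L, round(nrow(img0) * mpp0 / mpp))
  new_ncol <- max(1L, round(ncol(img0) * mpp0 / mpp))
  raw <- if (new_nrow == nrow(img0) && new_ncol == ncol(img0)) img0 else
    as.matrix(EBImage::resize(img0, w = new_nrow, h = new_ncol))

  if (params$median_filter_radius_um > 0) {
    sz <- max(1L, round(params$median_filter_radius_um / mpp))
    mx <- max(raw, 1e-8)
    raw <- as.matrix(EBImage::medianFilter(raw / mx, sz)) * mx
  }
  smooth <- if (params$sigma_um > 0) {
    as.matrix(EBImage::gblur(raw, sigma = params$sigma_um / mpp))
  } else raw
  bg <- if (params$background_radius_um > 0) {
    brush <- EBImage::makeBrush(2L * round(params$background_radius_um / mpp) + 1L,
                                shape = "disc")
    # grayscale morphology in EBImage clamps to [0, 1]: rescale around it
    mx <- max(smooth, 1e-8)
    as.matrix(EBImage::opening(smooth / mx, brush)) * mx
  } else matrix(0, nrow(raw), ncol(raw))

  sub_s <- smooth - bg
  sub_r <- raw - bg
  mask <- sub_s > params$threshold_od
  if (!any(mask)) {
    return(cell_set(empty_cells_tbl(), matrix(0L, new_nrow, new_ncol),
                    NULL, mpp, hema$origin))
  }

  # intensity watershed on the masked smoothed OD: peaks separated by a drop
  # of at least watershed_tolerance_od become distinct nuclei
  ws_in <- sub_s
  ws_in[!mask] <- 0
  ws <- EBImage::imageData(EBImage::watershed(
    ws_in, tolerance = params$watershed_tolerance_od, ext = 1))
  storage.mode(ws) <- "integer"

  # refine boundaries on the unsmoothed background-subtracted image: keep
  # pixels above max(threshold, half the object's own peak OD) so measured
  # areas are not inflated by the smoothing kernel or by edge softening
  nlab <- max(ws)
  pos <- ws > 0L
  peak <- vapply(split(sub_r[pos], ws[pos]),
                 function(v) quantile(v, 0.95, names = FALSE), 0)
  thr_lookup <- rep(params$threshold_od, nlab + 1L)
  thr_lookup[as.integer(names(peak)) + 1L] <-
    pmax(params$threshold_od, 0.5 * peak)
  ref <- ws
  ref[ref > 0L][sub_r[pos] <= thr_lookup[ws[pos] + 1L]] <- 0L

  px_area <- mpp^2
  areas_px <- tabulate(ref[ref > 0L], nbins = nlab)
  keep <- which(areas_px > 0L &
                  areas_px * px_area >= params$min_cell_area_um2 &
                  areas_px * px_area <= params$max_cell_area_um2)

  # background-OD rejection at the (refined) centroid
  if (length(keep)) {
    idx <- which(ref > 0L)
    labs <- ref[idx]
    rows <- ((idx - 1L) %% nrow(ref)) + 1L
    cols <- ((idx - 1L) %/% nrow(ref)) + 1L
    cy <- vapply(split(rows, labs), mean, 0)
    cx <- vapply(split(cols, labs), mean, 0)
    lab_ids <- as.integer(names(cy))
    cen_row <- setNames(cy, lab_ids); cen_col <- setNames(cx, lab_ids)
    keep <- keep[vapply(keep, function(l) {
      r <- round(cen_row[[as.character(l)]]); c <- round(cen_col[[as.character(l)]])
      bg[r, c] <= params$max_background_od
    }, TRUE)]
  }

  if (!length(keep)) {
    return(cell_set(empty_cells_tbl(), matrix(0L, new_nrow, new_ncol),
                    NULL, mpp, hema$origin))
  }

  relab <- integer(nlab + 1L)
  relab[keep + 1L] <- seq_along(keep)
  nuc <- matrix(relab[ref + 1L], nrow(ref), ncol(ref))
  storage.mode(nuc) <- "integer"

  org <- hema$origin
  polys <- label_polygons(nuc, mpp, org)
  cells <- tibble::tibble(
    cell = seq_along(keep),
    x_um = unname(org[1] + (cen_col[as.character(keep)] - 0.5) * mpp),
    y_um = unname(org[2] + (cen_row[as.character(keep)] - 0.5) * mpp),
    nucleus_area_um2 = areas_px[keep] * px_area,
    nucleus_poly = polys
  )
  cell_set(cells, nuc, NULL, mpp, org)
}

#' Expand nuclei to cell boundaries
#'
#' Dilates every nucleus by `cell_expansion_um`, constrained so the expansions
#' of distinct cells never overlap: each pixel within reach is assigned to its
#' nearest nucleus (exact Euclidean nearest-nucleus partition; ties go to the
#' lower cell id). With zero expansion the cell equals the nucleus.
#'
#' @param cs a [cell_set] from [detect_nuclei()] (non-overlapping nuclei).
#' @param params a [detection_params]; `cell_expansion_um` is used.
#' @return The cell set with `cell_labels`, `cell_area_um2`, `cell_poly` and
#'   `cell_nucleus_ratio` filled in.
#' @export
expand_cells <- function(cs, params = detection_params()) {
  stopifnot(inherits(cs, "cell_set"))
  nuc <- cs$nucleus_labels
  mpp <- cs$microns_per_pixel
  n <- nrow(cs$cells)
  if (n == 0) {
    cs$cell_labels <- nuc
    cs$cells$cell_area_um2 <- numeric(0)
    cs$cells$cell_poly <- list()
    cs$cells$cell_nucleus_ratio <- numeric(0)
    return(cs)
  }
  exp_px <- params$cell_expansion_um / mpp
  if (exp_px == 0) {
    cell_lab <- nuc
  } else {
    pad <- as.integer(ceiling(exp_px)) + 1L
    best_d <- matrix(Inf, nrow(nuc), ncol(nuc))
    best_d[nuc > 0L] <- 0
    cell_lab <- nuc
    idx_all <- which(nuc > 0L)
    rows_all <- ((idx_all - 1L) %% nrow(nuc)) + 1L
    cols_all <- ((idx_all - 1L) %/% nrow(nuc)) + 1L
    labs_all <- nuc[idx_all]
    for (id in seq_len(n)) {
      sel <- labs_all == id
      if (!any(sel)) next
      r0 <- max(1L, min(rows_all[sel]) - pad)
      r1 <- min(nrow(nuc), max(rows_all[sel]) + pad)
      c0 <- max(1L, min(cols_all[sel]) - pad)
      c1 <- min(ncol(nuc), max(cols_all[sel]) + pad)
      crop <- nuc[r0:r1, c0:c1] == id
      d <- EBImage::imageData(EBImage::distmap(1 - crop))
      upd <- d <= exp_px & d < best_d[r0:r1, c0:c1]
      if (any(upd)) {
        sub_d <- best_d[r0:r1, c0:c1]; sub_l <- cell_lab[r0:r1, c0:c1]
        sub_d[upd] <- d[upd]; sub_l[upd] <- id
        best_d[r0:r1, c0:c1] <- sub_d; cell_lab[r0:r1, c0:c1] <- sub_l
      }
    }
  }
  storage.mode(cell_lab) <- "integer"
  areas_px <- tabulate(cell_lab[cell_lab > 0L], nbins = n)
  cs$cell_labels <- cell_lab
  cs$cells$cell_area_um2 <- areas_px * mpp^2
  cs$cells$cell_poly <- label_polygons(cell_lab, mpp, cs$origin)
  cs$cells$cell_nucleus_ratio <-
    cs$cells$cell_area_um2 / cs$cells$nucleus_area_um2
  cs
}
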