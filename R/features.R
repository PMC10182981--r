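# per-label summary stats (mean/sd/min/max) of `values` grouped by `labels`,
# returned as an n x 4 matrix for labels 1..n; absent labels give all zeros
label_stats <- function(values, labels, n) {
  out <- matrix(0, n, 4, dimnames = list(NULL, c("mean", "sd", "min", "max")))
  pos <- labels > 0L
  if (!any(pos)) return(out)
  v <- values[pos]; l <- labels[pos]
  sp <- split(v, l)
  ids <- as.integer(names(sp))
  out[ids, "mean"] <- vapply(sp, mean, 0)
  out[ids, "sd"] <- vapply(sp, function(x) if (length(x) > 1) sd(x) else 0, 0)
  out[ids, "min"] <- vapply(sp, min, 0)
  out[ids, "max"] <- vapply(sp, max, 0)
  out
}

# resample a single-channel od_image to the grid of a cell_set
resample_to_grid <- function(od, cs) {
  dat <- od$data
  target <- dim(cs$nucleus_labels)
  if (identical(dim(dat), target)) return(dat)
  as.matrix(EBImage::resize(dat, w = target[1], h = target[2]))
}

#' Names of the base per-cell features
#'
#' Per-compartment (nucleus, cytoplasmic ring, whole cell) mean/sd/min/max of
#' hematoxylin and eosin OD, plus nuclear shape descriptors and the
#' cell/nucleus area ratio.
#' @return Character vector of feature column names.
#' @export
eastils_feature_names <- function() {
  comp <- c("nuc", "ring", "cell")
  chan <- c("hema", "eosin")
  stat <- c("mean", "sd", "min", "max")
  c(as.vector(outer(as.vector(outer(comp, chan, paste, sep = "_")),
                    stat, paste, sep = "_")),
    "nucleus_area_um2", "nucleus_perimeter_um", "circularity", "eccentricity",
    "max_caliper_um", "cell_area_um2", "cell_nucleus_ratio")
}

#' Compute per-cell morphometric and staining features
#'
#' Populates, for every cell: mean/sd/min/max hematoxylin and eosin OD in the
#' nucleus, the cytoplasmic ring (cell minus nucleus) and the whole cell;
#' nuclear shape (area, convex-hull perimeter, circularity `4*pi*A/P^2`
#' clamped to 1, eccentricity from the pixel second moments, max caliper); and
#' the cell/nucleus area ratio. Cells clipped by the image border are flagged
#' in `edge_clipped`. An empty cytoplasmic ring (zero expansion) yields zero
#' ring statistics.
#'
#' @param cs a [cell_set] with expanded cells (see [expand_cells()]).
#' @param hema,eosin single-channel [od_image]s (deconvolved stain channels).
#' @return The cell set with feature columns appended to its table.
#' @export
compute_features <- function(cs, hema, eosin) {
  stopifnot(inherits(cs, "cell_set"))
  if (is.null(cs$cell_labels)) {
    stop("cells must be expanded before feature computation (see expand_cells)",
         call. = FALSE)
  }
  n <- nrow(cs$cells)
  h <- resample_to_grid(hema, cs)
  e <- resample_to_grid(eosin, cs)
  nuc <- cs$nucleus_labels
  cell <- cs$cell_labels
  ring <- cell
  ring[nuc > 0L] <- 0L

  feats <- list(
    nuc_hema = label_stats(h, nuc, n), nuc_eosin = label_stats(e, nuc, n),
    ring_hema = label_stats(h, ring, n), ring_eosin = label_stats(e, ring, n),
    cell_hema = label_stats(h, cell, n), cell_eosin = label_stats(e, cell, n)
  )
  fm <- do.call(cbind, lapply(names(feats), function(nm) {
    m <- feats[[nm]]
    colnames(m) <- paste(nm, colnames(m), sep = "_")
    m
  }))

  shp <- nucleus_shape_features(nuc, n, cs$microns_per_pixel)

  tb <- cs$cells
  for (j in colnames(fm)) tb[[j]] <- unname(fm[, j])
  tb$nucleus_perimeter_um <- shp$perimeter
  tb$circularity <- shp$circularity
  tb$eccentricity <- shp$eccentricity
  tb$max_caliper_um <- shp$caliper
  tb$edge_clipped <- shp$edge
  cs$cells <- tb
  cs
}

nucleus_shape_features <- function(nuc, n, mpp) {
  perimeter <- numeric(n); circularity <- numeric(n)
  eccentricity <- numeric(n); caliper <- numeric(n); edge <- logical(n)
  if (n == 0) {
    return(list(perimeter = perimeter, circularity = circularity,
                eccentricity = eccentricity, caliper = caliper, edge = edge))
  }
  idx <- which(nuc > 0L)
  rows <- ((idx - 1L) %% nrow(nuc)) + 1L
  cols <- ((idx - 1L) %/% nrow(nuc)) + 1L
  labs <- nuc[idx]
  sp_r <- split(rows, labs); sp_c <- split(cols, labs)
  areas <- tabulate(labs, nbins = n) * mpp^2
  for (k in seq_along(sp_r)) {
    id <- as.integer(names(sp_r)[k])
    r <- sp_r[[k]]; c <- sp_c[[k]]
    edge[id] <- any(r == 1L | r == nrow(nuc) | c == 1L | c == ncol(nuc))
    x <- c * mpp; y <- r * mpp
    # convex hull of the pixel centres: robust perimeter/caliper for the
    # convex-ish shapes of nuclei (staircase-free)
    if (length(x) >= 3 && (var(x) > 0 || var(y) > 0)) {
      hull <- grDevices::chull(x, y)
      hx <- x[hull]; hy <- y[hull]
      # pad by half-pixel so a hull through centres matches the pixel footprint
      cxm <- mean(hx); cym <- mean(hy)
      rr <- sqrt((hx - cxm)^2 + (hy - cym)^2)
      sc <- ifelse(rr > 0, (rr + mpp / 2) / rr, 1)
      hx <- cxm + (hx - cxm) * sc; hy <- cym + (hy - cym) * sc
      per <- sum(sqrt(diff(c(hx, hx[1]))^2 + diff(c(hy, hy[1]))^2))
      dmax <- max(dist(cbind(hx, hy)))
    } else {
      per <- 4 * mpp
      dmax <- mpp
    }
    perimeter[id] <- per
    circularity[id] <- min(1, 4 * pi * areas[id] / per^2)
    caliper[id] <- dmax
    # eccentricity from second moments of the pixel distribution
    if (length(x) > 1) {
      cv <- stats::cov(cbind(x, y)) + diag(2) * (mpp^2 / 12)
      ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
      eccentricity[id] <- sqrt(max(0, 1 - ev[2] / ev[1]))
    } else {
      eccentricity[id] <- 0
    }
  }
  list(perimeter = perimeter, circularity = circularity,
       eccentricity = eccentricity, caliper = caliper, edge = edge)
}

#' Append neighbourhood-smoothed copies of the cell features
#'
#' For every cell and every base feature, appends the distance-weighted mean
#' over cells whose centroids lie within `radius_um` (the cell itself
#' included), with Gaussian weights `exp(-d^2 / (2 * (radius/2)^2))`. Applied
#' at 25 and then 50 um radius in the standard pipeline; smoothed columns get
#' the suffix `_s<radius>`.
#'
#' @param cs a [cell_set] with computed features (or a plain tibble with
#'   `x_um`/`y_um` and feature columns).
#' @param radius_um neighbourhood radius in microns.
#' @param features character vector of feature columns to smooth; defaults to
#'   the intersection of [eastils_feature_names()] with available columns.
#' @return The input with smoothed feature columns appended.
#' @export
smooth_features <- function(cs, radius_um, features = NULL) {
  tb <- if (inherits(cs, "cell_set")) cs$cells else tibble::as_tibble(cs)
  if (is.null(features)) {
    features <- intersect(eastils_feature_names(), names(tb))
  }
  n <- nrow(tb)
  suffix <- paste0("_s", radius_um)
  if (n == 0) {
    for (f in features) tb[[paste0(f, suffix)]] <- numeric(0)
  } else {
    fm <- as.matrix(tb[features])
    sm <- matrix(0, n, length(features))
    xs <- tb$x_um; ys <- tb$y_um
    s2 <- 2 * (radius_um / 2)^2
    block <- 512L
    for (b0 in seq(1L, n, by = block)) {
      b1 <- min(n, b0 + block - 1L)
      d2 <- outer(xs[b0:b1], xs, "-")^2 + outer(ys[b0:b1], ys, "-")^2
      w <- exp(-d2 / s2)
      w[d2 > radius_um^2] <- 0
      sm[b0:b1, ] <- (w %*% fm) / rowSums(w)
    }
    colnames(sm) <- paste0(features, suffix)
    for (j in colnames(sm)) tb[[j]] <- sm[, j]
  }
  if (inherits(cs, "cell_set")) {
    cs$cells <- tb
    cs
  } else {
    tb
  }
}
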