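#' Specification for a synthetic H&E tile
#'
#' Describes a tile with planted nuclei of the four cell classes used by the
#' classifier: `tumor` (large, moderate hematoxylin), `lymphocyte` (small,
#' round, dark), `stromal` (elongated, fibroblast-like, pale) and `other`
#' (small dense apoptotic-body-like fragments). Nucleus size is parameterised
#' by the equivalent-area radius `radius_um` (the ellipse has area
#' `pi * radius_um^2` regardless of eccentricity).
#'
#' Nuclei are planted without overlap by rejection sampling with a minimum
#' edge-to-edge clearance; `n_pairs` additionally plants nucleus pairs of
#' `pair_class` at sub-diameter centre spacing to exercise watershed splitting.
#'
#' @param width_um,height_um physical tile size in microns.
#' @param microns_per_pixel scanner pixel calibration (default 0.4986 um,
#'   a 20x whole-slide scan).
#' @param n_tumor,n_lymphocyte,n_stromal,n_other planted cell counts per class.
#' @param morphology named list (per class) of `radius_um`, `radius_sd`,
#'   `eccentricity` and `hema_od` (nuclear hematoxylin OD amplitude).
#' @param stroma_eosin_od,stroma_hema_od background (stromal) OD levels.
#' @param nuclear_eosin_frac fraction of the stromal eosin level retained
#'   inside nuclei (chromatin largely displaces cytoplasmic eosin).
#' @param noise_sd additive Gaussian noise, OD units, applied per RGB channel
#'   before exponentiation so Beer-Lambert inversion stays exact in expectation.
#' @param stain_profile a [stain_profile] used for composition.
#' @param clearance_um minimum edge-to-edge clearance between planted nuclei.
#' @param n_pairs number of touching nucleus pairs to plant (watershed test
#'   mode); members of a pair are exempt from the clearance rule.
#' @param pair_class,pair_spacing_um class and centre spacing of planted pairs.
#' @param max_retries rejection-sampling retries per cell before the spec is
#'   declared overcrowded.
#' @param seed integer RNG seed; fixing it fixes the tile bit-for-bit.
#' @return An object of class `tile_spec`.
#' @export
tile_spec <- function(width_um = 200, height_um = 200,
                      microns_per_pixel = 0.4986,
                      n_tumor = 15, n_lymphocyte = 30, n_stromal = 12,
                      n_other = 8,
                      morphology = default_morphology(),
                      stroma_eosin_od = 0.15, stroma_hema_od = 0.02,
                      nuclear_eosin_frac = 0.2,
                      noise_sd = 0.02,
                      stain_profile = default_he_profile(),
                      clearance_um = 5,
                      n_pairs = 0, pair_class = "lymphocyte",
                      pair_spacing_um = 4.5,
                      max_retries = 1000,
                      seed = NULL) {
  spec <- structure(
    list(width_um = width_um, height_um = height_um,
         microns_per_pixel = microns_per_pixel,
         counts = c(tumor = n_tumor, lymphocyte = n_lymphocyte,
                    stromal = n_stromal, other = n_other),
         morphology = morphology,
         stroma_eosin_od = stroma_eosin_od, stroma_hema_od = stroma_hema_od,
         nuclear_eosin_frac = nuclear_eosin_frac,
         noise_sd = noise_sd, stain_profile = stain_profile,
         clearance_um = clearance_um, n_pairs = n_pairs,
         pair_class = pair_class, pair_spacing_um = pair_spacing_um,
         max_retries = max_retries, seed = seed),
    class = "tile_spec"
  )
  validate_tile_spec(spec)
  spec
}

#' Default per-class nuclear morphology
#'
#' Class parameters chosen so the four classes are separable by the standard
#' morphometric feature set: lymphocytes small/round/dark, tumor nuclei large
#' with moderate staining, stromal (fibroblast) nuclei elongated and pale,
#' "other" rendered as small very dense fragments.
#'
#' @return Named list of per-class morphology parameters.
#' @export
default_morphology <- function() {
  list(
    tumor      = list(radius_um = 6.5, radius_sd = 0.7, eccentricity = 0.40,
                      hema_od = 0.50),
    lymphocyte = list(radius_um = 2.5, radius_sd = 0.20, eccentricity = 0.10,
                      hema_od = 0.90),
    stromal    = list(radius_um = 4.8, radius_sd = 0.40, eccentricity = 0.90,
                      hema_od = 0.35),
    other      = list(radius_um = 2.3, radius_sd = 0.15, eccentricity = 0.30,
                      hema_od = 1.30)
  )
}

#' Canonical cell class order
#'
#' Tumor, lymphocyte, stromal, other. Used for factor levels, classifier
#' outputs and deterministic tie-breaking.
#' @return Character vector of the four class names.
#' @export
cell_classes <- function() c("tumor", "lymphocyte", "stromal", "other")

validate_tile_spec <- function(spec) {
  if (spec$microns_per_pixel <= 0) stop("microns_per_pixel must be > 0", call. = FALSE)
  if (spec$width_um <= 0 || spec$height_um <= 0) stop("tile size must be positive", call. = FALSE)
  if (any(spec$counts < 0) || spec$n_pairs < 0) stop("cell counts must be >= 0", call. = FALSE)
  if (!all(cell_classes() %in% names(spec$morphology))) {
    stop("morphology must cover classes: ", paste(cell_classes(), collapse = ", "),
         call. = FALSE)
  }
  p <- spec$stain_profile
  for (v in list(p$hematoxylin, p$eosin)) {
    if (abs(sqrt(sum(v^2)) - 1) > 1e-6) stop("stain vectors must have unit norm", call. = FALSE)
  }
  if (!spec$pair_class %in% cell_classes()) stop("unknown pair_class", call. = FALSE)
  invisible(spec)
}

# vertices of an ellipse as an n-gon, in um
ellipse_polygon <- function(cx, cy, a, b, theta, n = 64) {
  t <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  ex <- a * cos(t); ey <- b * sin(t)
  cbind(x = cx + ex * cos(theta) - ey * sin(theta),
        y = cy + ex * sin(theta) + ey * cos(theta))
}

# raster indices (row, col) of pixels whose centres fall inside the ellipse
rasterize_ellipse <- function(cx, cy, a, b, theta, mpp, nrow, ncol) {
  rmax <- max(a, b)
  j0 <- max(1L, floor((cx - rmax) / mpp)); j1 <- min(ncol, ceiling((cx + rmax) / mpp) + 1L)
  i0 <- max(1L, floor((cy - rmax) / mpp)); i1 <- min(nrow, ceiling((cy + rmax) / mpp) + 1L)
  if (j0 > j1 || i0 > i1) return(matrix(integer(), 0, 2))
  jj <- j0:j1; ii <- i0:i1
  px <- (jj - 0.5) * mpp; py <- (ii - 0.5) * mpp
  dx <- outer(rep(1, length(ii)), px - cx)
  dy <- outer(py - cy, rep(1, length(jj)))
  u <- (dx * cos(theta) + dy * sin(theta)) / a
  v <- (-dx * sin(theta) + dy * cos(theta)) / b
  sel <- which(u * u + v * v <= 1, arr.ind = TRUE)
  if (nrow(sel) == 0) return(matrix(integer(), 0, 2))
  cbind(ii[sel[, 1]], jj[sel[, 2]])
}

#' Generate a synthetic H&E tile with known ground truth
#'
#' Composes an RGB tile via the Beer-Lambert law
#' (`I = 255 * 10^(-OD . stain_matrix)`): nuclei are filled ellipses with
#' class-dependent size, shape and hematoxylin OD; the stroma carries a uniform
#' eosin (and faint hematoxylin) level; Gaussian noise is added in OD space
#' before exponentiation and the result is quantised to 8 bits.
#'
#' The returned ground truth records every planted cell (centre, ellipse
#' parameters, analytic polygon, exact rasterized nucleus area), per-class
#' rasterized area sums, the tile-rectangle region and the true easTILs%
#' computed from the planted nucleus areas.
#'
#' @param spec a [tile_spec].
#' @return A list with elements `tile` (an [he_tile]) and `truth` (class
#'   `tile_truth`: `cells` tibble, `class_areas` tibble, `region`,
#'   `eastils_true`, `microns_per_pixel`).
#' @export
generate_tile <- function(spec) {
  validate_tile_spec(spec)
  with_seed(spec$seed, generate_tile_impl(spec))
}

generate_tile_impl <- function(spec) {
  mpp <- spec$microns_per_pixel
  ncol <- round(spec$width_um / mpp)
  nrow <- round(spec$height_um / mpp)

  # draw cell parameters: pairs first (they occupy the most room), then
  # singles from large to small so rejection sampling fills space greedily
  classes <- rep(names(spec$counts), spec$counts)
  draw_cell <- function(cl) {
    m <- spec$morphology[[cl]]
    # radius truncated at +/- 2 sd: keeps planted sizes within the class's
    # realistic range (and default classes inside the detectable area window)
    r <- max(0.5, min(max(rnorm(1, m$radius_um, m$radius_sd),
                          m$radius_um - 2 * m$radius_sd),
                      m$radius_um + 2 * m$radius_sd))
    s <- sqrt(1 - m$eccentricity^2)
    list(class = cl, a = r / sqrt(s), b = r * sqrt(s),
         theta = runif(1, 0, pi), od = m$hema_od, r = r)
  }

  placed <- list()   # each: cx, cy plus draw_cell fields
  # occupied footprint for clearance checks: centre + bounding radius
  occ_x <- numeric(0); occ_y <- numeric(0); occ_r <- numeric(0)

  place_one <- function(cell, extra_r = 0, fixed_xy = NULL) {
    rad <- cell$a + extra_r
    margin <- rad + 2
    if (2 * margin >= min(spec$width_um, spec$height_um)) {
      stop("tile too small for requested cell size", call. = FALSE)
    }
    for (k in seq_len(spec$max_retries)) {
      cx <- runif(1, margin, spec$width_um - margin)
      cy <- runif(1, margin, spec$height_um - margin)
      if (length(occ_x) == 0 ||
          all((occ_x - cx)^2 + (occ_y - cy)^2 >
              (occ_r + rad + spec$clearance_um)^2)) {
        return(c(cx, cy))
      }
    }
    stop("overcrowded tile spec: could not place a '", cell$class,
         "' nucleus without overlap after ", spec$max_retries, " retries",
         call. = FALSE)
  }

  # pairs: two nuclei of pair_class at fixed centre spacing
  for (p in seq_len(spec$n_pairs)) {
    c1 <- draw_cell(spec$pair_class); c2 <- draw_cell(spec$pair_class)
    half <- spec$pair_spacing_um / 2
    ctr <- place_one(list(class = spec$pair_class,
                          a = max(c1$a, c2$a) + half),
                     extra_r = 0)
    ang <- runif(1, 0, pi)
    c1$cx <- ctr[1] + half * cos(ang); c1$cy <- ctr[2] + half * sin(ang)
    c2$cx <- ctr[1] - half * cos(ang); c2$cy <- ctr[2] - half * sin(ang)
    c1$pair <- p; c2$pair <- p
    placed <- c(placed, list(c1, c2))
    occ_x <- c(occ_x, ctr[1]); occ_y <- c(occ_y, ctr[2])
    occ_r <- c(occ_r, max(c1$a, c2$a) + half)
  }

  cells <- lapply(classes, draw_cell)
  if (length(cells)) cells <- cells[order(-vapply(cells, `[[`, 0, "a"))]
  for (cell in cells) {
    xy <- place_one(cell)
    cell$cx <- xy[1]; cell$cy <- xy[2]; cell$pair <- NA_integer_
    placed <- c(placed, list(cell))
    occ_x <- c(occ_x, xy[1]); occ_y <- c(occ_y, xy[2])
    occ_r <- c(occ_r, cell$a)
  }

  # rasterize
  hema <- matrix(spec$stroma_hema_od, nrow, ncol)
  eosin <- matrix(spec$stroma_eosin_od, nrow, ncol)
  labels <- matrix(0L, nrow, ncol)
  npix <- integer(length(placed))
  for (i in seq_along(placed)) {
    cl <- placed[[i]]
    px <- rasterize_ellipse(cl$cx, cl$cy, cl$a, cl$b, cl$theta, mpp, nrow, ncol)
    if (nrow(px) > 0) {
      idx <- px[, 1] + (px[, 2] - 1L) * nrow
      hema[idx] <- pmax(hema[idx], spec$stroma_hema_od + cl$od)
      eosin[idx] <- spec$stroma_eosin_od * spec$nuclear_eosin_frac
      labels[idx] <- i
    }
  }
  # exact rasterized area: pixels currently owned by each cell (later cells
  # win on the rare pair-mode overlap, keeping per-class sums disjoint)
  tab <- tabulate(labels[labels > 0L], nbins = length(placed))
  npix <- tab

  prof <- spec$stain_profile
  M <- rbind(prof$hematoxylin, prof$eosin)   # 2 x 3, rows = stains
  od_rgb <- array(0, dim = c(nrow, ncol, 3))
  for (ch in 1:3) {
    od <- hema * M[1, ch] + eosin * M[2, ch]
    if (spec$noise_sd > 0) od <- od + rnorm(length(od), 0, spec$noise_sd)
    od_rgb[, , ch] <- pmax(od, 0)
  }
  rgb <- round(pmin(pmax(255 * 10^(-od_rgb), 0), 255))

  cells_tbl <- tibble::tibble(
    cell = seq_along(placed),
    class = factor(vapply(placed, `[[`, "", "class"), levels = cell_classes()),
    x_um = vapply(placed, `[[`, 0, "cx"),
    y_um = vapply(placed, `[[`, 0, "cy"),
    a_um = vapply(placed, `[[`, 0, "a"),
    b_um = vapply(placed, `[[`, 0, "b"),
    theta = vapply(placed, `[[`, 0, "theta"),
    radius_um = vapply(placed, `[[`, 0, "r"),
    hema_od = vapply(placed, `[[`, 0, "od"),
    pair = vapply(placed, `[[`, NA_integer_, "pair"),
    nucleus_area_um2 = npix * mpp^2,
    polygon = lapply(placed, function(cl)
      ellipse_polygon(cl$cx, cl$cy, cl$a, cl$b, cl$theta))
  )

  class_areas <- cells_tbl |>
    dplyr::group_by(.data$class, .drop = FALSE) |>
    dplyr::summarise(area_um2 = sum(.data$nucleus_area_um2), .groups = "drop")

  region <- region_annotation(list(cbind(
    x = c(0, spec$width_um, spec$width_um, 0),
    y = c(0, 0, spec$height_um, spec$height_um))))
  region_area <- spec$width_um * spec$height_um
  tumor_area <- class_areas$area_um2[class_areas$class == "tumor"]
  lymph_area <- class_areas$area_um2[class_areas$class == "lymphocyte"]
  eastils_true <- 100 * lymph_area / (region_area - tumor_area)

  truth <- structure(
    list(cells = cells_tbl, class_areas = class_areas, region = region,
         region_area_um2 = region_area, eastils_true = eastils_true,
         nucleus_labels = labels, microns_per_pixel = mpp),
    class = "tile_truth"
  )
  list(tile = he_tile(rgb, mpp), truth = truth)
}

#' @export
print.tile_truth <- function(x, ...) {
  cat(sprintf("<tile_truth> %d planted cells, true easTILs%% = %.3f\n",
              nrow(x$cells), x$eastils_true))
  print(x$class_areas)
  invisible(x)
}

#' Simulate separable per-cell feature vectors
#'
#' Draws feature vectors directly in feature space from class-conditional
#' Gaussians whose means follow [default_morphology()]. Used to exercise the
#' cell classifier at sample sizes that would be costly to reach by rendering
#' and segmenting tiles.
#'
#' @param n_per_class samples per class.
#' @param separation multiplier on between-class mean differences (1 =
#'   default, 0 = all classes identical).
#' @param seed RNG seed.
#' @return Tibble with a `class` factor and numeric feature columns.
#' @export
simulate_cell_features <- function(n_per_class = 500, separation = 1,
                                   seed = NULL) {
  with_seed(seed, {
    morph <- default_morphology()
    base <- lapply(cell_classes(), function(cl) {
      m <- morph[[cl]]
      mu0 <- c(nucleus_area_um2 = pi * m$radius_um^2,
               eccentricity = m$eccentricity,
               circularity = 1 - 0.6 * m$eccentricity^2,
               nuc_hema_mean = m$hema_od,
               nuc_hema_max = m$hema_od * 1.1,
               nuc_eosin_mean = 0.03,
               ring_eosin_mean = 0.15,
               max_caliper_um = 2 * m$radius_um / (1 - m$eccentricity^2)^0.25,
               cell_nucleus_ratio = (m$radius_um + 5)^2 / m$radius_um^2)
      mu <- separation * mu0 + (1 - separation) *
        c(60, 0.45, 0.8, 0.75, 0.85, 0.03, 0.15, 9, 6)
      sds <- abs(mu0) * 0.08 + 0.01
      feat <- vapply(seq_along(mu),
                     function(j) rnorm(n_per_class, mu[j], sds[j]),
                     numeric(n_per_class))
      colnames(feat) <- names(mu0)
      noise <- matrix(rnorm(n_per_class * 3), n_per_class, 3,
                      dimnames = list(NULL, paste0("noise_", 1:3)))
      tibble::as_tibble(cbind(feat, noise)) |>
        dplyr::mutate(class = factor(cl, levels = cell_classes()),
                      .before = 1)
    })
    dplyr::bind_rows(base)
  })
}
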