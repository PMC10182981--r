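# Synthetic single-channel OD image with one or more planted disks.
make_disk_image <- function(disks, od = 0.8, bg = 0.02, mpp = 0.4986,
                            width_px = 120, height_px = width_px) {
  h <- matrix(bg, height_px, width_px)
  xs <- (seq_len(width_px) - 0.5) * mpp
  ys <- (seq_len(height_px) - 0.5) * mpp
  for (d in disks) {
    dx <- outer(rep(1, height_px), xs - d$x)
    dy <- outer(ys - d$y, rep(1, width_px))
    a <- if (is.null(d$a)) d$r else d$a
    b <- if (is.null(d$b)) d$r else d$b
    h[(dx / a)^2 + (dy / b)^2 <= 1] <- bg + if (is.null(d$od)) od else d$od
  }
  od_image(h, "hematoxylin", mpp)
}

disk_of_area <- function(area_um2, x = 30, y = 30, od = NULL) {
  list(x = x, y = y, r = sqrt(area_um2 / pi), od = od)
}

# Independent point-in-polygon oracle: crossing number with an explicit
# on-boundary check (boundary counts as inside).
crossing_number_inside <- function(px, py, poly, eps = 1e-9) {
  n <- nrow(poly)
  # on-boundary?
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    ax <- poly[i, 1]; ay <- poly[i, 2]; bx <- poly[j, 1]; by <- poly[j, 2]
    vx <- bx - ax; vy <- by - ay
    L2 <- vx^2 + vy^2
    t <- if (L2 == 0) 0 else min(max(((px - ax) * vx + (py - ay) * vy) / L2, 0), 1)
    if ((ax + t * vx - px)^2 + (ay + t * vy - py)^2 <= eps^2) return(TRUE)
  }
  cn <- 0L
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    ax <- poly[i, 1]; ay <- poly[i, 2]; bx <- poly[j, 1]; by <- poly[j, 2]
    if ((ay <= py) != (by <= py)) {
      xint <- ax + (py - ay) / (by - ay) * (bx - ax)
      if (px < xint) cn <- cn + 1L
    }
  }
  cn %% 2L == 1L
}

# Exact two-sided Mann-Whitney p by full enumeration of group labelings.
enumerate_mw_p <- function(a, b) {
  n1 <- length(a); n <- n1 + length(b)
  vals <- c(a, b)
  u_of <- function(idx) {
    x <- vals[idx]; y <- vals[-idx]
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  }
  u_obs <- u_of(seq_len(n1))
  combs <- utils::combn(n, n1)
  us <- apply(combs, 2, u_of)
  mu <- n1 * (n - n1) / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}

# Exact two-sided Wilcoxon signed-rank p by enumeration of all sign flips.
enumerate_wilcoxon_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vs <- signs %*% r
  mean(abs(vs - mu) >= abs(v_obs - mu) - 1e-12)
}

# Small, fast tile spec for pipeline-level tests.
small_tile_spec <- function(seed, ...) {
  tile_spec(width_um = 140, height_um = 140, n_tumor = 7, n_lymphocyte = 14,
            n_stromal = 6, n_other = 4, seed = seed, ...)
}

# Train a small pipeline classifier once per session and cache it.
cached_tile_model <- local({
  model <- NULL
  function() {
    if (is.null(model)) {
      rows <- lapply(1:8, function(i) {
        g <- generate_tile(tile_spec(seed = 7000 + i))
        cs <- match_to_truth(process_tile(g$tile)$cells, g$truth)
        tb <- cs$cells[!is.na(cs$cells$true_class), ]
        tb$class <- tb$true_class
        tb
      })
      model <<- train_cell_classifier(dplyr::bind_rows(rows), seed = 11)
    }
    model
  }
})
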