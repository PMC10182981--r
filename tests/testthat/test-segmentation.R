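test_that("a single planted disk is detected with area within 20%", {
  cs <- detect_nuclei(make_disk_image(list(disk_of_area(50))))
  expect_equal(nrow(cs$cells), 1)
  expect_lt(abs(cs$cells$nucleus_area_um2 - 50) / 50, 0.20)
  expect_lt(abs(cs$cells$x_um - 30), 1)
  expect_lt(abs(cs$cells$y_um - 30), 1)
})

test_that("a disk below the minimum cell area is rejected", {
  cs <- detect_nuclei(make_disk_image(list(disk_of_area(8))))
  expect_equal(nrow(cs$cells), 0)
})

test_that("the area window [10, 400] um^2 is enforced exactly", {
  # the large object is elongated (minor axis below the background radius)
  # so the opening-based background model does not swallow it
  img <- make_disk_image(list(disk_of_area(8, x = 15, y = 15),
                              disk_of_area(50, x = 45, y = 15),
                              list(x = 50, y = 45, a = 17, b = 350 / (pi * 17))),
                         width_px = 220)
  cs <- detect_nuclei(img)
  expect_true(all(cs$cells$nucleus_area_um2 >= 10 &
                    cs$cells$nucleus_area_um2 <= 400))
  expect_equal(nrow(cs$cells), 2)  # the 8 um^2 disk is below the floor
  # both bounds act on the measured area, exactly
  hi <- detect_nuclei(img, detection_params(max_cell_area_um2 = 300))
  expect_equal(nrow(hi$cells), 1)
  expect_lt(hi$cells$nucleus_area_um2, 300)
  lo <- detect_nuclei(img, detection_params(min_cell_area_um2 = 60))
  expect_equal(nrow(lo$cells), 1)
  expect_gt(lo$cells$nucleus_area_um2, 60)
})

test_that("an empty image yields an empty cell set, not an error", {
  cs <- detect_nuclei(od_image(matrix(0, 80, 80), "hematoxylin", 0.5))
  expect_equal(nrow(cs$cells), 0)
})

test_that("missing calibration is an error", {
  expect_error(detect_nuclei(od_image(matrix(0, 10, 10), "hematoxylin", 1e-12)))
})

test_that("touching nuclei are split by the watershed", {
  img <- make_disk_image(list(list(x = 47, y = 50, r = 2.5),
                              list(x = 53, y = 50, r = 2.5)),
                         od = 0.9, width_px = 200)
  cs <- detect_nuclei(img)
  expect_equal(nrow(cs$cells), 2)
  expect_true(all(abs(cs$cells$nucleus_area_um2 - pi * 2.5^2) /
                    (pi * 2.5^2) < 0.25))
})

test_that("pair-mode planted nuclei are recovered as two detections", {
  g <- generate_tile(tile_spec(n_tumor = 0, n_lymphocyte = 0, n_stromal = 0,
                               n_other = 0, n_pairs = 4,
                               pair_spacing_um = 5.5, noise_sd = 0.01,
                               seed = 31))
  pr <- process_tile(g$tile)
  expect_equal(nrow(pr$cells$cells), 8)
})

test_that("detections with excessive local background OD are suppressed", {
  img <- make_disk_image(list(disk_of_area(50)), od = 0.8, bg = 2.5)
  cs <- detect_nuclei(img, detection_params(max_background_od = 2))
  expect_equal(nrow(cs$cells), 0)
  cs2 <- detect_nuclei(img, detection_params(max_background_od = 5))
  expect_equal(nrow(cs2$cells), 1)
})

test_that("detection is invariant to whole-pixel translation", {
  mpp <- 0.5
  base <- matrix(0.02, 160, 160)
  r <- sqrt(50 / pi)
  xs <- (seq_len(160) - 0.5) * mpp
  put_disk <- function(img, cx, cy) {
    dx <- outer(rep(1, 160), xs - cx); dy <- outer(xs - cy, rep(1, 160))
    img[dx^2 + dy^2 <= r^2] <- 0.85
    img
  }
  shift_px <- 14
  cs1 <- detect_nuclei(od_image(put_disk(base, 30, 30), "hematoxylin", mpp))
  cs2 <- detect_nuclei(od_image(put_disk(base, 30 + shift_px * mpp,
                                         30 + shift_px * mpp),
                                "hematoxylin", mpp))
  expect_equal(cs2$cells$x_um - cs1$cells$x_um, shift_px * mpp,
               tolerance = 1e-9)
  expect_equal(cs2$cells$y_um - cs1$cells$y_um, shift_px * mpp,
               tolerance = 1e-9)
  expect_equal(cs1$cells$nucleus_area_um2, cs2$cells$nucleus_area_um2)
})

test_that("detection recall and precision are 1.0 on well-separated tiles", {
  for (s in 1:5) {
    g <- generate_tile(small_tile_spec(seed = 500 + s))
    cs <- match_to_truth(process_tile(g$tile)$cells, g$truth)
    perf <- detection_performance(cs, g$truth)
    expect_equal(perf$recall, 1)
    expect_equal(perf$precision, 1)
  }
})

test_that("an isolated nucleus expands to approximately pi (r + 5)^2", {
  r <- 4
  cs <- detect_nuclei(make_disk_image(list(list(x = 30, y = 30, r = r))))
  cs <- expand_cells(cs)
  expect_equal(cs$cells$cell_area_um2, pi * (r + 5)^2, tolerance = 0.05)
  expect_gte(cs$cells$cell_area_um2, cs$cells$nucleus_area_um2)
})

test_that("zero expansion leaves the cell equal to the nucleus", {
  cs <- detect_nuclei(make_disk_image(list(disk_of_area(50))))
  cs <- expand_cells(cs, detection_params(cell_expansion_um = 0))
  expect_identical(cs$cell_labels, cs$nucleus_labels)
  expect_equal(cs$cells$cell_area_um2, cs$cells$nucleus_area_um2)
})

test_that("expansion partitions pixels by nearest nucleus (brute force)", {
  # hand-built nuclei 4 um apart (centres), exercising the shared boundary
  mpp <- 0.5
  nuc <- matrix(0L, 120, 120)
  xs <- (seq_len(120) - 0.5) * mpp
  put <- function(cx, cy, r, id) {
    dx <- outer(rep(1, 120), xs - cx); dy <- outer(xs - cy, rep(1, 120))
    nuc[dx^2 + dy^2 <= r^2] <<- id
  }
  put(28, 30, 2.5, 1L); put(32, 30, 2.5, 2L)
  # keep the nuclei disjoint: the overlap zone splits at the midline
  xmat <- outer(rep(1, 120), xs)
  nuc[nuc > 0L & xmat <= 30] <- 1L
  nuc[nuc > 0L & xmat > 30] <- 2L
  cells <- tibble::tibble(
    cell = 1:2, x_um = c(28, 32), y_um = c(30, 30),
    nucleus_area_um2 = tabulate(nuc[nuc > 0], 2) * mpp^2,
    nucleus_poly = list(NULL, NULL))
  cs <- cell_set(cells, nuc, NULL, mpp)
  cs <- expand_cells(cs)
  lab <- cs$cell_labels
  nuc <- cs$nucleus_labels
  mpp <- cs$microns_per_pixel
  # brute force: for every labelled pixel, nearest nucleus pixel decides
  idx_n <- which(nuc > 0L, arr.ind = TRUE)
  lab_n <- nuc[nuc > 0L]
  idx_c <- which(lab > 0L, arr.ind = TRUE)
  exp_px <- 5 / mpp
  for (k in seq_len(nrow(idx_c))) {
    d2 <- (idx_n[, 1] - idx_c[k, 1])^2 + (idx_n[, 2] - idx_c[k, 2])^2
    expect_equal(lab[idx_c[k, 1], idx_c[k, 2]], lab_n[which.min(d2)])
    expect_lte(sqrt(min(d2)), exp_px)
  }
  # total constrained area < sum of two unconstrained expansions
  expect_lt(sum(cs$cells$cell_area_um2), 2 * pi * (2.5 + 5)^2)
  # cells partition their union: labels are exclusive by construction
  expect_equal(sum(cs$cell_labels == 1) + sum(cs$cell_labels == 2),
               sum(cs$cell_labels > 0))
})

test_that("nuclei always lie inside their expanded cells", {
  g <- generate_tile(small_tile_spec(seed = 77))
  pr <- process_tile(g$tile)
  nuc <- pr$cells$nucleus_labels
  cell <- pr$cells$cell_labels
  pos <- nuc > 0L
  expect_true(all(cell[pos] == nuc[pos]))
})
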