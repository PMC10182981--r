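square_region <- function(w = 100) {
  region_annotation(list(cbind(x = c(0, w, w, 0), y = c(0, 0, w, w))))
}

test_that("region membership matches the crossing-number oracle", {
  set.seed(30)
  poly <- cbind(x = c(10, 90, 80, 50, 15), y = c(10, 20, 85, 60, 70))
  region <- region_annotation(list(poly))
  px <- runif(300, 0, 100); py <- runif(300, 0, 100)
  got <- eastils:::in_region(px, py, region)
  want <- vapply(seq_along(px), function(i)
    crossing_number_inside(px[i], py[i], poly), TRUE)
  expect_equal(got, want)
})

test_that("a centroid exactly on the boundary is inside", {
  region <- square_region(100)
  expect_true(eastils:::in_region(50, 0, region))
  expect_true(eastils:::in_region(0, 0, region))
  expect_true(eastils:::in_region(100, 37.5, region))
})

test_that("cells in exclusion holes are dropped", {
  region <- region_annotation(
    list(cbind(x = c(0, 100, 100, 0), y = c(0, 0, 100, 100))),
    holes = list(cbind(x = c(40, 60, 60, 40), y = c(40, 40, 60, 60))))
  expect_false(eastils:::in_region(50, 50, region))
  expect_true(eastils:::in_region(20, 20, region))
  expect_equal(region$area_um2, 100^2 - 20^2)
})

test_that("assign_cells_to_region filters cells and masks consistently", {
  g <- generate_tile(small_tile_spec(seed = 41))
  pr <- process_tile(g$tile)
  cs <- pr$cells
  cs$cells$class <- factor("tumor", levels = cell_classes())
  half <- region_annotation(list(cbind(x = c(0, 70, 70, 0),
                                       y = c(0, 0, 140, 140))))
  csr <- assign_cells_to_region(cs, half)
  expect_true(all(csr$cells$x_um <= 70))
  kept <- csr$cells$cell
  expect_true(all(unique(csr$nucleus_labels[csr$nucleus_labels > 0]) %in% kept))
})

test_that("the easTILs% arithmetic follows its formula", {
  s <- tibble::tibble(region_area_mm2 = 12, tumor_area_mm2 = 4,
                      lymphocyte_area_mm2 = 2, stromal_cell_area_mm2 = 1,
                      other_area_mm2 = 0.5, stromal_area_mm2 = 8)
  expect_equal(compute_eastils(s), 25.0)
  s$lymphocyte_area_mm2 <- 0
  expect_equal(compute_eastils(s), 0)
  s$stromal_area_mm2 <- 0
  expect_error(compute_eastils(s), "stromal")
})

test_that("region area sums over disjoint polygons", {
  two <- region_annotation(list(
    cbind(x = c(0, 10, 10, 0), y = c(0, 0, 10, 10)),
    cbind(x = c(20, 35, 35, 20), y = c(0, 0, 10, 10))))
  expect_equal(two$area_um2, 100 + 150)
})

test_that("per-class area sums recover planted areas within 10%", {
  g <- generate_tile(small_tile_spec(seed = 42))
  pr <- process_tile(g$tile)
  cs <- match_to_truth(pr$cells, g$truth)
  cs$cells$class <- cs$cells$true_class
  csr <- assign_cells_to_region(cs, g$truth$region)
  s <- summarize_areas(csr, area_basis = "nucleus")
  truth <- g$truth$class_areas
  cols <- c(tumor = "tumor_area_mm2", lymphocyte = "lymphocyte_area_mm2",
            stromal = "stromal_cell_area_mm2", other = "other_area_mm2")
  for (cl in cell_classes()) {
    want <- truth$area_um2[truth$class == cl] / 1e6
    got <- s[[cols[[cl]]]]
    expect_lt(abs(got - want) / want, 0.10)
  }
})

test_that("summarize_areas demands classified cells and conserves area", {
  g <- generate_tile(small_tile_spec(seed = 43))
  pr <- process_tile(g$tile)
  cs <- assign_cells_to_region(pr$cells, g$truth$region)
  expect_error(summarize_areas(cs), "unclassified")
  cs$cells$class <- factor("lymphocyte", levels = cell_classes())
  s <- summarize_areas(cs)
  total_cells <- s$tumor_area_mm2 + s$lymphocyte_area_mm2 +
    s$stromal_cell_area_mm2 + s$other_area_mm2
  expect_lte(total_cells, s$region_area_mm2)
})

test_that("no cells means zero class areas and stromal = region", {
  cs <- detect_nuclei(od_image(matrix(0, 100, 100), "hematoxylin", 0.5))
  cs <- expand_cells(cs)
  cs$cells$class <- factor(character(), levels = cell_classes())
  s <- summarize_areas(cs, square_region(50))
  expect_equal(s$lymphocyte_area_mm2, 0)
  expect_equal(s$tumor_area_mm2, 0)
  expect_equal(s$stromal_area_mm2, s$region_area_mm2)
})

test_that("easTILs% is invariant to coordinate scaling", {
  s <- tibble::tibble(lymphocyte_area_mm2 = 2, stromal_area_mm2 = 8)
  k <- 3.7
  s_scaled <- tibble::tibble(lymphocyte_area_mm2 = 2 * k^2,
                             stromal_area_mm2 = 8 * k^2)
  expect_equal(compute_eastils(s), compute_eastils(s_scaled))
})

test_that("adding a lymphocyte never decreases easTILs%", {
  s <- tibble::tibble(lymphocyte_area_mm2 = 2, stromal_area_mm2 = 8)
  s2 <- s; s2$lymphocyte_area_mm2 <- s2$lymphocyte_area_mm2 + 0.5
  expect_gte(compute_eastils(s2), compute_eastils(s))
})

test_that("dichotomization follows the strict-greater rule at both cutoffs", {
  expect_equal(as.character(dichotomize_tils(19.9, 19.9)), "low")
  expect_equal(as.character(dichotomize_tils(20.0, 19.9)), "high")
  expect_equal(as.character(dichotomize_tils(20.0, 20)), "low")   # sTILs rule
  expect_equal(as.character(dichotomize_tils(c(0, 19.9, 19.91))),
               c("low", "low", "high"))
  expect_error(dichotomize_tils(-1))
})
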