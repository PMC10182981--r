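test_that("an empty spec yields a uniform stroma tile with easTILs% = 0", {
  g <- generate_tile(tile_spec(n_tumor = 0, n_lymphocyte = 0, n_stromal = 0,
                               n_other = 0, noise_sd = 0, seed = 1))
  expect_equal(nrow(g$truth$cells), 0)
  expect_equal(g$truth$eastils_true, 0)
  # uniform: every pixel identical per channel
  for (ch in 1:3) expect_equal(length(unique(as.vector(g$tile$rgb[, , ch]))), 1)
})

test_that("tiles are bit-identical under a fixed seed", {
  g1 <- generate_tile(tile_spec(seed = 42))
  g2 <- generate_tile(tile_spec(seed = 42))
  expect_identical(g1$tile$rgb, g2$tile$rgb)
  expect_identical(g1$truth$cells$x_um, g2$truth$cells$x_um)
  expect_identical(g1$truth$class_areas, g2$truth$class_areas)
})

test_that("planted per-class areas match an independent rasterization oracle", {
  sp <- tile_spec(n_tumor = 0, n_lymphocyte = 50, n_stromal = 0, n_other = 0,
                  morphology = modifyList(default_morphology(),
                                          list(lymphocyte = list(
                                            radius_um = 2.5, radius_sd = 0,
                                            eccentricity = 0, hema_od = 0.9))),
                  seed = 3)
  g <- generate_tile(sp)
  tr <- g$truth$cells
  mpp <- g$truth$microns_per_pixel
  ncol_px <- round(sp$width_um / mpp); nrow_px <- round(sp$height_um / mpp)
  xs <- (seq_len(ncol_px) - 0.5) * mpp
  ys <- (seq_len(nrow_px) - 0.5) * mpp
  # brute-force pixel counting per planted ellipse
  oracle_px <- vapply(seq_len(nrow(tr)), function(i) {
    dx <- outer(rep(1, nrow_px), xs - tr$x_um[i])
    dy <- outer(ys - tr$y_um[i], rep(1, ncol_px))
    th <- tr$theta[i]
    u <- (dx * cos(th) + dy * sin(th)) / tr$a_um[i]
    v <- (-dx * sin(th) + dy * cos(th)) / tr$b_um[i]
    sum(u^2 + v^2 <= 1)
  }, 0)
  expect_equal(tr$nucleus_area_um2, oracle_px * mpp^2)
  lymph_sum <- g$truth$class_areas$area_um2[
    g$truth$class_areas$class == "lymphocyte"]
  expect_equal(lymph_sum, sum(oracle_px) * mpp^2)
})

test_that("stored easTILs% equals the value recomputed from ground-truth areas", {
  for (s in 1:5) {
    g <- generate_tile(small_tile_spec(seed = s))
    ca <- g$truth$class_areas
    lymph <- ca$area_um2[ca$class == "lymphocyte"]
    tum <- ca$area_um2[ca$class == "tumor"]
    expect_equal(g$truth$eastils_true,
                 100 * lymph / (g$truth$region_area_um2 - tum),
                 tolerance = 1e-9)
    expect_true(g$truth$eastils_true >= 0 && g$truth$eastils_true <= 100)
    expect_lte(sum(ca$area_um2), g$truth$region_area_um2)
  }
})

test_that("an overcrowded spec signals an error rather than overlapping cells", {
  sp <- tile_spec(width_um = 40, height_um = 40, n_tumor = 80,
                  n_lymphocyte = 0, n_stromal = 0, n_other = 0,
                  max_retries = 50, seed = 1)
  expect_error(generate_tile(sp), "overcrowded")
})

test_that("pair mode plants two nuclei at the requested spacing", {
  sp <- tile_spec(n_tumor = 0, n_lymphocyte = 0, n_stromal = 0, n_other = 0,
                  n_pairs = 3, pair_spacing_um = 4.5, seed = 9)
  g <- generate_tile(sp)
  expect_equal(nrow(g$truth$cells), 6)
  for (p in 1:3) {
    pr <- g$truth$cells[which(g$truth$cells$pair == p), ]
    d <- sqrt(diff(pr$x_um)^2 + diff(pr$y_um)^2)
    expect_equal(d, 4.5, tolerance = 1e-9)
  }
})

test_that("empty cohorts and invalid sizes behave as specified", {
  expect_equal(nrow(generate_cohort(cohort_spec(n_patients = 0))), 0)
  expect_error(cohort_spec(n_patients = -1), "n_patients")
})

test_that("cohorts are reproducible and respect invariants", {
  c1 <- generate_cohort(cohort_spec(seed = 5))
  c2 <- generate_cohort(cohort_spec(seed = 5))
  expect_identical(c1, c2)
  expect_true(all(c1$eastils_percent >= 0))
  expect_true(all(c1$stils_percent >= 0 & c1$stils_percent <= 100))
  expect_true(all(c1$efs_months > 0))
  expect_type(c1$pcr, "logical")
})

test_that("logistic cohort model with slope 0 recovers the intercept rate", {
  ch <- generate_cohort(cohort_spec(n_patients = 5000, model = "logistic",
                                    logistic_intercept = qlogis(0.3),
                                    logistic_slope = 0, seed = 21))
  p_hat <- mean(ch$pcr)
  se <- sqrt(0.3 * 0.7 / 5000)
  expect_lt(abs(p_hat - 0.3), 4 * se)
})

test_that("group-median cohorts recover the specified medians", {
  ch <- generate_cohort(cohort_spec(n_patients = 2000, pcr_rate = 0.5,
                                    seed = 8))
  med_pcr <- median(ch$eastils_percent[ch$pcr])
  med_rd <- median(ch$eastils_percent[!ch$pcr])
  # lognormal median resampling error at n ~ 1000 per group
  expect_lt(abs(med_pcr - 36.1) / 36.1, 0.10)
  expect_lt(abs(med_rd - 14.8) / 14.8, 0.10)
})
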