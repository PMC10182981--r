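mw_df <- function(a, b) {
  tibble::tibble(score = c(a, b),
                 grp = rep(c("A", "B"), c(length(a), length(b))))
}

test_that("Mann-Whitney: fully separated small groups give U = 0, p = 0.1", {
  r <- tils_mann_whitney(mw_df(1:3, 4:6), score, grp)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 0.1, tolerance = 1e-12)
})

test_that("Mann-Whitney: identical multisets give U = n^2/2, p = 1", {
  r <- tils_mann_whitney(mw_df(c(1, 2, 3), c(1, 2, 3)), score, grp)
  expect_equal(r$statistic, 4.5)
  expect_equal(r$p_value, 1)
  rd <- tils_mann_whitney(mw_df(rep(5, 4), rep(5, 4)), score, grp)
  expect_equal(rd$p_value, 1)
  expect_match(rd$note, "identical")
})

test_that("Mann-Whitney exact p matches full enumeration to 1e-12", {
  set.seed(50)
  for (k in 1:5) {
    a <- round(rnorm(6), 6); b <- round(rnorm(6) + 0.5, 6)
    r <- tils_mann_whitney(mw_df(a, b), score, grp)
    expect_equal(r$p_value, enumerate_mw_p(a, b), tolerance = 1e-12)
  }
  # also at n = 8 and unbalanced
  a <- rnorm(8); b <- rnorm(5)
  r <- tils_mann_whitney(mw_df(a, b), score, grp)
  expect_equal(r$p_value, enumerate_mw_p(a, b), tolerance = 1e-12)
})

test_that("Wilcoxon signed-rank: uniform decrease over 8 pairs gives p = 2/2^8", {
  d <- tibble::tibble(pre = c(10, 12, 9, 14, 11, 13, 8, 15))
  d$post <- d$pre - runif(8, 0.5, 2)
  r <- tils_wilcoxon_paired(d, pre, post)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 0.0078125, tolerance = 1e-12)
})

test_that("Wilcoxon signed-rank matches the sign-flip enumeration oracle", {
  set.seed(51)
  for (k in 1:4) {
    pre <- rnorm(10); post <- pre + rnorm(10, 0.3)
    d <- tibble::tibble(pre = pre, post = post)
    r <- tils_wilcoxon_paired(d, pre, post)
    expect_equal(r$p_value, enumerate_wilcoxon_p(post - pre),
                 tolerance = 1e-12)
  }
})

test_that("Wilcoxon conventions: zero differences dropped, all-zero flagged", {
  d <- tibble::tibble(pre = c(1, 2, 3, 4, 5), post = c(1, 2, 4, 5, 7))
  r <- tils_wilcoxon_paired(d, pre, post)
  expect_equal(r$n_informative, 3)
  r0 <- tils_wilcoxon_paired(tibble::tibble(pre = 1:4, post = 1:4), pre, post)
  expect_equal(r0$p_value, 1)
  expect_match(r0$note, "zero")
})

test_that("Pearson correlation handles exact and degenerate cases", {
  d <- tibble::tibble(x = 1:10, y = 2 * (1:10) + 1)
  expect_equal(tils_pearson(d, x, y)$estimate, 1, tolerance = 1e-12)
  set.seed(52)
  x <- rnorm(50)
  y0 <- rnorm(50)
  # residualizing against x makes the sample correlation exactly zero
  d2 <- tibble::tibble(x = x, y = stats::resid(stats::lm(y0 ~ x)))
  expect_lt(abs(tils_pearson(d2, x, y)$estimate), 1e-12)
  expect_error(tils_pearson(tibble::tibble(x = rep(1, 5), y = rnorm(5)), x, y),
               "variance")
})

test_that("simulated cohorts with target r = 0.6 are recovered across seeds", {
  covered <- 0
  for (s in 1:20) {
    set.seed(600 + s)
    n <- 113
    x <- rnorm(n)
    y <- 0.6 * x + sqrt(1 - 0.36) * rnorm(n)
    r <- tils_pearson(tibble::tibble(x = x, y = y), x, y)
    if (r$conf_low <= 0.6 && 0.6 <= r$conf_high) covered <- covered + 1
  }
  expect_gte(covered, 17)  # ~95% coverage over 20 seeds
})

test_that("chi-square matches the closed form on hand-computed tables", {
  r0 <- tils_chisq_2x2(matrix(c(10, 10, 10, 10), 2))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)

  tab <- matrix(c(20, 5, 10, 25), 2)  # rows: groups; cols: outcome
  # closed form: sum (O - E)^2 / E
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  chi <- sum((tab - E)^2 / E)
  r <- tils_chisq_2x2(tab)
  expect_equal(r$statistic, chi, tolerance = 1e-12)
  expect_equal(r$statistic, 108 / 7, tolerance = 1e-12)  # 15.43 by hand
  expect_equal(r$p_value, pchisq(108 / 7, 1, lower.tail = FALSE),
               tolerance = 1e-12)

  # statistic is homogeneous of degree 1 in the counts
  r10 <- tils_chisq_2x2(tab * 10)
  expect_equal(r10$statistic, 10 * r$statistic, tolerance = 1e-9)
  expect_error(tils_chisq_2x2(matrix(c(0, 0, 5, 5), 2)), "margin")
})

test_that("AUC equals U/(n1 n0) from the Mann-Whitney statistic, exactly", {
  set.seed(53)
  for (k in 1:5) {
    n1 <- sample(5:30, 1); n0 <- sample(5:30, 1)
    sc <- c(round(rnorm(n1, 1), 1), round(rnorm(n0), 1))  # ties likely
    oc <- rep(c(TRUE, FALSE), c(n1, n0))
    d <- tibble::tibble(score = sc, outcome = oc)
    roc <- tils_roc(d, score, outcome)
    u <- suppressWarnings(wilcox.test(sc[oc], sc[!oc], exact = FALSE))$statistic
    expect_equal(roc$auc, unname(u) / (n1 * n0), tolerance = 1e-12)
  }
})

test_that("ROC handles the degenerate extremes", {
  d <- tibble::tibble(score = c(1, 2, 3, 11, 12, 13),
                      outcome = rep(c(FALSE, TRUE), each = 3))
  expect_equal(tils_roc(d, score, outcome)$auc, 1.0)
  expect_error(tils_roc(tibble::tibble(score = 1:5,
                                       outcome = rep(TRUE, 5)),
                        score, outcome), "class")
  set.seed(54)
  big <- tibble::tibble(score = rnorm(4000),
                        outcome = rep(c(TRUE, FALSE), 2000))
  expect_lt(abs(tils_roc(big, score, outcome)$auc - 0.5), 0.03)
})

test_that("DeLong variance and paired test agree with the pROC reference", {
  skip_if_not_installed("pROC")
  set.seed(55)
  n <- 150
  x <- rnorm(n)
  oc <- runif(n) < plogis(1.2 * x)
  a <- x + rnorm(n, 0, 0.8)
  b <- 0.5 * x + rnorm(n, 0, 1)
  d <- tibble::tibble(a = a, b = b, outcome = oc)

  roc_mine <- tils_roc(d, a, outcome)
  ref <- pROC::roc(oc, a, quiet = TRUE, direction = "<")
  expect_equal(roc_mine$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
  expect_equal(roc_mine$variance, pROC::var(ref, method = "delong"),
               tolerance = 1e-10)

  mine <- tils_delong_test(d, a, b, outcome)
  ref2 <- pROC::roc.test(pROC::roc(oc, a, quiet = TRUE, direction = "<"),
                         pROC::roc(oc, b, quiet = TRUE, direction = "<"),
                         method = "delong", paired = TRUE)
  expect_equal(mine$statistic, unname(ref2$statistic), tolerance = 1e-10)
  expect_equal(mine$p_value, ref2$p.value, tolerance = 1e-10)
})

test_that("DeLong test is invariant under monotone transforms", {
  set.seed(56)
  d <- tibble::tibble(a = rnorm(80, 1), outcome = rep(c(TRUE, FALSE), 40))
  d$b <- exp(d$a)  # monotone transform, identical ranks
  r <- tils_delong_test(d, a, b, outcome)
  expect_equal(r$auc_diff, 0)
  expect_equal(r$p_value, 1)
  r2 <- tils_delong_test(d, a, a, outcome)
  expect_equal(r2$p_value, 1)
})

test_that("Kaplan-Meier reduces to the hand product-limit estimate", {
  d <- tibble::tibble(t = c(1, 2, 3), e = c(TRUE, TRUE, TRUE))
  km <- tils_km(d, t, e)
  tb <- tidy(km)
  expect_equal(tb$survival[tb$time == 2], 1 / 3, tolerance = 1e-12)  # 2/3 * 1/2
  expect_equal(tb$survival, c(2 / 3, 1 / 3, 0), tolerance = 1e-12)
})

test_that("KM equals the empirical survivor function without censoring", {
  set.seed(57)
  t <- round(rexp(40, 0.1), 2) + 0.01
  d <- tibble::tibble(t = t, e = TRUE)
  tb <- tidy(tils_km(d, t, e))
  for (i in seq_len(nrow(tb))) {
    expect_equal(tb$survival[i], mean(t > tb$time[i]), tolerance = 1e-12)
  }
})

test_that("log-rank conventions: no events and duplicated groups give p = 1", {
  d0 <- tibble::tibble(t = c(5, 6, 7, 8), e = FALSE,
                       g = c("a", "a", "b", "b"))
  km0 <- tils_km(d0, t, e, g)
  expect_equal(km0$p_value, 1)
  expect_true(all(tidy(km0)$survival == 1))

  set.seed(58)
  base <- tibble::tibble(t = rexp(30, 0.05) + 0.1, e = runif(30) < 0.7)
  dup <- dplyr::bind_rows(dplyr::mutate(base, g = "a"),
                          dplyr::mutate(base, g = "b"))
  expect_equal(tils_km(dup, t, e, g)$p_value, 1, tolerance = 1e-9)
  expect_error(tils_km(tibble::tibble(t = c(-1, 2, 3), e = TRUE), t, e),
               "positive")
})

test_that("logistic regression: intercept-only model recovers logit(rate)", {
  d <- tibble::tibble(y = rep(c(TRUE, FALSE), c(30, 70)))
  fit <- tils_logistic(d, y ~ 1)
  expect_equal(tidy(fit)$estimate, qlogis(0.3), tolerance = 1e-6)
})

test_that("logistic regression recovers known coefficients within 2 SE", {
  set.seed(59)
  n <- 2000
  x <- rnorm(n); z <- rbinom(n, 1, 0.5)
  beta <- c(-0.5, 0.8, -0.6)
  y <- runif(n) < plogis(beta[1] + beta[2] * x + beta[3] * z)
  fit <- tils_logistic(tibble::tibble(x = x, z = z, y = y), y ~ x + z)
  td <- tidy(fit)
  for (i in 1:3) {
    expect_lt(abs(td$estimate[i] - beta[i]), 2 * td$std_error[i] + 1e-9)
  }
})

test_that("separation and collinearity are reported as errors", {
  d <- tibble::tibble(x = c(rep(0, 20), rep(1, 20)),
                      y = c(rep(FALSE, 20), rep(TRUE, 20)))
  expect_error(tils_logistic(d, y ~ x), "separation")
  set.seed(60)
  d2 <- tibble::tibble(x = rnorm(50))
  d2$x2 <- 2 * d2$x
  d2$y <- runif(50) < plogis(d2$x)
  expect_error(tils_logistic(d2, y ~ x + x2), "collinear")
})

test_that("interaction terms are fit and testable through the formula", {
  ch <- generate_cohort(cohort_spec(n_patients = 400, seed = 61))
  fit <- tils_logistic(ch, pcr ~ eastils_percent * arm)
  td <- tidy(fit)
  expect_true(any(grepl(":", td$term)))
  expect_true(all(td$p_value >= 0 & td$p_value <= 1))
})

test_that("characteristics-table percentages match printed accounting", {
  expect_equal(table1_percentages(c(59, 152))[1], 28.0)
  expect_equal(table1_percentages(33, total = 113), 29.2)
  expect_equal(table1_percentages(c(0, 10))[1], 0)
  expect_error(table1_percentages(c(0, 0)), "total")
})

test_that("control-arm pooling collapses the control labels", {
  d <- tibble::tibble(arm = c("control_a", "control_b", "bev"))
  out <- pool_control_arms(d)
  expect_equal(out$arm, c("chemo", "chemo", "bev"))
})

test_that("stats procedures are invariant to row shuffling", {
  ch <- generate_cohort(cohort_spec(seed = 62))
  set.seed(63)
  sh <- ch[sample.int(nrow(ch)), ]
  expect_equal(tils_mann_whitney(ch, eastils_percent, pcr)$p_value,
               tils_mann_whitney(sh, eastils_percent, pcr)$p_value,
               tolerance = 1e-12)
  expect_equal(tils_roc(ch, eastils_percent, pcr)$auc,
               tils_roc(sh, eastils_percent, pcr)$auc, tolerance = 1e-12)
  expect_equal(tils_pearson(ch, eastils_percent, stils_percent)$estimate,
               tils_pearson(sh, eastils_percent, stils_percent)$estimate,
               tolerance = 1e-12)
})
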