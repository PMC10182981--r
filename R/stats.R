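#' Mann-Whitney test between two groups
#'
#' Two-sided Mann-Whitney U test for a score against a binary grouping, the
#' primary comparison of pretreatment TILs scores between pCR and residual
#' disease. Uses midranks for ties; the p-value is exact (full enumeration) when
#' both groups have at most `exact_max` observations and there are no ties, and
#' otherwise uses the normal approximation with tie correction. If every value
#' in both groups is identical the test is degenerate and `p = 1` is returned
#' with a note.
#'
#' @param data data frame.
#' @param score column with the score (tidy-eval).
#' @param group column with the two-level grouping (tidy-eval).
#' @param exact_max largest per-group n for which the exact distribution is
#'   enumerated (no ties).
#' @return One-row tibble: `statistic` (U of the first group vs the second),
#'   `p_value`, group medians and sizes, `method`, `note`.
#' @export
tils_mann_whitney <- function(data, score, group, exact_max = 8) {
  sc <- data[[as_name(enquo(score))]]
  gr <- data[[as_name(enquo(group))]]
  ok <- is.finite(sc) & !is.na(gr)
  sc <- sc[ok]; gr <- gr[ok]
  lev <- if (is.factor(gr)) levels(droplevels(gr)) else sort(unique(gr))
  if (length(lev) != 2) stop("group must have exactly 2 levels", call. = FALSE)
  a <- sc[gr == lev[1]]; b <- sc[gr == lev[2]]
  if (length(a) == 0 || length(b) == 0) stop("both groups must be nonempty", call. = FALSE)

  degenerate <- length(unique(c(a, b))) == 1
  if (degenerate) {
    u <- length(a) * length(b) / 2
    return(tibble::tibble(statistic = u, p_value = 1,
                          median_1 = median(a), median_2 = median(b),
                          n_1 = length(a), n_2 = length(b),
                          method = "mann-whitney",
                          note = "all values identical; p = 1 by convention"))
  }
  exact <- max(length(a), length(b)) <= exact_max && !any(duplicated(c(a, b)))
  wt <- suppressWarnings(wilcox.test(a, b, exact = exact, correct = !exact))
  tibble::tibble(statistic = unname(wt$statistic), p_value = wt$p.value,
                 median_1 = median(a), median_2 = median(b),
                 n_1 = length(a), n_2 = length(b),
                 method = if (exact) "mann-whitney (exact)" else
                   "mann-whitney (normal approximation, tie-corrected)",
                 note = NA_character_)
}

#' Wilcoxon matched-pairs signed-rank test
#'
#' Two-sided paired test for pre- versus post-treatment scores. Zero
#' differences are dropped (the standard signed-rank convention). Exact when at
#' most `exact_max` informative (non-zero) untied pairs remain, otherwise the
#' normal approximation. All-zero differences give `p = 1`, flagged.
#'
#' @param data data frame.
#' @param pre,post paired score columns (tidy-eval); rows with missing values
#'   in either are dropped.
#' @param exact_max largest number of informative pairs for the exact
#'   distribution.
#' @return One-row tibble: `statistic` (V, the positive-rank sum), `p_value`,
#'   `n_pairs`, `n_informative`, `method`, `note`.
#' @export
tils_wilcoxon_paired <- function(data, pre, post, exact_max = 15) {
  x <- data[[as_name(enquo(pre))]]
  y <- data[[as_name(enquo(post))]]
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) == 0) stop("no complete pairs", call. = FALSE)
  d <- y - x
  inf <- d[d != 0]
  if (length(inf) == 0) {
    return(tibble::tibble(statistic = 0, p_value = 1, n_pairs = length(d),
                          n_informative = 0L, method = "wilcoxon signed-rank",
                          note = "all differences zero; p = 1 by convention"))
  }
  exact <- length(inf) <= exact_max && !any(duplicated(abs(inf)))
  wt <- suppressWarnings(wilcox.test(y, x, paired = TRUE, exact = exact,
                                     correct = !exact))
  tibble::tibble(statistic = unname(wt$statistic), p_value = wt$p.value,
                 n_pairs = length(d), n_informative = length(inf),
                 method = if (exact) "wilcoxon signed-rank (exact)" else
                   "wilcoxon signed-rank (normal approximation)",
                 note = NA_character_)
}

#' Pearson correlation between two scores
#'
#' Pearson r with the two-sided t-based p-value; used to relate pathologist
#' sTILs% to the paired digital easTILs%.
#'
#' @param data data frame.
#' @param x,y numeric columns (tidy-eval); incomplete rows dropped.
#' @return One-row tibble: `estimate` (r), `statistic` (t), `p_value`,
#'   `conf_low`, `conf_high`, `n`.
#' @export
tils_pearson <- function(data, x, y) {
  xv <- data[[as_name(enquo(x))]]
  yv <- data[[as_name(enquo(y))]]
  ok <- is.finite(xv) & is.finite(yv)
  xv <- xv[ok]; yv <- yv[ok]
  if (length(xv) < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (sd(xv) == 0 || sd(yv) == 0) stop("zero variance input", call. = FALSE)
  ct <- cor.test(xv, yv, method = "pearson")
  tibble::tibble(estimate = unname(ct$estimate),
                 statistic = unname(ct$statistic), p_value = ct$p.value,
                 conf_low = ct$conf.int[1], conf_high = ct$conf.int[2],
                 n = length(xv))
}

#' Chi-square test on a 2x2 table
#'
#' Pearson chi-square (df = 1) comparing, e.g., pCR rates between dichotomized
#' TILs groups. No continuity correction by default (set `correct = TRUE` for
#' the Yates-corrected variant). All margins must be positive.
#'
#' @param table 2x2 matrix of nonnegative integer counts (rows = groups,
#'   columns = outcomes).
#' @param correct apply the Yates continuity correction.
#' @return One-row tibble: `statistic`, `p_value`, `df`, rates per row and
#'   row totals.
#' @export
tils_chisq_2x2 <- function(table, correct = FALSE) {
  if (!all(dim(table) == c(2, 2))) stop("need a 2x2 table", call. = FALSE)
  if (any(table < 0) || any(table != round(table))) {
    stop("counts must be nonnegative integers", call. = FALSE)
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("zero margin: test undefined", call. = FALSE)
  }
  ct <- suppressWarnings(chisq.test(table, correct = correct))
  tibble::tibble(statistic = unname(ct$statistic), p_value = ct$p.value,
                 df = unname(ct$parameter),
                 rate_1 = table[1, 1] / sum(table[1, ]),
                 rate_2 = table[2, 1] / sum(table[2, ]),
                 n_1 = sum(table[1, ]), n_2 = sum(table[2, ]))
}

# DeLong structural components: scores x (cases) against y (controls)
delong_components <- function(cases, controls) {
  psi <- outer(cases, controls,
               function(a, b) (a > b) + 0.5 * (a == b))
  list(auc = mean(psi), v10 = rowMeans(psi), v01 = colMeans(psi))
}

#' ROC curve and AUC with DeLong variance
#'
#' AUC via the Mann-Whitney identity (ties count one half) with the DeLong
#' structural-component variance and a Wald 95% confidence interval clipped to
#' `[0, 1]`.
#'
#' @param data data frame.
#' @param score numeric predictor column (tidy-eval).
#' @param outcome binary outcome column (tidy-eval): logical, 0/1 or a
#'   two-level factor (the higher level / `TRUE` / 1 are cases).
#' @param conf_level confidence level for the Wald interval.
#' @return An object of class `tils_roc`; see [glance.tils_roc()] /
#'   [tidy.tils_roc()] / [autoplot.tils_roc()].
#' @export
tils_roc <- function(data, score, outcome, conf_level = 0.95) {
  sc <- data[[as_name(enquo(score))]]
  oc <- binary_outcome(data[[as_name(enquo(outcome))]])
  ok <- is.finite(sc) & !is.na(oc)
  sc <- sc[ok]; oc <- oc[ok]
  if (length(unique(oc)) != 2) {
    stop("both outcome classes must be present", call. = FALSE)
  }
  cases <- sc[oc]; controls <- sc[!oc]
  dc <- delong_components(cases, controls)
  v <- var(dc$v10) / length(cases) + var(dc$v01) / length(controls)
  z <- qnorm(1 - (1 - conf_level) / 2)
  ci <- pmin(pmax(dc$auc + c(-1, 1) * z * sqrt(v), 0), 1)

  thr <- sort(unique(sc), decreasing = TRUE)
  curve <- tibble::tibble(
    threshold = c(Inf, thr),
    tpr = vapply(c(Inf, thr), function(t) mean(cases >= t), 0),
    fpr = vapply(c(Inf, thr), function(t) mean(controls >= t), 0))

  structure(list(auc = dc$auc, variance = v, conf_low = ci[1],
                 conf_high = ci[2], conf_level = conf_level, curve = curve,
                 n_cases = length(cases), n_controls = length(controls)),
            class = "tils_roc")
}

binary_outcome <- function(x) {
  if (is.logical(x)) return(x)
  if (is.numeric(x)) {
    if (!all(x %in% c(0, 1, NA))) stop("numeric outcome must be 0/1", call. = FALSE)
    return(x == 1)
  }
  f <- as.factor(x)
  if (nlevels(f) != 2) stop("outcome must be binary", call. = FALSE)
  f == levels(f)[2]
}

#' @export
print.tils_roc <- function(x, ...) {
  cat(sprintf("<tils_roc> AUC = %.4f (%.0f%% CI %.4f-%.4f), %d cases / %d controls\n",
              x$auc, 100 * x$conf_level, x$conf_low, x$conf_high,
              x$n_cases, x$n_controls))
  invisible(x)
}

#' @rdname tils_roc
#' @param x a `tils_roc` object.
#' @param ... unused.
#' @export
glance.tils_roc <- function(x, ...) {
  tibble::tibble(auc = x$auc, variance = x$variance, conf_low = x$conf_low,
                 conf_high = x$conf_high, n_cases = x$n_cases,
                 n_controls = x$n_controls)
}

#' @rdname tils_roc
#' @export
tidy.tils_roc <- function(x, ...) x$curve

#' DeLong test for two paired AUCs
#'
#' Compares the AUCs of two scores measured on the same patients against the
#' same outcome, using the paired DeLong structural-component covariance and a
#' two-sided z test. Scores that are monotone transforms of each other have
#' identical AUCs and `p = 1`.
#'
#' @param data data frame.
#' @param score_a,score_b the two paired score columns (tidy-eval).
#' @param outcome binary outcome column (tidy-eval).
#' @return One-row tibble: `auc_a`, `auc_b`, `auc_diff`, `statistic` (z),
#'   `p_value`, ns.
#' @export
tils_delong_test <- function(data, score_a, score_b, outcome) {
  sa <- data[[as_name(enquo(score_a))]]
  sb <- data[[as_name(enquo(score_b))]]
  oc <- binary_outcome(data[[as_name(enquo(outcome))]])
  ok <- is.finite(sa) & is.finite(sb) & !is.na(oc)
  sa <- sa[ok]; sb <- sb[ok]; oc <- oc[ok]
  if (length(unique(oc)) != 2) stop("both outcome classes must be present", call. = FALSE)
  da <- delong_components(sa[oc], sa[!oc])
  db <- delong_components(sb[oc], sb[!oc])
  n1 <- sum(oc); n0 <- sum(!oc)
  s10 <- cov(cbind(da$v10, db$v10))
  s01 <- cov(cbind(da$v01, db$v01))
  v <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / n1 +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n0
  diff <- da$auc - db$auc
  if (v <= 0) {
    z <- 0; p <- 1
  } else {
    z <- diff / sqrt(v)
    p <- 2 * pnorm(-abs(z))
  }
  tibble::tibble(auc_a = da$auc, auc_b = db$auc, auc_diff = diff,
                 statistic = z, p_value = p, n_cases = n1, n_controls = n0)
}

#' Kaplan-Meier curves and log-rank test
#'
#' Product-limit estimates of event-free survival with right censoring
#' (patients without an event are censored at last follow-up), and the
#' log-rank chi-square test across groups (standard hypergeometric variance
#' for ties). With a single group only the curve is estimated. When no events
#' occur at all the survival is identically 1 and `p = 1`, flagged.
#'
#' @param data data frame.
#' @param time,event survival time (months) and event-indicator columns
#'   (tidy-eval).
#' @param group optional grouping column (tidy-eval).
#' @return An object of class `tils_km` with `tidy()` (per-time curve table),
#'   `glance()` (log-rank statistic and p) and `autoplot()` methods.
#' @export
tils_km <- function(data, time, event, group = NULL) {
  tv <- data[[as_name(enquo(time))]]
  ev <- data[[as_name(enquo(event))]]
  if (any(tv <= 0)) stop("survival times must be positive", call. = FALSE)
  gq <- enquo(group)
  has_group <- !rlang::quo_is_null(gq)
  gv <- if (has_group) as.factor(data[[as_name(gq)]]) else
    factor(rep("all", length(tv)))
  if (any(table(gv) == 0)) stop("group with zero subjects", call. = FALSE)
  df <- data.frame(t = tv, e = as.integer(ev), g = gv)
  fit <- survival::survfit(survival::Surv(t, e) ~ g, data = df)
  note <- NA_character_
  if (has_group && nlevels(droplevels(gv)) >= 2 && sum(df$e) > 0) {
    sd_ <- survival::survdiff(survival::Surv(t, e) ~ g, data = df)
    chisq <- sd_$chisq
    dfree <- length(sd_$n) - 1
    p <- pchisq(chisq, dfree, lower.tail = FALSE)
  } else if (has_group && sum(df$e) == 0) {
    chisq <- 0; dfree <- nlevels(droplevels(gv)) - 1; p <- 1
    note <- "no events; p = 1 by convention"
  } else {
    chisq <- NA_real_; dfree <- NA_real_; p <- NA_real_
  }
  structure(list(fit = fit, chisq = chisq, df = dfree, p_value = p,
                 note = note, n = nrow(df), n_events = sum(df$e),
                 groups = levels(gv)),
            class = "tils_km")
}

#' @export
print.tils_km <- function(x, ...) {
  cat(sprintf("<tils_km> %d subjects, %d events", x$n, x$n_events))
  if (!is.na(x$p_value)) {
    cat(sprintf("; log-rank chi-square = %.3f (df %d), p = %.4g",
                x$chisq, x$df, x$p_value))
  }
  cat("\n")
  invisible(x)
}

#' @rdname tils_km
#' @param x a `tils_km` object.
#' @param ... unused.
#' @export
tidy.tils_km <- function(x, ...) {
  s <- summary(x$fit, censored = TRUE)
  strata <- if (is.null(s$strata)) rep(x$groups[1], length(s$time)) else
    sub("^g=", "", as.character(s$strata))
  tibble::tibble(group = strata, time = s$time, n_risk = s$n.risk,
                 n_event = s$n.event, n_censor = s$n.censor,
                 survival = s$surv, std_error = s$std.err,
                 conf_low = s$lower, conf_high = s$upper)
}

#' @rdname tils_km
#' @export
glance.tils_km <- function(x, ...) {
  tibble::tibble(n = x$n, n_events = x$n_events, statistic = x$chisq,
                 df = x$df, p_value = x$p_value, note = x$note)
}

#' Multivariable logistic regression for pCR
#'
#' Maximum-likelihood logistic regression (iteratively reweighted least
#' squares, convergence tolerance 1e-8, at most 50 iterations) with Wald tests
#' per term. Supports the TILs score as a continuous or dichotomized term and
#' marker-by-treatment interaction terms through the formula interface.
#' Complete separation and collinear (aliased) covariates are detected and
#' raised as errors naming the offending term.
#'
#' @param data data frame of patient records.
#' @param formula model formula with a binary response, e.g.
#'   `pcr ~ eastils_percent + arm + er_status + disease_type` or
#'   `pcr ~ eastils_percent * arm`.
#' @return An object of class `tils_logistic`; `tidy()` gives the coefficient
#'   table, `glance()` the fit summary.
#' @export
tils_logistic <- function(data, formula) {
  mf <- stats::model.frame(formula, data)
  if (nrow(mf) <= ncol(stats::model.matrix(formula, mf))) {
    stop("more model terms than observations", call. = FALSE)
  }
  fit <- suppressWarnings(
    glm(formula, data = data, family = binomial(),
        control = stats::glm.control(epsilon = 1e-8, maxit = 50)))
  if (any(is.na(coef(fit)))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    stop("collinear covariate(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  # separation: fitted probabilities pinned at 0/1 together with a diverging
  # coefficient (a strong but finite predictor alone is not flagged)
  mu <- fit$fitted.values
  eps <- 1e-10
  cf <- coef(fit)[-1]
  sds <- vapply(as.data.frame(stats::model.matrix(fit))[-1], sd, 0)
  scaled <- abs(cf) * ifelse(sds > 0, sds, 1)
  if (any(mu < eps | mu > 1 - eps) &&
      (length(scaled) && max(scaled) > 10 || !fit$converged)) {
    bad <- names(cf)[which.max(scaled)]
    stop("complete or quasi-complete separation detected (covariate: ", bad,
         ")", call. = FALSE)
  }
  structure(list(fit = fit, formula = formula, n = nrow(mf)),
            class = "tils_logistic")
}

#' @export
print.tils_logistic <- function(x, ...) {
  cat("<tils_logistic> ", deparse(x$formula), " (n = ", x$n, ")\n", sep = "")
  print(tidy(x))
  invisible(x)
}

#' @rdname tils_logistic
#' @param x a `tils_logistic` object.
#' @param ... unused.
#' @export
tidy.tils_logistic <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  tibble::tibble(term = rownames(sm), estimate = sm[, 1],
                 std_error = sm[, 2], statistic = sm[, 3],
                 p_value = sm[, 4],
                 odds_ratio = exp(sm[, 1]),
                 conf_low = exp(sm[, 1] - qnorm(0.975) * sm[, 2]),
                 conf_high = exp(sm[, 1] + qnorm(0.975) * sm[, 2]))
}

#' @rdname tils_logistic
#' @export
glance.tils_logistic <- function(x, ...) {
  f <- x$fit
  tibble::tibble(n = x$n, null_deviance = f$null.deviance,
                 deviance = f$deviance, aic = f$aic,
                 converged = f$converged, iterations = f$iter)
}

#' Column percentages for a characteristics table
#'
#' `100 * count / column total`, reported to one decimal, as in demographic
#' and disease characteristics tables.
#'
#' @param counts nonnegative integer vector (one category column), or a data
#'   frame of count columns.
#' @param total optional explicit column total; defaults to `sum(counts)`.
#' @return Percentages rounded to one decimal (vector, or tibble for a data
#'   frame input).
#' @export
table1_percentages <- function(counts, total = NULL) {
  if (is.data.frame(counts)) {
    return(tibble::as_tibble(lapply(counts, function(cl)
      table1_percentages(cl, total = total))))
  }
  if (any(counts < 0)) stop("counts must be nonnegative", call. = FALSE)
  tot <- if (is.null(total)) sum(counts) else total
  if (tot <= 0) stop("zero column total", call. = FALSE)
  round(100 * counts / tot, 1)
}
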