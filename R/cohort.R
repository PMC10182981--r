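#' Specification for a synthetic neoadjuvant-trial cohort
#'
#' Emulates a pretreatment breast-cancer cohort in which the digital TILs score
#' (easTILs%) differs between patients who reach pathologic complete response
#' (pCR) and those with residual disease (RD). Two marker models are supported:
#'
#' * `"group_medians"` (default): pCR is drawn first at `pcr_rate`, then
#'   easTILs% is lognormal within each outcome group with medians
#'   `median_pcr` / `median_rd` and common `sdlog`.
#' * `"logistic"`: easTILs% is drawn from a single lognormal (median
#'   `median_overall`), then pCR follows
#'   `Bernoulli(plogis(logistic_intercept + logistic_slope * easTILs))`.
#'
#' Pathologist sTILs% is linear in easTILs% plus Gaussian noise, truncated to
#' `[0, 100]`. Event-free survival (EFS) is exponential within outcome group
#' with uniform administrative censoring. A fraction of patients carries a
#' paired posttreatment easTILs% (lognormal multiplicative change).
#'
#' @param n_patients cohort size (0 gives an empty cohort).
#' @param model `"group_medians"` or `"logistic"`.
#' @param pcr_rate marginal pCR probability (group-medians model).
#' @param median_pcr,median_rd group medians of easTILs% (percent).
#' @param sdlog lognormal log-scale SD of easTILs% within outcome group.
#' @param median_overall overall easTILs% median (logistic model).
#' @param logistic_intercept,logistic_slope pCR model on the logit scale
#'   (logistic model).
#' @param stils_intercept,stils_slope,stils_sd sTILs% = intercept + slope *
#'   easTILs% + N(0, sd), truncated to `[0, 100]`.
#' @param bev_fraction probability of allocation to the bevacizumab arm.
#' @param hr_pos_fraction probability of hormone-receptor-positive status.
#' @param ibc_fraction probability of inflammatory (vs locally advanced)
#'   disease.
#' @param efs_median_pcr,efs_median_rd median EFS (months) per outcome group.
#' @param censor_range uniform administrative censoring window (months).
#' @param paired_fraction fraction with a paired posttreatment easTILs%.
#' @param post_change_meanlog,post_change_sdlog lognormal multiplicative change
#'   of posttreatment easTILs%.
#' @param seed RNG seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 113,
                        model = c("group_medians", "logistic"),
                        pcr_rate = 0.292,
                        median_pcr = 36.1, median_rd = 14.8, sdlog = 0.65,
                        median_overall = 17.0,
                        logistic_intercept = NULL, logistic_slope = NULL,
                        stils_intercept = 0, stils_slope = 0.83, stils_sd = 24.5,
                        bev_fraction = 0.478, hr_pos_fraction = 0.69,
                        ibc_fraction = 0.088,
                        efs_median_pcr = 80, efs_median_rd = 50,
                        censor_range = c(24, 72),
                        paired_fraction = 0.27,
                        post_change_meanlog = log(0.6), post_change_sdlog = 0.5,
                        seed = NULL) {
  model <- match.arg(model)
  spec <- structure(
    list(n_patients = n_patients, model = model, pcr_rate = pcr_rate,
         median_pcr = median_pcr, median_rd = median_rd, sdlog = sdlog,
         median_overall = median_overall,
         logistic_intercept = logistic_intercept,
         logistic_slope = logistic_slope,
         stils_intercept = stils_intercept, stils_slope = stils_slope,
         stils_sd = stils_sd, bev_fraction = bev_fraction,
         hr_pos_fraction = hr_pos_fraction, ibc_fraction = ibc_fraction,
         efs_median_pcr = efs_median_pcr, efs_median_rd = efs_median_rd,
         censor_range = censor_range, paired_fraction = paired_fraction,
         post_change_meanlog = post_change_meanlog,
         post_change_sdlog = post_change_sdlog, seed = seed),
    class = "cohort_spec"
  )
  validate_cohort_spec(spec)
  spec
}

validate_cohort_spec <- function(spec) {
  if (spec$n_patients < 0) stop("n_patients must be >= 0", call. = FALSE)
  probs <- c(spec$pcr_rate, spec$bev_fraction, spec$hr_pos_fraction,
             spec$ibc_fraction, spec$paired_fraction)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]", call. = FALSE)
  if (spec$model == "logistic" &&
      (is.null(spec$logistic_intercept) || is.null(spec$logistic_slope))) {
    stop("logistic model needs logistic_intercept and logistic_slope", call. = FALSE)
  }
  if (spec$median_pcr <= 0 || spec$median_rd <= 0 || spec$sdlog <= 0) {
    stop("easTILs distribution parameters must be positive", call. = FALSE)
  }
  if (spec$efs_median_pcr <= 0 || spec$efs_median_rd <= 0 ||
      any(spec$censor_range <= 0)) {
    stop("EFS parameters must be positive", call. = FALSE)
  }
  invisible(spec)
}

#' Generate a synthetic patient cohort
#'
#' @param spec a [cohort_spec].
#' @return Tibble with one row per patient: `patient_id`, `eastils_percent`,
#'   `stils_percent`, `pcr` (logical), `arm` (`chemo` / `chemo_bev`),
#'   `hr_status` (`HR+` / `HR-`), `er_status`, `disease_type` (`IBC` /
#'   `LABC`), `efs_months`, `efs_event`, `eastils_post_percent` (NA when
#'   unpaired). Reproducible under `spec$seed`.
#' @export
generate_cohort <- function(spec) {
  validate_cohort_spec(spec)
  n <- spec$n_patients
  empty <- tibble::tibble(
    patient_id = integer(), eastils_percent = numeric(),
    stils_percent = numeric(), pcr = logical(), arm = character(),
    hr_status = character(), er_status = character(),
    disease_type = character(), efs_months = numeric(),
    efs_event = logical(), eastils_post_percent = numeric())
  if (n == 0) return(empty)

  with_seed(spec$seed, {
    if (spec$model == "group_medians") {
      pcr <- runif(n) < spec$pcr_rate
      med <- ifelse(pcr, spec$median_pcr, spec$median_rd)
      eastils <- rlnorm(n, meanlog = log(med), sdlog = spec$sdlog)
    } else {
      eastils <- rlnorm(n, meanlog = log(spec$median_overall),
                        sdlog = spec$sdlog)
      pcr <- runif(n) < plogis(spec$logistic_intercept +
                                 spec$logistic_slope * eastils)
    }
    stils <- spec$stils_intercept + spec$stils_slope * eastils +
      rnorm(n, 0, spec$stils_sd)
    stils <- pmin(pmax(stils, 0), 100)

    arm <- ifelse(runif(n) < spec$bev_fraction, "chemo_bev", "chemo")
    hr <- ifelse(runif(n) < spec$hr_pos_fraction, "HR+", "HR-")
    er <- ifelse(hr == "HR+",
                 ifelse(runif(n) < 0.95, "ER+", "ER-"),
                 ifelse(runif(n) < 0.05, "ER+", "ER-"))
    disease <- ifelse(runif(n) < spec$ibc_fraction, "IBC", "LABC")

    rate <- log(2) / ifelse(pcr, spec$efs_median_pcr, spec$efs_median_rd)
    t_event <- rexp(n, rate)
    t_cens <- runif(n, spec$censor_range[1], spec$censor_range[2])
    efs_event <- t_event <= t_cens
    efs_months <- pmin(t_event, t_cens)

    paired <- runif(n) < spec$paired_fraction
    post <- ifelse(paired,
                   eastils * rlnorm(n, spec$post_change_meanlog,
                                    spec$post_change_sdlog),
                   NA_real_)

    tibble::tibble(
      patient_id = seq_len(n), eastils_percent = eastils,
      stils_percent = stils, pcr = pcr, arm = arm, hr_status = hr,
      er_status = er, disease_type = disease, efs_months = efs_months,
      efs_event = efs_event, eastils_post_percent = post)
  })
}

#' Pool control arms before arm-level comparisons
#'
#' Trials with several control chemotherapy arms are analysed with the control
#' arms combined against the experimental arm. Collapses all values of `arm`
#' found in `control_levels` to a single label.
#'
#' @param data cohort tibble.
#' @param arm column holding the treatment arm (tidy-eval).
#' @param control_levels arm values to pool.
#' @param pooled_label label replacing the pooled values.
#' @return The cohort with the pooled arm column.
#' @export
pool_control_arms <- function(data, arm = "arm",
                              control_levels = c("control_a", "control_b"),
                              pooled_label = "chemo") {
  av <- data[[arm]]
  data[[arm]] <- ifelse(av %in% control_levels, pooled_label, av)
  data
}
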