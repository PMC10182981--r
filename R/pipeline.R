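#' Pipeline configuration
#'
#' Bundles every knob of the end-to-end run: the synthetic tile specification,
#' detection parameters, classifier settings, the area basis for scoring, the
#' dichotomization cutoffs and the RNG seed (recorded in every output).
#'
#' @param tile a [tile_spec] describing the simulated slides (its `seed` is
#'   ignored; per-tile seeds are derived from `seed`).
#' @param params a [detection_params].
#' @param n_train_tiles,n_eval_tiles simulated slides used to train the
#'   classifier and to score, respectively.
#' @param classifier list of overrides passed to [train_cell_classifier()].
#' @param model optional pretrained [train_cell_classifier()] fit; when given,
#'   the training stage is skipped.
#' @param area_basis `"cell"` or `"nucleus"` area accounting for scoring.
#' @param eastils_cutoff,stils_cutoff dichotomization cutoffs (percent).
#' @param cohort optional [cohort_spec]; when present the cohort statistics
#'   stage runs.
#' @param out_dir optional output directory for per-slide artifacts and the
#'   manifest.
#' @param seed integer seed controlling the whole run.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(tile = tile_spec(), params = detection_params(),
                            n_train_tiles = 6, n_eval_tiles = 10,
                            classifier = list(), model = NULL,
                            area_basis = "cell",
                            eastils_cutoff = 19.9, stils_cutoff = 20,
                            cohort = NULL, out_dir = NULL, seed = 1) {
  structure(list(tile = tile, params = params,
                 n_train_tiles = n_train_tiles, n_eval_tiles = n_eval_tiles,
                 classifier = classifier, model = model,
                 area_basis = area_basis,
                 eastils_cutoff = eastils_cutoff, stils_cutoff = stils_cutoff,
                 cohort = cohort, out_dir = out_dir, seed = seed),
            class = "pipeline_config")
}

#' Run the stain / detect / classify stages on one tile
#'
#' Per-slide stain recalibration (falling back to the default H&E vectors when
#' estimation fails), colour deconvolution, watershed nucleus detection, cell
#' expansion, feature computation and neighbourhood smoothing at 25 and 50 um.
#'
#' @param tile an [he_tile].
#' @param params a [detection_params].
#' @param profile optional fixed [stain_profile]; estimated per slide when
#'   `NULL`.
#' @return List: `cells` (a [cell_set] with features), `profile`,
#'   `stain_estimated` (logical).
#' @export
process_tile <- function(tile, params = detection_params(), profile = NULL) {
  estimated <- FALSE
  if (is.null(profile)) {
    profile <- tryCatch({
      p <- estimate_stain_vectors(tile)
      estimated <- TRUE
      p
    }, eastils_stain_error = function(e) default_he_profile())
  }
  od <- rgb_to_od(tile, profile$I0)
  conc <- deconvolve(od, profile)
  hema <- od_channel(conc, "hematoxylin")
  eosin <- od_channel(conc, "eosin")
  cs <- detect_nuclei(hema, params)
  cs <- expand_cells(cs, params)
  cs <- compute_features(cs, hema, eosin)
  cs <- smooth_features(cs, 25)
  cs <- smooth_features(cs, 50)
  list(cells = cs, profile = profile, stain_estimated = estimated)
}

#' Match detections to planted ground-truth cells
#'
#' Greedy one-to-one nearest-centroid matching: the closest
#' detection/ground-truth pair is linked first, within a per-cell gate of the
#' planted semi-major axis plus `slack_um`.
#'
#' @param cs a [cell_set] of detections.
#' @param truth a `tile_truth`.
#' @param slack_um matching gate added to the planted semi-major axis.
#' @return The cell set with `true_class` and `truth_cell` columns (NA for
#'   unmatched detections).
#' @export
match_to_truth <- function(cs, truth, slack_um = 2) {
  det <- cs$cells
  tru <- truth$cells
  n_d <- nrow(det); n_t <- nrow(tru)
  true_class <- rep(NA_character_, n_d)
  truth_cell <- rep(NA_integer_, n_d)
  if (n_d > 0 && n_t > 0) {
    d2 <- outer(det$x_um, tru$x_um, "-")^2 + outer(det$y_um, tru$y_um, "-")^2
    gate <- matrix(rep((tru$a_um + slack_um)^2, each = n_d), n_d, n_t)
    d2[d2 > gate] <- Inf
    while (any(is.finite(d2))) {
      ij <- arrayInd(which.min(d2), dim(d2))
      true_class[ij[1]] <- as.character(tru$class[ij[2]])
      truth_cell[ij[1]] <- tru$cell[ij[2]]
      d2[ij[1], ] <- Inf
      d2[, ij[2]] <- Inf
    }
  }
  cs$cells$true_class <- factor(true_class, levels = cell_classes())
  cs$cells$truth_cell <- truth_cell
  cs
}

#' Detection performance against ground truth
#'
#' @param cs a matched [cell_set] (see [match_to_truth()]).
#' @param truth the `tile_truth`.
#' @return One-row tibble with `n_true`, `n_detected`, `n_matched`, `recall`,
#'   `precision`.
#' @export
detection_performance <- function(cs, truth) {
  n_matched <- sum(!is.na(cs$cells$truth_cell))
  tibble::tibble(n_true = nrow(truth$cells), n_detected = nrow(cs$cells),
                 n_matched = n_matched,
                 recall = n_matched / nrow(truth$cells),
                 precision = if (nrow(cs$cells) > 0)
                   n_matched / nrow(cs$cells) else NA_real_)
}

#' Run the end-to-end pipeline on simulated slides
#'
#' Simulate training tiles, train the cell classifier on ground-truth labels,
#' then simulate evaluation tiles and run stain recalibration, detection,
#' classification, slide QC (slides with more than 10% misclassified cells are
#' excluded and listed) and easTILs% scoring. When `config$cohort` is set, a
#' synthetic patient cohort is generated and the full statistical battery is
#' run (Mann-Whitney by pCR, Pearson easTILs/sTILs, chi-square on dichotomized
#' scores, ROC with paired DeLong comparison, Kaplan-Meier/log-rank, logistic
#' regression with marker-by-treatment interaction). Deterministic given
#' `config$seed`; when `config$out_dir` is set all per-slide artifacts plus a
#' manifest sufficient to rerun any slide are written there.
#'
#' @param config a [pipeline_config].
#' @return An object of class `eastils_pipeline`: `summaries` (per-slide
#'   tibble), `qc`, `excluded`, `model`, `performance`, `stats`, `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  if (!is.null(out) && !dir.exists(out)) dir.create(out, recursive = TRUE)

  tile_with_seed <- function(s) { sp <- config$tile; sp$seed <- s; sp }

  # ---- training stage -------------------------------------------------------
  if (!is.null(config$model)) {
    model <- config$model
  } else {
    train_rows <- list()
    for (i in seq_len(config$n_train_tiles)) {
      g <- generate_tile(tile_with_seed(config$seed + i))
      pr <- process_tile(g$tile, config$params)
      cs <- match_to_truth(pr$cells, g$truth)
      tb <- cs$cells
      tb <- tb[!is.na(tb$true_class), , drop = FALSE]
      tb$class <- tb$true_class
      train_rows[[i]] <- tb
    }
    train_tb <- dplyr::bind_rows(train_rows)
    cl_args <- modifyList(list(data = train_tb, label = "class",
                               seed = config$seed),
                          config$classifier)
    model <- do.call(train_cell_classifier, cl_args)
  }

  # ---- evaluation stage -----------------------------------------------------
  summaries <- list(); qc_rows <- list(); excluded <- character(0)
  perf_rows <- list()
  for (i in seq_len(config$n_eval_tiles)) {
    slide_id <- sprintf("slide_%03d", i)
    g <- generate_tile(tile_with_seed(config$seed + 1000L + i))
    pr <- process_tile(g$tile, config$params)
    cs <- classify_cells(pr$cells, model)
    cs <- match_to_truth(cs, g$truth)
    perf_rows[[i]] <- dplyr::mutate(detection_performance(cs, g$truth),
                                    slide = slide_id, .before = 1)

    if (nrow(cs$cells) == 0) {
      excluded <- c(excluded, slide_id)
      qc_rows[[i]] <- tibble::tibble(slide = slide_id, n_cells = 0L,
                                     n_misclassified = NA_integer_,
                                     fraction = NA_real_, pass = FALSE)
      next
    }
    matched <- !is.na(cs$cells$true_class)
    qc <- qc_slide(cs$cells$class[matched], cs$cells$true_class[matched])
    qc_rows[[i]] <- dplyr::mutate(qc, slide = slide_id, .before = 1)
    if (!qc$pass) {
      excluded <- c(excluded, slide_id)
      next
    }

    cs_r <- assign_cells_to_region(cs, g$truth$region)
    summ <- summarize_areas(cs_r, area_basis = config$area_basis)
    summ$eastils_percent <- compute_eastils(summ)
    summ$eastils_true <- g$truth$eastils_true
    summ$eastils_category <- as.character(
      dichotomize_tils(summ$eastils_percent, config$eastils_cutoff))
    summaries[[i]] <- dplyr::mutate(summ, slide = slide_id, .before = 1)

    if (!is.null(out)) {
      write_stain_profile(pr$profile, file.path(out, paste0(slide_id, "_stains.json")))
      write_detections_geojson(cs, file.path(out, paste0(slide_id, "_detections.geojson")))
      flat <- dplyr::select(cs$cells, -dplyr::any_of(c("nucleus_poly", "cell_poly")))
      utils::write.csv(flat, file.path(out, paste0(slide_id, "_cells.csv")),
                       row.names = FALSE)
    }
  }

  summaries <- dplyr::bind_rows(summaries)
  qc_tbl <- dplyr::bind_rows(qc_rows)
  perf_tbl <- dplyr::bind_rows(perf_rows)

  # ---- cohort statistics stage ---------------------------------------------
  stats_out <- NULL
  if (!is.null(config$cohort)) {
    csp <- config$cohort
    if (is.null(csp$seed)) csp$seed <- config$seed + 2000L
    cohort <- generate_cohort(csp)
    stats_out <- cohort_statistics(cohort,
                                   eastils_cutoff = config$eastils_cutoff,
                                   stils_cutoff = config$stils_cutoff)
    stats_out$cohort <- cohort
  }

  res <- structure(
    list(summaries = summaries, qc = qc_tbl, excluded = excluded,
         performance = perf_tbl, model = model, stats = stats_out,
         config = config),
    class = "eastils_pipeline")

  if (!is.null(out)) {
    utils::write.csv(summaries, file.path(out, "summaries.csv"),
                     row.names = FALSE)
    manifest <- list(
      package_version = as.character(packageVersion("eastils")),
      seed = config$seed,
      detection_params = unclass(config$params),
      area_basis = config$area_basis,
      cutoffs = list(eastils = config$eastils_cutoff,
                     stils = config$stils_cutoff),
      tile_spec = unclass(config$tile)[setdiff(names(unclass(config$tile)),
                                               c("stain_profile", "morphology"))],
      n_train_tiles = config$n_train_tiles,
      n_eval_tiles = config$n_eval_tiles,
      qc = qc_tbl, excluded_slides = excluded)
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  res
}

#' @export
print.eastils_pipeline <- function(x, ...) {
  cat(sprintf("<eastils_pipeline> %d slides scored, %d excluded by QC\n",
              nrow(x$summaries), length(x$excluded)))
  if (nrow(x$summaries)) {
    cat(sprintf("  easTILs%%: median %.2f (truth %.2f)\n",
                median(x$summaries$eastils_percent),
                median(x$summaries$eastils_true)))
  }
  invisible(x)
}

#' Cohort-level statistical battery
#'
#' Runs the standard association analyses of a TILs cohort: Mann-Whitney of
#' easTILs% and sTILs% by pCR, Pearson correlation between the two scores,
#' chi-square of pCR rates by dichotomized score, ROC for both scores with the
#' paired DeLong AUC comparison, Kaplan-Meier / log-rank of EFS by easTILs%
#' category, a multivariable logistic model (easTILs% + ER status + arm +
#' disease type) and the marker-by-treatment interaction model, and the paired
#' Wilcoxon pre/post comparison when posttreatment scores exist.
#'
#' @param cohort a cohort tibble (see [generate_cohort()] for the schema).
#' @param eastils_cutoff,stils_cutoff dichotomization cutoffs.
#' @return Named list of results.
#' @export
cohort_statistics <- function(cohort, eastils_cutoff = 19.9,
                              stils_cutoff = 20) {
  ch <- dplyr::mutate(
    cohort,
    eastils_cat = dichotomize_tils(.data$eastils_percent, eastils_cutoff),
    stils_cat = dichotomize_tils(.data$stils_percent, stils_cutoff))

  tab <- function(cat) {
    m <- rbind(high = c(sum(ch$pcr[cat == "high"]), sum(!ch$pcr[cat == "high"])),
               low = c(sum(ch$pcr[cat == "low"]), sum(!ch$pcr[cat == "low"])))
    colnames(m) <- c("pcr", "rd")
    m
  }

  out <- list(
    mw_eastils = tils_mann_whitney(ch, eastils_percent, pcr),
    mw_stils = tils_mann_whitney(ch, stils_percent, pcr),
    pearson = tils_pearson(ch, eastils_percent, stils_percent),
    chisq_eastils = tils_chisq_2x2(tab(ch$eastils_cat)),
    roc_eastils = tils_roc(ch, eastils_percent, pcr),
    roc_stils = tils_roc(ch, stils_percent, pcr),
    delong = tils_delong_test(ch, eastils_percent, stils_percent, pcr),
    km = tils_km(ch, efs_months, efs_event, eastils_cat),
    logistic = tils_logistic(
      ch, pcr ~ eastils_percent + er_status + arm + disease_type),
    interaction = tils_logistic(ch, pcr ~ eastils_percent * arm)
  )
  if (any(is.finite(ch$eastils_post_percent))) {
    out$paired_wilcoxon <- tils_wilcoxon_paired(ch, eastils_percent,
                                                eastils_post_percent)
  }
  out
}
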