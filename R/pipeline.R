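# Pipeline orchestration: configuration, the per-slide spatial stage
# (mask -> interface -> bands -> densities -> indicator grid) and the
# cohort survival stage (censor -> split -> screen -> enumerate ->
# fit/filter -> CV-rank -> test C-index -> tertiles -> risk score).

#' Read and validate a pipeline run configuration
#'
#' The configuration is a single YAML file; unknown keys are rejected and
#' missing ones filled with defaults. The full resolved configuration is
#' echoed into every pipeline output for provenance.
#'
#' @param path YAML file path.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- list(pixel_size_um = 0.5, band_width_um = 10,
                   max_width_um = 150, min_boundary_um = 1000,
                   widths_um = NULL, alpha = 0.05, cv_folds = 5,
                   n_train = 117, n_test = 40, horizon_months = 60,
                   seed = 1, out_dir = NULL, label_codes = NULL,
                   slides = NULL, clinical = NULL)
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg <- utils::modifyList(defaults, cfg, keep.null = TRUE)
  with(cfg, {
    stopifnot(pixel_size_um > 0, band_width_um > 0, min_boundary_um >= 0,
              alpha > 0, alpha < 1, cv_folds >= 2, horizon_months > 0)
  })
  structure(cfg, class = "run_config")
}

#' Read a clinical cohort table from CSV
#'
#' @param path CSV with at least `rfs_months` and `event`; recommended
#'   columns follow [simulate_cohort()]'s schema (grade and stage labels,
#'   history flags, covariates). Missing required columns raise a schema
#'   error listing every absence.
#' @return The cohort data frame.
#' @export
read_clinical_csv <- function(path) {
  d <- utils::read.csv(path)
  required <- c("rfs_months", "event")
  miss <- setdiff(required, names(d))
  if (length(miss))
    stop("clinical table lacks required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  d
}

#' Run the spatial stage over a set of slides
#'
#' For each slide: interface extraction, short-boundary filtering, band-map
#' construction, band and compartment densities, and the gradient-indicator
#' grid. A failing slide is recorded in the log and the run continues.
#'
#' @param slides named list; each element a list with `mask` (a
#'   [tissue_mask()] or a raster path) and `cells` (a [cell_set()] or a CSV
#'   path).
#' @param config a [read_run_config()] result or a plain list of the same
#'   keys (band/filter parameters, `pixel_size_um`, `out_dir`).
#' @return A list of class `spatial_result`: `indicators` (long data frame,
#'   one row per slide x variant), `compartments` (per-slide absolute
#'   densities), `profiles` (named list of band profiles), `log` (per-slide
#'   boundary counts, filtered lengths, failures), `config`.
#' @export
run_spatial <- function(slides, config = list()) {
  cfg <- utils::modifyList(
    list(pixel_size_um = 0.5, band_width_um = 10, max_width_um = 150,
         min_boundary_um = 1000, widths_um = NULL, out_dir = NULL,
         label_codes = NULL),
    config[!vapply(config, is.null, logical(1))], keep.null = TRUE)
  codes <- if (is.null(cfg$label_codes)) default_label_codes() else
    unlist(cfg$label_codes)
  if (is.null(names(slides)))
    names(slides) <- sprintf("slide%02d", seq_along(slides))
  indicators <- list(); compartments <- list(); profiles <- list()
  logs <- list()
  for (id in names(slides)) {
    res <- tryCatch({
      sl <- slides[[id]]
      mask <- if (inherits(sl$mask, "tissue_mask")) sl$mask else
        read_mask(sl$mask, pixel_size_um = cfg$pixel_size_um,
                  label_codes = codes)
      cells <- if (inherits(sl$cells, "cell_set")) sl$cells else
        read_cells_csv(sl$cells)
      interfaces <- extract_interface(mask)
      n_raw <- length(interfaces$boundaries)
      retained <- filter_short_boundaries(interfaces, cfg$min_boundary_um)
      bm <- compute_band_map(mask, retained,
                             band_width_um = cfg$band_width_um,
                             max_width_um = cfg$max_width_um)
      counts <- assign_cells_to_bands(cells, bm)
      prof <- band_density_profile(counts, bm$areas_mm2,
                                   band_width_um = cfg$band_width_um)
      comp <- compartment_densities(cells, mask, bm)
      ind <- if (bm$empty) NULL else variant_grid(prof, cfg$widths_um)
      list(ok = TRUE, prof = prof, comp = comp, ind = ind,
           n_raw = n_raw, n_kept = length(retained$boundaries),
           removed_um = sum(interface_lengths(interfaces)) -
             sum(interface_lengths(retained)))
    }, error = function(e) list(ok = FALSE, error = conditionMessage(e)))
    if (res$ok) {
      profiles[[id]] <- res$prof
      compartments[[id]] <- data.frame(
        slide = id,
        epithelial = res$comp$epithelial_density,
        stromal = res$comp$stromal_density,
        overall_iz = res$comp$overall_iz_density)
      if (!is.null(res$ind))
        indicators[[id]] <- cbind(slide = id, res$ind)
      logs[[id]] <- data.frame(slide = id, ok = TRUE,
                               boundaries_found = res$n_raw,
                               boundaries_kept = res$n_kept,
                               filtered_length_um = res$removed_um,
                               error = "")
    } else {
      logs[[id]] <- data.frame(slide = id, ok = FALSE, boundaries_found = NA,
                               boundaries_kept = NA, filtered_length_um = NA,
                               error = res$error)
    }
  }
  out <- structure(list(indicators = do.call(rbind, c(indicators,
                                                      make.row.names = FALSE)),
                        compartments = do.call(rbind, compartments),
                        profiles = profiles,
                        log = do.call(rbind, logs),
                        config = cfg),
                   class = "spatial_result")
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(out$indicators))
      utils::write.csv(out$indicators,
                       file.path(cfg$out_dir, "indicators.csv"),
                       row.names = FALSE)
    for (id in names(profiles))
      write_profile_csv(profiles[[id]],
                        file.path(cfg$out_dir, paste0("profile_", id, ".csv")))
    utils::write.csv(out$log, file.path(cfg$out_dir, "spatial_log.csv"),
                     row.names = FALSE)
  }
  out
}

#' Run the survival-model selection stage
#'
#' Executes the full statistical pipeline on a cohort: censoring at the
#' follow-up horizon, an event-stratified train/test split, univariable Cox
#' screening of every candidate feature (keeping, within each indicator
#' group, only the variant with the lowest p-value), enumeration of all
#' multivariable combinations, the all-covariates-significant filter,
#' 5-fold cross-validated ranking by mean Harrell's C, evaluation of the
#' best model on the hold-out set, tertile stratification of the gradient
#' indicators, Kaplan-Meier/log-rank comparisons and the combined 3-point
#' risk score.
#'
#' @param cohort cohort data frame (see [simulate_cohort()] for the
#'   schema).
#' @param features character vector of candidate covariate columns.
#' @param indicator_groups optional named list of column sets that are
#'   variants of one indicator (e.g. `list(id = c(...), cm = c(...))`);
#'   within a group only the lowest-p variant proceeds, ties going to the
#'   earlier column (order columns by increasing interface-zone width).
#' @param id_feature column used for the risk score's immunodrop tertile
#'   (default `"id_value"`, or the winning variant of the `id` group).
#' @param config list or [read_run_config()]: `alpha`, `cv_folds`,
#'   `n_train`, `n_test`, `horizon_months`, `seed`, `out_dir`.
#' @return A list of class `survival_result`: `screening` (data frame),
#'   `selected`, `models` (retained fits with `cv_cindex`), `ranking`
#'   (data frame sorted by mean validation C), `best` (fit plus
#'   `test_cindex`), `tertiles`, `risk` (per-patient scores), `km`
#'   (Kaplan-Meier results per stratification), `cohort` (censored, with
#'   tertile and risk columns), `split`, `config`.
#' @export
run_survival <- function(cohort, features, indicator_groups = NULL,
                         id_feature = NULL, config = list()) {
  cfg <- utils::modifyList(
    list(alpha = 0.05, cv_folds = 5, n_train = NULL, n_test = NULL,
         horizon_months = 60, seed = 1, out_dir = NULL),
    config[!vapply(config, is.null, logical(1))], keep.null = TRUE)
  miss <- setdiff(c("rfs_months", "event", features), names(cohort))
  if (length(miss))
    stop("cohort lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  cohort <- censor_rfs(cohort, cfg$horizon_months)
  if (sum(cohort$event) == 0)
    stop("cohort has no events; survival modeling is not possible",
         call. = FALSE)
  n <- nrow(cohort)
  if (is.null(cfg$n_train)) {
    cfg$n_train <- round(n * 117 / 157)
    cfg$n_test <- n - cfg$n_train
  }
  sp <- split_cohort(cohort, cfg$n_train, cfg$n_test, seed = cfg$seed)
  screening <- lapply(features, function(f) univariable_cox(sp$train, f))
  names(screening) <- features
  scr_tab <- do.call(rbind, lapply(screening, function(r) {
    data.frame(feature = r$feature,
               hr = if (is.null(r$table)) NA else r$table$hr[1],
               p = if (is.null(r$table)) NA else r$table$p[1],
               n = r$n, flagged = r$flagged)
  }))
  selected <- select_features(screening, cfg$alpha)
  # within each indicator group keep only the lowest-p variant
  if (!is.null(indicator_groups)) {
    for (grp in indicator_groups) {
      cand <- intersect(grp, selected)
      if (length(cand) > 1L) {
        pv <- scr_tab$p[match(cand, scr_tab$feature)]
        best <- cand[order(pv, match(cand, grp))][1L]
        selected <- setdiff(selected, setdiff(cand, best))
      }
    }
  }
  combos <- enumerate_models(selected)
  models <- fit_and_filter(sp$train, combos, cfg$alpha)
  for (i in seq_along(models))
    models[[i]]$cv_cindex <- as.numeric(
      cross_validate(sp$train, models[[i]]$covariates, k = cfg$cv_folds,
                     seed = cfg$seed + i))
  ranking <- if (length(models)) {
    rk <- data.frame(
      model = vapply(models, `[[`, character(1), "feature"),
      n_covariates = vapply(models, function(m) length(m$covariates),
                            integer(1)),
      mean_validation_cindex = vapply(models, `[[`, numeric(1), "cv_cindex"),
      aic = vapply(models, `[[`, numeric(1), "aic"),
      train_cindex = vapply(models, `[[`, numeric(1), "train_cindex"))
    rk[order(-rk$mean_validation_cindex), , drop = FALSE]
  } else NULL
  best <- NULL
  if (length(models)) {
    best <- models[[which.max(vapply(models, `[[`, numeric(1), "cv_cindex"))]]
    held <- sp$test[stats::complete.cases(
      sp$test[, best$covariates, drop = FALSE]), , drop = FALSE]
    lp <- unname(stats::predict(best$fit, newdata = held, type = "lp"))
    best$test_cindex <- suppressWarnings(
      harrell_c(lp, held$rfs_months, held$event))
  }
  # tertiles of the gradient indicators on the full censored cohort
  id_feature <- id_feature %||%
    (if (!is.null(indicator_groups$id))
      intersect(c(selected, indicator_groups$id), indicator_groups$id)[1L]
     else if ("id_value" %in% names(cohort)) "id_value" else NULL)
  tertiles <- list(); km <- list()
  if (!is.null(id_feature)) {
    cohort$id_tertile <- tertile_stratify(cohort[[id_feature]])
    tertiles$id <- table(cohort$id_tertile)
    km$id_tertile <- km_logrank(cohort, cohort$id_tertile)
  }
  if ("cm_value" %in% names(cohort)) {
    cohort$cm_tertile <- tertile_stratify(cohort$cm_value)
    tertiles$cm <- table(cohort$cm_tertile)
    km$cm_tertile <- km_logrank(cohort, cohort$cm_tertile)
  }
  risk <- NULL
  if (!is.null(id_feature) &&
      all(c("grade", "retur_or_recurrent") %in% names(cohort))) {
    risk <- risk_score(cohort$grade, cohort$retur_or_recurrent,
                       cohort$id_tertile)
    cohort$risk_points <- risk$points
    cohort$risk_category <- risk$category
    km$risk <- km_logrank(cohort, cohort$risk_category)
  }
  out <- structure(list(screening = scr_tab, selected = selected,
                        models = models, ranking = ranking, best = best,
                        tertiles = tertiles, risk = risk, km = km,
                        cohort = cohort, split = sp, config = cfg),
                   class = "survival_result")
  if (!is.null(cfg$out_dir)) .write_survival_outputs(out, cfg)
  out
}

.write_survival_outputs <- function(out, cfg) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(
    config = cfg[setdiff(names(cfg), "out_dir")],
    tie_method = "efron",
    screening = out$screening,
    selected = out$selected,
    ranking = out$ranking,
    best = if (!is.null(out$best)) list(
      covariates = out$best$covariates,
      table = out$best$table,
      aic = out$best$aic,
      train_cindex = out$best$train_cindex,
      mean_validation_cindex = out$best$cv_cindex,
      test_cindex = out$best$test_cindex) else NULL)
  jsonlite::write_json(report, file.path(cfg$out_dir, "model_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  for (nm in names(out$km))
    write_km_csv(out$km[[nm]],
                 file.path(cfg$out_dir, paste0("km_", nm, ".csv")))
  if (!is.null(out$risk))
    utils::write.csv(
      data.frame(patient = out$cohort$patient %||% seq_len(nrow(out$cohort)),
                 points = out$risk$points, category = out$risk$category),
      file.path(cfg$out_dir, "risk_scores.csv"), row.names = FALSE)
  invisible(NULL)
}
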