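# End-to-end study orchestration: simulate (or ingest) -> split ->
# preprocessing comparison -> index search + NISDI -> wavelength selection x
# regressor grid -> model ranking -> per-pixel water map -> cross-species
# evaluation, emitting a structured report.

#' Pipeline configuration
#'
#' All stages of the study run from one configuration under a single global
#' seed, fanned out deterministically to the stages.
#'
#' @param n_samples Synthetic sample count (default 360).
#' @param sim List of overrides passed to [sim_config()].
#' @param test_fraction,split_method Calibration/prediction split settings.
#' @param prep_compare Run the preprocessing comparison harness (default TRUE).
#' @param prep_method Preprocessing for the wavelength-selection workflow;
#'   `NULL` takes the comparison winner (or "SNV" if the comparison is off).
#' @param index_families Two-band families to search (default all three).
#' @param selectors Wavelength selectors to run (default CARS, SPA, UVE).
#' @param regressors Regressor kinds for the grid (default all four).
#' @param include_full_spectrum Also fit each regressor on all bands.
#' @param rank_delta_r2 Parsimony window of the ranking rule (default 0.025).
#' @param cube List: height, width, lamina_wc, vein_offset for the rendered
#'   water-map scene; `NULL` disables the mapping stage.
#' @param cross_species Evaluate the chosen model on matched and
#'   distribution-shifted external tables (default TRUE).
#' @param out_dir Output directory for the report and artifacts; `NULL`
#'   keeps everything in memory.
#' @param seed Global seed.
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(n_samples = 360L, sim = list(),
                            test_fraction = 0.3, split_method = "random",
                            prep_compare = TRUE, prep_method = NULL,
                            index_families = c("DVI", "RVI", "NDVI"),
                            selectors = c("CARS", "SPA", "UVE"),
                            regressors = c("PLSR", "MLR", "RF", "ANN"),
                            include_full_spectrum = TRUE,
                            rank_delta_r2 = 0.025,
                            cube = list(height = 48L, width = 48L,
                                        lamina_wc = 0.5, vein_offset = 0.1),
                            cross_species = TRUE,
                            out_dir = NULL, seed = 1L) {
  if (length(index_families) + length(selectors) * length(regressors) +
      include_full_spectrum * length(regressors) < 1 &&
      !("NISDI" %in% index_families)) {
    stopf("at least one model path must be enabled")
  }
  structure(list(
    n_samples = as.integer(n_samples), sim = sim,
    test_fraction = test_fraction, split_method = split_method,
    prep_compare = isTRUE(prep_compare), prep_method = prep_method,
    index_families = index_families, selectors = selectors,
    regressors = regressors,
    include_full_spectrum = isTRUE(include_full_spectrum),
    rank_delta_r2 = rank_delta_r2, cube = cube,
    cross_species = isTRUE(cross_species),
    out_dir = out_dir, seed = as.integer(seed)
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' The YAML keys mirror the arguments of [pipeline_config()]; missing keys
#' take the defaults.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    stopf("unknown configuration keys: %s", paste(unknown, collapse = ", "))
  }
  do.call(pipeline_config, vals)
}

#' Show a configuration as YAML
#'
#' @param config A `pipeline_config`.
#' @return The YAML string, invisibly; also printed.
#' @export
show_config <- function(config = pipeline_config()) {
  txt <- yaml::as.yaml(unclass(config))
  cat(txt)
  invisible(txt)
}

#' Bundle a fitted model with its feature extraction
#'
#' A bundle carries everything needed to predict water content from raw
#' reflectance on a (possibly different) wavelength grid: the fitted model,
#' a feature function over `(X, grid)`, the training grid, a label and the
#' number of wavelengths the features use.
#'
#' @param model Fitted model (`hl_model` or `index_model`).
#' @param features Function `(X, grid) -> feature matrix`.
#' @param grid Training `wavelength_grid`.
#' @param label Model label.
#' @param n_wavelengths Number of distinct wavelengths used.
#' @return A `wc_model_bundle`.
#' @export
wc_model_bundle <- function(model, features, grid, label, n_wavelengths) {
  structure(list(model = model, features = features, grid = grid,
                 label = label, n_wavelengths = as.integer(n_wavelengths)),
            class = "wc_model_bundle")
}

#' Predict water content from a sample table with a model bundle
#'
#' Spectra on a different grid are first resampled onto the bundle's grid by
#' linear interpolation; the external grid must cover the bundle grid's span.
#'
#' @param bundle A `wc_model_bundle`.
#' @param table A `sample_table`.
#' @return Numeric predictions, one per sample.
#' @export
predict_table <- function(bundle, table) {
  X <- table$reflectance
  if (!isTRUE(all.equal(table$grid$centers_nm, bundle$grid$centers_nm))) {
    src <- table$grid$centers_nm
    dst <- bundle$grid$centers_nm
    if (min(src) > min(dst) || max(src) < max(dst)) {
      stopf("external grid [%g, %g] nm does not cover the model grid [%g, %g] nm",
            min(src), max(src), min(dst), max(dst))
    }
    X <- t(apply(X, 1, function(row) stats::approx(src, row, xout = dst)$y))
  }
  feats <- bundle$features(X, bundle$grid)
  if (inherits(bundle$model, "index_model")) {
    predict(bundle$model, drop(feats[, 1]))
  } else {
    predict(bundle$model, feats)
  }
}

#' Rank candidate models by accuracy and parsimony
#'
#' Among models whose prediction-set R^2 is within `delta_r2` of the best,
#' the one using the fewest wavelengths wins; ties break by lower RMSEP.
#' Models outside the window are ignored, so when no competitor comes close
#' the rule reduces to the plain R^2 arg-max.
#'
#' @param rows data.frame with columns `model`, `r2_pred`, `rmsep`,
#'   `n_wavelengths`.
#' @param delta_r2 Parsimony window (default 0.025).
#' @return The chosen row (single-row data.frame) with attribute `index`.
#' @export
rank_models <- function(rows, delta_r2 = 0.025) {
  stopifnot(is.data.frame(rows))
  if (nrow(rows) == 0) stopf("no model rows to rank")
  need <- c("model", "r2_pred", "rmsep", "n_wavelengths")
  missing_cols <- setdiff(need, names(rows))
  if (length(missing_cols) > 0) {
    stopf("rows missing columns: %s", paste(missing_cols, collapse = ", "))
  }
  best_r2 <- max(rows$r2_pred)
  cand <- which(rows$r2_pred >= best_r2 - delta_r2)
  cand <- cand[order(rows$n_wavelengths[cand], rows$rmsep[cand])]
  chosen <- rows[cand[1], , drop = FALSE]
  attr(chosen, "index") <- cand[1]
  chosen
}

#' Evaluate a frozen model on an external species table
#'
#' Applies the bundle without refitting and reports the Pearson correlation
#' (with two-tailed p), prediction R^2 and RMSEP, overall and per subgroup.
#'
#' @param bundle A `wc_model_bundle`.
#' @param external A `sample_table` on a compatible grid.
#' @param subgroups Optional factor/character labels, one per sample.
#' @return data.frame with one `overall` row plus one row per subgroup.
#' @export
cross_species_eval <- function(bundle, external, subgroups = NULL) {
  pred <- predict_table(bundle, external)
  wc <- external$water_content
  eval_group <- function(name, idx) {
    pr <- pearson(pred[idx], wc[idx])
    data.frame(group = name, n = length(idx), r = pr$r, p = pr$p,
               r2_pred = r_squared(wc[idx], pred[idx]),
               rmsep = rmse(wc[idx], pred[idx]))
  }
  out <- eval_group("overall", seq_along(wc))
  if (!is.null(subgroups)) {
    stopifnot(length(subgroups) == length(wc))
    for (g in unique(subgroups)) {
      out <- rbind(out, eval_group(as.character(g), which(subgroups == g)))
    }
  }
  out
}

# one model row of the study report
model_row <- function(label, feature_method, regressor, n_wavelengths,
                      r2_cal, rmse_cal, r2_pred, rmsep) {
  data.frame(model = label, feature_method = feature_method,
             regressor = regressor, n_wavelengths = as.integer(n_wavelengths),
             r2_cal = r2_cal, rmse_cal = rmse_cal,
             r2_pred = r2_pred, rmsep = rmsep)
}

#' Run the full study pipeline
#'
#' Executes every enabled stage from one configuration: synthetic data
#' generation, calibration/prediction split, preprocessing comparison,
#' NISDI and exhaustive two-band index models, wavelength selection crossed
#' with the regressor grid, model ranking, per-pixel water mapping, and
#' cross-species evaluation on matched and distribution-shifted external
#' tables. With `out_dir` set, writes `report.json`, CSV tables and the
#' rendered map; the run is a pure function of the configuration, so the
#' written report is byte-identical across repeated runs.
#'
#' @param config A `pipeline_config`.
#' @return A `study_report` list: `models` (the metrics grid),
#'   `index_search`, `selection`, `prep_comparison`, `chosen`,
#'   `cross_species`, `map_summary`, `bundles` (fitted model bundles,
#'   in-memory only), `seed`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed
  sim_cfg <- do.call(sim_config, config$sim)
  grid <- sim_grid(sim_cfg)

  table <- simulate_sample_table(config$n_samples, sim_cfg,
                                 seed = derive_seed(seed, 11))
  parts <- split_table(table, config$test_fraction, config$split_method,
                       seed = derive_seed(seed, 12))
  cal <- parts$calibration
  pred <- parts$prediction
  y_cal <- cal$water_content
  y_pred <- pred$water_content

  prep_tab <- NULL
  prep_name <- config$prep_method
  if (config$prep_compare) {
    prep_tab <- compare_preprocessing(cal, seed = derive_seed(seed, 13))
    if (is.null(prep_name)) prep_name <- prep_tab$method[1]
  }
  if (is.null(prep_name)) prep_name <- "SNV"
  prep_m <- prep_method(prep_name)
  prep_cal <- apply_prep(prep_m, cal$reflectance, grid)
  prep_state <- prep_cal$state
  X_cal <- prep_cal$X
  X_pred <- apply_prep(prep_m, pred$reflectance, grid, prep_state)$X

  rows <- list()
  bundles <- list()

  # --- index models on raw reflectance ---
  nis_cal <- as.numeric(nisdi(cal$reflectance, grid))
  nis_pred <- as.numeric(nisdi(pred$reflectance, grid))
  m_nisdi <- fit_index_model(nis_cal, y_cal, nis_pred, y_pred)
  rows$NISDI <- model_row("NISDI-LR", "NISDI", "LR", 3,
                          m_nisdi$metrics$r2_cal, m_nisdi$metrics$rmse_cal,
                          m_nisdi$metrics$r2_pred, m_nisdi$metrics$rmsep)
  bundles[["NISDI-LR"]] <- wc_model_bundle(m_nisdi, nisdi_extractor(), grid,
                                           "NISDI-LR", 3)
  searches <- list()
  for (fam in config$index_families) {
    sr <- search_pairs(cal, fam)
    searches[[fam]] <- sr
    i <- sr$best_pair[["i"]]; j <- sr$best_pair[["j"]]
    iv_cal <- pair_index(fam, cal$reflectance[, i], cal$reflectance[, j])
    iv_pred <- pair_index(fam, pred$reflectance[, i], pred$reflectance[, j])
    m_idx <- fit_index_model(iv_cal, y_cal, iv_pred, y_pred)
    label <- sprintf("%s-LR", fam)
    rows[[label]] <- model_row(label, fam, "LR", 2,
                               m_idx$metrics$r2_cal, m_idx$metrics$rmse_cal,
                               m_idx$metrics$r2_pred, m_idx$metrics$rmsep)
    local({
      fam_ <- fam; i_ <- i; j_ <- j; m_ <- m_idx
      feats <- structure(function(X, g) {
        matrix(pair_index(fam_, X[, i_], X[, j_]), ncol = 1)
      }, class = c("feature_extractor", "function"))
      bundles[[label]] <<- wc_model_bundle(m_, feats, grid, label, 2)
    })
  }

  # --- wavelength selection x regressor grid on preprocessed spectra ---
  feature_sets <- list()
  selection <- list()
  for (sel_name in config$selectors) {
    res <- switch(sel_name,
                  CARS = cars(X_cal, y_cal, grid, seed = derive_seed(seed, 21)),
                  SPA = spa(X_cal, y_cal, grid, seed = derive_seed(seed, 22)),
                  UVE = uve(X_cal, y_cal, grid, seed = derive_seed(seed, 23)),
                  stopf("unknown selector '%s'", sel_name))
    selection[[sel_name]] <- res
    feature_sets[[sel_name]] <- res$selected_band_indices
  }
  if (config$include_full_spectrum) {
    feature_sets[["Full"]] <- seq_len(ncol(X_cal))
  }
  for (fs_name in names(feature_sets)) {
    sel <- feature_sets[[fs_name]]
    for (kind in config$regressors) {
      if (kind == "MLR" && nrow(X_cal) <= length(sel) + 1) {
        warnf("skipping %s-MLR: n (%d) too small for %d bands",
              fs_name, nrow(X_cal), length(sel))
        next
      }
      spec <- regressor_spec(kind)
      model <- tryCatch(
        fit_regressor(spec, X_cal[, sel, drop = FALSE], y_cal),
        error = function(e) {
          warnf("skipping %s-%s: %s", fs_name, kind, conditionMessage(e))
          NULL
        })
      if (is.null(model)) next
      ev_cal <- evaluate(model, X_cal[, sel, drop = FALSE], y_cal)
      ev_pred <- evaluate(model, X_pred[, sel, drop = FALSE], y_pred)
      label <- sprintf("%s-%s", fs_name, kind)
      rows[[label]] <- model_row(label, fs_name, kind, length(sel),
                                 ev_cal$r2, ev_cal$rmse, ev_pred$r2, ev_pred$rmse)
      local({
        sel_ <- sel; model_ <- model; pm <- prep_m; st <- prep_state
        feats <- structure(function(X, g) {
          apply_prep(pm, X, g, st)$X[, sel_, drop = FALSE]
        }, class = c("feature_extractor", "function"))
        bundles[[label]] <<- wc_model_bundle(model_, feats, grid, label,
                                             length(sel_))
      })
    }
  }

  models <- do.call(rbind, rows)
  rownames(models) <- NULL
  chosen <- rank_models(models, config$rank_delta_r2)
  chosen_bundle <- bundles[[chosen$model]]

  # --- per-pixel water map ---
  map_summary <- NULL
  map <- NULL
  if (!is.null(config$cube)) {
    sc <- simulate_cube(config$cube$height, config$cube$width, sim_cfg,
                        lamina_wc = config$cube$lamina_wc,
                        vein_offset = config$cube$vein_offset,
                        seed = derive_seed(seed, 31))
    map <- predict_map(sc$cube, chosen_bundle$model,
                       feature_extractor = chosen_bundle$features,
                       model_id = chosen_bundle$label)
    vein_mean <- mean(map$values[sc$veins])
    lam_mean <- mean(map$values[sc$cube$mask & !sc$veins])
    map_summary <- list(model = chosen_bundle$label,
                        mean_wc = map_mean(map),
                        vein_mean = vein_mean, lamina_mean = lam_mean,
                        true_mean = mean(sc$true_wc[sc$cube$mask]))
  }

  # --- cross-species evaluation ---
  cross <- NULL
  if (config$cross_species) {
    ext_matched <- simulate_sample_table(config$n_samples, sim_cfg,
                                         species = "synthetic-matched",
                                         role = "external",
                                         seed = derive_seed(seed, 41))
    shift_cfg <- sim_cfg
    shift_cfg$wc_range <- c(0.10, 0.96)
    shift_cfg$absorption_depth_per_wc <- sim_cfg$absorption_depth_per_wc * 0.75
    shift_cfg$absorption_widths_nm <- sim_cfg$absorption_widths_nm * 1.3
    shift_cfg$scatter_mult_sd <- sim_cfg$scatter_mult_sd * 1.5
    ext_shift <- simulate_sample_table(config$n_samples, shift_cfg,
                                       species = "synthetic-shifted",
                                       role = "external",
                                       seed = derive_seed(seed, 42))
    cross <- rbind(
      cbind(species = "matched",
            cross_species_eval(chosen_bundle, ext_matched)),
      cbind(species = "shifted",
            cross_species_eval(chosen_bundle, ext_shift))
    )
  }

  report <- structure(list(
    models = models,
    index_search = lapply(searches, function(s) {
      list(family = s$family, best_pair = as.integer(s$best_pair),
           best_wavelengths_nm = s$best_wavelengths_nm,
           best_abs_r = s$best_abs_r, best_p = s$best_p)
    }),
    selection = lapply(selection, function(s) {
      list(method = s$method,
           selected_band_indices = s$selected_band_indices,
           selected_wavelengths_nm = s$selected_wavelengths_nm,
           best_trace_value = s$best_trace_value,
           n_selected = length(s$selected_band_indices))
    }),
    prep_comparison = prep_tab,
    prep_method = prep_name,
    chosen = chosen,
    cross_species = cross,
    map_summary = map_summary,
    seed = seed
  ), class = "study_report")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_report(report, file.path(config$out_dir, "report.json"))
    utils::write.csv(models, file.path(config$out_dir, "model_metrics.csv"),
                     row.names = FALSE)
    if (!is.null(prep_tab)) {
      utils::write.csv(prep_tab,
                       file.path(config$out_dir, "prep_comparison.csv"),
                       row.names = FALSE)
    }
    if (!is.null(map)) {
      render_map(map, file.path(config$out_dir, "water_map.png"))
    }
  }
  report$bundles <- bundles
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report> %d model rows; chosen: %s (R_P^2 = %.4f, RMSEP = %.4f, %d wavelengths)\n",
              nrow(x$models), x$chosen$model, x$chosen$r2_pred,
              x$chosen$rmsep, x$chosen$n_wavelengths))
  invisible(x)
}

#' Write / read a study report as JSON
#'
#' The JSON holds every serializable part of the report (model bundles stay
#' in memory). Writing is deterministic: the same report yields
#' byte-identical files.
#'
#' @param report A `study_report`.
#' @param path JSON path.
#' @return `read_report` returns the deserialized report list.
#' @export
write_report <- function(report, path) {
  out <- unclass(report)
  out$bundles <- NULL
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}

#' Packaged benchmark model metrics
#'
#' A reference table of published model metrics from a peach-leaf
#' water-content benchmark (feature-selection method x regressor grid plus
#' the 3-wavelength NISDI linear model), used to exercise the ranking rule
#' on realistic numbers.
#'
#' @return data.frame with columns model, feature_method, regressor,
#'   n_wavelengths, r2_cal, rmse_cal, r2_pred, rmsep.
#' @export
benchmark_model_metrics <- function() {
  utils::read.csv(system.file("extdata", "benchmark_model_metrics.csv",
                              package = "hyperleaf"))
}

#' Packaged benchmark selected wavelengths
#'
#' Reference characteristic-wavelength lists chosen by CARS, SPA and UVE in
#' the same benchmark study, on the instrument's native (slightly
#' non-uniform) grid.
#'
#' @return data.frame with columns method, wavelength_nm.
#' @export
benchmark_selected_wavelengths <- function() {
  utils::read.csv(system.file("extdata", "benchmark_selected_wavelengths.csv",
                              package = "hyperleaf"))
}
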