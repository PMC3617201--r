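#' @keywords internal
write_report_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

report_manifest <- function(out_dir, step, config, seed, files) {
  manifest <- list(step = step, seed = seed,
                   config_hash = rlang::hash(config),
                   package_version = as.character(utils::packageVersion("crabacid")),
                   files = files)
  jsonlite::write_json(manifest, file.path(out_dir, paste0(step, "_manifest.json")),
                       auto_unbox = TRUE, pretty = TRUE)
  manifest
}

#' Simulate a cohort experiment and write its tables to disk
#'
#' Writes the four CSVs (temperature, census, molts, terminal assay)
#' consumed by the fitting steps, the ground-truth parameters as JSON, and
#' a manifest recording the seed and a hash of the configuration.
#'
#' @param config a [cohort_config()]; its seed drives all randomness.
#' @param out_dir output directory (created if needed).
#' @return (invisibly) the `synthetic_experiment` with a `files` attribute.
#' @export
run_simulate <- function(config = cohort_config(), out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  exp <- simulate_cohort(config)
  files <- c(temperature = file.path(out_dir, "temperature.csv"),
             census = file.path(out_dir, "census.csv"),
             molts = file.path(out_dir, "molts.csv"),
             assay = file.path(out_dir, "assay.csv"))
  write_report_csv(exp$temperature, files["temperature"])
  write_report_csv(exp$census, files["census"])
  write_report_csv(exp$molts, files["molts"])
  write_report_csv(exp$assay, files["assay"])
  gt <- lapply(exp$ground_truth, function(x)
    if (is.atomic(x) && !is.null(names(x))) as.list(x) else x)
  jsonlite::write_json(gt, file.path(out_dir, "ground_truth.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  report_manifest(out_dir, "simulate", config, config$seed, as.list(files))
  attr(exp, "files") <- files
  invisible(exp)
}

#' Fit the mortality model ladder and write survival reports
#'
#' Reads a census CSV (crab_id, treatment, day, status), fits the three
#' hazard structures, and writes (a) a per-treatment rate table in the
#' survival-figure layout (treatment, rate, SE, percent increase over
#' control) from the all-different fit and (b) the AICc ranking table
#' (Model, K, AICc, dAICc, Likelihood, Weight).
#'
#' @param census_csv path to the census table.
#' @param out_dir output directory.
#' @param n_aicc AICc sample-size convention (see [compare_structures()]).
#' @return (invisibly) the [compare_structures()] result.
#' @export
run_fit_survival <- function(census_csv, out_dir, n_aicc = "crabs") {
  census <- utils::read.csv(census_csv, stringsAsFactors = FALSE)
  recs <- census_to_records(census)
  cmp <- compare_structures(recs, n_aicc = n_aicc)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fit <- cmp$fits$all_different
  trt <- names(hazard_structure("all_different")$mapping)
  trt <- trt[trt %in% unique(as.character(recs$treatment))]
  idx <- hazard_structure("all_different")$mapping[trt]
  rates <- fit$rates[idx]
  ref <- if ("control" %in% trt) rates[match("control", trt)] else rates[1]
  rate_tab <- data.frame(
    treatment = trt, rate_per_day = rates, se_per_day = fit$se[idx],
    percent_increase_vs_control = ifelse(ref > 0,
                                         rate_percent_increase(rates, ref), NA))
  rank_tab <- data.frame(Model = cmp$ranking$model, K = cmp$ranking$K,
                         AICc = round(cmp$ranking$aicc, 2),
                         dAICc = round(cmp$ranking$delta_aicc, 2),
                         Likelihood = round(cmp$ranking$rel_likelihood, 2),
                         Weight = round(cmp$ranking$weight, 2))
  files <- c(rates = file.path(out_dir, "mortality_rates.csv"),
             ranking = file.path(out_dir, "mortality_ranking.csv"))
  write_report_csv(rate_tab, files["rates"])
  write_report_csv(rank_tab, files["ranking"])
  jsonlite::write_json(
    list(rates = as.list(stats::setNames(rates, trt)),
         se = as.list(stats::setNames(fit$se[idx], trt)),
         loglik = fit$loglik, flags = fit$flags),
    file.path(out_dir, "mortality_fit.json"), auto_unbox = TRUE, digits = NA)
  report_manifest(out_dir, "fit_survival",
                  list(census_csv = census_csv, n_aicc = n_aicc), NA, as.list(files))
  invisible(cmp)
}

#' Fit the growth models and write growth reports
#'
#' Reads the molt table (and temperature series for context), runs the
#' carapace-length ANCOVA and the four-variant wet-mass ladder, and writes
#' the per-treatment line fits, the wet-mass model ranking in the
#' growth-table layout, and the fitted parameters as JSON.
#'
#' @param molts_csv path to the molt/morphometrics table.
#' @param out_dir output directory.
#' @param n_aicc AICc convention for the wet-mass ladder.
#' @param alpha interaction-test significance level.
#' @return (invisibly) list with `cl` ([fit_cl_linear()]) and `wm`
#'   ([rank_wm_models()]).
#' @export
run_fit_growth <- function(molts_csv, out_dir, n_aicc = "observations",
                           alpha = 0.05) {
  molts <- utils::read.csv(molts_csv, stringsAsFactors = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cl <- fit_cl_linear(molts, alpha = alpha)
  wm <- rank_wm_models(molts[is.finite(molts$wm_g), ], n_aicc = n_aicc)
  files <- character(0)
  if (!is.null(cl$per_treatment)) {
    files["cl_lines"] <- file.path(out_dir, "cl_lines.csv")
    write_report_csv(cl$per_treatment, files["cl_lines"])
  }
  rk <- wm$ranking
  files["wm_ranking"] <- file.path(out_dir, "wm_ranking.csv")
  write_report_csv(data.frame(Model = rk$model, K = rk$K,
                              AICc = round(rk$aicc, 2),
                              dAICc = round(rk$delta_aicc, 2),
                              Likelihood = round(rk$rel_likelihood, 2),
                              Weight = round(rk$weight, 2)),
                   files["wm_ranking"])
  best <- wm$fits[[rk$model[1]]]
  jsonlite::write_json(
    list(cl_interaction = cl$interaction,
         wm_best_variant = best$variant,
         wm_b = as.list(best$b), wm_sigma = best$sigma,
         wm_loglik = best$loglik, converged = best$converged),
    file.path(out_dir, "growth_fit.json"), auto_unbox = TRUE, digits = NA)
  report_manifest(out_dir, "fit_growth",
                  list(molts_csv = molts_csv, n_aicc = n_aicc, alpha = alpha),
                  NA, as.list(files))
  invisible(list(cl = cl, wm = wm))
}

#' Run the morphometric PCA and nested ANOVA, writing reports
#'
#' Reads the molt table, standardizes the landmark columns, runs the PCA
#' and the nested Treatment x Molt ANOVA on PC1 scores, and writes the
#' eigenvalue/percent-variance table, the loadings, and the ANOVA table.
#'
#' @param molts_csv path to the molt/morphometrics table (landmark columns
#'   named landmark_*).
#' @param out_dir output directory.
#' @param min_fraction molt-inclusion filter (see [pc_anova()]).
#' @return (invisibly) list with `pca` and `anova`.
#' @export
run_morphometrics <- function(molts_csv, out_dir, min_fraction = 0.2) {
  molts <- utils::read.csv(molts_csv, stringsAsFactors = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  lm_cols <- grep("^landmark_", names(molts), value = TRUE)
  if (!length(lm_cols)) stop("no landmark_* columns in ", molts_csv)
  pca <- morpho_pca(normalize_morphometrics(molts[, lm_cols]))
  an <- pc_anova(pca$scores[, 1], molts$treatment, molts$molt_number,
                 molts$crab_id, min_fraction = min_fraction)
  files <- c(eigen = file.path(out_dir, "pca_eigenvalues.csv"),
             loadings = file.path(out_dir, "pca_loadings.csv"),
             anova = file.path(out_dir, "pc1_anova.csv"))
  write_report_csv(data.frame(PC = seq_along(pca$eigenvalues),
                              Eigenvalue = round(pca$eigenvalues, 2),
                              PercentVariation = round(pca$percent_variance, 1),
                              CumPercentVariation = round(pca$cumulative_percent, 1)),
                   files["eigen"])
  write_report_csv(cbind(Variable = rownames(pca$loadings),
                         as.data.frame(round(pca$loadings, 3))),
                   files["loadings"])
  write_report_csv(an$terms, files["anova"])
  report_manifest(out_dir, "morphometrics",
                  list(molts_csv = molts_csv, min_fraction = min_fraction),
                  NA, as.list(files))
  invisible(list(pca = pca, anova = an))
}

#' Run the terminal endpoint tests, writing a report
#'
#' Reads the terminal assay table, computes the condition index, and runs
#' the Levene-gated treatment comparison for condition index, percent
#' calcium and percent magnesium.
#'
#' @param assay_csv path to the terminal assay table.
#' @param out_dir output directory.
#' @param alpha significance level.
#' @return (invisibly) named list of `endpoint_test`s.
#' @export
run_endpoints <- function(assay_csv, out_dir, alpha = 0.05) {
  assay <- utils::read.csv(assay_csv, stringsAsFactors = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  assay$ci <- condition_index(assay$dry_mass_g, assay$length_mm)
  vars <- c(condition_index = "ci", pct_ca = "pct_ca", pct_mg = "pct_mg")
  tests <- lapply(vars, function(v)
    endpoint_comparison(assay[[v]], assay$treatment, alpha))
  rows <- do.call(rbind, lapply(names(tests), function(nm) {
    tt <- tests[[nm]]
    data.frame(variable = nm, test = tt$test, statistic = tt$statistic,
               p = tt$p, levene_p = tt$levene$p,
               group_means = paste(sprintf("%s=%.4g", names(tt$group_means),
                                           tt$group_means), collapse = "; "),
               percent_differences = paste(
                 sprintf("%s vs %s: %+.1f%%",
                         tt$percent_differences$group_a,
                         tt$percent_differences$group_b,
                         tt$percent_differences$percent_difference),
                 collapse = "; "),
               stringsAsFactors = FALSE)
  }))
  f <- file.path(out_dir, "endpoint_tests.csv")
  write_report_csv(rows, f)
  report_manifest(out_dir, "endpoints", list(assay_csv = assay_csv,
                                             alpha = alpha), NA, list(f))
  invisible(tests)
}

#' Solve the carbonate system for a water-sample table, writing a report
#'
#' Reads a water-chemistry sample CSV (treatment, pH_free, dic_mmol_kg,
#' temp_c, optional salinity), solves the speciation row-wise, and writes
#' a per-treatment mean +/- SE summary in the water-chemistry-table layout
#' plus the saturation-state classification.
#'
#' @param samples_csv path to the sample table.
#' @param out_dir output directory.
#' @param salinity default salinity for rows without one.
#' @return (invisibly) the [carbonate_summary()] result.
#' @export
run_carbonate <- function(samples_csv, out_dir, salinity = 32) {
  samples <- utils::read.csv(samples_csv, stringsAsFactors = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cs <- carbonate_summary(samples, salinity = salinity)
  summ <- cs$summary
  summ$aragonite_class <- classify_saturation(summ$omega_aragonite_mean)
  summ$calcite_class <- classify_saturation(summ$omega_calcite_mean)
  f <- file.path(out_dir, "carbonate_summary.csv")
  write_report_csv(summ, f)
  report_manifest(out_dir, "carbonate",
                  list(samples_csv = samples_csv, salinity = salinity),
                  NA, list(f))
  invisible(cs)
}
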