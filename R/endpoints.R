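#' Condition index (body-mass index) of a crab
#'
#' Dry mass in grams divided by the cube of the reference carapace
#' dimension in millimeters (carapace length for red king crab, carapace
#' width for Tanner crab); units g mm^-3. A mass-at-size proxy for
#' energetic condition.
#'
#' @param dry_mass_g dry mass (g, > 0).
#' @param length_mm reference carapace dimension (mm, > 0).
#' @return condition index (g mm^-3).
#' @export
condition_index <- function(dry_mass_g, length_mm) {
  if (any(dry_mass_g <= 0) || any(length_mm <= 0)) {
    stop("dry mass and length must be positive")
  }
  dry_mass_g / length_mm^3
}

#' Treatment comparison of a terminal or per-molt endpoint
#'
#' The homoscedasticity-gated test used for every endpoint (condition
#' index, percent calcium/magnesium, per-molt carapace size and wet mass,
#' intermolt duration): Levene's test decides between a one-way ANOVA
#' (with Fisher LSD contrasts when the omnibus F is significant) and a
#' Kruskal-Wallis test (with pairwise Wilcoxon rank-sum contrasts,
#' unadjusted, when significant). Group means and pairwise percent
#' differences of arithmetic means are always reported.
#'
#' @param values numeric endpoint values.
#' @param group treatment labels (>= 2 groups).
#' @param alpha significance level for the Levene gate, the omnibus test
#'   and the post-hoc gate (default 0.05).
#' @param levene_center center for Levene's test ("mean" or "median").
#' @return object of class `endpoint_test`: `test` ("anova" or
#'   "kruskal_wallis"), `statistic`, `df`, `p`, `levene` (W, p),
#'   `group_means`, `group_n`, `percent_differences` (100*(mean_a/mean_b-1)
#'   per pair), `posthoc` (LSD or rank-sum table, NULL if omnibus not
#'   significant).
#' @export
endpoint_comparison <- function(values, group, alpha = 0.05,
                                levene_center = "mean") {
  group <- check_grouped(values, group)
  lev <- levene(values, group, center = levene_center)
  hetero <- is.finite(lev$p) && lev$p < alpha
  means <- tapply(values, group, mean)
  ns <- as.integer(table(group))
  pairs <- utils::combn(levels(group), 2)
  pctdiff <- data.frame(
    group_a = pairs[1, ], group_b = pairs[2, ],
    percent_difference = apply(pairs, 2, function(pr)
      100 * (means[pr[1]] / means[pr[2]] - 1)),
    stringsAsFactors = FALSE)
  if (!hetero) {
    fit <- one_way_anova(values, group)
    posthoc <- if (fit$p < alpha) fisher_lsd(values, group, fit, alpha) else NULL
    out <- list(test = "anova", statistic = fit$F, df = fit$df, p = fit$p)
  } else {
    kw <- kruskal_wallis(values, group)
    posthoc <- NULL
    if (kw$p < alpha) {
      posthoc <- data.frame(
        group_a = pairs[1, ], group_b = pairs[2, ],
        p = apply(pairs, 2, function(pr) {
          stats::wilcox.test(values[group == pr[1]], values[group == pr[2]],
                             exact = FALSE)$p.value
        }), stringsAsFactors = FALSE)
    }
    out <- list(test = "kruskal_wallis", statistic = kw$H, df = kw$df, p = kw$p)
  }
  out$levene <- lev
  out$group_means <- means
  out$group_n <- stats::setNames(ns, levels(group))
  out$percent_differences <- pctdiff
  out$posthoc <- posthoc
  class(out) <- "endpoint_test"
  out
}

#' @export
print.endpoint_test <- function(x, ...) {
  lbl <- if (x$test == "anova") "one-way ANOVA" else "Kruskal-Wallis (Levene gate)"
  stat <- if (x$test == "anova") "F" else "H"
  cat(sprintf("%s: %s = %.3f, p = %.4g\n", lbl, stat, x$statistic, x$p))
  cat("  group means:", paste(sprintf("%s = %.4g", names(x$group_means),
                                      x$group_means), collapse = ", "), "\n")
  pd <- x$percent_differences
  cat("  percent differences:",
      paste(sprintf("%s vs %s: %+.1f%%", pd$group_a, pd$group_b,
                    pd$percent_difference), collapse = "; "), "\n")
  invisible(x)
}

#' Per-molt cross-sectional analysis for species without a growth trajectory
#'
#' When too few crabs molt enough times for a time-course fit (the Tanner
#' crab case), size and mass are compared across treatments separately at
#' each molt stage, and intermolt degree-day durations are compared between
#' consecutive molt pairs, all through [endpoint_comparison()].
#'
#' @param molts molt observation table (crab_id, treatment, day,
#'   molt_number, plus the measurement columns in `variables`).
#' @param series daily temperature series for the intermolt durations.
#' @param variables measurement columns to compare per molt (default
#'   c("cw_mm", "wm_g")).
#' @param alpha significance level.
#' @return list with `per_molt` (named list molt -> variable ->
#'   `endpoint_test`) and `intermolt` (named list "m-1 to m" ->
#'   `endpoint_test`).
#' @export
per_molt_comparison <- function(molts, series, variables = c("cw_mm", "wm_g"),
                                alpha = 0.05) {
  stopifnot(all(c("crab_id", "treatment", "molt_number") %in% names(molts)))
  variables <- intersect(variables, names(molts))
  per_molt <- lapply(sort(unique(molts$molt_number)), function(m) {
    sub <- molts[molts$molt_number == m, , drop = FALSE]
    res <- lapply(variables, function(v) {
      vals <- sub[[v]]
      ok <- is.finite(vals)
      if (length(unique(sub$treatment[ok])) < 2L || sum(ok) < 4L) return(NULL)
      tryCatch(endpoint_comparison(vals[ok], sub$treatment[ok], alpha),
               error = function(e) NULL)
    })
    names(res) <- variables
    res
  })
  names(per_molt) <- paste0("molt_", sort(unique(molts$molt_number)))
  im <- intermolt_periods(molts, series)
  intermolt <- lapply(sort(unique(im$to_molt)), function(m) {
    sub <- im[im$to_molt == m, , drop = FALSE]
    if (length(unique(sub$treatment)) < 2L || nrow(sub) < 4L) return(NULL)
    tryCatch(endpoint_comparison(sub$dd, sub$treatment, alpha),
             error = function(e) NULL)
  })
  names(intermolt) <- paste0("to_molt_", sort(unique(im$to_molt)))
  list(per_molt = per_molt, intermolt = intermolt)
}
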