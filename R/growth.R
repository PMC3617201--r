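#' Cumulative degree-days over an interval of a daily temperature series
#'
#' The thermal clock used for crustacean molting and growth: the sum of
#' daily mean temperatures above a base temperature over the half-open day
#' interval (start, end]. The base defaults to 0 degrees C.
#'
#' @param series data frame with columns `day` (contiguous integers) and
#'   `temp_c` (daily mean, degrees C).
#' @param start,end day indices within the series, start <= end.
#' @param base base temperature (degrees C) below which no degree-days
#'   accumulate.
#' @return degree-days (degree C x day).
#' @export
cumulative_degree_days <- function(series, start, end, base = 0) {
  stopifnot(all(c("day", "temp_c") %in% names(series)))
  if (start > end) stop("start must be <= end")
  if (start < min(series$day) - 1 || end > max(series$day)) {
    stop("interval (", start, ", ", end, "] outside temperature series")
  }
  if (start == end) return(0)
  sel <- series$day > start & series$day <= end
  sum(pmax(series$temp_c[sel] - base, 0))
}

#' Degree-days elapsed from experiment start to each of a vector of days
#' @noRd
dd_at <- function(series, days, base = 0) {
  cum <- cumsum(pmax(series$temp_c - base, 0))
  ifelse(days <= 0, 0, cum[pmin(days, length(cum))])
}

#' Linear carapace-length growth with nested ANCOVA
#'
#' Fits carapace length against time (degree-days) with Treatment fully
#' crossed with Time and Crab nested within Treatment, tests the
#' Treatment x Time interaction, and — when the interaction is significant
#' at `alpha`, indicating different growth rates — refits each treatment
#' separately with Time plus crab intercepts, reporting per-treatment slope
#' and intercept. Only crabs with at least `min_points` observations are
#' used; initial (molt 0) sizes are excluded by default because the molt
#' stage at entry is unknown.
#'
#' @param obs molt observations: data frame with crab_id, treatment, t
#'   (degree-days), cl_mm, and optionally molt_number.
#' @param alpha significance level for the interaction test.
#' @param min_points minimum observations per crab (default 3).
#' @param drop_initial drop molt_number == 0 rows when present.
#' @return object of class `cl_ancova`: `anova_table`, `interaction`
#'   (F, df, p), `per_treatment` (slope/intercept per treatment when the
#'   interaction is significant, else NULL), `n_crabs_used`, `dropped`.
#' @export
fit_cl_linear <- function(obs, alpha = 0.05, min_points = 3, drop_initial = TRUE) {
  stopifnot(all(c("crab_id", "treatment", "t", "cl_mm") %in% names(obs)))
  obs <- obs[is.finite(obs$cl_mm), , drop = FALSE]
  if (drop_initial && "molt_number" %in% names(obs)) {
    obs <- obs[obs$molt_number > 0, , drop = FALSE]
  }
  counts <- table(obs$crab_id)
  keep <- names(counts)[counts >= min_points]
  dropped <- setdiff(names(counts), keep)
  obs <- obs[obs$crab_id %in% keep, , drop = FALSE]
  # crabs must also span >= 2 distinct times
  times <- tapply(obs$t, obs$crab_id, function(x) length(unique(x)))
  degenerate <- names(times)[times < 2]
  if (length(degenerate)) {
    warning("dropping crab(s) with < 2 distinct times: ",
            paste(degenerate, collapse = ", "))
    obs <- obs[!obs$crab_id %in% degenerate, , drop = FALSE]
    dropped <- c(dropped, degenerate)
  }
  if (!nrow(obs)) stop("no crabs left after filtering")
  obs$treatment <- factor(obs$treatment)
  obs$crab_id <- factor(obs$crab_id)
  full <- stats::lm(cl_mm ~ treatment * t + treatment:crab_id, data = obs)
  tab <- stats::anova(full)
  it <- grep("^treatment:t$", rownames(tab))
  interaction <- list(F = tab[it, "F value"],
                      df = c(tab[it, "Df"], tab["Residuals", "Df"]),
                      p = tab[it, "Pr(>F)"])
  per_treatment <- NULL
  if (is.finite(interaction$p) && interaction$p < alpha ||
      !is.finite(interaction$p) && interaction$F > 0) {
    per_treatment <- do.call(rbind, lapply(levels(obs$treatment), function(tr) {
      d <- droplevels(obs[obs$treatment == tr, , drop = FALSE])
      fit <- if (nlevels(d$crab_id) > 1L) stats::lm(cl_mm ~ t + crab_id, data = d)
             else stats::lm(cl_mm ~ t, data = d)
      cf <- stats::coef(fit)
      # intercept reported as the mean over crab intercepts
      crab_adj <- cf[grep("^crab_id", names(cf))]
      data.frame(treatment = tr, slope = unname(cf["t"]),
                 intercept = unname(cf["(Intercept)"]) +
                   sum(crab_adj) / nlevels(d$crab_id),
                 n_crabs = nlevels(d$crab_id), stringsAsFactors = FALSE)
    }))
  }
  structure(list(anova_table = tab, interaction = interaction,
                 per_treatment = per_treatment,
                 n_crabs_used = length(unique(obs$crab_id)),
                 dropped = dropped),
            class = "cl_ancova")
}

#' @export
print.cl_ancova <- function(x, ...) {
  cat("Carapace-length ANCOVA (", x$n_crabs_used, " crabs)\n", sep = "")
  cat(sprintf("  Treatment x Time interaction: F(%d, %d) = %.3f, p = %.4g\n",
              x$interaction$df[1], x$interaction$df[2],
              x$interaction$F, x$interaction$p))
  if (!is.null(x$per_treatment)) {
    cat("  Per-treatment regressions (CL = slope * t + intercept):\n")
    print.data.frame(x$per_treatment, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

wm_variants <- c("a,b", "a(T),b", "a,b(T)", "a(T),b(T)")

#' Exponential wet-mass growth fit by maximum likelihood
#'
#' Wet mass follows WM = a_crab * exp(b t) with additive Gaussian errors on
#' the mass scale, t in degree-days. Per-crab intercepts a_crab are always
#' free; the variant controls whether the exponential growth coefficient b
#' is shared or treatment-specific, and whether the intercepts are read as
#' treatment-structured (a(T)): because per-crab intercepts absorb any
#' treatment-level mean, a(T) is structurally confounded with a and the
#' a(T) variants refit the same likelihood under the treatment-mean
#' reparameterization (see the package vignette). For a fixed b the
#' intercepts are profiled in closed form (weighted least squares against
#' exp(b t)), leaving a one-dimensional likelihood in each b, maximized by
#' golden-section search; the residual sd is profiled as sqrt(RSS/n) and
#' counted as a free parameter.
#'
#' @param obs data frame with crab_id, treatment, t (degree-days), wm_g.
#'   Wet mass is measured 7 days after each molt; when a `t_wm` column with
#'   the degree-days at the measurement is present it is used as the time
#'   axis, otherwise `t`.
#' @param variant one of "a,b", "a(T),b", "a,b(T)", "a(T),b(T)".
#' @param b_interval search interval for b (per degree-day).
#' @param error_scale "mass" (default; additive normal errors) or "log"
#'   (multiplicative lognormal errors, for robustness comparisons).
#' @return object of class `wm_fit`: `variant`, `b` (named per treatment or
#'   single shared value), `a` (per crab), `sigma`, `loglik`, `K`, `n_obs`,
#'   `converged`.
#' @export
fit_wm_exponential <- function(obs, variant = wm_variants,
                               b_interval = c(-0.005, 0.005),
                               error_scale = c("mass", "log")) {
  variant <- match.arg(variant)
  error_scale <- match.arg(error_scale)
  stopifnot(all(c("crab_id", "treatment", "t", "wm_g") %in% names(obs)))
  if (!"t_wm" %in% names(obs)) obs$t_wm <- obs$t
  obs$t_wm[!is.finite(obs$t_wm)] <- obs$t[!is.finite(obs$t_wm)]
  obs <- obs[is.finite(obs$wm_g) & obs$wm_g > 0, , drop = FALSE]
  nper <- table(obs$crab_id)
  obs <- obs[obs$crab_id %in% names(nper)[nper >= 2], , drop = FALSE]
  if (!nrow(obs)) stop("no crabs with >= 2 wet-mass observations")
  obs$crab_id <- factor(obs$crab_id)
  obs$treatment <- factor(obs$treatment)
  tt <- obs$t_wm
  y <- if (error_scale == "mass") obs$wm_g else log(obs$wm_g)
  b_by_treatment <- variant %in% c("a,b(T)", "a(T),b(T)")

  # profile RSS over per-crab intercepts at fixed b, within a subset
  rss_at_b <- function(b, rows) {
    x <- exp(b * tt[rows])
    yy <- y[rows]
    id <- obs$crab_id[rows]
    if (error_scale == "mass") {
      sxy <- tapply(x * yy, id, sum)
      sxx <- tapply(x * x, id, sum)
      a_i <- sxy / sxx
      res <- yy - a_i[as.character(id)] * x
    } else {
      # log scale: log y = log a + b t
      la <- tapply(yy - b * tt[rows], id, mean)
      res <- yy - (la[as.character(id)] + b * tt[rows])
      a_i <- exp(la)
    }
    list(rss = sum(res^2), a = a_i[!is.na(a_i)])
  }

  groups <- if (b_by_treatment) split(seq_len(nrow(obs)), obs$treatment)
            else list(all = seq_len(nrow(obs)))
  b_hat <- numeric(length(groups)); names(b_hat) <- names(groups)
  a_hat <- numeric(0)
  rss <- 0
  converged <- TRUE
  for (g in names(groups)) {
    rows <- groups[[g]]
    if (!length(rows)) { b_hat[g] <- NA_real_; next }
    opt <- stats::optimize(function(b) rss_at_b(b, rows)$rss,
                           interval = b_interval, tol = 1e-12)
    # flag optima pinned to the search boundary
    if (min(abs(opt$minimum - b_interval)) < 1e-6 * diff(b_interval)) {
      converged <- FALSE
    }
    b_hat[g] <- opt$minimum
    part <- rss_at_b(opt$minimum, rows)
    rss <- rss + part$rss
    a_hat <- c(a_hat, part$a)
  }
  n <- nrow(obs)
  sigma <- sqrt(rss / n)
  loglik <- if (sigma > 0) {
    base_ll <- -n / 2 * log(2 * pi * sigma^2) - n / 2
    if (error_scale == "log") base_ll - sum(y) else base_ll  # Jacobian of log
  } else Inf  # perfect interpolation; flagged below
  if (!is.finite(loglik)) {
    # noise-free data: report a degenerate but informative fit
    loglik <- Inf
  }
  n_crabs <- nlevels(obs$crab_id)
  n_b <- length(b_hat)
  K <- n_crabs + n_b + 1L  # crab intercepts + growth coefficient(s) + residual sd
  structure(list(variant = variant, b = b_hat, a = a_hat[order(names(a_hat))],
                 sigma = sigma, loglik = loglik, K = K, n_obs = n,
                 n_crabs = n_crabs, error_scale = error_scale,
                 converged = converged),
            class = "wm_fit")
}

#' @export
print.wm_fit <- function(x, ...) {
  cat("Exponential wet-mass fit, variant ", x$variant, " (",
      x$n_crabs, " crabs, ", x$n_obs, " observations)\n", sep = "")
  cat("  b:", paste(sprintf("%s = %.6g", names(x$b), x$b), collapse = ", "),
      "per degree-day\n")
  cat(sprintf("  residual sd: %.4g; log-likelihood: %.4f; K = %d\n",
              x$sigma, x$loglik, x$K))
  if (!x$converged) cat("  WARNING: optimum at search boundary\n")
  invisible(x)
}

#' Fit and rank the four wet-mass growth model variants
#'
#' Fits all four variants of [fit_wm_exponential()] and ranks them by AICc.
#' The effective sample size defaults to the number of wet-mass
#' observations: the parameter count (per-crab intercepts + growth
#' coefficients + residual sd) exceeds the number of crabs, so a
#' subject-based n would leave the small-sample correction undefined.
#'
#' @inheritParams fit_wm_exponential
#' @param n_aicc "observations" (default), "crabs", or a number.
#' @return list with `ranking` (a `model_ranking`) and `fits`.
#' @export
rank_wm_models <- function(obs, n_aicc = "observations",
                           b_interval = c(-0.005, 0.005)) {
  fits <- lapply(wm_variants, function(v)
    fit_wm_exponential(obs, v, b_interval = b_interval))
  names(fits) <- wm_variants
  n <- if (is.numeric(n_aicc)) n_aicc
       else if (n_aicc == "observations") fits[[1]]$n_obs
       else fits[[1]]$n_crabs
  ranking <- rank_models(wm_variants,
                         K = vapply(fits, `[[`, 0L, "K"),
                         loglik = vapply(fits, `[[`, 0, "loglik"), n = n)
  list(ranking = ranking, fits = fits)
}

#' Predicted percent size difference between two groups at a given time
#'
#' For linear carapace-length models, evaluates each line at t and returns
#' 100 * (CL_A/CL_B - 1); for exponential wet-mass models, evaluates
#' a * exp(b t) and returns the analogous ratio (with a shared intercept
#' the ratio reduces to exp((b_A - b_B) t), independent of a).
#'
#' @param params_a,params_b for `model = "linear"`: list(slope, intercept);
#'   for `model = "exponential"`: list(a, b).
#' @param t time in degree-days.
#' @param model "linear" or "exponential".
#' @return percent difference of group A over group B at time t.
#' @export
predict_percent_difference <- function(params_a, params_b, t,
                                       model = c("linear", "exponential")) {
  model <- match.arg(model)
  pred <- function(p) {
    if (model == "linear") p$slope * t + p$intercept
    else p$a * exp(p$b * t)
  }
  pa <- pred(params_a); pb <- pred(params_b)
  if (any(pb <= 0)) stop("reference prediction must be positive")
  100 * (pa / pb - 1)
}

#' Intermolt periods in degree-days
#'
#' Degree-days elapsed between consecutive molts of each crab (the interval
#' from experiment start to the first molt counts as the first period).
#'
#' @param molts data frame with crab_id, treatment, day, molt_number (> 0).
#' @param series daily temperature series (see [cumulative_degree_days()]).
#' @param base base temperature.
#' @return data frame: crab_id, treatment, from_molt, to_molt, dd.
#' @export
intermolt_periods <- function(molts, series, base = 0) {
  stopifnot(all(c("crab_id", "treatment", "day", "molt_number") %in% names(molts)))
  m <- molts[molts$molt_number > 0, , drop = FALSE]
  out <- do.call(rbind, lapply(split(m, m$crab_id), function(d) {
    d <- d[order(d$molt_number), , drop = FALSE]
    prev_day <- c(0, d$day[-nrow(d)])
    data.frame(crab_id = d$crab_id, treatment = d$treatment,
               from_molt = c(0, d$molt_number[-nrow(d)]),
               to_molt = d$molt_number,
               dd = vapply(seq_len(nrow(d)), function(i)
                 cumulative_degree_days(series, prev_day[i], d$day[i], base), 0),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
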