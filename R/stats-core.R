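#' Akaike's information criterion with small-sample correction
#'
#' AICc = -2 log L + 2K + 2K(K+1)/(n - K - 1). The correction term requires
#' n > K + 1; the effective sample size `n` is a modelling convention (see
#' the fitting functions, which default to the number of independent crabs
#' for survival fits and the number of observations for growth fits).
#'
#' @param loglik maximized log-likelihood of the model.
#' @param K number of free parameters (>= 1), counting every estimated
#'   quantity including any residual scale.
#' @param n effective sample size; must exceed K + 1.
#' @return the AICc value (numeric scalar).
#' @examples
#' aicc(loglik = 0, K = 1, n = 100)  # 2 + 4/98
#' @export
aicc <- function(loglik, K, n) {
  stopifnot(is.numeric(loglik), is.numeric(K), is.numeric(n))
  if (any(K < 1)) stop("K must be >= 1")
  if (any(n <= K + 1)) {
    stop("AICc undefined: need n > K + 1 (got n = ", n[which(n <= K + 1)[1]],
         ", K = ", K[which(n <= K + 1)[1]], ")")
  }
  -2 * loglik + 2 * K + 2 * K * (K + 1) / (n - K - 1)
}

#' Rank a set of fitted models by AICc
#'
#' Computes delta-AICc, relative likelihoods exp(-delta/2) and Akaike
#' weights (relative likelihoods normalized to sum to one). Models whose
#' AICc lies within 2 units of the best are flagged as ties: they explain
#' the data about equally well, and all of them are reported as co-best.
#'
#' @param labels character vector of model names.
#' @param K integer vector of parameter counts.
#' @param aicc_values AICc per model. Either supply this directly, or supply
#'   `loglik` and `n` and the AICc is computed.
#' @param loglik,n optional; used to compute AICc when `aicc_values` is NULL.
#' @return a `model_ranking` data frame (one row per model, sorted by AICc)
#'   with columns model, K, aicc, delta_aicc, rel_likelihood, weight, tied.
#' @export
rank_models <- function(labels, K, aicc_values = NULL, loglik = NULL, n = NULL) {
  if (length(labels) < 1L) stop("need at least one model to rank")
  if (is.null(aicc_values)) {
    if (is.null(loglik) || is.null(n)) stop("supply aicc_values, or loglik and n")
    aicc_values <- aicc(loglik, K, n)
  }
  stopifnot(length(labels) == length(K), length(K) == length(aicc_values))
  delta <- aicc_values - min(aicc_values)
  rel <- exp(-delta / 2)
  w <- rel / sum(rel)
  out <- data.frame(
    model = as.character(labels), K = as.integer(K), aicc = aicc_values,
    delta_aicc = delta, rel_likelihood = rel, weight = w,
    tied = delta < 2, stringsAsFactors = FALSE
  )
  out <- out[order(out$aicc), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("model_ranking", "data.frame")
  out
}

#' @export
print.model_ranking <- function(x, digits = 2, ...) {
  cat("Model ranking by AICc (", nrow(x), " models; best: ",
      paste(x$model[x$tied], collapse = ", "), ")\n", sep = "")
  df <- data.frame(Model = x$model, K = x$K,
                   AICc = round(x$aicc, digits),
                   dAICc = round(x$delta_aicc, digits),
                   Likelihood = round(x$rel_likelihood, digits),
                   Weight = round(x$weight, digits))
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

check_grouped <- function(values, group) {
  stopifnot(length(values) == length(group))
  group <- factor(group)
  if (nlevels(group) < 2L) stop("need at least 2 groups")
  if (any(table(group) == 0L)) group <- droplevels(group)
  if (length(values) <= nlevels(group)) stop("need more observations than groups")
  group
}

#' One-way analysis of variance
#'
#' Classical between/within mean-square F test for equality of group means,
#' computed through [stats::lm()]/[stats::anova()].
#'
#' @param values numeric response.
#' @param group group labels (coerced to factor; >= 2 non-empty groups).
#' @return list with elements `F`, `df` (numerator, denominator), `p`,
#'   `ms_within` (pooled error mean square) and `group_means`.
#' @export
one_way_anova <- function(values, group) {
  group <- check_grouped(values, group)
  if (stats::var(values) == 0) {
    stop("F undefined: zero between-group and within-group variance")
  }
  tab <- stats::anova(stats::lm(values ~ group))
  list(F = tab["group", "F value"],
       df = c(tab["group", "Df"], tab["Residuals", "Df"]),
       p = tab["group", "Pr(>F)"],
       ms_within = tab["Residuals", "Mean Sq"],
       group_means = c(tapply(values, group, mean)))
}

#' Levene's test for homogeneity of variance
#'
#' One-way ANOVA applied to absolute deviations from the group center
#' (classical mean-centered form by default; `center = "median"` gives the
#' Brown-Forsythe variant).
#'
#' @inheritParams one_way_anova
#' @param center "mean" (default) or "median".
#' @return list with `W` (the ANOVA F on absolute deviations), `df` and `p`.
#' @export
levene <- function(values, group, center = c("mean", "median")) {
  center <- match.arg(center)
  group <- check_grouped(values, group)
  centers <- tapply(values, group, if (center == "mean") mean else stats::median)
  dev <- abs(values - centers[as.character(group)])
  fit <- one_way_anova(dev, group)
  list(W = fit$F, df = fit$df, p = fit$p)
}

#' Kruskal-Wallis rank-sum test
#'
#' Nonparametric alternative to the one-way ANOVA, used when Levene's test
#' indicates heteroscedastic data. Wraps [stats::kruskal.test()] (midrank
#' tie correction, chi-square reference with groups - 1 df).
#'
#' @inheritParams one_way_anova
#' @return list with `H`, `df` and `p`.
#' @export
kruskal_wallis <- function(values, group) {
  group <- check_grouped(values, group)
  kt <- stats::kruskal.test(values, group)
  list(H = unname(kt$statistic), df = unname(kt$parameter), p = kt$p.value)
}

#' Fisher's least-significant-difference pairwise comparisons
#'
#' Pairwise t comparisons of group means using the pooled within-group mean
#' square from the omnibus ANOVA as the common error term (no multiplicity
#' adjustment, as is conventional for the LSD applied after a significant
#' omnibus F). By default refuses to run when the omnibus F is not
#' significant at `alpha`.
#'
#' @inheritParams one_way_anova
#' @param anova_fit result of [one_way_anova()] on the same data; computed
#'   if omitted.
#' @param alpha omnibus significance gate (default 0.05).
#' @param force logical; run even when the omnibus F is non-significant.
#' @return data frame with one row per pair: group_a, group_b, mean_diff,
#'   t, df, p.
#' @export
fisher_lsd <- function(values, group, anova_fit = NULL, alpha = 0.05,
                       force = FALSE) {
  group <- check_grouped(values, group)
  if (is.null(anova_fit)) anova_fit <- one_way_anova(values, group)
  if (!force && anova_fit$p > alpha) {
    stop("omnibus ANOVA not significant at alpha = ", alpha,
         "; LSD not applied (use force = TRUE to override)")
  }
  msw <- anova_fit$ms_within
  dfw <- anova_fit$df[2]
  if (msw <= 0) stop("zero pooled within-group variance: LSD t undefined")
  lev <- levels(group)
  ns <- table(group)
  ms <- tapply(values, group, mean)
  pairs <- utils::combn(lev, 2)
  res <- apply(pairs, 2, function(pr) {
    d <- ms[pr[1]] - ms[pr[2]]
    se <- sqrt(msw * (1 / ns[pr[1]] + 1 / ns[pr[2]]))
    tt <- d / se
    c(mean_diff = unname(d), t = unname(tt),
      p = 2 * stats::pt(-abs(unname(tt)), dfw))
  })
  data.frame(group_a = pairs[1, ], group_b = pairs[2, ],
             mean_diff = res["mean_diff", ], t = res["t", ],
             df = dfw, p = res["p", ], stringsAsFactors = FALSE)
}
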