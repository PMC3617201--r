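#' Standardize landmark measurements
#'
#' Expresses each landmark column in units of its standard deviation from
#' the column mean (z-scores; sd with the n-1 denominator), the
#' normalization applied before the principal component analysis.
#'
#' @param x numeric matrix or data frame of landmark measurements, one row
#'   per (crab, molt).
#' @return matrix with attributes `center` and `scale`; each column has
#'   mean 0 and sd 1.
#' @export
normalize_morphometrics <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("need at least 2 rows to standardize")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance column(s): ",
         paste(colnames(x)[sds == 0], collapse = ", "))
  }
  out <- scale(x, center = TRUE, scale = sds)
  attr(out, "scale") <- sds
  out
}

#' Invert [normalize_morphometrics()]
#' @param z standardized matrix carrying `center`/`scale` attributes.
#' @return the original-scale matrix.
#' @export
denormalize_morphometrics <- function(z) {
  ctr <- attr(z, "scaled:center")
  scl <- attr(z, "scale")
  if (is.null(ctr) || is.null(scl)) stop("z must come from normalize_morphometrics()")
  sweep(sweep(unclass(z), 2, scl, `*`), 2, ctr, `+`)
}

#' Principal component analysis of standardized morphometrics
#'
#' Eigendecomposition of the correlation matrix (PCA of the standardized
#' landmark table). In juvenile crabs a single overall-size axis dominates;
#' following the convention that size loads negatively on PC1, each
#' component's sign is fixed so that the majority of its loadings are
#' negative (ties broken by forcing the first loading negative), which
#' makes results reproducible across runs and linear-algebra backends.
#'
#' @param z standardized matrix (see [normalize_morphometrics()]); a raw
#'   matrix is standardized first.
#' @return object of class `morpho_pca`: `eigenvalues`, `percent_variance`,
#'   `cumulative_percent`, `loadings` (columns = components, unit norm),
#'   `scores` (rows match input rows), `rank`.
#' @export
morpho_pca <- function(z) {
  if (is.null(attr(z, "scaled:center"))) z <- normalize_morphometrics(z)
  p <- ncol(z)
  n <- nrow(z)
  cm <- stats::cor(z)
  eig <- eigen(cm, symmetric = TRUE)
  vals <- pmax(eig$values, 0)
  vecs <- eig$vectors
  # deterministic sign convention: majority-negative loadings
  for (j in seq_len(p)) {
    s <- sum(sign(vecs[, j]))
    if (s > 0 || (s == 0 && vecs[1, j] > 0)) vecs[, j] <- -vecs[, j]
  }
  rank <- sum(vals > max(vals) * 1e-10)
  scores <- unclass(z) %*% vecs
  colnames(vecs) <- colnames(scores) <- paste0("PC", seq_len(p))
  rownames(vecs) <- colnames(z)
  structure(list(eigenvalues = vals,
                 percent_variance = 100 * vals / sum(vals),
                 cumulative_percent = cumsum(100 * vals / sum(vals)),
                 loadings = vecs, scores = scores, rank = rank, n = n),
            class = "morpho_pca")
}

#' @export
print.morpho_pca <- function(x, n_show = 3, ...) {
  cat("Morphometric PCA (", x$n, " rows, ", length(x$eigenvalues),
      " landmarks, rank ", x$rank, ")\n", sep = "")
  k <- min(n_show, length(x$eigenvalues))
  df <- data.frame(PC = seq_len(k),
                   Eigenvalue = round(x$eigenvalues[seq_len(k)], 2),
                   PercentVariation = round(x$percent_variance[seq_len(k)], 1),
                   CumPercent = round(x$cumulative_percent[seq_len(k)], 1))
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

#' Nested factorial ANOVA on principal component scores
#'
#' Fixed-effects least-squares model of a PC score with Treatment fully
#' crossed with Molt number and Crab nested within Treatment, followed by
#' Fisher LSD comparisons of treatments within each molt (the lettering of
#' per-molt treatment contrasts). Molt stages reached by too few crabs are
#' excluded before fitting (sparse final molts carry almost no information
#' and unbalance the design); any treatment x molt cell left empty after
#' filtering drops the interaction term with a warning.
#'
#' @param scores numeric vector of PC scores.
#' @param treatment,molt,crab parallel factors (crab ids unique across
#'   treatments).
#' @param min_fraction drop molt stages where fewer than this fraction of
#'   crabs in any treatment contributed a score (default 0.2).
#' @param alpha significance level for the LSD gate.
#' @return object of class `pc_anova`: `anova_table`, `terms` (F/p per
#'   term), `lsd_by_molt` (list of LSD tables, NULL where the treatment
#'   term is not testable), `included_molts`.
#' @export
pc_anova <- function(scores, treatment, molt, crab, min_fraction = 0.2,
                     alpha = 0.05) {
  d <- data.frame(score = scores, treatment = factor(treatment),
                  molt = factor(molt), crab = factor(crab))
  # molt inclusion: in each treatment, fraction of that treatment's crabs
  # observed at the molt stage
  n_crabs_tr <- tapply(d$crab, d$treatment, function(x) length(unique(x)))
  keep_molt <- vapply(levels(d$molt), function(m) {
    sub <- d[d$molt == m, ]
    frac <- vapply(levels(d$treatment), function(tr)
      length(unique(sub$crab[sub$treatment == tr])) / n_crabs_tr[[tr]], 0)
    all(frac >= min_fraction)
  }, TRUE)
  d <- droplevels(d[d$molt %in% levels(d$molt)[keep_molt], , drop = FALSE])
  if (!nrow(d)) stop("no molt stage passes the inclusion filter")
  cells <- table(d$treatment, d$molt)
  form <- score ~ treatment * molt + treatment:crab
  if (any(cells == 0L)) {
    warning("empty treatment x molt cell(s); interaction term dropped")
    form <- score ~ treatment + molt + treatment:crab
  }
  fit <- stats::lm(form, data = d)
  tab <- stats::anova(fit)
  rn <- rownames(tab)
  terms <- data.frame(
    term = setdiff(rn, "Residuals"),
    F = tab[setdiff(rn, "Residuals"), "F value"],
    df1 = tab[setdiff(rn, "Residuals"), "Df"],
    df2 = tab["Residuals", "Df"],
    p = tab[setdiff(rn, "Residuals"), "Pr(>F)"],
    stringsAsFactors = FALSE)
  lsd <- lapply(levels(d$molt), function(m) {
    sub <- d[d$molt == m, ]
    if (length(unique(sub$treatment)) < 2L) return(NULL)
    tryCatch(fisher_lsd(sub$score, sub$treatment, force = TRUE),
             error = function(e) NULL)
  })
  names(lsd) <- levels(d$molt)
  structure(list(anova_table = tab, terms = terms, lsd_by_molt = lsd,
                 included_molts = levels(d$molt)),
            class = "pc_anova")
}

#' @export
print.pc_anova <- function(x, ...) {
  cat("Nested ANOVA on PC scores (molts included: ",
      paste(x$included_molts, collapse = ", "), ")\n", sep = "")
  df <- x$terms
  df$F <- round(df$F, 3); df$p <- signif(df$p, 3)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}
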