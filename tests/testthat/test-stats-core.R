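test_that("aicc matches the closed form and guards its domain", {
  expect_equal(aicc(loglik = 0, K = 1, n = 100), 2 + 4 / 98)
  expect_equal(aicc(loglik = -1000, K = 3, n = 90), 2000 + 6 + 24 / 86)
  # on a real fitted log-likelihood the formula is applied unchanged
  recs <- fixture_records_10()
  fit <- fit_mortality(recs, hazard_structure("all_same"))
  expect_equal(aicc(fit$loglik, K = 1, n = 10),
               -2 * fit$loglik + 2 + 4 / 8)
  expect_error(aicc(0, K = 3, n = 4), "n > K \\+ 1")
  expect_error(aicc(0, K = 0, n = 10), "K")
})

test_that("aicc converges to plain AIC for large n", {
  expect_lt(abs(aicc(-50, 3, 1e9) - (100 + 6)), 1e-6)
})

test_that("rank_models reproduces the published survival-model ranking shape", {
  # printed AICc ladder: 2232.82 best, 2703.17, 3687.07
  rk <- rank_models(c("All Same", "All Different", "Control<Acidified"),
                    K = c(1, 3, 2),
                    aicc_values = c(3687.07, 2232.82, 2703.17))
  expect_equal(rk$model[1], "All Different")
  expect_equal(rk$delta_aicc, c(0, 470.35, 1454.25))
  expect_equal(rk$weight[1], 1, tolerance = 1e-12)
  expect_lt(rk$weight[2], 1e-50)
  expect_true(rk$tied[1] && !any(rk$tied[-1]))
})

test_that("rank_models weights and ties behave as defined", {
  rk <- rank_models(c("m1", "m2"), K = c(1, 2), aicc_values = c(10, 10))
  expect_equal(rk$weight, c(0.5, 0.5))
  expect_true(all(rk$tied))
  rk2 <- rank_models(c("m1", "m2"), K = c(1, 2), aicc_values = c(10, 12))
  expect_equal(rk2$rel_likelihood[2], exp(-1))
  expect_error(rank_models(character(0), integer(0), numeric(0)), "at least one")
})

test_that("Akaike weights sum to one and track delta order on random ladders", {
  withr::with_seed(11, {
    for (i in 1:20) {
      k <- sample(2:6, 1)
      rk <- rank_models(paste0("m", 1:k), K = sample(1:5, k, TRUE),
                        aicc_values = runif(k, 100, 120))
      expect_equal(sum(rk$weight), 1, tolerance = 1e-12)
      expect_equal(order(rk$weight, decreasing = TRUE), order(rk$delta_aicc))
      expect_equal(rk$rel_likelihood, exp(-rk$delta_aicc / 2))
      expect_equal(min(rk$delta_aicc), 0)
    }
  })
})

test_that("one-way ANOVA matches hand-computed sums of squares", {
  v <- c(1, 2, 3, 2, 3, 4, 6, 7, 8)
  g <- rep(c("g1", "g2", "g3"), each = 3)
  fit <- one_way_anova(v, g)
  # hand computation: group means 2,3,7, grand mean 4
  # SSB = 3*((2-4)^2+(3-4)^2+(7-4)^2) = 42, MSB = 21
  # SSW = 3 groups x sum((x-mean)^2) = 2+2+2 = 6, MSW = 1
  expect_equal(fit$F, 21)
  expect_equal(fit$df, c(2, 6))
  expect_equal(fit$p, stats::pf(21, 2, 6, lower.tail = FALSE))
  expect_equal(unname(fit$group_means), c(2, 3, 7))
})

test_that("ANOVA F is zero for identical group means and errors when degenerate", {
  expect_equal(one_way_anova(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))$F, 0)
  expect_error(one_way_anova(rep(5, 6), rep(c("a", "b"), each = 3)),
               "undefined")
})

test_that("ANOVA p agrees with a permutation null on a small fixture", {
  # hand-coded F from explicit sums of squares, used as the oracle
  f_hand <- function(v, g) {
    gm <- tapply(v, g, mean); ns <- table(g)
    ssb <- sum(ns * (gm - mean(v))^2)
    ssw <- sum((v - gm[g])^2)
    (ssb / (length(gm) - 1)) / (ssw / (length(v) - length(gm)))
  }
  # group sizes of 10 keep the F reference distribution accurate enough
  # for the permutation comparison at this tolerance
  withr::with_seed(301, {
    v <- rnorm(30)
    g <- rep(c("a", "b", "c"), each = 10)
    fit <- one_way_anova(v, g)
    expect_equal(fit$F, f_hand(v, g))
    f_obs <- fit$F
    p_perm <- mean(replicate(10000, f_hand(v, sample(g)) >= f_obs))
    expect_lt(abs(fit$p - p_perm), 0.01)
  })
})

test_that("ANOVA F is invariant to shifting and scaling the response", {
  withr::with_seed(5, {
    v <- rnorm(18); g <- rep(c("a", "b", "c"), each = 6)
    f0 <- one_way_anova(v, g)$F
    expect_equal(one_way_anova(v + 100, g)$F, f0)
    expect_equal(one_way_anova(v * 3.7, g)$F, f0)
  })
})

test_that("Levene is the ANOVA of absolute deviations and detects scale shifts", {
  withr::with_seed(6, {
    v <- rnorm(30); g <- rep(c("a", "b", "c"), each = 10)
    lev <- levene(v, g)
    ctr <- tapply(v, g, mean)
    ref <- one_way_anova(abs(v - ctr[g]), g)
    expect_equal(lev$W, ref$F)
    expect_equal(lev$p, ref$p)
    # cross-check against the independent implementation in car
    cl <- car::leveneTest(v ~ factor(g), center = mean)
    expect_equal(lev$W, cl[1, "F value"])
    expect_equal(lev$p, cl[1, "Pr(>F)"])
  })
  withr::with_seed(7, {
    v <- c(rnorm(20), rnorm(20) * 10, rnorm(20))
    g <- rep(c("a", "b", "c"), each = 20)
    expect_lt(levene(v, g)$p, 0.05)
  })
})

test_that("Kruskal-Wallis matches a hand-ranked computation and exact permutation", {
  # equal rank sums across groups -> H = 0
  v <- c(1, 6, 8, 2, 4, 9, 3, 5, 7)
  g <- rep(c("a", "b", "c"), each = 3)
  expect_equal(kruskal_wallis(v, g)$H, 0)
  # 3 groups x 5 untied values: hand formula H = 12/(N(N+1)) sum R_i^2/n_i - 3(N+1)
  v2 <- c(3, 7, 12, 1, 8, 2, 5, 9, 14, 11, 4, 6, 10, 13, 15)
  g2 <- rep(c("a", "b", "c"), each = 5)
  R <- tapply(rank(v2), g2, sum)
  h_hand <- 12 / (15 * 16) * sum(R^2 / 5) - 3 * 16
  expect_equal(kruskal_wallis(v2, g2)$H, h_hand)
  # exact permutation distribution on n = 9 (all 1680 group assignments)
  v3 <- c(1.2, 3.4, 0.5, 2.2, 5.1, 4.4, 2.9, 0.9, 3.8)
  g3 <- rep(c("a", "b", "c"), each = 3)
  h_obs <- kruskal_wallis(v3, g3)$H
  idx_a <- utils::combn(9, 3)
  p_exact <- mean(apply(idx_a, 2, function(ia) {
    rest <- setdiff(1:9, ia)
    idx_b <- utils::combn(rest, 3)
    mean(apply(idx_b, 2, function(ib) {
      gg <- character(9); gg[ia] <- "a"; gg[ib] <- "b"; gg[gg == ""] <- "c"
      kruskal_wallis(v3, gg)$H >= h_obs - 1e-12
    }))
  }))
  # at three observations per group the chi-square reference is only
  # accurate to a few percent; assert agreement at that level
  expect_lt(abs(kruskal_wallis(v3, g3)$p - p_exact), 0.05)
})

test_that("Kruskal-Wallis H is invariant under monotone transforms", {
  withr::with_seed(8, {
    v <- rlnorm(24); g <- rep(c("a", "b", "c"), each = 8)
    h0 <- kruskal_wallis(v, g)$H
    expect_equal(kruskal_wallis(log(v), g)$H, h0)
    expect_equal(kruskal_wallis(v^3, g)$H, h0)
    expect_equal(kruskal_wallis(rank(v), g)$H, h0)
  })
})

test_that("Fisher LSD matches the pooled-variance hand formula", {
  withr::with_seed(9, {
    v <- c(rnorm(8), rnorm(8) + 2, rnorm(8) + 4)
    g <- rep(c("a", "b", "c"), each = 8)
    fit <- one_way_anova(v, g)
    lsd <- fisher_lsd(v, g, fit)
    ms <- tapply(v, g, mean)
    t_ab <- (ms["a"] - ms["b"]) / sqrt(fit$ms_within * (1 / 8 + 1 / 8))
    expect_equal(lsd$t[lsd$group_a == "a" & lsd$group_b == "b"],
                 unname(t_ab))
    expect_equal(lsd$df, rep(fit$df[2], 3))
    # agrees with pairwise.t.test with a pooled SD and no adjustment
    ref <- stats::pairwise.t.test(v, g, p.adjust.method = "none",
                                  pool.sd = TRUE)
    expect_equal(lsd$p[1], ref$p.value["b", "a"])
    expect_equal(lsd$p[3], ref$p.value["c", "b"])
  })
})

test_that("Fisher LSD reduces to the pooled two-sample t-test with 2 groups", {
  withr::with_seed(10, {
    v <- c(rnorm(10), rnorm(10) + 1.5)
    g <- rep(c("a", "b"), each = 10)
    lsd <- fisher_lsd(v, g, force = TRUE)
    tt <- stats::t.test(v[g == "a"], v[g == "b"], var.equal = TRUE)
    expect_equal(lsd$p, tt$p.value)
    expect_equal(abs(lsd$t), abs(unname(tt$statistic)))
  })
  # identical groups: t = 0, p = 1
  v <- rep(c(1, 2, 3), 2); g <- rep(c("a", "b"), each = 3)
  lsd0 <- fisher_lsd(v, g, force = TRUE)
  expect_equal(lsd0$t, 0)
  expect_equal(lsd0$p, 1)
})

test_that("LSD gates on the omnibus F by default", {
  withr::with_seed(12, {
    v <- rnorm(30); g <- rep(c("a", "b", "c"), each = 10)
    fit <- one_way_anova(v, g)
    if (fit$p > 0.05) expect_error(fisher_lsd(v, g, fit), "not significant")
    expect_s3_class(fisher_lsd(v, g, fit, force = TRUE), "data.frame")
  })
})

test_that("ANOVA and KW hold their nominal type-I rate under a simulated null", {
  withr::with_seed(2024, {
    reps <- 2000
    rej <- matrix(FALSE, reps, 2)
    g <- rep(c("a", "b", "c"), each = 20)
    for (i in seq_len(reps)) {
      v <- rnorm(60)
      rej[i, 1] <- one_way_anova(v, g)$p < 0.05
      rej[i, 2] <- kruskal_wallis(v, g)$p < 0.05
    }
    expect_lt(abs(mean(rej[, 1]) - 0.05), 0.015)
    expect_lt(abs(mean(rej[, 2]) - 0.05), 0.015)
  })
})
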