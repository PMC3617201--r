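test_that("cumulative_degree_days sums daily means over (start, end]", {
  ser <- flat_series(192, 9.1)
  expect_equal(cumulative_degree_days(ser, 10, 10), 0)
  expect_equal(cumulative_degree_days(ser, 0, 192), 192 * 9.1)
  withr::with_seed(31, {
    ser2 <- data.frame(day = 1:60, temp_c = runif(60, 2, 14))
    # brute-force loop oracle
    acc <- 0
    for (d in 13:41) acc <- acc + ser2$temp_c[ser2$day == d]
    expect_equal(cumulative_degree_days(ser2, 12, 41), acc)
    # additive over adjacent intervals
    expect_equal(cumulative_degree_days(ser2, 0, 25) +
                   cumulative_degree_days(ser2, 25, 60),
                 cumulative_degree_days(ser2, 0, 60))
  })
  expect_error(cumulative_degree_days(ser, 5, 400), "outside")
  # base temperature clips negative contributions
  ser3 <- data.frame(day = 1:3, temp_c = c(5, -1, 4))
  expect_equal(cumulative_degree_days(ser3, 0, 3), 9)
  expect_equal(cumulative_degree_days(ser3, 0, 3, base = 2), 5)
})

test_that("fit_cl_linear recovers exact lines and flags the interaction", {
  obs <- fixture_growth_exact()
  # noise-free data: the perfect fit makes stats::anova warn, by design here
  fit <- suppressWarnings(fit_cl_linear(obs))
  expect_lt(fit$interaction$p, 1e-10)
  pt <- fit$per_treatment
  expect_equal(pt$slope[pt$treatment == "control"], 0.000737, tolerance = 1e-10)
  expect_equal(pt$slope[pt$treatment == "ph78"], 0.000506, tolerance = 1e-10)
  expect_equal(pt$intercept[pt$treatment == "control"], 2.34, tolerance = 1e-8)
})

test_that("fit_cl_linear enforces the three-observation filter", {
  obs <- fixture_growth_exact()
  short <- data.frame(crab_id = "stub", treatment = "control",
                      t = c(300, 700), molt_number = 1:2,
                      cl_mm = c(2.5, 2.8), wm_g = c(0.01, 0.02))
  fit <- suppressWarnings(fit_cl_linear(rbind(obs, short)))
  expect_true("stub" %in% fit$dropped)
  expect_equal(fit$n_crabs_used, length(unique(obs$crab_id)))
})

test_that("ANCOVA interaction F equals an explicit sequential sums-of-squares computation", {
  withr::with_seed(32, {
    obs <- fixture_growth_exact(n_crabs = 3)
    obs$cl_mm <- obs$cl_mm + rnorm(nrow(obs), 0, 0.05)
    fit <- fit_cl_linear(obs)
    # oracle: sequential projections via QR on explicitly built design blocks
    tr <- factor(obs$treatment); cr <- factor(obs$crab_id)
    blocks <- list(
      model.matrix(~tr),
      model.matrix(~tr + obs$t),
      model.matrix(~tr * obs$t),
      model.matrix(~tr * obs$t + tr:cr))
    rss <- vapply(blocks, function(X)
      sum(qr.resid(qr(X), obs$cl_mm)^2), 0)
    df_resid <- nrow(obs) - qr(blocks[[4]])$rank
    ss_int <- rss[2] - rss[3]
    f_hand <- (ss_int / 1) / (rss[4] / df_resid)
    expect_equal(fit$interaction$F, f_hand)
    expect_equal(fit$interaction$df, c(1, df_resid))
  })
})

test_that("fit_wm_exponential recovers noise-free parameters almost exactly", {
  obs <- fixture_growth_exact()
  ctl <- obs[obs$treatment == "control", ]
  fit <- fit_wm_exponential(ctl, "a,b")
  expect_equal(unname(fit$b), 0.000829, tolerance = 1e-8)
  expect_equal(unname(fit$a), rep(0.00667, 4), tolerance = 1e-8)
  # both-treatment data, treatment-specific b
  fit2 <- fit_wm_exponential(obs, "a,b(T)")
  expect_equal(unname(fit2$b["control"]), 0.000829, tolerance = 1e-8)
  expect_equal(unname(fit2$b["ph78"]), 0.000557, tolerance = 1e-8)
})

test_that("wet-mass loglik at the optimum beats a coarse parameter grid", {
  withr::with_seed(33, {
    ex <- simulate_cohort(cohort_config(seed = 33))
    obs <- ex$molts[ex$molts$treatment == "control" & is.finite(ex$molts$wm_g), ]
    nper <- table(obs$crab_id)                    # mirror the >= 2 obs filter
    obs <- obs[obs$crab_id %in% names(nper)[nper >= 2], ]
    fit <- fit_wm_exponential(obs, "a,b")
    # grid oracle: shared b and a common log-intercept scale around truth
    gauss_ll <- function(b) {
      x <- exp(b * obs$t_wm)
      a_i <- tapply(obs$wm_g * x, obs$crab_id, sum) /
        tapply(x * x, obs$crab_id, sum)
      res <- obs$wm_g - a_i[as.character(obs$crab_id)] * x
      n <- nrow(obs); s2 <- sum(res^2) / n
      -n / 2 * log(2 * pi * s2) - n / 2
    }
    for (b in seq(0.0004, 0.0012, by = 0.00005)) {
      expect_gte(fit$loglik + 1e-8, gauss_ll(b))
    }
  })
})

test_that("wet-mass model ladder obeys nesting and its K bookkeeping", {
  withr::with_seed(34, {
    ex <- simulate_cohort(cohort_config(seed = 34))
    obs <- ex$molts[ex$molts$treatment != "ph75" & is.finite(ex$molts$wm_g), ]
    rk <- rank_wm_models(obs)
    f <- rk$fits
    n_crabs <- f[["a,b"]]$n_crabs
    expect_equal(f[["a,b"]]$K, n_crabs + 1L + 1L)
    expect_equal(f[["a,b(T)"]]$K, n_crabs + 2L + 1L)
    # the a(T) variants are reparameterizations: same likelihood and K
    expect_equal(f[["a(T),b"]]$loglik, f[["a,b"]]$loglik)
    expect_equal(f[["a(T),b(T)"]]$loglik, f[["a,b(T)"]]$loglik)
    # nesting: freeing b by treatment can only raise the likelihood
    expect_gte(f[["a,b(T)"]]$loglik + 1e-8, f[["a,b"]]$loglik)
  })
})

test_that("treatment-varying b data select a b(T) variant; recovery within 10%", {
  withr::with_seed(35, {
    wins <- 0; b_ctl <- b_ph <- numeric(20)
    for (i in 1:20) {
      ex <- simulate_cohort(cohort_config(seed = 1000 + i))
      obs <- ex$molts[ex$molts$treatment != "ph75" & is.finite(ex$molts$wm_g), ]
      rk <- rank_wm_models(obs)
      if (rk$ranking$model[1] %in% c("a,b(T)", "a(T),b(T)")) wins <- wins + 1
      fit <- rk$fits[["a,b(T)"]]
      b_ctl[i] <- fit$b["control"]; b_ph[i] <- fit$b["ph78"]
    }
    expect_gte(wins, 16)
    expect_lt(abs(mean(b_ctl) / 0.000829 - 1), 0.10)
    expect_lt(abs(mean(b_ph) / 0.000557 - 1), 0.10)
  })
})

test_that("predict_percent_difference covers the linear and exponential worked forms", {
  p0 <- list(a = 0.00667, b = 0.000829)
  expect_equal(predict_percent_difference(p0, p0, 1747, "exponential"), 0)
  # shared-a exponential contrast is independent of a
  pA <- list(a = 0.00667, b = 0.000829); pB <- list(a = 0.00667, b = 0.000557)
  d1 <- predict_percent_difference(pA, pB, 1747, "exponential")
  pA$a <- pB$a <- 42
  expect_equal(predict_percent_difference(pA, pB, 1747, "exponential"), d1)
  expect_equal(d1, 100 * (exp((0.000829 - 0.000557) * 1747) - 1))
  # linear contrast at the same horizon
  lc <- predict_percent_difference(list(slope = 0.000737, intercept = 2.34),
                                   list(slope = 0.000506, intercept = 2.38),
                                   1747.2, "linear")
  expect_equal(lc, 100 * ((0.000737 * 1747.2 + 2.34) /
                            (0.000506 * 1747.2 + 2.38) - 1))
  expect_error(predict_percent_difference(list(slope = 1, intercept = 0),
                                          list(slope = -1, intercept = 0),
                                          10, "linear"), "positive")
})

test_that("intermolt periods recover the generating degree-day distribution", {
  ex <- simulate_cohort(cohort_config(
    seed = 36, hazards = c(control = 0, ph78 = 0, ph75 = 0)))
  im <- intermolt_periods(ex$molts, ex$temperature)
  expect_lt(abs(mean(im$dd) / 450 - 1), 0.05)
  expect_true(all(im$dd > 0))
  # consecutive molt numbering within each crab
  ok <- tapply(im$to_molt, im$crab_id, function(m) all(diff(sort(m)) == 1))
  expect_true(all(ok))
})
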