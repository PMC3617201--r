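# Small fixtures shared across test files. All randomness is seeded locally.

# ten crabs, mixed deaths and censorings, two treatments
fixture_records_10 <- function() {
  data.frame(
    crab_id = sprintf("c%02d", 1:10),
    treatment = rep(c("control", "ph78"), each = 5),
    entry_day = 0L,
    last_day = c(12L, 45L, 100L, 100L, 73L, 5L, 19L, 100L, 66L, 100L),
    status = c("died", "died", "censored", "censored", "died",
               "died", "died", "censored", "died", "censored"),
    stringsAsFactors = FALSE)
}

# twenty crabs, single treatment, for grid-search comparisons
fixture_records_20 <- function(seed = 42, r = 0.01, dur = 150) {
  withr::with_seed(seed, {
    td <- ceiling(stats::rexp(20, r))
    died <- td <= dur
    data.frame(crab_id = sprintf("g%02d", 1:20), treatment = "control",
               entry_day = 0L, last_day = as.integer(ifelse(died, td, dur)),
               status = ifelse(died, "died", "censored"),
               stringsAsFactors = FALSE)
  })
}

# exhaustive grid-search oracle for a single shared hazard
grid_search_rate <- function(records, grid = seq(1e-5, 0.2, by = 1e-5)) {
  st <- hazard_structure("all_same")
  nll <- vapply(grid, function(r) neg_loglik_mortality(records, st, r), 0)
  grid[which.min(nll)]
}

# molt observations on exact lines/exponentials, two treatments
fixture_growth_exact <- function(n_crabs = 4, times = c(300, 700, 1100, 1500),
                                 slopes = c(control = 0.000737, ph78 = 0.000506),
                                 intercepts = c(control = 2.34, ph78 = 2.38),
                                 a = 0.00667,
                                 b = c(control = 0.000829, ph78 = 0.000557)) {
  do.call(rbind, lapply(names(slopes), function(tr) {
    do.call(rbind, lapply(seq_len(n_crabs), function(i) {
      data.frame(crab_id = paste0(tr, "_", i), treatment = tr, t = times,
                 molt_number = seq_along(times),
                 cl_mm = intercepts[[tr]] + slopes[[tr]] * times,
                 wm_g = a * exp(b[[tr]] * times), stringsAsFactors = FALSE)
    }))
  }))
}

flat_series <- function(n = 192, temp = 9.1) data.frame(day = 1:n, temp_c = temp)
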