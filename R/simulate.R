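#' Configuration for a synthetic crab cohort experiment
#'
#' Bundles every generating parameter of the simulator with the defaults
#' set to the study conditions the fitting modules are designed for. Two
#' species presets are provided: `red_king_crab` (192-day experiment,
#' intermolt 450 +/- 119 degree-days, 5 carapace landmarks, per-treatment
#' daily hazards 0.0023/0.0047/0.025) and `tanner` (199 days, intermolt
#' 873 +/- 198 degree-days, 8 landmarks, hazards 0.0010/0.0023/0.0050,
#' at most 3 molts).
#'
#' @param species "red_king_crab" or "tanner".
#' @param hazards named daily mortality hazards (day^-1) for control, ph78,
#'   ph75.
#' @param n_per_treatment crabs per treatment (default 30).
#' @param duration_days experiment length in days.
#' @param intermolt_mean,intermolt_sd intermolt period distribution
#'   (degree-days); draws are truncated below at `intermolt_min`.
#' @param intermolt_min truncation floor (degree-days, default 150).
#' @param max_molts cap on molts per crab (Inf for red king crab, 3 for
#'   Tanner).
#' @param cl_slope,cl_intercept per-treatment linear carapace-growth
#'   parameters (mm per degree-day; mm).
#' @param cl_sd measurement noise on carapace length (mm).
#' @param wm_a,wm_b per-treatment exponential wet-mass parameters
#'   (g; per degree-day); per-crab intercepts scatter lognormally around
#'   `wm_a` with sd `wm_a_cv` on the log scale.
#' @param wm_sd_frac wet-mass noise sd as a fraction of predicted mass.
#' @param n_landmarks number of morphometric landmarks.
#' @param morpho_noise_share share of landmark variance not explained by
#'   the single size axis (default 0.05).
#' @param ci_baseline condition-index baseline (g mm^-3) and
#'   `ci_multiplier` per-treatment multipliers (default control 25% above
#'   ph78); `ci_cv` lognormal noise.
#' @param ca_baseline percent-calcium baseline and `ca_multiplier`
#'   per-treatment multipliers (default control 10% above acidified);
#'   `ca_sd` additive noise. `mg_baseline`, `mg_sd` likewise for percent
#'   magnesium.
#' @param temp_anchors start/peak/end daily mean temperatures (degrees C)
#'   for the seasonal forcing; `temp_peak_day` day of the peak;
#'   `temp_jitter_sd` day-to-day jitter.
#' @param seed integer random seed; a fixed seed makes the generated
#'   experiment byte-identical across runs.
#' @return object of class `cohort_config` (a named list).
#' @export
cohort_config <- function(species = c("red_king_crab", "tanner"),
                          hazards = NULL,
                          n_per_treatment = 30,
                          duration_days = NULL,
                          intermolt_mean = NULL, intermolt_sd = NULL,
                          intermolt_min = 150,
                          max_molts = NULL,
                          cl_slope = c(control = 0.000737, ph78 = 0.000506,
                                       ph75 = 0.000400),
                          cl_intercept = c(control = 2.34, ph78 = 2.38,
                                           ph75 = 2.36),
                          cl_sd = 0.1,
                          wm_a = c(control = 0.00667, ph78 = 0.00667,
                                   ph75 = 0.00667),
                          wm_b = c(control = 0.000829, ph78 = 0.000557,
                                   ph75 = 0.000400),
                          wm_a_cv = 0.1, wm_sd_frac = 0.05,
                          n_landmarks = NULL, morpho_noise_share = 0.05,
                          ci_baseline = 4e-4,
                          ci_multiplier = c(control = 1.25, ph78 = 1.00,
                                            ph75 = 1.00),
                          ci_cv = 0.10,
                          ca_baseline = 20,
                          ca_multiplier = c(control = 1.10, ph78 = 1.00,
                                            ph75 = 0.99),
                          ca_sd = 1.5,
                          mg_baseline = 0.83, mg_sd = 0.03,
                          temp_anchors = c(start = 9.3, peak = 11.9, end = 4.4),
                          temp_peak_day = 100, temp_jitter_sd = 0,
                          seed = 1L) {
  species <- match.arg(species)
  preset <- if (species == "red_king_crab") {
    list(hazards = c(control = 0.0023, ph78 = 0.0047, ph75 = 0.025),
         duration_days = 192, intermolt_mean = 450, intermolt_sd = 119,
         max_molts = Inf, n_landmarks = 5)
  } else {
    list(hazards = c(control = 0.0010, ph78 = 0.0023, ph75 = 0.0050),
         duration_days = 199, intermolt_mean = 873, intermolt_sd = 198,
         max_molts = 3, n_landmarks = 8)
  }
  cfg <- list(
    species = species,
    hazards = if (is.null(hazards)) preset$hazards else hazards,
    n_per_treatment = n_per_treatment,
    duration_days = if (is.null(duration_days)) preset$duration_days else duration_days,
    intermolt_mean = if (is.null(intermolt_mean)) preset$intermolt_mean else intermolt_mean,
    intermolt_sd = if (is.null(intermolt_sd)) preset$intermolt_sd else intermolt_sd,
    intermolt_min = intermolt_min,
    max_molts = if (is.null(max_molts)) preset$max_molts else max_molts,
    cl_slope = cl_slope, cl_intercept = cl_intercept, cl_sd = cl_sd,
    wm_a = wm_a, wm_b = wm_b, wm_a_cv = wm_a_cv, wm_sd_frac = wm_sd_frac,
    n_landmarks = if (is.null(n_landmarks)) preset$n_landmarks else n_landmarks,
    morpho_noise_share = morpho_noise_share,
    ci_baseline = ci_baseline, ci_multiplier = ci_multiplier, ci_cv = ci_cv,
    ca_baseline = ca_baseline, ca_multiplier = ca_multiplier, ca_sd = ca_sd,
    mg_baseline = mg_baseline, mg_sd = mg_sd,
    temp_anchors = temp_anchors, temp_peak_day = temp_peak_day,
    temp_jitter_sd = temp_jitter_sd, seed = as.integer(seed))
  if (any(cfg$hazards < 0)) stop("hazards must be >= 0")
  if (cfg$intermolt_mean <= 0) stop("intermolt mean must be positive")
  if (cfg$intermolt_sd >= cfg$intermolt_mean) {
    warning("intermolt sd >= mean: heavy truncation at the floor; the ",
            "achieved intermolt distribution will deviate from the target")
  }
  class(cfg) <- "cohort_config"
  cfg
}

#' Read a cohort configuration from a YAML file
#'
#' The YAML file holds any subset of [cohort_config()]'s arguments by name
#' (named vectors as mappings, e.g. `hazards: {control: 0.0023, ph78:
#' 0.0047, ph75: 0.025}`); unspecified fields fall back to the species
#' preset defaults.
#'
#' @param path path to a YAML file.
#' @return a `cohort_config`.
#' @export
cohort_config_from_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(cohort_config))
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  raw <- lapply(raw, function(x) if (is.list(x)) unlist(x) else x)
  do.call(cohort_config, raw)
}

#' Seasonal daily temperature series
#'
#' Piecewise-cosine daily mean temperatures through three anchors: the
#' start-of-experiment temperature, a late-summer peak and the
#' end-of-experiment minimum (defaults 9.3, 11.9 and 4.4 degrees C with
#' the peak near day 100), plus optional seeded day-to-day jitter. With
#' the default anchors the 192-day mean is about 9.4 degrees C.
#'
#' @param duration_days number of days (>= 1).
#' @param anchors named vector c(start=, peak=, end=).
#' @param peak_day day of the peak (1 < peak_day < duration).
#' @param jitter_sd sd of additive daily jitter (degrees C).
#' @param seed optional seed for the jitter (ignored when jitter_sd = 0).
#' @return data frame with columns day (1..duration) and temp_c.
#' @export
generate_temperature <- function(duration_days,
                                 anchors = c(start = 9.3, peak = 11.9, end = 4.4),
                                 peak_day = 100, jitter_sd = 0, seed = NULL) {
  if (duration_days < 1) stop("duration must be >= 1")
  if (!all(c("start", "peak", "end") %in% names(anchors))) {
    stop("anchors must be named start, peak, end")
  }
  peak_day <- min(max(peak_day, 1), duration_days)
  day <- seq_len(duration_days)
  up <- day <= peak_day
  half_cos <- function(d, d0, d1, v0, v1) {
    if (d1 == d0) return(rep(v1, length(d)))
    frac <- (d - d0) / (d1 - d0)
    v0 + (v1 - v0) * (1 - cos(pi * frac)) / 2
  }
  temp <- numeric(duration_days)
  temp[up] <- half_cos(day[up], 1, peak_day, anchors[["start"]], anchors[["peak"]])
  temp[!up] <- half_cos(day[!up], peak_day, duration_days,
                        anchors[["peak"]], anchors[["end"]])
  if (jitter_sd > 0) {
    if (!is.null(seed)) {
      temp <- withr::with_seed(seed, temp + stats::rnorm(duration_days, 0, jitter_sd))
    } else {
      temp <- temp + stats::rnorm(duration_days, 0, jitter_sd)
    }
  }
  data.frame(day = day, temp_c = temp)
}

rtruncnorm1 <- function(n, mean, sd, lower) {
  # inverse-CDF draw from a normal truncated below at `lower`
  plo <- stats::pnorm(lower, mean, sd)
  stats::qnorm(plo + stats::runif(n) * (1 - plo), mean, sd)
}

#' Simulate a complete synthetic cohort experiment
#'
#' Generates, under one seed, the four tables every fitting module
#' consumes, with the statistical structure those modules assume: death
#' days drawn from the per-treatment exponential hazards and discretized
#' to the daily census (a crab dying during day t is found dead at check
#' t); molts placed where cumulative degree-days cross successive
#' truncated-normal intermolt draws; carapace length linear in degree-days
#' with Gaussian measurement noise; wet mass recorded 7 days after each
#' molt from a_crab exp(b t) with proportional Gaussian noise; landmark
#' vectors equal to a size scalar times a fixed loading vector plus
#' isotropic noise; terminal condition index and percent calcium/magnesium
#' from treatment-multiplied baselines, assayed only for crabs alive at
#' the end. Death and molting are independent. Molts are only recorded
#' while the crab is alive.
#'
#' @param config a [cohort_config()].
#' @return object of class `synthetic_experiment`: list with `temperature`,
#'   `census` (crab_id, treatment, day, status), `molts` (crab_id,
#'   treatment, day, molt_number, t (degree-days at the molt), t_wm
#'   (degree-days at the wet-mass measurement 7 days later), cl_mm, cw_mm,
#'   wm_g, landmark columns), `assay` (crab_id, treatment, dry_mass_g, length_mm,
#'   pct_ca, pct_mg), `ground_truth` (the generating parameters), `config`.
#' @export
simulate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  withr::with_seed(config$seed, simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(cfg) {
  treatments <- names(cfg$hazards)
  dur <- cfg$duration_days
  temp <- generate_temperature(dur, cfg$temp_anchors, cfg$temp_peak_day,
                               cfg$temp_jitter_sd)
  cumdd <- cumsum(pmax(temp$temp_c, 0))
  # fixed unit loading vector for the size axis (deterministic, not drawn)
  p <- cfg$n_landmarks
  loading <- rep(1 / sqrt(p), p)
  landmark_scale <- seq(1.5, 0.5, length.out = p)  # relative landmark sizes

  census <- list(); molts <- list(); assay <- list()
  n <- cfg$n_per_treatment
  for (tr in treatments) {
    if (n == 0) next
    r <- cfg$hazards[[tr]]
    ids <- sprintf("%s_%02d", tr, seq_len(n))
    # death day: continuous exponential, found dead at the ceiling day
    tdeath <- if (r > 0) stats::rexp(n, r) else rep(Inf, n)
    death_day <- ceiling(tdeath)
    died <- death_day <= dur
    last_day <- ifelse(died, death_day, dur)
    census[[tr]] <- data.frame(
      crab_id = ids, treatment = tr, day = last_day,
      status = ifelse(died, "dead", "censored"), stringsAsFactors = FALSE)

    a_crab <- cfg$wm_a[[tr]] * exp(stats::rnorm(n, 0, cfg$wm_a_cv))
    for (i in seq_len(n)) {
      # molt days: cumulative degree-days crossing successive intermolt draws
      molt_days <- integer(0)
      target <- 0
      m <- 0L
      repeat {
        if (m >= cfg$max_molts) break
        target <- target + rtruncnorm1(1, cfg$intermolt_mean,
                                       cfg$intermolt_sd, cfg$intermolt_min)
        d <- which(cumdd >= target)[1]
        if (is.na(d) || d >= last_day[i]) break
        molt_days <- c(molt_days, d)
        m <- m + 1L
      }
      if (!length(molt_days)) next
      mn <- seq_along(molt_days)
      t_molt <- cumdd[molt_days]
      cl <- cfg$cl_intercept[[tr]] + cfg$cl_slope[[tr]] * t_molt +
        stats::rnorm(m, 0, cfg$cl_sd)
      cl <- pmax(cl, 0.5)
      cw <- cl * 1.05 + stats::rnorm(m, 0, cfg$cl_sd / 2)
      # wet mass measured 7 days after the molt (at that day's degree-days)
      wm_day <- pmin(molt_days + 7L, dur)
      measured <- wm_day <= last_day[i]
      t_wm <- cumdd[wm_day]
      mu_wm <- a_crab[i] * exp(cfg$wm_b[[tr]] * t_wm)
      wm <- mu_wm + stats::rnorm(m, 0, cfg$wm_sd_frac * mu_wm)
      wm <- pmax(wm, 1e-4)
      wm[!measured] <- NA_real_
      # landmarks: size scalar (tracks CL) x loading + isotropic noise
      size <- cl
      sig_noise <- sqrt(cfg$morpho_noise_share / (1 - cfg$morpho_noise_share)) *
        stats::sd(c(cfg$cl_intercept[[tr]], cl)) # scale noise to size spread
      lm_mat <- outer(size, loading * sqrt(p) * landmark_scale) +
        matrix(stats::rnorm(m * p, 0, max(sig_noise, cfg$cl_sd)), m, p)
      colnames(lm_mat) <- paste0("landmark_", seq_len(p))
      t_wm[!measured] <- NA_real_
      molts[[paste(tr, i)]] <- cbind(
        data.frame(crab_id = ids[i], treatment = tr, day = molt_days,
                   molt_number = mn, t = t_molt, t_wm = t_wm, cl_mm = cl,
                   cw_mm = cw, wm_g = wm, stringsAsFactors = FALSE),
        as.data.frame(lm_mat))
    }
    # terminal assays for survivors only
    alive <- which(!died)
    if (length(alive)) {
      final_cl <- cfg$cl_intercept[[tr]] + cfg$cl_slope[[tr]] * cumdd[dur] +
        stats::rnorm(length(alive), 0, cfg$cl_sd)
      final_cl <- pmax(final_cl, 0.5)
      ci <- cfg$ci_baseline * cfg$ci_multiplier[[tr]] *
        exp(stats::rnorm(length(alive), 0, cfg$ci_cv))
      assay[[tr]] <- data.frame(
        crab_id = ids[alive], treatment = tr,
        dry_mass_g = ci * final_cl^3,
        length_mm = final_cl,
        pct_ca = pmin(pmax(cfg$ca_baseline * cfg$ca_multiplier[[tr]] +
                             stats::rnorm(length(alive), 0, cfg$ca_sd), 0), 100),
        pct_mg = pmin(pmax(cfg$mg_baseline +
                             stats::rnorm(length(alive), 0, cfg$mg_sd), 0), 100),
        stringsAsFactors = FALSE)
    }
  }
  empty_census <- data.frame(crab_id = character(0), treatment = character(0),
                             day = integer(0), status = character(0))
  empty_assay <- data.frame(crab_id = character(0), treatment = character(0),
                            dry_mass_g = numeric(0), length_mm = numeric(0),
                            pct_ca = numeric(0), pct_mg = numeric(0))
  molt_tab <- if (length(molts)) do.call(rbind, molts) else
    cbind(data.frame(crab_id = character(0), treatment = character(0),
                     day = integer(0), molt_number = integer(0), t = numeric(0),
                     t_wm = numeric(0), cl_mm = numeric(0), cw_mm = numeric(0),
                     wm_g = numeric(0)),
          as.data.frame(matrix(numeric(0), 0, cfg$n_landmarks,
                               dimnames = list(NULL, paste0("landmark_",
                                                            seq_len(cfg$n_landmarks))))))
  rownames(molt_tab) <- NULL
  out <- list(
    temperature = temp,
    census = if (length(census)) do.call(rbind, census) else empty_census,
    molts = molt_tab,
    assay = if (length(assay)) do.call(rbind, assay) else empty_assay,
    ground_truth = cfg[c("species", "hazards", "intermolt_mean",
                         "intermolt_sd", "cl_slope", "cl_intercept", "wm_a",
                         "wm_b", "ci_multiplier", "ca_multiplier", "seed")],
    config = cfg)
  rownames(out$census) <- rownames(out$assay) <- NULL
  class(out) <- "synthetic_experiment"
  out
}

#' @export
print.synthetic_experiment <- function(x, ...) {
  cat("Synthetic cohort experiment (", x$config$species, ", seed ",
      x$config$seed, ")\n", sep = "")
  cat("  ", nrow(x$census), " crabs over ", x$config$duration_days,
      " days; ", sum(x$census$status == "dead"), " deaths; ",
      nrow(x$molts), " molt observations; ", nrow(x$assay),
      " terminal assays\n", sep = "")
  invisible(x)
}
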