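#' Equilibrium constants of the seawater CO2 system
#'
#' Standard constant formulations at surface pressure: Weiss (1974) CO2
#' solubility K0; Lueker et al. (2000) carbonic acid K1/K2 (total pH
#' scale); Dickson (1990) boric acid KB (total scale) and bisulfate KS
#' (free scale); Millero (1995) water KW (total scale); Mucci (1983)
#' calcite and aragonite stoichiometric solubility products. Total sulfate
#' and borate are scaled with salinity; the free-to-total hydrogen-ion
#' scale factor 1 + ST/KS is returned alongside.
#'
#' @param temp_c temperature (degrees C).
#' @param salinity practical salinity (0 < S < 45; a warning flags
#'   extrapolation outside roughly 19-43, 2-35 degrees C, the fitted range
#'   of the K1/K2 formulation).
#' @param sulfate_total total sulfate (mol/kg); defaults to the
#'   salinity-scaled seawater value. Setting it to 0 makes the free and
#'   total hydrogen-ion scales coincide (free_to_total = 1).
#' @return named list: K0 (mol kg^-1 atm^-1), K1, K2, KB, KW (total
#'   scale, mol kg^-1), KS (free scale), Ksp_calcite, Ksp_aragonite
#'   (mol^2 kg^-2), ST, BT, Ca (mol kg^-1), free_to_total.
#' @export
equilibrium_constants <- function(temp_c, salinity, sulfate_total = NULL) {
  if (salinity <= 0 || salinity >= 45) stop("salinity out of range (0, 45)")
  if (temp_c < 2 || temp_c > 35 || salinity < 19 || salinity > 43) {
    warning("T/S outside the fitted range of the constant formulations; ",
            "values are extrapolated")
  }
  TK <- temp_c + 273.15
  S <- salinity
  lnTK <- log(TK)

  lnK0 <- -60.2409 + 93.4517 * (100 / TK) + 23.3585 * log(TK / 100) +
    S * (0.023517 - 0.023656 * (TK / 100) + 0.0047036 * (TK / 100)^2)
  K0 <- exp(lnK0)

  pK1 <- 3633.86 / TK - 61.2172 + 9.6777 * lnTK - 0.011555 * S + 0.0001152 * S^2
  pK2 <- 471.78 / TK + 25.9290 - 3.16967 * lnTK - 0.01781 * S + 0.0001122 * S^2
  K1 <- 10^(-pK1)
  K2 <- 10^(-pK2)

  lnKB <- (-8966.90 - 2890.53 * sqrt(S) - 77.942 * S + 1.728 * S^1.5 -
             0.0996 * S^2) / TK +
    148.0248 + 137.1942 * sqrt(S) + 1.62142 * S +
    (-24.4344 - 25.085 * sqrt(S) - 0.2474 * S) * lnTK +
    0.053105 * sqrt(S) * TK
  KB <- exp(lnKB)

  lnKW <- 148.9802 - 13847.26 / TK - 23.6521 * lnTK +
    (118.67 / TK - 5.977 + 1.0495 * lnTK) * sqrt(S) - 0.01615 * S
  KW <- exp(lnKW)

  IS <- 19.924 * S / (1000 - 1.005 * S)  # ionic strength, mol/kg-H2O
  lnKS <- -4276.1 / TK + 141.328 - 23.093 * lnTK +
    (-13856 / TK + 324.57 - 47.986 * lnTK) * sqrt(IS) +
    (35474 / TK - 771.54 + 114.723 * lnTK) * IS -
    2698 / TK * IS^1.5 + 1776 / TK * IS^2 +
    log(1 - 0.001005 * S)
  KS <- exp(lnKS)

  log10TK <- log10(TK)
  log10Kspc <- -171.9065 - 0.077993 * TK + 2839.319 / TK + 71.595 * log10TK +
    (-0.77712 + 0.0028426 * TK + 178.34 / TK) * sqrt(S) -
    0.07711 * S + 0.0041249 * S^1.5
  log10Kspa <- -171.945 - 0.077993 * TK + 2903.293 / TK + 71.595 * log10TK +
    (-0.068393 + 0.0017276 * TK + 88.135 / TK) * sqrt(S) -
    0.10018 * S + 0.0059415 * S^1.5

  ST <- if (is.null(sulfate_total)) 0.02824 * S / 35 else sulfate_total
  # total sulfate default: Morris & Riley salinity scaling
  BT <- 0.000416 * S / 35      # total borate (Uppstrom)
  Ca <- 0.010285 * S / 35      # calcium (Riley & Tongudai)

  list(K0 = K0, K1 = K1, K2 = K2, KB = KB, KW = KW, KS = KS,
       Ksp_calcite = 10^log10Kspc, Ksp_aragonite = 10^log10Kspa,
       ST = ST, BT = BT, Ca = Ca,
       free_to_total = 1 + ST / KS)
}

#' Closed-form carbonate speciation from pH and DIC
#'
#' With pH (free scale) and DIC both measured, the CO2 system is solved in
#' closed form: the carbonate fractions follow from K1, K2 and the
#' hydrogen-ion concentration converted to the total scale; pCO2 =
#' [CO2*]/K0; total alkalinity is assembled as [HCO3-] + 2[CO3--] + borate
#' + [OH-] - [H+]_free (nutrient terms omitted, unmeasured); saturation
#' states are OmegaX = [Ca++][CO3--]/Ksp_X with [Ca++] = 0.010285 S/35.
#'
#' @param pH_free pH on the free hydrogen-ion scale (6 < pH < 9).
#' @param dic dissolved inorganic carbon (mol/kg-solution).
#' @param temp_c temperature (degrees C).
#' @param salinity practical salinity (default 32, typical of coastal Gulf
#'   of Alaska surface water; the experiment did not report salinity so it
#'   must be chosen by the analyst).
#' @return object of class `carbonate_state` (a one-row data frame):
#'   pH_free, dic, temp_c, salinity, pco2_uatm, co2_mol_kg, hco3_mol_kg,
#'   co3_mol_kg, ta_mol_kg, omega_aragonite, omega_calcite.
#' @export
solve_speciation <- function(pH_free, dic, temp_c, salinity = 32) {
  if (any(pH_free <= 6 | pH_free >= 9)) stop("pH_free out of range (6, 9)")
  if (any(dic <= 0)) stop("DIC must be positive")
  k <- equilibrium_constants(temp_c, salinity)
  hF <- 10^(-pH_free)
  hT <- hF * k$free_to_total
  denom <- hT^2 + k$K1 * hT + k$K1 * k$K2
  co2 <- dic * hT^2 / denom
  hco3 <- dic * k$K1 * hT / denom
  co3 <- dic * k$K1 * k$K2 / denom
  pco2 <- co2 / k$K0 * 1e6
  borate <- k$BT * k$KB / (k$KB + hT)
  oh <- k$KW / hT
  ta <- hco3 + 2 * co3 + borate + oh - hF
  out <- data.frame(pH_free = pH_free, dic = dic, temp_c = temp_c,
                    salinity = salinity,
                    pco2_uatm = pco2, co2_mol_kg = co2, hco3_mol_kg = hco3,
                    co3_mol_kg = co3, ta_mol_kg = ta,
                    omega_aragonite = k$Ca * co3 / k$Ksp_aragonite,
                    omega_calcite = k$Ca * co3 / k$Ksp_calcite)
  class(out) <- c("carbonate_state", "data.frame")
  out
}

#' @export
print.carbonate_state <- function(x, ...) {
  cat(sprintf(
    "Carbonate state (pH_F %.2f, DIC %.3g mmol/kg, %.1f degC, S %.1f):\n",
    x$pH_free, x$dic * 1e3, x$temp_c, x$salinity))
  cat(sprintf("  pCO2 %.1f uatm; HCO3- %.2f, CO3-- %.3f mmol/kg; TA %.2f mmol/kg\n",
              x$pco2_uatm, x$hco3_mol_kg * 1e3, x$co3_mol_kg * 1e3,
              x$ta_mol_kg * 1e3))
  cat(sprintf("  Omega_aragonite %.2f (%s); Omega_calcite %.2f (%s)\n",
              x$omega_aragonite, classify_saturation(x$omega_aragonite),
              x$omega_calcite, classify_saturation(x$omega_calcite)))
  invisible(x)
}

#' Classify a saturation state relative to Omega = 1
#'
#' Band classification around saturation: Omega > 1 + band is
#' supersaturated, Omega < 1 - band undersaturated, otherwise
#' near-saturation ("right at saturation").
#'
#' @param omega saturation state (>= 0).
#' @param band half-width of the near-saturation band (default 0.15).
#' @return character vector in {"supersaturated", "near-saturation",
#'   "undersaturated"}.
#' @export
classify_saturation <- function(omega, band = 0.15) {
  if (any(omega < 0)) stop("omega must be non-negative")
  ifelse(omega > 1 + band, "supersaturated",
         ifelse(omega < 1 - band, "undersaturated", "near-saturation"))
}

#' Carbonate system summary of a water-sample table
#'
#' Applies [solve_speciation()] to each row of a water-chemistry sample
#' table and summarizes each treatment as mean and standard error of every
#' derived quantity.
#'
#' @param samples data frame with columns treatment, pH_free, dic_mmol_kg,
#'   temp_c and optionally salinity.
#' @param salinity default salinity used where the table has none.
#' @return list with `per_sample` (row-wise `carbonate_state`s) and
#'   `summary` (treatment x quantity means and SEs).
#' @export
carbonate_summary <- function(samples, salinity = 32) {
  stopifnot(all(c("treatment", "pH_free", "dic_mmol_kg", "temp_c") %in%
                  names(samples)))
  sal <- if ("salinity" %in% names(samples)) samples$salinity else
    rep(salinity, nrow(samples))
  per <- do.call(rbind, lapply(seq_len(nrow(samples)), function(i)
    solve_speciation(samples$pH_free[i], samples$dic_mmol_kg[i] / 1e3,
                     samples$temp_c[i], sal[i])))
  per$treatment <- samples$treatment
  qty <- c("pco2_uatm", "hco3_mol_kg", "co3_mol_kg", "ta_mol_kg",
           "omega_aragonite", "omega_calcite")
  summ <- do.call(rbind, lapply(split(per, per$treatment), function(d) {
    stats <- lapply(qty, function(q) {
      c(mean = mean(d[[q]]), se = stats::sd(d[[q]]) / sqrt(nrow(d)))
    })
    row <- as.data.frame(t(unlist(stats)))
    names(row) <- as.vector(outer(c("mean", "se"), qty,
                                  function(a, b) paste(b, a, sep = "_")))
    cbind(data.frame(treatment = d$treatment[1], n = nrow(d)), row)
  }))
  rownames(summ) <- NULL
  list(per_sample = per, summary = summ)
}
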