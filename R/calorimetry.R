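# The stoichiometric engine: substrate-oxidation rates from gas exchange,
# resting energy expenditure, and the fixed-factor energy partition.
#
# Oxidation rates (g min^-1) follow the indirect-calorimetry stoichiometry
#   fat = 1.67 V'O2 - 1.67 V'CO2 - 0.307 Pox
#   cho = 4.55 V'CO2 - 3.21 V'O2 - 0.459 Pox
# with Pox the protein oxidation rate, estimated from the convention that
# protein oxidation supplies ~12% of energy expenditure:
#   Pox = EE (kJ min^-1) * 0.12 / 16.74 (kJ g^-1).
# Raw rates are signed; reporting clips at zero (an RER above ~1 means fat
# oxidation is negligible, not negative) while the signed values stay
# available for diagnostics.

# Stoichiometric coefficients, one place only.
.stoich <- list(fat_o2 = 1.67, fat_co2 = 1.67, fat_pox = 0.307,
                cho_co2 = 4.55, cho_o2 = 3.21, cho_pox = 0.459)

# Weir resting-EE coefficients (kcal min^-1 per L min^-1) and kcal -> kJ.
.weir <- list(o2 = 3.941, co2 = 1.106, kcal_to_kj = 4.184)

#' Energy conversion factors
#'
#' Fixed energetic equivalents used throughout: carbohydrate and protein
#' 16.7 kJ g^-1, fat 37.7 kJ g^-1; the protein-oxidation estimate divides
#' 12% of energy expenditure by 16.74 kJ g^-1.
#'
#' @param kj_per_g_cho,kj_per_g_protein,kj_per_g_fat energy densities.
#' @param kj_per_g_protein_pox denominator of the protein-oxidation estimate.
#' @param protein_fraction_of_ee protein share of energy expenditure.
#' @return a list of class `conversion_factors`.
#' @export
conversion_factors <- function(kj_per_g_cho = 16.7,
                               kj_per_g_protein = 16.7,
                               kj_per_g_fat = 37.7,
                               kj_per_g_protein_pox = 16.74,
                               protein_fraction_of_ee = 0.12) {
  f <- list(kj_per_g_cho = kj_per_g_cho,
            kj_per_g_protein = kj_per_g_protein,
            kj_per_g_fat = kj_per_g_fat,
            kj_per_g_protein_pox = kj_per_g_protein_pox,
            protein_fraction_of_ee = protein_fraction_of_ee)
  if (any(unlist(f) <= 0)) stop_domain("all conversion factors must be positive")
  class(f) <- "conversion_factors"
  f
}

#' Protein oxidation rate from energy expenditure
#'
#' Pox = EE x 0.12 / 16.74, i.e. 12% of the energy turnover divided by the
#' energy density of protein. (The equivalent printed forms sometimes carry
#' a typographic minus in place of the division; a subtraction would yield
#' physically absurd negative rates.)
#'
#' @param ee energy expenditure, kJ min^-1; typically resting EE for graded
#'   tests and the session's own EE for submaximal sessions.
#' @param factors a [conversion_factors()].
#' @return g min^-1.
#' @export
protein_oxidation_rate <- function(ee, factors = conversion_factors()) {
  if (any(!is.finite(ee)) || any(ee < 0))
    stop_domain("energy expenditure must be nonnegative")
  ee * factors$protein_fraction_of_ee / factors$kj_per_g_protein_pox
}

#' Fat oxidation rate (signed, raw)
#'
#' @param vo2,vco2 L min^-1; nonnegative.
#' @param pox protein oxidation rate, g min^-1.
#' @return signed rate in g min^-1; the caller decides whether to clip
#'   negative values (RER > 1) at zero.
#' @export
fat_oxidation_rate <- function(vo2, vco2, pox = 0) {
  if (any(!is.finite(vo2)) || any(!is.finite(vco2)) ||
      any(vo2 < 0) || any(vco2 < 0))
    stop_domain("vo2 and vco2 must be finite and nonnegative")
  .stoich$fat_o2 * vo2 - .stoich$fat_co2 * vco2 - .stoich$fat_pox * pox
}

#' Carbohydrate oxidation rate (signed, raw)
#'
#' @inheritParams fat_oxidation_rate
#' @return signed rate in g min^-1.
#' @export
cho_oxidation_rate <- function(vo2, vco2, pox = 0) {
  if (any(!is.finite(vo2)) || any(!is.finite(vco2)) ||
      any(vo2 < 0) || any(vco2 < 0))
    stop_domain("vo2 and vco2 must be finite and nonnegative")
  .stoich$cho_co2 * vco2 - .stoich$cho_o2 * vo2 - .stoich$cho_pox * pox
}

#' Substrate oxidation rates from gas exchange
#'
#' Computes fat, carbohydrate and protein oxidation rates; reported rates
#' are clipped at zero, the signed raw values are kept alongside.
#'
#' @inheritParams fat_oxidation_rate
#' @return a data.frame with columns `fat`, `cho`, `protein` (clipped),
#'   `fat_raw`, `cho_raw` (signed) and logical `fat_clipped`, `cho_clipped`.
#' @export
substrate_rates <- function(vo2, vco2, pox = 0) {
  fat_raw <- fat_oxidation_rate(vo2, vco2, pox)
  cho_raw <- cho_oxidation_rate(vo2, vco2, pox)
  data.frame(fat = pmax(fat_raw, 0), cho = pmax(cho_raw, 0),
             protein = rep_len(pox, length(fat_raw)),
             fat_raw = fat_raw, cho_raw = cho_raw,
             fat_clipped = fat_raw < 0, cho_clipped = cho_raw < 0)
}

#' Energy partition of substrate oxidation rates
#'
#' Each (clipped, nonnegative) oxidation rate is multiplied by its energy
#' density; the total is their exact sum.
#'
#' @param rates a data.frame as returned by [substrate_rates()], or any
#'   data.frame with nonnegative `fat`, `cho`, `protein` columns (g min^-1).
#' @param factors a [conversion_factors()].
#' @return a data.frame with `from_cho`, `from_fat`, `from_protein` and
#'   `total` (all kJ min^-1).
#' @export
energy_partition <- function(rates, factors = conversion_factors()) {
  need <- c("fat", "cho", "protein")
  if (!all(need %in% names(rates)))
    stop_domain("rates must contain fat, cho and protein columns")
  if (any(rates$fat < 0) || any(rates$cho < 0) || any(rates$protein < 0))
    stop_domain("oxidation rates must be nonnegative; clip raw rates first")
  from_cho <- rates$cho * factors$kj_per_g_cho
  from_fat <- rates$fat * factors$kj_per_g_fat
  from_protein <- rates$protein * factors$kj_per_g_protein
  data.frame(from_cho = from_cho, from_fat = from_fat,
             from_protein = from_protein,
             total = from_cho + from_fat + from_protein)
}

#' Grams of substrate from an energy amount
#'
#' @param ee energy, kJ; nonnegative.
#' @param substrate `"cho"`, `"fat"` or `"protein"`.
#' @param factors a [conversion_factors()].
#' @return grams.
#' @export
grams_from_energy <- function(ee, substrate = c("cho", "fat", "protein"),
                              factors = conversion_factors()) {
  substrate <- match.arg(substrate)
  if (any(ee < 0)) stop_domain("energy must be nonnegative")
  ee / switch(substrate,
              cho = factors$kj_per_g_cho,
              fat = factors$kj_per_g_fat,
              protein = factors$kj_per_g_protein)
}

#' Resting energy expenditure (Weir equation, no protein correction)
#'
#' EE (kJ min^-1) = 4.184 x (3.941 V'O2 + 1.106 V'CO2). Used for canopy
#' basal-metabolic-rate recordings.
#'
#' @param vo2,vco2 L min^-1.
#' @return kJ min^-1.
#' @export
resting_ee_weir <- function(vo2, vco2) {
  if (any(vo2 < 0) || any(vco2 < 0))
    stop_domain("vo2 and vco2 must be nonnegative")
  .weir$kcal_to_kj * (.weir$o2 * vo2 + .weir$co2 * vco2)
}

#' Invert the gas-exchange/substrate map
#'
#' Solves the 2x2 linear system mapping (V'O2, V'CO2) to (fat, cho) at a
#' fixed protein oxidation rate, numerically (no hand-derived inverse).
#' Used by the synthetic generator to back-compute V'CO2 from a prescribed
#' fat-oxidation truth, and by tests as a round-trip oracle.
#'
#' @param fat,cho signed oxidation rates, g min^-1.
#' @param pox protein oxidation rate, g min^-1.
#' @return a list with `vo2` and `vco2` (L min^-1).
#' @export
invert_gas_exchange <- function(fat, cho, pox = 0) {
  A <- matrix(c(.stoich$fat_o2, -.stoich$fat_co2,
                -.stoich$cho_o2, .stoich$cho_co2),
              nrow = 2, byrow = TRUE)
  n <- max(length(fat), length(cho), length(pox))
  fat <- rep_len(fat, n); cho <- rep_len(cho, n); pox <- rep_len(pox, n)
  sol <- solve(A, rbind(fat + .stoich$fat_pox * pox,
                        cho + .stoich$cho_pox * pox))
  list(vo2 = sol[1L, ], vco2 = sol[2L, ])
}

# Substrate-sum energy rate directly from gas exchange (kJ min^-1), using
# *unclipped* rates; linear in (vo2, vco2, pox). Internal helper for the
# self-consistent protein-oxidation estimate and the session generator.
ee_rate_from_gas <- function(vo2, vco2, pox = 0,
                             factors = conversion_factors()) {
  a <- factors$kj_per_g_fat * .stoich$fat_o2 -
    factors$kj_per_g_cho * .stoich$cho_o2
  b <- factors$kj_per_g_cho * .stoich$cho_co2 -
    factors$kj_per_g_fat * .stoich$fat_co2
  cc <- factors$kj_per_g_protein - factors$kj_per_g_cho * .stoich$cho_pox -
    factors$kj_per_g_fat * .stoich$fat_pox
  a * vo2 + b * vco2 + cc * pox
}

# Self-consistent Pox for exercise windows: solve the fixed point
# Pox = frac * EE / denom with EE the substrate-sum energy rate (linear in
# Pox), so a closed form exists.
pox_self_consistent <- function(vo2, vco2, factors = conversion_factors()) {
  k <- factors$protein_fraction_of_ee / factors$kj_per_g_protein_pox
  cc <- factors$kj_per_g_protein - factors$kj_per_g_cho * .stoich$cho_pox -
    factors$kj_per_g_fat * .stoich$fat_pox
  ee0 <- ee_rate_from_gas(vo2, vco2, pox = 0, factors = factors)
  pmax(k * ee0 / (1 - k * cc), 0)
}

#' Analyze a canopy basal-metabolic-rate recording
#'
#' Averages V'O2 and V'CO2 over the recording after discarding the initial
#' adaptation period, then converts to daily energy expenditure with the
#' Weir equation.
#'
#' @param series a [gas_series()] of 1-min canopy averages.
#' @param discard_s initial seconds to exclude (adaptation to the canopy);
#'   the conventional discard is the first 5-10 min, default 600 s.
#' @return a list: `bmr_mj_day`, `ee_kj_min`, `vo2`, `vco2`, `rer`,
#'   `n_used`, `n_discarded`.
#' @export
analyze_bmr <- function(series, discard_s = 600) {
  keep <- series$t >= discard_s
  if (!any(keep)) stop_domain("discard window leaves no samples")
  n_disc <- sum(!keep)
  if (n_disc > 0)
    message("analyze_bmr: discarded ", n_disc,
            " adaptation sample(s) before ", discard_s, " s")
  vo2 <- mean(series$vo2[keep]); vco2 <- mean(series$vco2[keep])
  ee <- resting_ee_weir(vo2, vco2)
  list(bmr_mj_day = ee * 1440 / 1000, ee_kj_min = ee, vo2 = vo2, vco2 = vco2,
       rer = if (vo2 > 0) vco2 / vo2 else NA_real_,
       n_used = sum(keep), n_discarded = n_disc)
}

# Resting Pox (g min^-1) from a subject's measured BMR (MJ day^-1).
resting_pox <- function(bmr_mj_day, factors = conversion_factors()) {
  protein_oxidation_rate(bmr_mj_day * 1000 / 1440, factors)
}
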