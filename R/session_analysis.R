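# Analysis of recorded submaximal / training sessions: substrate oxidation
# over consecutive 5-min windows, session totals in the style of an
# energy-partition table (kJ and grams per substrate), and training-load
# summaries (mean HR, %HRmax, time shares at/above the HIIT cut).

#' Substrate oxidation over consecutive windows
#'
#' Splits the exercise phase into consecutive half-open windows (default
#' 5 min), averages the gas exchange per window, and computes substrate
#' rates and the energy partition. A trailing partial window is retained
#' with its true duration rather than dropped (dropping would bias session
#' totals low).
#'
#' @param series a [gas_series()].
#' @param pox protein oxidation rate (g min^-1) to use in every window, or
#'   `NULL` (default) for the self-consistent estimate in which protein
#'   oxidation supplies 12% of each window's own energy expenditure.
#' @param window window length, s.
#' @return data.frame with one row per window: `window_index`, `t_start`,
#'   `t_end`, `minutes`, mean `vo2`, `vco2`, `hr`, clipped and raw
#'   substrate-rate columns, `pox`, and energy columns `ee_kj_min`,
#'   `ee_cho`, `ee_fat`, `ee_protein` (kJ min^-1).
#' @export
window_rates <- function(series, pox = NULL, window = 300) {
  ex <- exercise_samples(series)
  if (nrow(ex) == 0L) stop_domain("series has no exercise samples")
  dt <- attr(series, "dt_nominal")
  t0 <- attr(series, "exercise_start")
  idx <- floor((ex$t - t0) / window)
  agg <- function(v) as.numeric(tapply(v, idx, mean))
  cnt <- as.numeric(table(idx))
  starts <- t0 + sort(unique(idx)) * window
  vo2 <- agg(ex$vo2); vco2 <- agg(ex$vco2); hr <- agg(ex$hr)
  pox_w <- if (is.null(pox)) pox_self_consistent(vo2, vco2)
           else rep_len(pox, length(vo2))
  rates <- substrate_rates(vo2, vco2, pox_w)
  part <- energy_partition(rates)
  data.frame(window_index = seq_along(vo2),
             t_start = starts,
             t_end = pmin(starts + window, t0 + max(idx + 1) * window),
             minutes = cnt * dt / 60,
             vo2 = vo2, vco2 = vco2, hr = hr,
             rates, pox = pox_w,
             ee_kj_min = part$total, ee_cho = part$from_cho,
             ee_fat = part$from_fat, ee_protein = part$from_protein)
}

#' Summarise a recorded training session
#'
#' Session totals are the window-level rates integrated over each window's
#' true duration: total energy, energy and grams per substrate, plus
#' time-weighted heart-rate load. Grams and energies are stored at full
#' precision; the print method rounds to integers as such tables are
#' conventionally reported.
#'
#' @param series a [gas_series()] of the session.
#' @param subject optional [subject()]; supplies `hr_peak` for %HRmax.
#' @param pox as in [window_rates()].
#' @param hrmax maximal heart rate (bpm); defaults to `subject$hr_peak`.
#' @param hiit_cut %HRmax at/above which time counts as high-intensity
#'   (the conventional HIIT definition is >= 85% HRmax).
#' @param window window length, s.
#' @return an object of class `session_summary`.
#' @export
summarize_session <- function(series, subject = NULL, pox = NULL,
                              hrmax = NULL, hiit_cut = 85, window = 300) {
  w <- window_rates(series, pox = pox, window = window)
  tot <- function(rate) sum(rate * w$minutes)
  ee_by <- c(cho = tot(w$ee_cho), fat = tot(w$ee_fat),
             protein = tot(w$ee_protein))
  g_by <- c(cho = tot(w$cho), fat = tot(w$fat), protein = tot(w$protein))
  hrmax <- hrmax %||% (if (!is.null(subject)) subject$hr_peak else NA_real_)
  hr_ok <- !all(is.na(series$hr))
  load <- if (hr_ok && is.finite(hrmax))
    training_load(series, hrmax, hiit_cut) else NULL
  res <- list(total_ee = sum(ee_by),
              ee_by_substrate = ee_by,
              grams_by_substrate = g_by,
              duration_min = sum(w$minutes),
              mean_hr = if (hr_ok)
                sum(w$hr * w$minutes) / sum(w$minutes) else NA_real_,
              mean_hr_pct_max = if (!is.null(load)) load$mean_pct else NA_real_,
              hiit_share = if (!is.null(load)) load$hiit_share else NA_real_,
              any_clipped = c(fat = any(w$fat_clipped),
                              cho = any(w$cho_clipped)),
              windows = w)
  class(res) <- "session_summary"
  res
}

#' @export
print.session_summary <- function(x, ...) {
  cat(sprintf("<session_summary> %.1f min, total EE %d kJ\n",
              x$duration_min, round(x$total_ee)))
  e <- round(x$ee_by_substrate); g <- round(x$grams_by_substrate)
  cat(sprintf("  CHO %d kJ (%d g) | Fat %d kJ (%d g) | Protein %d kJ (%d g)\n",
              e["cho"], g["cho"], e["fat"], g["fat"], e["protein"],
              g["protein"]))
  if (is.finite(x$mean_hr))
    cat(sprintf("  mean HR %.0f bpm (%.1f %%HRmax), HIIT share %.1f%%\n",
                x$mean_hr, x$mean_hr_pct_max, x$hiit_share))
  invisible(x)
}

#' Heart-rate training load of a session
#'
#' Time-weighted mean heart rate, its %HRmax, and the shares of exercise
#' time spent at/above versus below the high-intensity cut. The two shares
#' sum to 100 exactly.
#'
#' @param series a [gas_series()] with heart rate.
#' @param hrmax maximal heart rate, bpm; positive.
#' @param hiit_cut %HRmax defining high-intensity time (default 85).
#' @return list: `mean_hr`, `mean_pct`, `hiit_share`, `mict_share`
#'   (shares in % of exercise time).
#' @export
training_load <- function(series, hrmax, hiit_cut = 85) {
  if (!is.finite(hrmax) || hrmax <= 0) stop_domain("hrmax must be positive")
  ex <- exercise_samples(series)
  hr <- ex$hr[!is.na(ex$hr)]
  if (!length(hr)) stop_domain("series has no heart-rate samples")
  mean_hr <- mean(hr)
  hi <- mean(100 * hr / hrmax >= hiit_cut) * 100
  list(mean_hr = mean_hr, mean_pct = 100 * mean_hr / hrmax,
       hiit_share = hi, mict_share = 100 - hi)
}
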