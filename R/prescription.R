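# Training prescription: translate a graded-test result into executable
# sessions. Both session types are equated to the same energy budget of
# 20 kJ per kg fat-free mass (~1.4 MJ per session for these cohorts).
#
# The combined (COMB) session is a 5-min warm-up at 50% V'O2peak, three
# 2-min bouts at 95% separated by 1 min at 50%, then a continuous block at
# 60% whose duration is solved so the predicted session energy meets the
# budget. The continuous (MICT) session is a single block, 40% V'O2peak by
# default, with duration solved the same way.
#
# Predicted energy uses a fixed gross O2 energy equivalent (20.9 kJ per L
# O2 by default, configurable); an RER-dependent equivalent can be supplied
# through `kj_per_l_o2`.

#' Heart rate at a prescribed intensity
#'
#' Linear interpolation of the graded test's per-stage (intensity, HR)
#' pairs; above the top stage the top two stages are extrapolated linearly
#' to 100%, and below the bottom stage the bottom two are used (down to
#' 10 percentage points below the lowest stage). The result is clamped to
#' \[resting HR, HRpeak\].
#'
#' @param result a `graded_result`.
#' @param pct intensity, %V'O2peak.
#' @return bpm.
#' @export
hr_for_intensity <- function(result, pct) {
  st <- result$stages
  if (nrow(st) < 2L) stop_domain("need at least 2 stages to interpolate HR")
  x <- st$intensity; y <- st$hr
  ord <- order(x); x <- x[ord]; y <- y[ord]
  if (pct < min(x) - 10 || pct > 100)
    stop_domain("intensity ", pct, "% outside the prescribable range [",
                round(min(x) - 10, 1), ", 100]")
  n <- length(x)
  hr <- if (pct >= min(x) && pct <= max(x)) {
    approx(x, y, xout = pct)$y
  } else if (pct > max(x)) {
    slope <- (y[n] - y[n - 1L]) / (x[n] - x[n - 1L])
    y[n] + slope * (pct - x[n])
  } else {
    slope <- (y[2L] - y[1L]) / (x[2L] - x[1L])
    y[1L] + slope * (pct - x[1L])
  }
  lower <- if (is.finite(result$rest_hr)) result$rest_hr else min(y)
  upper <- if (is.finite(result$hrpeak)) result$hrpeak else max(y)
  min(max(hr, lower), upper)
}

#' Oxygen uptake at a prescribed intensity
#'
#' @param result a `graded_result`.
#' @param pct intensity, %V'O2peak, in (0, 100].
#' @return L min^-1.
#' @export
vo2_at_intensity <- function(result, pct) {
  if (any(pct <= 0) || any(pct > 100))
    stop_domain("intensity must be in (0, 100] %V'O2peak")
  pct / 100 * result$vo2peak
}

#' Session energy budget from fat-free mass
#'
#' @param ffm kg, positive.
#' @param budget_kj_per_kg kJ per kg FFM; default 20.
#' @return kJ.
#' @export
session_energy_target <- function(ffm, budget_kj_per_kg = 20) {
  if (any(ffm <= 0)) stop_domain("ffm must be positive")
  budget_kj_per_kg * ffm
}

#' Predicted energy expenditure of one session segment
#'
#' @param intensity %V'O2peak.
#' @param duration s.
#' @param result a `graded_result`.
#' @param kj_per_l_o2 gross energy equivalent of oxygen, kJ L^-1.
#' @return kJ.
#' @export
predicted_segment_ee <- function(intensity, duration, result,
                                 kj_per_l_o2 = 20.9) {
  if (any(duration < 0)) stop_domain("duration must be nonnegative")
  vo2_at_intensity(result, intensity) * (duration / 60) * kj_per_l_o2
}

new_session_plan <- function(segments, energy_target, predicted_energy,
                             result, kj_per_l_o2) {
  segments$hr_target <- vapply(segments$intensity, function(p)
    tryCatch(round(hr_for_intensity(result, p)),
             error = function(e) NA_real_), numeric(1))
  segments$ee_kj <- predicted_segment_ee(segments$intensity,
                                         segments$duration, result,
                                         kj_per_l_o2)
  hiit <- sum(segments$duration[segments$label == "HIIT"])
  total <- sum(segments$duration)
  structure(list(segments = segments, energy_target = energy_target,
                 predicted_energy = predicted_energy,
                 hiit_fraction = hiit / total,
                 duration_min = total / 60,
                 kj_per_l_o2 = kj_per_l_o2),
            class = "session_plan")
}

#' Design a combined (HIIT + continuous) training session
#'
#' Fixed structure 5' @ 50% + 3 x (2' @ 95%) with 2 x (1' @ 50%) recoveries,
#' followed by a continuous block at 60% V'O2peak whose duration is solved
#' in closed form so the predicted session energy equals the 20 kJ/kg FFM
#' budget. Warm-up and recoveries count toward session energy; only the
#' 95% bouts count as HIIT time in `hiit_fraction`.
#'
#' @param result a `graded_result`.
#' @param ffm fat-free mass, kg.
#' @param kj_per_l_o2 energy equivalent of oxygen, kJ L^-1.
#' @param budget_kj_per_kg session budget per kg FFM.
#' @return a `session_plan`: `segments` (label, intensity, duration s,
#'   hr_target), `energy_target`, `predicted_energy`, `hiit_fraction`,
#'   `duration_min`.
#' @export
design_comb_session <- function(result, ffm, kj_per_l_o2 = 20.9,
                                budget_kj_per_kg = 20) {
  target <- session_energy_target(ffm, budget_kj_per_kg)
  fixed <- data.frame(
    label = c("WARMUP", "HIIT", "RECOVERY", "HIIT", "RECOVERY", "HIIT"),
    intensity = c(50, 95, 50, 95, 50, 95),
    duration = c(300, 120, 60, 120, 60, 120))
  fixed_ee <- sum(predicted_segment_ee(fixed$intensity, fixed$duration,
                                       result, kj_per_l_o2))
  rate60 <- predicted_segment_ee(60, 60, result, kj_per_l_o2)  # kJ min^-1
  mict_min <- (target - fixed_ee) / rate60
  if (mict_min <= 0)
    stop_domain("infeasible: fixed segments alone expend ",
                round(fixed_ee), " kJ, exceeding the ", round(target),
                " kJ budget")
  segments <- rbind(fixed,
                    data.frame(label = "MICT", intensity = 60,
                               duration = mict_min * 60))
  predicted <- fixed_ee + rate60 * mict_min
  new_session_plan(segments, target, predicted, result, kj_per_l_o2)
}

#' Design a continuous (MICT) training session
#'
#' A single block at `intensity` %V'O2peak whose duration meets the energy
#' budget.
#'
#' @inheritParams design_comb_session
#' @param intensity %V'O2peak; the trial prescription is 40%, close to the
#'   Fatmax intensity of these cohorts.
#' @return a `session_plan`.
#' @export
design_mict_session <- function(result, ffm, intensity = 40,
                                kj_per_l_o2 = 20.9, budget_kj_per_kg = 20) {
  if (intensity <= 0) stop_domain("intensity must be positive")
  target <- session_energy_target(ffm, budget_kj_per_kg)
  rate <- predicted_segment_ee(intensity, 60, result, kj_per_l_o2)
  dur_min <- target / rate
  segments <- data.frame(label = "MICT", intensity = intensity,
                         duration = dur_min * 60)
  new_session_plan(segments, target, rate * dur_min, result, kj_per_l_o2)
}

#' @export
print.session_plan <- function(x, ...) {
  cat(sprintf("<session_plan> %.1f min, target %.0f kJ (predicted %.0f), HIIT share %.1f%%\n",
              x$duration_min, x$energy_target, x$predicted_energy,
              100 * x$hiit_fraction))
  seg <- x$segments
  for (i in seq_len(nrow(seg)))
    cat(sprintf("  %-8s %5.1f min @ %3.0f%% V'O2peak  (HR target %s bpm)\n",
                seg$label[i], seg$duration[i] / 60, seg$intensity[i],
                ifelse(is.na(seg$hr_target[i]), "-", seg$hr_target[i])))
  invisible(x)
}
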