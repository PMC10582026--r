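# Subject records and anthropometric derivations.

#' Construct a subject record
#'
#' @param subject_id opaque identifier.
#' @param group training group, `"COMB"` (combined interval + continuous) or
#'   `"MICT"` (moderate-intensity continuous training).
#' @param age years.
#' @param stature m.
#' @param body_mass kg.
#' @param ffm fat-free mass, kg; must satisfy `0 < ffm <= body_mass`.
#' @param bmr basal metabolic rate, MJ day^-1 (NA until measured).
#' @param hr_peak peak heart rate, bpm (NA until a graded test).
#' @param hr_rest resting heart rate, bpm (optional).
#' @return a list of class `subject`.
#' @export
subject <- function(subject_id, group = c("COMB", "MICT"), age, stature,
                    body_mass, ffm, bmr = NA_real_, hr_peak = NA_real_,
                    hr_rest = NA_real_) {
  group <- match.arg(group)
  if (!is.finite(stature) || stature <= 0) stop_domain("stature must be > 0")
  if (!is.finite(body_mass) || body_mass <= 0) stop_domain("body_mass must be > 0")
  if (!is.finite(ffm) || ffm <= 0 || ffm > body_mass)
    stop_domain("ffm must satisfy 0 < ffm <= body_mass")
  if (!is.finite(age) || age <= 0) stop_domain("age must be > 0")
  structure(list(subject_id = as.character(subject_id), group = group,
                 age = age, stature = stature, body_mass = body_mass,
                 ffm = ffm, bmr = bmr, hr_peak = hr_peak, hr_rest = hr_rest),
            class = "subject")
}

#' @export
print.subject <- function(x, ...) {
  cat(sprintf("<subject %s> group %s, %.1f y, %.2f m, BM %.1f kg, FFM %.1f kg\n",
              x$subject_id, x$group, x$age, x$stature, x$body_mass, x$ffm))
  invisible(x)
}

#' Body mass index
#'
#' BMI = body mass (kg) / stature (m)^2. Note that a group-mean BMI computed
#' from group-mean mass and stature differs from the mean of per-subject
#' BMIs (mean of ratios vs ratio of means).
#'
#' @param body_mass kg.
#' @param stature m; must be positive.
#' @return kg m^-2.
#' @export
bmi <- function(body_mass, stature) {
  if (any(!is.finite(stature)) || any(stature <= 0))
    stop_domain("stature must be positive")
  body_mass / stature^2
}

#' Fat mass from body mass and fat-free mass
#'
#' FM (kg) is the difference between body mass and fat-free mass; FM (%) is
#' its share of body mass.
#'
#' @param body_mass kg.
#' @param ffm fat-free mass, kg.
#' @return a list with components `fm_kg` and `fm_pct`.
#' @export
fat_mass <- function(body_mass, ffm) {
  if (any(ffm <= 0) || any(ffm > body_mass))
    stop_domain("ffm must satisfy 0 < ffm <= body_mass")
  fm <- body_mass - ffm
  list(fm_kg = fm, fm_pct = 100 * fm / body_mass)
}

#' Fat-free mass from bioimpedance via a user-supplied equation
#'
#' Population-specific bioimpedance regressions are an injection point, not
#' an implementation: the device settings used in this field (e.g. 800 uA at
#' 50 kHz) do not pin down the regression coefficients, which live in
#' external references. Supply the equation as a function of the impedance
#' record; its result is validated against the subject invariants.
#'
#' @param impedance_inputs a list/record handed verbatim to `equation`.
#' @param equation a function `record -> ffm (kg)`.
#' @param body_mass optional body mass (kg) to validate `ffm <= body_mass`.
#' @return fat-free mass in kg.
#' @export
ffm_from_bia <- function(impedance_inputs, equation = NULL, body_mass = NULL) {
  if (is.null(equation))
    stop_domain("no bioimpedance equation supplied; provide a function ",
                "`record -> ffm (kg)` for your population and device")
  ffm <- equation(impedance_inputs)
  if (!is.numeric(ffm) || length(ffm) != 1L || !is.finite(ffm) || ffm <= 0)
    stop_domain("bioimpedance equation must return a single positive number")
  if (!is.null(body_mass) && ffm > body_mass)
    stop_domain("bioimpedance equation returned ffm > body_mass (",
                round(ffm, 1), " > ", round(body_mass, 1), " kg)")
  ffm
}
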