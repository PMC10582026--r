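# Graded treadmill test analysis: V'O2peak, HRpeak, O2 pulse, per-stage
# substrate oxidation versus intensity, maximal fat oxidation (MFO) and the
# Fatmax intensity, and the intensity above which fat oxidation becomes
# negligible (the crossover region).

#' Construct a graded-test stage
#'
#' @param speed m s^-1, nonnegative.
#' @param incline % grade, nonnegative.
#' @param duration s, positive.
#' @export
stage <- function(speed, incline, duration = 300) {
  if (duration <= 0) stop_domain("stage duration must be positive")
  if (speed < 0 || incline < 0) stop_domain("speed and incline must be >= 0")
  structure(list(speed = speed, incline = incline, duration = duration),
            class = "stage")
}

#' Construct a graded-test protocol
#'
#' @param stages list of [stage()] objects, in order.
#' @param rest_duration pre-exercise rest, s.
#' @param hr_stop heart rate (bpm) at which the test is terminated to avoid
#'   maximal effort.
#' @export
graded_protocol <- function(stages, rest_duration = 600, hr_stop = 180) {
  if (!length(stages)) stop_domain("protocol needs at least one stage")
  if (hr_stop <= 100) stop_domain("hr_stop must exceed 100 bpm")
  structure(list(rest_duration = rest_duration, stages = stages,
                 hr_stop = hr_stop),
            class = "graded_protocol")
}

#' The default walking graded-test protocol
#'
#' Ten minutes of rest, then seven 5-min walking stages with speed (m s^-1)
#' and incline (%) following 0.6 (0), 1.0 (0), 1.0 (3), 1.3 (3), 1.4 (6),
#' 1.4 (9), 1.4 (12); exercise stops when heart rate reaches ~180 bpm.
#'
#' @return a [graded_protocol()].
#' @export
default_grad_protocol <- function() {
  speeds <- c(0.6, 1.0, 1.0, 1.3, 1.4, 1.4, 1.4)
  inclines <- c(0, 0, 3, 3, 6, 9, 12)
  graded_protocol(Map(stage, speeds, inclines, duration = 300),
                  rest_duration = 600, hr_stop = 180)
}

# Read a graded protocol from a YAML file with fields rest_duration,
# hr_stop and a list of {speed, incline, duration} stages.
#' Read a graded protocol from YAML
#' @param path YAML file.
#' @return a [graded_protocol()].
#' @export
read_protocol <- function(path) {
  y <- yaml::read_yaml(path)
  graded_protocol(lapply(y$stages, function(s)
    stage(s$speed, s$incline, s$duration %||% 300)),
    rest_duration = y$rest_duration %||% 600,
    hr_stop = y$hr_stop %||% 180)
}

#' Peak oxygen uptake from the end of a graded test
#'
#' V'O2peak is the mean V'O2 over the samples in the last `window` seconds
#' of the recording (half-open on the left, inclusive of the final sample;
#' with 5-s breath averaging that is 4 samples). HRpeak is the mean heart
#' rate over the same window, reported to 0.1 bpm. The value depends only
#' on the end of the recording, never on pre-exercise rest content.
#'
#' @param series a [gas_series()].
#' @param window s, default 20.
#' @return list with `vo2peak` (L min^-1) and `hrpeak` (bpm, NA if HR absent).
#' @export
detect_vo2peak <- function(series, window = 20) {
  ex <- exercise_samples(series)
  if (nrow(ex) == 0L) stop_domain("series has no exercise samples")
  t_end <- max(ex$t)
  span <- t_end - min(ex$t) + attr(series, "dt_nominal")
  if (span < window)
    stop_domain("exercise phase shorter than the ", window, "-s peak window")
  sel <- ex$t > t_end - window & ex$t <= t_end
  hr <- ex$hr[sel]
  list(vo2peak = mean(ex$vo2[sel]),
       hrpeak = if (all(is.na(hr))) NA_real_ else
         round(mean(hr, na.rm = TRUE), 1))
}

#' Oxygen pulse
#'
#' V'O2 per heart beat (mL beat^-1), an indirect index of stroke volume;
#' reported to 0.1.
#'
#' @param vo2peak L min^-1.
#' @param hrpeak bpm, positive.
#' @export
o2_pulse <- function(vo2peak, hrpeak) {
  if (any(hrpeak <= 0)) stop_domain("hrpeak must be positive")
  round(1000 * vo2peak / hrpeak, 1)
}

#' Per-stage measurements of a graded test
#'
#' Gas-exchange means over the final minute of each *completed* stage,
#' expressed against `vo2peak`, with substrate rates from the stoichiometric
#' equations at a fixed (resting) protein oxidation rate. Stages whose final
#' minute is not fully covered by data are excluded with a warning.
#'
#' @param series a [gas_series()] covering rest + stages per `protocol`.
#' @param protocol a [graded_protocol()].
#' @param pox protein oxidation rate, g min^-1.
#' @param vo2peak L min^-1, from [detect_vo2peak()].
#' @return data.frame with one row per completed stage: `stage_index`,
#'   `intensity` (%V'O2peak), `vo2`, `vco2`, `hr`, substrate-rate columns
#'   as in [substrate_rates()].
#' @export
stage_measurements <- function(series, protocol, pox, vo2peak) {
  if (vo2peak <= 0) stop_domain("vo2peak must be positive")
  dt <- attr(series, "dt_nominal")
  ends <- protocol$rest_duration +
    cumsum(vapply(protocol$stages, `[[`, numeric(1), "duration"))
  t_max <- max(series$t)
  rows <- lapply(seq_along(ends), function(j) {
    end <- ends[j]
    sel <- series$t >= end - 60 & series$t < end
    covered <- t_max >= end - dt && sum(sel) * dt >= 60 - dt
    if (!covered) return(NULL)
    data.frame(stage_index = j,
               vo2 = mean(series$vo2[sel]),
               vco2 = mean(series$vco2[sel]),
               hr = mean(series$hr[sel]))
  })
  dropped <- sum(vapply(rows, is.null, logical(1)) &
                   ends - dt <= t_max)
  if (dropped > 0)
    warning(dropped, " stage(s) with < 60 s of final-minute data excluded",
            call. = FALSE)
  rows <- do.call(rbind, rows)
  if (is.null(rows) || nrow(rows) == 0L)
    stop_domain("no completed stages in series")
  rates <- substrate_rates(rows$vo2, rows$vco2, pox)
  out <- cbind(rows, intensity = 100 * rows$vo2 / vo2peak, rates)
  out[order(out$intensity), , drop = FALSE]
}

#' Maximal fat oxidation and the Fatmax intensity
#'
#' `stage_max` (the default, matching per-workload determination): MFO is
#' the largest clipped fat-oxidation rate across stages and Fatmax its
#' intensity, ties broken toward the lower intensity. `poly3`: a
#' least-squares cubic of fat rate on intensity, maximised analytically on
#' the observed intensity range — useful for smooth oxidation curves.
#'
#' @param stages data.frame from [stage_measurements()] (needs `intensity`
#'   and `fat` columns), at least 3 rows.
#' @param method `"stage_max"` or `"poly3"`.
#' @return list: `mfo` (g min^-1), `fatmax` (%V'O2peak, NA when all fat
#'   rates are zero), `defined` (logical), `method`.
#' @export
find_mfo <- function(stages, method = c("stage_max", "poly3")) {
  method <- match.arg(method)
  if (nrow(stages) < 3L) stop_domain("need at least 3 stages")
  x <- stages$intensity; y <- stages$fat
  ord <- order(x); x <- x[ord]; y <- y[ord]
  if (all(y <= 0))
    return(list(mfo = 0, fatmax = NA_real_, defined = FALSE, method = method))
  if (method == "stage_max") {
    i <- which.max(y)  # first max = lowest intensity on ties
    return(list(mfo = y[i], fatmax = x[i], defined = TRUE, method = method))
  }
  fit <- lm(y ~ x + I(x^2) + I(x^3))
  b <- coef(fit)
  # candidates: interval endpoints + real roots of the derivative
  dcoef <- c(b[2], 2 * b[3], 3 * b[4])
  cand <- range(x)
  if (any(dcoef[-1] != 0)) {
    r <- polyroot(dcoef)
    r <- Re(r)[abs(Im(polyroot(dcoef))) < 1e-8]
    cand <- c(cand, r[r > min(x) & r < max(x)])
  }
  f <- function(p) b[1] + b[2] * p + b[3] * p^2 + b[4] * p^3
  vals <- vapply(cand, f, numeric(1))
  best <- max(vals)
  fatmax <- min(cand[vals >= best - 1e-12])  # tie -> lower intensity
  list(mfo = unname(best), fatmax = unname(fatmax), defined = TRUE,
       method = method)
}

#' Intensity above which fat oxidation becomes negligible
#'
#' Linear interpolation of the first downward crossing of the clipped
#' fat-oxidation curve through `threshold`, searching upward from the
#' Fatmax stage. If the curve never drops below the threshold the highest
#' observed intensity is returned with `crossed = FALSE`.
#'
#' @param stages data.frame ordered by `intensity` with a `fat` column.
#' @param threshold g min^-1 below which fat oxidation counts as
#'   negligible; default 0.05.
#' @return list: `crossover` (%V'O2peak), `crossed`, `defined`.
#' @export
crossover_intensity <- function(stages, threshold = 0.05) {
  x <- stages$intensity; y <- stages$fat
  ord <- order(x); x <- x[ord]; y <- y[ord]
  i0 <- which.max(y)
  if (length(x) - i0 < 1L || length(x) < 2L)
    return(list(crossover = NA_real_, crossed = FALSE, defined = FALSE))
  for (i in seq(i0, length(x))) {
    if (y[i] == threshold)
      return(list(crossover = x[i], crossed = TRUE, defined = TRUE))
    if (i < length(x) && y[i] > threshold && y[i + 1L] < threshold) {
      cr <- x[i] + (y[i] - threshold) / (y[i] - y[i + 1L]) * (x[i + 1L] - x[i])
      return(list(crossover = cr, crossed = TRUE, defined = TRUE))
    }
  }
  list(crossover = x[length(x)], crossed = FALSE, defined = TRUE)
}

#' Full graded-test analysis
#'
#' Runs peak detection, per-stage substrate oxidation, MFO/Fatmax and the
#' crossover search on one recording.
#'
#' @param series a [gas_series()] of the test (rest + stages).
#' @param protocol a [graded_protocol()].
#' @param subject optional [subject()]; supplies the resting protein
#'   oxidation rate (from measured BMR) and FFM-relative V'O2peak.
#' @param pox protein oxidation rate (g min^-1); default: derived from
#'   `subject$bmr` when available, else 0.
#' @param mfo_method passed to [find_mfo()].
#' @param crossover_threshold passed to [crossover_intensity()].
#' @return an object of class `graded_result`: `vo2peak`, `vo2peak_rel_ffm`,
#'   `hrpeak`, `o2pulse`, `rest_hr`, `stages`, `mfo`, `fatmax`, `crossover`,
#'   `crossed`, `pox`.
#' @export
analyze_graded <- function(series, protocol = default_grad_protocol(),
                           subject = NULL, pox = NULL,
                           mfo_method = "stage_max",
                           crossover_threshold = 0.05) {
  if (is.null(pox))
    pox <- if (!is.null(subject) && is.finite(subject$bmr))
      resting_pox(subject$bmr) else 0
  peak <- detect_vo2peak(series)
  st <- stage_measurements(series, protocol, pox, peak$vo2peak)
  mfo <- find_mfo(st, method = mfo_method)
  cross <- crossover_intensity(st, threshold = crossover_threshold)
  rest <- series[series$t < protocol$rest_duration, , drop = FALSE]
  rest_hr <- if (nrow(rest) && !all(is.na(rest$hr)))
    mean(rest$hr, na.rm = TRUE) else NA_real_
  res <- list(vo2peak = peak$vo2peak,
              vo2peak_rel_ffm = if (!is.null(subject))
                1000 * peak$vo2peak / subject$ffm else NA_real_,
              hrpeak = peak$hrpeak,
              o2pulse = if (is.na(peak$hrpeak)) NA_real_ else
                o2_pulse(peak$vo2peak, peak$hrpeak),
              rest_hr = rest_hr,
              stages = st,
              mfo = mfo$mfo, fatmax = mfo$fatmax, mfo_defined = mfo$defined,
              crossover = cross$crossover, crossed = cross$crossed,
              pox = pox)
  class(res) <- "graded_result"
  res
}

#' @export
print.graded_result <- function(x, ...) {
  cat(sprintf("<graded_result> V'O2peak %.2f L/min, HRpeak %.1f bpm, O2 pulse %.1f mL/beat\n",
              x$vo2peak, x$hrpeak, x$o2pulse))
  cat(sprintf("  %d stages; MFO %.3f g/min at %.1f %%V'O2peak; fat negligible above %.1f%%%s\n",
              nrow(x$stages), x$mfo, x$fatmax, x$crossover,
              if (x$crossed) "" else " (never crossed)"))
  invisible(x)
}
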