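# Gas-exchange time-series container and its CSV dialect.
#
# A gas series is a data.frame with columns t (s from recording start),
# vo2, vco2 (L min^-1 STPD), hr (bpm), speed (m s^-1), incline (% grade);
# optional channels are NA when unmeasured. Attributes carry the nominal
# sampling interval, the recording phase and where exercise starts. All
# window arithmetic elsewhere in the package treats time as half-open
# [start, end) so that a sample is never counted in two adjacent windows.

#' Construct a gas-exchange series
#'
#' @param t sample times in seconds from recording start; strictly increasing.
#' @param vo2,vco2 oxygen uptake and carbon-dioxide output, L min^-1 STPD.
#' @param hr heart rate in bpm, or `NULL` if not recorded. Values, when
#'   present, must lie in \[30, 230\].
#' @param speed treadmill speed in m s^-1, or `NULL`.
#' @param incline treadmill incline in % grade, or `NULL`.
#' @param dt_nominal nominal sampling interval in seconds (e.g. 60 for 1-min
#'   canopy averages, 5 for breath-averaged exercise data). Defaults to the
#'   median time step.
#' @param phase recording phase: `"EXERCISE"`, `"REST"` or `"MIXED"`.
#' @param exercise_start time (s) at which exercise begins; samples before it
#'   belong to the pre-exercise rest period. Ignored for pure-rest series.
#' @return an object of class `gas_series` (a data.frame).
#' @export
gas_series <- function(t, vo2, vco2, hr = NULL, speed = NULL, incline = NULL,
                       dt_nominal = NULL,
                       phase = c("EXERCISE", "REST", "MIXED"),
                       exercise_start = 0) {
  phase <- match.arg(phase)
  n <- length(t)
  if (n == 0L) stop_domain("a gas series must contain at least one sample")
  if (length(vo2) != n || length(vco2) != n)
    stop_domain("t, vo2 and vco2 must have equal length")
  if (anyNA(t) || any(!is.finite(t))) stop_domain("sample times must be finite")
  dt <- diff(t)
  if (any(dt == 0)) {
    bad <- t[which(dt == 0)[1L] + 1L]
    stop_domain("duplicated timestamp at t = ", bad, " s")
  }
  if (any(dt < 0)) stop_domain("sample times must be strictly increasing")
  if (any(vo2 < 0, na.rm = TRUE) || any(vco2 < 0, na.rm = TRUE))
    stop_domain("vo2 and vco2 must be nonnegative")
  hr <- if (is.null(hr)) rep(NA_real_, n) else as.numeric(hr)
  if (any(!is.na(hr) & (hr < 30 | hr > 230)))
    stop_domain("heart rate outside the plausible range [30, 230] bpm")
  speed <- if (is.null(speed)) rep(NA_real_, n) else as.numeric(speed)
  incline <- if (is.null(incline)) rep(NA_real_, n) else as.numeric(incline)
  x <- data.frame(t = as.numeric(t), vo2 = as.numeric(vo2),
                  vco2 = as.numeric(vco2), hr = hr,
                  speed = speed, incline = incline)
  attr(x, "dt_nominal") <- dt_nominal %||% (if (n > 1L) median(dt) else 1)
  attr(x, "phase") <- phase
  attr(x, "exercise_start") <- exercise_start
  class(x) <- c("gas_series", "data.frame")
  x
}

#' @export
print.gas_series <- function(x, ...) {
  cat(sprintf("<gas_series> %d samples, dt %.3g s, phase %s, t in [%.4g, %.4g] s\n",
              nrow(x), attr(x, "dt_nominal"), attr(x, "phase"),
              min(x$t), max(x$t)))
  invisible(x)
}

# Samples belonging to the exercise phase (t >= exercise_start).
exercise_samples <- function(series) {
  if (attr(series, "phase") == "REST") return(series[0L, , drop = FALSE])
  series[series$t >= attr(series, "exercise_start"), , drop = FALSE]
}

#' Breath-table CSV dialect
#'
#' The package's canonical breath-table file is comma-separated with dot
#' decimals and the header `t_s,vo2_lmin,vco2_lmin,hr_bpm,speed_ms,incline_pct`
#' (optional columns may be absent). Exports from real metabolic carts that
#' use other units or separators are adapted through this dialect object.
#'
#' @param sep field separator.
#' @param dec decimal mark.
#' @param vo2_unit,vco2_unit `"l_min"` or `"ml_min"`; millilitre data are
#'   divided by 1000 on read.
#' @param speed_unit `"m_s"` or `"km_h"`; km/h data are divided by 3.6.
#' @return a list of class `gas_dialect`.
#' @export
gas_dialect <- function(sep = ",", dec = ".",
                        vo2_unit = c("l_min", "ml_min"),
                        vco2_unit = c("l_min", "ml_min"),
                        speed_unit = c("m_s", "km_h")) {
  d <- list(sep = sep, dec = dec,
            vo2_unit = match.arg(vo2_unit),
            vco2_unit = match.arg(vco2_unit),
            speed_unit = match.arg(speed_unit))
  class(d) <- "gas_dialect"
  d
}

#' Read a breath-table CSV into a gas series
#'
#' Malformed rows (non-finite time or gas values) are dropped and counted;
#' the count is reported with a message so discard steps stay auditable.
#'
#' @param path file to read.
#' @param dialect a [gas_dialect()].
#' @param ... passed on to [gas_series()] (`phase`, `exercise_start`, ...).
#' @return a [gas_series()].
#' @export
read_gas_series <- function(path, dialect = gas_dialect(), ...) {
  if (!file.exists(path)) stop_domain("file not found: ", path)
  raw <- read.table(path, header = TRUE, sep = dialect$sep, dec = dialect$dec,
                    stringsAsFactors = FALSE)
  required <- c("t_s", "vo2_lmin", "vco2_lmin")
  missing <- setdiff(required, names(raw))
  if (length(missing))
    stop_domain("missing required column '", missing[1L], "' in ", path)
  num <- function(col) if (col %in% names(raw))
    suppressWarnings(as.numeric(raw[[col]])) else NULL
  t <- num("t_s"); vo2 <- num("vo2_lmin"); vco2 <- num("vco2_lmin")
  ok <- is.finite(t) & is.finite(vo2) & is.finite(vco2)
  n_bad <- sum(!ok)
  if (n_bad > 0L)
    message("read_gas_series: dropped ", n_bad, " malformed row(s) from ", path)
  keep <- which(ok)
  ord <- keep[order(t[keep])]
  scale_gas <- function(v, unit) if (identical(unit, "ml_min")) v / 1000 else v
  hr <- num("hr_bpm"); speed <- num("speed_ms"); incline <- num("incline_pct")
  if (!is.null(speed) && identical(dialect$speed_unit, "km_h"))
    speed <- speed / 3.6
  gas_series(t = t[ord],
             vo2 = scale_gas(vo2[ord], dialect$vo2_unit),
             vco2 = scale_gas(vco2[ord], dialect$vco2_unit),
             hr = if (is.null(hr)) NULL else hr[ord],
             speed = if (is.null(speed)) NULL else speed[ord],
             incline = if (is.null(incline)) NULL else incline[ord],
             ...)
}

#' Write a gas series as a breath-table CSV
#'
#' Values are written with 17 significant digits so that
#' `read_gas_series(write_gas_series(x))` round-trips bit-identically.
#'
#' @param series a [gas_series()].
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_gas_series <- function(series, path) {
  fmt <- function(v) ifelse(is.na(v), "", sprintf("%.17g", v))
  out <- data.frame(t_s = fmt(series$t),
                    vo2_lmin = fmt(series$vo2),
                    vco2_lmin = fmt(series$vco2),
                    hr_bpm = fmt(series$hr),
                    speed_ms = fmt(series$speed),
                    incline_pct = fmt(series$incline),
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = ",", dec = ".", quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  invisible(path)
}
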