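# Synthetic metabolic-cart data, calibrated to the group-level statistics
# the pipeline is meant to reproduce: subject anthropometrics and physical
# capacities per group and timepoint, 1-min ventilated-canopy recordings,
# 5-s breath-averaged graded treadmill tests, and energy-equated submaximal
# sessions.
#
# The fat-oxidation "truth" of a simulated subject is a beta-shaped
# unimodal curve of exercise intensity p (%V'O2peak),
#   f(p) = MFO * (p/F)^a * ((b-p)/(b-F))^(a*(b-F)/F),  0 <= p < b,
# which peaks exactly at (F = Fatmax, MFO) and whose right endpoint b is
# solved so the curve passes through the negligibility threshold at the
# subject's crossover intensity. The generator back-computes V'CO2 from
# this truth by inverting the stoichiometric equations, so a noiseless
# recording analysed by the graded-test pipeline returns the curve sampled
# at the stage intensities.

#' Measurement-noise model for simulated recordings
#'
#' @param gas_cv fractional SD applied multiplicatively and independently
#'   to each breath-averaged V'O2 and V'CO2 sample (default 0.04).
#' @param hr_sd additive heart-rate noise, bpm.
#' @param onset_tau time constant (s) of the mono-exponential V'O2 kinetics
#'   at work-rate transitions.
#' @param seed integer seed, or `NULL` to draw from the current RNG stream.
#' @return a list of class `noise_model`.
#' @export
noise_model <- function(gas_cv = 0.04, hr_sd = 3, onset_tau = 40,
                        seed = NULL) {
  if (gas_cv < 0 || hr_sd < 0 || onset_tau < 0)
    stop_domain("noise parameters must be nonnegative")
  structure(list(gas_cv = gas_cv, hr_sd = hr_sd, onset_tau = onset_tau,
                 seed = seed), class = "noise_model")
}

# Group-level presets: mean/SD cells per group and timepoint. Anthropo-
# metrics, capacities, the fat-oxidation landmarks (MFO, Fatmax, the
# crossover intensity) and the session energy-partition targets.
.presets <- list(
  COMB_W0 = list(
    name = "COMB_W0", group = "COMB", timepoint = "W0",
    age = c(15.7, 1.7), stature = c(1.75, 0.07), bm = c(117.7, 19.8),
    ffm = c(65.4, 7.9), bmr = c(7.44, 1.05),
    vo2peak = c(2.52, 0.46), hrpeak = c(176.0, 4.7),
    o2pulse = c(14.3, 2.5), hr_rest = c(72, 5),
    mfo = c(0.32, 0.07), fatmax = c(50, 9), crossover = c(74, 6),
    session = list(total = c(1362, 166), ee_cho = c(644, 189),
                   ee_fat = c(552, 137), ee_protein = c(174, 20),
                   cho_g = c(39, 11), fat_g = c(15, 4),
                   protein_g = c(10, 1))),
  COMB_W3 = list(
    name = "COMB_W3", group = "COMB", timepoint = "W3",
    age = c(15.8, 1.7), stature = c(1.75, 0.07), bm = c(112.6, 19.2),
    ffm = c(64.7, 7.5), bmr = c(7.20, 1.02),
    vo2peak = c(2.81, 0.45), hrpeak = c(176.0, 9.1),
    o2pulse = c(15.9, 2.5), hr_rest = c(72, 5),
    mfo = c(0.36, 0.07), fatmax = c(50, 9), crossover = c(74, 6),
    session = list(total = c(1312, 184), ee_cho = c(737, 211),
                   ee_fat = c(433, 157), ee_protein = c(165, 22),
                   cho_g = c(44, 13), fat_g = c(11, 5),
                   protein_g = c(10, 1))),
  MICT_W0 = list(
    name = "MICT_W0", group = "MICT", timepoint = "W0",
    age = c(16.2, 1.1), stature = c(1.72, 0.07), bm = c(111.5, 14.8),
    ffm = c(69.2, 7.5), bmr = c(8.66, 0.78),
    vo2peak = c(3.60, 0.42), hrpeak = c(176.1, 6.8),
    o2pulse = c(20.4, 2.3), hr_rest = c(72, 5),
    mfo = c(0.41, 0.09), fatmax = c(46, 8), crossover = c(74, 6),
    session = list(total = c(1521, 256), ee_cho = c(518, 107),
                   ee_fat = c(831, 178), ee_protein = c(172, 30),
                   cho_g = c(31, 6), fat_g = c(22, 5),
                   protein_g = c(10, 2))),
  MICT_W3 = list(
    name = "MICT_W3", group = "MICT", timepoint = "W3",
    age = c(16.3, 1.1), stature = c(1.72, 0.07), bm = c(103.2, 13.9),
    ffm = c(65.0, 8.4), bmr = c(8.13, 1.02),
    vo2peak = c(3.62, 0.36), hrpeak = c(177.8, 5.6),
    o2pulse = c(20.4, 2.3), hr_rest = c(72, 5),
    mfo = c(0.41, 0.09), fatmax = c(46, 8), crossover = c(74, 6),
    session = list(total = c(1549, 201), ee_cho = c(563, 142),
                   ee_fat = c(812, 221), ee_protein = c(173, 22),
                   cho_g = c(34, 9), fat_g = c(22, 6),
                   protein_g = c(10, 1))))

#' Group-level simulation preset
#'
#' @param name one of `"COMB_W0"`, `"COMB_W3"`, `"MICT_W0"`, `"MICT_W3"`.
#' @return a list of mean/SD cells (class `group_preset`).
#' @export
group_preset <- function(name) {
  if (!name %in% names(.presets))
    stop_domain("unknown preset '", name, "'; available: ",
                paste(names(.presets), collapse = ", "))
  structure(.presets[[name]], class = "group_preset")
}

#' Zero out the between-subject variability of a preset
#'
#' Useful for noiseless round-trip checks: every draw reproduces the preset
#' means exactly.
#'
#' @param preset a [group_preset()].
#' @return the preset with all SD cells set to 0.
#' @export
zero_sd_preset <- function(preset) {
  for (nm in names(preset)) {
    if (is.numeric(preset[[nm]]) && length(preset[[nm]]) == 2L)
      preset[[nm]][2L] <- 0
    if (nm == "session")
      preset$session <- lapply(preset$session, function(v) c(v[1L], 0))
  }
  preset
}

# Truncated-normal draw by redraw (falls back to clamping).
rtnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) return(rep(mean, n))
  x <- rnorm(n, mean, sd)
  for (i in 1:20) {
    bad <- x < lower | x > upper
    if (!any(bad)) break
    x[bad] <- rnorm(sum(bad), mean, sd)
  }
  pmin(pmax(x, lower), upper)
}

#' Beta-shaped fat-oxidation truth curve
#'
#' Returns a vectorised function f(p) of intensity (%V'O2peak) that peaks
#' at (`fatmax`, `mfo`), is zero at zero intensity, and crosses the
#' negligibility `threshold` at the `crossover` intensity (its right
#' endpoint is solved numerically); zero beyond the endpoint.
#'
#' @param fatmax peak intensity, %V'O2peak.
#' @param mfo peak fat-oxidation rate, g min^-1.
#' @param crossover intensity at which the curve equals `threshold`.
#' @param threshold negligibility threshold, g min^-1.
#' @param shape left-limb exponent of the beta form (curvature; default 2).
#' @return a function `p -> g min^-1`.
#' @export
fat_ox_curve <- function(fatmax, mfo, crossover, threshold = 0.05,
                         shape = 2) {
  if (crossover <= fatmax)
    stop_domain("crossover must exceed fatmax")
  f_at <- function(b, p) {
    beta <- shape * (b - fatmax) / fatmax
    mfo * (p / fatmax)^shape * ((b - p) / (b - fatmax))^beta
  }
  g <- function(b) f_at(b, crossover) - threshold
  upper <- crossover + 500
  b <- if (g(upper) < 0) upper else
    uniroot(g, c(crossover * (1 + 1e-9), upper), tol = 1e-10)$root
  beta <- shape * (b - fatmax) / fatmax
  function(p) {
    out <- numeric(length(p))
    in_range <- p > 0 & p < b
    out[in_range] <- mfo * (p[in_range] / fatmax)^shape *
      ((b - p[in_range]) / (b - fatmax))^beta
    out
  }
}

#' Draw a simulated subject from a group preset
#'
#' Anthropometrics and capacities are independent normal draws at the
#' preset mean/SD, truncated to physiological bounds (and FFM to at most
#' 95% of body mass). The subject additionally carries its latent truths:
#' `vo2peak_true`, `mfo_true`, `fatmax_true`, `crossover_true`.
#'
#' @param preset a [group_preset()].
#' @param seed integer seed or `NULL`.
#' @param id subject identifier.
#' @return a [subject()] with truth fields appended.
#' @export
make_subject <- function(preset, seed = NULL, id = NULL) {
  with_seed(seed, {
    d <- function(cell, lower = -Inf, upper = Inf)
      rtnorm(1L, cell[1L], cell[2L], lower, upper)
    stature <- d(preset$stature, 1.2, 2.2)
    bm <- d(preset$bm, 50, 250)
    ffm <- min(d(preset$ffm, 30, 120), 0.95 * bm)
    s <- subject(
      subject_id = id %||% sprintf("%s_sim", preset$name),
      group = preset$group,
      age = d(preset$age, 10, 22),
      stature = stature, body_mass = bm, ffm = ffm,
      bmr = d(preset$bmr, 3, 15),
      hr_peak = d(preset$hrpeak, 150, 215),
      hr_rest = d(preset$hr_rest, 45, 110))
    s$vo2peak_true <- d(preset$vo2peak, 1, 6)
    s$fatmax_true <- d(preset$fatmax, 25, 65)
    s$mfo_true <- d(preset$mfo, 0.05, 1.2)
    s$crossover_true <- max(d(preset$crossover, 55, 95),
                            s$fatmax_true + 5)
    s$preset <- preset$name
    s
  })
}

#' Simulate a ventilated-canopy BMR recording
#'
#' One-minute averages over `duration_min` minutes. The steady state is
#' chosen so that the Weir equation at RER 0.85 inverts exactly to the
#' subject's BMR; the first 8 minutes carry a quadratically decaying
#' adaptation transient (+25% at t = 0, zero from 8 min on), so the
#' conventional discard of the first 5-10 minutes is exercised.
#'
#' @param subject a [subject()] with `bmr` set (MJ day^-1).
#' @param noise a [noise_model()].
#' @param duration_min recording length, minutes (default 45).
#' @param rer steady-state respiratory exchange ratio.
#' @return a [gas_series()] with `phase = "REST"`.
#' @export
simulate_bmr_recording <- function(subject, noise = noise_model(),
                                   duration_min = 45, rer = 0.85) {
  if (!is.finite(subject$bmr)) stop_domain("subject has no measured bmr")
  with_seed(noise$seed, {
    ee <- subject$bmr * 1000 / 1440  # kJ min^-1
    vo2_ss <- ee / (.weir$kcal_to_kj * (.weir$o2 + .weir$co2 * rer))
    t <- seq(0, by = 60, length.out = duration_min)
    transient <- ifelse(t < 480, 1 + 0.25 * (1 - t / 480)^2, 1)
    vo2 <- vo2_ss * transient
    vco2 <- rer * vo2
    if (noise$gas_cv > 0) {
      vo2 <- pmax(vo2 * (1 + rnorm(length(t), 0, noise$gas_cv)), 0)
      vco2 <- pmax(vco2 * (1 + rnorm(length(t), 0, noise$gas_cv)), 0)
    }
    hr <- if (is.finite(subject$hr_rest))
      pmin(pmax(subject$hr_rest + rnorm(length(t), 0, noise$hr_sd), 30), 230)
    else NULL
    gas_series(t, vo2, vco2, hr = hr, dt_nominal = 60, phase = "REST")
  })
}

# Piecewise mono-exponential response toward a per-sample target, advanced
# sample by sample: v[i] relaxes toward target[i] with time constant tau.
onset_response <- function(target, dt, tau, v0) {
  n <- length(target)
  v <- numeric(n)
  decay <- if (tau > 0) exp(-dt / tau) else 0
  prev <- v0
  for (i in seq_len(n)) {
    prev <- target[i] + (prev - target[i]) * decay
    v[i] <- prev
  }
  v
}

#' Simulate a graded treadmill test
#'
#' Five-second breath averages over the protocol's rest period and stages.
#' Stage steady-state V'O2 climbs linearly in intensity from 35% to 100%
#' of the subject's true V'O2peak across the protocol's stages, with
#' mono-exponential onset kinetics at each transition. Heart rate is linear
#' in instantaneous V'O2 between the subject's resting and peak HR; the
#' recording is truncated at the first sample whose noiseless HR reaches
#' the protocol's stop criterion. V'CO2 is back-computed from the subject's
#' fat-oxidation truth curve by inverting the stoichiometric equations at
#' the subject's resting protein-oxidation rate.
#'
#' @param subject a simulated [subject()] (needs the truth fields from
#'   [make_subject()] and a measured `bmr`).
#' @param noise a [noise_model()].
#' @param protocol a [graded_protocol()].
#' @param dt sampling interval, s.
#' @return a [gas_series()] with `phase = "MIXED"` and `exercise_start` at
#'   the end of the rest period.
#' @export
simulate_graded_test <- function(subject, noise = noise_model(),
                                 protocol = default_grad_protocol(),
                                 dt = 5) {
  for (f in c("vo2peak_true", "fatmax_true", "mfo_true", "crossover_true"))
    if (is.null(subject[[f]]))
      stop_domain("subject lacks truth field '", f, "'; use make_subject()")
  with_seed(noise$seed, {
    pox <- resting_pox(subject$bmr)
    curve <- fat_ox_curve(subject$fatmax_true, subject$mfo_true,
                          subject$crossover_true)
    vo2pk <- subject$vo2peak_true
    ee_rest <- subject$bmr * 1000 / 1440
    vo2_rest <- ee_rest / (.weir$kcal_to_kj * (.weir$o2 + .weir$co2 * 0.85))
    n_st <- length(protocol$stages)
    phi <- seq(35, 100, length.out = n_st)
    durs <- vapply(protocol$stages, `[[`, numeric(1), "duration")
    t_ex_end <- protocol$rest_duration + sum(durs)
    t <- seq(0, t_ex_end - dt, by = dt)
    ex <- t >= protocol$rest_duration
    stage_of <- findInterval(t[ex] - protocol$rest_duration,
                             cumsum(c(0, durs)), rightmost.closed = FALSE)
    target <- c(rep(vo2_rest, sum(!ex)), phi[stage_of] / 100 * vo2pk)
    vo2_true <- onset_response(target, dt, noise$onset_tau, vo2_rest)
    p_inst <- 100 * vo2_true / vo2pk
    vco2_true <- ifelse(ex,
                        vo2_true - (curve(p_inst) + .stoich$fat_pox * pox) /
                          .stoich$fat_o2,
                        0.85 * vo2_true)
    hr_rest <- if (is.finite(subject$hr_rest)) subject$hr_rest else 72
    hr_true <- ifelse(ex,
                      hr_rest + (subject$hr_peak - hr_rest) *
                        vo2_true / vo2pk,
                      hr_rest)
    stop_at <- which(ex & hr_true >= protocol$hr_stop)
    keep <- if (length(stop_at)) seq_len(stop_at[1L] - 1L) else
      seq_along(t)
    n <- length(keep)
    vo2 <- vo2_true[keep]; vco2 <- vco2_true[keep]; hr <- hr_true[keep]
    if (noise$gas_cv > 0) {
      vo2 <- pmax(vo2 * (1 + rnorm(n, 0, noise$gas_cv)), 0)
      vco2 <- pmax(vco2 * (1 + rnorm(n, 0, noise$gas_cv)), 0)
    }
    if (noise$hr_sd > 0) hr <- hr + rnorm(n, 0, noise$hr_sd)
    gas_series(t[keep], vo2, vco2, hr = pmin(pmax(hr, 30), 230),
               dt_nominal = dt, phase = "MIXED",
               exercise_start = protocol$rest_duration)
  })
}

#' Simulate an energy-equated submaximal training session
#'
#' Walks the plan's segments in order. Each segment's fat-oxidation rate
#' follows the subject's truth curve at the segment intensity; V'O2 and
#' V'CO2 are then solved from the two-equation system requiring (a) that
#' fat stoichiometry, and (b) that the substrate-sum energy rate equal the
#' plan's predicted segment energy rate — the sessions were equated by
#' design, so the simulated subject expends energy at the planned rate.
#' Protein oxidation follows the 12%-of-session-EE convention, matching
#' the analysis default.
#'
#' @param subject a simulated [subject()].
#' @param plan a `session_plan` from [design_comb_session()] /
#'   [design_mict_session()].
#' @param noise a [noise_model()].
#' @param dt sampling interval, s.
#' @return a [gas_series()] with `phase = "EXERCISE"`.
#' @export
simulate_submax_session <- function(subject, plan, noise = noise_model(),
                                    dt = 5) {
  if (is.null(subject$fatmax_true))
    stop_domain("subject lacks truth fields; use make_subject()")
  with_seed(noise$seed, {
    factors <- conversion_factors()
    curve <- fat_ox_curve(subject$fatmax_true, subject$mfo_true,
                          subject$crossover_true)
    seg <- plan$segments
    # energy-rate coefficients of EE = a*vo2 + b*vco2 + cc*pox
    a <- factors$kj_per_g_fat * .stoich$fat_o2 -
      factors$kj_per_g_cho * .stoich$cho_o2
    b <- factors$kj_per_g_cho * .stoich$cho_co2 -
      factors$kj_per_g_fat * .stoich$fat_co2
    cc <- factors$kj_per_g_protein -
      factors$kj_per_g_cho * .stoich$cho_pox -
      factors$kj_per_g_fat * .stoich$fat_pox
    seg_gas <- lapply(seq_len(nrow(seg)), function(i) {
      e_rate <- seg$ee_kj[i] / (seg$duration[i] / 60)
      pox <- protein_oxidation_rate(e_rate, factors)
      f <- curve(seg$intensity[i])
      D <- (f + .stoich$fat_pox * pox) / .stoich$fat_o2
      vo2 <- (e_rate + b * D - cc * pox) / (a + b)
      c(vo2 = vo2, vco2 = vo2 - D)
    })
    n_per <- round(seg$duration / dt)
    vo2_t <- rep(vapply(seg_gas, `[[`, numeric(1), "vo2"), n_per)
    vco2_t <- rep(vapply(seg_gas, `[[`, numeric(1), "vco2"), n_per)
    ee_rest <- subject$bmr * 1000 / 1440
    vo2_rest <- ee_rest / (.weir$kcal_to_kj * (.weir$o2 + .weir$co2 * 0.85))
    vo2_true <- onset_response(vo2_t, dt, noise$onset_tau, vo2_rest)
    vco2_true <- onset_response(vco2_t, dt, noise$onset_tau,
                                0.85 * vo2_rest)
    hr_rest <- if (is.finite(subject$hr_rest)) subject$hr_rest else 72
    hr_true <- hr_rest + (subject$hr_peak - hr_rest) *
      vo2_true / subject$vo2peak_true
    n <- length(vo2_true)
    t <- seq(0, by = dt, length.out = n)
    vo2 <- vo2_true; vco2 <- vco2_true; hr <- hr_true
    if (noise$gas_cv > 0) {
      vo2 <- pmax(vo2 * (1 + rnorm(n, 0, noise$gas_cv)), 0)
      vco2 <- pmax(vco2 * (1 + rnorm(n, 0, noise$gas_cv)), 0)
    }
    if (noise$hr_sd > 0) hr <- hr + rnorm(n, 0, noise$hr_sd)
    gas_series(t, vo2, vco2, hr = pmin(pmax(hr, 30), 230),
               dt_nominal = dt, phase = "EXERCISE", exercise_start = 0)
  })
}

# Per-group pre-post change distributions (mean, SD); an NA SD means the
# change SD is derived from the W0/W3 marginal SDs and the within-subject
# correlation rho: sd_d = sqrt(s0^2 + s3^2 - 2 rho s0 s3).
.cohort_deltas <- list(
  COMB = list(bm = c(-5.0, 1.2), ffm = c(-0.7, NA), bmr = c(-0.24, NA),
              vo2peak = c(0.28, 0.22), hrpeak = c(0.0, NA),
              o2pulse = c(1.62, 1.53), mfo = c(0.04, 0.03)),
  MICT = list(bm = c(-8.4, 1.5), ffm = c(-4.2, NA), bmr = c(-0.53, NA),
              vo2peak = c(0.02, NA), hrpeak = c(1.7, NA),
              o2pulse = c(0.0, NA), mfo = c(0.0, NA)))

#' Simulate a two-group pre/post trial cohort
#'
#' Draws W0 values from the group presets and adds per-subject pre-post
#' changes; where a change SD is published it is used directly, otherwise
#' it is derived from the W0/W3 marginal SDs under a within-subject
#' correlation `rho`. Fat mass and BMI are derived per subject from body
#' mass, fat-free mass and stature, so the identity FM = BM - FFM holds in
#' every row.
#'
#' @param n_comb,n_mict subjects per group (the trial's own sizes are 10
#'   and 11); at least 2 each.
#' @param rho within-subject W0-W3 correlation used when a change SD must
#'   be derived (default 0.8).
#' @param seed integer seed or `NULL`.
#' @param with_series also simulate and attach the raw per-subject series
#'   (canopy BMR recording and graded test per timepoint); off by default.
#' @param noise a [noise_model()], used only when `with_series = TRUE`.
#' @return a [trial_table()] with outcomes BM, BMI, FFM, FM, FM_pct, BMR,
#'   VO2peak, HRpeak, O2pulse, MFO. When `with_series = TRUE` the table
#'   carries a `series` attribute (nested list by subject and timepoint).
#' @export
simulate_cohort <- function(n_comb = 10, n_mict = 11, rho = 0.8,
                            seed = NULL, with_series = FALSE,
                            noise = noise_model()) {
  if (n_comb < 2 || n_mict < 2) stop_domain("need at least 2 per group")
  with_seed(seed, {
    draw_group <- function(grp, n) {
      p0 <- group_preset(paste0(grp, "_W0"))
      p3 <- group_preset(paste0(grp, "_W3"))
      dl <- .cohort_deltas[[grp]]
      delta_sd <- function(nm) {
        if (!is.na(dl[[nm]][2L])) return(dl[[nm]][2L])
        s0 <- p0[[nm]][2L]; s3 <- p3[[nm]][2L]
        sqrt(max(s0^2 + s3^2 - 2 * rho * s0 * s3, 0))
      }
      stature <- rtnorm(n, p0$stature[1L], p0$stature[2L], 1.2, 2.2)
      age0 <- rtnorm(n, p0$age[1L], p0$age[2L], 10, 22)
      w0 <- list(bm = rtnorm(n, p0$bm[1L], p0$bm[2L], 50, 250),
                 ffm = rtnorm(n, p0$ffm[1L], p0$ffm[2L], 30, 120),
                 bmr = rtnorm(n, p0$bmr[1L], p0$bmr[2L], 3, 15),
                 vo2peak = rtnorm(n, p0$vo2peak[1L], p0$vo2peak[2L], 1, 6),
                 hrpeak = rtnorm(n, p0$hrpeak[1L], p0$hrpeak[2L], 150, 215),
                 o2pulse = rtnorm(n, p0$o2pulse[1L], p0$o2pulse[2L], 5, 35),
                 mfo = rtnorm(n, p0$mfo[1L], p0$mfo[2L], 0.05, 1.2))
      w0$ffm <- pmin(w0$ffm, 0.95 * w0$bm)
      w3 <- lapply(names(dl), function(nm)
        w0[[nm]] + rnorm(n, dl[[nm]][1L], delta_sd(nm)))
      names(w3) <- names(dl)
      w3$ffm <- pmin(w3$ffm, 0.95 * w3$bm)
      ids <- sprintf("%s%02d", grp, seq_len(n))
      one_tp <- function(vals, tp, age) {
        fm <- fat_mass(vals$bm, vals$ffm)
        data.frame(subject_id = ids, group = grp, timepoint = tp,
                   BM = vals$bm, BMI = bmi(vals$bm, stature),
                   FFM = vals$ffm, FM = fm$fm_kg, FM_pct = fm$fm_pct,
                   BMR = vals$bmr, VO2peak = vals$vo2peak,
                   HRpeak = vals$hrpeak, O2pulse = vals$o2pulse,
                   MFO = vals$mfo, stringsAsFactors = FALSE)
      }
      rbind(one_tp(w0, "W0", age0), one_tp(w3, "W3", age0 + 0.1))
    }
    data <- rbind(draw_group("COMB", n_comb), draw_group("MICT", n_mict))
    units <- c(BM = "kg", BMI = "kg/m2", FFM = "kg", FM = "kg",
               FM_pct = "%", BMR = "MJ/day", VO2peak = "L/min",
               HRpeak = "bpm", O2pulse = "mL/beat", MFO = "g/min")
    tab <- trial_table(data, units)
    if (with_series) {
      attr(tab, "series") <- make_cohort_series(tab, noise)
    }
    tab
  })
}

# Build raw recordings (BMR canopy + graded test) for every row of a
# simulated cohort table, reusing the tabulated values as subject truths.
make_cohort_series <- function(tab, noise) {
  out <- list()
  for (i in seq_len(nrow(tab))) {
    row <- tab[i, ]
    p <- group_preset(paste0(row$group, "_", row$timepoint))
    s <- subject(row$subject_id, row$group, age = 16,
                 stature = sqrt(row$BM / row$BMI), body_mass = row$BM,
                 ffm = row$FFM, bmr = row$BMR, hr_peak = row$HRpeak,
                 hr_rest = 72)
    s$vo2peak_true <- row$VO2peak
    s$mfo_true <- row$MFO
    s$fatmax_true <- p$fatmax[1L]
    s$crossover_true <- p$crossover[1L]
    out[[row$subject_id]][[row$timepoint]] <-
      list(bmr = simulate_bmr_recording(s, noise),
           graded = simulate_graded_test(s, noise))
  }
  out
}
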