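test_that("the default graded protocol is the 7-stage walking ladder", {
  p <- default_grad_protocol()
  expect_length(p$stages, 7L)
  expect_equal(p$stages[[4]]$speed, 1.3)
  expect_equal(p$stages[[4]]$incline, 3)
  expect_equal(sum(vapply(p$stages, `[[`, numeric(1), "duration")), 2100)
  expect_equal(p$rest_duration, 600)
  expect_equal(p$hr_stop, 180)
})

test_that("a protocol round-trips through YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  p <- default_grad_protocol()
  yaml::write_yaml(list(rest_duration = 600, hr_stop = 180,
                        stages = lapply(p$stages, unclass)), path)
  q <- read_protocol(path)
  expect_equal(unclass(q)[c("rest_duration", "hr_stop")],
               list(rest_duration = 600, hr_stop = 180))
  expect_equal(lapply(q$stages, unclass), lapply(p$stages, unclass))
})

test_that("V'O2peak is the mean of the final 20 s, rest-invariant", {
  s <- constant_series(2.52, 2.3, minutes = 5, hr = 176)
  pk <- detect_vo2peak(s)
  expect_equal(pk$vo2peak, 2.52)
  expect_equal(pk$hrpeak, 176)
  # 1-Hz ramp ending at 3.0 with slope 0.01: last 20 samples average 2.905
  t <- 0:299
  ramp <- gas_series(t, 3.0 - 0.01 * (299 - t), rep(2.5, 300),
                     dt_nominal = 1)
  expect_equal(detect_vo2peak(ramp)$vo2peak, 2.905)
  # prepending rest must not change the value
  t2 <- seq(-600, 299)
  ramp2 <- gas_series(t2 + 600, c(rep(0.3, 600), 3.0 - 0.01 * (299 - t[t >= 0])),
                      rep(2.5, 900), dt_nominal = 1, phase = "MIXED",
                      exercise_start = 600)
  expect_equal(detect_vo2peak(ramp2)$vo2peak, 2.905)
  expect_error(detect_vo2peak(constant_series(2, 1.8, minutes = 0.25, dt = 5),
                              window = 20), "window")
})

test_that("O2 pulse reports V'O2 per beat to 0.1 mL", {
  expect_equal(o2_pulse(2.52, 176), 14.3)
  expect_equal(o2_pulse(3.60, 176.1), 20.4)
  expect_equal(o2_pulse(1.76, 176), 10.0)
  expect_error(o2_pulse(2.52, 0), "hrpeak")
})

test_that("stage measurements average the final minute of completed stages", {
  proto <- default_grad_protocol()
  dt <- 5
  # noiseless plateaus: stage j has vo2 = 1 + 0.2 j
  t <- seq(0, 600 + 2100 - dt, by = dt)
  stage_of <- pmax(findInterval(t - 600, seq(0, 2100, by = 300)), 0)
  vo2 <- ifelse(t < 600, 0.3, 1 + 0.2 * stage_of)
  s <- gas_series(t, vo2, 0.85 * vo2, hr = 100 + 10 * stage_of,
                  dt_nominal = dt, phase = "MIXED", exercise_start = 600)
  st <- stage_measurements(s, proto, pox = 0, vo2peak = 2.4)
  expect_equal(nrow(st), 7L)
  expect_equal(st$vo2, 1 + 0.2 * (1:7))
  expect_equal(st$intensity[1], 100 * 1.2 / 2.4)  # plateau 1.2 at peak 2.4
  # truncate after 5 stages: only 5 measurements
  s5 <- s[s$t < 600 + 5 * 300, ]
  attr(s5, "dt_nominal") <- dt; attr(s5, "phase") <- "MIXED"
  attr(s5, "exercise_start") <- 600; class(s5) <- class(s)
  expect_equal(nrow(stage_measurements(s5, proto, 0, 2.4)), 5L)
})

test_that("MFO detection: stage max, ties, and cubic-fit vertex", {
  st <- data.frame(intensity = c(35, 50, 60, 75),
                   fat = c(0.20, 0.32, 0.28, 0.10))
  m <- find_mfo(st, "stage_max")
  expect_equal(m$mfo, 0.32)
  expect_equal(m$fatmax, 50)
  dec <- data.frame(intensity = c(35, 50, 65), fat = c(0.4, 0.3, 0.2))
  expect_equal(find_mfo(dec, "stage_max")$fatmax, 35)
  # symmetric parabola peaking at 55 with value 0.35
  x <- c(35, 45, 55, 65, 75)
  par3 <- data.frame(intensity = x, fat = 0.35 - 2e-4 * (x - 55)^2)
  p <- find_mfo(par3, "poly3")
  expect_equal(p$fatmax, 55, tolerance = 1e-6)
  expect_equal(p$mfo, 0.35, tolerance = 1e-6)
  zero <- data.frame(intensity = x, fat = rep(0, 5))
  z <- find_mfo(zero)
  expect_equal(z$mfo, 0)
  expect_false(z$defined)
  expect_error(find_mfo(st[1:2, ]), "3 stages")
})

test_that("crossover interpolates the first drop through the threshold", {
  st <- data.frame(intensity = c(50, 66, 80), fat = c(0.32, 0.10, 0.00))
  cr <- crossover_intensity(st, threshold = 0.05)
  expect_equal(cr$crossover, 73)
  expect_true(cr$crossed)
  high <- data.frame(intensity = c(40, 60, 80), fat = c(0.2, 0.3, 0.25))
  h <- crossover_intensity(high)
  expect_false(h$crossed)
  expect_equal(h$crossover, 80)
  exact <- data.frame(intensity = c(50, 70, 85), fat = c(0.3, 0.05, 0.0))
  expect_equal(crossover_intensity(exact)$crossover, 70)
})

test_that("crossover is never below Fatmax on simulated tests", {
  for (seed in 1:5) {
    s <- make_subject(group_preset("COMB_W0"), seed = seed)
    g <- analyze_graded(simulate_graded_test(s, noise_model(seed = seed)),
                        subject = s)
    if (g$mfo_defined && g$crossed) expect_gte(g$crossover, g$fatmax)
  }
})
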