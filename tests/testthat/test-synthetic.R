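test_that("subject draws are seed-reproducible and preset-faithful", {
  p <- group_preset("COMB_W0")
  s1 <- make_subject(p, seed = 7)
  s2 <- make_subject(p, seed = 7)
  expect_identical(unclass(s1), unclass(s2))
  z <- make_subject(zero_sd_preset(p), seed = 1)
  expect_equal(z$body_mass, 117.7)
  expect_equal(z$ffm, 65.4)
  expect_equal(z$bmr, 7.44)
  expect_equal(z$vo2peak_true, 2.52)
  expect_equal(z$fatmax_true, 50)
  set.seed(41)
  bm <- replicate(2000, make_subject(p)$body_mass)
  expect_lt(abs(mean(bm) - 117.7), 2 * 19.8 / sqrt(2000))
  expect_error(group_preset("NOPE"), "unknown preset 'NOPE'")
})

test_that("the fat-oxidation truth curve hits its three landmarks", {
  f <- fat_ox_curve(fatmax = 50, mfo = 0.32, crossover = 74)
  expect_equal(f(50), 0.32)
  expect_equal(f(74), 0.05, tolerance = 1e-8)
  expect_lt(f(49), 0.32); expect_lt(f(51), 0.32)  # true peak
  expect_equal(f(0), 0)
  expect_equal(f(150), 0)
  expect_error(fat_ox_curve(50, 0.32, 45), "crossover")
})

test_that("canopy recordings invert to the subject's BMR after discard", {
  s <- make_subject(zero_sd_preset(group_preset("COMB_W0")), seed = 1)
  rec <- simulate_bmr_recording(s, noiseless())
  res <- suppressMessages(analyze_bmr(rec, discard_s = 600))
  expect_equal(res$bmr_mj_day, s$bmr, tolerance = 1e-6)
  # keeping the adaptation transient biases the estimate high
  res0 <- analyze_bmr(rec, discard_s = 0)
  expect_gt(res0$bmr_mj_day, s$bmr)
  # reproducibility under a fixed noise seed
  r1 <- simulate_bmr_recording(s, noise_model(seed = 9))
  r2 <- simulate_bmr_recording(s, noise_model(seed = 9))
  expect_identical(r1$vo2, r2$vo2)
})

test_that("noiseless graded tests recover the latent truths", {
  for (preset in c("COMB_W0", "MICT_W0")) {
    s <- make_subject(zero_sd_preset(group_preset(preset)), seed = 1)
    rec <- simulate_graded_test(s, noiseless())
    g <- analyze_graded(rec, subject = s)
    expect_equal(g$vo2peak, s$vo2peak_true, tolerance = 1e-3)
    expect_equal(g$hrpeak, s$hr_peak, tolerance = 0.1)
    # stage grid resolution bounds the stage-max estimates
    grid_step <- 65 / 6
    expect_lt(abs(g$fatmax - s$fatmax_true), grid_step + 1e-9)
    expect_lt(abs(g$mfo - s$mfo_true), 0.02)
    expect_gte(g$crossover, g$fatmax)
  }
})

test_that("the stop criterion truncates the test when HR hits the limit", {
  s <- make_subject(zero_sd_preset(group_preset("COMB_W0")), seed = 1)
  s$hr_peak <- 195  # crosses 180 before the final stage
  rec <- simulate_graded_test(s, noiseless())
  full_len <- 600 + 2100
  expect_lt(max(rec$t), full_len - 5)
  g <- analyze_graded(rec, subject = s)
  expect_lt(nrow(g$stages), 7)
})

test_that("generated gas exchange respects the RER ceiling", {
  for (seed in 1:4) {
    s <- make_subject(group_preset("MICT_W0"), seed = seed)
    rec <- simulate_graded_test(s, noiseless())
    expect_true(all(rec$vco2 <= 1.1 * rec$vo2 + 1e-12))
  }
})

test_that("simulated sessions expend the planned energy", {
  s <- make_subject(zero_sd_preset(group_preset("MICT_W0")), seed = 1)
  g <- analyze_graded(simulate_graded_test(s, noiseless()), subject = s)
  plan <- design_mict_session(g, s$ffm)
  sess <- simulate_submax_session(s, plan, noiseless())
  summ <- summarize_session(sess, subject = s)
  expect_equal(summ$total_ee, plan$energy_target, tolerance = 0.02)
  expect_equal(summ$duration_min, plan$duration_min, tolerance = 0.1)
  # determinism
  a <- simulate_submax_session(s, plan, noise_model(seed = 5))
  b <- simulate_submax_session(s, plan, noise_model(seed = 5))
  expect_identical(a$vo2, b$vo2)
})

test_that("session substrate grams land in the published 2-SD bands", {
  # noiseless designs at the preset means against the energy-partition cells
  for (preset in c("MICT_W0", "COMB_W0")) {
    p <- group_preset(preset)
    s <- make_subject(zero_sd_preset(p), seed = 2)
    g <- analyze_graded(simulate_graded_test(s, noiseless()), subject = s)
    plan <- if (p$group == "MICT") design_mict_session(g, s$ffm)
            else design_comb_session(g, s$ffm)
    summ <- summarize_session(simulate_submax_session(s, plan, noiseless()),
                              subject = s)
    gms <- summ$grams_by_substrate
    for (nm in c("cho", "fat", "protein")) {
      cell <- p$session[[paste0(nm, "_g")]]
      expect_lt(abs(gms[[nm]] - cell[1]), 2 * cell[2] + 1e-9)
    }
  }
})

test_that("cohort simulation reproduces the published change means", {
  tab <- simulate_cohort(400, 400, seed = 43)
  dv <- function(grp) {
    w0 <- tab[tab$timepoint == "W0" & tab$group == grp, ]
    w3 <- tab[tab$timepoint == "W3" & tab$group == grp, ]
    w3$VO2peak[match(w0$subject_id, w3$subject_id)] - w0$VO2peak
  }
  d <- dv("COMB")
  expect_lt(abs(mean(d) - 0.28), 2 * 0.22 / sqrt(400))
  # identities hold row-wise
  expect_equal(tab$FM, tab$BM - tab$FFM)
  expect_equal(tab$FM_pct, 100 * tab$FM / tab$BM)
  expect_setequal(names(attr(tab, "units")), trial_outcomes(tab))
  expect_identical(as.data.frame(simulate_cohort(5, 5, seed = 2)),
                   as.data.frame(simulate_cohort(5, 5, seed = 2)))
})

test_that("the trial's own sample size detects the V'O2peak interaction in most seeds", {
  hits <- vapply(1:20, function(seed) {
    tab <- simulate_cohort(10, 11, seed = seed)
    a <- mixed_anova_2x2(tab, "VO2peak")
    a$effects$p[a$effects$effect == "GxT"] < 0.05
  }, logical(1))
  expect_gt(mean(hits), 0.5)
})

test_that("null cohort deltas give no systematic interaction", {
  # zero-delta construction: compare W0 draws against themselves plus noise
  set.seed(44)
  p <- replicate(60, {
    tab <- random_trial_table(10, 11)
    a <- mixed_anova_2x2(tab, "y")
    a$effects$p[a$effects$effect == "GxT"]
  })
  expect_lt(mean(p < 0.05), 0.2)
})

test_that("cohorts can carry raw per-subject recordings", {
  tab <- simulate_cohort(2, 2, seed = 45, with_series = TRUE)
  ser <- attr(tab, "series")
  expect_length(ser, 4L)
  first <- ser[[1]]$W0
  expect_s3_class(first$bmr, "gas_series")
  expect_s3_class(first$graded, "gas_series")
})
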