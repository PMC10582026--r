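test_that("HR at intensity interpolates stage pairs and clamps at the peak", {
  r <- fake_graded_result(intensity = c(50, 75), hr = c(120, 150),
                          vo2peak = 2.52, hrpeak = 176, rest_hr = 72)
  expect_equal(hr_for_intensity(r, 60), 132)
  expect_equal(hr_for_intensity(r, 50), 120)   # knot identity
  # extrapolation from the top two stages: 150 + 1.2 * 25 = 180 -> clamp 176
  expect_equal(hr_for_intensity(r, 100), 176)
  expect_error(hr_for_intensity(r, 20), "range")
  # monotone nondecreasing in pct
  pct <- seq(41, 100, by = 1)
  hrs <- vapply(pct, function(p) hr_for_intensity(r, p), numeric(1))
  expect_true(all(diff(hrs) >= 0))
})

test_that("V'O2 at intensity is the simple fraction of peak", {
  r <- fake_graded_result(c(50, 75), c(120, 150), vo2peak = 3.60)
  expect_equal(vo2_at_intensity(r, 40), 1.44)
  r2 <- fake_graded_result(c(50, 75), c(120, 150), vo2peak = 2.52)
  expect_equal(vo2_at_intensity(r2, 100), 2.52)
  expect_equal(vo2_at_intensity(r2, 60), 1.512)
  expect_error(vo2_at_intensity(r2, 0), "intensity")
})

test_that("the session energy budget is 20 kJ per kg FFM", {
  expect_equal(session_energy_target(69.2), 1384)
  expect_equal(session_energy_target(65.4), 1308)
  expect_equal(session_energy_target(50), 1000)
  expect_error(session_energy_target(0), "ffm")
})

test_that("segment energy prediction uses the O2 energy equivalent", {
  r <- fake_graded_result(c(50, 75), c(120, 150), vo2peak = 2.52)
  expect_equal(predicted_segment_ee(60, 1800, r), 1.512 * 30 * 20.9)
  expect_equal(predicted_segment_ee(60, 0, r), 0)
  r3 <- fake_graded_result(c(50, 75), c(120, 150), vo2peak = 3.0)
  expect_equal(predicted_segment_ee(100, 60, r3), 62.7)
})

test_that("the combined session solves the continuous block to the budget", {
  r <- fake_graded_result(c(50, 75), c(120, 150), vo2peak = 2.52,
                          hrpeak = 176, rest_hr = 72)
  plan <- design_comb_session(r, ffm = 65.4)
  # independent oracle: root-find total predicted energy in the MICT minutes
  fixed_ee <- sum(predicted_segment_ee(c(50, 95, 50, 95, 50, 95),
                                       c(300, 120, 60, 120, 60, 120), r))
  oracle <- uniroot(function(m)
    fixed_ee + predicted_segment_ee(60, m * 60, r) - 1308,
    c(0.1, 200), tol = 1e-10)$root
  mict <- plan$segments[plan$segments$label == "MICT", ]
  expect_equal(mict$duration / 60, oracle, tolerance = 1e-8)
  expect_equal(plan$predicted_energy, plan$energy_target, tolerance = 0.01)
  expect_equal(plan$hiit_fraction, 360 / sum(plan$segments$duration))
  # larger FFM -> longer session, monotonically
  d1 <- design_comb_session(r, 65.4)$duration_min
  d2 <- design_comb_session(r, 130.8)$duration_min
  expect_gt(d2, d1)
  expect_error(design_comb_session(r, ffm = 5), "infeasible")
})

test_that("the continuous session duration is budget over energy rate", {
  r_mict <- fake_graded_result(c(50, 75), c(110, 140), vo2peak = 3.60,
                               hrpeak = 176.1, rest_hr = 72)
  p40 <- design_mict_session(r_mict, ffm = 69.2, intensity = 40)
  expect_equal(p40$duration_min, 1384 / (1.44 * 20.9))
  expect_equal(round(p40$duration_min), 46)
  p80 <- design_mict_session(r_mict, ffm = 69.2, intensity = 80)
  expect_equal(p80$duration_min, p40$duration_min / 2)
  r_comb <- fake_graded_result(c(50, 75), c(120, 150), vo2peak = 2.52,
                               hrpeak = 176, rest_hr = 72)
  expect_equal(round(design_mict_session(r_comb, 65.4)$duration_min), 62)
  expect_error(design_mict_session(r_mict, 69.2, intensity = 0), "intensity")
})

test_that("both session types are equated to the same energy", {
  for (seed in 1:6) {
    preset <- group_preset(if (seed %% 2) "COMB_W0" else "MICT_W0")
    s <- make_subject(preset, seed = seed)
    g <- analyze_graded(simulate_graded_test(s, noiseless(seed)),
                        subject = s)
    comb <- design_comb_session(g, s$ffm)
    mict <- design_mict_session(g, s$ffm)
    expect_equal(comb$predicted_energy, comb$energy_target,
                 tolerance = 0.01)
    expect_equal(mict$predicted_energy, comb$predicted_energy,
                 tolerance = 0.01)
  }
})

test_that("COMB sessions keep the high-intensity share near the 80/20 split", {
  # exact at the group design points; bracketing band for individual draws
  for (preset in c("COMB_W0", "COMB_W3")) {
    s0 <- make_subject(zero_sd_preset(group_preset(preset)), seed = 1)
    g0 <- analyze_graded(simulate_graded_test(s0, noiseless()),
                         subject = s0)
    h0 <- design_comb_session(g0, s0$ffm)$hiit_fraction
    expect_gte(h0, 0.10); expect_lte(h0, 0.20)
  }
  for (seed in 1:6) {
    s <- make_subject(group_preset("COMB_W0"), seed = seed)
    g <- analyze_graded(simulate_graded_test(s, noiseless(seed)),
                        subject = s)
    h <- design_comb_session(g, s$ffm)$hiit_fraction
    expect_gte(h, 0.08); expect_lte(h, 0.22)
  }
})
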