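test_that("profile anthropometrics: BMI classes and IBW tidal volume", {
  p1 <- patient_profile(1.78, 84.1)
  expect_equal(p1$BMI, 26.6, tolerance = 0.01)
  expect_equal(p1$bmi_class, "overweight")
  expect_equal(p1$V_End, 2.6)
  p2 <- patient_profile(1.85, 105.7)
  expect_equal(p2$BMI, 30.9, tolerance = 0.01)
  expect_equal(p2$bmi_class, "obese")
  expect_equal(p2$V_End, 2.1)
  # Devine: 50 + 2.3 per inch over 60
  expect_equal(p1$IBW, 50 + 2.3 * (1.78 / 0.0254 - 60))
  expect_equal(p1$V_T, 7 * p1$IBW / 1000)
})

test_that("pressure normalization removes drift and preserves oscillation", {
  fs <- 25
  t <- seq(0, 300, by = 1 / fs)
  rec_const <- nasal_record(t, rep(3, length(t)))
  expect_true(all(abs(normalize_pressure(rec_const, 70)) < 1e-12))
  osc <- sin(2 * pi * t / 5)                 # 5-s breaths << 70-s window
  drift <- 0.01 * t
  rec <- nasal_record(t, osc + drift)
  out <- normalize_pressure(rec, 70)
  mid <- t > 50 & t < 250                    # away from edges
  expect_lt(max(abs(out[mid] - osc[mid])), 0.01 * max(osc))
  expect_lt(abs(mean(out[mid])), 0.01)
  expect_error(normalize_pressure(rec, 1000), "window")
})

test_that("conductance is recovered from synthetic records within 5%", {
  prof <- patient_profile(1.78, 84.1)
  spec <- breathing_spec(V_T = prof$V_T, V_D = prof$V_D, V_End = prof$V_End,
                         b_r = 14, total_duration = 300,
                         stabilization_time = 0)
  g <- 0.04
  rec <- synthetic_nasal_record(spec, conductance = g, fs = 25,
                                noise_sd = 0.02, drift_amplitude = 0.3,
                                seed = 11)
  fit <- fit_nasal_conductance(rec, prof, normal_segment = c(60, 180))
  expect_equal(fit$conductance, g, tolerance = 0.05)
  expect_equal(fit$b_r, 14, tolerance = 0.03)
  # scale equivariance: doubling all pressures halves the conductance
  rec2 <- rec
  rec2$pressure <- 2 * rec$pressure
  fit2 <- fit_nasal_conductance(rec2, prof, normal_segment = c(60, 180))
  expect_equal(fit2$conductance, fit$conductance / 2, tolerance = 1e-6)
  expect_error(fit_nasal_conductance(rec, prof, normal_segment = c(60, 66)),
               "3 full breaths")
})

test_that("lung volume round-trips through the pressure pipeline", {
  prof <- patient_profile(1.78, 84.1)
  # event onsets and durations aligned with end-expiration (5-s cycles)
  ev <- rbind(resp_event("apnea", 120, 20), resp_event("hypopnea", 200, 20))
  spec <- breathing_spec(V_T = prof$V_T, V_D = prof$V_D, V_End = prof$V_End,
                         b_r = 12, events = ev, total_duration = 300,
                         stabilization_time = 0)
  g <- 0.05
  rec <- synthetic_nasal_record(spec, conductance = g, fs = 25,
                                noise_sd = 0.02, drift_amplitude = 0.3,
                                seed = 5)
  fit <- fit_nasal_conductance(rec, prof, normal_segment = c(20, 110))
  pat <- pressure_to_lung_volume(rec, fit, stabilization_time = 0)
  truth <- breathing_pattern(spec, dt = 1 / 25)
  # source lung volume recovered within 3% RMS at default noise
  rms <- sqrt(mean((pat$V_A - truth$V_A)^2))
  expect_lt(rms / mean(truth$V_A), 0.03)
  # apnea epoch: volume nearly flat
  apnea_idx <- pat$times >= 122 & pat$times <= 138
  expect_lt(diff(range(pat$V_A[apnea_idx])), 0.15)
  # annotations survive the pipeline
  expect_equal(pat$events$kind, ev$kind)
  expect_equal(pat$events$start, ev$start)
})

test_that("zero pressure maps to constant volume at V_End", {
  prof <- patient_profile(1.78, 84.1)
  prof$conductance <- 0.05
  prof$b_r <- 12
  t <- seq(0, 200, by = 0.04)
  rec <- nasal_record(t, rep(0, length(t)))
  pat <- pressure_to_lung_volume(rec, prof, stabilization_time = 0)
  expect_true(all(abs(pat$V_A - prof$V_End) < 1e-12))
})

test_that("synthetic generator is seed-reproducible and self-consistent", {
  spec <- breathing_spec(total_duration = 100, stabilization_time = 0,
                         events = resp_event("apnea", 40, 15))
  r1 <- synthetic_nasal_record(spec, seed = 3)
  r2 <- synthetic_nasal_record(spec, seed = 3)
  expect_identical(r1$pressure, r2$pressure)
  r3 <- synthetic_nasal_record(spec, seed = 4)
  expect_false(identical(r3$pressure, r1$pressure))
  # noise 0, drift 0: pressure exactly proportional to dV_A/dt
  r0 <- synthetic_nasal_record(spec, conductance = 0.05, noise_sd = 0,
                               drift_amplitude = 0, seed = 1)
  pat <- breathing_pattern(spec, dt = 1 / 25)
  expect_equal(r0$pressure, pat$dV_A_dt / 0.05, tolerance = 1e-12)
  # annotated apnea aligns with the zero-flow epoch
  idx <- r0$times > 41 & r0$times < 54
  expect_true(all(abs(r0$pressure[idx]) < 1e-12))
})
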