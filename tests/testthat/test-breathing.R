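test_that("normal pattern reproduces the sinusoid anchors", {
  spec <- breathing_spec(V_T = 0.5, V_D = 0.15, V_End = 2.3, b_r = 12,
                         total_duration = 60, stabilization_time = 0)
  pat <- breathing_pattern(spec, dt = 0.005)
  expect_equal(pat$V_A[1], 2.3)                       # sin(-pi/2) = -1
  expect_equal(min(pat$V_A), 2.3, tolerance = 1e-6)
  expect_equal(max(pat$V_A), 2.65, tolerance = 1e-6)  # V_End + V_vent
  expect_equal(max(pat$V_A) - min(pat$V_A), 0.35, tolerance = 1e-6)
  # 12 cycles per minute: peaks 5 s apart
  peaks <- pat$times[which(diff(sign(pat$dV_A_dt)) < 0)]
  expect_equal(diff(peaks), rep(5, length(peaks) - 1), tolerance = 0.01)
  # derivative consistent with finite differencing
  num <- diff(pat$V_A) / 0.005
  expect_lt(max(abs(num - pat$dV_A_dt[-length(num) - 1])), 0.01)
})

test_that("spec validation enforces the volume ordering and event bounds", {
  expect_error(breathing_spec(V_T = 0.1, V_D = 0.15), "exceed")
  expect_error(
    breathing_spec(events = resp_event("apnea", 590, 20),
                   total_duration = 600), "inside")
  expect_error(
    breathing_spec(events = rbind(resp_event("apnea", 10, 20),
                                  resp_event("apnea", 25, 20)),
                   total_duration = 600), "overlap")
  expect_error(resp_event("apnea", 0, -5), "positive")
  expect_error(resp_event("apnea", 0, 10, airflow_fraction = 1.5), "0, 1")
})

test_that("events shape the trace: flat apneas, scaled hypopneas, overrides", {
  ev <- rbind(resp_event("apnea", 10, 10),
              resp_event("hypopnea", 30, 10, airflow_fraction = 0.5),
              resp_event("hyperventilation", 50, 10, V_T = 1.0, b_r = 24))
  spec <- breathing_spec(events = ev, total_duration = 70,
                         stabilization_time = 0)
  pat <- breathing_pattern(spec, dt = 0.005)
  t <- pat$times
  # apnea: flat at V_End
  expect_true(all(abs(pat$V_A[t > 10 & t < 20] - 2.3) < 1e-12))
  # hypopnea: half amplitude
  hyp <- pat$V_A[t >= 30 & t <= 40]
  expect_equal(max(hyp) - min(hyp), 0.5 * 0.35, tolerance = 1e-6)
  # hyperventilation: amplitude from V_T = 1.0, doubled rate
  hv <- pat$V_A[t >= 50 & t <= 60]
  expect_equal(max(hv) - min(hv), 1.0 - 0.15, tolerance = 1e-6)
  # continuity across every boundary
  expect_lt(max(abs(diff(pat$V_A))),
            max(abs(pat$dV_A_dt)) * 0.005 * (1 + 1e-6))
})

test_that("empty event list reproduces the normal pattern exactly", {
  spec0 <- breathing_spec(total_duration = 30, stabilization_time = 0)
  ev <- resp_event("wake", 5, 10)   # non-respiratory annotation only
  spec1 <- breathing_spec(events = ev, total_duration = 30,
                          stabilization_time = 0)
  expect_identical(breathing_pattern(spec0, dt = 0.01)$V_A,
                   breathing_pattern(spec1, dt = 0.01)$V_A)
})

test_that("misaligned event boundaries are reported", {
  # apnea starting mid-inspiration forces a jump to V_End
  spec <- breathing_spec(events = resp_event("apnea", 7.5, 10),
                         total_duration = 30, stabilization_time = 0)
  expect_warning(breathing_pattern(spec, dt = 0.005), "align")
})

test_that("AHI arithmetic matches the worked examples", {
  ev4 <- do.call(rbind, lapply(c(0, 150, 300, 450),
                               function(s) resp_event("apnea", s, 20)))
  expect_equal(compute_ahi(ev4, 600), 24)
  ev8 <- do.call(rbind, lapply(seq(0, 490, by = 70),
                               function(s) resp_event("apnea", s, 15)))
  expect_equal(compute_ahi(ev8, 600), 48)
  # sub-threshold events are not scored with the duration filter on
  ev10 <- rbind(ev4, do.call(rbind, lapply(seq(20, 120, by = 20),
                                           function(s) resp_event("apnea", s, 5))))
  expect_equal(compute_ahi(ev10, 600), 24)
  expect_equal(compute_ahi(ev10, 600, min_duration = 0), 60)
  expect_error(compute_ahi(ev4, 0), "positive")
})

test_that("AHI ignores ordering and non-respiratory annotations", {
  ev <- rbind(resp_event("apnea", 300, 20), resp_event("apnea", 0, 20),
              resp_event("wake", 100, 50), resp_event("RERA", 200, 15))
  expect_equal(compute_ahi(ev, 600), 12)
  expect_equal(compute_ahi(ev[sample(nrow(ev)), ], 600), 12)
})
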