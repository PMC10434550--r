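test_that("short normal run is finite, bounded and physiologically ordered", {
  sim <- quick_sim(total = 20, stab = 20)
  s <- sim$series
  expect_true(all(is.finite(as.matrix(s))))
  expect_true(all(s$S_sa >= 0 & s$S_sa <= 1))
  expect_true(all(s$S_sv >= 0 & s$S_sv <= 1))
  expect_true(all(s$S_sa > s$S_sv))            # arterial above venous
  expect_true(all(s$P_A > 0 & s$P_A < sim$params$P_I + 1))
  expect_true(all(s$C_sa_d > s$C_sv_d))
})

test_that("apnea produces delayed desaturation in arteries then veins", {
  sim <- quick_sim(total = 60, stab = 20,
                   events = resp_event("apnea", 10, 20))
  s <- sim$series
  base_S <- mean(s$S_sa[s$time < 20])
  # desaturation happens, with the arterial minimum before the venous one
  expect_lt(min(s$S_sa), base_S - 0.01)
  t_min_sa <- s$time[which.min(s$S_sa)]
  t_min_sv <- s$time[which.min(s$S_sv)]
  expect_gt(t_min_sa, 30)      # after apnea onset
  expect_gt(t_min_sv, t_min_sa)  # venous lags by the systemic transit
})

test_that("zero-amplitude breathing forever gives monotone decline", {
  spec <- breathing_spec(V_T = 0.150001, V_D = 0.15, total_duration = 30,
                         stabilization_time = 0)
  sim <- simulate_oxygen(breathing_pattern(spec, dt = 0.005), oxy_params())
  s <- sim$series
  late <- s$time > 2   # after the initial transient
  expect_true(all(diff(s$P_A[late]) < 1e-12))
  expect_true(all(diff(s$C_sa_d[late]) < 1e-9))
})

test_that("advection constraint is checked before the run", {
  spec <- breathing_spec(total_duration = 5, stabilization_time = 0)
  pat <- breathing_pattern(spec, dt = 0.05)
  expect_error(simulate_oxygen(pat, oxy_params()), "advection")
})

test_that("resampling onto a finer solver grid reproduces the coarse result", {
  spec <- breathing_spec(total_duration = 10, stabilization_time = 10)
  fine <- simulate_oxygen(breathing_pattern(spec, dt = 0.005), oxy_params())
  coarse_pat <- breathing_pattern(spec, dt = 0.02)
  resampled <- simulate_oxygen(coarse_pat, oxy_params(), dt = 0.005)
  i <- fine$series$time >= 10
  j <- resampled$series$time >= 10
  expect_equal(mean(fine$series$P_A[i]), mean(resampled$series$P_A[j]),
               tolerance = 1e-3)
})

test_that("metrics are zero on an undisturbed trace and react to events", {
  # stabilization must cover a few systemic transits before the reference
  # window so the cyclic steady state is reached
  sim0 <- quick_sim(total = 60, stab = 180)
  m0 <- oxygen_metrics(sim0)
  # steady cyclic breathing: minima reflect the breathing-cycle ripple only
  # (the arterial dissolved trace genuinely oscillates ~2% per breath)
  expect_true(all(m0$pct_decrease$pct_decrease < 3))
  expect_lt(m0$pct_decrease$pct_decrease[m0$pct_decrease$variable == "S_sa"],
            0.5)
  expect_lt(abs(m0$pct_reduction_mass_transfer), 0.5)
  expect_equal(nrow(m0$per_event), 0)

  sim1 <- quick_sim(total = 220, stab = 30,
                    events = resp_event("apnea", 10, 20))
  m1 <- oxygen_metrics(sim1)
  expect_gt(m1$pct_decrease$pct_decrease[m1$pct_decrease$variable == "S_sa"],
            1)
  expect_gt(m1$pct_reduction_mass_transfer, 0)
  expect_equal(nrow(m1$per_event), 1)
  expect_gt(m1$per_event$reox_time_s, 0)
  expect_error(oxygen_metrics(sim1, normal_window = c(5, 5)), "interval")
})

test_that("hypopnea scoring applies the 4% desaturation criterion", {
  # a mild hypopnea: candidate event that must not be scored
  sim <- quick_sim(total = 120, stab = 30,
                   events = resp_event("hypopnea", 10, 25,
                                       airflow_fraction = 0.5))
  ev <- score_events(sim)
  expect_equal(nrow(ev), 1)
  expect_false(ev$scored[1])
  expect_equal(ahi(sim), 0)
  # an apnea of the same duration is scored on duration alone
  sim2 <- quick_sim(total = 120, stab = 30,
                    events = resp_event("apnea", 10, 25))
  expect_true(score_events(sim2)$scored[1])
  expect_equal(ahi(sim2), 30)   # 1 event / 120 s
})

test_that("simulation outputs round-trip through the output bundle", {
  sim <- quick_sim(total = 10, stab = 5)
  d <- tempfile()
  write_sim_outputs(sim, d, seed = 7)
  expect_true(all(file.exists(file.path(d, c("timeseries.csv",
                                             "metrics.json",
                                             "manifest.json")))))
  ts <- utils::read.csv(file.path(d, "timeseries.csv"))
  expect_equal(nrow(ts), length(sim$times))
  expect_equal(ts$P_A_mmHg, sim$series$P_A)
  man <- jsonlite::read_json(file.path(d, "manifest.json"))
  expect_equal(man$seed, 7)
  unlink(d, recursive = TRUE)
})
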