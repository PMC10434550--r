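# Independent oracles used across the suite. These deliberately avoid the
# package's own numerical paths.

# plain bisection for the dissolved/total inversion (oracle for the
# production safeguarded-Newton solver)
bisect_dissolved <- function(C_T, C_Hb, beta_p, tol = 1e-14, maxit = 200) {
  vapply(C_T, function(target) {
    lo <- 0
    hi <- target
    f <- function(x) {
      P <- x / beta_p
      x + 4 * C_Hb * (P^3 + 150 * P) / ((P^3 + 150 * P) + 23400) - target
    }
    for (i in seq_len(maxit)) {
      mid <- (lo + hi) / 2
      if (f(mid) > 0) hi <- mid else lo <- mid
      if (hi - lo < tol) break
    }
    (lo + hi) / 2
  }, numeric(1))
}

# reference saturation evaluated the long way round
oracle_saturation <- function(P) 1 / (1 + 23400 / (P^3 + 150 * P))

# short normal-breathing simulation shared by a few tests
quick_sim <- function(total = 20, stab = 20, dt = 0.005, params = oxy_params(),
                      events = NULL, ...) {
  spec <- breathing_spec(events = events, total_duration = total,
                         stabilization_time = stab)
  simulate_oxygen(breathing_pattern(spec, dt = dt), params, ...)
}
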