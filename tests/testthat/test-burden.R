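test_that("wake baseline pools intervals correctly", {
  t <- seq(0, 100, by = 0.1)
  x <- rep(140, length(t))
  b <- wake_baseline(t, x, list(c(0, 10), c(50, 60)))
  expect_equal(b$mean, 140)
  expect_equal(b$sd, 0)
  # two equal-length intervals at constant values a and b average (a+b)/2
  x2 <- ifelse(t < 30, 100, 120)
  b2 <- wake_baseline(t, x2, list(c(0, 10), c(50, 60)))
  expect_equal(b2$mean, 110, tolerance = 1e-6)
  expect_error(wake_baseline(t, x, list()), "interval")
  expect_error(wake_baseline(t, x, list(c(200, 201))), "fewer than 2")
})

test_that("wake baseline of noisy synthetic wakefulness concentrates", {
  set.seed(123)
  n <- 1e4
  t <- seq_len(n)
  x <- rnorm(n, 140, 2)
  b <- wake_baseline(t, x, list(c(1, n)))
  expect_lt(abs(b$mean - 140), 0.1)
  expect_lt(abs(b$sd - 2), 0.1)
})

test_that("burden score: zero at baseline, depth for offsets, triangle law", {
  t <- seq(0, 500, by = 0.1)
  base <- wake_baseline(t, rep(140, length(t)), list(c(0, 500)))
  expect_equal(burden_score(t, rep(140, length(t)), base), 0)
  # constant deficit of 10 regardless of interval length
  expect_equal(burden_score(t, rep(130, length(t)), base), 10)
  expect_equal(burden_score(t[t <= 50], rep(130, sum(t <= 50)), base), 10)
  # triangular dip of depth d and width w in window T: score d w / (2 T)
  d <- 25; w <- 40; T_ <- 500
  dip <- pmax(0, 1 - abs(t - 250) / (w / 2)) * d
  expect_equal(burden_score(t, 140 - dip, base), d * w / (2 * T_),
               tolerance = 1e-3)
  # overshoot subtracts under the signed convention, not when clipped
  over <- 140 + dip
  expect_equal(burden_score(t, over, base), -d * w / (2 * T_),
               tolerance = 1e-3)
  expect_equal(burden_score(t, over, base, clip_deficit = TRUE), 0)
})

test_that("burden score properties: translation, scale, interval additivity", {
  set.seed(9)
  t <- seq(0, 200, by = 0.5)
  x <- 140 + cumsum(rnorm(length(t), 0, 0.3))
  base <- wake_baseline(t, x, list(c(0, 50)))
  s0 <- burden_score(t, x, base)
  # translation
  base_sh <- base; base_sh$mean <- base$mean + 7; base_sh$threshold <- base_sh$mean - base_sh$sd
  expect_equal(burden_score(t, x + 7, base_sh), s0, tolerance = 1e-9)
  # scale
  base_sc <- base; base_sc$mean <- base$mean * 3; base_sc$sd <- base$sd * 3
  expect_equal(burden_score(t, 3 * x, base_sc), 3 * s0, tolerance = 1e-9)
  # duration-weighted mean over disjoint intervals equals the union score
  i1 <- t <= 100; i2 <- t >= 100
  s1 <- burden_score(t[i1], x[i1], base)
  s2 <- burden_score(t[i2], x[i2], base)
  T1 <- diff(range(t[i1])); T2 <- diff(range(t[i2]))
  expect_equal((s1 * T1 + s2 * T2) / (T1 + T2), s0, tolerance = 1e-9)
})

test_that("hypoxia-period score thresholds at mean - sd", {
  t <- seq(0, 100, by = 0.1)
  x_wake <- 140 + 2 * sin(t)          # sd > 0
  base <- wake_baseline(t, x_wake, list(c(0, 100)))
  # always above threshold
  hp0 <- hypoxia_period_score(t, rep(150, length(t)), base)
  expect_equal(hp0$score, 0)
  expect_equal(hp0$time_in_hypoxia, 0)
  expect_equal(hp0$flag, "no-hypoxia")
  # constant 5 below threshold over the whole interval
  hp1 <- hypoxia_period_score(t, rep(base$threshold - 5, length(t)), base)
  expect_equal(hp1$score, 5)
  expect_equal(hp1$time_in_hypoxia, 100)
  # square-wave dips: score is the mean depth below threshold during dips
  x <- rep(base$threshold + 10, length(t))
  x[t >= 20 & t < 30] <- base$threshold - 8
  x[t >= 60 & t < 70] <- base$threshold - 4
  hp2 <- hypoxia_period_score(t, x, base)
  expect_equal(hp2$score, 6, tolerance = 0.01)
  expect_equal(hp2$time_in_hypoxia, 20, tolerance = 0.02)
  # degenerate baseline rejected
  base0 <- wake_baseline(t, rep(140, length(t)), list(c(0, 100)))
  expect_error(hypoxia_period_score(t, x, base0), "sd")
})

test_that("interval t test matches the textbook computation", {
  t <- 1:1000
  mk_trace <- function(d) {
    # trace whose interval means differ from the overall mean by d
    x <- rep(0, 1000)
    for (i in seq_along(d)) x[((i - 1) * 125 + 1):(i * 125)] <- d[i]
    x - mean(x)
  }
  ivs <- lapply(0:3, function(k) c(k * 125 + 1, (k + 1) * 125))
  # symmetric differences: t = 0, p = 1
  x <- mk_trace(c(-1, 1, -1, 1))
  res <- interval_ttest(t, list(v = x), ivs)
  expect_equal(res$t, 0, tolerance = 1e-9)
  expect_equal(res$p_value, 1, tolerance = 1e-9)
  # textbook one-sample t on hand-picked differences
  d <- c(-1.0, -1.5, -2.0, -0.9)
  x2 <- mk_trace(d)
  res2 <- interval_ttest(t, list(v = x2), ivs)
  dd <- vapply(ivs, function(iv) mean(x2[iv[1]:iv[2]]) - mean(x2), numeric(1))
  t_oracle <- mean(dd) / (sd(dd) / sqrt(4))
  p_oracle <- 2 * pt(-abs(t_oracle), df = 3)
  expect_equal(res2$t, t_oracle, tolerance = 1e-6)
  expect_equal(res2$p_value, p_oracle, tolerance = 1e-6)
  expect_true(res2$significant == (p_oracle < 0.05))
  # zero variance across intervals is an explicit error
  expect_error(interval_ttest(t, list(v = mk_trace(c(-2, -2, -2, -2))), ivs),
               "zero variance")
})
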