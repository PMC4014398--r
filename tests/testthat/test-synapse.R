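# synthetic AP-like waveform for driving the cascade
gauss_ap <- function(peak_mV = 25, width_scale = 0.35, dt = 0.01,
                     t_end = 4, t_peak = 1) {
  tm <- seq(0, t_end, by = dt)
  -65 + (peak_mV + 65) * exp(-((tm - t_peak) / width_scale)^2)
}

test_that("the m gate follows the closed-form relaxation under clamp", {
  mod <- ca_channel_model()
  v0 <- -10
  n <- 2001; dt <- 0.001
  v <- rep(v0, n)
  # start from rest: m(0) = m_inf(-65) carried by a short pre-segment
  v[1] <- -65
  # (the clamp never returns to rest; the truncation warning is expected)
  i <- suppressWarnings(ca_current(v, dt, mod))
  a <- mod$alpha(v0); b <- mod$beta(v0)
  minf <- a / (a + b); tau <- 1 / (a + b)
  m0 <- mod$alpha(-65) / (mod$alpha(-65) + mod$beta(-65))
  tm <- (seq_len(n) - 1) * dt
  m_exact <- minf + (m0 - minf) * exp(-tm / tau)
  m_num <- sqrt(i / (v0 - mod$e_ca_mV))
  expect_lt(max(abs(m_num[-1] - m_exact[-1]) / m_exact[-1]), 1e-6)
})

test_that("clamping at the reversal potential gives zero current", {
  mod <- ca_channel_model()
  v <- rep(mod$e_ca_mV, 500)
  expect_true(all(ca_current(v, 0.01, mod) == 0))
})

test_that("wider APs drive more total Ca influx", {
  dt <- 0.01
  v1 <- gauss_ap()
  tm <- seq(0, 4, by = dt)
  v2 <- approx((tm - 1) * 1.2 + 1, v1, xout = tm, rule = 2)$y  # 1.2x wider
  q1 <- sum(pmax(-ca_current(v1, dt), 0)) * dt
  q2 <- sum(pmax(-ca_current(v2, dt), 0)) * dt
  expect_gt(q2, 1.05 * q1)
})

test_that("the Ca transient matches the printed shape parameters", {
  dt <- 0.005
  i_ca <- ca_current(gauss_ap(dt = dt), dt)
  y <- pmax(-i_ca, 0)
  hw_in <- stochaxon:::transient_halfwidth((seq_along(y) - 1) * dt, y, 0)
  tr <- ca_transient(i_ca, dt)
  expect_equal(tr$peak_uM, 12, tolerance = 1e-9)
  expect_equal(tr$rest_uM, 0.05)
  expect_true(all(tr$conc_uM >= tr$rest_uM - 1e-12))
  # half-width lengthened by 100 us within one sample period
  expect_lt(abs(tr$halfwidth_ms - (hw_in + 0.1)), dt)
  # rise preserved: pre-peak samples are a pure amplitude mapping
  ipk <- which.max(y)
  expect_equal(tr$conc_uM[1:ipk], 0.05 + (12 - 0.05) * y[1:ipk] / max(y),
               tolerance = 1e-9)
  # flat input stays at the resting concentration
  flat <- ca_transient(rep(0, 100), dt)
  expect_true(all(flat$conc_uM == 0.05))
})

test_that("release model reproduces its limiting rates", {
  # no Ca: all occupancy stays in the unbound state, rate = l+ exactly
  tr0 <- release_trajectory(rep(0, 200), dt = 0.01)
  expect_equal(tr0$rate_s[1], 2e-4, tolerance = 1e-12)
  # over the window the unreleased pool only depletes at l+ itself
  expect_equal(tr0$rate_s, rep(2e-4, 200), tolerance = 1e-5)
  expect_equal(tr0$occupancy[, 1], rep(1, 200), tolerance = 1e-5)
  # saturating Ca: the unreleased pool collapses onto the fully bound state
  # and its per-vesicle rate approaches l+ f^5 (= 2e-4 * 31.3^5 per second);
  # normalize by the unreleased fraction because fusion drains the pool
  trs <- release_trajectory(rep(2000, 300), dt = 0.01)
  unrel <- pmax(1 - trs$released, 1e-12)
  expect_equal(max(trs$rate_s / unrel), 2e-4 * 31.3^5, tolerance = 0.01)
  i_half <- 51  # 0.5 ms: binding equilibrated, pool not yet drained
  expect_gt(trs$occupancy[i_half, 6] / unrel[i_half], 0.99)
})

test_that("release master equation conserves probability and is monotone in Ca", {
  dt <- 0.005
  tr <- ca_transient(ca_current(gauss_ap(dt = dt), dt), dt)
  rel <- release_trajectory(tr)
  total <- rowSums(rel$occupancy) + rel$released
  expect_lt(max(abs(total - 1)), 1e-9)
  expect_true(all(rel$occupancy >= -1e-12))
  expect_true(all(diff(rel$released) >= -1e-12))
  # clamped-Ca peak rate is non-decreasing over a 0-50 uM grid
  rates <- vapply(seq(0, 50, by = 5), function(ca) {
    max(release_trajectory(rep(ca, 1000), dt = 0.01)$rate_s)
  }, numeric(1))
  expect_true(all(diff(rates) >= 0))
})

test_that("release integration agrees with an independent stiff ODE solver", {
  skip_if_not_installed("deSolve")
  dt <- 0.005
  tr <- ca_transient(ca_current(gauss_ap(dt = dt), dt), dt)
  rel <- release_trajectory(tr)
  m <- release_model()
  ca_fun <- approxfun(tr$time, tr$conc_uM, rule = 2)
  deriv <- function(t, y, p) {
    ca <- ca_fun(t)
    x <- y[1:6]
    kb <- c(0, (1:5) * m$k_off_ms * m$b^(0:4))
    kr <- (m$l_plus_s / 1000) * m$f^(0:5)
    kf <- (5:0) * m$k_on_uM_ms * ca
    dx <- numeric(6)
    for (n in 1:6) {
      out <- kr[n] + kb[n] + (if (n < 6) kf[n] else 0)
      dx[n] <- -out * x[n] +
        (if (n > 1) kf[n - 1] * x[n - 1] else 0) +
        (if (n < 6) kb[n + 1] * x[n + 1] else 0)
    }
    list(c(dx, sum(kr * x)))
  }
  out <- deSolve::lsoda(c(1, rep(0, 5), 0), tr$time, deriv, NULL,
                        rtol = 1e-10, atol = 1e-12)
  expect_lt(max(abs(out[, 8] - rel$released)), 1e-7)
  rate_ode <- 1000 * ((m$l_plus_s / 1000) * m$f^(0:5)) %*% t(out[, 2:7])
  expect_lt(max(abs(as.numeric(rate_ode) - rel$rate_s)) / max(rel$rate_s),
            1e-5)
})

test_that("total release scales with the pool and its CV does not", {
  dt <- 0.005
  tr <- ca_transient(ca_current(gauss_ap(dt = dt), dt), dt)
  rel <- release_trajectory(tr)
  expect_equal(total_release(rel, 2000),
               2000 * rel$released[length(rel$released)])
  expect_equal(total_release(rel, 1), total_release(rel, 2000) / 2000)
  # ensemble CV of released counts is pool-size invariant
  waves <- t(vapply(c(22, 25, 28), function(p) gauss_ap(peak_mV = p),
                    gauss_ap()))
  c1 <- cascade_statistics(waves, 0.01, widths_ms = c(0.6, 0.7, 0.8),
                           pool_size = 100)
  c2 <- cascade_statistics(waves, 0.01, widths_ms = c(0.6, 0.7, 0.8),
                           pool_size = 5000)
  expect_equal(c1$cv$cv_pct, c2$cv$cv_pct, tolerance = 1e-9)
})

test_that("identical APs give zero CV at every cascade stage", {
  waves <- matrix(rep(gauss_ap(), 5), nrow = 5, byrow = TRUE)
  casc <- cascade_statistics(waves, 0.01, widths_ms = rep(0.7, 5))
  expect_true(all(abs(casc$cv$cv_pct) < 1e-9))
  expect_equal(nrow(casc$cv), 6)
})

test_that("ensemble-common transient scaling preserves per-AP peak variation", {
  waves <- t(vapply(c(20, 25, 30), function(p) gauss_ap(peak_mV = p),
                    gauss_ap()))
  casc <- cascade_statistics(waves, 0.01, widths_ms = c(0.7, 0.7, 0.7))
  # mean peak maps to 12 uM but individual peaks differ
  expect_equal(mean(casc$per_ap$peak_ca_uM), 12, tolerance = 0.01)
  expect_gt(sd(casc$per_ap$peak_ca_uM), 0)
  cv_i <- casc$cv$cv_pct[casc$cv$signal == "Ca peak current"]
  cv_ca <- casc$cv$cv_pct[casc$cv$signal == "Peak [Ca]"]
  expect_equal(cv_i, cv_ca, tolerance = 0.01)
})

test_that("EPSC power-law mapping amplifies width variability as predicted", {
  set.seed(8)
  expect_equal(epsc_from_width(c(0.6, 0.7, 0.8), k = 0)$cv_pct, 0)
  w <- runif(200, 0.6, 0.8)
  e1 <- epsc_from_width(w, k = 1)
  expect_equal(e1$cv_pct, 100 * sd_pop_(w) / mean(w), tolerance = 1e-9)
  # lognormal widths with CV 6% through k = 4: delta-method/analytic CV
  sigma2 <- log(1 + 0.06^2)
  wl <- rlnorm(2e5, log(0.7) - sigma2 / 2, sqrt(sigma2))
  e4 <- epsc_from_width(wl, k = 4)
  cv_analytic <- 100 * sqrt(exp(16 * sigma2) - 1)
  expect_equal(e4$cv_pct, cv_analytic, tolerance = 0.02)
  expect_gt(e4$cv_pct, 20)   # approx 25% amplification of a 6% width CV
  expect_lt(e4$cv_pct, 30)
})
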