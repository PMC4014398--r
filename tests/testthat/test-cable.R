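test_that("cable discretization arithmetic follows geometry and densities", {
  spec <- axon_preset("squid_hh", diameter_um = 0.2, length_um = 2000,
                      dx_um = 1)
  cab <- build_cable(spec)
  expect_equal(cab$n_comp, 2000)
  # 60 channels/um^2 * pi * 0.2 um * 1 um, rounded
  expect_equal(cab$pops[[1]]$n_per_comp, 38)
  expect_equal(cab$pops[[1]]$n_per_comp, round(60 * pi * 0.2 * 1))
  expect_equal(cab$pops[[2]]$n_per_comp, round(18 * pi * 0.2 * 1))
})

test_that("compartment length is held to a tenth of the length constant", {
  lam <- lambda_um(0.2, 35.4, 0.3)
  expect_error(axon_spec(0.2, 2000, dx_um = 0.11 * lam), "lambda/10")
  expect_silent(axon_spec(0.2, 2000, dx_um = 0.09 * lam))
})

test_that("passive cable steady state matches the sealed-end closed form", {
  # no channels: step current at the proximal end; the steady-state profile
  # of a finite sealed cable is V0 cosh((L - x)/lambda) / cosh(L/lambda)
  spec <- axon_spec(diameter_um = 0.5, length_um = 1000, dx_um = 10,
                    g_leak_mS_cm2 = 0.3, e_leak_mV = -65, v_rest_mV = -65,
                    ra_ohm_cm = 35.4, channels = list())
  pos <- seq(0.05, 0.95, by = 0.1)
  sim <- simulate_axon(spec, stim_pulse(0.05, duration_ms = 300,
                                        onset_ms = 1),
                       t_end_ms = 300, dt = 0.01, record_at = pos,
                       mode = "deterministic")
  v_ss <- sim$v[nrow(sim$v), ] + 65
  lam <- spec$lambda_um
  x_um <- (ceiling(pos * 100) - 0.5) * 10      # compartment centres
  shape <- cosh((1000 - x_um) / lam) / cosh(1000 / lam)
  pred <- v_ss[1] * shape / shape[1]
  expect_lt(max(abs(v_ss - pred) / v_ss[1]), 0.01)
})

test_that("charge bookkeeping closes in a space-clamped deterministic run", {
  sch <- hh_squid_schemes()
  spec <- axon_spec(diameter_um = 0.2, length_um = 10, dx_um = 10,
                    g_leak_mS_cm2 = 0.3, e_leak_mV = -54.4,
                    channels = list(list(scheme = sch$na, density_um2 = 60),
                                    list(scheme = sch$k, density_um2 = 18)))
  cab <- build_cable(spec)
  dt <- 0.001
  # backward-Euler voltage update (theta = 1): the recorded ionic currents
  # satisfy C dV/dt = I_stim - I_ion exactly, step by step
  sim <- simulate_axon(cab, stim_pulse(0.01, 1, onset_ms = 2), 12, dt = dt,
                       record_at = 0.5, sample_every = 1,
                       mode = "deterministic", theta = 1)
  C <- cab$cap_nF[1]
  v <- sim$v[, 1]
  n <- length(v)
  dvdt <- (v[2:n] - v[1:(n - 1)]) / dt
  i_mem <- sim$i_net[2:n, 1]
  i_stim <- sim$stim_nA[2:n]
  resid <- C * dvdt - (i_stim - i_mem)
  expect_lt(max(abs(resid)) / max(abs(C * dvdt)), 1e-8)
})

test_that("deterministic runs are bit-identical and refine cleanly", {
  spec <- axon_preset("squid_hh", diameter_um = 0.2)
  stim <- stim_pulse(0.03, 0.5, onset_ms = 2)
  sim1 <- simulate_axon(spec, stim, 25, record_at = 0.95,
                        mode = "deterministic")
  sim2 <- simulate_axon(spec, stim, 25, record_at = 0.95,
                        mode = "deterministic")
  expect_identical(sim1$v, sim2$v)
  ev <- detect_aps(sim1$time, sim1$v[, 1], -65)
  expect_equal(nrow(ev), 1)
  expect_gt(ev$peak_mV, 0)            # overshoot above 0 mV
  expect_gt(ev$width_ms, 0.5)         # squid-like width at 6.3 degC
  expect_lt(ev$width_ms, 2.5)

  # refinement: halving dt and dx changes width and height by < 1%
  ref <- function(dx, dt) {
    s <- axon_preset("squid_hh", diameter_um = 0.2, dx_um = dx)
    sm <- simulate_axon(s, stim, 25, dt = dt, record_at = 0.95,
                        mode = "deterministic")
    detect_aps(sm$time, sm$v[, 1], -65)[1, c("width_ms", "height_mV")]
  }
  base <- ref(10, 0.005)
  fine_dt <- ref(10, 0.0025)
  fine_dx <- ref(5, 0.005)
  expect_lt(abs(fine_dt$width_ms / base$width_ms - 1), 0.01)
  expect_lt(abs(fine_dt$height_mV / base$height_mV - 1), 0.01)
  expect_lt(abs(fine_dx$width_ms / base$width_ms - 1), 0.01)
  expect_lt(abs(fine_dx$height_mV / base$height_mV - 1), 0.01)
})

test_that("space-clamped deterministic AP matches an independent gate-variable ODE", {
  skip_if_not_installed("deSolve")
  sch <- hh_squid_schemes()
  spec <- axon_spec(diameter_um = 0.2, length_um = 10, dx_um = 10,
                    g_leak_mS_cm2 = 0.3, e_leak_mV = -54.4,
                    channels = list(list(scheme = sch$na, density_um2 = 60),
                                    list(scheme = sch$k, density_um2 = 18)))
  cab <- build_cable(spec)
  sim <- simulate_axon(cab, stim_pulse(0.005, 1, onset_ms = 2), 20,
                       dt = 0.001, record_at = 0.5, sample_every = 5,
                       mode = "deterministic")
  # classic gate-variable formulation with the same per-compartment
  # conductances (integer channel counts) and stimulus
  am <- function(v) 0.1 * (v + 40) / (1 - exp(-(v + 40) / 10))
  bm <- function(v) 4 * exp(-(v + 65) / 18)
  ah <- function(v) 0.07 * exp(-(v + 65) / 20)
  bh <- function(v) 1 / (1 + exp(-(v + 35) / 10))
  an <- function(v) 0.01 * (v + 55) / (1 - exp(-(v + 55) / 10))
  bn <- function(v) 0.125 * exp(-(v + 65) / 80)
  g_na <- cab$pops[[1]]$n_per_comp * 20e-6   # uS
  g_k <- cab$pops[[2]]$n_per_comp * 20e-6
  gl <- cab$g_leak_uS[1]; C <- cab$cap_nF[1]
  deriv <- function(t, y, p) {
    v <- y[1]; m <- y[2]; h <- y[3]; n <- y[4]
    i_stim <- if (t >= 2 && t < 3) 0.005 else 0
    dv <- (i_stim - g_na * m^3 * h * (v - 50) - g_k * n^4 * (v + 77) -
             gl * (v + 54.4)) / C
    list(c(dv, am(v) * (1 - m) - bm(v) * m, ah(v) * (1 - h) - bh(v) * h,
           an(v) * (1 - n) - bn(v) * n))
  }
  minf <- function(v) am(v) / (am(v) + bm(v))
  hinf <- function(v) ah(v) / (ah(v) + bh(v))
  ninf <- function(v) an(v) / (an(v) + bn(v))
  out <- deSolve::lsoda(c(-65, minf(-65), hinf(-65), ninf(-65)), sim$time,
                        deriv, NULL, rtol = 1e-9, atol = 1e-9)
  ev_sim <- detect_aps(sim$time, sim$v[, 1], -65)
  ev_ode <- detect_aps(out[, 1], out[, 2], -65)
  expect_equal(nrow(ev_sim), 1)
  expect_equal(nrow(ev_ode), 1)
  expect_lt(abs(ev_sim$height_mV / ev_ode$height_mV - 1), 0.02)
  expect_lt(abs(ev_sim$width_ms / ev_ode$width_ms - 1), 0.02)
  expect_lt(abs(ev_sim$t_align - ev_ode$t_align), 0.05)
})

test_that("filtered noise stimulus has the requested statistics", {
  set.seed(9)
  dt <- 0.005
  x <- make_filtered_noise(0.01, 1, dt, 10000)
  expect_equal(sd(x), 0.01, tolerance = 1e-12)     # rescaled exactly
  expect_lt(abs(mean(x)), 3 * 0.01 / sqrt(length(x) * 2 * pi * 1 * dt))
  # periodogram: power at 2 kHz at least 3 dB below the passband level
  sp <- spec.pgram(ts(x, deltat = dt / 1000), plot = FALSE, taper = 0,
                   spans = 51)
  pass <- mean(sp$spec[sp$freq < 200])
  at2k <- mean(sp$spec[sp$freq > 1900 & sp$freq < 2100])
  expect_lt(at2k / pass, 10^(-3 / 10))
  expect_error(make_filtered_noise(0.01, 200, dt, 100), "Nyquist")
})

test_that("identical seeds reproduce stochastic runs exactly", {
  spec <- axon_preset("squid_hh", diameter_um = 0.2, length_um = 500)
  stim <- stim_pulse(0.03, 0.5, onset_ms = 1)
  set.seed(77)
  a <- simulate_axon(spec, stim, 5, record_at = 0.9)
  set.seed(77)
  b <- simulate_axon(spec, stim, 5, record_at = 0.9)
  set.seed(78)
  c <- simulate_axon(spec, stim, 5, record_at = 0.9)
  expect_identical(a$v, b$v)
  expect_false(identical(a$v, c$v))
})

test_that("channel counts are conserved through a stochastic cable run", {
  spec <- axon_preset("squid_hh", diameter_um = 0.2, length_um = 500)
  set.seed(5)
  sim <- simulate_axon(spec, stim_pulse(0.03, 0.5, onset_ms = 1), 5,
                       record_at = 0.5)
  cab <- build_cable(spec)
  for (k in seq_along(sim$final_state)) {
    tot <- colSums(sim$final_state[[k]])
    expect_true(all(tot == cab$pops[[k]]$n_per_comp))
    expect_true(all(sim$final_state[[k]] >= 0))
  }
})

test_that("resting fluctuations grow as the axon gets thinner", {
  set.seed(13)
  sd_at <- vapply(c(1.0, 0.2), function(d) {
    spec <- axon_preset("squid_hh", diameter_um = d, length_um = 1000)
    sim <- simulate_axon(spec, stim_pulse(0, 0.1), 120, record_at = 0.5)
    sd(sim$v[sim$time > 20, 1])
  }, numeric(1))
  expect_gt(sd_at[2], sd_at[1])
})

test_that("the AP upstroke steepens away from the initiation site", {
  # the rising phase approaches its travelling steady-state shape within
  # the first few length constants: the 10-90% rise time shortens with
  # distance from the stimulated end
  spec <- axon_preset("squid_hh", diameter_um = 0.2)
  sim <- simulate_axon(spec, stim_pulse(0.03, 0.5, onset_ms = 2), 25,
                       record_at = c(0.01, 0.6), mode = "deterministic")
  rise <- vapply(1:2, function(j) {
    v <- sim$v[, j]; tm <- sim$time
    pk <- max(v); ipk <- which.max(v)
    l10 <- -65 + 0.1 * (pk + 65); l90 <- -65 + 0.9 * (pk + 65)
    tm[max(which(v[1:ipk] < l90))] - tm[max(which(v[1:ipk] < l10))]
  }, numeric(1))
  expect_lt(rise[2], 0.8 * rise[1])
})

test_that("single-AP protocol yields one AP per trial with matched features", {
  ens <- get_single_ap()
  expect_lte(ens$n_excluded, 10)
  ev <- ens$events
  per_trial <- table(ev$trial, ev$position)
  expect_true(all(per_trial == 1))
  expect_true(all(ev$width_ms > 0))
  expect_true(all(ev$height_mV > 0))
  # noise amplification: distal AP-height SD exceeds the resting-potential
  # fluctuation SD of the same axon
  set.seed(31)
  spec <- axon_preset("rat_interneuron", diameter_um = 0.2)
  rest <- simulate_axon(spec, stim_pulse(0, 0.1), 120, record_at = 0.95)
  sd_rest <- sd(rest$v[rest$time > 20, 1])
  ev95 <- ev[ev$position == 0.95, ]
  expect_gt(sd_pop_(ev95$height_mV), sd_rest)
})
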