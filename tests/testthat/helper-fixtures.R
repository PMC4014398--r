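# Shared fixtures. The expensive stochastic protocol runs are computed once
# per test session (lazily) and reused across test files.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, builder(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# minimal two-state scheme: closed -> open at rate r_on, open -> closed at
# r_off (unit conductance bookkeeping only)
two_state_scheme <- function(r_on = 1, r_off = 2) {
  kinetic_scheme(
    "two_state", c("closed", "open"),
    list(list(from = "closed", to = "open", rate = function(v) rep(r_on, length(v))),
         list(from = "open", to = "closed", rate = function(v) rep(r_off, length(v)))),
    conducting = "open", g_single_pS = 20, e_rev_mV = 0)
}

# triangular synthetic spike: rest -65 mV, rising to +35 mV in rise_ms and
# back in fall_ms; closed-form height 100 mV, width rise_ms/2 + fall_ms/2
triangle_trace <- function(rise_ms = 1, fall_ms = 2, dt = 0.001,
                           onset_ms = 5, tail_ms = 5) {
  t_up <- seq(0, rise_ms, by = dt)
  t_dn <- seq(dt, fall_ms, by = dt)
  v <- c(rep(-65, round(onset_ms / dt)),
         -65 + 100 * t_up / rise_ms,
         35 - 100 * t_dn / fall_ms,
         rep(-65, round(tail_ms / dt)))
  list(time = seq_along(v) * dt - dt, v = v)
}

# spike-train protocol at the study conditions: 0.2 um interneuron axon,
# 2 mm, Ra 70 Ohm cm, Rm 20000 Ohm cm2, white-noise stimulus SD 0.01 nA,
# 1 kHz corner; APs collected at 45% and 95% of length (1 mm apart).
get_train <- function() {
  fixture("train", function() {
    set.seed(20140508)
    spec <- axon_preset("rat_interneuron", diameter_um = 0.2,
                        g_leak_mS_cm2 = 0.05)
    suppressWarnings(run_spike_train_protocol(spec, duration_ms = 10000))
  })
}

# single-spike-per-trial ensemble, Table-2 passive parameters
get_single_ap <- function() {
  fixture("single_ap", function() {
    set.seed(101)
    spec <- axon_preset("rat_interneuron", diameter_um = 0.2)
    suppressWarnings(run_single_ap_protocol(spec, n_trials = 100))
  })
}

# squid single-AP ensembles across diameters for the scaling law
get_scaling <- function() {
  fixture("scaling", function() {
    set.seed(202)
    lapply(c(0.2, 0.5, 1.0), function(d) {
      spec <- axon_preset("squid_hh", diameter_um = d)
      suppressWarnings(run_single_ap_protocol(spec, n_trials = 50))
    })
  })
}

# small multi-position squid ensemble for correlation-vs-distance and
# profile-shape checks
get_multi_pos <- function() {
  fixture("multi_pos", function() {
    set.seed(303)
    spec <- axon_preset("squid_hh", diameter_um = 0.2)
    suppressWarnings(run_single_ap_protocol(
      spec, n_trials = 15, record_at = c(0.40, 0.45, 0.55, 0.70, 0.90)))
  })
}

sd_pop_ <- function(x) sqrt(mean((x - mean(x))^2))
cv_pct_ <- function(x) 100 * sd_pop_(x) / mean(x)
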