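#' Integrate the stochastic (or deterministic) cable equation
#'
#' Advances the compartmental cable with an unconditionally stable implicit
#' theta-scheme (tridiagonal solve; theta = 0.5 is Crank-Nicolson) for the
#' membrane/axial currents, while channel populations advance by the
#' binomial algorithm ([stochastic_step()] semantics) or its deterministic
#' expected-value limit at the same time step (operator splitting).
#'
#' Stochastic runs initialize channel counts by multinomial sampling from
#' the resting equilibrium distribution; deterministic runs use the
#' equilibrium fractions themselves, so repeated identical deterministic
#' runs are bit-identical.
#'
#' @param cable a [build_cable()] result or an [axon_spec()].
#' @param stimulus a [stim_pulse()] / [stim_noise()] object, or a numeric
#'   per-step current vector (nA) injected at `stim_site`.
#' @param t_end_ms simulated time (ms).
#' @param dt time step (ms); default 0.005 ms.
#' @param record_at recording positions as fractions of axon length.
#' @param sample_every record every this many steps.
#' @param mode `"stochastic"` or `"deterministic"`.
#' @param stim_site injection site (fraction of length) when `stimulus` is a
#'   plain vector.
#' @param theta implicitness of the voltage update (0.5 = Crank-Nicolson).
#' @return object of class `axon_sim`: `time` (ms), `v` (mV, samples x
#'   positions), per-population currents `i_pop` (nA, positive outward) and
#'   open-channel counts `open`, leak current `i_leak`, net membrane ionic
#'   current `i_net`, the stimulus vector, positions and run metadata.
#' @export
simulate_axon <- function(cable, stimulus, t_end_ms, dt = 0.005,
                          record_at = seq(0.05, 0.95, by = 0.1),
                          sample_every = 2,
                          mode = c("stochastic", "deterministic"),
                          stim_site = 0, theta = 0.5) {
  mode <- match.arg(mode)
  if (inherits(cable, "axon_spec")) cable <- build_cable(cable)
  stopifnot(inherits(cable, "cable"))
  spec <- cable$spec
  n_comp <- cable$n_comp
  n_steps <- round(t_end_ms / dt)
  if (any(record_at < 0) || any(record_at > 1))
    stop("recording positions must be fractions of axon length in [0, 1]")

  if (inherits(stimulus, "stimulus")) {
    stim_vec <- stimulus_vector(stimulus, dt, n_steps)
    stim_site <- stimulus$site
  } else {
    stim_vec <- rep_len(as.numeric(stimulus), n_steps)
  }
  stim_comp <- pos_to_comp(stim_site, n_comp)
  rec_comp <- vapply(record_at, pos_to_comp, integer(1), n_comp = n_comp)

  pops <- lapply(cable$pops, function(p) {
    rt <- scheme_rate_table(p$scheme)
    n_states <- length(p$scheme$states)
    if (mode == "stochastic") {
      st <- if (p$n_per_comp > 0)
        matrix(as.numeric(stats::rmultinom(n_comp, p$n_per_comp, p$eq)),
               nrow = n_states)
      else matrix(0, n_states, n_comp)
    } else {
      # expected occupancies in channel-count units, so conducting-state
      # occupancy times g_single is the population conductance in both modes
      st <- matrix(p$eq * p$n_per_comp, n_states, n_comp)
    }
    list(state = st, total = rep(p$n_per_comp, n_comp),
         g_single = p$scheme$g_single_pS * 1e-6,   # pS -> uS
         e_rev = p$scheme$e_rev_mV,
         conducting = match(p$scheme$conducting, p$scheme$states) - 1L,
         from = match(vapply(p$scheme$transitions, `[[`, "", "from"),
                      p$scheme$states) - 1L,
         to = match(vapply(p$scheme$transitions, `[[`, "", "to"),
                    p$scheme$states) - 1L,
         rate_tab = rt$tab, v0 = rt$v0, dv = rt$dv)
  })

  res <- .cable_run(rep(spec$v_rest_mV, n_comp), cable$cap_nF, cable$g_ax_uS,
                    cable$g_leak_uS, spec$e_leak_mV, pops, stim_vec,
                    stim_comp - 1L, dt, n_steps, rec_comp - 1L, sample_every,
                    mode == "stochastic", theta, 0.35)

  names(res$i_pop) <- names(res$open) <-
    vapply(cable$pops, function(p) p$scheme$name, "")
  i_net <- res$i_leak
  for (m in res$i_pop) i_net <- i_net + m
  structure(list(time = res$time, v = res$v, i_pop = res$i_pop,
                 open = res$open, i_leak = res$i_leak, i_net = i_net,
                 stim_nA = stim_vec, positions = record_at,
                 rec_comp = rec_comp, final_state = res$final_state,
                 meta = list(mode = mode, dt = dt, sample_every = sample_every,
                             theta = theta, n_comp = n_comp,
                             t_end_ms = t_end_ms, spec = spec)),
            class = "axon_sim")
}

pos_to_comp <- function(pos, n_comp) {
  as.integer(max(1L, min(n_comp, ceiling(pos * n_comp))))
}

#' @export
print.axon_sim <- function(x, ...) {
  cat("Axon simulation (", x$meta$mode, "): ", x$meta$t_end_ms, " ms, dt = ",
      x$meta$dt, " ms, ", x$meta$n_comp, " compartments\n", sep = "")
  cat("  recorded at fractions:", paste(signif(x$positions, 3), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
plot.axon_sim <- function(x, positions = seq_along(x$positions), ...) {
  graphics::matplot(x$time, x$v[, positions, drop = FALSE], type = "l",
                    lty = 1, xlab = "time (ms)", ylab = "V (mV)", ...)
  invisible(x)
}

#' Tune the single-AP trigger pulse amplitude
#'
#' The trigger stimulus for the single-spike-per-trial protocol is a 0.5 ms
#' rectangular pulse at the proximal end whose amplitude is set by bisection
#' on the deterministic model to the threshold for eliciting exactly one
#' propagating AP at the distal end, times a safety factor.
#'
#' @param spec an [axon_spec()].
#' @param pulse_ms pulse duration (ms).
#' @param dt time step (ms).
#' @param t_end_ms deterministic probe duration (ms).
#' @param factor multiple of threshold to return (default 1.5).
#' @param lo,hi initial bisection bracket (nA).
#' @param iters bisection iterations.
#' @return list: `amplitude_nA` (tuned amplitude), `threshold_nA`,
#'   `arrival_ms` (deterministic distal AP alignment time at the tuned
#'   amplitude).
#' @export
tune_pulse_amplitude <- function(spec, pulse_ms = 0.5, dt = 0.005,
                                 t_end_ms = NULL, factor = 1.5,
                                 lo = 1e-4, hi = 0.5, iters = 14) {
  cab <- build_cable(spec)
  if (is.null(t_end_ms))
    t_end_ms <- max(30, spec$length_um / 50)  # generous for slow kinetics
  n_distal <- function(amp) {
    # a numerical blow-up at huge amplitudes counts as suprathreshold so
    # the bisection brackets downwards
    sim <- tryCatch(
      simulate_axon(cab, stim_pulse(amp, pulse_ms, onset_ms = 2),
                    t_end_ms, dt, record_at = 0.95,
                    mode = "deterministic"),
      error = function(e) NULL)
    if (is.null(sim)) return(Inf)
    nrow(detect_aps(sim$time, sim$v[, 1], spec$v_rest_mV))
  }
  if (n_distal(hi) < 1) stop("upper bracket does not elicit an AP")
  if (n_distal(lo) >= 1) stop("lower bracket already elicits an AP")
  for (i in seq_len(iters)) {
    mid <- sqrt(lo * hi)
    if (n_distal(mid) >= 1) hi <- mid else lo <- mid
  }
  amp <- factor * hi
  sim <- simulate_axon(cab, stim_pulse(amp, pulse_ms, onset_ms = 2),
                       t_end_ms, dt, record_at = 0.95,
                       mode = "deterministic")
  ev <- detect_aps(sim$time, sim$v[, 1], spec$v_rest_mV)
  list(amplitude_nA = amp, threshold_nA = hi,
       arrival_ms = if (nrow(ev)) ev$t_align[1] else NA_real_)
}

#' Single-spike-per-trial protocol
#'
#' Runs `n_trials` independent stochastic simulations from identical initial
#' conditions and an identical suprathreshold trigger pulse, differing only
#' in the RNG stream. Each trial is expected to yield exactly one
#' propagating AP recorded at all requested positions; trials with 0 or >= 2
#' detected APs at any position are flagged and excluded from the feature
#' statistics (the count is reported).
#'
#' @param spec an [axon_spec()].
#' @param n_trials number of independent trials.
#' @param record_at recording positions (fractions of length).
#' @param dt time step (ms).
#' @param amplitude_nA trigger amplitude; if `NULL`, tuned by
#'   [tune_pulse_amplitude()].
#' @param pulse_ms trigger pulse duration (ms).
#' @param window_ms aligned waveform window around the half-peak crossing.
#' @param grid_dt_ms time grid of the aligned waveform windows (ms).
#' @return object of class `ap_ensemble`: `events` (one row per detected AP:
#'   trial, position, alignment time, peak, height, width), `waveforms`
#'   (list over positions of aligned-window matrices, one row per trial),
#'   `n_excluded`, and metadata.
#' @export
run_single_ap_protocol <- function(spec, n_trials = 100,
                                   record_at = c(0.45, 0.95), dt = 0.005,
                                   amplitude_nA = NULL, pulse_ms = 0.5,
                                   window_ms = c(-1, 3), grid_dt_ms = 0.01) {
  cab <- build_cable(spec)
  tun <- NULL
  if (is.null(amplitude_nA)) {
    tun <- tune_pulse_amplitude(spec, pulse_ms, dt)
    amplitude_nA <- tun$amplitude_nA
  }
  if (is.null(tun) || !is.finite(tun$arrival_ms)) {
    t_end <- max(30, spec$length_um / 50)
  } else {
    t_end <- tun$arrival_ms * 1.3 + 8
  }
  grid <- seq(window_ms[1], window_ms[2], by = grid_dt_ms)
  events <- vector("list", n_trials)
  waves <- lapply(record_at, function(p)
    matrix(NA_real_, n_trials, length(grid)))
  names(waves) <- as.character(record_at)
  n_excluded <- 0L
  for (tr in seq_len(n_trials)) {
    sim <- simulate_axon(cab, stim_pulse(amplitude_nA, pulse_ms, onset_ms = 2),
                         t_end, dt, record_at = record_at)
    evs <- lapply(seq_along(record_at), function(j)
      detect_aps(sim$time, sim$v[, j], spec$v_rest_mV))
    if (any(vapply(evs, nrow, 0L) != 1L)) {
      n_excluded <- n_excluded + 1L
      next
    }
    ev <- do.call(rbind, lapply(seq_along(evs), function(j) {
      cbind(trial = tr, position = record_at[j], evs[[j]])
    }))
    events[[tr]] <- ev
    for (j in seq_along(record_at))
      waves[[j]][tr, ] <- sample_waveform(sim$time, sim$v[, j],
                                          evs[[j]]$t_align[1], grid)
  }
  events <- do.call(rbind, events)
  keep <- stats::complete.cases(vapply(waves, function(w) w[, 1],
                                       numeric(n_trials)))
  waves <- lapply(waves, function(w) w[keep, , drop = FALSE])
  structure(list(events = events, waveforms = waves, grid = grid,
                 positions = record_at, n_excluded = n_excluded,
                 meta = list(n_trials = n_trials, amplitude_nA = amplitude_nA,
                             dt = dt, t_end_ms = t_end, spec = spec)),
            class = "ap_ensemble")
}

#' @export
print.ap_ensemble <- function(x, ...) {
  cat("Single-AP ensemble:", x$meta$n_trials, "trials,", x$n_excluded,
      "excluded;", if (!is.null(x$events)) nrow(x$events) else 0,
      "events at", length(x$positions), "positions\n")
  invisible(x)
}

#' Spike-train protocol under filtered white-noise stimulation
#'
#' Continuous stochastic run driven by the zero-mean filtered white-noise
#' current (default SD 0.01 nA, 1 kHz corner) injected at the proximal end
#' after a settling period. APs are detected at each recorded position;
#' per-AP aligned waveform windows are extracted at the distal site.
#'
#' @param spec an [axon_spec()]. For this protocol the passive membrane is
#'   typically set to R_a = 70 Ohm cm, R_m = 20000 Ohm cm^2 (see
#'   [axon_preset()] overrides).
#' @param duration_ms stimulated duration (ms).
#' @param sd_nA,corner_kHz noise stimulus parameters.
#' @param record_at recording positions; the last is treated as distal.
#' @param settle_ms settling time before the stimulus starts (ms).
#' @param dt time step (ms).
#' @param window_ms,grid_dt_ms aligned waveform window and its grid.
#' @param mode passed to [simulate_axon()]; the deterministic mode is a
#'   control in which channel noise is absent.
#' @return object of class `spike_train`: `events` (per position),
#'   `waveforms` (aligned windows at each position), firing `rate_hz`,
#'   interspike-interval stats, and metadata.
#' @export
run_spike_train_protocol <- function(spec, duration_ms = 10000,
                                     sd_nA = 0.01, corner_kHz = 1,
                                     record_at = c(0.45, 0.95),
                                     settle_ms = 20, dt = 0.005,
                                     window_ms = c(-1, 3), grid_dt_ms = 0.01,
                                     mode = "stochastic") {
  cab <- build_cable(spec)
  stim <- stim_noise(sd_nA, corner_kHz, duration_ms, onset_ms = settle_ms)
  sim <- simulate_axon(cab, stim, settle_ms + duration_ms, dt,
                       record_at = record_at, mode = mode)
  events <- lapply(seq_along(record_at), function(j) {
    ev <- detect_aps(sim$time, sim$v[, j], spec$v_rest_mV)
    ev <- ev[ev$t_align > settle_ms + 5, , drop = FALSE]  # stimulus-onset guard
    cbind(position = rep(record_at[j], nrow(ev)), ev)
  })
  names(events) <- as.character(record_at)
  grid <- seq(window_ms[1], window_ms[2], by = grid_dt_ms)
  waveforms <- lapply(seq_along(record_at), function(j) {
    ev <- events[[j]]
    t(vapply(ev$t_align, function(t0)
      sample_waveform(sim$time, sim$v[, j], t0, grid), numeric(length(grid))))
  })
  names(waveforms) <- as.character(record_at)
  distal <- events[[length(events)]]
  isi <- diff(distal$t_align)
  structure(list(events = events, waveforms = waveforms, grid = grid,
                 positions = record_at,
                 rate_hz = 1000 * nrow(distal) / duration_ms,
                 isi_mean_ms = if (length(isi)) mean(isi) else NA_real_,
                 isi_sd_ms = if (length(isi) > 1) stats::sd(isi) else NA_real_,
                 sim = sim,
                 meta = list(duration_ms = duration_ms, sd_nA = sd_nA,
                             corner_kHz = corner_kHz, settle_ms = settle_ms,
                             dt = dt, mode = mode, spec = spec)),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  distal <- x$events[[length(x$events)]]
  cat("Spike train: ", nrow(distal), " APs at distal site over ",
      x$meta$duration_ms / 1000, " s (", round(x$rate_hz, 1), " Hz)\n",
      sep = "")
  cat("  ISI ", round(x$isi_mean_ms, 1), " ms +/- ", round(x$isi_sd_ms, 1),
      " ms (mean +/- SD)\n", sep = "")
  invisible(x)
}
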