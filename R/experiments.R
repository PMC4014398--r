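#' Run a declarative simulation experiment
#'
#' Executes a run configuration (an R list or a YAML file path), writes the
#' feature tables, summary statistics, the exact configuration used and a
#' structured log to an output directory. Deterministic configurations
#' re-run bit-identically; stochastic configurations reproduce exactly for
#' the same seed.
#'
#' Configuration fields: `preset` (or an explicit `axon` list of
#' [axon_spec()] arguments), `diameter_um`, `length_um`, `dx_um`,
#' `protocol` (`"single_ap"`, `"spike_train"`), `seed`, `dt`, protocol
#' parameters (`n_trials`, `duration_ms`, `sd_nA`, `corner_kHz`,
#' `record_at`), `mode`, and optional [axon_spec()] overrides under
#' `overrides` (e.g. `g_leak_mS_cm2`).
#'
#' @param config list or path to a YAML file.
#' @param out_dir output directory (created if missing); `NULL` to skip
#'   writing.
#' @return invisibly, a list with the protocol result, feature statistics
#'   and the normalized configuration.
#' @export
run_experiment <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(list(
    preset = "rat_interneuron", diameter_um = 0.2, length_um = 2000,
    dx_um = 10, protocol = "spike_train", seed = 1, dt = 0.005,
    n_trials = 50, duration_ms = 2000, sd_nA = 0.01, corner_kHz = 1,
    record_at = c(0.45, 0.95), mode = "stochastic",
    overrides = list()), config)
  set.seed(cfg$seed)
  spec <- do.call(axon_preset,
                  c(list(name = cfg$preset, diameter_um = cfg$diameter_um,
                         length_um = cfg$length_um, dx_um = cfg$dx_um),
                    cfg$overrides))
  t0 <- Sys.time()
  if (cfg$protocol == "spike_train") {
    res <- run_spike_train_protocol(spec, duration_ms = cfg$duration_ms,
                                    sd_nA = cfg$sd_nA,
                                    corner_kHz = cfg$corner_kHz,
                                    record_at = cfg$record_at, dt = cfg$dt,
                                    mode = cfg$mode)
    events <- res$events[[length(res$events)]]
    excl <- 0L
  } else if (cfg$protocol == "single_ap") {
    res <- run_single_ap_protocol(spec, n_trials = cfg$n_trials,
                                  record_at = cfg$record_at, dt = cfg$dt)
    events <- res$events
    excl <- res$n_excluded
  } else stop("unknown protocol: ", cfg$protocol)
  stats_tab <- if (!is.null(events) && nrow(events) >= 2)
    feature_statistics(events) else NULL
  elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    yaml::write_yaml(cfg, file.path(out_dir, "config.yaml"))
    if (!is.null(events))
      utils::write.csv(events, file.path(out_dir, "features.csv"),
                       row.names = FALSE)
    if (!is.null(stats_tab))
      utils::write.csv(stats_tab, file.path(out_dir, "summary.csv"),
                       row.names = FALSE)
    writeLines(c(
      paste0("stochaxon ", as.character(utils::packageVersion("stochaxon"))),
      paste0("rng: ", RNGkind()[1], " seed ", cfg$seed),
      paste0("protocol: ", cfg$protocol, " (", cfg$mode, ")"),
      paste0("events: ", if (is.null(events)) 0L else nrow(events),
             ", excluded trials: ", excl),
      paste0("elapsed_s: ", round(elapsed, 2))),
      file.path(out_dir, "run.log"))
  }
  invisible(list(result = res, statistics = stats_tab, config = cfg,
                 n_excluded = excl))
}

#' Reproduce the study's figure/table-level analyses at reduced scale
#'
#' Runs the protocol behind one of the headline analyses at a configurable
#' scale factor and returns its underlying numbers:
#' \describe{
#'   \item{`fig3`}{resting-potential fluctuations and single-AP height SD
#'     vs diameter (noise amplification by the AP mechanism).}
#'   \item{`fig4`}{waveform variability profile (3xSD envelope) of a
#'     single-AP ensemble.}
#'   \item{`fig5`}{CV of AP height/width vs diameter with the power-law
#'     exponent.}
#'   \item{`fig7`}{spike-train waveform statistics and the cascade signal
#'     profiles.}
#'   \item{`fig8`}{distribution summaries of peak release rate and released
#'     vesicle count.}
#'   \item{`table1`}{stage-by-stage CV table of synaptic transmission.}
#' }
#' Scale 1 corresponds to the desk-scale defaults (2 mm axons, N = 50-300
#' APs, tens of seconds of train); smaller scales shrink trial counts and
#' durations proportionally.
#'
#' @param what one of `"fig3"`, `"fig4"`, `"fig5"`, `"fig7"`, `"fig8"`,
#'   `"table1"`.
#' @param scale scale factor in (0, 1].
#' @param seed RNG seed.
#' @return a report list; contents depend on `what`.
#' @export
reproduce <- function(what = c("fig5", "table1", "fig3", "fig4", "fig7",
                               "fig8"),
                      scale = 0.2, seed = 1) {
  what <- match.arg(what)
  stopifnot(scale > 0, scale <= 1)
  set.seed(seed)
  if (what == "fig3") {
    diams <- c(0.2, 1.0)
    out <- lapply(diams, function(d) {
      spec <- axon_preset("squid_hh", diameter_um = d)
      sim <- simulate_axon(spec, stim_pulse(0, 0.1), t_end_ms = 200 * scale + 50,
                           record_at = 0.5)
      sd_pop(sim$v[sim$time > 20, 1])
    })
    return(list(diameter_um = diams,
                resting_sd_mV = unlist(out)))
  }
  if (what == "fig4") {
    spec <- axon_preset("squid_hh", diameter_um = 0.2)
    ens <- run_single_ap_protocol(spec, n_trials = max(10, round(50 * scale)),
                                  record_at = c(0.45, 0.95))
    prof <- align_and_profile(ens$waveforms[[2]], ens$grid)
    return(list(profile = prof, n = prof$n))
  }
  if (what == "fig5") {
    diams <- c(0.2, 0.5, 1.0)
    n_tr <- max(10, round(50 * scale))
    cvs <- t(vapply(diams, function(d) {
      spec <- axon_preset("squid_hh", diameter_um = d)
      ens <- run_single_ap_protocol(spec, n_trials = n_tr,
                                    record_at = c(0.45, 0.95))
      ev <- ens$events[ens$events$position == 0.95, ]
      c(height = cv_pct(ev$height_mV), width = cv_pct(ev$width_ms))
    }, c(height = 0, width = 0)))
    fit_h <- fit_power_law(diams, cvs[, "height"])
    fit_w <- fit_power_law(diams, cvs[, "width"])
    return(list(diameter_um = diams, cv = cvs,
                exponent_height = fit_h$exponent,
                exponent_width = fit_w$exponent,
                r2_height = fit_h$r2, r2_width = fit_w$r2))
  }
  # fig7 / fig8 / table1 share the spike-train + cascade pipeline
  spec <- axon_preset("rat_interneuron", diameter_um = 0.2,
                      g_leak_mS_cm2 = 0.05)
  train <- run_spike_train_protocol(spec,
                                    duration_ms = max(2000, 30000 * scale))
  distal <- length(train$positions)
  ev <- train$events[[distal]]
  if (what == "fig7") {
    prof <- align_and_profile(train$waveforms[[distal]], train$grid)
    stats_tab <- feature_statistics(ev)
    return(list(rate_hz = train$rate_hz, features = stats_tab,
                profile = prof))
  }
  casc <- cascade_statistics(train$waveforms[[distal]],
                             dt = train$grid[2] - train$grid[1],
                             widths_ms = ev$width_ms)
  if (what == "fig8") {
    pa <- casc$per_ap
    return(list(
      peak_rate = c(mean = mean(pa$peak_rate_s), sd = sd_pop(pa$peak_rate_s)),
      released = c(mean = mean(pa$released), sd = sd_pop(pa$released)),
      n = nrow(pa)))
  }
  list(cv_table = casc$cv, n = nrow(casc$per_ap), rate_hz = train$rate_hz)
}
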