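#' Detect action potentials in a membrane-potential trace
#'
#' Threshold discriminator: each suprathreshold excursion yields one event.
#' The alignment time is the rising crossing of the alignment level
#' (`align_frac` of the resting-to-peak amplitude, default the half-peak),
#' computed by linear interpolation between the samples straddling the
#' level. Height is peak minus resting potential; width is the delay
#' between the rising and falling crossings of the mid-height level. A
#' refractory lockout prevents double counting; an excursion that does not
#' cross back below the mid-height level before the trace ends is discarded
#' with a warning.
#'
#' @param time uniformly sampled time stamps (ms).
#' @param v membrane potential (mV).
#' @param v_rest resting potential (mV).
#' @param threshold detection threshold (mV); default `v_rest + 40`.
#' @param lockout_ms refractory lockout between alignment times (ms).
#' @param align_frac fraction of the resting-to-peak amplitude at which the
#'   waveform is aligned (0.5 = half-peak).
#' @return data frame, one row per AP: `t_align`, `t_peak`, `peak_mV`
#'   (absolute peak potential), `height_mV` (resting-to-peak), `width_ms`.
#' @examples
#' t <- seq(0, 10, by = 0.01)
#' v <- rep(-65, length(t))  # flat trace at rest
#' nrow(detect_aps(t, v, -65))  # 0
#' @export
detect_aps <- function(time, v, v_rest, threshold = v_rest + 40,
                       lockout_ms = 2, align_frac = 0.5) {
  stopifnot(length(time) == length(v))
  empty <- data.frame(t_align = numeric(0), t_peak = numeric(0),
                      peak_mV = numeric(0), height_mV = numeric(0),
                      width_ms = numeric(0))
  above <- v >= threshold
  if (!any(above)) return(empty)
  d <- diff(above)
  starts <- which(d == 1) + 1L
  ends <- which(d == -1)
  if (above[1]) starts <- c(1L, starts)
  if (above[length(v)]) ends <- c(ends, length(v))
  out <- list()
  last_align <- -Inf
  n_discard <- 0L
  for (k in seq_along(starts)) {
    i0 <- starts[k]; i1 <- ends[k]
    ipk <- i0 - 1L + which.max(v[i0:i1])
    peak <- v[ipk]
    height <- peak - v_rest
    lv_align <- v_rest + align_frac * height
    lv_half <- v_rest + 0.5 * height
    # rising crossing of the alignment level (search backwards from peak)
    ir <- ipk
    while (ir > 1 && v[ir - 1] >= lv_align) ir <- ir - 1L
    if (ir == 1 && v[1] >= lv_align) next  # truncated at trace start
    t_align <- cross_time(time, v, ir - 1L, lv_align)
    # rising and falling crossings of the mid-height level (width)
    iw <- ipk
    while (iw > 1 && v[iw - 1] >= lv_half) iw <- iw - 1L
    t_up <- cross_time(time, v, iw - 1L, lv_half)
    jf <- ipk
    while (jf < length(v) && v[jf + 1] >= lv_half) jf <- jf + 1L
    if (jf >= length(v)) {
      n_discard <- n_discard + 1L
      next
    }
    t_down <- cross_time(time, v, jf, lv_half)
    if (t_align < last_align + lockout_ms) next
    last_align <- t_align
    out[[length(out) + 1L]] <-
      data.frame(t_align = t_align, t_peak = time[ipk], peak_mV = peak,
                 height_mV = height, width_ms = t_down - t_up)
  }
  if (n_discard > 0)
    warning(n_discard, " suprathreshold excursion(s) did not return below ",
            "the half-height level before the trace end; discarded")
  if (!length(out)) return(empty)
  do.call(rbind, out)
}

# linear interpolation of the time at which v crosses `level` between
# samples i and i+1
cross_time <- function(time, v, i, level) {
  if (i < 1) return(time[1])
  time[i] + (time[i + 1] - time[i]) * (level - v[i]) / (v[i + 1] - v[i])
}

#' Resample a waveform window aligned at a crossing time
#'
#' @param time uniformly sampled time stamps (ms).
#' @param v membrane potential (mV).
#' @param t_align alignment time (ms).
#' @param grid relative time grid (ms, e.g. `seq(-1, 3, by = 0.01)`).
#' @return numeric vector of `v` linearly interpolated at `t_align + grid`
#'   (NA outside the trace, with a warning).
#' @export
sample_waveform <- function(time, v, t_align, grid) {
  dt <- time[2] - time[1]
  x <- (t_align + grid - time[1]) / dt
  i <- floor(x)
  w <- x - i
  i <- i + 1L   # 1-based left sample
  ok <- i >= 1L & i < length(v)
  if (!all(ok))
    warning("waveform window exceeds the available trace; trimmed to NA")
  out <- rep(NA_real_, length(grid))
  out[ok] <- v[i[ok]] * (1 - w[ok]) + v[i[ok] + 1L] * w[ok]
  out
}

#' Mean waveform and variability envelope of an aligned AP ensemble
#'
#' Waveforms are assumed already resampled onto a common grid relative to
#' their alignment times (as produced by the protocol runners or
#' [sample_waveform()]). Returns the pointwise mean, population SD, the
#' 3xSD envelope and 1-99% quantile bands.
#'
#' @param waveforms matrix, one row per AP, columns on the common grid.
#' @param grid relative time grid (ms).
#' @return object of class `waveform_profile` with elements `grid`, `mean`,
#'   `sd`, `sd3_lo`, `sd3_hi`, `q01`, `q99`, `n`.
#' @export
align_and_profile <- function(waveforms, grid) {
  stopifnot(is.matrix(waveforms), ncol(waveforms) == length(grid))
  if (nrow(waveforms) < 2) stop("need at least 2 aligned waveforms")
  m <- colMeans(waveforms)
  s <- apply(waveforms, 2, sd_pop)
  structure(list(grid = grid, mean = m, sd = s,
                 sd3_lo = m - 3 * s, sd3_hi = m + 3 * s,
                 q01 = apply(waveforms, 2, stats::quantile, 0.01),
                 q99 = apply(waveforms, 2, stats::quantile, 0.99),
                 n = nrow(waveforms)),
            class = "waveform_profile")
}

#' @export
print.waveform_profile <- function(x, ...) {
  cat("Waveform profile of", x$n, "APs on [", min(x$grid), ",", max(x$grid),
      "] ms; max SD =", round(max(x$sd), 3), "mV at t =",
      round(x$grid[which.max(x$sd)], 3), "ms\n")
  invisible(x)
}

#' @export
plot.waveform_profile <- function(x, ...) {
  graphics::plot(x$grid, x$mean, type = "l", lwd = 2,
                 ylim = range(x$sd3_lo, x$sd3_hi),
                 xlab = "time from alignment (ms)", ylab = "V (mV)", ...)
  graphics::lines(x$grid, x$sd3_lo, lty = 2)
  graphics::lines(x$grid, x$sd3_hi, lty = 2)
  invisible(x)
}

# population (not sample) standard deviation; the package convention for
# all variability statistics (negligible difference at the ensemble sizes
# used, but stated for reproducibility)
sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

cv_pct <- function(x) 100 * sd_pop(x) / mean(x)

#' Mean, SD and CV of AP width and height
#'
#' Coefficient of variation is SD/mean; the population SD convention is
#' used throughout.
#'
#' @param events AP event table from [detect_aps()] (needs columns
#'   `width_ms`, `height_mV`).
#' @return data frame with one row per feature: n, mean, sd, cv_pct.
#' @export
feature_statistics <- function(events) {
  stopifnot(nrow(events) >= 2)
  data.frame(
    feature = c("width_ms", "height_mV"),
    n = nrow(events),
    mean = c(mean(events$width_ms), mean(events$height_mV)),
    sd = c(sd_pop(events$width_ms), sd_pop(events$height_mV)),
    cv_pct = c(cv_pct(events$width_ms), cv_pct(events$height_mV)))
}

#' Per-AP feature change between two recording sites
#'
#' Matches APs detected at an upstream site A with the same APs at a
#' downstream site B and computes per-AP feature differences (B - A), their
#' population SD, and the Pearson correlation of the features at the two
#' sites. When both event tables carry a `trial` column, matching is by
#' trial; otherwise the k-th AP at A is matched to the first AP at B whose
#' alignment time falls within `(t_A, t_A + max_delay_ms]` (propagation
#' delay window). Unmatched events are dropped and counted.
#'
#' @param events_a,events_b event tables from [detect_aps()].
#' @param max_delay_ms maximum propagation delay for time matching (ms).
#' @return list: `diff` (matched per-AP differences), `sd_dheight_mV`,
#'   `sd_dwidth_ms`, `cor_height`, `cor_width`, `n_matched`, `n_dropped`.
#' @export
pairwise_feature_change <- function(events_a, events_b, max_delay_ms = 20) {
  if (!is.null(events_a$trial) && !is.null(events_b$trial)) {
    common <- intersect(events_a$trial, events_b$trial)
    a <- events_a[match(common, events_a$trial), ]
    b <- events_b[match(common, events_b$trial), ]
  } else {
    ia <- ib <- integer(0)
    j0 <- 1L
    for (i in seq_len(nrow(events_a))) {
      ta <- events_a$t_align[i]
      j <- which(events_b$t_align > ta &
                   events_b$t_align <= ta + max_delay_ms)
      j <- j[j >= j0]
      if (length(j)) {
        ia <- c(ia, i); ib <- c(ib, j[1]); j0 <- j[1] + 1L
      }
    }
    a <- events_a[ia, ]; b <- events_b[ib, ]
  }
  n_matched <- nrow(a)
  if (n_matched < 2) stop("fewer than 2 matched AP pairs")
  dh <- b$height_mV - a$height_mV
  dw <- b$width_ms - a$width_ms
  list(diff = data.frame(t_align_a = a$t_align, dheight_mV = dh,
                         dwidth_ms = dw),
       sd_dheight_mV = sd_pop(dh), sd_dwidth_ms = sd_pop(dw),
       cor_height = stats::cor(a$height_mV, b$height_mV),
       cor_width = stats::cor(a$width_ms, b$width_ms),
       n_matched = n_matched,
       n_dropped = nrow(events_a) + nrow(events_b) - 2 * n_matched)
}

#' Correlation of waveform deviations between recording sites vs distance
#'
#' For each pair of recording positions, the per-AP waveform deviations
#' (individual aligned waveform minus the positionwise mean waveform) are
#' correlated and averaged over APs, giving a correlation-vs-separation
#' curve; a Spearman rank test of monotone decrease with distance is
#' reported. Deterministic ensembles have zero variance everywhere and the
#' correlation is reported as `NA`.
#'
#' @param waveforms list over positions of aligned-window matrices with
#'   matching rows (same APs/trials).
#' @param positions recording positions (fractions of axon length).
#' @param length_um axon length, to express separation in um (optional).
#' @return data frame of position pairs with separation and mean
#'   correlation, with the trend test in attributes `trend_rho`,
#'   `trend_p`.
#' @export
correlation_vs_distance <- function(waveforms, positions, length_um = NULL) {
  stopifnot(length(waveforms) == length(positions), length(positions) >= 3)
  devs <- lapply(waveforms, function(w) sweep(w, 2, colMeans(w)))
  pairs <- utils::combn(length(positions), 2)
  res <- apply(pairs, 2, function(ij) {
    a <- devs[[ij[1]]]; b <- devs[[ij[2]]]
    if (sd_pop(as.vector(a)) == 0 || sd_pop(as.vector(b)) == 0)
      return(NA_real_)
    mean(vapply(seq_len(nrow(a)), function(r) {
      if (stats::sd(a[r, ]) == 0 || stats::sd(b[r, ]) == 0) return(NA_real_)
      stats::cor(a[r, ], b[r, ])
    }, numeric(1)), na.rm = TRUE)
  })
  sep <- abs(positions[pairs[2, ]] - positions[pairs[1, ]])
  if (!is.null(length_um)) sep <- sep * length_um
  out <- data.frame(pos_a = positions[pairs[1, ]],
                    pos_b = positions[pairs[2, ]],
                    separation = sep, correlation = res)
  if (all(is.finite(res)) && length(unique(sep)) > 2) {
    ct <- suppressWarnings(
      stats::cor.test(sep, res, method = "spearman",
                      alternative = "less"))
    attr(out, "trend_rho") <- unname(ct$estimate)
    attr(out, "trend_p") <- ct$p.value
  } else {
    attr(out, "trend_rho") <- NA_real_
    attr(out, "trend_p") <- NA_real_
  }
  out
}

#' Fit the power-law scaling of waveform variability with axon diameter
#'
#' Least-squares straight line in log-log coordinates; the fitted exponent
#' is the slope. Channel-noise theory predicts CV growing as d^(-3/4) as
#' diameter decreases.
#'
#' @param diameters_um axon diameters (um), at least 3.
#' @param cvs coefficients of variation (any positive unit); non-positive
#'   values are excluded with a warning.
#' @return object of class `power_law_fit`: `exponent`, `intercept`
#'   (log-log), `r2`, and the data.
#' @examples
#' f <- fit_power_law(c(0.2, 0.5, 1), 3 * c(0.2, 0.5, 1)^-0.75)
#' coef(f)["exponent"]  # -0.75
#' @export
fit_power_law <- function(diameters_um, cvs) {
  stopifnot(length(diameters_um) == length(cvs))
  bad <- !(cvs > 0)
  if (any(bad)) {
    warning(sum(bad), " non-positive CV value(s) excluded from the fit")
    diameters_um <- diameters_um[!bad]
    cvs <- cvs[!bad]
  }
  if (length(cvs) < 3) stop("need at least 3 positive CVs")
  fit <- stats::lm(log(cvs) ~ log(diameters_um))
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((log(cvs) - mean(log(cvs)))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  structure(list(exponent = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r2 = r2,
                 diameters_um = diameters_um, cvs = cvs, lm = fit),
            class = "power_law_fit")
}

#' @export
coef.power_law_fit <- function(object, ...) {
  c(exponent = object$exponent, intercept = object$intercept)
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat("Power-law fit: CV ~ d^", round(x$exponent, 3), " (R2 = ",
      round(x$r2, 4), ", n = ", length(x$cvs), ")\n", sep = "")
  invisible(x)
}

#' @export
plot.power_law_fit <- function(x, ...) {
  graphics::plot(x$diameters_um, x$cvs, log = "xy",
                 xlab = "diameter (um)", ylab = "CV", ...)
  d <- exp(seq(log(min(x$diameters_um)), log(max(x$diameters_um)),
               length.out = 50))
  graphics::lines(d, exp(x$intercept) * d^x$exponent)
  invisible(x)
}
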