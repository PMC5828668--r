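#' Detect CAP peaks in one sweep
#'
#' Within each component's search window, the latency is the time of the most
#' negative voltage and the amplitude is measured from the preceding positive
#' peak (the maximum voltage between the window start and the negative peak)
#' to the negative peak. Default windows scale with electrode separation:
#' N1 searches (blank, blank + d/0.8 m/s\] and N2 the remainder up to
#' blank + d/0.1 m/s. A component is reported absent (`NA`, never a
#' fabricated latency) when its trough does not fall below the pre-stimulus
#' baseline mean by at least `prominence_sd` baseline noise SDs; the default
#' of 5 SDs keeps the extreme value of pure Gaussian noise across a
#' several-hundred-sample window from registering as a peak.
#'
#' @param trace a [cap_trace].
#' @param blank_ms post-stimulus blanking (ms) excluded from both windows.
#' @param n1_window_ms,n2_window_ms optional explicit windows
#'   `c(start, end)` in ms after the stimulus, overriding the
#'   distance-scaled defaults. Windows must be disjoint and after the blank.
#' @param prominence_sd absence threshold in baseline-noise SDs.
#' @param abs_prominence absolute trough-depth floor (voltage units) below
#'   which a component is absent even in noiseless records; keeps the tail of
#'   a neighboring deflection from registering as a peak.
#' @return data frame with rows `N1` and `N2`: component, latency_ms,
#'   amplitude, detected.
#' @export
detect_cap_peaks <- function(trace, blank_ms = 0.2,
                             n1_window_ms = NULL, n2_window_ms = NULL,
                             prominence_sd = 5, abs_prominence = 0.01) {
  stopifnot(inherits(trace, "cap_trace"))
  d <- trace$distance_mm
  if (is.null(n1_window_ms)) n1_window_ms <- c(blank_ms, blank_ms + d / 0.8)
  if (is.null(n2_window_ms)) n2_window_ms <- c(n1_window_ms[2], blank_ms + d / 0.1)
  if (n1_window_ms[1] < blank_ms || n2_window_ms[1] < n1_window_ms[2]) {
    stop("detect_cap_peaks: windows must be disjoint and after the blank")
  }
  t_rel <- trace$time_ms - trace$stimulus_time_ms
  if (n2_window_ms[2] > max(t_rel) || n1_window_ms[1] < min(t_rel)) {
    stop("detect_cap_peaks: search window outside the record")
  }
  base <- trace$voltage[t_rel < 0]
  base_mean <- if (length(base)) mean(base) else 0
  base_sd <- if (length(base) > 1) sd(base) else 0

  one <- function(win, comp) {
    idx <- which(t_rel > win[1] & t_rel <= win[2])
    v <- trace$voltage[idx]
    i_min <- which.min(v)
    trough <- v[i_min]
    detected <- trough < base_mean - prominence_sd * base_sd &&
      trough < base_mean - abs_prominence
    if (!detected) {
      return(data.frame(component = comp, latency_ms = NA_real_,
                        amplitude = NA_real_, detected = FALSE))
    }
    pre_pos <- max(v[seq_len(i_min)])
    data.frame(component = comp, latency_ms = t_rel[idx[i_min]],
               amplitude = pre_pos - trough, detected = TRUE)
  }
  rbind(one(n1_window_ms, "N1"), one(n2_window_ms, "N2"))
}

#' Average per-sweep latencies at one distance
#'
#' Arithmetic mean over the sweeps in which the component was detected; the
#' number of missed sweeps is reported. If every sweep missed the component,
#' the component is absent at that distance (`mean_latency_ms = NA`).
#'
#' @param latencies_ms per-sweep latencies, `NA` where undetected.
#' @return list: `mean_latency_ms`, `n_detected`, `n_missing`.
#' @export
mean_sweep_latency <- function(latencies_ms) {
  stopifnot(length(latencies_ms) >= 1L)
  det <- latencies_ms[!is.na(latencies_ms)]
  list(mean_latency_ms = if (length(det)) mean(det) else NA_real_,
       n_detected = length(det),
       n_missing = sum(is.na(latencies_ms)))
}

#' Build a latency-distance series from sweeps
#'
#' Runs [detect_cap_peaks()] on every sweep and averages per distance with
#' [mean_sweep_latency()].
#'
#' @param sweeps list of [cap_trace] objects.
#' @param component `"N1"` or `"N2"`.
#' @param ... passed to [detect_cap_peaks()].
#' @return data frame: distance_mm, mean_latency_ms, n_detected, n_missing.
#' @export
latency_distance_series <- function(sweeps, component = c("N1", "N2"), ...) {
  component <- match.arg(component)
  dist <- vapply(sweeps, `[[`, numeric(1), "distance_mm")
  lat <- vapply(sweeps, function(s) {
    pk <- detect_cap_peaks(s, ...)
    pk$latency_ms[pk$component == component]
  }, numeric(1))
  out <- lapply(sort(unique(dist)), function(d) {
    m <- mean_sweep_latency(lat[dist == d])
    data.frame(distance_mm = d, mean_latency_ms = m$mean_latency_ms,
               n_detected = m$n_detected, n_missing = m$n_missing)
  })
  do.call(rbind, out)
}

#' Conduction velocity from a latency-distance series
#'
#' Ordinary least squares of mean latency (ms) on distance (mm); the slope is
#' the inverse of the conduction velocity (ms/mm inverts to mm/ms = m/s). The
#' slope standard error and r^2 are returned for genotype comparison by
#' ANCOVA ([compare_slopes()]). A non-positive slope yields an undefined
#' velocity (`NA`) with a diagnostic message attached.
#'
#' @param series data frame with columns `distance_mm` and `mean_latency_ms`
#'   (rows with `NA` latency are dropped); >= 2 distinct distances required.
#' @param component label carried into the result.
#' @return object of class `cv_result`: component, slope_ms_per_mm,
#'   slope_se, intercept_ms, r_squared, velocity_m_per_s, diagnostic.
#' @export
fit_conduction_velocity <- function(series, component = "N1") {
  series <- series[!is.na(series$mean_latency_ms), , drop = FALSE]
  if (length(unique(series$distance_mm)) < 2L) {
    stop("fit_conduction_velocity: need >= 2 distinct distances with latencies")
  }
  fit <- lm(mean_latency_ms ~ distance_mm, data = series)
  # noiseless calibration series fit exactly; the perfect-fit warning from
  # summary.lm is expected there, not a problem
  sm <- withCallingHandlers(
    summary(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  slope <- coef(fit)[["distance_mm"]]
  vel <- if (slope > 0) 1 / slope else NA_real_
  structure(list(
    component = component,
    slope_ms_per_mm = slope,
    slope_se = sm$coefficients["distance_mm", "Std. Error"],
    intercept_ms = coef(fit)[["(Intercept)"]],
    r_squared = sm$r.squared,
    velocity_m_per_s = vel,
    diagnostic = if (slope <= 0) {
      sprintf("non-positive slope (%.4g ms/mm): velocity undefined", slope)
    } else NA_character_,
    fit = fit
  ), class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%s: slope %.4g ms/mm (SE %.3g), velocity %s m/s, r^2 %.4f\n",
              x$component, x$slope_ms_per_mm, x$slope_se,
              if (is.na(x$velocity_m_per_s)) "undefined" else
                sprintf("%.4g", x$velocity_m_per_s),
              x$r_squared))
  if (!is.na(x$diagnostic)) cat(" ", x$diagnostic, "\n")
  invisible(x)
}

#' CAP amplitude versus stimulus level
#'
#' Detects the chosen component in each trace and tabulates its amplitude
#' against the stimulus current. Undetected components (e.g. at 0 mA)
#' contribute amplitude 0, so the curve starts at the origin.
#'
#' @param traces list of [cap_trace] objects spanning stimulus levels.
#' @param component which deflection to measure (default `"N2"`).
#' @param ... passed to [detect_cap_peaks()].
#' @return data frame: stimulus_mA, amplitude (mean over sweeps per level).
#' @export
amplitude_curve <- function(traces, component = "N2", ...) {
  stim <- vapply(traces, `[[`, numeric(1), "stimulus_mA")
  amp <- vapply(traces, function(s) {
    pk <- detect_cap_peaks(s, ...)
    a <- pk$amplitude[pk$component == component]
    if (is.na(a)) 0 else a
  }, numeric(1))
  out <- lapply(sort(unique(stim)), function(s) {
    data.frame(stimulus_mA = s, amplitude = mean(amp[stim == s]))
  })
  do.call(rbind, out)
}

#' Short-time Fourier power of an LFP signal
#'
#' One-sided power spectral density over sliding windows (default 1 s Hamming
#' window with 90% overlap, giving 1 Hz frequency resolution). Scaling is
#' such that summing `power x df` over frequencies recovers the signal
#' variance of each window (Welch PSD convention, window-corrected).
#'
#' @param x numeric signal.
#' @param sampling_hz sampling rate.
#' @param window_s window length in seconds (default 1).
#' @param overlap_fraction fractional overlap in \[0, 1) (default 0.9).
#' @param window_fn `"hamming"` or `"rect"`.
#' @return object of class `spectrogram`: `power` (frequency x window
#'   matrix), `freq_hz`, `time_s` (window centers), `df_hz`.
#' @export
spectrogram_power <- function(x, sampling_hz, window_s = 1,
                              overlap_fraction = 0.9,
                              window_fn = c("hamming", "rect")) {
  window_fn <- match.arg(window_fn)
  stopifnot(overlap_fraction >= 0, overlap_fraction < 1,
            window_s * sampling_hz >= 2)
  n <- as.integer(round(window_s * sampling_hz))
  if (length(x) < n) stop("spectrogram_power: record shorter than one window")
  hop <- max(1L, as.integer(round(n * (1 - overlap_fraction))))
  w <- if (window_fn == "hamming") {
    0.54 - 0.46 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
  } else rep(1, n)
  starts <- seq(1L, length(x) - n + 1L, by = hop)
  nf <- n %/% 2L + 1L
  pow <- matrix(0, nf, length(starts))
  scale <- sampling_hz * sum(w^2)
  for (j in seq_along(starts)) {
    seg <- x[starts[j]:(starts[j] + n - 1L)] * w
    sp <- fft(seg)[seq_len(nf)]
    p <- (Mod(sp)^2) / scale
    # one-sided: double all bins except DC (and Nyquist for even n)
    dbl <- rep(2, nf)
    dbl[1] <- 1
    if (n %% 2L == 0L) dbl[nf] <- 1
    pow[, j] <- p * dbl
  }
  structure(list(power = pow,
                 freq_hz = (seq_len(nf) - 1) * sampling_hz / n,
                 time_s = (starts - 1 + (n - 1) / 2) / sampling_hz,
                 df_hz = sampling_hz / n,
                 window_s = window_s,
                 overlap_fraction = overlap_fraction),
            class = "spectrogram")
}

#' Stimulus-induced band power change
#'
#' Mean band power in the response window minus mean band power in the
#' baseline window. A spectrogram window belongs to an interval when its
#' center falls inside `[start, end)`; band membership is
#' `f_low <= f <= f_high`.
#'
#' @param sp a `spectrogram` from [spectrogram_power()].
#' @param band `c(f_low, f_high)` in Hz, inside Nyquist.
#' @param baseline_window,response_window `c(start, end)` in seconds.
#' @return list: `baseline`, `response`, `delta`.
#' @export
band_power_change <- function(sp, band, baseline_window, response_window) {
  stopifnot(inherits(sp, "spectrogram"), band[1] < band[2],
            band[2] <= max(sp$freq_hz))
  fsel <- sp$freq_hz >= band[1] & sp$freq_hz <= band[2]
  pick <- function(win) {
    tsel <- sp$time_s >= win[1] & sp$time_s < win[2]
    if (!any(tsel)) stop("band_power_change: no spectrogram window in [",
                         win[1], ", ", win[2], ") s")
    mean(sp$power[fsel, tsel])
  }
  b <- pick(baseline_window)
  r <- pick(response_window)
  list(baseline = b, response = r, delta = r - b)
}

#' Per-trial band power deltas of a recording
#'
#' Convenience wrapper: spectrogram per trial, then [band_power_change()] per
#' band, with the baseline window the 1 s ending at odor onset and the
#' response window 0.5-2.5 s after onset (the lick-scoring epoch).
#'
#' @param rec an `lfp_recording`.
#' @param bands named list of `c(f_low, f_high)` pairs; defaults to theta
#'   (6-14 Hz) and beta (15-30 Hz).
#' @param baseline_window,response_window seconds, relative to trial start;
#'   defaults derived from `rec$odor_onset_s`.
#' @param ... passed to [spectrogram_power()].
#' @return data frame: trial, label, band, baseline, response, delta.
#' @export
lfp_band_deltas <- function(rec,
                            bands = list(theta = c(6, 14), beta = c(15, 30)),
                            baseline_window = NULL, response_window = NULL,
                            ...) {
  stopifnot(inherits(rec, "lfp_recording"))
  on <- rec$odor_onset_s
  baseline_window <- baseline_window %||% c(on - 1, on)
  response_window <- response_window %||% c(on + 0.5, on + 2.5)
  rows <- list()
  for (i in seq_along(rec$trials)) {
    sp <- spectrogram_power(rec$trials[[i]]$signal, rec$sampling_hz, ...)
    for (bn in names(bands)) {
      ch <- band_power_change(sp, bands[[bn]], baseline_window,
                              response_window)
      rows[[length(rows) + 1L]] <- data.frame(
        trial = i, label = rec$trials[[i]]$label, band = bn,
        baseline = ch$baseline, response = ch$response, delta = ch$delta,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' Compare band power between groups
#'
#' Two-sided Mann-Whitney U test per band (exact null distribution when both
#' groups have n <= 8 and there are no ties; normal approximation with tie
#' correction otherwise), followed by Benjamini-Hochberg correction across
#' bands. Two identical constant groups give p = 1 by convention.
#'
#' @param deltas_a,deltas_b named lists (band -> numeric deltas) or a single
#'   numeric vector each (one band). Each group needs >= 3 values.
#' @return data frame: band, U, p, q.
#' @export
compare_band_power <- function(deltas_a, deltas_b) {
  if (is.numeric(deltas_a)) deltas_a <- list(band = deltas_a)
  if (is.numeric(deltas_b)) deltas_b <- list(band = deltas_b)
  stopifnot(identical(names(deltas_a), names(deltas_b)))
  rows <- lapply(names(deltas_a), function(bn) {
    a <- deltas_a[[bn]]; b <- deltas_b[[bn]]
    stopifnot(length(a) >= 3L, length(b) >= 3L)
    if (length(unique(c(a, b))) == 1L) {
      return(data.frame(band = bn, U = length(a) * length(b) / 2, p = 1))
    }
    ties <- anyDuplicated(c(a, b)) > 0L
    use_exact <- !ties && length(a) <= 8L && length(b) <= 8L
    wt <- suppressWarnings(
      wilcox.test(a, b, alternative = "two.sided", exact = use_exact,
                  correct = !use_exact)
    )
    data.frame(band = bn, U = unname(wt$statistic), p = wt$p.value)
  })
  out <- do.call(rbind, rows)
  out$q <- p.adjust(out$p, method = "BH")
  out
}
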