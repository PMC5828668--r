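#' Compound action potential sweep
#'
#' @param time_ms strictly increasing, uniformly sampled time axis (ms),
#'   relative to the stimulus (`stimulus_time_ms = 0` means the stimulus falls
#'   at time 0; samples before it are pre-stimulus baseline).
#' @param voltage recorded voltage, arbitrary units.
#' @param stimulus_time_ms stimulus time on the `time_ms` axis.
#' @param stimulus_mA stimulus current.
#' @param distance_mm stimulating-to-recording electrode separation.
#' @param sweep_index acquisition sweep number.
#' @return object of class `cap_trace`.
#' @export
cap_trace <- function(time_ms, voltage, stimulus_time_ms = 0,
                      stimulus_mA = NA_real_, distance_mm = NA_real_,
                      sweep_index = 1L) {
  stopifnot(length(time_ms) == length(voltage), length(time_ms) >= 2L)
  dt <- diff(time_ms)
  if (any(dt <= 0) || max(abs(dt - dt[1])) > 1e-9 * dt[1]) {
    stop("cap_trace: time must be strictly increasing with a uniform step")
  }
  if (stimulus_time_ms < time_ms[1] || stimulus_time_ms > time_ms[length(time_ms)]) {
    stop("cap_trace: stimulus time outside the record")
  }
  structure(list(time_ms = time_ms, voltage = voltage,
                 stimulus_time_ms = stimulus_time_ms,
                 stimulus_mA = stimulus_mA, distance_mm = distance_mm,
                 sweep_index = as.integer(sweep_index)),
            class = "cap_trace")
}

# Hill saturation of deflection amplitude with stimulus current.
cap_amplitude_factor <- function(spec, stimulus_mA) {
  s <- stimulus_mA
  s^spec$hill_exponent / (s^spec$hill_exponent + spec$hill_s50_mA^spec$hill_exponent)
}

#' Generate synthetic CAP sweeps
#'
#' Each sweep is baseline Gaussian noise plus two negative Gaussian-shaped
#' deflections centered at `onset_offset_ms + d / v` (ms) for the fast (N1)
#' and slow (N2) components, with independent per-sweep latency jitter.
#' `null_like = TRUE` omits the N1 deflection, emulating a record in which the
#' fast myelinated component is absent. Deflection depths scale with the
#' stimulus current through a saturating Hill curve.
#'
#' @param spec a [cap_sim_spec()].
#' @param null_like omit the N1 deflection?
#' @param stimulus_mA stimulus current; defaults to `spec$stimulus_mA`.
#' @return list of [cap_trace] objects (distances nested over sweeps), with
#'   the generator seed attached as attribute `seed`.
#' @export
#' @examples
#' sw <- generate_cap_sweeps(cap_sim_spec(latency_jitter_ms_sd = 0, noise_sd = 0))
#' length(sw) # 4 distances x 4 sweeps
generate_cap_sweeps <- function(spec, null_like = FALSE,
                                stimulus_mA = spec$stimulus_mA) {
  stopifnot(inherits(spec, "cap_sim_spec"))
  dt_ms <- 1 / spec$sampling_khz
  amp_fac <- cap_amplitude_factor(spec, stimulus_mA)
  sweeps <- with_seed(spec$seed, {
    out <- list()
    for (d in spec$distances_mm) {
      dur_ms <- spec$onset_offset_ms + d / 0.1 + 2 # covers the N2 window
      tt <- seq(-spec$pre_ms, dur_ms, by = dt_ms)
      for (sw in seq_len(spec$sweeps_per_distance)) {
        v <- if (spec$noise_sd > 0) rnorm(length(tt), 0, spec$noise_sd) else
          numeric(length(tt))
        c2 <- spec$onset_offset_ms + d / spec$v_n2_m_per_s +
          rnorm(1, 0, spec$latency_jitter_ms_sd)
        v <- v - amp_fac * spec$amp_n2 *
          exp(-(tt - c2)^2 / (2 * spec$width_n2_ms^2))
        if (!null_like) {
          c1 <- spec$onset_offset_ms + d / spec$v_n1_m_per_s +
            rnorm(1, 0, spec$latency_jitter_ms_sd)
          v <- v - amp_fac * spec$amp_n1 *
            exp(-(tt - c1)^2 / (2 * spec$width_n1_ms^2))
        } else {
          rnorm(1) # keep the RNG stream aligned across modes
        }
        out[[length(out) + 1L]] <- cap_trace(
          time_ms = tt, voltage = v, stimulus_time_ms = 0,
          stimulus_mA = stimulus_mA, distance_mm = d, sweep_index = sw
        )
      }
    }
    out
  })
  attr(sweeps, "seed") <- spec$seed
  sweeps
}
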