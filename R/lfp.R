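#' Generate a synthetic LFP recording
#'
#' Per trial, each configured band contributes a sum of sinusoids at 1 Hz
#' spacing across the band with independent random phases, scaled so that the
#' band's RMS equals `amplitude / sqrt(2)`; the amplitude switches from
#' `baseline_amplitude` to `response_amplitude` at odor onset and back at odor
#' offset. Broadband Gaussian noise is added throughout. Event times and trial
#' labels are recorded, and a fixed seed reproduces the recording
#' bit-identically.
#'
#' @param spec an [lfp_sim_spec()].
#' @return object of class `lfp_recording`: `trials` (list of
#'   `list(signal, label)`), `sampling_hz`, `odor_onset_s`, `odor_duration_s`,
#'   `seed`.
#' @export
generate_lfp <- function(spec) {
  stopifnot(inherits(spec, "lfp_sim_spec"))
  fs <- spec$sampling_hz
  dur_s <- spec$odor_onset_s + spec$odor_duration_s + spec$post_s
  n <- as.integer(round(dur_s * fs))
  tt <- (seq_len(n) - 1) / fs
  in_odor <- tt >= spec$odor_onset_s &
    tt < spec$odor_onset_s + spec$odor_duration_s

  with_seed(spec$seed, {
    labels <- rep(names(spec$n_trials), times = spec$n_trials)
    trials <- lapply(labels, function(lab) {
      sig <- numeric(n)
      for (b in spec$bands) {
        freqs <- seq(b$f_low, b$f_high, by = 1)
        scale <- 1 / sqrt(length(freqs))
        osc <- numeric(n)
        for (f in freqs) {
          osc <- osc + sin(2 * pi * f * tt + runif(1, 0, 2 * pi))
        }
        amp <- ifelse(in_odor, b$response_amplitude, b$baseline_amplitude)
        sig <- sig + amp * scale * osc
      }
      if (spec$broadband_noise_sd > 0) {
        sig <- sig + rnorm(n, 0, spec$broadband_noise_sd)
      }
      list(signal = sig, label = lab)
    })
    structure(list(trials = trials, sampling_hz = fs,
                   odor_onset_s = spec$odor_onset_s,
                   odor_duration_s = spec$odor_duration_s,
                   seed = spec$seed),
              class = "lfp_recording")
  })
}
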