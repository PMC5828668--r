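test_that("CAP peak detection finds troughs and measures trough-to-preceding-peak amplitude", {
  # constructed sweep: positive hump +0.2 at 1.0 ms, trough -0.3 at 1.5 ms
  tt <- seq(-1, 6, by = 0.01)
  v <- 0.2 * exp(-(tt - 1.0)^2 / (2 * 0.1^2)) -
    0.3 * exp(-(tt - 1.5)^2 / (2 * 0.1^2)) -
    0.5 * exp(-(tt - 4.0)^2 / (2 * 0.2^2))
  tr <- cap_trace(tt, v, distance_mm = 1)
  pk <- detect_cap_peaks(tr, n1_window_ms = c(0.2, 2.5),
                         n2_window_ms = c(2.5, 5.5))
  n1 <- pk[pk$component == "N1", ]
  expect_equal(n1$latency_ms, 1.5, tolerance = 0.011)
  # amplitude from +a to -b is a + b (the crossing Gaussians shift it slightly)
  expect_equal(n1$amplitude, 0.5, tolerance = 0.02)
  expect_equal(pk$latency_ms[pk$component == "N2"], 4.0, tolerance = 0.011)

  expect_error(detect_cap_peaks(tr, n1_window_ms = c(0.2, 2),
                                n2_window_ms = c(2, 50)),
               "outside the record")
})

test_that("absent components are reported absent, never fabricated", {
  nl <- generate_cap_sweeps(cap_sim_spec(seed = 9), null_like = TRUE)
  pk <- do.call(rbind, lapply(nl, detect_cap_peaks))
  expect_true(all(is.na(pk$latency_ms[pk$component == "N1"])))
  expect_true(all(pk$detected[pk$component == "N2"]))

  # absence propagates through the series: no N1 latency at any distance
  ser <- latency_distance_series(nl, "N1")
  expect_true(all(is.na(ser$mean_latency_ms)))
  expect_true(all(ser$n_missing == 4L))
})

test_that("sweep latencies average over detected sweeps and report misses", {
  expect_equal(mean_sweep_latency(c(1, 1, 1, 1))$mean_latency_ms, 1)
  expect_equal(mean_sweep_latency(c(0.9, 1.1))$mean_latency_ms, 1)
  m <- mean_sweep_latency(c(1.0, NA, 1.2, 1.1))
  expect_equal(m$mean_latency_ms, 1.1)
  expect_identical(m$n_missing, 1L)
  all_na <- mean_sweep_latency(c(NA_real_, NA_real_))
  expect_true(is.na(all_na$mean_latency_ms))
})

test_that("conduction velocity is the inverse slope of the latency-distance regression", {
  # exact line: latency = 0.6667 x distance
  ser <- data.frame(distance_mm = c(0.5, 1.0, 1.5, 2.0),
                    mean_latency_ms = c(0.5, 1.0, 1.5, 2.0) / 1.5)
  cv <- fit_conduction_velocity(ser)
  expect_equal(cv$slope_ms_per_mm, 1 / 1.5, tolerance = 1e-12)
  expect_equal(cv$velocity_m_per_s, 1.5, tolerance = 1e-12)
  expect_equal(cv$r_squared, 1)

  # degenerate: flat latencies -> zero slope, undefined velocity
  flat <- data.frame(distance_mm = c(0.5, 1, 1.5), mean_latency_ms = 1)
  cvf <- suppressWarnings(fit_conduction_velocity(flat)) # perfect-fit warning
  expect_true(is.na(cvf$velocity_m_per_s))
  expect_match(cvf$diagnostic, "non-positive")

  # jittered series equals the closed-form OLS oracle
  set.seed(12)
  x <- c(0.5, 1, 1.5, 2)
  y <- 0.3 + x / 1.5 + rnorm(4, 0, 0.02)
  got <- fit_conduction_velocity(data.frame(distance_mm = x,
                                            mean_latency_ms = y))
  oc <- oracle_ols(x, y)
  expect_equal(got$slope_ms_per_mm, unname(oc["slope"]), tolerance = 1e-10)
  expect_equal(got$intercept_ms, unname(oc["intercept"]), tolerance = 1e-10)

  expect_error(fit_conduction_velocity(
    data.frame(distance_mm = 1, mean_latency_ms = 1)), ">= 2 distinct")
})

test_that("the amplitude-stimulus curve rises from zero and saturates", {
  levels <- seq(0, 4, by = 0.25)
  traces <- unlist(lapply(levels, function(s) {
    generate_cap_sweeps(cap_sim_spec(distances_mm = 2,
                                     sweeps_per_distance = 1,
                                     latency_jitter_ms_sd = 0, noise_sd = 0,
                                     seed = 3),
                        stimulus_mA = s)
  }), recursive = FALSE)
  ac <- amplitude_curve(traces)
  expect_identical(nrow(ac), 17L)
  expect_equal(ac$amplitude[ac$stimulus_mA == 0], 0)
  expect_true(all(diff(ac$amplitude) >= -1e-9))
  # saturating recruitment: amplitude at 4 mA within 5% of the asymptote
  expect_gt(ac$amplitude[ac$stimulus_mA == 4], 0.95 * 0.8)
})

test_that("spectrogram power matches the explicit-DFT oracle and Parseval", {
  fs <- 200
  set.seed(41)
  x <- sin(2 * pi * 10 * (0:(6 * fs - 1)) / fs) + rnorm(6 * fs, 0, 0.3)
  sp <- spectrogram_power(x, fs)
  oc <- oracle_stft_power(x, fs)
  expect_equal(sp$power, oc$power, tolerance = 1e-9)
  expect_equal(sp$freq_hz, oc$freq_hz)
  expect_equal(sp$time_s, oc$time_s)

  # 60 s record, 1 s window, 90% overlap -> 591 windows
  long <- rnorm(60 * fs)
  expect_identical(ncol(spectrogram_power(long, fs)$power), 591L)

  # doubling white-noise amplitude quadruples the power
  set.seed(42)
  w1 <- rnorm(3 * fs)
  p1 <- mean(spectrogram_power(w1, fs)$power)
  p2 <- mean(spectrogram_power(2 * w1, fs)$power)
  expect_equal(p2 / p1, 4, tolerance = 1e-9)

  # Parseval: integrated PSD averaged over windows ~ time-domain variance
  set.seed(43)
  wlong <- rnorm(30 * fs)
  splong <- spectrogram_power(wlong, fs)
  expect_equal(mean(colSums(splong$power)) * splong$df_hz, var(wlong),
               tolerance = 0.05)

  expect_error(spectrogram_power(rnorm(10), fs), "shorter than one window")
})

test_that("band power change isolates the responding band", {
  # stationary signal -> delta ~ 0
  fs <- 500
  stat_spec <- lfp_sim_spec(sampling_hz = fs,
                            bands = list(theta = list(f_low = 6, f_high = 14,
                                                      baseline_amplitude = 1,
                                                      response_amplitude = 1)),
                            n_trials = c(rewarded = 1L),
                            broadband_noise_sd = 0, seed = 6)
  rec <- generate_lfp(stat_spec)
  sp <- spectrogram_power(rec$trials[[1]]$signal, fs)
  ch <- band_power_change(sp, c(6, 14), c(0.5, 1.5), c(2.0, 4.0))
  expect_lt(abs(ch$delta), 0.1 * ch$baseline)

  # theta-only response: theta delta > 0, beta delta ~ 0
  resp <- generate_lfp(lfp_sim_spec(sampling_hz = fs,
                                    broadband_noise_sd = 0, seed = 7))
  # default spec raises theta 1 -> 1.5 and beta 0.5 -> 0.8; isolate theta by
  # rebuilding with a flat beta band
  resp2 <- generate_lfp(lfp_sim_spec(
    sampling_hz = fs,
    bands = list(theta = list(f_low = 6, f_high = 14,
                              baseline_amplitude = 1,
                              response_amplitude = 1.5),
                 beta = list(f_low = 15, f_high = 30,
                             baseline_amplitude = 0.5,
                             response_amplitude = 0.5)),
    n_trials = c(rewarded = 2L), broadband_noise_sd = 0.05, seed = 8))
  dl <- lfp_band_deltas(resp2)
  theta <- dl$delta[dl$band == "theta"]
  beta <- dl$delta[dl$band == "beta"]
  expect_true(all(theta > 0))
  expect_true(all(abs(beta) < 0.2 * abs(theta)))

  expect_error(band_power_change(sp, c(6, 14), c(100, 101), c(2, 4)),
               "no spectrogram window")
})

test_that("Mann-Whitney comparisons use the exact null and Benjamini-Hochberg", {
  # identical groups -> p = 1 (constant-group convention)
  same <- compare_band_power(list(b = c(2, 2, 2)), list(b = c(2, 2, 2)))
  expect_equal(same$p, 1)
  expect_equal(same$q, 1)

  # complete separation of 3 vs 3: U = 0, exact two-sided p = 0.1
  sep <- compare_band_power(list(b = c(1, 2, 3)), list(b = c(4, 5, 6)))
  expect_equal(sep$U, 0)
  expect_equal(sep$p, 0.1)

  # exact branch equals full enumeration for group sizes <= 6
  set.seed(15)
  for (sizes in list(c(3, 3), c(4, 5), c(6, 6))) {
    a <- round(rnorm(sizes[1]), 6)
    b <- round(rnorm(sizes[2], 0.5), 6)
    got <- compare_band_power(list(x = a), list(x = b))$p
    expect_equal(got, oracle_mw_enum(a, b), tolerance = 1e-12)
  }

  # FDR across bands follows the hand Benjamini-Hochberg rule
  # (p = {0.01, 0.04} with m = 2 adjusts to q = {0.02, 0.04})
  d1 <- list(theta = c(1, 2, 3, 4), beta = c(1, 2, 3, 4))
  d2 <- list(theta = c(5, 6, 7, 8), beta = c(3.5, 4.5, 5.5, 6.5))
  res <- compare_band_power(d1, d2)
  hand_bh <- function(p) {
    m <- length(p)
    o <- order(p)
    adj <- p[o] * m / seq_len(m)
    adj <- rev(cummin(rev(adj)))
    pmin(1, adj)[order(o)]
  }
  expect_equal(res$q, hand_bh(res$p))
  expect_equal(hand_bh(c(0.01, 0.04)), c(0.02, 0.04))
})
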