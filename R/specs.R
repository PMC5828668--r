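#' Tile simulation parameters
#'
#' Describes one synthetic fluorescence tile: bright somata placed by a
#' uniform point process at a known density on a dim heterogeneous background
#' with thin bright processes. Defaults emulate the tiled confocal imagery the
#' counting pipeline targets: 1250x1250 px at 0.8 um/px (a 1 mm^2 field),
#' a 10 um maximum-projected stack, soma diameters of 16-20 px (13-16 um,
#' mature oligodendrocyte scale) and 2 px wide processes.
#'
#' @param width_px,height_px tile size in pixels.
#' @param pixel_size_um physical pixel size (um/pixel).
#' @param depth_um imaged tissue thickness represented by the projection (um).
#' @param true_density_cells_per_mm3 ground-truth soma density (cells/mm^3).
#' @param soma_radius_px_range min/max soma radius in pixels (min >= 2).
#' @param soma_peak_intensity_range min/max soma peak intensity, in \[0,1\].
#' @param soma_edge_sd_px SD of the Gaussian soma edge falloff (pixels);
#'   emulates the point-spread blur of an otherwise uniform cell body.
#' @param process_density_per_mm2 number of process segments per mm^2.
#' @param process_width_px width of each process polyline, pixels.
#' @param process_intensity_range min/max process intensity, in \[0,1\].
#' @param background_gradient_amplitude amplitude of the smooth low-frequency
#'   background field, in \[0,1\].
#' @param noise_sd standard deviation of i.i.d. Gaussian pixel noise.
#' @param seed integer seed; all randomness in the generated tile flows from
#'   it.
#' @return an object of class `tile_spec`.
#' @export
tile_spec <- function(width_px = 1250L,
                      height_px = 1250L,
                      pixel_size_um = 0.8,
                      depth_um = 10,
                      true_density_cells_per_mm3 = 3462,
                      soma_radius_px_range = c(8, 10),
                      soma_peak_intensity_range = c(0.5, 0.8),
                      soma_edge_sd_px = 1.5,
                      process_density_per_mm2 = 40,
                      process_width_px = 2L,
                      process_intensity_range = c(0.2, 0.4),
                      background_gradient_amplitude = 0.05,
                      noise_sd = 0.01,
                      seed = 1L) {
  spec <- list(
    width_px = as.integer(width_px), height_px = as.integer(height_px),
    pixel_size_um = pixel_size_um, depth_um = depth_um,
    true_density_cells_per_mm3 = true_density_cells_per_mm3,
    soma_radius_px_range = as.numeric(soma_radius_px_range),
    soma_peak_intensity_range = as.numeric(soma_peak_intensity_range),
    soma_edge_sd_px = soma_edge_sd_px,
    process_density_per_mm2 = process_density_per_mm2,
    process_width_px = as.integer(process_width_px),
    process_intensity_range = as.numeric(process_intensity_range),
    background_gradient_amplitude = background_gradient_amplitude,
    noise_sd = noise_sd,
    seed = as.integer(seed)
  )
  stopifnot(
    spec$width_px >= 32L, spec$height_px >= 32L,
    spec$pixel_size_um > 0, spec$depth_um > 0,
    spec$true_density_cells_per_mm3 >= 0,
    length(spec$soma_radius_px_range) == 2L,
    spec$soma_radius_px_range[1] >= 2,
    diff(spec$soma_radius_px_range) >= 0,
    all(spec$soma_peak_intensity_range >= 0),
    all(spec$soma_peak_intensity_range <= 1),
    spec$soma_edge_sd_px >= 0,
    spec$process_density_per_mm2 >= 0,
    all(spec$process_intensity_range >= 0),
    all(spec$process_intensity_range <= 1),
    spec$background_gradient_amplitude >= 0,
    spec$background_gradient_amplitude <= 1,
    spec$noise_sd >= 0, spec$noise_sd <= 1
  )
  structure(spec, class = "tile_spec")
}

#' Cohort simulation parameters
#'
#' A cohort is a set of genotypes, each with per-region true densities,
#' sampled over animals and tiles. Per-animal densities are the group density
#' multiplied by a lognormal factor with unit mean and coefficient of
#' variation `between_animal_cv`; the default 0.07 matches the between-animal
#' dispersion typical of tiled-section density measurements (SEM of a few
#' percent of the mean at n = 4).
#'
#' @param groups named list: genotype -> named numeric vector of true
#'   densities (cells/mm^3) per region, e.g.
#'   `list(WT = c(genu = 3462), null = c(genu = 4483))`.
#' @param n_animals_per_group animals per genotype (>= 2).
#' @param tiles_per_animal tiles generated per animal and region.
#' @param between_animal_cv coefficient of variation of the lognormal
#'   between-animal density factor (>= 0).
#' @param tile a [tile_spec()] used as the template for every generated tile
#'   (its density and seed are overridden per tile).
#' @param seed integer master seed.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(groups,
                        n_animals_per_group = 3L,
                        tiles_per_animal = 3L,
                        between_animal_cv = 0.07,
                        tile = tile_spec(),
                        seed = 1L) {
  stopifnot(
    is.list(groups), length(groups) >= 1L, !is.null(names(groups)),
    all(vapply(groups, function(g) is.numeric(g) && !is.null(names(g)),
               logical(1))),
    n_animals_per_group >= 2L, tiles_per_animal >= 1L,
    between_animal_cv >= 0,
    inherits(tile, "tile_spec")
  )
  structure(list(
    groups = groups,
    n_animals_per_group = as.integer(n_animals_per_group),
    tiles_per_animal = as.integer(tiles_per_animal),
    between_animal_cv = between_animal_cv,
    tile = tile,
    seed = as.integer(seed)
  ), class = "cohort_spec")
}

#' Compound action potential simulation parameters
#'
#' Each sweep is baseline noise plus two negative Gaussian deflections (fast
#' N1, slow N2) whose centers sit at `onset_offset_ms + distance / velocity`.
#' Deflection amplitude saturates with stimulus current following a Hill
#' curve, emulating progressive axon recruitment. Default distances and sweep
#' count follow the 0.5-2.0 mm, four-sweeps-per-distance protocol.
#'
#' @param distances_mm electrode separations, strictly increasing, > 0 (mm).
#' @param sweeps_per_distance sweeps acquired at each separation.
#' @param v_n1_m_per_s,v_n2_m_per_s true propagation speeds of the fast and
#'   slow components; must satisfy `v_n1 > v_n2 > 0`.
#' @param amp_n1,amp_n2 saturated deflection depths (arbitrary voltage units).
#' @param width_n1_ms,width_n2_ms Gaussian deflection SDs (ms).
#' @param latency_jitter_ms_sd per-sweep, per-component latency jitter SD.
#' @param onset_offset_ms fixed synaptic/utilization delay added to every
#'   latency (ms); becomes the regression intercept.
#' @param noise_sd baseline Gaussian noise SD (voltage units).
#' @param sampling_khz sampling rate (kHz).
#' @param stimulus_mA default stimulus current (mA).
#' @param hill_s50_mA,hill_exponent Hill parameters of the
#'   amplitude-vs-stimulus saturation.
#' @param pre_ms pre-stimulus baseline included in each sweep (ms).
#' @param seed integer seed.
#' @return an object of class `cap_sim_spec`.
#' @export
cap_sim_spec <- function(distances_mm = c(0.5, 1.0, 1.5, 2.0),
                         sweeps_per_distance = 4L,
                         v_n1_m_per_s = 1.5,
                         v_n2_m_per_s = 0.3,
                         amp_n1 = 0.5,
                         amp_n2 = 0.8,
                         width_n1_ms = 0.15,
                         width_n2_ms = 0.30,
                         latency_jitter_ms_sd = 0.02,
                         onset_offset_ms = 0.3,
                         noise_sd = 0.01,
                         sampling_khz = 100,
                         stimulus_mA = 4.0,
                         hill_s50_mA = 1.0,
                         hill_exponent = 3,
                         pre_ms = 1.0,
                         seed = 1L) {
  stopifnot(
    length(distances_mm) >= 1L, all(distances_mm > 0),
    all(diff(distances_mm) > 0),
    sweeps_per_distance >= 1L,
    v_n1_m_per_s > v_n2_m_per_s, v_n2_m_per_s > 0,
    amp_n1 >= 0, amp_n2 >= 0,
    width_n1_ms > 0, width_n2_ms > 0,
    latency_jitter_ms_sd >= 0, onset_offset_ms >= 0,
    noise_sd >= 0, sampling_khz > 0, stimulus_mA >= 0,
    hill_s50_mA > 0, hill_exponent > 0, pre_ms >= 0
  )
  structure(list(
    distances_mm = distances_mm,
    sweeps_per_distance = as.integer(sweeps_per_distance),
    v_n1_m_per_s = v_n1_m_per_s, v_n2_m_per_s = v_n2_m_per_s,
    amp_n1 = amp_n1, amp_n2 = amp_n2,
    width_n1_ms = width_n1_ms, width_n2_ms = width_n2_ms,
    latency_jitter_ms_sd = latency_jitter_ms_sd,
    onset_offset_ms = onset_offset_ms,
    noise_sd = noise_sd, sampling_khz = sampling_khz,
    stimulus_mA = stimulus_mA,
    hill_s50_mA = hill_s50_mA, hill_exponent = hill_exponent,
    pre_ms = pre_ms,
    seed = as.integer(seed)
  ), class = "cap_sim_spec")
}

#' Local field potential simulation parameters
#'
#' Each trial carries band-limited oscillations (sums of unit-spaced
#' sinusoids with random phases within each band) whose amplitude switches
#' from `baseline_amplitude` to `response_amplitude` at odor onset and back at
#' odor offset, plus broadband Gaussian noise. Defaults: 24 kHz sampling,
#' odor delivered 1.5 s into the trial for 2.5 s, theta = 6-14 Hz and
#' beta = 15-30 Hz.
#'
#' @param sampling_hz sampling rate (Hz); must exceed twice the highest band
#'   edge.
#' @param odor_onset_s odor onset time within each trial (s).
#' @param odor_duration_s odor presentation length (s).
#' @param post_s additional recording after odor offset (s).
#' @param bands named list; each element is
#'   `list(f_low, f_high, baseline_amplitude, response_amplitude)` with
#'   frequencies in Hz and amplitudes >= 0 (arbitrary units). The band RMS
#'   amplitude equals `amplitude / sqrt(2)` regardless of band width.
#' @param n_trials named integer vector of trials per label, e.g.
#'   `c(rewarded = 10, unrewarded = 10)`.
#' @param broadband_noise_sd SD of the added white noise.
#' @param seed integer seed.
#' @return an object of class `lfp_sim_spec`.
#' @export
lfp_sim_spec <- function(sampling_hz = 24000,
                         odor_onset_s = 1.5,
                         odor_duration_s = 2.5,
                         post_s = 0.5,
                         bands = list(
                           theta = list(f_low = 6, f_high = 14,
                                        baseline_amplitude = 1.0,
                                        response_amplitude = 1.5),
                           beta = list(f_low = 15, f_high = 30,
                                       baseline_amplitude = 0.5,
                                       response_amplitude = 0.8)
                         ),
                         n_trials = c(rewarded = 10L, unrewarded = 10L),
                         broadband_noise_sd = 0.1,
                         seed = 1L) {
  stopifnot(
    sampling_hz > 0, odor_onset_s > 0, odor_duration_s > 0, post_s >= 0,
    is.list(bands), length(bands) >= 1L, !is.null(names(bands)),
    !is.null(names(n_trials)), all(n_trials >= 1L),
    broadband_noise_sd >= 0
  )
  for (b in bands) {
    stopifnot(b$f_low < b$f_high,
              b$baseline_amplitude >= 0, b$response_amplitude >= 0,
              sampling_hz > 2 * b$f_high)
  }
  structure(list(
    sampling_hz = sampling_hz,
    odor_onset_s = odor_onset_s,
    odor_duration_s = odor_duration_s,
    post_s = post_s,
    bands = bands,
    n_trials = vapply(n_trials, as.integer, integer(1)),
    broadband_noise_sd = broadband_noise_sd,
    seed = as.integer(seed)
  ), class = "lfp_sim_spec")
}
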