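#' Read and write calibrated tiles as TIFF
#'
#' Tiles are stored as single- or multi-channel 32-bit float TIFF. Calibration
#' and metadata travel in a JSON sidecar (`<file>.json`) because baseline TIFF
#' tags do not carry them portably.
#'
#' @param tile an [intensity_tile].
#' @param path output TIFF path.
#' @return `write_tile_tiff` invisibly returns `path`; `read_tile_tiff`
#'   returns an [intensity_tile].
#' @export
write_tile_tiff <- function(tile, path) {
  stopifnot(inherits(tile, "intensity_tile"))
  px <- tile$pixels
  if (length(dim(px)) == 2L) {
    tiff::writeTIFF(px, path, bits.per.sample = 32L)
  } else {
    # one TIFF directory per channel
    planes <- lapply(seq_len(dim(px)[3]), function(k) px[, , k])
    tiff::writeTIFF(planes, path, bits.per.sample = 32L)
  }
  jsonlite::write_json(
    list(pixel_size_um = tile$pixel_size_um, depth_um = tile$depth_um,
         channel = tile$channel, animal = tile$animal,
         genotype = tile$genotype, region = tile$region),
    paste0(path, ".json"), auto_unbox = TRUE, null = "null"
  )
  invisible(path)
}

#' @rdname write_tile_tiff
#' @param pixel_size_um,depth_um calibration used when no JSON sidecar exists.
#' @export
read_tile_tiff <- function(path, pixel_size_um = 0.8, depth_um = 10) {
  planes <- tiff::readTIFF(path, all = TRUE)
  px <- if (length(planes) == 1L) planes[[1]] else {
    array(unlist(planes), dim = c(dim(planes[[1]]), length(planes)))
  }
  meta <- list(pixel_size_um = pixel_size_um, depth_um = depth_um,
               channel = if (length(planes) == 1L) "ch1" else
                 paste0("ch", seq_along(planes)),
               animal = NA_character_, genotype = NA_character_,
               region = NA_character_)
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    js <- jsonlite::read_json(side, simplifyVector = TRUE)
    for (nm in names(js)) if (!is.null(js[[nm]])) meta[[nm]] <- js[[nm]]
  }
  intensity_tile(px, meta$pixel_size_um, meta$depth_um,
                 channel = meta$channel,
                 animal = as.character(meta$animal %||% NA_character_),
                 genotype = as.character(meta$genotype %||% NA_character_),
                 region = as.character(meta$region %||% NA_character_))
}

#' Write and read CAP sweeps as CSV + JSON sidecar
#'
#' One CSV per dataset (columns: distance_mm, sweep_index, time_ms, voltage)
#' plus a JSON sidecar with the sampling rate, stimulus metadata and the seed.
#'
#' @param sweeps list of `cap_trace` objects from [generate_cap_sweeps()].
#' @param path output CSV path (sidecar written as `<path>.json`).
#' @export
write_cap_csv <- function(sweeps, path) {
  rows <- lapply(sweeps, function(s) {
    data.frame(distance_mm = s$distance_mm, sweep_index = s$sweep_index,
               stimulus_mA = s$stimulus_mA, time_ms = s$time_ms,
               voltage = s$voltage)
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  s1 <- sweeps[[1]]
  jsonlite::write_json(
    list(sampling_khz = 1 / diff(s1$time_ms[1:2]) / 1000 * 1000,
         stimulus_time_ms = s1$stimulus_time_ms,
         seed = attr(sweeps, "seed")),
    paste0(path, ".json"), auto_unbox = TRUE, null = "null"
  )
  invisible(path)
}

#' @rdname write_cap_csv
#' @export
read_cap_csv <- function(path) {
  df <- read.csv(path)
  side <- paste0(path, ".json")
  stim_t <- 0
  if (file.exists(side)) {
    js <- jsonlite::read_json(side, simplifyVector = TRUE)
    stim_t <- js$stimulus_time_ms %||% 0
  }
  keys <- unique(df[, c("distance_mm", "sweep_index")])
  sweeps <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- df[df$distance_mm == keys$distance_mm[i] &
                df$sweep_index == keys$sweep_index[i], ]
    cap_trace(time_ms = sub$time_ms, voltage = sub$voltage,
              stimulus_time_ms = stim_t, stimulus_mA = sub$stimulus_mA[1],
              distance_mm = keys$distance_mm[i],
              sweep_index = keys$sweep_index[i])
  })
  sweeps
}

#' Write and read LFP recordings as CSV + JSON sidecar
#'
#' The CSV has one row per sample (trial, sample_index, voltage); the sidecar
#' carries the sampling rate, odor event times, trial labels and the seed.
#'
#' @param rec an `lfp_recording` from [generate_lfp()].
#' @param path output CSV path.
#' @export
write_lfp_csv <- function(rec, path) {
  rows <- lapply(seq_along(rec$trials), function(i) {
    data.frame(trial = i, sample_index = seq_along(rec$trials[[i]]$signal),
               voltage = rec$trials[[i]]$signal)
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  jsonlite::write_json(
    list(sampling_hz = rec$sampling_hz, odor_onset_s = rec$odor_onset_s,
         odor_duration_s = rec$odor_duration_s,
         labels = vapply(rec$trials, `[[`, character(1), "label"),
         seed = rec$seed),
    paste0(path, ".json"), auto_unbox = TRUE, null = "null"
  )
  invisible(path)
}

#' @rdname write_lfp_csv
#' @export
read_lfp_csv <- function(path) {
  df <- read.csv(path)
  js <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  trials <- lapply(sort(unique(df$trial)), function(i) {
    sub <- df[df$trial == i, ]
    list(signal = sub$voltage[order(sub$sample_index)], label = js$labels[i])
  })
  structure(list(trials = trials, sampling_hz = js$sampling_hz,
                 odor_onset_s = js$odor_onset_s,
                 odor_duration_s = js$odor_duration_s, seed = js$seed),
            class = "lfp_recording")
}
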