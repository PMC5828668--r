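#' Calibrated intensity tile
#'
#' The elementary image container of the counting pipeline: a 2D matrix (or
#' height x width x channel array for multi-channel tiles) of intensities on a
#' 0-1 scale, with physical calibration and sample metadata. Pixels are
#' indexed (row, col), 1-based, origin top-left.
#'
#' @param pixels numeric matrix (or 3D array, third dimension = channel) with
#'   all values in \[0, 1\].
#' @param pixel_size_um physical pixel size, um/pixel (> 0).
#' @param depth_um imaged tissue thickness represented, um (> 0).
#' @param channel channel name(s).
#' @param animal,genotype,region sample metadata labels.
#' @return an object of class `intensity_tile`.
#' @export
intensity_tile <- function(pixels, pixel_size_um, depth_um,
                           channel = "ch1", animal = NA_character_,
                           genotype = NA_character_, region = NA_character_) {
  stopifnot(is.numeric(pixels), length(dim(pixels)) %in% c(2L, 3L),
            pixel_size_um > 0, depth_um > 0)
  rng <- range(pixels)
  if (rng[1] < 0 || rng[2] > 1) {
    stop("intensity_tile: pixel values must lie in [0, 1]; got range [",
         signif(rng[1], 4), ", ", signif(rng[2], 4), "]")
  }
  structure(list(
    pixels = pixels, pixel_size_um = pixel_size_um, depth_um = depth_um,
    channel = channel, animal = animal, genotype = genotype, region = region
  ), class = "intensity_tile")
}

#' @export
print.intensity_tile <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("intensity_tile: %d x %d px (%s channel%s), %.3g um/px, depth %.3g um\n",
              d[1], d[2], length(x$channel),
              if (length(x$channel) > 1) "s" else "", x$pixel_size_um,
              x$depth_um))
  invisible(x)
}

# geometry helpers ------------------------------------------------------

tile_area_mm2 <- function(width_px, height_px, pixel_size_um) {
  as.double(width_px) * as.double(height_px) * (pixel_size_um * 1e-3)^2
}

tile_volume_mm3 <- function(width_px, height_px, pixel_size_um, depth_um) {
  tile_area_mm2(width_px, height_px, pixel_size_um) * depth_um * 1e-3
}

# deterministic count realization: round(density x volume)
realized_count <- function(density, volume_mm3) {
  as.integer(round(density * volume_mm3))
}

# Rejection-sample n centroids with a minimum pairwise separation and an edge
# margin. Errors (naming the density) if placement fails within the retry
# budget, which indicates an infeasible packing.
place_centroids <- function(n, height_px, width_px, min_sep, margin,
                            density_label, existing = NULL) {
  if (n == 0L) {
    return(data.frame(row = numeric(0), col = numeric(0)))
  }
  lo_r <- 1 + margin; hi_r <- height_px - margin
  lo_c <- 1 + margin; hi_c <- width_px - margin
  if (hi_r <= lo_r || hi_c <= lo_c) {
    stop("tile too small for the requested soma size")
  }
  rows <- numeric(n); cols <- numeric(n)
  k <- 0L
  tries <- 0L
  max_tries <- 200L * n + 200L
  ex_r <- existing$row; ex_c <- existing$col
  min_sep2 <- min_sep^2
  while (k < n) {
    tries <- tries + 1L
    if (tries > max_tries) {
      stop("could not place ", n, " somata at density ", density_label,
           " cells/mm^3 without overlap (min separation ", min_sep,
           " px); density infeasible for this tile")
    }
    r <- runif(1, lo_r, hi_r)
    c <- runif(1, lo_c, hi_c)
    ok <- TRUE
    if (k > 0L) {
      ok <- all((rows[seq_len(k)] - r)^2 + (cols[seq_len(k)] - c)^2 >= min_sep2)
    }
    if (ok && length(ex_r)) {
      ok <- all((ex_r - r)^2 + (ex_c - c)^2 >= min_sep2)
    }
    if (ok) {
      k <- k + 1L
      rows[k] <- r; cols[k] <- c
    }
  }
  data.frame(row = rows, col = cols)
}

# Render somata as uniform-intensity cell bodies with a Gaussian-blurred
# edge (flat core of the soma radius, shoulder SD edge_sd emulating the PSF),
# truncated at 4 shoulder SDs; intensities add.
render_somata <- function(canvas, centroids, radii, peaks, edge_sd = 1.5) {
  nr <- nrow(canvas); nc <- ncol(canvas)
  for (i in seq_len(nrow(centroids))) {
    r0 <- centroids$row[i]; c0 <- centroids$col[i]
    rs <- radii[i]; pk <- peaks[i]
    ext <- ceiling(rs + 4 * edge_sd)
    rr <- max(1L, floor(r0 - ext)):min(nr, ceiling(r0 + ext))
    cc <- max(1L, floor(c0 - ext)):min(nc, ceiling(c0 + ext))
    d <- sqrt(outer((rr - r0)^2, (cc - c0)^2, `+`))
    bump <- pk * ifelse(d <= rs, 1, exp(-(d - rs)^2 / (2 * edge_sd^2)))
    bump[d > ext] <- 0
    canvas[rr, cc] <- canvas[rr, cc] + bump
  }
  canvas
}

# Thin bright polylines emulating labeled processes; drawn with pmax so
# crossings do not brighten.
render_processes <- function(canvas, n_proc, width_px, intensity_range) {
  if (n_proc == 0L) return(canvas)
  nr <- nrow(canvas); nc <- ncol(canvas)
  stamp <- which(disk_kernel(max(width_px / 2, 0.5)) == 1, arr.ind = TRUE)
  stamp <- stamp - (max(stamp) + 1L) / 2
  proc_img <- matrix(0, nr, nc)
  for (i in seq_len(n_proc)) {
    r0 <- runif(1, 1, nr); c0 <- runif(1, 1, nc)
    ang <- runif(1, 0, 2 * pi)
    len <- runif(1, 100, 400)
    inten <- runif(1, intensity_range[1], intensity_range[2])
    tt <- seq(0, len, by = 0.5)
    pr <- round(r0 + tt * sin(ang))
    pc <- round(c0 + tt * cos(ang))
    for (s in seq_len(nrow(stamp))) {
      qr <- pr + stamp[s, 1]; qc <- pc + stamp[s, 2]
      keep <- qr >= 1 & qr <= nr & qc >= 1 & qc <= nc
      idx <- cbind(qr[keep], qc[keep])
      proc_img[idx] <- pmax(proc_img[idx], inten)
    }
  }
  canvas + proc_img
}

# Smooth low-frequency multiplicative-free background field in [0, amplitude].
render_background <- function(nr, nc, amplitude) {
  if (amplitude == 0) return(matrix(0, nr, nc))
  fr <- runif(1, 0.5, 2); fc <- runif(1, 0.5, 2)
  pr <- runif(1, 0, 2 * pi); pc <- runif(1, 0, 2 * pi)
  sr <- sin(2 * pi * fr * seq_len(nr) / nr + pr)
  sc <- sin(2 * pi * fc * seq_len(nc) / nc + pc)
  amplitude * (0.5 + 0.5 * outer(sr, sc))
}

#' Generate a ground-truthed synthetic fluorescence tile
#'
#' Places somata by a uniform point process at the requested density
#' (realized count = `round(density x tile volume)`), with non-overlap
#' enforced by rejection sampling at a minimum centroid separation of twice
#' the maximum soma radius. Each soma is rendered as a bright disk with
#' smooth falloff; thin bright processes, a smooth low-frequency background
#' gradient and i.i.d. Gaussian noise are added, and the final image is
#' clipped to \[0, 1\]. Identical specs (including seed) give byte-identical
#' output.
#'
#' @param spec a [tile_spec()].
#' @param animal,genotype,region metadata labels copied into the tile.
#' @return list with elements `tile` ([intensity_tile]) and `truth`
#'   (class `ground_truth`: `centroids_px` data frame, per-object `channels`
#'   list, `true_count`, `true_density_cells_per_mm3`).
#' @export
#' @examples
#' out <- generate_tile(tile_spec(width_px = 256, height_px = 256,
#'                                true_density_cells_per_mm3 = 2000, seed = 7))
#' out$truth$true_count
generate_tile <- function(spec, animal = NA_character_,
                          genotype = NA_character_, region = NA_character_) {
  stopifnot(inherits(spec, "tile_spec"))
  vol <- tile_volume_mm3(spec$width_px, spec$height_px, spec$pixel_size_um,
                         spec$depth_um)
  n <- realized_count(spec$true_density_cells_per_mm3, vol)
  with_seed(spec$seed, {
    min_sep <- 2 * spec$soma_radius_px_range[2]
    cents <- place_centroids(n, spec$height_px, spec$width_px, min_sep,
                             margin = spec$soma_radius_px_range[2],
                             density_label = spec$true_density_cells_per_mm3)
    radii <- runif(n, spec$soma_radius_px_range[1], spec$soma_radius_px_range[2])
    peaks <- runif(n, spec$soma_peak_intensity_range[1],
                   spec$soma_peak_intensity_range[2])
    img <- render_background(spec$height_px, spec$width_px,
                             spec$background_gradient_amplitude)
    img <- render_somata(img, cents, radii, peaks, spec$soma_edge_sd_px)
    n_proc <- as.integer(round(spec$process_density_per_mm2 *
                                 tile_area_mm2(spec$width_px, spec$height_px,
                                               spec$pixel_size_um)))
    img <- render_processes(img, n_proc, spec$process_width_px,
                            spec$process_intensity_range)
    if (spec$noise_sd > 0) {
      img <- img + matrix(rnorm(length(img), 0, spec$noise_sd),
                          nrow(img), ncol(img))
    }
    img <- clip01(img)
    tile <- intensity_tile(img, spec$pixel_size_um, spec$depth_um,
                           animal = animal, genotype = genotype,
                           region = region)
    truth <- structure(list(
      centroids_px = cents,
      channels = rep(list("A"), n),
      true_count = n,
      true_density_cells_per_mm3 = n / vol,
      spec = spec
    ), class = "ground_truth")
    list(tile = tile, truth = truth)
  })
}

#' Generate a two-channel colocalization tile
#'
#' Channel-A objects are placed as in [generate_tile()]; a fraction
#' `joint_fraction` of them (rounded) is rendered in channel B at the same
#' centroid, and additional B-only objects are added so that channel B reaches
#' `spec_b_density`. Ground truth records each object's channel membership.
#'
#' @param spec_a a [tile_spec()] for channel A (its seed drives all
#'   randomness).
#' @param spec_b_density true density of channel-B objects (cells/mm^3).
#' @param joint_fraction fraction of A objects that are also B, in \[0, 1\].
#' @param channel_names names of the two channels.
#' @return list with `tile` (two-channel [intensity_tile]) and `truth`.
#' @export
generate_coloc_tile <- function(spec_a, spec_b_density, joint_fraction,
                                channel_names = c("A", "B")) {
  stopifnot(inherits(spec_a, "tile_spec"),
            spec_b_density >= 0,
            joint_fraction >= 0, joint_fraction <= 1,
            length(channel_names) == 2L)
  vol <- tile_volume_mm3(spec_a$width_px, spec_a$height_px,
                         spec_a$pixel_size_um, spec_a$depth_um)
  n_a <- realized_count(spec_a$true_density_cells_per_mm3, vol)
  n_b <- realized_count(spec_b_density, vol)
  n_ab <- as.integer(round(joint_fraction * n_a))
  n_b_only <- n_b - n_ab
  if (n_b_only < 0L) {
    stop("spec_b_density (", spec_b_density, " cells/mm^3 -> ", n_b,
         " objects) is below the requested joint count ", n_ab)
  }
  with_seed(spec_a$seed, {
    min_sep <- 2 * spec_a$soma_radius_px_range[2]
    margin <- spec_a$soma_radius_px_range[2]
    cents_a <- place_centroids(n_a, spec_a$height_px, spec_a$width_px, min_sep,
                               margin, spec_a$true_density_cells_per_mm3)
    joint_idx <- if (n_ab > 0L) sort(sample.int(n_a, n_ab)) else integer(0)
    cents_bo <- place_centroids(n_b_only, spec_a$height_px, spec_a$width_px,
                                min_sep, margin, spec_b_density,
                                existing = cents_a)

    render_channel <- function(cents) {
      k <- nrow(cents)
      img <- render_background(spec_a$height_px, spec_a$width_px,
                               spec_a$background_gradient_amplitude)
      img <- render_somata(img, cents,
                           runif(k, spec_a$soma_radius_px_range[1],
                                 spec_a$soma_radius_px_range[2]),
                           runif(k, spec_a$soma_peak_intensity_range[1],
                                 spec_a$soma_peak_intensity_range[2]),
                           spec_a$soma_edge_sd_px)
      n_proc <- as.integer(round(spec_a$process_density_per_mm2 *
                                   tile_area_mm2(spec_a$width_px,
                                                 spec_a$height_px,
                                                 spec_a$pixel_size_um)))
      img <- render_processes(img, n_proc, spec_a$process_width_px,
                              spec_a$process_intensity_range)
      if (spec_a$noise_sd > 0) {
        img <- img + matrix(rnorm(length(img), 0, spec_a$noise_sd),
                            nrow(img), ncol(img))
      }
      clip01(img)
    }

    img_a <- render_channel(cents_a)
    cents_b <- rbind(cents_a[joint_idx, , drop = FALSE], cents_bo)
    img_b <- render_channel(cents_b)

    pixels <- array(c(img_a, img_b),
                    dim = c(spec_a$height_px, spec_a$width_px, 2L))
    tile <- intensity_tile(pixels, spec_a$pixel_size_um, spec_a$depth_um,
                           channel = channel_names)

    cents_all <- rbind(cents_a, cents_bo)
    channels <- c(
      lapply(seq_len(n_a), function(i) {
        if (i %in% joint_idx) channel_names else channel_names[1]
      }),
      rep(list(channel_names[2]), n_b_only)
    )
    truth <- structure(list(
      centroids_px = cents_all,
      channels = channels,
      true_count = nrow(cents_all),
      true_density_cells_per_mm3 = nrow(cents_all) / vol,
      n_a = n_a, n_b = n_b, n_ab = n_ab,
      spec = spec_a
    ), class = "ground_truth")
    list(tile = tile, truth = truth)
  })
}
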