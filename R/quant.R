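#' Segmentation parameters
#'
#' Parameters of the soma-counting algorithm. The shipped presets (see
#' [seg_preset()]) carry the mean values chosen by blinded users on wild-type
#' and mutant tiles (opening disk radius 8.72 / 5.26 px, threshold
#' 0.14 / 0.15); they are presets, not constants — every parameter is
#' per-image configurable.
#'
#' @param open_disk_radius_px radius of the opening disk (pixels; may be
#'   fractional, see [disk_kernel()]).
#' @param threshold positive-pixel threshold, strict, in (0, 1).
#' @param min_object_px objects with area strictly below this are removed.
#' @param large_object_cutoff_px QC cutoff: fraction of objects strictly above
#'   this area is reported.
#' @param split_erosion_radius_px disk radius of the splitting erosion
#'   (0 disables splitting).
#' @param connectivity pixel connectivity for components, 4 or 8.
#' @return object of class `segmentation_params`.
#' @export
segmentation_params <- function(open_disk_radius_px,
                                threshold,
                                min_object_px = 5L,
                                large_object_cutoff_px = 50L,
                                split_erosion_radius_px = 1,
                                connectivity = 8L) {
  stopifnot(open_disk_radius_px > 0,
            threshold > 0, threshold < 1,
            min_object_px >= 1L,
            large_object_cutoff_px >= 1L,
            split_erosion_radius_px >= 0,
            connectivity %in% c(4L, 8L))
  structure(list(
    open_disk_radius_px = open_disk_radius_px, threshold = threshold,
    min_object_px = as.integer(min_object_px),
    large_object_cutoff_px = as.integer(large_object_cutoff_px),
    split_erosion_radius_px = split_erosion_radius_px,
    connectivity = as.integer(connectivity)
  ), class = "segmentation_params")
}

#' @rdname segmentation_params
#' @param name `"WT"` or `"null"`.
#' @export
seg_preset <- function(name = c("WT", "null")) {
  name <- match.arg(name)
  p <- switch(name,
              WT = segmentation_params(open_disk_radius_px = 8.72,
                                       threshold = 0.14),
              null = segmentation_params(open_disk_radius_px = 5.26,
                                         threshold = 0.15))
  p$preset <- name
  p
}

#' Normalize raw intensities to the 0-1 scale
#'
#' Divides by the bit-depth maximum (`2^bit_depth - 1`) or an explicit
#' `max_value`; this is a fixed rescaling, not min-max stretching, so
#' intensities stay comparable across tiles. Values exceeding the stated
#' maximum raise an error (they indicate a wrong bit depth).
#'
#' @param raw numeric matrix (or 3D z-stack) of raw intensities, >= 0.
#' @param bit_depth 8, 12 or 16; ignored when `max_value` is given.
#' @param max_value explicit intensity maximum overriding `bit_depth`.
#' @param pixel_size_um,depth_um,channel,animal,genotype,region metadata for
#'   the resulting [intensity_tile].
#' @return an [intensity_tile] (2D input) or normalized array (3D input).
#' @export
normalize_intensity <- function(raw, bit_depth = 16L, max_value = NULL,
                                pixel_size_um = 0.8, depth_um = 10,
                                channel = "ch1", animal = NA_character_,
                                genotype = NA_character_,
                                region = NA_character_) {
  if (is.null(max_value)) {
    stopifnot(bit_depth %in% c(8L, 12L, 16L))
    max_value <- 2^bit_depth - 1
  }
  if (min(raw) < 0) stop("raw intensities must be non-negative")
  if (max(raw) > max_value) {
    stop("raw intensities exceed the stated maximum ", max_value,
         " (max observed ", max(raw), "); wrong bit depth?")
  }
  px <- raw / max_value
  if (length(dim(px)) == 3L) return(px)
  intensity_tile(px, pixel_size_um, depth_um, channel = channel,
                 animal = animal, genotype = genotype, region = region)
}

#' Maximum intensity projection
#'
#' Per-pixel maximum over the planes of a z-stack.
#'
#' @param stack 3D array (row, col, plane) with >= 1 plane, or a 2D matrix
#'   (returned unchanged).
#' @return 2D matrix.
#' @export
max_project <- function(stack) {
  if (is.matrix(stack)) return(stack)
  d <- dim(stack)
  if (length(d) != 3L || d[3] < 1L) stop("max_project: need a stack with >= 1 plane")
  out <- stack[, , 1]
  for (k in seq_len(d[3])[-1]) out <- pmax(out, stack[, , k])
  out
}

# Extract the working pixel matrix from a tile or plain matrix.
tile_pixels <- function(x, channel = 1L) {
  if (inherits(x, "intensity_tile")) {
    if (length(dim(x$pixels)) == 3L) x$pixels[, , channel] else x$pixels
  } else x
}

#' Morphological opening filter
#'
#' Grayscale opening (erosion then dilation) with the package's discrete disk
#' ([disk_kernel()]). Opening is anti-extensive — output intensities never
#' exceed the input — and suppresses bright structures narrower than the
#' disk, which is what removes the thin labeled processes while the soma
#' signal survives. Border pixels use the in-bounds part of the neighborhood.
#'
#' @param tile an [intensity_tile] or numeric matrix.
#' @param radius_px disk radius (>= 1 and at most half the smaller image
#'   dimension).
#' @return same type as the input, with filtered pixels.
#' @export
open_filter <- function(tile, radius_px) {
  px <- tile_pixels(tile)
  if (radius_px < 1) stop("open_filter: radius must be >= 1")
  if (radius_px > min(dim(px)) / 2) {
    stop("open_filter: radius ", radius_px,
         " exceeds half the smaller image dimension")
  }
  k <- disk_kernel(radius_px)
  opened <- EBImage::dilate(EBImage::erode(px, k), k)
  opened <- matrix(as.numeric(opened), nrow(px), ncol(px))
  if (inherits(tile, "intensity_tile")) {
    out <- tile
    out$pixels <- opened
    out
  } else opened
}

#' Threshold to positive pixels
#'
#' A pixel is positive iff its intensity is strictly greater than the
#' threshold (a pixel exactly at the threshold is negative).
#'
#' @param tile an [intensity_tile] or numeric matrix.
#' @param threshold in (0, 1).
#' @return logical matrix.
#' @export
binarize <- function(tile, threshold) {
  stopifnot(threshold > 0, threshold < 1)
  tile_pixels(tile) > threshold
}

# Build a cell_objects container from a label matrix.
objects_from_labels <- function(lab, params = NULL, tile = NULL) {
  n <- max(lab, 0L)
  pos <- which(lab > 0L)
  if (n == 0L) {
    objs <- data.frame(id = integer(0), centroid_row = numeric(0),
                       centroid_col = numeric(0), area_px = integer(0))
    pixels <- list()
  } else {
    labs <- lab[pos]
    nr <- nrow(lab)
    rows <- ((pos - 1L) %% nr) + 1L
    cols <- ((pos - 1L) %/% nr) + 1L
    area <- tabulate(labs, nbins = n)
    objs <- data.frame(
      id = seq_len(n),
      centroid_row = rowsum(as.numeric(rows), labs)[, 1] / area,
      centroid_col = rowsum(as.numeric(cols), labs)[, 1] / area,
      area_px = as.integer(area)
    )
    pixels <- split(pos, labs)
    names(pixels) <- NULL
  }
  structure(list(objects = objs, pixels = pixels, dim = dim(lab),
                 params = params,
                 meta = if (inherits(tile, "intensity_tile")) {
                   tile[c("pixel_size_um", "depth_um", "channel", "animal",
                          "genotype", "region")]
                 } else NULL),
            class = "cell_objects")
}

#' @export
print.cell_objects <- function(x, ...) {
  cat(sprintf("cell_objects: %d object(s) on a %d x %d grid\n",
              nrow(x$objects), x$dim[1], x$dim[2]))
  invisible(x)
}

#' Label connected components
#'
#' Maximal connected components of the positive-pixel mask under 4- or
#' 8-connectivity. Object IDs follow the raster (column-major) order of each
#' component's first pixel, so labeling is deterministic.
#'
#' @param mask logical matrix.
#' @param connectivity 4 or 8 (default 8).
#' @param params optional [segmentation_params()] recorded with the objects.
#' @param tile optional source [intensity_tile]; its calibration and metadata
#'   are carried along.
#' @return object of class `cell_objects`: `objects` data frame (id,
#'   centroid_row, centroid_col, area_px), per-object `pixels` (linear
#'   indices), grid `dim`, `params`, `meta`.
#' @export
label_objects <- function(mask, connectivity = 8L, params = NULL,
                          tile = NULL) {
  stopifnot(is.logical(mask), is.matrix(mask), connectivity %in% c(4L, 8L))
  lab <- label_components_cpp(mask, as.integer(connectivity))
  res <- objects_from_labels(lab, params = params, tile = tile)
  res$connectivity <- as.integer(connectivity)
  res
}

#' Remove small objects
#'
#' Drops objects with pixel area strictly below `min_object_px` (too small to
#' be a cell); all other objects are untouched, keeping their IDs.
#'
#' @param objects a `cell_objects`.
#' @param min_object_px area floor (default 5).
#' @return filtered `cell_objects`.
#' @export
remove_small <- function(objects, min_object_px = 5L) {
  stopifnot(inherits(objects, "cell_objects"))
  keep <- objects$objects$area_px >= min_object_px
  objects$objects <- objects$objects[keep, , drop = FALSE]
  objects$pixels <- objects$pixels[keep]
  objects
}

#' Fraction of large connected objects
#'
#' QC statistic: the fraction of objects whose area strictly exceeds
#' `cutoff_px`, i.e. candidates for containing multiple cells. Returns 0 for
#' an empty object set.
#'
#' @param objects a `cell_objects`.
#' @param cutoff_px area cutoff (default 50).
#' @return fraction in \[0, 1\].
#' @export
qc_large_fraction <- function(objects, cutoff_px = 50L) {
  stopifnot(inherits(objects, "cell_objects"))
  n <- nrow(objects$objects)
  if (n == 0L) return(0)
  mean(objects$objects$area_px > cutoff_px)
}

#' Split merged objects by erosion
#'
#' Applies binary erosion with a disk of the given radius to the object mask;
#' the resulting components are re-labeled and counted as the final cells. An
#' object that erodes away entirely is retained as ONE cell at its original
#' centroid (fragmentation must not delete small cells). With
#' `only_ids` given, erosion is restricted to those objects (used by the
#' split-large-only mode); the rest pass through unchanged.
#'
#' @param objects a `cell_objects` (after [remove_small()]).
#' @param split_erosion_radius_px erosion disk radius; 0 returns the input.
#' @param only_ids optional object IDs to split; others are kept whole.
#' @return `cell_objects` of final cells. Fragments are numbered in raster
#'   order, followed by retained (annihilated or unsplit) parents in ID
#'   order; column `parent_id` maps each final cell to its pre-split object
#'   and `retained` flags cells kept by the annihilation rule.
#' @export
split_merged <- function(objects, split_erosion_radius_px = 1,
                         only_ids = NULL) {
  stopifnot(inherits(objects, "cell_objects"))
  if (split_erosion_radius_px == 0 || nrow(objects$objects) == 0L) {
    objects$objects$parent_id <- objects$objects$id
    objects$objects$retained <- rep(FALSE, nrow(objects$objects))
    return(objects)
  }
  ids <- objects$objects$id
  split_ids <- if (is.null(only_ids)) ids else intersect(ids, only_ids)
  pass_ids <- setdiff(ids, split_ids)

  # parent label image of the objects to be eroded
  parent <- matrix(0L, objects$dim[1], objects$dim[2])
  for (i in seq_along(ids)) {
    if (ids[i] %in% split_ids) parent[objects$pixels[[i]]] <- ids[i]
  }
  mask <- parent > 0L
  k <- disk_kernel(split_erosion_radius_px)
  eroded <- EBImage::erode(mask * 1, k) > 0.5
  lab <- label_components_cpp(eroded, objects$connectivity %||% 8L)
  frags <- objects_from_labels(lab, params = objects$params)

  # map fragments to parents via any fragment pixel (erosion is a subset op)
  frag_parent <- vapply(frags$pixels, function(p) parent[p[1]], integer(1))
  survived <- unique(frag_parent)
  annihilated <- setdiff(split_ids, survived)

  res_objs <- frags$objects
  res_objs$parent_id <- frag_parent
  res_objs$retained <- rep(FALSE, nrow(res_objs))
  res_pixels <- frags$pixels

  keep_whole <- c(pass_ids, annihilated)
  if (length(keep_whole)) {
    sel <- match(sort(keep_whole), ids)
    kept <- objects$objects[sel, , drop = FALSE]
    kept$parent_id <- kept$id
    kept$retained <- kept$id %in% annihilated
    res_objs <- rbind(res_objs, kept)
    res_pixels <- c(res_pixels, objects$pixels[sel])
  }
  res_objs$id <- seq_len(nrow(res_objs))
  structure(list(objects = res_objs, pixels = res_pixels,
                 dim = objects$dim, params = objects$params,
                 meta = objects$meta,
                 connectivity = objects$connectivity %||% 8L),
            class = "cell_objects")
}

#' Count cells and compute density
#'
#' Counts objects whose centroid lies inside the region of interest and
#' converts to cells/mm^3 using the tile calibration:
#' `area_mm2 = ROI pixels x (pixel_size_um x 1e-3)^2`,
#' `volume_mm3 = area_mm2 x depth_um x 1e-3`, `density = count / volume`.
#' Centroid membership (rounded to the nearest pixel) prevents double
#' counting across tiled ROIs.
#'
#' @param objects a `cell_objects` (final cells from the pipeline).
#' @param tile the source [intensity_tile] (calibration + metadata).
#' @param roi_mask optional logical matrix; default is the full tile.
#' @param qc_large_fraction QC fraction of the pre-split objects, echoed in
#'   the record.
#' @return one-row data frame (a density record): region, genotype, animal,
#'   count, area_mm2, volume_mm3, density_cells_per_mm3, qc_large_fraction.
#' @export
count_and_density <- function(objects, tile, roi_mask = NULL,
                              qc_large_fraction = NA_real_) {
  stopifnot(inherits(objects, "cell_objects"),
            inherits(tile, "intensity_tile"))
  d <- dim(tile_pixels(tile))
  if (is.null(roi_mask)) {
    n_px <- prod(d)
    count <- nrow(objects$objects)
  } else {
    stopifnot(is.logical(roi_mask), all(dim(roi_mask) == d))
    n_px <- sum(roi_mask)
    if (n_px == 0L) stop("count_and_density: zero-area ROI")
    if (nrow(objects$objects)) {
      r <- pmin(pmax(round(objects$objects$centroid_row), 1), d[1])
      c <- pmin(pmax(round(objects$objects$centroid_col), 1), d[2])
      count <- sum(roi_mask[cbind(r, c)])
    } else count <- 0L
  }
  area_mm2 <- n_px * (tile$pixel_size_um * 1e-3)^2
  volume_mm3 <- area_mm2 * tile$depth_um * 1e-3
  data.frame(
    region = tile$region, genotype = tile$genotype, animal = tile$animal,
    count = as.integer(count), area_mm2 = area_mm2, volume_mm3 = volume_mm3,
    density_cells_per_mm3 = count / volume_mm3,
    qc_large_fraction = qc_large_fraction,
    stringsAsFactors = FALSE
  )
}

#' Run the full soma-counting pipeline on one tile
#'
#' Opening (process suppression), strict thresholding, connected components,
#' small-object removal, QC, erosion splitting, and density computation — the
#' complete counting algorithm in its published order.
#'
#' @param tile an [intensity_tile] (2D, or give `channel` for multi-channel
#'   tiles).
#' @param params a [segmentation_params()] (e.g. [seg_preset()]).
#' @param roi_mask optional logical ROI; default full tile.
#' @param split_large_only if `TRUE`, the splitting erosion is applied only
#'   to objects above `large_object_cutoff_px`; by default every surviving
#'   object is eroded and the large-object figure is reported as QC only.
#' @param channel channel index for multi-channel tiles.
#' @return list: `record` (density record), `cells` (final `cell_objects`),
#'   `objects_presplit`, `mask`, `params`.
#' @export
#' @examples
#' out <- generate_tile(tile_spec(width_px = 300, height_px = 300,
#'                                true_density_cells_per_mm3 = 3000, seed = 2))
#' res <- count_cells(out$tile, seg_preset("WT"))
#' res$record$count == out$truth$true_count
count_cells <- function(tile, params, roi_mask = NULL,
                        split_large_only = FALSE, channel = 1L) {
  stopifnot(inherits(params, "segmentation_params"))
  px <- tile_pixels(tile, channel)
  opened <- open_filter(px, params$open_disk_radius_px)
  mask <- opened > params$threshold
  objs <- label_objects(mask, params$connectivity, params = params,
                        tile = tile)
  objs <- remove_small(objs, params$min_object_px)
  qc <- qc_large_fraction(objs, params$large_object_cutoff_px)
  only <- if (split_large_only) {
    objs$objects$id[objs$objects$area_px > params$large_object_cutoff_px]
  } else NULL
  cells <- split_merged(objs, params$split_erosion_radius_px,
                        only_ids = only)
  record <- count_and_density(cells, tile, roi_mask = roi_mask,
                              qc_large_fraction = qc)
  list(record = record, cells = cells, objects_presplit = objs,
       mask = mask, params = params)
}

#' Agreement between automated and reference counts
#'
#' Mean absolute percent difference of automated counts relative to paired
#' reference (e.g. manual or ground-truth) counts:
#' `mean(|auto - ref| / ref) x 100`. Pairs with a zero reference are excluded
#' with a warning.
#'
#' @param auto_counts,reference_counts paired numeric vectors.
#' @return mean absolute percent difference (%).
#' @export
validate_counts <- function(auto_counts, reference_counts) {
  stopifnot(length(auto_counts) == length(reference_counts),
            length(auto_counts) >= 1L)
  zero <- reference_counts == 0
  if (any(zero)) {
    warning(sum(zero), " pair(s) with zero reference count excluded")
    auto_counts <- auto_counts[!zero]
    reference_counts <- reference_counts[!zero]
  }
  if (!length(auto_counts)) stop("no pairs with positive reference count")
  mean(abs(auto_counts - reference_counts) / reference_counts) * 100
}
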