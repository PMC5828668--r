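#' Match objects across two channels
#'
#' Greedy nearest-centroid one-to-one matching: candidate pairs within
#' `max_centroid_dist_px` are accepted in order of (distance, A id, B id), and
#' each object participates in at most one pair. Object-based (centroid)
#' matching is used because the quantity of interest is double-positive cell
#' counts, not overlap area.
#'
#' @param objects_a,objects_b `cell_objects` detected on the two channels of
#'   one tile (geometries must agree).
#' @param max_centroid_dist_px acceptance radius; default 10 px (the maximum
#'   soma radius of the default simulation).
#' @return object of class `coloc_pairing`: data frame `pairs`
#'   (a_id, b_id, dist_px), plus `n_a`, `n_b`, `n_ab`.
#' @export
match_objects <- function(objects_a, objects_b, max_centroid_dist_px = 10) {
  stopifnot(inherits(objects_a, "cell_objects"),
            inherits(objects_b, "cell_objects"))
  if (!all(objects_a$dim == objects_b$dim)) {
    stop("match_objects: the two object sets come from different tile geometries")
  }
  a <- objects_a$objects
  b <- objects_b$objects
  pairs <- data.frame(a_id = integer(0), b_id = integer(0),
                      dist_px = numeric(0))
  if (nrow(a) && nrow(b)) {
    dmat <- sqrt(outer(a$centroid_row, b$centroid_row, `-`)^2 +
                   outer(a$centroid_col, b$centroid_col, `-`)^2)
    cand <- which(dmat <= max_centroid_dist_px, arr.ind = TRUE)
    if (nrow(cand)) {
      cd <- data.frame(ai = cand[, 1], bi = cand[, 2],
                       dist = dmat[cand])
      cd <- cd[order(cd$dist, a$id[cd$ai], b$id[cd$bi]), ]
      used_a <- logical(nrow(a)); used_b <- logical(nrow(b))
      keep <- logical(nrow(cd))
      for (i in seq_len(nrow(cd))) {
        if (!used_a[cd$ai[i]] && !used_b[cd$bi[i]]) {
          keep[i] <- TRUE
          used_a[cd$ai[i]] <- TRUE
          used_b[cd$bi[i]] <- TRUE
        }
      }
      cd <- cd[keep, , drop = FALSE]
      pairs <- data.frame(a_id = a$id[cd$ai], b_id = b$id[cd$bi],
                          dist_px = cd$dist)
    }
  }
  structure(list(pairs = pairs, n_a = nrow(a), n_b = nrow(b),
                 n_ab = nrow(pairs), dim = objects_a$dim,
                 max_centroid_dist_px = max_centroid_dist_px),
            class = "coloc_pairing")
}

#' Double-positive colocalization metrics
#'
#' Computes the three metric families of object-based colocalization:
#' double-positive density (cells/mm^3), percent of channel-A objects that
#' are also B, and percent of channel-B objects that are also A. A 0/0
#' percentage is reported as missing (`NA`), not 0.
#'
#' @param pairing a `coloc_pairing` from [match_objects()].
#' @param tile the source [intensity_tile] (calibration + metadata).
#' @return one-row data frame: region, genotype, animal, n_a, n_b, n_ab,
#'   density_ab_cells_per_mm3, pct_a_that_are_b, pct_b_that_are_a.
#' @export
coloc_metrics <- function(pairing, tile) {
  stopifnot(inherits(pairing, "coloc_pairing"),
            inherits(tile, "intensity_tile"))
  d <- pairing$dim
  vol <- tile_area_mm2(d[2], d[1], tile$pixel_size_um) * tile$depth_um * 1e-3
  data.frame(
    region = tile$region, genotype = tile$genotype, animal = tile$animal,
    n_a = pairing$n_a, n_b = pairing$n_b, n_ab = pairing$n_ab,
    density_ab_cells_per_mm3 = pairing$n_ab / vol,
    pct_a_that_are_b = if (pairing$n_a > 0) 100 * pairing$n_ab / pairing$n_a
                       else NA_real_,
    pct_b_that_are_a = if (pairing$n_b > 0) 100 * pairing$n_ab / pairing$n_b
                       else NA_real_,
    stringsAsFactors = FALSE
  )
}
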