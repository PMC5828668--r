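#' Quantify every tile of a cohort
#'
#' Runs [count_cells()] on each tile of a [generate_cohort()] dataset (or any
#' list of tile entries with the same shape) and stacks the density records.
#'
#' @param cohort a `cohort`, or a list of entries
#'   `list(tile, genotype, animal, region, tile_index)`.
#' @param params a [segmentation_params()] used for every tile, or a named
#'   list genotype -> params to mirror per-group user settings.
#' @param ... passed to [count_cells()].
#' @return data frame: one density record per tile, plus tile_index.
#' @export
quantify_cohort <- function(cohort, params, ...) {
  entries <- if (inherits(cohort, "cohort")) cohort$tiles else cohort
  rows <- lapply(entries, function(e) {
    p <- if (inherits(params, "segmentation_params")) params else
      params[[e$genotype]]
    rec <- count_cells(e$tile, p, ...)$record
    rec$tile_index <- e$tile_index
    rec
  })
  do.call(rbind, rows)
}

#' Per-animal mean densities
#'
#' Averages tile-level density records to one value per animal and region —
#' the unit of analysis for the cohort statistics.
#'
#' @param records data frame from [quantify_cohort()] (columns genotype,
#'   animal, region, density_cells_per_mm3).
#' @return data frame: genotype, animal, region, value (mean density).
#' @export
animal_densities <- function(records) {
  out <- aggregate(density_cells_per_mm3 ~ genotype + animal + region,
                   data = records, FUN = mean)
  names(out)[names(out) == "density_cells_per_mm3"] <- "value"
  out[order(out$genotype, out$animal, out$region), , drop = FALSE]
}
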