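#' Generate a ground-truthed synthetic cohort
#'
#' For each genotype, region and animal, the animal's true density is the
#' group density multiplied by a lognormal factor with unit mean and
#' coefficient of variation `spec$between_animal_cv`; `tiles_per_animal`
#' tiles are then generated at that density with [generate_tile()]. Every
#' tile's seed is derived deterministically from the cohort seed, so the full
#' dataset is reproducible from the spec alone.
#'
#' @param spec a [cohort_spec()].
#' @return object of class `cohort`: list with `tiles` (list of entries, each
#'   `list(tile, truth, genotype, animal, region, tile_index)`), `truth_table`
#'   (one row per tile: genotype, animal, region, tile_index, true_count,
#'   true_density_cells_per_mm3, animal_density), and the `spec`.
#' @export
#' @examples
#' cs <- cohort_spec(groups = list(WT = c(CC = 2000), null = c(CC = 3900)),
#'                   tile = tile_spec(width_px = 256, height_px = 256),
#'                   n_animals_per_group = 2, tiles_per_animal = 1, seed = 3)
#' ch <- generate_cohort(cs)
#' ch$truth_table
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  cv <- spec$between_animal_cv
  sigma <- sqrt(log(1 + cv^2))
  mu <- -sigma^2 / 2 # unit-mean lognormal

  tiles <- list()
  rows <- list()
  idx <- 0L
  for (g in names(spec$groups)) {
    regions <- spec$groups[[g]]
    for (a in seq_len(spec$n_animals_per_group)) {
      animal_id <- paste0(g, "_", a)
      for (rg in names(regions)) {
        idx <- idx + 1L
        factor_seed <- derive_seed(spec$seed, idx * 7L)
        lf <- if (cv > 0) {
          with_seed(factor_seed, rlnorm(1, meanlog = mu, sdlog = sigma))
        } else 1
        animal_density <- regions[[rg]] * lf
        for (tl in seq_len(spec$tiles_per_animal)) {
          ts <- spec$tile
          ts$true_density_cells_per_mm3 <- animal_density
          ts$seed <- derive_seed(spec$seed, idx * 1000L + tl)
          out <- generate_tile(ts, animal = animal_id, genotype = g,
                               region = rg)
          entry <- list(tile = out$tile, truth = out$truth, genotype = g,
                        animal = animal_id, region = rg, tile_index = tl)
          tiles[[length(tiles) + 1L]] <- entry
          rows[[length(rows) + 1L]] <- data.frame(
            genotype = g, animal = animal_id, region = rg, tile_index = tl,
            true_count = out$truth$true_count,
            true_density_cells_per_mm3 = out$truth$true_density_cells_per_mm3,
            animal_density = animal_density,
            stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  structure(list(
    tiles = tiles,
    truth_table = do.call(rbind, rows),
    spec = spec
  ), class = "cohort")
}

#' Write a synthetic cohort to disk
#'
#' Tiles are written as 32-bit float single-channel TIFFs and the ground truth
#' as two CSVs: `ground_truth.csv` (one row per object: object_id, row_px,
#' col_px, channels, animal, genotype, region, tile_index) and
#' `tile_summary.csv` (the cohort truth table plus file names). The cohort
#' seed is echoed in both CSVs' companion `cohort.json`.
#'
#' @param cohort a `cohort` from [generate_cohort()].
#' @param dir output directory (created if missing).
#' @return invisibly, the tile summary with file names.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  objs <- list()
  files <- character(length(cohort$tiles))
  for (i in seq_along(cohort$tiles)) {
    e <- cohort$tiles[[i]]
    fn <- sprintf("%s_%s_%s_tile%02d.tif", e$genotype, e$animal, e$region,
                  e$tile_index)
    files[i] <- fn
    write_tile_tiff(e$tile, file.path(dir, fn))
    tr <- e$truth
    if (tr$true_count > 0L) {
      objs[[length(objs) + 1L]] <- data.frame(
        object_id = seq_len(tr$true_count),
        row_px = tr$centroids_px$row,
        col_px = tr$centroids_px$col,
        channels = vapply(tr$channels, paste, character(1), collapse = "+"),
        animal = e$animal, genotype = e$genotype, region = e$region,
        tile_index = e$tile_index, stringsAsFactors = FALSE
      )
    }
  }
  gt <- if (length(objs)) do.call(rbind, objs) else
    data.frame(object_id = integer(0), row_px = numeric(0),
               col_px = numeric(0), channels = character(0),
               animal = character(0), genotype = character(0),
               region = character(0), tile_index = integer(0))
  write.csv(gt, file.path(dir, "ground_truth.csv"), row.names = FALSE)
  summ <- cbind(cohort$truth_table, file = files)
  write.csv(summ, file.path(dir, "tile_summary.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(seed = cohort$spec$seed,
         n_animals_per_group = cohort$spec$n_animals_per_group,
         tiles_per_animal = cohort$spec$tiles_per_animal,
         between_animal_cv = cohort$spec$between_animal_cv),
    file.path(dir, "cohort.json"), auto_unbox = TRUE
  )
  invisible(summ)
}
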