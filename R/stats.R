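#' Percent-of-control statistic with propagated SEM
#'
#' `100 x mean(test) / mean(control)`, with the SEM of the ratio propagated by
#' the delta method:
#' `SE(R) = R x sqrt((SE_t/m_t)^2 + (SE_c/m_c)^2)`.
#'
#' @param test_values,control_values per-animal values (e.g. densities) for
#'   the test (mutant) and control (WT) groups.
#' @return list: `percent`, `sem`, `n_test`, `n_control`.
#' @export
percent_of_wt <- function(test_values, control_values) {
  m_c <- mean(control_values)
  if (!is.finite(m_c) || m_c == 0) {
    stop("percent_of_wt: control mean is zero or undefined")
  }
  m_t <- mean(test_values)
  se_t <- sd(test_values) / sqrt(length(test_values))
  se_c <- sd(control_values) / sqrt(length(control_values))
  ratio <- m_t / m_c
  sem <- 100 * abs(ratio) * sqrt((se_t / m_t)^2 + (se_c / m_c)^2)
  list(percent = 100 * ratio, sem = sem,
       n_test = length(test_values), n_control = length(control_values))
}

#' Percent change relative to control
#'
#' `100 x (mean(test) - mean(control)) / mean(control)`; identically
#' `percent_of_wt - 100`.
#'
#' @inheritParams percent_of_wt
#' @return percent change (numeric scalar).
#' @export
percent_change <- function(test_values, control_values) {
  m_c <- mean(control_values)
  if (!is.finite(m_c) || m_c == 0) {
    stop("percent_change: control mean is zero or undefined")
  }
  100 * (mean(test_values) - m_c) / m_c
}

#' Sidak adjustment
#'
#' `p_adj = 1 - (1 - p)^m` for `m` comparisons; monotone in both `p` and `m`.
#'
#' @param p raw p values.
#' @param m number of comparisons.
#' @return adjusted p values.
#' @export
sidak_adjust <- function(p, m) {
  stopifnot(m >= 1)
  pmin(1, 1 - (1 - p)^m)
}

#' Blocked two-factor ANOVA with Sidak pairwise contrasts
#'
#' Repeated-measures-style analysis of a long cohort table: a two-factor
#' least-squares ANOVA of `value` on genotype x region with animal as the
#' blocking (error) factor for the repeated region dimension —
#' `aov(value ~ genotype * region + Error(animal))`. The genotype effect is
#' tested against between-animal variation; region and the interaction
#' against the within-animal residual. Per-region genotype contrasts are
#' Welch t tests on animal values with Sidak adjustment over the number of
#' regions. All-identical values give F = 0, p = 1 by convention.
#'
#' @param table long data frame with columns genotype, animal, region, value
#'   (one value per animal x region; average tiles first).
#' @return list: `anova` (term, df, F, p), `contrasts` (region, per-genotype
#'   mean/SEM/n, t, p_raw, p_sidak).
#' @export
blocked_anova <- function(table) {
  stopifnot(all(c("genotype", "animal", "region", "value") %in% names(table)))
  table$genotype <- factor(table$genotype)
  table$region <- factor(table$region)
  table$animal <- factor(table$animal)
  if (nlevels(table$genotype) < 2L) stop("need >= 2 genotypes")
  counts <- table(unique(table[c("genotype", "animal")])$genotype)
  if (any(counts < 2L)) {
    stop("group with a single animal: ",
         paste(names(counts)[counts < 2L], collapse = ", "))
  }

  if (length(unique(table$value)) == 1L) {
    terms <- c("genotype", "region", "genotype:region")
    anova_tab <- data.frame(term = terms, df = NA_real_, F = 0, p = 1)
  } else {
    fit <- stats::aov(value ~ genotype * region + Error(animal), data = table)
    sm <- summary(fit)
    rows <- list()
    for (stratum in sm) {
      tb <- as.data.frame(stratum[[1]])
      tb$term <- trimws(rownames(tb))
      tb <- tb[tb$term != "Residuals", , drop = FALSE]
      if (nrow(tb)) {
        rows[[length(rows) + 1L]] <- data.frame(
          term = tb$term, df = tb$Df, F = tb$`F value`, p = tb$`Pr(>F)`)
      }
    }
    anova_tab <- do.call(rbind, rows)
    anova_tab$F[is.na(anova_tab$F)] <- 0
    anova_tab$p[is.na(anova_tab$p)] <- 1
  }

  regions <- levels(table$region)
  gl <- levels(table$genotype)
  m <- length(regions)
  contr <- lapply(regions, function(rg) {
    sub <- table[table$region == rg, ]
    g1 <- sub$value[sub$genotype == gl[1]]
    g2 <- sub$value[sub$genotype == gl[2]]
    tt <- tryCatch(t.test(g2, g1), error = function(e) NULL)
    praw <- if (is.null(tt)) 1 else tt$p.value
    data.frame(
      region = rg,
      mean_1 = mean(g1), sem_1 = sd(g1) / sqrt(length(g1)), n_1 = length(g1),
      mean_2 = mean(g2), sem_2 = sd(g2) / sqrt(length(g2)), n_2 = length(g2),
      t = if (is.null(tt)) 0 else unname(tt$statistic),
      p_raw = praw,
      p_sidak = sidak_adjust(praw, m),
      stringsAsFactors = FALSE
    )
  })
  contrasts <- do.call(rbind, contr)
  names(contrasts)[2:7] <- c(paste0("mean_", gl[1]), paste0("sem_", gl[1]),
                             paste0("n_", gl[1]), paste0("mean_", gl[2]),
                             paste0("sem_", gl[2]), paste0("n_", gl[2]))
  list(anova = anova_tab, contrasts = contrasts)
}

#' Compare latency-distance slopes between genotypes (ANCOVA)
#'
#' Tests equality of the two regression slopes via the distance x genotype
#' interaction term of a pooled ordinary least squares fit
#' `latency ~ distance * genotype`. A zero interaction sum of squares (e.g.
#' identical series) gives p = 1.
#'
#' @param series data frame with columns distance_mm, latency_ms, genotype
#'   (two levels, each with >= 2 distinct distances).
#' @return list: `delta_slope_ms_per_mm`, `F`, `df`, `p`, `fit`.
#' @export
compare_slopes <- function(series) {
  stopifnot(all(c("distance_mm", "latency_ms", "genotype") %in% names(series)))
  series <- series[!is.na(series$latency_ms), ]
  series$genotype <- factor(series$genotype)
  if (nlevels(series$genotype) != 2L) stop("need exactly 2 genotypes")
  for (g in levels(series$genotype)) {
    if (length(unique(series$distance_mm[series$genotype == g])) < 2L) {
      stop("collinear design: genotype ", g, " has < 2 distinct distances")
    }
  }
  fit <- lm(latency_ms ~ distance_mm * genotype, data = series)
  an <- anova(fit)
  irow <- grep(":", rownames(an))
  ss_int <- an$`Sum Sq`[irow]
  ss_res <- an$`Sum Sq`[nrow(an)]
  cf <- coef(fit)
  delta <- cf[grep(":", names(cf))]
  eps <- 1e-12 * max(sum(an$`Sum Sq`), 1e-12)
  if (ss_int < eps) {
    # no interaction signal (e.g. identical series) -> p = 1
    Fv <- 0; p <- 1
  } else if (ss_res < eps) {
    # perfect fit with a real slope difference
    Fv <- Inf; p <- 0
  } else {
    Fv <- an$`F value`[irow]
    p <- an$`Pr(>F)`[irow]
  }
  list(delta_slope_ms_per_mm = unname(delta), F = Fv,
       df = c(an$Df[irow], an$Df[nrow(an)]), p = p, fit = fit)
}

#' Write a comparisons report
#'
#' Writes each result data frame as CSV with deterministic column order plus
#' a human-readable markdown summary; analysis parameters and seeds passed in
#' `provenance` are echoed into the summary and a JSON sidecar.
#'
#' @param results named list of data frames (e.g. densities, comparisons,
#'   band power).
#' @param dir output directory (created if missing).
#' @param provenance named list of parameters/seeds to echo (e.g. the
#'   segmentation preset name and generator seeds).
#' @return invisibly, the paths written.
#' @export
write_report <- function(results, dir, provenance = list()) {
  stopifnot(is.list(results), length(results) >= 1L, !is.null(names(results)))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  md <- c("# gliaquant report", "")
  if (length(provenance)) {
    md <- c(md, "## Provenance", "",
            paste0("- ", names(provenance), ": ",
                   vapply(provenance, function(x) paste(format(x), collapse = ", "),
                          character(1))),
            "")
  }
  for (nm in names(results)) {
    df <- results[[nm]]
    df <- df[, sort(names(df)), drop = FALSE]
    p <- file.path(dir, paste0(nm, ".csv"))
    write.csv(df, p, row.names = FALSE)
    paths <- c(paths, p)
    md <- c(md, paste0("## ", nm), "",
            paste0("- rows: ", nrow(df)),
            paste0("- columns: ", paste(names(df), collapse = ", ")), "")
  }
  summary_path <- file.path(dir, "summary.md")
  writeLines(md, summary_path)
  jsonlite::write_json(provenance, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, null = "null")
  invisible(c(paths, summary_path))
}
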