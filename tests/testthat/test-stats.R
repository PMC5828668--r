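test_that("percent-of-control and percent change are consistent ratio statistics", {
  expect_equal(percent_of_wt(c(100, 100), c(100, 100))$percent, 100)
  expect_equal(percent_of_wt(c(195, 195), c(100, 100))$percent, 195)
  expect_equal(percent_change(c(130, 130), c(100, 100)), 30)
  expect_equal(percent_change(c(100, 100), c(100, 100)), 0)

  set.seed(14)
  nulls <- rnorm(5, 150, 10); wts <- rnorm(5, 100, 10)
  expect_equal(percent_of_wt(nulls, wts)$percent - 100,
               percent_change(nulls, wts))
  expect_error(percent_of_wt(c(1, 2), c(0, 0)), "control mean")

  # delta-method SEM agrees with a simulation of the ratio of means
  set.seed(15)
  sims <- replicate(4000, mean(rnorm(4, 150, 12)) / mean(rnorm(4, 100, 12)))
  got <- percent_of_wt(rnorm(4, 150, 12), rnorm(4, 100, 12))
  # compare orders of magnitude: propagated SEM should be near the
  # simulation SD of the ratio (x100), not exact for any single draw
  expect_lt(abs(got$sem - 100 * sd(sims)) / (100 * sd(sims)), 0.6)
})

test_that("Sidak adjustment is the exact formula and is monotone", {
  expect_equal(sidak_adjust(0.05, 1), 0.05)
  expect_equal(sidak_adjust(0.02, 3), 1 - 0.98^3) # 0.058808
  expect_equal(sidak_adjust(0.02, 3), 0.058808, tolerance = 1e-9)
  p <- seq(0.01, 0.2, by = 0.01)
  expect_true(all(diff(sidak_adjust(p, 4)) > 0))
  expect_true(all(sidak_adjust(0.03, 1:6) == cummax(sidak_adjust(0.03, 1:6))))
  expect_true(all(sidak_adjust(p, 5) >= p))
})

test_that("blocked ANOVA handles degenerate and structured cohorts", {
  tab <- expand.grid(genotype = c("WT", "null"), idx = 1:3,
                     region = c("OB", "CC"), stringsAsFactors = FALSE)
  tab$animal <- paste0(tab$genotype, "_", tab$idx)

  # all-identical values: F = 0, p = 1 by convention
  tab$value <- 5
  res <- blocked_anova(tab)
  expect_true(all(res$anova$F == 0))
  expect_true(all(res$anova$p == 1))

  # a clear genotype effect is detected and contrasts are Sidak-adjusted
  set.seed(33)
  tab$value <- rnorm(nrow(tab), ifelse(tab$genotype == "null", 140, 100), 5)
  res2 <- blocked_anova(tab)
  p_gen <- res2$anova$p[res2$anova$term == "genotype"]
  expect_lt(p_gen, 0.01)
  expect_equal(res2$contrasts$p_sidak,
               sidak_adjust(res2$contrasts$p_raw, 2))
  expect_true(all(res2$contrasts$p_sidak >= res2$contrasts$p_raw))

  # single-animal group is refused by name
  bad <- tab[tab$animal != "WT_3" | tab$genotype != "WT", ]
  bad <- bad[!(bad$animal %in% c("WT_2", "WT_3")), ]
  expect_error(blocked_anova(bad), "single animal")
})

test_that("blocked ANOVA holds its nominal type-I error on null cohorts", {
  set.seed(77)
  n_rep <- 400
  rejections <- 0L
  layout <- expand.grid(genotype = c("WT", "null"), idx = 1:3,
                        region = c("r1", "r2", "r3"),
                        stringsAsFactors = FALSE)
  layout$animal <- paste0(layout$genotype, "_", layout$idx)
  animals <- unique(layout$animal)
  for (i in seq_len(n_rep)) {
    eff <- rnorm(length(animals), 0, 0.5)
    names(eff) <- animals
    layout$value <- 10 + eff[layout$animal] + rnorm(nrow(layout))
    res <- blocked_anova(layout)
    p <- res$anova$p[res$anova$term == "genotype"]
    if (p < 0.05) rejections <- rejections + 1L
  }
  rate <- rejections / n_rep
  # binomial 95% band around 0.05 for 400 replicates: ~ [0.029, 0.071]
  expect_gt(rate, 0.05 - 1.96 * sqrt(0.05 * 0.95 / n_rep))
  expect_lt(rate, 0.05 + 1.96 * sqrt(0.05 * 0.95 / n_rep))
})

test_that("slope ANCOVA detects different conduction slopes and not identical ones", {
  x <- c(0.5, 1, 1.5, 2)
  # identical series -> interaction p = 1
  same <- rbind(
    data.frame(distance_mm = x, latency_ms = 0.3 + x / 1.5, genotype = "a"),
    data.frame(distance_mm = x, latency_ms = 0.3 + x / 1.5, genotype = "b"))
  res_same <- suppressWarnings(compare_slopes(same)) # perfect-fit warning
  expect_equal(res_same$p, 1)

  # slopes 1/1.5 vs 1/0.75 ms/mm with tiny noise: interaction detected
  set.seed(55)
  ser <- do.call(rbind, lapply(1:3, function(r) rbind(
    data.frame(distance_mm = x,
               latency_ms = 0.3 + x / 1.5 + rnorm(4, 0, 0.01),
               genotype = "wt"),
    data.frame(distance_mm = x,
               latency_ms = 0.3 + x / 0.75 + rnorm(4, 0, 0.01),
               genotype = "null"))))
  res <- compare_slopes(ser)
  expect_lt(res$p, 0.01)
  expect_equal(abs(res$delta_slope_ms_per_mm), 1 / 0.75 - 1 / 1.5,
               tolerance = 0.05)

  # interaction F equals a hand-assembled design-matrix OLS
  g <- as.integer(ser$genotype == "wt")
  X_full <- cbind(1, ser$distance_mm, g, ser$distance_mm * g)
  X_red <- X_full[, 1:3]
  rss <- function(X) {
    b <- solve(t(X) %*% X, t(X) %*% ser$latency_ms)
    sum((ser$latency_ms - X %*% b)^2)
  }
  df2 <- nrow(ser) - ncol(X_full)
  f_oracle <- (rss(X_red) - rss(X_full)) / (rss(X_full) / df2)
  expect_equal(res$F, f_oracle, tolerance = 1e-8)

  expect_error(compare_slopes(
    data.frame(distance_mm = 1, latency_ms = 1,
               genotype = c("a", "b"))), "collinear")
})

test_that("reports round-trip deterministically and echo provenance", {
  dir <- withr::local_tempdir()
  dens <- data.frame(genotype = c("WT", "null"), region = "CC",
                     value = c(3462.5, 4480.1))
  paths <- write_report(list(densities = dens), dir,
                        provenance = list(preset = "WT", seed = 11))
  csv <- read.csv(file.path(dir, "densities.csv"))
  expect_equal(csv$value, dens$value)
  expect_identical(names(csv), sort(names(dens)))
  md <- readLines(file.path(dir, "summary.md"))
  expect_true(any(grepl("preset: WT", md)))
  expect_true(any(grepl("seed: 11", md)))

  # empty comparisons -> header-only CSV
  empty <- dens[0, ]
  write_report(list(empty = empty), dir)
  back <- read.csv(file.path(dir, "empty.csv"))
  expect_identical(nrow(back), 0L)
  expect_identical(names(back), sort(names(dens)))
})
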