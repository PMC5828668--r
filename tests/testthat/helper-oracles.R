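# Independent brute-force oracles used across the suite. These deliberately
# avoid the code paths they check (no EBImage, no union-find, no lm, no
# wilcox.test, no fft).

# sliding min (erosion) / max (dilation) over an explicit disk, in-bounds
# neighborhood at borders
oracle_morph <- function(x, radius, op = min) {
  r <- floor(radius)
  offs <- expand.grid(dr = -r:r, dc = -r:r)
  offs <- offs[offs$dr^2 + offs$dc^2 <= radius^2, ]
  nr <- nrow(x); nc <- ncol(x)
  out <- x
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      rr <- i + offs$dr; cc <- j + offs$dc
      ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
      out[i, j] <- op(x[cbind(rr[ok], cc[ok])])
    }
  }
  out
}

oracle_open <- function(x, radius) {
  oracle_morph(oracle_morph(x, radius, min), radius, max)
}

# recursive flood fill component count
oracle_component_count <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  if (connectivity == 8) {
    nb <- cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    nb <- cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  }
  count <- 0L
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      if (!mask[i, j] || seen[i, j]) next
      count <- count + 1L
      stack <- list(c(i, j))
      seen[i, j] <- TRUE
      while (length(stack)) {
        p <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        for (k in seq_len(nrow(nb))) {
          q <- p + nb[k, ]
          if (q[1] >= 1 && q[1] <= nr && q[2] >= 1 && q[2] <= nc &&
              mask[q[1], q[2]] && !seen[q[1], q[2]]) {
            seen[q[1], q[2]] <- TRUE
            stack[[length(stack) + 1L]] <- q
          }
        }
      }
    }
  }
  count
}

# closed-form simple OLS
oracle_ols <- function(x, y) {
  xb <- mean(x); yb <- mean(y)
  slope <- sum((x - xb) * (y - yb)) / sum((x - xb)^2)
  c(intercept = yb - slope * xb, slope = slope)
}

# exact two-sided Mann-Whitney p by full enumeration of group assignments
oracle_mw_enum <- function(a, b) {
  u_stat <- function(a, b) sum(outer(a, b, `>`)) # no ties assumed
  pooled <- c(a, b)
  n1 <- length(a)
  idx <- utils::combn(length(pooled), n1)
  mu <- n1 * length(b) / 2
  obs <- abs(u_stat(a, b) - mu)
  us <- apply(idx, 2, function(ii) u_stat(pooled[ii], pooled[-ii]))
  mean(abs(us - mu) >= obs - 1e-12)
}

# explicit-DFT short-time power with a Hamming window (independent of fft())
oracle_stft_power <- function(x, fs, window_s = 1, overlap = 0.9) {
  n <- round(window_s * fs)
  hop <- max(1, round(n * (1 - overlap)))
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(n - 1)) / (n - 1))
  starts <- seq(1, length(x) - n + 1, by = hop)
  nf <- n %/% 2 + 1
  tt <- 0:(n - 1)
  pow <- matrix(0, nf, length(starts))
  for (j in seq_along(starts)) {
    seg <- x[starts[j]:(starts[j] + n - 1)] * w
    for (k in seq_len(nf)) {
      re <- sum(seg * cos(2 * pi * (k - 1) * tt / n))
      im <- -sum(seg * sin(2 * pi * (k - 1) * tt / n))
      p <- (re^2 + im^2) / (fs * sum(w^2))
      dbl <- if (k == 1 || (n %% 2 == 0 && k == nf)) 1 else 2
      pow[k, j] <- p * dbl
    }
  }
  list(power = pow, freq_hz = (seq_len(nf) - 1) * fs / n,
       time_s = (starts - 1 + (n - 1) / 2) / fs)
}

# build a bare cell_objects container from centroids (for matching tests)
make_objects <- function(rows, cols, dim = c(100, 100)) {
  n <- length(rows)
  structure(list(
    objects = data.frame(id = seq_len(n), centroid_row = rows,
                         centroid_col = cols,
                         area_px = rep(10L, n)),
    pixels = vector("list", n),
    dim = dim, params = NULL, meta = NULL, connectivity = 8L
  ), class = "cell_objects")
}

# small fast tile spec for unit tests
small_tile_spec <- function(density = 4000, seed = 1, ...) {
  tile_spec(width_px = 400L, height_px = 400L,
            true_density_cells_per_mm3 = density, seed = seed, ...)
}
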