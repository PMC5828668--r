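#' Discrete disk structuring element
#'
#' Returns the binary disk used by all morphological operations in the
#' package: the set of integer offsets \eqn{(dr, dc)} with
#' \eqn{dr^2 + dc^2 \le r^2}. The radius may be fractional (the presets carry
#' the fractional radii reported for blinded users), in which case the disk is
#' the integer offsets within that Euclidean radius.
#'
#' @param radius_px disk radius in pixels (> 0; may be fractional).
#' @return square 0/1 matrix of odd side `2*floor(radius_px) + 1`.
#' @export
#' @examples
#' disk_kernel(1)   # the 5-pixel "plus"
disk_kernel <- function(radius_px) {
  stopifnot(is.numeric(radius_px), length(radius_px) == 1L, radius_px > 0)
  r <- floor(radius_px)
  side <- 2L * r + 1L
  k <- matrix(0, side, side)
  dr <- row(k) - r - 1L
  dc <- col(k) - r - 1L
  k[dr^2 + dc^2 <= radius_px^2] <- 1
  k
}

# Derive a child seed from a parent seed and an index; keeps results inside
# the 32-bit integer range R requires of set.seed().
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 104729) %%
               2147483647)
}

# Evaluate `expr` under a fixed RNG state without disturbing the caller's.
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a
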