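# Internal helpers for bare-matrix rasters.
#
# Convention: a raster is a plain numeric/integer matrix, row-major reading
# order with cell [1, 1] at the north-west corner. All layers of a stack
# share one grid; there is no reprojection machinery here.

# Moving-window (box) sum of a matrix over a (2r+1) x (2r+1) window,
# truncated at the edges, via a padded summed-area table.
.box_sum <- function(m, radius) {
  nr <- nrow(m)
  nc <- ncol(m)
  # summed-area table with a zero border so index arithmetic never underflows
  sat <- matrix(0, nr + 1L, nc + 1L)
  down <- matrix(apply(m, 2L, cumsum), nr, nc)   # apply drops dims at nr = 1
  sat[-1L, -1L] <- t(matrix(apply(down, 1L, cumsum), nc, nr))
  r1 <- pmax(seq_len(nr) - radius, 1L)
  r2 <- pmin(seq_len(nr) + radius, nr)
  c1 <- pmax(seq_len(nc) - radius, 1L)
  c2 <- pmin(seq_len(nc) + radius, nc)
  # window sum by inclusion-exclusion, vectorised over the full grid
  R1 <- matrix(r1, nr, nc)
  R2 <- matrix(r2 + 1L, nr, nc)
  C1 <- matrix(c1, nr, nc, byrow = TRUE)
  C2 <- matrix(c2 + 1L, nr, nc, byrow = TRUE)
  out <- sat[cbind(c(R2), c(C2))] - sat[cbind(c(R1), c(C2))] -
    sat[cbind(c(R2), c(C1))] + sat[cbind(c(R1), c(C1))]
  matrix(out, nr, nc)
}

# Number of cells in each edge-truncated (2r+1)^2 window.
.box_count <- function(nr, nc, radius) {
  .box_sum(matrix(1, nr, nc), radius)
}

# Gaussian blur by separable convolution; the kernel is renormalised at the
# edges so a constant field stays constant.
.gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  half <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-half, half), sd = sigma)
  k <- k / sum(k)
  band <- function(n) {
    # n x n banded convolution matrix with edge renormalisation
    B <- matrix(0, n, n)
    for (d in seq(-half, half)) {
      i <- seq_len(n)
      j <- i + d
      ok <- j >= 1L & j <= n
      B[cbind(i[ok], j[ok])] <- k[d + half + 1L]
    }
    B / rowSums(B)
  }
  band(nrow(m)) %*% m %*% t(band(ncol(m)))
}

# Standard-normal field smoothed to spatial autocorrelation length ~ sigma.
.smooth_field <- function(nr, nc, sigma) {
  f <- .gaussian_blur(matrix(stats::rnorm(nr * nc), nr, nc), sigma)
  (f - mean(f)) / stats::sd(f)
}

# Euclidean distance (in cell units) from every cell to its nearest source
# cell, brute force over sources: fine for the handful of seeded sources the
# synthetic landscapes use.
.distance_to <- function(nr, nc, source_cells) {
  stopifnot(length(source_cells) >= 1L)
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  sr <- ((source_cells - 1L) %% nr) + 1L
  sc <- ((source_cells - 1L) %/% nr) + 1L
  d2 <- matrix(Inf, nr, nc)
  for (s in seq_along(source_cells)) {
    d2 <- pmin(d2, (rows - sr[s])^2 + (cols - sc[s])^2)
  }
  sqrt(d2)
}

# Derived sub-seed so each synthetic component has its own reproducible
# stream; kept below 2^31.
.sub_seed <- function(seed, k) {
  (as.numeric(seed) * 97L + k * 7919) %% 2147483647
}
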