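# Independent oracles, coded separately from the package implementations.

# Crossing-number (even-odd) point-in-polygon test for a single point.
# Walks every edge and counts crossings of the horizontal ray to the right.
brute_point_in_polygon <- function(px, py, vertices) {
  n <- nrow(vertices)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- vertices[i, 1]; yi <- vertices[i, 2]
    xj <- vertices[j, 1]; yj <- vertices[j, 2]
    if ((yi > py) != (yj > py)) {
      xcross <- xi + (py - yi) * (xj - xi) / (yj - yi)
      if (px < xcross) inside <- !inside
    }
    j <- i
  }
  inside
}

# Brute-force rasterisation: loop over every pixel centre.
brute_rasterize <- function(vertices, width, height) {
  m <- matrix(0L, nrow = height, ncol = width)
  for (r in seq_len(height)) {
    for (c in seq_len(width)) {
      if (brute_point_in_polygon(c - 0.5, r - 0.5, vertices)) m[r, c] <- 1L
    }
  }
  m
}

# Global histogram equalisation: each pixel maps to the empirical CDF of
# its 256-level quantised intensity.
brute_global_equalize <- function(mono, bins = 256L) {
  b <- pmin(floor(mono * bins), bins - 1L) + 1L
  cdf <- cumsum(tabulate(b, nbins = bins)) / length(mono)
  matrix(cdf[b], nrow = nrow(mono), ncol = ncol(mono))
}

# Between-class variance of the two-class split of 'vals' at threshold t,
# on a 256-bin histogram (Otsu's objective).
brute_bcv <- function(vals, t) {
  lo <- vals[vals <= t]; hi <- vals[vals > t]
  if (!length(lo) || !length(hi)) return(0)
  w0 <- length(lo) / length(vals)
  w0 * (1 - w0) * (mean(lo) - mean(hi))^2
}

# Random star-shaped (hence simple) polygon around a centre point.
random_simple_polygon <- function(n_vertices, cx, cy, r_min, r_max) {
  th <- sort(stats::runif(n_vertices, 0, 2 * pi))
  r <- stats::runif(n_vertices, r_min, r_max)
  cbind(cx + r * cos(th), cy + r * sin(th))
}

# Deterministic item vector of length n in [0, max_item] summing to 'total'.
make_items <- function(total, n, max_item) {
  items <- integer(n)
  for (i in seq_len(n)) {
    take <- min(max_item, total)
    items[i] <- take
    total <- total - take
  }
  stopifnot(total == 0)
  items
}
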