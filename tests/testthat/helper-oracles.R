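# Independent oracles and small fixtures shared across test files.
# Each oracle re-derives the quantity from first principles, never through
# the code path it checks.

# Brute-force buffer statistics: enumerate every cell centre of the whole
# raster and apply the distance test directly.
bf_buffer_oracle <- function(x, y, residential, vegetation, building_height,
                             radius_m) {
  cc <- cell_centers(residential)
  grid <- expand.grid(cy = cc$y, cx = cc$x)  # row-major to match matrix
  inside <- (grid$cx - x)^2 + (grid$cy - y)^2 <= radius_m^2
  rs <- as.vector(residential$values)[inside]
  vs <- as.vector(vegetation$values)[inside]
  hs <- as.vector(building_height$values)[inside]
  valid <- !is.na(rs)
  h <- hs[valid]
  built <- h[h > 0]
  list(pct_residential = 100 * sum(rs[valid] == 1) / sum(valid),
       pct_vegetation = 100 * sum(vs[valid] == 1, na.rm = TRUE) / sum(valid),
       avg = if (length(built)) mean(built) else 0,
       std = if (length(built) > 1) sd(built) else 0)
}

# O(n^2) pairwise-comparison percentile oracle (Hazen position with
# average ranks for ties).
bf_percentile_oracle <- function(v) {
  n <- length(v)
  sapply(v, function(vi) {
    rank_i <- sum(v < vi) + (sum(v == vi) + 1) / 2
    100 * (rank_i - 0.5) / n
  })
}

# Derivative-free likelihood maximization by iterated grid refinement,
# independent of the IRLS path.
bf_loglik_grid <- function(X, y, lo = -5, hi = 5, rounds = 18, pts = 9) {
  p <- ncol(X)
  centre <- rep(0, p)
  width <- hi - lo
  ll <- function(b) {
    pr <- plogis(drop(X %*% b))
    sum(dbinom(y, 1, pr, log = TRUE))
  }
  for (r in seq_len(rounds)) {
    grids <- lapply(seq_len(p), function(k)
      seq(centre[k] - width / 2, centre[k] + width / 2, length.out = pts))
    cand <- as.matrix(do.call(expand.grid, grids))
    vals <- apply(cand, 1, ll)
    centre <- cand[which.max(vals), ]
    width <- width * 2 / (pts - 1)   # shrink around the best point
  }
  centre
}

# Small synthetic city for fast spatial tests.
small_city <- function(seed = 1, n_subjects = 800) {
  city_config(extent_m = 1500, base_resolution_m = 10, n_tpu = 16,
              n_subjects = n_subjects, seed = seed)
}

# A 9-cell toy land-use raster: 4 residential cells out of 9.
toy_landuse_3x3 <- function() {
  codes <- matrix(c(1, 4, 2,
                    6, 3, 5,
                    1, 6, 7), 3, 3, byrow = TRUE)
  raster_layer(codes, origin = c(0, 0), resolution_m = 10,
               levels = c("private residential", "public residential",
                          "rural settlement", "commercial", "industrial",
                          "open space", "road"))
}

# Expand a 2x2 table into individual-level exposure/outcome rows.
expand_two_by_two <- function(tab) {
  data.frame(
    case = c(rep(1, tab$a), rep(1, tab$b), rep(0, tab$c), rep(0, tab$d)),
    exposed = c(rep(1, tab$a), rep(0, tab$b), rep(1, tab$c), rep(0, tab$d)))
}
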