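# Small fixtures shared across test files; everything is generated in code.

# KDE model over arbitrary 1-D points with a forced scalar covariance.
model_1d <- function(points, C = 1, abramson = FALSE, alpha = 1) {
  ps <- point_set(matrix(points, ncol = 1L), normalize = FALSE)
  bw <- structure(list(C = matrix(C), lambda = rep(1, length(points)),
                       geometric_mean_density = NA_real_, alpha = 1,
                       abramson_enabled = FALSE, iterations_used = 0L,
                       converged = TRUE), class = "donkey_bandwidth")
  if (abramson) bw <- abramson_rescale(ps, bw)
  kde_model(ps, bw, alpha = alpha)
}

# KDE model over an n x d matrix with a forced covariance matrix.
model_nd <- function(points, C, abramson = FALSE, alpha = 1) {
  ps <- point_set(points, normalize = FALSE)
  bw <- structure(list(C = as.matrix(C), lambda = rep(1, nrow(points)),
                       geometric_mean_density = NA_real_, alpha = 1,
                       abramson_enabled = FALSE, iterations_used = 0L,
                       converged = TRUE), class = "donkey_bandwidth")
  if (abramson) bw <- abramson_rescale(ps, bw)
  kde_model(ps, bw, alpha = alpha)
}

# Two tight, well-separated isotropic 2-D clouds (sigma at unit separation).
two_clouds <- function(n_per = 25L, sigma = 0.05, seed = 7L) {
  set.seed(seed)
  pts <- rbind(matrix(rnorm(2 * n_per, sd = sigma), ncol = 2L),
               matrix(rnorm(2 * n_per, sd = sigma), ncol = 2L) +
                 matrix(c(1, 0), n_per, 2L, byrow = TRUE))
  list(points = pts, truth = rep(1:2, each = n_per))
}

# Full-pipeline scores on a simplex benchmark, memoized across test files
# (several acceptance blocks score the same configurations).
.simplex_score_cache <- new.env(parent = emptyenv())
simplex_scores <- function(dim, sigma, seed) {
  key <- sprintf("d%d_s%g_r%d", dim, sigma, seed)
  if (is.null(.simplex_score_cache[[key]])) {
    d <- make_simplex(dim, sigma = sigma, per_cluster = 100L, seed = seed)
    res <- suppressWarnings(suppressMessages(donkey(d$points)))
    .simplex_score_cache[[key]] <- v_measure(d$truth_labels, res$labels)
  }
  .simplex_score_cache[[key]]
}

# Dense-grid mode detection oracle for 1-D models.
grid_modes_1d <- function(model, lo, hi, n = 20001L) {
  xs <- seq(lo, hi, length.out = n)
  f <- donkey:::.kde_batch(model, matrix(xs, ncol = 1L))$density
  idx <- which(f[2:(n - 1L)] > f[1:(n - 2L)] & f[2:(n - 1L)] >= f[3:n]) + 1L
  list(locations = xs[idx], density = f[idx], xs = xs, f = f)
}
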