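## Seeded synthetic benchmark generators with ground-truth labels.
## All randomness flows through the explicit `seed` argument; the caller's
## RNG state is left untouched.

.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

.dataset <- function(points, labels, name, params, seed) {
  structure(list(points = points, truth_labels = as.integer(labels),
                 generator = name, parameters = params, seed = seed),
            class = "donkey_dataset")
}

#' @export
print.donkey_dataset <- function(x, ...) {
  cat("Synthetic dataset '", x$generator, "': ", nrow(x$points), " points, ",
      ncol(x$points), " features, ", length(unique(x$truth_labels)),
      " classes (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

# Split n as evenly as possible over k groups (first groups get the remainder).
.even_split <- function(n, k) {
  base <- n %/% k
  counts <- rep(base, k)
  if (n %% k) counts[seq_len(n %% k)] <- base + 1L
  counts
}

# Conventional toy-set centres (shared by the blobs and varied generators).
.toy_centers <- function() {
  matrix(c(-8.9471, -5.4628,
           -4.5894,  0.0888,
            1.9388,  0.5051), ncol = 2L, byrow = TRUE)
}

#' Anisotropic blobs benchmark
#'
#' Three 2-D Gaussian clusters sharing one covariance: isotropic draws around
#' fixed centres, sheared by a common linear transform so the principal axes
#' are not aligned with the feature axes; two of the sheared clusters lie
#' close together.
#'
#' @param n_total total number of points (split as evenly as possible).
#' @param seed RNG seed.
#' @param centers k x 2 matrix of pre-shear cluster centres.
#' @param cluster_sd shared isotropic standard deviation before shearing.
#' @param shear 2 x 2 shear matrix applied to every point (row-vector
#'   convention, `x %*% shear`).
#' @return a `donkey_dataset`.
#' @export
make_blobs_aniso <- function(n_total = 500L, seed = 1L,
                             centers = .toy_centers(), cluster_sd = 1,
                             shear = matrix(c(0.6, -0.4, -0.6, 0.8), 2L, 2L)) {
  stopifnot(n_total >= 3L)
  k <- nrow(centers)
  counts <- .even_split(n_total, k)
  .with_seed(seed, {
    pts <- do.call(rbind, lapply(seq_len(k), function(i) {
      matrix(rnorm(2L * counts[i], sd = cluster_sd), ncol = 2L,
             byrow = TRUE) + matrix(centers[i, ], counts[i], 2L, byrow = TRUE)
    }))
    labels <- rep(seq_len(k), counts)
    .dataset(pts %*% shear, labels, "blobs_aniso",
             list(n_total = n_total, cluster_sd = cluster_sd,
                  centers = centers, shear = shear), seed)
  })
}

#' Overlapping variable-variance blobs benchmark
#'
#' Three isotropic 2-D Gaussian clusters with distinct standard deviations at
#' mutually separated centres, chosen so the clusters overlap pairwise.
#'
#' @param n_total total number of points.
#' @param seed RNG seed.
#' @param centers k x 2 matrix of cluster centres.
#' @param cluster_sds per-cluster standard deviations.
#' @return a `donkey_dataset`.
#' @export
make_varied <- function(n_total = 500L, seed = 1L,
                        centers = .toy_centers(),
                        cluster_sds = c(1.0, 2.5, 0.5)) {
  stopifnot(n_total >= 3L, nrow(centers) == length(cluster_sds))
  k <- nrow(centers)
  counts <- .even_split(n_total, k)
  .with_seed(seed, {
    pts <- do.call(rbind, lapply(seq_len(k), function(i) {
      matrix(rnorm(2L * counts[i], sd = cluster_sds[i]), ncol = 2L,
             byrow = TRUE) + matrix(centers[i, ], counts[i], 2L, byrow = TRUE)
    }))
    labels <- rep(seq_len(k), counts)
    .dataset(pts, labels, "varied",
             list(n_total = n_total, cluster_sds = cluster_sds,
                  centers = centers), seed)
  })
}

#' Concentric rings benchmark
#'
#' Two concentric circles (outer radius 1), points placed uniformly in angle
#' (equally spaced, as in the standard toy-set construction this benchmark
#' emulates) and perturbed by Gaussian radial noise. The default noise keeps
#' the rings separated.
#'
#' @param n_total total number of points (split evenly between the rings).
#' @param noise_sd radial noise standard deviation.
#' @param radius_ratio inner/outer radius ratio in (0, 1).
#' @param seed RNG seed.
#' @return a `donkey_dataset`.
#' @export
make_circles <- function(n_total = 500L, noise_sd = 0.03, radius_ratio = 0.5,
                         seed = 1L) {
  stopifnot(n_total >= 2L, radius_ratio > 0, radius_ratio < 1, noise_sd >= 0)
  if (1 - radius_ratio < 4 * noise_sd) {
    warning("radial noise is large enough for the rings to touch")
  }
  counts <- .even_split(n_total, 2L)
  .with_seed(seed, {
    radii <- c(1, radius_ratio)
    pts <- do.call(rbind, lapply(1:2, function(i) {
      th <- seq(0, 2 * pi, length.out = counts[i] + 1L)[-1L]
      r <- radii[i] + rnorm(counts[i], sd = noise_sd)
      cbind(r * cos(th), r * sin(th))
    }))
    labels <- rep(1:2, counts)
    .dataset(pts, labels, "circles",
             list(n_total = n_total, noise_sd = noise_sd,
                  radius_ratio = radius_ratio), seed)
  })
}

# Vertices of a regular unit-edge simplex: D+1 points in D dimensions, all
# pairwise distances exactly 1. Built from the scaled standard basis of
# R^(D+1) projected onto the sum-zero subspace.
.simplex_vertices <- function(dim) {
  v <- diag(dim + 1L) / sqrt(2)
  v <- sweep(v, 2L, colMeans(v))
  q <- qr.Q(qr(t(v)))[, seq_len(dim), drop = FALSE]
  v %*% q
}

#' Unit-simplex Gaussian mixture benchmark
#'
#' `dim + 1` isotropic Gaussian clusters centred at the vertices of a
#' regular unit simplex, `per_cluster` points each. The default simplex is
#' the standard one spanned by the unit basis vectors, whose edge length is
#' `sqrt(2)`; pass `edge = 1` for a unit-edge simplex. The standard
#' deviation controls the overlap: 0.1 gives well-separated clusters, 0.2 a
#' small overlap, 0.3 a large overlap.
#'
#' @param dim simplex dimensionality (>= 1).
#' @param sigma isotropic cluster standard deviation.
#' @param per_cluster points per cluster.
#' @param seed RNG seed.
#' @param edge simplex edge length (default `sqrt(2)`, the standard unit
#'   simplex).
#' @return a `donkey_dataset`.
#' @export
make_simplex <- function(dim, sigma = 0.1, per_cluster = 100L, seed = 1L,
                         edge = sqrt(2)) {
  stopifnot(dim >= 1L, sigma > 0, per_cluster >= 1L, edge > 0)
  vertices <- .simplex_vertices(dim) * edge
  k <- dim + 1L
  .with_seed(seed, {
    pts <- do.call(rbind, lapply(seq_len(k), function(i) {
      matrix(rnorm(dim * per_cluster, sd = sigma), per_cluster, dim) +
        matrix(vertices[i, ], per_cluster, dim, byrow = TRUE)
    }))
    labels <- rep(seq_len(k), each = per_cluster)
    .dataset(pts, labels, "simplex",
             list(dim = dim, sigma = sigma, per_cluster = per_cluster,
                  edge = edge, vertices = vertices), seed)
  })
}
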