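#' Construct a normalized point set
#'
#' Wraps an N x D numeric matrix of data points and (by default) applies the
#' per-feature affine map onto \[0, 1\] that the clustering pipeline operates
#' in. The map is recorded so that locations found in normalized coordinates
#' (cluster centres, saddle points) can be reported on the original scale.
#'
#' Constant (zero-range) feature columns carry no information and make the
#' \[0,1\] map undefined; they are dropped with a message and their indices
#' recorded in `dropped_features`.
#'
#' @param x numeric matrix or data frame, one row per point.
#' @param normalize logical; map every feature onto \[0, 1\] (default `TRUE`).
#'   When `FALSE` the data are used as-is but the range bookkeeping is still
#'   recorded.
#' @return An object of class `donkey_pointset` with elements `points`
#'   (the working matrix), `feature_min`, `feature_max` (original per-feature
#'   ranges of the kept columns), `dropped_features`, `n_points`, `dim`,
#'   and `normalized`.
#' @examples
#' ps <- point_set(matrix(rnorm(40), 20, 2))
#' range(ps$points[, 1])
#' @export
point_set <- function(x, normalize = TRUE) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (anyNA(x) || any(!is.finite(x))) {
    stop("point set contains non-finite values")
  }
  if (nrow(x) < 2L) {
    stop("at least two data points are required (leave-one-out likelihood)")
  }
  cmin <- apply(x, 2L, min)
  cmax <- apply(x, 2L, max)
  rng <- cmax - cmin
  degenerate <- rng <= 0
  dropped <- which(degenerate)
  if (length(dropped)) {
    message("dropping ", length(dropped), " constant feature column(s): ",
            paste(dropped, collapse = ", "))
    x <- x[, !degenerate, drop = FALSE]
    cmin <- cmin[!degenerate]
    cmax <- cmax[!degenerate]
    rng <- rng[!degenerate]
  }
  if (normalize && ncol(x) > 0L) {
    x <- sweep(sweep(x, 2L, cmin, "-"), 2L, rng, "/")
  }
  structure(list(
    points = x,
    feature_min = cmin,
    feature_max = cmax,
    dropped_features = dropped,
    n_points = nrow(x),
    dim = ncol(x),
    normalized = normalize
  ), class = "donkey_pointset")
}

#' @export
print.donkey_pointset <- function(x, ...) {
  cat("Point set: ", x$n_points, " points in ", x$dim, " dimension(s)",
      if (x$normalized) ", normalized to [0,1]" else "", "\n", sep = "")
  if (length(x$dropped_features)) {
    cat("  dropped constant features:",
        paste(x$dropped_features, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Map normalized coordinates back to the original feature scale
#'
#' @param ps a `donkey_pointset`.
#' @param x matrix (or vector) of locations in the working coordinates.
#' @return matrix of locations on the original scale of the kept features.
#' @export
denormalize <- function(ps, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (!ps$normalized) return(x)
  rng <- ps$feature_max - ps$feature_min
  sweep(sweep(x, 2L, rng, "*"), 2L, ps$feature_min, "+")
}
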