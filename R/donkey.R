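## End-to-end pipeline: normalize -> optimize covariance -> Abramson ->
## mode assignment -> saddle search / merging -> outlier flags, with cheap
## warm restarts at the alpha, beta and gamma stages.

#' Cluster a point set by adaptive kernel density estimation
#'
#' Runs the full density-based clustering pipeline: per-feature \[0,1\]
#' normalization, leave-one-out-likelihood optimization of the shared kernel
#' covariance, Abramson local bandwidth rescaling, assignment of every point
#' to its dominant density maximum by safeguarded Newton ascent, and merging
#' of maxima separated only by high-lying first-order saddle points. The
#' defaults require no tuning; `alpha`, `beta` and `gamma` exist for the rare
#' cases where the density is over/under-smoothed, clusters fracture, or
#' outlier flagging is wanted.
#'
#' @param x N x D numeric matrix (or data frame) of points, or a
#'   `donkey_pointset`.
#' @param alpha global kernel broadening factor (> 0, default 1).
#' @param beta merge threshold on the saddle-to-peak density ratio, in (0,1);
#'   default `exp(-1)`, the Gaussian drop-off one standard deviation from a
#'   peak.
#' @param gamma outlier threshold on the point-to-centre density ratio
#'   (>= 0); 0 (default) disables outlier flagging.
#' @param abramson enable the Abramson local bandwidth correction (default
#'   `TRUE`); disable it if structure is suspected in the distribution tails.
#' @param normalize map features onto \[0,1\] first (default `TRUE`).
#' @param tol convergence tolerance used by the covariance fixed point and,
#'   scaled, by the ascent/saddle searches.
#' @param seed recorded in the result for provenance (the pipeline itself is
#'   deterministic).
#' @return An object of class `donkey`: `labels` (1-based, contiguous,
#'   ordered by decreasing peak density), `outlier_flags`, `maxima`
#'   (post-merge representatives with locations in both normalized and
#'   original coordinates), `merge_matrix`, `merge_history`, `parameters`,
#'   and the stored intermediates that [rerun_with()] reuses.
#' @examples
#' d <- make_simplex(2, sigma = 0.05, per_cluster = 30, seed = 7)
#' res <- donkey(d$points)
#' table(res$labels, d$truth_labels)
#' @export
donkey <- function(x, alpha = 1, beta = exp(-1), gamma = 0, abramson = TRUE,
                   normalize = TRUE, tol = 1e-6, seed = NULL) {
  if (!is.numeric(alpha) || alpha <= 0) stop("alpha must be positive")
  if (!is.numeric(beta) || beta <= 0 || beta >= 1) {
    stop("beta must lie strictly between 0 and 1")
  }
  if (!is.numeric(gamma) || gamma < 0) stop("gamma must be non-negative")
  ps <- if (inherits(x, "donkey_pointset")) x else point_set(x, normalize)
  n <- ps$n_points
  if (ps$dim == 0L) {
    # all features constant: every point is the same point — one cluster
    return(structure(list(
      labels = rep(1L, n), outlier_flags = rep(FALSE, n),
      maxima = list(list(location = numeric(0), location_original = numeric(0),
                         density = NA_real_, size = n)),
      merge_matrix = matrix(NA_real_, 1L, 1L),
      merge_history = data.frame(a = integer(0), b = integer(0),
                                 mu = numeric(0)),
      parameters = list(alpha = alpha, beta = beta, gamma = gamma,
                        abramson = abramson, normalize = normalize,
                        seed = seed),
      point_set = ps, bandwidth = NULL, model = NULL, assignment = NULL
    ), class = "donkey"))
  }
  bw <- optimize_covariance(ps, tol = tol)
  if (abramson) bw <- abramson_rescale(ps, bw)
  .donkey_from_bandwidth(ps, bw, alpha, beta, gamma, abramson, normalize,
                         seed)
}

# alpha stage onward: build the final KDE, assign, merge, flag.
.donkey_from_bandwidth <- function(ps, bw, alpha, beta, gamma, abramson,
                                   normalize, seed) {
  model <- kde_model(ps, bw, alpha = alpha)
  asg <- assign_points(model)
  mm <- merge_matrix(model, asg$maxima)
  .donkey_from_matrix(ps, bw, model, asg, mm, alpha, beta, gamma, abramson,
                      normalize, seed)
}

# beta stage onward: merge and flag using stored maxima and merging matrix.
.donkey_from_matrix <- function(ps, bw, model, asg, mm, alpha, beta, gamma,
                                abramson, normalize, seed) {
  mg <- merge_clusters(mm$m, beta = beta)
  labels <- mg$mapping[asg$labels]
  k_final <- max(mg$mapping)
  # representative of each merged group = its highest-density pre-merge
  # maximum (lowest pre-merge label, by the density ordering)
  rep_idx <- vapply(seq_len(k_final),
                    function(g) min(which(mg$mapping == g)), integer(1))
  center_density <- vapply(rep_idx, function(i) {
    max(vapply(which(mg$mapping == mg$mapping[i]),
               function(j) asg$maxima[[j]]$density, numeric(1)))
  }, numeric(1))
  point_density <- .kde_batch(model, ps$points)$density
  flags <- flag_outliers(point_density, labels, center_density, gamma)
  maxima <- lapply(seq_len(k_final), function(g) {
    loc <- asg$maxima[[rep_idx[g]]]$location
    list(location = loc,
         location_original = as.numeric(denormalize(ps, loc)),
         density = center_density[g],
         size = sum(labels == g))
  })
  structure(list(
    labels = labels,
    outlier_flags = flags,
    maxima = maxima,
    merge_matrix = mm$m,
    merge_history = mg$history,
    parameters = list(alpha = alpha, beta = beta, gamma = gamma,
                      abramson = abramson, normalize = normalize,
                      seed = seed),
    point_set = ps,
    bandwidth = bw,
    model = model,
    assignment = asg
  ), class = "donkey")
}

#' @export
print.donkey <- function(x, ...) {
  k <- length(x$maxima)
  cat("Density-based clustering: ", length(x$labels), " points -> ", k,
      " cluster(s)\n", sep = "")
  sizes <- vapply(x$maxima, `[[`, numeric(1), "size")
  cat("  sizes:", paste(sizes, collapse = ", "), "\n")
  if (nrow(x$merge_history)) {
    cat("  merges executed:", nrow(x$merge_history), "\n")
  }
  if (any(x$outlier_flags)) {
    cat("  outliers flagged:", sum(x$outlier_flags), "\n")
  }
  p <- x$parameters
  cat("  parameters: alpha = ", p$alpha, ", beta = ", format(p$beta),
      ", gamma = ", p$gamma, ", Abramson ",
      if (p$abramson) "on" else "off", "\n", sep = "")
  invisible(x)
}

#' Re-run the clustering from the cheapest possible stage
#'
#' Changing `alpha` restarts just before the maxima search (the optimized
#' covariance and Abramson factors are independent of it); changing `beta`
#' restarts at the merge loop (reusing the merging matrix); changing `gamma`
#' only recomputes the outlier flags. The result is identical to a cold run
#' with the same parameters.
#'
#' @param result a `donkey` result with stored intermediates.
#' @param alpha,beta,gamma the parameter to change (supply exactly one, or
#'   none to reproduce the result).
#' @return a new `donkey` result.
#' @export
rerun_with <- function(result, alpha = NULL, beta = NULL, gamma = NULL) {
  stopifnot(inherits(result, "donkey"))
  if (is.null(result$model) || is.null(result$bandwidth)) {
    stop("result carries no stored intermediates; re-run donkey() fully")
  }
  p <- result$parameters
  if (!is.null(alpha)) {
    return(.donkey_from_bandwidth(result$point_set, result$bandwidth, alpha,
                                  if (is.null(beta)) p$beta else beta,
                                  if (is.null(gamma)) p$gamma else gamma,
                                  p$abramson, p$normalize, p$seed))
  }
  if (!is.null(beta)) {
    mm <- list(m = result$merge_matrix)
    return(.donkey_from_matrix(result$point_set, result$bandwidth,
                               result$model, result$assignment, mm,
                               p$alpha, beta,
                               if (is.null(gamma)) p$gamma else gamma,
                               p$abramson, p$normalize, p$seed))
  }
  g <- if (is.null(gamma)) p$gamma else gamma
  mm <- list(m = result$merge_matrix)
  .donkey_from_matrix(result$point_set, result$bandwidth, result$model,
                      result$assignment, mm, p$alpha, p$beta, g,
                      p$abramson, p$normalize, p$seed)
}

#' Serialize a clustering result to JSON
#'
#' Writes labels, outlier flags, maxima (locations, densities, sizes), the
#' merging matrix and history, parameters, and the normalization map, so a
#' run can be audited or re-imported.
#'
#' @param result a `donkey` result.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_result_json <- function(result, path) {
  stopifnot(inherits(result, "donkey"))
  ps <- result$point_set
  out <- list(
    labels = result$labels,
    outlier_flags = result$outlier_flags,
    maxima = lapply(result$maxima, function(m) {
      list(location = m$location, location_original = m$location_original,
           density = m$density, size = m$size)
    }),
    merge_matrix = result$merge_matrix,
    merge_history = result$merge_history,
    parameters = result$parameters,
    normalization_map = list(feature_min = ps$feature_min,
                             feature_max = ps$feature_max,
                             dropped_features = ps$dropped_features,
                             normalized = ps$normalized),
    versions = list(donkey = as.character(utils::packageVersion("donkey")),
                    r = R.version.string)
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Export / import a bandwidth model as JSON
#'
#' Persists the pilot covariance, the per-point Abramson factors, and the
#' parameters so a fitted density model can be rebuilt without re-optimizing.
#'
#' @param bandwidth a `donkey_bandwidth`.
#' @param path file path.
#' @return for the writer, `path` invisibly; for the reader, a
#'   `donkey_bandwidth`.
#' @export
write_bandwidth_json <- function(bandwidth, path) {
  stopifnot(inherits(bandwidth, "donkey_bandwidth"))
  jsonlite::write_json(unclass(bandwidth), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_bandwidth_json
#' @export
read_bandwidth_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    C = as.matrix(raw$C),
    lambda = as.numeric(raw$lambda),
    geometric_mean_density = as.numeric(raw$geometric_mean_density),
    alpha = as.numeric(raw$alpha),
    abramson_enabled = isTRUE(raw$abramson_enabled),
    iterations_used = as.integer(raw$iterations_used),
    converged = isTRUE(raw$converged)
  ), class = "donkey_bandwidth")
}
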