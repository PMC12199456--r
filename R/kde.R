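## Kernel density core: Gaussian kernels with a full covariance matrix,
## leave-one-out likelihood, the fixed-point covariance optimizer, and the
## Abramson local-bandwidth correction.

# Cholesky with an SPD check; returns the upper factor.
.chol_spd <- function(covariance) {
  covariance <- as.matrix(covariance)
  if (!isSymmetric(covariance, tol = 1e-8)) {
    stop("covariance must be symmetric")
  }
  ch <- tryCatch(chol(covariance), error = function(e) NULL)
  if (is.null(ch)) stop("covariance must be positive definite")
  ch
}

#' Multivariate Gaussian kernel
#'
#' Normalized Gaussian density at a displacement, with covariance
#' `alpha * covariance`. The global broadening factor `alpha` rescales the
#' kernel covariance uniformly while keeping the kernel a proper density
#' (it integrates to 1 for every `alpha > 0`); `alpha = 1` is the plain
#' Gaussian kernel.
#'
#' @param displacement numeric vector x - y of length D.
#' @param covariance D x D symmetric positive-definite matrix.
#' @param alpha positive global broadening factor (default 1).
#' @return the kernel density value (non-negative scalar).
#' @examples
#' gaussian_kernel(0, matrix(1), 1)  # 1/sqrt(2*pi)
#' @export
gaussian_kernel <- function(displacement, covariance, alpha = 1) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0) {
    stop("alpha must be a positive scalar")
  }
  displacement <- as.numeric(displacement)
  covariance <- as.matrix(covariance)
  d <- length(displacement)
  if (!all(dim(covariance) == d)) {
    stop("dimension mismatch between displacement and covariance")
  }
  ch <- .chol_spd(covariance)
  ldet <- 2 * sum(log(diag(ch)))
  z <- backsolve(ch, displacement, transpose = TRUE)
  mah <- sum(z * z) / alpha
  exp(-0.5 * (mah + d * log(2 * pi * alpha) + ldet))
}

## ---- internal pairwise machinery ------------------------------------------

# Squared Mahalanobis distances x_p^T Cinv x_p between all rows of X and Y.
.mahalanobis_cross <- function(X, Y, cinv) {
  XC <- X %*% cinv
  qx <- rowSums(XC * X)
  qy <- rowSums((Y %*% cinv) * Y)
  m <- -2 * XC %*% t(Y)
  m <- m + outer(qx, rep(1, nrow(Y))) + outer(rep(1, nrow(X)), qy)
  m[m < 0] <- 0  # clip tiny negative round-off
  m
}

## ---- leave-one-out likelihood ---------------------------------------------

#' Leave-one-out log-likelihood of a KDE covariance
#'
#' Mean over points of the log density of each point under the kernel density
#' estimate built from all *other* points with the shared covariance `C`.
#' Excluding the point's own kernel prevents the likelihood from diverging as
#' the bandwidth collapses, which is what makes the covariance optimization
#' well-posed.
#'
#' @param points N x D matrix (or a `donkey_pointset`).
#' @param covariance D x D SPD matrix.
#' @return scalar log-likelihood (natural log).
#' @export
loo_log_likelihood <- function(points, covariance) {
  if (inherits(points, "donkey_pointset")) points <- points$points
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < 2L) stop("leave-one-out likelihood needs at least two points")
  ch <- .chol_spd(covariance)
  ldet <- 2 * sum(log(diag(ch)))
  cinv <- chol2inv(ch)
  d <- ncol(points)
  logk0 <- -0.5 * (d * log(2 * pi) + ldet)
  lw <- logk0 - 0.5 * .mahalanobis_cross(points, points, cinv)
  diag(lw) <- -Inf
  # row-wise log-sum-exp, stable even when all kernels underflow
  mx <- apply(lw, 1L, max)
  lse <- mx + log(rowSums(exp(lw - mx)))
  mean(lse - log(n - 1))
}

## ---- covariance optimization ----------------------------------------------

#' Optimize the pilot covariance by fixed-point iteration
#'
#' Finds the shared kernel covariance `C` maximising the leave-one-out
#' likelihood, by repeated substitution into the self-consistency relation
#' obtained from the stationarity condition: the updated `C` is the average
#' over points of the kernel-weighted outer products of pairwise differences.
#' The iteration starts from the D x D identity, which on \[0,1\]-normalized
#' data overestimates the spread so the fixed point is approached from above.
#'
#' @param points N x D matrix or `donkey_pointset`.
#' @param tol relative Frobenius-norm convergence tolerance (default `1e-6`).
#' @param max_iter iteration cap (default 500).
#' @param eig_floor smallest admissible eigenvalue of `C`; below it a ridge is
#'   added (degenerate data) and a warning issued.
#' @return object of class `donkey_bandwidth`: `C`, `lambda` (per-point
#'   Abramson factors, all 1 until [abramson_rescale()] is applied),
#'   `geometric_mean_density` (`NA` until rescaling), `alpha`,
#'   `abramson_enabled`, `iterations_used`, `converged`.
#' @export
optimize_covariance <- function(points, tol = 1e-6, max_iter = 500L,
                                eig_floor = 1e-8) {
  if (inherits(points, "donkey_pointset")) points <- points$points
  Y <- as.matrix(points)
  n <- nrow(Y)
  d <- ncol(Y)
  if (n < 2L) stop("covariance optimization needs at least two points")
  if (all(.mahalanobis_cross(Y, Y, diag(d)) < 1e-24)) {
    stop("all points identical; covariance optimization is undefined")
  }
  C <- diag(d)
  converged <- FALSE
  it <- 0L
  regularized <- FALSE
  repeat {
    it <- it + 1L
    ch <- .chol_spd(C)
    cinv <- chol2inv(ch)
    lw <- -0.5 * .mahalanobis_cross(Y, Y, cinv)  # log-kernel up to constant
    diag(lw) <- -Inf
    mx <- apply(lw, 1L, max)
    W <- exp(lw - mx)              # row-stable weights
    W <- W / rowSums(W)            # per-point normalized kernel weights
    # sum_ij w_ij (Y_i - Y_j)(Y_i - Y_j)^T / N, expanded into BLAS products
    csum <- colSums(W)
    TY <- t(Y) %*% W %*% Y
    Cnew <- (crossprod(Y) + crossprod(Y * sqrt(csum)) - TY - t(TY)) / n
    Cnew <- (Cnew + t(Cnew)) / 2
    ev <- eigen(Cnew, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < eig_floor) {
      Cnew <- Cnew + (eig_floor - min(ev)) * diag(d)
      regularized <- TRUE
    }
    delta <- norm(Cnew - C, "F") / max(norm(C, "F"), .Machine$double.eps)
    C <- Cnew
    if (delta < tol) { converged <- TRUE; break }
    if (it >= max_iter) break
  }
  if (!converged) {
    warning("covariance fixed-point iteration did not converge in ",
            max_iter, " iterations (last relative change ",
            format(delta, digits = 3), ")")
  }
  if (regularized) {
    warning("covariance eigenvalue fell below the floor (", eig_floor,
            "); ridge regularization applied - data may be degenerate ",
            "in some direction")
  }
  structure(list(
    C = C,
    lambda = rep(1, n),
    geometric_mean_density = NA_real_,
    alpha = 1,
    abramson_enabled = FALSE,
    iterations_used = it,
    converged = converged
  ), class = "donkey_bandwidth")
}

#' @export
print.donkey_bandwidth <- function(x, ...) {
  cat("Bandwidth model: pilot covariance ", nrow(x$C), "x", ncol(x$C),
      ", ", x$iterations_used, " iterations",
      if (!x$converged) " (NOT converged)", "\n", sep = "")
  cat("  Abramson local rescaling:",
      if (x$abramson_enabled) "enabled" else "disabled", "\n")
  invisible(x)
}

## ---- KDE model -------------------------------------------------------------

#' Build an evaluable kernel density model
#'
#' Combines a point set and a bandwidth model into a density estimate
#' `f(x) = (1/N) sum_i K(x - Y_i | alpha * lambda_i * C)` with analytic
#' gradient and Hessian. Per-kernel covariances are the pilot covariance
#' scaled by the Abramson factor `lambda_i` and the global broadening `alpha`.
#'
#' @param point_set a `donkey_pointset`.
#' @param bandwidth a `donkey_bandwidth`.
#' @param alpha positive global broadening factor; overrides the value stored
#'   in `bandwidth` when supplied.
#' @return object of class `donkey_kde`.
#' @export
kde_model <- function(point_set, bandwidth, alpha = NULL) {
  stopifnot(inherits(point_set, "donkey_pointset"),
            inherits(bandwidth, "donkey_bandwidth"))
  if (is.null(alpha)) alpha <- bandwidth$alpha
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0) {
    stop("alpha must be a positive scalar")
  }
  Y <- point_set$points
  d <- ncol(Y)
  if (!all(dim(bandwidth$C) == d)) {
    stop("bandwidth covariance dimension does not match the point set")
  }
  ch <- .chol_spd(bandwidth$C)
  s <- alpha * bandwidth$lambda           # per-kernel covariance scale factors
  cinv <- chol2inv(ch)
  Ycinv <- Y %*% cinv
  structure(list(
    point_set = point_set,
    bandwidth = bandwidth,
    alpha = alpha,
    Y = Y,
    n = nrow(Y),
    d = d,
    cinv = cinv,
    logdet_C = 2 * sum(log(diag(ch))),
    s = s,
    logk0 = -0.5 * (d * log(2 * pi) + 2 * sum(log(diag(ch))) + d * log(s)),
    # smallest kernel standard deviation: the natural step-length scale
    sigma_min = sqrt(min(eigen(bandwidth$C, symmetric = TRUE,
                               only.values = TRUE)$values) * min(s)),
    # precomputed per-kernel quantities reused by every evaluation
    Ycinv = Ycinv,
    qy = rowSums(Ycinv * Y),
    YY = Y[, rep(seq_len(d), each = d), drop = FALSE] *
         Y[, rep(seq_len(d), times = d), drop = FALSE]
  ), class = "donkey_kde")
}

#' @export
print.donkey_kde <- function(x, ...) {
  cat("KDE model: ", x$n, " kernels in ", x$d, " dimension(s), alpha = ",
      x$alpha, ", Abramson ",
      if (x$bandwidth$abramson_enabled) "on" else "off", "\n", sep = "")
  invisible(x)
}

# Batched evaluation at P probe points. Returns density (length P) and,
# optionally, gradients (P x D), Hessians (P x D x D), and the P x N kernel
# matrix (each entry K_i(x_p)/N) needed for per-cluster partial weights.
.kde_batch <- function(model, X, gradient = FALSE, hessian = FALSE,
                       kernels = FALSE) {
  X <- if (is.null(dim(X))) matrix(X, nrow = 1L) else as.matrix(X)
  p <- nrow(X)
  d <- model$d
  n <- model$n
  XC <- X %*% model$cinv
  mah <- -2 * XC %*% t(model$Y)
  mah <- mah + rowSums(XC * X) + rep(model$qy, each = p)
  mah[mah < 0] <- 0
  mah <- sweep(mah, 2L, model$s, "/")
  K <- exp(sweep(-0.5 * mah, 2L, model$logk0, "+"))
  f <- rowSums(K) / n
  out <- list(density = f)
  if (gradient || hessian) {
    Ks <- sweep(K, 2L, model$s, "/")
    w1 <- rowSums(Ks)
    # sum_i (K/s)_pi (x_p - Y_i) = w1_p x_p - (Ks Y)_p
    G <- (X * w1 - Ks %*% model$Y) %*% model$cinv / n
    out$gradient <- -G
  }
  if (hessian) {
    Ks2 <- sweep(K, 2L, model$s^2, "/")
    r <- rowSums(Ks2)
    A <- Ks2 %*% model$Y                                   # P x D
    B <- Ks2 %*% model$YY                                  # P x D^2
    H <- array(0, c(p, d, d))
    for (d1 in seq_len(d)) for (d2 in seq_len(d)) {
      S2 <- r * X[, d1] * X[, d2] - X[, d1] * A[, d2] -
            X[, d2] * A[, d1] + B[, (d1 - 1L) * d + d2]
      H[, d1, d2] <- S2
    }
    cinv <- model$cinv
    for (q in seq_len(p)) {
      S2q <- matrix(H[q, , ], d, d)
      Hq <- (cinv %*% S2q %*% cinv - w1[q] * cinv) / n
      H[q, , ] <- (Hq + t(Hq)) / 2
    }
    out$hessian <- H
  }
  if (kernels) out$kernels <- K / n
  out
}

#' Evaluate the density estimate with analytic derivatives
#'
#' @param model a `donkey_kde`.
#' @param x numeric vector of length D (one probe point).
#' @return list with `density` (scalar), `gradient` (length-D vector) and
#'   `hessian` (D x D symmetric matrix) of the estimate at `x`.
#' @export
kde_evaluate <- function(model, x) {
  stopifnot(inherits(model, "donkey_kde"))
  x <- as.numeric(x)
  if (length(x) != model$d) stop("probe point has wrong dimension")
  if (any(!is.finite(x))) stop("probe point must be finite")
  b <- .kde_batch(model, matrix(x, 1L), gradient = TRUE, hessian = TRUE)
  list(density = b$density[1L],
       gradient = as.numeric(b$gradient[1L, ]),
       hessian = matrix(b$hessian[1L, , ], model$d, model$d))
}

## ---- Abramson local rescaling ---------------------------------------------

#' Abramson variable-bandwidth rescaling of the pilot covariance
#'
#' Evaluates the pilot density at every data point and rescales each kernel's
#' covariance by `(f(Y_k) / g)^(-1/2)`, where `g` is the geometric mean of the
#' pilot densities. Kernels in dense regions narrow, kernels in sparse regions
#' broaden; the geometric mean of the factors is exactly 1 by construction.
#'
#' @param point_set a `donkey_pointset`.
#' @param bandwidth a `donkey_bandwidth` holding the uniform pilot covariance.
#' @return a new `donkey_bandwidth` with per-point factors `lambda` and
#'   `abramson_enabled = TRUE`.
#' @export
abramson_rescale <- function(point_set, bandwidth) {
  stopifnot(inherits(point_set, "donkey_pointset"),
            inherits(bandwidth, "donkey_bandwidth"))
  pilot <- kde_model(point_set, bandwidth, alpha = 1)
  f <- .kde_batch(pilot, point_set$points)$density
  if (any(f <= 0)) {
    warning("pilot density numerically zero at some data points; flooring")
    f <- pmax(f, .Machine$double.xmin)
  }
  logf <- log(f)
  logg <- mean(logf)
  lambda <- exp(-0.5 * (logf - logg))
  out <- bandwidth
  out$lambda <- lambda
  out$geometric_mean_density <- exp(logg)
  out$abramson_enabled <- TRUE
  out
}
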