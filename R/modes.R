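## Mode seeking: assign every point to the density maximum reached by
## safeguarded Newton ascent on the KDE, and deduplicate converged endpoints
## into cluster centres.

# Convergence test used by all climbers: the gradient norm is compared to
# tol * (1 + f) so the criterion is insensitive to the absolute scale of the
# density (which grows rapidly with dimension for narrow kernels); for f >> 1
# this is a tolerance on the gradient of log f.
.grad_converged <- function(gnorm, f, tol) gnorm <= tol * (1 + f)

# Relaxed criterion applied only when backtracking can no longer increase the
# density: at a peak the achievable gradient norm is limited by the floating-
# point precision of f itself, which can sit above the nominal tolerance.
.stall_tol <- function(tol) max(tol, 1e-6)

# Combined per-point analysis: convergence plus the ascent direction.
# Besides the gradient test, a point with a negative-definite Hessian is
# converged when its Newton decrement (the estimated remaining density gain
# 0.5 g^T (-H)^{-1} g) drops below the floating-point resolution of the
# density itself - at a sharp peak this resolution limit is reached while
# the gradient norm is still well above the nominal tolerance.
.climb_analyze <- function(g, H, f, tol, max_step = 0.25) {
  ev <- eigen(H, symmetric = TRUE)
  lam <- ev$values
  gp <- as.numeric(crossprod(ev$vectors, g))
  gn <- sqrt(sum(g * g))
  if (.grad_converged(gn, f, tol)) {
    return(list(converged = TRUE))
  }
  if (max(lam) < 0 && 0.5 * sum(gp^2 / (-lam)) <= 1e-12 * (1 + f)) {
    return(list(converged = TRUE))
  }
  if (max(lam) >= -1e-12) {
    lam <- lam - (max(lam) + 0.1 * max(abs(lam)) + 1e-12)
  }
  step <- -as.numeric(ev$vectors %*% (gp / lam))
  sn <- sqrt(sum(step * step))
  if (sn > max_step) step <- step * (max_step / sn)
  list(converged = FALSE, step = step)
}

#' Climb from a starting point to a local maximum of the density
#'
#' Safeguarded ascent on the final density estimate: a full Newton step where
#' the Hessian is negative definite, steepest ascent otherwise, with
#' backtracking so the density never decreases between accepted iterates.
#'
#' @param model a `donkey_kde`.
#' @param start numeric length-D starting location.
#' @param tol gradient-norm convergence tolerance (relative to `1 + density`).
#' @param max_iter maximum accepted iterations.
#' @param max_step step-length cap in normalized coordinates; by default a
#'   few kernel standard deviations, so one step cannot leap across a
#'   narrow density valley.
#' @return list with `location`, `density`, `iterations`, `converged`.
#' @export
climb_to_maximum <- function(model, start, tol = 1e-8, max_iter = 200L,
                             max_step = NULL) {
  stopifnot(inherits(model, "donkey_kde"))
  if (is.null(max_step)) max_step <- min(0.25, max(0.02, 3 * model$sigma_min))
  x <- as.numeric(start)
  if (length(x) != model$d) stop("start has wrong dimension")
  e <- kde_evaluate(model, x)
  it <- 0L
  converged <- FALSE
  while (it < max_iter) {
    an <- .climb_analyze(e$gradient, e$hessian, e$density, tol, max_step)
    if (an$converged) { converged <- TRUE; break }
    t_ <- 1
    repeat {
      xn <- x + t_ * an$step
      # interior checkpoints reject steps that hop across a density valley
      # into a neighbouring basin (an exact-quadratic Newton step always
      # passes: the density rises monotonically along it)
      fb <- .kde_batch(model, rbind(xn, x + 0.75 * t_ * an$step,
                                    x + 0.5 * t_ * an$step,
                                    x + 0.25 * t_ * an$step))$density
      fn <- fb[1L]
      if (all(fb >= e$density) || t_ < 1e-10) break
      t_ <- t_ / 2
    }
    if (fn - e$density <= 1e-13 * (1 + e$density)) {
      # stalled at floating-point precision: accept if the gradient is small
      converged <- .grad_converged(sqrt(sum(e$gradient^2)), e$density,
                                   .stall_tol(tol))
      break
    }
    x <- xn
    e <- kde_evaluate(model, x)
    it <- it + 1L
  }
  if (it == max_iter && !converged) {
    an <- .climb_analyze(e$gradient, e$hessian, e$density, tol, max_step)
    converged <- an$converged
  }
  list(location = x, density = e$density, iterations = it,
       converged = converged)
}

# Batched climber: advances all active probe points in lockstep; per-point
# backtracking keeps the per-climb ascent monotone. Equivalent to running
# climb_to_maximum from every row of X. Steps are capped at a few kernel
# standard deviations so a single step cannot leap over a narrow valley.
.climb_batch <- function(model, X, tol = 1e-8, max_iter = 200L) {
  X <- as.matrix(X)
  p <- nrow(X)
  d <- model$d
  max_step <- min(0.25, max(0.02, 3 * model$sigma_min))
  f <- .kde_batch(model, X)$density
  converged <- rep(FALSE, p)
  iters <- rep(0L, p)
  active <- seq_len(p)
  for (it in seq_len(max_iter)) {
    if (!length(active)) break
    b <- .kde_batch(model, X[active, , drop = FALSE],
                    gradient = TRUE, hessian = TRUE)
    na <- length(active)
    gn <- numeric(na)
    done <- logical(na)
    steps <- matrix(0, na, d)
    for (q in seq_len(na)) {
      gq <- b$gradient[q, ]
      gn[q] <- sqrt(sum(gq^2))
      an <- .climb_analyze(gq, matrix(b$hessian[q, , ], d, d),
                           b$density[q], tol, max_step)
      done[q] <- an$converged
      if (!an$converged) steps[q, ] <- an$step
    }
    converged[active[done]] <- TRUE
    keep <- !done
    active <- active[keep]
    if (!length(active)) break
    fa <- b$density[keep]
    steps <- steps[keep, , drop = FALSE]
    tq <- rep(1, length(active))
    xa <- X[active, , drop = FALSE]
    pending <- seq_along(active)
    Xn <- xa
    fn <- fa
    for (bt in 1:40) {
      if (!length(pending)) break
      xp <- xa[pending, , drop = FALSE]
      sp <- steps[pending, , drop = FALSE] * tq[pending]
      trial <- xp + sp
      ftr <- .kde_batch(model, trial)$density
      # interior checkpoints: reject valley-hopping steps
      # (see climb_to_maximum)
      ok <- ftr >= fa[pending]
      for (frac in c(0.25, 0.5, 0.75)) {
        if (!any(ok)) break
        fi <- .kde_batch(model, xp[ok, , drop = FALSE] +
                                frac * sp[ok, , drop = FALSE])$density
        ok[ok] <- fi >= fa[pending[ok]]
      }
      Xn[pending[ok], ] <- trial[ok, , drop = FALSE]
      fn[pending[ok]] <- ftr[ok]
      pending <- pending[!ok]
      tq[pending] <- tq[pending] / 2
    }
    # a step whose density gain is below floating-point resolution makes no
    # progress: treat it like a failed (stalled) step
    flat <- setdiff(which(fn - fa <= 1e-13 * (1 + fa)), pending)
    pending <- sort(c(pending, flat))
    moved <- !seq_along(active) %in% pending
    X[active[moved], ] <- Xn[moved, , drop = FALSE]
    f[active[moved]] <- fn[moved]
    iters[active] <- iters[active] + 1L
    if (length(pending)) {
      # stalled climbs: accept as converged if the gradient is at the
      # floating-point-limited level, else flag and stop them
      gnk <- gn[keep]
      stall_ok <- .grad_converged(gnk[pending], fa[pending],
                                  .stall_tol(tol))
      converged[active[pending[stall_ok]]] <- TRUE
      active <- active[moved]
    }
  }
  list(locations = X, density = f, converged = converged, iterations = iters)
}

#' Assign every data point to its dominant density maximum
#'
#' Climbs the final density estimate from every data point; converged
#' endpoints closer than `dedup_tol` (Euclidean, normalized coordinates) are
#' identified as the same maximum. Maxima are ordered by decreasing density
#' (ties broken lexicographically by location) and their member sets partition
#' the data. Non-converged climbs are assigned to the located maximum with the
#' smallest density-weighted distance (distance divided by peak density).
#'
#' @param model a `donkey_kde`.
#' @param dedup_tol endpoint identification tolerance (default `1e-3`).
#' @param tol,max_iter passed to the climber.
#' @return list with `maxima` (each: `location`, `density`, `members`) and
#'   `labels` (length-N integer vector, 1-based, ordered by peak density).
#' @export
assign_points <- function(model, dedup_tol = 1e-3, tol = 1e-8,
                          max_iter = 200L) {
  stopifnot(inherits(model, "donkey_kde"))
  cl <- .climb_batch(model, model$Y, tol = tol, max_iter = max_iter)
  n <- model$n
  if (any(!cl$converged)) {
    # stragglers: retry individually with short, cautious steps before
    # falling back to the heuristic assignment
    for (i in which(!cl$converged)) {
      retry <- climb_to_maximum(model, model$Y[i, ], tol = tol,
                                max_iter = 400L, max_step = 0.02)
      if (retry$converged) {
        cl$locations[i, ] <- retry$location
        cl$density[i] <- retry$density
        cl$converged[i] <- TRUE
      }
    }
  }
  if (any(!cl$converged)) {
    warning(sum(!cl$converged), " climb(s) did not converge; assigning by ",
            "density-weighted distance to the located maxima")
  }
  # deduplicate converged endpoints (greedy, in data order)
  reps <- integer(0)         # indices of representative endpoints
  grp <- integer(n)
  for (i in which(cl$converged)) {
    assigned <- FALSE
    for (k in seq_along(reps)) {
      if (sqrt(sum((cl$locations[i, ] - cl$locations[reps[k], ])^2)) <
          dedup_tol) {
        grp[i] <- k
        if (cl$density[i] > cl$density[reps[k]]) reps[k] <- i
        assigned <- TRUE
        break
      }
    }
    if (!assigned) { reps <- c(reps, i); grp[i] <- length(reps) }
  }
  if (!length(reps)) stop("no climb converged; cannot locate any maximum")
  locs <- cl$locations[reps, , drop = FALSE]
  dens <- cl$density[reps]
  for (i in which(!cl$converged)) {
    dd <- sqrt(rowSums(sweep(locs, 2L, cl$locations[i, ], "-")^2)) / dens
    grp[i] <- which.min(dd)
  }
  # order maxima by decreasing density, ties lexicographic by location
  ord <- do.call(order, c(list(-dens), lapply(seq_len(ncol(locs)),
                                              function(j) locs[, j])))
  relabel <- integer(length(ord))
  relabel[ord] <- seq_along(ord)
  labels <- relabel[grp]
  maxima <- lapply(seq_along(ord), function(k) {
    i <- ord[k]
    list(location = as.numeric(locs[i, ]), density = dens[i],
         members = which(labels == k))
  })
  list(maxima = maxima, labels = labels)
}
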