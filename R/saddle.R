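## First-order saddle search between density maxima (eigenvector-following
## via the Smith transformation), the merging matrix, the three-step merge
## procedure, and density-ratio outlier flagging.

#' Smith transformation of local derivatives
#'
#' Maps the gradient and Hessian of the density onto those of a surrogate
#' function whose maxima sit at the first-order saddle points of the density:
#' eigendecompose `H = U L U^T`, rotate the gradient into the eigenbasis,
#' negate the algebraically lowest eigenvalue and the matching gradient
#' component, and rotate back. The surrogate itself is never constructed;
#' only its derivatives are needed by the Newton search.
#'
#' @param gradient length-D numeric vector.
#' @param hessian D x D symmetric matrix.
#' @return list with `gradient` and `hessian` of the transformed problem.
#' @export
smith_transform <- function(gradient, hessian) {
  g <- as.numeric(gradient)
  H <- as.matrix(hessian)
  if (!isSymmetric(H, tol = 1e-8)) stop("hessian must be symmetric")
  ev <- eigen(H, symmetric = TRUE)   # eigenvalues in decreasing order
  d <- length(g)
  lam <- ev$values
  if (d > 1L && abs(lam[d] - lam[d - 1L]) < 1e-10) {
    warning("lowest Hessian eigenvalue is (near-)degenerate; ",
            "negating the first of the tied pair by eigen-solver order")
  }
  gp <- as.numeric(t(ev$vectors) %*% g)
  lam[d] <- -lam[d]
  gp[d] <- -gp[d]
  list(gradient = as.numeric(ev$vectors %*% gp),
       hessian = ev$vectors %*% (lam * t(ev$vectors)))
}

#' Per-cluster partial weights of the density at a point
#'
#' Splits the KDE value at `x` into the contributions of each cluster's
#' member kernels; the weights sum to the total density.
#'
#' @param model a `donkey_kde`.
#' @param x probe location.
#' @param members list of integer index vectors, one per cluster.
#' @return numeric vector of per-cluster weights.
#' @export
cluster_partial_weights <- function(model, x, members) {
  b <- .kde_batch(model, matrix(as.numeric(x), 1L), kernels = TRUE)
  k <- b$kernels[1L, ]
  vapply(members, function(idx) sum(k[idx]), numeric(1))
}

# Attribution of a converged index-1 point to a cluster pair: displace along
# the positive-curvature eigenvector to either side, ascend back to a
# maximum, and identify the two cluster centres the ascents reach. Returns
# the pair (sorted) or NULL when both sides reach the same centre.
.saddle_pair <- function(model, x, hessian, centers, offset = 2e-3) {
  ev <- eigen(hessian, symmetric = TRUE)
  v <- ev$vectors[, 1L]   # eigenvalues decreasing: first is the positive one
  # short, cautious ascents: large steps could hop into a different basin
  reached <- vapply(c(-1, 1), function(sgn) {
    cl <- climb_to_maximum(model, x + sgn * offset * v, max_step = 0.02)
    dd <- sqrt(rowSums(sweep(centers, 2L, cl$location, "-")^2))
    which.min(dd)
  }, integer(1))
  if (reached[1L] == reached[2L]) return(NULL)
  sort(reached)
}

# Index test: exactly one positive Hessian eigenvalue (relative threshold).
.is_index1 <- function(H) {
  ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
  thr <- 1e-8 * max(abs(ev), .Machine$double.eps)
  sum(ev > thr) == 1L && sum(ev < -thr) == length(ev) - 1L
}

#' Locate the connecting saddle between two clusters
#'
#' Runs modified-Newton searches (via [smith_transform()]) from the centroids
#' of the closest cross-cluster point pairs. A search is aborted when a third
#' cluster's partial weight exceeds the weights of both clusters under
#' consideration, or when the density falls below `density_floor` — in either
#' case the pair should not be merged directly. A converged endpoint is
#' accepted only if its Hessian has exactly one positive eigenvalue.
#'
#' Each search alternates a one-dimensional minimization of the density along
#' the inter-centre axis with a safeguarded Newton maximization in the
#' orthogonal hyperplane (transverse ascent onto the connecting ridge). The
#' alternation converges to a stationary point that is a minimum along the
#' axis and a maximum transversally - precisely a first-order saddle - and,
#' unlike an unconstrained Newton iteration, can neither wander off into
#' low-density regions nor fall into one of the adjacent peaks. A converged
#' endpoint is attributed to the pair it connects by following the positive-
#' curvature eigenvector of its Hessian a short distance to either side and
#' ascending back to a maximum.
#'
#' @param model a `donkey_kde`.
#' @param a,b cluster indices (into `maxima`).
#' @param maxima list of maxima as returned by [assign_points()].
#' @param n_start_pairs number of closest cross-cluster pairs used as starts.
#' @param density_floor abort threshold on the density.
#' @param tol gradient convergence tolerance (relative, as in the climber).
#' @param max_iter per-search iteration cap.
#' @return list with `density` (largest saddle density validly attributed to
#'   the pair `(a, b)`, 0 if none), `location` (or `NULL`), and `found` (all
#'   valid saddles encountered, each with the pair it connects - searches
#'   started between one pair occasionally converge onto a neighbouring
#'   pair's saddle, which is still useful information).
#' @export
find_saddle <- function(model, a, b, maxima, n_start_pairs = 5L,
                        density_floor = 0, tol = 1e-8, max_iter = 100L,
                        drag = TRUE) {
  stopifnot(inherits(model, "donkey_kde"))
  members <- lapply(maxima, `[[`, "members")
  centers <- do.call(rbind, lapply(maxima, `[[`, "location"))
  ia <- members[[a]]; ib <- members[[b]]
  Ya <- model$Y[ia, , drop = FALSE]
  Yb <- model$Y[ib, , drop = FALSE]
  d2 <- outer(rowSums(Ya^2), rep(1, nrow(Yb))) +
        outer(rep(1, nrow(Ya)), rowSums(Yb^2)) - 2 * Ya %*% t(Yb)
  ord <- order(d2)[seq_len(min(n_start_pairs, length(d2)))]
  rows <- (ord - 1L) %% nrow(Ya) + 1L
  cols <- (ord - 1L) %/% nrow(Ya) + 1L
  best <- list(density = 0, location = NULL, found = list())
  others <- setdiff(seq_along(members), c(a, b))
  v <- centers[b, ] - centers[a, ]
  sep <- sqrt(sum(v^2))
  v <- v / max(sep, .Machine$double.eps)
  d <- model$d
  # orthonormal basis of the hyperplane transverse to the inter-centre axis
  B <- if (d > 1L) qr.Q(qr(cbind(v, diag(d))))[, 2:d, drop = FALSE] else NULL
  check_rules <- function(x) {
    # rule (ii): density floor; rule (i): a third cluster dominates both
    bch <- .kde_batch(model, matrix(x, 1L), kernels = TRUE)
    if (bch$density[1L] < density_floor) return(FALSE)
    if (length(others)) {
      kr <- bch$kernels[1L, ]
      w <- vapply(members, function(idx) sum(kr[idx]), numeric(1))
      if (any(w[others] > w[a] + w[b])) return(FALSE)
    }
    TRUE
  }
  try_candidate <- function(x) {
    # phase 2: Newton polish to the stationary point, monotone in |gradient|
    pol <- .newton_polish(model, x, tol, max_iter = max_iter)
    x <- pol$location
    if (!check_rules(x)) return(invisible(NULL))
    if (!.grad_converged(sqrt(sum(pol$gradient^2)), pol$density,
                         .stall_tol(tol))) return(invisible(NULL))
    if (!.is_index1(pol$hessian)) return(invisible(NULL))
    pr <- .saddle_pair(model, x, pol$hessian, centers)
    if (is.null(pr)) return(invisible(NULL))
    best$found[[length(best$found) + 1L]] <<-
      list(pair = pr, density = pol$density, location = x)
    if (identical(pr, sort(c(a, b))) && pol$density > best$density) {
      best$density <<- pol$density
      best$location <<- x
    }
    invisible(NULL)
  }
  any_survived <- FALSE
  for (s in seq_along(ord)) {
    # the saddle between a pair is almost always unique: once one start has
    # located a validly attributed one, further starts add nothing
    if (best$density > 0) break
    x <- (Ya[rows[s], ] + Yb[cols[s], ]) / 2
    # phase 1: a few guided alternations (axis minimization between the two
    # centres, then transverse ascent onto the ridge) home in on the saddle
    # region without any risk of drifting away or falling into a peak
    ok <- TRUE
    for (it in 1:2) {
      if (!(ok <- check_rules(x))) break
      x_new <- .axis_minimize(model, x, v, centers[a, ], centers[b, ])
      if (!is.null(B)) x_new <- .transverse_ascent(model, x_new, B, tol)
      moved <- sqrt(sum((x_new - x)^2))
      x <- x_new
      if (moved < 1e-10) break
    }
    if (!ok || !check_rules(x)) next
    any_survived <- TRUE
    try_candidate(x)
  }
  best$bound <- 0
  if (best$density == 0 && drag && !is.null(B)) {
    # fallback for curved ridges and small satellite bumps, where the
    # chord-guided starts slide into a peak basin: drag a transverse-
    # ascended profile along the inter-centre segment (densely, including
    # close to both ends - the saddle to a low satellite peak sits right
    # at its shoulder) and polish from the profile's density minimum
    ts <- seq(0.03, 0.98, length.out = 17L)
    ridge_f <- rep(Inf, length(ts))
    ridge_x <- matrix(NA_real_, length(ts), d)
    for (i in seq_along(ts)) {
      x0 <- centers[a, ] + ts[i] * (centers[b, ] - centers[a, ])
      xi <- .transverse_ascent(model, x0, B, tol)
      # ascents that travel further than the pair separation left the
      # local ridge; their density belongs to some other feature
      if (sqrt(sum((xi - x0)^2)) > sep) next
      ridge_x[i, ] <- xi
      ridge_f[i] <- .kde_batch(model, matrix(xi, 1L))$density
    }
    i <- which.min(ridge_f)
    if (is.finite(ridge_f[i]) && check_rules(ridge_x[i, ])) {
      try_candidate(ridge_x[i, ])
    }
    if (best$density == 0) {
      # even without a located saddle, the minimum of the density along the
      # ridge polyline (refined with the midpoints of consecutive ridge
      # points) is a lower bound on the height of the connecting pass
      ok_pts <- which(is.finite(ridge_f))
      if (length(ok_pts) >= 2L) {
        mids <- (ridge_x[ok_pts[-length(ok_pts)], , drop = FALSE] +
                 ridge_x[ok_pts[-1L], , drop = FALSE]) / 2
        fm <- .kde_batch(model, mids)$density
        best$bound <- min(c(ridge_f[ok_pts], fm))
      }
    }
  }
  best
}

# Newton iteration toward the nearest stationary point, made monotone in the
# gradient norm by backtracking; quadratically convergent from a good start.
.newton_polish <- function(model, x, tol, max_iter = 60L, cap = 0.05) {
  e <- kde_evaluate(model, x)
  gn <- sqrt(sum(e$gradient^2))
  for (it in seq_len(max_iter)) {
    if (.grad_converged(gn, e$density, tol)) break
    ev <- eigen(e$hessian, symmetric = TRUE)
    lam <- ev$values
    gp <- as.numeric(crossprod(ev$vectors, e$gradient))
    # Tikhonov-damped Newton: near-singular modes contribute vanishing
    # displacement instead of exploding
    tau <- 1e-4 * max(abs(lam), 1e-300)
    step <- -as.numeric(ev$vectors %*% (gp * lam / (lam^2 + tau^2)))
    sn <- sqrt(sum(step^2))
    if (sn > cap) step <- step * (cap / sn)
    improved <- FALSE
    # the damped Newton direction reduces |g| near a stationary point; far
    # from one, fall back to the steepest-descent direction of |g|^2/2,
    # which is -Hg
    for (dir in list(step, {
      d2 <- -as.numeric(e$hessian %*% e$gradient)
      nd <- sqrt(sum(d2^2))
      if (nd > 0) d2 * (cap / 4 / nd) else d2
    })) {
      t_ <- 1
      repeat {
        xn <- x + t_ * dir
        en <- kde_evaluate(model, xn)
        gnn <- sqrt(sum(en$gradient^2))
        if (gnn < gn) { improved <- TRUE; break }
        t_ <- t_ / 2
        if (t_ < 1e-8) break
      }
      if (improved) break
    }
    if (!improved) break
    x <- xn; e <- en; gn <- gnn
  }
  list(location = x, density = e$density, gradient = e$gradient,
       hessian = e$hessian)
}

# 1-D minimization of the density along direction v through x, restricted to
# the axis interval spanned by the two cluster centres (so the search cannot
# drift out of the inter-cluster region): coarse scan then local refinement.
.axis_minimize <- function(model, x, v, center_a, center_b) {
  ta <- sum((center_a - x) * v)
  tb <- sum((center_b - x) * v)
  lo <- min(ta, tb); hi <- max(ta, tb)
  pad <- 0.02 * (hi - lo)
  ts <- seq(lo + pad, hi - pad, length.out = 41L)
  probes <- outer(rep(1, length(ts)), x) + outer(ts, v)
  f <- .kde_batch(model, probes)$density
  i <- which.min(f)
  # parabolic refinement through the bracketing triple (no extra evaluation;
  # the subsequent Newton polish removes any residual error)
  if (i > 1L && i < length(ts)) {
    denom <- f[i - 1L] - 2 * f[i] + f[i + 1L]
    if (denom > 0) {
      h <- ts[2L] - ts[1L]
      dt <- 0.5 * h * (f[i - 1L] - f[i + 1L]) / denom
      if (abs(dt) < h) return(x + (ts[i] + dt) * v)
    }
  }
  x + ts[i] * v
}

# Safeguarded Newton ascent restricted to the column space of B (the
# hyperplane transverse to the inter-centre axis), with the same midpoint
# backtracking as the full climber.
.transverse_ascent <- function(model, x, B, tol, max_iter = 15L) {
  for (it in seq_len(max_iter)) {
    e <- kde_evaluate(model, x)
    gt <- as.numeric(crossprod(B, e$gradient))
    Ht <- crossprod(B, e$hessian %*% B)
    an <- .climb_analyze(gt, Ht, e$density, tol, max_step = 0.1)
    if (an$converged) break
    t_ <- 1
    repeat {
      step <- as.numeric(B %*% an$step) * t_
      fb <- .kde_batch(model, rbind(x + step, x + 0.5 * step))$density
      if ((fb[1L] >= e$density && fb[2L] >= e$density) || t_ < 1e-10) break
      t_ <- t_ / 2
    }
    if (fb[1L] - e$density <= 1e-13 * (1 + e$density)) break
    x <- x + step
  }
  x
}

#' Build the merging matrix over all cluster pairs
#'
#' Diagonal entries are the densities at the cluster centres; off-diagonal
#' entries are the largest valid saddle densities found by [find_saddle()]
#' (0 where no admissible saddle exists). Searches between non-adjacent pairs
#' abort immediately at their starting centroids via the third-cluster rule,
#' so only neighbouring clusters contribute.
#'
#' @param model a `donkey_kde`.
#' @param maxima list of maxima as returned by [assign_points()].
#' @param n_start_pairs,tol,max_iter passed to [find_saddle()].
#' @param density_floor_frac the abort threshold as a fraction of the smaller
#'   of the two peak densities under consideration (default `1e-4`,
#'   scale-free; any saddle that could trigger a merge has density at least
#'   `beta` times that peak, so the floor is far below every relevant
#'   saddle).
#' @return list with `m` (K x K symmetric matrix) and `saddles` (locations).
#' @export
merge_matrix <- function(model, maxima, n_start_pairs = 5L,
                         density_floor_frac = 1e-4, tol = 1e-8,
                         max_iter = 100L) {
  k <- length(maxima)
  m <- diag(vapply(maxima, `[[`, numeric(1), "density"), nrow = k)
  peaks <- diag(m)
  saddles <- vector("list", 0L)
  if (k > 1L) {
    # only neighbouring clusters contribute to the saddle search: restrict
    # to pairs that are centre-distance k-nearest neighbours of each other
    # (a superset of the basin-adjacency graph for any realistic layout),
    # then discard pairs whose starting centroid already violates the
    # third-cluster or density-floor rule - evaluated for all pairs in one
    # vectorized pass
    centers <- do.call(rbind, lapply(maxima, `[[`, "location"))
    members <- lapply(maxima, `[[`, "members")
    cd <- as.matrix(stats::dist(centers))
    diag(cd) <- Inf
    nn <- min(6L, k - 1L)
    cand <- matrix(FALSE, k, k)
    for (a in seq_len(k)) {
      nb <- order(cd[a, ])[seq_len(nn)]
      cand[a, nb] <- TRUE
    }
    cand <- cand | t(cand)
    pairs <- which(upper.tri(cand) & cand, arr.ind = TRUE)
    if (nrow(pairs)) {
      starts <- matrix(unlist(lapply(seq_len(nrow(pairs)), function(r) {
        a <- pairs[r, 1L]; b <- pairs[r, 2L]
        Ya <- model$Y[members[[a]], , drop = FALSE]
        Yb <- model$Y[members[[b]], , drop = FALSE]
        d2 <- outer(rowSums(Ya^2), rep(1, nrow(Yb))) +
              outer(rep(1, nrow(Ya)), rowSums(Yb^2)) - 2 * Ya %*% t(Yb)
        ij <- which(d2 == min(d2), arr.ind = TRUE)[1L, ]
        (Ya[ij[1L], ] + Yb[ij[2L], ]) / 2
      })), ncol = ncol(centers), byrow = TRUE)
      bch <- .kde_batch(model, starts, kernels = TRUE)
      grp <- integer(model$n)
      for (c_ in seq_len(k)) grp[members[[c_]]] <- c_
      W <- t(rowsum(t(bch$kernels), grp))       # n_pairs x k partial weights
      keep <- vapply(seq_len(nrow(pairs)), function(r) {
        a <- pairs[r, 1L]; b <- pairs[r, 2L]
        if (bch$density[r] < density_floor_frac * min(peaks[a], peaks[b])) {
          return(FALSE)
        }
        !any(W[r, -c(a, b)] > W[r, a] + W[r, b])
      }, logical(1))
      pairs <- pairs[keep, , drop = FALSE]
    }
    if (nrow(pairs)) {
      # fast path: the density minimum along the straight segment between
      # two centres is a lower bound on the height of the connecting pass
      # (the pass is the best min over all connecting paths). When even the
      # bound clears the merge threshold by a wide margin the exact saddle
      # is irrelevant - record the bound and skip the search.
      nt <- 21L
      tseq <- seq(0, 1, length.out = nt)
      seg <- matrix(0, nrow(pairs) * nt, ncol(centers))
      for (r in seq_len(nrow(pairs))) {
        a <- pairs[r, 1L]; b <- pairs[r, 2L]
        seg[((r - 1L) * nt + 1L):(r * nt), ] <-
          outer(1 - tseq, centers[a, ]) + outer(tseq, centers[b, ])
      }
      segf <- .kde_batch(model, seg)$density
      smin <- vapply(seq_len(nrow(pairs)), function(r) {
        min(segf[((r - 1L) * nt + 1L):(r * nt)])
      }, numeric(1))
      ratio <- smin / vapply(seq_len(nrow(pairs)), function(r) {
        min(peaks[pairs[r, 1L]], peaks[pairs[r, 2L]])
      }, numeric(1))
      fast <- ratio > 0.55
      for (r in which(fast)) {
        a <- pairs[r, 1L]; b <- pairs[r, 2L]
        m[a, b] <- m[b, a] <- smin[r]
      }
      pairs <- pairs[!fast, , drop = FALSE]
      ratio <- ratio[!fast]
    }
    for (r in seq_len(nrow(pairs))) {
      a <- pairs[r, 1L]; b <- pairs[r, 2L]
      floor_abs <- density_floor_frac * min(peaks[a], peaks[b])
      # the ridge-drag fallback is only worthwhile when the segment bound
      # shows the pair is not separated by a deep valley
      sd_ <- find_saddle(model, a, b, maxima, n_start_pairs = n_start_pairs,
                         density_floor = floor_abs, tol = tol,
                         max_iter = max_iter, drag = ratio[r] > 0.05)
      # credit every valid saddle to the pair it actually connects
      for (fs in sd_$found) {
        i <- fs$pair[1L]; j <- fs$pair[2L]
        if (fs$density > m[i, j]) {
          m[i, j] <- m[j, i] <- fs$density
          saddles[[paste(i, j, sep = "-")]] <- fs$location
        }
      }
      # ridge-path lower bound: a failed search still yields a rigorous
      # lower bound on the pass height; recording it can only enable merges
      # the true saddle would also justify (it understates mu, never
      # overstates it)
      if (!is.null(sd_$bound) && sd_$bound > m[a, b]) {
        m[a, b] <- m[b, a] <- sd_$bound
      }
    }
  }
  list(m = m, saddles = saddles, density_floor_frac = density_floor_frac)
}

#' Execute the three-step merge procedure on a merging matrix
#'
#' Repeatedly merges the cluster pair with the highest saddle-to-peak ratio
#' `mu_ab = M_ab / min(M_aa, M_bb)` provided `mu_ab > beta`. After each merge
#' both diagonals are set to `max(M_aa, M_bb)` and the merged off-diagonal is
#' zeroed, which prevents a low-density cluster from indirectly linking two
#' high-density ones. Ties are broken by the lower pair indices.
#'
#' @param m K x K merging matrix.
#' @param beta merge threshold in (0, 1); default `exp(-1)`.
#' @return list with `mapping` (old label -> new contiguous label, merged
#'   groups labelled by their highest-density representative) and
#'   `history` (data frame of executed merges `a`, `b`, `mu`).
#' @export
merge_clusters <- function(m, beta = exp(-1)) {
  if (!is.numeric(beta) || length(beta) != 1L || beta <= 0 || beta >= 1) {
    stop("beta must lie strictly between 0 and 1")
  }
  m <- as.matrix(m)
  k <- nrow(m)
  parent <- seq_len(k)
  find_root <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  hist_a <- integer(0); hist_b <- integer(0); hist_mu <- numeric(0)
  if (k > 1L) repeat {
    mins <- outer(diag(m), diag(m), pmin)
    mu <- m / mins
    diag(mu) <- -Inf
    mu[m == 0] <- -Inf
    best <- max(mu)
    if (!is.finite(best) || best <= beta) break
    idx <- which(mu == best, arr.ind = TRUE)
    idx <- idx[idx[, 1L] < idx[, 2L], , drop = FALSE]
    idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
    a <- idx[1L, 1L]; b <- idx[1L, 2L]
    if (find_root(a) == find_root(b)) {
      # already one cluster via an earlier chain: drop the stale entry
      m[a, b] <- m[b, a] <- 0
      next
    }
    hist_a <- c(hist_a, a); hist_b <- c(hist_b, b)
    hist_mu <- c(hist_mu, best)
    parent[find_root(b)] <- find_root(a)
    # the merged pair is now one cluster: raise the diagonal of every label
    # belonging to it (not only a and b), else a chain of low-density
    # fragments retains tiny stale diagonals and can indirectly link two
    # high-density clusters - the situation step 3 exists to prevent
    root <- find_root(a)
    members_ab <- which(vapply(seq_len(k), find_root, integer(1)) == root)
    top <- max(diag(m)[members_ab])
    for (i in members_ab) m[i, i] <- top
    m[a, b] <- m[b, a] <- 0
  }
  roots <- vapply(seq_len(k), find_root, integer(1))
  reps <- sort(unique(roots))
  mapping <- match(roots, reps)
  list(mapping = mapping,
       history = data.frame(a = hist_a, b = hist_b, mu = hist_mu))
}

#' Flag low-density points as outliers
#'
#' A point in final cluster `c` is flagged when the ratio of its density to
#' the density at the centre of `c` falls below `gamma`. Flags are metadata:
#' labels are unchanged, and `gamma = 0` (the default pipeline setting) flags
#' nothing.
#'
#' @param point_density densities of the data points under the final KDE.
#' @param labels final cluster labels (1-based).
#' @param center_density per-cluster centre densities (post-merge diagonals).
#' @param gamma non-negative outlier threshold.
#' @return logical vector of flags.
#' @export
flag_outliers <- function(point_density, labels, center_density, gamma) {
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma < 0) {
    stop("gamma must be a non-negative scalar")
  }
  if (gamma == 0) return(rep(FALSE, length(labels)))
  point_density / center_density[labels] < gamma
}
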