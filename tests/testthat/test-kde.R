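# Kernel, leave-one-out likelihood, covariance optimization, Abramson.

test_that("gaussian kernel matches closed forms and stays normalized", {
  expect_equal(gaussian_kernel(0, matrix(1)), 1 / sqrt(2 * pi),
               tolerance = 1e-12)
  expect_equal(gaussian_kernel(1, matrix(1)), dnorm(1), tolerance = 1e-12)
  # isotropic h^2 I equals the scalar-bandwidth Gaussian in 1-D
  for (h in c(0.3, 1, 2.5)) {
    expect_equal(gaussian_kernel(0.7, matrix(h^2)), dnorm(0.7, sd = h),
                 tolerance = 1e-12)
  }
  # 2-D kernel integrates to 1 on a wide grid, including alpha != 1
  C <- matrix(c(1, 0.4, 0.4, 0.8), 2)
  for (alpha in c(1, 2.5)) {
    xs <- seq(-8, 8, length.out = 161L)
    h <- xs[2] - xs[1]
    vals <- outer(xs, xs, Vectorize(function(x, y) {
      gaussian_kernel(c(x, y), C, alpha)
    }))
    expect_equal(sum(vals) * h^2, 1, tolerance = 1e-4)
  }
  # alpha = 1 recovers the plain kernel bit for bit
  expect_identical(gaussian_kernel(c(0.3, -0.2), C, 1),
                   gaussian_kernel(c(0.3, -0.2), C))
})

test_that("gaussian kernel rejects bad inputs", {
  expect_error(gaussian_kernel(0, matrix(-1)), "positive definite")
  expect_error(gaussian_kernel(c(1, 2), matrix(1)), "dimension")
  expect_error(gaussian_kernel(0, matrix(1), alpha = 0), "alpha")
})

test_that("leave-one-out log-likelihood matches closed form and brute force", {
  # {0, 1}: each point sees only the other at distance 1
  expect_equal(loo_log_likelihood(matrix(c(0, 1)), matrix(1)),
               log(dnorm(1)), tolerance = 1e-12)
  # brute-force oracle by direct summation
  brute <- function(pts, C) {
    n <- nrow(pts)
    mean(vapply(seq_len(n), function(i) {
      log(mean(vapply(setdiff(seq_len(n), i), function(j) {
        gaussian_kernel(pts[i, ] - pts[j, ], C)
      }, numeric(1))))
    }, numeric(1)))
  }
  pts <- matrix(c(0, 1, 2))
  expect_equal(loo_log_likelihood(pts, matrix(1)), brute(pts, matrix(1)),
               tolerance = 1e-12)
  set.seed(11)
  pts2 <- matrix(rnorm(24), ncol = 2L)
  C <- matrix(c(0.8, 0.2, 0.2, 0.5), 2)
  expect_equal(loo_log_likelihood(pts2, C), brute(pts2, C),
               tolerance = 1e-12)
  # invariant under row permutation
  expect_equal(loo_log_likelihood(pts2[sample(nrow(pts2)), ], C),
               loo_log_likelihood(pts2, C), tolerance = 1e-12)
  expect_error(loo_log_likelihood(matrix(0, 1, 1), matrix(1)), "two points")
})

test_that("covariance fixed point solves the two-point case exactly", {
  bw <- optimize_covariance(matrix(c(0, 1)))
  expect_equal(as.numeric(bw$C), 1, tolerance = 1e-10)
  expect_true(bw$converged)
  # scaled two-point set: C = (separation)^2
  bw2 <- optimize_covariance(matrix(c(0, 0.4)))
  expect_equal(as.numeric(bw2$C), 0.16, tolerance = 1e-8)
})

test_that("covariance fixed point is translation invariant and self-consistent", {
  set.seed(3)
  pts <- matrix(rnorm(40), ncol = 2L)
  bw <- optimize_covariance(pts, tol = 1e-10)
  bw_shift <- optimize_covariance(sweep(pts, 2L, c(5, -3), "+"), tol = 1e-10)
  expect_equal(bw$C, bw_shift$C, tolerance = 1e-9)
  # substituting C back into the update reproduces C
  update_once <- function(Y, C) {
    n <- nrow(Y)
    num <- matrix(0, ncol(Y), ncol(Y))
    for (i in seq_len(n)) {
      ks <- vapply(setdiff(seq_len(n), i), function(j) {
        gaussian_kernel(Y[i, ] - Y[j, ], C)
      }, numeric(1))
      js <- setdiff(seq_len(n), i)
      s <- matrix(0, ncol(Y), ncol(Y))
      for (k in seq_along(js)) {
        d <- Y[i, ] - Y[js[k], ]
        s <- s + ks[k] * outer(d, d)
      }
      num <- num + s / sum(ks)
    }
    num / n
  }
  C_next <- update_once(pts, bw$C)
  expect_lt(norm(C_next - bw$C, "F") / norm(bw$C, "F"), 1e-6)
})

test_that("optimized scalar covariance agrees with grid search of the likelihood", {
  pts <- matrix(c(0, 0.1, 0.4, 0.9, 1.0))
  bw <- optimize_covariance(pts, tol = 1e-10)
  cs <- seq(0.005, 0.5, by = 5e-5)
  ll <- vapply(cs, function(cc) loo_log_likelihood(pts, matrix(cc)),
               numeric(1))
  expect_equal(as.numeric(bw$C), cs[which.max(ll)], tolerance = 1e-3)
})

test_that("degenerate inputs are refused or regularized", {
  expect_error(optimize_covariance(matrix(c(1, 1, 1))), "identical")
  # rank-deficient 2-D data (all on a line) triggers the ridge warning
  pts <- cbind(seq(0, 1, length.out = 12L), 0.5)
  expect_warning(bw <- optimize_covariance(pts[, ]), "regulariz")
  ev <- eigen(bw$C, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > 0))
})

test_that("kde_evaluate matches closed forms and finite differences", {
  m <- model_1d(c(0, 1), C = 1)
  e <- kde_evaluate(m, 0.5)
  expect_equal(e$density, dnorm(0.5), tolerance = 1e-12)  # (phi+phi)/2
  expect_equal(e$gradient, 0, tolerance = 1e-12)
  # random 2-D model: analytic derivatives vs central differences
  set.seed(5)
  pts <- matrix(rnorm(30), ncol = 2L)
  C <- matrix(c(0.5, 0.1, 0.1, 0.3), 2)
  m2 <- model_nd(pts, C, abramson = TRUE, alpha = 1.3)
  h <- 1e-5
  for (probe in list(c(0, 0), c(0.3, -0.4), c(-1, 0.7))) {
    e <- kde_evaluate(m2, probe)
    for (k in 1:2) {
      dx <- c(0, 0); dx[k] <- h
      fp <- kde_evaluate(m2, probe + dx)$density
      fm <- kde_evaluate(m2, probe - dx)$density
      expect_equal(e$gradient[k], (fp - fm) / (2 * h),
                   tolerance = 1e-5 * max(1, abs(e$gradient[k])))
      gp <- kde_evaluate(m2, probe + dx)$gradient
      gm <- kde_evaluate(m2, probe - dx)$gradient
      expect_equal(e$hessian[, k], (gp - gm) / (2 * h),
                   tolerance = 1e-5 * max(1, max(abs(e$hessian))))
    }
  }
})

test_that("the final density estimate integrates to one", {
  # 1-D with Abramson and broadening
  m <- model_1d(c(0, 0.2, 0.5, 0.9, 2), C = 0.09, abramson = TRUE,
                alpha = 1.5)
  xs <- seq(-6, 8, length.out = 8001L)
  f <- donkey:::.kde_batch(m, matrix(xs, ncol = 1L))$density
  expect_equal(sum(f) * (xs[2] - xs[1]), 1, tolerance = 1e-3)
  # 2-D
  set.seed(9)
  pts <- matrix(rnorm(20, sd = 0.3), ncol = 2L)
  m2 <- model_nd(pts, diag(0.2, 2), abramson = TRUE)
  xs <- seq(-4, 4, length.out = 201L)
  h <- xs[2] - xs[1]
  G <- as.matrix(expand.grid(xs, xs))
  f2 <- donkey:::.kde_batch(m2, G)$density
  expect_equal(sum(f2) * h^2, 1, tolerance = 1e-2)
})

test_that("Abramson factors broaden sparse regions with unit geometric mean", {
  # symmetric two-point set: equal densities, factors exactly 1
  ps <- point_set(matrix(c(0, 1)), normalize = FALSE)
  bw <- optimize_covariance(ps)
  ab <- abramson_rescale(ps, bw)
  expect_equal(ab$lambda, c(1, 1), tolerance = 1e-12)
  # isolated point gets the largest factor
  pts <- matrix(c(0, 0.1, 0.2, 5.0))
  ps2 <- point_set(pts, normalize = FALSE)
  bw2 <- structure(list(C = matrix(0.04), lambda = rep(1, 4),
                        geometric_mean_density = NA_real_, alpha = 1,
                        abramson_enabled = FALSE, iterations_used = 0L,
                        converged = TRUE), class = "donkey_bandwidth")
  ab2 <- abramson_rescale(ps2, bw2)
  expect_gt(ab2$lambda[4], max(ab2$lambda[1:3]))
  # geometric mean of the factors is 1 by construction
  set.seed(21)
  ps3 <- point_set(matrix(rnorm(60), ncol = 3L))
  ab3 <- abramson_rescale(ps3, optimize_covariance(ps3))
  expect_equal(exp(mean(log(ab3$lambda))), 1, tolerance = 1e-10)
})

test_that("point sets normalize to [0,1] and drop constant columns", {
  x <- cbind(runif(20, 3, 9), rnorm(20), 7)
  expect_message(ps <- point_set(x), "constant")
  expect_equal(ps$dim, 2L)
  expect_equal(ps$dropped_features, 3L)
  expect_equal(unname(apply(ps$points, 2, min)), c(0, 0))
  expect_equal(unname(apply(ps$points, 2, max)), c(1, 1))
  # denormalize inverts the map
  back <- denormalize(ps, ps$points)
  expect_equal(unname(back), unname(x[, 1:2]), tolerance = 1e-12)
  expect_error(point_set(matrix(1, 1, 2)), "two data points")
})
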