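# Regularized NCA: objective, gradient, fit, cross-validation.

test_that("two-point and constant-response edge cases have closed forms", {
  # n = 2: softmax normalization forces p_12 = p_21 = 1 for any w
  X <- rbind(c(0, 0), c(1, 1))
  y <- c(1, 4)
  for (w in list(c(0, 0), c(2, 3), c(-1, 5))) {
    ob <- nca_objective(w, X, y, lambda = 0.1)
    expect_equal(ob$value, abs(1 - 4) + 0.1 * sum(w^2), tolerance = 1e-12)
  }
  fit2 <- fit_nca(X, y, lambda = 0.1)
  expect_lt(max(fit2$importance), 1e-4)

  # constant y: data term vanishes, optimum at w = 0 for lambda > 0
  with_test_seed(3, Xc <- matrix(rnorm(40), 10, 4))
  fitc <- fit_nca(Xc, rep(2.5, 10), lambda = 0.05)
  expect_lt(max(fitc$importance), 1e-4)

  expect_error(nca_objective(c(1, 1), X[1, , drop = FALSE], y[1], 0.05),
               "at least 2")
  expect_error(nca_objective(c(1, NA), X, y, 0.05), "non-finite")
})

test_that("analytic gradient matches central finite differences", {
  with_test_seed(19, {
    for (i in 1:12) {
      X <- matrix(rnorm(20 * 6), 20, 6)
      y <- rnorm(20)
      w <- runif(6, -1.5, 1.5)
      lam <- runif(1, 0, 0.3)
      g <- nca_objective(w, X, y, lam)$gradient
      h <- 1e-6
      fd <- vapply(1:6, function(r) {
        wp <- w; wm <- w
        wp[r] <- wp[r] + h; wm[r] <- wm[r] - h
        (nca_objective(wp, X, y, lam)$value -
           nca_objective(wm, X, y, lam)$value) / (2 * h)
      }, 0)
      expect_lt(max(abs(g - fd) / pmax(abs(fd), 1e-8)), 1e-5)
    }
  })
})

test_that("objective is sign-invariant and fits are permutation-equivariant", {
  with_test_seed(5, {
    X <- scale(matrix(rnorm(60 * 4), 60, 4))
    y <- X[, 2] + rnorm(60, 0, 0.2)
  })
  w <- c(0.5, -1.2, 0.8, 2)
  v1 <- nca_objective(w, X, y, 0.05)$value
  for (r in 1:4) {
    wf <- w; wf[r] <- -wf[r]
    expect_equal(nca_objective(wf, X, y, 0.05)$value, v1, tolerance = 1e-12)
  }

  perm <- c(3, 1, 4, 2)
  f1 <- fit_nca(X, y, 0.05)
  f2 <- fit_nca(X[, perm], y, 0.05)
  expect_equal(unname(f2$importance), unname(f1$importance[perm]),
               tolerance = 1e-6)
})

test_that("duplicate rows are numerically safe and huge lambda kills all weights", {
  with_test_seed(6, X <- matrix(rnorm(30), 10, 3))
  Xd <- rbind(X, X[1:3, ])          # exact duplicates -> zero distances
  yd <- c(rnorm(10), rnorm(3))
  ob <- nca_objective(c(1, 1, 1), Xd, yd, 0.05)
  expect_true(is.finite(ob$value))
  expect_true(all(is.finite(ob$gradient)))
  fit <- fit_nca(Xd, yd, 0.05)
  expect_true(all(is.finite(fit$importance)))

  fit_inf <- fit_nca(scale(Xd), yd, lambda = 1e6)
  expect_lt(max(fit_inf$importance), 1e-3)
})

test_that("optimal penalty mass is non-increasing along the lambda grid", {
  with_test_seed(9, {
    X <- scale(matrix(rnorm(120 * 5), 120, 5))
    y <- X[, 1] - 0.5 * X[, 4] + rnorm(120, 0, 0.2)
  })
  mass <- vapply(c(0.01, 0.05, 0.2, 1, 5), function(lam)
    sum(fit_nca(X, y, lam)$weights^2), 0)
  expect_true(all(diff(mass) <= 1e-6))
})

test_that("planted signals earn dominant importance", {
  pass <- 0
  for (s in 1:5) {
    with_test_seed(100 + s, {
      X <- scale(matrix(rnorm(300 * 8), 300, 8))
      y <- X[, 5] + rnorm(300, 0, 0.15)
    })
    imp <- fit_nca(X, y, 0.05)$importance
    if (which.max(imp) == 5 && imp[5] >= 5 * median(imp[-5])) pass <- pass + 1
  }
  expect_gte(pass, 4)
})

test_that("lambda cross-validation is seeded, on-grid, and picks interior optima", {
  with_test_seed(31, {
    X <- scale(matrix(rnorm(80 * 5), 80, 5))
    y <- X[, 2] + rnorm(80, 0, 0.3)
  })
  grid <- c(1e-4, 0.01, 0.05, 0.5, 3)
  cv1 <- cross_validate_lambda(X, y, grid, k = 4, seed = 11)
  cv2 <- cross_validate_lambda(X, y, grid, k = 4, seed = 11)
  expect_true(cv1$lambda %in% grid)
  expect_identical(cv1$folds, cv2$folds)
  expect_identical(cv1$lambda, cv2$lambda)
  expect_error(cross_validate_lambda(X, y, numeric(0)), "empty")
  expect_error(cross_validate_lambda(X, y, grid, k = 50), "n >= 2k")

  # with strong noise features, CV loss at lambda* beats the grid extremes
  wins <- 0
  for (s in 1:6) {
    with_test_seed(200 + s, {
      Xs <- scale(matrix(rnorm(72 * 6), 72, 6))
      ys <- Xs[, 1] + rnorm(72, 0, 0.4)
    })
    cv <- cross_validate_lambda(Xs, ys, grid, k = 4, seed = s)
    ext <- cv$curve$loss[c(1, nrow(cv$curve))]
    if (min(cv$curve$loss) <= min(ext)) wins <- wins + 1
  }
  expect_gte(wins, 5)
})
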