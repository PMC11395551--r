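# NIPALS core against independent decomposition/arithmetic oracles.

test_that("autoscaling centers, scales, flags constants and inverts exactly", {
  X <- cbind(a = c(1, 2, 3), b = c(5, 5, 5))
  sc <- suppressMessages(autoscale(X, "unit_variance"))
  expect_equal(unname(sc$values[, 1]), c(-1, 0, 1))
  expect_equal(unname(sc$values[, 2]), c(0, 0, 0))
  expect_true(sc$constant[2])
  expect_equal(unname(sc$column_scales[2]), 1)

  set.seed(21)
  M <- matrix(rnorm(20), 5, 4)
  for (mode in c("unit_variance", "pareto", "center_only")) {
    sc <- autoscale(M, mode)
    expect_equal(descale(sc), M, tolerance = 1e-9)
    if (mode == "unit_variance") {
      expect_equal(unname(colMeans(sc$values)), rep(0, 4), tolerance = 1e-10)
      expect_equal(unname(apply(sc$values, 2, var)), rep(1, 4), tolerance = 1e-8)
    }
  }
})

test_that("PCA reproduces the SVD decomposition up to sign on random matrices", {
  # rank-1 matrix: PC1 explains everything
  r1 <- outer(c(1, 2, 3, 4), c(2, -1, 0.5))
  m1 <- pca_fit(r1, 1)
  expect_equal(m1$explained_per_component[1], 1, tolerance = 1e-10)

  set.seed(31)
  for (i in 1:25) {
    n <- sample(4:8, 1); p <- sample(3:6, 1)
    X <- scale(matrix(rnorm(n * p), n, p), scale = FALSE)
    k <- min(3, n - 1, p)
    m <- pca_fit(X, k)
    sv <- svd(X)
    for (a in seq_len(k)) {
      # sign-adjust against the oracle
      sgn <- sign(sum(m$P[, a] * sv$v[, a]))
      expect_equal(m$P[, a], sgn * sv$v[, a], tolerance = 1e-8)
      expect_equal(m$T[, a], sgn * sv$u[, a] * sv$d[a], tolerance = 1e-8)
      expect_equal(m$explained_per_component[a], sv$d[a]^2 / sum(sv$d^2),
                   tolerance = 1e-10)
    }
    G <- crossprod(m$T)
    expect_lt(max(abs(G[upper.tri(G)])), 1e-8)
  }
})

test_that("PLS recovers exact linear relations and matches the eigen oracle", {
  set.seed(41)
  X <- matrix(rnorm(40), 8, 5)
  B_true <- matrix(c(1, -2, 0, 0.5, 0), 5, 1)
  y <- X %*% B_true
  m <- pls_fit(scale(X), scale(y), 5)
  expect_equal(m$R2Y, 1, tolerance = 1e-8)

  # first PLS weight = dominant eigenvector of X' Y Y' X
  Xs <- scale(matrix(rnorm(15), 5, 3))
  Ys <- scale(matrix(rnorm(10), 5, 2))
  m2 <- pls_fit(Xs, Ys, 1)
  M <- t(Xs) %*% Ys %*% t(Ys) %*% Xs
  ev <- eigen(M, symmetric = TRUE)$vectors[, 1]
  sgn <- sign(sum(ev * m2$W[, 1]))
  expect_equal(unname(m2$W[, 1]), sgn * ev, tolerance = 1e-8)

  # zero response -> zero coefficients
  m0 <- pls_fit(Xs, matrix(0, 5, 1), 2)
  expect_equal(unname(m0$B), matrix(0, 3, 1))

  # fitted values reproduce X B
  m3 <- pls_fit(Xs, Ys, 2)
  fit_from_scores <- m3$T %*% t(m3$C)
  expect_equal(Xs %*% m3$B, fit_from_scores, tolerance = 1e-8)
})

test_that("OPLS-DA separates planted classes and keeps orthogonal scores orthogonal to y", {
  set.seed(51)
  cls <- rep(c(0, 1), each = 6)
  # class direction in variable 1, strong orthogonal variance in variable 2
  ortho <- rnorm(12, 0, 5)
  X <- cbind(cls * 4 + rnorm(12, 0, 0.1),
             ortho,
             matrix(rnorm(36, 0, 0.1), 12, 3))
  m0 <- opls_da_fit(autoscale(X[, 1, drop = FALSE]), cls, n_orth = 0, cv_folds = 4)
  expect_gte(m0$R2Y, 0.99)

  # center-only scaling keeps the planted orthogonal variance dominant
  m <- opls_da_fit(autoscale(X, "center_only"), cls, n_orth = 1, cv_folds = 4)
  expect_equal(m$n_orth, 1)
  y_c <- cls - mean(cls)
  expect_lt(max(abs(crossprod(m$T_orth, y_c))), 1e-8)
  # the recoverable part of the planted direction is its class-orthogonal
  # projection (orthogonal scores cannot carry any y variation)
  ortho_perp <- ortho - sum(ortho * y_c) / sum(y_c^2) * y_c
  expect_gt(abs(cor(m$T_orth[, 1], ortho_perp)), 0.95)
  expect_gt(abs(cor(m$T[, 1], cls)), 0.95)
  expect_lte(m$Q2, m$R2Y)
})

test_that("Q2 cross-validation matches hand-computed PRESS and behaves at the extremes", {
  # leave-one-out on 3 collinear points: hand PRESS bookkeeping
  X <- matrix(c(-1, 0, 1), 3, 1)
  y <- matrix(c(-2, 0, 2), 3, 1)
  q2 <- q2_cross_validation(X, y, 1, folds = 3)
  # hand calculation: each fold fits on 2 points; 1-comp PLS1 on centered
  # training data predicts the held-out point; assemble PRESS by hand
  # each fold recenters both blocks on its training split
  press <- 0
  for (i in 1:3) {
    mu_x <- colMeans(X[-i, , drop = FALSE])
    Xtr <- sweep(X[-i, , drop = FALSE], 2, mu_x)
    mu <- mean(y[-i, ])
    b <- oracle_pls1_coef(Xtr, y[-i, 1] - mu)
    press <- press + as.numeric(y[i] - ((X[i, ] - mu_x) %*% b + mu))^2
  }
  ss <- sum((y - mean(y))^2)
  expect_equal(q2, 1 - press / ss, tolerance = 1e-10)

  # noise-free linear relation: Q2 ~ 1
  set.seed(61)
  Xl <- matrix(rnorm(60), 20, 3)
  yl <- Xl %*% c(1, 2, -1)
  q <- q2_cross_validation(scale(Xl), scale(yl), 3, folds = 5)
  expect_gt(q[3], 0.99)

  # pure-noise labels: median Q2 < 0 over seeds
  meds <- replicate(40, {
    Xn <- matrix(rnorm(48), 16, 3)
    yn <- rnorm(16)
    q2_cross_validation(scale(Xn), scale(yn), 1, folds = 4)[1]
  })
  expect_lt(median(meds), 0)
})

test_that("VIP satisfies its normalization and matches direct formula evaluation", {
  set.seed(71)
  # one variable fully drives y, others are exactly zero
  X <- cbind(rnorm(10), 0, 0, 0)
  y <- X[, 1] * 2
  sc <- suppressMessages(autoscale(X))
  m <- pls_fit(sc, matrix(y - mean(y), ncol = 1), 1)
  v <- vip(m)
  expect_equal(unname(v), c(2, 0, 0, 0), tolerance = 1e-8)  # sqrt(p) = 2

  # any fitted model: mean squared VIP = 1; brute-force formula agreement
  for (i in 1:10) {
    Xr <- matrix(rnorm(8 * 4), 8, 4)
    Yr <- matrix(rnorm(8 * 2), 8, 2)
    m <- pls_fit(scale(Xr), scale(Yr), 2)
    v <- vip(m)
    expect_equal(mean(v^2), 1, tolerance = 1e-8)
    # direct summation oracle
    p <- 4
    num <- rep(0, p); den <- 0
    for (a in seq_len(m$n_components)) {
      wa <- m$W[, a] / sqrt(sum(m$W[, a]^2))
      num <- num + m$ssy_per_component[a] * wa^2
      den <- den + m$ssy_per_component[a]
    }
    expect_equal(unname(v), sqrt(p * num / den), tolerance = 1e-10)
  }
})

test_that("permutation p-value hits its floor on strong signal and is reproducible", {
  set.seed(81)
  cls <- rep(c(0, 1), each = 5)
  X <- cbind(cls * 5 + rnorm(10, 0, 0.2), matrix(rnorm(30, 0, 0.5), 10, 3))
  sc <- autoscale(X)
  pt <- permutation_test(sc, cls, n = 39, n_orth = 0, cv_folds = 5)
  expect_equal(pt$p_value, 1 / 40)   # no permutation beats the observed Q2
  expect_true(all(pt$permuted$Q2 < pt$observed$Q2))
  # refit on the identity permutation reproduces the observed Q2
  m_again <- opls_da_fit(sc, cls, n_orth = 0, cv_folds = 5)
  expect_equal(m_again$Q2, pt$observed$Q2)
  # intercept summaries exist and R2Y intercept >= Q2 intercept
  expect_gte(pt$r2y_intercept, pt$q2_intercept)
})

test_that("CV-ANOVA matches hand-assembled sums of squares and its boundary cases", {
  # null self-comparison: identical residuals, zero components -> F = 1
  r <- c(0.5, -0.2, 0.3, -0.4, 0.1, 0.2, -0.3, 0.6)
  out <- cv_anova(r, r, n_components = 0)
  expect_equal(out$F, 1)
  expect_gt(out$p_value, 0.4)

  # worked 8-observation case with explicit bookkeeping
  rn <- c(1, -1, 0.5, -0.5, 0.8, -0.8, 0.3, -0.3)
  rm <- rn / 4
  out2 <- cv_anova(rn, rm, n_components = 2)
  press0 <- sum(rn^2); press1 <- sum(rm^2)
  F_hand <- (press0 / 7) / (press1 / 5)
  expect_equal(out2$F, F_hand, tolerance = 1e-12)
  expect_equal(out2$p_value, pf(F_hand, 7, 5, lower.tail = FALSE))

  # near-perfect model -> significant
  out3 <- cv_anova(rn, rn / 100, n_components = 1)
  expect_lt(out3$p_value, 0.05)

  # zero model residuals -> F Inf, p 0 (flagged)
  out4 <- suppressMessages(cv_anova(rn, rep(0, 8), n_components = 1))
  expect_equal(out4$F, Inf)
  expect_equal(out4$p_value, 0)
})

test_that("null OPLS-DA models have negative median Q2", {
  set.seed(91)
  q2s <- replicate(40, {
    X <- matrix(rnorm(12 * 4), 12, 4)
    cls <- rep(c(0, 1), each = 6)
    opls_da_fit(autoscale(X), cls, n_orth = 0, cv_folds = 4)$Q2
  })
  expect_lt(median(q2s), 0)
})
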