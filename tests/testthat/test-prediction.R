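test_that("ridge solution matches direct inversion and the normal equations", {
  set.seed(1)
  n <- 5; m <- 3
  Z <- matrix(sample(c(0, 2), n * m, replace = TRUE), n, m)
  y <- rnorm(n)
  fit <- fit_testcross_model(y, Z, lambda = 2.5)
  Vi <- solve(tcrossprod(Z) + 2.5 * diag(n))
  mu <- sum(Vi %*% y) / sum(Vi)
  alpha <- solve(crossprod(Z) + 2.5 * diag(m), crossprod(Z, y - mu))
  expect_equal(fit$alpha, as.vector(alpha), tolerance = 1e-10)
  # REML-estimated fit satisfies the ridge normal equations
  set.seed(2)
  n <- 60; m <- 40
  Z <- matrix(sample(c(0, 2), n * m, replace = TRUE), n, m)
  y <- as.vector(Z %*% rnorm(m, 0, 0.2)) + rnorm(n)
  fit <- fit_testcross_model(y, Z)
  lhs <- (crossprod(Z) + fit$lambda * diag(m)) %*% fit$alpha
  rhs <- crossprod(Z, y - fit$mu)
  expect_lt(max(abs(lhs - rhs)) / max(abs(rhs)), 1e-8)
  # observation-space and marker-space solutions coincide for n < m
  alpha_m <- solve(crossprod(Z) + fit$lambda * diag(m),
                   crossprod(Z, y - fit$mu))
  expect_lt(max(abs(fit$alpha - alpha_m)), 1e-8)
})

test_that("constant phenotypes yield zero effects with a degenerate warning", {
  Z <- matrix(sample(c(0, 2), 20, replace = TRUE), 5, 4)
  expect_warning(fit <- fit_testcross_model(rep(3, 5), Z),
                 class = "sparsecross_degenerate")
  expect_equal(fit$alpha, rep(0, 4))
  expect_equal(fit$mu, 3)
  expect_warning(f2 <- fit_pool_specific_model(rep(1, 5),
                                               Z / 2, (2 - Z) / 2),
                 class = "sparsecross_degenerate")
  expect_equal(f2$a1, rep(0, 4))
})

test_that("marker-effect recovery improves with training-set size", {
  sim <- function(n, m, seed) {
    set.seed(seed)
    Z <- matrix(sample(c(0, 2), n * m, replace = TRUE), n, m)
    alpha <- rnorm(m)
    g <- as.vector(Z %*% alpha)
    y <- g + rnorm(n, 0, sqrt(var(g) * 0.25)) # h2 = 0.8
    cor(fit_testcross_model(y, Z)$alpha, alpha)
  }
  small <- vapply(1:10, function(s) sim(60, 100, s), numeric(1))
  large <- vapply(1:10, function(s) sim(300, 100, s + 100), numeric(1))
  expect_gt(mean(large), 0.6)
  expect_gt(mean(large), mean(small))
})

test_that("pool-specific BLUPs solve Henderson's equations at fixed variances", {
  set.seed(5)
  n <- 8; m <- 4
  Z1 <- matrix(sample(0:1, n * m, replace = TRUE), n, m)
  Z2 <- matrix(sample(0:1, n * m, replace = TRUE), n, m)
  W <- 1L * (Z1 != Z2)
  y <- rnorm(n)
  vc <- c(0.5, 0.7, 0.3, 1.2)
  fit <- fit_pool_specific_model(y, Z1, Z2, W, var_components = vc)
  X <- cbind(1, rowSums(W))
  Zc <- cbind(Z1, Z2, W)
  Gi <- diag(vc[4] / rep(vc[1:3], each = m))
  lhs <- rbind(cbind(crossprod(X), crossprod(X, Zc)),
               cbind(crossprod(Zc, X), crossprod(Zc) + Gi))
  sol <- solve(lhs, c(crossprod(X, y), crossprod(Zc, y)))
  expect_equal(c(fit$mu, fit$mu_d), sol[1:2], tolerance = 1e-8)
  expect_equal(c(fit$a1, fit$a2, fit$d_star), unname(sol[-(1:2)]),
               tolerance = 1e-8)
  expect_equal(fit$d_total, fit$d_star + fit$mu_d)
})

test_that("REML recovers pool-specific effects from simulated data", {
  set.seed(6)
  n <- 300; m <- 80
  Z1 <- matrix(sample(0:1, n * m, replace = TRUE), n, m)
  Z2 <- matrix(sample(0:1, n * m, replace = TRUE), n, m)
  W <- 1L * (Z1 != Z2)
  a1 <- rnorm(m, 0, 0.4); a2 <- rnorm(m, 0, 0.4); d <- rnorm(m, 0.25, 0.25)
  g <- as.vector(Z1 %*% a1 + Z2 %*% a2 + W %*% d)
  y <- g + rnorm(n, 0, sqrt(var(g) * 0.25))
  fit <- fit_pool_specific_model(y, Z1, Z2)
  expect_true(fit$converged)
  expect_gt(cor(fit$a1, a1), 0.5)
  expect_gt(cor(fit$a2, a2), 0.5)
  expect_gt(cor(fit$d_total, d), 0)
})

test_that("a single shared tester leaves tester effects exactly at zero", {
  set.seed(7)
  n <- 40; m <- 12
  Z1 <- matrix(sample(0:1, n * m, replace = TRUE), n, m)
  Z2 <- matrix(rep(sample(0:1, m, replace = TRUE), each = n), n, m)
  y <- as.vector(Z1 %*% rnorm(m)) + rnorm(n)
  fit <- fit_pool_specific_model(y, Z1, Z2)
  expect_equal(fit$a2, rep(0, m))
  expect_true(all(is.finite(fit$a1)))
})

test_that("inconsistent or degenerate dominance structure is handled", {
  set.seed(8)
  n <- 10; m <- 5
  Z1 <- matrix(sample(0:1, n * m, replace = TRUE), n, m)
  Z2 <- matrix(sample(0:1, n * m, replace = TRUE), n, m)
  Wbad <- 1L * (Z1 == Z2)
  if (all(Wbad == (Z1 != Z2))) Wbad[1, 1] <- 1L - Wbad[1, 1]
  expect_error(fit_pool_specific_model(rnorm(n), Z1, Z2, W = Wbad),
               "inconsistent")
  # complementary pools: every hybrid locus heterozygous, W1 constant
  Z2c <- 1L - Z1
  expect_warning(fitc <- fit_pool_specific_model(rnorm(n), Z1, Z2c),
                 class = "sparsecross_degenerate")
  expect_equal(fitc$mu_d, 0)
})

test_that("GCA marker effects combine additive and dominance terms", {
  fit <- structure(list(a1 = c(1, 2), a2 = c(0.5, 1), d_star = c(0, 0),
                        d_total = c(0.4, 0)), class = "pool_fit")
  eff <- gca_marker_effects(fit, freqs_pool1 = c(0.3, 0.5),
                            freqs_pool2 = c(0.1, 0.5))
  expect_equal(eff$alpha_pool1, c(0.5 * (1 + 0.4 * 0.8), 1)) # 0.66, 1
  expect_equal(eff$alpha_pool2, c(0.5 * (0.5 + 0.4 * 0.4), 0.5))
  # additive limit: d = 0 halves the additive effect
  fit0 <- structure(list(a1 = c(3, -1), a2 = c(1, 1), d_star = c(0, 0),
                         d_total = c(0, 0)), class = "pool_fit")
  eff0 <- gca_marker_effects(fit0, c(0.2, 0.9), c(0.7, 0.2))
  expect_equal(eff0$alpha_pool1, c(1.5, -0.5))
  expect_error(gca_marker_effects(fit, c(0.5), c(0.1, 0.2)), "match")
  expect_error(gca_marker_effects(fit, c(0.5, 1.2), c(0.1, 0.2)), "0, 1")
})

test_that("GCA prediction and truncation selection are deterministic", {
  G <- matrix(c(2, 0, 0, 2), 2, 2)
  expect_equal(predict_gca(G, c(0, 0)), c(0, 0))
  expect_equal(predict_gca(matrix(2, 1, 1), 1.5), 3)
  set.seed(9)
  G10 <- matrix(sample(c(0, 2), 200, replace = TRUE), 10, 20)
  al <- rnorm(20)
  expect_equal(predict_gca(G10, al),
               vapply(1:10, function(i) sum(G10[i, ] * al), numeric(1)))
  lp <- make_line_pop(matrix(sample(0:1, 100 * 5, replace = TRUE), 100, 5))
  sc <- rev(seq_len(100)) # strictly decreasing with index
  expect_equal(select_parents(lp, sc, 10)$ids, lp$ids[1:10])
  expect_equal(select_parents(lp, rep(1, 100), 10)$ids, lp$ids[1:10])
  set.seed(10)
  sc2 <- rnorm(100)
  expect_equal(select_parents(lp, sc2, 10)$ids,
               lp$ids[sort(order(sc2, decreasing = TRUE)[1:10])])
  expect_error(select_parents(lp, sc2, 101), "more lines")
})
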