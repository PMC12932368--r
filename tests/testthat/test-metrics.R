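test_that("the marginal true-GCA formula equals brute-force enumeration", {
  set.seed(1)
  for (case in 1:100) {
    nq <- 10
    a <- rnorm(nq); d <- rnorm(nq, 0.3, 0.4)
    tr <- make_trait(a, d)
    B_f <- matrix(sample(0:1, 5 * nq, replace = TRUE), 5, nq)
    B_m <- matrix(sample(0:1, 7 * nq, replace = TRUE), 7, nq)
    p_m <- colMeans(B_m)
    gca <- true_gca(B_f, p_m, tr)
    for (i in 1:5) {
      vals <- vapply(1:7, function(j) {
        brute_value(B_f[i, ] + B_m[j, ], a, d)
      }, numeric(1))
      expect_equal(gca[i], mean(vals))
    }
  }
  # opposite pool fixed for the 1 allele, no dominance: sum of a over
  # loci where the line carries the allele, minus a elsewhere
  tr2 <- make_trait(c(1, 2), c(0, 0))
  expect_equal(true_gca(c(1, 1), c(1, 1), tr2), 3)
  # line aa at the first locus gives a heterozygous hybrid there: value d = 0
  expect_equal(true_gca(c(0, 1), c(1, 1), tr2), 2)
})

test_that("without dominance GCA differences halve breeding-value differences", {
  set.seed(2)
  nq <- 20
  a <- rnorm(nq)
  tr <- make_trait(a, rep(0, nq))
  B <- matrix(sample(0:1, 6 * nq, replace = TRUE), 6, nq)
  p <- runif(nq)
  gca <- true_gca(B, p, tr)
  bv <- as.vector((2 * B) %*% a) # breeding values on the dosage scale
  expect_equal(gca[1] - gca[2], (bv[1] - bv[2]) / 2)
})

test_that("the full-factorial mean is exact against pair enumeration", {
  set.seed(3)
  for (case in 1:20) {
    nq <- 6
    a <- rnorm(nq); d <- rnorm(nq, 0.5, 0.5)
    tr <- make_trait(a, d)
    B_f <- matrix(sample(0:1, 4 * nq, replace = TRUE), 4, nq)
    B_m <- matrix(sample(0:1, 4 * nq, replace = TRUE), 4, nq)
    vals <- c()
    for (i in 1:4) for (j in 1:4) {
      vals <- c(vals, brute_value(B_f[i, ] + B_m[j, ], a, d))
    }
    expect_equal(full_factorial_mean(colMeans(B_f), colMeans(B_m), tr),
                 mean(vals))
  }
  tr1 <- make_trait(c(1, 2), c(5, 7))
  expect_equal(full_factorial_mean(c(1, 1), c(1, 1), tr1), 3) # sum of a
  expect_equal(full_factorial_mean(c(1, 1), c(0, 0), tr1), 12) # sum of d
})

test_that("SCA variance vanishes under pure additivity and tracks sampling", {
  set.seed(4)
  nq <- 15
  a <- rnorm(nq)
  tr_add <- make_trait(a, rep(0, nq))
  pf <- make_line_pop(matrix(sample(0:1, 12 * nq, replace = TRUE), 12, nq))
  pm <- make_line_pop(matrix(sample(0:1, 12 * nq, replace = TRUE), 12, nq),
                      pool = "male")
  vc <- gca_sca_variances(pf, pm, tr_add)
  expect_equal(vc[["var_sca"]], 0)
  expect_equal(vc[["var_hybrid"]], vc[["var_gca_f"]] + vc[["var_gca_m"]],
               tolerance = 1e-10)
  # Monte-Carlo hybrid variance agrees with enumeration within 3 SE
  tr_dom <- make_trait(a, abs(rnorm(nq, 0.5, 0.3)))
  vc_enum <- gca_sca_variances(pf, pm, tr_dom)
  vc_mc <- gca_sca_variances(pf, pm, tr_dom, n_sample_pairs = 20000,
                             max_enum = 10, seed = 9)
  se <- vc_enum[["var_hybrid"]] * sqrt(2 / 20000) * 3
  expect_lt(abs(vc_mc[["var_hybrid"]] - vc_enum[["var_hybrid"]]),
            3 * se + 0.05 * vc_enum[["var_hybrid"]])
})

test_that("prediction accuracy is the Pearson correlation with NA guards", {
  x <- c(1, 3, 2, 5, 4)
  expect_equal(prediction_accuracy(x, x), 1)
  expect_equal(prediction_accuracy(-x, x), -1)
  y <- c(2, 1, 4, 3, 6)
  expect_equal(prediction_accuracy(x, y), cor(x, y))
  expect_true(is.na(prediction_accuracy(rep(1, 5), y)))
  expect_error(prediction_accuracy(x[1:2], y[1:2]))
})

test_that("Nei distance counts only union-polymorphic QTN", {
  expect_equal(nei_min_distance(c(0.2, 0.7), c(0.2, 0.7)), 0)
  expect_equal(nei_min_distance(c(1, 0), c(0, 1)), 1)
  expect_equal(nei_min_distance(0.8, 0.3), 0.25)
  # same-allele-fixed loci are excluded from the average
  expect_equal(nei_min_distance(c(0.8, 1, 0), c(0.3, 1, 0)), 0.25)
  expect_true(is.na(nei_min_distance(c(0, 1), c(0, 1))))
})

test_that("heterosis follows Falconer's frequency-difference formula", {
  tr <- make_trait(c(1, 1), c(2, 1))
  expect_equal(mid_parent_heterosis(c(0.5, 0.3), tr, p_m = c(0.5, 0.3)), 0)
  expect_equal(mid_parent_heterosis(c(1, 0.5), tr, p_m = c(0.5, 0.5)), 0.5)
  # identity: hybrid mean minus mid-parent mean of the two random-mating
  # pools, computed independently per locus
  set.seed(5)
  nq <- 20
  a <- rnorm(nq); d <- rnorm(nq, 0.4, 0.5)
  trr <- make_trait(a, d)
  p_f <- runif(nq); p_m <- runif(nq)
  pool_mean <- function(p) sum(a * (2 * p - 1) + 2 * p * (1 - p) * d)
  H <- full_factorial_mean(p_f, p_m, trr) -
    (pool_mean(p_f) + pool_mean(p_m)) / 2
  expect_equal(mid_parent_heterosis(p_f, trr, p_m = p_m), H)
  # symmetry and sign behaviour
  expect_equal(mid_parent_heterosis(p_f, trr, p_m = p_m),
               mid_parent_heterosis(p_m, trr, p_m = p_f))
  tr_neg <- make_trait(a, -d)
  expect_equal(mid_parent_heterosis(p_f, tr_neg, p_m = p_m), -H)
})

test_that("fixation fractions count same- and opposite-fixed QTN", {
  p_f <- c(0, 0, 0, 1, 1, 0.5, 0.2, 0, 1, 0.9)
  p_m <- c(0, 0, 0, 1, 0, 0.5, 0.2, 1, 0.3, 0.9)
  fx <- fixed_allele_fractions(p_f, p_m = p_m, n_total_qtn = 10)
  expect_equal(fx[["frac_same"]], 0.4)
  expect_equal(fx[["frac_opposite"]], 0.2)
  expect_equal(unname(fixed_allele_fractions(c(1, 0), p_m = c(0, 1))),
               c(0, 1))
})

test_that("GRM principal components separate constructed clusters", {
  set.seed(6)
  base1 <- sample(c(0, 2), 40, replace = TRUE)
  base2 <- sample(c(0, 2), 40, replace = TRUE)
  flip <- function(g) {
    i <- sample(40, 4); g[i] <- 2 - g[i]; g
  }
  G <- rbind(t(replicate(10, flip(base1))), t(replicate(10, flip(base2))))
  fr <- grm_pc_variance_fractions(G, 3)
  expect_gt(fr[1], 0.5)
  expect_lte(sum(grm_pc_variance_fractions(G, 20)), 1 + 1e-8)
  # identical duplicated individuals carry no variance: NA
  expect_true(all(is.na(grm_pc_variance_fractions(rbind(base1, base1), 2))))
})
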