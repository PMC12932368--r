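test_that("half-diallel sampling covers all parents with distinct pairs", {
  ids <- sprintf("P%02d", 1:40)
  plan <- sample_half_diallel(ids, 60, seed = 1)
  expect_equal(nrow(plan), 60)
  expect_true(all(plan$mother != plan$father))
  expect_equal(sort(unique(c(plan$mother, plan$father))), sort(ids))
  expect_equal(anyDuplicated(paste(pmin(plan$mother, plan$father),
                                   pmax(plan$mother, plan$father))), 0)
  # two parents, one cross: the only pair
  p2 <- sample_half_diallel(c("a", "b"), 1, seed = 1)
  expect_equal(sort(c(p2$mother, p2$father)), c("a", "b"))
  # four parents, six crosses: necessarily the full half diallel
  p4 <- sample_half_diallel(letters[1:4], 6, seed = 3)
  expect_equal(sort(paste(pmin(p4$mother, p4$father),
                          pmax(p4$mother, p4$father))),
               sort(apply(combn(letters[1:4], 2), 2, paste, collapse = " ")))
  expect_error(sample_half_diallel(letters[1:4], 7, seed = 1), "more crosses")
  expect_error(sample_half_diallel(letters[1:6], 2, seed = 1), "cover")
  # coverage property over many seeds at the minimum feasible cross count
  for (s in 1:200) {
    p <- sample_half_diallel(sprintf("x%d", 1:10), 5, seed = s)
    expect_equal(length(unique(c(p$mother, p$father))), 10)
  }
})

test_that("meiosis reproduces Mendelian and Haldane expectations", {
  # fully homozygous parent: the gamete is the haplotype
  B <- matrix(rep(c(0L, 1L), each = 10), nrow = 2, byrow = TRUE)
  lp <- make_line_pop(B)
  g <- meiose(line_as_diploid(lp, 2), seed = 5)
  expect_equal(g[[1]], rep(1L, 10))
  # two loci 50 cM apart: recombinant fraction from the Haldane map
  f1 <- structure(list(haps = list(rbind(c(0L, 1L), c(0L, 1L))),
                       pos = list(c(10, 60)), role = list(c("QTN", "QTN")),
                       chr_len_cM = 200), class = "diploid_geno")
  dh <- derive_dh_lines(f1, 6000, seed = 9)
  al <- t(dh$haps[[1]])
  rec <- mean(al[, 1] != al[, 2])
  expect_lt(abs(rec - (1 - exp(-1)) / 2), 0.02) # 0.316...
  # per-locus transmission is fair
  expect_lt(abs(mean(al[, 1]) - 0.5), 0.02)
  # crossover count on a 200 cM chromosome has mean 2 (Poisson):
  # strand switches along a dense map count effective crossovers
  f2 <- structure(list(haps = list(cbind(rep(0L, 201), rep(1L, 201))),
                       pos = list(seq(0, 200, by = 1)),
                       role = list(rep("QTN", 201)), chr_len_cM = 200),
                  class = "diploid_geno")
  dh2 <- derive_dh_lines(f2, 4000, seed = 10)
  switches <- colSums(abs(diff(dh2$haps[[1]])))
  expect_lt(abs(mean(switches) - 2), 0.1)
})

test_that("doubled haploids are homozygous and segregate fairly", {
  pop <- tiny_pop()
  lines0 <- inbreed_founders(pop, seed = 2)
  expect_true(all(vapply(seq_along(lines0$haps), function(chr) {
    all(lines0$haps[[chr]] %in% 0:1)
  }, logical(1))))
  plan <- sample_half_diallel(lines0$ids[1:4], 4, seed = 1)
  dh <- dh_from_crosses(lines0, plan, 5, seed = 3, pool = "female")
  expect_equal(n_ind(dh), 20)
  expect_equal(unique(table(dh$family)), 5L)
  # F1 homozygous everywhere -> every DH identical to it
  B <- matrix(1L, 1, 8)
  f1 <- line_as_diploid(make_line_pop(B), 1)
  dhh <- derive_dh_lines(f1, 10, seed = 4)
  expect_true(all(dhh$haps[[1]] == 1L))
})

test_that("testcross genotypes are the sum of parental alleles", {
  expect_equal(make_testcross(c(2, 0), c(0, 0)), c(1, 0))
  expect_equal(make_testcross(c(2, 2), c(2, 2)), c(2, 2))
  expect_error(make_testcross(c(1, 0), c(0, 0)), "homozygous")
  # hybrid value equals the genotype-table value, locus by locus
  set.seed(21)
  a <- rnorm(100); d <- rnorm(100, 0.4, 0.3)
  tr <- make_trait(a, d)
  bl <- sample(0:1, 100, replace = TRUE)
  bt <- sample(0:1, 100, replace = TRUE)
  hyb <- make_testcross(2 * bl, 2 * bt)
  expect_equal(genetic_value(hyb, tr), brute_value(hyb, a, d))
  # grouped fast path agrees with the per-pair computation
  B_l <- matrix(sample(0:1, 500, replace = TRUE), 5, 100)
  B_t <- matrix(sample(0:1, 300, replace = TRUE), 3, 100)
  tof <- c(1, 3, 2, 1, 2)
  vals <- testcross_values(B_l, B_t, tof, tr)
  for (i in 1:5) {
    expect_equal(vals[i],
                 genetic_value(make_testcross(2 * B_l[i, ], 2 * B_t[tof[i], ]),
                               tr))
  }
  vm <- hybrid_value_matrix(B_l, B_t, tr)
  expect_equal(vm[cbind(1:5, tof)], vals)
})

test_that("error variance calibration matches the heritability identity", {
  set.seed(31)
  a <- rnorm(12); d <- rnorm(12, 0.4, 0.3)
  tr <- make_trait(a, d)
  pf <- make_line_pop(matrix(sample(0:1, 36, replace = TRUE), 3, 12))
  pm <- make_line_pop(matrix(sample(0:1, 36, replace = TRUE), 3, 12),
                      pool = "male")
  # brute-force variance of the nine enumerated hybrids
  vals <- c()
  for (i in 1:3) for (j in 1:3) {
    vals <- c(vals, brute_value(line_alleles(pf)[i, ] + line_alleles(pm)[j, ],
                                a, d))
  }
  s2g <- var(vals)
  expect_equal(calibrate_error_variance(pf, pm, tr, H2 = 0.5), s2g)
  expect_equal(calibrate_error_variance(pf, pm, tr, H2 = 0.3), s2g * 7 / 3)
  expect_error(calibrate_error_variance(pf, pf, make_trait(0 * a, 0 * d)),
               "zero genetic variance")
})

test_that("phenotype simulation adds calibrated iid noise", {
  g <- rnorm(10000, 50, 3)
  expect_equal(simulate_phenotypes(g, 0, seed = 1), g)
  ph <- simulate_phenotypes(g, 21, seed = 2)
  expect_lt(abs(var(ph - g) - 21), 1)
  expect_identical(ph, simulate_phenotypes(g, 21, seed = 2))
  expect_false(identical(ph, simulate_phenotypes(g, 21, seed = 3)))
})

test_that("initial pool formation produces the configured family structure", {
  pop <- tiny_pop()
  pools <- form_initial_pools(pop, seed = 5, generations = 2, n_crosses = 10,
                              dh_per_cross = 5, n_parents = 10)
  for (p in c("female", "male")) {
    expect_equal(n_ind(pools[[p]]), 50)
    expect_equal(length(unique(pools[[p]]$family)), 10)
    expect_equal(n_ind(pools[[paste0("parents_", p)]]), 10)
  }
  expect_equal(pools$female$pool, "female")
  # determinism
  pools2 <- form_initial_pools(pop, seed = 5, generations = 2,
                               n_crosses = 10, dh_per_cross = 5,
                               n_parents = 10)
  expect_identical(pools$female$haps, pools2$female$haps)
  # generations = 0: the inbred founders, split in two
  p0 <- form_initial_pools(pop, seed = 5, generations = 0)
  expect_equal(sort(c(p0$female$ids, p0$male$ids)), sort(pop$ids))
  expect_equal(n_ind(p0$female) + n_ind(p0$male), n_ind(pop))
})

test_that("allele frequencies drift without directional change", {
  pop <- tiny_pop()
  p_lines0 <- allele_freq(inbreed_founders(pop, seed = 99), "QTN")
  drift <- replicate(25, NA_real_)
  for (r in 1:25) {
    pools <- form_initial_pools(pop, seed = 1000 + r, generations = 1,
                                n_crosses = 10, dh_per_cross = 5,
                                n_parents = 10)
    p_new <- (allele_freq(pools$female, "QTN") +
                allele_freq(pools$male, "QTN")) / 2
    drift[r] <- mean(p_new - p_lines0)
  }
  # inbreeding redraws haplotypes, so compare against the founder frequency
  p_founder <- allele_freq(pop, "QTN")
  expect_lt(abs(mean(drift) + mean(p_lines0) - mean(p_founder)), 0.02)
})
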