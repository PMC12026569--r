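test_that("expected alt fraction follows the linear mixture and is monotone in k", {
  expect_equal(expected_alt_fraction(0, 1, 0.2), 0.10)
  expect_equal(expected_alt_fraction(1, 1, 0.37), 0.50)
  expect_equal(expected_alt_fraction(2, 2, 0.1), 1.00)
  # error adjustment pulls toward 0.5
  expect_equal(expected_alt_fraction(0, 0, 0.1, error_rate = 0.01), 0.01)
  expect_equal(expected_alt_fraction(2, 2, 0.1, error_rate = 0.01), 0.99)
  for (m in 0:2) for (f in c(0.01, 0.1, 0.3)) for (eps in c(0, 0.05)) {
    p <- expected_alt_fraction(m, 0:2, f, eps)
    expect_true(all(diff(p) > 0))
    expect_true(all(p >= 0 & p <= 1))
  }
  expect_error(expected_alt_fraction(3, 1, 0.1), "invalid-parameter")
  expect_error(expected_alt_fraction(0, 1, 1.2), "invalid-parameter")
})

test_that("genotype log-likelihood matches an independent binomial pmf", {
  # single Bernoulli read: p' = f*k/2 = 0.1
  expect_equal(genotype_log_likelihood(1, 1, m = 0, k = 1, f = 0.2), log(0.1))
  # two reads at p = 0.5: 2 * 0.25
  expect_equal(genotype_log_likelihood(1, 2, m = 1, k = 1, f = 0.33), log(0.5))
  expect_equal(genotype_log_likelihood(10, 100, m = 0, k = 1, f = 0.2),
               oracle_binom_logpmf(10, 100, 0.1), tolerance = 1e-12)
  expect_equal(genotype_log_likelihood(10, 100, m = 0, k = 1, f = 0.2),
               -2.025974, tolerance = 1e-6)
  expect_error(genotype_log_likelihood(1, 1, m = NA, k = 1, f = 0.1),
               "missing-data")
  expect_error(genotype_log_likelihood(0, 0, m = 0, k = 1, f = 0.1),
               "empty-observation")
})

test_that("genotype posterior equals exhaustive enumeration to 1e-9", {
  set.seed(101)
  for (i in 1:200) {
    depth <- sample(1:30, 1)
    alt <- sample(0:depth, 1)
    m <- sample(0:2, 1)
    f <- runif(1, 0, 0.3)
    eps <- runif(1, 0.001, 0.05)
    pr <- runif(3); pr <- pr / sum(pr)
    site <- snp_sites("chr1", 100, "A", "G", alt, depth,
                      maternal_copies = m, paternal_copies = 1)
    got <- call_fetal_genotype(site, f, prior = pr, error_rate = eps)
    want <- oracle_posterior(alt, depth, m, f, eps, pr)
    expect_equal(unlist(got[, c("post_k0", "post_k1", "post_k2")],
                        use.names = FALSE), want, tolerance = 1e-9)
    expect_equal(got$post_k0 + got$post_k1 + got$post_k2, 1, tolerance = 1e-9)
  }
})

test_that("maximum-likelihood calls match brute-force argmax on worked cases", {
  # frozen from the enumeration oracle
  s1 <- snp_sites("chr1", 1, "A", "G", 10, 100, maternal_copies = 0,
                  paternal_copies = 1)
  g1 <- call_fetal_genotype(s1, f = 0.2, error_rate = 0.01)
  expect_identical(g1$ml_call, 1L)
  expect_equal(g1$post_k1, 0.9823109, tolerance = 1e-6)
  s2 <- snp_sites("chr1", 1, "A", "G", 110, 200, maternal_copies = 1,
                  paternal_copies = 1)
  g2 <- call_fetal_genotype(s2, f = 0.1, error_rate = 0)
  expect_identical(g2$ml_call, 2L)
  expect_equal(g2$post_k2, 0.7218466, tolerance = 1e-6)
})

test_that("posterior collapses to the prior at f = 0 and ties break to smallest k", {
  s <- snp_sites("chr1", 1, "A", "G", 37, 80, maternal_copies = 1,
                 paternal_copies = 0)
  g <- call_fetal_genotype(s, f = 0, error_rate = 0.01)
  expect_equal(unlist(g[, c("post_k0", "post_k1", "post_k2")],
                      use.names = FALSE), rep(1 / 3, 3), tolerance = 1e-12)
  expect_identical(g$ml_call, 0L)  # exact tie -> smallest k
  pr <- c(0.2, 0.5, 0.3)
  g2 <- call_fetal_genotype(s, f = 0, prior = pr)
  expect_equal(unlist(g2[, c("post_k0", "post_k1", "post_k2")],
                      use.names = FALSE), pr, tolerance = 1e-12)
})

test_that("posterior stays normalized at very high depth (log-space arithmetic)", {
  s <- snp_sites("chr1", 1, "A", "G", 5200, 100000, maternal_copies = 0,
                 paternal_copies = 2)
  g <- call_fetal_genotype(s, f = 0.1, error_rate = 0.01)
  expect_equal(g$post_k0 + g$post_k1 + g$post_k2, 1, tolerance = 1e-9)
  expect_true(all(is.finite(unlist(g[, c("ll_k0", "ll_k1", "ll_k2")]))))
  expect_identical(g$ml_call, 1L)
})

test_that("at f = 1 the model reduces to an ordinary diploid genotype likelihood", {
  for (m in 0:2) for (k in 0:2) {
    got <- genotype_log_likelihood(7, 40, m = m, k = k, f = 1,
                                   error_rate = 0.02)
    p <- (k / 2) * (1 - 0.02) + (1 - k / 2) * 0.02
    expect_equal(got, oracle_binom_logpmf(7, 40, p), tolerance = 1e-12)
  }
})

test_that("fetal fraction estimator recovers exact and degenerate inputs", {
  # alt fraction exactly 0.05 at obligate-het sites -> 2 * mean = 0.10
  s <- snp_sites("chr1", 1:20, "A", "G", alt_count = 5, depth = 100,
                 maternal_copies = 0, paternal_copies = 2)
  est <- estimate_fetal_fraction(s)
  expect_equal(est$f, 0.10)
  expect_identical(est$n_informative_sites, 20L)
  # zero alt reads everywhere -> 0
  s0 <- snp_sites("chr1", 1:20, "A", "G", alt_count = 0, depth = 100,
                  maternal_copies = 0, paternal_copies = 2)
  expect_equal(estimate_fetal_fraction(s0)$f, 0)
  # no informative sites signals insufficient data
  s1 <- snp_sites("chr1", 1:3, "A", "G", 1, 10, maternal_copies = 1,
                  paternal_copies = 1)
  expect_error(estimate_fetal_fraction(s1), "insufficient-data")
  # het-father sites with the transmission correction: E[af] = f * p / 4
  set.seed(5)
  n <- 4000
  k <- rbinom(n, 1, 0.5)  # het father transmits alt half the time
  depth <- rep(300L, n)
  alt <- rbinom(n, depth, 0.1 * k / 2)
  sh <- snp_sites("chr1", 1:n, "A", "G", alt, depth,
                  maternal_copies = 0, paternal_copies = 1)
  est_h <- estimate_fetal_fraction(sh, min_paternal_copies = 1)
  expect_lt(abs(est_h$f - 0.1), 0.01)
})

test_that("informative-site partition is exhaustive, disjoint and correct", {
  s <- snp_sites("chr1", 1:6, "A", "G",
                 alt_count = 0, depth = 10,
                 maternal_copies = c(0L, 0L, 2L, 1L, NA, 2L),
                 paternal_copies = c(1L, 0L, 0L, 2L, 1L, NA))
  f <- flag_informative_sites(s)
  expect_equal(as.character(f$site_class),
               c("ff_informative",  # m=0, father carries alt
                 "fetal_tagging",   # m=0, father hom-ref
                 "fetal_tagging",   # m=2: ref reads can only be fetal
                 "uninformative",   # m=1: both alleles maternal
                 "uninformative",   # unknown maternal genotype
                 "fetal_tagging"))  # m=2, father unknown
  expect_false(any(is.na(f$site_class)))
  expect_equal(sum(table(f$site_class)), nrow(s))
})

test_that("mendelian prior matches transmission arithmetic", {
  expect_equal(mendelian_prior(0, 0), c(1, 0, 0))
  expect_equal(mendelian_prior(1, 1), c(0.25, 0.5, 0.25))
  expect_equal(mendelian_prior(2, 1), c(0, 0.5, 0.5))
  expect_equal(sum(mendelian_prior(1, 2)), 1)
})

test_that("site-table invariants are enforced", {
  expect_error(snp_sites("chr1", 0, "A", "G", 0, 1), "pos")
  expect_error(snp_sites("chr1", 1, "A", "A", 0, 1), "differ")
  expect_error(snp_sites("chr1", 1, "A", "G", 5, 3), "alt_count")
})
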