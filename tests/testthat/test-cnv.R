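make_ref <- function(n = 10, sigma = 0.05, ref_count = 100) {
  starts <- (seq_len(n) - 1L) * 1000L
  structure(list(bins = data.frame(chrom = "chr1", start = starts,
                                   end = starts + 1000L,
                                   ref_count = ref_count,
                                   stringsAsFactors = FALSE),
                 ratio_sigma = sigma, short_mean = NULL, short_sd = NULL,
                 p_short_fetal = NULL, p_short_maternal = NULL),
            class = "reference_bin_set")
}

make_bins <- function(ratio, n = length(ratio)) {
  starts <- (seq_len(n) - 1L) * 1000L
  b <- data.frame(chrom = "chr1", start = starts, end = starts + 1000L,
                  count = NA_real_, ratio = ratio,
                  short_fraction = NA_real_, masked = FALSE,
                  gross_deviation = FALSE, stringsAsFactors = FALSE)
  class(b) <- c("target_bins", "data.frame")
  b
}

test_that("expected ratio is 1 -/+ f/2 around diploid", {
  expect_equal(expected_ratio("fetal_del", 0.10), 0.95)
  expect_equal(expected_ratio("fetal_dup", 0.20), 1.10)
  expect_equal(expected_ratio("diploid", 0.37), 1.00)
  for (f in c(0.01, 0.05, 0.2)) {
    expect_lt(expected_ratio("fetal_del", f), 1)
    expect_gt(expected_ratio("fetal_dup", f), 1)
  }
  expect_error(expected_ratio("triploid", 0.1), "invalid-parameter")
})

test_that("bin normalization matches the double-median construction", {
  ref <- make_ref(10, ref_count = 100)
  counts <- data.frame(chrom = "chr1", start = (0:9) * 1000L,
                       end = (1:10) * 1000L, count = rep(100, 10))
  nb <- normalize_bins(counts, ref)
  expect_equal(nb$ratio, rep(1, 10))
  # one doubled bin against a flat background
  counts2 <- counts; counts2$count[4] <- 200
  nb2 <- normalize_bins(counts2, ref)
  expect_equal(nb2$ratio[4], 2, tolerance = 1e-12)
  expect_equal(stats::median(nb2$ratio), 1, tolerance = 1e-12)
  expect_true(nb2$gross_deviation[4])
  # missing reference bin
  counts3 <- counts; counts3$start[1] <- 55L
  expect_error(normalize_bins(counts3, ref), "incomplete-reference")
  # zero reference count masks the bin
  ref0 <- make_ref(10, ref_count = 100)
  ref0$bins$ref_count[2] <- 0
  expect_warning(nb4 <- normalize_bins(counts, ref0), "degenerate-bin")
  expect_true(nb4$masked[2])
  expect_true(is.na(nb4$ratio[2]))
})

test_that("simulated fetal deletion depresses event-bin ratios by about f/2", {
  means <- vapply(1:10, function(s) {
    co <- simulate_cohort(sim_config(
      seed = 300 + s, n_sites = 200,
      cnv_events = data.frame(chrom = "chr1", start = 2e6, end = 3e6,
                              state = "fetal_del")))
    nb <- normalize_bins(co$bins, co$reference)
    mean(nb$ratio[nb$start >= 2e6 & nb$end <= 3e6])
  }, numeric(1))
  expect_equal(mean(means), 0.95, tolerance = 0.01)
})

test_that("segment log-likelihood equals an independent per-bin sum", {
  ref <- make_ref(5, sigma = 0.04)
  bins <- make_bins(c(1.02, 0.97, 1.00, 0.95, 1.05))
  cfg <- cnv_config()
  for (st in c("fetal_del", "diploid", "fetal_dup")) {
    want <- sum(dnorm(log2(bins$ratio),
                      mean = log2(expected_ratio(st, 0.1)),
                      sd = 0.04, log = TRUE))
    expect_equal(segment_log_likelihood(bins, st, 0.1, ref, cfg), want,
                 tolerance = 1e-12)
  }
  # residual-free bins score exactly the Gaussian mode density
  at_mode <- make_bins(rep(expected_ratio("fetal_del", 0.1), 3))
  expect_equal(segment_log_likelihood(at_mode, "fetal_del", 0.1, ref, cfg),
               3 * dnorm(0, 0, 0.04, log = TRUE), tolerance = 1e-12)
  # wrong-model penalty on diploid data
  dip <- make_bins(rep(1, 5))
  expect_lt(segment_log_likelihood(dip, "fetal_del", 0.1, ref, cfg),
            segment_log_likelihood(dip, "diploid", 0.1, ref, cfg))
})

test_that("noise-free diploid data yields no CNV calls", {
  ref <- make_ref(20, sigma = 0.03)
  bins <- make_bins(rep(1, 20))
  calls <- call_cnvs(bins, 0.1, ref)
  expect_equal(nrow(calls), 0)
})

test_that("a clean 10-bin shift at the deletion mean is called exactly", {
  ref <- make_ref(30, sigma = 0.01)
  ratio <- rep(1, 30); ratio[11:20] <- 0.95
  calls <- call_cnvs(make_bins(ratio), 0.10, ref)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$copy_state, "fetal_del")
  expect_equal(calls$start, 10000L)
  expect_equal(calls$end, 20000L)
  expect_equal(calls$n_bins, 10L)
  expect_gt(calls$log_lr, 10)
})

test_that("calling at f = 0 warns and returns an empty callset", {
  ref <- make_ref(10)
  expect_warning(calls <- call_cnvs(make_bins(rep(0.9, 10)), 0, ref),
                 "indistinguishable")
  expect_equal(nrow(calls), 0)
})

test_that("size-shift z-scores standardize against the control baseline", {
  ref <- make_ref(3)
  ref$short_mean <- 0.25; ref$short_sd <- 0.02
  bins <- make_bins(rep(1, 3))
  bins$short_fraction <- c(0.25, 0.27, 0.21)
  z <- size_shift_statistic(bins, ref)
  expect_equal(z, c(0, 1, -2))
  ref$short_sd <- 0
  expect_error(size_shift_statistic(bins, ref), "degenerate-reference")
})

test_that("duplication bins shift the size statistic positive in expectation", {
  zs <- vapply(1:20, function(s) {
    co <- simulate_cohort(sim_config(
      seed = 400 + s, n_sites = 200, n_bins = 20,
      cnv_events = data.frame(chrom = "chr1", start = 5e5, end = 1.5e6,
                              state = "fetal_dup")))
    nb <- normalize_bins(co$bins, co$reference)
    ev <- nb$start >= 5e5 & nb$end <= 1.5e6
    mean(size_shift_statistic(nb[ev, ], co$reference))
  }, numeric(1))
  expect_gt(mean(zs), 0)
})

test_that("log-likelihood ratios favor the true state in expectation", {
  set.seed(77)
  lr_event <- lr_dip <- numeric(30)
  for (i in 1:30) {
    sim <- simulate_ratio_bins(n_bins = 20, sigma = 0.03, f = 0.1,
                               events = data.frame(start_bin = 6, end_bin = 15,
                                                   state = "fetal_del"),
                               seed = 500 + i)
    ev <- sim$bins[6:15, ]; dp <- sim$bins[c(1:5, 16:20), ]
    cfg <- cnv_config()
    lr_event[i] <- segment_log_likelihood(ev, "fetal_del", 0.1, sim$reference, cfg) -
      segment_log_likelihood(ev, "diploid", 0.1, sim$reference, cfg)
    lr_dip[i] <- segment_log_likelihood(dp, "fetal_del", 0.1, sim$reference, cfg) -
      segment_log_likelihood(dp, "diploid", 0.1, sim$reference, cfg)
  }
  expect_gt(mean(lr_event), 0)
  expect_lt(mean(lr_dip), 0)
})
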