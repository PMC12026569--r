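test_that("allele-fraction band keeps (0.20, 0.80] exactly", {
  v <- make_variants(6, af = c(0.15, 0.20, 0.21, 0.50, 0.80, 0.85))
  res <- allele_fraction_filter(v, filter_config())
  expect_equal(res$kept$allele_fraction, c(0.21, 0.50, 0.80))
  expect_equal(res$excluded$allele_fraction, c(0.15, 0.20, 0.85))
  expect_true(all(res$excluded$reason == "allele-fraction"))
  # missing AF is logged, not dropped silently
  vna <- make_variants(2, af = c(NA, 0.5))
  rna <- allele_fraction_filter(vna, filter_config())
  expect_equal(rna$excluded$reason, "missing-field")
  # empty input passes through
  expect_equal(nrow(allele_fraction_filter(make_variants(0),
                                           filter_config())$kept), 0)
  # hom-alt exemption keeps high-AF homozygous calls when switched on
  vh <- make_variants(2, af = c(0.95, 0.95), proband = c(2L, 1L))
  rh <- allele_fraction_filter(vh, filter_config(exempt_hom_alt = TRUE))
  expect_equal(rh$kept$proband, 2L)
})

test_that("blacklist filtering honors BED coordinate conventions", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t101", "chr2\t100\t200"), bed)
  bl <- read_bed(bed)
  v <- make_variants(4, chrom = c("chr1", "chr1", "chr2", "chr2"),
                     pos = c(101L, 100L, 100L, 200L))
  res <- blacklist_filter(v, bl)
  # BED [100,101) is exactly 1-based position 101
  expect_equal(res$excluded$pos, c(101L, 200L))
  # BED [100,200) covers 101..200, so 1-based 100 survives
  expect_equal(res$kept$pos, c(100L, 100L))
  # idempotent and identity on empty blacklist
  res2 <- blacklist_filter(res$kept, bl)
  expect_equal(res2$kept, res$kept)
  resE <- blacklist_filter(v, NULL)
  expect_equal(nrow(resE$kept), nrow(v))
})

test_that("depth filter boundary is >= min_depth", {
  v <- make_variants(3, depth = c(99L, 100L, 101L))
  res <- depth_filter(v, filter_config(min_depth = 100))
  expect_equal(res$kept$depth, c(100L, 101L))
  expect_equal(res$excluded$depth, 99L)
  res0 <- depth_filter(v, filter_config(min_depth = 0))
  expect_equal(nrow(res0$kept), 3)
})

test_that("trio classification implements the inheritance rules exhaustively", {
  expect_equal(classify_trio_variant(1, 0, 1), "paternal_inherited")
  expect_equal(classify_trio_variant(1, 0, 0), "de_novo")
  expect_equal(classify_trio_variant(1, 1, 0), "maternal_or_shared")
  expect_equal(classify_trio_variant(2, 0, 2), "paternal_inherited")
  expect_equal(classify_trio_variant(1, 0, NA), "unclassifiable")
  expect_equal(classify_trio_variant(0, 0, 1), "unclassifiable")
  expect_error(classify_trio_variant(NA, 0, 1), "missing-proband")
  # every genotype combination receives exactly one label
  combos <- expand.grid(proband = c(0:2, NA), mother = c(0:2, NA),
                        father = c(0:2, NA))
  combos <- combos[!is.na(combos$proband), ]
  lab <- classify_trio(combos)
  expect_equal(length(lab), nrow(combos))
  expect_false(any(is.na(lab)))
  expect_equal(sum(table(lab)), nrow(combos))
})

test_that("the artifact pipeline composes the three filters with provenance", {
  bed <- tempfile(fileext = ".bed")
  writeLines("chr1\t550\t650", bed)
  cfg <- filter_config(blacklist = read_bed(bed))
  v <- make_variants(6,
                     pos = c(100L, 200L, 300L, 400L, 600L, 500L),
                     af = c(0.10, 0.90, 0.50, 0.50, 0.50, 0.50),
                     depth = c(200L, 200L, 99L, 200L, 200L, 200L))
  res <- run_artifact_pipeline(v, cfg)
  expect_equal(nrow(res$variants), 2)
  expect_equal(res$report$removed, c(2L, 1L, 1L))
  expect_equal(sort(res$variants$pos), c(400L, 500L))
  # conservation: kept + per-stage removals = input
  expect_equal(nrow(res$variants) + sum(res$report$removed), nrow(v))
  # all-pass input is the identity with a zero-count report
  clean <- make_variants(4)
  resc <- run_artifact_pipeline(clean, cfg)
  expect_equal(nrow(resc$variants), 4)
  expect_equal(sum(resc$report$removed), 0)
  # classification column present and valid
  expect_true(all(res$variants$trio_class %in%
                    c("paternal_inherited", "de_novo", "maternal_or_shared",
                      "unclassifiable")))
})

test_that("filters commute and the pipeline equals their stagewise composition", {
  set.seed(42)
  bed <- tempfile(fileext = ".bed")
  writeLines("chr1\t1000\t3000", bed)
  cfg <- filter_config(blacklist = read_bed(bed))
  for (i in 1:20) {
    n <- 30
    v <- make_variants(n, pos = sample.int(5000, n),
                       af = round(runif(n), 2),
                       depth = sample(c(50L, 99L, 100L, 300L), n, TRUE))
    key <- function(d) paste(d$chrom, d$pos, d$allele_fraction, d$depth)
    ka <- key(allele_fraction_filter(v, cfg)$kept)
    kb <- key(blacklist_filter(v, cfg$blacklist)$kept)
    kd <- key(depth_filter(v, cfg)$kept)
    want <- intersect(intersect(ka, kb), kd)
    got <- key(run_artifact_pipeline(v, cfg)$variants)
    expect_setequal(got, want)
    # order independence: apply in reverse order
    r <- depth_filter(v, cfg)$kept
    r <- blacklist_filter(r, cfg$blacklist)$kept
    r <- allele_fraction_filter(r, cfg)$kept
    expect_setequal(key(r), want)
    # idempotence of each filter
    expect_equal(key(allele_fraction_filter(
      allele_fraction_filter(v, cfg)$kept, cfg)$kept), ka)
  }
})
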