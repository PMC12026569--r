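#' Canonical variant keys
#'
#' @param variants Data.frame with `chrom`, `pos`, `ref`, `alt`.
#' @return Character vector of `chrom:pos:ref:alt` keys.
#' @export
variant_key <- function(variants) {
  paste(variants$chrom, variants$pos, variants$ref, variants$alt, sep = ":")
}

#' Match a plasma callset against a truth callset
#'
#' Partitions the union of variant keys into common, plasma-only and
#' truth-only sets. Duplicate keys within one callset are collapsed with a
#' warning.
#'
#' @param plasma,truth Character vectors of variant keys (see
#'   [variant_key()]), or data.frames accepted by it.
#' @return List of class `matched_callsets` with character-vector elements
#'   `common`, `plasma_only`, `truth_only`.
#' @export
match_callsets <- function(plasma, truth) {
  as_keys <- function(x, label) {
    k <- if (is.data.frame(x)) variant_key(x) else as.character(x)
    if (anyDuplicated(k)) {
      warning("duplicate keys collapsed in ", label, " callset")
      k <- unique(k)
    }
    k
  }
  p <- as_keys(plasma, "plasma")
  t <- as_keys(truth, "truth")
  structure(list(common = intersect(t, p),
                 plasma_only = setdiff(p, t),
                 truth_only = setdiff(t, p)),
            class = "matched_callsets")
}

#' Round half away from zero
#'
#' `round_half_up(0.5) == 1`, unlike base R's banker's rounding.
#'
#' @param x Numeric vector.
#' @param digits Decimal digits (default 0).
#' @return Rounded values.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Overlap report for one sample and inheritance category
#'
#' The denominator is the truth-side (child/fetus) total: `total` counts
#' truth variants in the category, `common` those also seen in plasma, and
#' `uncommon` the truth variants missed in plasma. `pct_common` is
#' `100 * common / total` rounded half-up to an integer, and
#' `mean_cov_uncommon` is the mean plasma coverage at the missed sites —
#' low coverage there is the main reason a true variant goes unseen.
#'
#' @param sample_id Sample identifier.
#' @param category Inheritance category, e.g. `"father_inherited"` or
#'   `"de_novo"`.
#' @param matched A `matched_callsets` object.
#' @param coverage Named numeric vector of plasma coverage by variant key
#'   (used for the truth-only keys); may be `NULL` when unavailable.
#' @return One-row data.frame of class `overlap_report` with columns
#'   `sample_id`, `category`, `total`, `common`, `uncommon`, `pct_common`,
#'   `mean_cov_uncommon`.
#' @export
overlap_report <- function(sample_id, category, matched, coverage = NULL) {
  common <- length(matched$common)
  uncommon <- length(matched$truth_only)
  total <- common + uncommon
  if (total == 0) stop("empty-category: no truth variants for ", sample_id,
                       " / ", category)
  cov <- if (!is.null(coverage) && uncommon > 0) {
    mean(coverage[matched$truth_only], na.rm = TRUE)
  } else NA_real_
  out <- data.frame(sample_id = sample_id, category = category,
                    total = total, common = common, uncommon = uncommon,
                    pct_common = as.integer(round_half_up(100 * common / total)),
                    mean_cov_uncommon = cov, stringsAsFactors = FALSE)
  class(out) <- c("overlap_report", "data.frame")
  out
}

#' Recompute an overlap percentage after a coverage filter on missed sites
#'
#' Truth variants missed in plasma with plasma coverage at or below
#' `threshold` reads are dropped from the denominator: a site that plasma
#' sequencing barely touched cannot fairly count against the plasma
#' callset. The recomputed percentage is
#' `100 * common / (common + surviving uncommon)` and can never decrease.
#'
#' @param common Number of common variants.
#' @param uncommon_coverage Plasma coverage of each missed truth variant.
#' @param threshold Keep missed variants with coverage strictly above this
#'   (default 5 reads).
#' @return List with `common`, `uncommon` (surviving), `total` and
#'   `pct_common` (integer, half-up).
#' @export
apply_coverage_filter <- function(common, uncommon_coverage, threshold = 5) {
  surviving <- sum(uncommon_coverage > threshold, na.rm = TRUE)
  total <- common + surviving
  pct <- if (total == 0) NA_integer_ else
    as.integer(round_half_up(100 * common / total))
  list(common = common, uncommon = surviving, total = total,
       pct_common = pct)
}

#' Squared Pearson correlation
#'
#' @param x,y Numeric vectors of equal length, `n >= 2`, each with positive
#'   variance.
#' @param predictor Optional label for the predictor variable.
#' @return List of class `correlation_result` with `r2`, `n`, `predictor`.
#' @export
pearson_r2 <- function(x, y, predictor = NA_character_) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2) stop("undefined-correlation: need at least 2 points")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined-correlation: zero variance")
  structure(list(r2 = stats::cor(x, y)^2, n = length(x),
                 predictor = predictor),
            class = "correlation_result")
}

#' Per-category cohort summary of overlap reports
#'
#' @param reports Data.frame of stacked [overlap_report()] rows.
#' @return Data.frame with one row per category: `category`, `n_samples`,
#'   `mean_pct_common`, `mean_cov_uncommon`.
#' @export
cohort_summary <- function(reports) {
  stopifnot(nrow(reports) >= 1)
  out <- do.call(rbind, lapply(split(reports, reports$category), function(d) {
    data.frame(category = d$category[1], n_samples = nrow(d),
               mean_pct_common = mean(d$pct_common),
               mean_cov_uncommon = mean(d$mean_cov_uncommon, na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
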