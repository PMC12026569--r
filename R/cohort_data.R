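#' Bundled 36-family screening cohort tables
#'
#' The package ships two plain-text tables from a published 36-family
#' non-invasive prenatal screening cohort, used as worked examples for the
#' concordance statistics.
#'
#' `cohort_samples()` returns per-sample clinical summaries: gestational
#' age (`ga_weeks` completed weeks plus `ga_days` extra days), fetal
#' fraction in percent (`ff_pct`), the panel result type (`WT`, `SNV`,
#' `DEL`, `DUP`) with its ACMG classification tokens (`P`, `LP`, `VUS`,
#' combinations separated by `;` for multi-variant samples), and affected
#' genes where applicable.
#'
#' `cohort_concordance()` returns the plasma-vs-child callset comparison,
#' one row per sample and inheritance category (`father_inherited`,
#' `de_novo`): truth-side `total`, `common` and `uncommon` variant counts,
#' the published integer `pct_common`, and the mean plasma coverage of the
#' uncommon (missed) variants. The source study printed identical
#' comparison tables for its two child-side callers, so one table serves
#' both.
#'
#' @return A data.frame.
#' @export
cohort_samples <- function() {
  read_tsv(system.file("extdata", "cohort_samples.tsv", package = "cftrio"))
}

#' @rdname cohort_samples
#' @export
cohort_concordance <- function() {
  read_tsv(system.file("extdata", "cohort_concordance.tsv",
                       package = "cftrio"))
}

#' Gestational age in decimal weeks
#'
#' @param weeks Completed weeks.
#' @param days Extra days (0-6).
#' @return `weeks + days / 7`.
#' @export
gestational_weeks <- function(weeks, days) {
  stopifnot(all(days >= 0 & days <= 6))
  weeks + days / 7
}

#' Summarize the screening cohort table
#'
#' Computes the cohort-level quantities used in the worked examples: the
#' number of samples whose panel result includes at least one pathogenic or
#' likely-pathogenic SNV (ACMG token starting with `P` or `LP`; VUS-only
#' and CNV-only samples excluded), the numbers of deletion and duplication
#' calls, the fetal-fraction range, and the mean gestational age in
#' decimal weeks.
#'
#' @param samples Data.frame from [cohort_samples()] (or a compatible one).
#' @return List with `n_samples`, `n_plp_snv_samples`, `n_deletions`,
#'   `n_duplications`, `ff_min`, `ff_max`, `mean_ga_weeks`.
#' @export
summarize_cohort <- function(samples = cohort_samples()) {
  acmg_tokens <- strsplit(as.character(samples$acmg), ";", fixed = TRUE)
  has_plp <- vapply(acmg_tokens, function(tok)
    any(grepl("^(P|LP)", tok)), logical(1))
  plp_snv <- samples$result_type == "SNV" & has_plp
  list(n_samples = nrow(samples),
       n_plp_snv_samples = sum(plp_snv),
       n_deletions = sum(samples$result_type == "DEL"),
       n_duplications = sum(samples$result_type == "DUP"),
       ff_min = min(samples$ff_pct),
       ff_max = max(samples$ff_pct),
       mean_ga_weeks = mean(gestational_weeks(samples$ga_weeks,
                                              samples$ga_days)))
}

#' Correlates of plasma/child overlap across the cohort
#'
#' Joins the concordance table with per-sample fetal fractions and computes
#' squared Pearson correlations of the overlap percentage against the mean
#' coverage of missed variants and against the fetal fraction, both pooled
#' over the two inheritance categories and within each category.
#'
#' @param concordance Data.frame from [cohort_concordance()].
#' @param samples Data.frame from [cohort_samples()].
#' @return Data.frame with columns `pooling`, `predictor`, `r2`, `n`.
#' @export
overlap_correlations <- function(concordance = cohort_concordance(),
                                 samples = cohort_samples()) {
  m <- merge(concordance, samples[, c("sample_id", "ff_pct")],
             by = "sample_id")
  one <- function(d, pooling) {
    rbind(data.frame(pooling = pooling, predictor = "coverage",
                     r2 = pearson_r2(d$mean_cov_uncommon, d$pct_common)$r2,
                     n = nrow(d), stringsAsFactors = FALSE),
          data.frame(pooling = pooling, predictor = "fetal_fraction",
                     r2 = pearson_r2(d$ff_pct, d$pct_common)$r2,
                     n = nrow(d), stringsAsFactors = FALSE))
  }
  out <- one(m, "pooled")
  for (cc in unique(m$category)) out <- rbind(out, one(m[m$category == cc, ], cc))
  rownames(out) <- NULL
  out
}
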