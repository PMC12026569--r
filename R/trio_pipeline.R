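#' Artifact-filter configuration for child/fetal gDNA callsets
#'
#' Defaults follow the screening pipeline's artifact filters: variants with
#' allele fraction at or below 20% or above 80% are excluded (both tails
#' are artifact-enriched), variants in blacklisted regions of anomalous
#' mappability are excluded, and variants below 100x depth are excluded.
#' The upper allele-fraction cut also removes true homozygous variants when
#' read literally; set `exempt_hom_alt = TRUE` to keep variants whose
#' proband genotype is homozygous alt despite a high allele fraction.
#'
#' @param af_low,af_high Allele-fraction band: keep `af_low < AF <= af_high`.
#' @param min_depth Minimum read depth kept (default 100).
#' @param blacklist A `GRanges` of excluded regions (e.g. from
#'   [read_bed()]), or `NULL` for none.
#' @param exempt_hom_alt Keep homozygous-alt proband calls above `af_high`
#'   (default `FALSE`, the literal rule).
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(af_low = 0.20, af_high = 0.80, min_depth = 100L,
                          blacklist = NULL, exempt_hom_alt = FALSE) {
  stopifnot(af_low >= 0, af_low < af_high, af_high <= 1, min_depth >= 0)
  structure(list(af_low = af_low, af_high = af_high,
                 min_depth = as.integer(min_depth), blacklist = blacklist,
                 exempt_hom_alt = isTRUE(exempt_hom_alt)),
            class = "filter_config")
}

# split a variant table into kept rows and an exclusion log
split_kept <- function(variants, keep, reason) {
  excluded <- variants[!keep, , drop = FALSE]
  if (nrow(excluded) > 0) excluded$reason <- reason
  else excluded$reason <- character(0)
  list(kept = variants[keep, , drop = FALSE], excluded = excluded)
}

#' Allele-fraction band filter
#'
#' Keeps variants with `af_low < allele_fraction <= af_high`: an allele
#' fraction at or below the lower bound, or above the upper bound, is
#' excluded as artifact-enriched. Variants missing the allele fraction are
#' routed to the exclusion log with reason `missing-field`.
#'
#' @param variants Data.frame with an `allele_fraction` column (and
#'   `proband` genotypes if `exempt_hom_alt` is set).
#' @param config A [filter_config()].
#' @return List with `kept` (surviving variants) and `excluded` (removed
#'   variants with a `reason` column).
#' @export
allele_fraction_filter <- function(variants, config = filter_config()) {
  af <- variants$allele_fraction
  missing <- is.na(af)
  keep <- !missing & af > config$af_low & af <= config$af_high
  if (config$exempt_hom_alt && !is.null(variants$proband))
    keep <- keep | (!missing & af > config$af_high &
                      !is.na(variants$proband) & variants$proband == 2L)
  reason <- ifelse(missing, "missing-field", "allele-fraction")
  excluded <- variants[!keep, , drop = FALSE]
  excluded$reason <- reason[!keep]
  list(kept = variants[keep, , drop = FALSE], excluded = excluded)
}

#' Blacklist region filter
#'
#' Removes variants whose 1-based position falls inside any blacklist
#' interval. Blacklists are BED-derived (0-based half-open), so BED
#' interval `[100, 200)` covers 1-based positions 101..200. The filter is
#' idempotent.
#'
#' @param variants Data.frame with `chrom` and `pos` (1-based) columns.
#' @param blacklist A `GRanges` interval set, or `NULL`/empty for identity.
#' @return List with `kept` and `excluded` (reason `blacklist`).
#' @export
blacklist_filter <- function(variants, blacklist = NULL) {
  if (is.null(blacklist) || length(blacklist) == 0)
    return(split_kept(variants, rep(TRUE, nrow(variants)), "blacklist"))
  hit <- positions_in_intervals(variants$chrom, variants$pos, blacklist)
  split_kept(variants, !hit, "blacklist")
}

#' Read-depth filter
#'
#' Keeps variants with `depth >= min_depth`.
#'
#' @param variants Data.frame with a `depth` column.
#' @param config A [filter_config()].
#' @return List with `kept` and `excluded` (reason `depth`).
#' @export
depth_filter <- function(variants, config = filter_config()) {
  keep <- !is.na(variants$depth) & variants$depth >= config$min_depth
  split_kept(variants, keep, "depth")
}

#' Classify trio variants by inheritance
#'
#' For a proband variant (alt copies >= 1): absent from the maternal genome
#' and present in the father it is `paternal_inherited`; absent from both
#' parents it is `de_novo`; present in the mother it is
#' `maternal_or_shared`. A proband genotype of 0, or any required parental
#' genotype unknown, yields `unclassifiable`. Labels are mutually exclusive
#' and exhaustive.
#'
#' @param variants Data.frame with `proband`, `mother`, `father` alt-copy
#'   columns (0/1/2 or `NA`).
#' @return Factor of labels, one per variant.
#' @export
classify_trio <- function(variants) {
  pro <- variants$proband; mom <- variants$mother; dad <- variants$father
  if (is.null(pro) || all(is.na(pro)))
    stop("missing-proband: proband genotypes are required")
  lab <- rep("unclassifiable", nrow(variants))
  carrier <- !is.na(pro) & pro >= 1L
  lab[carrier & !is.na(mom) & mom >= 1L] <- "maternal_or_shared"
  lab[carrier & !is.na(mom) & mom == 0L & !is.na(dad) & dad >= 1L] <-
    "paternal_inherited"
  lab[carrier & !is.na(mom) & mom == 0L & !is.na(dad) & dad == 0L] <- "de_novo"
  factor(lab, levels = c("paternal_inherited", "de_novo",
                         "maternal_or_shared", "unclassifiable"))
}

#' @rdname classify_trio
#' @param proband,mother,father Single alt-copy genotypes for one variant.
#' @export
classify_trio_variant <- function(proband, mother, father) {
  if (is.na(proband)) stop("missing-proband: proband genotype unknown")
  as.character(classify_trio(data.frame(proband = proband, mother = mother,
                                        father = father)))
}

#' Run the full artifact-filter and trio-classification pipeline
#'
#' Applies the allele-fraction band filter, the blacklist filter and the
#' depth filter in that order, then classifies the survivors by trio
#' inheritance. Because the three filters are pure row predicates they
#' commute as set operations; the fixed order only determines which rule
#' each removed variant is attributed to in the provenance report
#' (first-rule attribution).
#'
#' @param variants Data.frame with `chrom`, `pos`, `ref`, `alt`,
#'   `allele_fraction`, `depth` and trio genotype columns `proband`,
#'   `mother`, `father`.
#' @param config A [filter_config()].
#' @return List of class `trio_pipeline_result` with `variants` (survivors,
#'   with a `trio_class` column), `exclusions` (removed variants with
#'   reasons) and `report` (per-stage removal counts, stage order recorded).
#' @export
run_artifact_pipeline <- function(variants, config = filter_config()) {
  s1 <- allele_fraction_filter(variants, config)
  s2 <- blacklist_filter(s1$kept, config$blacklist)
  s3 <- depth_filter(s2$kept, config)
  kept <- s3$kept
  if (nrow(kept) > 0) kept$trio_class <- classify_trio(kept)
  else kept$trio_class <- factor(character(0),
                                 levels = levels(classify_trio(
                                   data.frame(proband = 1L, mother = 0L,
                                              father = 0L))))
  exclusions <- rbind(s1$excluded, s2$excluded, s3$excluded)
  report <- data.frame(stage = c("allele_fraction", "blacklist", "depth"),
                       removed = c(nrow(s1$excluded), nrow(s2$excluded),
                                   nrow(s3$excluded)),
                       stringsAsFactors = FALSE)
  structure(list(variants = kept, exclusions = exclusions, report = report,
                 config = config),
            class = "trio_pipeline_result")
}
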