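#' Construct a cfDNA fragment table
#'
#' Fragments are alignment intervals in the 0-based half-open convention;
#' `length` is `end - start` in bp. `site_pos` / `allele` optionally record
#' the 1-based position of a tagging SNP the fragment covers and the allele
#' the fragment carries there.
#'
#' @param chrom Chromosome names.
#' @param start,end 0-based half-open interval.
#' @param site_pos 1-based position of a covered tagging site, or `NA`.
#' @param allele Observed base at `site_pos`, or `NA`.
#' @return A data.frame of class `fragment_records` with a `length` column.
#' @export
fragment_records <- function(chrom, start, end, site_pos = NA_integer_,
                             allele = NA_character_) {
  if (any(end <= start)) stop("invalid-parameter: end must exceed start")
  x <- data.frame(chrom = as.character(chrom), start = as.integer(start),
                  end = as.integer(end), length = as.integer(end - start),
                  site_pos = as.integer(site_pos),
                  allele = as.character(allele), stringsAsFactors = FALSE)
  class(x) <- c("fragment_records", "data.frame")
  x
}

#' Tag fragments as fetal or maternal by fetal-specific alleles
#'
#' At a site where the mother is homozygous, the allele she does not carry
#' can only come from the fetus (up to sequencing error). A fragment
#' covering such a site and carrying the maternally absent allele is tagged
#' `fetal`; one carrying the maternal-only allele is tagged `maternal`;
#' fragments covering no tagging site, or whose observed base matches
#' neither allele, stay `untagged`. Retagging is idempotent and each
#' fragment receives exactly one tag.
#'
#' @param fragments A `fragment_records` table.
#' @param tagging_sites A `snp_sites` table restricted to sites with a
#'   homozygous maternal genotype (classes `ff_informative` or
#'   `fetal_tagging` from [flag_informative_sites()]).
#' @return `fragments` with an added `allele_tag` column
#'   (`fetal` / `maternal` / `untagged`).
#' @export
tag_fragments <- function(fragments, tagging_sites) {
  tag <- rep("untagged", nrow(fragments))
  has_site <- !is.na(fragments$site_pos) & !is.na(fragments$allele)
  if (any(has_site)) {
    key <- paste(tagging_sites$chrom, tagging_sites$pos)
    idx <- match(paste(fragments$chrom, fragments$site_pos)[has_site], key)
    hit <- which(has_site)[!is.na(idx)]
    sidx <- idx[!is.na(idx)]
    # fragment must actually overlap the 1-based site it claims
    covered <- fragments$start[hit] < tagging_sites$pos[sidx] &
      tagging_sites$pos[sidx] <= fragments$end[hit]
    if (any(!covered))
      stop("inconsistent-input: fragment does not overlap its claimed site")
    m <- tagging_sites$maternal_copies[sidx]
    ref <- tagging_sites$ref[sidx]
    alt <- tagging_sites$alt[sidx]
    obs <- fragments$allele[hit]
    fetal_allele <- ifelse(m == 0L, alt, ifelse(m == 2L, ref, NA))
    maternal_allele <- ifelse(m == 0L, ref, ifelse(m == 2L, alt, NA))
    tag[hit[!is.na(fetal_allele) & obs == fetal_allele]] <- "fetal"
    tag[hit[!is.na(maternal_allele) & obs == maternal_allele]] <- "maternal"
  }
  out <- as.data.frame(fragments)
  out$allele_tag <- factor(tag, levels = c("fetal", "maternal", "untagged"))
  class(out) <- c("fragment_records", "data.frame")
  out
}

#' Fit a fragment-size distribution as a normalized histogram
#'
#' Fixed global bin edges (default 50-400 bp in 5 bp bins) keep
#' distributions comparable across samples; lengths outside the range are
#' clamped into the first/last bin. Densities are per-bin probabilities
#' summing to 1.
#'
#' @param lengths Integer fragment lengths in bp (at least one).
#' @param bin_width Bin width in bp (default 5).
#' @param range Two-element vector of the global edge range (default
#'   `c(50, 400)`).
#' @return An object of class `size_distribution`: list with `bin_edges`,
#'   `densities` and `n_fragments`.
#' @export
fit_size_distribution <- function(lengths, bin_width = 5, range = c(50, 400)) {
  if (length(lengths) == 0) stop("insufficient-data: no fragment lengths")
  stopifnot(bin_width >= 1, length(range) == 2, range[2] > range[1])
  edges <- seq(range[1], range[2], by = bin_width)
  if (edges[length(edges)] < range[2]) edges <- c(edges, range[2])
  clamped <- pmin(pmax(lengths, edges[1]), edges[length(edges)])
  counts <- tabulate(findInterval(clamped, edges, rightmost.closed = TRUE),
                     nbins = length(edges) - 1)
  structure(list(bin_edges = edges, densities = counts / sum(counts),
                 n_fragments = length(lengths)),
            class = "size_distribution")
}

#' Mean fragment length implied by a size distribution
#'
#' Density-weighted mean of bin midpoints.
#'
#' @param dist A `size_distribution`.
#' @return Mean length in bp.
#' @export
size_distribution_mean <- function(dist) {
  mids <- (dist$bin_edges[-1] + dist$bin_edges[-length(dist$bin_edges)]) / 2
  sum(mids * dist$densities)
}

# density of the bin containing each length (0 outside the edge range)
density_at_length <- function(dist, length) {
  idx <- findInterval(length, dist$bin_edges, rightmost.closed = TRUE)
  d <- rep(0, base::length(length))
  ok <- idx >= 1 & idx <= base::length(dist$densities)
  d[ok] <- dist$densities[idx[ok]]
  d
}

#' Posterior probability that a fragment is fetal given its length
#'
#' Bayes mixture of the fetal and maternal size distributions with prior
#' weight `f` on the fetal component:
#' `f * d_fetal(len) / (f * d_fetal(len) + (1 - f) * d_maternal(len))`.
#' Where both densities are zero the length carries no information and the
#' prior `f` is returned.
#'
#' @param length Fragment length(s) in bp.
#' @param fetal_dist,maternal_dist `size_distribution` objects.
#' @param f Fetal fraction in `[0, 1]`.
#' @return Probability vector in `[0, 1]`.
#' @export
fetal_probability_by_size <- function(length, fetal_dist, maternal_dist, f) {
  stopifnot(f >= 0, f <= 1)
  df <- density_at_length(fetal_dist, length)
  dm <- density_at_length(maternal_dist, length)
  num <- f * df
  den <- num + (1 - f) * dm
  out <- ifelse(den > 0, num / den, f)
  pmin(pmax(out, 0), 1)
}
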