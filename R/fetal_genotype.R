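#' Construct a table of plasma SNP sites
#'
#' A SNP-site table holds, per biallelic site, the plasma alt-allele read
#' count and total depth together with the parental genotypes (alt-allele
#' copy numbers, `NA` when unknown). It is the input to fetal-fraction
#' estimation and fetal genotype calling.
#'
#' @param chrom Chromosome names.
#' @param pos 1-based positions.
#' @param ref,alt Single-nucleotide alleles.
#' @param alt_count,depth Plasma alt-allele read count and total read depth.
#' @param maternal_copies,paternal_copies Parental alt copy numbers in
#'   \{0, 1, 2\} or `NA`.
#' @return A validated data.frame of class `snp_sites`.
#' @export
snp_sites <- function(chrom, pos, ref, alt, alt_count, depth,
                      maternal_copies = NA_integer_,
                      paternal_copies = NA_integer_) {
  x <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                  ref = as.character(ref), alt = as.character(alt),
                  alt_count = as.integer(alt_count), depth = as.integer(depth),
                  maternal_copies = as.integer(maternal_copies),
                  paternal_copies = as.integer(paternal_copies),
                  stringsAsFactors = FALSE)
  if (any(x$pos < 1)) stop("invalid-parameter: pos must be >= 1")
  if (any(x$ref == x$alt)) stop("invalid-parameter: ref and alt must differ")
  if (any(x$alt_count < 0 | x$depth < 0)) stop("invalid-parameter: negative counts")
  if (any(x$alt_count > x$depth)) stop("invalid-parameter: alt_count exceeds depth")
  ok <- function(g) all(is.na(g) | g %in% 0:2)
  if (!ok(x$maternal_copies) || !ok(x$paternal_copies))
    stop("invalid-parameter: genotypes must be 0, 1, 2 or NA")
  class(x) <- c("snp_sites", "data.frame")
  x
}

#' Expected plasma alt-allele fraction under the binomial mixture
#'
#' Plasma cfDNA is a mixture of maternal DNA (weight `1 - f`) and fetal DNA
#' (weight `f`). With maternal alt copy number `m` and fetal alt copy number
#' `k`, the expected alt-read fraction is the linear mixture
#' `p = (1 - f) * m/2 + f * k/2`, adjusted for a symmetric per-read miscall
#' probability `epsilon`: `p' = p * (1 - epsilon) + (1 - p) * epsilon`.
#'
#' For fixed `m` and `f > 0` (and `epsilon < 0.5`) the result is strictly
#' increasing in `k`, which is what makes the fetal genotype identifiable.
#'
#' @param m Maternal alt copies (0, 1 or 2); vectorized.
#' @param k Fetal alt copies (0, 1 or 2); vectorized.
#' @param f Fetal fraction in `[0, 1]`.
#' @param error_rate Per-read miscall probability in `[0, 0.5)`.
#' @return Expected alt-read fraction(s) in `[0, 1]`.
#' @export
expected_alt_fraction <- function(m, k, f, error_rate = 0) {
  if (any(!m %in% 0:2) || any(!k %in% 0:2))
    stop("invalid-parameter: m and k must be in {0, 1, 2}")
  if (any(f < 0 | f > 1)) stop("invalid-parameter: f must be in [0, 1]")
  if (any(error_rate < 0 | error_rate >= 0.5))
    stop("invalid-parameter: error_rate must be in [0, 0.5)")
  p <- (1 - f) * m / 2 + f * k / 2
  p * (1 - error_rate) + (1 - p) * error_rate
}

#' Binomial log-likelihood of plasma counts under a fetal genotype
#'
#' Log of `Binomial(alt_count | depth, p')` where `p'` is
#' [expected_alt_fraction()] at the site's maternal genotype, the candidate
#' fetal genotype `k`, the fetal fraction and the read-error rate.
#'
#' @param alt_count,depth Observed alt count and total depth (vectorized).
#' @param m Maternal alt copies; `NA` signals missing data.
#' @param k Candidate fetal alt copies.
#' @inheritParams expected_alt_fraction
#' @return Log-likelihood(s).
#' @export
genotype_log_likelihood <- function(alt_count, depth, m, k, f, error_rate = 0) {
  if (any(is.na(m))) stop("missing-data: maternal genotype unknown")
  if (any(depth < 1)) stop("empty-observation: depth must be >= 1")
  p <- expected_alt_fraction(m, k, f, error_rate)
  stats::dbinom(alt_count, depth, p, log = TRUE)
}

#' Call fetal genotypes from plasma allele counts
#'
#' Posterior over fetal alt copy number `k` in \{0, 1, 2\} at each site:
#' `posterior(k) \propto prior(k) * L(k)` with the binomial likelihood of
#' [genotype_log_likelihood()]. Normalization is done in log space with
#' max-subtraction so deep sites (depth up to 1e5) do not underflow. The
#' maximum-likelihood call `ml_call` is the argmax of the posterior, ties
#' broken to the smallest `k`. At `f = 0` the likelihood is identical for
#' all `k` and the posterior equals the prior.
#'
#' @param sites A `snp_sites` table (maternal genotypes must be known).
#' @param f Fetal fraction in `[0, 1]`.
#' @param prior Length-3 prior over `k = 0, 1, 2`; must sum to 1.
#' @param error_rate Per-read miscall probability.
#' @return The site table with added columns `ll_k0..ll_k2` (log-likelihoods),
#'   `post_k0..post_k2` (posterior probabilities, summing to 1) and `ml_call`.
#' @export
call_fetal_genotype <- function(sites, f, prior = rep(1 / 3, 3),
                                error_rate = 0.01) {
  stopifnot(length(prior) == 3)
  if (abs(sum(prior) - 1) > 1e-6) stop("invalid-parameter: prior must sum to 1")
  ll <- sapply(0:2, function(k) {
    genotype_log_likelihood(sites$alt_count, sites$depth,
                            sites$maternal_copies, k, f, error_rate)
  })
  if (is.null(dim(ll))) ll <- matrix(ll, nrow = 1)
  lp <- sweep(ll, 2, log(prior), `+`)
  mx <- apply(lp, 1, max)
  w <- exp(lp - mx)
  post <- w / rowSums(w)
  out <- as.data.frame(sites)
  out$ll_k0 <- ll[, 1]; out$ll_k1 <- ll[, 2]; out$ll_k2 <- ll[, 3]
  out$post_k0 <- post[, 1]; out$post_k1 <- post[, 2]; out$post_k2 <- post[, 3]
  out$ml_call <- max.col(post, ties.method = "first") - 1L
  class(out) <- c("genotype_calls", "data.frame")
  out
}

#' Mendelian prior over fetal genotypes from parental genotypes
#'
#' Transmission probabilities for the fetal alt copy number given both
#' parental genotypes, each parent passing one of its two alleles uniformly.
#'
#' @param m,p Maternal and paternal alt copy numbers in \{0, 1, 2\}.
#' @return Length-3 probability vector over `k = 0, 1, 2`.
#' @export
mendelian_prior <- function(m, p) {
  stopifnot(m %in% 0:2, p %in% 0:2)
  tx <- function(g) c(1 - g / 2, g / 2)  # P(transmit ref), P(transmit alt)
  pm <- tx(m); pp <- tx(p)
  c(pm[1] * pp[1], pm[1] * pp[2] + pm[2] * pp[1], pm[2] * pp[2])
}

#' Partition SNP sites by informativeness for fetal analysis
#'
#' Sites where the mother is homozygous reference and the father carries the
#' alt allele are fetal-fraction-informative: any alt reads (up to error) are
#' fetal, and their fraction estimates `f / 2`. Sites where one allele is
#' absent from the maternal genotype (mother homozygous for either allele)
#' but that do not qualify above are fetal-allele-tagging: reads carrying
#' the maternally absent allele can only be fetal. Everything else —
#' maternal heterozygous or unknown maternal genotype — is uninformative.
#' The three classes are exhaustive and disjoint.
#'
#' @param sites A `snp_sites` table.
#' @return The table with an added factor column `site_class` with levels
#'   `ff_informative`, `fetal_tagging`, `uninformative`.
#' @export
flag_informative_sites <- function(sites) {
  m <- sites$maternal_copies
  p <- sites$paternal_copies
  cls <- rep("uninformative", nrow(sites))
  hom_mother <- !is.na(m) & m %in% c(0L, 2L)
  cls[hom_mother] <- "fetal_tagging"
  cls[!is.na(m) & m == 0L & !is.na(p) & p >= 1L] <- "ff_informative"
  out <- as.data.frame(sites)
  out$site_class <- factor(cls, levels = c("ff_informative", "fetal_tagging",
                                           "uninformative"))
  out
}

#' Estimate the fetal fraction from informative SNP sites
#'
#' At sites where the mother is homozygous reference and the father is
#' homozygous alt, the fetus is an obligate heterozygote, alt reads are
#' fetal in origin, and the expected plasma alt fraction is `f/2`; the
#' estimator `f_hat = 2 * mean(alt_count / depth)` over those sites is
#' therefore unbiased. With `min_paternal_copies = 1`, heterozygous-father
#' sites are also used: the fetus then inherits the alt allele only with
#' probability `p/2` for paternal copy number `p`, so the expected alt
#' fraction at site `i` is `f * p_i / 4` and the estimator generalizes to
#' `f_hat = 4 * mean(alt fraction) / mean(p)` (which reduces to `2 * mean`
#' when every father is homozygous alt). When a per-read miscall rate is
#' supplied, the observed mean alt fraction `p'` is first inverted through
#' the error model `p' = p (1 - 2 epsilon) + epsilon`; without this, errors
#' inflate the estimate by about `2 epsilon`. The standard error follows by
#' the delta method from the spread of per-site alt fractions. The estimate
#' is clamped to `[0, 1]`.
#'
#' @param sites A `snp_sites` table.
#' @param min_paternal_copies Minimum paternal alt copy number for a site to
#'   enter the estimate. The default `2` restricts to obligate-heterozygote
#'   sites; `1` adds heterozygous fathers with the transmission correction.
#' @param error_rate Per-read miscall probability in `[0, 0.5)` used to
#'   de-bias the estimate (default 0).
#' @return An object of class `fetal_fraction`: a list with elements `f`,
#'   `n_informative_sites` and `stderr`.
#' @export
estimate_fetal_fraction <- function(sites, min_paternal_copies = 2L,
                                    error_rate = 0) {
  stopifnot(min_paternal_copies %in% 1:2, error_rate >= 0, error_rate < 0.5)
  info <- !is.na(sites$maternal_copies) & sites$maternal_copies == 0L &
    !is.na(sites$paternal_copies) &
    sites$paternal_copies >= min_paternal_copies & sites$depth > 0
  if (!any(info)) stop("insufficient-data: no informative sites")
  af <- sites$alt_count[info] / sites$depth[info]
  pbar <- mean(sites$paternal_copies[info])
  scale <- 4 / pbar  # = 2 when all fathers are homozygous alt
  debias <- (mean(af) - error_rate) / (1 - 2 * error_rate)
  f <- min(max(scale * debias, 0), 1)
  n <- sum(info)
  se <- if (n > 1) scale * stats::sd(af) / ((1 - 2 * error_rate) * sqrt(n))
        else NA_real_
  structure(list(f = f, n_informative_sites = n, stderr = se),
            class = "fetal_fraction")
}

#' @export
print.fetal_fraction <- function(x, ...) {
  cat(sprintf("Fetal fraction estimate: %.4f (n = %d informative sites, se = %s)\n",
              x$f, x$n_informative_sites,
              if (is.na(x$stderr)) "NA" else sprintf("%.4f", x$stderr)))
  invisible(x)
}
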