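# Independent brute-force oracles. These deliberately avoid the package's
# code paths (no dbinom, no expected_alt_fraction) so they can act as
# cross-checks of the model arithmetic.

# binomial log pmf from first principles
oracle_binom_logpmf <- function(k, n, p) {
  lchoose(n, k) +
    ifelse(k == 0, 0, k * log(p)) +
    ifelse(n - k == 0, 0, (n - k) * log(1 - p))
}

# posterior over fetal alt copies by direct enumeration (safe for depth <= ~500)
oracle_posterior <- function(alt, depth, m, f, eps, prior = rep(1 / 3, 3)) {
  w <- vapply(0:2, function(k) {
    p <- (1 - f) * m / 2 + f * k / 2
    p <- p * (1 - eps) + (1 - p) * eps
    prior[k + 1] * exp(oracle_binom_logpmf(alt, depth, p))
  }, numeric(1))
  w / sum(w)
}

# textbook Pearson correlation, written out
oracle_pearson_r2 <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  num <- sum((x - mx) * (y - my))
  (num / sqrt(sum((x - mx)^2) * sum((y - my)^2)))^2
}

# small trio variant table builder with sensible defaults
make_variants <- function(n = 0, chrom = "chr1", pos = seq_len(n) * 100L,
                          af = rep(0.5, n), depth = rep(200L, n),
                          proband = rep(1L, n), mother = rep(0L, n),
                          father = rep(1L, n)) {
  data.frame(chrom = rep_len(chrom, n), pos = pos,
             ref = rep("A", n), alt = rep("G", n),
             allele_fraction = af, depth = depth,
             proband = proband, mother = mother, father = father,
             stringsAsFactors = FALSE)
}
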