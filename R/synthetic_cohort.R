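#' Configuration for the synthetic trio-cohort simulator
#'
#' The generator emulates the statistical structure the analysis modules
#' assume: Hardy-Weinberg parental genotypes with Mendelian transmission,
#' binomial plasma allele counts at fetal fraction `f`, distinct fetal and
#' maternal fragment-length distributions (fetal mode 143 bp vs maternal
#' 166 bp, sd 20 — conventional cfDNA values), Poisson bin depths with
#' fetal CNV events scaling the fetal share, and presumed-diploid control
#' samples for reference construction. Defaults (2000 SNP sites, depth
#' 200, 50 bins of 100 kb) keep a full cohort simulation in the seconds
#' range; the default `f = 0.10` sits mid-range of the 5-20% fetal
#' fractions observed in screening cohorts.
#'
#' @param n_sites Number of biallelic SNP sites.
#' @param f True fetal fraction in `[0, 1]`.
#' @param mean_depth Mean plasma depth per site (Poisson).
#' @param error_rate Per-read miscall probability.
#' @param alt_freq_range Population alt-allele frequencies are drawn
#'   uniformly from this range.
#' @param de_novo_rate Per-site probability of injecting a de novo alt
#'   allele into the child (fixture convenience, not a biological rate).
#' @param fragment_params List with `fetal_mode`, `maternal_mode`, `sd`
#'   (bp) of the Gaussian fragment-length distributions.
#' @param n_bins,bin_size Number and width (bp) of targeted bins.
#' @param fragments_per_bin Expected diploid fragment count per bin. The
#'   default 2500 gives a Poisson log2-ratio noise of about 0.03,
#'   representative of a deeply sequenced targeted panel.
#' @param n_controls Number of presumed-diploid control samples.
#' @param short_threshold Fragment length (bp) below which a fragment
#'   counts as short.
#' @param tag_site_prob Probability that a simulated fragment covers a
#'   fetal-allele-tagging site and reports an allele there.
#' @param cnv_events `NULL` or a data.frame with `chrom`, `start`, `end`
#'   (0-based half-open) and `state` (`fetal_del` / `fetal_dup`); events
#'   must not overlap.
#' @param chrom Chromosome name used for all simulated coordinates.
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_sites = 2000L, f = 0.10, mean_depth = 200,
                       error_rate = 0.01, alt_freq_range = c(0.05, 0.95),
                       de_novo_rate = 1e-3,
                       fragment_params = list(fetal_mode = 143,
                                              maternal_mode = 166, sd = 20),
                       n_bins = 50L, bin_size = 100000L,
                       fragments_per_bin = 2500, n_controls = 20L,
                       short_threshold = 150, tag_site_prob = 0.1,
                       cnv_events = NULL, chrom = "chr1", seed = 1L) {
  stopifnot(n_sites >= 1, f >= 0, f <= 1, mean_depth > 0,
            error_rate >= 0, error_rate < 0.5,
            de_novo_rate >= 0, de_novo_rate <= 1,
            n_bins >= 1, bin_size >= 1, fragments_per_bin > 0,
            n_controls >= 2)
  if (!is.null(cnv_events)) {
    stopifnot(all(c("chrom", "start", "end", "state") %in% names(cnv_events)),
              all(cnv_events$state %in% c("fetal_del", "fetal_dup")),
              all(cnv_events$end > cnv_events$start))
    ev <- cnv_events[order(cnv_events$chrom, cnv_events$start), ]
    same <- ev$chrom[-1] == ev$chrom[-nrow(ev)]
    if (nrow(ev) > 1 && any(same & ev$start[-1] < ev$end[-nrow(ev)]))
      stop("invalid-parameter: cnv events overlap")
  }
  structure(list(n_sites = as.integer(n_sites), f = f,
                 mean_depth = mean_depth, error_rate = error_rate,
                 alt_freq_range = alt_freq_range,
                 de_novo_rate = de_novo_rate,
                 fragment_params = fragment_params,
                 n_bins = as.integer(n_bins), bin_size = as.integer(bin_size),
                 fragments_per_bin = fragments_per_bin,
                 n_controls = as.integer(n_controls),
                 short_threshold = short_threshold,
                 tag_site_prob = tag_site_prob,
                 cnv_events = cnv_events, chrom = chrom,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate trio genotypes under Hardy-Weinberg and Mendelian transmission
#'
#' Each site draws a population alt frequency, parents draw genotypes from
#' Hardy-Weinberg at that frequency, and the child receives one uniformly
#' chosen allele from each parent. De novo alt alleles are injected at
#' `de_novo_rate` and flagged.
#'
#' @param config A [sim_config()].
#' @return Data.frame with `chrom`, `pos`, `ref`, `alt`, `alt_freq`,
#'   `mother`, `father`, `child`, `de_novo`.
#' @export
simulate_trio_genotypes <- function(config) {
  set.seed(config$seed)
  n <- config$n_sites
  span <- config$n_bins * config$bin_size
  pos <- sort(sample.int(span, n, replace = FALSE))
  q <- stats::runif(n, config$alt_freq_range[1], config$alt_freq_range[2])
  mother <- stats::rbinom(n, 2, q)
  father <- stats::rbinom(n, 2, q)
  child <- stats::rbinom(n, 1, mother / 2) + stats::rbinom(n, 1, father / 2)
  dn <- stats::runif(n) < config$de_novo_rate & child < 2
  child[dn] <- child[dn] + 1L
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  data.frame(chrom = config$chrom, pos = pos, ref = ref, alt = unname(alt),
             alt_freq = q, mother = mother, father = father, child = child,
             de_novo = dn, stringsAsFactors = FALSE)
}

#' Simulate plasma allele counts from trio genotypes
#'
#' The generative twin of the inference model: per-site depth is Poisson
#' at `mean_depth` and the alt count is binomial at
#' [expected_alt_fraction()] of the maternal genotype, the child (fetal)
#' genotype, `f` and the error rate.
#'
#' @param genotypes Output of [simulate_trio_genotypes()].
#' @param config A [sim_config()].
#' @return A [snp_sites()] table.
#' @export
simulate_plasma_counts <- function(genotypes, config) {
  set.seed(config$seed + 1L)
  n <- nrow(genotypes)
  depth <- stats::rpois(n, config$mean_depth)
  p <- expected_alt_fraction(genotypes$mother, genotypes$child, config$f,
                             config$error_rate)
  alt_count <- stats::rbinom(n, depth, p)
  snp_sites(chrom = genotypes$chrom, pos = genotypes$pos,
            ref = genotypes$ref, alt = genotypes$alt,
            alt_count = alt_count, depth = depth,
            maternal_copies = genotypes$mother,
            paternal_copies = genotypes$father)
}

# fetal copy number per bin from the configured events (2 = diploid)
bin_copy_state <- function(config) {
  starts <- (seq_len(config$n_bins) - 1L) * config$bin_size
  ends <- starts + config$bin_size
  cc <- rep(2L, config$n_bins)
  ev <- config$cnv_events
  if (!is.null(ev)) {
    for (i in seq_len(nrow(ev))) {
      hit <- config$chrom == ev$chrom[i] & starts < ev$end[i] & ends > ev$start[i]
      cc[hit] <- if (ev$state[i] == "fetal_del") 1L else 3L
    }
  }
  data.frame(chrom = config$chrom, start = starts, end = ends, fetal_copies = cc)
}

#' Simulate cfDNA fragments, target-bin counts and control samples
#'
#' Fragment counts per bin are Poisson with mean
#' `fragments_per_bin * ((1 - f) + f * c/2)` for fetal copy number `c`, so
#' a fetal deletion depresses depth by `f/2` and a duplication raises it
#' by `f/2`. Each fragment is fetal with probability
#' `f * (c/2) / ((1 - f) + f * c/2)` and draws its length from the
#' origin-specific Gaussian. A `tag_site_prob` share of fragments report
#' an allele at a randomly assigned maternal-homozygous tagging site:
#' fetal-origin fragments carry the fetal-specific allele with probability
#' 1/2 (the fetus is heterozygous there), maternal fragments carry the
#' maternal allele, both subject to the read-error rate. Control samples
#' are diploid Poisson draws with matching short-fragment statistics.
#'
#' @param genotypes Output of [simulate_trio_genotypes()] (supplies
#'   tagging sites); may be `NULL` to skip allele tagging.
#' @param config A [sim_config()].
#' @return List with `fragments` (a [fragment_records()] table with an
#'   `origin` column), `bins` (`chrom`, `start`, `end`, `count`,
#'   `short_fraction`, `fetal_copies`), `control_counts` and
#'   `control_short` matrices.
#' @export
simulate_fragments_and_bins <- function(genotypes, config) {
  set.seed(config$seed + 2L)
  fp <- config$fragment_params
  bins <- bin_copy_state(config)
  ratio <- (1 - config$f) + config$f * bins$fetal_copies / 2
  counts <- stats::rpois(config$n_bins, config$fragments_per_bin * ratio)
  p_fetal <- config$f * (bins$fetal_copies / 2) / ratio
  frag <- vector("list", config$n_bins)
  short_fraction <- numeric(config$n_bins)
  tagging <- NULL
  if (!is.null(genotypes)) {
    tagging <- genotypes[genotypes$mother %in% c(0L, 2L), , drop = FALSE]
  }
  for (i in seq_len(config$n_bins)) {
    n <- counts[i]
    if (n == 0) { short_fraction[i] <- NA_real_; next }
    fetal <- stats::runif(n) < p_fetal[i]
    len <- as.integer(round(stats::rnorm(
      n, ifelse(fetal, fp$fetal_mode, fp$maternal_mode), fp$sd)))
    len <- pmin(pmax(len, 60L), 400L)
    start <- bins$start[i] + sample.int(config$bin_size, n, replace = TRUE) - 1L
    short_fraction[i] <- mean(len < config$short_threshold)
    site_pos <- rep(NA_integer_, n)
    allele <- rep(NA_character_, n)
    if (!is.null(tagging) && nrow(tagging) > 0) {
      tagged <- which(stats::runif(n) < config$tag_site_prob)
      if (length(tagged) > 0) {
        si <- sample.int(nrow(tagging), length(tagged), replace = TRUE)
        site_pos[tagged] <- tagging$pos[si]
        # place the fragment so it covers its site (0-based start in
        # [pos - length, pos - 1] leaves 1-based pos inside [start, end))
        offset <- floor(stats::runif(length(tagged)) * len[tagged])
        start[tagged] <- pmax(tagging$pos[si] - 1L - as.integer(offset), 0L)
        fetal_allele <- ifelse(tagging$mother[si] == 0L,
                               tagging$alt[si], tagging$ref[si])
        maternal_allele <- ifelse(tagging$mother[si] == 0L,
                                  tagging$ref[si], tagging$alt[si])
        carries_fetal <- ifelse(fetal[tagged],
                                stats::runif(length(tagged)) < 0.5, FALSE)
        err <- stats::runif(length(tagged)) < config$error_rate
        carries_fetal <- xor(carries_fetal, err)
        allele[tagged] <- ifelse(carries_fetal, fetal_allele, maternal_allele)
      }
    }
    fr <- data.frame(chrom = config$chrom, start = start,
                     end = start + len, length = len,
                     site_pos = site_pos, allele = allele,
                     origin = ifelse(fetal, "fetal", "maternal"),
                     stringsAsFactors = FALSE)
    frag[[i]] <- fr
  }
  fragments <- do.call(rbind, frag)
  if (!is.null(fragments)) {
    rownames(fragments) <- NULL
    class(fragments) <- c("fragment_records", "data.frame")
  }
  # diploid controls: Poisson counts and matching short-fraction mixture
  p_short_mix <- config$f *
    stats::pnorm(config$short_threshold, fp$fetal_mode, fp$sd) +
    (1 - config$f) *
    stats::pnorm(config$short_threshold, fp$maternal_mode, fp$sd)
  control_counts <- matrix(stats::rpois(config$n_bins * config$n_controls,
                                        config$fragments_per_bin),
                           nrow = config$n_bins)
  control_short <- matrix(stats::rbinom(config$n_bins * config$n_controls,
                                        as.vector(control_counts),
                                        p_short_mix) /
                            pmax(as.vector(control_counts), 1L),
                          nrow = config$n_bins)
  list(fragments = fragments,
       bins = data.frame(bins[, c("chrom", "start", "end")],
                         count = counts, short_fraction = short_fraction,
                         fetal_copies = bins$fetal_copies),
       control_counts = control_counts, control_short = control_short)
}

#' Simulate normalized bin ratios directly at a given noise level
#'
#' A lightweight generator for depth-channel-only experiments: log2 depth
#' ratios are Gaussian around the state's [expected_ratio()] with standard
#' deviation `sigma`. Returns the bins together with a matching reference
#' whose `ratio_sigma` equals the generating `sigma` (no size channel).
#'
#' @param n_bins Number of bins (100 kb each on one chromosome).
#' @param sigma Log2-ratio noise standard deviation.
#' @param f Fetal fraction used for event means.
#' @param events `NULL` or data.frame with `start_bin`, `end_bin`
#'   (1-based inclusive bin indices) and `state`.
#' @param bin_size Bin width in bp.
#' @param chrom Chromosome name.
#' @param seed Integer seed.
#' @return List with `bins` (a `target_bins` data.frame) and `reference`
#'   (a `reference_bin_set`).
#' @export
simulate_ratio_bins <- function(n_bins = 50L, sigma = 0.05, f = 0.10,
                                events = NULL, bin_size = 100000L,
                                chrom = "chr1", seed = 1L) {
  set.seed(seed)
  state <- rep("diploid", n_bins)
  if (!is.null(events)) {
    for (i in seq_len(nrow(events)))
      state[events$start_bin[i]:events$end_bin[i]] <- events$state[i]
  }
  mu <- log2(expected_ratio(state, f))
  ratio <- 2^stats::rnorm(n_bins, mu, sigma)
  starts <- (seq_len(n_bins) - 1L) * bin_size
  bins <- data.frame(chrom = chrom, start = starts, end = starts + bin_size,
                     count = NA_real_, ratio = ratio,
                     short_fraction = NA_real_, masked = FALSE,
                     gross_deviation = FALSE, stringsAsFactors = FALSE)
  class(bins) <- c("target_bins", "data.frame")
  reference <- structure(
    list(bins = data.frame(chrom = chrom, start = starts,
                           end = starts + bin_size, ref_count = 1,
                           stringsAsFactors = FALSE),
         ratio_sigma = sigma, short_mean = NULL, short_sd = NULL,
         p_short_fetal = NULL, p_short_maternal = NULL),
    class = "reference_bin_set")
  list(bins = bins, reference = reference)
}

#' Simulate a complete synthetic cohort
#'
#' Runs [simulate_trio_genotypes()], [simulate_plasma_counts()] and
#' [simulate_fragments_and_bins()] under one seed and assembles the
#' reference bin set from the simulated controls. The fetal/maternal
#' short-fragment probabilities for the reference are estimated from the
#' simulated fragments' tagged size distributions.
#'
#' @param config A [sim_config()].
#' @return List of class `simulated_cohort` with elements `config`,
#'   `genotypes`, `sites`, `fragments`, `bins`, `control_counts`,
#'   `control_short`, `reference`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  genotypes <- simulate_trio_genotypes(config)
  sites <- simulate_plasma_counts(genotypes, config)
  fb <- simulate_fragments_and_bins(genotypes, config)
  tagged <- tag_fragments(fb$fragments,
                          snp_sites(genotypes$chrom, genotypes$pos,
                                    genotypes$ref, genotypes$alt,
                                    alt_count = 0L, depth = 0L,
                                    maternal_copies = genotypes$mother,
                                    paternal_copies = genotypes$father))
  p_short <- function(tag) {
    len <- tagged$length[tagged$allele_tag == tag]
    if (length(len) < 10) return(NULL)
    mean(len < config$short_threshold)
  }
  reference <- reference_bin_set(fb$bins, fb$control_counts,
                                 control_short = fb$control_short,
                                 p_short_fetal = p_short("fetal"),
                                 p_short_maternal = p_short("maternal"))
  structure(list(config = config, genotypes = genotypes, sites = sites,
                 fragments = tagged, bins = fb$bins,
                 control_counts = fb$control_counts,
                 control_short = fb$control_short, reference = reference),
            class = "simulated_cohort")
}

#' Write a simulated cohort to disk
#'
#' Emits the trio genotypes as a three-sample VCF, the plasma sites as both
#' an allele-count TSV and a VCF, the fragments and bins as TSVs, the
#' control count matrix as a TSV, and a YAML manifest echoing the full
#' configuration (including the seed). All files are plain text and
#' re-readable by the package's readers; regenerating with the same seed
#' yields byte-identical output.
#'
#' @param cohort A `simulated_cohort`.
#' @param outdir Output directory (created if needed).
#' @return Named list of file paths, invisibly.
#' @export
emit_cohort <- function(cohort, outdir) {
  ok <- dir.exists(outdir) || dir.create(outdir, recursive = TRUE)
  if (!ok || file.access(outdir, 2) != 0)
    stop("io-error: cannot write to ", outdir)
  g <- cohort$genotypes
  paths <- list(
    trio_vcf = file.path(outdir, "trio.vcf"),
    plasma_counts = file.path(outdir, "plasma_counts.tsv"),
    plasma_vcf = file.path(outdir, "plasma.vcf"),
    fragments = file.path(outdir, "fragments.tsv"),
    bins = file.path(outdir, "bins.tsv"),
    controls = file.path(outdir, "control_counts.tsv"),
    manifest = file.path(outdir, "manifest.yaml"))
  trio <- data.frame(chrom = g$chrom, pos = g$pos, ref = g$ref, alt = g$alt,
                     proband = g$child, mother = g$mother, father = g$father)
  write_vcf(trio, paths$trio_vcf,
            genotype_cols = list(PROBAND = "proband", MOTHER = "mother",
                                 FATHER = "father"))
  s <- as.data.frame(cohort$sites)
  write_tsv(s[, c("chrom", "pos", "ref", "alt", "alt_count", "depth")],
            paths$plasma_counts)
  plasma <- data.frame(chrom = s$chrom, pos = s$pos, ref = s$ref, alt = s$alt,
                       af = ifelse(s$depth > 0, s$alt_count / s$depth, NA),
                       depth = s$depth)
  write_vcf(plasma, paths$plasma_vcf)
  write_tsv(as.data.frame(cohort$fragments), paths$fragments)
  write_tsv(cohort$bins, paths$bins)
  ctl <- as.data.frame(cohort$control_counts)
  names(ctl) <- paste0("control_", seq_len(ncol(ctl)))
  write_tsv(cbind(cohort$bins[, c("chrom", "start", "end")], ctl),
            paths$controls)
  cfg <- cohort$config
  class(cfg) <- NULL
  cfg$cnv_events <- if (is.null(cfg$cnv_events)) list() else
    as.list(as.data.frame(cfg$cnv_events))
  write_run_config(cfg, paths$manifest)
  invisible(paths)
}

#' Assemble a SNP-site table from an allele-count TSV and a trio VCF
#'
#' Joins plasma allele counts (`chrom`, `pos`, `ref`, `alt`, `alt_count`,
#' `depth`) with parental genotypes taken from the `MOTHER` and `FATHER`
#' samples of a trio VCF.
#'
#' @param counts_path Path to the allele-count TSV.
#' @param trio_vcf_path Path to a VCF with `MOTHER` and `FATHER` samples
#'   (may be `NULL`: parental genotypes stay `NA`).
#' @return A [snp_sites()] table.
#' @export
load_snp_sites <- function(counts_path, trio_vcf_path = NULL) {
  counts <- read_tsv(counts_path)
  m <- p <- rep(NA_integer_, nrow(counts))
  if (!is.null(trio_vcf_path)) {
    trio <- read_vcf(trio_vcf_path)
    idx <- match(variant_key(counts), variant_key(trio))
    if (!is.null(trio$gt_MOTHER)) m <- trio$gt_MOTHER[idx]
    if (!is.null(trio$gt_FATHER)) p <- trio$gt_FATHER[idx]
  }
  snp_sites(counts$chrom, counts$pos, counts$ref, counts$alt,
            counts$alt_count, counts$depth,
            maternal_copies = m, paternal_copies = p)
}
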