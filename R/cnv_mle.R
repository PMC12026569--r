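#' Configuration for the CNV caller
#'
#' @param min_bins Minimum number of contiguous bins in a call (default 3).
#' @param log_lr_threshold Log-likelihood-ratio threshold vs the diploid
#'   model for emitting a call (default 10).
#' @param max_span_bins Longest candidate segment scanned, in bins
#'   (default 25).
#' @param use_size_channel Add the fragment-size evidence channel when the
#'   reference carries size information (default `TRUE`).
#' @param size_weight Weight of the size channel in log space (default 1).
#' @param ratio_floor Depth ratios are floored at this value before taking
#'   log2 (default 1e-6).
#' @return A list of class `cnv_config`.
#' @export
cnv_config <- function(min_bins = 3L, log_lr_threshold = 10,
                       max_span_bins = 25L, use_size_channel = TRUE,
                       size_weight = 1, ratio_floor = 1e-6) {
  stopifnot(min_bins >= 1, log_lr_threshold >= 0, max_span_bins >= min_bins,
            ratio_floor > 0)
  structure(list(min_bins = as.integer(min_bins),
                 log_lr_threshold = log_lr_threshold,
                 max_span_bins = as.integer(max_span_bins),
                 use_size_channel = isTRUE(use_size_channel),
                 size_weight = size_weight, ratio_floor = ratio_floor),
            class = "cnv_config")
}

#' Build a reference bin set from presumed-diploid control samples
#'
#' Per-bin expected counts are medians across control samples; the ratio
#' noise `ratio_sigma` is the pooled standard deviation of log2 normalized
#' ratios of each control against that median profile. Optional
#' short-fragment statistics enable the fragment-size evidence channel:
#' `short_mean`/`short_sd` summarize the per-bin fraction of fragments
#' below the short-length threshold across controls, and
#' `p_short_fetal`/`p_short_maternal` give the probability that a fetal or
#' maternal fragment is short (from tagged fragment-size distributions).
#'
#' @param bins Data.frame with `chrom`, `start`, `end` (0-based half-open).
#' @param control_counts Numeric matrix, one row per bin, one column per
#'   control sample.
#' @param control_short Optional matrix of per-bin short-fragment fractions
#'   in controls (same shape as `control_counts`).
#' @param p_short_fetal,p_short_maternal Optional probabilities that a
#'   fetal / maternal fragment is below the short threshold.
#' @return An object of class `reference_bin_set`.
#' @export
reference_bin_set <- function(bins, control_counts, control_short = NULL,
                              p_short_fetal = NULL, p_short_maternal = NULL) {
  control_counts <- as.matrix(control_counts)
  stopifnot(nrow(bins) == nrow(control_counts), ncol(control_counts) >= 2)
  ref_count <- apply(control_counts, 1, stats::median)
  ref_med <- stats::median(ref_count)
  lr <- sapply(seq_len(ncol(control_counts)), function(j) {
    cc <- control_counts[, j]
    ratio <- (cc / stats::median(cc)) / (ref_count / ref_med)
    log2(pmax(ratio, 1e-6))
  })
  ratio_sigma <- stats::sd(as.vector(lr))
  if (!is.finite(ratio_sigma) || ratio_sigma <= 0)
    stop("degenerate-reference: ratio_sigma must be positive")
  short_mean <- short_sd <- NULL
  if (!is.null(control_short)) {
    control_short <- as.matrix(control_short)
    short_mean <- mean(control_short)
    short_sd <- stats::sd(as.vector(control_short))
    if (!is.finite(short_sd) || short_sd <= 0)
      stop("degenerate-reference: short-fraction sd must be positive")
  }
  structure(list(bins = data.frame(chrom = as.character(bins$chrom),
                                   start = as.integer(bins$start),
                                   end = as.integer(bins$end),
                                   ref_count = ref_count,
                                   stringsAsFactors = FALSE),
                 ratio_sigma = ratio_sigma,
                 short_mean = short_mean, short_sd = short_sd,
                 p_short_fetal = p_short_fetal,
                 p_short_maternal = p_short_maternal),
            class = "reference_bin_set")
}

#' Normalize per-bin fragment counts against a reference bin set
#'
#' `ratio_i = (count_i / median(count)) / (ref_i / median(ref))`, so a
#' diploid sample has median ratio 1 by construction. Bins with a zero
#' reference count are masked (ratio `NA`) rather than dropped. Bins whose
#' |log2 ratio| exceeds `gross_dev_guard` are flagged in the
#' `gross_deviation` column — such shifts are larger than any fetal event
#' at plausible fetal fractions and usually indicate a maternal-origin CNV
#' or a technical artifact.
#'
#' @param counts Data.frame with `chrom`, `start`, `end`, `count` and
#'   optionally `short_fraction`.
#' @param reference A `reference_bin_set` covering every bin in `counts`.
#' @param gross_dev_guard Absolute log2-ratio guard (default 0.5).
#' @return A data.frame of class `target_bins` with `ratio`, `masked` and
#'   `gross_deviation` columns.
#' @export
normalize_bins <- function(counts, reference, gross_dev_guard = 0.5) {
  key <- function(d) paste(d$chrom, d$start, d$end, sep = ":")
  idx <- match(key(counts), key(reference$bins))
  if (any(is.na(idx)))
    stop("incomplete-reference: ", sum(is.na(idx)), " target bins lack a reference bin")
  ref <- reference$bins$ref_count[idx]
  masked <- ref <= 0
  if (any(masked)) warning("degenerate-bin: ", sum(masked),
                           " bins with zero reference count masked")
  ratio <- rep(NA_real_, nrow(counts))
  med_s <- stats::median(counts$count[!masked])
  med_r <- stats::median(ref[!masked])
  ratio[!masked] <- (counts$count[!masked] / med_s) / (ref[!masked] / med_r)
  out <- data.frame(chrom = as.character(counts$chrom),
                    start = as.integer(counts$start),
                    end = as.integer(counts$end),
                    count = counts$count, ratio = ratio,
                    short_fraction = if (is.null(counts$short_fraction))
                      NA_real_ else counts$short_fraction,
                    masked = masked, stringsAsFactors = FALSE)
  out$gross_deviation <- !masked & abs(log2(pmax(ratio, 1e-6))) > gross_dev_guard
  class(out) <- c("target_bins", "data.frame")
  out
}

#' Expected depth ratio under a fetal copy state
#'
#' A heterozygous fetal event changes only the fetal share of plasma
#' fragments: with fetal copy number `c` (1 deletion, 2 diploid, 3
#' duplication) the expected normalized depth ratio is
#' `(1 - f) + f * c / 2`, i.e. `1 - f/2` for a fetal deletion, 1 for
#' diploid, `1 + f/2` for a fetal duplication.
#'
#' @param copy_state `"fetal_del"`, `"diploid"` or `"fetal_dup"`
#'   (vectorized).
#' @param f Fetal fraction in `[0, 1]`.
#' @return Expected ratio(s).
#' @export
expected_ratio <- function(copy_state, f) {
  stopifnot(all(f >= 0 & f <= 1))
  cc <- c(fetal_del = 1, diploid = 2, fetal_dup = 3)[copy_state]
  if (any(is.na(cc))) stop("invalid-parameter: unknown copy state")
  unname((1 - f) + f * cc / 2)
}

# expected per-bin short-fragment fraction under a copy state: the event
# rescales the fetal share of fragments from f to f*(c/2)/((1-f)+f*c/2)
expected_short_fraction <- function(copy_state, f, reference) {
  cc <- c(fetal_del = 1, diploid = 2, fetal_dup = 3)[copy_state]
  w <- f * (cc / 2) / ((1 - f) + f * cc / 2)
  # Shift from the diploid control baseline rather than an absolute mixture
  # mean: estimation bias in the absolute short probabilities (e.g. fetal
  # contamination of maternal-tagged fragments) cancels at diploid, and only
  # the fetal-maternal contrast drives sensitivity.
  unname(reference$short_mean +
           (w - f) * (reference$p_short_fetal - reference$p_short_maternal))
}

# per-bin log-likelihood under one copy state; depth channel always, size
# channel added when configured and available
per_bin_loglik <- function(bins, copy_state, f, reference, config) {
  lr <- log2(pmax(bins$ratio, config$ratio_floor))
  ll <- stats::dnorm(lr, mean = log2(expected_ratio(copy_state, f)),
                     sd = reference$ratio_sigma, log = TRUE)
  use_size <- config$use_size_channel && !is.null(reference$short_sd) &&
    !is.null(reference$p_short_fetal) && !is.null(reference$p_short_maternal) &&
    any(!is.na(bins$short_fraction))
  if (use_size) {
    mu <- expected_short_fraction(copy_state, f, reference)
    sz <- stats::dnorm(bins$short_fraction, mean = mu,
                       sd = reference$short_sd, log = TRUE)
    sz[is.na(sz)] <- 0
    ll <- ll + config$size_weight * sz
  }
  ll
}

#' Log-likelihood of a contiguous bin segment under a copy state
#'
#' Sum over bins of the Gaussian log-density of the log2 depth ratio at the
#' state's expected ratio ([expected_ratio()]) with the reference noise
#' `ratio_sigma`, plus (when enabled) the fragment-size channel: the
#' Gaussian log-density of the observed short-fragment fraction at the
#' state's expected value.
#'
#' @param bins A `target_bins` data.frame (unmasked rows).
#' @param copy_state `"fetal_del"`, `"diploid"` or `"fetal_dup"`.
#' @param f Fetal fraction.
#' @param reference A `reference_bin_set`.
#' @param config A [cnv_config()].
#' @return Scalar log-likelihood.
#' @export
segment_log_likelihood <- function(bins, copy_state, f, reference,
                                   config = cnv_config()) {
  if (nrow(bins) < 1) stop("invalid-parameter: empty segment")
  sum(per_bin_loglik(bins, copy_state, f, reference, config))
}

#' Fragment-size shift z-score for one bin
#'
#' Standardizes a bin's short-fragment fraction against the reference
#' control distribution: `z = (short_fraction - short_mean) / short_sd`.
#' Fetal duplications enrich short (fetal) fragments and push `z` positive;
#' deletions deplete them and push `z` negative.
#'
#' @param bins A `target_bins` data.frame (vectorized over rows).
#' @param reference A `reference_bin_set` with short-fraction statistics.
#' @return Numeric z-score(s).
#' @export
size_shift_statistic <- function(bins, reference) {
  if (is.null(reference$short_sd) || reference$short_sd <= 0)
    stop("degenerate-reference: no short-fraction sd available")
  (bins$short_fraction - reference$short_mean) / reference$short_sd
}

#' Call fetal CNVs on ordered target bins by maximum likelihood
#'
#' Scans every contiguous run of `min_bins` to `max_span_bins` unmasked
#' bins within each chromosome, scores it under the fetal-deletion,
#' diploid and fetal-duplication models, and keeps candidates whose best
#' non-diploid log-likelihood ratio against diploid exceeds
#' `log_lr_threshold`. Overlapping candidates are resolved greedily by
#' descending log-likelihood ratio, so the emitted calls are maximal
#' non-overlapping segments. At `f = 0` the three states are
#' indistinguishable and no calls are made.
#'
#' @param bins A `target_bins` data.frame sorted by coordinate.
#' @param f Fetal fraction.
#' @param reference A `reference_bin_set`.
#' @param config A [cnv_config()].
#' @return A data.frame of class `cnv_calls` with columns `chrom`, `start`,
#'   `end`, `copy_state`, `log_lr`, `n_bins`, `f_used`.
#' @export
call_cnvs <- function(bins, f, reference, config = cnv_config()) {
  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      copy_state = character(), log_lr = numeric(),
                      n_bins = integer(), f_used = numeric(),
                      stringsAsFactors = FALSE)
  class(empty) <- c("cnv_calls", "data.frame")
  if (f <= 0) {
    warning("f = 0: fetal copy states are indistinguishable, no calls made")
    return(empty)
  }
  use <- !bins$masked & !is.na(bins$ratio)
  b <- bins[use, , drop = FALSE]
  if (nrow(b) < config$min_bins) return(empty)
  states <- c("fetal_del", "fetal_dup")
  ll_dip <- per_bin_loglik(b, "diploid", f, reference, config)
  ll_alt <- sapply(states, function(s) per_bin_loglik(b, s, f, reference, config))
  if (is.null(dim(ll_alt))) ll_alt <- matrix(ll_alt, nrow = 1,
                                             dimnames = list(NULL, states))
  cand <- list()
  for (chr in unique(b$chrom)) {
    ii <- which(b$chrom == chr)
    n <- length(ii)
    if (n < config$min_bins) next
    cs_dip <- cumsum(ll_dip[ii])
    cs_alt <- apply(ll_alt[ii, , drop = FALSE], 2, cumsum)
    if (is.null(dim(cs_alt))) cs_alt <- matrix(cs_alt, nrow = n,
                                               dimnames = list(NULL, states))
    seg_sum <- function(cs, i, j) cs[j] - if (i > 1) cs[i - 1] else 0
    for (i in seq_len(n)) {
      jmax <- min(n, i + config$max_span_bins - 1L)
      jmin <- i + config$min_bins - 1L
      if (jmin > jmax) next
      for (j in jmin:jmax) {
        lr <- vapply(states, function(s)
          seg_sum(cs_alt[, s], i, j) - seg_sum(cs_dip, i, j), numeric(1))
        best <- which.max(lr)
        if (lr[best] > config$log_lr_threshold) {
          cand[[length(cand) + 1L]] <- list(
            chr = chr, i = ii[i], j = ii[j],
            state = states[best], log_lr = lr[best])
        }
      }
    }
  }
  if (length(cand) == 0) return(empty)
  ord <- order(-vapply(cand, `[[`, numeric(1), "log_lr"))
  taken <- rep(FALSE, nrow(b))
  calls <- list()
  for (cd in cand[ord]) {
    span <- cd$i:cd$j
    if (any(taken[span])) next
    taken[span] <- TRUE
    calls[[length(calls) + 1L]] <- data.frame(
      chrom = cd$chr, start = b$start[cd$i], end = b$end[cd$j],
      copy_state = cd$state, log_lr = cd$log_lr,
      n_bins = length(span), f_used = f, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, calls)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("cnv_calls", "data.frame")
  out
}

#' Write CNV calls as BED-like TSV and as symbolic-allele VCF records
#'
#' The BED-like table keeps the 0-based half-open convention; the VCF uses
#' 1-based `POS` with `<DEL>`/`<DUP>` symbolic alleles and `END` in INFO.
#'
#' @param calls A `cnv_calls` data.frame.
#' @param bed_path,vcf_path Output paths (either may be `NULL` to skip).
#' @return Invisibly, the list of paths written.
#' @export
write_cnv_calls <- function(calls, bed_path = NULL, vcf_path = NULL) {
  if (!is.null(bed_path)) write_tsv(as.data.frame(calls), bed_path)
  if (!is.null(vcf_path)) {
    hdr <- c("##fileformat=VCFv4.2",
             "##ALT=<ID=DEL,Description=\"Deletion\">",
             "##ALT=<ID=DUP,Description=\"Duplication\">",
             "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position\">",
             "##INFO=<ID=LOGLR,Number=1,Type=Float,Description=\"Log likelihood ratio vs diploid\">",
             "##INFO=<ID=FF,Number=1,Type=Float,Description=\"Fetal fraction used\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO"), collapse = "\t"))
    alt <- ifelse(calls$copy_state == "fetal_del", "<DEL>", "<DUP>")
    body <- sprintf("%s\t%d\t.\tN\t%s\t.\tPASS\tEND=%d;LOGLR=%.4f;FF=%.4f",
                    calls$chrom, calls$start + 1L, alt, calls$end,
                    calls$log_lr, calls$f_used)
    writeLines(c(hdr, body), vcf_path)
  }
  invisible(list(bed = bed_path, vcf = vcf_path))
}
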