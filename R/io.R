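#' Read a VCF file into a flat variant table
#'
#' Wraps [vcfR::read.vcfR()] and flattens the result into one row per
#' biallelic variant. Multiallelic records are split into one row per ALT
#' allele; per-sample genotypes are converted to alt-allele copy counts
#' (0, 1, 2, or `NA` for missing calls) relative to the row's ALT allele.
#'
#' @param path Path to a VCF 4.2-compatible file (plain or gzipped).
#' @return A data.frame with columns `chrom`, `pos` (1-based), `ref`, `alt`,
#'   `af` (INFO AF, `NA` if absent), `depth` (INFO DP, `NA` if absent), and
#'   one `gt_<sample>` column of alt copy counts per sample in the file.
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    out <- data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), af = numeric(), depth = numeric())
    return(out)
  }
  info_field <- function(info, key) {
    m <- regmatches(info, regexpr(paste0("(^|;)", key, "=[^;]+"), info))
    val <- rep(NA_character_, length(info))
    hit <- lengths(regmatches(info, gregexpr(paste0("(^|;)", key, "="), info))) > 0
    val[hit] <- sub(paste0(".*", key, "="), "", m)
    val
  }
  gt_mat <- NULL
  samples <- character()
  if (ncol(v@gt) > 1) {
    samples <- colnames(v@gt)[-1]
    gt_mat <- vcfR::extract.gt(v, element = "GT")
    if (is.null(dim(gt_mat))) gt_mat <- matrix(gt_mat, ncol = length(samples),
                                               dimnames = list(NULL, samples))
  }
  alts <- strsplit(fix$ALT, ",", fixed = TRUE)
  n_alt <- lengths(alts)
  rec <- rep(seq_len(nrow(fix)), n_alt)       # source record per output row
  alt_idx <- sequence(n_alt)                  # which ALT allele per row
  afs <- strsplit(info_field(fix$INFO, "AF"), ",", fixed = TRUE)
  af <- suppressWarnings(as.numeric(mapply(
    function(a, i) if (length(a) == 0 || all(is.na(a))) NA_character_
      else a[min(i, length(a))],
    afs[rec], alt_idx)))
  dp <- suppressWarnings(as.numeric(info_field(fix$INFO, "DP")))[rec]
  out <- data.frame(chrom = fix$CHROM[rec], pos = as.integer(fix$POS[rec]),
                    ref = fix$REF[rec], alt = unlist(alts),
                    af = af, depth = dp, stringsAsFactors = FALSE)
  for (s in samples) {
    gt <- gt_mat[rec, s]
    copies <- rep(NA_integer_, length(gt))
    simple <- !is.na(gt) & !grepl("\\.", gt)
    # count alleles equal to this row's ALT index
    tok <- strsplit(gt[simple], "[/|]")
    copies[simple] <- mapply(function(alleles, i) sum(alleles == as.character(i)),
                             tok, alt_idx[simple])
    out[[paste0("gt_", s)]] <- copies
  }
  rownames(out) <- NULL
  out
}

# GT string -> copies of the a-th ALT allele; NA for missing
gt_to_copies <- function(gt, alt_index = 1L) {
  if (is.na(gt) || gt %in% c(".", "./.", ".|.")) return(NA_integer_)
  alleles <- strsplit(gt, "[/|]")[[1]]
  if (any(alleles == ".")) return(NA_integer_)
  sum(alleles == as.character(alt_index))
}

#' Write a variant table as a minimal VCF 4.2 file
#'
#' Emits biallelic records with INFO `AF`/`DP` and per-sample `GT` fields.
#' Genotypes are alt copy counts encoded as `0/0`, `0/1`, `1/1`, `./.`.
#'
#' @param variants Data.frame with `chrom`, `pos`, `ref`, `alt` and optional
#'   `af`, `depth` columns.
#' @param path Output path.
#' @param genotype_cols Named list mapping sample name to the column of
#'   `variants` holding that sample's alt copy count, e.g.
#'   `list(PROBAND = "proband")`. May be empty for a site-only VCF.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, path, genotype_cols = list()) {
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Allele fraction\">",
           "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
  cols <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")
  if (length(genotype_cols) > 0) cols <- c(cols, "FORMAT", names(genotype_cols))
  enc_gt <- function(k) {
    out <- rep("./.", length(k))
    out[!is.na(k) & k == 0] <- "0/0"
    out[!is.na(k) & k == 1] <- "0/1"
    out[!is.na(k) & k == 2] <- "1/1"
    out
  }
  info <- rep(".", nrow(variants))
  if (!is.null(variants$af) || !is.null(variants$depth)) {
    af <- if (is.null(variants$af)) rep(NA, nrow(variants)) else variants$af
    dp <- if (is.null(variants$depth)) rep(NA, nrow(variants)) else variants$depth
    info <- mapply(function(a, d) {
      parts <- c(if (!is.na(a)) sprintf("AF=%.6g", a),
                 if (!is.na(d)) sprintf("DP=%d", as.integer(d)))
      if (length(parts) == 0) "." else paste(parts, collapse = ";")
    }, af, dp)
  }
  body <- data.frame(variants$chrom, variants$pos, ".", variants$ref,
                     variants$alt, ".", "PASS", info,
                     stringsAsFactors = FALSE)
  if (length(genotype_cols) > 0) {
    body <- cbind(body, "GT")
    for (col in unlist(genotype_cols)) body <- cbind(body, enc_gt(variants[[col]]))
  }
  lines <- c(hdr, paste(cols, collapse = "\t"),
             apply(body, 1, paste, collapse = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED file into a GRanges interval set
#'
#' BED intervals are 0-based half-open; the returned `GRanges` uses the
#' 1-based closed convention, so BED `chr1 100 200` becomes `chr1:101-200`
#' and covers 1-based positions 101..200.
#'
#' @param path Path to a 3+ column BED file (no header).
#' @return A [GenomicRanges::GRanges] object.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  raw <- tryCatch(utils::read.table(path, sep = "\t", stringsAsFactors = FALSE),
                  error = function(e) NULL)
  if (is.null(raw) || nrow(raw) == 0) {
    return(GenomicRanges::GRanges())
  }
  if (ncol(raw) < 3) stop("invalid-bed: fewer than 3 columns in ", path)
  start0 <- as.numeric(raw[[2]]); end0 <- as.numeric(raw[[3]])
  if (any(end0 <= start0)) stop("invalid-bed: interval with end <= start in ", path)
  GenomicRanges::GRanges(seqnames = raw[[1]],
                         ranges = IRanges::IRanges(start = start0 + 1, end = end0))
}

#' Test 1-based positions for membership in an interval set
#'
#' @param chrom,pos Vectors of chromosome names and 1-based positions.
#' @param intervals A `GRanges` (e.g. from [read_bed()]).
#' @return Logical vector: `TRUE` where the position falls inside an interval.
#' @export
positions_in_intervals <- function(chrom, pos, intervals) {
  if (length(intervals) == 0 || length(pos) == 0) return(rep(FALSE, length(pos)))
  q <- GenomicRanges::GRanges(seqnames = chrom,
                              ranges = IRanges::IRanges(start = pos, end = pos))
  GenomicRanges::countOverlaps(q, intervals) > 0
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read/write tab-separated tables with a header row
#'
#' Thin wrappers around [utils::read.delim()] / [utils::write.table()] fixing
#' the package's interchange conventions (tab separator, header, no quoting,
#' no row names).
#'
#' @param x Data.frame to write.
#' @param path File path.
#' @return `read_tsv()` returns a data.frame; `write_tsv()` returns `path`
#'   invisibly.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write run configuration as YAML
#'
#' A run configuration is a named list of module settings plus `seed`; it
#' round-trips losslessly through a YAML key-value file.
#'
#' @param config Named list.
#' @param path File path.
#' @return `read_run_config()` returns the named list.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  yaml::read_yaml(path)
}
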