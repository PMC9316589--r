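#' Quantify guides from FASTQ by exact spacer matching
#'
#' Assigns each read to at most one guide by exact (zero-mismatch) match of
#' the library spacer. In `"scan"` mode (the default) a spacer-length
#' window slides over the read and a unique dictionary hit assigns the
#' read; `"fixed_offset"` mode looks only at the declared offset, which is
#' faster when the read layout is known. Reads matching two or more
#' distinct guides are counted as ambiguous and assigned to neither. By
#' default only the forward strand is searched; `reverse_complement = TRUE`
#' adds a reverse-complement pass for reads with no forward hit.
#'
#' @param lib A [guide_library()].
#' @param fastq_paths Named character vector of FASTQ(.gz) paths, one per
#'   sample; names become sample names.
#' @param mode `"scan"` or `"fixed_offset"`.
#' @param offset 1-based spacer start for `"fixed_offset"` mode.
#' @param design Optional sample design (columns `sample`, `timepoint`,
#'   `treatment`, `role`); defaults to all-`none` QC-only metadata.
#' @param reverse_complement Also try the reverse complement of each read
#'   (default FALSE; amplicon screens read the spacer in one orientation).
#' @return A list with `counts` (a [screen_counts()]) and `stats` (a
#'   mapping-statistics tibble: per sample `total_reads`, `mapped_reads`,
#'   `ambiguous_reads`, `unmapped_reads`, `mapping_rate` in percent,
#'   `mean_coverage`, `median_coverage`, `zero_fraction`, `gini`).
#' @export
count_reads <- function(lib, fastq_paths, mode = c("scan", "fixed_offset"),
                        offset = NULL, design = NULL,
                        reverse_complement = FALSE) {
  mode <- match.arg(mode)
  if (mode == "fixed_offset" && is.null(offset)) {
    abort("fixed_offset mode needs an offset")
  }
  if (is.null(names(fastq_paths)) || any(!nzchar(names(fastq_paths)))) {
    abort("fastq_paths must be named by sample")
  }
  purrr::walk(fastq_paths, assert_file, what = "FASTQ file")
  sl <- attr(lib, "spacer_length")
  n_guides <- nrow(lib)

  per_sample <- purrr::imap(fastq_paths, function(fp, s) {
    reads <- read_fastq_sequences(fp, s)
    if (length(reads) == 0L) {
      warn(sprintf("sample %s: empty FASTQ, all counts zero", s))
      return(list(counts = integer(n_guides), total = 0L,
                  mapped = 0L, ambiguous = 0L))
    }
    asg <- assign_reads(reads, lib$spacer, sl, mode, offset)
    if (reverse_complement) {
      miss <- is.na(asg$guide) & !asg$ambiguous
      if (any(miss)) {
        rc <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAStringSet(reads[miss])))
        asg2 <- assign_reads(rc, lib$spacer, sl, mode, offset)
        asg$guide[miss] <- asg2$guide
        asg$ambiguous[miss] <- asg2$ambiguous
      }
    }
    mapped_idx <- asg$guide[!is.na(asg$guide)]
    list(counts = tabulate(mapped_idx, nbins = n_guides),
         total = length(reads),
         mapped = length(mapped_idx),
         ambiguous = sum(asg$ambiguous))
  })

  mat <- vapply(per_sample, `[[`, integer(n_guides), "counts")
  counts_tbl <- dplyr::bind_cols(
    tibble::tibble(guide_id = lib$guide_id, gene = lib$gene),
    tibble::as_tibble(mat))
  if (is.null(design)) {
    design <- tibble::tibble(sample = names(fastq_paths), timepoint = "none",
                             treatment = "none", role = "baseline")
  }
  counts <- screen_counts(counts_tbl, design)

  stats <- purrr::imap_dfr(per_sample, function(p, s) {
    k <- p$counts
    tibble::tibble(
      sample = s,
      total_reads = p$total,
      mapped_reads = p$mapped,
      ambiguous_reads = p$ambiguous,
      unmapped_reads = p$total - p$mapped - p$ambiguous,
      mapping_rate = if (p$total > 0L) 100 * p$mapped / p$total else NA_real_,
      mean_coverage = mean(k),
      median_coverage = median(k),
      zero_fraction = mean(k == 0L),
      gini = gini_index(k))
  })
  list(counts = counts, stats = stats)
}

read_fastq_sequences <- function(path, sample) {
  seqs <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fastq"),
    error = function(e) {
      abort(sprintf("sample %s: malformed FASTQ %s (%s)",
                    sample, path, conditionMessage(e)))
    })
  as.character(seqs)
}

## For each read, the set of distinct guide indices whose spacer occurs in
## it; unique hit -> assignment, >= 2 distinct guides -> ambiguous. Works
## column-wise over window offsets so the per-read reduction is vectorised.
assign_reads <- function(reads, spacers, sl, mode, offset) {
  offsets <- if (mode == "fixed_offset") {
    as.integer(offset)
  } else {
    seq_len(max(max(nchar(reads)) - sl + 1L, 1L))
  }
  lo <- NULL  # running min / max matched guide index per read
  hi <- NULL
  for (k in offsets) {
    hit <- match(substr(reads, k, k + sl - 1L), spacers)
    if (is.null(lo)) {
      lo <- hit
      hi <- hit
    } else {
      lo <- pmin(lo, hit, na.rm = TRUE)
      hi <- pmax(hi, hit, na.rm = TRUE)
    }
  }
  ambiguous <- !is.na(lo) & lo != hi
  guide <- ifelse(!is.na(lo) & lo == hi, lo, NA_integer_)
  list(guide = guide, ambiguous = ambiguous)
}

#' QC verdict on mapping statistics
#'
#' Flags samples whose mapping rate falls below `threshold_pct` (the
#' screen-QC convention is that all samples should exceed 75%) and reports
#' whether mean guide coverage lies inside the target representation
#' window (default 100-300x).
#'
#' @param stats The `stats` tibble from [count_reads()].
#' @param threshold_pct Minimum acceptable mapping rate in percent
#'   (default 75).
#' @param coverage_range Length-2 numeric target coverage window
#'   (default `c(100, 300)`).
#' @return `stats` with added columns `mapping_pass` and
#'   `coverage_in_band`.
#' @export
mapping_report <- function(stats, threshold_pct = 75,
                           coverage_range = c(100, 300)) {
  dplyr::mutate(
    stats,
    mapping_pass = .data$mapping_rate >= threshold_pct,
    coverage_in_band = .data$mean_coverage >= coverage_range[1] &
      .data$mean_coverage <= coverage_range[2])
}
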