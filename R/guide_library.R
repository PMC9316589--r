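#' Construct and validate an sgRNA guide library
#'
#' A guide library is a tibble with one row per sgRNA and columns
#' `guide_id`, `gene`, `spacer`, `is_nontargeting`. Nontargeting control
#' guides carry the reserved gene label `"non-targeting"`. Spacer sequences
#' must be unique because guide quantification assigns reads by exact
#' spacer match.
#'
#' @param records Data frame with columns `guide_id`, `gene`, `spacer`,
#'   `is_nontargeting`.
#' @param spacer_length Declared spacer length in nucleotides (default 20).
#' @return A validated `guide_library` tibble (row order preserved) with the
#'   spacer length stored in `attr(, "spacer_length")`.
#' @export
#' @examples
#' guide_library(data.frame(
#'   guide_id = c("TP53_1", "NTC_1"),
#'   gene = c("TP53", "non-targeting"),
#'   spacer = c(strrep("AC", 10), strrep("GT", 10)),
#'   is_nontargeting = c(FALSE, TRUE)
#' ))
guide_library <- function(records, spacer_length = 20L) {
  needed <- c("guide_id", "gene", "spacer", "is_nontargeting")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols)) {
    abort(paste0("library is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  lib <- tibble::as_tibble(records)[needed]
  lib$guide_id <- as.character(lib$guide_id)
  lib$gene <- as.character(lib$gene)
  lib$spacer <- toupper(as.character(lib$spacer))
  lib$is_nontargeting <- as.logical(lib$is_nontargeting)
  attr(lib, "spacer_length") <- as.integer(spacer_length)
  class(lib) <- c("guide_library", class(tibble::tibble()))
  validate_guide_library(lib)
}

#' @rdname guide_library
#' @param x Object to validate.
#' @export
validate_guide_library <- function(x) {
  spacer_length <- attr(x, "spacer_length")
  dup_id <- which(duplicated(x$guide_id) | duplicated(x$guide_id, fromLast = TRUE))
  if (length(dup_id)) {
    abort(sprintf("duplicate guide_id in rows: %s",
                  paste(head(dup_id, 10L), collapse = ", ")))
  }
  dup_sp <- which(duplicated(x$spacer) | duplicated(x$spacer, fromLast = TRUE))
  if (length(dup_sp)) {
    abort(sprintf("duplicate spacer in rows: %s (exact-match counting requires unique spacers)",
                  paste(head(dup_sp, 10L), collapse = ", ")))
  }
  bad_alpha <- which(!grepl("^[ACGT]+$", x$spacer))
  if (length(bad_alpha)) {
    abort(sprintf("non-ACGT spacer in rows: %s",
                  paste(head(bad_alpha, 10L), collapse = ", ")))
  }
  bad_len <- which(nchar(x$spacer) != spacer_length)
  if (length(bad_len)) {
    abort(sprintf("spacer length != %d in rows: %s",
                  spacer_length, paste(head(bad_len, 10L), collapse = ", ")))
  }
  bad_ntc <- which(x$is_nontargeting != (x$gene == NTC_LABEL))
  if (length(bad_ntc)) {
    abort(sprintf(
      "is_nontargeting must agree with the reserved gene label \"%s\" (rows: %s)",
      NTC_LABEL, paste(head(bad_ntc, 10L), collapse = ", ")))
  }
  x
}

#' Read / write a guide library TSV
#'
#' The on-disk dialect is tab-separated with a header
#' (`guide_id`, `gene`, `spacer`, `is_nontargeting`), UTF-8, no quoting.
#'
#' @param path Path to a library TSV.
#' @param spacer_length Declared spacer length (default 20).
#' @return `read_guide_library()` returns a validated [guide_library()];
#'   `write_guide_library()` returns `path` invisibly.
#' @export
read_guide_library <- function(path, spacer_length = 20L) {
  assert_file(path, "library file")
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  raw$is_nontargeting <- raw$is_nontargeting %in% c("TRUE", "true", "1")
  guide_library(raw, spacer_length = spacer_length)
}

#' @rdname read_guide_library
#' @param lib A [guide_library()].
#' @export
write_guide_library <- function(lib, path) {
  readr::write_tsv(tibble::as_tibble(lib), path, progress = FALSE)
  invisible(path)
}

#' Simulate a guide library
#'
#' Builds a synthetic library with `guides_per_gene` guides for each of
#' `n_genes` genes plus `n_nontargeting` nontargeting controls. Spacers are
#' random unique DNA of the declared length, drawn from a seeded generator,
#' so the same seed is bit-identical across runs.
#'
#' @param n_genes Number of targeting genes.
#' @param guides_per_gene Guides per gene (default 3, as in GeCKO-style
#'   sub-libraries).
#' @param n_nontargeting Number of nontargeting control guides.
#' @param spacer_length Spacer length in nt (default 20).
#' @param n_extra_guides Additional guides appended to the first gene beyond
#'   `guides_per_gene` (default 0); used by [gecko_b_profile()] to honour a
#'   total that is not a multiple of `guides_per_gene`.
#' @param seed Integer seed for spacer generation.
#' @return A [guide_library()].
#' @export
simulate_guide_library <- function(n_genes, guides_per_gene = 3L,
                                   n_nontargeting = 0L, spacer_length = 20L,
                                   n_extra_guides = 0L, seed = 1L) {
  stopifnot(n_genes >= 1L, guides_per_gene >= 1L, n_nontargeting >= 0L,
            n_extra_guides >= 0L)
  genes <- sprintf("GENE%05d", seq_len(n_genes))
  gene_col <- rep(genes, each = guides_per_gene)
  idx <- rep(seq_len(guides_per_gene), times = n_genes)
  if (n_extra_guides > 0L) {
    gene_col <- c(gene_col, rep(genes[1L], n_extra_guides))
    idx <- c(idx, guides_per_gene + seq_len(n_extra_guides))
  }
  guide_id <- paste0(gene_col, "_", idx)
  if (n_nontargeting > 0L) {
    gene_col <- c(gene_col, rep(NTC_LABEL, n_nontargeting))
    guide_id <- c(guide_id, sprintf("NTC_%04d", seq_len(n_nontargeting)))
  }
  n <- length(guide_id)
  spacers <- withr::with_seed(seed, {
    sp <- random_dna(n, spacer_length)
    while (anyDuplicated(sp)) {
      dup <- which(duplicated(sp))
      sp[dup] <- random_dna(length(dup), spacer_length)
    }
    sp
  })
  guide_library(
    tibble::tibble(guide_id = guide_id, gene = gene_col, spacer = spacers,
                   is_nontargeting = gene_col == NTC_LABEL),
    spacer_length = spacer_length
  )
}

#' GeCKO-B-like library preset
#'
#' Emulates the composition of the screened genome-wide knockout
#' sub-library: 58,028 sgRNAs in total, of which 1,000 are nontargeting
#' controls. The 57,028 targeting guides are laid out as 3 guides for each
#' of 19,009 synthetic genes plus one extra guide on the first gene
#' (57,028 = 3 x 19,009 + 1); the real library's gene count is not public,
#' so this preset honours every stated count simultaneously. Spacer
#' sequences are synthetic random 20-mers, which is all exact-match
#' counting needs.
#'
#' @param seed Integer seed for spacer generation.
#' @return A [guide_library()] of 58,028 records.
#' @export
gecko_b_profile <- function(seed = 1L) {
  simulate_guide_library(n_genes = 19009L, guides_per_gene = 3L,
                         n_nontargeting = 1000L, n_extra_guides = 1L,
                         seed = seed)
}

#' Export library spacers as FASTA
#'
#' One record per guide; header is the guide id, sequence is the spacer.
#'
#' @param lib A [guide_library()].
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
export_spacers_fasta <- function(lib, path) {
  seqs <- Biostrings::DNAStringSet(setNames(lib$spacer, lib$guide_id))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
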