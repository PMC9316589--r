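#' Guide-by-sample count table with attached sample design
#'
#' The central container of the pipeline: a tibble with annotation columns
#' `guide_id`, `gene` followed by one integer column per sample, plus a
#' sample design describing each sample's `timepoint` (`"ZT16"`, `"ZT28"`
#' or `"none"`), `treatment` (`"drug"`, `"vehicle"` or `"none"`) and `role`
#' (`"screen"` or `"baseline"`).
#'
#' @param counts Data frame with `guide_id`, `gene` and one column of
#'   nonnegative integers per sample.
#' @param design Data frame with columns `sample`, `timepoint`, `treatment`,
#'   `role`; one row per sample column of `counts`.
#' @return A `screen_counts` tibble; the design is stored in
#'   `attr(, "design")` and returned by [sample_design()].
#' @export
screen_counts <- function(counts, design) {
  counts <- tibble::as_tibble(counts)
  design <- tibble::as_tibble(design)
  needed <- c("sample", "timepoint", "treatment", "role")
  if (!all(needed %in% names(design))) {
    abort(paste0("design needs columns: ", paste(needed, collapse = ", ")))
  }
  smp <- sample_cols(counts)
  if (!setequal(smp, design$sample)) {
    abort("design samples and count columns disagree")
  }
  design <- design[match(smp, design$sample), ]
  bad <- design$role == "screen" &
    (!design$timepoint %in% c("ZT16", "ZT28") |
       !design$treatment %in% c("drug", "vehicle"))
  if (any(bad)) {
    abort(paste0("screen samples need timepoint in {ZT16, ZT28} and treatment ",
                 "in {drug, vehicle}: ", paste(design$sample[bad], collapse = ", ")))
  }
  vals <- as.matrix(counts[smp])
  if (anyNA(vals) || any(vals < 0) || any(vals != floor(vals))) {
    abort("counts must be nonnegative integers")
  }
  attr(counts, "design") <- design
  class(counts) <- unique(c("screen_counts", class(counts)))
  counts
}

#' @rdname screen_counts
#' @param x A `screen_counts` or normalized matrix object.
#' @export
sample_design <- function(x) {
  attr(x, "design")
}

#' Read / write counts and design TSVs
#'
#' Counts are stored as `guide_id`, `gene`, then one column per sample;
#' the design file has columns `sample`, `timepoint`, `treatment`, `role`.
#'
#' @param counts_path,design_path Paths to the counts and design TSVs.
#' @return A [screen_counts()] tibble.
#' @export
read_counts <- function(counts_path, design_path) {
  assert_file(counts_path, "counts file")
  assert_file(design_path, "design file")
  counts <- readr::read_tsv(counts_path, show_col_types = FALSE, progress = FALSE)
  design <- readr::read_tsv(design_path, show_col_types = FALSE, progress = FALSE)
  screen_counts(counts, design)
}

#' @rdname read_counts
#' @param x A [screen_counts()] tibble.
#' @export
write_counts <- function(x, counts_path, design_path = NULL) {
  readr::write_tsv(tibble::as_tibble(x), counts_path, progress = FALSE)
  if (!is.null(design_path)) {
    readr::write_tsv(sample_design(x), design_path, progress = FALSE)
  }
  invisible(counts_path)
}
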