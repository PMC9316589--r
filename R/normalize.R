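#' Median normalization of a screen count matrix
#'
#' Adjusts for library size and sequencing depth by dividing each sample by
#' a size factor.
#'
#' `"median_scaling"` (the default, the literal reading of "median
#' normalization"): the size factor is the sample's median guide count
#' divided by the global reference median (the median of per-sample
#' medians), so every sample's post-normalization median equals the
#' reference median.
#'
#' `"median_ratio"` (the robust alternative, as in DESeq-style analyses):
#' the size factor is the median, over guides positive in all samples, of
#' the ratio of the sample's count to the per-guide geometric-mean
#' pseudo-reference.
#'
#' Nontargeting guides take part in size-factor computation: they are part
#' of the sequenced library and are only removed later, at the hit-calling
#' step.
#'
#' @param counts A [screen_counts()].
#' @param method `"median_scaling"` or `"median_ratio"`.
#' @return A `screen_norm` tibble with the same layout as `counts`, real
#'   valued; size factors in `attr(, "size_factors")`, the method in
#'   `attr(, "method")`, and the design carried over.
#' @export
#' @examples
#' cnt <- screen_counts(
#'   tibble::tibble(guide_id = paste0("g", 1:4), gene = "G",
#'                  s1 = c(10, 20, 30, 40), s2 = c(20, 40, 60, 80)),
#'   tibble::tibble(sample = c("s1", "s2"), timepoint = "none",
#'                  treatment = "none", role = "baseline"))
#' median_normalize(cnt)  # both samples scale to median 37.5
median_normalize <- function(counts, method = c("median_scaling", "median_ratio")) {
  method <- match.arg(method)
  smp <- sample_cols(counts)
  mat <- as.matrix(counts[smp])

  if (method == "median_scaling") {
    med <- apply(mat, 2L, median)
    if (any(med <= 0)) {
      abort(paste0("sample(s) with zero median count: ",
                   paste(smp[med <= 0], collapse = ", "),
                   "; consider method = \"median_ratio\" or prefiltering"))
    }
    size_factors <- med / median(med)
  } else {
    pos <- rowSums(mat > 0) == ncol(mat)
    if (!any(pos)) {
      abort("median_ratio: no guide is positive in all samples")
    }
    ref <- exp(rowMeans(log(mat[pos, , drop = FALSE])))
    size_factors <- apply(mat[pos, , drop = FALSE] / ref, 2L, median)
    if (any(size_factors <= 0)) {
      abort("median_ratio produced a nonpositive size factor")
    }
  }

  norm <- counts
  for (j in seq_along(smp)) {
    norm[[smp[j]]] <- unname(mat[, j] / size_factors[[j]])
  }
  attr(norm, "size_factors") <- setNames(size_factors, smp)
  attr(norm, "method") <- method
  class(norm) <- unique(c("screen_norm", setdiff(class(norm), "screen_counts")))
  norm
}

#' @rdname median_normalize
#' @param x A `screen_norm` object.
#' @export
size_factors <- function(x) {
  attr(x, "size_factors")
}

#' Inter-sample quality-control report
#'
#' Summarises uniformity of guide representation and agreement between
#' samples: per-sample Gini index, zero-count fraction and coverage
#' summary, plus all pairwise Pearson and Spearman correlations of
#' log2(value + 1) guide vectors.
#'
#' @param norm A [median_normalize()] result (a raw [screen_counts()] is
#'   accepted too).
#' @return A list of class `screen_qc` with tibbles `samples` (per-sample
#'   stats) and `correlations` (one row per sample pair; empty with a
#'   warning for a single-sample matrix).
#' @export
qc_report <- function(norm) {
  smp <- sample_cols(norm)
  mat <- as.matrix(norm[smp])
  samples <- purrr::map_dfr(seq_along(smp), function(j) {
    v <- mat[, j]
    tibble::tibble(sample = smp[j], mean_coverage = mean(v),
                   median_coverage = median(v), zero_fraction = mean(v == 0),
                   gini = gini_index(v))
  })
  if (length(smp) < 2L) {
    warn("fewer than 2 samples: no correlation block")
    correlations <- tibble::tibble(sample_a = character(), sample_b = character(),
                                   pearson = numeric(), spearman = numeric())
  } else {
    lmat <- log2(mat + 1)
    ## a constant sample has no defined correlation; report NA quietly
    safe_cor <- function(x, y, method) {
      if (stats::sd(x) == 0 || stats::sd(y) == 0) {
        return(NA_real_)
      }
      cor(x, y, method = method)
    }
    pairs <- utils::combn(seq_along(smp), 2L)
    correlations <- purrr::map_dfr(seq_len(ncol(pairs)), function(p) {
      i <- pairs[1L, p]
      j <- pairs[2L, p]
      tibble::tibble(sample_a = smp[i], sample_b = smp[j],
                     pearson = safe_cor(lmat[, i], lmat[, j], "pearson"),
                     spearman = safe_cor(lmat[, i], lmat[, j], "spearman"))
    })
  }
  structure(list(samples = samples, correlations = correlations),
            class = "screen_qc")
}
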