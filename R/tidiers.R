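#' Tidy the gene-level hit calls
#'
#' One row per (gene, call-set) instance: which timepoint and direction
#' admitted the gene, through which rule, and whether the call is
#' time-specific.
#'
#' @param x A `chrono_hitcall` from [run_hitcall()].
#' @param ... Unused.
#' @return A tibble with columns `gene`, `timepoint`, `direction`,
#'   `set` (A3/B3/C3/D3), `admitted_by`, `time_specific` and
#'   `specific_set` (A4/B4/C4/D4 or NA when shared).
#' @export
tidy.chrono_hitcall <- function(x, ...) {
  map <- tibble::tibble(
    set = c("A3", "B3", "C3", "D3"),
    timepoint = c("ZT16", "ZT16", "ZT28", "ZT28"),
    direction = c("sensitivity", "resistance", "sensitivity", "resistance"),
    specific = c("A4", "B4", "C4", "D4"))
  purrr::pmap_dfr(map, function(set, timepoint, direction, specific) {
    called <- x$genes[x$genes[[set]], ]
    admitted <- called[[paste0("admitted_", set)]]
    is_specific <- called[[specific]]
    tibble::tibble(
      gene = called$gene, timepoint = timepoint, direction = direction,
      set = set, admitted_by = admitted, time_specific = is_specific,
      specific_set = ifelse(is_specific, specific, NA_character_))
  })
}

#' One-row summary of a hit-call ledger
#'
#' @param x A `chrono_hitcall` from [run_hitcall()].
#' @param ... Unused.
#' @return A one-row tibble: guide/gene counts after filtering and the
#'   sizes of every gene-level set.
#' @export
glance.chrono_hitcall <- function(x, ...) {
  sz <- purrr::map_int(x$sets, length)
  dplyr::bind_cols(
    tibble::tibble(n_guides = nrow(x$guides), n_genes = nrow(x$genes)),
    tibble::as_tibble(as.list(sz[c("A3", "B3", "C3", "D3",
                                   "A4", "B4", "C4", "D4",
                                   "shared_sen", "shared_res")])))
}

#' @rdname enrich
#' @param x A `screen_enrichment` tibble.
#' @param ... Unused.
#' @export
glance.screen_enrichment <- function(x, ...) {
  tibble::tibble(n_sets = nrow(x), n_significant = sum(x$q < 0.05),
                 min_p = min(x$p), min_q = min(x$q))
}
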