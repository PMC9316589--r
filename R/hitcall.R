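#' Parameters of the chrono-screen hit-calling algebra
#'
#' Thresholds and filters of the rule-based fold-change procedure that
#' turns the four normalized screen samples into time-specific
#' resistance/sensitivity gene sets.
#'
#' @param up_threshold Enrichment gate on the drug/vehicle ratio
#'   (default 2, inclusive: ratio >= 2 is enriched).
#' @param down_threshold Depletion gate (default 0.5, exclusive:
#'   ratio < 0.5 is depleted).
#' @param strong_up Single-guide rescue ratio for enrichment (default 5,
#'   inclusive): one guide at >= `strong_up` admits its gene even without
#'   a second concordant guide.
#' @param strong_down Single-guide rescue ratio for depletion (default 0.2,
#'   exclusive).
#' @param min_concordant_guides Number of distinct gated guides required
#'   for a gene call by concordance (default 2).
#' @param pseudocount Value added to every retained guide in every dataset
#'   before ratios (default 1).
#' @param zero_filter_scope `"any_sample"` (default: a guide with a zero in
#'   any of the four screen samples is dropped, so all four datasets share
#'   one guide index) or `"all_samples"` (dropped only if zero everywhere).
#' @return A `hitcall_params` list.
#' @export
hitcall_params <- function(up_threshold = 2, down_threshold = 0.5,
                           strong_up = 5, strong_down = 0.2,
                           min_concordant_guides = 2L, pseudocount = 1,
                           zero_filter_scope = c("any_sample", "all_samples")) {
  zero_filter_scope <- match.arg(zero_filter_scope)
  if (!(0 < strong_down && strong_down < down_threshold &&
        down_threshold < 1 && 1 < up_threshold && up_threshold <= strong_up)) {
    abort("need 0 < strong_down < down_threshold < 1 < up_threshold <= strong_up")
  }
  if (min_concordant_guides < 2L) {
    abort("min_concordant_guides must be >= 2")
  }
  if (pseudocount <= 0) {
    abort("pseudocount must be > 0")
  }
  structure(list(up_threshold = up_threshold, down_threshold = down_threshold,
                 strong_up = strong_up, strong_down = strong_down,
                 min_concordant_guides = as.integer(min_concordant_guides),
                 pseudocount = pseudocount,
                 zero_filter_scope = zero_filter_scope),
            class = "hitcall_params")
}

## Resolve the four screen samples to the dataset letters:
## A = ZT16 vehicle, B = ZT16 drug, C = ZT28 vehicle, D = ZT28 drug.
dataset_samples <- function(design) {
  cells <- list(A = c("ZT16", "vehicle"), B = c("ZT16", "drug"),
                C = c("ZT28", "vehicle"), D = c("ZT28", "drug"))
  out <- character(0)
  for (letter in names(cells)) {
    cell <- cells[[letter]]
    hit <- design$sample[design$role == "screen" &
                           design$timepoint == cell[1] &
                           design$treatment == cell[2]]
    if (length(hit) != 1L) {
      abort(sprintf("design needs exactly one screen sample for %s %s (dataset %s), found %d",
                    cell[1], cell[2], letter, length(hit)))
    }
    out[letter] <- hit
  }
  out
}

#' Filter and pseudocount the four screen datasets
#'
#' Builds the guide-level datasets A1, B1, C1, D1 (A = ZT16 vehicle,
#' B = ZT16 drug, C = ZT28 vehicle, D = ZT28 drug): nontargeting guides are
#' removed, guides failing the zero filter (on the pre-pseudocount values,
#' per `zero_filter_scope`) are removed, and the pseudocount is added to
#' every remaining value in every dataset. All four datasets share one
#' guide index. The baseline sample, if present, takes no part.
#'
#' @param norm A [median_normalize()] result whose design has exactly one
#'   screen sample per (timepoint x treatment) cell.
#' @param params A [hitcall_params()].
#' @return Tibble `guide_id`, `gene`, `A1`, `B1`, `C1`, `D1`.
#' @export
prepare_datasets <- function(norm, params = hitcall_params()) {
  ds <- dataset_samples(sample_design(norm))
  keep <- norm$gene != NTC_LABEL
  vals <- as.matrix(norm[unname(ds)])
  zero_fail <- if (params$zero_filter_scope == "any_sample") {
    rowSums(vals == 0) > 0
  } else {
    rowSums(vals == 0) == ncol(vals)
  }
  keep <- keep & !zero_fail
  if (!any(keep)) {
    abort("no guide survives the nontargeting/zero filter")
  }
  tibble::tibble(
    guide_id = norm$guide_id[keep],
    gene = norm$gene[keep],
    A1 = unname(vals[keep, 1L]) + params$pseudocount,
    B1 = unname(vals[keep, 2L]) + params$pseudocount,
    C1 = unname(vals[keep, 3L]) + params$pseudocount,
    D1 = unname(vals[keep, 4L]) + params$pseudocount)
}

#' Apply the per-guide fold-change gates
#'
#' Computes the drug/vehicle ratios r16 = B1/A1 and r28 = D1/C1 and the
#' gate memberships: B2 (r16 >= up), A2 (r16 < down), D2 (r28 >= up),
#' C2 (r28 < down). Threshold inclusivity follows the stated inequalities:
#' the enrichment gates are inclusive, the depletion gates strict. Ratios
#' are quotients of decimal-rounded (12 places) values so that gate
#' membership is platform-stable.
#'
#' @param prepared Output of [prepare_datasets()].
#' @param params A [hitcall_params()].
#' @return `prepared` with added columns `r16`, `r28`, `in_A2`, `in_B2`,
#'   `in_C2`, `in_D2`.
#' @export
guide_gates <- function(prepared, params = hitcall_params()) {
  dplyr::mutate(
    prepared,
    r16 = round_stable(.data$B1) / round_stable(.data$A1),
    r28 = round_stable(.data$D1) / round_stable(.data$C1),
    in_B2 = .data$r16 >= params$up_threshold,
    in_A2 = .data$r16 < params$down_threshold,
    in_D2 = .data$r28 >= params$up_threshold,
    in_C2 = .data$r28 < params$down_threshold)
}

## one side of the gene-level call: concordance (>= k gated guides, the
## primed set) or single strong guide (the double-primed set)
gene_side <- function(gates, in_col, ratio_col, strong_test, params) {
  by_gene <- dplyr::summarise(
    dplyr::group_by(gates, .data$gene),
    n_gated = sum(.data[[in_col]]),
    n_strong = sum(strong_test(.data[[ratio_col]])),
    .groups = "drop")
  dplyr::transmute(
    by_gene,
    gene = .data$gene,
    primed = .data$n_gated >= params$min_concordant_guides,
    double_primed = .data$n_strong >= 1L,
    called = .data$primed | .data$double_primed)
}

#' Gene-level calls from gated guides
#'
#' A gene enters a timepoint's call set either by concordance (at least
#' `min_concordant_guides` distinct guides in the gate, the primed sets
#' A2'..D2') or through a single strong-effect guide (ratio >= `strong_up`
#' or < `strong_down`, the double-primed sets A2''..D2''). The call sets
#' are the unions: A3 = A2' u A2'' (ZT16 sensitivity), B3 = B2' u B2''
#' (ZT16 resistance), C3/D3 the ZT28 analogues.
#'
#' @param gates Output of [guide_gates()].
#' @param params A [hitcall_params()].
#' @return Tibble with one row per gene and logical columns
#'   `A2p`, `A2pp`, `A3`, ..., `D2p`, `D2pp`, `D3`.
#' @export
gene_calls <- function(gates, params = hitcall_params()) {
  up <- function(r) r >= params$strong_up
  down <- function(r) r < params$strong_down
  sides <- list(
    A = gene_side(gates, "in_A2", "r16", down, params),
    B = gene_side(gates, "in_B2", "r16", up, params),
    C = gene_side(gates, "in_C2", "r28", down, params),
    D = gene_side(gates, "in_D2", "r28", up, params))
  out <- tibble::tibble(gene = sort(unique(gates$gene)))
  for (letter in names(sides)) {
    s <- sides[[letter]]
    i <- match(out$gene, s$gene)
    out[[paste0(letter, "2p")]] <- s$primed[i]
    out[[paste0(letter, "2pp")]] <- s$double_primed[i]
    out[[paste0(letter, "3")]] <- s$called[i]
  }
  out
}

#' Time-specific gene sets by set difference
#'
#' The timepoint-shared genes are removed by intersecting the per-timepoint
#' calls: B4 = B3 \\ D3 and D4 = D3 \\ B3 (time-specific resistance),
#' A4 = A3 \\ C3 and C4 = C3 \\ A3 (time-specific sensitivity). The shared
#' intersections B3 n D3 and A3 n C3 are reported separately.
#'
#' @param genes Output of [gene_calls()].
#' @return `genes` with added logical columns `A4`, `B4`, `C4`, `D4`,
#'   `shared_res` (B3 n D3) and `shared_sen` (A3 n C3).
#' @export
time_specific_sets <- function(genes) {
  dplyr::mutate(
    genes,
    A4 = .data$A3 & !.data$C3,
    C4 = .data$C3 & !.data$A3,
    B4 = .data$B3 & !.data$D3,
    D4 = .data$D3 & !.data$B3,
    shared_sen = .data$A3 & .data$C3,
    shared_res = .data$B3 & .data$D3)
}

#' Run the full hit-calling algebra
#'
#' Composes [prepare_datasets()], [guide_gates()], [gene_calls()] and
#' [time_specific_sets()] into the full dataset ledger, keeping every
#' intermediate: per-guide filtered values and ratios, guide gate sets,
#' gene-level primed/double-primed provenance, the per-timepoint call sets
#' and the final time-specific sets.
#'
#' @param norm A [median_normalize()] result.
#' @param params A [hitcall_params()].
#' @return An object of class `chrono_hitcall`: a list with `guides` (the
#'   guide-level ledger), `genes` (the gene-level ledger with an
#'   `admitted_by` provenance string per called gene), `sets` (named list
#'   of character vectors: guide sets A2, B2, C2, D2 and gene sets A2p..D3,
#'   A4..D4, shared_sen, shared_res) and `params`. See [tidy.chrono_hitcall()]
#'   and [glance.chrono_hitcall()].
#' @export
run_hitcall <- function(norm, params = hitcall_params()) {
  guides <- guide_gates(prepare_datasets(norm, params), params)
  genes <- time_specific_sets(gene_calls(guides, params))

  rule <- function(p, pp) {
    dplyr::case_when(p & pp ~ "concordance+strong", p ~ "concordance",
                     pp ~ "strong", .default = NA_character_)
  }
  genes$admitted_A3 <- rule(genes$A2p, genes$A2pp)
  genes$admitted_B3 <- rule(genes$B2p, genes$B2pp)
  genes$admitted_C3 <- rule(genes$C2p, genes$C2pp)
  genes$admitted_D3 <- rule(genes$D2p, genes$D2pp)

  gene_set <- function(col) genes$gene[genes[[col]]]
  sets <- c(
    list(A2 = guides$guide_id[guides$in_A2], B2 = guides$guide_id[guides$in_B2],
         C2 = guides$guide_id[guides$in_C2], D2 = guides$guide_id[guides$in_D2]),
    purrr::map(setNames(nm = c("A2p", "A2pp", "A3", "B2p", "B2pp", "B3",
                               "C2p", "C2pp", "C3", "D2p", "D2pp", "D3",
                               "A4", "B4", "C4", "D4",
                               "shared_sen", "shared_res")), gene_set))
  structure(list(guides = guides, genes = genes, sets = sets, params = params),
            class = "chrono_hitcall")
}

#' @export
print.chrono_hitcall <- function(x, ...) {
  cat("<chrono_hitcall>", nrow(x$guides), "guides,", nrow(x$genes),
      "genes after filtering\n")
  sz <- glance(x)
  cat("  ZT16: sensitivity A3 =", sz$A3, "(A4 specific:", sz$A4,
      ") resistance B3 =", sz$B3, "(B4 specific:", sz$B4, ")\n")
  cat("  ZT28: sensitivity C3 =", sz$C3, "(C4 specific:", sz$C4,
      ") resistance D3 =", sz$D3, "(D4 specific:", sz$D4, ")\n")
  invisible(x)
}

#' Extract a hit set from a fitted ledger
#'
#' @param x A `chrono_hitcall` object.
#' @param set Set name (e.g. `"B4"` for ZT16-specific resistance genes,
#'   `"C4"` for ZT28-specific sensitivity genes, `"B2"` for the ZT16
#'   enriched guide set).
#' @return Character vector of gene symbols (guide ids for the `*2` sets).
#' @export
hit_set <- function(x, set) {
  stopifnot(inherits(x, "chrono_hitcall"))
  if (!set %in% names(x$sets)) {
    abort(paste0("unknown set; available: ", paste(names(x$sets), collapse = ", ")))
  }
  x$sets[[set]]
}

#' Write the dataset ledger to disk
#'
#' Emits the guide-level TSV (values, ratios, gate flags), the gene-level
#' TSV (memberships and admitting rules) and a YAML sidecar echoing the
#' parameters for provenance.
#'
#' @param x A `chrono_hitcall` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_hitcall <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(x$guides, file.path(dir, "hitcall_guides.tsv"), progress = FALSE)
  readr::write_tsv(x$genes, file.path(dir, "hitcall_genes.tsv"), progress = FALSE)
  yaml::write_yaml(unclass(x$params), file.path(dir, "hitcall_params.yaml"))
  invisible(dir)
}
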