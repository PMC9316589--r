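#' Read / write gene-set collections in GMT format
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then member genes. Duplicate members within a set are collapsed.
#'
#' @param path Path to a GMT file.
#' @return `read_gmt()` returns a named list of character vectors.
#' @export
read_gmt <- function(path) {
  assert_file(path, "GMT file")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  n_fields <- lengths(strsplit(lines, "\t", fixed = TRUE))
  bad <- which(n_fields < 3L)
  if (length(bad)) {
    abort(sprintf("malformed GMT line(s) (< 3 tab-separated fields): %s",
                  paste(head(bad, 10L), collapse = ", ")))
  }
  sets <- purrr::map(fgsea::gmtPathways(path), unique)
  if (anyDuplicated(names(sets))) {
    abort("duplicate set names in GMT")
  }
  sets
}

#' @rdname read_gmt
#' @param sets Named list of character vectors.
#' @param descriptions Optional character vector of per-set descriptions
#'   (defaults to the set names).
#' @export
write_gmt <- function(sets, path, descriptions = names(sets)) {
  descriptions <- setNames(rep_len(descriptions, length(sets)), names(sets))
  lines <- purrr::imap_chr(sets, function(members, nm) {
    paste(c(nm, descriptions[[nm]], members), collapse = "\t")
  })
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric over-representation of a gene set
#'
#' For each pathway, tests whether the query gene set overlaps it more than
#' expected by chance when drawing `n` genes from a universe of `N`:
#' `p = P(X >= k)` for `X ~ Hypergeometric(N, K, n)`, with `k` the observed
#' overlap and `K` the pathway size, both after intersection with the
#' universe. p-values are BH-adjusted across all sets in the collection.
#' The universe should normally be the genes actually screened (all
#' targeting genes in the library), not the whole genome.
#'
#' @param query Character vector of gene symbols.
#' @param sets Named list of gene sets (e.g. from [read_gmt()]).
#' @param universe Character vector: the background gene list.
#' @return A tibble of class `screen_enrichment`, one row per set, sorted
#'   by `p`: `set`, `k` (overlap), `n` (query size in universe), `K` (set
#'   size in universe), `N` (universe size), `ratio` (k/n), `p`, `q`
#'   (BH-adjusted).
#' @export
#' @examples
#' enrich(c("a", "b", "c", "d"),
#'        list(S = c("a", "b", "c", "d", "e")),
#'        universe = letters[1:10])  # p = 5/210
enrich <- function(query, sets, universe) {
  if (is.null(names(sets)) || anyDuplicated(names(sets))) {
    abort("sets must be uniquely named")
  }
  universe <- unique(universe)
  query <- intersect(unique(query), universe)
  if (length(query) == 0L) {
    abort("query has no genes in the universe")
  }
  sets_u <- purrr::map(sets, intersect, universe)
  empty <- lengths(sets_u) == 0L
  if (any(empty)) {
    warn(sprintf("dropping %d set(s) with no gene in the universe", sum(empty)))
    sets_u <- sets_u[!empty]
  }
  if (length(sets_u) == 0L) {
    abort("no set overlaps the universe")
  }
  N <- length(universe)
  n <- length(query)
  res <- purrr::imap_dfr(sets_u, function(members, nm) {
    K <- length(members)
    k <- length(intersect(query, members))
    tibble::tibble(set = nm, k = k, n = n, K = K, N = N, ratio = k / n,
                   p = phyper(k - 1, K, N - K, n, lower.tail = FALSE))
  })
  res$q <- p.adjust(res$p, method = "BH")
  res <- dplyr::arrange(res, .data$p, .data$set)
  class(res) <- unique(c("screen_enrichment", class(res)))
  res
}

#' Intersect two enriched-pathway lists
#'
#' The Venn partition of pathway names significant (q < `q_cut`) in two
#' enrichment tables computed against the same collection — e.g. pathways
#' enriched both in a CRISPR hit set and in a differential-expression gene
#' set.
#'
#' @param rows_a,rows_b Two [enrich()] results over the same collection.
#' @param q_cut BH-adjusted significance cutoff (default 0.05).
#' @return A list with `shared`, `a_only`, `b_only` character vectors of
#'   set names.
#' @export
intersect_enrichments <- function(rows_a, rows_b, q_cut = 0.05) {
  if (!setequal(rows_a$set, rows_b$set)) {
    abort("the two enrichment tables were not computed against the same collection")
  }
  sig_a <- rows_a$set[rows_a$q < q_cut]
  sig_b <- rows_b$set[rows_b$q < q_cut]
  list(shared = sort(intersect(sig_a, sig_b)),
       a_only = sort(setdiff(sig_a, sig_b)),
       b_only = sort(setdiff(sig_b, sig_a)))
}
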