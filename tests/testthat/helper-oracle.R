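# Independent straight-line oracles, deliberately naive: plain loops and
# base R only, no calls into the package's own code paths.

# Full hit-calling procedure from raw counts: median normalization,
# nontargeting/zero filtering, pseudocount, per-guide gates, gene-level
# concordance/strong-guide calls, time-specific set differences.
oracle_hitcall <- function(counts_df, design,
                           up = 2, down = 0.5, strong_up = 5, strong_down = 0.2,
                           min_guides = 2L, pseudocount = 1,
                           scope = "any_sample") {
  pick <- function(tp, tr) {
    design$sample[design$role == "screen" & design$timepoint == tp &
                    design$treatment == tr]
  }
  sn <- c(A = pick("ZT16", "vehicle"), B = pick("ZT16", "drug"),
          C = pick("ZT28", "vehicle"), D = pick("ZT28", "drug"))

  # median scaling, by loop
  meds <- numeric(4)
  for (i in 1:4) meds[i] <- median(counts_df[[sn[i]]])
  ref <- median(meds)
  norm <- list()
  for (i in 1:4) norm[[i]] <- counts_df[[sn[i]]] / (meds[i] / ref)

  keep <- logical(nrow(counts_df))
  for (r in seq_len(nrow(counts_df))) {
    if (counts_df$gene[r] == "non-targeting") next
    zeros <- sum(norm[[1]][r] == 0, norm[[2]][r] == 0,
                 norm[[3]][r] == 0, norm[[4]][r] == 0)
    keep[r] <- if (scope == "any_sample") zeros == 0 else zeros < 4
  }
  idx <- which(keep)
  guide_id <- counts_df$guide_id[idx]
  gene <- counts_df$gene[idx]
  A1 <- norm[[1]][idx] + pseudocount
  B1 <- norm[[2]][idx] + pseudocount
  C1 <- norm[[3]][idx] + pseudocount
  D1 <- norm[[4]][idx] + pseudocount
  r16 <- round(B1, 12) / round(A1, 12)
  r28 <- round(D1, 12) / round(C1, 12)

  in_set <- function(r, type) {
    if (type == "up") r >= up else r < down
  }
  gates <- list(A2 = guide_id[in_set(r16, "down")],
                B2 = guide_id[in_set(r16, "up")],
                C2 = guide_id[in_set(r28, "down")],
                D2 = guide_id[in_set(r28, "up")])

  genes <- sort(unique(gene))
  call_side <- function(ratios, type) {
    primed <- character(0)
    strong <- character(0)
    for (g in genes) {
      rs <- ratios[gene == g]
      n_gate <- 0L
      n_str <- 0L
      for (v in rs) {
        if (type == "up") {
          if (v >= up) n_gate <- n_gate + 1L
          if (v >= strong_up) n_str <- n_str + 1L
        } else {
          if (v < down) n_gate <- n_gate + 1L
          if (v < strong_down) n_str <- n_str + 1L
        }
      }
      if (n_gate >= min_guides) primed <- c(primed, g)
      if (n_str >= 1L) strong <- c(strong, g)
    }
    list(primed = primed, strong = strong,
         called = sort(union(primed, strong)))
  }
  A <- call_side(r16, "down")
  B <- call_side(r16, "up")
  C <- call_side(r28, "down")
  D <- call_side(r28, "up")

  list(guide_id = guide_id, gene = gene,
       A1 = A1, B1 = B1, C1 = C1, D1 = D1, r16 = r16, r28 = r28,
       A2 = gates$A2, B2 = gates$B2, C2 = gates$C2, D2 = gates$D2,
       A2p = A$primed, A2pp = A$strong, A3 = A$called,
       B2p = B$primed, B2pp = B$strong, B3 = B$called,
       C2p = C$primed, C2pp = C$strong, C3 = C$called,
       D2p = D$primed, D2pp = D$strong, D3 = D$called,
       A4 = sort(setdiff(A$called, C$called)),
       C4 = sort(setdiff(C$called, A$called)),
       B4 = sort(setdiff(B$called, D$called)),
       D4 = sort(setdiff(D$called, B$called)))
}

# random small screen for oracle-equivalence checks: mixes zero counts,
# nontargeting guides and variable guides-per-gene
random_small_screen <- function(seed) {
  set.seed(seed)
  n_genes <- sample(3:12, 1)
  gpg <- sample(1:4, n_genes, replace = TRUE)
  gene <- rep(sprintf("G%02d", seq_len(n_genes)), gpg)
  n_ntc <- sample(0:5, 1)
  gene <- c(gene, rep("non-targeting", n_ntc))
  n <- length(gene)
  guide_id <- paste0(gene, "_", unlist(lapply(table(factor(gene, unique(gene))),
                                              seq_len)))
  mk <- function() {
    v <- rnbinom(n, mu = sample(c(5, 20, 80), 1), size = 2)
    v[sample(n, floor(n / 8))] <- 0L
    v
  }
  counts <- tibble::tibble(guide_id = guide_id, gene = gene,
                           zt16_vehicle = mk(), zt16_drug = mk(),
                           zt28_vehicle = mk(), zt28_drug = mk())
  # medians must be positive for median scaling
  for (s in c("zt16_vehicle", "zt16_drug", "zt28_vehicle", "zt28_drug")) {
    if (median(counts[[s]]) == 0) counts[[s]] <- counts[[s]] + 1L
  }
  counts
}

# exact hypergeometric upper tail by brute-force combinatorial sum
oracle_hyper_p <- function(k, K, n, N) {
  tot <- 0
  for (i in k:min(n, K)) {
    tot <- tot + choose(K, i) * choose(N - K, n - i)
  }
  tot / choose(N, n)
}
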