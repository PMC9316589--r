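test_that("parameter invariants are enforced", {
  expect_error(hitcall_params(up_threshold = 6), "strong_up")
  expect_error(hitcall_params(min_concordant_guides = 1), ">= 2")
  expect_error(hitcall_params(pseudocount = 0), "pseudocount")
})

test_that("dataset preparation filters nontargeting and zero guides", {
  tbl <- tibble::tibble(
    guide_id = c("a", "b", "c", "d"),
    gene = c("G1", "G1", "G2", "non-targeting"),
    zt16_vehicle = c(10L, 10L, 1L, 50L),
    zt16_drug = c(20L, 20L, 1L, 50L),
    zt28_vehicle = c(10L, 10L, 1L, 50L),
    zt28_drug = c(0L, 20L, 1L, 50L))
  norm <- median_normalize(screen_counts(tbl, screen_design_4()))

  any_scope <- prepare_datasets(norm, hitcall_params())
  # guide "a" has a zero in one screen sample; NTC removed despite high counts
  expect_equal(any_scope$guide_id, c("b", "c"))
  all_scope <- prepare_datasets(
    norm, hitcall_params(zero_filter_scope = "all_samples"))
  expect_equal(all_scope$guide_id, c("a", "b", "c"))
  # pseudocount lands after filtering, on every retained value
  expect_equal(all_scope$D1[all_scope$guide_id == "a"],
               0 / unname(size_factors(norm)["zt28_drug"]) + 1)

  all_zero <- tbl
  all_zero[1, c("zt16_vehicle", "zt16_drug", "zt28_vehicle", "zt28_drug")] <-
    list(0L, 0L, 0L, 0L)
  norm0 <- median_normalize(screen_counts(all_zero, screen_design_4()),
                            method = "median_ratio")
  expect_false("a" %in% prepare_datasets(
    norm0, hitcall_params(zero_filter_scope = "all_samples"))$guide_id)
})

test_that("a missing design cell is reported by name", {
  tbl <- toy_counts()
  design <- screen_design_4()
  design$treatment[2] <- "vehicle"  # two ZT16 vehicles, no ZT16 drug
  broken <- screen_counts(tibble::as_tibble(tbl), design)
  expect_error(run_hitcall(median_normalize(broken)),
               "ZT16 vehicle \\(dataset A\\), found 2")
})

test_that("gate inclusivity follows the stated inequalities", {
  tbl <- tibble::tibble(
    guide_id = paste0("g", 1:4), gene = paste0("G", 1:4),
    zt16_vehicle = 10L, zt16_drug = c(20L, 5L, 10L, 2L),
    zt28_vehicle = 10L, zt28_drug = 10L)
  # after +1: r16 = 21/11, 6/11, 1, 3/11 -- build exact boundary cases instead
  prepared <- tibble::tibble(
    guide_id = paste0("g", 1:4), gene = paste0("G", 1:4),
    A1 = c(10, 10, 10, 10), B1 = c(20, 5, 10, 2),
    C1 = c(10, 10, 10, 10), D1 = c(10, 10, 10, 10))
  gates <- guide_gates(prepared, hitcall_params())
  expect_true(gates$in_B2[1])    # ratio exactly 2 is enriched (inclusive)
  expect_false(gates$in_A2[2])   # ratio exactly 0.5 is NOT depleted (strict)
  expect_false(gates$in_B2[3] || gates$in_A2[3])  # ratio 1 in neither
  expect_true(gates$in_A2[4])    # ratio 0.2 depleted
  # strong-guide rescue boundaries: >= 5 inclusive, < 0.2 strict
  genes <- gene_calls(gates, hitcall_params())
  expect_false(genes$A2pp[genes$gene == "G4"])  # 0.2 exactly: no rescue
  prepared$B1[4] <- 50
  genes2 <- gene_calls(guide_gates(prepared, hitcall_params()),
                       hitcall_params())
  expect_true(genes2$B2pp[genes2$gene == "G4"])  # 5.0 exactly: rescued
})

test_that("the toy screen reproduces the full hand-traced ledger", {
  hc <- run_hitcall(toy_norm(extra_ntc = 2L))
  expect_setequal(hit_set(hc, "B2"), c("g1_1", "g1_2", "g2_1"))
  expect_setequal(hit_set(hc, "A2"), c("g3_1", "g3_2"))
  expect_equal(hit_set(hc, "B2p"), "g1")
  expect_equal(hit_set(hc, "B2pp"), "g2")
  expect_setequal(hit_set(hc, "B3"), c("g1", "g2"))
  expect_equal(hit_set(hc, "A2p"), "g3")
  expect_equal(hit_set(hc, "A2pp"), character(0))
  expect_equal(hit_set(hc, "A3"), "g3")
  expect_equal(hit_set(hc, "D3"), "g1")
  expect_equal(hit_set(hc, "D2p"), "g1")
  expect_equal(hit_set(hc, "D2pp"), character(0))
  expect_equal(hit_set(hc, "C3"), "g3")
  expect_equal(hit_set(hc, "C2p"), character(0))
  expect_equal(hit_set(hc, "C2pp"), "g3")
  expect_equal(hit_set(hc, "B4"), "g2")
  expect_equal(hit_set(hc, "D4"), character(0))
  expect_equal(hit_set(hc, "A4"), character(0))
  expect_equal(hit_set(hc, "C4"), character(0))
  expect_equal(hit_set(hc, "shared_res"), "g1")
  expect_equal(hit_set(hc, "shared_sen"), "g3")
})

test_that("ledger set-algebra invariants hold on the toy screen", {
  hc <- run_hitcall(toy_norm(extra_ntc = 3L))
  expect_length(intersect(hit_set(hc, "B4"), hit_set(hc, "D4")), 0)
  expect_length(intersect(hit_set(hc, "A4"), hit_set(hc, "C4")), 0)
  expect_length(intersect(hit_set(hc, "A2"), hit_set(hc, "B2")), 0)
  expect_true(all(hit_set(hc, "B4") %in% hit_set(hc, "B3")))
  expect_true(all(hit_set(hc, "A4") %in% hit_set(hc, "A3")))
  # no nontargeting label anywhere
  expect_false("non-targeting" %in% hc$genes$gene)
  expect_false(any(grepl("^NTC_", unlist(hc$sets))))
})

test_that("hit calling equals the naive-loop oracle on random screens", {
  params <- hitcall_params()
  for (seed in 1:200) {
    cnt <- random_small_screen(seed)
    sc <- screen_counts(cnt, screen_design_4())
    hc <- run_hitcall(median_normalize(sc), params)
    oc <- oracle_hitcall(cnt, screen_design_4())
    expect_identical(hc$guides$guide_id, oc$guide_id)
    expect_equal(hc$guides$A1, oc$A1)
    expect_equal(hc$guides$r16, oc$r16)
    for (s in c("A2", "B2", "C2", "D2", "A2p", "A2pp", "A3", "B2p", "B2pp",
                "B3", "C2p", "C2pp", "C3", "D2p", "D2pp", "D3",
                "A4", "B4", "C4", "D4")) {
      expect_setequal(hit_set(hc, s), oc[[s]])
    }
  }
})

test_that("oracle equivalence holds under non-default parameters", {
  params <- hitcall_params(up_threshold = 3, down_threshold = 1 / 3,
                           strong_up = 6, strong_down = 0.1,
                           min_concordant_guides = 3L, pseudocount = 0.5,
                           zero_filter_scope = "all_samples")
  for (seed in 201:260) {
    cnt <- random_small_screen(seed)
    sc <- screen_counts(cnt, screen_design_4())
    hc <- run_hitcall(median_normalize(sc), params)
    oc <- oracle_hitcall(cnt, screen_design_4(), up = 3, down = 1 / 3,
                         strong_up = 6, strong_down = 0.1, min_guides = 3L,
                         pseudocount = 0.5, scope = "all_samples")
    for (s in c("A2", "B2", "C2", "D2", "A3", "B3", "C3", "D3",
                "A4", "B4", "C4", "D4")) {
      expect_setequal(hit_set(hc, s), oc[[s]])
    }
  }
})

test_that("raising the enrichment gate never enlarges the enriched sets", {
  cnt <- random_small_screen(999)
  norm <- median_normalize(screen_counts(cnt, screen_design_4()))
  sizes <- purrr::map(c(1.5, 2, 3, 4.99), function(up) {
    hc <- run_hitcall(norm, hitcall_params(up_threshold = up))
    purrr::map_int(hc$sets[c("B2", "B2p", "B3", "B4")], length)
  })
  for (i in seq_len(length(sizes) - 1L)) {
    expect_true(all(sizes[[i + 1L]][c("B2", "B2p", "B3")] <=
                      sizes[[i]][c("B2", "B2p", "B3")]))
  }
  # dually, tightening the depletion gate shrinks the depleted sets
  dsizes <- purrr::map(c(0.5, 0.4, 0.21), function(down) {
    hc <- run_hitcall(norm, hitcall_params(down_threshold = down))
    purrr::map_int(hc$sets[c("A2", "A2p", "A3")], length)
  })
  for (i in seq_len(length(dsizes) - 1L)) {
    expect_true(all(dsizes[[i + 1L]] <= dsizes[[i]]))
  }
})

test_that("hit calling is invariant to guide order", {
  cnt <- random_small_screen(77)
  norm <- median_normalize(screen_counts(cnt, screen_design_4()))
  set.seed(78)
  perm <- sample(nrow(cnt))
  norm_p <- median_normalize(screen_counts(cnt[perm, ], screen_design_4()))
  h1 <- run_hitcall(norm)
  h2 <- run_hitcall(norm_p)
  for (s in names(h1$sets)) {
    expect_setequal(h1$sets[[s]], h2$sets[[s]])
  }
})

test_that("tidy and glance summarise the ledger faithfully", {
  hc <- run_hitcall(toy_norm())
  td <- tidy(hc)
  expect_setequal(td$gene[td$set == "B3"], c("g1", "g2"))
  expect_equal(td$time_specific[td$gene == "g2" & td$set == "B3"], TRUE)
  expect_equal(td$admitted_by[td$gene == "g2" & td$set == "B3"], "strong")
  expect_equal(td$admitted_by[td$gene == "g1" & td$set == "B3"], "concordance")
  gl <- glance(hc)
  expect_equal(gl$B3, 2L)
  expect_equal(gl$B4, 1L)
  expect_equal(gl$n_genes, 3L)
})

test_that("null-screen false-call counts agree with a Monte-Carlo oracle", {
  # no planted effects, deliberately noisy counts (dispersion 0.2) so the
  # gates fire occasionally; the pipeline's per-screen false-call totals
  # must be statistically indistinguishable from the naive-loop oracle run
  # on independent replicate screens
  lib <- simulate_guide_library(200, 3, 50, seed = 61L)
  null_cfg <- function(s) {
    sim_config(lib, mean_coverage = 300, dispersion = 0.2,
               effect_multiplier = 1, n_zt16_specific = 0L,
               n_zt28_specific = 0L, n_shared = 0L, seed = s)
  }
  n_rep <- 30L
  pipe_tot <- vapply(seq_len(n_rep), function(i) {
    sim <- simulate_counts(null_cfg(1000L + i))
    hc <- run_hitcall(median_normalize(sim$counts))
    sum(lengths(hc$sets[c("A4", "B4", "C4", "D4")]))
  }, 0)
  oracle_tot <- vapply(seq_len(n_rep), function(i) {
    sim <- simulate_counts(null_cfg(2000L + i))
    oc <- oracle_hitcall(tibble::as_tibble(sim$counts)[
      c("guide_id", "gene", "zt16_vehicle", "zt16_drug",
        "zt28_vehicle", "zt28_drug")], screen_design_4())
    length(oc$A4) + length(oc$B4) + length(oc$C4) + length(oc$D4)
  }, 0)
  se <- sqrt(var(pipe_tot) / n_rep + var(oracle_tot) / n_rep)
  expect_lt(abs(mean(pipe_tot) - mean(oracle_tot)), 4 * se + 1)
  # and the false-call burden stays a minority of the gene-set slots
  expect_lt(mean(pipe_tot) / (4 * 200), 0.25)
})
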