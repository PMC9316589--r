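# Shared fixtures, built in code.

screen_design_4 <- function() {
  tibble::tibble(
    sample    = c("zt16_vehicle", "zt16_drug", "zt28_vehicle", "zt28_drug"),
    timepoint = c("ZT16", "ZT16", "ZT28", "ZT28"),
    treatment = c("vehicle", "drug", "vehicle", "drug"),
    role      = "screen")
}

# Worked toy screen: three genes x three guides, all vehicle values 10.
# g1 is enriched at both timepoints, g2 only at ZT16 (via one strong guide),
# g3 is depleted at ZT16 by concordance and at ZT28 via one strong guide.
toy_counts <- function(extra_ntc = 0L) {
  tbl <- tibble::tibble(
    guide_id = paste0(rep(paste0("g", 1:3), each = 3L), "_", rep(1:3, 3L)),
    gene = rep(paste0("g", 1:3), each = 3L),
    zt16_vehicle = 10L,
    zt16_drug = c(40L, 25L, 10L, 60L, 10L, 10L, 4L, 3L, 10L),
    zt28_vehicle = 10L,
    zt28_drug = c(40L, 25L, 10L, 10L, 10L, 10L, 1L, 10L, 10L))
  if (extra_ntc > 0L) {
    ntc <- tibble::tibble(
      guide_id = sprintf("NTC_%04d", seq_len(extra_ntc)),
      gene = "non-targeting",
      zt16_vehicle = 10L, zt16_drug = 50L, zt28_vehicle = 10L, zt28_drug = 50L)
    tbl <- dplyr::bind_rows(tbl, ntc)
  }
  screen_counts(tbl, screen_design_4())
}

toy_norm <- function(...) median_normalize(toy_counts(...))

tiny_library <- function(n_genes = 4L, n_ntc = 2L, seed = 42L) {
  simulate_guide_library(n_genes, guides_per_gene = 3L, n_nontargeting = n_ntc,
                         seed = seed)
}

# small gene-set collection over genes of a simulated library
tiny_gmt <- function(path, universe) {
  sets <- list(
    setA = universe[seq(1L, min(10L, length(universe)))],
    setB = universe[seq(3L, min(12L, length(universe)))],
    setC = rev(universe)[seq_len(min(5L, length(universe)))])
  write_gmt(sets, path)
  sets
}
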