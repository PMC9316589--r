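# helper: write a plain-text FASTQ from read sequences
write_fastq <- function(reads, path, ids = paste0("r", seq_along(reads))) {
  con <- gzfile(path, "w")
  on.exit(close(con))
  for (i in seq_along(reads)) {
    writeLines(c(paste0("@", ids[i]), reads[i], "+",
                 strrep("I", nchar(reads[i]))), con)
  }
  invisible(path)
}

test_that("exact matching assigns, rejects mismatches, discards ambiguous", {
  lib <- tiny_library(n_genes = 2L, n_ntc = 1L)
  sp <- lib$spacer
  mism <- sp[1]
  substr(mism, 10, 10) <- setdiff(c("A", "C", "G", "T"),
                                  substr(sp[1], 10, 10))[1]
  reads <- c(
    paste0("AAAAA", sp[1], "TTTTT"),          # clean hit for guide 1
    paste0("AAAAA", mism, "TTTTT"),           # one substitution -> unmapped
    paste0(sp[2], sp[3]),                     # two guides -> ambiguous
    paste0("CCC", sp[1]))                     # hit at a different offset
  fq <- withr::local_tempfile(fileext = ".fastq.gz")
  write_fastq(reads, fq)
  res <- count_reads(lib, c(s1 = fq), mode = "scan")
  expect_equal(res$counts$s1[1], 2L)
  expect_equal(sum(res$counts$s1), 2L)
  expect_equal(res$stats$total_reads, 4L)
  expect_equal(res$stats$mapped_reads, 2L)
  expect_equal(res$stats$ambiguous_reads, 1L)
  expect_equal(res$stats$unmapped_reads, 1L)
  # conservation: mapped + unmapped + ambiguous = total
  expect_equal(with(res$stats, mapped_reads + unmapped_reads + ambiguous_reads),
               res$stats$total_reads)
})

test_that("fixed-offset mode only looks at the declared position", {
  lib <- tiny_library(n_genes = 2L, n_ntc = 0L)
  reads <- c(paste0("AAAAA", lib$spacer[1], "TTTTT"),
             paste0("AAAA", lib$spacer[2], "TTTTTT"))
  fq <- withr::local_tempfile(fileext = ".fastq.gz")
  write_fastq(reads, fq)
  res <- count_reads(lib, c(s1 = fq), mode = "fixed_offset", offset = 6L)
  expect_equal(res$counts$s1[1], 1L)
  expect_equal(res$counts$s1[4], 0L)
  expect_error(count_reads(lib, c(s1 = fq), mode = "fixed_offset"),
               "offset")
})

test_that("reverse-complement pass is opt-in", {
  lib <- tiny_library(n_genes = 1L, n_ntc = 0L)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(lib$spacer[1])))
  fq <- withr::local_tempfile(fileext = ".fastq.gz")
  write_fastq(paste0("AA", rc, "GGG"), fq)
  fwd <- count_reads(lib, c(s1 = fq), mode = "scan")
  both <- count_reads(lib, c(s1 = fq), mode = "scan",
                      reverse_complement = TRUE)
  expect_equal(sum(fwd$counts$s1), 0L)
  expect_equal(both$counts$s1[1], 1L)
})

test_that("counting is invariant to read order and additive over files", {
  lib <- tiny_library(n_genes = 3L, n_ntc = 1L)
  set.seed(31)
  reads <- paste0("GATTC", sample(lib$spacer, 60, replace = TRUE), "ACGTA")
  f1 <- withr::local_tempfile(fileext = ".fastq.gz")
  f2 <- withr::local_tempfile(fileext = ".fastq.gz")
  f3 <- withr::local_tempfile(fileext = ".fastq.gz")
  f12 <- withr::local_tempfile(fileext = ".fastq.gz")
  write_fastq(reads, f1)
  write_fastq(rev(reads), f2)
  write_fastq(reads[1:25], f3)
  write_fastq(c(reads[26:60], reads[1:25]), f12)
  c1 <- count_reads(lib, c(s = f1))$counts$s
  c2 <- count_reads(lib, c(s = f2))$counts$s
  expect_identical(c1, c2)
  c3 <- count_reads(lib, c(s = f3))$counts$s
  c4 <- count_reads(lib, c(s = f12))$counts$s
  expect_identical(c4 - c3, c1 - c3)  # concatenation sums count matrices
  expect_identical(c4, c1)
})

test_that("counting reproduces a simulated count matrix without contaminants", {
  lib <- simulate_guide_library(8, 3, 2, seed = 21L)
  cfg <- sim_config(lib, mean_coverage = 25, contaminant_fraction = 0,
                    n_zt16_specific = 1L, n_zt28_specific = 1L, n_shared = 0L,
                    seed = 22L)
  sim <- simulate_counts(cfg)
  dir <- withr::local_tempdir()
  info <- simulate_fastq(cfg, sim$counts, dir)
  res <- count_reads(lib, setNames(info$path, info$sample), mode = "scan",
                     design = sample_design(sim$counts))
  expect_equal(tibble::as_tibble(res$counts), tibble::as_tibble(sim$counts))
  expect_true(all(res$stats$mapping_rate == 100))
})

test_that("empty FASTQ warns and yields a zero-count sample", {
  lib <- tiny_library(n_genes = 1L, n_ntc = 0L)
  fq <- withr::local_tempfile(fileext = ".fastq.gz")
  con <- gzfile(fq, "w"); close(con)
  expect_warning(res <- count_reads(lib, c(s1 = fq)), "empty FASTQ")
  expect_equal(sum(res$counts$s1), 0L)
})

test_that("mapping report applies the threshold and coverage band", {
  stats <- tibble::tibble(sample = c("a", "b"),
                          total_reads = c(10L, 10L),
                          mapped_reads = c(8L, 7L),
                          ambiguous_reads = 0L,
                          unmapped_reads = c(2L, 3L),
                          mapping_rate = c(80, 70),
                          mean_coverage = c(150, 50),
                          median_coverage = c(150, 50),
                          zero_fraction = 0, gini = 0.1)
  rep <- mapping_report(stats, threshold_pct = 75)
  expect_equal(rep$mapping_pass, c(TRUE, FALSE))
  expect_equal(rep$coverage_in_band, c(TRUE, FALSE))
})

test_that("simulated contaminant fraction drives the mapping rate", {
  lib <- simulate_guide_library(30, 3, 5, seed = 41L)
  cfg <- sim_config(lib, mean_coverage = 40, contaminant_fraction = 0.2,
                    n_zt16_specific = 0L, n_zt28_specific = 0L, n_shared = 0L,
                    seed = 42L)
  sim <- simulate_counts(cfg)
  dir <- withr::local_tempdir()
  info <- simulate_fastq(cfg, sim$counts, dir)
  one <- info[info$sample == "baseline", ]
  res <- count_reads(lib, setNames(one$path, one$sample), mode = "scan")
  expect_gt(res$stats$mapping_rate, 78)
  expect_lt(res$stats$mapping_rate, 82)
})
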