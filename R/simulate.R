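## Canonical sample layout of a one-replicate chrono screen: a baseline
## taken before synchronisation plus the 2x2 (timepoint x treatment) cells.
screen_design_preset <- function() {
  tibble::tibble(
    sample    = c("baseline", "zt16_vehicle", "zt16_drug",
                  "zt28_vehicle", "zt28_drug"),
    timepoint = c("none", "ZT16", "ZT16", "ZT28", "ZT28"),
    treatment = c("none", "vehicle", "drug", "vehicle", "drug"),
    role      = c("baseline", "screen", "screen", "screen", "screen")
  )
}

#' Configure a synthetic chrono-screen simulation
#'
#' Parameters of the generative model used to emulate a pooled knockout
#' screen with timepoint-specific drug-fitness effects. Counts are negative
#' binomial around (guide abundance x coverage x treatment multiplier);
#' guide abundances are log-normal with mean 1; the effect multiplier acts
#' only on drugged samples of affected genes' effective guides.
#'
#' @param library A [guide_library()].
#' @param mean_coverage Target mean reads per guide (default 300, the upper
#'   end of the 100-300x representation band typical of such screens).
#' @param dispersion Negative-binomial overdispersion (variance =
#'   mu + dispersion * mu^2; default 0.01, the tight count-level
#'   reproducibility of a well-covered amplicon screen — most of the
#'   realised noise then comes from low-abundance guides via the Poisson
#'   term).
#' @param baseline_abundance_sdlog Log-normal sd of per-guide baseline
#'   abundance (default 0.5, a moderate post-cloning representation
#'   spread).
#' @param n_zt16_specific,n_zt28_specific,n_shared Numbers of planted genes
#'   with a drug effect only at ZT16, only at ZT28, or at both timepoints
#'   (defaults 20, 20, 10). Classes are disjoint and never include
#'   nontargeting guides.
#' @param effect_multiplier Fold applied to the mean of drugged samples for
#'   affected guides (default 8; values > 1 plant resistance, < 1
#'   sensitivity).
#' @param effective_guide_fraction Fraction of an affected gene's guides
#'   that actually carry the effect (default 1; real screens have inactive
#'   guides, so this can be lowered to stress gene-level concordance).
#' @param contaminant_fraction Fraction of simulated reads drawn from
#'   off-library random sequence (default 0); only used by
#'   [simulate_fastq()].
#' @param seed Integer seed; the same seed gives bit-identical output.
#' @return A `sim_config` list.
#' @export
sim_config <- function(library, mean_coverage = 300, dispersion = 0.01,
                       baseline_abundance_sdlog = 0.5,
                       n_zt16_specific = 20L, n_zt28_specific = 20L,
                       n_shared = 10L, effect_multiplier = 8,
                       effective_guide_fraction = 1,
                       contaminant_fraction = 0, seed = 1L) {
  if (mean_coverage <= 0 || dispersion <= 0) {
    abort("mean_coverage and dispersion must be > 0")
  }
  if (effect_multiplier <= 0) {
    abort("effect_multiplier must be > 0")
  }
  if (baseline_abundance_sdlog < 0) {
    abort("baseline_abundance_sdlog must be >= 0")
  }
  if (contaminant_fraction < 0 || contaminant_fraction >= 1) {
    abort("contaminant_fraction must be in [0, 1)")
  }
  if (effective_guide_fraction <= 0 || effective_guide_fraction > 1) {
    abort("effective_guide_fraction must be in (0, 1]")
  }
  n_target_genes <- length(unique(library$gene[!library$is_nontargeting]))
  if (n_zt16_specific + n_zt28_specific + n_shared > n_target_genes) {
    abort("more planted genes than targeting genes in the library")
  }
  structure(
    list(library = library, mean_coverage = mean_coverage,
         dispersion = dispersion,
         baseline_abundance_sdlog = baseline_abundance_sdlog,
         n_zt16_specific = as.integer(n_zt16_specific),
         n_zt28_specific = as.integer(n_zt28_specific),
         n_shared = as.integer(n_shared),
         effect_multiplier = effect_multiplier,
         effective_guide_fraction = effective_guide_fraction,
         contaminant_fraction = contaminant_fraction,
         seed = as.integer(seed)),
    class = "sim_config")
}

#' Simulate screen counts with planted chrono-specific effects
#'
#' Draws one five-sample screen (baseline plus the four timepoint x
#' treatment cells) from the model described in [sim_config()] and returns
#' the counts together with the planted ground truth.
#'
#' @param config A [sim_config()].
#' @return A list with `counts` (a [screen_counts()]) and `truth` (a tibble
#'   `gene`, `class`, `zt16_multiplier`, `zt28_multiplier`; genes not listed
#'   implicitly have multiplier 1 at both timepoints).
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  lib <- config$library
  design <- screen_design_preset()
  n <- nrow(lib)

  withr::with_seed(config$seed, {
    genes <- unique(lib$gene[!lib$is_nontargeting])
    n_plant <- config$n_zt16_specific + config$n_zt28_specific + config$n_shared
    planted <- sample(genes, n_plant)
    cls <- rep(c("zt16_specific", "zt28_specific", "shared"),
               c(config$n_zt16_specific, config$n_zt28_specific, config$n_shared))
    truth <- tibble::tibble(
      gene = planted, class = cls,
      zt16_multiplier = ifelse(cls %in% c("zt16_specific", "shared"),
                               config$effect_multiplier, 1),
      zt28_multiplier = ifelse(cls %in% c("zt28_specific", "shared"),
                               config$effect_multiplier, 1))

    sdl <- config$baseline_abundance_sdlog
    abundance <- rlnorm(n, meanlog = -sdl^2 / 2, sdlog = sdl)

    ## which guides of each planted gene carry the effect
    effective <- rep(TRUE, n)
    if (config$effective_guide_fraction < 1) {
      for (g in planted) {
        idx <- which(lib$gene == g)
        k <- max(1L, round(config$effective_guide_fraction * length(idx)))
        off <- sample(idx, length(idx) - k)
        effective[off] <- FALSE
      }
    }
    m16 <- rep(1, n)
    m28 <- rep(1, n)
    hit16 <- lib$gene %in% truth$gene[truth$zt16_multiplier != 1] & effective
    hit28 <- lib$gene %in% truth$gene[truth$zt28_multiplier != 1] & effective
    m16[hit16] <- config$effect_multiplier
    m28[hit28] <- config$effect_multiplier

    base_mu <- abundance * config$mean_coverage
    mu <- cbind(baseline     = base_mu,
                zt16_vehicle = base_mu,
                zt16_drug    = base_mu * m16,
                zt28_vehicle = base_mu,
                zt28_drug    = base_mu * m28)
    size <- 1 / config$dispersion
    counts <- matrix(0L, nrow = n, ncol = ncol(mu),
                     dimnames = list(NULL, colnames(mu)))
    for (j in seq_len(ncol(mu))) {
      counts[, j] <- rnbinom(n, size = size, mu = mu[, j])
    }
    out <- tibble::tibble(guide_id = lib$guide_id, gene = lib$gene)
    out <- dplyr::bind_cols(out, tibble::as_tibble(counts))
    list(counts = screen_counts(out, design), truth = truth)
  })
}

## Fixed amplicon layout for simulated reads: the spacer sits inside
## constant vector sequence (U6 promoter tail upstream, sgRNA scaffold
## downstream), so the counting stage can be exercised in both scan and
## fixed-offset modes.
FLANK5 <- "TTGTGGAAAGGACGAAACACCG"
FLANK3 <- "GTTTTAGAGCTAGAAATAGCAAGTTAAAATAAGGCTAGTCCGT"

#' Simulate per-sample FASTQ from a count matrix
#'
#' Writes one gzip FASTQ per sample. Each on-library read embeds the
#' guide's spacer at `spacer_offset` inside fixed flanking vector
#' sequence; the per-sample on-library read multiset matches the count
#' matrix exactly. A `contaminant_fraction` of reads (from the config) is
#' random off-library sequence, so the expected downstream mapping rate is
#' `100 * (1 - contaminant_fraction)` percent. Total reads per sample are
#' `round(sum(counts) / (1 - contaminant_fraction))`. Base qualities are a
#' constant 'I'.
#'
#' @param config The [sim_config()] the counts came from.
#' @param counts The [screen_counts()] from [simulate_counts()].
#' @param out_dir Output directory (created if needed).
#' @param read_length Read length in nt (default 50).
#' @param spacer_offset 1-based start of the spacer within the read
#'   (default 11).
#' @return Tibble `sample`, `path`, `total_reads`, `onlibrary_reads`,
#'   `contaminant_reads`.
#' @export
simulate_fastq <- function(config, counts, out_dir, read_length = 50L,
                           spacer_offset = 11L) {
  stopifnot(inherits(config, "sim_config"))
  lib <- config$library
  if (!identical(counts$guide_id, lib$guide_id)) {
    abort("counts do not match the config's library (guide_id mismatch)")
  }
  sl <- attr(lib, "spacer_length")
  if (spacer_offset < 1L || spacer_offset + sl - 1L > read_length) {
    abort("spacer does not fit in the read at this offset")
  }
  if (spacer_offset - 1L > nchar(FLANK5)) {
    abort(sprintf("spacer_offset must be <= %d", nchar(FLANK5) + 1L))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  left <- substr(FLANK5, nchar(FLANK5) - spacer_offset + 2L, nchar(FLANK5))
  right_len <- read_length - spacer_offset + 1L - sl
  right <- substr(FLANK3, 1L, right_len)
  smp <- sample_cols(counts)
  f <- config$contaminant_fraction

  withr::with_seed(config$seed + 1L, {
    purrr::map_dfr(smp, function(s) {
      k <- counts[[s]]
      n_on <- sum(k)
      n_total <- round(n_on / (1 - f))
      n_cont <- n_total - n_on
      reads <- c(paste0(left, rep(lib$spacer, k), right),
                 random_dna(n_cont, read_length))
      reads <- reads[sample.int(length(reads))]
      path <- file.path(out_dir, paste0(s, ".fastq.gz"))
      seqs <- Biostrings::DNAStringSet(reads)
      names(seqs) <- paste0(s, "_read", seq_along(reads))
      quals <- Biostrings::BStringSet(rep(strrep("I", read_length),
                                          length(reads)))
      Biostrings::writeXStringSet(seqs, path, format = "fastq",
                                  qualities = quals, compress = TRUE)
      tibble::tibble(sample = s, path = path, total_reads = n_total,
                     onlibrary_reads = n_on, contaminant_reads = n_cont)
    })
  })
}
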