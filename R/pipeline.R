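#' Read and validate a pipeline configuration
#'
#' The configuration is a YAML file (or an equivalent named list) with
#' paths and stage parameters:
#'
#' - `library`: library TSV path; `spacer_length` (default 20)
#' - `fastq`: named map sample -> FASTQ path, or `counts`: counts TSV path
#' - `design`: design TSV path (sample, timepoint, treatment, role)
#' - `counting`: `mode` (`scan`/`fixed_offset`), `offset`,
#'   `reverse_complement`
#' - `normalization`: `median_scaling` or `median_ratio`
#' - `hitcall`: any [hitcall_params()] arguments
#' - `gmt`: optional GMT path; `enrich_sets` (default A4, B4, C4, D4);
#'   `q_cut` (default 0.05)
#' - `out_dir`: output directory; `seed` (default 1)
#'
#' @param config Path to a YAML file or a named list.
#' @return The validated configuration list.
#' @export
read_pipeline_config <- function(config) {
  if (is.character(config)) {
    assert_file(config, "config file")
    config <- yaml::read_yaml(config)
  }
  if (is.null(config$library)) {
    abort("config needs a library path")
  }
  if (is.null(config$counts) && is.null(config$fastq)) {
    abort("config needs either counts or fastq")
  }
  if (is.null(config$design)) {
    abort("config needs a design file")
  }
  for (p in c("library", "counts", "design", "gmt")) {
    if (!is.null(config[[p]])) assert_file(config[[p]], p)
  }
  if (!is.null(config$fastq)) {
    purrr::walk(config$fastq, assert_file, what = "FASTQ file")
  }
  config$spacer_length <- config$spacer_length %||% 20L
  config$normalization <- config$normalization %||% "median_scaling"
  config$enrich_sets <- config$enrich_sets %||% c("A4", "B4", "C4", "D4")
  config$q_cut <- config$q_cut %||% 0.05
  config$seed <- config$seed %||% 1L
  config
}

pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("stage %s failed: %s", name, conditionMessage(e)))
  })
}

#' Run the full screen analysis pipeline
#'
#' Executes count (or count loading) -> normalize -> QC -> hit calling ->
#' enrichment in order, persisting every stage's outputs and a run
#' manifest (parameter echo plus md5 checksums) to `out_dir`. A rerun with
#' identical config and inputs is bit-identical. On a stage error the run
#' halts with the stage name and an `INCOMPLETE` marker is left in the
#' output directory.
#'
#' @param config A config list or YAML path (see [read_pipeline_config()]).
#' @param out_dir Output directory; defaults to `config$out_dir`.
#' @return Invisibly, a list with the fitted objects: `counts`, `stats`
#'   (when counted from FASTQ), `norm`, `qc`, `hitcall`, `enrichment`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  config <- read_pipeline_config(config)
  out_dir <- out_dir %||% config$out_dir
  if (is.null(out_dir)) {
    abort("no output directory given")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ## the marker is removed only after the manifest is written, so an
  ## aborted run leaves its partial outputs labelled incomplete
  marker <- file.path(out_dir, "INCOMPLETE")
  file.create(marker)

  lib <- pipeline_stage("library", read_guide_library(config$library,
                                                      config$spacer_length))
  stats <- NULL
  counts <- pipeline_stage("count", {
    if (!is.null(config$fastq)) {
      design <- readr::read_tsv(config$design, show_col_types = FALSE,
                                progress = FALSE)
      cc <- config$counting %||% list()
      res <- count_reads(lib, unlist(config$fastq),
                         mode = cc$mode %||% "scan", offset = cc$offset,
                         design = design,
                         reverse_complement = isTRUE(cc$reverse_complement))
      stats <<- res$stats
      readr::write_tsv(res$stats, file.path(out_dir, "mapping_stats.tsv"),
                       progress = FALSE)
      readr::write_tsv(mapping_report(res$stats),
                       file.path(out_dir, "mapping_report.tsv"),
                       progress = FALSE)
      write_counts(res$counts, file.path(out_dir, "counts.tsv"))
      res$counts
    } else {
      read_counts(config$counts, config$design)
    }
  })

  norm <- pipeline_stage("normalize", median_normalize(counts, config$normalization))
  readr::write_tsv(tibble::as_tibble(norm), file.path(out_dir, "normalized.tsv"),
                   progress = FALSE)
  readr::write_tsv(
    tibble::tibble(sample = names(size_factors(norm)),
                   size_factor = unname(size_factors(norm))),
    file.path(out_dir, "size_factors.tsv"), progress = FALSE)

  qc <- pipeline_stage("qc", qc_report(norm))
  readr::write_tsv(qc$samples, file.path(out_dir, "qc_samples.tsv"),
                   progress = FALSE)
  readr::write_tsv(qc$correlations, file.path(out_dir, "qc_correlations.tsv"),
                   progress = FALSE)

  hc_params <- do.call(hitcall_params, config$hitcall %||% list())
  hc <- pipeline_stage("hitcall", run_hitcall(norm, hc_params))
  write_hitcall(hc, out_dir)
  yaml::write_yaml(purrr::map(hc$sets, as.list),
                   file.path(out_dir, "hitcall_sets.yaml"))

  enrichment <- NULL
  if (!is.null(config$gmt)) {
    enrichment <- pipeline_stage("enrich", {
      sets <- read_gmt(config$gmt)
      universe <- unique(lib$gene[!lib$is_nontargeting])
      res <- purrr::compact(purrr::map(
        setNames(nm = config$enrich_sets), function(nm) {
          query <- hit_set(hc, nm)
          if (length(intersect(query, universe)) == 0L) return(NULL)
          enrich(query, sets, universe)
        }))
      purrr::iwalk(res, function(tab, nm) {
        readr::write_tsv(tibble::as_tibble(tab),
                         file.path(out_dir, paste0("enrichment_", nm, ".tsv")),
                         progress = FALSE)
      })
      res
    })
  }

  outputs <- sort(setdiff(list.files(out_dir), c("INCOMPLETE", "manifest.yaml")))
  manifest <- list(
    package = "chronoscreen",
    version = as.character(utils::packageVersion("chronoscreen")),
    seed = config$seed,
    inputs = purrr::compact(list(
      library = unname(tools::md5sum(config$library)),
      counts = if (!is.null(config$counts)) unname(tools::md5sum(config$counts)),
      design = unname(tools::md5sum(config$design)),
      gmt = if (!is.null(config$gmt)) unname(tools::md5sum(config$gmt)))),
    parameters = list(normalization = config$normalization,
                      hitcall = unclass(hc_params),
                      enrich_sets = config$enrich_sets, q_cut = config$q_cut),
    outputs = as.list(setNames(
      unname(tools::md5sum(file.path(out_dir, outputs))), outputs)))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  file.remove(marker)
  invisible(list(counts = counts, stats = stats, norm = norm, qc = qc,
                 hitcall = hc, enrichment = enrichment))
}

#' Read a normalized matrix written by the pipeline
#'
#' Reattaches the sample design so hit calling can be run on a
#' `normalized.tsv` produced by an earlier [run_pipeline()] or
#' [median_normalize()] call.
#'
#' @param norm_path Path to a normalized TSV (guide_id, gene, samples...).
#' @param design_path Path to the design TSV.
#' @return A `screen_norm` tibble.
#' @export
read_normalized <- function(norm_path, design_path) {
  assert_file(norm_path, "normalized file")
  assert_file(design_path, "design file")
  norm <- readr::read_tsv(norm_path, show_col_types = FALSE, progress = FALSE)
  design <- readr::read_tsv(design_path, show_col_types = FALSE, progress = FALSE)
  smp <- sample_cols(norm)
  design <- design[match(smp, design$sample), ]
  attr(norm, "design") <- design
  class(norm) <- unique(c("screen_norm", class(norm)))
  norm
}
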