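# End-to-end workflows: simulate a run, analyze a run (demultiplex ->
# align -> filter -> call -> report), derive thresholds from control
# runs. The command-line entry point in inst/cli/mitotiler.R is a thin
# wrapper over these functions.

#' Pipeline configuration
#'
#' @param genome a [circular_genome()] (default: the bundled synthetic
#'   rCRS-like reference).
#' @param panel a [panel()] (default: a control-region panel designed on
#'   `genome` with seed 1).
#' @param preset threshold preset name (see [preset_thresholds()]).
#' @param th explicit [thresholds()] overriding the preset.
#' @param numt optional [numt_db()].
#' @param target region reported on (defaults to the control region).
#' @param uas_compat C-stretch compatibility rendering flag.
#' @param max_mismatch demultiplexing per-index mismatch tolerance.
#' @param seed integer seed.
#' @return list configuration.
#' @export
pipeline_config <- function(genome = NULL, panel = NULL,
                            preset = "control-region", th = NULL,
                            numt = NULL, target = NULL, uas_compat = FALSE,
                            max_mismatch = 1L, seed = 1L) {
  if (is.null(genome)) genome <- load_rcrs_synthetic()
  regions <- named_regions()
  if (is.null(target)) target <- regions$control_region
  if (is.null(panel)) {
    panel <- design_tiled_panel(genome, target, 60L, 150L, 3L, seed = 1L)
  }
  if (is.null(th)) th <- preset_thresholds(preset)
  list(genome = genome, panel = panel, th = th, numt = numt,
       target = target, regions = regions, uas_compat = uas_compat,
       max_mismatch = as.integer(max_mismatch), seed = as.integer(seed))
}

#' Analyze one sample's reads
#'
#' Runs alignment, the read-level filter chain, pileup and calling for
#' one demultiplexed read set.
#'
#' @param reads reads data.frame.
#' @param config a [pipeline_config()].
#' @param sample_name reported name.
#' @return a [call_sample()] result with an extra `filter_counts` field
#'   auditing reads removed by each filter.
#' @export
analyze_sample <- function(reads, config, sample_name = "sample") {
  aln <- align_reads(reads, config$genome, config$panel)
  aln <- apply_read_filters(aln, config$genome, config$panel,
                            numt = config$numt, regions = config$regions)
  pup <- build_pileup(aln, config$genome, min_q = config$th$min_q)
  res <- call_sample(pup, config$th, config$target, config$genome,
                     sample_name = sample_name,
                     uas_compat = config$uas_compat,
                     regions = config$regions)
  res$filter_counts <- list(
    total_mates = nrow(aln),
    unaligned = sum(!aln$aligned),
    byproduct = sum(aln$byproduct_filtered),
    numt = sum(aln$numt_filtered),
    hvii_clipped = sum(aln$hvii_softclipped)
  )
  res$alignments <- aln
  res$pileup <- pup
  res
}

#' Analyze a full run
#'
#' Demultiplexes and analyzes every non-bait sheet entry, and reports
#' bait counts.
#'
#' @param reads reads data.frame for the whole run.
#' @param sheet sample sheet data.frame.
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory: per-sample variant TSV, VCF,
#'   SAM, no-call BED and EMPOP report plus run-level demux report are
#'   written there.
#' @return list with `demux`, `samples` (named list of results) and
#'   `baits` (carryover table).
#' @export
analyze_run <- function(reads, sheet, config, out_dir = NULL) {
  demux <- demultiplex(reads, sheet, config$max_mismatch)
  non_bait <- sheet$Sample_ID[sheet$role != "bait"]
  samples <- list()
  for (nm in non_bait) {
    r <- demux$assignments[[nm]]
    res <- analyze_sample(r, config, sample_name = nm)
    i <- match(nm, sheet$Sample_ID)
    res$index_i7 <- sheet$index[i]
    res$index_i5 <- sheet$index2[i]
    samples[[nm]] <- res
  }
  baits <- carryover_check(demux)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_demux_report(demux, file.path(out_dir, "demux_report.tsv"))
    for (nm in names(samples)) {
      res <- samples[[nm]]
      write_variant_tsv(res, file.path(out_dir, paste0(nm, ".variants.tsv")))
      write_vcf(res, config$genome, file.path(out_dir, paste0(nm, ".vcf")))
      write_sam(res$alignments, config$genome,
                file.path(out_dir, paste0(nm, ".sam")))
      write_nocall_bed(res, config$genome,
                       file.path(out_dir, paste0(nm, ".nocall.bed")))
      if (res$coverage_percent > 0) {
        empop_report(res, config$genome, config$target,
                     file.path(out_dir, paste0(nm, ".empop.txt")))
      }
    }
  }
  list(demux = demux, samples = samples, baits = baits)
}

#' Mixture scenario preset
#'
#' Builds a two-contributor [library_spec()] from minor:major parts,
#' mirroring the validation design (one well-characterized major
#' haplotype, a minor contributor differing at diagnostic sites).
#'
#' @param name sample name.
#' @param minor_hap,major_hap [haplotype_spec()]s.
#' @param minor_parts,major_parts mixture parts (e.g. 1 and 3).
#' @param total_read_pairs pairs to simulate.
#' @param seed integer seed.
#' @return a [library_spec()].
#' @export
mixture_library <- function(name, minor_hap, major_hap, minor_parts,
                            major_parts, total_read_pairs, seed = 1L) {
  w <- minor_parts / (minor_parts + major_parts)
  library_spec(name,
               contributors = list(
                 list(hap = minor_hap, weight = w),
                 list(hap = major_hap, weight = 1 - w)),
               total_read_pairs = total_read_pairs, seed = seed)
}

#' Derive thresholds from control-run measurements
#'
#' @param ntc_background per-position background reads from NTCs.
#' @param unexpected_pcts per-run unexpected-variant percentages from
#'   positive controls.
#' @param k_min SD multiplier for the minimum read count.
#' @param k_at SD multiplier for the AT.
#' @param at_rounding rounding mode for [derive_at()].
#' @param path optional YAML report path.
#' @return list with `min_read_count` and `at` (the [derive_at()]
#'   result).
#' @export
derive_thresholds <- function(ntc_background, unexpected_pcts, k_min = 1,
                              k_at = 3, at_rounding = "one-decimal",
                              path = NULL) {
  mrc <- derive_min_read_count(ntc_background, k_min)
  at <- derive_at(unexpected_pcts, k_at, at_rounding)
  if (!is.null(path)) {
    write_threshold_report(
      list(mean = mean(ntc_background),
           sd = stats::sd(ntc_background), k = k_min, value = mrc),
      at, path)
  }
  list(min_read_count = mrc, at = at)
}

#' Reference haplotypes bundled with the package
#'
#' Loads the packaged table of published control-region haplotype
#' strings (mock casework remains, buccal/hair sets, the five
#' well-characterized cross-kit samples and the 49-sample population
#' concordance set).
#'
#' @return data.frame with columns `set`, `sample`, `assay`,
#'   `haplotype`.
#' @export
known_haplotypes <- function() {
  utils::read.delim(
    system.file("extdata", "known_haplotypes.tsv", package = "mitotiler",
                mustWork = TRUE),
    stringsAsFactors = FALSE)
}
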