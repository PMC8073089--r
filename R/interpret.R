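# Threshold derivation from control runs, mixture assessment, NTC
# contamination estimation and run-level summary metrics.
#
# Thresholds for the calling step come from background measurements on
# negative and positive amplification controls: the minimum read count is
# mean + k standard deviations of the per-position background read depth
# in no-template controls, and the analytical threshold comes from the
# distribution of unexpected-variant percentages in positive controls.
# Sample (n-1) standard deviation is used throughout.

#' Derive a minimum read count from NTC background depths
#'
#' Computes `round(mean + k * sd)` (half-up to an integer) over
#' per-position background read counts observed in no-template controls.
#' With the published control-region background (mean 34 reads, SD 30,
#' k = 1) this yields the default minimum read count of 64.
#'
#' @param ntc_background numeric vector of background reads per position
#'   (or per amplicon).
#' @param k standard-deviation multiplier (default 1).
#' @return integer minimum read count.
#' @export
derive_min_read_count <- function(ntc_background, k = 1) {
  if (length(ntc_background) == 0L) abort("no background observations")
  if (k < 0) abort("k must be non-negative")
  s <- if (length(ntc_background) > 1L) stats::sd(ntc_background) else 0
  as.integer(round_half_up(mean(ntc_background) + k * s))
}

#' Derive an analytical threshold from unexpected-variant percentages
#'
#' Summarizes the per-run (or per-sample) percentages of unexpected
#' variants seen in positive amplification controls and derives a custom
#' AT as `mean + k * SD` under the chosen rounding: `"one-decimal"`
#' rounds half-up to one decimal (0.7% + 3x1.0% -> 3.7%) and
#' `"ceil-to-integer"` rounds up to the next whole percent
#' (0.7% + 3x0.5% = 2.2% -> 3%).
#'
#' @param unexpected_pcts numeric vector of unexpected-variant
#'   percentages.
#' @param k SD multiplier (default 3).
#' @param rounding `"one-decimal"` or `"ceil-to-integer"`.
#' @param hotspots optional list of [region()] that were excluded when
#'   computing `max_excluding_hotspots` (recorded in the summary only;
#'   the caller excludes hotspot observations before passing values).
#' @return list with `summary` (mean, sd, percentile95, max, n) and
#'   `custom_at` (percent).
#' @export
derive_at <- function(unexpected_pcts, k = 3,
                      rounding = c("one-decimal", "ceil-to-integer"),
                      hotspots = list()) {
  if (length(unexpected_pcts) == 0L) abort("no background observations")
  rounding <- match.arg(rounding)
  m <- mean(unexpected_pcts)
  s <- if (length(unexpected_pcts) > 1L) stats::sd(unexpected_pcts) else 0
  raw <- m + k * s
  at <- switch(rounding,
               "one-decimal" = round_half_up(raw, 1),
               "ceil-to-integer" = ceiling(raw - sqrt(.Machine$double.eps)))
  list(
    summary = list(
      mean = m, sd = s, k = k,
      percentile95 = unname(stats::quantile(unexpected_pcts, 0.95)),
      max = max(unexpected_pcts),
      n = length(unexpected_pcts),
      excluded_hotspots = vapply(hotspots, function(r)
        sprintf("%d..%d", r$start, r$end), character(1))
    ),
    custom_at = at
  )
}

#' Expected allele ratio of a two-person mixture
#'
#' For a minor:major mixture of `m`:`M` parts the expected minor variant
#' allele percentage is `round(100 * m / (m + M))` (half-up to an
#' integer); the major percentage is its complement.
#'
#' @param minor_parts,major_parts positive mixture parts (e.g. 1 and 5
#'   for a 1:5 mixture).
#' @return list with `minor` and `major` percentages (integers summing
#'   to 100).
#' @export
expected_mixture_ratio <- function(minor_parts, major_parts) {
  if (minor_parts <= 0 || major_parts <= 0) abort("mixture parts must be > 0")
  minor <- as.integer(round_half_up(100 * minor_parts /
                                      (minor_parts + major_parts)))
  list(minor = minor, major = 100L - minor)
}

#' Minor-variant detection rate
#'
#' @param observed number of expected minor-contributor variants actually
#'   detected.
#' @param expected number of minor-contributor variants expected.
#' @return percentage, one decimal half-up (e.g. 15 of 27 -> 55.6).
#' @export
detection_rate <- function(observed, expected) {
  if (expected <= 0) abort("expected count must be > 0")
  if (observed < 0) abort("observed count must be >= 0")
  round_half_up(100 * observed / expected, 1)
}

#' Amplicon dropout rate
#'
#' Percentage of targeted amplicons that dropped out across a study,
#' rounded half-up to two decimals (7 dropouts among 245 amplicons x 71
#' samples -> 0.04).
#'
#' @param n_dropout_amplicons dropout count.
#' @param amplicons_per_sample amplicons targeted per sample.
#' @param n_samples number of samples.
#' @return percentage to two decimals.
#' @export
dropout_rate <- function(n_dropout_amplicons, amplicons_per_sample,
                         n_samples) {
  if (n_dropout_amplicons < 0 || amplicons_per_sample < 0 || n_samples < 0) {
    abort("counts must be non-negative")
  }
  denom <- amplicons_per_sample * n_samples
  if (denom == 0) abort("zero amplicon denominator")
  round_half_up(100 * n_dropout_amplicons / denom, 2)
}

#' Flag a sample as a possible mixture
#'
#' Single-source mtDNA yields few or no mixed-base (IUPAC) calls; mixed
#' DNA shows a majority of mixed-base variants. The sample is flagged when
#' the fraction of mixed-base calls among all non-reference calls exceeds
#' `threshold` (default 0.5).
#'
#' @param sample_result a [call_sample()] result (field `haplotype`).
#' @param threshold mixed-base fraction above which to flag (default 0.5).
#' @return list with `observed_minor_variants` (count of mixed-base
#'   calls), `mixed_base_fraction` and `flagged_mixture`.
#' @export
flag_mixture <- function(sample_result, threshold = 0.5) {
  t <- sample_result$haplotype$tokens
  n <- nrow(t)
  mixed <- sum(t$kind == "substitution" &
                 t$symbol %in% c("R", "Y", "S", "W", "K", "M",
                                 "B", "D", "H", "V"))
  frac <- if (n == 0L) 0 else mixed / n
  list(observed_minor_variants = mixed,
       mixed_base_fraction = frac,
       flagged_mixture = n > 0L && frac > threshold)
}

#' Estimate NTC contamination depth per amplicon
#'
#' The control-region style estimate: total depth per amplicon obtained by
#' dividing the paired read count by the number of amplicons in the panel
#' and multiplying by two (each pair contributes both mates to depth).
#'
#' @param paired_read_count paired reads assigned to the NTC.
#' @param n_amplicons number of amplicons in the panel (18 for the
#'   control-region panel).
#' @return estimated total read depth per amplicon.
#' @export
ntc_depth_estimate <- function(paired_read_count, n_amplicons) {
  if (n_amplicons <= 0) abort("panel must have at least one amplicon")
  2 * paired_read_count / n_amplicons
}

#' Candidate crosstalk sources for NTC reads
#'
#' For each no-template control that received reads, lists the samples in
#' the run that share an i5 or i7 index with it and whose variant calls
#' match the NTC's calls within the NTC's covered region. NTC reads
#' matching no co-indexed sample are reported with an `"unexplained"`
#' note.
#'
#' @param sample_results named list of [call_sample()] results for real
#'   samples; each must carry `index_i7`/`index_i5` fields.
#' @param ntc_results named list of results for NTCs (same fields; an NTC
#'   with an empty haplotype and no covered positions is skipped).
#' @return data.frame with columns `ntc`, `source_sample`, `shared_index`,
#'   `shared_variants`, `note`.
#' @export
crosstalk_candidates <- function(sample_results, ntc_results) {
  out <- data.frame(ntc = character(), source_sample = character(),
                    shared_index = character(), shared_variants = character(),
                    note = character(), stringsAsFactors = FALSE)
  for (ntc_name in names(ntc_results)) {
    ntc <- ntc_results[[ntc_name]]
    if ((ntc$total_reads %||% 0) == 0) next
    ntc_keys <- token_keys(ntc$haplotype)
    found <- FALSE
    for (s_name in names(sample_results)) {
      s <- sample_results[[s_name]]
      shared_idx <- c(
        if (identical(s$index_i7, ntc$index_i7)) "i7",
        if (identical(s$index_i5, ntc$index_i5)) "i5"
      )
      if (length(shared_idx) == 0L) next
      shared <- intersect(ntc_keys, token_keys(s$haplotype))
      if (length(ntc_keys) > 0L && length(shared) == length(ntc_keys)) {
        found <- TRUE
        out <- rbind(out, data.frame(
          ntc = ntc_name, source_sample = s_name,
          shared_index = paste(shared_idx, collapse = "+"),
          shared_variants = paste(sub("^([0-9]+)\\.([0-9]+):", "\\1.\\2",
                                      shared), collapse = " "),
          note = "", stringsAsFactors = FALSE))
      }
    }
    if (!found) {
      out <- rbind(out, data.frame(
        ntc = ntc_name, source_sample = NA_character_,
        shared_index = NA_character_, shared_variants = NA_character_,
        note = "unexplained", stringsAsFactors = FALSE))
    }
  }
  out
}

#' Precision metric from average uncovered bases
#'
#' Bases covered as a fraction of total bases expected, expressed as a
#' percentage. Printed precision follows reporting convention: one decimal
#' below 99.9%, two decimals at or above (so a loss of 4 of 16,569 bases
#' reports as 99.98, and 356 of 16,569 as 97.9).
#'
#' @param avg_uncovered_bases average number of uncovered bases.
#' @param total_bases total bases expected.
#' @return percentage.
#' @export
precision_metric <- function(avg_uncovered_bases, total_bases) {
  if (total_bases <= 0) abort("total bases must be > 0")
  if (avg_uncovered_bases < 0 || avg_uncovered_bases > total_bases) {
    abort("uncovered bases must be within [0, total]")
  }
  pct <- 100 * (total_bases - avg_uncovered_bases) / total_bases
  if (pct >= 99.9) round_half_up(pct, 2) else round_half_up(pct, 1)
}

#' Write a threshold-derivation report as YAML
#'
#' @param min_read list from a [derive_min_read_count()] run: supply the
#'   observations and k used plus the derived value.
#' @param at result of [derive_at()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_threshold_report <- function(min_read, at, path) {
  yaml::write_yaml(list(minimum_read_count = min_read,
                        analytical_threshold = at), path)
  invisible(path)
}
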