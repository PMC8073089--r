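# Per-position stranded pileups and threshold-based variant calling.
#
# Calling is purely threshold-driven, as in forensic mtDNA practice: a
# base is detected when its fraction of the total read depth at the
# position meets the analytical threshold (AT), interpreted when it
# meets the interpretation threshold (IT), and a position is called at
# all only when its depth meets the minimum read count. Two retained
# bases render as the IUPAC mixed code (point heteroplasmy); insertion
# ordinals present in only part of the reads render lower case (length
# heteroplasmy).

#' Calling thresholds
#'
#' @param analytical_threshold percent of reads needed for a base to be
#'   detected (AT).
#' @param interpretation_threshold percent needed for interpretation
#'   (IT); calls in `[AT, IT)` are flagged `below_IT`.
#' @param min_read_count minimum per-position depth for any call.
#' @param min_q Phred floor for pileup counting.
#' @return list of thresholds.
#' @export
thresholds <- function(analytical_threshold = 10, interpretation_threshold = 10,
                       min_read_count = 64L, min_q = 30L) {
  if (analytical_threshold < 0 || analytical_threshold > 100 ||
      interpretation_threshold < analytical_threshold ||
      interpretation_threshold > 100) {
    abort("need 0 <= AT <= IT <= 100")
  }
  if (min_read_count < 0L) abort("min_read_count must be >= 0")
  list(analytical_threshold = analytical_threshold,
       interpretation_threshold = interpretation_threshold,
       min_read_count = as.integer(min_read_count),
       min_q = as.integer(min_q))
}

#' Per-kit threshold presets
#'
#' `"control-region"`: AT/IT 10%, minimum read count 64.
#' `"whole-genome"`: AT/IT 6%, minimum read count 45.
#'
#' @param preset preset name.
#' @return a [thresholds()] object.
#' @export
preset_thresholds <- function(preset = c("control-region", "whole-genome")) {
  preset <- match.arg(preset)
  switch(preset,
         "control-region" = thresholds(10, 10, 64L),
         "whole-genome" = thresholds(6, 6, 45L))
}

BASE_COLS <- c("A", "C", "G", "T", "del")

#' Build a stranded pileup from filtered alignments
#'
#' Counts exclude unaligned mates, byproduct- and NUMT-filtered reads,
#' bases masked below the quality floor, and bases outside each read's
#' usable span (primer trimming, HVII soft clip). Insertions are
#' re-anchored to the 3'-most position of a homopolymer before ordinal
#' naming, the standard forensic alignment convention.
#'
#' @param aln alignment data.frame after [apply_read_filters()].
#' @param genome a [circular_genome()].
#' @param min_q Phred floor (default 30).
#' @return object of class `pileup`: list with `counts` (L x 10 matrix,
#'   columns A+,C+,G+,T+,del+,A-,C-,G-,T-,del-), `insertions`
#'   (data.frame pos, ordinal, base, fwd, rev) and `genome_length`.
#' @export
build_pileup <- function(aln, genome, min_q = 30L) {
  keep <- aln$aligned & !aln$byproduct_filtered & !aln$numt_filtered
  aln <- aln[keep, , drop = FALSE]
  if (nrow(aln) == 0L) {
    counts <- matrix(0L, nrow = genome$length, ncol = 10)
    ins <- data.frame(pos = integer(), ordinal = integer(),
                      base = character(), fwd = integer(), rev = integer(),
                      stringsAsFactors = FALSE)
    return(structure(list(counts = counts, insertions = ins,
                          genome_length = genome$length),
                     class = "pileup"))
  }
  res <- .pileup_cpp(aln$seq, aln$qual, aln$start_unwrapped, aln$cigar,
                     ifelse(aln$strand == "-", 1L, 0L),
                     aln$keep_lo, aln$keep_hi, genome$length,
                     as.integer(min_q))
  ins <- aggregate_insertions(res$ins_pos, res$ins_seq, res$ins_strand,
                              genome)
  structure(list(counts = res$counts, insertions = ins,
                 genome_length = genome$length),
            class = "pileup")
}

#' @export
print.pileup <- function(x, ...) {
  cat(sprintf("<pileup> %d positions, %d with coverage, %d insertion events\n",
              x$genome_length, sum(rowSums(x$counts) > 0),
              nrow(x$insertions)))
  invisible(x)
}

# shift insertion anchors to the 3'-most position of a homopolymer and
# expand events into per-(pos, ordinal, base) stranded counts
aggregate_insertions <- function(pos, seqs, strands, genome) {
  out <- list()
  if (length(pos) > 0L) {
    for (i in seq_along(pos)) {
      p <- pos[i]; s <- seqs[i]
      b1 <- substr(s, 1, 1)
      if (nchar(s) >= 1L && all(strsplit(s, "")[[1]] == b1)) {
        while (p < genome$length &&
               substr(genome$sequence, p + 1L, p + 1L) == b1) {
          p <- p + 1L
        }
      }
      for (o in seq_len(nchar(s))) {
        key <- paste0(p, ".", o, ".", substr(s, o, o))
        if (is.null(out[[key]])) out[[key]] <- c(0L, 0L)
        out[[key]][strands[i] + 1L] <- out[[key]][strands[i] + 1L] + 1L
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(pos = integer(), ordinal = integer(),
                      base = character(), fwd = integer(), rev = integer(),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(names(out), ".", fixed = TRUE)
  data.frame(
    pos = as.integer(vapply(parts, `[`, character(1), 1)),
    ordinal = as.integer(vapply(parts, `[`, character(1), 2)),
    base = vapply(parts, `[`, character(1), 3),
    fwd = vapply(out, `[`, integer(1), 1),
    rev = vapply(out, `[`, integer(1), 2),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

position_counts <- function(pileup, position) {
  v <- pileup$counts[position, ]
  stats::setNames(v[1:5] + v[6:10], BASE_COLS)
}

total_depth <- function(pileup, position) {
  sum(pileup$counts[position, ])
}

#' Majority-strand read count at a position
#'
#' The displayed strand depth is the read count from whichever strand
#' carries the majority of reads; ties return the forward count.
#'
#' @param pileup a [build_pileup()] result.
#' @param position 1-based reference position.
#' @return reads on the majority strand.
#' @export
strand_depth <- function(pileup, position) {
  fwd <- sum(pileup$counts[position, 1:5])
  rev <- sum(pileup$counts[position, 6:10])
  if (fwd >= rev) fwd else rev
}

#' Call one position under the thresholds
#'
#' @param pileup a [build_pileup()] result.
#' @param position 1-based reference position.
#' @param th [thresholds()].
#' @return list with `position`, `status` (`called` / `below_IT` /
#'   `no_call`), `called` (base, IUPAC code or `"del"`), `fraction`
#'   (percent of total depth of the called allele, max over retained),
#'   `depth`, `strand_depth` and `retained` (named fractions).
#' @export
call_position <- function(pileup, position, th) {
  cnt <- position_counts(pileup, position)
  depth <- sum(cnt)
  sd <- strand_depth(pileup, position)
  if (depth < th$min_read_count) {
    return(list(position = position, status = "no_call", called = NA_character_,
                fraction = NA_real_, depth = depth, strand_depth = sd,
                retained = numeric()))
  }
  frac <- 100 * cnt / depth
  retained <- frac[frac >= th$analytical_threshold]
  if (length(retained) == 0L) {
    return(list(position = position, status = "no_call", called = NA_character_,
                fraction = NA_real_, depth = depth, strand_depth = sd,
                retained = numeric()))
  }
  ret_bases <- setdiff(names(retained), "del")
  called <- if (length(retained) == 1L) {
    names(retained)
  } else if (length(ret_bases) == length(retained)) {
    iupac_code(ret_bases)
  } else if ("del" %in% names(retained) &&
             retained[["del"]] == max(retained)) {
    "del"
  } else {
    iupac_code(ret_bases)
  }
  status <- if (max(retained) < th$interpretation_threshold) "below_IT"
            else "called"
  list(position = position, status = status, called = called,
       fraction = max(retained), depth = depth, strand_depth = sd,
       retained = retained)
}

#' Insertion calls in a region (length heteroplasmy aware)
#'
#' Reports insertion ordinals whose fraction of the anchor position's
#' depth meets the AT. An ordinal carried by less than `100 - AT` percent
#' of reads is a length heteroplasmy and renders lower case; an ordinal
#' in effectively all reads renders upper case. With `uas_compat = TRUE`
#' the two documented C-stretch corrections are applied by
#' [call_sample()] (the 16189 pattern and re-anchoring of 310 mixed
#' calls).
#'
#' @param pileup a [build_pileup()] result.
#' @param r [region()] to scan (`NULL` scans everywhere).
#' @param th [thresholds()].
#' @return data.frame `pos`, `ordinal`, `base`, `fraction`, `depth`,
#'   `lowercase`.
#' @export
length_heteroplasmy_calls <- function(pileup, r = NULL, th) {
  ins <- pileup$insertions
  if (!is.null(r)) {
    ins <- ins[ins$pos %in% region_positions(r, pileup$genome_length), ,
               drop = FALSE]
  }
  if (nrow(ins) == 0L) {
    return(data.frame(pos = integer(), ordinal = integer(),
                      base = character(), fraction = numeric(),
                      depth = integer(), lowercase = logical(),
                      stringsAsFactors = FALSE))
  }
  out <- lapply(seq_len(nrow(ins)), function(i) {
    depth <- total_depth(pileup, ins$pos[i])
    if (depth < th$min_read_count) return(NULL)
    fr <- 100 * (ins$fwd[i] + ins$rev[i]) / depth
    if (fr < th$analytical_threshold) return(NULL)
    data.frame(pos = ins$pos[i], ordinal = ins$ordinal[i],
               base = ins$base[i], fraction = fr, depth = depth,
               lowercase = fr < (100 - th$analytical_threshold),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(out, list(NULL)))
  if (is.null(out)) {
    return(data.frame(pos = integer(), ordinal = integer(),
                      base = character(), fraction = numeric(),
                      depth = integer(), lowercase = logical(),
                      stringsAsFactors = FALSE))
  }
  out[order(out$pos, out$ordinal), , drop = FALSE]
}

#' Call a sample over a target region
#'
#' Iterates the target positions, emits non-reference calls in
#' SWGDAM-style nomenclature, merges adjacent uncalled positions into
#' no-call regions and computes coverage. With `uas_compat = TRUE` the
#' two documented C-stretch corrections are applied: the
#' all-reads-deleted 16189 T with partial C insertion reports as
#' `16189C 16193c` (instead of the raw `16189c` rendering), and a mixed
#' 310 call is re-anchored as an additional `309.Nc` insertion.
#'
#' @param pileup a [build_pileup()] result.
#' @param th [thresholds()].
#' @param target [region()] to call (e.g. the control region).
#' @param genome the reference [circular_genome()].
#' @param sample_name reported sample name.
#' @param uas_compat apply the C-stretch compatibility corrections?
#' @param regions [named_regions()] used by the corrections.
#' @return object of class `sample_result`: list with `sample_name`,
#'   `haplotype`, `no_call_regions`, `coverage_percent`, `calls`
#'   (per-position data.frame of non-reference and no-call rows) and
#'   `total_reads`.
#' @export
call_sample <- function(pileup, th, target, genome, sample_name = "sample",
                        uas_compat = FALSE, regions = named_regions()) {
  tpos <- region_positions(target, genome$length)
  called_ok <- logical(length(tpos))
  tokens <- list()
  calls <- list()

  for (i in seq_along(tpos)) {
    p <- tpos[i]
    pc <- call_position(pileup, p, th)
    if (pc$status == "no_call") {
      calls[[length(calls) + 1L]] <- data.frame(
        position = p, kind = "no_call", call = NA_character_,
        fraction = NA_real_, depth = pc$depth,
        strand_depth = pc$strand_depth, status = "no_call",
        stringsAsFactors = FALSE)
      next
    }
    called_ok[i] <- TRUE
    refb <- substr(genome$sequence, p, p)
    if (pc$called != refb) {
      kind <- if (pc$called == "del") "deletion" else "substitution"
      is_mixed <- !(pc$called %in% c("A", "C", "G", "T", "del"))
      tokens[[length(tokens) + 1L]] <- data.frame(
        position = p, ordinal = 0L, kind = kind,
        symbol = pc$called, lowercase = FALSE, stringsAsFactors = FALSE)
      calls[[length(calls) + 1L]] <- data.frame(
        position = p, kind = kind,
        call = pc$called, fraction = pc$fraction, depth = pc$depth,
        strand_depth = pc$strand_depth, status = pc$status,
        stringsAsFactors = FALSE)
    }
  }

  ins <- length_heteroplasmy_calls(pileup, NULL, th)
  ins <- ins[ins$pos %in% tpos, , drop = FALSE]
  for (i in seq_len(nrow(ins))) {
    tokens[[length(tokens) + 1L]] <- data.frame(
      position = ins$pos[i], ordinal = ins$ordinal[i], kind = "insertion",
      symbol = ins$base[i], lowercase = ins$lowercase[i],
      stringsAsFactors = FALSE)
    calls[[length(calls) + 1L]] <- data.frame(
      position = ins$pos[i], kind = "insertion",
      call = sprintf("%d.%d%s", ins$pos[i], ins$ordinal[i],
                     if (ins$lowercase[i]) tolower(ins$base[i])
                     else ins$base[i]),
      fraction = ins$fraction[i], depth = ins$depth[i],
      strand_depth = strand_depth(pileup, ins$pos[i]), status = "called",
      stringsAsFactors = FALSE)
  }

  tok <- do.call(rbind, c(tokens, list(NULL)))
  if (is.null(tok)) {
    tok <- parse_haplotype("")$tokens
  }
  tok <- apply_cstretch_rendering(tok, uas_compat, regions)
  tok <- tok[order(tok$position, tok$ordinal), , drop = FALSE]
  rownames(tok) <- NULL

  nc_regions <- split_positions_to_ranges(tpos, tpos[!called_ok])
  hap <- new_haplotype(tok, covered_range =
                         split_positions_to_ranges(tpos, tpos[called_ok]))
  calls_df <- do.call(rbind, c(calls, list(NULL)))
  structure(list(
    sample_name = sample_name,
    haplotype = hap,
    no_call_regions = nc_regions,
    coverage_percent = round_half_up(100 * sum(called_ok) / length(tpos), 1),
    calls = calls_df %||% data.frame(),
    total_reads = sum(pileup$counts)
  ), class = "sample_result")
}

#' @export
print.sample_result <- function(x, ...) {
  cat(sprintf("<sample_result> %s: %.1f%% coverage, %d variants, %d no-call region(s)\n",
              x$sample_name, x$coverage_percent, nrow(x$haplotype$tokens),
              length(x$no_call_regions)))
  if (nrow(x$haplotype$tokens) > 0) {
    cat(" ", format_haplotype(x$haplotype), "\n")
  }
  invisible(x)
}

# C-stretch rendering rules around 16189 and 310.
# Raw pipeline output for the "16189 pattern" is a deletion at 16189 plus
# partial C insertions in the HVI stretch; the conventional rendering is
# "16189c" (UAS style, uas_compat = FALSE) or "16189C 16193c" (corrected
# style, uas_compat = TRUE). A mixed 310 call re-anchors to a 309.N c
# insertion under uas_compat.
apply_cstretch_rendering <- function(tok, uas_compat, regions) {
  if (nrow(tok) == 0L) return(tok)
  hv1 <- regions$hv1_cstretch
  del_16189 <- which(tok$position == 16189L & tok$kind == "deletion")
  ins_hv1 <- which(tok$kind == "insertion" &
                     tok$position >= hv1$start & tok$position <= hv1$end &
                     tok$symbol == "C" & tok$lowercase)
  if (length(del_16189) == 1L && length(ins_hv1) > 0L) {
    if (uas_compat) {
      tok$kind[del_16189] <- "substitution"
      tok$symbol[del_16189] <- "C"
      tok$lowercase[del_16189] <- FALSE
      first_ins <- ins_hv1[1]
      tok$position[first_ins] <- 16193L
      tok$ordinal[first_ins] <- 0L
      tok$kind[first_ins] <- "substitution"
      tok$symbol[first_ins] <- "C"
      tok$lowercase[first_ins] <- TRUE
      drop <- setdiff(ins_hv1, first_ins)
      if (length(drop) > 0L) tok <- tok[-drop, , drop = FALSE]
    } else {
      tok$kind[del_16189] <- "substitution"
      tok$symbol[del_16189] <- "C"
      tok$lowercase[del_16189] <- TRUE
      tok <- tok[-ins_hv1, , drop = FALSE]
    }
  }
  if (uas_compat) {
    mixed_310 <- which(tok$position == 310L & tok$kind == "substitution" &
                         tok$symbol == "Y")
    if (length(mixed_310) == 1L) {
      next_ord <- 1L + sum(tok$position == 309L & tok$kind == "insertion")
      tok$position[mixed_310] <- 309L
      tok$ordinal[mixed_310] <- next_ord
      tok$kind[mixed_310] <- "insertion"
      tok$symbol[mixed_310] <- "C"
      tok$lowercase[mixed_310] <- TRUE
    }
  }
  tok
}

#' Mean insert depth per amplicon
#'
#' @param pileup a [build_pileup()] result.
#' @param panel a [panel()].
#' @return named numeric vector of mean total depth over each amplicon's
#'   insert.
#' @export
per_amplicon_depth <- function(pileup, panel) {
  depths <- rowSums(pileup$counts)
  vapply(panel$amplicons, function(a) {
    mean(depths[region_positions(a$insert, panel$genome_length)])
  }, numeric(1)) |>
    stats::setNames(vapply(panel$amplicons, `[[`, character(1), "id"))
}

#' Write sample calls as TSV
#'
#' @param result a [call_sample()] result.
#' @param path output path.
#' @return `path` invisibly.
#' @export
write_variant_tsv <- function(result, path) {
  df <- result$calls
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write non-reference calls as VCF 4.2
#'
#' Emits a minimal single-sample VCF with a circular-contig header.
#' Deletions and insertions are left-anchored on the previous reference
#' base, VCF style.
#'
#' @param result a [call_sample()] result.
#' @param genome the reference [circular_genome()].
#' @param path output path.
#' @return `path` invisibly.
#' @export
write_vcf <- function(result, genome, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=mitotiler",
           sprintf("##contig=<ID=%s,length=%d,circular=true>", genome$name,
                   genome$length),
           "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total read depth\">",
           "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Allele fraction (percent)\">",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", sep = "\t"))
  t <- result$haplotype$tokens
  calls <- result$calls
  rows <- character()
  for (i in seq_len(nrow(t))) {
    p <- t$position[i]
    info_row <- calls[calls$position == p & calls$kind != "no_call", ][1, ]
    dp <- info_row$depth %||% NA_integer_
    af <- info_row$fraction %||% NA_real_
    if (t$kind[i] == "substitution") {
      ref <- substr(genome$sequence, p, p)
      alt <- t$symbol[i]
      pos <- p
    } else if (t$kind[i] == "deletion") {
      pos <- p - 1L
      ref <- substr(genome$sequence, pos, p)
      alt <- substr(genome$sequence, pos, pos)
    } else {  # insertion: one row per anchor covers all ordinals
      if (t$ordinal[i] > 1L) next
      ords <- t[t$position == p & t$kind == "insertion", ]
      pos <- p
      ref <- substr(genome$sequence, p, p)
      alt <- paste0(ref, paste(ords$symbol, collapse = ""))
    }
    rows <- c(rows, paste(genome$name, pos, ".", ref, alt, ".", "PASS",
                          sprintf("DP=%d;AF=%.2f", as.integer(dp),
                                  as.numeric(af)),
                          sep = "\t"))
  }
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Write no-call regions as BED
#'
#' 0-based half-open; regions wrapping the origin are split in two.
#'
#' @param result a [call_sample()] result.
#' @param genome the reference [circular_genome()].
#' @param path output path.
#' @return `path` invisibly.
#' @export
write_nocall_bed <- function(result, genome, path) {
  rows <- character()
  for (r in result$no_call_regions) {
    if (r$end >= r$start) {
      rows <- c(rows, paste(genome$name, r$start - 1L, r$end, "no_call",
                            sep = "\t"))
    } else {
      rows <- c(rows,
                paste(genome$name, r$start - 1L, genome$length, "no_call",
                      sep = "\t"),
                paste(genome$name, 0L, r$end, "no_call", sep = "\t"))
    }
  }
  writeLines(rows, path)
  invisible(path)
}
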