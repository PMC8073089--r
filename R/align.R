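# Alignment of reads to the circular reference and the read-level
# filters applied before any base is counted: per-base Q30 masking,
# short-byproduct removal, primer trimming, NUMT exclusion and the HVII
# C-stretch reverse-strand soft clip.
#
# The aligner seeds read k-mers against an index of the doubled reference
# (so reads spanning the origin align contiguously) and extends with a
# banded affine-gap fitting alignment (match +1, mismatch -4, gap open
# -6, gap extend -1, band 16 by default). Alignments are kept in the
# "unwrapped" doubled coordinate frame internally and folded modulo the
# genome length for reporting.

#' Alignment scoring parameters
#'
#' @param match,mismatch,gap_open,gap_extend scoring constants.
#' @param band half-width of the alignment band.
#' @param k seed k-mer size.
#' @param min_frac minimum score as a fraction of the perfect-match
#'   score; alignments below it are flagged unaligned.
#' @return list of parameters.
#' @export
align_params <- function(match = 1L, mismatch = -4L, gap_open = -6L,
                         gap_extend = -1L, band = 16L, k = 15L,
                         min_frac = 0.5) {
  list(match = match, mismatch = mismatch, gap_open = gap_open,
       gap_extend = gap_extend, band = band, k = k, min_frac = min_frac)
}

ref_span_of_cigar <- function(cigar) {
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[MIDS]", cigar))[[1]]
  sum(lens[ops %in% c("M", "D")])
}

#' Align read pairs to a circular genome
#'
#' Each mate is aligned in both orientations and the better one kept; by
#' paired-end construction R1 should align forward and R2 reverse. Each
#' aligned mate is assigned to the amplicon whose outer span best
#' contains it. Unalignable reads are flagged and excluded downstream
#' rather than erroring.
#'
#' @param reads reads data.frame from [simulate_library()] /
#'   [read_run_fastq()].
#' @param genome a [circular_genome()].
#' @param panel a [panel()].
#' @param params [align_params()].
#' @return data.frame of per-mate alignments: `pair_id`, `mate`, `seq`,
#'   `qual` (aligned orientation), `aligned`, `strand`, `ref_start`
#'   (folded, 1-based), `start_unwrapped`, `end_unwrapped`, `cigar`,
#'   `score`, `nm`, `amplicon`, `keep_lo`, `keep_hi` (usable span,
#'   unwrapped frame), and filter flags.
#' @export
align_reads <- function(reads, genome, panel, params = align_params()) {
  n <- nrow(reads)
  if (n == 0L) return(empty_alignments())
  seqs <- c(reads$r1_seq, reads$r2_seq)
  quals <- c(reads$r1_qual, reads$r2_qual)
  pair_id <- rep(reads$id, 2L)
  mate <- rep(c(1L, 2L), each = n)

  doubled <- paste0(genome$sequence, genome$sequence)
  run_aln <- function(ss) {
    .align_reads_cpp(ss, doubled, genome$length, params$k, params$match,
                     params$mismatch, params$gap_open, params$gap_extend,
                     params$band, params$min_frac)
  }
  fwd <- run_aln(seqs)
  rc <- reverse_complement_many(seqs)
  rev <- run_aln(rc)

  use_rev <- (rev$aligned & !fwd$aligned) |
    (rev$aligned & fwd$aligned & rev$score > fwd$score)
  use_rev[is.na(use_rev)] <- FALSE

  pick <- function(col) ifelse(use_rev, rev[[col]], fwd[[col]])
  aligned <- ifelse(use_rev, rev$aligned, fwd$aligned)
  out_seq <- ifelse(use_rev, rc, seqs)
  out_qual <- quals
  out_qual[use_rev] <- reverse_strings(quals[use_rev])
  start_unwrapped <- pick("ref_start")
  cigar <- ifelse(use_rev, as.character(rev$cigar), as.character(fwd$cigar))
  span <- ifelse(aligned,
                 vapply(cigar, function(cg)
                   if (is.na(cg)) NA_integer_ else ref_span_of_cigar(cg),
                   integer(1), USE.NAMES = FALSE),
                 NA_integer_)
  end_unwrapped <- start_unwrapped + span - 1L

  aln <- data.frame(
    pair_id = pair_id, mate = mate, seq = out_seq, qual = out_qual,
    aligned = aligned,
    strand = ifelse(use_rev, "-", "+"),
    ref_start = ifelse(aligned, (start_unwrapped - 1L) %% genome$length + 1L,
                       NA_integer_),
    start_unwrapped = ifelse(aligned, start_unwrapped, NA_integer_),
    end_unwrapped = ifelse(aligned, end_unwrapped, NA_integer_),
    cigar = cigar, score = pick("score"), nm = pick("nm"),
    stringsAsFactors = FALSE
  )
  aln$amplicon <- assign_amplicons(aln, panel)
  aln$keep_lo <- aln$start_unwrapped
  aln$keep_hi <- aln$end_unwrapped
  aln$byproduct_filtered <- FALSE
  aln$numt_filtered <- FALSE
  aln$hvii_softclipped <- FALSE
  aln$primer_trimmed <- FALSE
  aln
}

empty_alignments <- function() {
  data.frame(pair_id = character(), mate = integer(), seq = character(),
             qual = character(), aligned = logical(), strand = character(),
             ref_start = integer(), start_unwrapped = integer(),
             end_unwrapped = integer(), cigar = character(),
             score = integer(), nm = integer(), amplicon = character(),
             keep_lo = integer(), keep_hi = integer(),
             byproduct_filtered = logical(), numt_filtered = logical(),
             hvii_softclipped = logical(), primer_trimmed = logical(),
             stringsAsFactors = FALSE)
}

# assign each aligned mate to the amplicon whose outer span overlaps it
# most (unwrapped frame; amplicon spans are laid out on the doubled
# genome so wrap amplicons stay contiguous)
assign_amplicons <- function(aln, panel) {
  L <- panel$genome_length
  spans <- lapply(panel$amplicons, function(a) {
    s <- a$outer$start
    e <- if (a$outer$end >= a$outer$start) a$outer$end
         else a$outer$end + L
    c(s, e)
  })
  ids <- vapply(panel$amplicons, `[[`, character(1), "id")
  vapply(seq_len(nrow(aln)), function(i) {
    if (!isTRUE(aln$aligned[i])) return(NA_character_)
    s <- aln$start_unwrapped[i]; e <- aln$end_unwrapped[i]
    # fold the read span into [1, L] and also test shifted by L
    best <- NA_character_; best_ov <- 0L
    for (j in seq_along(spans)) {
      for (shift in c(0L, L)) {
        ov <- min(e, spans[[j]][2] + shift) - max(s, spans[[j]][1] + shift) + 1L
        if (!is.na(ov) && ov > best_ov) { best_ov <- ov; best <- ids[j] }
      }
    }
    best
  }, character(1))
}

#' Offsets of bases failing the quality floor
#'
#' Base calls with Phred quality strictly below `min_q` are masked: they
#' stay in the alignment (anchoring is preserved) but never contribute to
#' pileup counts.
#'
#' @param seq,qual read sequence and quality strings (same length).
#' @param min_q Phred floor (default 30; Q30 passes, Q29 is masked).
#' @return integer vector of 1-based masked read offsets.
#' @export
mask_low_quality <- function(seq, qual, min_q = 30L) {
  if (nchar(seq) != nchar(qual)) abort("sequence/quality length mismatch")
  which(qual_to_phred(qual) < min_q)
}

#' Filter short byproducts
#'
#' Paired alignments whose inferred insert (fragment) length is below
#' `min_insert` are discarded as primer/adapter dimers; the smallest
#' genuine amplicon is 60 bp, so the default cutoff of 40 ("< 40 is
#' removed", 40 itself is kept) cannot touch real product.
#'
#' @param aln alignment data.frame (modified in place and returned).
#' @param min_insert fragment-length cutoff.
#' @return `aln` with `byproduct_filtered` set for both mates of short
#'   fragments.
#' @export
filter_byproduct <- function(aln, min_insert = 40L) {
  ok <- aln$aligned
  if (!any(ok)) return(aln)
  s <- aln$start_unwrapped; e <- aln$end_unwrapped
  s[!ok] <- NA_integer_; e[!ok] <- NA_integer_
  pair_min <- stats::ave(s, aln$pair_id,
                         FUN = function(v) suppressWarnings(min(v, na.rm = TRUE)))
  pair_max <- stats::ave(e, aln$pair_id,
                         FUN = function(v) suppressWarnings(max(v, na.rm = TRUE)))
  frag <- pair_max - pair_min + 1L
  short <- ok & is.finite(frag) & frag < min_insert
  aln$byproduct_filtered[short] <- TRUE
  aln
}

#' Trim primer footprints from aligned reads
#'
#' Bases of a read that fall inside its assigned amplicon's primer
#' footprints are soft-clipped (excluded from the usable span) so that
#' only the targeted insert is reported; a read entirely within the
#' insert is unchanged. Mates with no assigned amplicon are left
#' untrimmed and flagged.
#'
#' @param aln alignment data.frame.
#' @param panel a [panel()].
#' @return `aln` with `keep_lo`/`keep_hi` narrowed to the insert and
#'   `primer_trimmed` set.
#' @export
trim_primers <- function(aln, panel) {
  L <- panel$genome_length
  ins_span <- lapply(panel$amplicons, function(a) {
    s <- a$insert$start
    e <- if (a$insert$end >= a$insert$start) a$insert$end else a$insert$end + L
    c(s, e)
  })
  names(ins_span) <- vapply(panel$amplicons, `[[`, character(1), "id")
  for (i in seq_len(nrow(aln))) {
    if (!isTRUE(aln$aligned[i]) || is.na(aln$amplicon[i])) next
    sp <- ins_span[[aln$amplicon[i]]]
    # choose the shift of the insert span closest to the read span
    shift <- if (abs(sp[1] - aln$start_unwrapped[i]) <=
                   abs(sp[1] + L - aln$start_unwrapped[i])) 0L else L
    lo <- max(aln$keep_lo[i], sp[1] + shift)
    hi <- min(aln$keep_hi[i], sp[2] + shift)
    if (lo != aln$keep_lo[i] || hi != aln$keep_hi[i]) {
      aln$primer_trimmed[i] <- TRUE
    }
    aln$keep_lo[i] <- lo
    aln$keep_hi[i] <- hi
  }
  aln
}

#' Flag reads of nuclear-mitochondrial (NUMT) origin
#'
#' A read is flagged when it matches a NUMT decoy within `max_distance`
#' edits *and* more closely than it matches the mtDNA reference (the
#' aligner's edit count). A k-mer prefilter skips reads sharing no k-mer
#' with any decoy.
#'
#' @param aln alignment data.frame.
#' @param db a [numt_db()]; an empty database disables filtering.
#' @param max_distance edit budget for a decoy match (default 2).
#' @param k prefilter k-mer size.
#' @return `aln` with `numt_filtered` set.
#' @export
numt_filter <- function(aln, db, max_distance = 2L, k = 15L) {
  if (length(db$sequences) == 0L || nrow(aln) == 0L) return(aln)
  decoys <- unlist(db$sequences, use.names = FALSE)
  d <- .numt_screen_cpp(aln$seq, decoys, k)
  mt_d <- ifelse(is.na(aln$nm), Inf, aln$nm)
  hit <- !is.na(d) & d <= max_distance & d < mt_d
  # unaligned reads matching a decoy within budget are NUMTs too
  aln$numt_filtered <- aln$numt_filtered | hit
  aln
}

#' Soft-clip reverse-strand reads across the HVII C-stretch
#'
#' Reverse-strand reads that begin sequencing at the amplicon boundary
#' near position 262 read into the HVII C-stretch late in the read where
#' accuracy and alignment degrade. Reads whose alignment shows at least
#' `min_events` non-match events (mismatches or gaps) inside the
#' C-stretch are clipped at position 303: bases at 304 and beyond no
#' longer contribute to calling, halving reverse-strand coverage of
#' 304..353 relative to 262..303.
#'
#' @param aln alignment data.frame.
#' @param genome a [circular_genome()].
#' @param cstretch the C-stretch [region()] (default 303..315).
#' @param anchor reverse reads starting within `tol` of this position are
#'   candidates (default 262).
#' @param tol anchor tolerance in bp.
#' @param min_events non-match events inside the C-stretch needed to
#'   trigger the clip.
#' @return `aln` with `keep_hi` capped at the C-stretch start and
#'   `hvii_softclipped` set for clipped reads.
#' @export
hvii_softclip <- function(aln, genome, cstretch = region(303, 315),
                          anchor = 262L, tol = 3L, min_events = 2L) {
  clip_at <- cstretch$start  # keep <= 303
  L <- genome$length
  for (i in seq_len(nrow(aln))) {
    if (!isTRUE(aln$aligned[i]) || aln$strand[i] != "-") next
    usable_start <- (aln$keep_lo[i] - 1L) %% L + 1L
    if (abs(usable_start - anchor) > tol) next
    ev <- nonmatch_events_in(aln$seq[i], aln$cigar[i],
                             aln$start_unwrapped[i], genome,
                             cstretch$start, cstretch$end)
    if (ev >= min_events) {
      clip_unwrapped <- aln$keep_lo[i] + (clip_at - usable_start)
      aln$keep_hi[i] <- min(aln$keep_hi[i], clip_unwrapped)
      aln$hvii_softclipped[i] <- TRUE
    }
  }
  aln
}

# count mismatches, insertions and deletion events of one alignment that
# touch reference positions lo..hi (folded frame; read assumed not to
# span the origin inside the window of interest)
nonmatch_events_in <- function(seq, cigar, start_unwrapped, genome, lo, hi) {
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[MIDS]", cigar))[[1]]
  rp <- start_unwrapped; qp <- 1L
  events <- 0L
  L <- genome$length
  for (t in seq_along(ops)) {
    len <- lens[t]
    if (ops[t] == "S") { qp <- qp + len; next }
    if (ops[t] == "M") {
      for (u in 0:(len - 1L)) {
        fold <- (rp + u - 1L) %% L + 1L
        if (fold >= lo && fold <= hi) {
          refb <- substr(genome$sequence, fold, fold)
          if (substr(seq, qp + u, qp + u) != refb) events <- events + 1L
        }
      }
      rp <- rp + len; qp <- qp + len
    } else if (ops[t] == "D") {
      fold <- (rp - 1L) %% L + 1L
      if (fold >= lo && fold <= hi) events <- events + 1L
      rp <- rp + len
    } else if (ops[t] == "I") {
      # inserted bases sit between rp-1 and rp; count the event if
      # either neighbour falls in the window (left-aligned insertions
      # at the window edge still belong to the homopolymer)
      fold_l <- (rp - 2L) %% L + 1L
      fold_r <- (rp - 1L) %% L + 1L
      if ((fold_l >= lo && fold_l <= hi) || (fold_r >= lo && fold_r <= hi)) {
        events <- events + 1L
      }
      qp <- qp + len
    }
  }
  events
}

#' Run the full read-level filter chain
#'
#' Convenience wrapper: byproduct filter, primer trimming, NUMT
#' exclusion and the HVII reverse-strand soft clip, in that order.
#'
#' @param aln alignment data.frame from [align_reads()].
#' @param genome a [circular_genome()].
#' @param panel a [panel()].
#' @param numt database for [numt_filter()] (`NULL` disables).
#' @param regions [named_regions()] supplying the HVII C-stretch.
#' @return filtered alignment data.frame.
#' @export
apply_read_filters <- function(aln, genome, panel, numt = NULL,
                               regions = named_regions()) {
  aln <- filter_byproduct(aln)
  aln <- trim_primers(aln, panel)
  if (!is.null(numt)) aln <- numt_filter(aln, numt)
  aln <- hvii_softclip(aln, genome, regions$hv2_cstretch)
  aln
}

#' Write alignments as SAM
#'
#' Emits a minimal SAM with an `@SQ` header for the circular genome.
#' Custom tags carry the assigned amplicon (`XA`), the usable span after
#' primer trimming and HVII clipping (`XK`), and filter flags (`XF`).
#'
#' @param aln alignment data.frame.
#' @param genome a [circular_genome()].
#' @param path output SAM path.
#' @return `path` invisibly.
#' @export
write_sam <- function(aln, genome, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d\tTP:circular", genome$name,
                   genome$length),
           "@PG\tID:mitotiler\tPN:mitotiler")
  rows <- vapply(seq_len(nrow(aln)), function(i) {
    a <- aln[i, ]
    flag <- 0L
    if (a$mate == 1L) flag <- flag + 64L else flag <- flag + 128L
    flag <- flag + 1L  # paired
    if (!isTRUE(a$aligned)) flag <- flag + 4L
    if (identical(a$strand, "-")) flag <- flag + 16L
    pos <- if (isTRUE(a$aligned)) a$ref_start else 0L
    cig <- if (isTRUE(a$aligned)) a$cigar else "*"
    rname <- if (isTRUE(a$aligned)) genome$name else "*"
    flags <- paste0(if (isTRUE(a$byproduct_filtered)) "B" else "",
                    if (isTRUE(a$numt_filtered)) "N" else "",
                    if (isTRUE(a$hvii_softclipped)) "H" else "")
    paste(paste0(a$pair_id, "/", a$mate), flag, rname, pos, 60L, cig,
          "*", 0L, 0L, a$seq, a$qual,
          paste0("XA:Z:", ifelse(is.na(a$amplicon), ".", a$amplicon)),
          paste0("XK:Z:", a$keep_lo, "-", a$keep_hi),
          paste0("XF:Z:", if (nzchar(flags)) flags else "."),
          sep = "\t")
  }, character(1))
  writeLines(c(hdr, rows), path)
  invisible(path)
}
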