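# Tiled amplicon panels: two staggered primer sets of small overlapping
# amplicons over a circular target.
#
# Primer sequences are proprietary in commercial kits and are not
# modeled; a primer here is a coordinate footprint of configurable length
# (default 20 bp) at each end of the amplicon. Adjacent amplicons must
# overlap by at least `min_overlap` insert bases so that no target base is
# lost to primer trimming, and alternate between set 1 and set 2 so that
# the two PCRs never compete over a shared footprint.

#' Construct an amplicon
#'
#' @param id amplicon identifier.
#' @param insert [region()] of the target bases between the primers.
#' @param fwd_primer_len,rev_primer_len primer footprint lengths (bp).
#' @param set_id 1 or 2 (staggered PCR set).
#' @param efficiency relative amplification weight (default 1).
#' @param genome_length circular genome length, used to derive the outer
#'   primer-to-primer span.
#' @param min_outer smallest supported outer length (60 bp for the
#'   commercial kits; lower for toy panels).
#' @return object of class `amplicon` with fields `id`, `outer`, `insert`,
#'   `fwd_primer_len`, `rev_primer_len`, `set_id`, `efficiency`.
#' @export
amplicon <- function(id, insert, fwd_primer_len = 20L, rev_primer_len = 20L,
                     set_id = 1L, efficiency = 1.0, genome_length,
                     min_outer = 60L) {
  wrap <- function(p) ((p - 1L) %% genome_length) + 1L
  outer <- region(wrap(insert$start - fwd_primer_len),
                  wrap(insert$end + rev_primer_len), id)
  a <- structure(
    list(id = as.character(id), outer = outer, insert = insert,
         fwd_primer_len = as.integer(fwd_primer_len),
         rev_primer_len = as.integer(rev_primer_len),
         set_id = as.integer(set_id), efficiency = as.numeric(efficiency)),
    class = "amplicon"
  )
  ol <- region_length(outer, genome_length)
  il <- region_length(insert, genome_length)
  if (ol != fwd_primer_len + il + rev_primer_len) {
    abort("amplicon %s: outer length %d != primers + insert (%d)",
          id, ol, fwd_primer_len + il + rev_primer_len)
  }
  if (ol < min_outer) {
    abort("amplicon %s: outer length %d below the %d bp minimum", id, ol,
          min_outer)
  }
  a
}

#' Construct a panel
#'
#' @param amplicons list of [amplicon()] ordered along the target.
#' @param target [region()] the panel tiles.
#' @param genome_name name of the reference genome.
#' @param genome_length circular genome length.
#' @param validate check panel invariants (complete coverage, >= 3 bp
#'   insert overlaps, alternating set ids)?
#' @return object of class `panel`.
#' @export
panel <- function(amplicons, target, genome_name, genome_length,
                  validate = TRUE) {
  p <- structure(
    list(amplicons = amplicons, target = target,
         genome_name = as.character(genome_name),
         genome_length = as.integer(genome_length)),
    class = "panel"
  )
  if (validate) validate_panel(p)
  p
}

#' @export
print.panel <- function(x, ...) {
  cat(sprintf("<panel> %d amplicons tiling %d..%d on %s (%d bp circle)\n",
              length(x$amplicons), x$target$start, x$target$end,
              x$genome_name, x$genome_length))
  invisible(x)
}

n_amplicons <- function(p) length(p$amplicons)

panel_is_circular <- function(p) {
  region_length(p$target, p$genome_length) == p$genome_length
}

# overlaps between genomically adjacent inserts, in panel order;
# includes the wrap pair when the panel tiles the full circle
adjacent_overlaps <- function(p) {
  n <- n_amplicons(p)
  if (n < 2L) return(integer())
  pos <- lapply(p$amplicons, function(a)
    region_positions(a$insert, p$genome_length))
  pairs <- cbind(seq_len(n - 1L), seq.int(2L, n))
  if (panel_is_circular(p)) pairs <- rbind(pairs, c(n, 1L))
  apply(pairs, 1L, function(ij)
    length(intersect(pos[[ij[1]]], pos[[ij[2]]])))
}

validate_panel <- function(p) {
  unc <- coverage_check(p, p$target, p$genome_length)
  if (length(unc) > 0L) {
    abort("panel does not cover the target (first gap %d..%d)",
          unc[[1]]$start, unc[[1]]$end)
  }
  ov <- adjacent_overlaps(p)
  if (length(ov) > 0L && min(ov) < 3L) {
    abort("adjacent inserts overlap by %d bp (< 3 bp minimum)", min(ov))
  }
  sets <- vapply(p$amplicons, `[[`, integer(1), "set_id")
  n <- length(sets)
  if (n >= 2L) {
    adj_same <- any(sets[-1] == sets[-n])
    if (panel_is_circular(p) && n %% 2L == 0L) {
      adj_same <- adj_same || sets[n] == sets[1]
    }
    if (adj_same) abort("adjacent amplicons share a primer set")
  }
  invisible(p)
}

#' Design a tiled two-set amplicon panel
#'
#' Walks the target drawing amplicon outer lengths uniformly from
#' `[min_len, max_len]` and insert overlaps uniformly from
#' `[min_overlap, min_overlap + 28]` (mean about 17 bp when
#' `min_overlap = 3`), alternating primer sets along the way. The final
#' amplicon is adjusted to end exactly at the target end (or, for a
#' full-circle target, to overlap the first insert), and for full-circle
#' targets an even amplicon count is enforced so that sets alternate all
#' the way around. Deterministic for a fixed seed.
#'
#' @param genome a [circular_genome()].
#' @param target [region()] to tile.
#' @param min_len,max_len outer amplicon length bounds (bp).
#' @param min_overlap minimum insert overlap between adjacent amplicons.
#' @param seed integer seed.
#' @param primer_len primer footprint length for both ends (bp).
#' @return a [panel()].
#' @export
design_tiled_panel <- function(genome, target, min_len = 60L, max_len = 150L,
                               min_overlap = 3L, seed = 1L,
                               primer_len = 20L) {
  t_len <- region_length(target, genome$length)
  if (max_len < min_len) abort("max_len < min_len")
  if (min_len < 2L * primer_len + 1L) {
    abort("min_len %d cannot hold two %d bp primers plus an insert",
          min_len, primer_len)
  }
  if (t_len < min_len) {
    abort("target of %d bp is shorter than the minimum amplicon (%d bp)",
          t_len, min_len)
  }
  min_insert <- min_len - 2L * primer_len
  if (min_overlap >= min_insert) {
    abort("min_overlap %d >= minimum insert length %d", min_overlap,
          min_insert)
  }
  circular <- t_len == genome$length
  tpos <- region_positions(target, genome$length)

  max_insert <- max_len - 2L * primer_len

  design_once <- function() {
    # local target coordinates 1..t_len; the last insert of a circular
    # design may run past t_len (wrapping into the first insert)
    starts <- integer(); ends <- integer()
    s <- 1L
    repeat {
      ins_len <- sample.int(max_insert - min_insert + 1L, 1L) +
        min_insert - 1L
      e <- s + ins_len - 1L
      if (e >= t_len) {
        if (circular) {
          # wrap: extend past t_len by a junction overlap into insert 1
          wrap_ov <- min_overlap + sample.int(15L, 1L) - 1L
          e <- t_len + wrap_ov
          if (e - s + 1L < min_insert) e <- s + min_insert - 1L
          if (e - s + 1L > max_insert) e <- s + max_insert - 1L
          if (e - t_len < min_overlap) e <- t_len + min_overlap
          if (e - s + 1L > max_insert) return(NULL)  # infeasible draw
        } else {
          e <- t_len
          if (e - s + 1L < min_insert) s <- t_len - min_insert + 1L
          if (e - s + 1L > max_insert) s <- e - max_insert + 1L
          if (s < 1L) return(NULL)
        }
        starts <- c(starts, s); ends <- c(ends, e)
        break
      }
      starts <- c(starts, s); ends <- c(ends, e)
      ov <- min_overlap + sample.int(29L, 1L) - 1L
      ov <- min(ov, ins_len - 1L)
      s <- e - ov + 1L
    }
    list(starts = starts, ends = ends)
  }

  local_to_genome <- function(x) tpos[((x - 1L) %% t_len) + 1L]

  set.seed(seed)
  for (attempt in 1:500) {
    d <- design_once()
    if (is.null(d)) next
    n <- length(d$starts)
    if (n < 2L) next
    if (circular && n %% 2L == 1L) next  # need even count to alternate sets
    ov_ok <- all((d$ends[-n] - d$starts[-1] + 1L) >= min_overlap)
    if (circular) ov_ok <- ov_ok && (d$ends[n] - t_len) >= min_overlap
    if (!ov_ok) next
    amps <- lapply(seq_len(n), function(i) {
      ins_start <- local_to_genome(d$starts[i])
      ins_end <- local_to_genome(d$ends[i])
      amplicon(id = sprintf("AMP%03d", i),
               insert = region(ins_start, ins_end),
               fwd_primer_len = primer_len, rev_primer_len = primer_len,
               set_id = if (i %% 2L == 1L) 1L else 2L,
               genome_length = genome$length, min_outer = min_len)
    })
    p <- tryCatch(
      panel(amps, target, genome$name, genome$length, validate = TRUE),
      error = function(e) NULL)
    if (!is.null(p)) return(p)
  }
  abort("panel design failed under the given constraints")
}

#' Summary statistics of a panel
#'
#' Lengths are outer (primer-to-primer) lengths; overlaps are insert
#' overlaps between genomically adjacent amplicons. Means are reported to
#' one decimal. A single-amplicon panel has no overlaps and reports
#' `mean_overlap = 0` with `n_overlaps = 0`.
#'
#' @param p a [panel()].
#' @return list with `n_amplicons`, `mean_length`, `min_length`,
#'   `max_length`, `mean_overlap`, `min_overlap`, `n_overlaps`.
#' @export
panel_stats <- function(p) {
  if (n_amplicons(p) == 0L) abort("empty panel")
  lens <- vapply(p$amplicons, function(a)
    region_length(a$outer, p$genome_length), integer(1))
  ov <- adjacent_overlaps(p)
  list(
    n_amplicons = n_amplicons(p),
    mean_length = round_half_up(mean(lens), 1),
    min_length = min(lens),
    max_length = max(lens),
    mean_overlap = if (length(ov)) round_half_up(mean(ov), 1) else 0,
    min_overlap = if (length(ov)) min(ov) else 0L,
    n_overlaps = length(ov)
  )
}

#' Uncovered target regions under a panel
#'
#' @param p a [panel()] (or a panel whose amplicons were subset).
#' @param target [region()] to check.
#' @param genome_length circular genome length.
#' @return list of uncovered [region()]s (empty when every target
#'   position lies in at least one insert).
#' @export
coverage_check <- function(p, target, genome_length) {
  tpos <- region_positions(target, genome_length)
  covered <- unique(unlist(lapply(p$amplicons, function(a)
    region_positions(a$insert, genome_length))))
  split_positions_to_ranges(tpos, setdiff(tpos, covered))
}

#' Write / read a panel as TSV
#'
#' Columns: `id, outer_start, outer_end, insert_start, insert_end,
#' fwd_primer_len, rev_primer_len, set_id, efficiency`.
#'
#' @param p a [panel()].
#' @param path output TSV path.
#' @return `path` invisibly.
#' @export
write_panel_tsv <- function(p, path) {
  df <- do.call(rbind, lapply(p$amplicons, function(a) data.frame(
    id = a$id, outer_start = a$outer$start, outer_end = a$outer$end,
    insert_start = a$insert$start, insert_end = a$insert$end,
    fwd_primer_len = a$fwd_primer_len, rev_primer_len = a$rev_primer_len,
    set_id = a$set_id, efficiency = a$efficiency,
    stringsAsFactors = FALSE)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_panel_tsv
#' @param target,genome_name,genome_length panel metadata (the TSV stores
#'   amplicons only).
#' @export
read_panel_tsv <- function(path, target, genome_name, genome_length) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  amps <- lapply(seq_len(nrow(df)), function(i) {
    amplicon(df$id[i], region(df$insert_start[i], df$insert_end[i]),
             df$fwd_primer_len[i], df$rev_primer_len[i], df$set_id[i],
             df$efficiency[i], genome_length,
             min_outer = min(60L, df$fwd_primer_len[i] +
                                    df$rev_primer_len[i] + 1L))
  })
  panel(amps, target, genome_name, genome_length, validate = FALSE)
}

#' Export panel inserts as BED
#'
#' Emits 6-column BED (0-based half-open). Inserts that wrap the origin
#' are split into two BED lines.
#'
#' @param p a [panel()].
#' @param path output BED path.
#' @return `path` invisibly.
#' @export
write_panel_bed <- function(p, path) {
  rows <- character()
  for (a in p$amplicons) {
    strand <- "+"
    score <- "0"
    if (a$insert$end >= a$insert$start) {
      rows <- c(rows, paste(p$genome_name, a$insert$start - 1L,
                            a$insert$end, a$id, score, strand, sep = "\t"))
    } else {
      rows <- c(rows,
                paste(p$genome_name, a$insert$start - 1L, p$genome_length,
                      a$id, score, strand, sep = "\t"),
                paste(p$genome_name, 0L, a$insert$end, a$id, score, strand,
                      sep = "\t"))
    }
  }
  writeLines(rows, path)
  invisible(path)
}
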