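# Simulation of tiled-amplicon sequencing runs: haplotypes, heteroplasmy,
# two-person mixtures, NTCs, NUMT contamination, index crosstalk and
# run-to-run carryover.
#
# Reads are represented in memory as a data.frame with one row per read
# pair: `id`, `r1_seq`, `r1_qual`, `r2_seq`, `r2_qual`, observed index
# columns `i7`/`i5`, and truth columns `truth_sample`, `truth_contributor`,
# `truth_amplicon`, `truth_numt`, `truth_origin`. Truth lives in its own
# columns (and a sidecar JSON on disk) so downstream checks never parse
# read names.

#' Specify one variant carried by a simulated molecule
#'
#' @param position 1-based reference coordinate.
#' @param kind `"substitution"`, `"insertion"` or `"deletion"`.
#' @param alt inserted bases (insertion), the new base (substitution) or
#'   `""` (deletion).
#' @param insertion_index ordinal for pos.N naming (insertions only).
#' @param fraction fraction of molecules carrying the variant in (0, 1];
#'   1 denotes a fixed variant, < 1 heteroplasmy.
#' @return one-row data.frame.
#' @export
variant_spec <- function(position, kind, alt = "", insertion_index = 0L,
                         fraction = 1.0) {
  kind <- match.arg(kind, c("substitution", "insertion", "deletion"))
  if (fraction <= 0 || fraction > 1) abort("fraction must be in (0, 1]")
  if (kind == "insertion" && insertion_index < 1L) {
    abort("insertions need insertion_index >= 1")
  }
  data.frame(position = as.integer(position), kind = kind,
             alt = toupper(alt), insertion_index = as.integer(insertion_index),
             fraction = fraction, stringsAsFactors = FALSE)
}

#' Specify a haplotype as a set of variants
#'
#' @param name haplotype name.
#' @param variants data.frame built by rbinding [variant_spec()] rows
#'   (may be empty).
#' @return object of class `haplotype_spec`.
#' @export
haplotype_spec <- function(name, variants = NULL) {
  if (is.null(variants)) {
    variants <- variant_spec(1, "substitution", "A")[0, ]
  }
  nonins <- variants[variants$kind != "insertion", ]
  if (anyDuplicated(nonins$position)) {
    abort("haplotype %s: conflicting variants at one position", name)
  }
  ins <- variants[variants$kind == "insertion", ]
  if (nrow(ins) > 0L) {
    for (p in unique(ins$position)) {
      ords <- sort(ins$insertion_index[ins$position == p])
      if (!identical(ords, seq_along(ords))) {
        abort("haplotype %s: insertion ordinals at %d not contiguous from 1",
              name, p)
      }
    }
  }
  structure(list(name = as.character(name), variants = variants),
            class = "haplotype_spec")
}

#' Build a haplotype spec from a SWGDAM-style variant string
#'
#' All variants are created as fixed (fraction 1); heteroplasmy fractions
#' can be set afterwards on the `variants` data.frame.
#'
#' @param name haplotype name.
#' @param text variant string, e.g. `"73G 263G 315.1C"`.
#' @param genome optional genome for position validation.
#' @return a [haplotype_spec()].
#' @export
haplotype_spec_from_string <- function(name, text, genome = NULL) {
  hap <- parse_haplotype(text, genome)
  t <- hap$tokens
  if (nrow(t) == 0L) return(haplotype_spec(name))
  vars <- do.call(rbind, lapply(seq_len(nrow(t)), function(i) {
    if (t$kind[i] == "deletion") {
      variant_spec(t$position[i], "deletion")
    } else if (t$kind[i] == "insertion") {
      variant_spec(t$position[i], "insertion", t$symbol[i], t$ordinal[i])
    } else {
      variant_spec(t$position[i], "substitution", t$symbol[i])
    }
  }))
  haplotype_spec(name, vars)
}

#' Apply the fixed variants of a haplotype to a genome
#'
#' Substitutions replace the base, insertions are inserted after the
#' named position in ordinal order, deletions remove the base. Only
#' fraction-1 variants are applied; sub-unit fractions are realized
#' per molecule by [simulate_library()].
#'
#' @param genome a [circular_genome()].
#' @param hap a [haplotype_spec()] (or `haplotype` from
#'   [parse_haplotype()], treated as all-fixed).
#' @return list with `sequence` (mutated string) and `map`, a data.frame
#'   with one row per mutated base: `mut_pos`, `ref_pos` (anchor position
#'   for inserted bases) and `is_insertion`.
#' @export
apply_haplotype <- function(genome, hap) {
  if (inherits(hap, "haplotype")) {
    hap <- haplotype_spec_from_string("hap", format_haplotype(hap))
  }
  v <- hap$variants
  v <- v[v$fraction >= 1.0, , drop = FALSE]
  if (any(v$position > genome$length)) {
    abort("variant position beyond genome length")
  }
  ref <- strsplit(genome$sequence, "")[[1]]
  out_base <- ref
  deleted <- rep(FALSE, genome$length)
  ins_after <- vector("list", genome$length)
  for (i in seq_len(nrow(v))) {
    p <- v$position[i]
    switch(v$kind[i],
      substitution = { out_base[p] <- v$alt[i] },
      deletion = { deleted[p] <- TRUE },
      insertion = {
        ins_after[[p]] <- c(ins_after[[p]],
                            stats::setNames(v$alt[i],
                                            v$insertion_index[i]))
      })
  }
  pieces <- character(0)
  ref_pos <- integer(0)
  is_ins <- logical(0)
  for (p in seq_len(genome$length)) {
    if (!deleted[p]) {
      pieces <- c(pieces, out_base[p]); ref_pos <- c(ref_pos, p)
      is_ins <- c(is_ins, FALSE)
    }
    if (!is.null(ins_after[[p]])) {
      ins <- ins_after[[p]][order(as.integer(names(ins_after[[p]])))]
      for (b in ins) {
        for (ch in strsplit(b, "")[[1]]) {
          pieces <- c(pieces, ch); ref_pos <- c(ref_pos, p)
          is_ins <- c(is_ins, TRUE)
        }
      }
    }
  }
  list(sequence = paste(pieces, collapse = ""),
       map = data.frame(mut_pos = seq_along(pieces), ref_pos = ref_pos,
                        is_insertion = is_ins))
}

#' Specify a simulated library
#'
#' @param sample_name library name.
#' @param contributors list of `list(hap = haplotype_spec, weight = w)`;
#'   weights must sum to 1.
#' @param total_read_pairs read pairs to simulate (0 models an NTC).
#' @param per_amplicon_efficiency optional named numeric vector of
#'   amplicon-id weights overriding the panel's efficiencies.
#' @param base_error_rate per-base substitution error probability.
#' @param quality_mean,quality_sd per-base Phred quality profile (clipped
#'   normal, floor 2).
#' @param stutter_prob probability of a +-1 slip per homopolymer run of
#'   five or more bases per molecule.
#' @param numt_fraction fraction of read pairs replaced by NUMT decoy
#'   fragments (needs `numt_db` at simulation time).
#' @param seed integer seed.
#' @return object of class `library_spec`.
#' @export
library_spec <- function(sample_name, contributors = list(),
                         total_read_pairs = 0L,
                         per_amplicon_efficiency = NULL,
                         base_error_rate = 0.001,
                         quality_mean = 36, quality_sd = 3,
                         stutter_prob = 0.01,
                         numt_fraction = 0, seed = 1L) {
  if (length(contributors) > 0L) {
    w <- vapply(contributors, `[[`, numeric(1), "weight")
    if (abs(sum(w) - 1) > 1e-8) abort("contributor weights must sum to 1")
  }
  if (total_read_pairs < 0L) abort("total_read_pairs must be >= 0")
  structure(list(sample_name = sample_name, contributors = contributors,
                 total_read_pairs = as.integer(total_read_pairs),
                 per_amplicon_efficiency = per_amplicon_efficiency,
                 base_error_rate = base_error_rate,
                 quality_mean = quality_mean, quality_sd = quality_sd,
                 stutter_prob = stutter_prob,
                 numt_fraction = numt_fraction, seed = as.integer(seed)),
            class = "library_spec")
}

empty_reads <- function() {
  data.frame(id = character(), r1_seq = character(), r1_qual = character(),
             r2_seq = character(), r2_qual = character(),
             i7 = character(), i5 = character(),
             truth_sample = character(), truth_contributor = character(),
             truth_amplicon = character(), truth_numt = logical(),
             truth_origin = character(), stringsAsFactors = FALSE)
}

# apply a contributor's variants to one amplicon's outer sequence.
# `present` selects which rows of vars are realized on this molecule.
mutate_amplicon_seq <- function(outer_seq, outer_pos, vars, present) {
  v <- vars[present, , drop = FALSE]
  if (nrow(v) == 0L) return(outer_seq)
  loc <- match(v$position, outer_pos)
  keep <- !is.na(loc)
  v <- v[keep, , drop = FALSE]; loc <- loc[keep]
  if (nrow(v) == 0L) return(outer_seq)
  chars <- strsplit(outer_seq, "")[[1]]
  app <- rep("", length(chars))
  for (i in order(loc, v$insertion_index)) {
    switch(v$kind[i],
      substitution = { chars[loc[i]] <- v$alt[i] },
      deletion = { chars[loc[i]] <- "" },
      insertion = { app[loc[i]] <- paste0(app[loc[i]], v$alt[i]) })
  }
  paste(paste0(chars, app), collapse = "")
}

# one +-1 slip in one randomly chosen qualifying homopolymer run
apply_stutter_one <- function(seq, min_run = 5L) {
  r <- rle(strsplit(seq, "")[[1]])
  runs <- which(r$lengths >= min_run)
  if (length(runs) == 0L) return(seq)
  hit <- runs[sample.int(length(runs), 1L)]
  r$lengths[hit] <- r$lengths[hit] + (if (stats::runif(1) < 0.5) -1L else 1L)
  paste(rep(r$values, r$lengths), collapse = "")
}

count_stutter_runs <- function(seq, min_run = 5L) {
  r <- rle(strsplit(seq, "")[[1]])
  sum(r$lengths >= min_run)
}

#' Simulate one library
#'
#' Each read pair derives from one amplicon of one contributor molecule:
#' the amplicon is chosen proportional to efficiency, the contributor
#' proportional to its weight, and each sub-unit-fraction variant is
#' realized per molecule as Bernoulli(fraction). R1 reads the forward
#' strand from the amplicon's outer start, R2 the reverse complement from
#' its outer end; both include primer bases and are truncated at
#' `read_length`. Per-base substitution errors are applied at
#' `base_error_rate`; indel errors occur only as homopolymer stutter.
#' Deterministic for a fixed `spec$seed`.
#'
#' @param genome a [circular_genome()].
#' @param panel a [panel()].
#' @param spec a [library_spec()].
#' @param read_length sequencing cycles per mate (151 or 201).
#' @return reads data.frame (see module header).
#' @export
simulate_library <- function(genome, panel, spec, read_length = 151L) {
  set.seed(spec$seed)
  n <- spec$total_read_pairs
  if (n == 0L) return(empty_reads())
  if (length(spec$contributors) == 0L) {
    abort("library %s has reads but no contributors", spec$sample_name)
  }
  amps <- panel$amplicons
  eff <- vapply(amps, `[[`, numeric(1), "efficiency")
  names(eff) <- vapply(amps, `[[`, character(1), "id")
  if (!is.null(spec$per_amplicon_efficiency)) {
    ids <- names(spec$per_amplicon_efficiency)
    unknown <- setdiff(ids, names(eff))
    if (length(unknown) > 0L) {
      abort("unknown amplicon id in efficiency spec: %s", unknown[1])
    }
    eff[ids] <- spec$per_amplicon_efficiency
  }
  w <- vapply(spec$contributors, `[[`, numeric(1), "weight")
  amp_idx <- sample.int(length(amps), n, replace = TRUE, prob = eff)
  con_idx <- sample.int(length(w), n, replace = TRUE, prob = w)

  outer_seq <- vapply(amps, function(a) subsequence(genome, a$outer),
                      character(1))
  outer_pos <- lapply(amps, function(a)
    region_positions(a$outer, genome$length))

  # per (contributor, amplicon): variant rows in range, split fixed/het
  var_cache <- list()
  get_vars <- function(ci, ai) {
    key <- paste0(ci, ":", ai)
    if (is.null(var_cache[[key]])) {
      v <- spec$contributors[[ci]]$hap$variants
      v <- v[v$position %in% outer_pos[[ai]], , drop = FALSE]
      var_cache[[key]] <<- v
    }
    var_cache[[key]]
  }

  # molecules are cached by (contributor, amplicon, realized het subset);
  # the per-molecule stutter model allows at most one slip per molecule
  # (the per-run slip probability aggregates to a molecule-level trigger)
  mol_cache <- new.env(parent = emptyenv())
  get_molecule <- function(ci, ai, present) {
    key <- paste0(ci, ":", ai, ":", paste(which(present), collapse = ","))
    val <- mol_cache[[key]]
    if (is.null(val)) {
      v <- get_vars(ci, ai)
      s <- mutate_amplicon_seq(outer_seq[ai], outer_pos[[ai]], v, present)
      val <- list(seq = s, nruns = count_stutter_runs(s))
      mol_cache[[key]] <- val
    }
    val
  }

  seqs <- character(n)
  for (i in seq_len(n)) {
    ai <- amp_idx[i]; ci <- con_idx[i]
    v <- get_vars(ci, ai)
    present <- v$fraction >= 1.0
    het <- which(!present)
    if (length(het) > 0L) {
      present[het] <- stats::runif(length(het)) < v$fraction[het]
    }
    mol <- get_molecule(ci, ai, present)
    s <- mol$seq
    if (spec$stutter_prob > 0 && mol$nruns > 0L &&
        stats::runif(1) < 1 - (1 - spec$stutter_prob)^mol$nruns) {
      s <- apply_stutter_one(s)
    }
    seqs[i] <- s
  }

  r1 <- substr(seqs, 1L, read_length)
  r2 <- substr(reverse_complement_many(seqs), 1L, read_length)

  r1 <- add_seq_errors(r1, spec$base_error_rate)
  r2 <- add_seq_errors(r2, spec$base_error_rate)
  q1 <- random_quals(nchar(r1), spec$quality_mean, spec$quality_sd)
  q2 <- random_quals(nchar(r2), spec$quality_mean, spec$quality_sd)

  data.frame(
    id = sprintf("%s:%06d", spec$sample_name, seq_len(n)),
    r1_seq = r1, r1_qual = q1, r2_seq = r2, r2_qual = q2,
    i7 = NA_character_, i5 = NA_character_,
    truth_sample = spec$sample_name,
    truth_contributor = vapply(con_idx, function(ci)
      spec$contributors[[ci]]$hap$name, character(1)),
    truth_amplicon = vapply(amp_idx, function(ai) amps[[ai]]$id,
                            character(1)),
    truth_numt = FALSE, truth_origin = "sample",
    stringsAsFactors = FALSE
  )
}

add_seq_errors <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  lens <- nchar(seqs)
  nerr <- stats::rbinom(length(seqs), lens, rate)
  hit <- which(nerr > 0L)
  bases <- c("A", "C", "G", "T")
  for (i in hit) {
    pos <- sample.int(lens[i], nerr[i])
    ch <- strsplit(seqs[i], "")[[1]]
    for (p in pos) {
      ch[p] <- sample(setdiff(bases, ch[p]), 1L)
    }
    seqs[i] <- paste(ch, collapse = "")
  }
  seqs
}

random_quals <- function(lens, mean_q, sd_q) {
  total <- sum(lens)
  if (total == 0L) return(rep("", length(lens)))
  q <- as.integer(round(stats::rnorm(total, mean_q, sd_q)))
  q <- pmin(pmax(q, 2L), 41L)
  big <- rawToChar(as.raw(q + 33L))
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  substring(big, starts, ends)
}

#' Specify a sequencing run
#'
#' @param libraries list of `list(spec = library_spec, i7 = , i5 = )`.
#' @param bait_indexes list of `list(i7 = , i5 = )` index pairs placed on
#'   the sample sheet with no physical library (carryover baits).
#' @param crosstalk_rate probability that a read pair is emitted under
#'   another sheet entry's index pair sharing its i5 or i7.
#' @param carryover optional `list(reads = <reads data.frame>,
#'   fraction = f)` from a previous run.
#' @param read_length cycles (151 or 201).
#' @param seed integer seed.
#' @return object of class `run_spec`.
#' @export
run_spec <- function(libraries, bait_indexes = list(), crosstalk_rate = 0,
                     carryover = NULL, read_length = 151L, seed = 1L) {
  keys <- c(vapply(libraries, function(l) paste0(l$i7, "+", l$i5),
                   character(1)),
            vapply(bait_indexes, function(b) paste0(b$i7, "+", b$i5),
                   character(1)))
  if (anyDuplicated(keys)) abort("duplicate index pairs in run")
  structure(list(libraries = libraries, bait_indexes = bait_indexes,
                 crosstalk_rate = crosstalk_rate, carryover = carryover,
                 read_length = as.integer(read_length),
                 seed = as.integer(seed)),
            class = "run_spec")
}

#' Deterministic dual-index pairs
#'
#' @param n number of pairs.
#' @return data.frame with `i7`, `i5` (8-mers, unique pairs).
#' @export
make_index_pairs <- function(n) {
  bases <- c("A", "C", "G", "T")
  enc <- function(k) {
    # 8-mer from integer, base-4 digits
    paste(bases[(k %/% 4^(7:0)) %% 4 + 1], collapse = "")
  }
  # spread codes so pairs differ at several positions
  i7 <- vapply(seq_len(n) * 2654435761, enc, character(1))
  i5 <- vapply(seq_len(n) * 40503 + 7919, enc, character(1))
  data.frame(i7 = i7, i5 = i5, stringsAsFactors = FALSE)
}

#' Simulate a full sequencing run
#'
#' Simulates each library, annotates reads with its index pair, applies
#' index crosstalk (a read's observed indexes are replaced by those of
#' another sheet entry sharing i5 or i7), and injects carryover reads
#' from a previous run under their original indexes. Bait index pairs
#' appear in the sample sheet but emit no reads themselves.
#'
#' @param runspec a [run_spec()].
#' @param genome a [circular_genome()].
#' @param panel a [panel()].
#' @return list with `reads` (data.frame), `samplesheet` (data.frame
#'   `Sample_ID,index,index2,role`) and `truth` (list).
#' @export
simulate_run <- function(runspec, genome, panel) {
  libs <- runspec$libraries
  reads_list <- lapply(libs, function(l) {
    r <- simulate_library(genome, panel, l$spec, runspec$read_length)
    if (nrow(r) > 0L) { r$i7 <- l$i7; r$i5 <- l$i5 }
    r
  })
  reads <- do.call(rbind, c(reads_list, list(empty_reads())))

  sheet <- rbind(
    do.call(rbind, c(lapply(libs, function(l) data.frame(
      Sample_ID = l$spec$sample_name, index = l$i7, index2 = l$i5,
      role = if (l$spec$total_read_pairs == 0L) "ntc" else "sample",
      stringsAsFactors = FALSE)), list(NULL))),
    do.call(rbind, c(lapply(seq_along(runspec$bait_indexes), function(i) {
      b <- runspec$bait_indexes[[i]]
      data.frame(Sample_ID = sprintf("bait%02d", i), index = b$i7,
                 index2 = b$i5, role = "bait", stringsAsFactors = FALSE)
    }), list(NULL)))
  )

  set.seed(runspec$seed)
  n_cross <- 0L
  if (runspec$crosstalk_rate > 0 && nrow(reads) > 0L) {
    flip <- stats::runif(nrow(reads)) < runspec$crosstalk_rate
    for (i in which(flip)) {
      shares <- which((sheet$index == reads$i7[i] |
                         sheet$index2 == reads$i5[i]) &
                        !(sheet$index == reads$i7[i] &
                            sheet$index2 == reads$i5[i]))
      if (length(shares) == 0L) next
      j <- shares[sample.int(length(shares), 1L)]
      reads$i7[i] <- sheet$index[j]
      reads$i5[i] <- sheet$index2[j]
      reads$truth_origin[i] <- "crosstalk"
      n_cross <- n_cross + 1L
    }
  }

  n_carry <- 0L
  if (!is.null(runspec$carryover) && runspec$carryover$fraction > 0) {
    prev <- runspec$carryover$reads
    n_carry <- stats::rbinom(1L, nrow(prev), runspec$carryover$fraction)
    if (n_carry > 0L) {
      idx <- sample.int(nrow(prev), n_carry)
      co <- prev[idx, , drop = FALSE]
      co$truth_origin <- "carryover"
      co$id <- paste0("carryover:", co$id)
      reads <- rbind(reads, co)
    }
  }

  truth <- list(
    samples = lapply(libs, function(l) list(
      name = l$spec$sample_name, i7 = l$i7, i5 = l$i5,
      read_pairs = l$spec$total_read_pairs,
      contributors = lapply(l$spec$contributors, function(co)
        list(name = co$hap$name, weight = co$weight)))),
    n_crosstalk_reads = n_cross,
    n_carryover_reads = n_carry
  )
  list(reads = reads, samplesheet = sheet, truth = truth)
}

#' Replace a fraction of reads with NUMT decoy fragments
#'
#' @param reads reads data.frame.
#' @param numt_db a [numt_db()] (decoy sequences).
#' @param fraction fraction of read pairs to replace.
#' @param seed integer seed.
#' @param read_length cycles per mate.
#' @return modified reads data.frame (`truth_numt` set on replaced rows).
#' @export
spike_numts <- function(reads, numt_db, fraction, seed = 1L,
                        read_length = 151L) {
  if (fraction < 0 || fraction > 1) abort("fraction must be in [0, 1]")
  if (fraction == 0 || nrow(reads) == 0L) return(reads)
  if (length(numt_db$sequences) == 0L) abort("empty NUMT database")
  set.seed(seed)
  n <- stats::rbinom(1L, nrow(reads), fraction)
  if (n == 0L) return(reads)
  idx <- sample.int(nrow(reads), n)
  for (i in idx) {
    d <- sample.int(length(numt_db$sequences), 1L)
    dseq <- numt_db$sequences[[d]]
    flen <- min(nchar(dseq), sample(100:200, 1L))
    start <- sample.int(nchar(dseq) - flen + 1L, 1L)
    frag <- substr(dseq, start, start + flen - 1L)
    reads$r1_seq[i] <- substr(frag, 1L, read_length)
    reads$r2_seq[i] <- substr(reverse_complement(frag), 1L, read_length)
    reads$r1_qual[i] <- random_quals(nchar(reads$r1_seq[i]), 36, 3)
    reads$r2_qual[i] <- random_quals(nchar(reads$r2_seq[i]), 36, 3)
    reads$truth_numt[i] <- TRUE
    reads$truth_origin[i] <- "numt"
  }
  reads
}

#' Write a simulated run to disk
#'
#' Writes standard 4-line FASTQ for R1 and R2 (index pair in the comment
#' field, `1:N:0:I7+I5`), an Illumina-style sample sheet CSV and the
#' truth sidecar JSON.
#'
#' @param run result of [simulate_run()].
#' @param dir output directory (created).
#' @return named list of file paths.
#' @export
write_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  r1_path <- file.path(dir, "R1.fastq")
  r2_path <- file.path(dir, "R2.fastq")
  sheet_path <- file.path(dir, "samplesheet.csv")
  truth_path <- file.path(dir, "truth.json")
  reads <- run$reads
  write_fastq <- function(path, seqs, quals, mate) {
    hdr <- sprintf("@%s %d:N:0:%s+%s", reads$id, mate, reads$i7, reads$i5)
    writeLines(as.vector(rbind(hdr, seqs, "+", quals)), path)
  }
  if (nrow(reads) > 0L) {
    write_fastq(r1_path, reads$r1_seq, reads$r1_qual, 1L)
    write_fastq(r2_path, reads$r2_seq, reads$r2_qual, 2L)
  } else {
    writeLines(character(), r1_path); writeLines(character(), r2_path)
  }
  utils::write.csv(run$samplesheet, sheet_path, row.names = FALSE,
                   quote = FALSE)
  jsonlite::write_json(run$truth, truth_path, auto_unbox = TRUE,
                       pretty = TRUE)
  list(r1 = r1_path, r2 = r2_path, samplesheet = sheet_path,
       truth = truth_path)
}

#' Read a run's FASTQ pair back into a reads table
#'
#' Inverse of [write_run()] for the read data (truth columns are filled
#' with placeholders; the sidecar JSON carries the truth).
#'
#' @param r1_path,r2_path FASTQ paths.
#' @return reads data.frame.
#' @export
read_run_fastq <- function(r1_path, r2_path) {
  parse_fq <- function(path) {
    lines <- readLines(path)
    if (length(lines) == 0L) return(NULL)
    hdr <- lines[seq(1, length(lines), 4)]
    seqs <- lines[seq(2, length(lines), 4)]
    quals <- lines[seq(4, length(lines), 4)]
    id <- sub("^@", "", sub("\\s.*$", "", hdr))
    comment <- sub("^\\S+\\s*", "", sub("^@", "", hdr))
    idx <- sub("^.*:", "", comment)
    i7 <- sub("\\+.*$", "", idx)
    i5 <- sub("^.*\\+", "", idx)
    data.frame(id = id, seq = seqs, qual = quals, i7 = i7, i5 = i5,
               stringsAsFactors = FALSE)
  }
  f1 <- parse_fq(r1_path); f2 <- parse_fq(r2_path)
  if (is.null(f1)) return(empty_reads())
  stopifnot(identical(f1$id, f2$id))
  data.frame(id = f1$id, r1_seq = f1$seq, r1_qual = f1$qual,
             r2_seq = f2$seq, r2_qual = f2$qual, i7 = f1$i7, i5 = f1$i5,
             truth_sample = NA_character_, truth_contributor = NA_character_,
             truth_amplicon = NA_character_, truth_numt = NA,
             truth_origin = NA_character_, stringsAsFactors = FALSE)
}

#' NUMT decoy database
#'
#' @param sequences named character vector or list of decoy sequences.
#' @param genome optional [circular_genome()]; when given, decoys that
#'   occur verbatim in the genome trigger a warning (such decoys cannot
#'   be distinguished from true mtDNA by exclusion matching).
#' @return object of class `numt_db`.
#' @export
numt_db <- function(sequences, genome = NULL) {
  sequences <- as.list(sequences)
  if (!is.null(genome) && length(sequences) > 0L) {
    doubled <- paste0(genome$sequence, genome$sequence)
    for (nm in seq_along(sequences)) {
      if (grepl(sequences[[nm]], doubled, fixed = TRUE)) {
        warning(sprintf(
          "NUMT decoy %s is identical to a reference segment; it cannot be detected by exclusion matching",
          names(sequences)[nm] %||% nm), call. = FALSE)
      }
    }
  }
  structure(list(sequences = sequences), class = "numt_db")
}

#' Load NUMT decoys from FASTA
#'
#' @param path FASTA of decoy sequences.
#' @param genome optional genome for the identity warning (see
#'   [numt_db()]).
#' @return a [numt_db()].
#' @export
load_numt_fasta <- function(path, genome = NULL) {
  set <- Biostrings::readDNAStringSet(path)
  seqs <- stats::setNames(as.list(as.character(set)),
                          sub("\\s.*$", "", names(set)))
  numt_db(seqs, genome)
}
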