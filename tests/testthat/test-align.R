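test_that("error-free amplicon reads align exactly where they came from", {
  g <- rcrs(); p <- cr_panel()
  a <- p$amplicons[[2]]
  seq <- subsequence(g, a$outer)
  reads <- data.frame(id = "r1", r1_seq = seq,
                      r1_qual = strrep("I", nchar(seq)),
                      r2_seq = reverse_complement(seq),
                      r2_qual = strrep("I", nchar(seq)),
                      i7 = NA, i5 = NA, truth_sample = "t",
                      truth_contributor = "t", truth_amplicon = a$id,
                      truth_numt = FALSE, truth_origin = "sample",
                      stringsAsFactors = FALSE)
  aln <- align_reads(reads, g, p)
  expect_true(all(aln$aligned))
  expect_equal(aln$ref_start[1], a$outer$start)
  expect_match(aln$cigar[1], "^[0-9]+M$")
  expect_equal(aln$amplicon, rep(a$id, 2))
  expect_equal(sort(aln$strand), c("+", "-"))
})

test_that("reads spanning the origin align contiguously on the circle", {
  g <- toy_genome(400L, seed = 2L)
  read <- paste0(subsequence(g, region(381, 400)),
                 subsequence(g, region(1, 30)))
  p <- design_tiled_panel(g, region(1, 400), 40L, 60L, 3L, seed = 2L,
                          primer_len = 10L)
  reads <- data.frame(id = "w", r1_seq = read,
                      r1_qual = strrep("I", nchar(read)),
                      r2_seq = reverse_complement(read),
                      r2_qual = strrep("I", nchar(read)),
                      i7 = NA, i5 = NA, truth_sample = "t",
                      truth_contributor = "t", truth_amplicon = NA,
                      truth_numt = FALSE, truth_origin = "sample",
                      stringsAsFactors = FALSE)
  aln <- align_reads(reads, g, p)
  expect_true(aln$aligned[1])
  expect_equal(aln$ref_start[1], 381L)
  expect_match(aln$cigar[1], "^50M$")
})

test_that("non-genomic reads are flagged unaligned, not errors", {
  g <- rcrs(); p <- cr_panel()
  set.seed(77)
  junk <- paste(sample(c("A", "C", "G", "T"), 120, replace = TRUE),
                collapse = "")
  reads <- data.frame(id = "j", r1_seq = junk,
                      r1_qual = strrep("I", 120),
                      r2_seq = junk, r2_qual = strrep("I", 120),
                      i7 = NA, i5 = NA, truth_sample = "t",
                      truth_contributor = "t", truth_amplicon = NA,
                      truth_numt = FALSE, truth_origin = "sample",
                      stringsAsFactors = FALSE)
  aln <- align_reads(reads, g, p)
  expect_false(any(aln$aligned))
})

test_that("banded aligner scores equal the full-DP oracle", {
  g <- rcrs()
  set.seed(123)
  par <- align_params()
  for (case in 1:40) {
    len <- sample(40:300, 1)
    start <- sample(g$length - len - 400L, 1)
    read <- substr(g$sequence, start, start + len - 1L)
    ch <- strsplit(read, "")[[1]]
    # a few substitutions and at most one short indel, inside the band
    nmut <- sample(0:3, 1)
    if (nmut > 0) {
      at <- sample(len, nmut)
      ch[at] <- vapply(ch[at], function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
    }
    if (runif(1) < 0.4 && len > 60) {
      cut <- sample(10:(len - 10), 1)
      ch <- ch[-(cut:(cut + sample(1:3, 1) - 1))]
    }
    read_mut <- paste(ch, collapse = "")
    win <- substr(g$sequence, start - 30L, start + len + 30L)
    got <- .fit_align_cpp(read_mut, win, par$match, par$mismatch,
                          par$gap_open, par$gap_extend, par$band, 30L)
    want <- oracle_fit_score(read_mut, win)
    expect_equal(got$score, want, info = paste("case", case))
  }
})

test_that("quality masking is strict at the Q30 boundary", {
  seq <- "ACGT"
  expect_length(mask_low_quality(seq, phred_to_qual_chr(c(36, 36, 36, 36))),
                0L)
  expect_equal(mask_low_quality(seq, phred_to_qual_chr(c(36, 29, 36, 36))),
               2L)
  expect_length(mask_low_quality(seq, phred_to_qual_chr(c(30, 30, 30, 30))),
                0L)
  expect_error(mask_low_quality("ACGT", "II"), "mismatch")
})

test_that("byproduct filter removes fragments under 40 bp only", {
  mk <- function(frag_len) {
    data.frame(pair_id = "p", mate = 1:2, seq = "A", qual = "I",
               aligned = TRUE, strand = c("+", "-"), ref_start = 100L,
               start_unwrapped = 100L,
               end_unwrapped = 100L + frag_len - 1L,
               cigar = "1M", score = 1L, nm = 0L, amplicon = "a",
               keep_lo = 100L, keep_hi = 100L + frag_len - 1L,
               byproduct_filtered = FALSE, numt_filtered = FALSE,
               hvii_softclipped = FALSE, primer_trimmed = FALSE,
               stringsAsFactors = FALSE)
  }
  expect_true(all(filter_byproduct(mk(39))$byproduct_filtered))
  expect_false(any(filter_byproduct(mk(40))$byproduct_filtered))
  expect_false(any(filter_byproduct(mk(60))$byproduct_filtered))
})

test_that("primer trimming restricts reads to the insert", {
  g <- rcrs(); p <- cr_panel()
  a <- p$amplicons[[3]]
  full <- subsequence(g, a$outer)
  insert_only <- subsequence(g, a$insert)
  mkreads <- function(s) data.frame(
    id = "r", r1_seq = s, r1_qual = strrep("I", nchar(s)),
    r2_seq = reverse_complement(s), r2_qual = strrep("I", nchar(s)),
    i7 = NA, i5 = NA, truth_sample = "t", truth_contributor = "t",
    truth_amplicon = a$id, truth_numt = FALSE, truth_origin = "sample",
    stringsAsFactors = FALSE)
  aln <- trim_primers(align_reads(mkreads(full), g, p), p)
  expect_true(all(aln$primer_trimmed))
  expect_equal(aln$keep_hi[1] - aln$keep_lo[1] + 1L,
               region_length(a$insert, g$length))
  aln2 <- trim_primers(align_reads(mkreads(insert_only), g, p), p)
  expect_false(any(aln2$primer_trimmed))
})

test_that("NUMT exclusion flags decoy-derived reads but not mtDNA reads", {
  g <- rcrs(); p <- cr_panel()
  seg <- subsequence(g, region(16100, 16250))
  ch <- strsplit(seg, "")[[1]]
  for (at in c(30, 75, 120)) {
    ch[at] <- setdiff(c("A", "C", "G", "T"), ch[at])[1]
  }
  decoy <- paste(ch, collapse = "")
  db <- numt_db(list(d1 = decoy))
  mkreads <- function(s) data.frame(
    id = "r", r1_seq = s, r1_qual = strrep("I", nchar(s)),
    r2_seq = reverse_complement(s), r2_qual = strrep("I", nchar(s)),
    i7 = NA, i5 = NA, truth_sample = "t", truth_contributor = "t",
    truth_amplicon = NA, truth_numt = FALSE, truth_origin = "sample",
    stringsAsFactors = FALSE)
  # read drawn from the decoy (3 diagnostic differences from the genome)
  aln <- numt_filter(align_reads(mkreads(decoy), g, p), db)
  expect_true(all(aln$numt_filtered))
  # read identical to the reference segment is kept
  aln2 <- numt_filter(align_reads(mkreads(seg), g, p), db)
  expect_false(any(aln2$numt_filtered))
  # empty database disables the filter
  aln3 <- numt_filter(align_reads(mkreads(decoy), g, p), numt_db(list()))
  expect_false(any(aln3$numt_filtered))
})

test_that("HVII soft clip drops reverse-strand C-stretch misreads after 303", {
  g <- rcrs()
  # amplicon spanning 262..353 like the HVII C-stretch amplicon
  amp <- amplicon("hvii", region(262, 353), 20L, 20L, 1L,
                  genome_length = g$length)
  p <- panel(list(amp), region(262, 353), g$name, g$length,
             validate = FALSE)
  mol <- subsequence(g, amp$outer)
  # stutter: one extra C in the 303..309 run
  stut <- sub("CCCCCCC", "CCCCCCCC", mol, fixed = TRUE)
  reads <- data.frame(
    id = "r", r1_seq = stut, r1_qual = strrep("I", nchar(stut)),
    r2_seq = reverse_complement(stut),
    r2_qual = strrep("I", nchar(stut)),
    i7 = NA, i5 = NA, truth_sample = "t", truth_contributor = "t",
    truth_amplicon = "hvii", truth_numt = FALSE, truth_origin = "sample",
    stringsAsFactors = FALSE)
  aln <- align_reads(reads, g, p)
  aln <- trim_primers(aln, p)
  clipped <- hvii_softclip(aln, g, min_events = 1L)
  rev_row <- which(clipped$strand == "-")
  fwd_row <- which(clipped$strand == "+")
  expect_true(clipped$hvii_softclipped[rev_row])
  expect_false(clipped$hvii_softclipped[fwd_row])  # forward never clipped
  # reverse read contributes only up to 303
  expect_lte(clipped$keep_hi[rev_row] - clipped$start_unwrapped[rev_row] +
               clipped$ref_start[rev_row], 303L)
  # clean reverse read across the region is untouched
  clean <- align_reads(within(reads, {
    r1_seq <- mol; r1_qual <- strrep("I", nchar(mol))
    r2_seq <- reverse_complement(mol); r2_qual <- strrep("I", nchar(mol))
  }), g, p)
  clean <- hvii_softclip(trim_primers(clean, p), g, min_events = 1L)
  expect_false(any(clean$hvii_softclipped))
})

test_that("no masked or clipped base reaches the pileup", {
  g <- rcrs(); p <- cr_panel()
  a <- p$amplicons[[1]]
  seq <- subsequence(g, a$outer)
  qual <- strrep("I", nchar(seq))
  # mask one insert base (Q10) at insert offset 5
  off <- a$fwd_primer_len + 5L
  substr(qual, off, off) <- rawToChar(as.raw(10 + 33))
  reads <- data.frame(id = "r", r1_seq = seq, r1_qual = qual,
                      r2_seq = reverse_complement(seq),
                      r2_qual = strrep("I", nchar(seq)),
                      i7 = NA, i5 = NA, truth_sample = "t",
                      truth_contributor = "t", truth_amplicon = a$id,
                      truth_numt = FALSE, truth_origin = "sample",
                      stringsAsFactors = FALSE)
  aln <- trim_primers(align_reads(reads, g, p), p)
  pup <- build_pileup(aln, g)
  ins_pos <- region_positions(a$insert, g$length)
  masked_pos <- ins_pos[5]
  depths <- rowSums(pup$counts)
  expect_equal(depths[masked_pos], 1)      # only the mate counts
  expect_equal(depths[ins_pos[6]], 2)      # both mates elsewhere
  # primer positions carry no counts at all
  primer_pos <- setdiff(region_positions(a$outer, g$length), ins_pos)
  expect_true(all(depths[primer_pos] == 0))
})
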