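#!/usr/bin/env Rscript
# Regenerates inst/extdata/rCRS_synthetic.fasta.
#
# The fixture is a SYNTHETIC 16,569 bp circular genome that stands in for
# the revised Cambridge Reference Sequence. The control-region motifs that
# the pipeline's logic depends on (HVII C-stretch 303..315 with the 310 T,
# HVI C-stretch 16184..16193 with the 16189 T, the AC repeat 515..524) and
# the reference bases at commonly reported variant positions are set to
# their true rCRS values; everything else is seeded random sequence. The
# placeholder N of the true rCRS (position 3107) is not reproduced.

set.seed(16569)
L <- 16569L
bases <- sample(c("A", "C", "G", "T"), L, replace = TRUE,
                prob = c(0.31, 0.31, 0.13, 0.25))  # mtDNA-like composition

put <- function(pos, value) {
  stopifnot(length(pos) == nchar(value))
  bases[pos] <<- strsplit(value, "")[[1]]
}

# homopolymer / repeat motifs
put(303:315, "CCCCCCCTCCCCC")    # HVII C-stretch, 310 is T
put(16184:16193, "CCCCCTCCCC")   # HVI C-stretch, 16189 is T
put(515:524, "ACACACACAC")       # AC dinucleotide repeat

# reference bases at commonly reported control-region variant sites
single <- c(
  "16" = "A", "41" = "C", "44" = "C", "64" = "C", "73" = "A", "93" = "A",
  "146" = "T", "150" = "C", "152" = "T", "153" = "A", "189" = "A",
  "194" = "C", "195" = "T", "198" = "C", "204" = "T", "207" = "G",
  "214" = "A", "228" = "G", "247" = "G", "249" = "A", "257" = "A",
  "263" = "A", "279" = "T", "290" = "A", "291" = "A", "295" = "C",
  "297" = "A", "316" = "G", "372" = "T", "378" = "A", "462" = "C",
  "477" = "T", "489" = "T", "493" = "A", "497" = "C", "499" = "G",
  "507" = "A", "514" = "C", "16051" = "A", "16069" = "C", "16092" = "T",
  "16093" = "T", "16111" = "C", "16124" = "T", "16126" = "T",
  "16129" = "G", "16142" = "C", "16172" = "T", "16183" = "A",
  "16192" = "C", "16217" = "T", "16223" = "C", "16256" = "C",
  "16260" = "C", "16264" = "C", "16270" = "C", "16278" = "C",
  "16291" = "C", "16292" = "C", "16294" = "C", "16296" = "C",
  "16304" = "T", "16309" = "A", "16311" = "T", "16316" = "A",
  "16320" = "C", "16325" = "T", "16356" = "T", "16357" = "T",
  "16362" = "T", "16390" = "G", "16398" = "G", "16399" = "A",
  "16519" = "T"
)
for (p in names(single)) put(as.integer(p), single[[p]])

seq <- paste(bases, collapse = "")
out <- file.path("inst", "extdata", "rCRS_synthetic.fasta")
lines <- c(">rCRS_synthetic synthetic rCRS-like circular reference, 16569 bp",
           substring(seq, seq(1, L, 70), pmin(seq(1, L, 70) + 69, L)))
writeLines(lines, out)
cat("wrote", out, "length", nchar(seq), "\n")
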