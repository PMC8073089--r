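# mitotiler

Forensic mitochondrial DNA (mtDNA) haplotyping with tiled-amplicon
sequencing, as an open, testable R package. It targets the workflow used
in forensic mtDNA validation studies: two staggered PCR primer sets tile
small overlapping amplicons (60–150 bp) across the circular 16,569 bp
mtDNA molecule (or just its ~1122 bp control region spanning the origin
at 16024..576); dual-indexed paired-end reads are demultiplexed, aligned
to the reference, filtered, and variants are called against the rCRS
coordinate system in SWGDAM-style nomenclature (`73G`, `315.1C`,
`249del`, IUPAC codes for point heteroplasmy, lower case for length
heteroplasmy).

The package covers the whole loop:

* **reference** — circular genome model, 1-based coordinates, regions
  that wrap the origin, named control-region annotations (HVI/HVII,
  C-stretches, AC repeat).
* **panel** — design and validate tiled two-set amplicon panels
  (complete coverage, ≥3 bp insert overlaps, alternating sets).
* **simulate** — synthetic sequencing runs: haplotypes, per-molecule
  heteroplasmy, two-person mixtures, no-template controls, NUMT
  contamination, index crosstalk, run-to-run carryover, with truth
  sidecars.
* **demux** — dual-index demultiplexing with mismatch tolerance, run QC
  gates, bait-index carryover checks.
* **align** — seeded banded alignment against the doubled (circular)
  reference plus the forensic read filters: per-base Q30 masking, <40 bp
  byproduct removal, primer trimming, NUMT exclusion, HVII C-stretch
  reverse-strand soft clipping.
* **call** — stranded pileups and threshold-based calling under the
  analytical threshold (AT), interpretation threshold (IT) and minimum
  read count, with the control-region (AT/IT 10%, 64 reads) and
  whole-genome (6%, 45 reads) presets.
* **nomenclature** — parse/format SWGDAM variant strings, compare
  haplotypes, EMPOP-compatible reports (FASTA block + variant list).
* **interpret** — derive thresholds from control runs
  (`mean + k·SD`), mixture expectations and detection rates, NTC depth
  estimates, crosstalk candidates, precision metrics.

The calling model is deliberately threshold-based, not likelihood-based:
a base is detected when its fraction of the position's total depth meets
the AT, and a position is called at all only when its depth meets the
minimum read count, which is itself derived from no-template-control
background as `round(mean + k·SD)`.

> **Note on the bundled reference.** The packaged FASTA
> (`inst/extdata/rCRS_synthetic.fasta`) is a *synthetic* rCRS-like
> genome: 16,569 bp with the true control-region motifs (C-stretches,
> 310T/16189T, AC repeat) and reference bases at commonly reported
> variant sites, but random elsewhere. It exists so the pipeline is
> fully testable without redistributing the reference genome; do not use
> it to interpret real data.

## Worked example

Simulate a control-region library for the HL-60-like positive control
haplotype, run the analysis, and compare the called haplotype with the
truth:

```r
library(mitotiler)

genome <- load_rcrs_synthetic()
panel  <- design_tiled_panel(genome, region(16024, 576),
                             min_len = 60, max_len = 150,
                             min_overlap = 3, seed = 1)

hl60 <- haplotype_spec_from_string(
  "HL60",
  "73G 150T 152C 263G 295T 315.1C 489C 16069T 16193T 16278T 16362C",
  genome)
spec  <- library_spec("hl60", list(list(hap = hl60, weight = 1)),
                      total_read_pairs = 6000, seed = 7)
reads <- simulate_library(genome, panel, spec)

aln <- apply_read_filters(align_reads(reads, genome, panel), genome, panel)
pup <- build_pileup(aln, genome)
res <- call_sample(pup, preset_thresholds("control-region"),
                   region(16024, 576), genome, "hl60")
res
#> <sample_result> hl60: 100.0% coverage, 11 variants, 0 no-call region(s)
#>   73G 150T 152C 263G 295T 315.1C 489C 16069T 16193T 16278T 16362C
```

The printed line is the full SWGDAM-style control-region haplotype: all
eleven simulated variants (ten substitutions and the `315.1C` insertion)
are recovered, every one of the 1122 control-region positions is covered
above the 64-read minimum, and no no-call regions remain. Threshold
derivation from control-run background reproduces the published
arithmetic:

```r
derive_min_read_count(c(4, 34, 64), k = 1)  # mean 34, SD 30 -> 64
#> [1] 64
expected_mixture_ratio(1, 5)
#> $minor [1] 17   $major [1] 83
```

A thin command-line wrapper (`inst/cli/mitotiler.R`) exposes
`simulate`, `analyze`, `derive-thresholds` and `compare` subcommands
over the same functions.

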