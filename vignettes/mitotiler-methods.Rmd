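---
title: "Methods: tiled-amplicon mtDNA simulation and haplotyping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tiled-amplicon mtDNA simulation and haplotyping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitotiler)
```

# The problem

Forensic mitochondrial DNA typing reports a *haplotype*: the list of
differences between a sample's mtDNA sequence and the revised Cambridge
Reference Sequence (rCRS), written in SWGDAM-style nomenclature
(`73G`, `315.1C`, `249del`, IUPAC codes such as `16093Y` for point
heteroplasmy and lower case such as `309.1c` for length heteroplasmy).
Modern kits enrich the circular 16,569 bp molecule — or just the
~1122 bp control region that wraps the origin at 16024..576 — with two
staggered sets of small tiled amplicons (60–150 bp), sequence the pooled
dual-indexed libraries paired-end, and call variants under explicit
analytical thresholds. mitotiler implements that secondary/tertiary
analysis together with a simulator rich enough to exercise every rule in
it, so each step can be validated against known truth.

# Coordinate model

Coordinates are 1-based and inclusive throughout, matching forensic
position nomenclature. A region with `end < start` wraps across the
origin; the control region itself (16024..576) is the canonical example,
and its length is `(L - start + 1) + end = 1122` on the 16,569 bp
circle. Alignment and pileup internally use an "unwrapped" frame over
the doubled genome sequence so that reads and amplicons spanning the
origin stay contiguous; positions are folded back modulo the genome
length at reporting time.

The bundled reference is a **synthetic** rCRS-like genome: the
control-region motifs the pipeline's logic depends on (the HVII
C-stretch 303..315 with its 310 T, the HVI C-stretch 16184..16193 with
its 16189 T, the AC repeat at 515..524) and the reference bases at
commonly reported variant sites are set to their true rCRS values, and
the remaining sequence is seeded random with mtDNA-like base
composition. The placeholder N of the true reference is not reproduced.
Because simulation and calling use the same genome, every result in
the test suite is internally consistent; results on this fixture say
nothing about any real sample.

# Panel design

`design_tiled_panel()` walks the target drawing outer amplicon lengths
uniformly from `[min_len, max_len]` (default 60–150 bp, primers
modelled as 20 bp coordinate footprints — primer *sequences* are
proprietary in commercial kits and are not needed by any downstream
rule) and adjacent insert overlaps uniformly from
`[min_overlap, min_overlap + 28]`, giving a mean overlap near 17 bp at
the default minimum of 3 bp. Primer sets strictly alternate along the
target so the two PCRs never share a junction; for full-circle targets
an even amplicon count is enforced so alternation survives the wrap,
and the final insert is extended past the origin so the junction
overlap also meets the minimum. Panel invariants — complete coverage,
all adjacent overlaps ≥ 3 bp, alternating sets — are checked on
construction and property-tested over 100 seeds.

Removing any single amplicon from a valid panel leaves at most one
uncovered region (the removed insert minus its neighbours' overlaps),
which is exactly the dropout signature a primer-binding-site mutation
produces; `dropout_rate()` turns such counts into the percentage of
targeted amplicons lost across a study.

# The simulator: what it emulates, and what it does not

`simulate_library()` draws each read pair from one amplicon of one
contributor molecule: amplicon ∝ efficiency weight, contributor ∝
mixture weight, and every sub-unit-fraction variant realized
per molecule as Bernoulli(fraction) — so point heteroplasmy and
two-person mixtures produce binomially distributed allele fractions,
which is what the AT-based caller assumes. R1 reads the forward strand
from the amplicon's outer start, R2 the reverse complement from its
outer end, both including primer bases and truncated at the read length
(151 or 201 cycles).

Noise model and defaults, chosen once:

* substitution errors at `base_error_rate = 0.001` per base, the right
  order for sequencing-by-synthesis after Q30 filtering;
* per-base qualities from a clipped normal (mean Q36, SD 3, floor Q2),
  so roughly 2% of bases fall below the Q30 mask;
* indel errors only as homopolymer stutter: a molecule with qualifying
  runs (≥5 bp) slips ±1 base with probability `1 - (1-p)^n_runs`
  (`p = 0.01` per run, at most one slip per molecule). This exercises
  the C-stretch logic without a full polymerase model;
* per-amplicon efficiencies default to 1 and are freely settable
  (log-normal perturbation, or zero to model a dropout).

`simulate_run()` adds the run-level structure: dual index pairs per
library, index crosstalk (a read's observed pair is replaced by another
sheet entry sharing its i5 or i7), carryover (a fraction of a previous
run's reads injected under their original indexes) and bait index pairs
that sit on the sample sheet with no physical library. Truth is carried
in dedicated columns and a sidecar JSON, never in read names.

Not emulated: flow-cell physics (cluster density, phasing enter only as
user-supplied QC metrics), PCR chimeras/doublewides, template
degradation profiles, and real NUMT biology (decoys are arbitrary
sequences). Passing tests therefore demonstrate the *analysis rules*
are implemented correctly — not that the pipeline is robust to every
artefact of real instruments.

# Alignment and read-level filters

The aligner seeds read k-mers (k = 15) against an index of the doubled
genome and extends candidates with a banded affine-gap *fitting*
alignment (read global, reference window free at both ends; match +1,
mismatch −4, gap open −6, gap extend −1, band 16). Reads that align
better reverse-complemented are recorded on the reverse strand. A full
unbanded dynamic program written independently in the test suite serves
as the score oracle; agreement is asserted over hundreds of random
instances with up to 3 substitutions and one short indel, which all fit
inside the band by construction. Alignments scoring below half the
perfect-match score are flagged unaligned and excluded downstream — a
read is never an error.

Filters, in order:

1. **Byproduct removal** — pairs whose inferred fragment is under 40 bp
   are discarded (40 itself is kept); the smallest genuine amplicon is
   60 bp, so no real product is touchable.
2. **Primer trimming** — bases over the assigned amplicon's primer
   footprints are excluded from the usable span, so only the targeted
   insert is ever counted; overlaps between adjacent inserts (≥3 bp)
   guarantee no position is lost to trimming.
3. **Quality masking** — bases with Phred < 30 are masked, not
   trimmed: they stay in the alignment (preserving anchoring) but never
   reach a pileup count. The boundary is strict: Q30 passes, Q29 does
   not.
4. **NUMT exclusion** — a read is flagged nuclear-mitochondrial when it
   matches a decoy within 2 edits *and* more closely than it matches
   the reference at its aligned locus; a k-mer prefilter skips reads
   sharing nothing with any decoy. A decoy identical to a reference
   segment triggers a warning at load time, since exclusion matching
   cannot see it.
5. **HVII soft clip** — reverse-strand reads whose usable span begins
   at the amplicon boundary near position 262 and whose alignment shows
   non-match events inside the C-stretch (303..315) are clipped at 303,
   so positions 304..353 retain roughly half the stranded coverage of
   262..303. The trigger is configurable; it defaults to ≥2 events. The
   simulator's stutter produces a single clean indel event per slipped
   molecule, so tests that exercise the clip set the trigger to 1 —
   real reverse-strand C-stretch reads degrade with scattered errors
   rather than one tidy gap, which is why 2 is the shipping default.

# Calling

`build_pileup()` accumulates stranded A/C/G/T/deletion counts per
position, excluding every masked, clipped or filtered base (an
invariant the tests assert directly). Insertions are collected as
events, re-anchored to the 3'-most position of a homopolymer (the
standard forensic alignment convention, so a C inserted anywhere in
303..309 reports at 309), and named with ordinals.

A position is called only when its total depth meets the minimum read
count; bases at or above the AT (as a percent of total depth) are
retained; one retained base calls as itself, two or more as the IUPAC
code over the retained set (point heteroplasmy); a retained deletion
calls as `del`. Calls in `[AT, IT)` are kept but flagged `below_IT` —
with the shipped presets AT and IT are equal, so the flag is the only
behavioural difference between the two thresholds. Insertion ordinals
at or above the AT report lower case when carried by less than
`100 − AT` percent of reads (length heteroplasmy) and upper case
otherwise. Coverage is the percentage of target positions with a call,
half-up to one decimal, and is 100 exactly when the no-call region list
is empty.

Two documented C-stretch renderings are controlled by `uas_compat`:
the all-reads-deleted 16189 T with partial C insertion renders as
`16189c` raw, or as `16189C 16193c` corrected; and a mixed 310 call
re-anchors to the next `309.Nc` insertion ordinal under the corrected
mode.

# Thresholds and interpretation

`derive_min_read_count()` is `round(mean + k·SD)` (half-up) over
no-template-control background depths, with the *sample* (n−1) standard
deviation — at the scale of real control runs the choice is immaterial
at printed precision, but it is fixed and documented. The control-region
preset (64 reads) corresponds to background with mean 34 and SD 30 at
k = 1; the whole-genome preset is 45 reads at AT/IT 6%. `derive_at()`
summarizes unexpected-variant percentages from positive controls (mean,
SD, 95th percentile, maximum, with hotspot exclusions carried in the
report) and derives a custom AT as `mean + 3·SD`, either to one decimal
(0.7% + 3×1.0% → 3.7%) or rounded up to a whole percent
(0.7% + 3×0.5% → 3%).

Mixture arithmetic follows the validation-study conventions: expected
minor percentage `round(100·m/(m+M))` with its complement; detection
rate to one decimal; a sample flags as a possible mixture when more
than half of its non-reference calls are mixed-base (IUPAC) calls.
NTC contamination depth is estimated control-region style as
`2 × paired reads / n_amplicons`, and `crosstalk_candidates()` links
NTC calls to co-indexed samples whose haplotypes contain them.
`precision_metric()` reports covered bases as a percentage with the
two-tier printed precision used in validation tables (one decimal below
99.9, two at or above).

Haplotype concordance uses the union of the two variant sets (restricted
to the mutually covered region) as the denominator — the conservative
choice where the field's "percentage of the same variants" leaves the
denominator unstated. Haplotypes with disjoint covered ranges are
reported not-comparable rather than 0%.

# Numerical choices and degenerate inputs

All reported percentages round half away from zero (`round_half_up()`),
matching how validation tables print; base R's round-half-to-even would
differ on exact boundaries. Strand depth displays the majority strand
and resolves ties to forward. A single-amplicon panel reports zero
overlaps rather than NA; an empty haplotype formats as the empty
string; an NTC analyzes to 0% coverage with an empty haplotype rather
than erroring; unalignable reads and reads with no assignable amplicon
are flagged and excluded, never fatal.

# Problem sizes

The test suite and acceptance script simulate at 6,000 read pairs per
control-region sample, about 750× insert depth — comfortably past ten
times the 64-read minimum, so single-source recovery is expected to be
exact. End-to-end recovery runs 20 random haplotypes in the suite and 6
in the acceptance script; the aligner oracle covers 200 random
instances (≤300 bp) in the suite and 60 in the script. Random
haplotypes for recovery avoid the C-stretches and the AC repeat, where
length-heteroplasmy rendering rather than substitution calling governs
the output; C-stretch behaviour is tested separately and directly.

# Known limitations

* The synthetic reference shares only motifs and selected sites with
  the true rCRS; EMPOP-style output on it is format-compatible but not
  database-queryable.
* Calling is purely threshold-based; there is no genotype-likelihood or
  probabilistic mixture deconvolution, mirroring the validated
  workflow's design.
* The simulator's stutter is a single ±1 slip per molecule; real
  C-stretch artefacts are messier, and the HVII clip trigger default
  (2 events) is tuned to that reality rather than to the simulator.
* Amplicon assignment is by best overlap with outer spans; unintended
  "doublewide" products spanning two same-set amplicons are not
  simulated or specially handled.
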