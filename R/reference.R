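# Circular mtDNA reference genome: coordinate system and named regions.
#
# Coordinates are 1-based inclusive throughout, matching forensic mtDNA
# position nomenclature ("73G" is the 73rd base). A region whose end is
# smaller than its start wraps across the origin, as the human control
# region does (16024..576).

#' Construct a circular genome
#'
#' @param name sequence name.
#' @param sequence nucleotide string over `A`, `C`, `G`, `T`, `N`
#'   (lower case accepted, stored upper case).
#' @return An object of class `circular_genome` with fields `name`,
#'   `sequence` and `length`.
#' @export
circular_genome <- function(name, sequence) {
  sequence <- toupper(sequence)
  if (nchar(sequence) == 0L) abort("genome sequence is empty")
  if (grepl("[^ACGTN]", sequence)) {
    abort("genome sequence contains characters outside {A,C,G,T,N}")
  }
  structure(
    list(name = as.character(name), sequence = sequence,
         length = nchar(sequence)),
    class = "circular_genome"
  )
}

#' @export
print.circular_genome <- function(x, ...) {
  cat(sprintf("<circular_genome> %s: %d bp\n", x$name, x$length))
  invisible(x)
}

#' Load a single-record FASTA as a circular genome
#'
#' @param path path to a FASTA file containing exactly one record.
#' @return A [circular_genome()].
#' @export
load_fasta <- function(path) {
  if (!file.exists(path)) abort("FASTA file not found: %s", path)
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0L) abort("FASTA file has no records: %s", path)
  if (length(set) > 1L) {
    abort("expected a single-record FASTA, found %d records: %s",
          length(set), path)
  }
  nm <- sub("\\s.*$", "", names(set)[1])
  circular_genome(nm, as.character(set[[1]]))
}

#' Define a 1-based inclusive region on a circular genome
#'
#' `end < start` denotes a region that wraps across the origin.
#'
#' @param start,end 1-based inclusive coordinates.
#' @param label optional region label.
#' @return An object of class `region`.
#' @export
region <- function(start, end, label = "") {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 1L || end < 1L) {
    abort("region coordinates must be positive integers")
  }
  structure(list(start = start, end = end, label = as.character(label)),
            class = "region")
}

#' @export
print.region <- function(x, ...) {
  lab <- if (nzchar(x$label)) paste0(" [", x$label, "]") else ""
  cat(sprintf("<region> %d..%d%s\n", x$start, x$end, lab))
  invisible(x)
}

validate_region <- function(r, genome_length) {
  if (r$start > genome_length || r$end > genome_length) {
    abort("region %d..%d out of range for genome of length %d",
          r$start, r$end, genome_length)
  }
  invisible(r)
}

#' Length of a region on a circular genome
#'
#' Non-wrapping regions have length `end - start + 1`; wrapping regions
#' (`end < start`) have length `(genome_length - start + 1) + end`.
#'
#' @param r a [region()].
#' @param genome_length genome length in bp.
#' @return region length in bp.
#' @examples
#' region_length(region(16024, 576), 16569)  # the 1122 bp control region
#' @export
region_length <- function(r, genome_length) {
  validate_region(r, genome_length)
  if (r$end >= r$start) r$end - r$start + 1L
  else (genome_length - r$start + 1L) + r$end
}

#' Positions covered by a region, in order
#'
#' @inheritParams region_length
#' @return integer vector of 1-based positions, wrapping across the origin
#'   when `end < start`.
#' @export
region_positions <- function(r, genome_length) {
  validate_region(r, genome_length)
  if (r$end >= r$start) seq.int(r$start, r$end)
  else c(seq.int(r$start, genome_length), seq.int(1L, r$end))
}

#' Extract the sequence of a region from a circular genome
#'
#' Wrapping regions concatenate the suffix and prefix of the linear
#' sequence.
#'
#' @param genome a [circular_genome()].
#' @param r a [region()].
#' @return nucleotide string of length `region_length(r, genome$length)`.
#' @export
subsequence <- function(genome, r) {
  validate_region(r, genome$length)
  if (r$end >= r$start) {
    substr(genome$sequence, r$start, r$end)
  } else {
    paste0(substr(genome$sequence, r$start, genome$length),
           substr(genome$sequence, 1L, r$end))
  }
}

#' Named regions of the human mtDNA control region
#'
#' Defaults follow the standard human mtDNA annotation: the control region
#' wraps the origin at 16024..576, hypervariable regions HVI (16024..16365)
#' and HVII (57..372), the two C-stretch homopolymers (16184..16193 in HVI,
#' 303..315 in HVII) and the AC dinucleotide repeat at 515..524.
#'
#' @param control_region,hv1,hv2,hv1_cstretch,hv2_cstretch,ac_repeat
#'   [region()] overrides.
#' @return A named list of regions with class `named_regions`.
#' @export
named_regions <- function(control_region = region(16024, 576, "CR"),
                          hv1 = region(16024, 16365, "HVI"),
                          hv2 = region(57, 372, "HVII"),
                          hv1_cstretch = region(16184, 16193, "HVI C-stretch"),
                          hv2_cstretch = region(303, 315, "HVII C-stretch"),
                          ac_repeat = region(515, 524, "AC repeat")) {
  structure(
    list(control_region = control_region, hv1 = hv1, hv2 = hv2,
         hv1_cstretch = hv1_cstretch, hv2_cstretch = hv2_cstretch,
         ac_repeat = ac_repeat),
    class = "named_regions"
  )
}

#' Path of the bundled synthetic rCRS-like reference
#'
#' The packaged reference is a deterministic, synthetic 16,569 bp circular
#' genome that mimics the revised Cambridge Reference Sequence: the
#' homopolymer and repeat motifs of the control region (HVII C-stretch with
#' 310T, HVI C-stretch with 16189T, the AC repeat at 515..524) and the
#' reference bases at commonly cited variant positions are placed at their
#' true rCRS values, while the remainder of the molecule is seeded random
#' sequence. It is *not* the true rCRS and must not be used to interpret
#' real data; it exists so that the whole pipeline can be exercised and
#' tested without redistribution of the reference genome.
#'
#' @return file path of the FASTA fixture.
#' @export
rcrs_synthetic_path <- function() {
  system.file("extdata", "rCRS_synthetic.fasta", package = "mitotiler",
              mustWork = TRUE)
}

#' Load the bundled synthetic rCRS-like reference
#'
#' @return A [circular_genome()] of length 16,569.
#' @seealso [rcrs_synthetic_path()]
#' @export
load_rcrs_synthetic <- function() {
  load_fasta(rcrs_synthetic_path())
}

reverse_complement <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# vectorized over many strings
reverse_complement_many <- function(seqs) {
  if (length(seqs) == 0L) return(character())
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs)))
}

reverse_strings <- function(x) {
  vapply(x, function(s) rawToChar(rev(charToRaw(s))), character(1),
         USE.NAMES = FALSE)
}
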