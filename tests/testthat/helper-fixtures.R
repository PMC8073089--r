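# Shared fixtures and independent oracles for the test suite.

# small deterministic circular genome with a planted C-stretch
toy_genome <- function(len = 400L, seed = 42L) {
  set.seed(seed)
  b <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  circular_genome("toy", paste(b, collapse = ""))
}

rcrs <- local({
  g <- NULL
  function() {
    if (is.null(g)) g <<- load_rcrs_synthetic()
    g
  }
})

cr_region <- function() region(16024, 576, "CR")

cr_panel <- local({
  p <- NULL
  function() {
    if (is.null(p)) {
      p <<- design_tiled_panel(rcrs(), cr_region(), 60L, 150L, 3L, seed = 1L)
    }
    p
  }
})

hl60_cr_string <- paste("73G 150T 152C 263G 295T 315.1C 489C",
                        "16069T 16193T 16278T 16362C")

single_source_library <- function(name, hap_string, n_pairs, seed,
                                  error = 0.001, stutter = 0.01) {
  hap <- haplotype_spec_from_string(name, hap_string, rcrs())
  library_spec(name, list(list(hap = hap, weight = 1)),
               total_read_pairs = n_pairs, base_error_rate = error,
               stutter_prob = stutter, seed = seed)
}

phred_to_qual_chr <- function(q) rawToChar(as.raw(as.integer(q) + 33L))

# Independent full-matrix fitting-alignment score oracle (affine gaps,
# read global, reference window free at both ends). Scores only; written
# without banding or seeding so it shares nothing with the production
# aligner beyond the scoring constants.
oracle_fit_score <- function(read, win, match = 1, mismatch = -4,
                             gap_open = -6, gap_extend = -1) {
  m <- nchar(read); w <- nchar(win)
  rd <- strsplit(read, "")[[1]]; wn <- strsplit(win, "")[[1]]
  NEG <- -1e9
  H <- matrix(NEG, m + 1, w + 1)  # best ending in aligned pair
  E <- matrix(NEG, m + 1, w + 1)  # gap consuming reference
  F_ <- matrix(NEG, m + 1, w + 1) # gap consuming read
  B <- matrix(NEG, m + 1, w + 1)
  B[1, ] <- 0
  for (i in 2:(m + 1)) {
    F_[i, 1] <- gap_open + (i - 2) * gap_extend
    B[i, 1] <- F_[i, 1]
  }
  for (i in 2:(m + 1)) {
    for (j in 2:(w + 1)) {
      s <- if (rd[i - 1] == wn[j - 1]) match else mismatch
      H[i, j] <- B[i - 1, j - 1] + s
      E[i, j] <- max(B[i, j - 1] + gap_open, E[i, j - 1] + gap_extend)
      F_[i, j] <- max(B[i - 1, j] + gap_open, F_[i - 1, j] + gap_extend)
      B[i, j] <- max(H[i, j], E[i, j], F_[i, j])
    }
  }
  max(B[m + 1, ])
}

# random single-source haplotype over the control region: substitutions
# at distinct positions away from homopolymer hotspots
random_cr_haplotype <- function(name, n_sub = 6L) {
  g <- rcrs()
  hotspots <- c(region_positions(region(300, 318), g$length),
                region_positions(region(16180, 16196), g$length),
                region_positions(region(512, 527), g$length))
  pool <- setdiff(region_positions(cr_region(), g$length), hotspots)
  pos <- sort(sample(pool, n_sub))
  toks <- vapply(pos, function(p) {
    refb <- substr(g$sequence, p, p)
    alt <- sample(setdiff(c("A", "C", "G", "T"), refb), 1L)
    paste0(p, alt)
  }, character(1))
  haplotype_spec_from_string(name, paste(toks, collapse = " "), g)
}
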