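# fabricate a pileup with chosen counts at chosen positions
fake_pileup <- function(L = 1000L, at = list(), ins = NULL) {
  counts <- matrix(0L, nrow = L, ncol = 10)
  # columns: A+,C+,G+,T+,del+,A-,C-,G-,T-,del-
  colmap <- c(A = 1, C = 2, G = 3, T = 4, del = 5)
  for (spec in at) {
    p <- spec$pos
    for (b in names(spec$fwd)) counts[p, colmap[b]] <- spec$fwd[[b]]
    for (b in names(spec$rev)) counts[p, colmap[b] + 5] <- spec$rev[[b]]
  }
  if (is.null(ins)) {
    ins <- data.frame(pos = integer(), ordinal = integer(),
                      base = character(), fwd = integer(), rev = integer(),
                      stringsAsFactors = FALSE)
  }
  structure(list(counts = counts, insertions = ins, genome_length = L),
            class = "pileup")
}

test_that("position calling follows AT / min-read-count logic", {
  th <- thresholds(10, 10, 45L)
  pup <- fake_pileup(at = list(
    list(pos = 100L, fwd = list(G = 50, A = 3), rev = list(G = 45, A = 2)),
    list(pos = 200L, fwd = list(C = 35, T = 15), rev = list(C = 35, T = 15)),
    list(pos = 300L, fwd = list(G = 20), rev = list(G = 20))
  ))
  c100 <- call_position(pup, 100L, th)
  expect_equal(c100$called, "G")   # 95:5, minor below 10% AT
  expect_equal(c100$status, "called")
  c200 <- call_position(pup, 200L, th)
  expect_equal(c200$called, "Y")   # 70 C / 30 T point heteroplasmy
  c300 <- call_position(pup, 300L, th)
  expect_equal(c300$status, "no_call")  # depth 40 < 45
  expect_equal(call_position(pup, 500L, th)$status, "no_call")
})

test_that("retained deletions call as del", {
  th <- thresholds(10, 10, 45L)
  pup <- fake_pileup(at = list(
    list(pos = 50L, fwd = list(del = 60, C = 2), rev = list(del = 58, C = 1))
  ))
  expect_equal(call_position(pup, 50L, th)$called, "del")
})

test_that("strand depth displays the majority strand, forward on ties", {
  pup <- fake_pileup(at = list(
    list(pos = 10L, fwd = list(A = 120), rev = list(A = 80)),
    list(pos = 20L, fwd = list(A = 50), rev = list(A = 50))
  ))
  expect_equal(strand_depth(pup, 10L), 120)
  expect_equal(strand_depth(pup, 20L), 50)
  expect_equal(strand_depth(pup, 30L), 0)
})

test_that("insertion ordinals render case by fraction carried", {
  th <- thresholds(10, 10, 45L)
  # 60% of 100 reads carry one inserted C at 309 -> lowercase
  pup <- fake_pileup(
    at = list(list(pos = 309L, fwd = list(C = 50), rev = list(C = 50))),
    ins = data.frame(pos = 309L, ordinal = 1L, base = "C", fwd = 30L,
                     rev = 30L, stringsAsFactors = FALSE))
  lh <- length_heteroplasmy_calls(pup, region(303, 315), th)
  expect_equal(nrow(lh), 1L)
  expect_true(lh$lowercase)
  # carried by 100% -> uppercase
  pup2 <- fake_pileup(
    at = list(list(pos = 309L, fwd = list(C = 50), rev = list(C = 50))),
    ins = data.frame(pos = 309L, ordinal = 1L, base = "C", fwd = 50L,
                     rev = 50L, stringsAsFactors = FALSE))
  lh2 <- length_heteroplasmy_calls(pup2, region(303, 315), th)
  expect_false(lh2$lowercase)
  # below AT -> dropped
  pup3 <- fake_pileup(
    at = list(list(pos = 309L, fwd = list(C = 50), rev = list(C = 50))),
    ins = data.frame(pos = 309L, ordinal = 1L, base = "C", fwd = 4L,
                     rev = 4L, stringsAsFactors = FALSE))
  expect_equal(nrow(length_heteroplasmy_calls(pup3, region(303, 315), th)),
               0L)
})

test_that("a simulated single-source sample reproduces its haplotype string", {
  g <- rcrs(); p <- cr_panel()
  spec <- single_source_library("hl60", hl60_cr_string, 6000L, seed = 42L)
  reads <- simulate_library(g, p, spec)
  aln <- apply_read_filters(align_reads(reads, g, p), g, p)
  pup <- build_pileup(aln, g)
  res <- call_sample(pup, preset_thresholds("control-region"), cr_region(),
                     g, "hl60")
  expect_equal(format_haplotype(res$haplotype), hl60_cr_string)
  expect_equal(res$coverage_percent, 100)
  expect_length(res$no_call_regions, 0L)
})

test_that("an NTC yields zero coverage and an empty haplotype", {
  g <- rcrs()
  pup <- fake_pileup(L = g$length)
  res <- call_sample(pup, preset_thresholds("control-region"), cr_region(),
                     g, "ntc")
  expect_equal(res$coverage_percent, 0)
  expect_equal(format_haplotype(res$haplotype), "")
  expect_length(res$no_call_regions, 1L)
})

test_that("amplicon dropout produces exactly its uncovered insert as no-call", {
  g <- rcrs(); p <- cr_panel()
  spec <- single_source_library("s", "", 6000L, seed = 13L)
  # kill one amplicon's efficiency
  victim <- p$amplicons[[5]]$id
  eff <- stats::setNames(rep(1, length(p$amplicons)),
                         vapply(p$amplicons, `[[`, character(1), "id"))
  eff[victim] <- 0
  spec$per_amplicon_efficiency <- eff
  reads <- simulate_library(g, p, spec)
  aln <- apply_read_filters(align_reads(reads, g, p), g, p)
  pup <- build_pileup(aln, g)
  res <- call_sample(pup, preset_thresholds("control-region"), cr_region(),
                     g, "dropout")
  expect_length(res$no_call_regions, 1L)
  # the gap is the victim insert minus neighbour overlaps
  gap <- region_positions(res$no_call_regions[[1]], g$length)
  victim_ins <- region_positions(p$amplicons[[5]]$insert, g$length)
  expect_true(all(gap %in% victim_ins))
  expect_lt(res$coverage_percent, 100)
})

test_that("coverage is 100 exactly when there are no no-call regions", {
  g <- rcrs(); p <- cr_panel()
  spec <- single_source_library("s", "73G", 4000L, seed = 21L)
  reads <- simulate_library(g, p, spec)
  aln <- apply_read_filters(align_reads(reads, g, p), g, p)
  pup <- build_pileup(aln, g)
  res <- call_sample(pup, preset_thresholds("control-region"), cr_region(),
                     g)
  expect_identical(res$coverage_percent == 100,
                   length(res$no_call_regions) == 0L)
})

test_that("raising the AT never adds calls; raising min reads never adds coverage", {
  g <- rcrs(); p <- cr_panel()
  minor <- haplotype_spec_from_string("m", "73G 195C", g)
  major <- haplotype_spec_from_string("M", "263G", g)
  spec <- mixture_library("mx", minor, major, 1, 3, 4000L, seed = 31L)
  reads <- simulate_library(g, p, spec)
  aln <- apply_read_filters(align_reads(reads, g, p), g, p)
  pup <- build_pileup(aln, g)
  prev_calls <- Inf
  for (at in c(5, 10, 20, 40)) {
    res <- call_sample(pup, thresholds(at, at, 64L), cr_region(), g)
    n <- nrow(res$haplotype$tokens)
    expect_lte(n, prev_calls)
    prev_calls <- n
  }
  prev_cov <- -1
  for (mrc in c(2000, 500, 64)) {
    res <- call_sample(pup, thresholds(10, 10, mrc), cr_region(), g)
    expect_gte(res$coverage_percent, prev_cov)
    prev_cov <- res$coverage_percent
  }
})

test_that("C-stretch rendering honors the compatibility mode", {
  tok_raw <- rbind(
    data.frame(position = 16189L, ordinal = 0L, kind = "deletion",
               symbol = "del", lowercase = FALSE, stringsAsFactors = FALSE),
    data.frame(position = 16193L, ordinal = 1L, kind = "insertion",
               symbol = "C", lowercase = TRUE, stringsAsFactors = FALSE))
  off <- mitotiler:::apply_cstretch_rendering(tok_raw, FALSE, named_regions())
  expect_equal(mitotiler:::format_variant_token(
    off$position[1], off$ordinal[1], off$symbol[1], off$lowercase[1]),
    "16189c")
  expect_equal(nrow(off), 1L)
  on <- mitotiler:::apply_cstretch_rendering(tok_raw, TRUE, named_regions())
  rendered <- mapply(mitotiler:::format_variant_token, on$position,
                     on$ordinal, on$symbol, on$lowercase)
  expect_setequal(rendered, c("16189C", "16193c"))
  # 310 mixed call re-anchors to 309.N under compat
  tok310 <- data.frame(position = 310L, ordinal = 0L, kind = "substitution",
                       symbol = "Y", lowercase = FALSE,
                       stringsAsFactors = FALSE)
  on310 <- mitotiler:::apply_cstretch_rendering(tok310, TRUE, named_regions())
  expect_equal(on310$position, 309L)
  expect_equal(on310$kind, "insertion")
  off310 <- mitotiler:::apply_cstretch_rendering(tok310, FALSE,
                                                 named_regions())
  expect_equal(off310$position, 310L)
})

test_that("variant TSV, VCF and no-call BED outputs are well formed", {
  g <- rcrs(); p <- cr_panel()
  spec <- single_source_library("s", "73G 249del 315.1C", 4000L, seed = 17L)
  reads <- simulate_library(g, p, spec)
  aln <- apply_read_filters(align_reads(reads, g, p), g, p)
  pup <- build_pileup(aln, g)
  res <- call_sample(pup, preset_thresholds("control-region"), cr_region(),
                     g, "s")
  expect_equal(format_haplotype(res$haplotype), "73G 249del 315.1C")

  dir <- withr::local_tempdir()
  tsv <- file.path(dir, "v.tsv"); vcf <- file.path(dir, "v.vcf")
  bed <- file.path(dir, "nc.bed")
  write_variant_tsv(res, tsv)
  tab <- read.delim(tsv)
  expect_true(all(c("position", "call", "fraction", "depth",
                    "strand_depth", "status") %in% names(tab)))
  write_vcf(res, g, vcf)
  lines <- readLines(vcf)
  expect_equal(lines[1], "##fileformat=VCFv4.2")
  body <- lines[!startsWith(lines, "#")]
  expect_equal(length(body), 3L)
  f <- strsplit(body[1], "\t")[[1]]
  expect_equal(f[2], "73")
  expect_equal(f[5], "G")
  # deletion is left-anchored at 248
  f2 <- strsplit(body[2], "\t")[[1]]
  expect_equal(f2[2], "248")
  expect_equal(nchar(f2[4]), 2L)
  write_nocall_bed(res, g, bed)
  expect_length(readLines(bed), 0L)
})

test_that("SAM output converts to BAM with the expected record count", {
  skip_if_not_installed("Rsamtools")
  g <- rcrs(); p <- cr_panel()
  spec <- single_source_library("s", "", 50L, seed = 2L)
  reads <- simulate_library(g, p, spec)
  aln <- align_reads(reads, g, p)
  dir <- withr::local_tempdir()
  sam <- file.path(dir, "out.sam")
  write_sam(aln, g, sam)
  bam <- Rsamtools::asBam(sam, file.path(dir, "out"),
                          indexDestination = FALSE)
  expect_equal(Rsamtools::countBam(bam)$records, nrow(aln))
})
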