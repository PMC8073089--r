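mk_sheet <- function(n, roles = NULL) {
  idx <- make_index_pairs(n)
  data.frame(Sample_ID = sprintf("s%02d", seq_len(n)), index = idx$i7,
             index2 = idx$i5,
             role = roles %||% rep("sample", n),
             stringsAsFactors = FALSE)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

mk_reads <- function(sheet, per = 10L) {
  do.call(rbind, lapply(seq_len(nrow(sheet)), function(j) {
    data.frame(id = sprintf("%s:%03d", sheet$Sample_ID[j], seq_len(per)),
               r1_seq = "ACGT", r1_qual = "IIII", r2_seq = "ACGT",
               r2_qual = "IIII", i7 = sheet$index[j],
               i5 = sheet$index2[j], truth_sample = sheet$Sample_ID[j],
               truth_contributor = "c", truth_amplicon = "a",
               truth_numt = FALSE, truth_origin = "sample",
               stringsAsFactors = FALSE)
  }))
}

test_that("exact-index reads all demultiplex and conservation holds", {
  sheet <- mk_sheet(6)
  reads <- mk_reads(sheet, 25L)
  d <- demultiplex(reads, sheet)
  expect_equal(sum(d$counts$reads) + nrow(d$unassigned), d$total)
  expect_equal(d$counts$reads, rep(25L, 6))
  expect_equal(nrow(d$unassigned), 0L)
})

test_that("mismatch tolerance assigns near misses but not double misses", {
  sheet <- mk_sheet(4)
  reads <- mk_reads(sheet, 1L)
  flip <- function(s, k) {
    for (p in seq_len(k)) {
      substr(s, p, p) <- setdiff(c("A", "C", "G", "T"),
                                 substr(s, p, p))[1]
    }
    s
  }
  reads$i7[1] <- flip(reads$i7[1], 1L)  # 1 mismatch -> assigned at mm 1
  reads$i7[2] <- flip(reads$i7[2], 2L)  # 2 mismatches -> unassigned
  d <- demultiplex(reads, sheet, max_mismatch = 1L)
  expect_equal(d$counts$reads[1], 1L)
  expect_equal(d$counts$reads[2], 0L)
  expect_equal(nrow(d$unassigned), 1L)
  # mm 0 assignments are a subset of mm 1 assignments
  d0 <- demultiplex(reads, sheet, max_mismatch = 0L)
  for (nm in names(d0$assignments)) {
    expect_true(all(d0$assignments[[nm]]$id %in% d$assignments[[nm]]$id))
  }
})

test_that("ambiguously close index pairs are refused", {
  sheet <- mk_sheet(3)
  sheet$index[2] <- sheet$index[1]
  sheet$index2[2] <- sub("^.", ifelse(substr(sheet$index2[1], 1, 1) == "A",
                                      "C", "A"), sheet$index2[1])
  expect_error(demultiplex(mk_reads(sheet, 1L), sheet, max_mismatch = 1L),
               "ambiguous")
  sheet2 <- mk_sheet(2)
  sheet2$index[2] <- sheet2$index[1]
  sheet2$index2[2] <- sheet2$index2[1]
  expect_error(demultiplex(mk_reads(sheet2[1, ], 1L), sheet2),
               "duplicate")
  sheet3 <- mk_sheet(2)
  sheet3$index[1] <- "ACGT"
  expect_error(demultiplex(mk_reads(sheet3[2, ], 1L), sheet3), "8 nt")
})

test_that("run QC gates flag out-of-target metrics as warnings only", {
  all_pass <- evaluate_run_qc(1000, 90, 0.1, 0.1)
  expect_equal(all_pass$overall, "pass")
  cd <- evaluate_run_qc(1700, 90, 0.1, 0.1)
  expect_equal(cd$cluster_density, "outside-target")
  expect_equal(cd$overall, "outside-target")
  cpf <- evaluate_run_qc(1000, 79.9, 0.1, 0.1)
  expect_equal(cpf$clusters_passing_filter, "outside-target")
  ph <- evaluate_run_qc(1000, 90, 0.3, 0.1)
  expect_equal(ph$phasing, "outside-target")
  pph <- evaluate_run_qc(1000, 90, 0.1, 0.2)
  expect_equal(pph$prephasing, "outside-target")
  # boundary values pass
  expect_equal(evaluate_run_qc(400, 80, 0.25, 0.15)$overall, "pass")
  expect_error(evaluate_run_qc(-1, 90, 0.1, 0.1), "non-negative")
})

test_that("bait indexes receive zero reads in a clean run", {
  sheet <- mk_sheet(15, roles = c(rep("sample", 10), rep("bait", 5)))
  reads <- mk_reads(sheet[sheet$role == "sample", ], 20L)
  d <- demultiplex(reads, sheet)
  baits <- carryover_check(d)
  expect_equal(nrow(baits), 5L)
  expect_true(all(baits$reads == 0L))
  expect_error(carryover_check(d, "nonexistent"), "not in sample sheet")
  # empty read set -> all counts 0
  d0 <- demultiplex(reads[0, ], sheet)
  expect_true(all(carryover_check(d0)$reads == 0L))
})

test_that("carryover from a previous run surfaces in bait counts", {
  g <- rcrs(); p <- cr_panel()
  idx <- make_index_pairs(14)
  prev_libs <- lapply(1:2, function(i) list(
    spec = single_source_library(paste0("prev", i), "73G", 300L, seed = i),
    i7 = idx$i7[i], i5 = idx$i5[i]))
  prev <- simulate_run(run_spec(prev_libs, seed = 3L), g, p)
  cur_libs <- list(list(
    spec = single_source_library("cur", "263G", 300L, seed = 9L),
    i7 = idx$i7[3], i5 = idx$i5[3]))
  cur <- simulate_run(run_spec(
    cur_libs,
    bait_indexes = lapply(1:2, function(i)
      list(i7 = idx$i7[i], i5 = idx$i5[i])),
    carryover = list(reads = prev$reads, fraction = 0.02), seed = 4L), g, p)
  d <- demultiplex(cur$reads, cur$samplesheet)
  baits <- carryover_check(d)
  expect_gt(sum(baits$reads), 0L)
  # demux conservation again on this realistic run
  expect_equal(sum(d$counts$reads) + nrow(d$unassigned), d$total)
})

test_that("demux report includes the unassigned tally", {
  sheet <- mk_sheet(3)
  reads <- mk_reads(sheet, 5L)
  reads$i7[1] <- "TTTTTTTT"
  d <- demultiplex(reads, sheet)
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_demux_report(d, tmp)
  tab <- read.delim(tmp)
  expect_equal(tab$reads[tab$Sample_ID == "UNASSIGNED"],
               nrow(d$unassigned))
})
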