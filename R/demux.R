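# Dual-index demultiplexing, run-level QC gates and the bait-index
# carryover check.

#' Read / write an Illumina-style sample sheet
#'
#' CSV with columns `Sample_ID,index,index2` and an optional `role`
#' column (`sample`, `ntc` or `bait`).
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
read_samplesheet <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("Sample_ID", "index", "index2")
  if (!all(need %in% names(df))) {
    abort("sample sheet must have columns %s", paste(need, collapse = ","))
  }
  if (is.null(df$role)) df$role <- "sample"
  df
}

hamming <- function(a, b) {
  if (nchar(a) != nchar(b)) return(Inf)
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

validate_samplesheet <- function(sheet, max_mismatch) {
  if (any(nchar(sheet$index) != 8L) || any(nchar(sheet$index2) != 8L)) {
    abort("indexes must be 8 nt")
  }
  keys <- paste0(sheet$index, "+", sheet$index2)
  if (anyDuplicated(keys)) abort("duplicate index pairs in sample sheet")
  n <- nrow(sheet)
  if (n > 1L && max_mismatch > 0L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        if (hamming(sheet$index[i], sheet$index[j]) <= 2L * max_mismatch &&
            hamming(sheet$index2[i], sheet$index2[j]) <= 2L * max_mismatch) {
          abort("index pairs of %s and %s are within the mismatch budget of each other; demultiplexing would be ambiguous",
                sheet$Sample_ID[i], sheet$Sample_ID[j])
        }
      }
    }
  }
  invisible(sheet)
}

#' Demultiplex reads by dual index
#'
#' A read pair is assigned to a sheet entry iff both of its indexes match
#' that entry within `max_mismatch` and no other entry also matches;
#' otherwise it is unassigned. The sheet is rejected up front if two
#' entries lie within twice the mismatch budget of each other.
#'
#' @param reads reads data.frame (columns `i7`, `i5`).
#' @param sheet sample sheet data.frame ([read_samplesheet()] format).
#' @param max_mismatch per-index mismatch tolerance (default 1).
#' @return object of class `demux_result`: list with `assignments`
#'   (named list of per-sample reads data.frames), `unassigned`
#'   (data.frame), `counts` (data.frame `Sample_ID,index,index2,role,
#'   reads`) and `total`.
#' @export
demultiplex <- function(reads, sheet, max_mismatch = 1L) {
  validate_samplesheet(sheet, max_mismatch)
  n <- nrow(reads)
  assign_to <- rep(NA_integer_, n)
  if (n > 0L) {
    key <- paste0(reads$i7, "+", reads$i5)
    sheet_key <- paste0(sheet$index, "+", sheet$index2)
    exact <- match(key, sheet_key)
    assign_to <- exact
    if (max_mismatch > 0L) {
      todo <- which(is.na(exact) & !is.na(reads$i7))
      if (length(todo) > 0L) {
        ukeys <- unique(key[todo])
        lut <- vapply(ukeys, function(kk) {
          parts <- strsplit(kk, "+", fixed = TRUE)[[1]]
          d7 <- vapply(sheet$index, hamming, numeric(1), a = parts[1])
          d5 <- vapply(sheet$index2, hamming, numeric(1), a = parts[2])
          hitset <- which(d7 <= max_mismatch & d5 <= max_mismatch)
          if (length(hitset) == 1L) hitset else NA_integer_
        }, integer(1))
        assign_to[todo] <- lut[key[todo]]
      }
    }
  }
  counts <- sheet
  counts$reads <- vapply(seq_len(nrow(sheet)), function(j)
    sum(assign_to == j, na.rm = TRUE), integer(1))
  assignments <- lapply(seq_len(nrow(sheet)), function(j)
    reads[which(assign_to == j), , drop = FALSE])
  names(assignments) <- sheet$Sample_ID
  structure(list(
    assignments = assignments,
    unassigned = reads[is.na(assign_to), , drop = FALSE],
    counts = counts[, c("Sample_ID", "index", "index2", "role", "reads")],
    total = n
  ), class = "demux_result")
}

#' @export
print.demux_result <- function(x, ...) {
  cat(sprintf("<demux_result> %d reads: %d assigned over %d entries, %d unassigned\n",
              x$total, sum(x$counts$reads), nrow(x$counts),
              nrow(x$unassigned)))
  invisible(x)
}

#' Run-level QC metric gates
#'
#' Recommended target ranges: cluster density 400-1650 K/mm^2, clusters
#' passing filter >= 80%, phasing <= 0.25%, pre-phasing <= 0.15%. A
#' metric outside its target is a warning ("outside-target"), never an
#' error: such runs can still produce usable results.
#'
#' @param cluster_density K/mm^2.
#' @param clusters_pf percent of clusters passing filter.
#' @param phasing,prephasing percent.
#' @return list with per-metric status (`"pass"`/`"outside-target"`) and
#'   `overall` (`"pass"` iff all pass).
#' @export
evaluate_run_qc <- function(cluster_density, clusters_pf, phasing,
                            prephasing) {
  vals <- c(cluster_density, clusters_pf, phasing, prephasing)
  if (any(vals < 0)) abort("QC metrics must be non-negative")
  st <- function(ok) if (ok) "pass" else "outside-target"
  out <- list(
    cluster_density = st(cluster_density >= 400 && cluster_density <= 1650),
    clusters_passing_filter = st(clusters_pf >= 80),
    phasing = st(phasing <= 0.25),
    prephasing = st(prephasing <= 0.15)
  )
  out$overall <- st(all(unlist(out) == "pass"))
  out
}

#' Bait-index carryover check
#'
#' Returns the read count demultiplexed to every bait index pair (sheet
#' entries with role `"bait"`); all-zero counts mean no detectable index
#' cross-contamination or run-to-run carryover.
#'
#' @param demux a [demultiplex()] result.
#' @param bait_ids optional bait Sample_IDs to check (defaults to all
#'   sheet entries with role `"bait"`; an id missing from the sheet
#'   errors).
#' @return data.frame `Sample_ID,index,index2,reads`.
#' @export
carryover_check <- function(demux, bait_ids = NULL) {
  cnt <- demux$counts
  if (is.null(bait_ids)) {
    bait_ids <- cnt$Sample_ID[cnt$role == "bait"]
  } else if (!all(bait_ids %in% cnt$Sample_ID)) {
    abort("bait %s not in sample sheet",
          setdiff(bait_ids, cnt$Sample_ID)[1])
  }
  out <- cnt[cnt$Sample_ID %in% bait_ids,
             c("Sample_ID", "index", "index2", "reads")]
  rownames(out) <- NULL
  out
}

#' Write a demultiplexing report as TSV
#'
#' @param demux a [demultiplex()] result.
#' @param path output path.
#' @return `path` invisibly.
#' @export
write_demux_report <- function(demux, path) {
  df <- demux$counts
  df <- rbind(df, data.frame(Sample_ID = "UNASSIGNED", index = "",
                             index2 = "", role = "",
                             reads = nrow(demux$unassigned)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
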