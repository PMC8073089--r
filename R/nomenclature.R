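# SWGDAM-style mtDNA variant nomenclature: parsing, formatting,
# haplotype comparison and EMPOP-compatible reporting.
#
# A haplotype is a whitespace-separated list of tokens of the form
# `<pos>[.<ordinal>]<symbol>` where `symbol` is a single IUPAC letter
# (upper case for fixed calls, lower case marking length heteroplasmy)
# or `del` for a deletion ("249del"). Insertions carry a dotted ordinal
# ("315.1C", "16193.2c"). Tokens sort by (position, ordinal).

IUPAC_LETTERS <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                   "B", "D", "H", "V", "N")

# two-base mixtures and their IUPAC codes (sorted base pairs)
IUPAC_2 <- c(AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K")
IUPAC_3 <- c(ACG = "V", ACT = "H", AGT = "D", CGT = "B", ACGT = "N")

#' IUPAC code for a set of bases
#'
#' @param bases character vector drawn from A, C, G, T.
#' @return single IUPAC letter covering the set.
#' @export
iupac_code <- function(bases) {
  bases <- sort(unique(toupper(bases)))
  if (length(bases) == 1L) return(bases)
  key <- paste(bases, collapse = "")
  code <- c(IUPAC_2, IUPAC_3)[[key]]
  if (is.null(code)) abort("no IUPAC code for base set {%s}", key)
  code
}

TOKEN_RE <- "^([0-9]+)(?:\\.([0-9]+))?([ACGTRYSWKMBDHVNacgtryswkmbdhvn]|[Dd][Ee][Ll])$"

#' Parse one SWGDAM-style variant token
#'
#' @param token e.g. `"73G"`, `"315.1C"`, `"249del"`, `"309.1c"`.
#' @return a one-row data.frame with columns `position`, `ordinal`
#'   (0 for none), `kind` (`substitution`/`insertion`/`deletion`),
#'   `symbol` (upper-case letter or `"del"`) and `lowercase` (logical
#'   length-heteroplasmy marker).
#' @export
parse_variant_token <- function(token) {
  m <- regmatches(token, regexec(TOKEN_RE, token))[[1]]
  if (length(m) == 0L) abort("malformed variant token: '%s'", token)
  pos <- as.integer(m[2])
  ord <- if (nzchar(m[3])) as.integer(m[3]) else 0L
  sym <- m[4]
  is_del <- toupper(sym) == "DEL"
  if (is_del && ord > 0L) {
    abort("deletion token cannot carry an insertion ordinal: '%s'", token)
  }
  kind <- if (is_del) "deletion" else if (ord > 0L) "insertion" else "substitution"
  data.frame(
    position = pos, ordinal = ord, kind = kind,
    symbol = if (is_del) "del" else toupper(sym),
    lowercase = !is_del && sym %in% letters,
    stringsAsFactors = FALSE
  )
}

format_variant_token <- function(position, ordinal, symbol, lowercase) {
  sym <- if (symbol == "del") "del" else if (lowercase) tolower(symbol) else symbol
  if (ordinal > 0L) sprintf("%d.%d%s", position, ordinal, sym)
  else sprintf("%d%s", position, sym)
}

#' Parse a haplotype string
#'
#' Splits on whitespace, parses each token and returns the tokens sorted
#' by (position, ordinal). Case is preserved (lower case marks length
#' heteroplasmy). When a genome is supplied, positions are validated
#' against its length.
#'
#' @param text whitespace-separated variant string (may be empty).
#' @param genome optional [circular_genome()] for position validation.
#' @return object of class `haplotype`: a list with `tokens` (data.frame)
#'   and `covered_range` (list of [region()], may be empty meaning
#'   unknown/full).
#' @export
parse_haplotype <- function(text, genome = NULL) {
  toks <- strsplit(trimws(text), "\\s+")[[1]]
  toks <- toks[nzchar(toks)]
  if (length(toks) == 0L) {
    tab <- data.frame(position = integer(), ordinal = integer(),
                      kind = character(), symbol = character(),
                      lowercase = logical(), stringsAsFactors = FALSE)
  } else {
    tab <- do.call(rbind, lapply(toks, parse_variant_token))
    if (!is.null(genome) && any(tab$position > genome$length)) {
      bad <- tab$position[tab$position > genome$length][1]
      abort("variant position %d out of range (genome length %d)",
            bad, genome$length)
    }
    if (anyDuplicated(tab[, c("position", "ordinal")])) {
      abort("duplicate (position, ordinal) in haplotype: '%s'", text)
    }
    tab <- tab[order(tab$position, tab$ordinal), , drop = FALSE]
    rownames(tab) <- NULL
  }
  new_haplotype(tab)
}

new_haplotype <- function(tokens, covered_range = list()) {
  structure(list(tokens = tokens, covered_range = covered_range),
            class = "haplotype")
}

#' @export
print.haplotype <- function(x, ...) {
  cat("<haplotype>", format_haplotype(x), "\n")
  invisible(x)
}

#' Format a haplotype as a canonical variant string
#'
#' Tokens are emitted sorted by (position, ordinal), single-spaced, with
#' case preserved; `format_haplotype(parse_haplotype(s))` canonicalizes
#' `s` and is the identity on already-canonical strings.
#'
#' @param hap a `haplotype`.
#' @return variant string ("" for an empty haplotype).
#' @export
format_haplotype <- function(hap) {
  t <- hap$tokens
  if (nrow(t) == 0L) return("")
  t <- t[order(t$position, t$ordinal), , drop = FALSE]
  paste(mapply(format_variant_token, t$position, t$ordinal, t$symbol,
               t$lowercase),
        collapse = " ")
}

token_keys <- function(hap) {
  t <- hap$tokens
  if (nrow(t) == 0L) return(character())
  paste0(t$position, ".", t$ordinal, ":", t$symbol,
         ifelse(t$lowercase, "-", "+"))
}

#' Compare two haplotypes
#'
#' Concordance is the percentage of shared variants over the union of the
#' two variant sets, restricted to `restrict` when given (the conservative
#' union denominator). Two identical sets (including two empty sets) give
#' 100. When the haplotypes carry disjoint covered ranges the comparison
#' is undefined and `concordance` is `NA` with `comparable = FALSE`.
#'
#' @param a,b `haplotype` objects.
#' @param restrict optional [region()]; only variants inside it are
#'   compared.
#' @param genome_length genome length, needed only when `restrict` wraps.
#' @return list with `concordance` (percent, one decimal), `shared`,
#'   `only_a`, `only_b` (character vectors of tokens) and `comparable`.
#' @export
compare_haplotypes <- function(a, b, restrict = NULL, genome_length = 16569L) {
  if (length(a$covered_range) > 0L && length(b$covered_range) > 0L) {
    pos_a <- unlist(lapply(a$covered_range, region_positions, genome_length))
    pos_b <- unlist(lapply(b$covered_range, region_positions, genome_length))
    if (length(intersect(pos_a, pos_b)) == 0L) {
      return(list(concordance = NA_real_, shared = character(),
                  only_a = character(), only_b = character(),
                  comparable = FALSE))
    }
  }
  filter_r <- function(h) {
    if (is.null(restrict)) return(h)
    keep <- h$tokens$position %in% region_positions(restrict, genome_length)
    new_haplotype(h$tokens[keep, , drop = FALSE], h$covered_range)
  }
  a <- filter_r(a); b <- filter_r(b)
  ka <- token_keys(a); kb <- token_keys(b)
  shared <- intersect(ka, kb)
  uni <- union(ka, kb)
  conc <- if (length(uni) == 0L) 100 else
    round_half_up(100 * length(shared) / length(uni), 1)
  strip <- function(k, h) {
    t <- h$tokens
    keys <- token_keys(h)
    vapply(k, function(x) {
      i <- match(x, keys)
      format_variant_token(t$position[i], t$ordinal[i], t$symbol[i],
                           t$lowercase[i])
    }, character(1), USE.NAMES = FALSE)
  }
  list(concordance = conc,
       shared = strip(shared, a),
       only_a = strip(setdiff(ka, kb), a),
       only_b = strip(setdiff(kb, ka), b),
       comparable = TRUE)
}

#' EMPOP-compatible report for a called sample
#'
#' Emits the two EMPOP-compatible blocks as plain text: (1) the sample's
#' reconstructed sequence over the covered range(s) in FASTA format and
#' (2) the variant list headed by the covered range(s). No-call regions
#' split the range header into the covered sub-ranges.
#'
#' @param sample_result a [call_sample()] result (needs fields `haplotype`,
#'   `no_call_regions`, `sample_name`).
#' @param genome the reference [circular_genome()].
#' @param range the reported [region()] (e.g. the control region).
#' @param path optional output file; when given the report is written
#'   there.
#' @return the report text, invisibly when `path` is given.
#' @export
empop_report <- function(sample_result, genome, range, path = NULL) {
  hap <- sample_result$haplotype
  name <- sample_result$sample_name %||% "sample"
  all_pos <- region_positions(range, genome$length)
  nc_pos <- unlist(lapply(sample_result$no_call_regions, region_positions,
                          genome$length))
  covered <- setdiff(all_pos, nc_pos)
  if (length(covered) == 0L) abort("sample has no covered positions in range")
  sub_ranges <- split_positions_to_ranges(all_pos, covered)
  range_hdr <- paste(vapply(sub_ranges, function(r)
    sprintf("%d-%d", r$start, r$end), character(1)), collapse = "; ")

  seqs <- vapply(sub_ranges, function(r)
    reconstruct_sequence(genome, r, hap), character(1))
  fasta <- unlist(lapply(seq_along(sub_ranges), function(i) {
    r <- sub_ranges[[i]]
    c(sprintf(">%s %d-%d", name, r$start, r$end),
      substring(seqs[i], seq(1, nchar(seqs[i]), 60),
                pmin(seq(1, nchar(seqs[i]), 60) + 59, nchar(seqs[i]))))
  }))
  var_str <- format_haplotype(hap)
  txt <- c(fasta, "",
           sprintf("Sample: %s", name),
           sprintf("Range: %s", range_hdr),
           sprintf("Variants: %s", var_str))
  out <- paste(txt, collapse = "\n")
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(out))
  }
  out
}

# contiguous runs of `covered` in the circular order given by all_pos
split_positions_to_ranges <- function(all_pos, covered) {
  inc <- all_pos %in% covered
  if (!any(inc)) return(list())
  r <- rle(inc)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  out <- list()
  for (i in seq_along(r$values)) {
    if (r$values[i]) {
      out[[length(out) + 1L]] <- region(all_pos[starts[i]], all_pos[ends[i]])
    }
  }
  out
}

# apply a haplotype's tokens to the reference subsequence of region r
reconstruct_sequence <- function(genome, r, hap) {
  pos <- region_positions(r, genome$length)
  ref <- strsplit(subsequence(genome, r), "")[[1]]
  t <- hap$tokens
  t <- t[t$position %in% pos, , drop = FALSE]
  pieces <- ref
  idx <- match(t$position, pos)
  for (i in seq_len(nrow(t))) {
    j <- idx[i]
    if (t$kind[i] == "substitution") {
      # IUPAC mixed codes and lowercase length-variants render as the
      # (upper-case) called symbol in the sequence string
      pieces[j] <- t$symbol[i]
    } else if (t$kind[i] == "deletion") {
      pieces[j] <- ""
    } else { # insertion appended after the anchor base, ordinal order
      pieces[j] <- paste0(pieces[j], t$symbol[i])
    }
  }
  paste(pieces, collapse = "")
}
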