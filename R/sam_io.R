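# Plain-text SAM parsing and CIGAR arithmetic.
#
# The pipeline starts from spliced alignments, so the observable primitive
# is the CIGAR walk over the reference: M/=/X/D consume reference within an
# aligned block, N opens an intron, I/S/H/P do not consume reference.
# Coordinates are converted from SAM's 1-based POS to 0-based half-open.

#' Read a SAM file into an alignment table
#'
#' Minimal text-mode SAM reader for headered, unsorted SAM. Secondary
#' (0x100), supplementary (0x800) and unmapped (0x4) flags are decoded, and
#' the `NH:i` (number of reported alignments) and `XS:A` (transcript strand)
#' tags are extracted when present.
#'
#' @param path SAM file path.
#' @return A tibble with one row per alignment record: `qname`, `flag`,
#'   `chrom`, `pos` (0-based leftmost reference position), `mapq`, `cigar`,
#'   `seq`, `nh`, `xs`, `primary`, `unmapped`. The header lines are attached
#'   as attribute `"sam_header"`.
#' @export
read_sam <- function(path) {
  lines <- readLines(path, warn = FALSE)
  is_header <- startsWith(lines, "@")
  if (length(lines) == 0 || !any(is_header)) {
    abort(sprintf("SAM file %s has no header", path))
  }
  body <- lines[!is_header]
  if (length(body) == 0) {
    aln <- tibble(
      qname = character(), flag = integer(), chrom = character(),
      pos = integer(), mapq = integer(), cigar = character(),
      seq = character(), nh = integer(), xs = character(),
      primary = logical(), unmapped = logical()
    )
    attr(aln, "sam_header") <- lines[is_header]
    return(aln)
  }
  f <- data.table::tstrsplit(body, "\t", fixed = TRUE, keep = c(1:6, 10))
  nh <- suppressWarnings(as.integer(
    stringr::str_match(body, "\\tNH:i:(\\d+)")[, 2]
  ))
  xs <- stringr::str_match(body, "\\tXS:A:([+-])")[, 2]
  flag <- as.integer(f[[2]])
  aln <- tibble(
    qname = f[[1]], flag = flag, chrom = f[[3]],
    pos = as.integer(f[[4]]) - 1L, mapq = as.integer(f[[5]]),
    cigar = f[[6]], seq = f[[7]], nh = nh, xs = xs,
    primary = bitwAnd(flag, 0x100L) == 0L & bitwAnd(flag, 0x800L) == 0L,
    unmapped = bitwAnd(flag, 0x4L) != 0L
  )
  attr(aln, "sam_header") <- lines[is_header]
  aln
}

# Explode CIGAR strings into a long per-op table with reference coordinates.
# Returns a data.table: aln_row, op, len, ref_start, ref_end (0-based
# half-open; ref_start == ref_end for ops that do not consume reference).
parse_cigar_table <- function(aln) {
  n <- nrow(aln)
  if (n == 0) {
    return(data.table::data.table(
      aln_row = integer(), op = character(), len = integer(),
      ref_start = integer(), ref_end = integer()
    ))
  }
  m <- gregexpr("\\d+[MIDNSHP=X]", aln$cigar, perl = TRUE)
  toks <- regmatches(aln$cigar, m)
  nops <- lengths(toks)
  if (any(nops == 0 & aln$cigar != "*")) {
    abort("unparseable CIGAR string encountered")
  }
  flat <- unlist(toks, use.names = FALSE)
  dt <- data.table::data.table(
    aln_row = rep(seq_len(n), nops),
    op = substr(flat, nchar(flat), nchar(flat)),
    len = as.integer(substr(flat, 1L, nchar(flat) - 1L))
  )
  ref_consume <- c(M = TRUE, I = FALSE, D = TRUE, N = TRUE, S = FALSE,
                   H = FALSE, P = FALSE, `=` = TRUE, X = TRUE)
  dt[, ref_len := len * as.integer(ref_consume[op])]
  dt[, ref_end := aln$pos[aln_row] + cumsum(ref_len), by = aln_row]
  dt[, ref_start := ref_end - ref_len]
  dt[, ref_len := NULL]
  dt[]
}

# Aligned reference blocks per record: contiguous runs of M/=/X/D, split at
# every N. Returns a tibble (aln_row, start, end).
sam_ref_blocks <- function(aln) {
  ops <- parse_cigar_table(aln)
  if (nrow(ops) == 0) {
    return(tibble(aln_row = integer(), start = integer(), end = integer()))
  }
  ops[, block_id := cumsum(op == "N"), by = aln_row]
  blocks <- ops[op %in% c("M", "=", "X", "D"),
    .(start = min(ref_start), end = max(ref_end)),
    by = .(aln_row, block_id)
  ]
  tibble(
    aln_row = blocks$aln_row,
    start = blocks$start, end = blocks$end
  ) %>% arrange(.data$aln_row, .data$start)
}

# Introns (N ops) per record, plus whether the N sits at a read edge (no
# aligned M/=/X block on both sides), which marks the record invalid for
# junction extraction. Returns a tibble
# (aln_row, start, end, edge_n).
sam_introns <- function(aln) {
  ops <- parse_cigar_table(aln)
  if (nrow(ops) == 0) {
    return(tibble(
      aln_row = integer(), start = integer(), end = integer(),
      edge_n = logical()
    ))
  }
  ops[, is_match := op %in% c("M", "=", "X")]
  ops[, `:=`(
    n_match_before = cumsum(is_match) - is_match,
    n_match_after = rev(cumsum(rev(is_match))) - is_match
  ), by = aln_row]
  introns <- ops[op == "N"]
  if (nrow(introns) == 0) {
    return(tibble(
      aln_row = integer(), start = integer(), end = integer(),
      edge_n = logical()
    ))
  }
  tibble(
    aln_row = introns$aln_row,
    start = introns$ref_start, end = introns$ref_end,
    edge_n = introns$n_match_before == 0L | introns$n_match_after == 0L
  )
}

# Read length implied by a CIGAR (ops consuming the query: M/I/S/=/X).
cigar_read_length <- function(cigar) {
  toks <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar, perl = TRUE))
  vapply(toks, function(t) {
    op <- substr(t, nchar(t), nchar(t))
    len <- as.integer(substr(t, 1L, nchar(t) - 1L))
    sum(len[op %in% c("M", "I", "S", "=", "X")])
  }, integer(1))
}
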