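# Independent oracle implementations used to cross-check the package's
# interval index, CIGAR walk and read-assignment logic. These are written
# as plain per-element loops, deliberately sharing no code with the
# package internals.

# linear-scan overlap oracle (half-open intervals)
oracle_overlaps <- function(features, chrom, start, end) {
  hit <- logical(nrow(features))
  for (i in seq_len(nrow(features))) {
    hit[i] <- features$chrom[i] == chrom &&
      features$start[i] < end && features$end[i] > start
  }
  features[hit, , drop = FALSE]
}

# character-by-character CIGAR walk: returns list(blocks=, introns=) of
# 0-based half-open reference intervals; edge_n TRUE when an N lacks an
# aligned M block on either side
oracle_cigar_walk <- function(pos0, cigar) {
  chars <- strsplit(cigar, "")[[1]]
  num <- ""
  ref <- pos0
  blocks <- list()
  introns <- list()
  cur_start <- NA_integer_
  seen_match <- FALSE
  pending_introns <- 0L
  edge_n <- FALSE
  for (ch in chars) {
    if (grepl("[0-9]", ch)) {
      num <- paste0(num, ch)
      next
    }
    len <- as.integer(num)
    num <- ""
    if (ch %in% c("M", "=", "X", "D")) {
      if (is.na(cur_start)) cur_start <- ref
      ref <- ref + len
      if (ch %in% c("M", "=", "X")) {
        seen_match <- TRUE
        pending_introns <- 0L
      }
    } else if (ch == "N") {
      if (!seen_match) edge_n <- TRUE
      if (!is.na(cur_start)) blocks[[length(blocks) + 1]] <- c(cur_start, ref)
      introns[[length(introns) + 1]] <- c(ref, ref + len)
      pending_introns <- pending_introns + 1L
      ref <- ref + len
      cur_start <- NA_integer_
    }
    # I, S, H, P consume no reference
  }
  if (!is.na(cur_start)) blocks[[length(blocks) + 1]] <- c(cur_start, ref)
  if (pending_introns > 0) edge_n <- TRUE
  list(blocks = blocks, introns = introns, edge_n = edge_n)
}

# brute-force per-read junction extraction over a SAM file
oracle_junctions <- function(sam_path) {
  lines <- readLines(sam_path)
  lines <- lines[!startsWith(lines, "@")]
  out <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    flag <- as.integer(f[2])
    if (bitwAnd(flag, 4L) != 0 || bitwAnd(flag, 256L) != 0 ||
      bitwAnd(flag, 2048L) != 0) {
      next
    }
    walk <- oracle_cigar_walk(as.integer(f[4]) - 1L, f[6])
    if (walk$edge_n || length(walk$introns) == 0) next
    for (iv in walk$introns) {
      out[[length(out) + 1]] <- data.frame(
        chrom = f[3], intron_start = iv[1], intron_end = iv[2]
      )
    }
  }
  if (length(out) == 0) {
    return(data.frame(
      chrom = character(), intron_start = integer(),
      intron_end = integer(), n_reads = integer()
    ))
  }
  agg <- do.call(rbind, out)
  stats::aggregate(
    list(n_reads = rep(1L, nrow(agg))),
    agg[, c("chrom", "intron_start", "intron_end")], sum
  )
}

# brute-force TE family assignment for one SAM file
oracle_te_counts <- function(sam_path, tes, mode) {
  lines <- readLines(sam_path)
  lines <- lines[!startsWith(lines, "@")]
  counts <- stats::setNames(
    numeric(length(unique(tes$family))), sort(unique(tes$family))
  )
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    flag <- as.integer(f[2])
    if (bitwAnd(flag, 4L) != 0) next
    nh_m <- regmatches(ln, regexpr("NH:i:[0-9]+", ln))
    nh <- if (length(nh_m)) as.integer(sub("NH:i:", "", nh_m)) else NA
    primary <- bitwAnd(flag, 256L) == 0 && bitwAnd(flag, 2048L) == 0
    if (mode == "unique" && (!primary || (!is.na(nh) && nh != 1))) next
    walk <- oracle_cigar_walk(as.integer(f[4]) - 1L, f[6])
    ov_by_family <- list()
    for (i in seq_len(nrow(tes))) {
      if (tes$chrom[i] != f[3]) next
      ov <- 0L
      for (b in walk$blocks) {
        ov <- ov + max(0L, min(b[2], tes$end[i]) - max(b[1], tes$start[i]))
      }
      if (ov > 0) {
        fam <- tes$family[i]
        ov_by_family[[fam]] <- (ov_by_family[[fam]] %||% 0L) + ov
      }
    }
    if (length(ov_by_family) == 0) next
    ovs <- unlist(ov_by_family)
    best <- names(ovs)[ovs == max(ovs)]
    if (length(best) != 1) next # ambiguous tie
    w <- if (mode == "unique") 1 else 1 / nh
    counts[best] <- counts[best] + w
  }
  counts
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# write a SAM file from a record tibble; records: chrom, pos (0-based),
# cigar, optional nh, xs, secondary
write_test_sam <- function(path, records, chrom_sizes) {
  header <- c(
    "@HD\tVN:1.6\tSO:unsorted",
    sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_sizes), chrom_sizes)
  )
  body <- character(0)
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    nh <- if ("nh" %in% names(records) && !is.na(r$nh)) r$nh else 1L
    flag <- if (isTRUE(r$secondary)) 256L else 0L
    read_len <- sum(as.integer(
      regmatches(r$cigar, gregexpr("[0-9]+(?=[MIS=X])", r$cigar,
        perl = TRUE
      ))[[1]]
    ))
    tags <- paste0("NH:i:", nh)
    if ("xs" %in% names(records) && !is.na(r$xs)) {
      tags <- paste0(tags, "\tXS:A:", r$xs)
    }
    body <- c(body, paste(
      sprintf("r%04d", i), flag, r$chrom, r$pos + 1L, 255L, r$cigar, "*",
      0L, 0L, strrep("A", max(read_len, 1)), "*", tags,
      sep = "\t"
    ))
  }
  writeLines(c(header, body), path)
  path
}

# random spliced-read SAM fixture: reads with 0-3 introns
random_spliced_sam <- function(path, n_reads, seed) {
  set.seed(seed)
  chrom_sizes <- c(chrA = 100000L, chrB = 80000L)
  recs <- list()
  for (i in seq_len(n_reads)) {
    chrom <- sample(names(chrom_sizes), 1)
    n_introns <- sample(0:3, 1, prob = c(0.3, 0.4, 0.2, 0.1))
    m_lens <- sample(20:60, n_introns + 1, replace = TRUE)
    n_lens <- if (n_introns > 0) sample(50:5000, n_introns) else integer()
    cigar <- paste0(m_lens[1], "M")
    if (n_introns > 0) {
      for (j in seq_len(n_introns)) {
        cigar <- paste0(cigar, n_lens[j], "N", m_lens[j + 1], "M")
      }
    }
    span <- sum(m_lens) + sum(n_lens)
    pos <- sample.int(chrom_sizes[[chrom]] - span - 1L, 1)
    recs[[i]] <- data.frame(
      chrom = chrom, pos = pos, cigar = cigar, nh = 1L, secondary = FALSE
    )
  }
  write_test_sam(path, do.call(rbind, recs), chrom_sizes)
}
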