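# Annotation I/O: gene models from GTF, TE instances from BED6/RepeatMasker,
# region sets, design tables, and an overlap index.
#
# Internal coordinate convention: 0-based half-open everywhere. GTF and
# RepeatMasker are 1-based inclusive and are converted at this boundary;
# BED is already 0-based half-open and passes through untouched.

TE_CLASSES <- c("LTR", "LINE", "SINE", "DNA", "other")

#' Read gene models from a GTF file
#'
#' Parses `exon` features, groups them per gene (union over all transcripts,
#' overlapping exons merged), and derives the strand-aware landmarks used by
#' the chimeric-transcript caller: the first annotated exon (5'-most exon in
#' gene orientation), the transcription start site, and the set of splice
#' acceptor positions (first genomic base of each non-first exon on `+`,
#' last base on `-`).
#'
#' @param path Path to a GTF file (1-based inclusive coordinates).
#' @return A tibble with one row per gene: `gene_id`, `chrom`, `strand`,
#'   `biotype` (`coding`, `lncRNA` or `other`), `n_exons`, `exons`
#'   (list-column of tibbles with 0-based half-open `start`/`end`),
#'   `first_exon_start`, `first_exon_end`, `tss`, and `acceptor_sites`
#'   (list-column of integer genomic positions).
#' @export
read_gtf <- function(path) {
  empty <- tibble(
    gene_id = character(), chrom = character(), strand = character(),
    biotype = character(), n_exons = integer(), exons = list(),
    first_exon_start = integer(), first_exon_end = integer(),
    tss = integer(), acceptor_sites = list()
  )
  lines <- readLines(path, warn = FALSE)
  data_idx <- which(!grepl("^\\s*(#|$)", lines))
  if (length(data_idx) == 0) {
    return(empty)
  }
  nfields <- vapply(
    strsplit(lines[data_idx], "\t", fixed = TRUE), length, integer(1)
  )
  bad <- data_idx[nfields != 9L]
  if (length(bad) > 0) {
    abort(sprintf(
      "malformed GTF line %d in %s: expected 9 tab-separated fields",
      bad[1], path
    ))
  }
  gff <- as_tibble(rtracklayer::readGFF(path))
  if (!"gene_id" %in% names(gff)) {
    abort(sprintf("GTF %s carries no gene_id attribute", path))
  }
  all_genes <- unique(stats::na.omit(as.character(gff$gene_id)))
  ex <- gff %>%
    filter(.data$type == "exon", !is.na(.data$gene_id)) %>%
    mutate(
      gene_id = as.character(.data$gene_id),
      chrom = as.character(.data$seqid),
      strand = as.character(.data$strand),
      start0 = as.integer(.data$start) - 1L,
      end0 = as.integer(.data$end)
    )
  exonless <- setdiff(all_genes, unique(ex$gene_id))
  if (length(exonless) > 0) {
    warn(sprintf(
      "excluding %d gene(s) with zero exon features: %s",
      length(exonless), paste(head(exonless, 5), collapse = ", ")
    ))
  }
  if (nrow(ex) == 0) {
    return(empty)
  }
  biotype_of <- function(b) {
    b <- as.character(b)
    dplyr::case_when(
      b %in% "protein_coding" ~ "coding",
      b %in% c("lncRNA", "lincRNA") ~ "lncRNA",
      TRUE ~ "other"
    )
  }
  bt_col <- intersect(c("gene_biotype", "gene_type"), names(gff))[1]
  ex$biotype <- if (!is.na(bt_col)) biotype_of(ex[[bt_col]]) else "other"

  ex %>%
    group_by(.data$gene_id) %>%
    dplyr::group_modify(function(d, key) {
      strand <- d$strand[1]
      merged <- IRanges::reduce(IRanges::IRanges(d$start0 + 1L, d$end0))
      exons <- tibble(
        start = IRanges::start(merged) - 1L,
        end = IRanges::end(merged)
      ) %>% arrange(.data$start)
      n <- nrow(exons)
      if (strand == "+") {
        fi <- 1L
        acceptors <- if (n > 1) exons$start[-fi] else integer()
        tss <- exons$start[fi]
      } else {
        fi <- n
        acceptors <- if (n > 1) exons$end[-fi] - 1L else integer()
        tss <- exons$end[fi] - 1L
      }
      fe_start <- exons$start[fi]
      fe_end <- exons$end[fi]
      tibble(
        chrom = d$chrom[1], strand = strand,
        biotype = d$biotype[1], n_exons = n, exons = list(exons),
        first_exon_start = fe_start, first_exon_end = fe_end,
        tss = as.integer(tss), acceptor_sites = list(as.integer(acceptors))
      )
    }) %>%
    ungroup() %>%
    arrange(.data$chrom, .data$first_exon_start, .data$gene_id)
}

#' Write gene models to GTF
#'
#' Inverse of [read_gtf()]: emits one `exon` feature per merged exon, with
#' coordinates converted back to the 1-based inclusive GTF convention.
#'
#' @param genes Gene tibble as returned by [read_gtf()].
#' @param path Output path.
#' @return `genes`, invisibly.
#' @export
write_gtf <- function(genes, path) {
  rows <- genes %>%
    select("gene_id", "chrom", "strand", "biotype", "exons") %>%
    tidyr::unnest("exons")
  gtf_biotype <- c(coding = "protein_coding", lncRNA = "lncRNA", other = "misc_RNA")
  lines <- sprintf(
    "%s\ttespectrum\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s.t1\"; gene_biotype \"%s\";",
    rows$chrom, rows$start + 1L, rows$end, rows$strand,
    rows$gene_id, rows$gene_id, gtf_biotype[rows$biotype]
  )
  writeLines(lines, path)
  invisible(genes)
}

#' Read TE instances from BED6 or a RepeatMasker table
#'
#' In BED6 input the name field encodes the repeat family, optionally with
#' its class as `family#class` (e.g. `MT2_Mm#LTR`); families without a class
#' annotation are assigned class `other`. RepeatMasker `.out` tables carry
#' the class in their class/family column (text before `/`). Classes outside
#' LTR/LINE/SINE/DNA collapse to `other`. Coordinates are converted to
#' 0-based half-open; BED input passes through.
#'
#' @param path Annotation file.
#' @param format `"bed6"` (default) or `"repeatmasker"`.
#' @return A tibble with `instance_id`, `family`, `te_class`, `chrom`,
#'   `start`, `end`, `strand`.
#' @export
read_te_annotation <- function(path, format = c("bed6", "repeatmasker")) {
  format <- match.arg(format)
  if (format == "bed6") {
    raw <- readr::read_tsv(path,
      col_names = c("chrom", "start", "end", "name", "score", "strand"),
      col_types = "ciiccc", progress = FALSE
    ) %>%
      # header/comment lines only (the '#' of family#class must survive)
      filter(!startsWith(.data$chrom, "#"))
    fam_class <- stringr::str_split_fixed(raw$name, stringr::fixed("#"), 2)
    tes <- tibble(
      family = fam_class[, 1],
      te_class = fam_class[, 2],
      chrom = raw$chrom, start = raw$start, end = raw$end,
      strand = raw$strand
    )
  } else {
    raw <- read.table(path,
      skip = 3, header = FALSE, fill = TRUE,
      stringsAsFactors = FALSE
    )
    tes <- tibble(
      family = as.character(raw[[10]]),
      te_class = sub("/.*$", "", as.character(raw[[11]])),
      chrom = as.character(raw[[5]]),
      start = as.integer(raw[[6]]) - 1L,
      end = as.integer(raw[[7]]),
      strand = if_else(as.character(raw[[9]]) == "C", "-", "+")
    )
  }
  bad <- which(tes$start >= tes$end)
  if (length(bad) > 0) {
    abort(sprintf(
      "TE record %d (%s:%d-%d, %s) rejected: start >= end",
      bad[1], tes$chrom[bad[1]], tes$start[bad[1]], tes$end[bad[1]],
      tes$family[bad[1]]
    ))
  }
  tes %>%
    mutate(
      te_class = if_else(.data$te_class %in% TE_CLASSES, .data$te_class, "other"),
      strand = if_else(.data$strand %in% c("+", "-"), .data$strand, "+"),
      instance_id = paste0(.data$family, ".", row_number())
    ) %>%
    select(
      "instance_id", "family", "te_class", "chrom", "start", "end", "strand"
    )
}

#' Write TE instances as BED6
#'
#' The name field is written as `family#class` so that
#' [read_te_annotation()] round-trips the class.
#'
#' @param tes TE tibble as returned by [read_te_annotation()].
#' @param path Output path.
#' @return `tes`, invisibly.
#' @export
write_te_bed <- function(tes, path) {
  lines <- sprintf(
    "%s\t%d\t%d\t%s#%s\t0\t%s",
    tes$chrom, tes$start, tes$end, tes$family, tes$te_class, tes$strand
  )
  writeLines(lines, path)
  invisible(tes)
}

#' Read a named region set from BED
#'
#' @param path BED file (>= 3 columns; column 4, when present, supplies the
#'   region label). Coordinates pass through as 0-based half-open.
#' @param set_name Name of the region set (e.g. `"promoters"`, `"imprints"`).
#' @return A tibble with `set_name`, `label`, `chrom`, `start`, `end`.
#'   Labels are made unique within the set.
#' @export
read_region_bed <- function(path, set_name) {
  raw <- readr::read_tsv(path,
    col_names = FALSE, comment = "#",
    col_types = readr::cols(.default = readr::col_guess()),
    progress = FALSE
  )
  if (nrow(raw) == 0) {
    return(tibble(
      set_name = character(), label = character(),
      chrom = character(), start = integer(), end = integer()
    ))
  }
  label <- if (ncol(raw) >= 4) {
    as.character(raw[[4]])
  } else {
    paste0(set_name, "_", seq_len(nrow(raw)))
  }
  out <- tibble(
    set_name = set_name,
    label = make.unique(label, sep = "_"),
    chrom = as.character(raw[[1]]),
    start = as.integer(raw[[2]]),
    end = as.integer(raw[[3]])
  )
  check_that(all(out$start < out$end), paste0("invalid interval in ", path))
  out
}

#' Write a region set as BED4
#'
#' @param regions Region tibble from [read_region_bed()].
#' @param path Output path.
#' @return `regions`, invisibly.
#' @export
write_region_bed <- function(regions, path) {
  writeLines(sprintf(
    "%s\t%d\t%d\t%s",
    regions$chrom, regions$start, regions$end, regions$label
  ), path)
  invisible(regions)
}

#' Read a sample design table
#'
#' Accepts either the commented-header TSV dialect used by all pipeline
#' writers or a plain-header TSV. Requires `sample_id` and `condition`
#' columns; `background` and `replicate` are optional.
#'
#' @param path TSV path.
#' @return A tibble with `sample_id`, `condition`, `background`, `replicate`.
#' @export
read_design <- function(path) {
  first <- readLines(path, n = 1L)
  design <- if (startsWith(first, "# ")) {
    read_spectrum_tsv(path)
  } else {
    strip_readr_attrs(
      readr::read_tsv(path, progress = FALSE, show_col_types = FALSE)
    )
  }
  check_that(
    all(c("sample_id", "condition") %in% names(design)),
    "design table must have sample_id and condition columns"
  )
  if (!"background" %in% names(design)) design$background <- "unknown"
  if (!"replicate" %in% names(design)) {
    design <- design %>%
      group_by(.data$condition) %>%
      mutate(replicate = row_number()) %>%
      ungroup()
  }
  check_that(
    !anyDuplicated(design$sample_id),
    "duplicate sample_id in design table"
  )
  design %>%
    mutate(
      sample_id = as.character(.data$sample_id),
      condition = as.character(.data$condition),
      background = as.character(.data$background),
      replicate = as.integer(.data$replicate)
    ) %>%
    select("sample_id", "condition", "background", "replicate")
}

# ---- interval index ---------------------------------------------------------

#' Build an overlap index over genomic features
#'
#' Wraps a per-chromosome [IRanges::IRanges] nested containment list so that
#' interval overlap queries over gene exons, TE instances or regions run in
#' near-logarithmic time. All coordinates are 0-based half-open.
#'
#' @param features A data frame with `chrom`, `start`, `end` columns (other
#'   columns are carried along and returned by queries).
#' @return An object of class `interval_index`.
#' @export
build_interval_index <- function(features) {
  features <- as_tibble(features)
  check_that(
    all(c("chrom", "start", "end") %in% names(features)),
    "features need chrom, start, end columns"
  )
  check_that(
    all(features$start < features$end),
    "feature intervals must satisfy start < end"
  )
  idx <- split(seq_len(nrow(features)), features$chrom)
  ranges <- lapply(idx, function(i) {
    IRanges::IRanges(features$start[i] + 1L, features$end[i])
  })
  structure(
    list(features = features, row_idx = idx, ranges = ranges),
    class = "interval_index"
  )
}

#' @export
print.interval_index <- function(x, ...) {
  cat(sprintf(
    "<interval_index: %d features on %d chromosome(s)>\n",
    nrow(x$features), length(x$ranges)
  ))
  invisible(x)
}

#' Query an interval index
#'
#' @param index An [build_interval_index()] object.
#' @param chrom Chromosome name.
#' @param start,end Query interval, 0-based half-open.
#' @return The rows of the indexed feature table intersecting the query
#'   (half-open semantics: abutting intervals do not overlap).
#' @export
query_overlaps <- function(index, chrom, start, end) {
  stopifnot(inherits(index, "interval_index"))
  hits <- index_overlaps(
    index,
    tibble(chrom = chrom, start = start, end = end)
  )
  index$features[hits$feature_row, , drop = FALSE]
}

# Vectorised overlap join: for a table of query intervals, return matching
# (query_row, feature_row, overlap_width) pairs. Internal workhorse for
# read counting and region methylation.
index_overlaps <- function(index, queries) {
  out <- vector("list", length(index$ranges))
  qidx <- split(seq_len(nrow(queries)), queries$chrom)
  k <- 0L
  for (chrom in names(qidx)) {
    if (is.null(index$ranges[[chrom]])) next
    qi <- qidx[[chrom]]
    qr <- IRanges::IRanges(queries$start[qi] + 1L, queries$end[qi])
    hits <- IRanges::findOverlaps(qr, index$ranges[[chrom]])
    if (length(hits) == 0) next
    qh <- IRanges::from(hits)
    fh <- IRanges::to(hits)
    ov <- IRanges::width(IRanges::pintersect(
      qr[qh], index$ranges[[chrom]][fh]
    ))
    k <- k + 1L
    out[[k]] <- tibble(
      query_row = qi[qh],
      feature_row = index$row_idx[[chrom]][fh],
      overlap_width = ov
    )
  }
  if (k == 0L) {
    return(tibble(
      query_row = integer(), feature_row = integer(),
      overlap_width = integer()
    ))
  }
  bind_rows(out[seq_len(k)]) %>% arrange(.data$query_row, .data$feature_row)
}
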