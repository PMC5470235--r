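# Splice-junction extraction and TE-to-gene chimeric transcript calling.
#
# A chimeric transcript initiates inside a transposable element and splices
# into a downstream annotated gene: its junction's donor (the last exonic
# base 5' of the intron in gene orientation) lies inside a TE instance
# strictly upstream of the gene's first annotated exon, and its acceptor
# coincides with an annotated splice-acceptor site of the gene.

#' Extract splice junctions from spliced SAM alignments
#'
#' Walks each primary alignment's CIGAR and records one junction per `N`
#' operation (reads with k `N` ops contribute k junctions). Support is
#' aggregated per distinct (chrom, intron) and per sample; junction strand
#' is taken from the `XS:A` tag where present, else `*` (unknown). Records
#' whose CIGAR places an `N` at a read edge (no aligned block on both
#' sides) are skipped with a warning.
#'
#' @param sam_paths Character vector of SAM paths, named by `sample_id`.
#' @return A tibble with one row per (junction, sample):
#'   `chrom`, `intron_start`, `intron_end` (0-based half-open, first skipped
#'   base to end-exclusive), `strand`, `sample_id`, `n_reads`.
#' @export
extract_junctions <- function(sam_paths) {
  check_that(
    !is.null(names(sam_paths)) && all(nzchar(names(sam_paths))),
    "sam_paths must be named by sample_id"
  )
  per_sample <- purrr::imap(sam_paths, function(path, sample_id) {
    aln <- read_sam(path)
    aln <- aln %>% filter(.data$primary, !.data$unmapped)
    introns <- sam_introns(aln)
    bad <- unique(introns$aln_row[introns$edge_n])
    if (length(bad) > 0) {
      warn(sprintf(
        "%s: skipped %d record(s) with N at a read edge", sample_id,
        length(bad)
      ))
      introns <- introns %>% filter(!.data$aln_row %in% bad)
    }
    if (nrow(introns) == 0) {
      return(tibble(
        chrom = character(), intron_start = integer(),
        intron_end = integer(), strand = character(),
        sample_id = character(), n_reads = integer()
      ))
    }
    introns %>%
      mutate(
        chrom = aln$chrom[.data$aln_row],
        strand = dplyr::coalesce(aln$xs[.data$aln_row], "*")
      ) %>%
      count(.data$chrom, .data$start, .data$end, .data$strand,
        name = "n_reads"
      ) %>%
      rename(intron_start = "start", intron_end = "end") %>%
      mutate(sample_id = sample_id)
  })
  juncs <- bind_rows(per_sample)
  if (nrow(juncs) == 0) {
    return(juncs)
  }
  # resolve strand per junction: the unique observed XS strand, else '*'
  juncs %>%
    group_by(.data$chrom, .data$intron_start, .data$intron_end) %>%
    mutate(strand = {
      s <- setdiff(unique(.data$strand), "*")
      if (length(s) == 1) s else "*"
    }) %>%
    group_by(
      .data$chrom, .data$intron_start, .data$intron_end, .data$strand,
      .data$sample_id
    ) %>%
    summarise(n_reads = sum(.data$n_reads), .groups = "drop") %>%
    arrange(
      .data$chrom, .data$intron_start, .data$intron_end, .data$sample_id
    )
}

#' Call TE-to-gene chimeric transcripts from splice junctions
#'
#' A junction yields a call for a gene on its chromosome when, in gene
#' orientation: (a) the junction donor lies inside a TE instance; (b) the
#' donor is strictly upstream of the gene's first annotated exon; (c) the
#' TE's gene-proximal edge lies within `W` bp of the first exon's 5' edge
#' (distance >= 0, so the TE itself is upstream); (d) the junction acceptor
#' matches an annotated acceptor site of the gene (exactly, unless
#' `acceptor_tolerance > 0`); and (e) at least `min_samples` samples carry
#' `min_support` or more supporting reads. Per-condition activity uses the
#' same thresholds within each condition's replicates; specificity is
#' `single-condition`, `restricted` (more than one but not all) or
#' `ubiquitous`. When several TE instances contain the donor the one
#' closest to the gene wins (ties broken by instance id).
#'
#' @param junctions Junction tibble from [extract_junctions()].
#' @param genes Gene tibble from [read_gtf()].
#' @param tes TE tibble from [read_te_annotation()].
#' @param design Design tibble mapping `sample_id` to `condition`.
#' @param W Maximum TE-to-gene distance in bp (default 10000).
#' @param min_support Minimum reads per supporting sample (default 2).
#' @param min_samples Minimum supporting samples / replicates (default 1).
#' @param require_gene_strand_match If `TRUE` (default) a junction with a
#'   known strand must match the gene strand.
#' @param require_te_strand_match If `TRUE` the TE strand must match the
#'   gene strand (default `FALSE`: LTR promoters fire in both orientations).
#' @param acceptor_tolerance Allowed acceptor mismatch in bp (default 0).
#' @return A tibble of chimeric calls with donor/acceptor positions, the
#'   TE-gene distance, per-condition support (`condition_support`
#'   list-column), `active_conditions`, and `specificity`. Junctions on
#'   chromosomes absent from the annotation are ignored and counted in
#'   attribute `"skip_log"`.
#' @export
call_chimeric <- function(junctions, genes, tes, design,
                          W = 10000, min_support = 2, min_samples = 1,
                          require_gene_strand_match = TRUE,
                          require_te_strand_match = FALSE,
                          acceptor_tolerance = 0) {
  check_that(W > 0 && min_support > 0 && min_samples > 0,
             "W, min_support and min_samples must be positive")
  empty <- tibble(
    te_instance_id = character(), gene_id = character(),
    chrom = character(), gene_strand = character(),
    intron_start = integer(), intron_end = integer(),
    donor_pos = integer(), acceptor_pos = integer(),
    te_gene_distance = integer(), total_support = integer(),
    n_samples_passing = integer(), condition_support = list(),
    active_conditions = list(), n_active_conditions = integer(),
    specificity = character()
  )
  skip_log <- tibble(chrom = character(), n_junctions = integer())
  if (nrow(junctions) == 0) {
    attr(empty, "skip_log") <- skip_log
    return(empty)
  }
  known_chroms <- unique(c(genes$chrom, tes$chrom))
  uj <- junctions %>%
    distinct(.data$chrom, .data$intron_start, .data$intron_end, .data$strand)
  skipped <- uj %>% filter(!.data$chrom %in% known_chroms)
  if (nrow(skipped) > 0) {
    skip_log <- skipped %>% count(.data$chrom, name = "n_junctions")
    inform(sprintf(
      "%d junction(s) on unannotated chromosome(s) ignored", nrow(skipped)
    ))
  }
  uj <- uj %>%
    filter(.data$chrom %in% known_chroms) %>%
    mutate(junction_id = row_number())

  # acceptor lookup, expanded by tolerance
  acc <- genes %>%
    select(
      "gene_id", "chrom",
      gene_strand = "strand", "first_exon_start", "first_exon_end",
      "acceptor_sites"
    ) %>%
    tidyr::unnest_longer("acceptor_sites", values_to = "acceptor_pos")
  tol <- as.integer(acceptor_tolerance)
  if (tol > 0) {
    acc <- acc %>%
      tidyr::crossing(shift = -tol:tol) %>%
      mutate(match_pos = .data$acceptor_pos + .data$shift) %>%
      select(-"shift")
  } else {
    acc <- acc %>% mutate(match_pos = .data$acceptor_pos)
  }

  # candidate (junction, gene) pairs via the acceptor match, per orientation
  cand <- bind_rows(
    uj %>%
      mutate(match_pos = .data$intron_end) %>%
      inner_join(acc %>% filter(.data$gene_strand == "+"),
        by = c("chrom", "match_pos")
      ),
    uj %>%
      mutate(match_pos = .data$intron_start - 1L) %>%
      inner_join(acc %>% filter(.data$gene_strand == "-"),
        by = c("chrom", "match_pos")
      )
  ) %>%
    mutate(
      donor_pos = if_else(.data$gene_strand == "+",
        .data$intron_start - 1L, .data$intron_end
      ),
      upstream = if_else(.data$gene_strand == "+",
        .data$donor_pos < .data$first_exon_start,
        .data$donor_pos > .data$first_exon_end - 1L
      )
    ) %>%
    filter(.data$upstream)
  if (require_gene_strand_match) {
    cand <- cand %>%
      filter(.data$strand == "*" | .data$strand == .data$gene_strand)
  }
  if (nrow(cand) == 0) {
    attr(empty, "skip_log") <- skip_log
    return(empty)
  }

  # donor must fall inside a TE instance
  te_idx <- build_interval_index(tes)
  donor_hits <- index_overlaps(te_idx, cand %>%
    mutate(start = .data$donor_pos, end = .data$donor_pos + 1L) %>%
    select("chrom", "start", "end"))
  if (nrow(donor_hits) == 0) {
    attr(empty, "skip_log") <- skip_log
    return(empty)
  }
  cand <- cand[donor_hits$query_row, ] %>%
    mutate(
      te_instance_id = tes$instance_id[donor_hits$feature_row],
      te_start = tes$start[donor_hits$feature_row],
      te_end = tes$end[donor_hits$feature_row],
      te_strand = tes$strand[donor_hits$feature_row],
      te_gene_distance = if_else(.data$gene_strand == "+",
        .data$first_exon_start - .data$te_end,
        .data$te_start - .data$first_exon_end
      )
    ) %>%
    filter(.data$te_gene_distance >= 0, .data$te_gene_distance <= W)
  if (require_te_strand_match) {
    cand <- cand %>% filter(.data$te_strand == .data$gene_strand)
  }
  if (nrow(cand) == 0) {
    attr(empty, "skip_log") <- skip_log
    return(empty)
  }
  # one TE per (junction, gene): the gene-proximal one
  cand <- cand %>%
    group_by(.data$junction_id, .data$gene_id) %>%
    arrange(.data$te_gene_distance, .data$te_instance_id, .by_group = TRUE) %>%
    slice(1) %>%
    ungroup()

  # support and per-condition activity
  support <- junctions %>%
    inner_join(
      cand %>% select("junction_id", "chrom", "intron_start", "intron_end"),
      by = c("chrom", "intron_start", "intron_end")
    ) %>%
    left_join(design %>% select("sample_id", "condition"), by = "sample_id")
  all_conditions <- unique(design$condition)
  sup_by_junc <- support %>%
    group_by(.data$junction_id) %>%
    summarise(
      total_support = sum(.data$n_reads),
      n_samples_passing = sum(.data$n_reads >= min_support),
      .groups = "drop"
    )
  cond_tabs <- support %>%
    group_by(.data$junction_id, .data$condition) %>%
    summarise(
      support = sum(.data$n_reads),
      n_samples_passing = sum(.data$n_reads >= min_support),
      .groups = "drop"
    ) %>%
    mutate(active = .data$n_samples_passing >= min_samples) %>%
    tidyr::nest(condition_support = c(
      "condition", "support", "n_samples_passing", "active"
    ))

  calls <- cand %>%
    left_join(sup_by_junc, by = "junction_id") %>%
    left_join(cond_tabs, by = "junction_id") %>%
    filter(.data$n_samples_passing >= min_samples) %>%
    mutate(
      acceptor_pos = as.integer(.data$acceptor_pos),
      active_conditions = purrr::map(
        .data$condition_support, ~ .x$condition[.x$active]
      ),
      n_active_conditions = lengths(.data$active_conditions),
      specificity = dplyr::case_when(
        n_active_conditions == 0 ~ "none",
        n_active_conditions == length(all_conditions) ~ "ubiquitous",
        n_active_conditions == 1 ~ "single-condition",
        TRUE ~ "restricted"
      )
    ) %>%
    select(
      "te_instance_id", "gene_id", "chrom", "gene_strand",
      "intron_start", "intron_end", "donor_pos", "acceptor_pos",
      "te_gene_distance", "total_support", "n_samples_passing",
      "condition_support", "active_conditions", "n_active_conditions",
      "specificity"
    ) %>%
    arrange(.data$chrom, .data$intron_start, .data$gene_id)
  attr(calls, "skip_log") <- skip_log
  calls
}

#' Summarise condition restriction of chimeric calls
#'
#' @param calls Output of [call_chimeric()].
#' @return A list with `calls` (per-call `gene_id`, `te_instance_id`,
#'   `active_conditions`, `specificity`) and `counts` (calls per
#'   specificity class with fractions).
#' @export
condition_restriction_table <- function(calls) {
  per_call <- calls %>%
    select(
      "gene_id", "te_instance_id", "active_conditions",
      "n_active_conditions", "specificity"
    )
  counts <- calls %>%
    count(.data$specificity, name = "n_calls") %>%
    mutate(fraction = .data$n_calls / sum(.data$n_calls))
  list(calls = per_call, counts = counts)
}

#' Write junctions as a BED file (intron intervals, score = total support)
#'
#' @param junctions Tibble from [extract_junctions()].
#' @param path Output path.
#' @return `junctions`, invisibly.
#' @export
write_junction_bed <- function(junctions, path) {
  tot <- junctions %>%
    group_by(
      .data$chrom, .data$intron_start, .data$intron_end, .data$strand
    ) %>%
    summarise(score = sum(.data$n_reads), .groups = "drop") %>%
    arrange(.data$chrom, .data$intron_start)
  writeLines(sprintf(
    "%s\t%d\t%d\tjunction_%d\t%d\t%s",
    tot$chrom, tot$intron_start, tot$intron_end,
    seq_len(nrow(tot)), tot$score,
    if_else(tot$strand == "*", ".", tot$strand)
  ), path)
  invisible(junctions)
}
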