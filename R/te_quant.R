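# TE family expression quantification with an explicit multimapper policy.

#' Count reads per TE family
#'
#' Assigns each alignment to the family of the TE instance its aligned
#' blocks overlap most (largest overlap in bp). In `unique` mode only
#' primary alignments with `NH = 1` (or no NH tag) are counted, and reads
#' whose best overlap ties between two families are discarded as ambiguous
#' (and logged in attribute `"ambiguous_log"`). In `fractional` mode every
#' reported alignment record (primary and secondary) contributes `1/NH` to
#' its best-overlap family, so heavily multimapping TE reads are spread
#' across their reported locations.
#'
#' @param sam_paths Character vector of SAM paths named by `sample_id`.
#' @param tes TE tibble from [read_te_annotation()].
#' @param mode `"unique"` (default) or `"fractional"`.
#' @return A wide count tibble (`feature_id` = family, one column per
#'   sample); integer counts in unique mode, reals in fractional mode.
#'   Attribute `"feature_kind"` is `"te_family"`.
#' @export
count_te_families <- function(sam_paths, tes, mode = c("unique", "fractional")) {
  mode <- match.arg(mode)
  check_that(
    !is.null(names(sam_paths)) && all(nzchar(names(sam_paths))),
    "sam_paths must be named by sample_id"
  )
  te_idx <- build_interval_index(tes)
  families <- sort(unique(tes$family))
  ambiguous <- list()
  cols <- purrr::imap(sam_paths, function(path, sample_id) {
    aln <- read_sam(path) %>% filter(!.data$unmapped)
    if (mode == "unique") {
      aln <- aln %>%
        filter(.data$primary, is.na(.data$nh) | .data$nh == 1L)
    } else if (nrow(aln) > 0 && anyNA(aln$nh)) {
      abort(paste0(
        "SAM file ", path, " lacks NH tags; fractional mode needs them ",
        "- use mode = 'unique'"
      ))
    }
    counts <- set_names(numeric(length(families)), families)
    if (nrow(aln) == 0) {
      return(counts)
    }
    blocks <- sam_ref_blocks(aln)
    blocks$chrom <- aln$chrom[blocks$aln_row]
    hits <- index_overlaps(te_idx, blocks)
    if (nrow(hits) == 0) {
      return(counts)
    }
    per_aln_fam <- tibble(
      aln_row = blocks$aln_row[hits$query_row],
      family = tes$family[hits$feature_row],
      ov = hits$overlap_width
    ) %>%
      group_by(.data$aln_row, .data$family) %>%
      summarise(ov = sum(.data$ov), .groups = "drop_last") %>%
      mutate(
        max_ov = max(.data$ov),
        n_best = sum(.data$ov == .data$max_ov)
      ) %>%
      ungroup() %>%
      filter(.data$ov == .data$max_ov)
    amb <- per_aln_fam %>% filter(.data$n_best > 1)
    if (mode == "unique" && nrow(amb) > 0) {
      ambiguous[[sample_id]] <<- tibble(
        sample_id = sample_id,
        qname = aln$qname[unique(amb$aln_row)]
      )
    }
    assigned <- per_aln_fam %>%
      filter(.data$n_best == 1) %>%
      mutate(weight = if (mode == "unique") {
        1
      } else {
        1 / aln$nh[.data$aln_row]
      })
    tallies <- assigned %>%
      group_by(.data$family) %>%
      summarise(n = sum(.data$weight), .groups = "drop")
    counts[tallies$family] <- tallies$n
    counts
  })
  out <- as_tibble(do.call(cbind, cols), .name_repair = "minimal")
  names(out) <- names(sam_paths)
  out <- dplyr::bind_cols(tibble(feature_id = families), out)
  if (mode == "unique") {
    out <- out %>% mutate(across(-"feature_id", as.integer))
  }
  attr(out, "feature_kind") <- "te_family"
  attr(out, "ambiguous_log") <- bind_rows(ambiguous)
  out
}

#' Summarise significant TE families by class
#'
#' @param de_results Family-level differential results from
#'   [differential_te()] (one or several contrasts; a family counts as
#'   significant if it is significant in any contrast).
#' @param tes TE tibble (supplies the family-to-class map).
#' @return A tibble per TE class: `n_tested`, `n_significant`,
#'   `proportion_of_significant` (share of all significant families in the
#'   class; 0 with an `n_significant` of 0 when nothing is significant).
#' @export
class_breakdown <- function(de_results, tes) {
  fam_class <- tes %>% distinct(.data$family, .data$te_class)
  check_that(
    !anyDuplicated(fam_class$family),
    "family->class mapping is not functional"
  )
  per_family <- de_results %>%
    group_by(.data$feature_id) %>%
    summarise(significant = any(.data$significant), .groups = "drop") %>%
    left_join(fam_class, by = c(feature_id = "family")) %>%
    mutate(te_class = dplyr::coalesce(.data$te_class, "other"))
  total_sig <- sum(per_family$significant)
  per_family %>%
    group_by(.data$te_class) %>%
    summarise(
      n_tested = n(),
      n_significant = sum(.data$significant),
      .groups = "drop"
    ) %>%
    mutate(
      proportion_of_significant = if (total_sig > 0) {
        .data$n_significant / total_sig
      } else {
        0
      }
    ) %>%
    arrange(desc(.data$n_significant), .data$te_class)
}
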