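# Weighted 5-mC levels from per-CpG bisulfite reports.
#
# The weighted (read-pooled) methylation level of a set of CpGs is
# sum(methylated calls) / sum(total calls): at shallow coverage this is far
# more stable than averaging per-CpG fractions, because a CpG seen once
# contributes one read's worth of evidence, not a hard 0 or 1.

#' Read a per-CpG methylation report
#'
#' Accepts a 4-column TSV/bedGraph dialect: chrom, position (0-based),
#' methylated count, total count; with or without a commented header line.
#' Zero-coverage records are retained (they never contribute to levels).
#'
#' @param path Report path.
#' @return A tibble `chrom`, `pos`, `meth`, `total`.
#' @export
read_cpg_report <- function(path) {
  cols <- c("chrom", "pos", "meth", "total")
  records <- strip_readr_attrs(readr::read_tsv(path,
    col_names = cols, col_types = "ciii", comment = "#", progress = FALSE
  ))
  bad <- which(records$meth > records$total | records$meth < 0)
  if (length(bad) > 0) {
    abort(sprintf(
      "CpG report %s record %d: methylated count %d exceeds total %d",
      path, bad[1], records$meth[bad[1]], records$total[bad[1]]
    ))
  }
  records
}

#' Global weighted methylation level
#'
#' @param records CpG tibble from [read_cpg_report()].
#' @return Pooled `sum(meth) / sum(total)` over covered CpGs, or `NA` (with
#'   a warning) when no CpG is covered.
#' @export
global_methylation <- function(records) {
  total <- sum(as.numeric(records$total))
  if (total == 0) {
    warn("no covered CpG; global methylation level is missing")
    return(NA_real_)
  }
  sum(as.numeric(records$meth)) / total
}

#' Weighted methylation level per region
#'
#' Pools methylated and total calls over the CpGs inside each region
#' (half-open: a CpG exactly at a region end is excluded) and reports the
#' weighted level per (region set, label). Regions whose pooled depth is
#' below `min_depth` are reported with a missing level, never a silent 0.
#'
#' @param records CpG tibble from [read_cpg_report()].
#' @param region_sets Region tibble from [read_region_bed()] (may stack
#'   several sets).
#' @param min_depth Minimum summed reads per region (default 10).
#' @param sample_id Optional sample label carried into the output.
#' @return A tibble `sample_id`, `set_name`, `label`, `n_cpgs_covered`,
#'   `total_depth`, `level`.
#' @export
region_methylation <- function(records, region_sets, min_depth = 10,
                               sample_id = NA_character_) {
  idx <- build_interval_index(region_sets)
  covered <- records
  hits <- index_overlaps(
    idx, covered %>% mutate(start = .data$pos, end = .data$pos + 1L)
  )
  per_region <- tibble(
    region_row = hits$feature_row,
    meth = covered$meth[hits$query_row],
    total = covered$total[hits$query_row]
  ) %>%
    group_by(.data$region_row) %>%
    summarise(
      n_cpgs_covered = sum(.data$total > 0),
      total_depth = sum(.data$total),
      meth_depth = sum(.data$meth),
      .groups = "drop"
    )
  region_sets %>%
    mutate(region_row = row_number()) %>%
    left_join(per_region, by = "region_row") %>%
    mutate(
      sample_id = sample_id,
      n_cpgs_covered = dplyr::coalesce(.data$n_cpgs_covered, 0L),
      total_depth = dplyr::coalesce(.data$total_depth, 0L),
      level = if_else(
        .data$total_depth >= min_depth,
        .data$meth_depth / .data$total_depth,
        NA_real_
      )
    ) %>%
    select(
      "sample_id", "set_name", "label", "n_cpgs_covered", "total_depth",
      "level"
    )
}

#' Per-set methylation summary (median over region labels)
#'
#' @param region_meth Output of [region_methylation()] (possibly several
#'   samples stacked).
#' @return Tibble `sample_id`, `set_name`, `median_level`,
#'   `n_regions_covered`.
#' @export
region_set_summary <- function(region_meth) {
  region_meth %>%
    group_by(.data$sample_id, .data$set_name) %>%
    summarise(
      median_level = if (all(is.na(.data$level))) {
        NA_real_
      } else {
        median(.data$level, na.rm = TRUE)
      },
      n_regions_covered = sum(!is.na(.data$level)),
      .groups = "drop"
    )
}

#' Imprint methylation status calls
#'
#' Genomic imprints sit near 50% methylation in normal cells; the status
#' thresholds are working definitions of departure from that: `maintained`
#' within `[0.35, 0.65]`, `erased` below 0.15, `atrophied` in
#' `[0.15, 0.35)`, `hyper` above 0.65.
#'
#' @param region_meth Output of [region_methylation()] restricted to the
#'   imprint set (rows with other `set_name`s are dropped).
#' @param thresholds Named numeric: `erased` (default 0.15), `atrophied`
#'   (0.35), `hyper` (0.65).
#' @param set_name Name of the imprint region set (default `"imprints"`).
#' @return Per-(sample, imprint) tibble with `level` and `status`
#'   (`NA` level gives status `"missing"`).
#' @export
imprint_report <- function(region_meth,
                           thresholds = c(
                             erased = 0.15, atrophied = 0.35, hyper = 0.65
                           ),
                           set_name = "imprints") {
  check_that(
    all(c("erased", "atrophied", "hyper") %in% names(thresholds)),
    "thresholds must name erased, atrophied, hyper"
  )
  region_meth %>%
    filter(.data$set_name == !!set_name) %>%
    mutate(status = dplyr::case_when(
      is.na(.data$level) ~ "missing",
      .data$level < thresholds[["erased"]] ~ "erased",
      .data$level < thresholds[["atrophied"]] ~ "atrophied",
      .data$level <= thresholds[["hyper"]] ~ "maintained",
      TRUE ~ "hyper"
    ))
}
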