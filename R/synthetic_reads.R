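# Read-level and CpG-level emission for the synthetic dataset.

nb_draw <- function(n, mean, dispersion) {
  mean <- pmax(mean, 0)
  if (dispersion <= 0) {
    rpois(n, mean)
  } else {
    rnbinom(n, size = 1 / dispersion, mu = mean)
  }
}

#' Simulate a negative-binomial count matrix from an expected-mean matrix
#'
#' Count-level companion to the read-level generator: draws one NB count per
#' cell of a features-by-samples matrix of expected means, at a common
#' dispersion. Dispersion 0 gives the Poisson limit. Used directly by the
#' differential-expression calibration checks.
#'
#' @param mean_matrix Numeric matrix (features x samples) of expected
#'   counts, with dimnames.
#' @param dispersion NB dispersion (`var = mu + dispersion * mu^2`).
#' @param seed Integer seed.
#' @return A wide count tibble: `feature_id` plus one column per sample.
#' @export
simulate_count_matrix <- function(mean_matrix, dispersion, seed = 1L) {
  stopifnot(is.matrix(mean_matrix), !is.null(rownames(mean_matrix)),
            !is.null(colnames(mean_matrix)))
  counts <- with_seed(seed, {
    matrix(
      nb_draw(length(mean_matrix), as.vector(mean_matrix), dispersion),
      nrow = nrow(mean_matrix), dimnames = dimnames(mean_matrix)
    )
  })
  as_tibble(counts, rownames = "feature_id")
}

# One SAM record line (vectorized over records). pos is 0-based; emitted
# 1-based.
sam_record <- function(qname, chrom, pos, cigar, read_len, nh = 1L,
                       xs = NA_character_, secondary = FALSE) {
  n <- length(qname)
  nh <- rep_len(nh, n)
  xs <- rep_len(xs, n)
  flag <- rep_len(ifelse(secondary, 256L, 0L), n)
  tags <- paste0("NH:i:", nh)
  has_xs <- !is.na(xs)
  tags[has_xs] <- paste0(tags[has_xs], "\tXS:A:", xs[has_xs])
  paste(qname, flag, chrom, pos + 1L, 255L, cigar, "*", 0L, 0L,
    strrep("A", read_len), "*", tags,
    sep = "\t"
  )
}

sam_header_lines <- function(chrom_sizes) {
  c(
    "@HD\tVN:1.6\tSO:unsorted",
    sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_sizes), chrom_sizes)
  )
}

#' Simulate spliced RNA-seq alignments per sample
#'
#' Emits one headered SAM file per sample of the design. Gene-derived reads
#' are ungapped and placed uniformly inside exons with per-gene counts drawn
#' NB around the condition's expected mean scaled to the library size.
#' TE-derived reads fall inside instances of each family, and a configured
#' fraction of them are written as NH=2 multimappers (one primary plus one
#' secondary record at another instance of the same family). Every planted
#' chimera active in a sample's condition receives exactly
#' `chimera_read_support` junction-spanning primary reads whose `N` span
#' equals the planted intron, tagged `XS:A:` with the gene strand; decoy
#' junctions receive spliced reads in a random pair of samples.
#'
#' @param sim A `spectrum_sim` from [simulate_annotations()].
#' @param dir Output directory for `<sample_id>.sam` files.
#' @return `sim` with `$sam_paths` (named by sample) and
#'   `$realized_gene_counts` / `$realized_te_counts` (the drawn per-sample
#'   truth counts) added.
#' @export
simulate_rnaseq <- function(sim, dir) {
  stopifnot(inherits(sim, "spectrum_sim"))
  with_seed(sim$config$seed + 2L, simulate_rnaseq_impl(sim, dir))
}

simulate_rnaseq_impl <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- sim$config
  rl <- cfg$read_length
  fl <- cfg$chimera_flank
  header <- sam_header_lines(sim$chrom_sizes)
  design <- sim$design

  gene_mean_mat <- gene_means_matrix(sim$gene_means)
  te_mean_mat <- gene_means_matrix(
    sim$te_family_means %>% rename(gene_id = "family")
  )
  gene_scale <- cfg$library_size / pmax(colSums(gene_mean_mat), 1)
  te_scale <- cfg$te_library_size / pmax(colSums(te_mean_mat), 1)

  # decoy support: each decoy junction is spliced in two random samples
  decoys <- sim$decoys
  decoy_samples <- lapply(seq_len(nrow(decoys)), function(i) {
    sample(design$sample_id, min(2L, nrow(design)))
  })

  fam_instances <- split(seq_len(nrow(sim$tes)), sim$tes$family)
  exon_tbl <- sim$genes %>%
    select("gene_id", "chrom", "exons") %>%
    tidyr::unnest("exons") %>%
    mutate(len = .data$end - .data$start)
  exons_by_gene <- split(exon_tbl, exon_tbl$gene_id)

  sam_paths <- set_names(
    file.path(dir, paste0(design$sample_id, ".sam")), design$sample_id
  )
  gene_counts <- matrix(0L,
    nrow = nrow(gene_mean_mat), ncol = nrow(design),
    dimnames = list(rownames(gene_mean_mat), design$sample_id)
  )
  te_counts <- matrix(0L,
    nrow = nrow(te_mean_mat), ncol = nrow(design),
    dimnames = list(rownames(te_mean_mat), design$sample_id)
  )

  for (si in seq_len(nrow(design))) {
    sample_id <- design$sample_id[si]
    cond <- design$condition[si]
    lines <- header
    if (cfg$library_size > 0) {
      rid <- 0L
      # gene reads
      gmeans <- gene_mean_mat[, cond] * gene_scale[cond]
      gcount <- nb_draw(length(gmeans), gmeans, cfg$nb_dispersion)
      gene_counts[, si] <- gcount
      for (gi in seq_along(gcount)) {
        k <- gcount[gi]
        if (k == 0) next
        ex <- exons_by_gene[[rownames(gene_mean_mat)[gi]]]
        pick <- sample.int(nrow(ex), k, replace = TRUE, prob = ex$len)
        offs <- floor(runif(k) * (ex$len[pick] - rl + 1L))
        pos <- ex$start[pick] + as.integer(offs)
        lines <- c(lines, sam_record(
          sprintf("%s_g%06d", sample_id, rid + seq_len(k)),
          ex$chrom[pick], pos, paste0(rl, "M"), rl
        ))
        rid <- rid + k
      }
      # TE reads
      tmeans <- te_mean_mat[, cond] * te_scale[cond]
      tcount <- nb_draw(length(tmeans), tmeans, cfg$nb_dispersion)
      te_counts[, si] <- tcount
      for (fi in seq_along(tcount)) {
        k <- tcount[fi]
        if (k == 0) next
        fam <- rownames(te_mean_mat)[fi]
        inst <- fam_instances[[fam]]
        if (is.null(inst)) next
        pick <- inst[sample.int(length(inst), k, replace = TRUE)]
        ilen <- sim$tes$end[pick] - sim$tes$start[pick]
        offs <- floor(runif(k) * pmax(ilen - rl + 1L, 1L))
        pos <- sim$tes$start[pick] + as.integer(offs)
        multi <- runif(k) < cfg$multimap_fraction & length(inst) >= 2L
        qn <- sprintf("%s_t%06d", sample_id, rid + seq_len(k))
        lines <- c(lines, sam_record(
          qn, sim$tes$chrom[pick], pos, paste0(rl, "M"), rl,
          nh = ifelse(multi, 2L, 1L)
        ))
        if (any(multi)) {
          for (j in which(multi)) {
            alt <- inst[inst != pick[j]]
            alt <- alt[sample.int(length(alt), 1L)]
            alt_len <- sim$tes$end[alt] - sim$tes$start[alt]
            apos <- sim$tes$start[alt] +
              as.integer(floor(runif(1) * max(alt_len - rl + 1L, 1L)))
            lines <- c(lines, sam_record(
              qn[j], sim$tes$chrom[alt], apos, paste0(rl, "M"), rl,
              nh = 2L, secondary = TRUE
            ))
          }
        }
        rid <- rid + k
      }
      # decoy junction reads
      for (di in seq_len(nrow(decoys))) {
        if (!sample_id %in% decoy_samples[[di]]) next
        n <- sample(2:4, 1)
        ilen <- decoys$intron_end[di] - decoys$intron_start[di]
        lines <- c(lines, sam_record(
          sprintf("%s_d%s_%d", sample_id, decoys$decoy_id[di], seq_len(n)),
          decoys$chrom[di], decoys$intron_start[di] - fl,
          sprintf("%dM%dN%dM", fl, ilen, fl), 2L * fl,
          xs = decoys$strand[di]
        ))
      }
      # chimeric junction reads
      for (ci in seq_len(nrow(sim$chimeras))) {
        ch <- sim$chimeras[ci, ]
        if (!cond %in% ch$active_conditions[[1]]) next
        ilen <- ch$intron_end - ch$intron_start
        lines <- c(lines, sam_record(
          sprintf(
            "%s_c%s_%d", sample_id, ch$chimera_id,
            seq_len(cfg$chimera_read_support)
          ),
          ch$chrom, ch$intron_start - fl,
          sprintf("%dM%dN%dM", fl, ilen, fl), 2L * fl,
          xs = ch$gene_strand
        ))
      }
    }
    writeLines(lines, sam_paths[si])
  }
  sim$sam_paths <- sam_paths
  sim$realized_gene_counts <- as_tibble(gene_counts, rownames = "gene_id")
  sim$realized_te_counts <- as_tibble(te_counts, rownames = "family")
  sim$files$sam <- unname(sam_paths)
  sim
}

gene_means_matrix <- function(means_long) {
  wide <- means_long %>%
    select("gene_id", "condition", "mean") %>%
    tidyr::pivot_wider(names_from = "condition", values_from = "mean") %>%
    arrange(.data$gene_id)
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$gene_id
  m
}

#' Simulate shallow whole-genome bisulfite CpG reports
#'
#' Enumerates CpG positions from the simulated genome sequence, then per
#' sample draws each CpG's read depth as Poisson(`cpg_coverage_mean`) and
#' its methylated count as Binomial(depth, level), where the level is the
#' condition's imprint level inside imprint regions and its global level
#' elsewhere. Writes one 4-column report per sample
#' (`chrom`, 0-based position, methylated count, total count), retaining
#' zero-coverage rows.
#'
#' @param sim A `spectrum_sim` from [simulate_annotations()].
#' @param dir Output directory for `<sample_id>.cpg.tsv` files.
#' @return `sim` with `$cpg_paths` added.
#' @export
simulate_wgbs <- function(sim, dir) {
  stopifnot(inherits(sim, "spectrum_sim"))
  with_seed(sim$config$seed + 3L, simulate_wgbs_impl(sim, dir))
}

simulate_wgbs_impl <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- sim$config
  cpgs <- purrr::map2(
    names(sim$genome), as.list(sim$genome),
    function(ch, seq) {
      pos <- Biostrings::start(Biostrings::matchPattern("CG", seq)) - 1L
      tibble(chrom = ch, pos = pos)
    }
  ) %>% bind_rows()
  imprint_regions <- sim$regions %>% filter(.data$set_name == "imprints")
  in_imprint <- rep(FALSE, nrow(cpgs))
  if (nrow(imprint_regions) > 0) {
    idx <- build_interval_index(imprint_regions)
    hits <- index_overlaps(
      idx, cpgs %>% mutate(start = .data$pos, end = .data$pos + 1L)
    )
    in_imprint[unique(hits$query_row)] <- TRUE
  }
  design <- sim$design
  cpg_paths <- set_names(
    file.path(dir, paste0(design$sample_id, ".cpg.tsv")), design$sample_id
  )
  for (si in seq_len(nrow(design))) {
    cond <- design$condition[si]
    level <- ifelse(
      in_imprint, cfg$imprint_levels[cond], cfg$methylation_levels[cond]
    )
    total <- rpois(nrow(cpgs), cfg$cpg_coverage_mean)
    meth <- rbinom(nrow(cpgs), total, level)
    data.table::fwrite(
      data.table::data.table(
        chrom = cpgs$chrom, pos = cpgs$pos, meth = meth, total = total
      ),
      cpg_paths[si],
      sep = "\t", col.names = FALSE
    )
  }
  sim$cpg_paths <- cpg_paths
  sim$files$cpg <- unname(cpg_paths)
  sim
}

#' Generate the complete synthetic dataset on disk
#'
#' Runs [simulate_annotations()], [simulate_rnaseq()] and [simulate_wgbs()]
#' under one seed and writes the planted-truth tables
#' (`truth_chimeras.tsv`, `truth_gene_means.tsv`, `truth_te_family_means.tsv`,
#' `truth_methylation.tsv`, `truth_spectrum_order.tsv`) alongside the data.
#'
#' @param config A [simulation_config()].
#' @param dir Output directory.
#' @return The `spectrum_sim` object with all file paths in `$files`.
#' @export
simulate_dataset <- function(config, dir) {
  sim <- simulate_annotations(config, dir = dir)
  sim <- simulate_rnaseq(sim, dir = file.path(dir, "sam"))
  sim <- simulate_wgbs(sim, dir = file.path(dir, "cpg"))
  truth_dir <- file.path(dir, "truth")
  dir.create(truth_dir, showWarnings = FALSE, recursive = TRUE)
  write_spectrum_tsv(
    sim$chimeras, file.path(truth_dir, "truth_chimeras.tsv")
  )
  write_spectrum_tsv(
    sim$gene_means, file.path(truth_dir, "truth_gene_means.tsv")
  )
  write_spectrum_tsv(
    sim$te_family_means, file.path(truth_dir, "truth_te_family_means.tsv")
  )
  write_spectrum_tsv(
    tibble(
      condition = config$conditions,
      global_level = unname(config$methylation_levels),
      imprint_level = unname(config$imprint_levels)
    ),
    file.path(truth_dir, "truth_methylation.tsv")
  )
  write_spectrum_tsv(
    tibble(
      rank = seq_along(config$conditions), condition = config$conditions
    ),
    file.path(truth_dir, "truth_spectrum_order.tsv")
  )
  sim$files$truth_dir <- truth_dir
  sim
}
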