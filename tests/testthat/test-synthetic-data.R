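tiny_config <- function(...) {
  args <- list(
    genome_size = 1.2e5, n_chroms = 1, n_genes = 2, n_te_instances = 2,
    n_planted_chimeras = 1, n_adversarial_chimeras = 0,
    n_decoy_junctions = 2, n_driver_genes = 1, n_planted_de_genes = 1,
    library_size = 300, te_library_size = 100, n_imprints = 2,
    n_enhancers = 2, cpg_coverage_mean = 2, seed = 71
  )
  do.call(simulation_config, utils::modifyList(args, list(...)))
}

test_that("the same seed reproduces byte-identical datasets", {
  d1 <- file.path(tempdir(), "det1")
  d2 <- file.path(tempdir(), "det2")
  sim1 <- simulate_dataset(small_sim_config(seed = 77), d1)
  sim2 <- simulate_dataset(small_sim_config(seed = 77), d2)
  files1 <- sort(list.files(d1, recursive = TRUE))
  expect_equal(files1, sort(list.files(d2, recursive = TRUE)))
  for (f in files1) {
    expect_equal(
      tools::md5sum(file.path(d1, f))[[1]],
      tools::md5sum(file.path(d2, f))[[1]],
      info = f
    )
  }
  # a different seed produces different reads
  d3 <- file.path(tempdir(), "det3")
  simulate_dataset(small_sim_config(seed = 78), d3)
  sam1 <- file.path(d1, "sam", paste0(sim1$design$sample_id[1], ".sam"))
  sam3 <- file.path(d3, "sam", paste0(sim1$design$sample_id[1], ".sam"))
  expect_false(tools::md5sum(sam1)[[1]] == tools::md5sum(sam3)[[1]])
})

test_that("planted chimeras satisfy the caller geometry by construction", {
  sim <- shared_sim()
  te_idx <- build_interval_index(sim$tes)
  for (i in seq_len(nrow(sim$chimeras))) {
    ch <- sim$chimeras[i, ]
    gene <- sim$genes[sim$genes$gene_id == ch$gene_id, ]
    # donor inside its TE
    hit <- query_overlaps(te_idx, ch$chrom, ch$donor_pos, ch$donor_pos + 1)
    expect_true(ch$te_instance_id %in% hit$instance_id)
    # acceptor is an annotated acceptor site
    expect_true(ch$acceptor_pos %in% gene$acceptor_sites[[1]])
    # donor strictly upstream of the first exon
    if (gene$strand == "+") {
      expect_lt(ch$donor_pos, gene$first_exon_start)
    } else {
      expect_gt(ch$donor_pos, gene$first_exon_end - 1)
    }
    # distance inside/outside the window by role
    if (ch$adversarial) {
      expect_gt(ch$te_gene_distance, sim$config$chimera_window)
    } else {
      expect_lte(ch$te_gene_distance, sim$config$chimera_window)
    }
  }
})

test_that("over-subscribed chimera configs are rejected", {
  expect_error(
    simulation_config(
      n_genes = 5, n_planted_chimeras = 10, genome_size = 1e6
    ),
    "more chimeras than genes"
  )
  expect_error(simulation_config(nb_dispersion = -1), "nb_dispersion")
  expect_error(simulation_config(multimap_fraction = 1.5), "fractions")
})

test_that("emitted SAM records are internally consistent", {
  sim <- shared_sim()
  aln <- tespectrum:::read_sam(sim$sam_paths[[1]])
  expect_gt(nrow(aln), 0)
  # CIGAR-implied read length equals SEQ length for every record
  expect_equal(
    tespectrum:::cigar_read_length(aln$cigar), nchar(aln$seq)
  )
  # secondary records share names with primaries and carry NH=2
  secondary <- aln[!aln$primary, ]
  if (nrow(secondary) > 0) {
    expect_true(all(secondary$nh == 2L))
    expect_true(all(secondary$qname %in% aln$qname[aln$primary]))
  }
  # junction reads' N spans equal planted introns exactly, with the gene
  # strand in XS
  introns <- tespectrum:::sam_introns(aln)
  cond <- sim$design$condition[sim$design$sample_id == names(sim$sam_paths)[1]]
  active <- sim$chimeras[
    vapply(sim$chimeras$active_conditions, function(a) cond %in% a, NA),
  ]
  for (i in seq_len(nrow(active))) {
    hits <- introns[
      introns$start == active$intron_start[i] &
        introns$end == active$intron_end[i],
    ]
    expect_equal(nrow(hits), sim$config$chimera_read_support)
    expect_true(all(
      aln$xs[hits$aln_row] == active$gene_strand[i]
    ))
  }
})

test_that("a zero library size yields a headered, record-free SAM", {
  cfg <- tiny_config(library_size = 0)
  d <- file.path(tempdir(), "zero_lib")
  sim <- simulate_annotations(cfg, d)
  sim <- simulate_rnaseq(sim, file.path(d, "sam"))
  lines <- readLines(sim$sam_paths[[1]])
  expect_true(all(startsWith(lines, "@")))
  expect_true(any(startsWith(lines, "@SQ")))
})

test_that("dispersion zero gives the Poisson limit (variance equals mean)", {
  means <- matrix(50, nrow = 1000, ncol = 1,
    dimnames = list(paste0("f", 1:1000), "s1")
  )
  counts <- simulate_count_matrix(means, dispersion = 0, seed = 72)
  draws <- counts$s1
  expect_equal(var(draws) / mean(draws), 1, tolerance = 0.05)
  # positive dispersion inflates the variance accordingly
  nb <- simulate_count_matrix(means, dispersion = 0.2, seed = 73)$s1
  expect_equal(
    var(nb), mean(nb) + 0.2 * mean(nb)^2,
    tolerance = 0.15 * (50 + 0.2 * 2500)
  )
})

test_that("realized gene counts track the planted NB means", {
  sim <- shared_sim()
  mean_mat <- tespectrum:::gene_means_matrix(sim$gene_means)
  scale <- sim$config$library_size / colSums(mean_mat)
  realized <- as.matrix(sim$realized_gene_counts[, -1])
  rownames(realized) <- sim$realized_gene_counts$gene_id
  for (si in seq_len(nrow(sim$design))) {
    cond <- sim$design$condition[si]
    expected <- mean_mat[rownames(realized), cond] * scale[cond]
    keep <- expected > 5
    # summed counts concentrate around the summed expectation
    expect_equal(
      sum(realized[keep, si]), sum(expected[keep]),
      tolerance = 0.2 * sum(expected[keep])
    )
  }
})

test_that("CpG reports concentrate on the planted methylation levels", {
  sim <- shared_sim()
  cfg <- sim$config
  s1 <- sim$design$sample_id[1] # first condition: global 0.28, imprint 0.25
  records <- read_cpg_report(sim$cpg_paths[[s1]])
  imprints <- sim$regions[sim$regions$set_name == "imprints", ]
  idx <- build_interval_index(imprints)
  hits <- tespectrum:::index_overlaps(
    idx, dplyr::mutate(records, start = pos, end = pos + 1L)
  )
  in_imp <- seq_len(nrow(records)) %in% hits$query_row
  cond <- sim$design$condition[1]
  expect_lt(
    abs(global_methylation(records[!in_imp, ]) -
      cfg$methylation_levels[[cond]]), 0.02
  )
  expect_lt(
    abs(global_methylation(records[in_imp, ]) -
      cfg$imprint_levels[[cond]]), 0.05 # far fewer CpGs inside imprints
  )
})

test_that("methylation level 0 yields all-zero methylated counts", {
  cfg <- tiny_config(
    methylation_levels = rep(0, 6), imprint_levels = rep(0, 6)
  )
  d <- file.path(tempdir(), "zero_meth")
  sim <- simulate_annotations(cfg, d)
  sim <- simulate_wgbs(sim, file.path(d, "cpg"))
  records <- read_cpg_report(sim$cpg_paths[[1]])
  expect_true(all(records$meth == 0))
  expect_gt(sum(records$total), 0)
})
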