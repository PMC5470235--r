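test_that("the chimeric rule fires on the canonical plus-strand geometry", {
  design <- toy_design() # cond1, cond2 x 2 reps
  j <- toy_junctions(
    "chr1", 3350, 6000,
    strand = "+",
    samples = design$sample_id[1], n_reads = 5
  )
  calls <- call_chimeric(j, toy_genes(), toy_tes(), design, W = 10000)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$gene_id, "gP")
  expect_equal(calls$te_instance_id, "MT2_Mm.1")
  expect_equal(calls$donor_pos, 3349L)
  expect_equal(calls$acceptor_pos, 6000L)
  expect_equal(calls$te_gene_distance, 1600L)
  expect_equal(calls$total_support, 5L)
})

test_that("each rule clause can veto a call", {
  design <- toy_design()
  ok <- toy_junctions("chr1", 3350, 6000, "+", design$sample_id[1], 5)

  # donor inside the first exon, not in a TE
  inside <- toy_junctions("chr1", 5101, 6000, "+", design$sample_id[1], 5)
  expect_equal(
    nrow(call_chimeric(inside, toy_genes(), toy_tes(), design)), 0L
  )
  # window too small: distance 1600 > W = 1000
  expect_equal(
    nrow(call_chimeric(ok, toy_genes(), toy_tes(), design, W = 1000)), 0L
  )
  # acceptor not an annotated acceptor site
  off <- toy_junctions("chr1", 3350, 6001, "+", design$sample_id[1], 5)
  expect_equal(nrow(call_chimeric(off, toy_genes(), toy_tes(), design)), 0L)
  # support below min_support
  weak <- toy_junctions("chr1", 3350, 6000, "+", design$sample_id[1], 1)
  expect_equal(nrow(call_chimeric(weak, toy_genes(), toy_tes(), design)), 0L)
  # junction strand conflicts with the gene strand
  anti <- toy_junctions("chr1", 3350, 6000, "-", design$sample_id[1], 5)
  expect_equal(nrow(call_chimeric(anti, toy_genes(), toy_tes(), design)), 0L)
  expect_equal(nrow(call_chimeric(anti, toy_genes(), toy_tes(), design,
    require_gene_strand_match = FALSE
  )), 1L)
  # unknown strand passes the strand gate
  unk <- toy_junctions("chr1", 3350, 6000, "*", design$sample_id[1], 5)
  expect_equal(nrow(call_chimeric(unk, toy_genes(), toy_tes(), design)), 1L)
})

test_that("minus-strand genes use the mirrored donor/acceptor geometry", {
  design <- toy_design()
  # gM: first exon [25000,25200), acceptor 23999, TE [26000,26500)
  j <- toy_junctions("chr1", 24000, 26020, "-", design$sample_id[1], 4)
  calls <- call_chimeric(j, toy_genes(), toy_tes(), design)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$gene_id, "gM")
  expect_equal(calls$donor_pos, 26020L)
  expect_equal(calls$acceptor_pos, 23999L)
  expect_equal(calls$te_gene_distance, 800L)
})

test_that("mirroring annotations and junctions mirrors the call set", {
  design <- toy_design()
  L <- 30000L
  j <- dplyr::bind_rows(
    toy_junctions("chr1", 3350, 6000, "+", design$sample_id[1], 5),
    toy_junctions("chr1", 24000, 26020, "-", design$sample_id[2], 4)
  )
  fwd <- call_chimeric(j, toy_genes(), toy_tes(), design)
  mir <- call_chimeric(
    mirror_junctions(j, L), mirror_genes(toy_genes(), L),
    mirror_tes(toy_tes(), L), design
  )
  expect_equal(nrow(mir), nrow(fwd))
  fwd_o <- fwd[order(fwd$gene_id), ]
  mir_o <- mir[order(mir$gene_id), ]
  expect_equal(mir_o$gene_id, fwd_o$gene_id)
  expect_equal(mir_o$donor_pos, L - 1L - fwd_o$donor_pos)
  expect_equal(mir_o$acceptor_pos, L - 1L - fwd_o$acceptor_pos)
  expect_equal(mir_o$te_gene_distance, fwd_o$te_gene_distance)
  expect_equal(mir_o$total_support, fwd_o$total_support)
})

test_that("raising min_support never adds calls (monotonicity)", {
  design <- toy_design(n_conditions = 3, reps = 2)
  set.seed(31)
  j <- dplyr::bind_rows(lapply(design$sample_id, function(s) {
    toy_junctions("chr1", 3350, 6000, "+", s, sample(0:6, 1))
  }))
  j <- j[j$n_reads > 0, ]
  key <- function(calls) {
    paste(calls$gene_id, calls$intron_start, calls$intron_end)
  }
  prev <- NULL
  for (ms in 1:6) {
    calls <- call_chimeric(j, toy_genes(), toy_tes(), design,
      min_support = ms
    )
    if (!is.null(prev)) expect_true(all(key(calls) %in% prev))
    prev <- key(calls)
  }
})

test_that("per-condition activity drives specificity classes", {
  design <- toy_design(n_conditions = 4, reps = 2)
  sample_of <- function(cond, rep) {
    design$sample_id[design$condition == cond][rep]
  }
  mk <- function(active_conds) {
    dplyr::bind_rows(lapply(active_conds, function(cn) {
      toy_junctions("chr1", 3350, 6000, "+", sample_of(cn, 1), 5)
    }))
  }
  one <- call_chimeric(mk("cond1"), toy_genes(), toy_tes(), design)
  expect_equal(one$specificity, "single-condition")
  two <- call_chimeric(
    mk(c("cond1", "cond3")), toy_genes(), toy_tes(), design
  )
  expect_equal(two$specificity, "restricted")
  all4 <- call_chimeric(
    mk(paste0("cond", 1:4)), toy_genes(), toy_tes(), design
  )
  expect_equal(all4$specificity, "ubiquitous")
  expect_equal(sort(all4$active_conditions[[1]]), paste0("cond", 1:4))

  summary <- condition_restriction_table(all4)
  expect_equal(summary$counts$n_calls, 1L)
  expect_equal(summary$counts$specificity, "ubiquitous")
})

test_that("junctions on unannotated chromosomes are ignored and logged", {
  design <- toy_design()
  j <- dplyr::bind_rows(
    toy_junctions("chr1", 3350, 6000, "+", design$sample_id[1], 5),
    toy_junctions("chrUn", 100, 500, "+", design$sample_id[1], 5)
  )
  expect_message(
    calls <- call_chimeric(j, toy_genes(), toy_tes(), design),
    "unannotated"
  )
  expect_equal(nrow(calls), 1L)
  expect_equal(attr(calls, "skip_log")$chrom, "chrUn")
})

test_that("planted chimeras are recovered exactly from the simulation", {
  sim <- shared_sim()
  junctions <- suppressWarnings(extract_junctions(sim$sam_paths))
  genes <- read_gtf(sim$files$gtf)
  tes <- read_te_annotation(sim$files$te_bed)
  calls <- call_chimeric(junctions, genes, tes, sim$design)
  key <- function(x) {
    paste(x$chrom, x$intron_start, x$intron_end, x$gene_id, sep = ":")
  }
  planted <- key(sim$chimeras[!sim$chimeras$adversarial, ])
  adversarial <- key(sim$chimeras[sim$chimeras$adversarial, ])
  called <- key(calls)
  expect_setequal(called, planted) # sensitivity and precision both 1
  expect_length(intersect(called, adversarial), 0)
  # per-condition activity matches the planted activity patterns
  truth_active <- sim$chimeras[!sim$chimeras$adversarial, ]
  m <- match(key(truth_active), called)
  for (i in seq_along(m)) {
    expect_setequal(
      calls$active_conditions[[m[i]]],
      truth_active$active_conditions[[i]]
    )
  }
})
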