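# Shared fixtures built in code. The small simulation is generated once
# per test run and reused across files.

small_sim_config <- function(seed = 11) {
  simulation_config(
    genome_size = 6e5, n_genes = 30, n_te_instances = 40,
    n_planted_chimeras = 8, n_adversarial_chimeras = 2,
    n_decoy_junctions = 60, n_driver_genes = 10, n_planted_de_genes = 8,
    library_size = 4000, te_library_size = 1000, cpg_coverage_mean = 2,
    seed = seed
  )
}

shared_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      dir <- file.path(tempdir(), "tespectrum_shared_sim")
      cache <<- simulate_dataset(small_sim_config(), dir)
    }
    cache
  }
})

# a hand-built two-gene annotation used by the chimera rule tests:
# gene gP on + with first exon [5000,5200) and acceptor 6000,
# gene gM on - with first exon [25000,25200) and acceptor 23999
toy_genes <- function() {
  tibble::tibble(
    gene_id = c("gP", "gM"),
    chrom = "chr1",
    strand = c("+", "-"),
    biotype = "coding",
    n_exons = 2L,
    exons = list(
      tibble::tibble(start = c(5000L, 6000L), end = c(5200L, 6300L)),
      tibble::tibble(start = c(23800L, 25000L), end = c(24000L, 25200L))
    ),
    first_exon_start = c(5000L, 25000L),
    first_exon_end = c(5200L, 25200L),
    tss = c(5000L, 25199L),
    acceptor_sites = list(6000L, 23999L)
  )
}

toy_tes <- function() {
  tibble::tibble(
    instance_id = c("MT2_Mm.1", "MERVL-int.1"),
    family = c("MT2_Mm", "MERVL-int"),
    te_class = "LTR",
    chrom = "chr1",
    start = c(3000L, 26000L),
    end = c(3400L, 26500L),
    strand = c("+", "-")
  )
}

toy_design <- function(n_conditions = 2, reps = 2) {
  conds <- paste0("cond", seq_len(n_conditions))
  tibble::tibble(
    sample_id = paste0(
      rep(conds, each = reps), "_r", rep(seq_len(reps), n_conditions)
    ),
    condition = rep(conds, each = reps),
    background = "129",
    replicate = rep(seq_len(reps), n_conditions)
  )
}

# junction support table in the extract_junctions shape
toy_junctions <- function(chrom, intron_start, intron_end, strand = "+",
                          samples, n_reads) {
  tibble::tibble(
    chrom = chrom, intron_start = as.integer(intron_start),
    intron_end = as.integer(intron_end), strand = strand,
    sample_id = samples, n_reads = as.integer(n_reads)
  )
}

# count matrix with a planted 6-condition expression gradient carried by a
# driver gene set (the PCA spectrum fixture)
planted_gradient_counts <- function(seed, n_genes = 400, n_driver = 40,
                                    reps = 2) {
  set.seed(seed)
  conds <- paste0("state", 1:6)
  g <- seq(0, 1, length.out = 6)
  base <- exp(runif(n_genes, log(50), log(300)))
  driver <- seq_len(n_driver)
  sgn <- rep_len(c(1, -1), n_driver)
  means <- sapply(seq_along(conds), function(ci) {
    mu <- base
    mu[driver] <- base[driver] * 2^(sgn * 3 * (g[ci] - 0.5))
    mu
  })
  means <- means[, rep(seq_along(conds), each = reps)]
  dimnames(means) <- list(
    paste0("f", seq_len(n_genes)),
    paste0("s", seq_len(6 * reps))
  )
  design <- tibble::tibble(
    sample_id = colnames(means),
    condition = rep(conds, each = reps)
  )
  counts <- simulate_count_matrix(means, dispersion = 0.05, seed = seed + 1)
  list(
    counts = counts, design = design, conds = conds,
    drivers = paste0("f", driver)
  )
}

# mirror a coordinate system of total length L: position x -> L - 1 - x,
# intervals [s,e) -> [L - e, L - s), strands flipped
mirror_genes <- function(genes, L) {
  flip <- function(s, e) list(start = L - e, end = L - s)
  out <- genes
  out$strand <- ifelse(genes$strand == "+", "-", "+")
  out$exons <- lapply(genes$exons, function(ex) {
    f <- flip(ex$start, ex$end)
    tibble::tibble(start = rev(f$start), end = rev(f$end))
  })
  fe <- flip(genes$first_exon_start, genes$first_exon_end)
  out$first_exon_start <- fe$start
  out$first_exon_end <- fe$end
  out$tss <- L - 1L - genes$tss
  out$acceptor_sites <- lapply(genes$acceptor_sites, function(a) L - 1L - a)
  out
}

mirror_tes <- function(tes, L) {
  out <- tes
  out$start <- L - tes$end
  out$end <- L - tes$start
  out$strand <- ifelse(tes$strand == "+", "-", "+")
  out
}

mirror_junctions <- function(junctions, L) {
  out <- junctions
  out$intron_start <- L - junctions$intron_end
  out$intron_end <- L - junctions$intron_start
  out$strand <- ifelse(junctions$strand == "+", "-",
    ifelse(junctions$strand == "-", "+", junctions$strand)
  )
  out
}
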