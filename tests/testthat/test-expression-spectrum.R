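test_that("gene counting uses exon overlap with the ambiguity rule", {
  genes <- toy_genes()
  sam <- tempfile(fileext = ".sam")
  write_test_sam(sam, data.frame(
    chrom = "chr1",
    pos = c(rep(5050L, 10), 23850L),
    cigar = "50M"
  ), c(chr1 = 30000L))
  counts <- count_genes(c(s1 = sam), genes)
  expect_equal(counts$s1[counts$feature_id == "gP"], 10L)
  expect_equal(counts$s1[counts$feature_id == "gM"], 1L)

  # a gene pair sharing exon space: the straddling read counts to neither
  overlapping <- dplyr::mutate(genes,
    gene_id = c("gX", "gY"), chrom = "chr1"
  )
  overlapping$exons[[2]] <- tibble::tibble(start = 5100L, end = 5400L)
  sam2 <- tempfile(fileext = ".sam")
  write_test_sam(sam2, data.frame(
    chrom = "chr1", pos = 5120L, cigar = "50M"
  ), c(chr1 = 30000L))
  counts2 <- count_genes(c(s1 = sam2), overlapping)
  expect_true(all(counts2$s1 == 0L))
})

test_that("gene counts equal a brute-force per-read scan on the simulation", {
  sim <- shared_sim()
  genes <- read_gtf(sim$files$gtf)
  s1 <- sim$sam_paths[1]
  got <- count_genes(s1, genes)
  # oracle: per primary NH=1 read, overlap blocks against every exon
  lines <- readLines(s1[[1]])
  lines <- lines[!startsWith(lines, "@")]
  want <- stats::setNames(integer(nrow(genes)), sort(genes$gene_id))
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    flag <- as.integer(f[2])
    if (bitwAnd(flag, 4L) != 0 || bitwAnd(flag, 256L) != 0) next
    nh_m <- regmatches(ln, regexpr("NH:i:[0-9]+", ln))
    if (length(nh_m) && as.integer(sub("NH:i:", "", nh_m)) != 1) next
    walk <- oracle_cigar_walk(as.integer(f[4]) - 1L, f[6])
    touched <- character()
    for (gi in seq_len(nrow(genes))) {
      if (genes$chrom[gi] != f[3]) next
      ex <- genes$exons[[gi]]
      for (b in walk$blocks) {
        if (any(ex$start < b[2] & ex$end > b[1])) {
          touched <- c(touched, genes$gene_id[gi])
          break
        }
      }
    }
    if (length(unique(touched)) == 1) {
      want[touched[1]] <- want[touched[1]] + 1L
    }
  }
  expect_equal(stats::setNames(got[[2]], got$feature_id), want)
})

test_that("correlation clustering separates planted condition blocks", {
  set.seed(81)
  base <- exp(runif(300, log(50), log(400)))
  shift <- rep(c(1, 6), each = 150)
  mk <- function(block_up) {
    mu <- base * ifelse(shift == block_up, 6, 1)
    rnbinom(300, size = 20, mu = mu)
  }
  m <- cbind(mk(1), mk(1), mk(1), mk(6), mk(6), mk(6))
  dimnames(m) <- list(paste0("f", 1:300), paste0("s", 1:6))
  cc <- correlation_clusters(tibble::as_tibble(m, rownames = "feature_id"),
    k_var_genes = 300
  )
  r <- as.matrix(cc$correlation[, -1])
  # the dendrogram's root split separates the two blocks
  split2 <- stats::cutree(cc$hclust, k = 2)
  expect_equal(length(unique(split2[c("s1", "s2", "s3")])), 1L)
  expect_equal(length(unique(split2[c("s4", "s5", "s6")])), 1L)
  expect_false(split2[["s1"]] == split2[["s4"]])
  # duplicated samples correlate at exactly 1
  dup <- cbind(m, s7 = m[, "s1"])
  cc2 <- correlation_clusters(
    tibble::as_tibble(dup, rownames = "feature_id"),
    k_var_genes = 300
  )
  r2 <- as.matrix(cc2$correlation[, -1])
  rownames(r2) <- cc2$correlation$sample_id
  expect_equal(r2["s1", "s7"], 1)

  # zero-variance sample is refused by name
  flat <- m
  flat[, 2] <- 7L
  expect_error(
    correlation_clusters(tibble::as_tibble(flat, rownames = "feature_id")),
    "s2"
  )
})

test_that("anti-correlated samples show non-positive correlation", {
  up <- seq(1, 300)
  m <- cbind(
    s1 = as.integer(10 + up), s2 = as.integer(10 + rev(up)),
    s3 = as.integer(10 + up)
  )
  rownames(m) <- paste0("f", 1:300)
  cc <- correlation_clusters(tibble::as_tibble(m, rownames = "feature_id"),
    k_var_genes = 300
  )
  r <- as.matrix(cc$correlation[, -1])
  rownames(r) <- cc$correlation$sample_id
  expect_lte(r["s1", "s2"], 0)
})

test_that("PCA recovers a planted condition gradient and its driver genes", {
  fx <- planted_gradient_counts(82)
  pca <- pca_spectrum(fx$counts, fx$design,
    k_var_genes = 400, reference_condition = "state1"
  )
  expect_equal(pca$order$condition, fx$conds) # Spearman 1 with the truth
  expect_equal(
    cor(pca$order$rank, match(pca$order$condition, fx$conds),
      method = "spearman"
    ), 1
  )
  # reference condition anchored negative
  expect_lt(
    mean(pca$scores$PC1[pca$scores$condition == "state1"]), 0
  )
  top <- top_loadings(pca, "PC1", 20)
  expect_gte(mean(top$feature_id %in% fx$drivers), 0.9)
  # SVD reconstruction of the centered matrix
  recon <- as.matrix(pca$scores[, -(1:2)]) %*% t(as.matrix(pca$loadings[, -1]))
  expect_lt(max(abs(recon - pca$centered)), 1e-8)
  # loadings are unit norm; explained variance non-increasing, sums <= 1
  norms <- colSums(as.matrix(pca$loadings[, -1])^2)
  expect_equal(unname(norms), rep(1, length(norms)), tolerance = 1e-10)
  ev <- pca$explained_variance$fraction
  expect_true(all(diff(ev) <= 1e-12))
  expect_lte(sum(ev), 1 + 1e-12)
})

test_that("PCA is invariant to sample order under the sign convention", {
  fx <- planted_gradient_counts(83)
  pca1 <- pca_spectrum(fx$counts, fx$design,
    k_var_genes = 400, reference_condition = "state1"
  )
  perm <- sample(seq_len(nrow(fx$design)))
  counts_p <- fx$counts[, c(1, perm + 1)]
  pca2 <- pca_spectrum(counts_p, fx$design[perm, ],
    k_var_genes = 400, reference_condition = "state1"
  )
  expect_equal(pca1$order$condition, pca2$order$condition)
  s1 <- pca1$scores[order(pca1$scores$sample_id), ]
  s2 <- pca2$scores[order(pca2$scores$sample_id), ]
  expect_equal(s1$PC1, s2$PC1, tolerance = 1e-8)
})

test_that("constant counts give an all-zero PCA", {
  m <- matrix(25L, nrow = 50, ncol = 4,
    dimnames = list(paste0("f", 1:50), paste0("s", 1:4))
  )
  design <- tibble::tibble(
    sample_id = paste0("s", 1:4), condition = rep(c("A", "B"), each = 2)
  )
  pca <- pca_spectrum(tibble::as_tibble(m, rownames = "feature_id"),
    design,
    k_var_genes = 50, reference_condition = "A"
  )
  expect_lt(max(abs(pca$singular_values)), 1e-8)
  expect_lt(max(abs(as.matrix(pca$scores[, -(1:2)]))), 1e-8)
})

test_that("broom-style accessors expose PCA results", {
  fx <- planted_gradient_counts(84, n_genes = 100, n_driver = 10)
  pca <- pca_spectrum(fx$counts, fx$design,
    k_var_genes = 100, reference_condition = "state1"
  )
  expect_equal(nrow(tidy(pca, "scores")), 12L)
  expect_equal(nrow(tidy(pca, "loadings")), 100L)
  expect_equal(tidy(pca, "order"), pca$order)
  g <- glance(pca)
  expect_equal(g$n_samples, 12L)
  p <- autoplot(pca)
  expect_s3_class(p, "ggplot")
})

test_that("TE-origin flags respect the half-open TE end and the window", {
  tes <- toy_tes() # MT2_Mm.1 at [3000,3400)
  gene_at <- function(tss) {
    g <- toy_genes()[1, ]
    g$tss <- as.integer(tss)
    g$strand <- "+"
    g
  }
  expect_true(classify_te_origin(gene_at(3350), tes)$te_origin)
  expect_false(classify_te_origin(gene_at(3400), tes)$te_origin)
  expect_true(
    classify_te_origin(gene_at(3450), tes, window = 100)$te_origin
  )
  expect_false(
    classify_te_origin(gene_at(3550), tes, window = 100)$te_origin
  )
  flagged <- classify_te_origin(gene_at(3350), tes)
  expect_equal(flagged$te_origin_instance, "MT2_Mm.1")
})
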