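make_counts <- function(m) {
  tibble::as_tibble(m, rownames = "feature_id")
}

test_that("median-of-ratios size factors behave under duplication and scaling", {
  set.seed(61)
  m <- matrix(rnbinom(600, size = 10, mu = 100),
    nrow = 100,
    dimnames = list(paste0("f", 1:100), paste0("s", 1:6))
  )
  m[, 2] <- m[, 1] # identical samples
  sf <- estimate_size_factors(make_counts(m))
  expect_equal(sf[["s1"]], sf[["s2"]])

  m2 <- m
  m2[, 3] <- m[, 3] * 4L
  sf2 <- estimate_size_factors(make_counts(m2))
  expect_equal(sf2[["s3"]] / sf[["s3"]], 4, tolerance = 1e-12)
})

test_that("log2 fold change is the ratio of normalized means (no pseudocount)", {
  # equal library sizes -> size factors 1; planted feature 100 vs 12.5
  m <- matrix(50L, nrow = 40, ncol = 4,
    dimnames = list(paste0("f", 1:40), paste0("s", 1:4))
  )
  m[1, ] <- c(100L, 100L, 12L, 13L)
  m[2, ] <- c(37L, 37L, 37L, 37L) # keeps libraries balanced enough
  design <- tibble::tibble(
    sample_id = paste0("s", 1:4), condition = rep(c("A", "B"), each = 2)
  )
  res <- de_pairwise(make_counts(m), design, c("A", "B"),
    size_factors = stats::setNames(rep(1, 4), paste0("s", 1:4))
  )
  expect_equal(res$log2fc[1], 3, tolerance = 1e-12)
  expect_equal(res$mean_a[1], 100)
  expect_equal(res$mean_b[1], 12.5)
})

test_that("BH adjustment is monotone in p rank and never below p", {
  set.seed(62)
  m <- matrix(rnbinom(1200, size = 10, mu = 80),
    nrow = 200,
    dimnames = list(paste0("f", 1:200), paste0("s", 1:6))
  )
  design <- tibble::tibble(
    sample_id = paste0("s", 1:6), condition = rep(c("A", "B"), each = 3)
  )
  res <- de_pairwise(make_counts(m), design, c("A", "B"))
  expect_true(all(res$padj >= res$p - 1e-12))
  o <- order(res$p)
  expect_true(all(diff(res$padj[o]) >= -1e-12))
})

test_that("type-I error is near nominal on all-null NB data", {
  # scaled-down check (5 seeds); the full 20-seed band is asserted in the
  # acceptance suite
  fracs <- vapply(1:5, function(s) {
    set.seed(s)
    n <- 1000
    mu <- exp(runif(n, log(20), log(500)))
    counts <- simulate_count_matrix(
      matrix(rep(mu, 6),
        nrow = n,
        dimnames = list(paste0("f", 1:n), paste0("s", 1:6))
      ),
      dispersion = 0.1, seed = s + 100
    )
    design <- tibble::tibble(
      sample_id = paste0("s", 1:6), condition = rep(c("A", "B"), each = 3)
    )
    res <- de_pairwise(counts, design, c("A", "B"))
    mean(res$p < 0.05)
  }, numeric(1))
  expect_gt(mean(fracs), 0.02)
  expect_lt(mean(fracs), 0.09)
})

test_that("planted 8-fold activations are recovered with no false positives", {
  set.seed(63)
  n <- 1000
  mu <- exp(runif(n, log(100), log(500)))
  mu_a <- mu
  mu_a[1:20] <- mu[1:20] * 8
  means <- cbind(
    matrix(rep(mu_a, 3), nrow = n), matrix(rep(mu, 3), nrow = n)
  )
  dimnames(means) <- list(paste0("f", 1:n), paste0("s", 1:6))
  counts <- simulate_count_matrix(means, dispersion = 0.1, seed = 64)
  design <- tibble::tibble(
    sample_id = paste0("s", 1:6), condition = rep(c("A", "B"), each = 3)
  )
  res <- de_pairwise(counts, design, c("A", "B"),
    alpha = 0.01, lfc_threshold = 2
  )
  expect_gte(mean(res$significant[1:20]), 0.95)
  expect_equal(sum(res$significant[-(1:20)]), 0L)
})

test_that("log2fc estimates are unbiased within 0.1 at n = 5 vs 5", {
  set.seed(65)
  n <- 500
  mu_b <- exp(runif(n, log(50), log(400)))
  true_lfc <- 1.5
  # balanced up/down effects leave the median-of-ratios reference
  # unshifted, isolating the estimator's own bias
  up_idx <- 1:25
  down_idx <- 26:50
  mu_a <- mu_b
  mu_a[up_idx] <- mu_b[up_idx] * 2^true_lfc
  mu_a[down_idx] <- mu_b[down_idx] * 2^-true_lfc
  means <- cbind(
    matrix(rep(mu_a, 5), nrow = n), matrix(rep(mu_b, 5), nrow = n)
  )
  dimnames(means) <- list(paste0("f", 1:n), paste0("s", 1:10))
  counts <- simulate_count_matrix(means, dispersion = 0.05, seed = 66)
  design <- tibble::tibble(
    sample_id = paste0("s", 1:10), condition = rep(c("A", "B"), each = 5)
  )
  res <- de_pairwise(counts, design, c("A", "B"))
  expect_lt(abs(mean(res$log2fc[up_idx]) - true_lfc), 0.1)
  expect_lt(abs(mean(res$log2fc[down_idx]) + true_lfc), 0.1)
  expect_lt(abs(mean(res$log2fc[-(1:50)])), 0.1)
})

test_that("duplicated replicate columns presented as two conditions yield no calls", {
  set.seed(67)
  m <- matrix(rnbinom(300, size = 20, mu = 120),
    nrow = 100, ncol = 3,
    dimnames = list(paste0("f", 1:100), paste0("a", 1:3))
  )
  m2 <- cbind(m, m)
  colnames(m2) <- paste0("s", 1:6)
  design <- tibble::tibble(
    sample_id = paste0("s", 1:6), condition = rep(c("A", "B"), each = 3)
  )
  res <- de_pairwise(make_counts(m2), design, c("A", "B"))
  expect_equal(sum(res$significant), 0L)
  expect_true(all(res$log2fc == 0))
})

test_that("single-replicate conditions fall back to a common dispersion with a warning", {
  set.seed(68)
  m <- matrix(rnbinom(200, size = 10, mu = 100),
    nrow = 100,
    dimnames = list(paste0("f", 1:100), c("s1", "s2"))
  )
  design <- tibble::tibble(
    sample_id = c("s1", "s2"), condition = c("A", "B")
  )
  expect_warning(
    res <- de_pairwise(make_counts(m), design, c("A", "B")),
    "common dispersion"
  )
  expect_true(all(is.finite(res$p)))
})

test_that("all-pairs testing reports the union of significant features", {
  set.seed(69)
  n <- 200
  mu <- rep(100, n)
  mk <- function(mult) {
    mm <- mu
    mm[1:10] <- mu[1:10] * mult
    matrix(rep(mm, 2), nrow = n)
  }
  means <- cbind(mk(1), mk(8), mk(1 / 8))
  dimnames(means) <- list(paste0("f", 1:n), paste0("s", 1:6))
  counts <- simulate_count_matrix(means, dispersion = 0.05, seed = 70)
  design <- tibble::tibble(
    sample_id = paste0("s", 1:6),
    condition = rep(c("A", "B", "C"), each = 2)
  )
  res <- differential_genes(counts, design)
  expect_equal(nrow(dplyr::distinct(
    tibble::as_tibble(res)[, c("condition_a", "condition_b")]
  )), 3L)
  expect_setequal(de_union(res), paste0("f", 1:10))
  g <- glance(res)
  expect_equal(nrow(g), 3L)
  expect_equal(g$alpha[1], 0.01)
})
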