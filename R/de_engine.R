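# Negative-binomial pairwise differential expression.
#
# The engine normalizes counts with median-of-ratios size factors, estimates
# a per-feature NB dispersion by method of moments on normalized counts,
# shrinks it 50/50 toward a trended mean-dispersion fit, and tests the
# log2 fold change between two conditions with a Wald statistic whose
# standard error comes from the NB variance function
# Var(K) = mu + dispersion * mu^2 by the delta method. The statistic is
# referenced to a t distribution with 4x the residual degrees of freedom:
# the 50/50 shrinkage quarters the dispersion estimator's sampling
# variance, and moment-matching the shrunk dispersion to a scaled
# chi-square yields that moderated df (a normal-reference Wald is
# anti-conservative at small n).

#' Median-of-ratios size factors
#'
#' Per-sample scaling factors computed as the median across features of the
#' ratio of a sample's count to a per-feature geometric-mean reference.
#' The reference for each sample is the geometric mean over the *other*
#' samples (leave-one-out), so that multiplying one sample's counts by `c`
#' multiplies exactly that sample's factor by `c`; features with a zero
#' anywhere are excluded from the reference. Falls back to total-count
#' ratios if no feature is everywhere-positive.
#'
#' @param counts Wide count tibble (`feature_id` + sample columns) or a
#'   numeric matrix with feature rownames.
#' @return Named numeric vector of size factors, one per sample.
#' @export
estimate_size_factors <- function(counts) {
  m <- count_matrix(counts)
  check_that(all(colSums(m) > 0), "every sample needs library size > 0")
  n_s <- ncol(m)
  if (n_s == 1) {
    return(set_names(1, colnames(m)))
  }
  lm_ <- log(m)
  ok <- apply(is.finite(lm_), 1, all)
  if (!any(ok)) {
    warn("no everywhere-positive feature; using total-count size factors")
    libs <- colSums(m)
    return(libs / exp(mean(log(libs))))
  }
  row_tot <- rowSums(lm_[ok, , drop = FALSE])
  sf <- vapply(seq_len(n_s), function(j) {
    loo_ref <- (row_tot - lm_[ok, j]) / (n_s - 1)
    exp(median(lm_[ok, j] - loo_ref))
  }, numeric(1))
  set_names(sf, colnames(m))
}

# wide tibble (feature_id + samples) -> numeric matrix
count_matrix <- function(counts) {
  if (is.matrix(counts)) {
    return(counts)
  }
  check_that(
    is.data.frame(counts) && names(counts)[1] == "feature_id",
    "counts must be a matrix or a tibble with feature_id first"
  )
  m <- as.matrix(counts[, -1, drop = FALSE])
  rownames(m) <- counts$feature_id
  check_that(all(m >= 0, na.rm = TRUE), "counts must be non-negative")
  m
}

# Trended dispersion fit: binned medians of the method-of-moments estimates
# regressed on a0 + a1/mu, coefficients clamped non-negative; falls back to
# the overall median when the fit is degenerate.
fit_dispersion_trend <- function(mu, disp) {
  ok <- is.finite(mu) & mu > 0 & is.finite(disp)
  fallback <- max(median(pmax(disp[ok], 0), na.rm = TRUE), 1e-8)
  if (sum(ok) < 10) {
    return(function(m) rep(fallback, length(m)))
  }
  bins <- cut(rank(mu[ok], ties.method = "first"),
    breaks = min(10, max(2, floor(sum(ok) / 20))), labels = FALSE
  )
  med <- tapply(pmax(disp[ok], 0), bins, median)
  mid <- tapply(mu[ok], bins, median)
  fit <- tryCatch(
    lm(med ~ I(1 / mid)),
    error = function(e) NULL
  )
  if (is.null(fit) || anyNA(coef(fit))) {
    return(function(m) rep(fallback, length(m)))
  }
  a0 <- max(coef(fit)[1], 1e-8)
  a1 <- max(coef(fit)[2], 0)
  function(m) a0 + a1 / pmax(m, 1e-8)
}

#' Pairwise NB Wald test between two conditions
#'
#' Core differential engine shared by the gene and TE-family stages. Counts
#' are normalized by [estimate_size_factors()] (optionally computed on a
#' companion count table, e.g. gene counts when testing TE families, so
#' that TE activation does not distort size factors); per-feature NB
#' dispersions are method-of-moments estimates on normalized counts pooled
#' across the two groups, shrunk 50/50 toward a trended mean-dispersion
#' fit; the Wald statistic tests `log2(mean_A / mean_B)`; p-values are
#' Benjamini-Hochberg adjusted across features within the contrast.
#'
#' @param counts Wide count tibble (`feature_id` + sample columns).
#' @param design Design tibble with `sample_id` and `condition`.
#' @param contrast Length-2 character vector `c(condition_A, condition_B)`;
#'   positive log2 fold changes mean higher in A.
#' @param alpha Adjusted-p significance threshold (default 0.01).
#' @param lfc_threshold Absolute log2-fold-change threshold (default 2).
#' @param size_factor_counts Optional wide count tibble to compute size
#'   factors from (same samples).
#' @param size_factors Optional precomputed named size factors, overriding
#'   both count tables.
#' @return A `spectrum_de` tibble: `feature_id`, `condition_a`,
#'   `condition_b`, `mean_a`, `mean_b` (normalized), `log2fc`, `dispersion`,
#'   `stat`, `p`, `padj`, `significant` (`padj < alpha` and
#'   `|log2fc| > lfc_threshold`).
#' @export
de_pairwise <- function(counts, design, contrast, alpha = 0.01,
                        lfc_threshold = 2, size_factor_counts = NULL,
                        size_factors = NULL) {
  check_that(length(contrast) == 2, "contrast must name two conditions")
  check_that(
    all(contrast %in% design$condition),
    paste0("contrast conditions missing from design: ",
           paste(setdiff(contrast, design$condition), collapse = ", "))
  )
  m <- count_matrix(counts)
  design <- design %>% filter(.data$sample_id %in% colnames(m))
  if (is.null(size_factors)) {
    sf_src <- if (is.null(size_factor_counts)) counts else size_factor_counts
    size_factors <- estimate_size_factors(sf_src)
  }
  samples_a <- design$sample_id[design$condition == contrast[1]]
  samples_b <- design$sample_id[design$condition == contrast[2]]
  check_that(
    length(samples_a) >= 1 && length(samples_b) >= 1,
    "each contrast condition needs at least one sample"
  )
  if (length(samples_a) < 2 || length(samples_b) < 2) {
    warn(paste0(
      "fewer than 2 samples in a condition; ",
      "falling back to a common dispersion"
    ))
  }
  sf_a <- size_factors[samples_a]
  sf_b <- size_factors[samples_b]
  qa <- sweep(m[, samples_a, drop = FALSE], 2, sf_a, "/")
  qb <- sweep(m[, samples_b, drop = FALSE], 2, sf_b, "/")
  na <- length(samples_a)
  nb <- length(samples_b)
  mu_a <- rowMeans(qa)
  mu_b <- rowMeans(qb)
  mu_base <- (na * mu_a + nb * mu_b) / (na + nb)

  row_var <- function(x) {
    if (ncol(x) < 2) {
      return(rep(NA_real_, nrow(x)))
    }
    rowSums((x - rowMeans(x))^2) / (ncol(x) - 1)
  }
  mom_group <- function(s2, mu, sf) {
    xi <- mean(1 / sf)
    ifelse(mu > 0, (s2 - mu * xi) / mu^2, NA_real_)
  }
  d_a <- mom_group(row_var(qa), mu_a, sf_a)
  d_b <- mom_group(row_var(qb), mu_b, sf_b)
  w_a <- max(na - 1, 0)
  w_b <- max(nb - 1, 0)
  disp_mom <- if (w_a + w_b > 0) {
    num <- w_a * dplyr::coalesce(d_a, d_b) + w_b * dplyr::coalesce(d_b, d_a)
    num / (w_a + w_b)
  } else {
    rep(NA_real_, nrow(m))
  }
  if (all(is.na(disp_mom))) {
    disp_mom <- rep(0, nrow(m))
  }
  disp_mom[is.na(disp_mom)] <- median(disp_mom, na.rm = TRUE)
  trend <- fit_dispersion_trend(mu_base, disp_mom)
  dispersion <- 0.5 * pmax(disp_mom, 0) + 0.5 * pmax(trend(mu_base), 1e-8)

  log2fc <- log2(mu_a / mu_b)
  log2fc[mu_a == 0 & mu_b == 0] <- 0
  # test-scale means: moderate exact zeros so the Wald SE is finite
  zero <- mu_a == 0 | mu_b == 0
  ma_t <- mu_a + 0.5 * zero
  mb_t <- mu_b + 0.5 * zero
  var_a <- (ma_t * sum(1 / sf_a) + na * dispersion * ma_t^2) / na^2
  var_b <- (mb_t * sum(1 / sf_b) + nb * dispersion * mb_t^2) / nb^2
  se_lfc <- sqrt(var_a / ma_t^2 + var_b / mb_t^2) / log(2)
  stat <- log2(ma_t / mb_t) / se_lfc
  stat[mu_a == 0 & mu_b == 0] <- 0
  # Moderated reference distribution: the 50/50 shrinkage quarters the
  # sampling variance of the dispersion estimate, so the squared statistic
  # behaves like t^2 with 4x the residual degrees of freedom
  # (moment-matching the shrunk dispersion to a scaled chi-square).
  df_mod <- 4 * max(na + nb - 2, 1)
  p <- 2 * stats::pt(-abs(stat), df = df_mod)
  padj <- p.adjust(p, method = "BH")
  out <- tibble(
    feature_id = rownames(m),
    condition_a = contrast[1], condition_b = contrast[2],
    mean_a = unname(mu_a), mean_b = unname(mu_b),
    log2fc = unname(log2fc), dispersion = unname(dispersion),
    stat = unname(stat), p = unname(p), padj = unname(padj),
    significant = unname(
      !is.na(padj) & padj < alpha & abs(log2fc) > lfc_threshold
    )
  )
  new_spectrum_de(out, alpha = alpha, lfc_threshold = lfc_threshold)
}

new_spectrum_de <- function(x, alpha, lfc_threshold) {
  structure(
    x,
    alpha = alpha, lfc_threshold = lfc_threshold,
    class = c("spectrum_de", class(tibble())))
}

#' Differentially active TE families for one contrast
#'
#' [de_pairwise()] applied to a TE-family count table. When a gene count
#' table is supplied, size factors are computed from it so that global TE
#' activation does not distort normalization.
#'
#' @inheritParams de_pairwise
#' @param gene_counts Optional gene-level count tibble for size factors.
#' @return A `spectrum_de` tibble (see [de_pairwise()]).
#' @export
differential_te <- function(counts, design, contrast, alpha = 0.01,
                            lfc_threshold = 2, gene_counts = NULL) {
  de_pairwise(counts, design, contrast,
    alpha = alpha, lfc_threshold = lfc_threshold,
    size_factor_counts = gene_counts
  )
}

#' Pairwise differential expression across all condition pairs
#'
#' Runs [de_pairwise()] for every unordered pair of conditions in the
#' design (or the supplied subset), BH-adjusting within each contrast, and
#' reports the union of features significant in at least one pair — the
#' "robust" differential set.
#'
#' @inheritParams de_pairwise
#' @param conditions Conditions to compare (default: all in `design`).
#' @return A `spectrum_de` tibble stacking all contrasts, with the union of
#'   significant features in attribute `"union_significant"` (also
#'   retrievable with [de_union()]).
#' @export
differential_genes <- function(counts, design, conditions = NULL,
                               alpha = 0.01, lfc_threshold = 2,
                               size_factor_counts = NULL) {
  conditions <- conditions %||% unique(design$condition)
  check_that(length(conditions) >= 2, "need at least two conditions")
  size_factors <- estimate_size_factors(
    if (is.null(size_factor_counts)) counts else size_factor_counts
  )
  pairs <- utils::combn(conditions, 2, simplify = FALSE)
  res <- purrr::map(pairs, function(pr) {
    de_pairwise(counts, design, pr,
      alpha = alpha, lfc_threshold = lfc_threshold,
      size_factors = size_factors
    )
  })
  out <- bind_rows(res)
  out <- new_spectrum_de(out, alpha = alpha, lfc_threshold = lfc_threshold)
  attr(out, "union_significant") <-
    sort(unique(out$feature_id[out$significant]))
  out
}

#' Union of significant features across contrasts
#'
#' @param de A `spectrum_de` tibble.
#' @return Character vector of features significant in at least one
#'   contrast.
#' @export
de_union <- function(de) {
  u <- attr(de, "union_significant")
  if (!is.null(u)) {
    return(u)
  }
  sort(unique(de$feature_id[de$significant]))
}

#' @export
tidy.spectrum_de <- function(x, ...) {
  as_tibble(x)
}

#' @export
glance.spectrum_de <- function(x, ...) {
  as_tibble(x) %>%
    group_by(.data$condition_a, .data$condition_b) %>%
    summarise(
      n_tested = n(),
      n_significant = sum(.data$significant),
      .groups = "drop"
    ) %>%
    mutate(
      alpha = attr(x, "alpha"),
      lfc_threshold = attr(x, "lfc_threshold")
    )
}
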