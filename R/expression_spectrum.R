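# Gene-level quantification, correlation structure, and the PCA spectrum
# ordering of conditions with its driving gene loadings.

#' Count reads per gene
#'
#' Counts primary, uniquely mapping (`NH = 1` or untagged) alignments whose
#' aligned blocks overlap the exons of exactly one gene; reads touching
#' exons of more than one gene are discarded as ambiguous.
#'
#' @param sam_paths Character vector of SAM paths named by `sample_id`.
#' @param genes Gene tibble from [read_gtf()].
#' @return A wide count tibble (`feature_id` = gene, one column per
#'   sample); attribute `"feature_kind"` is `"gene"`.
#' @export
count_genes <- function(sam_paths, genes) {
  check_that(
    !is.null(names(sam_paths)) && all(nzchar(names(sam_paths))),
    "sam_paths must be named by sample_id"
  )
  exon_tbl <- genes %>%
    select("gene_id", "chrom", "exons") %>%
    tidyr::unnest("exons")
  exon_idx <- build_interval_index(exon_tbl)
  gene_ids <- sort(unique(genes$gene_id))
  cols <- purrr::map(sam_paths, function(path) {
    aln <- read_sam(path) %>%
      filter(.data$primary, !.data$unmapped, is.na(.data$nh) | .data$nh == 1L)
    counts <- set_names(integer(length(gene_ids)), gene_ids)
    if (nrow(aln) == 0) {
      return(counts)
    }
    blocks <- sam_ref_blocks(aln)
    blocks$chrom <- aln$chrom[blocks$aln_row]
    hits <- index_overlaps(exon_idx, blocks)
    if (nrow(hits) == 0) {
      return(counts)
    }
    assign <- tibble(
      aln_row = blocks$aln_row[hits$query_row],
      gene_id = exon_tbl$gene_id[hits$feature_row]
    ) %>%
      distinct() %>%
      group_by(.data$aln_row) %>%
      filter(n() == 1) %>%
      ungroup()
    tallies <- assign %>% count(.data$gene_id)
    counts[tallies$gene_id] <- tallies$n
    counts
  })
  out <- dplyr::bind_cols(
    tibble(feature_id = gene_ids),
    as_tibble(do.call(cbind, cols), .name_repair = "minimal") %>%
      set_names(names(sam_paths))
  )
  attr(out, "feature_kind") <- "gene"
  out
}

# log2(CPM + 1) on a count matrix
log_cpm <- function(m) {
  libs <- colSums(m)
  check_that(all(libs > 0), "zero library size")
  log2(sweep(m, 2, libs, "/") * 1e6 + 1)
}

top_variable_rows <- function(lm_, k) {
  v <- apply(lm_, 1, var)
  k <- min(k, nrow(lm_))
  order(v, decreasing = TRUE)[seq_len(k)]
}

#' Sample correlation structure and hierarchical clustering
#'
#' Pearson correlation of `log2(CPM + 1)` over the top-`k` most variable
#' features, followed by average-linkage hierarchical clustering on the
#' correlation distance `1 - r`. Sample columns are processed in
#' `sample_id` order so the leaf order is deterministic.
#'
#' @param counts Wide count tibble (`feature_id` + sample columns).
#' @param k_var_genes Number of most-variable features used (default 2000,
#'   clamped to the number available).
#' @return A list of class `spectrum_correlation`: `correlation` (tibble,
#'   `sample_id` + one column per sample), `dendrogram_order` (character),
#'   and `hclust` (the [stats::hclust] object).
#' @export
correlation_clusters <- function(counts, k_var_genes = 2000) {
  m <- count_matrix(counts)
  check_that(ncol(m) >= 2, "need at least two samples")
  m <- m[, order(colnames(m)), drop = FALSE]
  lm_ <- log_cpm(m)
  sds <- apply(lm_, 2, sd)
  if (any(sds == 0)) {
    abort(paste0(
      "zero-variance sample(s): ",
      paste(colnames(m)[sds == 0], collapse = ", ")
    ))
  }
  lm_ <- lm_[top_variable_rows(lm_, k_var_genes), , drop = FALSE]
  r <- cor(lm_, method = "pearson")
  hc <- hclust(as.dist(1 - r), method = "average")
  structure(
    list(
      correlation = as_tibble(r, rownames = "sample_id"),
      dendrogram_order = colnames(r)[hc$order],
      hclust = hc
    ),
    class = "spectrum_correlation"
  )
}

#' @export
print.spectrum_correlation <- function(x, ...) {
  cat(sprintf(
    "<spectrum_correlation: %d samples; leaf order: %s>\n",
    nrow(x$correlation), paste(x$dendrogram_order, collapse = " ")
  ))
  invisible(x)
}

#' PCA spectrum ordering of conditions
#'
#' Computes the principal components of `log2(CPM + 1)` over the top-`k`
#' most variable genes (gene-centered, samples as observations, SVD). The
#' PC1 sign is fixed so that the `reference_condition` has a negative mean
#' score (the naive anchor of the spectrum), and conditions are ordered
#' along the spectrum by their mean PC1 score. Feature loadings are
#' unit-norm; explained-variance fractions are non-increasing.
#'
#' @param counts Wide count tibble (`feature_id` + sample columns).
#' @param design Design tibble with `sample_id` and `condition`.
#' @param k_var_genes Number of most-variable genes used (default 2000;
#'   clamped with a warning when fewer are available).
#' @param reference_condition Condition anchored at negative PC1.
#' @return An object of class `spectrum_pca` with `scores` (tibble:
#'   `sample_id`, `condition`, `PC1..PCn`), `loadings` (tibble:
#'   `feature_id`, `PC1..PCn`), `explained_variance` (tibble), `order`
#'   (the `SpectrumOrder` tibble: `rank`, `condition`, `mean_pc1`), and the
#'   centered input matrix dimensions. Methods: [tidy()], [glance()],
#'   [autoplot()].
#' @export
pca_spectrum <- function(counts, design, k_var_genes = 2000,
                         reference_condition) {
  m <- count_matrix(counts)
  check_that(ncol(m) >= 3, "need at least three samples for PCA")
  check_that(
    reference_condition %in% design$condition,
    paste0("reference condition not in design: ", reference_condition)
  )
  design <- design %>% filter(.data$sample_id %in% colnames(m))
  m <- m[, design$sample_id, drop = FALSE]
  lm_ <- log_cpm(m)
  if (k_var_genes > nrow(lm_)) {
    warn(sprintf(
      "k_var_genes = %d exceeds %d available genes; clamping",
      k_var_genes, nrow(lm_)
    ))
  }
  lm_ <- lm_[top_variable_rows(lm_, k_var_genes), , drop = FALSE]
  x <- t(lm_ - rowMeans(lm_)) # samples x genes, gene-centered
  sv <- svd(x)
  k <- length(sv$d)
  pcs <- paste0("PC", seq_len(k))
  scores <- sv$u %*% diag(sv$d, nrow = k)
  loadings <- sv$v
  # sign convention: reference condition sits at negative mean score
  ref_rows <- design$condition == reference_condition
  for (j in seq_len(k)) {
    flip <- if (j == 1) {
      mean(scores[ref_rows, 1]) > 0
    } else {
      # deterministic sign for the remaining components: largest-magnitude
      # loading is positive
      loadings[which.max(abs(loadings[, j])), j] < 0
    }
    if (flip) {
      scores[, j] <- -scores[, j]
      loadings[, j] <- -loadings[, j]
    }
  }
  ev <- sv$d^2 / max(sum(sv$d^2), .Machine$double.eps)
  score_tbl <- dplyr::bind_cols(
    tibble(sample_id = design$sample_id, condition = design$condition),
    as_tibble(scores, .name_repair = "minimal") %>% set_names(pcs)
  )
  loading_tbl <- dplyr::bind_cols(
    tibble(feature_id = rownames(lm_)),
    as_tibble(loadings, .name_repair = "minimal") %>% set_names(pcs)
  )
  order_tbl <- score_tbl %>%
    group_by(.data$condition) %>%
    summarise(mean_pc1 = mean(.data$PC1), .groups = "drop") %>%
    arrange(.data$mean_pc1) %>%
    mutate(rank = row_number()) %>%
    select("rank", "condition", "mean_pc1")
  structure(
    list(
      scores = score_tbl,
      loadings = loading_tbl,
      explained_variance = tibble(
        component = pcs, fraction = ev
      ),
      order = order_tbl,
      reference_condition = reference_condition,
      centered = x,
      singular_values = sv$d
    ),
    class = "spectrum_pca"
  )
}

#' @export
print.spectrum_pca <- function(x, ...) {
  cat(sprintf(
    "<spectrum_pca: %d samples, %d genes; spectrum order: %s>\n",
    nrow(x$scores), nrow(x$loadings),
    paste(x$order$condition, collapse = " -> ")
  ))
  invisible(x)
}

#' Top loading genes of a principal component
#'
#' @param pca A `spectrum_pca` object.
#' @param component Component name (default `"PC1"`).
#' @param n Number of genes (default 20).
#' @return Tibble of the `n` genes with largest `|loading|`, signed.
#' @export
top_loadings <- function(pca, component = "PC1", n = 20) {
  stopifnot(inherits(pca, "spectrum_pca"))
  pca$loadings %>%
    select("feature_id", loading = all_of(component)) %>%
    arrange(desc(abs(.data$loading))) %>%
    head(n)
}

#' @export
tidy.spectrum_pca <- function(x, matrix = c("scores", "loadings", "eigenvalues",
                                            "order"), ...) {
  matrix <- match.arg(matrix)
  switch(matrix,
    scores = x$scores,
    loadings = x$loadings,
    eigenvalues = x$explained_variance,
    order = x$order
  )
}

#' @export
glance.spectrum_pca <- function(x, ...) {
  tibble(
    n_samples = nrow(x$scores),
    n_genes = nrow(x$loadings),
    pc1_variance_fraction = x$explained_variance$fraction[1],
    reference_condition = x$reference_condition
  )
}

#' Flag features whose transcription start lies in (or just downstream of)
#' a TE
#'
#' A feature is TE-origin when its TSS (the 5' base of its first exon in
#' gene orientation) falls inside a TE instance, or within `window` bp
#' downstream of a TE's gene-proximal edge (default window 0: inside only;
#' a TSS exactly at a TE's half-open end is *not* inside).
#'
#' @param features Gene tibble from [read_gtf()] (uses `tss`, `strand`).
#' @param tes TE tibble.
#' @param window Downstream tolerance in bp (default 0).
#' @return `features` with logical column `te_origin` and, where flagged,
#'   `te_origin_instance`.
#' @export
classify_te_origin <- function(features, tes, window = 0) {
  te_idx <- build_interval_index(tes)
  tss_q <- features %>%
    mutate(start = .data$tss, end = .data$tss + 1L) %>%
    select("chrom", "start", "end")
  inside <- index_overlaps(te_idx, tss_q)
  flag <- rep(FALSE, nrow(features))
  inst <- rep(NA_character_, nrow(features))
  flag[inside$query_row] <- TRUE
  inst[inside$query_row] <- tes$instance_id[inside$feature_row]
  if (window > 0) {
    for (i in which(!flag)) {
      same_chrom <- which(tes$chrom == features$chrom[i])
      if (length(same_chrom) == 0) next
      d <- if (features$strand[i] == "+") {
        features$tss[i] - tes$end[same_chrom]
      } else {
        tes$start[same_chrom] - 1L - features$tss[i]
      }
      hit <- same_chrom[d >= 0 & d <= window]
      if (length(hit) > 0) {
        flag[i] <- TRUE
        inst[i] <- tes$instance_id[hit[which.min(d[d >= 0 & d <= window])]]
      }
    }
  }
  features %>% mutate(te_origin = flag, te_origin_instance = inst)
}
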