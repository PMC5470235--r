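# Deterministic synthetic-data generator.
#
# Builds a miniature two-chromosome genome with gene models, TE instances,
# region sets and a multi-condition design, then emits spliced SAM
# alignments and per-CpG bisulfite reports in which every downstream signal
# is planted by construction: a condition gradient in gene expression and
# TE-family activity, TE-to-gene chimeric junctions (plus beyond-window
# adversarial ones and decoy junctions), and a monotone global-methylation
# gradient with condition-specific imprint erosion. All randomness derives
# from a single seed; the same seed yields byte-identical files.

TE_FAMILY_CATALOG <- tibble::tribble(
  ~family, ~te_class,
  "MERVL-int", "LTR",
  "MT2_Mm", "LTR",
  "IAPEy-int", "LTR",
  "IAPLTR3", "LTR",
  "RLTR45", "LTR",
  "LTRIS2", "LTR",
  "RLTR12C", "LTR",
  "ETnERV2-int", "LTR",
  "RMER16", "LTR",
  "MER50B", "LTR",
  "L1Md_A", "LINE",
  "L1M6B", "LINE",
  "L1M3d", "LINE",
  "Lx2", "LINE",
  "B1_Mus1", "SINE",
  "B2_Mm2", "SINE",
  "Charlie1", "DNA",
  "Tigger1", "DNA"
)

#' Configuration for the synthetic multi-condition dataset
#'
#' Defaults model a six-state culture spectrum (2i/L, 2i/L with KSR, 2i,
#' Pd/L, Ch/L, feeder-free serum/LIF) with two replicates per condition, a
#' 2 Mb genome on two chromosomes, a monotone global 5-mC gradient that is
#' lowest in 2i/L, imprints that atrophy in 2i/L and erase in the KSR
#' condition, 30 planted TE-to-gene chimeric transcripts (plus 3 adversarial
#' ones placed beyond the caller's window and 300 decoy junctions), and
#' 8-fold planted expression effects on negative-binomial counts.
#'
#' @param conditions Ordered condition labels; the order is the planted
#'   spectrum (most naive first).
#' @param replicates_per_condition Samples per condition.
#' @param background Genetic-background label recorded in the design table.
#' @param genome_size,n_chroms Total genome length (bp) and chromosome count.
#' @param n_genes Number of gene models.
#' @param n_te_instances Number of background TE copies (planted chimera TEs
#'   come on top of these).
#' @param n_families Number of repeat families drawn from a built-in catalog
#'   of real mouse family names with their classes.
#' @param n_planted_chimeras,n_adversarial_chimeras Planted TE-to-gene
#'   chimeras inside, respectively beyond, the caller window.
#' @param n_decoy_junctions Junctions that must never be called chimeric
#'   (annotated gene introns plus random intergenic junctions).
#' @param n_driver_genes Genes whose expression follows the condition
#'   gradient (these drive PC1).
#' @param n_planted_de_genes Genes with a single-condition jump of
#'   `de_log2fc`, placed in mid-gradient conditions.
#' @param de_log2fc Planted effect size (log2).
#' @param nb_dispersion Negative-binomial dispersion; `0` gives the Poisson
#'   limit.
#' @param library_size Gene-derived reads per sample (0 gives a header-only
#'   SAM).
#' @param te_library_size TE-derived reads per sample.
#' @param chimera_read_support Junction reads per active sample per chimera.
#' @param multimap_fraction Fraction of TE reads written as NH=2
#'   multimappers (one primary plus one secondary record).
#' @param read_length,chimera_flank Read length and exonic flank of
#'   junction-spanning reads (bp).
#' @param chimera_window Geometry bound used when placing planted TEs; must
#'   match the caller's `W` for planted chimeras to be recoverable.
#' @param methylation_levels Per-condition global 5-mC fraction. Default is
#'   a monotone gradient 0.28..0.80 along `conditions`.
#' @param imprint_levels Per-condition 5-mC fraction inside imprints.
#'   Default: 0.25 (atrophied) in the first condition, 0.05 (erased) in the
#'   second, 0.50 (maintained) elsewhere.
#' @param n_imprints,n_enhancers Region counts.
#' @param cpg_coverage_mean Mean Poisson read depth per CpG (shallow).
#' @param seed Integer seed fixing all randomness.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(conditions = c("2i/L", "2i/L_K", "2i",
                                             "Pd/L", "Ch/L", "S/L_F"),
                              replicates_per_condition = 2,
                              background = "129",
                              genome_size = 2e6,
                              n_chroms = 2,
                              n_genes = 100,
                              n_te_instances = 120,
                              n_families = 18,
                              n_planted_chimeras = 30,
                              n_adversarial_chimeras = 3,
                              n_decoy_junctions = 300,
                              n_driver_genes = 30,
                              n_planted_de_genes = 30,
                              de_log2fc = 3,
                              nb_dispersion = 0.05,
                              library_size = 20000,
                              te_library_size = 4000,
                              chimera_read_support = 5,
                              multimap_fraction = 0.2,
                              read_length = 80,
                              chimera_flank = 40,
                              chimera_window = 10000,
                              methylation_levels = NULL,
                              imprint_levels = NULL,
                              n_imprints = 8,
                              n_enhancers = 40,
                              cpg_coverage_mean = 2,
                              seed = 1L) {
  k <- length(conditions)
  if (is.null(methylation_levels)) {
    methylation_levels <- if (k == 6) {
      c(0.28, 0.33, 0.42, 0.57, 0.72, 0.80)
    } else {
      seq(0.28, 0.80, length.out = k)
    }
  }
  if (is.null(imprint_levels)) {
    imprint_levels <- rep(0.50, k)
    imprint_levels[1] <- 0.25
    if (k >= 2) imprint_levels[2] <- 0.05
  }
  cfg <- list(
    conditions = conditions,
    replicates_per_condition = as.integer(replicates_per_condition),
    background = background,
    genome_size = as.integer(genome_size),
    n_chroms = as.integer(n_chroms),
    n_genes = as.integer(n_genes),
    n_te_instances = as.integer(n_te_instances),
    n_families = as.integer(n_families),
    n_planted_chimeras = as.integer(n_planted_chimeras),
    n_adversarial_chimeras = as.integer(n_adversarial_chimeras),
    n_decoy_junctions = as.integer(n_decoy_junctions),
    n_driver_genes = as.integer(n_driver_genes),
    n_planted_de_genes = as.integer(n_planted_de_genes),
    de_log2fc = de_log2fc,
    nb_dispersion = nb_dispersion,
    library_size = as.integer(library_size),
    te_library_size = as.integer(te_library_size),
    chimera_read_support = as.integer(chimera_read_support),
    multimap_fraction = multimap_fraction,
    read_length = as.integer(read_length),
    chimera_flank = as.integer(chimera_flank),
    chimera_window = as.integer(chimera_window),
    methylation_levels = set_names(methylation_levels, conditions),
    imprint_levels = set_names(imprint_levels, conditions),
    n_imprints = as.integer(n_imprints),
    n_enhancers = as.integer(n_enhancers),
    cpg_coverage_mean = cpg_coverage_mean,
    seed = as.integer(seed)
  )
  counts <- c(
    "replicates_per_condition", "n_genes", "n_te_instances", "n_families",
    "n_planted_chimeras", "n_adversarial_chimeras", "n_decoy_junctions",
    "n_driver_genes", "n_planted_de_genes", "library_size",
    "te_library_size", "chimera_read_support", "n_imprints", "n_enhancers"
  )
  check_that(all(unlist(cfg[counts]) >= 0), "all counts must be >= 0")
  check_that(
    all(methylation_levels >= 0 & methylation_levels <= 1) &&
      all(imprint_levels >= 0 & imprint_levels <= 1) &&
      multimap_fraction >= 0 && multimap_fraction <= 1,
    "fractions must lie in [0, 1]"
  )
  check_that(
    cfg$n_planted_chimeras + cfg$n_adversarial_chimeras <= cfg$n_genes,
    "config requests more chimeras than genes"
  )
  check_that(nb_dispersion >= 0, "nb_dispersion must be >= 0")
  structure(cfg, class = "simulation_config")
}

# Slot layout constants (bp): each gene lives at the far end of its slot,
# leaving an upstream corridor long enough for beyond-window adversarial
# TEs; a fixed zone near the slot's outer edge holds background TEs and
# enhancers; the tail of each chromosome is reserved for imprints.
.SIM <- list(
  imprint_reserve = 30000L, backte_zone = 2000L, backte_subslot = 1000L,
  enh_gap = 60L, enh_len = 200L, gene_margin = 150L, corridor_gap = 2300L
)

#' Generate the synthetic genome, annotations and design
#'
#' Lays out genes in non-overlapping slots, places background TE instances
#' intergenically, plants chimera TEs upstream of their target genes' first
#' exon (within the window, plus adversarial ones beyond it), fixes the
#' decoy junction set, and draws the expected per-condition expression means
#' for genes and TE families.
#'
#' @param config A [simulation_config()].
#' @param dir Optional output directory; when given, writes `genome.fa`,
#'   `genes.gtf`, `te_instances.bed`, `promoters.bed`, `enhancers.bed`,
#'   `imprints.bed` and `design.tsv` and records the paths in `$files`.
#' @return A `spectrum_sim` list holding the config, genome
#'   ([Biostrings::DNAStringSet]), `genes`, `tes`, `regions`, `design`
#'   tibbles, planted `chimeras` and `decoys`, and expected-mean tables
#'   `gene_means` and `te_family_means` (the simulation truth).
#' @export
simulate_annotations <- function(config, dir = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed + 1L, simulate_annotations_impl(config, dir))
}

simulate_annotations_impl <- function(config, dir) {
  z <- .SIM
  n_chroms <- config$n_chroms
  chrom_names <- paste0("chr", seq_len(n_chroms))
  chrom_len <- as.integer(floor(config$genome_size / n_chroms))
  chrom_sizes <- set_names(rep(chrom_len, n_chroms), chrom_names)

  # genome sequence
  genome <- Biostrings::DNAStringSet(vapply(
    chrom_names,
    function(ch) {
      paste(sample(c("A", "C", "G", "T"), chrom_len, replace = TRUE),
        collapse = ""
      )
    },
    character(1)
  ))
  names(genome) <- chrom_names

  # --- genes -----------------------------------------------------------
  gpc <- ceiling(config$n_genes / n_chroms)
  usable <- chrom_len - z$imprint_reserve
  slot <- as.integer(floor(usable / gpc))
  check_that(slot >= 18000L, "genome too small for the requested gene count")

  genes_list <- vector("list", config$n_genes)
  gi <- 0L
  for (ci in seq_len(n_chroms)) {
    n_here <- min(gpc, config$n_genes - (ci - 1L) * gpc)
    if (n_here <= 0) next
    for (si in seq_len(n_here)) {
      gi <- gi + 1L
      s <- (si - 1L) * slot
      strand <- if (gi %% 2L == 1L) "+" else "-"
      n_exons <- sample(2:3, 1)
      exon_lens <- sample(150:250, n_exons, replace = TRUE)
      intron_lens <- sample(300:700, max(n_exons - 1L, 0L), replace = TRUE)
      span <- sum(exon_lens) + sum(intron_lens)
      gene_start <- if (strand == "+") {
        s + slot - span - z$gene_margin
      } else {
        s + z$gene_margin
      }
      starts <- gene_start +
        cumsum(c(0L, head(exon_lens, -1) + intron_lens))
      exons <- tibble(start = as.integer(starts),
                      end = as.integer(starts + exon_lens))
      fi <- if (strand == "+") 1L else n_exons
      acceptors <- if (strand == "+") {
        exons$start[-1L]
      } else {
        exons$end[-n_exons] - 1L
      }
      fe_start <- exons$start[fi]
      fe_end <- exons$end[fi]
      tss_pos <- if (strand == "+") fe_start else fe_end - 1L
      genes_list[[gi]] <- tibble(
        gene_id = sprintf("g%03d", gi),
        chrom = chrom_names[ci], strand = strand,
        biotype = if (runif(1) < 0.15) "lncRNA" else "coding",
        n_exons = n_exons, exons = list(exons),
        first_exon_start = fe_start,
        first_exon_end = fe_end,
        tss = tss_pos,
        acceptor_sites = list(as.integer(acceptors)),
        slot_start = as.integer(s), slot_index = si, chrom_index = ci
      )
    }
  }
  genes <- bind_rows(genes_list)

  # --- TE families and instances ---------------------------------------
  families <- head(TE_FAMILY_CATALOG, config$n_families)
  if (config$n_families > nrow(TE_FAMILY_CATALOG)) {
    extra <- config$n_families - nrow(TE_FAMILY_CATALOG)
    families <- bind_rows(families, tibble(
      family = sprintf("FAM%02d", seq_len(extra)), te_class = "other"
    ))
  }
  ltr_families <- families$family[families$te_class == "LTR"]
  check_that(length(ltr_families) > 0, "need at least one LTR family")

  # background TEs: up to 2 fixed sub-slots in each slot's outer zone
  n_bg <- config$n_te_instances
  slot_tbl <- genes %>% select("chrom", "strand", "slot_start")
  bg_slots <- bind_rows(
    slot_tbl %>% mutate(sub = 0L),
    slot_tbl %>% mutate(sub = 1L)
  )
  check_that(nrow(bg_slots) >= n_bg, "too many background TEs for layout")
  bg_pick <- bg_slots[sample.int(nrow(bg_slots), n_bg), ]
  bg_len <- sample(300:800, n_bg, replace = TRUE)
  zone_start <- if_else(
    bg_pick$strand == "+",
    bg_pick$slot_start + 50L,
    bg_pick$slot_start + slot - 50L - z$backte_zone
  )
  off <- vapply(
    z$backte_subslot - bg_len,
    function(m) sample.int(m, 1L) - 1L, integer(1)
  )
  bg_start <- zone_start + bg_pick$sub * z$backte_subslot + off
  bg_tes <- tibble(
    family = sample(families$family, n_bg, replace = TRUE),
    chrom = bg_pick$chrom,
    start = as.integer(bg_start), end = as.integer(bg_start + bg_len),
    strand = sample(c("+", "-"), n_bg, replace = TRUE),
    role = "background"
  )

  # --- planted chimeras ------------------------------------------------
  n_chim <- config$n_planted_chimeras
  n_adv <- config$n_adversarial_chimeras
  target_idx <- sample.int(nrow(genes), n_chim + n_adv)
  w <- config$chimera_window
  chim_list <- vector("list", n_chim + n_adv)
  chim_tes <- vector("list", n_chim + n_adv)
  conds <- config$conditions
  k <- length(conds)
  for (i in seq_len(n_chim + n_adv)) {
    g <- genes[target_idx[i], ]
    adversarial <- i > n_chim
    d <- if (adversarial) {
      sample((w + 1500L):(w + 2500L), 1)
    } else {
      sample(200:3000, 1)
    }
    te_len <- if (adversarial) sample(300:500, 1) else sample(300:600, 1)
    if (g$strand == "+") {
      te_end <- g$first_exon_start - d
      te_start <- te_end - te_len
      donor <- te_end - 21L
      acceptor <- min(g$acceptor_sites[[1]])
      intron_start <- donor + 1L
      intron_end <- acceptor
    } else {
      te_start <- g$first_exon_end + d
      te_end <- te_start + te_len
      donor <- te_start + 20L
      acceptor <- max(g$acceptor_sites[[1]])
      intron_start <- acceptor + 1L
      intron_end <- donor
    }
    pattern <- i %% 3L
    active <- if (adversarial || pattern == 0L) {
      conds[(i %% k) + 1L]
    } else if (pattern == 1L) {
      conds[c((i %% k) + 1L, ((i + 1L) %% k) + 1L)]
    } else {
      conds
    }
    chim_tes[[i]] <- tibble(
      family = sample(ltr_families, 1),
      chrom = g$chrom, start = as.integer(te_start),
      end = as.integer(te_end),
      strand = sample(c("+", "-"), 1),
      role = if (adversarial) "adversarial" else "chimera"
    )
    chim_list[[i]] <- tibble(
      chimera_id = sprintf("chim%02d", i),
      gene_id = g$gene_id, chrom = g$chrom, gene_strand = g$strand,
      donor_pos = as.integer(donor), acceptor_pos = as.integer(acceptor),
      intron_start = as.integer(intron_start),
      intron_end = as.integer(intron_end),
      te_gene_distance = as.integer(d),
      adversarial = adversarial,
      active_conditions = list(active)
    )
  }
  tes <- bind_rows(bg_tes, bind_rows(chim_tes)) %>%
    left_join(families, by = "family") %>%
    arrange(.data$chrom, .data$start) %>%
    mutate(instance_id = paste0(.data$family, ".", row_number())) %>%
    select(
      "instance_id", "family", "te_class", "chrom", "start", "end",
      "strand", "role"
    )
  chimeras <- bind_rows(chim_list)
  # attach the TE instance id of each chimera (the TE containing its donor)
  te_idx <- build_interval_index(tes)
  hit <- index_overlaps(te_idx, chimeras %>%
    mutate(start = .data$donor_pos, end = .data$donor_pos + 1L) %>%
    select("chrom", "start", "end"))
  chimeras$te_instance_id <- NA_character_
  chimeras$te_instance_id[hit$query_row] <- tes$instance_id[hit$feature_row]
  check_that(!anyNA(chimeras$te_instance_id), "chimera donor not inside TE")

  # --- decoy junctions -------------------------------------------------
  gene_introns <- genes %>%
    select("gene_id", "chrom", "strand", "exons") %>%
    purrr::pmap(function(gene_id, chrom, strand, exons) {
      if (nrow(exons) < 2) {
        return(NULL)
      }
      tibble(
        chrom = chrom, strand = strand,
        intron_start = exons$end[-nrow(exons)],
        intron_end = exons$start[-1L],
        kind = "gene_intron"
      )
    }) %>%
    bind_rows()
  n_random <- max(config$n_decoy_junctions - nrow(gene_introns), 0L)
  all_acceptor_pos <- sort(unique(unlist(purrr::map2(
    genes$acceptor_sites, genes$chrom,
    function(a, ch) paste0(ch, ":", a)
  ))))
  random_decoys <- NULL
  if (n_random > 0) {
    pick <- genes[sample.int(nrow(genes), n_random, replace = TRUE), ]
    d_zone <- if_else(
      pick$strand == "+",
      pick$slot_start + 50L,
      pick$slot_start + slot - 50L - z$backte_zone
    )
    d_start <- d_zone + sample(60:900, n_random, replace = TRUE)
    d_len <- sample(200:900, n_random, replace = TRUE)
    random_decoys <- tibble(
      chrom = pick$chrom, strand = sample(c("+", "-"), n_random, TRUE),
      intron_start = as.integer(d_start),
      intron_end = as.integer(d_start + d_len),
      kind = "random"
    ) %>%
      # a decoy must not look like a chimeric junction for either gene
      # orientation: its acceptor candidate (intron end on +, intron
      # start - 1 on -) must not coincide with any annotated acceptor
      filter(
        !paste0(.data$chrom, ":", .data$intron_end) %in% all_acceptor_pos,
        !paste0(.data$chrom, ":", .data$intron_start - 1L) %in%
          all_acceptor_pos
      )
  }
  decoys <- bind_rows(gene_introns, random_decoys) %>%
    head(config$n_decoy_junctions) %>%
    mutate(decoy_id = sprintf("decoy%03d", row_number()))

  # --- region sets -----------------------------------------------------
  promoters <- genes %>%
    mutate(
      set_name = "promoters", label = paste0("prom_", .data$gene_id),
      start = if_else(.data$strand == "+",
        .data$first_exon_start - 500L, .data$first_exon_end
      ),
      end = .data$start + 500L
    ) %>%
    select("set_name", "label", "chrom", "start", "end")
  enh_genes <- genes[sample.int(nrow(genes), min(config$n_enhancers, nrow(genes))), ]
  enhancers <- enh_genes %>%
    mutate(
      set_name = "enhancers", label = sprintf("enh_%03d", row_number()),
      start = if_else(.data$strand == "+",
        .data$slot_start + 50L + z$backte_zone + z$enh_gap,
        .data$slot_start + slot - 50L - z$backte_zone - z$enh_gap - z$enh_len
      ),
      end = .data$start + z$enh_len
    ) %>%
    select("set_name", "label", "chrom", "start", "end")
  ipc <- ceiling(config$n_imprints / n_chroms)
  imprints <- tidyr::crossing(
    chrom_index = seq_len(n_chroms), j = seq_len(ipc)
  ) %>%
    head(config$n_imprints) %>%
    mutate(
      set_name = "imprints",
      label = sprintf("imp_%02d", row_number()),
      chrom = chrom_names[.data$chrom_index],
      start = as.integer(chrom_len - z$imprint_reserve + 2000L +
        (.data$j - 1L) * 3000L),
      end = .data$start + 1500L
    ) %>%
    select("set_name", "label", "chrom", "start", "end")
  regions <- bind_rows(promoters, enhancers, imprints)

  # --- design ----------------------------------------------------------
  design <- tidyr::crossing(
    condition = factor(conds, levels = conds),
    replicate = seq_len(config$replicates_per_condition)
  ) %>%
    mutate(
      condition = as.character(.data$condition),
      sample_id = sprintf(
        "%s_r%d", sanitize_label(.data$condition), .data$replicate
      ),
      background = config$background
    ) %>%
    select("sample_id", "condition", "background", "replicate")

  # --- expected expression means ---------------------------------------
  grad <- set_names(seq(0, 1, length.out = k), conds)
  free_idx <- setdiff(seq_len(nrow(genes)), integer())
  roles <- rep("flat", nrow(genes))
  driver_idx <- sample(free_idx, min(config$n_driver_genes, length(free_idx)))
  roles[driver_idx] <- "driver"
  jump_pool <- setdiff(free_idx, driver_idx)
  jump_idx <- sample(jump_pool, min(config$n_planted_de_genes, length(jump_pool)))
  roles[jump_idx] <- "jump"
  mid_conds <- conds[unique(pmax(1L, c(ceiling(k / 2), ceiling(k / 2) + 1L)))]
  mid_conds <- mid_conds[!is.na(mid_conds)]
  base <- stats::runif(nrow(genes), 100, 300)
  base[roles == "flat"] <- rlnorm(sum(roles == "flat"), log(60), 0.8)
  sign_i <- rep_len(c(1, -1), nrow(genes))
  jump_cond <- sample(mid_conds, nrow(genes), replace = TRUE)
  gene_means <- tidyr::crossing(
    gene_id = genes$gene_id, condition = conds
  ) %>%
    left_join(
      tibble(
        gene_id = genes$gene_id, role = roles, base = base,
        sgn = sign_i, jump_cond = jump_cond
      ),
      by = "gene_id"
    ) %>%
    mutate(
      g = grad[.data$condition],
      mean = dplyr::case_when(
        role == "driver" ~ base * 2^(sgn * config$de_log2fc * (.data$g - 0.5)),
        role == "jump" ~ base * if_else(
          condition == jump_cond, 2^(sgn * config$de_log2fc), 1
        ),
        TRUE ~ base
      )
    ) %>%
    select("gene_id", "condition", "role", "mean")

  fam_base <- set_names(
    stats::runif(nrow(families), 50, 200), families$family
  )
  te_family_means <- tidyr::crossing(
    family = families$family, condition = conds
  ) %>%
    mutate(
      g = grad[.data$condition],
      base = fam_base[.data$family],
      mean = dplyr::case_when(
        family %in% c("IAPEy-int", "RLTR45") ~
          base * 2^(config$de_log2fc * (0.5 - .data$g)),
        family %in% c("MER50B", "L1M6B") ~
          base * 2^(config$de_log2fc * (.data$g - 0.5)),
        family %in% c("MT2_Mm", "MERVL-int") ~
          base * if_else(condition == "2i", 2^config$de_log2fc, 1),
        family == "LTRIS2" ~
          base * if_else(condition == "Pd/L", 2^-config$de_log2fc, 1),
        TRUE ~ base
      )
    ) %>%
    select("family", "condition", "mean")

  sim <- structure(
    list(
      config = config,
      chrom_sizes = chrom_sizes,
      genome = genome,
      genes = genes %>% select(-"slot_start", -"slot_index", -"chrom_index"),
      families = families,
      tes = tes,
      regions = regions,
      design = design,
      chimeras = chimeras,
      decoys = decoys,
      gene_means = gene_means,
      te_family_means = te_family_means,
      spectrum_order = conds,
      files = list()
    ),
    class = "spectrum_sim"
  )
  if (!is.null(dir)) sim <- write_sim_annotations(sim, dir)
  sim
}

write_sim_annotations <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- list(
    genome = file.path(dir, "genome.fa"),
    gtf = file.path(dir, "genes.gtf"),
    te_bed = file.path(dir, "te_instances.bed"),
    promoters = file.path(dir, "promoters.bed"),
    enhancers = file.path(dir, "enhancers.bed"),
    imprints = file.path(dir, "imprints.bed"),
    design = file.path(dir, "design.tsv")
  )
  Biostrings::writeXStringSet(sim$genome, files$genome)
  write_gtf(sim$genes, files$gtf)
  write_te_bed(sim$tes, files$te_bed)
  for (set in c("promoters", "enhancers", "imprints")) {
    write_region_bed(
      sim$regions %>% filter(.data$set_name == set), files[[set]]
    )
  }
  write_spectrum_tsv(sim$design, files$design)
  sim$files <- utils::modifyList(sim$files, files)
  sim
}

#' @export
print.spectrum_sim <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<spectrum_sim: %d conditions x %d replicates, %d genes, %d TE",
      " instances, %d planted + %d adversarial chimeras, seed %d>\n"
    ),
    length(x$config$conditions), x$config$replicates_per_condition,
    nrow(x$genes), nrow(x$tes), x$config$n_planted_chimeras,
    x$config$n_adversarial_chimeras, x$config$seed
  ))
  invisible(x)
}
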