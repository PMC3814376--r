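# Synthetic world generator: a small genome with annotation, GRO replicate
# tables, nucleosome maps, TFBS, score tracks and gene lists, all with
# planted, recoverable structure so the downstream pipeline can be validated
# end to end with no external data.

#' Configuration for a synthetic world
#'
#' Bundles and validates every parameter of [generate_world()]. The defaults
#' encode the regulatory architecture the pipeline is designed to detect: a
#' nucleosome-free region (NFR) and phased nucleosome array around each TSS,
#' a GC dip over (-250, 0), a purine/pyrimidine skew switch at the TSS,
#' log-normal replicate noise around planted fold changes, class-specific
#' nucleosome linkers, and gene-set-specific histone-mark shifts.
#'
#' @param seed Integer seed; a fixed seed gives a byte-identical world.
#' @param n_chroms,chrom_length Number of chromosomes and their common
#'   length in bp.
#' @param n_genes Number of genes tiled over the chromosomes.
#' @param frac_up,frac_down Fractions of genes planted as up-/downregulated
#'   (must sum to < 1).
#' @param fold_up,fold_down Planted mean mutant/control ratios; recoverable
#'   by the 1.5 / 0.65 classification thresholds, hence `fold_up > 1.5` and
#'   `fold_down < 0.65` are required.
#' @param noise_sigma Standard deviation of the log-signal replicate noise.
#' @param n_replicates Replicates per strain (default 3).
#' @param nfr_halfwidth NFR width upstream of the TSS in bp (default 80).
#' @param nucleosome_width Nucleosome footprint in bp (default 147).
#' @param spacing_by_class Named edge-to-edge linker lengths in bp for
#'   `up`, `down` and `unchanged` genes (defaults 29 / 21 / 25).
#' @param gene_length_mean,gene_length_min Gene-body length distribution
#'   (log-normal around the mean, clamped at the minimum).
#' @param intergenic_mean,intergenic_min Intergenic gap distribution
#'   (shifted geometric with the stated mean, default mean 400 bp).
#' @param gc_background Background GC fraction (default 0.38, yeast-like).
#' @param gc_dip_depth Depth of the promoter GC dip over (-250, 0).
#' @param pr2_switch_amp Amplitude of the planted PR2 skew switch at the TSS.
#' @param mark_shift Effect size (in score SDs) of planted histone-mark
#'   differences.
#' @param esr_overlap_frac Fraction of planted deregulated genes also placed
#'   in the ESR lists (default 1/3).
#' @param base_log_mean,base_log_sd Log-normal distribution of baseline
#'   expression signals.
#' @param n_tf Number of synthetic transcription factors.
#' @return A validated `world_config` list.
#' @export
world_config <- function(seed = 1L,
                         n_chroms = 2L,
                         chrom_length = 220000L,
                         n_genes = 200L,
                         frac_up = 0.05, frac_down = 0.03,
                         fold_up = 2.0, fold_down = 0.5,
                         noise_sigma = 0.1,
                         n_replicates = 3L,
                         nfr_halfwidth = 80L,
                         nucleosome_width = 147L,
                         spacing_by_class = c(up = 29L, down = 21L, unchanged = 25L),
                         gene_length_mean = 1200L, gene_length_min = 600L,
                         intergenic_mean = 400L, intergenic_min = 60L,
                         gc_background = 0.38,
                         gc_dip_depth = 0.12,
                         pr2_switch_amp = 0.15,
                         mark_shift = 1.0,
                         esr_overlap_frac = 1 / 3,
                         base_log_mean = log(200), base_log_sd = 0.8,
                         n_tf = 12L) {
  cfg <- as.list(environment())
  props <- c(frac_up = frac_up, frac_down = frac_down,
             gc_background = gc_background, gc_dip_depth = gc_dip_depth,
             esr_overlap_frac = esr_overlap_frac)
  if (any(props < 0 | props > 1)) {
    abort("All proportions must lie in [0, 1].")
  }
  if (frac_up + frac_down >= 1) abort("frac_up + frac_down must be < 1.")
  if (fold_up <= 1.5) abort("fold_up must exceed 1.5 so planted genes are recoverable.")
  if (fold_down >= 0.65) abort("fold_down must be below 0.65 so planted genes are recoverable.")
  if (nucleosome_width <= 0) abort("nucleosome_width must be positive.")
  if (noise_sigma < 0) abort("noise_sigma must be non-negative.")
  if (n_replicates < 1) abort("Need at least one replicate per strain.")
  if (!all(c("up", "down", "unchanged") %in% names(spacing_by_class))) {
    abort("spacing_by_class must name 'up', 'down' and 'unchanged'.")
  }
  if (gc_background - gc_dip_depth < 0) abort("GC dip deeper than the background GC.")
  structure(cfg, class = "world_config")
}

# gene-oriented offset interval [a, b) -> 0-based half-open chrom interval
orient_interval <- function(tss, strand, a, b) {
  if (strand == "+") c(tss + a, tss + b) else c(tss - b + 1L, tss - a + 1L)
}

sample_bases <- function(n, gc, amp = 0) {
  ah <- (1 - gc) / 2; gh <- gc / 2
  # amp > 0: purine (A, G) excess; amp < 0: pyrimidine (T, C) excess
  p <- c(A = ah * (1 + amp), C = gh * (1 - amp),
         G = gh * (1 + amp), T = ah * (1 - amp))
  sample(names(p), n, replace = TRUE, prob = p)
}

revcomp_chars <- function(chars) rev(chartr("ACGT", "TGCA", chars))

weighted_list <- function(ids, size, class, w_up, w_down) {
  w <- rep(1, length(ids))
  w[class == "up"] <- w_up
  w[class == "down"] <- w_down
  sample(ids, min(size, length(ids)), prob = w)
}

#' Generate a synthetic world
#'
#' Builds the complete synthetic data set described by a [world_config()]:
#' genome sequence, gene annotation, GRO replicate table, nucleosome maps
#' (bulk plus appearing/evicted/fragile labels), TFBS positions, a
#' conservation track, histone-mark scores, named gene lists and the planted
#' truth. Deterministic for a fixed seed; the global RNG state is left
#' untouched.
#'
#' Planted structure, by module it exercises: control signals are log-normal
#' around a gene baseline and mutant signals carry the class fold change
#' (differential transcription); each promoter carries a GC dip over
#' (-250, 0) and a pyrimidine-to-purine skew switch at the TSS (composition
#' profiles); nucleosomes form an NFR plus phased arrays with class-specific
#' linkers (spacing and occupancy profiles); appearing nucleosomes sit at the
#' +1 position of downregulated genes and evicted/fragile nucleosomes
#' upstream of deregulated TSSs (dynamic profiles); upregulated genes carry a
#' mirror-symmetric sequence cassette at the +1 dyad (curvature symmetry);
#' histone-mark scores are shifted for planted classes, remodeler target
#' lists over-sample downregulated genes, and a configurable fraction of
#' planted genes is also placed in the ESR lists.
#'
#' @param config A [world_config()].
#' @return A `synthetic_world` list with components `config`, `genome`
#'   (named character vector), `genes`, `gro`, `nucleosomes`, `tfbs`,
#'   `tracks` (named list of per-chromosome numeric vectors), `marks`,
#'   `gene_lists` and `truth`.
#' @export
generate_world <- function(config = world_config()) {
  if (!inherits(config, "world_config")) {
    abort("`config` must come from world_config().")
  }
  withr::local_preserve_seed()
  set.seed(config$seed)
  cfg <- config
  margin <- 700L

  capacity <- cfg$n_chroms * (cfg$chrom_length - 2L * margin)
  need <- cfg$n_genes * (cfg$gene_length_mean + cfg$intergenic_mean)
  if (capacity < need) {
    abort(sprintf(
      "Genome too short for %d genes: %d bp available, ~%d bp needed. Increase chrom_length or n_chroms.",
      cfg$n_genes, capacity, need))
  }

  chroms <- sprintf("chr%s", as.roman(seq_len(cfg$n_chroms)))
  chrom_lengths <- setNames(rep(cfg$chrom_length, cfg$n_chroms), chroms)

  ## ---- gene layout -------------------------------------------------------
  genes <- vector("list", cfg$n_genes)
  gi <- 0L
  for (ch in chroms) {
    pos <- margin
    while (gi < cfg$n_genes) {
      gap <- cfg$intergenic_min +
        stats::rgeom(1, 1 / (cfg$intergenic_mean - cfg$intergenic_min + 1))
      len <- round(stats::rlnorm(1, log(cfg$gene_length_mean), 0.25))
      len <- max(cfg$gene_length_min, min(len, 4L * cfg$gene_length_mean))
      start <- pos + gap
      if (start + len > cfg$chrom_length - margin) break
      gi <- gi + 1L
      genes[[gi]] <- tibble(
        gene_id = sprintf("g%04d", gi), chrom = ch,
        start = as.integer(start), end = as.integer(start + len),
        strand = sample(c("+", "-"), 1))
      pos <- start + len
    }
    if (gi >= cfg$n_genes) break
  }
  if (gi < cfg$n_genes) {
    abort(sprintf("Genome too short: placed only %d of %d genes.", gi, cfg$n_genes))
  }
  genes <- bind_rows(genes) %>%
    mutate(tss = ifelse(.data$strand == "+", .data$start, .data$end - 1L))
  # free space upstream of each TSS, to the nearest neighbour boundary;
  # upstream bulk nucleosomes are confined to it so that a gene's -1/-2
  # nucleosomes never reach into a neighbour's gene body
  genes <- genes %>%
    group_by(.data$chrom) %>%
    arrange(.data$start, .by_group = TRUE) %>%
    mutate(upstream_space = dplyr::if_else(
      .data$strand == "+",
      .data$start - dplyr::lag(.data$end, default = 0L),
      dplyr::lead(.data$start, default = as.integer(cfg$chrom_length)) - .data$end
    )) %>%
    ungroup() %>%
    arrange(.data$gene_id)

  ## ---- planted classes ---------------------------------------------------
  n_up <- round(cfg$frac_up * cfg$n_genes)
  n_down <- round(cfg$frac_down * cfg$n_genes)
  planted <- sample(genes$gene_id, n_up + n_down)
  up_ids <- head(planted, n_up)
  down_ids <- tail(planted, n_down)
  genes$class <- "unchanged"
  genes$class[genes$gene_id %in% up_ids] <- "up"
  genes$class[genes$gene_id %in% down_ids] <- "down"

  ## ---- genome sequence with planted composition --------------------------
  genome_chars <- lapply(chrom_lengths, function(len) {
    sample_bases(len, cfg$gc_background)
  })
  dip_factor <- c(up = 0.75, down = 1.25, unchanged = 1)
  half_cassette <- 90L
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    # promoter: GC dip + pyrimidine excess over (-250, 0)
    dip_gc <- cfg$gc_background - cfg$gc_dip_depth * dip_factor[[g$class]]
    up_seq <- sample_bases(250L, dip_gc, amp = -cfg$pr2_switch_amp)
    # downstream: background GC + purine excess over (0, +250)
    dn_seq <- sample_bases(250L, cfg$gc_background, amp = cfg$pr2_switch_amp)
    patch <- if (g$strand == "+") c(up_seq, dn_seq) else revcomp_chars(c(up_seq, dn_seq))
    iv <- orient_interval(g$tss, g$strand, -250L, 250L)
    genome_chars[[g$chrom]][(iv[1] + 1L):iv[2]] <- patch
    if (g$class == "up") {
      # mirror-symmetric cassette centred on the +1 nucleosome dyad
      dyad <- 73L
      left <- sample_bases(half_cassette, 0.5)
      cassette <- c(left, chartr("ACGT", "TGCA", rev(left)))
      patch <- if (g$strand == "+") cassette else revcomp_chars(cassette)
      iv <- orient_interval(g$tss, g$strand, dyad - half_cassette,
                            dyad + half_cassette)
      genome_chars[[g$chrom]][(iv[1] + 1L):iv[2]] <- patch
    }
  }
  genome <- vapply(genome_chars, paste, character(1), collapse = "")

  ## ---- nucleosomes -------------------------------------------------------
  w <- cfg$nucleosome_width
  nfr <- cfg$nfr_halfwidth
  nuc_rows <- vector("list", nrow(genes))
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    linker <- cfg$spacing_by_class[[g$class]]
    body_len <- g$end - g$start
    offs <- list()
    # upstream of the NFR: -1 and -2 nucleosomes, confined to the intergenic
    # space so they never overlap a neighbour's gene body
    if (nfr + w <= g$upstream_space) {
      offs[[length(offs) + 1L]] <- c(-(nfr + w), -nfr)
    }
    if (nfr + 2L * w + linker <= g$upstream_space) {
      offs[[length(offs) + 1L]] <- c(-(nfr + 2L * w + linker),
                                     -(nfr + w + linker))
    }
    # downstream array: +1 at the TSS, then phased with the class linker
    a <- 0L
    k <- length(offs)
    while (a + w <= body_len) {
      k <- k + 1L
      offs[[k]] <- c(a, a + w)
      a <- a + w + linker
    }
    m <- do.call(rbind, offs)
    ivs <- t(vapply(seq_len(nrow(m)), function(j) {
      orient_interval(g$tss, g$strand, m[j, 1], m[j, 2])
    }, numeric(2)))
    bulk <- tibble(chrom = g$chrom, start = as.integer(ivs[, 1]),
                   end = as.integer(ivs[, 2]), label = "bulk")
    extra <- list()
    if (g$class == "down") {
      iv <- orient_interval(g$tss, g$strand, 0L, w)
      extra$appearing <- tibble(chrom = g$chrom, start = iv[1], end = iv[2],
                                label = "appearing")
    }
    if (g$class %in% c("up", "down")) {
      iv1 <- orient_interval(g$tss, g$strand, -(nfr + w), -nfr)
      iv2 <- orient_interval(g$tss, g$strand, -(nfr + 2L * w + linker),
                             -(nfr + w + linker))
      extra$evicted <- tibble(chrom = g$chrom, start = iv1[1], end = iv1[2],
                              label = "evicted")
      extra$fragile <- tibble(chrom = g$chrom, start = iv2[1], end = iv2[2],
                              label = "fragile")
    }
    nuc_rows[[i]] <- bind_rows(c(list(bulk), extra))
  }
  nucleosomes <- bind_rows(nuc_rows) %>%
    filter(.data$start >= 0, .data$end <= chrom_lengths[.data$chrom]) %>%
    mutate(start = as.integer(.data$start), end = as.integer(.data$end))

  ## ---- TFBS --------------------------------------------------------------
  tf_names <- sprintf("TF%02d", seq_len(cfg$n_tf))
  center_by_class <- c(up = -300, down = -150, unchanged = -200)
  tfbs <- purrr::map_dfr(tf_names, function(tf) {
    hit <- runif(nrow(genes)) < 0.35
    if (!any(hit)) return(tibble())
    g <- genes[hit, ]
    off <- round(stats::rnorm(nrow(g), center_by_class[g$class], 60))
    off <- pmax(-480L, pmin(-10L, as.integer(off)))
    ivs <- t(vapply(seq_len(nrow(g)), function(j) {
      orient_interval(g$tss[j], g$strand[j], off[j], off[j] + 8L)
    }, numeric(2)))
    tibble(factor = tf, chrom = g$chrom, start = as.integer(ivs[, 1]),
           end = as.integer(ivs[, 2]), strand = g$strand)
  }) %>%
    filter(.data$start >= 0, .data$end <= chrom_lengths[.data$chrom])

  ## ---- conservation track ------------------------------------------------
  block <- 100L
  tracks <- list(conservation = lapply(chrom_lengths, function(len) {
    n_blocks <- ceiling(len / block)
    rep(round(0.25 + 0.1 * runif(n_blocks), 4), each = block)[seq_len(len)]
  }))
  cons_boost <- c(up = 0.08, down = 0.25, unchanged = 0)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    boost <- cons_boost[[g$class]]
    if (boost == 0) next
    iv <- orient_interval(g$tss, g$strand, -400L, 400L)
    idx <- max(1L, iv[1] + 1L):min(chrom_lengths[[g$chrom]], iv[2])
    tracks$conservation[[g$chrom]][idx] <-
      tracks$conservation[[g$chrom]][idx] + boost
  }

  ## ---- GRO table ---------------------------------------------------------
  fold <- c(up = cfg$fold_up, down = cfg$fold_down, unchanged = 1)
  base <- stats::rlnorm(nrow(genes), cfg$base_log_mean, cfg$base_log_sd)
  arrays <- tidyr::expand_grid(strain = gro_strains,
                               replicate = seq_len(cfg$n_replicates)) %>%
    mutate(gdna = round(runif(dplyr::n(), 0.7, 1.3), 4))
  gro <- tidyr::expand_grid(gene_id = genes$gene_id,
                            strain = gro_strains,
                            replicate = seq_len(cfg$n_replicates)) %>%
    left_join(arrays, by = c("strain", "replicate")) %>%
    left_join(tibble(gene_id = genes$gene_id, base = base,
                     fold = fold[genes$class]),
              by = "gene_id") %>%
    mutate(
      noise = if (cfg$noise_sigma > 0) {
        exp(stats::rnorm(dplyr::n(), 0, cfg$noise_sigma))
      } else {
        1
      },
      true = dplyr::if_else(.data$strain == "mutant",
                            .data$base * .data$fold, .data$base),
      signal = .data$true * .data$noise * .data$gdna,
      gdna_signal = .data$gdna
    ) %>%
    select("gene_id", "strain", "replicate", "signal", "gdna_signal")

  ## ---- histone marks -----------------------------------------------------
  mark_names <- c("H3K9ac", "H4K12ac", "H2AZK14ac", "H3K4me3", "H3K36me2", "H2AZ")
  marks <- tidyr::expand_grid(gene_id = genes$gene_id, mark = mark_names) %>%
    left_join(select(genes, "gene_id", "class"), by = "gene_id") %>%
    mutate(promoter_score = stats::rnorm(dplyr::n()),
           orf_score = stats::rnorm(dplyr::n()))
  s <- cfg$mark_shift
  adj <- function(df, cls, mk, d_prom, d_orf) {
    sel <- df$class == cls & df$mark %in% mk
    df$promoter_score[sel] <- df$promoter_score[sel] + d_prom
    df$orf_score[sel] <- df$orf_score[sel] + d_orf
    df
  }
  marks <- marks %>%
    adj("up", c("H3K9ac", "H4K12ac", "H2AZK14ac"), -s, -s) %>%
    adj("up", "H3K36me2", -s, -s) %>%
    adj("up", "H2AZ", -s, s) %>%
    adj("down", "H2AZK14ac", s, 0) %>%
    adj("down", "H3K4me3", 0, s) %>%
    select(-"class")

  ## ---- gene lists --------------------------------------------------------
  ids <- genes$gene_id
  cls <- genes$class
  esr_extra <- round(0.06 * cfg$n_genes)
  esr_up <- unique(c(sample(up_ids, round(cfg$esr_overlap_frac * length(up_ids))),
                     sample(setdiff(ids, up_ids), esr_extra)))
  esr_down <- unique(c(sample(down_ids, round(cfg$esr_overlap_frac * length(down_ids))),
                       sample(setdiff(ids, c(down_ids, esr_up)), esr_extra)))
  gene_lists <- list(
    essential = weighted_list(ids, round(0.18 * cfg$n_genes), cls, 0.2, 3),
    tata = weighted_list(ids, round(0.18 * cfg$n_genes), cls, 3, 0.5),
    esr_up = esr_up,
    esr_down = esr_down
  )
  remodelers <- c("Ioc3", "Isw2", "Arp5", "Ino80", "Rsc8", "Snf2", "Ioc4", "Isw1")
  for (rem in remodelers) {
    gene_lists[[paste0("remodeler_", rem)]] <-
      weighted_list(ids, round(0.15 * cfg$n_genes), cls, 1 / 3, 3)
  }

  structure(
    list(config = cfg,
         chrom_lengths = chrom_lengths,
         genome = genome,
         genes = genes,
         gro = gro,
         nucleosomes = nucleosomes,
         tfbs = tfbs,
         tracks = tracks,
         marks = marks,
         gene_lists = gene_lists,
         truth = tibble(gene_id = c(up_ids, down_ids),
                        class = c(rep("up", length(up_ids)),
                                  rep("down", length(down_ids))),
                        fold = fold[c(rep("up", length(up_ids)),
                                      rep("down", length(down_ids)))])),
    class = "synthetic_world")
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf("Synthetic world (seed %d): %d chroms x %d bp, %d genes\n",
              x$config$seed, x$config$n_chroms, x$config$chrom_length,
              nrow(x$genes)))
  cat(sprintf("  planted: %d up (fold %.2f), %d down (fold %.2f); %d replicates, sigma %.2f\n",
              sum(x$truth$class == "up"), x$config$fold_up,
              sum(x$truth$class == "down"), x$config$fold_down,
              x$config$n_replicates, x$config$noise_sigma))
  cat(sprintf("  %d nucleosomes (%s)\n", nrow(x$nucleosomes),
              paste(sprintf("%s=%d", names(table(x$nucleosomes$label)),
                            table(x$nucleosomes$label)), collapse = ", ")))
  invisible(x)
}
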