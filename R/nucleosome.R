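# Nucleosome organisation: genic spacing, TSS-anchored occupancy
# meta-profiles, dynamic-nucleosome overlap, remodeler-target enrichment and
# histone-mark enrichment.

nucleosome_labels <- c("bulk", "appearing", "evicted", "fragile")

check_nucleosomes <- function(nuc, arg = "nucleosomes") {
  needed <- c("chrom", "start", "end")
  if (!all(needed %in% names(nuc))) {
    abort(sprintf("`%s` needs columns chrom, start, end.", arg))
  }
  if (any(nuc$end <= nuc$start)) {
    abort(sprintf("`%s` intervals must satisfy end > start.", arg))
  }
  if (!"label" %in% names(nuc)) nuc$label <- "bulk"
  bad <- setdiff(unique(nuc$label), nucleosome_labels)
  if (length(bad) > 0) {
    abort(sprintf("Unknown nucleosome label(s): %s.", paste(bad, collapse = ", ")))
  }
  nuc
}

#' Mean internucleosomal spacing per gene body
#'
#' Assigns bulk nucleosomes to gene bodies (by midpoint-in-interval by
#' default) and reports, for a gene occupied by N nucleosomes, the mean of
#' the N - 1 edge-to-edge distances between consecutive nucleosomes (linker
#' lengths). Spacing is undefined (`defined = FALSE`) for genes with fewer
#' than two assigned nucleosomes.
#'
#' @param genes Gene annotation tibble.
#' @param nucleosomes Nucleosome interval tibble (`chrom`, `start`, `end`,
#'   optional `label`); only `bulk` nucleosomes are used.
#' @param assign `"midpoint"` (default) assigns a nucleosome to a gene when
#'   its midpoint lies in the gene body; `"overlap"` when it overlaps it at
#'   all.
#' @return Tibble with `gene_id`, `n_nucleosomes`, `mean_spacing`, `defined`.
#' @export
gene_nucleosome_spacing <- function(genes, nucleosomes,
                                    assign = c("midpoint", "overlap")) {
  assign <- match.arg(assign)
  genes <- check_genes(genes)
  nuc <- check_nucleosomes(nucleosomes)
  nuc <- nuc[nuc$label == "bulk", ]
  by_chrom <- split(nuc, nuc$chrom)
  purrr::map_dfr(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    on_chrom <- by_chrom[[g$chrom]] %||% nuc[0, ]
    hit <- if (assign == "midpoint") {
      mid <- floor((on_chrom$start + on_chrom$end - 1) / 2)
      mid >= g$start & mid < g$end
    } else {
      on_chrom$start < g$end & on_chrom$end > g$start
    }
    nn <- on_chrom[hit, ]
    nn <- nn[order(nn$start), ]
    if (nrow(nn) < 2L) {
      tibble(gene_id = g$gene_id, n_nucleosomes = nrow(nn),
             mean_spacing = NA_real_, defined = FALSE)
    } else {
      gaps <- nn$start[-1] - nn$end[-nrow(nn)]
      tibble(gene_id = g$gene_id, n_nucleosomes = nrow(nn),
             mean_spacing = mean(gaps), defined = TRUE)
    }
  })
}

# 0/1 occupancy vector per chromosome from nucleosome intervals.
occupancy_coverage <- function(nuc, chrom_lengths) {
  lapply(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    sel <- nuc$chrom == ch
    if (!any(sel)) return(numeric(len))
    ir <- IRanges::IRanges(start = nuc$start[sel] + 1L,
                           end = pmin(nuc$end[sel], len))
    cov <- IRanges::coverage(ir, width = len)
    as.numeric(as.vector(cov) > 0)
  }) |> setNames(names(chrom_lengths))
}

#' TSS-anchored nucleosome-occupancy meta-profile
#'
#' For every gene, computes the fraction of each strand-oriented bin around
#' the TSS covered by any nucleosome, then averages over genes. Bins are
#' half-open: bin k covers gene-oriented offsets
#' `[-upstream + k*bin, -upstream + (k+1)*bin)`.
#'
#' @param nucleosomes Nucleosome interval tibble; filtered to `label` when
#'   given.
#' @param genes Gene annotation tibble (non-empty).
#' @param chrom_lengths Named integer vector of chromosome lengths.
#' @param upstream,downstream Window around the TSS in bp (defaults 500/500;
#'   their sum must be a multiple of `bin`).
#' @param bin Bin width in bp (default 10).
#' @param label Optional nucleosome label to restrict to (`bulk`,
#'   `appearing`, `evicted`, `fragile`); default uses `bulk`.
#' @param normalize `"raw"` occupancy fractions in `[0,1]` (default) or
#'   `"zscore"` of the averaged profile.
#' @param percent Report percentages instead of fractions (default FALSE).
#' @return A `meta_profile` tibble with `offset` (bin start), `value`, `n`.
#' @export
occupancy_meta_profile <- function(nucleosomes, genes, chrom_lengths,
                                   upstream = 500L, downstream = 500L,
                                   bin = 10L, label = "bulk",
                                   normalize = c("raw", "zscore"),
                                   percent = FALSE) {
  normalize <- match.arg(normalize)
  genes <- check_genes(genes)
  if (nrow(genes) == 0L) abort("Empty gene set.")
  nuc <- check_nucleosomes(nucleosomes)
  if (!label %in% nucleosome_labels) {
    abort(sprintf("Unknown nucleosome label '%s'.", label))
  }
  nuc <- nuc[nuc$label == label, ]
  span <- upstream + downstream
  if (span %% bin != 0) abort("upstream + downstream must be a multiple of bin.")
  cov <- occupancy_coverage(nuc, chrom_lengths)
  offsets <- seq(-upstream, downstream - 1L)
  n_bins <- span %/% bin
  acc <- matrix(NA_real_, nrow = nrow(genes), ncol = n_bins)
  dropped <- 0L
  for (i in seq_len(nrow(genes))) {
    v <- cov[[genes$chrom[i]]]
    if (is.null(v)) { dropped <- dropped + 1L; next }
    tss <- genes$tss[i]
    pos <- if (genes$strand[i] == "+") tss + offsets else tss - offsets
    if (min(pos) < 0L || max(pos) >= length(v)) { dropped <- dropped + 1L; next }
    occ <- v[pos + 1L]
    acc[i, ] <- colMeans(matrix(occ, nrow = bin))
  }
  value <- colMeans(acc, na.rm = TRUE)
  value[is.nan(value)] <- NA_real_
  n <- colSums(!is.na(acc))
  if (percent) value <- 100 * value
  prof <- new_meta_profile(
    tibble(offset = seq(-upstream, by = bin, length.out = n_bins),
           value = value, n = n),
    n_genes = nrow(genes) - dropped, n_dropped = dropped,
    statistic = paste0("occupancy_", label))
  if (normalize == "zscore") prof <- zscore_profile(prof)
  prof
}

#' Overlap profile of dynamic (appearing/evicted/fragile) nucleosomes
#'
#' Same computation as [occupancy_meta_profile()] restricted to one dynamic
#' nucleosome label, reported as a mean percentage of overlap.
#'
#' @inheritParams occupancy_meta_profile
#' @param label One of `"appearing"`, `"evicted"`, `"fragile"`.
#' @return A `meta_profile` in percent.
#' @export
dynamic_overlap_profile <- function(nucleosomes, genes, chrom_lengths,
                                    label = c("appearing", "evicted", "fragile"),
                                    upstream = 500L, downstream = 500L,
                                    bin = 10L) {
  label <- match.arg(label)
  occupancy_meta_profile(nucleosomes, genes, chrom_lengths,
                         upstream = upstream, downstream = downstream,
                         bin = bin, label = label, percent = TRUE)
}

#' Enrichment of gene sets among chromatin-remodeler targets
#'
#' For each (remodeler target list, gene set) pair, computes the
#' observed/expected enrichment ratio (genome average corresponds to 1) and a
#' bootstrap p-value from randomised gene sets of the same size.
#'
#' @param sets Named list of gene-id vectors (e.g. `up`, `down`).
#' @param target_lists Named list of remodeler target gene-id vectors.
#' @param universe Character vector of all genes under consideration.
#' @param n_trials Bootstrap trials (default 1000).
#' @param seed Optional integer seed for reproducible p-values.
#' @return Tibble with `remodeler`, `set`, `observed`, `expected`, `ratio`,
#'   `p_value`, `method`, `n_trials`.
#' @export
remodeler_enrichment <- function(sets, target_lists, universe,
                                 n_trials = 1000L, seed = NULL) {
  stopifnot(is.list(sets), is.list(target_lists))
  seeds <- if (is.null(seed)) {
    rep(list(NULL), length(target_lists) * length(sets))
  } else {
    as.list(seed + seq_len(length(target_lists) * length(sets)))
  }
  k <- 0L
  purrr::imap_dfr(target_lists, function(targets, rem) {
    targets <- intersect(targets, universe)
    if (length(targets) == 0L) {
      warn(sprintf("Remodeler '%s' has no targets in the universe; skipped.", rem))
      return(tibble())
    }
    purrr::imap_dfr(sets, function(ids, set_name) {
      k <<- k + 1L
      enr <- relative_enrichment(intersect(ids, universe), targets, universe)
      p <- bootstrap_enrichment(length(intersect(ids, universe)), targets,
                                universe, enr$ratio, n_trials = n_trials,
                                seed = seeds[[k]])
      tibble(remodeler = rem, set = set_name,
             observed = enr$observed, expected = enr$expected,
             ratio = enr$ratio, p_value = p,
             method = "bootstrap", n_trials = n_trials)
    })
  })
}

#' Histone-mark enrichment of a gene subset, per compartment
#'
#' For each histone mark and each compartment (promoter, ORF), compares the
#' subset's scores against the rest of the universe with a Wilcoxon rank-sum
#' test and reports the direction of the median difference and a
#' significance flag at `alpha`.
#'
#' @param marks Tibble with columns `gene_id`, `mark`, `promoter_score`,
#'   `orf_score`.
#' @param subset Character vector of gene ids (proper subset of `universe`).
#' @param universe Character vector of gene ids.
#' @param alpha Significance threshold for the `significant` flag (default
#'   0.001).
#' @param min_coverage Marks scored for less than this fraction of the
#'   subset are skipped with a warning (default 0.5).
#' @return Tibble with `mark`, `compartment`, `p_value`, `direction`
#'   (`enriched`/`depleted`/`none`), `significant`, `n_subset`, `n_background`.
#' @export
histone_mark_enrichment <- function(marks, subset, universe, alpha = 0.001,
                                    min_coverage = 0.5) {
  needed <- c("gene_id", "mark", "promoter_score", "orf_score")
  if (!all(needed %in% names(marks))) {
    abort("`marks` needs columns gene_id, mark, promoter_score, orf_score.")
  }
  subset <- intersect(unique(subset), universe)
  background <- setdiff(unique(universe), subset)
  if (length(background) == 0L) {
    abort("`subset` equals the universe; the background is empty.")
  }
  compartments <- c(promoter = "promoter_score", orf = "orf_score")
  purrr::map_dfr(split(marks, marks$mark), function(m) {
    covered <- sum(subset %in% m$gene_id) / length(subset)
    if (covered < min_coverage) {
      warn(sprintf("Mark '%s' scored for only %.0f%% of the subset; skipped.",
                   m$mark[1], 100 * covered))
      return(tibble())
    }
    purrr::imap_dfr(compartments, function(col, comp) {
      a <- m[[col]][m$gene_id %in% subset]
      b <- m[[col]][m$gene_id %in% background]
      a <- a[!is.na(a)]; b <- b[!is.na(b)]
      p <- wilcoxon_rank_sum(a, b)
      d <- stats::median(a) - stats::median(b)
      tibble(mark = m$mark[1], compartment = comp, p_value = p,
             direction = dplyr::case_when(d > 0 ~ "enriched",
                                          d < 0 ~ "depleted",
                                          TRUE ~ "none"),
             significant = p < alpha,
             n_subset = length(a), n_background = length(b))
    })
  })
}
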