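# Promoter geometry: intergenic promoter intervals, divergent (bidirectional)
# promoter pairs, and TSS-anchored transcription-factor binding-site matrices.
#
# Coordinates are 0-based half-open throughout; the TSS is the first
# transcribed base (start for + genes, end - 1 for - genes).

check_genes <- function(genes, arg = "genes") {
  needed <- c("gene_id", "chrom", "start", "end", "strand")
  missing <- setdiff(needed, names(genes))
  if (length(missing) > 0) {
    abort(sprintf("`%s` is missing column(s): %s.", arg,
                  paste(missing, collapse = ", ")))
  }
  if (!all(genes$strand %in% c("+", "-"))) {
    abort(sprintf("`%s$strand` must be '+' or '-'.", arg))
  }
  if (any(genes$start < 0) || any(genes$end <= genes$start)) {
    abort(sprintf("`%s` intervals must satisfy 0 <= start < end.", arg))
  }
  if (anyDuplicated(genes$gene_id)) {
    abort(sprintf("`%s$gene_id` must be unique.", arg))
  }
  if (!"tss" %in% names(genes)) {
    genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
  }
  genes
}

#' Promoter regions as complete upstream intergenic intervals
#'
#' Assigns each gene the complete intergenic region upstream of its TSS:
#' the interval from the gene's upstream boundary to the nearest boundary
#' (5' or 3' end) of the closest other gene on either strand, clipped at the
#' chromosome edge. Also classifies promoters as bidirectional when the gene
#' belongs to a divergent pair (see [find_bidirectional_pairs()]).
#'
#' @param genes Gene annotation tibble (`gene_id`, `chrom`, `start`, `end`,
#'   `strand`; 0-based half-open).
#' @param chrom_lengths Named integer vector of chromosome lengths, used to
#'   clip promoters at chromosome ends. When omitted promoters are clipped at
#'   coordinate 0 / the maximum annotated coordinate of the chromosome.
#' @param max_span Maximum TSS-to-TSS span for a divergent pair (default
#'   600 bp).
#' @return Tibble with `gene_id`, `chrom`, `start`, `end`, `length`, `kind`
#'   (`unidirectional`/`bidirectional`) and `partner`.
#' @export
promoter_regions <- function(genes, chrom_lengths = NULL, max_span = 600L) {
  genes <- check_genes(genes)
  pairs <- find_bidirectional_pairs(genes, max_span = max_span)
  partner <- c(setNames(pairs$gene_plus, pairs$gene_minus),
               setNames(pairs$gene_minus, pairs$gene_plus))

  out <- purrr::map_dfr(split(genes, genes$chrom), function(g) {
    g <- arrange(g, .data$start)
    len_chrom <- if (!is.null(chrom_lengths)) {
      unname(chrom_lengths[[g$chrom[1]]])
    } else {
      max(g$end)
    }
    bounds <- sort(c(g$start, g$end))
    owner <- order(c(g$start, g$end)) # index into c(starts, ends)
    n <- nrow(g)
    res <- purrr::map_dfr(seq_len(n), function(i) {
      other <- setdiff(seq_len(n), i)
      ob <- sort(c(g$start[other], g$end[other]))
      if (g$strand[i] == "+") {
        cand <- ob[ob <= g$start[i]]
        a <- if (length(cand) > 0) max(cand) else 0L
        tibble(start = a, end = g$start[i])
      } else {
        cand <- ob[ob >= g$end[i]]
        b <- if (length(cand) > 0) min(cand) else len_chrom
        tibble(start = g$end[i], end = min(b, len_chrom))
      }
    })
    tibble(gene_id = g$gene_id, chrom = g$chrom[1],
           start = pmax(0L, res$start), end = res$end)
  })
  out %>%
    mutate(
      length = pmax(0L, .data$end - .data$start),
      partner = unname(partner[.data$gene_id]),
      kind = dplyr::if_else(is.na(.data$partner),
                            "unidirectional", "bidirectional")
    ) %>%
    select("gene_id", "chrom", "start", "end", "length", "kind", "partner")
}

#' Divergent gene pairs sharing a bidirectional promoter
#'
#' Finds adjacent gene pairs transcribed divergently (the left gene on the
#' minus strand, the right gene on the plus strand, with no gene between
#' them) whose TSS-to-TSS span does not exceed `max_span`. Each gene appears
#' in at most one pair.
#'
#' @param genes Gene annotation tibble.
#' @param max_span Maximum TSS-to-TSS distance (default 600 bp).
#' @return Tibble with `chrom`, `gene_minus`, `gene_plus`, `span`.
#' @export
find_bidirectional_pairs <- function(genes, max_span = 600L) {
  genes <- check_genes(genes)
  purrr::map_dfr(split(genes, genes$chrom), function(g) {
    g <- arrange(g, .data$start)
    n <- nrow(g)
    if (n < 2L) return(tibble())
    left <- g[-n, ]; right <- g[-1, ]
    span <- right$tss - left$tss
    ok <- left$strand == "-" & right$strand == "+" & span <= max_span & span >= 0
    taken <- logical(n)
    keep <- logical(n - 1L)
    for (i in which(ok)) {
      if (!taken[i] && !taken[i + 1L]) {
        keep[i] <- TRUE
        taken[i] <- taken[i + 1L] <- TRUE
      }
    }
    tibble(chrom = g$chrom[1],
           gene_minus = left$gene_id[keep],
           gene_plus = right$gene_id[keep],
           span = span[keep])
  })
}

#' TSS-anchored binding-site count matrix per transcription factor
#'
#' Counts transcription-factor binding sites in strand-oriented bins around
#' the TSS of a gene set, producing one row per factor. Site positions are
#' taken as interval midpoints. Offsets are gene-oriented (negative =
#' upstream) and binned half-open: bin k covers offsets
#' `[-upstream + k*bin_size, -upstream + (k+1)*bin_size)`.
#'
#' @param tfbs Tibble of binding sites with columns `factor`, `chrom`,
#'   `start`, `end` (0-based half-open).
#' @param genes Gene annotation tibble defining the gene set.
#' @param upstream,downstream Window bounds around the TSS (defaults 500 and
#'   300 bp, giving 40 bins of 20 bp).
#' @param bin_size Bin width in bp (default 20).
#' @param normalize `"raw"` counts (default) or `"zscore"` per-factor rows;
#'   zero-variance rows are left raw and flagged in attribute `flat_rows`.
#' @return A `tfbs_matrix`: factors x bins numeric matrix with bin-start
#'   offsets as column names and attributes `bin_size`, `region`,
#'   `normalization`, `n_genes`.
#' @export
tfbs_bin_matrix <- function(tfbs, genes, upstream = 500L, downstream = 300L,
                            bin_size = 20L, normalize = c("raw", "zscore")) {
  normalize <- match.arg(normalize)
  genes <- check_genes(genes)
  needed <- c("factor", "chrom", "start", "end")
  if (!all(needed %in% names(tfbs))) {
    abort("`tfbs` needs columns factor, chrom, start, end.")
  }
  span <- upstream + downstream
  if (span %% bin_size != 0) {
    abort("upstream + downstream must be a multiple of bin_size.")
  }
  n_bins <- span %/% bin_size
  offsets <- seq(-upstream, by = bin_size, length.out = n_bins)
  factors <- sort(unique(tfbs$factor))
  mat <- matrix(0, nrow = length(factors), ncol = n_bins,
                dimnames = list(factors, offsets))
  if (nrow(tfbs) > 0 && nrow(genes) > 0) {
    mid <- floor((tfbs$start + tfbs$end - 1) / 2)
    for (ch in intersect(unique(genes$chrom), unique(tfbs$chrom))) {
      gi <- genes[genes$chrom == ch, ]
      si <- which(tfbs$chrom == ch)
      # gene x site oriented offsets
      off <- outer(gi$tss, mid[si], function(t, p) p - t)
      off[gi$strand == "-", ] <- -off[gi$strand == "-", , drop = FALSE]
      inside <- off >= -upstream & off < downstream
      if (!any(inside)) next
      idx <- which(inside, arr.ind = TRUE)
      bins <- (off[inside] + upstream) %/% bin_size + 1L
      fac <- match(tfbs$factor[si[idx[, 2]]], factors)
      for (j in seq_along(bins)) {
        mat[fac[j], bins[j]] <- mat[fac[j], bins[j]] + 1
      }
    }
  }
  flat <- character()
  if (normalize == "zscore") {
    for (f in rownames(mat)) {
      s <- sqrt(mean((mat[f, ] - mean(mat[f, ]))^2))
      if (s == 0) flat <- c(flat, f) else mat[f, ] <- zscore(mat[f, ])
    }
  }
  structure(mat, class = c("tfbs_matrix", "matrix", "array"),
            bin_size = bin_size, region = c(-upstream, downstream),
            normalization = normalize, n_genes = nrow(genes),
            flat_rows = flat)
}

#' @export
print.tfbs_matrix <- function(x, ...) {
  cat(sprintf("TFBS bin matrix: %d factors x %d bins of %d bp, region %d..%d, %s\n",
              nrow(x), ncol(x), attr(x, "bin_size"),
              attr(x, "region")[1], attr(x, "region")[2],
              attr(x, "normalization")))
  print(unclass(x)[seq_len(min(6, nrow(x))), seq_len(min(8, ncol(x))), drop = FALSE])
  invisible(x)
}
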