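# Genomic run-on (GRO) processing: genomic-DNA normalization, outlier
# filtering, replicate merging, ratio classification and ESR subtraction.

gro_strains <- c("control", "mutant")

check_gro_table <- function(gro, arg = "gro") {
  needed <- c("gene_id", "strain", "replicate", "signal", "gdna_signal")
  missing <- setdiff(needed, names(gro))
  if (length(missing) > 0) {
    abort(sprintf("`%s` is missing column(s): %s.", arg,
                  paste(missing, collapse = ", ")))
  }
  bad <- setdiff(unique(gro$strain), gro_strains)
  if (length(bad) > 0) {
    abort(sprintf("`%s$strain` must be one of %s (found: %s).", arg,
                  paste(gro_strains, collapse = "/"),
                  paste(bad, collapse = ", ")))
  }
  if (any(gro$signal < 0, na.rm = TRUE)) {
    abort(sprintf("`%s$signal` must be non-negative.", arg))
  }
  invisible(gro)
}

#' Normalize GRO signals by the genomic-DNA signal of each array
#'
#' Divides every gene signal by the genomic-DNA (gDNA) hybridisation signal
#' of its array. The gDNA signal may be a per-array scalar (constant within a
#' strain/replicate, the usual case) or probe-wise (varying by gene).
#'
#' @param gro Tibble with columns `gene_id`, `strain`, `replicate`, `signal`
#'   and `gdna_signal`.
#' @return The same tibble with `signal` divided by `gdna_signal` and
#'   `gdna_signal` reset to 1.
#' @export
normalize_signals <- function(gro) {
  check_gro_table(gro)
  bad <- is.na(gro$gdna_signal) | gro$gdna_signal <= 0
  if (any(bad)) {
    off <- dplyr::distinct(gro[bad, ], .data$strain, .data$replicate)
    abort(sprintf(
      "Zero or missing gDNA signal for array(s): %s.",
      paste(sprintf("%s/rep%s", off$strain, off$replicate), collapse = ", ")))
  }
  gro %>%
    mutate(signal = .data$signal / .data$gdna_signal, gdna_signal = 1)
}

#' Flag outlier values by a median-absolute-deviation rule
#'
#' A value is retained iff `|x - median(x)| <= k * MAD(x)` where
#' `MAD = median(|x - median(x)|)` is the unscaled median absolute deviation
#' of the vector. When the MAD is zero every value is retained.
#'
#' @param x Numeric vector (at least one value).
#' @param k MAD multiplier (default 3).
#' @return Logical vector, `TRUE` for retained values. The fraction discarded
#'   is attached as attribute `discard_frac`.
#' @export
filter_outliers <- function(x, k = 3) {
  if (length(x) < 1L) abort("`x` must have at least one value.")
  if (k <= 0) abort("`k` must be positive.")
  med <- stats::median(x)
  mad_u <- stats::median(abs(x - med))
  keep <- if (mad_u == 0) rep(TRUE, length(x)) else abs(x - med) <= k * mad_u
  keep[is.na(keep)] <- FALSE
  structure(keep, discard_frac = mean(!keep))
}

# Pooled-scale outlier rule: deviations of log-signals from each gene's
# per-strain mean, compared against k * MAD of all such deviations in the
# strain's replicate set. With few replicates a per-gene MAD degenerates
# (it reduces to the smaller of two spacings), so the pooled scale is what
# keeps the discard rate at the few-per-mille level expected of consistent
# replicates.
filter_outliers_pooled <- function(gro, k = 4) {
  gro %>%
    group_by(.data$strain) %>%
    mutate(.res = {
      lg <- log(pmax(.data$signal, .Machine$double.xmin))
      lg - stats::ave(lg, .data$gene_id, FUN = mean)
    }) %>%
    mutate(.retain = {
      mad_u <- stats::median(abs(.data$.res))
      if (mad_u == 0) rep(TRUE, dplyr::n()) else abs(.data$.res) <= k * mad_u
    }) %>%
    ungroup() %>%
    select(-".res")
}

#' Merge replicate values into a mean, requiring a minimum number of values
#'
#' @param x Numeric vector of retained replicate values for one gene/strain.
#' @param min_valid Minimum number of valid replicates needed to report a
#'   mean (default 2).
#' @return One-row tibble with `mean` (NA when excluded), `n_valid` and
#'   `excluded`.
#' @export
merge_replicates <- function(x, min_valid = 2L) {
  x <- x[!is.na(x)]
  n_valid <- length(x)
  if (n_valid < min_valid) {
    tibble(mean = NA_real_, n_valid = n_valid, excluded = TRUE)
  } else {
    tibble(mean = mean(x), n_valid = n_valid, excluded = FALSE)
  }
}

#' Classify mutant/control transcription-rate ratios
#'
#' Strict thresholds: a gene is `up` when its ratio exceeds `up_threshold`,
#' `down` when below `down_threshold`, otherwise `unchanged`.
#'
#' @param ratio Numeric vector of positive mutant/control ratios; NA is
#'   mapped to `excluded`.
#' @param up_threshold,down_threshold Fold-change cut-offs (defaults 1.5 and
#'   0.65, strict inequalities).
#' @return Character vector with values `up`, `down`, `unchanged`, `excluded`.
#' @export
classify_change <- function(ratio, up_threshold = 1.5, down_threshold = 0.65) {
  if (any(ratio <= 0, na.rm = TRUE)) {
    abort("Ratios must be positive (use NA for excluded genes).")
  }
  dplyr::case_when(
    is.na(ratio) ~ "excluded",
    ratio > up_threshold ~ "up",
    ratio < down_threshold ~ "down",
    TRUE ~ "unchanged"
  )
}

#' Per-gene transcription-rate changes from a GRO replicate table
#'
#' Runs the whole differential-transcription stage: gDNA normalization,
#' outlier filtering, replicate merging per strain (a gene is excluded unless
#' both strains retain at least `min_valid` replicates), ratio-of-means
#' computation and threshold classification.
#'
#' @param gro GRO tibble (`gene_id`, `strain`, `replicate`, `signal`,
#'   `gdna_signal`).
#' @param up_threshold,down_threshold Fold-change cut-offs, see
#'   [classify_change()].
#' @param min_valid Minimum valid replicates per strain (default 2).
#' @param outlier_k MAD multiplier for the outlier rule (default 4 for the
#'   pooled scope, 3 is conventional for the per-gene scope).
#' @param outlier_scope `"sample_set"` (default) pools log-signal deviations
#'   within each strain's replicate set and discards values beyond
#'   `outlier_k` pooled MADs; `"per_gene"` applies [filter_outliers()] to each
#'   gene's replicate vector independently; `"none"` disables filtering.
#' @param max_discard_frac Sanity cap on the discarded fraction (default
#'   0.02); exceeding it raises a warning, not an error.
#' @param normalize Whether to apply [normalize_signals()] first (default
#'   TRUE).
#' @return A `gro_changes` object: tibble with `gene_id`, `ratio`,
#'   `n_valid_control`, `n_valid_mutant`, `status`, plus attributes
#'   `discard_frac` and the thresholds used.
#' @export
transcription_changes <- function(gro,
                                  up_threshold = 1.5, down_threshold = 0.65,
                                  min_valid = 2L,
                                  outlier_k = NULL,
                                  outlier_scope = c("sample_set", "per_gene", "none"),
                                  max_discard_frac = 0.02,
                                  normalize = TRUE) {
  outlier_scope <- match.arg(outlier_scope)
  outlier_k <- outlier_k %||% if (outlier_scope == "per_gene") 3 else 4
  check_gro_table(gro)
  if (normalize) gro <- normalize_signals(gro)

  gro <- switch(outlier_scope,
    none = mutate(gro, .retain = TRUE),
    sample_set = filter_outliers_pooled(gro, k = outlier_k),
    per_gene = gro %>%
      group_by(.data$gene_id, .data$strain) %>%
      mutate(.retain = as.logical(filter_outliers(.data$signal, k = outlier_k))) %>%
      ungroup()
  )
  discard_frac <- mean(!gro$.retain)
  if (discard_frac > max_discard_frac) {
    warn(sprintf(
      "Outlier filter discarded %.1f%% of values (cap %.1f%%); inspect replicate quality.",
      100 * discard_frac, 100 * max_discard_frac))
  }

  merged <- gro %>%
    filter(.data$.retain) %>%
    group_by(.data$gene_id, .data$strain) %>%
    summarise(mean = mean(.data$signal), n_valid = dplyr::n(), .groups = "drop") %>%
    mutate(excluded = .data$n_valid < min_valid)

  all_ids <- unique(gro$gene_id)
  wide <- tidyr::pivot_wider(
    merged,
    id_cols = "gene_id",
    names_from = "strain",
    values_from = c("mean", "n_valid", "excluded"),
    values_fill = list(n_valid = 0L, excluded = TRUE)
  )
  for (col in c("mean_control", "mean_mutant")) {
    if (!col %in% names(wide)) wide[[col]] <- NA_real_
  }
  for (col in c("n_valid_control", "n_valid_mutant")) {
    if (!col %in% names(wide)) wide[[col]] <- 0L
  }
  for (col in c("excluded_control", "excluded_mutant")) {
    if (!col %in% names(wide)) wide[[col]] <- TRUE
  }
  out <- tibble(gene_id = all_ids) %>%
    left_join(wide, by = "gene_id") %>%
    mutate(
      n_valid_control = dplyr::coalesce(.data$n_valid_control, 0L),
      n_valid_mutant = dplyr::coalesce(.data$n_valid_mutant, 0L),
      ratio = dplyr::if_else(
        dplyr::coalesce(.data$excluded_control, TRUE) |
          dplyr::coalesce(.data$excluded_mutant, TRUE) |
          dplyr::coalesce(.data$mean_control, 0) <= 0,
        NA_real_,
        .data$mean_mutant / .data$mean_control
      ),
      status = classify_change(.data$ratio, up_threshold, down_threshold)
    ) %>%
    select("gene_id", "ratio", "n_valid_control", "n_valid_mutant", "status")

  structure(out,
            class = c("gro_changes", class(out)),
            up_threshold = up_threshold,
            down_threshold = down_threshold,
            discard_frac = discard_frac)
}

#' Deregulated gene sets, raw and after ESR subtraction
#'
#' Builds the up/down gene sets from classified transcription changes and
#' removes genes that belong to the environmental-stress-response (ESR)
#' lists, leaving the sets strictly attributable to the perturbation.
#'
#' @param changes A `gro_changes` object (or tibble with `gene_id`, `status`).
#' @param esr_up,esr_down Character vectors of ESR-induced / ESR-repressed
#'   gene ids (may be empty).
#' @return A `deregulated_sets` list with components `up_raw`, `down_raw`,
#'   `up_strict`, `down_strict`, `universe` (all non-excluded genes) and
#'   `esr_overlap` (fraction of each raw set removed).
#' @export
subtract_esr <- function(changes, esr_up = character(), esr_down = character()) {
  if (is.data.frame(changes)) {
    up_raw <- changes$gene_id[changes$status == "up"]
    down_raw <- changes$gene_id[changes$status == "down"]
    universe <- changes$gene_id[changes$status != "excluded"]
  } else {
    abort("`changes` must be a data frame from transcription_changes().")
  }
  up_strict <- setdiff(up_raw, esr_up)
  down_strict <- setdiff(down_raw, esr_down)
  overlap <- c(
    up = if (length(up_raw) > 0) 1 - length(up_strict) / length(up_raw) else 0,
    down = if (length(down_raw) > 0) 1 - length(down_strict) / length(down_raw) else 0
  )
  structure(
    list(up_raw = up_raw, down_raw = down_raw,
         up_strict = up_strict, down_strict = down_strict,
         universe = universe, esr_overlap = overlap),
    class = "deregulated_sets")
}

#' @export
print.deregulated_sets <- function(x, ...) {
  cat("Deregulated gene sets\n")
  cat(sprintf("  up:   %d raw, %d after ESR subtraction (%.0f%% overlap)\n",
              length(x$up_raw), length(x$up_strict), 100 * x$esr_overlap[["up"]]))
  cat(sprintf("  down: %d raw, %d after ESR subtraction (%.0f%% overlap)\n",
              length(x$down_raw), length(x$down_strict), 100 * x$esr_overlap[["down"]]))
  cat(sprintf("  universe: %d genes\n", length(x$universe)))
  invisible(x)
}

#' Pairwise Pearson concordance of replicates
#'
#' Computes all pairwise Pearson correlations between replicate arrays of
#' each strain on normalized signals, over the genes present in both
#' replicates of a pair.
#'
#' @param gro GRO tibble; normalized first unless `normalize = FALSE`.
#' @param normalize Apply [normalize_signals()] first (default TRUE).
#' @return Tibble with `strain`, `rep_a`, `rep_b`, `pearson_r` covering every
#'   ordered pair including the diagonal (r = 1).
#' @export
replicate_concordance <- function(gro, normalize = TRUE) {
  check_gro_table(gro)
  if (normalize) gro <- normalize_signals(gro)
  purrr::map_dfr(split(gro, gro$strain), function(g) {
    wide <- tidyr::pivot_wider(g, id_cols = "gene_id",
                               names_from = "replicate", values_from = "signal")
    reps <- setdiff(names(wide), "gene_id")
    if (length(reps) < 2L) abort("Need at least two replicates per strain.")
    grid <- expand.grid(rep_a = reps, rep_b = reps, stringsAsFactors = FALSE)
    grid$pearson_r <- purrr::map2_dbl(grid$rep_a, grid$rep_b, function(a, b) {
      ok <- !is.na(wide[[a]]) & !is.na(wide[[b]])
      if (sum(ok) < 2L) abort("Fewer than two genes shared between replicates.")
      stats::cor(wide[[a]][ok], wide[[b]][ok])
    })
    tibble(strain = g$strain[1], as_tibble(grid))
  })
}
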