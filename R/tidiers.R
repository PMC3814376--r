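# broom-style tidiers for the package's result objects.

#' Tidy a transcription-changes object
#'
#' @param x A `gro_changes` object.
#' @param ... Unused.
#' @return The per-gene tibble (`gene_id`, `ratio`, `n_valid_control`,
#'   `n_valid_mutant`, `status`).
#' @export
tidy.gro_changes <- function(x, ...) {
  as_tibble(x)
}

#' One-row summary of a transcription-changes object
#'
#' @param x A `gro_changes` object.
#' @param ... Unused.
#' @return Tibble with gene counts per status, the thresholds used and the
#'   fraction of replicate values discarded by the outlier filter.
#' @export
glance.gro_changes <- function(x, ...) {
  tibble(
    n_genes = nrow(x),
    n_up = sum(x$status == "up"),
    n_down = sum(x$status == "down"),
    n_unchanged = sum(x$status == "unchanged"),
    n_excluded = sum(x$status == "excluded"),
    up_threshold = attr(x, "up_threshold"),
    down_threshold = attr(x, "down_threshold"),
    discard_frac = attr(x, "discard_frac")
  )
}

#' Tidy a deregulated-sets object
#'
#' @param x A `deregulated_sets` object.
#' @param ... Unused.
#' @return Long tibble with `set` (`up`/`down`), `filter` (`raw`/`strict`)
#'   and `gene_id`.
#' @export
tidy.deregulated_sets <- function(x, ...) {
  bind_rows(
    tibble(set = "up", filter = "raw", gene_id = x$up_raw),
    tibble(set = "down", filter = "raw", gene_id = x$down_raw),
    tibble(set = "up", filter = "strict", gene_id = x$up_strict),
    tibble(set = "down", filter = "strict", gene_id = x$down_strict)
  )
}

#' One-row summary of a deregulated-sets object
#'
#' @param x A `deregulated_sets` object.
#' @param ... Unused.
#' @return Tibble of set sizes and ESR overlap fractions.
#' @export
glance.deregulated_sets <- function(x, ...) {
  tibble(
    n_up_raw = length(x$up_raw), n_down_raw = length(x$down_raw),
    n_up_strict = length(x$up_strict), n_down_strict = length(x$down_strict),
    n_universe = length(x$universe),
    esr_overlap_up = x$esr_overlap[["up"]],
    esr_overlap_down = x$esr_overlap[["down"]]
  )
}

#' Tidy a meta-profile
#'
#' @param x A `meta_profile`.
#' @param ... Unused.
#' @return Tibble with `offset`, `value`, `n` plus `statistic` and
#'   `normalization` columns.
#' @export
tidy.meta_profile <- function(x, ...) {
  as_tibble(x) %>%
    mutate(statistic = attr(x, "statistic"),
           normalization = attr(x, "normalization"))
}

#' One-row summary of a meta-profile
#'
#' @param x A `meta_profile`.
#' @param ... Unused.
#' @return Tibble with the number of genes, dropped genes, and the offsets of
#'   the profile's maximum and minimum.
#' @export
glance.meta_profile <- function(x, ...) {
  ok <- !is.na(x$value)
  tibble(
    n_genes = attr(x, "n_genes"),
    n_dropped = attr(x, "n_dropped"),
    statistic = attr(x, "statistic"),
    offset_max = x$offset[ok][which.max(x$value[ok])],
    offset_min = x$offset[ok][which.min(x$value[ok])]
  )
}

#' Tidy a TFBS bin matrix
#'
#' @param x A `tfbs_matrix`.
#' @param ... Unused.
#' @return Long tibble with `factor`, `offset` (bin start, gene-oriented)
#'   and `count`.
#' @export
tidy.tfbs_matrix <- function(x, ...) {
  m <- unclass(x)
  attributes(m) <- attributes(m)[c("dim", "dimnames")]
  tibble(
    factor = rep(rownames(m), times = ncol(m)),
    offset = rep(as.integer(colnames(m)), each = nrow(m)),
    count = as.vector(m)
  )
}
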