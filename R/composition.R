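# Sequence-composition profiles around the TSS: GC content, Chargaff
# second-parity-rule (PR2) skews, and conservation-track meta-profiles.

count_base <- function(chars, base) cumsum(chars == base)

window_counts <- function(cum, starts, window) {
  # starts are 0-based; cum has a leading 0
  cum[starts + window + 1L] - cum[starts + 1L]
}

#' Sliding-window sequence composition
#'
#' Computes GC fraction or PR2 skews -- `(A - T)/(A + T)`, `(G - C)/(G + C)`
#' -- in sliding windows along a sequence. Each window's value is assigned to
#' its centre position; windows with a zero denominator yield 0 and are
#' flagged.
#'
#' @param sequence A single DNA string over A/C/G/T (case-insensitive).
#' @param window Window width in bases (default 100).
#' @param step Step between window starts (default 1).
#' @param statistic One of `"gc_fraction"`, `"at_skew"`, `"gc_skew"`.
#' @return Tibble with `center` (0-based position of the window centre,
#'   `start + (window - 1) %/% 2`), `value`, and `flag` (TRUE where a zero
#'   denominator forced the value to 0).
#' @export
sliding_composition <- function(sequence, window = 100L, step = 1L,
                                statistic = c("gc_fraction", "at_skew", "gc_skew")) {
  statistic <- match.arg(statistic)
  n <- nchar(sequence)
  if (n < window) abort("Sequence is shorter than the window.")
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  starts <- seq(0L, n - window, by = step) # 0-based window starts
  cs <- list(A = c(0, count_base(chars, "A")), C = c(0, count_base(chars, "C")),
             G = c(0, count_base(chars, "G")), T = c(0, count_base(chars, "T")))
  wc <- function(b) window_counts(cs[[b]], starts, window)
  a <- wc("A"); cc <- wc("C"); g <- wc("G"); tt <- wc("T")
  res <- switch(statistic,
    gc_fraction = list(num = g + cc, den = rep(window, length(starts))),
    at_skew = list(num = a - tt, den = a + tt),
    gc_skew = list(num = g - cc, den = g + cc)
  )
  flag <- res$den == 0
  value <- ifelse(flag, 0, res$num / ifelse(flag, 1, res$den))
  tibble(center = starts + (window - 1L) %/% 2L, value = value, flag = flag)
}

# Full-length composition track: value at each 0-based position, NA where no
# complete window is centred there. Centre convention start + (w - 1) %/% 2;
# the complementary offset (w - 1) - (w - 1) %/% 2 is needed for exact
# minus-strand window correspondence (see tss offsets below).
composition_track <- function(sequence, window = 100L, statistic = "gc_fraction") {
  n <- nchar(sequence)
  out <- rep(NA_real_, n)
  sc <- sliding_composition(sequence, window = window, step = 1L,
                            statistic = statistic)
  out[sc$center + 1L] <- sc$value
  out
}

#' TSS-anchored meta-profile of a per-base track
#'
#' Extracts, for every gene, the track values over a window around its TSS in
#' gene orientation (minus-strand windows are reversed; sign-flipping is
#' available for strand-antisymmetric statistics such as PR2 skews), then
#' averages position-wise over genes. Genes whose window does not fit their
#' chromosome are dropped and counted.
#'
#' @param track Named list of per-chromosome numeric vectors; element `i` of
#'   a vector holds the value at 0-based position `i - 1`. Missing values are
#'   NA and are ignored in the averaging (mean over present values).
#' @param genes Gene annotation tibble.
#' @param upstream,downstream Window half-extents in bp around the TSS
#'   (offsets `-upstream .. downstream` inclusive).
#' @param flip_sign Negate values of minus-strand genes (TRUE for skew
#'   statistics, where strand complementation negates A - T and G - C).
#' @param center_shift Extra index shift applied to minus-strand extraction
#'   so that even-width window centres correspond across strands; pass
#'   the track's centre asymmetry (0 for odd windows).
#' @param statistic Label stored on the profile (free text).
#' @return A `meta_profile` tibble with `offset`, `value`, `n` (genes
#'   contributing at each offset) and attributes `n_genes`, `n_dropped`,
#'   `statistic`.
#' @export
tss_meta_profile <- function(track, genes, upstream = 500L, downstream = 500L,
                             flip_sign = FALSE, center_shift = 0L,
                             statistic = "track") {
  genes <- check_genes(genes)
  if (nrow(genes) == 0L) abort("Empty gene set.")
  if (!is.list(track) || is.null(names(track))) {
    abort("`track` must be a named list of per-chromosome numeric vectors.")
  }
  offsets <- seq(-upstream, downstream)
  acc <- matrix(NA_real_, nrow = nrow(genes), ncol = length(offsets))
  dropped <- 0L
  for (i in seq_len(nrow(genes))) {
    ch <- genes$chrom[i]
    v <- track[[ch]]
    if (is.null(v)) { dropped <- dropped + 1L; next }
    tss <- genes$tss[i]
    if (genes$strand[i] == "+") {
      pos <- tss + offsets
    } else {
      pos <- tss - offsets - center_shift
    }
    if (min(pos) < 0L || max(pos) >= length(v)) { dropped <- dropped + 1L; next }
    vals <- v[pos + 1L]
    if (flip_sign && genes$strand[i] == "-") vals <- -vals
    acc[i, ] <- vals
  }
  value <- colMeans(acc, na.rm = TRUE)
  value[is.nan(value)] <- NA_real_
  n <- colSums(!is.na(acc))
  new_meta_profile(tibble(offset = offsets, value = value, n = n),
                   n_genes = nrow(genes) - dropped, n_dropped = dropped,
                   statistic = statistic)
}

new_meta_profile <- function(df, n_genes, n_dropped = 0L, statistic = "track",
                             normalization = "raw") {
  structure(df, class = c("meta_profile", class(tibble())),
            n_genes = n_genes, n_dropped = n_dropped,
            statistic = statistic, normalization = normalization)
}

#' @export
print.meta_profile <- function(x, ...) {
  cat(sprintf("TSS meta-profile (%s, %s): offsets %d..%d, %d genes (%d dropped)\n",
              attr(x, "statistic"), attr(x, "normalization"),
              min(x$offset), max(x$offset),
              attr(x, "n_genes"), attr(x, "n_dropped")))
  NextMethod()
}

#' Z-score normalise a meta-profile
#'
#' @param profile A `meta_profile`.
#' @return The profile with `value` standardised (population convention).
#'   A constant profile cannot be standardised and raises an error.
#' @export
zscore_profile <- function(profile) {
  p <- profile
  p$value <- zscore(p$value)
  attr(p, "normalization") <- "zscore"
  p
}

#' Sequence-composition meta-profile around the TSS
#'
#' Runs [sliding_composition()] over each chromosome and averages the values
#' around gene TSSs in gene orientation. Skew statistics are sign-flipped on
#' minus-strand genes so that profiles read 5' to 3' along the gene.
#'
#' @param genome Named character vector of chromosome sequences.
#' @param genes Gene annotation tibble.
#' @param statistic `"gc_fraction"`, `"at_skew"` or `"gc_skew"`.
#' @param upstream,downstream Window around the TSS (defaults 500/500).
#' @param window Composition window width (default 100).
#' @return A `meta_profile` tibble.
#' @export
composition_meta_profile <- function(genome, genes,
                                     statistic = c("gc_fraction", "at_skew", "gc_skew"),
                                     upstream = 500L, downstream = 500L,
                                     window = 100L) {
  statistic <- match.arg(statistic)
  track <- lapply(genome, composition_track, window = window,
                  statistic = statistic)
  shift <- (window - 1L) - 2L * ((window - 1L) %/% 2L) # 0 for odd windows
  tss_meta_profile(track, genes, upstream = upstream, downstream = downstream,
                   flip_sign = statistic %in% c("at_skew", "gc_skew"),
                   center_shift = shift, statistic = statistic)
}

#' Conservation meta-profile around the TSS
#'
#' Position-wise mean of a per-base conservation track around gene TSSs,
#' orientation-aware. Positions with no track value are treated as absent
#' (not zero): the mean at each offset is over genes with data there.
#'
#' @param track Named list of per-chromosome numeric vectors (NA = missing).
#' @param genes Gene annotation tibble.
#' @param upstream,downstream Window around the TSS.
#' @return A `meta_profile`; a warning is recorded when more than half of the
#'   interrogated positions are missing.
#' @export
conservation_meta_profile <- function(track, genes, upstream = 500L,
                                      downstream = 500L) {
  prof <- tss_meta_profile(track, genes, upstream = upstream,
                           downstream = downstream, statistic = "conservation")
  cov <- sum(prof$n) / (attr(prof, "n_genes") * nrow(prof))
  if (!is.nan(cov) && cov < 0.5) {
    warn(sprintf("Conservation track covers only %.0f%% of interrogated positions.",
                 100 * cov))
  }
  prof
}
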