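# Shared statistical kernel: enrichment ratios, exact tests, bootstrap nulls,
# Z-scores, expression variability, covariate-ordered moving averages.

#' Observed/expected enrichment of a gene class in a subset
#'
#' Computes the ratio of observed over expected members of a gene class
#' falling in a subset of interest, relative to a gene universe. The expected
#' count is `|subset| * |class in universe| / |universe|`.
#'
#' @param subset Character vector of gene ids (must be contained in
#'   `universe`).
#' @param class_set Character vector of gene ids defining the class.
#' @param universe Character vector of all gene ids under consideration.
#' @return A one-row tibble with columns `observed`, `expected` and `ratio`.
#' @export
#' @examples
#' relative_enrichment(letters[1:10], letters[1:4], letters)
relative_enrichment <- function(subset, class_set, universe) {
  subset <- unique(subset)
  universe <- unique(universe)
  if (!all(subset %in% universe)) {
    abort("`subset` must be contained in `universe`.")
  }
  class_in_universe <- intersect(unique(class_set), universe)
  observed <- length(intersect(subset, class_in_universe))
  expected <- length(subset) * length(class_in_universe) / length(universe)
  if (expected == 0) {
    abort("Expected count is zero: class does not intersect the universe (ratio undefined).")
  }
  tibble(observed = observed, expected = expected, ratio = observed / expected)
}

#' Two-sided Fisher exact test for a 2x2 contingency table
#'
#' @param tab A 2x2 matrix of non-negative integer counts.
#' @return Two-sided p-value (probability-ordering convention: the sum of
#'   hypergeometric probabilities of tables no more likely than the observed
#'   one, at fixed margins).
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) {
    abort("`tab` must be a 2x2 matrix.")
  }
  if (any(tab < 0) || any(tab != round(tab)) || any(!is.finite(tab))) {
    abort("`tab` must contain non-negative integer counts.")
  }
  if (sum(tab) == 0) {
    abort("All margins of `tab` are zero; the test is undefined.")
  }
  stats::fisher.test(tab, alternative = "two.sided")$p.value
}

#' Bootstrap p-value for an enrichment ratio
#'
#' Draws `n_trials` random subsets of size `subset_size` from the universe,
#' computes the observed/expected enrichment ratio of `class_set` in each, and
#' reports an add-one-smoothed p-value for the observed ratio's deviation
#' from 1 (two-sided by default: trials are counted when
#' `|ratio_trial - 1| >= |observed_ratio - 1|`).
#'
#' @param subset_size Size of the subset whose enrichment was observed.
#' @param class_set,universe Gene-id vectors as in [relative_enrichment()].
#' @param observed_ratio The enrichment ratio whose significance is assessed.
#' @param n_trials Number of randomised trials (default 1000).
#' @param seed Optional integer seed; when given the computation is
#'   reproducible and leaves the global RNG untouched.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return p-value in (0, 1]; never exactly 0 by add-one smoothing.
#' @export
bootstrap_enrichment <- function(subset_size, class_set, universe,
                                 observed_ratio, n_trials = 1000L,
                                 seed = NULL,
                                 alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  universe <- unique(universe)
  if (subset_size > length(universe)) {
    abort("`subset_size` exceeds the universe size.")
  }
  class_in_universe <- intersect(unique(class_set), universe)
  frac <- length(class_in_universe) / length(universe)
  if (frac == 0) abort("Class does not intersect the universe.")
  expected <- subset_size * frac
  run <- function() {
    hits <- vapply(seq_len(n_trials), function(i) {
      draw <- sample(universe, subset_size, replace = FALSE)
      sum(draw %in% class_in_universe)
    }, numeric(1))
    hits / expected
  }
  ratios <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  extreme <- switch(alternative,
    two.sided = abs(ratios - 1) >= abs(observed_ratio - 1),
    greater   = ratios >= observed_ratio,
    less      = ratios <= observed_ratio
  )
  (1 + sum(extreme)) / (1 + n_trials)
}

#' Wilcoxon rank-sum test with midranks
#'
#' Two-sided rank-sum test of a location difference between two samples.
#' Ties are handled with midranks throughout. For small samples
#' (`length(a) + length(b) <= exact_max`) the p-value is exact, obtained by
#' enumerating all assignments of the pooled (mid)ranks; otherwise a normal
#' approximation with tie correction is used.
#'
#' @param a,b Numeric vectors (each non-empty).
#' @param exact_max Total sample size up to which the exact enumeration is
#'   used (default 12).
#' @return Two-sided p-value. When every value in both groups is identical
#'   the statistic is degenerate and 1 is returned.
#' @export
wilcoxon_rank_sum <- function(a, b, exact_max = 12L) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 1L || length(b) < 1L) abort("Both samples must be non-empty.")
  if (anyNA(a) || anyNA(b)) abort("Samples must not contain missing values.")
  na <- length(a); nb <- length(b); n <- na + nb
  r <- rank(c(a, b))
  w_obs <- sum(r[seq_len(na)])
  mu <- na * (n + 1) / 2
  if (n <= exact_max) {
    sets <- utils::combn(n, na)
    sums <- colSums(matrix(r[sets], nrow = na))
    return(mean(abs(sums - mu) >= abs(w_obs - mu) - 1e-12))
  }
  tie_tab <- table(r)
  sigma2 <- na * nb / 12 * ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
  if (sigma2 <= 0) return(1)
  z <- (w_obs - mu) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(-abs(z)))
}

#' Z-score standardisation (population convention)
#'
#' Subtracts the mean and divides by the population standard deviation
#' (divisor `n`).
#'
#' @param x Numeric vector with at least two values.
#' @return Standardised vector with mean 0 and population sd 1.
#' @export
zscore <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 2L) abort("`x` must have at least two values.")
  ok <- !is.na(x)
  m <- mean(x[ok])
  s <- sqrt(mean((x[ok] - m)^2))
  if (s == 0) abort("`x` has zero variance; Z-score is undefined.")
  (x - m) / s
}

#' Expression variability as a trimmed percentile range
#'
#' Measures a gene's dynamic range of expression across conditions as the
#' absolute difference between the 2nd and 98th percentiles, after discarding
#' values strictly below the 1st percentile and strictly above the 99th
#' percentile to blunt outliers. Percentiles use linear interpolation
#' (`quantile()` type 7).
#'
#' @param x Numeric vector of normalised expression values across conditions
#'   (at least `min_n` values).
#' @param min_n Minimum number of values required (default 10).
#' @return A one-row tibble with columns `range` and `n_conditions`.
#' @export
expression_variability <- function(x, min_n = 10L) {
  x <- as.numeric(x[!is.na(x)])
  if (length(x) < min_n) {
    abort(sprintf("Need at least %d values to score variability (got %d).",
                  min_n, length(x)))
  }
  lims <- stats::quantile(x, c(0.01, 0.99), type = 7, names = FALSE)
  kept <- x[x >= lims[1] & x <= lims[2]]
  qs <- stats::quantile(kept, c(0.02, 0.98), type = 7, names = FALSE)
  tibble(range = abs(qs[2] - qs[1]), n_conditions = length(x))
}

#' Moving average of a response ordered by a covariate
#'
#' Sorts observations by `covariate` and smooths `y` with a `window`-point
#' moving mean. Windows are centred in the interior; at the edges the window
#' either slides (keeps `window` points, default) or shrinks symmetrically.
#'
#' @param y Numeric response.
#' @param covariate Numeric ordering variable, same length as `y`.
#' @param window Number of points per window (default 100).
#' @param edges `"slide"` (default) keeps full-size windows at the edges by
#'   letting them become asymmetric; `"shrink"` shrinks them symmetrically.
#' @return Tibble with `covariate`, `y` and `smoothed`, sorted by covariate.
#' @export
moving_average_by_covariate <- function(y, covariate, window = 100L,
                                        edges = c("slide", "shrink")) {
  edges <- match.arg(edges)
  n <- length(y)
  if (length(covariate) != n) abort("`y` and `covariate` must have the same length.")
  if (window < 1L || window > n) abort("`window` must be between 1 and length(y).")
  ord <- order(covariate)
  ys <- y[ord]
  half_lo <- (window - 1L) %/% 2L
  half_hi <- window - 1L - half_lo
  cs <- cumsum(c(0, ys))
  sm <- vapply(seq_len(n), function(i) {
    if (edges == "slide") {
      lo <- max(1L, i - half_lo)
      hi <- min(n, lo + window - 1L)
      lo <- max(1L, hi - window + 1L)
    } else {
      h <- min(half_lo, i - 1L, n - i)
      lo <- i - h; hi <- i + h
    }
    (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  }, numeric(1))
  tibble(covariate = covariate[ord], y = ys, smoothed = sm)
}
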