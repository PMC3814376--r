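# Nucleosome-forming potential from the symmetry of predicted DNA curvature.
#
# Curvature is predicted with a dinucleotide wedge model: each base step
# deflects the helical axis by a roll angle in a direction that rotates with
# the helical twist; the curvature at a base is the magnitude of the vector
# sum of the deflections in a short window. The symmetry score then asks how
# mirror-symmetric the curvature profile is around a candidate dyad, the
# footprint that the two-fold symmetric histone octamer leaves on nucleosomal
# DNA: S = 1 / (1 + D), with D the mean absolute difference between the two
# flanks read towards the centre.

#' Dinucleotide wedge model for DNA curvature
#'
#' Loads the per-dinucleotide roll angles (degrees per base step) and the
#' helical repeat used by [predict_curvature()]. The bundled default table is
#' the package's own consensus-style scale: A-tract steps are rigid and
#' straight (small roll), pyrimidine-purine steps (TA, CA/TG, CG) are
#' flexible with large roll, and the remaining steps are intermediate. The
#' table is plain TSV and can be replaced; it must list all 16 dinucleotides
#' and be reverse-complement consistent (`roll[XY] == roll[revcomp(XY)]`,
#' which a roll-only wedge geometry requires for the two DNA strands to give
#' the same curvature).
#'
#' @param path Path to a two-column TSV (`dinucleotide`, `roll`); default the
#'   bundled table.
#' @param helical_repeat Helical repeat in bp per turn (default 10.4).
#' @return A `curvature_model` list with `roll` (named numeric vector) and
#'   `helical_repeat`.
#' @export
curvature_model <- function(path = NULL, helical_repeat = 10.4) {
  path <- path %||% system.file("extdata", "curvature_model.tsv",
                                package = "chromarch", mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("dinucleotide", "roll") %in% names(tab))) {
    abort("Curvature model table needs columns 'dinucleotide' and 'roll'.")
  }
  roll <- setNames(tab$roll, toupper(tab$dinucleotide))
  bases <- c("A", "C", "G", "T")
  all16 <- as.vector(outer(bases, bases, paste0))
  if (!setequal(names(roll), all16)) {
    abort("Curvature model must define all 16 dinucleotides exactly once.")
  }
  rc <- function(d) chartr("ACGT", "TGCA", paste(rev(strsplit(d, "")[[1]]), collapse = ""))
  for (d in all16) {
    if (abs(roll[[d]] - roll[[rc(d)]]) > 1e-9) {
      abort(sprintf("Model is not reverse-complement consistent at %s/%s.", d, rc(d)))
    }
  }
  structure(list(roll = roll[all16], helical_repeat = helical_repeat),
            class = "curvature_model")
}

#' Predict DNA curvature along a sequence
#'
#' Sums the dinucleotide wedge deflections with helical phasing over a
#' sliding window and reports the magnitude of the resulting bend per centre
#' base, in model roll units per step. Positions whose window touches an
#' ambiguous base (anything outside A/C/G/T) are masked (NA), as are
#' positions whose window does not fit the sequence.
#'
#' @param sequence A single DNA string.
#' @param model A [curvature_model()].
#' @param window Smoothing window in bases (default 31); the window's
#'   `window - 1` base steps are summed.
#' @return Numeric vector, one value per base, NA where undefined.
#' @export
predict_curvature <- function(sequence, model = curvature_model(), window = 31L) {
  n <- nchar(sequence)
  if (n <= window) abort("Sequence must be longer than the smoothing window.")
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  steps <- paste0(chars[-n], chars[-1]) # n - 1 base steps
  roll <- unname(model$roll[steps]) # NA for ambiguous steps
  phase <- 2 * pi * (seq_len(n - 1L) - 1L) / model$helical_repeat
  x <- roll * cos(phase)
  y <- roll * sin(phase)
  n_steps <- window - 1L
  h1 <- n_steps %/% 2L
  csx <- cumsum(c(0, ifelse(is.na(x), 0, x)))
  csy <- cumsum(c(0, ifelse(is.na(y), 0, y)))
  csna <- cumsum(c(0, is.na(roll)))
  out <- rep(NA_real_, n)
  # window of steps [i - h1, i - h1 + n_steps - 1] (1-based step index)
  first <- seq_len(n) - h1
  last <- first + n_steps - 1L
  ok <- first >= 1L & last <= n - 1L
  fi <- first[ok]; la <- last[ok]
  sx <- csx[la + 1L] - csx[fi]
  sy <- csy[la + 1L] - csy[fi]
  nna <- csna[la + 1L] - csna[fi]
  val <- sqrt(sx^2 + sy^2) / n_steps
  val[nna > 0] <- NA_real_
  out[ok] <- val
  out
}

#' Curvature-symmetry score at nucleotide resolution
#'
#' Scores every position as a candidate nucleosome dyad by the mirror
#' symmetry of the curvature profile around it:
#' `S(i) = 1 / (1 + D(i))` with
#' `D(i) = mean over k of |c(i - k) - c(i + k)|`, k = 1..`half_window`.
#' S lies in (0, 1] and equals 1 exactly when the two flanks are mirror
#' images. Positions whose flanks leave the vector, or touch a masked
#' curvature value, are undefined (NA).
#'
#' @param curvature Numeric vector from [predict_curvature()].
#' @param half_window Flank length in bp (default 73, the nucleosome
#'   half-length).
#' @return Numeric vector of S values, NA where undefined.
#' @export
symcurv_score <- function(curvature, half_window = 73L) {
  n <- length(curvature)
  if (n < 2L * half_window + 1L) {
    abort("Curvature vector shorter than 2 * half_window + 1.")
  }
  acc <- numeric(n)
  nas <- is.na(curvature)
  bad <- nas
  for (k in seq_len(half_window)) {
    left <- c(rep(NA_real_, k), curvature[seq_len(n - k)])
    right <- c(curvature[(k + 1L):n], rep(NA_real_, k))
    d <- abs(left - right)
    bad <- bad | is.na(d)
    acc <- acc + ifelse(is.na(d), 0, d)
  }
  s <- 1 / (1 + acc / half_window)
  s[bad] <- NA_real_
  s
}

#' SymCurv track for a sequence
#'
#' Convenience wrapper computing curvature and its symmetry score.
#'
#' @inheritParams predict_curvature
#' @inheritParams symcurv_score
#' @return Tibble with `position` (0-based), `curvature`, `symcurv`.
#' @export
symcurv_track <- function(sequence, model = curvature_model(), window = 31L,
                          half_window = 73L) {
  curv <- predict_curvature(sequence, model = model, window = window)
  tibble(position = seq_along(curv) - 1L,
         curvature = curv,
         symcurv = symcurv_score(curv, half_window = half_window))
}

#' TSS-anchored meta-profile of nucleosome-forming potential
#'
#' Computes the curvature-symmetry score over each chromosome and averages
#' it around gene TSSs in gene orientation, then Z-score normalises the mean
#' profile. A constant (degenerate) profile cannot be standardised and is
#' returned raw with attribute `degenerate = TRUE`.
#'
#' @param genome Named character vector of chromosome sequences.
#' @param genes Gene annotation tibble.
#' @param upstream,downstream Window around the TSS (defaults 500/500).
#' @param model A [curvature_model()].
#' @param window Curvature smoothing window (default 31).
#' @param half_window Symmetry flank length (default 73).
#' @param zscore Z-score normalise the averaged profile (default TRUE).
#' @return A `meta_profile` tibble.
#' @export
symcurv_meta_profile <- function(genome, genes, upstream = 500L,
                                 downstream = 500L, model = curvature_model(),
                                 window = 31L, half_window = 73L,
                                 zscore = TRUE) {
  track <- lapply(genome, function(s) {
    symcurv_score(predict_curvature(s, model = model, window = window),
                  half_window = half_window)
  })
  prof <- tss_meta_profile(track, genes, upstream = upstream,
                           downstream = downstream, statistic = "symcurv")
  attr(prof, "degenerate") <- FALSE
  if (zscore) {
    vals <- prof$value[!is.na(prof$value)]
    tol <- 1e-8 * max(1, abs(mean(vals))) # numerically constant counts as flat
    if (length(vals) >= 2L && sqrt(mean((vals - mean(vals))^2)) > tol) {
      prof <- zscore_profile(prof)
    } else {
      attr(prof, "degenerate") <- TRUE
    }
  }
  prof
}
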