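# Shared fixtures, built in code. Worlds are cached per option set so that
# test files can reuse them without regenerating.

.world_cache <- new.env(parent = emptyenv())

test_world <- function(seed = 7, ...) {
  key <- paste(seed, paste(deparse(list(...)), collapse = ""), sep = "|")
  if (is.null(.world_cache[[key]])) {
    .world_cache[[key]] <- generate_world(world_config(seed = seed, ...))
  }
  .world_cache[[key]]
}

# minimal strand-aware annotation builder
make_genes <- function(start, end, strand, chrom = "chrI",
                       id = sprintf("g%03d", seq_along(start))) {
  tibble::tibble(gene_id = id, chrom = chrom, start = as.integer(start),
                 end = as.integer(end), strand = strand)
}

# small GRO table builder: signals is a named list gene -> list(control=...,
# mutant=...) vectors; gdna per (strain, replicate) scalar or 1
make_gro <- function(signals, gdna = NULL) {
  rows <- list()
  for (g in names(signals)) {
    for (s in names(signals[[g]])) {
      v <- signals[[g]][[s]]
      for (r in seq_along(v)) {
        gd <- if (is.null(gdna)) 1 else gdna[[s]][r]
        rows[[length(rows) + 1]] <- tibble::tibble(
          gene_id = g, strain = s, replicate = r, signal = v[r],
          gdna_signal = gd)
      }
    }
  }
  dplyr::bind_rows(rows)
}

# independent brute-force two-sided Fisher p by hypergeometric enumeration
# (probability-ordering convention)
fisher_enum <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; cc <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; c1 <- a + cc; n <- a + b + cc + d
  lo <- max(0, r1 + c1 - n); hi <- min(r1, c1)
  ks <- lo:hi
  probs <- vapply(ks, function(k) {
    choose(c1, k) * choose(n - c1, r1 - k) / choose(n, r1)
  }, numeric(1))
  p_obs <- probs[ks == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# brute-force per-bp occupancy oracle for a single gene window
occupancy_oracle <- function(nuc, tss, strand, chrom_len, upstream, downstream, bin) {
  covered <- rep(FALSE, chrom_len)
  for (i in seq_len(nrow(nuc))) {
    lo <- max(0L, nuc$start[i]); hi <- min(chrom_len, nuc$end[i])
    if (hi > lo) covered[(lo + 1L):hi] <- TRUE
  }
  offs <- seq(-upstream, downstream - 1L)
  pos <- if (strand == "+") tss + offs else tss - offs
  occ <- covered[pos + 1L]
  colMeans(matrix(occ, nrow = bin))
}
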