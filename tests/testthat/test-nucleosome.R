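# Nucleosome spacing, occupancy meta-profiles, dynamic overlap, remodeler and
# histone-mark enrichment.

test_that("gene_nucleosome_spacing averages edge-to-edge linkers", {
  genes <- make_genes(start = 0, end = 400, strand = "+")
  nuc <- tibble::tibble(chrom = "chrI",
                        start = c(0L, 168L), end = c(147L, 315L))
  sp <- gene_nucleosome_spacing(genes, nuc)
  expect_equal(sp$mean_spacing, 21)
  expect_true(sp$defined)

  # a single nucleosome leaves the spacing undefined
  sp1 <- gene_nucleosome_spacing(genes, nuc[1, ])
  expect_false(sp1$defined)
  expect_true(is.na(sp1$mean_spacing))

  # gaps of 20 and 40 average to 30
  nuc3 <- tibble::tibble(chrom = "chrI",
                         start = c(0L, 120L, 260L), end = c(100L, 220L, 360L))
  expect_equal(gene_nucleosome_spacing(genes, nuc3)$mean_spacing, 30)
})

test_that("spacing is translation invariant", {
  genes <- make_genes(start = 100, end = 900, strand = "-")
  nuc <- tibble::tibble(chrom = "chrI",
                        start = c(150L, 320L, 500L), end = c(297L, 467L, 647L))
  base <- gene_nucleosome_spacing(genes, nuc)
  shift <- 5000L
  genes2 <- dplyr::mutate(genes, start = start + shift, end = end + shift)
  nuc2 <- dplyr::mutate(nuc, start = start + shift, end = end + shift)
  expect_equal(gene_nucleosome_spacing(genes2, nuc2)$mean_spacing,
               base$mean_spacing)
})

test_that("class-specific linkers are recovered from the synthetic world", {
  w <- test_world(seed = 7)
  sp <- gene_nucleosome_spacing(w$genes, w$nucleosomes)
  by_class <- split(sp$mean_spacing[sp$defined],
                    w$genes$class[match(sp$gene_id[sp$defined], w$genes$gene_id)])
  expect_equal(mean(by_class$down), 21, tolerance = 1 / 21)
  expect_equal(mean(by_class$up), 29, tolerance = 1 / 29)
})

test_that("occupancy_meta_profile matches the per-bp coverage oracle", {
  # tiling nucleosomes give occupancy 1 everywhere, none give 0
  genes <- make_genes(start = 2000, end = 3000, strand = "+")
  lens <- c(chrI = 6000L)
  tiling <- tibble::tibble(chrom = "chrI", start = 0L, end = 6000L)
  expect_true(all(occupancy_meta_profile(tiling, genes, lens)$value == 1))
  none <- tiling[0, ]
  expect_true(all(occupancy_meta_profile(none, genes, lens)$value == 0))

  # random small instances against the brute-force per-bp oracle
  set.seed(53)
  for (rep_i in 1:25) {
    n_nuc <- sample(1:8, 1)
    starts <- sample(1500:3400, n_nuc)
    nuc <- tibble::tibble(chrom = "chrI", start = starts,
                          end = starts + sample(c(100L, 147L), n_nuc, TRUE))
    strand <- sample(c("+", "-"), 1)
    g <- make_genes(start = 2200, end = 3200, strand = strand)
    prof <- occupancy_meta_profile(nuc, g, lens, upstream = 300,
                                   downstream = 300, bin = 10)
    tss <- if (strand == "+") 2200L else 3199L
    oracle <- occupancy_oracle(nuc, tss, strand, 6000L, 300L, 300L, 10L)
    expect_equal(prof$value, unname(oracle), tolerance = 1e-12)
  }
})

test_that("raw occupancy stays in [0,1] and zscored profiles standardise", {
  w <- test_world(seed = 7)
  raw <- occupancy_meta_profile(w$nucleosomes, w$genes, w$chrom_lengths)
  expect_true(all(raw$value >= 0 & raw$value <= 1))
  z <- occupancy_meta_profile(w$nucleosomes, w$genes, w$chrom_lengths,
                              normalize = "zscore")
  expect_equal(mean(z$value), 0, tolerance = 1e-9)
  expect_equal(sqrt(mean(z$value^2)), 1, tolerance = 1e-9)
})

test_that("dynamic_overlap_profile reports percent overlap for one label", {
  genes <- make_genes(start = 2000, end = 3000, strand = "+")
  lens <- c(chrI = 6000L)
  nuc <- tibble::tibble(chrom = "chrI", start = c(1800L, 2000L),
                        end = c(1947L, 2147L),
                        label = c("bulk", "appearing"))
  # an empty label gives 0 percent everywhere
  p_ev <- dynamic_overlap_profile(nuc, genes, lens, label = "evicted")
  expect_true(all(p_ev$value == 0))
  # a label identical to bulk gives the bulk profile times 100
  nuc2 <- dplyr::bind_rows(nuc[1, ],
                           dplyr::mutate(nuc[1, ], label = "fragile"))
  bulk <- occupancy_meta_profile(nuc2, genes, lens)
  frag <- dynamic_overlap_profile(nuc2, genes, lens, label = "fragile")
  expect_equal(frag$value, 100 * bulk$value)
  expect_error(dynamic_overlap_profile(nuc, genes, lens, label = "bulk"))
})

test_that("planted appearing nucleosomes peak just downstream of the TSS", {
  w <- test_world(seed = 7)
  down_genes <- w$genes[w$genes$class == "down", ]
  prof <- dynamic_overlap_profile(w$nucleosomes, down_genes, w$chrom_lengths,
                                  label = "appearing")
  peak <- prof$offset[which.max(prof$value)]
  expect_gte(peak, 0)
  expect_lt(peak, 200)
})

test_that("remodeler_enrichment combines ratios with bootstrap p-values", {
  universe <- sprintf("g%03d", 1:200)
  sets <- list(up = universe[1:20], down = universe[21:40])
  # a target list equal to the universe has ratio 1 and p = 1
  res <- remodeler_enrichment(sets, list(All = universe), universe,
                              n_trials = 100, seed = 2)
  expect_equal(res$ratio, c(1, 1))
  expect_equal(res$p_value, c(1, 1))

  # planted 3x enrichment of the down set in every target list
  set.seed(57)
  targets <- lapply(setNames(1:8, paste0("R", 1:8)), function(i) {
    unique(c(sample(sets$down, 15), sample(universe, 10)))
  })
  res3 <- remodeler_enrichment(sets, targets, universe,
                               n_trials = 400, seed = 11)
  down_rows <- res3[res3$set == "down", ]
  expect_true(all(down_rows$ratio > 1))
  expect_true(all(down_rows$p_value < 0.01))

  # determinism under a fixed seed
  res3b <- remodeler_enrichment(sets, targets, universe,
                                n_trials = 400, seed = 11)
  expect_identical(res3$p_value, res3b$p_value)

  expect_warning(
    remodeler_enrichment(sets, list(Empty = character()), universe,
                         n_trials = 10, seed = 1),
    "no targets")
})

test_that("histone_mark_enrichment recovers planted shifts and guards edge cases", {
  set.seed(59)
  universe <- sprintf("g%03d", 1:400)
  subset <- universe[1:60]
  marks <- tidyr::expand_grid(gene_id = universe,
                              mark = c("H3K9ac", "H3K4me3"))
  marks$promoter_score <- rnorm(nrow(marks))
  marks$orf_score <- rnorm(nrow(marks))
  # plant a -1 sd acetylation shift in the subset
  sel <- marks$gene_id %in% subset & marks$mark == "H3K9ac"
  marks$promoter_score[sel] <- marks$promoter_score[sel] - 1
  marks$orf_score[sel] <- marks$orf_score[sel] - 1

  res <- histone_mark_enrichment(marks, subset, universe)
  ac <- res[res$mark == "H3K9ac", ]
  expect_true(all(ac$direction == "depleted"))
  expect_true(all(ac$significant))
  null_rows <- res[res$mark == "H3K4me3", ]
  expect_true(all(!null_rows$significant))

  expect_error(histone_mark_enrichment(marks, universe, universe), "background")
  expect_warning(
    histone_mark_enrichment(
      dplyr::filter(marks, !(gene_id %in% subset[1:40] & mark == "H3K4me3")),
      subset[1:40], universe),
    "skipped")
})
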