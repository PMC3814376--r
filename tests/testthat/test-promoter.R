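# Promoter geometry, divergent pairs and TFBS bin matrices.

test_that("promoter_regions takes the full upstream intergenic interval", {
  genes <- make_genes(start = c(200, 1000), end = c(700, 2000),
                      strand = c("+", "+"))
  p <- promoter_regions(genes, chrom_lengths = c(chrI = 3000))
  # plus gene at [1000, 2000) with upstream neighbour ending at 700
  expect_equal(p$start[p$gene_id == "g002"], 700)
  expect_equal(p$end[p$gene_id == "g002"], 1000)
  expect_equal(p$length[p$gene_id == "g002"], 300)

  # minus gene at [1000, 2000) with the next gene starting at 2400
  genes2 <- make_genes(start = c(1000, 2400), end = c(2000, 3000),
                       strand = c("-", "+"))
  p2 <- promoter_regions(genes2, chrom_lengths = c(chrI = 4000))
  expect_equal(p2$start[p2$gene_id == "g001"], 2000)
  expect_equal(p2$end[p2$gene_id == "g001"], 2400)
  expect_equal(p2$length[p2$gene_id == "g001"], 400)

  # strand-flip oracle: mirror the plus-gene layout and flip strands;
  # promoter lengths must be identical
  L <- 3000
  mirrored <- make_genes(start = L - c(700, 2000), end = L - c(200, 1000),
                         strand = c("-", "-"))
  pm <- promoter_regions(mirrored, chrom_lengths = c(chrI = L))
  expect_equal(sort(pm$length), sort(p$length))

  # immediately abutting upstream gene gives a zero-length promoter
  genes3 <- make_genes(start = c(0, 500), end = c(500, 900),
                       strand = c("+", "+"))
  p3 <- promoter_regions(genes3, chrom_lengths = c(chrI = 1000))
  expect_equal(p3$length[p3$gene_id == "g002"], 0)
})

test_that("promoters never overlap any annotated gene body", {
  w <- test_world(seed = 7)
  p <- promoter_regions(w$genes, w$chrom_lengths)
  for (ch in unique(w$genes$chrom)) {
    g <- w$genes[w$genes$chrom == ch, ]
    pp <- p[p$chrom == ch & p$length > 0, ]
    for (i in seq_len(nrow(pp))) {
      overlaps <- g$start < pp$end[i] & g$end > pp$start[i]
      expect_length(g$gene_id[overlaps], 0)
    }
  }
})

test_that("find_bidirectional_pairs applies the span limit and orientation", {
  # divergent TSSs 400 bp apart -> pair
  g1 <- make_genes(start = c(100, 1000), end = c(601, 1500),
                   strand = c("-", "+"))
  expect_equal(nrow(find_bidirectional_pairs(g1)), 1)
  # 700 bp apart -> no pair
  g2 <- make_genes(start = c(100, 1300), end = c(601, 1800),
                   strand = c("-", "+"))
  expect_equal(nrow(find_bidirectional_pairs(g2)), 0)
  # convergent orientation -> no pair
  g3 <- make_genes(start = c(100, 1000), end = c(601, 1500),
                   strand = c("+", "-"))
  expect_equal(nrow(find_bidirectional_pairs(g3)), 0)
})

test_that("each gene joins at most one divergent pair and spans respect the limit", {
  w <- test_world(seed = 7)
  pairs <- find_bidirectional_pairs(w$genes)
  ids <- c(pairs$gene_minus, pairs$gene_plus)
  expect_equal(anyDuplicated(ids), 0)
  expect_true(all(pairs$span <= 600))
  expect_true(all(pairs$span >= 0))
})

test_that("tfbs_bin_matrix counts oriented bins and is mirror-invariant", {
  genes <- make_genes(start = 1000, end = 2000, strand = "+")
  empty <- tibble::tibble(factor = character(), chrom = character(),
                          start = integer(), end = integer())
  m0 <- tfbs_bin_matrix(empty, genes)
  expect_equal(sum(m0), 0)
  expect_equal(dim(m0), c(0L, 40L))

  # a site exactly at the TSS lands in the bin containing offset 0
  site <- tibble::tibble(factor = "TF1", chrom = "chrI",
                         start = 1000L, end = 1001L)
  m1 <- tfbs_bin_matrix(site, genes)
  expect_equal(sum(m1), 1)
  hit_bin <- which(m1["TF1", ] == 1)
  expect_equal(as.integer(colnames(m1)[hit_bin]), 0L)

  # mirror construction: flip strands and reflect all coordinates
  set.seed(31)
  L <- 10000L
  genes_f <- make_genes(start = c(2000, 6000), end = c(3000, 7000),
                        strand = c("+", "-"))
  sites_f <- tibble::tibble(
    factor = sample(c("TFa", "TFb"), 30, replace = TRUE),
    chrom = "chrI",
    start = sample(1000:8000, 30))
  sites_f$end <- sites_f$start + 1L
  genes_r <- make_genes(start = L - c(3000, 7000), end = L - c(2000, 6000),
                        strand = c("-", "+"), id = c("g001", "g002"))
  sites_r <- sites_f
  sites_r$start <- L - sites_f$end
  sites_r$end <- L - sites_f$start
  mf <- tfbs_bin_matrix(sites_f, genes_f)
  mr <- tfbs_bin_matrix(sites_r, genes_r)
  expect_equal(unclass(mf), unclass(mr), ignore_attr = TRUE)
})

test_that("zscore normalisation standardises rows and flags flat ones", {
  genes <- make_genes(start = c(1000, 3000), end = c(2000, 4000),
                      strand = c("+", "+"))
  sites <- tibble::tibble(
    factor = c(rep("varying", 3), "flat"),
    chrom = "chrI",
    start = c(900L, 920L, 700L, 50L), end = c(901L, 921L, 701L, 51L))
  m <- tfbs_bin_matrix(sites, genes, normalize = "zscore")
  expect_equal(mean(m["varying", ]), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean(m["varying", ]^2)), 1, tolerance = 1e-12)
  expect_equal(attr(m, "flat_rows"), "flat")
  expect_true(all(m["flat", ] == 0))
})
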