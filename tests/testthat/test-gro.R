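# GRO differential transcription: normalization, outlier filtering,
# replicate merging, classification, ESR subtraction and concordance.

test_that("normalize_signals divides by the array gDNA signal", {
  gro <- make_gro(list(a = list(control = c(100, 100), mutant = c(100, 100))),
                  gdna = list(control = c(2, 4), mutant = c(1, 1)))
  out <- normalize_signals(gro)
  expect_equal(out$signal[out$strain == "control"], c(50, 25))
  expect_equal(out$signal[out$strain == "mutant"], c(100, 100))

  # gdna = 1 everywhere is the identity
  gro1 <- make_gro(list(a = list(control = c(3, 7), mutant = c(1, 9))))
  expect_equal(normalize_signals(gro1)$signal, gro1$signal)

  # hand-computed three-gene table: equal raw signals, gdna 2 vs 4 means
  # the two replicates' normalized means differ by a factor of 2
  gro3 <- make_gro(list(a = list(control = c(10, 10)),
                        b = list(control = c(20, 20)),
                        c = list(control = c(30, 30))),
                   gdna = list(control = c(2, 4)))
  out3 <- normalize_signals(gro3)
  m1 <- mean(out3$signal[out3$replicate == 1])
  m2 <- mean(out3$signal[out3$replicate == 2])
  expect_equal(m1 / m2, 2)

  bad <- make_gro(list(a = list(control = c(1, 1), mutant = c(1, 1))),
                  gdna = list(control = c(1, 0), mutant = c(1, 1)))
  expect_error(normalize_signals(bad), "control/rep2")
})

test_that("filter_outliers applies the unscaled-MAD rule with degenerate guard", {
  expect_true(all(filter_outliers(c(5, 5, 5))))
  keep <- filter_outliers(c(9, 10, 11, 10, 1000), k = 3)
  expect_equal(as.logical(keep), c(TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_equal(attr(keep, "discard_frac"), 0.2)
  # symmetric spread: MAD = 2, deviations <= 2 <= 3 * MAD
  expect_true(all(filter_outliers(c(8, 10, 12), k = 3)))
  expect_error(filter_outliers(numeric(0)), "at least one")
})

test_that("merge_replicates enforces the two-valid-replicate minimum", {
  expect_equal(merge_replicates(c(2, 4)),
               tibble::tibble(mean = 3, n_valid = 2L, excluded = FALSE))
  m1 <- merge_replicates(7)
  expect_true(m1$excluded)
  expect_true(is.na(m1$mean))
  expect_true(merge_replicates(numeric(0))$excluded)
})

test_that("classify_change uses strict thresholds and is monotone in the ratio", {
  expect_equal(classify_change(c(1.6, 1.5, 0.5, 0.65, 1)),
               c("up", "unchanged", "down", "unchanged", "unchanged"))
  expect_error(classify_change(-1), "positive")
  # monotonicity: along an increasing grid the status never steps backwards
  grid <- seq(0.01, 5, by = 0.01)
  status_rank <- c(down = 1, unchanged = 2, up = 3)
  ranks <- status_rank[classify_change(grid)]
  expect_true(all(diff(ranks) >= 0))
})

test_that("subtract_esr removes stress-response genes from the raw sets", {
  ch <- tibble::tibble(gene_id = letters[1:6],
                       status = c("up", "up", "up", "down", "unchanged", "excluded"))
  s0 <- subtract_esr(ch)
  expect_equal(s0$up_strict, s0$up_raw)
  expect_equal(s0$down_strict, s0$down_raw)
  s1 <- subtract_esr(ch, esr_up = "b")
  expect_setequal(s1$up_strict, c("a", "c"))
  expect_equal(length(intersect(s1$up_raw, s1$down_raw)), 0)
  expect_false("f" %in% s1$universe)
})

test_that("one third ESR overlap shrinks strict sets to about two thirds of raw", {
  w <- test_world(seed = 7, n_genes = 400, frac_up = 0.1, frac_down = 0.08,
                  n_chroms = 4)
  ch <- transcription_changes(w$gro)
  sets <- subtract_esr(ch, w$gene_lists$esr_up, w$gene_lists$esr_down)
  expect_equal(length(sets$up_strict) / length(sets$up_raw), 2 / 3,
               tolerance = 0.15)
  expect_equal(length(sets$down_strict) / length(sets$down_raw), 2 / 3,
               tolerance = 0.15)
  expect_true(all(sets$up_strict %in% sets$up_raw))
  expect_true(all(sets$down_strict %in% sets$down_raw))
})

test_that("replicate_concordance computes pairwise Pearson r per strain", {
  gro <- make_gro(list(a = list(control = c(1, 1), mutant = c(1, 2)),
                       b = list(control = c(2, 2), mutant = c(2, 4)),
                       c = list(control = c(3, 3), mutant = c(3, 1))))
  cc <- replicate_concordance(gro)
  diag_rows <- cc[cc$rep_a == cc$rep_b, ]
  expect_true(all(diag_rows$pearson_r == 1))
  # symmetry
  r12 <- cc$pearson_r[cc$strain == "control" & cc$rep_a == "1" & cc$rep_b == "2"]
  r21 <- cc$pearson_r[cc$strain == "control" & cc$rep_a == "2" & cc$rep_b == "1"]
  expect_equal(r12, r21)
  expect_equal(r12, 1) # identical replicates
  # negation around the mean gives r = -1
  gro_neg <- make_gro(list(a = list(control = c(1, 3)),
                           b = list(control = c(2, 2)),
                           c = list(control = c(3, 1))))
  cc_neg <- replicate_concordance(gro_neg)
  expect_equal(min(cc_neg$pearson_r), -1)
})

test_that("low replicate noise yields concordance above 0.95", {
  w <- test_world(seed = 13, noise_sigma = 0.05)
  cc <- replicate_concordance(w$gro)
  expect_true(all(cc$pearson_r > 0.95))
})

test_that("noise-free synthetic data is recovered exactly", {
  w <- test_world(seed = 3, noise_sigma = 0, n_genes = 150)
  ch <- transcription_changes(w$gro)
  truth_up <- w$truth$gene_id[w$truth$class == "up"]
  truth_down <- w$truth$gene_id[w$truth$class == "down"]
  expect_setequal(ch$gene_id[ch$status == "up"], truth_up)
  expect_setequal(ch$gene_id[ch$status == "down"], truth_down)
  # planted folds are recovered exactly in the ratio column
  expect_equal(ch$ratio[match(truth_up, ch$gene_id)],
               rep(w$config$fold_up, length(truth_up)))
})

test_that("no-effect, no-noise worlds give ratios of exactly one", {
  w <- test_world(seed = 5, frac_up = 0, frac_down = 0, noise_sigma = 0,
                  n_genes = 80)
  ch <- transcription_changes(w$gro)
  expect_equal(ch$ratio, rep(1, nrow(ch)))
})

test_that("default outlier filtering discards at most two percent of values", {
  w <- test_world(seed = 7)
  ch <- transcription_changes(w$gro)
  expect_lte(attr(ch, "discard_frac"), 0.02)
})

test_that("up and down sets are always disjoint", {
  for (seed in c(1, 2, 3)) {
    w <- test_world(seed = seed, n_genes = 100)
    ch <- transcription_changes(w$gro)
    expect_length(intersect(ch$gene_id[ch$status == "up"],
                            ch$gene_id[ch$status == "down"]), 0)
  }
})
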