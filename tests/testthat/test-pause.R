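test_that("motif sites enumerate sliding windows with occurrence counts", {
  tx <- make_txome(c(g1 = "MKIPS"), utr5 = 100L, utr3 = 100L)
  p <- analysis_params()
  sites <- enumerate_motif_sites(tx, p)
  expect_equal(sites$motif, c("MKI", "KIP", "IPS"))
  expect_equal(sites$e_codon_index, 0:2)
  expect_equal(sites$track_pos, 100L + 3L * (0:2) + 18L)
  expect_equal(sites$n_occurrences, rep(1L, 3))
  # small gene: every window is too close to the ORF ends
  expect_true(all(!sites$eligible))
})

test_that("a uniform track scores exactly 1 at every eligible site", {
  tx <- make_txome(c(g1 = strrep("K", 120)), utr5 = 30L, utr3 = 30L)
  ts <- make_track_set(list(g1 = rep(3.7, tx$genes$tx_len)))
  p <- analysis_params()
  sc <- pause_scores(ts, enumerate_motif_sites(tx, p), p)
  expect_gt(sum(sc$eligible), 0)
  expect_equal(sc[eligible == TRUE, score], rep(1, sum(sc$eligible)))
  av <- average_pause_scores(sc, p, min_occurrences = 1)
  expect_equal(av$avg_score, 1)
})

test_that("an isolated spike scores as the ratio to the window mean", {
  tx <- make_txome(c(g1 = strrep("K", 60)), utr5 = 30L)
  v <- numeric(tx$genes$tx_len)
  v[100] <- 101                               # 0-based position 99
  ts <- make_track_set(list(g1 = v))
  p <- analysis_params()
  sites <- enumerate_motif_sites(tx, p)
  sc <- pause_scores(ts, sites, p)
  expect_equal(sc[track_pos == 99L, score], 101)   # 101 / (101/101)
})

test_that("sites whose window leaves the trimmed ORF are ineligible", {
  tx <- make_txome(c(g1 = strrep("K", 120)), utr5 = 10L, utr3 = 100L)
  p <- analysis_params()
  sites <- enumerate_motif_sites(tx, p)
  expect_false(sites[track_pos == 28L, eligible])  # e = 0: window below ORF
  expect_equal(sites[track_pos == 28L, reason], "window_outside_region")
  # zero-mean windows become ineligible as a value, not an error
  ts <- make_track_set(list(g1 = numeric(tx$genes$tx_len)))
  sc <- pause_scores(ts, sites, p)
  expect_true(all(!sc$eligible | sc$reason == "zero_window_mean"))
})

test_that("pause scores equal an independently coded ratio on random tracks", {
  tx <- make_txome(c(g1 = strrep("K", 80)), utr5 = 20L, utr3 = 20L)
  p <- analysis_params()
  sites <- enumerate_motif_sites(tx, p)
  elig <- sites[eligible == TRUE]
  set.seed(42)
  for (i in 1:100) {
    v <- rpois(tx$genes$tx_len, lambda = sample(c(0.3, 2, 20), 1)) *
      runif(tx$genes$tx_len)
    ts <- make_track_set(list(g1 = v))
    sc <- pause_scores(ts, sites, p)[eligible == TRUE]
    want <- vapply(sc$track_pos, function(pos) oracle_pause_score(v, pos),
                   numeric(1))
    expect_equal(sc$score, want)
  }
})

test_that("pause scores are invariant under track rescaling", {
  tx <- make_txome(c(g1 = strrep("K", 80)), utr5 = 20L, utr3 = 20L)
  p <- analysis_params()
  sites <- enumerate_motif_sites(tx, p)
  set.seed(7)
  v <- rpois(tx$genes$tx_len, 3) + 0.1
  s1 <- pause_scores(make_track_set(list(g1 = v)), sites, p)
  s2 <- pause_scores(make_track_set(list(g1 = v * 17.3)), sites, p)
  expect_equal(s1$score, s2$score)
})

test_that("motif averages, the occurrence filter and replicate averaging", {
  st <- data.table(gene_id = "g1", motif = c("KIP", "KIP", "AAA"),
                   e_codon_index = 1:3, track_pos = 1:3,
                   eligible = TRUE, reason = "ok",
                   n_occurrences = c(2L, 2L, 1L),
                   score = c(1, 3, 2), sample = "s1")
  av <- average_pause_scores(st, analysis_params(), min_occurrences = 2)
  expect_equal(av[motif == "KIP", avg_score], 2)    # mean of 1 and 3
  expect_false("AAA" %in% av$motif)
  expect_equal(attr(av, "excluded")$motif, "AAA")
  av1 <- average_pause_scores(st, analysis_params(), min_occurrences = 1)
  expect_equal(av1[motif == "AAA", avg_score], 2)   # single site, threshold 1
  # replicates averaged at the motif level
  r1 <- copy(av1)[, avg_score := c(1, 1)]
  r2 <- copy(av1)[, avg_score := c(3, 3)]
  expect_equal(average_replicates(list(r1, r2))$avg_score, c(2, 2))
})

test_that("condition comparison splits the motif universe at the fold cut", {
  p <- analysis_params()
  ta <- data.table(motif = c("KIP", "AAA"), avg_score = c(3, 1))
  tb <- data.table(motif = c("KIP", "AAA"), avg_score = c(1.5, 1))
  cmp <- compare_conditions(ta, tb, p)
  expect_equal(cmp[motif == "KIP", fold], 2)
  expect_equal(cmp[foreground == TRUE, motif], "KIP")
  expect_equal(cmp[foreground == FALSE, motif], "AAA")
  # foreground + background partition the universe
  expect_equal(sum(cmp$foreground) + sum(!cmp$foreground), nrow(cmp))
  # identical tables: empty foreground
  expect_equal(sum(compare_conditions(ta, ta, p)$foreground), 0L)
  # motifs present in only one table are dropped and reported
  tb2 <- rbind(tb, data.table(motif = "WWW", avg_score = 1))
  expect_equal(attr(compare_conditions(ta, tb2, p), "dropped"), "WWW")
})

test_that("Mann-Whitney matches closed forms and the enumeration oracle", {
  expect_equal(mann_whitney_u(c(1, 2), c(3, 4), "less")$p.value, 1 / 6)
  expect_equal(mann_whitney_u(c(1, 2), c(3, 4))$p.value, 1 / 3)
  expect_equal(mann_whitney_u(1:10, 11:20)$p.value, 2 / choose(20, 10))
  expect_equal(mann_whitney_u(c(1, 2, 3), c(1, 2, 3))$p.value, 1)
  expect_error(mann_whitney_u(numeric(), 1:3), "non-empty")
  set.seed(8)
  for (i in 1:10) {
    x <- sample(1:6, 7, replace = TRUE)
    y <- sample(1:6, 6, replace = TRUE)
    for (alt in c("two.sided", "less", "greater"))
      expect_equal(mann_whitney_u(x, y, alt)$p.value, oracle_mw(x, y, alt))
  }
})

test_that("the large-sample path matches the tie-corrected normal reference", {
  set.seed(9)
  x <- sample(1:15, 30, replace = TRUE)
  y <- sample(1:15, 40, replace = TRUE) + 1
  for (alt in c("two.sided", "less", "greater"))
    expect_equal(
      mann_whitney_u(x, y, alternative = alt, method = "normal")$p.value,
      stats::wilcox.test(x, y, alternative = alt, exact = FALSE,
                         correct = TRUE)$p.value)
})

test_that("pause-score ratios pair sites eligible in both samples", {
  base <- data.table(gene_id = "g1", e_codon_index = 1:4,
                     motif = "KIP", eligible = c(TRUE, TRUE, TRUE, FALSE),
                     score = c(2, 4, 1, 9))
  num <- copy(base)
  den <- copy(base)[, score := c(1, 2, NA, 3)][3, eligible := TRUE]
  rt <- pause_score_ratios(num, den)
  expect_equal(rt$ratio, c(2, 2))             # site 3 NA, site 4 ineligible
  ht <- xip_score_shift_test(c(1, 1.2, 0.9), c(3, 3.3, 2.8))
  expect_s3_class(ht, "htest")
  expect_lt(ht$p.value, 0.2)
})

test_that("residue enrichment computes pseudocounted positional log-odds", {
  fg <- paste0("AA", c(rep("P", 8), "G", "H"))           # 10 motifs, 8 P at A
  bg <- paste0("CC", c(rep("P", 5), rep("K", 95)))       # 100 motifs, 5 P at A
  en <- residue_enrichment(fg, bg)
  want <- log2(((8 + 0.5) / (10 + 1)) / ((5 + 0.5) / (100 + 1)))
  expect_equal(en[position == "A" & residue == "P", log2_odds], want)
  expect_lt(en[position == "A" & residue == "P", p_value], 0.01)
  # disjoint, equal-size sets with identical positional frequencies:
  # log-odds 0 at every cell, including residues absent from both
  en2 <- residue_enrichment(c("KDE", "EDK"), c("KDK", "EDE"))
  expect_equal(en2$log2_odds, rep(0, nrow(en2)))
  expect_error(residue_enrichment(character(), bg), "empty")
  expect_error(residue_enrichment(fg, fg), "disjoint")
})
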