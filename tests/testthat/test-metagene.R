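# genes large enough for the (100, 300) / (300, 100) metagene windows
big_txome <- function(n = 3, utr = 120L, n_aa = 150L, overlap = NULL) {
  prots <- setNames(rep(strrep("K", n_aa), n), paste0("g", seq_len(n)))
  make_txome(prots, utr5 = utr, utr3 = utr, overlap_flags = overlap)
}

test_that("metagene windows are window-sum normalized and averaged", {
  tx <- big_txome(2)
  p <- analysis_params()
  L <- tx$genes$tx_len[1]
  # gene 1: all window reads at one nt -> indicator vector; gene 2: uniform
  v1 <- numeric(L); v1[tx$genes$cds_start[1] + 1L + 30L] <- 5
  v2 <- rep(2, L)
  ts <- make_track_set(list(g1 = v1, g2 = v2))
  mg <- metagene(ts, tx, "start", p)
  expect_equal(nrow(mg), 400L)
  expect_equal(mg$offset, seq(-100L, 299L))
  # each per-gene window sums to 1, so the average does too
  expect_equal(sum(mg$mean), 1)
  expect_equal(attr(mg, "n_genes"), 2L)
  # indicator + flat mixture: spike cell = (1 + 1/400)/2
  expect_equal(mg[offset == 30L, mean], (1 + 1 / 400) / 2)
  # genes uniform in-window give a flat 1/400 profile with sd 0
  mg2 <- metagene(make_track_set(list(g1 = v2, g2 = v2)), tx, "start", p)
  expect_equal(mg2$mean, rep(1 / 400, 400))
  expect_equal(mg2$sd, rep(0, 400))
})

test_that("metagene exclusion rules drop exactly the offending genes", {
  p <- analysis_params()
  prots <- c(ok = strrep("K", 150), short_utr = strrep("K", 150),
             short_orf = strrep("K", 80), overlapping = strrep("K", 150),
             no_reads = strrep("K", 150))
  seqs <- vapply(names(prots), function(nm)
    make_gene_seq(prots[[nm]], utr5 = if (nm == "short_utr") 60L else 120L,
                  utr3 = 120L), "")
  genes <- data.table(gene_id = names(prots),
                      utr5_len = ifelse(names(prots) == "short_utr", 60L, 120L),
                      cds_len = 3L * (nchar(prots) + 1L),
                      utr3_len = 120L)
  tx <- transcriptome(genes, seqs,
                      overlap_flags = c(overlapping = TRUE))
  tracks <- lapply(setNames(tx$genes$tx_len, tx$genes$gene_id), function(L)
    rep(1, L))
  tracks$no_reads <- numeric(tx$genes[gene_id == "no_reads", tx_len])
  mg <- metagene(make_track_set(tracks), tx, "start", p)
  expect_equal(attr(mg, "n_genes"), 1L)       # only "ok" survives
  ex <- attr(mg, "excluded")
  expect_equal(ex[gene_id == "short_utr", reason],
               "feature_smaller_than_window")
  expect_equal(ex[gene_id == "overlapping", reason], "overlapping_orf")
  expect_equal(ex[gene_id == "no_reads", reason], "no_reads_in_window")
  # short_orf (240 nt CDS < 300) is excluded from the start metagene too
  expect_true("short_orf" %in% ex$gene_id)
  expect_equal(attr(mg, "n_genes") + nrow(ex), nrow(tx$genes))
  # everything excluded -> error
  zero <- make_track_set(lapply(tracks, function(v) numeric(length(v))))
  expect_error(metagene(zero, tx, "start", p), "no genes survive")
})

test_that("stop-anchored metagenes use the (300, 100) window", {
  tx <- big_txome(1)
  p <- analysis_params()
  L <- tx$genes$tx_len[1]
  ts <- make_track_set(list(g1 = rep(1, L)))
  mg <- metagene(ts, tx, "stop", p)
  expect_equal(mg$offset, seq(-300L, 99L))
  expect_equal(sum(mg$mean), 1)
})

test_that("motif metaprofiles are gene-mean normalized around the readout", {
  tx <- big_txome(1)
  p <- analysis_params()
  L <- tx$genes$tx_len[1]
  sites <- enumerate_motif_sites(tx, p)[eligible == TRUE][c(3, 13)]
  # uniform gene: profile is exactly 1 everywhere
  prof <- motif_metaprofile(make_track_set(list(g1 = rep(2.5, L))), sites,
                            tx, p)
  expect_equal(prof$mean, rep(1, 101))
  expect_equal(prof$offset, -50:50)
  # spikes at both sites: each window sees the other as a satellite peak
  v <- rep(1, L)
  v[sites$track_pos + 1L] <- 51
  prof2 <- motif_metaprofile(make_track_set(list(g1 = v)), sites, tx, p)
  gap <- sites$track_pos[2] - sites$track_pos[1]
  expect_equal(which.max(prof2$mean), which(prof2$offset == 0L))
  expect_gt(prof2[offset == gap, mean], prof2[offset == gap + 1L, mean])
  expect_gt(prof2[offset == -gap, mean], prof2[offset == -gap - 1L, mean])
  expect_error(motif_metaprofile(make_track_set(list(g1 = v)), sites[0], tx,
                                 p), "no eligible")
})

test_that("planted pauses appear as a central metaprofile peak", {
  cfg <- sim_config(seed = 17, n_genes = 30, cds_len_range = c(900, 1200),
                    utr5_len = 120, utr3_len = 120,
                    motif_multipliers = c(KIP = 5), sites_per_motif = 40,
                    base_depth = 20, dispersion = 10, end_jitter = 0)
  tx <- simulate_transcriptome(cfg)
  sim <- simulate_footprints(tx, cfg, "s1", classes = "mono")
  p <- analysis_params()
  ts <- build_track(sim$mono, tx, "three_prime_end")
  sites <- enumerate_motif_sites(tx, p)[motif == "KIP" & eligible == TRUE]
  prof <- motif_metaprofile(ts, sites, tx, p)
  # with no end jitter the peak sits exactly at offset 0 ...
  expect_equal(prof[which.max(mean), offset], 0L)
  # ... and matches the closed-form mean model: m * depth vs depth at other
  # in-frame offsets (ratio m), within sampling noise
  centre <- prof[offset == 0L, mean]
  frame <- prof[offset %% 3L == 0L & offset != 0L, mean]
  expect_gt(centre / mean(frame), 5 * 0.8)
  expect_lt(centre / mean(frame), 5 * 1.2)
})

test_that("quantitation implements the worked rpkm example exactly", {
  # 330 nt CDS, 15 nt trimmed from each end -> 300 nt quantitated region;
  # 60 P-site reads inside at 1e6 total mapped -> 60 rpm -> rpkm 200
  tx <- make_txome(c(g1 = strrep("K", 109)), utr5 = 50L, utr3 = 50L)
  expect_equal(tx$genes$cds_len, 330L)
  p <- analysis_params()
  set.seed(2)
  psite <- sample(seq(tx$genes$cds_start + 15L, tx$genes$cds_end - 16L), 60,
                  replace = TRUE)
  aln <- data.table(sample = "s1", gene_id = "g1",
                    three_prime_pos = psite + p$p_site_shift,
                    read_len = 28L, count = 1L)
  filler <- data.table(sample = "s1", gene_id = "g1", three_prime_pos = 1L,
                       read_len = 28L, count = 1e6L - 60L)
  ts <- build_track(rbind(aln, filler), tx, "three_prime_end")
  q <- quantitate(ts, tx, "cds", p, class = "ribo")
  expect_equal(q$rpm_sum, 60)
  expect_equal(q$region_len, 300L)
  expect_equal(q$rpkm, 200)
})

test_that("raw counts are integers, conserved, and independent of rpm", {
  tx <- make_txome(c(g1 = strrep("K", 109)), utr5 = 50L, utr3 = 50L)
  p <- analysis_params()
  pos <- seq(tx$genes$cds_start + 15L, by = 3L, length.out = 30) +
    p$p_site_shift
  aln <- data.table(sample = rep(c("a", "b"), each = 30), gene_id = "g1",
                    three_prime_pos = rep(pos, 2), read_len = 28L,
                    count = rep(c(1L, 2L), each = 30))
  cnt <- export_raw_counts(aln, tx, p)
  expect_identical(cnt["g1", "a"], 30L)
  expect_identical(cnt["g1", "b"], 60L)
  expect_equal(colSums(cnt), c(a = 30, b = 60))  # all placed reads in-region
  # doubling multiplicities doubles counts but leaves rpkm unchanged
  aln2 <- copy(aln)[, count := count * 2L]
  cnt2 <- export_raw_counts(aln2, tx, p)
  expect_equal(cnt2, cnt * 2L)
  ts1 <- build_track(aln[sample == "a"], tx, "three_prime_end")
  ts2 <- build_track(aln2[sample == "a"], tx, "three_prime_end")
  expect_equal(quantitate(ts1, tx, "cds", p)$rpkm,
               quantitate(ts2, tx, "cds", p)$rpkm)
})

test_that("translation efficiency is a guarded rpkm ratio", {
  expr <- data.table(gene_id = c("a", "b", "c"),
                     ribo_rpkm = c(200, 0, 50), rna_rpkm = c(100, 100, 0))
  te <- translation_efficiency(expr)
  expect_equal(te$te, c(2, 0, NA_real_))
})

test_that("TE is invariant under library-size rescaling of either library", {
  cfg <- sim_config(seed = 19, n_genes = 6, cds_len_range = c(600, 750),
                    utr5_len = 60, utr3_len = 60, base_depth = 3)
  tx <- simulate_transcriptome(cfg)
  sim <- simulate_footprints(tx, cfg, "s1")
  p <- analysis_params()
  ribo1 <- build_track(sim$mono, tx, "three_prime_end")
  rna1 <- build_track(sim$rna, tx, "coverage")
  deeper <- copy(sim$mono)[, count := count * 3L]
  ribo2 <- build_track(deeper, tx, "three_prime_end")
  e1 <- expression_table(ribo1, rna1, tx, p)
  e2 <- expression_table(ribo2, rna1, tx, p)
  expect_equal(e1$te, e2$te)
})

test_that("UTR occupancy distinguishes missing features from empty signal", {
  seqs <- c(g1 = make_gene_seq(strrep("K", 109), utr5 = 0L, utr3 = 50L))
  genes <- data.table(gene_id = "g1", utr5_len = 0L, cds_len = 330L,
                      utr3_len = 50L)
  tx <- transcriptome(genes, seqs)
  ts <- make_track_set(list(g1 = rep(1, tx$genes$tx_len)))
  q5 <- quantitate(ts, tx, "utr5", analysis_params(), class = "rna")
  q3 <- quantitate(ts, tx, "utr3", analysis_params(), class = "rna")
  expect_true(is.na(q5$rpm_sum))              # missing feature, not zero
  expect_equal(q3$rpm_sum, 50)
})
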