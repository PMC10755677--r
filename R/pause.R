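# The core statistic: site-level and motif-averaged pause scores for
# tri-amino-acid motifs occupying the ribosomal E, P and A sites.
#
# A site's pause score is the 3'-end rpm at its readout position (E-site
# codon start + 18 nt) divided by the mean rpm over the closed +/-50 nt
# window around that position (101 positions, motif position included).

#' Enumerate tri-amino-acid motif sites across a transcriptome
#'
#' Emits every overlapping 3-residue window of every protein, with the
#' residues read in E, P, A order (`e_codon_index` is the 0-based codon index
#' of the E-site residue). Each site carries its pause-score readout position
#' (`track_pos`, from [site_position()]), the motif's genome-wide occurrence
#' count, and an eligibility flag: a site is eligible when its full +/-50 nt
#' window lies inside the ORF interior trimmed by `end_trim` at both ends.
#'
#' @param txome a `transcriptome`.
#' @param params an [analysis_params()].
#' @return `data.table` of class `motif_sites`: `gene_id`, `motif`,
#'   `e_codon_index`, `track_pos`, `eligible`, `reason`, `n_occurrences`.
#' @export
enumerate_motif_sites <- function(txome, params = analysis_params()) {
  g <- txome$genes[nchar(protein) >= 3L]
  if (nrow(g) == 0L)
    stop("transcriptome has no protein of length >= 3")
  w <- params$pause_window
  trim <- params$end_trim
  sites <- g[, {
    L <- nchar(protein)
    e <- 0:(L - 3L)
    list(motif = substring(protein, e + 1L, e + 3L),
         e_codon_index = e,
         track_pos = site_position(cds_start + 3L * e, params),
         lo_ok = (cds_start + 3L * e + params$e_site_shift - w) >=
           (cds_start + trim),
         hi_ok = (cds_start + 3L * e + params$e_site_shift + w) <=
           (cds_end - trim - 1L))
  }, by = gene_id]
  sites[, eligible := lo_ok & hi_ok]
  sites[, reason := fifelse(eligible, "ok", "window_outside_region")]
  sites[, c("lo_ok", "hi_ok") := NULL]
  sites[, n_occurrences := .N, by = motif]
  setattr(sites, "class", c("motif_sites", class(sites)))
  sites[]
}

#' Compute site-level pause scores from a 3'-end occupancy track
#'
#' For every eligible site: `score = rpm[track_pos] / mean(rpm[track_pos - w
#' .. track_pos + w])` over the closed window of `2w + 1` positions. Sites
#' whose window mean is zero become ineligible with reason
#' `"zero_window_mean"` (a value, not an error); sites already flagged
#' ineligible keep `NA` scores.
#'
#' @param track_set a `track_set` in `three_prime_end` convention.
#' @param sites a `motif_sites` table from [enumerate_motif_sites()].
#' @param params an [analysis_params()].
#' @return Copy of `sites` with `score` and `sample` columns.
#' @export
pause_scores <- function(track_set, sites, params = analysis_params()) {
  if (track_set$convention != "three_prime_end")
    stop("pause scores require a three_prime_end track")
  w <- params$pause_window
  out <- copy(as.data.table(sites))
  out[, score := NA_real_]
  by_gene <- split(which(out$eligible), out$gene_id[out$eligible])
  for (gid in names(by_gene)) {
    idx <- by_gene[[gid]]
    v <- track_set$tracks[[gid]]
    if (is.null(v)) stop("no track for gene ", gid)
    cs <- cumsum(v)
    pos <- out$track_pos[idx]                     # 0-based
    lo <- pos - w                                 # window [pos-w, pos+w]
    lo_cum <- numeric(length(lo))
    lo_cum[lo > 0L] <- cs[lo[lo > 0L]]
    wsum <- cs[pos + w + 1L] - lo_cum
    sc <- v[pos + 1L] / (wsum / (2L * w + 1L))
    zero <- wsum == 0
    sc[zero] <- NA_real_
    set(out, idx, "score", sc)
    if (any(zero)) {
      set(out, idx[zero], "eligible", FALSE)
      set(out, idx[zero], "reason", "zero_window_mean")
    }
  }
  out[, sample := track_set$sample]
  setattr(out, "class", c("pause_score_table", "data.table", "data.frame"))
  out[]
}

#' Average site-level pause scores per motif
#'
#' Arithmetic mean over a motif's eligible, scored sites. Motifs represented
#' genome-wide fewer than `min_occurrences` times, and motifs with zero
#' eligible sites, are excluded (listed in the `excluded` attribute with a
#' reason).
#'
#' @param score_table output of [pause_scores()].
#' @param params an [analysis_params()].
#' @param min_occurrences occurrence threshold; defaults to
#'   `params$min_motif_occurrences`.
#' @return `data.table`: `motif`, `n_occurrences`, `n_sites` (eligible scored
#'   sites), `avg_score`; attribute `excluded`.
#' @export
average_pause_scores <- function(score_table, params = analysis_params(),
                                 min_occurrences = params$min_motif_occurrences) {
  st <- as.data.table(score_table)
  occ <- unique(st[, .(motif, n_occurrences)])
  avg <- st[eligible & !is.na(score),
            .(n_sites = .N, avg_score = mean(score)), by = motif]
  out <- merge(occ, avg, by = "motif", all.x = TRUE)
  excluded <- rbind(
    out[n_occurrences < min_occurrences,
        .(motif, reason = "below_occurrence_threshold")],
    out[n_occurrences >= min_occurrences & is.na(avg_score),
        .(motif, reason = "no_eligible_sites")])
  out <- out[n_occurrences >= min_occurrences & !is.na(avg_score)]
  setkey(out, motif)
  setattr(out, "excluded", excluded)
  out[]
}

#' Average replicate motif tables
#'
#' Replicates are combined at the motif-average level: the reported score of
#' a motif is the mean of its per-replicate average scores, over motifs
#' retained in every replicate.
#'
#' @param tables list of [average_pause_scores()] outputs.
#' @return `data.table`: `motif`, `n_occurrences`, `n_sites` (mean across
#'   replicates), `avg_score` (mean across replicates).
#' @export
average_replicates <- function(tables) {
  stopifnot(length(tables) >= 1L)
  common <- Reduce(intersect, lapply(tables, function(t) t$motif))
  stacked <- rbindlist(lapply(tables, function(t)
    as.data.table(t)[motif %in% common]))
  stacked[, .(n_occurrences = n_occurrences[1L],
              n_sites = mean(n_sites),
              avg_score = mean(avg_score)), by = motif][order(motif)]
}

#' Compare motif pause scores between two conditions
#'
#' Computes per-motif fold changes `avg_a / avg_b` over the motifs present in
#' both tables and splits the universe into foreground (fold >= `fg_fold`,
#' default 1.5) and background (the rest). Motifs present in only one table
#' are excluded from both sets and reported in the `dropped` attribute.
#'
#' @param table_a,table_b motif-average tables (e.g. treated vs untreated).
#' @param params an [analysis_params()].
#' @return `data.table`: `motif`, `avg_a`, `avg_b`, `fold`, `foreground`;
#'   attribute `dropped`.
#' @export
compare_conditions <- function(table_a, table_b, params = analysis_params()) {
  ta <- as.data.table(table_a)[, .(motif, avg_a = avg_score)]
  tb <- as.data.table(table_b)[, .(motif, avg_b = avg_score)]
  out <- merge(ta, tb, by = "motif")
  dropped <- setdiff(union(ta$motif, tb$motif), out$motif)
  out[, fold := avg_a / avg_b]
  out[, foreground := fold >= params$fg_fold]
  setkey(out, motif)
  setattr(out, "dropped", dropped)
  out[]
}

#' Mann-Whitney U test (exact enumeration for small samples)
#'
#' Independent two-group Mann-Whitney U test on mid-ranks. For combined
#' n <= `exact_max_n` (default 20) the null distribution of U is obtained by
#' exhaustive enumeration of all C(n, n_x) group labelings of the pooled
#' mid-ranks (ties handled exactly); otherwise the tie-corrected normal
#' approximation with continuity correction is used. Two-sided p-values
#' double the smaller tail (capped at 1).
#'
#' @param x,y numeric vectors (both non-empty).
#' @param alternative `"two.sided"`, `"less"` or `"greater"` (direction of
#'   `x` relative to `y`).
#' @param method `"auto"`, `"exact"` or `"normal"`.
#' @param exact_max_n largest combined sample size enumerated under
#'   `method = "auto"`.
#' @return An object of class `htest` with the U statistic for `x` and the
#'   p-value.
#' @export
mann_whitney_u <- function(x, y,
                           alternative = c("two.sided", "less", "greater"),
                           method = c("auto", "exact", "normal"),
                           exact_max_n = 20L) {
  alternative <- match.arg(alternative)
  method <- match.arg(method)
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y))
    stop("both samples must be non-empty")
  nx <- length(x); ny <- length(y); n <- nx + ny
  if (method == "auto") method <- if (n <= exact_max_n) "exact" else "normal"
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2

  if (method == "exact") {
    if (n > 24L) stop("exact enumeration limited to combined n <= 24")
    combos <- utils::combn(n, nx)
    u_all <- colSums(matrix(r[combos], nrow = nx)) - nx * (nx + 1) / 2
    eps <- 1e-8
    p_le <- mean(u_all <= u_obs + eps)
    p_ge <- mean(u_all >= u_obs - eps)
    p <- switch(alternative,
                two.sided = min(1, 2 * min(p_le, p_ge)),
                less = p_le,
                greater = p_ge)
  } else {
    mu <- nx * ny / 2
    tie_tab <- table(r)
    tie_term <- sum(tie_tab^3 - tie_tab) / (n * (n - 1))
    sigma <- sqrt(nx * ny / 12 * ((n + 1) - tie_term))
    if (sigma == 0) {
      p <- 1
    } else {
      cc <- 0.5
      p <- switch(alternative,
        two.sided = {
          z <- (u_obs - mu - sign(u_obs - mu) * cc) / sigma
          min(1, 2 * stats::pnorm(-abs(z)))
        },
        less = stats::pnorm((u_obs - mu + cc) / sigma),
        greater = stats::pnorm((u_obs - mu - cc) / sigma,
                               lower.tail = FALSE))
    }
  }
  structure(list(statistic = c(U = u_obs), p.value = p,
                 alternative = alternative,
                 method = paste("Mann-Whitney U test,", method),
                 data.name = paste(deparse(substitute(x)), "and",
                                   deparse(substitute(y)))),
            class = "htest")
}

#' Per-site pause-score ratios between two samples
#'
#' Ratio of site-level scores (e.g. peroxide / untreated) over sites eligible
#' and scored in both samples; sites ineligible in either are dropped and
#' counted in the `n_dropped` attribute.
#'
#' @param score_num,score_den [pause_scores()] tables for numerator and
#'   denominator samples.
#' @return `data.table`: `gene_id`, `e_codon_index`, `motif`, `score_num`,
#'   `score_den`, `ratio`.
#' @export
pause_score_ratios <- function(score_num, score_den) {
  a <- as.data.table(score_num)[eligible & !is.na(score),
                                .(gene_id, e_codon_index, motif,
                                  score_num = score)]
  b <- as.data.table(score_den)[eligible & !is.na(score),
                                .(gene_id, e_codon_index, motif,
                                  score_den = score)]
  out <- merge(a, b, by = c("gene_id", "e_codon_index", "motif"))
  out[, ratio := score_num / score_den]
  setattr(out, "n_dropped",
          nrow(score_num) + nrow(score_den) - 2L * nrow(out))
  out[]
}

#' Test for a shift in pause-score ratios between strains at selected sites
#'
#' Two-sided independent two-group Mann-Whitney U test comparing site-level
#' pause-score ratios (or scores) between two strains/conditions — e.g. the
#' peroxide/untreated ratio at X-Ile-Pro sites in wild type vs a deletion
#' strain.
#'
#' @param ratios_a,ratios_b numeric vectors, or [pause_score_ratios()] tables
#'   (their `ratio` column is used).
#' @param ... passed to [mann_whitney_u()].
#' @return An `htest` (U statistic and p-value).
#' @export
xip_score_shift_test <- function(ratios_a, ratios_b, ...) {
  get_vec <- function(v)
    if (is.data.frame(v)) as.data.table(v)$ratio else as.numeric(v)
  mann_whitney_u(get_vec(ratios_a), get_vec(ratios_b), ...)
}

#' Positional residue enrichment between motif sets
#'
#' Simplified positional log-odds (a pLogo-style readout): for each ribosome
#' site (E, P, A) and each of the 20 residues, computes
#' `log2(((fg + 0.5)/(n_fg + 1)) / ((bg + 0.5)/(n_bg + 1)))` plus a two-sided
#' binomial p-value of the foreground count given the background frequency.
#'
#' @param fg,bg disjoint character vectors of tri-amino-acid motifs
#'   (foreground and background).
#' @return `data.table`: `position` (E/P/A), `residue`, `fg_count`,
#'   `bg_count`, `log2_odds`, `p_value`.
#' @export
residue_enrichment <- function(fg, bg) {
  if (!length(fg)) stop("foreground motif set is empty")
  if (length(intersect(fg, bg)))
    stop("foreground and background motif sets must be disjoint")
  n_fg <- length(fg); n_bg <- length(bg)
  out <- CJ(position = c("E", "P", "A"), residue = .AA20, sorted = FALSE)
  pos_idx <- c(E = 1L, P = 2L, A = 3L)
  out[, fg_count := vapply(seq_len(.N), function(i)
    sum(substr(fg, pos_idx[position[i]], pos_idx[position[i]]) == residue[i]),
    integer(1))]
  out[, bg_count := vapply(seq_len(.N), function(i)
    sum(substr(bg, pos_idx[position[i]], pos_idx[position[i]]) == residue[i]),
    integer(1))]
  out[, log2_odds := log2(((fg_count + 0.5) / (n_fg + 1)) /
                          ((bg_count + 0.5) / (n_bg + 1)))]
  out[, p_value := vapply(seq_len(.N), function(i) {
    pb <- if (bg_count[i] == 0L || bg_count[i] == n_bg)
      (bg_count[i] + 0.5) / (n_bg + 1) else bg_count[i] / n_bg
    stats::binom.test(fg_count[i], n_fg, p = pb)$p.value
  }, numeric(1))]
  out[]
}
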