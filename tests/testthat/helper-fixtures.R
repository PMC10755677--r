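library(data.table)

# deterministic codon per amino acid (first codon alphabetically)
.aa2codon <- local({
  gc <- Biostrings::GENETIC_CODE
  tab <- vapply(split(names(gc), unname(gc)), function(x) sort(x)[1],
                character(1))
  tab
})

# build a transcript sequence encoding `protein` (plus ATG is implied by the
# protein's own first residue) with given UTR lengths
make_gene_seq <- function(protein, utr5 = 0L, utr3 = 0L, stop_codon = "TAA") {
  aa <- strsplit(protein, "")[[1]]
  cds <- paste0(paste(.aa2codon[aa], collapse = ""), stop_codon)
  paste0(strrep("C", utr5), cds, strrep("G", utr3))
}

# one-or-more-gene transcriptome from named protein strings
make_txome <- function(proteins, utr5 = 0L, utr3 = 0L, overlap_flags = NULL) {
  seqs <- vapply(proteins, make_gene_seq, "", utr5 = utr5, utr3 = utr3)
  genes <- data.table(gene_id = names(proteins),
                      utr5_len = utr5,
                      cds_len = 3L * (nchar(proteins) + 1L),
                      utr3_len = utr3)
  transcriptome(genes, seqs, overlap_flags = overlap_flags)
}

# forge a track_set directly from per-gene numeric vectors (rpm units)
make_track_set <- function(tracks, convention = "three_prime_end",
                           sample = "test", total_mapped = 1e6) {
  structure(list(tracks = tracks, convention = convention, sample = sample,
                 total_mapped = total_mapped),
            class = "track_set")
}

# independent pause-score oracle: plain one-line ratio over the closed window
oracle_pause_score <- function(v, pos0, w = 50L) {
  v[pos0 + 1L] / mean(v[(pos0 - w + 1L):(pos0 + w + 1L)])
}

# independent Mann-Whitney oracle: exhaustive enumeration of group labelings,
# U computed by direct pair counting (0.5 per tie)
oracle_mw <- function(x, y, alternative = "two.sided") {
  pool <- c(x, y)
  n <- length(pool); nx <- length(x)
  u_of <- function(xs, ys)
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  u_obs <- u_of(x, y)
  labelings <- utils::combn(n, nx)
  u_all <- apply(labelings, 2L, function(idx) u_of(pool[idx], pool[-idx]))
  eps <- 1e-9
  p_le <- mean(u_all <= u_obs + eps)
  p_ge <- mean(u_all >= u_obs - eps)
  switch(alternative,
         less = p_le, greater = p_ge,
         two.sided = min(1, 2 * min(p_le, p_ge)))
}
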