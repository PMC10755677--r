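# Start/stop metagenes, motif-aligned metaprofiles, and gene-level
# quantitation (rpkm, translation efficiency, UTR occupancy, raw counts).

#' Start- or stop-codon metagene profile
#'
#' Per gene, extracts the anchor window (start anchor: `metagene_start_window
#' = c(upstream, into_orf)` nt around the start codon; stop anchor:
#' `metagene_stop_window = c(orf, downstream)` nt around the stop), divides
#' by the window's total reads so each gene contributes a probability-like
#' vector, and averages across genes. Excluded genes: ORFs overlapping
#' another ORF, genes whose features are smaller than the window, and genes
#' without any reads in the window.
#'
#' Offsets are relative to the first nt of the start codon (start anchor) or
#' to the first nt after the stop codon (stop anchor).
#'
#' @param track_set a `track_set` spanning full transcripts (UTRs included).
#' @param txome a `transcriptome`.
#' @param anchor `"start"` or `"stop"`.
#' @param params an [analysis_params()].
#' @return `data.table` (`offset`, `mean`, `sd`) with attributes `n_genes`
#'   and `excluded` (gene_id, reason).
#' @export
metagene <- function(track_set, txome, anchor = c("start", "stop"),
                     params = analysis_params()) {
  anchor <- match.arg(anchor)
  g <- txome$genes
  win <- if (anchor == "start") params$metagene_start_window
         else params$metagene_stop_window
  span <- sum(win)
  excluded <- data.table(gene_id = character(), reason = character())
  mat <- matrix(NA_real_, nrow = nrow(g), ncol = span)
  used <- logical(nrow(g))
  for (i in seq_len(nrow(g))) {
    gi <- g[i]
    if (gi$overlaps_orf) {
      excluded <- rbind(excluded,
                        data.table(gene_id = gi$gene_id,
                                   reason = "overlapping_orf"))
      next
    }
    fits <- if (anchor == "start")
      gi$utr5_len >= win[1] && gi$cds_len >= win[2]
    else gi$cds_len >= win[1] && gi$utr3_len >= win[2]
    if (!fits) {
      excluded <- rbind(excluded,
                        data.table(gene_id = gi$gene_id,
                                   reason = "feature_smaller_than_window"))
      next
    }
    v <- track_set$tracks[[gi$gene_id]]
    from1 <- if (anchor == "start") gi$cds_start - win[1] + 1L
             else gi$cds_end - win[1] + 1L
    wv <- v[from1:(from1 + span - 1L)]
    if (sum(wv) == 0) {
      excluded <- rbind(excluded,
                        data.table(gene_id = gi$gene_id,
                                   reason = "no_reads_in_window"))
      next
    }
    mat[i, ] <- wv / sum(wv)
    used[i] <- TRUE
  }
  if (!any(used)) stop("no genes survive metagene exclusion rules")
  mat <- mat[used, , drop = FALSE]
  offsets <- if (anchor == "start") seq(-win[1], win[2] - 1L)
             else seq(-win[1], win[2] - 1L)
  out <- data.table(offset = offsets,
                    mean = colMeans(mat),
                    sd = apply(mat, 2L, stats::sd))
  setattr(out, "n_genes", sum(used))
  setattr(out, "excluded", excluded)
  setattr(out, "anchor", anchor)
  out[]
}

#' Motif-aligned average occupancy metaprofile
#'
#' For each eligible motif site, extracts the `+/- pause_window` nt occupancy
#' window centred on the site's readout position and divides it by the gene's
#' mean rpm, then averages across sites (the X-Ile-Pro metaprofile
#' normalization). Sites in genes with zero mean rpm are skipped and counted.
#'
#' @param track_set a `track_set`.
#' @param sites a `motif_sites` table (typically filtered to one motif class,
#'   e.g. all X-Ile-Pro sites); only eligible sites are used.
#' @param txome a `transcriptome`.
#' @param params an [analysis_params()].
#' @return `data.table` (`offset`, `mean`, `sd`) with attributes `n_sites`
#'   and `n_skipped`.
#' @export
motif_metaprofile <- function(track_set, sites, txome,
                              params = analysis_params()) {
  w <- params$pause_window
  st <- as.data.table(sites)[eligible == TRUE]
  if (nrow(st) == 0L) stop("no eligible motif sites supplied")
  gene_mean <- vapply(track_set$tracks, mean, numeric(1))
  st[, gmean := gene_mean[gene_id]]
  skipped <- st[gmean == 0]
  st <- st[gmean > 0]
  if (nrow(st) == 0L) stop("all sites fall in genes with zero occupancy")
  mat <- matrix(NA_real_, nrow = nrow(st), ncol = 2L * w + 1L)
  for (i in seq_len(nrow(st))) {
    v <- track_set$tracks[[st$gene_id[i]]]
    pos1 <- st$track_pos[i] + 1L
    mat[i, ] <- v[(pos1 - w):(pos1 + w)] / st$gmean[i]
  }
  out <- data.table(offset = seq(-w, w),
                    mean = colMeans(mat),
                    sd = apply(mat, 2L, stats::sd))
  setattr(out, "n_sites", nrow(st))
  setattr(out, "n_skipped", nrow(skipped))
  out[]
}

#' Gene-level quantitation in rpkm
#'
#' Sums normalized reads (rpm) over a region and divides by the quantitated
#' region length in kilobases. For ribosome footprints over the CDS, 3'-end
#' positions are first shifted by `p_site_shift` (15 nt) to the P site and
#' the first/last `end_trim` (15 nt) of the ORF are eliminated; the rpkm
#' denominator is the trimmed length. RNA-seq uses coverage tracks with no
#' shift and no trim. UTR quantitation applies no shift or trim; genes whose
#' UTR has zero length get `NA` (missing feature, not empty signal).
#'
#' @param track_set a `track_set` (`three_prime_end` for ribosome footprints,
#'   `coverage` for RNA).
#' @param txome a `transcriptome`.
#' @param region `"cds"`, `"utr5"` or `"utr3"`.
#' @param params an [analysis_params()].
#' @param class `"ribo"` (apply P-site shift + end trim for CDS) or `"rna"`.
#' @return `data.table`: `gene_id`, `rpm_sum`, `region_len`, `rpkm`.
#' @export
quantitate <- function(track_set, txome, region = c("cds", "utr5", "utr3"),
                       params = analysis_params(),
                       class = c("ribo", "rna")) {
  region <- match.arg(region)
  class <- match.arg(class)
  g <- txome$genes
  shift <- if (class == "ribo" && region == "cds") params$p_site_shift else 0L
  trim <- if (class == "ribo" && region == "cds") params$end_trim else 0L
  out <- data.table(gene_id = g$gene_id, rpm_sum = NA_real_,
                    region_len = NA_integer_, rpkm = NA_real_)
  for (i in seq_len(nrow(g))) {
    gi <- g[i]
    bounds <- switch(region,
                     cds = c(gi$cds_start + trim, gi$cds_end - trim),
                     utr5 = c(0L, gi$cds_start),
                     utr3 = c(gi$cds_end, gi$tx_len))
    len <- bounds[2] - bounds[1]
    if (len <= 0L) next  # missing/over-trimmed feature stays NA
    v <- track_set$tracks[[gi$gene_id]]
    # a read whose 3' end is at p represents site p - shift
    from1 <- bounds[1] + shift + 1L
    to1 <- bounds[2] + shift
    from1 <- max(from1, 1L)
    to1 <- min(to1, length(v))
    s <- if (to1 >= from1) sum(v[from1:to1]) else 0
    set(out, i, "rpm_sum", s)
    set(out, i, "region_len", as.integer(len))
    set(out, i, "rpkm", s / (len / 1000))
  }
  out[]
}

#' Build a gene-level expression table
#'
#' Combines ribosome-footprint CDS rpkm (P-site shifted, end-trimmed),
#' RNA-seq CDS rpkm (coverage), translation efficiency, and UTR occupancy
#' (summed rpm, 3'-end convention, unshifted) into one table.
#'
#' @param ribo_tracks `three_prime_end` `track_set` of monosome footprints.
#' @param rna_tracks `coverage` `track_set` of RNA-seq reads.
#' @param txome a `transcriptome`.
#' @param params an [analysis_params()].
#' @return `data.table`: `gene_id`, `ribo_rpkm`, `rna_rpkm`, `te`,
#'   `utr5_rpm`, `utr3_rpm`.
#' @export
expression_table <- function(ribo_tracks, rna_tracks, txome,
                             params = analysis_params()) {
  ribo <- quantitate(ribo_tracks, txome, "cds", params, class = "ribo")
  rna <- quantitate(rna_tracks, txome, "cds", params, class = "rna")
  u5 <- quantitate(ribo_tracks, txome, "utr5", params, class = "rna")
  u3 <- quantitate(ribo_tracks, txome, "utr3", params, class = "rna")
  out <- data.table(gene_id = txome$genes$gene_id,
                    ribo_rpkm = ribo$rpkm,
                    rna_rpkm = rna$rpkm,
                    utr5_rpm = u5$rpm_sum,
                    utr3_rpm = u3$rpm_sum)
  translation_efficiency(out)
}

#' Translation efficiency
#'
#' `te = ribo_rpkm / rna_rpkm`; undefined (`NA`) where `rna_rpkm` is zero or
#' missing. Invariant under rescaling of either library's total depth only
#' through rpkm's self-normalization.
#'
#' @param expr `data.table` with `ribo_rpkm` and `rna_rpkm` columns.
#' @return The table with a `te` column added (modified by reference and
#'   returned).
#' @export
translation_efficiency <- function(expr) {
  expr <- as.data.table(expr)
  expr[, te := fifelse(!is.na(rna_rpkm) & rna_rpkm > 0,
                       ribo_rpkm / rna_rpkm, NA_real_)]
  expr[]
}

#' Export raw per-gene counts for differential expression
#'
#' Integer read counts per gene and sample, CDS-assigned under the same
#' conventions as quantitation (P-site shift, end trim for ribosome
#' footprints). Counts are raw: unaffected by rpm normalization.
#'
#' @param alignments `data.table` of deduplicated alignments with `sample`,
#'   `gene_id`, `three_prime_pos`, optionally `count`.
#' @param txome a `transcriptome`.
#' @param params an [analysis_params()].
#' @param shift,trim assignment conventions; defaults are the ribosome
#'   footprint rules (set both 0 for RNA).
#' @return integer matrix, genes x samples.
#' @export
export_raw_counts <- function(alignments, txome, params = analysis_params(),
                              shift = params$p_site_shift,
                              trim = params$end_trim) {
  aln <- as.data.table(alignments)
  if (!"count" %in% names(aln)) aln[, count := 1L]
  g <- txome$genes[, .(gene_id, cds_start, cds_end)]
  aln <- merge(aln, g, by = "gene_id", sort = FALSE)
  aln[, site := three_prime_pos - shift]
  inreg <- aln[site >= cds_start + trim & site < cds_end - trim]
  counts <- dcast(inreg[, .(n = sum(count)), by = .(gene_id, sample)],
                  gene_id ~ sample, value.var = "n", fill = 0L)
  mat <- as.matrix(counts, rownames = "gene_id")
  full <- matrix(0L, nrow = nrow(txome$genes), ncol = ncol(mat),
                 dimnames = list(txome$genes$gene_id, colnames(mat)))
  full[rownames(mat), ] <- mat
  storage.mode(full) <- "integer"
  full
}

#' Write a count matrix in MatrixMarket + tab-separated form
#' @param counts integer matrix from [export_raw_counts()].
#' @param dir output directory.
#' @return Invisibly, the paths written.
#' @export
write_counts <- function(counts, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mtx <- file.path(dir, "counts.mtx")
  Matrix::writeMM(Matrix::Matrix(counts, sparse = TRUE), mtx)
  fwrite(data.table(gene_id = rownames(counts)),
         file.path(dir, "counts_genes.tsv"), sep = "\t", col.names = FALSE)
  fwrite(data.table(sample = colnames(counts)),
         file.path(dir, "counts_samples.tsv"), sep = "\t", col.names = FALSE)
  fwrite(data.table(gene_id = rownames(counts), as.data.table(counts)),
         file.path(dir, "counts.tsv"), sep = "\t")
  invisible(c(mtx = mtx))
}
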