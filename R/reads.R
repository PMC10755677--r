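# Raw-read handling: linker trimming + demultiplexing, UMI-based PCR
# deduplication, footprint size selection, and a toy exact-match aligner for
# synthetic reads.

#' Describe the library read layout
#'
#' The sequenced read carries, 5' to 3': a 2 nt RT-primer UMI, the insert
#' (footprint or RNA fragment), a 5 nt linker UMI, and a 5 nt sample barcode.
#' The full 7 nt UMI used for deduplication is the RT UMI concatenated with
#' the linker UMI.
#'
#' @param barcode_map named character vector: barcode sequence -> sample name.
#' @param linker_umi_len,barcode_len,rt_umi_len segment lengths in nt.
#' @return A list of class `read_layout`.
#' @export
read_layout <- function(barcode_map, linker_umi_len = 5L, barcode_len = 5L,
                        rt_umi_len = 2L) {
  bcs <- names(barcode_map)
  if (is.null(bcs) || !length(bcs))
    stop("barcode_map must be a named vector (barcode -> sample)")
  if (anyDuplicated(bcs)) stop("barcodes must be unique")
  if (any(nchar(bcs) != barcode_len))
    stop("all barcodes must have length barcode_len = ", barcode_len)
  if (any(grepl("[^ACGTN]", bcs)))
    stop("barcodes must be over the alphabet ACGTN")
  structure(list(barcode_map = barcode_map,
                 linker_umi_len = as.integer(linker_umi_len),
                 barcode_len = as.integer(barcode_len),
                 rt_umi_len = as.integer(rt_umi_len)),
            class = "read_layout")
}

.read_fastq <- function(path) {
  ss <- Biostrings::readDNAStringSet(path, format = "fastq")
  data.table(read_id = sub("\\s.*$", "", names(ss)),
             seq = as.character(ss))
}

#' Trim linkers and demultiplex pooled reads
#'
#' Strips the 3' linker (5 nt UMI + 5 nt barcode) and the 5' RT UMI from each
#' raw read, assigns the read to a sample by exact barcode match, and attaches
#' the combined 7 nt UMI. Reads with an unknown barcode are routed to the
#' `"unassigned"` bin (never dropped silently); reads too short to contain an
#' insert are discarded and counted.
#'
#' @param reads a FASTQ path, or a `data.table` with columns `read_id`, `seq`.
#' @param layout a [read_layout()].
#' @return list with `reads` (`data.table`: `sample`, `read_id`, `insert`,
#'   `umi`) and `counters` (named integer: `input`, `assigned`, `unassigned`,
#'   `discarded`). Conservation: `assigned + unassigned + discarded == input`.
#' @export
demultiplex_and_trim <- function(reads, layout) {
  if (is.character(reads)) reads <- .read_fastq(reads)
  reads <- as.data.table(reads)
  n_in <- nrow(reads)
  L <- nchar(reads$seq)
  min_len <- layout$rt_umi_len + layout$linker_umi_len + layout$barcode_len + 1L
  ok <- L >= min_len
  kept <- reads[ok]
  Lk <- L[ok]
  tail_len <- layout$linker_umi_len + layout$barcode_len
  out <- data.table(
    read_id = kept$read_id,
    insert = substr(kept$seq, layout$rt_umi_len + 1L, Lk - tail_len),
    umi = paste0(substr(kept$seq, 1L, layout$rt_umi_len),
                 substr(kept$seq, Lk - tail_len + 1L,
                        Lk - layout$barcode_len)),
    barcode = substr(kept$seq, Lk - layout$barcode_len + 1L, Lk))
  out[, sample := layout$barcode_map[barcode]]
  out[is.na(sample), sample := "unassigned"]
  counters <- c(input = n_in,
                assigned = sum(out$sample != "unassigned"),
                unassigned = sum(out$sample == "unassigned"),
                discarded = n_in - nrow(out))
  list(reads = out[, .(sample, read_id, insert, umi)], counters = counters)
}

#' Remove PCR duplicates by exact UMI-key collapse
#'
#' Retains exactly one read per (`sample`, `gene_id`, `three_prime_pos`,
#' `read_len`, `umi`) key. No UMI-distance clustering is performed: two reads
#' are duplicates only when the full key matches. Idempotent.
#'
#' @param alignments `data.table` of aligned reads with the key columns above.
#' @return Deduplicated `data.table` (one row per key, `count` set to 1), with
#'   attribute `dedup_stats` = `c(input, retained)`.
#' @export
dedup_umis <- function(alignments) {
  alignments <- as.data.table(alignments)
  key_cols <- c("sample", "gene_id", "three_prime_pos", "read_len", "umi")
  miss <- setdiff(key_cols, names(alignments))
  if (length(miss))
    stop("alignments lack dedup key column(s): ", paste(miss, collapse = ", "))
  n_in <- if ("count" %in% names(alignments)) sum(alignments$count)
          else nrow(alignments)
  out <- unique(alignments, by = key_cols)
  out[, count := 1L]
  setattr(out, "dedup_stats",
          c(input = as.integer(n_in), retained = nrow(out)))
  out[]
}

#' Select footprints by read length class
#'
#' Monosome footprints keep 25-34 nt, disome footprints 57-63 nt, RNA-seq
#' reads exactly 50 nt (ranges taken from `params`).
#'
#' @param alignments `data.table` with a `read_len` column.
#' @param class one of `"monosome"`, `"disome"`, `"rna"`.
#' @param params an [analysis_params()].
#' @return Filtered `data.table`, with attribute `size_select_stats`.
#' @export
size_select <- function(alignments, class = c("monosome", "disome", "rna"),
                        params = analysis_params()) {
  class <- match.arg(class)
  alignments <- as.data.table(alignments)
  rng <- switch(class,
                monosome = params$mono_len_range,
                disome = params$disome_len_range,
                rna = c(params$rna_len, params$rna_len))
  out <- alignments[read_len >= rng[1] & read_len <= rng[2]]
  setattr(out, "size_select_stats",
          c(input = nrow(alignments), kept = nrow(out),
            dropped = nrow(alignments) - nrow(out)))
  out[]
}

#' Exact-match alignment of synthetic inserts to a transcriptome
#'
#' Places each insert by exact, unique substring match against the
#' sense-strand transcript sequences. Reads matching more than one location
#' (within or across genes) are dropped as multimappers; reads with no
#' sense-strand match (including reverse-complement-only matches) are dropped
#' as unaligned. `three_prime_pos` is the 0-based transcript coordinate of the
#' match's 3'-most base.
#'
#' @param reads `data.table` with columns `sample`, `read_id`, `insert` and
#'   optionally `umi`.
#' @param txome a `transcriptome`.
#' @return `data.table` (`sample`, `read_id`, `gene_id`, `three_prime_pos`,
#'   `read_len`, `umi`, `count`) with attribute `align_stats`
#'   (`input`, `aligned`, `unaligned`, `multimapped`).
#' @export
toy_align <- function(reads, txome) {
  reads <- as.data.table(reads)
  if (!"umi" %in% names(reads)) reads[, umi := NA_character_]
  inserts <- unique(reads$insert)
  gene_ids <- txome$genes$gene_id
  hit_gene <- character(length(inserts))
  hit_pos <- integer(length(inserts))
  status <- character(length(inserts))
  for (i in seq_along(inserts)) {
    ins <- inserts[i]
    n_hits <- 0L
    for (gid in gene_ids) {
      m <- gregexpr(ins, txome$seqs[[gid]], fixed = TRUE)[[1]]
      if (m[1] != -1L) {
        n_hits <- n_hits + length(m)
        if (n_hits > 1L) break
        hit_gene[i] <- gid
        hit_pos[i] <- m[1]
      }
    }
    status[i] <- if (n_hits == 1L) "aligned"
                 else if (n_hits == 0L) "unaligned" else "multimapped"
  }
  lut <- data.table(insert = inserts, gene_id = hit_gene,
                    start1 = hit_pos, status = status)
  merged <- merge(reads, lut, by = "insert", sort = FALSE)
  aligned <- merged[status == "aligned",
                    .(sample, read_id, gene_id,
                      three_prime_pos = start1 - 1L + nchar(insert) - 1L,
                      read_len = nchar(insert), umi, count = 1L)]
  stats <- c(input = nrow(reads),
             aligned = nrow(aligned),
             unaligned = sum(merged$status == "unaligned"),
             multimapped = sum(merged$status == "multimapped"))
  setattr(aligned, "align_stats", stats)
  aligned[]
}

#' Pass-through contaminant filter hook
#'
#' Removes reads whose insert exactly matches a blocklist sequence (e.g.
#' rRNA). The default blocklist is empty, making this a no-op for synthetic
#' data.
#'
#' @param reads `data.table` with an `insert` column.
#' @param blocklist character vector of contaminant sequences.
#' @return Filtered `data.table` with attribute `filter_stats`.
#' @export
filter_contaminants <- function(reads, blocklist = character()) {
  reads <- as.data.table(reads)
  out <- if (length(blocklist)) reads[!insert %in% blocklist] else reads
  setattr(out, "filter_stats",
          c(input = nrow(reads), kept = nrow(out),
            removed = nrow(reads) - nrow(out)))
  out[]
}

#' Write stage counters as a tab-separated QC report
#' @param counters named list of named integer vectors (one per stage).
#' @param path output path.
#' @export
write_qc_report <- function(counters, path) {
  dt <- rbindlist(lapply(names(counters), function(stage)
    data.table(stage = stage, metric = names(counters[[stage]]),
               value = as.integer(counters[[stage]]))))
  fwrite(dt, path, sep = "\t")
  invisible(path)
}
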