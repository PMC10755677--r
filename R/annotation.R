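#' @import data.table
#' @importFrom stats rbinom rnbinom rpois runif setNames
#' @importFrom utils head tail
NULL

# Transcript coordinates are 0-based, half-open, sense-strand throughout.
# A GeneModel row: gene_id, utr5_len, cds_len, utr3_len with
# cds_start == utr5_len and cds_end == utr5_len + cds_len.

#' Construct a transcriptome object
#'
#' A `transcriptome` bundles per-transcript sense-strand sequences with a gene
#' model table giving 5' UTR, CDS and 3' UTR extents, plus the protein
#' translation of each CDS. All downstream statistics (occupancy tracks, pause
#' scores, metagenes, quantitation) consume this object.
#'
#' @param genes `data.table` with columns `gene_id`, `utr5_len`, `cds_len`,
#'   `utr3_len` (all nucleotides).
#' @param seqs named character vector of transcript sequences (5'->3',
#'   sense strand), names matching `gene_id`.
#' @param overlap_flags optional named logical vector marking genes whose ORF
#'   overlaps another ORF (used by metagene exclusion rules). Defaults to
#'   all-`FALSE`.
#' @param drop_invalid if `TRUE` (default), genes failing frame or length
#'   checks are dropped with a warning; if `FALSE` they raise an error.
#' @return An object of class `transcriptome`: a list with elements `genes`
#'   (a `data.table` with derived columns `cds_start`, `cds_end`, `tx_len`,
#'   `protein`, `overlaps_orf`) and `seqs`.
#' @export
transcriptome <- function(genes, seqs, overlap_flags = NULL, drop_invalid = TRUE) {
  genes <- as.data.table(genes)
  req <- c("gene_id", "utr5_len", "cds_len", "utr3_len")
  if (!all(req %in% names(genes)))
    stop("gene model must have columns: ", paste(req, collapse = ", "))
  if (anyDuplicated(genes$gene_id))
    stop("duplicate gene_ids in gene model")
  if (nrow(genes) == 0L) {
    return(structure(list(
      genes = data.table(gene_id = character(), utr5_len = integer(),
                         cds_len = integer(), utr3_len = integer(),
                         cds_start = integer(), cds_end = integer(),
                         tx_len = integer(), protein = character(),
                         overlaps_orf = logical()),
      seqs = character()), class = "transcriptome"))
  }
  missing_seq <- setdiff(genes$gene_id, names(seqs))
  if (length(missing_seq))
    stop("missing sequence for gene model row(s): ",
         paste(head(missing_seq, 5L), collapse = ", "))
  seqs <- toupper(seqs[genes$gene_id])

  genes[, `:=`(cds_start = as.integer(utr5_len),
               cds_end   = as.integer(utr5_len + cds_len),
               tx_len    = as.integer(utr5_len + cds_len + utr3_len))]

  bad <- character()
  note <- character()
  prot <- rep(NA_character_, nrow(genes))
  for (i in seq_len(nrow(genes))) {
    g <- genes[i]
    if (g$cds_len <= 0L || g$cds_len %% 3L != 0L) {
      bad <- c(bad, g$gene_id)
      note <- c(note, sprintf("%s: CDS length %d not a positive multiple of 3",
                              g$gene_id, g$cds_len))
      next
    }
    if (nchar(seqs[[g$gene_id]]) != g$tx_len) {
      bad <- c(bad, g$gene_id)
      note <- c(note, sprintf("%s: sequence length %d != utr5+cds+utr3 = %d",
                              g$gene_id, nchar(seqs[[g$gene_id]]), g$tx_len))
      next
    }
    p <- tryCatch(
      translate_cds(seqs[[g$gene_id]], g$cds_start, g$cds_end),
      error = function(e) e)
    if (inherits(p, "error")) {
      bad <- c(bad, g$gene_id)
      note <- c(note, sprintf("%s: %s", g$gene_id, conditionMessage(p)))
      next
    }
    prot[i] <- p
  }
  if (length(bad)) {
    msg <- paste0("dropping ", length(bad), " gene(s) failing validation:\n  ",
                  paste(note, collapse = "\n  "))
    if (!drop_invalid) stop(msg)
    warning(msg, call. = FALSE)
  }
  genes[, protein := prot]
  keep <- !(genes$gene_id %in% bad)
  genes <- genes[keep]
  seqs <- seqs[genes$gene_id]

  if (is.null(overlap_flags)) {
    genes[, overlaps_orf := FALSE]
  } else {
    genes[, overlaps_orf := unname(overlap_flags[gene_id])]
    genes[is.na(overlaps_orf), overlaps_orf := FALSE]
  }
  structure(list(genes = genes[], seqs = seqs), class = "transcriptome")
}

#' @export
print.transcriptome <- function(x, ...) {
  cat(sprintf("<transcriptome> %d gene(s), %s nt total\n",
              nrow(x$genes), format(sum(x$genes$tx_len), big.mark = ",")))
  invisible(x)
}

#' Translate a CDS with the standard genetic code
#'
#' Translates `seq[cds_start, cds_end)` and strips the terminal stop codon.
#' An internal stop codon is an error that reports the offending codon index.
#'
#' @param seq transcript sequence (character scalar).
#' @param cds_start,cds_end 0-based half-open CDS bounds in `seq`.
#' @return Amino-acid string without the stop symbol.
#' @export
translate_cds <- function(seq, cds_start, cds_end) {
  len <- cds_end - cds_start
  if (len <= 0L || len %% 3L != 0L)
    stop("CDS length ", len, " is not a positive multiple of 3")
  cds <- substr(seq, cds_start + 1L, cds_end)
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                           if.fuzzy.codon = "error"))
  n <- nchar(aa)
  body <- substr(aa, 1L, n - 1L)
  internal <- regexpr("*", body, fixed = TRUE)
  if (internal > 0L)
    stop("internal stop codon at codon ", internal, " (1-based)")
  if (substr(aa, n, n) != "*")
    stop("CDS does not end in a stop codon")
  body
}

#' Map codon indices to transcript nucleotide positions
#'
#' Codon `c` (0-based, counted from the start codon) occupies the transcript
#' interval `[cds_start + 3c, cds_start + 3c + 3)`.
#'
#' @param gene one row of a transcriptome's `genes` table (or a list with
#'   `cds_start`).
#' @param codon_index 0-based codon index (vectorised).
#' @return 0-based transcript position of the codon's first nucleotide.
#' @export
codon_to_nt <- function(gene, codon_index) {
  gene$cds_start + 3L * as.integer(codon_index)
}

#' @rdname codon_to_nt
#' @param nt_pos 0-based transcript position (must lie in the CDS).
#' @export
nt_to_codon <- function(gene, nt_pos) {
  (as.integer(nt_pos) - gene$cds_start) %/% 3L
}

#' Load a transcriptome from FASTA sequences and a gene model table
#'
#' The gene model is a 4-column tab-separated table (`gene_id`, `utr5_len`,
#' `cds_len`, `utr3_len`). FASTA records and model rows are matched by
#' `gene_id`; a model row without a sequence is a hard error, while genes
#' failing frame/length checks are reported and dropped.
#'
#' @param fasta_path FASTA file of spliced transcript sequences (sense strand).
#' @param model_path tab-separated gene model file with a header row.
#' @param overlap_flags optional named logical vector, see [transcriptome()].
#' @return A `transcriptome`.
#' @export
load_transcriptome <- function(fasta_path, model_path, overlap_flags = NULL) {
  model <- fread(model_path, sep = "\t", header = TRUE,
                 colClasses = list(character = "gene_id"))
  if (nrow(model) == 0L)
    return(transcriptome(model, character()))
  ss <- Biostrings::readDNAStringSet(fasta_path)
  names(ss) <- sub("\\s.*$", "", names(ss))
  seqs <- setNames(as.character(ss), names(ss))
  transcriptome(model, seqs, overlap_flags = overlap_flags)
}

#' Write a transcriptome back to FASTA + gene model files
#'
#' Inverse of [load_transcriptome()]: `load_transcriptome()` after
#' `write_transcriptome()` reproduces the object on valid inputs.
#'
#' @param txome a `transcriptome`.
#' @param fasta_path,model_path output paths.
#' @export
write_transcriptome <- function(txome, fasta_path, model_path) {
  ss <- Biostrings::DNAStringSet(txome$seqs)
  Biostrings::writeXStringSet(ss, fasta_path)
  fwrite(txome$genes[, .(gene_id, utr5_len, cds_len, utr3_len)],
         model_path, sep = "\t")
  invisible(c(fasta = fasta_path, model = model_path))
}

#' Convert a GFF3 annotation into the 4-column gene model table
#'
#' Import shim: reads `CDS`, `five_prime_UTR` and `three_prime_UTR` features
#' grouped by their `Parent` (or `ID`) attribute and emits per-transcript UTR
#' and CDS extents. Feature lengths are summed across segments, so spliced
#' models collapse to the transcript-relative lengths this package uses.
#'
#' @param gff3_path path to a GFF3 file.
#' @return `data.table` with columns `gene_id`, `utr5_len`, `cds_len`,
#'   `utr3_len`.
#' @export
gff3_to_gene_model <- function(gff3_path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("gff3_to_gene_model() requires the rtracklayer package")
  gr <- rtracklayer::import(gff3_path, format = "gff3")
  keep <- gr$type %in% c("CDS", "five_prime_UTR", "three_prime_UTR")
  gr <- gr[keep]
  parent <- as.character(vapply(as.list(gr$Parent), function(p)
    if (length(p)) p[[1L]] else NA_character_, character(1)))
  ids <- ifelse(is.na(parent) | parent == "", as.character(gr$ID), parent)
  dt <- data.table(gene_id = ids, type = as.character(gr$type),
                   width = as.data.frame(gr)$width)
  wide <- dcast(dt[, .(len = sum(width)), by = .(gene_id, type)],
                gene_id ~ type, value.var = "len", fill = 0L)
  for (col in c("CDS", "five_prime_UTR", "three_prime_UTR"))
    if (!col %in% names(wide)) wide[, (col) := 0L]
  wide[, .(gene_id,
           utr5_len = as.integer(five_prime_UTR),
           cds_len = as.integer(CDS),
           utr3_len = as.integer(three_prime_UTR))]
}
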