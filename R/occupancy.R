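# Normalized per-nucleotide occupancy tracks and ribosome-site coordinate
# conventions. Footprints are aligned by their 3' ends; fixed shifts map the
# 3'-end coordinate to ribosomal sites (-15 nt -> P site for gene
# quantitation, -18 nt -> E-site codon start for pause scoring, i.e. the
# pause score reads the track at E-site codon start + 18).

#' Numeric conventions for the whole analysis
#'
#' Collects every shift, window, length range and threshold in one validated
#' object. Defaults are the reference conventions: 18 nt E-site shift, 15 nt
#' P-site shift, +/-50 nt pause window, >=100 motif occurrences, 1.5-fold
#' foreground cut, 15 nt ORF end trim, (100, 300) start-codon and (300, 100)
#' stop-codon metagene windows, 25-34 nt monosome and 57-63 nt disome
#' footprints, 50 nt RNA reads.
#'
#' @param e_site_shift nt from footprint 3' end back to the E-site codon
#'   start (pause-score readout).
#' @param p_site_shift nt from footprint 3' end back to the P site (gene
#'   quantitation).
#' @param pause_window half-width (nt) of the pause-score window.
#' @param min_motif_occurrences motifs seen fewer times genome-wide are
#'   excluded from motif averages.
#' @param fg_fold fold-change cut defining foreground motifs in condition
#'   comparisons.
#' @param end_trim nt removed from both ORF ends for quantitation and
#'   pause-site eligibility.
#' @param metagene_start_window `c(upstream, into_orf)` nt for the
#'   start-codon metagene.
#' @param metagene_stop_window `c(orf, downstream)` nt for the stop-codon
#'   metagene.
#' @param mono_len_range,disome_len_range,rna_len size selections (nt).
#' @return A list of class `analysis_params`.
#' @export
analysis_params <- function(e_site_shift = 18L,
                            p_site_shift = 15L,
                            pause_window = 50L,
                            min_motif_occurrences = 100L,
                            fg_fold = 1.5,
                            end_trim = 15L,
                            metagene_start_window = c(100L, 300L),
                            metagene_stop_window = c(300L, 100L),
                            mono_len_range = c(25L, 34L),
                            disome_len_range = c(57L, 63L),
                            rna_len = 50L) {
  p <- list(e_site_shift = as.integer(e_site_shift),
            p_site_shift = as.integer(p_site_shift),
            pause_window = as.integer(pause_window),
            min_motif_occurrences = as.integer(min_motif_occurrences),
            fg_fold = fg_fold,
            end_trim = as.integer(end_trim),
            metagene_start_window = as.integer(metagene_start_window),
            metagene_stop_window = as.integer(metagene_stop_window),
            mono_len_range = as.integer(mono_len_range),
            disome_len_range = as.integer(disome_len_range),
            rna_len = as.integer(rna_len))
  nums <- unlist(p[c("e_site_shift", "p_site_shift", "pause_window",
                     "min_motif_occurrences", "fg_fold")])
  if (any(nums <= 0)) stop("all analysis parameters must be positive")
  if (p$end_trim < 0L) stop("end_trim must be >= 0")
  # one codon separates the E- and P-site readout under these conventions
  if (p$e_site_shift - p$p_site_shift != 3L)
    warning("e_site_shift - p_site_shift != 3: the E- and P-site readouts ",
            "are no longer one codon apart", call. = FALSE)
  structure(p, class = "analysis_params")
}

#' Map an E-site codon start to its pause-score track position
#'
#' The pause score reads the 3'-end track at `e_codon_start + e_site_shift`
#' (default 18 nt), the coordinate where footprints from a ribosome holding
#' this codon in its E site deposit their 3' ends.
#'
#' @param e_codon_start 0-based transcript position of the E-site codon's
#'   first nt (vectorised).
#' @param params an [analysis_params()].
#' @return 0-based track position(s).
#' @export
site_position <- function(e_codon_start, params = analysis_params()) {
  as.integer(e_codon_start) + params$e_site_shift
}

#' Build normalized occupancy tracks
#'
#' Under the `three_prime_end` convention each read adds its count at the
#' transcript position of its 3'-most base; under `coverage` at every
#' position it spans. Raw counts are converted to rpm (reads per million
#' mapped reads) by dividing by the sample's total mapped reads and
#' multiplying by 1e6. The denominator is the total read count of the
#' supplied (deduplicated, size-selected) alignment table.
#'
#' @param alignments `data.table` with `gene_id`, `three_prime_pos`,
#'   `read_len` and optionally `count` (default 1 per row).
#' @param txome a `transcriptome`; tracks span the full transcript, UTRs
#'   included.
#' @param convention `"three_prime_end"` or `"coverage"`.
#' @param sample_name label stored on the track set (defaults to the
#'   alignments' single `sample` value).
#' @return list of class `track_set`: `tracks` (named list of per-transcript
#'   rpm vectors), `convention`, `sample`, `total_mapped`.
#' @export
build_track <- function(alignments, txome,
                        convention = c("three_prime_end", "coverage"),
                        sample_name = NULL) {
  convention <- match.arg(convention)
  aln <- as.data.table(alignments)
  if (!"count" %in% names(aln)) aln[, count := 1L]
  if (is.null(sample_name))
    sample_name <- if ("sample" %in% names(aln) && nrow(aln))
      paste(sort(unique(aln$sample)), collapse = "+") else "sample"
  total <- sum(aln$count)
  if (total == 0L)
    stop("no mapped reads for sample ", sample_name, "; cannot normalize")
  unknown <- setdiff(unique(aln$gene_id), txome$genes$gene_id)
  if (length(unknown))
    stop("alignments reference unknown gene(s): ",
         paste(head(unknown, 5L), collapse = ", "))
  lens <- setNames(txome$genes$tx_len, txome$genes$gene_id)
  bad <- aln[three_prime_pos < 0L | three_prime_pos >= lens[gene_id]]
  if (nrow(bad))
    stop("alignment positions outside transcript bounds for gene(s): ",
         paste(head(unique(bad$gene_id), 5L), collapse = ", "))

  scale <- 1e6 / total
  tracks <- setNames(lapply(lens, function(L) numeric(L)), names(lens))
  if (convention == "three_prime_end")  # lengths are irrelevant: collapse
    aln <- aln[, .(count = sum(count)), by = .(gene_id, three_prime_pos)]
  by_gene <- split(aln, by = "gene_id")
  for (gid in names(by_gene)) {
    a <- by_gene[[gid]]
    v <- numeric(lens[[gid]])
    if (convention == "three_prime_end") {
      v[a$three_prime_pos + 1L] <- a$count
    } else {
      # coverage via delta encoding: +count at 5' end, -count after 3' end
      delta <- numeric(lens[[gid]] + 1L)
      start1 <- pmax(a$three_prime_pos - a$read_len + 2L, 1L)
      end1 <- a$three_prime_pos + 1L
      inc <- rowsum(a$count, start1)
      dec <- rowsum(a$count, end1 + 1L)
      delta[as.integer(rownames(inc))] <- inc[, 1L]
      ii <- as.integer(rownames(dec))
      delta[ii] <- delta[ii] - dec[, 1L]
      v <- cumsum(delta[seq_len(lens[[gid]])])
    }
    tracks[[gid]] <- v * scale
  }
  structure(list(tracks = tracks, convention = convention,
                 sample = sample_name, total_mapped = total),
            class = "track_set")
}

#' @export
print.track_set <- function(x, ...) {
  cat(sprintf("<track_set> sample=%s convention=%s genes=%d total_mapped=%d\n",
              x$sample, x$convention, length(x$tracks), x$total_mapped))
  invisible(x)
}

#' Export occupancy tracks as a per-gene tab-separated (bedGraph-like) file
#'
#' One row per nonzero position: `gene_id`, `position` (0-based), `rpm`.
#' Header comment lines record the convention, sample and total mapped reads
#' so [import_tracks()] can rebuild the `track_set` exactly.
#'
#' @param track_set a `track_set`.
#' @param path output path.
#' @export
export_tracks <- function(track_set, path) {
  hdr <- sprintf("#ribopause_track\tconvention=%s\tsample=%s\ttotal_mapped=%d",
                 track_set$convention, track_set$sample,
                 track_set$total_mapped)
  rows <- rbindlist(lapply(names(track_set$tracks), function(gid) {
    v <- track_set$tracks[[gid]]
    nz <- which(v != 0)
    data.table(gene_id = gid, position = nz - 1L, rpm = v[nz])
  }))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  write.table(rows, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname export_tracks
#' @param txome the `transcriptome` the tracks were built against (supplies
#'   transcript lengths and the gene universe).
#' @return `import_tracks()` returns the rebuilt `track_set`.
#' @export
import_tracks <- function(path, txome) {
  hdr <- readLines(path, n = 1L)
  if (!startsWith(hdr, "#ribopause_track"))
    stop("not a ribopause track file: ", path)
  fields <- strsplit(sub("^#ribopause_track\t", "", hdr), "\t")[[1]]
  kv <- strsplit(fields, "=", fixed = TRUE)
  meta <- setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
  rows <- fread(path, sep = "\t", skip = 1L, header = TRUE)
  lens <- setNames(txome$genes$tx_len, txome$genes$gene_id)
  tracks <- setNames(lapply(lens, function(L) numeric(L)), names(lens))
  for (gid in unique(rows$gene_id)) {
    r <- rows[gene_id == gid]
    tracks[[gid]][r$position + 1L] <- r$rpm
  }
  structure(list(tracks = tracks, convention = meta[["convention"]],
                 sample = meta[["sample"]],
                 total_mapped = as.integer(meta[["total_mapped"]])),
            class = "track_set")
}
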