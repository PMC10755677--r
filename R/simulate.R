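# Synthetic transcriptomes and footprint libraries with planted pauses.
#
# The generative model: the ribosome decoding codon `a` (A site) yields
# monosome footprints whose 3' end falls at E-site codon start + 18 nt,
# i.e. cds_start + 3a + 12, with +/- `end_jitter` nt of end heterogeneity
# (RNase trimming variability). Per-codon read counts are negative binomial
# with mean base_depth * m, where m is the multiplicative pause strength of
# the tri-amino-acid motif completed by codon `a` (1 elsewhere).

.AA20 <- sort(setdiff(unique(Biostrings::GENETIC_CODE), "*"))

.codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
}

#' Simulation configuration
#'
#' Defaults describe the package's reference study conditions: a yeast-like
#' (scaled-down) transcriptome of 800 genes with 1200-1800 nt CDSs, 150 nt
#' UTRs, uniform amino-acid composition, negative-binomial count noise
#' (dispersion 10), monosome footprints of 25-34 nt, disome footprints of
#' 57-63 nt and 50 nt RNA-seq reads.
#'
#' @param seed integer seed; identical configs reproduce identical output.
#' @param n_genes number of transcripts to simulate.
#' @param cds_len_range CDS length range in nt (rounded to codons).
#' @param utr5_len,utr3_len fixed UTR lengths in nt.
#' @param motif_multipliers named numeric vector mapping tri-amino-acid motifs
#'   (E,P,A order, e.g. `c(KIP = 5)`) to multiplicative pause strengths
#'   (all >= 1). Every occurrence of a configured motif — planted or arising
#'   by chance — receives its multiplier.
#' @param sites_per_motif number of sites planted per configured motif, each
#'   placed at least 17 codons from both CDS ends so pause windows are
#'   eligible.
#' @param base_depth mean reads per codon for unpaused codons.
#' @param dispersion negative-binomial size parameter
#'   (variance = mean + mean^2 / dispersion).
#' @param rna_depth mean RNA-seq reads per codon-equivalent of transcript.
#' @param mono_len_range,disome_len_range footprint length ranges (nt); must
#'   lie within the 25-34 and 57-63 nt size selections.
#' @param rna_read_len RNA-seq read length (nt).
#' @param collision_prob probability that a ribosome paused at a motif codon
#'   yields a disome footprint.
#' @param end_jitter half-width (nt) of uniform 3'-end heterogeneity; 0 places
#'   every 3' end exactly at E-site codon start + 18.
#' @param dup_factor PCR duplication factor used when writing FASTQ: every
#'   unique molecule is emitted this many times.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 800L,
                       cds_len_range = c(1200L, 1800L),
                       utr5_len = 150L,
                       utr3_len = 150L,
                       motif_multipliers = numeric(),
                       sites_per_motif = 200L,
                       base_depth = 2,
                       dispersion = 10,
                       rna_depth = base_depth,
                       mono_len_range = c(25L, 34L),
                       disome_len_range = c(57L, 63L),
                       rna_read_len = 50L,
                       collision_prob = 0.1,
                       end_jitter = 1L,
                       dup_factor = 1L) {
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              cds_len_range = as.integer(cds_len_range),
              utr5_len = as.integer(utr5_len), utr3_len = as.integer(utr3_len),
              motif_multipliers = motif_multipliers,
              sites_per_motif = as.integer(sites_per_motif),
              base_depth = base_depth, dispersion = dispersion,
              rna_depth = rna_depth,
              mono_len_range = as.integer(mono_len_range),
              disome_len_range = as.integer(disome_len_range),
              rna_read_len = as.integer(rna_read_len),
              collision_prob = collision_prob,
              end_jitter = as.integer(end_jitter),
              dup_factor = as.integer(dup_factor))
  if (length(cfg$motif_multipliers)) {
    motifs <- names(cfg$motif_multipliers)
    if (is.null(motifs) || any(nchar(motifs) != 3L) ||
        !all(strsplit(paste(motifs, collapse = ""), "")[[1]] %in% .AA20))
      stop("motif_multipliers names must be 3-letter motifs over the 20 ",
           "standard amino acids")
    if (any(cfg$motif_multipliers < 1))
      stop("pause multipliers must be >= 1")
  }
  if (cfg$base_depth <= 0) stop("base_depth must be > 0")
  if (cfg$dispersion <= 0) stop("dispersion must be > 0")
  if (cfg$mono_len_range[1] < 25L || cfg$mono_len_range[2] > 34L)
    stop("mono_len_range must lie within [25, 34] nt")
  if (cfg$disome_len_range[1] < 57L || cfg$disome_len_range[2] > 63L)
    stop("disome_len_range must lie within [57, 63] nt")
  if (cfg$collision_prob < 0 || cfg$collision_prob > 1)
    stop("collision_prob must be in [0, 1]")
  if (cfg$end_jitter < 0L) stop("end_jitter must be >= 0")
  if (cfg$dup_factor < 1L) stop("dup_factor must be >= 1")
  structure(cfg, class = "sim_config")
}

# margin (in codons, 0-based E-site index) keeping planted pause windows
# eligible after the 18 nt shift and 15 nt end trim
.PLANT_MARGIN_LO <- 20L
.PLANT_MARGIN_HI <- 31L

#' Simulate a transcriptome with planted pause motifs
#'
#' Draws random CDSs (uniform amino-acid composition, uniform synonymous-codon
#' choice, no internal stops) plus random UTRs, then overwrites
#' `sites_per_motif` positions per configured motif with that motif's residues.
#' Planted sites sit at least 17 codons from both CDS ends, so their +/-50 nt
#' pause window is always eligible.
#'
#' @param config a [sim_config()].
#' @return A `transcriptome` with attributes `planted` (a `data.table`:
#'   `gene_id`, `motif`, `e_index`) and `sim_config`.
#' @export
simulate_transcriptome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_codons_range <- config$cds_len_range %/% 3L
  motifs <- names(config$motif_multipliers)

  n_cod <- sample(n_codons_range[1]:n_codons_range[2], config$n_genes,
                  replace = TRUE)
  l_aa <- n_cod - 1L                      # protein length (stop translated off)
  if (length(motifs) &&
      min(l_aa) - .PLANT_MARGIN_HI < .PLANT_MARGIN_LO)
    stop("cds_len_range too short to plant motifs away from CDS ends ",
         "(need >= ", 3L * (.PLANT_MARGIN_LO + .PLANT_MARGIN_HI + 1L),
         " nt of CDS)")

  prots <- lapply(l_aa, function(L) c("M", sample(.AA20, L - 1L, replace = TRUE)))

  planted <- data.table(gene_id = character(), motif = character(),
                        e_index = integer())
  if (length(motifs)) {
    taken <- vector("list", config$n_genes)   # planted e-indices per gene
    for (mf in motifs) {
      aa3 <- strsplit(mf, "")[[1]]
      placed <- 0L
      guard <- 0L
      while (placed < config$sites_per_motif) {
        guard <- guard + 1L
        if (guard > 50L * config$sites_per_motif)
          stop("unable to place ", config$sites_per_motif,
               " sites for motif ", mf, "; enlarge the transcriptome")
        gi <- sample.int(config$n_genes, 1L, prob = l_aa)
        e <- sample(.PLANT_MARGIN_LO:(l_aa[gi] - .PLANT_MARGIN_HI), 1L)
        if (length(taken[[gi]]) && any(abs(taken[[gi]] - e) < 3L)) next
        prots[[gi]][(e + 1L):(e + 3L)] <- aa3
        taken[[gi]] <- c(taken[[gi]], e)
        planted <- rbind(planted,
                         data.table(gene_id = sprintf("g%04d", gi),
                                    motif = mf, e_index = e))
        placed <- placed + 1L
      }
    }
  }

  ct <- .codon_table()
  stops <- ct[["*"]]
  reverse_translate <- function(aavec) {
    out <- character(length(aavec))
    for (r in unique(aavec)) {
      idx <- which(aavec == r)
      out[idx] <- sample(ct[[r]], length(idx), replace = TRUE)
    }
    out
  }
  all_aa <- unlist(prots)
  all_codons <- reverse_translate(all_aa)
  ends <- cumsum(l_aa)
  starts <- ends - l_aa + 1L

  rand_nt <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                               collapse = "")
  seqs <- character(config$n_genes)
  for (i in seq_len(config$n_genes)) {
    cds <- paste0(paste(all_codons[starts[i]:ends[i]], collapse = ""),
                  sample(stops, 1L))
    seqs[i] <- paste0(rand_nt(config$utr5_len), cds, rand_nt(config$utr3_len))
  }
  ids <- sprintf("g%04d", seq_len(config$n_genes))
  names(seqs) <- ids

  genes <- data.table(gene_id = ids,
                      utr5_len = config$utr5_len,
                      cds_len = 3L * (l_aa + 1L),
                      utr3_len = config$utr3_len)
  tx <- transcriptome(genes, seqs)
  setattr(tx, "planted", planted)
  setattr(tx, "sim_config", config)
  tx
}

# split integer counts uniformly over k cells, vectorised over positions
.split_uniform <- function(counts, k) {
  out <- matrix(0L, nrow = length(counts), ncol = k)
  remaining <- counts
  for (j in seq_len(k - 1L)) {
    out[, j] <- rbinom(length(remaining), remaining, 1 / (k - j + 1L))
    remaining <- remaining - out[, j]
  }
  out[, k] <- remaining
  out
}

# splits (gene, pos) counts uniformly over read lengths; also drops empty
# cells and reads whose 5' end would fall before the transcript start
.expand_lengths <- function(dt, lens) {
  if (nrow(dt) == 0L)
    return(data.table(gene_id = character(), three_prime_pos = integer(),
                      read_len = integer(), count = integer()))
  k <- length(lens)
  cnt <- as.integer(.split_uniform(dt$count, k))
  gid <- rep(dt$gene_id, k)
  pos <- rep(dt$three_prime_pos, k)
  len <- rep(as.integer(lens), each = nrow(dt))
  keep <- which(cnt > 0L & pos - len + 1L >= 0L)
  setDT(list(gene_id = gid[keep], three_prime_pos = pos[keep],
             read_len = len[keep], count = cnt[keep]))[]
}

#' Simulate footprint libraries from a transcriptome
#'
#' Generates monosome, disome and RNA-seq read placements under the package's
#' occupancy model (see [sim_config()]) together with the ground-truth
#' expected relative occupancy of every codon.
#'
#' Monosome 3' ends fall at E-site codon start + 18 nt (+/- `end_jitter`);
#' read lengths are uniform over `mono_len_range` (5' end varies, 3' end
#' fixed). Disome footprints arise only from paused ribosomes, each with
#' probability `collision_prob`, under the same 3'-end rule. RNA-seq reads are
#' uniform over the transcript and counted by coverage downstream.
#'
#' @param txome a `transcriptome` (typically from [simulate_transcriptome()]).
#' @param config a [sim_config()].
#' @param sample_name sample label attached to all alignment rows.
#' @param seed seed for the count draws; defaults to `config$seed`. Give each
#'   simulated sample its own seed.
#' @param classes which read classes to generate; restricting (e.g. to
#'   `"mono"`) skips the cost of the others for deep pause-only runs.
#' @return list of class `footprint_sim` with elements `mono`, `disome`,
#'   `rna` (alignment `data.table`s: `sample`, `gene_id`, `three_prime_pos`,
#'   `read_len`, `count`), and `truth` (`gene_id`, `a_codon`, `track_pos`,
#'   `motif`, `multiplier` for every codon, multiplier 1.0 off-motif).
#' @export
simulate_footprints <- function(txome, config, sample_name = "sample1",
                                seed = config$seed,
                                classes = c("mono", "disome", "rna")) {
  stopifnot(inherits(txome, "transcriptome"), inherits(config, "sim_config"))
  set.seed(seed)
  g <- txome$genes
  mult <- config$motif_multipliers

  # per-codon truth over all genes (A-site codons 2 .. L-1, 0-based)
  truth <- g[, {
    L <- nchar(protein)
    a <- 2:(L - 1L)
    list(a_codon = a,
         motif = substring(protein, a - 1L, a + 1L),
         track_pos = cds_start + 3L * a + 12L)
  }, by = gene_id]
  truth[, multiplier := 1.0]
  if (length(mult))
    truth[motif %in% names(mult), multiplier := mult[motif]]

  n <- nrow(truth)
  counts <- rnbinom(n, size = config$dispersion,
                    mu = config$base_depth * truth$multiplier)

  place <- function(dt_counts, lens) {
    jit <- config$end_jitter
    if (jit > 0L) {
      offs <- (-jit):jit
      cnt <- as.integer(.split_uniform(dt_counts$count, length(offs)))
      pos <- rep(dt_counts$track_pos, length(offs)) +
        rep(offs, each = nrow(dt_counts))
      keep <- which(cnt > 0L)
      pc <- setDT(list(gene_id = rep(dt_counts$gene_id, length(offs))[keep],
                       three_prime_pos = pos[keep], count = cnt[keep]))
    } else {
      pc <- dt_counts[, .(gene_id, three_prime_pos = track_pos, count)]
    }
    # 3'-end containment checked per position; 5'-end containment inside
    # .expand_lengths
    tx_lens <- setNames(g$tx_len, g$gene_id)
    pc <- pc[three_prime_pos >= 0L & three_prime_pos < tx_lens[gene_id]]
    out <- .expand_lengths(pc, lens[1]:lens[2])
    # with jitter <= 1 the (gene, pos, len) cells are unique by construction
    # (3'-end positions of adjacent codons are 3 nt apart); wider jitter can
    # collide, so collapse then
    if (jit >= 2L)
      out <- out[, .(count = sum(count)),
                 by = .(gene_id, three_prime_pos, read_len)]
    out
  }

  empty_aln <- function()
    data.table(gene_id = character(), three_prime_pos = integer(),
               read_len = integer(), count = integer())

  mono <- if ("mono" %in% classes)
    place(truth[, .(gene_id, track_pos, count = counts)],
          config$mono_len_range) else empty_aln()

  disome <- empty_aln()
  if ("disome" %in% classes) {
    paused <- which(truth$multiplier > 1)
    if (length(paused)) {
      dis_counts <- rbinom(length(paused), counts[paused],
                           config$collision_prob)
      disome <- place(truth[paused][, .(gene_id, track_pos,
                                        count = dis_counts)][count > 0L],
                      config$disome_len_range)
    }
  }

  rna <- empty_aln()
  if ("rna" %in% classes) {
    n_rna <- rpois(nrow(g), config$rna_depth * g$cds_len / 3)
    rna <- g[, {
      k <- n_rna[.GRP]
      if (k > 0L) {
        start5 <- sample.int(tx_len - config$rna_read_len + 1L, k,
                             replace = TRUE) - 1L
        list(three_prime_pos = start5 + config$rna_read_len - 1L,
             read_len = rep(config$rna_read_len, k))
      } else {
        list(three_prime_pos = integer(), read_len = integer())
      }
    }, by = gene_id][, .(count = .N), by = .(gene_id, three_prime_pos,
                                             read_len)]
  }

  finish <- function(dt) {
    dt[, sample := sample_name]
    setcolorder(dt, c("sample", "gene_id", "three_prime_pos", "read_len",
                      "count"))
    setkey(dt, gene_id, three_prime_pos, read_len)[]
  }
  structure(list(mono = finish(mono), disome = finish(disome),
                 rna = finish(rna), truth = truth[],
                 sample = sample_name, config = config),
            class = "footprint_sim")
}

#' Write simulated footprints as a pooled FASTQ with linker/UMI/barcode layout
#'
#' Each molecule is emitted as `dup_factor` identical records (PCR
#' duplicates). The raw read layout is: 2 nt RT UMI, insert, 5 nt linker UMI,
#' 5 nt sample barcode — the layout [demultiplex_and_trim()] reverses.
#'
#' @param sim a `footprint_sim`.
#' @param txome the transcriptome the footprints were simulated from.
#' @param layout a [read_layout()] whose `barcode_map` contains the sim's
#'   sample name.
#' @param path output FASTQ path.
#' @param classes which read classes to write.
#' @param dup_factor PCR duplication factor (default from the sim config).
#' @return Invisibly, a list with `n_molecules` (unique pre-duplication
#'   molecules, i.e. distinct (sample, gene, 3' position, length, UMI) keys),
#'   `n_records` written, and the per-molecule `truth` table.
#' @export
write_footprint_fastq <- function(sim, txome, layout, path,
                                  classes = c("mono", "disome", "rna"),
                                  dup_factor = sim$config$dup_factor) {
  stopifnot(inherits(sim, "footprint_sim"))
  bc <- names(layout$barcode_map)[match(sim$sample, layout$barcode_map)]
  if (is.na(bc))
    stop("sample ", sim$sample, " has no barcode in layout$barcode_map")
  aln <- rbindlist(lapply(classes, function(cl) sim[[cl]]))
  reads <- aln[rep(seq_len(.N), count)]
  n <- nrow(reads)
  rand_str <- function(n, k)
    do.call(paste0, as.data.frame(matrix(sample(c("A", "C", "G", "T"),
                                                n * k, replace = TRUE),
                                         nrow = n)))
  reads[, umi := paste0(rand_str(n, layout$rt_umi_len),
                        rand_str(n, layout$linker_umi_len))]
  seqs <- txome$seqs[reads$gene_id]
  insert <- substr(seqs, reads$three_prime_pos - reads$read_len + 2L,
                   reads$three_prime_pos + 1L)
  raw <- paste0(substr(reads$umi, 1L, layout$rt_umi_len), insert,
                substr(reads$umi, layout$rt_umi_len + 1L,
                       layout$rt_umi_len + layout$linker_umi_len), bc)
  raw <- rep(raw, each = dup_factor)
  ids <- sprintf("@%s_m%07d_d%d", sim$sample,
                 rep(seq_len(n), each = dup_factor),
                 rep(seq_len(dup_factor), n))
  fq <- character(4L * length(raw))
  fq[seq(1L, by = 4L, length.out = length(raw))] <- ids
  fq[seq(2L, by = 4L, length.out = length(raw))] <- raw
  fq[seq(3L, by = 4L, length.out = length(raw))] <- "+"
  fq[seq(4L, by = 4L, length.out = length(raw))] <-
    strrep("I", nchar(raw))
  writeLines(fq, path)
  truth <- unique(reads[, .(sample, gene_id, three_prime_pos, read_len, umi)])
  invisible(list(n_molecules = nrow(truth),
                 n_records = length(raw),
                 truth = truth))
}

#' Write a simulated alignment table / ground truth to tab-separated files
#' @param sim a `footprint_sim`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_footprint_tables <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(mono = file.path(dir, paste0(sim$sample, "_mono.tsv")),
             disome = file.path(dir, paste0(sim$sample, "_disome.tsv")),
             rna = file.path(dir, paste0(sim$sample, "_rna.tsv")),
             truth = file.path(dir, paste0(sim$sample, "_truth.tsv")))
  fwrite(sim$mono, paths["mono"], sep = "\t")
  fwrite(sim$disome, paths["disome"], sep = "\t")
  fwrite(sim$rna, paths["rna"], sep = "\t")
  fwrite(sim$truth, paths["truth"], sep = "\t")
  invisible(paths)
}
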