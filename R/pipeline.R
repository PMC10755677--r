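# End-to-end runs from a single declarative config: simulate (or load)
# footprints, process reads, build tracks, score pauses, compare conditions,
# and emit tables + QC manifest.

#' Read a pipeline run configuration
#'
#' The config is YAML (or an equivalent R list) with fields:
#' \describe{
#'   \item{mode}{`"simulate"`, `"fastq"` or `"aligned"`.}
#'   \item{out_dir}{output directory.}
#'   \item{seed}{integer; drives every random draw of the run.}
#'   \item{sim}{overrides for [sim_config()] (simulate mode).}
#'   \item{params}{overrides for [analysis_params()].}
#'   \item{annotation}{`fasta` and `model` paths (fastq/aligned modes).}
#'   \item{samples}{aligned/fastq modes: list of `name`, `path`, `class`
#'     (`monosome`/`disome`/`rna`), `condition`.}
#' }
#'
#' @param path YAML file path.
#' @return list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  as_run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg an R list with the fields above.
#' @export
as_run_config <- function(cfg) {
  stopifnot(is.list(cfg))
  cfg$mode <- match.arg(cfg$mode, c("simulate", "fastq", "aligned"))
  if (is.null(cfg$seed)) cfg$seed <- 1L
  if (is.null(cfg$out_dir)) stop("run config needs an out_dir")
  if (!is.null(cfg$samples)) {
    nm <- vapply(cfg$samples, `[[`, "", "name")
    if (anyDuplicated(nm)) stop("sample names must be unique")
  }
  structure(cfg, class = "run_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full pause-analysis pipeline
#'
#' Simulate mode: builds a transcriptome with planted pause motifs, simulates
#' an untreated library (no pauses) and a treated library (configured
#' multipliers), then computes pause-score tables, the treated/untreated
#' motif comparison, motif metaprofiles for the configured motifs, start/stop
#' metagenes, and the expression/TE table. Aligned mode: loads annotation and
#' pre-aligned tables and computes the same statistics per sample. All
#' outputs are written to `out_dir` as tab-separated files plus a YAML
#' manifest recording parameters, seeds and stage-level read counts.
#'
#' @param config a `run_config`, an R list coercible to one, or a YAML path.
#' @return Invisibly, a result bundle (list of the computed objects).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  if (!inherits(config, "run_config")) config <- as_run_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  params <- do.call(analysis_params, config$params %||% list())
  manifest <- list(mode = config$mode, seed = config$seed,
                   params = unclass(params), counters = list())

  if (config$mode == "simulate") {
    sim_args <- config$sim %||% list()
    sim_args$seed <- config$seed
    if (!is.null(sim_args$motif_multipliers))
      sim_args$motif_multipliers <- unlist(sim_args$motif_multipliers)
    scfg <- do.call(sim_config, sim_args)
    txome <- .stage("simulate_transcriptome", simulate_transcriptome(scfg))
    untreated_cfg <- scfg
    untreated_cfg$motif_multipliers <- numeric()
    sims <- list(
      untreated = .stage("simulate_footprints",
        simulate_footprints(txome, untreated_cfg, "untreated",
                            seed = config$seed + 1L)),
      treated = .stage("simulate_footprints",
        simulate_footprints(txome, scfg, "treated",
                            seed = config$seed + 2L)))
    aln <- lapply(sims, `[[`, "mono")
    rna_aln <- lapply(sims, `[[`, "rna")
  } else {
    ann <- config$annotation
    if (is.null(ann) || !file.exists(ann$fasta %||% "") ||
        !file.exists(ann$model %||% ""))
      stop("pipeline stage 'annotation_io' failed: missing FASTA or gene ",
           "model file", call. = FALSE)
    txome <- .stage("annotation_io",
                    load_transcriptome(ann$fasta, ann$model))
    samples <- config$samples
    if (config$mode == "fastq") {
      layout <- read_layout(unlist(config$layout$barcode_map))
      aln <- list(); rna_aln <- list()
      for (s in samples) {
        dm <- .stage("demultiplex", demultiplex_and_trim(s$path, layout))
        manifest$counters[[paste0("demux_", s$name)]] <- dm$counters
        al <- .stage("toy_align", toy_align(dm$reads[sample == s$name], txome))
        manifest$counters[[paste0("align_", s$name)]] <-
          attr(al, "align_stats")
        dd <- .stage("dedup", dedup_umis(al))
        manifest$counters[[paste0("dedup_", s$name)]] <-
          attr(dd, "dedup_stats")
        sel <- size_select(dd, s$class %||% "monosome", params)
        if ((s$class %||% "monosome") == "rna") rna_aln[[s$name]] <- sel
        else aln[[s$name]] <- sel
      }
    } else {
      aln <- list(); rna_aln <- list()
      for (s in samples) {
        if (!file.exists(s$path))
          stop("pipeline stage 'load_alignments' failed: missing ", s$path,
               call. = FALSE)
        tab <- fread(s$path, sep = "\t")
        tab[, sample := s$name]
        sel <- size_select(tab, s$class %||% "monosome", params)
        if ((s$class %||% "monosome") == "rna") rna_aln[[s$name]] <- sel
        else aln[[s$name]] <- sel
      }
    }
  }

  min_occ <- config$min_motif_occurrences %||% params$min_motif_occurrences
  sites <- .stage("enumerate_motif_sites", enumerate_motif_sites(txome, params))
  tracks <- lapply(aln, function(a)
    .stage("build_track", build_track(a, txome, "three_prime_end")))
  scores <- lapply(tracks, function(ts)
    .stage("pause_scores", pause_scores(ts, sites, params)))
  avgs <- lapply(scores, function(s)
    average_pause_scores(s, params, min_occurrences = min_occ))

  bundle <- list(txome = txome, params = params, sites = sites,
                 tracks = tracks, scores = scores, motif_tables = avgs)

  for (nm in names(aln))
    manifest$counters[[paste0("mapped_", nm)]] <-
      c(reads = sum(aln[[nm]]$count %||% rep(1L, nrow(aln[[nm]]))))

  if (all(c("treated", "untreated") %in% names(avgs))) {
    cmp <- compare_conditions(avgs$treated, avgs$untreated, params)
    fwrite(cmp, file.path(config$out_dir, "motif_comparison.tsv"), sep = "\t")
    bundle$comparison <- cmp
  }
  for (nm in names(avgs))
    fwrite(avgs[[nm]], file.path(config$out_dir,
                                 paste0("pause_motifs_", nm, ".tsv")),
           sep = "\t")
  for (nm in names(scores))
    fwrite(scores[[nm]][eligible == TRUE,
                        .(gene_id, e_codon_index, motif, score)],
           file.path(config$out_dir, paste0("pause_sites_", nm, ".tsv")),
           sep = "\t")

  focus_motifs <- names(config$sim$motif_multipliers %||% c())
  if (length(focus_motifs)) {
    prof_sites <- sites[motif %in% focus_motifs & eligible == TRUE]
    if (nrow(prof_sites) && length(tracks)) {
      prof <- lapply(tracks, motif_metaprofile, sites = prof_sites,
                     txome = txome, params = params)
      for (nm in names(prof))
        fwrite(prof[[nm]], file.path(config$out_dir,
                                     paste0("metaprofile_", nm, ".tsv")),
               sep = "\t")
      bundle$metaprofiles <- prof
    }
  }

  if (length(tracks)) {
    mg <- lapply(tracks, function(ts) list(
      start = tryCatch(metagene(ts, txome, "start", params),
                       error = function(e) NULL),
      stop = tryCatch(metagene(ts, txome, "stop", params),
                      error = function(e) NULL)))
    bundle$metagenes <- mg
    for (nm in names(mg))
      for (an in c("start", "stop"))
        if (!is.null(mg[[nm]][[an]]))
          fwrite(mg[[nm]][[an]],
                 file.path(config$out_dir,
                           paste0("metagene_", an, "_", nm, ".tsv")),
                 sep = "\t")
  }

  if (length(rna_aln) && length(aln)) {
    ribo_ts <- tracks[[1L]]
    rna_ts <- .stage("build_track",
                     build_track(rna_aln[[1L]], txome, "coverage"))
    expr <- expression_table(ribo_ts, rna_ts, txome, params)
    fwrite(expr, file.path(config$out_dir, "expression.tsv"), sep = "\t")
    bundle$expression <- expr
  }

  yaml::write_yaml(manifest, file.path(config$out_dir, "manifest.yaml"))
  invisible(bundle)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
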