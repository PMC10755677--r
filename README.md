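# ribopause

Codon-level analysis of ribosome pausing from Ribo-seq, Disome-seq and
RNA-seq data, with a synthetic footprint simulator that plants known pauses
so every statistic can be validated against ground truth.

## What it computes, and for whom

Ribosome profiling measures where ribosomes sit on mRNAs; localized
accumulations of footprints mark slow codons. This package is for analysts
who want to quantify that pausing at the resolution of **tri-amino-acid
motifs** — the residues held in the ribosomal E, P and A sites — and compare
it between conditions (for example untreated vs. oxidatively stressed cells,
or wild type vs. a ubiquitination-pathway deletion).

The core statistic is the **pause score**. Footprints (25–34 nt monosome,
57–63 nt disome) are aligned by their 3′ ends into rpm-normalized
per-nucleotide tracks; a fixed 18 nt shift maps a 3′ end to the E-site codon
start. For a motif site with readout position *p*:

```
pause score = rpm[p] / mean(rpm[p - 50 .. p + 50])
```

a dimensionless local-enrichment ratio (1 = no pausing), averaged per motif
over all eligible sites, with motifs seen fewer than 100 times genome-wide
excluded. On top of this the package provides condition comparisons with a
1.5-fold foreground cut, positional residue enrichment (a simplified
sequence-logo readout), Mann-Whitney tests of site-level score shifts
(exact enumeration for combined n ≤ 20), motif-aligned metaprofiles,
start/stop metagenes, and gene-level quantitation (rpkm and translation
efficiency te = ribo_rpkm / rna_rpkm). Read processing covers the UMI/barcode
linker layout (5 + 5 nt on the linker, 2 nt on the RT primer), exact-key PCR
deduplication, size selection and a toy exact-match aligner for synthetic
reads.

See `vignettes/pause-analysis-methods.Rmd` for the model, parameter
meanings, and the simulator's assumptions.

## Worked example

Simulate a 300-gene transcriptome with a 5× pause planted at 50 KIP
(Lys-Ile-Pro) sites, sequence an "untreated" library (no pauses) and a
"treated" one, and ask which motifs pause more under treatment:

```r
library(ribopause)

cfg <- sim_config(seed = 42, n_genes = 300, cds_len_range = c(900, 1500),
                  motif_multipliers = c(KIP = 5), sites_per_motif = 50,
                  base_depth = 5, dispersion = 10)
tx <- simulate_transcriptome(cfg)
untreated_cfg <- cfg; untreated_cfg$motif_multipliers <- numeric()

params <- analysis_params()
sites <- enumerate_motif_sites(tx, params)
score_sample <- function(run_cfg, seed) {
  sim <- simulate_footprints(tx, run_cfg, "mono", seed = seed, classes = "mono")
  track <- build_track(sim$mono, tx, "three_prime_end")
  average_pause_scores(pause_scores(track, sites, params), params,
                       min_occurrences = 15)
}
treated   <- score_sample(cfg, 43)
untreated <- score_sample(untreated_cfg, 44)
cmp <- compare_conditions(treated, untreated, params)
cmp[order(-fold)][1:5]
```

```
    motif    avg_a     avg_b     fold foreground
1:    KIP 4.273691 1.1967678 3.571028       TRUE
2:    MYI 1.141037 0.3836903 2.973850       TRUE
3:    NIP 1.233342 0.4216064 2.925340       TRUE
4:    CRR 1.374784 0.4796380 2.866295       TRUE
5:    RMP 1.265739 0.4856319 2.606375       TRUE
```

The planted motif is recovered as the top-ranked fold change. Its average
score of ≈ 4.3 rather than 5 is expected: the motif's own signal sits inside
the ±50 nt window mean, compressing the ratio to `m·W/(W−1+m)` with
W ≈ 33.7 effective codons (≈ 4.5 for m = 5; see the methods vignette). The
runner-up folds (~2.5–3) are sampling noise on motifs near the occurrence
threshold at this modest depth.

An end-to-end run (simulation → tracks → pause tables → comparison →
metaprofiles → metagenes → expression/TE table → QC manifest) is one call:

```r
run_pipeline(list(mode = "simulate", out_dir = "run1", seed = 1,
                  sim = list(motif_multipliers = list(KIP = 5))))
```

or `Rscript inst/scripts/ribopause-run.R config.yaml` with the same fields
in YAML. Pre-aligned real data uses `mode = "aligned"` with a transcript
FASTA, a 4-column gene model (gene_id, utr5_len, cds_len, utr3_len; a GFF3
shim is provided) and per-sample 3′-end alignment tables.

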