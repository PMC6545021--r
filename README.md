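# repdyn

Repeatome expression and methylation dynamics in pre-implantation
single cells.

Transposable elements and other repeats are re-activated in stage-specific
waves during early embryogenesis, concurrently with a global wave of DNA
demethylation and remethylation. `repdyn` is a self-contained R pipeline
for analysing this from single-cell data. It consumes:

- a repeat-type × cell count matrix (fractional counts allowed, as emitted
  by multi-mapping-aware counters such as RepEnrich2), with cell metadata
  (cell id, developmental stage, embryo id);
- a gene TPM matrix;
- a RepeatMasker-style repeat instance annotation (BED, 0-based half-open);
- gene models with TSS and strand (BED6 or minimal GTF);
- per-CpG single-cell bisulfite records (chrom, position, methylated reads,
  total reads, cell).

## Core statistics

- **CPM normalisation** (`compute_cpm`, columns sum to 10⁶), a stage
  retention filter (≥ 1 CPM in all cells of at least one stage), a gene
  filter (< 1 TPM stage-mean everywhere → dropped), and log₂(CPM + 1).
- **Stage profiles**: per-stage means with SEM, coefficient of variation
  sd/mean per stage, and z-scores over stage means,
  z_s = (x̄_s − x̄) / s_x (sample sd; constant profiles → all zero).
- **PCA** with a deterministic sign convention and explained-variance
  fractions.
- **Promoter repeat enrichment**: strand-aware 2-kb upstream windows
  (half-open, TSS excluded), ES = (r/R)/(g/G), two-sided Fisher's exact
  test on [[r, R−r], [g−r, (G−g)−(R−r)]]; significant when supported by
  ≥ 5 genes with ES ≥ 1.5 and p ≤ 10⁻⁴; a strict tier requires ES > 3.5
  and p < 10⁻³.
- **Stage-specific co-expression primitives**: module eigengenes, the
  r > 0.50 / p < 10⁻³ stage-specificity rule, module merging at eigengene
  r ≥ 0.7, a simplified stage assigner, and import/export of externally
  produced (e.g. WGCNA) module files.
- **Methylation**: ≥ 5× coverage filter (audited), CpG-to-repeat
  assignment, read-weighted percentages 100·Σm/Σt, class/repeat × stage
  summaries.
- **Correlations**: exact-t Pearson tests, repeat–module gene
  correlations, class-level methylation-vs-expression correlation, and
  ANOVA + Tukey HSD across stages.
- **A deterministic synthetic-data generator** with machine-readable ground
  truth (planted Satellite 4-cell peak, SVA 8-cell/morula peak, a global
  blastocyst shift, a developmental random walk, planted promoter
  enrichment at an exact recounted ES, and a planted 4-cell methylation
  dip). The generator is first-class, tested code.

See `vignettes/repeatome-dynamics.Rmd` for the methods in full, including
formulas, parameter defaults and limitations.

## Worked example

Everything below is real output, generated with the package itself
(simulation seed 1, the package defaults: 300 repeats × 117 cells across
9 stages).

```r
library(repdyn)

cfg <- sim_config(seed = 1)
simulate_repeatome(cfg, "demo")          # writes counts, TPM, BED, CpGs, truth

counts <- read_count_matrix("demo/counts.tsv")
meta   <- read_cell_metadata("demo/meta.tsv")
cpm    <- compute_cpm(counts)
keep   <- filter_repeats_by_stage(cpm, meta)   # 298 of 300 retained
lg     <- log2_cpm(cpm[keep, , drop = FALSE])

inst <- read_repeat_annotation("demo/rmsk.bed")
cls  <- setNames(inst$repeat_class, inst$repeat_name)
cs   <- class_stage_means(lg, meta, cls[rownames(lg)])
cs[cs$repeat_class == "Satellite", c("stage", "mean", "sem")]
```

The planted Satellite programme peaks at the 4-cell stage:

```
           stage  mean    sem
          oocyte 10.32 0.1094
          zygote 10.24 0.1235
           2cell 10.17 0.1237
           4cell 11.91 0.0936   <- +~1.7 log2 over neighbours
           8cell  9.98 0.1180
          morula 10.24 0.1254
 late_blastocyst 10.11 0.1306
          ESC_P0  9.98 0.1317
         ESC_P10 10.06 0.1306
```

Promoter enrichment against the (truth-derived) stage modules recovers the
planted pair and nothing else:

```r
genes <- read_gene_models("demo/genes.bed", "bed6")
truth <- jsonlite::read_json("demo/truth.json", simplifyVector = TRUE)
mods  <- data.frame(gene_id = unlist(truth$module_genes$gene_id),
                    module_label = unlist(truth$module_genes$stage))
enr <- enrich_repeats(genes, inst, mods)
significant_enrichments(enr)
```

```
 repeat_name module  r  R  g   G n_genes   ES        p fig_tier
       SVA_1  8cell 12 22 15 108      12 3.93 7.77e-08     TRUE
```

Methylation shows the planted global 4-cell demethylation dip:

```r
rec <- read_cpg_records("demo/cpgs.bed")
mp  <- repeat_methylation_percent(
  assign_cpgs_to_repeats(filter_cpgs(rec), inst))
sm  <- stage_methylation_summary(mp, meta, classes = cls)$summary
round(tapply(sm$mean, sm$stage, mean, na.rm = TRUE), 1)
```

```
 oocyte zygote 2cell 4cell 8cell morula late_blastocyst ESC_P0 ESC_P10
   79.5   80.2  79.2  41.4  85.9   79.8            80.1   78.6    80.0
```

A thin command-line wrapper over the same functions ships in
`inst/scripts/repdyn` (subcommands `simulate`, `normalize`, `profile`,
`modules`, `enrich`, `methylation`, `correlate`).

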