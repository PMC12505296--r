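# dhfrscan

Analysis of deep mutational scanning (DMS) experiments read out by
DHFR protein-fragment complementation assays (DHFR-PCA).

## The problem

In a DHFR-PCA competition screen, every single-codon variant of a protein
interaction motif carries one fragment of a split dihydrofolate reductase;
the interaction partner (bait) carries the other. Binding reconstitutes the
enzyme and confers methotrexate resistance, so a variant's abundance
trajectory through pooled methotrexate selection measures its interaction
strength in vivo. A second bait that binds the prey outside the mutagenized
motif controls for changes in prey abundance rather than binding. dhfrscan
turns such experiments — amplicon reads or count tables, optical-density
series, colony-size grids — into filtered, classified interaction scores,
for groups running motif-level DMS interaction screens in yeast.

## The model

For variant *v*, the **interaction score** is the log2 fold change of its
pool frequency across selection, with pseudocount p = 0.5:

```
raw_v    = log2((c_post + p)/D_post) - log2((c_pre + p)/D_pre)
scaled_v = (raw_v - W) / (W - N)
```

where W and N are the per-library median raw scores of the wild-type
(+ silent) anchor and of nonsense variants; after rescaling, wild type = 0
and the nonsense median = -1 exactly. Variants need >= 20 pre-selection reads;
amino-acid scores are medians over synonymous codons and replicates
(>= 3 contributing scores). A Mann-Whitney / Benjamini-Hochberg cascade then
removes aberrant controls, control-condition growth defects and
abundance-changing mutants (via the control bait), and classifies the rest as
significantly stronger, weaker, or not different from wild type.
Per-generation selection coefficients use
`s = [log2(f_v_end/f_v_start) - log2(f_wt_end/f_wt_start)] / g` with
generations `g = log2(OD_end/OD_start)`. Growth curves are summarized by the
98th percentile of 5-point sliding-window slopes of log2 OD; colony arrays
are log2-transformed, median-polished per plate and rescaled so the
wild-type reference = 1 and the stuffer reference = 0.

A seeded synthetic-data generator (library design, counts, FASTQ reads, OD
trajectories, colony grids) with planted effects makes every stage testable
end to end; see the methods vignette (`vignettes/dms-dhfr-pca-methods.Rmd`)
for the full model, parameter defaults and known limitations.

## Worked example

```r
library(dhfrscan)

design  <- example_design("NNK")                  # 16-codon extended motif
params  <- sim_params(seed = 42, read_depth = 1e5,
                      conditions = c("MTX_sorbitol", "MTX"))
effects <- simulate_effects(design, params, prop_abundance = 0.05)
counts  <- simulate_counts(design, effects, params)
result  <- filter_cascade(counts, design)
str(result$summary)
#> List of 6
#>  $ n_scored            : int 506
#>  $ n_control_outliers  : int 2
#>  $ n_abundance_excluded: int 20
#>  $ n_classified        : int 284
#>  $ n_stronger          : int 32
#>  $ n_weaker            : int 178
```

506 distinguishable codon variants were scored; 2 aberrant control variants
were dropped from the rescaling anchors, 20 amino-acid changes were excluded
because their control-bait (Hog1) scores show an abundance change, and of the
284 classifiable missense changes, 32 bind significantly more strongly and
178 significantly more weakly than wild type (the planted landscape was 10%
stronger / 60% weaker). Aggregated scores are in `result$aa_scores`:

```r
head(result$aa_scores[result$aa_scores$aa_class == "missense",
                      c("aa_change_key", "score", "n_contributing",
                        "classification")], 3)
#>   aa_change_key  score n_contributing classification
#>          A-85-C -1.480              3         weaker
#>          A-85-D -0.227              3         weaker
#>          A-85-E  0.063              3  not_different
```

Scores between the two conditions agree in rank
(`correlate_conditions(...)`: Spearman rho 0.967 over 312 shared changes in
this run). `run_pipeline(pipeline_config(...))` executes the same stages from
a YAML configuration and writes TSVs plus a run log;
`inst/cli/dhfrscan.R` exposes each stage as a shell subcommand
(`simulate`, `call-variants`, `score`, `filter-classify`, `growth`,
`colony`, `run`).

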