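---
title: "Scoring deep mutational scans measured by DHFR-PCA: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring deep mutational scans measured by DHFR-PCA: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dhfrscan)
```

## The measurement

dhfrscan analyzes pooled competition assays in which the strength of a
protein-protein interaction is read out by growth. Each prey variant (here:
single-codon mutants of a kinase's SH3-binding motif and its flanking region)
carries one fragment of a split dihydrofolate reductase (DHFR); the bait
carries the complementary fragment. When bait and prey interact, the
reconstituted enzyme confers methotrexate (MTX) resistance, so a variant's
growth rate under MTX — and hence its trajectory in a pooled competition —
increases with its interaction strength. Two baits are measured: the binding
partner itself (Sho1), whose signal reflects binding affinity *and* prey
abundance, and a control partner (Hog1) that binds the prey independently of
the mutagenized motif and therefore reports abundance alone.

The pooled competition is quantified by amplicon sequencing of the mutagenized
locus before selection (right after diploid/strain selection) and at the end
of the final MTX cycle.

## Interaction scores

For variant $v$ with read count $c_v$ and sample depth $D$, the raw
interaction score is the log2 fold change of its pool frequency,

$$ \mathrm{raw}_v \;=\; \log_2\frac{c_v^{\text{post}} + p}{D^{\text{post}}}
 \;-\; \log_2\frac{c_v^{\text{pre}} + p}{D^{\text{pre}}}, $$

with pseudocount $p = 0.5$ added to counts only (not depths) so dropouts stay
finite. The pseudocount is configurable; 0.5 is the smallest standard choice
that keeps the estimator defined while perturbing well-measured variants
negligibly.

Raw scores from different libraries (bait x condition x replicate) are not
comparable — depth, bottleneck and mean fitness differ — so each library is
rescaled by the two-anchor affine map

$$ \mathrm{scaled}_v = \frac{\mathrm{raw}_v - W}{W - N}, $$

where $W$ is the median raw score of the wild-type anchor and $N$ the median
raw score of nonsense variants (both among records passing the count filter).
After the map the wild-type anchor sits at 0 and the nonsense median at
exactly -1; being affine, the map preserves the ordering of raw scores.

**Wild-type anchor policy.** Whether the anchor is the wild-type sequence
alone or the wild type pooled with synonymous (silent) variants is genuinely
open; the package supports both (`wt_policy`). The default pools wild type
with silent variants: silent codons are biological wild type at the protein
level, and pooling makes the anchor a median of many records instead of one.

**Count filter.** Variants with fewer than 20 pre-selection reads are dropped
(from anchors and from aggregation): low input counts produce inflated fold
changes. We apply the filter per codon-variant per replicate — the
alternative (per pooled amino-acid variant) would let one well-measured codon
rescue an unmeasured synonymous one.

**Aggregation.** The score of an amino-acid change is the median of the
scaled scores of all synonymous codon variants across replicates of a
condition, reported only when at least 3 replicate-level scores survive the
filter. Medians of even pools are midpoints of the central pair.

## Selection coefficients and generations

For pooled proliferation competitions the per-generation, wild-type-relative
selection coefficient is

$$ s_v = \frac{\log_2(f_v^{\text{end}}/f_v^{\text{start}})
             - \log_2(f_{wt}^{\text{end}}/f_{wt}^{\text{start}})}{g}, $$

with generations $g = \log_2(\mathrm{OD}_{\text{end}}/\mathrm{OD}_{\text{start}})$
summed over cycles, and frequencies compared between the first pre-selection
and the final post-selection sample. This WT-relative log2-ratio form is
stated explicitly so results are auditable; $s_{wt} = 0$ by construction.

## The statistical filter cascade

Order of operations (idempotent on re-run):

1. **Count filter** during scoring (above).
2. **Control outliers.** Every nonsense (resp. silent) codon variant is
   compared to the pooled other variants of its class (two-sided
   Mann-Whitney U, unadjusted P < 0.05, as a per-variant screen). Flagged
   controls are removed and the rescaling re-run without them as anchors.
3. **Control-condition defects.** In the MTX-free control with osmotic
   stress, growth does not depend on the reporter but does require the intact
   signaling function of the prey protein: nonsense mutants drop out of this
   condition. Each missense mutant is compared to the pooled nonsense scores
   (two-sided Mann-Whitney U, BH across missense); mutants *not* significantly
   different from the loss-of-function pool (adjusted p > 0.05) are removed —
   failure to separate from nonsense marks a proliferation defect. Note the
   rule's logic: absence of evidence of health is treated as a defect, so
   poorly measured mutants are removed too. That is deliberate conservatism,
   implemented as stated.
4. **Abundance exclusion.** Missense changes whose control-bait (Hog1) scores
   differ from the pooled wild-type + silent scores (two-sided Mann-Whitney U,
   BH, adjusted p < 0.05) changed prey abundance or stability rather than
   binding alone, and are removed from the binding dataset. Because abundance
   is condition-independent, replicate-level control-bait scores are pooled
   across both MTX conditions, which doubles the per-mutant sample size and
   is what gives 3-18 replicate scores per amino-acid change on a 16-codon
   NNK library.
5. **Classification.** Remaining missense changes are tested against the
   pooled wild-type + silent scores (two-sided Mann-Whitney U, BH): adjusted
   p < 0.05 with positive median is *stronger*, with negative median
   *weaker*, otherwise *not different*.
6. **Proliferation test** (separate assay): Welch's t of each mutant's
   replicate selection coefficients against the wild type's, BH across
   mutants.

**Mann-Whitney p-values.** U is a rank-sum statistic with average ranks for
ties. The p-value uses the exact null distribution of U whenever the pooled
data are tie-free — replicate scores are continuous, and the exact path keeps
resolution when a 3-replicate mutant is tested against a large pool (the
normal approximation floors such a p at ~0.004, which a BH family of several
hundred tests cannot act on). With ties, the normal approximation with tie
and continuity corrections is used. FDR control is Benjamini-Hochberg
throughout, the default of the R ecosystem this analysis style comes from.

## Growth curves

The maximal growth rate of an OD trajectory is estimated by the
window-percentile method: the least-squares slope of $\log_2$ OD over every
window of 5 consecutive measurements (15-min sampling), summarized by the
98th percentile (linear interpolation) of window slopes. The percentile makes
the estimate robust to isolated spikes — a single 10x outlier point corrupts
at most 5 windows, which the 98th percentile of ~280 windows ignores, whereas
the plain maximum fails. A slope on log2 OD was chosen over endpoint
differencing (the field description is ambiguous) because it is less
sensitive to single-point jitter; ODs are floored at $10^{-3}$ before the log
so blank-corrected wells stay finite.

**Known limitation.** The window-percentile estimator is biased upward under
per-point measurement noise: with iid noise of coefficient of variation
$\sigma$, a 5-point window slope has standard deviation
$\approx \sigma / (\ln 2 \sqrt{0.625\,\mathrm{h}^2}) \approx 1.8\,\sigma$
log2/h, and the 98th percentile across hundreds of windows sits roughly two
such standard deviations above the true rate. At realistic plate-reader noise
(0.2-0.5% of OD) this inflation is small in absolute terms but can still
dominate slow rates; at 5% noise it swamps the signal entirely. The estimator
is therefore reliable for *comparing* strains measured with the same
protocol (the bias is shared), and for absolute rates only when point noise
is small. Tests assert exact recovery on clean exponentials and spike
robustness; recovery under heavy iid noise is not achievable by this
estimator and is documented as a failing check rather than hidden.

Fragment interaction scores divide a strain's rate by the matched
no-fragment control strain's rate (a ratio, so a score of 1 means
control-like growth; a difference convention is available by flag). Strain
comparisons use one-sided Student's t (equal variance) with BH across the
comparison family. Strains excluded by manual QC (e.g. a mutant whose
no-MTX control growth reveals a construction problem) are listed in the
pipeline configuration (`exclude_strains`), not hard-coded.

## Colony arrays

Solid-media PCA screens are quantified from colony-size tables. Colonies that
failed diploid selection are removed (assay failures, not weak interactions —
zero sizes are treated as missing, never as score 0), as are the border
control positions (the outer two rows/columns carry a fast-growing control
pair to absorb edge effects). Sizes are log2 transformed, centered by the
plate median, and corrected by one round of row/column median polish per
plate: multiplicative plate/row/column biases are additive offsets in log2
and are removed exactly by the successive median subtractions on balanced
layouts. One iteration is the default (configurable); the real arrays are
randomized, so residual position-composition coupling is noise, not bias.
Normalized values are rescaled by the affine map sending the stuffer
(no-binding) reference median to 0 and the wild-type reference median to 1.
Bait comparisons use a one-sided Mann-Whitney U (weaker than the reference)
with BH across baits. The quadrant replicates of a repeated array are treated
as independent measurements of the same pair.

## The synthetic-data generator

Every stage is testable without the original sequencing data through a seeded
generator whose defaults are the study conditions:

* a 16-codon NNK (or 56-codon NNN) single-codon variant library; the bundled
  example design is a synthetic ORF carrying the motif KPLPPLP at codons
  93-99 with the extended-motif window 85-100 mutagenized;
* 3 replicate pools, up to 4 conditions (MTX/no-MTX x sorbitol/none), two
  selection cycles of 4 generations each (a 0.1-OD inoculum grown to
  saturation in selective medium), read depth $10^5$ per sample;
* selection acts multiplicatively per generation
  ($f \propto f_0 2^{s\,g}$), matching the selection-coefficient definition;
  initial pools are Dirichlet-perturbed uniform; sequencing is a multinomial
  draw;
* per-variant effects are drawn per amino-acid change (synonymous codons
  share effects): binding effects `b` act only with the binding bait under
  MTX (amplified 1.5x by sorbitol, reflecting pathway induction); abundance
  effects `a` act with every bait under MTX — nonsense variants lose the
  C-terminal reporter fragment and carry their whole deficit here, which is
  also why they anchor both baits' rescaling; a control-condition channel
  `ctrl` (pathway loss of function under osmotic stress without MTX) lets
  nonsense and optionally some missense variants drop out of the no-MTX
  control;
* the nonsense deficit is `s_null` = 0.125 per generation, so the wild-type
  to nonsense gap spans one log2 unit over the default 8 generations; planted
  missense effects are a mixture of 10% stronger, 60% weaker and 30%
  near-neutral (continuous, so rank recovery is well-defined); planted
  abundance effects default to complete reporter loss, i.e. strong
  destabilization;
* reads are emitted pre-merged as one full-length amplicon per counted
  molecule with row/column sample barcodes (pairwise Hamming distance >= 3,
  so one-substitution matching is unambiguous), iid per-base substitution
  errors and constant Q30 qualities;
* colony grids carry planted scores on a randomized interior layout with
  multiplicative plate/row/column biases and log-normal noise.

What the generator does **not** emulate: PCR jackpots and amplification
bias, position-dependent Illumina error profiles, indels, library bottleneck
dynamics, paired-end read structure, or spatially smooth agar gradients.
Passing tests therefore demonstrate the correctness of the statistical
machinery under the stated model, not robustness to every artifact of real
sequencing data.

## Variant calling choices

Reads are demultiplexed by both barcodes (<= 1 substitution each, unique
match required, ambiguous reads discarded), collapsed to unique sequences,
and globally aligned to the wild-type sequence (Needleman-Wunsch with affine
gaps; match +5, mismatch -4, gap open 10, gap extend 0.5, a gap of length
L costing open + L x extend; 'N' scores 0; traceback ties broken
deterministically diagonal > up > left). A read is called as a codon variant
only if it has no gaps and all mismatches fall in exactly one codon of the
mutagenized window; reads mutated in several codons, in a flank codon, or
with indels are tallied separately and excluded from frequency denominators —
in a single-mutant library such reads are sequencing artifacts, and excluding
them from the depth keeps frequencies relative among interpretable molecules.
Sequences exactly matching an enumerated variant skip the aligner (their
alignment is the identity). Quality-based read filtering (mean Q >= 20) is
available but off by default, since calling is already restricted to
interpretable molecules.

## Problem sizes used in tests

The bundled checks run the full pipeline at the study scale where it matters
(16-codon NNK library, 3 replicates, depth $10^5$ for scoring and recovery
checks; 1,536-position colony grids) and smaller designs (a 2-codon NNN
library, depth $4 \times 10^5$ for the read-level round trip, where
per-variant counts are large enough that multinomial exclusion noise sits
well inside the 1% comparison band) elsewhere. Statistical calibration checks
(null flag rates) use 60 simulation repeats.
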