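---
title: "Quantifying translation-initiation fidelity signals around the START codon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying translation-initiation fidelity signals around the START codon}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(atgscan)
library(dplyr)
```

## The problem

In eukaryotes the pre-initiation complex scans the transcript from the 5' cap
until it recognises an AUG in a favourable nucleotide context (the Kozak rule).
Scanning is leaky: the complex can miss the annotated START and initiate at an
upstream or downstream ATG in any reading frame, producing truncated, extended
or out-of-frame peptides that cost the cell energy and can be harmful. If such
spurious initiation matters to fitness, transcripts should show signatures of
selection around the START: fewer alternative ATGs near it, weaker (anti-Kozak)
contexts on the alternative ATGs that remain, and nearby in-frame stop codons
that keep the price of an accident low.

`atgscan` implements the statistical machinery to measure those signatures on
any genome supplied as 5'UTR/ORF sequences, and to test them against null
genomes that preserve everything about a gene except the signature itself.
Because the real genome builds and expression compendia that motivate the
method are large external downloads, the package ships a seeded generator that
produces synthetic genomes with the same statistical structure, so every stage
of the analysis can be exercised and tested end to end in code.

## Coordinates and data structures

Everything tabular is a tibble. A *gene set* has one row per gene with `utr5`
and `orf` nucleotide strings; positions on the transcript `utr5 + orf` are
signed and 0-based with position 0 at the `A` of the START ATG, so `-1` is the
last UTR nucleotide and a triplet's reading frame is just `pos %% 3`. An *ATG
site* is a row `(gene_id, pos, frame, region)`. Count profiles, region
results, feature tables, folding tests and the predictor ladder are all
tibbles too, each carrying a class so `autoplot()` and `tidy()`/`glance()`
know what to do with it.

Triplets starting at positions ±1 and ±2 overlap the START's `ATG` and can
never themselves read `ATG` (the overlap forces a mismatch); several estimators
treat those positions as structural zeros, noted where relevant below.

## The start-context PSSM and the relative context score

The context window covers the 6 nt before and 3 nt after the ATG. The PSSM is
trained on the START contexts of highly translated genes: genes are ranked by
*ribosomal load* (mRNA level x ribosomal density, a proxy for the number of
translation events), the top 4% form a pool, and a random half of the pool
(2% of the genome) becomes the training set. The random-half step, plus the
exclusion of the training genes from all downstream scoring, guards against
over-fitting. Cells get a pseudocount of 0.5 before normalisation so no
context has probability zero.

The *raw* context score of any ATG site is the geometric mean of the PSSM
probabilities of its context nucleotides; the *relative* score divides by the
raw score of the gene's own START, so the START scores exactly 1 and an
alternative site scores above 1 only when its context out-competes the gene's
actual initiation context. We chose the geometric-mean-ratio form because it
is scale-free, monotone in every per-position probability, renormalises
naturally when a context is truncated by a transcript end (such sites are
flagged `partial`), and reduces to 1 at the START. Sites whose context is
entirely unavailable are missing, never zero.

Positional conservation is summarised by the Shannon entropy of each PSSM
column in bits (2 = uniform, 0 = fixed), optionally z-scored across the
window's positions for cross-organism comparison. The classical Kozak
optimum `ACCATGG` is also supported directly as a hamming distance on the
`(-3, -2, -1, +1)` positions.

```{r pssm}
sim <- simulate_genome(sim_params(n_genes = 800, seed = 1))
train <- select_training_set(sim$expression, seed = 1)
pssm <- build_pssm(sim$genes, train)
glance(pssm)
positional_entropy(pssm, zscore = TRUE)
```

## Null genomes

Three randomization schemes produce genomes that keep a gene's protein while
scrambling the nucleotide-level signal:

* **codon resampling** - every internal codon is replaced by a synonymous
  codon drawn with probability proportional to its genome-wide count, the stop
  by a stop drawn from the genomic stop frequencies. Protein, codon bias and
  GC content are preserved (exactly, in expectation, and in expectation
  respectively).
* **codon permutation** - the internal codons of each gene are shuffled;
  the per-gene codon multiset is preserved exactly.
* **ramp-preserving resampling** - like resampling, but the first 40 codons
  use synonymous frequencies estimated from that region only, so the distinct
  codon composition at the start of ORFs (the translational ramp) survives
  randomization and cannot explain a depletion signal by itself.

5'UTRs are randomized by permuting their own nucleotides in every scheme,
preserving each UTR's nucleotide multiset and hence its GC content exactly.
Because ATG is the only methionine codon, the frame-0 ATG content of the ORF
is identical between a real gene and any resampled version - only frames 1
and 2 are informative in ORF null comparisons.

## Depletion profiles and the region under selection

`atg_count_profile()` counts, per frame and signed position over ±90 nt, how
many genes carry an ATG starting there, with per-position denominators so
genes with short UTRs contribute only where they exist. Two estimators turn a
profile into a *region of selection* length:

1. **Sliding-window KS** (`detect_region_ks()`): windows of 11 codons (the
   ribosome footprint), sliding 1 codon from the boundary inward (ORF) or
   outward (5'UTR), each tested by a two-sample Kolmogorov-Smirnov test of the
   window's per-position counts against the remaining in-frame positions of
   the 90-nt span, gated so that only windows whose mean lies *below* the
   remainder extend the region. If the first window is not significant at
   alpha = 0.05 the region is 0; otherwise it is `(window - 1) + run` codons,
   where `run` is the number of consecutive significant windows. Position 0
   (the START itself) is excluded from the frame-0 ORF samples - its count is
   the number of genes and carries no alternative-initiation information.
2. **Null-genome flags** (`empirical_position_flags()` +
   `detect_region_vs_null()`): a position is DEPLETED when at least 95% of 20
   null genomes have strictly more ATGs there than the real genome (ties count
   to neither side); the region is the boundary-anchored run of in-frame
   DEPLETED positions. The run anchors at ±3, the first position where an
   alternative ATG is possible; anchoring at ±1 would tie forever against the
   structural zeros and force the estimator to 0.

The two estimators behave as a bracket: the KS detector measures where counts
are low relative to the rest of the same genome (and over-covers a sharp zone
by a few codons - a window that still contains 8 of its 11 positions inside a
fully depleted zone remains significant, so a planted zone of L codons is
typically reported as about L + 3), while the flag detector requires
position-wise superiority of 19/20 nulls and is conservative. Cross-organism
summaries use `mean_region()`: average over frames within an organism, then
over organisms.

`codon_count_profile()` repeats the analysis for any triplet, the control
showing that depletion is specific to ATG and not a generic codon-composition
artefact; its scaled values are denominator-normalised first so variable UTR
lengths do not masquerade as signal.

```{r regions}
prof <- atg_count_profile(sim$genes, frame = 1)
detect_region_ks(prof, "ORF") %>% select(frame, region, length_codons)
```

## Expression stratification, stop distances and metabolic cost

Selection should be strongest where translation is most frequent.
`stratified_atg_comparison()` compares the top and bottom 15% of genes by
ribosomal load in per-gene ATG counts over the first 30 codons on each side
of the START (START excluded), per frame and pooled - eight KS tests.

For the cost of accidents, `alt_orf_stats()` walks in-frame from any
alternative ATG to its first stop codon (UTR sites may terminate inside the
ORF; the transcript is scanned as one string) and prices the intervening
peptide with a per-amino-acid ATP table - the bundled table holds the total
biosynthetic costs under respiratory conditions in budding yeast - optionally
adding the canonical 7 ATP of translation cost per residue. The initiator
methionine is included by default (`include_met` toggles it; the choice
shifts every cost by one Met and does not affect comparisons).
`near_far_comparison()` contrasts out-of-frame sites within 6 codons of the
START against the remainder of the 300-nt span, and `cost_vs_null()` plants
the real genome's alternative ATGs into codon-resampled null genomes -
controlling the number and position of sites exactly - and compares the real
peptide costs against the planted-null costs one-sidedly.

## The folding-energy control

Fewer ATGs near the START might in principle be a by-product of selection for
weak mRNA structure there. `atg_folding_test()` checks the direction of that
coupling: each 13-codon window around the START (sliding 1 nt over ±37 nt) is
randomized 20 times preserving amino-acid content in the ORF portion and
nucleotide content in the UTR portion; per gene, the mean predicted folding
energy of ATG-free variants is paired with that of ATG-containing variants,
and a paired t-test is run across genes per window position. The fixed START
triplet, present in every variant of a window that covers position 0, is not
counted as an ATG - only alternative ATGs carry contrast, and counting the
START would empty the ATG-free class for the whole centre of the profile.

The minimum-free-energy predictor is a pluggable `folding_engine()` contract:
a vectorised function from sequences to MFE values (kcal/mol, non-positive,
zero on homopolymers). The package ships a constant null engine and a fast
base-pair-count heuristic for testing the bookkeeping, plus an adapter for the
ViennaRNA `RNAfold` command-line predictor for thermodynamic analyses. The
pairing, dropping and testing logic is identical whichever engine is plugged
in, which is exactly what the stub-engine tests verify.

## The predictor ladder

Four features per gene: (1) Kozak hamming distance of the START context;
(2) raw PSSM context score of the START (the relative score is identically 1
there, so the raw score is the informative form); (3) the number of
alternative ATGs, all frames, starting less than 30 codons downstream of the
START; (4) the mean relative context score of those sites (missing when there
are none; such genes sit at the standardized feature mean when predicting).
Predictors A-D use features {1}, {2}, {2,3}, {2,3,4}.

Evaluation (`evaluate_predictor()` / `ladder_report()`): genes are split into
random halves 100 times; on each training half the data are binned by
descending target (protein abundance or ribosomal density) in bins of 15
genes, an ordinary least-squares combination of the standardized,
direction-aligned binned features is fitted (count and distance features enter
negated so that "better initiation" points the same way for every feature -
the combination rule is the package's choice, as is Pearson correlation on
bin means, with Spearman reported alongside), and the fit is scored on the
binned test half. The adjusted correlation
`sqrt(max(0, 1 - (1 - r^2)(n - 1)/(n - k - 1)))` discounts the gain from
adding features (k features, n test bins).

```{r ladder}
feats <- compute_features(sim$genes, pssm, exclude = train)
target <- sim$expression %>% select(gene_id, value = pa)
ladder_report(feats, target, reps = 20, seed = 1)
```

## The synthetic-genome generator

`simulate_genome()` emulates the features of real transcriptomes the analysis
relies on, with defaults fixed once:

* 5'UTR lengths Poisson with mean 82 nt (the budding-yeast mean), minimum 6 nt;
* ORF lengths Poisson with mean 150 codons, minimum 40 - compact genes chosen
  because no analysis stage looks beyond ~100 nt into the ORF, and a START
  ATG, a stop drawn from realistic stop-usage, and a stop-free frame-0 body;
* codon usage with a deterministic mild within-family bias (weights 1..k per
  family) unless a usage table is supplied;
* an ATG-depletion zone of 20 codons of UTR and 8 codons of ORF flanking the
  START at strength 0.5 (inside the 16-27 / 5-11 codon ranges typical of
  eukaryotes): every sampled ATG triplet inside the zone, in any frame, is
  rejected and locally resampled with the zone's probability, by re-drawing
  the codon, UTR triplet or context block that contains it - rejection keeps
  codon usage outside the hits unbiased, unlike post-hoc masking. The
  strength can be coupled to expression (`expr_coupling`) to emulate stronger
  selection on highly translated genes;
* START contexts drawn from a mixture of a strong consensus PSSM and a
  uniform PSSM with weight `plogis(context_effect * latent)`, tying context
  quality to the gene's latent log-expression (context draws whose +1..+3
  triplet would be a stop are redrawn: codon 2 of a real gene is never a
  stop);
* expression measurements `exp(latent component + Normal(0, 0.5))` for mRNA,
  ribosomal density and protein abundance - log-normal, matching the heavy
  tails of real compendia - with ribosomal load derived as their product.

One seed drives every draw, and the generator is byte-reproducible. What the
synthetic genomes deliberately do *not* contain: introns, IRES elements,
alternative transcripts, real dinucleotide composition, 3'UTR structure, or
correlated noise between expression platforms. Tests passing on these genomes
therefore validate the *machinery* - coordinates, statistics, null models,
recovery of planted effects - not the biological conclusions on any real
genome.

## Numerical choices and degenerate inputs

KS tests are two-sided via `stats::ks.test` (ties among integer counts make
the p-values asymptotic; the directional mean gate supplies the one-sidedness
where direction matters). Paired t-tests with zero-variance differences
return p = 1 when all differences are 0. Entropy uses `0 log 0 = 0`.
Geometric means are computed in log space. Empty groups (a near/far side with
no sites, a variant class with no members, a gene with no scoreable context)
are dropped and logged, never imputed as zero. Cross-validation repetitions
with zero-variance test bins are skipped and logged. All randomized
procedures take explicit integer seeds; replicate r of a null-genome ensemble
uses `seed + r` so single replicates can be regenerated independently.

Problem sizes used by the test-suite simulations (2,000 genes for region
calibration and predictor recovery, 500 for the folding control, 50 seeds for
calibration rates) were chosen as the smallest sizes at which the planted
effects are comfortably outside sampling noise.

## The pipeline

`run_pipeline(run_config(...))` chains every stage - simulate or load, train
the PSSM, profiles, null genomes and flags, both region estimators, the
context-score profile, stratification, cost statistics, the folding control
and the predictor ladder - writing one TSV/JSON per stage with a provenance
header echoing the seed and parameters. The bundle is byte-identical across
runs with the same configuration; stages needing expression data are skipped
with a notice when none is available.

## Known limitations

* The context-score functional form (geometric-mean ratio) is one reasonable
  choice among several (sum-of-logs, CAI-like weights); rankings are similar
  but absolute profile values are form-dependent.
* The KS region estimator over-covers sharp depletion zones by ~3 codons by
  construction (see above); treat it as the generous member of the bracket.
* The base-pair-count folding engine is a bookkeeping stub, not a
  thermodynamic model; use the RNAfold adapter for real folding questions.
* Binned Pearson correlations depend mildly on bin size; 15 is the default
  throughout, and `bin_size = 1` recovers unbinned correlation.
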