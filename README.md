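# atgscan

Genome-wide analysis of translation-initiation fidelity signals in eukaryotic
transcripts.

## The problem

The scanning model of eukaryotic initiation says the pre-initiation complex
walks the 5'UTR until it recognises an AUG in a favourable context. Scanning
is leaky, so ATG triplets near the annotated START — upstream *and*
downstream, in any reading frame — are potential sites of spurious
initiation, producing wasteful or harmful peptides. Genomes under selection
against such accidents should show, around the START:

* fewer alternative ATGs than expected from amino-acid content, codon bias
  and GC content;
* anti-optimal (weak) Kozak contexts on the alternative ATGs that remain;
* in-frame stop codons unusually close to alternative ATGs, capping the
  metabolic price of an accident.

`atgscan` measures all three signatures and quantifies their predictive power
for expression. The core quantities:

* a **start-context PSSM** trained on the top 2% of genes by ribosomal load
  (mRNA × ribosomal density), with the relative context score of a site *s*
  in gene *g* defined as
  `CS(s) = (prod_i p_i[n_i(s)])^(1/9) / (prod_i p_i[n_i(START_g)])^(1/9)`
  over the 9 context positions −6..−1, +1..+3, so `CS(START) = 1`;
* frame-resolved **ATG count profiles** over ±90 nt and two estimators of the
  depleted region length: sliding 11-codon-window Kolmogorov–Smirnov tests
  (region = `window − 1 + consecutive significant windows`, first-window
  gated), and boundary-anchored runs of positions where ≥95% of 20
  codon-resampled null genomes carry more ATGs than the real genome;
* **null genomes** by synonymous codon resampling (genomic codon bias,
  identical proteins), per-gene codon permutation, and a ramp-preserving
  variant that keeps the codon distribution of the first 40 codons;
* **distance-to-stop and ATP cost** of the peptide induced by each
  alternative ATG (amino-acid biosynthesis costs + 7 ATP/residue
  translation), compared near vs far from the START and against null genomes
  with the real ATGs planted back in;
* a **folding-energy control** (paired t-tests on MFE of ATG-containing vs
  ATG-free window randomizations, pluggable MFE engine incl. ViennaRNA
  RNAfold);
* a **predictor ladder** A–D (Kozak distance; START context score; + count
  of alternative ATGs within 30 codons downstream; + their mean relative
  context score) evaluated by 100 repeated 2-fold cross-validations on
  15-gene bins.

A seeded synthetic-genome generator (`simulate_genome()`) reproduces the
statistical structure the analysis assumes — variable 5'UTRs, codon-usage
bias, a tunable ATG-depletion zone, context strength coupled to expression,
log-normal measurements — so the whole pipeline runs and is tested without
any downloads.

## Worked example

```r
library(atgscan)

sim  <- simulate_genome(sim_params(n_genes = 800, seed = 1))
train <- select_training_set(sim$expression, seed = 1)
pssm  <- build_pssm(sim$genes, train)

prof <- atg_count_profile(sim$genes, frame = 1)
detect_region_ks(prof, "ORF")
#> # A tibble: 1 × 6
#>   frame region length_codons n_windows p_values   significant
#>   <int> <chr>          <int>     <int> <list>     <list>
#> 1     1 ORF               12        20 <dbl [20]> <lgl [20]>
```

The simulated genome plants a depletion zone of 8 ORF codons at strength 0.5;
the KS estimator reports a 12-codon frame-1 region — the planted zone plus
the expected few codons of window smear (a window still mostly inside the
zone stays significant). Context scoring and the predictor ladder:

```r
feats  <- compute_features(sim$genes, pssm, exclude = train)
target <- dplyr::select(sim$expression, gene_id, value = pa)
ladder_report(feats, target, reps = 20, seed = 1)
#> # A tibble: 4 × 6
#>   predictor features                                               r r_adjusted r_spearman n_bins
#>   <chr>     <chr>                                              <dbl>      <dbl>      <dbl>  <dbl>
#> 1 A         kozak_dist                                         0.644      0.625      0.697     27
#> 2 B         start_context                                      0.588      0.565      0.748     27
#> 3 C         start_context+alt_atg_count_30                     0.579      0.529      0.714     27
#> 4 D         start_context+alt_atg_count_30+alt_context_mean_30 0.559      0.473      0.690     27
```

In this genome expression influences only the START-context mixture (strong
consensus vs uniform), and the strong consensus is Kozak-like — so the Kozak
distance (A) and the PSSM score (B) both track it, while the alternative-ATG
features (C, D) add nothing and the adjusted correlation duly *drops* as
uninformative features are added. When expression is planted on all four
features (as the test suite and acceptance script do), the ladder rises from
A to D instead. Every result class has an `autoplot()` method;
`run_pipeline(run_config(...))` runs all stages end to end and writes a
deterministic TSV/JSON bundle.

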