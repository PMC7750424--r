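# aacap

Amino-acid composition, culture-media capacity, and antibody production-rate
modelling.

Recombinant antibody yield in transient mammalian expression depends not only
on the construct but on the amino acids available to the cell. `aacap` is an
analysis package for three linked questions around that observation:

1. **Signal-peptide composition.** Antibody V-gene families carry distinct
   N-terminal signal peptides (SPs). The package parses SP repertoires from
   FASTA, profiles each sequence by its essential amino-acid (EAA) content —
   the nine amino acids human cells cannot synthesise (F, H, I, K, L, M, T,
   V, W) — and derives per-family consensus sequences.
2. **Media stoichiometry.** Given a media formulation (per-amino-acid
   molecule supply, or g/L concentrations converted via
   `n = c·V/M · N_A`) and the per-copy amino-acid demand of a full-length
   antibody, the package computes the yield ceiling each amino acid imposes,
   `max_copies(a) = supply(a) / demand(a)`, and reports the limiting amino
   acid, zero-supply amino acids, and non-essential amino acids whose
   biosynthetic precursor is missing too.
3. **Production-rate prediction.** A three-class one-vs-rest L2-regularised
   logistic model over 20 amino-acid count features,
   `P(y_k | x) = 1 / (1 + exp(-(β₀ₖ + βₖ·x)))`, k ∈ {low, medium, high},
   with rates categorised at the 20% / 70% cuts, a 118:30:20
   model/test/test split, 20-fold cross-validation of the ridge strength
   scored by support-weighted precision, inverse-frequency class weights, a
   triplicate train/test protocol, and a stratified frequency baseline.
   Evaluation uses mean pairwise ROC AUC and support-weighted F1.

Because the underlying production measurements are not publicly available,
the package ships a seeded synthetic generator (`generate_variants()`) that
emulates their statistical shape — count features perturbed around a real
full-length antibody composition, a planted linear effect on the rate, and
an imbalanced three-class label distribution — so the whole pipeline is
testable end to end, including parameter recovery.

## Worked example

```r
library(aacap)

# Essential amino-acid profile of the IgE leader
eaa_profile("MDWTWILFLVAAATRVHS")
#> $variety   [1] 8
#> $total_eaa [1] 12
#> $length    [1] 18

# Which amino acid caps antibody yield in DMEM?
med <- media_fixture()
capacity(med$supply, med$demand)
#> Media capacity report
#>   limiting EAA:     W (1.88 x 1e18 copies)
#>   limiting overall: A (0.00 x 1e18 copies)
#>   zero-supply amino acids: A, D, E, N, P
#>   precursor gaps: N (from D), P (from E)
```

Tryptophan is the scarcest essential amino acid relative to demand: one
litre of the formulation supports at most 1.88 × 10¹⁸ antibody copies.
Among amino acids actually supplied, serine (1.51 × 10¹⁸) is the global
bottleneck; five non-essential amino acids are absent outright, two of them
(N, P) with their precursors (D, E) also missing.

```r
ds <- generate_variants(generator_config(seed = 101))   # 168 variants
reps <- run_replicates(ds$records, n_replicates = 3, base_seed = 101)
```

The analysis drivers under `analysis/` run these steps in order
(`01_sp_profiles.R` … `04_fit_evaluate.R`) and write their tables to
`results/`. On the simulated 168-variant panel the triplicate protocol
prints, per replicate and test set, pairwise AUC between 0.82 and 1.00 and
weighted F1 between 0.68 and 0.95 against a 0.50 baseline, and the
full-data fit recovers the sign of all five planted amino-acid effects
(|effect| ≥ 0.5 SD).

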