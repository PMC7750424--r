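---
title: "Amino-acid supply, signal peptides, and antibody production modelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Amino-acid supply, signal peptides, and antibody production modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aacap)
```

This vignette is the methods account of the package: the models it
implements, the assumptions behind them, the tunable parameters and why
their defaults are what they are, and the limits of what the synthetic
tests demonstrate.

## Essential amino-acid profiling of signal peptides

Antibody heavy and light chains are translated with an N-terminal signal
peptide (SP) that routes them into the secretory pathway and is cleaved
from the mature protein. Each V-gene family carries its own SP repertoire;
the package ships the consensus/representative leader of the six Vκ
light-chain families, the seven VH heavy-chain families, and the
myeloma-derived IgE leader as a FASTA fixture (`sp_fixture()`).

Profiling is deliberately simple: a sequence is summarised by its
composition (multiplicity of each of the 20 amino acids) and by two EAA
statistics, the number of distinct essential types present (`variety`,
0–9) and the number of essential residues (`total_eaa`). The essential set
is fixed to the nine classical human EAAs {F, H, I, K, L, M, T, V, W};
histidine is included, which is required for the fixture profiles to be
internally consistent. Sequences are handled case-insensitively and
validated strictly: letters outside the 20-letter alphabet (including the
ambiguity codes B/X and the rare U/O) abort parsing rather than being
dropped, because a silently shortened sequence would corrupt counts.

Family consensus is position-wise majority over pre-aligned, equal-length
members — family SPs have a fixed length, so no alignment step is needed
or provided. Ties are broken towards the alphabetically first tied residue
and each tie is reported via `message()`; any deterministic rule works
here, and the alphabetical one is the easiest to audit. A family with one
member (several families have only one or two database sequences) passes
through unchanged.

## Media stoichiometry

The capacity model treats a culture medium as a finite pool of free amino
acids and a protein as a fixed demand vector: with `supply(a)` molecules
of amino acid `a` available and `demand(a)` residues of `a` per antibody
copy, the medium supports at most

$$\mathrm{max\_copies}(a) = \frac{\mathrm{supply}(a)}{\mathrm{demand}(a)}$$

copies as far as `a` is concerned (infinite when the protein does not use
`a`), and the limiting amino acid is the argmin. This is pure
stoichiometry: no uptake kinetics, no cell growth, no competing cellular
protein synthesis, and no serum contribution. Those simplifications mean
the reported ceilings are upper bounds under an idealised "every molecule
goes into antibody" reading; the point of the analysis is the *ranking*
(which amino acid runs out first), which is insensitive to a uniform
efficiency factor because capacity is homogeneous of degree one in supply.

Two framings of "limiting" are surfaced, because both are informative: the
argmin over essential amino acids only (tryptophan in the DMEM fixture, at
1.88 × 10¹⁸ copies/L), and the argmin over all demanded amino acids (the
zero-supply non-essential amino acids, and serine at 1.51 × 10¹⁸ among
those actually supplied). Essential amino acids cannot be synthesised by
the cell, so their ceilings are hard; a missing non-essential amino acid
can in principle be made from a precursor, which is why the report also
flags *precursor gaps* — NEAAs absent from the medium whose donor (S for
C and G, D for N, E for Q, P and R, following standard human biosynthesis;
the pairing is configurable) is absent too. In the DMEM fixture that flags
N (donor D missing) and P (donor E missing).

Numerical conventions: capacities are real-valued ratios; the 2-decimal
×10¹⁸ presentation (and ×10²⁰ for supplies) is display-only and uses
half-up rounding (`capacity_table()`). Concentration inputs are converted
with `n = c \cdot V / M \cdot N_A` using average free-amino-acid molar
masses (with water); the mass table is configurable because formulations
are published to two or three significant figures and the choice of mass
table moves counts by well under that precision. The shipped molecule
counts themselves are the fixture of record; the conversion is validated
on glutamine, where 0.584 g/L reproduces the fixture's 24.07 × 10²⁰
molecules.

## The production-rate model

Production rates are percentages of a fixed reference construct (100%);
rates above 100% occur and are meaningful. Rates are categorised at the
20% / 70% cuts: low `< 20`, medium `20–70` inclusive on both ends (forced
by the strict inequalities defining low and high), high `> 70`.

The predictor is the literal one-vs-rest logistic form

$$P(y_k \mid x) = \frac{1}{1 + e^{-(\beta_{0k} + \beta_k \cdot x)}},\qquad
k \in \{0, 1, 2\},$$

one sigmoid per class over the 20 amino-acid count features — *not* a
softmax. Per-class scores therefore do not sum to one; for ranking metrics
a normalised view (scores divided by their row sum) is available, and
class prediction is the argmax with ties broken towards the lower class
index so reruns are deterministic.

Fitting minimises the class-weighted, L2-penalised binomial negative
log-likelihood per class with a damped Newton method (step-halving line
search), run to a gradient-norm tolerance of 1e-6 or 1000 iterations;
the objective trace is retained and tested to be monotone non-increasing.
The intercept is unpenalised. Features are z-scored using statistics of
the training portion only — without standardisation a ridge penalty on
raw counts would penalise abundant amino acids less per unit of effect.
Class weights default to inverse class frequency (normalised to mean 1)
to counter the deliberate scarcity of high producers; they are
configurable because no single weighting is canonical for mildly
imbalanced three-class data.

The regularisation strength is tuned on a grid of 10 values log-spaced
from 1e-4 to 1e4 by 20-fold cross-validation on the model set (~95%
train / 5% validation per cycle), scored by support-weighted precision on
the validation folds; ties prefer the smaller strength, and the final
model is refit on the whole model set at the selected value. A fold whose
training part loses a class entirely is skipped with a warning rather
than fitted degenerately.

The evaluation protocol mirrors the data-scale conventions: a uniform
random partition into a model set and two independent test sets with
sizes 118:30:20 at N = 168 (proportional largest-remainder scaling
otherwise), the whole train/test cycle run in triplicate with replicate
seeds advancing deterministically from a base seed, and a stratified
frequency baseline (constant prior scores, hence pairwise AUC 0.5 by
construction) fitted alongside. Metrics are support-weighted precision
and F1 and the mean pairwise ROC AUC: for every unordered class pair the
two-class AUC (Mann–Whitney rank form, ties 0.5) is computed in both
score directions and averaged, then averaged over the three pairs. All
three metrics are verified against independent brute-force references in
the test suite to 1e-10.

## The synthetic variant panel

The generator (`generate_variants()`) emulates the statistical shape of a
transient co-transfection variant panel, not its biology. Defaults, chosen
once as the package's study conditions:

* **n = 168 variants**, split 118:30:20 — the scale of a realistic
  permutation panel.
* **Class shares 0.40 / 0.40 / 0.20** (low/medium/high): high producers
  are a deliberate minority, in the 15–20% range typical of such panels.
* **Count features**: the full-length antibody demand profile serves as
  the base composition, perturbed per variant by symmetric integer noise
  (difference of two Poisson(3) draws, clipped at zero). This mimics
  variant-to-variant count variation from CDR and SP differences while
  keeping counts non-negative integers whose mean tracks the base
  composition (tested at n = 2000 within 5%).
* **Planted effects** on z-scored counts: W +1.0, K +0.7, I +0.5,
  L −0.8, S −0.6 (per SD), echoing the qualitative trends of the
  repertoire analyses (tryptophan availability helping, leucine/serine
  load hurting). Magnitudes are set for testability — large enough that
  sign recovery is a fair requirement at n = 500 — not as biological
  estimates, since the real effect sizes are unknown.
* **Rate map**: the latent score is squashed onto (0, 250)% by an affine
  logistic calibrated by quantile matching so the class cuts of the
  latent distribution land exactly on 20% and 70% — the simplest monotone
  map consistent with observed rate ranges (which reach ~240%) — then
  Gaussian noise with SD 3 percentage points is added and rates are
  clipped at 0. Realised class shares stay within ±5 points of target.

A single config seed governs everything; replicate seeds are fixed
increments. What passing tests show: the pipeline recovers planted signs,
separates classes (mean pairwise AUC ≥ 0.9 at n = 500), and beats the
baseline under the generator's assumptions — linear effects, independent
Poisson-ish count noise, additive Gaussian rate noise. What they do not
show: performance on real panels, where effects need not be linear,
counts are correlated through shared germline frameworks, and measurement
noise is heteroscedastic. The published accuracy range of comparable real
analyses is therefore not a reproduction target here.

## Design choices where the design was open

* **Sign recovery** is assessed on the high-minus-low coefficient
  contrast `β₂ − β₀`, the natural one-vs-rest analogue of "direction of
  effect" — individual class coefficients answer "class k vs rest", whose
  sign for the medium class is uninformative.
* **Class-weight proportions**: the weights are data-derived
  (inverse frequency) rather than fixed constants, because no consistent
  fixed partition of the three classes was available to hard-code.
* **Boundary rates** land in the medium class at both 20 and 70, the only
  assignment compatible with strict low/high inequalities.
* **Dummy baseline**: stratified sampling from training priors by
  default, `most_frequent` available — both are standard baseline
  conventions and the choice does not affect the AUC comparison, which
  only uses the (constant) prior scores.
* **VH1 and VH7** share an identical leader sequence and are kept as two
  records: they are distinct families and repertoire statistics count
  families, not unique sequences.

## Problem sizes

The shipped analyses use n = 168 (the panel scale) for the narrative
drivers and n = 500 for parameter-recovery checks; the law-of-large-numbers
composition check uses n = 2000. These sizes make every property sharp
enough to test while keeping the full suite and drivers fast to rerun.

## Known limitations

Stoichiometry ignores all competing demand for amino acids and any
feeding/uptake dynamics; capacity numbers are idealised ceilings. The
model is a linear logistic classifier by design — no interactions, no
alternative learners. Consensus assumes equal-length family members and
does not align. The generator plants a linear ground truth, so it cannot
probe model misspecification.
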