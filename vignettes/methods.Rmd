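---
title: "Predicting multi-point mutation effects on antibody-antigen binding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting multi-point mutation effects on antibody-antigen binding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Affinity maturation — improving how tightly an antibody binds its antigen —
usually requires several simultaneous point mutations, but most computational
predictors score one mutation at a time. `abddg` predicts the change in
binding free energy

$$\Delta\Delta G = \Delta G_{\text{wild}} - \Delta G_{\text{mutant}},
\qquad \Delta G = RT\,\ln K_D,$$

with $R = 1.987\times10^{-3}$ kcal mol$^{-1}$ K$^{-1}$, for arbitrary
multi-point mutations on an antibody–antigen complex structure. Under this
sign convention a positive $\Delta\Delta G$ means the mutant binds tighter.

## The model

A mutation is represented by structure-derived features computed from the
wild-type complex and a modelled mutant:

* **Graph-based signatures** (the cutoff scanning matrix): heavy atoms within
  an environment radius of the mutated sites are labelled with eight
  pharmacophore classes (hydrophobic, positive, negative, acceptor, donor,
  aromatic, sulfur, neutral; an atom may carry several). For every unordered
  class pair the signature counts atom pairs cumulatively over increasing
  distance thresholds. Multi-site mutations use one signature over the
  *union* environment of all sites, so neighbourhood overlap between nearby
  sites is captured rather than double-counted.
* **Pharmacophore changes**: per-class atom-count differences between the
  idealized mutant and wild-type residues, summed over sites.
* **Interaction-network deltas**: typed non-covalent contacts (hydrogen bond,
  ionic, aromatic–aromatic, cation–$\pi$, hydrophobic, polar, van der Waals)
  detected with heavy-atom geometric rules, counted in three scopes (whole
  complex, interface-crossing, involving mutated sites), mutant minus
  wild-type.
* **SASA deltas**: Shrake–Rupley solvent accessible surface area (mutated
  sites, whole complex, and interface-buried area).
* **Distances**: min/mean/max pairwise distance between mutated sites (with a
  0 Å sentinel plus an `n_sites` column for single mutations, so trees can
  condition on the site count instead of encountering missing values), and
  min/mean distance from the sites to the binding partner.
* **Evolutionary scores**: PAM30 substitution scores and, when PSI-BLAST
  PSSM files are supplied, per-position log-odds for the wild-type and mutant
  letters and their difference; aggregated over sites by sum and min.

The regressor is an ensemble of extremely randomized trees (via `ranger`,
`splitrule = "extratrees"`): every tree sees the full training set (no
bootstrap), split points are drawn at random, and — following the reference
formulation of the algorithm — all features are candidates at every split
(`mtry = p`). Predictions are deterministic given the stored seed, and a
trained model embeds a hash of the feature schema and refuses inputs in any
other schema.

## Mutant modelling

Mutants are built by incremental side-chain replacement: backbone atoms
(N, CA, C, O) are never moved; the side chain is replaced with an idealized
template (Engh–Huber-like bond lengths and angles, extended chi angles, no
rotamer search or minimization) rigidly aligned on the residue's own
N/CA/C frame. This keeps the package self-contained and deterministic; the
cost is that modelled side chains ignore packing, so contact and SASA deltas
describe an idealized conformer rather than a relaxed one. The proline ring
closure in the template is approximate (CD–N ≈ 1.7 Å), which only affects
features through geometry, never through energies.

## Curation and augmentation

Affinity records carry $K_D$ pairs in molar (or a direct $\Delta\Delta G$;
records carrying both are validated for consistency). Non-binders — mutants
whose binding is abolished — carry no $\Delta\Delta G$ and are excluded from
regression training; they are kept as a classification-only partition.
Because curated affinity data skew toward destabilizing mutations (the
synthetic generator reproduces a mean near $-1$ kcal/mol), training sets are
augmented with *hypothetical reverse mutations*: for each single-point record
with $|\Delta\Delta G| < 2$ kcal/mol, a record with swapped wild-type/mutant
letters and negated $\Delta\Delta G$ is added. The bound is interpreted as a
strict bound on the magnitude (the motivation is that large effects could
compromise binding in the reverse direction); it is configurable. Reverse
records are featurized from the modelled forward-mutant structure as the new
wild-type context, never by negating forward features.

A multi-point record whose constituent singles are all measured is labelled
*additive* when the sum of the single effects is within 1 kcal/mol of the
multi-point effect, else *synergistic*. For classification, $\Delta\Delta G >
0.5$ kcal/mol is affinity-increasing and $\Delta\Delta G \le -0.5$ decreasing;
the band in between is reported as its own neutral class and dropped from
binary metrics by default (binarizing at 0 is available behind a flag).

## Validation schemes

Stratified k-fold cross-validation assigns folds by $\Delta\Delta G$
quartile (the stratification variable is a package choice; the record count
per fold stays balanced within strata). Two leakage rules are enforced and
tested: augmented reverse records always travel with their forward record,
and leave-one-complex-out places all records of one complex in one fold.
Metrics are Pearson/Spearman/Kendall correlations, RMSE, and MCC/F1/AUC at
the ±0.5 kcal/mol thresholds.

Greedy forward feature selection adds, at each step, the feature that
maximizes cross-validated Pearson correlation (ties broken by schema order)
and stops when the improvement drops to $\varepsilon$ (default $10^{-3}$).
The selected-set size is data-dependent and reported, not enforced.

## Design mode

`enumerate_designs()` generates all $\binom{n}{k}\,19^k$ double ($k=2$) or
triple ($k=3$) substitutions of the interface residues on one side of the
complex; a residue is interfacial when any heavy atom lies within 5.0 Å of
the opposite partition (a common contact definition — the choice is ours and
configurable, as is everything above via `default_config()`).
`rank_designs()` scores candidates in bounded batches and returns the top
affinity-increasing and -decreasing lists; candidates are scored jointly as
one multi-mutation, not as sums of single-site predictions. Glycine and
proline substitutions are included but flagged (`has_gly_pro`) because the
backbone-preserving builder cannot represent their backbone strain.

## What the synthetic data does and does not show

`make_toy_complex()` builds ideal-geometry extended chains with template
side chains, placed at a requested interface separation;
`make_synthetic_dataset()` draws random mutations, computes their *real*
features, and plants a known effect model — linear in five named features
plus one pairwise interaction ($\Delta\Delta G$ SD ≈ 1.5 kcal/mol), Gaussian
noise $\sigma = 0.3$ kcal/mol, mean shifted to $-1$ — then back-computes
$K_D$ pairs through the thermodynamic relation so curation is exercised end
to end. Planted non-binders and additive/synergistic multi-records cover
those paths.

Passing the recovery experiments therefore shows the pipeline computes its
features correctly and the ensemble can recover a declared
structure-determined signal at realistic noise; it does *not* show accuracy
on real antibody complexes, whose folds, packing and epistasis the toy
structures do not emulate. Those evaluations require the curated
experimental datasets and structures, which the evaluation harness can
consume through the same CSV/PDB interfaces.

## Problem sizes and numerical choices

The shipped experiments use five toy complexes, 500-record synthetic
datasets ($\sigma = 0.3$), a 300-record noiseless set for the capacity
check, and 240-point SASA sampling inside featurization (960 for standalone
SASA, where the isolated-atom closed form is matched within 1%; the
golden-spiral lattice makes all of this deterministic). Signature bins
default to upper edges 2.5–10.0 Å in 1.5 Å steps with a 10 Å environment
radius; these are surfaced in `signature_params()` because the original
method does not publish them. Contact-rule thresholds are frozen in
`contact_config()`. Altloc ties resolve alphabetically; hydrogens are
ignored throughout ("heavy atoms only"); PDB insertion codes are preserved
verbatim and never renumbered.

## Known limitations

* The mutant builder ignores rotamers and relaxation; large buried
  substitutions are modelled optimistically.
* Contact typing is hydrogen-unaware (donor/acceptor roles come from a
  residue/atom table, not from explicit hydrogen geometry).
* PSSMs are consumed, never computed; without them the evolutionary family
  degrades to PAM30 features plus a missingness indicator with
  dataset-median imputation.
* How the original method aggregates per-site features for multi-point
  mutations is unpublished; the aggregation here (one mutant carrying all
  sites, deltas wt-vs-final-mutant, evolutionary scores by sum and min) is
  declared, not inferred.
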