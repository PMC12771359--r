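---
title: "Descriptor-based surrogate modelling of protein–GAG binding energies: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Descriptor-based surrogate modelling of protein-GAG binding energies: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gagsurr)
```

## The problem

Glycosaminoglycans (GAGs) — sulfated, strongly anionic linear
polysaccharides such as heparin or chondroitin sulfate — bind proteins
largely through electrostatics. MM-GBSA estimates of their binding free
energies are informative but expensive: every frame of a molecular-dynamics
trajectory needs an explicit molecular-mechanics plus generalized-Born
evaluation. `gagsurr` implements the alternative: summarize each frame of a
protein–GAG complex as a fixed vector of cheap structural and energetic
descriptors, and train regression models that map those descriptors to the
MM-GBSA energy. The MM-GBSA values themselves are always *inputs* here — the
package never computes GB solvation.

The package has three layers:

1. a **descriptor engine** turning a multi-model PDB trajectory (plus a
   per-atom parameter sidecar) into a 25-feature vector per frame;
2. a **modelling harness** with eight regression families behind one
   `gag_train()` / `predict()` contract, a fixed evaluation protocol, and two
   uncertainty procedures;
3. **synthetic generators** with closed-form ground truth, so every layer is
   testable without any external dataset.

## The descriptor vector

All coordinates and cutoffs are in Å, energies in kcal/mol, charges in
elementary-charge units — the conventions of the ff14SB/GLYCAM-style force
fields whose parameters the sidecar carries. The canonical feature set
(`CANONICAL_FEATURES`, 25 entries) is:

* **Formal charges** of protein and GAG: sums of the sidecar partial
  charges, rounded to the nearest integer (the raw sums are retained as an
  attribute for diagnostics).
* **Local charge environment**: counts of positively (Lys, Arg, His/Hie)
  and negatively (Asp, Glu) charged protein residues with any atom within
  5 Å of any GAG atom, and the signed net counts at 5 and 10 Å. "Near" is
  always the minimum atom–atom distance criterion.
* **Local polarity**: hydrophobic (Ala, Val, Leu, Ile, Phe, Trp, Met, Tyr)
  and hydrophilic (Ser, Thr, Asn, Gln, Asp, Glu, Lys, Arg, His/Hie) residue
  counts at both radii and their difference (the polarity index). Residues
  in neither class (e.g. Gly) count for neither. His and Hie are accepted
  as synonyms because protonation-state naming differs between pipelines.
* **Ligand geometry**: end-to-end distance (first atom of the first GAG
  residue to the last atom of the last, anchors configurable) and
  mass-weighted radius of gyration.
* **Complex geometry**: mass-weighted center-of-mass distance, and the
  angle between the first principal axes of protein and GAG, folded to
  \[0°, 90°\] because principal axes carry no sign. Coincident geometry
  (zero covariance) yields a flagged `NA` rather than an arbitrary angle.
* **Contacts**: unique (protein heavy atom, GAG heavy atom) pairs within
  3.5 Å (short) and 5.0 Å (medium). Pair counting, not unique-atom
  counting, matching the common trajectory-tool convention; hydrogens are
  excluded.
* **Hydrogen bonds**, separately with the GAG as donor and as acceptor:
  N/O donor with a bound hydrogen (H within 1.2 Å — the sidecar carries no
  bond table, so covalency is inferred geometrically), N/O acceptor,
  donor–acceptor distance ≤ 3.5 Å and donor–H–acceptor angle ≥ 135°.
* **Solvent-accessible surface areas** of protein alone, GAG alone, and
  the complex (Shrake–Rupley, below).
* **Linear interaction energies**: raw pairwise Coulomb and Lennard-Jones
  sums over protein–GAG atom pairs (below).

A frame with any flagged-missing feature is dropped (with a log message)
before model training; nothing is imputed, because in this workflow a
missing value means physically degenerate geometry (e.g. a dissociated
ligand), not measurement noise.

## Energetic descriptors: numerical choices

**LIE.** `lie_energy()` sums, over all receptor–ligand pairs within a
cutoff, `k·q_i·q_j / r` with `k = 332.0522` kcal·Å/(mol·e²) at dielectric 1,
and the Lennard-Jones term `ε_ij[(R_ij/r)^12 − 2(R_ij/r)^6]` with
`R_ij = Rmin/2_i + Rmin/2_j` and `ε_ij = √(ε_i ε_j)` — the Rmin/ε
convention and combining rules of the AMBER-family force fields. The cutoff
defaults to 12 Å (the customary trajectory-tool default; it is a config
field, not a constant). There is no periodic imaging, no switching
function, and no exclusion handling: interface pairs are never bonded. Any
evaluated pair closer than 0.1 Å raises an error, since that indicates
corrupt geometry rather than physics.

**SASA.** `shrake_rupley()` places a deterministic golden-spiral lattice of
`n_points` (default 960) on each atom's probe-expanded sphere (probe
1.4 Å); a point is accessible iff outside every other expanded sphere. A
deterministic lattice makes the result bit-reproducible, at the price of
exact rotational invariance: rotating a structure changes which lattice
points are occluded, so SASA is invariant under translation exactly but
under rotation only up to lattice resolution (about 2 % at 240 points,
tighter as `n_points` grows; the per-atom area is always bounded by the
full sphere area). An isolated atom is exact at any `n_points` — the test
suite uses that analytic limit.

## The modelling protocol

All models see z-scored features (population standard deviation, matching
the behaviour of the standard ML scaler) fitted on training data only;
test, validation, and future tables are transformed with the stored
training statistics. The evaluation protocol is:

* 80/20 random train/test split, regenerated with a fresh seed for every
  repetition (`run_repetitions()`, 10 repetitions by default, metrics
  reported as mean ± population SD);
* an untouched group-holdout validation table (e.g. one receptor subtype
  held out entirely, `split_group_holdout()`), never split and never
  scaled with its own statistics;
* R², MSE and MAE per set, with R² against the evaluated set's own mean.

The eight families and their defaults (each family's best grid setting):

| family | implementation | defaults |
|---|---|---|
| `elastic_net` | glmnet | strength 1.0, L1 ratio 0.5 |
| `linear_regression` | least squares | — |
| `linear_svr` | ε-SVR, linear kernel | C = 1, ε = 0.1, 10⁴ iterations |
| `rbf_sampler_linear_svr` | random Fourier features + linear SVR | 100 components, γ = 1/p |
| `gradient_boost` | xgboost (exact trees) | 200 rounds, depth 8, η 0.1, row/col subsample 0.8 |
| `hist_gradient_boost` | xgboost (histogram trees) | 200 iterations, depth 6, η 0.1, L2 0.1 |
| `random_forest` | ranger | 200 trees, depth 30, √p features |
| `fcnn` | native implementation | no hidden layers, dropout 0.01, ReLU |

The regularization objective of `elastic_net` maps the standard ML
parameterization (strength α, `l1_ratio`) onto glmnet's (λ, α) exactly, so
the defaults reproduce the usual `ElasticNet(alpha = 1, l1_ratio = 0.5)`
behaviour, including exact zeros from the L1 part.

**The FCNN** is implemented natively (plain matrix arithmetic): Adam
(learning rate 0.001, L2 weight decay 10⁻⁴), MSE loss, minibatches of 256,
inverted dropout on the input and every hidden activation, early stopping
(patience 15 epochs) monitored on a carved-out 10 % of the training rows,
and learning-rate halving on plateau. Six activations (ReLU, ELU, GELU,
LeakyReLU, Sigmoid, Tanh) are available; with zero hidden layers the model
is an input→output linear map with input dropout, and the activation is
irrelevant. Two numerical choices matter at desk scale:

* the network trains on the internally standardized target and
  back-transforms predictions. Adam's step size is scale-free, so without
  this the parameter distance to the optimum grows with the target's scale
  and offset and small tables cannot converge within any reasonable epoch
  budget;
* the optimisation budget is step-based, not epoch-based: `min_steps`
  (default 25 000) extends the epoch cap — and the patience,
  proportionally — on small tables, so a 500-row table receives the same
  number of Adam updates as a 50 000-row one. On large tables the epoch cap
  (200) behaves as usual. Patience measured purely in epochs is implicitly
  scale-dependent; this keeps the effective protocol comparable across
  table sizes.

**Uncertainty** comes from two independent procedures, reported separately:
Monte Carlo dropout (30 stochastic forward passes with dropout active at
inference; exactly zero spread at dropout 0) and repeated cross-validation
(30 rounds of seeded 10-fold partitions, per-row SD of out-of-fold
predictions).

## Experiments

`run_benchmark()` runs every family, optionally twice (with and without the
two LIE columns — the ablation asks whether models survive losing their
best single descriptor). `fcnn_sweep()` grids architecture × dropout ×
activation. `data_reduction_curve()` thins the development table to every
k-th row — because rows are ordered (system, trajectory, frame), this
respects the time-correlation structure of MD data — and retrains from
scratch per point, skipping points below 50 rows.
`trajectory_mean_eval()` and `first_frame_screen()` evaluate the
trajectory-averaged and single-structure use cases.
Feature-space structure is examined with `pearson_matrix()` and
average-linkage clustering on the distance `1 − |r|` (redundancy is about
correlation magnitude, not sign). Feature importance has four mechanisms —
standardized coefficients (linear families), built-in impurity/gain (tree
families), permutation importance, and leave-one-feature-out retraining —
each normalized by its own maximum absolute value so that different models
are comparable on one scale. Shapley-value importance is not implemented
(no engine for it is a package dependency); where a workflow would use it,
permutation importance is the substitute and reports itself as such.

## The synthetic generators

Two generators make every claim testable with known ground truth.

**Toy complexes** (`gen_toy_complex()`): a short coil of four-atom residues
with a chosen residue-class sequence, plus a chain of five-atom
sulfated-unit analogues carrying a configurable per-unit charge, placed at
one of six pose directions at a configurable offset. Alongside the
structure, every descriptor is recomputed by `oracle_descriptors()` — an
intentionally naive implementation with explicit loops over atoms, pairs,
and lattice points that shares no code with the production path. The
descriptor engine is accepted only if it reproduces the oracle exactly for
counts and to 10⁻⁸ relative for continuous values. The geometry is
schematic by design: it exercises every branch of the descriptor math
(charged/polar/unclassified residues, both hydrogen-bond directions,
contact shells, burial) but does not attempt realistic folds, sugar
puckers, or solvent.

**Feature tables** (`gen_feature_table()`): multivariate-normal features
with a specified correlation matrix (Cholesky construction), an optional
trajectory layout (frames per trajectory, AR(1)-correlated noise,
per-trajectory offsets, a trajectory-level share of feature variance, an
optional systematic first-frame drift), an optional mean-shifted held-out
group, and a target built from linear weights, optional product
interactions, and Gaussian noise. The attainable R² ceiling follows in
closed form (Isserlis' theorem handles the interaction variance), which is
what parameter-recovery and reduction-curve tests compare against.

The study-like preset (`table_spec_paperlike()`) encodes the qualitative
structure of real protein–GAG descriptor data: three correlated blocks
(electrostatic, interface, geometry), contacts anticorrelated with the
energy, and — the load-bearing choice — `lie_elec` generated as a λ = 0.85
proxy of the structural energy core plus a unique component, rather than as
an independent additive term. This mirrors the physics (the electrostatic
interaction energy largely *is* the binding energy) and it is what makes
the LIE-ablation experiment behave as it does on real data: when the LIE
columns are removed, linear models lose their only route to the core's
interaction (non-linear) part, while tree ensembles recover it from the
structural features directly. With an additive design instead, the optimal
Δ(R²) under ablation is provably family-independent and the experiment
degenerates to sampling noise. Preset magnitudes (core scale 7, unique
weight 2.5, noise SD 4, trajectory offset SD 1) give a ceiling R² of about
0.76 and a LIE–target correlation of about 0.85; they are chosen once from
the closed forms as plausible for this data class, not calibrated to any
dataset.

What passing these tests shows — and does not. Agreement with the oracle
and the closed-form ceilings validates the descriptor arithmetic and the
training protocol end to end. It does not certify accuracy on real
MM-GBSA data: Gaussian features cannot reproduce heavy-tailed descriptor
distributions, discrete counts, conformational clustering, or
force-field-specific couplings. Deposited descriptor tables can be ingested
through `read_feature_csv(column_map = ...)` for that purpose.

## Problem sizes and determinism

The test suite and `scripts/acceptance.R` run entirely on generated data at
sizes chosen to make the statistical comparisons sharp while staying
desk-sized: 20 toy complexes for oracle equivalence (240 lattice points —
equivalence is about implementation agreement, not convergence, which is
tested separately at 960/3840), 20 000–50 000-row tables for recovery and
ceiling checks, 6 000 rows × 2 repetitions for the eight-family ablation,
and a 50 000-row table for the 2 % data-reduction experiment. Every source
of randomness flows from explicit integer seeds; rerunning any experiment
with the same seed is bit-identical (xgboost and ranger are pinned to one
thread inside the package for exactly this reason).

## Known limitations

* Descriptor extraction is O(n·m) in receptor × ligand atoms and the SASA
  path O(n²) in atoms per frame — fine for single complexes and the
  package's scope, not tuned for thousand-frame production runs.
* The multi-model PDB reader expects MD-style output: consistent atom
  ordering across models, first-altloc-only, hydrogens present (H-bond
  counts silently become 0 otherwise, with a warning).
* The linear SVR uses the libsvm ε-regression solver, whose iteration
  behaviour differs from the liblinear-style solver the defaults were
  tuned for; with C = 1 on standardized features the fitted models agree
  closely, but the `max_iter` setting is recorded rather than enforced.
* The feature count is 25; workflows that require a 24-feature network
  input (dropping one of the redundant charge counts) can do so via
  `descriptor_config(feature_set = ...)` — the package deliberately does
  not guess which column to drop.
* `first_frame_screen()` labels a trajectory "strong" when its frame-0
  *prediction* is at or below the energy threshold (more favourable);
  thresholds are on the physical energy scale, where lower is stronger.
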