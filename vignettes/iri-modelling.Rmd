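---
title: "Modelling ice recrystallisation inhibition with iriscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling ice recrystallisation inhibition with iriscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Ice recrystallisation — the Ostwald-ripening-like growth of large ice
crystals at the expense of small ones in a frozen polycrystalline sample —
is a principal cause of freezing injury in cryopreserved cells and tissues.
Activity of an ice recrystallisation inhibitor (IRI) is quantified by the
splat-cooling assay as **% mean grain size (MGS)**: the mean ice crystal
size after annealing, relative to a saline-only control. Lower %MGS means
smaller crystals, i.e. a more active inhibitor. `iriscreen` implements a
quantitative structure–activity (QSAR) pipeline for this endpoint: six
molecular representations, ensemble feed-forward network models evaluated
under leave-one-out cross validation (LOO CV), and a virtual-screening
cascade that turns consensus predictions into a purchasable prediction set.

## Representations

Two representations come straight from the SMILES:

* **standard** — a frozen list of 45 physicochemical properties
  (`standard_descriptor_names()`): molecular weight, heavy-atom and ring
  counts, H-bond donors/acceptors, TPSA, calculated logP, rotatable bonds,
  connectivity and shape indices. The exact list is a package constant so
  feature vectors are reproducible.
* **cliques** — a count fingerprint over a dataset-derived vocabulary of
  molecular subgraphs: the smallest set of smallest rings (rings sharing
  more than two atoms merged, the junction-tree convention) plus every
  non-ring bond as a two-atom fragment. Counts rather than bits preserve
  multiplicity; whether the original formulation was binary is unrecorded,
  so this is a documented package choice. Out-of-vocabulary fragments are
  ignored with a warning.

Two need a 3D conformer:

* **H-wACSF** — weighted atom-centred symmetry functions: per-atom radial
  functions \(\sum_j Z_j e^{-\eta (r_{ij}-\mu)^2} f_c(r_{ij})\) and angular
  functions over atom triples, with the neighbour's atomic number as the
  weight and a cosine cutoff \(f_c\). Per-function values are pooled across
  atoms into a normalised histogram, giving a fixed length regardless of
  molecule size. Binning uses linear interpolation between bin centres
  rather than hard assignment so the descriptor is continuous in the
  coordinates. Defaults (cutoff 0.6 nm, 8 radial centres, \(\eta = 80\)
  nm\(^{-2}\), four \((\zeta, \lambda)\) angular terms, 10 bins) are
  conventional mid-range values — the originally optimised parameters were
  never published — and every one is exposed in `acsf_params()`.
* **SOAP** — the smooth-overlap-of-atomic-positions power spectrum. Each
  atomic environment is a sum of Gaussians (width 0.05 nm) on the
  neighbouring atoms; it is expanded in an orthonormalised Gaussian radial
  basis (analytically, via modified spherical Bessel functions) and real
  spherical harmonics to \(l_{max} = 4\), and the rotation-invariant power
  spectrum \(p_{nn'l} = \sum_m c_{nlm} c_{n'lm}\) is averaged over atoms.
  Invariance to rotation, translation and permutation of identical atoms is
  exact by construction and asserted by tests at 1e-8.

Two are bespoke, derived from solvated molecular-dynamics trajectories:

* **hydration histograms** — the probability density \(P(d)\) of all
  pairwise distances between water oxygens and solute atoms,
  \(P(d) = n_d / (\Delta d \sum_i n_i)\), with 100 bins to a 0.5 nm cutoff
  (\(\Delta d = 0.005\) nm), minimum-image convention on orthorhombic
  boxes, averaged over 100 evenly spaced frames (all frames when fewer
  exist, with a log note).
* **hydration indices** — ten hydration numbers divided by a molecular size
  metric. The hydration number at a cutoff is the mean count of waters
  whose *nearest-solute-atom* distance is below the cutoff: the histogram
  deliberately uses all pairs while the hydration number uses the nearest
  atom, because the two quantities are defined differently. The ten
  cutoff specifications are seven fixed distances (0.20–0.50 nm; the exact
  seven were never listed, so the package uses even 0.05 nm spacing,
  config-exposed), the first- and second-solvation-shell minima detected
  from a wide-range (0.8 nm) histogram after a 5-bin moving-average smooth,
  and a hydrogen-bond count under geometric criteria (donor–acceptor
  ≤ 0.35 nm, hydrogen–donor–acceptor angle ≤ 30°, both directions counted —
  standard trajectory-analysis defaults, as only "geometric criteria" is
  recorded). Size metrics are a grid-based van der Waals volume (0.02 nm
  grid, Bondi radii), Shrake–Rupley solvent-accessible surface area
  (0.14 nm probe, 960 deterministic sphere points) and the formula weight.
  Models train on the volume-normalised indices;
  `hydration_correlation_report()` tabulates the %MGS correlation of every
  (cutoff, metric) combination.

## Models and cross validation

Targets and features are Min-Max scaled to [0, 1] with statistics fitted on
the training fold only; constant columns map to 0 with a warning.
Classification encodes activity as `active` iff %MGS is strictly below the
threshold (default 70; the boundary is `inactive` — "active" should mean
strictly smaller grains, a choice the protocol leaves open) and balances
classes with SMOTE (synthetic minority rows interpolated between k = 5
minority nearest neighbours). The learner is a feed-forward network, two
rectifier hidden layers (64, 32) by default, trained full-batch with Adam
(step 0.003) for at most 300 epochs with binary cross-entropy
(classification) or mean squared error plus L2 penalty σ = 0.005
(regression), early-stopped on a 10 % validation split with patience 20 and
best-weight restoration. The (64, 32) architecture and patience are package
defaults — per-representation architectures were tuned in work that was
never published — and the Adam step of 0.003 was chosen for optimisation
stability on ~60-row scaled datasets (0.01 made fold-to-fold prediction
variance the dominant error source). All randomness (validation split,
SMOTE, initialisation) flows from one seed per fold derived from the global
seed, so a full LOO run is bit-reproducible.

`loo_cv()` re-runs the entire preprocessing inside every fold; a leakage
probe in the tests corrupts the held-out target after training and asserts
the fold's prediction is unchanged. Ensembles combine per-representation
models by majority vote (classification; exact ties default to `inactive`,
the conservative call for screening) or by the mean with the population SD
as the uncertainty (the models are the whole population of interest;
`ensemble_regress()` has a sample-SD switch). `search_ensembles()`
evaluates every subset of three or more models, ranking by F-score
(ties → higher precision) or PCC (ties → lower MSE); undefined metrics from
zero denominators are reported as `NA`, never silently as 0.

## Virtual screening

`select_seeds()` takes the 15 most and 5 least active training compounds
(ties broken by id). `build_prediction_library()` keeps a candidate iff its
best Tanimoto similarity to a seed (Morgan radius 2, 2048 bits — the
community default; the original fingerprint is unrecorded) exceeds 0.7, its
canonical SMILES is not in the training set, it is a single fragment (the
`.` separator is the only structure-level signal for co-salts and
co-additives) and its calculated logP is at most 1.8 (solubility proxy);
the audit reports per-filter removals in that order. `train_ensemble()`
refits each member on the full training set (no LOO at screening time),
`screen_library()` discards predictions with ensemble SD above 15 %MGS and
marks the ten lowest- and ten highest-predicted survivors as the prediction
set. Cost and availability considerations that shaped the original
purchased set are not computable and are out of scope.

## The synthetic world

Real inputs (assay tables, 20 ns solvated trajectories) cannot ship with a
package, so two seeded generators make every stage testable.

`generate_solvated_trajectory()` plants known hydration structure: each
shell holds exactly `n_waters` oxygens whose nearest-solute distance lies
in `[inner, outer)` in every frame (kept 0.002 nm clear of the boundaries
so GRO-precision round-trips cannot move a water across one), with a
triangular radial profile inside the band so shells look like solvation
peaks rather than flat plateaus, rigid water geometry (0.09572 nm,
104.52°) and bulk waters beyond the outermost shell. It makes no attempt at
thermodynamically realistic water structure — it exists so hydration
numbers and histograms can be checked against planted truth, which the
tests do with brute-force double loops and explicit minimum-image
arithmetic.

`generate_sar_dataset()` emulates a measured activity table: an enumerable
family of amino-acid-like scaffolds (six backbones × 24 side chains,
deduplicated and given a fixed hash-order shuffle so any contiguous slice —
e.g. a training set and a disjoint candidate library — spans the same
chemistry); true activity is a logistic function of three standard
descriptors (MolWt, TPSA, cLogP, frozen standardisation), rescaled to
[5, 110] %MGS so that regression on the pre-logistic scale recovers the
generating coefficients exactly at zero noise. Observed %MGS adds Gaussian
noise clamped to [0, 120]; replicate SDs are gamma-distributed with mean
equal to the noise level. Defaults are 63 compounds (the size of the
measured amino-acid training set) and a 10 %MGS noise SD (replicate SDs in
the measured data are mostly below 15, and the published "typical error"
band is of this order). A green test on this world establishes that the
machinery is correct, not that the chemistry of real IRIs is captured:
the synthetic activity is a smooth function of three 2D descriptors,
which real %MGS is not.

## Numerical choices and limitations

* The noise-ceiling property: with assay noise σ, the best possible
  prediction–measurement correlation is
  \(\sqrt{Var_{signal}/(Var_{signal}+\sigma^2)}\) (about 0.90 for the
  measured data). The acceptance benchmark checks the LOO PCC of a
  six-member seed-ensemble on the standard block against this ceiling at
  σ ∈ {0, 10, 25}. Note that LOO PCC is a pessimistic estimator: each
  observation's noise influences every *other* fold's model, which induces
  a negative empirical prediction–noise covariance worth several
  hundredths of PCC at n = 63 — at high noise even a near-oracle ridge
  regressor sits visibly below the analytic ceiling.
* Shell-minima detection needs adequately sampled histograms; with sparse
  statistics the smoothed density can show spurious dips. The smoothing
  window (5 bins) and detection range (0.8 nm) are config-exposed.
* Degenerate inputs: empty histograms warn rather than error; a missing
  second-shell minimum is an error naming the shell; constant metric
  vectors flag `NA` rather than fabricate a number; screening with too few
  survivors returns the whole surviving library with a warning.
* SOAP/H-wACSF parameter defaults are *not* the originally optimised
  values (unavailable); quantitative results under any concrete choice
  will differ from the published tables, which additionally depend on
  deposited datasets and per-representation architectures that are not in
  the public record.

## A worked run

```{r}
library(iriscreen)

training <- generate_sar_dataset(63, noise_sd = 10, seed = 1)
blocks <- list(standard = featurize(training, "standard"),
               cliques  = featurize(training, "cliques"))
per_model <- loo_cv_blocks(training, blocks,
                           model_config("regression", seed = 1))
search_ensembles(per_model, task = "regression")

library_set <- generate_sar_dataset(78, noise_sd = 10, seed = 2, skip = 63)
ens <- train_ensemble(training, blocks, model_config("regression", seed = 1))
lib_blocks <- list(standard = featurize(library_set, "standard"),
                   cliques  = featurize(library_set, "cliques",
                                        vocab = build_clique_vocabulary(training$smiles)))
screen_library(library_set, ens, lib_blocks, screen_config())
```
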