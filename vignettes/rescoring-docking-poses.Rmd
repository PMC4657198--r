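---
title: "Rescoring rigid-body docking poses with interface features and contact symmetry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rescoring rigid-body docking poses with interface features and contact symmetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poseRank)
```

## The problem

Rigid-body protein-protein docking engines enumerate thousands of
candidate dimer arrangements ("poses"). Their internal energy scores
are good at generating near-native poses somewhere in the ensemble,
but poor at putting them at the top. poseRank addresses the rescoring
step: given an ensemble of poses for a receptor-ligand pair, compute a
small set of per-pose attributes and combine them with a supervised
regression model so that near-native poses rise to the top ranks.

## The attributes

Four attributes are computed for every pose, plus a fifth for
homo-dimers:

1. **SVC and NBC interface scores.** An external interface-residue
   predictor assigns each receptor residue two probabilities of being
   interfacial (one from an SVM-type classifier, one from a naive
   Bayes classifier). The interface score of a pose is the sum of
   these probabilities over the receptor residues at the pose's
   interface (a residue is interfacial when any of its heavy atoms is
   within 10 Å of the partner chain). Poses that bury regions
   predicted to be interfacial score high. Using the continuous
   probabilities rather than a binary classification lets weak
   prediction signal still contribute.
2. **Docking-potential score.** Each residue carries up to three
   interaction sites: the side-chain center (unweighted centroid of
   side-chain heavy atoms; for glycine the Cα position by convention),
   the backbone carbonyl oxygen, and the backbone amide nitrogen. Site
   pairs across the interface are contacts at class-specific
   inclusive thresholds — 6.8 Å for side-chain/side-chain, 4.0 Å for
   backbone/backbone (all four O/N combinations), 5.6 Å for mixed
   pairs — and each contact contributes a parameter read from a
   pairwise potential table keyed by the two residue types and site
   classes. The parameter table is an input (the published values were
   obtained by linear-programming optimization elsewhere); pairs
   absent from the table contribute zero and are counted.
3. **External energy.** The docking engine's own total energy score is
   consumed as an opaque per-pose scalar; poseRank does not
   re-implement any engine's energy model.
4. **Contact-based symmetry (CBS), homo-dimers only.** Most
   homo-dimers form (approximately) C2-symmetric interfaces, while
   random decoys are overwhelmingly asymmetric. With residues of the
   two identical chains indexed on a common frame, each inter-chain
   contact is a pair $(x, y)$; ideal C2 symmetry means the contact set
   is closed under $(x,y) \mapsto (y,x)$. Splitting the contacts
   (self pairs $x = y$ excluded — they are trivially symmetric) into
   $S_1 = \{x < y\}$ and $S_2 = \{x > y\}$ and transposing $S_2$, the
   score is the Jaccard index
   $$\mathrm{CBS} = \frac{|S_1 \cap S_2'|}{|S_1 \cup S_2'|} \in [0, 1],$$
   which is 1 exactly when the non-self contact set is transposition
   closed. A contact-free pose has an empty union; it scores 0 by
   convention (flagged in the result), which deliberately penalizes
   non-interacting "dimers" in ranking.

Because chains of different proteins form interfaces of very
different sizes, raw attributes are standardized per target across the
ensemble: $Z = (x - \bar{x}) / \sigma_x$ with the **population**
(divide-by-N) standard deviation — the ensemble is the entire
population being standardized, not a sample. A constant attribute maps
to all-zero Z-scores rather than NaN.

### Residue correspondence for CBS

CBS needs the two chains on one residue index frame. When both chains
share author numbering (and no insertion codes), numbering is used
directly after a sanity check that residue types agree. Otherwise the
chains are globally aligned (BLOSUM62) and residues are indexed by
alignment column; insertion-code residues are handled naturally this
way, since integer comparison is undefined for them. Chains aligning
below 50 % identity are rejected with an error — CBS is a homo-dimer
score and silently returning 0 would be misleading.

## The ranker

Ranking is cast as regression of the interface RMSD (iRMSD) on the
standardized attributes: models predict iRMSD and poses are sorted
ascending, ties broken by pose id (deterministic and auditable). Two
model kinds are supported, following what works at the respective
data sizes: epsilon-SVR with an RBF kernel (via e1071/LIBSVM) for
homo-dimers, and ordinary linear regression for the much smaller
hetero-dimer data. SVR hyperparameters default to cost 1, epsilon
0.1, gamma 1/d; an optional small seeded grid search over cost and
gamma is available and everything used is recorded in the model's
training metadata. Benchmarking uses two-fold cross-validation with
folds split **by target** (never by pose) from a seeded permutation,
so no target's poses ever inform its own ranking.

`defaultHeteroModel()` ships the published hetero-dimer linear
weights (SVC 171.9, NBC 891.8, potential 122.7, energy 2.2, intercept
0). Only the magnitudes are published; whether the weighted sum is a
quality score (higher = better) or an iRMSD predictor (lower =
better) is not derivable from them. Both orientations are supported
explicitly; the default is "quality", because large positive weights
on interface-probability scores are most plausibly rewarding good
poses, and `predictRank()` honors whichever orientation the model
declares. Nothing is silently assumed: the orientation is stored in
the model metadata and serialized with it.

## Evaluation

* **iRMSD**: receptor Cα atoms of the pose are Kabsch-superposed onto
  the native receptor over all common residues, then the RMSD is taken
  over Cα atoms of the ligand interface residues. The interface is
  defined on the **native** complex (10 Å heavy-atom criterion) — the
  ambiguity between native- and model-defined interfaces is resolved
  this way so that the metric is comparable across poses of one
  target.
* **fnat / fnon-nat / PCS**: residue-pair contact classification over
  the universe of all receptor x ligand pairs: fnat = TP/(TP+FN),
  fnon-nat = FP/(TP+FP), and PCS is the Matthews correlation
  coefficient of the contact map. The standard MCC denominator
  $\sqrt{(TP{+}FP)(TP{+}FN)(TN{+}FP)(TN{+}FN)}$ is used; a
  non-standard variant that circulates in the literature (with
  $(TP{+}TN)$ and $(FP{+}FN)$ factors) is available behind
  `mccVariant = "printed"` for audit only, since it is not the MCC.
  Degenerate denominators yield 0 with a flag, never NaN.
* **Ranking summaries**: percentage of successful cases (targets with
  at least one hit in the top 10), hit count (mean hits per target in
  the top 10), and the success rate as a function of ranking depth
  n. Hit criteria are iRMSD at most 2.5/8.5/9.5 Å or PCS at least
  0.65/0.30/0.25 for experimental structures, high- and
  moderate-quality monomer models respectively
  (`evaluationConfig()`).
* **CBS distribution**: the cumulative fraction of inputs with CBS at
  or above each threshold, used to contrast near-native models with
  decoys.

All distance comparisons in the package are inclusive ("within 10 Å"
is read as ≤), and contact machinery is tested for exact set
equality against brute-force scans, monotonicity in the cutoff, and
invariance under rigid motion.

## The synthetic benchmark

Real benchmarks require experimental structures, docking-engine
ensembles and an external interface predictor. The generator module
reproduces the *statistical shape* of that setting from a seed:

* **Monomers**: helical or self-avoiding-coil Cα traces (3.8 Å step)
  with idealized backbone N/O positions and a single pseudo
  side-chain atom per residue (none for glycine). One atom per side
  chain is enough to exercise the side-chain-center and potential
  machinery without rotamer modeling. Atom spacing is kept at 2 Å or
  more.
* **Natives**: exact C2 dimers built by a 180° rotation, with the
  inter-chain gap bisected to a requested closest approach (default
  4 Å, a typical interface contact distance). Exact C2 forces CBS = 1.
* **Decoys**: the native ligand under a random rotation-plus-
  translation whose magnitude is bisected until the realized iRMSD
  matches a requested target within 0.1 Å; gross receptor overlap is
  rejected. Realized iRMSD is stored as truth and verified against
  the evaluation module to 1e-6 Å.
* **Probability tables**: true interface residues from the native,
  with a per-class label-flip rate solved from the expected-MCC curve
  and applied as an exact count, so that thresholding at 0.5 realizes
  the requested prediction MCC (within the rounding granularity of
  the chain; an infeasible request errors rather than silently
  degrading). SVC and NBC columns get independent flips.
* **Potential table**: random normal parameters over all (residue
  type, site class) pairs — a synthetic stand-in for the published
  optimized parameters, exercising lookup, symmetrization and the
  collective "bb" class.
* **Energies**: a Gaussian copula draw with the Pearson coefficient
  chosen so the Spearman correlation between energy and true iRMSD is
  the requested value (0.4 by default: informative but far from
  decisive, like a real engine score).

The default study conditions — 20 targets, 200 poses per target,
48-residue monomers, 3 % of poses in the near-native stratum (below
2.5 Å) and the rest spread to 30 Å, probability tables at MCC 0.5,
energy correlation 0.4 — emulate the sparse-hit regime of real
rigid-body ensembles, where a target typically has only a handful of
hits among thousands of decoys. The end-to-end check in the test
suite runs exactly these conditions and asserts two ordering
properties: the cross-validated combined ranker strictly beats
ranking by energy alone on top-10 hit count, and the homo-dimer
ranker with CBS strictly beats the same ranker without it.

What the generator does **not** emulate: real side-chain packing and
shape complementarity (decoys here do not cluster around funnels),
correlated errors between the SVC and NBC predictions, engine-specific
energy landscapes, and crystallographic artifacts (altloc disorder,
missing density) beyond what the PDB reader handles. Passing the
synthetic end-to-end test therefore demonstrates that the pipeline's
plumbing, learning and evaluation logic behave correctly and that the
feature set carries the intended signal — not that the shipped
defaults would reproduce any particular benchmark figure on real
complexes.

## Numerical choices and degenerate inputs

* Bisections (C2 gap, decoy iRMSD) run 50-60 halvings from a doubling
  bracket; tolerances are 0.01 Å (gap) and 0.1 Å (iRMSD).
* Altloc selection: highest occupancy, ties to the alphabetically
  first altloc; first MODEL only; hydrogens (H/D) and HETATM excluded
  at parse time.
* Side-chain centers are unweighted centroids by default ("center of
  mass" without a mass table is ambiguous; the unweighted centroid is
  exactly reproducible), with `massWeighted = TRUE` available.
* Ties in ranking break on ascending pose id; fold assignment comes
  from a seeded permutation; every generator restores the caller's
  RNG state.
* Empty contact sets: CBS 0 (flagged), interface scores 0, degenerate
  contact-map metrics 0 (flagged).

## Problem sizes

The shipped tests exercise chains of 8-50 residues against exhaustive
oracles, parameter recovery at 500 poses over 20 seeds, and the full
20 x 200 benchmark; these sizes give stable statistics for every
property asserted while keeping the whole suite comfortably
reproducible on a single CPU.

## Limitations

* CBS targets C2 (cyclic two-fold) contact symmetry only; higher
  cyclic or dihedral point groups, symmetry-axis fitting and
  geometric (RMSD-based) symmetry measures are out of scope.
* The docking potential's 253 published parameters are an input; the
  package ships no claim about their values.
* mmCIF, NMR multi-model ensembles, and ligand/cofactor chemistry are
  not handled.
* The hetero-dimer weight orientation remains a documented choice,
  not a derived fact.

## A short session

```{r example, eval = FALSE}
library(poseRank)

# a synthetic target: C2 native, 30-pose ensemble
monomer <- makeMonomer(48, "helix", seed = 7)
native <- makeC2Pose(monomer, contactGap = 4)
ens <- makeDecoyEnsemble(native, 30, c(1, 2, seq(3, 30, length.out = 28)),
                         seed = 7)
probs <- makeProbabilityTable(native, targetMcc = 0.5, seed = 7)
pot <- makePotentialTable(seed = 7)
energies <- makeEnergyColumn(ens$irmsd, rho = 0.4, seed = 7)

feats <- featurize(ens$poses, probs, pot, energies, homo = TRUE)
model <- trainRanker(feats, ens$irmsd, kind = "svr_rbf")
head(predictRank(model, feats))

cbsScore(native)          # CBS = 1 for the C2 native
irmsd(ens$poses[[3]], native)
```
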