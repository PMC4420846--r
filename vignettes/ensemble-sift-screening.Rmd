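---
title: "Ensemble SIFt profiles for post-docking virtual screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble SIFt profiles for post-docking virtual screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ensift)
```

## The problem

Molecular docking against a single receptor structure treats the binding
site as rigid, but real receptors — G protein-coupled receptors more than
most — sample many conformations, and a ligand series will not all bind the
same one. Ensemble post-docking addresses this by docking every compound
into a set of receptor conformations (crystal structures or homology
models) and combining the per-conformation results into one description per
compound. `ensift` implements that analysis: it encodes each docked complex
as a structural interaction fingerprint (SIFt), averages the fingerprints
over the ensemble into a per-ligand profile, trains a linear support vector
machine to separate actives from inactives or decoys, and measures how the
screening performance depends on the number of conformations included.

## The fingerprint

A SIFt is a binary string with one nine-bit chunk per binding-site residue.
The nine classes, in fixed order, are: any contact, main-chain contact,
side-chain contact, polar, hydrophobic, hydrogen-bond acceptor,
hydrogen-bond donor, aromatic, and charged. Two conventions deserve
emphasis because the literature is not uniform:

* **Direction of the hydrogen-bond bits.** `hb_donor` means the *residue*
  donates the hydrogen bond to the ligand; `hb_acceptor` means the residue
  accepts one. This is the residue-centric convention of the original SIFt
  work.
* **Derived bits.** `any` is set by any heavy-atom contact (and is always
  set when a typed interaction is detected, even a ring-centroid contact
  slightly beyond the generic cutoff); whenever `any` is set, at least one
  of `main_chain`/`side_chain` is set.

The geometric predicates operate on heavy atoms only, so poses with and
without explicit hydrogens are handled uniformly; when hydrogens do ride a
donor, the D–H…A angle test is applied in addition to the distance. The
cutoffs (see `?geometry_config`) are this package's choices, not literature
constants — interaction-fingerprint tools differ in these values, and no
single published set is canonical. They follow common practice: 4.5 Å
generic/hydrophobic contact, 3.5 Å polar and hydrogen-bond heavy-atom
distance with a 120° minimum angle, 5.0 Å aromatic centroid separation,
4.0 Å for opposite formal charges. All are configurable, and the
monotonicity property (growing a cutoff never clears an `any` bit) is part
of the test suite.

Receptor-side atom typing (donor/acceptor/charge/aromatic/hydrophobic per
standard residue) is table-driven; histidine nitrogens are kept as both
donor and acceptor because the tautomer is unknowable without hydrogens,
and carboxylate/amine/guanidinium groups carry the formal charges of
physiological pH. Ligand-side typing is derived from file connectivity:
donors are N/O/S with an explicit or valence-implied hydrogen, acceptors
are O/N with a free valence (and neutral S, weakly), hydrophobic atoms are
carbons or sulfurs with no bonded N/O, and aromaticity comes from aromatic
bond orders or kekulized 5/6-rings. These are deliberately simple,
connectivity-only rules; they do not attempt protonation-state or tautomer
enumeration (out of scope — upstream preparation tools own that).

## From fingerprints to profiles

For every compound with at least one pose in the ensemble, the profile is
the position-wise average of its binary fingerprints. The source
description — averaging "over all models" while only requiring one pose —
is ambiguous about compounds that failed to dock in some conformations.
Both readings are implemented:

* `denominator = "ensemble"` (default): divide by the full ensemble size,
  so missing poses contribute zero vectors. This is the literal reading,
  and it lets the profile encode "this compound docks rarely", which is
  itself a signal.
* `denominator = "poses"`: divide by the number of conformations with a
  pose, renormalising away dockability.

The two coincide when every conformation produced a pose; tests cover both.

Compounds expanded into several protonation-state instances keep their
parent compound's label, and cross-validation folds are grouped by parent
compound so instances of one molecule never straddle a train/test boundary
— the leakage-safe choice, on which the source is silent.

## The classifier

The screening model is the standard soft-margin linear SVM: minimise
½‖w‖² + C·Σξᵢ subject to yᵢ(⟨w, xᵢ⟩ − b) ≥ 1 − ξᵢ (one printed version of
this constraint circulating with the method contains a typesetting artifact,
"− var(αᵢ)ξᵢ"; the standard constraint is what is implemented). The dual is
solved by libsvm via `e1071` with a 1e-6 tolerance, but the model object
always exposes the dual multipliers, and feasibility — Σαᵢyᵢ = 0,
0 ≤ αᵢ ≤ C, w = Σαᵢyᵢxᵢ — is checked post hoc
(`check_dual_feasibility()`); the test suite additionally compares the
attained dual objective with a brute-force active-set enumeration solver on
small problems. Only the linear kernel is provided: profile features are
already in an interpretable, low-redundancy space, and the reference
protocol used no other kernel.

Model selection scans C over 0.01, 0.1, 1, 10, 100, 1000, 10000 under
10-fold stratified, compound-grouped cross-validation. Performance is the
Matthews correlation coefficient computed from confusion counts *pooled
over folds* — stabler than averaging per-fold MCCs when folds are small and
a fold can lack one class outcome entirely; the per-fold mean is reported
alongside for transparency. MCC's zero-denominator case returns 0, the
usual convention. Ties in the C scan go to the smaller C (the less complex
model). AUROC uses the Mann–Whitney pair-counting formulation with ties at
½.

## The ensemble-size experiment

`run_sweep()` evaluates ensemble sizes s = 3 … N by building profiles on
the *first s* conformations of a fixed order and re-running the full
C-grid cross-validation at each size. Prefix semantics — rather than the
best subset of each size — are the only computationally sane reading of
"adding one-by-one" (best-subset would need 2^N evaluations) and match the
incremental design of the original experiment. The addition order defaults
to the input order; an option orders conformations by descending AUROC from
the centroid pre-evaluation stage (`rank_conformations()`), and the sweep
records the step at which the top-AUROC conformation enters. Per-step
ΔMCC values telescope exactly to MCC(N) − MCC(3), which the tests assert,
and best/worst sizes break ties towards the smaller (cheaper) ensemble.

## What the synthetic generator emulates — and what it does not

No docking poses accompany the reference data, so the package ships a
generator (`simulate_fingerprints()`) that reproduces the *statistical*
structure the analysis relies on:

* actives share a conserved interaction pattern — by default
  `n_signal_bits = 3` typed positions, the classic three-point anchoring
  motif of aminergic GPCR ligands (ionic anchor, hydrogen bond, aromatic
  stack);
* each conformation reports a signal bit with per-conformation dropout
  probability `flip_prob = 0.3`, standing in for pose fluctuation across
  receptor conformations;
* all other typed positions carry sparse background contacts
  (`background_rate = 0.05`) for every class of compound;
* a compound misses a pose in a conformation with probability 0.05, and
  compounds that dock nowhere are omitted, mirroring the at-least-one-pose
  rule;
* derived bits are repaired after noise so every chunk satisfies the
  fingerprint invariants.

Averaging over s conformations shrinks the signal-bit variance as
p(1−p)/s — the binomial law the tests check — so ensemble growth denoises
the conserved pattern, which is precisely the mechanism invoked to explain
why more conformations screen better. A `noise_correlation` knob shares
noise across conformations through a Gaussian copula at fixed marginal
rates; at ρ = 0.8 it emulates a "crystal-like" ensemble whose members make
correlated mistakes, and averaging then cannot cancel them — reproducing
the observation that restricted conformational diversity hurts screening.

The default compound counts (550 active, 601 inactive, 2526 decoy
instances over 20 conformations) mirror a realistic campaign; the residue
count (30) approximates a GPCR binding-site contact set. With three signal
bits the small-ensemble regime is deliberately *not* separable
(cross-validated MCC ≈ 0.95 at three conformations, approaching 1 at
twenty), because a generator whose size-3 problem is already solved could
not express the ensemble effect at all.

What the generator does **not** emulate: real pose geometry (bits are
drawn, not computed from coordinates), chemical series structure among
actives, property-matched decoy difficulty, or inter-position correlation
beyond the chunk-repair rules. Passing tests therefore demonstrate that
the pipeline's statistics behave as designed, not that any particular
receptor will screen at these MCC values.

For geometry-level testing the complementary generator
`make_toy_complex()` builds receptor–ligand complexes in which requested
interaction classes hold *exactly* under the default cutoffs (hydrogen
bonds at 2.9 Å, polar pairs at 3.3 Å, contacts at 4.0 Å, stacked rings at
4.0 Å, charges at 3.5 Å) while every unrelated pair stays beyond 6 Å; its
residues are laid out on a deliberately exaggerated toy geometry, which is
what makes the no-cross-talk guarantee provable.

## Numerical choices and degenerate inputs

* Activity curation: strict inequalities exactly as stated (Ki < 100 nM
  active, > 1000 nM inactive); boundary values and the between-band are
  excluded. Replicates merge by geometric mean of Ki. IC50 halves to Ki
  before thresholding.
* Clustering: average-linkage on Tanimoto distance; the centroid is the
  member minimising mean distance to the rest of its cluster, ties broken
  lexicographically; two all-zero fingerprints count as identical.
  `cluster_count(n)` is floor(0.3·n), minimum 1.
* Decoy selection: property windows (MW ±25 Da, logP ±1, HBD/HBA ±1,
  rotatable bonds ±2 of *any* active) plus Tanimoto < 0.6 to *every*
  active, then seeded uniform down-sampling — a simplified, reproducible
  stand-in for the full DUD protocol.
* PDB reading: single-model files; waters and hetero groups dropped;
  alternate locations resolved by highest occupancy (ties → 'A');
  insertion codes rejected; ensembles must share an identical
  (chain, resnum, resname) sequence or assembly errors.
* All stochastic steps (fold assignment, simulation, down-sampling) take
  explicit integer seeds and are bit-reproducible.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run entirely on generated data at
desk scale: fingerprint/oracle agreement on 1000 (tests) and 500 (script)
random small complexes; SVM/QP-oracle comparisons on ≤6-point sets; the
ensemble-size experiment at 100 compounds per class, 20 conformations,
20 simulation seeds, with a one-sided sign test at α = 0.05 for the
size-20 > size-3 comparison and for the independent- vs correlated-noise
contrast. These sizes are the package's chosen trade-off between
statistical resolution and a test run that stays pleasant to iterate on.

## Known limitations

* Interaction classes are the nine listed only — no water-mediated,
  halogen-bond or cation–π classes, no per-atom fingerprints, no energies.
* Ligand chemistry perception is connectivity-based and minimal; unusual
  valences, organometallics and mesomeric charge delocalisation are out of
  scope.
* mmCIF receptors and multi-model PDB files are not supported.
* The generator's independence assumptions (above) mean quantitative MCC
  values on synthetic data should not be read as predictions for any real
  screening campaign; only the qualitative contrasts are transferable.
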