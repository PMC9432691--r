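---
title: "Inferring phytase positional specificity from achiral HPLC profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring phytase positional specificity from achiral HPLC profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(inospho)
```

## The model

A phytase removes one phosphate per catalytic event from the *myo*-inositol
ring, whose six positions are numbered 1–6 (position 2 axial). A
phosphorylation state is a subset of `{1..6}`; the species reachable from a
substrate form a directed acyclic graph on the subset lattice, with one edge
per single-phosphate removal. The package's central objects are this graph
(`build_network()`), a rate model assigning each edge the constant
`k = w[removed position] * level_scale[parent phosphate count]`, and a
simulated time course with explicit inorganic-phosphate accounting
(`simulate_network()`): every removal event liberates one Pi equivalent, so
`sum(n_p * [species]) + [Pi]` is conserved exactly, which the test suite
checks to a relative 1e-6 on every simulation.

Two kinetic laws are offered. The default, `first_order`, gives each edge
flux `k * [parent]`; it is linear, identifiable from a handful of
timepoints, and independent of the (unknown) initial amount after
per-timepoint normalization — both properties the inference below relies
on. The alternative `shared_enzyme_mm` law makes all substrate-bearing
species compete for one enzyme pool with substrate inhibition, edge flux
`k * Vmax * [parent] / (Km + T(1 + T/Ki))` with `T` the summed substrate
concentration. The single-pool competition form is this package's own
construction: nothing in the underlying assay literature prescribes a
multi-species rate law, so the simple symmetric choice is made and stated
rather than hidden. Level scaling defaults to 1 everywhere; the preset
`level_scale_insp5_boost()` expresses the common observation that the
pentakisphosphates are consumed faster than the hexakisphosphate.

## Mirror symmetry and what achiral data can never tell you

The ring's one relevant symmetry is the reflection through C2 and C5
(1↔3, 4↔6). It drives everything:

* `mirror()` implements it; states equal to their mirror are meso (16 of
  the 64), all others pair up into 24 enantiomer pairs;
* an achiral anion-exchange column reports **co-elution classes** — the
  pair or the meso singleton — never individual enantiomers;
* consequently the class-level likelihood is *exactly invariant* under
  relabeling every species and every attack weight by the reflection.
  `fit_preferences()` therefore recovers attack weights only up to this
  twofold degeneracy. The returned orientation is a stated convention
  (weight at 6 ≥ weight at 4) unless `resolve_locant` passes in the answer
  from orthogonal evidence.

That orthogonal evidence is the stereospecific-kinase assay modelled by
`kinase_evidence()` / `enantio_disambiguate()`: a kinase that
pyrophosphorylates exactly one member of the candidate pair converts the
purified unknown fraction, or does not. The logical contract is
deliberately asymmetric: conversion at or above the detection threshold
confirms the accepted enantiomer **present** but never excludes the mirror
partner, because a mixture is indistinguishable from the pure accepted
enantiomer in this assay. The default detection threshold is 0.05
(conversion fraction); the bundled preset `itpk1_evidence()` carries the
assay's reference yields (0.90 for InsP6, 0.58 for the pure accepted
standard, 0.12 for a typical unknown fraction). The threshold is a package
default, not a community standard — it sits comfortably below the positive
control yields and above plausible carry-over.

## The inference chain

`exclude_by_absence()` calls a position unattacked when the co-elution
class of its removal product stays below an absence floor at *every*
timepoint. The floor is 1% of the summed first-generation area per
timepoint — a package choice; assay practice reports absence across many
independent runs without quantifying a floor. Because pairs share a peak,
a chiral position can only be excluded together with its mirror partner:
the exclusion round-trip (generator forbidden set in, excluded set out)
holds exactly for mirror-closed forbidden sets, and that is what the tests
assert.

`rank_initial_attack()` normalizes first-generation areas at the earliest
informative timepoint into shares per attack locant set; at early times the
shares approximate `w_p / sum(w)`. `make_call()` assembles exclusions,
ranking and enantiomer resolution into a single report and refuses
contradictory inputs.

`fit_preferences()` minimizes squared residuals between per-timepoint
normalized observed and simulated class abundances. Normalization makes
unknown HPLC response factors and the unknown injected amount cancel;
multi-start bounded optimization (8 deterministic log-scale starts) guards
against local minima; the forward model inside the optimizer is an exact
eigendecomposition propagator for the linear system (with a matrix-
exponential fallback near defective spectra) rather than a stiff ODE
solve, purely for speed — the two agree to solver tolerance.

## Assay analytics

* **Calibration and units.** `calibrate()` is ordinary least squares on
  molybdenum-blue standards; `specific_activity()` implements the standard
  enzyme unit, 1 U = 1 µmol Pi released per minute. (Assay write-ups
  sometimes phrase the unit as a concentration per minute; the amount
  reading is the standard one and is used here.)
* **Substrate inhibition.** `v = Vmax·S/(Km + S(1 + S/Ki))` — the common
  commercial-software parameterization. The fit uses Levenberg–Marquardt
  from a fixed start grid; standard errors come from the Jacobian at the
  optimum. The derived optimum is `S_opt = sqrt(Km·Ki)` with
  `v(S_opt) = Vmax/(1 + 2·sqrt(Km/Ki))`. Monotone (inhibition-free) data
  degrade gracefully to plain Michaelis–Menten with `Ki = Inf` and a
  warning. At the canonical parameters (Vmax 228 U/mg, Km 0.65 mM,
  Ki 2.23 mM) and the twelve-concentration design spanning 12.5–3750 µM,
  noise-free recovery is exact to 1e-6 and the median of 100 seeded 5%-noise
  replicates recovers all three parameters within 10% (both are tested).
* **Profiles.** `profile_maxima()` merges within-sd ties into plateaus, so
  a broad optimum reads as an interval (e.g. pH 4.5–5) rather than an
  arbitrary point. `relative_retention()` and `rank_inhibition()` are thin,
  deliberately boring transformations kept in the package so reports are
  reproducible.
* **Expression.** `expression_analysis()` implements 2^−ΔΔCt with both an
  exact two-sided Mann–Whitney test (exact up to n = 8 per group, normal
  approximation above) and a Welch t test reported side by side — rather
  than switching on a normality screen, both answers are shown. Outliers
  are flagged by the median-absolute-deviation rule (robust z > 3.5), a
  transparent replacement for proprietary outlier procedures; reports state
  the rule.

## The synthetic generators

Each generator emulates the statistical structure its consumer assumes and
emits a truth sidecar for recovery tests:

* `gen_peak_table()` simulates the degradation network under truth weights
  (default: dominant 6-attack, minor 4/5/1/3, spared 2 — weights 4:1:1:0.5:0.5:0,
  global scale 0.15/h), collapses to co-elution classes, merges
  monophosphates into the solvent front (they co-elute with Pi on these
  columns), records absent first-generation classes as explicit zero areas,
  and applies multiplicative lognormal noise (HPLC areas are positive with
  roughly proportional error; default sd 5%). Default design: 5 mM
  substrate sampled at 0.5, 2, 4, 8 h.
* `gen_kinetics_table()` draws from the substrate-inhibition law at twelve
  log-spaced concentrations over 12.5–3750 µM.
* `gen_expression_table()` shifts target Ct by `log2(1/fold)` per condition
  (defaults plant 2.6-fold and 7.5-fold repression against a minimal-media
  control, sd 0.3 cycles, n = 9).
* `gen_fasta()` / `gen_toy_structure()` plant motifs and exact
  ligand-to-residue distances.

What they do **not** emulate: retention-time physics, peak overlap within a
class, detector saturation, response-factor differences between classes,
biological replicate structure beyond i.i.d. noise, or pyrophosphorylated
(InsP7-class) species. Green tests therefore demonstrate the inference
logic is sound under the stated noise model, not that any particular real
chromatogram will be called correctly.

## Sequence and structure utilities

`scan_motifs()` uses a deliberately small grammar (`x` wildcard,
single-position `[..]` alternatives) so hits stay auditable; the default
set covers the catalytic heptapeptide in the generalised form `RHGxRx[PL]`
(canonical histidine-acid-phytase `RHGxRxP` and the MINPP variant
`RHGSRGL`), the HD/HAE proton-donor motifs, the MINPP-specific `PMAAN` and
`LYNE`, and the U-loop tetrapeptide `DAA[AM]`. `classify_phytase()` calls
MINPP-like on heptapeptide + any MINPP-specific motif. `theoretical_mass()`
uses average residue masses (two-decimal kDa, the convention of common
sequence tools). The bundled `synthetic_minpp_protein()` is a constructed
stand-in — random background, planted motifs, composition adjusted to the
58.57 kDa mass of the enzyme the package models — and is labelled synthetic
wherever it appears.

`pocket_residues()` implements the specificity-pocket rule: every residue
with *any* atom within 5.0 Å (closed interval) of a ligand phosphorus atom.
Whether the rule should count side-chain atoms only is not settled in the
structural literature; any-atom is chosen and stated. Tests verify
agreement with an independent text-parsing oracle and invariance under
rigid-body motion to the 1e-3 Å resolution that fixed-width PDB coordinates
carry.

## Numerical choices and problem sizes

Stiff integration (lsoda) runs at rtol 1e-8 / atol 1e-12. The preference
fit uses 8 deterministic starts; the kinetics fit an 18-point start grid.
Tie-breaking is lexicographic everywhere (class representatives, node and
edge ordering) so outputs are byte-reproducible. The test suite sizes its
Monte-Carlo harnesses at 100 seeded replicates for kinetics recovery and
end-to-end call recovery, 200 for expression power, 11 for the (slower)
preference-fit recovery median — sizes chosen to keep the full suite
around a minute while leaving wide margins to the asserted thresholds.
The acceptance script reports medians over 101 seeded replicate fits.

## Known limitations

* Weight recovery is inherently mirror-degenerate (see above); only
  orthogonal stereochemical evidence resolves it.
* Exclusion can only ever exclude mirror-closed sets of positions.
* InsP3-level peaks are not resolved into isomers (real columns do not
  resolve them either); the terminal assignment of the monophosphate rests
  on the 2-phosphate-retention argument, not on chromatography.
* The shared-enzyme competition law is a modelling convenience, not a
  mechanistic claim; fitted attack weights are defined relative to the
  first-order law.
* No attempt is made at retention-time prediction, U-loop boundary
  detection (which needs a curated alignment), or signal-peptide calling.
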