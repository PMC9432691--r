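# inospho

Tools for characterising the **positional specificity of phytases** — the
enzymes that strip phosphate groups from phytate (*myo*-inositol
hexakisphosphate, InsP6) — from the kind of evidence a wet lab actually
produces: anion-exchange HPLC product profiles on achiral columns,
phosphate-release assays, and a stereospecific-kinase discrimination assay.
The package grew out of the analysis style used to characterise bacterial
MINPP-class phytases (Multiple Inositol Polyphosphate Phosphatases), which
attack several ring positions at once and so need more than a single
"3-phytase / 6-phytase" label.

## The problem

The six carbons of the *myo*-inositol ring are numbered 1–6; position 2
carries the ring's only axial substituent. The ring has one mirror symmetry
relevant to phosphorylation patterns: the reflection through C2 and C5,
exchanging 1↔3 and 4↔6. Two patterns related by this reflection are
**enantiomers**; a self-mirror pattern is **meso**. D- and L-numbering run in
opposite directions, so 1D-6 = 1L-4.

Achiral HPLC cannot separate enantiomers: removal of the 4- or the
6-phosphate from InsP6 yields the *same* peak (the D/L-Ins(1,2,3,4,5)P5
pair). Inferring where a phytase attacks therefore takes three steps, all
implemented here:

1. **Exclusion** — a position whose removal product class never appears is
   not attacked (e.g. absence of Ins(1,3,4,5,6)P5 ⇒ the axial 2-phosphate is
   spared).
2. **Ranking** — first-generation peak shares rank the attack positions,
   with enantiomer pairs left unresolved ({4,6}, {1,3}).
3. **Enantiodiscrimination** — a kinase known to pyrophosphorylate only one
   member of the pair (e.g. D-Ins(1,2,3,4,5)P5 but not D-Ins(1,2,3,5,6)P5)
   resolves the top pair. Positive evidence confirms one enantiomer present
   but never excludes its mirror partner — a mixture cannot be discounted.

Around this core the package provides:

* complete stereoisomer enumeration, meso/enantiomer classification,
  canonical D/L naming and co-elution class tables (2⁶ = 64 states; 16 meso);
* a degradation-network builder and simulator (one node per phosphorylation
  pattern, one edge per single-phosphate removal, stiff ODE integration
  with exact phosphate accounting), plus least-squares recovery of
  per-position attack weights from class-level peak areas — correct up to
  the inherent mirror degeneracy of achiral data;
* substrate-inhibition kinetics, v = V·S / (K<sub>m</sub> + S(1 + S/K<sub>i</sub>)),
  with multi-start nonlinear least squares and the derived optimum
  S<sub>opt</sub> = √(K<sub>m</sub>K<sub>i</sub>);
* molybdenum-blue phosphate calibration and specific activity (1 U = 1 µmol
  P<sub>i</sub>/min), pH/thermal/storage profiles, inhibition-panel ranking;
* qPCR relative expression by 2^−ΔΔCt with exact Mann–Whitney testing and a
  MAD outlier rule;
* FASTA I/O, degenerate motif scanning for histidine-acid-phytase/MINPP
  signatures (RHGxRx[PL], HD/HAE, PMAAN, LYNE, DAA[AM]), theoretical
  protein mass, and the 5 Å ligand-pocket residue rule on PDB coordinates;
* seeded synthetic-data generators for every stage, each emitting a truth
  sidecar so recovery is testable end to end.

## Worked example

```r
library(inospho)
res <- run_pipeline(run_config(seed = 7))
print(res)
```

```
Pipeline run (seed 7, config 18ffea1d)
stages: specificity, kinetics, expression, motifs

Positional-specificity call
  excluded positions: 2
  ranked initial attacks:
    D6       share 0.758
    D5       share 0.125
    D1/D3    share 0.117
  enantiomer status: resolved_D
  note: conversion 0.120 >= threshold 0.050: D-Ins(1,2,3,4,5)P5 confirmed present; the mirror partner D-Ins(1,2,3,5,6)P5 is NOT excluded (a mixture cannot be discounted)
  note: top attack pair {4,6} resolved to D6; D4 attack cannot be discounted

Substrate-inhibition kinetics fit: v = Vmax*S/(Km + S(1 + S/Ki))
  Vmax = 228 U/mg (SE 0)
  Km   = 0.65 mM   (SE 0)
  Ki   = 2.23 mM   (SE 0)
  S_opt = sqrt(Km*Ki) = 1.204 mM; v(S_opt) = 109.6 U/mg
  RSS = 0 on 12 points
...
Motif classification: MINPP_like (6 hits; theoretical mass 58.57 kDa)
```

Reading the call: the simulated enzyme never removes the axial 2-phosphate
(its product class is absent at every timepoint); about 73% of initial
attacks land on the 4/6 enantiotopic pair, which the kinase evidence
resolves to the D-6 position (about 76% of attacks in this seeded run);
attacks at 5 and at the 1/3 pair are minor activities. The kinetics stage regenerates rate data from the
substrate-inhibition law and recovers the parameters; with the noise turned
off (as in this config's default) recovery is exact.

Lower-level functions do the same work piecewise — see
`?gen_peak_table`, `?exclude_by_absence`, `?rank_initial_attack`,
`?enantio_disambiguate`, `?fit_preferences`, `?fit_substrate_inhibition`,
`?expression_analysis`, `?scan_motifs`, `?pocket_residues`.
A thin command-line wrapper lives at `inst/cli/inospho.R`.

## Vignette

`vignettes/phytase-specificity.Rmd` documents the model and its
assumptions, the mirror-degeneracy argument, parameter defaults and
numerical choices, and what the synthetic generators do and do not emulate.
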