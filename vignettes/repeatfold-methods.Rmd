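---
title: "Auditing structure predictions of perfect tandem repeats: methods and design"
author: "repeatfold"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing structure predictions of perfect tandem repeats: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repeatfold)
```

## The problem

Deep-learning structure predictors sometimes return highly confident
β-solenoid models for artificial, perfectly repetitive protein sequences that
have no homologues and, on inspection, implausible structural features:
same-sign charged residues stacked inside the core, hydrophobic side chains
spread over the surface, steric clashes, and residue environments that a
3D/1D compatibility profile scores poorly. `repeatfold` packages the full
desk-scale protocol for probing this behaviour:

1. **Design** repeat sequences from secondary-structure propensity pools.
2. **Forge** synthetic β-solenoid / α-helix / coil models with controlled,
   injectable defects (so the audit can be validated without running any
   predictor), or **ingest** real predictor output (PDB/mmCIF with pLDDT in
   the B-factor column).
3. **Audit** each model: SASA and burial, secondary structure, 3D/1D
   environment profile with the categorical 80 %/0.1 rule, buried
   charged-stack detection, exposed hydrophobics, clash counting, geometric
   fold classification, disorder flagging, and the "problematic" rule
   (confident pLDDT yet poor 3D/1D score or an uncompensated internal
   charged stack).
4. **Compare** models across prediction ranks and methods (Kabsch RMSD,
   TM-score).

## Sequence design

Residues are grouped into three propensity pools — β-favouring
(C, F, I, T, V, W, Y), α-favouring (A, E, K, M, Q, R, L) and neutral
(G, N, D, P, H, S). A repeat unit is drawn uniformly with replacement from
the union of the selected pools and concatenated (10 copies by default).
The expanded design crosses unit lengths 5–30 with the `beta`, `alpha+beta`
and `all` schemes (78 sequences); the preliminary design holds 31 random
20-residue-unit sequences (2 α + 3 β + 2 neutral + 3 of each two-pool
combination + 15 all-pool) plus 19 alanine-mutant slots. The design does not
fix which positions the 19 mutants alter, so mutant slots are abstract and
`alanine_mutant()` requires an explicit (parent, unit position) pair whose
residue is aromatic or charged (histidine counts as charged here; it is also
treated as positively charged in the audit, configurably, because His
participates in clashing charged stacks).

Sampling across pools is uniform because no weighting between pools is part
of the protocol; a cohort seed derives per-sequence seeds (`seed + index`)
so cohorts are exactly reproducible. Mean helix/sheet propensities use the
Chou–Fasman scale by default (the propensity grouping's original values are
not fixed by the protocol; Chou–Fasman is on the conventional scale where
values near 1.3 mean strongly favouring, and the table is a loadable TSV so
alternatives can be swapped in).

Because the external repeat-detection score (RADAR) is out of scope, the
package carries a native `repeat_perfection()` metric — mean column-wise
identity across copies — which is 1.0 for the perfect tandems generated
here; the length-normalized external score convention (score / unit length,
near-perfect above 7.0) is still exposed via `normalize_repeat_score()` /
`is_near_perfect()` for sequences scored externally.

## The synthetic forge

`build_solenoid()` places one residue per position on a helical path whose
cross-section repeats every rung: consecutive Cα atoms are exactly 3.8 Å
apart, and residue *i* sits exactly `rise_per_rung` (default 4.8 Å) above
residue *i − L*. The cross-section is found by an equal-chord shooting
construction: chord steps are marched around a closed convex boundary and
the boundary scale solved so the loop closes after exactly *L* steps.

The default cross-section (`n_sides = 2`) is a *stadium* (flattened oval):
two straight β-sheet walls joined by semicircular caps, with inward side
chains from opposite walls interdigitating across a packed core. This is
the flattened two-sheet architecture common among natural β-solenoids, and
— unlike a hollow polygonal tube — it actually buries inward side chains,
which the charged-stack detector requires. `n_sides ≥ 3` gives rounded
regular-polygon cross-sections; units too short to span the stadium caps
fall back to a circular cross-section automatically.

Residues are reduced to backbone N, Cα, C, O plus Cβ and one terminal
side-chain pseudo-atom (charge centre for D/E/K/R/H, ring centroid for
F/W/Y, functional-group centre otherwise; glycine has none, alanine Cβ
only). The pseudo-atoms represent whole chemical groups and carry
united-group SASA radii (≈2–2.7 Å); clash counting always uses plain
element radii so the enlarged SASA spheres cannot create spurious clashes.
Inward side chains stop at a clearance floor above the core plane (1.6 Å on
the parallel-normal stadium walls, 2.2 Å where inward normals converge in
caps and circular cross-sections), which keeps defect-free forged models
exactly clash-free.

Injections realise the audited defects geometrically: `charged_stack`
places a charged residue inward at one unit position of every rung
(consecutive charge centres one rung rise apart, far within the 7 Å linkage
default); `compensating_counter_charge` adds an opposite charge whose
centre is pulled to ~3.2 Å of the nearest stack member (inside the 4.5 Å
salt-bridge radius, outside clash range); `surface_hydrophobic` points a
hydrophobic residue outward in every rung; `clash` displaces successive-rung
side-chain tips pairwise into van der Waals overlap.

Decoys: `build_helix()` is an ideal α-helix (1.5 Å rise, 100° twist per
residue, side chains radial); `build_coil()` is a seeded self-avoiding
persistent random walk with 3.8 Å steps. The walk enforces a 5.2 Å floor
between non-adjacent Cα atoms — comfortably above the 4.5 Å contract — so
that the reduced backbones built around the trace rarely brush each other.

pLDDT annotation emulates the predictor dialects: `residue_bfactor`
(AF2-style, one value per residue on all its atoms) and `atomic_bfactor`
(AF3-style, per-atom values jittered ±2 around the residue value). The
atomic jitter is seeded and mean-preserving (the atom mean equals the
profile value exactly), so the atom→residue→model averaging path is
exercised deterministically. pLDDT scales are normalized by
`normalize_plddt_scale()`: inputs with a maximum ≤ 1 are treated as 0–1
scale output (RFAA-style) and multiplied by 100; the operation is
idempotent.

## The audit

**SASA.** Shrake–Rupley sampling with a deterministic golden-spiral point
set (960 points, probe 1.4 Å). Relative SASA divides by the same quantity
computed for the residue extracted in isolation; this representation-
adaptive reference works identically for reduced forged models and
full-atom predictor files (a fixed full-atom Gly-X-Gly maxima table is
available via `reference = "gxg"`). Burial decisions throughout the audit
use *side-chain* relative SASA: in a solenoid wall every residue's backbone
outer face touches solvent, so whole-residue accessibility can never reach
a buried cutoff even when the side chain is fully packed — and side-chain
accessibility is what environment-profile burial actually means. The
implementation was checked against an independent Shrake–Rupley
implementation (Biopython's) on a fixture with identical radii; the frozen
reference values live in the test suite.

**Secondary structure** is assigned from Cα geometry alone, so it works
without a full backbone: helix by the classical short-range distance
windows (d(i,i+2) ≈ 5.4 Å, d(i,i+3) ≈ 5.0–5.3 Å, d(i,i+4) ≈ 6.2 Å);
strand by local extension (d(i−1,i+1) ≥ 5 Å) *plus* a cross-strand register
partner — another Cα at sequence separation ≥ 4 within 4.2–5.7 Å, which in
a solenoid is the equivalent residue one rung up or down. The partner
requirement stops isolated extended stretches and coils from counting as
sheet. It presumes sheet-like rung spacing (≈4.2–5.7 Å); solenoids forged
with much larger rises would need the window widened.

**Environment classes.** Six burial classes crossed with three secondary-
structure states give the 18 classes of the 3D/1D profile: exposed
(side-chain rel-SASA > 0.40), partially buried (0.15–0.40; `P1`/`P2` split
at surrounding polar fraction 0.67) and buried (≤ 0.15; `B1` < 0.45,
`B2` < 0.58, `B3` ≥ 0.58 polar fraction). The polar fraction counts N/O
atoms among other residues' atoms within 6 Å of the side-chain centroid.
The cutoffs are config defaults: 0.15/0.40 are conventional buried/exposed
boundaries and the polar splits mirror the published 3D/1D environment
scheme's increasing-polarity subclasses.

**The score table.** The profile method needs a 20 × 18 compatibility
table. The published server's internal table is not available, so the
shipped default (`default_3d1d_table()`, also as TSV under `inst/extdata/`)
is generated from a documented closed-form heuristic: agreement between
residue hydropathy (Kyte–Doolittle, rescaled) and class burial, agreement
between residue polarity and surrounding polarity, a Chou–Fasman
secondary-structure term, and a −0.5 penalty for charged residues buried in
apolar surroundings. It reproduces the qualitative structure that matters
for the audit — buried charge strongly negative, exposed hydrophobics
negative, matched environments ≈0.2–0.6 — and every test that touches
3D/1D scoring feeds fixtures with known raw scores, so no result depends on
the table's exact numbers. Custom tables load via `read_3d1d_table()`.

**Profile and categorical rule.** Raw per-residue scores are smoothed with
a centred moving average (window 21, the conventional profile window;
truncated at the termini), the model mean is the mean of smoothed scores,
and the categorical failure fires when fewer than 80 % of residues reach
0.1. Whether the model mean should average raw or smoothed scores is
ambiguous in the source protocol; smoothed is used (for constant profiles
the two coincide).

**Charged stacks.** Same-sign charged residues (D/E negative, K/R and
optionally H positive) occupying the same unit position in consecutive
rungs are linked while consecutive charge centres are within 7 Å. A linked
run is a stack when it has ≥ 3 members and at least 3 of them are buried
(side-chain rel-SASA ≤ 0.15). Burial is a quorum rather than a per-member
requirement because the terminal rungs of any solenoid are genuinely
part-exposed while the physical feature — as seen in predictor output —
spans the full model; all linked members are reported. A stack is
compensated when any member has an opposite-sign charge centre within
4.5 Å (salt-bridge range). On the forged truth cohort the detector's
margins are wide: injected members sit one rung rise (4.8 Å) apart against
a 7 Å linkage cutoff, and interior members score ≤ 0.1 rel-SASA against
the 0.15 burial cutoff.

**Fold classification** is geometric: `beta_solenoid` needs rung
periodicity (median |Cα_i − Cα_{i+L}| in 4.0–7.0 Å, coefficient of
variation < 0.25) plus ≥ 25 % strand; `alpha_helical` needs ≥ 60 % helix
and a principal-axis extent ≥ 1.1 Å per residue (ideal helix: 1.5);
`none` means no secondary-structure class reaches 25 % and the rung test
fails (disorder); anything else is `other`. All criteria are internal
distances or fractions, so the classification is rigid-motion invariant.

**The problematic rule.** A model is problematic iff mean pLDDT > 70 *and*
(mean 3D/1D < 0.1 *or* an uncompensated internal charged stack is present).
The rule is monotone in the expected directions and is exercised on an
exhaustive boundary grid in the tests.

## Model comparison

`kabsch_superpose()` is a single-pass SVD Kabsch solution (proper rotation,
no outlier-rejection cycles, inputs unmodified), matching the
superposition-only settings used when comparing prediction ranks; the test
suite checks it against an independent quaternion-method oracle at 1e-8.
Rank and method comparisons are Cα-only with identity correspondence —
sequences are identical by construction, and a guard rejects mismatched
sequences rather than aligning them. Cα-only keeps the comparison
independent of side-chain representation, at the price of small numerical
differences from all-atom tools.

`tm_score()` uses d0(L) = 1.24·(L−15)^⅓ − 1.8 floored at 0.5 Å (the floor
is active for all L ≤ 21, e.g. the raw value 0.320 at L = 20), seeds the
superposition search on sliding fragments of lengths L, L/2 and L/4
(half-length steps) and refines each seed by re-superposing on residues
within max(d0, 3.5) Å until membership stabilises (≤ 20 iterations). The
full-length superposition is always a seed, so the search can only improve
on it. TM > 0.5 is reported as a significant (same-fold) match.

## The truth cohort and what passing means

`default_truth_config()` describes a 31-model cohort: clean solenoids,
solenoids with uncompensated stacks (confident and low-confidence),
compensated stacks, clash and surface-hydrophobic injections, ideal
helices and coils, across unit lengths 5–20, eight rungs, both pLDDT
dialects and both file formats. Sequences are designed, not arbitrary:
clean solenoids alternate a hydrophobic core (V/I/L/F inward) with a polar
surface (S/T/N/Q/G outward); helix decoys draw from E/K/Q/R only, because
an exposed alanine-rich surface scores as mildly hydrophobic and would blur
an otherwise clean decoy's label; when a stack is injected, the inward
position facing it across the core is set to phenylalanine so the stack is
packed against the opposite wall, as buried charges in real solenoid cores
are — with a short-side-chain draw there, interior members hover just above
the burial cutoff. Compensated-stack entries use units of ≥ 16 residues so
two charged positions do not dominate the 3D/1D mean of a small unit.

Against this cohort the audit achieves 100 % stack recall with zero false
positives, 100 % fold-class agreement, exact recovery of the injected
problematic fraction, and byte-identical reports on repeated runs; the
forge/audit pair runs in well under a minute on one CPU (problem sizes:
31 models of 40–160 residues; the test grid uses unit lengths {5, 12, 20,
30} × {4, 10} rungs).

Passing on forged models shows the *diagnostics* are correct, not that real
predictor output behaves any particular way: the forge emulates idealised
geometry (exact rises, pseudo side chains, constant pLDDT profiles), not a
predictor's output distribution, hydrogen bonding, or side-chain rotamers.
Statistics that require running AF2/AF3/ESMFold/RFAA (cohort-level fold
fractions of real predictions, cross-method pLDDT gaps, specific RMSD
values) are outside what this package can reproduce; it provides the
instruments to compute them when such output is supplied.

## Numerical choices and degenerate inputs

* Kabsch requires ≥ 3 non-collinear points; collinear sets error.
* TM-score normalization length must be ≥ 3; d0 floored at 0.5 Å.
* Secondary structure for chains of < 5 residues is all coil.
* `classify_fold()` requires at least two repeat units of residues.
* Smoothing windows must be odd; termini use truncated windows.
* The coil builder retries each step up to 200 times before failing
  (deterministically for a given seed).
* Ties: residues with missing CA fall back to atom means (warned) for
  pLDDT, and to the first atom for Cα coordinates.
* Audits share one SASA computation across all diagnostics, so a cohort
  audit is deterministic and O(models × atoms × neighbours).

## Known limitations

* The 3D/1D table is a heuristic stand-in with the right structure, not a
  statistical potential; absolute mean scores are comparable within this
  package, not to external server scores.
* Reduced side-chain geometry cannot express rotamer-level effects
  (aromatic stacking orientation, bidentate salt bridges).
* The strand detector assumes sheet-register spacing near one rung rise;
  unusual solenoid rises need the pairing window adjusted.
* Multi-chain complexes and PAE matrices are out of scope; the first
  polymer chain of the first model is audited.
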