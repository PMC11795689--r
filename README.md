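# repeatfold

Tools for probing how protein structure predictors behave on **perfect
tandem-repeat sequences** — and for auditing the plausibility of the
β-solenoid models they like to produce for them.

AlphaFold-family predictors sometimes return highly confident (pLDDT > 70)
β-solenoid models for artificial repeat sequences that have no homologues,
even when the models contain features essentially absent from real
proteins: stacks of same-sign charged residues buried in the core, exposed
hydrophobic surfaces, steric clashes, and residue environments that a
3D/1D compatibility profile scores poorly. `repeatfold` implements the full
desk-scale protocol around that observation:

* **Sequence design** (`make_unit`, `tandem`, `generate_expanded_cohort`,
  `enumerate_preliminary_design`, `alanine_mutant`): random repeat units
  drawn from secondary-structure propensity pools — β (C F I T V W Y),
  α (A E K M Q R L), neutral (G N D P H S) — concatenated into perfect
  tandems. Defaults reproduce the 78-sequence expanded design
  (unit lengths 5–30 × three pool schemes × 10 copies) and the 50-entry
  preliminary design (31 random 20-mers + 19 alanine-mutant slots).
* **Synthetic structure forge** (`build_solenoid`, `build_helix`,
  `build_coil`, `annotate_plddt`, `forge_truth_cohort`): parametric
  β-solenoids (4.8 Å rise per rung, packed two-sheet cross-section) with
  injectable defects — buried charged stacks, compensating counter-charges,
  surface hydrophobics, clashes — plus ideal-helix and disordered-coil
  decoys, annotated with AF2-style residue or AF3-style atomic pLDDT.
  Ground-truth labels ship with every forged cohort.
* **Structure I/O** (`read_structure`, `write_structure`, `residue_plddt`,
  `normalize_plddt_scale`, `mean_plddt`): PDB and mmCIF (gzip supported),
  with the predictor pLDDT conventions (residue vs atomic B-factors,
  0–1 vs 0–100 scales).
* **Plausibility audit** (`audit_model` and the individual diagnostics
  `sasa`, `assign_ss`, `profile_3d1d`, `detect_charged_stacks`,
  `detect_exposed_hydrophobics`, `count_clashes`, `classify_fold`,
  `disorder_flag`, `flag_problematic`): the categorical 3D/1D rule
  (fail when < 80 % of residues score ≥ 0.1), and the *problematic* rule —
  mean pLDDT > 70 but mean 3D/1D < 0.1 **or** an uncompensated internal
  charged stack.
* **Model comparison** (`kabsch_superpose`, `rank_model_rmsd`, `tm_score`,
  `divergence_table`): single-pass Kabsch RMSD between prediction ranks and
  TM-scores between methods, with d0(L) = 1.24·(L−15)^⅓ − 1.8 (floored at
  0.5 Å) and the TM > 0.5 same-fold convention.
* **Cohort orchestration** (`cohort_generate`, `cohort_audit`,
  `cohort_summarize`, `cohort_compare`, plus the `exec/repeatfold` CLI).

## Worked example

Generate the expanded cohort, forge a defective β-solenoid for one of its
sequences, and audit it:

```r
library(repeatfold)

seqs <- generate_expanded_cohort(seed = 1)   # 78 sequences
s <- seqs[["u20_beta"]]
s
#> repeat_sequence: 20-residue unit x 10 = 200 residues (scheme beta)
#>   unit: FCWTYYYVYFWYCTCFWWTV

round(propensity_means(s), 3)
#> mean_alpha  mean_beta
#>      0.893      1.376

m <- build_solenoid(solenoid_spec(s, injections = list(
  feature_injection("charged_stack", 4, "E"))))
audit_model(m, unit_length = 20, seq_id = "u20_beta")
#> audit: u20_beta  fold=beta_solenoid  pLDDT=90.0  3D/1D=0.030 (categorical fail)
#>   stacks=1 (uncompensated 1)  exposed hydrophobics=64  clashes=0  [PROBLEMATIC]
```

The audit recognises the fold (rung spacing 4.8 Å, all-strand), finds the
injected glutamate stack (10 members, one per rung, buried and
uncompensated), notes that a β-pool sequence forged this way carries a
hydrophobic surface, and — since the model is confident (pLDDT 90) while
its mean 3D/1D score is 0.030 — flags it *problematic*.

Compare the solenoid against an α-helix decoy of the same sequence, the
kind of disagreement seen between prediction ranks:

```r
h <- build_helix(model_sequence(m))
rank_model_rmsd(m, h, "solenoid", "helix")
#> compare solenoid vs helix: n=200 rmsd=73.64 A tm=-
round(as.numeric(tm_score(m, h)), 3)
#> [1] 0.044
```

RMSD of ~74 Å and TM 0.04 between two models of one sequence: different
folds entirely.

The same audit runs on real predictor output — pass a directory of
PDB/mmCIF files (pLDDT in the B-factor column; AF3 atomic values and RFAA
0–1 scales handled) and a manifest to `cohort_audit()`, then
`cohort_summarize()` for fold/pLDDT-band/problematic counts in
"32 of 78 (41 %)" form.

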