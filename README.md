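# coreceptor

Analysis pipeline for studying how intrinsically disordered regions (IDRs)
flanking the AUX/IAA degron shape auxin co-receptor assembly on the F-box
protein TIR1.

AUX/IAA transcriptional repressors carry a short core degron
(`VGWPP-[VI]-[RG]-x(2)-R`) that TIR1 binds with auxin as molecular glue;
the degron is flanked by disordered modules — an N-terminal stretch ending
in the conserved KR dipeptide, a linker, and a *degron tail* connecting
the degron to the folded PB1 domain. The package implements, end to end
and on seeded synthetic data with planted ground truth:

- **Sequence annotation** (`segment_domains`, `classify_disorder`,
  `hydropathy_profile`, `map_sites`): segmentation into DI / linker /
  degron / degron tail / PB1, disorder composition at the 0.4/0.6
  thresholds, Kyte-Doolittle hydropathy, lysine/ubiquitylation-site
  mapping.
- **Hydrodynamics** (`calibrate_sec`, `theoretical_rs`, `classify_fold`):
  SEC calibration and fold classification against the power-law bands
  `log10(Rs) = a + b·log10(M)` for NF / MG / PMG / IDP chains with 10%
  outer limits.
- **Binding** (`fit_one_site`, `model_total`): one-site total +
  nonspecific saturation radioligand model,
  `B(x) = Bmax·x/(Kd+x) + NS·x`, fitted by weighted Levenberg-Marquardt
  with joint or control-pinned NS.
- **Crosslinks** (`replicate_filter`, `cluster_residues`,
  `xl_to_restraints`, `tail_restraint`, `write_tbl`): replicate
  reproducibility filtering (≥2/3 kept; unanimous = solid), receptor
  residue-cluster detection, Cα–Cα distance restraints (DSBU, 30 Å
  default) and the degron-tail polymer restraint (bounds from the
  compact/disordered Stokes radii of the tail peptide), exported in the
  HADDOCK `assign` dialect.
- **Interaction space** (`scan_interaction_space`,
  `restraint_drop_curve`, `interaction_propensity`): exhaustive
  grid × rotation scan counting clash-free placements consistent with ≥k
  restraints, verified exactly against a brute-force census.
- **Energetics** (`accumulated_mean`, `equilibrated_stats`,
  `call_hotspots`, `cas_ddg`): MM-GBSA-style trajectory post-processing,
  hot-spot calling at ΔG_SC ≤ −1.0 kcal/mol, computational alanine
  scanning.
- **Synthetic data** (`gen_sequences`, `gen_binding`, `gen_xl_table`,
  `gen_toy_structures`, `gen_energy`): deterministic seeded generators
  with truth sidecars for every stage.

## Worked example

Simulate a saturation-binding experiment at the high-affinity co-receptor
(Kd = 20 nM, 10 log-spaced concentrations 1–2000 nM, triplicates, 10%
multiplicative noise) and refit it:

```r
library(coreceptor)
g <- gen_binding(1, kd_nM = 20)
fit_one_site(g$dataset)
#> <binding_fit> Kd = 19.8 nM (SE 0.986), Bmax = 1, NS = 0.000506/nM [joint, converged]
```

The fitted Kd (19.8 ± 1.0 nM) recovers the generating truth. The analysis
drivers under `analysis/` (run in order, `Rscript analysis/01_...R` …)
repeat this across the whole affinity panel and write their tables under
`results/`; stage 3 prints:

```
 complex                 kd_true kd_median rel_err_median coverage_2se
 TIR1.IAA7                    20     19.92         0.0041        0.935
 TIR1.IAA12                  200    199.69         0.0015        0.965
 TIR1.IAA7_BM3                53     53.04         0.0007        0.955
 TIR1.IAA12_BM3              143    142.28         0.0050        0.950
 TIR1.IAA12_results_text     226    224.99         0.0045        0.955
```

i.e. median recovered affinities within 0.5% of truth and ±2·SE coverage
of 93–97% over 200 simulations each. Stage 5 prints the
accessible-complex curve on the two-lobe toy geometry:

```
 n_restraints source accessible relative_drop
            0   none       6116            NA
            1     XL        872        0.8574
            2   TAIL         48        0.9450
```

— the degron-tail restraint applied last gives the sharpest relative
drop in accessible complexes, the signature of the tail pinning the PB1
body to one face of the receptor.

## Layout

```
R/                  package code (all computation lives here)
analysis/           numbered narrative drivers writing results/
scripts/acceptance.R
tests/testthat/     unit, property and end-to-end acceptance tests
vignettes/methods.Rmd   model assumptions, parameters, design choices
```
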