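---
title: "Methods: disordered-region-constrained auxin co-receptor analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disordered-region-constrained auxin co-receptor analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coreceptor)
```

# Scope and model system

AUX/IAA transcriptional repressors are recruited by the F-box protein TIR1
through a short core degron, with auxin acting as molecular glue in the
pocket beneath it. The regions flanking the degron — an N-terminal stretch
carrying the conserved KR dipeptide, a variable linker, and a disordered
degron tail connecting the degron to the folded PB1 domain — are
intrinsically disordered and modulate how the full-length repressor is
positioned on TIR1. `coreceptor` implements the computational chain used
to study this system: sequence segmentation and disorder composition,
hydrodynamic fold classification, auxin binding-affinity fitting,
crosslink-derived distance restraints including a polymer-scaling
restraint for the degron tail, an accessible-interaction-space scan, and
post-processing of effective binding free-energy tables. Every stage is
exercised on seeded synthetic fixtures with planted ground truth.

# Sequence segmentation

A sequence is split into five modules: DI (residue 1 through the first KR
dipeptide upstream of the degron), linker, core degron, degron tail and
PB1 domain. The core degron is located by the family consensus
`VGWPP-[VI]-[RG]-x(2)-R`, a 10-residue match that covers both the
canonical V/R variant and the I/G variant; the PB1 start is the first VKV
motif at or after the degron end. The motif consensus is the only
machine-checkable degron definition, so the annotated degron span is the
10-residue regex match; a configurable left extension (default 0, with 3
reproducing the 13-residue span often drawn in domain diagrams) is
available for display parity. Boundary conventions for the degron tail
differ between published figure sets (tail lengths quoted for the same
proteins vary by a handful of residues depending on where the degron is
cut); rather than reconciling them, the extension parameter exposes the
choice, and `degron_tail_length()` is always `PB1 start − degron end − 1`
under the chosen convention. First matches win for both the degron and
VKV motifs; multiple degron matches are reported in the annotation's
warning field.

Disorder classification thresholds a per-residue probability profile
(produced by any IUPred-style predictor; prediction itself is out of
scope) at 0.4 and 0.6 with the intermediate band closed on both sides, so
scores of exactly 0.4 or 0.6 are intermediate. Hydropathy uses the
Kyte-Doolittle index with a 9-residue window (the ProtScale default;
window width is a free parameter), shrinking the window at the termini so
the profile has one value per residue.

# Hydrodynamic fold classes

Stokes radii scale with molecular mass by fold-class-specific power laws,
`log10(Rs/Å) = a + b·log10(M/Da)`. The package ships the literature
coefficient sets for natively folded (a = −0.254, b = 0.369), molten
globule (−0.053, 0.334), premolten globule (−0.239, 0.392) and fully
disordered chains, with two disordered calibrations in circulation:
urea-unfolded (−0.649, 0.521, the default — the more expanded law, a
conservative outer bound for a disordered tail) and GdmCl-unfolded
(−0.549, 0.493). Classification brackets each theoretical radius with 10%
outer limits. Neighbouring bands overlap over part of the 5–100 kDa
range; a measurement falling in several bands is assigned to the nearest
band center, and all band-consistent classes are reported alongside, so
an ambiguous call is visible rather than silently resolved. SEC
calibration regresses `log10(Rs)` on elution volume (the common
log-linear form); a Kav axis is available when the void and total volumes
are known, since column reports state either convention.

# Saturation binding

Total binding follows the one-site model with a linear nonspecific
component, `B(x) = Bmax·x/(Kd + x) + NS·x`, with free ligand approximated
by added ligand (no depletion correction — receptor is at 10 nM against
ligand spanning 1–2000 nM). Two fitting modes are provided because assay
reports rarely state which was used: `joint` fits total and nonspecific
count tables simultaneously with a shared NS slope, and `pinned-ns` first
pins NS by a through-origin fit of the hot-plus-cold controls.
Scintillation-count noise is predominantly multiplicative, so the default
is relative weighting (1/fitted², applied in a second pass after an
unweighted pass); this keeps the ±2·SE intervals honest — simulation at
the study affinities gives 92–96% coverage, against ~70% unweighted at
the weakest affinities. Starting values are deterministic: Kd from the
concentration at half-maximal specific signal, NS from the control slope.
Non-convergence is reported as a flag with the last iterate, never an
exception. Curve normalization to the per-curve maximum is
presentation-only and never feeds the fit, because it destroys the Bmax
scale.

The synthetic generator mirrors the assay design: 10 log-spaced
concentrations from 1 to 2000 nM, technical triplicates, mean-one
lognormal multiplicative noise at CV = 10%, Bmax = 1 and NS = 5·10⁻⁴ per
nM so the nonspecific signal reaches the specific plateau at the top
concentration — the regime in which NS is identifiable but not dominant.
Simulate-and-refit over 200 seeds per affinity recovers medians within a
few percent at 20, 53, 143, 200 and 226 nM.

# Crosslink restraints and the degron-tail restraint

Crosslink tables (MeroX-export-like CSV) are keyed by the unordered
residue pair after construct-offset correction (expression constructs may
carry extra N-terminal residues; offsets are subtracted on load and
non-positive corrected indices flagged). Reproducibility filtering keeps
pairs found in at least `min_support` of the declared replicates (default
2, the 2-of-3 / 3-of-4 convention), labelling unanimous support `solid`
and partial support `dashed`. Receptor-side residue clusters are found by
1D single-linkage with a 30-residue gap default — large enough to bridge
adjacent leucine-rich repeats, small enough to separate patches a
solenoid-width apart. The crosslinkable-residue vocabulary (K/S/T/Y,
N-terminus — DSBU chemistry) is enforced only as a warning since spectral
identification upstream already applies it.

Each filtered inter-protein link becomes a distance restraint with a
0–30 Å Cα–Cα band: the DSBU spacer is ~12.5 Å, and side-chain plus
backbone excursions justify ~30 Å as a conservative cap; the bound is a
parameter and is logged into the restraint-file header. The degron tail
contributes one additional restraint: treating the tail as a peptide of
`length × 110 Da`, its theoretical Stokes radii in the compact (NF) and
fully disordered (IDP) states give the lower and upper bounds, scaled by
a geometry factor (default 2, end-to-end distance ≈ twice the
hydrodynamic radius for a coil). For peptides under ~4 residues the two
laws cross (they are calibrated on proteins, not short peptides), so the
bounds are the ordered pair of the two predictions. Restraints are
exported in the HADDOCK `assign` dialect with `d = upper`,
`dminus = upper − lower`, `dplus = 0`, sorted for byte-stable output.

# Accessible interaction space

The scan enumerates rigid placements of a ligand body around a receptor
body: ligand centers on a cubic grid anchored to the receptor bounding
box (padding = ligand radius + clash distance + the largest restraint
upper bound) crossed with a deterministic super-Fibonacci rotation set
(identity when one rotation is requested). A placement is accessible when
every inter-body bead distance is at least the clash distance (default
3 Å); for each accessible placement the number of satisfied restraints is
counted, giving `counts[k]`, the number of placements consistent with at
least k restraints. This is a deliberately coarse re-implementation of
the accessible-interaction-space idea with defaults grid 2 Å / 576
rotations: its correctness is anchored to a naive brute-force census over
the identical placement set (exact equality on all toy fixtures), not to
any FFT-accelerated reference, and absolute counts from such tools are
explicitly out of scope — the quantity of interest is the shape of the
counts-versus-restraints curve. On the two-lobe toy geometry the curve
reproduces the qualitative signature that motivates the degron-tail
restraint: crosslink restraints alone leave both placement lobes
populated, and the tail restraint applied last produces the sharpest
relative drop. Interaction propensity counts, over placements satisfying
all restraints, how often each receptor residue is contacted (any ligand
bead within 5 Å), normalized to mean 1 over contacted residues; residues
strictly above 1 form the active set, so a perfectly symmetric geometry
yields an empty set by construction.

# Energetics post-processing

Effective binding free-energy trajectories (20 ns productive window
sampled every 10 ps, hence 2000 frames) are consumed as tables; the
energy evaluation itself (MM-GBSA) is upstream and out of scope. The
accumulated mean is the running average; equilibrated statistics use
frames at or after t_eq (default 10 ns, inclusive). Frames are treated as
independent for the default SEM since no autocorrelation correction is
specified for this protocol; a block-averaging SEM (block length a
parameter) is provided for honest uncertainty under serial correlation.
Group selection takes the lowest equilibrated mean, breaking ties by
input order with a warning. Hot-spots are residues with side-chain
decomposition energy ≤ −1.0 kcal/mol, threshold inclusive; alanine
scanning differences paired post-equilibration windows,
`ΔΔG = mean(mut) − mean(wt)`, with SEMs propagated in quadrature. The
synthetic trajectory is plateau + exponential transient (τ = 1.5 ns,
amplitude 15 kcal/mol) + Gaussian noise (σ = 2 kcal/mol), which
reproduces the equilibration-then-plateau shape of such series; by 10 ns
the transient is below 0.02 kcal/mol, well under the plateau SEM.

# What the synthetic data do and do not show

The generators are seeded, restore the caller's RNG state, and write
machine-readable truth sidecars; recovery tests assert exact span
recovery, exact planted-link recovery, exact census equality and
statistical recovery (within 2 SEM, or ≥ 95% selection rates) as
appropriate. They emulate the *structure* of the real inputs — motif
grammar, replicate support patterns, one-site binding with multiplicative
counting noise, equilibration transients — but not their hard parts:
spectral misidentification, heteroscedastic detector effects,
conformational averaging in SEC, autocorrelated MD frames, or the real
geometry of a leucine-rich-repeat solenoid. Passing tests therefore
demonstrate that the pipeline's logic is correct under its stated model
assumptions, not that those assumptions hold for any particular
experimental dataset. Absolute accessible-complex counts, absolute
energy magnitudes and the receptor cluster coordinates from the deposited
crosslink data require the external datasets and the original
docking/MD runs; they are covered by the property tests and by an
optional check against the public data, not by the default suite.

# Numerical choices

Problem sizes in tests and drivers are chosen for exactness and
determinism: toy scan fixtures stay below 10⁴ placements so the
brute-force census is exact; simulate-and-refit uses 200 seeds per
affinity (median stable to ~1%); group-selection recovery uses 50 seeds.
Solver tolerances are Levenberg-Marquardt defaults with a 200-iteration
cap; noiseless data are recovered to 10⁻⁶ relative. Degenerate inputs
error early and namedly: empty profiles, even hydropathy windows,
non-divisible sampling windows, collinear SEC standards, all-zero
normalization curves, zero-length tails (a tail of length 0 simply
contributes no restraint). All file writers sort their output and avoid
timestamps, so identical inputs give byte-identical files.
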