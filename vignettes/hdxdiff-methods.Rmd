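---
title: "Models and methods behind hdxdiff"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind hdxdiff}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hdxdiff)
```

hdxdiff analyses peptide-level differential hydrogen–deuterium exchange
mass spectrometry (HDX-MS) data — free versus factor-bound states of a
protein or complex — and, independently, predicts exchange from structure
and molecular-dynamics hydrogen-bond statistics so the two can be compared
head to head. This vignette is the package's account of the science: the
models, the tunable parameters and their defaults, the numerical choices,
and what the synthetic-data generator does and does not emulate.

## The exchange model

Backbone amide hydrogens exchange with solvent deuterium. For an
unstructured amide the intrinsic rate $k_{int}$ depends on the
neighbouring side chains, pD and temperature; structure slows exchange by
a protection factor $PF \ge 1$. In the EX2 limit assumed throughout, a
residue deuterates as

$$D_i(t) = 1 - \exp(-k_{int,i}\, t / PF_i),$$

and a peptide's uptake is the sum of $D_i(t)$ over its *exchanging*
residues. Residue 1 of the chain and all prolines never count; in
addition the peptide's own first residue is excluded
(`exchangeable_amides()`, convention `skip_first`), because its amide
deuterium is lost during quench and chromatography — the counting
convention behind DynamX-style "maximum uptake per peptide". A
`skip_first_two` convention is available for workflows that assume the
second amide also back-exchanges completely.

### Intrinsic rates

`intrinsic_rates()` implements the Bai–Englander reference chemistry
(poly-DL-alanine low-salt parameter set, H→D direction): acid-, base- and
water-catalysed branches with left/right side-chain inductive factors,
N-/C-terminal corrections, per-branch Arrhenius temperature factors
(14/17/19 kcal/mol), and the glass-electrode correction
$pD = pH_{read} + 0.4$ (a flag disables it). Asp/Glu are treated as
carboxylates and His as neutral — appropriate above pD ≈ 6.5; no
per-residue pKa model is attempted. The D2O autoionization constant is
anchored at pKD = 15.05 (20 °C) with a van't Hoff slope that reproduces
14.87 at 25 °C. Defaults (pH read 7.9, 298.15 K) are the labeling
conditions of a Tris buffer at room temperature; every run records pD and
temperature in its output attributes. Rates are in min⁻¹; exposure times
are stored in seconds and converted at the point of use.

## The experimental pipeline

1. **Reading** (`read_uptake_table()`): canonical CSV or DynamX
   state-data layout (exposure minutes → seconds; uptake never rescaled).
   A `col_map` argument tolerates renamed columns in file variants.
   Tables are explicitly *uncorrected* on read; correction state is a
   provenance attribute, so a table always knows what has been done to it.
2. **Back-exchange correction** (`correct_backexchange()`): a template
   peptide assumed fully exchanged at its plateau gives
   $be = 1 - D_{template}/N_{exch}$; all uptakes and SDs are divided by
   $1 - be$. The default plateau is the last timepoint — on a 2-minute
   schedule a fitted plateau is unstable for fast templates — with a
   fitted option. If no template is named, the peptide closest to full
   exchange (largest uptake/$N_{exch}$, at least 3 exchangeable amides)
   is picked; note that this auto-pick maximises an observed ratio and is
   therefore slightly optimistic under noise — a designated template, as
   used in practice, is preferable.
3. **Kinetic fitting** (`fit_uptake()`): weighted least squares of
   $D(t) = A(1 - e^{-kt})$ per peptide and state, weights $1/\sigma^2$
   (unit where $\sigma = 0$), bounds $A \in [0, 1.2\,N_{exch}]$,
   $k \in (0, 10]$ s⁻¹, initialised at the maximum observed uptake and
   the reciprocal median nonzero timepoint. The t = 0 control is kept in
   the fit with its measured SD; it anchors the baseline.
4. **Differencing and calling** (`diff_uptake()`,
   `classify_significance()`): $\Delta D = A_{bound} - A_{free}$ with
   quadrature SD; a peptide is `protected` when
   $\Delta D \le -\max(\delta_{min}, m\,\sigma_{\Delta D})$ and
   `deprotected` symmetrically. Defaults $\delta_{min} = 0.5$ Da, $m = 2$:
   sub-deuteron changes around 0.9 Da should be callable when replicate
   precision supports them, and both arms must agree. No multiple-testing
   correction by default; a Benjamini–Hochberg mode is available.
5. **Overlap subtraction** (`subtract_overlaps()`): for peptide pairs
   where one span strictly contains the other and exactly one endpoint is
   shared, the overhanging region's uptake is the difference, SD
   propagated in quadrature, accepted only beyond 5 propagated SDs
   (configurable). The subtraction already removes the shared prefix, so
   the overhang's own first residue is *not* re-excluded; this is recorded
   in the result's metadata. The rule is applied per timepoint by default
   (a fitted-maximum mode can be built from the fits), and only pairwise —
   no multi-peptide least-squares deconvolution.

### Uncertainty of the fitted maximum uptake

With four timepoints, two conventional choices fail quietly. The
residual-variance covariance of the fitter has 2 degrees of freedom, so
"±3 fit-SD" intervals would miss the truth ~10% of the time; when every
point carries a replicate SD, hdxdiff instead treats those SDs as known
(absolute-sigma convention, covariance $(J^TWJ)^{-1}$). And for slow
exchangers ($k\,t_{max}$ small) the SSE surface is a curved valley along
which $A$ trades off against $k$; the local linearization understates the
plateau's real spread by large factors, which in a differential analysis
manufactures false calls. The reported `sd_A` is therefore the 1σ
half-width of the *profile likelihood* (smallest/largest $A$ at which the
$k$-profiled weighted SSE rises by 1, censored at the parameter box).
Fits with $k\,t_{max} < 0.2$ are additionally flagged
`plateau_not_reached`: their $A$ is a lower bound. Curves saturated by
the first timepoint make the Levenberg–Marquardt gradient singular at the
start; these fall back to a deterministic profile fit ($A$ is linear in
the model at fixed $k$).

## The structure/MD predictor

`classify_hbonds()` scans trajectory frames (multi-model PDB, or any
frame matrix such as one from `bio3d::read.dcd()`; a CSV flag format
decouples the pipeline from trajectory formats entirely) and marks each
non-proline backbone amide per frame as hydrogen-bonded to a protein
acceptor (backbone carbonyl O, side-chain O, His ring N; never its own
residue) and/or to a water oxygen. Criteria: N···acceptor ≤ 3.5 Å and
acceptor within 30° of the N–H axis — common MD practice, both
configurable, since published analyses rarely state their exact cutoffs.
Water is treated as an acceptor of the amide H; missing amide hydrogens
are rebuilt at ideal geometry (bisector rule, 1.01 Å) unless disabled.

The closed fraction $x_i$ (default observable: bonded to protein AND not
to water, reflecting the dual classification; `protein_only` for
sensitivity analysis) maps to a protection factor through a logistic
growth law on the log scale:

$$\ln PF_i = \frac{L}{1 + e^{-s(x_i - x_0)}},$$

with $L$ the ceiling of $\ln PF$, $x_0$ the midpoint occupancy, $s$ the
steepness, and a floor $PF \ge 1$ (protection can slow exchange, never
catalyse it). The parameters are a property of the force field, water
model and cutoffs, so the package ships the parameterised family plus
`calibrate_logistic()` rather than fixed constants: a deterministic
coarse grid (bounds $L \le \ln 10^9$, $s \le 100$, $x_0 \in [0,1]$)
refined by L-BFGS-B from the three best grid nodes (the SSE valley can be
shallow along an $L$–$x_0$ trade-off, where a single start can stall).
The default calibration target is the SSE over all nonzero timepoints —
strictly more informative than plateau values alone and better
identified; a maximum-uptake-only target is available. Predicted
per-residue deuteration then aggregates to peptides with the same
counting convention as the experimental analysis, making predicted and
measured tables directly comparable (predictions carry no back-exchange
loss and are flagged as corrected).

## SASA and correlation

`shrake_rupley()` computes per-atom solvent-accessible surface area by
probe-sphere point sampling with Bondi radii and a 1.4 Å probe. The
sampling lattice is a deterministic Fibonacci sphere, with a deterministic
golden-ratio orientation per atom: giving every atom its own orientation
decorrelates the cap-boundary counting error across atoms, so structure
totals converge much faster than with one shared lattice while remaining
exactly reproducible. The default density of 20480 points per atom was
chosen from a measured convergence curve on a 12-residue helix benchmark
so that total SASA is stable to well under 0.1% when the structure is
rigidly re-oriented (worst case 0.033% over 24 random rotations; 960
points — a common choice — leaves 0.1–0.3% orientation dependence, which
matters once SASA differences feed correlations). Coarser lattices remain
available through `n_points`.

`backbone_peptide_sasa()` sums the N, CA, C, O and amide-H atoms per
peptide (exchange happens at the amide hydrogen; drop `"H"` to exclude
it), flagging peptides with residues missing from the structure rather
than modelling them. `correlate_uptake()` reports the least-squares line
and Pearson r² over included points with an explicit exclusion list, and
`flag_outliers()` surfaces candidates by studentized residual — candidates
only: removal always remains the caller's explicit decision, mirroring
how poorly correlated peptides are reported and removed openly in
published analyses.

## The synthetic-data generator

`generate_ground_truth()` draws a random sequence (proline frequency
0.04) and a per-residue log10 PF landscape: base 3.5 with a ±1 uniform
spread, which at pD 8.3 / 25 °C places observed rates across the
resolvable-to-slow range of a 0/0.5/1/2-minute schedule — deliberately
including peptides whose plateau is not reached, because real maps have
them. A bound state differs by specified log10 PF shifts in specified
regions. `generate_peptide_map()` tiles the chain with random lengths and
overlaps and guarantees a nested same-start pair so overlap subtraction
is always exercised. `simulate_uptake()` is the forward model above plus
a global back-exchange loss and Gaussian replicate noise (default 0.1 Da,
3 replicates); means are clamped at zero as a nondeuterated control would
be. `generate_hbond_series()` draws independent Bernoulli frames per
residue. All generators are pure functions of their seed.

What the generator does *not* emulate: isotope envelopes, charge states
and centroiding; EX1 bimodality; correlated replicate error or
peptide-dependent back-exchange; autocorrelated hydrogen-bond time series
(real trajectories are not i.i.d. frames); conformational heterogeneity.
Passing tests therefore demonstrate correctness of the estimators under
the stated noise model, not robustness to every pathology of real data.

## Degenerate inputs and tie-breaks

All-zero curves fit to $A = 0$ and are flagged `degenerate`; tables with
fewer than three distinct timepoints, or without the t = 0 control, are
errors. Identical spans in overlap subtraction are skipped (zero-length
overhang). Peptides present in one state only, or with non-finite fit
uncertainty, are dropped from differencing with a message. Residues
absent from a protection profile are treated as unprotected (PF = 1).
Painted structure maps round B-factors to the 2-decimal PDB field and use
a −1.00 sentinel for unmapped residues. Written tables print numerics at
17 significant digits so a write/read round trip is bit-identical.

## Problem sizes used in the checks

The package's verification suite runs entirely on synthetic data at desk
scale: 1000-seed Monte-Carlo coverage of the exponential fit, 500-seed
null (free = bound) calling rate at default thresholds, 100 random maps
against a brute-force overlap oracle, 20 random pentapeptides against an
independent rate oracle, 2000-frame hydrogen-bond series for calibration
recovery, and a 12-residue helix for SASA invariance — a few minutes in
total on one CPU.
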