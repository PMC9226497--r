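# hdxdiff

Differential hydrogen–deuterium exchange mass spectrometry (HDX-MS)
analysis, plus a structure/MD-based exchange predictor, for R.

HDX-MS reads out protein structure and dynamics through the exchange of
backbone amide hydrogens with solvent deuterium: peptides from protected,
hydrogen-bonded regions take up deuterium slowly, exposed ones quickly.
Comparing a protein free and bound to a partner localises binding
interfaces and allosteric changes peptide by peptide. hdxdiff is aimed at
structural biologists and mass-spectrometry practitioners who have
peptide-level uptake tables (e.g. DynamX state data) for two states and
want a reproducible, scriptable path from raw uptake to significance
calls painted on a structure — and, on the computational side, at
modellers who want to predict deuteration from MD hydrogen-bond
statistics and compare it with experiment.

## What it computes

**Experimental pipeline.** Uptake tables are corrected for back-exchange
against a template peptide assumed fully exchanged at its plateau
(`be = 1 − D_template/N_exch`); each peptide time course is fitted by
weighted least squares to a single exponential

> D(t) = A·(1 − e^(−k·t)),

whose plateau *A* (maximum uptake, in deuterons) is the unit of
comparison between states. The difference ΔD = A_bound − A_free, with
uncertainty propagated in quadrature from profile-likelihood fit SDs, is
classified as `protected` / `deprotected` when both |ΔD| ≥ 0.5 Da and
|ΔD| ≥ 2·σ_ΔD (defaults; configurable). Overlapping peptides sharing one
endpoint are subtracted to resolve overhanging regions, accepted when the
difference exceeds 5× its propagated uncertainty.

**Prediction pipeline.** Per-frame backbone-amide hydrogen bonds
(protein vs water) from a trajectory give each residue a closed fraction
x; a logistic growth law ln PF = L / (1 + e^(−s(x − x₀))) converts it to
a protection factor; Bai–Englander intrinsic rates k_int (sequence, pD,
temperature) then yield predicted deuteration D_i(t) = 1 −
exp(−k_int·t/PF), aggregated to peptides for head-to-head comparison and
correlation (r²) with experiment, alongside Shrake–Rupley backbone SASA.

A synthetic-data generator (ground-truth protection landscapes, peptide
maps, uptake kinetics with replicate noise and back-exchange, Bernoulli
hydrogen-bond series) makes every stage testable end to end.

## Worked example

Simulate a 60-residue protein whose bound state is 10^1.5-fold more
protected across residues 20–35, then run the full differential analysis:

```r
library(hdxdiff)

gt  <- generate_ground_truth(60, delta_regions = list(c(20, 35, 1.5)), seed = 42)
map <- generate_peptide_map(60, seed = 42)
tbl <- simulate_uptake(gt, map, noise_sd = 0.05, seed = 42)

run <- run_differential(tbl, template = NA)  # simulated loss-free: skip correction
run
#> <hdx_differential_run> 7 peptides, 3 significant call(s)

dplyr::select(run$diffs, start, end, A_free, A_bound, delta_D, sd_delta_D, class)
#> # A tibble: 7 × 7
#>   start   end A_free A_bound delta_D sd_delta_D class
#>   <int> <int>  <dbl>   <dbl>   <dbl>      <dbl> <fct>
#> 1     1    14  11.6    11.5  -0.153      0.0698 not_significant
#> 2    13    19   4.48    4.55  0.0720     0.0648 not_significant
#> 3    13    25   9.39    6.61 -2.78       0.0555 protected
#> 4    23    34   8.16    4.32 -3.84       0.709  protected
#> 5    31    41   8.14    6.05 -2.09       0.0464 protected
#> 6    38    51  11.4    11.6   0.206      0.0561 not_significant
#> 7    49    60   8.33    8.06 -0.274      0.0601 not_significant
```

The three peptides overlapping the planted region lose 2–4 deuterons on
binding and are called `protected`; everything outside stays within the
0.5-deuteron / 2σ thresholds. `plot_woods(run$diffs)` draws the
corresponding Woods plot, `run$overhangs` holds the overlap-subtracted
overhang uptakes (here, region 20–25 resolved at ~5 deuterons from a
nested peptide pair), and `write_residue_map_pdb()` paints `run$residue_map`
onto a structure's B-factors for molecular viewers.

On the prediction side, `run_predict()` chains
`classify_hbonds()` → `compute_protection()` → `intrinsic_rates()` →
`predict_residue_uptake()` → `aggregate_to_peptides()` and, given an
experimental table, correlates predicted against observed uptake
(`calibrate_logistic()` fits L, x₀, s when they are unknown).

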