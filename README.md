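# csptitr

Chemical-shift-perturbation (CSP) titration analysis for protein-observed
NMR binding studies.

When a ligand binds a ¹⁵N-labelled protein in fast exchange, each backbone
amide cross peak in the 2D ¹H-¹⁵N HSQC spectrum moves continuously from
its free toward its bound position as ligand is added. This package turns
a series of peak lists from such a titration into (i) a per-residue map of
which surface of the protein responds, and (ii) a dissociation constant.
It was built for the kind of study that maps a lipid-binding surface
groove on a Sec14/CRAL-TRIO domain and measures micromolar
lysophospholipid affinities, but applies to any single-site fast-exchange
titration at NMR concentrations.

## What it computes

* **Combined CSP** per residue,
  Δδ = √(Δδ_H² + (α·Δδ_N)²), with the ¹⁵N scaling factor α = 0.154, and
  σ-threshold classification of significant residues (both the
  `mean + kσ` and the pure `kσ` readings of the threshold are available).
* **Peak tracking** across titration points by mutual-nearest-neighbour
  chaining in the scaled metric, with velocity prediction and a
  straight-line-trajectory repair step that resolves peak crossings;
  overlap flagging; assignment transfer between related constructs.
* **K_D estimation** by nonlinear least squares on the exact
  ligand-depletion (quadratic) isotherm

  Δδ_obs/Δδ_max = [(K_D+L_t+P_t) − √((K_D+L_t+P_t)² − 4·L_t·P_t)] / (2·P_t),

  fit per reporter residue and pooled as mean ± SD over reporters (or,
  alternatively, as a shared-K_D global fit), via `fit_binding()`, which
  returns a classed model object with `print`, `summary`, `coef`,
  `predict`, `plot`, `residuals` and `simulate` methods.
* **Structure mapping**: CSPs painted into the B-factor field of a
  PDB/mmCIF model, multi-chain Cα superposition statistics (Kabsch), and
  a permutation test for spatial clustering of the significant residues.
* **Synthetic titrations** with full ground truth (`default_scenario()`,
  `simulate_titration()`): 160 assignable amides at 0.4 mM protein,
  12-point schedules, planted binders, positional noise, unassigned
  clusters and a crowded decoy region — so every stage of the pipeline is
  verifiable without experimental data.

Readers/writers: Sparky-style `.list` peak lists, NMR-STAR v3
chemical-shift loops (BMRB-compatible), TSV/JSON result tables.

## Worked example

```r
library(csptitr)

truth  <- default_scenario("fc14-like", seed = 42)   # K_D 17.1 uM ground truth
series <- simulate_titration(truth)
tracks <- flag_overlap(series, track_series(series))
tab    <- classify_significance(tracks)
tab
#> <csp_table> 160 residues: mean = 0.0274 ppm, sigma = 0.0616 ppm (rule mean_plus_ksigma)
#>   ns 144 | 1sigma 5 | 2sigma 11 | unassigned 0

fit <- fit_binding(tracks, tab)
fit
#> Two-state ligand-depletion binding fit
#>   mode: per_residue_average, reporters: n = 16
#>   K_D = 15.6 +/- 5.16 uM
```

The CSP distribution has mean 0.027 ppm and σ 0.06 ppm; 11 residues
exceed the 2σ line and become, with the well-resolved 1σ residues, the
reporters of the fit. The pooled estimate 15.6 ± 5.2 μM recovers the
generating constant (17.1 μM) within its SD. `plot(fit)` draws the
normalised binding curve (mean ± SD over reporters) with the fitted
isotherm; `summary(fit)` lists per-residue K_D and Δδ_max values.

The same analysis runs end-to-end with
`run_pipeline(run_config(scenario = "fc14-like", seed = 42))`, writing
peak lists, CSP table, fit reports and a `summary.json`. For real data,
point `run_config()` at a directory of peak lists with a concentration
table, and give it a crystal structure to paint the CSPs onto. A thin
command-line wrapper lives at `inst/scripts/csp_pipeline.R`.

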