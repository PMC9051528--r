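# cxmpinn

Tracer-kinetic parameter estimation for dynamic contrast-enhanced (DCE)
myocardial perfusion imaging, with a physics-informed neural network
(PINN) estimator and the conventional pixelwise least-squares baseline it
is compared against.

Quantitative myocardial perfusion maps pixelwise concentration–time
curves to physiological parameters through the two-compartment exchange
model (2CXM):

    vp dCp/dt = Fp (C_AIF − Cp) + PS (Ce − Cp)
    ve dCe/dt = PS (Cp − Ce)
    C_myo     = vp Cp + ve Ce

with plasma flow `Fp` (ml/min/ml), fractional plasma and interstitial
volumes `vp`, `ve`, and permeability–surface area product `PS`
(ml/min/ml); `C_AIF` is the arterial input function sampled in the blood
pool. Inverting this model pixel by pixel is notoriously ill-posed:
non-linear least squares gets stuck in local optima and the parameters
are strongly correlated at clinical sampling rates.

The PINN estimator trains a small neural network `t ↦ (Cp_1..K, Ce_1..K,
C_AIF)` for all K pixels of a slice jointly, minimising

    L = (1/K) Σ_j [ wC·LC_j + wr·Lr_j + wb·Lb_j + wreg·Lreg_j ]

where `LC` fits the observed tissue curves (and the AIF), `Lr` penalises
the 2CXM residuals at random collocation times (derivatives by
forward-mode automatic differentiation through the network), `Lb`
enforces zero concentration at `t = 0`, and `Lreg` penalises negative
concentrations. The kinetic parameters are per-pixel trainables in log
space, so estimates are positive by construction. Three residual
variants are available: the compartment residuals (`"2cxm"`), the summed
tissue conservation law (`"reduced"`, which weights flow most heavily),
and both together (`"combined"`, the default and the best-performing
variant).

The package also provides:

* an exact (matrix-exponential) 2CXM forward solver, with an RK4
  cross-check path;
* a digital reference object (DRO) simulator — a 40×120×3 volume of
  noisy tissue curves tiling 144 known parameter combinations, with a
  gamma-variate AIF and per-curve SNR 17.5 — for validating estimators
  against ground truth;
* the bound-constrained L-BFGS-B pixelwise NLLS baseline;
* NMSE and SSIM map evaluation and a four-method comparison driver
  (`run_experiment()`).

The network engine (forward-mode time tangents, reverse-mode gradients
including the batch-normalisation statistics, Adam) is implemented in
RcppArmadillo; gradients are verified against finite differences in the
test suite.

## Worked example

Simulate a small DRO, estimate its parameters with the combined-residual
PINN, and score the maps against ground truth:

```r
library(cxmpinn)

dro <- simulate_dro(dro_config(
  Fp_values = c(0.5, 1.5), vp_values = 0.05,
  ve_values = 0.2, PS_values = c(0.5, 1.5),
  block = c(5, 5, 1)))
dro
#> 2CXM digital reference object
#>   volume: 10 x 5 x 2 pixels, 100 time points (dt = 0.02 min)
#>   unique parameter combinations: 4
#>   noise sigma: 0.02719 mM (seed 1)

fit <- fit_pinn(dro, variant = "combined",
                control = training_config(iterations = 10000), seed = 1)
fit
#> 2CXM fit (pinn_combined): 100 pixels
#> parameter medians:
#>     Fp     vp     ve     PS
#> 0.5660 0.0578 0.1090 0.7600

evaluate_fit(fit, dro)
#> Parameter-map evaluation (pinn_combined)
#>  parameter   nmse   ssim
#>         Fp 0.1380 0.6320
#>         vp 0.2700 0.0252
#>         ve 0.2100 0.2410
#>         PS 0.0718 0.0482
#>      Total 0.1730 0.2370
```

The printed noise level corresponds to each curve carrying SNR 17.5, and
the NMSE column scores each estimated map against the known truth
(`Fp ∈ {0.5, 1.5}`, `PS ∈ {0.5, 1.5}`): total parameter NMSE 0.17 on
this small object, with the flow map recovering the two-level block
structure (SSIM 0.63). Estimation from 100 pixels is harder than from a
full slice — the identifiability discussion in the methods vignette
explains why small pixel sets bias the flow estimates low. `plot(fit)` shows the evolution of the four loss
terms and of the volume-mean parameters over training;
`predict(fit)` returns the fitted tissue curves. `fit_nlls(dro)` runs
the baseline on the same object, and `run_experiment()` drives the full
methods-by-realisations comparison table.

Per-pixel kinetic estimates convert to blood-flow units with
`plasma_to_blood()` (haematocrit 0.45, density 1.05 g/ml by default).

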