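# regenDXA

Can the material properties of regenerate bone be estimated non-invasively?
During limb lengthening by distraction osteogenesis, new ("regenerate")
bone forms in the distraction gap and must consolidate before the external
fixator is removed; premature removal risks collapse under axial load.
`regenDXA` implements, as a tested and reusable R pipeline, the analysis
that relates dual-energy X-ray absorptiometry (DXA) measures of the
regenerate to mechanical parameters from compression testing to failure —
for biomechanics and orthopaedics researchers who have (or want to
simulate) paired densitometry and materials-testing data.

## What it computes

**Volumetric BMD from two projections.** Modelling the regenerate as an
elliptical cylinder with the AP and lateral scan widths as diameters and
the ROI height as length:

    A    = π · (w_AP / 2) · (w_LAT / 2)        cross-section, cm²
    V    = A · h                               volume, cm³
    vBMD = BMC / V                             g/cm³

with BMC, areal BMD and vBMD averaged over the two projections.

**Compression mechanics.** Load-displacement records are transformed to
stress-strain (σ = F/A, ε = d/lo) and each curve yields the modulus of
elasticity E (maximum moving-window regression slope), the 0.2 % offset
yield point (σ_y, ε_y), the ultimate failure point (σ_f, ε_f), and
strain-energy densities at yield and failure (trapezoidal integration;
post-yield energy is their difference).

**Correlation statistics.** For the 3 × 7 grid of DXA parameters (BMC,
BMD, vBMD) against mechanical parameters (E, e_Y, σ_y, ε_y, e_F, σ_f,
ε_f): Spearman rank correlation with Fisher-z 95 % confidence interval
(tanh(atanh r ± z*/√(n−3))), a two-sided p from t = r√(n−2)/√(1−r²), power
at 5 % significance, and a simple linear regression for interpolation.

**Synthetic cohorts.** A Gaussian-copula generator emulates a 41-specimen
cohort at the published moments (vBMD 0.63 ± 0.09 g/cm³, E 0.55 ± 0.235
GPa, σ_y 17.1 ± 4.55 MPa, …) with a tunable latent Spearman correlation
(default 0.5) between vBMD and the material parameters, emitting DXA
tables and bilinear load-displacement curves with known ground truth.

## Worked example

```r
library(regenDXA)

co      <- generate_cohort(cohort_config(seed = 1))     # 41 specimens
derived <- derive_dxa(co$dxa_measurements)              # vBMD per specimen
mech    <- analyze_mechanics(co$mechanical_curves, co$specimens, derived)
tab     <- build_correlation_table(derived, mech)

cohort_table(mech, derived)
#>    parameter        n    mean     sd
#>  1 BMC             41  0.271  0.104
#>  2 BMD             41  0.432  0.0988
#>  3 vBMD            41  0.641  0.0763
#>  4 E               41  0.587  0.214
#>  5 e_Y             41  0.251  0.0892
#>  6 sigma_y         41 16.1    5.21
#>  7 epsilon_y       41  0.0319 0.0117
#>  8 e_F             41  0.703  0.342
#>  9 sigma_f         41 19.9    4.03
#> 10 epsilon_f       41  0.0609 0.0393
#> 11 post_yield_e    41  0.452  0.353

tab[tab$dxa_parameter == "vBMD" &
      tab$mechanical_parameter %in% c("E", "sigma_y", "sigma_f"),
    c("mechanical_parameter", "n", "spearman_rho", "ci_low", "ci_high",
      "p_two_sided", "power")]
#>   mechanical_parameter  n spearman_rho  ci_low ci_high p_two_sided power
#> 1                    E 41        0.541  0.2796   0.727    2.62e-04 0.962
#> 2              sigma_y 41        0.616  0.3798   0.776    1.84e-05 0.993
#> 3              sigma_f 41        0.269 -0.0423   0.532    8.92e-02 0.397
```

The cohort summary recovers the generator's moments (vBMD 0.64 vs the
0.63 g/cm³ target; yield stress 16.1 vs 17.1 MPa — offset yield sits
slightly off the underlying kink); the vBMD rows show the rank correlation
with modulus and yield stress for this seed, each with its Fisher-z
interval, p-value and post-hoc power. Estimates scatter around the latent
0.5 from cohort to cohort with an SD of about 0.13 at n = 41.

The same workflow runs from the shell over CSV files (real or simulated;
any stage's input can be replaced by scanner / testing-machine exports):

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/regen-pipeline.R", package="regenDXA"))')" \
    run-all --seed 1 --out results/run1
```

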