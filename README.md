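# relkin

Release-kinetics modelling for nanocarrier drug delivery.

`relkin` analyses cumulative drug-release curves — percent of the total
load released versus time — from spherical nanocarriers such as polymer
nanoparticles and drug-loaded metal-organic frameworks (MOFs). It is aimed
at pharmaceutics and materials researchers who have a time–release table
and want mechanistic rate constants, diffusivities, and a defensible model
comparison out of it.

## The models

Three forward models for the released percentage R(t) of a sphere of
radius *r*:

1. **Exact sphere-diffusion (desorption) series**

   R(t) = 100 ( 1 − (6/π²) Σᵢ (1/i²) exp(−D i² π² t / r²) ),  i = 1, 2, …

   the classical solution of the transient diffusion equation in spherical
   coordinates, with surface diffusion coefficient *D*. Evaluated with an
   adaptive, tail-bounded truncation.

2. **Single-exponential (long-time) approximation**

   R(t) = 100 ( 1 − A e^(−k t) ),

   the first series term with amplitude *A* and rate *k* refitted freely.
   For A < 1 it starts at R(0) = 100(1 − A) > 0 and cannot reproduce the
   initial diffusion burst.

3. **Bimodal (two-population) model**

   R(t) = 100 [ φ (1 − e^(−K₁t)) + (1 − φ)(1 − e^(−K₂t)) ],

   two sub-populations of drug molecules, a fraction φ releasing fast
   (K₁) and 1 − φ releasing slowly (K₂).

Fits are unweighted least squares from a deterministic multi-start grid,
scored with the root-mean-square deviation

S = [ Σᵢ (R_model,i − R_exp,i)² / N ]^(1/2)

over the N non-trivial points (cumulative release < 99%). Fitted rate
constants convert to diffusivities through the linear driving force
relation for a sphere, K = 15 D / r² (K per day, D in m²/s).

The package also provides closed-form formulation arithmetic
(Solomon–Ciuta single-point intrinsic viscosity, Mark–Houwink–Sakurada
molecular weight, weight loss, nanoparticle yield, drug loading,
entrapment efficiency), a rigid-ellipsoid screen for whether a guest
molecule can traverse MOF pore windows and reside in cage cavities, and a
seeded synthetic-curve generator for validating the fitting pipeline.

## Worked example

Simulate a noisy 15-day release curve from the built-in MOF-composite
nanoparticle scenario (φ = 0.29, K₁ = 1.74 d⁻¹, K₂ = 0.123 d⁻¹, σ =
1.65%), then fit and rank all three models:

```r
library(relkin)

rc <- simulate_scenario("mpeg_pcl_fe_btc_ptx")
cmp <- compare_models(rc, radius = 71.5e-9)  # r = half the 143 nm DLS size
glance(cmp)
#> # A tibble: 3 × 7
#>   model       s_value n_points n_starts converged   d_fast    d_slow
#>   <chr>         <dbl>    <int>    <int> <lgl>        <dbl>     <dbl>
#> 1 bimodal        1.47       30       75 TRUE      6.56e-21  4.97e-22
#> 2 series         1.77       30        1 TRUE      6.41e-22 NA
#> 3 single_term    2.22       30       25 TRUE      5.40e-22 NA
```

The bimodal model wins (smallest S, here about the injected noise level),
and its fast/slow rate constants convert to diffusivities:

```r
fast_slow_diffusivities(cmp$fits$bimodal, radius = 71.5e-9)
#> # A tibble: 2 × 3
#>   mode   rate diffusivity
#>   <chr> <dbl>       <dbl>
#> 1 fast  1.66     6.56e-21
#> 2 slow  0.126    4.97e-22
```

i.e. a fast population diffusing at ~6.6·10⁻²¹ m²/s and a slow one an
order of magnitude below — the recovered values sit on top of the
scenario's true constants. `autoplot(cmp)` overlays the three fitted
curves on the data.

The pore-geometry screen classifies paclitaxel (triaxial ellipsoid
7.9 × 15.2 × 18.2 Å) against the built-in Fe-BTC/MIL-100(Fe) dimensions:

```r
passage_screen()
#> # A tibble: 4 × 5
#>   feature           kind   diameter_A verdict            clearance_A
#> 1 5-membered window window        7.3 MARGINALLY_BLOCKED      -0.600
#> 2 6-membered window window       10.8 PASSES_ORIENTED          2.9
#> 3 s-cage cavity     cavity       24.6 FITS                     6.4
#> 4 l-cage cavity     cavity       30.1 FITS                    11.9
```

So the drug fits in either cage but can only reach them through the
6-membered windows, and only in favourable orientations.

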