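# bivalvepop

Population-size estimation for epifaunal bivalves — blue mussels
(*Mytilus edulis*), Pacific oysters (*Magallana gigas*) and European
flat oysters (*Ostrea edulis*) — from stratified survey data and gridded
environmental covariates, by combining species distribution (occurrence)
models with conditional abundance models.

Mussel and oyster reefs filter plankton, stabilise sediment and house
other species; how much these functions matter depends on *how many*
animals there are, not just where they occur. `bivalvepop` is aimed at
coastal ecologists and managers who need defensible totals (individuals
and tonnes of biomass, with standard errors) for a stretch of coast
surveyed by camera tows and hand quadrats.

## The method

The workflow is a hurdle design over a 10 × 10 m grid masked to 0–10 m
depth:

1. **Occurrence.** A gradient-boosted tree classifier gives per-cell
   presence probabilities p̂(s). Probabilities become presences at a
   *prevalence-matched* threshold: t is chosen so the modelled
   prevalence equals the observed survey prevalence (stratified random
   sampling makes that an estimate of true prevalence).
2. **Conditional abundance.** On presence sites only, a boosted-tree
   regression predicts log density, with the averaged out-of-bag
   occurrence probability as an extra covariate. Back-transformation
   bias is corrected by a regression of observed on estimated values
   (ROE: ŷ → a + b·ŷ) followed by Duan's smearing factor
   D = mean(exp(residual)); cell counts are exp(a + b·ŷ)·D × 100 m².
3. **Validation.** Every stage runs under the bootstrap 0.632+
   estimator: B bootstrap refits scored on their own sample (apparent)
   and the omitted sites (out-of-bag), combined as
   (1−w)·apparent + w·oob′ with w = 0.632/(1 − 0.368·R) and R the
   relative overfitting rate against the no-information rate.
4. **Population totals**, three ways:
   - *Method 1*: stratified mean extrapolation, N̂ = Σ A_zs · d̄_zs over
     5 coastal zones × 4 depth strata (0–0.5, 0.5–3, 3–6, 6–10 m), with
     the classical Cochran variance;
   - *Method 2*: mean presence-site density × area predicted occupied at
     each bootstrap threshold t_b, SE by product error propagation;
   - *Method 3*: the thresholded model count map, S_b = Σ counts·[p̂ ≥ t_b],
     calibrated by the mean ratio ρ of predicted to observed individuals
     on omitted sites: N̂ = mean(S_b)/mean(ρ_b).

   Biomass is B = N̂·w̄ (tonnes) with
   SE(B) = √(N̂²·SE(w̄)² + w̄²·SE(N̂)²).

A synthetic seascape generator (`generate_seascape()`,
`generate_truth()`, `sample_sites()`) reproduces the statistical
structure this analysis assumes — autocorrelated covariate fields,
zero-one-inflated substrate covers, hurdle species truth with known
totals, ~800 sites stratified by depth and wave exposure with 16 m²
camera tows and 1 m² quadrats — so the whole pipeline is testable
end to end with no external data.

## Worked example

A mussel-like species on a 150 × 150 synthetic seascape with known
truth, surveyed at 800 sites, with `B = 25` bootstrap iterations:

```r
library(bivalvepop)

seascape <- generate_seascape(150, 150, seed = 1)
truth    <- list(mussel = generate_truth(seascape,
                                         species_defaults()$mussel, seed = 2))
survey   <- sample_sites(seascape, truth, sampling_design(), seed = 3)

run <- run_pipeline(survey, seascape, "mussel", B = 25, seed = 4,
                    weights = list(mussel = c(0.8, 0.05)))
print(run$species$mussel$occurrence)
print(run$species$mussel$abundance)
```

```
occurrence model for mussel - B = 25 bootstrap iterations
mean prevalence-matched threshold: 0.506
      metric apparent mean_oob  best
         auc    0.968    0.898 0.921
 sensitivity    0.872    0.759 0.795
 specificity    0.931    0.857 0.879
    accuracy    0.910    0.821 0.849
         tss    0.803    0.616 0.674
abundance model for mussel - B = 25 iterations
ROE a = -0.607, b = 1.219; smearing D = 1.076; mean rho = 0.899
       metric apparent mean_oob   best
 spearman_rho    0.875    0.406  0.505
    pearson_r    0.725    0.301  0.384
           r2    0.526    0.103  0.146
         rmse   27.587   37.508 32.799
```

The "best" column is the 0.632+ estimate: the honest performance after
correcting the optimism visible in the apparent column. The three
population estimates against the (here known) truth of 6.99 million
individuals:

```
Method 1 population estimate: 7.406e+06 +/- 6.4e+05 individuals
Method 2 population estimate: 7.692e+06 +/- 5.94e+05 individuals
Method 3 population estimate: 6.933e+06 +/- 1.58e+06 individuals
true total: 6993000
dry-weight biomass: 5.5 +/- 1.3 t
```

Mean extrapolation (Methods 1–2) overshoots — the survey oversamples
exposed cells where mussels are denser — while the calibrated
model-based Method 3 lands within 1 % of the truth; its biomass line
converts the total with a mean individual dry weight of 0.8 ± 0.05 g.

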