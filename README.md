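# bymlogit

Bayesian spatio-temporal multilevel logistic models for areal
patient-reported outcomes, built around the Besag–York–Mollié (BYM)
decomposition of area-level risk.

Registries of prostate-cancer surgery patients record, per patient, the
areal unit of residence (e.g. a local government area), the year of
surgery, clinical covariates, and the five EPIC-26 quality-of-life domain
scores (0–100).  `bymlogit` provides the complete small-area analysis of a
binary *poor quality of life* outcome for such data, for biostatisticians
and epidemiologists working with population-based clinical registries:

* **Outcome derivation** — cohort-quartile binning of the five domain
  scores, a composite score from 5 (worst) to 20 (best), and a
  median split (`quartile_bin()`, `composite_score()`, `median_split()`,
  `derive_poor_qol()`), with an exclusion report for incomplete scores.
* **Spatial weight matrices** — queen contiguity from polygons and
  centroid distance bands, including the smallest band leaving no area
  isolated (`queen_contiguity()`, `distance_band()`,
  `min_connecting_band()`), with GAL and GeoJSON exchange.
* **The model** — for patient *i* in area *j(i)* at centred year *t*:

  logit P(y&#7522; = 1) = α + x&#7522;ᵀβ + δ₁t&#7522; + δ₂t&#7522;² + u_{j(i)} + v_{j(i)}

  with an intrinsic CAR (ICAR) prior on the structured effect *u*
  (sum-to-zero, precision τ_u), iid Normal heterogeneity *v* (precision
  τ_v), and Normal(0, precision 0.725) coefficient priors — the precision
  that puts 95% prior odds-ratio mass in (0.1, 10).  Fitting is by a
  purpose-built adaptive Metropolis-within-Gibbs sampler (`run_mcmc()`,
  C++ core, fully seed-reproducible), with conjugate Gibbs updates for
  τ_u, τ_v.
* **Diagnostics and comparison** — Gelman–Rubin potential scale reduction
  factors (`gelman_rubin()`, `psrf_report()`) and WAIC with streaming
  pointwise log-likelihood accumulation (`waic()`, `compare_models()`,
  `sequential_waic()`).
* **Outputs** — the spatial fraction φ = var(u)/(var(u)+var(v))
  (`phi_statistic()`), observed/expected relative-risk tables by area and
  year (`rr_table()`), weight-matrix sensitivity of coefficients
  (`coefficient_percent_change()`), and prevalence crosstabs with
  chi-square tests (`crosstab_prevalence()`).
* **Synthetic registry** — a generator (`sim_config()`,
  `simulate_registry()`, `simulate_domain_scores()`) emulating the
  structure of a state-wide registry: 80 areal units, seven calendar
  years, study-matched covariate frequencies, BYM spatial structure and a
  quadratic year trend, with ~36% outcome prevalence.

## Worked example

```r
library(bymlogit)

cfg <- sim_config(seed = 1)                       # 80 areas, 5238 patients
reg <- simulate_registry(cfg)
patients <- simulate_domain_scores(reg$patients, seed = 2)

scored <- derive_poor_qol(patients)               # quartiles -> composite -> median split

Wq <- queen_contiguity(reg$areas)
Wd <- distance_band(reg$areas, min_connecting_band(reg$areas))

mc <- mcmc_config(n_iter = 10000, burn_in = 5000, thin = 2,
                  n_chains = 2, seeds = c(1, 2))
fit_q <- run_mcmc(patients, Wq, mcmc = mc)
fit_d <- run_mcmc(patients, Wd, mcmc = mc)

compare_models(list(queen = waic(fit_q), distance = waic(fit_d)))
posterior_summaries(fit_d)
phi_statistic(pooled_draws(fit_d, "u"), pooled_draws(fit_d, "v"))
```

Output (abridged):

```
median composite 15; 34.82% poor QoL
     label     waic      delta
1 distance 6366.323 0.00000000
2    queen 6366.358 0.03533668
max fixed-effect PSRF: 1.026
                         term    or lower upper
              age_group=76-85 4.119 2.889  5.88
           institution=Public 1.302 1.133  1.49
 remoteness=Highly accessible 0.753 0.555  1.03
var(u) = 0.017, var(v) = 0.285, spatial fraction = 0.06
RR range 0.00-2.87 over 558 area-year cells
```

Reading this: the outcome derivation lands the cohort median at composite
15 with ~35% labelled poor; the generating effects (public institution
OR 1.35, age 76–85 OR 2.90, highly accessible OR 0.60) sit inside or near
their 95% credible intervals at this desk-scale chain length; both weight
matrices fit this cohort almost equally (the generating spatial field here
is queen-structured and weak, so the spatial fraction is small); and the
relative-risk table spans areas with no poor patients (RR 0) up to almost
three times the expected count.

The `analysis/` directory holds the same workflow as numbered driver
scripts (`01_simulate.R` … `04_outputs.R`), each writing its tables under
`results/`.

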