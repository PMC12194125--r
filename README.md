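# trmkin

Kinetics of CD4+ tissue-resident memory T cell (TRM) maintenance,
estimated from inducible fate-reporter label timecourses.

## The problem

TRM in skin and gut lamina propria (LP) protect barrier sites, but
their persistence is governed by three entangled processes: recruitment
of new cells from precursors (fractional rate μ per day), in-situ
self-renewal (per-cell division rate ρ, mean interdivision time 1/ρ),
and loss by death, egress or differentiation (total rate δ, mean
residence time 1/δ). At steady state δ = ρ + μ. None of these is
directly observable, but dual genetic fate reporters make them
identifiable: after a tamoxifen pulse, one reporter strain (Ki67-DIVN)
permanently labels cells that were dividing (YFP), another (Cd4-FR)
labels all CD4-expressing cells (mTom). In a closed steady-state
population label *frequencies* stay constant, so any decline reveals
replacement from precursors, and combining label kinetics with
Ki67-high fractions (Ki67 persists ~3–4 days after division, decay
rate β) separates all three rates.

`trmkin` provides, for people who analyse such fate-mapping
experiments:

* the deterministic label-kinetics model — a linear ODE system for the
  four YFP × Ki67 states plus the mTom fraction, with three
  recruitment modes (quiescent, neutral, division-linked immigrant
  Ki67 status) — and its closed-form steady state;
* empirical log-odds relaxation descriptors for precursor label
  frequencies, fitted jointly with the target;
* binomial count likelihoods per mouse × channel, joint Bayesian
  estimation by MCMC, and broom-style `tidy()` / `glance()` /
  `autoplot()` accessors;
* PSIS-LOO model comparison over candidate precursors and recruitment
  modes with stacking or pseudo-BMA+ weights;
* derived quantities: residence times, interdivision times, daily
  replacement, clonal half-life ln 2/(δ − ρ), and Ki67-only
  residence-time bounds;
* a synthetic-data generator reproducing the dual-strain study design
  (31 Ki67-DIVN mice, 9-week chase; 36 Cd4-FR mice, 57-week chase) for
  parameter-recovery validation.

## Worked example

```r
library(trmkin)

# Closed-form checks from published point estimates -------------------
# skin TRM: 2%/day replacement, 7-week interdivision time,
# division-linked recruitment, 3-day Ki67-high lifetime
steady_state_ki67_fraction(
  kinetic_params(mu = 0.02, rho = 1/49, beta = 1/3,
                 mode = "division_linked"))
#> [1] 0.1542975        # the measured skin Ki67-high fraction is ~0.15

ki67_residence_bounds(k = 0.15, mu = 0.02, beta = 1/3.5)
#> # A tibble: 1 x 2
#>   lower_days upper_days
#>        <dbl>      <dbl>
#> 1       21.3       28.4  # brackets the reported 22-28 d skin range

clonal_half_life(rho = 1/49, delta = 1/24)
#> [1] 32.60564            # ~5 weeks: skin clones halve in about a month

# Simulate the dual-reporter study and re-estimate the rates ----------
d <- simulate_reporter_data("skin_trm", study_design(), seed = 1)
fit <- fit_trm_model(d, trm_config(chains = 4, warmup = 500,
                                   iter = 500, seed = 1))
summarize_posterior(fit) |>
  dplyr::filter(term %in% c("replacement_pct_per_day", "residence_days",
                            "interdivision_days", "ki67hi_duration_days"))
#> # A tibble: 4 x 6
#>   term                      map median  lo95  hi95 n_nondecaying
#>   <chr>                   <dbl>  <dbl> <dbl> <dbl>         <int>
#> 1 residence_days          24.7   24.3  23.0  25.7              0
#> 2 interdivision_days      49.7   48.3  43.8  53.8              0
#> 3 replacement_pct_per_day  2.04   2.04  1.92  2.14              0
#> 4 ki67hi_duration_days     3.02   2.98  2.79  3.16              0
```

The generating truth (μ = 0.02/day, interdivision 49 d, Ki67 lifetime
3 d, residence 24.5 d) is recovered within a few percent from one
synthetic dataset at study scale. `autoplot(fit)` overlays the MAP
trajectories on the per-mouse fractions; `compare_models()` ranks
candidate precursor/recruitment-mode combinations by PSIS-LOO weight.

See the vignette (`vignettes/trm-kinetics.Rmd`) for the model
derivation, prior choices, sampler design and the limits of what
synthetic recovery demonstrates.

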