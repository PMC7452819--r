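# dietmix

Bayesian multi-proxy diet mixing models with rank-order priors, for
trophic ecologists reconstructing consumer diets from stable isotopes
(δ13C, δ15N) and radiocarbon (Δ14C), optionally constrained by
prey-preference orderings from DNA metabarcoding.

## The model

A consumer's expected signal on proxy *j* is a concentration-weighted
convex combination of offset-shifted source signals over the unknown diet
proportions *p* on the simplex:

    mu_j = sum_i p_i w_ij (s_ij + d_ij) / sum_i p_i w_ij

with latent source signals `s_ij ~ N(S_ij, sigma_ij)` from the measured
means and SDs, trophic discrimination offsets `d_ij ~ N(Delta_j, tau_j)`
(per-mil TDFs; 0.5 ± 1‰ for δ13C, 3.46 ± 2‰ for δ15N, exactly 0 for
Δ14C), and the observed target value `T_j ~ N(mu_j, sigma_Tj)`. The prior
on *p* is a Dirichlet, truncated by strict rank constraints such as
`AM1 > AM2 > H > C` and by source exclusions (e.g. no cannibalism).
Posteriors are drawn by a Metropolis-within-Gibbs sampler (logistic-normal
random walk on the simplex, conjugate Gaussian updates for the latents,
constraint enforcement by rejection) with split-chain R-hat and ESS
diagnostics. See the vignette `vignettes/multiproxy-diet-models.Rmd` for
the full model, its assumptions, and validation against brute-force
enumeration.

The package ships a complete case study of a groundwater (calcrete
aquifer) food web — three subterranean diving beetles as consumers, two
amphipods and two copepod groups as prey — and compares four designs:
`SIA` (two proxies), `multi_proxy` (three proxies), `SIA_DNA` (two
proxies + metabarcoding priors), and `multi_factor` (three proxies +
priors). A synthetic-scenario generator with known truth supports
parameter-recovery experiments.

## Worked example

Fit the two-proxy, prior-informed design for the smallest beetle (S) on
the bundled data:

```r
library(dietmix)
built <- build_target_dataset("S", design_config("SIA_DNA"))
fit <- sample_posterior(built$dataset, built$prior_set, mcmc_settings())
summarize_posterior(fit)
```

```
 source  mean    sd median ci68_low ci68_high ci95_low ci95_high
      B  5.61  4.97   4.19     1.07     10.40     0.19     18.30
      M 17.70 11.15  15.51     7.25     28.14     2.67     45.13
    AM1 45.70 13.02  45.12    32.49     59.10    22.13     72.28
    AM2  9.97  5.45   9.27     4.40     15.64     1.69     22.06
      C  3.51  3.07   2.71     0.69      6.42     0.10     11.41
      H 17.50  7.07  17.19    10.14     24.80     5.00     32.05
```

All values are posterior percentages of diet: amphipod AM1 is the top
prey item (45.7 ± 13.0%), harpacticoids and the mid-sized sister beetle
follow, and the rank prior keeps every chain ordering (`AM1 > H > AM2 >
C`, `M > B`) satisfied in every retained draw. `compare_designs()` on a
full `run_study()` condenses the four designs into one table of mean/max
posterior SDs, top-ranked sources, and combined sister-beetle shares.

A command-line interface wraps the same functions
(`fit`, `compare-designs`, `simulate`, `recover`); see `?cli_entry`.

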