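# foidecomp

Decomposing multi-host symbiont transmission into its component parts:
contact rates, per-contact transmission success, and infestation
prevalence.

## The scientific problem

In a community where several host species share a symbiont (a parasite or
a mutualist), the force of infection (FOI) experienced by a susceptible
focal host is the sum of each host species' contribution:

    FOI_focal = Σ_i c(N_i) · v_i · (I_i / N_i)

where `c(N)` is the density-dependent contact rate, `v` the probability
that a contact transmits the symbiont, and `I/N` the probability that a
contact is with an infested individual. A host species that is abundant,
infectious, or highly infested can dominate community transmission — or a
single weak component (a transmission barrier such as strong symbiont
host preference) can neutralize it. Because the components multiply, a
field estimate of the net FOI alone cannot identify which component is
responsible; each one has to be measured.

`foidecomp` implements the three analysis stages that decompose the net
rate, for snail–oligochaete systems and structurally similar
sentinel-host designs:

1. **Multi-host FOI model** (`fit_foi`). Sentinel infestation trials
   paired with weekly density surveys are fit to

       FOI_F = β_FF · N_F^k_FF · (I_F/N_F) + β_FA · N_A^k_FA · (I_A/N_A)

   with the proportion of sentinels infested after `t` days given by
   `1 − exp(−FOI_F · t)`. The unitless exponents `k` interpolate between
   frequency-dependent (`k = 0`) and density-dependent (`k = 1`)
   transmission. A binomial trial-level likelihood is sampled under
   bounded-uniform priors (β ∈ [0, 2], k ∈ [0, 1]) with the package's
   adaptive random-walk Metropolis engine (`run_mcmc`), and the nested
   single-host model (`β_FA ≡ 0`) is compared by DIC.
2. **Holling Type II contact model** (`fit_contacts`). Container-mean
   contact counts are fit to
   `contacts = e·T·N / (1 + e·H·(N − 1))`, a saturating functional
   response in which the handling time `H` caps the contact rate at
   `T/H`; normal likelihood on container means, uniform priors
   (e ∈ [0, 1] min⁻¹, H ∈ [0, 44] min). `compare_functional_responses`
   contrasts two fits (e.g. interspecific vs intraspecific).
3. **Transmission success** (`fit_binomial_glm`, `fit_poisson_glm`,
   `dispersal_summary`, `worm_accounting`). Donor–receiver pairing
   experiments are summarized as pooled dispersal proportions with exact
   Clopper–Pearson intervals, modelled with a binomial logit GLM
   (treatment × symbiont-source interaction) and a Poisson log-link GLM
   for surviving-symbiont counts, and audited with a worm-fate table
   (donor / receiver / cup / missing).

A synthetic-data module (`gen_field_season`, `gen_contact_experiment`,
`gen_transmission_experiment`) generates datasets with the exact
statistical structure each stage assumes, from known ground truth, so
every fit is testable by parameter recovery without any field data.

## Worked example

Simulate the contact experiment at its design (densities 1–14, 16, 18;
three replicates; 45-min observations) from truth `e = 0.012`,
`H = 3.25`, and refit:

```r
library(foidecomp)
contacts <- gen_contact_experiment(seed = 11)
fit <- fit_contacts(contacts, n_iter = 8000, burn_in = 4000, seed = 12)
fit
#> posterior_chains: 3 chains x 4000 kept draws, 3 parameters
#>  parameter      point      lower      upper level
#>          e 0.01197071 0.00915093 0.01582051  0.95
#>          H 4.28758594 2.11579080 6.40264832  0.95
#>      sigma 0.84359589 0.69273801 1.05107857  0.95
#> Rhat: e=1.004, H=1.004, sigma=1.002; acceptance: 0.35, 0.32, 0.36
```

Both generating values sit inside their 95% credible intervals; the
fitted encounter rate (posterior median 0.0120 min⁻¹) says a focal snail
encounters roughly one partner per 83 minutes per unit density, and the
handling time sets a ceiling of `T/H ≈ 45/4.3 ≈ 10` contacts per 45-min
observation.

Simulate the 2×2 transmission experiment (treatment × symbiont source,
replicate counts 20/21/40/49) and analyse dispersal:

```r
reps <- gen_transmission_experiment(seed = 13)
print(dispersal_summary(reps)[, 1:7], digits = 3)
#>       treatment              source dispersed attached proportion  lower  upper
#> 1 intraspecific       focal_sourced        50      161     0.3106 0.2401 0.3882
#> 2 interspecific       focal_sourced        49       62     0.7903 0.6682 0.8834
#> 3 intraspecific alternative_sourced         6      112     0.0536 0.0199 0.1130
#> 4 interspecific alternative_sourced        14      392     0.0357 0.0197 0.0592

fit_binomial_glm(reps)
#> GLM (logit link), residual d.f. = 121, deviance = 126.22
#>                                                    estimate        se         z            p
#> (Intercept)                                      -0.7975072 0.1703203 -4.682396 2.835407e-06
#> treatmentinterspecific                            2.1243781 0.3554437  5.976693 2.277125e-09
#> sourcealternative_sourced                        -2.0741724 0.4528903 -4.579856 4.652962e-06
#> treatmentinterspecific:sourcealternative_sourced -2.5485354 0.6136081 -4.153360 3.276290e-05
```

The positive `treatmentinterspecific` coefficient (log odds ratio within
focal-sourced replicates) and the large negative interaction show the
host-preference signature: symbionts readily leave a donor of the
"wrong" species but rarely leave their own, so the treatment effect
reverses between symbiont sources.

The full pipeline (simulate → fit → report) is available as functions
(`cmd_simulate`, `cmd_fit_foi`, `cmd_fit_contacts`,
`cmd_fit_transmission`, `cmd_report`) and as a thin command-line wrapper
in `inst/scripts/foidecomp.R`.

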