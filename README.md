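# emnet

Ectomycorrhizal (EM) fungi live in symbiosis with the root tips of host
trees. `emnet` asks how the EM fungal community of a focal tree relates to
the *neighboring plant community* across forest types, and implements the
full analysis chain a root-tip amplicon study of that question needs:

- **alpha diversity** — richness, Shannon ($-\sum p_i \ln p_i$),
  Gini–Simpson ($1-\sum p_i^2$), bias-corrected Chao1
  ($S_{obs} + F_1(F_1-1)/(2(F_2+1))$), ACE;
- **beta partitioning** — pairwise and multiple-site Sørensen
  dissimilarity split into turnover and nestedness,
  $\beta_{sor} = \beta_{sim} + \beta_{sne}$;
- **signed co-occurrence networks** — Spearman $|\rho| \ge 0.6$ at
  $p \le 0.001$ (fungal) or $p \le 0.05$ (cross-kingdom), per-sample
  induced subnetworks, and a composite multi-complexity index (mean of
  z-scored node number, edge number, betweenness);
- **Zi–Pi node roles** — within-module degree z-score and participation
  coefficient $P_i = 1-\sum_m (k_{im}/k_i)^2$, thresholds 2.5 / 0.62,
  keystones = non-peripherals;
- **log response ratios** — $\ln R = \ln\bar{X}_E - \ln\bar{X}_C$ with
  $v = SD_E^2/(n_E\bar{X}_E^2) + SD_C^2/(n_C\bar{X}_C^2)$;
- **association models** — log–log diversity regressions, ANOVA +
  Duncan letters, collinearity screening ($|r| < 0.6$), interaction
  mixed models `y ~ plant * env + (1|site)`, random-forest contributions;
- **PLS path modeling** — from first principles (mode A, path scheme),
  with $GoF = \sqrt{\bar{C} \times \bar{R^2}}$, effect decomposition,
  and seeded bootstrap CIs.

A seeded synthetic-data generator produces study-shaped datasets (18
composite samples, 6 per forest type, fungal + bacterial tables, plant
richness, soil covariates) with known coupling, so every stage is
testable and parameter recovery is measurable.

The package is tidyverse-native: functions take data frames first and
return tibbles, results have `tidy()`/`glance()` methods and
`autoplot()` figures.

## Worked example

```r
library(emnet)

run <- run_emnet_pipeline(seed = 1)   # simulate + full analysis, ~15 s
run
#> <emnet_run>
#>   samples: 18; fungal network (all): 189 nodes / 537 edges
#>   PLS-PM GoF: 0.478; keystones: 0

head(as.data.frame(
  run$respratio[c("variable", "treat", "lnR", "percent_change", "stars")]
), 4)
#>   variable treat    lnR percent_change stars
#> 1 richness   QPF 0.2179          24.35    **
#> 2 richness   QBF 0.4803          61.66    **
#> 3  shannon   QPF 0.0549           5.64     *
#> 4  shannon   QBF 0.1606          17.42    **

subset(as.data.frame(run$regressions), metric == "richness" & group == "overall")
#>     metric   group  n  slope intercept r_squared p_value response_scale
#> 1 richness overall 18 0.4213      2.38    0.4045  0.0046            log
```

Reading the output: under the generator's default coupling
(`coupling_beta = 0.5`), both mixed forests carry higher EM diversity
than the pure stand (richness +24% in the oak–pine mixture, +62% in the
oak–broadleaf mixture, starred by the meta-analytic z-test), and the
overall log–log regression of EM richness on neighboring plant richness
recovers a positive elasticity (slope 0.42, $R^2 = 0.40$) — attenuated
from 0.5 in any single 18-plot draw, unbiased across many (see the test
suite). `autoplot(run$roles)` draws the Zi–Pi plane,
`autoplot(run$respratio)` the response-ratio forest plot, and
`autoplot(run$plspm)` the path coefficients.

Individual stages compose with pipes on your own tables:

```r
tab <- read_abundance_table("fungal_table.tsv")
alpha <- alpha_diversity(tab)
net <- tab |>
  filter_by_relative_abundance(1e-4) |>
  build_network(r_cut = 0.6, p_cut = 0.001)
roles <- zi_pi(net)
```

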