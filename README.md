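# ofmscreen

Quantitative tools for studying how budding yeast maintains chromosomes
that lack efficient replication origins.

When several adjacent origins fail to fire, a chromosome must replicate a
long inter-origin gap with forks travelling far beyond their usual ~40-kb
stints. Derivatives of *S. cerevisiae* chromosome III from which the five
efficient origins of the left arm and centromere region were deleted (the
5ORIΔ-ΔR fragment and its relatives) are the classic model for this
situation: mutants that preferentially destabilise them — *originless
fragment maintenance* (Ofm) mutants — point at the machinery that rescues
long gaps. `ofmscreen` implements the statistics and simulations of that
experimental programme for anyone analysing chromosome-loss assays or
modelling gap replication:

* **Fluctuation analysis.** Per-division loss rates from parallel-culture
  (colony isolation) assays under the Luria–Delbrück model: the P0
  estimator, the Lea–Coulson median estimator (the root of
  \(\tilde r/m - \ln m = 1.24\)), a maximum-likelihood estimator over the
  Luria–Delbrück count distribution, and bootstrap percentile confidence
  intervals. `simulate_assay()` generates assays with known rates.
* **The Ofm index.** For a mutant and a baseline strain,
  \[
  \mathrm{Ofm} = \frac{\mu_5^{mut}-\mu_5^{base}}{\mu_0^{mut}-\mu_0^{base}},
  \]
  the ratio of *additional* loss events per 10⁵ divisions sustained by the
  origin-depleted (5ORIΔ-ΔR) versus origin-replete (0ORIΔ-ΔR) derivative.
  An equal-opportunity destabiliser (say, a kinetochore mutant) scores ≈1;
  a gap-replication defect scores ≫1. `score_ofm()` computes and
  classifies; a transcription of the published checkpoint-mutant rate
  table ships as `table2_rates()`.
* **Colony sectoring screen.** A branching-process simulator of red-sector
  formation in colonies (`simulate_sectors()`), the semi-quantitative
  class boundaries used to score chromoductants by eye
  (`classify_sectors()`), and the duplicate-chromoductant decision rules
  (`screen_call()`).
* **Gap replication simulator.** Stochastic origin firing (competence ×
  truncated-normal firing time), finite fork speed, permanent fork arrest
  with either a constant per-kb hazard or a rising fork-aging hazard, and
  dormant-origin rescue — with packaged origin maps of the four chromosome
  III derivatives and regimes for wild-type, *rad9*-like, *mec1*-like and
  *mrc1*-like genotypes (`simulate_replication()`, `regime_contrast()`).
* **Synthetic screens.** `make_panel()` + `run_virtual_screen()` run the
  whole pipeline — sectoring, verdicts, fluctuation assays, index
  estimation — on virtual strain panels with known truth.

Everything takes and returns tibbles, so the functions chain with the
pipe; fitted objects support `tidy()`/`glance()` and result objects have
`autoplot()` methods.

## Worked example

Recompute the published Ofm indices from the packaged rate table:

```r
library(ofmscreen)
table2_rates() |> score_ofm(baseline = "Wild Type")
#> # A tibble: 10 × 6
#>   strain       baseline  index index_sd rounded_index call
#>   <chr>        <chr>     <dbl>    <dbl>         <dbl> <chr>
#> 1 sml1D        Wild Type -3.33     3.97            -3 non-Ofm
#> 2 rad9 (ofm14) Wild Type 80.6     23.5             81 Ofm
#> 3 rad9D        Wild Type 65.2     19.8             65 Ofm
#> # … 7 more rows
```

The *rad9Δ* row says: relative to wild type, the origin-depleted fragment
suffers ~65 additional losses for every additional loss of the
origin-replete fragment — a defect specific to replicating the gap, hence
the `Ofm` call. `sml1D`'s slightly negative index (its 5ORIΔ-ΔR rate is a
touch *below* wild type) is reported as-is.

Estimate a loss rate from a simulated 50-culture fluctuation assay at a
true rate of 5 × 10⁻⁴ per division:

```r
simulate_assay(5e-4, culture_size = 1e4, n_cultures = 50, seed = 11) |>
  bootstrap_ci("lc_median", n_boot = 1000, seed = 12) |>
  tidy()
#> # A tibble: 1 × 7
#>   method    m_hat rate_per_division rate_e5 ci_low_e5 ci_high_e5 n_cultures
#> 1 lc_median  3.58          0.000358    35.8      32.9       49.4         50
```

`m_hat` is the expected loss events per 10⁴-cell culture; dividing by the
culture size gives the per-division rate (35.8 × 10⁻⁵, bootstrap 95% CI
33–49), which brackets the true 50 × 10⁻⁵ within typical assay noise.

Calibrate the visual sectoring scale:

```r
calibration_curve(c(2.1e-3, 1e-2, 1e-1), seed = 1)
#> # A tibble: 3 × 3
#>       mu median_sectors class
#> 1 0.0021              1 wildtype_like
#> 2 0.01                5 elevated
#> 3 0.1                36 high
```

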