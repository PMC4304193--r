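# pcombine

Combining p-values from independent studies into one test of the global
null hypothesis that no study has an effect. This is the standard situation
in meta-analysis of genome-wide association studies (and in set-based
analyses such as rare-variant tests) when effect sizes and confidence
intervals are unavailable and only per-study p-values can be pooled.

## Methods

For K independent studies with p-values p₁,…,p_K (uniform on (0,1) under
the global null), the package implements:

* **Weighted z-tests** — Z = Σ wᵢ Φ⁻¹(pᵢ) / √(Σ wⱼ²), standard normal under
  the null. Unit weights give the Stouffer test (`z`); wᵢ = nᵢ the
  Mosteller–Bush test (`z_n`); √nᵢ and 1/seᵢ weightings (`z_sqrt_n`,
  `z_se`) are also provided. Inputs are one-sided p-values with small
  values supporting a common directional alternative, so the combined
  p-value is Φ(Z).
* **Fisher's method** (`fisher`) — X = −2 Σ ln pᵢ, chi-square with 2K df.
* **Lancaster's method** (`lancaster`) — Σ F⁻¹_{dᵢ}(1−pᵢ) with per-study
  chi-square df dᵢ; chi-square with Σdᵢ df under the null. dᵢ ≡ 2 recovers
  Fisher; dᵢ ≡ 1 is the **Chen–Nadarajah test** (`cn`).
* **Gamma-quantile combiners** (`gamma`) — T = Σ G⁻¹_{αᵢ,β}(1−pᵢ); gamma
  (Σαᵢ, β) under the null; the combined p-value is invariant to β.
* **Adaptive-shape gamma test** (`new`) — T = Σ G⁻¹_{1/pᵢ,1}(1−pᵢ): each
  study's shape parameter is the inverse of its own p-value, so small
  p-values get both a large expected contribution and a far upper-tail
  quantile. Because the shape is data-dependent, T has no closed-form
  null; the p-value is estimated by drawing N vectors of K i.i.d.
  Uniform(0,1) values, recomputing T for each, and taking the smoothed
  exceedance proportion (#{t ≥ T} + 1)/(N + 1), with Monte-Carlo standard
  error √(p̂(1−p̂)/N). This test targets the heterogeneous-effects regime
  where only a few of many studies carry signal.

A simulation engine (`run_power_study()`) estimates type-I error and power
for all combiners on two-group normal data with configurable per-study
effect allocations, Poisson-distributed sample sizes and gamma-distributed
standard deviations. `analyze_count_table()` runs pooled two-proportion
z-tests on per-study 2×2 case/control counts and feeds the combiners.

## Worked example

The package ships a five-study case-control meta-analysis of the
association between SNP rs17110747-A and major depression as summary
counts and as the five reported per-study p-values
(0.94, 0.0015, 0.97, 0.79, 0.81):

```r
library(pcombine)
pv <- read_pvalue_table(system.file("extdata", "depression_pvalues.tsv",
                                    package = "pcombine"))
res <- combine_pvalues(pv$pvalues, methods = c("z", "fisher", "cn", "new"),
                       sample_sizes = pv$n, null_n = 1e6, seed = 1)
combine_results_table(res)
#>        method   statistic  combined_p    mc_stderr           null_description
#> z           z   0.9624691 0.832093046           NA            standard normal
#> fisher fisher  14.0821363 0.169277980           NA           chi-square df=10
#> cn         cn  10.2144351 0.069382742           NA            chi-square df=5
#> new       new 746.7235442 0.007742992 8.764469e-05 MC null, 1000000 samples, seed 1
```

Reading the output: the z-test sees nothing (the five p-values point in
mixed directions), Fisher and Chen–Nadarajah are suggestive but not
significant, and only the adaptive gamma test — driven by the single
strong study at p = 0.0015 — falls below 0.05. Its p-value is a
Monte-Carlo estimate with the quoted standard error.

The same analysis from the command line:

```sh
Rscript inst/cli/pcombine.R gwas \
  --pvalues inst/extdata/depression_pvalues.tsv \
  --method z,fisher,cn,new --null-n 1000000 --seed 1
```

and a power study from a scenario config:

```sh
Rscript inst/cli/pcombine.R simulate --config scenario_k2.yaml --reps 10000
```

(`generate_fixtures(dir)` writes example configs for the K = 2
effect-ratio grid and the K = 10 / K = 100 sparse-signal designs.)

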