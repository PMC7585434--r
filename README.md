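# multistab

Multi-scale diversity–stability analysis for replicated grassland
nutrient-addition experiments.

Eutrophication usually raises grassland productivity while eroding plant
diversity — and with it, the mechanisms that keep productivity *stable*
from year to year. `multistab` implements the statistical machinery for
asking whether that erosion is scale dependent: it partitions the temporal
stability of productivity within and among the replicated 1 m² communities
of a site, links the pieces to local and beta diversity with standardized
path models, and tests whether chronic NPK fertilization weakens those
links.

The partition works with the temporal mean/SD ratio at each scale. With
`m`, `w` the temporal means and covariances of species cover (species `i`,
subplot `k`) and `mu`, `v` those of subplot biomass:

```
species stability  = Σ m_ik / Σ √w_ii,kk
species asynchrony = Σ_ik √w_ii,kk / Σ_k √(Σ_ij w_ij,kk)      (≥ 1)
alpha stability    = Σ mu_k / Σ √v_kk
spatial asynchrony = Σ_k √v_kk / √(Σ_kl v_kl)                  (≥ 1)
gamma stability    = Σ mu_k / √(Σ_kl v_kl)
```

so that `alpha × spatial asynchrony = gamma` exactly, and
`species stability × species asynchrony` equals the cover-currency alpha
stability exactly. Diversity uses the multiplicative abundance-based
partition (gamma inverse Simpson over the pooled subplots; beta =
gamma / mean local inverse Simpson). Path coefficients are pooled across
experimental durations (4–9 years) by fixed-effect meta-analysis, and
control-vs-fertilized differences per path are tested with two-group
Cochrane Q statistics. A fully parameterized synthetic community
generator (42 sites × 3 subplots × 2 arms, with switchable fertilization
effects and ground truth) drives validation, power analysis and the
acceptance checks.

## Worked example

Simulate a fertilization experiment in which the fertilized arm loses
~1.8 species per subplot, gains 30% biomass, and has its species responses
homogenized — then run the full pipeline:

```r
library(multistab)
res <- run_pipeline(preset = "fertilized_like", seed = 1, out_dir = "out")

subset(res$meta, path %in% c("richness -> species_asynchrony",
                             "beta_div -> spatial_asynchrony"))
#>                            path treatment pooled     se   ci_lo ci_hi
#>  richness -> species_asynchrony   Control 0.4951 0.0680  0.3618 0.628
#>  richness -> species_asynchrony       NPK 0.1716 0.0768  0.0211 0.322
#>  beta_div -> spatial_asynchrony   Control 0.5388 0.0648  0.4117 0.666
#>  beta_div -> spatial_asynchrony       NPK 0.0958 0.0775 -0.0561 0.248

head(res$treatment_q, 3)
#>                            path     Q df        p
#>   richness -> species_stability 13.76  1 2.08e-04
#>  richness -> species_asynchrony  9.94  1 1.62e-03
#>  beta_div -> spatial_asynchrony 19.22  1 1.17e-05
```

Reading the output: in the unfertilized arm, richer communities have more
asynchronous species dynamics (pooled standardized coefficient 0.50, CI
excluding 0) and sites with higher beta diversity have more asynchronous
subplot dynamics (0.54); in the fertilized arm both links collapse (0.17
and 0.10, the latter indistinguishable from 0), and the Q tests reject
equality of the control and fertilized path coefficients. The per-window
metric tables are in `res$diversity` / `res$stability` (also written to
`out/`):

```r
head(res$stability, 3)
#>  site_code     trt duration detrended species_stability species_asynchrony
#>    site_01 Control        4         0             3.370              1.414
#>    site_01 Control        5         0             3.193              1.403
#>    site_01 Control        6         0             2.031              2.213
#>  alpha_stability spatial_asynchrony gamma_stability
#>            4.031              1.980           7.981
#>            3.703              1.829           6.773
#>            3.728              1.790           6.674
```

The same pipeline runs from the shell on real long-format CSVs
(`site_code, block, trt, year_trt, [season,] Taxon, max_cover` for cover;
`…, live_mass` for biomass):

```sh
exec/multistab all --cover cover.csv --biomass biomass.csv --out out/
exec/multistab all --preset control_like --seed 1 --out out/
```

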