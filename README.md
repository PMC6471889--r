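# growthseq

Growth kinetics, immigration and environmental prediction for staged
bioreactor communities.

## What it is for

In a coupled treatment train — an upflow anaerobic sludge blanket (UASB)
reactor feeding parallel activated-sludge (AS) lines — 16S amplicon tables
of the downstream community mix populations that actually grow there with
immigrants from the upstream reactor that are merely washing through.
`growthseq` is for engineers and microbial ecologists who want to separate
the two from routine monitoring data (an OTU/ASV count table, sample
metadata, and reactor flows/volumes/VSS), and then ask the downstream
questions properly: how strong is immigration, and which environmental
parameters does the community actually track?

The core statistic is the per-population net growth rate from a
steady-state mass balance on one aeration tank + clarifier control volume:

```
mu_x = (Q_waste * X_waste * p_waste,x  -  Q_in * X_in * p_in,x)
       / (V_AS * X_AS * p_AS,x)            [1/d]
```

where `Q` are flows (m3/d), `X` VSS concentrations (g/L), `V_AS` the tank
volume (m3) and `p_.,x` the population's relative abundance in each biomass
stream. `mu_x > 0` defines an *active* population; `mu_x <= 0` (or washout:
present in the influent, never detected in the tank) defines an *inactive*
one. Around this the package provides the Sloan neutral-model immigration
probability `m`, shared-taxon (Venn) summaries, random-forest regression of
environmental parameters on the entire versus the active community,
redundancy analysis with marginal permutation tests, and a fully
ground-truthed synthetic generator for the whole UASB→AS system.

## Worked example

Everything below is generated — no downloads. The numbers shown are the
actual output of this code (seed 7).

```r
library(growthseq)

b <- simulate_reactor_system(sim_config(), seed = 7)
b$otu
#> <otu_table> 1200 features x 66 samples, 1,226,148 reads total

g <- growth_rates(b$otu, b$metadata, b$reactor)
as_ids <- b$metadata$sample_id[b$metadata$location %in%
                                 c("aeration_tank", "clarifier_underflow")]
rel <- to_relative_abundance(unclass(b$otu)[, as_ids])
active_community_summary(g, rel)
#> $n_active            [1] 778
#> $n_inactive          [1] 422
#> $n_washed_out        [1] 110
#> $active_seq_fraction [1] 0.9853152
```

778 of 1200 OTUs grow in the activated sludge and carry 98.5% of its reads;
the 422 inactive OTUs (110 of them pure washouts never detected in the
tanks) are immigrant background — the same structure the method was built
to expose. Regressing temperature on composition, the active subset
predicts at least as well as the entire community:

```r
regress_parameter(b$otu, b$metadata, "temperature", "entire", seed = 7)
#> <regression_report> temperature (entire community): MSE 0.6113, R2 0.978, slope 0.920 (n=43/11)
regress_parameter(b$otu, b$metadata, "temperature", "active",
                  growth = g, seed = 7)
#> <regression_report> temperature (active community): MSE 0.5414, R2 0.981, slope 0.935 (n=43/11)
```

(The advantage of the active subset is small at this fixture's mild
immigration level and grows with immigrant load; see the methods vignette.)
The neutral model is fit to occurrence frequencies on the rarefied table:

```r
r <- rarefy(b$otu, 18578, seed = 7)
obs <- observed_frequency(r, as_ids)
fit_neutral_m(obs$freq_obs, obs$p_mean, N_T = 18578)
#> <neutral_fit> m = 0.7209 (local reproduction 0.2791), R2 = 0.879, 1113 OTUs, N_T = 18578
```

On this niche-structured fixture the fitted `m` is large — most taxa are
persistent residents, so occupancy looks "neutral with high immigration".
Estimator correctness for small `m` is established separately: data drawn
from the package's beta-binomial sub-generator at `m = 0.028` are refit to
a median absolute error below 0.01 (see `tests/testthat/test-acceptance.R`).

RDA with 999-permutation marginal tests:

```r
act <- rel[rownames(rel) %in% g$otu_id[g$active], ]
act <- sweep(act, 2, colSums(act), "/")
Y <- hellinger_transform(t(act))
X <- b$metadata[match(as_ids, b$metadata$sample_id),
                c("temperature", "TOC", "DO", "NH4", "TA")]
rda_significance(Y, X, n_perm = 999, seed = 7)
#>      variable   pseudo_F p_value  n n_perm
#> 1 temperature 34.6320480   0.001 54    999
#> 2         TOC  6.3542461   0.002 54    999
#> 3          DO  0.6020098   0.878 54    999
#> 4         NH4 19.7778624   0.001 54    999
#> 5          TA  1.2573374   0.228 54    999
```

Temperature (and its coupled parameters) constrain the active community;
dissolved oxygen does not — the structure the fixture encodes by design.

## Command line and pipeline

```sh
growthseq simulate --out fixtures/demo --seed 7
growthseq growth --otu-table fixtures/demo/otu_table.tsv \
                 --metadata fixtures/demo/metadata.tsv \
                 --reactor fixtures/demo/reactor.tsv --out growth.tsv
growthseq run --config pipeline.json --out results/
```

`run_pipeline()` chains simulate → growth → neutral → overlap → regression
→ RDA, writes per-stage subdirectories plus a `report.json` with file
digests, and is byte-deterministic for a given config and seed.

## Layout

- `R/` — tables/metadata IO, mass-balance kinetics, neutral model and
  overlap, regression (Rcpp ensemble in `src/rf.cpp`), RDA, simulator,
  pipeline, CLI.
- `vignettes/growthseq-methods.Rmd` — the model, its assumptions, the
  generator's stated world, and design decisions.
- `tests/testthat/` — unit, property and acceptance suites.
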