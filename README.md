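# littermix

Meta-analysis of non-additive litter-mixture decomposition effects.

Leaf litter in forests decomposes in multi-species mixtures, but
decomposition rates are usually measured on single species. `littermix`
synthesises litterbag experiments that compare mixtures against their
components: it builds the additive-null expectation for every mixture
observation, turns observed/expected pairs into log-response-ratio effect
sizes, pools them under a random-effects model with bootstrap confidence
intervals, partitions heterogeneity across ecological subgroups (biome,
species richness, evenness, leaf-habit composition, forest type and
stand structure, litterbag mesh class), traces how mixing effects develop
across decomposition stages, and regresses them on initial chemical
trait divergence and site climate. A synthetic-data generator with
recorded ground truth makes the entire pipeline testable end to end.

## The model in brief

For a mixture with component mass fractions *p<sub>i</sub>* and
single-species responses *x<sub>i</sub>* at the same harvest, the
additive null is X̄<sub>c</sub> = Σ p<sub>i</sub> x<sub>i</sub>. Each
pair yields

- effect size: lnRR = ln X̄<sub>e</sub> − ln X̄<sub>c</sub>
  (&gt; 0 synergistic, &lt; 0 antagonistic),
- sampling variance: v = s<sub>e</sub>²/(N<sub>e</sub> X̄<sub>e</sub>²) +
  s<sub>c</sub>²/(N<sub>c</sub> X̄<sub>c</sub>²).

Effects are pooled with DerSimonian–Laird τ² and random-effects weights
1/(v + τ²); 95% CIs come from a bias-corrected observation-level
bootstrap that re-estimates τ² per replicate. Subgroup analysis
partitions Q<sub>total</sub> = Q<sub>between</sub> + Q<sub>within</sub>
under fixed-effect weights (one-way weighted ANOVA style). Trait
divergence within a mixture is Rao's quadratic entropy
Σ<sub>i&lt;j</sub> d<sub>ij</sub> p<sub>i</sub> p<sub>j</sub> with
d<sub>ij</sub> the mean absolute character difference. The methods
vignette (`vignettes/littermix-methods.Rmd`) derives and motivates every
estimator and default.

## Worked example

```r
library(littermix)

ds <- generate_dataset(generator_config(seed = 7))   # 65-study compilation
pairs <- build_pairs(ds)                             # observed vs additive null
effects <- compute_effect_sizes(pairs)               # lnRR + variance per pair

ml <- dplyr::filter(effects, is_final_harvest, response == "mass_loss")
meta_analyze(ml, reps = 999, seed = 3)
#> <litter_meta> k = 278 | lnRR = 0.0273 (2.8%) | tau^2 = 0.0039
#>   95% bootstrap CI [0.0169, 0.0378] -> synergistic
```

The overall final-harvest mixture effect on mass loss is +2.8% with a
bootstrap CI excluding zero: mixtures in this generated compilation
decompose faster than their components predict, driven by the configured
temperate and subtropical study effects. Subgroups, staging and
regressions:

```r
subgroup_analysis(ml, "biome", reps = 999, seed = 3)   # per-biome pooling + Q partition
st <- staged_meta(effects, reps = 999, seed = 4)       # effect by 10% mass-loss stage
autoplot(st)                                           # trajectory figure
divergence_regressions(ds, effects, traits = "Ca")     # effect ~ trait divergence
```

Or run everything at once and write the report tables:

```r
report <- run_pipeline(ds, pipeline_config(reps = 4999, seed = 1))
write_report(report, "report/")   # report.json, effects.csv, staging_results.csv, ...
```

A thin command-line wrapper is installed at `inst/cli/littermix.R`
(`generate` and `run` subcommands).

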