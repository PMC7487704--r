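# CNPmix

Bayesian copy number genotyping for SNP-array cohorts with latent batch
effects, and disease-association modelling that carries the copy number
uncertainty through to the end.

## Who this is for

Genome-wide association studies that want to include copy number
polymorphisms (CNPs) face a specific obstacle: the one-dimensional log2 R
ratio summaries of a CNV region cluster by integer copy number, but groups
of samples processed together — chemistry plates at a central lab, not
necessarily the study sites — shift and rescale those clusters, and the
responsible grouping differs from region to region. CNPmix is for analysts
of such cohorts (thousands of samples, hundreds of candidate regions) who
need probabilistic integer copy numbers that are robust to these latent
batch effects, and who want the genotyping uncertainty propagated into the
case-control model rather than discarded at a hard-call boundary.

## The model in brief

For sample *i* in latent batch *b*, the region summary follows a K-component
mixture of scaled t distributions (d = 100),

  r<sub>ib</sub> | z<sub>ib</sub>=h ~ t<sub>d</sub>(θ<sub>hb</sub>, σ<sub>hb</sub>),  z<sub>ib</sub> ~ Multinomial(π<sub>b1</sub>, …, π<sub>bK</sub>),

with a conjugate hierarchy shrinking batch-level parameters towards
component-level ones: θ<sub>hb</sub> ~ N(μ<sub>h</sub>, τ²<sub>h</sub>), precisions
1/σ²<sub>hb</sub> ~ Gamma(ν₀/2, ν₀σ₀²/2), and hyperpriors on μ<sub>h</sub>, τ²<sub>h</sub>, σ₀², ν₀. Batches
are discovered per region by recursively merging chemistry plates whose
summary eCDFs are indistinguishable (two-sample Kolmogorov–Smirnov, α =
0.01). Fitted components are mapped to integer copy numbers 0–4 by
maximising a beta–binomial likelihood of the region's SNP B allele
frequencies over admissible mappings. Disease risk is then modelled as

  logit P(y<sub>i</sub>=1) = Xᵢβ + z·(β₇ C<sub>i</sub> + β₈ C<sub>i</sub>·I[high quality]),

where the integer copy number C<sub>i</sub> is sampled each MCMC scan from its
genotyped posterior, and the spike indicator z (Bernoulli(0.5) prior) gives
a posterior probability of association. All samplers (the conjugate Gibbs
sampler for the mixture, Chib's marginal likelihood for model comparison,
Metropolis-within-Gibbs for the regression) are implemented in the package.

The methods vignette (`vignettes/cnpmix-methods.Rmd`) documents every stage,
the tunable parameters with defaults, and the generator used for validation.

## Worked example

Simulate the benchmark cohort — 990 samples on 16 plates, one 54-marker
region spanning a deletion polymorphism at allele frequency 0.22 — distort
half the plates, and run the full workflow:

```r
library(CNPmix)
design <- simulationDesign()                       # delta = 0, xi = 1
cohort <- applyBatchEffects(simulateCohort(design, seed = 1), seed = 2)
res <- cnpPipeline(cohort$experiment, variants = "auto", nStarts = 5,
                   startBurnin = 100, nBurnin = 300, nIter = 600, seed = 3)
res$batches
#> BatchAssignment for region_all
#>   16 plates merged into 2 batch(es)
#>   plates per batch: A=9, B=7
res$comparison
#> ModelComparison: 8 model(s); selected MBP K = 3 (escalated to multi-batch)
res$calls
#> CopyNumberCalls for region_all
#>   component -> copy number: 1->0, 2->1, 3->2
#>   hard calls: 0=52, 1=330, 2=608, 3=0, 4=0
evaluateCalls(res$calls, cohort$truth)$auc
#> [1] 1
h <- hweChisq(as.vector(table(factor(hardCalls(res$calls), levels = 0:2))))
sprintf("HWE chi2 = %.2f, p = %.2f, q = %.3f", h$chi2, h$p.value, h$q)
#> [1] "HWE chi2 = 0.68, p = 0.41, q = 0.219"
```

Reading the output: the eCDF merging found two latent batches among the 16
plates; the cascade escalated from single-batch to multi-batch models and
selected the pooled-variance multi-batch model with three components; the
B allele frequencies mapped the components to copy numbers 0, 1 and 2 (a
deletion polymorphism); carrier-versus-noncarrier AUC against the simulation
truth is 1.0 with 99.8% hard-call accuracy; and the genotyped frequencies
are consistent with Hardy–Weinberg equilibrium at a deletion allele
frequency of 0.219 — the post-hoc QC one expects when no technical
variation is left unmodelled.

A thin command-line wrapper over the same functions is installed at
`inst/scripts/cnpmix.R` with `simulate`, `preprocess`, `batch` and `fit`
subcommands, each taking `--config` (INI-style key=value), `--seed` and
`--out`.

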