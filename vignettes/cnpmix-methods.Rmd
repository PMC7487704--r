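---
title: "Copy number genotyping across latent batches: models and methods"
author: "CNPmix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Copy number genotyping across latent batches}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CNPmix)
```

## The problem

Germline copy number polymorphisms (CNPs) shift the log2 R ratio of SNP-array
probes: a hemizygous deletion lowers it by roughly half a unit, a homozygous
deletion by around three units, a duplication raises it. In cohorts of
thousands of samples, the per-sample summary of a CNV region (the median log2
R ratio across its probes, or the first principal component of the probe
submatrix) forms clusters corresponding to integer copy numbers — but the
clusters are distorted by *batch effects*: groups of samples processed
together (chemistry plates) can differ systematically in location and scale,
and the responsible grouping is usually unknown a priori. Fitting one mixture
to all samples then either inflates the component variances or hallucinates
components, and the errors propagate into any downstream disease-association
analysis.

CNPmix addresses this in four stages, each usable on its own:

1. **Preprocessing** — GC and spatial LOESS correction of probe-level log2 R
   ratios, per-sample quality metrics, and consolidation of per-sample CNV
   calls into analysis regions.
2. **Latent batch discovery** — chemistry plates whose empirical distribution
   functions of the region summary are statistically indistinguishable are
   merged recursively, separately at every region.
3. **Hierarchical Bayesian mixture** — a K-component mixture of
   t-distributions whose component means and variances are batch-specific
   but shrunk towards shared component-level locations, fitted by Gibbs
   sampling; components are mapped to integer copy numbers from the B allele
   frequencies of the region's SNPs.
4. **Association** — a Bayesian logistic regression in which the integer
   copy number enters as a latent covariate sampled from its per-sample
   posterior, with a spike indicator whose posterior mean is the probability
   of association.

## Preprocessing

GC correction fits, per sample, a LOESS (local linear, tricube weights,
span 1/3) of log2 R ratio on probe GC content over a random 30,000-probe
subsample and subtracts the prediction for every probe. Spatial correction
then smooths the GC-corrected values of *balanced* SNPs (0.4 < BAF < 0.6,
which are diploid-heterozygous and hence carry no copy number signal)
against probe order within each chromosome arm and subtracts the predicted
trend from all probes on the arm. Arms with fewer than 10 balanced anchors
are left uncorrected with a warning, as are datasets without a centromere
table (whole chromosomes are then treated as single arms). Smoothing weights
use the probe index within the arm rather than genomic base pairs, so the
design points are uniform regardless of probe spacing.

Sample quality is summarised by the median absolute deviation and the lag-10
autocorrelation of position-ordered autosomal log2 R ratios; the default
stratification flags samples with autocorrelation at or above 0.06 as low
quality, with an optional top-decile rule.

Region consolidation breaks the pooled CNV call boundaries into disjoint
intervals, keeps intervals carried by at least 150 distinct samples, and
merges runs of touching kept intervals; the final span covers the member
intervals carried by at least half of the run's carrier set. "Touching"
means a gap of zero base pairs, since disjoint intervals partition the
pooled footprint. Call concordance between pipelines uses the 50% reciprocal
overlap rule.

## Batch discovery

For one region, per-sample summaries below −1 (likely homozygous deletions,
which are biology rather than batch) are set aside, and plates are compared
pairwise by the two-sample Kolmogorov–Smirnov statistic with its asymptotic
p-value. The pair of current groups with the *largest* p-value is merged
while that p-value exceeds α = 0.01, recomputing eCDFs after every merge;
ties break on the lexicographically smallest pair, making the result
invariant to plate input order. Plates contributing fewer than five usable
values are pre-merged with the plate of closest mean before testing, and
excluded samples inherit their plate's final batch. Labels are consecutive
letters ordered by batch mean. Note the direction of the α knob: a *smaller*
α makes merging easier, so batch counts are non-increasing as α decreases.
The same machinery applies to any grouping surrogate (e.g. DNA extraction
method) by relabelling the grouping column.

## The hierarchical mixture

For sample $i$ in batch $b$ with latent component $z_{ib}=h$,

$$r_{ib} \mid z_{ib}=h, U_{ib} \sim \mathrm{Normal}\!\left(\theta_{hb},
\sigma^2_{hb}/U_{ib}\right), \qquad U_{ib} \sim
\mathrm{Gamma}(d/2,\, d/2),$$

so that marginally $r_{ib}$ follows a scaled t-distribution with $d$ degrees
of freedom (default $d = 100$, a near-Gaussian compromise that still damps
occasional outliers; $d$ is fixed, not estimated). Component weights
$\pi_{b\cdot}$ are batch-specific with a symmetric Dirichlet(1) prior. The
hierarchy shrinks batch-level parameters towards component-level ones:

$$\theta_{hb} \sim \mathrm{Normal}(\mu_h, \tau^2_h), \qquad
\tilde\sigma^2_{hb} \sim \mathrm{Gamma}\!\left(\tfrac12\nu_0,
\tfrac12\nu_0\sigma_0^2\right),$$

with conjugate priors $\mu_h \sim \mathrm{Normal}(\mu_0, \tau_0^2)$,
$\tilde\tau^2_h \sim \mathrm{Gamma}(\tfrac12\eta_0, \tfrac12\eta_0 m_0^2)$,
$\sigma_0^2 \sim \mathrm{Gamma}(a_0, b_0)$ and $\nu_0 \sim
\mathrm{Geometric}(\beta)$ truncated at 100. Defaults
($\mu_0 = 0$, $\tau_0^2 = 0.4$, $\eta_0 = 32$, $m_0^2 = 0.5$, $a_0 = 1.8$,
$b_0 = 6$, $\beta = 0.1$, $\alpha_h = 1$) are package defaults, all
configurable; the informative $\tau^2$ prior keeps a component's batch means
within roughly $\pm 0.7$ of each other, which is what discourages label
switching at genuine polymorphisms. Four variants are available: batch-
specific means and variances (MB), pooled variance within batch (MBP), and
the single-batch specials SB and SBP; SB/SBP are exactly MB/MBP run with all
batches collapsed, so the code path is shared and the chains coincide when
B = 1.

All full conditionals are conjugate and the Gibbs scan order is fixed:
$z, U, \theta, \sigma^2, \pi, \mu, \tau^2, \sigma_0^2, \nu_0$. Component
probabilities are Rao-Blackwellised averages of the per-scan conditional
assignment probabilities, normalised with log-sum-exp throughout.

### Initialisation and label alignment

Initialisation matters more here than in a generic mixture because the
likelihood is invariant to *per-batch* label permutations: a chain in which
component 2 tracks hemizygous deletions in one batch and diploids in another
fits the data exactly as well, and only the $\theta_{hb}\mid\mu_h,\tau^2_h$
hierarchy term distinguishes the modes — weakly, when the batch shift is
comparable to the cluster gap. Three measures keep inference in the aligned
mode:

* each of the (default 10) starts anchors component means, variances and
  weights at a per-batch k-means solution with centres sorted ascending
  (jittered; hyperparameters drawn from their priors), so labels open
  rank-aligned across batches;
* the best start is chosen by the observed-data log likelihood *plus* the
  hierarchical prior on the batch means, the only term that penalises
  misaligned modes;
* genotyping consumes batch-rank-aligned probabilities: component labels
  are matched across batches by the rank of their batch-specific posterior
  means, which is exact for any location/scale batch distortion (such
  distortions preserve cluster order).

When sub-threshold observations (below −1) occur in some but not all
batches, the data are augmented with 10 flagged pseudo-observations per
lacking batch, drawn from a normal distribution matched to the observed
sub-threshold values (SD floored at 0.1). This pins the lowest-ranked
component to the homozygous-deletion state everywhere — the empirical-prior
reading is that large negative values at a germline CNV region are bona fide
homozygous deletions rather than outliers. Augmented points are flagged and
excluded from posterior summaries, genotype frequencies and association.

### Model cascade and comparison

Candidate component counts are {3, 4} when apparent homozygous deletions are
present and {1, …, 4} otherwise. Single-batch models are fitted first;
multi-batch models are evaluated only when more than 2% of samples have a
maximum component probability below 0.99 in the better single-batch model.
Among fitted models the highest final log likelihood wins, preferring the
more parsimonious model (pooled variance, then smaller K) within 2 log
units; when the top two models differ by less than 10 in final log
likelihood, Chib's marginal likelihood decides. Chib's estimator evaluates
$\log \hat m(r) = \log p(r\mid\psi^*) + \log p(\psi^*) - \log
\hat p(\psi^*\mid r)$ at the posterior mean of the relabelled draws, with
the posterior ordinate decomposed into block ordinates
$(\theta, \tilde\sigma^2, \pi, \mu, \tau^2, \sigma_0^2, \nu_0)$ estimated by
Rao-Blackwellised averages over reduced Gibbs runs; the $\tau^2$ and $\nu_0$
ordinates are free of latent data and evaluated exactly. Fits flagged for
label switching (windowed rank order of component means disagreeing between
chain segments) are refused, as the ordinate is then ill-defined. Posterior
predictive replicates of the region summaries, compared with the observed
summaries by a Kolmogorov–Smirnov statistic, guard against selecting the
best of several poor fits.

## Genotyping from B allele frequencies

At a SNP, the BAF of a sample with allelic genotype $g$ out of $c$ total
copies clusters near $g/c$. For a candidate mapping $f$ from components to
copy numbers, the likelihood of the observed BAFs averages, per sample and
SNP, beta densities for each allelic genotype weighted by the binomial
probability of $g$ B alleles out of $c$ at the cohort allele frequency.
Only samples assigned to one component with probability at least 0.99 enter;
copy number 0 uses a uniform beta, since BAF is pure noise without alleles.
Default beta shapes (homozygous 1/99, balanced heterozygote 20/20,
copy-3 13.3/26.7, copy-4 quarters 10/30) are package defaults, configurable
via `allelicModel()`. Candidate mappings are non-decreasing over
mean-ordered components with steps of 0 or 1, bounded by copy numbers 0–4,
and anchored so the modal component is diploid (unless a duplication-only
region is declared); this admits the one-to-one deletion mapping
$\{0,1,2\}$, many-to-one collapses like $\{2,2,2\}$, and duplication
mappings like $\{2,3\}$. Ties prefer the mapping with more distinct states.
The cohort allele frequency is estimated from diploid-called samples by BAF
thresholds (<0.25, 0.25–0.75, >0.75). Regions without usable SNPs fall back
to a documented log2R-mean heuristic with a warning.

Hardy–Weinberg equilibrium over genotyped copy numbers 0/1/2 serves as
post-hoc QC: the model nowhere assumes HWE, so agreement with it is evidence
that no major technical variation remains.

## Association model

Case status is modelled as Bernoulli with

$$\mathrm{logit}\,\theta_i = \beta_0 + \beta_1\,\mathrm{age}_i +
\beta_2\,\mathrm{male}_i + \beta_3\,\mathrm{PC1}_i + \beta_4\,\mathrm{PC2}_i
+ \beta_5\,\mathrm{PC3}_i + \beta_6 I_{hq,i} + z\,(\beta_7 C_i + \beta_8
C_i I_{hq,i}),$$

with Cauchy(0, 2.5) priors on all coefficients (the conventional weakly
informative scale for logistic regression), $z \sim \mathrm{Bernoulli}(0.5)$
and $C_i$ sampled each scan from the genotyped copy number probabilities
re-weighted by the Bernoulli likelihood. The sampler is Metropolis-within-
Gibbs: coefficients move one at a time by random-walk proposals whose step
sizes adapt towards a 0.44 acceptance rate during burn-in and are frozen
afterwards; $z$ is a conditional Bernoulli from the likelihood ratio of the
slab versus zero-slope model; when $z = 0$ the slab coefficients are
refreshed from their priors, which is their exact conditional, so no
pseudo-prior is needed. The posterior mean of $z$ estimates the probability
of association; odds ratios are reported with 90% equal-tailed credible
intervals, matching the reporting convention of the method. The unstratified
variant drops the quality main effect and interaction. Defaults are 5000
iterations with a thin of 25.

## The synthetic cohort generator

`simulateCohort()` emulates the benchmark conditions under which the method
was characterised: 990 samples randomised to 16 chemistry plates, one region
of 54 markers (1 SNP and 53 nonpolymorphic), a deletion allele at frequency
0.22 under Hardy–Weinberg proportions, and copy number cluster means of −3
(homozygous deletion), −0.5 (hemizygous) and 0 (diploid), with 0.4 available
for duplication designs. Probe values add two noise layers: probe-level
measurement noise (SD 0.15, typical of raw log2 R ratios) and a per-sample
baseline random effect (SD 0.1) emulating sample-to-sample quality and wave
variation. The sample effect is what gives region *summaries* realistic
dispersion — the median of 54 probes would otherwise have a standard error
near 0.02 and every analysis would be trivially separable. SNP BAFs are
drawn from the same allelic beta model the genotyper uses, keeping the two
modules consistent.

`applyBatchEffects()` draws each plate affected with probability 0.5 and
transforms affected-plate values as $r^* = (r - \bar r_c)\,\xi + \bar r_c +
\varepsilon$ with $\varepsilon \sim N(\delta, 0.02^2)$, over the grid
$\delta \in \{0, 0.3, 0.4, 0.5\}$, $\xi \in \{1, 1.25, 1.5, 1.75, 2\}$;
unaffected plates pass through untouched. Evaluation uses the trapezoidal
carrier-versus-noncarrier AUC with $1 - \Pr(\mathrm{cn}=2)$ as the score,
plus hard-call accuracy overall and per copy number.

What the generator does *not* emulate: real probe-level heteroscedasticity
across copy states, GC waves (summaries enter the mixture after correction
anyway), linkage between neighbouring regions, and genotyping-chemistry
artefacts in BAF such as asymmetric cluster compression. Passing the
simulation benchmarks therefore demonstrates correct inference under the
stated distortion model, not performance on raw array data.

## Numerical choices and problem sizes

Sampler schedules follow the recommended regime (10 anchored starts × 200
burn-in scans, then 500 burn-in + 1000 retained); the packaged tests and
the acceptance script run reduced schedules (about 5 starts × 100, 300 +
600 retained, and 1500–2000 association iterations) chosen so the full
suite completes on a single core while leaving comfortable margins on every
assertion. Variances are floored at 1e−8, categorical draws use the
Gumbel-max trick on log weights, mixture likelihoods use log-sum-exp, and
the Bernoulli log likelihood is evaluated through `plogis(sign * eta,
log.p = TRUE)` for stability at extreme linear predictors. The discrete
$\nu_0$ conditional is sampled on the truncated grid 1–100, where the
geometric tail mass beyond is negligible. The K-S comparison uses the
asymptotic p-value (plate groups are large and ties are immaterial after
summarisation).

## Known limitations

* The degrees of freedom $d$ is fixed, not estimated.
* Chromosomes X and Y are out of scope; inference is autosomal.
* The 5-state HMM that proposes CNV calls is external; the package consumes
  its call tables.
* Chib ordinates require a label-stable chain; heavily overlapping
  components at too-large K are refused rather than rescued.
* Mapping enumeration caps copy numbers at 0–4 and requires the modal
  component to be diploid, which covers deletion and common duplication
  polymorphisms but not exotic multi-allelic loci.

## A worked run

```{r, eval = FALSE}
design <- simulationDesign(delta = 0.5, xi = 1)
cohort <- applyBatchEffects(simulateCohort(design, seed = 1), seed = 2)
res <- cnpPipeline(cohort$experiment, variants = "auto", seed = 3)
res$batches          # plates merged into latent batches
res$comparison       # fitted variants and the selection
res$calls            # copy number calls with the BAF-derived mapping
evaluateCalls(res$calls, cohort$truth)$auc
```
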