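---
title: "Dirichlet-multinomial differential abundance: model, sampler and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dirichlet-multinomial differential abundance: model, sampler and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the statistics it implements:
the hierarchical Dirichlet-multinomial (DMM) model and its sampler, the
credible-mass decision rule, the surrounding community and phenotype
statistics, what the synthetic-data generator does and does not emulate, and
the numerical choices that a careful user should know about. It states no
empirical result that the test suite and `scripts/acceptance.R` do not
themselves compute.

## The model

A 16S count table is compositional: each sample is a multinomial draw of
fixed total (the sequencing depth) from the sample's relative-abundance
vector. Replicates within a treatment group do not share one such vector —
biological and technical variation make them overdispersed. The DMM captures
both facts with one hierarchy per sampling group $g$:

$$
\mathbf{p}_j \sim \mathrm{Dirichlet}(\theta_g \, \boldsymbol\pi_g), \qquad
\mathbf{x}_j \sim \mathrm{Multinomial}(d_j, \mathbf{p}_j),
$$

where $\boldsymbol\pi_g$ (a point on the $K$-simplex) is the group's
expected composition, $\theta_g > 0$ the intensity (large $\theta$ means
replicates hug $\boldsymbol\pi_g$ tightly; the variance of a replicate
proportion is $\pi_i(1-\pi_i)/(\theta+1)$ plus multinomial noise), and
$d_j$ the observed depth. Because analysis happens on the proportion scale
with all replicates informing $\boldsymbol\pi_g$, rarefaction is
unnecessary and deliberately not offered; unequal depths simply carry
unequal information.

The replicate-level $\mathbf{p}_j$ is never sampled: integrating it out
analytically gives the Dirichlet-multinomial likelihood

$$
\log P(\mathbf{x}_j \mid \boldsymbol\pi_g, \theta_g)
 = \log\binom{d_j}{\mathbf{x}_j}
 + \log\Gamma(\theta_g) - \log\Gamma(\theta_g + d_j)
 + \sum_i \big[\log\Gamma(\theta_g\pi_i + x_{ji}) - \log\Gamma(\theta_g\pi_i)\big],
$$

implemented in `dm_log_likelihood()` (the multinomial coefficient is
included, so the pmf sums to one; the tests verify this by enumeration).
The marginal posterior of $(\boldsymbol\pi, \theta)$ is identical to the
latent-$\mathbf{p}$ formulation, and mixing is far better when $K$ is in
the tens to hundreds, because the high-dimensional latent block is gone.

**Priors.** The data source this model family targets does not pin down
priors, so they are explicit arguments with weakly informative defaults: a
symmetric $\mathrm{Dirichlet}(1)$ (uniform) prior on each
$\boldsymbol\pi_g$ and a half-Cauchy(scale 100) prior on each $\theta_g$,
heavy-tailed enough to let the data place $\theta$ anywhere over several
orders of magnitude. Each group in a fit has its own intensity; with a
generator that uses a single $\theta_{\mathrm{true}}$, both group
posteriors concentrate on it.

## The sampler

`fit_dmm()` runs an adaptive Metropolis-within-Gibbs sampler (in C++) on
the unconstrained coordinates $u_{gi} = \log \alpha_{gi}$ with
$\boldsymbol\alpha_g = \theta_g \boldsymbol\pi_g$, recovering
$\boldsymbol\pi_g = \boldsymbol\alpha_g / \sum_i \alpha_{gi}$ and
$\theta_g = \sum_i \alpha_{gi}$ deterministically. This parametrisation was
chosen over the additive-log-ratio transform of $\boldsymbol\pi$ plus
$\log\theta$ for a computational reason with no inferential cost: a
single-coordinate update changes only $\alpha_{gi}$ and the total
$\sum\alpha$, so its likelihood delta costs $O(n_g)$ Gamma-function
evaluations instead of $O(n_g K)$ — roughly a tenfold saving at $K = 50$ —
while the posterior is exactly the same distribution (the change of
variables contributes $\theta^{-(K-1)}$, and sampling on the log scale adds
$\sum_i \log\alpha_{gi}$; both Jacobians are included).

Each sweep updates every coordinate with a Gaussian random walk, then makes
one whole-group *scale move* (a common shift of all $u_{gi}$, i.e. a
$\theta_g$ update at fixed $\boldsymbol\pi_g$). The scale move matters:
$\theta$ is a sum of $K$ coordinates and would otherwise evolve as a slow
random walk; with it, the worst-case potential scale reduction across
parameters in the test fits sits near 1.01.

Step sizes adapt per coordinate toward a 0.44 acceptance rate by a
Robbins-Monro recursion that is **frozen at the end of burn-in**, so the
retained sweeps form a valid Markov chain. Defaults follow common practice
for this model family: 4 chains, 1,500 burn-in sweeps, 1,000 retained
sweeps per chain — 4,000 retained posterior draws. Chains start from
overdispersed initial points (empirical group proportions jittered on the
log scale, intensity drawn around 300 with unit log-normal spread) so the
Gelman-Rubin diagnostic (`gelman_rubin()`, the classic
$\hat R = \sqrt{((n-1)/n\,W + B/n)/W}$ on the unconstrained scale) is an
honest convergence check. All randomness flows through R's RNG, so a seed
makes the draw arrays bit-identical.

Numerical guards: $\log\alpha$ is clamped to $[-30, 30]$ (far outside any
posterior mass at realistic depths); cached likelihood terms are refreshed
exactly every 500 sweeps against floating-point drift; compositions stay
strictly interior by construction, so zero counts need no pseudocounts.

## The decision rule and fold changes

`compare_groups()` pools draws across chains and computes, per taxon,
$\Pr(\pi_{i,g1} > \pi_{i,g2})$. A taxon is flagged when that probability is
$\ge 0.95$ or $\le 0.05$ (the boundary counts as flagged — a tie-break that
must be fixed somewhere and is documented here). No multiple-comparison
correction is layered on top; instead the realised false-flag fraction
under a true null is measured by simulation in the acceptance suite (20
null datasets at the emulated design; the mean flagged fraction is required
to stay at or below 0.07). Effect sizes are posterior draws of
$\log_{10}(\pi_{i,g1}/\pi_{i,g2})$, summarised as mean and equal-tailed
interval and also expressed on the "$x$-fold" scale.

One behaviour worth understanding: planting a large enrichment on one taxon
*renormalises* every other taxon of that group downward by the factor
$c = 1/(1 + (f-1)\pi_{\mathrm{base}})$. Flags on non-planted taxa in such
simulations are therefore usually genuine (the truth really differs), not
false positives; the calibration study uses fully null data for exactly
this reason.

The three standard contrasts (`standard_comparisons()`) are fitted as
separate two-group models — all diploid vs all tetraploid, Columbia vs
Landsberg, Col-4x vs the other three planted groups pooled — with soil
controls always excluded.

## Community statistics

Bray-Curtis operates on raw counts (the `adonis` convention) and Jaccard on
presence-absence, as their "(abundance)" and "(presence-absence)" labels
suggest; the quantitative Jaccard variant sits behind a flag. PERMANOVA is
single-factor by design — every contrast in the emulated study is a binary
factor — using the Gower-centred decomposition, pseudo-
$F = (SS_B/(k-1))/(SS_W/(n-k))$, and the permutation convention
$p = (1 + \#\{F^\ast \ge F\})/(1 + n_{\mathrm{perm}})$ with
$n_{\mathrm{perm}} = 999$ by default. When the number of distinct label
assignments is at most 10,000 the full enumeration replaces sampling and
$p$ is exact. Distance matrices are always computed *after* subsetting to
the samples of a comparison (soil controls enter only the plant-vs-soil
row); computing them before subsetting would change nothing for these
metrics but the choice is fixed and documented. PCoA reports negative
eigenvalues uncorrected — silently dropping them hides non-Euclidean
structure. Shannon diversity uses the natural logarithm; Welch's unequal-
variance $t$ with Satterthwaite degrees of freedom handles the group
comparisons of diversity.

## Phenotype statistics

The feedback experiment is analysed with a fixed-effect, main-effects-only
three-way ANOVA (`response ~ inoculum + genotype + block`), sequential sums
of squares in that order (equal to marginal sums of squares on the balanced
designs the generator produces — the tests verify the equality). The
genotype-by-inoculum interaction is available behind a flag but off by
default: the model names exactly three explanatory variables. Block is
fixed, not random. Missing responses are dropped listwise per response,
which is why different traits can have different $n$. For display,
residuals after genotype and block (`residualize()`) are summarised by
inoculum — the bar-chart convention for inoculum effects. Tukey HSD uses
the full model's residual mean square and the studentized range, with a
compact letter display computed by insert-and-absorb; planned contrasts of
inoculum level means use the full-model residual variance and are
deliberately unadjusted (planned, not post hoc).

## The synthetic-data generator

`synthetic_spec()` + `generate_truth()` + `simulate_counts()` are the exact
generative dual of the fitted likelihood: baseline composition from a
symmetric Dirichlet (concentration 0.3 by default, giving realistically
uneven rank-abundance curves), multiplicative fold-change effects with
renormalisation (matching the "$x$-fold" scale on which effects are
reported), replicate compositions from
$\mathrm{Dirichlet}(\theta_{\mathrm{true}}\boldsymbol\pi)$, uniform-integer
depths on 36,033–143,254 (the emulated study reports only the depth range,
so uniform is the least-informative choice), and multinomial counts.
Default design: four planted groups of 8 replicates plus 7 unplanted soil
controls with an independent soil composition. $\theta_{\mathrm{true}}$
defaults to 500 — a free parameter of the simulation, not an estimate, as
no overdispersion value is available to emulate; the recovery and
calibration studies pin it explicitly. All randomness derives from one spec
seed through named substreams (composition, soil, depths, counts,
phenotypes), so each stage is independently reproducible. K defaults to a
desk-scale 50 and scales up (the emulated study has 2,689 ASVs); test and
acceptance runs use $K$ between 40 and 60 with 16–39 samples, sizes chosen
to exercise the full pipeline in seconds per fit.

What the generator does **not** emulate — and hence what passing tests do
not demonstrate about real data: taxonomic correlation structure (effects
on real communities cluster phylogenetically; planted effects here hit
arbitrary taxa), block or batch effects on counts, depth-abundance
correlations, zero-inflation beyond what the Dirichlet-multinomial itself
produces, and contamination. The placeholder taxonomy
(`synthetic_taxonomy()`) exists so filters and rank aggregation can be
exercised; it carries no signal.

## Filters and formats

Non-target removal drops chloroplast, mitochondrial and eukaryotic ASVs and
those without a kingdom-level classification, while ASVs merely unassigned
("NA") below kingdom are retained. The total-read filter keeps taxa with
**strictly more than** the threshold reads summed over all samples — the
">100 reads" phrasing taken literally. The rank-aggregation display filter
(default off, 0.05 when mimicking phylum barplots) removes individual ASVs
below the threshold per sample *before* summing within rank, so displayed
rows may sum to less than one; unassigned ranks pool into a literal "NA"
bin. TSV orientation is declared by the caller, never guessed — silent
transposes are a classic microbiome bug. Every written count table gets a
JSON provenance sidecar listing the filters and parameters applied, and
outputs are byte-stable across reruns.

## Known limitations

* Two-group comparisons only; covariate regression, phylogenetic priors and
  zero-inflated variants are out of scope.
* The random-walk sampler is adequate at desk scale ($K$ in the tens to few
  hundreds); at thousands of taxa a gradient-based sampler behind the same
  interface would be preferable.
* Per-group intensities mean overdispersion is not shared across groups;
  with very few replicates per group the $\theta$ posterior is wide and
  prior-sensitive.
* The interval-coverage and error bounds quantified in the acceptance suite
  are properties under the generator's own model; model misspecification on
  real data (e.g. taxon-specific overdispersion) is not covered.
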