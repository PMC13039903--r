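---
title: "Models and methods: diet-microbiome associations and co-occurrence network stability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: diet-microbiome associations and co-occurrence network stability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dietnet)
```

# Scope and data model

`dietnet` implements the analytical chain of a pediatric diet-microbiome
cohort study: per-sample dietary metrics, community-level ecology, per-taxon
association models, compositional co-occurrence networks, and
network-stability analysis, all orchestrated by `run_pipeline()` from a
single root seed. The central container is the `abundance_table`
(samples x taxa relative abundances, optional counts, per-taxon prevalence);
taxa observed in fewer than 10% of samples are removed before modeling
(`filter_prevalence()`, strict "below the floor" removal). We do **not**
renormalize rows after filtering — the retained abundances keep their
original scale, so a sample's retained fraction still reflects how much of
its community survived the filter; `renormalize = TRUE` restores closure for
users who prefer it.

# Dietary metrics

**Component indices.** Diet-quality indices of the children's-diet-index /
AHEI family are sums of component scores, each scored against an unhealthy
and a healthy cutoff. The engine (`compute_component_index()`) interpolates
linearly between cutoffs, awarding 0 at or beyond the unhealthy cutoff and
the component maximum at or beyond the healthy one. `range_optimal`
components (sensible for quantities with a biological optimum, such as
macronutrient energy shares) peak at the window midpoint and fall linearly
to zero at either cutoff; the published tables do not pin this shape down,
and the triangular profile is the simplest one consistent with "peaks inside
the window". The shipped CCDI-style configuration is **illustrative**: the
exact published component tables live in supplementary material, so the
engine is config-driven (14 components x 10 points, preserving the 0-140
theoretical range) and any exact table can be supplied as data.

**DII.** Each parameter's energy-adjusted intake is standardized against a
global reference mean and SD, mapped to a centered percentile
$2\Phi(z) - 1 \in (-1, 1)$, weighted by a literature-derived inflammatory
effect score, and summed. At the reference means the index is exactly 0;
the shipped reference table is again an illustrative stand-in keyed to the
generator's diet variables.

**HFD.** With consumption shares $s_i$ and health values $hv_i \in [0,1]$,
$\mathrm{HFD} = \left(\sum_i s_i\, hv_i\right)\left(1 - \sum_i s_i^2\right)$.
A single consumed food gives 0 (the Berry index vanishes); $k$ equal-share
foods with a common health value $hv$ give $hv\,(1 - 1/k)$.

**Insufficiencies and additives.** Micronutrient insufficiency counts
compare **absolute** daily intakes against dietary reference intakes
(strictly below counts; exactly at the DRI does not), since DRIs are
absolute recommendations. Emulsifier exposures (polysorbate-80,
carboxymethylcellulose, carrageenan) are annual grams divided by body
weight, plus their total; tertile cutpoints are computed across **all**
participants (type-7 quantiles, ties to the lower tertile) and then applied
within subgroups, so subgroup tertile sizes may be unequal — this mirrors
the exposure-stratification convention of the study design the package
serves.

**Energy adjustment** scales non-macronutrients to amounts per 1000 kcal;
macronutrients become percentages of energy via Atwater factors 4/4/9
(configurable; the convention is not stated in the source literature).

# Community ecology

Alpha diversity (observed richness, natural-log Shannon) is computed
*before* prevalence filtering, since filtering would truncate richness
artificially; this is configurable. Bray–Curtis dissimilarity
$d_{ij} = \sum |x_i - x_j| / \sum (x_i + x_j)$ is delegated to
`vegan::vegdist` and verified against a brute-force oracle in the tests.

**Dysbiosis score.** Each sample's score is its median Bray–Curtis
dissimilarity to the neurotypical reference samples, excluding the sample
itself and any sample from the same subject (the stricter of the two
readings of "excluding samples from the same subject"; with one sample per
subject the two coincide). The dysbiotic flag marks scores above the 90th
percentile of the reference-group scores. Quantiles use linear
interpolation (type 7) throughout the package; for $n$ distinct reference
scores this flags $n - \lceil 0.9n \rceil$ of the reference group itself
(10 of 100), which is the calibration the threshold is meant to encode.

**PERMANOVA.** `permanova()` implements sequential (Type I) sums of squares
on the Gower-centered squared-distance matrix, with terms in the configured
order and p-values from whole-row permutations,
$p = (1 + \#\{F^\ast \ge F\})/(1 + n_\mathrm{perm})$ (9999 by default).
Per-term $R^2$ sums to 1 with the residual. The implementation is checked
against `vegan::adonis2(by = "terms")` to 1e-9 on shared fixtures. A
perfectly explained distance matrix leaves a numerically-zero residual; we
clamp it so F degenerates to $+\infty$ instead of a rounding-sign artifact.

# Association engine

Abundances are CLR-transformed (pseudocount: half the smallest nonzero
relative abundance in the table; a log-total-sum alternative is available
via the `pseudocount` argument). Diet variables are standardized before
fitting so coefficients are comparable across panels — the source
convention is unstated, and z-scoring is the choice that makes
"coefficient per SD of exposure" well-defined. Per (taxon, diet variable)
pair we fit OLS with age, sex and gastrointestinal symptoms as adjustment
covariates, report two-sided Wald p-values, and apply Benjamini–Hochberg
correction **within each metadata panel** (indices / nutrients / food
groups / additives), matching per-panel reporting; flags are set at
q < 0.1 and q < 0.05. Features are ranked per panel by their number of
significant associations (ties: smallest minimum q, then lexicographic ID)
and the top 50 retained, with overlap counts between groups for Venn-style
summaries.

Diet-by-group effect modification uses
`microbe ~ diet + group + diet:group + covariates`, flagged at q < 0.2.
Group-size imbalance is addressed by greedy 1:1 nearest-neighbor matching:
exact on categorical variables, minimal age distance among exact candidates,
treated order shuffled by the seed, controls used at most once; a
standardized-mean-difference balance report is attached.

**Mediation.** The linear no-interaction mediation model is fit as
M ~ T (+C) and Y ~ T + M (+C); the ACME point estimate is the product of
the T→M and M→Y coefficients. Uncertainty is quasi-Bayesian: `nsim` draws
of each model's coefficients from their asymptotic normal sampling
distributions give ACME draws, a 95% percentile interval, and a two-sided
simulation p-value $2\min(\Pr(\le 0), \Pr(\ge 0))$ floored at 1/nsim.
Coverage of the true a·b is verified by simulation in the test suite.

**Predictability.** Random forests (1000 trees, default mtry) predict each
diet variable from the microbiome, five repeats of 10-fold
cross-validation; regression is scored by per-fold Spearman ρ, and
classification — on the **median-split** binary target, a binarization the
source leaves unstated and we therefore document prominently — by per-fold
AUC, with medians reported.

# SparCC networks

With log-ratio variances $t_{ij} = \mathrm{Var}\log(x_i/x_j)$ and basis
variances $\omega_i$, the sparsity approximation yields the linear system
$(D-2)\,\omega_i + \sum_j \omega_j = \sum_{j\ne i} t_{ij}$ and
$\rho_{ij} = (\omega_i + \omega_j - t_{ij}) / (2\sqrt{\omega_i\omega_j})$,
clipped to [−1, 1]. Strongly correlated pairs violate the sparsity
assumption, so the most-correlated pair above the exclusion threshold (0.1)
is removed from the system and the basis re-solved. The classic
implementation caps this loop at 10 iterations; that cap silently truncates
the exclusion whenever a correlated block contributes more than 10 strong
pairs (an 8-taxon block has 28), and the remaining violations bias the
whole matrix — on our planted-block fixtures, running the loop to
convergence cuts the planted-pair error threefold and pulls the null
background back under the estimation-noise floor. The default is therefore
exclusion to convergence (with a guard that never disconnects a taxon from
the system); a finite `excl_iters` reproduces the classic behavior. With
counts, each of
20 resamples draws fractions from a Dirichlet posterior (counts + 1) and
the final ρ is the elementwise median; plain fractions are
pseudocount-smoothed. Non-positive solved basis variances are clipped to a
small positive value with a warning.

**Significance.** Permutation p-values shuffle each taxon's sample vector
independently and recompute ρ on a closed-form single-resample fast path
(no exclusion loop — the permuted null rarely contains pairs whose exclusion
would change the solution, and the fast path is what makes 1000
permutations and 1000-replicate bootstraps tractable). Two conventions are
offered: the add-one pseudo-p $(1+x)/(1+B)$, whose minimum attainable value
floors the BH q at $m/(k(1+B))$ for $k$ significant pairs among $m$ — a
conservative choice under which the stringent dual criterion
(q < 0.005 and |r| > 0.5) is effectively unreachable at moderate $B$ — and
the classic SparCC script convention $x/B$, which can reach 0 and therefore
supports that criterion; `run_pipeline()` uses the latter so that the
reported networks behave like the published ones, while the conservative
convention remains the function default.

**Topology.** Networks keep taxon pairs passing the dual criterion; nodes
are endpoints of retained edges. The summary panel reports edges by sign,
vertices, average degree 2E/V, mean unweighted shortest path over connected
ordered pairs (unreachable pairs are ignored — these networks are routinely
disconnected), global transitivity (average-local clustering is a known
variant; we report the global form), Freeman-normalized degree
centralization together with the raw maximum degree (published
"centralization degree" values match neither variant exactly, so both are
exposed and neither is promised to reproduce that column), and modularity
from greedy modularity maximization on the positive-edge subgraph weighted
by |r|, counting modules with at least 2 vertices.

# Robustness

**Natural connectivity** $\bar\lambda = \ln\frac{1}{N}\sum_i e^{\lambda_i}$
over the adjacency eigenvalues is computed with log-sum-exp; an edgeless
graph gives exactly 0, and the index is monotone under edge addition.

**Attack simulation** removes nodes one at a time, recomputing
$\bar\lambda$ on the remaining induced subgraph: random mode averages
uniformly random orders over replicates with a 95% percentile band;
targeted mode uses the **static** initial-degree ranking (ties by node ID),
the literal reading of "node removal based on ranked degrees" — adaptive
re-ranking is available as an option. The percentile band is an ordinary
Monte-Carlo band over removal replicates; no posterior-sampling machinery
is involved in uniform node removal, so none is used. Curves are compared
pointwise on a common removal-fraction grid with a two-sided Wilcoxon
rank-sum test; identical curves are fully tied, where the tie-corrected
normal approximation is undefined, and we return p = 1.

**Bootstrap topology comparison.** Per stratum, samples are resampled with
replacement B = 1000 times and SparCC → threshold → metrics recomputed per
resample on the fast path. Per-resample networks threshold on |r| alone
(and the observed networks inside this comparison use the same rule, for
comparability): re-running a permutation test inside every bootstrap
replicate would multiply cost by the permutation count, and at these sample
sizes edges with |r| > 0.5 are essentially always significant at the
permutation test. For each metric and stratum pair, with bootstrap
differences $\Delta^\ast_b$, the default p-value is the two-tailed
percentile test $2\min(u, 1-u)$ with the mid-p tail
$u = (\#\{\Delta^\ast < 0\} + \tfrac12\#\{\Delta^\ast = 0\})/B$ (ties at
zero counted half, so discrete metrics with an atom at zero stay
calibrated). Efron's bias-corrected variant —
$z_0 = \Phi^{-1}(\#\{\Delta^\ast < \hat\Delta\}/B)$ with ties counted
half, $\tilde u = \Phi(\Phi^{-1}(u) - 2z_0)$, p =
$2\min(\tilde u, 1-\tilde u)$ — is available as `method = "bc"` but is
**not** the default: in calibration simulations on thresholded edge-count
metrics it rejects a true null 15–40% of the time at nominal 5%, at every
stratum size we tested. The mechanism is that resampling duplicates inflate
correlation estimates, shifting the bootstrap difference distribution away
from the observed difference; the bias correction reads that resampling
artifact as median bias of the estimator and doubles the apparent evidence
instead of removing it. The percentile test is calibrated (empirical
type-I 0–4%) and loses no practical power on planted dense-vs-sparse
contrasts at realistic stratum sizes. Degenerate difference distributions
return p = 1 with a flag. P-values are Holm-adjusted across the pairwise family
per metric and rendered as compact letters (insert-and-absorb: significant
pairs share no letter; non-significant pairs share one where consistently
possible). The default metric set for the resample loop excludes average
path length and modularity — both are well-defined per resample but
dominate runtime; they can be requested explicitly. Letters are compared
within diagnosis group by default when the pipeline stratifies by exposure;
cross-group letter families are a configuration choice.

# Synthetic cohorts and what the tests show

The generator draws latent log-abundances
$y \sim \mathcal N(\mu + \text{shifts}, \Sigma(\text{stratum}))$ with
block-structured correlation, closes to compositions, and draws multinomial
counts at the configured depth — the logistic-normal regime under which
SparCC's basis-correlation estimand is well-defined, which is what makes
"recovery of planted truth" a meaningful test. Planted truth lives on the
latent basis, not the closed composition. Group differences in network
topology are planted as different block structures per stratum (fewer or
weaker blocks for a "fragile" stratum), which induces the published style
of topology contrast directly. Defaults mirror the cohort the package is
designed around: 356 + 462 children, 27.3% female, ages 3–12, excess
gastrointestinal symptoms and medication use in the ASD stratum; diet
variables share a latent diet-quality factor; emulsifier annual intakes are
lognormal; mediation triples are T → M → Y with true ACME = a·b.

What passing tests on these cohorts do **not** show: real gut metagenomes
are sparser, heavier-tailed, and phylogenetically structured; real diet
measurements carry correlated reporting error; and real effect sizes are
smaller and confounded. The synthetic results certify the *machinery*
(estimators, error control, determinism), not field performance.

# Problem sizes and numerical choices

The packaged fixture used for end-to-end determinism is 200 samples x 60
taxa at depth 2e4 — large enough for non-trivial networks in every exposure
tertile, small enough that a full pipeline run (9999 PERMANOVA
permutations, 1000 SparCC permutations, 1000-replicate bootstraps, 5x10
random-forest folds at 1000 trees) completes in about two minutes on one
CPU. Test-suite simulations use 16–40 taxa and 30–500 samples; bootstrap
calibration runs use B = 200 over 200 replicate cohorts. Seeds for every
stochastic stage derive from one root seed via a string-hash scheme
(`derive_seed()`), which is what makes reruns bit-identical.

Other numerical conventions: quantiles are type 7 everywhere; SparCC ρ is
clipped to [−1, 1] and non-positive basis variances to 1e-10; the CLR
pseudocount is half the table-wide minimum nonzero abundance; BH families
are metadata panels (associations) or the upper triangle (networks); Holm
is used across pairwise bootstrap families; matching ties break on sample
ID; module detection breaks ties by node ID through the deterministic
greedy agglomeration.

# Known limitations

* The shipped CCDI/DII/DRI tables are illustrative stand-ins; exact
  published component tables must be supplied as configuration to reproduce
  published index values.
* The association engine implements the fixed-effects linear path only (no
  random effects or alternative normalizations of the full published
  association tool).
* The sulfur-diet score's component table is supplementary-only upstream;
  the generic component engine accepts it via configuration but none ships.
* Degree centralization is reported in two variants because the published
  variant is not identifiable from the source text.
* The conservative permutation-p convention cannot reach q < 0.005 at
  moderate permutation counts (see the SparCC section); users who need the
  stringent dual criterion should use the `"raw"` convention explicitly.
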