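# dietnet

Diet–microbiome association and co-occurrence network analysis for
pediatric cohort studies, with a synthetic-cohort generator that makes
every stage testable against known ground truth.

## What it is for

Cohort studies of children with and without autism spectrum disorder (ASD)
increasingly pair shotgun-metagenomic gut profiles with detailed dietary
assessments: diet-quality indices, nutrient intakes, food-group quantities
and food-additive (emulsifier) exposures. `dietnet` packages the full
analytical chain such a study needs:

* **Dietary metrics** — a config-driven component-index engine (e.g. a
  children's diet-quality index with theoretical range 0–140), the Dietary
  Inflammatory Index (DII; per parameter the standardized intake
  z = (x − μ)/σ is mapped to a centered percentile 2Φ(z) − 1 and summed with
  inflammatory effect weights), the healthy food diversity index
  (HFD = Σ sᵢ·hvᵢ × (1 − Σ sᵢ²), consumption shares times a Berry index),
  micronutrient-insufficiency counts against dietary reference intakes, and
  emulsifier exposures in g/kg body weight/year with population-wide
  tertiles.
* **Community ecology** — observed richness and Shannon diversity,
  Bray–Curtis dissimilarity, a dysbiosis score (a sample's median
  Bray–Curtis dissimilarity to the neurotypical reference set, flagged above
  the reference 90th percentile), and PERMANOVA variance partitioning with
  sequential sums of squares and whole-row permutations.
* **Association engine** — per-taxon ordinary-least-squares models of
  CLR-transformed abundances on standardized diet variables adjusted for
  age, sex and gastrointestinal symptoms, Benjamini–Hochberg q-values per
  metadata panel, diet×group interaction models, top-feature ranking with
  cross-group overlap counts, greedy 1:1 nearest-neighbor matching,
  quasi-Bayesian causal mediation (ACME = product of the treatment→mediator
  and mediator→outcome path coefficients), and random-forest
  diet-predictability scores (Spearman ρ / AUC over repeated 10-fold
  cross-validation).
* **Co-occurrence networks** — SparCC basis correlations
  (ρᵢⱼ = (ωᵢ + ωⱼ − tᵢⱼ) / 2√(ωᵢωⱼ) from log-ratio variances tᵢⱼ under the
  sparsity approximation, with iterative strong-pair exclusion and Dirichlet
  resampling), permutation significance, networks under the dual criterion
  q < 0.005 and |r| > 0.5, and the standard topology panel (edges by sign,
  vertices, average degree, path length, transitivity, degree
  centralization, modularity, module count).
* **Network robustness** — natural connectivity
  λ̄ = ln((1/N) Σ exp(λᵢ)) of the adjacency spectrum, random and
  degree-targeted node-removal attack curves with Wilcoxon comparisons, and
  bootstrap comparison of topology metrics across exposure strata
  (calibrated percentile test by default, Efron's bias-corrected variant as
  an option) rendered as compact letter displays.
* **Synthetic cohorts** — logistic-normal/multinomial compositions with
  block-structured basis correlations per stratum, group-level dysbiotic
  shifts, diet variables coupled to planted taxa (optionally in one stratum
  only), lognormal emulsifier exposures, and mediation triples with known
  ACME, so recovery is well-posed end to end.

## Worked example

```r
library(dietnet)

spec <- generator_spec(n_nonasd = 150, n_asd = 150, n_taxa = 40, depth = 5e4,
                       blocks = list(list(size = 8, rho = 0.75)),
                       shift_delta = 0)
cohort <- simulate_cohort(spec, seed = 102)

est <- sparcc_correlations(cohort$abundance, resamples = 20, seed = 1)
pairs <- which(upper.tri(diag(40)), arr.ind = TRUE)
in_block <- pairs[, 1] <= 8 & pairs[, 2] <= 8
mean(abs(est$rho[pairs[in_block, ]] - 0.75))   # 0.0140  planted-pair error
median(abs(est$rho[pairs[!in_block, ]]))       # 0.0327  off-block background

natural_connectivity(matrix(1, 3, 3) - diag(3))  # 0.9963107 (triangle graph)

tri <- simulate_mediation_triple(0.5, 0.4, 0.2, n = 2000,
                                 noise_sds = c(0.5, 0.5), seed = 7)
med <- run_mediation(tri$T, tri$M, tri$Y, nsim = 1000, seed = 1)
med$acme        # 0.1945  (true ACME = 0.5 x 0.4 = 0.20)
med$acme_ci     # 0.1707 0.2185
```

The SparCC estimate recovers the planted 0.75 basis-correlation block to
within ~0.014 while keeping the uncorrelated background near zero, and the
mediation machinery returns the product-of-paths ACME with a quasi-Bayesian
interval around the planted 0.20.

The full pipeline — diet metrics, ecology, associations, networks,
robustness, mediation, prediction — runs from one root seed:

```r
res <- run_pipeline(analysis_config(seed = 1), out_dir = "out")
```

writing one TSV per result table plus a JSON run manifest; reruns with the
same seed are bit-identical. A thin command-line wrapper is installed at
`inst/cli/dietnet.R` (`Rscript dietnet.R run --seed 1 --out DIR`,
`... simulate --seed 1 --out DIR`).

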