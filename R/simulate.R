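#' Generator specification for synthetic cohorts
#'
#' Defines the study conditions a synthetic cohort emulates: per-stratum
#' sample sizes, taxa count, block-structured basis correlations on the
#' latent log scale, a group-level mean shift on a subset of taxa (the
#' dysbiotic shift), diet variables coupled through a latent diet-quality
#' factor, planted diet-to-taxon effects (optionally restricted to one
#' stratum for interaction testing), lognormal emulsifier exposures, and
#' mediation coefficients. Defaults mirror a pediatric case-control cohort:
#' 356 neurotypical and 462 autistic children, 27.3% female, ages 3-12,
#' excess gastrointestinal symptoms in the autistic stratum.
#'
#' @param n_nonasd,n_asd samples per stratum.
#' @param n_taxa number of taxa D.
#' @param blocks list of blocks, each `list(size =, rho =)`, giving
#'   within-block basis correlation on the latent log scale; applied to both
#'   strata unless `blocks_asd` is given.
#' @param blocks_asd optional distinct block structure for the ASD stratum
#'   (used to plant topology differences between strata).
#' @param mu_log mean vector of latent log-abundances (length `n_taxa` or a
#'   single spread to draw from).
#' @param sigma_log latent log-abundance standard deviation.
#' @param depth sequencing depth (multinomial total per sample).
#' @param shift_taxa,shift_delta indices and size of the ASD group mean
#'   shift on the latent scale (drives the dysbiosis-score separation).
#' @param diet_effects data.frame with columns `taxon` (index), `diet`
#'   (variable name), `beta` (latent effect per SD of diet), `scope`
#'   (`"all"`, `"ASD"` or `"nonASD"`).
#' @param asd_fraction used only when drawing group labels jointly instead of
#'   fixed per-stratum sizes (`NULL` = fixed sizes).
#' @param female_fraction,gi_prob_nonasd,gi_prob_asd metadata marginals.
#' @param emulsifier_meanlog,emulsifier_sdlog lognormal annual-intake
#'   parameters (grams/year) shared by the three emulsifiers.
#' @param mediation list with `a`, `b`, `c_prime`, `sd_m`, `sd_y`.
#' @return a list of class `generator_spec`.
#' @export
generator_spec <- function(n_nonasd = 356, n_asd = 462, n_taxa = 150,
                           blocks = list(list(size = 8, rho = 0.75),
                                         list(size = 6, rho = 0.6)),
                           blocks_asd = NULL,
                           mu_log = NULL, sigma_log = 1,
                           depth = 1e5,
                           shift_taxa = NULL, shift_delta = 0.5,
                           diet_effects = NULL,
                           asd_fraction = NULL,
                           female_fraction = 0.273,
                           gi_prob_nonasd = 0.10, gi_prob_asd = 0.21,
                           emulsifier_meanlog = 0, emulsifier_sdlog = 1,
                           mediation = list(a = 0.5, b = 0.4, c_prime = 0.2,
                                            sd_m = 1, sd_y = 1)) {
  if (n_nonasd < 2 || n_asd < 2) stop("need at least 2 samples per stratum")
  stopifnot(n_taxa >= 4, depth >= 1)
  chk_blocks <- function(b) {
    if (is.null(b)) return(invisible())
    sizes <- vapply(b, `[[`, numeric(1), "size")
    rhos <- vapply(b, `[[`, numeric(1), "rho")
    if (sum(sizes) > n_taxa) stop("block sizes exceed number of taxa")
    if (any(rhos <= -1 | rhos >= 1)) stop("block correlations must be in (-1, 1)")
  }
  chk_blocks(blocks); chk_blocks(blocks_asd)
  if (is.null(shift_taxa)) shift_taxa <- seq_len(min(10L, n_taxa))
  structure(
    list(n_nonasd = n_nonasd, n_asd = n_asd, n_taxa = n_taxa,
         blocks = blocks, blocks_asd = blocks_asd,
         mu_log = mu_log, sigma_log = sigma_log, depth = depth,
         shift_taxa = shift_taxa, shift_delta = shift_delta,
         diet_effects = diet_effects, asd_fraction = asd_fraction,
         female_fraction = female_fraction,
         gi_prob_nonasd = gi_prob_nonasd, gi_prob_asd = gi_prob_asd,
         emulsifier_meanlog = emulsifier_meanlog,
         emulsifier_sdlog = emulsifier_sdlog,
         mediation = mediation),
    class = "generator_spec"
  )
}

block_correlation <- function(n_taxa, blocks) {
  R <- diag(n_taxa)
  at <- 1L
  for (b in blocks %||% list()) {
    idx <- seq.int(at, length.out = b$size)
    R[idx, idx] <- b$rho
    diag(R)[idx] <- 1
    at <- at + b$size
  }
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) stop("assembled correlation matrix is not positive semi-definite")
  R
}

#' Simulate sample metadata
#'
#' @param spec a `generator_spec`.
#' @param seed integer seed.
#' @return a data.frame with sample_id, subject_id, group, age, sex,
#'   gi_symptoms, bristol_type, bmi, medication.
#' @export
simulate_metadata <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "generator_spec"))
  set.seed(seed)
  if (!is.null(spec$asd_fraction)) {
    n <- spec$n_nonasd + spec$n_asd
    group <- ifelse(stats::runif(n) < spec$asd_fraction, "ASD", "nonASD")
  } else {
    group <- c(rep("nonASD", spec$n_nonasd), rep("ASD", spec$n_asd))
  }
  n <- length(group)
  gi_p <- ifelse(group == "ASD", spec$gi_prob_asd, spec$gi_prob_nonasd)
  data.frame(
    sample_id = sprintf("S%04d", seq_len(n)),
    subject_id = sprintf("P%04d", seq_len(n)),
    group = group,
    age = round(stats::runif(n, 3, 12), 1),
    sex = ifelse(stats::runif(n) < spec$female_fraction, "F", "M"),
    gi_symptoms = as.integer(stats::runif(n) < gi_p),
    bristol_type = sample(1:7, n, replace = TRUE,
                          prob = c(.15, .1, .3, .3, .05, .05, .05)),
    bmi = round(stats::rlnorm(n, log(16.3), 0.15), 1),
    medication = as.integer(stats::runif(n) < ifelse(group == "ASD", .25, .05)),
    stringsAsFactors = FALSE
  )
}

#' Simulate a diet table
#'
#' Energy, nutrients and food-group quantities are coupled through a latent
#' diet-quality factor so that index scores and individual nutrients carry a
#' shared signal; emulsifier annual intakes are lognormal and divided by body
#' weight downstream. The latent factor is returned as attribute
#' `"diet_factor"` so composition simulation can couple planted taxa to it.
#'
#' @param spec a `generator_spec`.
#' @param metadata output of [simulate_metadata()].
#' @param seed integer seed.
#' @return diet data.frame, one row per sample.
#' @export
simulate_diet <- function(spec, metadata, seed = 1) {
  stopifnot(inherits(spec, "generator_spec"))
  if (spec$emulsifier_sdlog <= 0) stop("emulsifier scale parameter must be positive")
  set.seed(seed + 1L)
  n <- nrow(metadata)
  h <- stats::rnorm(n)            # latent diet-quality factor
  nz <- function(base, load, sd) pmax(base + load * h + stats::rnorm(n, 0, sd), 0)
  diet <- data.frame(
    sample_id = metadata$sample_id,
    energy_kcal = pmax(stats::rnorm(n, 1800, 250), 800),
    protein_g = nz(55, 6, 8),
    carbohydrate_g = nz(240, -10, 25),
    fat_g = nz(65, -4, 9),
    fiber_g = nz(14, 3, 3),
    starch_g = nz(120, -12, 18),
    magnesium_mg = nz(230, 30, 40),
    zinc_mg = nz(8, 1.2, 1.5),
    vitamin_c_mg = nz(70, 18, 20),
    vitamin_d_ug = nz(6, 1.5, 2),
    calcium_mg = nz(650, 90, 120),
    iron_mg = nz(11, 1.5, 2),
    vegetables_g = nz(180, 45, 40),
    fruits_g = nz(150, 40, 40),
    beans_g = nz(40, 12, 15),
    whole_grains_g = nz(60, 20, 20),
    snacks_g = nz(90, -25, 25),
    sugary_drinks_ml = nz(180, -60, 60),
    p80_g_yr = stats::rlnorm(n, spec$emulsifier_meanlog, spec$emulsifier_sdlog),
    cmc_g_yr = stats::rlnorm(n, spec$emulsifier_meanlog, spec$emulsifier_sdlog),
    crn_g_yr = stats::rlnorm(n, spec$emulsifier_meanlog, spec$emulsifier_sdlog),
    bodyweight_kg = pmax(stats::rnorm(n, 30, 7), 12),
    stringsAsFactors = FALSE
  )
  attr(diet, "diet_factor") <- h
  diet
}

#' Simulate compositional abundances with known ground truth
#'
#' Latent log-abundances are multivariate normal with block-structured
#' correlation (logistic-normal basis, the regime SparCC assumes); the ASD
#' stratum receives a mean shift on `shift_taxa` and, when planted,
#' diet-coupled shifts on chosen taxa. Counts are multinomial at the
#' configured depth, and relative abundances are re-derived from counts.
#'
#' @param spec a `generator_spec`.
#' @param metadata output of [simulate_metadata()].
#' @param seed integer seed.
#' @param diet optional output of [simulate_diet()]; required when
#'   `spec$diet_effects` is non-NULL.
#' @return list with `table` (an `abundance_table` with counts), `truth`
#'   (class `synthetic_truth`: per-stratum basis correlation matrices,
#'   planted effects, shift taxa, latent matrix `y`).
#' @export
simulate_composition <- function(spec, metadata, seed = 1, diet = NULL) {
  stopifnot(inherits(spec, "generator_spec"))
  set.seed(seed + 2L)
  D <- spec$n_taxa
  n <- nrow(metadata)
  mu <- spec$mu_log %||% stats::rnorm(D, 0, 1.2)
  R_non <- block_correlation(D, spec$blocks)
  R_asd <- if (is.null(spec$blocks_asd)) R_non else
    block_correlation(D, spec$blocks_asd)
  chol_non <- chol(R_non * spec$sigma_log^2 + diag(1e-10, D))
  chol_asd <- chol(R_asd * spec$sigma_log^2 + diag(1e-10, D))
  z <- matrix(stats::rnorm(n * D), n, D)
  is_asd <- metadata$group == "ASD"
  y <- matrix(0, n, D)
  if (any(!is_asd)) y[!is_asd, ] <- z[!is_asd, , drop = FALSE] %*% chol_non
  if (any(is_asd)) y[is_asd, ] <- z[is_asd, , drop = FALSE] %*% chol_asd
  y <- sweep(y, 2, mu, "+")
  y[is_asd, spec$shift_taxa] <- y[is_asd, spec$shift_taxa] + spec$shift_delta
  if (!is.null(spec$diet_effects)) {
    if (is.null(diet)) stop("diet table required to plant diet effects")
    for (k in seq_len(nrow(spec$diet_effects))) {
      ef <- spec$diet_effects[k, ]
      dv <- diet[[ef$diet]]
      zdv <- as.numeric(scale(dv))
      rows <- switch(ef$scope %||% "all",
                     all = rep(TRUE, n), ASD = is_asd, nonASD = !is_asd,
                     stop("unknown effect scope: ", ef$scope))
      y[rows, ef$taxon] <- y[rows, ef$taxon] + ef$beta * zdv[rows]
    }
  }
  x <- exp(y)
  x <- x / rowSums(x)
  counts <- t(vapply(seq_len(n),
                     function(i) stats::rmultinom(1, spec$depth, x[i, ])[, 1],
                     numeric(D)))
  taxa <- sprintf("T%03d", seq_len(D))
  samples <- metadata$sample_id
  dimnames(counts) <- list(samples, taxa)
  rel <- counts / rowSums(counts)
  keep_all <- rowSums(counts) > 0
  tab <- abundance_table(rel[keep_all, , drop = FALSE],
                         counts = counts[keep_all, , drop = FALSE])
  truth <- structure(
    list(R_nonasd = R_non, R_asd = R_asd, mu_log = mu,
         shift_taxa = spec$shift_taxa, shift_delta = spec$shift_delta,
         diet_effects = spec$diet_effects,
         acme = spec$mediation$a * spec$mediation$b,
         latent_y = y, composition = x),
    class = "synthetic_truth"
  )
  list(table = tab, truth = truth)
}

#' Simulate a treatment-mediator-outcome triple with known ACME
#'
#' T is standard normal, M = a*T + noise, Y = c_prime*T + b*M + noise; the
#' true average causal mediation effect is a*b by construction.
#'
#' @param a,b,c_prime path coefficients.
#' @param n sample size (>= 10).
#' @param noise_sds length-2 positive vector: mediator and outcome noise SD.
#' @param seed integer seed.
#' @return data.frame with columns T, M, Y; true ACME in attribute `"acme"`.
#' @export
simulate_mediation_triple <- function(a, b, c_prime, n, noise_sds = c(1, 1),
                                      seed = 1) {
  if (n < 10) stop("n must be at least 10")
  if (any(noise_sds <= 0)) stop("noise SDs must be positive")
  set.seed(seed + 3L)
  Tr <- stats::rnorm(n)
  M <- a * Tr + stats::rnorm(n, 0, noise_sds[1])
  Y <- c_prime * Tr + b * M + stats::rnorm(n, 0, noise_sds[2])
  out <- data.frame(T = Tr, M = M, Y = Y)
  attr(out, "acme") <- a * b
  out
}

#' Simulate a full cohort (metadata, diet, composition, truth)
#'
#' Convenience wrapper running the three generators under the shared-seed
#' protocol so planted diet effects are consistent between tables.
#'
#' @param spec a `generator_spec`.
#' @param seed integer root seed.
#' @return list of class `synthetic_cohort`: `metadata`, `diet`, `abundance`,
#'   `truth`.
#' @export
simulate_cohort <- function(spec = generator_spec(), seed = 1) {
  md <- simulate_metadata(spec, seed)
  dt <- simulate_diet(spec, md, seed)
  comp <- simulate_composition(spec, md, seed, diet = dt)
  keep <- comp$table$sample_ids
  structure(
    list(metadata = md[match(keep, md$sample_id), , drop = FALSE],
         diet = dt[match(keep, dt$sample_id), , drop = FALSE],
         abundance = comp$table, truth = comp$truth),
    class = "synthetic_cohort"
  )
}
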